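# Saturating (non-convex) fusion penalty optimized by iterated local
# quadratic approximation (LQA). The penalty on a coefficient difference of
# magnitude theta is quadratic near the origin, tapers from a/2 and plateaus
# at a; beyond a its derivative is zero, so sufficiently dissimilar
# coefficient pairs are effectively "unfused" and incur no further penalty.
# This is an MCP-like penalty adapted to differences: L2 rather than L1 at
# the origin, since there is no reason to expect most differences to be
# exactly zero.

#' Saturating fusion penalty
#'
#' @param lam Base penalty scale (>= 0). In the quadratic region the LQA
#'   weight is `lam / 2`, so setting `lam = 2 * lambda_s` makes adaptive
#'   fusion at small differences reproduce fused L2 with fusion weight
#'   `lambda_s` exactly.
#' @param a Saturation point (> 0): differences beyond `a` incur no further
#'   penalty.
#' @return An object of class `saturating_penalty`.
#' @export
saturating_penalty <- function(lam, a) {
  stopifnot(lam >= 0, a > 0)
  structure(list(lam = lam, a = a), class = "saturating_penalty")
}

#' Derivative of the saturating penalty
#'
#' Piecewise linear and continuous: `lam * theta` for `theta <= a/2`,
#' `lam * (a - theta)` for `a/2 < theta <= a`, and 0 beyond `a`. Its maximum
#' is `lam * a / 2` at `theta = a/2`.
#'
#' @param theta Non-negative difference magnitude(s); callers pass absolute
#'   differences.
#' @param pen A [saturating_penalty()].
#' @return Derivative value(s), vectorized over `theta`.
#' @export
penalty_derivative <- function(theta, pen) {
  stopifnot(inherits(pen, "saturating_penalty"))
  if (any(theta < 0)) stop("theta must be non-negative")
  ifelse(theta <= pen$a / 2, pen$lam * theta,
         pmax(pen$lam * (pen$a - theta), 0))
}

#' Value of the saturating penalty
#'
#' The integral of [penalty_derivative()]: `lam * theta^2 / 2` up to `a/2`,
#' then a tapering quadratic, constant at `lam * a^2 / 4` beyond `a`.
#'
#' @inheritParams penalty_derivative
#' @return Penalty value(s), vectorized over `theta`.
#' @export
penalty_value <- function(theta, pen) {
  stopifnot(inherits(pen, "saturating_penalty"))
  if (any(theta < 0)) stop("theta must be non-negative")
  lam <- pen$lam; a <- pen$a
  ifelse(theta <= a / 2,
         lam * theta^2 / 2,
         ifelse(theta <= a,
                lam * a^2 / 8 + lam * (a * theta - theta^2 / 2 - 3 * a^2 / 8),
                lam * a^2 / 4))
}

#' Local quadratic approximation weight
#'
#' The per-constraint quadratic weight `p'(theta) / (2 theta)` that matches
#' the saturating penalty's gradient at the current iterate. At `theta = 0`
#' the limit `lam / 2` is used; for `theta >= a` the weight is 0 and the
#' constraint is effectively removed.
#'
#' @inheritParams penalty_derivative
#' @return Quadratic weight(s), vectorized over `theta`.
#' @export
lqa_weight <- function(theta, pen) {
  stopifnot(inherits(pen, "saturating_penalty"))
  if (any(theta < 0)) stop("theta must be non-negative")
  out <- numeric(length(theta))
  zero <- theta == 0
  out[zero] <- pen$lam / 2
  mid <- !zero & theta < pen$a
  out[mid] <- penalty_derivative(theta[mid], pen) / (2 * theta[mid])
  out # theta >= a stays 0
}

#' Select the saturation point from independently fit networks
#'
#' Sets `a` to a percentile (linear-interpolation convention, R quantile
#' type 7) of the absolute differences between fused coefficient pairs in
#' networks fit without fusion. The chosen percentile expresses the working
#' hypothesis for the fraction of constraints that should remain fused: at
#' the 60th percentile roughly 40% of constraints start in the saturated
#' zone and are candidates for unfusing.
#'
#' @param networks_independent A `network_coefficients` object fit with
#'   `lambda_s = 0`.
#' @param cs A non-empty `constraint_set`.
#' @param percentile Percentile in (0, 100); default 60.
#' @return The saturation point `a`.
#' @export
select_a <- function(networks_independent, cs, percentile = 60) {
  if (is.null(cs) || nrow(cs) == 0) {
    stop("cannot select `a` from an empty constraint set")
  }
  stopifnot(percentile > 0, percentile < 100)
  d <- abs(constraint_differences(cs, networks_independent))
  unname(stats::quantile(d, percentile / 100, type = 7))
}

#' Adaptive fusion by iterated local quadratic approximation
#'
#' Alternates between (1) computing each constraint's current difference
#' magnitude theta from the networks (theta = 0 for all constraints at the
#' first iteration, so the first solve equals fused L2 in the quadratic
#' regime), (2) setting each constraint's effective weight to
#' [lqa_weight()], and (3) solving the resulting convex fused-L2 problem
#' exactly, until the maximum absolute coefficient change falls below
#' `cfg$tol` or `cfg$max_iter` is reached. Because the LQA weight is
#' non-increasing in theta, each quadratic surrogate majorizes the
#' saturating penalty and the adaptive objective is non-increasing across
#' iterations. Constraints whose final effective weight is zero (theta >= a
#' at convergence) are reported as unfused.
#'
#' @inheritParams solve_fused_direct
#' @param pen A [saturating_penalty()]; defaults to
#'   `saturating_penalty(2 * cfg$lambda_s, a)` scale matching when `lam` is
#'   `NULL`.
#' @return An object of class `adaptive_result`: list with `networks`,
#'   `constraint_weights` (final effective per-constraint fusion weights),
#'   `theta` (final difference magnitudes), `unfused` (logical per
#'   constraint), `iterations`, `converged` and `objective` (the adaptive
#'   objective at each LQA iterate, non-increasing).
#' @export
solve_adaptive <- function(tasks, cs, cfg, pen) {
  tasks <- as_task_list(tasks)
  stopifnot(inherits(pen, "saturating_penalty"))
  if (is.null(cs) || nrow(cs) == 0) {
    stop("adaptive fusion requires a non-empty constraint set")
  }

  base_w <- cs$weight
  theta <- rep(0, nrow(cs)) # theta(0) = 0: first solve is fully fused
  networks <- NULL
  prev <- NULL
  converged <- FALSE
  iter <- 0L
  obj_history <- numeric(0)

  repeat {
    iter <- iter + 1L
    w_eff <- base_w * lqa_weight(theta, pen)
    cs_t <- cs
    cs_t$weight <- w_eff
    cfg_t <- cfg
    cfg_t$lambda_s <- 1 # effective weights carry the full fusion scale
    networks <- solve_fused_direct(tasks, cs_t, cfg_t)
    theta <- abs(constraint_differences(cs, networks))
    obj_history[iter] <- adaptive_objective(tasks, cs, cfg, networks, pen)

    if (!is.null(prev)) {
      maxdiff <- max(vapply(names(networks), function(nm) {
        max(abs(networks[[nm]] - prev[[nm]]))
      }, numeric(1)))
      if (maxdiff < cfg$tol) { converged <- TRUE; break }
    }
    if (iter >= cfg$max_iter) break
    prev <- networks
  }

  w_final <- base_w * lqa_weight(theta, pen)
  structure(
    list(
      networks = networks,
      constraint_weights = w_final,
      theta = theta,
      unfused = w_final == 0,
      iterations = iter,
      converged = converged,
      objective = obj_history
    ),
    class = "adaptive_result"
  )
}

#' @export
print.adaptive_result <- function(x, ...) {
  cat("adaptive_result: ", sum(x$unfused), "/", length(x$unfused),
      " constraints unfused after ", x$iterations, " iterations (",
      if (x$converged) "converged" else "NOT converged", ")\n", sep = "")
  invisible(x)
}

#' Adaptive-fusion objective (saturating penalty substituted)
#'
#' Residual plus ridge plus the saturating penalty summed over constraints;
#' the quantity the LQA iteration descends.
#'
#' @inheritParams fused_objective
#' @param pen A [saturating_penalty()].
#' @return A scalar objective value.
#' @export
adaptive_objective <- function(tasks, cs, cfg, networks, pen) {
  cfg0 <- cfg
  cfg0$lambda_s <- 0
  base <- fused_objective(tasks, NULL, cfg0, networks)
  d <- abs(constraint_differences(cs, networks))
  base + sum(cs$weight * penalty_value(d, pen))
}
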