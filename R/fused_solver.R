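# Multi-output ridge regression with pairwise L2 fusion penalties.
#
# Objective, over sources S with design X_S, response Y_S and network beta_S:
#   sum_S ||X_S beta_S - Y_S||^2 + lambda_r * sum kappa_c beta_c^2
#     + lambda_s * sum_constraints w (beta_left - beta_right)^2
# Self interactions (TF j on gene j) are dropped from each response's
# predictor set before solving and reported as structural zeros.

#' Solver configuration
#'
#' @param lambda_r Ridge penalty weight (>= 0; > 0 required for a unique
#'   solution on under-determined data).
#' @param lambda_s Fusion penalty weight (>= 0).
#' @param prior_relax Multiplier in (0, 1] applied to `lambda_r` for
#'   coefficients listed in `priors`, relaxing shrinkage on interactions with
#'   prior evidence. Default 0.1.
#' @param priors Optional named list (by source id) of data frames with
#'   columns `tf`, `gene` naming prior-known interactions.
#' @param max_iter Maximum iterations for the iterative and adaptive solvers.
#' @param tol Convergence tolerance on the maximum absolute coefficient
#'   change.
#' @param component_size_limit Components with more coefficients than this are
#'   routed to the iterative solver by [solve_fused()].
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(lambda_r = 1, lambda_s = 0, prior_relax = 0.1,
                          priors = NULL, max_iter = 50, tol = 1e-6,
                          component_size_limit = 5000) {
  stopifnot(lambda_r >= 0, lambda_s >= 0,
            prior_relax > 0, prior_relax <= 1,
            max_iter >= 1, tol > 0, component_size_limit >= 1)
  structure(
    list(lambda_r = lambda_r, lambda_s = lambda_s,
         prior_relax = prior_relax, priors = priors,
         max_iter = as.integer(max_iter), tol = tol,
         component_size_limit = component_size_limit),
    class = "solver_config"
  )
}

# kappa multiplier matrix (TFs x genes) for one source
kappa_matrix <- function(task, cfg) {
  K <- matrix(1, length(task$tf_ids), length(task$gene_ids),
              dimnames = list(task$tf_ids, task$gene_ids))
  pr <- cfg$priors[[task$source_id]]
  if (!is.null(pr) && nrow(pr) > 0) {
    keep <- pr$tf %in% task$tf_ids & pr$gene %in% task$gene_ids
    pr <- pr[keep, , drop = FALSE]
    K[cbind(match(pr$tf, task$tf_ids), match(pr$gene, task$gene_ids))] <-
      cfg$prior_relax
  }
  K
}

empty_networks <- function(tasks) {
  tasks <- as_task_list(tasks)
  nets <- lapply(tasks, function(t) {
    matrix(0, length(t$tf_ids), length(t$gene_ids),
           dimnames = list(t$tf_ids, t$gene_ids))
  })
  structure(nets, class = "network_coefficients")
}

#' @export
print.network_coefficients <- function(x, ...) {
  cat("network_coefficients over", length(x), "source(s):\n")
  for (nm in names(x)) {
    cat("  ", nm, ": ", nrow(x[[nm]]), " TFs x ", ncol(x[[nm]]),
        " genes\n", sep = "")
  }
  invisible(x)
}

#' Build the augmented least-squares system for one constraint component
#'
#' Stacks, per response in the component, its source's design block
#' (diagonal concatenation), then ridge rows `sqrt(lambda_r * kappa)` on the
#' coefficient diagonal, then one row per fusion constraint internal to the
#' component carrying `+sqrt(lambda_s * w)` and `-sqrt(lambda_s * w)` at the
#' fused coefficient positions. The response vector concatenates the
#' corresponding Y columns, padded with zeros for all penalty rows. The
#' square-root scaling makes the squared residual of a penalty row reproduce
#' `lambda_r * kappa * beta^2` and `lambda_s * w * (beta_i - beta_j)^2`
#' exactly.
#'
#' @param component Data frame with columns `source`, `gene` (one component
#'   from [constraint_components()]).
#' @param tasks List of `regression_task` objects.
#' @param cs A `constraint_set` (or `NULL`).
#' @param cfg A [solver_config()].
#' @return List with the augmented design `A`, response `b`, and `index`, a
#'   data frame mapping columns to (source, tf, gene).
#' @export
build_augmented_system <- function(component, tasks, cs, cfg) {
  tasks <- as_task_list(tasks)
  idx <- do.call(rbind, lapply(seq_len(nrow(component)), function(i) {
    src <- component$source[i]; gene <- component$gene[i]
    task <- tasks[[src]]
    if (is.null(task)) stop("component references unknown source: ", src)
    tfs <- setdiff(task$tf_ids, gene) # self interaction dropped
    data.frame(source = src, tf = tfs, gene = gene, resp = i,
               stringsAsFactors = FALSE)
  }))
  idx$col <- seq_len(nrow(idx))
  ncoef <- nrow(idx)

  n_data <- sum(vapply(seq_len(nrow(component)), function(i) {
    nrow(tasks[[component$source[i]]]$X)
  }, numeric(1)))

  internal <- NULL
  if (!is.null(cs) && nrow(cs) > 0) {
    comp_resp <- resp_key(component$source, component$gene)
    in_comp <- resp_key(cs$source_a, cs$gene_a) %in% comp_resp &
      resp_key(cs$source_b, cs$gene_b) %in% comp_resp
    straddle <- xor(resp_key(cs$source_a, cs$gene_a) %in% comp_resp,
                    resp_key(cs$source_b, cs$gene_b) %in% comp_resp)
    if (any(straddle)) {
      stop("internal error: constraint crosses component boundary; ",
           "component decomposition is inconsistent")
    }
    internal <- cs[in_comp, , drop = FALSE]
  }
  n_cons <- if (is.null(internal)) 0L else nrow(internal)

  A <- matrix(0, n_data + ncoef + n_cons, ncoef)
  b <- numeric(nrow(A))

  r0 <- 0L
  for (i in seq_len(nrow(component))) {
    task <- tasks[[component$source[i]]]
    rows <- r0 + seq_len(nrow(task$X))
    cols <- idx$col[idx$resp == i]
    A[rows, cols] <- task$X[, idx$tf[idx$resp == i], drop = FALSE]
    b[rows] <- task$Y[, component$gene[i]]
    r0 <- r0 + nrow(task$X)
  }

  kap <- vapply(seq_len(ncoef), function(j) {
    pr <- cfg$priors[[idx$source[j]]]
    if (!is.null(pr) && nrow(pr) > 0 &&
        any(pr$tf == idx$tf[j] & pr$gene == idx$gene[j])) {
      cfg$prior_relax
    } else 1
  }, numeric(1))
  A[cbind(n_data + seq_len(ncoef), seq_len(ncoef))] <-
    sqrt(cfg$lambda_r * kap)

  if (n_cons > 0) {
    ck <- stats::setNames(idx$col,
                          coef_key(idx$source, idx$tf, idx$gene))
    ca <- ck[coef_key(internal$source_a, internal$tf_a, internal$gene_a)]
    cb <- ck[coef_key(internal$source_b, internal$tf_b, internal$gene_b)]
    if (anyNA(ca) || anyNA(cb)) {
      stop("internal error: constraint references a coefficient outside ",
           "the component (possibly a structurally excluded self ",
           "interaction)")
    }
    s <- sqrt(cfg$lambda_s * internal$weight)
    rows <- n_data + ncoef + seq_len(n_cons)
    A[cbind(rows, ca)] <- s
    A[cbind(rows, cb)] <- A[cbind(rows, cb)] - s # robust if ca == cb impossible
  }

  list(A = A, b = b, index = idx)
}

solve_ls <- function(A, b, lambda_r) {
  fit <- stats::lm.fit(A, b)
  beta <- fit$coefficients
  if (anyNA(beta)) {
    if (lambda_r <= 0) {
      stop("augmented system is singular; set lambda_r > 0 to regularize")
    }
    stop("internal error: singular augmented system despite lambda_r > 0")
  }
  beta
}

# fast path: per-response ridge with self-masking, no fusion
solve_ridge_single <- function(task, cfg, XtX = NULL, XtY = NULL) {
  X <- task$X
  if (is.null(XtX)) XtX <- crossprod(X)
  if (is.null(XtY)) XtY <- crossprod(X, task$Y)
  p <- ncol(X)
  K <- kappa_matrix(task, cfg)
  beta <- matrix(0, p, ncol(task$Y),
                 dimnames = list(task$tf_ids, task$gene_ids))
  for (g in seq_along(task$gene_ids)) {
    gene <- task$gene_ids[g]
    keep <- which(task$tf_ids != gene)
    M <- XtX[keep, keep, drop = FALSE]
    diag(M) <- diag(M) + cfg$lambda_r * K[keep, g]
    sol <- tryCatch(solve(M, XtY[keep, g]), error = function(e) NULL)
    if (is.null(sol)) {
      if (cfg$lambda_r <= 0) {
        stop("singular system for gene '", gene,
             "'; set lambda_r > 0 to regularize")
      }
      stop("internal error: singular ridge system despite lambda_r > 0")
    }
    beta[keep, g] <- sol
  }
  beta
}

#' Solve the fused ridge problem exactly by componentwise augmented systems
#'
#' Minimizes the convex fused objective (residual + ridge + pairwise L2
#' fusion) exactly, solving each constraint component as an independent
#' augmented least-squares problem via a QR factorization. Responses with no
#' constraints are solved by the per-response ridge closed form.
#'
#' @param tasks List of `regression_task` objects (standardize first with
#'   [standardize_predictors()] so the penalties act on a common scale).
#' @param cs A `constraint_set` or `NULL`.
#' @param cfg A [solver_config()].
#' @return A `network_coefficients` object: one TFs x genes matrix per
#'   source, with structural zeros on self interactions.
#' @export
solve_fused_direct <- function(tasks, cs = NULL, cfg = solver_config()) {
  tasks <- as_task_list(tasks)
  nets <- empty_networks(tasks)

  if (is.null(cs) || nrow(cs) == 0 || cfg$lambda_s == 0) {
    for (nm in names(tasks)) {
      nets[[nm]] <- solve_ridge_single(tasks[[nm]], cfg)
    }
    return(nets)
  }

  comps <- constraint_components(cs, tasks)
  constrained_resp <- unique(c(resp_key(cs$source_a, cs$gene_a),
                               resp_key(cs$source_b, cs$gene_b)))
  # a singleton component may still carry a within-response constraint
  is_free <- vapply(comps, function(comp) {
    nrow(comp) == 1 &&
      !(resp_key(comp$source, comp$gene) %in% constrained_resp)
  }, logical(1))

  # batch all unconstrained responses per source through the closed form
  single <- do.call(rbind, comps[is_free])
  if (!is.null(single) && nrow(single) > 0) {
    for (nm in unique(single$source)) {
      genes <- single$gene[single$source == nm]
      t_sub <- tasks[[nm]]
      full_beta <- solve_ridge_single(t_sub, cfg)
      nets[[nm]][, genes] <- full_beta[, genes]
    }
  }

  for (comp in comps[!is_free]) {
    sys <- build_augmented_system(comp, tasks, cs, cfg)
    beta <- solve_ls(sys$A, sys$b, cfg$lambda_r)
    for (j in seq_len(nrow(sys$index))) {
      nets[[sys$index$source[j]]][sys$index$tf[j], sys$index$gene[j]] <-
        beta[j]
    }
  }
  nets
}

# adjacency of constraints per response, for the iterative solver
constraint_adjacency <- function(cs, tasks) {
  tasks <- as_task_list(tasks)
  if (is.null(cs) || nrow(cs) == 0) return(list())
  both <- rbind(
    data.frame(src = cs$source_a, tf = cs$tf_a, gene = cs$gene_a,
               psrc = cs$source_b, ptf = cs$tf_b, pgene = cs$gene_b,
               w = cs$weight, stringsAsFactors = FALSE),
    data.frame(src = cs$source_b, tf = cs$tf_b, gene = cs$gene_b,
               psrc = cs$source_a, ptf = cs$tf_a, pgene = cs$gene_a,
               w = cs$weight, stringsAsFactors = FALSE)
  )
  split(both, resp_key(both$src, both$gene))
}

#' Solve the fused ridge problem along a fusion path by Jacobi iteration
#'
#' For each fusion weight in `lambda_s_grid` (ascending), iterates
#' per-response ridge solves in which each fused coefficient is pulled toward
#' its partner's value from the previous iterate, until the maximum absolute
#' coefficient change drops below `cfg$tol` or `cfg$max_iter` is reached.
#' Each grid value is warm-started from the previous solution. Because the
#' objective is convex and the per-response subproblems use the previous
#' iterate (parallel updates), the fixed point is the global minimizer and
#' the converged result matches [solve_fused_direct()].
#'
#' @inheritParams solve_fused_direct
#' @param lambda_s_grid Increasing vector of fusion weights.
#' @return A list of `network_coefficients`, one per grid value, each with
#'   attributes `converged`, `iterations` and `lambda_s`. Non-convergence is
#'   flagged with a warning, never silently.
#' @export
solve_fused_iterative <- function(tasks, cs = NULL, cfg = solver_config(),
                                  lambda_s_grid = cfg$lambda_s) {
  tasks <- as_task_list(tasks)
  if (is.unsorted(lambda_s_grid)) {
    stop("lambda_s_grid must be sorted ascending")
  }
  adj <- constraint_adjacency(cs, tasks)

  # per-source precomputations
  pre <- lapply(tasks, function(t) {
    list(XtX = crossprod(t$X), XtY = crossprod(t$X, t$Y),
         K = kappa_matrix(t, cfg))
  })

  # warm start at the independent ridge solution
  beta <- solve_fused_direct(tasks, NULL, cfg)

  out <- vector("list", length(lambda_s_grid))
  for (li in seq_along(lambda_s_grid)) {
    ls <- lambda_s_grid[li]
    if (ls == 0 || length(adj) == 0) {
      res <- solve_fused_direct(tasks, NULL, cfg)
      attr(res, "converged") <- TRUE
      attr(res, "iterations") <- 1L
      attr(res, "lambda_s") <- ls
      out[[li]] <- res
      beta <- res
      next
    }

    # Cholesky factors are fixed per (response, lambda_s): only the RHS
    # changes across Jacobi sweeps.
    chols <- lapply(names(tasks), function(nm) {
      t <- tasks[[nm]]; p <- pre[[nm]]
      lapply(seq_along(t$gene_ids), function(g) {
        gene <- t$gene_ids[g]
        keep <- which(t$tf_ids != gene)
        M <- p$XtX[keep, keep, drop = FALSE]
        dg <- cfg$lambda_r * p$K[keep, g]
        a <- adj[[resp_key(nm, gene)]]
        if (!is.null(a)) {
          add <- tapply(ls * a$w, a$tf, sum)
          pos <- match(names(add), t$tf_ids[keep])
          ok <- !is.na(pos)
          dg[pos[ok]] <- dg[pos[ok]] + add[ok]
        }
        diag(M) <- diag(M) + dg
        list(R = chol(M), keep = keep)
      })
    })
    names(chols) <- names(tasks)

    iter <- 0L
    converged <- FALSE
    repeat {
      iter <- iter + 1L
      maxdiff <- 0
      newb <- beta
      for (nm in names(tasks)) {
        t <- tasks[[nm]]; p <- pre[[nm]]
        for (g in seq_along(t$gene_ids)) {
          gene <- t$gene_ids[g]
          ch <- chols[[nm]][[g]]
          rhs <- p$XtY[ch$keep, g]
          a <- adj[[resp_key(nm, gene)]]
          if (!is.null(a)) {
            pv <- vapply(seq_len(nrow(a)), function(r) {
              beta[[a$psrc[r]]][a$ptf[r], a$pgene[r]]
            }, numeric(1))
            pull <- tapply(ls * a$w * pv, a$tf, sum)
            pos <- match(names(pull), t$tf_ids[ch$keep])
            ok <- !is.na(pos)
            rhs[pos[ok]] <- rhs[pos[ok]] + pull[ok]
          }
          sol <- backsolve(ch$R, forwardsolve(t(ch$R), rhs))
          old <- beta[[nm]][ch$keep, g]
          maxdiff <- max(maxdiff, max(abs(sol - old)))
          newb[[nm]][ch$keep, g] <- sol
        }
      }
      beta <- newb
      if (maxdiff < cfg$tol) { converged <- TRUE; break }
      if (iter >= cfg$max_iter) break
    }
    if (!converged) {
      warning("iterative solver did not converge at lambda_s = ", ls,
              " within ", cfg$max_iter, " iterations (max change ",
              signif(maxdiff, 3), ")")
    }
    res <- beta
    attr(res, "converged") <- converged
    attr(res, "iterations") <- iter
    attr(res, "lambda_s") <- ls
    out[[li]] <- res
  }
  out
}

#' Solve the fused ridge problem, routing by component size
#'
#' Components whose coefficient count exceeds `cfg$component_size_limit` are
#' routed to the iterative solver; all others are solved directly.
#'
#' @inheritParams solve_fused_direct
#' @return A `network_coefficients` object.
#' @export
solve_fused <- function(tasks, cs = NULL, cfg = solver_config()) {
  tasks <- as_task_list(tasks)
  if (!is.null(cs) && nrow(cs) > 0 && cfg$lambda_s > 0) {
    comps <- constraint_components(cs, tasks)
    ncoef <- vapply(comps, function(comp) {
      sum(vapply(seq_len(nrow(comp)), function(i) {
        length(tasks[[comp$source[i]]]$tf_ids) -
          (comp$gene[i] %in% tasks[[comp$source[i]]]$tf_ids)
      }, numeric(1)))
    }, numeric(1))
    if (max(ncoef) > cfg$component_size_limit) {
      res <- solve_fused_iterative(tasks, cs, cfg, cfg$lambda_s)[[1]]
      return(res)
    }
  }
  solve_fused_direct(tasks, cs, cfg)
}

#' Evaluate the fused ridge objective
#'
#' Returns the total of squared residuals, ridge penalty (with prior
#' relaxation multipliers) and pairwise fusion penalty for given networks;
#' the quantity minimized by [solve_fused_direct()].
#'
#' @inheritParams solve_fused_direct
#' @param networks A `network_coefficients` object (or a named list of TFs x
#'   genes matrices).
#' @return A scalar objective value.
#' @export
fused_objective <- function(tasks, cs, cfg, networks) {
  tasks <- as_task_list(tasks)
  total <- 0
  for (nm in names(tasks)) {
    t <- tasks[[nm]]
    beta <- networks[[nm]]
    resid <- t$Y - t$X %*% beta
    K <- kappa_matrix(t, cfg)
    total <- total + sum(resid^2) + cfg$lambda_r * sum(K * beta^2)
  }
  if (!is.null(cs) && nrow(cs) > 0 && cfg$lambda_s > 0) {
    d <- constraint_differences(cs, networks)
    total <- total + cfg$lambda_s * sum(cs$weight * d^2)
  }
  total
}

#' Signed differences across the constraints of a constraint set
#'
#' @param cs A `constraint_set`.
#' @param networks A `network_coefficients` object.
#' @return Numeric vector `beta_left - beta_right`, one entry per constraint.
#' @export
constraint_differences <- function(cs, networks) {
  if (is.null(cs) || nrow(cs) == 0) return(numeric(0))
  vapply(seq_len(nrow(cs)), function(i) {
    networks[[cs$source_a[i]]][cs$tf_a[i], cs$gene_a[i]] -
      networks[[cs$source_b[i]]][cs$tf_b[i], cs$gene_b[i]]
  }, numeric(1))
}

#' Report network coefficients on the original predictor scale
#'
#' Coefficients fitted on standardized predictors are divided by each TF
#' column's recorded standard deviation, undoing the scaling (centering does
#' not affect slope coefficients in this intercept-free dynamics model beyond
#' a vanishing mean shift).
#'
#' @param networks A `network_coefficients` object fitted on standardized
#'   tasks.
#' @param tasks The tasks the networks were fitted on.
#' @return A `network_coefficients` object on the original scale.
#' @export
rescale_network <- function(networks, tasks) {
  tasks <- as_task_list(tasks)
  for (nm in names(tasks)) {
    networks[[nm]] <- networks[[nm]] / tasks[[nm]]$x_sds
  }
  networks
}

#' Mean squared error between two networks
#'
#' @param est,truth TFs x genes coefficient matrices with matching dimnames.
#' @param subset Optional logical matrix selecting the coefficients to
#'   average over (e.g. the constrained subnetwork).
#' @return Mean squared coefficient error over the selected entries,
#'   excluding structural self interactions.
#' @export
network_mse <- function(est, truth, subset = NULL) {
  stopifnot(all(dim(est) == dim(truth)))
  keep <- matrix(TRUE, nrow(est), ncol(est))
  self <- intersect(rownames(est), colnames(est))
  keep[cbind(match(self, rownames(est)), match(self, colnames(est)))] <- FALSE
  if (!is.null(subset)) keep <- keep & subset
  mean((est[keep] - truth[keep])^2)
}

#' Logical mask of constrained coefficients for one source
#'
#' @param cs A `constraint_set`.
#' @param task The `regression_task` of the source of interest.
#' @return Logical TFs x genes matrix, `TRUE` where the coefficient takes
#'   part in at least one fusion constraint.
#' @export
constrained_mask <- function(cs, task) {
  M <- matrix(FALSE, length(task$tf_ids), length(task$gene_ids),
              dimnames = list(task$tf_ids, task$gene_ids))
  if (is.null(cs) || nrow(cs) == 0) return(M)
  for (side in c("a", "b")) {
    sel <- cs[[paste0("source_", side)]] == task$source_id
    if (!any(sel)) next
    M[cbind(match(cs[[paste0("tf_", side)]][sel], task$tf_ids),
            match(cs[[paste0("gene_", side)]][sel], task$gene_ids))] <- TRUE
  }
  M
}
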