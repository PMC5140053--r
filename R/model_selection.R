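# Two-stage hyperparameter selection by cross-validation (ridge weight
# first with no fusion, then the fusion weight along the iterative path) and
# end-to-end workflow orchestration.

#' Cross-validation plan
#'
#' Assigns each regression row to one of `n_folds` folds, balanced and
#' seeded. Rows are the unit of folding: each steady-state condition or
#' time-series transition is one row.
#'
#' @param n_rows Number of regression rows.
#' @param n_folds Number of folds (>= 2).
#' @param seed Integer seed.
#' @return An object of class `cv_plan` with `n_folds`, `assignments` (fold
#'   id per row) and `seed`.
#' @export
cv_plan <- function(n_rows, n_folds = 5, seed = 1) {
  if (n_folds < 2) stop("cross-validation needs at least 2 folds")
  if (n_rows < n_folds) stop("fewer rows (", n_rows, ") than folds (",
                             n_folds, ")")
  set.seed(seed)
  assignments <- sample(rep_len(seq_len(n_folds), n_rows))
  structure(list(n_folds = n_folds, assignments = assignments, seed = seed),
            class = "cv_plan")
}

#' Select the ridge weight by cross-validation
#'
#' With the fusion weight fixed at zero, fits the independent ridge model on
#' each training fold for every grid value and returns the value minimizing
#' the mean held-out squared prediction error. Ties are broken toward the
#' larger penalty. The gold standard plays no role here.
#'
#' @param task A (standardized) `regression_task`.
#' @param plan A [cv_plan()] over the task's rows.
#' @param grid Positive ridge weights, tried in descending order.
#' @param cfg Base [solver_config()] supplying priors/relaxation; its
#'   `lambda_r` is overridden by each grid value.
#' @return The selected `lambda_r`, with the CV error curve attached as
#'   attribute `"cv_error"`.
#' @export
select_lambda_r <- function(task, plan, grid, cfg = solver_config()) {
  stopifnot(inherits(task, "regression_task"), inherits(plan, "cv_plan"))
  if (length(grid) == 0 || any(grid <= 0)) {
    stop("`grid` must be non-empty positive ridge weights")
  }
  grid <- sort(unique(grid), decreasing = TRUE)
  if (length(plan$assignments) != nrow(task$X)) {
    stop("plan does not match the task's row count")
  }
  err <- matrix(NA_real_, plan$n_folds, length(grid))
  for (f in seq_len(plan$n_folds)) {
    tr <- plan$assignments != f
    t_tr <- subset_task(task, tr)
    t_te <- subset_task(task, !tr)
    for (li in seq_along(grid)) {
      cfg_l <- cfg
      cfg_l$lambda_r <- grid[li]
      beta <- solve_ridge_single(t_tr, cfg_l)
      err[f, li] <- mean((t_te$Y - t_te$X %*% beta)^2)
    }
  }
  cv <- colMeans(err)
  best <- which(cv == min(cv))
  lam <- max(grid[best]) # ties toward more regularization
  attr(lam, "cv_error") <- stats::setNames(cv, grid)
  lam
}

#' Select the fusion weight by cross-validation along the solution path
#'
#' With `lambda_r` fixed at its selected value, computes the fusion path on
#' each training fold with the warm-started iterative solver and returns the
#' grid value minimizing the mean held-out squared prediction error pooled
#' over sources. Ties are broken toward the larger penalty. The gold
#' standard plays no role here.
#'
#' @param tasks Named list of (standardized) `regression_task` objects.
#' @param cs A `constraint_set`.
#' @param plans Named list of [cv_plan()]s, one per source, all with the
#'   same number of folds.
#' @param lambda_r The ridge weight from [select_lambda_r()].
#' @param grid Ascending fusion weights (0 allowed).
#' @param cfg Base [solver_config()].
#' @return The selected `lambda_s`, with the CV error curve attached as
#'   attribute `"cv_error"`.
#' @export
select_lambda_s <- function(tasks, cs, plans, lambda_r, grid,
                            cfg = solver_config()) {
  tasks <- as_task_list(tasks)
  grid <- sort(unique(grid))
  if (any(grid < 0)) stop("fusion weights must be non-negative")
  if (is.null(cs) || nrow(cs) == 0) {
    warning("empty constraint set: lambda_s has no effect; ",
            "returning the grid minimum")
    return(min(grid))
  }
  nf <- unique(vapply(plans, function(p) p$n_folds, numeric(1)))
  if (length(nf) != 1) stop("all plans must use the same number of folds")
  for (nm in names(tasks)) {
    if (is.null(plans[[nm]]) ||
        length(plans[[nm]]$assignments) != nrow(tasks[[nm]]$X)) {
      stop("missing or mismatched cv_plan for source '", nm, "'")
    }
  }
  cfg$lambda_r <- lambda_r

  err <- matrix(NA_real_, nf, length(grid))
  for (f in seq_len(nf)) {
    tr_tasks <- lapply(names(tasks), function(nm) {
      subset_task(tasks[[nm]], plans[[nm]]$assignments != f)
    })
    names(tr_tasks) <- names(tasks)
    path <- solve_fused_iterative(tr_tasks, cs, cfg, grid)
    for (li in seq_along(grid)) {
      sse <- 0; cnt <- 0
      for (nm in names(tasks)) {
        te <- subset_task(tasks[[nm]], plans[[nm]]$assignments == f)
        r <- te$Y - te$X %*% path[[li]][[nm]]
        sse <- sse + sum(r^2); cnt <- cnt + length(r)
      }
      err[f, li] <- sse / cnt
    }
  }
  cv <- colMeans(err)
  best <- which(cv == min(cv))
  lam <- max(grid[best])
  attr(lam, "cv_error") <- stats::setNames(cv, grid)
  lam
}

#' Workflow configuration
#'
#' Collects every input and option of the end-to-end inference workflow.
#'
#' @param datasets Named list of [expression_dataset()]s (one per source).
#' @param orthology Optional [orthology_map()].
#' @param operons Optional named list (by source) of operon membership data
#'   frames (`gene`, `operon_id`).
#' @param gold Named list (by source) of [prior_network()]s; the evaluation
#'   source's gold standard is split in half into prior and leave-out sets.
#' @param eval_source Source evaluated against its gold standard; defaults
#'   to the first source with a gold standard.
#' @param alpha Decay rate passed to [build_response_design()]; `NULL` uses
#'   each dataset's `"alpha"` attribute (set by the simulator) or 0.1.
#' @param folds Number of outer folds (>= 2): the evaluation source's rows
#'   are divided into folds and each fold is fit alone — fused to the other
#'   sources' full data — to emulate the data-poor regime.
#' @param inner_folds Folds for the nested lambda-selection CV.
#' @param use_tfa Estimate TF activities from the prior half and use them as
#'   predictors.
#' @param adaptive Use the saturating penalty with LQA instead of fused L2.
#' @param a_percentile Percentile used by [select_a()] when `adaptive`.
#' @param lambda_r_grid Ridge grid; `NULL` for 20 log-spaced values up to
#'   `max |X'Y|`.
#' @param lambda_s_grid Fusion grid (default includes the 1.0 operating
#'   point).
#' @param lambda_s Optional fixed fusion weight, skipping its CV.
#' @param prior_relax Ridge relaxation multiplier for prior-known edges.
#' @param seed Master seed.
#' @return A list of class `workflow_config`.
#' @export
workflow_config <- function(datasets, orthology = NULL, operons = NULL,
                            gold = NULL, eval_source = NULL, alpha = NULL,
                            folds = 5, inner_folds = 5, use_tfa = FALSE,
                            adaptive = FALSE, a_percentile = 60,
                            lambda_r_grid = NULL,
                            lambda_s_grid = c(0, 0.01, 0.1, 0.5, 1, 2, 5, 10),
                            lambda_s = NULL, prior_relax = 0.1, seed = 1) {
  if (is.null(names(datasets))) {
    names(datasets) <- vapply(datasets, function(d) d$source_id, character(1))
  }
  structure(
    list(datasets = datasets, orthology = orthology, operons = operons,
         gold = gold, eval_source = eval_source, alpha = alpha,
         folds = folds, inner_folds = inner_folds, use_tfa = use_tfa,
         adaptive = adaptive, a_percentile = a_percentile,
         lambda_r_grid = lambda_r_grid, lambda_s_grid = lambda_s_grid,
         lambda_s = lambda_s, prior_relax = prior_relax,
         seed = as.integer(seed)),
    class = "workflow_config"
  )
}

#' Run the end-to-end fused network inference workflow
#'
#' Executes the full procedure: load data, build fusion constraints from
#' orthology and operons, split the gold standard into prior and leave-out
#' halves, optionally estimate TF activities from the prior half, optionally
#' select the saturation point `a` from independently fit networks, then for
#' each outer fold select `lambda_r` (nested CV, no fusion) and `lambda_s`
#' (nested CV along the fusion path), fit both the fused (or adaptive) model
#' and the independent baseline, score edges, and evaluate precision-recall
#' against the leave-out gold standard; finally average curves over folds.
#' Hyperparameters are chosen without reference to the gold standard.
#'
#' @param config A [workflow_config()].
#' @return An object of class `workflow_result`: per-fold results (chosen
#'   lambdas, AUPR fused/independent, PR curves, unfused constraints when
#'   adaptive), averaged AUPRs, and a manifest of seeds and parameters.
#' @export
run_workflow <- function(config) {
  stopifnot(inherits(config, "workflow_config"))
  cfgw <- config
  if (cfgw$folds < 2) stop("folds must be >= 2 (cannot cross-validate)")
  datasets <- cfgw$datasets
  if (length(datasets) == 0) stop("no datasets supplied")
  if (is.null(cfgw$gold) || length(cfgw$gold) == 0) {
    stop("a gold standard is required for evaluation")
  }
  eval_source <- cfgw$eval_source
  if (is.null(eval_source)) eval_source <- names(cfgw$gold)[1]
  if (!eval_source %in% names(datasets)) {
    stop("eval_source '", eval_source, "' is not among the datasets")
  }

  # gold split: prior half (TFA + ridge relaxation) vs leave-out half
  splits <- lapply(names(cfgw$gold), function(nm) {
    split_gold_standard(cfgw$gold[[nm]],
                        seed = stage_seed(cfgw$seed, "gold"))
  })
  names(splits) <- names(cfgw$gold)
  priors <- lapply(splits, `[[`, "prior")
  gold_eval <- splits[[eval_source]]$eval

  # predictors: TFA from the prior half, or raw TF expression
  activities <- NULL
  if (cfgw$use_tfa) {
    activities <- lapply(names(datasets), function(nm) {
      estimate_tfa(datasets[[nm]], priors[[nm]])
    })
    names(activities) <- names(datasets)
  }

  tasks <- lapply(names(datasets), function(nm) {
    ds <- datasets[[nm]]
    a <- cfgw$alpha
    if (is.null(a)) a <- attr(ds, "alpha")
    if (is.null(a)) a <- 0.1
    standardize_predictors(
      build_response_design(ds, alpha = a, predictors = activities[[nm]])
    )
  })
  names(tasks) <- names(datasets)

  cs <- constraints_from_orthology(tasks, cfgw$orthology)
  if (!is.null(cfgw$operons)) {
    op_cs <- lapply(names(cfgw$operons), function(nm) {
      constraints_from_operons(tasks[[nm]], cfgw$operons[[nm]])
    })
    cs <- do.call(combine_constraints, c(list(cs), op_cs))
  }

  base_cfg <- solver_config(prior_relax = cfgw$prior_relax,
                            priors = lapply(priors, function(p) {
                              as.data.frame(p)[, c("tf", "gene")]
                            }))

  eval_task <- tasks[[eval_source]]
  lr_grid <- cfgw$lambda_r_grid
  if (is.null(lr_grid)) lr_grid <- default_lambda_r_grid(eval_task)

  # saturation point from independently fit networks on the full data
  a_sat <- NULL
  if (cfgw$adaptive) {
    if (nrow(cs) == 0) stop("adaptive fusion requires fusion constraints")
    pre_plan <- cv_plan(nrow(eval_task$X),
                        min(cfgw$inner_folds, nrow(eval_task$X)),
                        seed = stage_seed(cfgw$seed, "workflow"))
    cfg0 <- base_cfg
    cfg0$lambda_r <- as.numeric(select_lambda_r(eval_task, pre_plan, lr_grid,
                                                base_cfg))
    nets0 <- solve_fused_direct(tasks, NULL, cfg0)
    a_sat <- select_a(nets0, cs, cfgw$a_percentile)
  }

  set.seed(stage_seed(cfgw$seed, "workflow"))
  fold_of <- sample(rep_len(seq_len(cfgw$folds), nrow(eval_task$X)))

  # the eligible universe: all non-self edges, minus prior-half edges (their
  # relaxed shrinkage would make them trivially top-ranked)
  uni <- expand.grid(tf = eval_task$tf_ids, gene = eval_task$gene_ids,
                     stringsAsFactors = FALSE)
  uni <- uni[uni$tf != uni$gene, , drop = FALSE]
  pr_edges <- priors[[eval_source]]
  if (!is.null(pr_edges) && nrow(pr_edges) > 0) {
    uni <- uni[!(paste(uni$tf, uni$gene, sep = SEP) %in%
                   paste(pr_edges$tf, pr_edges$gene, sep = SEP)), ,
               drop = FALSE]
  }

  fold_results <- vector("list", cfgw$folds)
  for (f in seq_len(cfgw$folds)) {
    rows <- which(fold_of == f) # this fold's data IS the available data
    t_f <- subset_task(eval_task, rows)
    tasks_f <- tasks
    tasks_f[[eval_source]] <- t_f

    inner <- min(cfgw$inner_folds, length(rows))
    if (inner < 2) stop("fold ", f, " has too few rows for nested CV")
    plan_f <- cv_plan(length(rows), inner,
                      seed = stage_seed(cfgw$seed + f, "workflow"))
    lam_r <- as.numeric(select_lambda_r(t_f, plan_f, lr_grid, base_cfg))

    lam_s <- cfgw$lambda_s
    if (is.null(lam_s) && nrow(cs) > 0) {
      plans <- lapply(names(tasks_f), function(nm) {
        if (nm == eval_source) plan_f
        else cv_plan(nrow(tasks_f[[nm]]$X), inner,
                     seed = stage_seed(cfgw$seed + f + 1000L, "workflow"))
      })
      names(plans) <- names(tasks_f)
      lam_s <- as.numeric(select_lambda_s(tasks_f, cs, plans, lam_r,
                                          cfgw$lambda_s_grid, base_cfg))
    }
    if (is.null(lam_s)) lam_s <- 0

    cfg_f <- base_cfg
    cfg_f$lambda_r <- lam_r

    # independent baseline
    net_ind <- solve_fused_direct(tasks_f, NULL, cfg_f)

    unfused <- NULL
    if (cfgw$adaptive) {
      pen <- saturating_penalty(2 * max(lam_s, .Machine$double.eps), a_sat)
      ad <- solve_adaptive(tasks_f, cs, cfg_f, pen)
      net_fused <- ad$networks
      unfused <- cs[ad$unfused, , drop = FALSE]
      unfused$final_theta <- ad$theta[ad$unfused]
    } else {
      cfg_f$lambda_s <- lam_s
      net_fused <- solve_fused(tasks_f, cs, cfg_f)
    }

    sc_fused <- confidence_scores(t_f, net_fused[[eval_source]])
    sc_ind <- confidence_scores(t_f, net_ind[[eval_source]])
    ev_fused <- evaluate_pr(sc_fused$ranking, gold_eval, uni)
    ev_ind <- evaluate_pr(sc_ind$ranking, gold_eval, uni)

    fold_results[[f]] <- list(
      fold = f, n_rows = length(rows),
      lambda_r = lam_r, lambda_s = lam_s,
      aupr_fused = ev_fused$aupr, aupr_independent = ev_ind$aupr,
      auroc_fused = ev_fused$auroc, auroc_independent = ev_ind$auroc,
      curve_fused = ev_fused$curve, curve_independent = ev_ind$curve,
      unfused = unfused
    )
  }

  mean_of <- function(field) {
    mean(vapply(fold_results, `[[`, numeric(1), field))
  }
  avg_curve <- function(field) {
    grid <- seq(0, 1, by = 0.01)
    prec <- vapply(fold_results, function(fr) {
      cv <- fr[[field]]
      vapply(grid, function(r) {
        i <- which(cv$recall >= r)
        if (length(i) == 0) cv$precision[nrow(cv)] else cv$precision[i[1]]
      }, numeric(1))
    }, numeric(length(grid)))
    data.frame(recall = grid, precision = rowMeans(prec))
  }

  structure(
    list(
      folds = fold_results,
      mean_aupr_fused = mean_of("aupr_fused"),
      mean_aupr_independent = mean_of("aupr_independent"),
      avg_curve_fused = avg_curve("curve_fused"),
      avg_curve_independent = avg_curve("curve_independent"),
      constraints = cs,
      a = a_sat,
      eval_source = eval_source,
      manifest = list(
        seed = cfgw$seed,
        folds = cfgw$folds,
        inner_folds = cfgw$inner_folds,
        use_tfa = cfgw$use_tfa,
        adaptive = cfgw$adaptive,
        a_percentile = if (cfgw$adaptive) cfgw$a_percentile else NULL,
        a = a_sat,
        lambda_r_grid = lr_grid,
        lambda_s_grid = cfgw$lambda_s_grid,
        chosen_lambda_r = vapply(fold_results, `[[`, numeric(1), "lambda_r"),
        chosen_lambda_s = vapply(fold_results, `[[`, numeric(1), "lambda_s"),
        n_constraints = nrow(cs)
      )
    ),
    class = "workflow_result"
  )
}

#' @export
print.workflow_result <- function(x, ...) {
  cat("workflow_result (", length(x$folds), " folds, eval on '",
      x$eval_source, "')\n", sep = "")
  cat("  mean AUPR fused:       ", signif(x$mean_aupr_fused, 4), "\n")
  cat("  mean AUPR independent: ", signif(x$mean_aupr_independent, 4), "\n")
  invisible(x)
}
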