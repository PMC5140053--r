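# Shared fixtures: hand-built datasets/tasks, random small instances, and a
# generic numerical minimizer of the fused objective used as the solver
# oracle.

# tiny dataset: explicit values, all steady state unless meta given
make_dataset <- function(values, tf_ids, meta = NULL, source_id = "s1") {
  expression_dataset(values, tf_ids, meta, source_id)
}

# a regression task built directly from X and Y matrices
make_task <- function(X, Y, source_id = "s1", alpha = 0.1,
                      tf_ids = colnames(X), gene_ids = colnames(Y)) {
  structure(
    list(source_id = source_id, X = X, Y = Y, alpha = alpha,
         tf_ids = tf_ids, gene_ids = gene_ids,
         x_means = stats::setNames(rep(0, ncol(X)), tf_ids),
         x_sds = stats::setNames(rep(1, ncol(X)), tf_ids),
         constant_cols = stats::setNames(rep(FALSE, ncol(X)), tf_ids),
         standardized = FALSE),
    class = "regression_task"
  )
}

# constraint set from a plain data frame (canonicalized by the package)
make_cs <- function(df) {
  if (is.null(df$weight)) df$weight <- 1
  if (is.null(df$label)) df$label <- TRUE
  combine_constraints(df)
}

# random 2-source instance with random cross-source constraints
random_instance <- function(seed, n_tfs = 3, n_genes = 5, n_rows = 8,
                            n_cons = 6, lambda_r = NULL, lambda_s = NULL) {
  set.seed(seed)
  tfs <- paste0("t", seq_len(n_tfs))
  genes <- c(tfs[1], paste0("g", seq_len(n_genes - 1))) # one TF is a gene too
  mk <- function(src) {
    X <- matrix(rnorm(n_rows * n_tfs), n_rows, n_tfs,
                dimnames = list(NULL, tfs))
    Y <- matrix(rnorm(n_rows * n_genes), n_rows, n_genes,
                dimnames = list(NULL, genes))
    make_task(X, Y, src)
  }
  tasks <- list(s1 = mk("s1"), s2 = mk("s2"))
  pick <- function(src) {
    repeat {
      tf <- sample(tfs, 1); g <- sample(genes, 1)
      if (tf != g) return(c(src, tf, g))
    }
  }
  cons <- t(vapply(seq_len(n_cons), function(i) {
    c(pick("s1"), pick("s2"))
  }, character(6)))
  cs <- make_cs(data.frame(
    source_a = cons[, 1], tf_a = cons[, 2], gene_a = cons[, 3],
    source_b = cons[, 4], tf_b = cons[, 5], gene_b = cons[, 6],
    stringsAsFactors = FALSE
  ))
  cfg <- solver_config(
    lambda_r = if (is.null(lambda_r)) runif(1, 0.5, 2) else lambda_r,
    lambda_s = if (is.null(lambda_s)) runif(1, 0.1, 2) else lambda_s
  )
  list(tasks = tasks, cs = cs, cfg = cfg)
}

# generic numerical minimizer of fused_objective (BFGS with analytic
# gradient); independent of the augmented-matrix solution path
oracle_minimize <- function(tasks, cs, cfg) {
  layout <- lapply(tasks, function(t) {
    sel <- which(outer(t$tf_ids, t$gene_ids, "!="))
    list(task = t, sel = sel)
  })
  npar <- sum(vapply(layout, function(l) length(l$sel), numeric(1)))
  unpack <- function(par) {
    nets <- list()
    off <- 0L
    for (nm in names(layout)) {
      l <- layout[[nm]]
      b <- matrix(0, length(l$task$tf_ids), length(l$task$gene_ids),
                  dimnames = list(l$task$tf_ids, l$task$gene_ids))
      b[l$sel] <- par[off + seq_along(l$sel)]
      off <- off + length(l$sel)
      nets[[nm]] <- b
    }
    structure(nets, class = "network_coefficients")
  }
  fn <- function(par) fused_objective(tasks, cs, cfg, unpack(par))
  gr <- function(par) {
    nets <- unpack(par)
    grads <- lapply(names(layout), function(nm) {
      t <- layout[[nm]]$task
      b <- nets[[nm]]
      2 * (crossprod(t$X) %*% b - crossprod(t$X, t$Y)) +
        2 * cfg$lambda_r * b
    })
    names(grads) <- names(layout)
    if (!is.null(cs) && nrow(cs) > 0 && cfg$lambda_s > 0) {
      d <- constraint_differences(cs, nets)
      for (i in seq_len(nrow(cs))) {
        g <- 2 * cfg$lambda_s * cs$weight[i] * d[i]
        grads[[cs$source_a[i]]][cs$tf_a[i], cs$gene_a[i]] <-
          grads[[cs$source_a[i]]][cs$tf_a[i], cs$gene_a[i]] + g
        grads[[cs$source_b[i]]][cs$tf_b[i], cs$gene_b[i]] <-
          grads[[cs$source_b[i]]][cs$tf_b[i], cs$gene_b[i]] - g
      }
    }
    unlist(lapply(names(layout), function(nm) {
      grads[[nm]][layout[[nm]]$sel]
    }), use.names = FALSE)
  }
  fit <- stats::optim(rep(0, npar), fn, gr, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  list(networks = unpack(fit$par), value = fit$value)
}

# build standardized tasks for all sources of a simulated study
study_tasks <- function(study) {
  tasks <- lapply(study$datasets, function(d) {
    standardize_predictors(
      build_response_design(d, alpha = attr(d, "alpha"))
    )
  })
  names(tasks) <- names(study$datasets)
  tasks
}
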