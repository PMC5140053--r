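# Direct augmented-matrix solver, iterative path solver, and the fused
# objective they minimize.

test_that("augmented system encodes ridge and fusion rows with sqrt scaling", {
  X <- matrix(c(1, 2, 3, 4), 2, 2, dimnames = list(NULL, c("t1", "t2")))
  y <- c(1, 2)
  task <- make_task(X, matrix(y, 2, 1, dimnames = list(NULL, "g1")))
  comp <- data.frame(source = "s1", gene = "g1")

  cfg <- solver_config(lambda_r = 4, lambda_s = 0)
  sys <- build_augmented_system(comp, list(task), NULL, cfg)
  expect_equal(dim(sys$A), c(2 + 2, 2))
  expect_equal(sys$A[3:4, ], 2 * diag(2)) # sqrt(4) = 2
  expect_equal(sys$b, c(y, 0, 0))
  # normal equations of the augmented system reproduce the ridge closed form
  beta_aug <- qr.solve(sys$A, sys$b)
  beta_ridge <- solve(crossprod(X) + 4 * diag(2), crossprod(X, y))
  expect_equal(beta_aug, drop(beta_ridge), ignore_attr = TRUE,
               tolerance = 1e-12)

  # fusion row: lambda_s = 9, w = 1 -> +3 / -3
  cs <- make_cs(data.frame(source_a = "s1", tf_a = "t1", gene_a = "g1",
                           source_b = "s1", tf_b = "t2", gene_b = "g1"))
  cfg2 <- solver_config(lambda_r = 4, lambda_s = 9)
  sys2 <- build_augmented_system(comp, list(task), cs, cfg2)
  frow <- sys2$A[nrow(sys2$A), ]
  expect_setequal(frow, c(3, -3))
  expect_equal(sum(frow), 0)

  # lambda_r = lambda_s = 0: plain least-squares system
  cfg0 <- solver_config(lambda_r = 0, lambda_s = 0)
  sys0 <- build_augmented_system(comp, list(task), NULL, cfg0)
  expect_equal(sys0$A[3:4, ], matrix(0, 2, 2))
})

test_that("lambda_s = 0 reduces exactly to independent ridge", {
  X <- diag(2); colnames(X) <- c("t1", "t2")
  task <- make_task(X, matrix(c(1, 2), 2, 1, dimnames = list(NULL, "g1")))
  net <- solve_fused_direct(list(task), NULL, solver_config(lambda_r = 1))
  expect_equal(unname(net$s1[, "g1"]), c(0.5, 1.0)) # (I + I)^-1 y

  inst <- random_instance(7)
  cfg0 <- inst$cfg; cfg0$lambda_s <- 0
  net_cs <- solve_fused_direct(inst$tasks, inst$cs, cfg0)
  net_no <- solve_fused_direct(inst$tasks, NULL, cfg0)
  expect_equal(net_cs, net_no, tolerance = 1e-12)
})

test_that("huge lambda_s with one-to-one fusion approaches the pooled fit", {
  set.seed(11)
  tfs <- paste0("t", 1:3); genes <- paste0("g", 1:2)
  X <- matrix(rnorm(12), 4, 3, dimnames = list(NULL, tfs))
  Y <- matrix(rnorm(8), 4, 2, dimnames = list(NULL, genes))
  tasks <- list(s1 = make_task(X, Y, "s1"), s2 = make_task(X, Y, "s2"))
  grid <- expand.grid(tf = tfs, gene = genes, stringsAsFactors = FALSE)
  cs <- make_cs(data.frame(source_a = "s1", tf_a = grid$tf,
                           gene_a = grid$gene, source_b = "s2",
                           tf_b = grid$tf, gene_b = grid$gene))
  lam_r <- 0.7
  net <- solve_fused_direct(tasks, cs, solver_config(lambda_r = lam_r,
                                                     lambda_s = 1e8))
  # stacked-data ridge with the per-source penalties summed (2 * lambda_r)
  pooled <- solve(2 * crossprod(X) + 2 * lam_r * diag(3),
                  2 * crossprod(X, Y))
  expect_lt(max(abs(net$s1 - net$s2)), 1e-4)
  expect_lt(max(abs(net$s1 - pooled)), 1e-4)
})

test_that("fused exchangeable predictors get identical coefficients", {
  set.seed(3)
  x <- rnorm(6)
  X <- cbind(t1 = x, t2 = x) # identical columns
  Y <- matrix(rnorm(6), 6, 1, dimnames = list(NULL, "g1"))
  task <- make_task(X, Y)
  cs <- make_cs(data.frame(source_a = "s1", tf_a = "t1", gene_a = "g1",
                           source_b = "s1", tf_b = "t2", gene_b = "g1"))
  net <- solve_fused_direct(list(task), cs,
                            solver_config(lambda_r = 0.5, lambda_s = 2))
  expect_equal(net$s1["t1", "g1"], net$s1["t2", "g1"], tolerance = 1e-12)
})

test_that("direct solver matches numerical minimization of the objective", {
  for (seed in 1:5) {
    inst <- random_instance(seed)
    net <- solve_fused_direct(inst$tasks, inst$cs, inst$cfg)
    orc <- oracle_minimize(inst$tasks, inst$cs, inst$cfg)
    f_net <- fused_objective(inst$tasks, inst$cs, inst$cfg, net)
    expect_lt(abs(f_net - orc$value) / max(1, abs(orc$value)), 1e-6)
    expect_lte(f_net, orc$value + 1e-8) # the exact solver can only be better
  }
})

test_that("iterative path solver converges to the direct solution", {
  inst <- random_instance(21, n_tfs = 3, n_genes = 5, n_rows = 8)
  cfg <- inst$cfg; cfg$tol <- 1e-9; cfg$max_iter <- 500
  grid <- c(0, 0.1, 1, 10)
  path <- solve_fused_iterative(inst$tasks, inst$cs, cfg, grid)
  expect_length(path, 4)

  # lambda_s = 0: one pass, exact ridge
  expect_equal(attr(path[[1]], "iterations"), 1L)
  cfg0 <- cfg; cfg0$lambda_s <- 0
  expect_equal(path[[1]]$s1, solve_fused_direct(inst$tasks, NULL, cfg0)$s1,
               tolerance = 1e-12)

  # each path point matches the direct solve; fused differences shrink
  sq_diff <- numeric(length(grid))
  for (i in seq_along(grid)) {
    cfg_i <- cfg; cfg_i$lambda_s <- grid[i]
    direct <- solve_fused_direct(inst$tasks, inst$cs, cfg_i)
    dev <- max(vapply(names(direct), function(nm) {
      max(abs(direct[[nm]] - path[[i]][[nm]]))
    }, numeric(1)))
    expect_lt(dev, 1e-6)
    sq_diff[i] <- sum(constraint_differences(inst$cs, path[[i]])^2)
  }
  expect_true(all(diff(sq_diff) <= 1e-12)) # monotone in lambda_s
})

test_that("objective evaluates residual, ridge and fusion terms", {
  inst <- random_instance(5)
  zero <- solve_fused_direct(inst$tasks, NULL,
                             solver_config(lambda_r = 1e12)) # ~ 0 networks
  f0 <- fused_objective(inst$tasks, inst$cs, inst$cfg, zero)
  ssq_y <- sum(vapply(inst$tasks, function(t) sum(t$Y^2), numeric(1)))
  expect_equal(f0, ssq_y, tolerance = 1e-6)

  # two equal fused coefficients contribute no fusion term
  nets <- zero
  nets$s1[] <- 0; nets$s2[] <- 0
  nets$s1[inst$cs$tf_a[1], inst$cs$gene_a[1]] <- 1.5
  nets$s2[inst$cs$tf_b[1], inst$cs$gene_b[1]] <- 1.5
  cfg_no_r <- inst$cfg; cfg_no_r$lambda_r <- 0
  resid_only <- fused_objective(inst$tasks, empty_constraints(), cfg_no_r,
                                nets)
  expect_equal(fused_objective(inst$tasks, inst$cs[1, ], cfg_no_r, nets),
               resid_only)

  # local optimality: 1000 small perturbations never beat the solution
  net <- solve_fused_direct(inst$tasks, inst$cs, inst$cfg)
  f_star <- fused_objective(inst$tasks, inst$cs, inst$cfg, net)
  set.seed(99)
  worse <- vapply(1:1000, function(i) {
    pert <- net
    for (nm in names(pert)) {
      pert[[nm]] <- pert[[nm]] +
        matrix(rnorm(length(pert[[nm]]), sd = 0.01), nrow(pert[[nm]]))
      # keep structural zeros intact
      self <- intersect(rownames(pert[[nm]]), colnames(pert[[nm]]))
      pert[[nm]][cbind(self, self)] <- 0
    }
    fused_objective(inst$tasks, inst$cs, inst$cfg, pert)
  }, numeric(1))
  expect_true(all(worse >= f_star - 1e-9))
})

test_that("component independence: joint solve equals componentwise solve", {
  inst <- random_instance(13, n_cons = 3)
  comps <- constraint_components(inst$cs, inst$tasks)
  # solve everything as one big component
  all_resp <- do.call(rbind, comps)
  sys <- build_augmented_system(all_resp, inst$tasks, inst$cs, inst$cfg)
  beta_joint <- qr.solve(sys$A, sys$b)
  net <- solve_fused_direct(inst$tasks, inst$cs, inst$cfg)
  for (j in seq_len(nrow(sys$index))) {
    expect_equal(
      net[[sys$index$source[j]]][sys$index$tf[j], sys$index$gene[j]],
      beta_joint[j], tolerance = 1e-8
    )
  }
})

test_that("Gaussian-prior equivalence holds for the two-coefficient model", {
  # precision lambda_r I + lambda_s (1gg + 1hh - 1gh - 1hg), inverted
  # numerically
  lam_r <- 1; lam_s <- 1
  prec <- lam_r * diag(2) + lam_s * matrix(c(1, -1, -1, 1), 2, 2)
  cov <- solve(prec)
  expect_equal(cov[1, 1], 2 / 3, tolerance = 1e-12)
  expect_equal(cov[1, 2], 1 / 3, tolerance = 1e-12)
  # closed form from the model: (lr + ls) / (lr^2 + 2 lr ls), ls / (...)
  expect_equal(cov[1, 1], (lam_r + lam_s) / (lam_r^2 + 2 * lam_r * lam_s))
  expect_equal(cov[1, 2], lam_s / (lam_r^2 + 2 * lam_r * lam_s))

  # and the solver equals the posterior mean under that prior
  set.seed(8)
  X <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("t1", "t2")))
  y <- rnorm(5)
  task <- make_task(X, matrix(y, 5, 1, dimnames = list(NULL, "g1")))
  cs <- make_cs(data.frame(source_a = "s1", tf_a = "t1", gene_a = "g1",
                           source_b = "s1", tf_b = "t2", gene_b = "g1"))
  net <- solve_fused_direct(list(task), cs,
                            solver_config(lambda_r = lam_r,
                                          lambda_s = lam_s))
  post <- solve(crossprod(X) + prec, crossprod(X, y))
  expect_equal(unname(net$s1[, "g1"]), unname(drop(post)),
               tolerance = 1e-10)
})

test_that("singular unpenalized systems advise setting lambda_r", {
  X <- matrix(c(1, 1, 2, 2), 2, 2, dimnames = list(NULL, c("t1", "t2")))
  task <- make_task(X, matrix(c(1, 2), 2, 1, dimnames = list(NULL, "g1")))
  expect_error(
    solve_fused_direct(list(task), NULL,
                       solver_config(lambda_r = 0, lambda_s = 0)),
    "lambda_r > 0"
  )
})

test_that("prior interactions get relaxed shrinkage", {
  set.seed(17)
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("t1", "t2")))
  beta_true <- c(2, 0)
  y <- X %*% beta_true + rnorm(10, sd = 0.05)
  task <- make_task(X, matrix(y, 10, 1, dimnames = list(NULL, "g1")))
  priors <- list(s1 = data.frame(tf = "t1", gene = "g1"))
  cfg_pr <- solver_config(lambda_r = 50, prior_relax = 0.01, priors = priors)
  cfg_no <- solver_config(lambda_r = 50)
  b_pr <- solve_fused_direct(list(task), NULL, cfg_pr)$s1["t1", "g1"]
  b_no <- solve_fused_direct(list(task), NULL, cfg_no)$s1["t1", "g1"]
  expect_gt(b_pr, b_no) # less shrinkage toward zero on the prior edge
})
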