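# Synthetic study generator: orthology pairing, fused network sampling,
# two-timepoint expression, and orthology corruption.

test_that("orthology pairing hits the configured fractions per pool", {
  cfg0 <- simulation_config(n_tfs = 5, n_genes = 25, ortho_frac_tf = 0,
                            ortho_frac_gene = 0, seed = 2)
  expect_equal(nrow(generate_orthology(cfg0)), 0)

  cfg1 <- simulation_config(n_tfs = 5, n_genes = 25, ortho_frac_tf = 1,
                            ortho_frac_gene = 1, seed = 2)
  orth1 <- generate_orthology(cfg1)
  expect_equal(nrow(orth1), 5 + 20) # all TFs + all non-TF genes paired

  # 75% of 200 non-TF genes -> 150 gene pairs (floor convention)
  cfg <- simulation_config(n_tfs = 10, n_genes = 210, ortho_frac_tf = 0,
                           ortho_frac_gene = 0.75, seed = 2)
  orth <- generate_orthology(cfg)
  expect_equal(nrow(orth), 150)
  # pools never mix: TFs pair with TFs, genes with genes
  expect_true(all(startsWith(orth$gene_a, "G") == startsWith(orth$gene_b,
                                                             "G")))
})

test_that("fused networks share group values up to divergence noise", {
  cfg_sparse <- simulation_config(n_tfs = 4, n_genes = 20, sparsity = 1,
                                  seed = 3)
  nets <- generate_fused_networks(cfg_sparse, generate_orthology(cfg_sparse))
  expect_true(all(nets$s1 == 0) && all(nets$s2 == 0))

  cfg_exact <- simulation_config(n_tfs = 4, n_genes = 20, sparsity = 0.3,
                                 sigma_f = 0, ortho_frac_tf = 1,
                                 ortho_frac_gene = 1, seed = 4)
  orth <- generate_orthology(cfg_exact)
  nets_e <- generate_fused_networks(cfg_exact, orth)
  tasks <- list(
    s1 = make_task(matrix(0, 2, 4,
                          dimnames = list(NULL, rownames(nets_e$s1))),
                   matrix(0, 2, 20,
                          dimnames = list(NULL, colnames(nets_e$s1))), "s1"),
    s2 = make_task(matrix(0, 2, 4,
                          dimnames = list(NULL, rownames(nets_e$s2))),
                   matrix(0, 2, 20,
                          dimnames = list(NULL, colnames(nets_e$s2))), "s2")
  )
  cs <- constraints_from_orthology(tasks, orth)
  expect_gt(nrow(cs), 0)
  expect_equal(max(abs(constraint_differences(cs, nets_e))), 0) # sigma_f = 0

  # self interactions are structural zeros
  expect_true(all(diag(nets_e$s1[, rownames(nets_e$s1)]) == 0))
})

test_that("nonzero coefficients have variance 1 + sigma_f^2", {
  sigma_f <- 0.5
  vals <- unlist(lapply(1:10, function(s) {
    cfg <- simulation_config(n_tfs = 6, n_genes = 80, sparsity = 0.4,
                             sigma_f = sigma_f, seed = 100 + s)
    nets <- generate_fused_networks(cfg, generate_orthology(cfg))
    c(nets$s1[nets$s1 != 0], nets$s2[nets$s2 != 0])
  }))
  expect_lt(abs(var(vals) - (1 + sigma_f^2)) / (1 + sigma_f^2), 0.10)
})

test_that("cross-source differences of fused entries have variance 2 sigma_f^2", {
  sigma_f <- 0.4
  # align fused entries via the constraints the orthology generates
  diffs <- unlist(lapply(1:10, function(s) {
    cfg <- simulation_config(n_tfs = 6, n_genes = 80, sparsity = 0.4,
                             sigma_f = sigma_f, ortho_frac_tf = 1,
                             ortho_frac_gene = 1, seed = 200 + s)
    orth <- generate_orthology(cfg)
    nets <- generate_fused_networks(cfg, orth)
    mk <- function(src) make_task(
      matrix(0, 2, 6, dimnames = list(NULL, rownames(nets$s1))),
      matrix(0, 2, 80, dimnames = list(NULL, colnames(nets$s1))), src)
    cs <- constraints_from_orthology(list(s1 = mk("s1"), s2 = mk("s2")),
                                     orth)
    d <- constraint_differences(cs, nets)
    left <- vapply(seq_len(nrow(cs)), function(i) {
      nets[[cs$source_a[i]]][cs$tf_a[i], cs$gene_a[i]]
    }, numeric(1))
    d[left != 0]
  }))
  expect_lt(abs(var(diffs) - 2 * sigma_f^2) / (2 * sigma_f^2), 0.15)
})

test_that("group sparsity matches the configured rate", {
  cfg <- simulation_config(n_tfs = 5, n_genes = 60, sparsity = 0.6,
                           sigma_f = 0, ortho_frac_tf = 1,
                           ortho_frac_gene = 1, seed = 9)
  nets <- generate_fused_networks(cfg, generate_orthology(cfg))
  # sigma_f = 0 and full orthology: each source-1 entry represents one group
  sel <- outer(rownames(nets$s1), colnames(nets$s1), "!=")
  vals <- nets$s1[sel]
  n_groups <- length(vals)
  p_hat <- mean(vals == 0)
  ci <- qbinom(c(0.005, 0.995), n_groups, 0.6) / n_groups
  expect_gte(p_hat, ci[1])
  expect_lte(p_hat, ci[2])
})

test_that("two-timepoint expression follows the stated dynamics", {
  cfg <- simulation_config(n_tfs = 3, n_genes = 10, sparsity = 0.3,
                           noise_sd = 0, n_samples = 6, seed = 5)
  nets <- generate_fused_networks(cfg, generate_orthology(cfg))

  # beta = 0, noise 0 -> second timepoint equals the first
  zero_net <- nets$s1; zero_net[] <- 0
  ds0 <- simulate_expression(zero_net, cfg, "s1")
  t1 <- ds0$values[, !grepl("_t2$", colnames(ds0$values))]
  t2 <- ds0$values[, grepl("_t2$", colnames(ds0$values))]
  expect_equal(unname(t1), unname(t2))

  # determinism under the same seed
  ds_a <- simulate_expression(nets$s1, cfg, "s1")
  ds_b <- simulate_expression(nets$s1, cfg, "s1")
  expect_identical(ds_a$values, ds_b$values)

  # identifiability: with many noiseless samples OLS recovers beta
  cfg_big <- simulation_config(n_tfs = 3, n_genes = 10, sparsity = 0.3,
                               noise_sd = 0, n_samples = 500, seed = 5)
  ds <- simulate_expression(nets$s1, cfg_big, "s1")
  task <- build_response_design(ds, alpha = attr(ds, "alpha"))
  beta_ols <- qr.solve(task$X, task$Y)
  target <- nets$s1
  target[cbind(rownames(target), rownames(target))] <- 0
  expect_lt(max(abs(beta_ols - target)), 1e-8)
})

test_that("orthology corruption respects its unit conventions", {
  cfg <- simulation_config(n_tfs = 6, n_genes = 46, ortho_frac_tf = 0.5,
                           ortho_frac_gene = 0.25, seed = 6)
  orth <- generate_orthology(cfg) # 3 TF pairs + 10 gene pairs

  cfg_clean <- cfg; cfg_clean$fp_rate <- 0; cfg_clean$fn_rate <- 0
  expect_equal(nrow(corrupt_orthology(orth, cfg_clean)), nrow(orth))

  cfg_fn <- cfg; cfg_fn$fn_rate <- 1
  expect_equal(nrow(corrupt_orthology(orth, cfg_fn)), 0)

  # fp in units of true pairs: 10 true gene pairs, rate 0.5 -> 5 false
  cfg_fp <- cfg; cfg_fp$fp_rate <- 0.5
  out <- corrupt_orthology(orth, cfg_fp)
  added <- out[!out$true, ]
  gene_added <- added[startsWith(added$gene_a, "G"), ]
  expect_equal(nrow(gene_added), 5)
  tf_added <- added[!startsWith(added$gene_a, "G"), ]
  expect_equal(nrow(tf_added), round(0.5 * 3))

  # false pairs never duplicate true pairs, pools never mix
  key <- function(df) paste(df$gene_a, df$gene_b)
  expect_length(intersect(key(added), key(orth)), 0)
  expect_true(all(startsWith(added$gene_a, "G") ==
                    startsWith(added$gene_b, "G")))

  # impossible request is rejected with counts
  cfg_bad <- cfg; cfg_bad$fp_rate <- 50
  expect_error(corrupt_orthology(orth, cfg_bad), "unpaired")
})

test_that("steady design decouples TF mRNA from the driving activities", {
  cfg <- simulation_config(n_tfs = 3, n_genes = 12, sparsity = 0.3,
                           design = "steady", tfa_noise_sd = 0,
                           noise_sd = 0, n_samples = 30, seed = 8)
  nets <- generate_fused_networks(cfg, generate_orthology(cfg))
  ds <- simulate_expression(nets$s1, cfg, "s1")
  A <- attr(ds, "activities")
  # with tfa_noise_sd = 0 mRNA equals activity
  expect_equal(ds$values[rownames(A), ], A, tolerance = 1e-12)
  # non-TF expression is the activity-driven linear response
  non_tf <- setdiff(rownames(ds$values), rownames(A))
  expect_equal(ds$values[non_tf, ],
               t(t(A) %*% nets$s1[, non_tf]), tolerance = 1e-10)
})

test_that("a full study writes and reloads losslessly", {
  cfg <- simulation_config(n_tfs = 4, n_genes = 12, n_samples = 10,
                           sparsity = 0.4, fp_rate = 0.5, fn_rate = 0.2,
                           ortho_frac_tf = 0.5, ortho_frac_gene = 0.5,
                           seed = 11)
  dir <- file.path(tempdir(), "study_fixture")
  unlink(dir, recursive = TRUE)
  st <- generate_study(cfg, dir = dir)
  expect_error(generate_study(cfg, dir = dir), "force")

  back <- read_study(dir)
  expect_equal(back$datasets$s1$values, st$datasets$s1$values,
               tolerance = 1e-12)
  expect_equal(back$datasets$s1$condition_meta,
               st$datasets$s1$condition_meta)
  expect_equal(as.data.frame(back$orthology), as.data.frame(st$orthology))
  expect_equal(back$networks$s1[rownames(st$networks$s1),
                                colnames(st$networks$s1)],
               st$networks$s1, tolerance = 1e-12)
  expect_equal(back$alpha, 0)
  unlink(dir, recursive = TRUE)
})
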