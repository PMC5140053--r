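# Scaled-down simulation studies reproducing the qualitative findings the
# method was designed around: fusion pooling data across related sources,
# constrained/non-constrained subnetwork recovery, adaptive relaxation of
# false constraints, and the benefit of TF-activity predictors. Each study
# is seeded and returns the raw quantities so callers can aggregate over
# replicates.

#' Default ridge grid: log-spaced up to the gradient scale of the task
#'
#' Twenty log-spaced values spanning `1e-3 * lambda_max` to `lambda_max`,
#' where `lambda_max = max |X'Y|`.
#'
#' @param task A `regression_task`.
#' @param n Number of grid points.
#' @return Numeric vector of ridge weights.
#' @export
default_lambda_r_grid <- function(task, n = 20) {
  lam_max <- max(abs(crossprod(task$X, task$Y)))
  if (!is.finite(lam_max) || lam_max <= 0) lam_max <- 1
  exp(seq(log(1e-3 * lam_max), log(lam_max), length.out = n))
}

study_setup <- function(cfg) {
  st <- generate_study(cfg)
  tasks <- lapply(st$datasets, function(d) {
    standardize_predictors(build_response_design(d, attr(d, "alpha")))
  })
  names(tasks) <- names(st$datasets)
  cs <- constraints_from_orthology(tasks, st$orthology)
  list(study = st, tasks = tasks, cs = cs)
}

cv_lambda_r <- function(task, seed, folds = 5, cfg = solver_config()) {
  plan <- cv_plan(nrow(task$X), min(folds, nrow(task$X)), seed = seed)
  as.numeric(select_lambda_r(task, plan, default_lambda_r_grid(task), cfg))
}

#' Fusion-benefit study: data-poor source rescued by a data-rich relative
#'
#' Generates two related networks with partial orthology, gives source 1 few
#' expression samples and source 2 many, selects `lambda_r` (no fusion) and
#' `lambda_s` (fusion path) by cross-validation, and compares the mean
#' squared error of the recovered source-1 network against the true
#' coefficients, fused versus independent.
#'
#' @param seed Seed for the replicate.
#' @param n_tfs,n_genes,ortho_frac,sparsity,sigma_f Generator settings.
#' @param n1,n2 Samples for source 1 (data-poor) and source 2 (data-rich).
#' @param lambda_s_grid CV grid for the fusion weight.
#' @return List with `mse_fused`, `mse_independent`, `lambda_r`, `lambda_s`.
#' @export
sim_fusion_benefit_study <- function(seed, n_tfs = 10, n_genes = 50,
                                     ortho_frac = 0.75, sparsity = 0.75,
                                     sigma_f = 0.1, n1 = 10, n2 = 40,
                                     lambda_s_grid = c(0, 0.01, 0.1, 0.5,
                                                       1, 2, 5, 10)) {
  cfg <- simulation_config(n_tfs = n_tfs, n_genes = n_genes,
                           ortho_frac_tf = ortho_frac,
                           ortho_frac_gene = ortho_frac,
                           sparsity = sparsity, sigma_f = sigma_f,
                           n_samples = c(n1, n2), seed = seed)
  s <- study_setup(cfg)
  lam_r <- cv_lambda_r(s$tasks$s1, seed)
  base <- solver_config(lambda_r = lam_r, tol = 1e-6, max_iter = 200)
  plans <- lapply(s$tasks, function(t) {
    cv_plan(nrow(t$X), min(5, nrow(t$X)), seed = seed)
  })
  lam_s <- as.numeric(select_lambda_s(s$tasks, s$cs, plans, lam_r,
                                      lambda_s_grid, base))
  net_ind <- solve_fused_direct(s$tasks, NULL, base)
  cfg_f <- base; cfg_f$lambda_s <- lam_s
  net_fus <- solve_fused_direct(s$tasks, s$cs, cfg_f)
  truth <- s$study$networks$s1
  list(
    mse_fused = network_mse(rescale_network(net_fus, s$tasks)$s1, truth),
    mse_independent = network_mse(rescale_network(net_ind, s$tasks)$s1,
                                  truth),
    lambda_r = lam_r, lambda_s = lam_s
  )
}

#' Subnetwork recovery study: effect of fusion on (non-)constrained edges
#'
#' Generates two related networks, fits source 1 independently and under
#' fusion, and evaluates edge-recovery AUPR against the true network
#' separately on the constrained subnetwork (edges carrying a fusion
#' constraint) and the non-constrained remainder.
#'
#' @inheritParams sim_fusion_benefit_study
#' @param n_samples Samples per source.
#' @param lambda_s Fusion weight for the fused fit.
#' @return List of AUPRs `constrained_fused`, `constrained_independent`,
#'   `nonconstrained_fused`, `nonconstrained_independent`, plus `lambda_r`.
#' @export
sim_subnetwork_aupr_study <- function(seed, n_tfs = 20, n_genes = 100,
                                      ortho_frac = 0.5, sparsity = 0.5,
                                      sigma_f = 0.1, n_samples = 15,
                                      lambda_s = 1) {
  cfg <- simulation_config(n_tfs = n_tfs, n_genes = n_genes,
                           ortho_frac_tf = ortho_frac,
                           ortho_frac_gene = ortho_frac,
                           sparsity = sparsity, sigma_f = sigma_f,
                           n_samples = n_samples, seed = seed)
  s <- study_setup(cfg)
  lam_r <- cv_lambda_r(s$tasks$s1, seed)
  base <- solver_config(lambda_r = lam_r)
  net_ind <- solve_fused_direct(s$tasks, NULL, base)
  cfg_f <- base; cfg_f$lambda_s <- lambda_s
  net_fus <- solve_fused_direct(s$tasks, s$cs, cfg_f)

  gold <- gold_from_network(s$study$networks$s1, "s1")
  mask <- constrained_mask(s$cs, s$tasks$s1)
  all_edges <- expand.grid(tf = s$tasks$s1$tf_ids,
                           gene = s$tasks$s1$gene_ids,
                           stringsAsFactors = FALSE)
  all_edges <- all_edges[all_edges$tf != all_edges$gene, ]
  in_mask <- mask[cbind(all_edges$tf, all_edges$gene)]
  uni_c <- all_edges[in_mask, ]
  uni_n <- all_edges[!in_mask, ]

  aupr_on <- function(net, uni) {
    sc <- confidence_scores(s$tasks$s1, net$s1)
    evaluate_pr(sc$ranking, gold, uni)$aupr
  }
  list(
    constrained_fused = aupr_on(net_fus, uni_c),
    constrained_independent = aupr_on(net_ind, uni_c),
    nonconstrained_fused = aupr_on(net_fus, uni_n),
    nonconstrained_independent = aupr_on(net_ind, uni_n),
    lambda_r = lam_r
  )
}

#' Adaptive-fusion recovery study with corrupted orthology
#'
#' Generates networks from a partial true orthology, injects false ortholog
#' pairs, and compares fused L2 against adaptive fusion with the saturation
#' point set at a percentile of the independent-fit differences. Reports the
#' unfusing rate of false versus true constraints and the recovery error on
#' the incorrectly fused part of the network.
#'
#' @inheritParams sim_subnetwork_aupr_study
#' @param fp_rate False orthologs added, in units of the true ortholog
#'   count (2/3 turns 60% true coverage into an extra 40% false coverage).
#' @param a_percentile Percentile for [select_a()].
#' @return List with `unfused_rate_true`, `unfused_rate_false`,
#'   `mse_misfused_adaptive`, `mse_misfused_fused`, `mse_misfused_independent`,
#'   `a`, `lambda_r`, `converged`.
#' @export
sim_adaptive_recovery_study <- function(seed, n_tfs = 35, n_genes = 100,
                                        ortho_frac = 0.6, fp_rate = 2 / 3,
                                        sparsity = 0.5, sigma_f = 0.1,
                                        n_samples = 30, lambda_s = 1,
                                        a_percentile = 60) {
  cfg <- simulation_config(n_tfs = n_tfs, n_genes = n_genes,
                           ortho_frac_tf = ortho_frac,
                           ortho_frac_gene = ortho_frac,
                           sparsity = sparsity, sigma_f = sigma_f,
                           n_samples = n_samples, fp_rate = fp_rate,
                           seed = seed)
  s <- study_setup(cfg)
  lam_r <- cv_lambda_r(s$tasks$s1, seed)
  base <- solver_config(lambda_r = lam_r, tol = 1e-4, max_iter = 50)

  net_ind <- solve_fused_direct(s$tasks, NULL, base)
  cfg_f <- base; cfg_f$lambda_s <- lambda_s
  net_fus <- solve_fused_direct(s$tasks, s$cs, cfg_f)

  a <- select_a(net_ind, s$cs, a_percentile)
  ad <- solve_adaptive(s$tasks, s$cs, cfg_f,
                       saturating_penalty(2 * lambda_s, a))

  truth <- s$study$networks$s1
  false_cs <- s$cs[!s$cs$label, , drop = FALSE]
  mis_mask <- constrained_mask(false_cs, s$tasks$s1)
  mse_on <- function(net) {
    network_mse(rescale_network(net, s$tasks)$s1, truth, subset = mis_mask)
  }
  list(
    unfused_rate_true = mean(ad$unfused[s$cs$label]),
    unfused_rate_false = mean(ad$unfused[!s$cs$label]),
    mse_misfused_adaptive = mse_on(ad$networks),
    mse_misfused_fused = mse_on(net_fus),
    mse_misfused_independent = mse_on(net_ind),
    a = a, lambda_r = lam_r, converged = ad$converged
  )
}

#' TF-activity benefit study: latent activities versus TF mRNA predictors
#'
#' Generates steady-state data in which latent TF activities drive target
#' expression while observed TF mRNA is a noisy proxy, estimates activities
#' from half of the gold standard, and compares network recovery using
#' activity predictors against raw TF-expression predictors.
#'
#' @inheritParams sim_fusion_benefit_study
#' @param n_samples Samples for the evaluated source.
#' @param tfa_noise_sd Noise decoupling TF mRNA from activity.
#' @return List with `mse_tfa`, `mse_expression`, `lambda_r_tfa`,
#'   `lambda_r_expression`.
#' @export
sim_tfa_benefit_study <- function(seed, n_tfs = 10, n_genes = 100,
                                  sparsity = 0.9, sigma_f = 0.1,
                                  n_samples = 40, tfa_noise_sd = 2) {
  cfg <- simulation_config(n_tfs = n_tfs, n_genes = n_genes,
                           sparsity = sparsity, sigma_f = sigma_f,
                           n_samples = n_samples, design = "steady",
                           tfa_noise_sd = tfa_noise_sd, seed = seed)
  orth <- generate_orthology(cfg)
  nets <- generate_fused_networks(cfg, orth)
  truth <- nets$s1
  # TF transcript levels are exogenous in the steady design (activity plus
  # measurement noise), so the consistent ground truth has no TF-targeting
  # edges
  truth[, rownames(truth)] <- 0
  ds <- simulate_expression(truth, cfg, "s1")

  gold <- gold_from_network(truth, "s1")
  halves <- split_gold_standard(gold, seed = stage_seed(seed, "gold"))
  activities <- estimate_tfa(ds, halves$prior)

  # estimated activities carry an arbitrary scale (the pseudoinverse of a
  # sign matrix), so recovery is compared on the unit-variance predictor
  # scale, where the generating coefficients live (activities have unit
  # variance by construction)
  fit_mse <- function(predictors) {
    task <- standardize_predictors(
      build_response_design(ds, alpha = attr(ds, "alpha"),
                            predictors = predictors)
    )
    lam_r <- cv_lambda_r(task, seed)
    net <- solve_fused_direct(list(task), NULL,
                              solver_config(lambda_r = lam_r))
    list(mse = network_mse(net$s1, truth), lambda_r = lam_r)
  }
  tfa <- fit_mse(activities)
  expr <- fit_mse(NULL)
  list(mse_tfa = tfa$mse, mse_expression = expr$mse,
       lambda_r_tfa = tfa$lambda_r, lambda_r_expression = expr$lambda_r)
}
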