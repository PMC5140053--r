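# TF activity estimation, confidence scoring, rank combination and
# precision-recall evaluation.

test_that("TFA with an identity prior returns TF expression exactly", {
  set.seed(6)
  vals <- matrix(rnorm(12), 3, 4,
                 dimnames = list(c("t1", "t2", "g3"), paste0("c", 1:4)))
  ds <- make_dataset(vals, c("t1", "t2"))
  prior <- prior_network(data.frame(tf = c("t1", "t2"),
                                    gene = c("t1", "t2"), sign = 1))
  A <- estimate_tfa(ds, prior)
  expect_equal(A, vals[c("t1", "t2"), ], tolerance = 1e-12)
})

test_that("TFA solves the signed prior system by pseudoinverse", {
  # one TF, two targets with expression rows (2, 4) and (4, 8):
  # pinv([1, 1]') = [0.5, 0.5] -> activities (3, 6)
  vals <- rbind(t1 = c(0, 0), gA = c(2, 4), gB = c(4, 8))
  colnames(vals) <- c("c1", "c2")
  ds <- make_dataset(vals, "t1")
  prior <- prior_network(data.frame(tf = "t1", gene = c("gA", "gB"),
                                    sign = 1))
  A <- estimate_tfa(ds, prior)
  expect_equal(unname(A["t1", ]), c(3, 6), tolerance = 1e-10)

  # a TF absent from the prior keeps its own expression as activity
  vals2 <- rbind(vals, t2 = c(9, 7))
  ds2 <- make_dataset(vals2, c("t1", "t2"))
  A2 <- estimate_tfa(ds2, prior)
  expect_equal(unname(A2["t2", ]), c(9, 7))

  # repression signs flip the reconstruction
  prior_neg <- prior_network(data.frame(tf = "t1", gene = c("gA", "gB"),
                                        sign = "repression"))
  A3 <- estimate_tfa(ds, prior_neg)
  expect_equal(unname(A3["t1", ]), c(-3, -6), tolerance = 1e-10)
})

test_that("confidence scores follow the variance-ratio approximation", {
  # sigma2 = 1, beta = 1, var(TF) = 1 -> S = 0.5; beta = 0 -> S = 1
  X <- cbind(t1 = c(1, -1), t2 = c(1, 1)) # population var 1 and 0
  beta <- matrix(c(1, 0), 2, 1, dimnames = list(c("t1", "t2"), "g1"))
  y <- X %*% beta + c(1, -1) # residuals (1, -1): mean square 1
  task <- make_task(X, matrix(y, 2, 1, dimnames = list(NULL, "g1")))
  sc <- confidence_scores(task, beta)
  expect_equal(sc$S["t1", "g1"], 0.5)
  expect_equal(sc$S["t2", "g1"], 1) # zero coefficient -> lowest confidence
  expect_equal(sc$confidence["t1", "g1"], 0.5)

  # S strictly decreasing in |beta| with sigma^2 and var(TF) held fixed
  S_of <- function(b) {
    bm <- matrix(c(b, 0), 2, 1, dimnames = list(c("t1", "t2"), "g1"))
    yb <- X %*% bm + c(1, -1) # same residuals for every b
    tb <- make_task(X, matrix(yb, 2, 1, dimnames = list(NULL, "g1")))
    confidence_scores(tb, bm)$S["t1", "g1"]
  }
  vals <- vapply(c(0.5, 1, 2, 4), S_of, numeric(1))
  expect_true(all(diff(vals) < 0))

  # permutation equivariance over genes
  set.seed(10)
  Xb <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("t1", "t2")))
  Yb <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("gA", "gB", "gC")))
  taskb <- make_task(Xb, Yb)
  netb <- solve_fused_direct(list(taskb), NULL, solver_config(lambda_r = 1))
  S1 <- confidence_scores(taskb, netb$s1)$S
  perm <- c("gC", "gA", "gB")
  taskp <- make_task(Xb, Yb[, perm])
  S2 <- confidence_scores(taskp, netb$s1[, perm])$S
  expect_equal(S1[, perm], S2, tolerance = 1e-12)
})

test_that("full-refit scoring is bounded and agrees on zero coefficients", {
  set.seed(14)
  X <- matrix(rnorm(30), 10, 3,
              dimnames = list(NULL, c("t1", "t2", "t3")))
  Y <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("gA", "gB")))
  task <- make_task(X, Y)
  cfg <- solver_config(lambda_r = 1)
  net <- solve_fused_direct(list(task), NULL, cfg)
  sc <- confidence_scores(task, net$s1, variant = "full_refit", cfg = cfg)
  expect_true(all(sc$S > 0 & sc$S <= 1))
})

test_that("rank combination averages ranks over the common edge set", {
  mk <- function(svals) {
    matrix(svals, 1, 3, dimnames = list("t1", c("gA", "gB", "gC")))
  }
  # identical rankings are preserved, also for k copies
  r1 <- mk(c(0.1, 0.2, 0.3))
  comb <- rank_combine(list(r1, r1, r1))
  expect_equal(comb$gene, c("gA", "gB", "gC"))

  # opposite rankings tie completely
  comb2 <- rank_combine(list(mk(c(0.1, 0.2, 0.3)), mk(c(0.3, 0.2, 0.1))))
  expect_true(all(comb2$mean_rank == 2))

  # (1,2,3) + (2,1,3): edges 1 and 2 tie at 1.5, then edge 3
  comb3 <- rank_combine(list(mk(c(0.1, 0.2, 0.3)), mk(c(0.2, 0.1, 0.3))))
  expect_equal(comb3$mean_rank, c(1.5, 1.5, 3))
  expect_setequal(comb3$gene[1:2], c("gA", "gB"))

  expect_error(rank_combine(list(r1, mk(c(1, 2, 3))[, 1:2, drop = FALSE])),
               "identical edge sets")
})

test_that("precision-recall follows the step-integration convention", {
  ranking <- data.frame(tf = "t1", gene = paste0("e", 1:4))
  gold <- data.frame(tf = "t1", gene = c("e1", "e3"), sign = 1)
  ev <- evaluate_pr(ranking, gold)
  # precision at recalls (0.5, 1.0) = (1, 2/3); step AUPR = 5/6
  expect_equal(ev$curve$precision[ev$curve$recall == 0.5][1], 1)
  expect_equal(ev$curve$precision[ev$curve$recall == 1][1], 2 / 3)
  expect_equal(ev$aupr, 5 / 6)
  expect_equal(ev$curve$precision[1], 1)
  expect_equal(ev$curve$recall[4], 1)

  # all gold first -> AUPR 1
  gold_top <- data.frame(tf = "t1", gene = c("e1", "e2"), sign = 1)
  expect_equal(evaluate_pr(ranking, gold_top)$aupr, 1)

  # invariance under monotone transforms of the score (order unchanged)
  expect_equal(evaluate_pr(ranking[order(1:4), ], gold)$aupr,
               evaluate_pr(ranking[order(exp(1:4)), ], gold)$aupr)

  # universe restriction drops outside edges and outside gold
  uni <- data.frame(tf = "t1", gene = c("e1", "e2", "e3"))
  ev_u <- evaluate_pr(ranking, gold, uni)
  expect_equal(ev_u$n_edges, 3)
  expect_error(evaluate_pr(ranking,
                           data.frame(tf = "t1", gene = "zzz", sign = 1)),
               "no gold-standard edges")
})

test_that("random rankings score near the positive rate", {
  set.seed(123)
  auprs <- vapply(1:30, function(i) {
    edges <- paste0("e", 1:500)
    ranking <- data.frame(tf = "t1", gene = sample(edges))
    gold <- data.frame(tf = "t1", gene = sample(edges, 50), sign = 1)
    evaluate_pr(ranking, gold)$aupr
  }, numeric(1))
  expect_lt(abs(mean(auprs) - 0.1), 0.02)
})

test_that("gold standards split reproducibly into disjoint halves", {
  gold <- prior_network(data.frame(tf = "t1", gene = paste0("g", 1:20),
                                   sign = rep(c(1, -1), 10)))
  sp1 <- split_gold_standard(gold, seed = 5)
  sp2 <- split_gold_standard(gold, seed = 5)
  expect_equal(sp1$prior, sp2$prior)
  expect_equal(nrow(sp1$prior), 10)
  expect_length(intersect(sp1$prior$gene, sp1$eval$gene), 0)
})
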