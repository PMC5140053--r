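# Transcription factor activity estimation, confidence scoring of fitted
# coefficients, rank combination of networks, and precision-recall
# evaluation against gold standards.

#' Construct a prior / gold-standard network
#'
#' @param edges Data frame with columns `tf`, `gene` and `sign`; signs may be
#'   `+1`/`-1` or the words `"activation"`/`"repression"`.
#' @param source_id Source the network refers to.
#' @return An object of class `prior_network` (data frame with signs in
#'   {-1, +1} and no duplicate edges).
#' @export
prior_network <- function(edges, source_id = "source1") {
  if (!all(c("tf", "gene", "sign") %in% names(edges))) {
    stop("prior edges need columns `tf`, `gene`, `sign`")
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  edges$tf <- as.character(edges$tf)
  edges$gene <- as.character(edges$gene)
  s <- edges$sign
  if (is.character(s) || is.factor(s)) {
    s <- as.character(s)
    map <- c(activation = 1, repression = -1, `+1` = 1, `-1` = -1,
             `1` = 1)
    if (!all(s %in% names(map))) {
      stop("gold-standard signs must be +1/-1 or activation/repression; ",
           "offending values: ",
           paste(unique(s[!s %in% names(map)]), collapse = ", "))
    }
    s <- unname(map[s])
  }
  if (!all(s %in% c(-1, 1))) {
    stop("gold-standard signs must be +1 or -1")
  }
  edges$sign <- as.numeric(s)
  if (anyDuplicated(paste(edges$tf, edges$gene, sep = SEP))) {
    stop("duplicate (tf, gene) edges in prior network")
  }
  attr(edges, "source_id") <- source_id
  class(edges) <- c("prior_network", "data.frame")
  edges
}

#' Estimate transcription factor activities by network component analysis
#'
#' Solves `P %*% A ~ E` for the activity matrix `A` (TFs x conditions), where
#' `P` is the signed prior connectivity over prior-target genes and `E` their
#' expression, using the Moore-Penrose pseudoinverse (minimum-norm least
#' squares). TFs with no prior targets retain their own expression as
#' activity, so with an identity prior (each TF regulating only itself with
#' sign +1) the activities equal TF expression exactly.
#'
#' @param ds An [expression_dataset()].
#' @param prior A [prior_network()]; TFs and genes must exist in `ds`.
#' @return Matrix of activities, TFs x conditions, with dimnames.
#' @export
estimate_tfa <- function(ds, prior) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (length(ds$tf_ids) == 0) stop("dataset declares no TFs")
  tfs <- ds$tf_ids
  A <- ds$values[tfs, , drop = FALSE] # fallback: expression as activity
  if (is.null(prior) || nrow(prior) == 0) return(A)

  bad <- setdiff(prior$tf, tfs)
  if (length(bad) > 0) {
    stop("prior TFs absent from dataset: ", paste(bad, collapse = ", "))
  }
  bad <- setdiff(prior$gene, ds$gene_ids)
  if (length(bad) > 0) {
    stop("prior targets absent from dataset: ", paste(bad, collapse = ", "))
  }

  prior_tfs <- intersect(tfs, unique(prior$tf))
  targets <- sort(unique(prior$gene))
  P <- matrix(0, length(targets), length(prior_tfs),
              dimnames = list(targets, prior_tfs))
  P[cbind(match(prior$gene, targets), match(prior$tf, prior_tfs))] <-
    prior$sign
  E <- ds$values[targets, , drop = FALSE]
  A[prior_tfs, ] <- MASS::ginv(P) %*% E
  A
}

#' Confidence scores for ranked regulatory hypotheses
#'
#' Rescales fitted coefficients into scores `S` in (0, 1]. The default
#' `"approximation"` variant computes, per interaction,
#' `S = sigma2_full / (sigma2_full + beta^2 * var(TF))`, where `sigma2_full`
#' is the full model's mean squared residual for the target gene; it uses
#' only the fitted model, so information gained through fusion is retained.
#' The `"full_refit"` variant instead refits the (independent ridge) model
#' without each predictor and reports the ratio of full to reduced residual
#' variances; it is provided for comparison and disregards fusion. Smaller
#' `S` means more variance explained, so edges are ranked by ascending `S`;
#' the reported `confidence = 1 - S` makes larger values better. A zero
#' coefficient always yields `S = 1` (lowest confidence).
#'
#' @param task The `regression_task` the network was fitted on.
#' @param network The fitted TFs x genes coefficient matrix for this source.
#' @param variant `"approximation"` (default) or `"full_refit"`.
#' @param cfg A [solver_config()]; needed by the `"full_refit"` variant.
#' @return An object of class `confidence_matrix`: list with matrices `S`
#'   and `confidence`, and `ranking`, a data frame of non-self edges ordered
#'   best first (ties broken lexicographically for determinism).
#' @export
confidence_scores <- function(task, network,
                              variant = c("approximation", "full_refit"),
                              cfg = solver_config()) {
  variant <- match.arg(variant)
  stopifnot(inherits(task, "regression_task"))
  beta <- network
  if (inherits(network, "network_coefficients")) {
    beta <- network[[task$source_id]]
  }
  stopifnot(nrow(beta) == length(task$tf_ids),
            ncol(beta) == length(task$gene_ids))

  resid <- task$Y - task$X %*% beta
  n <- nrow(task$X)
  sigma2 <- colSums(resid^2) / n
  floored <- sigma2 < 1e-12 & apply(beta != 0, 2, any)
  if (any(floored)) {
    warning("zero residual variance with nonzero coefficients for ",
            sum(floored), " gene(s); flooring sigma^2 at 1e-12")
  }
  sigma2 <- pmax(sigma2, 1e-12)

  if (variant == "approximation") {
    v <- colMeans(sweep(task$X, 2, colMeans(task$X), "-")^2) # population var
    S <- 1 / (1 + sweep(beta^2 * v, 2, sigma2, "/"))
  } else {
    # refit the independent ridge model without each predictor
    S <- matrix(1, nrow(beta), ncol(beta),
                dimnames = dimnames(beta))
    XtX <- crossprod(task$X)
    XtY <- crossprod(task$X, task$Y)
    K <- kappa_matrix(task, cfg)
    for (g in seq_along(task$gene_ids)) {
      gene <- task$gene_ids[g]
      keep_full <- which(task$tf_ids != gene)
      for (j in keep_full) {
        keep <- setdiff(keep_full, j)
        if (length(keep) == 0) next
        M <- XtX[keep, keep, drop = FALSE]
        diag(M) <- diag(M) + cfg$lambda_r * K[keep, g]
        b_red <- solve(M, XtY[keep, g])
        r_red <- task$Y[, g] - task$X[, keep, drop = FALSE] %*% b_red
        S[j, g] <- sigma2[g] / max(mean(r_red^2), 1e-12)
      }
    }
    S <- pmin(S, 1)
  }
  dimnames(S) <- list(task$tf_ids, task$gene_ids)

  ranking <- ranking_from_scores(S, beta)
  structure(list(S = S, confidence = 1 - S, ranking = ranking),
            class = "confidence_matrix")
}

# order non-self edges by ascending S, ties broken lexicographically
ranking_from_scores <- function(S, beta = NULL) {
  df <- data.frame(
    tf = rep(rownames(S), times = ncol(S)),
    gene = rep(colnames(S), each = nrow(S)),
    S = as.vector(S),
    stringsAsFactors = FALSE
  )
  if (!is.null(beta)) df$beta <- as.vector(beta)
  df <- df[df$tf != df$gene, , drop = FALSE]
  df <- df[order(df$S, df$tf, df$gene), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Rank-combine several confidence matrices
#'
#' Converts each matrix to ranks over the common edge set (average ranks for
#' ties), averages ranks per edge, and re-ranks edges by mean rank — the
#' standard community approach to combining networks learned from disparate
#' datasets.
#'
#' @param networks List of `confidence_matrix` objects (or S matrices) over
#'   a common edge set.
#' @return Data frame of edges with `mean_rank`, ordered best first (ties
#'   broken lexicographically).
#' @export
rank_combine <- function(networks) {
  mats <- lapply(networks, function(x) {
    if (inherits(x, "confidence_matrix")) x$S else x
  })
  ref <- dimnames(mats[[1]])
  for (m in mats) {
    if (!identical(dimnames(m), ref)) {
      stop("rank_combine requires matrices over identical edge sets")
    }
  }
  sel <- which(outer(ref[[1]], ref[[2]], "!="))
  edge_df <- data.frame(
    tf = rep(ref[[1]], times = length(ref[[2]]))[sel],
    gene = rep(ref[[2]], each = length(ref[[1]]))[sel],
    stringsAsFactors = FALSE
  )
  ranks <- vapply(mats, function(m) rank(m[sel], ties.method = "average"),
                  numeric(length(sel)))
  edge_df$mean_rank <- rowMeans(ranks)
  edge_df <- edge_df[order(edge_df$mean_rank, edge_df$tf, edge_df$gene), ,
                     drop = FALSE]
  edge_df$rank <- seq_len(nrow(edge_df))
  rownames(edge_df) <- NULL
  edge_df
}

#' Precision-recall (and ROC) evaluation against a gold standard
#'
#' Walks the ranked edge list treating gold-standard edges as positives
#' (signs ignored) and computes the precision-recall curve and its area by
#' the step convention: AUPR is the sum over positive hits of
#' `delta_recall * precision` at the hit, i.e. average precision. AUROC is
#' computed from the Mann-Whitney statistic on the ranking. The eligible
#' universe can be restricted (e.g. to the constrained or non-constrained
#' subnetwork); gold edges outside the universe are dropped.
#'
#' @param ranking Data frame with columns `tf`, `gene`, ordered best first
#'   (e.g. from [confidence_scores()] or [rank_combine()]).
#' @param gold A [prior_network()] or data frame with `tf`, `gene`.
#' @param universe Optional data frame with columns `tf`, `gene` restricting
#'   the eligible edges; defaults to the edges of `ranking`.
#' @return List with `curve` (data frame `recall`, `precision`), `aupr`,
#'   `auroc`, and counts `n_positive`, `n_edges`.
#' @export
evaluate_pr <- function(ranking, gold, universe = NULL) {
  stopifnot(all(c("tf", "gene") %in% names(ranking)),
            all(c("tf", "gene") %in% names(gold)))
  edge_id <- function(df) paste(df$tf, df$gene, sep = SEP)
  rk <- edge_id(ranking)
  if (anyDuplicated(rk)) stop("ranking contains duplicate edges")
  if (!is.null(universe)) {
    uni <- unique(edge_id(universe))
    keep <- rk %in% uni
    ranking <- ranking[keep, , drop = FALSE]
    rk <- rk[keep]
  }
  gold_ids <- unique(edge_id(gold))
  gold_ids <- intersect(gold_ids, rk)
  if (length(gold_ids) == 0) {
    stop("no gold-standard edges fall inside the eligible universe")
  }
  pos <- rk %in% gold_ids
  tp <- cumsum(pos)
  k <- seq_along(pos)
  precision <- tp / k
  recall <- tp / length(gold_ids)
  # step AUPR: precision collected at each new true positive
  aupr <- sum(precision[pos] * (1 / length(gold_ids)))
  # AUROC via rank statistic (smaller rank index = better)
  n_pos <- length(gold_ids)
  n_neg <- length(rk) - n_pos
  auroc <- if (n_neg == 0) {
    NA_real_
  } else {
    (sum(k[!pos]) - n_neg * (n_neg + 1) / 2) / (n_pos * n_neg)
  }
  list(
    curve = data.frame(recall = recall, precision = precision),
    aupr = aupr,
    auroc = auroc,
    n_positive = n_pos,
    n_edges = length(rk)
  )
}

#' Split a gold standard into prior and evaluation halves
#'
#' Randomly divides the known interactions in half: one half serves as the
#' prior (for TFA estimation and ridge relaxation), the other is reserved
#' for evaluation.
#'
#' @param gold A [prior_network()].
#' @param seed Integer seed for the split.
#' @return List with elements `prior` and `eval`, both `prior_network`s.
#' @export
split_gold_standard <- function(gold, seed = 1) {
  stopifnot(inherits(gold, "prior_network"))
  n <- nrow(gold)
  if (n < 2) stop("gold standard too small to split")
  set.seed(seed)
  idx <- sample.int(n, floor(n / 2))
  src <- attr(gold, "source_id")
  list(
    prior = prior_network(as.data.frame(gold)[idx, , drop = FALSE], src),
    eval = prior_network(as.data.frame(gold)[-idx, , drop = FALSE], src)
  )
}
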