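# Generator for paired regulatory networks, two-timepoint expression data and
# corruptible orthology, emulating the structure of related biological
# processes so every stage of the pipeline is testable without downloads.

#' Simulation configuration
#'
#' @param n_tfs Number of TFs per source.
#' @param n_genes Total number of genes per source (TFs included; the first
#'   `n_tfs` genes are the TFs).
#' @param n_sources Number of sources (>= 2).
#' @param ortho_frac_tf,ortho_frac_gene Fractions in `[0, 1]` of TFs and of
#'   non-TF genes assigned one-to-one orthologs between each pair of sources
#'   (pair counts are floored).
#' @param sparsity Probability that an entire fused coefficient group is zero.
#' @param sigma_f Divergence noise: fused group members are `v + N(0,
#'   sigma_f^2)` around a shared `v ~ N(0, 1)`, so nonzero coefficients are
#'   `N(0, 1 + sigma_f^2)` and cross-source differences of truly fused
#'   entries have variance `2 sigma_f^2`.
#' @param n_samples Number of expression samples per source (scalar or vector
#'   of length `n_sources`).
#' @param noise_sd Standard deviation of the expression noise term.
#' @param fp_rate False-positive orthology rate, in units of the number of
#'   true orthologs (per TF/gene class).
#' @param fn_rate Fraction of true ortholog pairs discarded.
#' @param design `"timeseries"` (two-timepoint pairs, decay treated as 0) or
#'   `"steady"` (steady-state conditions driven by latent TF activities,
#'   decay rate 1).
#' @param tfa_noise_sd For the `"steady"` design: standard deviation of the
#'   noise separating observed TF mRNA from the latent activity that actually
#'   drives targets. 0 makes mRNA equal activity.
#' @param seed Master seed; every stage derives its own substream from it.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_tfs = 10, n_genes = 200, n_sources = 2,
                              ortho_frac_tf = 0.75, ortho_frac_gene = 0.75,
                              sparsity = 0.75, sigma_f = 0.1,
                              n_samples = 20, noise_sd = 0.1,
                              fp_rate = 0, fn_rate = 0,
                              design = c("timeseries", "steady"),
                              tfa_noise_sd = 0, seed = 1) {
  design <- match.arg(design)
  stopifnot(n_tfs >= 1, n_genes > n_tfs, n_sources >= 2,
            ortho_frac_tf >= 0, ortho_frac_tf <= 1,
            ortho_frac_gene >= 0, ortho_frac_gene <= 1,
            sparsity >= 0, sparsity <= 1, sigma_f >= 0,
            all(n_samples >= 2), noise_sd >= 0,
            fp_rate >= 0, fn_rate >= 0, fn_rate <= 1,
            tfa_noise_sd >= 0)
  if (length(n_samples) == 1) n_samples <- rep(n_samples, n_sources)
  stopifnot(length(n_samples) == n_sources)
  structure(
    list(n_tfs = n_tfs, n_genes = n_genes, n_sources = n_sources,
         ortho_frac_tf = ortho_frac_tf, ortho_frac_gene = ortho_frac_gene,
         sparsity = sparsity, sigma_f = sigma_f, n_samples = n_samples,
         noise_sd = noise_sd, fp_rate = fp_rate, fn_rate = fn_rate,
         design = design, tfa_noise_sd = tfa_noise_sd,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# deterministic per-stage substream seeds, kept below 2^31
stage_seed <- function(seed, stage) {
  stages <- c(orthology = 1L, networks = 2L, expression = 3L,
              corruption = 4L, workflow = 5L, gold = 6L)
  off <- stages[[stage]]
  as.integer((as.numeric(seed) * 48271 + off * 104729) %% 2147483629)
}

sim_sources <- function(cfg) paste0("s", seq_len(cfg$n_sources))

sim_tf_ids <- function(cfg) sprintf("T%03d", seq_len(cfg$n_tfs))

sim_gene_ids <- function(cfg) {
  c(sim_tf_ids(cfg), sprintf("G%03d", seq_len(cfg$n_genes - cfg$n_tfs)))
}

#' Generate a random one-to-one orthology map
#'
#' Pairs random genes between each pair of sources until the configured
#' fraction has been assigned an ortholog (pair counts floored), separately
#' for TFs and non-TF genes so the two pools never mix.
#'
#' @param cfg A [simulation_config()].
#' @return An [orthology_map()] with all pairs labelled true.
#' @export
generate_orthology <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(stage_seed(cfg$seed, "orthology"))
  sources <- sim_sources(cfg)
  tfs <- sim_tf_ids(cfg)
  nontf <- setdiff(sim_gene_ids(cfg), tfs)
  out <- list()
  for (i in seq_len(cfg$n_sources - 1)) {
    for (j in seq((i + 1), cfg$n_sources)) {
      pair_pool <- function(pool, frac) {
        k <- floor(frac * length(pool))
        if (k == 0) return(NULL)
        data.frame(source_a = sources[i],
                   gene_a = sample(pool, k),
                   source_b = sources[j],
                   gene_b = sample(pool, k),
                   true = TRUE, stringsAsFactors = FALSE)
      }
      out[[paste(i, j)]] <- rbind(pair_pool(tfs, cfg$ortho_frac_tf),
                                  pair_pool(nontf, cfg$ortho_frac_gene))
    }
  }
  df <- do.call(rbind, out)
  if (is.null(df)) {
    df <- data.frame(source_a = character(), gene_a = character(),
                     source_b = character(), gene_b = character(),
                     true = logical(), stringsAsFactors = FALSE)
  }
  orthology_map(df)
}

#' Generate a family of fused regulatory networks
#'
#' Walks the coefficient entries of all sources; each unfilled entry defines
#' a fused group consisting of the entry together with every entry it is
#' (transitively) fused to through true orthology. With probability
#' `sparsity` the whole group is set to zero; otherwise a shared value
#' `v ~ N(0, 1)` is drawn and each member set to `v + N(0, sigma_f^2)`.
#' Self interactions are structural zeros.
#'
#' @param cfg A [simulation_config()].
#' @param orth An [orthology_map()]; only pairs labelled true participate in
#'   group construction (false pairs model corrupted knowledge, not shared
#'   biology).
#' @return A `network_coefficients` object (one TFs x genes matrix per
#'   source).
#' @export
generate_fused_networks <- function(cfg, orth) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(stage_seed(cfg$seed, "networks"))
  sources <- sim_sources(cfg)
  tfs <- sim_tf_ids(cfg)
  genes <- sim_gene_ids(cfg)

  true_orth <- orth[orth$true, , drop = FALSE]
  class_of <- function(ids_per_source, pairs) {
    verts <- unlist(lapply(sources, function(s) {
      paste(s, ids_per_source, sep = SEP)
    }))
    edges <- data.frame(
      from = paste(pairs$source_a, pairs$gene_a, sep = SEP),
      to = paste(pairs$source_b, pairs$gene_b, sep = SEP),
      stringsAsFactors = FALSE
    )
    edges <- edges[edges$from %in% verts & edges$to %in% verts, , drop = FALSE]
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = data.frame(name = verts))
    igraph::components(g)$membership[verts]
  }
  tf_class <- class_of(tfs, true_orth[true_orth$gene_a %in% tfs, ,
                                      drop = FALSE])
  # TFs are targets too: all orthology pairs link targets
  gene_class <- class_of(genes, true_orth)

  entries <- do.call(rbind, lapply(sources, function(s) {
    g <- expand.grid(tf = tfs, gene = genes, stringsAsFactors = FALSE)
    g <- g[g$tf != g$gene, , drop = FALSE]
    g$source <- s
    g$key <- paste(tf_class[paste(s, g$tf, sep = SEP)],
                   gene_class[paste(s, g$gene, sep = SEP)], sep = SEP)
    g
  }))

  nets <- lapply(sources, function(s) {
    matrix(0, length(tfs), length(genes), dimnames = list(tfs, genes))
  })
  names(nets) <- sources

  groups <- split(seq_len(nrow(entries)), entries$key)
  # iterate groups in a deterministic order for reproducibility
  for (gi in groups[order(names(groups))]) {
    if (stats::runif(1) < cfg$sparsity) next # whole group zero
    v <- stats::rnorm(1)
    vals <- v + stats::rnorm(length(gi), sd = cfg$sigma_f)
    for (k in seq_along(gi)) {
      e <- entries[gi[k], ]
      nets[[e$source]][e$tf, e$gene] <- vals[k]
    }
  }
  structure(nets, class = "network_coefficients")
}

#' Simulate expression data from a network
#'
#' Under the `"timeseries"` design, draws first-timepoint expression
#' `Y_T1 ~ N(0, I)` over all genes, takes `X_T1` as its TF columns, and sets
#' `Y_T2 = Y_T1 + X_T1 beta + eps` with `eps ~ N(0, noise_sd^2)`, treating
#' the decay rate as zero. Conditions are emitted as time-series pairs with
#' `delta_t = 1`; first timepoints carry no predecessor and contribute no
#' regression row.
#'
#' Under the `"steady"` design, latent activities `A ~ N(0, I)` drive target
#' expression `x = A beta + eps` at steady state (decay rate 1); observed TF
#' mRNA is `A + N(0, tfa_noise_sd^2)`, decoupling activity from abundance
#' when `tfa_noise_sd > 0`. The latent activities are attached as attribute
#' `"activities"`.
#'
#' @param network TFs x genes coefficient matrix for one source.
#' @param cfg A [simulation_config()].
#' @param source_id Source label for the dataset.
#' @param n Number of samples; defaults to the configured count for this
#'   source.
#' @param seed Substream seed; defaults to a stream derived from
#'   `cfg$seed` and `source_id`.
#' @return An [expression_dataset()] with attribute `"alpha"` giving the
#'   decay rate the design builder should use (0 for `"timeseries"`, 1 for
#'   `"steady"`).
#' @export
simulate_expression <- function(network, cfg, source_id = "s1", n = NULL,
                                seed = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  sources <- sim_sources(cfg)
  if (is.null(n)) {
    pos <- match(source_id, sources)
    n <- if (is.na(pos)) cfg$n_samples[1] else cfg$n_samples[pos]
  }
  if (is.null(seed)) {
    pos <- match(source_id, sources)
    if (is.na(pos)) pos <- 1L
    seed <- stage_seed(cfg$seed + pos, "expression")
  }
  set.seed(seed)
  tfs <- rownames(network)
  genes <- colnames(network)

  if (cfg$design == "timeseries") {
    Y1 <- matrix(stats::rnorm(n * length(genes)), n, length(genes),
                 dimnames = list(NULL, genes))
    X1 <- Y1[, tfs, drop = FALSE]
    eps <- matrix(stats::rnorm(n * length(genes), sd = cfg$noise_sd),
                  n, length(genes))
    Y2 <- Y1 + X1 %*% network + eps
    vals <- t(rbind(Y1, Y2)) # genes x conditions
    c1 <- sprintf("c%03d_t1", seq_len(n))
    c2 <- sprintf("c%03d_t2", seq_len(n))
    colnames(vals) <- c(c1, c2)
    meta <- data.frame(
      condition = c(c1, c2),
      is_time_series = TRUE,
      predecessor = c(rep(NA_character_, n), c1),
      delta_t = c(rep(NA_real_, n), rep(1, n)),
      stringsAsFactors = FALSE
    )
    ds <- expression_dataset(vals, tfs, meta, source_id)
    attr(ds, "alpha") <- 0
  } else {
    A <- matrix(stats::rnorm(n * length(tfs)), n, length(tfs),
                dimnames = list(NULL, tfs))
    eps <- matrix(stats::rnorm(n * length(genes), sd = cfg$noise_sd),
                  n, length(genes))
    E <- A %*% network + eps # conditions x genes
    # observed TF mRNA tracks activity up to noise; it may differ from the
    # activity that actually drives the targets
    E[, tfs] <- A + matrix(stats::rnorm(n * length(tfs),
                                        sd = cfg$tfa_noise_sd),
                           n, length(tfs))
    vals <- t(E)
    colnames(vals) <- sprintf("c%03d", seq_len(n))
    ds <- expression_dataset(vals, tfs, NULL, source_id)
    attr(ds, "alpha") <- 1
    attr(ds, "activities") <- t(A) # TFs x conditions
    colnames(attr(ds, "activities")) <- colnames(vals)
  }
  ds
}

#' Corrupt an orthology map
#'
#' Removes a fraction of true pairs uniformly at random and adds false pairs
#' drawn among the genes currently without orthologs (TF-to-TF and
#' gene-to-gene only, so pools never mix). The false-positive count is
#' `round(fp_rate * number of true pairs)` per class, expressing the rate in
#' units of the number of true orthologs rather than possible orthologs.
#'
#' @param orth An [orthology_map()] (all pairs labelled true).
#' @param cfg A [simulation_config()] supplying `fp_rate`, `fn_rate` and the
#'   TF/gene pools.
#' @return An [orthology_map()] with a logical `true` column labelling
#'   surviving true pairs versus injected false pairs.
#' @export
corrupt_orthology <- function(orth, cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(stage_seed(cfg$seed, "corruption"))
  tfs <- sim_tf_ids(cfg)
  df <- as.data.frame(orth, stringsAsFactors = FALSE)

  # false negatives: drop a fraction of true pairs uniformly
  n_drop <- round(cfg$fn_rate * nrow(df))
  if (n_drop > 0) {
    df <- df[-sample.int(nrow(df), n_drop), , drop = FALSE]
  }

  out <- df
  src_pairs <- unique(df[, c("source_a", "source_b")])
  if (nrow(src_pairs) == 0 && cfg$fp_rate > 0) {
    src_pairs <- data.frame(source_a = sim_sources(cfg)[1],
                            source_b = sim_sources(cfg)[2],
                            stringsAsFactors = FALSE)
  }
  if (cfg$fp_rate > 0) {
    all_true <- as.data.frame(orth, stringsAsFactors = FALSE)
    for (r in seq_len(nrow(src_pairs))) {
      sa <- src_pairs$source_a[r]; sb <- src_pairs$source_b[r]
      sub_true <- all_true[all_true$source_a == sa & all_true$source_b == sb, ]
      cur <- out[out$source_a == sa & out$source_b == sb, ]
      for (cls in c("tf", "gene")) {
        pool <- if (cls == "tf") tfs else setdiff(sim_gene_ids(cfg), tfs)
        n_true_cls <- sum(sub_true$gene_a %in% pool)
        n_fp <- round(cfg$fp_rate * n_true_cls)
        if (n_fp == 0) next
        free_a <- setdiff(pool, cur$gene_a[cur$gene_a %in% pool])
        free_b <- setdiff(pool, cur$gene_b[cur$gene_b %in% pool])
        if (length(free_a) < n_fp || length(free_b) < n_fp) {
          stop("cannot add ", n_fp, " false ", cls, " pairs: only ",
               length(free_a), " x ", length(free_b), " unpaired ids left")
        }
        fp <- data.frame(source_a = sa,
                         gene_a = sample(free_a, n_fp),
                         source_b = sb,
                         gene_b = sample(free_b, n_fp),
                         true = FALSE, stringsAsFactors = FALSE)
        out <- rbind(out, fp)
        cur <- rbind(cur, fp)
      }
    }
  }
  rownames(out) <- NULL
  orthology_map(out)
}

#' Generate a complete simulation study
#'
#' Runs the full generator: true orthology, fused networks, expression data
#' per source, and (optionally corrupted) orthology handed to inference.
#' When `dir` is given, all files are written in the TSV formats the
#' workflow consumes, along with a manifest recording the seed and all
#' parameters.
#'
#' @param cfg A [simulation_config()].
#' @param dir Optional output directory for the on-disk fixture.
#' @param force Overwrite an existing non-empty directory.
#' @return Invisibly, a list with `datasets` (per source), `networks` (true
#'   coefficients), `orthology` (as given to inference, with truth labels),
#'   `orthology_true`, `alpha`, and `config`.
#' @export
generate_study <- function(cfg, dir = NULL, force = FALSE) {
  stopifnot(inherits(cfg, "simulation_config"))
  orth_true <- generate_orthology(cfg)
  networks <- generate_fused_networks(cfg, orth_true)
  orth <- if (cfg$fp_rate > 0 || cfg$fn_rate > 0) {
    corrupt_orthology(orth_true, cfg)
  } else {
    orth_true
  }
  sources <- sim_sources(cfg)
  datasets <- lapply(sources, function(s) {
    simulate_expression(networks[[s]], cfg, source_id = s)
  })
  names(datasets) <- sources
  alpha <- attr(datasets[[1]], "alpha")

  study <- list(datasets = datasets, networks = networks,
                orthology = orth, orthology_true = orth_true,
                alpha = alpha, config = cfg)
  class(study) <- "simulation_study"
  if (!is.null(dir)) write_study(study, dir, force = force)
  invisible(study)
}

#' Gold standard derived from a true simulated network
#'
#' The nonzero, non-self entries of the true coefficient matrix, signed.
#'
#' @param network TFs x genes true coefficient matrix.
#' @param source_id Source label.
#' @return A [prior_network()].
#' @export
gold_from_network <- function(network, source_id = "s1") {
  idx <- which(network != 0, arr.ind = TRUE)
  df <- data.frame(
    tf = rownames(network)[idx[, 1]],
    gene = colnames(network)[idx[, 2]],
    sign = ifelse(network[idx] > 0, 1, -1),
    stringsAsFactors = FALSE
  )
  df <- df[df$tf != df$gene, , drop = FALSE]
  df <- df[order(df$tf, df$gene), , drop = FALSE]
  prior_network(df, source_id)
}
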