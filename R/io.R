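# TSV readers/writers for every interchange format, study fixtures and run
# outputs. All files are tab-separated UTF-8 with '#' comment lines;
# outputs are deterministically ordered for diffability.

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          comment.char = "#", check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(path, ": missing column(s) ", paste(missing, collapse = ", "))
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

#' Read an expression dataset from TSV files
#'
#' @param expression_path TSV with first column `gene` and one column per
#'   condition.
#' @param meta_path Optional condition-metadata TSV with columns `condition`,
#'   `isTs` (TRUE/FALSE), `prevCond` (condition id or NA) and `del.t`
#'   (minutes or NA). When omitted all conditions are steady state.
#' @param tf_path Text file with one TF id per line.
#' @param source_id Source label.
#' @return An [expression_dataset()].
#' @export
read_expression_tsv <- function(expression_path, tf_path, meta_path = NULL,
                                source_id = "source1") {
  df <- read_tsv_checked(expression_path, "gene", "expression")
  genes <- as.character(df$gene)
  mat <- as.matrix(df[, setdiff(names(df), "gene"), drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(as.numeric(mat))) & !is.na(mat))
    stop(expression_path, ": non-numeric expression values (first at ",
         "entry ", if (length(bad)) bad[1] else "?", ")")
  }
  rownames(mat) <- genes

  tfs <- readLines(tf_path, warn = FALSE)
  tfs <- trimws(tfs)
  tfs <- tfs[nzchar(tfs) & !startsWith(tfs, "#")]

  meta <- NULL
  if (!is.null(meta_path)) {
    m <- read_tsv_checked(meta_path, c("condition", "isTs", "prevCond",
                                       "del.t"), "condition metadata")
    meta <- data.frame(
      condition = as.character(m$condition),
      is_time_series = as.logical(m$isTs),
      predecessor = ifelse(is.na(m$prevCond) | m$prevCond == "NA",
                           NA_character_, as.character(m$prevCond)),
      delta_t = suppressWarnings(as.numeric(m$del.t)),
      stringsAsFactors = FALSE
    )
  }
  expression_dataset(mat, tfs, meta, source_id)
}

#' Write an expression dataset to TSV files
#'
#' @param ds An [expression_dataset()].
#' @param expression_path,tf_path,meta_path Output paths.
#' @return Invisibly, the dataset.
#' @export
write_expression_tsv <- function(ds, expression_path, tf_path,
                                 meta_path = NULL) {
  df <- data.frame(gene = ds$gene_ids, ds$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, expression_path)
  writeLines(ds$tf_ids, tf_path)
  if (!is.null(meta_path)) {
    m <- ds$condition_meta
    write_tsv(data.frame(condition = m$condition, isTs = m$is_time_series,
                         prevCond = ifelse(is.na(m$predecessor), "NA",
                                           m$predecessor),
                         del.t = m$delta_t, stringsAsFactors = FALSE),
              meta_path)
  }
  invisible(ds)
}

#' Read an orthology map from TSV
#'
#' Columns `source_a`, `gene_a`, `source_b`, `gene_b` and optionally `true`.
#'
#' @param path Input TSV.
#' @return An [orthology_map()].
#' @export
read_orthology_tsv <- function(path) {
  df <- read_tsv_checked(path, c("source_a", "gene_a", "source_b", "gene_b"),
                         "orthology")
  if (!is.null(df$true)) df$true <- as.logical(df$true)
  orthology_map(df)
}

#' Write an orthology map to TSV
#' @param orth An [orthology_map()].
#' @param path Output path.
#' @return Invisibly, the map.
#' @export
write_orthology_tsv <- function(orth, path) {
  write_tsv(as.data.frame(orth), path)
  invisible(orth)
}

#' Read operon membership from TSV (columns `gene`, `operon_id`)
#' @param path Input TSV.
#' @return Data frame with columns `gene`, `operon_id`.
#' @export
read_operons_tsv <- function(path) {
  df <- read_tsv_checked(path, c("gene", "operon_id"), "operon")
  data.frame(gene = as.character(df$gene),
             operon_id = as.character(df$operon_id),
             stringsAsFactors = FALSE)
}

#' Read a prior / gold-standard network from TSV (columns `tf`, `gene`,
#' `sign`)
#' @param path Input TSV.
#' @param source_id Source the network refers to.
#' @return A [prior_network()].
#' @export
read_prior_tsv <- function(path, source_id = "source1") {
  df <- read_tsv_checked(path, c("tf", "gene", "sign"), "prior network")
  prior_network(df, source_id)
}

#' Write a prior network to TSV
#' @param prior A [prior_network()].
#' @param path Output path.
#' @return Invisibly, the prior.
#' @export
write_prior_tsv <- function(prior, path) {
  write_tsv(as.data.frame(prior), path)
  invisible(prior)
}

#' Write fitted networks to TSV (columns `source`, `tf`, `gene`, `beta`)
#' @param networks A `network_coefficients` object.
#' @param path Output path.
#' @return Invisibly, the networks.
#' @export
write_network_tsv <- function(networks, path) {
  rows <- lapply(names(networks), function(nm) {
    b <- networks[[nm]]
    df <- data.frame(
      source = nm,
      tf = rep(rownames(b), times = ncol(b)),
      gene = rep(colnames(b), each = nrow(b)),
      beta = as.vector(b),
      stringsAsFactors = FALSE
    )
    df[df$tf != df$gene, , drop = FALSE]
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$source, df$tf, df$gene), , drop = FALSE]
  write_tsv(df, path)
  invisible(networks)
}

#' Read fitted networks from TSV
#' @param path TSV with columns `source`, `tf`, `gene`, `beta`.
#' @return A `network_coefficients` object.
#' @export
read_network_tsv <- function(path) {
  df <- read_tsv_checked(path, c("source", "tf", "gene", "beta"), "network")
  nets <- lapply(split(df, df$source), function(sub) {
    tfs <- sort(unique(sub$tf))
    genes <- sort(unique(c(sub$gene, tfs)))
    b <- matrix(0, length(tfs), length(genes),
                dimnames = list(tfs, genes))
    b[cbind(match(sub$tf, tfs), match(sub$gene, genes))] <- sub$beta
    b
  })
  structure(nets, class = "network_coefficients")
}

#' Write a simulation study to disk
#'
#' Emits, per source, expression / metadata / TF-list TSVs, plus the
#' orthology map handed to inference (with truth labels), the uncorrupted
#' orthology, the true networks, a gold standard derived from each true
#' network, and a manifest with the seed and all generator parameters.
#'
#' @param study A `simulation_study` from [generate_study()].
#' @param dir Output directory.
#' @param force Overwrite an existing non-empty directory.
#' @return Invisibly, the study.
#' @export
write_study <- function(study, dir, force = FALSE) {
  stopifnot(inherits(study, "simulation_study"))
  if (dir.exists(dir) && length(dir(dir)) > 0 && !force) {
    stop("output directory ", dir, " exists and is not empty; use force")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, paste0(...))
  for (nm in names(study$datasets)) {
    ds <- study$datasets[[nm]]
    write_expression_tsv(ds, p(nm, "_expression.tsv"), p(nm, "_tfs.txt"),
                         p(nm, "_meta.tsv"))
    write_prior_tsv(gold_from_network(study$networks[[nm]], nm),
                    p(nm, "_gold.tsv"))
  }
  write_orthology_tsv(study$orthology, p("orthology.tsv"))
  write_orthology_tsv(study$orthology_true, p("orthology_true.tsv"))
  write_network_tsv(study$networks, p("true_networks.tsv"))
  cfg <- study$config
  yaml::write_yaml(
    c(unclass(cfg), list(alpha = study$alpha,
                         sources = names(study$datasets))),
    p("manifest.yaml")
  )
  invisible(study)
}

#' Read a simulation study back from disk
#'
#' Round-trips the fixture written by [write_study()].
#'
#' @param dir Study directory.
#' @return A list with `datasets`, `networks`, `orthology`,
#'   `orthology_true`, `gold`, `alpha` and `manifest`.
#' @export
read_study <- function(dir) {
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  sources <- man$sources
  p <- function(...) file.path(dir, paste0(...))
  datasets <- lapply(sources, function(nm) {
    ds <- read_expression_tsv(p(nm, "_expression.tsv"), p(nm, "_tfs.txt"),
                              p(nm, "_meta.tsv"), nm)
    attr(ds, "alpha") <- man$alpha
    ds
  })
  names(datasets) <- sources
  gold <- lapply(sources, function(nm) read_prior_tsv(p(nm, "_gold.tsv"), nm))
  names(gold) <- sources
  list(
    datasets = datasets,
    networks = read_network_tsv(p("true_networks.tsv")),
    orthology = read_orthology_tsv(p("orthology.tsv")),
    orthology_true = read_orthology_tsv(p("orthology_true.tsv")),
    gold = gold,
    alpha = man$alpha,
    manifest = man
  )
}

#' Write workflow results and a run manifest
#'
#' Emits the averaged PR curves, per-fold summary, the unfused-constraint
#' TSV when adaptive fusion was used, and a YAML manifest of seeds, grids
#' and chosen penalties. Orderings are deterministic.
#'
#' @param result A `workflow_result` from [run_workflow()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(result, outdir) {
  stopifnot(inherits(result, "workflow_result"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    pr_fused = file.path(outdir, "pr_curve_fused.tsv"),
    pr_independent = file.path(outdir, "pr_curve_independent.tsv"),
    folds = file.path(outdir, "folds.tsv"),
    manifest = file.path(outdir, "manifest.yaml")
  )
  write_tsv(result$avg_curve_fused, paths[["pr_fused"]])
  write_tsv(result$avg_curve_independent, paths[["pr_independent"]])
  folds_df <- do.call(rbind, lapply(result$folds, function(fr) {
    data.frame(fold = fr$fold, n_rows = fr$n_rows, lambda_r = fr$lambda_r,
               lambda_s = fr$lambda_s, aupr_fused = fr$aupr_fused,
               aupr_independent = fr$aupr_independent,
               stringsAsFactors = FALSE)
  }))
  write_tsv(folds_df, paths[["folds"]])

  unfused <- do.call(rbind, lapply(result$folds, function(fr) {
    if (is.null(fr$unfused) || nrow(fr$unfused) == 0) return(NULL)
    cbind(fold = fr$fold, as.data.frame(fr$unfused))
  }))
  if (!is.null(unfused)) {
    paths <- c(paths, unfused = file.path(outdir, "unfused_constraints.tsv"))
    write_tsv(unfused, paths[["unfused"]])
  }
  yaml::write_yaml(result$manifest, paths[["manifest"]])
  invisible(paths)
}
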