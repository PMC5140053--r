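# Fusion-constraint generation from orthology / operons and decomposition of
# the joint regression problem into independently solvable components.

SEP <- "\x1f" # internal key separator, never appears in ids

resp_key <- function(source, gene) paste(source, gene, sep = SEP)
coef_key <- function(source, tf, gene) paste(source, tf, gene, sep = SEP)

#' Construct an orthology map
#'
#' A symmetric set of cross-source gene pairs. Pairs are stored canonically
#' (lexicographically ordered endpoints) and deduplicated; self pairs within a
#' single source are rejected.
#'
#' @param pairs Data frame with columns `source_a`, `gene_a`, `source_b`,
#'   `gene_b` and optionally `true` (logical truth label used by simulation
#'   studies; defaults to `TRUE`).
#' @return An object of class `orthology_map` (a canonicalized data frame).
#' @export
orthology_map <- function(pairs) {
  required <- c("source_a", "gene_a", "source_b", "gene_b")
  if (!all(required %in% names(pairs))) {
    stop("orthology pairs need columns: ", paste(required, collapse = ", "))
  }
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  for (col in required) pairs[[col]] <- as.character(pairs[[col]])
  if (is.null(pairs$true)) pairs$true <- rep(TRUE, nrow(pairs))

  if (nrow(pairs) > 0) {
    key_a <- paste(pairs$source_a, pairs$gene_a, sep = SEP)
    key_b <- paste(pairs$source_b, pairs$gene_b, sep = SEP)
    if (any(key_a == key_b)) stop("orthology self-pairs are not allowed")
    flip <- key_a > key_b
    if (any(flip)) {
      tmp_s <- pairs$source_a[flip]; tmp_g <- pairs$gene_a[flip]
      pairs$source_a[flip] <- pairs$source_b[flip]
      pairs$gene_a[flip] <- pairs$gene_b[flip]
      pairs$source_b[flip] <- tmp_s
      pairs$gene_b[flip] <- tmp_g
    }
    dup <- duplicated(paste(pairs$source_a, pairs$gene_a,
                            pairs$source_b, pairs$gene_b, sep = SEP))
    pairs <- pairs[!dup, , drop = FALSE]
    rownames(pairs) <- NULL
  }
  class(pairs) <- c("orthology_map", "data.frame")
  pairs
}

new_constraint_set <- function(df) {
  cols <- c("source_a", "tf_a", "gene_a", "source_b", "tf_b", "gene_b",
            "weight", "label")
  if (nrow(df) == 0) {
    df <- data.frame(source_a = character(), tf_a = character(),
                     gene_a = character(), source_b = character(),
                     tf_b = character(), gene_b = character(),
                     weight = numeric(), label = logical(),
                     stringsAsFactors = FALSE)
  }
  df <- df[, cols]
  if (any(df$weight < 0)) stop("constraint weights must be non-negative")
  if (nrow(df) > 0) {
    ka <- coef_key(df$source_a, df$tf_a, df$gene_a)
    kb <- coef_key(df$source_b, df$tf_b, df$gene_b)
    if (any(ka == kb)) stop("a constraint cannot fuse a coefficient to itself")
    flip <- ka > kb
    if (any(flip)) {
      tmp <- df[flip, c("source_a", "tf_a", "gene_a")]
      df[flip, c("source_a", "tf_a", "gene_a")] <-
        df[flip, c("source_b", "tf_b", "gene_b")]
      df[flip, c("source_b", "tf_b", "gene_b")] <- tmp
      ka <- coef_key(df$source_a, df$tf_a, df$gene_a)
      kb <- coef_key(df$source_b, df$tf_b, df$gene_b)
    }
    dup <- duplicated(paste(ka, kb, sep = SEP))
    df <- df[!dup, , drop = FALSE]
    df <- df[order(ka[!dup], kb[!dup]), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("constraint_set", "data.frame")
  df
}

#' Create an empty constraint set
#' @return A `constraint_set` with zero constraints.
#' @export
empty_constraints <- function() new_constraint_set(data.frame())

#' Combine constraint sets
#'
#' @param ... `constraint_set` objects (e.g. orthology- and operon-derived).
#' @return The canonical, deduplicated union.
#' @export
combine_constraints <- function(...) {
  parts <- list(...)
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (length(parts) == 0) return(empty_constraints())
  new_constraint_set(do.call(rbind, lapply(parts, as.data.frame)))
}

as_task_list <- function(tasks) {
  if (inherits(tasks, "regression_task")) tasks <- list(tasks)
  nm <- vapply(tasks, function(t) t$source_id, character(1))
  if (anyDuplicated(nm)) stop("duplicate source ids among tasks")
  stats::setNames(tasks, nm)
}

#' Generate fusion constraints from orthology
#'
#' Introduces one constraint per (TF ortholog pair) x (gene ortholog pair)
#' between each pair of sources: when regulator g in source A is orthologous
#' to regulator h in source B, and target k is orthologous to target l, the
#' interaction weights beta(g -> k) and beta(h -> l) are fused. A pair acts on
#' the regulator side only when both members are declared TFs in their tasks,
#' and on the target side whenever both members are genes. Self interactions
#' (a TF regulating its own gene) are structurally excluded and generate no
#' constraints. Many-to-many orthologs generate the full bipartite product.
#'
#' @param tasks List of `regression_task` objects (one per source).
#' @param orth An [orthology_map()]. Every id must exist in its source's task.
#' @param weight Per-constraint weight multiplier on the fusion penalty
#'   (default 1).
#' @return A `constraint_set`. Constraints inherit a `label` that is `TRUE`
#'   only when both generating ortholog pairs are labelled true.
#' @export
constraints_from_orthology <- function(tasks, orth, weight = 1) {
  tasks <- as_task_list(tasks)
  if (nrow(orth) == 0) return(empty_constraints())

  known <- names(tasks)
  bad_src <- setdiff(unique(c(orth$source_a, orth$source_b)), known)
  if (length(bad_src) > 0) {
    stop("orthology names unknown sources: ", paste(bad_src, collapse = ", "))
  }
  for (i in seq_len(nrow(orth))) {
    for (side in c("a", "b")) {
      src <- orth[[paste0("source_", side)]][i]
      g <- orth[[paste0("gene_", side)]][i]
      if (!(g %in% c(tasks[[src]]$gene_ids, tasks[[src]]$tf_ids))) {
        stop("ortholog id '", g, "' is absent from source '", src, "'")
      }
    }
  }

  out <- list()
  src_pair <- paste(orth$source_a, orth$source_b, sep = SEP)
  for (sp in unique(src_pair)) {
    sub <- orth[src_pair == sp, , drop = FALSE]
    sa <- sub$source_a[1]; sb <- sub$source_b[1]
    is_tf_pair <- sub$gene_a %in% tasks[[sa]]$tf_ids &
      sub$gene_b %in% tasks[[sb]]$tf_ids
    is_gene_pair <- sub$gene_a %in% tasks[[sa]]$gene_ids &
      sub$gene_b %in% tasks[[sb]]$gene_ids
    tf_pairs <- sub[is_tf_pair, , drop = FALSE]
    gene_pairs <- sub[is_gene_pair, , drop = FALSE]
    if (nrow(tf_pairs) == 0 || nrow(gene_pairs) == 0) next
    g <- expand.grid(ti = seq_len(nrow(tf_pairs)),
                     gi = seq_len(nrow(gene_pairs)))
    df <- data.frame(
      source_a = sa,
      tf_a = tf_pairs$gene_a[g$ti],
      gene_a = gene_pairs$gene_a[g$gi],
      source_b = sb,
      tf_b = tf_pairs$gene_b[g$ti],
      gene_b = gene_pairs$gene_b[g$gi],
      weight = weight,
      label = tf_pairs$true[g$ti] & gene_pairs$true[g$gi],
      stringsAsFactors = FALSE
    )
    # drop self-interactions on either side: those coefficients do not exist
    df <- df[df$tf_a != df$gene_a & df$tf_b != df$gene_b, , drop = FALSE]
    out[[sp]] <- df
  }
  if (length(out) == 0) return(empty_constraints())
  new_constraint_set(do.call(rbind, out))
}

#' Generate fusion constraints from operon membership
#'
#' Genes in one operon are transcribed as a unit and expected to share
#' regulators: for each TF t and each unordered pair of distinct genes (i, j)
#' in the same operon, the weights beta(t -> i) and beta(t -> j) are fused
#' within the single source. Pairs involving the TF's own gene are skipped
#' (self interactions are structurally excluded).
#'
#' @param task A `regression_task`.
#' @param operons Data frame with columns `gene` and `operon_id`; genes
#'   without an assignment generate nothing.
#' @param weight Per-constraint weight multiplier (default 1).
#' @return A `constraint_set` internal to `task`'s source.
#' @export
constraints_from_operons <- function(task, operons, weight = 1) {
  stopifnot(inherits(task, "regression_task"))
  if (!all(c("gene", "operon_id") %in% names(operons))) {
    stop("operons need columns `gene` and `operon_id`")
  }
  operons <- operons[operons$gene %in% task$gene_ids, , drop = FALSE]
  if (nrow(operons) == 0) return(empty_constraints())
  out <- list()
  for (op in unique(operons$operon_id)) {
    members <- sort(unique(operons$gene[operons$operon_id == op]))
    if (length(members) < 2) next
    pr <- utils::combn(members, 2)
    for (tf in task$tf_ids) {
      keep <- pr[1, ] != tf & pr[2, ] != tf
      if (!any(keep)) next
      out[[paste(op, tf, sep = SEP)]] <- data.frame(
        source_a = task$source_id, tf_a = tf, gene_a = pr[1, keep],
        source_b = task$source_id, tf_b = tf, gene_b = pr[2, keep],
        weight = weight, label = TRUE, stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0) return(empty_constraints())
  new_constraint_set(do.call(rbind, out))
}

#' Decompose responses into independently solvable components
#'
#' Builds the graph whose nodes are response variables (source, gene) and
#' whose edges join responses sharing any fusion constraint, and returns its
#' connected components. Responses in different components can be solved
#' separately; unconstrained responses are singleton components.
#'
#' @param cs A `constraint_set` (or `NULL` for none).
#' @param tasks List of `regression_task` objects.
#' @return A list of data frames, each with columns `source` and `gene`
#'   giving the responses of one component.
#' @export
constraint_components <- function(cs, tasks) {
  tasks <- as_task_list(tasks)
  all_resp <- do.call(rbind, lapply(tasks, function(t) {
    data.frame(source = t$source_id, gene = t$gene_ids,
               stringsAsFactors = FALSE)
  }))
  rownames(all_resp) <- NULL
  verts <- resp_key(all_resp$source, all_resp$gene)

  if (is.null(cs) || nrow(cs) == 0) {
    return(lapply(seq_len(nrow(all_resp)),
                  function(i) all_resp[i, , drop = FALSE]))
  }
  ea <- resp_key(cs$source_a, cs$gene_a)
  eb <- resp_key(cs$source_b, cs$gene_b)
  unknown <- setdiff(unique(c(ea, eb)), verts)
  if (length(unknown) > 0) {
    parts <- strsplit(unknown, SEP, fixed = TRUE)
    stop("constraints reference unknown responses: ",
         paste(vapply(parts, function(p) paste0(p[1], ":", p[2]),
                      character(1)), collapse = ", "))
  }
  g <- igraph::graph_from_data_frame(
    d = unique(data.frame(from = ea, to = eb, stringsAsFactors = FALSE)),
    directed = FALSE,
    vertices = data.frame(name = verts, stringsAsFactors = FALSE)
  )
  membership <- igraph::components(g)$membership[verts]
  idx <- split(seq_len(nrow(all_resp)), membership)
  lapply(unname(idx), function(i) all_resp[i, , drop = FALSE])
}
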