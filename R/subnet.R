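# Seed-based subnetwork extraction and candidate-regulator selection.
#
# Guilt-by-association workflow: starting from a curated bait (seed) list,
# extract either the seed-seed subgraph (no score cutoff, for recall of
# known associations) or the 1-step neighborhood (seed-incident edges at
# SIR >= 0.03, i.e. roughly the top-30 mutual-rank partners of each bait),
# then keep transcription factors connected to at least five distinct
# seeds as candidate regulators.

seed_genes_of <- function(seeds) {
  if (inherits(seeds, "seed_set")) seeds$members$gene
  else sorted_unique(as.character(seeds))
}

restrict_fused <- function(fused, keep, name) {
  e <- fused$edges[keep, , drop = FALSE]
  rownames(e) <- NULL
  fused_network(e, sources = fused$sources, name = name)
}

#' Extract the seed-seed subnetwork
#'
#' Keeps edges whose two endpoints are both seed genes; by default no
#' score cutoff is applied (bait-only extraction "without cutoffs").
#'
#' @param fused a [fused_network()].
#' @param seeds a [seed_set()] or character vector of seed genes.
#' @param cutoff optional SIR threshold (closed bound, `sir >= cutoff`);
#'   `NULL` for none.
#' @return A [fused_network()] restricted to seed-seed edges.
#' @export
extract_seed_subnetwork <- function(fused, seeds, cutoff = NULL) {
  stopifnot(inherits(fused, "fused_network"))
  sg <- seed_genes_of(seeds)
  if (length(sg) == 0) validation_error("empty seed set")
  keep <- fused$edges$gene_a %in% sg & fused$edges$gene_b %in% sg
  if (!is.null(cutoff)) keep <- keep & fused$edges$sir >= cutoff
  restrict_fused(fused, keep, paste0(fused$name, "_seed"))
}

#' Extract the 1-step seed neighborhood
#'
#' Keeps edges with at least one endpoint in the seed set and
#' `sir >= cutoff` (closed bound; the default 0.03 corresponds to a
#' reference-only edge at reciprocal rank 1/0.03 ~ 33, i.e. roughly each
#' bait's top-30 mutual-rank partners).  Seed-seed edges are retained
#' under the same rule; edges between two non-seeds are never included
#' (star-like construction, no neighbor-neighbor closure).
#'
#' @inheritParams extract_seed_subnetwork
#' @param cutoff SIR threshold, must be positive (default 0.03).
#' @return A [fused_network()]; attributes `n_bait_nodes` and
#'   `n_nonbait_nodes` report how many retained nodes are/aren't seeds.
#' @export
extract_one_step <- function(fused, seeds, cutoff = 0.03) {
  stopifnot(inherits(fused, "fused_network"))
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0) {
    validation_error("one-step extraction requires a positive SIR cutoff")
  }
  sg <- seed_genes_of(seeds)
  if (length(sg) == 0) validation_error("empty seed set")
  keep <- (fused$edges$gene_a %in% sg | fused$edges$gene_b %in% sg) &
    fused$edges$sir >= cutoff
  out <- restrict_fused(fused, keep, paste0(fused$name, "_1step"))
  nodes <- network_nodes(out)
  attr(out, "n_bait_nodes") <- sum(nodes %in% sg)
  attr(out, "n_nonbait_nodes") <- sum(!nodes %in% sg)
  out
}

#' Select candidate regulator transcription factors
#'
#' From a 1-step subnetwork, takes the non-seed nodes that are
#' transcription factors, counts each one's distinct seed partners
#' (overall and per seed category), and keeps those with at least
#' `min_seed_edges` seed partners ("fewer than five edges with seed genes"
#' excluded, by default).  Rows are sorted by seed-edge count descending,
#' ties by gene id.
#'
#' @param one_step a [fused_network()], typically from
#'   [extract_one_step()].
#' @param seeds a [seed_set()] (categories are taken from it).
#' @param tf_list character vector of transcription-factor gene ids.
#' @param min_seed_edges minimum distinct seed partners (default 5).
#' @param tf_families optional named character vector gene -> family label.
#' @return A data frame of class `candidate_table`: `gene`, `is_tf`,
#'   `n_seed_edges`, one count column per seed category, and `family`
#'   when supplied.
#' @export
select_candidate_tfs <- function(one_step, seeds, tf_list,
                                 min_seed_edges = 5, tf_families = NULL) {
  stopifnot(inherits(one_step, "fused_network"),
            inherits(seeds, "seed_set"))
  tf_list <- sorted_unique(as.character(tf_list))
  if (length(tf_list) == 0) validation_error("empty transcription-factor list")
  sg <- seeds$members$gene
  cat_of <- stats::setNames(seeds$members$category, sg)
  cats <- intersect(seeds$vocabulary, unique(seeds$members$category))

  e <- one_step$edges
  long <- data.frame(gene = c(e$gene_a, e$gene_b),
                     partner = c(e$gene_b, e$gene_a),
                     stringsAsFactors = FALSE)
  long <- long[long$gene %in% tf_list & !(long$gene %in% sg) &
                 long$partner %in% sg, , drop = FALSE]
  long <- unique(long)   # distinct seed partners

  genes <- sorted_unique(long$gene)
  counts <- matrix(0L, nrow = length(genes), ncol = length(cats),
                   dimnames = list(genes, cats))
  if (nrow(long) > 0) {
    tab <- table(factor(long$gene, levels = genes),
                 factor(cat_of[long$partner], levels = cats))
    counts[] <- as.integer(tab)
  }
  n_seed <- rowSums(counts)
  keep <- n_seed >= min_seed_edges
  genes <- genes[keep]
  counts <- counts[keep, , drop = FALSE]
  n_seed <- n_seed[keep]
  ord <- order(-n_seed, genes, method = "radix")
  out <- data.frame(gene = genes[ord], is_tf = TRUE,
                    n_seed_edges = as.integer(n_seed[ord]),
                    stringsAsFactors = FALSE)
  for (cl in cats) out[[cl]] <- as.integer(counts[ord, cl])
  if (!is.null(tf_families)) {
    out$family <- unname(tf_families[out$gene])
  }
  rownames(out) <- NULL
  class(out) <- c("candidate_table", "data.frame")
  out
}

#' Seed-category degree matrix with z-scoring and clustering
#'
#' Counts each row gene's distinct seed partners per seed category, then
#' z-scores (population SD; a constant column maps to all zeros) and
#' orders rows by agglomerative hierarchical clustering (Euclidean
#' distance, complete linkage) of the z-scored profiles, with
#' deterministic tie-breaking by gene id.
#'
#' @param net a [fused_network()] (or any network object).
#' @param rows character vector of row genes (e.g. candidate TFs).
#' @param seeds a [seed_set()].
#' @param zscore `"column"` (per category, the default) or `"row"`.
#' @param n_groups number of groups to cut the dendrogram into
#'   (default 3, capped at the number of rows).
#' @return Object of class `degree_matrix`: `counts`, `z`, `row_order`,
#'   `groups` (named group index per gene), and `hclust` (when >= 3 rows).
#' @export
category_degree_matrix <- function(net, rows, seeds,
                                   zscore = c("column", "row"),
                                   n_groups = 3) {
  zscore <- match.arg(zscore)
  stopifnot(inherits(seeds, "seed_set"))
  rows <- sorted_unique(as.character(rows))
  if (length(rows) == 0) validation_error("empty row gene set")
  sg <- seeds$members$gene
  cat_of <- stats::setNames(seeds$members$category, sg)
  cats <- intersect(seeds$vocabulary, unique(seeds$members$category))

  ef <- edge_frame(net)
  long <- data.frame(gene = c(ef$gene_a, ef$gene_b),
                     partner = c(ef$gene_b, ef$gene_a),
                     stringsAsFactors = FALSE)
  long <- long[long$gene %in% rows & long$partner %in% sg, , drop = FALSE]
  long <- unique(long)
  counts <- matrix(0L, nrow = length(rows), ncol = length(cats),
                   dimnames = list(rows, cats))
  if (nrow(long) > 0) {
    tab <- table(factor(long$gene, levels = rows),
                 factor(cat_of[long$partner], levels = cats))
    counts[] <- as.integer(tab)
  }

  pop_z <- function(x) {
    mu <- mean(x)
    sd_pop <- sqrt(mean((x - mu)^2))
    if (sd_pop == 0) rep(0, length(x)) else (x - mu) / sd_pop
  }
  z <- if (zscore == "column") apply(counts, 2, pop_z)
       else t(apply(counts, 1, pop_z))
  if (is.null(dim(z))) {                      # single row collapses to vector
    z <- matrix(z, nrow = nrow(counts), dimnames = dimnames(counts))
  }

  hc <- NULL
  if (nrow(z) >= 3) {
    hc <- stats::hclust(stats::dist(z, method = "euclidean"),
                        method = "complete")
    row_order <- rownames(z)[hc$order]
    groups <- stats::cutree(hc, k = min(n_groups, nrow(z)))
  } else {
    row_order <- rownames(z)
    groups <- stats::setNames(seq_len(nrow(z)), rownames(z))
  }
  structure(list(counts = counts, z = z, row_order = row_order,
                 groups = groups, hclust = hc),
            class = "degree_matrix")
}

#' @export
print.degree_matrix <- function(x, ...) {
  cat(sprintf("<degree_matrix> %d genes x %d categories\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}
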