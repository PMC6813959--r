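# S3 containers for the network types the toolkit passes between modules.

#' Built-in score systems
#'
#' The three scoring dialects found in published gene networks, plus a
#' `generic` escape hatch: `pcc` (Pearson-correlation style, higher is
#' better, declared range 0.5--1), `hrr` (highest-reciprocal-rank style,
#' lower is better, 0--200), `lls` (log-likelihood style, higher is better,
#' 1--5).
#'
#' @format A named list; each entry has `polarity` and `range`.
#' @export
score_systems <- list(
  pcc     = list(polarity = "higher_better", range = c(0.5, 1)),
  hrr     = list(polarity = "lower_better",  range = c(0, 200)),
  lls     = list(polarity = "higher_better", range = c(1, 5)),
  generic = list(polarity = NULL,            range = NULL)
)

#' Controlled vocabulary for seed-gene categories
#'
#' Default category labels for cell-wall seed (bait) genes: biosynthetic
#' families plus known and ortholog-inferred transcription factors.
#'
#' @export
seed_categories <- c(
  "lignin", "sw_cesa", "pw_cesa", "mlg", "hydroxycinnamate_at",
  "xylan", "tf_known", "tf_ortholog"
)

#' Construct a scored network
#'
#' An undirected weighted edge list with a declared score system.  Pairs are
#' canonicalized (`gene_a < gene_b`), self-loops and duplicate pairs are
#' rejected, and scores are checked against the declared range.
#'
#' @param edges data frame with columns `gene_a`, `gene_b`, `score`.
#' @param name label for the network.
#' @param score_system one of `names(score_systems)`.
#' @param polarity `"higher_better"` or `"lower_better"`; required for
#'   `score_system = "generic"`, otherwise defaulted from the system.
#' @param declared_range numeric length-2 `(min, max)` or `NULL` (unbounded).
#' @return An object of class `scored_network`.
#' @export
scored_network <- function(edges, name = "network", score_system = "generic",
                           polarity = NULL, declared_range = NULL) {
  score_system <- match.arg(score_system, names(score_systems))
  sys <- score_systems[[score_system]]
  polarity <- polarity %||% sys$polarity
  if (is.null(polarity)) {
    validation_error("score system '%s' requires an explicit polarity", score_system)
  }
  polarity <- match.arg(polarity, c("higher_better", "lower_better"))
  if (is.null(declared_range)) declared_range <- sys$range

  stopifnot(is.data.frame(edges),
            all(c("gene_a", "gene_b", "score") %in% names(edges)))
  edges <- data.frame(gene_a = as.character(edges$gene_a),
                      gene_b = as.character(edges$gene_b),
                      score  = as.numeric(edges$score),
                      stringsAsFactors = FALSE)
  if (nrow(edges) > 0) {
    cp <- canonical_pairs(edges$gene_a, edges$gene_b)
    edges$gene_a <- cp$gene_a
    edges$gene_b <- cp$gene_b
    if (any(edges$gene_a == edges$gene_b)) {
      validation_error("self-loop edge(s) present, e.g. %s",
                       edges$gene_a[edges$gene_a == edges$gene_b][1])
    }
    keys <- edge_key(edges$gene_a, edges$gene_b)
    if (anyDuplicated(keys)) {
      validation_error("duplicate gene pair(s), e.g. %s-%s",
                       edges$gene_a[duplicated(keys)][1],
                       edges$gene_b[duplicated(keys)][1])
    }
    if (anyNA(edges$score)) validation_error("missing score(s) in edge list")
    if (!is.null(declared_range)) {
      bad <- edges$score < declared_range[1] | edges$score > declared_range[2]
      if (any(bad)) {
        off <- utils::head(sprintf("%s-%s=%g", edges$gene_a[bad],
                                   edges$gene_b[bad], edges$score[bad]), 5)
        validation_error(
          "%d score(s) outside declared range [%g, %g]: %s%s",
          sum(bad), declared_range[1], declared_range[2],
          paste(off, collapse = ", "),
          if (sum(bad) > 5) ", ..." else "")
      }
    }
    edges <- edges[order(edges$gene_a, edges$gene_b, method = "radix"), ,
                   drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(name = name, score_system = score_system,
                 polarity = polarity, declared_range = declared_range,
                 edges = edges),
            class = "scored_network")
}

# Ranked form: each edge carries directed neighbor ranks, the mutual rank
# mr = sqrt(rank_ab * rank_ba) and inv_mr = 1/mr in (0, 1].
#' Construct a ranked network
#'
#' Edges annotated with per-endpoint neighbor ranks, mutual rank
#' `mr = sqrt(rank_ab * rank_ba)` and its inverse `inv_mr = 1/mr`.
#' Usually produced by [compute_mutual_rank()].
#'
#' @param edges data frame with columns `gene_a`, `gene_b`, `rank_ab`,
#'   `rank_ba`, `mr`, `inv_mr`.
#' @param name source label.
#' @return An object of class `ranked_network`.
#' @export
ranked_network <- function(edges, name = "ranked") {
  stopifnot(is.data.frame(edges),
            all(c("gene_a", "gene_b", "rank_ab", "rank_ba", "mr", "inv_mr")
                %in% names(edges)))
  if (nrow(edges) > 0) {
    if (any(edges$rank_ab < 1) || any(edges$rank_ba < 1)) {
      validation_error("neighbor ranks must be >= 1")
    }
    if (max(abs(edges$mr - sqrt(edges$rank_ab * edges$rank_ba))) > 1e-9) {
      validation_error("mr inconsistent with sqrt(rank_ab * rank_ba)")
    }
    if (any(edges$inv_mr <= 0) || any(edges$inv_mr > 1 + 1e-12)) {
      validation_error("inv_mr must lie in (0, 1]")
    }
    edges <- edges[order(edges$gene_a, edges$gene_b, method = "radix"), ,
                   drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(name = name, edges = edges), class = "ranked_network")
}

#' Construct a fused network
#'
#' Edges scored by the summed inverse rank (SIR) with per-source provenance.
#' Usually produced by [apply_fusion()].
#'
#' @param edges data frame with columns `gene_a`, `gene_b`, `sir`, and one
#'   `inv_mr_<source>` column per source (`NA` where the source lacks the
#'   edge).
#' @param sources named numeric vector of source weights, reference first
#'   with weight 1.
#' @param name network label.
#' @return An object of class `fused_network`.
#' @export
fused_network <- function(edges, sources, name = "fused") {
  stopifnot(is.data.frame(edges), is.numeric(sources),
            !is.null(names(sources)))
  src_cols <- paste0("inv_mr_", names(sources))
  stopifnot(all(c("gene_a", "gene_b", "sir") %in% names(edges)),
            all(src_cols %in% names(edges)))
  if (nrow(edges) > 0) {
    present <- rowSums(!is.na(as.matrix(edges[src_cols]))) > 0
    if (!all(present)) validation_error("edge(s) with no supporting source")
    if (any(edges$sir <= 0)) validation_error("sir must be positive")
    edges <- edges[order(edges$gene_a, edges$gene_b, method = "radix"),
                   c("gene_a", "gene_b", "sir", src_cols), drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(name = name, sources = sources, edges = edges),
            class = "fused_network")
}

#' Construct a GO annotation set
#'
#' @param gene_to_terms named list mapping gene id to a character vector of
#'   GO biological-process term ids (`GO:` followed by 7 digits).
#' @param universe optional character vector of all genes, used to derive
#'   the annotated fraction.
#' @return An object of class `go_annotation`.
#' @export
go_annotation <- function(gene_to_terms, universe = NULL) {
  stopifnot(is.list(gene_to_terms), !is.null(names(gene_to_terms)))
  if (length(gene_to_terms) == 0) validation_error("empty annotation set")
  terms <- unique(unlist(gene_to_terms, use.names = FALSE))
  bad <- terms[!grepl("^GO:[0-9]{7}$", terms)]
  if (length(bad) > 0) {
    parse_error("malformed GO term id(s): %s",
                paste(utils::head(bad, 5), collapse = ", "))
  }
  gene_to_terms <- lapply(gene_to_terms, sorted_unique)
  gene_to_terms <- gene_to_terms[sort(names(gene_to_terms),
                                      method = "radix")]
  annotated_fraction <- if (!is.null(universe)) {
    length(intersect(names(gene_to_terms), unique(universe))) /
      length(unique(universe))
  } else NA_real_
  structure(list(gene_to_terms = gene_to_terms,
                 annotated_fraction = annotated_fraction),
            class = "go_annotation")
}

#' Construct a seed (bait) gene set
#'
#' @param gene character vector of seed genes (unique).
#' @param category category label per gene, drawn from `vocabulary`.
#' @param vocabulary allowed category labels; defaults to [seed_categories].
#' @return An object of class `seed_set`.
#' @export
seed_set <- function(gene, category, vocabulary = seed_categories) {
  gene <- as.character(gene)
  category <- as.character(category)
  stopifnot(length(gene) == length(category))
  if (length(gene) == 0) validation_error("seed set must be non-empty")
  if (anyDuplicated(gene)) {
    validation_error("duplicate seed gene(s): %s",
                     paste(unique(gene[duplicated(gene)]), collapse = ", "))
  }
  unknown <- setdiff(unique(category), vocabulary)
  if (length(unknown) > 0) {
    validation_error("unknown seed categor%s %s; allowed: %s",
                     if (length(unknown) > 1) "ies" else "y",
                     paste(unknown, collapse = ", "),
                     paste(vocabulary, collapse = ", "))
  }
  members <- data.frame(gene = gene, category = category,
                        stringsAsFactors = FALSE)
  members <- members[order(members$gene, method = "radix"), , drop = FALSE]
  rownames(members) <- NULL
  structure(list(members = members, vocabulary = vocabulary),
            class = "seed_set")
}

#' Construct a many-to-many ortholog map
#'
#' @param group_id group label per row.
#' @param species species label per row (exactly two distinct labels over
#'   the whole table).
#' @param gene gene id per row; a gene may appear in at most one group per
#'   species.
#' @return An object of class `ortholog_map` with one row per
#'   (group, species, gene).
#' @export
ortholog_map <- function(group_id, species, gene) {
  df <- data.frame(group_id = as.character(group_id),
                   species = as.character(species),
                   gene = as.character(gene), stringsAsFactors = FALSE)
  if (nrow(df) == 0) validation_error("empty ortholog map")
  sp <- sorted_unique(df$species)
  if (length(sp) != 2) {
    validation_error("ortholog map must cover exactly 2 species, found: %s",
                     paste(sp, collapse = ", "))
  }
  for (s in sp) {
    g <- df$gene[df$species == s]
    if (anyDuplicated(g)) {
      validation_error("gene(s) in more than one row for species %s: %s", s,
                       paste(utils::head(unique(g[duplicated(g)]), 5),
                             collapse = ", "))
    }
  }
  by_grp <- split(df, df$group_id)
  incomplete <- names(by_grp)[vapply(by_grp, function(d)
    length(unique(d$species)) < 2, logical(1))]
  if (length(incomplete) > 0) {
    validation_error("group(s) with an empty species side: %s",
                     paste(incomplete, collapse = ", "))
  }
  df <- df[order(df$group_id, df$species, df$gene, method = "radix"), ,
           drop = FALSE]
  rownames(df) <- NULL
  structure(list(groups = df, species = sp), class = "ortholog_map")
}

#' Nodes of a network
#'
#' @param net a `scored_network`, `ranked_network` or `fused_network`.
#' @return Sorted character vector of gene ids touched by at least one edge.
#' @export
network_nodes <- function(net) {
  e <- net$edges
  sorted_unique(c(e$gene_a, e$gene_b))
}

#' Number of edges in a network
#'
#' @param net a network object.
#' @return Integer edge count.
#' @export
n_edges <- function(net) nrow(net$edges)

# Uniform (gene_a, gene_b, score) view used by evaluation/extraction code.
# Fused networks expose sir; ranked networks inv_mr; scored networks their
# raw score (higher-is-better only -- mutual-rank a lower-is-better network
# first).
edge_frame <- function(net) {
  if (inherits(net, "fused_network")) {
    data.frame(gene_a = net$edges$gene_a, gene_b = net$edges$gene_b,
               score = net$edges$sir, stringsAsFactors = FALSE)
  } else if (inherits(net, "ranked_network")) {
    data.frame(gene_a = net$edges$gene_a, gene_b = net$edges$gene_b,
               score = net$edges$inv_mr, stringsAsFactors = FALSE)
  } else if (inherits(net, "scored_network")) {
    if (net$polarity != "higher_better") {
      evaluation_error(paste0(
        "network '%s' scores are lower-is-better; convert with ",
        "compute_mutual_rank() before score-threshold analyses"), net$name)
    }
    data.frame(gene_a = net$edges$gene_a, gene_b = net$edges$gene_b,
               score = net$edges$score, stringsAsFactors = FALSE)
  } else {
    validation_error("not a network object: %s",
                     paste(class(net), collapse = "/"))
  }
}

#' @export
print.scored_network <- function(x, ...) {
  cat(sprintf("<scored_network '%s'> %d edges, %d nodes; system=%s (%s)%s\n",
              x$name, nrow(x$edges), length(network_nodes(x)),
              x$score_system, x$polarity,
              if (!is.null(x$declared_range))
                sprintf(", range [%g, %g]", x$declared_range[1],
                        x$declared_range[2]) else ""))
  invisible(x)
}

#' @export
print.ranked_network <- function(x, ...) {
  cat(sprintf("<ranked_network '%s'> %d edges, %d nodes; inv_mr in [%g, %g]\n",
              x$name, nrow(x$edges), length(network_nodes(x)),
              if (nrow(x$edges)) min(x$edges$inv_mr) else NA,
              if (nrow(x$edges)) max(x$edges$inv_mr) else NA))
  invisible(x)
}

#' @export
print.fused_network <- function(x, ...) {
  w <- paste(sprintf("%s=%g", names(x$sources), x$sources), collapse = ", ")
  cat(sprintf("<fused_network '%s'> %d edges, %d nodes; sources: %s\n",
              x$name, nrow(x$edges), length(network_nodes(x)), w))
  invisible(x)
}

#' @export
print.go_annotation <- function(x, ...) {
  cat(sprintf("<go_annotation> %d genes, %d terms%s\n",
              length(x$gene_to_terms),
              length(unique(unlist(x$gene_to_terms, use.names = FALSE))),
              if (!is.na(x$annotated_fraction))
                sprintf(", annotated fraction %.2f", x$annotated_fraction)
              else ""))
  invisible(x)
}

#' @export
print.seed_set <- function(x, ...) {
  cat(sprintf("<seed_set> %d genes in %d categories\n",
              nrow(x$members), length(unique(x$members$category))))
  invisible(x)
}

#' @export
print.ortholog_map <- function(x, ...) {
  cat(sprintf("<ortholog_map> %d groups across %s\n",
              length(unique(x$groups$group_id)),
              paste(x$species, collapse = " / ")))
  invisible(x)
}
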