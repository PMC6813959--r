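# GO-BP based network quality evaluation.
#
# An edge is "matched" when its two genes share at least one retained
# biological-process term.  The most general (most frequent) terms are
# excluded first to avoid rewarding ubiquitous annotations; only edges
# whose genes both keep at least one term are evaluable.  Confusion counts
# over a grid of score cutoffs yield ROC and precision-recall curves, and
# a degree-free random network over the same gene universe provides the
# null control.

#' Label network edges by GO-BP term matching
#'
#' Removes the `n_exclude` most frequent terms (by number of annotated
#' genes, ties broken by term id), then labels every edge whose two genes
#' both retain at least one term: matched if they share a retained term,
#' unmatched otherwise.  Edges with an unannotated endpoint are dropped
#' from evaluation (they can be neither matched nor unmatched).
#'
#' @param net a network object ([fused_network()], [ranked_network()] or a
#'   higher-is-better [scored_network()]).
#' @param annotations a [go_annotation()].
#' @param n_exclude number of most-frequent terms to exclude (default 10).
#' @return A data frame of class `labeled_edges` with columns `gene_a`,
#'   `gene_b`, `score`, `matched`, and attributes `excluded_terms` (data
#'   frame of term/count), `n_input_edges`, `n_dropped_edges`.
#' @export
build_match_labels <- function(net, annotations, n_exclude = 10) {
  stopifnot(inherits(annotations, "go_annotation"), n_exclude >= 0)
  ef <- edge_frame(net)
  g2t <- annotations$gene_to_terms

  term_count <- sort(table(unlist(lapply(g2t, unique), use.names = FALSE)),
                     decreasing = TRUE)
  # deterministic order: frequency desc, then term id
  ord <- order(-as.integer(term_count), names(term_count), method = "radix")
  term_count <- term_count[ord]
  excluded <- utils::head(names(term_count), n_exclude)
  if (length(excluded) > 0) {
    g2t <- lapply(g2t, function(tt) setdiff(tt, excluded))
    g2t <- g2t[lengths(g2t) > 0]
  }
  ta <- g2t[ef$gene_a]
  tb <- g2t[ef$gene_b]
  evaluable <- lengths(ta) > 0 & lengths(tb) > 0
  if (!any(evaluable)) {
    evaluation_error("no evaluable edges: no edge has both genes annotated")
  }
  matched <- mapply(function(x, y) length(intersect(x, y)) > 0,
                    ta[evaluable], tb[evaluable], USE.NAMES = FALSE)
  out <- data.frame(gene_a = ef$gene_a[evaluable],
                    gene_b = ef$gene_b[evaluable],
                    score = ef$score[evaluable],
                    matched = as.logical(matched),
                    stringsAsFactors = FALSE)
  attr(out, "excluded_terms") <- data.frame(
    term = excluded,
    n_genes = as.integer(term_count[excluded]),
    stringsAsFactors = FALSE)
  attr(out, "n_input_edges") <- nrow(ef)
  attr(out, "n_dropped_edges") <- sum(!evaluable)
  class(out) <- c("labeled_edges", "data.frame")
  out
}

#' Confusion counts at a score cutoff
#'
#' With a closed lower bound (score >= cutoff counts as a prediction):
#' TP = matched edges at or above the cutoff, FP = unmatched at or above,
#' TN = unmatched below, FN = matched below.  `n_predictions = TP + FP`
#' and `total_true = TP + FN` (constant across cutoffs).
#'
#' @param labeled a `labeled_edges` frame from [build_match_labels()].
#' @param cutoff score threshold.
#' @return An object of class `confusion_counts`.
#' @export
confusion_at_cutoff <- function(labeled, cutoff) {
  stopifnot(inherits(labeled, "labeled_edges"), nrow(labeled) > 0)
  pred <- labeled$score >= cutoff
  tp <- sum(labeled$matched & pred)
  fp <- sum(!labeled$matched & pred)
  tn <- sum(!labeled$matched & !pred)
  fn <- sum(labeled$matched & !pred)
  structure(list(cutoff = cutoff, tp = tp, fp = fp, tn = tn, fn = fn,
                 n_predictions = tp + fp, total_true = tp + fn),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf(
    "<confusion_counts> cutoff=%g: TP=%d FP=%d TN=%d FN=%d (N=%d, total true=%d)\n",
    x$cutoff, x$tp, x$fp, x$tn, x$fn, x$n_predictions, x$total_true))
  invisible(x)
}

cutoff_grid <- function(scores, n_cutoffs, grid = c("quantile", "value")) {
  grid <- match.arg(grid)
  if (grid == "quantile") {
    # interior evenly spaced quantiles: inverse-rank scores are heavily
    # right-skewed and value-spaced grids collapse the curve
    probs <- seq_len(n_cutoffs) / (n_cutoffs + 1)
    unname(stats::quantile(scores, probs = probs, type = 7, names = FALSE))
  } else {
    seq(min(scores), max(scores), length.out = n_cutoffs)
  }
}

#' ROC curve and AUC over a cutoff grid
#'
#' Sweeps `n_cutoffs` score cutoffs (evenly spaced quantiles of the
#' evaluable-edge score distribution by default, or evenly spaced raw
#' values), computes (FPR, TPR) at each, anchors the curve at (0,0) and
#' (1,1), and integrates by the trapezoid rule.
#'
#' @param labeled a `labeled_edges` frame.
#' @param n_cutoffs number of cutoffs (default 40).
#' @param grid `"quantile"` or `"value"` spacing.
#' @return An object of class `roc_result`: `points` (fpr/tpr data frame),
#'   `auc`, `cutoffs`.
#' @export
roc_auc <- function(labeled, n_cutoffs = 40, grid = c("quantile", "value")) {
  stopifnot(inherits(labeled, "labeled_edges"), n_cutoffs >= 1)
  total_true <- sum(labeled$matched)
  total_false <- sum(!labeled$matched)
  if (total_true == 0 || total_false == 0) {
    evaluation_error(
      "ROC undefined: need >= 1 matched and >= 1 unmatched edge (have %d/%d)",
      total_true, total_false)
  }
  cutoffs <- cutoff_grid(labeled$score, n_cutoffs, grid)
  pts <- t(vapply(cutoffs, function(th) {
    cc <- confusion_at_cutoff(labeled, th)
    c(fpr = cc$fp / total_false, tpr = cc$tp / total_true)
  }, numeric(2)))
  pts <- rbind(c(0, 0), pts, c(1, 1))
  pts <- pts[order(pts[, 1], pts[, 2]), , drop = FALSE]
  auc <- sum(diff(pts[, 1]) * (utils::head(pts[, 2], -1) +
                                 utils::tail(pts[, 2], -1)) / 2)
  structure(list(points = data.frame(fpr = pts[, 1], tpr = pts[, 2]),
                 auc = auc, cutoffs = cutoffs),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f over %d cutoffs\n", x$auc,
              length(x$cutoffs)))
  invisible(x)
}

#' Precision-recall curve over a cutoff grid
#'
#' At each cutoff, `precision = TP / N` (where `N = TP + FP` is the number
#' of predictions; cutoffs with `N = 0` are skipped) and
#' `recall = TP / total_true`.
#'
#' @inheritParams roc_auc
#' @return An object of class `pr_result` with a `points` data frame
#'   (`cutoff`, `recall`, `precision`) and `total_true`.
#' @export
precision_recall <- function(labeled, n_cutoffs = 40,
                             grid = c("quantile", "value")) {
  stopifnot(inherits(labeled, "labeled_edges"), n_cutoffs >= 1)
  total_true <- sum(labeled$matched)
  if (total_true < 1) {
    evaluation_error("precision-recall undefined: no matched edges")
  }
  cutoffs <- cutoff_grid(labeled$score, n_cutoffs, grid)
  rows <- lapply(cutoffs, function(th) {
    cc <- confusion_at_cutoff(labeled, th)
    if (cc$n_predictions == 0) return(NULL)
    data.frame(cutoff = th, recall = cc$tp / total_true,
               precision = cc$tp / cc$n_predictions)
  })
  pts <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(pts) <- NULL
  structure(list(points = pts, total_true = total_true),
            class = "pr_result")
}

#' @export
print.pr_result <- function(x, ...) {
  cat(sprintf("<pr_result> %d points, total true = %d\n", nrow(x$points),
              x$total_true))
  invisible(x)
}

#' Random-network control
#'
#' Uniformly samples `n_edges` distinct unordered gene pairs (no self
#' loops, no replacement) from the universe and assigns each a uniform
#' (0, 1] score.  Used as the label-independent null against which a
#' network's GO-based AUC is compared.
#'
#' @param node_universe character vector of genes to wire between.
#' @param n_edges number of edges to draw.
#' @param seed optional integer; the caller's RNG state is untouched.
#' @return A higher-is-better [scored_network()].
#' @export
make_random_network <- function(node_universe, n_edges, seed = NULL) {
  genes <- sorted_unique(as.character(node_universe))
  n <- length(genes)
  if (n < 2 && n_edges > 0) validation_error("universe too small")
  max_pairs <- n * (n - 1) / 2
  if (n_edges > max_pairs) {
    validation_error("n_edges = %d exceeds the %d possible pairs",
                     n_edges, max_pairs)
  }
  if (n_edges == 0) {
    return(scored_network(
      data.frame(gene_a = character(), gene_b = character(),
                 score = numeric()),
      name = "random", score_system = "generic",
      polarity = "higher_better", declared_range = c(0, 1)))
  }
  with_seed(seed, {
    idx <- sample.int(max_pairs, n_edges)
    # unrank pair index t (1-based, ordered by gene_a then gene_b)
    starts <- cumsum(c(0, (n - 1):1))
    a <- findInterval(idx - 1, starts)
    b <- a + (idx - starts[a])
    scores <- stats::runif(n_edges)
    scored_network(
      data.frame(gene_a = genes[a], gene_b = genes[b], score = scores,
                 stringsAsFactors = FALSE),
      name = "random", score_system = "generic",
      polarity = "higher_better", declared_range = c(0, 1))
  })
}

#' Full GO-based evaluation of a network
#'
#' Labels edges, computes ROC/AUC and precision-recall, and (optionally) a
#' random-network control with the same node universe, edge count and
#' annotations.
#'
#' @inheritParams build_match_labels
#' @inheritParams roc_auc
#' @param random_control evaluate a matched random network as well?
#' @param seed seed for the random control.
#' @return List with `labels`, `roc`, `pr`, `excluded_terms`, and (when
#'   requested) `random` (itself holding `roc` and `pr`).
#' @export
evaluate_network <- function(net, annotations, n_exclude = 10,
                             n_cutoffs = 40, grid = c("quantile", "value"),
                             random_control = FALSE, seed = NULL) {
  grid <- match.arg(grid)
  labeled <- build_match_labels(net, annotations, n_exclude = n_exclude)
  out <- list(labels = labeled,
              roc = roc_auc(labeled, n_cutoffs, grid),
              pr = precision_recall(labeled, n_cutoffs, grid),
              excluded_terms = attr(labeled, "excluded_terms"))
  if (random_control) {
    rnd <- make_random_network(network_nodes(net), n_edges(net), seed = seed)
    rnd_lab <- build_match_labels(rnd, annotations, n_exclude = n_exclude)
    out$random <- list(roc = roc_auc(rnd_lab, n_cutoffs, grid),
                       pr = precision_recall(rnd_lab, n_cutoffs, grid))
  }
  out
}
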