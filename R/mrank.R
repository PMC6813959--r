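# Inverse mutual-rank rescaling.
#
# Every source network, whatever its native score dialect, is re-expressed
# on a common scale: for an edge A-B, rank(A,B) is B's position in A's
# neighbor list (best = 1 under the network's polarity), the mutual rank is
# the geometric mean MR = sqrt(rank(A,B) * rank(B,A)), and the edge score
# becomes 1/MR in (0, 1].  Ranks are computed among listed neighbors only:
# the edge list IS the network, as published deposits are thresholded edge
# lists, not dense similarity matrices.

# Long view of an undirected edge list: one row per directed incidence.
directed_incidences <- function(net) {
  e <- net$edges
  data.frame(gene = c(e$gene_a, e$gene_b),
             neighbor = c(e$gene_b, e$gene_a),
             score = c(e$score, e$score),
             stringsAsFactors = FALSE)
}

#' Rank each gene's neighbors by score
#'
#' For every gene, its listed neighbors are ranked by score with best = 1
#' under the network's polarity (`higher_better`: descending score,
#' `lower_better`: ascending).  Ties receive the average (fractional) rank,
#' so the ranks of a gene with k neighbors always sum to k(k+1)/2.
#'
#' @param net a [scored_network()].
#' @return Named list: gene -> named numeric vector of neighbor ranks.
#' @examples
#' net <- scored_network(
#'   data.frame(gene_a = "A", gene_b = c("B", "C", "D"),
#'              score = c(0.9, 0.8, 0.7)),
#'   score_system = "generic", polarity = "higher_better")
#' rank_neighbors(net)$A  # B=1, C=2, D=3
#' @export
rank_neighbors <- function(net) {
  stopifnot(inherits(net, "scored_network"))
  if (nrow(net$edges) == 0) validation_error("cannot rank an empty network")
  long <- directed_incidences(net)
  key <- if (net$polarity == "higher_better") -long$score else long$score
  r <- stats::ave(key, long$gene,
                  FUN = function(v) rank(v, ties.method = "average"))
  out <- split(stats::setNames(r, long$neighbor), long$gene)
  out[sorted_unique(long$gene)]
}

#' Convert a scored network to the inverse mutual-rank scale
#'
#' Annotates every edge with its two directed neighbor ranks, the mutual
#' rank `mr = sqrt(rank_ab * rank_ba)` and `inv_mr = 1/mr`.  The edge set
#' is unchanged; only the scale is.  Because the computation is rank-based
#' it is invariant to any strictly monotone transform of the scores.
#'
#' @param net a [scored_network()].
#' @return A [ranked_network()].
#' @examples
#' net <- scored_network(
#'   data.frame(gene_a = c("A", "A", "B"), gene_b = c("B", "C", "C"),
#'              score = c(0.9, 0.8, 0.95)),
#'   score_system = "generic", polarity = "higher_better")
#' compute_mutual_rank(net)$edges
#' @export
compute_mutual_rank <- function(net) {
  stopifnot(inherits(net, "scored_network"))
  if (nrow(net$edges) == 0) validation_error("cannot rank an empty network")
  long <- directed_incidences(net)
  key <- if (net$polarity == "higher_better") -long$score else long$score
  r <- stats::ave(key, long$gene,
                  FUN = function(v) rank(v, ties.method = "average"))
  m <- nrow(net$edges)
  rank_ab <- r[seq_len(m)]          # rank of gene_b among gene_a's neighbors
  rank_ba <- r[m + seq_len(m)]      # rank of gene_a among gene_b's neighbors
  mr <- sqrt(rank_ab * rank_ba)
  ranked_network(
    data.frame(gene_a = net$edges$gene_a, gene_b = net$edges$gene_b,
               rank_ab = rank_ab, rank_ba = rank_ba, mr = mr,
               inv_mr = 1 / mr, stringsAsFactors = FALSE),
    name = net$name)
}
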