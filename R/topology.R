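# Degree-distribution statistics: power-law fit and genome coverage.
#
# Biological association networks are typically scale-free: the degree
# distribution follows P(k) ~ k^gamma.  Fit quality is summarized by the
# R^2 of an ordinary least-squares regression of log10 P(k) on log10 k
# over the observed (nonzero) degree bins; maximum-likelihood power-law
# estimation is deliberately out of scope.

#' Empirical degree distribution
#'
#' `P(k)` = (number of nodes of degree k) / (number of nodes).  Nodes are
#' defined by edge membership, so only `k >= 1` occurs and the
#' probabilities sum to 1.
#'
#' @param net a network object.
#' @return Data frame with columns `k` (integer degree) and `p`.
#' @export
degree_distribution <- function(net) {
  ef <- if (inherits(net, "data.frame")) net else net$edges
  if (nrow(ef) == 0) validation_error("empty network has no degrees")
  deg <- table(c(ef$gene_a, ef$gene_b))
  tab <- table(as.integer(deg))
  data.frame(k = as.integer(names(tab)),
             p = as.numeric(tab) / length(deg))
}

#' Fit a power law to a degree distribution
#'
#' Ordinary least squares of `log10 P(k)` on `log10 k` over bins with
#' nonzero probability; the slope is the exponent `gamma` and the fit
#' quality is the regression's R^2.  At least 3 distinct degree values are
#' required.
#'
#' @param distribution a `k`/`p` data frame from [degree_distribution()],
#'   or a network object (converted internally).
#' @return Object of class `power_law_fit`: `gamma`, `r_squared`,
#'   `n_bins`, and the fitted `log10 k` / `log10 P(k)` pairs.
#' @export
fit_power_law <- function(distribution) {
  if (!is.data.frame(distribution)) {
    distribution <- degree_distribution(distribution)
  }
  d <- distribution[distribution$p > 0, , drop = FALSE]
  if (nrow(d) < 3) {
    topology_error(
      "power-law fit needs >= 3 distinct degree values, have %d", nrow(d))
  }
  lk <- log10(d$k)
  lp <- log10(d$p)
  fit <- stats::lm(lp ~ lk)
  # R^2 computed directly; summary.lm() warns on an exactly linear histogram
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((lp - mean(lp))^2)
  r2 <- min(max(r2, 0), 1)
  structure(list(gamma = unname(stats::coef(fit)[2]),
                 r_squared = r2,
                 n_bins = nrow(d),
                 points = data.frame(log10_k = lk, log10_p = lp)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> gamma = %.4f, R^2 = %.4f over %d degree bins\n",
              x$gamma, x$r_squared, x$n_bins))
  invisible(x)
}

#' Genome coverage of a network
#'
#' Fraction of the gene universe touched by at least one edge.
#'
#' @param net a network object.
#' @param gene_universe character vector of genes (e.g. all annotated
#'   genes of the genome).
#' @return A fraction in \[0, 1\].
#' @export
genome_coverage <- function(net, gene_universe) {
  uni <- unique(as.character(gene_universe))
  if (length(uni) == 0) validation_error("empty gene universe")
  length(intersect(network_nodes(net), uni)) / length(uni)
}

#' Topology summary of a network
#'
#' Convenience wrapper bundling [degree_distribution()],
#' [fit_power_law()] and, when a universe is given, [genome_coverage()].
#'
#' @param net a network object.
#' @param gene_universe optional gene universe.
#' @return List with `distribution`, `fit`, `n_nodes`, `n_edges`, and
#'   `coverage` (`NA` without a universe).
#' @export
network_topology <- function(net, gene_universe = NULL) {
  dist <- degree_distribution(net)
  list(distribution = dist,
       fit = fit_power_law(dist),
       n_nodes = length(network_nodes(net)),
       n_edges = n_edges(net),
       coverage = if (is.null(gene_universe)) NA_real_
                  else genome_coverage(net, gene_universe))
}
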