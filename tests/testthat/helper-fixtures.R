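# Shared fixture builders; everything is generated in code.

make_net <- function(a, b, s, polarity = "higher_better", name = "toy",
                     range = NULL) {
  scored_network(data.frame(gene_a = a, gene_b = b, score = s,
                            stringsAsFactors = FALSE),
                 name = name, score_system = "generic",
                 polarity = polarity, declared_range = range)
}

# Random simple graph on n nodes with roughly edge_prob density; scores
# uniform, optionally duplicated to force ties.
random_scored_net <- function(n_nodes, edge_prob = 0.15, seed = 1,
                              polarity = "higher_better",
                              tie_fraction = 0) {
  set.seed(seed)
  genes <- sprintf("N%03d", seq_len(n_nodes))
  prs <- t(combn(genes, 2))
  keep <- runif(nrow(prs)) < edge_prob
  prs <- prs[keep, , drop = FALSE]
  if (nrow(prs) < 2) {
    prs <- t(combn(genes, 2))[1:3, , drop = FALSE]
  }
  s <- runif(nrow(prs))
  if (tie_fraction > 0) {
    # reuse a small score pool so ties are guaranteed
    pool <- round(runif(max(2, ceiling(nrow(prs) * (1 - tie_fraction)))), 2)
    s <- sample(pool, nrow(prs), replace = TRUE)
  }
  make_net(prs[, 1], prs[, 2], s, polarity = polarity,
           name = paste0("rand", seed))
}

# Brute-force mutual-rank oracle: explicit per-node neighbor sort with
# average ranks for ties, independent of the package implementation.
brute_force_mutual_rank <- function(net) {
  e <- net$edges
  adj <- list()
  for (i in seq_len(nrow(e))) {
    adj[[e$gene_a[i]]] <- rbind(adj[[e$gene_a[i]]],
                                data.frame(nb = e$gene_b[i], s = e$score[i]))
    adj[[e$gene_b[i]]] <- rbind(adj[[e$gene_b[i]]],
                                data.frame(nb = e$gene_a[i], s = e$score[i]))
  }
  rank_of <- function(g, nb) {
    d <- adj[[g]]
    key <- if (net$polarity == "higher_better") -d$s else d$s
    r <- rank(key, ties.method = "average")
    r[match(nb, d$nb)]
  }
  data.frame(
    gene_a = e$gene_a, gene_b = e$gene_b,
    rank_ab = mapply(rank_of, e$gene_a, e$gene_b),
    rank_ba = mapply(rank_of, e$gene_b, e$gene_a),
    stringsAsFactors = FALSE)
}

# Minimal fused network over explicit sir values from a single source.
make_fused <- function(a, b, sir, source_name = "ref") {
  e <- data.frame(gene_a = a, gene_b = b, sir = sir,
                  stringsAsFactors = FALSE)
  e[[paste0("inv_mr_", source_name)]] <- sir
  fused_network(e, sources = setNames(1, source_name), name = "toyfused")
}

# Annotation builder from gene = terms pairs.
make_annotation <- function(...) {
  go_annotation(list(...))
}

# Full enumeration oracle written from first principles: probability of a
# 2x2 table with fixed margins via binomial coefficients, two-sided p as
# the mass of all tables no more probable than the observed one.
enumerate_fisher_p <- function(k1, n1, k2, n2) {
  m <- k1 + k2
  support <- max(0, m - n2):min(n1, m)
  prob <- choose(n1, support) * choose(n2, m - support) /
    choose(n1 + n2, m)
  sum(prob[prob <= prob[support == k1] * (1 + 1e-7)])
}

default_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- synthetic_study()
    cache
  }
})
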