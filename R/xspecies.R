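# Cross-species connectivity comparison.
#
# For each ortholog group, the network partners of all co-orthologs in a
# species are pooled by set union, and the two species' partner counts
# (against configurable totals) are compared with a two-sided Fisher exact
# test.  Raw p-values are flagged at 0.05 and 0.01, as is conventional for
# per-group connectivity comparisons; Benjamini-Hochberg adjusted values
# are emitted alongside for users who want them.

#' Pooled partner set of an ortholog group
#'
#' Union over the group's genes of their network neighbors, optionally
#' restricted to a partner pool (e.g. the cell-wall seed genes), with the
#' group's own genes excluded (an edge to one's own co-ortholog is not an
#' external interaction).
#'
#' @param net a network object.
#' @param group_genes non-empty character vector (the group's genes in
#'   this species).
#' @param partner_pool optional character vector restricting which
#'   partners count.
#' @return Sorted character vector of partners.
#' @export
union_partner_set <- function(net, group_genes, partner_pool = NULL) {
  group_genes <- unique(as.character(group_genes))
  if (length(group_genes) == 0) validation_error("empty ortholog group")
  ef <- if (inherits(net, "data.frame")) net else net$edges
  hit_a <- ef$gene_a %in% group_genes
  hit_b <- ef$gene_b %in% group_genes
  partners <- c(ef$gene_b[hit_a], ef$gene_a[hit_b])
  if (!is.null(partner_pool)) {
    partners <- partners[partners %in% partner_pool]
  }
  sorted_unique(setdiff(partners, group_genes))
}

#' Two-sided Fisher exact test for connectivity
#'
#' Exact two-sided p-value for the 2x2 table
#' `[[k1, N1-k1], [k2, N2-k2]]`, computed by full hypergeometric
#' enumeration: with margins fixed, every table whose probability does not
#' exceed the observed table's contributes to p (the conventional
#' `1 + 1e-7` relative slack guards against floating-point ties).
#'
#' @param k1,n1 partner count and total for species 1 (`0 <= k1 <= n1`).
#' @param k2,n2 partner count and total for species 2.
#' @return Two-sided p-value in (0, 1].
#' @examples
#' fisher_connectivity(3, 4, 1, 4)   # 34/70
#' @export
fisher_connectivity <- function(k1, n1, k2, n2) {
  vals <- c(k1 = k1, n1 = n1, k2 = k2, n2 = n2)
  if (any(!is.finite(vals)) || any(vals != round(vals))) {
    validation_error("fisher_connectivity requires integer counts")
  }
  if (n1 < 1 || n2 < 1 || k1 < 0 || k2 < 0 || k1 > n1 || k2 > n2) {
    validation_error("invalid 2x2 table: k1=%g n1=%g k2=%g n2=%g",
                     k1, n1, k2, n2)
  }
  m <- k1 + k2                       # first-column margin
  support <- max(0, m - n2):min(n1, m)
  probs <- stats::dhyper(support, n1, n2, m)
  p_obs <- stats::dhyper(k1, n1, n2, m)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(p, 1)
}

#' Compare ortholog-group connectivity between two species
#'
#' For every group in the map: pools each species' co-ortholog partners by
#' [union_partner_set()] (optionally restricted to per-species partner
#' pools), forms the 2x2 table against each species' total, and tests with
#' [fisher_connectivity()].  A group absent from both networks yields
#' `k = 0` on both sides and `p = 1`.
#'
#' @param net_a,net_b network objects for species A and B (the order of
#'   `map$species`, i.e. alphabetical species label).
#' @param map an [ortholog_map()].
#' @param pool_a,pool_b optional partner pools per species.
#' @param total_a,total_b comparison denominators; default: number of
#'   genes in each species' network (`total_mode = "network"`).  With
#'   `total_mode = "pool"` the pool sizes are used instead.
#' @param total_mode `"network"` or `"pool"`.
#' @return A data frame of class `degree_comparison`, one row per group:
#'   partner counts, totals, proportions, `fisher_p`, `p_bh`
#'   (Benjamini-Hochberg), `flag_05`, `flag_01`; sorted by `group_id`.
#' @export
compare_orthogroups <- function(net_a, net_b, map,
                                pool_a = NULL, pool_b = NULL,
                                total_a = NULL, total_b = NULL,
                                total_mode = c("network", "pool")) {
  stopifnot(inherits(map, "ortholog_map"))
  total_mode <- match.arg(total_mode)
  if (inherits(pool_a, "seed_set")) pool_a <- pool_a$members$gene
  if (inherits(pool_b, "seed_set")) pool_b <- pool_b$members$gene
  if (total_mode == "pool") {
    if (is.null(pool_a) || is.null(pool_b)) {
      config_error("total_mode = 'pool' requires both partner pools")
    }
    total_a <- total_a %||% length(unique(pool_a))
    total_b <- total_b %||% length(unique(pool_b))
  } else {
    total_a <- total_a %||% length(network_nodes(net_a))
    total_b <- total_b %||% length(network_nodes(net_b))
  }
  sp <- map$species
  by_grp <- split(map$groups, map$groups$group_id)
  rows <- lapply(names(by_grp), function(gid) {
    d <- by_grp[[gid]]
    genes_a <- d$gene[d$species == sp[1]]
    genes_b <- d$gene[d$species == sp[2]]
    k1 <- length(union_partner_set(net_a, genes_a, pool_a))
    k2 <- length(union_partner_set(net_b, genes_b, pool_b))
    if (k1 > total_a || k2 > total_b) {
      validation_error(
        "group %s: partner count exceeds the configured total", gid)
    }
    p <- fisher_connectivity(k1, total_a, k2, total_b)
    data.frame(group_id = gid,
               partners_a = k1, total_a = total_a,
               partners_b = k2, total_b = total_b,
               proportion_a = k1 / total_a, proportion_b = k2 / total_b,
               fisher_p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$group_id, method = "radix"), , drop = FALSE]
  out$p_bh <- stats::p.adjust(out$fisher_p, method = "BH")
  out$flag_05 <- out$fisher_p < 0.05
  out$flag_01 <- out$fisher_p < 0.01
  rownames(out) <- NULL
  class(out) <- c("degree_comparison", "data.frame")
  out
}
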