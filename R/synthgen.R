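# Deterministic synthetic-data generator.
#
# Produces the statistical structure the fusion and evaluation methods
# assume, at desk scale and with no downloads: a scale-free
# (preferential-attachment) backbone, planted functional modules (cliques)
# whose members share a GO-BP term, regulator nodes wired into the seed
# module, three source networks in the three score dialects with partial
# edge overlap and decoy edges, exactly-linear (or noisy) calibration
# fixtures, and a mirror species for cross-species comparison.  Every
# generator is fully deterministic under its seed.

#' Specification for a synthetic study
#'
#' Defaults describe a realistic desk-scale benchmark: 1,000 genes, a
#' preferential-attachment backbone with m = 2, six 10-gene functional
#' modules, three regulators wired to 8 members of the seed module, 70%
#' per-source edge retention, a 30% decoy-edge rate, and planted
#' calibration weights 0.33 / 0.025.
#'
#' @param n_genes number of genes.
#' @param n_modules number of planted functional modules.
#' @param module_size genes per module (>= 3).
#' @param attachment_m edges added per node in the preferential-attachment
#'   backbone.
#' @param overlap named per-source edge-retention probabilities in (0, 1]
#'   (`pcc`, `hrr`, `lls`).
#' @param decoy_rate false (decoy) edges added per source, as a fraction of
#'   its retained true edges.
#' @param noise_sd Gaussian noise SD for calibration fixtures.
#' @param coefficients planted linear calibration weights.
#' @param n_regulators planted regulator nodes wired into the seed module.
#' @param regulator_degree seed-module members each regulator connects to.
#' @param n_decoy_tfs non-regulator genes listed as TFs (should never be
#'   selected as candidates).
#' @param n_background_terms size of the generic GO-BP term pool.
#' @param annotated_fraction fraction of background genes given GO terms.
#' @param seed master seed; equal specs yield identical outputs.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 1000, n_modules = 6, module_size = 10,
                           attachment_m = 2,
                           overlap = c(pcc = 0.7, hrr = 0.7, lls = 0.7),
                           decoy_rate = 0.3, noise_sd = 0.01,
                           coefficients = c(coexpr_pcc = 0.33,
                                            coexpr_hrr = 0.025),
                           n_regulators = 3, regulator_degree = 8,
                           n_decoy_tfs = 5, n_background_terms = 30,
                           annotated_fraction = 0.4, seed = 42) {
  if (any(overlap <= 0) || any(overlap > 1)) {
    validation_error("overlap probabilities must lie in (0, 1]")
  }
  if (n_modules > 0 && module_size < 3) {
    validation_error("module_size must be >= 3")
  }
  if (n_modules * module_size + n_regulators > n_genes) {
    validation_error("modules and regulators do not fit in %d genes", n_genes)
  }
  if (annotated_fraction < 0 || annotated_fraction > 1) {
    validation_error("annotated_fraction must lie in [0, 1]")
  }
  structure(list(n_genes = n_genes, n_modules = n_modules,
                 module_size = module_size, attachment_m = attachment_m,
                 overlap = overlap, decoy_rate = decoy_rate,
                 noise_sd = noise_sd, coefficients = coefficients,
                 n_regulators = n_regulators,
                 regulator_degree = regulator_degree,
                 n_decoy_tfs = n_decoy_tfs,
                 n_background_terms = n_background_terms,
                 annotated_fraction = annotated_fraction, seed = seed),
            class = "synthetic_spec")
}

dedupe_edges <- function(a, b, functional) {
  cp <- canonical_pairs(a, b)
  a <- cp$gene_a; b <- cp$gene_b
  keep <- a != b
  a <- a[keep]; b <- b[keep]; functional <- functional[keep]
  key <- edge_key(a, b)
  # a functional flag wins over a backbone duplicate of the same pair
  ord <- order(key, !functional, method = "radix")
  a <- a[ord]; b <- b[ord]; functional <- functional[ord]; key <- key[ord]
  first <- !duplicated(key)
  data.frame(gene_a = a[first], gene_b = b[first],
             functional = functional[first], stringsAsFactors = FALSE)
}

#' Generate the latent truth graph
#'
#' A preferential-attachment backbone on `n_genes` nodes (so the graph is
#' scale-free), plus a clique over each planted module, plus
#' `n_regulators` regulator nodes each wired to `regulator_degree` members
#' of the first module (the future seed module).  Module, clique and
#' regulator edges are marked `functional`.
#'
#' @param spec a [synthetic_spec()].
#' @return Object of class `synthetic_truth`: `edges` (with a `functional`
#'   flag), `modules` (list of gene vectors), `regulators`, `genes`, and
#'   the `spec`.
#' @export
generate_truth_graph <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$n_modules > 0 && spec$module_size > spec$n_genes) {
    validation_error("module_size exceeds n_genes")
  }
  with_seed(spec$seed, {
    genes <- sprintf("G%05d", seq_len(spec$n_genes))
    g <- igraph::sample_pa(spec$n_genes, m = spec$attachment_m,
                           directed = FALSE)
    el <- igraph::as_edgelist(g, names = FALSE)
    a <- genes[el[, 1]]; b <- genes[el[, 2]]
    functional <- rep(FALSE, length(a))

    n_planted <- spec$n_modules * spec$module_size
    modules <- list()
    regulators <- character(0)
    if (spec$n_modules > 0) {
      pick <- sample(spec$n_genes, n_planted + spec$n_regulators)
      modules <- lapply(seq_len(spec$n_modules), function(i) {
        sort(genes[pick[((i - 1) * spec$module_size + 1):
                          (i * spec$module_size)]])
      })
      regulators <- sort(genes[utils::tail(pick, spec$n_regulators)])
      for (mod in modules) {
        prs <- utils::combn(mod, 2)
        a <- c(a, prs[1, ]); b <- c(b, prs[2, ])
        functional <- c(functional, rep(TRUE, ncol(prs)))
      }
      seed_mod <- modules[[1]]
      for (r in regulators) {
        tgt <- sample(seed_mod, min(spec$regulator_degree,
                                    length(seed_mod)))
        a <- c(a, rep(r, length(tgt))); b <- c(b, tgt)
        functional <- c(functional, rep(TRUE, length(tgt)))
      }
    }
    structure(list(edges = dedupe_edges(a, b, functional),
                   modules = modules, regulators = regulators,
                   genes = genes, spec = spec),
              class = "synthetic_truth")
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "<synthetic_truth> %d genes, %d edges (%d functional), %d modules, %d regulators\n",
    length(x$genes), nrow(x$edges), sum(x$edges$functional),
    length(x$modules), length(x$regulators)))
  invisible(x)
}

sample_decoys <- function(genes, n_decoys, existing_keys) {
  a <- character(0); b <- character(0)
  guard <- 0
  while (length(a) < n_decoys && guard < 50) {
    need <- (n_decoys - length(a)) * 2 + 10
    ca <- sample(genes, need, replace = TRUE)
    cb <- sample(genes, need, replace = TRUE)
    cp <- canonical_pairs(ca, cb)
    ok <- cp$gene_a != cp$gene_b &
      !(edge_key(cp$gene_a, cp$gene_b) %in% existing_keys) &
      !duplicated(edge_key(cp$gene_a, cp$gene_b))
    a <- c(a, cp$gene_a[ok]); b <- c(b, cp$gene_b[ok])
    dup <- duplicated(edge_key(a, b))
    a <- a[!dup]; b <- b[!dup]
    guard <- guard + 1
  }
  list(gene_a = utils::head(a, n_decoys), gene_b = utils::head(b, n_decoys))
}

#' Generate the three source networks from a truth graph
#'
#' Each source retains each truth edge independently with its `overlap`
#' probability and adds `decoy_rate` false edges; scores follow the
#' source's dialect (PCC-like in \[0.5, 1\] higher-better; HRR-like
#' integers in \[0, 200\] lower-better; LLS-like in \[1, 5\]
#' higher-better), with functional (module/regulator) edges receiving
#' stochastically better scores than backbone edges, and decoys worse
#' still.
#'
#' @param truth a `synthetic_truth` from [generate_truth_graph()].
#' @param spec the [synthetic_spec()] (defaults to the one inside `truth`).
#' @return Named list of three [scored_network()] objects:
#'   `coexpr_pcc`, `coexpr_hrr`, `funcnet_lls`.
#' @export
generate_score_networks <- function(truth, spec = truth$spec) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (nrow(truth$edges) == 0) validation_error("empty truth graph")
  with_seed(spec$seed + 1L, {
    te <- truth$edges
    truth_keys <- edge_key(te$gene_a, te$gene_b)
    score_edges <- function(n_func, n_bg, n_decoy, dialect) {
      switch(dialect,
        pcc = c(stats::runif(n_func, 0.85, 1),
                stats::runif(n_bg, 0.5, 0.9),
                stats::runif(n_decoy, 0.5, 0.75)),
        hrr = c(sample(0:30, n_func, replace = TRUE),
                sample(20:150, n_bg, replace = TRUE),
                sample(100:200, n_decoy, replace = TRUE)),
        lls = c(stats::runif(n_func, 3.5, 5),
                stats::runif(n_bg, 1, 3.8),
                stats::runif(n_decoy, 1, 2.5)))
    }
    make_source <- function(dialect, system_code, name) {
      keep <- stats::runif(nrow(te)) <= spec$overlap[[dialect]]
      kept <- te[keep, , drop = FALSE]
      ord <- order(!kept$functional)   # functional first, for scoring
      kept <- kept[ord, , drop = FALSE]
      n_func <- sum(kept$functional); n_bg <- sum(!kept$functional)
      n_decoy <- round(spec$decoy_rate * nrow(kept))
      dec <- sample_decoys(truth$genes, n_decoy, truth_keys)
      scores <- score_edges(n_func, n_bg, length(dec$gene_a), dialect)
      scored_network(
        data.frame(gene_a = c(kept$gene_a, dec$gene_a),
                   gene_b = c(kept$gene_b, dec$gene_b),
                   score = scores, stringsAsFactors = FALSE),
        name = name, score_system = system_code)
    }
    list(coexpr_pcc = make_source("pcc", "pcc", "coexpr_pcc"),
         coexpr_hrr = make_source("hrr", "hrr", "coexpr_hrr"),
         funcnet_lls = make_source("lls", "lls", "funcnet_lls"))
  })
}

# Wrap an inverse-mutual-rank vector as a degenerate ranked network whose
# edges are disjoint reciprocal pairs (rank_ab = rank_ba = 1/inv_mr, hence
# mr = sqrt(rank_ab * rank_ba) = 1/inv_mr exactly).
vector_as_ranked <- function(values, name) {
  n <- length(values)
  ranked_network(
    data.frame(gene_a = sprintf("GA%06d", seq_len(n)),
               gene_b = sprintf("GB%06d", seq_len(n)),
               rank_ab = 1 / values, rank_ba = 1 / values,
               mr = 1 / values, inv_mr = values,
               stringsAsFactors = FALSE),
    name = name)
}

#' Generate a calibration-truth fixture
#'
#' Draws predictor inverse-mutual-rank vectors uniformly on (0, 1] over a
#' shared set of common edges and sets the reference to the planted linear
#' combination, plus optional Gaussian noise.  Noise draws that would push
#' a reference value off the (0, 1] inverse-rank scale are redrawn
#' (truncated noise).  The result feeds [fit_calibration()] directly.
#'
#' @param n_edges number of common edges (>= 10).
#' @param coefficients planted weights, named per auxiliary (weights must
#'   sum to at most 1 so the reference stays on the inverse-rank scale).
#' @param noise_sd Gaussian noise SD (0 for an exactly linear fixture).
#' @param seed integer seed.
#' @return List: `reference` (a [ranked_network()]), `auxiliaries` (named
#'   list of [ranked_network()]), `coefficients` (the planted weights).
#' @export
generate_calibration_truth <- function(n_edges,
                                       coefficients = c(coexpr_pcc = 0.33,
                                                        coexpr_hrr = 0.025),
                                       noise_sd = 0, seed = 1) {
  if (n_edges < 10) validation_error("n_edges must be >= 10")
  if (sum(abs(coefficients)) > 1) {
    validation_error("planted coefficients must sum to at most 1")
  }
  k <- length(coefficients)
  nm <- names(coefficients) %||% paste0("aux", seq_len(k))
  nm[!nzchar(nm)] <- paste0("aux", which(!nzchar(nm)))
  with_seed(seed, {
    X <- matrix(stats::runif(n_edges * k), nrow = n_edges)
    y <- drop(X %*% coefficients)
    if (noise_sd > 0) {
      y <- y + stats::rnorm(n_edges, 0, noise_sd)
      bad <- which(y <= 0 | y > 1)
      guard <- 0
      while (length(bad) > 0 && guard < 1000) {
        y[bad] <- drop(X[bad, , drop = FALSE] %*% coefficients) +
          stats::rnorm(length(bad), 0, noise_sd)
        bad <- which(y <= 0 | y > 1)
        guard <- guard + 1
      }
      if (length(bad) > 0) y[bad] <- .Machine$double.eps
    }
    list(reference = vector_as_ranked(y, "reference"),
         auxiliaries = stats::setNames(
           lapply(seq_len(k), function(j)
             vector_as_ranked(X[, j], nm[j])), nm),
         coefficients = stats::setNames(as.numeric(coefficients), nm))
  })
}

#' Generate annotations, seeds, TF list and ortholog map
#'
#' Each planted module gets a distinct GO-BP term shared by its members
#' (plus one generic background term each); background genes are annotated
#' with generic terms at `annotated_fraction`.  The first module becomes
#' the seed set (categories cycled over biosynthetic labels), its planted
#' regulators become the true TF candidates, and `n_decoy_tfs` weakly
#' connected genes are added to the TF list as decoys.  A mirror second
#' species (prefix `B_`) yields a one-to-one ortholog map over the TFs.
#'
#' @param truth a `synthetic_truth` with at least one module.
#' @param spec the [synthetic_spec()] (defaults to the one inside `truth`).
#' @return List: `annotations` ([go_annotation()]), `seeds` ([seed_set()]),
#'   `tf_list` (character), `decoy_tfs` (character, subset of `tf_list`),
#'   `ortholog_map` ([ortholog_map()]).
#' @export
generate_annotations_and_seeds <- function(truth, spec = truth$spec) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (length(truth$modules) == 0) {
    validation_error("annotations need at least one planted module")
  }
  with_seed(spec$seed + 2L, {
    module_terms <- sprintf("GO:%07d", 1100000 + seq_along(truth$modules))
    bg_terms <- sprintf("GO:%07d", 2000000 + seq_len(spec$n_background_terms))
    ann <- list()
    module_genes <- unlist(truth$modules, use.names = FALSE)
    for (i in seq_along(truth$modules)) {
      for (g in truth$modules[[i]]) {
        ann[[g]] <- c(module_terms[i], sample(bg_terms, 1))
      }
    }
    for (r in truth$regulators) {
      ann[[r]] <- c(module_terms[1], sample(bg_terms, 1))
    }
    others <- setdiff(truth$genes, c(module_genes, truth$regulators))
    hit <- others[stats::runif(length(others)) <= spec$annotated_fraction]
    for (g in hit) {
      ann[[g]] <- sample(bg_terms, sample(1:2, 1))
    }

    seed_mod <- truth$modules[[1]]
    cats <- rep_len(c("lignin", "sw_cesa", "xylan", "mlg", "pw_cesa"),
                    length(seed_mod))
    seeds <- seed_set(seed_mod, cats)

    # decoy TFs: weakly module-connected genes that must never be selected
    te <- truth$edges
    into_seed <- c(te$gene_a[te$gene_b %in% seed_mod],
                   te$gene_b[te$gene_a %in% seed_mod])
    seed_deg <- table(into_seed)
    pool <- setdiff(others, names(seed_deg)[seed_deg > 1])
    decoys <- sort(sample(pool, min(spec$n_decoy_tfs, length(pool))))
    tf_list <- sort(c(truth$regulators, decoys))

    omap <- ortholog_map(
      group_id = rep(sprintf("OG%03d", seq_along(tf_list)), each = 2),
      species = rep(c("sp_a", "sp_b"), length(tf_list)),
      gene = as.vector(rbind(tf_list, paste0("B_", tf_list))))
    list(annotations = go_annotation(ann, universe = truth$genes),
         seeds = seeds, tf_list = tf_list, decoy_tfs = decoys,
         ortholog_map = omap)
  })
}

#' Mirror a fused network into a second species
#'
#' Renames every gene with a prefix (preserving canonical pair order) and
#' optionally thins the edges incident to chosen genes, emulating a
#' species in which those regulators lost most of their connectivity.
#'
#' @param fused a [fused_network()].
#' @param prefix gene-id prefix for the mirror species (default `"B_"`).
#' @param thin_genes original gene ids whose incident edges are
#'   down-sampled.
#' @param keep_fraction probability of keeping each such edge.
#' @param seed seed for the thinning draw.
#' @return A [fused_network()] in the mirror species' namespace.
#' @export
mirror_fused_network <- function(fused, prefix = "B_", thin_genes = NULL,
                                 keep_fraction = 0.1, seed = NULL) {
  stopifnot(inherits(fused, "fused_network"))
  e <- fused$edges
  keep <- rep(TRUE, nrow(e))
  if (!is.null(thin_genes) && nrow(e) > 0) {
    hit <- e$gene_a %in% thin_genes | e$gene_b %in% thin_genes
    keep[hit] <- with_seed(seed, stats::runif(sum(hit)) <= keep_fraction)
  }
  e <- e[keep, , drop = FALSE]
  e$gene_a <- paste0(prefix, e$gene_a)
  e$gene_b <- paste0(prefix, e$gene_b)
  rownames(e) <- NULL
  fused_network(e, sources = fused$sources,
                name = paste0(prefix, fused$name))
}

#' Run the full synthetic study
#'
#' Generates the truth graph, the three source networks, annotations and
#' seeds; mutual-ranks every source; calibrates the two co-expression
#' sources against the LLS-style reference; and fuses.  This is the
#' default end-to-end fixture for benchmarking the pipeline.
#'
#' @param spec a [synthetic_spec()].
#' @param fit_mode calibration fit mode (default `"pairwise"`).
#' @return List: `truth`, `sources`, `ranked`, `model`, `fused`,
#'   `annotations`, `seeds`, `tf_list`, `decoy_tfs`, `ortholog_map`.
#' @export
synthetic_study <- function(spec = synthetic_spec(),
                            fit_mode = c("pairwise", "joint")) {
  fit_mode <- match.arg(fit_mode)
  truth <- generate_truth_graph(spec)
  sources <- generate_score_networks(truth, spec)
  side <- generate_annotations_and_seeds(truth, spec)
  ranked <- lapply(sources, compute_mutual_rank)
  fused <- fuse_networks(ranked$funcnet_lls,
                         ranked[c("coexpr_pcc", "coexpr_hrr")],
                         fit_mode = fit_mode, name = "combined")
  c(list(truth = truth, sources = sources, ranked = ranked,
         model = fused$model, fused = fused$network), side)
}
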