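# Calibration and fusion.
#
# Auxiliary networks are mapped onto the reference network's inverse
# mutual-rank scale with a no-intercept Gaussian GLM (identity link) fitted
# on edges the networks share, and the fused edge score is the summed
# inverse rank (SIR): the reference inverse MR (weight 1) plus each
# auxiliary's coefficient-weighted inverse MR, summed over whatever sources
# actually contain the edge.  Throughout, predictors and response are on
# the 1/MR scale, not raw MR -- consistent with the summed-inverse-rank
# score and the 0.03 extraction cutoff (1/0.03 ~ rank 33).

ranked_keyed <- function(rn) {
  stats::setNames(rn$edges$inv_mr, edge_key(rn$edges$gene_a, rn$edges$gene_b))
}

check_aux_list <- function(auxiliaries) {
  if (inherits(auxiliaries, "ranked_network")) {
    auxiliaries <- list(auxiliaries)
  }
  stopifnot(is.list(auxiliaries), length(auxiliaries) > 0,
            all(vapply(auxiliaries, inherits, logical(1), "ranked_network")))
  nm <- names(auxiliaries) %||%
    vapply(auxiliaries, function(x) x$name, character(1))
  nm[!nzchar(nm)] <- vapply(auxiliaries[!nzchar(nm)], function(x) x$name,
                            character(1))
  if (anyDuplicated(nm)) {
    config_error("auxiliary network names must be unique: %s",
                 paste(nm, collapse = ", "))
  }
  stats::setNames(auxiliaries, nm)
}

#' Fit the calibration model for auxiliary networks
#'
#' Regresses the reference network's inverse mutual rank on each auxiliary
#' network's inverse mutual rank over their common edges, using a
#' no-intercept Gaussian GLM with identity link.  `fit_mode = "pairwise"`
#' (default) fits each auxiliary separately on its own common-edge set with
#' the reference; `"joint"` fits all auxiliaries simultaneously on the
#' edges common to every network.  A negative fitted coefficient is
#' retained but flagged with a warning.
#'
#' @param reference a [ranked_network()] providing the target scale.
#' @param auxiliaries a named list of [ranked_network()] objects (names
#'   default to each network's own name).
#' @param fit_mode `"pairwise"` or `"joint"`.
#' @return An object of class `calibration_model` with fields
#'   `reference_name`, `coefficients` (named, one per auxiliary),
#'   `fit_mode`, `n_common_edges`, `residual_sse`.
#' @export
fit_calibration <- function(reference, auxiliaries,
                            fit_mode = c("pairwise", "joint")) {
  stopifnot(inherits(reference, "ranked_network"))
  fit_mode <- match.arg(fit_mode)
  auxiliaries <- check_aux_list(auxiliaries)
  ref_map <- ranked_keyed(reference)
  aux_maps <- lapply(auxiliaries, ranked_keyed)

  coefs <- numeric(0)
  n_common <- integer(0)
  sse <- 0
  if (fit_mode == "pairwise") {
    for (nm in names(aux_maps)) {
      common <- intersect(names(ref_map), names(aux_maps[[nm]]))
      if (length(common) < 2) {
        calibration_error(
          "source '%s' shares only %d edge(s) with the reference; >= 2 required",
          nm, length(common))
      }
      d <- data.frame(y = unname(ref_map[common]),
                      x = unname(aux_maps[[nm]][common]))
      fit <- stats::glm(y ~ x - 1, data = d,
                        family = stats::gaussian(link = "identity"))
      coefs[nm] <- unname(stats::coef(fit))
      n_common[nm] <- length(common)
      sse <- sse + sum(stats::residuals(fit)^2)
    }
  } else {
    common <- names(ref_map)
    for (m in aux_maps) common <- intersect(common, names(m))
    if (length(common) < 2) {
      calibration_error(
        "only %d edge(s) common to all networks; >= 2 required for a joint fit",
        length(common))
    }
    d <- data.frame(y = unname(ref_map[common]))
    for (nm in names(aux_maps)) d[[nm]] <- unname(aux_maps[[nm]][common])
    fml <- stats::reformulate(sprintf("`%s`", names(aux_maps)),
                              response = "y", intercept = FALSE)
    fit <- stats::glm(fml, data = d,
                      family = stats::gaussian(link = "identity"))
    coefs <- stats::setNames(unname(stats::coef(fit)), names(aux_maps))
    n_common <- stats::setNames(rep(length(common), length(aux_maps)),
                                names(aux_maps))
    sse <- sum(stats::residuals(fit)^2)
  }
  if (anyNA(coefs) || any(!is.finite(coefs))) {
    calibration_error("non-finite calibration coefficient(s) for: %s",
                      paste(names(coefs)[!is.finite(coefs)], collapse = ", "))
  }
  neg <- names(coefs)[coefs < 0]
  if (length(neg) > 0) {
    warning(sprintf("negative calibration coefficient retained for: %s",
                    paste(neg, collapse = ", ")), call. = FALSE)
  }
  structure(list(reference_name = reference$name, coefficients = coefs,
                 fit_mode = fit_mode, n_common_edges = n_common,
                 residual_sse = sse),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> reference '%s' (weight 1), fit_mode=%s\n",
              x$reference_name, x$fit_mode))
  for (nm in names(x$coefficients)) {
    cat(sprintf("  %s: coefficient %.6g on %d common edges\n", nm,
                x$coefficients[[nm]], x$n_common_edges[[nm]]))
  }
  cat(sprintf("  residual SSE %.6g\n", x$residual_sse))
  invisible(x)
}

#' Fuse calibrated networks into a combined ranked network
#'
#' The fused edge universe is the union of all source edge sets.  Each
#' edge's summed inverse rank is
#' `sir = inv_mr_ref + sum_i beta_i * inv_mr_i`, where each term is
#' included only when that source contains the edge (an absent source
#' contributes zero, not an imputed rank).  Per-source inverse mutual
#' ranks are retained as provenance.
#'
#' @param reference the reference [ranked_network()] (implicit weight 1).
#' @param auxiliaries named list of auxiliary [ranked_network()] objects.
#' @param model a `calibration_model` from [fit_calibration()] covering
#'   every auxiliary by name.
#' @param name label for the fused network.
#' @return A [fused_network()].
#' @export
apply_fusion <- function(reference, auxiliaries, model, name = "fused") {
  stopifnot(inherits(reference, "ranked_network"),
            inherits(model, "calibration_model"))
  auxiliaries <- if (length(auxiliaries) == 0) list()
                 else check_aux_list(auxiliaries)
  if (!setequal(names(auxiliaries), names(model$coefficients))) {
    config_error("model covers [%s] but auxiliaries are [%s]",
                 paste(sort(names(model$coefficients)), collapse = ", "),
                 paste(sort(names(auxiliaries)), collapse = ", "))
  }
  ref_name <- reference$name
  if (ref_name %in% names(auxiliaries)) {
    config_error("reference name '%s' collides with an auxiliary", ref_name)
  }
  maps <- c(stats::setNames(list(ranked_keyed(reference)), ref_name),
            lapply(auxiliaries[names(model$coefficients)], ranked_keyed))
  weights <- c(stats::setNames(1, ref_name), model$coefficients)

  all_keys <- sorted_unique(unlist(lapply(maps, names), use.names = FALSE))
  mat <- matrix(NA_real_, nrow = length(all_keys), ncol = length(maps),
                dimnames = list(NULL, names(maps)))
  for (nm in names(maps)) {
    mat[match(names(maps[[nm]]), all_keys), nm] <- unname(maps[[nm]])
  }
  term <- sweep(mat, 2, weights, `*`)
  sir <- rowSums(term, na.rm = TRUE)
  pair <- strsplit(all_keys, "\x1f", fixed = TRUE)
  e <- data.frame(gene_a = vapply(pair, `[[`, character(1), 1),
                  gene_b = vapply(pair, `[[`, character(1), 2),
                  sir = sir, stringsAsFactors = FALSE)
  for (nm in names(maps)) e[[paste0("inv_mr_", nm)]] <- mat[, nm]
  fused_network(e, sources = weights, name = name)
}

#' Calibrate and fuse in one call
#'
#' Convenience wrapper: [fit_calibration()] followed by [apply_fusion()].
#'
#' @inheritParams fit_calibration
#' @param name label for the fused network.
#' @return List with elements `model` (the `calibration_model`) and
#'   `network` (the [fused_network()]).
#' @export
fuse_networks <- function(reference, auxiliaries,
                          fit_mode = c("pairwise", "joint"),
                          name = "fused") {
  model <- fit_calibration(reference, auxiliaries, fit_mode)
  list(model = model,
       network = apply_fusion(reference, auxiliaries, model, name = name))
}
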