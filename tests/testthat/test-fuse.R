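# Calibration and summed-inverse-rank fusion.

test_that("joint no-intercept fit recovers planted weights exactly", {
  fx <- generate_calibration_truth(1000, c(src1 = 0.33, src2 = 0.025),
                                   noise_sd = 0, seed = 7)
  model <- fit_calibration(fx$reference, fx$auxiliaries, "joint")
  expect_equal(unname(model$coefficients), c(0.33, 0.025),
               tolerance = 1e-6)
  expect_equal(unname(model$n_common_edges), c(1000, 1000))
  expect_lt(model$residual_sse, 1e-12)
})

test_that("single-auxiliary fit recovers its planted weight exactly", {
  fx <- generate_calibration_truth(1000, c(only = 0.27),
                                   noise_sd = 0, seed = 8)
  model <- fit_calibration(fx$reference, fx$auxiliaries, "pairwise")
  expect_equal(unname(model$coefficients), 0.27, tolerance = 1e-6)
})

test_that("noisy recovery stays within 0.01 across 10 seeds", {
  for (seed in 1:10) {
    fx <- generate_calibration_truth(5000, c(a = 0.33, b = 0.025),
                                     noise_sd = 0.01, seed = seed)
    model <- fit_calibration(fx$reference, fx$auxiliaries, "joint")
    expect_true(all(abs(model$coefficients - c(0.33, 0.025)) <= 0.01))
  }
})

test_that("calibration requires at least two common edges per source", {
  fx <- generate_calibration_truth(100, c(a = 0.3), noise_sd = 0, seed = 1)
  lonely <- ranked_network(fx$auxiliaries$a$edges[1, , drop = FALSE],
                           name = "lonely")
  expect_error(fit_calibration(fx$reference, list(lonely = lonely)),
               "lonely", class = "netfuse_calibration_error")
})

test_that("negative fitted coefficients are kept but flagged", {
  # plant a genuinely negative weight: y = 0.8 x1 - 0.2 x2 stays positive
  # when x1 is bounded away from zero
  set.seed(2)
  mk <- function(v, name) {
    ranked_network(data.frame(gene_a = sprintf("GA%04d", seq_along(v)),
                              gene_b = sprintf("GB%04d", seq_along(v)),
                              rank_ab = 1 / v, rank_ba = 1 / v,
                              mr = 1 / v, inv_mr = v,
                              stringsAsFactors = FALSE), name = name)
  }
  x1 <- runif(200, 0.5, 1)
  x2 <- runif(200)
  ref <- mk(0.8 * x1 - 0.2 * x2, "ref")
  expect_warning(
    model <- fit_calibration(ref, list(a = mk(x1, "a"), b = mk(x2, "b")),
                             "joint"),
    "negative")
  expect_equal(unname(model$coefficients), c(0.8, -0.2), tolerance = 1e-6)
})

test_that("fusion evaluates the weighted sum over present sources", {
  mk_ranked <- function(a, b, v, name) {
    ranked_network(data.frame(gene_a = a, gene_b = b, rank_ab = 1 / v,
                              rank_ba = 1 / v, mr = 1 / v, inv_mr = v,
                              stringsAsFactors = FALSE), name = name)
  }
  ref <- mk_ranked(c("A", "A"), c("B", "C"), c(1, 0.5), "ref")
  a1 <- mk_ranked(c("A", "A"), c("B", "D"), c(1, 0.5), "a1")
  a2 <- mk_ranked("A", "B", 1, "a2")
  model <- structure(list(reference_name = "ref",
                          coefficients = c(a1 = 0.33, a2 = 0.025),
                          fit_mode = "pairwise",
                          n_common_edges = c(a1 = 2L, a2 = 1L),
                          residual_sse = 0),
                     class = "calibration_model")
  fused <- apply_fusion(ref, list(a1 = a1, a2 = a2), model)
  e <- fused$edges
  # edge in all three sources with unit inverse ranks
  expect_equal(e$sir[e$gene_a == "A" & e$gene_b == "B"], 1.355)
  # reference-only edge
  expect_equal(e$sir[e$gene_a == "A" & e$gene_b == "C"], 0.5)
  # edge present only in the beta = 0.33 source at inv_mr 0.5
  expect_equal(e$sir[e$gene_a == "A" & e$gene_b == "D"], 0.165)
  # universe is the union of nodes
  expect_setequal(network_nodes(fused), c("A", "B", "C", "D"))
})

test_that("removing a source lowers each affected sir by its exact term", {
  st <- default_study()
  model <- st$model
  full <- apply_fusion(st$ranked$funcnet_lls,
                       st$ranked[c("coexpr_pcc", "coexpr_hrr")], model)
  m1 <- structure(list(reference_name = model$reference_name,
                       coefficients = model$coefficients["coexpr_pcc"],
                       fit_mode = model$fit_mode,
                       n_common_edges = model$n_common_edges["coexpr_pcc"],
                       residual_sse = 0), class = "calibration_model")
  less <- apply_fusion(st$ranked$funcnet_lls,
                       st$ranked["coexpr_pcc"], m1)
  key_full <- paste(full$edges$gene_a, full$edges$gene_b)
  key_less <- paste(less$edges$gene_a, less$edges$gene_b)
  shared <- intersect(key_full, key_less)
  i <- match(shared, key_full); j <- match(shared, key_less)
  dropped_term <- ifelse(is.na(full$edges$inv_mr_coexpr_hrr[i]), 0,
                         full$edges$inv_mr_coexpr_hrr[i]) *
    model$coefficients[["coexpr_hrr"]]
  expect_equal(full$edges$sir[i] - less$edges$sir[j], dropped_term,
               tolerance = 1e-12)
})

test_that("fusing a network with itself as sole source is the identity", {
  st <- default_study()
  ref <- st$ranked$funcnet_lls
  model <- structure(list(reference_name = ref$name,
                          coefficients = stats::setNames(numeric(0),
                                                         character(0)),
                          fit_mode = "pairwise",
                          n_common_edges = integer(0), residual_sse = 0),
                     class = "calibration_model")
  solo <- apply_fusion(ref, list(), model)
  expect_equal(solo$edges$sir, ref$edges$inv_mr)
})

test_that("model/auxiliary name mismatches are configuration errors", {
  fx <- generate_calibration_truth(50, c(a = 0.3), noise_sd = 0, seed = 3)
  model <- fit_calibration(fx$reference, fx$auxiliaries)
  expect_error(apply_fusion(fx$reference,
                            stats::setNames(fx$auxiliaries, "wrong"),
                            model),
               class = "netfuse_config_error")
})

test_that("fused node coverage is at least every source's coverage", {
  st <- default_study()
  fused_nodes <- network_nodes(st$fused)
  for (src in st$ranked) {
    expect_true(all(network_nodes(src) %in% fused_nodes))
  }
})
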