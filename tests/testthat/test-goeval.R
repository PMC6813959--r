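# GO-BP based evaluation: labels, confusion counts, ROC, PR, random control.

four_edge_fixture <- function() {
  net <- make_fused(c("G1", "G1", "G2", "G3"), c("G2", "G3", "G4", "G4"),
                    c(0.9, 0.8, 0.4, 0.3))
  ann <- make_annotation(G1 = "GO:0000001", G2 = "GO:0000001",
                         G3 = "GO:0000002", G4 = "GO:0000003")
  build_match_labels(net, ann, n_exclude = 0)
}

test_that("edges are matched when genes share a retained term", {
  lab <- four_edge_fixture()
  expect_equal(nrow(lab), 4)
  m <- lab$matched[order(-lab$score)]
  # (G1,G2) share GO:0000001; the rest do not share any term
  expect_equal(m, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("excluding a ubiquitous term flips edges matched only through it", {
  ann <- make_annotation(A = c("GO:0000009", "GO:0000001"),
                         B = c("GO:0000009", "GO:0000002"),
                         C = c("GO:0000009", "GO:0000001"))
  net <- make_fused(c("A", "A"), c("B", "C"), c(0.9, 0.8))
  lab0 <- build_match_labels(net, ann, n_exclude = 0)
  expect_true(all(lab0$matched))        # everyone shares the general term
  lab1 <- build_match_labels(net, ann, n_exclude = 1)
  expect_equal(attr(lab1, "excluded_terms")$term, "GO:0000009")
  m <- lab1$matched[order(-lab1$score)]
  expect_equal(m, c(FALSE, TRUE))       # A-B was matched only via GO:0000009
})

test_that("the worked 4-edge confusion table holds at cutoff 0.5", {
  # score/label layout: (0.9, matched), (0.8, unmatched), (0.4, unmatched),
  # (0.3, matched)
  net <- make_fused(c("G1", "G1", "G2", "G3"), c("G2", "G3", "G4", "G4"),
                    c(0.9, 0.8, 0.4, 0.3))
  ann <- make_annotation(G1 = "GO:0000001", G2 = "GO:0000001",
                         G3 = "GO:0000007", G4 = "GO:0000007")
  lab <- build_match_labels(net, ann, n_exclude = 0)
  cc <- confusion_at_cutoff(lab, 0.5)
  expect_equal(c(cc$tp, cc$fp, cc$tn, cc$fn), c(1, 1, 1, 1))
  expect_equal(cc$n_predictions, 2)
  expect_equal(cc$total_true, 2)
  # precision = TP/N, recall = TP/Total True
  expect_equal(cc$tp / cc$n_predictions, 0.5)
  expect_equal(cc$tp / cc$total_true, 0.5)

  # boundary cutoffs
  low <- confusion_at_cutoff(lab, min(lab$score) - 1)
  expect_equal(low$tn + low$fn, 0)
  expect_equal(low$tp + low$fp, 4)
  high <- confusion_at_cutoff(lab, max(lab$score) + 1)
  expect_equal(high$tp + high$fp, 0)
})

test_that("conservation identities hold at every cutoff", {
  st <- default_study()
  lab <- build_match_labels(st$fused, st$annotations)
  roc <- roc_auc(lab, n_cutoffs = 40)
  total_true <- sum(lab$matched)
  total_false <- sum(!lab$matched)
  for (th in roc$cutoffs) {
    cc <- confusion_at_cutoff(lab, th)
    expect_identical(cc$tp + cc$fn, total_true)
    expect_identical(cc$fp + cc$tn, total_false)
    expect_identical(cc$tp + cc$fp + cc$tn + cc$fn, nrow(lab))
  }
})

test_that("perfectly separated scores give AUC 1 and random labels 0.5", {
  genes <- sprintf("P%02d", 1:40)
  ann_terms <- c(rep("GO:0000011", 20), rep("GO:0000012", 10),
                 rep("GO:0000013", 10))
  ann <- go_annotation(stats::setNames(as.list(ann_terms), genes))
  # matched edges (within the GO:0000011 block) all score high,
  # unmatched (across blocks) all score low
  hi <- data.frame(a = genes[seq(1, 19, 2)], b = genes[seq(2, 20, 2)])
  lo <- data.frame(a = genes[21:30], b = genes[31:40])
  net <- make_fused(c(hi$a, lo$a), c(hi$b, lo$b),
                    c(runif(10, 0.8, 1), runif(10, 0.01, 0.2)))
  lab <- build_match_labels(net, ann, n_exclude = 0)
  expect_true(all(lab$matched == (lab$score > 0.5)))
  expect_equal(roc_auc(lab)$auc, 1.0)

  # labels independent of scores: AUC ~ 0.5 on 10,000 edges
  set.seed(21)
  n <- 10000
  lab_rand <- structure(
    data.frame(gene_a = sprintf("a%05d", 1:n),
               gene_b = sprintf("b%05d", 1:n),
               score = runif(n), matched = runif(n) < 0.3),
    class = c("labeled_edges", "data.frame"))
  expect_equal(roc_auc(lab_rand)$auc, 0.5, tolerance = 0.02)
})

test_that("the 40-cutoff AUC tracks the rank-statistic oracle on 20 edges", {
  set.seed(13)
  score <- round(runif(20), 2)
  matched <- runif(20) < 0.5
  lab <- structure(
    data.frame(gene_a = sprintf("x%02d", 1:20),
               gene_b = sprintf("y%02d", 1:20),
               score = score, matched = matched),
    class = c("labeled_edges", "data.frame"))
  # tie-corrected pairwise concordance (Mann-Whitney U / n1 n2)
  pos <- score[matched]; neg <- score[!matched]
  conc <- mean(outer(pos, neg, function(p, q)
    (p > q) + 0.5 * (p == q)))
  expect_equal(roc_auc(lab)$auc, conc, tolerance = 0.02)
})

test_that("ROC is undefined for single-class inputs", {
  net <- make_fused(c("A", "A"), c("B", "C"), c(0.9, 0.8))
  ann <- make_annotation(A = "GO:0000001", B = "GO:0000001",
                         C = "GO:0000001")
  lab <- build_match_labels(net, ann, n_exclude = 0)
  expect_error(roc_auc(lab), class = "netfuse_evaluation_error")
  # but precision-recall still works and is 1 everywhere; the value grid
  # starts at the minimum score, where recall is complete
  pr <- precision_recall(lab, grid = "value")
  expect_true(all(pr$points$precision == 1))
  expect_equal(max(pr$points$recall), 1)
})

test_that("random networks are reproducible and respect the pair budget", {
  uni <- sprintf("U%02d", 1:20)
  expect_equal(n_edges(make_random_network(uni, 0)), 0)
  n1 <- make_random_network(uni, 50, seed = 5)
  n2 <- make_random_network(uni, 50, seed = 5)
  expect_equal(n1$edges, n2$edges)
  expect_false(any(n1$edges$gene_a == n1$edges$gene_b))
  expect_equal(anyDuplicated(paste(n1$edges$gene_a, n1$edges$gene_b)), 0L)
  expect_error(make_random_network(uni, 191),
               class = "netfuse_validation_error")
})

test_that("random wiring over an annotated universe has AUC near 0.5", {
  # labels drawn independently of the wiring: a densely annotated
  # universe keeps the matched class large enough for a tight bound
  set.seed(31)
  genes <- sprintf("G%04d", 1:1000)
  pool <- sprintf("GO:%07d", 3000000 + 1:50)
  ann <- go_annotation(stats::setNames(
    lapply(genes, function(g) sample(pool, 3)), genes))
  aucs <- vapply(1:10, function(s) {
    rnd <- make_random_network(genes, 10000, seed = s)
    lab <- build_match_labels(rnd, ann)   # default top-10 exclusion
    roc_auc(lab)$auc
  }, numeric(1))
  expect_true(all(abs(aucs - 0.5) <= 0.05))
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})
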