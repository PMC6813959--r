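# Readers, writers and identifier normalization.

test_that("gene ids are normalized and normalization is idempotent", {
  expect_equal(normalize_gene_id("LOC_Os01g18240.1"), "LOC_OS01G18240")
  expect_equal(normalize_gene_id("At3g62160"), "AT3G62160")
  expect_equal(normalize_gene_id("  LOC_Os04g08060 "), "LOC_OS04G08060")
  once <- normalize_gene_id(c("LOC_Os01g18240.12", "at1g01010.2", "X.3"))
  expect_equal(normalize_gene_id(once), once)
  expect_error(normalize_gene_id("   "), class = "netfuse_validation_error")
  expect_error(normalize_gene_id(character(0)),
               class = "netfuse_validation_error")
})

test_that("edge lists parse, canonicalize and detect headers", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_a\tgene_b\tscore",
               "LOC_Os01g18240\tLOC_Os05g04820\t0.87",
               "LOC_Os05g04820\tLOC_Os01g18240\t0.87",
               "b1\ta1\t0.7"), f)
  net <- read_edge_list(f, score_system = "pcc")
  expect_s3_class(net, "scored_network")
  expect_equal(nrow(net$edges), 2)         # reversed duplicate collapsed
  expect_equal(attr(net, "n_duplicates_collapsed"), 1)
  expect_true(all(net$edges$gene_a < net$edges$gene_b))
  expect_equal(net$polarity, "higher_better")
  expect_true("A1" %in% net$edges$gene_a)  # normalized, canonical order

  # headerless file with numeric third field on line 1
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb\t0.9", "a\tc\t0.8"), f2)
  net2 <- read_edge_list(f2, score_system = "generic",
                         polarity = "higher_better")
  expect_equal(nrow(net2$edges), 2)
})

test_that("edge-list parse errors cite the offending line", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(sprintf("g%02d", 1:16), sprintf("h%02d", 1:16),
                     sprintf("%.2f", runif(16)), sep = "\t"),
               "short\tline"), f)
  expect_error(read_edge_list(f, "generic", "higher_better"),
               "line 17", class = "netfuse_parse_error")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb\t0.9", "a\tc\tnot_a_number"), f2)
  expect_error(read_edge_list(f2, "generic", "higher_better"),
               "line 2", class = "netfuse_parse_error")
  expect_error(read_edge_list(file.path(tempdir(), "nope.tsv"),
                              "generic", "higher_better"),
               class = "netfuse_parse_error")
})

test_that("scores outside the declared range are rejected with offenders", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb\t0.9", "a\tc\t0.2"), f)
  expect_error(read_edge_list(f, score_system = "pcc"),
               "0.2", class = "netfuse_validation_error")
})

test_that("conflicting duplicate pairs keep the better score and warn", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb\t0.9", "b\ta\t0.6", "a\tc\t0.8"), f)
  expect_warning(net <- read_edge_list(f, "generic", "higher_better"),
                 "duplicate")
  expect_equal(net$edges$score[net$edges$gene_a == "A" &
                                 net$edges$gene_b == "B"], 0.9)

  # lower-is-better polarity keeps the smaller score
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb\t30", "b\ta\t12"), f2)
  expect_warning(net2 <- read_edge_list(f2, score_system = "hrr"),
                 "duplicate")
  expect_equal(net2$edges$score, 12)
})

test_that("self-loops are dropped with a counted warning, never silently", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\ta\t0.9", "a\tb\t0.8"), f)
  expect_warning(net <- read_edge_list(f, "generic", "higher_better"),
                 "1 self-loop")
  expect_equal(nrow(net$edges), 1)
})

test_that("GO annotations accumulate terms and honour dialects", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("g1\tGO:0009834", "g1\tGO:0006355", "g2\tGO:0009834"), f)
  ann <- read_go_annotations(f)
  expect_setequal(ann$gene_to_terms$G1, c("GO:0009834", "GO:0006355"))
  expect_equal(ann$gene_to_terms$G2, "GO:0009834")

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("g2\tGO:12", bad)
  expect_error(read_go_annotations(bad), class = "netfuse_parse_error")

  gaf <- withr::local_tempfile(fileext = ".gaf")
  writeLines(c("!gaf-version: 2.1",
               paste("DB", "g1", "sym", "", "GO:0009834", "ref", "IEA",
                     "", "P", sep = "\t"),
               paste("DB", "g1", "sym", "", "GO:0003674", "ref", "IEA",
                     "", "F", sep = "\t")), gaf)
  ann2 <- read_go_annotations(gaf, dialect = "gaf")
  expect_equal(ann2$gene_to_terms$G1, "GO:0009834")  # aspect F excluded
})

test_that("seed sets and ortholog maps enforce their invariants", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tcategory", "s1\tlignin", "s2\txylan", "s3\tlignin"),
             f)
  ss <- read_seed_set(f)
  expect_equal(nrow(ss$members), 3)
  expect_setequal(unique(ss$members$category), c("lignin", "xylan"))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("s1\tnot_a_category", bad)
  expect_error(read_seed_set(bad), "allowed",
               class = "netfuse_validation_error")

  om <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("G1\trice\tr1", "G1\trice\tr2", "G1\tath\ta1"), om)
  map <- read_ortholog_map(om)
  expect_equal(length(unique(map$groups$group_id)), 1)
  expect_equal(sum(map$groups$species == "rice"), 2)

  om2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("G1\trice\tr1", "G1\tath\ta1",
               "G2\trice\tr1", "G2\tath\ta2"), om2)
  expect_error(read_ortholog_map(om2), class = "netfuse_validation_error")
})

test_that("fused networks round-trip through TSV exactly", {
  st <- default_study()
  sub <- extract_one_step(st$fused, st$seeds)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_fused_network(sub, f)
  back <- read_fused_network(f)
  expect_equal(back$sources, sub$sources)
  expect_equal(back$edges, sub$edges)

  # single-source support leaves the other columns empty on disk
  expect_true(anyNA(sub$edges$inv_mr_coexpr_pcc))

  # empty network round-trips as a header-only file
  empty <- extract_seed_subnetwork(st$fused, c("ZZZZ1", "ZZZZ2"))
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_fused_network(empty, f2)
  back2 <- read_fused_network(f2)
  expect_equal(nrow(back2$edges), 0)
  expect_equal(back2$sources, st$fused$sources)
})

test_that("generated fixtures pass their own readers without warnings", {
  st <- default_study()
  dir <- withr::local_tempdir()
  expect_no_warning({
    write_edge_list(st$sources$coexpr_pcc, file.path(dir, "pcc.tsv"))
    write_seed_set(st$seeds, file.path(dir, "seeds.tsv"))
    write_go_annotations(st$annotations, file.path(dir, "go.tsv"))
    write_ortholog_map(st$ortholog_map, file.path(dir, "om.tsv"))
    net <- read_edge_list(file.path(dir, "pcc.tsv"), score_system = "pcc")
    seeds <- read_seed_set(file.path(dir, "seeds.tsv"))
    ann <- read_go_annotations(file.path(dir, "go.tsv"))
    om <- read_ortholog_map(file.path(dir, "om.tsv"))
  })
  expect_equal(net$edges, st$sources$coexpr_pcc$edges)
  expect_equal(seeds$members, st$seeds$members)
  expect_equal(ann$gene_to_terms, st$annotations$gene_to_terms)
  expect_equal(om$groups, st$ortholog_map$groups)
})
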