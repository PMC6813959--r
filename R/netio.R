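# Readers and writers for every file the toolkit touches.
#
# All TSV output: "." decimal separator, UTF-8, Unix newlines.  Gene ids are
# normalized (uppercase, transcript suffix stripped) at every ingestion
# point, because public deposits mix locus and transcript forms.

#' Normalize a gene identifier
#'
#' Uppercases the id, strips surrounding whitespace and a trailing
#' transcript suffix of the form `.<digits>` (so `LOC_Os01g18240.1` and
#' `LOC_Os01g18240` collapse to the same locus).
#'
#' @param raw_id character vector of raw identifiers.
#' @return Character vector of normalized ids.
#' @examples
#' normalize_gene_id("LOC_Os01g18240.1")  # "LOC_OS01G18240"
#' normalize_gene_id("At3g62160")         # "AT3G62160"
#' @export
normalize_gene_id <- function(raw_id) {
  x <- trimws(as.character(raw_id))
  if (length(x) == 0 || any(is.na(x)) || any(!nzchar(x))) {
    validation_error("empty gene identifier")
  }
  toupper(sub("\\.[0-9]+$", "", x))
}

split_tsv_lines <- function(path) {
  if (!file.exists(path)) parse_error("file not found: %s", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- nzchar(trimws(lines))
  list(lines = lines, fields = strsplit(lines, "\t", fixed = TRUE),
       keep = keep)
}

looks_numeric <- function(x) !is.na(suppressWarnings(as.numeric(x)))

#' Read a weighted edge list
#'
#' Parses a TSV with at least three columns (`gene_a`, `gene_b`, `score`).
#' A header line is detected heuristically (non-numeric third field on line
#' 1); pass `header = TRUE/FALSE` to override.  Pairs are canonicalized,
#' gene ids normalized, self-loops dropped with a counted warning, and a
#' duplicate pair with conflicting scores resolved by keeping the better
#' score under the network's polarity (with a warning).
#'
#' @param path TSV file path.
#' @param score_system one of `"pcc"`, `"hrr"`, `"lls"`, `"generic"`.
#' @param polarity,declared_range overrides; defaulted from the score
#'   system (see [score_systems]).
#' @param header `NA` (detect), `TRUE` or `FALSE`.
#' @param name network label; defaults to the file name.
#' @return A [scored_network()].
#' @export
read_edge_list <- function(path, score_system = "generic", polarity = NULL,
                           declared_range = NULL, header = NA, name = NULL) {
  tsv <- split_tsv_lines(path)
  fields <- tsv$fields
  n <- length(fields)
  if (n == 0) parse_error("%s: empty file", path)
  if (is.na(header)) {
    f1 <- fields[[1]]
    header <- length(f1) >= 3 && !looks_numeric(f1[3])
  }
  start <- if (header) 2L else 1L
  rows_idx <- seq.int(start, length.out = max(0L, n - start + 1L))
  rows_idx <- rows_idx[tsv$keep[rows_idx]]
  if (length(rows_idx) == 0) {
    return(scored_network(
      data.frame(gene_a = character(), gene_b = character(),
                 score = numeric()),
      name = name %||% basename(path), score_system = score_system,
      polarity = polarity, declared_range = declared_range))
  }
  nf <- lengths(fields[rows_idx])
  if (any(nf < 3)) {
    parse_error("%s: line %d has %d field(s), expected >= 3",
                path, rows_idx[which(nf < 3)[1]], nf[nf < 3][1])
  }
  a <- vapply(fields[rows_idx], `[[`, character(1), 1)
  b <- vapply(fields[rows_idx], `[[`, character(1), 2)
  s_raw <- vapply(fields[rows_idx], `[[`, character(1), 3)
  s <- suppressWarnings(as.numeric(s_raw))
  if (anyNA(s)) {
    i <- which(is.na(s))[1]
    parse_error("%s: line %d has non-numeric score '%s'",
                path, rows_idx[i], s_raw[i])
  }
  a <- normalize_gene_id(a)
  b <- normalize_gene_id(b)
  cp <- canonical_pairs(a, b)
  a <- cp$gene_a; b <- cp$gene_b

  loops <- a == b
  if (any(loops)) {
    warning(sprintf("%s: dropped %d self-loop line(s)", path, sum(loops)),
            call. = FALSE)
    a <- a[!loops]; b <- b[!loops]; s <- s[!loops]
  }
  pol <- polarity %||% score_systems[[
    match.arg(score_system, names(score_systems))]]$polarity
  keys <- edge_key(a, b)
  if (anyDuplicated(keys)) {
    better_first <- if (identical(pol, "lower_better")) order(keys, s)
                    else order(keys, -s)
    a <- a[better_first]; b <- b[better_first]; s <- s[better_first]
    keys <- keys[better_first]
    dup <- duplicated(keys)
    conflicting <- sum(tapply(s, keys, function(v) length(unique(v)) > 1))
    if (conflicting > 0) {
      warning(sprintf(
        "%s: %d duplicate pair(s) with conflicting scores; kept the better score under %s polarity",
        path, conflicting, pol), call. = FALSE)
    }
    a <- a[!dup]; b <- b[!dup]; s <- s[!dup]
  }
  net <- scored_network(data.frame(gene_a = a, gene_b = b, score = s,
                                   stringsAsFactors = FALSE),
                        name = name %||% basename(path),
                        score_system = score_system, polarity = polarity,
                        declared_range = declared_range)
  # counts a caller can assert on: nothing is dropped silently
  attr(net, "n_self_loops_dropped") <- sum(loops)
  attr(net, "n_duplicates_collapsed") <- length(loops) - sum(loops) -
    nrow(net$edges)
  net
}

#' Read gene-to-GO-BP annotations
#'
#' Two dialects: `two_column_tsv` (`gene<TAB>GO:nnnnnnn`, one pair per
#' line) and `gaf` (GAF 2.x; `!` comment lines skipped and only aspect
#' `"P"` rows retained, since evaluation uses biological-process terms
#' only).  Gene ids are normalized.
#'
#' @param path file path.
#' @param dialect `"two_column_tsv"` or `"gaf"`.
#' @param universe optional gene universe for the annotated fraction.
#' @return A [go_annotation()].
#' @export
read_go_annotations <- function(path,
                                dialect = c("two_column_tsv", "gaf"),
                                universe = NULL) {
  dialect <- match.arg(dialect)
  tsv <- split_tsv_lines(path)
  if (dialect == "two_column_tsv") {
    idx <- which(tsv$keep)
    if (length(idx) && identical(tolower(tsv$fields[[idx[1]]][1]), "gene")) {
      idx <- idx[-1]
    }
    genes <- character(0); terms <- character(0)
    for (i in idx) {
      f <- tsv$fields[[i]]
      if (length(f) < 2) parse_error("%s: line %d has < 2 fields", path, i)
      if (!grepl("^GO:[0-9]{7}$", f[2])) {
        parse_error("%s: line %d has malformed GO id '%s'", path, i, f[2])
      }
      genes <- c(genes, f[1]); terms <- c(terms, f[2])
    }
  } else {
    idx <- which(tsv$keep & !startsWith(tsv$lines, "!"))
    genes <- character(0); terms <- character(0)
    for (i in idx) {
      f <- tsv$fields[[i]]
      if (length(f) < 9) parse_error("%s: line %d has < 9 GAF fields", path, i)
      if (f[9] != "P") next
      if (!grepl("^GO:[0-9]{7}$", f[5])) {
        parse_error("%s: line %d has malformed GO id '%s'", path, i, f[5])
      }
      genes <- c(genes, f[2]); terms <- c(terms, f[5])
    }
  }
  if (length(genes) == 0) validation_error("%s: no usable annotations", path)
  genes <- normalize_gene_id(genes)
  go_annotation(split(terms, genes), universe = universe)
}

#' Read a seed (bait) gene table
#'
#' TSV with columns `gene`, `category`.  A header line equal to
#' `gene<TAB>category` is skipped.  Categories must come from the supplied
#' vocabulary and genes must be unique.
#'
#' @param path file path.
#' @param vocabulary allowed categories; defaults to [seed_categories].
#' @return A [seed_set()].
#' @export
read_seed_set <- function(path, vocabulary = seed_categories) {
  tsv <- split_tsv_lines(path)
  idx <- which(tsv$keep)
  if (length(idx) && identical(tolower(tsv$fields[[idx[1]]][1]), "gene")) {
    idx <- idx[-1]
  }
  if (length(idx) == 0) validation_error("%s: empty seed set", path)
  nf <- lengths(tsv$fields[idx])
  if (any(nf < 2)) {
    parse_error("%s: line %d has < 2 fields", path, idx[which(nf < 2)[1]])
  }
  gene <- normalize_gene_id(vapply(tsv$fields[idx], `[[`, character(1), 1))
  category <- vapply(tsv$fields[idx], `[[`, character(1), 2)
  seed_set(gene, category, vocabulary = vocabulary)
}

#' Read a many-to-many ortholog map
#'
#' TSV with columns `group_id`, `species`, `gene`; exactly two species over
#' the whole table, both sides of every group non-empty, and each gene in
#' at most one group per species.
#'
#' @param path file path.
#' @return An [ortholog_map()].
#' @export
read_ortholog_map <- function(path) {
  tsv <- split_tsv_lines(path)
  idx <- which(tsv$keep)
  if (length(idx) &&
      identical(tolower(tsv$fields[[idx[1]]][1]), "group_id")) {
    idx <- idx[-1]
  }
  if (length(idx) == 0) validation_error("%s: empty ortholog map", path)
  nf <- lengths(tsv$fields[idx])
  if (any(nf < 3)) {
    parse_error("%s: line %d has < 3 fields", path, idx[which(nf < 3)[1]])
  }
  ortholog_map(
    group_id = vapply(tsv$fields[idx], `[[`, character(1), 1),
    species  = vapply(tsv$fields[idx], `[[`, character(1), 2),
    gene     = normalize_gene_id(vapply(tsv$fields[idx], `[[`,
                                        character(1), 3)))
}

#' Write a fused network to TSV
#'
#' Columns: `gene_a`, `gene_b`, `sir`, then one `inv_mr_<source>` column
#' per source (empty where the source lacks the edge).  A leading
#' `#sources:` comment line records each source's weight so that
#' [read_fused_network()] round-trips the object exactly.
#'
#' @param fused a [fused_network()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fused_network <- function(fused, path) {
  stopifnot(inherits(fused, "fused_network"))
  src <- names(fused$sources)
  src_cols <- paste0("inv_mr_", src)
  hdr <- c(sprintf("#sources:\t%s",
                   paste(sprintf("%s=%s", src, fmt_num(fused$sources)),
                         collapse = "\t")),
           paste(c("gene_a", "gene_b", "sir", src_cols), collapse = "\t"))
  e <- fused$edges
  body <- if (nrow(e) > 0) {
    cols <- c(list(e$gene_a, e$gene_b, fmt_num(e$sir)),
              lapply(src_cols, function(cl) fmt_num(e[[cl]])))
    do.call(paste, c(cols, sep = "\t"))
  } else character(0)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, body), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a fused network written by [write_fused_network()]
#'
#' @param path file path.
#' @param name network label; defaults to the file name.
#' @return A [fused_network()].
#' @export
read_fused_network <- function(path, name = NULL) {
  tsv <- split_tsv_lines(path)
  if (length(tsv$lines) < 2 || !startsWith(tsv$lines[1], "#sources:")) {
    parse_error("%s: missing #sources: header line", path)
  }
  wt_tok <- tsv$fields[[1]][-1]
  wt <- vapply(strsplit(wt_tok, "=", fixed = TRUE), function(p) {
    if (length(p) != 2) parse_error("%s: bad source weight '%s'", path,
                                    paste(p, collapse = "="))
    as.numeric(p[2])
  }, numeric(1))
  names(wt) <- vapply(strsplit(wt_tok, "=", fixed = TRUE), `[[`,
                      character(1), 1)
  hdr <- tsv$fields[[2]]
  src_cols <- hdr[-(1:3)]
  if (!identical(hdr[1:3], c("gene_a", "gene_b", "sir")) ||
      !identical(src_cols, paste0("inv_mr_", names(wt)))) {
    parse_error("%s: header does not match #sources line", path)
  }
  idx <- which(tsv$keep)
  idx <- idx[idx > 2]
  ncol_exp <- length(hdr)
  parse_col <- function(j) {
    vapply(idx, function(i) {
      f <- tsv$fields[[i]]
      if (j <= length(f) && nzchar(f[j])) f[j] else NA_character_
    }, character(1))
  }
  if (length(idx) == 0) {
    e <- data.frame(gene_a = character(), gene_b = character(),
                    sir = numeric())
    for (cl in src_cols) e[[cl]] <- numeric(0)
  } else {
    nf <- lengths(tsv$fields[idx])
    if (any(nf < 3)) {
      parse_error("%s: line %d has < 3 fields", path, idx[which(nf < 3)[1]])
    }
    e <- data.frame(gene_a = parse_col(1), gene_b = parse_col(2),
                    sir = as.numeric(parse_col(3)),
                    stringsAsFactors = FALSE)
    for (j in seq_along(src_cols)) {
      e[[src_cols[j]]] <- as.numeric(parse_col(3 + j))
    }
  }
  fused_network(e, sources = wt, name = name %||% basename(path))
}

#' Write a scored network as a plain edge-list TSV
#'
#' @param net a [scored_network()].
#' @param path output path.
#' @param header write a `gene_a/gene_b/score` header line (default TRUE).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path, header = TRUE) {
  stopifnot(inherits(net, "scored_network"))
  e <- net$edges
  body <- if (nrow(e)) paste(e$gene_a, e$gene_b, fmt_num(e$score),
                             sep = "\t") else character(0)
  lines <- c(if (header) "gene_a\tgene_b\tscore", body)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Write a ranked network to TSV
#'
#' Columns `gene_a`, `gene_b`, `rank_ab`, `rank_ba`, `inv_mr`; inverse
#' mutual ranks are printed with 6 significant digits.
#'
#' @param rn a [ranked_network()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ranked_network <- function(rn, path) {
  stopifnot(inherits(rn, "ranked_network"))
  e <- rn$edges
  body <- if (nrow(e)) {
    paste(e$gene_a, e$gene_b, format(e$rank_ab, trim = TRUE),
          format(e$rank_ba, trim = TRUE),
          formatC(e$inv_mr, digits = 6, format = "g"), sep = "\t")
  } else character(0)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("gene_a\tgene_b\trank_ab\trank_ba\tinv_mr", body), con,
             sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Write a seed set / GO annotations / ortholog map to TSV
#'
#' Inverse operations of the corresponding readers, used mainly by the
#' synthetic-fixture generator.
#'
#' @param x the object to write.
#' @param path output path.
#' @return `path`, invisibly.
#' @name netio-writers
NULL

#' @rdname netio-writers
#' @export
write_seed_set <- function(x, path) {
  stopifnot(inherits(x, "seed_set"))
  writeLines(c("gene\tcategory",
               paste(x$members$gene, x$members$category, sep = "\t")),
             path)
  invisible(path)
}

#' @rdname netio-writers
#' @export
write_go_annotations <- function(x, path) {
  stopifnot(inherits(x, "go_annotation"))
  genes <- rep(names(x$gene_to_terms), lengths(x$gene_to_terms))
  terms <- unlist(x$gene_to_terms, use.names = FALSE)
  writeLines(c("gene\tgo_term", paste(genes, terms, sep = "\t")), path)
  invisible(path)
}

#' @rdname netio-writers
#' @export
write_ortholog_map <- function(x, path) {
  stopifnot(inherits(x, "ortholog_map"))
  g <- x$groups
  writeLines(c("group_id\tspecies\tgene",
               paste(g$group_id, g$species, g$gene, sep = "\t")),
             path)
  invisible(path)
}
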