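# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Classed conditions so callers can distinguish parse/validation/etc. failures.
nf_stop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "netfuse_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

parse_error       <- function(fmt, ...) nf_stop("netfuse_parse_error", fmt, ...)
validation_error  <- function(fmt, ...) nf_stop("netfuse_validation_error", fmt, ...)
calibration_error <- function(fmt, ...) nf_stop("netfuse_calibration_error", fmt, ...)
evaluation_error  <- function(fmt, ...) nf_stop("netfuse_evaluation_error", fmt, ...)
topology_error    <- function(fmt, ...) nf_stop("netfuse_topology_error", fmt, ...)
config_error      <- function(fmt, ...) nf_stop("netfuse_config_error", fmt, ...)

# Run code under a temporary RNG state; the caller's stream is untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Canonical undirected pair: gene_a < gene_b lexicographically (C locale).
canonical_pairs <- function(a, b) {
  swap <- as.logical(a > b)
  list(gene_a = ifelse(swap, b, a), gene_b = ifelse(swap, a, b))
}

edge_key <- function(a, b) paste(a, b, sep = "\x1f")

# Exact-round-trip formatting for doubles in TSV output.
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- ""
  out
}

sorted_unique <- function(x) sort(unique(x), method = "radix")
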