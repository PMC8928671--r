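# Internal helpers: seeded evaluation, seed derivation, error classes,
# provenance headers.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded package
#' operations never perturb the caller's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministically mix a master seed with named substream tokens.
# Keeps results below 2^31 so they remain valid R integer seeds.
derive_seed <- function(seed, ...) {
  tokens <- list(...)
  h <- as.numeric(seed) %% 2147483647
  for (tok in tokens) {
    if (is.character(tok)) tok <- sum(utf8ToInt(tok) * seq_along(utf8ToInt(tok)))
    h <- (h * 31 + as.numeric(tok) * 7919 + 97) %% 2147483647
  }
  as.integer(h)
}

# Error signalled when a QC metric has an undefined value (zero
# denominator); qc_report() catches this class and records the reason.
undefined_metric <- function(metric, reason) {
  stop(structure(
    class = c("atacqc_undefined_metric", "error", "condition"),
    list(message = sprintf("metric '%s' undefined: %s", metric, reason),
         call = sys.call(-1), metric = metric, reason = reason)
  ))
}

is_wholenumber <- function(x, tol = 1e-8) {
  is.numeric(x) && all(is.finite(x)) && all(abs(x - round(x)) < tol)
}

# Tiny FNV-1a string hash used for provenance headers (hex string).
fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647), as.integer(b))
    h <- (as.numeric(h) * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483647))
}

#' Write a table as TSV with a provenance header
#'
#' Output files carry comment lines recording the package version, the
#' seed in effect and a short hash of the configuration so that runs can
#' be matched to their inputs.
#'
#' @param df A data.frame.
#' @param path Output path.
#' @param seed Seed recorded in the header (may be NULL).
#' @param config Arbitrary R object hashed into the header.
#' @return `path`, invisibly.
#' @export
write_tsv_provenance <- function(df, path, seed = NULL, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# atacqc %s",
                     as.character(utils::packageVersion("atacqc"))), con)
  writeLines(sprintf("# seed=%s", if (is.null(seed)) "NA" else seed), con)
  writeLines(sprintf("# config=%s", fnv1a(config)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Read a TSV written by write_tsv_provenance (or any TSV with '#' comments).
read_tsv_comments <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
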