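#' Genome layout
#'
#' A minimal description of the reference genome an ATAC-seq library was
#' aligned to: chromosome names with lengths, plus the designated
#' mitochondrial chromosome. All coordinates in the package are 0-based
#' half-open (BED convention). The nuclear subset is every chromosome
#' except the mitochondrial one; the mitochondrial/nuclear partition
#' drives %mito and the nuclear filtering applied by every other metric.
#'
#' @param seqlengths Named numeric vector of chromosome lengths in bases.
#' @param mito Name of the mitochondrial chromosome (default `"chrM"`).
#'   It need not be present in `seqlengths`; if absent, no record can be
#'   classified as mitochondrial.
#' @return An object of class `genome_layout`.
#' @examples
#' genome_layout(c(chr1 = 1e6, chr2 = 5e5, chrM = 16571))
#' @export
genome_layout <- function(seqlengths, mito = "chrM") {
  if (is.null(names(seqlengths)) || any(!nzchar(names(seqlengths))))
    stop("'seqlengths' must be a named vector of chromosome lengths")
  if (anyDuplicated(names(seqlengths)))
    stop("chromosome names must be unique")
  if (any(!is.finite(seqlengths)) || any(seqlengths <= 0))
    stop("chromosome lengths must be positive and finite")
  if (length(mito) != 1L || !is.character(mito))
    stop("'mito' must be a single chromosome name")
  nuclear <- setdiff(names(seqlengths), mito)
  structure(
    list(seqlengths = seqlengths, mito = mito, nuclear = nuclear),
    class = "genome_layout"
  )
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("genome_layout:", length(x$seqlengths), "chromosomes,",
      sum(x$seqlengths), "bp total\n")
  cat("  nuclear:", paste(x$nuclear, collapse = ", "), "\n")
  cat("  mitochondrial:", x$mito,
      if (x$mito %in% names(x$seqlengths)) "" else "(absent)", "\n")
  invisible(x)
}

# Total length of the nuclear (default) or full genome.
genome_size <- function(layout, nuclear = TRUE) {
  if (nuclear) sum(layout$seqlengths[layout$nuclear])
  else sum(layout$seqlengths)
}
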