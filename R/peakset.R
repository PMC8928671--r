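#' Peak sets
#'
#' A named set of genomic intervals (0-based half-open), optionally
#' carrying per-interval condition labels. Used as the reference for
#' FRiP, as the unit of cross-condition reproducibility bookkeeping, and
#' as the container for ChIP-seq peaks and genome-segmentation tracks.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end 0-based half-open coordinates, `start < end`.
#' @param name Optional interval names.
#' @param labels Optional list of character vectors: the condition
#'   labels attached to each interval.
#' @param ... Further equal-length columns kept alongside (e.g. summit).
#' @return An object of class `peak_set` (a data.frame).
#' @export
peak_set <- function(chrom = character(), start = numeric(),
                     end = numeric(), name = NULL, labels = NULL, ...) {
  n <- max(length(chrom), length(start))
  if (n > 0) chrom <- rep_len(as.character(chrom), n)
  stopifnot(length(start) == n, length(end) == n)
  if (n > 0 && any(start >= end))
    stop("peak start must be < end (interval ", which(start >= end)[1L], ")")
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- as.character(name)
  if (!is.null(labels)) {
    stopifnot(length(labels) == n)
    df$labels <- I(lapply(labels, as.character))
  }
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  class(df) <- c("peak_set", "data.frame")
  df
}

#' @export
print.peak_set <- function(x, ...) {
  cat("peak_set:", nrow(x), "intervals,",
      format(sum(x$end - x$start), big.mark = ","), "bp\n")
  if (!is.null(x$labels))
    cat("  labels:", paste(sort(unique(unlist(x$labels))), collapse = ", "),
        "\n")
  invisible(x)
}

# Internal: peak_set -> GRanges (1-based closed, as Bioconductor uses).
ps_granges <- function(ps) {
  GenomicRanges::GRanges(ps$chrom, IRanges::IRanges(ps$start + 1, ps$end))
}

# Internal: GRanges -> peak_set columns (back to 0-based half-open).
granges_ps <- function(gr, ...) {
  peak_set(as.character(GenomicRanges::seqnames(gr)),
           GenomicRanges::start(gr) - 1,
           GenomicRanges::end(gr), ...)
}

#' Merge overlapping intervals
#'
#' Fuses intervals that overlap by at least one base (half-open
#' arithmetic: abutting intervals such as `[100,200)` and `[200,300)` do
#' not overlap and stay separate). The output is sorted and
#' non-overlapping. When `union_labels` is set, each merged interval
#' carries the union of the condition labels of its constituents.
#'
#' @param ps A [peak_set()].
#' @param union_labels Propagate the union of `labels` onto merged
#'   intervals.
#' @return A merged [peak_set()].
#' @export
merge_intervals <- function(ps, union_labels = FALSE) {
  if (nrow(ps) == 0) return(peak_set())
  gr <- ps_granges(ps)
  red <- GenomicRanges::reduce(gr, with.revmap = TRUE, min.gapwidth = 0L)
  out <- if (union_labels && !is.null(ps$labels)) {
    revmap <- S4Vectors::mcols(red)$revmap
    labs <- lapply(seq_along(red), function(i)
      sort(unique(unlist(ps$labels[revmap[[i]]]))))
    granges_ps(red, labels = labs)
  } else {
    granges_ps(red)
  }
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read peaks from BED or narrowPeak
#'
#' BED column 4, when present, is interpreted as a comma-joined list of
#' condition labels (the serialization used by
#' [write_condition_table()]); narrowPeak files additionally carry the
#' summit offset in column 10.
#'
#' @param path Input path.
#' @param format `"auto"` (by extension), `"bed"` or `"narrowPeak"`.
#' @return A [peak_set()].
#' @export
read_peaks <- function(path, format = c("auto", "bed", "narrowPeak")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("narrowPeak$", path, ignore.case = TRUE))
      "narrowPeak" else "bed"
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("peak file must have >= 3 columns: ", path)
  if (format == "narrowPeak" && ncol(df) >= 10) {
    peak_set(df[[1]], df[[2]], df[[3]],
             name = if (ncol(df) >= 4) df[[4]] else NULL,
             summit = df[[10]])
  } else if (ncol(df) >= 4) {
    peak_set(df[[1]], df[[2]], df[[3]],
             labels = strsplit(as.character(df[[4]]), ","))
  } else {
    peak_set(df[[1]], df[[2]], df[[3]])
  }
}

#' Write peaks
#'
#' `write_peaks()` emits BED3 (or BED4 with comma-joined labels);
#' `write_narrowpeak()` emits the 10-column narrowPeak layout with the
#' pileup summit offset in column 10 (-1 when unknown).
#'
#' @param ps A [peak_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(ps, path) {
  df <- data.frame(ps$chrom,
                   format(ps$start, scientific = FALSE, trim = TRUE),
                   format(ps$end, scientific = FALSE, trim = TRUE))
  if (!is.null(ps$labels))
    df$labels <- vapply(ps$labels, paste, "", collapse = ",")
  else if (!is.null(ps$name)) df$name <- ps$name
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_peaks
#' @export
write_narrowpeak <- function(ps, path) {
  n <- nrow(ps)
  df <- data.frame(
    chrom = ps$chrom,
    start = format(ps$start, scientific = FALSE, trim = TRUE),
    end = format(ps$end, scientific = FALSE, trim = TRUE),
    name = ps$name %||% paste0("peak_", seq_len(n)),
    score = rep(0L, n), strand = rep(".", n),
    signalValue = rep(0, n), pValue = rep(-1, n), qValue = rep(-1, n),
    summit = ps$summit %||% rep(-1L, n))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
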