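#' Fragment library
#'
#' An ordered collection of aligned, properly-paired ATAC-seq fragments.
#' Each record is a fragment (insert) on the genome: chromosome, 0-based
#' half-open start/end, the per-mate read length used to reconstruct the
#' two read spans, and a duplicate flag. The library carries the
#' pre-deduplication read counts (total and mitochondrial) needed for
#' %mito, which is defined before duplicate removal.
#'
#' The two mate read spans of a fragment are
#' `[start, min(start + readlen, end))` and
#' `[max(end - readlen, start), end)`: mates never extend past the
#' opposite fragment end.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors, 0-based half-open fragment
#'   coordinates. `end - start` must be at most 2000 bases (libraries are
#'   mapped with a 2 kb maximum insert).
#' @param layout A [genome_layout()]; all chromosomes must be declared.
#' @param readlen Read length per mate in bases (default 75, i.e. 76 bp
#'   reads with one 3' base trimmed before alignment).
#' @param is_dup Logical duplicate flags (default all `FALSE`; see
#'   [mark_duplicates()]).
#' @param total_reads,mito_reads Pre-deduplication read counts. Default
#'   to twice the number of (mitochondrial) fragments supplied.
#' @return An object of class `fragment_library` (a data.frame with
#'   columns `chrom`, `start`, `end`, `readlen`, `is_dup` and library
#'   metadata in attributes).
#' @seealso [read_fragments()], [mark_duplicates()], [qc_report()]
#' @export
fragment_library <- function(chrom, start, end, layout, readlen = 75L,
                             is_dup = FALSE, total_reads = NULL,
                             mito_reads = NULL) {
  n <- length(chrom)
  stopifnot(length(start) == n, length(end) == n)
  if (!inherits(layout, "genome_layout"))
    stop("'layout' must be a genome_layout")
  if (n > 0) {
    bad <- !(chrom %in% names(layout$seqlengths))
    if (any(bad))
      stop("unknown chromosome(s): ",
           paste(unique(chrom[bad]), collapse = ", "))
    if (any(start >= end))
      stop("fragment start must be < end (record ",
           which(start >= end)[1L], ")")
    if (any(start < 0))
      stop("fragment start must be >= 0")
    if (any(end - start > 2000))
      stop("fragment length exceeds 2000 bp (record ",
           which(end - start > 2000)[1L], ")")
    if (any(end > layout$seqlengths[chrom]))
      stop("fragment extends past chromosome end (record ",
           which(end > layout$seqlengths[chrom])[1L], ")")
  }
  if (any(readlen < 1)) stop("'readlen' must be >= 1")
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end),
                   readlen = as.numeric(rep_len(readlen, n)),
                   is_dup = rep_len(as.logical(is_dup), n),
                   stringsAsFactors = FALSE)
  is_mito <- df$chrom == layout$mito
  attr(df, "layout") <- layout
  attr(df, "total_reads") <- total_reads %||% (2 * n)
  attr(df, "mito_reads") <- mito_reads %||% (2 * sum(is_mito))
  attr(df, "deduped") <- FALSE
  class(df) <- c("fragment_library", "data.frame")
  df
}

#' @export
print.fragment_library <- function(x, ...) {
  cat("fragment_library:", nrow(x), "fragments (",
      total_reads(x), "reads pre-dedup,", mito_reads(x), "mitochondrial )\n")
  if (isTRUE(attr(x, "deduped")))
    cat("  duplicates marked:", sum(x$is_dup), "flagged\n")
  invisible(x)
}

#' Library read counts
#'
#' `total_reads()` and `mito_reads()` return the pre-deduplication,
#' post-trim read counts carried by a [fragment_library()]; `%mito` is
#' defined on these. `n_fragments()` counts records.
#'
#' @param lib A `fragment_library`.
#' @return A single number.
#' @export
total_reads <- function(lib) attr(lib, "total_reads")

#' @rdname total_reads
#' @export
mito_reads <- function(lib) attr(lib, "mito_reads")

#' @rdname total_reads
#' @export
n_fragments <- function(lib) nrow(lib)

lib_layout <- function(lib) attr(lib, "layout")

# Rebuild a fragment_library from a row subset, preserving layout and
# (optionally overriding) the pre-dedup counts.
subset_library <- function(lib, idx, total_reads = NULL, mito_reads = NULL) {
  out <- fragment_library(lib$chrom[idx], lib$start[idx], lib$end[idx],
                          layout = lib_layout(lib),
                          readlen = lib$readlen[idx],
                          is_dup = lib$is_dup[idx],
                          total_reads = total_reads %||% attr(lib, "total_reads"),
                          mito_reads = mito_reads %||% attr(lib, "mito_reads"))
  attr(out, "deduped") <- attr(lib, "deduped")
  out
}

#' Mark PCR duplicates
#'
#' Among records sharing an identical fragment triple
#' (chromosome, start, end), exactly one (the first in file order) is
#' left unflagged; the rest get `is_dup = TRUE`. For proper pairs this
#' coincides with keying on both mates' 5' positions, which is how
#' standard duplicate markers operate. The pre-deduplication read counts
#' are left untouched.
#'
#' @param lib A [fragment_library()]; must be non-empty.
#' @return The library with duplicate flags set and the unique-fragment
#'   count available via [unique_fragments()].
#' @export
mark_duplicates <- function(lib) {
  if (nrow(lib) == 0) stop("cannot mark duplicates in an empty library")
  key <- paste(lib$chrom, lib$start, lib$end, sep = "\r")
  lib$is_dup <- duplicated(key)
  attr(lib, "deduped") <- TRUE
  lib
}

#' Deduplicated and nuclear views of a library
#'
#' `dedup()` returns the deduplicated view (one record per distinct
#' fragment coordinate), marking duplicates first if needed.
#' `nuclear()` drops mitochondrial records. `unique_fragments()` counts
#' distinct nuclear fragment coordinates (the quantity the
#' Lander-Waterman complexity estimate consumes).
#'
#' @param lib A [fragment_library()].
#' @return A `fragment_library` (or a count for `unique_fragments()`).
#' @export
dedup <- function(lib) {
  if (nrow(lib) == 0) return(lib)
  if (!isTRUE(attr(lib, "deduped"))) lib <- mark_duplicates(lib)
  subset_library(lib, !lib$is_dup)
}

#' @rdname dedup
#' @export
nuclear <- function(lib) {
  layout <- lib_layout(lib)
  subset_library(lib, lib$chrom != layout$mito)
}

#' @rdname dedup
#' @export
unique_fragments <- function(lib) {
  nuc <- lib[lib$chrom != lib_layout(lib)$mito, , drop = FALSE]
  length(unique(paste(nuc$chrom, nuc$start, nuc$end, sep = "\r")))
}

#' Mate read spans as GRanges
#'
#' Reconstructs the two per-mate read intervals of every fragment from
#' the fragment ends and the read length. The left mate is reported on
#' the + strand, the right mate on the - strand. These are the "reads"
#' that FRiP, TSS enrichment and the peak caller operate on.
#'
#' @param lib A [fragment_library()].
#' @return A `GRanges` with two ranges per fragment (strand +/-) and a
#'   `fragment` metadata column giving the source record index.
#' @export
read_spans <- function(lib) {
  n <- nrow(lib)
  layout <- lib_layout(lib)
  sl <- layout$seqlengths
  if (n == 0) {
    return(GenomicRanges::GRanges(seqlengths = sl))
  }
  left_end <- pmin(lib$start + lib$readlen, lib$end)
  right_start <- pmax(lib$end - lib$readlen, lib$start)
  GenomicRanges::GRanges(
    seqnames = factor(rep(lib$chrom, 2L), levels = names(sl)),
    ranges = IRanges::IRanges(
      start = c(lib$start, right_start) + 1,
      end = c(left_end, lib$end)),
    strand = rep(c("+", "-"), each = n),
    fragment = rep(seq_len(n), 2L),
    seqlengths = sl)
}

#' 5' insertion sites of every read
#'
#' One single-base range per mate: the fragment start for the left (+)
#' mate and the last covered base for the right (-) mate. These mark the
#' transposase insertion points and drive both the peak-caller pileup and
#' genome-segmentation annotation.
#'
#' @param lib A [fragment_library()].
#' @return A `GRanges` of width-1 ranges, two per fragment.
#' @export
five_prime_sites <- function(lib) {
  n <- nrow(lib)
  sl <- lib_layout(lib)$seqlengths
  if (n == 0) return(GenomicRanges::GRanges(seqlengths = sl))
  pos1 <- c(lib$start + 1, lib$end)  # 1-based single bases
  GenomicRanges::GRanges(
    seqnames = factor(rep(lib$chrom, 2L), levels = names(sl)),
    ranges = IRanges::IRanges(start = pos1, width = 1L),
    strand = rep(c("+", "-"), each = n),
    seqlengths = sl)
}

#' Insert-size histogram
#'
#' Counts deduplicated nuclear fragments per insert size (1 bp bins).
#'
#' @param lib A [fragment_library()].
#' @return A named integer vector of class `insert_size_histogram`
#'   (names are insert sizes in bases).
#' @seealso [subnucleosomal_score()]
#' @export
insert_size_histogram <- function(lib) {
  d <- nuclear(dedup(lib))
  sizes <- d$end - d$start
  tab <- table(sizes)
  out <- as.integer(tab)
  names(out) <- names(tab)
  class(out) <- "insert_size_histogram"
  out
}

#' Read fragments from a BED-like file
#'
#' Expects at least three tab-separated columns (chrom, start, end;
#' 0-based half-open). Records on chromosomes not declared in the layout
#' and fragments longer than 2000 bp (the mapping pipeline's maximum
#' insert) are dropped with a warning; a record with `end <= start` is a
#' hard error naming the line.
#'
#' @param path Path to a BED3+ file.
#' @param layout A [genome_layout()].
#' @param readlen Read length per mate in bases.
#' @return A [fragment_library()] preserving file order.
#' @export
read_fragments <- function(path, layout, readlen = 75L) {
  cols <- utils::read.delim(path, header = FALSE, comment.char = "#",
                            stringsAsFactors = FALSE)
  if (ncol(cols) < 3)
    stop("fragment file must have >= 3 tab-separated columns: ", path)
  chrom <- as.character(cols[[1]])
  start <- as.numeric(cols[[2]])
  end <- as.numeric(cols[[3]])
  bad_coord <- which(!(start < end))
  if (length(bad_coord))
    stop("fragment with end <= start at line ", bad_coord[1L], " of ", path)
  keep <- rep(TRUE, length(chrom))
  unknown <- !(chrom %in% names(layout$seqlengths))
  if (any(unknown)) {
    warning(sum(unknown), " record(s) on unknown chromosome(s) dropped: ",
            paste(utils::head(unique(chrom[unknown]), 5), collapse = ", "))
    keep <- keep & !unknown
  }
  toolong <- (end - start) > 2000
  if (any(toolong & keep)) {
    warning(sum(toolong & keep),
            " fragment(s) longer than 2000 bp dropped")
    keep <- keep & !toolong
  }
  fragment_library(chrom[keep], start[keep], end[keep], layout = layout,
                   readlen = readlen)
}

#' Write fragments as BED3
#'
#' @param lib A [fragment_library()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(lib, path) {
  df <- data.frame(lib$chrom, format(lib$start, scientific = FALSE, trim = TRUE),
                   format(lib$end, scientific = FALSE, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
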