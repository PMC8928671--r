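#' Desk-scale Poisson pileup peak caller
#'
#' Emulates the shifted/extended fixed-window invocation of a standard
#' ATAC peak caller: every read contributes a window of `extsize` bases
#' (default 200) centered on its 5' insertion site, the per-base pileup
#' is tested against a Poisson background whose rate is the larger of
#' the genome-wide rate and the local rate in a 10 kb window, per-base
#' p-values are Benjamini-Hochberg adjusted, significant bases
#' (`q < qcut`) closer than `gap` bases are fused, and regions shorter
#' than `min_length` bases are discarded. Multi-summit regions are
#' already merged by construction. Records are used as given
#' (keep-duplicates semantics); only nuclear reads contribute.
#'
#' This is an explicit desk-scale stand-in for MACS2's procedure, not a
#' bit-exact reimplementation; externally produced narrowPeak files are
#' accepted wherever a [peak_set()] is consumed.
#'
#' @param lib A [fragment_library()].
#' @param qcut Adjusted p-value threshold (default 0.05).
#' @param extsize Smoothing window in bases centered on each 5' site.
#' @param gap Maximum gap between significant bases fused into one
#'   region.
#' @param min_length Minimum region length kept (defaults to `extsize`).
#' @param local_halfwidth Half-width of the local background window.
#' @return A [peak_set()] of disjoint intervals with a `summit` column
#'   (0-based offset of the maximum pileup within each peak).
#' @export
call_peaks <- function(lib, qcut = 0.05, extsize = 200L, gap = 30L,
                       min_length = extsize, local_halfwidth = 5000L) {
  layout <- lib_layout(lib)
  nuc <- nuclear(lib)
  if (nrow(nuc) == 0) return(peak_set())
  gsize <- genome_size(layout, nuclear = TRUE)
  n_reads <- 2 * nrow(nuc)
  lambda_bg <- n_reads * extsize / gsize
  half <- extsize %/% 2L

  sites <- five_prime_sites(nuc)
  run_chrom <- character(0); run_start <- run_end <- numeric(0)
  run_p <- numeric(0)
  pileups <- list()
  for (chr in unique(as.character(GenomicRanges::seqnames(sites)))) {
    L <- layout$seqlengths[[chr]]
    s1 <- GenomicRanges::start(sites[GenomicRanges::seqnames(sites) == chr])
    win <- IRanges::IRanges(pmax(s1 - half, 1L), pmin(s1 + half - 1L, L))
    pile <- IRanges::coverage(win, width = L)
    loc <- IRanges::IRanges(pmax(s1 - local_halfwidth, 1L),
                            pmin(s1 + local_halfwidth - 1L, L))
    lam <- IRanges::coverage(loc, width = L) *
      (extsize / (2 * local_halfwidth))
    S4Vectors::runValue(lam) <- pmax(S4Vectors::runValue(lam), lambda_bg)
    # decompose (pileup, lambda) into common runs
    ends <- sort(unique(c(cumsum(S4Vectors::runLength(pile)),
                          cumsum(S4Vectors::runLength(lam)))))
    starts <- c(1, utils::head(ends, -1) + 1)
    pv <- as.numeric(pile[ends])
    lv <- as.numeric(lam[ends])
    run_chrom <- c(run_chrom, rep(chr, length(ends)))
    run_start <- c(run_start, starts)
    run_end <- c(run_end, ends)
    run_p <- c(run_p, stats::ppois(pv - 1, lv, lower.tail = FALSE))
    pileups[[chr]] <- pile
  }
  # genome-wide BH on base-weighted runs (equivalent to per-base p.adjust)
  w <- run_end - run_start + 1
  N <- sum(w)
  o <- order(run_p)
  cand <- run_p[o] * N / cumsum(w[o])
  q_sorted <- pmin(rev(cummin(rev(cand))), 1)
  q <- numeric(length(run_p)); q[o] <- q_sorted

  sig <- q < qcut
  if (!any(sig)) return(peak_set())
  out <- list(); k <- 0L
  for (chr in unique(run_chrom[sig])) {
    sel <- sig & run_chrom == chr
    ir <- IRanges::reduce(IRanges::IRanges(run_start[sel], run_end[sel]),
                          min.gapwidth = gap + 1L)
    ir <- ir[IRanges::width(ir) >= min_length]
    if (!length(ir)) next
    summit_abs <- IRanges::viewWhichMaxs(IRanges::Views(pileups[[chr]], ir))
    k <- k + 1L
    out[[k]] <- data.frame(chrom = chr, start = IRanges::start(ir) - 1,
                           end = IRanges::end(ir),
                           summit = summit_abs - IRanges::start(ir),
                           stringsAsFactors = FALSE)
  }
  if (!k) return(peak_set())
  df <- do.call(rbind, out)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  peak_set(df$chrom, df$start, df$end,
           name = paste0("peak_", seq_len(nrow(df))), summit = df$summit)
}

#' Subsample a library to a fixed read count
#'
#' Uniform random sample of `n_reads / 2` fragments without replacement
#' (mates are never separated), seeded and order-stable: the sampled
#' records keep their original relative order.
#'
#' @param lib A [fragment_library()].
#' @param n_reads Even number of reads to keep.
#' @param seed Integer seed.
#' @return A [fragment_library()] whose pre-dedup counts reflect the
#'   subsample.
#' @export
subsample_library <- function(lib, n_reads, seed = 1L) {
  if (!is_wholenumber(n_reads) || n_reads %% 2 != 0)
    stop("'n_reads' must be an even integer (pairs are kept intact)")
  avail <- 2 * nrow(lib)
  if (n_reads > avail)
    stop("requested ", n_reads, " reads but only ", avail, " available")
  n_pairs <- n_reads / 2
  idx <- sort(with_seed(seed, sample.int(nrow(lib), n_pairs)))
  keep_mito <- 2 * sum(lib$chrom[idx] == lib_layout(lib)$mito)
  subset_library(lib, idx, total_reads = n_reads, mito_reads = keep_mito)
}

#' Cross-condition peak table
#'
#' Concatenates per-condition peak sets, merges intervals that overlap
#' by at least one base into master intervals, and labels each master
#' interval with every condition contributing at least one overlapping
#' peak. The table exposes the reproducible subset (peaks seen in at
#' least `min_conditions` conditions) and, per condition, the "missing"
#' subset: peaks reproducibly seen in at least `min_conditions` other
#' conditions but absent from the condition of interest.
#'
#' @param per_condition_peaks Named list of [peak_set()]s, one per
#'   condition; at least two, with unique names.
#' @return A `condition_peak_table` (a labeled, merged [peak_set()]).
#' @export
build_condition_table <- function(per_condition_peaks) {
  labels <- names(per_condition_peaks)
  if (is.null(labels) || any(!nzchar(labels)))
    stop("'per_condition_peaks' must be a named list")
  if (anyDuplicated(labels))
    stop("duplicate condition labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  if (length(per_condition_peaks) < 2)
    stop("need at least two conditions")
  parts <- lapply(labels, function(lab) {
    ps <- per_condition_peaks[[lab]]
    peak_set(ps$chrom, ps$start, ps$end,
             labels = rep(list(lab), nrow(ps)))
  })
  all <- do.call(rbind, parts)
  class(all) <- c("peak_set", "data.frame")
  tbl <- merge_intervals(all, union_labels = TRUE)
  attr(tbl, "conditions") <- labels
  class(tbl) <- c("condition_peak_table", class(tbl))
  tbl
}

#' @rdname build_condition_table
#' @param tbl A `condition_peak_table`.
#' @param min_conditions Reproducibility threshold (default 3).
#' @export
reproducible_peaks <- function(tbl, min_conditions = 3L) {
  out <- tbl[lengths(tbl$labels) >= min_conditions, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname build_condition_table
#' @param condition A condition label present in the table.
#' @export
missing_peaks <- function(tbl, condition, min_conditions = 3L) {
  if (!condition %in% attr(tbl, "conditions"))
    stop("unknown condition label: '", condition, "'")
  has <- vapply(tbl$labels, function(l) condition %in% l, TRUE)
  others <- vapply(tbl$labels, function(l)
    sum(l != condition), 0L)
  out <- tbl[!has & others >= min_conditions, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Serialize a condition table as BED4
#'
#' Column 4 holds the comma-joined condition labels of each master
#' interval.
#'
#' @param tbl A `condition_peak_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_condition_table <- function(tbl, path) write_peaks(tbl, path)

#' Compare peak calls with and without deduplication
#'
#' Partitions the merged union of two peak sets into intervals covered
#' by both inputs (>= 1 bp overlap with each), and intervals unique to
#' either.
#'
#' @param peaks_a,peaks_b Two [peak_set()]s (e.g. calls on deduplicated
#'   and non-deduplicated reads).
#' @return A list of [peak_set()]s: `shared`, `unique_a`, `unique_b`.
#' @export
compare_dedup_nodedup <- function(peaks_a, peaks_b) {
  if (nrow(peaks_a) == 0 && nrow(peaks_b) == 0)
    return(list(shared = peak_set(), unique_a = peak_set(),
                unique_b = peak_set()))
  both <- rbind(data.frame(chrom = peaks_a$chrom, start = peaks_a$start,
                           end = peaks_a$end),
                data.frame(chrom = peaks_b$chrom, start = peaks_b$start,
                           end = peaks_b$end))
  merged <- merge_intervals(peak_set(both$chrom, both$start, both$end))
  mgr <- ps_granges(merged)
  in_a <- if (nrow(peaks_a)) IRanges::overlapsAny(mgr, ps_granges(peaks_a))
          else rep(FALSE, length(mgr))
  in_b <- if (nrow(peaks_b)) IRanges::overlapsAny(mgr, ps_granges(peaks_b))
          else rep(FALSE, length(mgr))
  list(shared = merged[in_a & in_b, , drop = FALSE],
       unique_a = merged[in_a & !in_b, , drop = FALSE],
       unique_b = merged[!in_a & in_b, , drop = FALSE])
}

#' Peak-by-sample read count matrix
#'
#' Entry (p, s) is the number of deduplicated nuclear reads of sample s
#' overlapping peak p by at least one base.
#'
#' @param libs Named list of [fragment_library()]s.
#' @param common_peaks A merged [peak_set()].
#' @return A numeric matrix with peaks as rows (named
#'   `chrom:start-end`) and samples as columns.
#' @export
build_count_matrix <- function(libs, common_peaks) {
  if (nrow(common_peaks) == 0)
    return(matrix(0, nrow = 0, ncol = length(libs),
                  dimnames = list(NULL, names(libs))))
  pg <- ps_granges(common_peaks)
  counts <- vapply(libs, function(lib) {
    reads <- read_spans(nuclear(dedup(lib)))
    GenomicRanges::countOverlaps(pg, reads, ignore.strand = TRUE)
  }, numeric(length(pg)))
  counts <- matrix(counts, nrow = length(pg),
                   dimnames = list(
                     paste0(common_peaks$chrom, ":", common_peaks$start,
                            "-", common_peaks$end),
                     names(libs)))
  counts
}

#' Write a count matrix as TSV
#'
#' @param m Matrix from [build_count_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(m, path) {
  df <- data.frame(peak = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
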