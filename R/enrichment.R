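#' Missing-peak enrichment against a ChIP-seq peak set
#'
#' Tests whether the peaks "missing" from one condition (reproducibly
#' detected in at least `min_conditions` other conditions but absent
#' from the condition of interest) are enriched for overlap with a
#' ChIP-seq peak set, using a hypergeometric upper tail. The background
#' population is the reproducible master set (peaks seen in at least
#' `min_conditions` conditions); overlap means at least one shared base.
#'
#' With `B` background peaks of which `K` overlap the ChIP set, and `n`
#' missing peaks of which `k` overlap, the p-value is
#' `P(X >= k)` for `X ~ Hypergeometric(B, K, n)` (upper tail including
#' `k`) and the fold enrichment is `(k/n) / (K/B)`.
#'
#' @param tbl A [build_condition_table()] result.
#' @param condition Condition label under test.
#' @param chip A [peak_set()] of ChIP-seq peaks.
#' @param min_conditions Reproducibility threshold (default 3).
#' @return A one-row data.frame with columns `condition`, `p`, `fold`,
#'   `k`, `n`, `K`, `B`, `chip_peaks` and `testable` (FALSE when
#'   `n == 0` or `K == 0`, in which case `p` is NA).
#' @export
missing_peak_enrichment <- function(tbl, condition, chip,
                                    min_conditions = 3L) {
  known <- attr(tbl, "conditions") %||% unique(unlist(tbl$labels))
  if (!condition %in% known)
    stop("unknown condition label: '", condition, "'")
  labs <- tbl$labels
  nl <- lengths(labs)
  has <- vapply(labs, function(l) condition %in% l, TRUE)
  bg <- nl >= min_conditions        # reproducible background
  miss <- bg & !has                 # absent from `condition`, >= min others
  B <- sum(bg); n <- sum(miss)
  chip_gr <- if (nrow(chip)) ps_granges(merge_intervals(chip)) else NULL
  ov <- logical(length(nl))
  if (!is.null(chip_gr) && B > 0) {
    ov[bg] <- IRanges::overlapsAny(
      GenomicRanges::GRanges(tbl$chrom[bg],
                             IRanges::IRanges(tbl$start[bg] + 1,
                                              tbl$end[bg])),
      chip_gr)
  }
  K <- sum(ov[bg])
  k <- sum(ov[miss])
  testable <- n > 0 && K > 0
  p <- if (!testable) NA_real_ else
    stats::phyper(k - 1, K, B - K, n, lower.tail = FALSE)
  fold <- if (!testable) NA_real_ else (k / n) / (K / B)
  data.frame(condition = condition, p = p, fold = fold,
             k = k, n = n, K = K, B = B, chip_peaks = nrow(chip),
             testable = testable, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment with monotonicity
#' enforcement; input values outside [0, 1] are a hard error.
#'
#' @param pvalues Numeric vector of p-values (NA allowed).
#' @return Adjusted p-values, same length and order.
#' @export
adjust_bh <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Enrichment table across conditions and ChIP factors
#'
#' Runs [missing_peak_enrichment()] for every condition x factor pair
#' and applies Benjamini-Hochberg adjustment per condition across
#' factors. The layout mirrors the per-factor enrichment tables
#' typically reported alongside such screens.
#'
#' @param tbl A [build_condition_table()] result.
#' @param chip_sets Named list of ChIP [peak_set()]s (names = factors).
#' @param conditions Conditions to test (default: all in the table).
#' @param min_conditions Reproducibility threshold.
#' @param alpha Significance cutoff recorded in the `significant`
#'   column (default 0.05, applied to adjusted p-values).
#' @return A data.frame with columns `factor`, `p`, `p_adj`, `fold`,
#'   `k`, `n`, `K`, `B`, `chip_peaks`, `condition`, `significant`.
#' @export
enrichment_table <- function(tbl, chip_sets,
                             conditions = attr(tbl, "conditions"),
                             min_conditions = 3L, alpha = 0.05) {
  stopifnot(length(chip_sets) >= 1, !is.null(names(chip_sets)))
  rows <- list()
  for (cond in conditions) {
    res <- do.call(rbind, lapply(names(chip_sets), function(f) {
      r <- missing_peak_enrichment(tbl, cond, chip_sets[[f]],
                                   min_conditions)
      cbind(factor = f, r, stringsAsFactors = FALSE)
    }))
    res$p_adj <- NA_real_
    res$p_adj[res$testable] <- adjust_bh(res$p[res$testable])
    rows[[cond]] <- res
  }
  out <- do.call(rbind, rows)
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  out <- out[, c("factor", "p", "p_adj", "fold", "k", "n", "K", "B",
                 "chip_peaks", "condition", "testable", "significant")]
  rownames(out) <- NULL
  out
}

#' FRiP-ChIP and FRiP-TF for one library
#'
#' FRiP-ChIP is the fraction of deduplicated nuclear reads overlapping
#' the merged union of all ChIP-seq peak sets. FRiP-TF for factor f is
#' the number of reads overlapping factor f's peaks divided by the
#' number of reads overlapping ANY ChIP peak - i.e. the composition of
#' ChIP-covered signal, which is robust to read depth.
#'
#' @param lib A [fragment_library()].
#' @param chip_sets Named list of ChIP [peak_set()]s.
#' @return A list with `frip_chip` (fraction), `frip_tf` (named vector;
#'   all NA with `missing = TRUE` when no read overlaps any ChIP peak)
#'   and `reads_in_any`.
#' @export
frip_chip_tf <- function(lib, chip_sets) {
  stopifnot(length(chip_sets) >= 1, !is.null(names(chip_sets)))
  reads <- read_spans(nuclear(dedup(lib)))
  if (length(reads) == 0)
    undefined_metric("frip_chip", "no deduplicated nuclear reads")
  union_df <- do.call(rbind, lapply(chip_sets, function(ps)
    data.frame(chrom = ps$chrom, start = ps$start, end = ps$end)))
  union_gr <- ps_granges(merge_intervals(
    peak_set(union_df$chrom, union_df$start, union_df$end)))
  in_any <- IRanges::overlapsAny(reads, union_gr, ignore.strand = TRUE)
  denom <- sum(in_any)
  frip_chip <- denom / length(reads)
  if (denom == 0) {
    tf <- stats::setNames(rep(NA_real_, length(chip_sets)),
                          names(chip_sets))
    return(list(frip_chip = frip_chip, frip_tf = tf, reads_in_any = 0,
                missing = TRUE))
  }
  tf <- vapply(chip_sets, function(ps) {
    sum(IRanges::overlapsAny(reads, ps_granges(merge_intervals(ps)),
                             ignore.strand = TRUE)) / denom
  }, 0)
  list(frip_chip = frip_chip, frip_tf = tf, reads_in_any = denom,
       missing = FALSE)
}

#' Row-wise z-scores and MAD of a coverage matrix
#'
#' Rows are factors (or segmentation classes), columns samples. The
#' z-score uses the sample standard deviation (n - 1); display capping
#' at +/- `cap` applies only to the exported `z_display` copy, never to
#' the stored scores. The MAD is the raw median absolute deviation
#' `median(|x - median(x)|)` (no consistency constant) - a robust
#' variability summary per factor.
#'
#' @param m Numeric matrix with at least 2 columns.
#' @param cap Display cap for z-scores.
#' @return A list with `z`, `z_display`, `mad` (per row) and
#'   `constant_rows` (logical; such rows carry zero z-scores).
#' @export
summarize_matrix <- function(m, cap = 1.5) {
  m <- as.matrix(m)
  if (ncol(m) < 2) stop("need at least 2 columns")
  mu <- rowMeans(m)
  sdv <- apply(m, 1, stats::sd)
  constant <- sdv == 0 | !is.finite(sdv)
  z <- (m - mu) / ifelse(constant, 1, sdv)
  z[constant, ] <- 0
  mad_raw <- apply(m, 1, function(x) stats::median(abs(x - stats::median(x))))
  list(z = z, z_display = pmin(pmax(z, -cap), cap), mad = mad_raw,
       constant_rows = constant)
}

#' Annotate reads by genome-segmentation class
#'
#' Assigns every deduplicated nuclear read to at most one segmentation
#' class by the single base at its 5' end, and reports per-class read
#' fractions (class count / total deduplicated nuclear reads). Reads
#' whose 5' base falls in no segment are counted in no class, so the
#' fractions may sum to less than 1. Segments of different classes must
#' not overlap (a segmentation partitions the genome).
#'
#' @param lib A [fragment_library()].
#' @param segments A [peak_set()] whose `name` column holds the class of
#'   each interval (canonically one of TSS, E, WE, CTCF, R, T, PF).
#' @return Named numeric vector of per-class fractions with an
#'   `unassigned` attribute.
#' @export
annotate_segments <- function(lib, segments) {
  if (is.null(segments$name)) stop("'segments' must carry a class name column")
  classes <- unique(segments$name)
  merged_by_class <- lapply(classes, function(cl) {
    sub <- segments[segments$name == cl, , drop = FALSE]
    GenomicRanges::reduce(ps_granges(sub))
  })
  flat <- do.call(c, merged_by_class)
  if (any(GenomicRanges::countOverlaps(flat, flat) > 1))
    stop("segmentation intervals of different classes overlap; ",
         "a segmentation must partition the genome")
  sites <- five_prime_sites(nuclear(dedup(lib)))
  total <- length(sites)
  if (total == 0)
    undefined_metric("segment_fractions", "no deduplicated nuclear reads")
  counts <- vapply(merged_by_class, function(gr)
    sum(IRanges::overlapsAny(sites, gr, ignore.strand = TRUE)), 0)
  fr <- stats::setNames(counts / total, classes)
  attr(fr, "unassigned") <- 1 - sum(fr)
  fr
}
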