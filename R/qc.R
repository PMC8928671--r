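#' Fraction of reads in peaks (FRiP)
#'
#' The fraction of deduplicated, non-mitochondrial reads that overlap a
#' reference peak set by at least one base. Each mate is counted
#' independently as a read interval (the convention of intersecting
#' reads with peaks with `-u` semantics); set `by = "fragment"` to count
#' whole fragments instead.
#'
#' @param lib A [fragment_library()]. Deduplicated and mitochondrial
#'   filtering are applied internally.
#' @param ref_peaks A [peak_set()] reference; merged internally.
#' @param by Count overlapping `"read"` mate intervals (default) or
#'   whole `"fragment"` intervals.
#' @return A fraction in `[0, 1]`. An empty reference gives 0; a library
#'   with no deduplicated nuclear reads raises an undefined-metric error.
#' @export
frip <- function(lib, ref_peaks, by = c("read", "fragment")) {
  by <- match.arg(by)
  d <- nuclear(dedup(lib))
  if (nrow(d) == 0)
    undefined_metric("frip", "no deduplicated nuclear reads")
  if (nrow(ref_peaks) == 0) return(0)
  peaks <- ps_granges(merge_intervals(ref_peaks))
  if (by == "read") {
    reads <- read_spans(d)
    sum(IRanges::overlapsAny(reads, peaks, ignore.strand = TRUE)) /
      length(reads)
  } else {
    frags <- ps_granges(peak_set(d$chrom, d$start, d$end))
    sum(IRanges::overlapsAny(frags, peaks)) / length(frags)
  }
}

#' TSS enrichment score
#'
#' Aggregates per-base read-span depth over a window (default 4000 bp)
#' centered on every TSS, orienting each window by strand so that
#' negative offsets are always upstream. The aggregate profile is
#' normalized by the mean depth in the 100 outermost bases at each end
#' of the window, and the score is the maximum normalized depth in the
#' 200 bp upstream of the TSS (`mode = "upstream200"`, offsets -200..-1).
#' `mode = "centered200"` instead takes the maximum in a symmetric
#' window around the TSS (offsets -200..+199), the convention of some
#' other pipelines.
#'
#' Only deduplicated nuclear reads contribute. A zero flank mean (no
#' reads near the window edges of any TSS) is an undefined-metric error,
#' never silently zero.
#'
#' @param lib A [fragment_library()].
#' @param tss A [tss_reference()]; must be non-empty.
#' @param half_window Half-width of the profile window in bases.
#' @param flank Number of outermost bases at each end used for
#'   normalization.
#' @param mode Where the maximum is taken (see above).
#' @param return_profile Also return the normalized aggregate profile.
#' @return The fold-enrichment score, or (with `return_profile`) a list
#'   with elements `score` and `profile` (named by offset).
#' @export
tss_enrichment <- function(lib, tss, half_window = 2000L, flank = 100L,
                           mode = c("upstream200", "centered200"),
                           return_profile = FALSE) {
  mode <- match.arg(mode)
  if (nrow(tss) == 0) stop("'tss' reference is empty")
  d <- nuclear(dedup(lib))
  if (nrow(d) == 0)
    undefined_metric("tss_enrichment", "no deduplicated nuclear reads")
  sl <- lib_layout(lib)$seqlengths
  cov <- GenomicRanges::coverage(read_spans(d))
  W <- 2L * half_window
  profile <- numeric(W)
  for (chr in unique(tss$chrom)) {
    if (!chr %in% names(cov)) next
    rle <- cov[[chr]]
    L <- sl[[chr]]
    rows <- which(tss$chrom == chr)
    for (i in rows) {
      pos <- tss$pos[i]
      if (tss$strand[i] == "+") {
        lo <- pos - half_window + 1     # 1-based index of offset -half_window
        win <- window_padded(rle, lo, lo + W - 1L, L)
      } else {
        # minus strand: offset o maps to genomic base pos - o; extract the
        # ascending slice and reverse it so upstream stays at negative o.
        lo <- pos - half_window + 2
        win <- rev(window_padded(rle, lo, lo + W - 1L, L))
      }
      profile <- profile + win
    }
  }
  flank_idx <- c(seq_len(flank), (W - flank + 1L):W)
  norm <- mean(profile[flank_idx])
  if (norm == 0)
    undefined_metric("tss_enrichment", "zero read depth in window flanks")
  scaled <- profile / norm
  max_idx <- if (mode == "upstream200") {
    (half_window - 200L + 1L):half_window
  } else {
    (half_window - 200L + 1L):(half_window + 200L)
  }
  score <- max(scaled[max_idx])
  if (return_profile) {
    names(scaled) <- seq_len(W) - half_window - 1L
    list(score = score, profile = scaled)
  } else score
}

# Extract rle[a:b] as numeric, zero-padding outside [1, L].
window_padded <- function(rle, a, b, L) {
  lo <- max(a, 1L); hi <- min(b, L)
  if (lo > hi) return(numeric(b - a + 1L))
  core <- as.numeric(S4Vectors::window(rle, lo, hi))
  c(numeric(lo - a), core, numeric(b - hi))
}

#' Sub-nucleosomal score
#'
#' The ratio between the maximum fragment count at insert sizes below
#' 150 bp and the maximum count at sizes of 150 bp or more, computed on
#' the deduplicated insert-size histogram. Proxies the balance between
#' open-chromatin (sub-nucleosomal) and mono-nucleosome fragments.
#'
#' @param x An [insert_size_histogram()] or a [fragment_library()].
#' @return The ratio. If either side of the 150 bp boundary holds no
#'   fragments, an undefined-metric error is raised.
#' @export
subnucleosomal_score <- function(x) {
  if (inherits(x, "fragment_library")) x <- insert_size_histogram(x)
  sizes <- as.numeric(names(x))
  if (!length(sizes))
    undefined_metric("subnucleosomal_score", "empty insert-size histogram")
  sub <- x[sizes < 150]
  nuc <- x[sizes >= 150]
  if (!length(nuc) || all(nuc == 0))
    undefined_metric("subnucleosomal_score", "no fragments >= 150 bp")
  if (!length(sub) || all(sub == 0))
    undefined_metric("subnucleosomal_score", "no fragments < 150 bp")
  max(sub) / max(nuc)
}

#' Percent mitochondrial reads
#'
#' 100 times the number of reads mapping to the mitochondrial genome
#' divided by the total number of post-trim reads, computed BEFORE
#' duplicate removal (duplicates count).
#'
#' @param lib A [fragment_library()].
#' @return A percentage in `[0, 100]`.
#' @export
pct_mito <- function(lib) {
  tot <- total_reads(lib)
  if (is.null(tot) || tot == 0)
    undefined_metric("pct_mito", "zero total reads")
  100 * mito_reads(lib) / tot
}

#' Lander-Waterman library complexity estimate
#'
#' Estimates the number of distinct fragments in the sequenced library
#' from the observed duplication, by solving the saturation model
#' `unique = X * (1 - exp(-total / X))` for `X`. This is the model
#' behind standard duplicate-marking complexity estimates. When no
#' duplicates were observed (`unique == total`) the estimate is
#' unbounded and `Inf` is returned.
#'
#' @param total_fragments Total (nuclear) fragments sequenced.
#' @param unique_fragments Distinct fragment coordinates observed;
#'   must satisfy `0 < unique <= total`.
#' @param tol Relative tolerance of the root.
#' @return The estimated number of distinct fragments (`>= unique`), or
#'   `Inf`.
#' @export
estimate_complexity <- function(total_fragments, unique_fragments,
                                tol = 1e-9) {
  total <- as.numeric(total_fragments)
  unique <- as.numeric(unique_fragments)
  if (length(total) != 1 || length(unique) != 1 ||
      !is.finite(total) || !is.finite(unique))
    stop("'total_fragments' and 'unique_fragments' must be single numbers")
  if (unique <= 0) stop("'unique_fragments' must be positive")
  if (unique > total)
    stop("'unique_fragments' cannot exceed 'total_fragments'")
  if (unique == total) return(Inf)
  # Solve in r = total/X: (1 - exp(-r))/r decreases from 1 to 0, and
  # X > unique forces r < total/unique.
  ratio <- unique / total
  g <- function(r) (1 - exp(-r)) / r - ratio
  root <- stats::uniroot(g, lower = 1e-12, upper = total / unique,
                         tol = 1e-13)$root
  x <- total / root
  # Newton polish on f(X) = X (1 - e^(-total/X)) - unique.
  for (it in 1:5) {
    e <- exp(-total / x)
    f <- x * (1 - e) - unique
    fp <- 1 - e - (total / x) * e
    step <- f / fp
    x <- x - step
    if (abs(step) <= tol * abs(x)) break
  }
  x
}

#' Full library QC report
#'
#' Computes the five library-quality metrics (FRiP, TSS enrichment,
#' sub-nucleosomal score, %mito, estimated complexity) plus the
#' supporting counts for one library. Metrics whose denominators are
#' degenerate are reported as `NA` with the reason recorded, never as a
#' silent zero, so that cross-condition medians are not corrupted.
#'
#' @param lib A [fragment_library()].
#' @param ref_peaks A [peak_set()] used for FRiP.
#' @param tss A [tss_reference()] (may be NULL to skip TSS enrichment).
#' @param tss_mode Passed to [tss_enrichment()].
#' @return An object of class `qc_report`: a list with elements
#'   `metrics` (named numeric, NA when undefined), `counts` and
#'   `reasons`.
#' @export
qc_report <- function(lib, ref_peaks = NULL, tss = NULL,
                      tss_mode = "upstream200") {
  reasons <- list()
  grab <- function(name, expr) {
    tryCatch(expr, atacqc_undefined_metric = function(e) {
      reasons[[name]] <<- conditionMessage(e)
      NA_real_
    })
  }
  marked <- if (nrow(lib) > 0) mark_duplicates(lib) else lib
  dn <- if (nrow(lib) > 0) nuclear(dedup(marked)) else lib
  nuc_frag <- if (nrow(lib) > 0) nrow(nuclear(marked)) else 0L
  uniq <- if (nrow(lib) > 0) unique_fragments(marked) else 0L

  reads_in_peaks <- if (nrow(lib) == 0) 0 else NA_real_
  frip_v <- if (is.null(ref_peaks) || nrow(lib) == 0) NA_real_ else
    grab("frip", {
      v <- frip(marked, ref_peaks)
      reads_in_peaks <- round(v * 2 * nrow(dn))
      v
    })
  tssv <- if (is.null(tss) || nrow(lib) == 0) NA_real_ else
    grab("tss_enrichment", tss_enrichment(marked, tss, mode = tss_mode))
  sns <- if (nrow(lib) == 0) NA_real_ else
    grab("subnucleosomal_score", subnucleosomal_score(marked))
  pm <- if (nrow(lib) == 0) NA_real_ else grab("pct_mito", pct_mito(lib))
  cx <- if (nuc_frag == 0) NA_real_ else
    estimate_complexity(nuc_frag, uniq)

  structure(list(
    metrics = c(frip = frip_v, tss_enrichment = tssv,
                subnucleosomal_score = sns, pct_mito = pm,
                estimated_complexity = cx),
    counts = c(total_reads = if (nrow(lib)) total_reads(lib) else 0,
               mito_reads = if (nrow(lib)) mito_reads(lib) else 0,
               dedup_nuclear_reads = 2 * nrow(dn),
               reads_in_peaks = reads_in_peaks,
               total_fragments = nrow(lib),
               unique_fragments = uniq),
    reasons = reasons), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("ATAC-seq QC report\n")
  m <- x$metrics
  fmt <- function(v, digits = 3) if (is.na(v)) "NA (undefined)" else
    format(signif(v, digits))
  cat(sprintf("  FRiP                 : %s\n", fmt(m["frip"])))
  cat(sprintf("  TSS enrichment       : %s\n", fmt(m["tss_enrichment"])))
  cat(sprintf("  sub-nucleosomal score: %s\n",
              fmt(m["subnucleosomal_score"])))
  cat(sprintf("  %%mito                : %s\n", fmt(m["pct_mito"])))
  cx <- m["estimated_complexity"]
  cat(sprintf("  est. complexity      : %s\n",
              if (is.na(cx)) "NA (undefined)"
              else if (is.infinite(cx)) "Inf (no duplicates observed)"
              else sprintf("%.2fM fragments", cx / 1e6)))
  cat("  counts:",
      paste(names(x$counts), format(x$counts, trim = TRUE), sep = "=",
            collapse = " "), "\n")
  invisible(x)
}

#' @export
as.data.frame.qc_report <- function(x, ...) {
  data.frame(t(c(x$metrics, x$counts)))
}
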