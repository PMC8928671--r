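#' Partition a library into signal and background read pairs
#'
#' Classifies every deduplicated nuclear fragment by its mate read
#' intervals against a master peak set: pairs with at least one mate
#' overlapping a peak (>= 1 base) are "signal", pairs with neither mate
#' overlapping are "background". The two classes are disjoint and
#' jointly exhaust the deduplicated nuclear library; they are the pools
#' from which defined-FRiP libraries are reconstituted.
#'
#' @param lib A [fragment_library()] (deduplicated internally).
#' @param master A merged [peak_set()].
#' @return A `signal_background_partition`: list with
#'   [fragment_library()] elements `signal` and `background`.
#' @export
partition_by_peaks <- function(lib, master) {
  d <- nuclear(dedup(lib))
  if (nrow(master) == 0)
    stop("'master' peak set is empty: nothing to partition against")
  peaks <- ps_granges(merge_intervals(master))
  reads <- read_spans(d)
  hit <- IRanges::overlapsAny(reads, peaks, ignore.strand = TRUE)
  frag_hit <- hit[seq_len(nrow(d))] | hit[nrow(d) + seq_len(nrow(d))]
  structure(list(signal = subset_library(d, frag_hit,
                                         total_reads = 2 * sum(frag_hit),
                                         mito_reads = 0),
                 background = subset_library(d, !frag_hit,
                                             total_reads = 2 * sum(!frag_hit),
                                             mito_reads = 0)),
            class = "signal_background_partition")
}

#' @export
print.signal_background_partition <- function(x, ...) {
  cat("signal/background partition:", nrow(x$signal), "signal pairs,",
      nrow(x$background), "background pairs\n")
  invisible(x)
}

#' Reconstitute a library at a defined FRiP and depth
#'
#' Samples `round(target_frip * depth_reads / 2)` signal pairs and the
#' complementary number of background pairs without replacement (pairs
#' intact, seeded) and concatenates them, producing a synthetic library
#' whose signal-read fraction equals the target within rounding.
#'
#' @param part A [partition_by_peaks()] result.
#' @param target_frip Fraction in (0, 1].
#' @param depth_reads Even total read count of the constructed library.
#' @param seed Integer seed.
#' @return A [fragment_library()].
#' @export
construct_defined_frip <- function(part, target_frip, depth_reads,
                                   seed = 1L) {
  stopifnot(inherits(part, "signal_background_partition"))
  if (!(target_frip > 0 && target_frip <= 1))
    stop("'target_frip' must be in (0, 1]")
  if (!is_wholenumber(depth_reads) || depth_reads %% 2 != 0)
    stop("'depth_reads' must be an even integer")
  n_pairs <- depth_reads / 2
  n_sig <- round(target_frip * n_pairs)
  n_bg <- n_pairs - n_sig
  if (n_sig > nrow(part$signal))
    stop("insufficient signal pool: need ", n_sig, " pairs, have ",
         nrow(part$signal), " (short by ", n_sig - nrow(part$signal), ")")
  if (n_bg > nrow(part$background))
    stop("insufficient background pool: need ", n_bg, " pairs, have ",
         nrow(part$background), " (short by ",
         n_bg - nrow(part$background), ")")
  idx <- with_seed(seed, list(
    sig = if (n_sig > 0) sort(sample.int(nrow(part$signal), n_sig))
          else integer(0),
    bg = if (n_bg > 0) sort(sample.int(nrow(part$background), n_bg))
         else integer(0)))
  s <- part$signal; b <- part$background
  lib <- fragment_library(
    c(s$chrom[idx$sig], b$chrom[idx$bg]),
    c(s$start[idx$sig], b$start[idx$bg]),
    c(s$end[idx$sig], b$end[idx$bg]),
    layout = lib_layout(s),
    readlen = c(s$readlen[idx$sig], b$readlen[idx$bg]),
    total_reads = depth_reads, mito_reads = 0)
  attr(lib, "deduped") <- TRUE   # pools were deduplicated
  attr(lib, "target_frip") <- target_frip
  lib
}

#' Defined-FRiP simulation grid
#'
#' The design of the metric-robustness sweep: defined-FRiP levels by
#' read depths by replicates. Defaults are desk scale (hundreds of
#' thousands of reads); `full_scale = TRUE` switches the depth grid to
#' 10-50 million reads in 5 million increments, the design used on real
#' deep libraries.
#'
#' @param frip_levels Defined-FRiP levels in (0, 1).
#' @param depths Read depths (even counts of mates).
#' @param replicates Replicate subsamples per cell.
#' @param seed Master seed; per-cell seeds are derived deterministically
#'   from (seed, level, depth, replicate).
#' @param full_scale Use the 10M-50M read depth grid.
#' @return A `simulation_grid` list.
#' @export
simulation_grid <- function(frip_levels = seq(0.1, 0.9, by = 0.1),
                            depths = c(2e5, 5e5, 1e6, 2e6),
                            replicates = 3L, seed = 1L,
                            full_scale = FALSE) {
  if (full_scale) depths <- seq(1e7, 5e7, by = 5e6)
  stopifnot(all(frip_levels > 0), all(frip_levels < 1),
            all(depths %% 2 == 0), replicates >= 1)
  structure(list(frip_levels = frip_levels, depths = depths,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "simulation_grid")
}

#' Run the defined-FRiP simulation sweep
#'
#' For every (defined FRiP, depth, replicate) cell: construct the
#' synthetic library, call peaks on it, and record the peak count, the
#' subsample FRiP (against the library's own peaks), the aggregate FRiP
#' (against the master set), the external FRiP (against an independent
#' reference, if given), the TSS enrichment and the sub-nucleosomal
#' score. Per-cell failures are recorded and the sweep continues.
#'
#' @param part A [partition_by_peaks()] result.
#' @param grid A [simulation_grid()].
#' @param master The master [peak_set()] used for the partition.
#' @param external Optional independent reference [peak_set()].
#' @param tss Optional [tss_reference()].
#' @param call_peaks_args Optional list of extra arguments for
#'   [call_peaks()].
#' @return A long-format data.frame with columns `frip_level`, `depth`,
#'   `replicate`, `metric`, `value`; failed cells carried as an
#'   `errors` attribute.
#' @export
run_grid <- function(part, grid, master, external = NULL, tss = NULL,
                     call_peaks_args = list()) {
  stopifnot(inherits(grid, "simulation_grid"))
  rows <- list(); errors <- list()
  for (li in seq_along(grid$frip_levels)) {
    for (di in seq_along(grid$depths)) {
      for (rep_i in seq_len(grid$replicates)) {
        lev <- grid$frip_levels[li]; dep <- grid$depths[di]
        cell_seed <- derive_seed(grid$seed, round(1000 * lev), dep, rep_i)
        res <- tryCatch({
          lib <- construct_defined_frip(part, lev, dep, seed = cell_seed)
          own <- do.call(call_peaks, c(list(lib), call_peaks_args))
          vals <- c(
            peak_count = nrow(own),
            subsample_frip = if (nrow(own)) frip(lib, own) else 0,
            aggregate_frip = frip(lib, master),
            subnucleosomal_score = tryCatch(
              subnucleosomal_score(lib),
              atacqc_undefined_metric = function(e) NA_real_))
          if (!is.null(external))
            vals <- c(vals, external_frip = frip(lib, external))
          if (!is.null(tss))
            vals <- c(vals, tss_enrichment = tryCatch(
              tss_enrichment(lib, tss),
              atacqc_undefined_metric = function(e) NA_real_))
          data.frame(frip_level = lev, depth = dep, replicate = rep_i,
                     metric = names(vals), value = unname(vals),
                     stringsAsFactors = FALSE)
        }, error = function(e) e)
        if (inherits(res, "error")) {
          errors[[length(errors) + 1L]] <-
            list(frip_level = lev, depth = dep, replicate = rep_i,
                 message = conditionMessage(res))
        } else {
          rows[[length(rows) + 1L]] <- res
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(frip_level = numeric(), depth = numeric(),
               replicate = integer(), metric = character(),
               value = numeric())
  rownames(out) <- NULL
  attr(out, "errors") <- errors
  out
}

#' Summarize grid outcomes per cell
#'
#' Mean and min-max per (defined FRiP, depth, metric) - the error-bar
#' convention used when plotting the sweep.
#'
#' @param results Long-format output of [run_grid()].
#' @return A data.frame with columns `frip_level`, `depth`, `metric`,
#'   `mean`, `min`, `max`, `n`.
#' @export
summarize_grid <- function(results) {
  key <- interaction(results$frip_level, results$depth, results$metric,
                     drop = TRUE)
  parts <- split(results, key)
  out <- do.call(rbind, lapply(parts, function(g) {
    v <- g$value[!is.na(g$value)]
    data.frame(frip_level = g$frip_level[1], depth = g$depth[1],
               metric = g$metric[1],
               mean = if (length(v)) mean(v) else NA_real_,
               min = if (length(v)) min(v) else NA_real_,
               max = if (length(v)) max(v) else NA_real_,
               n = length(v), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$metric, out$frip_level, out$depth), , drop = FALSE]
  rownames(out) <- NULL
  out
}
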