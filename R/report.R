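qc_metric_names <- c("frip", "tss_enrichment", "subnucleosomal_score",
                     "pct_mito", "estimated_complexity")

#' QC workflow over a panel of libraries
#'
#' Computes a [qc_report()] per sample, tabulates one row per sample
#' (metadata columns first, then the five metrics and supporting
#' counts), appends grouped medians for any grouping variables, and
#' computes the pairwise Pearson correlation matrix of the five metrics
#' per stratum. When `out_dir` is given, writes
#' `qc_samples.tsv`, `qc_group_medians.tsv` and one
#' `qc_correlations_<stratum>.tsv` per stratum, each with a provenance
#' header.
#'
#' @param libs Named list of [fragment_library()]s.
#' @param ref_peaks A [peak_set()] used for FRiP.
#' @param tss A [tss_reference()] (optional).
#' @param metadata Optional data.frame with a `sample` column matching
#'   `names(libs)` plus grouping variables (e.g. buffer, temperature,
#'   fixation).
#' @param group_by Metadata columns to group medians/correlations by.
#' @param out_dir Optional output directory.
#' @param seed Seed recorded in provenance headers.
#' @param tss_mode Passed to [qc_report()].
#' @return A list with `samples` (data.frame), `medians` (data.frame or
#'   NULL) and `correlations` (named list of matrices).
#' @export
atac_qc <- function(libs, ref_peaks = NULL, tss = NULL, metadata = NULL,
                    group_by = NULL, out_dir = NULL, seed = NULL,
                    tss_mode = "upstream200") {
  stopifnot(length(libs) >= 1, !is.null(names(libs)))
  rows <- lapply(names(libs), function(s) {
    rep <- qc_report(libs[[s]], ref_peaks, tss, tss_mode = tss_mode)
    cbind(data.frame(sample = s, stringsAsFactors = FALSE),
          as.data.frame(rep))
  })
  samples <- do.call(rbind, rows)
  if (!is.null(metadata)) {
    stopifnot("sample" %in% names(metadata))
    samples <- merge(metadata, samples, by = "sample", sort = FALSE)
  }
  medians <- if (!is.null(group_by)) {
    missing_cols <- setdiff(group_by, names(samples))
    if (length(missing_cols))
      stop("grouping column(s) not in metadata: ",
           paste(missing_cols, collapse = ", "))
    qc_group_medians(samples, by = group_by)
  } else NULL
  strata <- if (is.null(group_by)) list(all = samples) else
    split(samples, interaction(samples[group_by], drop = TRUE, sep = "_"))
  correlations <- lapply(strata, function(g) {
    m <- as.matrix(g[, qc_metric_names, drop = FALSE])
    if (nrow(m) >= 3)
      suppressWarnings(stats::cor(m, use = "pairwise.complete.obs",
                                  method = "pearson"))
    else NULL
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv_provenance(samples, file.path(out_dir, "qc_samples.tsv"),
                         seed = seed, config = group_by)
    if (!is.null(medians))
      write_tsv_provenance(medians,
                           file.path(out_dir, "qc_group_medians.tsv"),
                           seed = seed, config = group_by)
    for (nm in names(correlations)) {
      if (is.null(correlations[[nm]])) next
      cm <- data.frame(metric = rownames(correlations[[nm]]),
                       correlations[[nm]], check.names = FALSE)
      write_tsv_provenance(
        cm, file.path(out_dir, paste0("qc_correlations_", nm, ".tsv")),
        seed = seed, config = group_by)
    }
  }
  list(samples = samples, medians = medians, correlations = correlations)
}

#' Grouped medians of the five QC metrics
#'
#' @param df A data.frame holding the metric columns (`frip`,
#'   `tss_enrichment`, `subnucleosomal_score`, `pct_mito`,
#'   `estimated_complexity`) plus grouping variables.
#' @param by Character vector of grouping columns.
#' @param metrics Metric columns to summarize.
#' @return One row per group with the median of each metric
#'   (NA values excluded).
#' @export
qc_group_medians <- function(df, by, metrics = qc_metric_names) {
  metrics <- intersect(metrics, names(df))
  if (!length(metrics)) stop("no metric columns found")
  groups <- split(df, interaction(df[by], drop = TRUE, sep = "_"))
  out <- do.call(rbind, lapply(groups, function(g) {
    meds <- vapply(metrics, function(m)
      stats::median(g[[m]], na.rm = TRUE), 0)
    cbind(unique(g[by]), data.frame(n = nrow(g)), t(meds))
  }))
  rownames(out) <- NULL
  out
}

#' Read a per-sample QC metric table
#'
#' Reads a TSV of per-sample QC rows (sample id, experimental
#' components, then metric columns), the layout used for per-sample
#' metric supplements. Comment lines starting with `#` are skipped.
#'
#' @param path TSV path.
#' @return A data.frame.
#' @export
read_qc_table <- function(path) read_tsv_comments(path)

#' Per-condition peak counts from a condition table
#'
#' Counts, for every condition label, the master intervals in which
#' that condition detected a peak.
#'
#' @param tbl A [build_condition_table()] result (or any labeled
#'   [peak_set()]).
#' @return Named integer vector of per-condition peak counts.
#' @export
condition_peak_counts <- function(tbl) {
  if (is.null(tbl$labels)) stop("table carries no condition labels")
  tab <- table(unlist(tbl$labels))
  conds <- attr(tbl, "conditions") %||% names(tab)
  out <- stats::setNames(integer(length(conds)), conds)
  out[names(tab)] <- as.integer(tab)
  out
}

#' Median/extreme summary of per-condition peak counts
#'
#' @param counts Named vector from [condition_peak_counts()].
#' @param groups Optional factor/character grouping of the conditions
#'   (e.g. native vs fixed); one summary row per group.
#' @return A data.frame with columns `group`, `median`, `min`, `max`,
#'   `which_max`, `which_min`, `sd`.
#' @export
peak_count_summary <- function(counts, groups = NULL) {
  if (is.null(groups)) groups <- rep("all", length(counts))
  parts <- split(seq_along(counts), groups)
  out <- do.call(rbind, lapply(names(parts), function(g) {
    v <- counts[parts[[g]]]
    data.frame(group = g, median = stats::median(v), min = min(v),
               max = max(v), which_max = names(v)[which.max(v)],
               which_min = names(v)[which.min(v)],
               sd = stats::sd(v), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Simulation workflow
#'
#' Partitions a library against a master peak set and runs the
#' defined-FRiP sweep, writing the long-format outcome table and the
#' per-cell mean/min-max summary.
#'
#' @param lib A [fragment_library()] (or a ready
#'   `signal_background_partition`).
#' @param master Master [peak_set()]; must be non-empty.
#' @param grid A [simulation_grid()].
#' @param external,tss Optional references forwarded to [run_grid()].
#' @param out_dir Optional output directory for
#'   `simulation_long.tsv` / `simulation_summary.tsv`.
#' @return A list with `results` and `summary` data.frames.
#' @export
atac_simulate <- function(lib, master, grid = simulation_grid(),
                          external = NULL, tss = NULL, out_dir = NULL) {
  if (nrow(master) == 0)
    stop("master peak set is empty; cannot define signal/background")
  part <- if (inherits(lib, "signal_background_partition")) lib
          else partition_by_peaks(lib, master)
  results <- run_grid(part, grid, master, external = external, tss = tss)
  summary <- summarize_grid(results)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv_provenance(results, file.path(out_dir, "simulation_long.tsv"),
                         seed = grid$seed, config = grid)
    write_tsv_provenance(summary,
                         file.path(out_dir, "simulation_summary.tsv"),
                         seed = grid$seed, config = grid)
  }
  list(results = results, summary = summary)
}

#' Functional-enrichment workflow
#'
#' Missing-peak enrichment rows per condition and ChIP factor (with
#' per-condition BH adjustment), the FRiP-TF coverage matrix with
#' row-wise z-scores and MAD, and genome-segmentation read fractions.
#' With fewer than four conditions the "missing in >= 3 others"
#' definition is degenerate and a warning is issued.
#'
#' @param tbl A [build_condition_table()] result.
#' @param chip_sets Named list of ChIP [peak_set()]s (optional).
#' @param libs Named list of [fragment_library()]s for the coverage
#'   matrix / segmentation fractions (optional).
#' @param segments Segmentation [peak_set()] (optional).
#' @param conditions Conditions to test; every label must exist in the
#'   table (hard error naming the offender).
#' @param min_conditions Reproducibility threshold.
#' @param out_dir Optional output directory.
#' @param seed Seed recorded in provenance headers.
#' @return A list with `enrichment`, `frip_tf` (matrix), `frip_chip`,
#'   `matrix_summary`, `segment_fractions`.
#' @export
atac_enrich <- function(tbl, chip_sets = NULL, libs = NULL,
                        segments = NULL,
                        conditions = attr(tbl, "conditions"),
                        min_conditions = 3L, out_dir = NULL, seed = NULL) {
  known <- attr(tbl, "conditions")
  bad <- setdiff(conditions, known)
  if (length(bad))
    stop("condition label not in table: '", bad[1L], "'")
  if (length(known) < 4)
    warning("fewer than 4 conditions: the 'missing in >= ",
            min_conditions, " others' definition is degenerate")
  enr <- if (!is.null(chip_sets))
    enrichment_table(tbl, chip_sets, conditions, min_conditions)
  else NULL
  frip_tf <- frip_chip <- msum <- NULL
  if (!is.null(chip_sets) && !is.null(libs)) {
    cols <- lapply(libs, frip_chip_tf, chip_sets = chip_sets)
    frip_tf <- vapply(cols, function(x) x$frip_tf,
                      numeric(length(chip_sets)))
    frip_tf <- matrix(frip_tf, nrow = length(chip_sets),
                      dimnames = list(names(chip_sets), names(libs)))
    frip_chip <- vapply(cols, function(x) x$frip_chip, 0)
    if (ncol(frip_tf) >= 2 && !anyNA(frip_tf))
      msum <- summarize_matrix(frip_tf)
  }
  segfr <- if (!is.null(segments) && !is.null(libs)) {
    t(vapply(libs, annotate_segments, segments = segments,
             FUN.VALUE = numeric(length(unique(segments$name)))))
  } else NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(enr))
      write_tsv_provenance(enr, file.path(out_dir, "enrichment.tsv"),
                           seed = seed, config = conditions)
    if (!is.null(frip_tf)) {
      df <- data.frame(factor = rownames(frip_tf), frip_tf,
                       check.names = FALSE)
      if (!is.null(msum)) df$mad <- msum$mad
      write_tsv_provenance(df, file.path(out_dir, "frip_tf.tsv"),
                           seed = seed, config = conditions)
    }
    if (!is.null(segfr))
      write_tsv_provenance(
        data.frame(sample = rownames(segfr), segfr, check.names = FALSE),
        file.path(out_dir, "segment_fractions.tsv"),
        seed = seed, config = conditions)
  }
  list(enrichment = enr, frip_tf = frip_tf, frip_chip = frip_chip,
       matrix_summary = msum, segment_fractions = segfr)
}
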