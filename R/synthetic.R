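#' Generator configuration
#'
#' One seeded configuration object drives the synthetic genome,
#' annotation and fragment-library generator. Defaults describe a
#' desk-scale caricature of a human ATAC-seq experiment: a two-
#' chromosome 10 Mb nuclear genome plus a 16.6 kb mitochondrial
#' chromosome, a few hundred accessibility peaks with heterogeneous
#' intensities, a tri-modal insert-size mixture (sub-nucleosomal,
#' mono-nucleosome ~200 bp, di-nucleosome ~380 bp), substantial
#' mitochondrial contamination, and a finite latent fragment pool so
#' that PCR duplicates arise naturally at depth.
#'
#' @param seed Master seed. All generator randomness flows from it
#'   through named substreams.
#' @param chrom_lengths Named lengths of the nuclear chromosomes.
#' @param mito_chrom,mito_length Mitochondrial chromosome name/length.
#' @param n_peaks Number of planted accessibility peaks.
#' @param peak_width_min,peak_width_max Peak width range in bases.
#' @param min_gap Minimum gap enforced between planted peaks.
#' @param peak_weight_shape Gamma shape of per-peak intensity weights;
#'   values below 1 give many weak peaks and a detection continuum.
#' @param tss_fraction Fraction of peaks flagged TSS-proximal (a TSS is
#'   planted inside each).
#' @param tss_strength Extra sampling weight multiplier for
#'   TSS-proximal peaks (weight scales by `1 + tss_strength`).
#' @param depth_fragments Fragments drawn per library.
#' @param frip Probability that a nuclear fragment is placed in a peak;
#'   approximately the aggregate FRiP of the library.
#' @param size_weights Mixture weights (sub, mono, di); must sum to 1.
#' @param mito_fraction Fraction of fragments on the mitochondrial
#'   chromosome.
#' @param complexity True size of the latent nuclear fragment pool
#'   (Lander-Waterman "X"); `Inf` for a duplicate-free library.
#' @param readlen Read length per mate.
#' @param factor_names ChIP factors simulated; each gets a class of
#'   accessibility peaks plus decoy peaks.
#' @param class_fraction Fraction of peaks assigned to some factor
#'   class (the rest are class "none").
#' @param chip_sensitivity Probability a class member appears in its
#'   factor's ChIP set.
#' @param chip_decoy_frac Decoy ChIP peaks (outside accessibility
#'   peaks) as a fraction of true members.
#' @param segments_per_chrom Segmentation intervals per nuclear
#'   chromosome, tiled over the 7-class vocabulary.
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 1L,
                             chrom_lengths = c(chr1 = 5e6, chr2 = 5e6),
                             mito_chrom = "chrM", mito_length = 16571,
                             n_peaks = 500L,
                             peak_width_min = 300L, peak_width_max = 700L,
                             min_gap = 1000L,
                             peak_weight_shape = 4,
                             tss_fraction = 0.3, tss_strength = 2,
                             depth_fragments = 2e5,
                             frip = 0.5,
                             size_weights = c(sub = 0.62, mono = 0.28,
                                              di = 0.10),
                             mito_fraction = 0.24,
                             complexity = 1e6,
                             readlen = 75L,
                             factor_names = c("CTCF", "POLR2A", "EP300",
                                              "RAD21", "TBP"),
                             class_fraction = 0.7,
                             chip_sensitivity = 0.9,
                             chip_decoy_frac = 0.2,
                             segments_per_chrom = 200L) {
  stopifnot(abs(sum(size_weights) - 1) < 1e-8,
            frip >= 0, frip <= 1, mito_fraction >= 0, mito_fraction < 1,
            tss_fraction >= 0, tss_fraction <= 1,
            peak_width_min >= 150, peak_width_max >= peak_width_min,
            complexity > 0)
  structure(as.list(environment()), class = "generator_config")
}

segment_classes <- c("TSS", "E", "WE", "CTCF", "R", "T", "PF")

#' Generate a synthetic genome annotation
#'
#' Plants disjoint accessibility peaks with per-peak intensity weights
#' and factor-class assignments, a strand-aware TSS inside a configured
#' fraction of them, one ChIP peak set per factor (a sensitivity-thinned
#' copy of the factor's class plus decoys outside accessibility peaks),
#' and a 7-class genome segmentation that tiles every nuclear base
#' exactly once.
#'
#' @param cfg A [generator_config()].
#' @return An `atac_annotation` list: `layout`, `peaks` (a
#'   [peak_set()] with `weight`, `is_tss`, `class` columns), `tss`,
#'   `chip` (named list of [peak_set()]s), `segments`, `config`.
#' @export
generate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  layout <- genome_layout(
    c(cfg$chrom_lengths,
      stats::setNames(cfg$mito_length, cfg$mito_chrom)),
    mito = cfg$mito_chrom)
  with_seed(derive_seed(cfg$seed, "annotation"), {
    chroms <- names(cfg$chrom_lengths)
    alloc <- round(cfg$n_peaks * cfg$chrom_lengths / sum(cfg$chrom_lengths))
    alloc[1] <- cfg$n_peaks - sum(alloc[-1])
    peak_rows <- list()
    for (ci in seq_along(chroms)) {
      k <- alloc[ci]
      if (k == 0) next
      L <- cfg$chrom_lengths[ci]
      w <- round(stats::runif(k, cfg$peak_width_min, cfg$peak_width_max))
      slack <- L - sum(w) - (k + 1) * cfg$min_gap
      if (slack < 0)
        stop("requested peaks exceed genome capacity on ", chroms[ci])
      cuts <- sort(stats::runif(k, 0, slack))
      extra <- diff(c(0, cuts))
      starts <- numeric(k)
      pos <- 0
      for (i in seq_len(k)) {
        pos <- pos + cfg$min_gap + extra[i]
        starts[i] <- floor(pos)
        pos <- pos + w[i]
      }
      peak_rows[[ci]] <- data.frame(chrom = chroms[ci], start = starts,
                                    end = starts + w,
                                    stringsAsFactors = FALSE)
    }
    pk <- do.call(rbind, peak_rows)
    np <- nrow(pk)
    pk$weight <- stats::rgamma(np, shape = cfg$peak_weight_shape, rate = 1)
    pk$weight <- pk$weight / sum(pk$weight)
    n_tss <- round(cfg$tss_fraction * np)
    pk$is_tss <- FALSE
    if (n_tss > 0) pk$is_tss[sample.int(np, n_tss)] <- TRUE
    # factor classes: a configured share of peaks belongs to some factor
    cls <- rep("none", np)
    n_classed <- round(cfg$class_fraction * np)
    if (n_classed > 0 && length(cfg$factor_names) > 0) {
      picked <- sample.int(np, n_classed)
      cls[picked] <- sample(cfg$factor_names, n_classed, replace = TRUE)
    }
    pk$class <- cls

    tss <- if (n_tss > 0) {
      ti <- which(pk$is_tss)
      pos <- pk$start[ti] +
        floor(stats::runif(length(ti)) * (pk$end[ti] - pk$start[ti]))
      tss_reference(pk$chrom[ti], pos,
                    sample(c("+", "-"), length(ti), replace = TRUE))
    } else tss_reference()

    peaks_gr <- GenomicRanges::GRanges(pk$chrom,
                                       IRanges::IRanges(pk$start + 1, pk$end))
    chip <- lapply(cfg$factor_names, function(f) {
      members <- which(pk$class == f)
      keep <- members[stats::runif(length(members)) <= cfg$chip_sensitivity]
      n_decoy <- round(cfg$chip_decoy_frac * length(keep))
      decoys <- if (n_decoy > 0)
        sample_clear_intervals(n_decoy, 300L, cfg$chrom_lengths, peaks_gr)
      else NULL
      df <- data.frame(chrom = pk$chrom[keep], start = pk$start[keep],
                       end = pk$end[keep], stringsAsFactors = FALSE)
      if (!is.null(decoys)) df <- rbind(df, decoys)
      df <- df[order(df$chrom, df$start), , drop = FALSE]
      peak_set(df$chrom, df$start, df$end,
               name = paste0(f, "_", seq_len(nrow(df))))
    })
    names(chip) <- cfg$factor_names

    seg_rows <- lapply(chroms, function(chr) {
      L <- cfg$chrom_lengths[[chr]]
      m <- max(1L, cfg$segments_per_chrom)
      bounds <- sort(sample.int(L - 1L, m - 1L))
      s <- c(0, bounds); e <- c(bounds, L)
      data.frame(chrom = chr, start = s, end = e,
                 class = sample(segment_classes, m, replace = TRUE),
                 stringsAsFactors = FALSE)
    })
    seg <- do.call(rbind, seg_rows)
    segments <- peak_set(seg$chrom, seg$start, seg$end, name = seg$class)

    structure(list(layout = layout,
                   peaks = peak_set(pk$chrom, pk$start, pk$end,
                                    name = paste0("peak_", seq_len(np)),
                                    weight = pk$weight, is_tss = pk$is_tss,
                                    class = pk$class),
                   tss = tss, chip = chip, segments = segments,
                   config = cfg),
              class = "atac_annotation")
  })
}

# Rejection-sample n intervals of the given width that do not overlap
# `avoid` (a GRanges); used for decoy ChIP peaks and background reads.
sample_clear_intervals <- function(n, width, chrom_lengths, avoid,
                                   max_tries = 50L) {
  chroms <- names(chrom_lengths)
  probs <- chrom_lengths / sum(chrom_lengths)
  out_chrom <- character(n); out_start <- numeric(n)
  todo <- seq_len(n)
  for (try in seq_len(max_tries)) {
    ci <- sample.int(length(chroms), length(todo), replace = TRUE,
                     prob = probs)
    st <- floor(stats::runif(length(todo)) * (chrom_lengths[ci] - width))
    gr <- GenomicRanges::GRanges(chroms[ci],
                                 IRanges::IRanges(st + 1, st + width))
    ok <- !IRanges::overlapsAny(gr, avoid)
    out_chrom[todo[ok]] <- chroms[ci][ok]
    out_start[todo[ok]] <- st[ok]
    todo <- todo[!ok]
    if (!length(todo)) break
  }
  if (length(todo))
    stop("could not place ", length(todo),
         " interval(s) clear of peaks after ", max_tries, " rounds")
  data.frame(chrom = out_chrom, start = out_start,
             end = out_start + width, stringsAsFactors = FALSE)
}

#' Generate a synthetic fragment library
#'
#' Draws `depth_fragments` fragments (with replacement) from a latent
#' pool of `complexity` distinct nuclear fragments plus a
#' proportionally-sized mitochondrial pool, so that duplicates arise
#' naturally and the Lander-Waterman model is exactly the right
#' recovery model for the nuclear pool size. Pool fragments are placed
#' in planted peaks with probability `frip` (fully inside the peak
#' whenever they fit, peak chosen proportionally to its intensity
#' weight, TSS boost and any class multiplier) and in peak-free
#' background otherwise; insert sizes follow the tri-modal
#' sub-nucleosomal / mono- / di-nucleosome mixture.
#'
#' @param cfg A [generator_config()].
#' @param ann A [generate_annotation()] result.
#' @param frip,depth_fragments,mito_fraction,tss_strength,complexity
#'   Optional overrides of the corresponding `cfg` values.
#' @param class_multipliers Named numeric vector: sampling-weight
#'   multipliers applied to peaks of the named factor classes
#'   (emulating condition-specific coverage biases).
#' @param seed Seed; defaults to a substream of `cfg$seed`.
#' @return A [fragment_library()].
#' @export
generate_library <- function(cfg, ann, frip = cfg$frip,
                             depth_fragments = cfg$depth_fragments,
                             mito_fraction = cfg$mito_fraction,
                             tss_strength = cfg$tss_strength,
                             complexity = cfg$complexity,
                             class_multipliers = NULL,
                             seed = derive_seed(cfg$seed, "library")) {
  stopifnot(inherits(ann, "atac_annotation"))
  depth <- as.integer(depth_fragments)
  X <- complexity
  if (is.finite(X)) {
    n_nuc_pool <- as.integer(round(X))
    n_mito_pool <- as.integer(round(X * mito_fraction / (1 - mito_fraction)))
  } else {
    n_nuc_pool <- n_mito_pool <- NA_integer_  # resolved under seed below
  }
  pk <- ann$peaks
  layout <- ann$layout
  nuclear_lengths <- layout$seqlengths[layout$nuclear]
  peaks_gr <- ps_granges(pk)

  pool <- with_seed(derive_seed(seed, "placement"), {
    if (!is.finite(X)) {
      n_mito_pool <- stats::rbinom(1, depth, mito_fraction)
      n_nuc_pool <- depth - n_mito_pool
    }
    sizes <- with_seed(derive_seed(seed, "sizes"),
                       draw_insert_sizes(n_nuc_pool + n_mito_pool,
                                         cfg$size_weights))
    is_mito <- rep(c(FALSE, TRUE), c(n_nuc_pool, n_mito_pool))
    chrom <- character(length(sizes)); start <- numeric(length(sizes))

    # nuclear: signal fragments inside peaks, background clear of them
    mult <- rep(1, nrow(pk))
    if (!is.null(class_multipliers)) {
      for (nm in names(class_multipliers))
        mult[pk$class == nm] <- class_multipliers[[nm]]
    }
    w <- pk$weight * (1 + tss_strength * pk$is_tss) * mult
    nuc_idx <- which(!is_mito)
    sig <- stats::runif(length(nuc_idx)) < frip
    si <- nuc_idx[sig]; bi <- nuc_idx[!sig]
    if (length(si)) {
      pj <- sample.int(nrow(pk), length(si), replace = TRUE,
                       prob = w / sum(w))
      pw <- pk$end[pj] - pk$start[pj]
      s <- sizes[si]
      fits <- s <= pw
      off <- numeric(length(si))
      off[fits] <- floor(stats::runif(sum(fits)) * (pw[fits] - s[fits] + 1))
      off[!fits] <- floor((pw[!fits] - s[!fits]) / 2)  # centered overhang
      st <- pk$start[pj] + off
      st <- pmax(st, 0)
      st <- pmin(st, layout$seqlengths[pk$chrom[pj]] - s)
      chrom[si] <- pk$chrom[pj]; start[si] <- st
    }
    if (length(bi)) {
      bg <- sample_background_fragments(sizes[bi], nuclear_lengths,
                                        peaks_gr)
      chrom[bi] <- bg$chrom; start[bi] <- bg$start
    }
    if (any(is_mito)) {
      mi <- which(is_mito)
      s <- pmin(sizes[mi], layout$seqlengths[[layout$mito]] - 1)
      sizes[mi] <- s
      chrom[mi] <- layout$mito
      start[mi] <- floor(stats::runif(length(mi)) *
                           (layout$seqlengths[[layout$mito]] - s))
    }
    data.frame(chrom = chrom, start = start, end = start + sizes,
               stringsAsFactors = FALSE)
  })

  idx <- if (is.finite(X))
    with_seed(derive_seed(seed, "duplication"),
              sample.int(nrow(pool), depth, replace = TRUE))
  else seq_len(nrow(pool))
  fragment_library(pool$chrom[idx], pool$start[idx], pool$end[idx],
                   layout = layout, readlen = cfg$readlen)
}

# Tri-modal insert-size mixture: sub-nucleosomal (< 150 bp),
# mono-nucleosome (~200 bp) and di-nucleosome (~380 bp) components,
# truncated so the sub component stays below the 150 bp boundary.
draw_insert_sizes <- function(n, weights) {
  comp <- sample(c("sub", "mono", "di"), n, replace = TRUE,
                 prob = weights[c("sub", "mono", "di")])
  out <- numeric(n)
  draw_trunc <- function(m, rfun, lo, hi) {
    x <- rfun(m)
    bad <- which(x < lo | x > hi)
    while (length(bad)) {
      x[bad] <- rfun(length(bad))
      bad <- bad[x[bad] < lo | x[bad] > hi]
    }
    x
  }
  ns <- sum(comp == "sub")
  if (ns) out[comp == "sub"] <-
      draw_trunc(ns, function(m) 30 + stats::rgamma(m, 4, scale = 18),
                 30, 149)
  nm <- sum(comp == "mono")
  if (nm) out[comp == "mono"] <-
      draw_trunc(nm, function(m) stats::rnorm(m, 200, 35), 150, 290)
  nd <- sum(comp == "di")
  if (nd) out[comp == "di"] <-
      draw_trunc(nd, function(m) stats::rnorm(m, 380, 45), 291, 700)
  round(out)
}

# Background fragments: uniform over the nuclear genome, rejection-
# sampled so the fragment interval overlaps no planted peak.
sample_background_fragments <- function(sizes, chrom_lengths, peaks_gr,
                                        max_tries = 100L) {
  n <- length(sizes)
  chroms <- names(chrom_lengths)
  probs <- chrom_lengths / sum(chrom_lengths)
  chrom <- character(n); start <- numeric(n)
  todo <- seq_len(n)
  for (try in seq_len(max_tries)) {
    ci <- sample.int(length(chroms), length(todo), replace = TRUE,
                     prob = probs)
    st <- floor(stats::runif(length(todo)) *
                  (chrom_lengths[ci] - sizes[todo]))
    gr <- GenomicRanges::GRanges(chroms[ci],
                                 IRanges::IRanges(st + 1, st + sizes[todo]))
    ok <- !IRanges::overlapsAny(gr, peaks_gr)
    chrom[todo[ok]] <- chroms[ci][ok]
    start[todo[ok]] <- st[ok]
    todo <- todo[!ok]
    if (!length(todo)) break
  }
  if (length(todo))
    stop("failed to place ", length(todo),
         " background fragment(s) clear of peaks")
  data.frame(chrom = chrom, start = start)
}

#' Generate a panel of condition-specific libraries
#'
#' One library per experimental condition, sharing the annotation.
#' Each condition may scale the sampling weight of factor-annotated
#' peak classes (emulating, e.g., a buffer that under-covers CTCF
#' sites), enabling end-to-end tests of missing-peak enrichment and
#' FRiP-TF clustering signal.
#'
#' @param cfg A [generator_config()].
#' @param ann A [generate_annotation()] result.
#' @param conditions Named list; each element a list of overrides for
#'   [generate_library()] (`class_multipliers`, `frip`,
#'   `depth_fragments`, `mito_fraction`, `tss_strength`).
#' @return Named list of [fragment_library()]s.
#' @export
generate_condition_panel <- function(cfg, ann, conditions) {
  stopifnot(length(conditions) >= 2, !is.null(names(conditions)))
  out <- lapply(names(conditions), function(lab) {
    spec <- conditions[[lab]]
    do.call(generate_library, c(
      list(cfg = cfg, ann = ann, seed = derive_seed(cfg$seed, "panel", lab)),
      spec[intersect(names(spec),
                     c("class_multipliers", "frip", "depth_fragments",
                       "mito_fraction", "tss_strength", "complexity"))]))
  })
  names(out) <- names(conditions)
  out
}

#' Write annotation artifacts as standard files
#'
#' Emits the planted peaks (narrowPeak), the TSS reference as a
#' minimal GTF of single-transcript genes, the segmentation (BED4) and
#' one narrowPeak per ChIP factor, so file-based pipelines can run on
#' generated fixtures end to end.
#'
#' @param ann A [generate_annotation()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of paths, invisibly.
#' @export
write_annotation <- function(ann, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(peaks = file.path(dir, "peaks.narrowPeak"),
             tss = file.path(dir, "tss.gtf"),
             segments = file.path(dir, "segments.bed"))
  write_narrowpeak(ann$peaks, paths["peaks"])
  write_tss_gtf(ann$tss, ann$layout, paths["tss"])
  write_peaks(ann$segments, paths["segments"])
  for (f in names(ann$chip)) {
    p <- file.path(dir, paste0("chip_", f, ".narrowPeak"))
    write_narrowpeak(ann$chip[[f]], p)
    paths[paste0("chip_", f)] <- p
  }
  invisible(paths)
}

# Minimal GTF (one protein_coding transcript per TSS) whose most
# upstream base reproduces each reference site.
write_tss_gtf <- function(tss, layout, path, tx_len = 1000L) {
  n <- nrow(tss)
  if (n == 0) { writeLines(character(0), path); return(invisible(path)) }
  L <- layout$seqlengths[tss$chrom]
  start1 <- ifelse(tss$strand == "+", tss$pos + 1,
                   pmax(1, tss$pos + 1 - tx_len + 1))
  end1 <- ifelse(tss$strand == "+", pmin(L, tss$pos + tx_len), tss$pos + 1)
  attrs <- sprintf(paste0('gene_id "G%d"; transcript_id "T%d"; ',
                          'gene_type "protein_coding"; ',
                          'transcript_type "protein_coding";'),
                   seq_len(n), seq_len(n))
  lines <- sprintf("%s\tatacqc\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                   tss$chrom, as.integer(start1), as.integer(end1),
                   tss$strand, attrs)
  writeLines(lines, path)
  invisible(path)
}
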