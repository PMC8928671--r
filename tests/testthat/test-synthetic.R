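cfg_small <- generator_config(seed = 101, n_peaks = 120,
                              depth_fragments = 20000,
                              chrom_lengths = c(chr1 = 2e6, chr2 = 2e6))

test_that("planted annotation satisfies its structural invariants", {
  ann <- generate_annotation(cfg_small)
  pk <- ann$peaks
  expect_equal(nrow(pk), 120)
  expect_equal(nrow(merge_intervals(pk)), 120)   # disjoint
  expect_true(all(pk$end <= ann$layout$seqlengths[pk$chrom]))
  expect_equal(sum(pk$weight), 1)
  # every planted TSS sits inside its flagged peak
  for (i in seq_len(nrow(ann$tss))) {
    t <- ann$tss[i, ]
    expect_true(any(pk$chrom == t$chrom & pk$start <= t$pos &
                      t$pos < pk$end))
  }
  expect_equal(nrow(ann$tss), round(cfg_small$tss_fraction * 120))
  # ChIP sets exist per factor and decoys avoid accessibility peaks
  expect_named(ann$chip, cfg_small$factor_names)
})

test_that("segmentation covers every nuclear base exactly once", {
  ann <- generate_annotation(cfg_small)
  seg <- ann$segments
  for (chr in names(cfg_small$chrom_lengths)) {
    s <- seg[seg$chrom == chr, ]
    cov <- IRanges::coverage(IRanges::IRanges(s$start + 1, s$end),
                             width = cfg_small$chrom_lengths[[chr]])
    expect_equal(unique(S4Vectors::runValue(cov)), 1L)
  }
  expect_setequal(unique(seg$name),
                  c("TSS", "E", "WE", "CTCF", "R", "T", "PF"))
})

test_that("impossible peak requests and empty TSS configs behave", {
  too_many <- generator_config(seed = 1, n_peaks = 5000,
                               chrom_lengths = c(chr1 = 1e6))
  expect_error(generate_annotation(too_many), "capacity")
  no_tss <- generator_config(seed = 1, tss_fraction = 0)
  expect_equal(nrow(generate_annotation(no_tss)$tss), 0)
})

test_that("generated libraries recover their generating parameters", {
  cfg <- generator_config(seed = 61, depth_fragments = 50000, frip = 0.8,
                          mito_fraction = 0.25, complexity = Inf)
  ann <- generate_annotation(cfg)
  lib <- generate_library(cfg, ann)
  # aggregate FRiP within binomial sampling error of the dial
  expect_equal(frip(lib, ann$peaks), 0.8, tolerance = 0.01)
  # %mito within binomial error (sd ~ 0.19pp at this depth)
  expect_equal(pct_mito(lib), 25, tolerance = 0.04)
  # all records valid instances: constructor re-validates
  relib <- fragment_library(lib$chrom, lib$start, lib$end,
                            layout = ann$layout)
  expect_equal(n_fragments(relib), 50000)
})

test_that("true pool size is recovered through the saturation model", {
  cfg <- generator_config(seed = 71, depth_fragments = 20000,
                          mito_fraction = 0, complexity = 10000)
  ann <- generate_annotation(cfg)
  lib <- mark_duplicates(generate_library(cfg, ann))
  est <- estimate_complexity(n_fragments(lib), unique_fragments(lib))
  expect_equal(est, 10000, tolerance = 0.1)
})

test_that("sub-nucleosomal score tracks the mixture weight ratio", {
  ann <- generate_annotation(cfg_small)
  hi <- generate_library(
    generator_config(seed = 5, depth_fragments = 20000,
                     size_weights = c(sub = 0.75, mono = 0.18, di = 0.07)),
    ann)
  lo <- generate_library(
    generator_config(seed = 5, depth_fragments = 20000,
                     size_weights = c(sub = 0.30, mono = 0.55, di = 0.15)),
    ann)
  expect_gt(subnucleosomal_score(hi), subnucleosomal_score(lo))
})

test_that("generation is deterministic in the seed", {
  ann <- generate_annotation(cfg_small)
  a <- generate_library(cfg_small, ann)
  b <- generate_library(cfg_small, ann)
  expect_identical(a$start, b$start)
  expect_identical(a$chrom, b$chrom)
  d <- generate_library(cfg_small, ann, seed = 999)
  expect_false(identical(a$start, d$start))
  # full annotation regeneration is byte-identical too
  ann2 <- generate_annotation(cfg_small)
  expect_identical(ann$peaks$start, ann2$peaks$start)
  expect_identical(ann$tss$pos, ann2$tss$pos)
})

test_that("condition panels share annotation and apply class effects", {
  cfg <- generator_config(seed = 81, depth_fragments = 15000,
                          mito_fraction = 0, complexity = Inf)
  ann <- generate_annotation(cfg)
  same <- list(a = list(), b = list(), c = list())
  panel <- generate_condition_panel(cfg, ann, same)
  expect_named(panel, c("a", "b", "c"))
  # near-identical protocols: FRiP-TF rows nearly constant, MAD ~ 0
  cols <- vapply(panel, function(l)
    frip_chip_tf(l, ann$chip)$frip_tf, numeric(length(ann$chip)))
  s <- summarize_matrix(cols)
  expect_lt(max(s$mad), 0.01)
  # a CTCF-depleted condition shifts reads away from CTCF peaks
  biased <- generate_condition_panel(
    cfg, ann, list(ref = list(),
                   dep = list(class_multipliers = c(CTCF = 0.05))))
  tf <- vapply(biased, function(l)
    frip_chip_tf(l, ann$chip)$frip_tf, numeric(length(ann$chip)))
  expect_lt(tf["CTCF", "dep"], 0.5 * tf["CTCF", "ref"])
  # regeneration with the same seeds is byte-identical
  panel2 <- generate_condition_panel(cfg, ann, same)
  expect_identical(panel$a$start, panel2$a$start)
})

test_that("annotation artifacts round-trip through standard files", {
  ann <- generate_annotation(cfg_small)
  dir <- withr::local_tempdir()
  paths <- write_annotation(ann, dir)
  pk <- read_peaks(paths[["peaks"]])
  expect_equal(pk$start, ann$peaks$start)
  tss <- build_tss_reference(paths[["tss"]])
  expect_equal(tss$pos, ann$tss$pos)
  expect_equal(tss$strand, ann$tss$strand)
  seg <- read_peaks(paths[["segments"]])
  expect_equal(nrow(seg), nrow(ann$segments))
})
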