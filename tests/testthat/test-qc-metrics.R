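test_that("FRiP counts mate read intervals against merged peaks", {
  # peak [0, 927): only the left mate of fragment 1 overlaps (by 1 base)
  lib <- toy_lib(data.frame(chrom = c("chr1", "chr1"),
                            start = c(926, 5000), end = c(1002, 5200)))
  peaks <- peak_set("chr1", 0, 927)
  expect_equal(frip(lib, peaks), 0.25)
  # all-pairs interval oracle over the four mates
  mates <- rbind(mate_intervals(926, 1002, 75),
                 mate_intervals(5000, 5200, 75))
  hits <- apply(mates, 1, function(m) m[1] < 927 && 0 < m[2])
  expect_equal(sum(hits) / 4, 0.25)

  inside <- toy_lib(data.frame(chrom = "chr1", start = 100, end = 300))
  expect_equal(frip(inside, peak_set("chr1", 0, 1000)), 1.0)
  expect_equal(frip(inside, peak_set()), 0.0)
})

test_that("fragment-level FRiP counts whole inserts", {
  # fragment spans the peak but neither 75 bp mate touches it
  lib <- toy_lib(data.frame(chrom = c("chr1", "chr1"),
                            start = c(900, 5000), end = c(1300, 5100)))
  peaks <- peak_set("chr1", 1000, 1100)
  expect_equal(frip(lib, peaks, by = "read"), 0)
  expect_equal(frip(lib, peaks, by = "fragment"), 0.5)
})

test_that("FRiP is undefined without deduplicated nuclear reads", {
  mito_only <- toy_lib(data.frame(chrom = "chrM", start = 10, end = 200))
  expect_error(frip(mito_only, peak_set("chr1", 0, 100)),
               class = "atacqc_undefined_metric")
})

test_that("TSS enrichment is 1 under uniform coverage", {
  # fragments of insert 150 with 75 bp mates tile the chromosome at depth 1
  starts <- seq(0, 1e5 - 150, by = 150)
  lib <- toy_lib(data.frame(chrom = "chr1", start = starts,
                            end = starts + 150))
  tss <- tss_reference("chr1", 50000, "+")
  expect_equal(tss_enrichment(lib, tss), 1.0)
})

test_that("TSS enrichment recovers a constructed 10-fold upstream stack", {
  starts <- seq(0, 1e5 - 200, by = 200)
  tile <- data.frame(chrom = "chr1", start = starts, end = starts + 200)
  # nine distinct fragments whose right mate covers exactly [2800, 3000)
  extra <- data.frame(chrom = "chr1", start = 2600 - (0:8), end = 3000)
  lib <- fragment_library(c(tile$chrom, extra$chrom),
                          c(tile$start, extra$start),
                          c(tile$end, extra$end),
                          layout = toy_layout(),
                          readlen = c(rep(100, nrow(tile)), rep(200, 9)))
  tss <- tss_reference("chr1", 3000, "+")
  expect_equal(tss_enrichment(lib, tss), 10.0)
  # per-base oracle: brute-force coverage over the window
  spans <- as.data.frame(read_spans(nuclear(dedup(lib))))
  depth <- numeric(4000)
  for (i in seq_len(nrow(spans))) {
    lo <- max(spans$start[i], 1001); hi <- min(spans$end[i], 5000)
    if (lo <= hi) {
      idx <- (lo - 1000):(hi - 1000)
      depth[idx] <- depth[idx] + 1
    }
  }
  flank <- mean(depth[c(1:100, 3901:4000)])
  expect_equal(max(depth[1801:2000] / flank), 10.0)
})

test_that("TSS enrichment is strand symmetric", {
  set.seed(31)
  df <- random_intervals(400, max_pos = 90000, max_len = 300)
  df$end <- pmin(df$end + 100, 1e6)
  lib <- toy_lib(df)
  tss <- tss_reference("chr1", c(20000, 40000, 60000), c("+", "-", "+"))
  a <- tss_enrichment(lib, tss)
  b <- tss_enrichment(mirror_lib(lib), mirror_tss(tss, toy_layout()))
  expect_equal(a, b)
})

test_that("TSS enrichment with empty flanks is an explicit error", {
  lib <- toy_lib(data.frame(chrom = "chr1", start = 500000, end = 500200))
  tss <- tss_reference("chr1", 1e4, "+")
  expect_error(tss_enrichment(lib, tss),
               class = "atacqc_undefined_metric")
})

test_that("sub-nucleosomal score splits the histogram at 150 bp", {
  h <- structure(c(50L, 25L), names = c("100", "200"),
                 class = "insert_size_histogram")
  expect_equal(subnucleosomal_score(h), 2.0)
  boundary <- structure(c(7L, 7L), names = c("149", "150"),
                        class = "insert_size_histogram")
  expect_equal(subnucleosomal_score(boundary), 1.0)
  only_large <- structure(5L, names = "200",
                          class = "insert_size_histogram")
  expect_error(subnucleosomal_score(only_large),
               class = "atacqc_undefined_metric")
  only_small <- structure(5L, names = "80",
                          class = "insert_size_histogram")
  expect_error(subnucleosomal_score(only_small),
               class = "atacqc_undefined_metric")
})

test_that("sub-nucleosomal score equals an exhaustive histogram scan", {
  set.seed(5)
  for (rep in 1:10) {
    sizes <- c(round(rnorm(200, 80, 20)), round(rnorm(120, 200, 25)),
               round(rnorm(40, 380, 35)))
    sizes <- sizes[sizes >= 20]
    tab <- table(sizes)
    h <- structure(as.integer(tab), names = names(tab),
                   class = "insert_size_histogram")
    best_sub <- 0; best_nuc <- 0
    for (i in seq_along(h)) {
      s <- as.numeric(names(h)[i])
      if (s < 150) best_sub <- max(best_sub, h[[i]])
      else best_nuc <- max(best_nuc, h[[i]])
    }
    expect_equal(subnucleosomal_score(h), best_sub / best_nuc)
  }
})

test_that("%mito is computed before duplicate removal", {
  all_mito <- toy_lib(data.frame(chrom = "chrM", start = 1:4 * 10,
                                 end = 1:4 * 10 + 100))
  expect_equal(pct_mito(all_mito), 100)
  one_of_four <- toy_lib(data.frame(
    chrom = c("chrM", "chr1", "chr1", "chr2"),
    start = c(10, 100, 300, 500), end = c(200, 250, 450, 700)))
  expect_equal(pct_mito(one_of_four), 25)
  # two duplicate mito fragments + two distinct nuclear: duplicates count
  dup_mito <- toy_lib(data.frame(chrom = c("chrM", "chrM", "chr1", "chr2"),
                                 start = c(10, 10, 100, 300),
                                 end = c(200, 200, 250, 500)))
  expect_equal(pct_mito(mark_duplicates(dup_mito)), 50)
})

test_that("complexity estimate solves the Lander-Waterman saturation", {
  expect_identical(estimate_complexity(100, 100), Inf)
  x1 <- estimate_complexity(100, 50)
  expect_equal(x1, bisect_complexity(100, 50), tolerance = 1e-9)
  expect_equal(x1, 62.7, tolerance = 0.01)
  x2 <- estimate_complexity(2, 1)
  expect_equal(x2, bisect_complexity(2, 1), tolerance = 1e-9)
  expect_equal(x2, 1.26, tolerance = 0.01)
  expect_error(estimate_complexity(10, 11), "exceed")
})

test_that("complexity estimate is monotone in the unique count", {
  uniques <- seq(100, 990, by = 89)
  est <- vapply(uniques, function(u) estimate_complexity(1000, u), 0)
  expect_true(all(diff(est) > 0))
  expect_true(all(est >= uniques))
})

test_that("qc_report aggregates metrics and flags undefined ones", {
  cfg <- generator_config(seed = 3, depth_fragments = 20000,
                          mito_fraction = 0.25, complexity = Inf)
  ann <- generate_annotation(cfg)
  lib <- generate_library(cfg, ann)
  rep <- qc_report(lib, ann$peaks, ann$tss)
  expect_equal(unname(rep$metrics["frip"]), cfg$frip, tolerance = 0.05)
  expect_equal(unname(rep$metrics["pct_mito"]), 25, tolerance = 0.08)
  expect_true(all(c("total_reads", "unique_fragments") %in%
                    names(rep$counts)))

  empty <- fragment_library(character(), numeric(), numeric(),
                            layout = toy_layout())
  er <- qc_report(empty, ann$peaks, ann$tss)
  expect_true(all(is.na(er$metrics)))
  expect_true(all(er$counts == 0))
})
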