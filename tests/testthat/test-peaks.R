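small_layout <- genome_layout(c(chr1 = 50000, chrM = 16571), mito = "chrM")

test_that("an empty library yields no peaks", {
  empty <- fragment_library(character(), numeric(), numeric(),
                            layout = small_layout)
  expect_equal(nrow(call_peaks(empty)), 0)
})

test_that("a read stack over scattered background yields exactly one peak", {
  layout <- genome_layout(c(chr1 = 1e6, chrM = 16571), mito = "chrM")
  stack <- data.frame(chrom = "chr1", start = 500000, end = 500150)
  bg_starts <- round(seq(1000, 990000, length.out = 100))
  bg <- data.frame(chrom = "chr1", start = bg_starts,
                   end = bg_starts + 150)
  df <- rbind(stack[rep(1, 2500), ], bg)
  lib <- fragment_library(df$chrom, df$start, df$end, layout = layout)
  peaks <- call_peaks(lib)
  expect_equal(nrow(peaks), 1)
  expect_true(peaks$start <= 500000 && peaks$end >= 500150)
  # survival-function oracle at the locus: the stack's pileup against the
  # local lambda must be astronomically unlikely under the Poisson model
  pile_center <- 5000             # all 5000 window centers within 100 bp
  lam_local <- max(5200 * 200 / 1e6, 5000 * 200 / 10000)
  expect_lt(ppois(pile_center - 1, lam_local, lower.tail = FALSE), 1e-300)
})

test_that("uniform reads at the genome-wide rate produce zero peaks", {
  starts <- seq(0, 49500, by = 500)
  lib <- fragment_library(rep("chr1", length(starts)), starts,
                          starts + 150, layout = small_layout)
  expect_equal(nrow(call_peaks(lib)), 0)
})

test_that("caller output matches a brute-force per-base recomputation", {
  set.seed(19)
  layout <- genome_layout(c(chr1 = 30000, chrM = 16571), mito = "chrM")
  starts <- c(sample.int(29000, 150),
              round(rnorm(60, 10000, 50)), round(rnorm(50, 21000, 60)))
  starts <- pmax(pmin(starts, 29000), 100)
  lib <- fragment_library(rep("chr1", length(starts)), starts,
                          starts + 120, layout = layout)
  got <- call_peaks(lib)

  # independent recomputation, base by base
  L <- 30000; extsize <- 200; half <- 100
  s5 <- c(starts, starts + 120 - 1) + 1   # 1-based 5' bases of both mates
  pile <- integer(L); lamn <- integer(L)
  for (s in s5) {
    w <- max(s - half, 1):min(s + half - 1, L)
    pile[w] <- pile[w] + 1L
    v <- max(s - 5000, 1):min(s + 5000 - 1, L)
    lamn[v] <- lamn[v] + 1L
  }
  lam <- pmax(lamn * extsize / 10000, length(s5) * extsize / L)
  p <- ppois(pile - 1, lam, lower.tail = FALSE)
  q <- p.adjust(p, method = "BH")
  sig <- which(q < 0.05)
  expected <- data.frame(start = numeric(), end = numeric())
  if (length(sig)) {
    brk <- which(diff(sig) > 31)
    seg_start <- sig[c(1, brk + 1)]; seg_end <- sig[c(brk, length(sig))]
    keep <- (seg_end - seg_start + 1) >= 200
    expected <- data.frame(start = seg_start[keep] - 1,
                           end = seg_end[keep])
  }
  expect_equal(got$start, expected$start)
  expect_equal(got$end, expected$end)
  # summits sit at the pileup maximum of each region
  for (i in seq_len(nrow(got))) {
    region <- (got$start[i] + 1):got$end[i]
    expect_equal(pile[got$start[i] + 1 + got$summit[i]],
                 max(pile[region]))
  }
})

test_that("called peaks are disjoint and at least min_length wide", {
  cfg <- generator_config(seed = 23, depth_fragments = 30000)
  ann <- generate_annotation(cfg)
  peaks <- call_peaks(dedup(generate_library(cfg, ann)))
  expect_true(all(peaks$end - peaks$start >= 200))
  m <- merge_intervals(peaks)
  expect_equal(nrow(m), nrow(peaks))
})

test_that("planted peak bases are recovered at depth", {
  cfg <- generator_config(seed = 29, depth_fragments = 100000, frip = 0.5,
                          mito_fraction = 0, complexity = Inf)
  ann <- generate_annotation(cfg)
  lib <- generate_library(cfg, ann)
  expect_gte(2 * n_fragments(lib), 200000)
  peaks <- call_peaks(lib)
  expect_gte(planted_base_recovery(ann$peaks, peaks), 0.9)
})

test_that("subsampling is seeded, order-stable and pair-preserving", {
  df <- random_intervals(50, max_pos = 5000, chroms = c("chr1", "chr2"))
  lib <- toy_lib(df)
  all <- subsample_library(lib, 100, seed = 1)
  expect_equal(all$start, lib$start)
  none <- subsample_library(lib, 0, seed = 1)
  expect_equal(n_fragments(none), 0)
  a <- subsample_library(lib, 40, seed = 9)
  b <- subsample_library(lib, 40, seed = 9)
  expect_identical(a$start, b$start)
  expect_equal(total_reads(a), 40)
  # order stability: sampled rows appear in original relative order
  expect_true(!is.unsorted(match(paste(a$chrom, a$start, a$end),
                                 paste(lib$chrom, lib$start, lib$end))))
  expect_error(subsample_library(lib, 39, seed = 1), "even")
  expect_error(subsample_library(lib, 200, seed = 1), "available")
})

test_that("condition table tracks reproducible and missing peaks", {
  shared <- peak_set("chr1", 1000, 1400)
  only2 <- peak_set("chr1", 5000, 5300)
  conds <- list(
    a = rbind(shared, only2), b = rbind(shared, only2), c = shared,
    d = peak_set("chr1", 9000, 9400))
  class(conds$a) <- class(conds$b) <- c("peak_set", "data.frame")
  tbl <- build_condition_table(conds)
  rep3 <- reproducible_peaks(tbl)
  expect_equal(nrow(rep3), 1)
  expect_equal(rep3$start, 1000)
  miss_d <- missing_peaks(tbl, "d")
  expect_equal(miss_d$start, 1000)        # seen in a, b, c but not d
  expect_equal(nrow(missing_peaks(tbl, "a")), 0)
  # the 2-condition peak is excluded from the reproducible background
  expect_false(5000 %in% rep3$start)
  expect_error(build_condition_table(conds[c(1, 1)]), "duplicate")
})

test_that("condition labels match a brute-force enumeration", {
  set.seed(13)
  for (rep in 1:10) {
    conds <- lapply(1:4, function(i) {
      df <- random_intervals(12, max_pos = 2000, max_len = 80)
      peak_set(df$chrom, df$start, df$end)
    })
    names(conds) <- paste0("c", 1:4)
    tbl <- build_condition_table(conds)
    for (i in seq_len(nrow(tbl))) {
      expected <- names(conds)[vapply(conds, function(ps)
        any(ps$start < tbl$end[i] & tbl$start[i] < ps$end), TRUE)]
      expect_setequal(tbl$labels[[i]], expected)
    }
  }
})

test_that("dedup/no-dedup comparison partitions the merged union", {
  a <- peak_set("chr1", c(100, 500), c(200, 700))
  same <- compare_dedup_nodedup(a, a)
  expect_equal(nrow(same$shared), 2)
  expect_equal(nrow(same$unique_a) + nrow(same$unique_b), 0)
  b <- peak_set("chr1", 1000, 1200)
  disj <- compare_dedup_nodedup(a, b)
  expect_equal(nrow(disj$shared), 0)
  expect_equal(nrow(disj$unique_a), 2)
  expect_equal(nrow(disj$unique_b), 1)

  set.seed(3)
  x <- random_intervals(20); y <- random_intervals(20)
  parts <- compare_dedup_nodedup(peak_set(x$chrom, x$start, x$end),
                                 peak_set(y$chrom, y$start, y$end))
  merged <- merge_oracle(rbind(x, y))
  in_a <- overlaps_oracle(merged, x); in_b <- overlaps_oracle(merged, y)
  expect_equal(nrow(parts$shared), sum(in_a & in_b))
  expect_equal(nrow(parts$unique_a), sum(in_a & !in_b))
  expect_equal(nrow(parts$unique_b), sum(in_b & !in_a))
})

test_that("count matrix equals a triple-loop overlap oracle", {
  peaks <- merge_intervals(peak_set("chr1", c(100, 1000, 4000),
                                    c(400, 1500, 4300)))
  libs <- list(
    s1 = toy_lib(data.frame(chrom = "chr1", start = c(150, 160, 1100),
                            end = c(350, 390, 1400))),
    s2 = toy_lib(data.frame(chrom = "chr1", start = c(9000, 9100),
                            end = c(9200, 9300))))
  m <- build_count_matrix(libs, peaks)
  expect_equal(dim(m), c(3, 2))
  oracle <- matrix(0, 3, 2)
  for (s in 1:2) {
    lib <- nuclear(dedup(libs[[s]]))
    for (f in seq_len(nrow(lib))) {
      mates <- mate_intervals(lib$start[f], lib$end[f], 75)
      for (r in 1:2) for (p in 1:3) {
        if (mates[r, 1] < peaks$end[p] && peaks$start[p] < mates[r, 2])
          oracle[p, s] <- oracle[p, s] + 1
      }
    }
  }
  expect_equal(unname(m), oracle)
  expect_equal(sum(m[, "s2"]), 0)
  # one sample entirely inside one peak
  solo <- list(x = toy_lib(data.frame(chrom = "chr1", start = 110,
                                      end = 300)))
  ms <- build_count_matrix(solo, peaks)
  expect_equal(as.numeric(ms), c(2, 0, 0))
  # column sums bounded by dedup nuclear read counts
  expect_true(all(colSums(m) <=
                    vapply(libs, function(l)
                      2 * n_fragments(nuclear(dedup(l))), 0)))
})
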