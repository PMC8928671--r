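# Shared fixtures and independent oracles. Oracles are deliberately
# naive (quadratic scans, exhaustive enumeration, bisection) and share
# no code with the package internals they check.

toy_layout <- function(len = 1e6, mito_len = 16571) {
  genome_layout(c(chr1 = len, chr2 = len, chrM = mito_len), mito = "chrM")
}

# Build a library from a compact spec: data.frame(chrom, start, end).
toy_lib <- function(df, layout = toy_layout(), readlen = 75) {
  fragment_library(df$chrom, df$start, df$end, layout = layout,
                   readlen = readlen)
}

random_intervals <- function(n, max_pos = 1000, max_len = 60,
                             chroms = "chr1") {
  start <- sample.int(max_pos, n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + len,
             stringsAsFactors = FALSE)
}

# O(n^2) interval merge: repeated pairwise fusion until fixpoint.
merge_oracle <- function(df) {
  rows <- split(df, seq_len(nrow(df)))
  repeat {
    fused <- FALSE
    for (i in seq_along(rows)) {
      if (fused) break
      for (j in seq_along(rows)) {
        if (i >= j) next
        a <- rows[[i]]; b <- rows[[j]]
        if (a$chrom == b$chrom && a$start < b$end && b$start < a$end) {
          rows[[i]] <- data.frame(chrom = a$chrom,
                                  start = min(a$start, b$start),
                                  end = max(a$end, b$end),
                                  stringsAsFactors = FALSE)
          rows[[j]] <- NULL
          fused <- TRUE
          break
        }
      }
    }
    if (!fused) break
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Naive per-query overlap test against a set of intervals (half-open).
overlaps_oracle <- function(q, s) {
  vapply(seq_len(nrow(q)), function(i) {
    any(s$chrom == q$chrom[i] & s$start < q$end[i] & q$start[i] < s$end)
  }, TRUE)
}

# Count distinct fragment coordinates without using duplicated().
unique_count_oracle <- function(df) {
  key <- paste(df$chrom, df$start, df$end)
  nrow(table(key))
}

# Bisection root of unique = X (1 - exp(-total/X)).
bisect_complexity <- function(total, unique, iters = 200) {
  f <- function(x) x * (1 - exp(-total / x)) - unique
  lo <- unique
  hi <- unique * 2
  while (f(hi) < 0) hi <- hi * 2
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Upper-tail hypergeometric by direct enumeration of the pmf.
hyper_tail_oracle <- function(k, K, B, n) {
  js <- k:min(n, K)
  if (k > min(n, K)) return(0)
  sum(stats::dhyper(js, K, B - K, n))
}

# Hand step-up Benjamini-Hochberg.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Mate read intervals of a fragment, the definition used throughout.
mate_intervals <- function(start, end, readlen) {
  rbind(c(start, min(start + readlen, end)),
        c(max(end - readlen, start), end))
}

# Mirror a library through the midpoint of each chromosome (coordinate
# x -> L - x), used for strand-symmetry checks.
mirror_lib <- function(lib) {
  layout <- attr(lib, "layout")
  L <- layout$seqlengths[lib$chrom]
  fragment_library(lib$chrom, L - lib$end, L - lib$start, layout = layout,
                   readlen = lib$readlen)
}

mirror_tss <- function(tss, layout) {
  L <- layout$seqlengths[tss$chrom]
  tss_reference(tss$chrom, L - 1 - tss$pos,
                ifelse(tss$strand == "+", "-", "+"))
}

# A condition table with exact (B, K, n, k) composition: intervals at
# isolated loci, labeled so that `missing` and `background` have known
# sizes, and a ChIP set overlapping a chosen subset.
make_counts_table <- function(B, n, k, K) {
  stopifnot(n <= B, k <= n, K - k <= B - n)
  start <- (seq_len(B) - 1) * 1000
  labels <- c(rep(list(c("a", "b", "d")), n),
              rep(list(c("a", "b", "c", "d")), B - n))
  tbl <- peak_set("chr1", start, start + 200, labels = labels)
  attr(tbl, "conditions") <- c("a", "b", "c", "d")
  class(tbl) <- c("condition_peak_table", class(tbl))
  chip_rows <- c(seq_len(k), n + seq_len(K - k))
  chip <- peak_set("chr1", start[chip_rows], start[chip_rows] + 200)
  list(tbl = tbl, chip = chip)
}

# Fraction of planted peak bases recovered by a set of called peaks.
planted_base_recovery <- function(planted, called) {
  tot <- sum(planted$end - planted$start)
  hit <- 0
  for (chr in unique(planted$chrom)) {
    p <- planted[planted$chrom == chr, ]
    c0 <- called[called$chrom == chr, ]
    if (!nrow(c0)) next
    hit <- hit + sum(IRanges::width(IRanges::intersect(
      IRanges::IRanges(p$start + 1, p$end),
      IRanges::IRanges(c0$start + 1, c0$end))))
  }
  hit / tot
}
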