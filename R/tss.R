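#' TSS reference construction
#'
#' Builds a strand-aware set of single-base transcription start sites
#' from a GTF annotation, following the filtering used by common
#' single-cell ATAC pipelines: the most upstream base of every
#' transcript (its start on the + strand, its last covered base on the
#' - strand), retaining only transcripts whose gene type AND transcript
#' type are both in a whitelist of coding/lncRNA/immune-receptor
#' biotypes, and excluding transcripts tagged `readthrough_transcript`
#' or `PAR`. Duplicated (chrom, position, strand) entries are collapsed.
#'
#' GTF coordinates (1-based inclusive) are converted to the package's
#' 0-based convention at this boundary. Both `gene_type`/`transcript_type`
#' (GENCODE) and `gene_biotype`/`transcript_biotype` (Ensembl) attribute
#' spellings are accepted. Attributes are parsed in-package because a
#' transcript may carry several `tag` attributes and all of them must be
#' inspected.
#'
#' @param path Path to a GTF file.
#' @param types Character vector of allowed gene/transcript types.
#' @return A `tss_reference`: data.frame with columns `chrom`, `pos`
#'   (0-based base), `strand`.
#' @export
build_tss_reference <- function(path, types = tss_type_whitelist()) {
  lines <- readLines(path)
  ln <- seq_along(lines)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lines <- lines[keep]; ln <- ln[keep]
  if (!length(lines)) return(tss_reference())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9))
    stop("malformed GTF record (fewer than 9 fields) at line ",
         ln[which(nf < 9)[1L]])
  feat <- vapply(fields, `[[`, "", 3L)
  tx <- which(feat == "transcript")
  if (!length(tx)) return(tss_reference())

  out <- vector("list", length(tx))
  for (i in seq_along(tx)) {
    f <- fields[[tx[i]]]
    attrs <- parse_gtf_attributes(f[9], ln[tx[i]])
    gt <- attrs$value[attrs$key %in% c("gene_type", "gene_biotype")]
    tt <- attrs$value[attrs$key %in% c("transcript_type",
                                       "transcript_biotype")]
    tags <- attrs$value[attrs$key == "tag"]
    if (!length(gt) || !length(tt)) next
    if (!(gt[1] %in% types) || !(tt[1] %in% types)) next
    if (any(tags %in% c("readthrough_transcript", "PAR"))) next
    strand <- f[7]
    if (!strand %in% c("+", "-"))
      stop("transcript without +/- strand at line ", ln[tx[i]])
    start1 <- as.numeric(f[4]); end1 <- as.numeric(f[5])
    pos0 <- if (strand == "+") start1 - 1 else end1 - 1
    out[[i]] <- data.frame(chrom = f[1], pos = pos0, strand = strand,
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) return(tss_reference())
  df <- do.call(rbind, out)
  df <- unique(df)
  df <- df[order(df$chrom, df$pos, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("tss_reference", "data.frame")
  df
}

# key "value" pairs separated by semicolons; errors carry the file line.
parse_gtf_attributes <- function(attr_string, line) {
  m <- gregexpr('([A-Za-z_][A-Za-z0-9_]*)\\s+"([^"]*)"', attr_string)
  hits <- regmatches(attr_string, m)[[1]]
  if (!length(hits))
    stop("malformed GTF attribute column at line ", line)
  key <- sub('^([A-Za-z_][A-Za-z0-9_]*)\\s+".*$', "\\1", hits)
  value <- sub('^[A-Za-z_][A-Za-z0-9_]*\\s+"([^"]*)"$', "\\1", hits)
  list(key = key, value = value)
}

#' @rdname build_tss_reference
#' @export
tss_type_whitelist <- function() {
  c("protein_coding", "lncRNA",
    "IG_C_gene", "IG_D_gene", "IG_J_gene", "IG_LV_gene", "IG_V_gene",
    "IG_V_pseudogene", "IG_J_pseudogene", "IG_C_pseudogene",
    "TR_C_gene", "TR_D_gene", "TR_J_gene", "TR_V_gene",
    "TR_V_pseudogene", "TR_J_pseudogene")
}

#' Construct a TSS reference directly
#'
#' @param chrom Chromosome names.
#' @param pos 0-based TSS coordinates.
#' @param strand `"+"` or `"-"` per entry.
#' @return A `tss_reference` data.frame.
#' @export
tss_reference <- function(chrom = character(), pos = numeric(),
                          strand = character()) {
  n <- max(length(chrom), length(pos))
  if (n > 0) {
    chrom <- rep_len(as.character(chrom), n)
    strand <- rep_len(as.character(strand), n)
  }
  stopifnot(length(pos) == length(chrom), length(strand) == length(chrom))
  if (length(strand) && !all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  df <- unique(data.frame(chrom = as.character(chrom),
                          pos = as.numeric(pos),
                          strand = as.character(strand),
                          stringsAsFactors = FALSE))
  rownames(df) <- NULL
  class(df) <- c("tss_reference", "data.frame")
  df
}

#' @export
print.tss_reference <- function(x, ...) {
  cat("tss_reference:", nrow(x), "sites (",
      sum(x$strand == "+"), "+ /", sum(x$strand == "-"), "- )\n")
  invisible(x)
}
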