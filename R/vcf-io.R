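#' Read a multi-sample VCF into a genotype table
#'
#' Parses GT fields of a VCF v4.2 file (via vcfR) into alt-allele dosages.
#' Only biallelic records are accepted by default; `./.` and half-missing
#' calls become `NA`. Phased separators (`|`) are treated like `/`.
#'
#' @param path Path to a (possibly gzipped) VCF file.
#' @param biallelic_only Error on multi-allelic records (`TRUE`, default) or
#'   silently drop them.
#' @return A [genotype_table()].
#' @seealso [write_vcf()]
#' @export
read_vcf <- function(path, biallelic_only = TRUE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  if (any(multi)) {
    if (biallelic_only) {
      abort(sprintf("%d multi-allelic record(s); biallelic VCF required", sum(multi)))
    }
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix), dimnames = list(NULL, names(gt)))
  gt <- gsub("|", "/", gt, fixed = TRUE)
  dose <- matrix(NA_integer_, nrow = ncol(gt), ncol = nrow(gt))
  lookup <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  codes <- lookup[gt]
  dose[] <- t(matrix(codes, nrow = nrow(gt)))
  variants <- tibble(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"],
    alt = unname(fix[, "ALT"])
  )
  genotype_table(variants, dose, samples = colnames(gt))
}

#' Write a genotype table as a GT-only VCF v4.2
#'
#' Emits a plain-text, deterministic VCF (no compression) so fixed-seed
#' simulations round-trip byte-for-byte. Dosage 1 is written as `0/1`,
#' missing as `./.`.
#'
#' @param x A [genotype_table()].
#' @param path Output file path.
#' @param contig_lengths Optional named vector of chromosome lengths for
#'   `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path, contig_lengths = NULL) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=feralscan",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
  )
  if (!is.null(contig_lengths)) {
    header <- c(header, sprintf(
      "##contig=<ID=%s,length=%d>",
      names(contig_lengths), as.integer(contig_lengths)
    ))
  }
  header <- c(header, paste(
    c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
      x$samples),
    collapse = "\t"
  ))
  gt_chr <- c("0/0", "0/1", "1/1")
  g <- x$geno
  codes <- matrix("./.", nrow = nrow(g), ncol = ncol(g))
  ok <- !is.na(g)
  codes[ok] <- gt_chr[g[ok] + 1L]
  body <- vapply(seq_len(nrow(x$variants)), function(j) {
    paste(c(
      x$variants$chrom[j], x$variants$pos[j], ".",
      x$variants$ref[j], x$variants$alt[j], ".", "PASS", ".", "GT",
      codes[, j]
    ), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
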