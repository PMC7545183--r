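#' Construct a genotype table
#'
#' The central genotype container: biallelic variants with per-sample
#' alt-allele dosages. Dosages are coded 0/1/2 with `NA` for missing; wheat
#' accessions are treated as near-homozygous inbred lines, so heterozygous
#' calls are rare but representable.
#'
#' @param variants Data frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, one row per biallelic site, positions strictly increasing within
#'   each chromosome.
#' @param geno Integer matrix, samples x variants, values in `{0, 1, 2, NA}`.
#' @param samples Character vector of sample ids (defaults to
#'   `rownames(geno)`).
#' @return An object of class `genotype_table`.
#' @examples
#' gt <- genotype_table(
#'   tibble::tibble(chrom = "chr1A", pos = c(100, 200), ref = "A", alt = "T"),
#'   matrix(c(0L, 2L, 1L, NA), nrow = 2, dimnames = list(c("s1", "s2"), NULL))
#' )
#' gt
#' @export
genotype_table <- function(variants, geno, samples = rownames(geno)) {
  variants <- as_tibble(variants)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(variants)))
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(variants) != ncol(geno)) {
    abort("`geno` must have one column per variant")
  }
  if (is.null(samples)) samples <- paste0("sample", seq_len(nrow(geno)))
  stopifnot(length(samples) == nrow(geno), !anyDuplicated(samples))
  bad <- geno[!is.na(geno)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    abort("dosages must lie in {0, 1, 2, NA}")
  }
  ooo <- variants |>
    group_by(.data$chrom) |>
    summarise(sorted = !is.unsorted(.data$pos, strictly = TRUE))
  if (!all(ooo$sorted)) {
    abort("positions must be strictly increasing within each chromosome")
  }
  rownames(geno) <- samples
  structure(
    list(variants = variants, geno = geno, samples = samples),
    class = "genotype_table"
  )
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(
    "<genotype_table> ", length(x$samples), " samples x ",
    nrow(x$variants), " biallelic variants on ",
    length(unique(x$variants$chrom)), " chromosome(s)\n",
    sep = ""
  )
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missing dosage fraction: %.3f\n", miss))
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) c(length(x$samples), nrow(x$variants))

#' Number of samples / variants in a genotype table
#' @param x A [genotype_table()].
#' @return Integer scalar.
#' @export
n_samples <- function(x) length(x$samples)

#' @rdname n_samples
#' @export
n_variants <- function(x) nrow(x$variants)

#' Subset a genotype table
#'
#' @param x A [genotype_table()].
#' @param i Sample index (logical, integer, or character ids).
#' @param j Variant index (logical or integer).
#' @param ... Unused.
#' @return A [genotype_table()].
#' @export
`[.genotype_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$samples)
  if (missing(j)) j <- seq_len(nrow(x$variants))
  if (is.character(i)) i <- match(i, x$samples)
  genotype_table(
    x$variants[j, , drop = FALSE],
    x$geno[i, j, drop = FALSE],
    x$samples[i]
  )
}

#' @exportS3Method tibble::as_tibble
as_tibble.genotype_table <- function(x, ...) {
  long <- as_tibble(x$variants)
  long$site_index <- seq_len(nrow(long))
  geno <- as_tibble(t(x$geno), .name_repair = "minimal")
  names(geno) <- x$samples
  dplyr::bind_cols(long, geno) |>
    tidyr::pivot_longer(dplyr::all_of(x$samples),
      names_to = "sample", values_to = "dosage"
    )
}

#' Per-site alt-allele frequency and missingness
#'
#' @param x A [genotype_table()].
#' @return A tibble with `chrom`, `pos`, `af` (alt allele frequency over
#'   called alleles), `maf`, `missing` (fraction of missing genotypes),
#'   `n_called`.
#' @export
site_summary <- function(x) {
  g <- x$geno
  n_called <- colSums(!is.na(g))
  ac <- colSums(g, na.rm = TRUE)
  af <- ifelse(n_called > 0, ac / (2 * n_called), NA_real_)
  tibble(
    chrom = x$variants$chrom, pos = x$variants$pos,
    af = af, maf = pmin(af, 1 - af),
    missing = colSums(is.na(g)) / length(x$samples),
    n_called = as.integer(n_called)
  )
}
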