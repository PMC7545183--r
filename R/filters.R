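#' Filter variants on minor allele frequency and missingness
#'
#' Applies the standard cohort site filters: sites are kept when
#' `MAF >= maf_min` and the missing-genotype fraction is below
#' `missing_max`. Two strictness conventions coexist in practice — the
#' discovery-set rule keeps missingness `<= 40%` while the association-set
#' rule keeps missingness strictly `< 30%` — so the comparison is a knob.
#'
#' Filtering is idempotent: applying the same filter twice equals once.
#'
#' @param x A [genotype_table()].
#' @param maf_min Minimum minor allele frequency (kept when `MAF >= maf_min`);
#'   in `[0, 0.5]`.
#' @param missing_max Maximum missing fraction, in `[0, 1]`.
#' @param missing_strict If `TRUE` (default) keep sites with missingness
#'   strictly `< missing_max`; if `FALSE` keep `<= missing_max`.
#' @return A filtered [genotype_table()]. An empty result warns rather than
#'   errors.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_sites = 50, seed = 1))
#' apply_variant_filters(cohort$genotypes, maf_min = 0.05, missing_max = 0.3)
#' @export
apply_variant_filters <- function(x, maf_min = 0.05, missing_max = 0.3,
                                  missing_strict = TRUE) {
  if (maf_min < 0 || maf_min > 0.5) abort("`maf_min` must be in [0, 0.5]")
  if (missing_max < 0 || missing_max > 1) abort("`missing_max` must be in [0, 1]")
  s <- site_summary(x)
  keep_maf <- !is.na(s$maf) & s$maf >= maf_min
  keep_miss <- if (missing_strict) s$missing < missing_max else s$missing <= missing_max
  keep <- keep_maf & keep_miss
  if (!any(keep)) warn("all sites removed by variant filters")
  x[, keep]
}

#' Prune variants in high linkage disequilibrium
#'
#' Greedy intra-chromosomal LD pruning: sites are visited left to right and a
#' site is dropped when its squared dosage correlation with any already-kept
#' site among the trailing `window_sites` kept sites reaches `r2_max`. The
#' earlier site always wins, so output is deterministic under a fixed input
#' order. r-squared is computed on dosages over pairwise-complete samples.
#'
#' @param x A [genotype_table()].
#' @param r2_max Prune when `r^2 >= r2_max`; in `(0, 1]`. Default 0.4.
#' @param window_sites Number of trailing kept sites compared against.
#' @return A pruned [genotype_table()].
#' @export
ld_prune <- function(x, r2_max = 0.4, window_sites = 50) {
  if (r2_max <= 0 || r2_max > 1) abort("`r2_max` must be in (0, 1]")
  keep <- logical(nrow(x$variants))
  for (ch in unique(x$variants$chrom)) {
    idx <- which(x$variants$chrom == ch)
    kept <- integer(0)
    for (j in idx) {
      cmp <- tail(kept, window_sites)
      ok <- TRUE
      for (k in cmp) {
        r2 <- .dosage_r2(x$geno[, j], x$geno[, k])
        if (!is.na(r2) && r2 >= r2_max) {
          ok <- FALSE
          break
        }
      }
      if (ok) {
        kept <- c(kept, j)
        keep[j] <- TRUE
      }
    }
  }
  x[, keep]
}

# squared Pearson correlation on pairwise-complete dosages
.dosage_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2) return(NA_real_)
  ca <- a[ok]
  cb <- b[ok]
  if (sd(ca) == 0 || sd(cb) == 0) return(NA_real_)
  cor(ca, cb)^2
}
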