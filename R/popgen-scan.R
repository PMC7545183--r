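# Weir & Cockerham (1984) two-population variance components, vectorised
# over sites. geno: samples x sites dosage matrix; g1/g2: row indices.
# Returns per-site a (among-population), b (among-individual),
# c (within-individual) and a usable flag.
.fst_components_matrix <- function(geno, g1, g2) {
  comp_group <- function(rows) {
    g <- geno[rows, , drop = FALSE]
    n <- colSums(!is.na(g))
    p <- ifelse(n > 0, colSums(g, na.rm = TRUE) / (2 * n), NA_real_)
    h <- ifelse(n > 0, colSums(g == 1L, na.rm = TRUE) / n, NA_real_)
    list(n = n, p = p, h = h)
  }
  c1 <- comp_group(g1)
  c2 <- comp_group(g2)
  n1 <- c1$n; n2 <- c2$n
  nbar <- (n1 + n2) / 2
  usable <- n1 >= 1 & n2 >= 1 & nbar > 1
  nc <- 2 * nbar - (n1^2 + n2^2) / (2 * nbar)
  pbar <- (n1 * c1$p + n2 * c2$p) / (2 * nbar)
  s2 <- (n1 * (c1$p - pbar)^2 + n2 * (c2$p - pbar)^2) / nbar
  hbar <- (n1 * c1$h + n2 * c2$h) / (2 * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 / 2 - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  poly <- usable & !is.na(pbar) & pbar > 0 & pbar < 1
  a[!poly] <- 0; b[!poly] <- 0; cc[!poly] <- 0
  a[!usable] <- NA_real_; b[!usable] <- NA_real_; cc[!usable] <- NA_real_
  list(a = a, b = b, c = cc, usable = poly)
}

.split_groups <- function(x, sample_groups) {
  sample_groups <- as_tibble(sample_groups)
  stopifnot(all(c("sample", "group") %in% names(sample_groups)))
  lev <- if (is.factor(sample_groups$group)) {
    levels(droplevels(sample_groups$group))
  } else {
    unique(sample_groups$group)
  }
  if (length(lev) != 2) abort("exactly two groups are required")
  g1 <- match(sample_groups$sample[sample_groups$group == lev[1]], x$samples)
  g2 <- match(sample_groups$sample[sample_groups$group == lev[2]], x$samples)
  if (anyNA(g1) || anyNA(g2)) abort("sample ids not found in genotype table")
  if (length(intersect(g1, g2))) abort("groups must be disjoint")
  if (!length(g1) || !length(g2)) abort("both groups must be nonempty")
  list(g1 = g1, g2 = g2, levels = lev)
}

#' Per-site Weir-Cockerham variance components
#'
#' Computes the Weir & Cockerham (1984) two-population components for one
#' biallelic site from diploid dosage vectors: `a` (among populations), `b`
#' (among individuals within populations), `c` (within individuals, driven
#' by observed heterozygosity). Per-site sample sizes come from non-missing
#' calls. Sites monomorphic across both groups return `(0, 0, 0)` with
#' `usable = FALSE`; sites callable in fewer than two groups return `NA`.
#'
#' @param dosages_group1,dosages_group2 Integer dosage vectors (0/1/2/NA),
#'   one element per individual.
#' @return A one-row tibble with `a`, `b`, `c`, `usable`, and the per-site
#'   ratio `fst = a / (a + b + c)` (NA when the denominator is 0).
#' @examples
#' site_fst_components(c(2L, 2L, 2L), c(0L, 0L, 0L)) # fixed difference
#' @export
site_fst_components <- function(dosages_group1, dosages_group2) {
  geno <- rbind(
    matrix(as.integer(dosages_group1), ncol = 1),
    matrix(as.integer(dosages_group2), ncol = 1)
  )
  k <- .fst_components_matrix(
    geno,
    seq_along(dosages_group1),
    length(dosages_group1) + seq_along(dosages_group2)
  )
  denom <- k$a + k$b + k$c
  tibble(
    a = k$a, b = k$b, c = k$c, usable = k$usable,
    fst = ifelse(!is.na(denom) & denom != 0, k$a / denom, NA_real_)
  )
}

#' Windowed Weir-Cockerham FST between two groups
#'
#' The windowed ("weighted") estimator is the ratio of sums over usable
#' polymorphic sites in each window, `sum(a) / sum(a + b + c)` — the form
#' reported by the standard VCF windowed-FST tools. Windows without usable
#' sites are `NA`. Negative values are reported, not clamped.
#'
#' @param x A [genotype_table()].
#' @param sample_groups Data frame with columns `sample` and `group`
#'   (exactly two group labels; the first label is population 1).
#' @param grid Window grid from [build_windows()].
#' @return A tibble: `chrom`, `start`, `end`, `window_id`, `n_sites`
#'   (usable polymorphic sites), `fst`.
#' @export
windowed_fst <- function(x, sample_groups, grid) {
  sp <- .split_groups(x, sample_groups)
  k <- .fst_components_matrix(x$geno, sp$g1, sp$g2)
  wid <- .window_of(grid, x$variants$chrom, x$variants$pos)
  use <- k$usable & !is.na(wid)
  num <- rowsum(k$a[use], wid[use])
  den <- rowsum((k$a + k$b + k$c)[use], wid[use])
  cnt <- rowsum(rep(1L, sum(use)), wid[use])
  out <- grid
  out$n_sites <- 0L
  out$fst <- NA_real_
  ridx <- match(as.integer(rownames(num)), grid$window_id)
  out$n_sites[ridx] <- as.integer(cnt)
  out$fst[ridx] <- ifelse(den != 0, num / den, NA_real_)
  as_tibble(out)
}

#' Windowed nucleotide diversity (pi)
#'
#' Per site, pairwise diversity is `x * (n - x) / choose(n, 2)` with `x` the
#' alt-allele count among `n` called alleles; window pi is the sum over
#' variant sites divided by the window width in bp (monomorphic sites
#' contribute zero; sites with fewer than two called alleles are skipped).
#'
#' @param x A [genotype_table()].
#' @param samples Character vector of sample ids forming the group.
#' @param grid Window grid from [build_windows()].
#' @return A tibble: `chrom`, `start`, `end`, `window_id`, `pi`.
#' @export
windowed_pi <- function(x, samples, grid) {
  rows <- match(samples, x$samples)
  if (anyNA(rows)) abort("sample ids not found in genotype table")
  if (!length(rows)) abort("group must be nonempty")
  g <- x$geno[rows, , drop = FALSE]
  n <- 2 * colSums(!is.na(g))
  ac <- colSums(g, na.rm = TRUE)
  persite <- ifelse(n >= 2, ac * (n - ac) / (n * (n - 1) / 2), 0)
  wid <- .window_of(grid, x$variants$chrom, x$variants$pos)
  use <- !is.na(wid)
  sums <- rowsum(persite[use], wid[use])
  out <- grid
  out$pi <- 0
  ridx <- match(as.integer(rownames(sums)), grid$window_id)
  out$pi[ridx] <- as.numeric(sums)
  out$pi <- out$pi / (out$end - out$start)
  as_tibble(out)
}

#' Diversity ratio between two groups
#'
#' The per-window ratio `pi_num / pi_den` used to flag diversity loss under
#' selection (for the de-domestication contrast: `pi_DO / pi_DE`). Windows
#' with zero denominator diversity are flagged undefined (`NA`).
#'
#' @param pi_num,pi_den Numeric vectors of per-window pi, aligned.
#' @return Numeric vector of ratios with `NA` where `pi_den == 0`.
#' @export
pi_ratio <- function(pi_num, pi_den) {
  stopifnot(length(pi_num) == length(pi_den))
  ifelse(!is.na(pi_den) & pi_den > 0, pi_num / pi_den, NA_real_)
}

#' Combined two-group window scan
#'
#' Convenience wrapper returning FST, per-group pi, and the pi ratio
#' (second group over first: with groups ordered (DE, DO) this is
#' `pi_DO / pi_DE`) on one grid.
#'
#' @inheritParams windowed_fst
#' @return A `window_track` tibble: `chrom`, `start`, `end`, `window_id`,
#'   `n_sites`, `fst`, `pi_1`, `pi_2`, `pi_ratio` (group labels kept in the
#'   `groups` attribute).
#' @export
scan_windows <- function(x, sample_groups, grid) {
  sp <- .split_groups(x, sample_groups)
  track <- windowed_fst(x, sample_groups, grid)
  track$pi_1 <- windowed_pi(x, x$samples[sp$g1], grid)$pi
  track$pi_2 <- windowed_pi(x, x$samples[sp$g2], grid)$pi
  track$pi_ratio <- pi_ratio(track$pi_2, track$pi_1)
  attr(track, "groups") <- sp$levels
  class(track) <- c("window_track", class(track))
  track
}

#' Call candidate regions from the top quantile per subgenome partition
#'
#' Thresholds are computed separately for the A&B subgenomes and the D
#' subgenome (wild-relative introgression inflates A/B divergence). Within
#' each partition the threshold is the k-th largest statistic with
#' `k = max(1, floor(quantile * n_windows))`; windows with the statistic
#' `>= threshold` are returned (ties may return more than k).
#'
#' @param track A window tibble (e.g. from [scan_windows()]).
#' @param stat Column name of the statistic (default `"fst"`).
#' @param quantile Top tail fraction (default 0.05).
#' @return A tibble of candidate windows with `partition` and `threshold`
#'   columns attached.
#' @export
candidate_regions <- function(track, stat = "fst", quantile = 0.05) {
  vals <- track[[stat]]
  part <- subgenome_partition(track$chrom)
  out <- list()
  for (p in setdiff(unique(part), "Un")) {
    v <- vals[part == p]
    v <- v[!is.na(v)]
    if (!length(v)) {
      warn(sprintf("partition %s has no non-missing windows", p))
      next
    }
    k <- max(1L, floor(quantile * length(v)))
    thr <- sort(v, decreasing = TRUE)[k]
    sel <- part == p & !is.na(vals) & vals >= thr
    hit <- track[sel, ]
    hit$partition <- p
    hit$threshold <- thr
    out[[p]] <- hit
  }
  bind_rows(out)
}

#' Label-shuffling permutation null for the windowed FST scan
#'
#' Shuffles group labels jointly over the whole cohort (samples, not
#' windows, are exchangeable), preserving group sizes exactly, recomputes
#' the genome-wide windowed FST for each replicate, and records the maximum
#' per subgenome partition. Comparing the observed top-quantile threshold
#' with these null maxima rules out population-structure artefacts.
#'
#' @inheritParams windowed_fst
#' @param n_perm Number of label shuffles (default 100).
#' @param seed RNG seed.
#' @return A tibble: `perm`, `partition`, `max_fst`.
#' @export
permutation_max_fst <- function(x, sample_groups, grid, n_perm = 100,
                                seed = 1L) {
  if (n_perm < 1) abort("`n_perm` must be >= 1")
  sp <- .split_groups(x, sample_groups)
  set.seed(as.integer(seed))
  pool <- c(sp$g1, sp$g2)
  n1 <- length(sp$g1)
  part_of <- subgenome_partition(grid$chrom)
  wid_all <- .window_of(grid, x$variants$chrom, x$variants$pos)
  out <- vector("list", n_perm)
  for (i in seq_len(n_perm)) {
    shuffled <- sample(pool)
    k <- .fst_components_matrix(x$geno, shuffled[seq_len(n1)],
      shuffled[-seq_len(n1)])
    use <- k$usable & !is.na(wid_all)
    num <- rowsum(k$a[use], wid_all[use])
    den <- rowsum((k$a + k$b + k$c)[use], wid_all[use])
    fst <- ifelse(den != 0, num / den, NA_real_)
    wpart <- part_of[match(as.integer(rownames(num)), grid$window_id)]
    maxima <- tapply(fst, wpart, function(v) {
      if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
    })
    out[[i]] <- tibble(
      perm = i, partition = names(maxima),
      max_fst = as.numeric(maxima)
    )
  }
  bind_rows(out)
}

#' Effective population size from scaled diversity
#'
#' Inverts `theta = 4 * Ne * mu * L` for `Ne`, with the neutral per-site
#' per-generation mutation rate `mu` (default 6.5e-9 for wheat) and the
#' generation time `L` in years (default 1 for an annual crop).
#'
#' @param theta Scaled diversity.
#' @param mu Mutation rate per site per generation.
#' @param L Generation time in years.
#' @return `Ne = theta / (4 * mu * L)`.
#' @examples
#' estimate_Ne(1.74208e-3) # ~ 67,003
#' @export
estimate_Ne <- function(theta, mu = 6.5e-9, L = 1) {
  if (any(theta <= 0)) abort("`theta` must be positive")
  if (any(mu <= 0) || any(L <= 0)) abort("`mu` and `L` must be positive")
  theta / (4 * mu * L)
}
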