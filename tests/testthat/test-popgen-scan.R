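test_that("per-site variance components match the edge-case expectations", {
  # equal frequencies, no heterozygotes: a -> 0 as n grows (O(1/n) bias)
  a_of <- function(n) {
    site_fst_components(rep(c(0L, 2L), n / 2), rep(c(0L, 2L), n / 2))$a
  }
  expect_lt(abs(a_of(100)), 0.005)
  expect_lt(abs(a_of(1000)), 5e-4)
  expect_lt(abs(a_of(1000)), abs(a_of(100)))

  # fixed difference: per-site ratio is 1
  k2 <- site_fst_components(rep(2L, 20), rep(0L, 20))
  expect_equal(k2$fst, 1)

  # monomorphic across both groups: zero components, not usable
  k3 <- site_fst_components(rep(0L, 10), rep(0L, 10))
  expect_equal(c(k3$a, k3$b, k3$c), c(0, 0, 0))
  expect_false(k3$usable)
})

test_that("components equal the independently transcribed W&C 1984 oracle", {
  # alt 4/20 vs 16/20 alleles, all homozygotes
  g1 <- c(rep(2L, 2), rep(0L, 8)) # p1 = 0.2, n1 = 10
  g2 <- c(rep(2L, 8), rep(0L, 2)) # p2 = 0.8
  k <- site_fst_components(g1, g2)
  o <- wc_oracle(list(g1, g2))
  expect_equal(k$a, o$a, tolerance = 1e-12)
  expect_equal(k$b, o$b, tolerance = 1e-12)
  expect_equal(k$c, o$c, tolerance = 1e-12)

  # 1000 random sites with heterozygotes and missingness, max abs diff < 1e-10
  set.seed(101)
  worst <- 0
  for (i in 1:1000) {
    n1 <- sample(5:30, 1)
    n2 <- sample(5:30, 1)
    g1 <- sample(c(0L, 1L, 2L, NA), n1, replace = TRUE,
      prob = c(0.4, 0.1, 0.4, 0.1))
    g2 <- sample(c(0L, 1L, 2L, NA), n2, replace = TRUE,
      prob = c(0.2, 0.1, 0.6, 0.1))
    if (sum(!is.na(g1)) == 0 || sum(!is.na(g2)) == 0) next
    k <- site_fst_components(g1, g2)
    if (!k$usable) next
    o <- wc_oracle(list(g1, g2))
    worst <- max(worst, abs(k$a - o$a), abs(k$b - o$b), abs(k$c - o$c))
  }
  expect_lt(worst, 1e-10)
})

test_that("windowed FST is the ratio of summed components", {
  grid <- build_windows(c(chr1A = 300), size = 100)
  # window 1: fixed difference site; window 2: empty; window 3: three sites
  geno <- cbind(
    c(rep(2L, 6), rep(0L, 6)), # pos 50, fixed difference
    c(rep(c(0L, 2L), 3), rep(c(2L, 0L), 3)), # pos 210
    c(rep(0L, 5), 2L, rep(2L, 5), 0L), # pos 250
    c(rep(c(0L, 2L, 2L), 2), rep(2L, 6)) # pos 280
  )
  gt <- make_gt(geno, pos = c(50L, 210L, 250L, 280L))
  groups <- tibble::tibble(
    sample = gt$samples,
    group = rep(c("DE", "DO"), each = 6)
  )
  tr <- windowed_fst(gt, groups, grid)
  expect_equal(tr$fst[1], 1)
  expect_true(is.na(tr$fst[2]))
  expect_equal(tr$n_sites, c(1L, 0L, 3L))
  # ratio-of-sums from the per-site oracle
  de <- 1:6
  do_ <- 7:12
  osum <- lapply(2:4, function(j) wc_oracle(list(geno[de, j], geno[do_, j])))
  expect_equal(
    tr$fst[3],
    sum(vapply(osum, `[[`, numeric(1), "a")) /
      sum(vapply(osum, function(o) o$a + o$b + o$c, numeric(1))),
    tolerance = 1e-12
  )
})

test_that("windowed pi follows the closed form and its invariances", {
  grid <- build_windows(c(chr1A = 100), size = 100)
  # one site, x = 5 alt alleles of n = 10, in a 100 bp window
  gt <- make_gt(cbind(c(2L, 2L, 0L, 0L, 1L)), pos = 10L)
  pi1 <- windowed_pi(gt, gt$samples, grid)$pi
  expect_equal(pi1, (25 / 45) / 100, tolerance = 1e-12)
  # matches the brute-force pairwise-allele oracle
  expect_equal(pi1 * 100, pi_site_oracle(c(2L, 2L, 0L, 0L, 1L)))

  # monomorphic window -> 0
  gt0 <- make_gt(cbind(rep(2L, 5)), pos = 10L)
  expect_equal(windowed_pi(gt0, gt0$samples, grid)$pi, 0)

  # doubling window size halves pi
  grid2 <- build_windows(c(chr1A = 200), size = 200)
  expect_equal(windowed_pi(gt, gt$samples, grid2)$pi, pi1 / 2)

  # invariant to sample relabeling and ref/alt coding swap
  coh <- simulate_cohort(cohort_config(n_per_group = c(DE = 15, DO = 15),
    chromosomes = c(chr1A = 1e5), n_sites = 200, seed = 21))
  g100 <- build_windows(c(chr1A = 1e5), size = 1e4)
  base <- windowed_pi(coh$genotypes, coh$samples$sample, g100)$pi
  shuf <- windowed_pi(coh$genotypes, sample(coh$samples$sample), g100)$pi
  expect_equal(shuf, base)
  swapped <- genotype_table(
    coh$genotypes$variants,
    2L - coh$genotypes$geno,
    coh$genotypes$samples
  )
  expect_equal(windowed_pi(swapped, swapped$samples, g100)$pi, base)
})

test_that("pi ratio handles equal, zero, and doubled diversities", {
  expect_equal(pi_ratio(5e-4, 5e-4), 1)
  expect_true(is.na(pi_ratio(6e-4, 0)))
  expect_equal(pi_ratio(6e-4, 3e-4), 2)
})

test_that("candidate regions take the top tail per subgenome partition", {
  set.seed(3)
  grid <- build_windows(c(chr1A = 1e7, chr1D = 1e7), size = 1e5)
  track <- grid
  track$fst <- c(runif(100, 0, 0.3), runif(100, 0.5, 0.9))
  cand <- candidate_regions(track, quantile = 0.05)
  ab <- cand[cand$partition == "AB", ]
  dd <- cand[cand$partition == "D", ]
  expect_equal(nrow(ab), 5) # 100 windows -> floor(0.05 * 100) = 5
  expect_equal(nrow(dd), 5)
  expect_false(ab$threshold[1] == dd$threshold[1])
  # sort oracle: threshold is the 5th largest value in partition
  ab_vals <- track$fst[1:100]
  expect_equal(ab$threshold[1], sort(ab_vals, decreasing = TRUE)[5])
  expect_true(all(ab$fst >= ab$threshold[1]))
  expect_true(all(ab_vals[!track$window_id[1:100] %in% ab$window_id] <
    ab$threshold[1]))
})

test_that("permutation null is size-preserving and seed-deterministic", {
  coh <- simulate_cohort(cohort_config(
    n_per_group = c(DE = 12, DO = 14), chromosomes = c(chr1A = 2e5),
    n_sites = 300, seed = 31
  ))
  grid <- build_windows(c(chr1A = 2e5), size = 1e5)
  groups <- coh$samples[, c("sample", "group")]
  a <- permutation_max_fst(coh$genotypes, groups, grid, n_perm = 5, seed = 42)
  b <- permutation_max_fst(coh$genotypes, groups, grid, n_perm = 5, seed = 42)
  expect_identical(a, b)
  expect_equal(nrow(a), 5)
  expect_error(
    permutation_max_fst(coh$genotypes, groups, grid, n_perm = 0),
    "n_perm"
  )
})

test_that("null and observed scan maxima share a distribution under delta = 0", {
  # observed maxima across seeds vs permutation maxima: same distribution
  grid <- build_windows(c(chr1A = 3e5), size = 1e5)
  obs <- vapply(1:12, function(s) {
    coh <- simulate_cohort(cohort_config(
      n_per_group = c(DE = 20, DO = 20), chromosomes = c(chr1A = 3e5),
      n_sites = 600, seed = 500 + s
    ))
    max(windowed_fst(coh$genotypes, coh$samples[, c("sample", "group")],
      grid)$fst, na.rm = TRUE)
  }, numeric(1))
  coh <- simulate_cohort(cohort_config(
    n_per_group = c(DE = 20, DO = 20), chromosomes = c(chr1A = 3e5),
    n_sites = 600, seed = 599
  ))
  null <- permutation_max_fst(coh$genotypes,
    coh$samples[, c("sample", "group")], grid, n_perm = 40, seed = 9)
  ks <- suppressWarnings(stats::ks.test(obs, null$max_fst))
  expect_gt(ks$p.value, 0.01)
})

test_that("effective size inverts the scaled-diversity formula", {
  expect_equal(estimate_Ne(4 * 6.5e-9), 1)
  expect_equal(round(estimate_Ne(1.74208e-3, mu = 6.5e-9, L = 1)), 67003)
  expect_equal(estimate_Ne(2 * 1e-3, mu = 1e-8, L = 2),
    2 * estimate_Ne(1e-3, mu = 1e-8, L = 2))
  expect_error(estimate_Ne(0), "positive")
  expect_error(estimate_Ne(1e-3, mu = 0), "positive")
})

test_that("frequency shifts increase window FST in expectation", {
  deltas <- c(0, 0.4, 0.8)
  means <- vapply(deltas, function(d) {
    vals <- vapply(1:5, function(s) {
      cfg <- cohort_config(
        n_per_group = c(DE = 25, DO = 25), chromosomes = c(chr1A = 1e5),
        n_sites = 300,
        divergent_windows = if (d > 0) {
          tibble::tibble(chrom = "chr1A", start = 0, end = 1e5, delta = d)
        },
        seed = 700 + s * 7 + round(d * 10)
      )
      coh <- simulate_cohort(cfg)
      windowed_fst(coh$genotypes, coh$samples[, c("sample", "group")],
        build_windows(c(chr1A = 1e5), 1e5))$fst
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})
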