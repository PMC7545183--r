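sim_assoc_cohort <- function(n = 50, m = 120, seed = 1) {
  simulate_cohort(cohort_config(
    n_per_group = c(DE = n / 2, DO = n / 2),
    chromosomes = c(chr3B = 5e5, chr3D = 5e5), n_sites = m,
    het_rate = 0, missing_rate = 0.02, seed = seed
  ))
}

test_that("genotype PCA matches a dense eigendecomposition and separates clusters", {
  coh <- sim_assoc_cohort(20, 50, seed = 41)
  pcs <- genotype_pca(coh$genotypes, k = 3)
  z <- feralscan:::.standardized_dosages(coh$genotypes)
  ev <- eigen(tcrossprod(z), symmetric = TRUE)
  for (j in 1:3) {
    ref <- ev$vectors[, j] * sqrt(ev$values[j])
    got <- pcs[[paste0("PC", j)]]
    expect_equal(abs(cor(got, ref)), 1, tolerance = 1e-8)
    expect_equal(sort(abs(got)), sort(abs(ref)), tolerance = 1e-6)
  }

  # two well-separated clusters: PC1 splits them
  half <- matrix(c(rep(0L, 10 * 20), rep(2L, 10 * 20)), nrow = 20,
    byrow = TRUE)
  noise <- matrix(rbinom(20 * 20, 1, 0.5) * 2L, nrow = 20)
  gt <- make_gt(cbind(half, noise))
  p <- genotype_pca(gt, k = 2)
  expect_true(all(p$PC1[1:10] * p$PC1[11:20] < 0) ||
    (max(p$PC1[1:10]) < min(p$PC1[11:20]) ||
      min(p$PC1[1:10]) > max(p$PC1[11:20])))

  # duplicated sample lands on identical coordinates
  dup <- genotype_table(
    coh$genotypes$variants,
    coh$genotypes$geno[c(1, 1, 2:10), ],
    c("dup0", coh$genotypes$samples[1:10])
  )
  pd <- genotype_pca(dup, k = 2)
  expect_equal(pd$PC1[1], pd$PC1[2], tolerance = 1e-8)
  expect_error(genotype_pca(coh$genotypes, k = 100), "smaller")
})

test_that("kinship matches the brute-force VanRaden double loop", {
  coh <- sim_assoc_cohort(10, 30, seed = 43)
  K <- kinship_matrix(coh$genotypes)
  Ko <- kinship_oracle(coh$genotypes$geno)
  expect_equal(unname(K), Ko, tolerance = 1e-10)
  expect_equal(K, t(K))
  # identical samples have equal rows
  dup <- genotype_table(
    coh$genotypes$variants,
    coh$genotypes$geno[c(1, 1, 2:10), ],
    c("dup0", coh$genotypes$samples[1:10])
  )
  Kd <- kinship_matrix(dup)
  expect_equal(unname(Kd[1, ]), unname(Kd[2, ]), tolerance = 1e-12)
  # self-relationship at least as large as the average off-diagonal
  expect_gt(mean(diag(K)), mean(K[upper.tri(K)]))
})

test_that("with K = I and no covariates the MLM equals the OLS oracle", {
  coh <- sim_assoc_cohort(40, 80, seed = 47)
  gt <- apply_variant_filters(coh$genotypes, maf_min = 0.05)
  set.seed(5)
  y <- rnorm(40)
  fit <- mlm_association(gt, y, K = diag(40))
  pv <- ols_pvalues(gt$geno, y)
  expect_lt(max(abs(tidy(fit)$p_value - pv), na.rm = TRUE), 1e-8)

  # a marker perfectly aligned with the phenotype separates at n = 100
  g <- matrix(rbinom(100 * 10, 1, 0.4) * 2L, nrow = 100)
  g[, 1] <- rep(c(0L, 2L), each = 50)
  gt2 <- make_gt(g)
  y2 <- as.numeric(g[, 1] / 2)
  fit2 <- mlm_association(gt2, y2, K = diag(100))
  expect_lt(tidy(fit2)$p_value[1], 1e-10)
})

test_that("null type-I error is nominal and kinship controls inflation", {
  # two diverged subpopulations + polygenic phenotype: structure confounds
  set.seed(61)
  n <- 60
  m <- 300
  pop <- rep(0:1, each = n / 2)
  p1 <- rbeta(m, 0.8, 0.8)
  shift <- pmin(pmax(p1 + ifelse(rbinom(m, 1, 0.5), 0.4, -0.4), 0.02), 0.98)
  g <- matrix(0L, n, m)
  for (j in seq_len(m)) {
    pj <- ifelse(pop == 1, shift[j], p1[j])
    g[, j] <- 2L * rbinom(n, 1, pj)
  }
  rownames(g) <- sprintf("s%02d", 1:n)
  gt <- make_gt(g)
  y <- 2 * pop + rnorm(n, sd = 0.5) # strongly structured trait
  K <- kinship_matrix(gt)
  fit_k <- mlm_association(gt, y, K = K)
  fit_i <- mlm_association(gt, y, K = diag(n))
  lam_k <- genomic_lambda(tidy(fit_k)$p_value)
  lam_i <- genomic_lambda(tidy(fit_i)$p_value)
  expect_lt(abs(lam_k - 1), 0.25)
  expect_gt(lam_i, 1.2)

  # permuted phenotype: empirical type-I error within 3 binomial SE of 0.05
  coh <- sim_assoc_cohort(50, 200, seed = 53)
  gt0 <- apply_variant_filters(coh$genotypes, maf_min = 0.05)
  set.seed(7)
  y0 <- rnorm(50)
  fit0 <- mlm_association(gt0, y0, K = kinship_matrix(gt0))
  rate <- mean(tidy(fit0)$p_value < 0.05, na.rm = TRUE)
  se <- sqrt(0.05 * 0.95 / sum(!is.na(tidy(fit0)$p_value)))
  expect_lt(abs(rate - 0.05), 3 * se)
})

test_that("Bonferroni threshold follows alpha / n exactly", {
  expect_equal(signif(bonferroni_threshold(0.01, 35045206), 3), 2.85e-10)
  expect_equal(bonferroni_threshold(0.05, 10), 5e-3)
  ns <- c(10, 100, 1000, 10000)
  expect_true(all(diff(bonferroni_threshold(0.01, ns)) < 0))
  expect_error(bonferroni_threshold(1.2, 10), "alpha")
  expect_error(bonferroni_threshold(0.01, 0), "n_sites")
})

test_that("SV pseudo-variants encode and round-trip losslessly", {
  calls <- tibble::tibble(
    sample = rep(sprintf("s%d", 1:5), 2),
    sv_id = rep(c("del3D", "teQ5A"), each = 5),
    present = c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, NA, FALSE, NA, TRUE)
  )
  gt <- encode_sv_pseudo_variants(calls,
    sv_sites = tibble::tibble(sv_id = c("del3D", "teQ5A"),
      chrom = c("chr3D", "chr5A"), pos = c(55500000L, 650129563L)))
  expect_equal(unname(gt$geno[, 1]), c(2L, 0L, 2L, 0L, 2L))
  expect_equal(unname(gt$geno[, 2]), c(2L, NA, 0L, NA, 2L))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gt, f)
  raw <- readLines(f)
  expect_true(any(grepl("1/1", raw)) && any(grepl("\\./\\.", raw)))
  back <- read_vcf(f)
  expect_equal(back$geno, gt$geno)
  # conflicting duplicates rejected
  bad <- dplyr::bind_rows(calls,
    tibble::tibble(sample = "s1", sv_id = "del3D", present = FALSE))
  expect_error(encode_sv_pseudo_variants(bad), "conflict")
})

test_that("variance explained behaves at its extremes and recovers truth", {
  set.seed(71)
  n <- 80
  x <- rbinom(n, 1, 0.5) * 2
  # marker orthogonal to the phenotype: ~0
  y_orth <- rnorm(n)
  expect_lt(abs(variance_explained(x, y_orth)), 0.1)
  # marker equal to the phenotype: ~1
  expect_gt(variance_explained(x, as.numeric(x)), 0.999)

  # planted 75% variance recovered within 5 points over 50 seeds
  planted <- 0.75
  est <- vapply(1:50, function(s) {
    set.seed(1000 + s)
    xs <- rbinom(n, 1, 0.5) * 2
    signal <- xs - mean(xs)
    noise <- rnorm(n)
    y <- signal + noise * sd(signal) * sqrt((1 - planted) / planted) / sd(noise)
    variance_explained(xs, y)
  }, numeric(1))
  expect_lt(abs(mean(est) - planted), 0.05)
})

test_that("local + global PCs combine and collinear columns are filtered", {
  coh <- sim_assoc_cohort(30, 200, seed = 83)
  cov10 <- local_structure_covariates(coh$genotypes, "chr3B",
    k_local = 5, k_global = 5)
  expect_equal(ncol(cov10) - 1, 10)
  expect_true(all(grepl("^LPC", names(cov10)[2:6])))
  # a duplicated-chromosome table makes local and global PCs collinear
  v <- coh$genotypes$variants
  half <- v$chrom == "chr3B"
  dup <- genotype_table(
    v[half, ], coh$genotypes$geno[, half], coh$genotypes$samples
  )
  expect_warning(
    covd <- local_structure_covariates(dup, "chr3B", k_local = 3,
      k_global = 3),
    "collinear"
  )
  expect_lt(ncol(covd) - 1, 6)
  expect_error(
    local_structure_covariates(coh$genotypes, "chr9Z"),
    "too few"
  )
})

test_that("local-structure covariates reduce chromosome-local inflation", {
  # planted stratification confined to chr3B: local PCs absorb it
  set.seed(91)
  n <- 60
  m_local <- 150
  m_rest <- 100
  pop <- rep(0:1, each = n / 2)
  g_local <- matrix(0L, n, m_local)
  p1 <- rbeta(m_local, 0.8, 0.8)
  shift <- pmin(pmax(p1 + 0.5 * (2 * rbinom(m_local, 1, 0.5) - 1), 0.02), 0.98)
  for (j in seq_len(m_local)) {
    g_local[, j] <- 2L * rbinom(n, 1, ifelse(pop == 1, shift[j], p1[j]))
  }
  g_rest <- matrix(2L * rbinom(n * m_rest, 1, 0.5), n)
  g <- cbind(g_local, g_rest)
  rownames(g) <- sprintf("s%02d", 1:n)
  gt <- make_gt(g,
    chrom = rep(c("chr3B", "chr3D"), c(m_local, m_rest)),
    pos = c(seq_len(m_local) * 100L, seq_len(m_rest) * 100L))
  y <- 1.5 * pop + rnorm(n, sd = 0.7)
  pcs_g <- genotype_pca(gt[, gt$variants$chrom == "chr3D"], k = 3)
  pcs_l <- local_structure_covariates(gt, "chr3B", k_local = 5, k_global = 3)
  on3b <- gt$variants$chrom == "chr3B"
  fit_g <- mlm_association(gt[, on3b], y, covariates = pcs_g, K = diag(n))
  fit_l <- mlm_association(gt[, on3b], y, covariates = pcs_l, K = diag(n))
  lam_g <- genomic_lambda(tidy(fit_g)$p_value)
  lam_l <- genomic_lambda(tidy(fit_l)$p_value)
  expect_lt(lam_l, lam_g)
})
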