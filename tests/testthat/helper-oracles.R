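# Independent oracles, coded separately from the package implementations.

# Weir & Cockerham (1984) variance components, transcribed in the original
# r-population notation with explicit loops (r = number of populations).
# Input: list of dosage vectors, one per population. Returns a, b, c.
wc_oracle <- function(pops) {
  r <- length(pops)
  n <- vapply(pops, function(g) sum(!is.na(g)), numeric(1))
  p <- vapply(pops, function(g) sum(g, na.rm = TRUE) / (2 * sum(!is.na(g))),
    numeric(1))
  h <- vapply(pops, function(g) mean(g[!is.na(g)] == 1), numeric(1))
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
    ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cval <- hbar / 2
  list(a = a, b = b, c = cval)
}

# brute-force per-site pairwise nucleotide diversity: mean difference
# indicator over all pairs of called alleles
pi_site_oracle <- function(dosages) {
  alleles <- unlist(lapply(dosages[!is.na(dosages)], function(g) {
    c(as.integer(g >= 1), as.integer(g == 2))
  }))
  n <- length(alleles)
  if (n < 2) return(0)
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) tot <- tot + as.integer(alleles[i] != alleles[j])
  }
  tot / choose(n, 2)
}

# O(n^2 m) VanRaden kinship by explicit double loop
kinship_oracle <- function(geno) {
  p <- colMeans(geno, na.rm = TRUE) / 2
  z <- geno
  for (j in seq_len(ncol(geno))) {
    z[is.na(z[, j]), j] <- 2 * p[j]
    z[, j] <- z[, j] - 2 * p[j]
  }
  denom <- 2 * sum(p * (1 - p))
  n <- nrow(geno)
  k <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) k[i, j] <- sum(z[i, ] * z[j, ]) / denom
  }
  k
}

# OLS marker p-values via lm() F drop test
ols_pvalues <- function(geno, y, W = NULL) {
  vapply(seq_len(ncol(geno)), function(j) {
    x <- geno[, j]
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    d <- if (is.null(W)) data.frame(y = y, x = x) else
      data.frame(y = y, x = x, W)
    full <- lm(y ~ ., data = d)
    cf <- summary(full)$coefficients
    if (!"x" %in% rownames(cf)) return(NA_real_)
    cf["x", 4]
  }, numeric(1))
}

# brute-force Nx by cumulative scan over sorted lengths
nx_oracle <- function(lengths, x) {
  s <- sort(lengths, decreasing = TRUE)
  target <- x / 100 * sum(s)
  acc <- 0
  for (l in s) {
    acc <- acc + l
    if (acc >= target) return(l)
  }
  NA_real_
}

# small literal genotype table from a dosage matrix (samples x sites)
make_gt <- function(geno, chrom = "chr1A", pos = NULL) {
  geno <- as.matrix(geno)
  if (is.null(rownames(geno))) {
    rownames(geno) <- sprintf("s%02d", seq_len(nrow(geno)))
  }
  if (is.null(pos)) pos <- seq_len(ncol(geno)) * 100L
  if (length(chrom) == 1) chrom <- rep(chrom, ncol(geno))
  genotype_table(
    tibble::tibble(chrom = chrom, pos = as.integer(pos), ref = "A", alt = "T"),
    geno
  )
}
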