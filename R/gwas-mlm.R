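# standardized dosage matrix: impute missing to the site mean, centre,
# scale to unit variance; monomorphic sites drop out as zero columns
.standardized_dosages <- function(x, rows = NULL) {
  g <- x$geno
  if (!is.null(rows)) g <- g[rows, , drop = FALSE]
  mu <- colMeans(g, na.rm = TRUE)
  gi <- g
  for (j in which(colSums(is.na(g)) > 0)) gi[is.na(g[, j]), j] <- mu[j]
  gc <- sweep(gi, 2, mu)
  s <- apply(gc, 2, sd)
  s[s == 0 | is.na(s)] <- Inf
  sweep(gc, 2, s, `/`)
}

#' Principal components of the genotype matrix
#'
#' Top-k components of the standardized dosage matrix (missing imputed to
#' the site mean), the usual population-structure covariates for
#' mixed-model association. Component signs are fixed deterministically by
#' forcing the largest-magnitude loading of each component positive.
#'
#' @param x A filtered, pruned [genotype_table()].
#' @param k Number of components (default 5; must be `< n_samples`).
#' @return A tibble: `sample`, `PC1` ... `PCk`; the singular values are in
#'   the `"d"` attribute.
#' @export
genotype_pca <- function(x, k = 5) {
  n <- n_samples(x)
  if (k >= n) abort("`k` must be smaller than the number of samples")
  z <- .standardized_dosages(x)
  sv <- svd(z, nu = k, nv = k)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k)
  for (j in seq_len(k)) {
    i <- which.max(abs(sv$v[, j]))
    if (sv$v[i, j] < 0) scores[, j] <- -scores[, j]
  }
  out <- as_tibble(scores, .name_repair = "minimal")
  names(out) <- paste0("PC", seq_len(k))
  out <- dplyr::bind_cols(tibble(sample = x$samples), out)
  attr(out, "d") <- sv$d[seq_len(k)]
  out
}

#' Genomic relationship (kinship) matrix
#'
#' VanRaden's centred form: `K = Z Z' / (2 * sum p (1 - p))` with `Z` the
#' dosage matrix centred by twice the allele frequency and missing values
#' imputed to the site mean. Symmetric by construction.
#'
#' @param x A [genotype_table()] with polymorphic sites.
#' @return A samples x samples numeric matrix with sample-id dimnames.
#' @export
kinship_matrix <- function(x) {
  g <- x$geno
  if (any(rowSums(!is.na(g)) == 0)) abort("sample with all genotypes missing")
  p <- colMeans(g, na.rm = TRUE) / 2
  gi <- g
  for (j in which(colSums(is.na(g)) > 0)) gi[is.na(g[, j]), j] <- 2 * p[j]
  z <- sweep(gi, 2, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  if (denom == 0) abort("all sites monomorphic")
  k <- z %*% t(z) / denom
  dimnames(k) <- list(x$samples, x$samples)
  (k + t(k)) / 2
}

# eigen-rotated restricted likelihood machinery (EMMA-style).
# Returns the rotation plus the REML-optimal variance ratio
# delta = sigma_e^2 / sigma_g^2 under the null model y ~ W.
.fit_null_mlm <- function(y, W, K, stabilize_tol = 1e-8) {
  n <- length(y)
  eg <- eigen(K, symmetric = TRUE)
  if (min(eg$values) < -stabilize_tol * max(abs(eg$values))) {
    inform("kinship not PSD; stabilizing with diagonal ridge")
  }
  lam <- pmax(eg$values, 0)
  U <- eg$vectors
  yt <- drop(crossprod(U, y))
  Wt <- crossprod(U, W)
  p <- ncol(W)
  reml <- function(logd) {
    d <- exp(logd)
    w <- 1 / (lam + d)
    WtW <- crossprod(Wt, Wt * w)
    beta <- solve(WtW, crossprod(Wt, yt * w))
    r <- yt - drop(Wt %*% beta)
    rss <- sum(w * r^2)
    sg2 <- rss / (n - p)
    -0.5 * ((n - p) * log(sg2) + sum(log(lam + d)) +
      determinant(WtW, logarithm = TRUE)$modulus)
  }
  opt <- optimize(reml, c(-12, 12), maximum = TRUE)
  delta <- exp(opt$maximum)
  w <- 1 / (lam + delta)
  WtW <- crossprod(Wt, Wt * w)
  beta <- solve(WtW, crossprod(Wt, yt * w))
  r <- yt - drop(Wt %*% beta)
  rss <- sum(w * r^2)
  sg2 <- rss / (n - p)
  list(
    U = U, lam = lam, yt = yt, Wt = Wt, weights = w, delta = delta,
    sigma_g2 = sg2, sigma_e2 = delta * sg2, rss_null = rss, n = n, p = p,
    reml = opt$objective
  )
}

#' Mixed-linear-model association scan
#'
#' Tests each variant's effect in `y = W a + x b + u + e` with polygenic
#' random effect `u ~ N(0, sigma_g^2 K)`. Variance components are
#' estimated once under the null by eigen-rotated REML and reused for
#' every marker (the P3D/EMMAX approximation; `per_marker = TRUE` re-fits
#' REML per marker). With `K = I` and no covariates the test reduces
#' exactly to the ordinary-least-squares F test. Binary phenotypes (e.g.
#' brittle rachis coded 1) are analysed with the linear model, as the
#' field's association tools do.
#'
#' @param x A [genotype_table()].
#' @param phenotype Data frame `sample`, `phenotype` (numeric; binary
#'   traits coded 0/1), or a numeric vector aligned to `x$samples`.
#' @param covariates Optional covariate tibble from [genotype_pca()] /
#'   [local_structure_covariates()] (column `sample` plus numeric columns),
#'   or `NULL`.
#' @param K Kinship matrix (default [kinship_matrix()] of `x`; use
#'   `diag(n)` for no polygenic term).
#' @param alpha Family-wise error level for the Bonferroni threshold
#'   attached to the result (default 0.01).
#' @param per_marker Re-estimate variance components per marker (slower).
#' @return An object of class `feralscan_mlm`; `tidy()` gives the
#'   per-variant tibble (`chrom`, `pos`, `beta`, `se`, `statistic`,
#'   `p_value`), `glance()` the model-level summary. The Bonferroni
#'   threshold `alpha / n_sites` is stored in the object.
#' @export
mlm_association <- function(x, phenotype, covariates = NULL, K = NULL,
                            alpha = 0.01, per_marker = FALSE) {
  n <- n_samples(x)
  if (is.data.frame(phenotype)) {
    y <- phenotype$phenotype[match(x$samples, phenotype$sample)]
  } else {
    y <- as.numeric(phenotype)
  }
  if (anyNA(y)) abort("phenotype missing for some samples")
  W <- matrix(1, n, 1)
  if (!is.null(covariates)) {
    cv <- as_tibble(covariates)
    cm <- as.matrix(cv[match(x$samples, cv$sample),
      setdiff(names(cv), "sample")])
    W <- cbind(W, cm)
  }
  if (qr(W)$rank < ncol(W)) abort("singular covariate matrix")
  if (is.null(K)) K <- kinship_matrix(x)
  null_fit <- .fit_null_mlm(y, W, K)
  g <- x$geno
  p_imp <- colMeans(g, na.rm = TRUE)
  res <- matrix(NA_real_, nrow = n_variants(x), ncol = 4)
  for (j in seq_len(n_variants(x))) {
    xj <- g[, j]
    xj[is.na(xj)] <- p_imp[j]
    fit <- if (per_marker) .fit_null_mlm(y, cbind(W, xj), K) else null_fit
    xt <- drop(crossprod(fit$U, xj))
    X <- cbind(fit$Wt, xt)
    w <- fit$weights
    XtX <- crossprod(X, X * w)
    if (rcond(XtX) < 1e-12) next
    beta <- solve(XtX, crossprod(X, fit$yt * w))
    r <- fit$yt - drop(X %*% beta)
    rss <- sum(w * r^2)
    df <- n - ncol(X)
    if (df <= 0) next
    s2 <- rss / df
    vb <- s2 * solve(XtX)[ncol(X), ncol(X)]
    tstat <- beta[ncol(X)] / sqrt(vb)
    res[j, ] <- c(beta[ncol(X)], sqrt(vb), tstat,
      2 * pt(-abs(tstat), df))
  }
  assoc <- tibble(
    chrom = x$variants$chrom, pos = x$variants$pos,
    beta = res[, 1], se = res[, 2], statistic = res[, 3], p_value = res[, 4]
  )
  structure(
    list(
      results = assoc, alpha = alpha,
      bonferroni = bonferroni_threshold(alpha, n_variants(x)),
      null_fit = null_fit[c("delta", "sigma_g2", "sigma_e2", "rss_null",
        "n", "p", "reml")],
      n_sites = n_variants(x), per_marker = per_marker
    ),
    class = "feralscan_mlm"
  )
}

#' @export
print.feralscan_mlm <- function(x, ...) {
  cat("<feralscan_mlm> ", x$n_sites, " variants, n = ", x$null_fit$n,
    "\n  sigma_g2 = ", signif(x$null_fit$sigma_g2, 4),
    ", sigma_e2 = ", signif(x$null_fit$sigma_e2, 4),
    "\n  Bonferroni threshold (alpha = ", x$alpha, "): ",
    signif(x$bonferroni, 3), "\n", sep = "")
  invisible(x)
}

#' @rdname mlm_association
#' @param x A `feralscan_mlm` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.feralscan_mlm <- function(x, ...) x$results

#' @rdname mlm_association
#' @exportS3Method generics::glance
glance.feralscan_mlm <- function(x, ...) {
  tibble(
    n = x$null_fit$n, n_sites = x$n_sites,
    sigma_g2 = x$null_fit$sigma_g2, sigma_e2 = x$null_fit$sigma_e2,
    delta = x$null_fit$delta, bonferroni = x$bonferroni,
    lambda_gc = genomic_lambda(x$results$p_value)
  )
}

#' Bonferroni family-wise threshold
#'
#' `alpha / n_sites`: with the study-scale 35,045,206 variant sites and
#' `alpha = 0.01` this is the genome-wide 2.85e-10 cutoff.
#'
#' @param alpha Family-wise error level in `(0, 1)`.
#' @param n_sites Number of tests (>= 1).
#' @return The per-test threshold.
#' @examples
#' bonferroni_threshold(0.01, 35045206)
#' @export
bonferroni_threshold <- function(alpha, n_sites) {
  if (any(alpha <= 0 | alpha >= 1)) abort("`alpha` must be in (0, 1)")
  if (any(n_sites < 1)) abort("`n_sites` must be >= 1")
  alpha / n_sites
}

#' Genomic-control inflation factor
#'
#' Median chi-squared statistic of the p-values divided by the null median
#' (0.4549); ~1 indicates well-calibrated tests.
#'
#' @param p Vector of p-values.
#' @return Numeric scalar lambda.
#' @export
genomic_lambda <- function(p) {
  p <- p[!is.na(p)]
  median(qchisq(p, df = 1, lower.tail = FALSE)) / qchisq(0.5, df = 1)
}

#' Encode structural-variant calls as pseudo-VCF genotypes
#'
#' Deletion and TE-insertion calls enter association as biallelic
#' pseudo-variants: presence is written `1/1`, absence `0/0`, unknown
#' `./.`. Round-trips through [write_vcf()] / [read_vcf()] into dosages
#' `{2, 0, NA}` losslessly.
#'
#' @param sv_calls Data frame `sample`, `sv_id`, `present` (logical or
#'   `NA` for unknown).
#' @param sv_sites Optional data frame `sv_id`, `chrom`, `pos` giving each
#'   pseudo-variant a coordinate (defaults to chrUn with consecutive
#'   positions).
#' @return A [genotype_table()] with one pseudo-variant per `sv_id`.
#' @export
encode_sv_pseudo_variants <- function(sv_calls, sv_sites = NULL) {
  sv_calls <- as_tibble(sv_calls)
  dup <- sv_calls |>
    dplyr::distinct(.data$sample, .data$sv_id, .data$present) |>
    dplyr::count(.data$sample, .data$sv_id) |>
    filter(n > 1)
  if (nrow(dup)) abort("conflicting duplicate SV calls")
  sv_calls <- dplyr::distinct(sv_calls, .data$sample, .data$sv_id,
    .keep_all = TRUE)
  ids <- unique(sv_calls$sv_id)
  samples <- unique(sv_calls$sample)
  if (is.null(sv_sites)) {
    sv_sites <- tibble(sv_id = ids, chrom = "chrUn", pos = seq_along(ids))
  } else {
    sv_sites <- as_tibble(sv_sites)[match(ids, as_tibble(sv_sites)$sv_id), ]
  }
  geno <- matrix(NA_integer_, nrow = length(samples), ncol = length(ids),
    dimnames = list(samples, NULL))
  for (i in seq_len(nrow(sv_calls))) {
    v <- sv_calls$present[i]
    geno[sv_calls$sample[i], match(sv_calls$sv_id[i], ids)] <-
      if (is.na(v)) NA_integer_ else if (v) 2L else 0L
  }
  ord <- order(sv_sites$chrom, sv_sites$pos)
  genotype_table(
    tibble(chrom = sv_sites$chrom, pos = sv_sites$pos,
      ref = "A", alt = "T")[ord, ],
    geno[, ord, drop = FALSE], samples
  )
}

#' Phenotypic variance explained by a marker
#'
#' GLS partial R-squared on the decorrelated (eigen-rotated, weighted)
#' model: `(RSS_null - RSS_marker) / RSS_null`, where the null model holds
#' the covariates and the polygenic term. This is the quantity used to
#' attribute brittleness variance to the chr3D 0.8-Mb deletion and the
#' *TaQ-5A* TE insertion pseudo-variants.
#'
#' @param marker Numeric dosage vector aligned to samples, or a
#'   single-variant [genotype_table()].
#' @param phenotype As in [mlm_association()].
#' @param covariates Optional covariate tibble.
#' @param K Kinship matrix (default identity).
#' @param samples Sample ids (required when `marker` is a bare vector and
#'   `phenotype` is a data frame).
#' @return Fraction of variance explained, in `[0, 1]`.
#' @export
variance_explained <- function(marker, phenotype, covariates = NULL,
                               K = NULL, samples = NULL) {
  if (inherits(marker, "genotype_table")) {
    samples <- marker$samples
    marker <- as.numeric(marker$geno[, 1])
  }
  n <- length(marker)
  if (is.data.frame(phenotype)) {
    if (is.null(samples)) abort("`samples` required to align the phenotype")
    y <- phenotype$phenotype[match(samples, phenotype$sample)]
  } else {
    y <- as.numeric(phenotype)
  }
  marker[is.na(marker)] <- mean(marker, na.rm = TRUE)
  W <- matrix(1, n, 1)
  if (!is.null(covariates)) {
    cv <- as_tibble(covariates)
    W <- cbind(W, as.matrix(cv[match(samples, cv$sample),
      setdiff(names(cv), "sample")]))
  }
  if (is.null(K)) K <- diag(n)
  fit <- .fit_null_mlm(y, W, K)
  if (fit$rss_null == 0) abort("null model has zero residual variance")
  xt <- drop(crossprod(fit$U, marker))
  X <- cbind(fit$Wt, xt)
  w <- fit$weights
  beta <- solve(crossprod(X, X * w), crossprod(X, fit$yt * w))
  rss <- sum(w * (fit$yt - drop(X %*% beta))^2)
  (fit$rss_null - rss) / fit$rss_null
}

#' Global plus chromosome-local structure covariates
#'
#' Concatenates `k_local` PCs computed from the target chromosome's sites
#' with `k_global` genome-wide PCs — the covariate set used to correct
#' chromosome-local stratification (the chr3B case). Columns made
#' redundant by collinearity are dropped with a warning.
#'
#' @param x A [genotype_table()].
#' @param target_chrom Chromosome whose local structure is modelled.
#' @param k_local,k_global Component counts (defaults 5 and 5).
#' @return A covariate tibble (`sample`, `LPC*`, `PC*`) after rank
#'   filtering.
#' @export
local_structure_covariates <- function(x, target_chrom, k_local = 5,
                                       k_global = 5) {
  on_target <- x$variants$chrom == target_chrom
  if (sum(on_target) < k_local + 1) abort("too few sites on target chromosome")
  local <- genotype_pca(x[, on_target], k = k_local)
  names(local) <- c("sample", paste0("LPC", seq_len(k_local)))
  global <- genotype_pca(x, k = k_global)
  out <- left_join(local, global, by = "sample")
  m <- as.matrix(out[, -1])
  qrm <- qr(cbind(1, m))
  keep <- qrm$pivot[seq_len(qrm$rank)] - 1L
  keep <- sort(keep[keep >= 1])
  if (length(keep) < ncol(m)) {
    warn(sprintf("dropping %d collinear covariate column(s)",
      ncol(m) - length(keep)))
  }
  dplyr::bind_cols(out[, 1], out[, 1 + keep])
}
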