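#' Restrict two genotype tables to sites polymorphic in both
#'
#' When merging a resequencing cohort with an exome-capture panel, only
#' SNPs segregating in both data sets are informative for joint haplotype
#' frequencies; this intersects on (chrom, pos) and drops sites monomorphic
#' in either table.
#'
#' @param table_a,table_b [genotype_table()] objects sharing a coordinate
#'   system.
#' @return A list with the two restricted tables (`a`, `b`). An empty
#'   intersection warns.
#' @export
intersect_polymorphic <- function(table_a, table_b) {
  key_a <- paste(table_a$variants$chrom, table_a$variants$pos)
  key_b <- paste(table_b$variants$chrom, table_b$variants$pos)
  poly <- function(x) {
    s <- site_summary(x)
    !is.na(s$maf) & s$maf > 0
  }
  ok_a <- poly(table_a)
  ok_b <- poly(table_b)
  shared <- intersect(key_a[ok_a], key_b[ok_b])
  if (!length(shared)) warn("no shared polymorphic sites")
  list(
    a = table_a[, key_a %in% shared],
    b = table_b[, key_b %in% shared]
  )
}

#' Call per-gene haplotypes from homozygous genotypes
#'
#' Builds one haplotype string per sample over the SNPs inside a gene
#' interval: homozygous reference/alternate dosages map to the respective
#' allele, heterozygous and missing calls become `N` (inbred-line
#' assumption; set `het = "drop"` to discard heterozygous samples
#' instead). Samples whose string has a missing fraction above
#' `max_missing` are excluded; genes with fewer than `min_sites` SNPs
#' return no haplotypes.
#'
#' @param x A [genotype_table()].
#' @param gene One-row data frame or list with `gene`, `chrom`, `start`,
#'   `end` (0-based half-open).
#' @param min_sites Minimum SNPs required in the gene (default 2).
#' @param max_missing Maximum fraction of `N` symbols per sample (default
#'   0.5).
#' @param het `"missing"` (default: heterozygous sites become `N`) or
#'   `"drop"` (samples with any heterozygous site are excluded).
#' @return A list of class `gene_haplotypes`: `gene`, `sites` (variant
#'   tibble), `calls` (tibble `sample`, `haplotype` string, `hap_id`),
#'   `haplotypes` (tibble `hap_id`, `haplotype`, `n`).
#' @export
call_gene_haplotypes <- function(x, gene, min_sites = 2, max_missing = 0.5,
                                 het = c("missing", "drop")) {
  het <- match.arg(het)
  in_gene <- x$variants$chrom == gene$chrom &
    x$variants$pos - 1L >= gene$start & x$variants$pos - 1L < gene$end
  if (!any(in_gene)) abort("no SNPs inside the gene interval")
  sites <- x$variants[in_gene, ]
  if (nrow(sites) < min_sites) {
    warn(sprintf("gene %s has fewer than %d sites; dropped",
      gene$gene %||% "?", min_sites))
    return(structure(
      list(gene = gene, sites = sites,
        calls = tibble(sample = character(0), haplotype = character(0),
          hap_id = character(0)),
        haplotypes = tibble(hap_id = character(0), haplotype = character(0),
          n = integer(0))),
      class = "gene_haplotypes"
    ))
  }
  g <- x$geno[, in_gene, drop = FALSE]
  allele <- matrix("N", nrow = nrow(g), ncol = ncol(g))
  for (j in seq_len(ncol(g))) {
    allele[g[, j] == 0L & !is.na(g[, j]), j] <- sites$ref[j]
    allele[g[, j] == 2L & !is.na(g[, j]), j] <- sites$alt[j]
  }
  if (het == "drop") {
    has_het <- apply(g, 1, function(v) any(v == 1L, na.rm = TRUE))
  } else {
    has_het <- rep(FALSE, nrow(g))
  }
  strings <- apply(allele, 1, paste, collapse = "")
  miss_frac <- apply(allele == "N", 1, mean)
  keep <- !has_het & miss_frac <= max_missing
  calls <- tibble(sample = x$samples[keep], haplotype = strings[keep])
  haps <- calls |>
    dplyr::count(.data$haplotype, name = "n") |>
    arrange(dplyr::desc(.data$n), .data$haplotype)
  haps$hap_id <- sprintf("H%02d", seq_len(nrow(haps)))
  calls$hap_id <- haps$hap_id[match(calls$haplotype, haps$haplotype)]
  structure(
    list(gene = gene, sites = sites, calls = calls,
      haplotypes = select(haps, "hap_id", "haplotype", "n")),
    class = "gene_haplotypes"
  )
}

#' @export
print.gene_haplotypes <- function(x, ...) {
  cat("<gene_haplotypes> ", x$gene$gene %||% "?", ": ",
    nrow(x$haplotypes), " haplotype(s) over ", nrow(x$sites),
    " site(s), ", nrow(x$calls), " sample(s)\n", sep = "")
  invisible(x)
}

#' Classify gene haplotypes as high- or low-altitude adapted
#'
#' A haplotype is labelled `HA` when it carries the alternate allele at at
#' least one amino-acid-changing (missense) site and is more frequent in
#' the high-altitude group than in the low-altitude group; haplotypes
#' failing either condition are `LA`. Ties (`freq_HA == freq_LA`) and
#' haplotypes absent from both groups are `unclassified`. Swapping the
#' HA/LA sample labels swaps the classifications.
#'
#' @param haps A `gene_haplotypes` from [call_gene_haplotypes()].
#' @param missense_sites Data frame `chrom`, `pos` of missense SNPs (an
#'   empty list warns and leaves everything unclassified).
#' @param sample_groups Data frame `sample`, `altitude` with values
#'   `"HA"` / `"LA"`.
#' @return A tibble: `hap_id`, `haplotype`, `carries_missense`, `freq_HA`,
#'   `freq_LA`, `label`.
#' @export
classify_ha_la <- function(haps, missense_sites, sample_groups) {
  stopifnot(inherits(haps, "gene_haplotypes"))
  sample_groups <- as_tibble(sample_groups)
  if (is.null(missense_sites) || nrow(as_tibble(missense_sites)) == 0) {
    warn("missense site list is empty; all haplotypes unclassified")
    return(mutate(haps$haplotypes,
      carries_missense = NA, freq_HA = NA_real_, freq_LA = NA_real_,
      label = "unclassified"))
  }
  missense_sites <- as_tibble(missense_sites)
  mis_idx <- which(paste(haps$sites$chrom, haps$sites$pos) %in%
    paste(missense_sites$chrom, missense_sites$pos))
  calls <- left_join(haps$calls, sample_groups, by = "sample")
  n_ha <- sum(calls$altitude == "HA", na.rm = TRUE)
  n_la <- sum(calls$altitude == "LA", na.rm = TRUE)
  out <- haps$haplotypes
  out$carries_missense <- vapply(out$haplotype, function(h) {
    any(substring(h, mis_idx, mis_idx) == haps$sites$alt[mis_idx])
  }, logical(1))
  out$freq_HA <- vapply(out$hap_id, function(id) {
    if (n_ha == 0) return(0)
    sum(calls$hap_id == id & calls$altitude == "HA", na.rm = TRUE) / n_ha
  }, numeric(1))
  out$freq_LA <- vapply(out$hap_id, function(id) {
    if (n_la == 0) return(0)
    sum(calls$hap_id == id & calls$altitude == "LA", na.rm = TRUE) / n_la
  }, numeric(1))
  out$label <- dplyr::case_when(
    out$freq_HA == out$freq_LA ~ "unclassified",
    out$carries_missense & out$freq_HA > out$freq_LA ~ "HA",
    .default = "LA"
  )
  out
}

#' Haplotype-class frequencies by group or region
#'
#' Tallies, per group/region, the proportion of samples carrying each
#' haplotype label (the orange "HA-adapted" sectors of a haplotype
#' geography map). Proportions sum to 1 within each group.
#'
#' @param haps A `gene_haplotypes`.
#' @param classes Output of [classify_ha_la()].
#' @param sample_groups Data frame `sample` plus a grouping column.
#' @param by Name of the grouping column (default `"region"`).
#' @return A tibble: one row per group x label with `n` and `prop`.
#' @export
haplotype_frequencies <- function(haps, classes, sample_groups,
                                  by = "region") {
  calls <- haps$calls |>
    left_join(select(classes, "hap_id", "label"), by = "hap_id") |>
    left_join(as_tibble(sample_groups), by = "sample")
  if (any(is.na(calls[[by]]))) warn("samples with missing group dropped")
  calls <- calls[!is.na(calls[[by]]), ]
  if (nrow(calls) == 0) abort("no samples left to tabulate")
  calls |>
    group_by(.data[[by]], .data$label) |>
    summarise(n = dplyr::n(), .groups = "drop_last") |>
    mutate(prop = .data$n / sum(.data$n)) |>
    ungroup()
}
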