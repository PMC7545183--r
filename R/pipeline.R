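#' Pipeline configuration
#'
#' Collects stage toggles, thresholds, and the global seed for
#' [run_pipeline()]. Defaults are the study's printed operating points:
#' 100 kb scan windows, 5 kb depth windows with 0.8/0.2 PAV thresholds and
#' 10 kb merging, top-5% candidate quantile, 100 permutations, alpha 0.01,
#' 5 PCs, 22-read chrUn threshold, 300 bp pseudomolecule gaps. The global
#' seed fans out deterministically to per-stage child seeds.
#'
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "filter", "scan", "cnv", "te", "gwas", "anchor")`.
#' @param out_dir Output directory.
#' @param seed Global seed.
#' @param cohort A [cohort_config()]; built from the defaults plus `seed`
#'   when `NULL`.
#' @param scan_window,scan_step Scan window geometry (bp).
#' @param depth_window Depth/PAV grid size (bp).
#' @param pav_hi,pav_lo,merge_gap PAV thresholds and merge gap.
#' @param top_quantile Candidate-region tail fraction.
#' @param n_perm Permutations for the scan null.
#' @param alpha Family-wise level for the Bonferroni threshold.
#' @param n_pcs Principal components for association.
#' @param min_reads chrUn probe-read threshold.
#' @param gap Pseudomolecule gap (bp).
#' @param mean_cov Simulated mean coverage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(stages = c("simulate", "filter", "scan", "cnv",
                                       "te", "gwas", "anchor"),
                            out_dir = tempfile("feralscan_"), seed = 1L,
                            cohort = NULL,
                            scan_window = 1e5, scan_step = 1e5,
                            depth_window = 5e3, pav_hi = 0.8, pav_lo = 0.2,
                            merge_gap = 1e4, top_quantile = 0.05,
                            n_perm = 100, alpha = 0.01, n_pcs = 5,
                            min_reads = 22, gap = 300, mean_cov = 10) {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(
    list(
      stages = stages, out_dir = out_dir, seed = as.integer(seed),
      cohort = cohort, scan_window = scan_window, scan_step = scan_step,
      depth_window = depth_window, pav_hi = pav_hi, pav_lo = pav_lo,
      merge_gap = merge_gap, top_quantile = top_quantile, n_perm = n_perm,
      alpha = alpha, n_pcs = n_pcs, min_reads = min_reads, gap = gap,
      mean_cov = mean_cov
    ),
    class = "pipeline_config"
  )
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return [read_pipeline_config()] returns a `pipeline_config`;
#'   [write_pipeline_config()] returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  cohort <- vals$cohort
  vals$cohort <- NULL
  cfg <- do.call(pipeline_config, vals)
  if (!is.null(cohort)) {
    # YAML lowers vectors and data frames to lists; restore the shapes
    for (f in c("n_per_group", "chromosomes", "maf_beta")) {
      if (!is.null(cohort[[f]])) cohort[[f]] <- unlist(cohort[[f]])
    }
    for (f in c("divergent_windows", "deletion_truth")) {
      if (!is.null(cohort[[f]])) cohort[[f]] <- as_tibble(cohort[[f]])
    }
    cfg$cohort <- do.call(cohort_config, cohort)
  }
  cfg
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  vals <- unclass(config)
  if (!is.null(vals$cohort)) {
    ch <- unclass(vals$cohort)
    # named vectors go out as YAML maps so names survive the round trip
    for (f in c("n_per_group", "chromosomes")) ch[[f]] <- as.list(ch[[f]])
    vals$cohort <- ch
  }
  yaml::write_yaml(vals, path)
  invisible(path)
}

# deterministic per-stage child seeds from the global seed
.stage_seed <- function(seed, stage) {
  (seed * 1000L +
    match(stage, c("simulate", "filter", "scan", "cnv", "te", "gwas",
      "anchor"))) %% .Machine$integer.max
}

#' Run the scan pipeline end to end
#'
#' Executes the enabled stages in order — simulate, filter, scan
#' (FST/pi/candidates + permutation null), cnv (NCN, CNV-index, deletion
#' genotypes), te (soft-clip genotyping), gwas (MLM with PCs + kinship and
#' SV pseudo-variants), anchor (scaffold world + placements) — writing each
#' stage's tables under `config$out_dir` and a manifest of outputs with
#' md5 checksums. Identical seeds yield identical manifests. Stages needing
#' a disabled upstream stage fail with a clear error.
#'
#' @param config A [pipeline_config()].
#' @return A list with the in-memory stage results plus `manifest` (tibble
#'   `file`, `md5`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  need <- function(what, stage) {
    if (is.null(res[[what]])) {
      abort(sprintf("stage '%s' needs output of disabled stage '%s'",
        stage, what))
    }
    res[[what]]
  }
  out <- function(name) file.path(config$out_dir, name)
  written <- character(0)
  emit_tsv <- function(df, name) {
    utils::write.table(df, out(name), sep = "\t", quote = FALSE,
      row.names = FALSE)
    written <<- c(written, out(name))
  }

  if ("simulate" %in% config$stages) {
    cc <- config$cohort %||% cohort_config(
      chromosomes = c(chr1A = 1e6, chr1D = 1e6),
      n_sites = 4000,
      divergent_windows = tibble(chrom = "chr1A", start = 3e5, end = 4e5,
        delta = 0.8),
      deletion_truth = tibble(chrom = "chr1D", start = 5e5, end = 5.6e5,
        carrier_group = "DE", carrier_frac = 0.9),
      te_truth = list(chrom = "chr1A", site = 650129L, te_seq = NULL,
        carrier_group = "DE", carrier_frac = 0.9),
      seed = .stage_seed(config$seed, "simulate")
    )
    res$simulate <- simulate_cohort(cc)
    write_vcf(res$simulate$genotypes, out("cohort.vcf"),
      contig_lengths = cc$chromosomes)
    written <- c(written, out("cohort.vcf"))
    emit_tsv(res$simulate$samples, "samples.tsv")
    res$depth <- simulate_depth_matrix(res$simulate,
      mean_cov = config$mean_cov, window_size = config$depth_window,
      seed = .stage_seed(config$seed, "simulate") + 1L)
  }

  if ("filter" %in% config$stages) {
    sim <- need("simulate", "filter")
    res$filter <- apply_variant_filters(sim$genotypes, maf_min = 0.05,
      missing_max = 0.3)
    emit_tsv(site_summary(res$filter), "filtered_sites.tsv")
  }

  if ("scan" %in% config$stages) {
    sim <- need("simulate", "scan")
    gt <- res$filter %||% sim$genotypes
    grid <- build_windows(sim$truth$config$chromosomes,
      size = config$scan_window, step = config$scan_step)
    groups <- select(sim$samples, "sample", "group")
    res$scan <- scan_windows(gt, groups, grid)
    res$candidates <- candidate_regions(res$scan,
      quantile = config$top_quantile)
    res$perm_null <- permutation_max_fst(gt, groups, grid,
      n_perm = config$n_perm, seed = .stage_seed(config$seed, "scan"))
    emit_tsv(res$scan, "window_scan.tsv")
    emit_tsv(res$candidates, "candidate_regions.tsv")
    emit_tsv(res$perm_null, "permutation_null.tsv")
  }

  if ("cnv" %in% config$stages) {
    sim <- need("simulate", "cnv")
    ncn <- normalize_depth(res$depth)
    grid100 <- build_windows(sim$truth$config$chromosomes,
      size = config$scan_window)
    res$cnv <- cnv_index(ncn, select(sim$samples, "sample", "group"),
      grid = grid100)
    emit_tsv(res$cnv, "cnv_index.tsv")
    delt <- sim$truth$deletion_truth
    if (!is.null(delt)) {
      res$del_genotypes <- genotype_deletion(ncn, delt[1, ],
        hi = config$pav_hi, lo = config$pav_lo)
      emit_tsv(res$del_genotypes, "deletion_genotypes.tsv")
    }
  }

  if ("te" %in% config$stages) {
    sim <- need("simulate", "te")
    ev <- simulate_te_alignments(sim,
      seed = .stage_seed(config$seed, "te"))
    res$te <- genotype_te_cohort(ev$records, ev$site, ev$te_seq,
      ev$ref_seq, ev$ref_offset, chrom = ev$chrom)
    emit_tsv(res$te, "te_genotypes.tsv")
  }

  if ("gwas" %in% config$stages) {
    sim <- need("simulate", "gwas")
    gt <- res$filter %||% sim$genotypes
    calls <- list()
    if (!is.null(res$del_genotypes)) {
      calls$del <- tibble(sample = res$del_genotypes$sample, sv_id = "chr3D_del",
        present = dplyr::case_when(
          res$del_genotypes$call == "deleted" ~ TRUE,
          res$del_genotypes$call == "present" ~ FALSE,
          .default = NA))
    }
    if (!is.null(res$te)) {
      calls$te <- tibble(sample = res$te$sample, sv_id = "TaQ5A_te",
        present = dplyr::case_when(
          res$te$call == "insertion" ~ TRUE,
          res$te$call == "non_insertion" ~ FALSE,
          .default = NA))
    }
    pcs <- genotype_pca(gt, k = config$n_pcs)
    K <- kinship_matrix(gt)
    phen <- select(sim$samples, "sample", "phenotype")
    if (length(calls)) {
      pseudo <- encode_sv_pseudo_variants(bind_rows(calls))
      res$sv_variance <- purrr::map_dbl(seq_len(n_variants(pseudo)),
        function(j) {
          variance_explained(pseudo[, j], phen, covariates = pcs, K = K)
        })
      names(res$sv_variance) <- paste0(pseudo$variants$chrom, ":",
        pseudo$variants$pos)
      write_vcf(pseudo, out("sv_pseudo.vcf"))
      written <- c(written, out("sv_pseudo.vcf"))
    }
    res$gwas <- mlm_association(gt, phen, covariates = pcs, K = K,
      alpha = config$alpha)
    emit_tsv(tidy(res$gwas), "gwas_results.tsv")
  }

  if ("anchor" %in% config$stages) {
    world <- simulate_scaffold_world(
      seed = .stage_seed(config$seed, "anchor"))
    res$placements <- anchor_scaffolds(world$scaffolds, world$reference,
      min_reads = config$min_reads)
    res$pseudomolecules <- build_pseudomolecules(res$placements,
      world$scaffolds, gap = config$gap)
    emit_tsv(res$placements, "placements.tsv")
    Biostrings::writeXStringSet(res$pseudomolecules$sequences,
      out("pseudomolecules.fa"))
    emit_tsv(res$pseudomolecules$agp, "pseudomolecules.agp")
    written <- c(written, out("pseudomolecules.fa"))
  }

  manifest <- tibble(
    file = basename(written),
    md5 = unname(tools::md5sum(written))
  ) |> arrange(.data$file)
  emit_tsv(manifest, "manifest.tsv")
  res$manifest <- manifest
  res
}
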