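#' Configuration for a synthetic wheat cohort
#'
#' Describes a two-group resequencing cohort with known ground truth:
#' group-divergent windows (an allele-frequency shift `delta` between the
#' first two groups), segmental deletions carried by a fraction of one group,
#' a transposable-element (TE) insertion with a known carrier set, and a
#' binary rachis-brittleness phenotype driven by the structural variants.
#'
#' Defaults emulate the de-domestication study design: a brittle-rachis
#' feral group of 50 (DE) against a domesticated group of 52 (DO),
#' near-homozygous inbred genotypes (heterozygote rate capped at 2%), and a
#' Beta allele-frequency prior.
#'
#' @param n_per_group Named integer vector of samples per group label; the
#'   first two labels receive the divergence shift.
#' @param chromosomes Named numeric vector of chromosome lengths (bp).
#' @param n_sites Total variant count, allocated to chromosomes by length.
#' @param maf_beta Length-2 shape parameters of the Beta prior on the
#'   baseline alt-allele frequency.
#' @param divergent_windows Data frame `chrom`, `start`, `end`, `delta`
#'   (0-based half-open intervals; `delta` in `[0, 1]`).
#' @param deletion_truth Data frame `chrom`, `start`, `end`,
#'   `carrier_group`, `carrier_frac` of true segmental deletions.
#' @param te_truth `NULL`, or a list with `chrom`, `site` (1-based insertion
#'   breakpoint: the TE sits after this base), `te_seq` (161 bp; generated
#'   when `NULL`), `carrier_group`, `carrier_frac`.
#' @param het_rate Probability cap on heterozygous calls (inbred lines).
#' @param missing_rate Per-genotype missingness rate.
#' @param phenotype_misclass Probability a sample's brittle/non-brittle
#'   label is flipped.
#' @param seed RNG seed; a fixed seed makes all outputs byte-identical.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = c(DE = 50, DO = 52),
                          chromosomes = c(chr1A = 1e6, chr1D = 1e6),
                          n_sites = 5000,
                          maf_beta = c(0.8, 0.8),
                          divergent_windows = NULL,
                          deletion_truth = NULL,
                          te_truth = NULL,
                          het_rate = 0.02,
                          missing_rate = 0.02,
                          phenotype_misclass = 0,
                          seed = 1L) {
  stopifnot(length(n_per_group) >= 1, !is.null(names(n_per_group)))
  if (any(n_per_group < 1)) abort("every group needs at least one sample")
  if (!is.null(divergent_windows)) {
    divergent_windows <- as_tibble(divergent_windows)
    if (any(divergent_windows$delta < 0 | divergent_windows$delta > 1)) {
      abort("`delta` must lie in [0, 1]")
    }
    lens <- chromosomes[divergent_windows$chrom]
    if (any(is.na(lens)) || any(divergent_windows$end > lens) ||
      any(divergent_windows$start < 0)) {
      abort("divergent windows must lie within chromosome bounds")
    }
  }
  if (!is.null(deletion_truth)) deletion_truth <- as_tibble(deletion_truth)
  structure(
    list(
      n_per_group = n_per_group, chromosomes = chromosomes,
      n_sites = n_sites, maf_beta = maf_beta,
      divergent_windows = divergent_windows,
      deletion_truth = deletion_truth, te_truth = te_truth,
      het_rate = het_rate, missing_rate = missing_rate,
      phenotype_misclass = phenotype_misclass, seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

# altitude/de-domestication metadata implied by common group labels
.group_meta <- function(label) {
  alt <- c(DE = "HA", DO = "HA", TS = "HA", TL = "HA", HA = "HA",
           LA = "LA", CL = "LA", CC = "LA", NCL = "LA", NCC = "LA")
  ded <- c(DE = "DE", DO = "DO")
  list(altitude = unname(alt[label]), dedom = unname(ded[label]))
}

#' Simulate a genotyped cohort with known truth
#'
#' Draws inbred-style diploid genotypes site by site: a baseline alt-allele
#' frequency from the Beta prior, shifted by `-delta/2` / `+delta/2` in the
#' first / second group inside each divergent window (the baseline is kept in
#' `[delta/2, 1 - delta/2]` so shifted frequencies stay in `[0, 1]`;
#' `delta = 1` therefore yields fixed differences). Structural-variant
#' carriers and the brittleness phenotype are drawn from the configured
#' truth records.
#'
#' @param config A [cohort_config()].
#' @return A list with elements `genotypes` ([genotype_table()]), `samples`
#'   (tibble: `sample`, `group`, `altitude`, `dedom`, `phenotype`), and
#'   `truth` (list: per-site true group frequencies, divergent site ids,
#'   deletion carriers, TE carriers and sequence).
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_sites = 100, seed = 42))
#' cohort$genotypes
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  groups <- rep(names(config$n_per_group), config$n_per_group)
  samples <- sprintf("%s_%03d", groups, unlist(lapply(config$n_per_group, seq_len)))
  n <- length(samples)

  # allocate sites to chromosomes by length, draw sorted unique positions
  alloc <- round(config$n_sites * config$chromosomes / sum(config$chromosomes))
  alloc[1] <- config$n_sites - sum(alloc[-1])
  variants <- purrr::imap(alloc, function(k, ch) {
    tibble(
      chrom = ch,
      pos = sort(sample.int(config$chromosomes[[ch]] - 1L, k)) + 1L
    )
  }) |> bind_rows()
  bases <- c("A", "C", "G", "T")
  m <- nrow(variants)
  variants$ref <- sample(bases, m, replace = TRUE)
  variants$alt <- vapply(variants$ref, function(r) sample(setdiff(bases, r), 1),
    character(1), USE.NAMES = FALSE
  )

  # baseline frequencies, shifted inside divergent windows
  p0 <- stats::rbeta(m, config$maf_beta[1], config$maf_beta[2])
  delta <- numeric(m)
  if (!is.null(config$divergent_windows)) {
    for (i in seq_len(nrow(config$divergent_windows))) {
      w <- config$divergent_windows[i, ]
      hit <- variants$chrom == w$chrom & variants$pos - 1L >= w$start &
        variants$pos - 1L < w$end
      delta[hit] <- w$delta
    }
  }
  p0 <- pmin(pmax(p0, delta / 2), 1 - delta / 2)
  glab <- names(config$n_per_group)
  pg <- matrix(rep(p0, length(glab)), ncol = length(glab))
  colnames(pg) <- glab
  pg[, 1] <- p0 - delta / 2
  if (length(glab) >= 2) pg[, 2] <- p0 + delta / 2

  geno <- matrix(NA_integer_, nrow = n, ncol = m)
  for (g in glab) {
    rows <- which(groups == g)
    pm <- matrix(pg[, g], nrow = length(rows), ncol = m, byrow = TRUE)
    hom <- 2L * matrix(rbinom(length(rows) * m, 1, pm), nrow = length(rows))
    hwe <- matrix(rbinom(length(rows) * m, 2, pm), nrow = length(rows))
    use_hwe <- matrix(runif(length(rows) * m) < config$het_rate, nrow = length(rows))
    geno[rows, ] <- ifelse(use_hwe, hwe, hom)
  }
  if (config$missing_rate > 0) {
    geno[matrix(runif(n * m) < config$missing_rate, nrow = n)] <- NA_integer_
  }

  # structural-variant carrier truth
  del_carriers <- list()
  if (!is.null(config$deletion_truth)) {
    for (i in seq_len(nrow(config$deletion_truth))) {
      d <- config$deletion_truth[i, ]
      pool <- samples[groups == d$carrier_group]
      k <- round(d$carrier_frac * length(pool))
      del_carriers[[i]] <- sort(sample(pool, k))
    }
  }
  te <- config$te_truth
  te_carriers <- character(0)
  if (!is.null(te)) {
    if (is.null(te$te_seq)) {
      te$te_seq <- paste(sample(bases, 161, replace = TRUE), collapse = "")
    }
    if (nchar(te$te_seq) != 161) abort("TE sequence must be 161 bp")
    pool <- samples[groups == te$carrier_group]
    te_carriers <- sort(sample(pool, round(te$carrier_frac * length(pool))))
  }

  # phenotype: brittle when carrying any causal SV, else group-based fallback
  carrier_any <- samples %in% unique(c(unlist(del_carriers), te_carriers))
  if (length(del_carriers) || length(te_carriers)) {
    phen <- as.integer(carrier_any)
  } else {
    phen <- as.integer(groups == glab[1])
  }
  if (config$phenotype_misclass > 0) {
    flip <- runif(n) < config$phenotype_misclass
    phen[flip] <- 1L - phen[flip]
  }

  meta <- .group_meta(groups)
  list(
    genotypes = genotype_table(variants, geno, samples),
    samples = tibble(
      sample = samples, group = groups,
      altitude = meta$altitude, dedom = meta$dedom, phenotype = phen
    ),
    truth = list(
      config = config,
      site_freq = pg, divergent_sites = which(delta > 0),
      deletion_truth = config$deletion_truth,
      deletion_carriers = del_carriers,
      te = te, te_carriers = te_carriers
    )
  )
}

#' Simulate a per-sample, per-window read-depth matrix
#'
#' Window depth is driven by the true copy state (0 inside a deletion
#' carried by the sample, 1 elsewhere). Under `noise = "poisson"` the read
#' count per window is Poisson with mean
#' `mean_cov * copy * width / read_len` and the window mean depth is
#' `count * read_len / width`; `noise = "none"` returns the expectation
#' (the noise-free limit used for exact-recovery tests).
#'
#' @param cohort Result of [simulate_cohort()].
#' @param mean_cov Genome-wide mean coverage per sample (must be positive).
#' @param window_size Depth window size in bp (PAV grid default: 5 kb).
#' @param read_len Read length controlling count granularity.
#' @param noise `"poisson"` or `"none"`.
#' @param seed RNG seed.
#' @return A list of class `depth_matrix`: `depth` (samples x windows),
#'   `grid` (window tibble), `genome_mean` (per-sample width-weighted mean),
#'   `samples`.
#' @export
simulate_depth_matrix <- function(cohort, mean_cov = 10, window_size = 5000,
                                  read_len = 150, noise = c("poisson", "none"),
                                  seed = 1L) {
  noise <- match.arg(noise)
  if (mean_cov <= 0) abort("`mean_cov` must be positive")
  set.seed(as.integer(seed))
  config <- cohort$truth$config
  grid <- build_windows(config$chromosomes, size = window_size)
  samples <- cohort$samples$sample
  nw <- nrow(grid)
  copy <- matrix(1, nrow = length(samples), ncol = nw,
    dimnames = list(samples, NULL)
  )
  delt <- cohort$truth$deletion_truth
  if (!is.null(delt)) {
    for (i in seq_len(nrow(delt))) {
      d <- delt[i, ]
      win <- grid$chrom == d$chrom & grid$start < d$end & grid$end > d$start
      copy[cohort$truth$deletion_carriers[[i]], win] <- 0
    }
  }
  width <- grid$end - grid$start
  lam <- sweep(copy, 2, mean_cov * width / read_len, `*`)
  depth <- if (noise == "poisson") {
    matrix(rpois(length(lam), lam), nrow = nrow(lam), dimnames = dimnames(copy))
  } else {
    lam
  }
  depth <- sweep(depth, 2, read_len / width, `*`)
  structure(
    list(
      depth = depth, grid = grid,
      genome_mean = as.numeric(depth %*% width) / sum(width),
      samples = samples
    ),
    class = "depth_matrix"
  )
}

#' @export
print.depth_matrix <- function(x, ...) {
  cat(
    "<depth_matrix> ", length(x$samples), " samples x ", nrow(x$grid),
    " windows; mean genome-wide depth ",
    sprintf("%.2f", mean(x$genome_mean)), "\n",
    sep = ""
  )
  invisible(x)
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate read evidence at a TE insertion site
#'
#' Builds a local reference around the insertion breakpoint and emits
#' minimal alignment records per sample. Carriers produce junction reads
#' whose soft-clipped tails are exact TE prefixes/suffixes abutting the
#' site; non-carriers produce reads matching the reference across the site.
#' `n_reads = 0` yields empty evidence (genotyped downstream as unknown).
#'
#' @param cohort Result of [simulate_cohort()] whose config carries
#'   `te_truth`.
#' @param n_reads Reads generated per sample.
#' @param read_len Read length (must exceed the clip length + 20).
#' @param clip_len Soft-clip length emitted for carrier junction reads
#'   (> 10 to satisfy the insertion rule).
#' @param flank Reference context kept on each side of the site.
#' @param seed RNG seed.
#' @return A list: `records` (named list of per-sample alignment tibbles
#'   with `qname`, `flag`, `rname`, `pos`, `mapq`, `cigar`, `seq`),
#'   `ref_seq`, `ref_offset` (1-based position of `ref_seq[1]`), `site`,
#'   `te_seq`, `chrom`.
#' @export
simulate_te_alignments <- function(cohort, n_reads = 6, read_len = 100,
                                   clip_len = 25, flank = 400, seed = 1L) {
  te <- cohort$truth$te
  if (is.null(te)) abort("cohort config has no `te_truth`")
  if (read_len <= clip_len + 20) abort("`read_len` too short to span the site")
  set.seed(as.integer(seed))
  site <- te$site
  ref_offset <- site - flank + 1L
  ref_seq <- .random_dna(2L * flank)
  carriers <- cohort$truth$te_carriers
  ref_at <- function(pos, len) {
    substr(ref_seq, pos - ref_offset + 1L, pos - ref_offset + len)
  }
  records <- lapply(cohort$samples$sample, function(s) {
    if (n_reads == 0) {
      return(tibble(
        qname = character(0), flag = integer(0), rname = character(0),
        pos = integer(0), mapq = integer(0), cigar = character(0),
        seq = character(0)
      ))
    }
    recs <- vector("list", n_reads)
    for (i in seq_len(n_reads)) {
      if (s %in% carriers) {
        if (i %% 2 == 1) {
          # left flank into TE: right soft clip of the TE prefix
          mlen <- read_len - clip_len
          pos <- site - mlen + 1L
          seq <- paste0(ref_at(pos, mlen), substr(te$te_seq, 1, clip_len))
          cigar <- sprintf("%dM%dS", mlen, clip_len)
        } else {
          # TE tail into right flank: left soft clip of the TE suffix
          mlen <- read_len - clip_len
          pos <- site + 1L
          seq <- paste0(
            substr(te$te_seq, 161 - clip_len + 1, 161),
            ref_at(pos, mlen)
          )
          cigar <- sprintf("%dS%dM", clip_len, mlen)
        }
      } else {
        off <- sample.int(read_len - 12L, 1) # keep site +/- 5 inside the read
        pos <- site - 5L - off + 1L
        seq <- ref_at(pos, read_len)
        cigar <- sprintf("%dM", read_len)
      }
      recs[[i]] <- tibble(
        qname = sprintf("%s_r%03d", s, i), flag = 0L, rname = te$chrom,
        pos = as.integer(pos), mapq = 60L, cigar = cigar, seq = seq
      )
    }
    bind_rows(recs)
  })
  names(records) <- cohort$samples$sample
  list(
    records = records, ref_seq = ref_seq, ref_offset = ref_offset,
    site = site, te_seq = te$te_seq, chrom = te$chrom
  )
}

#' Simulate a scaffold world with known placements
#'
#' Cuts scaffolds out of random reference chromosomes (some
#' reverse-complemented), and adds unplaceable scaffolds: random sequence
#' absent from the reference and, optionally, a fragment too short to yield
#' probe reads. Truth records chromosome, 0-based offset, and strand
#' (`"chrUn"` / `"*"` for unplaceable).
#'
#' @param n_chrom Number of reference chromosomes.
#' @param chrom_len Length of each chromosome (bp).
#' @param n_scaffolds Number of placeable scaffolds cut from the reference.
#' @param scaffold_len Range (min, max) of placeable scaffold lengths.
#' @param n_random Number of random unplaceable scaffolds.
#' @param short_scaffold Add one scaffold shorter than the probe span.
#' @param seed RNG seed.
#' @return A list: `reference`, `scaffolds` (both
#'   [Biostrings::DNAStringSet]), `truth` tibble (`scaffold`, `chrom`,
#'   `offset`, `strand`).
#' @export
simulate_scaffold_world <- function(n_chrom = 3, chrom_len = 2e5,
                                    n_scaffolds = 20,
                                    scaffold_len = c(11000, 30000),
                                    n_random = 2, short_scaffold = TRUE,
                                    seed = 1L) {
  set.seed(as.integer(seed))
  chroms <- sprintf("chr%d%s", rep(1:7, length.out = n_chrom),
    rep(c("A", "B", "D"), length.out = n_chrom)
  )
  ref <- setNames(vapply(chroms, function(x) .random_dna(chrom_len),
    character(1)
  ), chroms)
  truth <- list()
  seqs <- character(0)
  used <- lapply(chroms, function(x) integer(0))
  names(used) <- chroms
  for (i in seq_len(n_scaffolds)) {
    len <- sample(seq(scaffold_len[1], scaffold_len[2], by = 1000), 1)
    repeat {
      ch <- sample(chroms, 1)
      off <- sample.int(chrom_len - len, 1) - 1L
      span <- seq(off, off + len - 1L)
      if (!any(span %in% used[[ch]])) break
    }
    used[[ch]] <- c(used[[ch]], span)
    strand <- sample(c("+", "-"), 1)
    s <- substr(ref[[ch]], off + 1L, off + len)
    if (strand == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    id <- sprintf("scaffold%02d", i)
    seqs[id] <- s
    truth[[id]] <- tibble(scaffold = id, chrom = ch, offset = off, strand = strand)
  }
  for (i in seq_len(n_random)) {
    id <- sprintf("random%02d", i)
    seqs[id] <- .random_dna(15000)
    truth[[id]] <- tibble(scaffold = id, chrom = "chrUn", offset = NA_integer_,
      strand = "*")
  }
  if (short_scaffold) {
    seqs[["short01"]] <- .random_dna(600)
    truth[["short01"]] <- tibble(scaffold = "short01", chrom = "chrUn",
      offset = NA_integer_, strand = "*")
  }
  list(
    reference = Biostrings::DNAStringSet(ref),
    scaffolds = Biostrings::DNAStringSet(seqs),
    truth = bind_rows(truth)
  )
}
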