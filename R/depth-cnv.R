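#' Normalised coverage number (NCN)
#'
#' Divides each sample's per-window mean depth by its genome-wide mean
#' depth, giving a unitless copy-state proxy (1 for single-copy presence, 0
#' for absence). Samples with zero genome-wide mean are dropped with a
#' warning. NCN is invariant to uniform per-sample depth rescaling.
#'
#' @param depth A `depth_matrix` (see [simulate_depth_matrix()]) or a plain
#'   samples x windows matrix plus `grid`.
#' @param grid Window grid (required when `depth` is a bare matrix).
#' @return A list of class `ncn_matrix`: `ncn` (samples x windows), `grid`,
#'   `samples`.
#' @export
normalize_depth <- function(depth, grid = NULL) {
  if (inherits(depth, "depth_matrix")) {
    mat <- depth$depth
    grid <- depth$grid
    gm <- depth$genome_mean
  } else {
    mat <- as.matrix(depth)
    if (is.null(grid)) abort("`grid` is required for a bare depth matrix")
    w <- grid$end - grid$start
    gm <- as.numeric(mat %*% w) / sum(w)
  }
  if (any(mat < 0)) abort("depths must be non-negative")
  drop <- gm <= 0
  if (any(drop)) {
    warn(sprintf("dropping %d sample(s) with zero genome-wide depth", sum(drop)))
    mat <- mat[!drop, , drop = FALSE]
    gm <- gm[!drop]
  }
  structure(
    list(ncn = sweep(mat, 1, gm, `/`), grid = grid, samples = rownames(mat)),
    class = "ncn_matrix"
  )
}

.ncn_vector <- function(ncn, who = NULL) {
  if (inherits(ncn, "ncn_matrix")) {
    m <- ncn$ncn
    if (!is.null(who)) m <- m[who, , drop = FALSE]
    colMeans(m)
  } else {
    as.numeric(ncn)
  }
}

#' Call presence-absence variation (PAV) regions from paired NCN tracks
#'
#' A window is "retained in self / absent in other" when the self-genome
#' track covers it normally (`NCN > hi`, strict) while the other genome's
#' reads barely cover it (`NCN < lo`, strict). Selected windows closer than
#' `merge_gap` bp are merged into one region (a gap of exactly `merge_gap`
#' is not merged). Calls are invariant to uniform per-sample rescaling and
#' merging is idempotent.
#'
#' @param ncn_self,ncn_other Per-window NCN vectors on the same grid (or
#'   `ncn_matrix` objects whose per-window mean is used).
#' @param grid The shared (5 kb) window grid.
#' @param hi,lo Retention / absence thresholds (defaults 0.8 / 0.2).
#' @param merge_gap Merge window gap in bp (default 10 kb).
#' @return A tibble of PAV calls: `chrom`, `start`, `end`, `n_windows`,
#'   `direction`.
#' @export
call_pav_regions <- function(ncn_self, ncn_other, grid, hi = 0.8, lo = 0.2,
                             merge_gap = 10000) {
  self <- .ncn_vector(ncn_self)
  other <- .ncn_vector(ncn_other)
  if (length(self) != nrow(grid) || length(other) != nrow(grid)) {
    abort("NCN tracks and grid have mismatched window counts")
  }
  sel <- self > hi & other < lo
  hits <- grid[which(sel), ]
  if (nrow(hits) == 0) {
    return(tibble(
      chrom = character(0), start = numeric(0), end = numeric(0),
      n_windows = integer(0), direction = character(0)
    ))
  }
  hits <- arrange(hits, .data$chrom, .data$start)
  merged <- list()
  cur <- hits[1, ]
  cur$n_windows <- 1L
  for (i in seq_len(nrow(hits))[-1]) {
    h <- hits[i, ]
    if (h$chrom == cur$chrom && (h$start - cur$end) < merge_gap) {
      cur$end <- h$end
      cur$n_windows <- cur$n_windows + 1L
    } else {
      merged[[length(merged) + 1]] <- cur
      cur <- h
      cur$n_windows <- 1L
    }
  }
  merged[[length(merged) + 1]] <- cur
  bind_rows(merged) |>
    select("chrom", "start", "end", "n_windows") |>
    mutate(direction = "retained_in_self")
}

#' Call PAV genes from gene-level normalised depth
#'
#' Gene mean depth is computed from overlapping windows weighted by overlap
#' length, normalised genome-wide, and the same `hi`/`lo` rule as
#' [call_pav_regions()] is applied per gene.
#'
#' @param genes Data frame `gene`, `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param ncn_self,ncn_other Per-window NCN vectors (or `ncn_matrix`).
#' @param grid Window grid.
#' @inheritParams call_pav_regions
#' @return A tibble: `gene`, `chrom`, `start`, `end`, `ncn_self`,
#'   `ncn_other`, `pav` (logical: retained in self / absent in other).
#' @export
call_pav_genes <- function(genes, ncn_self, ncn_other, grid, hi = 0.8,
                           lo = 0.2) {
  genes <- as_tibble(genes)
  if (any(genes$end <= genes$start)) abort("zero-length gene interval")
  self <- .ncn_vector(ncn_self)
  other <- .ncn_vector(ncn_other)
  gene_ncn <- function(track, g) {
    win <- grid$chrom == g$chrom & grid$start < g$end & grid$end > g$start
    if (!any(win)) return(NA_real_)
    ov <- pmin(grid$end[win], g$end) - pmax(grid$start[win], g$start)
    sum(track[win] * ov) / sum(ov)
  }
  genes$ncn_self <- vapply(seq_len(nrow(genes)),
    function(i) gene_ncn(self, genes[i, ]), numeric(1))
  genes$ncn_other <- vapply(seq_len(nrow(genes)),
    function(i) gene_ncn(other, genes[i, ]), numeric(1))
  genes$pav <- !is.na(genes$ncn_self) & !is.na(genes$ncn_other) &
    genes$ncn_self > hi & genes$ncn_other < lo
  genes
}

#' CNV-index between de-domesticated and domesticated groups
#'
#' For each (100 kb) window, the group means of NCN are compared:
#' `cnv_index = NCN_DO - NCN_DE`. Positive values indicate more accessions
#' in the de-domesticated (DE) group carry a segmental deletion in the
#' window; swapping the groups flips the sign exactly.
#'
#' @param ncn An `ncn_matrix` from [normalize_depth()].
#' @param sample_groups Data frame `sample`, `group`; the first group label
#'   is DE-like (deletion-enriched), the second DO-like.
#' @param grid Optional coarser grid (e.g. 100 kb) onto which the NCN grid
#'   is averaged (width-weighted); defaults to the NCN grid itself.
#' @return A tibble: `chrom`, `start`, `end`, `window_id`, `ncn_de`,
#'   `ncn_do`, `cnv_index`.
#' @export
cnv_index <- function(ncn, sample_groups, grid = NULL) {
  stopifnot(inherits(ncn, "ncn_matrix"))
  sample_groups <- as_tibble(sample_groups)
  lev <- unique(sample_groups$group)
  if (length(lev) != 2) abort("exactly two groups are required")
  de <- sample_groups$sample[sample_groups$group == lev[1]]
  do_ <- sample_groups$sample[sample_groups$group == lev[2]]
  if (!length(de) || !length(do_)) abort("both groups must be nonempty")
  ncn_de <- .ncn_vector(ncn, de)
  ncn_do <- .ncn_vector(ncn, do_)
  base <- ncn$grid
  if (!is.null(grid)) {
    w <- base$end - base$start
    agg <- function(v) {
      out <- numeric(nrow(grid))
      for (i in seq_len(nrow(grid))) {
        win <- base$chrom == grid$chrom[i] & base$start < grid$end[i] &
          base$end > grid$start[i]
        ov <- pmin(base$end[win], grid$end[i]) - pmax(base$start[win], grid$start[i])
        out[i] <- if (any(win)) sum(v[win] * ov) / sum(ov) else NA_real_
      }
      out
    }
    ncn_de <- agg(ncn_de)
    ncn_do <- agg(ncn_do)
    base <- grid
  }
  base |>
    mutate(ncn_de = ncn_de, ncn_do = ncn_do, cnv_index = ncn_do - ncn_de) |>
    as_tibble()
}

#' Genotype a known segmental deletion per sample
#'
#' The mean regional NCN (windows overlapping the region, width-weighted)
#' is thresholded: `< lo` is a deletion carrier, `> hi` present, anything
#' between is left unknown rather than forced to a binary call.
#'
#' @param ncn An `ncn_matrix`.
#' @param region List or one-row data frame with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param hi,lo Presence / deletion thresholds (defaults 0.8 / 0.2).
#' @return A tibble: `sample`, `regional_ncn`, `call` in
#'   `{"deleted", "present", "unknown"}`.
#' @export
genotype_deletion <- function(ncn, region, hi = 0.8, lo = 0.2) {
  stopifnot(inherits(ncn, "ncn_matrix"))
  grid <- ncn$grid
  win <- grid$chrom == region$chrom & grid$start < region$end &
    grid$end > region$start
  if (!any(win)) abort("region does not overlap the depth grid")
  ov <- pmin(grid$end[win], region$end) - pmax(grid$start[win], region$start)
  regional <- as.numeric(ncn$ncn[, win, drop = FALSE] %*% ov) / sum(ov)
  tibble(
    sample = ncn$samples,
    regional_ncn = regional,
    call = ifelse(regional < lo, "deleted",
      ifelse(regional > hi, "present", "unknown"))
  )
}
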