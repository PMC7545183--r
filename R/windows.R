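#' Tile chromosomes into a fixed window grid
#'
#' Builds the sliding/tiling window grid on which all windowed statistics
#' (FST, pi, CNV-index, depth normalisation) are computed. The scan defaults
#' are 100 kb windows with a 100 kb step; the PAV depth grid uses 5 kb.
#'
#' Coordinates are 0-based half-open internally; `start`/`end` columns follow
#' that convention (BED-like), and 1-based inclusive coordinates are used only
#' when formatting output files.
#'
#' @param chrom_lengths Named numeric vector (or two-column data frame with
#'   columns `chrom`, `length`) of chromosome lengths in bp.
#' @param size Window size in bp.
#' @param step Window step in bp. `step > size` leaves gaps and is flagged
#'   with a warning.
#' @return A tibble with columns `chrom`, `start`, `end`, `window_id`. The
#'   terminal window of each chromosome is truncated at the chromosome end.
#' @examples
#' build_windows(c(chr1A = 250e3), size = 100e3, step = 100e3)
#' @export
build_windows <- function(chrom_lengths, size, step = size) {
  if (is.data.frame(chrom_lengths)) {
    chrom_lengths <- setNames(chrom_lengths$length, chrom_lengths$chrom)
  }
  stopifnot(length(chrom_lengths) > 0, !is.null(names(chrom_lengths)))
  if (size <= 0 || step <= 0) abort("`size` and `step` must be positive")
  if (step > size) warn("step > size: window grid leaves uncovered gaps")
  grids <- purrr::imap(chrom_lengths, function(len, chrom) {
    starts <- seq(0, max(0, len - 1), by = step)
    starts <- starts[starts < len]
    tibble(chrom = chrom, start = starts, end = pmin(starts + size, len))
  })
  out <- bind_rows(grids)
  out$window_id <- seq_len(nrow(out))
  out
}

#' Assign a wheat chromosome name to its subgenome
#'
#' Hexaploid wheat carries three homoeologous subgenomes (A, B, D); scan
#' thresholds are computed separately for the A&B set and the D set because
#' of extensive wild-relative introgression into A and B. The terminal letter
#' of names like `chr5A` / `chr3D` determines the subgenome; anything else
#' (including `chrUn`) maps to `"Un"`.
#'
#' @param chrom_name Character vector of chromosome names.
#' @return Character vector over `{"A", "B", "D", "Un"}`.
#' @examples
#' assign_subgenome(c("chr5A", "chr3D", "chrUn"))
#' @export
assign_subgenome <- function(chrom_name) {
  last <- toupper(sub("^.*?([A-Za-z])$", "\\1", chrom_name))
  out <- ifelse(last %in% c("A", "B", "D") & grepl("[0-9][ABDabd]$", chrom_name),
    last, "Un"
  )
  unname(out)
}

#' Partition label used for separate scan thresholds
#'
#' Maps a subgenome letter to the threshold partition: A and B share one
#' empirical distribution ("AB"), D has its own ("D"); unknown chromosomes
#' fall into "Un" and take no part in threshold setting.
#'
#' @param chrom_name Character vector of chromosome names.
#' @return Character vector over `{"AB", "D", "Un"}`.
#' @export
subgenome_partition <- function(chrom_name) {
  sg <- assign_subgenome(chrom_name)
  ifelse(sg %in% c("A", "B"), "AB", ifelse(sg == "D", "D", "Un"))
}

# map positions (1-based) onto a window grid; returns window_id or NA
.window_of <- function(grid, chrom, pos) {
  out <- rep(NA_integer_, length(pos))
  for (ch in unique(chrom)) {
    g <- grid[grid$chrom == ch, ]
    if (nrow(g) == 0) next
    sel <- which(chrom == ch)
    idx <- findInterval(pos[sel] - 1L, g$start)
    ok <- idx >= 1 & (pos[sel] - 1L) < g$end[pmax(idx, 1L)]
    out[sel[ok]] <- g$window_id[idx[ok]]
  }
  out
}
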