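#' Simulate probe read pairs along scaffolds
#'
#' Deterministic paired-end probe reads used to anchor scaffolds onto a
#' reference: 500 bp mates with a 500 bp insert at a 1000 bp step. The pair
#' span defaults to 1000 bp (two abutting mates — "insert" read as fragment
#' spacing); `insert_mode = "inner"` instead places a 500 bp gap between the
#' mates (span 1500 bp). A scaffold shorter than the span yields zero reads.
#' The pair count per scaffold is `floor((L - span) / step) + 1`.
#'
#' @param scaffolds A [Biostrings::DNAStringSet] (or named character
#'   vector) of scaffold sequences.
#' @param read_len Mate length (default 500).
#' @param insert Insert size (default 500).
#' @param step Step between pair origins (default 1000).
#' @param insert_mode `"span"` (default: total pair span =
#'   `read_len + insert`) or `"inner"` (span = `2 * read_len + insert`).
#' @return A tibble of probe reads: `scaffold`, `ordinal` (0-based along
#'   the scaffold), `mate`, `offset` (0-based scaffold offset), `seq`.
#' @export
simulate_probe_reads <- function(scaffolds, read_len = 500, insert = 500,
                                 step = 1000,
                                 insert_mode = c("span", "inner")) {
  insert_mode <- match.arg(insert_mode)
  if (inherits(scaffolds, "DNAStringSet")) {
    scaffolds <- setNames(as.character(scaffolds), names(scaffolds))
  }
  span <- if (insert_mode == "span") read_len + insert else 2 * read_len + insert
  mate2_off <- span - read_len
  out <- purrr::imap(scaffolds, function(s, id) {
    L <- nchar(s)
    if (L < span) {
      inform(sprintf("scaffold %s shorter than pair span; no probe reads", id))
      return(NULL)
    }
    n_pairs <- floor((L - span) / step) + 1
    origins <- (seq_len(n_pairs) - 1) * step
    tibble(
      scaffold = id,
      ordinal = as.integer(rep(2 * (seq_len(n_pairs) - 1), each = 2) + c(0, 1)),
      mate = rep(c(1L, 2L), n_pairs),
      offset = as.integer(rep(origins, each = 2) + c(0, mate2_off)),
      seq = vapply(
        rep(origins, each = 2) + c(0, mate2_off),
        function(o) substr(s, o + 1, o + read_len), character(1)
      )
    )
  })
  bind_rows(out)
}

#' Map probe reads to a reference by unique exact match
#'
#' Each read is located in the reference on either strand; reads occurring
#' exactly once (over both strands and all chromosomes) report a hit,
#' anything else is unmapped. At desk scale this unique-exact-substring
#' matcher plays the role a short-read aligner plays at genome scale.
#'
#' @param reads Probe-read tibble from [simulate_probe_reads()].
#' @param reference A [Biostrings::DNAStringSet] of chromosomes.
#' @return `reads` with `chrom`, `pos` (0-based reference offset), and
#'   `strand` columns (`NA` / `"*"` when unmapped or ambiguous).
#' @export
map_probe_reads <- function(reads, reference) {
  stopifnot(inherits(reference, "DNAStringSet"))
  chroms <- names(reference)
  n <- nrow(reads)
  chrom <- rep(NA_character_, n)
  pos <- rep(NA_integer_, n)
  strand <- rep("*", n)
  for (i in seq_len(n)) {
    pat <- Biostrings::DNAString(reads$seq[i])
    hits <- list()
    for (ch in chroms) {
      fwd <- Biostrings::start(Biostrings::matchPattern(pat, reference[[ch]]))
      rev <- Biostrings::start(Biostrings::matchPattern(
        Biostrings::reverseComplement(pat), reference[[ch]]
      ))
      for (p in fwd) hits[[length(hits) + 1]] <- list(ch, p - 1L, "+")
      for (p in rev) hits[[length(hits) + 1]] <- list(ch, p - 1L, "-")
    }
    if (length(hits) == 1) {
      chrom[i] <- hits[[1]][[1]]
      pos[i] <- hits[[1]][[2]]
      strand[i] <- hits[[1]][[3]]
    }
  }
  reads$chrom <- chrom
  reads$pos <- pos
  reads$strand <- strand
  reads
}

#' Assign each scaffold to a chromosome by majority probe-read vote
#'
#' The winning chromosome is the one with the most mapped probe reads;
#' scaffolds whose best chromosome attracts fewer than `min_reads` reads
#' (default 22, counting single reads) are reserved for chrUn. Ties are
#' broken lexicographically and logged.
#'
#' @param hits Mapped reads from [map_probe_reads()].
#' @param scaffolds Optional character vector of all scaffold ids, so
#'   scaffolds without a single mapped read still appear (as chrUn).
#' @param min_reads Assignment threshold (default 22).
#' @return A tibble: `scaffold`, `chrom` (or `"chrUn"`), `n_supporting`.
#' @export
assign_chromosome <- function(hits, scaffolds = NULL, min_reads = 22) {
  tab <- hits |>
    filter(!is.na(.data$chrom)) |>
    dplyr::count(.data$scaffold, .data$chrom, name = "n_hits")
  best <- tab |>
    group_by(.data$scaffold) |>
    arrange(dplyr::desc(.data$n_hits), .data$chrom, .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup()
  tie <- tab |>
    group_by(.data$scaffold) |>
    filter(sum(.data$n_hits == max(.data$n_hits)) > 1) |>
    ungroup()
  if (nrow(tie)) {
    inform(sprintf(
      "chromosome-assignment tie for %d scaffold(s); broken lexicographically",
      length(unique(tie$scaffold))
    ))
  }
  out <- tibble(
    scaffold = best$scaffold,
    chrom = ifelse(best$n_hits >= min_reads, best$chrom, "chrUn"),
    n_supporting = best$n_hits
  )
  if (!is.null(scaffolds)) {
    missing <- setdiff(scaffolds, out$scaffold)
    if (length(missing)) {
      out <- bind_rows(out, tibble(
        scaffold = missing, chrom = "chrUn", n_supporting = 0L
      ))
      out <- out[match(scaffolds, out$scaffold), ]
    }
  }
  out
}

# find runs of >= k consecutive ordinals on one chromosome/strand with
# reference positions advancing monotonically within tol
.aligned_runs <- function(h, k = 5, step = 1000, tol = 2 * step) {
  h <- arrange(h, .data$ordinal)
  runs <- list()
  start <- 1
  i <- 2
  while (i <= nrow(h) + 1) {
    ok <- i <= nrow(h) &&
      h$ordinal[i] == h$ordinal[i - 1] + 1L &&
      !is.na(h$chrom[i]) && !is.na(h$chrom[i - 1]) &&
      h$chrom[i] == h$chrom[i - 1] &&
      h$strand[i] == h$strand[i - 1] &&
      {
        d <- h$pos[i] - h$pos[i - 1]
        if (h$strand[i] == "+") d > 0 && d <= tol else d < 0 && -d <= tol
      }
    if (!ok) {
      if (i - start >= k) runs[[length(runs) + 1]] <- h[start:(i - 1), ]
      start <- i
    }
    i <- i + 1
  }
  runs
}

#' Place and orient an assigned scaffold on its chromosome
#'
#' Follows the first-five / last-five rule: among the scaffold's reads
#' mapped to the assigned chromosome, the first and last runs of at least
#' five continuously aligned reads (consecutive ordinals, same strand,
#' monotone positions within `2 * step`) fix the relative position (mean
#' reference position of the two runs) and the orientation (strand of the
#' runs / direction of travel). Scaffolds without such a run are demoted
#' to chrUn.
#'
#' @param hits Mapped reads of one scaffold (rows of [map_probe_reads()]
#'   output).
#' @param chrom The chromosome assigned by [assign_chromosome()].
#' @param run_len Run length required (default 5).
#' @param step Probe step used for the monotonicity tolerance.
#' @return One-row tibble: `chrom`, `position`, `orientation` (`"+"` /
#'   `"-"`), `placed` (FALSE on demotion).
#' @export
place_and_orient <- function(hits, chrom, run_len = 5, step = 1000) {
  h <- hits[!is.na(hits$chrom) & hits$chrom == chrom, ]
  runs <- if (nrow(h) >= run_len) .aligned_runs(h, k = run_len, step = step)
    else list()
  if (!length(runs)) {
    inform("no continuous run; scaffold demoted to chrUn")
    return(tibble(chrom = "chrUn", position = NA_real_,
      orientation = "*", placed = FALSE))
  }
  first <- runs[[1]]
  last <- runs[[length(runs)]]
  pos_key <- mean(c(mean(first$pos), mean(last$pos)))
  strand <- first$strand[1]
  orientation <- if (strand == "+") "+" else "-"
  tibble(chrom = chrom, position = pos_key, orientation = orientation,
    placed = TRUE)
}

#' Anchor scaffolds: assignment, placement, and orientation in one pass
#'
#' Convenience wrapper running [simulate_probe_reads()],
#' [map_probe_reads()], [assign_chromosome()], and [place_and_orient()]
#' over a scaffold set.
#'
#' @param scaffolds A [Biostrings::DNAStringSet] of scaffolds.
#' @param reference A [Biostrings::DNAStringSet] of chromosomes.
#' @param min_reads chrUn threshold (default 22).
#' @param read_len,insert,step Probe-read geometry.
#' @return A placement tibble: `scaffold`, `chrom`, `position`,
#'   `orientation`, `n_supporting`, `placed`.
#' @export
anchor_scaffolds <- function(scaffolds, reference, min_reads = 22,
                             read_len = 500, insert = 500, step = 1000) {
  reads <- simulate_probe_reads(scaffolds, read_len = read_len,
    insert = insert, step = step)
  hits <- if (nrow(reads)) map_probe_reads(reads, reference) else reads
  assign <- assign_chromosome(hits, scaffolds = names(scaffolds),
    min_reads = min_reads)
  placements <- purrr::pmap(assign, function(scaffold, chrom, n_supporting) {
    if (chrom == "chrUn") {
      return(tibble(scaffold = scaffold, chrom = "chrUn",
        position = NA_real_, orientation = "*",
        n_supporting = n_supporting, placed = FALSE))
    }
    p <- place_and_orient(hits[hits$scaffold == scaffold, ], chrom)
    tibble(scaffold = scaffold, chrom = p$chrom, position = p$position,
      orientation = p$orientation, n_supporting = n_supporting,
      placed = p$placed)
  })
  bind_rows(placements)
}

#' Build pseudomolecules from placed scaffolds
#'
#' Scaffolds assigned to each chromosome are ordered by their position
#' key (ties broken by scaffold id), reverse-complemented when oriented
#' `"-"`, and concatenated with `gap` N bases between neighbours (300 bp
#' by default). Unplaced scaffolds are concatenated the same way into
#' chrUn. An AGP v2.1 table consistent with the FASTA is returned.
#'
#' @param placements Placement tibble from [anchor_scaffolds()].
#' @param scaffolds A [Biostrings::DNAStringSet] of scaffold sequences.
#' @param gap Gap size in N bases (default 300).
#' @return A list: `sequences` ([Biostrings::DNAStringSet] of
#'   pseudomolecules), `agp` (tibble with AGP v2.1 columns).
#' @export
build_pseudomolecules <- function(placements, scaffolds, gap = 300) {
  stopifnot(inherits(scaffolds, "DNAStringSet"))
  placements <- as_tibble(placements)
  placements$chrom[!placements$placed] <- "chrUn"
  seqs <- list()
  agp <- list()
  for (ch in unique(placements$chrom)) {
    rows <- placements[placements$chrom == ch, ]
    rows <- rows[order(rows$position, rows$scaffold), ]
    parts <- character(0)
    cursor <- 0L
    part_n <- 0L
    for (i in seq_len(nrow(rows))) {
      if (i > 1) {
        part_n <- part_n + 1L
        agp[[length(agp) + 1]] <- tibble(
          object = ch, object_beg = cursor + 1L, object_end = cursor + gap,
          part_number = part_n, component_type = "U", component_id = as.character(gap),
          component_beg = "scaffold", component_end = "yes", orientation = "paired-ends"
        )
        parts <- c(parts, strrep("N", gap))
        cursor <- cursor + as.integer(gap)
      }
      s <- as.character(scaffolds[[rows$scaffold[i]]])
      if (rows$orientation[i] == "-") s <- .revcomp_chr(s)
      part_n <- part_n + 1L
      agp[[length(agp) + 1]] <- tibble(
        object = ch, object_beg = cursor + 1L, object_end = cursor + nchar(s),
        part_number = part_n, component_type = "W",
        component_id = rows$scaffold[i], component_beg = "1",
        component_end = as.character(nchar(s)), orientation = rows$orientation[i]
      )
      parts <- c(parts, s)
      cursor <- cursor + nchar(s)
    }
    seqs[[ch]] <- paste(parts, collapse = "")
  }
  ord <- order(names(seqs) == "chrUn", names(seqs))
  list(
    sequences = Biostrings::DNAStringSet(unlist(seqs)[ord]),
    agp = bind_rows(agp)
  )
}

#' Assembly summary statistics
#'
#' Standard Nx statistics plus the gap fraction: `Nx` is the sequence
#' length at which the cumulative sorted-descending length first reaches
#' x% of the total; `gap_fraction = gap_bases / total`.
#'
#' @param lengths Numeric vector of sequence lengths (nonempty).
#' @param gap_bases Total assembly gap bases (default 0).
#' @return A tibble: `n50`, `n90`, `max`, `total`, `gap_fraction`.
#' @examples
#' assembly_stats(c(5, 4, 3, 2, 1)) # N50 = 4
#' @export
assembly_stats <- function(lengths, gap_bases = 0) {
  if (!length(lengths)) abort("`lengths` must be nonempty")
  s <- sort(lengths, decreasing = TRUE)
  cum <- cumsum(s)
  nx <- function(x) s[which(cum >= x / 100 * sum(s))[1]]
  tibble(
    n50 = nx(50), n90 = nx(90), max = s[1], total = sum(s),
    gap_fraction = gap_bases / sum(s)
  )
}
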