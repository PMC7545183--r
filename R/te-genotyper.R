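# parse a CIGAR string into op/length tibble; supports M, I, D, S, H, N, =, X
.parse_cigar <- function(cigar) {
  if (cigar == "*") return(tibble(op = character(0), len = integer(0)))
  ops <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)[[1]]
  if (ops[1] == -1) abort(sprintf("malformed CIGAR: %s", cigar))
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  tibble(
    op = substr(toks, nchar(toks), nchar(toks)),
    len = as.integer(substr(toks, 1, nchar(toks) - 1L))
  )
}

# map reference positions to read offsets; returns per-base alignment:
# tibble(refpos, readpos, op) for M/=/X ops, plus clip records
.align_walk <- function(pos, cigar) {
  cg <- .parse_cigar(cigar)
  refp <- pos
  readp <- 1L
  rows <- vector("list", nrow(cg))
  for (i in seq_len(nrow(cg))) {
    op <- cg$op[i]
    len <- cg$len[i]
    rows[[i]] <- tibble(
      op = op, len = len, ref_start = refp, read_start = readp
    )
    if (op %in% c("M", "=", "X")) {
      refp <- refp + len
      readp <- readp + len
    } else if (op %in% c("I", "S")) {
      readp <- readp + len
    } else if (op %in% c("D", "N")) {
      refp <- refp + len
    }
    # H, P consume nothing here
  }
  bind_rows(rows)
}

.revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# does `clip` match the TE sequence per the strict rule: exact identity,
# length > min_len, against either TE end on either strand?
.clip_match_len <- function(clip, te_seq, min_len = 10L) {
  L <- nchar(clip)
  if (L <= min_len) return(0L)
  te_len <- nchar(te_seq)
  cand <- unique(c(clip, .revcomp_chr(clip)))
  for (cc in cand) {
    k <- min(L, te_len)
    # a clip longer than the TE must contain the whole TE at the junction end
    if (substr(cc, 1, k) == substr(te_seq, 1, k)) return(L)
    if (substr(cc, L - k + 1L, L) == substr(te_seq, te_len - k + 1L, te_len)) {
      return(L)
    }
  }
  0L
}

#' Classify one sample at a TE insertion site
#'
#' Implements the strict two-rule soft-clip genotyping of a known
#' transposable-element insertion (the 161 bp TE in the fifth exon of
#' *TaQ-5A* at chr5A:650129563 is the motivating case):
#'
#' * Rule 1 (checked first): at least two reads spanning the site window
#'   (`site` plus/minus `span_flank` bp) with an all-match CIGAR across the
#'   window and zero mismatches to the reference there classify the sample
#'   as `non_insertion`.
#' * Rule 2: any read soft-clipped with its clip boundary within 2 bp of
#'   the site whose clipped bases match the TE sequence with 100% identity
#'   over a length strictly greater than 10 bp (either TE end, either
#'   strand) classifies the sample as `insertion`.
#' * Otherwise the sample is `unknown` (insufficient evidence).
#'
#' Rule order is total: a sample satisfying both rules is `non_insertion`
#' and flagged as a conflict.
#'
#' @param records Alignment tibble (`rname`, `pos`, `cigar`, `seq`; extra
#'   columns ignored) for one sample.
#' @param site 1-based insertion breakpoint (TE inserted after this base).
#' @param te_seq The TE sequence (161 bp for the *TaQ-5A* insertion).
#' @param ref_seq Local reference sequence around the site.
#' @param ref_offset 1-based reference position of `ref_seq[1]`.
#' @param chrom Reference name records must match (default: taken from the
#'   records themselves if unique).
#' @param span_flank Half-width of the perfect-match window (default 5 bp).
#' @return One-row tibble: `call`, `n_perfect_spanning`,
#'   `best_clip_match_len`, `conflict`.
#' @export
classify_te_sample <- function(records, site, te_seq, ref_seq, ref_offset,
                               chrom = NULL, span_flank = 5L) {
  records <- as_tibble(records)
  if (!is.null(chrom)) {
    bad <- records$rname != chrom
    if (any(bad)) abort("alignment records on the wrong reference name")
  }
  win_lo <- site - span_flank
  win_hi <- site + span_flank
  n_perfect <- 0L
  best_clip <- 0L
  for (i in seq_len(nrow(records))) {
    walk <- .align_walk(records$pos[i], records$cigar[i])
    mm <- walk[walk$op %in% c("M", "=", "X"), ]
    # perfect spanning: one match block covering the whole window,
    # read bases equal to reference over the window
    span <- mm[mm$ref_start <= win_lo & mm$ref_start + mm$len > win_hi, ]
    if (nrow(span) >= 1) {
      b <- span[1, ]
      read_lo <- b$read_start + (win_lo - b$ref_start)
      nwin <- win_hi - win_lo + 1L
      read_bases <- substr(records$seq[i], read_lo, read_lo + nwin - 1L)
      ref_bases <- substr(ref_seq, win_lo - ref_offset + 1L,
        win_hi - ref_offset + 1L)
      if (identical(read_bases, ref_bases)) n_perfect <- n_perfect + 1L
    }
    # soft clips abutting the site (within 2 bp)
    clips <- walk[walk$op == "S", ]
    for (j in seq_len(nrow(clips))) {
      cl <- clips[j, ]
      boundary <- if (cl$read_start == 1L) {
        records$pos[i] - 1L # left clip: junction just before POS
      } else {
        cl$ref_start - 1L # right clip: last aligned reference base
      }
      if (abs(boundary - site) > 2L) next
      clip_seq <- substr(records$seq[i], cl$read_start,
        cl$read_start + cl$len - 1L)
      best_clip <- max(best_clip, .clip_match_len(clip_seq, te_seq))
    }
  }
  call <- if (n_perfect >= 2L) {
    "non_insertion"
  } else if (best_clip > 0L) {
    "insertion"
  } else {
    "unknown"
  }
  tibble(
    call = call, n_perfect_spanning = n_perfect,
    best_clip_match_len = best_clip,
    conflict = n_perfect >= 2L && best_clip > 0L
  )
}

#' Genotype a cohort at a TE insertion site
#'
#' Applies [classify_te_sample()] to each sample's alignment records.
#' Samples with zero records are `unknown`.
#'
#' @param records Named list of per-sample alignment tibbles (or SAM file
#'   paths, read with [read_sam()]).
#' @inheritParams classify_te_sample
#' @return A tibble with one row per sample: `sample`, `call`,
#'   `n_perfect_spanning`, `best_clip_match_len`, `conflict`.
#' @export
genotype_te_cohort <- function(records, site, te_seq, ref_seq, ref_offset,
                               chrom = NULL, span_flank = 5L) {
  stopifnot(is.list(records), !is.null(names(records)))
  purrr::imap(records, function(rec, s) {
    if (is.character(rec)) rec <- read_sam(rec)
    classify_te_sample(rec, site, te_seq, ref_seq, ref_offset,
      chrom = chrom, span_flank = span_flank) |>
      mutate(sample = s, .before = 1)
  }) |> bind_rows()
}

#' Read a minimal SAM file
#'
#' Parses the mandatory columns of a plain-text SAM file (header lines
#' skipped) into the alignment tibble used by the TE genotyper. Only
#' QNAME/FLAG/RNAME/POS/MAPQ/CIGAR/SEQ are retained.
#'
#' @param path Path to a SAM file.
#' @return A tibble: `qname`, `flag`, `rname`, `pos`, `mapq`, `cigar`,
#'   `seq`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) {
    return(tibble(
      qname = character(0), flag = integer(0), rname = character(0),
      pos = integer(0), mapq = integer(0), cigar = character(0),
      seq = character(0)
    ))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(f, length, integer(1)) < 11L
  if (any(bad)) abort("SAM records with fewer than 11 fields")
  tibble(
    qname = vapply(f, `[[`, character(1), 1),
    flag = as.integer(vapply(f, `[[`, character(1), 2)),
    rname = vapply(f, `[[`, character(1), 3),
    pos = as.integer(vapply(f, `[[`, character(1), 4)),
    mapq = as.integer(vapply(f, `[[`, character(1), 5)),
    cigar = vapply(f, `[[`, character(1), 6),
    seq = vapply(f, `[[`, character(1), 10)
  )
}

#' Write alignment records as a minimal SAM file
#'
#' @param records Alignment tibble (`qname`, `flag`, `rname`, `pos`,
#'   `mapq`, `cigar`, `seq`).
#' @param path Output path.
#' @param sq Optional named vector of reference lengths for `@SQ` lines.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, path, sq = NULL) {
  header <- "@HD\tVN:1.6\tSO:unsorted"
  if (!is.null(sq)) {
    header <- c(header, sprintf("@SQ\tSN:%s\tLN:%d", names(sq), as.integer(sq)))
  }
  body <- sprintf(
    "%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
    records$qname, records$flag, records$rname, records$pos,
    records$mapq, records$cigar, records$seq
  )
  writeLines(c(header, body), path)
  invisible(path)
}
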