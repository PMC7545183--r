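random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

test_that("probe-read counts and positions follow the pair geometry", {
  set.seed(1)
  span <- 1000
  # L = span: exactly one pair
  sc1 <- Biostrings::DNAStringSet(setNames(random_dna(span), "s1"))
  r1 <- simulate_probe_reads(sc1)
  expect_equal(nrow(r1), 2)
  # L = span + 2500, step 1000: 3 pairs
  sc2 <- Biostrings::DNAStringSet(setNames(random_dna(span + 2500), "s2"))
  r2 <- simulate_probe_reads(sc2)
  expect_equal(nrow(r2), 6)
  expect_equal(unique(diff(unique(r2$offset[r2$mate == 1]))), 1000)
  # reads reconstruct their scaffold offsets exactly
  s <- as.character(sc2[[1]])
  for (i in seq_len(nrow(r2))) {
    expect_identical(r2$seq[i],
      substr(s, r2$offset[i] + 1, r2$offset[i] + 500))
  }
  # inner-distance interpretation widens the span
  r3 <- simulate_probe_reads(sc2, insert_mode = "inner")
  expect_equal(nrow(r3), 6) # span 1500: floor((3500-1500)/1000)+1 = 3 pairs
  # too-short scaffold yields no reads, with a message
  short <- Biostrings::DNAStringSet(setNames(random_dna(500), "tiny"))
  expect_message(r0 <- simulate_probe_reads(short), "shorter")
  expect_equal(nrow(r0), 0)
})

test_that("unique-exact matching reports position and strand, else unmapped", {
  set.seed(2)
  ref <- Biostrings::DNAStringSet(c(chr2B = random_dna(5000)))
  read <- substr(as.character(ref[[1]]), 1001, 1500)
  reads <- tibble::tibble(scaffold = "x", ordinal = 0L, mate = 1L,
    offset = 0L, seq = read)
  hit <- map_probe_reads(reads, ref)
  expect_equal(hit$chrom, "chr2B")
  expect_equal(hit$pos, 1000L)
  expect_equal(hit$strand, "+")
  # reverse-complement read maps with strand "-"
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(read)))
  hit2 <- map_probe_reads(dplyr::mutate(reads, seq = rc), ref)
  expect_equal(hit2$strand, "-")
  expect_equal(hit2$pos, 1000L)
  # a duplicated read is ambiguous and stays unmapped
  dup_ref <- Biostrings::DNAStringSet(c(
    chr2B = paste0(as.character(ref[[1]]), as.character(ref[[1]]))))
  hit3 <- map_probe_reads(reads, dup_ref)
  expect_true(is.na(hit3$chrom))
})

test_that("the 21-versus-22 read chrUn boundary is exact", {
  set.seed(3)
  ref_seq <- random_dna(40000)
  ref <- Biostrings::DNAStringSet(c(chr1A = ref_seq))
  # 11 pairs = 22 reads, every read unique in the reference
  sc <- substr(ref_seq, 5001, 5000 + 11000)
  world <- Biostrings::DNAStringSet(c(s22 = sc))
  reads <- simulate_probe_reads(world)
  expect_equal(nrow(reads), 22)
  hits <- map_probe_reads(reads, ref)
  a22 <- assign_chromosome(hits, min_reads = 22)
  expect_equal(a22$chrom, "chr1A")
  expect_equal(a22$n_supporting, 22L)
  # corrupt one read's source window: 21 mapped reads -> chrUn
  sc21 <- sc
  substr(sc21, 5001, 5500) <- random_dna(500)
  reads21 <- simulate_probe_reads(Biostrings::DNAStringSet(c(s21 = sc21)))
  hits21 <- map_probe_reads(reads21, ref)
  expect_equal(sum(!is.na(hits21$chrom)), 21)
  a21 <- assign_chromosome(hits21, min_reads = 22)
  expect_equal(a21$chrom, "chrUn")
  expect_equal(a21$n_supporting, 21L)
  # majority vote across chromosomes
  fake <- tibble::tibble(
    scaffold = "m", ordinal = 0:34, mate = 1L, offset = 0L, seq = "A",
    chrom = rep(c("chr1A", "chr1B"), c(30, 5)), pos = 1:35, strand = "+"
  )
  expect_equal(assign_chromosome(fake, min_reads = 22)$chrom, "chr1A")
})

test_that("placement and orientation recover a synthetic world exactly", {
  w <- simulate_scaffold_world(n_chrom = 3, chrom_len = 2e5,
    n_scaffolds = 20, seed = 17)
  expect_message(
    placements <- anchor_scaffolds(w$scaffolds, w$reference),
    "shorter"
  )
  m <- dplyr::left_join(placements, w$truth, by = "scaffold")
  expect_equal(m$chrom.x, m$chrom.y)
  placed <- m[m$placed, ]
  expect_equal(placed$orientation, placed$strand)
  # recovered order along each chromosome equals the true offset order
  for (ch in unique(placed$chrom.x)) {
    p <- placed[placed$chrom.x == ch, ]
    expect_equal(order(p$position), order(p$offset))
  }
  # scaffolds with >= 22 mappable reads all placed
  expect_true(all(m$placed[m$n_supporting >= 22]))
})

test_that("pseudomolecule construction inserts 300 bp gaps consistently", {
  set.seed(5)
  sc <- Biostrings::DNAStringSet(c(a = random_dna(1200), b = random_dna(800)))
  placements <- tibble::tibble(
    scaffold = c("a", "b"), chrom = "chr1A", position = c(100, 900),
    orientation = c("+", "-"), n_supporting = 22L, placed = TRUE
  )
  pm <- build_pseudomolecules(placements, sc, gap = 300)
  expect_equal(length(pm$sequences[["chr1A"]]), 1200 + 800 + 300)
  # AGP components reproduce the input scaffolds
  agp <- pm$agp
  wa <- agp[agp$component_id == "a", ]
  seq_a <- Biostrings::subseq(pm$sequences[["chr1A"]], wa$object_beg,
    wa$object_end)
  expect_identical(as.character(seq_a), as.character(sc[["a"]]))
  wb <- agp[agp$component_id == "b", ]
  seq_b <- Biostrings::subseq(pm$sequences[["chr1A"]], wb$object_beg,
    wb$object_end)
  expect_identical(as.character(Biostrings::reverseComplement(seq_b)),
    as.character(sc[["b"]]))
  gap_row <- agp[agp$component_type == "U", ]
  expect_equal(gap_row$object_end - gap_row$object_beg + 1L, 300L)
  # single scaffold: no gap
  pm1 <- build_pseudomolecules(placements[1, ], sc["a"])
  expect_equal(length(pm1$sequences[["chr1A"]]), 1200)
  # total length identity over a mixed placement set
  placements2 <- dplyr::bind_rows(placements, tibble::tibble(
    scaffold = "c", chrom = "chrUn", position = NA_real_,
    orientation = "*", n_supporting = 3L, placed = FALSE
  ))
  sc2 <- c(sc, Biostrings::DNAStringSet(c(c = random_dna(400))))
  pm2 <- build_pseudomolecules(placements2, sc2)
  n_placed <- 2
  expect_equal(
    sum(Biostrings::width(pm2$sequences)) -
      length(pm2$sequences[["chrUn"]]),
    1200 + 800 + 300 * (n_placed - 1)
  )
})

test_that("assembly statistics agree with the brute-force oracle", {
  expect_equal(assembly_stats(c(5, 4, 3, 2, 1))$n50, 4)
  expect_equal(assembly_stats(7)$n50, 7)
  set.seed(9)
  for (i in 1:20) {
    lens <- sample.int(1e6, sample(3:40, 1))
    st <- assembly_stats(lens)
    expect_equal(st$n50, nx_oracle(lens, 50))
    expect_equal(st$n90, nx_oracle(lens, 90))
    expect_equal(st$max, max(lens))
    expect_equal(st$total, sum(lens))
  }
  # the study-scale gap fraction: 153,963,770 of 14,707,915,341 bases
  gf <- assembly_stats(14707915341, gap_bases = 153963770)$gap_fraction
  expect_equal(round(100 * gf, 2), 1.05)
  expect_error(assembly_stats(numeric(0)), "nonempty")
})
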