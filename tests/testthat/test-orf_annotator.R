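test_that("aa length arithmetic reproduces the published unique-ORF table", {
  got <- aa_length(TABLE2$start, TABLE2$end, TABLE2$strand)
  expect_equal(got, TABLE2$aa)
  expect_error(aa_length(1, 5), "divisible")
  # wrapping ORF: 30 bp spanning the origin of a 100 bp genome
  expect_equal(aa_length(90, 19, "+", genome_length = 100, wraps = TRUE), 9L)
})

test_that("ORF size threshold is a strict codon-count boundary", {
  # ATG + 48 further sense codons (49 codons total) + stop
  orf49 <- paste0("ATG", strrep("GCA", 48), "TAA")
  g <- genome("g", orf49, topology = "linear")
  expect_equal(nrow(enumerate_orfs(g, min_codons = 50L)), 0L)
  found <- enumerate_orfs(g, min_codons = 49L)
  expect_equal(nrow(found), 1L)
  expect_equal(found$aa_length, 49L)
  expect_equal(c(found$start, found$end), c(1L, nchar(orf49)))
})

test_that("planted ORFs are recovered at exact coordinates", {
  r <- generate_genome(synth_genome_spec(
    length = 12000L, n_orfs = 3L, hr_units = integer(),
    dr_unit_lengths = integer(), dr_copies = integer(), seed = 13L))
  found <- enumerate_orfs(r$genome, min_codons = 50L)
  tr <- r$truth$orfs
  for (i in seq_len(nrow(tr))) {
    hit <- found$start == tr$start[i] & found$end == tr$end[i] &
      found$strand == tr$strand[i] & found$aa_length == tr$aa_length[i]
    expect_true(any(hit), label = sprintf("truth ORF %d recovered", i))
  }
})

test_that("an ORF spanning the circular origin is found and flagged", {
  # place an ORF across the junction by rotating a planted genome
  r <- generate_genome(synth_genome_spec(
    length = 10000L, n_orfs = 1L, hr_units = integer(),
    dr_unit_lengths = integer(), dr_copies = integer(), seed = 17L))
  tr <- r$truth$orfs[1L, ]
  mid <- tr$start + 150L  # origin lands inside the ORF
  g2 <- rotate(r$genome, mid)
  found <- enumerate_orfs(g2, min_codons = 50L)
  new_start <- rotate_coord(tr$start, mid, r$genome$length)
  new_end <- rotate_coord(tr$end, mid, r$genome$length)
  hit <- found[found$start == new_start & found$end == new_end, ]
  expect_equal(nrow(hit), 1L)
  expect_true(hit$wraps)
  expect_equal(hit$aa_length, tr$aa_length)
})

test_that("ORF enumeration commutes with rotation of a circular genome", {
  r <- generate_genome(synth_genome_spec(
    length = 9000L, n_orfs = 2L, hr_units = integer(),
    dr_unit_lengths = integer(), dr_copies = integer(), seed = 19L))
  g <- r$genome
  base <- enumerate_orfs(g, min_codons = 50L)
  for (k in c(37L, 4000L, 8999L)) {
    got <- enumerate_orfs(rotate(g, k), min_codons = 50L)
    expected_start <- sort(rotate_coord(base$start, k, g$length))
    expect_equal(sort(got$start), expected_start)
    expect_equal(sort(got$aa_length), sort(base$aa_length))
  }
})

test_that("annotation rules: homology overrides, 75 bp overlap boundary, ab-initio gating", {
  L <- 10000L
  cands <- data.frame(
    start = c(1000L, 1828L, 1829L, 5000L, 7000L),
    end   = c(1902L, 2330L, 2331L, 5502L, 7502L),
    strand = c("+", "+", "+", "+", "+"),
    wraps = FALSE,
    aa_length = c(300L, 167L, 167L, 167L, 167L))
  # cand 2 overlaps cand 1 by 75 bp, cand 3 by 74 bp... check both directions
  ov2 <- 1902L - 1828L + 1L
  expect_equal(ov2, 75L)
  repeats <- data.frame(start = 6900L, end = 7100L)
  ev <- data.frame(
    start = cands$start, end = cands$end, strand = cands$strand,
    has_homology = c(1L, 0L, 0L, 0L, 1L),
    coding_predicted = c(0L, 1L, 1L, 1L, 0L))
  kept <- apply_annotation_rules(cands, ev, repeats, genome_length = L)
  # 75 bp overlap with the longer kept ORF is tolerated
  expect_true(1828L %in% kept$start)
  # homology-supported ORF inside a repeat region is kept regardless
  expect_true(7000L %in% kept$start)
  # 76 bp overlap: shift candidate 2 one base left
  cands76 <- cands; cands76$start[2L] <- 1827L
  ev76 <- ev; ev76$start[2L] <- 1827L
  kept76 <- apply_annotation_rules(cands76, ev76, repeats, genome_length = L)
  expect_false(1827L %in% kept76$start)
  # no-homology candidate without coding prediction is dropped
  ev_nc <- ev; ev_nc$coding_predicted[4L] <- 0L
  kept_nc <- apply_annotation_rules(cands, ev_nc, repeats, genome_length = L)
  expect_false(5000L %in% kept_nc$start)
  # no-homology candidate inside a repeat region is dropped
  cands_r <- cands; ev_r <- ev
  ev_r$has_homology[5L] <- 0L; ev_r$coding_predicted[5L] <- 1L
  kept_r <- apply_annotation_rules(cands_r, ev_r, repeats, genome_length = L)
  expect_false(7000L %in% kept_r$start)
  # candidates absent from the evidence table get both flags false
  kept_no_ev <- apply_annotation_rules(cands, NULL, repeats, genome_length = L)
  expect_equal(nrow(kept_no_ev), 0L)
})

test_that("raising the overlap tolerance never removes a kept ORF", {
  set.seed(7)
  starts <- sort(sample(seq(1L, 8000L, by = 3L), 12L))
  cands <- data.frame(start = starts, end = starts + 3L * sample(60:200, 12L),
                      strand = "+", wraps = FALSE)
  cands$aa_length <- (cands$end - cands$start + 1L) %/% 3L - 1L
  ev <- data.frame(start = cands$start, end = cands$end, strand = "+",
                   has_homology = 0L, coding_predicted = 1L)
  prev <- NULL
  for (mo in c(0L, 25L, 75L, 150L, 1000L)) {
    kept <- apply_annotation_rules(cands, ev, NULL, genome_length = 100000L,
                                   max_overlap = mo)
    if (!is.null(prev)) expect_true(all(prev %in% kept$start))
    prev <- kept$start
  }
})

test_that("numbering anchors the genome at the polh/gran-style ORF", {
  r <- generate_genome(synth_genome_spec(
    length = 15000L, n_orfs = 4L, hr_units = integer(),
    dr_unit_lengths = integer(), dr_copies = integer(), seed = 23L))
  g <- r$genome
  tr <- r$truth$orfs
  cand <- enumerate_orfs(g, 50L)
  ev <- data.frame(start = tr$start, end = tr$end, strand = tr$strand,
                   has_homology = 1L, coding_predicted = 1L)
  kept <- apply_annotation_rules(cand, ev, NULL, genome_length = g$length)
  anchor <- tr[tr$strand == "+", ][1L, ]
  res <- number_orfs(kept, anchor$start, anchor$end, "+", g)
  expect_equal(res$orfs$number, seq_len(nrow(res$orfs)))
  a_row <- res$orfs[res$orfs$start == 1L, ]
  expect_equal(a_row$number, 1L)
  # re-enumeration oracle: scanning the rotated genome finds every ORF at
  # the transformed coordinates
  rescan <- enumerate_orfs(res$genome, 50L)
  for (i in seq_len(nrow(res$orfs))) {
    o <- res$orfs[i, ]
    expect_true(any(rescan$start == o$start & rescan$end == o$end &
                      rescan$strand == o$strand))
  }
  # anchor must be among the kept ORFs
  expect_error(number_orfs(kept, 99999L, 100100L, "+", g), "anchor")
})

test_that("three kept ORFs in genome order get numbers 1, 2, 3", {
  pad <- function(n) substr(strrep("TAGA", ceiling(n / 4)), 1L, n)
  s <- paste0(
    "ATG", strrep("GGA", 60), "TAA",   # 186 bp ORF at 1
    pad(313L),
    "ATG", strrep("GGA", 70), "TAA",   # 216 bp ORF at 500
    pad(184L),
    "ATG", strrep("GGA", 80), "TAA",   # 246 bp ORF at 900
    pad(200L))
  g <- genome("g", s)
  cand <- enumerate_orfs(g, 50L)
  ev <- data.frame(start = cand$start, end = cand$end, strand = cand$strand,
                   has_homology = 1L, coding_predicted = 1L)
  kept <- apply_annotation_rules(cand, ev, NULL, genome_length = g$length)
  res <- number_orfs(kept, 1L, 186L, "+", g)
  expect_equal(res$orfs$number, 1:3)
  expect_equal(res$orfs$start, c(1L, 500L, 900L))
})
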