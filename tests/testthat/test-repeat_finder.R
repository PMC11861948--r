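test_that("palindrome score matches a position-by-position complement check", {
  expect_equal(palindrome_score("GAATTC"), 1.0)
  expect_equal(palindrome_score("AAAAAA"), 0.0)
  # independent brute-force oracle on random sequences
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (seed in 1:10) {
    s <- rand_dna(20L + seed, seed = seed)
    v <- strsplit(s, "")[[1L]]
    oracle <- mean(vapply(seq_along(v), function(i) {
      v[i] == comp[[v[length(v) + 1L - i]]]
    }, TRUE))
    expect_equal(palindrome_score(s), oracle)
    expect_equal(palindrome_score(revcomp(s)), palindrome_score(s))
  }
})

test_that("the 44 bp hr consensus is an imperfect palindrome", {
  expect_equal(nchar(HR_CONSENSUS), 44L)
  # value frozen from an independent hand check (22 of 44 complementary)
  expect_equal(palindrome_score(HR_CONSENSUS), 0.5)
  expect_lt(palindrome_score(HR_CONSENSUS), 1.0)
})

test_that("probe search finds exact and diverged units in both orientations", {
  probe <- HR_CONSENSUS
  set.seed(101)
  spacer <- function(n) rand_dna(n, seed = sample(1e6, 1L))
  s <- paste0(spacer(1000L), probe, spacer(1000L), probe, spacer(1000L),
              probe, spacer(1000L), probe, spacer(1000L), probe, spacer(500L))
  g <- genome("g", s)
  hits <- find_repeat_units(g, probe)
  expect_equal(nrow(hits), 5L)
  expect_true(all(hits$identity == 1.0))
  expect_true(all(hits$orientation == "+"))
  # reverse-complement unit is found and flagged
  s2 <- paste0(spacer(800L), revcomp(probe), spacer(800L))
  h2 <- find_repeat_units(genome("g2", s2), probe)
  expect_equal(nrow(h2), 1L)
  expect_equal(h2$orientation, "-")
  expect_equal(h2$start, 801L)
})

test_that("units at 10% divergence pass 0.75 identity but not 0.95", {
  r <- generate_genome(synth_genome_spec(
    length = 30000L, n_orfs = 0L, hr_units = c(3L, 4L, 2L),
    hr_mutation_rate = 0.10, dr_unit_lengths = integer(),
    dr_copies = integer(), seed = 31L))
  h_loose <- find_repeat_units(r$genome, HR_CONSENSUS, min_identity = 0.75)
  expect_equal(nrow(h_loose), 9L)
  h_tight <- find_repeat_units(r$genome, HR_CONSENSUS, min_identity = 0.95)
  expect_equal(nrow(h_tight), 0L)
})

test_that("hit clustering merges by gap and discards singletons", {
  g <- rand_genome(20000L, seed = 37L)
  mk <- function(starts) data.frame(start = starts, end = starts + 43L,
                                    orientation = "+", identity = 1)
  seven <- mk(seq(1000L, by = 144L, length.out = 7L))
  one <- cluster_into_hrs(seven, g)
  expect_equal(nrow(one), 1L)
  expect_equal(one$copies, 7L)
  expect_equal(one$name, "hr1")
  far <- mk(c(1000L, 11000L))
  expect_equal(nrow(cluster_into_hrs(far, g)), 0L)
})

test_that("planted hr clusters are recovered exactly in count and copies", {
  spec <- synth_genome_spec(length = 60000L, n_orfs = 5L, seed = 41L)
  r <- generate_genome(spec)
  hrs <- cluster_into_hrs(find_repeat_units(r$genome, spec$hr_consensus),
                          r$genome)
  tr <- r$truth$hrs
  expect_equal(nrow(hrs), nrow(tr))
  for (i in seq_len(nrow(tr))) {
    m <- which(hrs$start <= tr$end[i] & hrs$end >= tr$start[i])
    expect_length(m, 1L)
    expect_equal(hrs$copies[m], tr$copies[i])
  }
})

test_that("de-novo search recovers planted repeat units without a probe", {
  set.seed(53)
  unit <- rand_dna(44L, seed = 53L)
  s <- paste0(rand_dna(2000L, seed = 1L), unit,
              rand_dna(1500L, seed = 2L), unit,
              rand_dna(1500L, seed = 3L), unit,
              rand_dna(1000L, seed = 4L))
  g <- genome("g", s)
  hits <- find_repeat_units(g, probe = NULL, unit_length = 44L)
  expect_gte(nrow(hits), 3L)
  expect_true(any(hits$start == 2001L))
})

test_that("tandem arrays: exact unit and copy recovery, period grid", {
  # canonical small example
  set.seed(61)
  g <- genome("t", paste0(rand_dna(3000L, seed = 61L),
                          strrep("ACGTTCGATT", 6L),
                          rand_dna(3000L, seed = 62L)))
  d <- find_tandem_direct_repeats(g)
  expect_equal(nrow(d), 1L)
  expect_equal(d$unit_length, 10L)
  expect_equal(d$copies, 6L)
  expect_equal(d$start, 3001L)
  expect_equal(d$consensus, "ACGTTCGATT")
  # exhaustive small grid of exact arrays
  for (p in c(8L, 25L, 100L)) for (cc in c(4L, 12L)) {
    set.seed(p * 1000L + cc)
    unit <- paste(sample(c("A", "C", "G", "T"), p, TRUE), collapse = "")
    gg <- genome("t", paste0(rand_dna(1500L, seed = p + cc), strrep(unit, cc),
                             rand_dna(1500L, seed = p + cc + 1L)))
    dd <- find_tandem_direct_repeats(gg)
    expect_equal(nrow(dd), 1L, label = sprintf("p=%d c=%d: one array", p, cc))
    expect_equal(dd$unit_length, p)
    expect_equal(dd$copies, cc)
  }
})

test_that("a diverged 12-copy array keeps its period, copies within one", {
  for (seed in 71:73) {
    r <- generate_genome(synth_genome_spec(
      length = 30000L, n_orfs = 0L, hr_units = integer(),
      dr_unit_lengths = 44L, dr_copies = 12L, dr_mutation_rate = 0.05,
      seed = seed))
    d <- find_tandem_direct_repeats(r$genome)
    tr <- r$truth$drs
    m <- which(d$start <= tr$end[1L] & d$end >= tr$start[1L])
    expect_length(m, 1L)
    expect_equal(d$unit_length[m], 44L)
    expect_lte(abs(d$copies[m] - 12L), 1L)
  }
})

test_that("homopolymer runs are not reported as tandem arrays", {
  g <- genome("t", paste0(rand_dna(2000L, seed = 81L), strrep("A", 80L),
                          rand_dna(2000L, seed = 82L)))
  d <- find_tandem_direct_repeats(g)
  expect_false(any(d$start <= 2080L & d$end >= 2001L))
  # dinucleotide arrays are excluded too
  g2 <- genome("t", paste0(rand_dna(2000L, seed = 83L), strrep("AC", 40L),
                           rand_dna(2000L, seed = 84L)))
  d2 <- find_tandem_direct_repeats(g2)
  expect_false(any(d2$start <= 2080L & d2$end >= 2001L))
})

test_that("consensus building is column-majority with fixed tie order", {
  expect_equal(build_consensus(c("ACGT", "ACGT", "ACGA")), "ACGT")
  expect_equal(build_consensus(c("TGCA", "TGCA")), "TGCA")
  # ties resolve A < C < G < T
  expect_equal(build_consensus(c("AG", "CT")), "AG")
  expect_error(build_consensus(c("ACG", "AC")), "length")
  # units mutated at 10% from a known 44-mer: consensus restores the original
  restored <- 0L
  for (seed in 1:20) {
    set.seed(seed)
    units <- vapply(1:10, function(i) {
      v <- strsplit(HR_CONSENSUS, "")[[1L]]
      pos <- sample(44L, 4L)
      for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1L)
      paste(v, collapse = "")
    }, "")
    restored <- restored + (build_consensus(units) == HR_CONSENSUS)
  }
  expect_gte(restored, 19L)
})

test_that("reported regions stay in bounds and units tile the region", {
  spec <- synth_genome_spec(length = 40000L, n_orfs = 3L, seed = 91L)
  r <- generate_genome(spec)
  hrs <- cluster_into_hrs(find_repeat_units(r$genome, spec$hr_consensus),
                          r$genome)
  drs <- find_tandem_direct_repeats(r$genome)
  for (rr in list(hrs, drs)) {
    if (!nrow(rr)) next
    expect_true(all(rr$start >= 1L & rr$end <= r$genome$length))
    for (i in seq_len(nrow(rr))) {
      u <- rr$units[[i]]
      expect_true(all(u$start >= rr$start[i] & u$end <= rr$end[i]))
      expect_equal(nrow(u), rr$copies[i])
    }
  }
})
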