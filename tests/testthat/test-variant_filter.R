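test_that("frequency filter is inclusive at the threshold", {
  v <- data.frame(position = 1:5, ref = "A", alt = "G",
                  frequency = c(0.05, 0.099, 0.10, 0.102, 0.185))
  kept <- filter_variants(v)
  expect_equal(nrow(kept), 3L)
  expect_equal(kept$frequency, c(0.10, 0.102, 0.185))
  expect_equal(nrow(filter_variants(v, min_freq = 0)), 5L)
  expect_error(filter_variants(data.frame(frequency = c(0.5, 1.2))),
               "\\(0, 1\\]")
  expect_error(filter_variants(data.frame(frequency = c(0, 0.5))),
               "\\(0, 1\\]")
})

test_that("kept count is non-increasing in the threshold", {
  set.seed(201)
  v <- data.frame(position = 1:200, ref = "A", alt = "G",
                  frequency = runif(200, 0.01, 1))
  sizes <- vapply(c(0, 0.05, 0.1, 0.2, 0.5, 1),
                  function(t) nrow(filter_variants(v, t)), 0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("context classification matches a brute-force interval oracle", {
  L <- 10000L
  orfs <- data.frame(start = c(1000L, 4000L, 9500L), end = c(2000L, 4600L, 300L),
                     wraps = c(FALSE, FALSE, TRUE))
  reps <- data.frame(start = c(1900L, 6000L), end = c(2400L, 6100L),
                     kind = c("hr", "dr"))
  set.seed(211)
  pos <- sample(L, 200L, replace = TRUE)
  got <- classify_context(pos, orfs, reps, L)
  oracle <- vapply(pos, function(p) {
    in_orf <- any((orfs$wraps & (p >= orfs$start | p <= orfs$end)) |
                    (!orfs$wraps & p >= orfs$start & p <= orfs$end))
    if (in_orf) return("orf")
    hit <- which(p >= reps$start & p <= reps$end)
    if (length(hit)) reps$kind[hit[1L]] else "intergenic"
  }, "")
  expect_equal(got, oracle)
  # precedence: inside both ORF and repeat -> orf
  expect_equal(classify_context(1950L, orfs, reps, L), "orf")
  expect_error(classify_context(0L, orfs, reps, L), "bounds")
})

test_that("coding effect translates ref and alt codons on either strand", {
  # plus-strand ORF: ATG GGA TAA at 11..19
  g <- genome("g", paste0(rand_dna(10L, seed = 221L), "ATGGGATAA",
                          rand_dna(10L, seed = 222L)))
  orf <- list(start = 11L, end = 19L, strand = "+", wraps = FALSE)
  expect_equal(coding_effect(16L, "A", "G", orf, g), "synonymous")  # GGA->GGG
  expect_equal(coding_effect(11L, "A", "C", orf, g), "non_synonymous") # ATG->CTG
  expect_equal(coding_effect(14L, "G", "A", orf, g), "non_synonymous") # GGA->AGA
  expect_equal(coding_effect(16L, "A", "AT", orf, g), "na")
  expect_error(coding_effect(14L, "T", "A", orf, g), "does not match")
  # minus-strand ORF: genome shows revcomp(ATGGGATAA) = TTATCCCAT
  gm <- genome("g", paste0(rand_dna(10L, seed = 223L), "TTATCCCAT",
                           rand_dna(10L, seed = 224L)))
  orfm <- list(start = 11L, end = 19L, strand = "-", wraps = FALSE)
  # third codon base of GGA is genome position 14 (T on plus = A on coding)
  expect_equal(coding_effect(14L, "T", "C", orfm, gm), "synonymous")
  expect_equal(coding_effect(19L, "T", "G", orfm, gm), "non_synonymous")
})

test_that("coding effect is invariant under genome rotation", {
  r <- generate_genome(synth_genome_spec(
    length = 9000L, n_orfs = 2L, hr_units = integer(),
    dr_unit_lengths = integer(), dr_copies = integer(), seed = 231L))
  g <- r$genome
  orf <- as.list(r$truth$orfs[1L, ])
  orf$wraps <- FALSE
  pos <- orf$start + 7L
  ref <- substr(g$sequence, pos, pos)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1L]
  eff0 <- coding_effect(pos, ref, alt, orf, g)
  for (k in c(500L, 7000L)) {
    g2 <- rotate(g, k)
    orf2 <- orf
    orf2$start <- rotate_coord(orf$start, k, g$length)
    orf2$end <- rotate_coord(orf$end, k, g$length)
    orf2$wraps <- orf2$start > orf2$end
    pos2 <- rotate_coord(pos, k, g$length)
    expect_equal(coding_effect(pos2, ref, alt, orf2, g2), eff0)
  }
})

test_that("variant tables round-trip from TSV and minimal VCF", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("position\tref\talt\tfrequency",
               "100\tA\tG\t0.25", "200\tAC\tA\t0.5"), tsv)
  v <- read_variants(tsv)
  expect_equal(v$kind, c("snp", "indel"))
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr\t150\t.\tG\tT\t.\tPASS\tAF=0.13;DP=88",
               "chr\t300\t.\tT\tTTA\t.\tPASS\tAF=0.42"), vcf)
  w <- read_variants(vcf)
  expect_equal(w$position, c(150L, 300L))
  expect_equal(w$frequency, c(0.13, 0.42))
  expect_equal(w$kind, c("snp", "indel"))
})

test_that("annotated variants partition by context with exact planted counts", {
  r <- generate_genome(synth_genome_spec(
    length = 30000L, n_orfs = 4L, hr_units = c(3L, 2L),
    dr_unit_lengths = c(20L), dr_copies = c(6L), seed = 241L))
  g <- r$genome
  orfs <- r$truth$orfs
  orfs$wraps <- FALSE
  reps <- rbind(
    data.frame(start = r$truth$hrs$start, end = r$truth$hrs$end, kind = "hr"),
    data.frame(start = r$truth$drs$start, end = r$truth$drs$end, kind = "dr"))
  # plant variants: 5 in ORFs, 3 in hrs, 2 in drs, 4 intergenic
  pick <- function(n, lo, hi) as.integer(seq(lo, hi, length.out = n + 2L))[2:(n + 1L)]
  pos <- c(unlist(lapply(1:4, function(i) pick(2, orfs$start[i], orfs$end[i])))[1:5],
           pick(3L, reps$start[1L], reps$end[1L]),
           pick(2L, reps$start[3L], reps$end[3L]),
           integer(0))
  inter <- setdiff(seq(10L, 29990L, by = 997L),
                   unlist(lapply(seq_len(nrow(orfs)), function(i)
                     orfs$start[i]:orfs$end[i])))
  inter <- inter[vapply(inter, function(p)
    !any(p >= reps$start & p <= reps$end), TRUE)][1:4]
  pos <- c(pos, inter)
  v <- data.frame(position = pos,
                  ref = substring(g$sequence, pos, pos),
                  alt = "N", frequency = 0.25)
  v$alt <- vapply(v$ref, function(b) setdiff(c("A", "C", "G", "T"), b)[1L], "")
  ann <- annotate_variants(v, g, orfs, reps)
  expect_equal(sum(ann$context == "orf"), 5L)
  expect_equal(sum(ann$context == "hr"), 3L)
  expect_equal(sum(ann$context == "dr"), 2L)
  expect_equal(sum(ann$context == "intergenic"), 4L)
  s <- attr(ann, "summary")
  expect_equal(s$total, nrow(ann))
  expect_equal(s$total, sum(unlist(s$by_context)))
  expect_true(all(ann$coding_effect[ann$context == "orf"] %in%
                    c("synonymous", "non_synonymous")))
  expect_true(all(ann$coding_effect[ann$context != "orf"] == "na"))
})
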