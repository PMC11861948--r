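# shared fixtures: random genomes with no planted features come from the
# generator itself, so tests and generator share one seeded RNG discipline
rand_genome <- function(len, gc = 0.4, seed = 1L, id = "rand") {
  g <- generate_genome(synth_genome_spec(
    length = len, gc = gc, n_orfs = 0L, hr_units = integer(),
    dr_unit_lengths = integer(), dr_copies = integer(), seed = seed))$genome
  g$id <- id
  g
}

rand_dna <- function(len, seed = 1L, gc = 0.5) {
  rand_genome(max(len, 1300L), gc = gc, seed = seed)$sequence |>
    substr(1L, len)
}

# the hr unit consensus printed for the PlidNPV-type genome; also the
# generator default
HR_CONSENSUS <- "CCTAAATGGAATTCATTACCGAATGTAAATGGAGCCAGTTTGGA"

# the unique-ORF coordinate/size table used as a coordinate-arithmetic
# fixture: start, end, strand, printed aa size
TABLE2 <- data.frame(
  isolate = c(rep("NPV", 6), rep("GV", 9)),
  orf = c(7, 28, 36, 101, 108, 121, 9, 17, 18, 21, 30, 35, 76, 92, 110),
  start = c(7197, 30507, 36833, 99237, 102642, 114940,
            5428, 11791, 13005, 17812, 27087, 28907, 59983, 75968, 93221),
  end = c(8261, 31052, 37321, 99662, 103100, 115479,
          5964, 12639, 14015, 17979, 27341, 29260, 60270, 76708, 93871),
  strand = c("+", "-", "+", "+", "+", "-",
             "+", "-", "-", "+", "-", "-", "+", "+", "-"),
  aa = c(354, 181, 162, 141, 152, 179,
         178, 282, 336, 55, 84, 117, 95, 246, 216))

# minimal GenBank flat file written on the fly
write_tiny_genbank <- function(path, id = "TEST01", seqtxt, circular = TRUE,
                               cds = NULL) {
  lines <- c(sprintf("LOCUS       %s             %d bp    DNA     %s   VRL",
                     id, nchar(seqtxt), if (circular) "circular" else "linear"),
             sprintf("DEFINITION  synthetic test record %s.", id),
             "FEATURES             Location/Qualifiers",
             sprintf("     source          1..%d", nchar(seqtxt)))
  if (!is.null(cds)) {
    for (i in seq_len(nrow(cds))) {
      loc <- sprintf("%d..%d", cds$start[i], cds$end[i])
      if (cds$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
      lines <- c(lines, sprintf("     CDS             %s", loc),
                 sprintf("                     /label=cds%d", i))
    }
  }
  lines <- c(lines, "ORIGIN")
  s <- tolower(seqtxt)
  for (off in seq(1L, nchar(s), by = 60L)) {
    chunk <- substr(s, off, min(off + 59L, nchar(s)))
    grps <- substring(chunk, seq(1L, nchar(chunk), 10L),
                      pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", off, paste(grps, collapse = " ")))
  }
  writeLines(c(lines, "//"), path)
  path
}
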