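# Run code with a local RNG seed, leaving the caller's RNG state untouched.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# i.i.d. background sequence at a target GC fraction
.random_dna <- function(n, gc) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# mutate exactly round(rate * L) positions, each to a different base
.mutate_exact <- function(s, rate) {
  v <- strsplit(s, "", fixed = TRUE)[[1L]]
  k <- round(rate * length(v))
  if (k == 0L) return(s)
  pos <- sample(length(v), k)
  for (p in pos) {
    v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1L)
  }
  paste(v, collapse = "")
}

# per-base Bernoulli mutation to a different base; returns seq + count
.mutate_bernoulli <- function(s, rate) {
  v <- strsplit(s, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(v)) < rate)
  for (p in hit) {
    v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1L)
  }
  list(sequence = paste(v, collapse = ""), n_mutations = length(hit))
}

# random ORF cassette: in-frame guard stop, ATG, codons-1 sense codons, TAA
.orf_cassette <- function(codons) {
  stops <- c("TAA", "TAG", "TGA")
  all_codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                  c("A", "C", "G", "T")), 1L, paste,
                      collapse = "")
  sense <- setdiff(all_codons, stops)
  body <- paste(sample(sense, codons - 1L, replace = TRUE), collapse = "")
  paste0("TAA", "ATG", body, "TAA")
}

#' Build a synthetic genome specification
#'
#' The defaults emulate the architecture of an alphabaculovirus genome:
#' ~120 kb circular sequence at 39% GC carrying protein-coding ORFs, ten
#' homologous regions (hrs) of 44-bp imperfect palindromic units (two to
#' seven units each), and tandem direct-repeat (dr) arrays with six to
#' twelve copies.
#'
#' @param length Genome length in bp (default 120000).
#' @param gc Target GC fraction of the background (default 0.39).
#' @param n_orfs Number of planted ORFs (default 30).
#' @param orf_codons Range of ORF sizes in codons (default 60-400).
#' @param hr_consensus 44-bp hr unit consensus used as the planting template.
#' @param hr_units Units per hr region (default: ten regions with two to
#'   seven units).
#' @param hr_mutation_rate Per-unit divergence from the consensus; applied
#'   as an exact count of mutated positions per unit (default 0.10).
#' @param dr_unit_lengths,dr_copies dr unit lengths and copy numbers
#'   (defaults: five regions, copies 6/6/12/11/6).
#' @param dr_mutation_rate Per-unit divergence within dr arrays (default 0.05).
#' @param seed Integer seed; the generator is a pure function of the spec.
#' @return list of class `synth_spec`.
#' @export
synth_genome_spec <- function(length = 120000L, gc = 0.39,
                              n_orfs = 30L, orf_codons = c(60L, 400L),
                              hr_consensus = paste0(
                                "CCTAAATGGAATTCATTACC",
                                "GAATGTAAATGGAGCCAGTTTGGA"),
                              hr_units = c(2L, 3L, 4L, 5L, 6L,
                                           7L, 2L, 4L, 3L, 5L),
                              hr_mutation_rate = 0.10,
                              dr_unit_lengths = c(15L, 20L, 44L, 30L, 12L),
                              dr_copies = c(6L, 6L, 12L, 11L, 6L),
                              dr_mutation_rate = 0.05,
                              seed = 1L) {
  stopifnot(length(dr_unit_lengths) == length(dr_copies))
  structure(list(length = as.integer(length), gc = gc, n_orfs = n_orfs,
                 orf_codons = orf_codons, hr_consensus = toupper(hr_consensus),
                 hr_units = hr_units, hr_mutation_rate = hr_mutation_rate,
                 dr_unit_lengths = dr_unit_lengths, dr_copies = dr_copies,
                 dr_mutation_rate = dr_mutation_rate, seed = as.integer(seed)),
            class = "synth_spec")
}

#' Generate a synthetic genome with a known truth set
#'
#' Features (ORF cassettes, hr regions, dr arrays) are laid out left to
#' right in a deterministic shuffled order with random background spacers,
#' so planted features never overlap. The result is a pure function of the
#' spec (including its seed).
#'
#' @param spec A `synth_spec` from [synth_genome_spec()].
#' @return list with `genome` (a `genome`) and `truth` (list with data
#'   frames `orfs`, `hrs`, `drs`; coordinates are 1-based inclusive on the
#'   emitted sequence).
#' @export
generate_genome <- function(spec) {
  .with_seed(spec$seed, {
    feats <- list()
    for (i in seq_len(spec$n_orfs)) {
      codons <- sample(seq.int(spec$orf_codons[1L], spec$orf_codons[2L]), 1L)
      strand <- sample(c("+", "-"), 1L)
      cassette <- .orf_cassette(codons)
      if (strand == "-") cassette <- revcomp(cassette)
      feats[[length(feats) + 1L]] <- list(type = "orf", seq = cassette,
                                          codons = codons, strand = strand)
    }
    uL <- nchar(spec$hr_consensus)
    for (i in seq_along(spec$hr_units)) {
      n_units <- spec$hr_units[i]
      pieces <- character(0)
      offs <- integer(0)
      at <- 0L
      for (u in seq_len(n_units)) {
        unit <- .mutate_exact(spec$hr_consensus, spec$hr_mutation_rate)
        offs <- c(offs, at)
        pieces <- c(pieces, unit)
        at <- at + uL
        if (u < n_units) {
          sp <- sample(5:30, 1L)
          pieces <- c(pieces, .random_dna(sp, spec$gc))
          at <- at + sp
        }
      }
      feats[[length(feats) + 1L]] <- list(type = "hr",
                                          seq = paste(pieces, collapse = ""),
                                          unit_offsets = offs,
                                          unit_length = uL, copies = n_units)
    }
    for (i in seq_along(spec$dr_unit_lengths)) {
      unit <- .random_dna(spec$dr_unit_lengths[i], 0.5)
      copies <- spec$dr_copies[i]
      arr <- paste(vapply(seq_len(copies), function(u) {
        .mutate_exact(unit, spec$dr_mutation_rate)
      }, ""), collapse = "")
      feats[[length(feats) + 1L]] <- list(type = "dr", seq = arr,
                                          unit = unit,
                                          unit_length = nchar(unit),
                                          copies = copies)
    }
    feats <- feats[sample(length(feats))]
    feat_len <- sum(vapply(feats, function(f) nchar(f$seq), 0L))
    n_gaps <- length(feats) + 1L
    # every feature is separated by at least 600 bp of background, so
    # distinct planted repeat regions never merge under default clustering
    min_gap <- 600L
    spare <- spec$length - feat_len
    if (spare < n_gaps * min_gap)
      stop("planted features do not fit within the genome length")
    cuts <- sort(sample(seq_len(spare - n_gaps * min_gap + 1L) - 1L,
                        n_gaps - 1L, replace = TRUE))
    gaps <- diff(c(0L, cuts, spare - n_gaps * min_gap)) + min_gap
    pieces <- character(0)
    orfs <- list(); hrs <- list(); drs <- list()
    pos <- 0L
    for (i in seq_along(feats)) {
      g <- .random_dna(gaps[i], spec$gc)
      pieces <- c(pieces, g)
      pos <- pos + gaps[i]
      f <- feats[[i]]
      pieces <- c(pieces, f$seq)
      if (f$type == "orf") {
        # cassette = guard stop (3 bp) + ORF; ORF spans cassette[4..end]
        if (f$strand == "+") {
          orfs[[length(orfs) + 1L]] <- data.frame(
            start = pos + 4L, end = pos + nchar(f$seq), strand = "+",
            aa_length = f$codons)
        } else {
          orfs[[length(orfs) + 1L]] <- data.frame(
            start = pos + 1L, end = pos + nchar(f$seq) - 3L, strand = "-",
            aa_length = f$codons)
        }
      } else if (f$type == "hr") {
        hrs[[length(hrs) + 1L]] <- data.frame(
          start = pos + 1L, end = pos + nchar(f$seq),
          unit_length = f$unit_length, copies = f$copies)
      } else {
        drs[[length(drs) + 1L]] <- data.frame(
          start = pos + 1L, end = pos + nchar(f$seq),
          unit_length = f$unit_length, copies = f$copies, unit = f$unit)
      }
      pos <- pos + nchar(f$seq)
    }
    pieces <- c(pieces, .random_dna(gaps[length(gaps)], spec$gc))
    seqtxt <- paste(pieces, collapse = "")
    stopifnot(nchar(seqtxt) == spec$length)
    g <- genome(sprintf("synth-%d", spec$seed), seqtxt, "circular")
    bind <- function(x, empty_cols) {
      if (length(x)) do.call(rbind, x) else empty_cols
    }
    truth <- list(
      orfs = bind(orfs, data.frame(start = integer(), end = integer(),
                                   strand = character(),
                                   aa_length = integer())),
      hrs = bind(hrs, data.frame(start = integer(), end = integer(),
                                 unit_length = integer(), copies = integer())),
      drs = bind(drs, data.frame(start = integer(), end = integer(),
                                 unit_length = integer(), copies = integer(),
                                 unit = character())))
    list(genome = g, truth = truth)
  })
}

#' Plant a mutated cross-genome transfer into a recipient genome
#'
#' Copies `donor_span` from the donor, point-mutates it at `mutation_rate`
#' per base (Bernoulli; each mutation to a different base), and splices it
#' into the recipient in place of an equal-length segment starting at
#' `insert_at` (wrapping the origin when necessary). This emulates a recent
#' interspecies recombination event.
#'
#' @param donor,recipient `genome` objects.
#' @param donor_span `span` on the donor (plus strand).
#' @param insert_at Recipient position where the transfer begins.
#' @param mutation_rate Per-base mutation probability (default 0.025).
#' @param seed Integer seed.
#' @return list with `genome` (modified recipient) and `truth` (list:
#'   donor_start/donor_end, start/end on the recipient, length,
#'   expected_identity = 1 - realized mutations / length).
#' @export
plant_recombination <- function(donor, recipient, donor_span, insert_at,
                                mutation_rate = 0.025, seed = 1L) {
  .with_seed(seed, {
    seg <- subsequence(donor, donor_span)
    n <- nchar(seg)
    mut <- .mutate_bernoulli(seg, mutation_rate)
    L <- recipient$length
    if (n > L) stop("transfer longer than the recipient genome")
    end_at <- insert_at + n - 1L
    s <- recipient$sequence
    if (end_at <= L) {
      s <- paste0(substr(s, 1L, insert_at - 1L), mut$sequence,
                  substr(s, end_at + 1L, L))
      wraps <- FALSE
      end_pos <- end_at
    } else {
      if (recipient$topology != "circular")
        stop("wrapping insertion on a linear genome")
      tail_n <- L - insert_at + 1L
      s <- paste0(substr(mut$sequence, tail_n + 1L, n),
                  substr(s, n - tail_n + 1L, insert_at - 1L),
                  substr(mut$sequence, 1L, tail_n))
      wraps <- TRUE
      end_pos <- n - tail_n
    }
    g <- genome(recipient$id, s, recipient$topology)
    list(genome = g,
         truth = list(donor_start = donor_span$start,
                      donor_end = donor_span$end,
                      start = insert_at, end = end_pos, wraps = wraps,
                      length = n,
                      n_mutations = mut$n_mutations,
                      expected_identity = 1 - mut$n_mutations / n))
  })
}

#' Evolve an aligned sequence pair under a two-rate substitution model
#'
#' A random ancestor is drawn, and each site of the derived copy differs by
#' a transition with probability `ts_rate` or by a transversion (one of the
#' two, equiprobable) with probability `tv_rate`. Realized difference
#' counts are returned as truth, so distance estimators can be checked
#' against the exact generating proportions.
#'
#' @param length Alignment length in sites.
#' @param ts_rate,tv_rate Per-site probabilities of a transition /
#'   transversion difference (`ts_rate + tv_rate < 0.75`).
#' @param seed Integer seed.
#' @param gc Ancestor GC fraction (default 0.5).
#' @return list with a, b (aligned strings), P_true, Q_true (realized
#'   proportions), n.
#' @export
evolve_pair <- function(length, ts_rate, tv_rate, seed = 1L, gc = 0.5) {
  if (ts_rate < 0 || tv_rate < 0 || ts_rate + tv_rate >= 0.75)
    stop("invalid rates: need ts_rate, tv_rate >= 0 and sum < 0.75")
  .with_seed(seed, {
    transition <- c(A = "G", G = "A", C = "T", T = "C")
    transversions <- list(A = c("C", "T"), G = c("C", "T"),
                          C = c("A", "G"), T = c("A", "G"))
    a <- strsplit(.random_dna(length, gc), "", fixed = TRUE)[[1L]]
    u <- stats::runif(length)
    b <- a
    is_ts <- u < ts_rate
    is_tv <- !is_ts & u < ts_rate + tv_rate
    b[is_ts] <- transition[a[is_ts]]
    if (any(is_tv)) {
      b[is_tv] <- vapply(a[is_tv], function(x) sample(transversions[[x]], 1L),
                         "")
    }
    list(a = paste(a, collapse = ""), b = paste(b, collapse = ""),
         P_true = mean(is_ts), Q_true = mean(is_tv), n = length)
  })
}
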