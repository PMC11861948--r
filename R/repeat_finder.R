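#' Palindromic self-complementarity score
#'
#' Fraction of positions i (1..L) at which `seq[i]` equals the complement of
#' `seq[L + 1 - i]`. A perfect DNA palindrome (e.g. an EcoRI site) scores
#' 1.0; baculovirus hr repeat units are imperfect palindromes and score
#' below 1.
#'
#' @param seq Nucleotide string.
#' @return Fraction in `[0, 1]`.
#' @export
palindrome_score <- function(seq) {
  s <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  if (!length(s)) stop("empty sequence")
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "X")
  mean(s == unname(comp[rev(s)]), na.rm = FALSE)
}

# Hamming identity between two equal-length strings (N counts as mismatch)
.hamming_identity <- function(x, y) {
  a <- strsplit(x, "", fixed = TRUE)[[1L]]
  b <- strsplit(y, "", fixed = TRUE)[[1L]]
  mean(a == b & a != "N" & b != "N")
}

# probe scan over one working string; returns start positions and identities
.probe_scan <- function(wseq, probe, min_identity) {
  L <- nchar(probe)
  max_mm <- floor((1 - min_identity) * L + 1e-9)
  hits <- Biostrings::matchPattern(probe, Biostrings::DNAString(wseq),
                                   max.mismatch = max_mm, with.indels = FALSE)
  st <- Biostrings::start(hits)
  if (!length(st)) return(data.frame(start = integer(), identity = numeric()))
  ident <- vapply(seq_along(st), function(i) {
    .hamming_identity(substr(wseq, st[i], st[i] + L - 1L), probe)
  }, 0)
  data.frame(start = st, identity = ident)
}

#' Find occurrences of a repeat unit in a genome
#'
#' Scans both orientations of the genome (crossing the origin when
#' circular) for ungapped windows of length `unit_length` with Hamming
#' identity to `probe` at least `min_identity`. Overlapping hits are merged,
#' keeping the best. When `probe` is NULL a de-novo search is performed:
#' k-mers occurring at least twice seed candidate units, seeds are extended
#' to `unit_length`, grouped by similarity, and the genome is re-scanned
#' with each group consensus.
#'
#' @param g A `genome`.
#' @param probe Consensus sequence of the unit, or NULL for de-novo mode.
#' @param unit_length Unit length in bp (>= 8). Defaults to `nchar(probe)`.
#' @param min_identity Minimum Hamming identity to report a window
#'   (default 0.75, loose enough for a consensus to recruit diverged units).
#' @return data.frame with columns start, end, orientation ("+" forward,
#'   "-" reverse complement), identity; sorted by start. Wrapping hits on
#'   circular genomes report their canonical start (<= genome length).
#' @export
find_repeat_units <- function(g, probe = NULL, unit_length = NULL,
                              min_identity = 0.75) {
  if (is.null(unit_length)) {
    if (is.null(probe)) stop("unit_length required in de-novo mode")
    unit_length <- nchar(probe)
  }
  if (unit_length < 8L) stop("unit_length must be >= 8")
  if (is.null(probe)) {
    return(.find_units_denovo(g, unit_length, min_identity))
  }
  probe <- toupper(probe)
  if (nchar(probe) != unit_length) stop("probe length != unit_length")
  L <- g$length
  w <- if (g$topology == "circular") {
    paste0(g$sequence, substr(g$sequence, 1L, min(unit_length - 1L, L)))
  } else {
    g$sequence
  }
  res <- list()
  for (orient in c("+", "-")) {
    p <- if (orient == "+") probe else revcomp(probe)
    h <- .probe_scan(w, p, min_identity)
    if (nrow(h)) {
      h$orientation <- orient
      res[[length(res) + 1L]] <- h
    }
  }
  if (!length(res)) {
    return(data.frame(start = integer(), end = integer(),
                      orientation = character(), identity = numeric()))
  }
  hits <- do.call(rbind, res)
  hits <- hits[order(hits$start, -hits$identity), , drop = FALSE]
  # merge overlapping windows, keeping the best-identity one
  keep <- logical(nrow(hits))
  last_end <- -1L
  for (i in seq_len(nrow(hits))) {
    if (hits$start[i] > last_end) {
      keep[i] <- TRUE
      last_end <- hits$start[i] + unit_length - 1L
    } else if (hits$identity[i] > hits$identity[which(keep)[sum(keep)]]) {
      keep[which(keep)[sum(keep)]] <- FALSE
      keep[i] <- TRUE
      last_end <- hits$start[i] + unit_length - 1L
    }
  }
  hits <- hits[keep, , drop = FALSE]
  hits$end <- hits$start + unit_length - 1L
  # canonicalize wrapped hits
  hits$start <- ((hits$start - 1L) %% L) + 1L
  hits$end <- ((hits$end - 1L) %% L) + 1L
  hits <- hits[, c("start", "end", "orientation", "identity")]
  rownames(hits) <- NULL
  hits
}

# de-novo unit discovery: repeated seed k-mers -> candidate units -> groups
.find_units_denovo <- function(g, unit_length, min_identity, seed_k = 14L) {
  s <- g$sequence
  n <- nchar(s)
  seed_k <- min(seed_k, unit_length)
  pos <- seq_len(n - seed_k + 1L)
  kmers <- substring(s, pos, pos + seed_k - 1L)
  tab <- table(kmers)
  rep_k <- names(tab)[tab >= 2L]
  if (!length(rep_k)) {
    return(data.frame(start = integer(), end = integer(),
                      orientation = character(), identity = numeric()))
  }
  seeds <- pos[kmers %in% rep_k]
  seeds <- seeds[seeds + unit_length - 1L <= n]
  groups <- list()
  for (p in seeds) {
    unit <- substr(s, p, p + unit_length - 1L)
    placed <- FALSE
    for (gi in seq_along(groups)) {
      if (.hamming_identity(unit, groups[[gi]][1L]) >= min_identity) {
        groups[[gi]] <- c(groups[[gi]], unit)
        placed <- TRUE
        break
      }
    }
    if (!placed) groups[[length(groups) + 1L]] <- unit
  }
  groups <- groups[lengths(groups) >= 2L]
  out <- list()
  for (grp in groups) {
    cons <- build_consensus(grp)
    out[[length(out) + 1L]] <- find_repeat_units(g, cons, unit_length,
                                                 min_identity)
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(),
                      orientation = character(), identity = numeric()))
  }
  hits <- unique(do.call(rbind, out))
  hits <- hits[order(hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Cluster repeat-unit hits into hr regions
#'
#' Consecutive hits separated by at most `max_gap` bp are merged into one
#' homologous region (hr); regions with fewer than `min_units` units are
#' discarded. Regions are numbered hr1, hr2, ... in genome order.
#'
#' @param hits data.frame from [find_repeat_units()].
#' @param g The `genome` (used to extract unit sequences for the consensus).
#' @param max_gap Maximum inter-unit gap within one region (default 500 bp).
#' @param min_units Minimum units per region (default 2).
#' @return data.frame with one row per region: name, kind, start, end,
#'   unit_length, copies, mean_unit_identity, mean_palindrome, consensus,
#'   plus a list-column `units` of per-unit data.frames.
#' @export
cluster_into_hrs <- function(hits, g, max_gap = 500L, min_units = 2L) {
  empty <- data.frame(name = character(), kind = character(),
                      start = integer(), end = integer(),
                      unit_length = integer(), copies = integer(),
                      mean_unit_identity = numeric(),
                      mean_palindrome = numeric(), consensus = character())
  if (!nrow(hits)) { empty$units <- list(); return(empty) }
  hits <- hits[order(hits$start), , drop = FALSE]
  gap <- c(0L, hits$start[-1L] - hits$end[-nrow(hits)] - 1L)
  cluster <- cumsum(gap > max_gap)
  regions <- list()
  for (cl in unique(cluster)) {
    u <- hits[cluster == cl, , drop = FALSE]
    if (nrow(u) < min_units) next
    unit_seqs <- vapply(seq_len(nrow(u)), function(i) {
      sp <- span(u$start[i], u$end[i],
                 strand = if (u$orientation[i] == "-") "-" else "+",
                 wraps = u$end[i] < u$start[i])
      subsequence(g, sp)
    }, "")
    regions[[length(regions) + 1L]] <- data.frame(
      name = "", kind = "hr", start = min(u$start), end = max(u$end),
      unit_length = u$end[1L] - u$start[1L] + 1L,
      copies = nrow(u),
      mean_unit_identity = mean(u$identity),
      mean_palindrome = mean(vapply(unit_seqs, palindrome_score, 0)),
      consensus = build_consensus(unit_seqs))
    attr(regions[[length(regions)]], "units") <- u
  }
  if (!length(regions)) { empty$units <- list(); return(empty) }
  units <- lapply(regions, attr, "units")
  out <- do.call(rbind, regions)
  out$name <- paste0("hr", seq_len(nrow(out)))
  out$units <- units
  rownames(out) <- NULL
  out
}

#' Find tandem direct-repeat (dr) arrays
#'
#' Self-comparison at each candidate period p: positions where the sequence
#' matches itself p bp downstream form runs; runs interrupted only by
#' isolated mismatches are merged, and merged segments long enough to hold
#' `min_copies` units become candidate arrays. Unit boundaries are phased
#' from the array start; the best period per locus is the one giving the
#' longest array. Period-1/period-2 (homopolymer and dinucleotide) arrays
#' are excluded as low-complexity.
#'
#' @param g A `genome`.
#' @param min_unit,max_unit Period range in bp (defaults 8-100).
#' @param min_copies Minimum number of unit copies (default 4).
#' @param min_unit_identity Minimum mean identity of units to their
#'   consensus (default 0.8).
#' @return data.frame in the same shape as [cluster_into_hrs()], with
#'   kind "dr" and names dr1, dr2, ... in genome order.
#' @export
find_tandem_direct_repeats <- function(g, min_unit = 8L, max_unit = 100L,
                                       min_copies = 4L,
                                       min_unit_identity = 0.8) {
  stopifnot(min_unit <= max_unit, min_unit >= 3L)
  s <- g$sequence
  v <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(v)
  cand <- list()
  for (p in seq.int(min_unit, min(max_unit, n %/% 2L))) {
    eq <- v[seq_len(n - p)] == v[seq.int(p + 1L, n)]
    # max-scoring segments of the self-match profile (+1 match, -1 mismatch):
    # a tandem array self-matches at most positions and climbs steadily,
    # random sequence (~1/4 matches) drifts downward, so the running score
    # above its prefix minimum spikes only inside arrays
    C <- cumsum(ifelse(eq, 1L, -1L))
    pref <- c(0L, C)
    premin <- cummin(pref[-length(pref)])
    cur <- C - premin
    hi <- which(cur >= 8L)
    if (!length(hi)) next
    brk <- which(diff(hi) > max(2L * p, 50L))
    cl_first <- hi[c(1L, brk + 1L)]
    cl_last <- hi[c(brk, length(hi))]
    segs <- list()
    for (ci in seq_along(cl_first)) {
      i1 <- cl_first[ci]; i2 <- cl_last[ci]
      # climb starts right after the prefix minimum preceding the spike
      arr_start <- max(which(pref[seq_len(i1)] == premin[i1]))
      peak_at <- i1 + which.max(cur[i1:i2]) - 1L
      if (peak_at >= arr_start) segs[[length(segs) + 1L]] <- c(arr_start, peak_at)
    }
    for (sg in segs) {
      arr_start <- sg[1L]
      arr_end <- min(sg[2L] + p, n)
      copies <- (arr_end - arr_start + 1L) %/% p
      if (copies < min_copies) next
      if (mean(eq[sg[1L]:sg[2L]]) < 0.5) next
      cand[[length(cand) + 1L]] <- data.frame(
        start = arr_start, end = arr_start + copies * p - 1L,
        period = p, copies = copies,
        run = sg[2L] - sg[1L] + 1L)
    }
  }
  empty <- data.frame(name = character(), kind = character(),
                      start = integer(), end = integer(),
                      unit_length = integer(), copies = integer(),
                      mean_unit_identity = numeric(),
                      mean_palindrome = numeric(), consensus = character())
  if (!length(cand)) { empty$units <- list(); return(empty) }
  cand <- do.call(rbind, cand)
  # screen candidates: unit identity to the consensus and complexity, before
  # choosing the best period per locus
  screened <- list()
  for (i in seq_len(nrow(cand))) {
    a <- cand[i, ]
    p <- a$period
    ustarts <- seq.int(a$start, by = p, length.out = a$copies)
    units <- substring(s, ustarts, ustarts + p - 1L)
    cons <- build_consensus(units)
    ident <- vapply(units, .hamming_identity, 0, y = cons)
    # trim terminal units recruited from random flanking sequence: clearly
    # below the identity floor and an outlier against the array's own units
    bad_unit <- function(x) x < min_unit_identity &&
      x < stats::median(ident) - 0.1
    while (length(ident) >= 2L && bad_unit(ident[1L])) {
      units <- units[-1L]; ident <- ident[-1L]; ustarts <- ustarts[-1L]
    }
    while (length(ident) >= 2L && bad_unit(ident[length(ident)])) {
      units <- units[-length(units)]; ident <- ident[-length(ident)]
      ustarts <- ustarts[-length(ustarts)]
    }
    if (length(units) < min_copies) next
    cons <- build_consensus(units)
    ident <- vapply(units, .hamming_identity, 0, y = cons)
    if (mean(ident) < min_unit_identity) next
    # low-complexity exclusion on the trimmed span: arrays that are equally
    # well explained as period-1/2 (homopolymer or dinucleotide) repeats
    sub <- v[ustarts[1L]:(ustarts[length(ustarts)] + p - 1L)]
    lag1 <- mean(sub[-length(sub)] == sub[-1L])
    lag2 <- if (length(sub) > 2L)
      mean(sub[seq_len(length(sub) - 2L)] == sub[-(1:2)]) else 0
    if (lag1 >= 0.9 || lag2 >= 0.9) next
    a$start <- ustarts[1L]
    a$end <- ustarts[length(ustarts)] + p - 1L
    a$copies <- length(units)
    reg <- data.frame(
      name = "", kind = "dr", start = a$start, end = a$end,
      unit_length = p, copies = a$copies, run = a$run,
      mean_unit_identity = mean(ident),
      mean_palindrome = mean(vapply(units, palindrome_score, 0)),
      consensus = cons)
    attr(reg, "units") <- data.frame(
      start = ustarts, end = ustarts + p - 1L, orientation = "+",
      identity = unname(ident))
    screened[[length(screened) + 1L]] <- reg
  }
  if (!length(screened)) { empty$units <- list(); return(empty) }
  # best period per locus: most copies wins (a 2p-periodic reading of a
  # p-periodic array halves the copy number), then the longest self-match
  # run, then the smaller period; overlapping candidates are suppressed
  run_len <- vapply(screened, function(r) r$run, 0)
  periods <- vapply(screened, function(r) r$unit_length, 0)
  ncopies <- vapply(screened, function(r) r$copies, 0)
  ord <- order(-ncopies, -run_len, periods)
  acc <- list()
  for (i in ord) {
    ci <- screened[[i]]
    clash <- any(vapply(acc, function(a) {
      min(ci$end, a$end) - max(ci$start, a$start) + 1L > 0L
    }, TRUE))
    if (!clash) acc[[length(acc) + 1L]] <- ci
  }
  units <- lapply(acc, attr, "units")
  out <- do.call(rbind, acc)
  out$run <- NULL
  ords <- order(out$start)
  out <- out[ords, , drop = FALSE]
  units <- units[ords]
  out$name <- paste0("dr", seq_len(nrow(out)))
  out$units <- units
  rownames(out) <- NULL
  out
}

#' Column-wise majority consensus of equal-length units
#'
#' Ties are broken by fixed base order A < C < G < T.
#'
#' @param units Character vector of equal-length nucleotide strings.
#' @return Consensus string of the same length.
#' @export
build_consensus <- function(units) {
  if (length(units) < 1L) stop("need at least one unit")
  L <- nchar(units[1L])
  if (any(nchar(units) != L)) stop("units differ in length")
  m <- do.call(rbind, strsplit(units, "", fixed = TRUE))
  paste(apply(m, 2L, function(col) {
    counts <- table(factor(col, levels = c("A", "C", "G", "T", "N")))
    names(counts)[which.max(counts)]
  }), collapse = "")
}
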