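#' Percent identity of two aligned sequences
#'
#' Identity = matching columns / total alignment columns. Gap columns and
#' columns containing N count as mismatches (a conservative convention,
#' recorded with every report).
#'
#' @param aligned_a,aligned_b Equal-length aligned strings (gaps as "-").
#' @return Fraction in `[0, 1]`.
#' @export
percent_identity <- function(aligned_a, aligned_b) {
  if (nchar(aligned_a) != nchar(aligned_b)) stop("aligned lengths differ")
  a <- strsplit(toupper(aligned_a), "", fixed = TRUE)[[1L]]
  b <- strsplit(toupper(aligned_b), "", fixed = TRUE)[[1L]]
  mean(a == b & !a %in% c("-", "N") & !b %in% c("-", "N"))
}

# ungapped X-drop extension; returns how far the window can be pushed
# (steps) rightward along ca/cb starting at ia/ib moving by dir
.xdrop_extend <- function(ca, cb, ia, ib, dir, match = 1, mismatch = -2,
                          xdrop = 12) {
  best <- 0; score <- 0; best_step <- 0L; step <- 0L
  na <- length(ca); nb <- length(cb)
  repeat {
    step <- step + 1L
    pa <- ia + dir * step; pb <- ib + dir * step
    if (pa < 1L || pb < 1L || pa > na || pb > nb) break
    score <- score + if (ca[pa] == cb[pb] && ca[pa] != "N") match else mismatch
    if (score > best) { best <- score; best_step <- step }
    if (best - score > xdrop) break
  }
  best_step
}

#' Find cross-genome homology blocks
#'
#' Exact k-mer anchors shared between the two genomes (both orientations)
#' are chained by colinearity, chains are extended outward by ungapped
#' X-drop extension, and each chained interval is realigned (Hamming when
#' the chain is gap-free, banded global alignment otherwise). Blocks
#' shorter than `min_block` or below `min_identity` are dropped; among
#' overlapping blocks the best-scoring is kept. A near-identical block
#' between an alphabaculovirus and a betabaculovirus genome is the
#' signature of recent interspecies recombination.
#'
#' @param genome_a,genome_b `genome` objects.
#' @param k Anchor k-mer size (default 16, effectively unique at the
#'   ~100 kb scale of baculovirus genomes).
#' @param min_block Minimum alignment length in bp (default 200).
#' @param min_identity Minimum percent identity (default 0.8).
#' @param max_anchor_gap Maximum distance between chained anchors
#'   (default 500 bp).
#' @param band Maximum diagonal drift within a chain (default 20 bp).
#' @return data.frame with columns start_a, end_a, start_b, end_b,
#'   alignment_length, matches, percent_identity, orientation
#'   ("same"/"inverted"), sorted by start_a.
#' @export
find_homology_blocks <- function(genome_a, genome_b, k = 16L,
                                 min_block = 200L, min_identity = 0.8,
                                 max_anchor_gap = 500L, band = 20L) {
  empty <- data.frame(start_a = integer(), end_a = integer(),
                      start_b = integer(), end_b = integer(),
                      alignment_length = integer(), matches = integer(),
                      percent_identity = numeric(), orientation = character())
  sa <- genome_a$sequence
  blocks <- list()
  for (orient in c("same", "inverted")) {
    sb <- if (orient == "same") genome_b$sequence else revcomp(genome_b$sequence)
    anchors <- .kmer_anchors(sa, sb, k)
    if (!nrow(anchors)) next
    chains <- .chain_anchors(anchors, k, max_anchor_gap, band)
    for (ch in chains) {
      bl <- .chain_to_block(ch, sa, sb, k, band)
      if (is.null(bl)) next
      if (bl$alignment_length < min_block) next
      if (bl$percent_identity < min_identity) next
      # map inverted coordinates back to the plus strand of b
      if (orient == "inverted") {
        Lb <- genome_b$length
        tmp <- bl$start_b
        bl$start_b <- Lb - bl$end_b + 1L
        bl$end_b <- Lb - tmp + 1L
      }
      bl$orientation <- orient
      blocks[[length(blocks) + 1L]] <- bl
    }
  }
  if (!length(blocks)) return(empty)
  blocks <- do.call(rbind, blocks)
  # resolve overlaps by score (matches), best first
  blocks <- blocks[order(-blocks$matches), , drop = FALSE]
  keep <- logical(nrow(blocks))
  for (i in seq_len(nrow(blocks))) {
    ok <- TRUE
    for (j in which(keep)) {
      ova <- min(blocks$end_a[i], blocks$end_a[j]) -
        max(blocks$start_a[i], blocks$start_a[j]) + 1L
      ovb <- min(blocks$end_b[i], blocks$end_b[j]) -
        max(blocks$start_b[i], blocks$start_b[j]) + 1L
      len <- blocks$end_a[i] - blocks$start_a[i] + 1L
      if (max(ova, ovb) > 0.5 * len) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  blocks <- blocks[keep, , drop = FALSE]
  blocks <- blocks[order(blocks$start_a), , drop = FALSE]
  rownames(blocks) <- NULL
  blocks
}

# shared k-mer positions between two strings, low-complexity k-mers dropped
.kmer_anchors <- function(sa, sb, k, max_occ = 10L) {
  pa <- seq_len(nchar(sa) - k + 1L)
  pb <- seq_len(nchar(sb) - k + 1L)
  ka <- substring(sa, pa, pa + k - 1L)
  kb <- substring(sb, pb, pb + k - 1L)
  common <- intersect(ka, kb)
  if (!length(common)) return(data.frame(pa = integer(), pb = integer()))
  da <- data.frame(kmer = ka, pa = pa)[ka %in% common, ]
  db <- data.frame(kmer = kb, pb = pb)[kb %in% common, ]
  ta <- table(da$kmer); tb <- table(db$kmer)
  busy <- union(names(ta)[ta > max_occ], names(tb)[tb > max_occ])
  da <- da[!da$kmer %in% busy, ]
  db <- db[!db$kmer %in% busy, ]
  if (!nrow(da) || !nrow(db)) return(data.frame(pa = integer(), pb = integer()))
  m <- merge(da, db, by = "kmer")
  m[order(m$pa, m$pb), c("pa", "pb")]
}

# greedy colinear chaining of anchors sorted by pa
.chain_anchors <- function(anchors, k, max_gap, band) {
  n <- nrow(anchors)
  assigned <- rep(FALSE, n)
  chains <- list()
  diag <- anchors$pb - anchors$pa
  for (i in seq_len(n)) {
    if (assigned[i]) next
    idx <- i
    assigned[i] <- TRUE
    cur <- i
    for (j in seq_len(n)) {
      if (j <= cur || assigned[j]) next
      if (anchors$pa[j] - anchors$pa[cur] > max_gap + k) break
      if (anchors$pb[j] > anchors$pb[cur] &&
          abs(diag[j] - diag[cur]) <= band) {
        idx <- c(idx, j)
        assigned[j] <- TRUE
        cur <- j
      }
    }
    chains[[length(chains) + 1L]] <- anchors[idx, , drop = FALSE]
  }
  chains
}

# turn one chain into an aligned, extended block
.chain_to_block <- function(ch, sa, sb, k, band) {
  ca <- strsplit(sa, "", fixed = TRUE)[[1L]]
  cb <- strsplit(sb, "", fixed = TRUE)[[1L]]
  a1 <- min(ch$pa); a2 <- max(ch$pa) + k - 1L
  b1 <- min(ch$pb); b2 <- max(ch$pb) + k - 1L
  left <- .xdrop_extend(ca, cb, a1, b1, -1L)
  right <- .xdrop_extend(ca, cb, a2, b2, +1L)
  a1 <- a1 - left; b1 <- b1 - left
  a2 <- a2 + right; b2 <- b2 + right
  gap_free <- length(unique(ch$pb - ch$pa)) == 1L
  xa <- substr(sa, a1, a2)
  xb <- substr(sb, b1, b2)
  if (gap_free && nchar(xa) == nchar(xb)) {
    va <- strsplit(xa, "", fixed = TRUE)[[1L]]
    vb <- strsplit(xb, "", fixed = TRUE)[[1L]]
    matches <- sum(va == vb & va != "N")
    cols <- nchar(xa)
  } else {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(xa), Biostrings::DNAString(xb),
      type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -2, baseOnly = FALSE),
      gapOpening = 5, gapExtension = 2)
    pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1L]]
    ps <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1L]]
    matches <- sum(pa == ps & !pa %in% c("-", "N"))
    cols <- length(pa)
  }
  data.frame(start_a = a1, end_a = a2, start_b = b1, end_b = b2,
             alignment_length = as.integer(cols),
             matches = as.integer(matches),
             percent_identity = matches / cols)
}

#' Global protein identity
#'
#' Needleman-Wunsch global alignment with identity scoring (match +1,
#' mismatch -1, gap opening 10, gap extension 0.5); identity is the
#' fraction of alignment columns with identical residues (gaps count
#' against identity).
#'
#' @param prot_a,prot_b Amino-acid strings.
#' @return Fraction in `[0, 1]`.
#' @export
protein_global_identity <- function(prot_a, prot_b) {
  if (!nchar(prot_a) || !nchar(prot_b)) stop("empty protein sequence")
  al <- .protein_align(prot_a, prot_b)
  a <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1L]]
  b <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1L]]
  mean(a == b & a != "-")
}

.protein_align <- function(prot_a, prot_b) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V", "B", "Z", "X", "*")
  m <- matrix(-1, length(aa), length(aa), dimnames = list(aa, aa))
  diag(m) <- 1
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(toupper(prot_a)), Biostrings::AAString(toupper(prot_b)),
    type = "global", substitutionMatrix = m,
    gapOpening = 10, gapExtension = 0.5)
}

#' Reciprocal-best-hit ortholog assignment
#'
#' All-against-all global protein identity; a pair (i, j) is an ortholog
#' pair when j is i's best hit, i is j's best hit, and identity and mutual
#' coverage pass the thresholds. Returns a one-to-one mapping.
#'
#' @param proteome_a,proteome_b Character vectors of amino-acid sequences
#'   in ORF-number order.
#' @param min_identity Minimum alignment identity (default 0.25).
#' @param min_coverage Minimum fraction of the longer protein covered by
#'   aligned (non-gap in both) columns (default 0.5).
#' @return data.frame with columns a, b (1-based indices) and identity.
#' @export
rbh_orthologs <- function(proteome_a, proteome_b, min_identity = 0.25,
                          min_coverage = 0.5) {
  na <- length(proteome_a); nb <- length(proteome_b)
  if (!na || !nb) stop("empty proteome")
  ident <- matrix(0, na, nb)
  cover <- matrix(0, na, nb)
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    al <- .protein_align(proteome_a[i], proteome_b[j])
    a <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1L]]
    b <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1L]]
    ident[i, j] <- mean(a == b & a != "-")
    cover[i, j] <- sum(a != "-" & b != "-") /
      max(nchar(proteome_a[i]), nchar(proteome_b[j]))
  }
  best_a <- apply(ident, 1L, which.max)
  best_b <- apply(ident, 2L, which.max)
  pairs <- list()
  for (i in seq_len(na)) {
    j <- best_a[i]
    if (best_b[j] == i && ident[i, j] >= min_identity &&
        cover[i, j] >= min_coverage) {
      pairs[[length(pairs) + 1L]] <- data.frame(a = i, b = j,
                                                identity = ident[i, j])
    }
  }
  if (!length(pairs)) {
    return(data.frame(a = integer(), b = integer(), identity = numeric()))
  }
  out <- do.call(rbind, pairs)
  rownames(out) <- NULL
  out
}

#' Gene parity points for a two-genome synteny plot
#'
#' Each ortholog pair contributes the point (ordinal in genome A, ordinal
#' in genome B); ORFs present in only one genome are plotted directly on
#' the corresponding axis (the missing ordinal is 0). Diagonal runs of
#' points indicate conserved gene order.
#'
#' @param mapping data.frame with columns a, b from [rbh_orthologs()].
#' @param n_a,n_b Number of annotated ORFs in each genome.
#' @param core_a Integer vector of ORF numbers in genome A that are
#'   baculovirus core genes (flagged on their points).
#' @return data.frame with columns orf_a, orf_b, is_core.
#' @export
gene_parity_points <- function(mapping, n_a, n_b, core_a = integer()) {
  if (nrow(mapping)) {
    stopifnot(all(mapping$a >= 1L & mapping$a <= n_a),
              all(mapping$b >= 1L & mapping$b <= n_b))
  }
  pts <- data.frame(orf_a = mapping$a, orf_b = mapping$b)
  only_a <- setdiff(seq_len(n_a), mapping$a)
  only_b <- setdiff(seq_len(n_b), mapping$b)
  pts <- rbind(pts,
               data.frame(orf_a = only_a, orf_b = rep(0L, length(only_a))),
               data.frame(orf_a = rep(0L, length(only_b)), orf_b = only_b))
  pts$is_core <- pts$orf_a %in% core_a & pts$orf_a > 0L
  pts <- pts[order(pts$orf_a, pts$orf_b), , drop = FALSE]
  rownames(pts) <- NULL
  pts
}

#' Translate an ORF to protein
#'
#' @param g A `genome`.
#' @param start,end,strand,wraps ORF span fields.
#' @param include_stop Keep the trailing stop as "*"? Default FALSE.
#' @return Amino-acid string.
#' @export
translate_orf <- function(g, start, end, strand = "+", wraps = FALSE,
                          include_stop = FALSE) {
  nt <- subsequence(g, span(start, end, strand = strand, wraps = wraps))
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                           if.fuzzy.codon = "X"))
  if (!include_stop) aa <- sub("\\*$", "", aa)
  aa
}
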