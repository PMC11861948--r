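#' Amino-acid length of an ORF from its coordinates
#'
#' An ORF spanning positions start..end (1-based inclusive, stop codon
#' included) of length divisible by 3 encodes `(end - start + 1)/3 - 1`
#' amino acids: the stop codon is excluded. This is the arithmetic used in
#' published baculovirus ORF tables.
#'
#' @param start,end 1-based inclusive coordinates.
#' @param strand Unused for the length (kept for interface symmetry).
#' @param genome_length Needed only when `wraps = TRUE`.
#' @param wraps Does the ORF cross the circular origin?
#' @return Integer number of codons excluding the stop.
#' @export
aa_length <- function(start, end, strand = "+", genome_length = NULL,
                      wraps = FALSE) {
  len <- if (wraps) {
    if (is.null(genome_length)) stop("genome_length required for wrapping ORF")
    (genome_length - start + 1L) + end
  } else {
    end - start + 1L
  }
  if (any(len %% 3L != 0L)) stop("ORF span not divisible by 3")
  as.integer(len / 3L - 1L)
}

# Find plus-strand ORFs in a linear working string. Returns codon-resolved
# start/end positions on that string (start = first nt of ATG, end = last nt
# of stop). ORF = first ATG after the upstream in-frame stop.
.scan_orfs <- function(w, min_codons) {
  n <- nchar(w)
  out <- list()
  for (f in 0:2) {
    cs <- seq.int(f + 1L, n - 2L, by = 3L)
    if (length(cs) < 2L) next
    codons <- substring(w, cs, cs + 2L)
    stops <- which(codons %in% c("TAA", "TAG", "TGA"))
    starts <- which(codons == "ATG")
    if (!length(stops) || !length(starts)) next
    # next stop strictly after each start
    nxt <- stops[findInterval(starts, stops) + 1L]
    ok <- !is.na(nxt)
    starts <- starts[ok]; nxt <- nxt[ok]
    if (!length(starts)) next
    # first ATG per stop segment
    first <- tapply(starts, nxt, min)
    stop_idx <- as.integer(names(first))
    aa <- stop_idx - as.integer(first)
    keep <- aa >= min_codons
    if (!any(keep)) next
    out[[length(out) + 1L]] <- data.frame(
      start = cs[as.integer(first)[keep]],
      end = cs[stop_idx[keep]] + 2L,
      aa = aa[keep])
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(), aa = integer()))
  }
  do.call(rbind, out)
}

# Map a working-string interval to canonical genome span fields.
.canon_span <- function(p_start, p_end, L) {
  a <- ((p_start - 1L) %% L) + 1L
  b <- ((p_end - 1L) %% L) + 1L
  wraps <- !(a <= b && (b - a) == (p_end - p_start))
  list(start = a, end = b, wraps = wraps)
}

#' Enumerate ORFs on a genome
#'
#' Finds all maximal ATG-to-stop open reading frames of at least
#' `min_codons` codons (stop excluded) on both strands. Start codon is ATG
#' only; stops are TAA/TAG/TGA (standard genetic code). On circular genomes
#' ORFs crossing the origin are found and flagged `wraps = TRUE`; each ORF is
#' reported once, with coordinates given left-to-right on the plus strand
#' (`start <= end` unless wrapping).
#'
#' @param g A `genome`.
#' @param min_codons Minimum ORF size in codons, stop excluded (default 50,
#'   the conventional annotation floor for baculovirus genomes).
#' @return data.frame with columns start, end, strand, wraps, aa_length,
#'   ordered by start.
#' @export
enumerate_orfs <- function(g, min_codons = 50L) {
  L <- g$length
  circ <- g$topology == "circular"
  res <- list()
  for (strand in c("+", "-")) {
    base <- if (strand == "+") g$sequence else revcomp(g$sequence)
    w <- if (circ) paste0(base, base) else base
    hits <- .scan_orfs(w, min_codons)
    # report each circular ORF once: canonical start within the first copy,
    # total extent at most one genome length
    hits <- hits[hits$start <= L & (hits$end - hits$start + 1L) <= L, ,
                 drop = FALSE]
    if (!nrow(hits)) next
    for (i in seq_len(nrow(hits))) {
      if (strand == "+") {
        cs <- .canon_span(hits$start[i], hits$end[i], L)
      } else {
        # map from reverse-complement coordinates back to the plus strand
        n <- nchar(w)
        cs <- .canon_span(n - hits$end[i] + 1L, n - hits$start[i] + 1L, L)
      }
      res[[length(res) + 1L]] <- data.frame(
        start = cs$start, end = cs$end, strand = strand, wraps = cs$wraps,
        aa_length = hits$aa[i],
        stop_key = paste0(if (strand == "+") cs$end else cs$start, strand))
    }
  }
  if (!length(res)) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), wraps = logical(),
                      aa_length = integer()))
  }
  orfs <- do.call(rbind, res)
  # one ORF per stop codon and strand: keep the longest (first ATG after the
  # upstream stop); duplicates arise near the origin of circular genomes
  orfs <- orfs[order(-orfs$aa_length), , drop = FALSE]
  orfs <- orfs[!duplicated(orfs$stop_key), , drop = FALSE]
  orfs$stop_key <- NULL
  orfs <- orfs[order(orfs$start, orfs$end, orfs$strand), , drop = FALSE]
  rownames(orfs) <- NULL
  orfs
}

# bp intervals covered by a (possibly wrapping) span
.span_pieces <- function(start, end, wraps, L) {
  if (wraps) rbind(c(start, L), c(1L, end)) else rbind(c(start, end))
}

#' Genomic overlap in bp between two spans
#'
#' Strand-agnostic overlap on the (possibly circular) genome.
#'
#' @param s1,e1,w1 First span's start, end, wraps flag.
#' @param s2,e2,w2 Second span.
#' @param L Genome length.
#' @return Integer bp of overlap.
#' @export
span_overlap <- function(s1, e1, w1, s2, e2, w2, L) {
  p1 <- .span_pieces(s1, e1, w1, L)
  p2 <- .span_pieces(s2, e2, w2, L)
  tot <- 0L
  for (i in seq_len(nrow(p1))) for (j in seq_len(nrow(p2))) {
    tot <- tot + max(0L, min(p1[i, 2L], p2[j, 2L]) -
                       max(p1[i, 1L], p2[j, 1L]) + 1L)
  }
  tot
}

#' Apply annotation filter rules to ORF candidates
#'
#' An ORF with homology evidence is always annotated. An ORF without
#' homology evidence is annotated only if it (a) does not overlap a repeat
#' region, (b) does not overlap a longer annotated ORF by more than
#' `max_overlap` bp, and (c) is predicted to be protein-coding by an
#' ab-initio gene finder. Candidates are processed in decreasing amino-acid
#' length (ties: lower start first) so that larger ORFs take precedence.
#'
#' @param candidates data.frame from [enumerate_orfs()].
#' @param evidence data.frame with columns start, end, strand, has_homology,
#'   coding_predicted and optionally name; candidates absent from the table
#'   get both flags FALSE. See [read_evidence()].
#' @param repeat_regions data.frame with columns start, end (and optionally
#'   wraps) of repeat regions; may be empty.
#' @param genome_length Genome length in bp.
#' @param max_overlap Maximum tolerated overlap with a longer annotated ORF
#'   (default 75 bp; overlaps strictly greater are disqualifying).
#' @return data.frame of kept ORFs with columns of `candidates` plus
#'   `basis` ("homology" or "ab_initio") and `name`.
#' @export
apply_annotation_rules <- function(candidates, evidence = NULL,
                                   repeat_regions = NULL, genome_length,
                                   max_overlap = 75L) {
  n <- nrow(candidates)
  key <- paste(candidates$start, candidates$end, candidates$strand)
  has_hom <- logical(n); coding <- logical(n); name <- character(n)
  if (!is.null(evidence) && nrow(evidence)) {
    ekey <- paste(evidence$start, evidence$end, evidence$strand)
    m <- match(key, ekey)
    hit <- !is.na(m)
    has_hom[hit] <- as.logical(evidence$has_homology[m[hit]])
    coding[hit] <- as.logical(evidence$coding_predicted[m[hit]])
    if ("name" %in% names(evidence))
      name[hit] <- as.character(evidence$name[m[hit]])
  }
  candidates$basis <- ifelse(has_hom, "homology", "ab_initio")
  candidates$name <- name
  candidates$.coding <- coding
  if (is.null(repeat_regions)) {
    repeat_regions <- data.frame(start = integer(), end = integer())
  }
  if (!"wraps" %in% names(repeat_regions)) {
    repeat_regions$wraps <- rep(FALSE, nrow(repeat_regions))
  }
  ord <- order(-candidates$aa_length, candidates$start)
  candidates <- candidates[ord, , drop = FALSE]
  keep <- logical(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    ci <- candidates[i, ]
    if (ci$basis == "homology") {
      keep[i] <- TRUE
      next
    }
    if (!ci$.coding) next
    in_repeat <- FALSE
    for (r in seq_len(nrow(repeat_regions))) {
      if (span_overlap(ci$start, ci$end, ci$wraps,
                       repeat_regions$start[r], repeat_regions$end[r],
                       repeat_regions$wraps[r], genome_length) > 0L) {
        in_repeat <- TRUE
        break
      }
    }
    if (in_repeat) next
    ok <- TRUE
    for (j in which(keep)) {
      cj <- candidates[j, ]
      if (span_overlap(ci$start, ci$end, ci$wraps, cj$start, cj$end,
                       cj$wraps, genome_length) > max_overlap) {
        ok <- FALSE
        break
      }
    }
    keep[i] <- ok
  }
  out <- candidates[keep, , drop = FALSE]
  out$.coding <- NULL
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rotate the genome to an anchor ORF and number annotated ORFs
#'
#' Baculovirus convention: the first nucleotide of the polyhedrin (polh) or
#' granulin (gran) ORF becomes position 1 of the genome, and annotated ORFs
#' are numbered consecutively downstream. The anchor must be a plus-strand
#' kept ORF (orient the assembly first if polh/gran reads on the minus
#' strand).
#'
#' @param kept data.frame of annotated ORFs (from
#'   [apply_annotation_rules()]).
#' @param anchor_start,anchor_end,anchor_strand Coordinates identifying the
#'   anchor ORF among `kept`.
#' @param g The `genome` (circular).
#' @return list with `genome` (rotated) and `orfs` (data.frame with `number`
#'   and re-mapped coordinates, anchor numbered 1).
#' @export
number_orfs <- function(kept, anchor_start, anchor_end, anchor_strand, g) {
  hit <- which(kept$start == anchor_start & kept$end == anchor_end &
                 kept$strand == anchor_strand)
  if (!length(hit)) stop("anchor ORF not found among kept ORFs")
  if (anchor_strand != "+")
    stop("anchor ORF must lie on the plus strand; reverse-complement the assembly first")
  L <- g$length
  g2 <- rotate(g, anchor_start)
  new_start <- rotate_coord(kept$start, anchor_start, L)
  new_end <- rotate_coord(kept$end, anchor_start, L)
  # wrap flag from transformed coordinates and conserved span length
  old_len <- mapply(function(s, e, w) {
    if (w) (L - s + 1L) + e else e - s + 1L
  }, kept$start, kept$end, kept$wraps)
  wraps <- !(new_start <= new_end & (new_end - new_start + 1L) == old_len)
  out <- kept
  out$start <- new_start
  out$end <- new_end
  out$wraps <- wraps
  out <- out[order(out$start, out$end), , drop = FALSE]
  out$number <- seq_len(nrow(out))
  rownames(out) <- NULL
  list(genome = g2, orfs = out[, c("number", setdiff(names(out), "number"))])
}

#' Read an ORF evidence table
#'
#' TSV with columns start, end, strand, has_homology (0/1),
#' coding_predicted (0/1) and optionally name. These flags stand in for
#' homology-search and ab-initio gene-finder support.
#'
#' @param path Path to the TSV.
#' @return data.frame.
#' @export
read_evidence <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("start", "end", "strand", "has_homology", "coding_predicted")
  miss <- setdiff(need, names(ev))
  if (length(miss)) stop("evidence table missing columns: ",
                         paste(miss, collapse = ", "))
  ev
}
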