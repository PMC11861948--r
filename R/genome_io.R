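#' Construct a genome object
#'
#' A `genome` is the container every pipeline stage consumes: an identifier,
#' an uppercase nucleotide sequence over A/C/G/T/N, and a topology. Baculovirus
#' genomes are circular dsDNA, so topology defaults to `"circular"`.
#'
#' @param id Character scalar, the genome identifier.
#' @param sequence Character scalar, nucleotide sequence. Uppercased on ingest.
#' @param topology `"circular"` or `"linear"`.
#' @return An object of class `genome` with fields `id`, `sequence`,
#'   `topology`, and derived `length`.
#' @export
genome <- function(id, sequence, topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  stopifnot(is.character(id), length(id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) stop("genome sequence must be non-empty")
  bad <- gregexpr("[^ACGTN]", sequence)[[1L]]
  if (bad[1L] != -1L) {
    stop(sprintf("genome '%s': non-nucleotide symbol '%s' at position %d",
                 id, substr(sequence, bad[1L], bad[1L]), bad[1L]))
  }
  structure(list(id = id, sequence = sequence, topology = topology,
                 length = nchar(sequence)),
            class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %s: %s bp, %s\n", x$id,
              format(x$length, big.mark = ","), x$topology))
  invisible(x)
}

#' Reverse complement of a nucleotide string
#'
#' N maps to N. Self-inverse: `revcomp(revcomp(s)) == s`.
#'
#' @param s Character scalar over A/C/G/T/N.
#' @return Character scalar.
#' @export
revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]),
                                 collapse = ""))
}

#' Create a span (1-based inclusive coordinates)
#'
#' Coordinates are 1-based inclusive throughout, matching the convention of
#' baculovirus genome tables where an ORF of aa length n occupies
#' 3*(n+1) nucleotides. `wraps` marks spans crossing the origin of a
#' circular genome: for those, `start > end` is allowed and the span covers
#' `start..L` followed by `1..end`.
#'
#' @param start,end Integer positions, 1-based inclusive.
#' @param strand `"+"` or `"-"`.
#' @param wraps Logical, does the span cross the circular origin?
#' @return A list of class `span`.
#' @export
span <- function(start, end, strand = "+", wraps = FALSE) {
  stopifnot(start >= 1L, end >= 1L, strand %in% c("+", "-"))
  if (!wraps && start > end) stop("start > end for a non-wrapping span")
  structure(list(start = as.integer(start), end = as.integer(end),
                 strand = strand, wraps = isTRUE(wraps)),
            class = "span")
}

#' Length of a span in bp
#'
#' @param sp A `span`.
#' @param genome_length Genome length in bp (needed for wrapping spans).
#' @return Integer length in bp.
#' @export
span_length <- function(sp, genome_length = NULL) {
  if (sp$wraps) {
    if (is.null(genome_length)) stop("genome_length required for wrapping span")
    (genome_length - sp$start + 1L) + sp$end
  } else {
    sp$end - sp$start + 1L
  }
}

#' Read genomes from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @param topology Topology to assign to every record (default circular).
#' @return A list of `genome` objects in file order.
#' @export
read_fasta <- function(path, topology = "circular") {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA: ", path)
  lapply(seq_along(set), function(i) {
    id <- sub("\\s.*$", "", names(set)[i])
    genome(id, as.character(set[[i]]), topology = topology)
  })
}

#' Write genomes to a FASTA file
#'
#' @param genomes A `genome` or list of `genome`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genomes, path) {
  if (inherits(genomes, "genome")) genomes <- list(genomes)
  seqs <- Biostrings::DNAStringSet(vapply(genomes, `[[`, "", "sequence"))
  names(seqs) <- vapply(genomes, `[[`, "", "id")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a GenBank flat file (sequence and CDS features)
#'
#' Minimal reader for deposited assemblies: parses LOCUS (id, topology),
#' the ORIGIN sequence block, and CDS feature locations (including
#' complement(), ignoring joins). Intended for ingest only.
#'
#' @param path Path to a GenBank flat file.
#' @return A list with `genome` (a `genome`) and `cds` (data.frame with
#'   start, end, strand).
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) == 0L) stop("not a GenBank flat file: ", path)
  toks <- strsplit(trimws(locus[1L]), "\\s+")[[1L]]
  id <- toks[2L]
  topology <- if (any(grepl("circular", locus[1L]))) "circular" else "linear"
  ori <- grep("^ORIGIN", lines)
  if (length(ori) == 0L) stop("no ORIGIN block in ", path)
  endrec <- grep("^//", lines)
  endrec <- endrec[endrec > ori[1L]][1L]
  if (is.na(endrec)) endrec <- length(lines) + 1L
  seqlines <- lines[(ori[1L] + 1L):(endrec - 1L)]
  seqtxt <- toupper(gsub("[ 0-9]", "", paste(seqlines, collapse = "")))
  cds_lines <- grep("^\\s{5}CDS\\s", lines, value = TRUE)
  cds <- data.frame(start = integer(), end = integer(), strand = character())
  if (length(cds_lines)) {
    loc <- trimws(sub("^\\s{5}CDS\\s+", "", cds_lines))
    strand <- ifelse(grepl("^complement", loc), "-", "+")
    nums <- regmatches(loc, gregexpr("[0-9]+", loc))
    keep <- lengths(nums) >= 2L
    cds <- data.frame(
      start = vapply(nums[keep], function(x) as.integer(x[1L]), 1L),
      end = vapply(nums[keep], function(x) as.integer(x[length(x)]), 1L),
      strand = strand[keep])
  }
  list(genome = genome(id, seqtxt, topology = topology), cds = cds)
}

#' GC content of a genome
#'
#' Fraction (G + C) / (A + C + G + T); ambiguous bases (N) are excluded from
#' both numerator and denominator.
#'
#' @param g A `genome`.
#' @return Fraction in `[0, 1]`.
#' @export
gc_content <- function(g) {
  counts <- table(strsplit(g$sequence, "", fixed = TRUE)[[1L]])
  acgt <- sum(counts[names(counts) %in% c("A", "C", "G", "T")])
  if (acgt == 0L) stop("GC content undefined: no unambiguous bases")
  gcc <- sum(counts[names(counts) %in% c("G", "C")])
  as.numeric(gcc / acgt)
}

#' Rotate a circular genome to a new origin
#'
#' Returns the genome whose sequence begins at position `new_origin` of the
#' input. The conventional anchor for baculoviruses is the first nucleotide
#' of the polyhedrin/granulin ORF.
#'
#' @param g A circular `genome`.
#' @param new_origin Position (1-based) that becomes position 1.
#' @return A `genome` of identical length.
#' @export
rotate <- function(g, new_origin) {
  if (g$topology != "circular") stop("cannot rotate a linear genome")
  new_origin <- as.integer(new_origin)
  if (new_origin < 1L || new_origin > g$length)
    stop("new_origin out of range")
  if (new_origin == 1L) return(g)
  s <- paste0(substr(g$sequence, new_origin, g$length),
              substr(g$sequence, 1L, new_origin - 1L))
  genome(g$id, s, topology = "circular")
}

#' Map a coordinate through a rotation
#'
#' Position `pos` on the original genome becomes this position after
#' `rotate(g, new_origin)`.
#'
#' @param pos Integer position(s), 1-based.
#' @param new_origin Rotation origin used.
#' @param genome_length Genome length.
#' @return Integer position(s) on the rotated genome.
#' @export
rotate_coord <- function(pos, new_origin, genome_length) {
  ((as.integer(pos) - as.integer(new_origin)) %% genome_length) + 1L
}

#' Extract the sequence of a span
#'
#' Minus-strand spans return the reverse complement; wrapping spans
#' concatenate the tail and head of a circular genome.
#'
#' @param g A `genome`.
#' @param sp A `span`.
#' @return Character scalar.
#' @export
subsequence <- function(g, sp) {
  if (sp$start > g$length || sp$end > g$length)
    stop("span coordinates out of range")
  s <- if (sp$wraps) {
    if (g$topology != "circular") stop("wrapping span on a linear genome")
    paste0(substr(g$sequence, sp$start, g$length),
           substr(g$sequence, 1L, sp$end))
  } else {
    substr(g$sequence, sp$start, sp$end)
  }
  if (sp$strand == "-") revcomp(s) else s
}

#' Write features as GFF3
#'
#' @param features data.frame with columns start, end, strand and optionally
#'   type, id, name (per-row attributes).
#' @param genome_id Sequence identifier for column 1.
#' @param path Output path.
#' @param source Source label for column 2.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, genome_id, path, source = "bacuchar") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(features)) {
    type <- if ("type" %in% names(features)) features$type else "CDS"
    id <- if ("id" %in% names(features)) features$id else seq_len(nrow(features))
    attrs <- paste0("ID=", id)
    if ("name" %in% names(features) && any(nzchar(features$name)))
      attrs <- ifelse(nzchar(features$name),
                      paste0(attrs, ";Name=", features$name), attrs)
    writeLines(paste(genome_id, source, type, features$start, features$end,
                     ".", features$strand, ".", attrs, sep = "\t"), con)
  }
  invisible(path)
}

#' Write repeat regions as BED
#'
#' BED is 0-based half-open; score is mean unit identity scaled to 0-1000.
#'
#' @param regions data.frame of repeat regions (see [find_repeat_regions()]).
#' @param genome_id Sequence identifier.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, genome_id, path) {
  lines <- character()
  if (nrow(regions)) {
    lines <- paste(genome_id, regions$start - 1L, regions$end,
                   regions$name, round(regions$mean_unit_identity * 1000),
                   sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}
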