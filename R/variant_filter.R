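#' Read a variant table (TSV or minimal VCF)
#'
#' TSV columns: position, ref, alt, frequency. Minimal VCF: CHROM POS ID
#' REF ALT QUAL FILTER INFO with an AF= key in INFO (fraction in (0,1]).
#'
#' @param path Path to the file.
#' @return data.frame with columns position, ref, alt, frequency, kind
#'   ("snp" when both alleles are single bases, else "indel").
#' @export
read_variants <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "##fileformat=VCF") || grepl("\\.vcf$", path)) {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#")]
    f <- strsplit(lines, "\t", fixed = TRUE)
    v <- data.frame(
      position = vapply(f, function(x) as.integer(x[2L]), 1L),
      ref = vapply(f, `[`, "", 3L + 1L),
      alt = vapply(f, `[`, "", 5L),
      frequency = vapply(f, function(x) {
        m <- regmatches(x[8L], regexpr("AF=[0-9.eE+-]+", x[8L]))
        if (!length(m)) return(NA_real_)
        as.numeric(sub("AF=", "", m))
      }, 0))
  } else {
    v <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("position", "ref", "alt", "frequency")
    miss <- setdiff(need, names(v))
    if (length(miss)) stop("variant table missing columns: ",
                           paste(miss, collapse = ", "))
  }
  v$kind <- ifelse(nchar(v$ref) == 1L & nchar(v$alt) == 1L, "snp", "indel")
  v
}

#' Filter variants by minimum frequency
#'
#' Keeps records with frequency >= `min_freq` (inclusive threshold: a
#' variant at exactly the cutoff is kept). Order is preserved.
#'
#' @param records data.frame with a `frequency` column, fractions in (0,1].
#' @param min_freq Minimum frequency (default 0.10).
#' @return Filtered data.frame.
#' @export
filter_variants <- function(records, min_freq = 0.10) {
  f <- records$frequency
  if (any(is.na(f)) || any(f <= 0) || any(f > 1))
    stop("variant frequencies must lie in (0, 1]")
  records[f >= min_freq, , drop = FALSE]
}

#' Classify the genomic context of variants
#'
#' A position inside any annotated ORF span (strand-agnostic) is "orf";
#' otherwise inside a repeat region it takes the region kind ("hr"/"dr");
#' otherwise "intergenic". ORFs take precedence over repeats.
#'
#' @param positions Integer positions (1-based).
#' @param orfs data.frame with start, end (and optionally wraps).
#' @param repeat_regions data.frame with start, end, kind.
#' @param genome_length Genome length (bounds check and wrap handling).
#' @return Character vector of contexts.
#' @export
classify_context <- function(positions, orfs, repeat_regions, genome_length) {
  if (any(positions < 1L | positions > genome_length))
    stop("variant position out of genome bounds")
  inside <- function(pos, start, end, wraps) {
    if (isTRUE(wraps)) pos >= start | pos <= end else pos >= start & pos <= end
  }
  ctx <- rep("intergenic", length(positions))
  if (!is.null(repeat_regions) && nrow(repeat_regions)) {
    for (r in seq_len(nrow(repeat_regions))) {
      w <- if ("wraps" %in% names(repeat_regions)) repeat_regions$wraps[r] else FALSE
      hit <- inside(positions, repeat_regions$start[r], repeat_regions$end[r], w)
      ctx[hit] <- repeat_regions$kind[r]
    }
  }
  if (!is.null(orfs) && nrow(orfs)) {
    for (r in seq_len(nrow(orfs))) {
      w <- if ("wraps" %in% names(orfs)) orfs$wraps[r] else FALSE
      hit <- inside(positions, orfs$start[r], orfs$end[r], w)
      ctx[hit] <- "orf"
    }
  }
  ctx
}

# 1-based index of a genomic position within the coding sequence of an ORF
.coding_index <- function(pos, start, end, strand, wraps, L) {
  if (strand == "+") {
    if (!wraps) pos - start + 1L
    else if (pos >= start) pos - start + 1L
    else (L - start + 1L) + pos
  } else {
    if (!wraps) end - pos + 1L
    else if (pos <= end) end - pos + 1L
    else end + (L - pos + 1L)
  }
}

#' Coding effect of a SNP within an ORF
#'
#' Translates the affected codon with the reference and the alternate base
#' on the coding strand; identical amino acids mean "synonymous". Indels
#' return "na".
#'
#' @param position Variant position (1-based, genome coordinates).
#' @param ref,alt Alleles (genome plus-strand).
#' @param orf One-row data.frame (or list) with start, end, strand, wraps.
#' @param g The `genome`.
#' @return `"synonymous"`, `"non_synonymous"`, or `"na"`.
#' @export
coding_effect <- function(position, ref, alt, orf, g) {
  if (nchar(ref) != 1L || nchar(alt) != 1L) return("na")
  wraps <- if (!is.null(orf$wraps)) isTRUE(orf$wraps) else FALSE
  cds <- subsequence(g, span(orf$start, orf$end, strand = orf$strand,
                             wraps = wraps))
  idx <- .coding_index(position, orf$start, orf$end, orf$strand, wraps,
                       g$length)
  if (idx < 1L || idx > nchar(cds)) stop("position outside the ORF")
  base_ref <- toupper(ref); base_alt <- toupper(alt)
  if (orf$strand == "-") {
    flip <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    base_ref <- unname(flip[base_ref]); base_alt <- unname(flip[base_alt])
  }
  if (substr(cds, idx, idx) != base_ref)
    stop("reference allele does not match the genome sequence")
  codon_i <- (idx - 1L) %/% 3L
  codon <- substr(cds, codon_i * 3L + 1L, codon_i * 3L + 3L)
  off <- idx - codon_i * 3L
  alt_codon <- codon
  substr(alt_codon, off, off) <- base_alt
  aa1 <- Biostrings::GENETIC_CODE[[codon]]
  aa2 <- Biostrings::GENETIC_CODE[[alt_codon]]
  if (identical(aa1, aa2)) "synonymous" else "non_synonymous"
}

#' Annotate a variant table with context and coding effect
#'
#' Applies the frequency filter, classifies genomic context against the
#' annotated ORFs and repeat regions, and computes per-SNP coding effects
#' for variants falling inside ORFs.
#'
#' @param records data.frame from [read_variants()] (or equivalent).
#' @param g The `genome`.
#' @param orfs Annotated ORF data.frame (start, end, strand, wraps).
#' @param repeat_regions Repeat region data.frame (start, end, kind).
#' @param min_freq Frequency cutoff (default 0.10, inclusive).
#' @return Filtered data.frame with added columns context and coding_effect,
#'   plus a `summary` attribute (counts by kind and context).
#' @export
annotate_variants <- function(records, g, orfs, repeat_regions,
                              min_freq = 0.10) {
  kept <- filter_variants(records, min_freq)
  if (!"kind" %in% names(kept)) {
    kept$kind <- ifelse(nchar(kept$ref) == 1L & nchar(kept$alt) == 1L,
                        "snp", "indel")
  }
  kept$context <- classify_context(kept$position, orfs, repeat_regions,
                                   g$length)
  kept$coding_effect <- "na"
  for (i in seq_len(nrow(kept))) {
    if (kept$kind[i] != "snp" || kept$context[i] != "orf") next
    w <- if ("wraps" %in% names(orfs)) orfs$wraps else rep(FALSE, nrow(orfs))
    hit <- which(ifelse(w, kept$position[i] >= orfs$start | kept$position[i] <= orfs$end,
                        kept$position[i] >= orfs$start & kept$position[i] <= orfs$end))
    if (!length(hit)) next
    kept$coding_effect[i] <- coding_effect(
      kept$position[i], kept$ref[i], kept$alt[i],
      orfs[hit[1L], , drop = FALSE], g)
  }
  attr(kept, "summary") <- list(
    total = nrow(kept),
    snps = sum(kept$kind == "snp"),
    indels = sum(kept$kind == "indel"),
    by_context = as.list(table(kept$context)))
  kept
}
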