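#' Default pipeline configuration
#'
#' Every threshold used anywhere in the pipeline, in one place, so a report
#' can record the exact parameters that produced it.
#'
#' @param ... Overrides for individual parameters.
#' @return Named list of parameters.
#' @export
default_config <- function(...) {
  cfg <- list(
    min_codons = 50L,          # ORF size floor, codons excluding stop
    max_overlap = 75L,         # tolerated overlap with a longer kept ORF, bp
    hr_probe = NULL,           # hr unit consensus; NULL = de-novo search
    hr_unit_length = 44L,      # hr unit length, bp
    hr_min_identity = 0.75,    # unit-vs-probe Hamming identity floor
    hr_max_gap = 500L,         # max intra-hr unit gap, bp
    hr_min_units = 2L,         # min units per hr
    dr_min_unit = 8L,          # dr period range, bp
    dr_max_unit = 100L,
    dr_min_copies = 4L,
    dr_min_unit_identity = 0.8,
    block_k = 16L,             # homology-block anchor k-mer
    block_min_length = 200L,   # bp
    block_min_identity = 0.8,
    rbh_min_identity = 0.25,
    rbh_min_coverage = 0.5,
    variant_min_freq = 0.10,   # inclusive frequency cutoff
    k2p_gamma_a = NULL,        # NULL = plain K2P
    demarcation_threshold = 0.05)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Characterize one genome
#'
#' Runs the per-genome stages in order: ORF enumeration, annotation filter,
#' optional anchor rotation and numbering, repeat-region discovery (hr via
#' probe or de-novo, dr via tandem-array search), and variant
#' classification. The report mirrors a genome-properties table: size, %GC,
#' annotated ORF count, repeat regions, variant summary.
#'
#' @param g A `genome`.
#' @param evidence Optional evidence data.frame (see [read_evidence()]).
#' @param variants Optional variant data.frame (see [read_variants()]).
#' @param anchor Optional c(start, end) of the plus-strand anchor ORF
#'   (polh/gran convention) for rotation and numbering.
#' @param config Parameter list from [default_config()].
#' @return list of class `characterization` with fields genome, orfs,
#'   repeats, variants, report.
#' @export
characterize <- function(g, evidence = NULL, variants = NULL, anchor = NULL,
                         config = default_config()) {
  cand <- enumerate_orfs(g, min_codons = config$min_codons)
  hr_hits <- if (!is.null(config$hr_probe)) {
    find_repeat_units(g, probe = config$hr_probe,
                      unit_length = config$hr_unit_length,
                      min_identity = config$hr_min_identity)
  } else {
    find_repeat_units(g, probe = NULL,
                      unit_length = config$hr_unit_length,
                      min_identity = config$hr_min_identity)
  }
  hrs <- cluster_into_hrs(hr_hits, g, max_gap = config$hr_max_gap,
                          min_units = config$hr_min_units)
  drs <- find_tandem_direct_repeats(
    g, min_unit = config$dr_min_unit, max_unit = config$dr_max_unit,
    min_copies = config$dr_min_copies,
    min_unit_identity = config$dr_min_unit_identity)
  # a tandem array recruited by the unit probe is better explained as a dr:
  # drop hr calls whose span overlaps a detected dr array
  if (nrow(hrs) && nrow(drs)) {
    clash <- vapply(seq_len(nrow(hrs)), function(i) {
      any(hrs$start[i] <= drs$end & hrs$end[i] >= drs$start)
    }, TRUE)
    hrs <- hrs[!clash, , drop = FALSE]
    if (nrow(hrs)) hrs$name <- paste0("hr", seq_len(nrow(hrs)))
  }
  repeats <- rbind(hrs, drs)
  kept <- apply_annotation_rules(cand, evidence, repeats,
                                 genome_length = g$length,
                                 max_overlap = config$max_overlap)
  g_out <- g
  if (!is.null(anchor)) {
    numbered <- number_orfs(kept, anchor[1L], anchor[2L], "+", g)
    g_out <- numbered$genome
    kept <- numbered$orfs
    shift <- function(x) rotate_coord(x, anchor[1L], g$length)
    repeats$start <- shift(repeats$start)
    repeats$end <- shift(repeats$end)
    repeats <- repeats[order(repeats$start), , drop = FALSE]
    repeats$name <- paste0(repeats$kind,
                           stats::ave(seq_len(nrow(repeats)), repeats$kind,
                                      FUN = seq_along))
    if (!is.null(variants))
      variants$position <- shift(variants$position)
  } else {
    kept$number <- seq_len(nrow(kept))
  }
  var_out <- NULL
  if (!is.null(variants)) {
    var_out <- annotate_variants(variants, g_out, kept, repeats,
                                 min_freq = config$variant_min_freq)
  }
  report <- list(
    genome_id = g$id,
    length_bp = g$length,
    gc_percent = 100 * gc_content(g),
    annotated_orfs = nrow(kept),
    evidence_provided = !is.null(evidence) && nrow(evidence) > 0L,
    repeat_regions = list(
      hr_count = sum(repeats$kind == "hr"),
      dr_count = sum(repeats$kind == "dr"),
      regions = if (nrow(repeats)) {
        rr <- repeats[, c("name", "kind", "start", "end", "unit_length",
                          "copies", "mean_unit_identity")]
        rownames(rr) <- NULL
        rr
      } else NULL),
    variants = if (!is.null(var_out)) attr(var_out, "summary") else NULL,
    config = config[!vapply(config, is.null, TRUE)])
  structure(list(genome = g_out, orfs = kept, repeats = repeats,
                 variants = var_out, report = report),
            class = "characterization")
}

#' @export
print.characterization <- function(x, ...) {
  r <- x$report
  cat(sprintf("<characterization> %s\n", r$genome_id))
  cat(sprintf("  length: %s bp   GC: %.2f%%\n",
              format(r$length_bp, big.mark = ","), r$gc_percent))
  cat(sprintf("  annotated ORFs: %d\n", r$annotated_orfs))
  cat(sprintf("  repeat regions: %d hr, %d dr\n",
              r$repeat_regions$hr_count, r$repeat_regions$dr_count))
  if (!is.null(r$variants))
    cat(sprintf("  variants kept: %d (%d SNP, %d indel)\n",
                r$variants$total, r$variants$snps, r$variants$indels))
  invisible(x)
}

#' Compare two characterized genomes
#'
#' Detects cross-genome homology blocks, flags annotated ORFs that each
#' block overlaps (and whether the block boundary truncates them), assigns
#' orthologs by reciprocal best hit, derives gene-parity points, and (when
#' locus coordinates are supplied) computes per-locus K2P distances with
#' the species-demarcation verdict.
#'
#' @param char_a,char_b `characterization` objects from [characterize()].
#' @param loci Optional data.frame with columns name, start_a, end_a,
#'   strand_a, start_b, end_b, strand_b giving aligned-locus coordinates on
#'   the two (rotated) genomes.
#' @param core_a Optional integer vector of core-gene ORF numbers in A.
#' @param config Parameter list from [default_config()].
#' @return list of class `comparison` with fields blocks, block_orfs,
#'   orthologs, parity, distances.
#' @export
compare_genomes <- function(char_a, char_b, loci = NULL, core_a = integer(),
                            config = default_config()) {
  ga <- char_a$genome; gb <- char_b$genome
  blocks <- find_homology_blocks(ga, gb, k = config$block_k,
                                 min_block = config$block_min_length,
                                 min_identity = config$block_min_identity)
  block_orfs <- .blocks_vs_orfs(blocks, char_a$orfs, ga$length, "a")
  block_orfs <- rbind(block_orfs,
                      .blocks_vs_orfs(blocks, char_b$orfs, gb$length, "b"))
  prot_a <- vapply(seq_len(nrow(char_a$orfs)), function(i) {
    o <- char_a$orfs[i, ]
    translate_orf(ga, o$start, o$end, o$strand, o$wraps)
  }, "")
  prot_b <- vapply(seq_len(nrow(char_b$orfs)), function(i) {
    o <- char_b$orfs[i, ]
    translate_orf(gb, o$start, o$end, o$strand, o$wraps)
  }, "")
  mapping <- if (length(prot_a) && length(prot_b)) {
    rbh_orthologs(prot_a, prot_b,
                  min_identity = config$rbh_min_identity,
                  min_coverage = config$rbh_min_coverage)
  } else {
    data.frame(a = integer(), b = integer(), identity = numeric())
  }
  parity <- gene_parity_points(mapping, length(prot_a), length(prot_b),
                               core_a = core_a)
  dist_tab <- NULL
  if (!is.null(loci) && nrow(loci)) {
    pairs <- lapply(seq_len(nrow(loci)), function(i) {
      la <- subsequence(ga, span(loci$start_a[i], loci$end_a[i],
                                 strand = loci$strand_a[i]))
      lb <- subsequence(gb, span(loci$start_b[i], loci$end_b[i],
                                 strand = loci$strand_b[i]))
      al <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(la), Biostrings::DNAString(lb), type = "global")
      list(as.character(Biostrings::alignedPattern(al)),
           as.character(Biostrings::alignedSubject(al)))
    })
    names(pairs) <- loci$name
    dist_tab <- distance_table(pairs, gamma_a = config$k2p_gamma_a,
                               threshold = config$demarcation_threshold)
  } else if (!is.null(loci)) {
    warning("empty locus table; distance section omitted")
  }
  structure(list(genome_a = ga$id, genome_b = gb$id, blocks = blocks,
                 block_orfs = block_orfs, orthologs = mapping,
                 parity = parity, distances = dist_tab,
                 config = config[!vapply(config, is.null, TRUE)]),
            class = "comparison")
}

# which ORFs does each block overlap, and does it truncate them?
.blocks_vs_orfs <- function(blocks, orfs, L, which_genome) {
  out <- data.frame(block = integer(), genome = character(),
                    orf_number = integer(), overlap_bp = integer(),
                    truncated = logical())
  if (!nrow(blocks) || !nrow(orfs)) return(out)
  bs <- blocks[[paste0("start_", which_genome)]]
  be <- blocks[[paste0("end_", which_genome)]]
  for (i in seq_len(nrow(blocks))) {
    for (j in seq_len(nrow(orfs))) {
      ov <- span_overlap(bs[i], be[i], FALSE,
                         orfs$start[j], orfs$end[j], isTRUE(orfs$wraps[j]), L)
      if (ov > 0L) {
        olen <- if (isTRUE(orfs$wraps[j]))
          (L - orfs$start[j] + 1L) + orfs$end[j]
        else orfs$end[j] - orfs$start[j] + 1L
        out <- rbind(out, data.frame(
          block = i, genome = which_genome,
          orf_number = if ("number" %in% names(orfs)) orfs$number[j] else j,
          overlap_bp = ov, truncated = ov < olen))
      }
    }
  }
  out
}

#' @export
print.comparison <- function(x, ...) {
  cat(sprintf("<comparison> %s vs %s\n", x$genome_a, x$genome_b))
  cat(sprintf("  homology blocks: %d\n", nrow(x$blocks)))
  if (nrow(x$blocks)) {
    top <- x$blocks[which.max(x$blocks$matches), ]
    cat(sprintf("  top block: %d bp at %.1f%% identity (%d-%d vs %d-%d)\n",
                top$alignment_length, 100 * top$percent_identity,
                top$start_a, top$end_a, top$start_b, top$end_b))
  }
  cat(sprintf("  ortholog pairs: %d   parity points: %d\n",
              nrow(x$orthologs), nrow(x$parity)))
  if (!is.null(x$distances)) {
    for (i in seq_len(nrow(x$distances)))
      cat(sprintf("  %s: d = %.3f (%s)\n", x$distances$locus[i],
                  x$distances$d[i], x$distances$verdict[i]))
  }
  invisible(x)
}

#' Write a characterization or comparison report bundle
#'
#' JSON is the machine-readable report; ORFs additionally go to GFF3 and
#' TSV, repeat regions to BED, blocks and parity to TSV.
#'
#' @param x A `characterization` or `comparison`.
#' @param outdir Output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_report <- function(x, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(x, "characterization")) {
    jsonlite::write_json(x$report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.table(x$orfs, file.path(outdir, "orfs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    gff_feats <- if (nrow(x$orfs)) {
      data.frame(start = x$orfs$start, end = x$orfs$end,
                 strand = x$orfs$strand, type = "CDS",
                 id = paste0("ORF", x$orfs$number), name = x$orfs$name)
    } else {
      data.frame(start = integer(), end = integer(), strand = character())
    }
    write_gff3(gff_feats, x$genome$id, file.path(outdir, "orfs.gff3"))
    if (nrow(x$repeats))
      write_bed(x$repeats, x$genome$id, file.path(outdir, "repeats.bed"))
    if (!is.null(x$variants))
      utils::write.table(x$variants, file.path(outdir, "variants.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (inherits(x, "comparison")) {
    rep <- x
    rep$blocks <- NULL; rep$parity <- NULL
    jsonlite::write_json(rep, file.path(outdir, "comparison.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    utils::write.table(x$blocks, file.path(outdir, "blocks.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(x$parity, file.path(outdir, "parity.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    stop("unsupported report object")
  }
  invisible(outdir)
}
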