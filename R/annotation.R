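#' Genes overlapping a mapped interval
#'
#' Returns the gene models whose genomic span overlaps the interval by at
#' least one base pair, in positional order. Membership is any-overlap: a gene
#' touching the interval boundary is included.
#'
#' @param models List of `gene_model` objects.
#' @param interval A `genomic_interval`.
#' @return List of `gene_model`, sorted by 5'-most genomic coordinate.
#' @export
genes_in_interval <- function(models, interval) {
  hit <- vapply(models, function(m) {
    sp <- gene_span(m)
    m$chrom == interval$chrom && sp[1L] <= interval$end && sp[2L] >= interval$start
  }, logical(1))
  kept <- models[hit]
  kept[order(gene_positions(kept))]
}

#' Filter variants by supporting-read depth
#'
#' Keeps variants supported by at least `min_support` distinct reads. Unknown
#' depth (NA) fails the filter whenever `min_support > 0`.
#'
#' @param variants A `variant_table` (see [read_variants()]).
#' @param min_support Minimum read support; default 2.
#' @return The filtered `variant_table`.
#' @export
filter_variants_by_support <- function(variants, min_support = 2L) {
  keep <- !is.na(variants$support_depth) & variants$support_depth >= min_support
  if (min_support <= 0L) keep <- keep | !is.na(variants$support_depth)
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Localize a variant relative to a gene model
#'
#' Region labels partition the genome relative to one gene, given a flanking
#' window: `upstream` within `window_bp` of the strand-aware transcription
#' start (inclusive at exactly `window_bp`), `downstream` mirrored from the
#' transcription end, `exon_coding`/`exon_noncoding`/`intron` inside the gene
#' span, and `intergenic` beyond the window. Localization uses the variant's
#' anchor position (`pos`).
#'
#' @param variant One-row `variant_table` or a list with `chrom` and `pos`.
#' @param model A `gene_model`.
#' @param window_bp Flanking window in bp; default 10000.
#' @return List with `region` and `distance_bp` (bp to the nearest gene
#'   boundary for upstream/downstream, 0 for genic, NA for intergenic).
#' @export
classify_variant_location <- function(variant, model, window_bp = 10000L) {
  pos <- as.integer(variant$pos)
  if (!identical(variant$chrom, model$chrom))
    return(list(region = "intergenic", distance_bp = NA_integer_))
  sp <- gene_span(model)
  if (pos >= sp[1L] && pos <= sp[2L]) {
    cd <- model$coding
    if (nrow(cd) > 0L && any(pos >= cd$start & pos <= cd$end))
      return(list(region = "exon_coding", distance_bp = 0L))
    ex <- model$exons
    if (any(pos >= ex$start & pos <= ex$end))
      return(list(region = "exon_noncoding", distance_bp = 0L))
    return(list(region = "intron", distance_bp = 0L))
  }
  # 5' flank is before the span start on '+', after the span end on '-'
  if (model$strand == "+") {
    d5 <- sp[1L] - pos   # positive when variant is left of the gene
    d3 <- pos - sp[2L]
  } else {
    d5 <- pos - sp[2L]
    d3 <- sp[1L] - pos
  }
  if (d5 >= 1L && d5 <= window_bp)
    return(list(region = "upstream", distance_bp = d5))
  if (d3 >= 1L && d3 <= window_bp)
    return(list(region = "downstream", distance_bp = d3))
  list(region = "intergenic", distance_bp = NA_integer_)
}

#' Spliced coding sequence of a gene model
#'
#' Concatenates the coding spans in transcription order; on the minus strand
#' the result is the reverse complement of the plus-strand concatenation.
#'
#' @param model A `gene_model` with at least one coding span.
#' @param sequence Named character vector/list, chromosome to nucleotide
#'   string.
#' @return List with `cds` (nucleotide string, transcription sense) and
#'   `in_frame` (TRUE when length is divisible by 3).
#' @export
spliced_coding_sequence <- function(model, sequence) {
  if (nrow(model$coding) == 0L) stop("gene ", model$gene_id, " has no CDS")
  if (!model$chrom %in% names(sequence))
    stop("chromosome ", model$chrom, " not in sequence")
  chrom_seq <- sequence[[model$chrom]]
  if (max(model$coding$end) > nchar(chrom_seq))
    stop("gene ", model$gene_id, ": coding span outside sequence")
  parts <- substring(chrom_seq, model$coding$start, model$coding$end)
  cds <- paste(parts, collapse = "")
  if (model$strand == "-")
    cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  list(cds = cds, in_frame = nchar(cds) %% 3L == 0L)
}

# Translate a nucleotide string (must be full codons) to a protein string with
# '*' for stops, standard nuclear genetic code.
translate_cds <- function(nt) {
  n <- nchar(nt) - nchar(nt) %% 3L
  if (n == 0L) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(substr(nt, 1L, n)),
                                     no.init.codon = TRUE))
}

comp_base <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# Map a genomic position inside a coding span to the 1-based position in the
# spliced CDS (transcription sense).
cds_position <- function(model, pos) {
  cd <- model$coding
  hit <- which(pos >= cd$start & pos <= cd$end)
  if (length(hit) != 1L) stop("position ", pos, " not in a coding span of ",
                              model$gene_id)
  before <- if (hit > 1L) sum(cd$end[seq_len(hit - 1L)] -
                                cd$start[seq_len(hit - 1L)] + 1L) else 0L
  plus_pos <- before + (pos - cd$start[hit] + 1L)
  total <- sum(cd$end - cd$start + 1L)
  if (model$strand == "+") plus_pos else total - plus_pos + 1L
}

#' Protein-level consequence of a coding SNP
#'
#' Translates the reference and mutated spliced coding sequences with the
#' standard genetic code and classifies the change as `synonymous`,
#' `missense` (notation refAA-residue-altAA, e.g. "N253D"), `stop_gained`, or
#' `stop_lost`. For a lost natural stop the downstream genomic sequence is
#' scanned in frame and `extension_aa` counts the additional residues up to
#' (excluding) the next in-frame stop, bounded by `max_extension_scan_aa`.
#'
#' @param variant One-row `variant_table` (must be a SNP inside a coding span).
#' @param model A `gene_model`.
#' @param sequence Named chromosome to nucleotide-string mapping.
#' @param max_extension_scan_aa Scan bound for stop-loss extensions.
#' @return List with `consequence`, `protein_change`, `extension_aa`,
#'   `extension_censored`.
#' @export
predict_coding_consequence <- function(variant, model, sequence,
                                       max_extension_scan_aa = 1000L) {
  if (variant$kind != "snp")
    stop("consequence prediction is defined for SNPs only")
  pos <- as.integer(variant$pos)
  chrom_seq <- sequence[[model$chrom]]
  ref_base <- toupper(substr(chrom_seq, pos, pos))
  if (ref_base != toupper(variant$ref))
    stop("reference mismatch at ", model$chrom, ":", pos, " (sequence ",
         ref_base, ", variant ref ", variant$ref, ")")
  cp <- cds_position(model, pos)  # errors if not in a coding span
  ref <- spliced_coding_sequence(model, sequence)
  if (!ref$in_frame)
    warning("gene ", model$gene_id, ": CDS length not a multiple of 3")
  alt_base <- toupper(variant$alt)
  cds_alt <- if (model$strand == "-") comp_base[[alt_base]] else alt_base
  mut_cds <- ref$cds
  substr(mut_cds, cp, cp) <- cds_alt

  ref_aa <- translate_cds(ref$cds)
  mut_aa <- translate_cds(mut_cds)
  codon_idx <- as.integer(ceiling(cp / 3))
  out <- list(consequence = "synonymous", protein_change = NA_character_,
              extension_aa = NA_integer_, extension_censored = FALSE)
  if (identical(ref_aa, mut_aa)) return(out)
  ref_res <- substr(ref_aa, codon_idx, codon_idx)
  mut_res <- substr(mut_aa, codon_idx, codon_idx)
  if (ref_res == mut_res) return(out)
  change <- paste0(ref_res, codon_idx, mut_res)
  if (ref_res != "*" && mut_res == "*") {
    out$consequence <- "stop_gained"
    out$protein_change <- change
  } else if (ref_res == "*" && mut_res != "*") {
    out$consequence <- "stop_lost"
    out$protein_change <- change
    ext <- scan_stop_extension(model, sequence, max_extension_scan_aa)
    out$extension_aa <- ext$extension_aa
    out$extension_censored <- ext$censored
  } else {
    out$consequence <- "missense"
    out$protein_change <- change
  }
  out
}

# Count additional residues read through a destroyed natural stop: 1 for the
# former stop codon itself plus downstream in-frame codons until (excluding)
# the next stop, read from genomic sequence past the CDS end.
scan_stop_extension <- function(model, sequence, max_aa) {
  chrom_seq <- sequence[[model$chrom]]
  n <- nchar(chrom_seq)
  need <- 3L * (max_aa - 1L)
  if (model$strand == "+") {
    from <- max(model$coding$end) + 1L
    tail_nt <- if (from > n) "" else substr(chrom_seq, from, min(n, from + need - 1L))
  } else {
    to <- min(model$coding$start) - 1L
    raw <- if (to < 1L) "" else substr(chrom_seq, max(1L, to - need + 1L), to)
    tail_nt <- if (nchar(raw)) as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(raw))) else ""
  }
  ext <- 1L  # the mutated former stop codon now encodes a residue
  n_codons <- nchar(tail_nt) %/% 3L
  i <- 1L
  while (i <= n_codons) {
    codon <- substr(tail_nt, 3L * i - 2L, 3L * i)
    if (translate_cds(codon) == "*")
      return(list(extension_aa = ext, censored = FALSE))
    ext <- ext + 1L
    if (ext >= max_aa) return(list(extension_aa = max_aa, censored = TRUE))
    i <- i + 1L
  }
  # ran off the chromosome before finding a stop
  list(extension_aa = ext, censored = TRUE)
}

#' Annotate variants against all gene models
#'
#' Each variant is annotated against every gene whose flanking window contains
#' it, so one variant may yield several rows; a variant inside no window gets
#' a single `intergenic` row. Coding SNPs receive a protein-level consequence
#' when sequence is supplied; coding indels are flagged
#' (`frameshift_not_called`) rather than consequence-called.
#'
#' @param variants A `variant_table`.
#' @param models List of `gene_model` objects.
#' @param sequence Optional chromosome to nucleotide-string mapping; without
#'   it, region labels are still produced but `consequence` stays `"none"`.
#' @param window_bp Flanking window in bp; default 10000.
#' @param max_extension_scan_aa Passed to [predict_coding_consequence()].
#' @return data.frame with columns chrom, pos, ref, alt, kind, support_depth,
#'   gene_id, region, distance_bp, consequence, protein_change, extension_aa,
#'   extension_censored, note.
#' @export
annotate_variants <- function(variants, models, sequence = NULL,
                              window_bp = 10000L,
                              max_extension_scan_aa = 1000L) {
  rows <- vector("list", 0L)
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, , drop = FALSE]
    hit_any <- FALSE
    for (m in models) {
      if (!identical(v$chrom, m$chrom)) next
      loc <- classify_variant_location(v, m, window_bp)
      if (loc$region == "intergenic") next
      hit_any <- TRUE
      cons <- "none"; pchg <- NA_character_
      ext <- NA_integer_; cens <- FALSE; note <- ""
      if (loc$region == "exon_coding") {
        if (v$kind == "indel") {
          note <- "frameshift_not_called"
        } else if (!is.null(sequence)) {
          pc <- predict_coding_consequence(v, m, sequence,
                                           max_extension_scan_aa)
          cons <- pc$consequence; pchg <- pc$protein_change
          ext <- pc$extension_aa; cens <- pc$extension_censored
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
        kind = v$kind, support_depth = v$support_depth,
        gene_id = m$gene_id, region = loc$region,
        distance_bp = loc$distance_bp, consequence = cons,
        protein_change = pchg, extension_aa = ext,
        extension_censored = cens, note = note,
        stringsAsFactors = FALSE)
    }
    if (!hit_any) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
        kind = v$kind, support_depth = v$support_depth,
        gene_id = NA_character_, region = "intergenic",
        distance_bp = NA_integer_, consequence = "none",
        protein_change = NA_character_, extension_aa = NA_integer_,
        extension_censored = FALSE, note = "",
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty_annotation_frame())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_annotation_frame <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), kind = character(), support_depth = integer(),
             gene_id = character(), region = character(),
             distance_bp = integer(), consequence = character(),
             protein_change = character(), extension_aa = integer(),
             extension_censored = logical(), note = character(),
             stringsAsFactors = FALSE)
}
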