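#' Genomic interval
#'
#' 1-based, fully closed interval on a named chromosome. All coordinates in
#' the package follow the GFF3/VCF convention (1-based, inclusive).
#'
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive bounds, `start <= end`.
#' @return An object of class `genomic_interval`.
#' @export
genomic_interval <- function(chrom, start, end) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (length(chrom) != 1L || !is.character(chrom) || is.na(chrom))
    stop("chrom must be a single string")
  if (is.na(start) || is.na(end) || start > end)
    stop("invalid interval: need start <= end, got [", start, ", ", end, "]")
  structure(list(chrom = chrom, start = start, end = end),
            class = "genomic_interval")
}

#' @export
format.genomic_interval <- function(x, ...) {
  sprintf("%s:%d-%d", x$chrom, x$start, x$end)
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat("<genomic_interval>", format(x), "\n")
  invisible(x)
}

#' Length of a genomic interval in bp
#' @param interval A `genomic_interval`.
#' @return Integer width (end - start + 1).
#' @export
interval_length <- function(interval) {
  interval$end - interval$start + 1L
}

#' Stranded gene model
#'
#' A gene with sorted, non-overlapping exons and coding spans (CDS). The
#' transcription start (`tss`) and end (`tes`) are strand-aware: on the minus
#' strand `tss > tes`.
#'
#' @param gene_id Unique gene identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with integer columns `start`, `end` (1-based
#'   inclusive); will be sorted by position.
#' @param coding data.frame with columns `start`, `end` for CDS spans; each
#'   span must lie within the union of exons. May have zero rows for a
#'   non-coding gene.
#' @return An object of class `gene_model` with fields `gene_id`, `chrom`,
#'   `strand`, `tss`, `tes`, `exons`, `coding`, `warnings`.
#' @export
gene_model <- function(gene_id, chrom, strand, exons, coding = exons[0, ]) {
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  exons <- data.frame(start = as.integer(exons$start),
                      end = as.integer(exons$end))
  coding <- data.frame(start = as.integer(coding$start),
                       end = as.integer(coding$end))
  if (nrow(exons) == 0L) stop("gene model needs at least one exon")
  exons <- exons[order(exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  coding <- coding[order(coding$start), , drop = FALSE]
  rownames(coding) <- NULL
  if (any(exons$end < exons$start) || any(coding$end < coding$start))
    stop("gene ", gene_id, ": span with end < start")
  if (nrow(exons) > 1L && any(exons$start[-1L] <= exons$end[-nrow(exons)]))
    stop("gene ", gene_id, ": overlapping or unsorted exons")
  for (i in seq_len(nrow(coding))) {
    inside <- any(coding$start[i] >= exons$start & coding$end[i] <= exons$end)
    if (!inside)
      stop("gene ", gene_id, ": coding span ", coding$start[i], "-",
           coding$end[i], " not contained in an exon")
  }
  warnings <- character()
  cds_len <- sum(coding$end - coding$start + 1L)
  if (cds_len > 0L && cds_len %% 3L != 0L)
    warnings <- c(warnings, "cds_length_not_multiple_of_3")
  span <- c(min(exons$start), max(exons$end))
  structure(list(
    gene_id = gene_id, chrom = chrom, strand = strand,
    tss = if (strand == "+") span[1L] else span[2L],
    tes = if (strand == "+") span[2L] else span[1L],
    exons = exons, coding = coding, warnings = warnings
  ), class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d (%s), %d exon(s), %d CDS span(s)\n",
              x$gene_id, x$chrom, gene_span(x)[1L], gene_span(x)[2L],
              x$strand, nrow(x$exons), nrow(x$coding)))
  invisible(x)
}

#' Genomic span of a gene model
#' @param model A `gene_model`.
#' @return Integer vector `c(start, end)` in genomic (plus-strand) order.
#' @export
gene_span <- function(model) {
  c(min(model$exons$start), max(model$exons$end))
}

#' Total coding length of a gene model in bp
#' @param model A `gene_model`.
#' @return Integer number of coding bases.
#' @export
coding_length <- function(model) {
  if (nrow(model$coding) == 0L) return(0L)
  sum(model$coding$end - model$coding$start + 1L)
}

# Positions of genes (5'-most genomic coordinate), used for stable ordering.
gene_positions <- function(models) {
  vapply(models, function(m) gene_span(m)[1L], integer(1))
}

#' Validate a set of gene models against a sequence
#'
#' Checks identifier uniqueness and, when sequence is supplied, that every
#' exon lies within its chromosome.
#'
#' @param models List of `gene_model` objects.
#' @param sequence Optional named character vector or list, chromosome name to
#'   nucleotide string.
#' @return Invisibly `TRUE`; errors describe the first violation found.
#' @export
validate_annotation <- function(models, sequence = NULL) {
  ids <- vapply(models, `[[`, character(1), "gene_id")
  if (anyDuplicated(ids))
    stop("duplicate gene identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (!is.null(sequence)) {
    for (m in models) {
      if (!m$chrom %in% names(sequence))
        stop("gene ", m$gene_id, ": chromosome ", m$chrom, " not in sequence")
      len <- nchar(sequence[[m$chrom]])
      if (max(m$exons$end) > len)
        stop("gene ", m$gene_id, ": exon beyond end of ", m$chrom,
             " (", len, " bp)")
    }
  }
  invisible(TRUE)
}
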