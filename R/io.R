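#' Read gene models from GFF3
#'
#' Parses gene/mRNA/exon/CDS features (1-based inclusive coordinates) into
#' [gene_model()] objects, one per gene, with exons and coding spans sorted by
#' position. A CDS whose total length is not divisible by 3 is loaded with a
#' validation warning recorded on the model.
#'
#' @param path Path to a GFF3 file.
#' @param text Alternatively, GFF3 content as a character vector of lines.
#' @return List of `gene_model` objects, ordered by genomic position.
#' @export
read_gene_models <- function(path = NULL, text = NULL) {
  if (is.null(path)) {
    path <- tempfile(fileext = ".gff3")
    on.exit(unlink(path))
    writeLines(text, path)
  }
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  if (length(body) == 0L) return(list())
  nfield <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, integer(1))
  if (any(nfield != 9L))
    stop("malformed GFF3 line ", body[which(nfield != 9L)[1L]],
         ": expected 9 tab-separated fields")
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  df$type <- as.character(df$type)
  first_parent <- function(p) if (length(p) >= 1L) p[[1L]] else NA_character_
  df$parent <- vapply(df$Parent, function(p)
    if (length(p) >= 1L) as.character(p)[1L] else NA_character_, character(1))

  genes <- df[df$type == "gene", , drop = FALSE]
  mrnas <- df[df$type == "mRNA", , drop = FALSE]
  models <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    gid <- genes$ID[i]
    tx <- mrnas$ID[!is.na(mrnas$parent) & mrnas$parent == gid]
    owners <- c(gid, tx)
    kids <- df[!is.na(df$parent) & df$parent %in% owners, , drop = FALSE]
    ex <- kids[kids$type == "exon", c("start", "end"), drop = FALSE]
    cd <- kids[kids$type == "CDS", c("start", "end"), drop = FALSE]
    if (nrow(ex) == 0L) ex <- genes[i, c("start", "end"), drop = FALSE]
    models[[i]] <- gene_model(gene_id = gid, chrom = genes$seqnames[i],
                              strand = genes$strand[i], exons = ex,
                              coding = cd)
  }
  validate_annotation(models)
  models[order(gene_positions(models))]
}

# GFF3 phase of CDS spans in transcription order.
cds_phases <- function(model) {
  cd <- model$coding
  if (nrow(cd) == 0L) return(integer())
  ord <- if (model$strand == "+") order(cd$start) else order(-cd$start)
  lens <- (cd$end - cd$start + 1L)[ord]
  ph <- integer(length(lens))
  done <- 0L
  for (i in seq_along(lens)) {
    ph[i] <- (3L - done %% 3L) %% 3L
    done <- done + lens[i]
  }
  ph[order(ord)]  # back to positional order
}

#' Write gene models as GFF3
#'
#' Emits gene, mRNA, exon and CDS features (one mRNA per gene) with computed
#' CDS phases; output is deterministic so identical models give identical
#' bytes. Round-trips through [read_gene_models()].
#'
#' @param models List of `gene_model` objects.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_gene_models <- function(models, path) {
  out <- "##gff-version 3"
  models <- models[order(gene_positions(models))]
  for (m in models) {
    sp <- gene_span(m)
    tx <- paste0(m$gene_id, ".1")
    line <- function(type, s, e, phase, attrs)
      paste(m$chrom, "fsqtl", type, s, e, ".", m$strand, phase, attrs,
            sep = "\t")
    out <- c(out,
             line("gene", sp[1L], sp[2L], ".", paste0("ID=", m$gene_id)),
             line("mRNA", sp[1L], sp[2L], ".",
                  paste0("ID=", tx, ";Parent=", m$gene_id)))
    for (j in seq_len(nrow(m$exons)))
      out <- c(out, line("exon", m$exons$start[j], m$exons$end[j], ".",
                         paste0("ID=", tx, ".exon", j, ";Parent=", tx)))
    ph <- cds_phases(m)
    for (j in seq_len(nrow(m$coding)))
      out <- c(out, line("CDS", m$coding$start[j], m$coding$end[j], ph[j],
                         paste0("ID=", tx, ".cds", j, ";Parent=", tx)))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read variants from VCF
#'
#' Loads VCF 4.x records into a `variant_table` data.frame. Supporting-read
#' depth is taken from the INFO `DP` field; a missing depth is recorded as NA
#' (unknown), which downstream support filtering treats as failing. Kind is
#' inferred from allele lengths (`snp` iff both alleles are single bases).
#'
#' @param path Path to a plain-text or bgzipped VCF.
#' @param text Alternatively, VCF content as a character vector of lines.
#' @return data.frame of class `variant_table` with columns chrom, pos, ref,
#'   alt, support_depth, kind.
#' @export
read_variants <- function(path = NULL, text = NULL) {
  if (is.null(path)) {
    path <- tempfile(fileext = ".vcf")
    on.exit(unlink(path))
    writeLines(text, path)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE),
                       stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) return(empty_variant_table())
  if (any(grepl(",", fix$ALT, fixed = TRUE)))
    stop("multi-allelic records are not supported; split them first")
  dp <- suppressWarnings(as.integer(sub(".*\\bDP=([0-9]+).*", "\\1",
                                        fix$INFO)))
  dp[!grepl("\\bDP=[0-9]+", fix$INFO)] <- NA_integer_
  out <- variant_table(chrom = fix$CHROM, pos = as.integer(fix$POS),
                       ref = toupper(fix$REF), alt = toupper(fix$ALT),
                       support_depth = dp)
  out
}

#' Construct a variant table
#'
#' @param chrom,pos,ref,alt,support_depth Parallel vectors of record fields;
#'   `support_depth` may be NA for unknown depth.
#' @return data.frame of class `variant_table`, sorted by chrom then pos.
#' @export
variant_table <- function(chrom, pos, ref, alt, support_depth = NA_integer_) {
  out <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                    ref = as.character(ref), alt = as.character(alt),
                    support_depth = as.integer(support_depth),
                    stringsAsFactors = FALSE)
  if (any(out$ref == out$alt))
    stop("ref and alt alleles must differ (row ",
         which(out$ref == out$alt)[1L], ")")
  out$kind <- ifelse(nchar(out$ref) == 1L & nchar(out$alt) == 1L,
                     "snp", "indel")
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("variant_table", "data.frame")
  out
}

empty_variant_table <- function() {
  variant_table(character(), integer(), character(), character(), integer())
}

#' Write variants as plain-text VCF 4.2
#'
#' Deterministic byte output; depth is emitted as `DP=<n>` in INFO, missing
#' depth as `.`. Round-trips through [read_variants()].
#'
#' @param variants A `variant_table`.
#' @param path Output file path.
#' @param contigs Optional named integer vector of contig lengths for the
#'   header.
#' @return Invisibly, `path`.
#' @export
write_variants <- function(variants, path, contigs = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Supporting read depth\">")
  if (!is.null(contigs))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                          as.integer(contigs)))
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- ifelse(is.na(variants$support_depth), ".",
                 sprintf("DP=%d", variants$support_depth))
  rec <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t%s", variants$chrom, variants$pos,
                 variants$ref, variants$alt, info)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read a genomic sequence from FASTA
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, chromosome name to nucleotide string.
#' @export
read_sequence <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write a genomic sequence as FASTA
#'
#' @param sequence Named character vector/list, chromosome to nucleotide
#'   string.
#' @param path Output file path.
#' @param width Line width; default 70.
#' @return Invisibly, `path`.
#' @export
write_sequence <- function(sequence, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(sequence)) {
    writeLines(paste0(">", nm), con)
    s <- sequence[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read an expression table (TSV)
#'
#' First column must be the gene identifier; remaining columns are samples.
#' Empty cells are loaded as absent (NA), never as zero. Duplicate gene ids
#' and non-numeric cells are errors.
#'
#' @param path Path to a tab-separated table with a header row.
#' @param name Dataset name; defaults to the file name.
#' @param samples Optional data.frame with columns `sample`, `tissue`,
#'   `genotype` describing the columns.
#' @return An `expression_dataset`.
#' @export
read_expression_table <- function(path, name = basename(path),
                                  samples = NULL) {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = c("NA", ""))
  if (ncol(raw) < 2L) stop("expression table needs a gene column and samples")
  ids <- raw[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate gene id: ", ids[duplicated(ids)][1L])
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = list(ids, colnames(vals))))
  bad <- which(!is.na(vals) & is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("non-numeric cell at gene ", ids[bad[1L, 1L]], ", sample ",
         colnames(vals)[bad[1L, 2L]], ": '", vals[bad[1L, , drop = FALSE]], "'")
  expression_dataset(name = name, values = num, samples = samples)
}

#' Construct an expression dataset
#'
#' @param name Dataset name.
#' @param values Numeric gene-by-sample matrix with rownames = gene ids;
#'   absent measurements as NA.
#' @param samples Optional sample-description data.frame (`sample`, `tissue`,
#'   `genotype`).
#' @return Object of class `expression_dataset`.
#' @export
expression_dataset <- function(name, values, samples = NULL) {
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have gene rownames and sample colnames")
  if (any(values < 0, na.rm = TRUE)) stop("RPKM values must be non-negative")
  if (is.null(samples))
    samples <- data.frame(sample = colnames(values), tissue = NA_character_,
                          genotype = NA_character_, stringsAsFactors = FALSE)
  structure(list(name = name, values = values, samples = samples),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %s: %d genes x %d samples (%d absent cells)\n",
              x$name, nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' Write an expression dataset as TSV
#'
#' Absent cells are written as `NA`; values are emitted with full precision
#' (up to 15 significant digits) so read/write round-trips.
#'
#' @param dataset An `expression_dataset`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_expression_table <- function(dataset, path) {
  m <- dataset$values
  df <- data.frame(gene_id = rownames(m),
                   apply(m, 2L, function(col) ifelse(is.na(col), NA,
                                                     format(col, digits = 15L,
                                                            trim = TRUE,
                                                            scientific = FALSE))),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a phenotype table (TSV)
#'
#' Expected columns: `plant_id`, `genotype` (mutant/heterozygous/wild-type),
#' `organ`, `length_mm`, `width_mm`, optionally `widest_position_mm`.
#'
#' @param path Path to the table.
#' @return data.frame of measurements.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("plant_id", "genotype", "organ", "length_mm", "width_mm")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("phenotype table missing column(s): ", paste(missing, collapse = ", "))
  if (any(df$length_mm <= 0 | df$width_mm <= 0, na.rm = TRUE))
    stop("lengths and widths must be positive")
  df
}

#' Read a term-to-gene map (TSV)
#'
#' Expected columns: `term_id`, `gene_id`, optionally `label`.
#'
#' @param path Path to the table.
#' @return data.frame with columns term_id, gene_id, label.
#' @export
read_term_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("term_id", "gene_id") %in% names(df)))
    stop("term map needs columns term_id and gene_id")
  if (is.null(df$label)) df$label <- df$term_id
  df[, c("term_id", "gene_id", "label")]
}

#' Read curated function flags (TSV)
#'
#' Expert-curated putative-function evidence: columns `gene_id`, `flag`
#' (TRUE/FALSE), optionally `annotation` free text.
#'
#' @param path Path to the table.
#' @return data.frame with columns gene_id, flag, annotation.
#' @export
read_function_flags <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "flag") %in% names(df)))
    stop("function flag table needs columns gene_id and flag")
  df$flag <- as.logical(df$flag)
  if (is.null(df$annotation)) df$annotation <- ""
  df[, c("gene_id", "flag", "annotation")]
}
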