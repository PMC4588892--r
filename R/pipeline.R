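#' Read a paired family comparison table (TSV)
#'
#' Columns: `gene_id`, `rpkm_mut`, `rpkm_wt`; empty cells are absent.
#'
#' @param path Path to the table.
#' @return data.frame with the three columns.
#' @export
read_family_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  need <- c("gene_id", "rpkm_mut", "rpkm_wt")
  if (!all(need %in% names(df)))
    stop("family table needs columns ", paste(need, collapse = ", "))
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene id in family table: ",
         df$gene_id[duplicated(df$gene_id)][1L])
  df[, need]
}

#' Pipeline configuration for a candidate scan
#'
#' @param gff Path to the gene-model GFF3.
#' @param vcf Path to the variant VCF.
#' @param family_files Named character vector (family label to path) of the
#'   three paired comparison tables.
#' @param smallest_family Label of the smallest-introgression family.
#' @param dataset_files Named character vector (dataset id to path) of
#'   expression tables used for expressed/tissue calls.
#' @param dataset_classes Named character vector mapping each dataset id to
#'   `"ovary"`, `"meristem"` or `"other"`.
#' @param interval A [genomic_interval()] delimiting the mapped region.
#' @param fasta Optional path to the genomic FASTA (enables consequence
#'   calls).
#' @param function_flags Optional path to a curated function-flag table.
#' @param out_dir Output directory.
#' @param rpkm_threshold,fc_threshold,window_bp,min_support,pseudocount
#'   Pipeline thresholds (defaults 2 RPKM, 0.5, 10 kb, 2 reads, 0.1).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(gff, vcf, family_files, smallest_family,
                            dataset_files, dataset_classes, interval,
                            fasta = NULL, function_flags = NULL,
                            out_dir = tempfile("fsqtl_scan_"),
                            rpkm_threshold = 2, fc_threshold = 0.5,
                            window_bp = 10000L, min_support = 2L,
                            pseudocount = 0.1) {
  if (length(family_files) != 3L || is.null(names(family_files)))
    stop("family_files must be a named vector of three paths")
  if (!smallest_family %in% names(family_files))
    stop("smallest_family must name one of the family_files")
  if (is.null(names(dataset_files)))
    stop("dataset_files must be named")
  if (!all(names(dataset_files) %in% names(dataset_classes)))
    stop("every dataset needs a class in dataset_classes")
  if (!all(dataset_classes %in% c("ovary", "meristem", "other")))
    stop("dataset classes must be ovary, meristem or other")
  stopifnot(rpkm_threshold > 0, fc_threshold > 0, window_bp > 0,
            min_support >= 0)
  structure(list(gff = gff, vcf = vcf, family_files = family_files,
                 smallest_family = smallest_family,
                 dataset_files = dataset_files,
                 dataset_classes = dataset_classes, interval = interval,
                 fasta = fasta, function_flags = function_flags,
                 out_dir = out_dir, rpkm_threshold = rpkm_threshold,
                 fc_threshold = fc_threshold, window_bp = window_bp,
                 min_support = min_support, pseudocount = pseudocount),
            class = "pipeline_config")
}

#' End-to-end candidate-gene scan
#'
#' Runs interval extraction, expressed calls, the tissue-relevance filter,
#' consistent differential-expression calls, variant support filtering,
#' variant-to-gene annotation, and evidence integration, then writes the
#' candidate table, per-stage tables and a run manifest to the output
#' directory. A stage failure aborts with the stage name and removes partial
#' outputs. Outputs are a deterministic function of the inputs and config.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `candidates`, `de_calls`, `annotations`,
#'   `expressed`, `retained`, and `paths` of the written files.
#' @export
run_candidate_scan <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  fail <- function(stage, e) {
    unlink(written)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  }
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    fail(name, e))

  models <- stage("read_annotation", read_gene_models(config$gff))
  sequence <- if (!is.null(config$fasta))
    stage("read_sequence", read_sequence(config$fasta)) else NULL
  region <- stage("interval_extraction",
                  genes_in_interval(models, config$interval))
  region_ids <- vapply(region, `[[`, character(1), "gene_id")

  datasets <- stage("read_expression", {
    out <- list()
    for (d in names(config$dataset_files))
      out[[d]] <- read_expression_table(config$dataset_files[[d]], name = d)
    out
  })
  calls <- stage("expressed_calls",
                 expressed_call(datasets, config$rpkm_threshold))
  calls <- calls[calls$gene_id %in% region_ids, , drop = FALSE]
  # region genes absent from every dataset: expressed nowhere
  missing <- setdiff(region_ids, calls$gene_id)
  if (length(missing)) {
    pad <- calls[rep(NA_integer_, length(missing)), , drop = FALSE]
    pad$gene_id <- missing
    pad[setdiff(names(pad), "gene_id")] <- FALSE
    calls <- rbind(calls, pad)
  }
  calls <- calls[match(region_ids, calls$gene_id), , drop = FALSE]
  rownames(calls) <- NULL

  retained <- stage("tissue_filter", {
    cls <- config$dataset_classes
    profiles <- expression_profiles(calls,
                                    dataset_cols = names(config$dataset_files))
    tissue_relevance_filter(
      profiles,
      ovary_sets = names(cls)[cls == "ovary"],
      meristem_sets = names(cls)[cls == "meristem"],
      other_sets = names(cls)[cls == "other"])
  })

  de_calls <- stage("de_calls", {
    fams <- names(config$family_files)
    mk <- function(col) {
      m <- matrix(NA_real_, length(region_ids), 3L,
                  dimnames = list(region_ids, fams))
      for (f in fams) {
        tab <- read_family_table(config$family_files[[f]])
        i <- match(region_ids, tab$gene_id)
        m[, f] <- tab[[col]][i]
      }
      m
    }
    cs <- comparison_set(mk("rpkm_mut"), mk("rpkm_wt"),
                         config$smallest_family, config$pseudocount)
    region_de_call(cs, config$fc_threshold)
  })

  annotations <- stage("variant_annotation", {
    variants <- read_variants(config$vcf)
    supported <- filter_variants_by_support(variants, config$min_support)
    annotate_variants(supported, region, sequence, config$window_bp)
  })
  evidence <- stage("variant_evidence",
                    attach_variant_evidence(retained, annotations))

  flags <- if (!is.null(config$function_flags))
    stage("function_flags", read_function_flags(config$function_flags))
  else NULL

  candidates <- stage("candidate_selection", {
    pos <- stats::setNames(gene_positions(region), region_ids)
    select_candidates(retained, de_calls, evidence, flags, pos)
  })

  paths <- list(candidates = file.path(config$out_dir, "candidates.tsv"),
                annotations = file.path(config$out_dir, "annotations.tsv"),
                expressed = file.path(config$out_dir, "expressed_calls.tsv"),
                de = file.path(config$out_dir, "de_calls.tsv"),
                manifest = file.path(config$out_dir, "manifest.txt"))
  written <- c(unlist(paths), paths$candidates,
               paste0(paths$candidates, ".summary.txt"))
  stage("write_reports", {
    rep <- render_candidate_report(candidates, paths$candidates)
    wt <- function(df, path) utils::write.table(
      df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
    wt(annotations, paths$annotations)
    wt(calls, paths$expressed)
    wt(de_calls, paths$de)
    manifest <- c(
      "fsqtl candidate scan manifest",
      sprintf("interval: %s", format(config$interval)),
      sprintf("gff: %s", config$gff),
      sprintf("vcf: %s", config$vcf),
      sprintf("fasta: %s", config$fasta %||% "(none)"),
      sprintf("families: %s (smallest: %s)",
              paste(names(config$family_files), collapse = ", "),
              config$smallest_family),
      sprintf("datasets: %s",
              paste(sprintf("%s[%s]", names(config$dataset_files),
                            config$dataset_classes[names(config$dataset_files)]),
                    collapse = ", ")),
      sprintf("thresholds: rpkm>%g, |log2fc|>%g, window=%d bp, support>=%d, pseudocount=%g",
              config$rpkm_threshold, config$fc_threshold, config$window_bp,
              config$min_support, config$pseudocount))
    writeLines(manifest, paths$manifest)
  })
  invisible(list(candidates = candidates, de_calls = de_calls,
                 annotations = annotations, expressed = calls,
                 retained = retained, paths = paths))
}

#' Per-organ phenotype statistics
#'
#' For each organ: genotype means and standard errors of maximal length,
#' maximal width and shape index (per-plant means of per-organ ratios),
#' pooled-variance t tests of mutant versus wild type, and the D/A gene
#' action when heterozygotes are present. Organs with fewer than two plants
#' in a genotype are omitted with a warning.
#'
#' @param phenotypes Path to a phenotype TSV (see [read_phenotypes()]) or an
#'   equivalent data.frame.
#' @param out_dir Optional output directory for `morpho_stats.tsv`.
#' @return data.frame, one row per organ, invisibly written when `out_dir` is
#'   given.
#' @export
run_morpho_stats <- function(phenotypes, out_dir = NULL) {
  df <- if (is.character(phenotypes)) read_phenotypes(phenotypes)
        else phenotypes
  df$shape <- shape_index(df$length_mm, df$width_mm)
  per_plant <- stats::aggregate(
    df[, c("length_mm", "width_mm", "shape")],
    by = list(organ = df$organ, genotype = df$genotype,
              plant_id = df$plant_id), FUN = mean)
  se <- function(x) stats::sd(x) / sqrt(length(x))
  rows <- list()
  for (organ in sort(unique(per_plant$organ))) {
    sub <- per_plant[per_plant$organ == organ, , drop = FALSE]
    counts <- table(sub$genotype)
    thin <- names(counts)[counts < 2L]
    if (length(thin)) {
      warning("organ ", organ, ": fewer than two plants for genotype(s) ",
              paste(thin, collapse = ", "), "; omitted")
      next
    }
    g <- function(geno, col) sub[[col]][sub$genotype == geno]
    have <- rownames(counts)
    row <- data.frame(organ = organ, stringsAsFactors = FALSE)
    for (geno in c("mutant", "heterozygous", "wild-type")) {
      if (!geno %in% have) next
      tag <- sub("-", "_", geno)
      for (col in c("length_mm", "width_mm", "shape")) {
        row[[paste0(tag, "_", col, "_mean")]] <- mean(g(geno, col))
        row[[paste0(tag, "_", col, "_se")]] <- se(g(geno, col))
      }
      row[[paste0(tag, "_n")]] <- sum(sub$genotype == geno)
    }
    if (all(c("mutant", "wild-type") %in% have)) {
      for (col in c("length_mm", "width_mm", "shape")) {
        pt <- progeny_test(g("mutant", col), g("wild-type", col))
        row[[paste0(col, "_t")]] <- pt$t
        row[[paste0(col, "_p")]] <- pt$p_value
      }
      if ("heterozygous" %in% have) {
        mu <- function(col, geno) mean(g(geno, col))
        for (col in c("length_mm", "shape")) {
          mm <- mu(col, "mutant"); mw <- mu(col, "wild-type")
          row[[paste0(col, "_DA")]] <- if (mm == mw) NA_real_
            else gene_action(mm, mu(col, "heterozygous"), mw)
        }
      }
    }
    rows[[length(rows) + 1L]] <- row
  }
  out <- if (length(rows)) do.call(rbind_fill, rows) else data.frame()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fmt <- out
    num <- vapply(fmt, is.numeric, logical(1))
    fmt[num] <- lapply(fmt[num], function(x) sprintf("%.6g", x))
    utils::write.table(fmt, file.path(out_dir, "morpho_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
  }
  out
}

# rbind data.frames with unequal columns, filling with NA.
rbind_fill <- function(...) {
  dfs <- list(...)
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    for (c in setdiff(cols, names(d))) d[[c]] <- NA
    d[, cols, drop = FALSE]
  }))
}
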