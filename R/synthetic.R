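#' Configuration of a synthetic QTL candidate-gene study
#'
#' Defines a complete seeded study: a mapped interval with stranded gene
#' models, background and planted sequence variants, three paired mutant/WT
#' expression comparisons plus tissue atlas datasets, and genotype-dependent
#' organ measurements. Defaults emulate the fs8.1 study conditions at 1:10
#' scale: a 100 kb interval with 12 genes, 16 background SNPs and 1 small
#' indel (the full-scale regime is 3.03 Mb, ~122 genes, 158 SNPs and 5
#' indels and is available via `full_scale_config()`), planted fold-changes
#' near the reported candidate values (-4.1 and +0.6), and an ovary phenotype
#' plan with wild-type length 1.93 mm shifted by +0.27 mm in the mutant,
#' width 1.95 mm unchanged, and dominance -0.47 toward the wild type.
#'
#' @param seed Integer seed; every generator is a pure function of the config.
#' @param chrom Chromosome name of the interval.
#' @param interval_length Interval length in bp.
#' @param n_genes Number of genes packed into the interval.
#' @param n_background_snps,n_background_indels Background variant counts.
#' @param frac_low_support Fraction of background variants drawn with read
#'   support below 2 (exercises the support filter).
#' @param families Labels of the three family comparisons.
#' @param smallest_family Family with the smallest introgression (rule iii).
#' @param de_plan data.frame with columns `gene_index` and the three per-family
#'   target log2 fold-changes `fc1`, `fc2`, `fc3`.
#' @param planted_variants data.frame with columns `gene_index`,
#'   `consequence` in missense/stop_gained/stop_lost.
#' @param tissue_plan List with integer gene indices `ao_only` (expressed only
#'   in the anthesis-ovary dataset), `mer_only` (only in the meristem dataset)
#'   and `silent` (expressed nowhere).
#' @param noise_sd Lognormal noise sd (natural-log scale) on RPKM.
#' @param baseline_meanlog,baseline_sdlog Lognormal baseline RPKM parameters.
#' @param phenotype List: `n_per_genotype`, `wt_length_mm`, `length_effect_mm`
#'   (mutant minus wild type), `width_mm`, `sd_mm` (per-plant sd, default
#'   0.025 mm, i.e. the printed ovary standard errors of about 0.01 mm scaled
#'   back up by sqrt(6) plants), `dominance` (target D/A).
#' @return Object of class `study_config`.
#' @export
study_config <- function(seed = 1L,
                         chrom = "chr8",
                         interval_length = 100000L,
                         n_genes = 12L,
                         n_background_snps = 16L,
                         n_background_indels = 1L,
                         frac_low_support = 0.15,
                         families = c("F204", "F236", "F237"),
                         smallest_family = "F204",
                         de_plan = data.frame(
                           gene_index = c(2L, 9L),
                           fc1 = c(0.60, -4.1), fc2 = c(0.55, -4.0),
                           fc3 = c(0.65, -4.2)),
                         planted_variants = data.frame(
                           gene_index = c(3L, 5L, 7L),
                           consequence = c("missense", "stop_gained",
                                           "stop_lost"),
                           stringsAsFactors = FALSE),
                         tissue_plan = list(ao_only = 10L, mer_only = 11L,
                                            silent = 12L),
                         noise_sd = 0.15,
                         baseline_meanlog = 3,
                         baseline_sdlog = 1,
                         phenotype = list(n_per_genotype = 20L,
                                          wt_length_mm = 1.93,
                                          length_effect_mm = 0.27,
                                          width_mm = 1.95,
                                          sd_mm = 0.025,
                                          dominance = -0.47)) {
  stopifnot(interval_length > 0L, n_genes >= 0L, n_background_snps >= 0L,
            n_background_indels >= 0L, length(families) == 3L,
            smallest_family %in% families)
  if (!is.null(de_plan) && nrow(de_plan) > 0L &&
      any(de_plan$gene_index > n_genes))
    stop("de_plan references a gene index beyond n_genes")
  if (!is.null(planted_variants) && nrow(planted_variants) > 0L &&
      any(planted_variants$gene_index > n_genes))
    stop("planted_variants references a gene index beyond n_genes")
  structure(list(seed = as.integer(seed), chrom = chrom,
                 interval_length = as.integer(interval_length),
                 n_genes = as.integer(n_genes),
                 n_background_snps = as.integer(n_background_snps),
                 n_background_indels = as.integer(n_background_indels),
                 frac_low_support = frac_low_support, families = families,
                 smallest_family = smallest_family, de_plan = de_plan,
                 planted_variants = planted_variants,
                 tissue_plan = tissue_plan, noise_sd = noise_sd,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog, phenotype = phenotype),
            class = "study_config")
}

#' Full-scale study configuration
#'
#' The same generator at the scale of the mapped fs8.1 region: 3.03 Mb, 122
#' genes, 158 background SNPs and 5 small indels.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [study_config()].
#' @return A `study_config`.
#' @export
full_scale_config <- function(seed = 1L, ...) {
  study_config(seed = seed, interval_length = 3030000L, n_genes = 122L,
               n_background_snps = 158L, n_background_indels = 5L, ...)
}

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

sense_codons <- function() {
  all <- as.vector(outer(as.vector(outer(BASES, BASES, paste0)), BASES,
                         paste0))
  setdiff(all, STOP_CODONS)
}

# Collapse a sorted integer vector into maximal runs of consecutive values.
runs_to_spans <- function(pos) {
  pos <- sort(pos)
  breaks <- which(diff(pos) != 1L)
  starts <- pos[c(1L, breaks + 1L)]
  ends <- pos[c(breaks, length(pos))]
  data.frame(start = starts, end = ends)
}

#' Generate a synthetic annotated interval
#'
#' Packs non-overlapping stranded genes into the interval. Every gene has 1-3
#' exons, untranslated leader/trailer sequence, and a valid CDS (ATG start,
#' sense codons only, in-frame stop) written into the emitted chromosome
#' sequence; intron and intergenic sequence is random. Deterministic under the
#' config seed.
#'
#' @param config A [study_config()].
#' @return List with `models` (list of `gene_model`, positional order, ids
#'   gene01...) and `sequence` (named nucleotide string).
#' @export
generate_annotation <- function(config) {
  set.seed(config$seed)
  L <- config$interval_length
  seq_chars <- sample(BASES, L, replace = TRUE)
  models <- list()
  n <- config$n_genes
  if (n > 0L) {
    slot <- L %/% n
    if (slot < 1500L)
      stop("interval too short to pack ", n, " genes (slot ", slot, " bp)")
    codons <- sense_codons()
    for (i in seq_len(n)) {
      n_exons <- sample(1:3, 1L)
      n_codons <- sample(40:120, 1L)  # internal sense codons
      cds <- paste0("ATG", paste(sample(codons, n_codons, replace = TRUE),
                                 collapse = ""),
                    sample(STOP_CODONS, 1L))
      u5 <- sample(10:60, 1L)
      u3 <- sample(10:60, 1L)
      tx_len <- u5 + nchar(cds) + u3
      # split transcript into exons of >= 30 bp
      if (n_exons > 1L) {
        repeat {
          cuts <- sort(sample(seq_len(tx_len - 1L), n_exons - 1L))
          lens <- diff(c(0L, cuts, tx_len))
          if (all(lens >= 30L)) break
        }
      } else lens <- tx_len
      introns <- if (n_exons > 1L) sample(60:200, n_exons - 1L,
                                          replace = TRUE) else integer()
      span_len <- tx_len + sum(introns)
      slot_start <- (i - 1L) * slot + 1L
      margin <- slot - span_len - 100L
      if (margin < 1L) stop("gene ", i, " does not fit its slot")
      gs <- slot_start + sample(seq_len(margin), 1L)
      ex_start <- gs + c(0L, cumsum(lens[-n_exons] + introns))
      ex_end <- ex_start + lens - 1L
      strand <- sample(c("+", "-"), 1L)
      tx2g <- unlist(Map(seq, ex_start, ex_end), use.names = FALSE)
      if (strand == "-") tx2g <- rev(tx2g)
      tx_seq <- c(sample(BASES, u5, replace = TRUE),
                  strsplit(cds, "")[[1L]],
                  sample(BASES, u3, replace = TRUE))
      written <- if (strand == "+") tx_seq else unname(comp_base[tx_seq])
      seq_chars[tx2g] <- written
      g_cds <- tx2g[(u5 + 1L):(u5 + nchar(cds))]
      models[[i]] <- gene_model(
        gene_id = sprintf("gene%02d", i), chrom = config$chrom,
        strand = strand, exons = data.frame(start = ex_start, end = ex_end),
        coding = runs_to_spans(g_cds))
    }
  }
  sequence <- stats::setNames(paste(seq_chars, collapse = ""), config$chrom)
  ann <- list(models = models, sequence = sequence)
  # self-check: every CDS starts with ATG and translates without internal stop
  for (m in models) {
    aa <- translate_cds(spliced_coding_sequence(m, sequence)$cds)
    body <- substr(aa, 1L, nchar(aa) - 1L)
    if (substr(aa, 1L, 1L) != "M" || grepl("*", body, fixed = TRUE) ||
        substr(aa, nchar(aa), nchar(aa)) != "*")
      stop("internal error: generated CDS of ", m$gene_id, " is invalid")
  }
  ann
}

# Genomic positions of a CDS in transcription order.
cds_to_genome <- function(model) {
  g <- unlist(Map(seq, model$coding$start, model$coding$end),
              use.names = FALSE)
  if (model$strand == "-") rev(g) else g
}

# Find a single-base substitution in a gene realizing the intended coding
# consequence; returns list(pos, ref, alt) in genomic (plus-strand) terms.
plant_coding_variant <- function(model, sequence, consequence,
                                 max_extension_scan_aa = 1000L) {
  cds <- spliced_coding_sequence(model, sequence)$cds
  n_codons <- nchar(cds) %/% 3L
  cds2g <- cds_to_genome(model)
  try_positions <- function(codon_range) {
    for (ci in codon_range) {
      codon <- substr(cds, 3L * ci - 2L, 3L * ci)
      ref_aa <- translate_cds(codon)
      for (p in 1:3) {
        for (alt in setdiff(BASES, substr(codon, p, p))) {
          mut <- codon
          substr(mut, p, p) <- alt
          mut_aa <- translate_cds(mut)
          ok <- switch(consequence,
            missense = ref_aa != "*" && mut_aa != "*" && ref_aa != mut_aa,
            stop_gained = ref_aa != "*" && mut_aa == "*",
            stop_lost = ref_aa == "*" && mut_aa != "*",
            stop("unknown consequence: ", consequence))
          if (ok) {
            cp <- 3L * (ci - 1L) + p
            g <- cds2g[cp]
            cds_ref <- substr(cds, cp, cp)
            if (model$strand == "+")
              return(list(pos = g, ref = cds_ref, alt = alt))
            return(list(pos = g, ref = comp_base[[cds_ref]],
                        alt = comp_base[[alt]]))
          }
        }
      }
    }
    NULL
  }
  range <- switch(consequence,
                  stop_lost = n_codons,
                  sample(2:(n_codons - 1L)))  # random internal codon order
  hit <- try_positions(range)
  if (is.null(hit))
    stop("cannot plant a ", consequence, " variant in ", model$gene_id)
  check <- predict_coding_consequence(
    variant_table(model$chrom, hit$pos, hit$ref, hit$alt, 50L)[1L, ],
    model, sequence, max_extension_scan_aa)
  if (check$consequence != consequence)
    stop("planted variant verification failed for ", model$gene_id, ": got ",
         check$consequence)
  hit
}

#' Generate synthetic variants for a study
#'
#' Plants the configured coding variants (verified at generation time against
#' the consequence caller), adds uniformly placed background SNPs and
#' non-coding small indels, and draws supporting-read depths with a
#' configurable fraction below 2 reads.
#'
#' @param config A [study_config()].
#' @param annotation Output of [generate_annotation()].
#' @return List with `variants` (a `variant_table`) and `truth` (data.frame of
#'   planted variants: gene_id, consequence, pos).
#' @export
generate_variants <- function(config, annotation) {
  set.seed(config$seed + 1L)
  L <- config$interval_length
  chrom <- config$chrom
  chrom_seq <- annotation$sequence[[chrom]]
  base_at <- function(p) substr(chrom_seq, p, p)

  planted <- list()
  truth <- data.frame(gene_id = character(), consequence = character(),
                      pos = integer(), stringsAsFactors = FALSE)
  pv <- config$planted_variants
  if (!is.null(pv) && nrow(pv) > 0L) {
    for (i in seq_len(nrow(pv))) {
      m <- annotation$models[[pv$gene_index[i]]]
      hit <- plant_coding_variant(m, annotation$sequence, pv$consequence[i])
      planted[[i]] <- data.frame(chrom = chrom, pos = hit$pos, ref = hit$ref,
                                 alt = hit$alt, support_depth = 50L,
                                 stringsAsFactors = FALSE)
      truth <- rbind(truth, data.frame(gene_id = m$gene_id,
                                       consequence = pv$consequence[i],
                                       pos = hit$pos,
                                       stringsAsFactors = FALSE))
    }
  }
  taken <- if (length(planted)) vapply(planted, `[[`, integer(1), "pos")
           else integer()

  coding_pos <- unlist(lapply(annotation$models, function(m)
    unlist(Map(seq, m$coding$start, m$coding$end))), use.names = FALSE)

  bg <- list()
  n_snp <- config$n_background_snps
  if (n_snp > 0L) {
    pool <- setdiff(seq_len(L), taken)
    pos <- sample(pool, n_snp)
    ref <- vapply(pos, base_at, character(1))
    alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1L), character(1))
    bg[[1L]] <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                           support_depth = NA_integer_,
                           stringsAsFactors = FALSE)
  }
  n_ind <- config$n_background_indels
  if (n_ind > 0L) {
    pool <- setdiff(seq_len(L - 10L), c(taken, coding_pos))
    pos <- sample(pool, n_ind)
    rows <- lapply(pos, function(p) {
      if (stats::runif(1) < 0.5) {  # insertion
        ref <- base_at(p)
        alt <- paste0(ref, paste(sample(BASES, sample(2:6, 1L),
                                        replace = TRUE), collapse = ""))
      } else {                      # deletion
        k <- sample(2:6, 1L)
        ref <- substr(chrom_seq, p, p + k)
        alt <- base_at(p)
      }
      data.frame(chrom = chrom, pos = p, ref = ref, alt = alt,
                 support_depth = NA_integer_, stringsAsFactors = FALSE)
    })
    bg[[length(bg) + 1L]] <- do.call(rbind, rows)
  }
  bg_df <- if (length(bg)) do.call(rbind, bg) else NULL
  if (!is.null(bg_df)) {
    n_bg <- nrow(bg_df)
    depth <- stats::rpois(n_bg, 30) + 2L
    n_low <- round(config$frac_low_support * n_bg)
    if (n_low > 0L) {
      low <- sample(n_bg, n_low)
      depth[low] <- sample(0:1, n_low, replace = TRUE)
    }
    bg_df$support_depth <- depth
  }
  all_df <- rbind(if (length(planted)) do.call(rbind, planted), bg_df)
  if (is.null(all_df) || nrow(all_df) == 0L)
    return(list(variants = empty_variant_table(), truth = truth))
  variants <- variant_table(all_df$chrom, all_df$pos, all_df$ref, all_df$alt,
                            all_df$support_depth)
  list(variants = variants, truth = truth)
}

#' Generate synthetic expression data for a study
#'
#' Draws lognormal baseline RPKM per gene, realizes the planted per-family
#' log2 fold-changes in expectation (exactly when `noise_sd = 0`), and emits
#' three tissue datasets (anthesis ovary with the six family samples, a
#' meristem atlas, a wild-relative atlas) shaped by the tissue plan.
#'
#' @param config A [study_config()].
#' @param annotation Output of [generate_annotation()].
#' @return List with `comparisons` (a `comparison_set`), `datasets` (named
#'   list of `expression_dataset`: AO, MER, WILD) and `truth` (gene-by-family
#'   matrix of planted log2 fold-changes).
#' @export
generate_expression <- function(config, annotation) {
  set.seed(config$seed + 2L)
  genes <- vapply(annotation$models, `[[`, character(1), "gene_id")
  n <- length(genes)
  fam <- config$families
  baseline <- stats::rlnorm(n, config$baseline_meanlog, config$baseline_sdlog)
  # planted causal genes are expressed by construction: a fold-change or
  # coding plant on a never-expressed gene would be untestable downstream
  planted_idx <- unique(c(config$de_plan$gene_index,
                          config$planted_variants$gene_index))
  planted_idx <- planted_idx[!is.na(planted_idx)]
  if (length(planted_idx)) baseline[planted_idx] <- pmax(baseline[planted_idx], 8)
  targets <- matrix(0, n, 3L, dimnames = list(genes, fam))
  dp <- config$de_plan
  if (!is.null(dp) && nrow(dp) > 0L)
    for (i in seq_len(nrow(dp)))
      targets[dp$gene_index[i], ] <- c(dp$fc1[i], dp$fc2[i], dp$fc3[i])
  noise <- function(k) exp(stats::rnorm(k, 0, config$noise_sd))
  wt <- baseline * matrix(noise(3L * n), n, 3L)
  mut <- baseline * 2^targets * matrix(noise(3L * n), n, 3L)
  dimnames(wt) <- dimnames(mut) <- list(genes, fam)

  tp <- config$tissue_plan
  silent_idx <- c(tp$silent %||% integer())
  ao_off <- c(tp$mer_only %||% integer(), silent_idx)
  mer_off <- c(tp$ao_only %||% integer(), silent_idx)
  wild_off <- c(tp$ao_only %||% integer(), tp$mer_only %||% integer(),
                silent_idx)
  mut[ao_off, ] <- 0
  wt[ao_off, ] <- 0

  ao_vals <- cbind(mut, wt)
  colnames(ao_vals) <- c(paste0(fam, "_fs"), paste0(fam, "_wt"))
  mer_vals <- baseline * matrix(noise(2L * n), n, 2L,
                                dimnames = list(genes, c("VM", "FM")))
  mer_vals[mer_off, ] <- 0
  wild_vals <- baseline * matrix(noise(3L * n), n, 3L,
                                 dimnames = list(genes,
                                                 c("VM_wild", "YFB", "AF")))
  wild_vals[wild_off, ] <- 0

  list(
    comparisons = comparison_set(mut, wt, config$smallest_family),
    datasets = list(
      AO = expression_dataset("AO", ao_vals),
      MER = expression_dataset("MER", mer_vals),
      WILD = expression_dataset("WILD", wild_vals)),
    truth = targets)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate synthetic organ phenotypes
#'
#' Per-plant maximal length and width of anthesis ovaries for the three
#' genotype classes. Mutant mean length is shifted by the planted effect,
#' width distributions are identical across genotypes, and the heterozygote
#' mean sits at midparent plus dominance times the additive effect so that
#' [gene_action()] recovers the planted D/A.
#'
#' @param config A [study_config()].
#' @return data.frame with plant_id, genotype, organ, length_mm, width_mm.
#' @export
generate_phenotypes <- function(config) {
  set.seed(config$seed + 3L)
  ph <- config$phenotype
  n <- ph$n_per_genotype
  if (n < 2L) stop("need at least two plants per genotype")
  a <- ph$length_effect_mm / 2
  mu <- c(`wild-type` = ph$wt_length_mm,
          heterozygous = ph$wt_length_mm + a + ph$dominance * a,
          mutant = ph$wt_length_mm + ph$length_effect_mm)
  rows <- lapply(names(mu), function(g)
    data.frame(genotype = g,
               length_mm = stats::rnorm(n, mu[[g]], ph$sd_mm),
               width_mm = stats::rnorm(n, ph$width_mm, ph$sd_mm),
               stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$plant_id <- sprintf("P%03d", seq_len(nrow(out)))
  out$organ <- "ovary"
  out[, c("plant_id", "genotype", "organ", "length_mm", "width_mm")]
}

#' Generate and write a complete synthetic study
#'
#' Runs all generators for a config and writes the fixture files a pipeline
#' run consumes: GFF3 annotation, FASTA sequence, VCF variants, per-family
#' comparison tables, per-dataset expression tables, a phenotype table, and a
#' truth record of the planted structure. Regeneration from the same config is
#' byte-identical.
#'
#' @param config A [study_config()].
#' @param dir Output directory (created if needed).
#' @return List with the in-memory objects (`annotation`, `variants`,
#'   `expression`, `phenotypes`, `truth`) and `paths` to every written file.
#' @export
generate_study <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- generate_annotation(config)
  var <- generate_variants(config, ann)
  expr <- generate_expression(config, ann)
  phen <- generate_phenotypes(config)

  p <- list(gff = file.path(dir, "annotation.gff3"),
            fasta = file.path(dir, "sequence.fa"),
            vcf = file.path(dir, "variants.vcf"),
            phenotypes = file.path(dir, "phenotypes.tsv"),
            truth = file.path(dir, "truth.tsv"))
  write_gene_models(ann$models, p$gff)
  write_sequence(ann$sequence, p$fasta)
  write_variants(var$variants, p$vcf,
                 contigs = stats::setNames(config$interval_length,
                                           config$chrom))
  fam_paths <- character()
  for (f in config$families) {
    fp <- file.path(dir, paste0("family_", f, ".tsv"))
    df <- data.frame(gene_id = rownames(expr$comparisons$rpkm_mut),
                     rpkm_mut = format(expr$comparisons$rpkm_mut[, f],
                                       digits = 15L, trim = TRUE,
                                       scientific = FALSE),
                     rpkm_wt = format(expr$comparisons$rpkm_wt[, f],
                                      digits = 15L, trim = TRUE,
                                      scientific = FALSE),
                     stringsAsFactors = FALSE)
    utils::write.table(df, fp, sep = "\t", quote = FALSE, row.names = FALSE)
    fam_paths[f] <- fp
  }
  ds_paths <- character()
  for (d in names(expr$datasets)) {
    dp <- file.path(dir, paste0("dataset_", d, ".tsv"))
    write_expression_table(expr$datasets[[d]], dp)
    ds_paths[d] <- dp
  }
  p$families <- fam_paths
  p$datasets <- ds_paths
  utils::write.table(
    data.frame(plant_id = phen$plant_id, genotype = phen$genotype,
               organ = phen$organ,
               length_mm = sprintf("%.6f", phen$length_mm),
               width_mm = sprintf("%.6f", phen$width_mm)),
    p$phenotypes, sep = "\t", quote = FALSE, row.names = FALSE)

  genes <- vapply(ann$models, `[[`, character(1), "gene_id")
  truth_rows <- list(data.frame(kind = "planted_variant",
                                gene_id = var$truth$gene_id,
                                detail = var$truth$consequence,
                                value = as.character(var$truth$pos),
                                stringsAsFactors = FALSE))
  de <- expr$truth[rowSums(expr$truth != 0) > 0L, , drop = FALSE]
  if (nrow(de))
    truth_rows[[2L]] <- data.frame(
      kind = "planted_de", gene_id = rownames(de),
      detail = "mean_target_log2fc",
      value = sprintf("%.4f", rowMeans(de)), stringsAsFactors = FALSE)
  truth <- do.call(rbind, truth_rows)
  utils::write.table(truth, p$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  invisible(list(annotation = ann, variants = var$variants,
                 expression = expr, phenotypes = phen,
                 truth = list(variants = var$truth, de = expr$truth),
                 paths = p))
}
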