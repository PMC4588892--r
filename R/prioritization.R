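#' Tissue-relevance filter on expression profiles
#'
#' The locus acts before anthesis, so genes expressed only in anthesis-stage
#' ovaries, or only in vegetative meristem, are unlikely candidates and are
#' eliminated; genes expressed nowhere are eliminated too. All other expressed
#' genes are retained.
#'
#' @param profiles Named list: gene_id to character vector of dataset ids the
#'   gene is expressed in (may be empty).
#' @param ovary_sets Dataset ids of anthesis-ovary type.
#' @param meristem_sets Dataset ids of vegetative-meristem type.
#' @param other_sets Dataset ids of reproductive-development type (floral
#'   meristem, flower bud, ...). Together the three groups must cover every id
#'   seen in `profiles`; an unknown id is an error.
#' @return Character vector of retained gene ids.
#' @export
tissue_relevance_filter <- function(profiles, ovary_sets, meristem_sets,
                                    other_sets = character()) {
  known <- c(ovary_sets, meristem_sets, other_sets)
  seen <- unique(unlist(profiles))
  unknown <- setdiff(seen, known)
  if (length(unknown))
    stop("unknown dataset id(s): ", paste(unknown, collapse = ", "))
  keep <- vapply(profiles, function(sets) {
    length(sets) > 0L &&
      !all(sets %in% ovary_sets) &&
      !all(sets %in% meristem_sets)
  }, logical(1))
  names(profiles)[keep]
}

#' Expression profiles from expressed calls
#'
#' Convenience bridge from [expressed_call()] output to the profile list
#' consumed by [tissue_relevance_filter()].
#'
#' @param calls data.frame from [expressed_call()].
#' @param dataset_cols Names of the per-dataset logical columns; defaults to
#'   every column except `gene_id` and `expressed_any`.
#' @return Named list, gene_id to character vector of dataset ids.
#' @export
expression_profiles <- function(calls,
                                dataset_cols = setdiff(names(calls),
                                                       c("gene_id",
                                                         "expressed_any"))) {
  out <- lapply(seq_len(nrow(calls)), function(i)
    dataset_cols[unlist(calls[i, dataset_cols])])
  names(out) <- calls$gene_id
  out
}

# Severity order for summarizing several coding consequences into one call.
consequence_severity <- c(stop_gained = 4L, stop_lost = 3L, missense = 2L,
                          synonymous = 1L, none = 0L)

#' Summarize variant annotations per gene
#'
#' For each gene, reports the most severe coding consequence (severity order:
#' stop gained > stop lost > missense > synonymous) and the set of non-coding
#' variant classes (upstream, downstream, intron, exon_noncoding) inside the
#' flanking window.
#'
#' @param genes Character vector of gene ids to report (typically the retained
#'   set).
#' @param annotations data.frame from [annotate_variants()], computed on
#'   support-filtered variants.
#' @return data.frame with gene_id, coding_change ("none" or a consequence),
#'   protein_change, noncoding_classes (comma-collapsed, "" when none),
#'   n_variants.
#' @export
attach_variant_evidence <- function(genes, annotations) {
  noncoding <- c("upstream", "downstream", "intron", "exon_noncoding")
  rows <- lapply(genes, function(g) {
    a <- annotations[!is.na(annotations$gene_id) & annotations$gene_id == g, ,
                     drop = FALSE]
    sev <- consequence_severity[a$consequence]
    best <- if (nrow(a) && max(sev) > 0L) which.max(sev) else NA_integer_
    data.frame(
      gene_id = g,
      coding_change = if (is.na(best)) "none" else a$consequence[best],
      protein_change = if (is.na(best)) NA_character_
                       else a$protein_change[best],
      noncoding_classes = paste(sort(unique(a$region[a$region %in% noncoding])),
                                collapse = ","),
      n_variants = nrow(a),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Integrate evidence into a candidate-gene table
#'
#' A retained gene is selected when at least one sufficient evidence rule
#' fires: a consistent differential-expression call, a protein-altering coding
#' change (missense, stop gained or stop lost), or a curated putative-function
#' flag. Non-coding variants near a gene are carried as supporting context but
#' never select a gene alone. `reasons` records the rules that fired, in the
#' fixed order differential_expression, coding_variant, putative_function.
#'
#' @param retained Character vector of gene ids surviving the tissue filter.
#' @param de_calls data.frame from [region_de_call()].
#' @param variant_evidence data.frame from [attach_variant_evidence()].
#' @param function_flags Optional data.frame (gene_id, flag, annotation) from
#'   [read_function_flags()].
#' @param positions Optional named integer vector of gene start positions used
#'   to sort the table; unknown genes sort last by id.
#' @return data.frame of class `candidate_table`: gene_id, position, retained,
#'   de_direction, de_avg_log2fc, coding_change, protein_change,
#'   noncoding_classes, function_flag, function_note, selected, reasons.
#' @export
select_candidates <- function(retained, de_calls, variant_evidence,
                              function_flags = NULL, positions = NULL) {
  idx <- function(df, key) match(retained, df[[key]])
  de_i <- idx(de_calls, "gene_id")
  ve_i <- idx(variant_evidence, "gene_id")
  de_dir <- ifelse(is.na(de_i), "none", de_calls$direction[de_i])
  de_avg <- ifelse(is.na(de_i), NA_real_, de_calls$avg_log2fc[de_i])
  coding <- ifelse(is.na(ve_i), "none", variant_evidence$coding_change[ve_i])
  pchg <- ifelse(is.na(ve_i), NA_character_,
                 variant_evidence$protein_change[ve_i])
  noncod <- ifelse(is.na(ve_i), "", variant_evidence$noncoding_classes[ve_i])
  if (is.null(function_flags)) {
    ff <- rep(FALSE, length(retained)); fn <- rep("", length(retained))
  } else {
    fi <- idx(function_flags, "gene_id")
    ff <- ifelse(is.na(fi), FALSE, function_flags$flag[fi])
    fn <- ifelse(is.na(fi), "", function_flags$annotation[fi])
  }
  r_de <- de_dir != "none"
  r_cv <- coding %in% c("missense", "stop_gained", "stop_lost")
  r_fn <- ff
  reasons <- mapply(function(a, b, c) paste(
    c("differential_expression", "coding_variant",
      "putative_function")[c(a, b, c)], collapse = ","), r_de, r_cv, r_fn)
  out <- data.frame(
    gene_id = retained,
    position = if (is.null(positions)) NA_integer_
               else unname(positions[retained]),
    retained = TRUE, de_direction = de_dir, de_avg_log2fc = de_avg,
    coding_change = coding, protein_change = pchg,
    noncoding_classes = noncod, function_flag = ff, function_note = fn,
    selected = r_de | r_cv | r_fn, reasons = reasons,
    stringsAsFactors = FALSE)
  out <- out[order(is.na(out$position), out$position, out$gene_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_table", "data.frame")
  out
}

#' Write the candidate table and a human-readable summary
#'
#' Emits a deterministic TSV mirroring the evidence columns and, alongside it,
#' a plain-text summary with selection counts per reason.
#'
#' @param table A `candidate_table` from [select_candidates()].
#' @param path Output TSV path; the summary goes to `<path>.summary.txt`.
#' @return Invisibly, a list with `tsv` and `summary` paths.
#' @export
render_candidate_report <- function(table, path) {
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, logical(1)) & names(df) != "position"
  df[num] <- lapply(df[num], function(x) ifelse(is.na(x), NA,
                                                sprintf("%.4f", x)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  sel <- table[table$selected, , drop = FALSE]
  count_reason <- function(r) sum(grepl(r, sel$reasons, fixed = TRUE))
  summary_lines <- c(
    sprintf("retained genes: %d", nrow(table)),
    sprintf("selected candidates: %d", nrow(sel)),
    sprintf("  by differential expression: %d",
            count_reason("differential_expression")),
    sprintf("  by coding variant: %d", count_reason("coding_variant")),
    sprintf("  by putative function: %d", count_reason("putative_function")))
  spath <- paste0(path, ".summary.txt")
  writeLines(summary_lines, spath)
  invisible(list(tsv = path, summary = spath))
}
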