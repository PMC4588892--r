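#' Reads per kilobase of exon model per million mapped reads
#'
#' RPKM = count * 1e9 / (library_size * exon_length_bp). Vectorized over
#' counts and lengths.
#'
#' @param read_count Non-negative read count(s).
#' @param exon_model_length_bp Total exon length in bp (> 0).
#' @param mapped_reads_total Library size in mapped reads (> 0).
#' @return Numeric RPKM.
#' @export
compute_rpkm <- function(read_count, exon_model_length_bp,
                         mapped_reads_total) {
  if (any(exon_model_length_bp <= 0)) stop("exon model length must be > 0")
  if (any(mapped_reads_total <= 0)) stop("mapped read total must be > 0")
  read_count * 1e9 / (as.numeric(mapped_reads_total) * exon_model_length_bp)
}

#' Log2 fold-change of mutant over wild-type RPKM
#'
#' log2((mut + pseudocount) / (wt + pseudocount)). The pseudocount (default
#' 0.1 RPKM) guards against zeros; absent inputs give absent (NA) results.
#'
#' @param rpkm_mut,rpkm_wt RPKM values (vectorized).
#' @param pseudocount Added to both values; default 0.1.
#' @return Numeric log2 fold-change, NA where either input is NA.
#' @export
log2_fold_change <- function(rpkm_mut, rpkm_wt, pseudocount = 0.1) {
  log2((rpkm_mut + pseudocount) / (rpkm_wt + pseudocount))
}

#' Per-gene RPKM pairs and fold-changes for three paired comparisons
#'
#' Bundles the three near-isogenic family comparisons (mutant vs wild-type
#' anthesis-ovary RNA-Seq) the pipeline treats as independent experiments. One
#' family carries the "smallest introgression" role used by filter rule (iii).
#'
#' @param rpkm_mut,rpkm_wt Numeric gene-by-family matrices (3 columns, same
#'   dimnames); NA marks absent measurements.
#' @param smallest_family Column name of the smallest-introgression family.
#' @param pseudocount Pseudocount for [log2_fold_change()].
#' @return Object of class `comparison_set` with fields `families`,
#'   `smallest_family`, `rpkm_mut`, `rpkm_wt`, `log2fc`, `pseudocount`.
#' @export
comparison_set <- function(rpkm_mut, rpkm_wt, smallest_family,
                           pseudocount = 0.1) {
  if (!identical(dimnames(rpkm_mut), dimnames(rpkm_wt)))
    stop("mutant and wild-type matrices must share dimnames")
  if (ncol(rpkm_mut) != 3L)
    stop("exactly three family comparisons are required, got ",
         ncol(rpkm_mut))
  if (!smallest_family %in% colnames(rpkm_mut))
    stop("smallest_family '", smallest_family, "' is not a family column")
  structure(list(
    families = colnames(rpkm_mut), smallest_family = smallest_family,
    rpkm_mut = rpkm_mut, rpkm_wt = rpkm_wt,
    log2fc = log2_fold_change(rpkm_mut, rpkm_wt, pseudocount),
    pseudocount = pseudocount
  ), class = "comparison_set")
}

#' @export
print.comparison_set <- function(x, ...) {
  cat(sprintf("<comparison_set> %d genes x families %s (smallest: %s)\n",
              nrow(x$rpkm_mut), paste(x$families, collapse = ", "),
              x$smallest_family))
  invisible(x)
}

#' Expressed / not-expressed calls across datasets
#'
#' A gene is called expressed in a dataset iff any of its sample RPKM values
#' is strictly greater than the threshold (default 2 RPKM); absent cells never
#' support an expressed call. Genes missing from a dataset are not expressed
#' there.
#'
#' @param datasets Named list of `expression_dataset` objects.
#' @param threshold RPKM threshold, strict; default 2.
#' @return data.frame with `gene_id`, one logical column per dataset, and
#'   `expressed_any`.
#' @export
expressed_call <- function(datasets, threshold = 2) {
  if (is.null(names(datasets)) || any(!nzchar(names(datasets))))
    stop("datasets must be a named list")
  genes <- sort(unique(unlist(lapply(datasets, function(d) rownames(d$values)))))
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (nm in names(datasets)) {
    m <- datasets[[nm]]$values
    hit <- apply(m > threshold, 1L, any, na.rm = TRUE)
    out[[nm]] <- genes %in% rownames(m)[hit]
  }
  out$expressed_any <- Reduce(`|`, out[names(datasets)])
  out
}

#' Genome-wide differential-expression filter (rules i-iii)
#'
#' Keeps genes that satisfy all three threshold rules across the three family
#' comparisons: (i) RPKM > `rpkm_threshold` in at least two of the three
#' comparisons; (ii) log2 fold-change with the same strict sign in all three
#' (a zero fails); (iii) |log2FC| > `fc_threshold` in the
#' smallest-introgression family and in at least one of the other two. Genes
#' with an absent fold-change in any family fail rule (ii).
#'
#' @param comparisons A `comparison_set`.
#' @param rpkm_threshold Rule (i) threshold, strict; default 2.
#' @param fc_threshold Rule (iii) threshold, strict; default 0.5.
#' @param rule_i_scope Which sample of each pair rule (i) looks at: the
#'   mutant, the wild type, or either (default).
#' @return Character vector of gene ids passing all rules, in matrix order.
#' @export
genomewide_de_filter <- function(comparisons, rpkm_threshold = 2,
                                 fc_threshold = 0.5,
                                 rule_i_scope = c("either", "mutant",
                                                  "wild-type")) {
  rule_i_scope <- match.arg(rule_i_scope)
  mu <- comparisons$rpkm_mut
  wt <- comparisons$rpkm_wt
  fc <- comparisons$log2fc
  over <- switch(rule_i_scope,
                 either = (!is.na(mu) & mu > rpkm_threshold) |
                   (!is.na(wt) & wt > rpkm_threshold),
                 mutant = !is.na(mu) & mu > rpkm_threshold,
                 `wild-type` = !is.na(wt) & wt > rpkm_threshold)
  rule1 <- rowSums(over) >= 2L
  sgn <- sign(fc)
  rule2 <- !apply(fc, 1L, anyNA) &
    (rowSums(sgn == 1) == 3L | rowSums(sgn == -1) == 3L)
  small <- comparisons$smallest_family
  others <- setdiff(comparisons$families, small)
  big <- abs(fc) > fc_threshold
  rule3 <- !is.na(big[, small]) & big[, small] &
    rowSums(big[, others, drop = FALSE], na.rm = TRUE) >= 1L
  rownames(mu)[rule1 & rule2 & rule3]
}

#' Consistent differential-expression call for interval genes
#'
#' A gene is called down iff its log2 fold-change is below `-fc_threshold` in
#' all three families, up iff above `+fc_threshold` in all three, otherwise
#' none. The average is the arithmetic mean over the three families. An absent
#' family value forces direction `none` and sets the `flagged` column.
#'
#' @param comparisons A `comparison_set`, or a 3-column log2FC matrix with
#'   gene rownames.
#' @param fc_threshold Strict threshold; default 0.5.
#' @return data.frame with gene_id, direction (up/down/none), avg_log2fc,
#'   per-family columns, flagged.
#' @export
region_de_call <- function(comparisons, fc_threshold = 0.5) {
  fc <- if (inherits(comparisons, "comparison_set")) comparisons$log2fc
        else comparisons
  if (ncol(fc) != 3L) stop("three family fold-changes are required")
  incomplete <- apply(fc, 1L, anyNA)
  down <- !incomplete & rowSums(fc < -fc_threshold) == 3L
  up <- !incomplete & rowSums(fc > fc_threshold) == 3L
  out <- data.frame(gene_id = rownames(fc),
                    direction = ifelse(down, "down", ifelse(up, "up", "none")),
                    avg_log2fc = rowMeans(fc),
                    stringsAsFactors = FALSE)
  for (f in colnames(fc)) out[[paste0("log2fc_", f)]] <- fc[, f]
  out$flagged <- incomplete
  rownames(out) <- NULL
  out
}
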