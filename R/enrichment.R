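#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the chance of drawing at least k
#' genes of a K-gene term when sampling n genes from a universe of N without
#' replacement. Computed through the stable log-space tail of
#' [stats::phyper()].
#'
#' @param N Universe size.
#' @param K Term (category) size, <= N.
#' @param n Selection size, <= N.
#' @param k Overlap, <= min(K, n).
#' @return The upper-tail p-value; 1 when k = 0.
#' @export
hypergeometric_tail <- function(N, K, n, k) {
  if (K > N || n > N || k > min(K, n) || k < 0 || any(c(N, K, n) < 0))
    stop("inconsistent counts: need k <= min(K, n), K <= N, n <= N")
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Term over-representation in a selected gene set
#'
#' Hypergeometric upper-tail test of each functional term against the
#' universe, with multiple-testing adjustment (Benjamini-Hochberg by default).
#' Term gene sets are intersected with the universe before testing, and an
#' exclusion set (e.g. the genes of the mapped introgression itself) can be
#' removed from both selection and universe. Terms with no selected gene are
#' omitted.
#'
#' @param selected Character vector of selected gene ids, subset of universe.
#' @param universe Character vector of all testable gene ids.
#' @param term_map data.frame with columns term_id, gene_id and optionally
#'   label (see [read_term_map()]).
#' @param method Adjustment method for [stats::p.adjust()]; default "BH".
#' @param exclude Gene ids removed from universe and selection before testing.
#' @return data.frame sorted by adjusted then raw p-value: term_id, label,
#'   universe_size, term_size, selection_size, overlap, p_value, p_adjusted.
#' @export
enrich_terms <- function(selected, universe, term_map, method = "BH",
                         exclude = character()) {
  universe <- setdiff(unique(universe), exclude)
  selected <- setdiff(unique(selected), exclude)
  stray <- setdiff(selected, universe)
  if (length(stray))
    stop("selected genes outside the universe: ",
         paste(stray, collapse = ", "))
  if (is.null(term_map$label)) term_map$label <- term_map$term_id
  N <- length(universe)
  n <- length(selected)
  terms <- split(term_map$gene_id, term_map$term_id)
  labels <- tapply(term_map$label, term_map$term_id, `[`, 1L)
  rows <- lapply(names(terms), function(tid) {
    tg <- intersect(unique(terms[[tid]]), universe)
    k <- length(intersect(tg, selected))
    if (k == 0L) return(NULL)
    data.frame(term_id = tid, label = unname(labels[tid]), universe_size = N,
               term_size = length(tg), selection_size = n, overlap = k,
               p_value = hypergeometric_tail(N, length(tg), n, k),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    return(data.frame(term_id = character(), label = character(),
                      universe_size = integer(), term_size = integer(),
                      selection_size = integer(), overlap = integer(),
                      p_value = numeric(), p_adjusted = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = method)
  out <- out[order(out$p_adjusted, out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
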