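#' Organ shape index
#'
#' Ratio of maximal length to maximal width (proximal-distal over mediolateral
#' extent). Vectorized.
#'
#' @param length_mm Maximal length (same units as width).
#' @param width_mm Maximal width, > 0.
#' @return length / width.
#' @export
shape_index <- function(length_mm, width_mm) {
  if (any(width_mm <= 0)) stop("width must be positive")
  length_mm / width_mm
}

#' Relative height of the widest fruit position
#'
#' y / L, where y is the height of the widest cross-section and L the maximal
#' length; in [0, 1].
#'
#' @param y_mm Height of widest position, 0 <= y <= L.
#' @param length_mm Maximal length, > 0.
#' @return y / L.
#' @export
width_widest_position <- function(y_mm, length_mm) {
  if (any(length_mm <= 0)) stop("length must be positive")
  if (any(y_mm < 0 | y_mm > length_mm)) stop("need 0 <= y <= length")
  y_mm / length_mm
}

#' Pericarp thickness from four radial measurements
#'
#' Arithmetic mean of the two height-axis (h1, h2) and two width-axis (w1, w2)
#' thickness measurements.
#'
#' @param h1,h2,w1,w2 Non-negative thicknesses (mm).
#' @return (h1 + h2 + w1 + w2) / 4.
#' @export
pericarp_thickness <- function(h1, h2, w1, w2) {
  if (any(c(h1, h2, w1, w2) < 0)) stop("thicknesses must be non-negative")
  (h1 + h2 + w1 + w2) / 4
}

#' Average cell size in a boxed pericarp region
#'
#' Total boxed area divided by the number of cells it contains.
#'
#' @param total_area_um2 Combined area of the boxed regions (square microns).
#' @param n_cells Total cell count in the boxes, > 0.
#' @return Mean cell area.
#' @export
average_cell_size <- function(total_area_um2, n_cells) {
  if (any(n_cells <= 0)) stop("cell count must be positive")
  total_area_um2 / n_cells
}

#' Large-cell size: mean area of the six biggest cells
#'
#' @param cell_areas_um2 Numeric vector of at least six positive cell areas.
#' @return Mean of the six largest values.
#' @export
large_cell_size <- function(cell_areas_um2) {
  if (length(cell_areas_um2) < 6L) stop("need at least six cell areas")
  if (any(cell_areas_um2 <= 0)) stop("cell areas must be positive")
  mean(sort(cell_areas_um2, decreasing = TRUE)[1:6])
}

#' Two-sample progeny-test comparison
#'
#' Student's two-sample t test (pooled variance by default) of a trait between
#' the mutant and wild-type genotype classes of a progeny family. Degenerate
#' input (zero variance in both groups) returns t = 0, p = 1 when the means
#' are equal, and |t| = Inf, p = 0 otherwise.
#'
#' @param group_mut,group_wt Numeric trait vectors, each of length >= 2.
#' @param var_equal Pooled-variance form (default TRUE); FALSE gives Welch.
#' @return List with `t`, `p_value`, `mean_mut`, `mean_wt`, `df`.
#' @export
progeny_test <- function(group_mut, group_wt, var_equal = TRUE) {
  if (length(group_mut) < 2L || length(group_wt) < 2L)
    stop("each group needs at least two values")
  m1 <- mean(group_mut); m2 <- mean(group_wt)
  df <- length(group_mut) + length(group_wt) - 2
  if (stats::sd(group_mut) == 0 && stats::sd(group_wt) == 0) {
    if (m1 == m2)
      return(list(t = 0, p_value = 1, mean_mut = m1, mean_wt = m2, df = df))
    return(list(t = sign(m1 - m2) * Inf, p_value = 0, mean_mut = m1,
                mean_wt = m2, df = df))
  }
  tt <- stats::t.test(group_mut, group_wt, var.equal = var_equal)
  list(t = unname(tt$statistic), p_value = tt$p.value, mean_mut = m1,
       mean_wt = m2, df = unname(tt$parameter))
}

#' Dominance/additivity (D/A) gene action
#'
#' Additive effect A = (mu_mut - mu_wt) / 2 (mutant minus wild type);
#' dominance deviation D = mu_het - midparent. D/A = 0 is pure additivity,
#' +1 complete dominance of the mutant allele, negative values dominance
#' toward the wild type, |D/A| > 1 overdominance.
#'
#' @param mu_mut,mu_het,mu_wt Trait means of the three genotype classes.
#' @return D/A ratio.
#' @export
gene_action <- function(mu_mut, mu_het, mu_wt) {
  if (any(mu_mut == mu_wt))
    stop("D/A is undefined when the homozygote means are equal")
  a <- (mu_mut - mu_wt) / 2
  d <- mu_het - (mu_mut + mu_wt) / 2
  d / a
}

#' Percent-of-wild-type metabolite level with paired t test
#'
#' percent = 100 * mean(mutant) / mean(wild type); the test is a paired
#' Student's t test on the per-replicate differences. Identical pairs return
#' the p = 1 convention.
#'
#' @param mutant,wild_type Aligned per-replicate levels (>= 2 pairs).
#' @return List with `percent`, `t`, `p_value`, `n_pairs`.
#' @export
percent_of_wt <- function(mutant, wild_type) {
  if (length(mutant) != length(wild_type))
    stop("pairs must be aligned by replicate")
  if (length(mutant) < 2L) stop("need at least two pairs")
  if (mean(wild_type) == 0) stop("wild-type mean is zero")
  pct <- 100 * mean(mutant) / mean(wild_type)
  d <- mutant - wild_type
  if (stats::sd(d) == 0) {
    t <- if (all(d == 0)) 0 else sign(mean(d)) * Inf
    p <- if (all(d == 0)) 1 else 0
  } else {
    tt <- stats::t.test(mutant, wild_type, paired = TRUE)
    t <- unname(tt$statistic); p <- tt$p.value
  }
  list(percent = pct, t = t, p_value = p, n_pairs = length(mutant))
}
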