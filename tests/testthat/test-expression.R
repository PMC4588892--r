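mk_cs <- function(mut, wt, smallest = "A", pseudocount = 0.1) {
  fam <- c("A", "B", "C")
  genes <- paste0("g", seq_len(length(mut) / 3))
  comparison_set(matrix(mut, ncol = 3, byrow = TRUE,
                        dimnames = list(genes, fam)),
                 matrix(wt, ncol = 3, byrow = TRUE,
                        dimnames = list(genes, fam)),
                 smallest, pseudocount)
}

test_that("RPKM follows the reads-per-kb-per-million definition", {
  expect_identical(compute_rpkm(0, 500, 1e6), 0)
  expect_identical(compute_rpkm(1000, 1000, 1e6), 1000)
  expect_error(compute_rpkm(10, 0, 1e6), "length")
  expect_error(compute_rpkm(10, 500, 0), "mapped")
  # doubling the library halves RPKM; direct-formula cross-check
  set.seed(1)
  for (i in 1:20) {
    cnt <- sample.int(1e5, 1); len <- sample.int(1e4, 1)
    lib <- as.numeric(sample.int(1e8, 1))
    expect_equal(compute_rpkm(cnt, len, 2 * lib),
                 compute_rpkm(cnt, len, lib) / 2)
    expect_equal(compute_rpkm(cnt, len, lib), cnt * 1e9 / (lib * len))
  }
})

test_that("log2 fold-change is antisymmetric and pseudocount-guarded", {
  expect_identical(log2_fold_change(5, 5), 0)
  expect_identical(log2_fold_change(4, 2, pseudocount = 0), 1)
  expect_true(is.na(log2_fold_change(NA, 2)))
  expect_true(is.finite(log2_fold_change(0, 7)))
  set.seed(2)
  x <- runif(50, 0, 100); y <- runif(50, 0, 100)
  expect_equal(log2_fold_change(x, y), -log2_fold_change(y, x))
})

test_that("expressed calls use a strict >2 RPKM threshold per dataset", {
  d1 <- expression_dataset("d1", matrix(c(2.0, 2.01, NA, 1),
                                        nrow = 2,
                                        dimnames = list(c("g1", "g2"),
                                                        c("s1", "s2"))))
  d2 <- expression_dataset("d2", matrix(c(0, 0), nrow = 2,
                                        dimnames = list(c("g1", "g2"), "s1")))
  calls <- expressed_call(list(d1 = d1, d2 = d2))
  expect_identical(calls$d1, c(FALSE, TRUE))   # 2.0 is NOT "more than 2"
  expect_identical(calls$d2, c(FALSE, FALSE))
  expect_identical(calls$expressed_any, c(FALSE, TRUE))
})

test_that("expressed-gene counts on a synthetic matrix match a recount", {
  set.seed(3)
  for (r in 1:10) {
    m <- matrix(rlnorm(60, 0.5, 1.2), nrow = 20,
                dimnames = list(paste0("g", 1:20), paste0("s", 1:3)))
    m[sample(length(m), 8)] <- NA
    calls <- expressed_call(list(d = expression_dataset("d", m)))
    manual <- vapply(rownames(m), function(g)
      any(!is.na(m[g, ]) & m[g, ] > 2), logical(1))
    expect_identical(calls$d, unname(manual[calls$gene_id]))
  }
})

test_that("genome-wide filter applies rules i-iii as stated", {
  # rule i: never above 2 RPKM anywhere -> excluded
  cs <- mk_cs(mut = c(1, 1, 1), wt = c(1.5, 0.5, 2.0))
  expect_identical(genomewide_de_filter(cs), character())
  # rule ii: direction conflict -> excluded even with large changes
  cs2 <- mk_cs(mut = c(30, 13, 33), wt = c(20, 20, 20))  # +,-,+
  expect_identical(genomewide_de_filter(cs2), character())
  # rule iii: >0.5 in smallest family and one other -> included
  cs3 <- mk_cs(mut = c(2^0.6 * 20, 2^0.2 * 20, 2^0.6 * 20),
               wt = c(20, 20, 20), pseudocount = 0)
  expect_identical(genomewide_de_filter(cs3), "g1")
  # but not when the 0.6 changes avoid the smallest family
  cs4 <- mk_cs(mut = c(2^0.2 * 20, 2^0.6 * 20, 2^0.6 * 20),
               wt = c(20, 20, 20), pseudocount = 0)
  expect_identical(genomewide_de_filter(cs4), character())
})

test_that("genome-wide filter equals brute-force rule re-evaluation", {
  for (seed in 1:25) {
    set.seed(seed)
    n <- 40L
    genes <- paste0("g", seq_len(n))
    mut <- matrix(rlnorm(3 * n, 1, 1.5), n, 3,
                  dimnames = list(genes, c("A", "B", "C")))
    wt <- matrix(rlnorm(3 * n, 1, 1.5), n, 3,
                 dimnames = list(genes, c("A", "B", "C")))
    drop <- sample(length(mut), 5)
    mut[drop] <- NA
    cs <- comparison_set(mut, wt, "B")
    expect_identical(genomewide_de_filter(cs),
                     oracle_de_filter(mut, wt, "B"))
  }
})

test_that("region DE calls need all three families beyond the cutoff", {
  fc <- matrix(c(-1.2, -1.4, -1.0,
                 -0.6, 0.7, -0.8,
                 0.6, 0.55, 0.65), ncol = 3, byrow = TRUE,
               dimnames = list(c("g1", "g2", "g3"), c("A", "B", "C")))
  calls <- region_de_call(fc)
  expect_identical(calls$direction, c("down", "none", "up"))
  expect_equal(calls$avg_log2fc[1], -1.2)
  expect_equal(calls$avg_log2fc[3], 0.60)  # the reported upregulated case
  # absent family value forces none + flag
  fc2 <- matrix(c(-2, NA, -2), 1, 3, dimnames = list("g", NULL))
  c2 <- region_de_call(fc2)
  expect_identical(c2$direction, "none")
  expect_true(c2$flagged)
})

test_that("direction calls are invariant to common positive rescaling when
          pseudocount is zero", {
  set.seed(9)
  mut <- matrix(rlnorm(30, 2, 1), 10, 3,
                dimnames = list(paste0("g", 1:10), c("A", "B", "C")))
  wt <- matrix(rlnorm(30, 2, 1), 10, 3, dimnames = dimnames(mut))
  base <- region_de_call(comparison_set(mut, wt, "A", pseudocount = 0))
  for (k in c(0.2, 3, 40)) {
    scaled <- region_de_call(comparison_set(k * mut, k * wt, "A",
                                            pseudocount = 0))
    expect_identical(scaled$direction, base$direction)
  }
})

test_that("raising the fold-change threshold never adds genes", {
  set.seed(10)
  mut <- matrix(rlnorm(90, 1.5, 1.5), 30, 3,
                dimnames = list(paste0("g", 1:30), c("A", "B", "C")))
  wt <- matrix(rlnorm(90, 1.5, 1.5), 30, 3, dimnames = dimnames(mut))
  cs <- comparison_set(mut, wt, "A")
  prev <- genomewide_de_filter(cs, fc_threshold = 0.1)
  for (thr in c(0.3, 0.5, 1, 2)) {
    cur <- genomewide_de_filter(cs, fc_threshold = thr)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})
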