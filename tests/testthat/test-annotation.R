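mk_gene <- function(strand = "+", exons = data.frame(start = 10001L,
                                                     end = 10600L),
                    coding = exons, chrom = "c", id = "g") {
  gene_model(id, chrom, strand, exons, coding)
}

test_that("interval membership is any-overlap and ordered by position", {
  g1 <- mk_gene(exons = data.frame(start = 10L, end = 20L), id = "a")
  g2 <- mk_gene(exons = data.frame(start = 30L, end = 40L), id = "b")
  hit <- function(iv) vapply(genes_in_interval(list(g2, g1), iv),
                             `[[`, character(1), "gene_id")
  expect_identical(hit(genomic_interval("c", 1, 5)), character())
  expect_identical(hit(genomic_interval("c", 20, 30)), c("a", "b"))
  expect_identical(hit(genomic_interval("x", 1, 100)), character())
})

test_that("interval membership matches exhaustive per-gene overlap check", {
  set.seed(41)
  genes <- lapply(1:200, function(i) {
    s <- sample.int(99000L, 1L)
    mk_gene(exons = data.frame(start = s, end = s + sample.int(900L, 1L)),
            id = paste0("g", i))
  })
  for (r in 1:20) {
    a <- sample.int(100000L, 1L); b <- sample.int(100000L, 1L)
    iv <- genomic_interval("c", min(a, b), max(a, b))
    got <- vapply(genes_in_interval(genes, iv), `[[`, character(1), "gene_id")
    want <- vapply(genes, function(g) {
      sp <- gene_span(g)
      if (length(intersect(sp[1L]:sp[2L], iv$start:iv$end)) > 0L) g$gene_id
      else NA_character_
    }, character(1))
    expect_setequal(got, want[!is.na(want)])
  }
})

test_that("read-support filter keeps >=2 reads and drops unknown depth", {
  v <- variant_table(rep("c", 4), 1:4, rep("A", 4), rep("G", 4),
                     c(1L, 2L, 50L, NA))
  expect_identical(filter_variants_by_support(v)$pos, c(2L, 3L))
  expect_identical(filter_variants_by_support(v, 0L)$pos, c(1L, 2L, 3L))
})

test_that("upstream window is strand-aware and inclusive at 10 kb", {
  g <- mk_gene("+")  # tss = 10001
  at <- function(pos, model = g) classify_variant_location(
    list(chrom = "c", pos = pos), model)
  expect_identical(at(10000L), list(region = "upstream", distance_bp = 1L))
  expect_identical(at(1L), list(region = "upstream", distance_bp = 10000L))
  expect_identical(at(10001L)$region, "exon_coding")
  expect_identical(at(10601L), list(region = "downstream", distance_bp = 1L))
  # minus strand mirrors: 5' flank lies at higher coordinates
  gm <- mk_gene("-")
  expect_identical(at(10601L, gm), list(region = "upstream",
                                        distance_bp = 1L))
  expect_identical(at(10000L, gm), list(region = "downstream",
                                        distance_bp = 1L))
  expect_identical(at(40000L)$region, "intergenic")
  expect_identical(at(5L, mk_gene(chrom = "other"))$region, "intergenic")
})

test_that("region labels agree with the exhaustive membership oracle", {
  ann <- small_study(seed = 17, interval_length = 40000L, n_genes = 5L)
  set.seed(99)
  pos <- sample.int(40000L, 500L)
  for (m in ann$models) {
    got <- vapply(pos, function(p)
      classify_variant_location(list(chrom = "chr8", pos = p), m)$region,
      character(1))
    want <- vapply(pos, oracle_region, character(1), model = m)
    expect_identical(got, want)
  }
})

test_that("spliced CDS extraction equals a per-base walk on both strands", {
  seqs <- c(c = paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                      collapse = ""))
  for (strand in c("+", "-")) {
    m <- gene_model("g", "c", strand,
                    exons = data.frame(start = c(11L, 101L, 201L),
                                       end = c(52L, 160L, 250L)),
                    coding = data.frame(start = c(20L, 101L, 201L),
                                        end = c(52L, 160L, 230L)))
    expect_identical(spliced_coding_sequence(m, seqs)$cds,
                     oracle_spliced_cds(m, seqs))
  }
  # single span examples: substring and its reverse complement
  m1 <- gene_model("g", "c", "+", data.frame(start = 5L, end = 16L))
  m1$coding <- data.frame(start = 5L, end = 16L)
  expect_identical(spliced_coding_sequence(m1, seqs)$cds,
                   substr(seqs[["c"]], 5, 16))
  m2 <- m1; m2$strand <- "-"
  expect_identical(spliced_coding_sequence(m2, seqs)$cds,
                   oracle_revcomp(substr(seqs[["c"]], 5, 16)))
})

test_that("coding SNP consequences: missense N253D, stop gain, stop loss", {
  # construct a 255-codon CDS whose codon 253 is AAT (Asn)
  set.seed(7)
  codons <- sample(setdiff(names(CODON_TABLE),
                           c("TAA", "TAG", "TGA", "ATG")), 254,
                   replace = TRUE)
  codons[253] <- "AAT"
  cds <- paste0("ATG", paste(codons[-1], collapse = ""), "TAA")
  flank <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE),
                 collapse = "")
  seqs <- c(c = paste0(flank, cds, "CCGTAAGG"))  # in-frame TAA 2 codons past
  m <- gene_model("g", "c", "+",
                  exons = data.frame(start = 51L, end = 50L + nchar(cds)))
  m$coding <- m$exons
  snp <- function(pos, ref, alt)
    variant_table("c", pos, ref, alt, 10L)[1L, ]

  # AAT -> GAT at codon 253: first base of codon 253 is at 50 + 253*3 - 2
  p253 <- 50L + 253L * 3L - 2L
  res <- predict_coding_consequence(snp(p253, "A", "G"), m, seqs)
  expect_identical(res$consequence, "missense")
  expect_identical(res$protein_change, "N253D")

  # internal CAA -> TAA is a premature stop
  codons2 <- codons; codons2[100] <- "CAA"
  cds2 <- paste0("ATG", paste(codons2[-1], collapse = ""), "TAA")
  seqs2 <- c(c = paste0(flank, cds2, "CCGTAAGG"))
  p100 <- 50L + 100L * 3L - 2L
  res2 <- predict_coding_consequence(snp(p100, "C", "T"), m, seqs2)
  expect_identical(res2$consequence, "stop_gained")

  # destroying the natural stop extends translation to the next in-frame
  # stop; here 5 new codons are read: the mutated stop itself plus CCG TAA ->
  # build a tail with the next stop exactly 5 codons downstream
  tail5 <- paste0(paste(rep("CCA", 4), collapse = ""), "TGAGG")
  seqs3 <- c(c = paste0(flank, cds, tail5))
  pstop <- 50L + nchar(cds) - 2L  # first base of the TAA stop codon
  res3 <- predict_coding_consequence(snp(pstop, "T", "C"), m, seqs3)
  expect_identical(res3$consequence, "stop_lost")
  expect_identical(res3$extension_aa, 5L)
  expect_false(res3$extension_censored)

  # reference mismatch is an error
  expect_error(predict_coding_consequence(snp(p253, "C", "G"), m, seqs),
               "reference mismatch")
  # a stop-to-stop substitution is synonymous
  res4 <- predict_coding_consequence(snp(pstop + 1L, "A", "G"), m, seqs)
  expect_identical(res4$consequence, "synonymous")
})

test_that("consequence labels agree with full-protein translation oracle", {
  ann <- small_study(seed = 23, interval_length = 30000L, n_genes = 4L)
  set.seed(23)
  n_checked <- 0L
  for (m in ann$models) {
    coding_pos <- unlist(Map(seq, m$coding$start, m$coding$end))
    for (p in sample(coding_pos, 30L)) {
      ref <- substr(ann$sequence[[1L]], p, p)
      for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
        v <- variant_table("chr8", p, ref, alt, 10L)[1L, ]
        got <- predict_coding_consequence(v, m, ann$sequence)$consequence
        want <- oracle_consequence(p, alt, m, ann$sequence)
        expect_identical(got, want)
        n_checked <- n_checked + 1L
      }
    }
  }
  expect_gte(n_checked, 300L)
})

test_that("strand mirror symmetry: reflected coordinates keep region labels", {
  L <- 30000L
  ann <- small_study(seed = 31, interval_length = L, n_genes = 4L)
  set.seed(31)
  pos <- sample.int(L, 200L)
  for (m in ann$models) {
    mr <- reflect_model(m, L)
    orig <- vapply(pos, function(p)
      classify_variant_location(list(chrom = "chr8", pos = p), m)$region,
      character(1))
    refl <- vapply(L - pos + 1L, function(p)
      classify_variant_location(list(chrom = "chr8", pos = p), mr)$region,
      character(1))
    expect_identical(orig, refl)
  }
})

test_that("variants are annotated against every gene window they fall in", {
  g1 <- mk_gene(exons = data.frame(start = 10001L, end = 11000L), id = "g1")
  g2 <- mk_gene(exons = data.frame(start = 13000L, end = 14000L), id = "g2")
  v <- variant_table("c", 12000L, "A", "G", 9L)
  ann <- annotate_variants(v, list(g1, g2))
  expect_identical(nrow(ann), 2L)
  expect_setequal(ann$gene_id, c("g1", "g2"))
  expect_setequal(ann$region, c("downstream", "upstream"))
  expect_identical(ann$distance_bp, c(1000L, 1000L))

  expect_identical(nrow(annotate_variants(empty_variant_table(),
                                          list(g1, g2))), 0L)
  # far-away variant keeps a single intergenic record
  far <- annotate_variants(variant_table("c", 99999L, "A", "G", 9L),
                           list(g1, g2))
  expect_identical(far$region, "intergenic")
  expect_true(is.na(far$gene_id))
})

test_that("annotation summary counts equal an exhaustive recount", {
  ann <- small_study(seed = 47, interval_length = 50000L, n_genes = 6L)
  set.seed(47)
  pos <- sample.int(50000L, 120L)
  refs <- vapply(pos, function(p) substr(ann$sequence[[1L]], p, p),
                 character(1))
  alts <- vapply(refs, function(b) setdiff(c("A", "C", "G", "T"), b)[1L],
                 character(1))
  v <- variant_table("chr8", pos, refs, alts, 10L)
  tab <- annotate_variants(v, ann$models, ann$sequence, window_bp = 5000L)
  recount <- table(unlist(lapply(seq_len(nrow(v)), function(i) {
    labs <- vapply(ann$models, function(m)
      oracle_region(v$pos[i], m, 5000L), character(1))
    if (all(labs == "intergenic")) "intergenic"
    else labs[labs != "intergenic"]
  })))
  expect_identical(as.vector(table(tab$region)[names(recount)]),
                   as.vector(recount))
})
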