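OV <- "AO"; MER <- "VM"; OTHER <- c("FM", "YFB")

test_that("tissue-relevance filter eliminates ovary-only, meristem-only and
          silent genes", {
  profiles <- list(only_ovary = OV, only_meristem = MER,
                   ovary_and_fm = c(OV, "FM"), fm_only = "FM",
                   silent = character())
  kept <- tissue_relevance_filter(profiles, OV, MER, OTHER)
  expect_setequal(kept, c("ovary_and_fm", "fm_only"))
  expect_error(tissue_relevance_filter(list(g = "mystery"), OV, MER, OTHER),
               "unknown dataset")
})

test_that("variant evidence summarizes per gene with fixed severity order", {
  ann <- data.frame(
    gene_id = c("g1", "g2", "g2", "g3", "g3", NA),
    region = c("exon_coding", "exon_coding", "exon_coding", "upstream",
               "upstream", "intergenic"),
    consequence = c("missense", "stop_gained", "missense", "none", "none",
                    "none"),
    protein_change = c("N253D", "Q88*", "A10V", NA, NA, NA),
    stringsAsFactors = FALSE)
  ev <- attach_variant_evidence(c("g1", "g2", "g3", "g4"), ann)
  expect_identical(ev$coding_change, c("missense", "stop_gained", "none",
                                       "none"))
  expect_identical(ev$protein_change[1:2], c("N253D", "Q88*"))
  expect_identical(ev$noncoding_classes, c("", "", "upstream", ""))
})

mk_evidence <- function(genes, de_dir = "none", de_avg = 0,
                        coding = "none", noncoding = "") {
  list(de = data.frame(gene_id = genes, direction = de_dir,
                       avg_log2fc = de_avg, stringsAsFactors = FALSE),
       ve = data.frame(gene_id = genes, coding_change = coding,
                       protein_change = NA_character_,
                       noncoding_classes = noncoding,
                       stringsAsFactors = FALSE))
}

test_that("selection requires retained plus a sufficient evidence rule", {
  e <- mk_evidence(c("a", "b", "c", "d"),
                   de_dir = c("down", "none", "none", "none"),
                   de_avg = c(-4.11, 0, 0, 0),
                   coding = c("none", "stop_gained", "none", "synonymous"),
                   noncoding = c("", "", "upstream", ""))
  tab <- select_candidates(c("a", "b", "c", "d"), e$de, e$ve)
  expect_identical(tab$selected, c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(tab$reasons[1], "differential_expression")
  expect_identical(tab$reasons[2], "coding_variant")
  # non-coding variants alone never select; synonymous changes never select
  expect_identical(tab$noncoding_classes[3], "upstream")
  # function flag is sufficient for a retained gene
  ff <- data.frame(gene_id = "c", flag = TRUE,
                   annotation = "cytokinin oxidase",
                   stringsAsFactors = FALSE)
  tab2 <- select_candidates(c("a", "b", "c", "d"), e$de, e$ve, ff)
  expect_true(tab2$selected[tab2$gene_id == "c"])
  expect_identical(tab2$reasons[tab2$gene_id == "c"], "putative_function")
  # non-retained genes never appear
  tab3 <- select_candidates(c("a"), e$de, e$ve)
  expect_identical(tab3$gene_id, "a")
})

test_that("selection is monotone: adding evidence never de-selects", {
  set.seed(12)
  genes <- paste0("g", 1:30)
  for (r in 1:20) {
    de_dir <- sample(c("up", "down", "none"), 30, replace = TRUE,
                     prob = c(.2, .2, .6))
    coding <- sample(c("none", "synonymous", "missense", "stop_gained"),
                     30, replace = TRUE)
    e <- mk_evidence(genes, de_dir = de_dir, coding = coding)
    base <- select_candidates(genes, e$de, e$ve)
    # upgrade one gene's evidence
    i <- sample(30, 1)
    e$ve$coding_change[i] <- "stop_gained"
    e$de$direction[i] <- "down"
    more <- select_candidates(genes, e$de, e$ve)
    expect_true(all(base$selected[base$gene_id %in%
                                    more$gene_id[more$selected]] |
                      TRUE))  # structure guard
    expect_true(all(more$selected[match(base$gene_id[base$selected],
                                        more$gene_id)]))
    expect_true(more$selected[more$gene_id == genes[i]])
  }
})

test_that("recorded reasons are faithful to the evidence", {
  set.seed(13)
  genes <- paste0("g", 1:40)
  de_dir <- sample(c("up", "down", "none"), 40, replace = TRUE)
  coding <- sample(c("none", "synonymous", "missense", "stop_lost"),
                   40, replace = TRUE)
  flag <- sample(c(TRUE, FALSE), 40, replace = TRUE)
  e <- mk_evidence(genes, de_dir = de_dir, coding = coding)
  ff <- data.frame(gene_id = genes, flag = flag, annotation = "",
                   stringsAsFactors = FALSE)
  tab <- select_candidates(genes, e$de, e$ve, ff)
  for (i in seq_len(nrow(tab))) {
    g <- tab$gene_id[i]
    want <- c("differential_expression"[de_dir[genes == g] != "none"],
              "coding_variant"[coding[genes == g] %in%
                                 c("missense", "stop_gained", "stop_lost")],
              "putative_function"[flag[genes == g]])
    expect_identical(tab$reasons[i], paste(want, collapse = ","))
    expect_identical(tab$selected[i], length(want) > 0L)
  }
})

test_that("candidate report renders deterministic TSV plus summary counts", {
  e <- mk_evidence(c("a", "b", "c"), de_dir = c("down", "none", "none"),
                   coding = c("none", "missense", "none"))
  tab <- select_candidates(c("a", "b", "c"), e$de, e$ve,
                           positions = c(a = 300L, b = 100L, c = 200L))
  expect_identical(tab$gene_id, c("b", "c", "a"))  # positional order
  path <- withr::local_tempfile(fileext = ".tsv")
  out <- render_candidate_report(tab, path)
  lines <- readLines(out$tsv)
  expect_length(lines, 4L)  # header + 3 rows
  expect_match(readLines(out$summary), "selected candidates: 2",
               all = FALSE)
  # empty table -> header only
  empty <- tab[0, , drop = FALSE]
  render_candidate_report(empty, path)
  expect_length(readLines(path), 1L)
})
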