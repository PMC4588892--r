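# Independent oracles: direct enumerations and per-base walks, deliberately
# written without touching the package's own code paths so that agreement is
# a real cross-check.

CODON_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

oracle_translate <- function(nt) {
  n <- nchar(nt) %/% 3L
  paste(vapply(seq_len(n),
               function(i) CODON_TABLE[[substr(nt, 3L * i - 2L, 3L * i)]],
               character(1)), collapse = "")
}

oracle_revcomp <- function(nt) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(nt, "")[[1]]]), collapse = "")
}

# Per-base walk over the coding spans.
oracle_spliced_cds <- function(model, sequence) {
  s <- sequence[[model$chrom]]
  chars <- character()
  for (i in seq_len(nrow(model$coding)))
    for (p in model$coding$start[i]:model$coding$end[i])
      chars <- c(chars, substr(s, p, p))
  cds <- paste(chars, collapse = "")
  if (model$strand == "-") oracle_revcomp(cds) else cds
}

# Exhaustive interval-membership region labelling: every relevant position
# set is enumerated and membership tested directly.
oracle_region <- function(pos, model, window = 10000L) {
  span <- c(min(model$exons$start), max(model$exons$end))
  genic <- span[1L]:span[2L]
  exonic <- unlist(Map(seq, model$exons$start, model$exons$end))
  coding <- if (nrow(model$coding) > 0L)
    unlist(Map(seq, model$coding$start, model$coding$end)) else integer()
  if (model$strand == "+") {
    up <- (span[1L] - window):(span[1L] - 1L)
    down <- (span[2L] + 1L):(span[2L] + window)
  } else {
    up <- (span[2L] + 1L):(span[2L] + window)
    down <- (span[1L] - window):(span[1L] - 1L)
  }
  if (pos %in% coding) return("exon_coding")
  if (pos %in% exonic) return("exon_noncoding")
  if (pos %in% genic) return("intron")
  if (pos %in% up) return("upstream")
  if (pos %in% down) return("downstream")
  "intergenic"
}

# Full-protein comparison oracle for coding SNP consequences: mutate the
# whole chromosome, rebuild and translate both proteins, and classify from
# the stop positions.
oracle_consequence <- function(pos, alt, model, sequence) {
  mut_seq <- sequence
  s <- mut_seq[[model$chrom]]
  substr(s, pos, pos) <- alt
  mut_seq[[model$chrom]] <- s
  ref_p <- oracle_translate(oracle_spliced_cds(model, sequence))
  mut_p <- oracle_translate(oracle_spliced_cds(model, mut_seq))
  if (identical(ref_p, mut_p)) return("synonymous")
  ref_stop <- regexpr("*", ref_p, fixed = TRUE)
  mut_stop <- regexpr("*", mut_p, fixed = TRUE)
  if (mut_stop > 0L && (ref_stop < 0L || mut_stop < ref_stop))
    return("stop_gained")
  if (ref_stop > 0L && (mut_stop < 0L || mut_stop > ref_stop))
    return("stop_lost")
  "missense"
}

# Brute-force re-evaluation of the three genome-wide filter rules.
oracle_de_filter <- function(mut, wt, smallest, rpkm_thr = 2, fc_thr = 0.5,
                             pseudo = 0.1) {
  keep <- character()
  others <- setdiff(colnames(mut), smallest)
  for (g in rownames(mut)) {
    n_over <- 0L
    for (f in colnames(mut)) {
      a <- mut[g, f]; b <- wt[g, f]
      if ((!is.na(a) && a > rpkm_thr) || (!is.na(b) && b > rpkm_thr))
        n_over <- n_over + 1L
    }
    fc <- sapply(colnames(mut), function(f)
      log2((mut[g, f] + pseudo) / (wt[g, f] + pseudo)))
    if (any(is.na(fc))) next
    same_dir <- all(fc > 0) || all(fc < 0)
    rule3 <- abs(fc[smallest]) > fc_thr && any(abs(fc[others]) > fc_thr)
    if (n_over >= 2L && same_dir && rule3) keep <- c(keep, g)
  }
  keep
}

oracle_region_call <- function(fc_row, fc_thr = 0.5) {
  if (any(is.na(fc_row))) return("none")
  if (all(fc_row < -fc_thr)) return("down")
  if (all(fc_row > fc_thr)) return("up")
  "none"
}

# Exhaustive enumeration of all n-subsets of a universe of N with a K-member
# category: tail probability of an overlap of at least k.
oracle_hyper_tail <- function(N, K, n, k) {
  if (k == 0L) return(1)
  if (n == 0L) return(0)
  draws <- utils::combn(N, n)
  overlaps <- colSums(draws <= K)
  mean(overlaps >= k)
}

# Mirror a study's coordinates about the interval midpoint, flipping strand.
reflect_model <- function(model, L) {
  refl <- function(s, e) data.frame(start = L - e + 1L, end = L - s + 1L)
  gene_model(gene_id = model$gene_id, chrom = model$chrom,
             strand = if (model$strand == "+") "-" else "+",
             exons = refl(model$exons$start, model$exons$end),
             coding = refl(model$coding$start, model$coding$end))
}

# A small deterministic annotated fixture for variant-level tests; no
# planted structure so any gene count is allowed.
small_study <- function(seed = 1, ...) {
  generate_annotation(study_config(seed = seed, de_plan = NULL,
                                   planted_variants = NULL,
                                   tissue_plan = list(), ...))
}
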