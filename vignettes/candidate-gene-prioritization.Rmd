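---
title: "Candidate-gene prioritization in a fine-mapped fruit-shape QTL interval"
author: "fsqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Candidate-gene prioritization in a fine-mapped fruit-shape QTL interval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fsqtl)
```

## The problem

The tomato locus *fs8.1* is a major quantitative trait locus (QTL) for
elongated fruit shape that sits in a pericentromeric region where meiotic
recombination is strongly suppressed. Fine-mapping stalls at an interval of
roughly 3 Mb containing on the order of a hundred annotated genes, far too
many to test transgenically one by one. The practical way forward is evidence
integration: combine interval membership, expression in the relevant tissues,
differential expression between near-isogenic lines (NILs) carrying the
mutant or wild-type allele, sequence variants near or inside gene models, and
curated knowledge of gene function, and reduce the gene list to a tractable
candidate set.

`fsqtl` implements that integration as a reusable, deterministic pipeline,
together with the organ morphometrics used to characterize what the locus
does to the plant, and a seeded synthetic-study generator so every stage can
be exercised and validated without any external data.

## The filtering model

### Expression and the tissue-relevance filter

Expression is quantified as RPKM (reads per kilobase of exon model per
million mapped reads),

$$\mathrm{RPKM} = \frac{10^9 \, c}{N \, \ell},$$

with $c$ the read count, $\ell$ the exon-model length in bp and $N$ the
mapped-library size. A gene is *expressed* in a dataset when any sample
exceeds 2 RPKM, strictly; a value of exactly 2 does not qualify, and absent
measurements never do (`expressed_call()`). Absent cells are kept as `NA`
throughout — an unmeasured gene is not an unexpressed gene.

Because the locus has finished acting on organ shape by anthesis, genes whose
expression is confined to anthesis-stage ovaries cannot have set up the
phenotype earlier in development, and genes confined to the vegetative
meristem are acting in the wrong organ. `tissue_relevance_filter()` therefore
eliminates genes expressed *only* in anthesis-ovary-type datasets or *only*
in vegetative-meristem-type datasets, along with genes expressed nowhere;
everything else is retained.

### Differential expression without replicates

The three NIL families are independent backcross derivatives, so their
RNA-Seq pairs cannot be pooled into a replicated count model; each mutant/WT
pair is treated as a separate experiment summarized by a log2 fold-change

$$\mathrm{log2FC} = \log_2 \frac{m + \epsilon}{w + \epsilon},$$

with pseudocount $\epsilon = 0.1$ RPKM (configurable; the value only matters
near zero and 0.1 is an order of magnitude below the expressed threshold).
Two threshold filters are built from these:

* **Genome-wide filter** (`genomewide_de_filter()`), used to assemble the
  gene set for term enrichment: (i) RPKM > 2 in at least two of three
  comparisons, (ii) the same strict sign of log2FC in all three (a zero
  fails), and (iii) |log2FC| > 0.5 in the smallest-introgression family and
  in at least one of the other two. The smallest-introgression family is a
  *role*, not a hard-coded name: that family has the least residual donor
  genome, so a change reproduced there is least likely to be driven by a
  linked passenger locus. Rule (i) accepts either member of a pair above
  threshold (`rule_i_scope` makes this configurable), since a gene switched
  off in one genotype is exactly the interesting case.
* **Interval DE call** (`region_de_call()`), used as candidate evidence:
  consistently down means log2FC < −0.5 in all three families, consistently
  up means > +0.5 in all three; anything else is `none`. The reported
  average is the arithmetic mean of the three fold-changes.

### Variants and protein consequences

Variants enter as VCF records with supporting-read depth and are first
filtered to ≥ 2 distinct supporting reads (`filter_variants_by_support()`);
records with unknown depth fail, on the view that unverifiable support is no
support. Each surviving variant is localized against every gene whose 10 kb
flanking window contains it (`classify_variant_location()`): `upstream`
within 10 kb of the strand-aware transcription start (inclusive at exactly
10 000 bp), `downstream` mirrored from the transcription end, and
`exon_coding` / `exon_noncoding` / `intron` inside the gene span. The labels
partition the genome relative to a gene, and a variant between two genes is
deliberately reported against both — nearest-gene assignment is a summary
view, not the data model.

Coding SNPs are consequence-called by translating the spliced reference and
mutated coding sequences with the standard nuclear genetic code
(`predict_coding_consequence()`): `synonymous`, `missense` (notated like
`N253D`), `stop_gained`, or `stop_lost`. For a destroyed natural stop the
downstream genomic sequence is scanned in frame and `extension_aa` counts
the additional residues translated before the next in-frame stop, bounded by
`max_extension_scan_aa` (default 1000) and censored if the bound or the end
of the contig is reached first. Coding indels are flagged
(`frameshift_not_called`) rather than consequence-called: frameshift
semantics would add assumptions the rest of the pipeline never uses, and
non-coding indels — where small indels typically fall in this design — are
fully handled by the region classifier.

### Evidence integration

`select_candidates()` marks a retained gene as a candidate when at least one
*sufficient* rule fires: a consistent DE call, a protein-altering coding
change (missense, stop gained, stop lost — a fixed severity order,
stop_gained > stop_lost > missense > synonymous, summarizes multiple hits),
or a curated putative-function flag. Function flags are an input table, not
a text-mining step: which annotations count as shape-relevant is expert
judgement, and encoding it as data keeps the pipeline honest about that.
Non-coding variants near a gene are carried in the table as supporting
context but never select a gene alone; a promoter SNP strengthens a DE-based
candidate rather than creating one. The `reasons` column records exactly
which rules fired, and selection is monotone in evidence by construction.

### Enrichment

`enrich_terms()` performs the classical hypergeometric over-representation
test of functional terms in a selected set against a universe, upper tail
$P(X \ge k)$ computed in log space, Benjamini–Hochberg adjustment by default
(raw p-values are always reported alongside). The universe is the caller's
choice — the natural one is all genes with expression data — and genes of the
mapped interval itself can be excluded so that linkage with the introgression
does not masquerade as functional enrichment.

## Morphometrics and gene action

The measurement formulas are simple ratios and means: shape index $L/W$,
widest-position ratio $y/L$, pericarp thickness $(h_1+h_2+w_1+w_2)/4$,
average cell size as boxed area over boxed cell count, and large-cell size
as the mean of the six biggest cell areas. Group comparisons use Student's
pooled-variance two-sample t test (`progeny_test()`, Welch available via
`var_equal = FALSE`), with the degenerate zero-variance case mapped to
$t = 0, p = 1$ when means are equal. Metabolite levels are compared as
percent of wild type with a paired t test on per-replicate differences
(`percent_of_wt()`).

Gene action is summarized by the dominance/additivity ratio: with genotype
class means $\mu_{mut}, \mu_{het}, \mu_{wt}$,

$$A = \frac{\mu_{mut} - \mu_{wt}}{2}, \qquad
  D = \mu_{het} - \frac{\mu_{mut} + \mu_{wt}}{2}, \qquad
  \text{gene action} = D/A .$$

Zero is pure additivity, $\pm 1$ complete dominance, $|D/A| > 1$
overdominance. The additive effect is oriented mutant-minus-wild-type, so a
negative ratio means dominance toward the wild-type allele.
`run_morpho_stats()` summarizes shape per plant as the mean of per-organ
ratios before averaging per genotype; note that a ratio of group means is
not in general the mean of ratios, and the package computes both where a
comparison is wanted.

## The synthetic-study generator

`study_config()` fixes the study conditions; every generator is a pure
function of the config, so regeneration is byte-identical and each emitted
truth record can be re-verified by running the corresponding pipeline stage
on the emitted files.

The default configuration is a 1:10 desk-scale image of the mapped region:
a 100 kb interval carrying 12 genes, 16 background SNPs and one small indel
(the full regime — 3.03 Mb, 122 genes, 158 SNPs, 5 indels — is available as
`full_scale_config()`). Genes are packed without overlap, each with 1–3
exons, untranslated leader and trailer, and a verified CDS (ATG start, sense
codons, in-frame stop) written into the emitted FASTA. Planted coding
variants are found by codon search and verified against the consequence
caller at generation time; background variant support depths are Poisson
(mean ≈ 32) with a configurable fraction dropped below 2 reads to exercise
the support filter.

Expression baselines are lognormal on RPKM (meanlog 3, sdlog 1 — median
around 20 RPKM with a realistic heavy right tail), with multiplicative
lognormal noise of sd 0.15 on the natural-log scale per sample. The noise
model is a simplicity choice: positive-valued, heavy-tailed, and exact in
the zero-noise limit, but it ignores count-level sampling variance at low
expression, so tests passing on these fixtures say nothing about
low-coverage behaviour on real libraries. The default DE plan plants one
consistently upregulated gene near +0.6 and one strongly downregulated gene
near −4.1 — the magnitudes of the reported up- and strongest down-regulated
candidates — and planted causal genes are given a baseline floor (8 RPKM) so
that a plant is always in principle detectable. The tissue plan reserves one
gene expressed only in the ovary dataset, one only in the meristem dataset
and one silent gene, exercising every branch of the tissue filter.

Phenotypes emulate the anthesis-ovary organ row: wild-type length 1.93 mm,
mutant effect +0.27 mm, width 1.95 mm identically distributed across
genotypes, and heterozygote mean at midparent plus a dominance parameter
(default −0.47, the reported shape-index gene action) times the additive
effect. The per-plant standard deviation of 0.025 mm is the printed standard
errors of about 0.01 mm scaled back up by $\sqrt{6}$ plants.

What the generator does *not* emulate: read-level noise (no FASTQ), genome
gaps and repeat structure, linkage between expression and genotype beyond
the planted effects, multi-transcript genes, and structural variants. Tests
against these fixtures validate the pipeline's logic and numerics, not its
robustness to assembly artefacts.

## Numerical and design notes

* Coordinates are 1-based inclusive (GFF3/VCF convention) everywhere in the
  domain model; half-open arithmetic, where used, is internal.
* Thresholds are strict inequalities (`> 2` RPKM, `|log2FC| > 0.5`), and the
  10 kb flanking window is inclusive at exactly 10 000 bp.
* Stop-loss extensions are reported as computed from the supplied sequence;
  the extension depends only on the downstream in-frame stop and is censored,
  never guessed, when the scan bound is hit.
* Verification problem sizes were chosen for fast desk-scale iteration: the
  oracle-equivalence suites run 100 seeded fixtures each (30-gene expression
  matrices; 5-gene, 20 kb annotations with 500 variant-gene pairs), recovery
  studies use 50 seeds at the default 100 kb scale, and statistical
  calibration uses 1000 null replicates and 200 plants per genotype.
* Tie-breaks: candidate tables sort by gene position with identifier as
  fallback; enrichment results sort by adjusted then raw p-value then term.
* Degenerate inputs are contracts, not crashes: empty feature files give
  empty model lists, an empty VCF gives a complete scan with all variant
  evidence `none`, zero-variance t tests follow the conventions above, and
  genes missing from every expression table are treated as expressed
  nowhere.

## Known limitations

* Rule (i)'s pair scope ("either sample above 2 RPKM") is one defensible
  reading; the alternative mutant-only or wild-type-only scopes are exposed
  as options and can change the enrichment universe.
* The consequence caller handles single-nucleotide substitutions in CDS;
  splice-site disruption, regulatory-motif changes and coding indels are out
  of scope by design.
* Shape-index summaries from group means and from per-organ ratios disagree
  in general; both are computed, and which one a published table printed
  must be established per row.
* The hypergeometric test treats term annotations as fixed and genes as
  exchangeable; no graph propagation over term hierarchies is attempted.
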