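---
title: "Nominating GWAS candidate genes and profiling their conservation in Drosophila"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nominating GWAS candidate genes and profiling their conservation in Drosophila}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwasfly)
```

## The problem

Genome-wide association studies report index SNPs, not genes. Because an
association peak spans a linkage-disequilibrium block, the causal gene behind
a signal may be the gene the SNP falls in, a neighbor, or any gene within a
few hundred kilobases. Before a human susceptibility candidate can be followed
up in *Drosophila*, three questions must be answered systematically: which
genes does each SNP implicate, which of those genes have a fly ortholog at
all, and what is known about the fly ortholog's expression and phenotypes.
`gwasfly` implements that pipeline as composable, tested functions over tidy
tables.

## Candidate nomination: four nested criteria

For every association the pipeline nominates genes under four criteria of
increasing liberality:

1. **intragenic** — genes whose span contains the SNP (exonic or intronic);
2. **nearest neighbors** — the intragenic gene(s) plus the nearest
   non-overlapping gene on each side;
3. **within 250 kb** — all genes overlapping a window extending 125 kb on
   each side of the SNP;
4. **within 500 kb** — the same with a 250 kb half-width.

The window tiers are nested by construction
(intragenic ⊆ within 250 kb ⊆ within 500 kb). Nearest neighbors are *not*
nested inside the windows: on a sparse chromosome the nearest gene can lie
beyond 125 kb, and the implementation deliberately preserves that.

Design choices a user should know about:

* **Coordinates.** Everything internal is 0-based half-open. GFF3 (1-based
  inclusive) and catalog positions (1-based) are converted on ingest; BED is
  used as-is. A single convention removes off-by-one ambiguity from every
  overlap and distance computation.
* **Gene bodies, not exon models.** "Intragenic" means containment in the
  full gene span. Intron/exon structure is transcript-dependent and the
  criteria here are deliberately transcript-agnostic; this is the assumption
  documented in the package rather than resolved by it.
* **Strand is stored but ignored** by all distance and overlap logic; the
  nomination criteria are positional.
* **Nested genes.** When a SNP falls inside several overlapping genes, all of
  them are reported intragenic and the assignment row carries a
  `multi_intragenic` audit flag, so a stricter one-gene-per-SNP analysis can
  be filtered after the fact. Silently choosing one gene would lose
  information.
* **Ties** between equidistant flanking genes break to the smaller `gene_id`;
  windows truncate at position 0.

Interval queries run on a `GenomicRanges` index; the test suite checks them
against plain linear-scan oracles on randomized annotations (including
overlapping and nested gene models), and `true_tier_memberships()` provides
the same reference scan for whole assignments.

## Catalog parsing and trait categories

The association reader consumes the public GWAS-catalog TSV dialect with a
configurable column mapping. Multi-SNP cells (haplotypes, SNP × SNP
interactions) are split on `";"` or `"x"` with chromosome/position tokens
aligned by index; tokens with no usable position are dropped and counted in a
parse report so that `rows kept + rows dropped = rows read` always holds.
P-values are carried but never filtered on — every catalog entry is treated
as a reported finding. Deduplication defaults to the `(rsid, trait)` key; a
per-`rsid` key is available because the right choice depends on whether a
SNP associated with two traits should count once or twice, which the pipeline
exposes rather than decides.

Traits are mapped to categories under two separate schemes — target tissue
and disease mechanism — by normalized exact match (case-folding plus
whitespace squishing). Unmapped traits flow through with `NA` category and
surface in an "uncategorized" bucket rather than being silently dropped from
trait-level output.

## Orthology: integrative vote scores

Conservation in fly is called from an integrative ortholog score: the number
of *distinct* prediction algorithms supporting a (human gene, fly gene) pair.
The individual algorithms are out of scope; their votes are the input, either
as raw per-algorithm rows (`integrate_predictions()`) or as a pre-integrated
score table (`read_ortholog_scores()`), so a published integrative resource
can be ingested directly.

A human gene is **conserved** when any of its pairs reaches the threshold —
`min_score = 2`, i.e. at least two algorithms agree, inclusive at exactly 2.
This is a liberal criterion (documented as such in the source analysis);
the threshold is a parameter, and the conserved set is provably monotone
non-increasing in it. Genes with no pairs at all are "not conserved";
supplying a gene universe distinguishes them (pair count 0) from genes with
weak evidence. Whether "conserved" should require the *best* pair or *any*
pair to pass is unstated in the source analysis; the two coincide when scores
are per-pair maxima, and any-pair is implemented.

`best_orthologs()` returns the tied top scorers, id-sorted, and downstream
profiling aggregates across ties with an **any-of** rule: a human gene counts
as head-expressed (or lethal, or neuronal) if any tied best ortholog is. This
mirrors the liberal conservation logic and keeps profiles deterministic.

## Functional profiles

Expression calls use an RPKM threshold, default 2.0, inclusive at the
boundary; a missing (gene, tissue) cell means "not detected", never
"unknown", and repeated cells keep the maximum RPKM. Phenotype classes are
set-membership queries against configured controlled-vocabulary term sets:
a *neuronal* set (the published analysis used 41 curated FlyBase CV terms
whose identities are not recoverable from the text — the package therefore
ships clearly synthetic placeholder ids in `default_term_config()` and treats
the real sets as required user configuration) and a *lethal* set defining
essentiality, with no lethal-phase distinction.

## Category summaries

`conservation_summary()` reports, per group and tier, the candidate count,
conserved count, fraction, and fold enrichment over the genome baseline
(`fraction / baseline` at full precision; rounding to the conventional one
decimal of a "1.2-fold" is presentation only). Groups with zero candidates
are marked undefined — written as the sentinel `ND` in reports — never as 0.
Fisher exact p-values on the category-vs-background 2×2 table, with
Benjamini–Hochberg adjustment across categories, are computed as a clearly
labelled descriptive extension; the headline outputs are the folds. A
zero-margin table returns p = 1 by convention.

## What the generator emulates — and what it does not

`simulate_study()` stands in for five external resources (association
catalog, gene annotation, ortholog predictions, tissue RPKM, phenotype
terms) with known ground truth. Its default configuration *is* the study
condition the package is validated under:

| parameter | default | rationale |
|---|---|---|
| genes / chromosomes | 15,000 / 5 | desk-scale genome preserving the gene density regime of the human genome |
| gene length | log-normal, median 30 kb (sdlog 0.8) | typical protein-coding span |
| intergenic gap | log-normal, median 100 kb (sdlog 1.0) | a few genes per 500 kb window, as in gene-dense loci |
| SNPs | 3,000 | desk-scale stand-in for the 15,825 catalog SNPs |
| intragenic SNP fraction | 0.40 | roughly the intronic+exonic share of catalog index SNPs |
| genome-wide conserved fraction | 0.53 | the published genome-wide baseline |
| candidate conservation lift | 1.2× on intragenic candidates | the published enrichment; applied to the intragenic tier because that is where the published enrichment is strongest and all downstream profiling is restricted to it |
| algorithms / TPR / FPR / decoys | 10 / 0.95 / 0.005 / 2 | ten voting algorithms as in the integrative tool; high-sensitivity votes for true pairs, rare spurious votes on two decoy partners per gene |
| expression (candidate homologs) | head 0.77, whole 0.72, gut 0.69 | the published tissue profile |
| expression (genome-wide) | head 0.55, whole 0.60, gut 0.50 | plausible broad-expression rates for the reference rows (not printed in the source) |
| RPKM magnitudes | expressed: log-normal median 15; unexpressed: median 0.2 (both sdlog 0.8) | >99% of each class falls on the correct side of the threshold, so calls and flags agree up to ~1% leakage |
| lethality | candidates 0.43, genome-wide 0.25 | the published essentiality enrichment |
| neuronal phenotype | candidates 0.33, genome-wide 0.25 | the published neuronal-term enrichment |
| other annotation | 0.11 | tuned so candidate homolog annotation coverage lands at the published ~66% |

One modelling decision deserves emphasis. The published genome-wide figures
(53% conserved, 25% lethal, the all-fly-genes expression rows) are averages
over *all* genes, candidates included. A generator that drew non-candidates
at the genome-wide rate *and* candidates at the lifted rate would therefore
overshoot every genome-wide figure by construction. `gwasfly` instead plants
the genome-wide rate: candidates draw at the lifted rate and the remaining
genes at the complementary rate `(p - w·p_lift)/(1 - w)` (with `w` the
realized candidate fraction), so the genome-wide mean equals the planted
value exactly and the enrichment is carried entirely by the candidate class.

Randomness is split into one stream per sub-generator, derived from the
master seed, so enlarging the SNP panel does not perturb the genome draw and
every emitted file is byte-identical across runs of the same configuration.

The generator deliberately does **not** emulate: linkage disequilibrium or
allele frequencies (the pipeline never uses them), realistic chromosome-level
gene clustering, overlapping/nested gene models (its layout is tiled, though
the readers and queries support overlap and are tested on overlapping
annotations), many-to-many orthology (each gene has one true partner plus
decoys), or correlated expression across tissues. Passing the recovery tests
therefore demonstrates that the pipeline measures what the generator plants —
not that real catalog data are free of the LD, annotation-version, and
curation artifacts that a real analysis must still confront.

## Validation strategy and problem sizes

The test suite validates three layers, all at sizes chosen to keep a full run
within a couple of minutes on one CPU:

* **oracle equivalence** — indexed interval queries vs linear scans on 1,000
  randomized instances over a 400-gene annotation with overlapping genes;
* **analytic recovery** — the conserved-call fraction on 10,000 simulated
  genes against the closed form implied by the vote model (a gene is called
  when its true pair reaches 2 of `n` votes at the TPR, or any decoy pair
  does at the FPR), within 3 binomial standard errors;
* **end-to-end recovery** — the full default scenario (15,000 genes, 3,000
  SNPs) through the whole pipeline, recovering the planted baseline, lift,
  expression, and lethality values within 3 SE of their planted values (the
  expression checks carry an extra 1.5-point allowance for the ~1% RPKM
  tail leakage noted above).

`scripts/acceptance.R` re-runs the end-to-end scenario from scratch under a
caller-supplied seed and writes the measured headline quantities as JSON.

## Worked example

```{r example}
genes <- read_gene_annotations(
  system.file("extdata", "cd2ap_region.gff3", package = "gwasfly"), "gff3")
snp <- tibble::tibble(rsid = "rs9349407", chrom = "6", pos = 47520025L,
                      trait = "Alzheimer's disease")
assign_candidates(snp, genes)
```

The index SNP sits in an intron of *CD2AP* (distance 0, all four tiers);
*TNFRSF21* and *ADGRF2* are the flanking nearest neighbors; *ADGRF4* enters
only at the 500 kb tier.

## Known limitations

* Gene-body containment can differ from an exon/intron-resolved "intragenic"
  call for SNPs in annotation gaps of specific transcript sets.
* Distance-based nomination ignores regulatory architecture: an eQTL acting
  on a gene outside the 500 kb window is invisible to every tier.
* Vote scores treat algorithms as exchangeable; no weighting, no paralog
  disambiguation beyond the tied-best rule.
* The placeholder phenotype term sets are for testing only; real analyses
  must supply curated neuronal and lethality term sets.
* Undefined fractions propagate as `NA`/`ND`; small categories are reported
  with their n so the reader can judge stability, but no minimum-n filter is
  imposed.
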