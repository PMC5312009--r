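# gwasfly

Cross-species triage of GWAS findings for *Drosophila* follow-up: nominate
human candidate susceptibility genes around index SNPs, call their
conservation in the fly genome, and profile what is known about the fly
homologs — as a tidyverse-style R package in which every step takes a data
frame and returns a tibble.

It is written for human geneticists deciding which GWAS loci are tractable in
flies, and for fly biologists asking which human disease genes their system
can model.

## What it computes

**Candidate nomination.** A GWAS reports index SNPs, not genes. For each
association the package nominates genes under four nested criteria:
*intragenic* (the SNP lies in the gene span), *nearest neighbors* (the
intragenic gene plus the immediately proximal and distal genes), and all
genes overlapping windows of ±125 kb (*within 250 kb*) and ±250 kb (*within
500 kb*) around the SNP.

**Conservation calls.** For a human gene *h* with ortholog predictions from
*n* algorithms, the integrative vote score of a human–fly pair is

&nbsp;&nbsp;&nbsp;&nbsp;score(h, f) = #{distinct algorithms predicting (h, f)},

and *h* is called conserved when max<sub>f</sub> score(h, f) ≥ 2 (at least
two algorithms agree; inclusive threshold, configurable).

**Category summaries.** Per trait category (two schemes: target tissue and
disease mechanism) and per nomination tier: conserved fraction *p̂*, fold
enrichment *p̂* / *p̂*<sub>genome</sub> against the genome-wide baseline, and a
Fisher exact p-value as a descriptive extension. Fly homologs of candidates
are further profiled for tissue expression (RPKM ≥ 2) and phenotype classes
(lethal/essential, neuronal, any annotation) via their best-scoring
orthologs.

**Synthetic data.** `simulate_study()` generates all five inputs (catalog,
GFF3 annotation, per-algorithm predictions, RPKM report, phenotype terms)
with known ground truth, so the whole pipeline is testable offline; the
defaults plant a 53% genome-wide conservation baseline with a 1.2× candidate
lift, a 77/72/69% head/whole/gut expression profile, and 43% vs 25%
lethality enrichment.

## Worked example

The bundled chr6 fixture is the locus where an Alzheimer's disease index SNP
(rs9349407) falls in an intron of *CD2AP*:

```r
library(gwasfly)

genes <- read_gene_annotations(
  system.file("extdata", "cd2ap_region.gff3", package = "gwasfly"), "gff3")
snp <- tibble::tibble(rsid = "rs9349407", chrom = "6", pos = 47520025L,
                      trait = "Alzheimer's disease")
assign_candidates(snp, genes)
#> # A tibble: 4 × 10
#>   rsid      symbol   intragenic nearest_neighbor within_250kb within_500kb distance
#> 1 rs9349407 CD2AP    TRUE       TRUE             TRUE         TRUE                0
#> 2 rs9349407 ADGRF2   FALSE      TRUE             FALSE        TRUE           132204
#> 3 rs9349407 ADGRF4   FALSE      FALSE            FALSE        TRUE           157397
#> 4 rs9349407 TNFRSF21 FALSE      TRUE             FALSE        TRUE          -210142
```

*CD2AP* is intragenic (distance 0, all four tiers), *TNFRSF21* and *ADGRF2*
are the flanking neighbors (signed distance: negative = proximal side), and
*ADGRF4* enters only at the 500 kb tier.

A full study on simulated inputs:

```r
sim <- simulate_study(sim_config(seed = 1), dir = "simdata")
study <- run_conservation_study(
  read_gwas_catalog("simdata/gwas_catalog.tsv"),
  read_gene_annotations("simdata/genes.gff3", "gff3"),
  predictions = read_predictions("simdata/ortholog_predictions.tsv"),
  expression = read_rpkm_report("simdata/gene_rpkm_report.tsv"),
  phenotypes = read_phenotypes("simdata/phenotypes.tsv"),
  trait_categories = read_trait_categories("simdata/trait_categories.tsv"),
  fly_universe = sim$fly_universe)
study
#> <gwasfly_study>
#>   associations: 3000   candidate nominations: 9919
#>   genome baseline conserved: 51.9% of 15000 genes
#>   intragenic candidates: 1209 (60.8% conserved, 1.17-fold vs baseline)
tidy(study)
#> # A tibble: 4 × 9
#>   tier             group n_candidates n_conserved fraction baseline_fraction fold_enrichment
#> 1 intragenic       all           1209         735    0.608             0.519            1.17
#> 2 nearest_neighbor all           5612        2947    0.525             0.519            1.01
#> 3 within_250kb     all           4106        2198    0.535             0.519            1.03
#> 4 within_500kb     all           6470        3391    0.524             0.519            1.01
```

The intragenic tier recovers the planted 1.2× conservation lift over the
53% baseline (both within sampling noise at this size); the liberal tiers sit
at baseline because the simulation plants no enrichment there.
`study$expression_summary` and `study$phenotype_summary` hold the per-category
expression and lethality tables, `autoplot()` draws each summary, and
`write_study_report()` exports everything as TSV plus a run manifest.

A thin command-line wrapper with `simulate` and `run-all` subcommands is
installed at `system.file("cli", "gwasfly.R", package = "gwasfly")`.

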