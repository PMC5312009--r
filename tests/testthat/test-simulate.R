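small_cfg <- function(seed = 3, ...) {
  sim_config(seed = seed, n_genes = 600, n_snps = 150, n_chromosomes = 2, ...)
}

test_that("identical config and seed give byte-identical emitted files", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_study(small_cfg(), dir = d1)
  simulate_study(small_cfg(), dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  other <- simulate_study(small_cfg(seed = 4))
  base <- simulate_study(small_cfg())
  expect_false(identical(base$catalog, other$catalog))
})

test_that("every emitted file parses through its reader with zero dropped rows", {
  d <- withr::local_tempdir()
  sim <- simulate_study(small_cfg(), dir = d)
  genes <- read_gene_annotations(file.path(d, "genes.gff3"), "gff3")
  expect_equal(genes[, c("gene_id", "chrom", "start", "end")],
               sim$genes[, c("gene_id", "chrom", "start", "end")])
  assoc <- read_gwas_catalog(file.path(d, "gwas_catalog.tsv"))
  rep <- parse_report(assoc)
  expect_equal(rep$n_rows_dropped, 0L)
  expect_equal(rep$n_tokens_dropped, 0L)
  expect_equal(nrow(assoc), 150)
  # positions round-trip through the 1-based catalog dialect
  expect_equal(assoc$pos, sim$truth$snps$pos)
  preds <- read_predictions(file.path(d, "ortholog_predictions.tsv"))
  expect_equal(nrow(preds), nrow(sim$predictions))
  expr <- read_rpkm_report(file.path(d, "gene_rpkm_report.tsv"))
  expect_equal(nrow(expr), 600 * 3)
  phen <- read_phenotypes(file.path(d, "phenotypes.tsv"))
  expect_gt(nrow(phen), 0)
  traits <- read_trait_categories(file.path(d, "trait_categories.tsv"))
  expect_equal(nrow(traits), nrow(default_trait_table()))
})

test_that("degenerate geometry configs behave", {
  empty <- simulate_genome(sim_config(n_genes = 0, n_snps = 0))
  expect_equal(nrow(empty), 0)
  genes <- simulate_genome(small_cfg())
  expect_true(all(genes$start >= 0 & genes$start < genes$end))
  # genes on one chromosome never overlap (tiled layout with positive gaps)
  by_chrom <- split(genes, genes$chrom)
  for (g in by_chrom) {
    g <- g[order(g$start), ]
    expect_true(all(head(g$end, -1) <= g$start[-1]))
  }
})

test_that("realized gene length tracks the configured log-normal at n = 5000", {
  cfg <- sim_config(n_genes = 5000, n_snps = 0, gene_length = c(meanlog = log(2e4), sdlog = 0.5))
  genes <- simulate_genome(cfg)
  len <- genes$end - genes$start
  mu <- exp(log(2e4) + 0.5^2 / 2)
  sdm <- sqrt((exp(0.5^2) - 1) * exp(2 * log(2e4) + 0.5^2)) / sqrt(5000)
  expect_lt(abs(mean(len) - mu), 3 * sdm)
})

test_that("intragenic placement hits its target: closed loop at 0 and 1, 3 SE otherwise", {
  genes <- simulate_genome(small_cfg())

  all_in <- simulate_associations(small_cfg(frac_intragenic = 1), genes)
  a1 <- assign_candidates(
    tibble::tibble(rsid = all_in$truth$rsid, chrom = all_in$truth$chrom,
                   pos = all_in$truth$pos, trait = all_in$truth$trait),
    genes)
  expect_true(all(all_in$truth$rsid %in% a1$rsid[a1$intragenic]))

  none_in <- simulate_associations(small_cfg(frac_intragenic = 0), genes)
  a0 <- assign_candidates(
    tibble::tibble(rsid = none_in$truth$rsid, chrom = none_in$truth$chrom,
                   pos = none_in$truth$pos, trait = none_in$truth$trait),
    genes)
  expect_equal(sum(a0$intragenic), 0)

  cfg <- sim_config(seed = 9, n_genes = 2000, n_snps = 2000, frac_intragenic = 0.4)
  g2 <- simulate_genome(cfg)
  mid <- simulate_associations(cfg, g2)
  expect_lt(abs(mean(mid$truth$intragenic) - 0.4),
            3 * sqrt(0.4 * 0.6 / 2000))
})

test_that("noiseless orthology recovers truth exactly; impossible thresholds call nothing", {
  cfg <- small_cfg(algo_tpr = 1, algo_fpr = 0)
  genes <- simulate_genome(cfg)
  orth <- simulate_orthology(cfg, genes)
  pairs <- integrate_predictions(orth$predictions)
  calls <- call_conserved(pairs, 2, universe = genes$gene_id)
  merged <- dplyr::left_join(orth$truth, calls,
                             by = c(human_gene = "human_gene"))
  expect_equal(merged$conserved, merged$truly_conserved)
  none <- call_conserved(pairs, cfg$n_algorithms + 1)
  expect_equal(sum(none$conserved), 0)
})

test_that("zero expression probability yields almost no expression calls (tail mass < 1%)", {
  cfg <- small_cfg(p_expressed = list(
    candidate = c(head = 0, whole = 0, gut = 0),
    background = c(head = 0, whole = 0, gut = 0)
  ))
  genes <- simulate_genome(cfg)
  orth <- simulate_orthology(cfg, genes)
  expr <- simulate_expression(cfg, orth$truth)
  tab <- read_rpkm_report(paste(
    c("FBgn#\tRNASource_name\tRPKM_value",
      paste(expr$report$`FBgn#`, expr$report$RNASource_name,
            expr$report$RPKM_value, sep = "\t")), collapse = "\n"))
  frac_called <- mean(tab$rpkm >= 2)
  expect_lt(frac_called, 0.01)
})

test_that("null lethality plant gives fold ~ 1 and planted rates are recovered", {
  cfg <- sim_config(seed = 17, n_genes = 2000, n_snps = 600,
                    p_lethal = c(candidate = 0.25, background = 0.25))
  genes <- simulate_genome(cfg)
  assoc <- simulate_associations(cfg, genes)
  cand <- unique(assoc$truth$placed_gene[!is.na(assoc$truth$placed_gene)])
  orth <- simulate_orthology(cfg, genes, cand)
  phen <- simulate_phenotypes(cfg, orth$truth)
  is_cand <- orth$truth$candidate
  rate_cand <- mean(phen$truth$lethal[is_cand])
  rate_all <- mean(phen$truth$lethal)
  se <- sqrt(0.25 * 0.75 / sum(is_cand))
  expect_lt(abs(rate_cand - rate_all), 3 * se)
})
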