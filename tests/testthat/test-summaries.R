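fake_calls <- function(conserved_ids, others = character()) {
  ids <- c(conserved_ids, others)
  tibble::tibble(
    human_gene = ids,
    conserved = ids %in% conserved_ids,
    n_pairs = 1L, max_score = ifelse(ids %in% conserved_ids, 3L, 1L),
    best_fly_genes = as.list(paste0("fly_", ids))
  )
}

test_that("genome baseline is the conserved fraction of the universe", {
  calls <- fake_calls(c("g1", "g2"), "g3")
  expect_equal(genome_baseline(calls, c("g1", "g2", "g3")), 2 / 3)
  expect_equal(genome_baseline(calls, c("g1", "g2")), 1)
  expect_equal(genome_baseline(calls, c("x1", "x2")), 0)
  expect_error(genome_baseline(calls, character()), "non-empty")
  # planted fraction recovered exactly under a deterministic plant
  universe <- sprintf("u%05d", 1:20950)
  planted <- universe[1:11122]
  expect_equal(genome_baseline(fake_calls(planted), universe), 11122 / 20950)
})

test_that("conservation summaries compute fractions and folds exactly", {
  genes <- sprintf("g%02d", 1:10)
  calls <- fake_calls(genes[1:6], genes[7:10])
  gs <- tibble::tibble(group = "all", gene_id = genes)
  s <- conservation_summary(gs, calls, baseline = 0.5)
  expect_equal(s$n_candidates, 10L)
  expect_equal(s$n_conserved, 6L)
  expect_equal(s$fraction, 0.6)
  expect_equal(s$fold_enrichment, 1.2)

  s2 <- conservation_summary(gs, calls, baseline = 0.6)
  expect_equal(s2$fold_enrichment, 1)   # fraction equals baseline

  # zero-candidate group flagged undefined, not zero; sorted by fraction
  gs3 <- tibble::tibble(group = c(rep("a", 4), rep("b", 2)),
                        gene_id = c(genes[1:4], genes[7:8]))
  s3 <- conservation_summary(gs3, calls, baseline = 0.5, universe = genes)
  expect_equal(s3$group, c("a", "b"))
  expect_equal(s3$fraction, c(1, 0))
  expect_true(all(s3$p_value > 0 & s3$p_value <= 1))
})

test_that("the exact enrichment test matches hypergeometric enumeration", {
  expect_equal(enrichment_test(5, 10, 50, 100), 1.0)       # identical proportions
  expect_equal(enrichment_test(9, 10, 1, 10),
               fisher_enum(9, 1, 1, 9), tolerance = 1e-10)
  # symmetry under transposing the 2x2 table
  expect_equal(enrichment_test(7, 12, 3, 9),
               enrichment_test(7, 10, 5, 11), tolerance = 1e-12)
  expect_equal(enrichment_test(0, 0, 5, 10), 1)            # zero margin
  expect_equal(enrichment_test(0, 5, 0, 10), 1)            # zero conserved column
})

test_that("expression summaries aggregate profiles with reference rows", {
  profiles <- tibble::tibble(
    human_gene = rep(c("h1", "h2", "h3"), each = 2),
    fly_genes = rep(c("f1", "f2", "f3"), each = 2),
    tissue = rep(c("head", "gut"), 3),
    expressed = c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE),
    neuronal = FALSE, lethal = FALSE, annotated = FALSE
  )
  gs <- tibble::tibble(group = c("nervous system", "nervous system", "eye"),
                       gene_id = c("h1", "h2", "h3"))
  s <- expression_profile_summary(gs, profiles, c("head", "gut"))
  ns_head <- s[s$group == "nervous system" & s$tissue == "head", ]
  expect_equal(ns_head$fraction, 1)
  ns_gut <- s[s$group == "nervous system" & s$tissue == "gut", ]
  expect_equal(ns_gut$fraction, 0.5)
  allc <- s[s$group == "all GWAS candidates" & s$tissue == "head", ]
  expect_equal(allc$n, 3)

  # empty category yields an undefined row, and the all-fly-genes reference
  # row is computed from the expression table directly
  gs2 <- dplyr::bind_rows(gs, tibble::tibble(group = "skin", gene_id = "h9"))
  expr <- tibble::tibble(fly_gene = c("f1", "f2"), tissue = "head", rpkm = c(5, 0))
  s2 <- expression_profile_summary(gs2, profiles, "head",
                                   expression = expr, fly_universe = c("f1", "f2"))
  expect_true(is.na(s2$fraction[s2$group == "skin"]))
  expect_equal(s2$fraction[s2$group == "all fly genes"], 0.5)
})

test_that("phenotype summaries report lethal/neuronal/annotated fractions", {
  profiles <- tibble::tibble(
    human_gene = c("h1", "h2", "h3", "h4"),
    fly_genes = c("f1", "f2", "f3", "f4"),
    tissue = "head", expressed = TRUE,
    neuronal = c(TRUE, FALSE, FALSE, FALSE),
    lethal = c(TRUE, TRUE, FALSE, FALSE),
    annotated = c(TRUE, TRUE, TRUE, FALSE)
  )
  gs <- tibble::tibble(group = "neurodegenerative", gene_id = c("h1", "h2", "h3", "h4"))
  s <- phenotype_summary(gs, profiles)
  nd <- s[s$group == "neurodegenerative", ]
  expect_equal(nd$frac_lethal, 0.5)
  expect_equal(nd$frac_neuronal, 0.25)
  expect_equal(nd$frac_annotated, 0.75)
  expect_true(all(s$frac_annotated >= s$frac_lethal, na.rm = TRUE))

  # with no phenotype annotations at all, every fraction is zero
  prof0 <- dplyr::mutate(profiles, neuronal = FALSE, lethal = FALSE, annotated = FALSE)
  s0 <- phenotype_summary(gs, prof0)
  expect_true(all(s0$frac_lethal == 0 & s0$frac_neuronal == 0 & s0$frac_annotated == 0))
})

test_that("reports are deterministic, lossless, and mark undefined values", {
  s <- tibble::tibble(group = c("a", "b"), n_candidates = c(3L, 0L),
                      fraction = c(0.5, NA))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- write_report(list(conservation = s), d1, manifest = list(seed = 1))
  f2 <- write_report(list(conservation = s), d2, manifest = list(seed = 1))
  expect_identical(readLines(file.path(d1, "conservation.tsv")),
                   readLines(file.path(d2, "conservation.tsv")))
  expect_identical(readLines(file.path(d1, "run_manifest.json")),
                   readLines(file.path(d2, "run_manifest.json")))
  # undefined fraction emitted as sentinel string, not 0
  raw <- readLines(file.path(d1, "conservation.tsv"))
  expect_true(any(grepl("\tND$", raw)))
  # round-trip is lossless for counts and defined values
  back <- readr::read_tsv(file.path(d1, "conservation.tsv"),
                          na = "ND", show_col_types = FALSE)
  expect_equal(back$n_candidates, s$n_candidates)
  expect_equal(back$fraction, s$fraction)
  # empty summaries produce a header-only TSV
  write_report(list(empty = s[0, ]), d1)
  expect_equal(length(readLines(file.path(d1, "empty.tsv"))), 1)
})

test_that("supplementary-style per-gene tables aggregate deterministically", {
  s2 <- summarize_supplementary_candidates(c(
    "rsid\ttrait\tgene_id\ttiers\tconserved",
    "rs1\tA\tg1\tintragenic,nearest_neighbor,within_250kb,within_500kb\tTRUE",
    "rs2\tA\tg1\tintragenic,nearest_neighbor,within_250kb,within_500kb\tTRUE",
    "rs1\tA\tg2\twithin_500kb\tFALSE",
    "rs3\tB\tg3\tnearest_neighbor,within_500kb\tTRUE"
  ))
  intr <- s2[s2$tier == "intragenic", ]
  expect_equal(intr$n_candidates, 1L)   # g1 counted once despite two SNPs
  expect_equal(intr$n_conserved, 1L)
  w500 <- s2[s2$tier == "within_500kb", ]
  expect_equal(w500$n_candidates, 3L)
  expect_equal(w500$fraction, 2 / 3)

  s3 <- summarize_supplementary_expression(c(
    "gene_id\tcategory\ttissue\texpressed",
    "g1\tnervous system\thead\tTRUE",
    "g2\tnervous system\thead\tFALSE",
    "g1\tnervous system\tgut\tTRUE"
  ))
  expect_equal(s3$fraction[s3$tissue == "head"], 0.5)
  expect_equal(s3$fraction[s3$tissue == "gut"], 1)

  s4 <- summarize_supplementary_lethality(c(
    "gene_id\tcategory\tlethal",
    "g1\tall GWAS candidates\t1",
    "g2\tall GWAS candidates\t0",
    "g3\tall fly genes\t0"
  ))
  expect_equal(s4$fraction[s4$category == "all GWAS candidates"], 0.5)
  expect_equal(s4$fraction[s4$category == "all fly genes"], 0)
})
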