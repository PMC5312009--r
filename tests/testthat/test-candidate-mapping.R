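test_that("the chr6 CD2AP locus reproduces the published worked example", {
  genes <- cd2ap_fixture()
  snp <- cd2ap_snp()

  expect_equal(map_intragenic(snp, genes)$symbol, "CD2AP")
  expect_setequal(map_nearest_neighbors(snp, genes)$symbol,
                  c("CD2AP", "TNFRSF21", "ADGRF2"))
  # the 500 kb tier adds ADGRF4; the SNP +/- 250 kb interval holds all four
  w500 <- map_window(snp, genes, 250000)$symbol
  expect_setequal(w500, c("CD2AP", "TNFRSF21", "ADGRF2", "ADGRF4"))
  expect_false("ADGRF4" %in% map_window(snp, genes, 125000)$symbol)
  expect_setequal(
    genes_overlapping(genes, "6", snp$pos - 250000, snp$pos + 250000)$symbol,
    c("CD2AP", "TNFRSF21", "ADGRF2", "ADGRF4")
  )

  a <- assign_candidates(snp, genes)
  expect_equal(nrow(a), 4)
  cd2ap <- a[a$symbol == "CD2AP", ]
  expect_true(all(unlist(cd2ap[, c("intragenic", "nearest_neighbor",
                                   "within_250kb", "within_500kb")])))
  expect_equal(cd2ap$distance, 0L)
  adgrf4 <- a[a$symbol == "ADGRF4", ]
  expect_false(any(unlist(adgrf4[, c("intragenic", "nearest_neighbor", "within_250kb")])))
  expect_true(adgrf4$within_500kb)
  # sign convention: upstream gene negative, downstream positive
  expect_lt(a$distance[a$symbol == "TNFRSF21"], 0)
  expect_gt(a$distance[a$symbol == "ADGRF2"], 0)
})

test_that("intragenic containment is half-open at the gene end", {
  g <- validate_annotation(tibble::tibble(
    gene_id = "G1", chrom = "1", start = 100, end = 200
  ))
  at_end <- tibble::tibble(rsid = "r", chrom = "1", pos = 200L, trait = "t")
  at_start <- tibble::tibble(rsid = "r", chrom = "1", pos = 100L, trait = "t")
  expect_equal(nrow(map_intragenic(at_end, g)), 0)
  expect_equal(map_intragenic(at_start, g)$gene_id, "G1")
})

test_that("degenerate placements behave: gene desert, gene-free chromosome", {
  genes <- random_annotation(50, seed = 5)
  nowhere <- tibble::tibble(rsid = "r", chrom = "17", pos = 1000L, trait = "t")
  expect_equal(nrow(map_nearest_neighbors(nowhere, genes)), 0)
  expect_equal(nrow(map_window(nowhere, genes, 250000)), 0)
  expect_equal(nrow(assign_candidates(nowhere, genes)), 0)
})

test_that("primitive maps and tier sets agree with brute-force scans per SNP", {
  genes <- random_annotation(300, seed = 21)
  set.seed(22)
  snps <- tibble::tibble(
    rsid = sprintf("rs%03d", 1:300),
    chrom = as.character(sample.int(3, 300, TRUE)),
    pos = sample.int(1.2e6, 300, TRUE) - 1L,
    trait = sample(c("t1", "t2", "t3"), 300, TRUE)
  )
  a <- assign_candidates(snps, genes, halfwidths = c(50000, 100000))
  truth <- true_tier_memberships(genes, snps, halfwidths = c(50000, 100000))
  key <- function(d) paste(d$rsid, d$gene_id)
  a_sorted <- a[order(key(a)), ]
  t_sorted <- truth[order(key(truth)), ]
  expect_equal(key(a_sorted), key(t_sorted))
  for (col in c("intragenic", "nearest_neighbor", "within_250kb", "within_500kb")) {
    expect_equal(a_sorted[[col]], t_sorted[[col]], info = col)
  }
})

test_that("per-SNP tier nesting holds and aggregate counts are non-decreasing", {
  genes <- random_annotation(250, seed = 31)
  set.seed(32)
  snps <- tibble::tibble(
    rsid = sprintf("rs%03d", 1:500),
    chrom = as.character(sample.int(3, 500, TRUE)),
    pos = sample.int(1.2e6, 500, TRUE) - 1L,
    trait = "t"
  )
  a <- assign_candidates(snps, genes)
  # INTRAGENIC subset of NEAREST_NEIGHBOR and of both windows, per (SNP, gene)
  expect_true(all(!a$intragenic | a$nearest_neighbor))
  expect_true(all(!a$intragenic | a$within_250kb))
  expect_true(all(!a$within_250kb | a$within_500kb))
  n_at <- function(tier) nrow(candidate_gene_sets(a, tier))
  expect_lte(n_at("intragenic"), n_at("within_250kb"))
  expect_lte(n_at("within_250kb"), n_at("within_500kb"))
})

test_that("candidate gene sets deduplicate within groups and respect mappings", {
  genes <- validate_annotation(tibble::tibble(
    gene_id = c("G1", "G2"), chrom = "1", start = c(0, 10000), end = c(5000, 15000)
  ))
  snps <- tibble::tibble(
    rsid = c("r1", "r2", "r3"),
    chrom = "1", pos = c(100L, 200L, 10100L),
    trait = c("Asthma", "Asthma", "Eczema")
  )
  a <- assign_candidates(snps, genes)
  all_set <- candidate_gene_sets(a, "intragenic")
  expect_equal(nrow(all_set), 2)        # G1 nominated twice counts once
  by_trait <- candidate_gene_sets(a, "intragenic", group_by = "trait")
  expect_equal(by_trait$gene_id[by_trait$group == "Asthma"], "G1")
  mapped <- candidate_gene_sets(a, "intragenic",
                                group_by = tibble::tibble(
                                  trait = "Asthma", group = "pulmonary"))
  expect_equal(unique(mapped$group), "pulmonary")   # unmapped Eczema dropped
  expect_equal(nrow(candidate_gene_sets(a[0, ], "intragenic")), 0)
})

test_that("assignment export schema round-trips tiers and distances", {
  genes <- cd2ap_fixture()
  a <- assign_candidates(cd2ap_snp(), genes)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_assignments(a, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(a))
  expect_true(grepl("intragenic", back$tiers[back$gene_id == a$gene_id[a$symbol == "CD2AP"]]))
  expect_equal(sort(back$distance), sort(a$distance))
})
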