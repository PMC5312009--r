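#' Default trait table for simulations
#'
#' A synthetic stand-in for a curated trait-to-category table: a fixed set of
#' trait labels, each assigned a target-tissue category and a
#' disease-mechanism category. Category labels follow the two classification
#' schemes used for GWAS trait curation (target tissue; disease mechanism).
#'
#' @param n_per_tissue Number of synthetic traits per tissue category.
#' @return Tibble with columns `trait`, `tissue_category`,
#'   `mechanism_category`.
#' @export
default_trait_table <- function(n_per_tissue = 5) {
  tissues <- c("nervous system", "cardiovascular", "pulmonary", "eye", "blood",
               "urogenital", "skin", "gastrointestinal", "endocrine",
               "musculoskeletal")
  mechanisms <- c("neurodegenerative", "vascular", "inflammatory",
                  "developmental", "metabolic", "neoplastic", "psychiatric",
                  "autoimmune")
  grid <- tidyr::expand_grid(tissue_category = tissues, i = seq_len(n_per_tissue))
  tibble(
    trait = sprintf("%s trait %d", grid$tissue_category, grid$i),
    tissue_category = grid$tissue_category,
    mechanism_category = mechanisms[((seq_len(nrow(grid)) - 1) %% length(mechanisms)) + 1]
  )
}

#' Simulation configuration
#'
#' Defines the study conditions the generator emulates: a gene-dense genome,
#' index SNPs with a controlled intragenic fraction, a planted genome-wide
#' conservation rate with a multiplicative lift for intragenic candidate
#' genes, a per-algorithm ortholog-vote model, tissue expression rates with
#' RPKM magnitudes, and phenotype-annotation rates. Defaults mirror the
#' published study's headline structure: genome-wide conservation 0.53 with
#' a 1.2-fold candidate lift; homologs of candidates expressed at 0.77
#' (head) / 0.72 (whole fly) / 0.69 (gut); lethality 0.43 for candidate
#' homologs vs 0.25 genome-wide; neuronal phenotypes 0.33 vs 0.25.
#'
#' @param seed Master seed; each sub-generator derives its own stream so,
#'   e.g., adding SNPs does not perturb the genome draw.
#' @param n_chromosomes,n_genes,gene_length,intergenic_gap Genome geometry;
#'   lengths and gaps are log-normal (`meanlog`, `sdlog`, in bp).
#' @param n_snps,frac_intragenic Number of index SNPs and the probability a
#'   SNP is placed inside a random gene (otherwise uniformly in intergenic
#'   space).
#' @param traits Trait table (see [default_trait_table()]).
#' @param p_conserved_bg Planted genome-wide conserved fraction.
#' @param conserved_lift Multiplicative conservation lift for intragenic
#'   candidate genes; non-candidates are drawn at the complementary rate so
#'   the genome-wide mean stays at `p_conserved_bg`.
#' @param n_algorithms,algo_tpr,algo_fpr,n_decoys Ortholog-vote model: each
#'   of `n_algorithms` votes for the true pair of a conserved gene with
#'   probability `algo_tpr` and for each of `n_decoys` spurious pairs with
#'   probability `algo_fpr`.
#' @param tissues Tissue labels for the expression table.
#' @param p_expressed Named list with elements `candidate` and `background`,
#'   each a named vector of per-tissue expression probabilities.
#' @param rpkm_expressed,rpkm_unexpressed Log-normal RPKM magnitudes for
#'   expressed cells (mass above 2) and unexpressed cells (mass below 2).
#' @param p_lethal,p_neuronal,p_other_annotation Named vectors
#'   (`candidate`, `background`) of phenotype-annotation rates.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_chromosomes = 5,
                       n_genes = 15000,
                       gene_length = c(meanlog = log(3e4), sdlog = 0.8),
                       intergenic_gap = c(meanlog = log(1e5), sdlog = 1.0),
                       n_snps = 3000,
                       frac_intragenic = 0.4,
                       traits = default_trait_table(),
                       p_conserved_bg = 0.53,
                       conserved_lift = 1.2,
                       n_algorithms = 10,
                       algo_tpr = 0.95,
                       algo_fpr = 0.005,
                       n_decoys = 2,
                       tissues = c("head", "whole", "gut"),
                       p_expressed = list(
                         candidate = c(head = 0.77, whole = 0.72, gut = 0.69),
                         background = c(head = 0.55, whole = 0.60, gut = 0.50)
                       ),
                       rpkm_expressed = c(meanlog = log(15), sdlog = 0.8),
                       rpkm_unexpressed = c(meanlog = log(0.2), sdlog = 0.8),
                       p_lethal = c(candidate = 0.43, background = 0.25),
                       p_neuronal = c(candidate = 0.33, background = 0.25),
                       p_other_annotation = c(candidate = 0.11, background = 0.11)) {
  cfg <- list(
    seed = as.integer(seed), n_chromosomes = n_chromosomes, n_genes = n_genes,
    gene_length = gene_length, intergenic_gap = intergenic_gap,
    n_snps = n_snps, frac_intragenic = frac_intragenic, traits = traits,
    p_conserved_bg = p_conserved_bg, conserved_lift = conserved_lift,
    n_algorithms = n_algorithms, algo_tpr = algo_tpr, algo_fpr = algo_fpr,
    n_decoys = n_decoys, tissues = tissues, p_expressed = p_expressed,
    rpkm_expressed = rpkm_expressed, rpkm_unexpressed = rpkm_unexpressed,
    p_lethal = p_lethal, p_neuronal = p_neuronal,
    p_other_annotation = p_other_annotation
  )
  probs <- c(frac_intragenic, p_conserved_bg, algo_tpr, algo_fpr,
             unlist(p_expressed), p_lethal, p_neuronal, p_other_annotation)
  stopifnot(
    all(probs >= 0 & probs <= 1),
    p_conserved_bg * conserved_lift <= 1,
    conserved_lift >= 0,
    n_genes >= 0, n_snps >= 0, n_chromosomes >= 1,
    n_algorithms >= 1, n_decoys >= 0,
    all(tissues %in% names(p_expressed$candidate)),
    all(tissues %in% names(p_expressed$background))
  )
  structure(cfg, class = "sim_config")
}

# independent stream per sub-generator, derived from the master seed
sub_seed <- function(seed, k) {
  as.integer((as.double(seed) + k * 1048573) %% 2147483647)
}

# Background-class rate that keeps the genome-wide mean at the planted value
# when a fraction w of genes is drawn at the lifted candidate rate: published
# genome-wide reference figures (53% conserved, 25% lethal, the all-fly-genes
# expression rows) include the enriched candidate genes, so the non-candidate
# rate must sit below them.
complement_rate <- function(p_genomewide, p_candidate, w) {
  if (w >= 1) return(p_candidate)
  p <- (p_genomewide - w * p_candidate) / (1 - w)
  if (p < 0 || p > 1) {
    abort("candidate rate incompatible with the planted genome-wide rate at this candidate fraction")
  }
  p
}

#' Simulate a gene annotation
#'
#' Genes are laid end-to-start along each chromosome with log-normal lengths
#' and intergenic gaps; deterministic under the config seed.
#'
#' @param config A [sim_config()].
#' @return Annotation tibble (see [read_gene_annotations()]).
#' @export
simulate_genome <- function(config) {
  set.seed(sub_seed(config$seed, 1))
  n <- config$n_genes
  if (n == 0) return(validate_annotation(tibble(
    gene_id = character(), chrom = character(), start = integer(), end = integer()
  )))
  chrom <- as.character(rep_len(seq_len(config$n_chromosomes), n))
  chrom <- chrom[order(as.integer(chrom))]
  len <- pmax(200, round(rlnorm(n, config$gene_length[["meanlog"]],
                                config$gene_length[["sdlog"]])))
  gap <- pmax(1, round(rlnorm(n, config$intergenic_gap[["meanlog"]],
                              config$intergenic_gap[["sdlog"]])))
  if (any(gap < 0)) abort("impossible geometry: negative intergenic gap")
  start <- integer(n)
  end <- integer(n)
  offset <- 0L
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    s <- cumsum(gap[idx]) + c(0, cumsum(len[idx]))[seq_along(idx)]
    start[idx] <- as.integer(s)
    end[idx] <- as.integer(s + len[idx])
  }
  validate_annotation(tibble(
    gene_id = sprintf("HSG%05d", seq_len(n)),
    symbol = sprintf("HSG%05d", seq_len(n)),
    chrom = chrom,
    start = start,
    end = end,
    strand = sample(c("+", "-"), n, replace = TRUE),
    biotype = "protein_coding"
  ))
}

#' Simulate GWAS-catalog associations over an annotation
#'
#' Each SNP is placed inside a uniformly chosen gene with probability
#' `frac_intragenic`, otherwise uniformly in intergenic space (gaps sampled
#' proportional to width). Traits are assigned uniformly from the config
#' trait table. The emitted table uses the GWAS-catalog dialect (1-based
#' positions).
#'
#' @param config A [sim_config()].
#' @param genes Annotation tibble (must be non-empty when
#'   `frac_intragenic > 0` or SNPs are requested).
#' @return List with `catalog` (catalog-dialect tibble ready to serialize),
#'   `truth` (tibble `rsid`, `chrom`, `pos`, `intragenic`, `placed_gene`).
#' @export
simulate_associations <- function(config, genes) {
  set.seed(sub_seed(config$seed, 2))
  n <- config$n_snps
  if (n > 0 && nrow(genes) == 0) abort("cannot place SNPs on an empty annotation")
  intragenic <- runif(n) < config$frac_intragenic
  chrom <- character(n)
  pos <- integer(n)
  placed <- rep(NA_character_, n)
  n_in <- sum(intragenic)
  if (n_in > 0) {
    gi <- sample.int(nrow(genes), n_in, replace = TRUE)
    chrom[intragenic] <- genes$chrom[gi]
    pos[intragenic] <- genes$start[gi] +
      floor(runif(n_in) * (genes$end[gi] - genes$start[gi]))
    placed[intragenic] <- genes$gene_id[gi]
  }
  n_out <- sum(!intragenic)
  if (n_out > 0) {
    gaps <- intergenic_gaps(genes)
    if (nrow(gaps) == 0) abort("no intergenic space available")
    gj <- sample.int(nrow(gaps), n_out, replace = TRUE, prob = gaps$width)
    chrom[!intragenic] <- gaps$chrom[gj]
    pos[!intragenic] <- gaps$start[gj] + floor(runif(n_out) * gaps$width[gj])
  }
  trait <- sample(config$traits$trait, n, replace = TRUE)
  rsid <- sprintf("rs%06d", seq_len(n))
  catalog <- tibble(
    SNPS = rsid, CHR_ID = chrom, CHR_POS = as.character(pos + 1L),
    `DISEASE/TRAIT` = trait, PUBMEDID = "00000000", `P-VALUE` = "5e-8"
  )
  truth <- tibble(rsid = rsid, chrom = chrom, pos = as.integer(pos),
                  trait = trait, intragenic = intragenic, placed_gene = placed)
  list(catalog = catalog, truth = truth)
}

# gaps between consecutive genes per chromosome (plus the leading gap),
# 0-based half-open
intergenic_gaps <- function(genes) {
  genes %>%
    group_by(.data$chrom) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    dplyr::reframe(
      gap_start = c(0L, head(.data$end, -1)),
      gap_end = .data$start
    ) %>%
    rename(start = "gap_start", end = "gap_end") %>%
    mutate(width = .data$end - .data$start) %>%
    filter(.data$width > 0)
}

#' Reference tier memberships by exhaustive scan
#'
#' Ground-truth candidate memberships for each SNP under the four criteria,
#' computed with plain linear scans (no interval index) so they can serve as
#' an independent reference for [assign_candidates()].
#'
#' @param genes Annotation tibble.
#' @param snps Tibble with `rsid`, `chrom`, `pos`.
#' @param halfwidths Window half-widths (defaults 125 kb / 250 kb).
#' @return Tibble `rsid`, `gene_id`, logical tier columns.
#' @export
true_tier_memberships <- function(genes, snps, halfwidths = c(125000, 250000)) {
  out <- vector("list", nrow(snps))
  for (i in seq_len(nrow(snps))) {
    g <- genes[genes$chrom == normalize_chrom(snps$chrom[i]), ]
    p <- snps$pos[i]
    intra <- g$start <= p & g$end > p
    w250 <- g$start < p + halfwidths[1] + 1 & g$end > max(0, p - halfwidths[1])
    w500 <- g$start < p + halfwidths[2] + 1 & g$end > max(0, p - halfwidths[2])
    up_ok <- g$end <= p
    up <- logical(nrow(g))
    if (any(up_ok)) {
      cand <- which(up_ok & g$end == max(g$end[up_ok]))
      up[cand[order(g$gene_id[cand])][1]] <- TRUE
    }
    down_ok <- g$start > p
    down <- logical(nrow(g))
    if (any(down_ok)) {
      cand <- which(down_ok & g$start == min(g$start[down_ok]))
      down[cand[order(g$gene_id[cand])][1]] <- TRUE
    }
    nn <- intra | up | down
    keep <- intra | nn | w250 | w500
    if (!any(keep)) next
    out[[i]] <- tibble(
      rsid = snps$rsid[i], gene_id = g$gene_id[keep],
      intragenic = intra[keep], nearest_neighbor = nn[keep],
      within_250kb = w250[keep], within_500kb = w500[keep]
    )
  }
  bind_rows(out)
}

#' Simulate ortholog predictions with planted conservation
#'
#' Each human gene gets one designated fly partner. Intragenic-candidate
#' genes are truly conserved with probability `p_conserved_bg *
#' conserved_lift`; the remaining genes at the complementary rate, so the
#' genome-wide conserved fraction is planted at `p_conserved_bg` (the
#' published 53% genome-wide figure includes the enriched candidate genes,
#' so background genes must sit below it). Each algorithm votes for a
#' conserved gene's true pair with probability `algo_tpr`; each gene also
#' carries `n_decoys` spurious fly partners voted with probability
#' `algo_fpr` per algorithm.
#'
#' @param config A [sim_config()].
#' @param genes Annotation tibble (human gene universe).
#' @param candidate_ids Character vector of intragenic-candidate gene ids.
#' @return List with `predictions` (tibble `human_gene`, `fly_gene`,
#'   `algorithm`), `truth` (tibble `human_gene`, `fly_partner`,
#'   `truly_conserved`, `candidate`), and `fly_universe` (character vector).
#' @export
simulate_orthology <- function(config, genes, candidate_ids = character()) {
  set.seed(sub_seed(config$seed, 3))
  n <- nrow(genes)
  fly <- sprintf("FBgnS%05d", seq_len(n))
  is_cand <- genes$gene_id %in% candidate_ids
  w <- mean(is_cand)
  p_cand <- min(1, config$p_conserved_bg * config$conserved_lift)
  p_bg <- complement_rate(config$p_conserved_bg, p_cand, w)
  truly <- runif(n) < ifelse(is_cand, p_cand, p_bg)
  algs <- sprintf("alg%02d", seq_len(config$n_algorithms))

  pred <- list()
  # true-pair votes
  ci <- which(truly)
  if (length(ci) > 0) {
    votes <- matrix(runif(length(ci) * config$n_algorithms) < config$algo_tpr,
                    nrow = length(ci))
    hit <- which(votes, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      pred$true <- tibble(
        human_gene = genes$gene_id[ci[hit[, 1]]],
        fly_gene = fly[ci[hit[, 1]]],
        algorithm = algs[hit[, 2]]
      )
    }
  }
  # decoy votes
  if (config$n_decoys > 0 && n > 1) {
    offs <- matrix(sample.int(n - 1, n * config$n_decoys, replace = TRUE), nrow = n)
    decoy_idx <- ((seq_len(n) - 1 + offs) %% n) + 1
    hg <- rep(seq_len(n), config$n_decoys)
    fg <- as.vector(decoy_idx)
    votes <- matrix(runif(n * config$n_decoys * config$n_algorithms) < config$algo_fpr,
                    nrow = n * config$n_decoys)
    hit <- which(votes, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      pred$decoy <- tibble(
        human_gene = genes$gene_id[hg[hit[, 1]]],
        fly_gene = fly[fg[hit[, 1]]],
        algorithm = algs[hit[, 2]]
      )
    }
  }
  predictions <- if (length(pred) > 0) {
    arrange(bind_rows(pred), .data$human_gene, .data$fly_gene, .data$algorithm)
  } else {
    tibble(human_gene = character(), fly_gene = character(), algorithm = character())
  }
  truth <- tibble(human_gene = genes$gene_id, fly_partner = fly,
                  truly_conserved = truly, candidate = is_cand)
  list(predictions = predictions, truth = truth, fly_universe = fly)
}

#' Simulate a gene-by-tissue RPKM report
#'
#' Fly genes paired with candidate human genes draw expression flags at the
#' candidate rates, all other fly genes at the background rates; expressed
#' cells draw RPKM from `rpkm_expressed` (mass above 2) and unexpressed
#' cells from `rpkm_unexpressed` (mass below 2).
#'
#' @param config A [sim_config()].
#' @param ortholog_truth Truth tibble from [simulate_orthology()].
#' @return List with `report` (rpkm-report-dialect tibble) and `truth`
#'   (tibble `fly_gene`, `tissue`, `expressed`).
#' @export
simulate_expression <- function(config, ortholog_truth) {
  set.seed(sub_seed(config$seed, 4))
  fly <- ortholog_truth$fly_partner
  cls <- ifelse(ortholog_truth$candidate, "candidate", "background")
  w <- mean(cls == "candidate")
  rows <- list()
  for (ts in config$tissues) {
    p_cand <- config$p_expressed$candidate[[ts]]
    p_bg <- complement_rate(config$p_expressed$background[[ts]], p_cand, w)
    p <- ifelse(cls == "candidate", p_cand, p_bg)
    expressed <- runif(length(fly)) < p
    rpkm <- ifelse(
      expressed,
      rlnorm(length(fly), config$rpkm_expressed[["meanlog"]],
             config$rpkm_expressed[["sdlog"]]),
      rlnorm(length(fly), config$rpkm_unexpressed[["meanlog"]],
             config$rpkm_unexpressed[["sdlog"]])
    )
    rows[[ts]] <- tibble(fly_gene = fly, tissue = ts,
                         rpkm = round(rpkm, 4), expressed = expressed)
  }
  long <- bind_rows(rows)
  report <- tibble(
    `FBgn#` = long$fly_gene,
    RNASource_name = long$tissue,
    RPKM_value = format(long$rpkm, trim = TRUE, scientific = FALSE)
  )
  list(report = report, truth = long[, c("fly_gene", "tissue", "expressed")])
}

#' Simulate a gene-to-phenotype-term table
#'
#' Lethal, neuronal, and generic annotations are drawn per fly gene at the
#' class rates (`candidate` vs `background`); lethal genes carry the
#' configured lethal term, neuronal genes a random term from the neuronal
#' set, and "other" annotations a generic placeholder term.
#'
#' @param config A [sim_config()].
#' @param ortholog_truth Truth tibble from [simulate_orthology()].
#' @param term_config Term sets (see [default_term_config()]).
#' @return List with `phenotypes` (tibble `fly_gene`, `term_id`) and `truth`
#'   (tibble `fly_gene`, `lethal`, `neuronal`, `annotated`).
#' @export
simulate_phenotypes <- function(config, ortholog_truth,
                                term_config = default_term_config()) {
  set.seed(sub_seed(config$seed, 5))
  fly <- ortholog_truth$fly_partner
  cand <- ortholog_truth$candidate
  w <- mean(cand)
  pick <- function(p) {
    ifelse(cand, p[["candidate"]],
           complement_rate(p[["background"]], p[["candidate"]], w))
  }
  lethal <- runif(length(fly)) < pick(config$p_lethal)
  neuronal <- runif(length(fly)) < pick(config$p_neuronal)
  other <- runif(length(fly)) < pick(config$p_other_annotation)
  rows <- list(
    tibble(fly_gene = fly[lethal], term_id = term_config$lethal_terms[[1]]),
    tibble(fly_gene = fly[neuronal],
           term_id = sample(term_config$neuronal_terms, sum(neuronal), replace = TRUE)),
    tibble(fly_gene = fly[other], term_id = "FBcv:SYN-OTHER-01")
  )
  phen <- arrange(bind_rows(rows), .data$fly_gene, .data$term_id)
  truth <- tibble(fly_gene = fly, lethal = lethal, neuronal = neuronal,
                  annotated = lethal | neuronal | other)
  list(phenotypes = phen, truth = truth)
}

#' Simulate a complete study with ground truth
#'
#' Runs every sub-generator in order (genome, associations, orthology,
#' expression, phenotypes) under per-component streams derived from the
#' master seed, and optionally writes all inputs in exactly the dialects the
#' package readers consume, plus ground-truth TSVs and a config snapshot.
#' Identical config and seed give byte-identical files.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory; created if needed.
#' @param term_config Phenotype term sets.
#' @return List with elements `config`, `genes`, `catalog`, `predictions`,
#'   `expression_report`, `phenotypes`, `trait_categories`, `fly_universe`,
#'   and `truth` (list: `snps`, `orthologs`, `expression`, `phenotypes`,
#'   `candidate_ids`).
#' @export
simulate_study <- function(config = sim_config(), dir = NULL,
                           term_config = default_term_config()) {
  genes <- simulate_genome(config)
  assoc <- simulate_associations(config, genes)
  candidate_ids <- unique(assoc$truth$placed_gene[!is.na(assoc$truth$placed_gene)])
  orth <- simulate_orthology(config, genes, candidate_ids)
  expr <- simulate_expression(config, orth$truth)
  phen <- simulate_phenotypes(config, orth$truth, term_config)
  out <- list(
    config = config,
    genes = genes,
    catalog = assoc$catalog,
    predictions = orth$predictions,
    expression_report = expr$report,
    phenotypes = phen$phenotypes,
    trait_categories = config$traits,
    fly_universe = orth$fly_universe,
    truth = list(
      snps = assoc$truth,
      orthologs = orth$truth,
      expression = expr$truth,
      phenotypes = phen$truth,
      candidate_ids = candidate_ids
    )
  )
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_gff3(genes, file.path(dir, "genes.gff3"))
    readr::write_tsv(assoc$catalog, file.path(dir, "gwas_catalog.tsv"), progress = FALSE)
    readr::write_tsv(
      rename(orth$predictions, human_gene_id = "human_gene", fly_gene_id = "fly_gene"),
      file.path(dir, "ortholog_predictions.tsv"), progress = FALSE)
    readr::write_tsv(expr$report, file.path(dir, "gene_rpkm_report.tsv"), progress = FALSE)
    readr::write_tsv(rename(phen$phenotypes, fly_gene_id = "fly_gene"),
                     file.path(dir, "phenotypes.tsv"), progress = FALSE)
    readr::write_tsv(config$traits, file.path(dir, "trait_categories.tsv"), progress = FALSE)
    readr::write_tsv(assoc$truth, file.path(dir, "truth_snps.tsv"), progress = FALSE)
    readr::write_tsv(orth$truth, file.path(dir, "truth_orthologs.tsv"), progress = FALSE)
    readr::write_tsv(expr$truth, file.path(dir, "truth_expression.tsv"), progress = FALSE)
    readr::write_tsv(phen$truth, file.path(dir, "truth_phenotypes.tsv"), progress = FALSE)
    cfg <- unclass(config)
    cfg$traits <- NULL
    jsonlite::write_json(cfg, file.path(dir, "config.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}
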