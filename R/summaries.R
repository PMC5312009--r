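#' Genome-wide conservation baseline
#'
#' Fraction of a gene universe called conserved — the genome-wide reference
#' against which category-level conservation is compared (the published
#' analysis found 53%: 11,122 of 20,950 protein-coding genes).
#'
#' @param calls Conservation calls from [call_conserved()].
#' @param universe Non-empty character vector of gene ids.
#' @return Fraction in \[0, 1\].
#' @export
genome_baseline <- function(calls, universe) {
  if (length(universe) == 0) abort("gene universe must be non-empty")
  conserved <- calls$human_gene[calls$conserved]
  mean(universe %in% conserved)
}

#' Two-sided exact enrichment test on a 2x2 table
#'
#' Fisher's exact test of category vs background by conserved vs not.
#' A table with a zero margin carries no signal and returns p = 1 by
#' convention. Reported as a descriptive extension alongside the fold
#' enrichments.
#'
#' @param n_in_conserved,n_in Conserved count and total in the category.
#' @param n_bg_conserved,n_bg Conserved count and total in the background.
#' @return Two-sided exact p-value.
#' @export
enrichment_test <- function(n_in_conserved, n_in, n_bg_conserved, n_bg) {
  stopifnot(n_in_conserved >= 0, n_bg_conserved >= 0,
            n_in_conserved <= n_in, n_bg_conserved <= n_bg)
  m <- matrix(c(n_in_conserved, n_in - n_in_conserved,
                n_bg_conserved, n_bg - n_bg_conserved), nrow = 2)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) return(1)
  stats::fisher.test(m)$p.value
}

#' Conservation summary by group
#'
#' For each candidate-gene group (a trait, a trait category, or "all"),
#' counts conserved genes, computes the conserved fraction and its fold
#' enrichment over the genome baseline (`fraction / baseline`, kept at full
#' precision; round only for presentation). Groups with zero candidates are
#' retained with `NA` fraction rather than a fake 0. When `universe` is
#' supplied, Fisher exact p-values (category vs rest of universe) and
#' Benjamini-Hochberg adjusted values are added as descriptive extensions.
#'
#' @param gene_sets Tibble with columns `group`, `gene_id` from
#'   [candidate_gene_sets()].
#' @param calls Conservation calls from [call_conserved()].
#' @param baseline Genome-wide conserved fraction in (0, 1\]; computed from
#'   `universe` when omitted.
#' @param universe Optional gene universe (character vector).
#' @return A `gwasfly_conservation` tibble sorted by descending fraction,
#'   with columns `group`, `n_candidates`, `n_conserved`, `fraction`,
#'   `baseline_fraction`, `fold_enrichment`, `p_value`, `p_adjusted`.
#' @export
conservation_summary <- function(gene_sets, calls, baseline = NULL, universe = NULL) {
  if (is.null(baseline)) {
    if (is.null(universe)) abort("supply `baseline` or `universe`")
    baseline <- genome_baseline(calls, universe)
  }
  stopifnot(baseline > 0, baseline <= 1)
  conserved_ids <- calls$human_gene[calls$conserved]
  out <- gene_sets %>%
    distinct(.data$group, .data$gene_id) %>%
    group_by(.data$group) %>%
    summarise(
      n_candidates = dplyr::n(),
      n_conserved = sum(.data$gene_id %in% conserved_ids),
      .groups = "drop"
    ) %>%
    mutate(
      fraction = ifelse(.data$n_candidates > 0,
                        .data$n_conserved / .data$n_candidates, NA_real_),
      baseline_fraction = baseline,
      fold_enrichment = .data$fraction / baseline
    )
  if (!is.null(universe)) {
    n_bg <- length(universe)
    n_bg_cons <- sum(universe %in% conserved_ids)
    out$p_value <- purrr::map2_dbl(out$n_conserved, out$n_candidates, function(k, n) {
      enrichment_test(k, n, n_bg_cons - k, n_bg - n)
    })
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  } else {
    out$p_value <- NA_real_
    out$p_adjusted <- NA_real_
  }
  out <- arrange(out, dplyr::desc(.data$fraction))
  class(out) <- c("gwasfly_conservation", class(out))
  out
}

#' Expression-profile summary by category and tissue
#'
#' Per (category, tissue): the fraction of conserved-candidate homolog
#' profiles called expressed. Reference rows are added for the pooled
#' candidate set (`"all GWAS candidates"`) and, when a genome-wide
#' expression table and fly-gene universe are supplied, for `"all fly
#' genes"`.
#'
#' @param gene_sets Candidate gene sets (`group`, `gene_id`; human ids).
#' @param profiles Homolog profiles from [homolog_profile()].
#' @param tissues Tissue labels to summarize.
#' @param expression Optional expression tibble for the all-fly-genes row.
#' @param fly_universe Optional character vector of all fly gene ids.
#' @param rpkm_threshold Expression threshold for the reference row.
#' @return A `gwasfly_expression` tibble with columns `group`, `tissue`,
#'   `n`, `n_expressed`, `fraction` (`NA` for empty groups).
#' @export
expression_profile_summary <- function(gene_sets, profiles, tissues,
                                       expression = NULL, fly_universe = NULL,
                                       rpkm_threshold = 2.0) {
  groups <- split(gene_sets$gene_id, gene_sets$group)
  groups[["all GWAS candidates"]] <- unique(gene_sets$gene_id)
  rows <- purrr::imap(groups, function(ids, grp) {
    sub <- profiles[profiles$human_gene %in% ids, ]
    purrr::map(tissues, function(ts) {
      cell <- sub[sub$tissue == ts, ]
      tibble(group = grp, tissue = ts, n = nrow(cell),
             n_expressed = sum(cell$expressed),
             fraction = ifelse(nrow(cell) > 0, mean(cell$expressed), NA_real_))
    }) %>% bind_rows()
  })
  out <- bind_rows(rows)
  if (!is.null(expression) && !is.null(fly_universe)) {
    ref <- purrr::map(tissues, function(ts) {
      ex <- is_expressed(expression, fly_universe, ts, rpkm_threshold)
      tibble(group = "all fly genes", tissue = ts, n = length(fly_universe),
             n_expressed = sum(ex), fraction = mean(ex))
    }) %>% bind_rows()
    out <- bind_rows(out, ref)
  }
  class(out) <- c("gwasfly_expression", class(out))
  out
}

#' Phenotype and essentiality summary by category
#'
#' Per category: the fractions of conserved-candidate homolog profiles
#' classified lethal (essential), neuronal, and carrying any phenotype
#' annotation. When a phenotype table and fly-gene universe are supplied, a
#' reference row for all fly genes is added (classified directly on fly
#' genes).
#'
#' @param gene_sets Candidate gene sets (`group`, `gene_id`).
#' @param profiles Homolog profiles from [homolog_profile()].
#' @param phenotypes Optional phenotype tibble for the reference row.
#' @param fly_universe Optional character vector of all fly gene ids.
#' @param term_config Term sets from [default_term_config()].
#' @return A `gwasfly_phenotype` tibble with columns `group`, `n`,
#'   `frac_lethal`, `frac_neuronal`, `frac_annotated`.
#' @export
phenotype_summary <- function(gene_sets, profiles, phenotypes = NULL,
                              fly_universe = NULL,
                              term_config = default_term_config()) {
  per_gene <- distinct(profiles, .data$human_gene, .data$neuronal,
                       .data$lethal, .data$annotated)
  groups <- split(gene_sets$gene_id, gene_sets$group)
  groups[["all GWAS candidates"]] <- unique(gene_sets$gene_id)
  rows <- purrr::imap(groups, function(ids, grp) {
    sub <- per_gene[per_gene$human_gene %in% ids, ]
    tibble(
      group = grp, n = nrow(sub),
      frac_lethal = ifelse(nrow(sub) > 0, mean(sub$lethal), NA_real_),
      frac_neuronal = ifelse(nrow(sub) > 0, mean(sub$neuronal), NA_real_),
      frac_annotated = ifelse(nrow(sub) > 0, mean(sub$annotated), NA_real_)
    )
  })
  out <- bind_rows(rows)
  if (!is.null(phenotypes) && !is.null(fly_universe)) {
    out <- bind_rows(out, tibble(
      group = "all fly genes", n = length(fly_universe),
      frac_lethal = mean(classify_by_terms(phenotypes, fly_universe, term_config$lethal_terms)),
      frac_neuronal = mean(classify_by_terms(phenotypes, fly_universe, term_config$neuronal_terms)),
      frac_annotated = mean(fly_universe %in% unique(phenotypes$fly_gene))
    ))
  }
  class(out) <- c("gwasfly_phenotype", class(out))
  out
}

#' Write summary tables and a run manifest
#'
#' Writes each summary as a deterministic TSV (column order and row order as
#' in the tibble; undefined fractions are emitted as the sentinel string
#' `"ND"`, never as 0) plus a single machine-readable `run_manifest.json`
#' recording inputs, thresholds, seed and package version. Output is
#' byte-identical across runs on identical input.
#'
#' @param summaries Named list of data frames.
#' @param destination Directory (created if needed).
#' @param manifest Named list of run metadata merged into the manifest.
#' @return Character vector of files written, invisibly.
#' @export
write_report <- function(summaries, destination, manifest = list()) {
  stopifnot(is.list(summaries), !is.null(names(summaries)),
            all(names(summaries) != ""))
  ok <- dir.create(destination, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(destination)) abort(paste0("cannot create destination: ", destination))
  files <- character()
  for (nm in names(summaries)) {
    path <- file.path(destination, paste0(nm, ".tsv"))
    readr::write_tsv(as_tibble(summaries[[nm]]), path, na = "ND", progress = FALSE)
    files <- c(files, path)
  }
  man <- c(list(
    package = "gwasfly",
    version = as.character(utils::packageVersion("gwasfly")),
    tables = names(summaries)
  ), manifest)
  man_path <- file.path(destination, "run_manifest.json")
  jsonlite::write_json(man, man_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(files, man_path))
}
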