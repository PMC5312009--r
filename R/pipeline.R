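#' Run the full cross-species conservation study
#'
#' End-to-end wrapper: deduplicates associations, assigns candidate genes
#' under the four nested criteria, integrates ortholog votes, calls
#' conservation at the score threshold, and builds the category summaries
#' (conservation by tier and by trait category, tissue-expression profiles,
#' phenotype/essentiality fractions). Profiling of expression and phenotype
#' is restricted to candidates nominated by intragenic SNPs, the strictest
#' tier, which is also where conservation enrichment is strongest.
#'
#' @param associations Association tibble from [read_gwas_catalog()].
#' @param genes Annotation tibble from [read_gene_annotations()]; also the
#'   human gene universe unless `universe` is given.
#' @param predictions Per-algorithm prediction tibble (used when `pairs` is
#'   `NULL`).
#' @param pairs Pre-integrated ortholog-pair tibble (skips vote
#'   integration).
#' @param expression Expression tibble from [read_rpkm_report()], or `NULL`
#'   to skip expression profiling.
#' @param phenotypes Phenotype tibble from [read_phenotypes()], or `NULL` to
#'   skip phenotype profiling.
#' @param trait_categories Trait-category table (see
#'   [read_trait_categories()]), or `NULL` for trait-level grouping only.
#' @param term_config Phenotype term sets.
#' @param tissues Tissue labels to profile (default: all tissues present in
#'   `expression`).
#' @param universe Human gene universe (default: all annotated genes).
#' @param fly_universe Fly gene universe for the reference rows (default:
#'   all fly genes present in `expression`).
#' @param min_score Conservation vote-score threshold (default 2).
#' @param rpkm_threshold Expression-call RPKM threshold (default 2).
#' @param halfwidths Window-tier half-widths in bp.
#' @param dedupe_key Columns defining association uniqueness.
#' @return Object of class `gwasfly_study`: a list with `associations`,
#'   `assignments`, `pairs`, `calls`, `baseline`, `by_tier` (conservation
#'   per tier, pooled over traits), `by_tissue_category`,
#'   `by_mechanism_category` (conservation of intragenic candidates per
#'   category), `profiles`, `expression_summary` (by tissue category),
#'   `phenotype_summary` (by mechanism category), and `params`.
#' @export
run_conservation_study <- function(associations, genes,
                                   predictions = NULL, pairs = NULL,
                                   expression = NULL, phenotypes = NULL,
                                   trait_categories = NULL,
                                   term_config = default_term_config(),
                                   tissues = NULL,
                                   universe = NULL, fly_universe = NULL,
                                   min_score = 2, rpkm_threshold = 2.0,
                                   halfwidths = c(125000, 250000),
                                   dedupe_key = c("rsid", "trait")) {
  if (is.null(pairs)) {
    if (is.null(predictions)) abort("supply `predictions` or `pairs`")
    pairs <- integrate_predictions(predictions)
  }
  if (is.null(universe)) universe <- genes$gene_id
  associations <- dedupe_associations(associations, key = dedupe_key)
  assignments <- assign_candidates(associations, genes, halfwidths = halfwidths)
  calls <- call_conserved(pairs, min_score = min_score, universe = universe)
  baseline <- genome_baseline(calls, universe)

  by_tier <- purrr::map(TIERS, function(tier) {
    gs <- candidate_gene_sets(assignments, tier, group_by = NULL)
    s <- conservation_summary(gs, calls, baseline = baseline, universe = universe)
    s$tier <- tier
    s
  }) %>% bind_rows()
  by_tier <- by_tier[, c("tier", setdiff(names(by_tier), "tier"))]
  class(by_tier) <- c("gwasfly_conservation", class(tibble()))

  category_summary <- function(scheme) {
    if (is.null(trait_categories)) return(NULL)
    map <- tibble(trait = trait_categories$trait,
                  group = trait_categories[[paste0(scheme, "_category")]])
    gs <- candidate_gene_sets(assignments, "intragenic", group_by = map)
    conservation_summary(gs, calls, baseline = baseline, universe = universe)
  }
  by_tissue <- category_summary("tissue")
  by_mechanism <- category_summary("mechanism")

  intragenic_sets_all <- candidate_gene_sets(assignments, "intragenic", group_by = NULL)
  intragenic_ids <- unique(intragenic_sets_all$gene_id)
  calls_intragenic <- calls[calls$human_gene %in% intragenic_ids, ]

  profiles <- NULL
  expr_summary <- NULL
  phen_summary <- NULL
  if (!is.null(expression) || !is.null(phenotypes)) {
    if (is.null(tissues)) {
      tissues <- if (!is.null(expression)) sort(unique(expression$tissue)) else character()
    }
    profiles <- homolog_profile(
      calls_intragenic, NULL,
      expression = expression %||% tibble(fly_gene = character(), tissue = character(), rpkm = double()),
      phenotypes = phenotypes %||% tibble(fly_gene = character(), term_id = character()),
      term_config = term_config, tissues = tissues,
      rpkm_threshold = rpkm_threshold
    )
    tissue_sets <- if (!is.null(trait_categories)) {
      candidate_gene_sets(assignments, "intragenic",
                          group_by = tibble(trait = trait_categories$trait,
                                            group = trait_categories$tissue_category))
    } else {
      intragenic_sets_all
    }
    mech_sets <- if (!is.null(trait_categories)) {
      candidate_gene_sets(assignments, "intragenic",
                          group_by = tibble(trait = trait_categories$trait,
                                            group = trait_categories$mechanism_category))
    } else {
      intragenic_sets_all
    }
    if (!is.null(expression)) {
      if (is.null(fly_universe)) fly_universe <- sort(unique(expression$fly_gene))
      expr_summary <- expression_profile_summary(
        tissue_sets, profiles, tissues,
        expression = expression, fly_universe = fly_universe,
        rpkm_threshold = rpkm_threshold
      )
    }
    if (!is.null(phenotypes)) {
      if (is.null(fly_universe)) fly_universe <- sort(unique(phenotypes$fly_gene))
      phen_summary <- phenotype_summary(
        mech_sets, profiles, phenotypes = phenotypes,
        fly_universe = fly_universe, term_config = term_config
      )
    }
  }

  structure(list(
    associations = associations,
    assignments = assignments,
    pairs = pairs,
    calls = calls,
    baseline = baseline,
    by_tier = by_tier,
    by_tissue_category = by_tissue,
    by_mechanism_category = by_mechanism,
    profiles = profiles,
    expression_summary = expr_summary,
    phenotype_summary = phen_summary,
    params = list(min_score = min_score, rpkm_threshold = rpkm_threshold,
                  halfwidths = halfwidths, dedupe_key = dedupe_key,
                  n_universe = length(universe))
  ), class = "gwasfly_study")
}

#' @export
print.gwasfly_study <- function(x, ...) {
  intr <- x$by_tier[x$by_tier$tier == "intragenic", ]
  cat("<gwasfly_study>\n")
  cat(sprintf("  associations: %d   candidate nominations: %d\n",
              nrow(x$associations), nrow(x$assignments)))
  cat(sprintf("  genome baseline conserved: %.1f%% of %d genes\n",
              100 * x$baseline, x$params$n_universe))
  cat(sprintf("  intragenic candidates: %d (%.1f%% conserved, %.2f-fold vs baseline)\n",
              intr$n_candidates, 100 * intr$fraction, intr$fold_enrichment))
  invisible(x)
}

#' @describeIn run_conservation_study Tier-level conservation table (one row
#'   per nested criterion).
#' @param x A `gwasfly_study`.
#' @param ... Unused.
#' @method tidy gwasfly_study
#' @export
tidy.gwasfly_study <- function(x, ...) {
  as_tibble(x$by_tier)
}

#' @describeIn run_conservation_study One-row study overview.
#' @method glance gwasfly_study
#' @export
glance.gwasfly_study <- function(x, ...) {
  bt <- x$by_tier
  tier_n <- setNames(bt$n_candidates, bt$tier)
  intr <- bt[bt$tier == "intragenic", ]
  tibble(
    n_associations = nrow(x$associations),
    n_candidates_intragenic = unname(tier_n[["intragenic"]]),
    n_candidates_within_500kb = unname(tier_n[["within_500kb"]]),
    baseline_fraction = x$baseline,
    intragenic_fraction = intr$fraction,
    intragenic_fold = intr$fold_enrichment
  )
}

#' Export every summary table of a study
#'
#' Convenience wrapper over [write_report()] mirroring the supplementary
#' table layout: trait categories, candidate assignments, conservation,
#' expression, and phenotype summaries.
#'
#' @param study A `gwasfly_study`.
#' @param destination Output directory.
#' @param manifest Extra manifest metadata.
#' @return Files written, invisibly.
#' @export
write_study_report <- function(study, destination, manifest = list()) {
  summaries <- list(
    conservation_by_tier = as_tibble(study$by_tier),
    candidate_assignments = study$assignments
  )
  if (!is.null(study$by_tissue_category)) {
    summaries$conservation_by_tissue_category <- as_tibble(study$by_tissue_category)
  }
  if (!is.null(study$by_mechanism_category)) {
    summaries$conservation_by_mechanism_category <- as_tibble(study$by_mechanism_category)
  }
  if (!is.null(study$expression_summary)) {
    summaries$expression_by_category <- as_tibble(study$expression_summary)
  }
  if (!is.null(study$phenotype_summary)) {
    summaries$phenotype_by_category <- as_tibble(study$phenotype_summary)
  }
  write_report(summaries, destination,
               manifest = c(study$params, manifest))
}
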