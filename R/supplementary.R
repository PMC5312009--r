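#' Summarize a published per-gene candidate/conservation table
#'
#' Deterministic aggregation of a candidate table in the assignment schema
#' (one row per SNP-gene nomination, columns `rsid`, `gene_id`, `tiers` —
#' comma-separated satisfied criteria — and a logical/0-1 `conserved`
#' column): unique-gene candidate totals and conserved counts per tier.
#' With the article's supplementary candidate table this reproduces the
#' printed totals (4009 intragenic candidates, 2573 of them conserved, up to
#' 16,544 / 9660 at the 500 kb tier).
#'
#' @param file TSV path or raw lines.
#' @return Tibble with `tier`, `n_candidates`, `n_conserved`, `fraction`.
#' @export
summarize_supplementary_candidates <- function(file) {
  tab <- readr::read_tsv(materialize_text(file),
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  stopifnot(all(c("gene_id", "tiers", "conserved") %in% names(tab)))
  conserved <- tolower(tab$conserved) %in% c("true", "1", "yes")
  purrr::map(TIERS, function(tier) {
    hit <- stringr::str_detect(tab$tiers, stringr::fixed(tier))
    genes <- unique(tab$gene_id[hit])
    cons <- unique(tab$gene_id[hit & conserved])
    tibble(tier = tier, n_candidates = length(genes),
           n_conserved = length(cons),
           fraction = ifelse(length(genes) > 0, length(cons) / length(genes), NA_real_))
  }) %>% bind_rows()
}

#' Summarize a published per-gene expression table
#'
#' Aggregates a gene-level expression table (columns `gene_id`, `category`,
#' `tissue`, logical/0-1 `expressed`) into per-(category, tissue) expressed
#' fractions — the aggregation that reproduces the printed nervous-system
#' head/whole/gut fractions from the article's supplementary expression
#' table.
#'
#' @param file TSV path or raw lines.
#' @return Tibble with `category`, `tissue`, `n`, `n_expressed`, `fraction`.
#' @export
summarize_supplementary_expression <- function(file) {
  tab <- readr::read_tsv(materialize_text(file),
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  stopifnot(all(c("gene_id", "category", "tissue", "expressed") %in% names(tab)))
  tab$expressed <- tolower(tab$expressed) %in% c("true", "1", "yes")
  tab %>%
    distinct(.data$gene_id, .data$category, .data$tissue, .data$expressed) %>%
    group_by(.data$category, .data$tissue) %>%
    summarise(n = dplyr::n(), n_expressed = sum(.data$expressed),
              fraction = mean(.data$expressed), .groups = "drop")
}

#' Summarize a published per-gene essentiality table
#'
#' Aggregates a gene-level lethality table (columns `gene_id`, `category`,
#' logical/0-1 `lethal`) into per-category lethal fractions — the
#' aggregation that reproduces the printed lethality enrichment (43% for
#' candidate homologs vs 25% genome-wide) from the article's supplementary
#' essentiality table.
#'
#' @param file TSV path or raw lines.
#' @return Tibble with `category`, `n`, `n_lethal`, `fraction`.
#' @export
summarize_supplementary_lethality <- function(file) {
  tab <- readr::read_tsv(materialize_text(file),
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  stopifnot(all(c("gene_id", "category", "lethal") %in% names(tab)))
  tab$lethal <- tolower(tab$lethal) %in% c("true", "1", "yes")
  tab %>%
    distinct(.data$gene_id, .data$category, .data$lethal) %>%
    group_by(.data$category) %>%
    summarise(n = dplyr::n(), n_lethal = sum(.data$lethal),
              fraction = mean(.data$lethal), .groups = "drop")
}
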