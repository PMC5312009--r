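#' Column mapping for a gene-by-tissue RPKM report
#'
#' Defaults match the FlyBase `gene_rpkm_report` TSV dialect (one row per
#' gene per RNA-seq sample).
#'
#' @param gene,sample,rpkm Column names in the source file.
#' @return Named character vector used by [read_rpkm_report()].
#' @export
rpkm_dialect <- function(gene = "FBgn#", sample = "RNASource_name",
                         rpkm = "RPKM_value") {
  c(gene = gene, sample = sample, rpkm = rpkm)
}

#' Read a gene-by-tissue RPKM expression report
#'
#' Parses the long-format report into one cell per (gene, sample); repeated
#' (gene, sample) rows keep the maximum RPKM.
#'
#' @param file TSV path or raw lines. Comment lines starting with `##` are
#'   skipped (`#` alone cannot mark comments: the FlyBase dialect uses it
#'   inside column names such as `FBgn#`).
#' @param dialect Column mapping from [rpkm_dialect()].
#' @return Tibble with columns `fly_gene`, `tissue`, `rpkm` (>= 0).
#' @export
read_rpkm_report <- function(file, dialect = rpkm_dialect()) {
  lines <- readLines(materialize_text(file), warn = FALSE)
  lines <- lines[!startsWith(lines, "##")]
  tab <- readr::read_tsv(I(paste(lines, collapse = "\n")),
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing_cols <- dialect[!dialect %in% names(tab)]
  if (length(missing_cols) > 0) {
    abort(paste0("RPKM report is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(tab) == 0) {
    return(tibble(fly_gene = character(), tissue = character(), rpkm = double()))
  }
  rpkm <- suppressWarnings(as.numeric(tab[[dialect[["rpkm"]]]]))
  bad <- which(is.na(rpkm) | rpkm < 0)
  if (length(bad) > 0) {
    abort(sprintf("non-numeric or negative RPKM in data row %d", bad[1]))
  }
  tibble(
    fly_gene = tab[[dialect[["gene"]]]],
    tissue = tab[[dialect[["sample"]]]],
    rpkm = rpkm
  ) %>%
    group_by(.data$fly_gene, .data$tissue) %>%
    summarise(rpkm = max(.data$rpkm), .groups = "drop")
}

#' Is a fly gene expressed in a tissue?
#'
#' Expression is called at an RPKM threshold, inclusive: RPKM exactly equal
#' to the threshold (default 2) counts as expressed. A missing (gene,
#' tissue) cell means "not detected" and yields `FALSE`.
#'
#' @param expression Expression tibble from [read_rpkm_report()].
#' @param fly_gene,tissue Gene id and tissue label (vectors recycled to a
#'   common length).
#' @param threshold RPKM threshold >= 0 (default 2).
#' @return Logical vector.
#' @export
is_expressed <- function(expression, fly_gene, tissue, threshold = 2.0) {
  stopifnot(threshold >= 0)
  idx <- match(paste0(fly_gene, "\r", tissue),
               paste0(expression$fly_gene, "\r", expression$tissue))
  val <- expression$rpkm[idx]
  !is.na(val) & val >= threshold
}

#' Default phenotype term-set configuration
#'
#' The published analysis classified fly phenotypes with a curated set of 41
#' controlled-vocabulary terms for "neuronal" and a lethality term set; the
#' identities of those terms are not part of this package, so the generator
#' and tests use clearly synthetic placeholder ids. Supply your own term ids
#' for real annotation data.
#'
#' @param neuronal_terms Character vector of CV term ids classed as neuronal
#'   (default: 41 synthetic placeholder ids).
#' @param lethal_terms Character vector of CV term ids classed as lethal.
#' @return List with elements `neuronal_terms` and `lethal_terms`.
#' @export
default_term_config <- function(
    neuronal_terms = sprintf("FBcv:SYN-NEURO-%02d", 1:41),
    lethal_terms = "FBcv:SYN-LETHAL-01") {
  stopifnot(length(neuronal_terms) > 0, length(lethal_terms) > 0)
  list(neuronal_terms = neuronal_terms, lethal_terms = lethal_terms)
}

#' Read a long-format gene-to-phenotype-term table
#'
#' @param file TSV with columns `fly_gene_id` (or `fly_gene`) and `term_id`,
#'   or raw lines.
#' @return Tibble with columns `fly_gene`, `term_id`.
#' @export
read_phenotypes <- function(file) {
  tab <- readr::read_tsv(materialize_text(file),
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if ("fly_gene_id" %in% names(tab)) names(tab)[names(tab) == "fly_gene_id"] <- "fly_gene"
  stopifnot(all(c("fly_gene", "term_id") %in% names(tab)))
  distinct(tab[, c("fly_gene", "term_id")])
}

#' Classify fly genes by phenotype-term membership
#'
#' `TRUE` when a gene's annotated term set intersects `term_set`; genes with
#' no annotation are `FALSE`. Monotone in `term_set`: enlarging the set
#' never flips `TRUE` to `FALSE`.
#'
#' @param phenotypes Phenotype tibble (`fly_gene`, `term_id`).
#' @param fly_gene Character vector of gene ids.
#' @param term_set Non-empty character vector of term ids.
#' @return Logical vector along `fly_gene`.
#' @export
classify_by_terms <- function(phenotypes, fly_gene, term_set) {
  stopifnot(length(term_set) > 0)
  hits <- unique(phenotypes$fly_gene[phenotypes$term_id %in% term_set])
  fly_gene %in% hits
}

#' Functional profiles of human genes projected through their fly orthologs
#'
#' For every conserved human gene, projects tissue expression and phenotype
#' classes onto its best-scoring fly ortholog(s). With several tied best
#' orthologs the calls aggregate any-of: the human gene is "expressed in
#' head" if ANY tied ortholog is, and likewise for the neuronal/lethal/
#' annotated flags. Non-conserved genes get no profile rows (empty profile).
#'
#' @param calls Conservation calls from [call_conserved()].
#' @param pairs Ortholog-pair tibble (used only via the `best_fly_genes`
#'   already stored in `calls`; accepted for interface symmetry and ignored
#'   when `NULL`).
#' @param expression Expression tibble from [read_rpkm_report()].
#' @param phenotypes Phenotype tibble from [read_phenotypes()].
#' @param term_config List from [default_term_config()].
#' @param tissues Character vector of tissue labels to profile.
#' @param rpkm_threshold Expression-call threshold (default 2).
#' @return Long tibble with one row per (conserved human gene, tissue):
#'   `human_gene`, `fly_genes` (comma-collapsed tied best orthologs),
#'   `tissue`, `expressed`, plus per-gene flags `neuronal`, `lethal`,
#'   `annotated` (any phenotype annotation) repeated across tissues.
#' @export
homolog_profile <- function(calls, pairs = NULL, expression, phenotypes,
                            term_config = default_term_config(),
                            tissues, rpkm_threshold = 2.0) {
  conserved <- calls[calls$conserved, ]
  empty <- tibble(
    human_gene = character(), fly_genes = character(), tissue = character(),
    expressed = logical(), neuronal = logical(), lethal = logical(),
    annotated = logical()
  )
  if (nrow(conserved) == 0) return(empty)
  long <- tidyr::unnest(
    tibble(human_gene = conserved$human_gene, fly_gene = conserved$best_fly_genes),
    "fly_gene"
  )
  annotated_genes <- unique(phenotypes$fly_gene)
  long$neuronal <- classify_by_terms(phenotypes, long$fly_gene, term_config$neuronal_terms)
  long$lethal <- classify_by_terms(phenotypes, long$fly_gene, term_config$lethal_terms)
  long$annotated <- long$fly_gene %in% annotated_genes
  per_tissue <- lapply(tissues, function(ts) {
    long$expressed <- is_expressed(expression, long$fly_gene, ts, rpkm_threshold)
    long %>%
      group_by(.data$human_gene) %>%
      summarise(
        fly_genes = paste(sort(.data$fly_gene), collapse = ","),
        tissue = ts,
        expressed = any(.data$expressed),
        neuronal = any(.data$neuronal),
        lethal = any(.data$lethal),
        annotated = any(.data$annotated),
        .groups = "drop"
      )
  })
  arrange(bind_rows(per_tissue), .data$human_gene, .data$tissue)
}
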