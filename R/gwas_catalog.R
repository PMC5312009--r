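#' Column mapping for a GWAS-catalog-style association table
#'
#' Defaults match the NHGRI-EBI GWAS catalog TSV dialect.
#'
#' @param snp,chrom,pos,trait,study,pvalue Column names in the source file.
#' @return Named character vector used by [read_gwas_catalog()].
#' @export
catalog_dialect <- function(snp = "SNPS", chrom = "CHR_ID", pos = "CHR_POS",
                            trait = "DISEASE/TRAIT", study = "PUBMEDID",
                            pvalue = "P-VALUE") {
  c(snp = snp, chrom = chrom, pos = pos, trait = trait, study = study,
    pvalue = pvalue)
}

#' Read a GWAS-catalog-style association table
#'
#' Parses a tab-separated association table into one row per (row x SNP
#' token). Multi-SNP cells (haplotypes and SNP-by-SNP interactions packed
#' into one row) are split on `";"` or `"x"`, with the corresponding tokens
#' of the chromosome and position columns aligned by index; tokens left
#' without a parseable chromosome or position are dropped and counted.
#' Printed 1-based positions are converted to the internal 0-based
#' convention; chromosome names are normalized with a leading `"chr"`
#' stripped.
#'
#' @param file Path to the TSV, or a character vector of raw lines.
#' @param dialect Column mapping from [catalog_dialect()]. The `pvalue`
#'   column is optional in the file; all others must be present.
#' @return Tibble with columns `rsid`, `chrom`, `pos` (0-based), `trait`,
#'   `study_id`, `pvalue`. A parse report (tibble with `n_data_rows`,
#'   `n_rows_dropped`, `n_rows_emitted`, `n_tokens_dropped`,
#'   `n_associations`) is attached as attribute `"parse_report"`; see
#'   [parse_report()].
#' @export
read_gwas_catalog <- function(file, dialect = catalog_dialect()) {
  path <- materialize_text(file)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, na = character())
  if (nrow(raw) == 0 && ncol(raw) == 0) abort("empty catalog file: no header row")
  needed <- dialect[c("snp", "chrom", "pos", "trait", "study")]
  missing_cols <- needed[!needed %in% names(raw)]
  if (length(missing_cols) > 0) {
    abort(paste0("catalog is missing mapped column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  has_p <- dialect[["pvalue"]] %in% names(raw)

  snp_raw <- raw[[dialect[["snp"]]]]
  chrom_raw <- raw[[dialect[["chrom"]]]]
  pos_raw <- raw[[dialect[["pos"]]]]
  trait_raw <- raw[[dialect[["trait"]]]]
  study_raw <- raw[[dialect[["study"]]]]
  p_raw <- if (has_p) suppressWarnings(as.numeric(raw[[dialect[["pvalue"]]]])) else rep(NA_real_, nrow(raw))

  # expand each row into its SNP tokens (multi-SNP cells split on ";" or "x",
  # the chromosome/position cells aligned by token index)
  snp_tok <- strsplit(snp_raw, "[;x]")
  chrom_tok <- strsplit(chrom_raw, "[;x]")
  pos_tok <- strsplit(pos_raw, "[;x]")
  k <- pmax(lengths(snp_tok), 1L)
  pick <- function(tok, i, j) {
    v <- tok[[i]]
    if (j <= length(v)) trimws(v[[j]]) else NA_character_
  }
  row_of <- rep(seq_len(nrow(raw)), k)
  tok_of <- unlist(lapply(k, seq_len), use.names = FALSE)
  snps <- mapply(pick, i = row_of, j = tok_of, MoreArgs = list(tok = snp_tok))
  chroms <- mapply(pick, i = row_of, j = tok_of, MoreArgs = list(tok = chrom_tok))
  poss <- mapply(pick, i = row_of, j = tok_of, MoreArgs = list(tok = pos_tok))
  if (length(row_of) == 0) {
    snps <- chroms <- poss <- character()
  }
  pos_num <- suppressWarnings(as.numeric(poss))
  ok <- !is.na(snps) & snps != "" & !is.na(chroms) & chroms != "" &
    !is.na(pos_num) & pos_num >= 1
  n_tokens_dropped <- sum(!ok)
  emitted_rows <- unique(row_of[ok])
  n_rows_dropped <- nrow(raw) - length(emitted_rows)
  out <- tibble(
    rsid = as.character(snps[ok]),
    chrom = normalize_chrom(as.character(chroms[ok])),
    pos = as.integer(pos_num[ok]) - 1L,
    trait = trait_raw[row_of[ok]],
    study_id = study_raw[row_of[ok]],
    pvalue = p_raw[row_of[ok]]
  )
  if (nrow(out) == 0) {
    out <- tibble(rsid = character(), chrom = character(), pos = integer(),
                  trait = character(), study_id = character(), pvalue = double())
  }
  report <- tibble(
    n_data_rows = nrow(raw),
    n_rows_dropped = n_rows_dropped,
    n_rows_emitted = nrow(raw) - n_rows_dropped,
    n_tokens_dropped = n_tokens_dropped,
    n_associations = nrow(out)
  )
  attr(out, "parse_report") <- report
  out
}

#' Retrieve the parse report attached by [read_gwas_catalog()]
#'
#' @param associations Tibble returned by [read_gwas_catalog()].
#' @return One-row tibble of row/token accounting, or `NULL` if absent.
#' @export
parse_report <- function(associations) {
  attr(associations, "parse_report", exact = TRUE)
}

#' Deduplicate associations
#'
#' Keeps the first occurrence of each key combination (default:
#' `(rsid, trait)`), preserving input order. Idempotent.
#'
#' @param associations Association tibble.
#' @param key Character vector of columns defining uniqueness.
#' @return Deduplicated tibble.
#' @export
dedupe_associations <- function(associations, key = c("rsid", "trait")) {
  stopifnot(all(key %in% names(associations)))
  associations[!duplicated(associations[, key, drop = FALSE]), ]
}

#' Read a trait-to-category table
#'
#' Long-lived trait labels are mapped to a target-tissue category and a
#' disease-mechanism category (two separate classification schemes). Trait
#' labels must be unique after normalization.
#'
#' @param file Path to a TSV with columns `trait`, `tissue_category`,
#'   `mechanism_category` (empty cells mean uncategorized), or a data frame
#'   with those columns.
#' @return Tibble with normalized `trait` plus the two category columns.
#' @export
read_trait_categories <- function(file) {
  tab <- if (is.data.frame(file)) {
    as_tibble(file)
  } else {
    readr::read_tsv(materialize_text(file),
                    col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  }
  needed <- c("trait", "tissue_category", "mechanism_category")
  if (!all(needed %in% names(tab))) {
    abort(paste0("trait-category table needs columns: ", paste(needed, collapse = ", ")))
  }
  tab <- tab[, needed]
  tab$trait <- normalize_trait(tab$trait)
  tab$tissue_category <- dplyr::na_if(as.character(tab$tissue_category), "")
  tab$mechanism_category <- dplyr::na_if(as.character(tab$mechanism_category), "")
  if (anyDuplicated(tab$trait)) {
    abort(paste0("duplicate trait label after normalization: ",
                 tab$trait[duplicated(tab$trait)][1]))
  }
  tab
}

normalize_trait <- function(x) {
  tolower(stringr::str_squish(as.character(x)))
}

#' Look up the category of a trait under one classification scheme
#'
#' Exact-match lookup after case-folding and whitespace normalization;
#' traits absent from the table map to `NA` (uncategorized).
#'
#' @param trait Character vector of trait labels.
#' @param table Trait-category table from [read_trait_categories()].
#' @param scheme `"tissue"` or `"mechanism"`.
#' @return Character vector of categories (`NA` when unmapped).
#' @export
categorize_trait <- function(trait, table, scheme = c("tissue", "mechanism")) {
  scheme <- match.arg(scheme)
  col <- paste0(scheme, "_category")
  idx <- match(normalize_trait(trait), table$trait)
  table[[col]][idx]
}
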