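#' Integrate per-algorithm ortholog predictions into vote scores
#'
#' Each (human gene, fly gene) pair is scored by the number of DISTINCT
#' prediction algorithms supporting it — the integrative vote score used to
#' call conservation. Duplicate (human, fly, algorithm) rows collapse to a
#' single vote. `is_best` flags, per human gene, every pair tied at the
#' maximal score.
#'
#' @param predictions Tibble with columns `human_gene`, `fly_gene`,
#'   `algorithm` (all non-empty), e.g. from [read_predictions()].
#' @return Tibble with columns `human_gene`, `fly_gene`, `score` (integer
#'   >= 1) and `is_best`, sorted by `(human_gene, -score, fly_gene)`.
#' @export
#' @examples
#' preds <- tibble::tibble(
#'   human_gene = c("h1", "h1", "h1"),
#'   fly_gene = c("f1", "f1", "f2"),
#'   algorithm = c("algA", "algB", "algA")
#' )
#' integrate_predictions(preds)
integrate_predictions <- function(predictions) {
  stopifnot(all(c("human_gene", "fly_gene", "algorithm") %in% names(predictions)))
  bad <- which(
    is.na(predictions$human_gene) | predictions$human_gene == "" |
    is.na(predictions$fly_gene) | predictions$fly_gene == "" |
    is.na(predictions$algorithm) | predictions$algorithm == ""
  )
  if (length(bad) > 0) {
    abort(sprintf("blank field in prediction row %d", bad[1]))
  }
  pairs <- predictions %>%
    distinct(.data$human_gene, .data$fly_gene, .data$algorithm) %>%
    count(.data$human_gene, .data$fly_gene, name = "score") %>%
    group_by(.data$human_gene) %>%
    mutate(is_best = .data$score == max(.data$score)) %>%
    ungroup()
  arrange(pairs, .data$human_gene, dplyr::desc(.data$score), .data$fly_gene)
}

#' Read a per-algorithm ortholog prediction table
#'
#' @param file TSV with columns `human_gene_id`, `fly_gene_id`, `algorithm`
#'   (or already-internal names), or a character vector of raw lines.
#' @return Prediction tibble for [integrate_predictions()].
#' @export
read_predictions <- function(file) {
  tab <- readr::read_tsv(materialize_text(file),
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  nm <- c(human_gene_id = "human_gene", fly_gene_id = "fly_gene")
  for (old in names(nm)) {
    if (old %in% names(tab)) names(tab)[names(tab) == old] <- nm[[old]]
  }
  stopifnot(all(c("human_gene", "fly_gene", "algorithm") %in% names(tab)))
  tab[, c("human_gene", "fly_gene", "algorithm")]
}

#' Read a pre-integrated ortholog score table
#'
#' Accepts a table that already carries integrated vote scores (columns
#' `human_gene_id`/`human_gene`, `fly_gene_id`/`fly_gene`, `score`), so a
#' published integrative-ortholog resource can be ingested directly without
#' re-running vote integration. `is_best` is recomputed per human gene.
#'
#' @param file TSV path or raw lines.
#' @return Ortholog-pair tibble in the same shape as
#'   [integrate_predictions()] output.
#' @export
read_ortholog_scores <- function(file) {
  tab <- readr::read_tsv(materialize_text(file),
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  nm <- c(human_gene_id = "human_gene", fly_gene_id = "fly_gene")
  for (old in names(nm)) {
    if (old %in% names(tab)) names(tab)[names(tab) == old] <- nm[[old]]
  }
  stopifnot(all(c("human_gene", "fly_gene", "score") %in% names(tab)))
  tab$score <- as.integer(tab$score)
  tab %>%
    select("human_gene", "fly_gene", "score") %>%
    group_by(.data$human_gene) %>%
    mutate(is_best = .data$score == max(.data$score)) %>%
    ungroup() %>%
    arrange(.data$human_gene, dplyr::desc(.data$score), .data$fly_gene)
}

#' Call conservation of human genes in fly at a vote-score threshold
#'
#' A human gene is conserved when any of its ortholog pairs reaches
#' `min_score` distinct supporting algorithms (inclusive; the default
#' threshold 2 requires at least two algorithms to agree). Human genes with
#' no pair at all are not conserved; supplying a `universe` adds explicit
#' `conserved = FALSE` rows for genes absent from the pair table.
#'
#' @param pairs Ortholog-pair tibble from [integrate_predictions()] or
#'   [read_ortholog_scores()].
#' @param min_score Integer threshold >= 1 (default 2).
#' @param universe Optional character vector of human gene ids defining the
#'   full gene universe.
#' @return Tibble with columns `human_gene`, `conserved`, `n_pairs`,
#'   `max_score`, and `best_fly_genes` (list-column from
#'   [best_orthologs()]; empty when the gene has no pairs).
#' @export
call_conserved <- function(pairs, min_score = 2, universe = NULL) {
  stopifnot(min_score >= 1)
  calls <- pairs %>%
    group_by(.data$human_gene) %>%
    summarise(
      conserved = max(.data$score) >= min_score,
      n_pairs = dplyr::n(),
      max_score = max(.data$score),
      best_fly_genes = list(sort(.data$fly_gene[.data$score == max(.data$score)])),
      .groups = "drop"
    )
  if (!is.null(universe)) {
    missing <- setdiff(universe, calls$human_gene)
    if (length(missing) > 0) {
      calls <- bind_rows(calls, tibble(
        human_gene = missing, conserved = FALSE, n_pairs = 0L,
        max_score = 0L, best_fly_genes = rep(list(character()), length(missing))
      ))
    }
    calls <- calls[calls$human_gene %in% universe, ]
  }
  arrange(calls, .data$human_gene)
}

#' Best-scoring fly orthologs of a human gene
#'
#' @param human_gene Single human gene id.
#' @param pairs Ortholog-pair tibble.
#' @return Character vector of fly gene ids with the maximal score, ordered
#'   by (descending score, ascending fly gene id) — i.e. the tied best set,
#'   id-sorted. Empty when the gene has no pairs.
#' @export
best_orthologs <- function(human_gene, pairs) {
  p <- pairs[pairs$human_gene == human_gene, ]
  if (nrow(p) == 0) return(character())
  best <- p$fly_gene[p$score == max(p$score)]
  sort(best)
}
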