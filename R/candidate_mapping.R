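#' Genes containing an association position (intragenic criterion)
#'
#' A gene is intragenic for a SNP when its span contains the position under
#' the 0-based half-open convention (`start <= pos < end`), i.e. the SNP is
#' exonic or intronic with respect to the gene body.
#'
#' @param assoc One-row association (tibble with `chrom`, `pos`), or a list
#'   with those elements.
#' @param genes Annotation tibble.
#' @return Tibble of gene rows (possibly empty; nested genes all retained).
#' @export
map_intragenic <- function(assoc, genes) {
  genes_overlapping(genes, assoc$chrom[[1]], assoc$pos[[1]], assoc$pos[[1]] + 1L)
}

#' Nearest-neighbor candidate genes for an association
#'
#' The intragenic gene(s) plus the genes immediately proximal and distal to
#' the SNP (the nearest non-overlapping gene on each side), per
#' [flanking_genes()]. Typically 2-3 genes per SNP on a gene-dense
#' chromosome; empty on a gene-free chromosome.
#'
#' @inheritParams map_intragenic
#' @return Tibble of unique gene rows, ordered by `(start, gene_id)`.
#' @export
map_nearest_neighbors <- function(assoc, genes) {
  inside <- map_intragenic(assoc, genes)
  flanks <- flanking_genes(genes, assoc$chrom[[1]], assoc$pos[[1]])
  out <- bind_rows(inside, flanks[, names(genes)])
  arrange(distinct(out, .data$gene_id, .keep_all = TRUE), .data$start, .data$gene_id)
}

#' Window-criterion candidate genes for an association
#'
#' All genes overlapping the interval extending `halfwidth` base pairs on
#' each side of the SNP (half-widths 125 kb and 250 kb give the "within
#' 250 kb" and "within 500 kb" tiers). The window is truncated at position 0.
#' Intragenic genes are included by construction.
#'
#' @inheritParams map_intragenic
#' @param halfwidth Window half-width in base pairs (> 0).
#' @return Tibble of gene rows ordered by `(start, gene_id)`.
#' @export
map_window <- function(assoc, genes, halfwidth) {
  stopifnot(halfwidth > 0)
  pos <- assoc$pos[[1]]
  genes_overlapping(genes, assoc$chrom[[1]],
                    max(0, pos - halfwidth), pos + halfwidth + 1)
}

#' Assign candidate genes to associations under the four nested criteria
#'
#' For every association, nominates each distinct gene reached by any of the
#' four criteria and records the full set of criteria it satisfies. The
#' window tiers are purely positional; the nearest-neighbor genes may lie
#' beyond both windows (nearest-neighbor is not nested within them).
#'
#' @param associations Association tibble (`rsid`, `chrom`, `pos`, `trait`,
#'   optionally more columns carried through by join later).
#' @param genes Annotation tibble.
#' @param halfwidths Length-2 numeric: half-widths of the two window tiers
#'   (defaults 125 kb and 250 kb, i.e. the "within 250 kb"/"within 500 kb"
#'   criteria).
#' @return Tibble with one row per (association, nominated gene):
#'   `rsid`, `trait`, `gene_id`, `symbol`, logical tier columns
#'   `intragenic`, `nearest_neighbor`, `within_250kb`, `within_500kb`,
#'   `distance` (signed bp from SNP to the nearest gene boundary; 0 when
#'   intragenic, negative when the gene is on the lower-coordinate side),
#'   and `multi_intragenic` (audit flag: TRUE when the SNP falls inside more
#'   than one gene). Rows are ordered by association input order, then
#'   `(abs(distance), gene_id)`.
#' @export
assign_candidates <- function(associations, genes,
                              halfwidths = c(125000, 250000)) {
  stopifnot(length(halfwidths) == 2, all(halfwidths > 0), halfwidths[1] <= halfwidths[2])
  n <- nrow(associations)
  empty <- tibble(
    rsid = character(), trait = character(), gene_id = character(),
    symbol = character(), intragenic = logical(), nearest_neighbor = logical(),
    within_250kb = logical(), within_500kb = logical(), distance = integer(),
    multi_intragenic = logical()
  )
  if (n == 0 || nrow(genes) == 0) return(empty)

  gr <- gene_ranges(genes)
  pos <- as.integer(associations$pos)
  chrom <- normalize_chrom(associations$chrom)

  # one indexed overlap pass per window size (+ the point query)
  window_hits <- function(hw) {
    qs <- pmax(0, pos - hw) + 1L          # 1-based inclusive query start
    qe <- pos + hw + 1L                   # covers [pos-hw, pos+hw] inclusive
    q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(qs, qe))
    ov <- suppressWarnings(GenomicRanges::findOverlaps(q, gr, ignore.strand = TRUE))
    tibble(.q = S4Vectors::queryHits(ov), row = S4Vectors::subjectHits(ov))
  }
  point_hits <- {
    q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, pos + 1L))
    ov <- suppressWarnings(GenomicRanges::findOverlaps(q, gr, ignore.strand = TRUE))
    tibble(.q = S4Vectors::queryHits(ov), row = S4Vectors::subjectHits(ov))
  }
  flank_hits <- flank_lookup(genes, chrom, pos)[, c(".q", "row")]
  w250 <- window_hits(halfwidths[1])
  w500 <- window_hits(halfwidths[2])

  pairs <- distinct(bind_rows(point_hits, flank_hits, w250, w500),
                    .data$.q, .data$row)
  key <- function(h) paste(h$.q, h$row)
  pk <- key(pairs)
  pairs$intragenic <- pk %in% key(point_hits)
  pairs$nearest_neighbor <- pairs$intragenic | pk %in% key(flank_hits)
  pairs$within_250kb <- pk %in% key(w250)
  pairs$within_500kb <- pk %in% key(w500)

  g_start <- genes$start[pairs$row]
  g_end <- genes$end[pairs$row]
  p <- pos[pairs$.q]
  pairs$distance <- as.integer(ifelse(
    pairs$intragenic, 0L,
    ifelse(g_end <= p, -(p - g_end + 1L), g_start - p)
  ))
  n_intra <- table(factor(point_hits$.q, levels = seq_len(n)))
  pairs$multi_intragenic <- as.vector(n_intra[pairs$.q] > 1)

  out <- tibble(
    rsid = associations$rsid[pairs$.q],
    trait = if ("trait" %in% names(associations)) associations$trait[pairs$.q] else NA_character_,
    gene_id = genes$gene_id[pairs$row],
    symbol = genes$symbol[pairs$row],
    intragenic = pairs$intragenic,
    nearest_neighbor = pairs$nearest_neighbor,
    within_250kb = pairs$within_250kb,
    within_500kb = pairs$within_500kb,
    distance = pairs$distance,
    multi_intragenic = pairs$multi_intragenic,
    .q = pairs$.q
  )
  out <- arrange(out, .data$.q, abs(.data$distance), .data$gene_id)
  out$.q <- NULL
  out
}

#' Unique candidate-gene sets per group at one tier
#'
#' Deduplicates nominated genes within each group: a gene nominated by
#' several SNPs of one group counts once, matching how the published totals
#' (e.g. 4009 intragenic candidates) are unique-gene counts.
#'
#' @param assignments Output of [assign_candidates()].
#' @param tier One of `"intragenic"`, `"nearest_neighbor"`,
#'   `"within_250kb"`, `"within_500kb"`.
#' @param group_by Grouping: `NULL` (single group `"all"`), the name of a
#'   column of `assignments` (e.g. `"trait"`), or a data frame with columns
#'   `trait` and `group` mapping each trait to a category (traits mapped to
#'   `NA` are dropped from grouped output).
#' @return Tibble with columns `group` and `gene_id`, one row per distinct
#'   (group, gene) pair.
#' @export
candidate_gene_sets <- function(assignments, tier = "intragenic", group_by = NULL) {
  tier <- match_tier(tier)
  hit <- assignments[assignments[[tier]], ]
  if (is.null(group_by)) {
    hit$group <- "all"
  } else if (is.character(group_by) && length(group_by) == 1) {
    stopifnot(group_by %in% names(assignments))
    hit$group <- hit[[group_by]]
  } else {
    gb <- as_tibble(group_by)
    stopifnot(all(c("trait", "group") %in% names(gb)))
    hit$group <- gb$group[match(normalize_trait(hit$trait), normalize_trait(gb$trait))]
    hit <- hit[!is.na(hit$group), ]
  }
  distinct(arrange(hit[, c("group", "gene_id")], .data$group, .data$gene_id))
}

#' Export candidate assignments as TSV
#'
#' Writes one row per (SNP, gene) nomination with the satisfied tiers
#' collapsed into a comma-separated column, the schema used for the
#' supplementary-style candidate table.
#'
#' @param assignments Output of [assign_candidates()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(assignments, path) {
  tiers <- apply(as.matrix(assignments[, TIERS]), 1, function(x) {
    paste(TIERS[x], collapse = ",")
  })
  out <- tibble(
    rsid = assignments$rsid, trait = assignments$trait,
    gene_id = assignments$gene_id, tiers = as.character(tiers),
    distance = assignments$distance
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Export SNP windows as BED intervals
#'
#' Emits the window intervals around each association (0-based half-open,
#' BED convention) for genome-browser inspection.
#'
#' @param associations Association tibble.
#' @param halfwidth Window half-width in bp.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_windows_bed <- function(associations, halfwidth, path) {
  lines <- sprintf(
    "%s\t%d\t%d\t%s",
    associations$chrom,
    pmax(0, associations$pos - halfwidth),
    associations$pos + halfwidth + 1,
    associations$rsid
  )
  writeLines(lines, path)
  invisible(path)
}
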