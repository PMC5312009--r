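#' Read gene annotations from GFF3 or BED
#'
#' Parses gene models into the tidy annotation table used by all interval
#' queries. GFF3 coordinates (1-based, inclusive) are converted to the
#' package-internal 0-based half-open convention on ingest; BED coordinates
#' are already 0-based half-open and are used as-is. Only GFF3 features of
#' type `gene` are retained; every gene feature must carry an `ID` attribute.
#' Chromosome names are normalized by stripping a leading `"chr"` so that
#' `"6"` and `"chr6"` match.
#'
#' @param file Path to a GFF3 or BED file, or a character vector of raw lines
#'   (treated as file content when it has length > 1 or contains a newline).
#' @param format `"gff3"` or `"bed"`.
#' @return A tibble with one row per gene and columns `gene_id`, `symbol`,
#'   `chrom`, `start`, `end` (0-based half-open), `strand` (`"+"`, `"-"`, or
#'   `"*"` for unknown) and `biotype`.
#' @export
#' @examples
#' gff <- c(
#'   "##gff-version 3",
#'   "6\tsrc\tgene\t101\t200\t.\t+\t.\tID=G1;Name=geneA"
#' )
#' read_gene_annotations(gff, format = "gff3")
read_gene_annotations <- function(file, format = c("gff3", "bed")) {
  format <- match.arg(format)
  path <- materialize_text(file)
  prescan_annotation(path, format)
  gr <- rtracklayer::import(path, format = if (format == "gff3") "gff3" else "bed")
  if (format == "gff3") {
    gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
    ids <- gr$ID
    if (length(gr) > 0 && (is.null(ids) || anyNA(ids) || any(ids == ""))) {
      abort("GFF3 gene feature without an ID attribute")
    }
    symbols <- if (!is.null(gr$Name)) as.character(gr$Name) else NA_character_
    biotype <- gr$biotype
    if (is.null(biotype)) biotype <- gr$gene_biotype
    biotype <- if (is.null(biotype)) NA_character_ else as.character(biotype)
  } else {
    ids <- gr$name
    if (length(gr) > 0 && (is.null(ids) || anyNA(ids) || any(ids == ""))) {
      abort("BED line without a name field (column 4) to use as gene_id")
    }
    symbols <- as.character(ids)
    biotype <- NA_character_
  }
  genes <- tibble(
    gene_id = as.character(ids) %||% character(),
    symbol = as.character(symbols),
    chrom = normalize_chrom(as.character(GenomicRanges::seqnames(gr))),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    biotype = biotype
  )
  genes$symbol <- if_else(is.na(genes$symbol), genes$gene_id, genes$symbol)
  genes$biotype <- if_else(is.na(genes$biotype), "protein_coding", genes$biotype)
  validate_annotation(genes)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

materialize_text <- function(file) {
  is_content <- length(file) > 1 || any(grepl("[\n\t]", file)) ||
    (length(file) == 1 && !file.exists(file) && grepl("^#", file))
  if (is_content) {
    path <- tempfile(fileext = ".txt")
    writeLines(unlist(strsplit(file, "\n", fixed = TRUE)), path)
    return(path)
  }
  if (!file.exists(file)) abort(paste0("file not found: ", file))
  file
}

prescan_annotation <- function(path, format) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (ln == "" || startsWith(ln, "#")) next
    if (format == "bed" &&
        (startsWith(ln, "track") || startsWith(ln, "browser"))) next
    nf <- length(strsplit(ln, "\t", fixed = TRUE)[[1]])
    if (format == "gff3" && nf != 9) {
      abort(sprintf("malformed GFF3 line %d: expected 9 tab-separated fields, found %d", i, nf))
    }
    if (format == "bed" && nf < 4) {
      abort(sprintf("malformed BED line %d: expected >= 4 tab-separated fields, found %d", i, nf))
    }
  }
  invisible(path)
}

normalize_chrom <- function(x) {
  sub("^chr", "", x, ignore.case = TRUE)
}

#' Validate (and normalize) a gene annotation table
#'
#' Checks the annotation invariants: coordinates satisfy `0 <= start < end`,
#' chromosome names are non-empty, and `gene_id` is unique. Rows are sorted
#' by `(chrom, start, gene_id)` so downstream queries are deterministic.
#'
#' @param genes A data frame with at least `gene_id`, `chrom`, `start`, `end`;
#'   missing `symbol`, `strand`, `biotype` columns are filled with defaults.
#' @return The validated, sorted annotation tibble.
#' @export
validate_annotation <- function(genes) {
  genes <- as_tibble(genes)
  if (!"symbol" %in% names(genes)) genes$symbol <- genes$gene_id
  if (!"strand" %in% names(genes)) genes$strand <- "*"
  if (!"biotype" %in% names(genes)) genes$biotype <- "protein_coding"
  genes <- genes[, c("gene_id", "symbol", "chrom", "start", "end", "strand", "biotype")]
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  genes$chrom <- normalize_chrom(as.character(genes$chrom))
  if (nrow(genes) == 0) return(genes)
  if (any(is.na(genes$start) | is.na(genes$end) | genes$start < 0 | genes$start >= genes$end)) {
    bad <- which(is.na(genes$start) | is.na(genes$end) | genes$start < 0 | genes$start >= genes$end)[1]
    abort(sprintf("gene '%s' violates 0 <= start < end", genes$gene_id[bad]))
  }
  if (any(genes$chrom == "" | is.na(genes$chrom))) abort("empty chromosome name")
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate gene_id in annotation: ", dup[1]))
  }
  arrange(genes, .data$chrom, .data$start, .data$gene_id)
}

#' Write a gene annotation table as GFF3
#'
#' Inverse of [read_gene_annotations()] for gene features; internal 0-based
#' half-open coordinates are converted back to 1-based inclusive GFF3.
#'
#' @param genes Annotation tibble (see [read_gene_annotations()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3", sprintf(
    "%s\tgwasfly\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s;biotype=%s",
    genes$chrom, genes$start + 1L, genes$end, genes$strand,
    genes$gene_id, genes$symbol, genes$biotype
  ))
  writeLines(lines, path)
  invisible(path)
}

# GRanges view of the annotation (1-based inclusive), for indexed queries.
gene_ranges <- function(genes) {
  GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end)
  )
}

#' Genes overlapping a genomic interval
#'
#' Returns exactly the genes `g` on `chrom` with `g$start < end` and
#' `g$end > start` (any overlap with the 0-based half-open query interval),
#' ordered by `(start, gene_id)`. An unknown chromosome yields an empty
#' result, not an error.
#'
#' @param genes Annotation tibble.
#' @param chrom Chromosome name (normalized against the annotation).
#' @param start,end Query interval, 0-based half-open, `start <= end`.
#' @return Tibble of gene rows (possibly empty).
#' @export
genes_overlapping <- function(genes, chrom, start, end) {
  stopifnot(length(chrom) == 1, length(start) == 1, length(end) == 1)
  if (start > end) abort("query interval must satisfy start <= end")
  chrom <- normalize_chrom(chrom)
  empty <- genes[0, ]
  if (nrow(genes) == 0) return(empty)
  if (start == end) {
    # degenerate zero-width query: keep the definitional filter
    hit <- genes$chrom == chrom & genes$start < end & genes$end > start
    out <- genes[hit, ]
  } else {
    q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
    ov <- suppressWarnings(
      GenomicRanges::findOverlaps(q, gene_ranges(genes), ignore.strand = TRUE)
    )
    out <- genes[S4Vectors::subjectHits(ov), ]
  }
  arrange(out, .data$start, .data$gene_id)
}

#' Nearest non-overlapping genes on each side of a position
#'
#' Finds the gene with the largest `end <= pos` (upstream, lower-coordinate
#' side) and the gene with the smallest `start > pos` (downstream). Genes
#' whose span contains `pos` are never returned; absent sides are simply
#' missing rows. Ties on the boundary coordinate are broken by the smaller
#' `gene_id`.
#'
#' @param genes Annotation tibble.
#' @param chrom Chromosome name.
#' @param pos 0-based position, `pos >= 0`.
#' @return Tibble with 0-2 rows: the gene columns plus `side`
#'   (`"upstream"`/`"downstream"`) and `distance` (base pairs from `pos` to
#'   the nearer gene boundary, always >= 1).
#' @export
flanking_genes <- function(genes, chrom, pos) {
  stopifnot(length(chrom) == 1, length(pos) == 1, pos >= 0)
  hits <- flank_lookup(genes, chrom, pos)
  res <- genes[hits$row, ]
  res$side <- hits$side
  res$distance <- hits$distance
  res
}

# Vectorized indexed flank lookup over (chrom, pos) query vectors.
# Returns a tibble (.q = query index, row = row in `genes`, side, distance).
# Per chromosome, boundary coordinates are deduplicated (ties resolved to the
# smallest gene_id) and queried with findInterval.
flank_lookup <- function(genes, chrom, pos) {
  chrom <- normalize_chrom(chrom)
  n <- length(pos)
  empty <- tibble(.q = integer(), row = integer(), side = character(),
                  distance = integer())
  if (n == 0 || nrow(genes) == 0) return(empty)
  out <- list()
  for (ch in unique(chrom)) {
    rows <- which(genes$chrom == ch)
    qi <- which(chrom == ch)
    if (length(rows) == 0) next
    g <- genes[rows, ]
    # upstream index: unique end coordinates, representative = min gene_id
    o <- order(g$end, g$gene_id)
    keep <- !duplicated(g$end[o])
    ends_u <- g$end[o][keep]
    rep_u <- rows[o][keep]
    k <- findInterval(pos[qi], ends_u)  # count of ends <= pos
    has_up <- k >= 1
    if (any(has_up)) {
      out[[length(out) + 1]] <- tibble(
        .q = qi[has_up],
        row = rep_u[k[has_up]],
        side = "upstream",
        distance = as.integer(pos[qi][has_up] - ends_u[k[has_up]] + 1L)
      )
    }
    # downstream index: unique start coordinates, representative = min gene_id
    o <- order(g$start, g$gene_id)
    keep <- !duplicated(g$start[o])
    starts_u <- g$start[o][keep]
    rep_d <- rows[o][keep]
    j <- findInterval(pos[qi], starts_u)  # count of starts <= pos
    has_down <- j < length(starts_u)
    if (any(has_down)) {
      jj <- j[has_down] + 1L
      out[[length(out) + 1]] <- tibble(
        .q = qi[has_down],
        row = rep_d[jj],
        side = "downstream",
        distance = as.integer(starts_u[jj] - pos[qi][has_down])
      )
    }
  }
  if (length(out) == 0) return(empty)
  arrange(bind_rows(out), .data$.q, .data$side == "downstream")
}
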