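# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately avoid the package's indexed query paths.

bf_overlap <- function(genes, chrom, start, end) {
  hit <- genes$chrom == chrom & genes$start < end & genes$end > start
  out <- genes[hit, ]
  out[order(out$start, out$gene_id), ]
}

bf_flanks <- function(genes, chrom, pos) {
  g <- genes[genes$chrom == chrom, ]
  res <- list()
  up <- g[g$end <= pos, ]
  if (nrow(up) > 0) {
    up <- up[up$end == max(up$end), ]
    up <- up[which.min(rank(up$gene_id)), ]
    res$upstream <- list(gene_id = up$gene_id, distance = pos - up$end + 1)
  }
  down <- g[g$start > pos, ]
  if (nrow(down) > 0) {
    down <- down[down$start == min(down$start), ]
    down <- down[which.min(rank(down$gene_id)), ]
    res$downstream <- list(gene_id = down$gene_id, distance = down$start - pos)
  }
  res
}

# random annotation with possibly overlapping/nested genes (harder than the
# generator's tiled layout)
random_annotation <- function(n, seed, n_chrom = 3, span = 1e6) {
  set.seed(seed)
  starts <- sample.int(span, n, replace = TRUE) - 1L
  lens <- sample(100:50000, n, replace = TRUE)
  validate_annotation(tibble::tibble(
    gene_id = sprintf("G%04d", seq_len(n)),
    chrom = as.character(sample.int(n_chrom, n, replace = TRUE)),
    start = starts,
    end = starts + lens
  ))
}

cd2ap_fixture <- function() {
  read_gene_annotations(
    system.file("extdata", "cd2ap_region.gff3", package = "gwasfly"),
    format = "gff3"
  )
}

# rs9349407, intronic in CD2AP (0-based position)
cd2ap_snp <- function() {
  tibble::tibble(rsid = "rs9349407", chrom = "6", pos = 47520025L,
                 trait = "Alzheimer's disease")
}

symbols_of <- function(genes, df) sort(df$symbol)

# analytic probability that a simulated gene is called conserved at score >= 2:
# its true pair reaches 2 of n_alg votes (conserved genes only), or any of its
# decoy pairs does
p_called <- function(truly_conserved, n_alg, tpr, fpr, n_decoys) {
  a <- 1 - pbinom(1, n_alg, tpr)
  b <- 1 - pbinom(1, n_alg, fpr)
  ifelse(truly_conserved,
         1 - (1 - a) * (1 - b)^n_decoys,
         1 - (1 - b)^n_decoys)
}

# exact two-sided Fisher p by hypergeometric enumeration
fisher_enum <- function(x11, x12, x21, x22) {
  r1 <- x11 + x12; c1 <- x11 + x21; n <- x11 + x12 + x21 + x22
  k <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(k, c1, n - c1, r1)
  p_obs <- dhyper(x11, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

toy_catalog <- function() {
  c(
    "SNPS\tCHR_ID\tCHR_POS\tDISEASE/TRAIT\tPUBMEDID\tP-VALUE",
    "rs1\t6\t101\tAlzheimer's disease\t11111\t5e-8",
    "rs2\t6\t50000\tAlzheimer's disease\t11111\t4e-9",
    "rs3; rs4\t6;6\t70000;90000\tType 2 diabetes\t22222\t1e-12",
    "rs5\t2\t300\tHeight\t33333\t2e-10",
    "rs6\t2\t\tHeight\t33333\t2e-10"
  )
}
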