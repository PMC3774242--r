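# Shared fixtures, built in code.

# SNP panel with exact per-class allele counts: x1 of n1 "functional" and
# x2 of n2 "nonfunctional" accessions carry allele 1 at each SNP.
panel_from_counts <- function(x1, n1, x2, n2, spacing = 1000L) {
  m <- length(x1)
  stopifnot(length(x2) == m)
  g1 <- vapply(x1, function(x) c(rep(1L, x), rep(0L, n1 - x)), integer(n1))
  g2 <- vapply(x2, function(x) c(rep(1L, x), rep(0L, n2 - x)), integer(n2))
  geno <- rbind(matrix(g1, n1), matrix(g2, n2))
  ids <- sprintf("a%03d", seq_len(n1 + n2))
  rownames(geno) <- ids
  snps <- data.frame(id = sprintf("s%03d", seq_len(m)), chrom = "1",
                     pos = spacing * seq_len(m), stringsAsFactors = FALSE)
  colnames(geno) <- snps$id
  acc <- data.frame(id = ids,
                    class = c(rep("functional", n1),
                              rep("nonfunctional", n2)),
                    stringsAsFactors = FALSE)
  snp_panel(geno, snps, acc)
}

# Panel whose window SNPs are exact copies of the label (perfect tags),
# with no other SNPs near the focal locus.
perfect_tag_panel <- function(n = 60, n_tags = 3, f = 0.5, seed = 1) {
  set.seed(seed)
  z <- stats::rbinom(n, 1L, f)
  while (min(table(z)) < 8) z <- stats::rbinom(n, 1L, f)
  geno <- matrix(rep(z, n_tags), n)
  ids <- sprintf("a%03d", seq_len(n))
  rownames(geno) <- ids
  snps <- data.frame(id = sprintf("w%02d", seq_len(n_tags)), chrom = "4",
                     pos = 269000L + 1000L * seq_len(n_tags) - 2000L,
                     stringsAsFactors = FALSE)
  colnames(geno) <- snps$id
  acc <- data.frame(id = ids,
                    class = ifelse(z == 1, "functional", "nonfunctional"),
                    stringsAsFactors = FALSE)
  snp_panel(geno, snps, acc, focal = list(chrom = "4", bp = 269000L))
}

# Small RIL design used across tests: one shared QTL only, unit scales.
unit_scale_args <- function() {
  list(trait_location = c(wue = 0, ft = 0, gr = 0),
       trait_scale = c(wue = 1, ft = 1, gr = 1))
}

# two-locus RIL chain oracle: P(A at midpoint | flanking genotypes), by
# explicit matrix algebra on the two-state chain
chain_midpoint_oracle <- function(gl, gr, d_left, d_right,
                                  map_scale = "meiotic") {
  Tm <- function(d) {
    R <- ril_transition(d, map_scale)
    matrix(c(1 - R, R, R, 1 - R), 2, byrow = TRUE)  # rows/cols: A, B
  }
  il <- if (gl == 1) 1 else 2
  ir <- if (gr == 1) 1 else 2
  TL <- Tm(d_left); TR <- Tm(d_right)
  num <- TL[il, 1] * TR[1, ir]
  den <- TL[il, 1] * TR[1, ir] + TL[il, 2] * TR[2, ir]
  num / den
}
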