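#' SNP panel of inbred accessions
#'
#' Container for a biallelic, haploid-coded genotype matrix over inbred
#' accessions, with SNP coordinates, per-accession class labels
#' (functional / non-functional at the focal locus; NA = unlabeled) and
#' optional geography.
#'
#' @param geno accession x SNP matrix of 0/1 allele calls (NA = missing);
#'   rownames are accession ids, colnames SNP ids.
#' @param snps data frame with columns `id`, `chrom`, `pos` (1-based bp),
#'   one row per genotype column, positions sorted within chromosome.
#' @param accessions data frame with columns `id`, `class` and optionally
#'   `cluster`, `lat`, `lon`.
#' @param focal optional list(chrom, bp): coordinate of the focal locus.
#' @return an `snp_panel` object.
#' @export
snp_panel <- function(geno, snps, accessions, focal = NULL) {
  geno <- as.matrix(geno)
  stopifnot(ncol(geno) == nrow(snps), nrow(geno) == nrow(accessions))
  vals <- geno[!is.na(geno)]
  if (length(vals) && !all(vals %in% c(0, 1))) {
    stop("genotype coding must be binary 0/1")
  }
  for (ch in unique(snps$chrom)) {
    if (is.unsorted(snps$pos[snps$chrom == ch])) {
      stop("SNP positions not sorted on chromosome ", ch)
    }
  }
  if (is.null(rownames(geno))) rownames(geno) <- accessions$id
  if (is.null(colnames(geno))) colnames(geno) <- snps$id
  structure(list(geno = geno, snps = snps, accessions = accessions,
                 focal = focal),
            class = "snp_panel")
}

#' @export
print.snp_panel <- function(x, ...) {
  lab <- x$accessions$class
  cat(sprintf("SNP panel: %d accessions x %d SNPs (%d labeled: %d functional, %d nonfunctional)\n",
              nrow(x$geno), ncol(x$geno), sum(!is.na(lab)),
              sum(lab == "functional", na.rm = TRUE),
              sum(lab == "nonfunctional", na.rm = TRUE)))
  invisible(x)
}

.panel_labels <- function(panel, labels) {
  if (is.null(labels)) labels <- panel$accessions$class
  labels <- as.character(labels)
  lv <- sort(unique(labels[!is.na(labels)]))
  if (length(lv) != 2) stop("need exactly two label classes, got: ",
                            paste(lv, collapse = ", "))
  list(labels = labels, levels = lv)
}

# Per-SNP class allele counts for one or many label divisions.
# L: accession x B matrix, entries 1 (class 1), 0 (class 2), NA (excluded).
.class_counts <- function(G, L) {
  L <- as.matrix(L)
  Mobs <- !is.na(G)
  G0 <- G; G0[!Mobs] <- 0
  L1 <- L; L1[is.na(L1)] <- 0
  Lin <- (!is.na(L)) + 0  # in either class
  L2 <- Lin - L1
  list(x1 = crossprod(G0, L1), n1 = crossprod(Mobs + 0, L1),
       x2 = crossprod(G0, L2), n2 = crossprod(Mobs + 0, L2))
}

# Vectorized Nei and Weir-Cockerham per-SNP FST from class counts.
.fst_from_counts <- function(x1, n1, x2, n2, estimator, max_missing,
                             n_total_obs = NULL) {
  p1 <- x1 / n1; p2 <- x2 / n2
  pbar <- (x1 + x2) / (n1 + n2)
  usable <- n1 >= 2 & n2 >= 2 & pbar > 0 & pbar < 1
  if (!is.null(n_total_obs)) {
    usable <- usable & ((n1 + n2) >= (1 - max_missing) * n_total_obs)
  }
  if (estimator == "nei") {
    Ht <- 2 * pbar * (1 - pbar)
    Hs <- (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2
    fst <- (Ht - Hs) / Ht
    num <- Ht - Hs; den <- Ht
  } else {
    N <- n1 + n2
    pw <- (n1 * p1 + n2 * p2) / N
    MSP <- n1 * (p1 - pw)^2 + n2 * (p2 - pw)^2
    MSG <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (N - 2)
    nc <- N - (n1^2 + n2^2) / N
    num <- MSP - MSG
    den <- MSP + (nc - 1) * MSG
    fst <- num / den
  }
  fst[!usable] <- NA_real_
  num[!usable] <- NA_real_
  den[!usable] <- NA_real_
  list(fst = fst, num = num, den = den, usable = usable)
}

#' Per-SNP FST between focal-allele functionality classes
#'
#' Nei form: FST = (Ht - Hs)/Ht with Ht = 2p(1-p) at the pooled
#' (complete-case) allele frequency and Hs the unweighted mean of the two
#' within-class expected heterozygosities. WC form: the Weir-Cockerham
#' variance-components estimator for haploid samples (can go negative).
#' SNPs that are monomorphic in the pooled sample, have fewer than two
#' observed accessions in either class, or exceed the missingness threshold
#' are skipped and counted.
#'
#' @param panel an [snp_panel()].
#' @param labels two-class label vector (default: the panel's `class`
#'   column); accessions with NA labels are excluded.
#' @param estimator `"nei"` or `"wc"`.
#' @param max_missing skip SNPs with more than this fraction missing among
#'   labeled accessions (default 0.2).
#' @return an `fst_result`: per-SNP table (id, p per class, fst), mean FST,
#'   estimator, counts of SNPs used and skipped.
#' @export
per_snp_fst <- function(panel, labels = NULL, estimator = c("nei", "wc"),
                        max_missing = 0.2) {
  estimator <- match.arg(estimator)
  pl <- .panel_labels(panel, labels)
  keep <- !is.na(pl$labels)
  G <- panel$geno[keep, , drop = FALSE]
  lab <- pl$labels[keep]
  L <- matrix(as.numeric(lab == pl$levels[1]), ncol = 1)
  cc <- .class_counts(G, L)
  res <- .fst_from_counts(cc$x1[, 1], cc$n1[, 1], cc$x2[, 1], cc$n2[, 1],
                          estimator, max_missing, nrow(G))
  per_snp <- data.frame(id = panel$snps$id, chrom = panel$snps$chrom,
                        pos = panel$snps$pos,
                        p1 = cc$x1[, 1] / cc$n1[, 1],
                        p2 = cc$x2[, 1] / cc$n2[, 1],
                        fst = res$fst, stringsAsFactors = FALSE)
  structure(list(per_snp = per_snp,
                 mean_fst = mean(res$fst, na.rm = TRUE),
                 ratio_of_sums = sum(res$num, na.rm = TRUE) /
                   sum(res$den, na.rm = TRUE),
                 estimator = estimator, classes = pl$levels,
                 n_used = sum(res$usable), n_skipped = sum(!res$usable)),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("FST (%s, %s vs %s): mean %.4f over %d SNPs (%d skipped)\n",
              x$estimator, x$classes[1], x$classes[2], x$mean_fst,
              x$n_used, x$n_skipped))
  invisible(x)
}

#' Genome-wide FST between functionality classes
#'
#' Unweighted mean of the per-SNP values over non-skipped SNPs (Nei), or
#' optionally the ratio-of-sums aggregation of the variance components for
#' the WC estimator.
#'
#' @inheritParams per_snp_fst
#' @param aggregate `"mean"` (mean of per-SNP ratios) or `"ratio_of_sums"`.
#' @return scalar FST.
#' @export
genomewide_fst <- function(panel, labels = NULL, estimator = c("nei", "wc"),
                           aggregate = NULL, max_missing = 0.2) {
  estimator <- match.arg(estimator)
  if (is.null(aggregate)) {
    aggregate <- if (estimator == "wc") "ratio_of_sums" else "mean"
  }
  res <- per_snp_fst(panel, labels, estimator, max_missing)
  if (res$n_used == 0) stop("no usable SNPs for FST")
  if (aggregate == "mean") res$mean_fst else res$ratio_of_sums
}

#' Thin SNPs to a minimum physical spacing
#'
#' Greedy left-to-right selection per chromosome: keep the first SNP, then
#' the next SNP at least `interval_bp` downstream of the last kept one, and
#' so on. Duplicated positions keep the first occurrence only.
#'
#' @param panel an [snp_panel()].
#' @param interval_bp minimum spacing (default 50 kb).
#' @return the thinned [snp_panel()].
#' @export
thin_snps <- function(panel, interval_bp = 50000) {
  keep <- logical(nrow(panel$snps))
  for (ch in unique(panel$snps$chrom)) {
    idx <- which(panel$snps$chrom == ch)
    pos <- panel$snps$pos[idx]
    last <- -Inf
    for (j in seq_along(idx)) {
      if (pos[j] >= last + interval_bp || !is.finite(last)) {
        keep[idx[j]] <- TRUE
        last <- pos[j]
      }
    }
  }
  snp_panel(panel$geno[, keep, drop = FALSE],
            panel$snps[keep, , drop = FALSE],
            panel$accessions, panel$focal)
}

#' Regional FST within geographic clusters
#'
#' Within each cluster: thin SNPs to `interval_bp`, compute the mean pooled
#' expected heterozygosity over thinned SNPs (Ht), the mean within-class
#' heterozygosity per functionality class averaged (unweighted) over the two
#' classes (Hs), and FST = (Ht - Hs)/Ht. Clusters lacking two accessions of
#' each class are skipped and flagged. Optionally attaches a
#' frequency-matched bootstrap p-value per cluster (see
#' [frequency_matched_bootstrap()]).
#'
#' @param panel an [snp_panel()].
#' @param labels two-class labels (default: panel classes).
#' @param clusters cluster id per accession (default: panel `cluster`).
#' @param interval_bp thinning interval (default 50 kb).
#' @param n_boot if > 0, number of frequency-matched bootstrap divisions
#'   used to compute a per-cluster empirical p-value.
#' @param tolerance,boot_seed frequency-matching tolerance and seed for the
#'   bootstrap.
#' @return data frame: cluster, n per class, fst, skipped flag, and p_boot
#'   when `n_boot > 0`.
#' @export
regional_fst <- function(panel, labels = NULL, clusters = NULL,
                         interval_bp = 50000, n_boot = 0,
                         tolerance = 0.05, boot_seed = 1L) {
  pl <- .panel_labels(panel, labels)
  if (is.null(clusters)) clusters <- panel$accessions$cluster
  thinned <- thin_snps(panel, interval_bp)
  ucl <- sort(unique(clusters[!is.na(clusters)]))
  rows <- lapply(ucl, function(cl) {
    sel <- which(clusters == cl & !is.na(pl$labels))
    lab <- pl$labels[sel]
    n1 <- sum(lab == pl$levels[1]); n2 <- sum(lab == pl$levels[2])
    row <- data.frame(cluster = cl, n_class1 = n1, n_class2 = n2,
                      fst = NA_real_, skipped = TRUE, p_boot = NA_real_)
    if (n1 < 2 || n2 < 2) return(row)
    G <- thinned$geno[sel, , drop = FALSE]
    fst <- .regional_ht_hs_fst(G, lab == pl$levels[1])
    row$fst <- fst
    row$skipped <- FALSE
    if (n_boot > 0) {
      sub <- snp_panel(G, thinned$snps,
                       thinned$accessions[sel, , drop = FALSE])
      bn <- tryCatch(
        frequency_matched_bootstrap(sub, labels = lab, n_snps = n_boot,
                                    tolerance = tolerance, K = n_boot,
                                    seed = boot_seed,
                                    statistic = "ht_hs"),
        error = function(e) NULL)
      if (!is.null(bn)) row$p_boot <- bn$p_value
    }
    row
  })
  out <- do.call(rbind, rows)
  if (n_boot == 0) out$p_boot <- NULL
  rownames(out) <- NULL
  out
}

# Ht/Hs aggregate FST: mean heterozygosities over SNPs, then the ratio.
.regional_ht_hs_fst <- function(G, is_class1) {
  cc <- .class_counts(G, matrix(as.numeric(is_class1), ncol = 1))
  p1 <- cc$x1[, 1] / cc$n1[, 1]
  p2 <- cc$x2[, 1] / cc$n2[, 1]
  pbar <- (cc$x1[, 1] + cc$x2[, 1]) / (cc$n1[, 1] + cc$n2[, 1])
  ok <- is.finite(p1) & is.finite(p2) & is.finite(pbar)
  Ht <- mean(2 * pbar[ok] * (1 - pbar[ok]))
  Hs <- (mean(2 * p1[ok] * (1 - p1[ok])) +
           mean(2 * p2[ok] * (1 - p2[ok]))) / 2
  (Ht - Hs) / Ht
}
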