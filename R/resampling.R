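#' Resampling null for class-contrast FST
#'
#' [permutation_null()] relabels accessions uniformly at random, preserving
#' the exact class counts, and recomputes the genome-wide mean FST for each
#' of K random divisions. [frequency_matched_bootstrap()] instead divides
#' the accessions by the alleles of randomly chosen SNPs whose minor-allele
#' frequency is within a tolerance of the focal class frequency — a null
#' that holds the division frequency fixed at the focal locus's. The
#' dividing SNP is excluded from its own recomputed statistic (its FST is 1
#' by construction, which would bias every resample upward; the focal-locus
#' division has no counterpart SNP in the genome scan). Both report
#' the empirical p-value (1 + #\{resample >= observed\}) / (K + 1), which is
#' never zero, and are seed-reproducible.
#'
#' @param panel an [snp_panel()].
#' @param labels two-class label vector (default: panel classes).
#' @param K number of resampled divisions.
#' @param estimator `"nei"` or `"wc"` per-SNP estimator.
#' @param statistic `"mean_fst"` (unweighted mean of per-SNP FST) or
#'   `"ht_hs"` (heterozygosities averaged over SNPs first, then the ratio).
#' @param max_missing per-SNP missingness threshold.
#' @param seed integer seed.
#' @param chunk internal batch size for the vectorized resample loop.
#' @return a `resampling_null`: observed statistic, resampled statistics,
#'   empirical p-value, K and seed.
#' @export
permutation_null <- function(panel, labels = NULL, K = 5000,
                             estimator = c("nei", "wc"),
                             statistic = c("mean_fst", "ht_hs"),
                             max_missing = 0.2, seed = 1L, chunk = 200L) {
  estimator <- match.arg(estimator)
  statistic <- match.arg(statistic)
  if (K < 100) stop("K must be >= 100")
  pl <- .panel_labels(panel, labels)
  keep <- !is.na(pl$labels)
  G <- panel$geno[keep, , drop = FALSE]
  lab <- pl$labels[keep]
  n1 <- sum(lab == pl$levels[1])
  obs <- .division_statistic(G, matrix(as.numeric(lab == pl$levels[1]),
                                       ncol = 1),
                             estimator, statistic, max_missing)
  set.seed(seed)
  stats_out <- numeric(K)
  done <- 0L
  while (done < K) {
    b <- min(chunk, K - done)
    L <- vapply(seq_len(b), function(i) {
      v <- numeric(nrow(G))
      v[sample.int(nrow(G), n1)] <- 1
      v
    }, numeric(nrow(G)))
    stats_out[done + seq_len(b)] <-
      .division_statistic(G, L, estimator, statistic, max_missing)
    done <- done + b
  }
  .resampling_null(obs, stats_out, seed, method = "permutation")
}

#' @rdname permutation_null
#' @param n_snps number of frequency-matched SNPs drawn; each defines one
#'   division (K defaults to `n_snps`; if K > n_snps the extra draws are
#'   with replacement).
#' @param tolerance match SNPs whose minor-allele frequency is within
#'   +/- `tolerance` of the focal class frequency (default 0.02).
#' @export
frequency_matched_bootstrap <- function(panel, labels = NULL, n_snps = 5000,
                                        tolerance = 0.02, K = n_snps,
                                        estimator = c("nei", "wc"),
                                        statistic = c("mean_fst", "ht_hs"),
                                        max_missing = 0.2, seed = 1L,
                                        chunk = 200L) {
  estimator <- match.arg(estimator)
  statistic <- match.arg(statistic)
  pl <- .panel_labels(panel, labels)
  keep <- !is.na(pl$labels)
  G <- panel$geno[keep, , drop = FALSE]
  lab <- pl$labels[keep]
  f_focal <- mean(lab == pl$levels[1])
  f_focal <- min(f_focal, 1 - f_focal)
  obs <- .division_statistic(G, matrix(as.numeric(lab == pl$levels[1]),
                                       ncol = 1),
                             estimator, statistic, max_missing)
  freq <- colMeans(G, na.rm = TRUE)
  maf <- pmin(freq, 1 - freq)
  matched <- which(abs(maf - f_focal) <= tolerance & maf > 0)
  if (length(matched) < n_snps) {
    stop(sprintf(paste0("only %d SNPs match the focal frequency %.3f within ",
                        "+/- %.3f; %d required"),
                 length(matched), f_focal, tolerance, n_snps))
  }
  set.seed(seed)
  subset_snps <- sample(matched, n_snps)
  draw <- if (K <= n_snps) subset_snps[seq_len(K)] else
    c(subset_snps, sample(subset_snps, K - n_snps, replace = TRUE))
  stats_out <- numeric(K)
  done <- 0L
  while (done < K) {
    b <- min(chunk, K - done)
    idx <- draw[done + seq_len(b)]
    L <- G[, idx, drop = FALSE] + 0
    stats_out[done + seq_len(b)] <-
      .division_statistic(G, L, estimator, statistic, max_missing,
                          exclude = idx)
    done <- done + b
  }
  out <- .resampling_null(obs, stats_out, seed,
                          method = "frequency_matched_bootstrap")
  out$n_matched <- length(matched)
  out$tolerance <- tolerance
  out$focal_frequency <- f_focal
  out$snps_drawn <- panel$snps$id[draw]
  out
}

# statistic for one or many divisions given as columns of L (1/0/NA);
# exclude[b], if given, drops that SNP from column b's statistic (used for
# SNP-defined divisions, whose dividing SNP has FST 1 by construction)
.division_statistic <- function(G, L, estimator, statistic, max_missing,
                                exclude = NULL) {
  cc <- .class_counts(G, L)
  keep_for <- function(b) {
    if (is.null(exclude)) seq_len(nrow(cc$x1)) else
      seq_len(nrow(cc$x1))[-exclude[b]]
  }
  if (statistic == "ht_hs") {
    return(vapply(seq_len(ncol(cc$x1)), function(b) {
      k <- keep_for(b)
      p1 <- cc$x1[k, b] / cc$n1[k, b]; p2 <- cc$x2[k, b] / cc$n2[k, b]
      pbar <- (cc$x1[k, b] + cc$x2[k, b]) / (cc$n1[k, b] + cc$n2[k, b])
      ok <- is.finite(p1) & is.finite(p2) & is.finite(pbar) &
        cc$n1[k, b] >= 2 & cc$n2[k, b] >= 2
      Ht <- mean(2 * pbar[ok] * (1 - pbar[ok]))
      Hs <- (mean(2 * p1[ok] * (1 - p1[ok])) +
               mean(2 * p2[ok] * (1 - p2[ok]))) / 2
      (Ht - Hs) / Ht
    }, numeric(1)))
  }
  vapply(seq_len(ncol(cc$x1)), function(b) {
    k <- keep_for(b)
    res <- .fst_from_counts(cc$x1[k, b], cc$n1[k, b], cc$x2[k, b],
                            cc$n2[k, b], estimator, max_missing, nrow(G))
    if (estimator == "wc") {
      sum(res$num, na.rm = TRUE) / sum(res$den, na.rm = TRUE)
    } else {
      mean(res$fst, na.rm = TRUE)
    }
  }, numeric(1))
}

.resampling_null <- function(observed, resamples, seed, method) {
  K <- length(resamples)
  structure(list(observed = observed, resamples = resamples, K = K,
                 p_value = (1 + sum(resamples >= observed)) / (K + 1),
                 seed = seed, method = method),
            class = "resampling_null")
}

#' @export
print.resampling_null <- function(x, ...) {
  cat(sprintf("%s null: observed %.4f, K = %d, empirical p = %.4g\n",
              x$method, x$observed, x$K, x$p_value))
  invisible(x)
}
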