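#' Single-trait genome scan by Haley-Knott regression
#'
#' Regresses the phenotype on the expected parent-A genotype dosage at every
#' grid position and reports LOD(x) = (n/2) log10(RSS0 / RSS1(x)), the
#' likelihood-odds of a single QTL at x versus none under a Gaussian model.
#' RSS1 is floored at 1e-12 * RSS0 so degenerate perfect fits yield a large
#' finite LOD. Missing phenotypes are dropped. The genome-wide argmax
#' resolves ties to the lowest (chromosome, position).
#'
#' @param probs a [genotype_probabilities()] object.
#' @param phenotype numeric vector, one value per line (NA allowed).
#' @param trait optional trait name carried into the profile.
#' @return a `lod_profile` data frame (chrom, pos, lod) with attributes
#'   `trait`, `max_lod`, `peak` (chrom, pos).
#' @export
scan_trait <- function(probs, phenotype, trait = "trait") {
  stopifnot(inherits(probs, "genotype_probs"))
  if (length(phenotype) != probs$n_lines) {
    stop("phenotype length must equal the number of lines")
  }
  keep <- !is.na(phenotype)
  y <- phenotype[keep]
  X <- probs$P[keep, , drop = FALSE]
  n <- length(y)
  yc <- y - mean(y)
  ssy <- sum(yc^2)
  if (ssy <= 0) {
    warning("zero phenotypic variance; LOD profile is identically zero")
    lod <- rep(0, ncol(X))
  } else {
    Xc <- sweep(X, 2, colMeans(X))
    ssx <- colSums(Xc^2)
    sxy <- as.numeric(crossprod(Xc, yc))
    rss1 <- ssy - ifelse(ssx > 0, sxy^2 / ssx, 0)
    rss1 <- pmax(rss1, 1e-12 * ssy)
    lod <- (n / 2) * log10(ssy / rss1)
  }
  .lod_profile(probs$grid, lod, trait)
}

.lod_profile <- function(grid, lod, trait) {
  prof <- data.frame(chrom = grid$chrom, pos = grid$pos, lod = lod,
                     stringsAsFactors = FALSE)
  peak_i <- which.max(lod)  # first max = lowest (chrom, pos) in grid order
  structure(prof, trait = trait, max_lod = lod[peak_i],
            peak = list(chrom = grid$chrom[peak_i], pos = grid$pos[peak_i],
                        index = peak_i),
            class = c("lod_profile", "data.frame"))
}

# genome-wide max LOD for many phenotype columns at once
.max_lod_multi <- function(Xc, ssx, Y) {
  n <- nrow(Y)
  Yc <- sweep(Y, 2, colMeans(Y))
  ssy <- colSums(Yc^2)
  SXY <- crossprod(Xc, Yc)                       # positions x perms
  ratio <- sweep(SXY^2, 1, ifelse(ssx > 0, ssx, Inf), "/")
  rss1_min <- pmax(sweep(-ratio, 2, ssy, "+") |> apply(2, min),
                   1e-12 * ssy)
  (n / 2) * log10(ssy / rss1_min)
}

#' Permutation threshold for the genome scan
#'
#' Shuffles the phenotype across lines, rescans, and records the genome-wide
#' maximum LOD of each permutation. The threshold is the k-th largest
#' maximum with k = floor(alpha * (n_perm + 1)), the order statistic whose
#' exceedance probability under the null is alpha (capped to the smallest
#' maximum at alpha = 1).
#'
#' @inheritParams scan_trait
#' @param n_perm number of permutations (>= 100).
#' @param alpha experiment-wise type-I error rate, in (0, 1].
#' @param seed integer seed.
#' @return scalar LOD threshold with attributes `maxima` and `alpha`.
#' @export
permutation_threshold <- function(probs, phenotype, n_perm = 1000,
                                  alpha = 0.05, seed = 1L) {
  stopifnot(inherits(probs, "genotype_probs"))
  if (n_perm < 100) stop("n_perm must be >= 100")
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1) {
    stop("alpha must lie in (0, 1]")
  }
  keep <- !is.na(phenotype)
  y <- phenotype[keep]
  X <- probs$P[keep, , drop = FALSE]
  Xc <- sweep(X, 2, colMeans(X))
  ssx <- colSums(Xc^2)
  set.seed(seed)
  maxima <- numeric(n_perm)
  done <- 0L
  while (done < n_perm) {
    b <- min(500L, n_perm - done)
    Y <- vapply(seq_len(b), function(i) y[sample.int(length(y))],
                numeric(length(y)))
    maxima[done + seq_len(b)] <- .max_lod_multi(Xc, ssx, Y)
    done <- done + b
  }
  k <- min(n_perm, max(1L, floor(alpha * (n_perm + 1))))
  thr <- sort(maxima, decreasing = TRUE)[k]
  structure(thr, maxima = maxima, alpha = alpha, n_perm = n_perm)
}
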