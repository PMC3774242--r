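#' Multiple-QTL additive model machinery
#'
#' A `qtl_model` is a data frame with one row per QTL (chrom, pos, effect,
#' pve, lod) plus attributes `model_lod` (joint-model LOD against the null),
#' `penalized_lod` and the grid indices of the QTLs. Effects are reported as
#' the fitted difference between the parent-A and parent-B homozygote
#' classes in trait units; PVE is the drop-one sum of squares as a
#' percentage of the total; the per-QTL LOD is the drop-one LOD
#' (n/2) log10(RSS_without / RSS_full).
#'
#' @name qtl_model
NULL

.qtl_model <- function(grid, idx, effect = numeric(0), pve = numeric(0),
                       lod = numeric(0), model_lod = 0,
                       penalized_lod = NA_real_, penalty = NA_real_) {
  df <- data.frame(chrom = grid$chrom[idx], pos = grid$pos[idx],
                   effect = if (length(effect)) effect else
                     rep(NA_real_, length(idx)),
                   pve = if (length(pve)) pve else rep(NA_real_, length(idx)),
                   lod = if (length(lod)) lod else rep(NA_real_, length(idx)),
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  structure(df, grid_index = idx, model_lod = model_lod,
            penalized_lod = penalized_lod, penalty = penalty,
            class = c("qtl_model", "data.frame"))
}

#' @export
print.qtl_model <- function(x, ...) {
  cat(sprintf("QTL model: %d QTL, model LOD %.2f", nrow(x),
              attr(x, "model_lod")))
  if (is.finite(attr(x, "penalized_lod"))) {
    cat(sprintf(" (penalized %.2f)", attr(x, "penalized_lod")))
  }
  cat("\n")
  if (nrow(x)) print.data.frame(x, digits = 4)
  invisible(x)
}

.model_matrices <- function(probs, phenotype) {
  keep <- !is.na(phenotype)
  y <- phenotype[keep]
  list(X = probs$P[keep, , drop = FALSE], y = y, n = length(y),
       sst = sum((y - mean(y))^2))
}

.model_rss <- function(X, y, idx) {
  if (!length(idx)) return(sum((y - mean(y))^2))
  fit <- stats::lm.fit(cbind(1, X[, idx, drop = FALSE]), y)
  sum(fit$residuals^2)
}

.lod_from_rss <- function(n, sst, rss) {
  rss <- max(rss, 1e-12 * sst)
  (n / 2) * log10(sst / rss)
}

# RSS of model idx + each single candidate column, vectorized over candidates
.forward_rss <- function(X, y, idx) {
  C <- cbind(1, X[, idx, drop = FALSE])
  qrC <- qr(C)
  yr <- qr.resid(qrC, y)
  Xr <- X - qr.fitted(qrC, X)
  ssxr <- colSums(Xr^2)
  sxy <- as.numeric(crossprod(Xr, yr))
  rss_c <- sum(yr^2)
  rss <- rss_c - ifelse(ssxr > 1e-10, sxy^2 / ssxr, 0)
  list(rss = rss, rss_current = rss_c)
}

#' Construct an unfitted QTL model at given grid positions
#'
#' @param grid a [build_grid()] pseudo-marker grid.
#' @param chrom,pos parallel vectors of QTL locations; each must match a
#'   grid position exactly.
#' @return an unfitted [qtl_model] (pass to [fit_model()] or
#'   [refine_positions()]).
#' @export
qtl_model_at <- function(grid, chrom, pos) {
  stopifnot(length(chrom) == length(pos))
  idx <- vapply(seq_along(chrom), function(j) {
    w <- which(grid$chrom == as.character(chrom[j]) &
                 abs(grid$pos - pos[j]) < 1e-8)
    if (!length(w)) stop("position off the grid: ", chrom[j], "@", pos[j])
    w[1]
  }, integer(1))
  .qtl_model(grid, idx)
}

#' Forward-backward additive QTL model selection
#'
#' Forward step: add the grid position that maximizes the joint-model LOD,
#' accepting while the penalized LOD (model LOD minus penalty per QTL)
#' increases. Backward step: drop QTLs while dropping increases the
#' penalized LOD. The returned model is fitted (effects, PVE, drop-one LOD)
#' via [fit_model()].
#'
#' @param probs a [genotype_probabilities()] object.
#' @param phenotype numeric phenotype vector.
#' @param penalty positive LOD penalty per QTL, typically a
#'   [permutation_threshold()].
#' @param max_qtl cap on model size.
#' @return a [qtl_model].
#' @export
stepwise_additive <- function(probs, phenotype, penalty, max_qtl = 10L) {
  if (!is.numeric(penalty) || penalty <= 0) stop("penalty must be positive")
  mm <- .model_matrices(probs, phenotype)
  idx <- integer(0)
  plod <- 0
  repeat {
    if (length(idx) >= max_qtl) break
    fr <- .forward_rss(mm$X, mm$y, idx)
    fr$rss[idx] <- Inf
    best <- which.min(fr$rss)
    new_lod <- .lod_from_rss(mm$n, mm$sst, fr$rss[best])
    new_plod <- new_lod - penalty * (length(idx) + 1)
    if (!is.finite(new_plod) || new_plod <= plod + 1e-8) break
    idx <- c(idx, best)
    plod <- new_plod
  }
  # backward pruning
  repeat {
    if (!length(idx)) break
    drop_plod <- vapply(seq_along(idx), function(j) {
      .lod_from_rss(mm$n, mm$sst, .model_rss(mm$X, mm$y, idx[-j])) -
        penalty * (length(idx) - 1)
    }, numeric(1))
    j <- which.max(drop_plod)
    if (drop_plod[j] > plod + 1e-8) {
      idx <- idx[-j]
      plod <- drop_plod[j]
    } else break
  }
  fit_model(.qtl_model(probs$grid, idx), probs, phenotype, penalty = penalty)
}

#' Iterative QTL position refinement
#'
#' Cycles over the QTLs of a model, re-scanning the position of one QTL at
#' a time with the others held fixed and moving it to the grid position that
#' maximizes the joint-model LOD. Iterates to a fixed point; the model LOD
#' is non-decreasing across moves. Ties resolve to the lowest grid index.
#'
#' @param model a [qtl_model].
#' @param probs a [genotype_probabilities()] object.
#' @param phenotype numeric phenotype vector.
#' @param max_iter cycle cap.
#' @return the refined, refitted [qtl_model].
#' @export
refine_positions <- function(model, probs, phenotype, max_iter = 25L) {
  idx <- attr(model, "grid_index")
  if (!length(idx)) stop("model is empty; nothing to refine")
  mm <- .model_matrices(probs, phenotype)
  penalty <- attr(model, "penalty")
  for (iter in seq_len(max_iter)) {
    moved <- FALSE
    for (j in seq_along(idx)) {
      fr <- .forward_rss(mm$X, mm$y, idx[-j])
      fr$rss[setdiff(idx, idx[j])] <- Inf
      best <- which.min(fr$rss)
      if (best != idx[j] && fr$rss[best] <
            .model_rss(mm$X, mm$y, idx) - 1e-9 * mm$sst) {
        idx[j] <- best
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  fit_model(.qtl_model(probs$grid, idx), probs, phenotype, penalty = penalty)
}

#' Fit a multiple-QTL model: effects, PVE and drop-one LOD
#'
#' Joint linear regression of the phenotype on the expected genotype dosages
#' at the model positions. Per-QTL percent variance explained is the
#' drop-one sum of squares over the total sum of squares; the drop-one LOD
#' is (n/2) log10(RSS_without / RSS_full). Collinear dosage columns get a
#' drop-one LOD of 0 with a warning.
#'
#' @param model a [qtl_model] (positions on the grid).
#' @param probs a [genotype_probabilities()] object.
#' @param phenotype numeric phenotype vector.
#' @param penalty optional penalty used to report the penalized model LOD.
#' @return the fitted [qtl_model].
#' @export
fit_model <- function(model, probs, phenotype, penalty = NULL) {
  idx <- attr(model, "grid_index")
  if (is.null(idx)) {
    idx <- vapply(seq_len(nrow(model)), function(j) {
      w <- which(probs$grid$chrom == model$chrom[j] &
                   abs(probs$grid$pos - model$pos[j]) < 1e-8)
      if (!length(w)) stop("model position off the grid: ",
                           model$chrom[j], "@", model$pos[j])
      w[1]
    }, integer(1))
  }
  if (is.null(penalty)) penalty <- attr(model, "penalty")
  if (is.null(penalty)) penalty <- NA_real_
  mm <- .model_matrices(probs, phenotype)
  if (!length(idx)) {
    return(.qtl_model(probs$grid, idx, model_lod = 0,
                      penalized_lod = if (is.finite(penalty)) 0 else NA_real_,
                      penalty = penalty))
  }
  D <- mm$X[, idx, drop = FALSE]
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, D), mm$y)
  rss_full <- sum(fit$residuals^2)
  model_lod <- .lod_from_rss(mm$n, mm$sst, rss_full)
  effect <- fit$coefficients[-1]
  aliased <- is.na(effect)
  if (any(aliased)) {
    warning("collinear dosage columns; drop-one LOD reported as 0 for: ",
            paste(idx[aliased], collapse = ", "))
    effect[aliased] <- 0
  }
  drop_lod <- numeric(length(idx))
  pve <- numeric(length(idx))
  for (j in seq_along(idx)) {
    rss_wo <- .model_rss(mm$X, mm$y, idx[-j])
    drop_lod[j] <- if (aliased[j]) 0 else
      (mm$n / 2) * log10(max(rss_wo, 1e-12 * mm$sst) /
                           max(rss_full, 1e-12 * mm$sst))
    pve[j] <- 100 * max(0, rss_wo - rss_full) / mm$sst
  }
  .qtl_model(probs$grid, idx, effect = as.numeric(effect), pve = pve,
             lod = drop_lod, model_lod = model_lod,
             penalized_lod = if (is.finite(penalty))
               model_lod - penalty * length(idx) else NA_real_,
             penalty = penalty)
}
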