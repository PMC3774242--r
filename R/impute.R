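#' Extract the SNP feature window around the focal locus
#'
#' Selects every SNP whose position lies within the closed interval
#' \[focal - half_span, focal + half_span\] on the focal chromosome and
#' builds the accession x SNP 0/1 feature matrix. Missing entries are filled
#' with the SNP's major allele (complete-case majority; ties fill with 0),
#' with a message reporting how many entries were filled.
#'
#' @param panel an [snp_panel()].
#' @param focal list(chrom, bp) focal coordinate (default: the panel's).
#' @param half_span_bp window half-span in bp (default 100 kb).
#' @return a `feature_window`: feature matrix `X`, SNP ids, focal
#'   coordinate and half-span.
#' @export
extract_window <- function(panel, focal = NULL, half_span_bp = 100000) {
  if (is.null(focal)) focal <- panel$focal
  if (is.null(focal)) stop("no focal coordinate available")
  if (half_span_bp < 0) stop("half_span_bp must be non-negative")
  sel <- which(panel$snps$chrom == focal$chrom &
                 abs(panel$snps$pos - focal$bp) <= half_span_bp)
  if (!length(sel)) stop("no SNPs within the window around the focal locus")
  X <- panel$geno[, sel, drop = FALSE]
  n_missing <- sum(is.na(X))
  if (n_missing > 0) {
    for (j in seq_len(ncol(X))) {
      miss <- is.na(X[, j])
      if (any(miss)) {
        major <- as.integer(mean(X[!miss, j]) > 0.5)
        X[miss, j] <- if (any(!miss)) major else 0L
      }
    }
    message(n_missing, " missing window entries filled with the major allele")
  }
  structure(list(X = X, snp_ids = panel$snps$id[sel], focal = focal,
                 half_span_bp = half_span_bp,
                 n_missing_filled = n_missing),
            class = "feature_window")
}

#' Radial-basis-kernel classifier grid and CV settings
#'
#' @param gamma_grid RBF kernel width parameters (gamma in
#'   exp(-gamma ||u - v||^2)).
#' @param cost_grid regularization (soft-margin cost) parameters.
#' @param inner_folds folds of the inner CV used by the grid search.
#' @return a `classifier_spec`.
#' @export
classifier_spec <- function(gamma_grid = 2^seq(-6, 2, by = 2),
                            cost_grid = 2^seq(-2, 6, by = 2),
                            inner_folds = 3L) {
  if (!length(gamma_grid) || !length(cost_grid)) stop("empty parameter grid")
  if (any(gamma_grid <= 0) || any(cost_grid <= 0)) {
    stop("kernel width and regularization must be positive")
  }
  structure(list(gamma_grid = sort(gamma_grid), cost_grid = sort(cost_grid),
                 inner_folds = as.integer(inner_folds)),
            class = "classifier_spec")
}

# stratified fold assignment: per class, shuffled and dealt round-robin
.stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

.svm_fit <- function(X, y, gamma, cost) {
  e1071::svm(x = X, y = y, kernel = "radial", gamma = gamma, cost = cost,
             scale = FALSE)
}

.svm_acc <- function(model, X, y) mean(predict(model, X) == y)

# inner-CV grid search; ties -> smallest cost, then smallest gamma
.grid_search <- function(X, y, spec) {
  k <- min(spec$inner_folds, min(table(y)))
  grid <- expand.grid(gamma = spec$gamma_grid, cost = spec$cost_grid)
  grid <- grid[order(grid$cost, grid$gamma), ]
  if (k < 2) {  # too few per class for an inner split: take mid-grid values
    return(list(gamma = stats::median(spec$gamma_grid),
                cost = stats::median(spec$cost_grid), accuracy = NA_real_))
  }
  fold <- .stratified_folds(as.character(y), k)
  acc <- vapply(seq_len(nrow(grid)), function(g) {
    mean(vapply(seq_len(k), function(f) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2) return(NA_real_)
      m <- .svm_fit(X[tr, , drop = FALSE], y[tr], grid$gamma[g], grid$cost[g])
      .svm_acc(m, X[!tr, , drop = FALSE], y[!tr])
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  best <- which.max(acc)  # first max in (cost, gamma) order
  list(gamma = grid$gamma[best], cost = grid$cost[best],
       accuracy = acc[best])
}

#' Train the functionality classifier on a feature window
#'
#' Grid search over (kernel width, regularization) pairs by stratified
#' inner cross-validation on the labeled accessions, ties resolved to the
#' smallest regularization then the smallest width; the final model is
#' refit on all labeled data at the selected pair.
#'
#' @param window a [extract_window()] feature window.
#' @param labels class label per panel accession (NA = unlabeled).
#' @param spec a [classifier_spec()].
#' @param seed integer seed (inner fold assignment).
#' @return a `functionality_classifier` (svm fit, selected parameters,
#'   training ids).
#' @export
train_classifier <- function(window, labels, spec = classifier_spec(),
                             seed = 1L) {
  stopifnot(inherits(window, "feature_window"))
  lab <- as.character(labels)
  keep <- !is.na(lab)
  if (length(unique(lab[keep])) < 2) stop("need two labeled classes")
  if (min(table(lab[keep])) < 2) stop("need >= 2 labeled accessions per class")
  X <- window$X[keep, , drop = FALSE]
  y <- factor(lab[keep])
  set.seed(seed)
  gs <- .grid_search(X, y, spec)
  model <- .svm_fit(X, y, gs$gamma, gs$cost)
  structure(list(model = model, gamma = gs$gamma, cost = gs$cost,
                 inner_cv_accuracy = gs$accuracy,
                 snp_ids = window$snp_ids, focal = window$focal,
                 half_span_bp = window$half_span_bp,
                 classes = levels(y), train_ids = rownames(window$X)[keep],
                 seed = seed),
            class = "functionality_classifier")
}

#' @export
print.functionality_classifier <- function(x, ...) {
  cat(sprintf("RBF-kernel functionality classifier: %d SNPs, gamma = %g, cost = %g",
              length(x$snp_ids), x$gamma, x$cost))
  if (is.finite(x$inner_cv_accuracy)) {
    cat(sprintf(", inner-CV accuracy %.3f", x$inner_cv_accuracy))
  }
  cat("\n")
  invisible(x)
}

.cv_report <- function(protocol, fold_acc, n, repeats, seed, extra = NULL) {
  out <- c(list(protocol = protocol, fold_accuracies = fold_acc,
                mean_accuracy = mean(fold_acc), n = n, repeats = repeats,
                seed = seed), extra)
  class(out) <- "cv_report"
  out
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%s CV: mean accuracy %.3f over %d folds/repeats (n = %d)\n",
              x$protocol, x$mean_accuracy, length(x$fold_accuracies), x$n))
  invisible(x)
}

#' Stratified k-fold cross-validation of the functionality classifier
#'
#' The hyperparameter grid search runs inside each training split only (no
#' information leaks from a held-out fold into model selection).
#'
#' @param window a [extract_window()] feature window.
#' @param labels class labels (NA = unlabeled, excluded).
#' @param k number of folds (default 4).
#' @param spec a [classifier_spec()].
#' @param seed integer seed.
#' @return a `cv_report` with per-fold and mean accuracy.
#' @export
kfold_cv <- function(window, labels, k = 4L, spec = classifier_spec(),
                     seed = 1L) {
  lab <- as.character(labels)
  keep <- which(!is.na(lab))
  X <- window$X[keep, , drop = FALSE]
  y <- factor(lab[keep])
  if (k < 2) stop("k must be >= 2")
  if (min(table(y)) < k) stop("stratified ", k, "-fold split infeasible")
  set.seed(seed)
  fold <- .stratified_folds(as.character(y), k)
  acc <- vapply(seq_len(k), function(f) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2) stop("class absent from a training split")
    gs <- .grid_search(X[tr, , drop = FALSE], y[tr], spec)
    m <- .svm_fit(X[tr, , drop = FALSE], y[tr], gs$gamma, gs$cost)
    .svm_acc(m, X[!tr, , drop = FALSE], y[!tr])
  }, numeric(1))
  .cv_report(sprintf("%d-fold", k), acc, n = length(keep), repeats = 1L,
             seed = seed)
}

#' Leave-one-out cross-validation on random accession subsets
#'
#' For each repeat, draws `n` labeled accessions at random (redrawing up to
#' 100 times if a draw lands single-class), runs leave-one-out CV within the
#' subset — the grid search runs inside each training split — and records
#' the subset accuracy; reports the per-repeat accuracies and their mean.
#'
#' @param window a [extract_window()] feature window.
#' @param labels class labels (NA = unlabeled, excluded).
#' @param n subset size (<= number of labeled accessions).
#' @param repeats random subsets drawn (default 20).
#' @param spec a [classifier_spec()].
#' @param seed integer seed.
#' @return a `cv_report`; `fold_accuracies` holds one accuracy per repeat.
#' @export
subset_loocv <- function(window, labels, n, repeats = 20L,
                         spec = classifier_spec(), seed = 1L) {
  lab <- as.character(labels)
  keep <- which(!is.na(lab))
  if (n > length(keep)) stop("n exceeds the number of labeled accessions")
  X <- window$X[keep, , drop = FALSE]
  y <- factor(lab[keep])
  set.seed(seed)
  acc <- vapply(seq_len(repeats), function(rep_i) {
    sub <- NULL
    for (attempt in seq_len(100L)) {
      cand <- sample(seq_along(keep), n)
      if (length(unique(y[cand])) == 2) { sub <- cand; break }
    }
    if (is.null(sub)) stop("could not draw a two-class subset of size ", n)
    correct <- vapply(seq_len(n), function(i) {
      tr <- sub[-i]
      if (length(unique(y[tr])) < 2) return(NA_real_)
      gs <- .grid_search(X[tr, , drop = FALSE], y[tr], spec)
      m <- .svm_fit(X[tr, , drop = FALSE], y[tr], gs$gamma, gs$cost)
      as.numeric(predict(m, X[sub[i], , drop = FALSE]) == y[sub[i]])
    }, numeric(1))
    mean(correct, na.rm = TRUE)
  }, numeric(1))
  .cv_report("subset-LOO", acc, n = n, repeats = repeats, seed = seed)
}

#' Impute functionality labels for all accessions
#'
#' Predicts the focal-locus functionality class for every accession from its
#' window SNPs; accessions with an observed label keep it. Accessions
#' missing every window SNP are labeled NA and excluded downstream. The
#' decision-function margin is reported per accession, signed so that
#' positive margins correspond to the predicted class being the model's
#' first class.
#'
#' @param classifier a [train_classifier()] fit.
#' @param panel an [snp_panel()].
#' @return data frame: id, class (observed or imputed), margin, source
#'   (`"observed"` / `"imputed"` / `"unknown"`).
#' @export
impute_labels <- function(classifier, panel) {
  sel <- match(classifier$snp_ids, panel$snps$id)
  if (anyNA(sel)) stop("panel lacks window SNPs used by the classifier")
  X <- panel$geno[, sel, drop = FALSE]
  all_missing <- rowSums(!is.na(X)) == 0
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (any(miss)) {
      obs <- X[!miss, j]
      X[miss, j] <- if (length(obs)) as.integer(mean(obs) > 0.5) else 0L
    }
  }
  pred <- predict(classifier$model, X, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  # libsvm convention: positive decision value = the first class of the pair
  first_class <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
  margin <- as.numeric(dv[, 1])
  observed <- panel$accessions$class
  cls <- as.character(pred)
  src <- ifelse(is.na(observed), "imputed", "observed")
  cls[!is.na(observed)] <- observed[!is.na(observed)]
  cls[all_missing & is.na(observed)] <- NA_character_
  src[all_missing & is.na(observed)] <- "unknown"
  out <- data.frame(id = panel$accessions$id, class = cls,
                    predicted = as.character(pred), margin = margin,
                    source = src, stringsAsFactors = FALSE)
  attr(out, "margin_positive_class") <- first_class
  out
}
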