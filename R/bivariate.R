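#' Standardize a LOD profile by its genome-wide maximum
#'
#' Divides every LOD value by the profile's maximum so the standardized
#' profile peaks at exactly 1. Standardization is idempotent and invariant
#' to positive rescaling of the raw LODs. An all-zero profile cannot be
#' standardized.
#'
#' @param profile a `lod_profile` from [scan_trait()].
#' @return a `lod_profile` with an additional `stand_lod` column and
#'   attribute `standardized = TRUE`.
#' @export
standardize_profile <- function(profile) {
  stopifnot(inherits(profile, "lod_profile"))
  mx <- max(profile$lod)
  if (mx <= 0) stop("all-zero LOD profile: standardization undefined")
  out <- profile
  out$stand_lod <- out$lod / mx
  attr(out, "standardized") <- TRUE
  out
}

#' Sum two standardized LOD profiles into a bivariate profile
#'
#' The bivariate co-localization score at grid position x is
#' S(x) = stand_LOD_1(x) + stand_LOD_2(x), so 0 <= S(x) <= 2 with S near 2
#' only where both traits' profiles approach their own maxima. The joint
#' peak is the argmax of S (ties resolve to the lowest chromosome and
#' position).
#'
#' @param p1,p2 standardized profiles from [standardize_profile()] on the
#'   same grid.
#' @return a `bivariate_profile` data frame (chrom, pos, stand_lod_1,
#'   stand_lod_2, score) with attributes `traits`, `peak` and the raw
#'   profiles' LODs retained as `lod_1`, `lod_2` columns.
#' @export
sum_profiles <- function(p1, p2) {
  stopifnot(inherits(p1, "lod_profile"), inherits(p2, "lod_profile"))
  if (is.null(p1$stand_lod) || is.null(p2$stand_lod)) {
    stop("profiles must be standardized first (standardize_profile)")
  }
  if (nrow(p1) != nrow(p2) || any(p1$chrom != p2$chrom) ||
      any(abs(p1$pos - p2$pos) > 1e-9)) {
    stop("profiles are on different grids")
  }
  score <- p1$stand_lod + p2$stand_lod
  peak_i <- which.max(score)
  bp <- data.frame(chrom = p1$chrom, pos = p1$pos,
                   lod_1 = p1$lod, lod_2 = p2$lod,
                   stand_lod_1 = p1$stand_lod, stand_lod_2 = p2$stand_lod,
                   score = score, stringsAsFactors = FALSE)
  structure(bp,
            traits = c(attr(p1, "trait"), attr(p2, "trait")),
            peak = list(chrom = bp$chrom[peak_i], pos = bp$pos[peak_i],
                        index = peak_i, score = score[peak_i]),
            class = c("bivariate_profile", "data.frame"))
}

#' @export
print.bivariate_profile <- function(x, ...) {
  pk <- attr(x, "peak")
  cat(sprintf("Bivariate profile (%s + %s): joint peak chr %s @ %.1f cM, S = %.3f\n",
              attr(x, "traits")[1], attr(x, "traits")[2],
              pk$chrom, pk$pos, pk$score))
  invisible(x)
}

#' Bivariate QTL interval around the joint peak
#'
#' Contiguous interval on the joint peak's chromosome. Under the default
#' `peak_fraction` rule the interval extends from the peak until the summed
#' score first falls below `param * S(peak)` on each side (param in (0, 1);
#' as param approaches 1 the interval shrinks to the peak grid point).
#' The `literal` rule follows the source wording of the statistic: the
#' crossing threshold at x is the positionwise average of the two
#' unstandardized LOD profiles rescaled so its maximum matches the summed
#' profile's maximum; the interval extends while S(x) stays at or above that
#' threshold. The literal reading is near-degenerate (the threshold tracks
#' S itself) and is kept only as a documented alternative.
#'
#' @param bp a [sum_profiles()] bivariate profile.
#' @param rule `"peak_fraction"` (default) or `"literal"`.
#' @param param fraction of the peak score for `peak_fraction` (default 0.5).
#' @return list(chrom, start, end, peak_pos, rule, param); the interval
#'   always contains the joint peak.
#' @export
bivariate_interval <- function(bp, rule = c("peak_fraction", "literal"),
                               param = 0.5) {
  stopifnot(inherits(bp, "bivariate_profile"))
  rule <- match.arg(rule)
  pk <- attr(bp, "peak")
  sel <- which(bp$chrom == pk$chrom)
  pos <- bp$pos[sel]
  S <- bp$score[sel]
  pi <- match(pk$index, sel)
  if (rule == "peak_fraction") {
    if (!is.numeric(param) || param <= 0 || param >= 1) {
      stop("peak_fraction param must lie in (0, 1)")
    }
    thr <- rep(param * pk$score, length(sel))
  } else {
    avg <- (bp$lod_1[sel] + bp$lod_2[sel]) / 2
    mx <- max(avg)
    if (mx <= 0) stop("flat average profile; literal rule undefined")
    thr <- avg / mx * max(S)
  }
  lo <- pi
  while (lo > 1 && S[lo - 1] >= thr[lo - 1]) lo <- lo - 1
  hi <- pi
  while (hi < length(S) && S[hi + 1] >= thr[hi + 1]) hi <- hi + 1
  list(chrom = pk$chrom, start = pos[lo], end = pos[hi],
       peak_pos = pk$pos, rule = rule,
       param = if (rule == "peak_fraction") param else NA_real_)
}
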