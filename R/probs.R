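#' Conditional genotype probabilities on the pseudo-marker grid
#'
#' For every line and grid position, the probability that the line carries
#' the parent-A homozygote, conditioning on the nearest informative flanking
#' markers under the two-state Markov chain on the RIL scale: the transition
#' probability between positions d cM apart is [ril_transition()] on the
#' grid's map scale. At a fully observed marker the probability is exactly
#' 0 or 1; a line missing every marker on a chromosome falls back to the
#' marginal 0.5 with a warning.
#'
#' @param panel a `ril_panel` (genotype matrix coded 1 = parent A homozygote,
#'   0 = parent B homozygote, NA = missing).
#' @param grid a [build_grid()] pseudo-marker grid over the panel's map.
#' @param map_scale override of the grid's map scale (`"ril"`/`"meiotic"`).
#' @return a `genotype_probs` object: line x grid-position probability
#'   matrix `P` plus the grid.
#' @export
genotype_probabilities <- function(panel, grid, map_scale = NULL) {
  stopifnot(inherits(grid, "pseudo_grid"))
  if (is.null(map_scale)) map_scale <- attr(grid, "map_scale")
  if (is.null(map_scale)) map_scale <- "ril"
  geno <- panel$geno
  map <- panel$map
  n <- nrow(geno)
  P <- matrix(NA_real_, n, nrow(grid))
  n_uninformative <- 0L
  for (ch in unique(grid$chrom)) {
    gsel <- which(grid$chrom == ch)
    gpos <- grid$pos[gsel]
    msel <- which(map$chrom == ch)
    mpos <- map$pos[msel]
    Gm <- geno[, map$marker[msel], drop = FALSE]
    complete <- !rowSums(is.na(Gm))
    if (any(complete)) {
      P[complete, gsel] <- .probs_complete(Gm[complete, , drop = FALSE],
                                           mpos, gpos, map_scale)
    }
    for (i in which(!complete)) {
      obs <- which(!is.na(Gm[i, ]))
      if (!length(obs)) {
        P[i, gsel] <- 0.5
        n_uninformative <- n_uninformative + 1L
        next
      }
      P[i, gsel] <- .probs_line(Gm[i, obs], mpos[obs], gpos, map_scale)
    }
  }
  if (n_uninformative > 0) {
    warning(n_uninformative, " line-chromosome(s) with no informative ",
            "markers; probabilities set to the marginal 0.5")
  }
  rownames(P) <- rownames(geno)
  structure(list(P = P, grid = grid, map_scale = map_scale,
                 n_lines = n), class = "genotype_probs")
}

# all lines fully observed: flanking indices shared across lines
.probs_complete <- function(Gm, mpos, gpos, map_scale) {
  n <- nrow(Gm)
  li <- findInterval(gpos, mpos)
  ri <- li + 1L
  exact <- match(round(gpos, 9), round(mpos, 9))
  is_exact <- !is.na(exact)
  li[is_exact] <- exact[is_exact]
  ri[is_exact] <- exact[is_exact]
  left_only <- !is_exact & ri > length(mpos)
  right_only <- !is_exact & li < 1L
  both <- !is_exact & !left_only & !right_only

  out <- matrix(NA_real_, n, length(gpos))
  if (any(is_exact)) out[, is_exact] <- Gm[, li[is_exact], drop = FALSE]
  if (any(left_only)) {
    RL <- ril_transition(gpos[left_only] - mpos[li[left_only]], map_scale)
    GL <- Gm[, li[left_only], drop = FALSE]
    out[, left_only] <- GL * rep(1 - 2 * RL, each = n) + rep(RL, each = n)
  }
  if (any(right_only)) {
    RR <- ril_transition(mpos[ri[right_only]] - gpos[right_only], map_scale)
    GR <- Gm[, ri[right_only], drop = FALSE]
    out[, right_only] <- GR * rep(1 - 2 * RR, each = n) + rep(RR, each = n)
  }
  if (any(both)) {
    RL <- ril_transition(gpos[both] - mpos[li[both]], map_scale)
    RR <- ril_transition(mpos[ri[both]] - gpos[both], map_scale)
    GL <- Gm[, li[both], drop = FALSE]
    GR <- Gm[, ri[both], drop = FALSE]
    RLm <- rep(RL, each = n); RRm <- rep(RR, each = n)
    pLA <- GL * (1 - RLm) + (1 - GL) * RLm   # P(X = A | left obs)
    pRA <- GR * (1 - RRm) + (1 - GR) * RRm   # P(right obs | X = A) by symmetry
    pLB <- 1 - pLA
    pRB <- GR * RRm + (1 - GR) * (1 - RRm)
    out[, both] <- pLA * pRA / (pLA * pRA + pLB * pRB)
  }
  out
}

# single line with informative markers at mpos (subset), values g in {0,1}
.probs_line <- function(g, mpos, gpos, map_scale) {
  Gm <- matrix(g, nrow = 1)
  .probs_complete(Gm, mpos, gpos, map_scale)[1, ]
}
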