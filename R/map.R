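#' Genetic map of ordered markers
#'
#' A genetic map is a data frame with one row per marker, columns `marker`,
#' `chrom` and `pos` (centiMorgan, chromosome-local), ordered by chromosome
#' and position. The `map_scale` attribute records whether the cM distances
#' are on the expanded RIL scale (`"ril"`, typical for maps estimated from
#' RIL data) or the meiotic scale (`"meiotic"`, used by the simulator, whose
#' configured distances are per-meiosis).
#'
#' @param marker character vector of marker names (unique).
#' @param chrom chromosome identifier per marker.
#' @param pos cM position per marker, non-decreasing within chromosome
#'   (strictly increasing when `strict = TRUE`).
#' @param map_scale `"ril"` or `"meiotic"`.
#' @param strict require strictly increasing positions within chromosome.
#' @return a `genetic_map` data frame.
#' @export
genetic_map <- function(marker, chrom, pos, map_scale = c("ril", "meiotic"),
                        strict = TRUE) {
  map_scale <- match.arg(map_scale)
  stopifnot(length(marker) == length(chrom), length(marker) == length(pos))
  if (anyDuplicated(marker)) {
    stop("duplicated marker names: ",
         paste(unique(marker[duplicated(marker)]), collapse = ", "))
  }
  if (any(!is.finite(pos))) stop("non-finite map positions")
  m <- data.frame(marker = as.character(marker), chrom = as.character(chrom),
                  pos = as.numeric(pos), stringsAsFactors = FALSE)
  m <- m[order(match(m$chrom, unique(m$chrom))), , drop = FALSE]
  for (ch in unique(m$chrom)) {
    p <- m$pos[m$chrom == ch]
    d <- diff(p)
    bad <- if (strict) which(d <= 0) else which(d < 0)
    if (length(bad)) {
      mk <- m$marker[m$chrom == ch][bad[1] + 1]
      stop(sprintf("map positions not %s on chromosome %s at marker %s",
                   if (strict) "strictly increasing" else "non-decreasing",
                   ch, mk))
    }
  }
  rownames(m) <- NULL
  structure(m, map_scale = map_scale,
            class = c("genetic_map", "data.frame"))
}

#' Map scale of a genetic map or grid
#' @param x a `genetic_map` or `pseudo_grid`.
#' @return `"ril"` or `"meiotic"` (defaults to `"ril"` when unflagged).
#' @export
map_scale <- function(x) {
  ms <- attr(x, "map_scale")
  if (is.null(ms)) "ril" else ms
}

#' RIL-scale transition probability between two loci
#'
#' Converts a cM map distance into the probability that an inbred line
#' carries different parental alleles at the two loci. Uses the inverse
#' Haldane map function r = (1 - exp(-2d/100))/2 (no interference). On the
#' meiotic scale the per-meiosis fraction r is then expanded to the RIL
#' (selfing, F-infinity) scale via R = 2r/(1 + 2r); on the `ril` scale the
#' distances are taken as already expanded, so R is the inverse Haldane
#' value directly.
#'
#' @param d non-negative cM distance(s).
#' @param map_scale `"ril"` or `"meiotic"` — the scale `d` is measured on.
#' @return transition probability in [0, 0.5).
#' @export
ril_transition <- function(d, map_scale = c("ril", "meiotic")) {
  map_scale <- match.arg(map_scale)
  if (any(d < 0)) stop("negative map distance")
  r <- 0.5 * (1 - exp(-2 * d / 100))
  if (map_scale == "meiotic") 2 * r / (1 + 2 * r) else r
}

#' Build a pseudo-marker grid over a genetic map
#'
#' Inserts evenly spaced pseudo-markers into each inter-marker gap so that
#' no two consecutive grid points are more than `step_cM` apart, while
#' retaining every true marker. A gap g is split into ceiling(g/step) equal
#' segments.
#'
#' @param map a [genetic_map()].
#' @param step_cM maximum spacing between grid points (default 2 cM).
#' @return a `pseudo_grid` data frame with columns `chrom`, `pos`,
#'   `is_marker` and `marker` (NA at pseudo-markers); carries the map's
#'   `map_scale`.
#' @export
build_grid <- function(map, step_cM = 2) {
  stopifnot(inherits(map, "genetic_map"))
  if (!is.numeric(step_cM) || length(step_cM) != 1 || step_cM <= 0) {
    stop("step_cM must be a positive number")
  }
  out <- lapply(unique(map$chrom), function(ch) {
    sub <- map[map$chrom == ch, , drop = FALSE]
    pos <- sub$pos
    if (length(pos) == 1L) {
      return(data.frame(chrom = ch, pos = pos, is_marker = TRUE,
                        marker = sub$marker, stringsAsFactors = FALSE))
    }
    gp <- pos[1]
    for (j in seq_len(length(pos) - 1L)) {
      gap <- pos[j + 1] - pos[j]
      nseg <- max(1L, ceiling(gap / step_cM - 1e-9))
      gp <- c(gp, pos[j] + gap * seq_len(nseg) / nseg)
    }
    gp <- gp[!duplicated(signif(gp, 12))]
    is_mk <- gp %in% pos
    mk <- rep(NA_character_, length(gp))
    mk[is_mk] <- sub$marker[match(gp[is_mk], pos)]
    data.frame(chrom = ch, pos = gp, is_marker = is_mk, marker = mk,
               stringsAsFactors = FALSE)
  })
  g <- do.call(rbind, out)
  rownames(g) <- NULL
  structure(g, map_scale = map_scale(map), step_cM = step_cM,
            class = c("pseudo_grid", "data.frame"))
}
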