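#' Configuration for the synthetic RIL population
#'
#' Describes a biparental recombinant-inbred-line (RIL) design: lines are
#' fully homozygous mosaics of the two parental genomes, simulated directly
#' at the RIL (F-infinity) scale as a two-state Markov chain along each
#' chromosome with transition probability R = 2r/(1+2r), r the per-meiosis
#' recombination fraction from the inverse Haldane map function. QTL effects
#' are specified in phenotype-SD units; phenotypes are the sum of QTL
#' effects, a polygenic term (many small random marker effects) and Gaussian
#' residual noise, then placed on each trait's natural scale.
#'
#' The default configuration is the study design the package emulates: 343
#' lines, 166 markers on 5 chromosomes of 85 cM, a shared pleiotropic QTL at
#' 4 cM on chromosome 4 explaining 25% / 15% of water-use-efficiency (WUE,
#' as delta-13C) and flowering-time (FT) variance plus a trait-specific QTL
#' for each trait, and a growth-rate effect expressed through leaf areas at
#' two dates.
#'
#' @param n_lines number of RILs (>= 2).
#' @param chr_lengths cM length per chromosome (meiotic scale).
#' @param n_markers_per_chrom marker count per chromosome (evenly spaced,
#'   ignored when `marker_positions` is given).
#' @param marker_positions optional list of explicit cM positions per
#'   chromosome (non-decreasing).
#' @param qtl data frame with columns `chrom`, `pos` and one `eff_<trait>`
#'   column per trait, effects in phenotype-SD units (difference between the
#'   two homozygote classes).
#' @param polygenic_sd,residual_sd named per-trait SDs (SD units).
#' @param residual_cor correlation between the WUE and FT residual noise
#'   (default 0.26, which together with the shared QTL puts the line-mean
#'   WUE-FT correlation near r = 0.37, i.e. r-squared ~ 0.14, the RIL-scale
#'   value the design targets).
#' @param trait_location,trait_scale affine placement of each trait on its
#'   natural scale (value = location + scale * z).
#' @param residual_het probability an entry is residually heterozygous;
#'   such entries are recorded as missing (default 0: the ~0.4% F9
#'   heterozygosity is ignored).
#' @param gr_base,gr_sd_scale mean and SD (per day) of relative leaf-area
#'   growth rate; `la_t1_meanlog`, `la_t1_sdlog` lognormal leaf area at the
#'   first measurement; `t1`, `t2` measurement days.
#' @param seed integer seed.
#' @return a `ril_sim_config` list.
#' @export
ril_sim_config <- function(n_lines = 343L,
                           chr_lengths = rep(85, 5),
                           n_markers_per_chrom = c(34L, 33L, 33L, 33L, 33L),
                           marker_positions = NULL,
                           qtl = NULL,
                           polygenic_sd = c(wue = 0.2, ft = 0.2, gr = 0.2),
                           residual_sd = c(wue = sqrt(0.63), ft = sqrt(0.73),
                                           gr = sqrt(0.87)),
                           residual_cor = 0.26,
                           trait_location = c(wue = -33.5, ft = 55, gr = 0),
                           trait_scale = c(wue = 0.8, ft = 10, gr = 1),
                           residual_het = 0,
                           gr_base = 0.12, gr_sd_scale = 0.01,
                           la_t1_meanlog = 5.7, la_t1_sdlog = 0.25,
                           t1 = 14, t2 = 21,
                           seed = 1L) {
  if (is.null(qtl)) {
    # shared pleiotropic QTL (PVE 25% WUE / 15% FT / 9% GR with unit total
    # variance) plus one trait-specific QTL per mapped trait; placements
    # adapt to smaller maps
    nc <- length(chr_lengths)
    qtl <- data.frame(
      chrom = as.character(c(min(4, nc), 1, min(2, nc))),
      pos = c(min(4, 0.1 * chr_lengths[min(4, nc)]),
              min(40, 0.5 * chr_lengths[1]),
              min(60, 0.8 * chr_lengths[min(2, nc)])),
      eff_wue = c(2 * sqrt(0.25), 2 * sqrt(0.08), 0),
      eff_ft = c(2 * sqrt(0.15), 0, 2 * sqrt(0.08)),
      eff_gr = c(-2 * sqrt(0.09), 0, 0),
      stringsAsFactors = FALSE
    )
  }
  cfg <- list(n_lines = as.integer(n_lines), chr_lengths = chr_lengths,
              n_markers_per_chrom = as.integer(n_markers_per_chrom),
              marker_positions = marker_positions, qtl = qtl,
              polygenic_sd = polygenic_sd, residual_sd = residual_sd,
              residual_cor = residual_cor,
              trait_location = trait_location, trait_scale = trait_scale,
              residual_het = residual_het,
              gr_base = gr_base, gr_sd_scale = gr_sd_scale,
              la_t1_meanlog = la_t1_meanlog, la_t1_sdlog = la_t1_sdlog,
              t1 = t1, t2 = t2, seed = as.integer(seed))
  validate_ril_sim_config(cfg)
  class(cfg) <- "ril_sim_config"
  cfg
}

validate_ril_sim_config <- function(cfg) {
  if (cfg$n_lines < 2) stop("n_lines must be >= 2")
  if (any(!is.finite(cfg$chr_lengths)) || any(cfg$chr_lengths < 0)) {
    stop("chromosome lengths must be finite and non-negative")
  }
  if (is.null(cfg$marker_positions) &&
      length(cfg$n_markers_per_chrom) != length(cfg$chr_lengths)) {
    stop("n_markers_per_chrom must match chr_lengths")
  }
  q <- cfg$qtl
  effcols <- grep("^eff_", names(q), value = TRUE)
  if (!length(effcols)) stop("qtl table needs eff_<trait> columns")
  if (any(!is.finite(as.matrix(q[effcols])))) stop("non-finite QTL effects")
  chrs <- as.character(seq_along(cfg$chr_lengths))
  if (any(!as.character(q$chrom) %in% chrs)) {
    stop("QTL chromosome outside the map")
  }
  lim <- cfg$chr_lengths[match(as.character(q$chrom), chrs)]
  if (any(q$pos < 0 | q$pos > lim)) stop("QTL position outside its chromosome")
  traits <- sub("^eff_", "", effcols)
  for (fld in c("polygenic_sd", "residual_sd")) {
    v <- cfg[[fld]]
    if (any(!is.finite(v)) || any(v < 0)) stop(fld, " must be non-negative")
    if (!all(traits %in% names(v))) stop(fld, " missing a trait")
  }
  if (!is.finite(cfg$residual_cor) || abs(cfg$residual_cor) >= 1) {
    stop("residual_cor must lie in (-1, 1)")
  }
  if (cfg$residual_het < 0 || cfg$residual_het >= 1) {
    stop("residual_het must be in [0, 1)")
  }
  if (cfg$t2 <= cfg$t1) stop("t2 must exceed t1")
  invisible(cfg)
}

# Markov-chain genotypes at given loci (0 = parent B, 1 = parent A)
.sim_chain <- function(n, pos) {
  g <- matrix(0L, n, length(pos))
  g[, 1] <- stats::rbinom(n, 1L, 0.5)
  if (length(pos) > 1L) {
    R <- ril_transition(diff(pos), "meiotic")
    for (j in seq_along(R)) {
      flip <- stats::rbinom(n, 1L, R[j])
      g[, j + 1] <- ifelse(flip == 1L, 1L - g[, j], g[, j])
    }
  }
  g
}

#' Simulate a RIL population with known ground truth
#'
#' Generates marker genotypes chromosome by chromosome as a two-state Markov
#' chain at the RIL scale (QTL positions are simulated jointly with the
#' markers so linkage between a QTL and its flanking markers is exact), then
#' builds phenotypes as QTL effects + polygenic term + residual noise.
#'
#' @param config a [ril_sim_config()].
#' @return a list with elements `map` (a [genetic_map()], meiotic scale),
#'   `panel` (a `ril_panel`: genotype matrix, phenotype table, map) and
#'   `truth` (QTL positions/effects and simulation metadata).
#' @export
simulate_ril_panel <- function(config) {
  stopifnot(inherits(config, "ril_sim_config"))
  set.seed(config$seed)
  n <- config$n_lines
  chrs <- as.character(seq_along(config$chr_lengths))
  effcols <- grep("^eff_", names(config$qtl), value = TRUE)
  traits <- sub("^eff_", "", effcols)

  geno <- NULL
  map_rows <- list()
  qtl_geno <- matrix(0L, n, nrow(config$qtl))
  for (ci in seq_along(chrs)) {
    ch <- chrs[ci]
    if (!is.null(config$marker_positions)) {
      mpos <- config$marker_positions[[ci]]
    } else {
      nm <- config$n_markers_per_chrom[ci]
      mpos <- if (nm == 1L) 0 else
        seq(0, config$chr_lengths[ci], length.out = nm)
    }
    qidx <- which(as.character(config$qtl$chrom) == ch)
    loci <- sort(unique(c(mpos, config$qtl$pos[qidx])))
    g <- .sim_chain(n, loci)
    mcol <- match(mpos, loci)
    gm <- g[, mcol, drop = FALSE]
    colnames(gm) <- sprintf("c%s_m%02d", ch, seq_along(mpos))
    geno <- cbind(geno, gm)
    if (length(qidx)) {
      qtl_geno[, qidx] <- g[, match(config$qtl$pos[qidx], loci), drop = FALSE]
    }
    map_rows[[ci]] <- data.frame(marker = colnames(gm), chrom = ch,
                                 pos = mpos, stringsAsFactors = FALSE)
  }
  mapdf <- do.call(rbind, map_rows)
  map <- genetic_map(mapdf$marker, mapdf$chrom, mapdf$pos,
                     map_scale = "meiotic", strict = FALSE)
  line_ids <- sprintf("RIL%03d", seq_len(n))
  rownames(geno) <- line_ids

  # phenotypes on the z scale, then placed on natural scales
  M <- ncol(geno)
  gc <- geno - 0.5
  # residual noise: unit normals, with the wue-ft pair correlated
  E <- matrix(stats::rnorm(n * length(traits)), n,
              dimnames = list(NULL, traits))
  if (all(c("wue", "ft") %in% traits) && config$residual_cor != 0) {
    rho <- config$residual_cor
    E[, "ft"] <- rho * E[, "wue"] + sqrt(1 - rho^2) * E[, "ft"]
  }
  z <- matrix(0, n, length(traits), dimnames = list(line_ids, traits))
  for (ti in seq_along(traits)) {
    tr <- traits[ti]
    a <- config$qtl[[effcols[ti]]]
    qterm <- if (any(a != 0)) qtl_geno %*% a else rep(0, n)
    psd <- config$polygenic_sd[[tr]]
    pterm <- if (psd > 0) {
      beta <- stats::rnorm(M, 0, psd / sqrt(0.25 * M))
      as.numeric(gc %*% beta)
    } else rep(0, n)
    z[, ti] <- as.numeric(qterm) + pterm +
      config$residual_sd[[tr]] * E[, ti]
  }

  pheno <- data.frame(id = line_ids, stringsAsFactors = FALSE)
  for (tr in intersect(c("wue", "ft"), traits)) {
    pheno[[tr]] <- config$trait_location[[tr]] +
      config$trait_scale[[tr]] * z[, tr]
  }
  if ("gr" %in% traits) {
    gr_day <- config$gr_base + config$gr_sd_scale * z[, "gr"]
    la1 <- exp(stats::rnorm(n, config$la_t1_meanlog, config$la_t1_sdlog))
    pheno$la_t1 <- la1
    pheno$la_t2 <- la1 * exp(gr_day * (config$t2 - config$t1))
  }

  if (config$residual_het > 0) {
    het <- matrix(stats::rbinom(length(geno), 1L, config$residual_het),
                  nrow(geno))
    geno[het == 1L] <- NA_integer_
  }

  panel <- structure(list(geno = geno, pheno = pheno, map = map,
                          t1 = config$t1, t2 = config$t2),
                     class = "ril_panel")
  truth <- list(kind = "ril", seed = config$seed,
                qtl = config$qtl, traits = traits,
                trait_location = as.list(config$trait_location),
                trait_scale = as.list(config$trait_scale),
                n_lines = n, n_markers = ncol(geno))
  list(map = map, panel = panel, truth = truth)
}

#' @export
print.ril_panel <- function(x, ...) {
  cat(sprintf("RIL panel: %d lines x %d markers, %d chromosomes\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$map$chrom))))
  cat("phenotypes:", paste(setdiff(names(x$pheno), "id"), collapse = ", "),
      "\n")
  invisible(x)
}
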