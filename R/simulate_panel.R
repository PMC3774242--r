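#' Configuration for the synthetic accession panel
#'
#' Describes a panel of inbred natural accessions segregating a biallelic
#' focal locus whose "functionality" (functional vs non-functional allele)
#' is the class label of interest: SNPs in a window around the focal locus
#' tag the label at a tunable LD (r-squared), genome-wide SNPs carry
#' class-differentiated allele frequencies calibrated to a target Nei FST,
#' accessions fall into geographic clusters (a configurable number of which
#' carry no class differentiation), and climate variables are independent
#' Gaussians given class with a configurable mean shift.
#'
#' Defaults emulate the study panel: 1188 accessions of which 317 carry an
#' observed functionality label, a 100-kb SNP window around the focal locus,
#' 19 climate variables, and 11 geographic clusters with differentiation in
#' all but one.
#'
#' @param n_accessions panel size; `n_labeled` of them carry an observed
#'   functionality label (the rest are imputation targets).
#' @param focal_allele_frequency probability an accession carries the
#'   functional allele, in (0, 1).
#' @param focal_chrom,focal_bp coordinate of the focal locus.
#' @param n_window_snps,window_span_bp SNPs within +/- `window_span_bp` of
#'   the focal locus.
#' @param tag_ld_r2 target squared correlation between each window SNP and
#'   the focal label, in \[0, 1\] (recycled across window SNPs).
#' @param n_genome_snps,snp_spacing_bp,n_chromosomes genome-wide background
#'   SNPs with roughly exponential spacing.
#' @param base_freq_range range the per-SNP base allele frequency is drawn
#'   from.
#' @param fst_between_classes target per-SNP Nei FST between classes, in
#'   \[0, 1): class frequencies are p +/- delta with
#'   delta = sqrt(FST * p(1-p)), truncated to the feasible boundary and
#'   flagged where unreachable.
#' @param n_geo_clusters,n_null_clusters geographic clusters; in "null"
#'   clusters genotypes ignore the class label.
#' @param n_climate_vars,climate_effect,n_climate_shifted number of climate
#'   variables, between-class mean shift in SD units, and how many of the
#'   variables carry the shift.
#' @param seed integer seed.
#' @return a `panel_sim_config` list.
#' @export
panel_sim_config <- function(n_accessions = 1188L, n_labeled = 317L,
                             focal_allele_frequency = 0.35,
                             focal_chrom = "4", focal_bp = 269000L,
                             n_window_snps = 40L, window_span_bp = 100000L,
                             tag_ld_r2 = 0.9,
                             n_genome_snps = 20000L, snp_spacing_bp = 5000,
                             n_chromosomes = 5L,
                             base_freq_range = c(0.2, 0.8),
                             fst_between_classes = 0.05,
                             n_geo_clusters = 11L, n_null_clusters = 1L,
                             n_climate_vars = 19L, climate_effect = 1,
                             n_climate_shifted = 5L,
                             seed = 1L) {
  cfg <- list(n_accessions = as.integer(n_accessions),
              n_labeled = as.integer(n_labeled),
              focal_allele_frequency = focal_allele_frequency,
              focal_chrom = as.character(focal_chrom),
              focal_bp = as.integer(focal_bp),
              n_window_snps = as.integer(n_window_snps),
              window_span_bp = as.integer(window_span_bp),
              tag_ld_r2 = tag_ld_r2,
              n_genome_snps = as.integer(n_genome_snps),
              snp_spacing_bp = snp_spacing_bp,
              n_chromosomes = as.integer(n_chromosomes),
              base_freq_range = base_freq_range,
              fst_between_classes = fst_between_classes,
              n_geo_clusters = as.integer(n_geo_clusters),
              n_null_clusters = as.integer(n_null_clusters),
              n_climate_vars = as.integer(n_climate_vars),
              climate_effect = climate_effect,
              n_climate_shifted = as.integer(n_climate_shifted),
              seed = as.integer(seed))
  validate_panel_sim_config(cfg)
  class(cfg) <- "panel_sim_config"
  cfg
}

validate_panel_sim_config <- function(cfg) {
  f <- cfg$focal_allele_frequency
  if (!is.finite(f) || f <= 0 || f >= 1) {
    stop("focal_allele_frequency must lie in (0, 1)")
  }
  if (cfg$n_labeled > cfg$n_accessions) stop("n_labeled exceeds n_accessions")
  if (any(cfg$tag_ld_r2 < 0 | cfg$tag_ld_r2 > 1)) {
    stop("tag_ld_r2 must lie in [0, 1]")
  }
  F <- cfg$fst_between_classes
  if (!is.finite(F) || F < 0 || F >= 1) {
    stop("fst_between_classes must lie in [0, 1); requested ", F,
         " is infeasible")
  }
  if (cfg$n_null_clusters > cfg$n_geo_clusters) {
    stop("n_null_clusters exceeds n_geo_clusters")
  }
  if (any(cfg$base_freq_range <= 0) || any(cfg$base_freq_range >= 1) ||
      diff(cfg$base_freq_range) < 0) {
    stop("base_freq_range must be an increasing range inside (0, 1)")
  }
  if (cfg$n_climate_shifted > cfg$n_climate_vars) {
    stop("n_climate_shifted exceeds n_climate_vars")
  }
  invisible(cfg)
}

# Flip probability e such that cor(label, flipped label)^2 == r2, for a
# Bernoulli(f) label. e = 0 gives r2 = 1; e = 0.5 gives r2 = 0.
.tag_flip_prob <- function(r2, f) {
  if (r2 >= 1) return(0)
  if (r2 <= 0) return(0.5)
  corr2 <- function(e) {
    px <- f * (1 - e) + (1 - f) * e
    num <- (1 - 2 * e) * f * (1 - f)
    num^2 / (f * (1 - f) * px * (1 - px)) - r2
  }
  stats::uniroot(corr2, c(1e-12, 0.5 - 1e-12), tol = 1e-12)$root
}

#' Simulate an accession panel, climate table and ground truth
#'
#' @param config a [panel_sim_config()].
#' @return list with `panel` (a [snp_panel()]), `climate` (data frame: id,
#'   class, bio01..bioNN) and `truth` (true labels, window LD targets,
#'   per-SNP differentiation with truncation flags, climate shifts, null
#'   clusters).
#' @export
simulate_accession_panel <- function(config) {
  stopifnot(inherits(config, "panel_sim_config"))
  set.seed(config$seed)
  n <- config$n_accessions
  ids <- sprintf("acc%04d", seq_len(n))
  f <- config$focal_allele_frequency
  z <- stats::rbinom(n, 1L, f)  # 1 = functional allele
  labeled <- sort(sample.int(n, config$n_labeled))

  cluster <- sample(rep_len(seq_len(config$n_geo_clusters), n))
  null_clusters <- if (config$n_null_clusters > 0)
    seq_len(config$n_null_clusters) else integer(0)
  in_null <- cluster %in% null_clusters

  # window SNPs: label copies flipped with probability solved from target r2
  r2 <- rep_len(config$tag_ld_r2, config$n_window_snps)
  wpos <- sort(config$focal_bp +
                 sample(seq(-config$window_span_bp, config$window_span_bp),
                        config$n_window_snps))
  flipp <- vapply(r2, .tag_flip_prob, numeric(1), f = f)
  W <- matrix(0L, n, config$n_window_snps)
  for (j in seq_len(config$n_window_snps)) {
    fl <- stats::rbinom(n, 1L, flipp[j])
    W[, j] <- ifelse(fl == 1L, 1L - z, z)
  }

  # genome-wide SNPs: class frequencies p +/- delta, sign randomized per SNP
  m <- config$n_genome_snps
  chrom_g <- as.character(rep_len(seq_len(config$n_chromosomes), m))
  chrom_g <- sort(chrom_g)
  pos_g <- integer(m)
  for (ch in unique(chrom_g)) {
    k <- sum(chrom_g == ch)
    pos_g[chrom_g == ch] <-
      cumsum(pmax(1, round(stats::rexp(k, 1 / config$snp_spacing_bp))))
  }
  p <- stats::runif(m, config$base_freq_range[1], config$base_freq_range[2])
  delta <- sqrt(config$fst_between_classes * p * (1 - p))
  truncated <- delta > pmin(p, 1 - p)
  delta[truncated] <- pmin(p, 1 - p)[truncated]
  sgn <- sample(c(-1, 1), m, replace = TRUE)
  p_func <- p + sgn * delta
  p_null <- p - sgn * delta
  pm <- matrix(rep(p, each = n), n, m)
  pm[z == 1L & !in_null, ] <-
    matrix(rep(p_func, each = sum(z == 1L & !in_null)),
           sum(z == 1L & !in_null), m)
  pm[z == 0L & !in_null, ] <-
    matrix(rep(p_null, each = sum(z == 0L & !in_null)),
           sum(z == 0L & !in_null), m)
  G <- matrix(stats::rbinom(n * m, 1L, pm), n, m)
  rm(pm)

  # assemble: window SNPs interleaved into the focal chromosome by position
  geno <- cbind(W, G)
  snps <- data.frame(
    id = c(sprintf("w%03d", seq_len(config$n_window_snps)),
           sprintf("s%06d", seq_len(m))),
    chrom = c(rep(config$focal_chrom, config$n_window_snps), chrom_g),
    pos = c(wpos, pos_g),
    stringsAsFactors = FALSE)
  ord <- order(match(snps$chrom, unique(snps$chrom)), snps$pos)
  geno <- geno[, ord, drop = FALSE]
  snps <- snps[ord, , drop = FALSE]
  colnames(geno) <- snps$id
  rownames(geno) <- ids

  class_lab <- ifelse(z == 1L, "functional", "nonfunctional")
  obs_class <- rep(NA_character_, n)
  obs_class[labeled] <- class_lab[labeled]

  centers_lat <- 36 + 2.2 * seq_len(config$n_geo_clusters)
  centers_lon <- -10 + 3.6 * seq_len(config$n_geo_clusters)
  acc <- data.frame(id = ids, class = obs_class, cluster = cluster,
                    lat = centers_lat[cluster] + stats::rnorm(n, 0, 0.8),
                    lon = centers_lon[cluster] + stats::rnorm(n, 0, 0.8),
                    stringsAsFactors = FALSE)

  panel <- snp_panel(geno, snps, acc,
                     focal = list(chrom = config$focal_chrom,
                                  bp = config$focal_bp))

  shift <- c(rep(config$climate_effect, config$n_climate_shifted),
             rep(0, config$n_climate_vars - config$n_climate_shifted))
  clim <- matrix(stats::rnorm(n * config$n_climate_vars), n) +
    outer(z, shift)
  colnames(clim) <- sprintf("bio%02d", seq_len(config$n_climate_vars))
  climate <- data.frame(id = ids, class = class_lab, clim,
                        stringsAsFactors = FALSE)

  truth <- list(kind = "panel", seed = config$seed,
                labels = class_lab, labeled_ids = ids[labeled],
                window = data.frame(id = sprintf("w%03d",
                                                 seq_len(config$n_window_snps)),
                                    r2_target = r2, flip_prob = flipp,
                                    stringsAsFactors = FALSE),
                fst_target = config$fst_between_classes,
                n_truncated = sum(truncated),
                null_clusters = null_clusters,
                climate_shift = shift)
  list(panel = panel, climate = climate, truth = truth)
}
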