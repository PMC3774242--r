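#' Default pipeline configuration
#'
#' A nested list covering every stage of the synthetic end-to-end analysis:
#' simulate (RIL population + accession panel), scan (grid step,
#' permutations, alpha), bivariate (interval rule), fst (estimator,
#' resampling sizes), impute (window span, CV protocol) and stats. Every
#' stochastic stage has an explicit seed derived from the master seed. The
#' config round-trips through YAML unchanged via [yaml::write_yaml()] /
#' [yaml::read_yaml()].
#'
#' @param seed master seed; per-stage seeds are seed + fixed offsets.
#' @param out_dir output directory for [run_pipeline()].
#' @param ril,panel named lists of overrides passed to [ril_sim_config()]
#'   and [panel_sim_config()].
#' @return a `pipeline_config` list.
#' @export
default_pipeline_config <- function(seed = 1L, out_dir = "results/pipeline",
                                    ril = list(), panel = list()) {
  structure(list(
    stages = c("simulate", "scan", "bivariate", "fst", "impute", "stats"),
    out_dir = out_dir,
    inputs = list(geno_csv = NULL, pheno_csv = NULL, snp_matrix = NULL,
                  accessions_csv = NULL, climate_csv = NULL),
    seeds = list(ril = seed, panel = seed + 1000L, scan = seed + 2000L,
                 fst = seed + 3000L, impute = seed + 4000L),
    ril = ril,
    panel = panel,
    scan = list(step_cM = 2, n_perm = 1000L, alpha = 0.05,
                traits = c("wue", "ft")),
    bivariate = list(rule = "peak_fraction", param = 0.5),
    fst = list(estimator = "nei", n_perm = 500L, thin_bp = 50000,
               boot_n_snps = 500L, boot_tolerance = 0.02),
    impute = list(half_span_bp = 100000, k = 4L),
    stats = list(alpha = 0.05)
  ), class = "pipeline_config")
}

.stage_need <- function(state, what, stage) {
  if (is.null(state[[what]])) {
    stop(sprintf("stage '%s' needs '%s' from an earlier stage or an input path",
                 stage, what))
  }
  state[[what]]
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes the requested stages in order — simulate, scan, bivariate, fst,
#' impute, stats — writing per-stage tables under `config$out_dir` plus a
#' provenance manifest (config, config-file MD5, per-stage seeds, package
#' and R versions). Stages beyond `simulate` consume either the in-memory
#' results of earlier stages or the input paths named in `config$inputs`;
#' a missing dependency raises an error naming the stage.
#'
#' @param config a [default_pipeline_config()]-style list.
#' @return invisibly, a list of per-stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  state <- list()
  t_all <- Sys.time()
  for (stage in config$stages) {
    t0 <- Sys.time()
    message("stage: ", stage)
    state <- switch(
      stage,
      simulate = .stage_simulate(config, state),
      scan = .stage_scan(config, state),
      bivariate = .stage_bivariate(config, state),
      fst = .stage_fst(config, state),
      impute = .stage_impute(config, state),
      stats = .stage_stats(config, state),
      stop("unknown stage: ", stage)
    )
    message(sprintf("  done in %.1f s",
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  cfg_file <- file.path(config$out_dir, "config.yaml")
  yaml::write_yaml(unclass(config), cfg_file)
  manifest <- list(
    config_file = basename(cfg_file),
    config_md5 = unname(tools::md5sum(cfg_file)),
    seeds = config$seeds,
    stages_run = config$stages,
    package_version = as.character(utils::packageVersion("pleioscan")),
    r_version = R.version.string,
    elapsed_s = as.numeric(difftime(Sys.time(), t_all, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(state)
}

.stage_simulate <- function(config, state) {
  rcfg <- do.call(ril_sim_config, c(config$ril,
                                    list(seed = config$seeds$ril)))
  ril <- simulate_ril_panel(rcfg)
  pcfg <- do.call(panel_sim_config, c(config$panel,
                                      list(seed = config$seeds$panel)))
  acc <- simulate_accession_panel(pcfg)
  od <- config$out_dir
  write_cross(ril$panel, file.path(od, "ril_geno.csv"),
              file.path(od, "ril_pheno.csv"))
  write_truth(ril$truth, file.path(od, "truth_ril.json"))
  write_snp_matrix(acc$panel, file.path(od, "snp_panel.csv"))
  write_accessions(acc$panel, file.path(od, "accessions.csv"))
  utils::write.csv(acc$climate, file.path(od, "climate.csv"),
                   row.names = FALSE)
  write_truth(acc$truth, file.path(od, "truth_panel.json"))
  state$ril <- ril$panel
  state$panel <- acc$panel
  state$climate <- acc$climate
  state
}

.load_ril <- function(config, state) {
  if (!is.null(state$ril)) return(state$ril)
  if (!is.null(config$inputs$geno_csv)) {
    return(read_cross(config$inputs$geno_csv, config$inputs$pheno_csv,
                      map_scale = "meiotic")$panel)
  }
  NULL
}

.load_panel <- function(config, state) {
  if (!is.null(state$panel)) return(state$panel)
  if (!is.null(config$inputs$snp_matrix)) {
    return(read_snp_panel(config$inputs$snp_matrix,
                          accessions = config$inputs$accessions_csv))
  }
  NULL
}

.stage_scan <- function(config, state) {
  ril <- .load_ril(config, state)
  if (is.null(ril)) stop("stage 'scan' needs a RIL panel ",
                         "(run 'simulate' or set inputs$geno_csv)")
  state$ril <- ril
  grid <- build_grid(ril$map, config$scan$step_cM)
  probs <- genotype_probabilities(ril, grid)
  state$probs <- probs
  state$profiles <- list()
  state$models <- list()
  for (ti in seq_along(config$scan$traits)) {
    tr <- config$scan$traits[ti]
    y <- ril$pheno[[tr]]
    prof <- scan_trait(probs, y, trait = tr)
    thr <- permutation_threshold(probs, y, n_perm = config$scan$n_perm,
                                 alpha = config$scan$alpha,
                                 seed = config$seeds$scan + ti)
    model <- stepwise_additive(probs, y, penalty = as.numeric(thr))
    if (nrow(model)) model <- refine_positions(model, probs, y)
    state$profiles[[tr]] <- prof
    state$models[[tr]] <- model
    utils::write.csv(as.data.frame(prof),
                     file.path(config$out_dir,
                               sprintf("lod_%s.csv", tr)),
                     row.names = FALSE)
    mdf <- as.data.frame(model)
    mdf$threshold <- as.numeric(thr)
    utils::write.csv(mdf, file.path(config$out_dir,
                                    sprintf("qtl_model_%s.csv", tr)),
                     row.names = FALSE)
  }
  state
}

.stage_bivariate <- function(config, state) {
  if (length(state$profiles) < 2) {
    stop("stage 'bivariate' needs two scanned traits from stage 'scan'")
  }
  p1 <- standardize_profile(state$profiles[[1]])
  p2 <- standardize_profile(state$profiles[[2]])
  bp <- sum_profiles(p1, p2)
  iv <- bivariate_interval(bp, rule = config$bivariate$rule,
                           param = config$bivariate$param)
  utils::write.csv(as.data.frame(bp),
                   file.path(config$out_dir, "bivariate_profile.csv"),
                   row.names = FALSE)
  jsonlite::write_json(c(iv, list(peak_score = attr(bp, "peak")$score)),
                       file.path(config$out_dir, "bivariate_interval.json"),
                       auto_unbox = TRUE, digits = NA)
  state$bivariate <- bp
  state$interval <- iv
  state
}

.stage_fst <- function(config, state) {
  panel <- .load_panel(config, state)
  if (is.null(panel)) stop("stage 'fst' needs an SNP panel ",
                           "(run 'simulate' or set inputs$snp_matrix)")
  state$panel <- panel
  labels <- if (!is.null(state$imputed)) state$imputed$class else
    state$panel$accessions$class
  est <- config$fst$estimator
  res <- per_snp_fst(panel, labels, estimator = est)
  perm <- permutation_null(panel, labels, K = config$fst$n_perm,
                           estimator = est, seed = config$seeds$fst)
  boot <- tryCatch(
    frequency_matched_bootstrap(panel, labels,
                                n_snps = config$fst$boot_n_snps,
                                tolerance = config$fst$boot_tolerance,
                                estimator = est,
                                seed = config$seeds$fst + 1L),
    error = function(e) {
      message("  frequency-matched bootstrap skipped: ",
              conditionMessage(e))
      NULL
    })
  reg <- regional_fst(panel, labels, interval_bp = config$fst$thin_bp)
  utils::write.csv(res$per_snp, file.path(config$out_dir, "fst_per_snp.csv"),
                   row.names = FALSE)
  utils::write.csv(reg, file.path(config$out_dir, "fst_regional.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(estimator = est, mean_fst = res$mean_fst, n_snps = res$n_used,
         permutation_p = perm$p_value,
         bootstrap_p = if (!is.null(boot)) boot$p_value else NA),
    file.path(config$out_dir, "fst_summary.json"),
    auto_unbox = TRUE, digits = NA, na = "null")
  state$fst <- res
  state$fst_perm <- perm
  state$fst_boot <- boot
  state$fst_regional <- reg
  state
}

.stage_impute <- function(config, state) {
  panel <- .load_panel(config, state)
  if (is.null(panel)) stop("stage 'impute' needs an SNP panel ",
                           "(run 'simulate' or set inputs$snp_matrix)")
  state$panel <- panel
  window <- extract_window(panel, half_span_bp = config$impute$half_span_bp)
  labels <- panel$accessions$class
  cv <- kfold_cv(window, labels, k = config$impute$k,
                 seed = config$seeds$impute)
  clf <- train_classifier(window, labels, seed = config$seeds$impute)
  imp <- impute_labels(clf, panel)
  utils::write.csv(imp, file.path(config$out_dir, "imputed_labels.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(protocol = cv$protocol, mean_accuracy = cv$mean_accuracy,
         fold_accuracies = cv$fold_accuracies,
         gamma = clf$gamma, cost = clf$cost),
    file.path(config$out_dir, "impute_cv.json"),
    auto_unbox = TRUE, digits = NA)
  state$cv <- cv
  state$classifier <- clf
  state$imputed <- imp
  state
}

.stage_stats <- function(config, state) {
  out <- list()
  od <- config$out_dir
  if (!is.null(state$ril)) {
    ph <- state$ril$pheno
    if (all(c("wue", "ft") %in% names(ph))) {
      out$wue_ft <- genetic_correlation(ph$wue, ph$ft)
    }
    if (all(c("la_t1", "la_t2") %in% names(ph))) {
      t1 <- state$ril$t1 %||% 14
      t2 <- state$ril$t2 %||% 21
      ph$gr_la <- growth_rate(ph$la_t1, ph$la_t2, t1, t2)
    }
    # genotype-class ANOVA at the marker nearest the strongest model QTL
    if (length(state$models)) {
      m1 <- state$models[[1]]
      if (nrow(m1)) {
        top <- which.max(m1$lod)
        mk <- state$ril$map
        msel <- mk[mk$chrom == m1$chrom[top], , drop = FALSE]
        nearest <- msel$marker[which.min(abs(msel$pos - m1$pos[top]))]
        g <- state$ril$geno[, nearest]
        out$anova <- lapply(intersect(c("wue", "ft", "gr_la"), names(ph)),
                            function(tr) {
                              a <- one_way_anova(ph[[tr]], g)
                              list(trait = tr, F = a$F, p = a$p_value,
                                   pve = a$pve)
                            })
        out$anova_marker <- nearest
      }
    }
  }
  if (!is.null(state$climate)) {
    climate <- state$climate
    if (!is.null(state$imputed)) {
      climate$class <- state$imputed$class[match(climate$id,
                                                 state$imputed$id)]
    }
    ct <- climate_tests(climate, alpha = config$stats$alpha)
    rs <- rank_summary(climate)
    utils::write.csv(ct, file.path(od, "climate_tests.csv"),
                     row.names = FALSE)
    utils::write.csv(rs, file.path(od, "climate_ranks.csv"),
                     row.names = FALSE)
    out$n_climate_significant <- sum(ct$significant)
  }
  if (!length(out)) {
    stop("stage 'stats' needs RIL phenotypes or a climate table upstream")
  }
  jsonlite::write_json(out, file.path(od, "assoc_summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  state$stats <- out
  state
}

`%||%` <- function(a, b) if (is.null(a)) b else a
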