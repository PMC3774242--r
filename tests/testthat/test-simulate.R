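test_that("default RIL design has the study dimensions", {
  sim <- simulate_ril_panel(ril_sim_config(seed = 11))
  expect_equal(dim(sim$panel$geno), c(343, 166))
  expect_equal(length(unique(sim$map$chrom)), 5)
  expect_setequal(na.omit(unique(as.vector(sim$panel$geno))), c(0L, 1L))
  expect_true(all(c("wue", "ft", "la_t1", "la_t2") %in%
                    names(sim$panel$pheno)))
})

test_that("zero map distance yields zero recombinants", {
  cfg <- ril_sim_config(n_lines = 500, chr_lengths = 10,
                        n_markers_per_chrom = 2L,
                        marker_positions = list(c(5, 5)),
                        qtl = data.frame(chrom = "1", pos = 5,
                                         eff_wue = 0, eff_ft = 0),
                        seed = 3)
  sim <- simulate_ril_panel(cfg)
  expect_identical(sim$panel$geno[, 1], sim$panel$geno[, 2])
})

test_that("adjacent-marker recombination follows the RIL map expansion", {
  # d = 10 cM: r = (1 - e^-0.2)/2, R = 2r/(1+2r) ~ 0.1533
  r <- (1 - exp(-0.2)) / 2
  expect_equal(ril_transition(10, "meiotic"), 2 * r / (1 + 2 * r))
  cfg <- ril_sim_config(n_lines = 4000, chr_lengths = 20,
                        n_markers_per_chrom = 2L,
                        marker_positions = list(c(0, 10)),
                        qtl = data.frame(chrom = "1", pos = 0,
                                         eff_wue = 0, eff_ft = 0),
                        seed = 5)
  sim <- simulate_ril_panel(cfg)
  obs <- mean(sim$panel$geno[, 1] != sim$panel$geno[, 2])
  R <- ril_transition(10, "meiotic")
  expect_lt(abs(obs - R), 3 * sqrt(R * (1 - R) / 4000))
})

test_that("simulation is seed-reproducible and seed-sensitive", {
  a <- simulate_ril_panel(ril_sim_config(seed = 9, n_lines = 50))
  b <- simulate_ril_panel(ril_sim_config(seed = 9, n_lines = 50))
  c <- simulate_ril_panel(ril_sim_config(seed = 10, n_lines = 50))
  expect_identical(a$panel$geno, b$panel$geno)
  expect_identical(a$panel$pheno, b$panel$pheno)
  expect_false(identical(a$panel$geno, c$panel$geno))
})

test_that("residual heterozygosity is recorded as missing", {
  sim <- simulate_ril_panel(ril_sim_config(seed = 2, n_lines = 200,
                                           residual_het = 0.05))
  miss <- mean(is.na(sim$panel$geno))
  expect_gt(miss, 0.03)
  expect_lt(miss, 0.07)
})

test_that("invalid RIL configs are rejected", {
  expect_error(ril_sim_config(n_lines = 1), "n_lines")
  expect_error(ril_sim_config(qtl = data.frame(chrom = "9", pos = 1,
                                               eff_wue = 1, eff_ft = 0)),
               "chromosome")
  expect_error(ril_sim_config(qtl = data.frame(chrom = "1", pos = 900,
                                               eff_wue = 1, eff_ft = 0)),
               "position")
  expect_error(ril_sim_config(qtl = data.frame(chrom = "1", pos = 10,
                                               eff_wue = Inf, eff_ft = 0)),
               "finite")
  expect_error(ril_sim_config(residual_cor = 1.2), "residual_cor")
})

test_that("truth records round-trip through JSON", {
  sim <- simulate_ril_panel(ril_sim_config(seed = 4, n_lines = 20))
  f <- withr::local_tempfile(fileext = ".json")
  write_truth(sim$truth, f)
  back <- read_truth(f)
  expect_equal(back$qtl, sim$truth$qtl)
  expect_equal(back$seed, sim$truth$seed)
  ps <- simulate_accession_panel(
    panel_sim_config(seed = 4, n_accessions = 25, n_labeled = 20,
                     n_window_snps = 4, n_genome_snps = 40,
                     n_geo_clusters = 2, n_null_clusters = 0))
  f2 <- withr::local_tempfile(fileext = ".json")
  write_truth(ps$truth, f2)
  back2 <- read_truth(f2)
  expect_identical(back2$labels, ps$truth$labels)
  expect_equal(back2$window, ps$truth$window)
  expect_equal(back2$climate_shift, ps$truth$climate_shift)
})

test_that("a perfect tag SNP is a deterministic relabeling of the label", {
  ps <- simulate_accession_panel(
    panel_sim_config(seed = 6, n_accessions = 120, n_labeled = 120,
                     n_window_snps = 3, tag_ld_r2 = 1,
                     n_genome_snps = 50, n_geo_clusters = 2,
                     n_null_clusters = 0))
  z <- as.integer(ps$truth$labels == "functional")
  for (id in ps$truth$window$id) {
    x <- ps$panel$geno[, id]
    expect_true(all(x == z) || all(x == 1L - z))
  }
})

test_that("zero target FST gives near-zero mean per-SNP FST", {
  ps <- simulate_accession_panel(
    panel_sim_config(seed = 7, n_accessions = 200, n_labeled = 200,
                     focal_allele_frequency = 0.5, n_window_snps = 2,
                     n_genome_snps = 10000, fst_between_classes = 0,
                     n_geo_clusters = 2, n_null_clusters = 0))
  fst <- genomewide_fst(ps$panel, ps$truth$labels, "nei")
  # small positive sampling bias only
  expect_lt(abs(fst), 0.012)
})

test_that("infeasible panel configs error with the feasible bound", {
  expect_error(panel_sim_config(fst_between_classes = 1), "infeasible")
  expect_error(panel_sim_config(tag_ld_r2 = 1.4), "tag_ld_r2")
  expect_error(panel_sim_config(focal_allele_frequency = 0), "\\(0, 1\\)")
})
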