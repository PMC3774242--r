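test_that("window extraction uses a closed interval and fills missing", {
  offsets <- c(-120000, -100000, 0, 99000, 101000)
  n <- 6
  geno <- matrix(rep(c(0L, 1L), length.out = n * 5), n)
  snps <- data.frame(id = paste0("s", 1:5), chrom = "4",
                     pos = 269000 + offsets)
  acc <- data.frame(id = paste0("a", 1:n),
                    class = rep(c("functional", "nonfunctional"), 3))
  p <- snp_panel(geno, snps, acc, focal = list(chrom = "4", bp = 269000))
  w <- extract_window(p, half_span_bp = 100000)
  expect_equal(w$snp_ids, c("s2", "s3", "s4"))  # -100k, 0, +99k kept
  w0 <- extract_window(p, half_span_bp = 0)
  expect_equal(w0$snp_ids, "s3")
  expect_error(extract_window(p, focal = list(chrom = "2", bp = 5)),
               "no SNPs")
  # no missing data: features equal raw genotypes
  expect_identical(w$X, p$geno[, 2:4])
  # missing entries get the major allele, with a message
  p2 <- p
  p2$geno[1:2, 3] <- NA
  expect_message(w2 <- extract_window(p2, half_span_bp = 0), "filled")
  maj <- as.integer(mean(p$geno[3:6, 3]) > 0.5)
  expect_true(all(w2$X[1:2, 1] == maj))
})

test_that("a perfect tag window classifies perfectly in every protocol", {
  p <- perfect_tag_panel(n = 48, n_tags = 2, seed = 3)
  w <- extract_window(p)
  lab <- p$accessions$class
  cv <- kfold_cv(w, lab, k = 4, seed = 1)
  expect_equal(cv$mean_accuracy, 1)
  sl <- subset_loocv(w, lab, n = 12, repeats = 3, seed = 1)
  expect_equal(sl$mean_accuracy, 1)
  clf <- train_classifier(w, lab, seed = 1)
  imp <- impute_labels(clf, p)
  expect_identical(imp$predicted, lab)
})

test_that("label permutation drives CV accuracy to the majority baseline", {
  set.seed(91)
  ps <- simulate_accession_panel(
    panel_sim_config(seed = 12, n_accessions = 160, n_labeled = 160,
                     focal_allele_frequency = 0.5, n_window_snps = 15,
                     tag_ld_r2 = 0.8, n_genome_snps = 100,
                     snp_spacing_bp = 1e6, n_geo_clusters = 2,
                     n_null_clusters = 0))
  w <- extract_window(ps$panel)
  perm_lab <- sample(ps$panel$accessions$class)
  cv <- kfold_cv(w, perm_lab, k = 4, seed = 2)
  baseline <- max(table(perm_lab)) / length(perm_lab)
  # within ~3 binomial SE of the majority baseline: no leakage
  se <- sqrt(baseline * (1 - baseline) / length(perm_lab))
  expect_lt(abs(cv$mean_accuracy - baseline), 3 * se + 0.02)
})

test_that("hyperparameter selection is seed-reproducible", {
  ps <- simulate_accession_panel(
    panel_sim_config(seed = 17, n_accessions = 90, n_labeled = 90,
                     n_window_snps = 10, tag_ld_r2 = 0.6,
                     n_genome_snps = 60, snp_spacing_bp = 1e6,
                     n_geo_clusters = 2, n_null_clusters = 0))
  w <- extract_window(ps$panel)
  lab <- ps$panel$accessions$class
  a <- train_classifier(w, lab, seed = 5)
  b <- train_classifier(w, lab, seed = 5)
  expect_identical(c(a$gamma, a$cost), c(b$gamma, b$cost))
  cv1 <- kfold_cv(w, lab, k = 4, seed = 9)
  cv2 <- kfold_cv(w, lab, k = 4, seed = 9)
  expect_identical(cv1$fold_accuracies, cv2$fold_accuracies)
  expect_error(train_classifier(w, rep("functional", 90)), "two labeled")
})

test_that("subset LOOCV with the full labeled set equals plain LOOCV", {
  p <- perfect_tag_panel(n = 20, n_tags = 1, seed = 6)
  # flip two entries so accuracy is informative but below 1 for some folds
  p$geno[1, 1] <- 1L - p$geno[1, 1]
  w <- extract_window(p)
  lab <- p$accessions$class
  a <- subset_loocv(w, lab, n = 20, repeats = 1, seed = 3)
  b <- subset_loocv(w, lab, n = 20, repeats = 1, seed = 99)
  # the "subset" is the whole labeled set, so the draw does not matter
  expect_equal(a$mean_accuracy, b$mean_accuracy)
  expect_equal(length(a$fold_accuracies), 1)
})

test_that("imputed margins are sign-consistent and imputation recovers FST", {
  ps <- simulate_accession_panel(
    panel_sim_config(seed = 29, n_accessions = 250, n_labeled = 150,
                     focal_allele_frequency = 0.5, n_window_snps = 20,
                     tag_ld_r2 = 0.9, n_genome_snps = 4000,
                     fst_between_classes = 0.1,
                     n_geo_clusters = 2, n_null_clusters = 0))
  w <- extract_window(ps$panel)
  clf <- train_classifier(w, ps$panel$accessions$class, seed = 1)
  imp <- impute_labels(clf, ps$panel)
  pos_class <- attr(imp, "margin_positive_class")
  expect_true(all((imp$margin > 0) == (imp$predicted == pos_class)))
  # observed labels are preserved
  obs <- !is.na(ps$panel$accessions$class)
  expect_identical(imp$class[obs], ps$panel$accessions$class[obs])
  expect_true(all(imp$source[obs] == "observed"))
  # end-to-end: FST between imputed classes tracks FST between true classes
  fst_true <- genomewide_fst(ps$panel, ps$truth$labels)
  fst_imp <- genomewide_fst(ps$panel, imp$class)
  expect_lt(abs(fst_true - fst_imp), 0.02)
})

test_that("accessions missing the whole window are labeled unknown", {
  p <- perfect_tag_panel(n = 30, n_tags = 2, seed = 8)
  p$accessions$class[29:30] <- NA
  p$geno[30, ] <- NA
  w <- extract_window(snp_panel(p$geno[1:28, ], p$snps,
                                p$accessions[1:28, ], p$focal))
  clf <- train_classifier(w, p$accessions$class[1:28], seed = 1)
  imp <- impute_labels(clf, p)
  expect_equal(imp$source[30], "unknown")
  expect_true(is.na(imp$class[30]))
  expect_equal(imp$source[29], "imputed")
})
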