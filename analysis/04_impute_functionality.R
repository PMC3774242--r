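#!/usr/bin/env Rscript

# Stage 4: impute focal-locus functionality for unlabeled accessions.
#
# Trains a radial-basis-kernel classifier on the SNPs within 100 kb of the
# focal locus for the labeled accessions, reports fourfold CV accuracy and
# the subset leave-one-out accuracy curve over n = 10..40 (the sample-size
# sensitivity protocol), then imputes functionality for the whole panel.

suppressPackageStartupMessages(library(pleioscan))

dat <- "results/data"
out <- "results/impute"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

panel <- read_snp_panel(file.path(dat, "snp_panel.csv"),
                        accessions = file.path(dat, "accessions.csv"),
                        focal = list(chrom = "4", bp = 269000L))
labels <- panel$accessions$class
window <- extract_window(panel, half_span_bp = 100000)
cat(sprintf("window: %d SNPs within 100 kb; %d labeled accessions\n",
            length(window$snp_ids), sum(!is.na(labels))))

cv <- kfold_cv(window, labels, k = 4, seed = 46)
print(cv)

curve <- do.call(rbind, lapply(c(10, 15, 20, 25, 30, 35, 40), function(n) {
  sl <- subset_loocv(window, labels, n = n, repeats = 10, seed = 46 + n)
  cat(sprintf("  subset-LOOCV n = %2d: mean accuracy %.3f\n",
              n, sl$mean_accuracy))
  data.frame(n = n, mean_accuracy = sl$mean_accuracy)
}))

clf <- train_classifier(window, labels, seed = 47)
print(clf)
imp <- impute_labels(clf, panel)
truth <- read_truth(file.path(dat, "truth_panel.json"))
cat(sprintf("imputed %d accessions; agreement with truth: %.3f\n",
            sum(imp$source == "imputed"),
            mean(imp$class == truth$labels, na.rm = TRUE)))

write.csv(cv$fold_accuracies, file.path(out, "fourfold_accuracies.csv"),
          row.names = FALSE)
write.csv(curve, file.path(out, "subset_loocv_curve.csv"),
          row.names = FALSE)
write.csv(imp, file.path(out, "imputed_labels.csv"), row.names = FALSE)
cat("wrote", out, "\n")
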