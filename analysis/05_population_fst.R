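#!/usr/bin/env Rscript

# Stage 5: population differentiation between functionality classes.
#
# Computes genome-wide per-SNP Nei FST between the (imputed) functional
# and non-functional classes, a 1000-division permutation null preserving
# class counts, a frequency-matched bootstrap (divisions defined by SNPs
# whose minor-allele frequency matches the focal class frequency), and
# regional Ht/Hs FST on 50-kb-thinned SNPs within geographic clusters.

suppressPackageStartupMessages(library(pleioscan))

dat <- "results/data"
out <- "results/fst"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

panel <- read_snp_panel(file.path(dat, "snp_panel.csv"),
                        accessions = file.path(dat, "accessions.csv"),
                        focal = list(chrom = "4", bp = 269000L))
imp <- read.csv("results/impute/imputed_labels.csv",
                stringsAsFactors = FALSE)
labels <- imp$class[match(panel$accessions$id, imp$id)]
cat(sprintf("classes: %d functional / %d nonfunctional (imputed + observed)\n",
            sum(labels == "functional", na.rm = TRUE),
            sum(labels == "nonfunctional", na.rm = TRUE)))

res <- per_snp_fst(panel, labels, estimator = "nei")
print(res)
perm <- permutation_null(panel, labels, K = 1000, seed = 48)
print(perm)
boot <- frequency_matched_bootstrap(panel, labels, n_snps = 1000,
                                    tolerance = 0.02, K = 1000, seed = 49)
print(boot)

reg <- regional_fst(panel, labels, interval_bp = 50000)
truth <- read_truth(file.path(dat, "truth_panel.json"))
reg$null_cluster <- reg$cluster %in% truth$null_clusters
cat("\nregional Ht/Hs FST (50-kb thinned):\n")
print(reg, digits = 3)

write.csv(res$per_snp, file.path(out, "fst_per_snp.csv"), row.names = FALSE)
write.csv(reg, file.path(out, "fst_regional.csv"), row.names = FALSE)
jsonlite::write_json(
  list(mean_fst = res$mean_fst, n_snps = res$n_used,
       permutation_p = perm$p_value, bootstrap_p = boot$p_value),
  file.path(out, "fst_summary.json"), auto_unbox = TRUE, digits = NA)
cat("wrote", out, "\n")
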