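#!/usr/bin/env Rscript

# Stage 6: phenotype and climate association statistics.
#
# RIL side: relative growth rate from the two leaf-area measurements,
# genotype-class ANOVA (effect size as percent variance explained) at the
# marker nearest the shared QTL, and the WUE-FT genetic correlation.
# Panel side: Welch t-tests of the 19 climate variables between
# functionality classes with Bonferroni correction, and normalized mean
# ranks per class.

suppressPackageStartupMessages(library(pleioscan))

dat <- "results/data"
out <- "results/assoc"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cross <- read_cross(file.path(dat, "ril_geno.csv"),
                    file.path(dat, "ril_pheno.csv"), map_scale = "meiotic")
ph <- cross$panel$pheno
ph$gr_la <- growth_rate(ph$la_t1, ph$la_t2, 14, 21)
truth <- read_truth(file.path(dat, "truth_ril.json"))
mk4 <- cross$map[cross$map$chrom == truth$qtl$chrom[1], ]
nearest <- mk4$marker[which.min(abs(mk4$pos - truth$qtl$pos[1]))]
g <- cross$panel$geno[, nearest]
cat(sprintf("genotype-class ANOVA at %s (nearest the shared QTL):\n",
            nearest))
for (tr in c("wue", "ft", "gr_la")) {
  a <- one_way_anova(ph[[tr]], g)
  cat(sprintf("  %-5s F(%d,%d) = %6.1f, p = %.2g, PVE = %.1f%%\n",
              tr, a$df_between, a$df_within, a$F, a$p_value, a$pve))
}
gc <- genetic_correlation(ph$wue, ph$ft)
cat(sprintf("WUE-FT genetic correlation: r2 = %.3f (n = %d, p = %.2g)\n",
            gc$r2, gc$n, gc$p_value))

climate <- read.csv(file.path(dat, "climate.csv"),
                    stringsAsFactors = FALSE)
imp <- read.csv("results/impute/imputed_labels.csv",
                stringsAsFactors = FALSE)
climate$class <- imp$class[match(climate$id, imp$id)]
ct <- climate_tests(climate)
cat(sprintf("\nclimate t-tests: %d of %d variables significant after Bonferroni\n",
            sum(ct$significant), nrow(ct)))
print(ct[ct$significant, c("variable", "t", "p", "p_bonf")], digits = 3)
rs <- rank_summary(climate)

write.csv(ct, file.path(out, "climate_tests.csv"), row.names = FALSE)
write.csv(rs, file.path(out, "climate_ranks.csv"), row.names = FALSE)
jsonlite::write_json(
  list(wue_ft_r2 = gc$r2, n = gc$n,
       n_climate_significant = sum(ct$significant)),
  file.path(out, "assoc_summary.json"), auto_unbox = TRUE, digits = NA)
cat("wrote", out, "\n")
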