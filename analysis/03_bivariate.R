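#!/usr/bin/env Rscript

# Stage 3: bivariate co-localization of the WUE and FT scans.
#
# Standardizes each trait's LOD profile by its genome-wide maximum, sums
# the standardized scores over the grid, and reports the joint peak and
# the bivariate interval (peak-fraction rule, alpha = 0.5).

suppressPackageStartupMessages(library(pleioscan))

qtl <- "results/qtl"
out <- "results/bivariate"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

load_prof <- function(tr) {
  df <- read.csv(file.path(qtl, sprintf("lod_%s.csv", tr)),
                 colClasses = c(chrom = "character"))
  grid <- structure(df[c("chrom", "pos")],
                    class = c("pseudo_grid", "data.frame"))
  pleioscan:::.lod_profile(grid, df$lod, tr)
}

p1 <- standardize_profile(load_prof("wue"))
p2 <- standardize_profile(load_prof("ft"))
bp <- sum_profiles(p1, p2)
print(bp)
iv <- bivariate_interval(bp, rule = "peak_fraction", param = 0.5)
cat(sprintf("bivariate interval: chr %s, %.1f - %.1f cM (peak %.1f cM)\n",
            iv$chrom, iv$start, iv$end, iv$peak_pos))

truth <- read_truth("results/data/truth_ril.json")
cat(sprintf("true shared QTL: chr %s @ %g cM; covered: %s\n",
            truth$qtl$chrom[1], truth$qtl$pos[1],
            iv$chrom == truth$qtl$chrom[1] &&
              iv$start <= truth$qtl$pos[1] && iv$end >= truth$qtl$pos[1]))

write.csv(as.data.frame(bp), file.path(out, "bivariate_profile.csv"),
          row.names = FALSE)
jsonlite::write_json(iv, file.path(out, "bivariate_interval.json"),
                     auto_unbox = TRUE, digits = NA)
cat("wrote", out, "\n")
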