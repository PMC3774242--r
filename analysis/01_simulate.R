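#!/usr/bin/env Rscript

# Stage 1: generate the synthetic study populations with known ground truth.
#
# Two datasets are produced under results/data/:
#   - a 343-line, 166-marker F9 RIL population segregating a shared
#     pleiotropic QTL (chromosome 4, 4 cM) for water-use efficiency,
#     flowering time and growth rate, plus one trait-specific QTL per
#     mapped trait;
#   - a 1188-accession panel (317 with observed focal-locus functionality
#     labels) with a tagged 100-kb SNP window, genome-wide
#     class-differentiated SNPs, 11 geographic clusters (one carrying no
#     differentiation) and 19 climate variables.

suppressPackageStartupMessages(library(pleioscan))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ril <- simulate_ril_panel(ril_sim_config(seed = 42))
print(ril$panel)
write_cross(ril$panel, file.path(out, "ril_geno.csv"),
            file.path(out, "ril_pheno.csv"))
write_truth(ril$truth, file.path(out, "truth_ril.json"))
cat(sprintf("true QTL: %s\n",
            paste(sprintf("chr%s@%gcM", ril$truth$qtl$chrom,
                          ril$truth$qtl$pos), collapse = ", ")))

acc <- simulate_accession_panel(panel_sim_config(seed = 43))
print(acc$panel)
write_snp_matrix(acc$panel, file.path(out, "snp_panel.csv"))
write_accessions(acc$panel, file.path(out, "accessions.csv"))
write.csv(acc$climate, file.path(out, "climate.csv"), row.names = FALSE)
write_truth(acc$truth, file.path(out, "truth_panel.json"))
cat(sprintf("functional allele frequency (truth): %.3f\n",
            mean(acc$truth$labels == "functional")))
cat(sprintf("genome-wide target FST between classes: %.3f (%d SNPs)\n",
            acc$truth$fst_target, nrow(acc$panel$snps)))
cat("wrote", out, "\n")
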