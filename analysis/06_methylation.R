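#!/usr/bin/env Rscript
# Step 6: genome-wide methylation analysis.
#
# Applies the probe exclusions (sex chromosomes, TSS CpG islands for the
# intergenic view, low-variance probes, 12,000-probe subsample for
# clustering), bins the intergenic probes in 300-kb windows, clusters the
# samples, and detects group-A-specific hypomethylated bins; promoter
# methylation of the planted hypermethylated gene is summarized last.

suppressPackageStartupMessages(library(gistomics))
dir.create("results", showWarnings = FALSE)

bundle <- generate_cohort(cohort_config(seed = 1L))
groups <- bundle$truth$groups

# clustering view: all exclusions + subsample (mirrors the probe-filtering
# cascade of EPIC-array studies; subsample size scaled to the desk-scale
# manifest)
fp_cluster <- filter_probes(bundle$beta, bundle$beta_manifest,
                            steps = c("drop_sex", "drop_tss_cgi",
                                      "variance_filter", "subsample"),
                            delta = 0.1, n = 12000, seed = 1)
print(fp_cluster$log)
cl <- cluster_samples(fp_cluster$beta, k = 2)
cat("\nk=2 probe-level clusters vs group:\n")
print(table(cluster = cl$clusters, group = groups[names(cl$clusters)]))

# intergenic 300-kb bin view
fp <- filter_probes(bundle$beta, bundle$beta_manifest,
                    steps = c("drop_sex", "drop_tss_cgi"))
bb <- bin_beta(fp$beta, fp$manifest)
det <- detect_group_hypomethylation(bb, groups)
truth_bins <- bundle$truth$hypomethylated_bins
got <- paste0(det$bins$chrom, ":", det$bins$start)
cat("\nhypomethylated bins flagged:", nrow(det$bins), "of",
    nrow(bb$means), "; sensitivity vs truth:",
    round(mean(truth_bins %in% got), 3), "\n")
write.table(det$bins, "results/hypomethylated_bins.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
# BED track of flagged bins
write.table(det$bins[, c("chrom", "start", "end")],
            "results/hypomethylated_bins.bed", sep = "\t", quote = FALSE,
            row.names = FALSE, col.names = FALSE)

# promoter methylation of the planted gene
ph <- bundle$truth$promoter_hypermeth
man <- bundle$beta_manifest
gp <- list(man$probe[!is.na(man$gene) & man$gene == ph$gene])
names(gp) <- ph$gene
pm <- promoter_methylation(bundle$beta, gp)
cat("\npromoter beta of", ph$gene, "- planted sample",
    ph$samples, ":", round(pm[1, ph$samples], 3),
    "; cohort median:", round(median(pm[1, ]), 3), "\n")
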