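#!/usr/bin/env Rscript
# Step 1: simulate the synthetic 30-sample GIST cohort.
#
# Generates every omics layer (sample sheet with planted KIT exon-11
# mutations, SNV/indel/SV call sets, allele-specific CN segments, the
# methylation beta matrix, the raw expression matrix, mask tracks and gene
# models) with the planted group-dependent effects, and writes the bundle as
# plain-text files plus a JSON truth record. All downstream steps regenerate
# the same bundle deterministically from the seed, so this step exists to
# materialize the files for inspection.

suppressPackageStartupMessages(library(gistomics))

seed <- 1L
outdir <- "results/cohort"

cfg <- cohort_config(seed = seed)
bundle <- generate_cohort(cfg)
print(bundle)

files <- write_cohort(bundle, outdir)
cat("wrote", length(files), "files to", outdir, "\n")

burd <- bundle_burdens(bundle)
agg <- aggregate(cbind(sv, snv, indel) ~ group, burd, mean)
cat("\nmean burdens per group:\n")
print(agg, row.names = FALSE)
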