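test_that("invalid configurations are rejected", {
  expect_error(cohort_config(group_sizes = c(A = -1, B = 6, C = 6, D = 6)),
               ">= 0")
  bad_mix <- list(A = c(SBSS1 = 0.5, SBSS2 = 0.6),
                  B = c(SBSS1 = 1), C = c(SBSS1 = 1), D = c(SBSS1 = 1))
  expect_error(cohort_config(sbs_mix = bad_mix), "sum to 1")
  expect_error(cohort_config(sv_imprecise_frac = 1.5), "\\[0, 1\\]")
  expect_error(cohort_config(genome = data.frame()), "genome|centromere")
})

test_that("the bundle is a deterministic function of config and seed", {
  b1 <- generate_cohort(light_config(seed = 5))
  b2 <- generate_cohort(light_config(seed = 5))
  expect_identical(b1, b2)
  b3 <- generate_cohort(light_config(seed = 6))
  expect_false(identical(b1$snv, b3$snv))
})

test_that("the default design has 12 A, 6 B, 6 C, 6 D samples with
           consistent KIT mutation strings", {
  b <- generate_cohort(light_config(seed = 2))
  sheet <- b$sample_sheet
  expect_equal(unname(c(table(sheet$group)[c("A", "B", "C", "D")])),
               c(12L, 6L, 6L, 6L))
  # planted mutation strings reproduce the group labels through the
  # classification rule
  cls <- classify_cases(data.frame(case_id = sheet$sample,
                                   risk = sheet$risk,
                                   derivation = sheet$derivation,
                                   mutation = sheet$mutation))
  expect_equal(cls$group, sheet$group)
})

test_that("sample ids are consistent across all omics layers", {
  b <- generate_cohort(light_config(seed = 3))
  ids <- b$sample_sheet$sample
  expect_setequal(unique(b$snv$sample), ids)
  expect_setequal(unique(b$sv$sample), ids)
  expect_setequal(unique(b$cn_segments$sample), ids)
  expect_identical(colnames(b$beta), ids)
  expect_identical(colnames(b$expression), ids)
})

test_that("copy-number segments tile every chromosome without gaps", {
  b <- generate_cohort(light_config(seed = 4))
  glen <- stats::setNames(b$config$genome$length, b$config$genome$chrom)
  for (sm in unique(b$cn_segments$sample)[1:5]) {
    for (ch in names(glen)) {
      seg <- b$cn_segments[b$cn_segments$sample == sm &
                             b$cn_segments$chrom == ch, ]
      seg <- seg[order(seg$start), ]
      expect_equal(seg$start[1], 0)
      expect_equal(seg$end[nrow(seg)], unname(glen[ch]))
      if (nrow(seg) > 1)
        expect_equal(seg$start[-1], seg$end[-nrow(seg)])
    }
  }
})

test_that("pure single-signature mutation sets reproduce the catalog column", {
  cat5 <- synthetic_catalog("SBS96")
  cfg <- light_config(seed = 10,
    sbs_mix = list(A = c(SBSS1 = 0, SBSS2 = 0, SBSS3 = 1, SBSS4 = 0,
                         SBSS5 = 0),
                   B = c(SBSS1 = 1, SBSS2 = 0, SBSS3 = 0, SBSS4 = 0,
                         SBSS5 = 0),
                   C = c(SBSS1 = 1, SBSS2 = 0, SBSS3 = 0, SBSS4 = 0,
                         SBSS5 = 0),
                   D = c(SBSS1 = 1, SBSS2 = 0, SBSS3 = 0, SBSS4 = 0,
                         SBSS5 = 0)))
  set.seed(101)
  mut <- gistomics:::generate_mutations("A", cfg, n_override = 10000)
  cats <- mapply(sbs96_context, mut$snv$trinucleotide, mut$snv$ref,
                 mut$snv$alt)
  prof <- build_profile(cats, "SBS96")
  expect_gt(cosine_similarity(prof, cat5[, "SBSS3"]), 0.99)
})

test_that("a zero burden mean yields an empty mutation set", {
  cfg <- light_config(seed = 11,
    burden_means = list(A = c(snv = 0, indel = 0, sv = 0),
                        B = c(snv = 0, indel = 0, sv = 0),
                        C = c(snv = 0, indel = 0, sv = 0),
                        D = c(snv = 0, indel = 0, sv = 0)))
  set.seed(1)
  mut <- gistomics:::generate_mutations("A", cfg)
  expect_equal(nrow(mut$snv), 0L)
  expect_equal(nrow(mut$indel), 0L)
  expect_error(gistomics:::generate_mutations("Z", cfg), "missing")
})

test_that("a 3x burden ratio is detected by Welch tests in most seeds", {
  cfg <- light_config(seed = 1,
    burden_means = list(A = c(snv = 300, indel = 0, sv = 0),
                        B = c(snv = 100, indel = 0, sv = 0),
                        C = c(snv = 100, indel = 0, sv = 0),
                        D = c(snv = 100, indel = 0, sv = 0)))
  hits <- 0L
  n_seeds <- 100L
  for (s in seq_len(n_seeds)) {
    set.seed(1000 + s)
    a <- stats::rnbinom(12, mu = 300, size = cfg$burden_dispersion)
    d <- stats::rnbinom(6, mu = 100, size = cfg$burden_dispersion)
    if (welch_t(a, d)$p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.9)
  # the same negative-binomial draw is what the generator uses: spot-check
  # the generated per-sample counts against the configured scale
  b <- generate_cohort(cfg)
  burd <- bundle_burdens(b)
  expect_gt(mean(burd$snv[burd$group == "A"]),
            mean(burd$snv[burd$group == "D"]))
})

test_that("a forced arm deletion drives every group-A sample below CN 1.5", {
  cfg <- light_config(seed = 12,
    arm_deletion_probs = list(
      A = c(chr2q = 1.0), B = c(chr2q = 0), C = c(chr2q = 0),
      D = c(chr2q = 0)),
    wgd_samples = c(A = 0L, D = 0L))
  b <- generate_cohort(cfg)
  arms <- arm_table(cfg$genome)
  ac <- suppressWarnings(
    arm_average_cn(b$cn_segments, arms[arms$arm == "chr2q", ]))
  grp <- b$truth$groups[ac$sample]
  expect_true(all(ac$mean_cn[grp == "A"] <= 1.5))
  expect_true(all(ac$mean_cn[grp != "A"] > 1.5))
})

test_that("the truth record books every planted effect", {
  b <- generate_cohort(light_config(seed = 13))
  expect_equal(unname(b$truth$groups), b$sample_sheet$group)
  expect_equal(nrow(b$truth$de_genes), b$config$de_genes)
  expect_true("SNAI2" %in% b$truth$de_genes$gene)
  expect_true(all(abs(b$truth$de_genes$log2_shift) >=
                    b$config$de_shift_range[1]))
  # hypomethylated bins: the configured fraction of autosomal bins
  man <- b$beta_manifest
  auto_bins <- unique(sprintf(
    "%s:%.0f", man$chrom[!man$is_sex_chrom],
    man$pos[!man$is_sex_chrom] %/% 3e5 * 3e5))
  expect_equal(length(b$truth$hypomethylated_bins),
               round(b$config$hypomethylation[["fraction"]] *
                       length(auto_bins)))
  expect_true(all(b$truth$hypomethylated_bins %in% auto_bins))
  # promoter hypermethylation sample is a group-A sample
  ph <- b$truth$promoter_hypermeth
  expect_equal(unname(b$truth$groups[ph$samples]), "A")
})

test_that("a zero hypomethylation shift leaves group A at the cohort mean", {
  cfg <- light_config(seed = 14,
                      hypomethylation = c(fraction = 0.4, shift = 0))
  b <- generate_cohort(cfg)
  fp <- filter_probes(b$beta, b$beta_manifest,
                      steps = c("drop_sex", "drop_tss_cgi"))
  bb <- bin_beta(fp$beta, fp$manifest)
  grp <- b$truth$groups[colnames(bb$means)]
  mean_a <- mean(bb$means[, grp == "A"])
  mean_rest <- mean(bb$means[, grp != "A"])
  expect_lt(abs(mean_a - mean_rest), 0.01)
  det <- detect_group_hypomethylation(bb, b$truth$groups)
  expect_equal(nrow(det$bins), 0L)
})

test_that("planted promoter hypermethylation is recovered per gene", {
  b <- generate_cohort(light_config(seed = 15))
  ph <- b$truth$promoter_hypermeth
  man <- b$beta_manifest
  gene_probes <- list(man$probe[!is.na(man$gene) & man$gene == ph$gene])
  names(gene_probes) <- ph$gene
  pm <- promoter_methylation(b$beta, gene_probes)
  target <- pm[ph$gene, ph$samples]
  others <- pm[ph$gene, setdiff(colnames(pm), ph$samples)]
  expect_gt(target, mean(others) + 0.2)
})

test_that("bundles round-trip through the plain-text writers", {
  b <- generate_cohort(light_config(seed = 16))
  dir <- withr::local_tempdir()
  files <- write_cohort(b, dir)
  expect_true(all(file.exists(files)))

  sv <- read_sv_vcf(file.path(dir, "svs.vcf"))
  expect_equal(nrow(sv), nrow(b$sv))
  expect_equal(sv$pos1, b$sv$pos1)
  expect_equal(sv$svclass, b$sv$svclass)
  expect_equal(sv$imprecise, b$sv$imprecise)
  expect_equal(sv$chrom2, b$sv$chrom2)

  seg <- read_seg(file.path(dir, "cn_segments.seg.tsv"))
  expect_equal(nrow(seg), nrow(b$cn_segments))
  expect_equal(seg$total_cn, b$cn_segments$total_cn, tolerance = 1e-9)

  beta <- read_matrix_tsv(file.path(dir, "beta_matrix.tsv"))
  expect_equal(dim(beta), dim(b$beta))
  expect_equal(unname(beta[5, ]), unname(b$beta[5, ]), tolerance = 1e-9)

  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_setequal(truth$de_genes$gene, b$truth$de_genes$gene)
})
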