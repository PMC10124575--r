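make_sv <- function(chrom1 = "chr1", pos1 = 1000L, chrom2 = "chr1",
                    pos2 = 5000L, svclass = "deletion",
                    imprecise = FALSE, id = "sv1") {
  data.frame(sv_id = id, chrom1 = chrom1, pos1 = pos1, chrom2 = chrom2,
             pos2 = pos2, svclass = svclass, imprecise = imprecise,
             stringsAsFactors = FALSE)
}

test_that("precision and mask-proximity filtering with reasons", {
  masks <- list(
    segmental_duplications = data.frame(chrom = "chr1", start = 2000,
                                        end = 2500),
    encode_blacklist = data.frame(chrom = "chr2", start = 100, end = 400))
  svs <- rbind(
    make_sv(pos1 = 2650, pos2 = 9000, id = "far"),       # 150 bp away
    make_sv(pos1 = 2550, pos2 = 9000, id = "near"),      # 50 bp away
    make_sv(pos1 = 9000, pos2 = 20000, id = "imp", imprecise = TRUE),
    make_sv(pos1 = 2600, pos2 = 9000, id = "edge100"),   # exactly 100 bp
    make_sv(pos1 = 2200, pos2 = 9000, id = "inside"))
  res <- filter_svs(svs, masks)
  expect_setequal(res$kept$sv_id, "far")
  expect_equal(res$discarded$reason[res$discarded$sv_id == "near"],
               "segmental_duplications")
  expect_equal(res$discarded$reason[res$discarded$sv_id == "imp"],
               "imprecise")
  # the 100-bp rule is inclusive
  expect_true("edge100" %in% res$discarded$sv_id)
  expect_true("inside" %in% res$discarded$sv_id)
  # partition: kept and discarded recompose the input
  expect_setequal(c(res$kept$sv_id, res$discarded$sv_id), svs$sv_id)
  # idempotence on the kept set
  res2 <- filter_svs(res$kept, masks)
  expect_equal(res2$kept$sv_id, res$kept$sv_id)
  expect_equal(nrow(res2$discarded), 0L)
})

test_that("an SV whose second breakpoint is near a mask is discarded", {
  masks <- list(simple_repeats = data.frame(chrom = "chr1", start = 10000,
                                            end = 10500))
  sv <- make_sv(pos1 = 1000, pos2 = 10550)  # bp2 50 bp from the mask
  res <- filter_svs(sv, masks)
  expect_equal(nrow(res$kept), 0L)
  expect_equal(res$discarded$reason, "simple_repeats")
})

test_that("breakpoint chromosomes absent from the mask universe warn", {
  masks <- list(microsatellites = data.frame(chrom = "chr1", start = 0,
                                             end = 100))
  expect_warning(res <- filter_svs(make_sv(chrom1 = "chr9", pos1 = 5,
                                           chrom2 = "chr9"), masks),
                 "absent from mask universe")
  expect_equal(nrow(res$kept), 1L)
})

test_that("mask distance agrees with a linear-scan oracle", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 200
    starts <- sort(sample.int(5e5, n))
    ends <- starts + sample.int(300, n, replace = TRUE)
    mask <- list(simple_repeats = data.frame(chrom = "chr1", start = starts,
                                             end = ends))
    positions <- sample.int(5e5 + 1000, 50)
    for (p in positions) {
      d_oracle <- oracle_mask_distance(p, starts, ends)
      res <- filter_svs(make_sv(pos1 = p, pos2 = 9e9, chrom2 = "chr1"),
                        mask)
      expect_equal(nrow(res$discarded) == 1L, d_oracle <= 100,
                   info = paste("pos", p, "oracle dist", d_oracle))
    }
  }
})

test_that("breakend orientations map to the five SV classes", {
  expect_equal(classify_sv("chr1", 100, "+", "chr2", 500, "-"),
               "translocation")
  expect_equal(classify_sv("chr1", 100, "+", "chr1", 5000, "-"), "deletion")
  expect_equal(classify_sv("chr1", 100, "-", "chr1", 5000, "+"),
               "duplication")
  expect_equal(classify_sv("chr1", 100, "+", "chr1", 5000, "+"),
               "inversion")
  expect_equal(classify_sv("chr1", 100, "-", "chr1", 5000, "-"),
               "inversion")
  # orientation is read left-to-right regardless of mate order
  expect_equal(classify_sv("chr1", 5000, "-", "chr1", 100, "+"), "deletion")
  expect_equal(classify_sv("chr1", 100, "+", "chr1", 5000, "-",
                           has_insertion = TRUE), "insertion")
  expect_error(classify_sv("chr1", 100, "+", NA, NA, "-"), "missing mate")
})

toy_genes <- function() {
  data.frame(
    symbol = c("TSG1", "ONC1"),
    chrom = c("chr1", "chr1"),
    start = c(10000, 50000), end = c(20000, 60000),
    strand = c("+", "-"),
    cds_start = c(11000, 51000), cds_end = c(19000, 59000),
    exon_starts = c("10000,14000,18000", "50000,55000"),
    exon_ends = c("12000,16000,20000", "52000,60000"),
    role = c("TSG", "oncogene"),
    stringsAsFactors = FALSE)
}

test_that("TSG coding disruption yields tier 3, database match tier 2", {
  genes <- toy_genes()
  # deletion spanning two coding exons of the TSG
  del <- make_sv(pos1 = 13000, pos2 = 17000)
  ann <- annotate_and_tier(del, genes)
  expect_equal(ann$tier, 3L)
  # fully intergenic inversion: no tier
  inv <- make_sv(pos1 = 30000, pos2 = 40000, svclass = "inversion")
  expect_true(is.na(annotate_and_tier(inv, genes)$tier))
  expect_equal(annotate_and_tier(inv, genes)$breakpoints$gene,
               c("intergenic", "intergenic"))
  # duplication matching a curated driver entry: tier 2 beats tier 3
  dupl <- make_sv(pos1 = 52000, pos2 = 58000, svclass = "duplication")
  db <- data.frame(gene = "ONC1", svclass = "duplication")
  expect_equal(annotate_and_tier(dupl, genes, db)$tier, 2L)
  expect_true(is.na(annotate_and_tier(dupl, genes)$tier))  # oncogene, no db
  # empty gene set: everything intergenic, no tier
  ann0 <- annotate_and_tier(del, genes[0, ])
  expect_true(is.na(ann0$tier))
  expect_equal(ann0$breakpoints$gene, c("intergenic", "intergenic"))
})

test_that("breakpoints are annotated with exon/intron indices", {
  genes <- toy_genes()
  sv <- make_sv(pos1 = 11000, pos2 = 13000)
  ann <- annotate_and_tier(sv, genes)
  expect_equal(ann$breakpoints$gene, c("TSG1", "TSG1"))
  expect_equal(ann$breakpoints$feature, c("exon1", "intron1"))
  # minus-strand gene: exon indices count from the transcription start
  sv2 <- make_sv(pos1 = 51000, pos2 = 59000)
  ann2 <- annotate_and_tier(sv2, genes)
  expect_equal(ann2$breakpoints$feature, c("exon2", "exon1"))
})

test_that("enlarging a tier-3 deletion never lowers its tier", {
  genes <- toy_genes()
  base <- make_sv(pos1 = 13000, pos2 = 17000)
  expect_equal(annotate_and_tier(base, genes)$tier, 3L)
  for (grow in c(1000, 5000, 12000)) {
    big <- make_sv(pos1 = 13000 - grow, pos2 = 17000 + grow)
    expect_true(annotate_and_tier(big, genes)$tier <= 3L)
  }
})
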