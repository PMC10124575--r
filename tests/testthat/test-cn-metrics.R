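genome4 <- default_genome()           # 3 autosomes + chrX, 60 Mb, cen 25 Mb
arms4 <- arm_table(genome4)
auto_arms <- arms4[!arms4$is_sex, ]

test_that("arm averages are length-weighted with strict deletion rule", {
  segs <- flat_segments()
  ac <- quiet_arm_calls(segs, auto_arms[auto_arms$chrom == "chr1", ])
  expect_equal(ac$mean_cn, c(2, 2))
  expect_equal(ac$status, c("neutral", "neutral"))
  expect_false(any(ac$deleted))

  # half the p arm at CN 1, half at CN 2: mean exactly 1.5, loss by status
  # (<= 1.5) but NOT deleted (strict < 1.5)
  segs2 <- data.frame(sample = "s1", chrom = "chr1",
                      start = c(0, 12.5e6, 25e6),
                      end = c(12.5e6, 25e6, 60e6),
                      total_cn = c(1, 2, 2), minor_cn = c(0, 1, 1))
  ac2 <- quiet_arm_calls(segs2, auto_arms[auto_arms$chrom == "chr1", ])
  p_arm <- ac2[ac2$arm == "chr1p", ]
  # oracle: weighted mean by hand
  expect_equal(p_arm$mean_cn, (1 * 12.5e6 + 2 * 12.5e6) / 25e6)
  expect_equal(p_arm$status, "loss")
  expect_false(p_arm$deleted)

  # full arm at CN 1: deleted under the printed < 1.5 rule
  segs3 <- flat_segments(total = 1, minor = 0)
  ac3 <- quiet_arm_calls(segs3, auto_arms[auto_arms$chrom == "chr1", ])
  expect_true(all(ac3$deleted))

  # uncovered arm: missing call with a warning
  segs4 <- data.frame(sample = "s1", chrom = "chr1", start = 0, end = 25e6,
                      total_cn = 2, minor_cn = 1)
  expect_warning(ac4 <- arm_average_cn(segs4,
                                       auto_arms[auto_arms$chrom == "chr1", ]),
                 "zero covered")
  expect_true(is.na(ac4$mean_cn[ac4$arm == "chr1q"]))
})

test_that("ploidy score counts non-neutral autosomal arms", {
  ac <- quiet_arm_calls(flat_segments(), auto_arms)
  expect_equal(ploidy_score(ac), 0L)
  # one gained and one lost arm
  segs <- rbind(
    data.frame(sample = "s1", chrom = "chr1", start = c(0, 25e6),
               end = c(25e6, 60e6), total_cn = c(3, 2), minor_cn = c(1, 1)),
    data.frame(sample = "s1", chrom = "chr2", start = c(0, 25e6),
               end = c(25e6, 60e6), total_cn = c(2, 1), minor_cn = c(1, 0)),
    data.frame(sample = "s1", chrom = "chr3", start = 0, end = 60e6,
               total_cn = 2, minor_cn = 1))
  expect_equal(ploidy_score(quiet_arm_calls(segs, auto_arms)), 2L)
  # all six autosomal arms lost
  lost <- do.call(rbind, lapply(c("chr1", "chr2", "chr3"), function(ch)
    flat_segments(chrom = ch, total = 1, minor = 0)))
  expect_equal(ploidy_score(quiet_arm_calls(lost, auto_arms)), 6L)
})

test_that("ploidy score is invariant to equal-CN segment splitting", {
  segs <- rbind(
    data.frame(sample = "s1", chrom = "chr1", start = 0, end = 60e6,
               total_cn = 3, minor_cn = 1),
    flat_segments(chrom = "chr2"), flat_segments(chrom = "chr3"))
  split_segs <- do.call(rbind, lapply(seq_len(nrow(segs)), function(i) {
    s <- segs[i, ]
    mid <- (s$start + s$end) / 2
    rbind(transform(s, end = mid), transform(s, start = mid))
  }))
  expect_equal(ploidy_score(quiet_arm_calls(segs, auto_arms)),
               ploidy_score(quiet_arm_calls(split_segs, auto_arms)))
})

test_that("WGD flag uses the length-weighted genome mean", {
  expect_true(call_wgd(flat_segments(total = 4))$wgd)
  expect_false(call_wgd(flat_segments(total = 2))$wgd)
  # mixed segments with mean just above 3 (oracle by hand)
  segs <- data.frame(sample = "s1", chrom = "chr1",
                     start = c(0, 30e6), end = c(30e6, 60e6),
                     total_cn = c(2.2, 4.0), minor_cn = c(1, 2))
  expect_equal(call_wgd(segs)$mean_cn, 3.1)
  expect_true(call_wgd(segs)$wgd)
  # monotone in a uniform offset
  for (off in c(0.5, 1, 2))
    expect_true(call_wgd(transform(segs, total_cn = total_cn + off))$wgd)
})

test_that("HRD components match hand-built segment oracles", {
  # fully diploid balanced genome
  dip <- do.call(rbind, lapply(genome4$chrom[1:3], function(ch)
    flat_segments(chrom = ch)))
  h <- hrd_score(dip, genome4)
  expect_equal(c(h$loh, h$tai, h$lst, h$hrd_sum), c(0L, 0L, 0L, 0L))

  # one 20-Mb interstitial LOH segment: LOH + 2 LSTs (both flanks >= 10 Mb)
  seg <- data.frame(sample = "s1", chrom = "chr1",
                    start = c(0, 20e6, 40e6), end = c(20e6, 40e6, 60e6),
                    total_cn = c(2, 2, 2), minor_cn = c(1, 0, 1))
  h2 <- hrd_score(rbind(seg, flat_segments(chrom = "chr2"),
                        flat_segments(chrom = "chr3")), genome4)
  expect_equal(h2$loh, 1L)
  expect_equal(h2$tai, 0L)   # interstitial: touches no telomere
  expect_equal(h2$lst, 2L)
  expect_equal(h2$hrd_sum, h2$loh + h2$tai + h2$lst)

  # whole-chromosome LOH is excluded from the LOH score
  whole <- rbind(flat_segments(chrom = "chr1", total = 2, minor = 0),
                 flat_segments(chrom = "chr2"),
                 flat_segments(chrom = "chr3"))
  expect_equal(hrd_score(whole, genome4)$loh, 0L)

  # telomeric allelic imbalance: 15-Mb imbalanced tail not crossing the
  # centromere
  tai_seg <- data.frame(sample = "s1", chrom = "chr1",
                        start = c(0, 45e6), end = c(45e6, 60e6),
                        total_cn = c(2, 3), minor_cn = c(1, 1))
  h3 <- hrd_score(rbind(tai_seg, flat_segments(chrom = "chr2"),
                        flat_segments(chrom = "chr3")), genome4)
  expect_equal(h3$tai, 1L)
  # the same imbalance crossing the centromere does not count
  tai_cross <- data.frame(sample = "s1", chrom = "chr1",
                          start = c(0, 20e6), end = c(20e6, 60e6),
                          total_cn = c(2, 3), minor_cn = c(1, 1))
  h4 <- hrd_score(rbind(tai_cross, flat_segments(chrom = "chr2"),
                        flat_segments(chrom = "chr3")), genome4)
  expect_equal(h4$tai, 0L)

  # conservation holds on every input
  for (h in list(h2, h3, h4))
    expect_equal(h$hrd_sum, h$loh + h$tai + h$lst)

  expect_error(hrd_score(transform(dip, minor_cn = NA), genome4),
               "minor copy number")
})

test_that("short segments are smoothed out of the LST computation", {
  # a 2-Mb interruption inside a long segment does not create transitions
  seg <- data.frame(sample = "s1", chrom = "chr1",
                    start = c(0, 29e6, 31e6), end = c(29e6, 31e6, 60e6),
                    total_cn = c(2, 4, 2), minor_cn = c(1, 1, 1))
  h <- hrd_score(rbind(seg, flat_segments(chrom = "chr2"),
                       flat_segments(chrom = "chr3")), genome4)
  expect_equal(h$lst, 0L)
})

test_that("group comparisons: Fisher oracle and planted arm deletion", {
  # identical groups: Fisher p = 1
  segs <- do.call(rbind, lapply(sprintf("s%02d", 1:8), function(s)
    flat_segments(sample = s, chrom = "chr2")))
  groups <- stats::setNames(rep(c("A", "B"), each = 4),
                            sprintf("s%02d", 1:8))
  ac <- quiet_arm_calls(segs, auto_arms[auto_arms$chrom == "chr2", ])
  # add tiny distinct noise so Welch is defined
  set.seed(1)
  ac$mean_cn <- ac$mean_cn + rnorm(nrow(ac), 0, 1e-3)
  cmp <- compare_arm_groups(ac, groups, "chr2q")
  expect_equal(cmp$fisher_p, 1)

  # forced deletion in all 6 target vs none of 6: Fisher p = 2/C(12,6)
  segs2 <- do.call(rbind, lapply(1:12, function(i)
    flat_segments(sample = sprintf("s%02d", i), chrom = "chr2",
                  total = if (i <= 6) 1 else 2,
                  minor = if (i <= 6) 0 else 1)))
  groups2 <- stats::setNames(rep(c("A", "B"), each = 6),
                             sprintf("s%02d", 1:12))
  ac2 <- quiet_arm_calls(segs2, auto_arms[auto_arms$chrom == "chr2", ])
  set.seed(2)
  ac2$mean_cn <- ac2$mean_cn + rnorm(nrow(ac2), 0, 1e-3)
  cmp2 <- compare_arm_groups(ac2, groups2, "chr2q")
  # oracle: only the two extreme tables among C(12,6) arrangements reach
  # this imbalance, so p = 2 / 924
  expect_equal(cmp2$fisher_p, 2 / choose(12, 6), tolerance = 1e-10)
  expect_lt(cmp2$welch_p, 1e-6)
  expect_equal(unname(cmp2$deleted_table[1, ]), c(6, 0))
})
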