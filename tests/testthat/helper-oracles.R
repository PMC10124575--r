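# Brute-force oracles and small fixtures shared across the suite.

# linear-scan distance from a 1-based point to the nearest base of any
# 0-based half-open interval (independent of the package's implementation)
oracle_mask_distance <- function(pos, starts, ends) {
  if (!length(starts)) return(Inf)
  d <- Inf
  for (i in seq_along(starts)) {
    bases <- (starts[i] + 1):ends[i]
    d <- min(d, min(abs(pos - bases)))
  }
  d
}

# dense grid search for the best nonnegative 2-signature combination
oracle_grid_nnls2 <- function(profile, catalog2, upper, step) {
  best <- c(NA, NA); best_err <- Inf
  for (a in seq(0, upper, by = step)) for (b in seq(0, upper, by = step)) {
    err <- sum((profile - catalog2 %*% c(a, b))^2)
    if (err < best_err) { best_err <- err; best <- c(a, b) }
  }
  best
}

# exhaustive subset search: smallest signature subset reaching within
# `tol` of the best achievable reconstruction cosine
oracle_best_subset <- function(profile, catalog, tol = 1e-9) {
  n <- ncol(catalog)
  best_cos <- gistomics::fit_signatures(profile, catalog)$cosine
  for (k in 1:n) {
    subsets <- utils::combn(n, k, simplify = FALSE)
    for (s in subsets) {
      fit <- gistomics::fit_signatures(profile,
                                       catalog[, s, drop = FALSE])
      if (!is.na(fit$cosine) && fit$cosine >= best_cos - tol)
        return(sort(colnames(catalog)[s]))
    }
  }
  sort(colnames(catalog))
}

# a tiny explicit reference genome for context classification
tiny_genome <- function() {
  Biostrings::DNAStringSet(c(
    chrT1 = "ACGTACGTTTTTTGCAGATATATATGGCCAAGCTTACGACGTAGCTAGC",
    chrT2 = "TTGCAACGGTTTAAACCCGGGTTTTACGATCGATCGAAGGTCCAGGTCA"))
}

# hand-built diploid segment set covering one 60-Mb chromosome
flat_segments <- function(sample = "s1", chrom = "chr1", total = 2,
                          minor = 1, len = 6e7) {
  data.frame(sample = sample, chrom = chrom, start = 0, end = len,
             total_cn = total, minor_cn = minor)
}

quiet_arm_calls <- function(...) suppressWarnings(arm_average_cn(...))

# a reduced-size cohort configuration for tests that do not probe the
# mutation or methylation layers at full default scale
light_config <- function(seed, ...) {
  defaults <- list(
    burden_means = list(
      A = c(snv = 60, indel = 20, sv = 12),
      B = c(snv = 30, indel = 10, sv = 8),
      C = c(snv = 30, indel = 10, sv = 8),
      D = c(snv = 25, indel = 10, sv = 8)),
    meth_probe_spacing = 50000L,
    meth_tss_probes = 2L,
    seed = seed)
  do.call(cohort_config, utils::modifyList(defaults, list(...)))
}
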