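#' Probe filtering for methylation analyses
#'
#' Applies, in the order given, the exclusion steps used before clustering:
#' \describe{
#'   \item{`drop_sex`}{remove probes on sex chromosomes}
#'   \item{`drop_tss_cgi`}{remove probes in CpG islands around transcription
#'     start sites (leaving the "intergenic" probe set)}
#'   \item{`variance_filter`}{remove probes whose every sample lies within
#'     `delta` (default 0.1) of the probe's cross-sample mean beta}
#'   \item{`subsample`}{draw `n` probes uniformly without replacement using
#'     `seed`}
#' }
#'
#' @param beta numeric matrix probes x samples, values in [0, 1]
#' @param manifest data.frame: `probe`, `chrom`, `pos` (1-based),
#'   `is_sex_chrom`, `is_tss_cgi`; must cover all matrix probes
#' @param steps character vector, ordered subset of
#'   `c("drop_sex", "drop_tss_cgi", "variance_filter", "subsample")`
#' @param delta variance-filter half-width (default 0.1)
#' @param n,seed subsample size and RNG seed
#' @return list: `beta`, `manifest` (filtered), `log` (data.frame with probes
#'   removed per step)
#' @export
filter_probes <- function(beta, manifest,
                          steps = c("drop_sex", "drop_tss_cgi"),
                          delta = 0.1, n = NULL, seed = NULL) {
  stopifnot(is.matrix(beta))
  if (!all(rownames(beta) %in% manifest$probe))
    stop("manifest does not cover all matrix probes", call. = FALSE)
  manifest <- manifest[match(rownames(beta), manifest$probe), , drop = FALSE]
  log <- data.frame(step = character(), removed = integer(),
                    remaining = integer())
  for (st in steps) {
    keep <- switch(st,
      drop_sex = !manifest$is_sex_chrom,
      drop_tss_cgi = !manifest$is_tss_cgi,
      variance_filter = {
        dev <- abs(beta - rowMeans(beta, na.rm = TRUE))
        apply(dev, 1, max, na.rm = TRUE) > delta
      },
      subsample = {
        if (is.null(n) || is.null(seed))
          stop("subsample step needs n and seed", call. = FALSE)
        if (n > nrow(beta))
          stop("subsample size ", n, " exceeds ", nrow(beta),
               " remaining probes", call. = FALSE)
        idx <- withr_seed_sample(seq_len(nrow(beta)), n, seed)
        seq_len(nrow(beta)) %in% idx
      },
      stop("unknown filter step: ", st, call. = FALSE))
    log <- rbind(log, data.frame(step = st, removed = sum(!keep),
                                 remaining = sum(keep)))
    beta <- beta[keep, , drop = FALSE]
    manifest <- manifest[keep, , drop = FALSE]
  }
  list(beta = beta, manifest = manifest, log = log)
}

# draw a fixed-seed sample without disturbing the caller's RNG stream
withr_seed_sample <- function(x, n, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample(x, n)
}

#' Average beta values over 300-kb genomic bins
#'
#' Bins each chromosome into half-open windows `[k*bin_size, (k+1)*bin_size)`
#' anchored at coordinate 0 and averages (unweighted) the probes falling in
#' each bin, per sample. Bins without probes are omitted.
#'
#' @param beta probes x samples matrix
#' @param manifest manifest covering the matrix probes
#' @param bin_size bin width in bp (default 300000)
#' @return list: `bins` (data.frame `chrom`, `start`, `end`, `n_probes`),
#'   `means` (bins x samples matrix, rownames `chrom:start-end`)
#' @export
bin_beta <- function(beta, manifest, bin_size = 300000) {
  manifest <- manifest[match(rownames(beta), manifest$probe), , drop = FALSE]
  # half-open on the position value: pos p falls in bin floor(p / bin_size)
  bin_start <- manifest$pos %/% bin_size * bin_size
  key <- sprintf("%s:%.0f-%.0f", manifest$chrom, bin_start,
                 bin_start + bin_size)
  ord <- order(manifest$chrom, bin_start)
  ukey <- unique(key[ord])
  means <- matrix(NA_real_, nrow = length(ukey), ncol = ncol(beta),
                  dimnames = list(ukey, colnames(beta)))
  idx <- split(seq_len(nrow(beta)), key)
  for (k in ukey)
    means[k, ] <- colMeans(beta[idx[[k]], , drop = FALSE], na.rm = TRUE)
  first <- !duplicated(key)
  bins <- data.frame(chrom = manifest$chrom[first],
                     start = as.integer(bin_start[first]),
                     end = as.integer(bin_start[first] + bin_size),
                     n_probes = lengths(idx)[key[first]],
                     row.names = key[first])
  bins <- bins[ukey, ]
  list(bins = bins, means = means)
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering of the sample columns; rows with missing values
#' are dropped before computing distances.
#'
#' @param mat features x samples matrix (probe betas or bin means)
#' @param method linkage (default `"average"`)
#' @param distance `"euclidean"` (default) or any [stats::dist()] method
#' @param k optional number of flat clusters to cut
#' @return list: `hclust` object, and `clusters` (named integer vector) when
#'   `k` is given
#' @export
cluster_samples <- function(mat, method = "average", distance = "euclidean",
                            k = NULL) {
  if (ncol(mat) < 2L) stop("need >= 2 samples to cluster", call. = FALSE)
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  if (!nrow(mat)) stop("no complete feature rows to cluster on",
                       call. = FALSE)
  hc <- stats::hclust(stats::dist(t(mat), method = distance),
                      method = method)
  out <- list(hclust = hc)
  if (!is.null(k)) out$clusters <- stats::cutree(hc, k = k)
  out
}

#' Detect group-specific hypomethylated bins
#'
#' Flags bins whose target-group mean beta is at least `min_diff` below the
#' mean of the remaining samples, guarded by a Welch t test at `alpha`.
#' Bins with fewer than two usable samples on either side are skipped and
#' counted.
#'
#' @param binned result of [bin_beta()]
#' @param groups named character vector sample -> group
#' @param target_group group tested for hypomethylation (default `"A"`)
#' @param min_diff minimum beta difference (default 0.1)
#' @param alpha Welch guard level (default 0.05)
#' @return list: `bins` (data.frame of flagged bins with `mean_target`,
#'   `mean_rest`, `diff`, `p`, genome-ordered), `skipped` count
#' @export
detect_group_hypomethylation <- function(binned, groups, target_group = "A",
                                         min_diff = 0.1, alpha = 0.05) {
  means <- binned$means
  grp <- groups[colnames(means)]
  in_target <- grp == target_group
  if (sum(in_target) < 2L || sum(!in_target) < 2L)
    stop("need >= 2 samples on each side", call. = FALSE)
  skipped <- 0L
  rows <- vector("list", nrow(means))
  for (i in seq_len(nrow(means))) {
    x <- means[i, in_target]; y <- means[i, !in_target]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) < 2L || length(y) < 2L) { skipped <- skipped + 1L; next }
    d <- mean(y) - mean(x)
    if (d < min_diff) next
    if (stats::sd(x) == 0 && stats::sd(y) == 0) { skipped <- skipped + 1L; next }
    p <- stats::t.test(x, y, var.equal = FALSE)$p.value
    if (p >= alpha) next
    rows[[i]] <- data.frame(bin = rownames(means)[i],
                            chrom = binned$bins$chrom[i],
                            start = binned$bins$start[i],
                            end = binned$bins$end[i],
                            mean_target = mean(x), mean_rest = mean(y),
                            diff = d, p = p)
  }
  flagged <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(flagged))
    flagged <- data.frame(bin = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          mean_target = numeric(), mean_rest = numeric(),
                          diff = numeric(), p = numeric())
  flagged <- flagged[order(flagged$chrom, flagged$start), ]
  rownames(flagged) <- NULL
  list(bins = flagged, skipped = skipped)
}

#' Promoter methylation per gene
#'
#' Mean beta over each gene's TSS CpG-island probes, per sample.
#'
#' @param beta probes x samples matrix
#' @param gene_probes named list gene -> character vector of probe ids
#' @return genes x samples matrix; genes with zero matching probes get `NA`
#'   rows with a warning
#' @export
promoter_methylation <- function(beta, gene_probes) {
  if (!length(gene_probes)) stop("empty gene -> probe map", call. = FALSE)
  out <- matrix(NA_real_, nrow = length(gene_probes), ncol = ncol(beta),
                dimnames = list(names(gene_probes), colnames(beta)))
  empty <- character()
  for (g in names(gene_probes)) {
    pr <- intersect(gene_probes[[g]], rownames(beta))
    if (!length(pr)) { empty <- c(empty, g); next }
    out[g, ] <- colMeans(beta[pr, , drop = FALSE], na.rm = TRUE)
  }
  if (length(empty))
    warning("gene(s) with zero probes: ", paste(empty, collapse = ","),
            call. = FALSE)
  out
}
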