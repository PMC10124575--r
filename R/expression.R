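#' Log2 + 75th-percentile normalization of expression intensities
#'
#' Per sample: log2-transform the raw intensities, then subtract that
#' sample's 75th percentile (linear-interpolation quantile, R type 7), so
#' every normalized sample has 75th percentile 0. Nonpositive intensities
#' become missing with a warning.
#'
#' @param raw probes x samples matrix of raw signal intensities
#' @return probes x samples matrix of normalized log2 values
#' @export
normalize_expression <- function(raw) {
  stopifnot(is.matrix(raw))
  if (any(raw <= 0, na.rm = TRUE)) {
    warning(sum(raw <= 0, na.rm = TRUE),
            " nonpositive intensities set to missing", call. = FALSE)
    raw[!is.na(raw) & raw <= 0] <- NA
  }
  lg <- log2(raw)
  n_finite <- colSums(is.finite(lg))
  if (any(n_finite < 4L))
    stop("sample(s) with < 4 finite values: ",
         paste(colnames(lg)[n_finite < 4L], collapse = ","), call. = FALSE)
  q75 <- apply(lg, 2, stats::quantile, probs = 0.75, na.rm = TRUE,
               type = 7, names = FALSE)
  sweep(lg, 2, q75, "-")
}

#' Expression signature score (z of mean log2 expression)
#'
#' For each sample, averages the normalized log2 expression over the
#' signature's probes, then z-scores the per-sample means across the cohort
#' (subtract cohort mean, divide by cohort SD).
#'
#' @param mat normalized probes x samples matrix
#' @param probes character vector of signature probe ids; unresolvable
#'   probes are dropped with a warning
#' @return named numeric vector of per-sample scores; all zero (flagged by
#'   warning) when the cross-sample SD is zero
#' @export
signature_score <- function(mat, probes) {
  hit <- intersect(probes, rownames(mat))
  if (!length(hit)) stop("no signature probes resolvable", call. = FALSE)
  if (length(hit) < length(probes))
    warning(length(probes) - length(hit), " signature probe(s) unresolved",
            call. = FALSE)
  if (ncol(mat) < 2L) stop("need >= 2 samples", call. = FALSE)
  m <- colMeans(mat[hit, , drop = FALSE], na.rm = TRUE)
  s <- stats::sd(m)
  if (s == 0) {
    warning("zero cross-sample SD: scores set to 0", call. = FALSE)
    return(stats::setNames(rep(0, length(m)), names(m)))
  }
  (m - mean(m)) / s
}

#' Group-versus-rest differential expression
#'
#' Per probe: Welch t test of the target group against the rest on
#' normalized log2 values, Benjamini-Hochberg adjustment over all tested
#' probes, and log2 fold change as the difference of group means. Probes
#' with zero variance on both sides (or too few finite values) are excluded
#' from testing and from the BH family, with a count reported.
#'
#' @param mat normalized probes x samples matrix
#' @param groups named character vector sample -> group
#' @param target_group group contrasted against the rest (default `"A"`)
#' @return data.frame (one row per probe): `probe`, `log2fc`, `p`, `q`,
#'   `tested`; attribute `n_excluded`
#' @export
differential_expression <- function(mat, groups, target_group = "A") {
  grp <- groups[colnames(mat)]
  in_target <- grp == target_group
  if (sum(in_target) < 2L || sum(!in_target) < 2L)
    stop("need >= 2 samples on each side", call. = FALSE)
  x <- mat[, in_target, drop = FALSE]
  y <- mat[, !in_target, drop = FALSE]
  nx <- rowSums(is.finite(x)); ny <- rowSums(is.finite(y))
  mx <- rowMeans(x, na.rm = TRUE); my <- rowMeans(y, na.rm = TRUE)
  vx <- apply(x, 1, stats::var, na.rm = TRUE)
  vy <- apply(y, 1, stats::var, na.rm = TRUE)
  tested <- nx >= 2 & ny >= 2 & (vx > 0 | vy > 0)
  se2 <- vx / nx + vy / ny
  tstat <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  p[!tested] <- NA
  q <- rep(NA_real_, length(p))
  q[tested] <- stats::p.adjust(p[tested], method = "BH")
  out <- data.frame(probe = rownames(mat), log2fc = mx - my, p = p, q = q,
                    tested = tested, row.names = NULL)
  attr(out, "n_excluded") <- sum(!tested)
  out
}

#' Volcano selection of differentially expressed probes and genes
#'
#' @param de result of [differential_expression()]
#' @param probe_gene named character vector probe -> gene symbol
#' @param fc_cut absolute log2 fold-change cutoff (default 1, i.e. linear
#'   fold change 2); inclusive
#' @param q_cut Q-value cutoff (default 0.05); strict
#' @return list: `probes` (selected probe ids), `genes` (deduplicated gene
#'   symbols), `table` (selected rows of `de`)
#' @export
volcano_select <- function(de, probe_gene = NULL, fc_cut = 1.0,
                           q_cut = 0.05) {
  sel <- de$tested & !is.na(de$q) & abs(de$log2fc) >= fc_cut & de$q < q_cut
  probes <- de$probe[sel]
  genes <- if (!is.null(probe_gene)) {
    unique(stats::na.omit(unname(probe_gene[probes])))
  } else character(0)
  list(probes = probes, genes = genes, table = de[sel, , drop = FALSE])
}

#' Per-sample mutation-burden landscape
#'
#' Counts per sample and burden type, pairwise Pearson correlations among
#' SV/SNV/indel counts, and Welch tests of the target group against each
#' other group per burden type.
#'
#' @param burdens data.frame: `sample`, `group`, `sv`, `snv`, `indel`
#' @param target_group default `"A"`
#' @return list: `table` (the input), `correlations` (3x3 Pearson matrix,
#'   `NA` when < 3 samples), `welch` (data.frame `burden`, `other_group`,
#'   `p`)
#' @export
burden_landscape <- function(burdens, target_group = "A") {
  stopifnot(all(c("sample", "group", "sv", "snv", "indel") %in%
                  names(burdens)))
  cnt <- as.matrix(burdens[, c("sv", "snv", "indel")])
  correlations <- if (nrow(cnt) >= 3L) stats::cor(cnt, method = "pearson")
                  else matrix(NA_real_, 3, 3,
                              dimnames = list(colnames(cnt), colnames(cnt)))
  others <- setdiff(unique(burdens$group), target_group)
  welch <- do.call(rbind, lapply(others, function(g) {
    do.call(rbind, lapply(c("sv", "snv", "indel"), function(b) {
      x <- burdens[burdens$group == target_group, b]
      y <- burdens[burdens$group == g, b]
      p <- if (length(x) >= 2 && length(y) >= 2 &&
               (stats::sd(x) > 0 || stats::sd(y) > 0))
        stats::t.test(x, y, var.equal = FALSE)$p.value else NA_real_
      data.frame(burden = b, other_group = g, p = p)
    }))
  }))
  list(table = burdens, correlations = correlations, welch = welch)
}

#' Welch two-sample t test
#'
#' @param x,y numeric vectors (>= 2 finite values each, not both constant)
#' @return list: `t`, `df`, `p`
#' @export
welch_t <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("welch_t needs >= 2 finite values per vector", call. = FALSE)
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    stop("welch_t undefined: zero variance in both samples", call. = FALSE)
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Two-sided p by summing hypergeometric probabilities of tables (with the
#' observed margins) no more likely than the observed one.
#'
#' @param tab 2x2 matrix of nonnegative integers
#' @return p value
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L)) || any(tab < 0) ||
      any(tab != round(tab)))
    stop("fisher_exact needs a 2x2 table of nonnegative integers",
         call. = FALSE)
  stats::fisher.test(tab)$p.value
}

#' Pearson correlation coefficient
#'
#' @param x,y numeric vectors with >= 2 finite pairs and nonzero variance
#' @return correlation coefficient
#' @export
pearson_r <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L)
    stop("pearson_r needs >= 2 finite pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("pearson_r undefined: zero variance", call. = FALSE)
  stats::cor(x, y, method = "pearson")
}
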