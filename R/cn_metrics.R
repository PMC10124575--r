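#' Arm-level copy-number calls
#'
#' Length-weighted mean total copy number of the segments overlapping each
#' chromosome arm, with gain/loss status (gain when mean >= 2.5, loss when
#' mean <= 1.5, else neutral) and a `deleted` flag using the strict
#' deletion rule mean CN < 1.5. Acrocentric p arms are simply absent from
#' the arm table. Arms with zero covered length yield a flagged missing call.
#'
#' @param segments data.frame: `sample`, `chrom`, `start`, `end` (0-based
#'   half-open bp), `total_cn`, optional `minor_cn`
#' @param arms arm table from [arm_table()] (autosomes and sex chromosomes;
#'   callers may pre-filter)
#' @param gain_cut,loss_cut status thresholds (defaults 2.5 / 1.5)
#' @return data.frame: `sample`, `arm`, `chrom`, `mean_cn`, `status`,
#'   `deleted`, `covered_bp`
#' @export
arm_average_cn <- function(segments, arms, gain_cut = 2.5, loss_cut = 1.5) {
  stopifnot(all(c("sample", "chrom", "start", "end", "total_cn") %in%
                  names(segments)))
  samples <- unique(segments$sample)
  out <- expand.grid(sample = samples, arm = arms$arm,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- merge(out, arms[, c("arm", "chrom", "start", "end")], by = "arm")
  out$mean_cn <- NA_real_
  out$covered_bp <- 0
  for (i in seq_len(nrow(out))) {
    seg <- segments[segments$sample == out$sample[i] &
                      segments$chrom == out$chrom[i], , drop = FALSE]
    if (!nrow(seg)) next
    ov <- pmin(seg$end, out$end[i]) - pmax(seg$start, out$start[i])
    ov[ov < 0] <- 0
    if (sum(ov) == 0) next
    out$mean_cn[i] <- sum(seg$total_cn * ov) / sum(ov)
    out$covered_bp[i] <- sum(ov)
  }
  out$status <- ifelse(is.na(out$mean_cn), NA_character_,
                ifelse(out$mean_cn >= gain_cut, "gain",
                ifelse(out$mean_cn <= loss_cut, "loss", "neutral")))
  out$deleted <- !is.na(out$mean_cn) & out$mean_cn < loss_cut
  if (any(is.na(out$mean_cn)))
    warning("arm(s) with zero covered length: ",
            paste(unique(out$arm[is.na(out$mean_cn)]), collapse = ","),
            call. = FALSE)
  out[order(out$sample, out$arm),
      c("sample", "arm", "chrom", "mean_cn", "status", "deleted",
        "covered_bp")]
}

#' Ploidy score: autosomal arms gained or lost
#'
#' @param arm_calls arm-call data.frame for one sample (see
#'   [arm_average_cn()]), restricted by the caller to autosomal arms
#' @return integer count of arms with non-neutral status
#' @export
ploidy_score <- function(arm_calls) {
  sum(!is.na(arm_calls$status) & arm_calls$status != "neutral")
}

#' Whole-genome duplication flag
#'
#' A sample is WGD when its length-weighted genome-wide mean total copy
#' number exceeds `cutoff` (default 3, i.e. "ploidy > 3").
#'
#' @param segments segment data.frame for one sample
#' @param cutoff mean-CN cutoff (default 3.0, strict >)
#' @return list: `wgd` logical, `mean_cn`
#' @export
call_wgd <- function(segments, cutoff = 3.0) {
  w <- segments$end - segments$start
  mean_cn <- sum(segments$total_cn * w) / sum(w)
  list(wgd = mean_cn > cutoff, mean_cn = mean_cn)
}

#' HRD score: LOH + telomeric allelic imbalance + large-scale transitions
#'
#' Component definitions (all thresholds configurable):
#' \itemize{
#'   \item LOH score: segments with minor CN 0 and total CN >= 1, longer
#'     than `loh_min` (default 15 Mb) and not spanning a whole chromosome.
#'   \item TAI score: allelic-imbalance segments (total != 2 x minor)
#'     touching a telomere (chromosome start or end), not crossing the
#'     centromere, longer than `tai_min` (default 11 Mb).
#'   \item LST score: breakpoints between adjacent segments in different
#'     copy-number states, both at least `lst_min` (default 10 Mb) long,
#'     after dropping segments shorter than `lst_smooth` (default 3 Mb) and
#'     merging equal-state neighbors.
#' }
#'
#' @param segments segment data.frame for one sample with `minor_cn`
#' @param genome genome table from [default_genome()]
#' @param loh_min,tai_min,lst_min,lst_smooth thresholds in bp
#' @return list: `loh`, `tai`, `lst`, `hrd_sum`
#' @export
hrd_score <- function(segments, genome, loh_min = 15e6, tai_min = 11e6,
                      lst_min = 10e6, lst_smooth = 3e6) {
  if (!"minor_cn" %in% names(segments) || anyNA(segments$minor_cn))
    stop("HRD unavailable: minor copy number missing", call. = FALSE)
  seg <- segments[order(segments$chrom, segments$start), , drop = FALSE]
  seg$len <- seg$end - seg$start
  glen <- stats::setNames(genome$length, genome$chrom)
  gcen <- stats::setNames(genome$centromere, genome$chrom)

  whole_chrom <- seg$start == 0 & seg$end == glen[seg$chrom]
  loh <- sum(round(seg$minor_cn) == 0 & round(seg$total_cn) >= 1 &
               seg$len > loh_min & !whole_chrom)

  imbal <- round(seg$total_cn) != 2 * round(seg$minor_cn)
  telomeric <- seg$start == 0 | seg$end == glen[seg$chrom]
  crosses_cen <- seg$start < gcen[seg$chrom] & seg$end > gcen[seg$chrom]
  tai <- sum(imbal & telomeric & !crosses_cen & seg$len > tai_min)

  lst <- 0L
  for (ch in unique(seg$chrom)) {
    s <- seg[seg$chrom == ch & seg$len >= lst_smooth, , drop = FALSE]
    if (nrow(s) < 2L) next
    state <- paste(round(s$total_cn), round(s$minor_cn))
    keep <- c(TRUE, state[-1] != state[-nrow(s)])
    # merge equal-state neighbors
    grp <- cumsum(keep)
    merged <- data.frame(
      start = tapply(s$start, grp, min),
      end   = tapply(s$end, grp, max)
    )
    merged$len <- merged$end - merged$start
    if (nrow(merged) < 2L) next
    lst <- lst + sum(merged$len[-1] >= lst_min &
                       merged$len[-nrow(merged)] >= lst_min)
  }
  list(loh = as.integer(loh), tai = as.integer(tai), lst = as.integer(lst),
       hrd_sum = as.integer(loh + tai + lst))
}

#' Group-wise arm-deletion comparison
#'
#' For one arm, compares a target group against the rest: Welch two-sample t
#' test on per-sample arm mean CN, and Fisher exact test on the 2x2 table of
#' deleted (mean CN < 1.5) versus not. Samples with missing arm calls are
#' dropped; optionally high-ploidy samples are excluded first.
#'
#' @param arm_calls arm-call data.frame (all samples)
#' @param groups named character vector sample -> group
#' @param arm arm id, e.g. `"chr2q"`
#' @param target_group group compared against the rest (default `"A"`)
#' @param exclude samples to drop before testing (e.g. high-ploidy cases)
#' @return list: `welch_p`, `fisher_p`, `mean_target`, `mean_rest`,
#'   `deleted_table` (2x2)
#' @export
compare_arm_groups <- function(arm_calls, groups, arm, target_group = "A",
                               exclude = character()) {
  ac <- arm_calls[arm_calls$arm == arm & !is.na(arm_calls$mean_cn) &
                    !(arm_calls$sample %in% exclude), , drop = FALSE]
  grp <- groups[ac$sample]
  in_target <- grp == target_group
  if (sum(in_target) < 2L || sum(!in_target) < 2L)
    stop("need >= 2 samples on each side for arm ", arm, call. = FALSE)
  x <- ac$mean_cn[in_target]; y <- ac$mean_cn[!in_target]
  welch_p <- if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    warning("zero variance in both groups: Welch t undefined", call. = FALSE)
    NA_real_
  } else {
    stats::t.test(x, y, var.equal = FALSE)$p.value
  }
  tab <- matrix(c(sum(ac$deleted[in_target]), sum(!ac$deleted[in_target]),
                  sum(ac$deleted[!in_target]), sum(!ac$deleted[!in_target])),
                nrow = 2,
                dimnames = list(c("deleted", "not"),
                                c(target_group, "rest")))
  fisher_p <- stats::fisher.test(tab)$p.value
  list(welch_p = welch_p, fisher_p = fisher_p,
       mean_target = mean(x), mean_rest = mean(y), deleted_table = tab)
}
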