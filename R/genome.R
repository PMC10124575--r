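#' Miniature genome used by the synthetic cohort
#'
#' The simulator works on a desk-scale genome of three autosomes plus one sex
#' chromosome, 60 Mb each, with a centromere placed at 25 Mb so that every
#' chromosome has a p arm (0-25 Mb) and a q arm (25-60 Mb). Arm-level logic
#' (gain/loss calls, ploidy score, telomeric allelic imbalance) needs at least
#' two arms per chromosome but not human scale.
#'
#' @param n_autosomes number of autosomes (default 3)
#' @param chrom_length chromosome length in bp (default 6e7)
#' @param centromere centromere position in bp (default 2.5e7)
#' @return data.frame with columns `chrom`, `length`, `centromere`, `is_sex`
#' @export
default_genome <- function(n_autosomes = 3, chrom_length = 6e7,
                           centromere = 2.5e7) {
  stopifnot(n_autosomes >= 1, chrom_length > centromere, centromere > 0)
  chroms <- c(paste0("chr", seq_len(n_autosomes)), "chrX")
  data.frame(
    chrom      = chroms,
    length     = chrom_length,
    centromere = centromere,
    is_sex     = chroms == "chrX",
    stringsAsFactors = FALSE
  )
}

#' Chromosome-arm table for a genome
#'
#' Derives the arm intervals (0-based half-open) from a genome table.
#' Acrocentric chromosomes (if flagged) contribute only their q arm, mirroring
#' the convention of showing only q arms for acrocentric human chromosomes.
#'
#' @param genome data.frame as returned by [default_genome()]
#' @param acrocentric character vector of chromosome names whose p arm is
#'   dropped (default none)
#' @return data.frame with columns `chrom`, `arm` (e.g. "chr1p"), `start`,
#'   `end`, `is_sex`
#' @export
arm_table <- function(genome, acrocentric = character()) {
  rows <- lapply(seq_len(nrow(genome)), function(i) {
    g <- genome[i, ]
    arms <- data.frame(
      chrom = g$chrom,
      arm   = paste0(g$chrom, c("p", "q")),
      start = c(0, g$centromere),
      end   = c(g$centromere, g$length),
      is_sex = g$is_sex,
      stringsAsFactors = FALSE
    )
    if (g$chrom %in% acrocentric) arms <- arms[2, , drop = FALSE]
    arms
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
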