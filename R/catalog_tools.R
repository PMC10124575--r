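#' Construct a random peaked signature catalog
#'
#' Builds well-separated synthetic reference signatures for a scheme: each
#' signature is a sparse gamma draw with a handful of strongly boosted
#' "peak" categories, normalized to sum to 1. Useful for simulation studies
#' and for generating the bundled desk-scale catalogs.
#'
#' @param scheme `"SBS96"`, `"ID83"` or `"CN48"`
#' @param n_signatures number of signature columns
#' @param seed RNG seed (the catalog is a pure function of its arguments)
#' @param n_peaks peak categories per signature (default 8)
#' @param boost peak boost factor (default 30)
#' @return catalog matrix categories x signatures, columns summing to 1
#' @export
random_catalog <- function(scheme = c("SBS96", "ID83", "CN48"),
                           n_signatures = 5, seed = 1, n_peaks = 8,
                           boost = 30) {
  scheme <- match.arg(scheme)
  levels <- switch(scheme,
    SBS96 = sbs96_categories(),
    ID83  = id83_categories(),
    CN48  = cn48_categories())
  prefix <- switch(scheme, SBS96 = "SBSS", ID83 = "IDS", CN48 = "CNS")
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  n <- length(levels)
  m <- matrix(0, nrow = n, ncol = n_signatures,
              dimnames = list(levels, paste0(prefix, seq_len(n_signatures))))
  for (j in seq_len(n_signatures)) {
    v <- stats::rgamma(n, shape = 0.15)
    peaks <- sample.int(n, min(n_peaks, n))
    v[peaks] <- v[peaks] + stats::rgamma(length(peaks), shape = 2) * boost
    m[, j] <- v / sum(v)
  }
  m
}
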