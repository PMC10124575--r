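#' Cosine similarity between two nonnegative vectors
#'
#' @param a,b numeric vectors of equal length
#' @return cosine similarity in [0, 1] for nonnegative inputs; `NA` when
#'   either vector is all zero
#' @export
cosine_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}

#' Build a context profile from classified events
#'
#' Aggregates per-event category labels into the fixed-length vector of the
#' scheme: counts for SBS96/ID83, summed segment lengths (bp) for CN48
#' (optionally normalized to relative length so the vector sums to 1).
#'
#' @param categories character vector of category labels, one per event
#' @param scheme `"SBS96"`, `"ID83"` or `"CN48"`
#' @param weights optional per-event weights (CN48 segment lengths); default
#'   1 per event
#' @param relative for CN48, divide by the total so entries are relative
#'   lengths (default FALSE)
#' @return named numeric vector over the scheme's canonical category order
#' @export
build_profile <- function(categories, scheme = c("SBS96", "ID83", "CN48"),
                          weights = NULL, relative = FALSE) {
  scheme <- match.arg(scheme)
  levels <- switch(scheme,
    SBS96 = sbs96_categories(),
    ID83  = id83_categories(),
    CN48  = cn48_categories())
  if (is.null(weights)) weights <- rep(1, length(categories))
  stopifnot(length(weights) == length(categories))
  bad <- setdiff(unique(categories), levels)
  if (length(bad))
    stop("unknown ", scheme, " categories: ", paste(bad, collapse = ", "),
         call. = FALSE)
  v <- vapply(levels, function(l) sum(weights[categories == l]), numeric(1))
  if (relative && sum(v) > 0) v <- v / sum(v)
  v
}

#' Read a reference signature catalog from TSV
#'
#' First column holds category labels, remaining columns one signature each.
#' Columns are normalized to sum to 1.
#'
#' @param path TSV file path
#' @param scheme expected scheme; the row count and labels are validated
#' @return numeric matrix categories x signatures with dimnames
#' @export
read_signature_catalog <- function(path, scheme = c("SBS96", "ID83", "CN48")) {
  scheme <- match.arg(scheme)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  levels <- switch(scheme,
    SBS96 = sbs96_categories(),
    ID83  = id83_categories(),
    CN48  = cn48_categories())
  if (!setequal(df[[1]], levels))
    stop("catalog categories do not match the ", scheme, " scheme",
         call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m <- m[levels, , drop = FALSE]
  if (any(m < 0)) stop("negative catalog entries", call. = FALSE)
  sweep(m, 2, colSums(m), "/")
}

#' Load one of the bundled synthetic signature catalogs
#'
#' Desk-scale reference catalogs (5 SBS, 3 ID, 3 CN signatures) shipped as
#' plain-text fixtures; real catalogs in the same layout are loadable with
#' [read_signature_catalog()].
#'
#' @param scheme `"SBS96"`, `"ID83"` or `"CN48"`
#' @return catalog matrix (see [read_signature_catalog()])
#' @export
synthetic_catalog <- function(scheme = c("SBS96", "ID83", "CN48")) {
  scheme <- match.arg(scheme)
  file <- paste0("catalog_", tolower(scheme), "_synthetic.tsv")
  read_signature_catalog(
    system.file("extdata", file, package = "gistomics", mustWork = TRUE),
    scheme = scheme)
}

#' Refit a context profile against a signature catalog
#'
#' Nonnegative least squares: minimizes ||profile - catalog x|| subject to
#' x >= 0, and reports the reconstruction cosine similarity.
#'
#' @param profile numeric vector over the catalog's categories
#' @param catalog matrix categories x signatures (columns sum to 1)
#' @return list of class `signature_fit`: `contribution` (named, same units
#'   as the profile), `relative` (sums to 1 when total > 0), `cosine`
#'   (`NA` for a zero profile), `fitted`
#' @export
fit_signatures <- function(profile, catalog) {
  stopifnot(is.matrix(catalog), length(profile) == nrow(catalog),
            ncol(catalog) >= 1L)
  if (any(profile < 0)) stop("profile has negative entries", call. = FALSE)
  if (sum(profile) == 0) {
    x <- stats::setNames(rep(0, ncol(catalog)), colnames(catalog))
    return(structure(list(contribution = x, relative = x, cosine = NA_real_,
                          fitted = rep(0, length(profile))),
                     class = "signature_fit"))
  }
  x <- pracma::lsqnonneg(catalog, as.numeric(profile))$x
  names(x) <- colnames(catalog)
  fitted <- as.numeric(catalog %*% x)
  rel <- if (sum(x) > 0) x / sum(x) else x
  structure(list(contribution = x, relative = rel,
                 cosine = cosine_similarity(profile, fitted),
                 fitted = fitted),
            class = "signature_fit")
}

#' @export
print.signature_fit <- function(x, ...) {
  cat("<signature_fit>", sum(x$contribution > 0), "active signatures,",
      "cosine", format(x$cosine, digits = 4), "\n")
  active <- x$relative[x$contribution > 0]
  if (length(active))
    print(round(sort(active, decreasing = TRUE), 4))
  invisible(x)
}

#' Strict signature refitting by backward elimination
#'
#' Fits all catalog signatures, then repeatedly removes the signature with
#' the smallest contribution (ties broken by catalog column order) and
#' refits; elimination stops when removing another signature would drop the
#' reconstruction cosine by more than `max_delta` relative to the previous
#' accepted fit. The returned fit carries zero contributions for eliminated
#' signatures.
#'
#' @param profile numeric vector over the catalog's categories
#' @param catalog matrix categories x signatures
#' @param max_delta maximum tolerated per-step cosine decrease (default
#'   0.004, the published default of the strict refitting procedure)
#' @return `signature_fit` over the full catalog
#' @export
fit_signatures_strict <- function(profile, catalog, max_delta = 0.004) {
  stopifnot(max_delta >= 0)
  full <- fit_signatures(profile, catalog)
  if (is.na(full$cosine)) return(full)
  active <- colnames(catalog)
  best <- full
  while (length(active) > 1L) {
    idx <- which.min(best$contribution[active])  # first minimum = column order
    candidate <- setdiff(active, active[idx])
    fit <- fit_signatures(profile, catalog[, candidate, drop = FALSE])
    if (best$cosine - fit$cosine > max_delta) break
    active <- candidate
    best <- fit
  }
  contribution <- stats::setNames(rep(0, ncol(catalog)), colnames(catalog))
  contribution[active] <- best$contribution
  rel <- if (sum(contribution) > 0) contribution / sum(contribution)
         else contribution
  structure(list(contribution = contribution, relative = rel,
                 cosine = best$cosine,
                 fitted = as.numeric(catalog %*% contribution)),
            class = "signature_fit")
}

#' Detected signatures under the >5% contribution rule
#'
#' @param fit `signature_fit`
#' @param threshold relative-contribution threshold, strictly exceeded
#'   (default 0.05)
#' @return character vector of signature names
#' @export
detect_signatures <- function(fit, threshold = 0.05) {
  stopifnot(inherits(fit, "signature_fit"))
  if (sum(fit$contribution) == 0) return(character(0))
  names(fit$relative)[fit$relative > threshold]
}
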