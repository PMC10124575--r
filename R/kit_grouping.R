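#' Parse a KIT exon-11 protein change string
#'
#' Accepts the HGVS-p dialects used in GIST case tables:
#' `p.<aa><n><aa>` (substitution), `p.<aa><n>del` / `p.<aa><n>_<aa><m>del`
#' (deletion), `p.<aa><n>_<aa><m>delins<seq>` (deletion-insertion) and the
#' corresponding `dup` forms, optionally prefixed by an exon tag such as
#' `"E11: "`. When several comma-separated changes are listed (e.g. an exon-11
#' change plus a secondary exon-13 substitution), the exon-11 entry is parsed.
#'
#' @param s protein change string, e.g. `"E11: p.W557_K558del"`
#' @return an object of class `exon_mutation`: a list with fields `raw`,
#'   `start_codon`, `end_codon`, `ref_start`, `ref_end` (reference amino-acid
#'   letters), `mclass` (one of `"substitution"`, `"deletion"`, `"delins"`,
#'   `"duplication"`) and `inserted` (inserted amino-acid string, `""` if none)
#' @export
#' @examples
#' parse_hgvs_p("E11: p.W557_K558del")
#' parse_hgvs_p("E11: p.V560D")
parse_hgvs_p <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  raw <- s
  parts <- trimws(strsplit(s, ",", fixed = TRUE)[[1]])
  if (length(parts) > 1L) {
    e11 <- grep("^E11\\s*:", parts)
    parts <- if (length(e11)) parts[e11[1]] else parts[1]
  }
  tok <- sub("^E\\d+\\s*:\\s*", "", parts)

  m <- regmatches(tok, regexec(
    "^p\\.([A-Z])(\\d+)_([A-Z])(\\d+)delins([A-Z*]+)$", tok))[[1]]
  if (length(m)) {
    return(new_exon_mutation(raw, as.integer(m[3]), as.integer(m[5]),
                             m[2], m[4], "delins", m[6]))
  }
  m <- regmatches(tok, regexec(
    "^p\\.([A-Z])(\\d+)_([A-Z])(\\d+)(del|dup)$", tok))[[1]]
  if (length(m)) {
    cls <- if (m[6] == "del") "deletion" else "duplication"
    return(new_exon_mutation(raw, as.integer(m[3]), as.integer(m[5]),
                             m[2], m[4], cls, ""))
  }
  m <- regmatches(tok, regexec("^p\\.([A-Z])(\\d+)(del|dup)$", tok))[[1]]
  if (length(m)) {
    cls <- if (m[4] == "del") "deletion" else "duplication"
    return(new_exon_mutation(raw, as.integer(m[3]), as.integer(m[3]),
                             m[2], m[2], cls, ""))
  }
  m <- regmatches(tok, regexec("^p\\.([A-Z])(\\d+)([A-Z*])$", tok))[[1]]
  if (length(m)) {
    return(new_exon_mutation(raw, as.integer(m[3]), as.integer(m[3]),
                             m[2], m[2], "substitution", m[4]))
  }
  stop("cannot parse protein change token: '", tok, "'", call. = FALSE)
}

new_exon_mutation <- function(raw, start_codon, end_codon, ref_start, ref_end,
                              mclass, inserted) {
  if (start_codon > end_codon)
    stop("start codon ", start_codon, " exceeds end codon ", end_codon,
         call. = FALSE)
  structure(
    list(raw = raw, start_codon = start_codon, end_codon = end_codon,
         ref_start = ref_start, ref_end = ref_end,
         mclass = mclass, inserted = inserted),
    class = "exon_mutation"
  )
}

#' Format an exon mutation back to canonical HGVS-p
#'
#' Inverse of [parse_hgvs_p()] (without the exon prefix).
#' @param m `exon_mutation`
#' @return character scalar such as `"p.W557_K558del"`
#' @export
format_hgvs_p <- function(m) {
  stopifnot(inherits(m, "exon_mutation"))
  pos <- if (m$start_codon == m$end_codon) {
    paste0(m$ref_start, m$start_codon)
  } else {
    paste0(m$ref_start, m$start_codon, "_", m$ref_end, m$end_codon)
  }
  suffix <- switch(m$mclass,
    substitution = m$inserted,
    deletion     = "del",
    duplication  = "dup",
    delins       = paste0("delins", m$inserted)
  )
  paste0("p.", pos, suffix)
}

#' @export
print.exon_mutation <- function(x, ...) {
  cat(sprintf("<exon_mutation> %s [%s codons %d-%d%s]\n", format_hgvs_p(x),
              x$mclass, x$start_codon, x$end_codon,
              if (nzchar(x$inserted)) paste0(" ins ", x$inserted) else ""))
  invisible(x)
}

#' Does a KIT exon-11 mutation delete both codons 557 and 558?
#'
#' The Delta 557-558 lesion requires BOTH codons removed: deletions and
#' deletion-insertions whose interval covers codons 557 and 558. Deletions
#' touching only one of the two codons (e.g. p.K558_E562del) do not qualify;
#' substitutions and duplications never do.
#'
#' @param m `exon_mutation` from [parse_hgvs_p()]
#' @return logical scalar
#' @export
involves_557_558 <- function(m) {
  stopifnot(inherits(m, "exon_mutation"))
  m$mclass %in% c("deletion", "delins") &&
    m$start_codon <= 557L && m$end_codon >= 558L
}

#' Assign a case to group A/B/C/D
#'
#' Cases are malignant when high-risk by the modified NIH classification or
#' when the sample derives from a metastasis or recurrence. Crossing
#' malignancy with Delta 557-558 status yields:
#' A = malignant with the deletion, B = malignant without it,
#' C = non-malignant (low/intermediate risk) with the deletion,
#' D = non-malignant without it.
#'
#' @param delta logical, Delta 557-558 status (see [involves_557_558()])
#' @param risk `"High"`, `"Intermediate"`, `"Low"` or `NA`
#' @param derivation `"Primary"`, `"Metastasis"` or `"Recurrence"`
#' @return `"A"`, `"B"`, `"C"`, `"D"`, or `NA_character_` when risk is
#'   missing for a primary tumor (unassignable)
#' @export
assign_group <- function(delta, risk, derivation) {
  stopifnot(is.logical(delta), length(delta) == 1L)
  if (!derivation %in% c("Primary", "Metastasis", "Recurrence"))
    stop("unknown derivation: ", derivation, call. = FALSE)
  if (!is.na(risk) && !risk %in% c("High", "Intermediate", "Low"))
    stop("unknown risk class: ", risk, call. = FALSE)
  malignant_by_site <- derivation %in% c("Metastasis", "Recurrence")
  if (is.na(risk) && !malignant_by_site) return(NA_character_)
  malignant <- malignant_by_site || (!is.na(risk) && risk == "High")
  if (malignant) {
    if (delta) "A" else "B"
  } else {
    if (delta) "C" else "D"
  }
}

#' Classify a case table into groups A-D
#'
#' Runs parse -> Delta 557-558 test -> group assignment over a sample sheet
#' and, when a reported group column is present, flags discordances between
#' the rule-derived group and the reported label instead of overriding either.
#'
#' @param cases data.frame with columns `case_id`, `risk`, `derivation`,
#'   `mutation` and optionally `reported_group`
#' @return the input with added columns `delta_557_558` (0/1), `group`
#'   (rule-derived) and, if `reported_group` exists, logical `discordant`
#' @export
classify_cases <- function(cases) {
  need <- c("case_id", "risk", "derivation", "mutation")
  missing_cols <- setdiff(need, names(cases))
  if (length(missing_cols))
    stop("sample sheet lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  parsed <- lapply(cases$mutation, parse_hgvs_p)
  delta <- vapply(parsed, involves_557_558, logical(1))
  grp <- mapply(assign_group, delta, cases$risk, cases$derivation,
                USE.NAMES = FALSE)
  cases$delta_557_558 <- as.integer(delta)
  cases$group <- grp
  if ("reported_group" %in% names(cases))
    cases$discordant <- !is.na(grp) & grp != cases$reported_group
  cases
}

#' Load the bundled 30-case GIST clinical table
#'
#' Clinicopathologic entries (risk classification, primary/metastasis/
#' recurrence status and KIT exon-11 protein change) for the 30-case study
#' cohort, shipped as a plain-text fixture.
#'
#' @return data.frame with columns `case_id`, `risk`, `derivation`,
#'   `mutation`, `reported_group`
#' @export
load_gist_cases <- function() {
  path <- system.file("extdata", "gist30_cases.tsv", package = "gistomics",
                      mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  df$risk <- as.character(df$risk)
  df
}
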