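#' Structural-variant filtering and driver tiering
#'
#' SV calls are represented as data.frames with one row per call:
#' columns `sv_id`, `chrom1`, `pos1`, `chrom2`, `pos2` (1-based breakpoint
#' positions), `svclass` (translocation/insertion/deletion/duplication/
#' inversion) and logical `imprecise`. Mask tracks are data.frames with
#' columns `chrom`, `start`, `end` in BED convention (0-based half-open).
#'
#' @name sv_pipeline
NULL

# distance (bp) from a 1-based breakpoint to the nearest base of any interval
# of one mask track; 0 when the breakpoint lies inside an interval.
# Masks are 0-based half-open, so bases occupy 1-based positions
# (start+1)..end.
mask_distance <- function(chrom, pos, mask) {
  mk <- mask[mask$chrom == chrom, , drop = FALSE]
  if (nrow(mk) == 0L) return(Inf)
  first <- mk$start + 1L
  last  <- mk$end
  d <- pmax(first - pos, pos - last, 0)
  min(d)
}

#' Filter SV calls by precision and mask proximity
#'
#' Discards calls flagged IMPRECISE and calls with either breakpoint within
#' `proximity_bp` (inclusive) of a masked interval (segmental duplications,
#' microsatellites, simple repeats, low-complexity regions, blacklist).
#' Every discarded record carries its reason(s); the union of kept and
#' discarded is the input, and the filter is idempotent.
#'
#' @param svs SV data.frame (see [sv_pipeline])
#' @param masks named list of mask-track data.frames
#' @param proximity_bp proximity threshold in bp, default 100 (inclusive)
#' @return list with data.frames `kept` and `discarded` (the latter with an
#'   added `reason` column, `;`-separated)
#' @export
filter_svs <- function(svs, masks, proximity_bp = 100) {
  stopifnot(is.data.frame(svs), is.list(masks))
  if (is.null(names(masks)) || any(!nzchar(names(masks))))
    stop("mask tracks must be named", call. = FALSE)
  mask_chroms <- unique(unlist(lapply(masks, function(m) m$chrom)))
  reasons <- vector("list", nrow(svs))
  for (i in seq_len(nrow(svs))) {
    r <- character()
    if (isTRUE(svs$imprecise[i])) r <- c(r, "imprecise")
    for (nm in names(masks)) {
      d1 <- mask_distance(svs$chrom1[i], svs$pos1[i], masks[[nm]])
      d2 <- mask_distance(svs$chrom2[i], svs$pos2[i], masks[[nm]])
      if (min(d1, d2) <= proximity_bp) r <- c(r, nm)
    }
    unseen <- setdiff(c(svs$chrom1[i], svs$chrom2[i]), mask_chroms)
    if (length(unseen) && length(mask_chroms))
      warning("breakpoint chromosome(s) absent from mask universe: ",
              paste(unseen, collapse = ","), call. = FALSE)
    reasons[[i]] <- r
  }
  drop <- lengths(reasons) > 0L
  kept <- svs[!drop, , drop = FALSE]
  discarded <- svs[drop, , drop = FALSE]
  discarded$reason <- vapply(reasons[drop], paste, character(1), collapse = ";")
  rownames(kept) <- rownames(discarded) <- NULL
  list(kept = kept, discarded = discarded)
}

#' Classify a paired-breakend call into one of five SV classes
#'
#' Uses read-pair mapping orientation: inter-chromosomal mates are
#' translocations; on one chromosome, a +/- orientation (left breakend
#' pointing right, right breakend pointing left) is a deletion, -/+ a tandem
#' duplication, +/+ or -/- an inversion. Calls carrying inserted sequence are
#' insertions.
#'
#' @param chrom1,pos1,strand1 first breakend (strand `"+"` or `"-"`)
#' @param chrom2,pos2,strand2 second breakend; `NA` chrom2 marks a missing
#'   mate (unclassifiable)
#' @param has_insertion logical, record carries inserted sequence
#' @return one of `"translocation"`, `"insertion"`, `"deletion"`,
#'   `"duplication"`, `"inversion"`; errors on a missing mate
#' @export
classify_sv <- function(chrom1, pos1, strand1, chrom2, pos2, strand2,
                        has_insertion = FALSE) {
  if (is.na(chrom2) || is.na(pos2))
    stop("missing mate: breakend pair incomplete", call. = FALSE)
  if (isTRUE(has_insertion)) return("insertion")
  if (chrom1 != chrom2) return("translocation")
  # order mates by position so orientations read left-to-right
  if (pos1 > pos2) {
    tmp <- c(strand1, strand2); strand1 <- tmp[2]; strand2 <- tmp[1]
  }
  if (strand1 == strand2) return("inversion")
  if (strand1 == "+" && strand2 == "-") return("deletion")
  "duplication"
}

#' Annotate an SV against gene models and assign a driver tier
#'
#' Each breakpoint is annotated with its containing gene (or intergenic) and
#' exon/intron index. Tier 2 when the SV matches an entry of a curated driver
#' list (gene symbol plus SV class, `"*"` matching any class); otherwise
#' tier 3 when the coding sequence of a tumor-suppressor gene is disrupted:
#' the deleted/duplicated/inverted interval intersects a TSG coding interval,
#' or a breakpoint falls within one. Multi-gene hits report every overlapped
#' gene; the tier is the best across genes.
#'
#' @param sv one-row SV data.frame (see [sv_pipeline])
#' @param genes gene-model data.frame: `symbol`, `chrom`, `start`, `end`
#'   (0-based half-open gene span), `strand`, `cds_start`, `cds_end`,
#'   `exon_starts`, `exon_ends` (comma-separated, 0-based half-open),
#'   `role` in `{"TSG","oncogene","other"}`
#' @param driver_db optional curated data.frame `gene`, `svclass` (or `"*"`)
#' @return list with `breakpoints` (data.frame: breakpoint, gene, feature)
#'   and `tier` (`2L`, `3L`, or `NA` for none)
#' @export
annotate_and_tier <- function(sv, genes, driver_db = NULL) {
  stopifnot(nrow(sv) == 1L)
  bps <- data.frame(
    chrom = c(sv$chrom1, sv$chrom2),
    pos   = c(sv$pos1, sv$pos2),
    stringsAsFactors = FALSE
  )
  ann <- lapply(seq_len(2L), function(i)
    locate_breakpoint(bps$chrom[i], bps$pos[i], genes))
  bps$gene    <- vapply(ann, `[[`, character(1), "gene")
  bps$feature <- vapply(ann, `[[`, character(1), "feature")

  hit_genes <- unique(unlist(lapply(ann, `[[`, "symbols")))
  intrachrom <- !is.na(sv$chrom2) && sv$chrom1 == sv$chrom2 &&
    sv$svclass %in% c("deletion", "duplication", "inversion")
  if (intrachrom && nrow(genes)) {
    span <- sort(c(sv$pos1, sv$pos2))
    ov <- genes$chrom == sv$chrom1 &
      genes$start < span[2] & genes$end > span[1] - 1L
    hit_genes <- unique(c(hit_genes, genes$symbol[ov]))
  }

  tier <- NA_integer_
  if (!is.null(driver_db) && nrow(driver_db)) {
    match2 <- driver_db$gene %in% hit_genes &
      (driver_db$svclass == "*" | driver_db$svclass == sv$svclass)
    if (any(match2)) tier <- 2L
  }
  if (is.na(tier) && nrow(genes)) {
    tsg <- genes[genes$role == "TSG" & genes$symbol %in% hit_genes, ,
                 drop = FALSE]
    if (nrow(tsg) && disrupts_coding(sv, tsg)) tier <- 3L
  }
  list(breakpoints = bps, tier = tier)
}

locate_breakpoint <- function(chrom, pos, genes) {
  if (!nrow(genes))
    return(list(gene = "intergenic", feature = "intergenic",
                symbols = character()))
  g <- genes[genes$chrom == chrom & genes$start < pos & genes$end >= pos, ,
             drop = FALSE]
  if (!nrow(g))
    return(list(gene = "intergenic", feature = "intergenic",
                symbols = character()))
  feats <- vapply(seq_len(nrow(g)), function(i) {
    ex_s <- as.numeric(strsplit(g$exon_starts[i], ",")[[1]])
    ex_e <- as.numeric(strsplit(g$exon_ends[i], ",")[[1]])
    in_exon <- which(pos > ex_s & pos <= ex_e)
    if (length(in_exon)) {
      idx <- in_exon[1]
      if (g$strand[i] == "-") idx <- length(ex_s) - idx + 1L
      paste0("exon", idx)
    } else {
      idx <- sum(ex_e < pos)
      if (g$strand[i] == "-") idx <- length(ex_s) - idx
      paste0("intron", idx)
    }
  }, character(1))
  list(gene = paste(g$symbol, collapse = ","),
       feature = paste(feats, collapse = ","),
       symbols = g$symbol)
}

disrupts_coding <- function(sv, tsg) {
  for (i in seq_len(nrow(tsg))) {
    cds <- c(tsg$cds_start[i], tsg$cds_end[i])
    inside <- function(chrom, pos)
      chrom == tsg$chrom[i] && pos > cds[1] && pos <= cds[2]
    if (inside(sv$chrom1, sv$pos1) || inside(sv$chrom2, sv$pos2)) return(TRUE)
    if (!is.na(sv$chrom2) && sv$chrom1 == sv$chrom2 &&
        sv$svclass %in% c("deletion", "duplication", "inversion")) {
      span <- sort(c(sv$pos1, sv$pos2))
      if (sv$chrom1 == tsg$chrom[i] && span[1] <= cds[2] &&
          span[2] > cds[1]) return(TRUE)
    }
  }
  FALSE
}
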