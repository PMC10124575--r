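#' Canonical SBS96 category labels
#'
#' Single-base substitutions standardized to a pyrimidine (C or T) reference
#' base with one flanking base on each side: 6 substitution types x 4 5' bases
#' x 4 3' bases = 96 categories, ordered by substitution type, then 5' base,
#' then 3' base (the conventional catalog order).
#'
#' @return character vector of length 96, e.g. `"A[C>A]A"`
#' @export
sbs96_categories <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (s in subs) for (b5 in bases) for (b3 in bases)
    out <- c(out, paste0(b5, "[", s, "]", b3))
  out
}

.complement <- c(A = "T", C = "G", G = "C", T = "A")

revcomp_chr <- function(s) {
  paste(rev(.complement[strsplit(s, "")[[1]]]), collapse = "")
}

#' Classify an SNV into its SBS96 category
#'
#' The substitution is standardized to a pyrimidine center: when the reference
#' base is a purine (A/G) the trinucleotide context is reverse-complemented
#' and the alternate base complemented, so an SNV and its reverse complement
#' map to the same category.
#'
#' @param trinucleotide 3-base reference context centered on the variant base
#' @param ref,alt single reference/alternate bases
#' @return SBS96 category label (element of [sbs96_categories()])
#' @export
#' @examples
#' sbs96_context("ACG", "C", "T")  # "A[C>T]G"
#' sbs96_context("TGA", "G", "A")  # "T[C>T]A"
sbs96_context <- function(trinucleotide, ref, alt) {
  stopifnot(nchar(trinucleotide) == 3L, nchar(ref) == 1L, nchar(alt) == 1L)
  if (substr(trinucleotide, 2, 2) != ref)
    stop("reference base '", ref, "' disagrees with context '",
         trinucleotide, "'", call. = FALSE)
  if (ref == alt) stop("ref and alt are identical", call. = FALSE)
  if (ref %in% c("A", "G")) {
    trinucleotide <- revcomp_chr(trinucleotide)
    ref <- unname(.complement[ref])
    alt <- unname(.complement[alt])
  }
  paste0(substr(trinucleotide, 1, 1), "[", ref, ">", alt, "]",
         substr(trinucleotide, 3, 3))
}

#' Classify an SNV against a reference genome
#'
#' Looks up the trinucleotide context on the reference and validates the
#' stated reference base before delegating to [sbs96_context()].
#'
#' @param genome `Biostrings::DNAStringSet` keyed by chromosome
#' @param chrom,pos chromosome name and 1-based position
#' @param ref,alt single bases
#' @return SBS96 category label
#' @export
sbs96_context_genome <- function(genome, chrom, pos, ref, alt) {
  seq <- genome[[chrom]]
  if (pos < 2L || pos > length(seq) - 1L)
    stop("position ", pos, " lacks a flanking base on ", chrom, call. = FALSE)
  tri <- as.character(Biostrings::subseq(seq, pos - 1L, pos + 1L))
  sbs96_context(tri, ref, alt)
}

#' Canonical ID83 category labels
#'
#' The small-indel classification: 1-bp deletions/insertions of C or T by
#' homopolymer length, longer (2/3/4/5+ bp) deletions/insertions at tandem
#' repeats by repeat-unit count, and deletions with flanking microhomology by
#' homology length. Labels follow the `len:type:subtype:bin` convention
#' (e.g. `"1:Del:T:5"`, `"3:Del:M:2"`); 83 categories in the conventional
#' catalog order.
#'
#' @return character vector of length 83
#' @export
id83_categories <- function() {
  out <- character(0)
  for (b in c("C", "T")) out <- c(out, paste0("1:Del:", b, ":", 0:5))
  for (b in c("C", "T")) out <- c(out, paste0("1:Ins:", b, ":", 0:5))
  for (l in 2:5) out <- c(out, paste0(l, ":Del:R:", 0:5))
  for (l in 2:5) out <- c(out, paste0(l, ":Ins:R:", 0:5))
  for (l in 2:5) {
    # the 5+ length group spans deletions of length >= 5, so homology runs
    # up to the 5+ bin; shorter deletions are capped at length - 1
    mmax <- if (l == 5L) 5L else l - 1L
    out <- c(out, paste0(l, ":Del:M:", seq_len(mmax)))
  }
  out
}

# longest run of `base` in `s` containing or adjacent to index `at`
run_length_at <- function(s, at, base) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  if (at < 1L || at > n || ch[at] != base) return(0L)
  lo <- at; hi <- at
  while (lo > 1L && ch[lo - 1L] == base) lo <- lo - 1L
  while (hi < n && ch[hi + 1L] == base) hi <- hi + 1L
  hi - lo + 1L
}

# number of full tandem copies of `unit` in `s` starting at `from` (1-based)
count_copies <- function(s, from, unit) {
  L <- nchar(unit); n <- nchar(s); k <- 0L
  while (from + L - 1L <= n && substr(s, from, from + L - 1L) == unit) {
    k <- k + 1L
    from <- from + L
  }
  k
}

common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b)); k <- 0L
  while (k < n && substr(a, k + 1L, k + 1L) == substr(b, k + 1L, k + 1L))
    k <- k + 1L
  k
}

common_suffix_len <- function(a, b) {
  common_prefix_len(paste(rev(strsplit(a, "")[[1]]), collapse = ""),
                    paste(rev(strsplit(b, "")[[1]]), collapse = ""))
}

#' Classify a small indel into its ID83 category
#'
#' Takes the indel in local-context form: the sequence `context` (reference
#' bases around the event), the 1-based offset `at` of the base immediately
#' before the event within `context`, and the inserted or deleted sequence.
#' The event is left-aligned against the context before classification, so
#' the category reflects the flanking repeat structure:
#' \itemize{
#'   \item 1-bp events: C/T (purines complemented) by homopolymer length in
#'     the reference (deletions count the deleted base, bins 0-5 = lengths
#'     1-6+; insertions count pre-existing bases, bins 0-5+).
#'   \item >=2-bp events at tandem repeats: repeat-unit bins count additional
#'     full copies of the indel sequence in the reference (0-5+).
#'   \item Deletions with no additional copy but partial flanking homology:
#'     microhomology bins by homology length.
#' }
#'
#' @param context reference sequence window containing the event site
#' @param at 1-based index within `context` of the base preceding the event
#' @param seq inserted (for insertions) or deleted (for deletions) bases
#' @param type `"del"` or `"ins"`
#' @return ID83 category label (element of [id83_categories()])
#' @export
id83_context <- function(context, at, seq, type = c("del", "ins")) {
  type <- match.arg(type)
  L <- nchar(seq)
  stopifnot(L >= 1L, at >= 0L, at <= nchar(context))
  if (type == "del" &&
      substr(context, at + 1L, at + L) != seq)
    stop("deleted sequence '", seq, "' disagrees with context", call. = FALSE)

  # left-align: shift while the base before the event equals the event's
  # last base (equivalently the event sequence rotated)
  while (at >= 1L &&
         substr(context, at, at) == substr(seq, L, L)) {
    seq <- paste0(substr(seq, L, L), substr(seq, 1L, L - 1L))
    at <- at - 1L
  }

  if (L == 1L) {
    base <- seq
    if (base %in% c("A", "G")) base <- unname(.complement[base])
    if (type == "del") {
      run <- run_length_at(context, at + 1L, substr(seq, 1, 1))
      bin <- min(run - 1L, 5L)
      return(paste0("1:Del:", base, ":", bin))
    }
    run <- run_length_at(context, at + 1L, substr(seq, 1, 1))
    bin <- min(run, 5L)
    return(paste0("1:Ins:", base, ":", bin))
  }

  lbin <- min(L, 5L)
  if (type == "ins") {
    copies <- count_copies(context, at + 1L, seq)
    return(paste0(lbin, ":Ins:R:", min(copies, 5L)))
  }
  # deletion of length >= 2: additional copies 3' of the deleted copy
  copies <- count_copies(context, at + L + 1L, seq)
  if (copies >= 1L) return(paste0(lbin, ":Del:R:", min(copies, 5L)))
  flank3 <- substr(context, at + L + 1L, nchar(context))
  flank5 <- substr(context, 1L, at)
  mh <- max(common_prefix_len(seq, flank3), common_suffix_len(seq, flank5))
  mh <- min(mh, L - 1L, 5L)  # full-length homology would be a repeat copy
  if (mh >= 1L) return(paste0(lbin, ":Del:M:", mh))
  paste0(lbin, ":Del:R:0")
}

#' Classify a VCF-style indel against a reference genome
#'
#' Accepts anchored `ref`/`alt` alleles (first base shared, as in VCF) and a
#' window half-width, extracts the local context from the genome and
#' delegates to [id83_context()]. Events at contig edges use the truncated
#' available context with a warning.
#'
#' @param genome `Biostrings::DNAStringSet`
#' @param chrom,pos chromosome and 1-based position of the anchor base
#' @param ref,alt VCF-style alleles (one of them length 1)
#' @param window context half-width in bp (default 50)
#' @return ID83 category label
#' @export
id83_context_genome <- function(genome, chrom, pos, ref, alt, window = 50L) {
  seq <- genome[[chrom]]
  if (nchar(ref) > 1L && nchar(alt) == 1L) {
    type <- "del"; event <- substr(ref, 2L, nchar(ref))
  } else if (nchar(alt) > 1L && nchar(ref) == 1L) {
    type <- "ins"; event <- substr(alt, 2L, nchar(alt))
  } else stop("not a simple indel: ref='", ref, "' alt='", alt, "'",
              call. = FALSE)
  lo <- max(1L, pos - window)
  hi <- min(length(seq), pos + nchar(event) + window)
  if (lo > pos - window || hi < pos + nchar(event) + window)
    warning("indel context truncated at contig edge (", chrom, ":", pos, ")",
            call. = FALSE)
  ctx <- as.character(Biostrings::subseq(seq, lo, hi))
  id83_context(ctx, at = pos - lo + 1L, seq = event, type = type)
}

#' Canonical CN48 category labels
#'
#' Copy-number segments classified by type (homozygous deletion; loss of
#' heterozygosity, minor copy number 0 with total >= 1; heterozygous,
#' minor >= 1), total-CN level and segment length. Homozygous deletions carry
#' three length bins (0-100kb, 100kb-1Mb, >1Mb); LOH segments carry CN levels
#' 1, 2, 3-4, 5-8, 9+ and heterozygous segments CN levels 2, 3-4, 5-8, 9+,
#' each crossed with five length bins (0-100kb, 100kb-1Mb, 1Mb-10Mb,
#' 10Mb-40Mb, >40Mb): 3 + 25 + 20 = 48 categories.
#'
#' @return character vector of length 48, e.g. `"2:LOH:1Mb-10Mb"`
#' @export
cn48_categories <- function() {
  len5 <- c("0-100kb", "100kb-1Mb", "1Mb-10Mb", "10Mb-40Mb", ">40Mb")
  len3 <- c("0-100kb", "100kb-1Mb", ">1Mb")
  out <- paste0("0:homdel:", len3)
  for (cn in c("1", "2", "3-4", "5-8", "9+"))
    out <- c(out, paste0(cn, ":LOH:", len5))
  for (cn in c("2", "3-4", "5-8", "9+"))
    out <- c(out, paste0(cn, ":het:", len5))
  out
}

cn_level_bin <- function(cn) {
  if (cn <= 2) as.character(cn)
  else if (cn <= 4) "3-4"
  else if (cn <= 8) "5-8"
  else "9+"
}

cn_length_bin <- function(len, homdel = FALSE) {
  if (homdel) {
    if (len <= 1e5) "0-100kb" else if (len <= 1e6) "100kb-1Mb" else ">1Mb"
  } else {
    if (len <= 1e5) "0-100kb"
    else if (len <= 1e6) "100kb-1Mb"
    else if (len <= 1e7) "1Mb-10Mb"
    else if (len <= 4e7) "10Mb-40Mb"
    else ">40Mb"
  }
}

#' Classify a copy-number segment into its CN48 category
#'
#' @param total_cn,minor_cn total and minor allele copy number (real; rounded
#'   to integers for classification)
#' @param length segment length in bp
#' @return CN48 category label (element of [cn48_categories()])
#' @export
#' @examples
#' cn48_context(2, 0, 5e6)   # "2:LOH:1Mb-10Mb"
#' cn48_context(2, 1, 5e7)   # "2:het:>40Mb"
cn48_context <- function(total_cn, minor_cn, length) {
  stopifnot(length > 0)
  tot <- as.integer(round(total_cn))
  mn  <- as.integer(round(minor_cn))
  if (tot < 0 || mn < 0)
    stop("negative copy number", call. = FALSE)
  if (mn > floor(tot / 2))
    stop("minor CN ", mn, " exceeds total/2 for total CN ", tot, call. = FALSE)
  if (tot == 0L)
    return(paste0("0:homdel:", cn_length_bin(length, homdel = TRUE)))
  if (mn == 0L)
    return(paste0(cn_level_bin(tot), ":LOH:", cn_length_bin(length)))
  # heterozygous: minor >= 1 implies total >= 2
  paste0(cn_level_bin(tot), ":het:", cn_length_bin(length))
}
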