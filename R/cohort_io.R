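#' Write a cohort bundle to plain-text files
#'
#' Serializes every layer of a synthetic cohort into the conventional
#' formats: sample sheet / SEG-like segments / beta matrix + manifest /
#' expression matrix + probe-gene map / gene models as TSV; mask tracks as
#' BED (0-based half-open); SNV/indel and SV call sets as VCF 4.2 (SVs with
#' INFO keys SVTYPE, END and the IMPRECISE flag); the truth record as JSON.
#'
#' @param bundle `cohort_bundle` from [generate_cohort()]
#' @param dir output directory (created if needed)
#' @return invisibly, the vector of files written
#' @export
write_cohort <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wt <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <<- c(files, path)
  }
  wt(bundle$sample_sheet, "sample_sheet.tsv")
  seg <- bundle$cn_segments[, c("sample", "chrom", "start", "end",
                                "total_cn", "minor_cn")]
  wt(seg, "cn_segments.seg.tsv")
  wt(data.frame(probe = rownames(bundle$beta), bundle$beta,
                check.names = FALSE), "beta_matrix.tsv")
  wt(bundle$beta_manifest, "beta_manifest.tsv")
  wt(data.frame(probe = rownames(bundle$expression), bundle$expression,
                check.names = FALSE), "expression_raw.tsv")
  wt(data.frame(probe = names(bundle$probe_gene),
                gene = unname(bundle$probe_gene)), "probe_gene_map.tsv")
  wt(bundle$gene_models, "gene_models.tsv")

  for (nm in names(bundle$masks)) {
    path <- file.path(dir, paste0("mask_", nm, ".bed"))
    m <- bundle$masks[[nm]]
    utils::write.table(cbind(m$chrom, m$start, m$end), path, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    files <- c(files, path)
  }

  files <- c(files, write_small_variant_vcf(bundle, file.path(dir,
                                                      "small_variants.vcf")))
  files <- c(files, write_sv_vcf(bundle$sv, bundle$config$genome,
                                 file.path(dir, "svs.vcf")))

  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(bundle$truth, truth_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- c(files, truth_path)
  invisible(files)
}

vcf_header <- function(genome, extra_info = character()) {
  c("##fileformat=VCFv4.2",
    paste0("##contig=<ID=", genome$chrom, ",length=", genome$length, ">"),
    extra_info,
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "SAMPLE", sep = "\t"))
}

write_small_variant_vcf <- function(bundle, path) {
  lines <- vcf_header(bundle$config$genome,
    "##INFO=<ID=TRI,Number=1,Type=String,Description=\"Trinucleotide context\">")
  rows <- character(0)
  if (!is.null(bundle$snv) && nrow(bundle$snv)) {
    s <- bundle$snv
    rows <- c(rows, paste(s$chrom, s$pos, ".", s$ref, s$alt, ".", "PASS",
                          paste0("TRI=", s$trinucleotide), s$sample,
                          sep = "\t"))
  }
  if (!is.null(bundle$indel) && nrow(bundle$indel)) {
    d <- bundle$indel
    anchor <- substr(d$context, d$at, d$at)
    ref <- ifelse(d$type == "del", paste0(anchor, d$seq), anchor)
    alt <- ifelse(d$type == "del", anchor, paste0(anchor, d$seq))
    rows <- c(rows, paste(d$chrom, d$pos, ".", ref, alt, ".", "PASS", ".",
                          d$sample, sep = "\t"))
  }
  writeLines(c(lines, rows), path)
  path
}

write_sv_vcf <- function(sv, genome, path) {
  lines <- vcf_header(genome, c(
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV class\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"Second breakpoint\">",
    "##INFO=<ID=CHR2,Number=1,Type=String,Description=\"Mate chromosome\">",
    "##INFO=<ID=IMPRECISE,Number=0,Type=Flag,Description=\"Imprecise call\">"))
  rows <- character(0)
  if (!is.null(sv) && nrow(sv)) {
    type <- toupper(substr(sv$svclass, 1, 3))
    info <- paste0("SVTYPE=", type, ";END=", sv$pos2,
                   ifelse(sv$chrom2 != sv$chrom1,
                          paste0(";CHR2=", sv$chrom2), ""),
                   ifelse(sv$imprecise, ";IMPRECISE", ""))
    rows <- paste(sv$chrom1, sv$pos1, sv$sv_id, "N", paste0("<", type, ">"),
                  ".", "PASS", info, sv$sample, sep = "\t")
  }
  writeLines(c(lines, rows), path)
  path
}

#' Read an SV VCF written by [write_cohort()]
#'
#' @param path VCF path
#' @return SV data.frame in the package's call layout
#' @export
read_sv_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body))
    return(data.frame(sv_id = character(), chrom1 = character(),
                      pos1 = integer(), chrom2 = character(),
                      pos2 = integer(), svclass = character(),
                      imprecise = logical(), sample = character()))
  f <- strsplit(body, "\t", fixed = TRUE)
  get_info <- function(info, key) {
    m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]+)"), info))
    vapply(m, function(x) if (length(x)) x[2] else NA_character_,
           character(1))
  }
  info <- vapply(f, `[`, character(1), 8)
  chrom1 <- vapply(f, `[`, character(1), 1)
  type <- get_info(info, "SVTYPE")
  class_map <- c(DEL = "deletion", DUP = "duplication", INV = "inversion",
                 TRA = "translocation", INS = "insertion")
  chr2 <- get_info(info, "CHR2")
  data.frame(
    sv_id = vapply(f, `[`, character(1), 3),
    chrom1 = chrom1,
    pos1 = as.integer(vapply(f, `[`, character(1), 2)),
    chrom2 = ifelse(is.na(chr2), chrom1, chr2),
    pos2 = as.integer(get_info(info, "END")),
    svclass = unname(class_map[type]),
    imprecise = grepl("(^|;)IMPRECISE($|;)", info),
    sample = vapply(f, `[`, character(1), 9),
    stringsAsFactors = FALSE)
}

#' Read a SEG-like copy-number TSV
#'
#' @param path TSV with columns `sample`, `chrom`, `start`, `end`,
#'   `total_cn`, `minor_cn`
#' @return segment data.frame
#' @export
read_seg <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "chrom", "start", "end", "total_cn")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("SEG file lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df
}

#' Read a beta (or expression) matrix TSV with a `probe` id column
#'
#' @param path TSV path, first column `probe`
#' @return numeric matrix probes x samples
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
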