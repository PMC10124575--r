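#' Configuration for the synthetic GIST cohort
#'
#' Defaults mirror the study's cohort structure: four groups A/B/C/D of
#' 12/6/6/6 samples crossing KIT Delta 557-558 status with malignancy;
#' group-dependent SNV/indel/SV burdens (negative-binomial); planted
#' signature mixtures; arm-level deletions enriched in malignant samples on
#' the 14q/22q/9p analog arms of the miniature genome (chr1q/chr2q/chr3p);
#' two high-ploidy (WGD) samples; group-A intergenic hypomethylation
#' (-0.15 beta on 40% of autosomal bins); 62 planted differentially
#' expressed genes including an upregulated SNAI2; and group-A up-shifts on
#' the hypoxia/CIN/p53-inactivation expression signature gene sets.
#' Per-group burden means are free parameters (the study does not report
#' them); the defaults are desk-scale choices documented in the package
#' vignette.
#'
#' @param group_sizes named integer vector, samples per group
#' @param genome genome table from [default_genome()]
#' @param burden_means list group -> c(snv=, indel=, sv=) mean counts
#' @param burden_dispersion negative-binomial size parameter
#' @param sbs_mix,id_mix list group -> signature weights (sum to 1) over the
#'   bundled SBS/ID catalogs
#' @param arm_deletion_probs list group -> named vector arm -> probability
#'   of a whole-arm deletion (total CN 1, minor 0)
#' @param wgd_samples named integer vector group -> number of samples with a
#'   tetraploid (whole-genome duplicated) baseline
#' @param hypomethylation c(fraction=, shift=): fraction of autosomal 300-kb
#'   bins whose intergenic probes are shifted down by `shift` in group A
#' @param promoter_hypermeth list(gene=, shift=, n_samples=): planted
#'   promoter CpG-island hypermethylation in that many group-A samples
#' @param de_genes number of planted differentially expressed genes
#' @param de_shift_range absolute log2 shift range for planted DE genes
#' @param signature_shift group-A log2 up-shift on expression-signature genes
#' @param sv_imprecise_frac,sv_near_mask_frac fractions of simulated SVs
#'   flagged IMPRECISE / placed within 100 bp of a mask interval
#' @param n_genes number of gene models on the miniature genome
#' @param expr_noise_sd per-sample expression noise SD (log2)
#' @param meth_probe_spacing background methylation probe spacing (bp)
#' @param meth_tss_probes probes per TSS CpG island
#' @param meth_concentration beta-distribution concentration of per-sample
#'   probe values around the probe baseline
#' @param cn_jitter_sd SD of segment-level total-CN measurement noise
#' @param seed integer RNG seed; the bundle is a deterministic function of
#'   the configuration including the seed
#' @return object of class `cohort_config`
#' @export
cohort_config <- function(
    group_sizes = c(A = 12L, B = 6L, C = 6L, D = 6L),
    genome = default_genome(),
    burden_means = list(
      A = c(snv = 3000, indel = 400, sv = 70),
      B = c(snv = 1500, indel = 150, sv = 45),
      C = c(snv = 1300, indel = 150, sv = 30),
      D = c(snv = 1100, indel = 150, sv = 25)),
    burden_dispersion = 8,
    sbs_mix = list(
      A = c(SBSS1 = 0.40, SBSS2 = 0.20, SBSS3 = 0.20, SBSS4 = 0.10,
            SBSS5 = 0.10),
      B = c(SBSS1 = 0.60, SBSS2 = 0.30, SBSS3 = 0.10, SBSS4 = 0,
            SBSS5 = 0),
      C = c(SBSS1 = 0.50, SBSS2 = 0.25, SBSS3 = 0.15, SBSS4 = 0.10,
            SBSS5 = 0),
      D = c(SBSS1 = 0.70, SBSS2 = 0.20, SBSS3 = 0.10, SBSS4 = 0,
            SBSS5 = 0)),
    id_mix = list(
      A = c(IDS1 = 0.60, IDS2 = 0.30, IDS3 = 0.10),
      B = c(IDS1 = 0.40, IDS2 = 0.50, IDS3 = 0.10),
      C = c(IDS1 = 0.40, IDS2 = 0.50, IDS3 = 0.10),
      D = c(IDS1 = 0.40, IDS2 = 0.50, IDS3 = 0.10)),
    arm_deletion_probs = list(
      A = c(chr1q = 0.6, chr2q = 0.8, chr3p = 0.6),
      B = c(chr1q = 0.6, chr2q = 0.5, chr3p = 0.05),
      C = c(chr1q = 0.6, chr2q = 0.2, chr3p = 0.05),
      D = c(chr1q = 0.6, chr2q = 0.2, chr3p = 0.05)),
    wgd_samples = c(A = 1L, D = 1L),
    hypomethylation = c(fraction = 0.4, shift = 0.15),
    promoter_hypermeth = list(gene = "CDKN2A", shift = 0.4, n_samples = 1L),
    de_genes = 62L,
    de_shift_range = c(1.5, 3),
    signature_shift = 0.7,
    sv_imprecise_frac = 0.15,
    sv_near_mask_frac = 0.2,
    n_genes = 1000L,
    expr_noise_sd = 0.5,
    meth_probe_spacing = 5000L,
    meth_tss_probes = 5L,
    meth_concentration = 60,
    cn_jitter_sd = 0.05,
    seed = 1L) {
  cfg <- list(group_sizes = group_sizes, genome = genome,
              burden_means = burden_means,
              burden_dispersion = burden_dispersion,
              sbs_mix = sbs_mix, id_mix = id_mix,
              arm_deletion_probs = arm_deletion_probs,
              wgd_samples = wgd_samples,
              hypomethylation = hypomethylation,
              promoter_hypermeth = promoter_hypermeth,
              de_genes = de_genes, de_shift_range = de_shift_range,
              signature_shift = signature_shift,
              sv_imprecise_frac = sv_imprecise_frac,
              sv_near_mask_frac = sv_near_mask_frac,
              n_genes = n_genes, expr_noise_sd = expr_noise_sd,
              meth_probe_spacing = meth_probe_spacing,
              meth_tss_probes = meth_tss_probes,
              meth_concentration = meth_concentration,
              cn_jitter_sd = cn_jitter_sd, seed = seed)
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (any(cfg$group_sizes < 0))
    stop("group sizes must be >= 0", call. = FALSE)
  groups <- names(cfg$group_sizes)
  for (g in groups) {
    for (mx in c("sbs_mix", "id_mix")) {
      if (is.null(cfg[[mx]][[g]]))
        stop(mx, " missing for group ", g, call. = FALSE)
      w <- cfg[[mx]][[g]]
      if (any(w < 0) || abs(sum(w) - 1) > 1e-8)
        stop(mx, " weights for group ", g,
             " must be nonnegative and sum to 1", call. = FALSE)
    }
    if (is.null(cfg$burden_means[[g]]))
      stop("burden_means missing for group ", g, call. = FALSE)
  }
  probs <- c(unlist(cfg$arm_deletion_probs), cfg$hypomethylation["fraction"],
             cfg$sv_imprecise_frac, cfg$sv_near_mask_frac)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  if (is.null(cfg$genome) || !nrow(cfg$genome))
    stop("genome undefined", call. = FALSE)
  invisible(cfg)
}

# mutation-string pools; the delta pool deletes both codons 557 and 558
.delta_pool <- c("p.W557_K558del", "p.K550_K558del", "p.W557_K558delinsE",
                 "p.W557_V559delinsF", "p.W557_E561del", "p.P551_K558delinsQ",
                 "p.W557_V560delinsF")
.nondelta_pool <- c("p.V560D", "p.V559G", "p.L576P", "p.K558_E562del",
                    "p.D579del", "p.Y570_L576del", "p.W557R", "p.V559D")

generate_sample_sheet <- function(cfg) {
  rows <- list()
  idx <- 0L
  for (g in names(cfg$group_sizes)) {
    n <- cfg$group_sizes[[g]]
    if (n == 0L) next
    delta <- g %in% c("A", "C")
    pool <- if (delta) .delta_pool else .nondelta_pool
    for (j in seq_len(n)) {
      idx <- idx + 1L
      malignant <- g %in% c("A", "B")
      derivation <- "Primary"
      risk <- if (malignant) "High" else
        sample(c("Low", "Intermediate"), 1, prob = c(0.8, 0.2))
      if (malignant && j == 1L) {
        derivation <- sample(c("Metastasis", "Recurrence"), 1)
        risk <- NA_character_
      }
      rows[[idx]] <- data.frame(
        sample = sprintf("S%02d", idx),
        group = g,
        risk = risk,
        derivation = derivation,
        location = sample(c("Stomach", "Small intestine"), 1,
                          prob = c(0.75, 0.25)),
        mutation = paste0("E11: ", sample(pool, 1)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# instantiate a concrete local context realizing one ID83 category, so the
# classifier recovers the category from the record (round-trip property)
instantiate_id83 <- function(category) {
  parts <- strsplit(category, ":", fixed = TRUE)[[1]]
  len <- as.integer(parts[1]); type <- parts[2]
  sub <- parts[3]; bin <- as.integer(parts[4])
  bases <- c("A", "C", "G", "T")
  other <- function(b) sample(setdiff(bases, b), 1)
  if (len == 1L) {
    b <- sub  # C or T representation
    if (type == "Del") {
      run <- if (bin < 5L) bin + 1L else 6L
      ctx <- paste0(other(b), strrep(b, run), other(b))
      return(list(context = ctx, at = 1L, seq = b, type = "del"))
    }
    run <- if (bin < 5L) bin else 5L
    ctx <- paste0(other(b), strrep(b, run), other(b))
    return(list(context = ctx, at = 1L, seq = b, type = "ins"))
  }
  L <- if (len < 5L) len
       else if (sub == "M" && bin == 5L) sample(6:8, 1)  # homology <= L-1
       else sample(5:7, 1)
  unit <- paste(sample(bases, L, replace = TRUE), collapse = "")
  first <- substr(unit, 1, 1); last <- substr(unit, L, L)
  x_last <- other(last)   # prevents left-shift and 5' homology
  if (sub == "R") {
    copies <- if (bin < 5L) bin else 5L
    y <- other(first)     # prevents extra copies and 3' homology
    if (type == "Del") {
      ctx <- paste0("A", x_last, strrep(unit, copies + 1L), y, "A")
      return(list(context = ctx, at = 2L, seq = unit, type = "del"))
    }
    ctx <- paste0("A", x_last, strrep(unit, copies), y, "A")
    return(list(context = ctx, at = 2L, seq = unit, type = "ins"))
  }
  # microhomology deletion: 3' flank starts with bin bases of the unit
  m <- bin
  mh <- substr(unit, 1, m)
  brk <- other(substr(unit, m + 1L, m + 1L))
  ctx <- paste0("A", x_last, unit, mh, brk, "A")
  list(context = ctx, at = 2L, seq = unit, type = "del")
}

generate_mutations <- function(group, cfg, n_override = NULL) {
  if (is.null(cfg$sbs_mix[[group]]))
    stop("group ", group, " missing from config", call. = FALSE)
  sbs_cat <- synthetic_catalog("SBS96")
  id_cat <- synthetic_catalog("ID83")
  means <- cfg$burden_means[[group]]

  n_snv <- if (!is.null(n_override)) n_override else
    stats::rnbinom(1, mu = means[["snv"]], size = cfg$burden_dispersion)
  snv <- if (n_snv > 0) {
    w <- cfg$sbs_mix[[group]][colnames(sbs_cat)]
    sig <- sample(colnames(sbs_cat), n_snv, replace = TRUE, prob = w)
    cat96 <- sbs96_categories()
    category <- character(n_snv)
    for (s in unique(sig)) {
      k <- sig == s
      category[k] <- sample(cat96, sum(k), replace = TRUE,
                            prob = sbs_cat[, s])
    }
    tri <- paste0(substr(category, 1, 1), substr(category, 3, 3),
                  substr(category, 7, 7))
    ref <- substr(category, 3, 3)
    alt <- substr(category, 5, 5)
    # half the records are stored on the purine strand; classification
    # must standardize them back (strand symmetry)
    flip <- stats::runif(n_snv) < 0.5
    tri[flip] <- vapply(tri[flip], revcomp_chr, character(1))
    ref[flip] <- unname(.complement[ref[flip]])
    alt[flip] <- unname(.complement[alt[flip]])
    auto <- cfg$genome$chrom[!cfg$genome$is_sex]
    glen <- stats::setNames(cfg$genome$length, cfg$genome$chrom)
    chrom <- sample(auto, n_snv, replace = TRUE)
    data.frame(
      chrom = chrom,
      pos = floor(stats::runif(n_snv) * (glen[chrom] - 4)) + 2L,
      trinucleotide = tri, ref = ref, alt = alt,
      true_signature = sig, true_category = category,
      stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = character(), pos = integer(),
               trinucleotide = character(), ref = character(),
               alt = character(), true_signature = character(),
               true_category = character())
  }

  n_id <- stats::rnbinom(1, mu = means[["indel"]],
                         size = cfg$burden_dispersion)
  indel <- if (n_id > 0) {
    w <- cfg$id_mix[[group]][colnames(id_cat)]
    sig <- sample(colnames(id_cat), n_id, replace = TRUE, prob = w)
    cat83 <- id83_categories()
    category <- character(n_id)
    for (s in unique(sig)) {
      k <- sig == s
      category[k] <- sample(cat83, sum(k), replace = TRUE,
                            prob = id_cat[, s])
    }
    inst <- lapply(category, instantiate_id83)
    auto <- cfg$genome$chrom[!cfg$genome$is_sex]
    glen <- stats::setNames(cfg$genome$length, cfg$genome$chrom)
    chrom <- sample(auto, n_id, replace = TRUE)
    data.frame(
      chrom = chrom,
      pos = floor(stats::runif(n_id) * (glen[chrom] - 200)) + 100L,
      context = vapply(inst, `[[`, character(1), "context"),
      at = vapply(inst, `[[`, integer(1), "at"),
      seq = vapply(inst, `[[`, character(1), "seq"),
      type = vapply(inst, `[[`, character(1), "type"),
      true_signature = sig, true_category = category,
      stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = character(), pos = integer(), context = character(),
               at = integer(), seq = character(), type = character(),
               true_signature = character(), true_category = character())
  }
  list(snv = snv, indel = indel)
}

generate_masks <- function(cfg, per_track = 30L) {
  tracks <- c("segmental_duplications", "microsatellites", "simple_repeats",
              "low_complexity", "encode_blacklist")
  out <- lapply(tracks, function(t) {
    chrom <- sample(cfg$genome$chrom, per_track, replace = TRUE)
    len <- stats::setNames(cfg$genome$length, cfg$genome$chrom)[chrom]
    width <- sample(200:5000, per_track, replace = TRUE)
    start <- floor(stats::runif(per_track) * (len - width))
    df <- data.frame(chrom = chrom, start = start, end = start + width,
                     stringsAsFactors = FALSE)
    df[order(df$chrom, df$start), ]
  })
  names(out) <- tracks
  out
}

generate_svs <- function(group, cfg, masks) {
  means <- cfg$burden_means[[group]]
  n <- stats::rnbinom(1, mu = means[["sv"]], size = cfg$burden_dispersion)
  if (n == 0)
    return(data.frame(sv_id = character(), chrom1 = character(),
                      pos1 = integer(), chrom2 = character(),
                      pos2 = integer(), svclass = character(),
                      imprecise = logical(), length = numeric()))
  classes <- sample(c("deletion", "duplication", "inversion",
                      "translocation", "insertion"),
                    n, replace = TRUE,
                    prob = c(0.35, 0.2, 0.2, 0.15, 0.1))
  glen <- stats::setNames(cfg$genome$length, cfg$genome$chrom)
  chrom1 <- sample(cfg$genome$chrom, n, replace = TRUE)
  svlen <- round(10^stats::runif(n, 3, 6))
  pos1 <- floor(stats::runif(n) * (glen[chrom1] - svlen - 200)) + 100L
  # a configurable fraction of breakpoints land within 100 bp of a mask
  near <- stats::runif(n) < cfg$sv_near_mask_frac
  all_masks <- do.call(rbind, masks)
  for (i in which(near)) {
    mk <- all_masks[sample.int(nrow(all_masks), 1), ]
    chrom1[i] <- mk$chrom
    pos1[i] <- mk$end + sample(0:100, 1)
  }
  chrom2 <- chrom1
  pos2 <- pos1 + svlen
  tra <- classes == "translocation"
  for (i in which(tra)) {
    chrom2[i] <- sample(setdiff(cfg$genome$chrom, chrom1[i]), 1)
    pos2[i] <- sample.int(glen[chrom2[i]] - 200L, 1) + 100L
  }
  data.frame(
    sv_id = sprintf("sv%04d", seq_len(n)),
    chrom1 = unname(chrom1), pos1 = as.integer(pos1),
    chrom2 = unname(chrom2), pos2 = as.integer(pos2),
    svclass = classes,
    imprecise = stats::runif(n) < cfg$sv_imprecise_frac,
    length = ifelse(tra, NA_real_, svlen),
    stringsAsFactors = FALSE)
}

# overlay an event interval on a tiling segment set (one chromosome)
overlay_segment <- function(segs, start, end, total, minor) {
  keep <- list(); k <- 0L
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, ]
    if (s$end <= start || s$start >= end) {
      k <- k + 1L; keep[[k]] <- s; next
    }
    if (s$start < start) {
      k <- k + 1L
      keep[[k]] <- data.frame(start = s$start, end = start,
                              total_cn = s$total_cn, minor_cn = s$minor_cn)
    }
    if (s$end > end) {
      k <- k + 1L
      keep[[k]] <- data.frame(start = end, end = s$end,
                              total_cn = s$total_cn, minor_cn = s$minor_cn)
    }
  }
  k <- k + 1L
  keep[[k]] <- data.frame(start = start, end = end, total_cn = total,
                          minor_cn = minor)
  out <- do.call(rbind, keep)
  out[order(out$start), ]
}

generate_cn_segments <- function(group, cfg, wgd = FALSE) {
  if (is.null(cfg$genome) || !nrow(cfg$genome))
    stop("genome undefined", call. = FALSE)
  arms <- arm_table(cfg$genome)
  base <- if (wgd) c(4, 2) else c(2, 1)
  per_chrom <- lapply(seq_len(nrow(cfg$genome)), function(ci) {
    g <- cfg$genome[ci, ]
    segs <- data.frame(start = 0, end = g$length,
                       total_cn = base[1], minor_cn = base[2])
    if (!wgd) {
      probs <- cfg$arm_deletion_probs[[group]]
      for (a in names(probs)) {
        arm <- arms[arms$arm == a, ]
        if (!nrow(arm) || arm$chrom != g$chrom) next
        if (stats::runif(1) < probs[[a]])
          segs <- overlay_segment(segs, arm$start, arm$end, 1, 0)
      }
    }
    n_focal <- stats::rpois(1, 1)
    for (j in seq_len(n_focal)) {
      len <- round(10^stats::runif(1, 4.5, 6.9))
      start <- floor(stats::runif(1) * (g$length - len))
      type <- sample(c("del", "homdel", "gain", "cnloh"), 1,
                     prob = c(0.4, 0.1, 0.3, 0.2))
      cnm <- switch(type,
        del = c(1, 0),
        homdel = c(0, 0),
        gain = c(sample(3:6, 1), 1),
        cnloh = c(2, 0))
      if (type == "homdel") len <- min(len, 5e5)
      segs <- overlay_segment(segs, start, start + len, cnm[1], cnm[2])
    }
    segs$chrom <- g$chrom
    segs
  })
  out <- do.call(rbind, per_chrom)
  out$total_cn <- pmax(0, out$total_cn +
                         stats::rnorm(nrow(out), 0, cfg$cn_jitter_sd))
  out[, c("chrom", "start", "end", "total_cn", "minor_cn")]
}

generate_gene_models <- function(cfg) {
  special <- data.frame(
    symbol = c("CDKN2A", "DEPDC5", "MAX", "AKT3", "MGMT", "LRP1B", "SNAI2"),
    chrom  = c("chr3", "chr2", "chr1", "chr1", "chr2", "chr3", "chr2"),
    # CDKN2A on the 9p analog (chr3p), DEPDC5 on the 22q analog (chr2q),
    # MAX on the 14q analog (chr1q)
    pos    = c(8e6, 40e6, 38e6, 55e6, 12e6, 30e6, 6e6),
    role   = c("TSG", "TSG", "TSG", "oncogene", "TSG", "TSG", "other"),
    stringsAsFactors = FALSE)
  n_bg <- cfg$n_genes - nrow(special)
  bg_chrom <- sample(cfg$genome$chrom, n_bg, replace = TRUE)
  glen <- stats::setNames(cfg$genome$length, cfg$genome$chrom)
  bg <- data.frame(
    symbol = sprintf("GENE%03d", seq_len(n_bg)),
    chrom = bg_chrom,
    pos = floor(stats::runif(n_bg) * (glen[bg_chrom] - 3e5)) + 1e5,
    role = sample(c("TSG", "oncogene", "other"), n_bg, replace = TRUE,
                  prob = c(0.1, 0.1, 0.8)),
    stringsAsFactors = FALSE)
  genes <- rbind(special, bg)
  n <- nrow(genes)
  width <- sample(20000:200000, n, replace = TRUE)
  genes$start <- genes$pos
  genes$end <- genes$pos + width
  genes$strand <- sample(c("+", "-"), n, replace = TRUE)
  n_ex <- sample(3:8, n, replace = TRUE)
  ex <- lapply(seq_len(n), function(i) {
    # exon grid: split the span into 2*n_ex+1 slots, exons on even slots
    bounds <- round(seq(genes$start[i], genes$end[i],
                        length.out = 2L * n_ex[i] + 1L))
    s <- bounds[seq(1, 2 * n_ex[i], by = 2)]
    e <- bounds[seq(2, 2 * n_ex[i] + 1, by = 2)]
    list(s = s, e = e)
  })
  genes$exon_starts <- vapply(ex, function(z) paste(z$s, collapse = ","),
                              character(1))
  genes$exon_ends <- vapply(ex, function(z) paste(z$e, collapse = ","),
                            character(1))
  genes$cds_start <- genes$start + round(0.1 * width)
  genes$cds_end <- genes$end - round(0.1 * width)
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  rownames(genes) <- NULL
  genes[, c("symbol", "chrom", "start", "end", "strand", "tss",
            "cds_start", "cds_end", "exon_starts", "exon_ends", "role")]
}

generate_methylation <- function(sheet, genes, cfg) {
  glen <- stats::setNames(cfg$genome$length, cfg$genome$chrom)
  bg <- do.call(rbind, lapply(cfg$genome$chrom, function(ch) {
    pos <- seq(2500L, glen[[ch]], by = cfg$meth_probe_spacing)
    data.frame(chrom = ch, pos = pos, is_tss_cgi = FALSE,
               stringsAsFactors = FALSE)
  }))
  tss <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    off <- (seq_len(cfg$meth_tss_probes) -
              (cfg$meth_tss_probes + 1) / 2) * 100
    data.frame(chrom = genes$chrom[i],
               pos = as.integer(round(genes$tss[i] + off)),
               is_tss_cgi = TRUE, gene = genes$symbol[i],
               stringsAsFactors = FALSE)
  }))
  bg$gene <- NA_character_
  manifest <- rbind(bg, tss)
  manifest <- manifest[manifest$pos >= 1 & manifest$pos <= glen[manifest$chrom], ]
  manifest$probe <- sprintf("cg%06d", seq_len(nrow(manifest)))
  manifest$is_sex_chrom <- manifest$chrom %in%
    cfg$genome$chrom[cfg$genome$is_sex]

  # probe baselines: intergenic high-beta, TSS CpG-island low-beta
  n <- nrow(manifest)
  mu <- ifelse(manifest$is_tss_cgi,
               stats::rbeta(n, 1.5, 8.5), stats::rbeta(n, 7.5, 2.5))
  mu <- pmin(pmax(mu, 0.02), 0.98)

  # choose the hypomethylated autosomal 300-kb bins
  bin_size <- 300000
  auto <- !manifest$is_sex_chrom
  bin_key <- sprintf("%s:%.0f", manifest$chrom,
                     manifest$pos %/% bin_size * bin_size)
  all_bins <- sort(unique(bin_key[auto]))
  n_hypo <- round(cfg$hypomethylation[["fraction"]] * length(all_bins))
  hypo_bins <- sort(sample(all_bins, n_hypo))
  shifted_probe <- auto & !manifest$is_tss_cgi & bin_key %in% hypo_bins

  k <- cfg$meth_concentration
  beta <- matrix(NA_real_, nrow = n, ncol = nrow(sheet),
                 dimnames = list(manifest$probe, sheet$sample))
  shift <- cfg$hypomethylation[["shift"]]
  for (j in seq_len(nrow(sheet))) {
    mu_j <- mu
    if (sheet$group[j] == "A")
      mu_j[shifted_probe] <- pmin(pmax(mu[shifted_probe] - shift, 0.02),
                                  0.98)
    beta[, j] <- stats::rbeta(n, mu_j * k, (1 - mu_j) * k)
  }

  # planted promoter hypermethylation in group-A sample(s)
  ph <- cfg$promoter_hypermeth
  ph_samples <- character(0)
  if (!is.null(ph) && ph$n_samples > 0) {
    a_samples <- sheet$sample[sheet$group == "A"]
    ph_samples <- utils::head(a_samples, ph$n_samples)
    pr <- manifest$probe[!is.na(manifest$gene) & manifest$gene == ph$gene]
    for (sm in ph_samples)
      beta[pr, sm] <- pmin(beta[pr, sm] + ph$shift, 0.99)
  }

  list(beta = beta,
       manifest = manifest[, c("probe", "chrom", "pos", "is_sex_chrom",
                               "is_tss_cgi", "gene")],
       hypo_bins = hypo_bins,
       promoter_hypermeth_samples = ph_samples)
}

generate_expression <- function(sheet, genes, cfg) {
  n_g <- nrow(genes)
  two_probe <- stats::runif(n_g) < 0.2
  probe_gene <- c(genes$symbol, genes$symbol[two_probe])
  probe_id <- sprintf("P%04d", seq_along(probe_gene))
  names(probe_gene) <- probe_id

  # planted DE genes: SNAI2 forced in, strongly up
  if (cfg$de_genes > 0L) {
    candidates <- setdiff(genes$symbol, "SNAI2")
    de_genes <- c("SNAI2", sample(candidates, cfg$de_genes - 1L))
    de_shift <- stats::runif(cfg$de_genes, cfg$de_shift_range[1],
                             cfg$de_shift_range[2]) *
      sample(c(1, -1), cfg$de_genes, replace = TRUE, prob = c(0.4, 0.6))
    de_shift[1] <- cfg$de_shift_range[2]   # SNAI2: maximal up-shift
    names(de_shift) <- de_genes
  } else {
    de_genes <- character(0)
    de_shift <- numeric(0)
  }

  # expression-signature gene sets drawn from non-DE background genes
  sig_pool <- setdiff(genes$symbol, de_genes)
  sig_sets <- list()
  for (nm in c("TP53_inactivation", "CIN", "hypoxia")) {
    sig_sets[[nm]] <- sort(sample(sig_pool, 20))
    sig_pool <- setdiff(sig_pool, sig_sets[[nm]])
  }

  gene_mean <- stats::setNames(stats::rnorm(n_g, 8, 1.5), genes$symbol)
  probe_eff <- stats::rnorm(length(probe_id), 0, 0.3)
  sample_scale <- stats::rnorm(nrow(sheet), 0, 0.3)  # removed by 75th pct

  lg <- matrix(NA_real_, nrow = length(probe_id), ncol = nrow(sheet),
               dimnames = list(probe_id, sheet$sample))
  sig_genes_all <- unlist(sig_sets, use.names = FALSE)
  for (j in seq_len(nrow(sheet))) {
    shift_j <- stats::setNames(rep(0, n_g), genes$symbol)
    if (sheet$group[j] == "A") {
      shift_j[de_genes] <- de_shift
      shift_j[sig_genes_all] <- shift_j[sig_genes_all] + cfg$signature_shift
    }
    lg[, j] <- gene_mean[probe_gene] + shift_j[probe_gene] + probe_eff +
      sample_scale[j] + stats::rnorm(length(probe_id), 0, cfg$expr_noise_sd)
  }
  list(raw = 2^lg, probe_gene = probe_gene,
       de_genes = data.frame(gene = de_genes, log2_shift = unname(de_shift),
                             stringsAsFactors = FALSE),
       signature_sets = sig_sets)
}

#' Generate a complete synthetic GIST cohort
#'
#' Produces every omics layer for the configured cohort: sample sheet with
#' planted KIT mutation strings; per-sample SNV/indel sets drawn from the
#' group's signature mixtures (each indel record carries a concrete local
#' reference context realizing its category); SV sets with configurable
#' IMPRECISE and near-mask fractions; tiling allele-specific copy-number
#' segments with planted arm deletions and WGD samples; a methylation beta
#' matrix + probe manifest with the planted group-A intergenic
#' hypomethylation; a raw expression matrix + probe-to-gene map with planted
#' DE genes and signature up-shifts; mask tracks; gene models; and a truth
#' record listing every planted effect. Deterministic given the
#' configuration (including its seed).
#'
#' @param config a [cohort_config()]
#' @return list of class `cohort_bundle` with elements `config`,
#'   `sample_sheet`, `snv`, `indel`, `sv` (data.frames with `sample`
#'   column), `cn_segments`, `masks`, `gene_models`, `beta`,
#'   `beta_manifest`, `expression`, `probe_gene`, `signature_sets`, `truth`
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(config$seed)

  sheet <- generate_sample_sheet(config)
  masks <- generate_masks(config)
  genes <- generate_gene_models(config)

  wgd_flag <- stats::setNames(rep(FALSE, nrow(sheet)), sheet$sample)
  for (g in names(config$wgd_samples)) {
    nw <- config$wgd_samples[[g]]
    if (nw > 0) {
      sm <- utils::head(sheet$sample[sheet$group == g], nw)
      wgd_flag[sm] <- TRUE
    }
  }

  snv_list <- list(); indel_list <- list(); sv_list <- list()
  cn_list <- list()
  for (i in seq_len(nrow(sheet))) {
    sm <- sheet$sample[i]; g <- sheet$group[i]
    mut <- generate_mutations(g, config)
    if (nrow(mut$snv)) mut$snv$sample <- sm
    if (nrow(mut$indel)) mut$indel$sample <- sm
    snv_list[[sm]] <- mut$snv
    indel_list[[sm]] <- mut$indel
    sv <- generate_svs(g, config, masks)
    if (nrow(sv)) sv$sample <- sm
    sv_list[[sm]] <- sv
    cn <- generate_cn_segments(g, config, wgd = wgd_flag[[sm]])
    cn$sample <- sm
    cn_list[[sm]] <- cn
  }
  meth <- generate_methylation(sheet, genes, config)
  expr <- generate_expression(sheet, genes, config)

  truth <- list(
    groups = stats::setNames(sheet$group, sheet$sample),
    wgd_samples = names(wgd_flag)[wgd_flag],
    burden_means = config$burden_means,
    sbs_mix = config$sbs_mix, id_mix = config$id_mix,
    arm_deletion_probs = config$arm_deletion_probs,
    hypomethylated_bins = meth$hypo_bins,
    hypomethylation_shift = unname(config$hypomethylation[["shift"]]),
    promoter_hypermeth = list(
      gene = config$promoter_hypermeth$gene,
      shift = config$promoter_hypermeth$shift,
      samples = meth$promoter_hypermeth_samples),
    de_genes = expr$de_genes,
    signature_shift = config$signature_shift,
    signature_sets = expr$signature_sets)

  structure(list(
    config = config,
    sample_sheet = sheet,
    snv = do.call(rbind, snv_list),
    indel = do.call(rbind, indel_list),
    sv = do.call(rbind, sv_list),
    cn_segments = do.call(rbind, cn_list),
    masks = masks,
    gene_models = genes,
    beta = meth$beta,
    beta_manifest = meth$manifest,
    expression = expr$raw,
    probe_gene = expr$probe_gene,
    signature_sets = expr$signature_sets,
    truth = truth
  ), class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("<cohort_bundle>", nrow(x$sample_sheet), "samples (",
      paste(names(table(x$sample_sheet$group)),
            table(x$sample_sheet$group), sep = "=", collapse = ", "),
      ")\n")
  cat("  SNVs:", nrow(x$snv), " indels:", nrow(x$indel),
      " SVs:", nrow(x$sv), "\n")
  cat("  CN segments:", nrow(x$cn_segments),
      " methylation probes:", nrow(x$beta),
      " expression probes:", nrow(x$expression), "\n")
  invisible(x)
}

#' Per-sample burden table of a cohort bundle
#'
#' @param bundle `cohort_bundle`
#' @return data.frame `sample`, `group`, `sv`, `snv`, `indel`
#' @export
bundle_burdens <- function(bundle) {
  sheet <- bundle$sample_sheet
  count_by <- function(df) {
    if (is.null(df) || !nrow(df)) return(stats::setNames(integer(0),
                                                         character(0)))
    table(df$sample)
  }
  sv_t <- count_by(bundle$sv); snv_t <- count_by(bundle$snv)
  id_t <- count_by(bundle$indel)
  get0i <- function(t, s) if (s %in% names(t)) as.integer(t[[s]]) else 0L
  data.frame(
    sample = sheet$sample, group = sheet$group,
    sv = vapply(sheet$sample, get0i, integer(1), t = sv_t),
    snv = vapply(sheet$sample, get0i, integer(1), t = snv_t),
    indel = vapply(sheet$sample, get0i, integer(1), t = id_t),
    row.names = NULL)
}
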