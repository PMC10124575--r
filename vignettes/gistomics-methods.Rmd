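---
title: "Methods: multi-omics characterization of KIT delta-557/558 GISTs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omics characterization of KIT delta-557/558 GISTs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gistomics)
```

## The scientific question

Gastrointestinal stromal tumors (GISTs) driven by KIT exon-11 mutations
behave very differently depending on the exact lesion. Deletions that remove
both codons 557 and 558 (KIT delta-557/558) are associated with malignant
behavior; point mutations and deletions elsewhere in the exon are not.
`gistomics` implements the computational arm of a multi-omics comparison of
these strata: it classifies cases into four groups crossing delta-557/558
status with malignancy, and provides the downstream machinery — structural
variant (SV) filtering and driver tiering, mutational/copy-number signature
refitting, arm-level copy-number (CN) metrics, genome-wide methylation
binning, and expression statistics — needed to contrast the groups.

Patient-level data for such a study are controlled-access. The package
therefore ships a synthetic-cohort generator that plants the relevant group
structure (mutation strings, burdens, signature mixtures, arm deletions,
intergenic hypomethylation, differential expression) so that every analysis
stage can be exercised and validated end to end against a known truth
record.

## Case grouping

`parse_hgvs_p()` handles the protein-change dialects found in GIST case
tables (`p.W557_K558del`, `p.V560D`, `p.W557_V559delinsF`, `p.D579del`,
`dup` forms, optional `E11:` prefixes, compound entries). Three grouping
decisions deserve justification:

* **Both codons must be deleted.** Loose readings ("deletions at codon 557
  and/or 558") conflict with the published group labels of cases whose
  deletions start at codon 558 (e.g. `p.K558_E562del`, assigned to the
  non-delta groups). `involves_557_558()` therefore requires the deleted
  interval to cover codons 557 *and* 558. Deletion-insertions count as
  deletions of the replaced interval (`p.W557_V559delinsF` is delta).
* **Malignancy** is high risk under the modified NIH classification *or*
  derivation from a metastasis/recurrence, whichever applies; intermediate
  risk is non-malignant (the low/intermediate stratum defines group C).
  A primary tumor without a risk label is unassignable and flagged.
* **Discordances are reported, not repaired.** Applying the rule to the
  bundled 30-case table reproduces 12 group-A and 18 malignant cases; one
  case (`p.K550_V555delinsL`, low risk, reported as group C) does not cover
  codons 557-558 and is flagged as discordant rather than silently
  reassigned.

## SV filtering and tiering

`filter_svs()` discards calls flagged IMPRECISE and calls with either
breakpoint within 100 bp of five mask tracks (segmental duplications,
microsatellites, simple repeats, low-complexity regions, blacklist).
Numerical conventions: breakpoints are 1-based point positions (no
confidence intervals), masks are BED 0-based half-open, and the 100-bp rule
is inclusive (a breakpoint exactly 100 bp from the nearest masked base is
discarded) — the conservative reading of a discard rule. Filtering is
idempotent, order-independent, and partitions its input; the distance
computation is tested against a brute-force linear scan.

`classify_sv()` maps breakend orientation to the five SV classes
(inter-chromosomal: translocation; `+/-`: deletion; `-/+`: duplication;
same-orientation: inversion; inserted sequence: insertion).
`annotate_and_tier()` reports every overlapped gene per breakpoint with
exon/intron indices and assigns tier 2 to matches against a user-supplied
curated driver list and tier 3 to SVs disrupting the coding sequence of a
tumor-suppressor gene. Tier 1 calls require a proprietary pathogenicity
database and are out of scope: the curated-list mechanism is the package's
simplification, and a multi-gene hit takes the best tier across genes.

## Context schemes and strict signature refitting

Three canonical category schemes are implemented as total functions with
enumerable category sets:

* **SBS96** — substitutions standardized to a pyrimidine center with one
  flanking base each side; purine-reference records are
  reverse-complemented, so an SNV and its reverse complement share a
  category.
* **ID83** — 1-bp insertions/deletions of C/T by homopolymer length, longer
  events by tandem-repeat unit count, and deletions with flanking
  microhomology by homology length. Indels are left-aligned before
  classification because the category depends on the flanking repeat
  structure. The length-5+ deletion group carries microhomology bins 1-5;
  shorter deletions are capped at length − 1 (full-length homology would be
  a repeat copy). This bin accounting is what makes the category count 83.
* **CN48** — allele-specific segments typed as homozygous deletion
  (3 length bins), LOH (CN levels 1/2/3-4/5-8/9+ x 5 length bins) or
  heterozygous (CN levels 2/3-4/5-8/9+ x 5 length bins): 3 + 25 + 20 = 48.
  A naive 6 x 5 x 3 cross would give 90 invalid combinations; the reduction
  above is the standard scheme consistent with 48. CN48 profiles accumulate
  segment *lengths*, optionally normalized per sample to relative length
  (the default for refitting, matching the "relative length" construction).

`fit_signatures()` is nonnegative least squares (via `pracma::lsqnonneg`)
of a profile on a column-normalized catalog, reporting the reconstruction
cosine. `fit_signatures_strict()` adds backward elimination: repeatedly
drop the signature with the smallest contribution (ties broken by catalog
column order, for determinism) and refit, stopping when a removal would
cost more than `max_delta` cosine relative to the previous accepted fit.
`max_delta = 0.004` is the published default of the strict-refitting
procedure this mirrors. Limit behaviors are pinned by tests:
`max_delta = Inf` leaves a single signature, `max_delta = 0` reproduces the
plain fit's active set. `detect_signatures()` applies the strict >5%
relative-contribution rule (5% exactly is excluded, per the printed ">").

## Arm-level CN metrics

Arm averages are length-weighted means of total CN over the arm's overlap —
the natural weighting when segments have very different sizes. Calls are
*gain* at mean >= 2.5, *loss* at <= 1.5, and *deleted* (the comparison
flag) at mean < 1.5 strictly, matching the printed "(CN: <1.5)" rule; the
gain cutoff mirrors the loss cutoff symmetrically because no printed value
exists. The ploidy score counts non-neutral autosomal arms and is invariant
to splitting segments at equal CN. The WGD flag replaces a caller-specific
annotation with a transparent rule — length-weighted genome mean CN > 3 —
consistent with describing high-ploidy samples as "ploidy > 3"; the cutoff
is configurable.

The HRD score is the sum of three counts whose exact definitions are not
restated in GIST-specific sources, so the standard published definitions
are used with every threshold exposed: LOH segments (minor CN 0, total
>= 1) longer than 15 Mb not spanning a whole chromosome; telomeric
allelic-imbalance segments (total != 2 x minor) touching a chromosome end,
not crossing the centromere, longer than 11 Mb; and large-scale state
transitions — breakpoints between adjacent >= 10 Mb segments after removing
segments < 3 Mb and merging equal-CN-state neighbors.

`compare_arm_groups()` contrasts one group against the rest per arm with a
Welch t test on per-sample arm means and a Fisher exact test on deleted
counts, optionally excluding high-ploidy samples first (arm averages of a
tetraploid genome are uninformative about deletion).

## Methylation pipeline

`filter_probes()` applies ordered exclusion steps with a provenance log:
sex-chromosome probes; TSS CpG-island probes (their removal defines the
"intergenic" probe set); low-variance probes; and a seeded uniform
subsample for clustering. The variance rule — "difference within 0.1 of the
average beta" — is read as *every* sample lying within 0.1 of the probe's
cross-sample mean; this max-deviation reading is the strictest coherent
interpretation and is pinned by tests. The original study subsampled with a
spreadsheet RAND call, which is irreproducible by construction; here the
subsample uses R's RNG with a recorded seed.

`bin_beta()` averages probes in 300-kb windows anchored at coordinate 0
(the anchor is not stated anywhere; 0 is the only canonical choice),
half-open on the position value. Clustering defaults to Euclidean distance
with average linkage — unremarkable defaults for beta-value matrices, made
explicit because the source names neither. `detect_group_hypomethylation()`
flags bins whose target-group mean beta sits at least `min_diff = 0.1`
below the remaining samples with a Welch guard at alpha = 0.05, returning a
genome-ordered track. `promoter_methylation()` is the unweighted mean beta
over a gene's TSS CpG-island probes.

## Expression statistics

`normalize_expression()` log2-transforms raw intensities and subtracts each
sample's 75th percentile (type-7 linear-interpolation quantile, the R
default, stated here because percentile conventions differ), making samples
scale-free. `signature_score()` averages normalized values over a
signature's probes per sample, then z-scores across the cohort —
mean-over-genes *then* z, the order implied by "z-scores from the mean log2
expression values"; the per-gene-z alternative changes gene weighting and
is not used. `differential_expression()` runs per-probe Welch t tests
(group A vs rest), excludes probes with zero variance on both sides from
the test and from the multiple-testing family, and adjusts with
Benjamini-Hochberg. `volcano_select()` keeps probes with |log2 FC| >= 1
(i.e. linear fold change 2; FC is a difference of log2 group means,
matching a log2-FC volcano axis) and Q < 0.05, deduplicating genes through
the probe-to-gene map. Shared statistics (`welch_t`, `fisher_exact`,
`pearson_r`) delegate to the standard R implementations; the Fisher test is
validated against full hypergeometric table enumeration in the suite.

## The synthetic cohort: what it emulates and what it does not

The generator's defaults are the study conditions: 12/6/6/6 samples in
groups A-D; group-consistent KIT mutation strings drawn from delta and
non-delta pools; negative-binomial burdens (overdispersion size 8) with
group-A means set highest; planted SBS/ID signature mixtures over bundled
synthetic catalogs (5 SBS, 3 ID, 3 CN signatures, constructed as
well-separated sparse "peaked" distributions); whole-arm deletions with
group-dependent probabilities on the 14q/22q/9p analog arms
(chr1q/chr2q/chr3p of the miniature genome); one group-A and one group-D
tetraploid sample (the study observed exactly two high-ploidy cases, one in
each of these strata); a −0.15 beta shift on 40% of autosomal 300-kb bins'
intergenic probes in group A; planted promoter hypermethylation of a
CDKN2A-analog gene in one group-A sample; and 62 planted differentially
expressed genes (|log2 shift| in [1.5, 3], SNAI2 forced to the maximal
up-shift) plus a +0.7 log2 up-shift on the three 20-gene expression
signature sets in group A.

Design choices that merit explanation:

* **Miniature genome.** Three autosomes plus one sex chromosome, 60 Mb
  each, centromere at 25 Mb. Arm-level logic needs two arms per chromosome,
  telomeres and centromeres; it does not need human scale. Acrocentric
  handling is exercised through the arm table rather than the default
  genome.
* **Mutation records carry their own context.** Materializing 240 Mb of
  sequence would dominate memory and runtime for no statistical benefit.
  SNV records store their trinucleotide (half on the purine strand, so
  classification must standardize them), and each indel record stores a
  concrete local reference context *instantiated to realize its sampled
  ID83 category* — the suite verifies that every one of the 83 categories
  round-trips through instantiation and classification. Genome-backed
  classification (`sbs96_context_genome`, `id83_context_genome`) is
  exercised on small explicit sequences.
* **Per-group burden means are free parameters.** No per-group means are
  published; the defaults (group A: 3000 SNVs / 400 indels / 70 SVs per
  sample; other groups 1100-1500 / 150 / 25-45) are desk-scale choices that
  preserve the qualitative structure: group A highest in all three types,
  total SV count near 1.3k across the cohort, and positive cross-type
  correlations.
* **Gene universe size.** 1000 gene models, so the 122 planted genes (62 DE
  + 60 signature genes) are ~12% of the universe. In a real array the
  planted fraction is far smaller still (~0.2%); what matters is that
  percentile normalization stays anchored by unperturbed genes. With a much
  smaller universe the planted up-shifts would move each group-A sample's
  75th percentile and partially cancel themselves — a desk-scale artifact,
  not a property of the method.
* **Probe manifest.** One background probe per 5 kb plus 5 probes per gene
  TSS, ~10% of the manifest flagged TSS-CGI; beta baselines are bimodal
  (promoter-CGI probes low, intergenic probes high, per-sample values
  concentrated around the probe baseline with concentration 60).
* **CN measurement noise.** Segment total CN carries N(0, 0.05) jitter so
  that per-sample arm means have sampling variance and Welch tests are
  well-posed; minor CN stays integral and classification rounds.

What the generator does **not** emulate: tumor purity and subclonality,
read-level artifacts, probe cross-hybridization, batch effects, correlated
CN/expression/methylation dosage coupling, and realistic human genome
coordinates. Passing the planted-effect recovery tests therefore shows the
*analysis machinery* is correct and well-calibrated at the study's design
points; it does not show robustness to the measurement pathologies of real
tumor data.

## Problem sizes and determinism

The default cohort (30 samples, ~60k SNVs, ~8k indels, ~1.3k SVs, ~400 CN
segments, 53k methylation probes, ~1.2k expression probes) generates in a
few seconds and the full analysis completes in well under ten minutes on a
single CPU. The test suite runs reduced configurations — lighter burdens
and a sparser methylation manifest — wherever a check does not probe those
layers at full scale; planted effect sizes, group sizes and all analysis
thresholds stay at their defaults. Every stochastic step flows from a
single integer seed: the same configuration and seed reproduce the bundle
bit for bit, and power-style checks (signature recovery in >= 95% of 50
seeds, clustering separation and score shifts in >= 90% of 20 seeds,
type-I control under null configurations) fix their seed sets in code.

## Known limitations

* Tier-1 SV annotation is intentionally absent (no public pathogenicity
  database); tier 2 depends entirely on the curated list supplied.
* The strict-refit elimination is greedy; the suite validates it against
  exhaustive subset search only at desk scale (<= 10 signatures).
* HRD thresholds are the standard published ones, not re-derived; on the
  miniature genome the absolute scores are not comparable to human-genome
  values.
* `detect_group_hypomethylation()` tests bins independently (difference
  guard + Welch p); no spatial smoothing across neighboring bins is
  attempted.
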