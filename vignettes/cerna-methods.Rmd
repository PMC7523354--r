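---
title: "Methods: ceRNA network inference and CNV-deficiency survival screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ceRNA network inference and CNV-deficiency survival screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernaweaver)
```

## The model

The competing endogenous RNA (ceRNA) hypothesis holds that transcripts
sharing miRNA-response elements compete for a common miRNA pool. Two
observable consequences drive everything this package computes: a lncRNA
and an mRNA that sponge the same miRNA should be *positively* coexpressed,
and each should be *negatively* associated with that miRNA. `cernaweaver`
operationalizes this as three reconstruction rules applied after
differential expression and target filtering:

1. a (lncRNA, mRNA) pair is coexpressed when Pearson r > 0.4 and its
   two-sided p-value is below 0.01, with p from
   $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom;
2. a coexpressed pair and a miRNA predicted to target both members form a
   triplet when both members oppose the miRNA (details below);
3. triplets are assembled into a tripartite network whose only edge types
   are lncRNA–miRNA and miRNA–mRNA.

Hub lncRNAs are ranked by a pair count: for lncRNA $L$, the number of
distinct partner miRNAs plus the number of distinct (miRNA, mRNA) pairs
over the triplets containing $L$. Restricting the miRNA–mRNA pairs to
triplets that contain $L$ makes the hub total exactly the edge count of
$L$'s first-neighbour subnetwork — an invariant the tests exercise on
every random network.

### The anti-correlation rule with disjoint cohorts

Rule 2 cannot be a matched-sample correlation when the miRNA cohorts
(arrays) and the RNA cohort (RNA-seq) contain different individuals, which
is the situation of the motivating multi-cohort design. The package's
default mode, `de_direction`, therefore tests sign opposition of fold
changes: the miRNA's log2FC must have the opposite sign to both the
lncRNA's and the mRNA's. A `matched_samples` mode implements the literal
negative-correlation reading (r < 0 for both members, with an optional
p-threshold `p_max_neg`, off by default because none is part of the rule)
for datasets that profile miRNAs and genes in the same samples. Both modes
are tested for planted-triplet recovery.

## Statistical components

**Differential expression.** The pipeline contract is only
(log2FC, p, adjusted p), so the DE statistic is a plug-in: the built-in is
a Welch two-sample *t* on log2 intensities (arrays) or on
log2(median-of-ratios-normalized count + 1) (RNA-seq), with log2FC the
tumour-minus-benign mean difference. Users with moderated-variance DE
tables (limma, DESeq2) can supply them directly to `de_filter()` and
onward; nothing downstream depends on how the table was made. Multiple
testing uses Benjamini–Hochberg, the common default of the moderated
pipelines. Median-of-ratios normalization excludes any gene with a zero
count from the geometric-mean reference (the standard convention) but
still normalizes it.

**Thresholds are strict where stated as strict.** |log2FC| > 1,
adjusted p < 0.05, r > 0.4, coexpression p < 0.01, and the univariate
screen p < 0.05 are all strict inequalities; the CNV call
seg.mean ≤ −0.3 is inclusive. Boundary unit tests pin each one
(log2FC = 1.0 excluded; a 4-programme record kept and a 3-programme
record dropped; r exactly at the cutoff excluded; seg.mean = −0.30
deficient, −0.29 not).

**Target votes.** The ≥ 4-of-7-programme rule is applied to mRNA targets
by default and optionally to lncRNAs (`apply_to`), because the published
phrasing of the rule names only the target mRNA while lncRNA prediction
programme coverage is much sparser in practice. Programme labels are
opaque strings; duplicate (miRNA, target) rows merge by programme-set
union.

**Consensus direction.** A miRNA counts toward the ≥ 2-cohort consensus
only when its direction of change agrees across the cohorts where it
passes; `require_consistent_direction = FALSE` disables this. The check
defaults on because a candidate regulator that flips sign between cohorts
is more plausibly a batch artefact than a reproducible signal.

**Enrichment.** Over-representation is the upper-tail hypergeometric
probability; `ease = TRUE` decrements the overlap by one (the
conservative variant popularized by DAVID), off by default for textbook
Fisher behaviour. The background defaults to the union of all collection
members and is overridable; with any offline background, p-values are not
comparable to those of a hosted service with a proprietary gene universe,
so published enrichment tables are treated as qualitative context only.

**Survival.** Exon and segment coordinates are treated as 1-based fully
closed (the genome-browser display convention); `half_open = TRUE`
converts 0-based half-open SEG input. Overlap is any shared base with any
exon — the most permissive reading of "deletion of these exons" — and
chromosome names are normalized across the `chr11`/`11` dialects. Cox
models use the Efron tie approximation. The Kaplan–Meier median is the
smallest event time with $S(t) \le 0.5$ (with a $10^{-9}$ tolerance on
the cumulative product); this differs from `survfit`'s convention of
averaging the two flanking times when the curve hits 0.5 exactly, and
matches the estimand used in the group-median columns. Hazard-ratio
tables are labelled HR throughout: some published tables print the same
Wald quantity under an "OR" heading, and the aliasing is deliberate to
avoid propagating it.

## The synthetic-data generator

The generator is first-class, tested code; its defaults *are* the study
conditions the package is validated under.

- **miRNA cohorts.** Three array cohorts of 8/23, 11/20 and 9/92
  benign/tumour samples (the motivating design), unit-variance Gaussian
  log2 intensities around per-miRNA baselines ~ N(7, 1.5²). Planted
  miRNAs shift **down** in tumour by `de_log2fc` (default 3) in ≥ 2
  cohorts; decoys shift in exactly one cohort and must not survive the
  consensus.
- **RNA-seq cohort.** 30 + 30 samples, 50 lncRNAs, 200 mRNAs,
  negative-binomial counts (dispersion 0.05) with log-normal baselines
  (log2 mean 9 ± 1). For each of the 10 planted triplets a latent
  per-sample miRNA activity $a$ and a shared sponge factor $s$ drive the
  two genes' log2 means with loadings chosen so the latent pair
  correlation is `sponge_rho` (0.9) and each gene–activity correlation is
  `anti_rho` (−0.8); this requires
  $\text{anti}^2 + |\text{sponge} - \text{anti}^2| \le 1$, which the
  config validator enforces. Planted genes additionally shift **up** in
  tumour by 2 log2 units so the DE filter, the sign-opposition rule and
  the coexpression rule are all exercised by the same planted objects.
  A matched miRNA matrix (activity + N(0, 0.3²) measurement noise) is
  emitted for `matched_samples` mode. Non-planted genes are null, which
  keeps the null-calibration check of the coexpression filter exact.
- **Target table.** Planted miRNA→lncRNA and miRNA→mRNA rows draw votes
  from `true_vote_range` (4–7); decoy rows (100 by default) from
  `decoy_vote_range` (1–3), so the vote filter separates them exactly at
  its default cutoff.
- **CNV and survival.** 537 patients (the motivating cohort size).
  Per gene, 15% of patients (the deficient fraction observed for the
  top hub gene in the motivating cohort) receive a segment inside a
  random exon with seg.mean ~ U(−1.2, −0.35); the rest get a copy-neutral
  segment spanning the locus. Survival is exponential with hazard
  $h_0 \exp(\beta_{\text{def}}\,\text{def}_1 + 0.3\,(\text{stage}-1))$,
  $h_0 = 0.02$/month, $\beta_{\text{def}} = \log 2$ on the *first* gene
  only; age and sex are null, so the univariate screen has exactly one
  true positive to find. Independent exponential censoring is tuned to a
  30% censoring rate (a typical oncology-registry figure; none is part
  of the motivating design).

What the generator does **not** emulate: batch effects, probe-level array
physics, isoform structure, library-size heterogeneity beyond
median-of-ratios scale factors, correlated decoy DE genes, or realistic
segment geometry. Passing the recovery tests therefore shows the
*inference machinery* is correct under the assumed generative model, not
that real cohorts will yield networks of any particular size.

## Validation design and problem sizes

- Exact oracle equivalence: correlation + p, BH, vote filter, consensus,
  network assembly, hub scores and CNV calls are each checked against
  independently coded brute-force oracles on ≥ 100 random small
  instances.
- End-to-end recovery: 25 seeded pipeline replicates (60 RNA samples, 10
  planted triplets) must reach median precision and recall ≥ 0.9.
- Null calibration: with no planted triplets, the fraction of the 10,000
  lncRNA–mRNA pairs passing r > 0.4 & p < 0.01 is compared to the
  analytic upper-tail rate $P(r > 0.4 \mid \rho = 0)$ (at n = 60 the
  r-cutoff strictly dominates the p-cutoff, so that tail *is* the joint
  rate), pooled over 5 replicates.
- Cox recovery: 100 replicates at n = 500, true HR = 2, with a
  **balanced** (50%) deficiency fraction. The balanced design is
  deliberate: it is an estimator-recovery experiment, and at the
  package-default 15% deficient fraction the Wald SE of the log-HR
  (~0.15 with ~52 deficient-group events) is too large for a ±25% band
  around HR = 2 to say anything about bias. With balance the SE is
  ~0.11 and the band corresponds to ±2 SE. Coverage of the 95% CI is
  checked in the same run. The generator default stays at 15%.
- Large-n bias: the log-HR estimate is checked for |bias| < 0.05 at
  n = 2000 over true log-HR ∈ {−0.5, 0, 0.5}.

These sizes were chosen so the whole suite runs in well under a minute on
one core while keeping every stochastic bound several Monte-Carlo
standard errors away from its threshold.

## Known limitations

- The Welch-*t* DE statistic has no variance moderation; at very small
  group sizes (n = 2–3 per group) moderated alternatives are more
  powerful, which is precisely why external DE tables can be slotted in.
- `de_direction` mode uses only fold-change signs, so it cannot
  distinguish a genuine ceRNA triplet from co-regulation that happens to
  oppose the miRNA's direction; `matched_samples` mode is stronger
  evidence when the data allow it.
- The hub score is a degree statistic; it carries no edge weights and no
  uncertainty, and ties are broken lexicographically by id.
- Deficiency calling treats any one-base overlap of any exon as a hit;
  per-exon aggregation rules (e.g. requiring all exons lost) are not
  implemented.
- Enrichment p-values depend strongly on the chosen background; defaults
  reproduce textbook Fisher behaviour, not any hosted service's universe.
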