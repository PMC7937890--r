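---
title: "Mapping Rsm protein regulons from RAP-Seq tag data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping Rsm protein regulons from RAP-Seq tag data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsmtargets)
```

## The problem

CsrA/Rsm-family proteins are small bacterial RNA-binding regulators that
repress (occasionally activate) translation by binding GGA-motif hairpins in
the 5' region of target mRNAs. *Pseudomonas putida* KT2440 carries three of
them — RsmA, RsmE and RsmI — with partly overlapping target repertoires.
Affinity purification of each tagged protein followed by sequencing of the
co-purified RNA (RAP-Seq), compared against a total-RNA control from the
same culture, identifies the transcripts bound in vivo.

`rsmtargets` implements the downstream analysis as a reusable, fully
parameterized cascade:

1. **Peak calling** (`call_peaks()`): MACS-style Poisson scoring of binned
   pulldown coverage against a local control background, per technical
   replicate, with an empirical sample-swap FDR (`empirical_fdr()`).
2. **Technical consensus** (`technical_consensus()`): only regions present in
   all three replicate extractions of a culture are kept.
3. **Cut-off selection** (`ci_lower_limit()`, `select_cutoffs()`): per-culture
   95% confidence-interval lower limits of the fold-enrichment (FE) and
   PV (`-10 log10 p`) distributions feed a reconstruction of the published
   cut-off rule.
4. **Replicate filtering** (`filter_targets()`): a target must be present in
   every biological replicate and above both cut-offs in each.
5. **Annotation** (`assign_features()`, `collapse_to_unique()`): each region
   is assigned to its RNA molecule — the summit disambiguates divergent gene
   pairs, since the libraries are unstranded — and redundant peaks within one
   molecule are collapsed.
6. **Comparison/evaluation** (`venn_partition()`, `recovery_metrics()`,
   `competition_index()`): regulon overlap structure and, on simulated data,
   recovery of the planted truth.

A synthetic-data generator (`simulation_config()` and friends) supplies the
whole cascade with inputs and ground truth, so every stage is testable
without any external download.

## The peak-calling model

Tags are 5' positions of aligned reads. Each tag is extended to a fragment of
length $d$ (default 100 nt) toward 3' on its strand, and fragments are
counted per bin of width $b$ (default 10 nt) using overlap counting, so a bin
collects fragments at a rate proportional to $b + d$. A bin with count $k$ is
scored
$$\mathrm{PV} = -10\log_{10} P(X \ge k), \qquad X \sim \mathrm{Poisson}(\lambda),$$
computed in log space (`poisson_sf_score()` stays exact to scores of several
thousand). The background $\lambda$ is the maximum of

* the genome-wide control rate,
* the control rate measured **on the candidate interval itself**, and
* control rates in windows of 1, 5 and 10 kb centered on the interval,

each scaled to the interval length and to the treatment depth (control is
scaled to treatment by the ratio of total tag counts). The interval's own
rate is not part of the classical ChIP formulation; it matters here because
the control is a transcriptome rather than flat input DNA. A sharply bounded,
abundant transcript dilutes its own background roughly three-fold inside a
1 kb window, and without the self-window every well-expressed gene scores as
"enriched" — the null condition (no planted enrichment) would produce
hundreds of false peaks instead of none.

Bins exceeding the candidate threshold (default $p < 10^{-5}$, PV > 50) are
merged when closer than the extension length; merged intervals shorter than
two bins are dropped. The summit is the position of maximal fragment pileup
(leftmost on ties); the peak's FE is the summit-bin count over its local
$\lambda$, so in expectation it estimates the *relative* enrichment
$e_f / Z$ (see below). Duplicating all tags in both libraries leaves FE
unchanged and cannot lower the score of a called peak.

The sample-swap FDR for a peak with score $s$ is
$100 \cdot \#\{\text{swapped} \ge s\} / \#\{\text{forward} \ge s\}$, where
the swapped list comes from exchanging treatment and control. The raw ratio
is not automatically monotone in $s$; the reported value takes a running
minimum over ascending scores so that a stronger peak never reports a larger
FDR than a weaker one.

## Cut-off selection

The published analysis established per-protein cut-offs "PV > 130, FE ≥ 2.15"
(RsmA), "PV > 170, FE ≥ 4" (RsmE) and "PV > 145, FE ≥ 2.5" (RsmI) from the
per-replicate confidence intervals, without stating the exact mapping rule.
The rule implemented here —

* FE cut-off: **minimum** of the per-replicate 95% CI lower limits, rounded
  down to the nearest 0.05;
* PV cut-off: **arithmetic mean** of the per-replicate limits, rounded down
  to the nearest multiple of 5 —

reproduces all six published cut-offs from the published per-replicate
limits (shipped as `reference_ci_limits()`). The rule is not uniquely
determined by six data points; both aggregation functions and both rounding
grids are arguments of `select_cutoffs()`. The confidence interval itself is
interpreted as the t-based CI of the distribution mean; a
distribution-percentile alternative is available
(`ci_lower_limit(method = "percentile")`).

Two threshold modes drive `run_pipeline()`:

* **adaptive** — the rule above, applied to the data at hand. This is
  deliberately strict: it sits near the center of the score distribution, so
  it discards a large fraction of genuine targets in exchange for
  specificity, exactly as the original analysis intended.
* **fixed** (default `FE >= 1`, `PV > 50`) — used for recovery scoring
  against planted truth, where the question is "did the cascade find what
  was planted", not "which targets clear a conservative evidence bar". With
  planted enrichments of 4–16 and a compositional normalization factor
  $Z \approx 2$, relative enrichments below ~2 are genuine targets that the
  adaptive rule would discard by construction; an FE floor of 1 separates
  them from depleted background (relative FE $\approx 1/Z < 0.6$) while the
  Poisson significance does the heavy lifting.

## The synthetic model

`simulation_config()` defaults define the desk-scale study conditions:

| quantity | default | rationale |
|---|---|---|
| genome | 500 kb, one replicon | ~1/12 of the real chromosome |
| features | 835 coding + 40 ncRNA + 3 repeat families × 3 copies + 16 pseudogenes | compact 200–500 nt genes keep per-feature depth at study-like coverage |
| divergent pairs | 30 head-to-head pairs | exercises the summit disambiguation |
| tag depths | 200k pulldown / 400k control | ~1/5 of the printed per-sample counts; with the 1/12 genome this reproduces the study's 60–76× coverage |
| replicates | RsmA 2, RsmE 3, RsmI 2 cultures × 3 technical extractions | the study's retained replicate structure |
| abundance | log-normal, sdlog 1 | standard transcriptome shape |
| enrichment | log-uniform on [4, 16] per (protein, target) | strong binders, as the strict published cut-offs presuppose |
| Venn design | singles 10/12/10, pairs 10/10/10, triple 15 | scaled-down image of the published partition; every class ≥ 10 |
| background | 5% of tag mass uniform | lets intergenic/insertion-site regions carry signal |

Decisions worth spelling out:

* **Compositional normalization.** Pulldown libraries are normalized to a
  fixed depth, so enriching some transcripts necessarily depletes the rest:
  the observable relative enrichment of a planted target is $e_f / Z$ with
  $Z = \sum_f w_f e_f / \sum_f w_f$ the abundance-weighted mean enrichment
  (`expected_relative_enrichment()` gives the closed form, and the simulator
  is tested against it). Keeping the planted fraction of the transcriptome
  small (~8% of features) keeps $Z \approx 2$ and planted targets
  detectable; this mirrors reality, where bound transcripts are a minority
  of the transcriptome mass.
* **Planted targets are expressed.** Planted units draw their abundance from
  the upper half of the abundance distribution. Pulldown enrichment is only
  observable for transcripts that are present; a planted target at the 1st
  abundance percentile would be undetectable at any realistic depth and
  would measure sequencing depth, not the cascade.
* **One transcriptome per simulation.** Abundances are drawn once; cultures
  (biological replicates) apply a small log-normal jitter (sdlog 0.05) and
  are otherwise independent tag draws. Technical extractions share 70% of
  their culture's master tag pool (`resample_fraction = 0.3`), making them
  correlated the way repeated extractions from one lysate are.
* **Repeat families.** Copies of an IS-like family are position-identical
  units. Each copy carries the same shared abundance and enrichment draw
  (every copy is independently transcribed, and multi-mapping allocation is
  symmetric), the family is planted and scored as a single target unit, and
  assignments to any copy are collapsed onto the family
  (`repeat_family_map()`).
* **Determinism.** Every library derives its RNG substream from the master
  seed by fixed-order hashing, so adding a protein or replicate never
  perturbs the others, and identical configuration and seed give
  byte-identical artifacts (hash-verified in the pipeline manifest).

What the generator does **not** model: sequence content (no FASTA/FASTQ),
rRNA depletion artifacts, library-preparation biases, positional coverage
structure within transcripts, and the quality failure that cost the study
one RsmA and one RsmI culture. Passing recovery tests therefore show that
the cascade's logic is sound under its stated noise model — not that the
pipeline is robust to every artifact of real libraries.

## Annotation choices

Libraries are unstranded, so candidate features come from both strands.
Summit containment overrides overlap length (the published disambiguator for
divergent gene pairs); pure-overlap mode is available. Equal-overlap ties
without summit containment are flagged ambiguous and keep both candidates
rather than being dropped. Peaks with no feature overlap are first-class
intergenic targets labelled with their flanking loci.

One extension beyond the classical assignment: two adjacent transcripts that
are *both* enriched merge into a single region (their significant bins are
closer than the merge gap), and a single summit can name only one of them.
`assign_features()` therefore also reports co-assigned loci — candidates the
region covers over ≥ 80% of their length and ≥ 150 nt — and
`expand_coassigned()` materializes them as targets. The thresholds come from
the extension geometry: coverage spill past an enriched feature cannot
exceed the extension length (100 nt), so an incidentally overlapped
neighbour can never satisfy both conditions, while a fully covered
runner-up is itself made of significant bins. Without this rule, adjacent
planted genes closer than ~100 nt were systematically lost with
misleadingly high enrichment.

## Numerical conventions

Internal coordinates are 0-based half-open everywhere; GFF3 I/O converts at
the boundary (1-based closed), BED tags enter at their 5' coordinate
(`start` for `+`, `end − 1` for `−`). Serialized scores are fixed at 4
decimals so outputs diff cleanly across platforms. The GFF3 writer is
deterministic (no date stamps) and emits `##sequence-region` pragmas so
annotations round-trip byte-identically. The floor-to-grid rounding in
`select_cutoffs()` guards against binary representation (2.15/0.05 must not
floor to 42). Histograms follow the upper-limit-inclusive convention of the
published figures, with a final open-ended bin.

## Problem sizes used by the test-suite

The packaged checks run the full cascade at the default desk-scale
conditions: five seeds of the three-protein recovery experiment and twenty
seeds of the single-protein null experiment (all enrichments 1), each about
ten seconds of work. At these sizes the null cascade yields zero surviving
targets and recovery stays at precision ≥ 0.9 and recall ≥ 0.9 per protein
with the planted Venn classes recovered within ±10%. The study-scale Venn
partition (241/261/206 targets, union 437, 75 shared by all three, each
pairwise class within the published 36–45 band, exactly-two total forced to
121 by inclusion–exclusion) is exercised at the set level, where it is
exact; reproducing the published *counts* from raw data would require the
archived libraries and is out of scope by design.

## Known limitations

* The cut-off mapping rule is a reconstruction constrained by six published
  values; other rules fit the same data.
* The caller has no broad-peak mode, no paired-end handling and no duplicate
  removal (simulated tags have none).
* Whether the replicate-discard rule operates on technical or biological
  replicates is ambiguous in the published description; it is implemented
  across biological replicates, which the published per-stage counts
  ("peaks in all biological replicas") support.
* Ambiguity in multi-copy repeat attribution is resolved by reporting the
  family, not by distributing evidence among copies.
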