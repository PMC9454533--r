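---
title: "Matched plasma/urine ctDNA filtering, classification and concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matched plasma/urine ctDNA filtering, classification and concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Circulating cell-free DNA (cfDNA) in blood plasma and in urine both carry
fragments shed by a tumor (ctDNA). When a patient contributes a matched
plasma and urine sample, the two somatic variant callsets can be compared:
how many variants are shared between the fluids, how many are exclusive to
one of them, and what fraction of one fluid's variants is *recovered* in the
other. This package implements that comparison as a reusable pipeline for
cohorts of matched annotated VCF pairs: a three-stage somatic variant filter
cascade, ACMG/AMP five-class impact classification, AMP/ASCO/CAP four-tier
clinical significance, VAF abundance binning, per-patient concordance with
cohort aggregation, and the nonparametric statistics used for cfDNA
concentration comparisons.

The package deliberately consumes *annotated post-calling* VCFs. Read
mapping, UMI consensus, base calling, effect prediction, population allele
frequencies and evidence codes are upstream concerns; they enter as input
tags (see `default_tag_config()`).

## The filter cascade

Variants pass three sequential filters; each removal is tagged with its
first failing criterion so attrition is reportable per stage and reason.

1. **Confidence filter** — keeps a variant iff call quality ≥ 50, VAF ≥ 3%,
   and the position does not fall into an excluded "exonically variable"
   window (consumed as a BED track, never computed here).
2. **Common-variant filter** — removes variants with population allele
   fraction > 1%, *unless* flagged as established pathogenic. A missing
   population frequency means the variant is absent from the population
   databases, which is evidence of rarity, so it is kept.
3. **Predicted-deleterious filter** — keeps variants no more than 20 bases
   into the intron that additionally satisfy at least one retention clause:
   ACMG class pathogenic / likely pathogenic / VUS, a gain- or
   loss-of-function association, an effect among frameshift, in-frame
   indel, start/stop codon change, missense or copy-number loss, a
   splice-region variant within 2 bases of the exon (splice-site loss), or
   an external splice-disruption prediction (e.g. a maximum-entropy splice
   model, consumed as a boolean flag).

All thresholds are inclusive on the keep side (quality ≥ 50, VAF ≥ 3%,
population AF ≤ 1%, offset ≤ 20). The methods wording of such cascades
("below 50", "less than 3%", ">1%") describes the removal side; the
detection condition "VAF ≥ 3%" fixes the boundary. The same classification
engine that produces the reported class distributions also drives the
deleterious filter's class clause; nothing in the inputs distinguishes two
engines, and one engine keeps the pipeline internally consistent.

## Classification

`acmg_classify()` combines ACMG/AMP 2015 evidence codes (PVS1, PS1–PS4,
PM1–PM6, PP1–PP5, BA1, BS1–BS4, BP1–BP7) with the standard combining rules
(see the function's help page for the full table). Two deliberate choices:

* **Conflicts resolve to VUS.** If a pathogenic-side and a benign-side rule
  both fire, the variant is of uncertain significance — deterministic and
  guideline-consistent.
* **Codes are inputs.** Commercial interpretation engines aggregate many in
  silico predictors into their evidence assignments; here the codes arrive
  as VCF tags and only the combining arithmetic is owned by the package.
  Per-variant agreement with any proprietary engine is therefore out of
  reach; distribution-level behaviour is what the tests check.

Tiers follow the class and the clinical evidence level: benign-side classes
are tier IV regardless of evidence; otherwise level A/B gives tier I, C/D
tier II, and no evidence tier III. This makes "tier IV ⇔ benign-side class"
an invariant, mirroring the observation that the tier III fraction tracks
the VUS fraction.

VAF abundance bins are 3–5, 5–10, 10–20, 20–50 and 50–100 percent,
left-closed half-open with the last bin closed. The conventional "3 ≤ 5%"
notation does not say where 5.0 falls; half-open bins make the five groups a
partition of [3, 100], so distribution tables always sum to the fluid total.

## Concordance

Variant identity is the normalized `(chrom, pos, ref, alt)` tuple — shared
trailing bases trimmed, then shared leading bases trimmed with the position
advanced, and an optional reference context enabling full left-alignment of
indels in repeat regions. VAF, quality and annotations are attributes, not
identity: two fluids share a *variant*, not a measurement. The
`recovery_rate()` of fluid A in fluid B is `100·|A∩B|/|A|`, undefined (and
dropped from cohort medians, not zero-filled) when the source set is empty.
Pathogenic-only recovery classifies the variant in the *source* fluid; the
matched fluid only needs to contain the key.

Cohort medians use the even-count-average convention. The per-gene table
sorts by total variant count descending with ties broken alphabetically.
The pathogenic presence matrix orders rows by the number of positive
samples, so a variant found in every sample ranks first.

## Statistics

* `spearman_rho()` — Pearson correlation of mid-ranks, p from the
  t-distribution approximation.
* `wilcoxon_signed_rank()` — two-sided; zero differences dropped; exact
  null distribution when there are fewer than 50 non-zero differences and
  no tied absolute differences, otherwise the normal approximation with tie
  and continuity correction. Published analyses of this kind rarely state
  their convention (commercial statistics packages differ in zero handling
  and continuity correction); the package documents its own and the tests
  accept a convention band rather than an exact value for the printed
  p = 0.117 concentration comparison (this package computes 0.118 on the
  same pairs, which contain one tied absolute difference).
* `chi_square_independence()` — Pearson statistic, no continuity
  correction: the use case is a 2×5 class table whose expected counts are
  all well above 1, where the Yates correction would only bias the
  statistic downward.

## The synthetic cohort generator

Sequencing-scale inputs for this pipeline cannot be shipped or recomputed
at desk scale — they require raw reads plus a commercial annotation stack.
The generator instead emits cohorts with the *statistical structure* of a
real matched TNBC cohort, so every pipeline property is testable offline:

* per-sample survivor counts log-normal around medians 66 (plasma) and 110
  (urine), log-SD 0.45 (giving a realistic 2–4× spread across patients);
* VAF drawn from the abundance-bin mixture 37/32/19/10/2% (bin chosen by
  mass, uniform within the bin);
* class proportions 5% pathogenic, 9% likely pathogenic, 85% VUS, 1%
  benign-side, realized as evidence-code templates that classify to the
  intended class;
* a `shared_fraction` of 0.47: each plasma survivor's key is independently
  planted in the matched urine sample with that probability (the observed
  plasma-in-urine recovery of ~47%);
* planted removals, each violating exactly one cascade criterion while
  satisfying every other, at configurable per-reason rates — this makes
  cascade recall/precision an *exact* check, not a statistical one;
* cfDNA concentrations log-normal with medians 172/196 ng/mL, coupled by a
  Gaussian copula with correlation −0.19 and urine zero-inflated at 2/15
  (undetectable cfDNA happens in practice).

Determinism is a contract: one cohort-level stream (seeded with the
mandatory seed) drives window placement and concentrations, and each
patient's variants come from a substream derived from `(seed, patient
index)`, so identical configurations give byte-identical file trees.

What the generator does **not** emulate: read-level error processes,
coverage and its effect on VAF accuracy, linkage between variants,
real gene coordinates (the bundled 93-gene panel uses synthetic
coordinates; only the symbol set is meaningful), gene-length bias (MUC16's
outsized share in real data; an optional per-gene weight vector can emulate
it), or evidence-code realism beyond class-consistency. Passing tests
therefore demonstrate the *pipeline's* correctness on structurally
realistic inputs — not concordance with any particular sequencing run.

## Numerical choices and degenerate inputs

* Normalization without reference context performs trimming only; with
  context it left-aligns until the anchor base differs. The canonical form
  minimizes combined allele length first, then position.
* `ref == alt` after trimming, VAF outside [0, 100], population AF outside
  [0, 1], malformed evidence codes and negative concentrations are errors
  at ingest, not silent repairs.
* Empty filter inputs yield empty outputs with zero counts; an empty
  variant source makes a recovery rate undefined rather than 0.
* Constant vectors (Spearman), all-zero difference vectors (Wilcoxon) and
  zero margins (chi-square) are errors, matching the tests' documented
  expectations.

## Problem sizes

The test suite and acceptance script run 15-patient cohorts (the scale of
the motivating study) for end-to-end checks and one 100-patient cohort for
parameter-recovery checks at tighter sampling tolerances; the classifier
equivalence check enumerates all 3,683 evidence-code subsets of size ≤ 3;
Wilcoxon exactness is verified against full 2^n sign enumeration up to
n = 10. These sizes give sampling tolerances (3 SE bands) that are
meaningful without requiring long runtimes.

## Known limitations

* Classification fidelity is distribution-level by construction: the
  package cannot reproduce a proprietary engine's per-variant calls.
* The window track, splice predictions, effects and population frequencies
  are trusted inputs; no attempt is made to recompute or sanity-check them
  against a reference genome.
* Multi-transcript annotation duplicates are not modelled; counting is per
  unique normalized key.
* The copula-based concentration model reproduces the marginal medians and
  a target rank correlation, not the full joint distribution of real
  paired concentrations.
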