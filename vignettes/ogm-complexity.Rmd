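---
title: "Curating OGM call sets and scoring genomic complexity in CLL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating OGM call sets and scoring genomic complexity in CLL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ogmcll)
```

## The problem

Optical genome mapping (OGM) calls structural variants (SVs) from
label-pattern deviations on imaged long DNA molecules and copy number
variants (CNVs) from label coverage, genome-wide in a single assay. In
chronic lymphocytic leukemia (CLL) the clinically relevant readout is
not any single call but the *number* of somatic abnormalities per
patient: genomic complexity by chromosome banding (CBA) or microarray
(CMA) — classically 3–4 abnormalities for intermediate and ≥ 5 for high
risk — predicts shorter time to first treatment (TTFT). Raw
rare-variant-pipeline exports cannot be counted directly: they contain
low-confidence calls, sub-resolution events, calls in unmappable
(peri-)centromeric or telomeric regions, benign germline polymorphisms,
CNVs fragmented into segments, the same biological event reported by
both the SV and the CNV channel, and translocation artifacts. This
package turns raw call tables into a curated, countable abnormality set,
checks it against what CBA/FISH/CMA already knew, classifies patients by
OGM complexity and relates that classification to outcome.

## The curation model

Curation is a deterministic composition of stages over a shared record
table in which every input call ends in exactly one terminal status
(`kept`, `filtered_*`, `deduplicated`, `artifact_flagged`, `rescued`);
records with status `kept` or `rescued` are countable. The order
matters and is fixed: confidence → size → regions → CNV merging → SV/CNV
deduplication → artifact flagging → optional rescue.

**Confidence prefilter.** Per-type minima follow the rare-variant
pipeline's recommended defaults: insertion 0, deletion 0, inversion
0.7, duplication −1 (i.e. all duplications pass), intra-chromosomal
translocation 0.3, inter-chromosomal translocation 0.65, CNV 0.99.
Calls are kept when confidence is *at or above* the threshold; the
boundary behavior (0.70 kept, 0.69 filtered) is documented and tested
because the sources of such defaults rarely state strict vs inclusive.

**Size filters.** Insertions, deletions, inversions and duplications are
kept at ≥ 100 Kb — chosen to make OGM counts commensurate with CMA
resolution, not because smaller calls are wrong — and CNVs at strictly
\> 500 Kb, the CNV channel's own floor ("larger than 500 Kb" read
literally). Translocations have no size.

**Region exclusion.** An SV is removed when either breakpoint falls in a
masked region (coverage-unstable, mostly pericentromeric/telomeric); a
CNV when ≥ 50% of its length is masked, since a long CNV touching a
centromere is still interpretable. Deletions, duplications and CNVs are
removed as polymorphisms when they have ≥ 70% reciprocal overlap with a
same-sign catalogued germline variant — reciprocal overlap,
min(ov/len₁, ov/len₂), is the field's standard CNV-equivalence measure
and 70% its usual stringency for database matching.

**Segmented-CNV merging.** Same-sign CNVs of one patient and chromosome
separated by ≤ 500 Kb (the CNV channel's resolution floor) are merged
into min(start)..max(end), transitively; the merge is idempotent and
order-independent, with provenance retained. 500 Kb is configurable
(`cnv_merge_gap_bp`).

**SV/CNV duplicate resolution.** The same unbalanced event is often
called twice. A CNV gain with ≥ 50% reciprocal overlap against a
duplication, or a CNV loss against a deletion, collapses onto the SV
record — SV coordinates are the more precise and are kept. A CNV loss
whose boundaries both lie within 500 Kb of the two breakpoints of an
intra-chromosomal translocation is the same event too, because the SV
caller emits interstitial deletions \> 5 Mb as intra-chromosomal
translocations; when such a translocation spans ≥ 5 Mb it is relabeled
a deletion. Ties (one CNV matching several SVs) resolve to the highest
overlap, then the smaller SV span, then lexicographic id — fixed so the
output is order-independent.

**Translocation artifact flag.** A translocation is flagged when the
*smaller* of its two per-partner label counts is ≤ 10 or the smaller raw
partner confidence is \< 10 ("at least one of the partners"). Two
quality metrics are deliberately not used: the supporting molecule
count, because genuine subclonal translocations can rest on 5–9
molecules, and the assembly chimeric score, which validated
translocations routinely fail. Flagged calls stay in the table
(status `artifact_flagged`) but are not countable.

**Targeted rescue.** Known aberrations missed by the default thresholds
can be recovered by re-running the confidence and size filters with a
permissive configuration (`permissive_curation_config()`: halved
translocation thresholds, CNV confidence 0.9, CNV size 250 Kb),
restricted to calls overlapping a known-aberration region of the same
patient. Rescue never resurrects artifact-signature translocations, and
a permissive threshold above the default is a configuration error.

**Chromothripsis.** No operational definition is standard at this data
granularity, so the package states its own and exposes both knobs: a
chromosome is flagged when it carries ≥ 10 SV breakpoints among
countable records *and* its CNV segments switch copy state ≥ 2 times
along the chromosome. The switch count interpolates a normal state in
the gaps between segments and ignores the flanks, so one long monotone
loss contributes zero switches while loss–normal–loss oscillation
contributes two or more. Both conditions together are required — many
breakpoints with a flat copy profile (e.g. balanced complexity) and
oscillation with few breakpoints both fail.

## Concordance with CBA/FISH/CMA

The known-aberration inventory keeps one entry per distinct
abnormality: CMA coordinates are authoritative for CNVs when several
techniques describe the same event; balanced rearrangements keep
karyotype breakpoints; "add" material of unknown origin contributes a
single breakpoint. Matching tolerances acknowledge resolution: a known
CNV matches a same-sign curated record at ≥ 25% reciprocal overlap *or*
both boundaries within 5 Mb (absorbing the 2–5 Mb of telomeric masking
on large CNVs); karyotype breakpoints carry a 10 Mb band-resolution
tolerance. One curated record may confirm several known entries, but
each known entry counts once in the denominator. Unmatched entries get
a reason with fixed precedence — (peri-)centromeric/telomeric
involvement, masked region, sensitivity (clone fraction \< 20%), small
(\< 150 Kb) deletion within chromothripsis, unknown — so reports are
deterministic.

Novel translocations (no inventory counterpart) are binned for manual
review: breakpoints near (≤ 5 Mb) a known CNV boundary are
`potentially_real` (putative unbalanced rearrangement under the CNV);
externally invalidated calls are `false_positive`; unsupported calls
with the artifact signature are `potential_false_positive`; unsupported
calls with clean metrics are retained as `real`, mirroring how
high-label calls are indirectly validated by whole-chromosome painting
rather than discarded.

## Complexity and statistics

Per-patient complexity is the number of countable records; deduplicated
CNVs count once through their surviving SV. The OGM scheme is two-tier
with the cutoff at ≥ 10 abnormalities (C-OGM vs NC-OGM); the CBA/CMA
schemes use 0–2 / 3–4 / ≥ 5. The combined high-risk flag is ≥ 5
abnormalities by CBA *and/or* CMA.

Statistical choices, where a convention had to be picked:

- Cohen's κ = (p_o − p_e)/(1 − p_e) with the one-sided large-sample z
  test of κ = 0 using the null-hypothesis standard error (Fleiss);
  degenerate margins (p_e = 1) are an error, not a silent NA.
- Fisher's exact test uses the two-sided "probability mass ≤ observed"
  rule (the `stats::fisher.test` convention, cross-checked in the test
  suite against direct hypergeometric enumeration); the chi-square test
  replaces it in group comparisons only when all expected counts are
  ≥ 5. An empty margin returns p = 1 with a warning.
- Spearman's ρ uses mid-ranks with the t approximation; Mann–Whitney U
  uses the exact distribution when the smaller group has ≤ 8 tie-free
  observations and the tie-corrected normal approximation otherwise.
- Kaplan–Meier medians are the smallest time with S(t) ≤ 0.5; at tied
  times events are processed before censorings. The log-rank test is
  the standard 1-df pooled-hypergeometric form.
- Harrell's C counts pairs whose order is determinable under right
  censoring (the shorter follow-up ends in an event); predictor ties
  add 0.5. Orientation is fixed so that *higher* abnormality counts
  predicting *earlier* treatment gives C \> 0.5 — the package reports
  0.7, never its mirror 0.3.

## What the synthetic generator emulates — and what it does not

`simulate_cohort()` draws per-patient truth sets (zero-truncated
negative binomial counts, mean 4 in the non-complex and 20 in the
complex group, at a 18/42 complex fraction emulating a CK-enriched
cohort; class mix matching the curated spectrum of a real cohort:
deletions 6%, inversions 0.5%, duplications 0.7%, intra-translocations
25%, inter-translocations 32%, gains 10%, losses 26%), assigns clone
fractions (major clone Beta(6,2) truncated to [0.05, 1], subclones
uniform above 2%), and observes them through platform channels:

- OGM detection is clone-fraction driven and piecewise linear: zero
  below the channel floor (5% allele fraction for SVs, 10% for CNVs),
  rising to 0.5 at 15% and to 1 at 20%. The floors and the unreliable
  15–20% band are documented platform behavior; the linear ramp between
  them is this package's modeling choice, isolated in `sim_config()`,
  since no quantitative sensitivity curve exists for that interval.
- CMA records abnormalities at ≥ 20% clone fraction; CBA passes through
  a clone-selection model (culture may over- or under-represent a
  clone) with band-resolution coordinates and ~10 Mb CNV resolution;
  FISH covers the classic CLL loci (13q14, 11q22/ATM, 17p13/TP53) down
  to a few percent of nuclei.
- Nuisance processes: breakpoint jitter, CNV segmentation with gaps
  below the merge gap, SV/CNV dual calls (rate 0.2, matching the ~20%
  dual-call fraction seen in curated data), artifact translocations
  (1.2 per patient) with the low-label/low-raw-confidence signature,
  polymorphic CNV calls at a generated germline catalogue, and
  low-confidence emission (5%) that the rescue stage can recover at
  known loci.
- Distinct true abnormalities are placed with ≥ 1 Mb of genomic
  separation (outside the deliberately clustered chromothripsis
  regions), encoding the convention that two abutting same-sign
  segments are one abnormality. TTFT is exponential with baseline
  median 43 months and hazard ratio 3 for patients with ≥ 10 true
  abnormalities, so group separation is detectable at cohort sizes of
  40–200.

Every observed call carries a truth pointer or an artifact/polymorphism
origin label, which is what `evaluate_recovery()` scores. The generator
does **not** emulate molecule-level label patterns, map assembly,
breakpoint microhomology, clonal evolution over time, CN-LOH (which the
CNV channel cannot see anyway), or realistic chromosome-specific
abnormality hotspots. Passing recovery tests therefore demonstrates
that the pipeline's logic is faithful to its stated rules under
realistic noise — not that real-cohort detection rates or C-indexes
will take any particular value.

Published point estimates that require the original cohort's clinical
tables (C-index 0.696/0.602/0.661, median TTFT 2 vs 43 months,
Spearman 0.734/0.845, the 22 Kb median boundary difference) are not
desk-reproducible; the test suite substitutes property-based checks
(oracle equivalence for matching, Fisher and the C-index; conservation,
idempotence, monotonicity and order-independence of curation; exact KM
equality with the empirical survival function without censoring) and
seeded synthetic-recovery thresholds (risk-class recovery ≥ 90% among
fully-detectable patients, artifact precision ≥ 95% at n = 200).

## Numerical and scale choices

All coordinates are 1-based inclusive on hg19 without the "chr" prefix;
BED input/output converts at the boundary. Readers validate every row
and report rejections with reasons, conserving row counts. Interval
overlap is computed with vectorized joins — cohorts here are hundreds of
calls, far below where interval trees pay off — and the test suite pins
the results to exhaustive all-pairs oracles. Problem sizes in the
default test run were chosen to exercise every code path while keeping
the suite fast: 1,000 randomized mini-cohorts (≈ 7 calls each, run as
one batch of independent patients) for the curation invariants, 100
inventory entries for the matching oracle, 20 records for the C-index
enumeration, and one 200-patient cohort for recovery. A seed-pinned
sample of several hundred 2×2 tables spanning totals up to 40 checks the
Fisher routine against full enumeration; enumerating all 135,751 such
tables adds minutes without adding coverage.

## Known limitations

- The chromothripsis rule is an operational stand-in; published
  criteria work on raw copy-number oscillation counts and breakpoint
  clustering statistics that need segment-level input this pipeline
  does not carry.
- Inventory building resolves CNV descriptions across techniques by
  overlap clustering; exotic nested or overlapping same-sign events of
  genuinely different clonal origin would be collapsed.
- The ISCN vocabulary is reduced to six abnormality classes plus "add"
  breakpoints; derivative-chromosome reconstruction is out of scope.
- Matching tolerances (25% reciprocal overlap, 5 Mb boundaries, 10 Mb
  bands) encode "the same abnormality, allowing some variability" —
  they are configurable because that phrase has no unique
  quantification.
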