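# ogmcll

Downstream analysis of optical genome mapping (OGM) call sets for genomic
complexity assessment in chronic lymphocytic leukemia (CLL).

OGM images long, fluorescently labeled DNA molecules and calls structural
variants (SVs) from label-pattern deviations and copy number variants
(CNVs) from label coverage. Raw call tables from a rare-variant pipeline
are noisy: they mix real somatic events with low-confidence calls, small
germline variants, benign polymorphisms, segmented CNV calls, duplicities
between the SV and CNV channels, and translocation artifacts. Clinical
interpretation in CLL needs a curated abnormality count per patient,
because genomic complexity — classically a complex karyotype (CK, ≥ 3
abnormalities by chromosome banding) or ≥ 5 abnormalities by banding
(CBA) or microarray (CMA) — is an adverse prognostic marker.

This package implements the full downstream path, for cytogeneticists and
computational biologists working with SMAP-like SV exports:

- **Curation** (`curate()`): per-type confidence prefilter (insertion 0,
  deletion 0, inversion 0.7, duplication −1, intra-translocation 0.3,
  inter-translocation 0.65, CNV 0.99), size filters (SVs kept at
  ≥ 100 Kb, CNVs at > 500 Kb, translocations exempt), masked-region and
  DGV-style polymorphism exclusion, segmented-CNV merging, SV/CNV
  duplicate resolution (SV coordinates win), translocation artifact
  flagging (≤ 10 labels on a partner or raw partner confidence < 10; the
  supporting-molecule count is deliberately *not* used), targeted rescue
  of known aberrations under permissive thresholds, and chromothripsis
  flagging.
- **Concordance** (`build_known_inventory()`, `match_calls()`,
  `summarize_concordance()`): matching curated records against the
  CBA/FISH/CMA-derived inventory under band-resolution tolerances, with
  discrepancy-reason assignment ((peri-)centromeric/telomeric, masked,
  sensitivity, small-within-chromothripsis).
- **Complexity** (`count_abnormalities()`, `classify_risk()`): per-patient
  countable abnormality counts; two-tier OGM classification — complex
  (C-OGM) at ≥ 10 abnormalities vs non-complex (NC-OGM) — against the
  0–2 / 3–4 / ≥ 5 CBA/CMA risk bins; Cohen's κ = (p_o − p_e)/(1 − p_e),
  Fisher exact, Spearman ρ and Mann–Whitney U statistics.
- **Survival** (`km_estimate()`, `log_rank_test()`, `c_index()`):
  Kaplan–Meier time to first treatment (TTFT), log-rank comparison of
  complexity groups, and Harrell's concordance index
  C = P(pred_i > pred_j | t_i < t_j, event_i) for abnormality counts as
  continuous predictors.
- **Synthetic cohorts** (`simulate_cohort()`, `evaluate_recovery()`):
  a truth-tracked generator with clone-fraction-driven platform
  sensitivity (SV channel floor 5%, CNV floor 10%, unreliable 15–20%
  band; CMA floor 20%; CBA clone-selection model), artifact
  translocations, polymorphisms, CNV segmentation and exponential TTFT
  with a complexity hazard ratio, so every stage is testable without
  patient data.

All user-facing functions take a data frame first and return tibbles;
fitted objects have `tidy()`/`glance()` methods and `autoplot()`/`plot_*()`
figures.

## Worked example

```r
library(ogmcll)

cohort <- simulate_cohort(sim_config(n_patients = 42), seed = 7)
cohort
#> <ogm_cohort> 42 patients, 463 true abnormalities, 382 SV + 224 CNV calls, 420 known records (seed 7)

curated <- curate(cohort$sv, cohort$cnv,
                  masks = cohort$masks,
                  polymorphisms = cohort$polymorphism_regions,
                  known = cohort$inventory,
                  permissive_cfg = permissive_curation_config())
curated
#> <ogm_curation> 606 calls: 464 countable (433 kept + 31 rescued), 52 filtered,
#>   39 deduplicated, 51 artifact-flagged
```

606 raw calls reduce to 464 countable abnormalities: 52 fail the
confidence/size/region filters, 39 CNVs are duplicates of SV-channel
calls (counted once, SV coordinates kept), and 51 translocations carry
the low-label/low-raw-confidence artifact signature. Rescue recovered 31
calls at known-aberration loci under the permissive thresholds.

```r
profiles <- count_abnormalities(curated, cohort$clinical)
dplyr::count(profiles, ogm_class)
#>   ogm_class     n
#> 1 NC_OGM       26
#> 2 C_OGM        16

conc <- summarize_concordance(match_calls(cohort$inventory, curated))
conc
#> <concordance_summary> 414/415 known abnormalities detected (99.8%)

el <- profiles[!profiles$pre_treated & !is.na(profiles$ttft_months), ]
log_rank_test(el, "ogm_class")
#>   chisq    df  p_value     n median_1 median_2
#> 1  11.3     1 0.000758    38     44.4     17.3
c_index(el, "n_ogm")
#>   c_index n_pairs     n
#> 1   0.788     425    38
```

16 of 42 simulated patients are complex by OGM (≥ 10 countable
abnormalities); 99.8% of the CBA/FISH/CMA-known aberrations are
recovered. Complex patients start treatment earlier (median TTFT 17.3 vs
44.4 months, log-rank p = 7.6 × 10⁻⁴), and the abnormality count
predicts TTFT with C = 0.79. `cohen_kappa()` on the cross-classification
against the combined CBA/CMA high-risk flag gives κ = 0.72 for this
seed.

`run_pipeline(outdir, seed = 7)` executes the same five stages end to
end, writes every stage table plus a digest manifest, and is
byte-reproducible for a fixed config and seed.

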