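# Curation stages: printed-threshold boundaries, region exclusion,
# segmented-CNV merging, SV/CNV duplicate resolution, artifact flagging,
# rescue and chromothripsis, plus the pipeline-level invariants
# (conservation, idempotence, monotonicity, order-independence).

status_of <- function(records, id) records$status[records$call_id == id]

test_that("confidence prefilter keeps calls at or above the per-type threshold", {
  sv <- make_sv(call_id = c("inv_lo", "inv_hi", "dup_neg", "int_lo", "int_hi"),
                sv_type = c("inversion", "inversion", "duplication",
                            "inter_translocation", "inter_translocation"),
                chrom1 = "2", pos1 = 1e7,
                chrom2 = c("2", "2", "2", "9", "9"),
                pos2 = c(1.2e7, 1.2e7, 1.2e7, 2e7, 2e7),
                size_bp = c(2e6, 2e6, 2e6, 0, 0),
                confidence = c(0.69, 0.70, -0.5, 0.64, 0.65))
  cnv <- make_cnv(call_id = c("cnv_lo", "cnv_hi"), start = 5e7, end = 5.1e7,
                  confidence = c(0.98, 0.99))
  rec <- prefilter_confidence(abnormality_records(sv, cnv))
  expect_equal(status_of(rec, "inv_lo"), "filtered_confidence")
  expect_equal(status_of(rec, "inv_hi"), "kept")
  expect_equal(status_of(rec, "dup_neg"), "kept")
  expect_equal(status_of(rec, "int_lo"), "filtered_confidence")
  expect_equal(status_of(rec, "int_hi"), "kept")
  expect_equal(status_of(rec, "cnv_lo"), "filtered_confidence")
  expect_equal(status_of(rec, "cnv_hi"), "kept")
  # partition is exhaustive and disjoint
  expect_true(all(rec$status %in% c("kept", "filtered_confidence")))
  bad <- abnormality_records(make_sv())
  bad$ab_class <- "mystery"
  expect_error(prefilter_confidence(bad), "mystery")
})

test_that("size filters: SVs keep-if >= 100 Kb, CNVs strict > 500 Kb, translocations exempt", {
  sv <- make_sv(call_id = c("del99", "del100", "tr0"),
                sv_type = c("deletion", "deletion", "inter_translocation"),
                chrom1 = "4", pos1 = 1e7,
                chrom2 = c("4", "4", "11"),
                pos2 = c(1e7 + 99999, 1e7 + 100000, 5e7),
                size_bp = c(99999, 100000, 0))
  cnv <- make_cnv(call_id = c("cnv500k", "cnv500k1"), start = 1,
                  end = c(500000, 500001))
  rec <- apply_size_filters(abnormality_records(sv, cnv))
  expect_equal(status_of(rec, "del99"), "filtered_size")
  expect_equal(status_of(rec, "del100"), "kept")
  expect_equal(status_of(rec, "tr0"), "kept")
  expect_equal(status_of(rec, "cnv500k"), "filtered_size")
  expect_equal(status_of(rec, "cnv500k1"), "kept")
})

test_that("masked regions remove SVs by breakpoint and CNVs by covered fraction", {
  masks <- tibble::tibble(chrom = "13", start = 1.6e7, end = 2.0e7,
                          label = "masked")
  sv <- make_sv(call_id = c("in_mask", "out_mask"),
                chrom1 = "13", pos1 = c(1.7e7, 3e7),
                chrom2 = "13", pos2 = c(2.5e7, 3.2e7))
  cnv <- make_cnv(call_id = c("cnv_60pct", "cnv_20pct"),
                  chrom = "13",
                  start = c(1.7e7, 1.9e7), end = c(2.2e7, 2.4e7))
  rec <- filter_regions(abnormality_records(sv, cnv), masks = masks)
  expect_equal(status_of(rec, "in_mask"), "filtered_masked")
  expect_equal(status_of(rec, "out_mask"), "kept")
  expect_equal(status_of(rec, "cnv_60pct"), "filtered_masked")  # 3/5 inside
  expect_equal(status_of(rec, "cnv_20pct"), "kept")             # 1/5 inside
})

test_that("polymorphism exclusion needs >= 70% reciprocal overlap and matching sign", {
  poly <- tibble::tibble(chrom = "13", start = 5.0e7, end = 5.1e7,
                         label = "polymorphism",
                         name = c("loss", "gain"))
  cnv <- make_cnv(call_id = c("loss_90", "gain_90", "loss_far"),
                  chrom = "13",
                  start = c(5.0e7, 5.0e7, 5.05e7),
                  end = c(5.09e7, 5.09e7, 5.6e7),
                  cnv_type = c("loss", "gain", "loss"))
  rec <- filter_regions(abnormality_records(cnv = cnv),
                        polymorphisms = poly)
  expect_equal(status_of(rec, "loss_90"), "filtered_polymorphism")
  expect_equal(status_of(rec, "gain_90"), "filtered_polymorphism")
  expect_equal(status_of(rec, "loss_far"), "kept")
  # sign mismatch keeps the call
  rec2 <- filter_regions(abnormality_records(cnv = cnv[2, ]),
                         polymorphisms = poly[poly$name == "loss", ])
  expect_equal(status_of(rec2, "gain_90"), "kept")
})

test_that("segmented CNVs merge transitively; brute-force union-find agrees", {
  cnv <- make_cnv(call_id = c("s1", "s2", "s3", "gain_adjacent"),
                  chrom = "13",
                  start = c(5.00e7, 5.10e7, 5.19e7, 5.28e7),
                  end = c(5.09e7, 5.18e7, 5.27e7, 5.4e7),
                  cnv_type = c("loss", "loss", "loss", "gain"))
  rec <- merge_segmented_cnvs(abnormality_records(cnv = cnv))
  survivor <- rec[rec$call_id == "s1", ]
  expect_equal(survivor$status, "kept")
  expect_equal(c(survivor$pos1, survivor$pos2), c(5.00e7, 5.27e7))
  expect_setequal(survivor$provenance[[1]], c("s1", "s2", "s3"))
  expect_equal(status_of(rec, "s2"), "deduplicated")
  expect_equal(status_of(rec, "s3"), "deduplicated")
  expect_equal(status_of(rec, "gain_adjacent"), "kept")  # sign mismatch

  # property: chain membership equals union-find closure over all pairs
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    s <- sort(round(runif(n, 1e7, 9e7)))
    e <- s + round(runif(n, 1e5, 8e6))
    cnvr <- make_cnv(call_id = sprintf("c%02d", 1:n), chrom = "5",
                     start = s, end = e, cnv_type = "loss")
    rec <- merge_segmented_cnvs(abnormality_records(cnv = cnvr))
    # brute force: union-find over all pairs with gap <= 500 Kb
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      gap <- max(s[i], s[j]) - min(e[i], e[j])
      if (gap <= 500000) parent[find(j)] <- find(i)
    }
    comp <- vapply(seq_len(n), find, integer(1))
    expected_survivors <- length(unique(comp))
    expect_equal(sum(rec$status == "kept"), expected_survivors)
    for (g in unique(comp)) {
      members <- cnvr$call_id[comp == g]
      surv <- rec[rec$call_id %in% members & rec$status == "kept", ]
      expect_equal(nrow(surv), 1)
      expect_equal(c(surv$pos1, surv$pos2),
                   c(min(s[comp == g]), max(e[comp == g])))
    }
  }
})

test_that("merging is idempotent and order-independent", {
  cnv <- make_cnv(call_id = c("a", "b", "c"), chrom = "7",
                  start = c(1e7, 1.55e7, 2.1e7),
                  end = c(1.5e7, 2.05e7, 2.6e7))
  r1 <- merge_segmented_cnvs(abnormality_records(cnv = cnv))
  r2 <- merge_segmented_cnvs(r1)
  expect_equal(r1$status, r2$status)
  perm <- merge_segmented_cnvs(abnormality_records(cnv = cnv[c(3, 1, 2), ]))
  expect_equal(dplyr::arrange(r1[c("call_id", "status", "pos1", "pos2")],
                              call_id),
               dplyr::arrange(perm[c("call_id", "status", "pos1", "pos2")],
                              call_id))
})

test_that("SV/CNV deduplication takes SV coordinates and relabels large intra-translocations", {
  sv <- make_sv(call_id = c("del1", "intra1"),
                sv_type = c("deletion", "intra_translocation"),
                chrom1 = c("13", "11"), pos1 = c(50020000, 60100000),
                chrom2 = c("13", "11"), pos2 = c(50930000, 69800000),
                size_bp = c(910001, 9700000))
  cnv <- make_cnv(call_id = c("cnvA", "cnvB", "cnvC"),
                  chrom = c("13", "11", "13"),
                  start = c(50000000, 60000000, 50000000),
                  end = c(50950000, 70000000, 50950000),
                  cnv_type = c("loss", "loss", "gain"))
  rec <- deduplicate_sv_cnv(abnormality_records(sv, cnv))
  # loss + deletion -> one record with SV coordinates
  expect_equal(status_of(rec, "cnvA"), "deduplicated")
  del <- rec[rec$call_id == "del1", ]
  expect_equal(del$source, "merged")
  expect_equal(c(del$pos1, del$pos2), c(50020000, 50930000))
  # loss + bracketing intra-translocation > 5 Mb -> relabeled deletion
  expect_equal(status_of(rec, "cnvB"), "deduplicated")
  expect_equal(rec$ab_class[rec$call_id == "intra1"], "deletion")
  # gain does not pair with a deletion (class mismatch)
  expect_equal(status_of(rec, "cnvC"), "kept")
  # conservation: rows in = rows out, merges only flip statuses
  expect_equal(nrow(rec), 5)
  expect_equal(sum(rec$status == "kept"), 3)
})

test_that("a CNV matching several SVs goes to the highest-overlap one", {
  sv <- make_sv(call_id = c("small", "big"),
                sv_type = "deletion", chrom1 = "6",
                pos1 = c(1.00e7, 1.00e7), chrom2 = "6",
                pos2 = c(1.08e7, 1.10e7), size_bp = c(8e5, 1e6))
  cnv <- make_cnv(call_id = "cnv1", chrom = "6", start = 1.0e7, end = 1.1e7)
  rec <- deduplicate_sv_cnv(abnormality_records(sv, cnv))
  expect_equal(rec$dedup_into[rec$call_id == "cnv1"], "big")
  expect_equal(status_of(rec, "small"), "kept")
})

test_that("translocation artifact flag uses min labels <= 10 or min rawconf < 10, never molecules", {
  sv <- make_sv(
    call_id = c("low_labels", "low_rawconf", "clean_few_molecules",
                "boundary_labels", "boundary_rawconf"),
    sv_type = "inter_translocation",
    chrom1 = "3", pos1 = 1e7, chrom2 = "9", pos2 = 2e7, size_bp = 0,
    confidence = 0.9,
    labels_bp1 = c(8, 12, 15, 10, 11), labels_bp2 = c(25, 25, 20, 25, 25),
    raw_conf_left = c(30, 9.5, 30, 30, 10), raw_conf_right = 30,
    self_molecules = c(40, 40, 6, 40, 40))
  rec <- flag_translocation_artifacts(abnormality_records(sv))
  expect_equal(status_of(rec, "low_labels"), "artifact_flagged")
  expect_equal(status_of(rec, "low_rawconf"), "artifact_flagged")
  expect_equal(status_of(rec, "clean_few_molecules"), "kept")
  expect_equal(status_of(rec, "boundary_labels"), "artifact_flagged")  # <= 10
  expect_equal(status_of(rec, "boundary_rawconf"), "kept")             # 10 not < 10
  expect_false(any(rec$countable[rec$status == "artifact_flagged"]))
  # missing metrics: cannot evaluate, passes with a warning
  sv_na <- make_sv(call_id = "na_metrics", sv_type = "inter_translocation",
                   chrom1 = "3", pos1 = 1e7, chrom2 = "9", pos2 = 2e7,
                   size_bp = 0, labels_bp1 = NA_real_, labels_bp2 = NA_real_,
                   raw_conf_left = NA_real_, raw_conf_right = NA_real_)
  expect_warning(rec2 <- flag_translocation_artifacts(
    abnormality_records(sv_na)), "lack label counts")
  expect_equal(status_of(rec2, "na_metrics"), "kept")
})

test_that("targeted rescue recovers known-region calls under permissive thresholds only", {
  known <- make_known(ab_id = "k11q", chrom = "11", start = 106600681,
                      end = 106991146, ab_class = "cnv_gain")
  cnv <- make_cnv(call_id = c("small_known", "small_unknown"),
                  chrom = c("11", "2"),
                  start = c(106600681, 5e7),
                  end = c(106600681 + 390465, 5e7 + 390465),
                  cnv_type = "gain")
  sv <- make_sv(call_id = "lowconf_tr", sv_type = "inter_translocation",
                chrom1 = "11", pos1 = 106700000, chrom2 = "14",
                pos2 = 1.05e8, size_bp = 0, confidence = 0.5)
  known2 <- make_known(ab_id = "ktr", ab_class = "translocation",
                       technique = "CBA", chrom = NA_character_,
                       start = NA_real_, end = NA_real_,
                       chrom1 = "11", pos1 = 106700000,
                       chrom2 = "14", pos2 = 1.05e8, bp_tolerance_bp = 1e7)
  cfg <- curation_config()
  perm <- permissive_curation_config(cfg)
  rec <- abnormality_records(sv, cnv) |>
    prefilter_confidence(cfg) |>
    apply_size_filters(cfg)
  expect_equal(status_of(rec, "small_known"), "filtered_size")
  expect_equal(status_of(rec, "lowconf_tr"), "filtered_confidence")
  out <- targeted_rescue(rec, dplyr::bind_rows(known, known2), perm, cfg)
  expect_equal(status_of(out, "small_known"), "rescued")
  expect_equal(status_of(out, "small_unknown"), "filtered_size")  # no known region
  expect_equal(status_of(out, "lowconf_tr"), "rescued")
  expect_true(all(out$countable[out$status == "rescued"]))
  # permissive thresholds must not exceed defaults
  too_high <- cfg
  too_high$conf_thresholds[["inversion"]] <- 0.9
  expect_error(targeted_rescue(rec, known, too_high, cfg), "permissive")
  # artifact-signature translocations are never rescued
  sv_art <- make_sv(call_id = "art_tr", sv_type = "inter_translocation",
                    chrom1 = "11", pos1 = 106700000, chrom2 = "14",
                    pos2 = 1.05e8, size_bp = 0, confidence = 0.5,
                    labels_bp1 = 5)
  rec_art <- abnormality_records(sv_art) |> prefilter_confidence(cfg)
  out_art <- targeted_rescue(rec_art, known2, perm, cfg)
  expect_equal(status_of(out_art, "art_tr"), "filtered_confidence")
})

test_that("chromothripsis needs many breakpoints AND oscillating copy states", {
  # 6 intra-translocations = 12 breakpoints, 3 separated losses = 4 switches
  sv <- make_sv(call_id = sprintf("t%d", 1:6), sv_type = "intra_translocation",
                chrom1 = "13", pos1 = seq(2e7, 4.5e7, length.out = 6),
                chrom2 = "13", pos2 = seq(3e7, 5.5e7, length.out = 6),
                size_bp = 1e7)
  cnv <- make_cnv(call_id = sprintf("l%d", 1:3), chrom = "13",
                  start = c(2e7, 2.5e7, 3e7), end = c(2.2e7, 2.7e7, 3.2e7))
  ct <- detect_chromothripsis(abnormality_records(sv, cnv))
  expect_true(ct$chromothripsis[ct$chrom == "13"])
  expect_equal(ct$n_breakpoints[ct$chrom == "13"], 12)
  expect_equal(ct$n_state_switches[ct$chrom == "13"], 4)
  # few breakpoints: not flagged
  ct2 <- detect_chromothripsis(abnormality_records(sv[1, ], cnv))
  expect_false(any(ct2$chromothripsis))
  # monotone single loss: 0 switches, not flagged despite 12 breakpoints
  one_loss <- make_cnv(call_id = "L", chrom = "13", start = 2e7, end = 4e7)
  ct3 <- detect_chromothripsis(abnormality_records(sv, one_loss))
  expect_equal(ct3$n_state_switches[ct3$chrom == "13"], 0)
  expect_false(any(ct3$chromothripsis))
})

test_that("curate conserves every input call with a terminal status", {
  rc <- random_calls(40, seed = 101)
  cur <- suppressWarnings(curate(rc$sv, rc$cnv))
  expect_equal(nrow(cur), nrow(rc$sv) + nrow(rc$cnv))
  expect_setequal(cur$call_id, c(rc$sv$call_id, rc$cnv$call_id))
  expect_true(all(cur$status %in% c("kept", "filtered_confidence",
                                    "filtered_size", "filtered_masked",
                                    "filtered_polymorphism", "deduplicated",
                                    "artifact_flagged", "rescued")))
  expect_equal(cur$countable, cur$status %in% c("kept", "rescued"))
  # empty input
  empty <- curate(NULL, NULL)
  expect_equal(nrow(empty), 0)
  # no-filter identity case
  sv <- make_sv(call_id = c("a", "b"), chrom1 = c("1", "2"),
                pos1 = c(2e7, 3e7), chrom2 = c("1", "2"),
                pos2 = c(2.2e7, 3.3e7))
  cur2 <- curate(sv, NULL)
  expect_true(all(cur2$countable))
})

test_that("reciprocal-overlap dedup agrees with exhaustive all-pairs brute force", {
  set.seed(77)
  for (rep in 1:10) {
    n_sv <- sample(5:15, 1)
    n_cnv <- sample(5:15, 1)
    s1 <- round(runif(n_sv, 1e7, 1.2e8))
    sv <- make_sv(call_id = sprintf("s%02d", 1:n_sv),
                  sv_type = sample(c("deletion", "duplication"), n_sv, TRUE),
                  chrom1 = "4", pos1 = s1, chrom2 = "4",
                  pos2 = s1 + round(runif(n_sv, 2e5, 2e7)))
    s2 <- round(runif(n_cnv, 1e7, 1.2e8))
    cnv <- make_cnv(call_id = sprintf("c%02d", 1:n_cnv),
                    chrom = "4", start = s2,
                    end = s2 + round(runif(n_cnv, 6e5, 2e7)),
                    cnv_type = sample(c("gain", "loss"), n_cnv, TRUE))
    rec <- deduplicate_sv_cnv(abnormality_records(sv, cnv))
    # brute force: each CNV pairs with best same-sign SV at recip >= 0.5
    for (i in seq_len(n_cnv)) {
      want <- if (cnv$cnv_type[i] == "gain") "duplication" else "deletion"
      ro <- reciprocal_overlap_test(cnv$start[i], cnv$end[i], sv$pos1,
                                    sv$pos2)
      ok <- sv$sv_type == want & ro >= 0.5
      got <- rec$status[rec$call_id == cnv$call_id[i]]
      if (any(ok)) {
        best <- order(-ro, sv$pos2 - sv$pos1, sv$call_id)
        best <- best[ok[best]][1]
        expect_equal(got, "deduplicated")
        expect_equal(rec$dedup_into[rec$call_id == cnv$call_id[i]],
                     sv$call_id[best])
      } else {
        expect_equal(got, "kept")
      }
    }
  }
})

test_that("tightening thresholds never increases the countable count", {
  rc <- random_calls(30, seed = 202)
  base_cfg <- curation_config()
  base <- suppressWarnings(curate(rc$sv, rc$cnv, cfg = base_cfg))
  for (tweak in list(
    curation_config(sv_min_size_bp = 5e5),
    curation_config(cnv_min_size_bp = 2e6),
    curation_config(conf_thresholds = c(insertion = 0.3, deletion = 0.3,
                                        inversion = 0.9, duplication = 0.3,
                                        intra_translocation = 0.6,
                                        inter_translocation = 0.9,
                                        cnv = 0.999)),
    curation_config(label_artifact_max = 20),
    curation_config(rawconf_artifact_min = 25))) {
    tightened <- suppressWarnings(curate(rc$sv, rc$cnv, cfg = tweak))
    expect_lte(sum(tightened$countable), sum(base$countable))
  }
})
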