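# Known-aberration inventory building, matching under band tolerances,
# discrepancy reasons, detection-rate summaries and novel-translocation
# classification.

curated_fixture <- function(...) {
  # wrap kept abnormality records as a curation result for match_calls
  rec <- abnormality_records(...)
  rec$ab_id <- sprintf("AB%03d", seq_len(nrow(rec)))
  rec
}

test_that("inventory prioritizes CMA coordinates and keeps technique-unique entries", {
  fish <- make_known(ab_id = "f1", technique = "FISH", ab_class = "cnv_loss",
                     chrom = "13", start = 4.95e7, end = 5.15e7)
  cma <- make_known(ab_id = "m1", technique = "CMA", ab_class = "cnv_loss",
                    chrom = "13", start = 5.00e7, end = 5.09e7)
  cba <- make_known(ab_id = "c1", technique = "CBA",
                    ab_class = "add_breakpoint", chrom = NA_character_,
                    start = NA_real_, end = NA_real_,
                    chrom1 = "8", pos1 = 1.31e8, bp_tolerance_bp = 1e7)
  inv <- build_known_inventory(cba, fish, cma)
  expect_equal(nrow(inv), 2)
  cnv_entry <- inv[inv$ab_class == "cnv_loss", ]
  expect_equal(cnv_entry$technique, "CMA")
  expect_equal(c(cnv_entry$start, cnv_entry$end), c(5.00e7, 5.09e7))
  expect_equal(inv$ab_class[inv$technique == "CBA"], "add_breakpoint")
  # trisomy with no CMA stays as the whole-chromosome gain record
  tri <- make_known(ab_id = "t1", technique = "FISH", ab_class = "trisomy",
                    chrom = "12", start = 1, end = 133851895)
  inv2 <- build_known_inventory(fish_records = tri)
  expect_equal(inv2$ab_class, "trisomy")
  # conflicting signs both retained, with a warning
  gain <- make_known(ab_id = "g1", technique = "CBA", ab_class = "cnv_gain",
                     chrom = "13", start = 4.9e7, end = 5.2e7)
  expect_warning(inv3 <- build_known_inventory(gain, fish, cma),
                 "conflicting sign")
  expect_equal(nrow(inv3[inv3$chrom == "13", ]), 2)
})

test_that("CNV matching honors sign, overlap threshold and boundary tolerance", {
  known <- make_known(ab_id = "k1", chrom = "13", start = 5.00e7,
                      end = 5.09e7)
  cur <- curated_fixture(cnv = make_cnv(call_id = "c1", chrom = "13",
                                        start = 50022000, end = 50900000))
  res <- match_calls(known, cur)
  expect_true(res$matched)
  expect_equal(res$coord_diff_bp, 22000)
  # sign mismatch: unmatched despite full overlap
  cur_gain <- curated_fixture(cnv = make_cnv(call_id = "c2", chrom = "13",
                                             start = 5.00e7, end = 5.09e7,
                                             cnv_type = "gain"))
  expect_false(match_calls(known, cur_gain)$matched)
  # a deletion SV satisfies a known loss
  cur_del <- curated_fixture(make_sv(call_id = "d1", chrom1 = "13",
                                     pos1 = 5.00e7, chrom2 = "13",
                                     pos2 = 5.09e7))
  expect_true(match_calls(known, cur_del)$matched)
})

test_that("translocations match within band tolerance; add entries need one breakpoint", {
  known <- make_known(
    ab_id = c("tr1", "add9"),
    technique = "CBA", ab_class = c("translocation", "add_breakpoint"),
    chrom = NA_character_, start = NA_real_, end = NA_real_,
    chrom1 = c("14", "9"), pos1 = c(1.06e8, 1.33e8),
    chrom2 = c("18", NA), pos2 = c(6.0e7, NA),
    bp_tolerance_bp = 1e7)
  cur <- curated_fixture(make_sv(
    call_id = c("t1", "t2"), sv_type = "inter_translocation",
    chrom1 = c("14", "3"), pos1 = c(1.05e8, 5e7),
    chrom2 = c("18", "9"), pos2 = c(6.2e7, 1.30e8), size_bp = 0))
  res <- match_calls(known, cur)
  expect_true(all(res$matched))
  # the add entry matched through the second partner of t2
  expect_equal(res$ogm_ids[res$known_id == "add9"][[1]],
               cur$ab_id[cur$call_id == "t2"])
  # outside tolerance: no match
  far <- make_known(ab_id = "far", technique = "CBA",
                    ab_class = "translocation", chrom = NA_character_,
                    start = NA_real_, end = NA_real_,
                    chrom1 = "14", pos1 = 5e7, chrom2 = "18", pos2 = 6e7,
                    bp_tolerance_bp = 1e7)
  expect_false(match_calls(far, cur)$matched)
})

test_that("match_calls agrees with an exhaustive all-pairs oracle", {
  set.seed(11)
  n_known <- 60
  pids <- sprintf("P%02d", sample(1:6, n_known, replace = TRUE))
  s <- round(runif(n_known, 1e7, 1.1e8))
  known <- make_known(ab_id = sprintf("k%02d", 1:n_known),
                      patient_id = pids,
                      chrom = sample(as.character(1:10), n_known, TRUE),
                      start = s, end = s + round(runif(n_known, 5e5, 3e7)),
                      ab_class = sample(c("cnv_loss", "cnv_gain"),
                                        n_known, TRUE))
  s2 <- round(runif(80, 1e7, 1.1e8))
  cnv <- make_cnv(call_id = sprintf("c%02d", 1:80),
                  patient_id = sprintf("P%02d", sample(1:6, 80, TRUE)),
                  chrom = sample(as.character(1:10), 80, TRUE),
                  start = s2, end = s2 + round(runif(80, 5e5, 3e7)),
                  cnv_type = sample(c("gain", "loss"), 80, TRUE))
  cur <- curated_fixture(cnv = cnv)
  crit <- match_criteria()
  res <- match_calls(known, cur, crit)
  for (i in seq_len(n_known)) {
    k <- known[i, ]
    sign <- if (k$ab_class == "cnv_gain") "gain" else "loss"
    hit <- FALSE
    for (j in seq_len(nrow(cnv))) {
      if (cnv$patient_id[j] != k$patient_id) next
      if (cnv$chrom[j] != k$chrom) next
      if (cnv$cnv_type[j] != sign) next
      ro <- reciprocal_overlap_test(k$start, k$end, cnv$start[j], cnv$end[j])
      near <- abs(cnv$start[j] - k$start) <= crit$cnv_bp_tolerance_bp &&
        abs(cnv$end[j] - k$end) <= crit$cnv_bp_tolerance_bp
      if (ro >= crit$cnv_reciprocal_overlap_min || near) hit <- TRUE
    }
    expect_equal(res$matched[i], hit)
  }
  # conservation: matched + unmatched = inventory size
  expect_equal(sum(res$matched) + sum(!res$matched), n_known)
})

test_that("matching is invariant under a constant coordinate shift", {
  known <- make_known(ab_id = "k1", chrom = "5", start = 3e7, end = 4e7)
  cnv <- make_cnv(call_id = "c1", chrom = "5", start = 3.1e7, end = 4.05e7)
  base <- match_calls(known, curated_fixture(cnv = cnv))
  shift <- 7e6
  known2 <- known
  known2$start <- known2$start + shift
  known2$end <- known2$end + shift
  cnv2 <- cnv
  cnv2$start <- cnv2$start + shift
  cnv2$end <- cnv2$end + shift
  shifted <- match_calls(known2, curated_fixture(cnv = cnv2))
  expect_equal(base$matched, shifted$matched)
  expect_equal(base$coord_diff_bp, shifted$coord_diff_bp)
})

test_that("raising tolerances never decreases the detection rate", {
  set.seed(13)
  s <- round(runif(40, 2e7, 1e8))
  known <- make_known(ab_id = sprintf("k%02d", 1:40), chrom = "2",
                      start = s, end = s + 2e6)
  cnv <- make_cnv(call_id = sprintf("c%02d", 1:40), chrom = "2",
                  start = s + round(runif(40, -8e6, 8e6)),
                  end = s + 2e6 + round(runif(40, -8e6, 8e6)))
  cnv <- cnv[cnv$end > cnv$start, ]
  cur <- curated_fixture(cnv = cnv)
  r1 <- mean(match_calls(known, cur,
                         match_criteria(cnv_bp_tolerance_bp = 2e6))$matched)
  r2 <- mean(match_calls(known, cur,
                         match_criteria(cnv_bp_tolerance_bp = 5e6))$matched)
  r3 <- mean(match_calls(known, cur,
                         match_criteria(cnv_bp_tolerance_bp = 1e7))$matched)
  expect_lte(r1, r2)
  expect_lte(r2, r3)
})

test_that("discrepancy reasons follow the fixed precedence", {
  known <- make_known(
    ab_id = c("peri", "subclonal", "small_ct", "none"),
    ab_class = c("translocation", "cnv_loss", "cnv_loss", "cnv_loss"),
    technique = c("CBA", "FISH", "CMA", "CMA"),
    chrom = c(NA, "13", "13", "6"),
    start = c(NA, 5.0e7, 9.552e7, 9e7),
    end = c(NA, 5.1e7, 9.552e7 + 137999, 9.2e7),
    chrom1 = c("13", NA, NA, NA), pos1 = c(1.79e7, NA, NA, NA),
    chrom2 = c("21", NA, NA, NA), pos2 = c(1.32e7, NA, NA, NA),
    clone_fraction = c(NA, 0.17, 0.8, 0.8))
  results <- tibble::tibble(
    known_id = known$ab_id, patient_id = "P1", ab_class = known$ab_class,
    matched = FALSE, ogm_ids = list(character(), character(), character(),
                                    character()),
    coord_diff_bp = NA_real_, discrepancy_reason = NA_character_)
  ct <- tibble::tibble(patient_id = "P1", chrom = "13",
                       n_breakpoints = 14L, n_state_switches = 4L,
                       chromothripsis = TRUE)
  out <- assign_discrepancy_reasons(results, known, chromothripsis = ct)
  expect_equal(out$discrepancy_reason,
               c("centromeric_telomeric", "sensitivity",
                 "small_within_chromothripsis", "unknown"))
})

test_that("summarize_concordance reports rates overall, by class and by stratum", {
  results <- tibble::tibble(
    known_id = sprintf("k%02d", 1:10),
    patient_id = rep(c("A", "B"), each = 5),
    ab_class = rep(c("cnv_loss", "translocation"), 5),
    matched = c(rep(TRUE, 8), FALSE, FALSE),
    ogm_ids = replicate(10, character(), simplify = FALSE),
    coord_diff_bp = NA_real_,
    discrepancy_reason = c(rep(NA, 8), "sensitivity", "unknown"))
  s <- summarize_concordance(
    results, strata = tibble::tibble(patient_id = c("A", "B"),
                                     stratum = c("non-CK", "CK")))
  expect_equal(s$overall$n_matched, 8)
  expect_equal(s$overall$detection_pct, 80)
  expect_equal(sum(s$by_class$n_known), 10)
  expect_equal(s$by_stratum$n_matched[s$by_stratum$stratum == "non-CK"], 5)
  expect_equal(sum(s$reasons$n), 2)
  expect_error(summarize_concordance(results[0, ]), "empty")
  # all matched -> 100%
  all_m <- results
  all_m$matched <- TRUE
  expect_equal(summarize_concordance(all_m)$overall$detection_pct, 100)
})

test_that("novel translocations are classified with the stated precedence", {
  known <- make_known(
    ab_id = c("ktr", "kcnv"),
    technique = c("CBA", "CMA"), ab_class = c("translocation", "cnv_loss"),
    chrom = c(NA, "4"), start = c(NA, 6e7), end = c(NA, 7e7),
    chrom1 = c("14", NA), pos1 = c(1.06e8, NA),
    chrom2 = c("18", NA), pos2 = c(6.0e7, NA), bp_tolerance_bp = 1e7)
  sv <- make_sv(
    call_id = c("known_tr", "cnv_edge_tr", "clean_unsupported", "low_label"),
    sv_type = "inter_translocation",
    chrom1 = c("14", "4", "2", "5"),
    pos1 = c(1.05e8, 6.02e7, 3e7, 9e7),
    chrom2 = c("18", "21", "7", "6"),
    pos2 = c(6.1e7, 2e7, 8e7, 1.3e8), size_bp = 0,
    labels_bp1 = c(30, 30, 30, 6))
  cur <- suppressWarnings(curate(sv, NULL))
  cls <- classify_novel_translocations(cur, known)
  got <- setNames(cls$category,
                  cur$call_id[match(cls$ogm_id, cur$ab_id)])
  expect_equal(unname(got["known_tr"]), "real")
  expect_equal(unname(got["cnv_edge_tr"]), "potentially_real")
  expect_equal(unname(got["clean_unsupported"]), "real")
  expect_equal(unname(got["low_label"]), "potential_false_positive")
  # externally invalidated calls are false positives unless known-matched
  cur2 <- cur
  cur2$invalidated <- cur2$call_id == "clean_unsupported"
  cls2 <- classify_novel_translocations(cur2, known)
  got2 <- setNames(cls2$category, cur$call_id[match(cls2$ogm_id, cur$ab_id)])
  expect_equal(unname(got2["clean_unsupported"]), "false_positive")
  # every call classified exactly once
  expect_equal(nrow(cls), 4)
})
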