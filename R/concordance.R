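# Concordance of curated OGM records with the abnormalities previously
# defined by chromosome banding (CBA), FISH and microarray (CMA): building
# the known-aberration inventory, matching under band-resolution
# tolerances, explaining misses, and classifying novel translocations.

#' Matching criteria
#'
#' Concordance allows "some variability in size or breakpoints": a known
#' CNV matches a same-sign curated record by reciprocal overlap or by
#' both boundary differences falling within `cnv_bp_tolerance_bp` (which
#' also absorbs the 2-5 Mb telomeric masking of large CNVs); karyotype
#' breakpoints are band-resolution only, hence the 10 Mb default for
#' translocations.
#'
#' @param cnv_reciprocal_overlap_min minimum reciprocal overlap for CNV
#'   matches.
#' @param cnv_bp_tolerance_bp per-boundary tolerance for CNV matches, bp.
#' @param cba_bp_tolerance_bp breakpoint tolerance for translocation
#'   matches against karyotype breakpoints, bp.
#' @param require_same_sign require gain/loss agreement for CNV matches.
#' @return A list of class `match_criteria`.
#' @export
match_criteria <- function(cnv_reciprocal_overlap_min = 0.25,
                           cnv_bp_tolerance_bp = 5e6,
                           cba_bp_tolerance_bp = 1e7,
                           require_same_sign = TRUE) {
  stopifnot(cnv_reciprocal_overlap_min > 0, cnv_reciprocal_overlap_min <= 1,
            cnv_bp_tolerance_bp >= 0, cba_bp_tolerance_bp >= 0)
  structure(list(cnv_reciprocal_overlap_min = cnv_reciprocal_overlap_min,
                 cnv_bp_tolerance_bp = cnv_bp_tolerance_bp,
                 cba_bp_tolerance_bp = cba_bp_tolerance_bp,
                 require_same_sign = require_same_sign),
            class = "match_criteria")
}

#' Build the known-aberration inventory
#'
#' Compiles per-patient records from the three standard techniques into
#' one entry per distinct abnormality: (i) for CNVs, CMA coordinates are
#' prioritized when CMA and FISH/CBA describe the same gain or loss
#' (same sign, overlapping region); FISH/CBA-only CNVs are retained;
#' (ii) balanced rearrangements keep the karyotype breakpoints; (iii)
#' "add" material of unknown origin contributes a single known
#' breakpoint. Overlapping records of conflicting sign are both retained
#' with a warning.
#'
#' @param cba_records,fish_records,cma_records known-aberration tibbles
#'   (columns as in [read_cohort()]); any may be `NULL`.
#' @return A known-aberration tibble, one row per inventory entry.
#' @export
build_known_inventory <- function(cba_records = NULL, fish_records = NULL,
                                  cma_records = NULL) {
  all_recs <- dplyr::bind_rows(cba_records, fish_records, cma_records)
  if (nrow(all_recs) == 0) return(all_recs)
  cnv_classes <- c("cnv_gain", "cnv_loss", "trisomy")
  cnv <- all_recs[all_recs$ab_class %in% cnv_classes, ]
  other <- all_recs[!all_recs$ab_class %in% cnv_classes, ]
  out_cnv <- list()
  if (nrow(cnv) > 0) {
    cnv$sign <- ifelse(cnv$ab_class %in% c("cnv_gain", "trisomy"),
                       "gain", "loss")
    groups <- cnv |>
      dplyr::group_by(.data$patient_id, .data$chrom, .data$sign) |>
      dplyr::arrange(.data$start, .data$end, .by_group = TRUE) |>
      dplyr::mutate(cluster = cumsum(
        dplyr::row_number() == 1 |
          .data$start > cummax(dplyr::lag(.data$end, default = -Inf)))) |>
      dplyr::group_by(.data$patient_id, .data$chrom, .data$sign,
                      .data$cluster)
    out_cnv <- lapply(dplyr::group_split(groups), function(grp) {
      pick <- if (any(grp$technique == "CMA")) {
        grp[grp$technique == "CMA", ][1, ]
      } else {
        grp[1, ]
      }
      pick$cluster <- NULL
      pick$sign <- NULL
      pick
    })
    # conflicting signs over one region across techniques: keep both, warn
    conflict <- cnv |>
      dplyr::inner_join(cnv, by = c("patient_id", "chrom"),
                        relationship = "many-to-many") |>
      dplyr::filter(.data$sign.x == "gain", .data$sign.y == "loss",
                    .data$start.x <= .data$end.y,
                    .data$end.x >= .data$start.y)
    if (nrow(conflict) > 0) {
      rlang::warn(sprintf(
        "%d region(s) described with conflicting sign across techniques; both entries retained",
        nrow(conflict)))
    }
  }
  out <- dplyr::bind_rows(c(out_cnv, list(other)))
  dplyr::arrange(out, .data$patient_id, .data$ab_id)
}

known_sign <- function(ab_class) {
  dplyr::case_when(ab_class %in% c("cnv_gain", "trisomy") ~ "gain",
                   ab_class == "cnv_loss" ~ "loss",
                   TRUE ~ NA_character_)
}

# candidate curated classes for a known CNV sign
curated_cnv_classes <- function(sign) {
  if (sign == "gain") c("cnv_gain", "duplication") else c("cnv_loss", "deletion")
}

match_one_cnv <- function(k, cur, crit) {
  classes <- if (crit$require_same_sign) {
    curated_cnv_classes(known_sign(k$ab_class))
  } else {
    c("cnv_gain", "cnv_loss", "duplication", "deletion")
  }
  cand <- cur[cur$ab_class %in% classes & cur$chrom1 == k$chrom &
                cur$chrom2 == k$chrom, , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  ro <- reciprocal_overlap(k$start, k$end, cand$pos1, cand$pos2)
  d1 <- abs(cand$pos1 - k$start)
  d2 <- abs(cand$pos2 - k$end)
  ok <- ro >= crit$cnv_reciprocal_overlap_min |
    (d1 <= crit$cnv_bp_tolerance_bp & d2 <= crit$cnv_bp_tolerance_bp)
  if (!any(ok)) return(NULL)
  cand <- cand[ok, , drop = FALSE]
  ord <- order(-ro[ok], pmax(d1, d2)[ok], cand$ab_id)
  list(ogm_ids = cand$ab_id[ord], coord_diff_bp = pmax(d1, d2)[ok][ord][1])
}

transloc_bp_distance <- function(k, cand) {
  # unordered breakpoint pairing; Inf when a chromosome does not match
  d <- function(kc, kp, cc, cp) {
    ifelse(!is.na(kc) & kc == cc, abs(kp - cp), Inf)
  }
  straight <- pmax(d(k$chrom1, k$pos1, cand$chrom1, cand$pos1),
                   d(k$chrom2, k$pos2, cand$chrom2, cand$pos2))
  crossed <- pmax(d(k$chrom1, k$pos1, cand$chrom2, cand$pos2),
                  d(k$chrom2, k$pos2, cand$chrom1, cand$pos1))
  pmin(straight, crossed)
}

match_one_breakpoint <- function(k, cur, crit) {
  tol <- k$bp_tolerance_bp
  if (is.na(tol)) tol <- crit$cba_bp_tolerance_bp
  classes <- if (k$ab_class == "inversion") {
    c("inversion", "intra_translocation")
  } else {
    c("intra_translocation", "inter_translocation")
  }
  cand <- cur[cur$ab_class %in% classes, , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  if (k$ab_class == "add_breakpoint") {
    # single known breakpoint: either curated partner may satisfy it
    d <- pmin(
      ifelse(cand$chrom1 == k$chrom1, abs(cand$pos1 - k$pos1), Inf),
      ifelse(cand$chrom2 == k$chrom1, abs(cand$pos2 - k$pos1), Inf))
  } else {
    d <- transloc_bp_distance(k, cand)
  }
  ok <- is.finite(d) & d <= tol
  if (!any(ok)) return(NULL)
  cand <- cand[ok, , drop = FALSE]
  ord <- order(d[ok], cand$ab_id)
  list(ogm_ids = cand$ab_id[ord], coord_diff_bp = d[ok][ord][1])
}

#' Match curated OGM records against the known inventory
#'
#' Each known entry is matched to at most the best-scoring curated record
#' of the same patient (one curated record may satisfy several known
#' entries). Known CNVs (gains, losses, trisomies) match same-sign
#' curated CNVs/deletions/duplications by reciprocal overlap or boundary
#' tolerance; translocations and inversions match when both breakpoints
#' agree within the band tolerance; "add" entries need a single
#' breakpoint. `coord_diff_bp` is the larger per-boundary difference for
#' CNV matches and the matched breakpoint distance otherwise.
#'
#' @param known known-aberration inventory (see
#'   [build_known_inventory()]).
#' @param curated an [curate()] result (only countable records are
#'   eligible).
#' @param crit a [match_criteria()].
#' @return A tibble with one row per known entry: `known_id`,
#'   `patient_id`, `ab_class`, `matched`, `ogm_ids` (list),
#'   `coord_diff_bp`, `discrepancy_reason` (filled by
#'   [assign_discrepancy_reasons()]).
#' @export
match_calls <- function(known, curated, crit = match_criteria()) {
  stopifnot(nrow(known) > 0)
  cur <- tibble::as_tibble(curated)[curated$countable, , drop = FALSE]
  res <- purrr::map(seq_len(nrow(known)), function(i) {
    k <- known[i, ]
    cur_p <- cur[cur$patient_id == k$patient_id, , drop = FALSE]
    m <- if (k$ab_class %in% c("cnv_gain", "cnv_loss", "trisomy")) {
      match_one_cnv(k, cur_p, crit)
    } else {
      match_one_breakpoint(k, cur_p, crit)
    }
    tibble::tibble(
      known_id = k$ab_id, patient_id = k$patient_id,
      ab_class = k$ab_class, matched = !is.null(m),
      ogm_ids = list(if (is.null(m)) character() else m$ogm_ids),
      coord_diff_bp = if (is.null(m)) NA_real_ else m$coord_diff_bp,
      discrepancy_reason = NA_character_)
  })
  dplyr::bind_rows(res)
}

known_breakpoints <- function(k) {
  bp <- list()
  if (!is.na(k$chrom) && !is.na(k$start)) {
    bp <- c(bp, list(c(k$chrom, k$start), c(k$chrom, k$end)))
  }
  if (!is.na(k$chrom1) && !is.na(k$pos1)) bp <- c(bp, list(c(k$chrom1, k$pos1)))
  if (!is.na(k$chrom2) && !is.na(k$pos2)) bp <- c(bp, list(c(k$chrom2, k$pos2)))
  bp
}

#' Assign discrepancy reasons to unmatched known entries
#'
#' Fixed precedence: `centromeric_telomeric` when a breakpoint lies
#' within `centrotel_dist_bp` of a centromere/telomere annotation;
#' `masked_region` when at least half of the known interval is masked;
#' `sensitivity` when the clone fraction is below 20%;
#' `small_within_chromothripsis` for events smaller than 150 Kb on a
#' chromothripsis-flagged chromosome; otherwise `unknown`.
#'
#' @param results a [match_calls()] tibble.
#' @param known the known inventory the results refer to.
#' @param annotations centromere/telomere region tibble (default
#'   [centromere_telomere_regions()]).
#' @param masks masked-region tibble (optional).
#' @param chromothripsis per patient/chromosome flags from [curate()]
#'   (attribute `chromothripsis`), optional.
#' @param centrotel_dist_bp distance defining (peri-)centromeric or
#'   telomeric involvement.
#' @param sensitivity_max_fraction clone-fraction ceiling for the
#'   `sensitivity` reason.
#' @param small_max_bp size ceiling for `small_within_chromothripsis`.
#' @return `results` with `discrepancy_reason` filled on unmatched rows.
#' @export
assign_discrepancy_reasons <- function(results, known,
                                       annotations = centromere_telomere_regions(),
                                       masks = NULL,
                                       chromothripsis = NULL,
                                       centrotel_dist_bp = 1e6,
                                       sensitivity_max_fraction = 0.20,
                                       small_max_bp = 150000) {
  ann <- annotations
  ann$start <- pmax(1, ann$start - centrotel_dist_bp)
  ann$end <- ann$end + centrotel_dist_bp
  for (i in which(!results$matched)) {
    k <- known[known$ab_id == results$known_id[i], ]
    bps <- known_breakpoints(k)
    chroms <- vapply(bps, `[`, "", 1)
    poss <- as.numeric(vapply(bps, `[`, "", 2))
    reason <- "unknown"
    size <- if (!is.na(k$start)) interval_size(k$start, k$end) else NA_real_
    ct_chroms <- if (!is.null(chromothripsis)) {
      chromothripsis$chrom[chromothripsis$chromothripsis &
                             chromothripsis$patient_id == k$patient_id]
    } else character()
    if (length(bps) > 0 && any(point_in_regions(chroms, poss, ann))) {
      reason <- "centromeric_telomeric"
    } else if (!is.null(masks) && !is.na(k$chrom) &&
                 masked_fraction(k$chrom, k$start, k$end, masks) >= 0.5) {
      reason <- "masked_region"
    } else if (!is.na(k$clone_fraction) &&
                 k$clone_fraction < sensitivity_max_fraction) {
      reason <- "sensitivity"
    } else if (!is.na(size) && size < small_max_bp &&
                 k$chrom %in% ct_chroms) {
      reason <- "small_within_chromothripsis"
    }
    results$discrepancy_reason[i] <- reason
  }
  results
}

#' Summarize concordance
#'
#' Detection rate = matched / total, overall, per known class and per
#' optional patient stratum, plus a histogram of discrepancy reasons.
#'
#' @param results a [match_calls()] tibble.
#' @param strata optional tibble `patient_id`, `stratum`.
#' @return A list of class `concordance_summary` with elements `overall`
#'   (one-row tibble: `n_known`, `n_matched`, `detection_rate`,
#'   `detection_pct`), `by_class`, `by_stratum`, `reasons`.
#' @export
summarize_concordance <- function(results, strata = NULL) {
  if (is.null(results) || nrow(results) == 0) {
    rlang::abort("empty match results: detection rate undefined")
  }
  overall <- tibble::tibble(
    n_known = nrow(results), n_matched = sum(results$matched),
    detection_rate = mean(results$matched),
    detection_pct = 100 * mean(results$matched))
  by_class <- results |>
    dplyr::group_by(.data$ab_class) |>
    dplyr::summarise(n_known = dplyr::n(), n_matched = sum(.data$matched),
                     detection_rate = mean(.data$matched), .groups = "drop")
  by_stratum <- NULL
  if (!is.null(strata)) {
    by_stratum <- results |>
      dplyr::inner_join(strata, by = "patient_id") |>
      dplyr::group_by(.data$stratum) |>
      dplyr::summarise(n_known = dplyr::n(), n_matched = sum(.data$matched),
                       detection_rate = mean(.data$matched),
                       .groups = "drop")
  }
  reasons <- results |>
    dplyr::filter(!.data$matched) |>
    dplyr::count(.data$discrepancy_reason, name = "n")
  structure(list(overall = overall, by_class = by_class,
                 by_stratum = by_stratum, reasons = reasons),
            class = "concordance_summary")
}

#' @export
glance.concordance_summary <- function(x, ...) x$overall

#' @export
tidy.concordance_summary <- function(x, ...) x$by_class

#' @export
print.concordance_summary <- function(x, ...) {
  cat(sprintf("<concordance_summary> %d/%d known abnormalities detected (%.1f%%)\n",
              x$overall$n_matched, x$overall$n_known,
              x$overall$detection_pct))
  if (nrow(x$reasons) > 0) {
    cat("discrepancy reasons:\n")
    print(x$reasons)
  }
  invisible(x)
}

#' Classify novel translocation calls
#'
#' Curated translocation calls without a known-inventory counterpart are
#' binned into the review categories used for manual follow-up:
#' `real` when matching a known translocation/add breakpoint (or, for
#' unsupported calls with clean quality metrics, retained as real the way
#' high-label calls are indirectly validated by whole-chromosome
#' painting); `potentially_real` when a breakpoint lies within
#' `cnv_bp_tolerance_bp` of a known CNV/CMA segment boundary (a putative
#' unbalanced rearrangement underlying the CNV); `false_positive` only
#' when externally invalidated (logical `invalidated` column on the
#' curated records); `potential_false_positive` for unsupported calls
#' carrying the artifact signature. Precedence: real > potentially_real >
#' false_positive > potential_false_positive.
#'
#' @param curated a [curate()] result; translocation records with status
#'   `kept`, `rescued` or `artifact_flagged` are classified.
#' @param known known-aberration inventory.
#' @param cma_segments optional CNV segment tibble (`patient_id`,
#'   `chrom`, `start`, `end`) whose boundaries also anchor
#'   `potentially_real`.
#' @param crit a [match_criteria()].
#' @return A tibble `ogm_id`, `patient_id`, `category`.
#' @export
classify_novel_translocations <- function(curated, known,
                                          cma_segments = NULL,
                                          crit = match_criteria()) {
  cur <- tibble::as_tibble(curated)
  tr <- cur[is_transloc_class(cur$ab_class) &
              cur$status %in% c("kept", "rescued", "artifact_flagged"), ,
            drop = FALSE]
  if (nrow(tr) == 0) {
    return(tibble::tibble(ogm_id = character(), patient_id = character(),
                          category = character()))
  }
  known_bp <- known[known$ab_class %in%
                      c("translocation", "inversion", "add_breakpoint"), ,
                    drop = FALSE]
  boundaries <- dplyr::bind_rows(
    known |>
      dplyr::filter(.data$ab_class %in% c("cnv_gain", "cnv_loss", "trisomy"),
                    !is.na(.data$chrom)) |>
      dplyr::select("patient_id", "chrom", "start", "end"),
    if (!is.null(cma_segments)) {
      cma_segments |> dplyr::select("patient_id", "chrom", "start", "end")
    }
  )
  categories <- vapply(seq_len(nrow(tr)), function(i) {
    rec <- tr[i, ]
    kb <- known_bp[known_bp$patient_id == rec$patient_id, , drop = FALSE]
    is_real <- FALSE
    if (nrow(kb) > 0) {
      for (j in seq_len(nrow(kb))) {
        m <- match_one_breakpoint(kb[j, ], rec, crit)
        if (!is.null(m)) {
          is_real <- TRUE
          break
        }
      }
    }
    if (is_real) return("real")
    b <- boundaries[boundaries$patient_id == rec$patient_id, , drop = FALSE]
    near_boundary <- FALSE
    if (nrow(b) > 0) {
      near_boundary <- any(
        (rec$chrom1 == b$chrom &
           (abs(rec$pos1 - b$start) <= crit$cnv_bp_tolerance_bp |
              abs(rec$pos1 - b$end) <= crit$cnv_bp_tolerance_bp)) |
          (rec$chrom2 == b$chrom &
             (abs(rec$pos2 - b$start) <= crit$cnv_bp_tolerance_bp |
                abs(rec$pos2 - b$end) <= crit$cnv_bp_tolerance_bp)))
    }
    if (near_boundary) return("potentially_real")
    if ("invalidated" %in% names(rec) && isTRUE(rec$invalidated)) {
      return("false_positive")
    }
    if (rec$status == "artifact_flagged") return("potential_false_positive")
    "real"
  }, character(1))
  tibble::tibble(ogm_id = tr$ab_id, patient_id = tr$patient_id,
                 category = categories)
}
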