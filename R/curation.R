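# Curation: raw SV/CNV call tables -> the deduplicated abnormality set
# that complexity counting operates on. Stage order: confidence prefilter,
# size filters, masked/polymorphic region exclusion, segmented-CNV
# merging, SV/CNV duplicate resolution, translocation artifact flagging,
# optional targeted rescue against the known-aberration inventory, and
# chromothripsis flagging. Every stage assigns terminal statuses to a
# shared record tibble, so each input call maps to exactly one status.

#' Curation configuration
#'
#' Thresholds follow the recommended defaults of the rare-variant pipeline
#' (Bionano Access 1.6 era) plus the manual-review conventions used for
#' CLL cohorts: per-type confidence minima (keep if confidence >=
#' threshold), SV size kept if >= 100 Kb, CNV size kept if > 500 Kb,
#' translocations exempt from size filtering; translocation calls with <=
#' 10 labels on a partner or a raw partner confidence < 10 are flagged as
#' artifacts (supporting molecule count is deliberately not used).
#'
#' @param conf_thresholds named numeric vector of per-class confidence
#'   minima; must cover the six SV types plus `cnv`.
#' @param sv_min_size_bp minimum SV size kept (inclusive), bp.
#' @param cnv_min_size_bp CNV size must exceed this (strict), bp.
#' @param label_artifact_max flag a translocation if either partner maps
#'   <= this many labels.
#' @param rawconf_artifact_min flag if either raw partner confidence is <
#'   this value.
#' @param cnv_merge_gap_bp same-sign CNV segments separated by at most
#'   this gap are merged.
#' @param dedup_bp_tolerance_bp breakpoint tolerance linking a CNV loss to
#'   an intrachromosomal translocation.
#' @param intra_reinterpret_min_bp intrachromosomal translocations at
#'   least this large whose breakpoints bracket a CNV loss are re-labeled
#'   deletions (the SV caller emits interstitial deletions > 5 Mb as
#'   intrachromosomal translocations).
#' @param mask_cnv_min_frac CNV masked-region exclusion fraction.
#' @param polymorphism_min_recip reciprocal-overlap threshold against
#'   same-sign polymorphism records.
#' @param chromothripsis_min_breakpoints,chromothripsis_min_state_switches
#'   chromothripsis rule: a chromosome is flagged iff it carries at least
#'   this many SV breakpoints and its CNV segments switch copy state at
#'   least this many times.
#' @return A list of class `curation_config`.
#' @export
curation_config <- function(conf_thresholds = c(insertion = 0, deletion = 0,
                                                inversion = 0.7,
                                                duplication = -1,
                                                intra_translocation = 0.3,
                                                inter_translocation = 0.65,
                                                cnv = 0.99),
                            sv_min_size_bp = 100000,
                            cnv_min_size_bp = 500000,
                            label_artifact_max = 10,
                            rawconf_artifact_min = 10,
                            cnv_merge_gap_bp = 500000,
                            dedup_bp_tolerance_bp = 500000,
                            intra_reinterpret_min_bp = 5e6,
                            mask_cnv_min_frac = 0.5,
                            polymorphism_min_recip = 0.7,
                            chromothripsis_min_breakpoints = 10,
                            chromothripsis_min_state_switches = 2) {
  needed <- c(SV_TYPES, "cnv")
  missing <- setdiff(needed, names(conf_thresholds))
  if (length(missing) > 0) {
    rlang::abort(paste0("conf_thresholds missing: ",
                        paste(missing, collapse = ", ")))
  }
  stopifnot(sv_min_size_bp >= 0, cnv_min_size_bp >= 0,
            label_artifact_max >= 0, cnv_merge_gap_bp >= 0,
            dedup_bp_tolerance_bp >= 0)
  structure(list(conf_thresholds = conf_thresholds,
                 sv_min_size_bp = sv_min_size_bp,
                 cnv_min_size_bp = cnv_min_size_bp,
                 label_artifact_max = label_artifact_max,
                 rawconf_artifact_min = rawconf_artifact_min,
                 cnv_merge_gap_bp = cnv_merge_gap_bp,
                 dedup_bp_tolerance_bp = dedup_bp_tolerance_bp,
                 intra_reinterpret_min_bp = intra_reinterpret_min_bp,
                 mask_cnv_min_frac = mask_cnv_min_frac,
                 polymorphism_min_recip = polymorphism_min_recip,
                 chromothripsis_min_breakpoints = chromothripsis_min_breakpoints,
                 chromothripsis_min_state_switches = chromothripsis_min_state_switches),
            class = "curation_config")
}

#' Unify SV and CNV calls into one abnormality-record tibble
#'
#' The record tibble is the working unit of curation: one row per input
#' call with a `status` column (initially `"kept"`), `countable` flag,
#' provenance (list of contributing call ids) and unified coordinates
#' (`chrom1`/`pos1`/`chrom2`/`pos2`; CNVs use their interval boundaries).
#'
#' @param sv SV call tibble (may be `NULL` or empty).
#' @param cnv CNV call tibble (may be `NULL` or empty).
#' @return An abnormality-record tibble.
#' @export
abnormality_records <- function(sv = NULL, cnv = NULL) {
  recs <- list()
  if (!is.null(sv) && nrow(sv) > 0) {
    recs$sv <- tibble::tibble(
      call_id = sv$call_id, patient_id = sv$patient_id,
      source = "sv_pipeline", ab_class = sv$sv_type,
      chrom1 = sv$chrom1, pos1 = sv$pos1,
      chrom2 = sv$chrom2, pos2 = sv$pos2,
      size_bp = dplyr::coalesce(sv$size_bp,
                                ifelse(sv$chrom1 == sv$chrom2,
                                       abs(sv$pos2 - sv$pos1), 0)),
      confidence = sv$confidence,
      raw_conf_left = sv$raw_conf_left, raw_conf_right = sv$raw_conf_right,
      labels_bp1 = sv$labels_bp1, labels_bp2 = sv$labels_bp2,
      self_molecules = sv$self_molecules,
      cell_fraction = if ("vaf" %in% names(sv)) sv$vaf else NA_real_
    )
  }
  if (!is.null(cnv) && nrow(cnv) > 0) {
    recs$cnv <- tibble::tibble(
      call_id = cnv$call_id, patient_id = cnv$patient_id,
      source = "cnv_pipeline", ab_class = paste0("cnv_", cnv$cnv_type),
      chrom1 = cnv$chrom, pos1 = cnv$start,
      chrom2 = cnv$chrom, pos2 = cnv$end,
      size_bp = interval_size(cnv$start, cnv$end),
      confidence = cnv$confidence,
      raw_conf_left = NA_real_, raw_conf_right = NA_real_,
      labels_bp1 = NA_real_, labels_bp2 = NA_real_,
      self_molecules = NA_real_,
      cell_fraction = cnv$cell_fraction
    )
  }
  out <- dplyr::bind_rows(recs)
  if (nrow(out) == 0) return(empty_records())
  out$status <- "kept"
  out$countable <- TRUE
  out$dedup_into <- NA_character_
  out$provenance <- as.list(out$call_id)
  # deterministic processing order regardless of input row order
  out <- dplyr::arrange(out, .data$patient_id,
                        match(.data$chrom1, chrom_levels()),
                        .data$pos1, .data$pos2, .data$ab_class,
                        .data$call_id)
  out
}

empty_records <- function() {
  tibble::tibble(call_id = character(), patient_id = character(),
                 source = character(), ab_class = character(),
                 chrom1 = character(), pos1 = numeric(),
                 chrom2 = character(), pos2 = numeric(), size_bp = numeric(),
                 confidence = numeric(), raw_conf_left = numeric(),
                 raw_conf_right = numeric(), labels_bp1 = numeric(),
                 labels_bp2 = numeric(), self_molecules = numeric(),
                 cell_fraction = numeric(), status = character(),
                 countable = logical(), dedup_into = character(),
                 provenance = list())
}

is_cnv_class <- function(ab_class) ab_class %in% c("cnv_gain", "cnv_loss")

is_transloc_class <- function(ab_class) {
  ab_class %in% c("intra_translocation", "inter_translocation")
}

set_status <- function(records, idx, status) {
  records$status[idx] <- status
  records$countable[idx] <- status %in% c("kept", "rescued")
  records
}

conf_threshold_for <- function(ab_class, cfg) {
  key <- ifelse(is_cnv_class(ab_class), "cnv", ab_class)
  unknown <- setdiff(unique(key), names(cfg$conf_thresholds))
  if (length(unknown) > 0) {
    rlang::abort(paste0("no confidence threshold for type: ",
                        paste(unknown, collapse = ", ")))
  }
  unname(cfg$conf_thresholds[key])
}

#' Confidence prefilter
#'
#' Keeps a call iff its confidence is at or above the per-type threshold.
#'
#' @param records abnormality-record tibble (see [abnormality_records()]).
#' @param cfg a [curation_config()].
#' @return The record tibble with `status = "filtered_confidence"` set on
#'   failing calls.
#' @export
prefilter_confidence <- function(records, cfg = curation_config()) {
  if (nrow(records) == 0) return(records)
  if (any(!is.finite(records$confidence))) {
    rlang::abort("non-finite confidence in input")
  }
  thr <- conf_threshold_for(records$ab_class, cfg)
  fail <- records$status == "kept" & records$confidence < thr
  set_status(records, fail, "filtered_confidence")
}

#' Size filters
#'
#' Insertions, deletions, inversions and duplications are kept iff their
#' size is >= `sv_min_size_bp`; CNVs iff strictly larger than
#' `cnv_min_size_bp`; translocations are exempt.
#'
#' @inheritParams prefilter_confidence
#' @export
apply_size_filters <- function(records, cfg = curation_config()) {
  if (nrow(records) == 0) return(records)
  sv_sized <- records$ab_class %in% c("insertion", "deletion", "inversion",
                                      "duplication")
  fail <- records$status == "kept" &
    ((sv_sized & records$size_bp < cfg$sv_min_size_bp) |
       (is_cnv_class(records$ab_class) &
          records$size_bp <= cfg$cnv_min_size_bp))
  set_status(records, fail, "filtered_size")
}

# bp-in-region test: TRUE where (chrom,pos) falls inside any region row
point_in_regions <- function(chrom, pos, regions) {
  if (is.null(regions) || nrow(regions) == 0) return(rep(FALSE, length(chrom)))
  q <- tibble::tibble(.i = seq_along(chrom), chrom = chrom, pos = pos)
  hit <- dplyr::inner_join(q, regions, by = "chrom",
                           relationship = "many-to-many") |>
    dplyr::filter(.data$pos >= .data$start, .data$pos <= .data$end)
  seq_along(chrom) %in% hit$.i
}

# fraction of each interval covered by the union of the regions
masked_fraction <- function(chrom, start, end, regions) {
  n <- length(chrom)
  if (is.null(regions) || nrow(regions) == 0) return(rep(0, n))
  q <- tibble::tibble(.i = seq_len(n), chrom = chrom, qs = start, qe = end)
  hits <- dplyr::inner_join(q, regions, by = "chrom",
                            relationship = "many-to-many") |>
    dplyr::mutate(os = pmax(.data$qs, .data$start),
                  oe = pmin(.data$qe, .data$end)) |>
    dplyr::filter(.data$oe >= .data$os)
  cov <- rep(0, n)
  if (nrow(hits) > 0) {
    # union length per query: sweep merged sub-intervals
    cov_tbl <- hits |>
      dplyr::group_by(.data$.i) |>
      dplyr::arrange(.data$os, .data$oe, .by_group = TRUE) |>
      dplyr::mutate(new_chain = cumsum(
        dplyr::lag(.data$oe, default = -Inf) < .data$os - 1 |
          dplyr::row_number() == 1)) |>
      dplyr::group_by(.data$.i, .data$new_chain) |>
      dplyr::summarise(len = max(.data$oe) - min(.data$os) + 1,
                       .groups = "drop") |>
      dplyr::group_by(.data$.i) |>
      dplyr::summarise(len = sum(.data$len), .groups = "drop")
    cov[cov_tbl$.i] <- cov_tbl$len
  }
  cov / interval_size(start, end)
}

sign_of_class <- function(ab_class) {
  dplyr::case_when(ab_class %in% c("deletion", "cnv_loss") ~ "loss",
                   ab_class %in% c("duplication", "cnv_gain") ~ "gain",
                   TRUE ~ NA_character_)
}

#' Masked-region and polymorphism exclusion
#'
#' A CNV is masked-filtered iff at least `mask_cnv_min_frac` of its length
#' lies within masked regions; an SV is masked-filtered iff either
#' breakpoint falls inside a masked region. A deletion/duplication/CNV is
#' polymorphism-filtered iff it has reciprocal overlap >=
#' `polymorphism_min_recip` with a same-sign polymorphism record (the
#' polymorphism set's `name` column carries "gain"/"loss"; an unnamed
#' record matches either sign).
#'
#' @inheritParams prefilter_confidence
#' @param masks,polymorphisms region tibbles from [read_bed_regions()]
#'   (or `NULL` to skip).
#' @export
filter_regions <- function(records, masks = NULL, polymorphisms = NULL,
                           cfg = curation_config()) {
  if (nrow(records) == 0) return(records)
  live <- records$status == "kept"
  cnv <- is_cnv_class(records$ab_class)
  if (!is.null(masks) && nrow(masks) > 0) {
    sv_hit <- point_in_regions(records$chrom1, records$pos1, masks) |
      point_in_regions(records$chrom2, records$pos2, masks)
    cnv_frac <- masked_fraction(records$chrom1, records$pos1, records$pos2,
                                masks)
    fail <- live & ((!cnv & sv_hit) |
                      (cnv & cnv_frac >= cfg$mask_cnv_min_frac))
    records <- set_status(records, fail, "filtered_masked")
    live <- records$status == "kept"
  }
  if (!is.null(polymorphisms) && nrow(polymorphisms) > 0) {
    sgn <- sign_of_class(records$ab_class)
    q <- tibble::tibble(.i = seq_len(nrow(records)),
                        chrom = records$chrom1, qs = records$pos1,
                        qe = records$pos2, sign = sgn)
    q <- q[live & !is.na(sgn) & records$chrom1 == records$chrom2, ]
    if (!("name" %in% names(polymorphisms))) polymorphisms$name <- NA_character_
    hits <- dplyr::inner_join(q, polymorphisms, by = "chrom",
                              relationship = "many-to-many") |>
      dplyr::filter(is.na(.data$name) | .data$name == .data$sign) |>
      dplyr::mutate(ro = reciprocal_overlap(.data$qs, .data$qe,
                                            .data$start, .data$end)) |>
      dplyr::filter(.data$ro >= cfg$polymorphism_min_recip)
    fail <- seq_len(nrow(records)) %in% hits$.i
    records <- set_status(records, fail, "filtered_polymorphism")
  }
  records
}

#' Merge segmented CNV calls
#'
#' Same-sign CNV records of one patient and chromosome separated by a gap
#' of at most `cnv_merge_gap_bp` are replaced by one record spanning
#' min(start)..max(end). The first segment (genomic order) survives and
#' carries the merged span and the full provenance; absorbed segments get
#' `status = "deduplicated"`. Merging is transitive, order-independent and
#' idempotent.
#'
#' @inheritParams prefilter_confidence
#' @export
merge_segmented_cnvs <- function(records, cfg = curation_config()) {
  if (nrow(records) == 0) return(records)
  idx <- which(records$status == "kept" & is_cnv_class(records$ab_class))
  if (length(idx) < 2) return(records)
  seg <- records[idx, ] |>
    dplyr::mutate(.i = idx) |>
    dplyr::group_by(.data$patient_id, .data$chrom1, .data$ab_class) |>
    dplyr::arrange(.data$pos1, .data$pos2, .data$call_id, .by_group = TRUE) |>
    dplyr::mutate(chain = cumsum(
      dplyr::row_number() == 1 |
        .data$pos1 - cummax(dplyr::lag(.data$pos2, default = -Inf)) >
          cfg$cnv_merge_gap_bp)) |>
    dplyr::group_by(.data$patient_id, .data$chrom1, .data$ab_class,
                    .data$chain) |>
    dplyr::filter(dplyr::n() > 1)
  if (nrow(seg) == 0) return(records)
  for (grp in dplyr::group_split(seg)) {
    if (nrow(grp) < 2) next
    keep_i <- grp$.i[1]
    drop_i <- grp$.i[-1]
    records$pos1[keep_i] <- min(grp$pos1)
    records$pos2[keep_i] <- max(grp$pos2)
    records$size_bp[keep_i] <- interval_size(min(grp$pos1), max(grp$pos2))
    records$provenance[[keep_i]] <-
      unique(c(unlist(records$provenance[grp$.i])))
    records <- set_status(records, seq_len(nrow(records)) %in% drop_i,
                          "deduplicated")
    records$dedup_into[drop_i] <- records$call_id[keep_i]
  }
  records
}

#' Resolve SV/CNV duplicities
#'
#' A CNV gain matching a kept duplication (reciprocal overlap >= 50%), or
#' a CNV loss matching a kept deletion (same rule) or an intrachromosomal
#' translocation whose breakpoints both lie within
#' `dedup_bp_tolerance_bp` of the CNV boundaries, is folded into the SV
#' record: the SV's coordinates are taken, its source becomes `"merged"`
#' and the CNV is marked `deduplicated`. Intrachromosomal translocations
#' of span >= `intra_reinterpret_min_bp` that absorb a CNV loss this way
#' are re-labeled as deletions. A CNV matching several SVs goes to the
#' highest-overlap SV (tie: smaller SV span).
#'
#' @inheritParams prefilter_confidence
#' @param min_recip reciprocal-overlap threshold defining "overlapped".
#' @export
deduplicate_sv_cnv <- function(records, cfg = curation_config(),
                               min_recip = 0.5) {
  if (nrow(records) == 0) return(records)
  live <- records$status == "kept"
  cnv_i <- which(live & is_cnv_class(records$ab_class))
  sv_i <- which(live & records$source == "sv_pipeline")
  if (length(cnv_i) == 0 || length(sv_i) == 0) return(records)
  cnv <- records[cnv_i, c("call_id", "patient_id", "ab_class", "chrom1",
                          "pos1", "pos2")] |>
    dplyr::mutate(.i = cnv_i)
  sv <- records[sv_i, c("call_id", "patient_id", "ab_class", "chrom1",
                        "pos1", "pos2")] |>
    dplyr::mutate(.j = sv_i)
  pairs <- dplyr::inner_join(cnv, sv, by = c("patient_id", "chrom1"),
                             suffix = c("_c", "_s"),
                             relationship = "many-to-many")
  if (nrow(pairs) == 0) return(records)
  pairs <- pairs |>
    dplyr::mutate(
      ro = reciprocal_overlap(.data$pos1_c, .data$pos2_c,
                              .data$pos1_s, .data$pos2_s),
      bp_linked = .data$ab_class_s == "intra_translocation" &
        .data$ab_class_c == "cnv_loss" &
        abs(.data$pos1_s - .data$pos1_c) <= cfg$dedup_bp_tolerance_bp &
        abs(.data$pos2_s - .data$pos2_c) <= cfg$dedup_bp_tolerance_bp,
      ro_match = (.data$ab_class_c == "cnv_gain" &
                    .data$ab_class_s == "duplication" &
                    .data$ro >= min_recip) |
        (.data$ab_class_c == "cnv_loss" & .data$ab_class_s == "deletion" &
           .data$ro >= min_recip),
      match = .data$ro_match | .data$bp_linked,
      sv_span = .data$pos2_s - .data$pos1_s
    ) |>
    dplyr::filter(.data$match) |>
    dplyr::group_by(.data$.i) |>
    dplyr::arrange(dplyr::desc(.data$ro), .data$sv_span, .data$call_id_s,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  if (nrow(pairs) == 0) return(records)
  for (k in seq_len(nrow(pairs))) {
    ci <- pairs$.i[k]
    sj <- pairs$.j[k]
    if (records$status[ci] != "kept") next
    records <- set_status(records, seq_len(nrow(records)) == ci,
                          "deduplicated")
    records$dedup_into[ci] <- records$call_id[sj]
    records$source[sj] <- "merged"
    records$provenance[[sj]] <- unique(c(records$provenance[[sj]],
                                         records$provenance[[ci]]))
    if (records$ab_class[sj] == "intra_translocation" &&
        pairs$bp_linked[k] &&
        (records$pos2[sj] - records$pos1[sj]) >= cfg$intra_reinterpret_min_bp) {
      records$ab_class[sj] <- "deletion"
      records$size_bp[sj] <- records$pos2[sj] - records$pos1[sj]
    }
  }
  records
}

#' Flag translocation artifacts
#'
#' A kept translocation (intra- or interchromosomal) is artifact-flagged
#' iff the smaller of its per-partner label counts is <=
#' `label_artifact_max` or the smaller raw partner confidence is <
#' `rawconf_artifact_min`. The supporting molecule count is not used: low
#' molecule support also occurs in validated subclonal translocations.
#' Records with missing label counts cannot be evaluated and pass with a
#' warning.
#'
#' @inheritParams prefilter_confidence
#' @export
flag_translocation_artifacts <- function(records, cfg = curation_config()) {
  if (nrow(records) == 0) return(records)
  tr <- records$status %in% c("kept", "rescued") &
    is_transloc_class(records$ab_class)
  min_labels <- pmin(records$labels_bp1, records$labels_bp2)
  min_rawconf <- pmin(records$raw_conf_left, records$raw_conf_right)
  not_evaluable <- tr & is.na(min_labels) & is.na(min_rawconf)
  if (any(not_evaluable)) {
    rlang::warn(sprintf(
      "%d translocation call(s) lack label counts and raw confidences; artifact rule not evaluated",
      sum(not_evaluable)))
  }
  flag <- tr & ((!is.na(min_labels) & min_labels <= cfg$label_artifact_max) |
                  (!is.na(min_rawconf) &
                     min_rawconf < cfg$rawconf_artifact_min))
  set_status(records, flag, "artifact_flagged")
}

known_regions_for_rescue <- function(known) {
  ivl <- known |>
    dplyr::filter(!is.na(.data$chrom), !is.na(.data$start), !is.na(.data$end)) |>
    dplyr::transmute(patient_id = .data$patient_id, chrom = .data$chrom,
                     start = .data$start, end = .data$end)
  tol <- dplyr::coalesce(known$bp_tolerance_bp, 1e7)
  bps <- dplyr::bind_rows(
    known |>
      dplyr::mutate(tol = tol) |>
      dplyr::filter(!is.na(.data$chrom1), !is.na(.data$pos1)) |>
      dplyr::transmute(patient_id = .data$patient_id, chrom = .data$chrom1,
                       start = pmax(1, .data$pos1 - .data$tol),
                       end = .data$pos1 + .data$tol),
    known |>
      dplyr::mutate(tol = tol) |>
      dplyr::filter(!is.na(.data$chrom2), !is.na(.data$pos2)) |>
      dplyr::transmute(patient_id = .data$patient_id, chrom = .data$chrom2,
                       start = pmax(1, .data$pos2 - .data$tol),
                       end = .data$pos2 + .data$tol)
  )
  dplyr::bind_rows(ivl, bps)
}

overlaps_known_region <- function(records, regions) {
  if (nrow(regions) == 0) return(rep(FALSE, nrow(records)))
  q <- tibble::tibble(.i = seq_len(nrow(records)),
                      patient_id = records$patient_id,
                      c1 = records$chrom1, p1 = records$pos1,
                      c2 = records$chrom2, p2 = records$pos2,
                      cnv = is_cnv_class(records$ab_class))
  hit <- dplyr::inner_join(q, regions, by = "patient_id",
                           relationship = "many-to-many") |>
    dplyr::filter(
      # interval overlap for CNV-like records on the region's chromosome
      (.data$cnv & .data$c1 == .data$chrom &
         .data$p1 <= .data$end & .data$p2 >= .data$start) |
        # either breakpoint inside the region otherwise
        (!.data$cnv & ((.data$c1 == .data$chrom & .data$p1 >= .data$start &
                          .data$p1 <= .data$end) |
                         (.data$c2 == .data$chrom & .data$p2 >= .data$start &
                            .data$p2 <= .data$end))))
  seq_len(nrow(records)) %in% hit$.i
}

#' Targeted rescue of known aberrations
#'
#' Re-runs the confidence and size filters under a permissive
#' configuration, restricted to calls that overlap a known-aberration
#' region of the same patient. Calls that pass under the permissive
#' thresholds get `status = "rescued"` and re-enter the countable set.
#' Artifact-signature translocations are never rescued.
#'
#' @inheritParams prefilter_confidence
#' @param known validated known-aberration tibble (see [read_cohort()]).
#' @param permissive_cfg a [curation_config()] with thresholds at or below
#'   the defaults in `cfg`.
#' @export
targeted_rescue <- function(records, known, permissive_cfg,
                            cfg = curation_config()) {
  if (is.null(known) || nrow(known) == 0 || nrow(records) == 0) {
    return(records)
  }
  if (any(permissive_cfg$conf_thresholds >
            cfg$conf_thresholds[names(permissive_cfg$conf_thresholds)]) ||
      permissive_cfg$sv_min_size_bp > cfg$sv_min_size_bp ||
      permissive_cfg$cnv_min_size_bp > cfg$cnv_min_size_bp) {
    rlang::abort("permissive thresholds must not exceed the defaults")
  }
  cand <- records$status %in% c("filtered_confidence", "filtered_size")
  if (!any(cand)) return(records)
  regions <- known_regions_for_rescue(known)
  in_scope <- overlaps_known_region(records, regions)
  thr <- conf_threshold_for(records$ab_class, permissive_cfg)
  sv_sized <- records$ab_class %in% c("insertion", "deletion", "inversion",
                                      "duplication")
  passes <- records$confidence >= thr &
    !(sv_sized & records$size_bp < permissive_cfg$sv_min_size_bp) &
    !(is_cnv_class(records$ab_class) &
        records$size_bp <= permissive_cfg$cnv_min_size_bp)
  artifacty <- is_transloc_class(records$ab_class) &
    ((!is.na(records$labels_bp1) &
        pmin(records$labels_bp1, records$labels_bp2) <=
          cfg$label_artifact_max) |
       (!is.na(records$raw_conf_left) &
          pmin(records$raw_conf_left, records$raw_conf_right) <
            cfg$rawconf_artifact_min))
  rescue <- cand & in_scope & passes & !artifacty
  set_status(records, rescue, "rescued")
}

#' Chromothripsis flags
#'
#' A chromosome of a patient is flagged iff it carries at least
#' `chromothripsis_min_breakpoints` SV breakpoints among curated
#' (countable) records and its CNV segments switch copy state at least
#' `chromothripsis_min_state_switches` times along the chromosome (the
#' normal state is interpolated in gaps between segments; flanks are not
#' counted, so a single un-oscillating loss contributes no switches).
#'
#' @inheritParams prefilter_confidence
#' @return A tibble with columns `patient_id`, `chrom`, `n_breakpoints`,
#'   `n_state_switches`, `chromothripsis`.
#' @export
detect_chromothripsis <- function(records, cfg = curation_config()) {
  live <- records[records$countable, , drop = FALSE]
  if (nrow(live) == 0) {
    return(tibble::tibble(patient_id = character(), chrom = character(),
                          n_breakpoints = integer(),
                          n_state_switches = integer(),
                          chromothripsis = logical()))
  }
  sv <- live[!is_cnv_class(live$ab_class), ]
  bps <- dplyr::bind_rows(
    tibble::tibble(patient_id = sv$patient_id, chrom = sv$chrom1),
    tibble::tibble(patient_id = sv$patient_id, chrom = sv$chrom2)
  ) |>
    dplyr::count(.data$patient_id, .data$chrom, name = "n_breakpoints")
  cnv <- live[is_cnv_class(live$ab_class), ]
  switches <- cnv |>
    dplyr::group_by(.data$patient_id, chrom = .data$chrom1) |>
    dplyr::arrange(.data$pos1, .by_group = TRUE) |>
    dplyr::summarise(n_state_switches = n_state_switches(
      .data$ab_class, .data$pos1, .data$pos2), .groups = "drop")
  out <- dplyr::full_join(bps, switches, by = c("patient_id", "chrom")) |>
    dplyr::mutate(
      n_breakpoints = dplyr::coalesce(.data$n_breakpoints, 0L),
      n_state_switches = dplyr::coalesce(.data$n_state_switches, 0L),
      chromothripsis = .data$n_breakpoints >=
        cfg$chromothripsis_min_breakpoints &
        .data$n_state_switches >= cfg$chromothripsis_min_state_switches)
  out
}

# copy-state switch count along one chromosome: states of the ordered CNV
# segments with "normal" interpolated in the gaps between them
n_state_switches <- function(ab_class, pos1, pos2) {
  if (length(ab_class) == 0) return(0L)
  states <- character(0)
  prev_end <- NULL
  for (k in seq_along(ab_class)) {
    if (!is.null(prev_end) && pos1[k] > prev_end + 1) {
      states <- c(states, "normal")
    }
    states <- c(states, ab_class[k])
    prev_end <- max(prev_end %||% -Inf, pos2[k])
  }
  sum(states[-1] != states[-length(states)])
}

#' Curate raw call tables
#'
#' Deterministic composition of the curation stages in order: confidence
#' prefilter, size filters, masked/polymorphic exclusion, segmented-CNV
#' merging, SV/CNV duplicate resolution, translocation artifact flagging,
#' optional targeted rescue, chromothripsis flagging. Every input call
#' appears exactly once in the output with a terminal status; records with
#' status `kept` or `rescued` are countable toward genomic complexity.
#'
#' @param sv,cnv validated call tibbles (either may be `NULL`).
#' @param masks,polymorphisms region tibbles (optional).
#' @param known known-aberration tibble enabling targeted rescue
#'   (optional).
#' @param cfg a [curation_config()].
#' @param permissive_cfg permissive [curation_config()] for rescue;
#'   `NULL` disables rescue.
#' @return An abnormality-record tibble of class `ogm_curation`, with
#'   attributes `summary` (counts by class and status), `chromothripsis`
#'   (per patient/chromosome flags) and `config`. Records are sorted and
#'   assigned stable `ab_id`s.
#' @export
curate <- function(sv = NULL, cnv = NULL, masks = NULL,
                   polymorphisms = NULL, known = NULL,
                   cfg = curation_config(), permissive_cfg = NULL) {
  records <- abnormality_records(sv, cnv) |>
    prefilter_confidence(cfg) |>
    apply_size_filters(cfg) |>
    filter_regions(masks, polymorphisms, cfg) |>
    merge_segmented_cnvs(cfg) |>
    deduplicate_sv_cnv(cfg) |>
    flag_translocation_artifacts(cfg)
  if (!is.null(known) && !is.null(permissive_cfg)) {
    records <- targeted_rescue(records, known, permissive_cfg, cfg)
  }
  records <- dplyr::arrange(records, .data$patient_id,
                            match(.data$chrom1, chrom_levels()),
                            .data$pos1, .data$pos2, .data$ab_class,
                            .data$call_id)
  records$ab_id <- sprintf("AB%05d", seq_len(nrow(records)))
  records <- records[c("ab_id", setdiff(names(records), "ab_id"))]
  ct <- detect_chromothripsis(records, cfg)
  summary <- records |>
    dplyr::count(.data$ab_class, .data$status, name = "n") |>
    dplyr::arrange(.data$ab_class, .data$status)
  structure(records, class = c("ogm_curation", class(records)),
            summary = summary, chromothripsis = ct, config = cfg)
}

#' @export
tidy.ogm_curation <- function(x, ...) {
  out <- x
  attributes(out)[c("summary", "chromothripsis", "config")] <- NULL
  class(out) <- setdiff(class(out), "ogm_curation")
  tibble::as_tibble(out)
}

#' @export
glance.ogm_curation <- function(x, ...) {
  tibble::tibble(
    n_input = nrow(x),
    n_countable = sum(x$countable),
    n_kept = sum(x$status == "kept"),
    n_rescued = sum(x$status == "rescued"),
    n_artifact_flagged = sum(x$status == "artifact_flagged"),
    n_deduplicated = sum(x$status == "deduplicated"),
    n_filtered = sum(x$status %in% c("filtered_confidence", "filtered_size",
                                     "filtered_masked",
                                     "filtered_polymorphism")),
    n_chromothripsis_chroms = sum(attr(x, "chromothripsis")$chromothripsis)
  )
}

#' @export
print.ogm_curation <- function(x, ...) {
  g <- glance.ogm_curation(x)
  cat(sprintf(
    "<ogm_curation> %d calls: %d countable (%d kept + %d rescued), %d filtered, %d deduplicated, %d artifact-flagged\n",
    g$n_input, g$n_countable, g$n_kept, g$n_rescued, g$n_filtered,
    g$n_deduplicated, g$n_artifact_flagged))
  NextMethod()
}
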