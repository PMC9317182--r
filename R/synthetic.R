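# Synthetic cohort generator: per-patient true abnormality sets with
# clonal fractions, platform-specific observed tables (OGM SV/CNV calls,
# CBA/FISH/CMA known-aberration records), artifact and polymorphism
# calls, and clinical outcomes. Every observed call carries a truth
# pointer (or an artifact/polymorphism origin label) so pipeline recovery
# can be scored exactly.

#' Simulation configuration
#'
#' Defaults emulate a 42-patient CLL cohort enriched in complex
#' karyotypes: ~43% of patients carry high complexity, true abnormality
#' counts follow zero-truncated negative binomials with means 4
#' (non-complex) and 20 (complex), and the curated class mix follows the
#' observed proportions of deletions, inversions, duplications, intra-
#' and interchromosomal translocations and CNV gains/losses. Platform
#' sensitivity is clone-fraction driven: the SV channel detects nothing
#' below a 5% allele fraction and the CNV channel nothing below 10%,
#' with detection ramping linearly through the unreliable 15-20% band to
#' certainty above it; CMA records only abnormalities present in at
#' least 20% of cells; CBA detection passes through a clone-selection
#' model in which subclones may be missed or over-represented in
#' culture. Artifact translocations carry the low-label / low raw
#' confidence signature; genuine translocations always map > 10 labels
#' with raw confidences >= 10, while their supporting molecule counts
#' follow a wide law that includes values of 5-9.
#'
#' @param n_patients cohort size.
#' @param ck_fraction fraction of patients drawn from the high-complexity
#'   group.
#' @param complexity_mean_nc,complexity_mean_ck means of the
#'   zero-truncated negative binomial abnormality counts.
#' @param complexity_size negative binomial size (dispersion) parameter.
#' @param subclone_prob probability an abnormality is subclonal rather
#'   than at the major clone fraction.
#' @param fixed_clone_fraction when non-`NULL`, every abnormality is
#'   generated at exactly this clone fraction (e.g. 1 for the noiseless
#'   fully clonal regime); otherwise major-clone fractions follow a
#'   Beta(6, 2) law truncated to [0.05, 1] with subclones uniform above
#'   0.02.
#' @param sv_detect_floor,cnv_detect_floor allele fractions below which
#'   the SV / CNV channel never emits a call.
#' @param soft_sensitivity_band clone-fraction band over which detection
#'   ramps to 1.
#' @param cma_detect_floor minimum clone fraction for a CMA record.
#' @param artifact_translocation_rate expected artifact translocations
#'   per patient (Poisson).
#' @param polymorphism_rate expected benign polymorphic CNV calls per
#'   patient (Poisson).
#' @param cnv_segmentation_prob probability a true CNV is emitted as 2-3
#'   segments.
#' @param dual_call_prob probability a CNV-class truth is additionally
#'   emitted by the SV channel (and vice versa for large SV gains/losses),
#'   creating the duplicities curation must resolve.
#' @param low_conf_prob probability an otherwise detected call is emitted
#'   below its confidence threshold (rescuable when a known aberration
#'   covers it).
#' @param chromothripsis_prob_ck probability a complex patient carries a
#'   chromothripsis chromosome (clustered breakpoints with oscillating
#'   copy states).
#' @param tp53_prob_nc,tp53_prob_ck probability of a TP53-locus deletion
#'   by group.
#' @param ttft_median_baseline_months baseline exponential median time to
#'   first treatment.
#' @param ttft_hazard_ratio_complex multiplicative hazard for patients
#'   with >= 10 true abnormalities.
#' @param censor_max_months follow-up censoring horizon (uniform).
#' @param pre_treated_prob probability a patient was treated before
#'   genetic testing (excluded from TTFT analyses downstream).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 42,
                       ck_fraction = 18 / 42,
                       complexity_mean_nc = 4,
                       complexity_mean_ck = 20,
                       complexity_size = 2.5,
                       subclone_prob = 0.25,
                       fixed_clone_fraction = NULL,
                       sv_detect_floor = 0.05,
                       cnv_detect_floor = 0.10,
                       soft_sensitivity_band = c(0.15, 0.20),
                       cma_detect_floor = 0.20,
                       artifact_translocation_rate = 1.2,
                       polymorphism_rate = 0.8,
                       cnv_segmentation_prob = 0.15,
                       dual_call_prob = 0.2,
                       low_conf_prob = 0.05,
                       chromothripsis_prob_ck = 0.4,
                       tp53_prob_nc = 0.04,
                       tp53_prob_ck = 0.5,
                       ttft_median_baseline_months = 43,
                       ttft_hazard_ratio_complex = 3,
                       censor_max_months = 95,
                       pre_treated_prob = 0.05) {
  stopifnot(n_patients >= 1, ck_fraction >= 0, ck_fraction <= 1,
            sv_detect_floor < soft_sensitivity_band[1],
            cnv_detect_floor < soft_sensitivity_band[1],
            soft_sensitivity_band[1] < soft_sensitivity_band[2],
            cnv_segmentation_prob >= 0, cnv_segmentation_prob <= 1,
            dual_call_prob >= 0, dual_call_prob <= 1,
            ttft_hazard_ratio_complex > 0)
  structure(as.list(environment()), class = "sim_config")
}

# class mix of the curated abnormality spectrum (no insertions survive
# the 100 Kb cutoff in practice)
TRUE_CLASS_PROBS <- c(deletion = 36, inversion = 3, duplication = 4,
                      intra_translocation = 142, inter_translocation = 185,
                      cnv_gain = 59, cnv_loss = 150) / 579

# piecewise-linear detection probability: 0 below the floor, 0.5 at the
# lower band edge, 1 at the upper edge
detection_probability <- function(clone_fraction, floor, band) {
  p <- ifelse(clone_fraction < floor, 0,
              ifelse(clone_fraction < band[1],
                     0.5 * (clone_fraction - floor) / (band[1] - floor),
                     ifelse(clone_fraction < band[2],
                            0.5 + 0.5 * (clone_fraction - band[1]) /
                              (band[2] - band[1]),
                            1)))
  pmin(pmax(p, 0), 1)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# uniform position on a chromosome avoiding (peri-)centromeric and
# terminal zones; returns NA when the chromosome cannot host the span
sample_position <- function(chrom_row, span) {
  avoid_lo <- chrom_row$centromere_bp - 3.5e6
  avoid_hi <- chrom_row$centromere_bp + 3.5e6
  lo <- 1.5e6
  hi <- chrom_row$length_bp - 1.5e6 - span
  if (hi <= lo) return(NA_real_)
  for (k in 1:20) {
    s <- runif(1, lo, hi)
    if (s + span < avoid_lo || s > avoid_hi) return(round(s))
  }
  NA_real_
}

sample_chrom <- function(chroms, n = 1) {
  chroms$chrom[sample.int(nrow(chroms), n, replace = TRUE,
                          prob = chroms$length_bp)]
}

rztnb <- function(n, mu, size) {
  out <- integer(n)
  for (i in seq_len(n)) {
    x <- 0L
    while (x == 0L) x <- stats::rnbinom(1, mu = mu, size = size)
    out[i] <- x
  }
  out
}

TP53_LOCUS <- list(chrom = "17", start = 7565097, end = 7590856)
FISH_LOCI <- tibble::tibble(
  locus = c("13q14", "11q22_ATM", "17p13_TP53"),
  chrom = c("13", "11", "17"),
  start = c(50000000, 108093211, 7565097),
  end = c(51000000, 108239829, 7590856))

truth_for_patient <- function(pid, complex_group, cfg, chroms) {
  n_abn <- rztnb(1, if (complex_group) cfg$complexity_mean_ck else
    cfg$complexity_mean_nc, cfg$complexity_size)
  cf_major <- clamp(rbeta(1, 6, 2), 0.05, 1)
  recs <- list()
  # placement registry: distinct abnormalities keep >= 1 Mb of genomic
  # separation so they can never be merged or deduplicated into one
  placed <- list()
  register <- function(chrom, s, e) {
    placed[[length(placed) + 1]] <<- c(chrom, s, e)
  }
  is_free <- function(chrom, s, e, margin = 1e6) {
    for (iv in placed) {
      if (iv[1] == chrom && as.numeric(iv[2]) <= e + margin &&
            as.numeric(iv[3]) >= s - margin) {
        return(FALSE)
      }
    }
    TRUE
  }
  add_rec <- function(ab_class, c1, p1, c2, p2, size, cf, chromothripsis = FALSE) {
    recs[[length(recs) + 1]] <<- tibble::tibble(
      patient_id = pid, ab_class = ab_class, chrom1 = c1, pos1 = p1,
      chrom2 = c2, pos2 = p2, size_bp = size, clone_fraction = cf,
      in_chromothripsis = chromothripsis)
  }
  if (!is.null(cfg$fixed_clone_fraction)) {
    cf_major <- cfg$fixed_clone_fraction
  }
  draw_cf <- function() {
    if (is.null(cfg$fixed_clone_fraction) &&
          runif(1) < cfg$subclone_prob) {
      runif(1, 0.02, cf_major)
    } else {
      cf_major
    }
  }
  # TP53 deletion enriched in the complex group
  if (runif(1) < (if (complex_group) cfg$tp53_prob_ck else cfg$tp53_prob_nc)) {
    size <- round(runif(1, 2e6, 9e6))
    add_rec("cnv_loss", "17", 1500000, "17", 1500000 + size - 1, size,
            cf_major)
    register("17", 1500000, 1500000 + size - 1)
    n_abn <- max(0L, n_abn - 1L)
  }
  # chromothripsis chromosome: clustered breakpoints, oscillating losses
  if (complex_group && runif(1) < cfg$chromothripsis_prob_ck) {
    ctc <- sample_chrom(chroms)
    row <- chroms[chroms$chrom == ctc, ]
    base <- sample_position(row, 3e7)
    if (!is.na(base) && is_free(ctc, base, base + 3e7)) {
      register(ctc, base, base + 3e7)
      pos <- base
      for (k in 1:3) {
        size <- round(runif(1, 6e5, 1.5e6))
        add_rec("cnv_loss", ctc, pos, ctc, pos + size - 1, size, cf_major,
                TRUE)
        pos <- pos + size + round(runif(1, 1.2e6, 3e6))
      }
      for (k in 1:6) {
        p1 <- base + round(runif(1, 0, 2.2e7))
        p2 <- p1 + round(runif(1, 5.6e6, min(1.5e7, base + 3e7 - p1)))
        add_rec("intra_translocation", ctc, p1, ctc, p2, p2 - p1, cf_major,
                TRUE)
      }
    }
  }
  classes <- sample(names(TRUE_CLASS_PROBS), n_abn, replace = TRUE,
                    prob = TRUE_CLASS_PROBS)
  for (cl in classes) {
    cf <- draw_cf()
    if (cl %in% c("cnv_gain", "cnv_loss")) {
      size <- round(clamp(rlnorm(1, log(2.5e6), 0.8), 6e5, 3e7))
      for (try in 1:10) {
        c1 <- sample_chrom(chroms)
        s <- sample_position(chroms[chroms$chrom == c1, ], size)
        if (!is.na(s) && is_free(c1, s, s + size - 1)) {
          add_rec(cl, c1, s, c1, s + size - 1, size, cf)
          register(c1, s, s + size - 1)
          break
        }
      }
    } else if (cl %in% c("deletion", "duplication", "inversion")) {
      size <- round(clamp(rlnorm(1, log(4e5), 0.7), 1.1e5, 4.8e6))
      for (try in 1:10) {
        c1 <- sample_chrom(chroms)
        s <- sample_position(chroms[chroms$chrom == c1, ], size)
        if (!is.na(s) && is_free(c1, s, s + size - 1)) {
          add_rec(cl, c1, s, c1, s + size - 1, size, cf)
          register(c1, s, s + size - 1)
          break
        }
      }
    } else if (cl == "intra_translocation") {
      span <- round(clamp(rlnorm(1, log(2e7), 0.6), 5.6e6, 8e7))
      for (try in 1:10) {
        c1 <- sample_chrom(chroms)
        s <- sample_position(chroms[chroms$chrom == c1, ], span)
        if (!is.na(s) && is_free(c1, s, s) && is_free(c1, s + span, s + span)) {
          add_rec(cl, c1, s, c1, s + span, span, cf)
          register(c1, s, s)
          register(c1, s + span, s + span)
          break
        }
      }
    } else {
      for (try in 1:10) {
        cs <- sample(chroms$chrom, 2, prob = chroms$length_bp)
        p1 <- sample_position(chroms[chroms$chrom == cs[1], ], 0)
        p2 <- sample_position(chroms[chroms$chrom == cs[2], ], 0)
        if (!is.na(p1) && !is.na(p2) && is_free(cs[1], p1, p1) &&
              is_free(cs[2], p2, p2)) {
          add_rec(cl, cs[1], p1, cs[2], p2, 0, cf)
          register(cs[1], p1, p1)
          register(cs[2], p2, p2)
          break
        }
      }
    }
  }
  dplyr::bind_rows(recs)
}

sv_conf_threshold <- function(ab_class) {
  c(insertion = 0, deletion = 0, inversion = 0.7, duplication = -1,
    intra_translocation = 0.3, inter_translocation = 0.65)[ab_class]
}

#' Split CNV calls into segments
#'
#' With probability `cnv_segmentation_prob`, a CNV call is emitted as 2-3
#' same-sign segments whose outer boundaries equal the original interval
#' and whose internal gaps stay below the merge gap, so that
#' [merge_segmented_cnvs()] recovers the original span exactly.
#'
#' @param cnv a CNV call tibble.
#' @param cfg a [sim_config()].
#' @param merge_gap_bp the curation merge gap the gaps must stay below.
#' @return A CNV call tibble (segment rows replace split originals).
#' @export
inject_segmentation <- function(cnv, cfg = sim_config(),
                                merge_gap_bp = 500000) {
  if (nrow(cnv) == 0 || cfg$cnv_segmentation_prob == 0) return(cnv)
  rows <- list()
  for (i in seq_len(nrow(cnv))) {
    rec <- cnv[i, ]
    size <- rec$end - rec$start + 1
    if (runif(1) >= cfg$cnv_segmentation_prob || size < 1.5e6) {
      rows[[length(rows) + 1]] <- rec
      next
    }
    n_seg <- sample(2:3, 1)
    cuts <- sort(round(runif(n_seg - 1, rec$start + 2e5, rec$end - 2e5)))
    bounds <- cbind(c(rec$start, cuts + 1), c(cuts, rec$end))
    for (s in seq_len(n_seg)) {
      seg <- rec
      seg$call_id <- paste0(rec$call_id, "_seg", s)
      seg$start <- bounds[s, 1]
      seg$end <- bounds[s, 2]
      # shave a sub-merge-gap internal gap off segment starts after the first
      if (s > 1) {
        gap_hi <- min(merge_gap_bp - 1e4, floor((seg$end - seg$start) / 2))
        if (gap_hi > 1e4) {
          seg$start <- seg$start + round(runif(1, 1e4, gap_hi))
        }
      }
      rows[[length(rows) + 1]] <- seg
    }
  }
  dplyr::bind_rows(rows)
}

observe_patient <- function(truth, pid, cfg, chroms, poly_regions) {
  sv_rows <- list()
  cnv_rows <- list()
  known_rows <- list()
  band <- cfg$soft_sensitivity_band
  emit_sv <- function(ab_class, c1, p1, c2, p2, size, cf, truth_id, origin,
                      artifact = FALSE) {
    thr <- unname(sv_conf_threshold(ab_class))
    low <- runif(1) < cfg$low_conf_prob
    conf <- if (low) thr - runif(1, 0.05, 0.25) else
      runif(1, max(thr, 0) + 0.02, 1)
    if (artifact) {
      if (runif(1) < 0.5) {
        l1 <- sample(2:10, 1); l2 <- sample(11:40, 1)
        rc <- sort(runif(2, 10, 40))
      } else {
        l1 <- sample(11:40, 1); l2 <- sample(11:40, 1)
        rc <- c(runif(1, 0.5, 9.5), runif(1, 10, 40))
      }
      if (runif(1) < 0.5) { tmp <- l1; l1 <- l2; l2 <- tmp }
    } else {
      l1 <- sample(12:60, 1); l2 <- sample(12:60, 1)
      rc <- runif(2, 11, 55)
    }
    sv_rows[[length(sv_rows) + 1]] <<- tibble::tibble(
      call_id = NA_character_, patient_id = pid, sv_type = ab_class,
      chrom1 = c1, pos1 = p1, chrom2 = c2, pos2 = p2, size_bp = size,
      confidence = round(conf, 3),
      raw_conf_left = round(rc[1], 2), raw_conf_right = round(rc[2], 2),
      labels_bp1 = l1, labels_bp2 = l2,
      self_molecules = clamp(round(rlnorm(1, log(40), 0.7)), 5, 175),
      vaf = round(clamp(cf + rnorm(1, 0, 0.02), 0.01, 1), 3),
      truth_id = truth_id, origin = origin)
  }
  emit_cnv <- function(cnv_type, c1, s, e, cf, truth_id, origin) {
    low <- runif(1) < cfg$low_conf_prob
    conf <- if (low) runif(1, 0.9, 0.989) else runif(1, 0.991, 1)
    cnv_rows[[length(cnv_rows) + 1]] <<- tibble::tibble(
      call_id = NA_character_, patient_id = pid, chrom = c1,
      start = s, end = e, cnv_type = cnv_type,
      confidence = round(conf, 4),
      cell_fraction = round(clamp(cf + rnorm(1, 0, 0.03), 0.01, 1), 3),
      truth_id = truth_id, origin = origin)
  }
  emit_known <- function(technique, ab_class, truth_id, chrom = NA, s = NA,
                         e = NA, c1 = NA, p1 = NA, c2 = NA, p2 = NA,
                         tol = NA, cf = NA) {
    known_rows[[length(known_rows) + 1]] <<- tibble::tibble(
      ab_id = NA_character_, patient_id = pid, technique = technique,
      ab_class = ab_class, chrom = chrom, start = s, end = e,
      chrom1 = c1, pos1 = p1, chrom2 = c2, pos2 = p2,
      bp_tolerance_bp = tol, clone_fraction = cf, truth_id = truth_id)
  }
  jit <- function(x, sd) round(x + rnorm(length(x), 0, sd))
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    cf <- tr$clone_fraction
    p_sv <- detection_probability(cf, cfg$sv_detect_floor, band)
    p_cnv <- detection_probability(cf, cfg$cnv_detect_floor, band)
    is_cnv <- tr$ab_class %in% c("cnv_gain", "cnv_loss")
    if (!is_cnv && runif(1) < p_sv) {
      p1 <- jit(tr$pos1, 5e3)
      p2 <- jit(tr$pos2, 5e3)
      if (tr$chrom1 == tr$chrom2 && p2 < p1) { t <- p1; p1 <- p2; p2 <- t }
      emit_sv(tr$ab_class, tr$chrom1, p1, tr$chrom2, p2,
              if (tr$chrom1 == tr$chrom2) p2 - p1 else 0,
              cf, tr$truth_id, "true")
      # large unbalanced SVs may also surface in the coverage profile
      if (tr$ab_class %in% c("deletion", "duplication") &&
            tr$size_bp > 6e5 && runif(1) < cfg$dual_call_prob * p_cnv) {
        emit_cnv(if (tr$ab_class == "deletion") "loss" else "gain",
                 tr$chrom1, jit(tr$pos1, 3e4), jit(tr$pos2, 3e4), cf,
                 tr$truth_id, "true_dual")
      }
    }
    if (is_cnv && runif(1) < p_cnv) {
      s <- jit(tr$pos1, 3e4)
      e <- jit(tr$pos2, 3e4)
      if (e - s < 5e5) e <- s + tr$size_bp - 1
      emit_cnv(sub("cnv_", "", tr$ab_class), tr$chrom1, s, e, cf,
               tr$truth_id, "true")
      # duplicity: the SV pipeline calls the same event
      if (runif(1) < cfg$dual_call_prob * p_sv) {
        span <- tr$pos2 - tr$pos1
        sv_class <- if (tr$ab_class == "cnv_gain") "duplication"
        else if (span > 5e6) "intra_translocation" else "deletion"
        p1 <- jit(tr$pos1, 1e4)
        p2 <- jit(tr$pos2, 1e4)
        emit_sv(sv_class, tr$chrom1, p1, p2 = max(p2, p1 + 1e5),
                c2 = tr$chrom1, size = max(p2, p1 + 1e5) - p1, cf = cf,
                truth_id = tr$truth_id, origin = "true_dual")
      }
    }
    # CBA: culture clone-selection; band-level resolution, >= ~10 Mb CNVs
    cf_eff <- clamp(cf * rlnorm(1, 0, 0.35), 0, 1)
    cba_detected <- cf_eff >= 0.1 && runif(1) < pmin(1, 1.6 * cf_eff)
    if (cba_detected) {
      if (is_cnv && tr$size_bp >= 1e7) {
        emit_known("CBA", tr$ab_class, tr$truth_id, chrom = tr$chrom1,
                   s = pmax(1, jit(tr$pos1, 2e6)), e = jit(tr$pos2, 2e6),
                   cf = cf)
      } else if (tr$ab_class == "inversion" && tr$size_bp >= 1e7) {
        emit_known("CBA", "inversion", tr$truth_id,
                   c1 = tr$chrom1, p1 = jit(tr$pos1, 1.5e6),
                   c2 = tr$chrom2, p2 = jit(tr$pos2, 1.5e6), tol = 1e7,
                   cf = cf)
      } else if (tr$ab_class %in% c("intra_translocation",
                                    "inter_translocation")) {
        if (runif(1) < 0.3) {
          emit_known("CBA", "add_breakpoint", tr$truth_id,
                     c1 = tr$chrom1, p1 = jit(tr$pos1, 1.5e6), tol = 1e7,
                     cf = cf)
        } else {
          emit_known("CBA", "translocation", tr$truth_id,
                     c1 = tr$chrom1, p1 = jit(tr$pos1, 1.5e6),
                     c2 = tr$chrom2, p2 = jit(tr$pos2, 1.5e6), tol = 1e7,
                     cf = cf)
        }
      }
    }
    # CMA: unbalanced changes only, clone fraction >= floor
    if ((is_cnv || tr$ab_class %in% c("deletion", "duplication")) &&
          cf >= cfg$cma_detect_floor) {
      cma_class <- if (tr$ab_class %in% c("cnv_gain", "duplication"))
        "cnv_gain" else "cnv_loss"
      emit_known("CMA", cma_class, tr$truth_id, chrom = tr$chrom1,
                 s = pmax(1, jit(tr$pos1, 2e4)), e = jit(tr$pos2, 2e4),
                 cf = cf)
    }
    # FISH: CLL panel loci, sensitive down to a few percent of nuclei
    if (tr$ab_class == "cnv_loss" && cf >= 0.03) {
      hit <- FISH_LOCI[FISH_LOCI$chrom == tr$chrom1 &
                         FISH_LOCI$start <= tr$pos2 &
                         FISH_LOCI$end >= tr$pos1, ]
      if (nrow(hit) == 1 && runif(1) < 0.95) {
        emit_known("FISH", "cnv_loss", tr$truth_id, chrom = hit$chrom,
                   s = pmax(1, hit$start - 5e5), e = hit$end + 5e5,
                   cf = cf)
      }
    }
  }
  # artifact translocations: low labels or low raw confidence
  for (k in seq_len(rpois(1, cfg$artifact_translocation_rate))) {
    cs <- sample(chroms$chrom, 2, prob = chroms$length_bp)
    p1 <- sample_position(chroms[chroms$chrom == cs[1], ], 0)
    p2 <- sample_position(chroms[chroms$chrom == cs[2], ], 0)
    if (is.na(p1) || is.na(p2)) next
    emit_sv("inter_translocation", cs[1], p1, cs[2], p2, 0,
            runif(1, 0.05, 0.5), NA_character_, "artifact",
            artifact = TRUE)
  }
  # benign polymorphic CNV calls at catalogued regions
  for (k in seq_len(rpois(1, cfg$polymorphism_rate))) {
    reg <- poly_regions[sample.int(nrow(poly_regions), 1), ]
    emit_cnv(reg$name, reg$chrom, jit(reg$start, 1e4),
             jit(reg$end, 1e4), runif(1, 0.3, 1), NA_character_,
             "polymorphism")
  }
  list(sv = dplyr::bind_rows(sv_rows), cnv = dplyr::bind_rows(cnv_rows),
       known = dplyr::bind_rows(known_rows))
}

#' Simulate a cohort with known truth
#'
#' Generates per-patient true abnormality sets, the observed OGM SV and
#' CNV call tables (with detection driven by clone fraction, breakpoint
#' jitter, segmentation, duplicities, artifacts and polymorphisms), the
#' CBA/FISH/CMA known-aberration records, region sets and the clinical
#' table. Fully reproducible given the seed; every observed call carries
#' `truth_id` or an `origin` label of `artifact`/`polymorphism`.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @return A list of class `ogm_cohort`: `truth`, `sv`, `cnv`, `known`
#'   (per-technique records), `inventory` (after
#'   [build_known_inventory()]), `clinical`, `masks`, `polymorphism_regions`,
#'   `config`, `seed`.
#' @export
simulate_cohort <- function(cfg = sim_config(), seed = 1) {
  set.seed(seed)
  chroms <- hg19_chromosomes()
  # benign-polymorphism catalogue emulating a germline CNV database
  poly_regions <- tibble::tibble(
    chrom = sample_chrom(chroms, 40),
    size = round(runif(40, 6e5, 2e6))
  )
  poly_regions$start <- vapply(seq_len(40), function(i) {
    sample_position(chroms[chroms$chrom == poly_regions$chrom[i], ],
                    poly_regions$size[i])
  }, numeric(1))
  poly_regions <- poly_regions[!is.na(poly_regions$start), ]
  poly_regions$end <- poly_regions$start + poly_regions$size - 1
  poly_regions$name <- sample(c("gain", "loss"), nrow(poly_regions),
                              replace = TRUE)
  poly_regions$label <- "polymorphism"
  poly_regions$size <- NULL
  masks <- centromere_telomere_regions()
  masks$label <- "masked"

  ids <- sprintf("P%03d", seq_len(cfg$n_patients))
  complex_group <- runif(cfg$n_patients) < cfg$ck_fraction
  patient_seeds <- sample.int(.Machine$integer.max - 1, cfg$n_patients)

  truths <- list()
  svs <- list()
  cnvs <- list()
  knowns <- list()
  for (i in seq_len(cfg$n_patients)) {
    set.seed(patient_seeds[i])
    tr <- truth_for_patient(ids[i], complex_group[i], cfg, chroms)
    if (nrow(tr) > 0) {
      tr$truth_id <- sprintf("%s_T%03d", ids[i], seq_len(nrow(tr)))
    } else {
      tr$truth_id <- character(0)
    }
    obs <- observe_patient(tr, ids[i], cfg, chroms, poly_regions)
    if (nrow(obs$cnv) > 0) {
      obs$cnv$call_id <- sprintf("%s_CNV%03d", ids[i], seq_len(nrow(obs$cnv)))
      obs$cnv <- inject_segmentation(obs$cnv, cfg)
    }
    if (nrow(obs$sv) > 0) {
      obs$sv$call_id <- sprintf("%s_SV%03d", ids[i], seq_len(nrow(obs$sv)))
    }
    if (nrow(obs$known) > 0) {
      obs$known$ab_id <- sprintf("%s_K%03d", ids[i], seq_len(nrow(obs$known)))
    }
    truths[[i]] <- tr
    svs[[i]] <- obs$sv
    cnvs[[i]] <- obs$cnv
    knowns[[i]] <- obs$known
  }
  truth <- dplyr::bind_rows(truths)
  known <- dplyr::bind_rows(knowns)
  for (col in setdiff(c(KNOWN_COLUMNS, "truth_id"), names(known))) {
    known[[col]] <- NA
  }
  known <- known[c(KNOWN_COLUMNS, "truth_id")]

  # clinical outcomes: exponential TTFT with a complexity hazard ratio
  set.seed(patient_seeds[cfg$n_patients] + 1)
  true_counts <- truth |>
    dplyr::count(.data$patient_id, name = "n_true") |>
    dplyr::right_join(tibble::tibble(patient_id = ids), by = "patient_id") |>
    dplyr::mutate(n_true = dplyr::coalesce(.data$n_true, 0L)) |>
    dplyr::arrange(match(.data$patient_id, ids))
  complex_true <- true_counts$n_true >= 10
  h0 <- log(2) / cfg$ttft_median_baseline_months
  hazard <- h0 * ifelse(complex_true, cfg$ttft_hazard_ratio_complex, 1)
  t_event <- stats::rexp(cfg$n_patients, hazard)
  censor <- runif(cfg$n_patients, 3, cfg$censor_max_months)
  treated <- t_event <= censor
  tp53 <- truth |>
    dplyr::filter(.data$ab_class == "cnv_loss", .data$chrom1 == "17",
                  .data$pos1 <= TP53_LOCUS$end,
                  .data$pos2 >= TP53_LOCUS$start,
                  .data$clone_fraction >= 0.05) |>
    dplyr::pull(.data$patient_id)
  cba_counts <- known |>
    dplyr::filter(.data$technique == "CBA") |>
    dplyr::count(.data$patient_id, name = "n_abn_cba")
  cma_counts <- known |>
    dplyr::filter(.data$technique == "CMA") |>
    dplyr::count(.data$patient_id, name = "n_abn_cma")
  clinical <- tibble::tibble(patient_id = ids) |>
    dplyr::left_join(cba_counts, by = "patient_id") |>
    dplyr::left_join(cma_counts, by = "patient_id") |>
    dplyr::mutate(
      n_abn_cba = dplyr::coalesce(.data$n_abn_cba, 0L),
      n_abn_cma = dplyr::coalesce(.data$n_abn_cma, 0L),
      ck_by_cba = .data$n_abn_cba >= 3,
      tp53_abnormal = .data$patient_id %in% tp53,
      ttft_months = round(pmin(t_event, censor), 1),
      treated = treated,
      pre_treated = runif(cfg$n_patients) < cfg$pre_treated_prob
    ) |>
    dplyr::select(dplyr::all_of(CLINICAL_COLUMNS))

  truth_profile <- true_counts |>
    dplyr::mutate(complex_true = complex_true,
                  group_ck = complex_group[match(.data$patient_id, ids)])

  v_sv <- validate_sv_calls(dplyr::bind_rows(svs))
  v_cnv <- validate_cnv_calls(dplyr::bind_rows(cnvs))
  stopifnot(nrow(v_sv$rejected) == 0, nrow(v_cnv$rejected) == 0)
  inventory <- if (nrow(known) > 0) {
    suppressWarnings(build_known_inventory(
      known[known$technique == "CBA", ],
      known[known$technique == "FISH", ],
      known[known$technique == "CMA", ]))
  } else known
  structure(list(truth = truth, truth_profile = truth_profile,
                 sv = v_sv$calls, cnv = v_cnv$calls, known = known,
                 inventory = inventory, clinical = clinical,
                 masks = masks, polymorphism_regions = poly_regions,
                 config = cfg, seed = seed),
            class = "ogm_cohort")
}

#' @export
print.ogm_cohort <- function(x, ...) {
  cat(sprintf(
    "<ogm_cohort> %d patients, %d true abnormalities, %d SV + %d CNV calls, %d known records (seed %d)\n",
    nrow(x$clinical), nrow(x$truth), nrow(x$sv), nrow(x$cnv),
    nrow(x$known), x$seed))
  invisible(x)
}

#' Permissive thresholds for targeted rescue
#'
#' A lower-threshold configuration used to re-examine calls at known
#' aberration loci: halved translocation confidence thresholds, CNV
#' confidence 0.9 and CNV size 250 Kb.
#'
#' @param base a [curation_config()] to relax.
#' @return A [curation_config()].
#' @export
permissive_curation_config <- function(base = curation_config()) {
  thr <- base$conf_thresholds
  thr[["inversion"]] <- 0.3
  thr[["intra_translocation"]] <- 0.1
  thr[["inter_translocation"]] <- 0.3
  thr[["cnv"]] <- 0.9
  cfg <- base
  cfg$conf_thresholds <- thr
  cfg$cnv_min_size_bp <- 250000
  cfg
}

#' Score pipeline recovery against the simulated truth
#'
#' Runs curation and complexity counting on the simulated tables and
#' compares with the truth set: per-patient count error and risk-class
#' agreement, risk confusion matrix, artifact-filter precision/recall
#' (flagged calls vs. generator-labeled artifacts among translocations
#' that reached the flagging stage), and the detection rate as a
#' function of clone fraction.
#'
#' @param cohort an [simulate_cohort()] result.
#' @param cfg a [curation_config()].
#' @param rescue apply [targeted_rescue()] with
#'   [permissive_curation_config()].
#' @return A list of class `recovery_report`; `tidy()` gives the
#'   per-patient table, `glance()` the headline rates.
#' @export
evaluate_recovery <- function(cohort, cfg = curation_config(),
                              rescue = TRUE) {
  curated <- suppressWarnings(curate(
    cohort$sv, cohort$cnv, masks = cohort$masks,
    polymorphisms = cohort$polymorphism_regions,
    known = if (rescue) cohort$inventory else NULL, cfg = cfg,
    permissive_cfg = if (rescue) permissive_curation_config(cfg) else NULL))
  profiles <- count_abnormalities(curated, cohort$clinical)
  stopifnot(all(profiles$patient_id %in% cohort$clinical$patient_id))
  per_patient <- cohort$truth_profile |>
    dplyr::left_join(profiles[c("patient_id", "n_ogm", "ogm_class")],
                     by = "patient_id") |>
    dplyr::mutate(
      n_ogm = dplyr::coalesce(.data$n_ogm, 0L),
      recovered_class = dplyr::coalesce(.data$ogm_class == "C_OGM", FALSE),
      class_match = .data$recovered_class == .data$complex_true,
      count_error = .data$n_ogm - .data$n_true)
  min_cf <- cohort$truth |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(min_cf = min(.data$clone_fraction), .groups = "drop")
  per_patient <- dplyr::left_join(per_patient, min_cf, by = "patient_id")
  confusion <- table(truth = per_patient$complex_true,
                     recovered = per_patient$recovered_class)
  # artifact filter: among translocation calls that reached flagging
  cur <- tibble::as_tibble(curated)
  id2origin <- setNames(cohort$sv$origin, cohort$sv$call_id)
  tr <- cur[is_transloc_class(cur$ab_class) &
              cur$status %in% c("kept", "rescued", "artifact_flagged"), ]
  tr$is_artifact_truth <- id2origin[tr$call_id] == "artifact"
  flagged <- tr$status == "artifact_flagged"
  precision <- if (sum(flagged) > 0) {
    sum(flagged & tr$is_artifact_truth) / sum(flagged)
  } else NA_real_
  recall <- if (sum(tr$is_artifact_truth) > 0) {
    sum(flagged & tr$is_artifact_truth) / sum(tr$is_artifact_truth)
  } else NA_real_
  # detection vs clone fraction: a truth record is recovered when any
  # countable curated record traces back to it
  call2truth <- c(setNames(cohort$sv$truth_id, cohort$sv$call_id),
                  setNames(cohort$cnv$truth_id, cohort$cnv$call_id))
  recovered_truths <- unique(stats::na.omit(
    call2truth[unlist(cur$provenance[cur$countable])]))
  det <- cohort$truth |>
    dplyr::mutate(detected = .data$truth_id %in% recovered_truths,
                  cf_bin = cut(.data$clone_fraction,
                               c(0, 0.05, 0.10, 0.15, 0.20, 0.30, 0.50, 1),
                               include.lowest = TRUE)) |>
    dplyr::group_by(.data$cf_bin) |>
    dplyr::summarise(n = dplyr::n(), detection_rate = mean(.data$detected),
                     .groups = "drop")
  structure(list(per_patient = per_patient, confusion = confusion,
                 artifact = tibble::tibble(precision = precision,
                                           recall = recall,
                                           n_flagged = sum(flagged)),
                 detection_curve = det, curated = curated,
                 profiles = profiles),
            class = "recovery_report")
}

#' @export
tidy.recovery_report <- function(x, ...) x$per_patient

#' @export
glance.recovery_report <- function(x, ...) {
  pp <- x$per_patient
  high <- pp[!is.na(pp$min_cf) & pp$min_cf >= 0.3, ]
  tibble::tibble(
    n_patients = nrow(pp),
    risk_class_recovery = mean(pp$class_match),
    risk_class_recovery_high_cf = if (nrow(high) > 0) mean(high$class_match)
      else NA_real_,
    n_high_cf = nrow(high),
    artifact_precision = x$artifact$precision,
    artifact_recall = x$artifact$recall,
    median_count_error = stats::median(pp$count_error))
}

#' @export
print.recovery_report <- function(x, ...) {
  g <- glance.recovery_report(x)
  cat(sprintf(
    "<recovery_report> %d patients: risk-class recovery %.1f%% (%.1f%% at clone fractions >= 0.3), artifact precision %.2f, recall %.2f\n",
    g$n_patients, 100 * g$risk_class_recovery,
    100 * g$risk_class_recovery_high_cf, g$artifact_precision,
    g$artifact_recall))
  invisible(x)
}

#' Write all cohort tables to a directory
#'
#' @param cohort an [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_sv_calls(cohort$sv, file.path(dir, "sv_calls.tsv"))
  write_cnv_calls(cohort$cnv, file.path(dir, "cnv_calls.tsv"))
  write_known_aberrations(cohort$known[KNOWN_COLUMNS],
                          file.path(dir, "known_aberrations.tsv"))
  write_clinical_table(cohort$clinical, file.path(dir, "clinical.tsv"))
  write_bed_regions(cohort$masks, file.path(dir, "masked_regions.bed"))
  write_bed_regions(cohort$polymorphism_regions,
                    file.path(dir, "polymorphism_regions.bed"))
  readr::write_tsv(cohort$truth, file.path(dir, "truth.tsv"),
                   progress = FALSE)
  invisible(dir)
}
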