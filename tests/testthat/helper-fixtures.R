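# Fixture builders: minimal validated call/known/clinical tables built in
# code. Defaults pass every curation filter so tests flip one property at
# a time.

make_sv <- function(..., n = NULL) {
  defaults <- list(call_id = NA_character_, patient_id = "P1",
                   sv_type = "deletion", chrom1 = "13", pos1 = 50000000,
                   chrom2 = "13", pos2 = 50200000, size_bp = NA_real_,
                   confidence = 0.95, raw_conf_left = 30,
                   raw_conf_right = 30, labels_bp1 = 25, labels_bp2 = 25,
                   self_molecules = 40, vaf = 0.8)
  args <- utils::modifyList(defaults, list(...))
  df <- tibble::as_tibble(args)
  if (!is.null(n)) df <- df[rep(1, n), ]
  if (all(is.na(df$call_id))) {
    df$call_id <- sprintf("SV%03d", seq_len(nrow(df)))
  }
  df$size_bp <- ifelse(is.na(df$size_bp) & df$chrom1 == df$chrom2,
                       df$pos2 - df$pos1, df$size_bp)
  df$size_bp[is.na(df$size_bp)] <- 0
  df
}

make_cnv <- function(...) {
  defaults <- list(call_id = NA_character_, patient_id = "P1",
                   chrom = "13", start = 50000000, end = 51000000,
                   cnv_type = "loss", confidence = 0.995,
                   cell_fraction = 0.8)
  df <- tibble::as_tibble(utils::modifyList(defaults, list(...)))
  if (all(is.na(df$call_id))) {
    df$call_id <- sprintf("CNV%03d", seq_len(nrow(df)))
  }
  df
}

make_known <- function(...) {
  defaults <- list(ab_id = NA_character_, patient_id = "P1",
                   technique = "CMA", ab_class = "cnv_loss",
                   chrom = "13", start = 50000000, end = 51000000,
                   chrom1 = NA_character_, pos1 = NA_real_,
                   chrom2 = NA_character_, pos2 = NA_real_,
                   bp_tolerance_bp = NA_real_, clone_fraction = 0.8)
  df <- tibble::as_tibble(utils::modifyList(defaults, list(...)))
  if (all(is.na(df$ab_id))) df$ab_id <- sprintf("K%03d", seq_len(nrow(df)))
  df
}

make_clinical <- function(patient_id = "P1", ttft_months = 24,
                          treated = TRUE, pre_treated = FALSE,
                          tp53_abnormal = FALSE, ck_by_cba = FALSE,
                          n_abn_cba = 1, n_abn_cma = 1) {
  tibble::tibble(patient_id = patient_id, ttft_months = ttft_months,
                 treated = treated, pre_treated = pre_treated,
                 tp53_abnormal = tp53_abnormal, ck_by_cba = ck_by_cba,
                 n_abn_cba = n_abn_cba, n_abn_cma = n_abn_cma)
}

# random small cohorts for property tests: every patient is an
# independent mini-cohort; coordinates land in the clean arms of a few
# chromosomes so no fixed mask interferes unless supplied
random_calls <- function(n_patients, mean_calls = 8, seed = 1) {
  set.seed(seed)
  svs <- list()
  cnvs <- list()
  for (p in seq_len(n_patients)) {
    pid <- sprintf("R%04d", p)
    n_sv <- rpois(1, mean_calls * 0.6)
    n_cnv <- rpois(1, mean_calls * 0.4)
    if (n_sv > 0) {
      type <- sample(c("deletion", "inversion", "duplication",
                       "intra_translocation", "inter_translocation"),
                     n_sv, replace = TRUE)
      c1 <- sample(as.character(1:8), n_sv, replace = TRUE)
      p1 <- round(runif(n_sv, 6e7, 1.2e8))
      span <- round(runif(n_sv, 2e4, 3e7))
      c2 <- ifelse(type == "inter_translocation",
                   sample(as.character(9:12), n_sv, replace = TRUE), c1)
      p2 <- ifelse(type == "inter_translocation",
                   round(runif(n_sv, 6e7, 1.1e8)), p1 + span)
      svs[[p]] <- make_sv(
        call_id = sprintf("%s_SV%02d", pid, seq_len(n_sv)),
        patient_id = pid, sv_type = type, chrom1 = c1, pos1 = p1,
        chrom2 = c2, pos2 = p2,
        size_bp = ifelse(type == "inter_translocation", 0, span),
        confidence = round(runif(n_sv, -0.5, 1), 3),
        raw_conf_left = round(runif(n_sv, 0, 40), 1),
        raw_conf_right = round(runif(n_sv, 0, 40), 1),
        labels_bp1 = sample(2:40, n_sv, replace = TRUE),
        labels_bp2 = sample(2:40, n_sv, replace = TRUE))
    }
    if (n_cnv > 0) {
      s <- round(runif(n_cnv, 6e7, 1.2e8))
      cnvs[[p]] <- make_cnv(
        call_id = sprintf("%s_CNV%02d", pid, seq_len(n_cnv)),
        patient_id = pid, chrom = sample(as.character(1:8), n_cnv,
                                         replace = TRUE),
        start = s, end = s + round(runif(n_cnv, 1e5, 5e6)),
        cnv_type = sample(c("gain", "loss"), n_cnv, replace = TRUE),
        confidence = round(runif(n_cnv, 0.95, 1), 4),
        cell_fraction = round(runif(n_cnv, 0.05, 1), 3))
    }
  }
  list(sv = dplyr::bind_rows(svs), cnv = dplyr::bind_rows(cnvs))
}

# rebuild call tables from curated records with a given status set, for
# idempotence checks
records_to_calls <- function(records,
                             statuses = c("kept", "rescued")) {
  keep <- tibble::as_tibble(records)[records$status %in% statuses, ]
  sv <- keep[keep$source != "cnv_pipeline", ]
  cnv <- keep[keep$source == "cnv_pipeline", ]
  list(
    sv = if (nrow(sv) > 0) make_sv(
      call_id = sv$call_id, patient_id = sv$patient_id,
      sv_type = sv$ab_class, chrom1 = sv$chrom1, pos1 = sv$pos1,
      chrom2 = sv$chrom2, pos2 = sv$pos2, size_bp = sv$size_bp,
      confidence = sv$confidence, raw_conf_left = sv$raw_conf_left,
      raw_conf_right = sv$raw_conf_right, labels_bp1 = sv$labels_bp1,
      labels_bp2 = sv$labels_bp2) else NULL,
    cnv = if (nrow(cnv) > 0) make_cnv(
      call_id = cnv$call_id, patient_id = cnv$patient_id,
      chrom = cnv$chrom1, start = cnv$pos1, end = cnv$pos2,
      cnv_type = sub("cnv_", "", cnv$ab_class),
      confidence = cnv$confidence,
      cell_fraction = cnv$cell_fraction) else NULL)
}

# independent reciprocal-overlap re-implementation for oracle checks
reciprocal_overlap_test <- function(s1, e1, s2, e2) {
  ov <- pmax(pmin(e1, e2) - pmax(s1, s2) + 1, 0)
  pmin(ov / (e1 - s1 + 1), ov / (e2 - s2 + 1))
}

# exact two-sided Fisher p by direct hypergeometric enumeration (log-space
# choose arithmetic; independent of stats::fisher.test)
fisher_enum_p <- function(t) {
  a <- t[1]; b <- t[2]; c <- t[3]; d <- t[4]
  m <- a + b
  n <- c + d
  k <- a + c
  lo <- max(0, k - n)
  hi <- min(k, m)
  logp <- vapply(lo:hi, function(x) {
    lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)
  }, numeric(1))
  obs <- logp[a - lo + 1]
  sum(exp(logp[logp <= obs + 1e-7]))
}
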