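# Shared data model: canonical column sets, validators and the hg19
# chromosome table used throughout the package. All coordinates are
# 1-based inclusive on hg19 chromosome names without the "chr" prefix.

SV_TYPES <- c("insertion", "deletion", "inversion", "duplication",
              "intra_translocation", "inter_translocation")

CNV_TYPES <- c("gain", "loss")

AB_CLASSES <- c(SV_TYPES, "cnv_gain", "cnv_loss")

KNOWN_CLASSES <- c("cnv_gain", "cnv_loss", "translocation", "inversion",
                   "trisomy", "add_breakpoint")

AB_STATUSES <- c("kept", "filtered_confidence", "filtered_size",
                 "filtered_masked", "filtered_polymorphism",
                 "deduplicated", "artifact_flagged", "rescued")

SV_COLUMNS <- c("call_id", "patient_id", "sv_type", "chrom1", "pos1",
                "chrom2", "pos2", "size_bp", "confidence",
                "raw_conf_left", "raw_conf_right", "labels_bp1",
                "labels_bp2", "self_molecules", "vaf")

CNV_COLUMNS <- c("call_id", "patient_id", "chrom", "start", "end",
                 "cnv_type", "confidence", "cell_fraction")

KNOWN_COLUMNS <- c("ab_id", "patient_id", "technique", "ab_class",
                   "chrom", "start", "end", "chrom1", "pos1", "chrom2",
                   "pos2", "bp_tolerance_bp", "clone_fraction")

CLINICAL_COLUMNS <- c("patient_id", "ttft_months", "treated",
                      "pre_treated", "tp53_abnormal", "ck_by_cba",
                      "n_abn_cba", "n_abn_cma")

#' hg19 chromosome table
#'
#' Chromosome lengths and approximate centromere midpoints for GRCh37/hg19,
#' used by the synthetic cohort generator and by the default
#' centromere/telomere annotation. Names carry no "chr" prefix.
#'
#' @return A tibble with columns `chrom`, `length_bp`, `centromere_bp`.
#' @export
#' @examples
#' hg19_chromosomes()
hg19_chromosomes <- function() {
  tibble::tibble(
    chrom = c(as.character(1:22), "X", "Y"),
    length_bp = c(249250621, 243199373, 198022430, 191154276, 180915260,
                  171115067, 159138663, 146364022, 141213431, 135534747,
                  135006516, 133851895, 115169878, 107349540, 102531392,
                  90354753, 81195210, 78077248, 59128983, 63025520,
                  48129895, 51304566, 155270560, 59373566),
    centromere_bp = c(125000000, 93300000, 91000000, 50400000, 48400000,
                      61000000, 59900000, 45600000, 49000000, 40200000,
                      53700000, 35800000, 17900000, 17600000, 19000000,
                      36600000, 24000000, 17200000, 26500000, 27500000,
                      13200000, 14700000, 60600000, 12500000)
  )
}

chrom_levels <- function() c(as.character(1:22), "X", "Y")

strip_chr <- function(x) sub("^chr", "", as.character(x))

check_chrom <- function(chrom) {
  chrom <- strip_chr(chrom)
  bad <- !chrom %in% chrom_levels()
  list(chrom = chrom, bad = bad)
}

#' Default centromere/telomere annotation
#'
#' Builds a region table flagging (peri-)centromeric and telomeric zones of
#' hg19, used when assigning discrepancy reasons and by the synthetic
#' generator's masked-region model. A custom BED-derived table can be used
#' instead anywhere this one is accepted.
#'
#' @param centromere_halfwidth_bp half-width of the pericentromeric zone.
#' @param telomere_width_bp width of each terminal telomeric zone.
#' @return A tibble with columns `chrom`, `start`, `end`, `label`.
#' @export
centromere_telomere_regions <- function(centromere_halfwidth_bp = 3e6,
                                        telomere_width_bp = 1e6) {
  chroms <- hg19_chromosomes()
  dplyr::bind_rows(
    chroms |>
      dplyr::transmute(
        chrom = .data$chrom,
        start = pmax(1, .data$centromere_bp - centromere_halfwidth_bp),
        end = pmin(.data$length_bp, .data$centromere_bp + centromere_halfwidth_bp),
        label = "centromere"
      ),
    chroms |>
      dplyr::transmute(chrom = .data$chrom, start = 1,
                       end = telomere_width_bp, label = "telomere"),
    chroms |>
      dplyr::transmute(chrom = .data$chrom,
                       start = .data$length_bp - telomere_width_bp + 1,
                       end = .data$length_bp, label = "telomere")
  )
}

# --- record validation -----------------------------------------------------

# Validates SV rows; returns list(calls, rejected). `rejected` carries the
# original row number and a reason string (one row per rejected record).
validate_sv_calls <- function(df) {
  df$.row <- seq_len(nrow(df))
  df$chrom1 <- strip_chr(df$chrom1)
  df$chrom2 <- strip_chr(df$chrom2)
  reasons <- rep(NA_character_, nrow(df))
  note <- function(idx, msg) {
    idx[is.na(idx)] <- TRUE   # a condition unevaluable due to NA rejects
    reasons[idx & is.na(reasons)] <<- msg
  }
  note(!df$sv_type %in% SV_TYPES, "unknown sv_type")
  note(!df$chrom1 %in% chrom_levels() | !df$chrom2 %in% chrom_levels(),
       "chromosome not in reference set")
  note(df$pos1 < 1 | df$pos2 < 1, "position < 1")
  inter <- df$sv_type == "inter_translocation"
  note(is.na(reasons) & inter & df$chrom1 == df$chrom2,
       "inter_translocation with identical chromosomes")
  note(is.na(reasons) & !inter & df$chrom1 != df$chrom2,
       "intrachromosomal type with differing chromosomes")
  note(is.na(reasons) & !inter & df$pos1 > df$pos2,
       "pos1 > pos2 for same-chromosome call")
  sized <- df$sv_type %in% c("deletion", "duplication", "inversion")
  note(is.na(reasons) & sized & !is.na(df$size_bp) &
         abs(df$size_bp - (df$pos2 - df$pos1)) > 1,
       "size_bp inconsistent with breakpoint span")
  note(is.na(df$confidence), "missing confidence")
  note(duplicated(df$call_id), "duplicate call_id")
  keep <- is.na(reasons)
  rejected <- tibble::tibble(row = df$.row[!keep], call_id = df$call_id[!keep],
                             reason = reasons[!keep])
  calls <- df[keep, , drop = FALSE]
  calls$.row <- NULL
  list(calls = tibble::as_tibble(calls), rejected = rejected)
}

validate_cnv_calls <- function(df) {
  df$.row <- seq_len(nrow(df))
  df$chrom <- strip_chr(df$chrom)
  reasons <- rep(NA_character_, nrow(df))
  note <- function(idx, msg) {
    idx[is.na(idx)] <- TRUE
    reasons[idx & is.na(reasons)] <<- msg
  }
  note(!df$cnv_type %in% CNV_TYPES, "unknown cnv_type")
  note(!df$chrom %in% chrom_levels(), "chromosome not in reference set")
  note(df$start < 1 | df$end < df$start, "invalid interval")
  note(is.na(df$confidence) | df$confidence < 0 | df$confidence > 1,
       "confidence outside [0,1]")
  note(!is.na(df$cell_fraction) &
         (df$cell_fraction < 0 | df$cell_fraction > 1),
       "cell_fraction outside [0,1]")
  note(duplicated(df$call_id), "duplicate call_id")
  keep <- is.na(reasons)
  rejected <- tibble::tibble(row = df$.row[!keep], call_id = df$call_id[!keep],
                             reason = reasons[!keep])
  calls <- df[keep, , drop = FALSE]
  calls$.row <- NULL
  list(calls = tibble::as_tibble(calls), rejected = rejected)
}

attach_rejected <- function(calls, rejected, n_input) {
  attr(calls, "rejected") <- rejected
  attr(calls, "n_input") <- n_input
  if (nrow(rejected) > 0) {
    rlang::warn(sprintf("%d of %d rows rejected (see rejected_rows())",
                        nrow(rejected), n_input))
  }
  calls
}

#' Rejected rows from a table reader
#'
#' Readers validate every row; rows violating a record invariant are dropped
#' from the returned tibble and reported here with their input row number
#' and reason. Accepted plus rejected rows always equal the input rows.
#'
#' @param x a tibble returned by one of the `read_*` functions.
#' @return A tibble with columns `row`, `call_id`, `reason`.
#' @export
rejected_rows <- function(x) {
  attr(x, "rejected") %||%
    tibble::tibble(row = integer(), call_id = character(),
                   reason = character())
}

interval_size <- function(start, end) end - start + 1

# Reciprocal overlap of 1-based inclusive intervals (vectorized).
reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- pmin(e1, e2) - pmax(s1, s2) + 1
  ov <- pmax(ov, 0)
  pmin(ov / interval_size(s1, e1), ov / interval_size(s2, e2))
}
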