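# Readers and writers for the tabular interfaces: SMAP-like SV call
# tables, CNV call tables, BED region files, known-aberration and clinical
# tables. All readers validate records and report rejected rows; all
# writers emit a deterministic column order so that write -> read is the
# identity on validated tables.

#' SMAP-like dialect descriptor
#'
#' Maps the semantic fields of an SV call table onto the column names of a
#' concrete file, so that real pipeline exports with different headers can
#' be read without code change. `type_map` translates the file's SV type
#' strings onto the canonical set (`insertion`, `deletion`, `inversion`,
#' `duplication`, `intra_translocation`, `inter_translocation`).
#'
#' The table which SMAP column the per-partner "labels mapped" counts come
#' from is export-dependent; point `labels_bp1`/`labels_bp2` at whichever
#' columns carry them in your export.
#'
#' @param ... named overrides of the default column mapping; names must be
#'   semantic field names (see `smap_dialect()` for the set).
#' @param type_map named character vector, file type string -> canonical
#'   SV type.
#' @return A list of class `smap_dialect`.
#' @export
#' @examples
#' smap_dialect(confidence = "Conf", type_map = c(trans = "inter_translocation"))
smap_dialect <- function(..., type_map = NULL) {
  columns <- list(
    call_id = "SmapEntryID", patient_id = "SampleID", sv_type = "Type",
    chrom1 = "RefcontigID1", pos1 = "RefStartPos",
    chrom2 = "RefcontigID2", pos2 = "RefEndPos", size_bp = "SVsize",
    confidence = "Confidence", raw_conf_left = "RawConfidenceLeft",
    raw_conf_right = "RawConfidenceRight", labels_bp1 = "LabelsBp1",
    labels_bp2 = "LabelsBp2", self_molecules = "SelfMolecules",
    vaf = "VAF"
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(columns))
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown dialect fields: ",
                        paste(unknown, collapse = ", ")))
  }
  columns[names(overrides)] <- overrides
  default_types <- c(
    insertion = "insertion", deletion = "deletion", inversion = "inversion",
    duplication = "duplication",
    intra_translocation = "intra_translocation",
    inter_translocation = "inter_translocation",
    translocation_intrachr = "intra_translocation",
    translocation_interchr = "inter_translocation",
    duplication_split = "duplication", duplication_inverted = "duplication",
    inversion_paired = "inversion"
  )
  structure(list(columns = columns,
                 type_map = c(type_map, default_types)),
            class = "smap_dialect")
}

read_tsv_quiet <- function(path, ...) {
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE, ...)
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    rlang::abort(sprintf("%s: missing required column(s): %s", path,
                         paste(missing, collapse = ", ")))
  }
}

#' Read an SMAP-like SV call table
#'
#' Tab-separated, `#`-prefixed comment lines allowed. Every row is
#' validated against the SV call invariants; rejected rows are reported via
#' [rejected_rows()]. Columns beyond the dialect mapping are preserved.
#'
#' @param path file path.
#' @param dialect an [smap_dialect()] describing the file's columns.
#' @param patient_id fallback patient id when the file has no sample
#'   column.
#' @return A tibble of validated SV calls (one row per call).
#' @export
read_sv_calls <- function(path, dialect = smap_dialect(),
                          patient_id = NULL) {
  df <- read_tsv_quiet(path)
  if (nrow(df) == 0) {
    return(attach_rejected(empty_sv_calls(), rejected_empty(), 0L))
  }
  cols <- dialect$columns
  optional <- c("patient_id", "vaf", "self_molecules")
  require_columns(df, unlist(cols[setdiff(names(cols), optional)]), path)
  out <- tibble::tibble(
    call_id = as.character(df[[cols$call_id]]),
    patient_id = if (cols$patient_id %in% names(df)) {
      as.character(df[[cols$patient_id]])
    } else {
      rep(patient_id %||% NA_character_, nrow(df))
    },
    sv_type = unname(dialect$type_map[as.character(df[[cols$sv_type]])]),
    chrom1 = as.character(df[[cols$chrom1]]),
    pos1 = as.numeric(df[[cols$pos1]]),
    chrom2 = as.character(df[[cols$chrom2]]),
    pos2 = as.numeric(df[[cols$pos2]]),
    size_bp = as.numeric(df[[cols$size_bp]]),
    confidence = as.numeric(df[[cols$confidence]]),
    raw_conf_left = as.numeric(df[[cols$raw_conf_left]]),
    raw_conf_right = as.numeric(df[[cols$raw_conf_right]]),
    labels_bp1 = as.numeric(df[[cols$labels_bp1]]),
    labels_bp2 = as.numeric(df[[cols$labels_bp2]]),
    self_molecules = if (cols$self_molecules %in% names(df)) {
      as.numeric(df[[cols$self_molecules]])
    } else NA_real_,
    vaf = if (cols$vaf %in% names(df)) as.numeric(df[[cols$vaf]]) else NA_real_
  )
  out$sv_type[is.na(out$sv_type)] <-
    paste0("unmapped:", df[[cols$sv_type]][is.na(out$sv_type)])
  extra <- setdiff(names(df), unlist(cols))
  out <- dplyr::bind_cols(out, df[extra])
  v <- validate_sv_calls(out)
  attach_rejected(v$calls, v$rejected, nrow(df))
}

empty_sv_calls <- function() {
  tibble::tibble(call_id = character(), patient_id = character(),
                 sv_type = character(), chrom1 = character(),
                 pos1 = numeric(), chrom2 = character(), pos2 = numeric(),
                 size_bp = numeric(), confidence = numeric(),
                 raw_conf_left = numeric(), raw_conf_right = numeric(),
                 labels_bp1 = numeric(), labels_bp2 = numeric(),
                 self_molecules = numeric(), vaf = numeric())
}

empty_cnv_calls <- function() {
  tibble::tibble(call_id = character(), patient_id = character(),
                 chrom = character(), start = numeric(), end = numeric(),
                 cnv_type = character(), confidence = numeric(),
                 cell_fraction = numeric())
}

rejected_empty <- function() {
  tibble::tibble(row = integer(), call_id = character(),
                 reason = character())
}

#' Read a CNV call table
#'
#' Tab-separated with columns `call_id`, `patient_id`, `chrom`, `start`,
#' `end`, `cnv_type` (gain/loss), `confidence`, `cell_fraction`.
#' Coordinates are 1-based inclusive, so a row 13:50000000-50900000 spans
#' 900,001 bp.
#'
#' @inheritParams read_sv_calls
#' @return A tibble of validated CNV calls.
#' @export
read_cnv_calls <- function(path, patient_id = NULL) {
  df <- read_tsv_quiet(path)
  if (nrow(df) == 0) {
    return(attach_rejected(empty_cnv_calls(), rejected_empty(), 0L))
  }
  require_columns(df, setdiff(CNV_COLUMNS, c("patient_id", "cell_fraction")),
                  path)
  out <- tibble::tibble(
    call_id = as.character(df$call_id),
    patient_id = if ("patient_id" %in% names(df)) {
      as.character(df$patient_id)
    } else rep(patient_id %||% NA_character_, nrow(df)),
    chrom = as.character(df$chrom),
    start = as.numeric(df$start), end = as.numeric(df$end),
    cnv_type = as.character(df$cnv_type),
    confidence = as.numeric(df$confidence),
    cell_fraction = if ("cell_fraction" %in% names(df)) {
      as.numeric(df$cell_fraction)
    } else NA_real_
  )
  extra <- setdiff(names(df), CNV_COLUMNS)
  out <- dplyr::bind_cols(out, df[extra])
  v <- validate_cnv_calls(out)
  attach_rejected(v$calls, v$rejected, nrow(df))
}

#' Read both call tables of a sample export
#'
#' @param sv_path,cnv_path file paths.
#' @param dialect an [smap_dialect()].
#' @return A list with elements `sv` and `cnv`.
#' @export
read_call_tables <- function(sv_path, cnv_path, dialect = smap_dialect()) {
  list(sv = read_sv_calls(sv_path, dialect = dialect),
       cnv = read_cnv_calls(cnv_path))
}

#' Write SV / CNV call tables
#'
#' Deterministic column order and formatting; `write_sv_calls()` followed
#' by [read_sv_calls()] round-trips validated tables exactly.
#'
#' @param calls a call tibble.
#' @param path output file path.
#' @param dialect an [smap_dialect()] giving the output column names.
#' @return `path`, invisibly.
#' @export
write_sv_calls <- function(calls, path, dialect = smap_dialect()) {
  cols <- dialect$columns
  out <- calls[SV_COLUMNS]
  names(out) <- unlist(cols[SV_COLUMNS])
  extra <- setdiff(names(calls), SV_COLUMNS)
  out <- dplyr::bind_cols(out, calls[sort(extra)])
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_sv_calls
#' @export
write_cnv_calls <- function(calls, path) {
  out <- calls[CNV_COLUMNS]
  extra <- setdiff(names(calls), CNV_COLUMNS)
  out <- dplyr::bind_cols(out, calls[sort(extra)])
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a BED region file
#'
#' Standard BED: 0-based half-open; converted at the boundary to the
#' internal 1-based inclusive convention (`start+1`, `end`). Overlapping
#' lines are retained as-is (no merging). A 4th column, when present, is
#' kept as `name`; for polymorphism sets it carries the sign
#' ("gain"/"loss").
#'
#' @param path BED file path.
#' @param label region-set label, e.g. `"masked"` or `"polymorphism"`.
#' @return A tibble with columns `chrom`, `start`, `end`, `label`, `name`.
#' @export
read_bed_regions <- function(path, label = "masked") {
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), label = character(),
                          name = character()))
  }
  parts <- strsplit(lines, "\t| +")
  n_fields <- lengths(parts)
  if (any(n_fields < 3)) {
    rlang::abort(sprintf("%s: BED line with fewer than 3 fields (line %d)",
                         path, which(n_fields < 3)[1]))
  }
  start0 <- as.numeric(vapply(parts, `[`, "", 2))
  end0 <- as.numeric(vapply(parts, `[`, "", 3))
  if (any(is.na(start0) | is.na(end0) | start0 < 0 | end0 < start0)) {
    rlang::abort(paste0(path, ": negative or inverted BED coordinates"))
  }
  tibble::tibble(
    chrom = strip_chr(vapply(parts, `[`, "", 1)),
    start = start0 + 1,
    end = end0,
    label = label,
    name = ifelse(n_fields >= 4, vapply(parts, `[`, "", 4), NA_character_)
  )
}

#' @rdname read_bed_regions
#' @param bed_paths named character vector of BED paths; names are the
#'   region-set labels.
#' @export
read_region_sets <- function(bed_paths) {
  stopifnot(!is.null(names(bed_paths)))
  purrr::imap(as.list(bed_paths), function(p, lab) read_bed_regions(p, lab))
}

#' @rdname read_bed_regions
#' @param regions a region tibble in internal coordinates.
#' @export
write_bed_regions <- function(regions, path) {
  out <- data.frame(chrom = regions$chrom,
                    start = format(regions$start - 1, scientific = FALSE,
                                   trim = TRUE),
                    end = format(regions$end, scientific = FALSE,
                                 trim = TRUE))
  if ("name" %in% names(regions) && any(!is.na(regions$name))) {
    out$name <- ifelse(is.na(regions$name), ".", regions$name)
  }
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

validate_known <- function(df) {
  df$.row <- seq_len(nrow(df))
  reasons <- rep(NA_character_, nrow(df))
  note <- function(idx, msg) {
    idx[is.na(idx)] <- TRUE
    reasons[idx & is.na(reasons)] <<- msg
  }
  note(!df$ab_class %in% KNOWN_CLASSES, "unknown ab_class")
  note(!df$technique %in% c("CMA", "FISH", "CBA"), "unknown technique")
  cnv <- df$ab_class %in% c("cnv_gain", "cnv_loss", "trisomy")
  note(cnv & (is.na(df$chrom) | is.na(df$start) | is.na(df$end)),
       "CNV-class record without interval")
  bp <- df$ab_class %in% c("translocation", "inversion", "add_breakpoint")
  has_bp1 <- !is.na(df$chrom1) & !is.na(df$pos1)
  has_bp2 <- !is.na(df$chrom2) & !is.na(df$pos2)
  note(bp & !has_bp1 & !has_bp2, "breakpoint-class record without breakpoints")
  note(df$ab_class == "add_breakpoint" & has_bp1 & has_bp2,
       "add_breakpoint must carry exactly one breakpoint")
  if (any(duplicated(df$ab_id))) {
    rlang::abort(paste0("duplicate ab_id: ",
                        paste(unique(df$ab_id[duplicated(df$ab_id)]),
                              collapse = ", ")))
  }
  keep <- is.na(reasons)
  list(records = tibble::as_tibble(df[keep, setdiff(names(df), ".row")]),
       rejected = tibble::tibble(row = df$.row[!keep],
                                 call_id = df$ab_id[!keep],
                                 reason = reasons[!keep]))
}

validate_clinical <- function(df) {
  bad <- df$treated & !df$pre_treated & is.na(df$ttft_months)
  if (any(bad, na.rm = TRUE)) {
    rlang::abort(sprintf(
      "treated patients without ttft_months: %s",
      paste(df$patient_id[which(bad)], collapse = ", ")))
  }
  if (any(df$ttft_months < 0, na.rm = TRUE)) {
    rlang::abort("negative ttft_months")
  }
  tibble::as_tibble(df)
}

#' Read the known-aberration and clinical tables
#'
#' The known-aberration table is the per-patient inventory of abnormalities
#' compiled from chromosome banding (CBA), FISH and microarray (CMA)
#' reports; the clinical table carries the time-to-first-treatment
#' covariates. Patient ids must cross-reference: a known-aberration row for
#' a patient absent from the clinical table is an error.
#'
#' @param known_path,clinical_path TSV file paths.
#' @return A list with elements `known` and `clinical`.
#' @export
read_cohort <- function(known_path, clinical_path) {
  known <- read_tsv_quiet(known_path)
  clinical <- read_tsv_quiet(clinical_path)
  require_columns(clinical, CLINICAL_COLUMNS, clinical_path)
  require_columns(known, c("ab_id", "patient_id", "technique", "ab_class"),
                  known_path)
  for (col in setdiff(KNOWN_COLUMNS, names(known))) known[[col]] <- NA
  known <- known[KNOWN_COLUMNS]
  known$chrom <- strip_chr(known$chrom)
  known$chrom1 <- strip_chr(known$chrom1)
  known$chrom2 <- strip_chr(known$chrom2)
  orphans <- setdiff(known$patient_id, clinical$patient_id)
  if (length(orphans) > 0) {
    rlang::abort(paste0("known-aberration patient ids absent from the ",
                        "clinical table: ", paste(orphans, collapse = ", ")))
  }
  v <- validate_known(known)
  clinical <- validate_clinical(clinical)
  list(known = attach_rejected(v$records, v$rejected, nrow(known)),
       clinical = clinical)
}

#' @rdname read_cohort
#' @param known validated known-aberration tibble.
#' @param path output path.
#' @export
write_known_aberrations <- function(known, path) {
  readr::write_tsv(known[KNOWN_COLUMNS], path, progress = FALSE)
  invisible(path)
}

#' @rdname read_cohort
#' @param clinical validated clinical tibble.
#' @export
write_clinical_table <- function(clinical, path) {
  out <- clinical[c(CLINICAL_COLUMNS,
                    setdiff(names(clinical), CLINICAL_COLUMNS))]
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
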