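# End-to-end orchestration: simulate -> curate -> concordance ->
# complexity -> survival as one reproducible run with a machine-readable
# manifest (config snapshot, file digests, stage timings, seed).

#' Run the full pipeline
#'
#' Executes the five stages in order on a simulated cohort (or on tables
#' read from `input_dir`), writes every stage output as TSV/JSON under
#' `outdir` and records a manifest with MD5 digests of all files read
#' and written, per-stage timings, the config snapshot and the seed.
#' Reruns with the same config and seed produce identical digests.
#'
#' @param outdir output directory.
#' @param seed integer seed for the simulation stage.
#' @param sim a [sim_config()].
#' @param curation a [curation_config()].
#' @param criteria a [match_criteria()].
#' @param rescue apply targeted rescue with
#'   [permissive_curation_config()].
#' @param input_dir optional directory of existing tables (as written by
#'   [write_cohort()]); when given, the simulate stage is skipped and
#'   the tables are read instead.
#' @return The manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(outdir, seed = 1, sim = sim_config(),
                         curation = curation_config(),
                         criteria = match_criteria(), rescue = TRUE,
                         input_dir = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = seed,
                   version = as.character(utils::packageVersion("ogmcll")),
                   config = list(sim = unclass(sim),
                                 curation = unclass(curation),
                                 criteria = unclass(criteria)),
                   stages = list(), files = list())
  t_all <- proc.time()[["elapsed"]]
  stage <- function(name, fn) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fn(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "error",
                                       message = conditionMessage(e))
      write_manifest(manifest, outdir)
      rlang::abort(sprintf("stage '%s' failed: %s", name,
                           conditionMessage(e)))
    })
    manifest$stages[[name]] <<- list(
      status = "ok",
      elapsed_s = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }

  cohort <- stage("simulate", function() {
    if (!is.null(input_dir)) {
      read_cohort_dir(input_dir)
    } else {
      ch <- simulate_cohort(sim, seed = seed)
      write_cohort(ch, file.path(outdir, "cohort"))
      ch
    }
  })

  curated <- stage("curate", function() {
    cur <- suppressWarnings(curate(
      cohort$sv, cohort$cnv, masks = cohort$masks,
      polymorphisms = cohort$polymorphism_regions,
      known = if (rescue) cohort$inventory else NULL, cfg = curation,
      permissive_cfg = if (rescue) permissive_curation_config(curation)
        else NULL))
    out <- tidy(cur)
    out$provenance <- vapply(out$provenance, paste, "", collapse = ",")
    readr::write_tsv(out, file.path(outdir, "curated.tsv"),
                     progress = FALSE)
    jsonlite::write_json(
      list(summary = attr(cur, "summary"),
           chromothripsis = attr(cur, "chromothripsis")),
      file.path(outdir, "curation_summary.json"), digits = NA)
    cur
  })

  concordance <- stage("concord", function() {
    if (nrow(cohort$inventory) == 0) return(NULL)
    res <- match_calls(cohort$inventory, curated, criteria) |>
      assign_discrepancy_reasons(
        cohort$inventory, masks = cohort$masks,
        chromothripsis = attr(curated, "chromothripsis"))
    summ <- summarize_concordance(res)
    out <- res
    out$ogm_ids <- vapply(out$ogm_ids, paste, "", collapse = ",")
    readr::write_tsv(out, file.path(outdir, "concordance.tsv"),
                     progress = FALSE)
    jsonlite::write_json(list(overall = summ$overall,
                              by_class = summ$by_class,
                              reasons = summ$reasons),
                         file.path(outdir, "concordance_summary.json"),
                         digits = NA)
    list(results = res, summary = summ)
  })

  profiles <- stage("complexity", function() {
    pr <- count_abnormalities(curated, cohort$clinical)
    readr::write_tsv(pr, file.path(outdir, "patient_profiles.tsv"),
                     progress = FALSE)
    cross <- as.data.frame(table(
      combined_high = pr$combined_high, ogm_class = pr$ogm_class))
    jsonlite::write_json(cross, file.path(outdir, "risk_cross.json"),
                         digits = NA)
    pr
  })

  survival_res <- stage("survive", function() {
    if (is.null(cohort$clinical)) {
      rlang::abort("clinical table required for the survive stage")
    }
    el <- profiles[!profiles$pre_treated & !is.na(profiles$ttft_months), ]
    res <- list(
      km = glance(km_estimate(el)),
      log_rank = if (nlevels(droplevels(factor(el$ogm_class))) == 2 &&
                       any(el$treated)) {
        log_rank_test(el, "ogm_class")
      } else NULL,
      c_index = c_index(el, "n_ogm"))
    jsonlite::write_json(res, file.path(outdir, "survival.json"),
                         digits = NA)
    res
  })

  manifest$elapsed_s <- round(proc.time()[["elapsed"]] - t_all, 3)
  manifest$files <- digest_dir(outdir)
  write_manifest(manifest, outdir)
  invisible(list(manifest = manifest, curated = curated,
                 concordance = concordance, profiles = profiles,
                 survival = survival_res))
}

digest_dir <- function(dir) {
  files <- list.files(dir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  md5 <- tools::md5sum(files)
  lapply(split(unname(md5), sub(paste0("^", dir, "/?"), "", files)),
         identity)
}

write_manifest <- function(manifest, outdir) {
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

#' @rdname run_pipeline
#' @export
read_cohort_dir <- function(input_dir) {
  need <- c("sv_calls.tsv", "cnv_calls.tsv", "known_aberrations.tsv",
            "clinical.tsv")
  missing <- need[!file.exists(file.path(input_dir, need))]
  if (length(missing) > 0) {
    rlang::abort(paste0("missing input table(s): ",
                        paste(missing, collapse = ", ")))
  }
  sv <- read_sv_calls(file.path(input_dir, "sv_calls.tsv"))
  cnv <- read_cnv_calls(file.path(input_dir, "cnv_calls.tsv"))
  ck <- read_cohort(file.path(input_dir, "known_aberrations.tsv"),
                    file.path(input_dir, "clinical.tsv"))
  masks_path <- file.path(input_dir, "masked_regions.bed")
  poly_path <- file.path(input_dir, "polymorphism_regions.bed")
  known <- ck$known
  structure(list(
    truth = NULL, sv = sv, cnv = cnv, known = known,
    inventory = suppressWarnings(build_known_inventory(
      known[known$technique == "CBA", ],
      known[known$technique == "FISH", ],
      known[known$technique == "CMA", ])),
    clinical = ck$clinical,
    masks = if (file.exists(masks_path)) {
      read_bed_regions(masks_path, "masked")
    } else NULL,
    polymorphism_regions = if (file.exists(poly_path)) {
      read_bed_regions(poly_path, "polymorphism")
    } else NULL),
    class = "ogm_cohort")
}
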