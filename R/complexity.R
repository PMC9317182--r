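# Genomic-complexity scoring and the agreement / group-comparison
# statistics: per-patient abnormality counts, two-tier OGM risk
# classification (complex at >= 10 countable abnormalities) against the
# 0-2 / 3-4 / >=5 banding and microarray schemes, Cohen's kappa, Fisher
# exact, Spearman and Mann-Whitney tests, and a Table-style group report.

#' Risk classification schemes
#'
#' `OGM`: non-complex (`NC_OGM`) below 10 abnormalities, complex
#' (`C_OGM`) at 10 or more. `CBA`/`CMA`/`CBA_or_CMA`: low risk at 0-2
#' abnormalities, intermediate at 3-4, high at >= 5 (the complexity bins
#' validated for banding and microarray counts in CLL).
#'
#' @param name one of `"OGM"`, `"CBA"`, `"CMA"`, `"CBA_or_CMA"`.
#' @return A list of class `risk_scheme` with `bin_edges` and `labels`.
#' @export
risk_scheme <- function(name = c("OGM", "CBA", "CMA", "CBA_or_CMA")) {
  name <- match.arg(name)
  if (name == "OGM") {
    structure(list(name = name, bin_edges = 10,
                   labels = c("NC_OGM", "C_OGM")), class = "risk_scheme")
  } else {
    structure(list(name = name, bin_edges = c(3, 5),
                   labels = c("Low", "Intermediate", "High")),
              class = "risk_scheme")
  }
}

#' Classify a patient by abnormality count
#'
#' Half-open binning on the scheme's edges; monotone in the count.
#'
#' @param count non-negative abnormality count (vectorized).
#' @param scheme a [risk_scheme()].
#' @return A factor with the scheme's labels.
#' @export
#' @examples
#' classify_risk(c(9, 10), risk_scheme("OGM"))
#' classify_risk(c(2, 3, 5), risk_scheme("CBA"))
classify_risk <- function(count, scheme = risk_scheme("OGM")) {
  if (any(count < 0, na.rm = TRUE)) rlang::abort("negative abnormality count")
  idx <- findInterval(count, scheme$bin_edges) + 1
  factor(scheme$labels[idx], levels = scheme$labels)
}

#' Count countable abnormalities per patient
#'
#' Deduplicated records are counted once (through their surviving
#' record); artifact-flagged and filtered records are excluded. Clinical
#' covariates, conventional-method risk classes and per-patient
#' chromothripsis flags are joined in when available.
#'
#' @param curated a [curate()] result (or any abnormality-record tibble).
#' @param clinical optional validated clinical tibble; patients present
#'   only there get zero counts.
#' @return A patient-profile tibble with counts (`n_ogm`, `n_ogm_cnv`,
#'   `n_ogm_transloc`, `n_ogm_other`), `ogm_class`, CBA/CMA risk classes
#'   and `combined_high` (>= 5 abnormalities by CBA and/or CMA) when
#'   clinical counts are available, and `chromothripsis`.
#' @export
count_abnormalities <- function(curated, clinical = NULL) {
  cur <- tibble::as_tibble(curated)
  counts <- cur |>
    dplyr::filter(.data$countable) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      n_ogm = dplyr::n(),
      n_ogm_cnv = sum(is_cnv_class(.data$ab_class)),
      n_ogm_transloc = sum(is_transloc_class(.data$ab_class)),
      .groups = "drop") |>
    dplyr::mutate(n_ogm_other = .data$n_ogm - .data$n_ogm_cnv -
                    .data$n_ogm_transloc)
  if (!is.null(clinical)) {
    counts <- clinical |>
      dplyr::select(dplyr::all_of(CLINICAL_COLUMNS)) |>
      dplyr::left_join(counts, by = "patient_id") |>
      dplyr::mutate(dplyr::across(dplyr::starts_with("n_ogm"),
                                  ~ dplyr::coalesce(.x, 0L)))
  }
  counts$ogm_class <- classify_risk(counts$n_ogm, risk_scheme("OGM"))
  if (!is.null(clinical)) {
    counts$cba_class <- classify_risk(counts$n_abn_cba, risk_scheme("CBA"))
    counts$cma_class <- classify_risk(counts$n_abn_cma, risk_scheme("CMA"))
    counts$combined_high <- dplyr::coalesce(counts$n_abn_cba >= 5, FALSE) |
      dplyr::coalesce(counts$n_abn_cma >= 5, FALSE)
  }
  ct <- attr(curated, "chromothripsis")
  if (!is.null(ct)) {
    flags <- ct |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(chromothripsis = any(.data$chromothripsis),
                       .groups = "drop")
    counts <- counts |>
      dplyr::left_join(flags, by = "patient_id") |>
      dplyr::mutate(chromothripsis = dplyr::coalesce(.data$chromothripsis,
                                                     FALSE))
  }
  counts
}

as_2x2 <- function(x) {
  if (is.matrix(x)) {
    stopifnot(all(dim(x) == c(2, 2)))
    return(x)
  }
  stopifnot(length(x) == 4)
  matrix(as.numeric(x), nrow = 2, byrow = TRUE)
}

#' Cohen's kappa for a 2x2 cross-classification
#'
#' kappa = (po - pe) / (1 - pe) with po the observed agreement and pe the
#' chance agreement from the margins. The p-value is a one-sided
#' large-sample z test of kappa = 0 using the standard error under the
#' null (Fleiss).
#'
#' @param x a 2x2 matrix (rows = classifier 1, columns = classifier 2) or
#'   a length-4 vector `c(a, b, c, d)` filling the table by row.
#' @return A one-row tibble: `kappa`, `z`, `p_value`, `n`.
#' @export
#' @examples
#' cohen_kappa(c(11, 1, 3, 27))
cohen_kappa <- function(x) {
  t <- as_2x2(x)
  n <- sum(t)
  if (n < 2) rlang::abort("kappa needs n >= 2")
  po <- sum(diag(t)) / n
  row_p <- rowSums(t) / n
  col_p <- colSums(t) / n
  pe <- sum(row_p * col_p)
  if (1 - pe < .Machine$double.eps) {
    rlang::abort("degenerate margins: chance agreement is 1, kappa undefined")
  }
  kappa <- (po - pe) / (1 - pe)
  se0 <- sqrt(pe + pe^2 - sum(row_p * col_p * (row_p + col_p))) /
    ((1 - pe) * sqrt(n))
  z <- kappa / se0
  tibble::tibble(kappa = kappa, z = z,
                 p_value = stats::pnorm(z, lower.tail = FALSE), n = n)
}

#' Fisher exact test for a 2x2 table
#'
#' Exact hypergeometric two-sided p-value (sum of the probabilities of
#' tables, at the observed margins, no more likely than the observed
#' one), with the conditional maximum-likelihood odds ratio. An empty
#' margin yields p = 1 with a warning.
#'
#' @inheritParams cohen_kappa
#' @return A one-row tibble: `p_value`, `odds_ratio`, `n`.
#' @export
#' @examples
#' fisher_exact_2x2(c(7, 5, 1, 29))
fisher_exact_2x2 <- function(x) {
  t <- as_2x2(x)
  n <- sum(t)
  if (n < 1) rlang::abort("empty table")
  if (any(rowSums(t) == 0) || any(colSums(t) == 0)) {
    rlang::warn("empty margin: p = 1 by convention")
    or <- if (t[1, 1] * t[2, 2] == 0 && t[1, 2] * t[2, 1] == 0) NA_real_
          else (t[1, 1] * t[2, 2]) / (t[1, 2] * t[2, 1])
    return(tibble::tibble(p_value = 1, odds_ratio = or, n = n))
  }
  ft <- stats::fisher.test(t)
  tibble::tibble(p_value = ft$p.value, odds_ratio = unname(ft$estimate),
                 n = n)
}

#' Spearman rank correlation
#'
#' Rho on mid-ranks (ties averaged), p-value from the t approximation.
#'
#' @param x,y equal-length numeric vectors (n >= 3).
#' @return A one-row tibble: `rho`, `p_value`, `n`.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) rlang::abort("spearman needs n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rlang::abort("zero variance: rho undefined")
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x))
}

#' Mann-Whitney U test
#'
#' U statistic with mid-rank tie handling; exact p-value when the smaller
#' group has at most 8 observations and the data are tie-free, normal
#' approximation (tie-corrected) otherwise. Identical constant groups
#' give p = 1.
#'
#' @param g1,g2 numeric vectors (non-empty).
#' @return A one-row tibble: `u`, `p_value`, `n1`, `n2`.
#' @export
mann_whitney_u <- function(g1, g2) {
  stopifnot(length(g1) > 0, length(g2) > 0)
  n1 <- length(g1)
  n2 <- length(g2)
  r <- rank(c(g1, g2))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (stats::sd(c(g1, g2)) == 0) {
    return(tibble::tibble(u = u, p_value = 1, n1 = n1, n2 = n2))
  }
  ties <- any(duplicated(c(g1, g2)))
  wt <- suppressWarnings(
    stats::wilcox.test(g1, g2, exact = min(n1, n2) <= 8 && !ties,
                       correct = FALSE))
  tibble::tibble(u = u, p_value = wt$p.value, n1 = n1, n2 = n2)
}

summarize_numeric <- function(x, group) {
  tapply(x, group, function(v) {
    v <- v[!is.na(v)]
    sprintf("%g (%g-%g)", stats::median(v), min(v), max(v))
  })
}

#' Compare patient groups on clinical and genomic covariates
#'
#' For each categorical (logical) covariate a Fisher exact test (or
#' chi-square when all expected counts are >= 5) on the 2x2 table against
#' the grouping; for each count/numeric covariate a Mann-Whitney test
#' with medians and ranges. Rows with missing covariate values are
#' excluded per covariate and the denominators reported.
#'
#' @param profiles patient-profile tibble (see [count_abnormalities()]).
#' @param group name of a two-level grouping column (default
#'   `"ogm_class"`).
#' @param cat_vars,num_vars covariate column names; defaults pick the
#'   logical and count columns present.
#' @return A tibble with one row per covariate: per-group summaries,
#'   denominators, test used and p-value.
#' @export
compare_groups <- function(profiles, group = "ogm_class",
                           cat_vars = NULL, num_vars = NULL) {
  g <- factor(profiles[[group]])
  if (nlevels(droplevels(g)) != 2) {
    rlang::abort("compare_groups needs exactly two non-empty groups")
  }
  g <- droplevels(g)
  if (is.null(cat_vars)) {
    cat_vars <- names(profiles)[vapply(profiles, is.logical, TRUE)]
  }
  if (is.null(num_vars)) {
    num_vars <- intersect(c("n_ogm", "n_ogm_cnv", "n_ogm_transloc",
                            "n_abn_cba", "n_abn_cma", "ttft_months"),
                          names(profiles))
  }
  rows <- list()
  for (v in cat_vars) {
    x <- profiles[[v]]
    ok <- !is.na(x) & !is.na(g)
    tab <- table(factor(x[ok], levels = c(TRUE, FALSE)), g[ok])
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    use_chisq <- all(expected >= 5)
    p <- if (use_chisq) {
      stats::chisq.test(tab, correct = FALSE)$p.value
    } else {
      fisher_exact_2x2(matrix(as.numeric(tab), 2))$p_value
    }
    pos <- tapply(x[ok], g[ok], sum)
    n <- tapply(x[ok], g[ok], length)
    rows[[v]] <- tibble::tibble(
      covariate = v, type = "categorical",
      group1 = sprintf("%d/%d (%.1f%%)", pos[1], n[1], 100 * pos[1] / n[1]),
      group2 = sprintf("%d/%d (%.1f%%)", pos[2], n[2], 100 * pos[2] / n[2]),
      n_used = sum(ok), test = if (use_chisq) "chi-square" else "fisher",
      p_value = p)
  }
  for (v in num_vars) {
    x <- profiles[[v]]
    ok <- !is.na(x) & !is.na(g)
    if (sum(ok) == 0) next
    s <- summarize_numeric(x[ok], g[ok])
    p <- mann_whitney_u(x[ok][g[ok] == levels(g)[1]],
                        x[ok][g[ok] == levels(g)[2]])$p_value
    rows[[v]] <- tibble::tibble(
      covariate = v, type = "numeric", group1 = s[1], group2 = s[2],
      n_used = sum(ok), test = "mann-whitney", p_value = p)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "groups") <- levels(g)
  out
}
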