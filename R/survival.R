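# Time-to-first-treatment analysis: Kaplan-Meier estimation, log-rank
# comparison of complexity groups, and Harrell's concordance index for
# abnormality counts used as continuous predictors. Patients treated
# before genetic testing are expected to be excluded upstream
# (pre_treated flag in the clinical table).

survival_inputs <- function(records, time = "ttft_months",
                            event = "treated") {
  t <- records[[time]]
  e <- as.logical(records[[event]])
  if (any(is.na(t)) || any(!is.finite(t))) {
    rlang::abort("missing or non-finite follow-up times")
  }
  if (any(t < 0)) rlang::abort("negative follow-up times")
  list(time = t, event = e)
}

#' Kaplan-Meier estimate of time to first treatment
#'
#' Product-limit estimator; records censored at t remain at risk through
#' t. The median is the smallest time at which the survival step falls to
#' 0.5 or below, undefined (NA) when never reached.
#'
#' @param records tibble with a follow-up time column and an event
#'   indicator column.
#' @param time,event column names (defaults `ttft_months` / `treated`).
#' @return An object of class `ogm_km`: `tidy()` gives the step table
#'   (`time`, `n_risk`, `n_event`, `survival`), `glance()` the median and
#'   counts, `autoplot()` the step curve.
#' @export
km_estimate <- function(records, time = "ttft_months", event = "treated") {
  stopifnot(nrow(records) >= 1)
  s <- survival_inputs(records, time, event)
  fit <- survival::survfit(survival::Surv(s$time, s$event) ~ 1)
  curve <- tibble::tibble(time = fit$time, n_risk = fit$n.risk,
                          n_event = fit$n.event, n_censor = fit$n.censor,
                          survival = fit$surv)
  med_idx <- which(curve$survival <= 0.5 & curve$n_event > 0)
  median_time <- if (length(med_idx) > 0) curve$time[min(med_idx)] else NA_real_
  structure(list(curve = curve, median = median_time, n = length(s$time),
                 n_events = sum(s$event), fit = fit),
            class = "ogm_km")
}

#' @export
tidy.ogm_km <- function(x, ...) x$curve

#' @export
glance.ogm_km <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events, median = x$median)
}

#' @export
print.ogm_km <- function(x, ...) {
  cat(sprintf("<ogm_km> n = %d, events = %d, median = %s\n", x$n,
              x$n_events,
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' Log-rank comparison of two groups
#'
#' Standard 1-df log-rank statistic over the pooled event times, p-value
#' from the chi-square upper tail. Invariant to swapping the group
#' labels; 0 on identical groups.
#'
#' @inheritParams km_estimate
#' @param group name of a two-level grouping column.
#' @return A one-row tibble: `chisq`, `df`, `p_value`, `n`, plus
#'   per-group medians.
#' @export
log_rank_test <- function(records, group, time = "ttft_months",
                          event = "treated") {
  s <- survival_inputs(records, time, event)
  g <- factor(records[[group]])
  g <- droplevels(g)
  if (nlevels(g) != 2) rlang::abort("log-rank needs exactly two groups")
  if (all(!s$event)) rlang::abort("no events observed in either group")
  sd <- survival::survdiff(survival::Surv(s$time, s$event) ~ g)
  meds <- vapply(levels(g), function(l) {
    km_estimate(records[g == l, , drop = FALSE], time, event)$median
  }, numeric(1))
  tibble::tibble(chisq = sd$chisq, df = 1,
                 p_value = stats::pchisq(sd$chisq, df = 1,
                                         lower.tail = FALSE),
                 n = length(s$time),
                 median_1 = meds[1], median_2 = meds[2])
}

#' Harrell's concordance index for right-censored data
#'
#' Among pairs whose ordering is determinable under censoring (the
#' shorter follow-up ends in an event), the fraction in which the
#' shorter-time member carries the higher predictor value; predictor
#' ties contribute 0.5. Orientation: a larger abnormality count is taken
#' to predict earlier treatment, so perfectly prognostic counts give
#' C = 1. Invariant under strictly monotone transforms of the predictor.
#'
#' @inheritParams km_estimate
#' @param predictor name of the numeric predictor column (e.g. `n_ogm`).
#' @return A one-row tibble: `c_index`, `n_pairs` (comparable pairs),
#'   `n`.
#' @export
c_index <- function(records, predictor, time = "ttft_months",
                    event = "treated") {
  s <- survival_inputs(records, time, event)
  p <- records[[predictor]]
  stopifnot(is.numeric(p), !any(is.na(p)))
  n <- length(p)
  ti <- matrix(s$time, n, n)
  ei <- matrix(s$event, n, n)
  tj <- t(ti)
  ej <- t(ei)
  pi_ <- matrix(p, n, n)
  pj <- t(pi_)
  comparable <- (ti < tj & ei) | (ti == tj & ei & !ej)
  diag(comparable) <- FALSE
  if (sum(comparable) == 0) {
    rlang::abort("no comparable pairs: concordance undefined")
  }
  concordant <- sum(comparable & pi_ > pj)
  tied <- sum(comparable & pi_ == pj)
  tibble::tibble(c_index = (concordant + 0.5 * tied) / sum(comparable),
                 n_pairs = sum(comparable), n = n)
}

#' @rdname km_estimate
#' @param object an `ogm_km` object.
#' @param ... unused.
#' @export
autoplot.ogm_km <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(time = 0, survival = 1),
    object$curve[c("time", "survival")]
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time to first treatment (months)",
                  y = "Treatment-free proportion") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curves by group
#'
#' Step curves of treatment-free survival for each level of a grouping
#' column, with the log-rank p-value in the subtitle.
#'
#' @inheritParams log_rank_test
#' @return A ggplot object.
#' @export
plot_km_by_group <- function(records, group, time = "ttft_months",
                             event = "treated") {
  g <- factor(records[[group]])
  curves <- purrr::map(levels(g), function(l) {
    km <- km_estimate(records[g == l, , drop = FALSE], time, event)
    dplyr::bind_rows(tibble::tibble(time = 0, survival = 1),
                     km$curve[c("time", "survival")]) |>
      dplyr::mutate(group = l)
  }) |> dplyr::bind_rows()
  lr <- log_rank_test(records, group, time, event)
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$time, y = .data$survival,
                                       color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time to first treatment (months)",
                  y = "Treatment-free proportion", color = group,
                  subtitle = sprintf("log-rank p = %.3g", lr$p_value)) +
    ggplot2::theme_minimal()
}
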