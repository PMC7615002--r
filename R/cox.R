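# Hazard-ratio estimation from cohort data: Cox proportional hazards on an
# age timescale (entry age as left truncation), stratified jointly by region
# and 5-year baseline-age band, with Efron tie handling; cause-specific and
# Fine-Gray competing-risk variants; episode splitting by age at risk; and
# population attributable risk.

#' Fit a stratified Cox model on the age timescale
#'
#' Hazard ratios for an exposure (typically the lifestyle-score group) from
#' a cohort table, using age as the timescale: subjects enter the risk set
#' at their entry age (left truncation) and leave at their exit age. The
#' partial likelihood is stratified jointly by region and by 5-year band of
#' age at baseline, with the Efron approximation for ties.
#'
#' @param cohort Cohort tibble with columns `entry_age`, `exit_age`,
#'   `event` (0/1), `cause`, `region`, and the exposure/covariate columns.
#' @param exposure Name of the exposure column (coerced to a factor; the
#'   first level is the reference).
#' @param covariates Character vector of adjustment covariate columns.
#' @param strata Character vector of stratification columns; a 5-year
#'   baseline-age band stratum is always added.
#' @param cause `"all"` for all-cause mortality, or a cause label for a
#'   cause-specific fit in which competing deaths are censored at their
#'   occurrence.
#' @param sex Optional `"M"`/`"W"` to restrict the cohort to one sex
#'   (`NULL`, the default, uses everyone and labels results `"both"`).
#' @param exclude_first_years Drop subjects who died within this many years
#'   of entry before fitting (reverse-causality sensitivity; default 0).
#' @param age_band_width Width in years of the baseline-age stratum bands.
#' @return An object of class `hr_fit`: access the hazard-ratio table with
#'   [tidy()] (columns `level`, `cause`, `sex`, `hr`, `ci_low`, `ci_high`,
#'   `log_se`, `n_events`) and fit summaries with [glance()].
#' @export
fit_stratified_cox <- function(cohort,
                               exposure = "group",
                               covariates = character(),
                               strata = "region",
                               cause = "all",
                               sex = NULL,
                               exclude_first_years = 0,
                               age_band_width = 5) {
  need <- c("entry_age", "exit_age", "event", exposure, covariates, strata)
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols)) {
    abort_lg(paste("cohort lacks columns:", paste(missing_cols, collapse = ", ")))
  }
  if (any(cohort$exit_age <= cohort$entry_age)) {
    abort_lg("exit_age must exceed entry_age for every subject")
  }
  d <- tibble::as_tibble(cohort)
  sex_label <- if (is.null(sex)) "both" else sex
  if (!is.null(sex)) d <- d[d$sex == sex, ]

  if (exclude_first_years > 0) {
    early_death <- d$event == 1 &
      (d$exit_age - d$entry_age) <= exclude_first_years
    d <- d[!early_death, ]
  }

  status <- if (identical(cause, "all")) {
    d$event
  } else {
    if (!"cause" %in% names(d)) abort_lg("cohort lacks a cause column")
    as.integer(d$event == 1 & !is.na(d$cause) & d$cause == cause)
  }
  if (sum(status) == 0) abort_lg(sprintf("no events of cause '%s'", cause))

  d$.exposure <- droplevels(factor(d[[exposure]]))
  d$.status <- status
  d$.ageband <- (floor(d$entry_age) %/% age_band_width) * age_band_width

  lv <- levels(d$.exposure)
  if (length(lv) < 2L) {
    # degenerate contrast: no comparison possible
    tab <- tibble::tibble(
      level = lv, cause = cause, sex = sex_label,
      hr = 1, ci_low = NA_real_, ci_high = NA_real_, log_se = NA_real_,
      n_events = sum(status), note = "constant exposure: no contrast"
    )
    return(new_hr_fit(NULL, tab, exposure, cause, sex_label,
                      n = nrow(d), n_events = sum(status)))
  }

  rhs <- paste(c(".exposure", covariates,
                 sprintf("strata(%s)",
                         paste(c(strata, ".ageband"), collapse = ", "))),
               collapse = " + ")
  fml <- stats::as.formula(
    paste("Surv(entry_age, exit_age, .status) ~", rhs)
  )
  fit <- survival::coxph(fml, data = d, ties = "efron")

  events_by_level <- tapply(d$.status, d$.exposure, sum)
  tab <- hr_table_from_fit(fit, prefix = ".exposure", levels = lv[-1],
                           cause = cause, sex = sex_label)
  tab$n_events <- as.integer(events_by_level[tab$level])
  tab$note <- ifelse(!is.na(tab$log_se) & tab$log_se > 50,
                     "unbounded CI (zero events?)", NA_character_)
  ref <- tibble::tibble(
    level = lv[1], cause = cause, sex = sex_label, hr = 1,
    ci_low = 1, ci_high = 1, log_se = 0,
    n_events = as.integer(events_by_level[lv[1]]), note = "reference"
  )
  new_hr_fit(fit, dplyr::bind_rows(ref, tab), exposure, cause, sex_label,
             n = nrow(d), n_events = sum(status))
}

hr_table_from_fit <- function(fit, prefix, levels, cause, sex) {
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  keep <- startsWith(names(co), prefix)
  lev <- sub(prefix, "", names(co)[keep], fixed = TRUE)
  z <- qnorm(0.975)
  tibble::tibble(
    level = lev,
    cause = cause,
    sex = sex,
    hr = exp(unname(co[keep])),
    ci_low = exp(unname(co[keep]) - z * unname(se[keep])),
    ci_high = exp(unname(co[keep]) + z * unname(se[keep])),
    log_se = unname(se[keep])
  )
}

new_hr_fit <- function(fit, hr_table, exposure, cause, sex, n, n_events) {
  structure(
    list(fit = fit, hr_table = hr_table, exposure = exposure,
         cause = cause, sex = sex, n = n, n_events = n_events),
    class = "hr_fit"
  )
}

#' @export
print.hr_fit <- function(x, ...) {
  cat(sprintf("<hr_fit> exposure '%s', cause '%s', sex '%s': %d subjects, %d events\n",
              x$exposure, x$cause, x$sex, x$n, x$n_events))
  print(x$hr_table)
  invisible(x)
}

#' @rdname fit_stratified_cox
#' @param x An `hr_fit` object.
#' @param ... Unused.
#' @method tidy hr_fit
#' @export
tidy.hr_fit <- function(x, ...) x$hr_table

#' @rdname fit_stratified_cox
#' @method glance hr_fit
#' @export
glance.hr_fit <- function(x, ...) {
  if (is.null(x$fit)) {
    return(tibble::tibble(n = x$n, n_events = x$n_events,
                          loglik = NA_real_, concordance = NA_real_))
  }
  s <- summary(x$fit)
  tibble::tibble(
    n = x$n,
    n_events = x$n_events,
    loglik = unname(x$fit$loglik[2]),
    concordance = unname(s$concordance[1])
  )
}

#' Cause-specific and Fine-Gray competing-risk hazard ratios
#'
#' `method = "cause_specific"` fits the stratified Cox model of
#' [fit_stratified_cox()] with competing deaths censored at their
#' occurrence. `method = "fine_gray"` fits the proportional subdistribution
#' hazard model: subjects failing from competing causes are retained in
#' weighted risk sets via inverse-probability-of-censoring weights
#' (constructed with [survival::finegray()]), so the hazard ratio acts on
#' the cumulative incidence scale.
#'
#' @inheritParams fit_stratified_cox
#' @param cause Cause label whose mortality is modelled.
#' @param method `"cause_specific"` or `"fine_gray"`.
#' @return An `hr_fit` object (see [fit_stratified_cox()]).
#' @export
fit_cause_specific <- function(cohort,
                               cause,
                               method = c("cause_specific", "fine_gray"),
                               exposure = "group",
                               covariates = character(),
                               strata = "region",
                               sex = NULL,
                               exclude_first_years = 0,
                               age_band_width = 5) {
  method <- match.arg(method)
  if (method == "cause_specific") {
    return(fit_stratified_cox(cohort, exposure = exposure,
                              covariates = covariates, strata = strata,
                              cause = cause, sex = sex,
                              exclude_first_years = exclude_first_years,
                              age_band_width = age_band_width))
  }

  d <- tibble::as_tibble(cohort)
  sex_label <- if (is.null(sex)) "both" else sex
  if (!is.null(sex)) d <- d[d$sex == sex, ]
  if (exclude_first_years > 0) {
    early_death <- d$event == 1 &
      (d$exit_age - d$entry_age) <= exclude_first_years
    d <- d[!early_death, ]
  }
  if (!any(d$event == 1 & !is.na(d$cause) & d$cause == cause)) {
    abort_lg(sprintf("no events of cause '%s'", cause))
  }
  d$.exposure <- droplevels(factor(d[[exposure]]))
  lv <- levels(d$.exposure)
  if (length(lv) < 2L) abort_lg("constant exposure: no contrast to estimate")
  d$.ageband <- (floor(d$entry_age) %/% age_band_width) * age_band_width
  d$.etype <- factor(
    ifelse(d$event == 0, "censor",
           ifelse(d$cause == cause, "target", "competing")),
    levels = c("censor", "target", "competing")
  )
  d$.id <- seq_len(nrow(d))

  fg <- survival::finegray(
    Surv(entry_age, exit_age, .etype) ~ .,
    data = d, etype = "target", id = .id
  )
  rhs <- paste(c(".exposure", covariates,
                 sprintf("strata(%s)",
                         paste(c(strata, ".ageband"), collapse = ", "))),
               collapse = " + ")
  fml <- stats::as.formula(
    paste("Surv(fgstart, fgstop, fgstatus) ~", rhs)
  )
  fit <- survival::coxph(fml, data = fg, weights = fg$fgwt, ties = "efron")

  n_events <- sum(d$.etype == "target")
  events_by_level <- tapply(d$.etype == "target", d$.exposure, sum)
  tab <- hr_table_from_fit(fit, prefix = ".exposure", levels = lv[-1],
                           cause = cause, sex = sex_label)
  tab$n_events <- as.integer(events_by_level[tab$level])
  tab$note <- NA_character_
  ref <- tibble::tibble(
    level = lv[1], cause = cause, sex = sex_label, hr = 1,
    ci_low = 1, ci_high = 1, log_se = 0,
    n_events = as.integer(events_by_level[lv[1]]), note = "reference"
  )
  new_hr_fit(fit, dplyr::bind_rows(ref, tab), exposure, cause, sex_label,
             n = nrow(d), n_events = n_events)
}

#' Split follow-up into age-at-risk episodes
#'
#' Partitions each subject's follow-up interval `[entry_age, exit_age]` at
#' fixed age cutpoints, so that Cox fits can be run per age-at-risk band.
#' Episodes partition the follow-up exactly (no gaps or overlaps) and the
#' event, if any, falls on the last episode.
#'
#' @param cohort Cohort tibble (see [fit_stratified_cox()]).
#' @param cutpoints Either a numeric vector of age cutpoints applied to
#'   everyone, or a named list with elements `M` and `W` of sex-specific
#'   cutpoints (default: men split at 50, 60, 70, 80; women at 70).
#' @return Episode tibble: the cohort columns with `entry_age`, `exit_age`,
#'   `event` now per episode, plus `age_at_risk_band`.
#' @export
split_by_age_at_risk <- function(cohort,
                                 cutpoints = list(M = c(50, 60, 70, 80),
                                                  W = 70)) {
  if (any(cohort$exit_age <= cohort$entry_age)) {
    abort_lg("exit_age must exceed entry_age for every subject")
  }
  d <- tibble::as_tibble(cohort)
  if (!"id" %in% names(d)) d$id <- seq_len(nrow(d))
  split_one <- function(dd, cuts) {
    cuts <- sort(unique(cuts))
    s <- survival::survSplit(
      Surv(entry_age, exit_age, event) ~ ., data = as.data.frame(dd),
      cut = cuts, episode = ".band_idx"
    )
    lo <- c(-Inf, cuts)
    hi <- c(cuts, Inf)
    s$age_at_risk_band <- sprintf(
      "%s-%s",
      ifelse(is.finite(lo[s$.band_idx]), lo[s$.band_idx], ""),
      ifelse(is.finite(hi[s$.band_idx]), hi[s$.band_idx], "")
    )
    s$.band_idx <- NULL
    tibble::as_tibble(s)
  }
  if (is.list(cutpoints)) {
    out <- dplyr::bind_rows(lapply(intersect(c("M", "W"), unique(d$sex)),
                                   function(sx) {
      split_one(d[d$sex == sx, ], cutpoints[[sx]])
    }))
  } else {
    out <- split_one(d, cutpoints)
  }
  dplyr::arrange(out, .data$id, .data$entry_age)
}

#' Population attributable risk percent (case-load weighted)
#'
#' PAR% from the distribution of deaths across exposure strata and the
#' adjusted relative risk of each stratum versus the low-risk reference:
#' `PAR = 1 - sum_j pd_j / RR_j`, where `pd_j` is the proportion of deaths
#' in stratum j (reference stratum has RR 1). Interpreted as the percentage
#' of deaths that would be prevented were the whole population in the
#' reference stratum, assuming causality. The confidence interval
#' propagates log-RR sampling uncertainty by Monte-Carlo (lognormal draws,
#' percentile interval), which reproduces the asymmetric bounds typical of
#' rare-cause PARs.
#'
#' @param data Tibble with one row per exposure stratum.
#' @param deaths Column of death counts (or proportions) per stratum.
#' @param rr Column of adjusted relative risks (reference stratum 1).
#' @param log_se Optional column of log-scale standard errors of the RRs
#'   (0 or `NA` for the reference). When present, a percentile CI is
#'   computed.
#' @param n_draws,seed,ci_level Monte-Carlo settings for the CI.
#' @return One-row tibble: `par_pct` and, when `log_se` is given, `ci_low`,
#'   `ci_high` (all in percent).
#' @export
#' @examples
#' compute_par(
#'   tibble::tibble(deaths = c(10, 90), rr = c(1, 1.6)),
#'   deaths = deaths, rr = rr
#' )
compute_par <- function(data, deaths, rr, log_se = NULL,
                        n_draws = 10000L, seed = 1L, ci_level = 0.95) {
  dth <- dplyr::pull(data, {{ deaths }})
  rrv <- dplyr::pull(data, {{ rr }})
  if (any(rrv <= 0)) abort_lg("relative risks must be positive")
  if (any(dth < 0)) abort_lg("death counts must be non-negative")
  pd <- dth / sum(dth)
  par_hat <- 1 - sum(pd / rrv)

  se_quo <- rlang::enquo(log_se)
  if (rlang::quo_is_null(se_quo)) {
    return(tibble::tibble(par_pct = 100 * par_hat))
  }
  sev <- dplyr::pull(data, !!se_quo)
  sev[is.na(sev)] <- 0
  set.seed(seed)
  z <- matrix(rnorm(n_draws * length(rrv)), n_draws)
  rr_draws <- exp(sweep(z, 2, sev, `*`) + rep(log(rrv), each = n_draws))
  par_draws <- 1 - (1 / rr_draws) %*% pd
  alpha <- (1 - ci_level) / 2
  qs <- quantile(par_draws, c(alpha, 1 - alpha), names = FALSE)
  tibble::tibble(par_pct = 100 * par_hat,
                 ci_low = 100 * qs[1], ci_high = 100 * qs[2])
}
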