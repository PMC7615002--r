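# Synthetic cohorts, prevalence tables and mortality schedules with known
# ground truth, so every downstream stage (Cox fits, rate partitioning, life
# tables, decomposition) can be tested end-to-end without external microdata.
#
# The generating model is a piecewise-constant proportional-hazards model:
# each cause of death has a baseline rate step function on an age grid, each
# lifestyle group multiplies every cause's rate by a fixed hazard ratio, and
# competing causes race as independent piecewise exponentials from the entry
# age (left truncation: no events are generated before entry).

#' Simulation configuration
#'
#' Bundles everything the synthetic-data generators need: cohort size, seed,
#' entry-age range, administrative censoring horizon, per-cause baseline
#' hazards on an age grid, true hazard ratios per (group, cause), lifestyle
#' group prevalence by sex and 5-year age band, and the number of region
#' strata.
#'
#' Defaults emulate a large adult cohort recruited at ages 30-79 and followed
#' for about 11 years, with four cause-of-death channels (CVD, cancer,
#' chronic respiratory disease, other), Gompertz-like baseline mortality, and
#' protective hazard ratios that decrease log-linearly with the number of
#' low-risk lifestyle factors.
#'
#' @param n_subjects Number of subjects to simulate.
#' @param seed Integer seed; all generators are deterministic given the seed.
#' @param entry_age_range Length-2 numeric, uniform entry-age range in years.
#' @param admin_censor_years Administrative censoring horizon, years after
#'   entry.
#' @param baseline_hazards Tibble with columns `sex`, `cause`, `age_lo`,
#'   `rate`: piecewise-constant cause-specific rates (per person-year) on a
#'   left-closed age grid; the last segment of each (sex, cause) extends
#'   indefinitely.
#' @param true_hr Tibble with columns `group`, `cause`, `hr`: true hazard
#'   ratio multiplying the baseline rate of `cause` for members of `group`.
#' @param prevalence_spec Tibble with columns `sex`, `age_band`, `group`,
#'   `p`: probability of group membership by sex and 5-year age band
#'   (30-34 ... 80-84); each (sex, age_band) row set sums to 1.
#' @param n_regions Number of region strata (sampled uniformly).
#' @param loss_rate Rate (per person-year) of an independent exponential
#'   loss-to-follow-up process; default 0 (cohorts of this kind report <1%
#'   loss).
#'
#' @return An object of class `sim_config` (a named list).
#' @export
#' @examples
#' cfg <- sim_config(n_subjects = 1000, seed = 42)
#' cohort <- generate_cohort(cfg)
sim_config <- function(n_subjects = 10000L,
                       seed = 1L,
                       entry_age_range = c(30, 79),
                       admin_censor_years = 11,
                       baseline_hazards = default_baseline_hazards(),
                       true_hr = default_true_hr(),
                       prevalence_spec = default_prevalence_spec(),
                       n_regions = 10L,
                       loss_rate = 0) {
  stopifnot(
    length(n_subjects) == 1L, n_subjects >= 1,
    length(entry_age_range) == 2L, diff(entry_age_range) >= 0,
    entry_age_range[1] >= 0,
    admin_censor_years > 0, n_regions >= 1, loss_rate >= 0
  )
  if (any(baseline_hazards$rate < 0)) {
    abort_lg("baseline hazard rates must be non-negative")
  }
  if (any(true_hr$hr <= 0)) abort_lg("true hazard ratios must be positive")
  bad <- prevalence_spec %>%
    dplyr::group_by(.data$sex, .data$age_band) %>%
    dplyr::summarise(s = sum(.data$p), neg = any(.data$p < 0), .groups = "drop")
  if (any(bad$neg)) abort_lg("prevalence_spec has negative proportions")
  if (any(abs(bad$s - 1) > 1e-12)) {
    abort_lg("prevalence_spec rows must sum to 1 within 1e-12")
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      seed = as.integer(seed),
      entry_age_range = as.numeric(entry_age_range),
      admin_censor_years = as.numeric(admin_censor_years),
      baseline_hazards = baseline_hazards,
      true_hr = true_hr,
      prevalence_spec = prevalence_spec,
      n_regions = as.integer(n_regions),
      loss_rate = as.numeric(loss_rate)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  subjects:", x$n_subjects, " seed:", x$seed, "\n")
  cat("  entry ages:", x$entry_age_range[1], "-", x$entry_age_range[2],
      " censor horizon:", x$admin_censor_years, "y\n")
  cat("  groups:", paste(unique(x$true_hr$group), collapse = ", "), "\n")
  cat("  causes:", paste(unique(x$baseline_hazards$cause), collapse = ", "), "\n")
  invisible(x)
}

#' Default piecewise-constant baseline hazards
#'
#' Gompertz-like all-cause mortality (`A * exp(B * age)` with `A = 1e-4`,
#' `B = 0.085` for men, scaled by 0.7 for women) discretised on 5-year
#' segments from age 30 to 95 (the last segment open-ended), split across
#' four cause channels in proportions resembling the adult Chinese cause-of-
#' death mix (CVD 38%, cancer 33%, CRD 8%, other 21%).
#'
#' @param age_step Width of the age segments in years.
#' @return Tibble with columns `sex`, `cause`, `age_lo`, `rate`.
#' @export
default_baseline_hazards <- function(age_step = 5) {
  age_lo <- seq(30, 95, by = age_step)
  mid <- age_lo + age_step / 2
  cause_frac <- c(cvd = 0.38, cancer = 0.33, crd = 0.08, other = 0.21)
  sex_mult <- c(M = 1, W = 0.7)
  tidyr::expand_grid(
    sex = .lg$sexes,
    cause = .lg$causes,
    age_lo = age_lo
  ) %>%
    dplyr::mutate(
      rate = 1e-4 * exp(0.085 * (.env$mid[match(.data$age_lo, .env$age_lo)])) *
        cause_frac[.data$cause] * sex_mult[.data$sex]
    )
}

#' Default true hazard ratios by lifestyle-score group
#'
#' Five score groups ("0-1", "2", "3", "4", "5" low-risk factors), with the
#' "0-1" group as reference (HR 1). The "5" group's hazard ratios are set to
#' protective values typical of combined-lifestyle cohort analyses
#' (all-cause-scale 0.38; CVD 0.37; cancer 0.47; CRD 0.30; other 0.45), and
#' intermediate groups interpolate log-linearly.
#'
#' @return Tibble with columns `group`, `cause`, `hr`.
#' @export
default_true_hr <- function() {
  top <- c(cvd = 0.37, cancer = 0.47, crd = 0.30, other = 0.45)
  groups <- c("0-1", "2", "3", "4", "5")
  purrr::map_dfr(names(top), function(cz) {
    tibble::tibble(
      group = groups,
      cause = cz,
      hr = exp(seq(0, log(top[[cz]]), length.out = 5))
    )
  })
}

#' Default lifestyle-group prevalence by sex and 5-year age band
#'
#' Shares of the five score groups ("0-1" ... "5") with magnitudes matching
#' large nutrition-surveillance surveys (about 2-3% of adults hold all five
#' low-risk factors, about two thirds hold at least three), a mild shift
#' toward higher-risk groups at older ages, and slightly more low-risk
#' membership among women. Bands run 30-34 through 80-84.
#'
#' @return Tibble with columns `sex`, `age_band`, `group`, `p`; each
#'   (sex, age_band) block sums to 1.
#' @export
default_prevalence_spec <- function() {
  band_lo <- seq(30L, 80L, by = 5L)
  groups <- c("0-1", "2", "3", "4", "5")
  base <- c(`0-1` = 0.10, `2` = 0.22, `3` = 0.40, `4` = 0.255, `5` = 0.025)
  tidyr::expand_grid(sex = .lg$sexes, band_lo = band_lo, group = groups) %>%
    dplyr::mutate(
      # linear drift of mass from high-score to low-score groups with age
      drift = (.data$band_lo - 30L) / 50,
      w = base[.data$group] *
        (1 + 0.35 * .data$drift * (.data$group == "0-1")) *
        (1 - 0.30 * .data$drift * (.data$group %in% c("4", "5"))) *
        ifelse(.data$sex == "W" & .data$group %in% c("4", "5"), 1.15, 1)
    ) %>%
    dplyr::group_by(.data$sex, .data$band_lo) %>%
    dplyr::mutate(p = .data$w / sum(.data$w)) %>%
    dplyr::ungroup() %>%
    dplyr::transmute(
      sex = .data$sex,
      age_band = sprintf("%d-%d", .data$band_lo, .data$band_lo + 4L),
      group = .data$group,
      p = .data$p
    )
}

# ---- piecewise-exponential machinery ---------------------------------------

# Cumulative hazard of a piecewise-constant rate function at arbitrary ages.
# breaks: increasing segment starts; rates: one per segment, the last
# extending indefinitely. Origin of integration is breaks[1].
pc_cumhaz <- function(breaks, rates, age) {
  k <- length(breaks)
  widths <- diff(breaks)
  H <- c(0, cumsum(widths * rates[-k]))
  i <- findInterval(age, breaks, rightmost.closed = FALSE)
  i <- pmax(i, 1L)
  H[i] + (age - breaks[i]) * rates[i]
}

# Inverse of pc_cumhaz: smallest age with H0(age) = target. findInterval
# returns the largest segment whose cumulative hazard is <= target, which
# skips interior zero-rate segments; a zero terminal rate that cannot absorb
# the remaining hazard yields Inf (the event never happens).
pc_invert <- function(breaks, rates, target) {
  k <- length(breaks)
  H <- c(0, cumsum(diff(breaks) * rates[-k]))
  i <- pmax(findInterval(target, H), 1L)
  ifelse(rates[i] > 0, breaks[i] + (target - H[i]) / rates[i], Inf)
}

# Draw one event age per subject from a piecewise-constant hazard scaled by
# a per-subject multiplier, conditional on survival to the entry age.
draw_event_age <- function(breaks, rates, entry, mult) {
  h_entry <- pc_cumhaz(breaks, rates, entry)
  target <- h_entry + rexp(length(entry)) / mult
  pc_invert(breaks, rates, target)
}

# ---- generators ------------------------------------------------------------

#' Generate a synthetic cohort
#'
#' One row per subject: sex, region stratum, lifestyle group (drawn from the
#' prevalence specification at the entry-age band), entry and exit age,
#' event indicator and cause of death. Competing causes race as independent
#' piecewise exponentials from the entry age; the earliest event wins unless
#' administrative censoring (or loss to follow-up, if configured) occurs
#' first. Deterministic under the config seed.
#'
#' @param config A [sim_config()].
#' @return A tibble (`id`, `sex`, `region`, `group`, `education`,
#'   `entry_age`, `exit_age`, `event`, `cause`). `event` is 1 for deaths,
#'   0 otherwise; `cause` is `NA` for censored rows.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_subjects

  sex <- sample(.lg$sexes, n, replace = TRUE)
  entry <- runif(n, config$entry_age_range[1], config$entry_age_range[2])
  region <- sample.int(config$n_regions, n, replace = TRUE)
  education <- sample.int(4L, n, replace = TRUE)

  # group membership from the prevalence spec at the subject's entry band
  band <- age_band_5y(entry)
  prev <- config$prevalence_spec
  groups <- unique(prev$group)
  key <- paste(sex, band)
  pmat <- prev %>%
    dplyr::mutate(key = paste(.data$sex, .data$age_band)) %>%
    dplyr::select("key", "group", "p") %>%
    tidyr::pivot_wider(names_from = "group", values_from = "p") %>%
    tibble::column_to_rownames("key")
  pmat <- as.matrix(pmat[, groups, drop = FALSE])
  if (anyNA(pmat[key, ])) abort_lg("prevalence_spec does not cover all entry-age bands")
  u <- runif(n)
  ones <- upper.tri(diag(ncol(pmat)), diag = TRUE)
  cum <- pmat %*% ones  # row-wise cumulative sums, robust to 1 group
  gi <- rowSums(u > cum[key, , drop = FALSE]) + 1L
  group <- groups[pmin(gi, length(groups))]

  # per-cause event ages
  causes <- unique(config$baseline_hazards$cause)
  hr_tab <- config$true_hr
  event_age <- matrix(Inf, n, length(causes), dimnames = list(NULL, causes))
  for (sx in .lg$sexes) {
    si <- which(sex == sx)
    if (!length(si)) next
    for (cz in causes) {
      bh <- config$baseline_hazards %>%
        dplyr::filter(.data$sex == sx, .data$cause == cz) %>%
        dplyr::arrange(.data$age_lo)
      if (!nrow(bh)) abort_lg(sprintf("no baseline hazard for sex %s cause %s", sx, cz))
      hr_map <- hr_tab %>% dplyr::filter(.data$cause == cz)
      mult <- hr_map$hr[match(group[si], hr_map$group)]
      if (anyNA(mult)) abort_lg(sprintf("missing true HR for cause %s", cz))
      if (all(bh$rate == 0)) next  # no events possible from this channel
      event_age[si, cz] <- draw_event_age(bh$age_lo, bh$rate, entry[si], mult)
    }
  }

  first_event <- do.call(pmin, as.data.frame(event_age))
  first_cause <- causes[max.col(-event_age, ties.method = "first")]
  censor_age <- entry + config$admin_censor_years
  if (config$loss_rate > 0) {
    censor_age <- pmin(censor_age, entry + rexp(n, config$loss_rate))
  }
  died <- first_event < censor_age
  exit <- ifelse(died, first_event, censor_age)

  tibble::tibble(
    id = seq_len(n),
    sex = sex,
    region = region,
    group = factor(group, levels = groups),
    education = education,
    entry_age = entry,
    exit_age = exit,
    event = as.integer(died),
    cause = ifelse(died, first_cause, NA_character_)
  )
}

#' Emit the prevalence table of a simulation configuration
#'
#' Validated pass-through of the configuration's prevalence specification:
#' proportions of each lifestyle group by sex and 5-year age band
#' (30-34 ... 80-84), each row set summing to 1.
#'
#' @param config A [sim_config()].
#' @return Tibble with columns `sex`, `age_band`, `group`, `p`.
#' @export
generate_prevalence_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  prev <- tibble::as_tibble(config$prevalence_spec)
  if (any(prev$p < 0)) abort_lg("negative proportions in prevalence table")
  prev
}

#' Generate the population mortality schedule implied by a configuration
#'
#' Computes, for each sex, cause, and single year of age 30-94 plus the open
#' interval 95+, the population central death rate implied by the generating
#' model: the baseline rate times the prevalence-weighted mean hazard ratio
#' at that age, `m_pop(x) = r0(x) * sum_g p_g(x) HR_g`. An all-cause row
#' (`cause = "all"`) equal to the sum over causes is appended. This is the
#' schedule a national mortality database would report if the whole
#' population followed the generating model.
#'
#' @param config A [sim_config()].
#' @param open_age Lower bound of the terminal open age interval.
#' @return A mortality schedule tibble (`sex`, `cause`, `age`, `mx`).
#' @export
generate_mortality_schedule <- function(config, open_age = 95L) {
  stopifnot(inherits(config, "sim_config"))
  ages <- seq(.lg$index_age, open_age)
  causes <- unique(config$baseline_hazards$cause)
  grid <- tidyr::expand_grid(sex = .lg$sexes, cause = causes, age = ages)

  # baseline rate at each single year (constant within hazard segments)
  bh <- config$baseline_hazards %>% dplyr::arrange(.data$sex, .data$cause, .data$age_lo)
  rate_at <- function(sx, cz, age) {
    seg <- bh[bh$sex == sx & bh$cause == cz, ]
    seg$rate[pmax(findInterval(age, seg$age_lo), 1L)]
  }
  mean_hr <- config$prevalence_spec %>%
    dplyr::inner_join(config$true_hr, by = "group",
                      relationship = "many-to-many") %>%
    dplyr::group_by(.data$sex, .data$age_band, .data$cause) %>%
    dplyr::summarise(mhr = sum(.data$p * .data$hr), .groups = "drop")

  out <- grid %>%
    dplyr::mutate(
      age_band = age_band_5y(.data$age),
      r0 = purrr::pmap_dbl(
        list(.data$sex, .data$cause, .data$age),
        rate_at
      )
    ) %>%
    dplyr::left_join(mean_hr, by = c("sex", "age_band", "cause")) %>%
    dplyr::mutate(mx = .data$r0 * .data$mhr) %>%
    dplyr::select("sex", "cause", "age", "mx")
  if (anyNA(out$mx)) abort_lg("missing ages or prevalence bands in schedule")

  allc <- out %>%
    dplyr::group_by(.data$sex, .data$age) %>%
    dplyr::summarise(mx = sum(.data$mx), .groups = "drop") %>%
    dplyr::mutate(cause = "all", .after = "sex")
  dplyr::bind_rows(out, allc) %>%
    dplyr::arrange(.data$sex, .data$cause, .data$age)
}

#' Monte-Carlo mean residual life at age 30 from a mortality schedule
#'
#' Brute-force oracle for the life-table builder: draws individual ages at
#' death from the piecewise-constant hazard implied by a single-sex all-cause
#' schedule (single-year rates through the open interval, exponential
#' residual beyond it) and returns the mean age at death minus 30 with its
#' Monte-Carlo standard error.
#'
#' @param schedule Tibble with columns `age`, `mx` for one sex/group: single
#'   years from 30 with a terminal open-interval row (highest age). The
#'   open-interval rate must be positive.
#' @param n Number of simulated lifetimes.
#' @param seed Integer seed.
#' @return One-row tibble: `e30` (mean residual life at 30), `mc_se`, `n`.
#' @export
simulate_lifetimes <- function(schedule, n = 100000L, seed = 1L) {
  stopifnot(all(c("age", "mx") %in% names(schedule)))
  sched <- dplyr::arrange(schedule, .data$age)
  if (any(duplicated(sched$age))) {
    abort_lg("schedule must contain one row per age for a single sex/group")
  }
  if (any(diff(sched$age) != 1)) abort_lg("schedule ages must be contiguous")
  if (any(sched$mx < 0)) abort_lg("negative rates in schedule")
  open_rate <- sched$mx[nrow(sched)]
  if (open_rate <= 0) {
    abort_lg("open-interval rate must be positive (residual life undefined)")
  }
  set.seed(seed)
  breaks <- sched$age
  rates <- sched$mx
  death_age <- pc_invert(breaks, rates, rexp(n))
  res <- death_age - sched$age[1]
  tibble::tibble(e30 = mean(res), mc_se = stats::sd(res) / sqrt(n), n = n)
}
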