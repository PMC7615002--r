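toy_cohort <- function(entry, exit, event, x, region = 1L) {
  tibble::tibble(
    id = seq_along(entry), sex = "M", region = region,
    group = factor(ifelse(x == 1, "exposed", "unexposed"),
                   levels = c("unexposed", "exposed")),
    entry_age = entry, exit_age = exit, event = event,
    cause = ifelse(event == 1, "all", NA_character_)
  )
}

test_that("Cox log-HR matches the brute-force partial-likelihood oracle", {
  # 4 subjects, no ties, event times interleaved across groups so the
  # partial-likelihood maximiser is finite
  co <- toy_cohort(entry = rep(30, 4), exit = c(35, 40, 45, 50),
                   event = rep(1L, 4), x = c(1, 0, 1, 0))
  beta_hat <- grid_mle(co$entry_age, co$exit_age, co$event,
                       as.integer(co$group == "exposed"))
  fit <- fit_stratified_cox(co)
  expect_lt(abs(log(tidy(fit)$hr[2]) - beta_hat), 1e-4 + 1e-4 / 2)

  # 6 subjects with staggered entry (left truncation changes risk sets);
  # a single baseline-age stratum so the unstratified oracle applies
  co2 <- toy_cohort(entry = c(30, 33, 35, 40, 31, 44),
                    exit = c(36, 41, 44, 52, 47, 58),
                    event = c(1L, 1L, 0L, 1L, 1L, 1L),
                    x = c(1, 0, 1, 1, 0, 0))
  beta2 <- grid_mle(co2$entry_age, co2$exit_age, co2$event,
                    as.integer(co2$group == "exposed"))
  fit2 <- fit_stratified_cox(co2, age_band_width = 60)
  expect_lt(abs(log(tidy(fit2)$hr[2]) - beta2), 1e-4 + 1e-4 / 2)
})

test_that("a constant exposure is returned as a flagged degenerate fit", {
  co <- toy_cohort(rep(30, 4), c(35, 40, 45, 50), rep(1L, 4), rep(1, 4))
  fit <- fit_stratified_cox(co)
  td <- tidy(fit)
  expect_equal(td$hr, 1)
  expect_true(is.na(td$ci_low))
  expect_match(td$note, "no contrast")
})

test_that("stratified Cox recovers a strong protective effect", {
  cfg <- two_group_config(n = 30000, seed = 17, hr5 = 0.38)
  co <- generate_cohort(cfg)
  fit <- fit_stratified_cox(co, covariates = "education")
  tab <- tidy(fit)[2, ]
  expect_lt(abs(log(tab$hr) - log(0.38)) / tab$log_se, 3)
  g <- glance(fit)
  expect_equal(g$n, nrow(co))
  expect_gt(g$concordance, 0.5)
})

test_that("log-HR recovery is unbiased with honest CI coverage (scaled down)", {
  true_hrs <- c(0.5, 1, 2)
  reps <- 40
  for (thr in true_hrs) {
    est <- se <- numeric(reps)
    for (r in seq_len(reps)) {
      cfg <- two_group_config(n = 6000, seed = 1000 * thr + r, hr5 = thr,
                              rate0 = 0.02, censor_years = 11)
      co <- generate_cohort(cfg)
      tab <- tidy(fit_stratified_cox(co))[2, ]
      est[r] <- log(tab$hr); se[r] <- tab$log_se
    }
    bias <- mean(est) - log(thr)
    mc_err <- stats::sd(est) / sqrt(reps)
    expect_lt(abs(bias), 0.02 + 3 * mc_err)
    covered <- mean(abs(est - log(thr)) <= qnorm(0.975) * se)
    # binomial band around 0.95 at this replicate count
    expect_gte(covered, 0.95 - 3 * sqrt(0.95 * 0.05 / reps))
  }
})

test_that("excluding early deaths leaves a null effect unbiased", {
  cfg <- two_group_config(n = 25000, seed = 77, hr5 = 1)
  co <- generate_cohort(cfg)
  n_early <- sum(co$event == 1 & (co$exit_age - co$entry_age) <= 2)
  expect_gt(n_early, 0)
  fit <- fit_stratified_cox(co, exclude_first_years = 2)
  expect_equal(fit$n, nrow(co) - n_early)
  tab <- tidy(fit)[2, ]
  expect_lt(abs(log(tab$hr)) / tab$log_se, 3)
})

test_that("cause-specific and Fine-Gray coincide without competing events", {
  cfg <- two_group_config(n = 8000, seed = 41, hr5 = 0.5)
  co <- generate_cohort(cfg)  # single 'all' channel: no competing causes
  cs <- fit_cause_specific(co, cause = "all", method = "cause_specific")
  fg <- fit_cause_specific(co, cause = "all", method = "fine_gray")
  expect_lt(abs(log(tidy(cs)$hr[2]) - log(tidy(fg)$hr[2])), 1e-6)
})

test_that("cause-specific Cox recovers each channel and Fine-Gray attenuates", {
  # cancer channel with HR 0.5 amid a dominant competing channel that the
  # exposure also protects against (HR 0.4): exposed subjects escape
  # competing death, accumulate more cancer incidence, and the
  # subdistribution HR is attenuated toward 1 relative to cause-specific.
  bh <- tidyr::expand_grid(sex = c("M", "W"), cause = c("cancer", "other"),
                           age_lo = seq(30, 95, 5))
  bh$rate <- ifelse(bh$cause == "cancer", 0.01, 0.03)
  hr <- tibble::tibble(group = rep(c("0-1", "5"), 2),
                       cause = rep(c("cancer", "other"), each = 2),
                       hr = c(1, 0.5, 1, 0.4))
  prev <- tidyr::expand_grid(
    sex = c("M", "W"),
    age_band = sprintf("%d-%d", seq(30, 80, 5), seq(34, 84, 5)),
    group = c("0-1", "5")
  )
  prev$p <- 0.5
  cfg <- sim_config(n_subjects = 30000, seed = 55, baseline_hazards = bh,
                    true_hr = hr, prevalence_spec = prev)
  co <- generate_cohort(cfg)

  cs <- tidy(fit_cause_specific(co, cause = "cancer"))[2, ]
  expect_lt(abs(log(cs$hr) - log(0.5)) / cs$log_se, 3)

  # protective competing effect -> exposed survive 'other' more, accumulate
  # more cancer incidence -> subdistribution HR attenuated toward 1
  fg <- tidy(fit_cause_specific(co, cause = "cancer", method = "fine_gray"))[2, ]
  expect_gt(fg$hr, cs$hr)
})

test_that("episode splitting partitions follow-up exactly", {
  cfg <- sim_config(n_subjects = 3000, seed = 13)
  co <- generate_cohort(cfg)
  ep <- split_by_age_at_risk(co)
  # per-subject person-years conserved
  py <- ep %>%
    dplyr::summarise(py = sum(exit_age - entry_age), .by = id) %>%
    dplyr::arrange(id)
  expect_equal(py$py, co$exit_age - co$entry_age, tolerance = 1e-12)
  # events preserved, on the last episode only
  ev <- ep %>%
    dplyr::arrange(id, entry_age) %>%
    dplyr::summarise(n_ev = sum(event), last_ev = dplyr::last(event),
                     .by = id)
  expect_equal(sum(ev$n_ev), sum(co$event))
  expect_true(all(ev$n_ev <= 1))
  expect_true(all(ev$n_ev == 0 | ev$last_ev == 1))
  # no gaps or overlaps
  gaps <- ep %>%
    dplyr::arrange(id, entry_age) %>%
    dplyr::group_by(id) %>%
    dplyr::summarise(ok = all(abs(utils::head(exit_age, -1) -
                                    utils::tail(entry_age, -1)) < 1e-12))
  expect_true(all(gaps$ok))

  # worked example: man entering 45, dying at 63, cuts {50,60,70,80}
  one <- split_by_age_at_risk(
    toy_cohort(entry = 45, exit = 63, event = 1L, x = 0),
    cutpoints = c(50, 60, 70, 80)
  )
  expect_equal(one$entry_age, c(45, 50, 60))
  expect_equal(one$exit_age, c(50, 60, 63))
  expect_equal(one$event, c(0, 0, 1))

  # woman entering 40, censored at 65, cut {70}: a single episode
  two <- split_by_age_at_risk(
    toy_cohort(entry = 40, exit = 65, event = 0L, x = 0),
    cutpoints = 70
  )
  expect_equal(nrow(two), 1L)
  expect_equal(two$event, 0)
})

test_that("PAR follows the case-load-weighted formula and its limits", {
  # all strata at RR 1
  expect_equal(
    compute_par(tibble::tibble(d = c(30, 70), r = c(1, 1)),
                deaths = d, rr = r)$par_pct, 0
  )
  # all deaths exposed at RR 2: 1 - 1/2
  expect_equal(
    compute_par(tibble::tibble(d = c(0, 100), r = c(1, 2)),
                deaths = d, rr = r)$par_pct, 50
  )
  # worked example: pd_exposed 0.9 at RR 1.6
  expect_equal(
    compute_par(tibble::tibble(d = c(10, 90), r = c(1, 1.6)),
                deaths = d, rr = r)$par_pct,
    100 * (1 - (0.1 / 1 + 0.9 / 1.6))
  )
  # invariant to scaling death counts
  p1 <- compute_par(tibble::tibble(d = c(12, 34, 54), r = c(1, 1.3, 1.9)),
                    deaths = d, rr = r)$par_pct
  p2 <- compute_par(tibble::tibble(d = 7 * c(12, 34, 54), r = c(1, 1.3, 1.9)),
                    deaths = d, rr = r)$par_pct
  expect_equal(p1, p2)
  # pd_exposed -> 1 limit: PAR -> 1 - 1/RR
  p3 <- compute_par(tibble::tibble(d = c(1e-9, 1), r = c(1, 1.8)),
                    deaths = d, rr = r)$par_pct
  expect_equal(p3, 100 * (1 - 1 / 1.8), tolerance = 1e-6)
  expect_error(
    compute_par(tibble::tibble(d = c(1, 1), r = c(1, -2)), deaths = d, rr = r),
    "positive"
  )
})

test_that("PAR Monte-Carlo CI brackets the point estimate and is asymmetric-capable", {
  tab <- tibble::tibble(d = c(10, 90), r = c(1, 1.6), s = c(0, 0.4))
  out <- compute_par(tab, deaths = d, rr = r, log_se = s,
                     n_draws = 5000, seed = 4)
  expect_lt(out$ci_low, out$par_pct)
  expect_gt(out$ci_high, out$par_pct)
  # wide log-SE on a rare contrast can push the lower bound negative
  expect_lt(out$ci_low, 0)
})
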