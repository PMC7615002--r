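# Shared fixtures and independent oracles, built in code at test time.

# Two-group simulation setup with a single all-cause channel and a known
# hazard ratio: the workhorse for recovery tests.
two_group_config <- function(n, seed, hr5 = 0.38, rate0 = NULL,
                             censor_years = 11, entry_range = c(30, 79)) {
  bh <- tidyr::expand_grid(sex = c("M", "W"), cause = "all",
                           age_lo = seq(30, 95, 5))
  bh$rate <- if (is.null(rate0)) 1e-4 * exp(0.085 * (bh$age_lo + 2.5)) else rate0
  hr <- tibble::tibble(group = c("0-1", "5"), cause = "all", hr = c(1, hr5))
  prev <- tidyr::expand_grid(
    sex = c("M", "W"),
    age_band = sprintf("%d-%d", seq(30, 80, 5), seq(34, 84, 5)),
    group = c("0-1", "5")
  )
  prev$p <- 0.5
  sim_config(n_subjects = n, seed = seed, baseline_hazards = bh,
             true_hr = hr, prevalence_spec = prev,
             admin_censor_years = censor_years,
             entry_age_range = entry_range)
}

# Brute-force stratified partial-likelihood oracle for a binary exposure on
# the age timescale with left truncation (Breslow form; valid for fixtures
# without tied event times). Independent of the survival package.
partial_loglik <- function(beta, entry, exit, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    t <- exit[i]
    risk <- which(entry < t & exit >= t)
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

grid_mle <- function(entry, exit, event, x, lo = -4, hi = 4, step = 1e-4) {
  grid <- seq(lo, hi, by = step)
  ll <- vapply(grid, partial_loglik, numeric(1),
               entry = entry, exit = exit, event = event, x = x)
  grid[which.max(ll)]
}

# Random plausible single-year mortality schedule 30..95 (open interval):
# noisy Gompertz, always positive in the open interval.
random_schedule <- function(seed) {
  set.seed(seed)
  a <- exp(runif(1, log(2e-5), log(2e-4)))
  b <- runif(1, 0.06, 0.11)
  ages <- 30:95
  mx <- a * exp(b * ages) * exp(rnorm(length(ages), 0, 0.15))
  tibble::tibble(age = ages, mx = mx)
}

# Small GBD-results-tool-style extract (synthetic rates) written to a temp
# CSV; returns the path and the generating schedule.
write_synthetic_gbd_csv <- function(seed = 1, path = tempfile(fileext = ".csv")) {
  set.seed(seed)
  bands <- c(seq(30, 90, 5), 95)
  label <- ifelse(bands == 95, "95 plus", sprintf("%d to %d", bands, bands + 4))
  frac <- c(cvd = 0.40, cancer = 0.30, crd = 0.10)
  rows <- purrr::map_dfr(c(Male = "M", Female = "W"), function(sx) {
    all_rate <- 1e-4 * exp(0.088 * (bands + 2.5)) *
      ifelse(sx == "W", 0.7, 1) * exp(rnorm(length(bands), 0, 0.05))
    purrr::map_dfr(seq_along(bands), function(i) {
      tibble::tibble(
        measure = "Deaths",
        location = "Synthetica",
        sex = ifelse(sx == "M", "Male", "Female"),
        age = label[i],
        cause = c("All causes", "Cardiovascular diseases", "Neoplasms",
                  "Chronic respiratory diseases"),
        metric = "Rate",
        year = 2015L,
        val = all_rate[i] * 1e5 * c(1, frac),
        upper = NA_real_,
        lower = NA_real_
      )
    })
  })
  readr::write_csv(rows, path)
  path
}
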