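# Monte-Carlo propagation of hazard-ratio sampling uncertainty into any
# downstream statistic (life expectancy, gained years, decomposition
# totals, PAR). Hazard ratios are resampled on the log scale from
# independent normal distributions (i.e. lognormal HRs), and intervals are
# empirical percentiles, which reproduces the asymmetric bounds typical of
# published life-expectancy CIs.

#' Monte-Carlo configuration
#'
#' @param n_draws Number of Monte-Carlo draws (at least 100; default
#'   10,000).
#' @param seed Integer seed.
#' @param ci_level Two-sided interval coverage (default 0.95).
#' @return An object of class `mc_config`.
#' @export
mc_config <- function(n_draws = 10000L, seed = 1L, ci_level = 0.95) {
  stopifnot(n_draws >= 100, ci_level > 0, ci_level < 1)
  structure(
    list(n_draws = as.integer(n_draws), seed = as.integer(seed),
         ci_level = ci_level),
    class = "mc_config"
  )
}

#' Log-scale standard error from a Wald 95% confidence interval
#'
#' Back-calculates `(ln hi - ln lo) / (2 * 1.96)`, the standard error of
#' the log hazard ratio implied by a printed symmetric-on-the-log-scale
#' 95% CI.
#'
#' @param hr,lo,hi Hazard ratio and its CI bounds (vectors; must satisfy
#'   `0 < lo <= hr <= hi`).
#' @return Numeric vector of log-scale standard errors.
#' @export
#' @examples
#' log_se_from_ci(0.38, 0.34, 0.43)  # about 0.06
log_se_from_ci <- function(hr, lo, hi) {
  if (any(!(lo > 0 & lo <= hr & hr <= hi))) {
    abort_lg("CI ordering violated: need 0 < lo <= hr <= hi")
  }
  (log(hi) - log(lo)) / (2 * qnorm(0.975))
}

#' Sample perturbed hazard-ratio tables
#'
#' Replaces each row's `hr` by `exp(N(ln hr, log_se^2))`, independently
#' across rows and draws. Deterministic under the config seed.
#'
#' @param hrs Hazard-ratio tibble with columns `hr` and `log_se` (plus any
#'   identifying columns, preserved).
#' @param config An [mc_config()].
#' @return Tibble of `n_draws` stacked copies of `hrs` with a leading
#'   `draw` column and perturbed `hr`.
#' @export
sample_hr_draws <- function(hrs, config = mc_config()) {
  stopifnot(all(c("hr", "log_se") %in% names(hrs)))
  if (anyNA(hrs$log_se)) abort_lg("log_se missing for some rows")
  set.seed(config$seed)
  r <- nrow(hrs)
  z <- matrix(rnorm(config$n_draws * r), nrow = config$n_draws, byrow = TRUE)
  hr_draws <- exp(sweep(z, 2, hrs$log_se, `*`) +
                    rep(log(hrs$hr), each = config$n_draws))
  out <- hrs[rep(seq_len(r), times = config$n_draws), ]
  out$draw <- rep(seq_len(config$n_draws), each = r)
  out$hr <- as.vector(t(hr_draws))
  dplyr::relocate(tibble::as_tibble(out), "draw")
}

#' Monte-Carlo percentile interval for a statistic of a hazard-ratio table
#'
#' Evaluates `statistic` at the point hazard ratios, then on each perturbed
#' draw from [sample_hr_draws()], and reports empirical percentile bounds.
#' `statistic` may return a single number or a named numeric vector (each
#' element gets its own interval). Draws on which the statistic fails are
#' dropped and counted.
#'
#' @param statistic Function taking a hazard-ratio tibble (same columns as
#'   `hrs`) and returning a numeric scalar or named vector.
#' @param hrs Hazard-ratio tibble with `hr` and `log_se` columns.
#' @param config An [mc_config()].
#' @return Tibble (`term`, `estimate`, `ci_low`, `ci_high`) with attribute
#'   `n_failed` (number of dropped draws).
#' @export
mc_interval <- function(statistic, hrs, config = mc_config()) {
  point <- statistic(hrs)
  if (is.null(names(point))) {
    names(point) <- if (length(point) == 1L) "statistic" else
      paste0("statistic", seq_along(point))
  }
  draws <- sample_hr_draws(hrs, config)
  per_draw <- split(dplyr::select(draws, -"draw"), draws$draw)
  vals <- purrr::map(per_draw, function(d) {
    tryCatch(statistic(d), error = function(e) NULL)
  })
  failed <- sum(vapply(vals, is.null, logical(1)))
  mat <- do.call(rbind, vals[!vapply(vals, is.null, logical(1))])
  if (is.null(mat) || nrow(mat) == 0) abort_lg("statistic failed on every draw")
  alpha <- (1 - config$ci_level) / 2
  qs <- apply(mat, 2, quantile, probs = c(alpha, 1 - alpha), names = FALSE)
  out <- tibble::tibble(
    term = names(point),
    estimate = unname(point),
    ci_low = qs[1, ],
    ci_high = qs[2, ]
  )
  attr(out, "n_failed") <- failed
  out
}
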