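# The pipeline driver: cohort -> hazard ratios -> partitioned rates ->
# life tables -> gains with Monte-Carlo CIs -> Arriaga decomposition ->
# PAR. Inputs come either from files (cohort/prevalence CSV, GBD-format
# mortality CSV, HR CSV) or from the synthetic generators.

#' Pipeline configuration
#'
#' Collects the inputs and switches of [run_pipeline()]. Inputs are either
#' file paths or, when `NULL`, generated from `sim` (a [sim_config()]).
#'
#' @param sim A [sim_config()] used for any input not supplied as a file.
#' @param cohort_csv,prevalence_csv,mortality_csv,hr_csv Optional paths:
#'   cohort and prevalence CSVs as written by [write_table_csv()], a
#'   GBD-format mortality CSV for [read_gbd_csv()], and a pre-computed
#'   hazard-ratio CSV (columns `level`/`group`, `cause`, `sex`, `hr`,
#'   `ci_low`, `ci_high`) which skips the Cox stage.
#' @param index_age Exact age for life expectancy (default 30).
#' @param causes Cause channels carried through partitioning and
#'   decomposition.
#' @param group_var Cohort column defining the exposure groups.
#' @param reference Reference group (default: first factor level).
#' @param covariates,strata Passed to the Cox fits.
#' @param method `"cause_specific"` or `"fine_gray"` for cause-specific
#'   hazard ratios.
#' @param exclude_first_years Sensitivity switch: drop subjects dying
#'   within this many years of entry before fitting.
#' @param mc An [mc_config()] for the uncertainty stage.
#' @param decompose_sexes Sexes for which the top-vs-reference gap is
#'   decomposed.
#' @param output_dir Optional directory; when set, every output table is
#'   written as CSV together with a run manifest.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            cohort_csv = NULL,
                            prevalence_csv = NULL,
                            mortality_csv = NULL,
                            hr_csv = NULL,
                            index_age = 30,
                            causes = c("cvd", "cancer", "crd", "other"),
                            group_var = "group",
                            reference = NULL,
                            covariates = character(),
                            strata = "region",
                            method = c("cause_specific", "fine_gray"),
                            exclude_first_years = 0,
                            mc = mc_config(n_draws = 1000L),
                            decompose_sexes = c("M", "W"),
                            output_dir = NULL) {
  structure(
    list(sim = sim, cohort_csv = cohort_csv, prevalence_csv = prevalence_csv,
         mortality_csv = mortality_csv, hr_csv = hr_csv,
         index_age = index_age, causes = causes, group_var = group_var,
         reference = reference, covariates = covariates, strata = strata,
         method = match.arg(method),
         exclude_first_years = exclude_first_years, mc = mc,
         decompose_sexes = decompose_sexes, output_dir = output_dir),
    class = "pipeline_config"
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort_lg(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full life-expectancy pipeline
#'
#' Stages: (1) load or simulate the cohort, prevalence table and mortality
#' schedule; (2) estimate hazard ratios per cause from the cohort (or load
#' them); (3) partition the population schedule into group-specific rates
#' and build life tables, giving life expectancy and gained years per
#' group; (4) propagate HR uncertainty into those quantities by
#' Monte-Carlo; (5) decompose the top-versus-reference gap by age and
#' cause; (6) compute the PAR% of not holding all low-risk factors. Pure
#' function of (inputs, config, seeds); inputs are never mutated.
#'
#' @param config A [pipeline_config()].
#' @return A `lifegain_result` list: `hr_table`, `le_table`, `ci_table`,
#'   `decomposition` (one `le_decomposition` per sex), `par_table`,
#'   `manifest`, plus the input tables used.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))

  cohort <- stage("cohort", {
    if (is.null(config$cohort_csv)) generate_cohort(config$sim)
    else read_table_csv(config$cohort_csv)
  })
  prevalence <- stage("prevalence", {
    if (is.null(config$prevalence_csv)) generate_prevalence_table(config$sim)
    else read_table_csv(config$prevalence_csv)
  })
  schedule <- stage("mortality", {
    if (is.null(config$mortality_csv)) generate_mortality_schedule(config$sim)
    else read_gbd_csv(config$mortality_csv)
  })

  hr_table <- stage("hazard ratios", {
    if (!is.null(config$hr_csv)) {
      h <- read_table_csv(config$hr_csv)
      if (!"log_se" %in% names(h)) {
        h$log_se <- ifelse(h$hr == 1 & h$ci_low == 1, 0,
                           log_se_from_ci(h$hr, h$ci_low, h$ci_high))
      }
      h
    } else {
      purrr::map_dfr(config$causes, function(cz) {
        tidy(fit_cause_specific(
          cohort, cause = cz, method = config$method,
          exposure = config$group_var, covariates = config$covariates,
          strata = config$strata,
          exclude_first_years = config$exclude_first_years
        ))
      })
    }
  })

  groups <- unique(hr_table$level %||% hr_table$group)
  reference <- config$reference %||% groups[1]
  top <- groups[length(groups)]

  le_table <- stage("life tables", {
    life_expectancy_by_group(schedule, prevalence, hr_table,
                             index_age = config$index_age,
                             reference = reference)
  })

  ci_table <- stage("uncertainty", {
    statistic <- function(h) {
      le <- life_expectancy_by_group(schedule, prevalence, h,
                                     index_age = config$index_age,
                                     reference = reference)
      setNames(
        c(le$ex, le$gain),
        c(paste0("ex_", le$sex, "_", le$group),
          paste0("gain_", le$sex, "_", le$group))
      )
    }
    mc_interval(statistic, hr_table, config$mc)
  })

  decomposition <- stage("decomposition", {
    out <- lapply(config$decompose_sexes, function(sx) {
      decompose_le_gap(schedule, prevalence, hr_table,
                       group1 = reference, group2 = top,
                       sex = sx, index_age = config$index_age)
    })
    names(out) <- config$decompose_sexes
    out
  })

  par_table <- stage("PAR", {
    ch <- cohort
    ch$.all5 <- factor(ifelse(ch[[config$group_var]] == top, top, "other"),
                       levels = c(top, "other"))
    fit <- fit_stratified_cox(ch, exposure = ".all5",
                              covariates = config$covariates,
                              strata = config$strata,
                              exclude_first_years = config$exclude_first_years)
    tab <- tidy(fit)
    compute_par(tab, deaths = n_events, rr = hr, log_se = log_se,
                n_draws = config$mc$n_draws, seed = config$mc$seed,
                ci_level = config$mc$ci_level) %>%
      dplyr::mutate(cause = "all", .before = 1)
  })

  manifest <- list(
    package = "lifegain",
    version = as.character(utils::packageVersion("lifegain")),
    r_version = as.character(getRversion()),
    config_hash = rlang::hash(config),
    sim_seed = if (is.null(config$cohort_csv)) config$sim$seed else NA,
    mc_seed = config$mc$seed
  )

  result <- structure(
    list(hr_table = hr_table, le_table = le_table, ci_table = ci_table,
         decomposition = decomposition, par_table = par_table,
         manifest = manifest,
         inputs = list(cohort = cohort, prevalence = prevalence,
                       schedule = schedule)),
    class = "lifegain_result"
  )

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(x, f) write_table_csv(x, file.path(config$output_dir, f))
    wr(hr_table, "hr_table.csv")
    wr(le_table, "life_expectancy.csv")
    wr(ci_table, "intervals.csv")
    wr(purrr::imap_dfr(decomposition, function(d, sx) {
      dplyr::mutate(d$by_age_cause, sex = sx, .before = 1)
    }), "decomposition_age_cause.csv")
    wr(purrr::imap_dfr(decomposition, function(d, sx) {
      dplyr::mutate(d$shares, sex = sx, .before = 1)
    }), "cause_shares.csv")
    wr(par_table, "par.csv")
    yaml::write_yaml(manifest, file.path(config$output_dir, "manifest.yaml"))
  }
  result
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.lifegain_result <- function(x, ...) {
  cat("<lifegain_result>\n")
  cat("Life expectancy by group:\n")
  print(x$le_table)
  cat("\nPAR:\n")
  print(x$par_table)
  invisible(x)
}
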