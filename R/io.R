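# File interfaces: the GBD results-tool CSV dialect for national mortality
# rates, plain CSV round-trips for the pipeline tables, and YAML
# serialisation of the simulation configuration.

#' Read a GBD results-tool mortality CSV into a schedule
#'
#' Consumes the results-tool export layout (columns `measure`, `location`,
#' `sex`, `age`, `cause`, `metric`, `year`, `val`, `upper`, `lower`),
#' keeping death-rate rows (`metric = "Rate"`, per 100,000, converted to
#' per person-year), parsing 5-year age labels (`"30 to 34"`, ...,
#' `"95 plus"`), mapping cause names through `cause_map`, and expanding to
#' single years of age via [expand_schedule()]. The residual
#' `all - (named causes)` is assigned to `"other"`; if the named causes
#' overshoot the all-cause row by more than 2% at any age, a warning is
#' issued and the residual is clamped at zero.
#'
#' @param path CSV path.
#' @param cause_map Named character vector mapping GBD cause names to the
#'   schedule's cause labels (must map one name to `"all"`).
#' @param sex_map Named character vector mapping GBD sex labels to
#'   `"M"`/`"W"`.
#' @param year Calendar year to keep (default: the only year present;
#'   required if the file holds several).
#' @return Mortality schedule tibble (`sex`, `cause`, `age`, `mx`)
#'   including the `"all"` and `"other"` rows.
#' @export
read_gbd_csv <- function(path,
                         cause_map = c("All causes" = "all",
                                       "Cardiovascular diseases" = "cvd",
                                       "Neoplasms" = "cancer",
                                       "Chronic respiratory diseases" = "crd"),
                         sex_map = c(Male = "M", Female = "W"),
                         year = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("measure", "sex", "age", "cause", "metric", "year", "val")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    abort_lg(paste("GBD file lacks columns:",
                   paste(missing_cols, collapse = ", ")))
  }
  d <- raw %>%
    dplyr::filter(.data$measure == "Deaths", .data$metric == "Rate")
  if (!is.null(year)) d <- d[d$year == year, ]
  if (length(unique(d$year)) > 1L) {
    abort_lg("several years present; pass `year`")
  }
  if (!all(d$sex %in% names(sex_map))) abort_lg("unknown sex label")
  unknown_cause <- setdiff(unique(d$cause), names(cause_map))
  if (length(unknown_cause)) {
    abort_lg(paste("cause not in cause_map:", unknown_cause[1]))
  }
  if (!"all" %in% cause_map) abort_lg("cause_map must map one cause to 'all'")

  parse_age <- function(a) {
    lo <- suppressWarnings(as.integer(sub("^(\\d+).*", "\\1", a)))
    if (anyNA(lo)) abort_lg(sprintf("unknown age-band label '%s'", a[which(is.na(lo))[1]]))
    lo
  }
  five <- d %>%
    dplyr::transmute(
      sex = unname(.env$sex_map[.data$sex]),
      cause = unname(.env$cause_map[.data$cause]),
      age_lo = parse_age(.data$age),
      mx = .data$val / 1e5
    )
  open_age <- max(five$age_lo)

  sched <- expand_schedule(five, open_age = open_age)

  # residual channel: all-cause minus the named causes
  named <- sched %>% dplyr::filter(.data$cause != "all")
  wide <- sched %>%
    dplyr::filter(.data$cause == "all") %>%
    dplyr::select("sex", "age", all_mx = "mx") %>%
    dplyr::left_join(
      named %>%
        dplyr::group_by(.data$sex, .data$age) %>%
        dplyr::summarise(named_mx = sum(.data$mx), .groups = "drop"),
      by = c("sex", "age")
    ) %>%
    dplyr::mutate(named_mx = dplyr::coalesce(.data$named_mx, 0))
  if (any(wide$named_mx > wide$all_mx * 1.02)) {
    warning("named causes exceed all-cause rate by >2% at some ages; ",
            "residual 'other' clamped at zero", call. = FALSE)
  }
  other <- wide %>%
    dplyr::transmute(.data$sex, cause = "other", .data$age,
                     mx = pmax(.data$all_mx - .data$named_mx, 0))
  dplyr::bind_rows(sched, other) %>%
    dplyr::arrange(.data$sex, .data$cause, .data$age)
}

#' Write and read pipeline tables as CSV
#'
#' Thin [readr] wrappers used by the pipeline driver; doubles survive the
#' round trip losslessly (shortest round-trip representation).
#'
#' @param x Tibble to write.
#' @param path CSV path.
#' @return `write_table_csv()` returns `x` invisibly; `read_table_csv()`
#'   the tibble.
#' @export
write_table_csv <- function(x, path) {
  out <- x
  # 17 significant digits guarantee a lossless double round trip
  dbl <- vapply(out, is.double, logical(1))
  out[dbl] <- lapply(out[dbl], function(v) {
    ifelse(is.na(v), NA_character_, sprintf("%.17g", v))
  })
  readr::write_csv(out, path)
  invisible(x)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  # base parser: correctly rounded doubles, so 17-digit output reads back
  # bit-identical
  tibble::as_tibble(utils::read.csv(path))
}

#' Serialise a simulation configuration to YAML
#'
#' @param config A [sim_config()].
#' @param path YAML file path.
#' @return `config`, invisibly.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  obj <- config
  for (f in c("baseline_hazards", "true_hr", "prevalence_spec")) {
    obj[[f]] <- as.list(as.data.frame(obj[[f]]))
  }
  yaml::write_yaml(obj, path, precision = 17L)
  invisible(config)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  obj <- yaml::read_yaml(path)
  sim_config(
    n_subjects = obj$n_subjects,
    seed = obj$seed,
    entry_age_range = unlist(obj$entry_age_range),
    admin_censor_years = obj$admin_censor_years,
    baseline_hazards = tibble::as_tibble(obj$baseline_hazards),
    true_hr = tibble::as_tibble(obj$true_hr),
    prevalence_spec = tibble::as_tibble(obj$prevalence_spec),
    n_regions = obj$n_regions,
    loss_rate = obj$loss_rate
  )
}
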