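# Period life tables and the partition of national mortality rates into
# lifestyle-group-specific rates. The partition is the bridge between the
# three data sources: cohort hazard ratios, population prevalence of the
# lifestyle groups, and national mortality schedules. For each cause c and
# age x it solves
#   m_pop,c(x) = sum_g p_g(x) * m0_c(x) * HR_{g,c}
# for the reference rate m0_c(x), so that the prevalence-weighted group
# rates reproduce the population schedule exactly at every age and cause.

#' Expand a 5-year mortality schedule to single years of age
#'
#' Each single year inherits its 5-year band's central death rate
#' (constant-within-band expansion); the terminal open-interval row is
#' passed through unchanged. Any grouping columns (e.g. `sex`, `cause`)
#' are preserved.
#'
#' @param five_year Tibble with columns `age_lo` (30, 35, ..., 90, plus the
#'   open-interval age, default 95) and `mx`, plus optional grouping
#'   columns.
#' @param open_age Lower bound of the terminal open interval.
#' @return Tibble with `age` (single years) and `mx`, grouping columns
#'   preserved.
#' @export
expand_schedule <- function(five_year, open_age = 95L) {
  stopifnot(all(c("age_lo", "mx") %in% names(five_year)))
  keys <- setdiff(names(five_year), c("age_lo", "mx"))
  check_bands <- function(a) {
    a <- sort(a)
    expect <- c(seq(min(a), open_age - 5L, by = 5L), open_age)
    if (!identical(as.integer(a), as.integer(expect))) {
      abort_lg("5-year bands must be contiguous up to the open interval")
    }
  }
  five_year %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) %>%
    dplyr::group_modify(function(g, ...) {
      check_bands(g$age_lo)
      g %>%
        dplyr::mutate(
          width = ifelse(.data$age_lo >= open_age, 1L, 5L)
        ) %>%
        tidyr::uncount(.data$width, .id = "off") %>%
        dplyr::transmute(age = .data$age_lo + .data$off - 1L, mx = .data$mx)
    }) %>%
    dplyr::ungroup()
}

#' Partition a population mortality schedule into lifestyle-group rates
#'
#' For each sex, cause, and age, scales a cause-specific reference rate so
#' that the prevalence-weighted mean of the group rates equals the
#' population rate: `m0 = m_pop / sum_g p_g * HR_g`, `m_g = m0 * HR_g`.
#' Ages above the oldest prevalence band reuse that band (surveillance
#' prevalence typically stops at 80-84).
#'
#' @param schedule Mortality schedule tibble (`sex`, `cause`, `age`, `mx`);
#'   rows with `cause = "all"` are ignored (the all-cause group rate is the
#'   sum of its cause rates).
#' @param prevalence Prevalence tibble (`sex`, `age_band`, `group`, `p`);
#'   each (sex, band) block must sum to 1 within 1e-12.
#' @param hrs Hazard-ratio tibble with columns `group` (or `level`),
#'   `cause`, `sex`, `hr`; rows with sex `"both"` apply to both sexes.
#' @return Tibble (`sex`, `group`, `cause`, `age`, `mx`) covering every
#'   cause present in `schedule` (except `"all"`).
#' @export
partition_rates <- function(schedule, prevalence, hrs) {
  if ("level" %in% names(hrs) && !"group" %in% names(hrs)) {
    hrs <- dplyr::rename(hrs, group = "level")
  }
  stopifnot(all(c("sex", "cause", "age", "mx") %in% names(schedule)),
            all(c("sex", "age_band", "group", "p") %in% names(prevalence)),
            all(c("group", "cause", "hr") %in% names(hrs)))
  if (!"sex" %in% names(hrs)) hrs$sex <- "both"

  sums <- prevalence %>%
    dplyr::group_by(.data$sex, .data$age_band) %>%
    dplyr::summarise(s = sum(.data$p), .groups = "drop")
  if (any(abs(sums$s - 1) > 1e-12)) {
    abort_lg("prevalence rows must sum to 1 within 1e-12")
  }
  if (any(hrs$hr <= 0)) abort_lg("hazard ratios must be positive")

  sched <- schedule %>% dplyr::filter(.data$cause != "all")
  # a schedule carrying only the all-cause aggregate is partitioned as a
  # single channel
  if (!nrow(sched)) sched <- schedule
  band_hi <- max(as.integer(sub("-.*", "", prevalence$age_band)))
  causes <- unique(sched$cause)
  sexes <- unique(sched$sex)

  pick_hr <- function(sx) {
    h <- hrs[hrs$sex %in% c(sx, "both"), c("group", "cause", "hr", "sex")]
    # sex-specific rows win over "both"
    h %>%
      dplyr::arrange(.data$group, .data$cause, .data$sex != sx) %>%
      dplyr::distinct(.data$group, .data$cause, .keep_all = TRUE) %>%
      dplyr::select("group", "cause", "hr")
  }

  out <- purrr::map_dfr(sexes, function(sx) {
    h <- pick_hr(sx)
    missing_hr <- tidyr::expand_grid(group = unique(prevalence$group),
                                     cause = causes) %>%
      dplyr::anti_join(h, by = c("group", "cause"))
    if (nrow(missing_hr)) {
      abort_lg(sprintf("missing HR for group '%s', cause '%s'",
                       missing_hr$group[1], missing_hr$cause[1]))
    }
    sched %>%
      dplyr::filter(.data$sex == sx) %>%
      dplyr::mutate(age_band = age_band_5y(.data$age, hi = band_hi)) %>%
      dplyr::inner_join(
        prevalence %>% dplyr::filter(.data$sex == sx) %>%
          dplyr::select("age_band", "group", "p"),
        by = "age_band", relationship = "many-to-many"
      ) %>%
      dplyr::inner_join(h, by = c("group", "cause")) %>%
      dplyr::group_by(.data$cause, .data$age) %>%
      dplyr::mutate(mx = .data$mx * .data$hr / sum(.data$p * .data$hr)) %>%
      dplyr::ungroup() %>%
      dplyr::transmute(sex = sx, group = .data$group, cause = .data$cause,
                       age = .data$age, mx = .data$mx)
  })
  dplyr::arrange(out, .data$sex, .data$group, .data$cause, .data$age)
}

#' Build a single-year period life table
#'
#' Standard period life-table columns from central death rates on one-year
#' age bands with a terminal open interval: `qx = mx / (1 + (1 - ax) mx)`
#' with `ax = 0.5` (deaths mid-interval on average), survivors `lx` from a
#' radix of 100,000 at the index age, `dx = lx qx`,
#' `Lx = l_{x+1} + ax dx`, open interval `qx = 1` and `Lx = lx / mx`,
#' `Tx` the tail sum of `Lx`, and `ex = Tx / lx`.
#'
#' @param rates Tibble with columns `age` (contiguous ages on a uniform
#'   grid, by default single years, last row the open interval) and `mx`
#'   for one sex/group.
#' @param radix Survivors at the index age.
#' @param ax Average fraction of the interval lived by those dying in it.
#' @return A `life_table` tibble with columns `age`, `mx`, `qx`, `lx`,
#'   `dx`, `Lx`, `Tx`, `ex`.
#' @export
build_life_table <- function(rates, radix = 1e5, ax = 0.5) {
  stopifnot(all(c("age", "mx") %in% names(rates)))
  lt <- dplyr::arrange(tibble::as_tibble(rates), .data$age)
  if (any(duplicated(lt$age))) abort_lg("one row per age required")
  step <- diff(lt$age)
  if (length(step) && (any(step <= 0) || any(abs(step - step[1]) > 1e-9))) {
    abort_lg("ages must be contiguous on a uniform grid")
  }
  h <- if (length(step)) step[1] else 1
  if (any(lt$mx < 0)) abort_lg("negative death rates")
  n <- nrow(lt)
  if (lt$mx[n] <= 0) abort_lg("open-interval rate must be positive")

  qx <- h * lt$mx / (1 + (1 - ax) * h * lt$mx)
  qx[n] <- 1
  lx <- radix * cumprod(c(1, 1 - qx[-n]))
  dx <- lx * qx
  Lx <- c(h * (lx[-1] + ax * dx[-n]), lx[n] / lt$mx[n])
  Tx <- rev(cumsum(rev(Lx)))
  ex <- ifelse(lx > 0, Tx / lx, 0)

  out <- tibble::tibble(age = lt$age, mx = lt$mx, qx = qx, lx = lx,
                        dx = dx, Lx = Lx, Tx = Tx, ex = ex)
  class(out) <- c("life_table", class(out))
  out
}

#' Life expectancy at an exact age from a life table
#'
#' @param lt A [build_life_table()] result.
#' @param age Exact age (must be a table row).
#' @return `ex` at that age, in years.
#' @export
life_expectancy <- function(lt, age = 30) {
  i <- match(age, lt$age)
  if (is.na(i)) abort_lg("age not in life table")
  lt$ex[i]
}

#' Life expectancy by lifestyle group, with gained years versus reference
#'
#' Composes [partition_rates()] and [build_life_table()]: partitions the
#' population schedule into group-specific cause rates, sums causes into
#' all-cause group schedules, builds one life table per sex and group, and
#' reports life expectancy at the index age plus the gain relative to the
#' reference group.
#'
#' @inheritParams partition_rates
#' @param index_age Exact age at which life expectancy is evaluated.
#' @param reference Reference group for gains (default: the first group in
#'   `hrs`, conventionally the highest-risk "0-1" score group).
#' @return Tibble (`sex`, `group`, `ex`, `gain`).
#' @export
life_expectancy_by_group <- function(schedule, prevalence, hrs,
                                     index_age = 30, reference = NULL) {
  if ("level" %in% names(hrs) && !"group" %in% names(hrs)) {
    hrs <- dplyr::rename(hrs, group = "level")
  }
  groups <- unique(hrs$group)
  if (is.null(reference)) reference <- groups[1]
  if (!reference %in% groups) abort_lg("unknown reference group")

  part <- partition_rates(schedule, prevalence, hrs)
  allc <- part %>%
    dplyr::group_by(.data$sex, .data$group, .data$age) %>%
    dplyr::summarise(mx = sum(.data$mx), .groups = "drop")

  out <- allc %>%
    dplyr::group_by(.data$sex, .data$group) %>%
    dplyr::group_modify(function(g, ...) {
      lt <- build_life_table(g)
      tibble::tibble(ex = life_expectancy(lt, index_age))
    }) %>%
    dplyr::ungroup() %>%
    dplyr::group_by(.data$sex) %>%
    dplyr::mutate(gain = .data$ex - .data$ex[.data$group == reference]) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(group = factor(.data$group, levels = groups)) %>%
    dplyr::arrange(.data$sex, .data$group)
  out
}
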