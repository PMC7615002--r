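# Classification of the five lifestyle factors into low-/high-risk flags and
# the two combined scores: the simple count (0-5) of low-risk factors and the
# expanded graded score (5-25, each factor graded 1 = least healthy to
# 5 = most healthy).

#' Diet score from five dietary criteria
#'
#' One point per criterion met: fresh vegetables daily, fresh fruit daily,
#' red meat 1-6 days/week, legumes on at least 4 days/week, fish on at least
#' 1 day/week. A score of 4-5 marks the low-risk diet group.
#'
#' @param veg_daily,fruit_daily,red_meat_1_6,legumes_4plus,fish_1plus
#'   Logical vectors (recycled to a common length).
#' @return Integer vector of scores in 0-5.
#' @export
#' @examples
#' diet_score(TRUE, TRUE, TRUE, TRUE, TRUE)  # 5
diet_score <- function(veg_daily, fruit_daily, red_meat_1_6,
                       legumes_4plus, fish_1plus) {
  flags <- cbind(veg_daily, fruit_daily, red_meat_1_6, legumes_4plus, fish_1plus)
  if (!is.logical(flags)) abort_lg("diet criteria must be logical")
  as.integer(rowSums(flags))
}

smoking_levels <- c("never", "former_quit_not_illness", "former_quit_illness",
                    "current")
drinking_levels <- c("less_than_daily", "former", "daily")

#' Classify lifestyle records into low-risk flags and the simple score
#'
#' Applies the five low-risk definitions to a data frame of lifestyle
#' records and appends one logical flag per factor plus `simple_score`
#' (the count of low-risk factors, 0-5):
#'
#' * smoking: never smoked, or quit for reasons other than illness;
#' * alcohol: less-than-daily drinking, or daily drinking below 30 g
#'   (men) / 15 g (women) of pure alcohol per day; former drinkers are not
#'   low risk (sick-quitter exclusion);
#' * physical activity: total activity at or above the sex- and age-specific
#'   median (age bands <50, 50-59, >= 60);
#' * diet: diet score 4-5 (see [diet_score()]);
#' * body shape: BMI in \[18.5, 27.9\] kg/m2 (inclusive) and waist
#'   circumference strictly below 90 cm (men) / 85 cm (women).
#'
#' @param data Data frame with columns `sex` ("M"/"W"), `age`,
#'   `smoking_status` (one of `"never"`, `"former_quit_not_illness"`,
#'   `"former_quit_illness"`, `"current"`), `drinking_status` (one of
#'   `"less_than_daily"`, `"former"`, `"daily"`), `pure_alcohol_g_day`,
#'   `total_pa` (MET-h/day), `diet_score` (0-5; or the five logical
#'   `diet_*` columns accepted by [diet_score()]), `bmi`, `wc`.
#' @param pa_medians Data frame with columns `sex`, `pa_band` (`"<50"`,
#'   `"50-59"`, `">=60"`), `median_pa`: reference medians of total physical
#'   activity, computed externally from the reference cohort.
#' @return `data` with logical columns `low_smoking`, `low_alcohol`,
#'   `low_activity`, `low_diet`, `low_body` and integer `simple_score`
#'   appended, as a tibble.
#' @export
classify_lifestyle <- function(data, pa_medians) {
  need <- c("sex", "age", "smoking_status", "drinking_status",
            "pure_alcohol_g_day", "total_pa", "bmi", "wc")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort_lg(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  }
  if (!all(data$smoking_status %in% smoking_levels)) {
    abort_lg("unknown smoking_status level")
  }
  if (!all(data$drinking_status %in% drinking_levels)) {
    abort_lg("unknown drinking_status level")
  }
  if (any(data$bmi <= 0) || any(data$wc <= 0) || any(data$total_pa < 0)) {
    abort_lg("bmi and wc must be positive and total_pa non-negative")
  }
  if (!"diet_score" %in% names(data)) {
    data <- dplyr::mutate(
      data,
      diet_score = diet_score(.data$diet_veg_daily, .data$diet_fruit_daily,
                              .data$diet_red_meat_1_6, .data$diet_legumes_4plus,
                              .data$diet_fish_1plus)
    )
  }

  med <- pa_medians
  stopifnot(all(c("sex", "pa_band", "median_pa") %in% names(med)))

  tibble::as_tibble(data) %>%
    dplyr::mutate(
      pa_band = dplyr::case_when(
        .data$age < 50 ~ "<50",
        .data$age < 60 ~ "50-59",
        TRUE ~ ">=60"
      )
    ) %>%
    dplyr::left_join(med, by = c("sex", "pa_band")) %>%
    dplyr::mutate(
      low_smoking = .data$smoking_status %in%
        c("never", "former_quit_not_illness"),
      low_alcohol = .data$drinking_status == "less_than_daily" |
        (.data$drinking_status == "daily" &
           .data$pure_alcohol_g_day < ifelse(.data$sex == "M", 30, 15)),
      low_activity = .data$total_pa >= .data$median_pa,
      low_diet = .data$diet_score >= 4,
      low_body = .data$bmi >= 18.5 & .data$bmi <= 27.9 &
        .data$wc < ifelse(.data$sex == "M", 90, 85),
      simple_score = as.integer(.data$low_smoking) +
        as.integer(.data$low_alcohol) + as.integer(.data$low_activity) +
        as.integer(.data$low_diet) + as.integer(.data$low_body)
    ) %>%
    dplyr::select(-"pa_band", -"median_pa")
}

#' Default grade tables for the expanded lifestyle score
#'
#' Grades each factor's categories from 1 (least healthy) to 5 (most
#' healthy) following the ordering of adjusted all-cause hazard ratios
#' across categories in large-cohort analyses of these factors; ties are
#' broken by conventional category order. Smokers who quit because of
#' illness grade with current smokers; former drinkers grade with the
#' heaviest-drinking category (the two carry similar death risk and are
#' conventionally merged).
#'
#' @return Tibble with columns `factor`, `category`, `grade`.
#' @export
default_grade_tables <- function() {
  tibble::tribble(
    ~factor,     ~category,                 ~grade,
    "smoking",   "current_20plus",          1L,
    "smoking",   "current_1_9",             2L,
    "smoking",   "current_10_19",           3L,
    "smoking",   "former_quit_not_illness", 4L,
    "smoking",   "never",                   5L,
    "alcohol",   "former_or_60plus",        1L,
    "alcohol",   "daily_30_59",             2L,
    "alcohol",   "daily_15_29",             3L,
    "alcohol",   "less_than_daily",         4L,
    "alcohol",   "daily_lt15",              5L,
    "activity",  "q1",                      1L,
    "activity",  "q2",                      2L,
    "activity",  "q3",                      3L,
    "activity",  "q4",                      4L,
    "activity",  "q5",                      5L,
    "diet",      "score_0_1",               1L,
    "diet",      "score_2",                 2L,
    "diet",      "score_3",                 3L,
    "diet",      "score_4",                 4L,
    "diet",      "score_5",                 5L,
    "body",      "obese_general_abdominal", 1L,
    "body",      "underweight",             2L,
    "body",      "obese_general_only",      3L,
    "body",      "normal_bmi_high_wc",      4L,
    "body",      "normal",                  5L
  )
}

#' Expanded lifestyle score (5-25)
#'
#' Sums the grades (1-5) of each subject's category on the five lifestyle
#' factors. Categories are supplied as columns `smoking_cat`, `alcohol_cat`,
#' `activity_cat`, `diet_cat`, `body_cat` holding category labels present in
#' the grade table.
#'
#' @param data Data frame with the five `*_cat` columns.
#' @param grade_tables Tibble mapping (`factor`, `category`) to `grade`,
#'   as produced by [default_grade_tables()].
#' @return `data` with an integer `expanded_score` column appended.
#' @export
expanded_score <- function(data, grade_tables = default_grade_tables()) {
  cols <- c(smoking = "smoking_cat", alcohol = "alcohol_cat",
            activity = "activity_cat", diet = "diet_cat", body = "body_cat")
  missing_cols <- setdiff(unname(cols), names(data))
  if (length(missing_cols)) {
    abort_lg(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  }
  total <- rep(0L, nrow(data))
  for (f in names(cols)) {
    tab <- grade_tables[grade_tables$factor == f, ]
    g <- tab$grade[match(data[[cols[[f]]]], tab$category)]
    if (anyNA(g)) {
      abort_lg(sprintf("category not in grade table for factor '%s'", f))
    }
    total <- total + g
  }
  dplyr::mutate(tibble::as_tibble(data), expanded_score = as.integer(total))
}
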