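# Arriaga decomposition: exact additive attribution of a life-expectancy
# difference between two populations to single-year age groups, and
# proration of each age's contribution across causes of death by the
# cause-specific rate differences at that age.

#' Age-specific contributions to a life-expectancy difference (Arriaga)
#'
#' Decomposes `e2(index) - e1(index)` into per-age contributions using the
#' combined direct + indirect + interaction form: for ages below the open
#' interval
#' \deqn{\Delta_x = \frac{l^1_x}{l^1_{30}}\left(\frac{L^2_x}{l^2_x} -
#'   \frac{L^1_x}{l^1_x}\right) + \frac{T^2_{x+1}}{l^1_{30}}
#'   \left(\frac{l^1_x}{l^2_x} - \frac{l^1_{x+1}}{l^2_{x+1}}\right)}
#' and for the open interval
#' \deqn{\Delta_x = \frac{l^1_x}{l^1_{30}}\left(\frac{T^2_x}{l^2_x} -
#'   \frac{T^1_x}{l^1_x}\right).}
#' The contributions are exact: they sum to the life-expectancy difference
#' (population 2 minus population 1) up to floating-point error.
#'
#' @param lt1,lt2 [build_life_table()] results on identical age grids with
#'   the same radix; population 1 is the reference (conventionally the
#'   higher-mortality group).
#' @return Tibble (`age`, `delta`) in years.
#' @export
arriaga_age_contributions <- function(lt1, lt2) {
  if (!identical(lt1$age, lt2$age)) abort_lg("life tables on different age grids")
  n <- nrow(lt1)
  l1 <- lt1$lx; l2 <- lt2$lx
  L1 <- lt1$Lx; L2 <- lt2$Lx
  T1 <- lt1$Tx; T2 <- lt2$Tx
  radix <- l1[1]

  delta <- numeric(n)
  i <- seq_len(n - 1L)
  delta[i] <- (l1[i] / radix) * (L2[i] / l2[i] - L1[i] / l1[i]) +
    (T2[i + 1L] / radix) * (l1[i] / l2[i] - l1[i + 1L] / l2[i + 1L])
  delta[n] <- (l1[n] / radix) * (T2[n] / l2[n] - T1[n] / l1[n])
  tibble::tibble(age = lt1$age, delta = delta)
}

#' Allocate age contributions across causes of death
#'
#' Prorates each age's contribution by the cause-specific rate differences:
#' `delta_{x,c} = delta_x (m1_{x,c} - m2_{x,c}) / (m1_x - m2_x)`. Ages
#' where the all-cause rates of the two groups differ by less than 1e-12
#' contribute zero to every cause (their `delta_x` is itself negligible).
#'
#' @param age_contrib Tibble (`age`, `delta`) from
#'   [arriaga_age_contributions()].
#' @param rates1,rates2 Cause-specific schedules for the two groups:
#'   tibbles (`cause`, `age`, `mx`) covering the same causes and ages; rows
#'   with `cause = "all"`, if present, must equal the sum over causes
#'   within 1e-9.
#' @return Tibble (`age`, `cause`, `delta`); per age, the cause
#'   contributions sum to the age contribution.
#' @export
allocate_causes <- function(age_contrib, rates1, rates2) {
  prep <- function(r, tag) {
    r <- tibble::as_tibble(r)
    stopifnot(all(c("cause", "age", "mx") %in% names(r)))
    by_cause <- r %>% dplyr::filter(.data$cause != "all")
    tot <- by_cause %>%
      dplyr::group_by(.data$age) %>%
      dplyr::summarise(m_all = sum(.data$mx), .groups = "drop")
    declared <- r %>% dplyr::filter(.data$cause == "all")
    if (nrow(declared)) {
      chk <- dplyr::inner_join(declared, tot, by = "age")
      if (any(abs(chk$mx - chk$m_all) > 1e-9)) {
        abort_lg(sprintf("cause rates do not sum to all-cause in rates%s", tag))
      }
    }
    dplyr::inner_join(by_cause, tot, by = "age")
  }
  r1 <- prep(rates1, "1")
  r2 <- prep(rates2, "2")

  joined <- dplyr::inner_join(
    r1, r2, by = c("cause", "age"), suffix = c("1", "2")
  ) %>%
    dplyr::inner_join(age_contrib, by = "age")
  if (!nrow(joined)) abort_lg("no common (cause, age) rows between groups")

  joined %>%
    dplyr::mutate(
      denom = .data$m_all1 - .data$m_all2,
      delta = ifelse(abs(.data$denom) < 1e-12, 0,
                     .data$delta * (.data$mx1 - .data$mx2) / .data$denom)
    ) %>%
    dplyr::select("age", "cause", "delta") %>%
    dplyr::arrange(.data$age, .data$cause)
}

#' Per-cause totals and shares of a decomposition
#'
#' Sums cause contributions over ages and expresses each cause's total as a
#' percentage of the grand total (the overall life-expectancy difference).
#'
#' @param alloc Tibble (`age`, `cause`, `delta`) from [allocate_causes()],
#'   or any tibble with `cause` and `delta` columns.
#' @return Tibble (`cause`, `years`, `share_pct`); shares sum to 100.
#' @export
cause_shares <- function(alloc) {
  stopifnot(all(c("cause", "delta") %in% names(alloc)))
  tot <- alloc %>%
    dplyr::group_by(.data$cause) %>%
    dplyr::summarise(years = sum(.data$delta), .groups = "drop")
  grand <- sum(tot$years)
  if (abs(grand) < .Machine$double.eps * 100) {
    abort_lg("grand total is zero: shares undefined")
  }
  dplyr::mutate(tot, share_pct = 100 * .data$years / grand)
}

#' Decompose the life-expectancy gap between two lifestyle groups
#'
#' End-to-end driver: partitions the population schedule into group rates,
#' builds the two groups' life tables, runs the Arriaga decomposition by
#' age, allocates contributions to causes, and summarises cause shares.
#' Group 2 is the (lower-mortality) comparison group, so positive totals
#' mean years gained by group 2 relative to group 1.
#'
#' @inheritParams partition_rates
#' @param group1,group2 Group labels; group 1 is the reference.
#' @param sex `"M"` or `"W"`.
#' @param index_age Exact age at which the gap is decomposed.
#' @return An object of class `le_decomposition`: a list with `by_age`,
#'   `by_age_cause`, `shares`, `e1`, `e2`, `gap`, `sex`, `groups`.
#' @export
decompose_le_gap <- function(schedule, prevalence, hrs, group1, group2,
                             sex, index_age = 30) {
  part <- partition_rates(schedule, prevalence, hrs) %>%
    dplyr::filter(.data$sex == .env$sex, .data$group %in% c(group1, group2))
  if (!nrow(part)) abort_lg("unknown sex or groups")

  rates_of <- function(g) part %>%
    dplyr::filter(.data$group == g) %>%
    dplyr::select("cause", "age", "mx")
  all_of_g <- function(r) r %>%
    dplyr::group_by(.data$age) %>%
    dplyr::summarise(mx = sum(.data$mx), .groups = "drop")

  r1 <- rates_of(group1); r2 <- rates_of(group2)
  lt1 <- build_life_table(all_of_g(r1))
  lt2 <- build_life_table(all_of_g(r2))
  by_age <- arriaga_age_contributions(lt1, lt2)
  by_age_cause <- allocate_causes(by_age, r1, r2)

  structure(
    list(
      by_age = by_age,
      by_age_cause = by_age_cause,
      shares = cause_shares(by_age_cause),
      e1 = life_expectancy(lt1, index_age),
      e2 = life_expectancy(lt2, index_age),
      gap = life_expectancy(lt2, index_age) - life_expectancy(lt1, index_age),
      sex = sex,
      groups = c(group1, group2)
    ),
    class = "le_decomposition"
  )
}

#' @export
print.le_decomposition <- function(x, ...) {
  cat(sprintf(
    "<le_decomposition> sex %s: e(%s) %.2f y vs e(%s) %.2f y, gap %.2f y\n",
    x$sex, x$groups[1], x$e1, x$groups[2], x$e2, x$gap
  ))
  print(x$shares)
  invisible(x)
}
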