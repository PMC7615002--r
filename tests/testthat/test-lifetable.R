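test_that("5-year bands expand constant-within-band and round-trip", {
  five <- tibble::tibble(age_lo = c(seq(30, 90, 5), 95),
                         mx = c(seq(0.001, 0.013, length.out = 13), 0.3))
  single <- expand_schedule(five)
  expect_equal(single$age, 30:95)
  expect_equal(single$mx[single$age %in% 30:34], rep(0.001, 5))
  expect_equal(single$mx[single$age == 95], 0.3)
  # monotone bands stay monotone
  expect_true(all(diff(single$mx) >= 0))
  # averaging single years back to bands recovers the input exactly
  back <- single %>%
    dplyr::mutate(age_lo = ifelse(age >= 95, 95L, (age %/% 5L) * 5L)) %>%
    dplyr::summarise(mx = mean(mx), .by = age_lo)
  expect_equal(back$mx, five$mx)
  # grouping columns preserved
  two <- dplyr::bind_rows(dplyr::mutate(five, sex = "M"),
                          dplyr::mutate(five, sex = "W", mx = mx / 2))
  ex2 <- expand_schedule(two)
  expect_equal(nrow(ex2), 2 * 66)
  expect_error(expand_schedule(five[-3, ]), "contiguous")
})

test_that("rate partition satisfies its closed forms and conservation", {
  # two groups p = (0.5, 0.5), HR = (1, 2), m_pop = 0.01
  sched <- tibble::tibble(sex = "M", cause = "all", age = 30:95, mx = 0.01)
  prev <- tidyr::expand_grid(
    sex = "M", age_band = sprintf("%d-%d", seq(30, 80, 5), seq(34, 84, 5)),
    group = c("a", "b")
  )
  prev$p <- 0.5
  hrs <- tibble::tibble(group = c("a", "b"), cause = "all", sex = "both",
                        hr = c(1, 2))
  part <- partition_rates(sched, prev, hrs)
  expect_equal(unique(part$mx[part$group == "a"]), 0.01 / 1.5)
  expect_equal(unique(part$mx[part$group == "b"]), 0.02 / 1.5)

  # all HRs 1: every group reproduces the population schedule
  hrs1 <- dplyr::mutate(hrs, hr = 1)
  p1 <- partition_rates(sched, prev, hrs1)
  expect_true(all(abs(p1$mx - 0.01) < 1e-15))

  # single group with p = 1: conservation forces m_g = m_pop for any HR
  prev1 <- dplyr::mutate(prev[prev$group == "a", ], p = 1)
  hrs_38 <- tibble::tibble(group = "a", cause = "all", sex = "both", hr = 0.38)
  pg <- partition_rates(sched, prev1, hrs_38)
  expect_true(all(abs(pg$mx - 0.01) < 1e-15))

  expect_error(partition_rates(sched, dplyr::mutate(prev, p = 0.4), hrs),
               "sum to 1")
  expect_error(partition_rates(sched, prev, hrs[1, ]), "missing HR")
})

test_that("conservation holds at every age and cause on realistic inputs", {
  cfg <- sim_config(n_subjects = 100, seed = 2)
  sched <- generate_mortality_schedule(cfg)
  prev <- generate_prevalence_table(cfg)
  hrs <- dplyr::mutate(cfg$true_hr, sex = "both")
  part <- partition_rates(sched, prev, hrs)
  prev_l <- dplyr::select(prev, sex, age_band, group, p)
  chk <- part %>%
    dplyr::mutate(age_band = sprintf("%d-%d", pmin((age %/% 5L) * 5L, 80L),
                                     pmin((age %/% 5L) * 5L, 80L) + 4L)) %>%
    dplyr::inner_join(prev_l, by = c("sex", "age_band", "group")) %>%
    dplyr::summarise(m_recon = sum(p * mx), .by = c(sex, cause, age)) %>%
    dplyr::inner_join(dplyr::filter(sched, cause != "all"),
                      by = c("sex", "cause", "age"))
  expect_lt(max(abs(chk$m_recon - chk$mx)), 1e-12)
})

test_that("life table matches closed forms", {
  # constant hazard 0.02 at every age including the open interval
  lt <- build_life_table(tibble::tibble(age = 30:95, mx = 0.02))
  expect_lt(abs(life_expectancy(lt, 30) - 50), 0.2)
  expect_true(all(diff(lt$lx) < 0))
  expect_true(all(lt$qx >= 0 & lt$qx <= 1))
  expect_equal(lt$Tx, rev(cumsum(rev(lt$Lx))))
  expect_equal(lt$ex, lt$Tx / lt$lx)

  # certain survival to 95 then exponential with m = 0.05: e30 = 65 + 20
  lt2 <- build_life_table(tibble::tibble(age = 30:95,
                                         mx = c(rep(0, 65), 0.05)))
  expect_equal(life_expectancy(lt2, 30), 85)

  expect_error(build_life_table(tibble::tibble(age = 30:95,
                                               mx = c(rep(0.01, 65), 0))),
               "open-interval")
  expect_error(build_life_table(tibble::tibble(age = c(30:40, 42:95),
                                               mx = 0.01)),
               "uniform grid")
})

test_that("life-table e(30) agrees with the lifetime-simulation oracle", {
  for (s in 1:4) {
    sched <- random_schedule(s)
    e_lt <- life_expectancy(build_life_table(sched), 30)
    orc <- simulate_lifetimes(sched, n = 60000, seed = s + 100)
    expect_lt(abs(e_lt - orc$e30), 3 * orc$mc_se + 0.05)
  }
})

test_that("pointwise rate dominance implies lower life expectancy", {
  base <- random_schedule(7)
  worse <- dplyr::mutate(base, mx = mx * 1.15)
  e_base <- life_expectancy(build_life_table(base), 30)
  e_worse <- life_expectancy(build_life_table(worse), 30)
  expect_lt(e_worse, e_base)
})

test_that("halving the age step barely changes e(30) on a smooth schedule", {
  gomp <- function(a) 8e-5 * exp(0.09 * a)
  e_at <- function(h) {
    ages <- seq(30, 95, by = h)
    mx <- ifelse(ages >= 95, gomp(95.5), gomp(ages + h / 2))
    life_expectancy(build_life_table(tibble::tibble(age = ages, mx = mx)), 30)
  }
  expect_lt(abs(e_at(1) - e_at(0.5)), 0.05)
})

test_that("life expectancy by group is monotone under monotone HRs", {
  cfg <- sim_config(n_subjects = 100, seed = 2)
  sched <- generate_mortality_schedule(cfg)
  prev <- generate_prevalence_table(cfg)
  hrs <- dplyr::mutate(cfg$true_hr, sex = "both")
  le <- life_expectancy_by_group(sched, prev, hrs)
  for (sx in c("M", "W")) {
    exs <- le$ex[le$sex == sx]
    expect_true(all(diff(exs) > 0))
    gains <- le$gain[le$sex == sx]
    expect_equal(gains[1], 0)
    expect_equal(gains, exs - exs[1])
  }
  # all HRs 1: gains are exactly zero
  le0 <- life_expectancy_by_group(sched, prev, dplyr::mutate(hrs, hr = 1))
  expect_true(all(abs(le0$gain) < 1e-12))
})
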