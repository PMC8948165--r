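test_that("logistic incidence curve hits its midpoint, scale points and asymptote", {
  expect_equal(logistic_cif(60, L = 0.08), 0.04)
  expect_equal(logistic_cif(1e6, L = 0.08), 0.08)
  expect_equal(logistic_cif(60 - 8 * log(19), L = 0.3), 0.05 * 0.3)
  ages <- seq(0, 120, by = 1)
  expect_true(all(diff(logistic_cif(ages, L = 0.1)) > 0))
})

test_that("logistic inversion recovers ages and the 90% onset interval", {
  expect_equal(invert_logistic_cif(0.04, L = 0.08), 60)
  # closed form x0 -+ (1/k) log(19), independent of L
  expect_equal(invert_logistic_cif(0.05 * 0.08, L = 0.08),
               60 - 8 * log(19), tolerance = 1e-12)
  expect_equal(invert_logistic_cif(0.95 * 0.02, L = 0.02),
               60 + 8 * log(19), tolerance = 1e-12)
  expect_equal(round(invert_logistic_cif(c(0.05, 0.95) * 0.08, L = 0.08), 1),
               c(36.4, 83.6))
  # round trip
  p <- c(1e-4, 0.01, 0.05, 0.079)
  expect_equal(logistic_cif(invert_logistic_cif(p, L = 0.08), L = 0.08), p,
               tolerance = 1e-9)
  expect_error(invert_logistic_cif(0.09, L = 0.08), "between 0 and L")
  expect_error(invert_logistic_cif(0.08, L = 0.08), "between 0 and L")
})

test_that("Aalen-Johansen reduces to the empirical CDF without competing events", {
  aj <- aalen_johansen_cif(c(1, 2, 3, 4), rep("event", 4))
  expect_equal(cif_at(aj, 2.5), 0.5)
  expect_equal(cif_at(aj, 0.5), 0)
  expect_equal(cif_at(aj, 10), 1)

  none <- aalen_johansen_cif(c(1, 2, 3), rep("competing", 3))
  expect_equal(cif_at(none, 5), 0)
})

test_that("Aalen-Johansen matches the hand-computed product-limit table", {
  # subjects: interest t=1, competing t=2, censored t=3, interest t=4,
  # alive (censored) t=5
  aj <- aalen_johansen_cif(c(1, 2, 3, 4, 5),
                           c("event", "competing", "censored", "event",
                             "censored"))
  # t=1: 1/5 = 0.2; t=2: competing 0.8 * 1/4 = 0.2;
  # t=4: 0.2 + S(4-) * 1/2 = 0.2 + 0.6 * 0.5 = 0.5
  expect_equal(cif_at(aj, 1), 0.2)
  expect_equal(cif_at(aj, 2, which = "competing"), 0.2)
  expect_equal(cif_at(aj, 4), 0.5)
  expect_equal(aj$cif + aj$cif_competing + aj$surv, rep(1, nrow(aj)))
  expect_true(all(diff(aj$cif) >= 0))

  gl <- glance(aj)
  expect_equal(gl$n, 5)
  expect_equal(gl$n_event, 2)
})

test_that("merging competing events into censoring upper-bounds the CIF", {
  set.seed(4)
  times <- round(rexp(60, 1 / 30) + 1, 1)
  kinds <- sample(c("event", "competing", "censored"), 60, replace = TRUE)
  aj <- aalen_johansen_cif(times, kinds)
  km <- aalen_johansen_cif(times, ifelse(kinds == "competing", "censored",
                                         kinds))
  grid <- sort(unique(times))
  expect_true(all(cif_at(km, grid) - cif_at(aj, grid) >= -1e-12))
})

test_that("Aalen-Johansen rejects degenerate inputs", {
  expect_error(aalen_johansen_cif(numeric(), character()), "no observations")
  expect_error(aalen_johansen_cif(c(1, -2), c("event", "event")),
               "non-negative")
  expect_error(aalen_johansen_cif(1, "death"), "kinds")
})

test_that("incidence surface returns stored values and steps between them", {
  surf <- build_incidence_surface(toy_incidence_table())
  expect_equal(cum_inc_at(surf, "male", 1950, 40), 0.03)
  expect_equal(cum_inc_at(surf, "female", 1980, 80), 0.05)
  # last observation carried forward between grid ages
  expect_equal(cum_inc_at(surf, "male", 1950, 59.9), 0.03)
  expect_equal(cum_inc_at(surf, "male", 1950, 60), 0.06)
  # before the first tabulated age: nothing diagnosed yet
  expect_equal(cum_inc_at(surf, "male", 1950, 10), 0)
  # lifetime value for missing age
  expect_equal(cum_inc_at(surf, "male", 1950, NA), 0.08)
})

test_that("queries clamp to the nearest birth year and average unknown sex", {
  surf <- build_incidence_surface(toy_incidence_table())
  expect_warning(v <- cum_inc_at(surf, "male", 2000, 40), "clamped")
  expect_equal(v, 0.05)  # nearest year is 1980
  expect_warning(v2 <- cum_inc_at(surf, "male", 1900, 40), "clamped")
  expect_equal(v2, 0.03)
  expect_equal(cum_inc_at(surf, NA, 1950, 60), (0.06 + 0.02) / 2)
})

test_that("non-monotone strata are rejected with the offending ages", {
  tab <- toy_incidence_table()
  tab$cum_inc[tab$sex == "male" & tab$birth_year == 1950 & tab$age == 60] <-
    0.02
  expect_error(build_incidence_surface(tab), "decreases with age.*60")
  tab2 <- toy_incidence_table()
  tab2$cum_inc[1] <- 1.3
  expect_error(build_incidence_surface(tab2), "proportions")
})

test_that("surface round-trips through its exported table", {
  surf <- build_incidence_surface(toy_incidence_table())
  surf2 <- build_incidence_surface(export_incidence(surf))
  grid <- expand.grid(sex = c("male", "female"), by = c(1950, 1980),
                      age = c(20, 35, 60, 80, 100), stringsAsFactors = FALSE)
  expect_equal(cum_inc_at(surf2, grid$sex, grid$by, grid$age),
               cum_inc_at(surf, grid$sex, grid$by, grid$age))
})

test_that("personalized constraints implement the case/control/unknown rules", {
  surf <- build_incidence_surface(tibble::tibble(
    sex = rep(c("male", "female"), each = 3),
    birth_year = NA_integer_,
    age = rep(c(20, 50, 80), 2),
    cum_inc = c(0.01, 0.08, 0.10, 0.005, 0.02, 0.04)
  ))
  person <- tibble::tibble(family_id = "f", person_id = "p", role = "index",
                           sex = "male", birth_year = NA_integer_,
                           status = 0L, age = 50, age_of_onset = NA_real_)
  # control at cumulative incidence 0.08: upper bound qnorm(0.92) = 1.405
  ctrl <- personalized_constraint(person, surf)
  expect_equal(ctrl$kind, "interval")
  expect_equal(ctrl$lower, -Inf)
  expect_equal(round(ctrl$upper, 3), 1.405)

  # case with onset where cumulative incidence = 0.02: fixed at 2.054
  case <- person
  case$status <- 1L; case$sex <- "female"; case$age_of_onset <- 50
  fx <- personalized_constraint(case, surf)
  expect_equal(fx$kind, "fixed")
  expect_equal(round(fx$fixed_value, 3), 2.054)

  # case without onset: one-sided interval above the age threshold
  case2 <- person; case2$status <- 1L
  iv <- personalized_constraint(case2, surf)
  expect_equal(iv$kind, "interval")
  expect_equal(iv$lower, threshold_from_cip(0.08))
  expect_equal(iv$upper, Inf)

  # unknown status: unconstrained
  unk <- person; unk$status <- NA_integer_
  u <- personalized_constraint(unk, surf)
  expect_equal(c(u$lower, u$upper), c(-Inf, Inf))

  # known status, missing age: lifetime (maximum-age) incidence threshold
  noage <- person; noage$age <- NA_real_
  na_ctrl <- personalized_constraint(noage, surf)
  expect_equal(na_ctrl$upper, threshold_from_cip(0.10))
})

test_that("personalized thresholds are non-increasing in age within strata", {
  surf <- build_incidence_surface(toy_incidence_table())
  for (s in c("male", "female")) {
    for (by in c(1950, 1980)) {
      ages <- seq(15, 90, by = 2.5)
      thr <- threshold_from_cip(pmax(cum_inc_at(surf, s, by, ages), 1e-6))
      expect_true(all(diff(thr) <= 0))
    }
  }
})
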