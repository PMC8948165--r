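test_that("Gaussian conditioning matches the bivariate regression identity", {
  h2 <- 0.35
  sg <- liability_covariance(h2)
  t_fix <- 1.7
  cond <- condition_on_fixed(c(gen = 0, full = 0), sg, c(full = t_fix))
  expect_equal(cond$free, "gen")
  expect_equal(unname(cond$mean), h2 * t_fix)
  expect_equal(unname(drop(cond$sigma)), h2 * (1 - h2))
})

test_that("conditioning with no fixed coordinates is the identity", {
  sg <- liability_covariance(0.5, c("father", "mother"))
  cond <- condition_on_fixed(rep(0, 4), sg)
  expect_equal(cond$sigma, sg)
  expect_equal(length(cond$free), 4)
})

test_that("conditioning on both parents at zero leaves the genetic mean at zero", {
  sg <- liability_covariance(0.5, c("father", "mother"))
  cond <- condition_on_fixed(rep(0, 4), sg,
                             c(father_1 = 0, mother_2 = 0))
  expect_equal(unname(cond$mean["gen"]), 0)
})

test_that("the latent genetic coordinate cannot be fixed", {
  sg <- liability_covariance(0.5)
  expect_error(condition_on_fixed(c(0, 0), sg, c(gen = 1)), "cannot be fixed")
})

test_that("truncated normal draws have the right moments and support", {
  set.seed(11)
  n <- 1e5
  x <- sample_truncated_normal(n, mean = 0.3, sd = 2)
  expect_lt(abs(mean(x) - 0.3), 3 * 2 / sqrt(n))

  # one-sided truncation: closed-form mean phi(T)/(1 - Phi(T))
  t0 <- 1.2
  y <- sample_truncated_normal(n, 0, 1, lower = t0)
  m_true <- dnorm(t0) / pnorm(t0, lower.tail = FALSE)
  sd_true <- sqrt(1 + t0 * m_true - m_true^2)
  expect_lt(abs(mean(y) - m_true), 3 * sd_true / sqrt(n))
  expect_true(all(y > t0))
})

test_that("truncated normal sampling stays exact in the far tail", {
  set.seed(12)
  z <- sample_truncated_normal(1e4, 0, 1, lower = 10)
  expect_true(all(is.finite(z)))
  expect_true(all(z >= 10))
  # Mills-ratio mean for an extreme threshold
  expect_lt(abs(mean(z) - dnorm(10) / pnorm(10, lower.tail = FALSE)), 0.01)
  expect_error(sample_truncated_normal(10, 0, 1, 2, 2), "strictly below")
  expect_error(sample_truncated_normal(10, 0, -1), "sd")
})

test_that("truncated normal draws match the analytic distribution (KS)", {
  set.seed(13)
  for (b in list(c(1.5, Inf), c(-1, 0.5), c(-Inf, -2))) {
    x <- sample_truncated_normal(2e4, 0, 1, b[1], b[2])
    # inverse-CDF draws clamp to the bound at floating-point resolution,
    # so an occasional duplicated boundary value is expected
    ks <- suppressWarnings(
      stats::ks.test(x, function(q) truncnorm::ptruncnorm(q, a = b[1],
                                                          b = b[2]))
    )
    expect_gt(ks$p.value, 1e-3)
  }
})

test_that("unconstrained Gibbs sampling recovers the covariance", {
  set.seed(21)
  sg <- liability_covariance(0.5, c("father", "mother"))
  res <- gibbs_truncated_mvn(rep(0, 4), sg, rep(-Inf, 4), rep(Inf, 4),
                             sampler_config(max_samples = 1e5,
                                            sem_tol = 1e-6),
                             keep_samples = TRUE)
  emp <- stats::cov(res$samples)
  rel <- norm(emp - sg, "F") / norm(sg, "F")
  expect_lt(rel, 0.05)
  expect_lt(abs(res$mean), 0.02)
})

test_that("one-dimensional Gibbs reduces to direct truncated sampling", {
  set.seed(22)
  res <- gibbs_truncated_mvn(0, matrix(1), 1.2, Inf,
                             sampler_config(max_samples = 5e4,
                                            sem_tol = 1e-6))
  m_true <- dnorm(1.2) / pnorm(1.2, lower.tail = FALSE)
  expect_lt(abs(res$mean - m_true), 0.02)
  expect_error(gibbs_truncated_mvn(0, matrix(1), 2, 1, sampler_config()),
               "infeasible")
})

test_that("Gibbs posterior means agree with the rejection oracle", {
  for (seed in 1:6) {
    fam <- random_constraint_family(seed)
    set.seed(1000 + seed)
    orc <- rejection_oracle(rep(0, nrow(fam$sigma)), fam$sigma, fam$lower,
                            fam$upper, n_accept = 2e4)
    set.seed(2000 + seed)
    gbs <- gibbs_truncated_mvn(rep(0, nrow(fam$sigma)), fam$sigma,
                               fam$lower, fam$upper,
                               sampler_config(sem_tol = 0.005))
    tol <- 3 * sqrt(orc$se^2 + gbs$se^2)
    expect_lt(abs(gbs$mean - orc$mean), max(tol, 0.02))
  }
})

lone_index <- function(status, age = NA_real_, onset = NA_real_,
                       sex = "male") {
  tibble::tibble(family_id = "f1", person_id = "f1_i", role = "index",
                 sex = sex, birth_year = NA_integer_, status = status,
                 age = age, age_of_onset = onset)
}

test_that("lone case and control match the closed-form truncated-normal means", {
  K <- 0.05; h2 <- 0.5
  surf <- logistic_incidence_surface(K, K)
  t_k <- qnorm(1 - K)
  cfg <- sampler_config(sem_tol = 0.004, seed = 5)

  est_case <- estimate_liability(lone_index(1L), surf, h2, cfg)
  expect_lt(abs(est_case$post_mean - h2 * dnorm(t_k) / K), 3 * 0.004 + 0.003)

  est_ctrl <- estimate_liability(lone_index(0L), surf, h2, cfg)
  expect_lt(abs(est_ctrl$post_mean - (-h2 * dnorm(t_k) / (1 - K))),
            3 * 0.004 + 0.003)
})

test_that("a case with onset at threshold t gets exactly h2 * t without sampling", {
  K <- 0.05; h2 <- 0.5
  surf <- logistic_incidence_surface(K, K)
  est <- estimate_liability(lone_index(1L, age = 60, onset = 60), surf, h2)
  t60 <- threshold_from_cip(cum_inc_at(surf, "male", NA, 60))
  expect_equal(est$post_mean, h2 * t60)
  expect_equal(est$n_samples, 0)
  expect_true(est$converged)
})

test_that("earlier onset gives a strictly larger posterior mean", {
  surf <- logistic_incidence_surface(0.05, 0.05)
  means <- vapply(c(30, 45, 60, 75), function(a) {
    estimate_liability(lone_index(1L, age = a, onset = a), surf, 0.5)$post_mean
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("LT-FH mode reproduces sign and family-history monotonicity", {
  ped3 <- function(zi, zf, zm) {
    tibble::tibble(
      family_id = "f1",
      person_id = c("f1_i", "f1_f", "f1_m"),
      role = c("index", "father", "mother"),
      sex = c("male", "male", "female"), birth_year = NA_integer_,
      status = c(zi, zf, zm), age = NA_real_, age_of_onset = NA_real_
    )
  }
  cfg <- sampler_config(sem_tol = 0.005, seed = 9)
  all_ctrl <- ltfh_liability(ped3(0L, 0L, 0L), 0.05, h2 = 0.5, config = cfg)
  expect_lt(all_ctrl$post_mean, 0)

  case_case <- ltfh_liability(ped3(1L, 1L, 1L), 0.05, h2 = 0.5, config = cfg)
  case_ctrl <- ltfh_liability(ped3(1L, 0L, 0L), 0.05, h2 = 0.5, config = cfg)
  expect_gt(case_case$post_mean, case_ctrl$post_mean)
})

test_that("LT-FH mode matches the rejection oracle over the six configurations", {
  K <- 0.05; h2 <- 0.5
  thr <- qnorm(1 - K)
  sg <- liability_covariance(h2, c("father", "mother"))
  cfg <- sampler_config(sem_tol = 0.005, seed = 14)
  configs <- list(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 1, 1),
                  c(1, 1, 0), c(1, 1, 1))
  for (z in configs) {
    lower <- c(-Inf, ifelse(z == 1, thr, -Inf))
    upper <- c(Inf, ifelse(z == 1, Inf, thr))
    set.seed(300 + sum(z * c(1, 2, 4)))
    orc <- rejection_oracle(rep(0, 4), sg, lower, upper, n_accept = 2e4)

    ped <- tibble::tibble(
      family_id = "f1", person_id = c("f1_i", "f1_f", "f1_m"),
      role = c("index", "father", "mother"),
      sex = c("male", "male", "female"), birth_year = NA_integer_,
      status = as.integer(z), age = NA_real_, age_of_onset = NA_real_
    )
    est <- ltfh_liability(ped, K, h2 = h2, config = cfg)
    tol <- 3 * sqrt(orc$se^2 + est$post_se^2)
    expect_lt(abs(est$post_mean - orc$mean), max(tol, 0.02))
  }
})

test_that("estimates are deterministic and independent of family order", {
  pop <- model_consistent_population(12, 0.5, 0.05, seed = 31)
  surf <- logistic_incidence_surface(0.05, 0.05)
  cfg <- sampler_config(sem_tol = 0.05, seed = 77)
  a <- estimate_liability(pop$pedigree, surf, 0.5, cfg)
  b <- estimate_liability(pop$pedigree, surf, 0.5, cfg)
  expect_identical(a$post_mean, b$post_mean)

  # reversed family blocks: same per-family results
  rev_ped <- pop$pedigree[order(pop$pedigree$family_id, decreasing = TRUE), ]
  c_rev <- estimate_liability(rev_ped, surf, 0.5, cfg)
  expect_equal(c_rev$post_mean[match(a$family_id, c_rev$family_id)],
               a$post_mean)
})

test_that("relatives with unknown status are excluded from the family model", {
  surf <- logistic_incidence_surface(0.05, 0.05)
  cfg <- sampler_config(sem_tol = 0.01, seed = 3)
  with_unk <- tibble::tibble(
    family_id = "f1", person_id = c("f1_i", "f1_f", "f1_m"),
    role = c("index", "father", "mother"),
    sex = c("male", "male", "female"), birth_year = NA_integer_,
    status = c(1L, 1L, NA), age = c(50, 70, NA),
    age_of_onset = c(50, 70, NA)
  )
  without <- with_unk[1:2, ]
  expect_equal(estimate_liability(with_unk, surf, 0.5, cfg)$post_mean,
               estimate_liability(without, surf, 0.5, cfg)$post_mean)
})

test_that("posterior means are population-consistent and more variable than LT-FH", {
  n <- 500; h2 <- 0.5; L <- 0.05
  pop <- model_consistent_population(n, h2, L, seed = 8)
  surf <- logistic_incidence_surface(L, L)
  cfg <- sampler_config(sem_tol = 0.03, seed = 19)
  pp <- estimate_liability(pop$pedigree, surf, h2, cfg)
  lt <- ltfh_liability(pop$pedigree, prev_child = L, h2 = h2, config = cfg)

  expect_lt(abs(mean(pp$post_mean)), 3 * sd(pp$post_mean) / sqrt(n) + 0.01)
  expect_lte(var(pp$post_mean), h2)
  expect_gt(var(pp$post_mean), var(lt$post_mean))
  # the posterior mean tracks the true genetic liability
  expect_gt(cor(pp$post_mean, pop$lg), cor(lt$post_mean, pop$lg) - 0.05)
})

test_that("rejection oracle aborts on vanishing acceptance", {
  sg <- liability_covariance(0.5)
  expect_error(
    rejection_oracle(c(0, 0), sg, c(-Inf, 6.5), c(Inf, Inf),
                     n_accept = 1e4),
    "acceptance"
  )
})

test_that("tidiers summarise liability estimates", {
  pop <- model_consistent_population(8, 0.5, 0.05, seed = 41)
  surf <- logistic_incidence_surface(0.05, 0.05)
  est <- estimate_liability(pop$pedigree, surf, 0.5,
                            sampler_config(sem_tol = 0.05, seed = 2))
  td <- tidy(est)
  expect_s3_class(td, "tbl_df")
  gl <- glance(est)
  expect_equal(gl$n_families, 8)
  expect_equal(gl$method, "ltfhpp")
  expect_true(gl$converged_frac >= 0 && gl$converged_frac <= 1)
})
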