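# Fixtures built in code: small pedigrees, surfaces and generated
# populations shared across test files.

toy_pedigree <- function() {
  tibble::tibble(
    family_id = c("f1", "f1", "f1", "f2", "f2"),
    person_id = c("f1_i", "f1_d", "f1_m", "f2_i", "f2_m"),
    role = c("index", "father", "mother", "index", "mother"),
    sex = c("male", "male", "female", "female", "female"),
    birth_year = c(1980L, 1955L, 1957L, 1990L, 1965L),
    status = c(1L, 0L, 1L, 0L, NA),
    age = c(35, 60, 50, 28, 55),
    age_of_onset = c(35, NA, 50, NA, NA)
  )
}

toy_incidence_table <- function() {
  dplyr::bind_rows(
    tibble::tibble(sex = "male", birth_year = 1950L,
                   age = c(20, 40, 60, 80), cum_inc = c(0.01, 0.03, 0.06, 0.08)),
    tibble::tibble(sex = "male", birth_year = 1980L,
                   age = c(20, 40, 60, 80), cum_inc = c(0.02, 0.05, 0.09, 0.12)),
    tibble::tibble(sex = "female", birth_year = 1950L,
                   age = c(20, 40, 60, 80), cum_inc = c(0.005, 0.01, 0.02, 0.03)),
    tibble::tibble(sex = "female", birth_year = 1980L,
                   age = c(20, 40, 60, 80), cum_inc = c(0.01, 0.02, 0.04, 0.05))
  )
}

# One family with random roles and random interval constraints on each
# person's full liability; returns the pieces needed for both the Gibbs
# path and the rejection oracle.
random_constraint_family <- function(seed, h2 = NULL) {
  set.seed(seed)
  if (is.null(h2)) h2 <- sample(c(0.25, 0.5, 0.75), 1)
  roles <- c(
    if (runif(1) < 0.8) "father",
    if (runif(1) < 0.8) "mother",
    rep("sibling", sample(0:2, 1))
  )
  d <- 2L + length(roles)
  sigma <- liability_covariance(h2, roles)
  lower <- rep(-Inf, d)
  upper <- rep(Inf, d)
  for (j in seq_len(d - 1) + 1L) {
    thr <- rnorm(1, 1, 0.7)
    if (runif(1) < 0.5) lower[j] <- thr else upper[j] <- thr
  }
  list(h2 = h2, roles = roles, sigma = sigma, lower = lower, upper = upper)
}

# Families generated exactly under the age-dependent liability threshold
# model: liability vectors from the family covariance, uniform ages, case
# status iff the onset implied by the liability is before the person's age.
# This is the population for which the personalized-threshold estimator is
# the correctly specified model.
model_consistent_population <- function(n, h2, L, seed, k = 1 / 8, x0 = 60) {
  set.seed(seed)
  sg <- liability_covariance(h2, c("father", "mother"))
  z <- matrix(rnorm(n * 4), n, 4) %*% chol(sg)
  full <- z[, 2:4]
  age <- matrix(runif(n * 3, 10, 80), n, 3)
  p <- 1 - pnorm(full)
  onset <- matrix(NA_real_, n, 3)
  can <- p < L
  onset[can] <- pmax(invert_logistic_cif(p[can], L, k, x0), 0)
  case <- !is.na(onset) & onset <= age
  age_rec <- ifelse(case, onset, age)
  fid <- sprintf("g%05d", seq_len(n))
  ped <- tibble::tibble(
    family_id = rep(fid, each = 3),
    person_id = paste0(rep(fid, each = 3), "_", rep(c("i", "f", "m"), n)),
    role = rep(c("index", "father", "mother"), n),
    sex = rep(c("male", "male", "female"), n),
    birth_year = NA_integer_,
    status = as.integer(t(case)),
    age = as.numeric(t(age_rec)),
    age_of_onset = ifelse(as.logical(t(case)), as.numeric(t(onset)), NA_real_)
  )
  list(pedigree = ped, lg = z[, 1])
}
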