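#' Logistic cumulative incidence function
#'
#' `L / (1 + exp(-k * (age - x0)))`: a logistic curve with maximal attainable
#' prevalence `L`, growth rate `k` per year, and midpoint `x0`, the age at
#' which the cumulative incidence reaches `L / 2` (the median age of onset).
#' Used as the generative incidence curve in the simulation study.
#'
#' @param age Age in years (vectorized).
#' @param L Maximal attainable prevalence, in `(0, 1)`.
#' @param k Growth rate per year, `> 0`.
#' @param x0 Midpoint / median onset age in years, `> 0`.
#' @return Cumulative incidence proportions, strictly increasing in `age`.
#' @export
#' @examples
#' logistic_cif(60, L = 0.08)  # 0.04: half the lifetime prevalence
logistic_cif <- function(age, L, k = 1 / 8, x0 = 60) {
  check_logistic_params(L, k, x0)
  if (any(!is.finite(age))) abort("age must be finite")
  L / (1 + exp(-k * (age - x0)))
}

#' Invert the logistic cumulative incidence function
#'
#' Age at which the logistic curve reaches cumulative incidence `p`:
#' `x0 - (1/k) * log(L/p - 1)`.  Used to assign ages of onset from liability
#' quantiles in the simulation study.
#'
#' @inheritParams logistic_cif
#' @param p Cumulative incidence proportions in `(0, L)`.
#' @return Ages in years; `logistic_cif(invert_logistic_cif(p, ...), ...)`
#'   recovers `p`.
#' @export
#' @examples
#' invert_logistic_cif(0.04, L = 0.08)          # 60, the median onset
#' invert_logistic_cif(0.05 * 0.08, L = 0.08)   # approx 36.4
invert_logistic_cif <- function(p, L, k = 1 / 8, x0 = 60) {
  check_logistic_params(L, k, x0)
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= L)) {
    abort("p must lie strictly between 0 and L (onset is never reached at L)")
  }
  x0 - log(L / p - 1) / k
}

check_logistic_params <- function(L, k, x0) {
  if (any(L <= 0) || any(L >= 1)) abort("L must lie in (0, 1)")
  if (any(k <= 0)) abort("k must be positive")
  if (any(x0 <= 0)) abort("x0 must be positive")
  invisible(NULL)
}

#' Aalen-Johansen cumulative incidence under competing risks
#'
#' Estimates the cumulative incidence function (CIF) of an event of interest
#' when competing events (e.g. death, emigration) can preclude it, using the
#' Aalen-Johansen multi-state estimator via [survival::survfit()].  With no
#' competing events and no censoring the estimate reduces to the empirical
#' CDF of the event times, and at every time point
#' `CIF(interest) + CIF(competing) + S(t) = 1`.
#'
#' Tied times follow the standard convention: all events at a tied time use
#' the risk set just before it, and censorings at the same time are removed
#' afterwards.
#'
#' @param times Non-negative event/censoring times (years of age).
#' @param kinds Character vector aligned with `times`: `"event"` (of
#'   interest), `"competing"`, or `"censored"`.
#' @return An object of class `aj_cif`: a tibble with columns `time`,
#'   `n_risk`, `cif` (event of interest), `cif_competing`, and `surv`, one
#'   row per distinct event time.  Query it with [cif_at()].
#' @export
#' @examples
#' aj <- aalen_johansen_cif(c(1, 2, 3, 4), rep("event", 4))
#' cif_at(aj, 2.5)  # 0.5: empirical CDF when nothing competes
aalen_johansen_cif <- function(times, kinds) {
  if (length(times) == 0) abort("no observations supplied")
  if (length(kinds) != length(times)) {
    abort("times and kinds must have the same length")
  }
  if (any(!is.finite(times)) || any(times < 0)) {
    abort("times must be finite and non-negative")
  }
  if (!all(kinds %in% c("event", "competing", "censored"))) {
    abort("kinds must be 'event', 'competing' or 'censored'")
  }
  state <- factor(kinds, levels = c("censored", "event", "competing"))
  fit <- survival::survfit(survival::Surv(times, state) ~ 1)
  states <- fit$states
  i_event <- which(states == "event")
  i_comp <- which(states == "competing")
  pstate <- fit$pstate
  out <- tibble::tibble(
    time = fit$time,
    n_risk = fit$n.risk[, 1],
    cif = if (length(i_event)) pstate[, i_event] else rep(0, length(fit$time)),
    cif_competing = if (length(i_comp)) pstate[, i_comp]
                    else rep(0, length(fit$time)),
  )
  out$surv <- 1 - out$cif - out$cif_competing
  class(out) <- c("aj_cif", class(out))
  attr(out, "n") <- length(times)
  attr(out, "n_event") <- sum(kinds == "event")
  attr(out, "n_competing") <- sum(kinds == "competing")
  out
}

#' Evaluate an Aalen-Johansen CIF at given ages
#'
#' Step-function (last observation carried forward) evaluation; ages before
#' the first event time return 0.
#'
#' @param aj An `aj_cif` object from [aalen_johansen_cif()].
#' @param age Ages at which to evaluate (vectorized).
#' @param which Which component: `"event"` (default) or `"competing"`.
#' @return Cumulative incidence proportions.
#' @export
cif_at <- function(aj, age, which = c("event", "competing")) {
  which <- match.arg(which)
  col <- if (which == "event") aj$cif else aj$cif_competing
  idx <- findInterval(age, aj$time)
  ifelse(idx == 0, 0, col[pmax(idx, 1)])
}

#' @export
tidy.aj_cif <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
glance.aj_cif <- function(x, ...) {
  tibble::tibble(
    n = attr(x, "n"),
    n_event = attr(x, "n_event"),
    n_competing = attr(x, "n_competing"),
    cif_final = x$cif[nrow(x)]
  )
}

#' Build a queryable cumulative incidence surface
#'
#' Turns a long-format table of cumulative incidence by sex, birth year and
#' age into a surface that can be queried for any person.  Within each
#' (sex, birth year) stratum the curve must be non-decreasing in age.
#'
#' Interpolation between tabulated ages is a step function (last observation
#' carried forward), matching yearly register counts; set
#' `interpolation = "linear"` for piecewise-linear curves (useful when the
#' table tabulates a smooth generative curve).  Queries for a birth year
#' outside the tabulated range are clamped to the nearest available year
#' with a warning.  Queries with unknown sex average the male and female
#' values.
#'
#' @param table Data frame with columns `sex`, `birth_year`, `age`,
#'   `cum_inc` (proportions in `[0, 1]`).  `birth_year` may be `NA`
#'   throughout for tables without birth-year structure.
#' @param interpolation `"step"` (default) or `"linear"`.
#' @return An `incidence_surface` object.
#' @seealso [cum_inc_at()], [read_incidence()], [logistic_incidence_surface()]
#' @export
build_incidence_surface <- function(table, interpolation = c("step",
                                                             "linear")) {
  interpolation <- match.arg(interpolation)
  required <- c("sex", "birth_year", "age", "cum_inc")
  missing_cols <- setdiff(required, names(table))
  if (length(missing_cols) > 0) {
    abort(paste0("incidence table is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  tab <- tibble::as_tibble(table)
  if (any(!is.finite(tab$cum_inc)) || any(tab$cum_inc < 0) ||
      any(tab$cum_inc > 1)) {
    abort("cum_inc must be proportions in [0, 1]")
  }
  if (!all(tab$sex %in% c("male", "female"))) {
    abort("sex must be 'male' or 'female' in the incidence table")
  }
  tab$birth_year <- ifelse(is.na(tab$birth_year), -1L,
                           as.integer(tab$birth_year))
  tab <- dplyr::arrange(tab, .data$sex, .data$birth_year, .data$age)

  key <- paste(tab$sex, tab$birth_year, sep = "\r")
  strata <- split(tab, key)
  for (s in strata) {
    if (anyDuplicated(s$age)) {
      abort(paste0("duplicate ages in stratum sex=", s$sex[1],
                   " birth_year=", s$birth_year[1]))
    }
    drops <- diff(s$cum_inc) < 0
    if (any(drops)) {
      bad <- which(drops) + 1L
      abort(paste0(
        "cumulative incidence decreases with age in stratum sex=", s$sex[1],
        " birth_year=", s$birth_year[1], " at age(s) ",
        paste(head(s$age[bad], 5), collapse = ", ")
      ))
    }
  }
  structure(
    list(table = tab, strata = strata, interpolation = interpolation),
    class = "incidence_surface"
  )
}

#' @export
print.incidence_surface <- function(x, ...) {
  cat("<incidence_surface>", length(x$strata), "strata,",
      x$interpolation, "interpolation\n")
  invisible(x)
}

#' Export the table underlying an incidence surface
#'
#' Returns the tidy `sex, birth_year, age, cum_inc` table; rebuilding a
#' surface from it reproduces all stored values exactly.
#'
#' @param surface An `incidence_surface`.
#' @return A tibble.
#' @export
export_incidence <- function(surface) {
  tab <- surface$table
  tab$birth_year <- ifelse(tab$birth_year < 0, NA_integer_, tab$birth_year)
  tab
}

# single-stratum lookup, vectorized over age
stratum_cif <- function(stratum, age, interpolation) {
  if (interpolation == "linear") {
    stats::approx(stratum$age, stratum$cum_inc, xout = age, rule = 2,
                  ties = "ordered")$y
  } else {
    idx <- findInterval(age, stratum$age)
    ifelse(idx == 0, 0, stratum$cum_inc[pmax(idx, 1)])
  }
}

#' Query a cumulative incidence surface
#'
#' Vectorized lookup of cumulative incidence for people described by sex,
#' birth year and age.  Unknown (`NA`) sex averages the two sexes; birth
#' years outside the tabulated range (including `NA` against a table with
#' birth-year structure) are clamped to the nearest tabulated year, with a
#' warning.  `age = NA` returns the stratum's lifetime (maximum tabulated
#' age) cumulative incidence.
#'
#' @param surface An `incidence_surface`.
#' @param sex,birth_year,age Vectors (recycled to a common length).
#' @return Numeric vector of proportions.
#' @export
cum_inc_at <- function(surface, sex, birth_year, age) {
  n <- max(length(sex), length(birth_year), length(age))
  sex <- rep_len(as.character(sex), n)
  birth_year <- rep_len(as.integer(ifelse(is.na(birth_year), -1L,
                                          birth_year)), n)
  age <- rep_len(as.numeric(age), n)

  out <- numeric(n)
  una <- is.na(sex)
  if (any(una)) {
    # unknown sex: unweighted average of the two sex-specific values
    m <- cum_inc_at(surface, rep("male", sum(una)), birth_year[una],
                    age[una])
    f <- cum_inc_at(surface, rep("female", sum(una)), birth_year[una],
                    age[una])
    out[una] <- (m + f) / 2
  }
  idx <- which(!una)
  if (length(idx) == 0) return(out)

  years_by_sex <- lapply(split(surface$table$birth_year, surface$table$sex),
                         unique)
  clamped_any <- FALSE
  for (s in unique(sex[idx])) {
    rows <- idx[sex[idx] == s]
    avail <- years_by_sex[[s]]
    if (is.null(avail)) abort(paste0("no incidence strata for sex ", s))
    by <- birth_year[rows]
    nearest <- vapply(by, function(y) avail[which.min(abs(avail - y))],
                      numeric(1))
    if (any(nearest != by)) clamped_any <- TRUE
    for (y in unique(nearest)) {
      sub <- rows[nearest == y]
      stratum <- surface$strata[[paste(s, y, sep = "\r")]]
      a <- age[sub]
      a[is.na(a)] <- max(stratum$age)  # lifetime incidence
      out[sub] <- stratum_cif(stratum, a, surface$interpolation)
    }
  }
  if (clamped_any) {
    warn("some birth years fell outside the incidence table; clamped to the nearest tabulated birth year")
  }
  out
}

#' Tabulate a logistic incidence curve as an incidence surface
#'
#' Convenience constructor matching the simulation study's generative model:
#' one logistic cumulative incidence curve per sex, no birth-year structure.
#' Tabulated on a fine age grid with linear interpolation so queried values
#' track the analytic curve closely.
#'
#' @param L_male,L_female Sex-specific maximal attainable prevalences.
#' @param k,x0 Logistic growth rate and midpoint (see [logistic_cif()]).
#' @param ages Age grid to tabulate on.
#' @return An `incidence_surface`.
#' @export
logistic_incidence_surface <- function(L_male, L_female, k = 1 / 8, x0 = 60,
                                       ages = seq(0, 200, by = 0.5)) {
  tab <- dplyr::bind_rows(
    tibble::tibble(sex = "male", birth_year = NA_integer_, age = ages,
                   cum_inc = logistic_cif(ages, L_male, k, x0)),
    tibble::tibble(sex = "female", birth_year = NA_integer_, age = ages,
                   cum_inc = logistic_cif(ages, L_female, k, x0))
  )
  build_incidence_surface(tab, interpolation = "linear")
}

#' Personalized liability constraints for a pedigree
#'
#' Converts each person's record into a constraint on their full liability
#' under the age-dependent liability threshold model:
#'
#' * case with known age of onset: liability **fixed** at the threshold
#'   implied by the stratum's cumulative incidence at the onset age;
#' * case without onset: interval `[T(age), +Inf)` using the cumulative
#'   incidence at the censoring age (or lifetime incidence if age missing);
#' * control: interval `(-Inf, T(age))`;
#' * unknown status: unconstrained `(-Inf, +Inf)`.
#'
#' Each person's own sex, birth year and age determine their stratum; the
#' index's stratum is never reused for relatives.
#'
#' @param pedigree A validated pedigree table (see [validate_pedigree()]).
#' @param surface An `incidence_surface`.
#' @return The pedigree tibble with added columns `kind` (`"fixed"`,
#'   `"interval"`), `fixed_value`, `lower`, `upper`.
#' @export
liability_constraints <- function(pedigree, surface) {
  ped <- validate_pedigree(pedigree)
  n <- nrow(ped)
  is_case <- !is.na(ped$status) & ped$status == 1
  is_control <- !is.na(ped$status) & ped$status == 0
  has_onset <- is_case & !is.na(ped$age_of_onset)

  # age used for the threshold: onset for cases with onset, censoring age
  # otherwise; NA falls back to lifetime incidence inside cum_inc_at()
  th_age <- ifelse(has_onset, ped$age_of_onset, ped$age)
  ci <- cum_inc_at(surface, ped$sex, ped$birth_year, th_age)
  thr <- threshold_from_cip(ci)

  kind <- ifelse(has_onset, "fixed", "interval")
  fixed_value <- ifelse(has_onset, thr, NA_real_)
  lower <- rep(-Inf, n)
  upper <- rep(Inf, n)
  lower[is_case & !has_onset] <- thr[is_case & !has_onset]
  upper[is_control] <- thr[is_control]

  ped$kind <- kind
  ped$fixed_value <- fixed_value
  ped$lower <- lower
  ped$upper <- upper
  ped
}

#' @rdname liability_constraints
#' @param person A single-row pedigree table.
#' @return `personalized_constraint()`: a one-row tibble with the constraint
#'   columns only.
#' @export
personalized_constraint <- function(person, surface) {
  stopifnot(nrow(person) == 1)
  # a lone relative row is still a valid query; satisfy the validator by
  # treating the person as their own index
  p <- person
  p$role <- "index"
  res <- liability_constraints(p, surface)
  res[, c("person_id", "kind", "fixed_value", "lower", "upper")]
}
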