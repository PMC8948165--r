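#' Validate a long-format family phenotype table
#'
#' A pedigree table has one row per person: the genotyped index individual
#' plus any relatives, linked by `family_id`.  Columns:
#'
#' * `family_id`, `person_id`: opaque identifiers (character or coercible).
#' * `role`: one of `"index"`, `"father"`, `"mother"`, `"sibling"`.
#' * `sex`: `"male"`, `"female"`, or `NA` (unknown).
#' * `birth_year`: integer year, or `NA`.
#' * `status`: `1` (case), `0` (control), or `NA` (unknown).
#' * `age`: age in years at censoring for controls (current age, or age at
#'   death/emigration); for cases this is the age at onset when known.
#' * `age_of_onset`: age at onset in years for cases, `NA` otherwise.
#'
#' Checks enforced: exactly one index row per family; at most one father and
#' one mother; controls must not carry an `age_of_onset`; ages and birth
#' years, when present, are finite and non-negative.
#'
#' @param pedigree A data frame in the format above.
#' @return The validated table as a tibble (invisibly usable in pipes).
#' @export
#' @examples
#' ped <- tibble::tibble(
#'   family_id = "f1", person_id = c("i1", "d1", "m1"),
#'   role = c("index", "father", "mother"), sex = c("male", "male", "female"),
#'   birth_year = NA_integer_, status = c(1, 0, 0),
#'   age = c(40, 70, 68), age_of_onset = c(40, NA, NA)
#' )
#' validate_pedigree(ped)
validate_pedigree <- function(pedigree) {
  required <- c("family_id", "person_id", "role", "sex", "birth_year",
                "status", "age", "age_of_onset")
  missing_cols <- setdiff(required, names(pedigree))
  if (length(missing_cols) > 0) {
    abort(paste0("pedigree is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  ped <- tibble::as_tibble(pedigree)
  ped$family_id <- as.character(ped$family_id)
  ped$person_id <- as.character(ped$person_id)

  bad_role <- !ped$role %in% c("index", "father", "mother", "sibling")
  if (any(bad_role)) {
    abort(paste0("invalid role(s): ",
                 paste(unique(ped$role[bad_role]), collapse = ", ")))
  }
  bad_sex <- !is.na(ped$sex) & !ped$sex %in% c("male", "female")
  if (any(bad_sex)) abort("sex must be 'male', 'female' or NA")
  bad_status <- !is.na(ped$status) & !ped$status %in% c(0, 1)
  if (any(bad_status)) abort("status must be 1 (case), 0 (control) or NA")

  for (col in c("age", "age_of_onset", "birth_year")) {
    v <- ped[[col]]
    if (any(!is.na(v) & (!is.finite(v) | v < 0))) {
      abort(paste0(col, " must be finite and non-negative when present"))
    }
  }
  ctrl_onset <- !is.na(ped$status) & ped$status == 0 & !is.na(ped$age_of_onset)
  if (any(ctrl_onset)) {
    abort(paste0("controls must not have an age_of_onset (person_id: ",
                 paste(head(ped$person_id[ctrl_onset], 5), collapse = ", "),
                 ")"))
  }

  counts <- dplyr::summarise(
    dplyr::group_by(ped, .data$family_id),
    n_index = sum(.data$role == "index"),
    n_father = sum(.data$role == "father"),
    n_mother = sum(.data$role == "mother"),
    .groups = "drop"
  )
  bad <- counts$n_index != 1 | counts$n_father > 1 | counts$n_mother > 1
  if (any(bad)) {
    abort(paste0(
      "each family needs exactly one index and at most one father/mother; ",
      "offending families: ",
      paste(head(counts$family_id[bad], 5), collapse = ", ")
    ))
  }
  ped
}

#' Liability covariance matrix for a family
#'
#' Builds the covariance matrix of the multivariate normal liability vector
#' `(l_g, l_o, l_rel1, l_rel2, ...)`, where `l_g` is the genetic component of
#' the index individual's liability, `l_o` the index's full liability, and
#' the remaining coordinates are the relatives' full liabilities.  Under the
#' liability threshold model with heritability `h2`:
#'
#' * `Var(l_g) = h2`, all full liabilities have variance 1;
#' * `Cov(l_g, l_o) = h2`, `Cov(l_g, l_rel) = Cov(l_o, l_rel) = r * h2` with
#'   `r` the coefficient of relationship (0.5 for parents and full siblings);
#' * father and mother are unrelated (covariance 0); sibling pairs and
#'   parent-sibling pairs have covariance `0.5 * h2`;
#' * environmental components are independent between family members.
#'
#' @param h2 Heritability on the liability scale, in `[0, 1]`.
#' @param roles Character vector of relative roles, each `"father"`,
#'   `"mother"` or `"sibling"` (any number of siblings; at most one father
#'   and one mother).  `character(0)` gives the 2x2 single-person model.
#' @param r Optional numeric vector of coefficients of relationship to the
#'   index, same length as `roles`; defaults to 0.5 for all supported roles.
#'   Values must lie in `(0, 1]`.  Intended for internal experimentation;
#'   cross-relative covariances are only defined for the standard roles.
#' @return A symmetric positive semi-definite matrix with dimnames
#'   `c("gen", "full", <roles>)` and attributes `h2` and `r`.
#' @export
#' @examples
#' liability_covariance(0.5, c("father", "mother", "sibling"))
liability_covariance <- function(h2, roles = character(), r = NULL) {
  if (!is.numeric(h2) || length(h2) != 1 || !is.finite(h2) ||
      h2 < 0 || h2 > 1) {
    abort("h2 must be a single value in [0, 1]")
  }
  if (sum(roles == "father") > 1 || sum(roles == "mother") > 1) {
    abort("at most one father and one mother are allowed")
  }
  known <- roles %in% c("father", "mother", "sibling")
  if (is.null(r)) {
    if (!all(known)) abort("roles must be father, mother or sibling")
    r <- rep(0.5, length(roles))
  }
  if (length(r) != length(roles) || any(r <= 0 | r > 1)) {
    abort("r must match roles and lie in (0, 1]")
  }

  d <- 2L + length(roles)
  labs <- c("gen", "full",
            if (length(roles)) paste0(roles, "_", seq_along(roles)))
  sigma <- matrix(0, d, d, dimnames = list(labs, labs))
  sigma[1, 1] <- h2
  sigma[2, 2] <- 1
  sigma[1, 2] <- sigma[2, 1] <- h2
  for (i in seq_along(roles)) {
    k <- i + 2L
    sigma[k, k] <- 1
    sigma[1, k] <- sigma[k, 1] <- r[i] * h2
    sigma[2, k] <- sigma[k, 2] <- r[i] * h2
    if (i > 1) {
      for (j in seq_len(i - 1)) {
        m <- j + 2L
        pair <- sort(c(roles[i], roles[j]))
        cov_ij <- if (identical(pair, c("father", "mother"))) {
          0
        } else if (all(known[c(i, j)])) {
          0.5 * h2  # sibling-sibling and parent-sibling
        } else {
          0  # non-standard roles: assumed unrelated to each other
        }
        sigma[k, m] <- sigma[m, k] <- cov_ij
      }
    }
  }
  attr(sigma, "h2") <- h2
  attr(sigma, "r") <- r
  sigma
}

#' Liability threshold from a cumulative incidence proportion
#'
#' The threshold `T` such that `P(l >= T) = p` for a standard normal
#' liability `l`, i.e. the upper-tail normal quantile of the cumulative
#' incidence (or prevalence) `p`.  Values are clamped to
#' `[1e-12, 1 - 1e-12]` first so that near-certain outcomes (e.g. mortality
#' at high ages) keep finite thresholds.
#'
#' @param p Numeric vector of proportions in `[0, 1]`.
#' @return Numeric vector of thresholds, strictly decreasing in `p`.
#' @export
#' @examples
#' threshold_from_cip(c(0.08, 0.02))  # approx 1.41 and 2.05
threshold_from_cip <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("p must be finite proportions in [0, 1]")
  }
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  qnorm(p, lower.tail = FALSE)
}

#' Diagnosis probability over an age interval under the age-dependent
#' liability threshold model
#'
#' Probability that an individual with genetic liability `g` is diagnosed
#' while the threshold falls from `T_t` (at age t) to `T_tdt` (at age t+dt),
#' conditional on not being diagnosed before age t:
#' `1 - Phi((T_tdt - g)/s) / Phi((T_t - g)/s)` with `s = sqrt(1 - h2)`.
#' Divided by `dt` this approximates the model's hazard rate.
#'
#' @param t_now Threshold at the start of the interval.
#' @param t_next Threshold at the end of the interval; must satisfy
#'   `t_next <= t_now` (thresholds are non-increasing in age).
#' @param g Genetic liability.
#' @param h2 Heritability on the liability scale, in `[0, 1)`.
#' @return Probability in `[0, 1]`.  Vectorized over all arguments.
#' @seealso [cox_hazard_probability()] for the proportional-hazards analogue.
#' @export
hazard_probability <- function(t_now, t_next, g, h2) {
  if (any(!is.finite(h2)) || any(h2 < 0) || any(h2 >= 1)) {
    abort("h2 must lie in [0, 1); h2 = 1 makes the full liability degenerate")
  }
  if (any(t_next > t_now)) {
    abort("t_next must not exceed t_now: thresholds are non-increasing in age")
  }
  s <- sqrt(1 - h2)
  # ratio on log scale: Phi((t_next-g)/s) <= Phi((t_now-g)/s), so the log
  # ratio is <= 0 and the result stays in [0, 1] even deep in the tails
  log_ratio <- pnorm((t_next - g) / s, log.p = TRUE) -
    pnorm((t_now - g) / s, log.p = TRUE)
  1 - exp(log_ratio)
}

#' Diagnosis probability over an age interval under a constant-baseline Cox
#' model
#'
#' Companion to [hazard_probability()]: for a Cox model with hazard
#' `lambda(t | g) = alpha * exp(g)`, the probability of an event in a short
#' interval of length `dt` is `dt * alpha * exp(g)`.  Used to plot the two
#' hazard parameterizations side by side.
#'
#' @param dt Interval length in years, `> 0`.
#' @param alpha Baseline incidence rate, `> 0`.
#' @param g Genetic liability (log hazard ratio scale).
#' @return `dt * alpha * exp(g)`.  Vectorized.
#' @export
cox_hazard_probability <- function(dt, alpha, g) {
  if (any(!is.finite(dt)) || any(dt <= 0)) abort("dt must be positive")
  if (any(!is.finite(alpha)) || any(alpha <= 0)) {
    abort("alpha must be positive")
  }
  dt * alpha * exp(g)
}

# roles of the relatives of one family, in input order, for the covariance
# coordinate layout (gen, full, relatives...)
family_roles <- function(ped_family) {
  ped_family$role[ped_family$role != "index"]
}
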