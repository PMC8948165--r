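#' Gibbs sampler configuration
#'
#' Stopping rule: after `burn_in` sweeps, samples are retained in batches of
#' `batch_size`; sampling stops when the batch-means Monte Carlo standard
#' error of the tracked posterior mean falls to `sem_tol`, or when
#' `max_samples` retained samples have been drawn.  Because the batch-means
#' SE estimate has few degrees of freedom early on, convergence is only
#' declared after at least five batches and two consecutive checks at or
#' below `sem_tol`.  The defaults make the Monte Carlo noise (0.01
#' liability units) negligible against the between-person spread of
#' posterior means.
#'
#' @param burn_in Discarded initial sweeps.
#' @param batch_size Retained samples per convergence check.
#' @param max_samples Cap on retained samples.
#' @param sem_tol Target Monte Carlo standard error of the posterior mean.
#' @param seed Master seed; per-family seeds are derived from it and the
#'   family id, so results do not depend on processing order.
#' @return A list of class `sampler_config`.
#' @export
sampler_config <- function(burn_in = 200L, batch_size = 1000L,
                           max_samples = 1e5, sem_tol = 0.01, seed = 1L) {
  vals <- list(burn_in = as.integer(burn_in),
               batch_size = as.integer(batch_size),
               max_samples = as.numeric(max_samples),
               sem_tol = as.numeric(sem_tol),
               seed = as.integer(seed))
  if (any(vapply(vals, function(v) !is.finite(v) || v <= 0, logical(1)))) {
    abort("all sampler_config values must be positive")
  }
  structure(vals, class = "sampler_config")
}

# deterministic 31-bit hash of (seed, id) for per-family RNG streams
derive_seed <- function(seed, id) {
  h <- as.numeric(seed) %% 2147483647
  for (b in utf8ToInt(as.character(id))) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h)
}

#' Condition a liability covariance model on fixed full liabilities
#'
#' Exact Gaussian conditioning (Schur complement): given a mean vector and
#' covariance over liability coordinates, and known values for a subset of
#' *full-liability* coordinates (cases with known age of onset), returns the
#' conditional mean and covariance over the remaining coordinates.  The
#' genetic coordinate `"gen"` is latent and can never be fixed.
#'
#' @param mean Mean vector (named as the covariance's dimnames).
#' @param sigma Covariance matrix with dimnames from
#'   [liability_covariance()].
#' @param fixed Named numeric vector: coordinate name -> fixed value.  An
#'   empty vector returns the inputs unchanged.
#' @return List with `mean`, `sigma` (over free coordinates, in their
#'   original order) and `free` (names of the free coordinates).
#' @export
condition_on_fixed <- function(mean, sigma, fixed = numeric()) {
  labs <- colnames(sigma)
  if (is.null(names(mean))) names(mean) <- labs
  if (length(fixed) == 0) {
    return(list(mean = mean, sigma = sigma, free = labs))
  }
  if (is.null(names(fixed)) || !all(names(fixed) %in% labs)) {
    abort("fixed must be named by coordinates of sigma")
  }
  if ("gen" %in% names(fixed)) {
    abort("the genetic liability coordinate 'gen' cannot be fixed")
  }
  k <- match(names(fixed), labs)
  f <- setdiff(seq_along(labs), k)
  s_kk <- sigma[k, k, drop = FALSE]
  s_fk <- sigma[f, k, drop = FALSE]
  sol <- tryCatch(solve(s_kk, t(s_fk)),
                  error = function(e) {
                    solve(s_kk + diag(1e-10, nrow(s_kk)), t(s_fk))
                  })
  cmean <- mean[f] + drop(s_fk %*% solve_vec(s_kk, fixed - mean[k]))
  csig <- sigma[f, f, drop = FALSE] - s_fk %*% sol
  csig <- (csig + t(csig)) / 2
  list(mean = cmean, sigma = csig, free = labs[f])
}

solve_vec <- function(a, b) {
  tryCatch(solve(a, b), error = function(e) {
    solve(a + diag(1e-10, nrow(a)), b)
  })
}

#' Draw from a truncated univariate normal distribution
#'
#' Inverse-CDF sampling on the central range with a dedicated
#' shifted-exponential rejection algorithm beyond 4 standard deviations, so
#' draws stay exact for truncation points far in the tails (e.g. thresholds
#' from near-one cumulative mortality).
#'
#' @param n Number of draws.
#' @param mean,sd Location and scale (`sd > 0`).
#' @param lower,upper Truncation bounds, `lower < upper`; infinite bounds
#'   allowed.  All arguments are recycled.
#' @return Numeric vector of `n` draws in `(lower, upper)`.
#' @export
sample_truncated_normal <- function(n, mean = 0, sd = 1, lower = -Inf,
                                    upper = Inf) {
  if (any(sd <= 0)) abort("sd must be positive")
  if (any(lower >= upper)) abort("lower must be strictly below upper")
  .rtnorm_cpp(as.integer(n), as.numeric(mean), as.numeric(sd),
              as.numeric(lower), as.numeric(upper))
}

#' Gibbs sampling from a truncated multivariate normal
#'
#' Coordinates are cycled in fixed order; each is drawn from its univariate
#' full conditional truncated to the coordinate's interval.  Fixed-value
#' constraints must be removed beforehand with [condition_on_fixed()].
#' The first coordinate (the genetic liability in this package's layout) is
#' tracked for the stopping rule unless `track` says otherwise.
#'
#' @param mean Mean vector.
#' @param sigma Covariance matrix (positive definite; a tiny ridge is added
#'   if numerically singular).
#' @param lower,upper Truncation bounds per coordinate.
#' @param config A [sampler_config()].  The caller controls the RNG state
#'   (use `set.seed()`); this function does not reseed.
#' @param track Index of the monitored coordinate (default 1).
#' @param keep_samples Return the retained samples of all coordinates.
#' @return List with `mean`, `se`, `n_samples`, `converged`, `batch_means`
#'   and (optionally) `samples` (matrix, one column per coordinate).
#' @export
gibbs_truncated_mvn <- function(mean, sigma, lower, upper,
                                config = sampler_config(), track = 1L,
                                keep_samples = FALSE) {
  d <- length(mean)
  stopifnot(nrow(sigma) == d, length(lower) == d, length(upper) == d)
  if (any(lower >= upper)) abort("infeasible constraints: lower >= upper")

  q <- tryCatch(solve(sigma), error = function(e) {
    solve(sigma + diag(1e-8, d))
  })
  cvar <- 1 / diag(q)
  if (any(!is.finite(cvar)) || any(cvar < 0)) {
    abort("covariance matrix is not positive definite")
  }
  w <- -q / diag(q)
  diag(w) <- 0
  max_batches <- max(1L, ceiling(config$max_samples / config$batch_size))
  res <- .gibbs_tmvn_cpp(as.numeric(mean), w, sqrt(pmax(cvar, 0)),
                         as.numeric(lower), as.numeric(upper),
                         config$burn_in, config$batch_size,
                         as.integer(max_batches), config$sem_tol,
                         as.integer(track) - 1L, keep_samples)
  if (!keep_samples) res$samples <- NULL
  res
}

# Estimate E[gen | constraints] for one family.
# constraints: data frame with columns kind, fixed_value, lower, upper, in
# coordinate order (index first, then relatives); roles: relative roles.
estimate_family <- function(roles, constraints, h2, config, fam_seed) {
  sigma <- liability_covariance(h2, roles)
  labs <- colnames(sigma)
  mean0 <- stats::setNames(rep(0, length(labs)), labs)

  person_labs <- labs[-1]  # full-liability coordinates
  fixed_idx <- which(constraints$kind == "fixed")
  fixed <- stats::setNames(constraints$fixed_value[fixed_idx],
                           person_labs[fixed_idx])
  cond <- condition_on_fixed(mean0, sigma, fixed)

  free_people <- setdiff(cond$free, "gen")
  if (length(free_people) == 0) {
    # everyone fixed: posterior of gen is Gaussian, mean known analytically
    return(list(mean = unname(cond$mean["gen"]), se = 0, n_samples = 0,
                converged = TRUE))
  }
  rows <- match(free_people, person_labs)
  lower <- c(-Inf, constraints$lower[rows])
  upper <- c(Inf, constraints$upper[rows])
  # unconstrained non-gen coordinates carry no information; drop them
  keep <- c(TRUE, is.finite(constraints$lower[rows]) |
                  is.finite(constraints$upper[rows]))
  sel <- match(c("gen", free_people[keep[-1]]), cond$free)
  if (length(sel) == 1) {
    return(list(mean = unname(cond$mean["gen"]), se = 0, n_samples = 0,
                converged = TRUE))
  }
  set.seed(fam_seed)
  res <- gibbs_truncated_mvn(cond$mean[sel], cond$sigma[sel, sel],
                             lower[keep], upper[keep], config)
  list(mean = res$mean, se = res$se, n_samples = res$n_samples,
       converged = res$converged)
}

# shared driver: per-family estimation from a constraints table
estimate_from_constraints <- function(constraints, h2, config, method) {
  # relatives with unknown status carry no constraint and are excluded
  drop <- constraints$role != "index" & is.na(constraints$status)
  constraints <- constraints[!drop, , drop = FALSE]

  fams <- split(constraints, constraints$family_id)
  rows <- purrr::map(fams, function(fam) {
    ord <- order(fam$role != "index")  # index first, relatives in input order
    fam <- fam[ord, , drop = FALSE]
    roles <- fam$role[-1]
    est <- estimate_family(roles, fam, h2, config,
                           derive_seed(config$seed, fam$family_id[1]))
    tibble::tibble(
      family_id = fam$family_id[1],
      person_id = fam$person_id[fam$role == "index"][1],
      post_mean = est$mean, post_se = est$se,
      n_samples = est$n_samples, converged = est$converged
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- out[order(match(out$family_id, unique(constraints$family_id))), ]
  structure(out, class = c("liability_estimates", class(out)),
            h2 = h2, method = method, config = config)
}

#' Posterior mean genetic liabilities from family history and age of onset
#'
#' The package's main estimator.  For each family, builds the multivariate
#' liability model over the index individual and relatives with known
#' status, converts every person's record into a personalized liability
#' constraint via the cumulative incidence surface (see
#' [liability_constraints()]), conditions exactly on cases with known onset,
#' and Gibbs-samples the remaining truncated coordinates to obtain the
#' posterior mean genetic liability of the index individual.  This posterior
#' mean is the continuous GWAS outcome.
#'
#' Relatives with unknown status are excluded from their family's model.
#' Families are processed independently with seeds derived from
#' `config$seed` and the family id, so results do not depend on processing
#' order and are reproducible bit-for-bit.
#'
#' @param pedigree Long-format pedigree table (see [validate_pedigree()]).
#' @param surface An `incidence_surface` providing sex/birth-year/age
#'   specific cumulative incidence.
#' @param h2 Liability-scale heritability in `(0, 1)`.
#' @param config A [sampler_config()].
#' @return A `liability_estimates` tibble: `family_id`, `person_id` (the
#'   index), `post_mean`, `post_se`, `n_samples`, `converged`.
#' @seealso [ltfh_liability()] for the group-threshold (no age) variant,
#'   [gwax_phenotype()] for the proxy-case phenotype,
#'   [write_plink_phenotype()] to export for association tools.
#' @export
estimate_liability <- function(pedigree, surface, h2,
                               config = sampler_config()) {
  if (h2 < 0 || h2 > 1) abort("h2 must lie in [0, 1]")
  constraints <- liability_constraints(pedigree, surface)
  estimate_from_constraints(constraints, h2, config, method = "ltfhpp")
}

#' Posterior mean genetic liabilities from case-control family history only
#'
#' The group-threshold variant: a single threshold (from `prev_child`) for
#' the index and all siblings and another (from `prev_parent`) for parents,
#' ignoring age, sex and birth year.  All constraints are intervals —
#' cases above and controls below their group threshold.  Each sibling's
#' own status is used (per-sibling records are required; no "at least one
#' affected sibling" aggregation).
#'
#' @param pedigree Long-format pedigree table.
#' @param prev_child Prevalence for the index and siblings, in `(0, 1)`.
#' @param prev_parent Prevalence for parents; defaults to `prev_child`.
#' @inheritParams estimate_liability
#' @return A `liability_estimates` tibble.
#' @export
ltfh_liability <- function(pedigree, prev_child, prev_parent = prev_child,
                           h2, config = sampler_config()) {
  ped <- validate_pedigree(pedigree)
  thr <- ifelse(ped$role %in% c("father", "mother"),
                threshold_from_cip(prev_parent),
                threshold_from_cip(prev_child))
  is_case <- !is.na(ped$status) & ped$status == 1
  is_control <- !is.na(ped$status) & ped$status == 0
  ped$kind <- "interval"
  ped$fixed_value <- NA_real_
  ped$lower <- ifelse(is_case, thr, -Inf)
  ped$upper <- ifelse(is_control, thr, Inf)
  estimate_from_constraints(ped, h2, config, method = "ltfh")
}

#' @export
tidy.liability_estimates <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.liability_estimates <- function(x, ...) {
  tibble::tibble(
    n_families = nrow(x),
    converged_frac = mean(x$converged),
    mean_post = mean(x$post_mean),
    var_post = stats::var(x$post_mean),
    h2 = attr(x, "h2"),
    method = attr(x, "method")
  )
}

#' Rejection-sampling oracle for the posterior mean genetic liability
#'
#' Test oracle: draws from the unconstrained multivariate normal and keeps
#' draws satisfying all interval constraints, giving an unbiased (if
#' inefficient) estimate of the constrained posterior mean of the tracked
#' coordinate.  Fixed-value constraints must be removed beforehand with
#' [condition_on_fixed()].  Aborts if the acceptance probability appears to
#' be below `1e-6`.
#'
#' @inheritParams gibbs_truncated_mvn
#' @param n_accept Target number of accepted draws.
#' @param max_draws Cap on proposals.
#' @param track Tracked coordinate (default 1, the genetic liability).
#' @return List with `mean`, `se` (Monte Carlo), `n_accepted`,
#'   `acceptance`.
#' @export
rejection_oracle <- function(mean, sigma, lower, upper, n_accept = 5e4,
                             max_draws = 2e7, track = 1L) {
  d <- length(mean)
  if (any(lower >= upper)) abort("infeasible constraints: lower >= upper")
  ch <- chol(sigma + diag(1e-12, d))
  kept <- numeric(0)
  drawn <- 0
  block <- 2e5
  while (length(kept) < n_accept && drawn < max_draws) {
    z <- matrix(rnorm(block * d), block, d) %*% ch
    z <- sweep(z, 2, mean, "+")
    ok <- rep(TRUE, block)
    for (j in seq_len(d)) {
      ok <- ok & z[, j] > lower[j] & z[, j] < upper[j]
    }
    kept <- c(kept, z[ok, track])
    drawn <- drawn + block
    if (drawn >= 2e6 && length(kept) / drawn < 1e-6) {
      abort("rejection oracle: acceptance probability below 1e-6")
    }
  }
  if (length(kept) < 2) {
    abort("rejection oracle: too few accepted draws")
  }
  list(mean = mean(kept), se = sd(kept) / sqrt(length(kept)),
       n_accepted = length(kept), acceptance = length(kept) / drawn)
}
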