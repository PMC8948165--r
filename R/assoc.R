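#' GWAX proxy-case phenotype
#'
#' The proxy-case design: an index individual is scored 1 if they or any
#' family member is a case, 0 if at least one status is known and no one is
#' a case, and `NA` when every status in the family is unknown.
#'
#' @param pedigree Long-format pedigree table (see [validate_pedigree()]).
#' @return Tibble with `family_id`, `person_id` (the index) and `gwax`.
#' @export
#' @examples
#' # a control with a case mother becomes a proxy case
gwax_phenotype <- function(pedigree) {
  ped <- validate_pedigree(pedigree)
  dplyr::summarise(
    dplyr::group_by(ped, .data$family_id),
    person_id = .data$person_id[.data$role == "index"][1],
    gwax = if (all(is.na(.data$status))) NA_real_
           else as.numeric(any(.data$status == 1, na.rm = TRUE)),
    .groups = "drop"
  )
}

new_gwas_result <- function(snp_id, beta, se, chisq, phenotype) {
  out <- tibble::tibble(
    snp_id = snp_id, beta = beta, se = se, chisq = chisq,
    p = pchisq(chisq, df = 1, lower.tail = FALSE),
    phenotype = phenotype
  )
  class(out) <- c("gwas_result", class(out))
  out
}

# residualize y (vector or matrix columns) on covariates with intercept
project_out <- function(x, covariates) {
  if (is.null(covariates)) {
    if (is.matrix(x)) sweep(x, 2, colMeans(x)) else x - mean(x)
  } else {
    cv <- as.matrix(covariates)
    qr.resid(qr(cbind(1, cv)), x)
  }
}

#' Per-SNP linear-regression GWAS on a continuous phenotype
#'
#' Ordinary least squares of the phenotype on each SNP's additive genotype
#' coding, with optional covariates projected out of both sides.  The
#' association statistic is `chisq = (beta / se)^2`, referred to a 1-df
#' chi-squared distribution.  SNPs with zero genotype variance (after
#' projection) get `NA` statistics.
#'
#' @param genotypes Numeric matrix, individuals x SNPs (0/1/2 coding);
#'   column names become `snp_id`.
#' @param y Continuous phenotype, no missing values.
#' @param covariates Optional numeric matrix/data frame of covariates.
#' @param phenotype Label recorded in the result.
#' @return A `gwas_result` tibble: `snp_id`, `beta`, `se`, `chisq`, `p`,
#'   `phenotype`.
#' @export
linear_gwas <- function(genotypes, y, covariates = NULL, phenotype = "y") {
  g <- as.matrix(genotypes)
  if (anyNA(y)) abort("y must not contain missing values")
  stopifnot(length(y) == nrow(g))
  n <- nrow(g)
  q <- if (is.null(covariates)) 1L else 1L + ncol(as.matrix(covariates))

  yr <- project_out(y, covariates)
  gr <- project_out(g, covariates)
  sxx <- colSums(gr^2)
  syy <- sum(yr^2)
  sxy <- drop(crossprod(gr, yr))

  ok <- sxx > 1e-12
  beta <- se <- rep(NA_real_, ncol(g))
  beta[ok] <- sxy[ok] / sxx[ok]
  df <- n - q - 1L
  rss <- syy - beta[ok]^2 * sxx[ok]
  se[ok] <- sqrt(pmax(rss, 0) / df / sxx[ok])
  chisq <- (beta / se)^2
  if (any(!ok)) {
    warn(paste(sum(!ok), "SNP(s) with zero genotype variance; statistics set to NA"))
  }
  ids <- colnames(g)
  if (is.null(ids)) ids <- paste0("snp", seq_len(ncol(g)))
  new_gwas_result(ids, beta, se, chisq, phenotype)
}

#' Per-SNP 1-df trend test on a binary phenotype
#'
#' Without covariates this is the Cochran-Armitage trend test on additive
#' genotype coding (the score test of logistic regression), a 1-df
#' chi-squared statistic that is invariant to swapping case/control labels.
#' With covariates it falls back to the linear-regression test of
#' [linear_gwas()] on the 0/1 outcome, which is asymptotically equivalent.
#'
#' @param genotypes Numeric matrix, individuals x SNPs.
#' @param z Binary 0/1 phenotype with both classes present.
#' @inheritParams linear_gwas
#' @return A `gwas_result` tibble; `beta`/`se` are `NA` for the trend test
#'   (it is a score test without an effect estimate).
#' @export
case_control_test <- function(genotypes, z, covariates = NULL,
                              phenotype = "casecontrol") {
  if (anyNA(z)) abort("z must not contain missing values")
  if (length(unique(z)) < 2) abort("both classes must be present")
  if (!all(z %in% c(0, 1))) abort("z must be coded 0/1")
  if (!is.null(covariates)) {
    res <- linear_gwas(genotypes, z, covariates, phenotype)
    return(res)
  }
  g <- as.matrix(genotypes)
  stopifnot(length(z) == nrow(g))
  n <- nrow(g)
  sx <- colSums(g)
  sxx <- colSums(g^2)
  sz <- sum(z)
  sxz <- drop(crossprod(g, z))
  denom <- sz * (n - sz) * (n * sxx - sx^2)
  ok <- denom > 1e-12
  chisq <- rep(NA_real_, ncol(g))
  chisq[ok] <- n * (n * sxz[ok] - sx[ok] * sz)^2 / denom[ok]
  if (any(!ok)) {
    warn(paste(sum(!ok), "SNP(s) with zero genotype variance; statistics set to NA"))
  }
  ids <- colnames(g)
  if (is.null(ids)) ids <- paste0("snp", seq_len(ncol(g)))
  new_gwas_result(ids, rep(NA_real_, ncol(g)), rep(NA_real_, ncol(g)),
                  chisq, phenotype)
}

#' @export
glance.gwas_result <- function(x, ...) {
  tibble::tibble(
    n_snps = nrow(x),
    mean_chisq = mean(x$chisq, na.rm = TRUE),
    lambda_gc = stats::median(x$chisq, na.rm = TRUE) /
      stats::qchisq(0.5, df = 1),
    n_genomewide = sum(x$p < 5e-8, na.rm = TRUE),
    phenotype = x$phenotype[1]
  )
}

#' Power: fraction of causal SNPs reaching significance
#'
#' `(# causal SNPs with p strictly below alpha) / (# causal SNPs)`.
#'
#' @param results A `gwas_result` (or any tibble with `snp_id` and `p`).
#' @param causal Character vector of causal SNP ids; must all be present in
#'   `results` and non-empty.
#' @param alpha Significance threshold (default genome-wide, `5e-8`).
#' @return A proportion.
#' @export
gwas_power <- function(results, causal, alpha = 5e-8) {
  if (length(causal) == 0) abort("causal set must be non-empty")
  miss <- setdiff(causal, results$snp_id)
  if (length(miss) > 0) {
    abort(paste0("causal SNPs not present in results: ",
                 paste(head(miss, 5), collapse = ", ")))
  }
  p <- results$p[match(causal, results$snp_id)]
  mean(!is.na(p) & p < alpha)
}

#' Compare chi-squared statistics between two phenotype constructions
#'
#' Estimates the relative power / effective-sample-size gain of phenotype
#' `a` over phenotype `b` as the through-origin regression slope of the
#' chi-squared statistics of `a` on those of `b`, over a common variant
#' selection, minus one.  By default the selection is all variants with a
#' p value strictly below `p_threshold` for at least one of the two
#' results (the selection rule is applied identically to both).
#'
#' @param results_a,results_b `gwas_result` tibbles over common variants.
#' @param p_threshold Selection threshold (default `5e-6`).
#' @param variants Optional explicit character vector of variant ids
#'   (e.g. an LD-pruned external list), overriding the p-value selection.
#' @return An object of class `chisq_comparison` with the joined per-variant
#'   table, the slope, and `gain = slope - 1`; see [tidy()] / [glance()].
#' @export
compare_chisq <- function(results_a, results_b, p_threshold = 5e-6,
                          variants = NULL) {
  joined <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(results_a), "snp_id",
                  chisq_a = "chisq", p_a = "p"),
    dplyr::select(tibble::as_tibble(results_b), "snp_id",
                  chisq_b = "chisq", p_b = "p"),
    by = "snp_id"
  )
  sel <- if (is.null(variants)) {
    joined$p_a < p_threshold | joined$p_b < p_threshold
  } else {
    joined$snp_id %in% variants
  }
  sel[is.na(sel)] <- FALSE
  data <- joined[sel, , drop = FALSE]
  if (nrow(data) == 0) abort("empty variant selection")
  slope <- sum(data$chisq_a * data$chisq_b) / sum(data$chisq_b^2)
  structure(
    list(data = data, slope = slope, gain = slope - 1,
         n_variants = nrow(data),
         labels = c(a = results_a$phenotype[1], b = results_b$phenotype[1])),
    class = "chisq_comparison"
  )
}

#' @export
print.chisq_comparison <- function(x, ...) {
  cat("<chisq_comparison>", x$labels["a"], "vs", x$labels["b"], "over",
      x$n_variants, "variants\n  slope:", signif(x$slope, 4),
      " relative gain:", sprintf("%+.1f%%", 100 * x$gain), "\n")
  invisible(x)
}

#' @export
tidy.chisq_comparison <- function(x, ...) {
  x$data
}

#' @export
glance.chisq_comparison <- function(x, ...) {
  tibble::tibble(slope = x$slope, gain = x$gain, n_variants = x$n_variants,
                 phenotype_a = unname(x$labels["a"]),
                 phenotype_b = unname(x$labels["b"]))
}

#' All four phenotype constructions for a simulated cohort
#'
#' Convenience pipeline used throughout the examples and benchmarks:
#' computes, for each index individual of a simulated cohort, the
#' case-control status, the GWAX proxy status, the LT-FH posterior mean
#' (group thresholds at the overall prevalence), and the LT-FH++ posterior
#' mean (personalized thresholds from the sex-specific logistic incidence
#' curves that generated the data).
#'
#' @param cohort A `sim_cohort` (possibly ascertained).
#' @param h2 Heritability used by the estimators; defaults to the
#'   generative value.
#' @param prevalence Prevalence used by the estimators; defaults to the
#'   generative value.
#' @param config A [sampler_config()].
#' @param methods Subset of `c("casecontrol", "gwax", "ltfh", "ltfhpp")`.
#' @return Tibble with `family_id`, `person_id` and one column per method.
#' @export
cohort_phenotypes <- function(cohort, h2 = cohort$config$h2,
                              prevalence = cohort$config$prevalence,
                              config = sampler_config(),
                              methods = c("casecontrol", "gwax", "ltfh",
                                          "ltfhpp")) {
  methods <- match.arg(methods, several.ok = TRUE)
  ped <- cohort$pedigree
  idx <- dplyr::filter(ped, .data$role == "index")
  out <- tibble::tibble(family_id = idx$family_id,
                        person_id = idx$person_id)
  if ("casecontrol" %in% methods) {
    out$casecontrol <- idx$status
  }
  if ("gwax" %in% methods) {
    out <- dplyr::left_join(out, gwax_phenotype(ped),
                            by = c("family_id", "person_id"))
  }
  if ("ltfh" %in% methods) {
    est <- ltfh_liability(ped, prev_child = prevalence, h2 = h2,
                          config = config)
    out$ltfh <- est$post_mean[match(out$family_id, est$family_id)]
  }
  if ("ltfhpp" %in% methods) {
    prev <- sex_prevalence(prevalence, cohort$config$male_multiplier)
    surface <- logistic_incidence_surface(prev[["male"]], prev[["female"]],
                                          cohort$config$k, cohort$config$x0)
    est <- estimate_liability(ped, surface, h2, config = config)
    out$ltfhpp <- est$post_mean[match(out$family_id, est$family_id)]
  }
  out
}
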