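#' Configuration for the liability-scale simulation study
#'
#' Defaults reproduce the study conditions of the package's benchmark
#' simulations: 100,000 families each with 100,000 independent SNPs of which
#' 1,000 are causal, liability heritability 0.5, lifetime prevalence 5% with
#' males four times as likely to be cases as females (8% male / 2% female),
#' a logistic cumulative incidence curve with growth rate 1/8 per year and
#' median onset age 60, two parents and 0-2 siblings per family.
#'
#' @param n_families Number of genotyped index individuals (families).
#' @param n_snps Total number of independent SNPs.
#' @param n_causal Number of causal SNPs.
#' @param h2 Liability-scale heritability.
#' @param maf_range Allele-frequency range (uniform draw).
#' @param prevalence Overall lifetime prevalence `K`.
#' @param male_multiplier Male:female prevalence ratio.
#' @param k,x0 Logistic incidence growth rate and midpoint (years).
#' @param n_siblings Siblings per family (0-2).
#' @param downsample Ascertain by downsampling controls to a 50/50
#'   case-control split (see [ascertain()]).
#' @param seed RNG seed for the whole generative process.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_families = 1e5, n_snps = 1e5, n_causal = 1000,
                       h2 = 0.5, maf_range = c(0.01, 0.49),
                       prevalence = 0.05, male_multiplier = 4,
                       k = 1 / 8, x0 = 60, n_siblings = 0,
                       downsample = FALSE, seed = 1L) {
  stopifnot(n_causal <= n_snps, n_siblings %in% 0:2,
            h2 >= 0, h2 <= 1, prevalence > 0, prevalence < 1,
            male_multiplier > 0)
  prev <- sex_prevalence(prevalence, male_multiplier)
  if (any(prev >= 1)) abort("sex-specific prevalence reaches 1; lower prevalence or male_multiplier")
  structure(
    list(n_families = as.integer(n_families), n_snps = as.integer(n_snps),
         n_causal = as.integer(n_causal), h2 = h2, maf_range = maf_range,
         prevalence = prevalence, male_multiplier = male_multiplier,
         k = k, x0 = x0, n_siblings = as.integer(n_siblings),
         downsample = isTRUE(downsample), seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Sex-specific lifetime prevalences
#'
#' Splits an overall prevalence `K` into male and female lifetime
#' prevalences with a given male:female ratio `m`, assuming equal numbers of
#' each sex: `K_female = 2K / (1 + m)`, `K_male = m * K_female`.
#'
#' @param prevalence Overall lifetime prevalence.
#' @param male_multiplier Male:female prevalence ratio.
#' @return Named vector `c(male = , female = )`.
#' @export
#' @examples
#' sex_prevalence(0.05, 4)  # 8% male, 2% female
sex_prevalence <- function(prevalence, male_multiplier) {
  f <- 2 * prevalence / (1 + male_multiplier)
  c(male = male_multiplier * f, female = f)
}

#' Simulate parental and offspring genotypes for independent SNPs
#'
#' Parents' genotypes are Binomial(2, AF) draws; each child's genotype is
#' the average of the parents' genotypes, with half-integer averages rounded
#' up or down with equal probability.  This inheritance scheme preserves the
#' allele frequency and gives parent-offspring genetic correlation 0.5.
#'
#' @param n Number of families.
#' @param af Allele frequencies, one per SNP.
#' @param n_children Number of child genotype vectors to draw (index
#'   individual plus siblings).
#' @return List with integer matrices `father`, `mother` (each `n` x
#'   `length(af)`) and a list `children` of such matrices.
#' @export
simulate_genotypes <- function(n, af, n_children = 1) {
  m <- length(af)
  draw_parent <- function() {
    matrix(rbinom(n * m, 2L, rep(af, each = n)), n, m)
  }
  father <- draw_parent()
  mother <- draw_parent()
  children <- lapply(seq_len(n_children), function(i) {
    avg <- (father + mother) / 2
    half <- avg %% 1 != 0
    child <- floor(avg)
    child[half] <- child[half] + rbinom(sum(half), 1L, 0.5)
    storage.mode(child) <- "integer"
    child
  })
  storage.mode(father) <- "integer"
  storage.mode(mother) <- "integer"
  list(father = father, mother = mother, children = children)
}

# standardized-genotype liability contribution
lg_contrib <- function(geno, af, beta) {
  centered <- sweep(geno, 2, 2 * af)
  scaled <- sweep(centered, 2, sqrt(2 * af * (1 - af)), "/")
  drop(scaled %*% beta)
}

#' Assign case-control status and ages of onset from liabilities
#'
#' Within each sex, the individuals with the top `K_sex * n_sex` (rounded)
#' full liabilities are cases, fixing case counts exactly to the sex-specific
#' prevalence.  A case's age of onset is found by inverting the logistic
#' cumulative incidence at their liability's upper-tail quantile
#' `1 - Phi(l)` (clamped just below the sex's lifetime prevalence `L`), so
#' higher liability means earlier onset; the case's age equals the onset
#' age.  Controls keep their censoring age (drawn uniformly on (10, 60) when
#' not supplied).
#'
#' @param liability Full liabilities.
#' @param sex `"male"` / `"female"`, same length.
#' @param config A [sim_config()].
#' @param censoring_age Optional control censoring ages; defaults to
#'   `runif(n, 10, 60)`.
#' @return Tibble with `status` (1/0), `age`, `age_of_onset`.
#' @export
assign_status_and_onset <- function(liability, sex, config,
                                    censoring_age = NULL) {
  n <- length(liability)
  stopifnot(length(sex) == n)
  if (is.null(censoring_age)) censoring_age <- runif(n, 10, 60)
  prev <- sex_prevalence(config$prevalence, config$male_multiplier)

  status <- integer(n)
  onset <- rep(NA_real_, n)
  for (s in c("male", "female")) {
    idx <- which(sex == s)
    if (length(idx) == 0) next
    L <- prev[[s]]
    n_cases <- round(L * length(idx))
    ranks <- rank(-liability[idx], ties.method = "first")
    case <- ranks <= n_cases
    status[idx[case]] <- 1L
    p <- 1 - pnorm(liability[idx[case]])
    p <- pmin(p, L * (1 - 1e-6))  # boundary cases: very late onset
    # extreme liabilities invert to negative ages; onset at birth instead
    onset[idx[case]] <- pmax(invert_logistic_cif(p, L, config$k, config$x0),
                             0)
  }
  tibble::tibble(
    status = status,
    age = ifelse(status == 1L, onset, censoring_age),
    age_of_onset = onset
  )
}

#' Simulate a family cohort under the liability threshold model
#'
#' Full generative pipeline: allele frequencies, parental and offspring
#' genotypes at the causal SNPs, standardized-genotype genetic liabilities
#' (`Var(l_g) = h2` by construction), independent environmental components,
#' exact-count case assignment per sex, logistic ages of onset, and
#' censoring ages (index/sibling controls uniform on (10, 60); parents their
#' child's age plus uniform (20, 35)).  Index individuals get an exactly
#' balanced sex split so that per-sex case counts — and the ascertained
#' sample size — are exact; relatives' sexes are independent 50/50 (parents
#' fixed).  Genotypes are generated in SNP blocks so only the index
#' individuals' causal genotypes are retained.
#'
#' @param config A [sim_config()].
#' @param block_size SNPs per generation block (memory knob; no effect on
#'   the distribution of any output for a fixed seed and block size).
#' @return A list of class `sim_cohort`: `pedigree` (long-format tibble),
#'   `genotypes` (index-by-causal-SNP integer matrix), `liabilities`
#'   (per-person genetic and full liabilities), `af` (all SNPs), `causal`
#'   (causal SNP indices), `beta` (standardized-scale effects), `config`.
#' @export
simulate_cohort <- function(config = sim_config(), block_size = 500L) {
  set.seed(config$seed)
  n <- config$n_families
  af_all <- runif(config$n_snps, config$maf_range[1], config$maf_range[2])
  causal <- sort(sample.int(config$n_snps, config$n_causal))
  beta <- rnorm(config$n_causal, 0, sqrt(config$h2 / config$n_causal))

  n_child <- 1L + config$n_siblings
  persons <- c("index", "father", "mother",
               if (config$n_siblings > 0) paste0("sibling", seq_len(config$n_siblings)))
  lg <- matrix(0, n, length(persons), dimnames = list(NULL, persons))
  geno_index <- matrix(0L, n, config$n_causal)

  af_c <- af_all[causal]
  blocks <- split(seq_len(config$n_causal),
                  ceiling(seq_len(config$n_causal) / block_size))
  for (b in blocks) {
    g <- simulate_genotypes(n, af_c[b], n_children = n_child)
    lg[, "father"] <- lg[, "father"] + lg_contrib(g$father, af_c[b], beta[b])
    lg[, "mother"] <- lg[, "mother"] + lg_contrib(g$mother, af_c[b], beta[b])
    lg[, "index"] <- lg[, "index"] + lg_contrib(g$children[[1]], af_c[b],
                                                beta[b])
    if (config$n_siblings > 0) {
      for (sib in seq_len(config$n_siblings)) {
        col <- paste0("sibling", sib)
        lg[, col] <- lg[, col] + lg_contrib(g$children[[sib + 1L]],
                                            af_c[b], beta[b])
      }
    }
    geno_index[, b] <- g$children[[1]]
  }

  family_id <- sprintf("F%06d", seq_len(n))
  # balanced sex split for the index so per-sex case counts are exact
  index_sex <- sample(rep_len(c("male", "female"), n))
  sib_sex <- if (config$n_siblings > 0) {
    matrix(sample(c("male", "female"), n * config$n_siblings, replace = TRUE),
           n, config$n_siblings)
  }

  l_full <- lg + matrix(rnorm(n * length(persons), 0, sqrt(1 - config$h2)),
                        n, length(persons))

  idx_out <- assign_status_and_onset(l_full[, "index"], index_sex, config)
  parent_age <- function() idx_out$age + runif(n, 20, 35)
  fa_out <- assign_status_and_onset(l_full[, "father"], rep("male", n),
                                    config, censoring_age = parent_age())
  mo_out <- assign_status_and_onset(l_full[, "mother"], rep("female", n),
                                    config, censoring_age = parent_age())

  make_rows <- function(role, suffix, sex, out) {
    tibble::tibble(
      family_id = family_id,
      person_id = paste0(family_id, "_", suffix),
      role = role, sex = sex, birth_year = NA_integer_,
      status = out$status, age = out$age,
      age_of_onset = ifelse(out$status == 1L, out$age_of_onset, NA_real_)
    )
  }
  rows <- list(make_rows("index", "i", index_sex, idx_out),
               make_rows("father", "f", rep("male", n), fa_out),
               make_rows("mother", "m", rep("female", n), mo_out))
  liab <- list(
    tibble::tibble(family_id = family_id,
                   person_id = paste0(family_id, "_i"), role = "index",
                   lg = lg[, "index"], l_full = l_full[, "index"]),
    tibble::tibble(family_id = family_id,
                   person_id = paste0(family_id, "_f"), role = "father",
                   lg = lg[, "father"], l_full = l_full[, "father"]),
    tibble::tibble(family_id = family_id,
                   person_id = paste0(family_id, "_m"), role = "mother",
                   lg = lg[, "mother"], l_full = l_full[, "mother"])
  )
  if (config$n_siblings > 0) {
    for (sib in seq_len(config$n_siblings)) {
      col <- paste0("sibling", sib)
      s_out <- assign_status_and_onset(l_full[, col], sib_sex[, sib], config)
      rows <- c(rows, list(make_rows("sibling", paste0("s", sib),
                                     sib_sex[, sib], s_out)))
      liab <- c(liab, list(
        tibble::tibble(family_id = family_id,
                       person_id = paste0(family_id, "_s", sib),
                       role = "sibling", lg = lg[, col],
                       l_full = l_full[, col])
      ))
    }
  }
  pedigree <- dplyr::arrange(dplyr::bind_rows(rows), .data$family_id)
  dimnames(geno_index) <- list(paste0(family_id, "_i"),
                               paste0("snp", causal))
  structure(
    list(pedigree = pedigree, genotypes = geno_index,
         liabilities = dplyr::arrange(dplyr::bind_rows(liab),
                                      .data$family_id),
         af = af_all, causal = causal, beta = beta, config = config),
    class = "sim_cohort"
  )
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("<sim_cohort>", x$config$n_families, "families,",
      length(x$causal), "causal SNPs, prevalence",
      x$config$prevalence, "\n")
  invisible(x)
}

#' Ascertain a simulated cohort by downsampling controls
#'
#' Keeps every index case and a uniform random sample of index controls of
#' the same size, emulating case enrichment in ascertained studies (50%
#' cases, 50% controls).
#'
#' @param cohort A `sim_cohort`.
#' @return The cohort restricted to the retained families.
#' @export
ascertain <- function(cohort) {
  idx <- dplyr::filter(cohort$pedigree, .data$role == "index")
  cases <- idx$family_id[idx$status == 1L]
  controls <- idx$family_id[idx$status == 0L]
  if (length(cases) > length(controls)) {
    abort("more cases than controls; cannot downsample to a 50/50 split")
  }
  keep <- c(cases, sample(controls, length(cases)))
  keep_rows <- cohort$pedigree$family_id %in% keep
  cohort$pedigree <- cohort$pedigree[keep_rows, , drop = FALSE]
  gkeep <- sub("_i$", "", rownames(cohort$genotypes)) %in% keep
  cohort$genotypes <- cohort$genotypes[gkeep, , drop = FALSE]
  cohort$liabilities <-
    cohort$liabilities[cohort$liabilities$family_id %in% keep, ,
                       drop = FALSE]
  attr(cohort, "ascertained") <- TRUE
  cohort
}

#' Simulate a block of null (non-causal) index genotypes
#'
#' Draws fresh allele frequencies and parent/child genotypes for SNPs with
#' no effect on the phenotype, for test-statistic calibration experiments.
#' Uses the current RNG state.
#'
#' @param n Number of index individuals.
#' @param n_snps Number of null SNPs.
#' @param maf_range Allele-frequency range.
#' @return Integer matrix `n` x `n_snps` of child genotypes.
#' @export
simulate_null_block <- function(n, n_snps, maf_range = c(0.01, 0.49)) {
  af <- runif(n_snps, maf_range[1], maf_range[2])
  g <- simulate_genotypes(n, af, n_children = 1)
  colnames(g$children[[1]]) <- paste0("null", seq_len(n_snps))
  g$children[[1]]
}
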