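#' Read and write long-format pedigree tables
#'
#' CSV dialect: columns `family_id,person_id,role,sex,birth_year,status,
#' age,age_of_onset`, header required, empty cells for missing values,
#' `status` coded 1 (case) / 0 (control) / empty (unknown).
#'
#' @param path File path.
#' @return `read_pedigree()`: a validated pedigree tibble.
#' @export
read_pedigree <- function(path) {
  ped <- readr::read_csv(
    path,
    col_types = readr::cols(
      family_id = readr::col_character(),
      person_id = readr::col_character(),
      role = readr::col_character(),
      sex = readr::col_character(),
      birth_year = readr::col_integer(),
      status = readr::col_integer(),
      age = readr::col_double(),
      age_of_onset = readr::col_double()
    )
  )
  if (nrow(ped) == 0) abort(paste0("no pedigree rows in ", path))
  validate_pedigree(ped)
}

#' @rdname read_pedigree
#' @param pedigree A pedigree table.
#' @export
write_pedigree <- function(pedigree, path) {
  readr::write_csv(validate_pedigree(pedigree), path, na = "")
  invisible(path)
}

#' Read and write cumulative-incidence tables
#'
#' CSV dialect: columns `sex,birth_year,age,cum_inc`, header required,
#' proportions in `[0, 1]`; `birth_year` may be empty for tables without
#' birth-year structure.
#'
#' @param path File path.
#' @param interpolation Passed to [build_incidence_surface()].
#' @return `read_incidence()`: an `incidence_surface`.
#' @export
read_incidence <- function(path, interpolation = "step") {
  tab <- readr::read_csv(
    path,
    col_types = readr::cols(
      sex = readr::col_character(),
      birth_year = readr::col_integer(),
      age = readr::col_double(),
      cum_inc = readr::col_double()
    )
  )
  if (nrow(tab) == 0) abort(paste0("no incidence rows in ", path))
  build_incidence_surface(tab, interpolation = interpolation)
}

#' @rdname read_incidence
#' @param surface An `incidence_surface`.
#' @export
write_incidence <- function(surface, path) {
  readr::write_csv(export_incidence(surface), path, na = "")
  invisible(path)
}

#' Write a PLINK-compatible continuous phenotype file
#'
#' Whitespace-delimited `FID IID <value>` with a header, the format external
#' association tools (PLINK, mixed-model GWAS software) read as a
#' quantitative phenotype.  Both FID and IID are set to the person id.
#'
#' @param estimates A `liability_estimates` tibble (or any tibble with
#'   `person_id` and the value column).
#' @param path Output path.
#' @param value_col Column to export (default `post_mean`).
#' @param name Phenotype column name in the file header.
#' @return The path, invisibly.
#' @export
write_plink_phenotype <- function(estimates, path, value_col = "post_mean",
                                  name = "ltfhpp") {
  out <- tibble::tibble(FID = estimates$person_id,
                        IID = estimates$person_id,
                        value = estimates[[value_col]])
  names(out)[3] <- name
  readr::write_delim(out, path, delim = " ")
  invisible(path)
}

#' Read and write per-variant summary statistics
#'
#' Tab-separated columns `snp_id, beta, se, chisq, p, phenotype`.
#'
#' @param path File path.
#' @return `read_summary_stats()`: a `gwas_result` tibble.
#' @export
read_summary_stats <- function(path) {
  tab <- readr::read_tsv(
    path,
    col_types = readr::cols(
      snp_id = readr::col_character(),
      beta = readr::col_double(),
      se = readr::col_double(),
      chisq = readr::col_double(),
      p = readr::col_double(),
      phenotype = readr::col_character()
    )
  )
  class(tab) <- c("gwas_result", class(tab))
  tab
}

#' @rdname read_summary_stats
#' @param results A `gwas_result` tibble.
#' @export
write_summary_stats <- function(results, path) {
  readr::write_tsv(tibble::as_tibble(results), path, na = "NA")
  invisible(path)
}

#' Write the full estimation report
#'
#' CSV with posterior mean, Monte Carlo standard error, sample count and
#' convergence flag per family, alongside the PLINK phenotype file.
#'
#' @param estimates A `liability_estimates` tibble.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_estimates <- function(estimates, path) {
  readr::write_csv(tibble::as_tibble(estimates), path, na = "")
  invisible(path)
}
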