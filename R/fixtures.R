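#' Published CCM cost calibration table
#'
#' The cost-per-child-treated calibration table for the five exemplar
#' countries (Nigeria, Egypt, Bangladesh, Cambodia, Peru): U5MR, the
#' constant antibiotic cost (US$ 0.27 everywhere), the non-antibiotic cost
#' and the total CCM cost per child treated, for the national "Overall"
#' stratum and each wealth quintile Q1 (wealthiest) to Q5 (poorest).
#' These 30 (U5MR, non-antibiotic cost) pairs are the calibration data for
#' [fit_cost_model()] / [default_cost_model()].
#'
#' @return data frame with columns `country`, `stratum` (`"Overall"`,
#'   `"Q1"` .. `"Q5"`), `u5mr`, `antibiotic_cost`, `nonantibiotic_cost`,
#'   `total_cost`.
#' @export
ccm_cost_table <- function() {
  utils::read.csv(system.file("extdata", "ccm_cost_table.csv",
                              package = "ccmequity"),
                  fileEncoding = "UTF-8")
}

#' Historical CCM effectiveness studies
#'
#' Nine historical community-case-management effectiveness studies
#' (1986-1998) plus the conventional anchor point of 100% effectiveness at
#' U5MR 0, each paired with the U5MR of the study country in the year of
#' publication.  This is the calibration set for [fit_effectiveness()].
#'
#' @return data frame with columns `study`, `location`, `year`, `u5mr`,
#'   `effectiveness` (percent, in \[0, 100\]).
#' @export
ccm_effectiveness_studies <- function() {
  utils::read.csv(system.file("extdata", "ccm_effectiveness_studies.csv",
                              package = "ccmequity"),
                  fileEncoding = "UTF-8")
}

#' Exemplar country datasets (U5MR only)
#'
#' The five exemplar countries as [country_dataset()] objects with the
#' published quintile U5MRs and overall U5MR filled in.  Coverage, births,
#' CFR and cause proportions are left `NA`: they are unpublished at
#' quintile level and must be supplied by configuration or by the
#' synthetic generator (see [demo_scenario()] for a fully populated,
#' clearly synthetic counterpart).
#'
#' @return named list of five `country_dataset` objects.
#' @examples
#' sapply(exemplar_datasets(), quintile_ratio)
#' @export
exemplar_datasets <- function() {
  tab <- ccm_cost_table()
  qt <- tab[tab$stratum != "Overall", ]
  ov <- tab[tab$stratum == "Overall", ]
  out <- lapply(unique(tab$country), function(cn) {
    d <- qt[qt$country == cn, ]
    country_dataset(cn, data.frame(
      quintile = as.integer(sub("Q", "", d$stratum)),
      u5mr = d$u5mr, coverage = NA_real_, births = NA_real_,
      cfr = NA_real_), overall_u5mr = ov$u5mr[ov$country == cn])
  })
  names(out) <- unique(tab$country)
  out
}

#' The 30 published (U5MR, non-antibiotic cost) calibration pairs
#'
#' Convenience accessor extracting the calibration pairs from
#' [ccm_cost_table()] in the layout [fit_cost_model()] expects.
#'
#' @return data frame with columns `u5mr` and `cost` (30 rows).
#' @export
ccm_cost_pairs <- function() {
  tab <- ccm_cost_table()
  data.frame(u5mr = tab$u5mr, cost = tab$nonantibiotic_cost)
}
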