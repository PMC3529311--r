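#' Fit the linear non-antibiotic cost law
#'
#' CCM cost per child treated is split into a constant antibiotic cost
#' (US$ 0.27 per child in every quintile of every country) and a
#' non-antibiotic cost that rises with the stratum's U5MR (poorer, higher
#' mortality strata are costlier to reach).  The non-antibiotic component
#' is modelled as a straight line in U5MR fitted by ordinary least squares.
#'
#' @param pairs data frame with columns `u5mr` and `cost` (US$ per child
#'   treated, non-antibiotic component); at least two distinct `u5mr`
#'   values are required.
#' @param antibiotic_cost constant antibiotic cost in US$ per child
#'   treated; default 0.27.
#' @return object of class `ccm_cost_model` with elements `intercept`,
#'   `slope` (US$ per U5MR unit), `antibiotic_cost`, `residuals` and
#'   `sigma` (residual standard error).  A non-positive fitted slope
#'   violates the cost-rises-with-U5MR assumption and triggers a warning.
#' @examples
#' m <- fit_cost_model(ccm_cost_pairs())
#' cost_per_child(m, 219)  # ~3.11 US$
#' @export
fit_cost_model <- function(pairs, antibiotic_cost = 0.27) {
  stopifnot(is.data.frame(pairs), all(c("u5mr", "cost") %in% names(pairs)))
  if (antibiotic_cost < 0) stop("antibiotic_cost must be >= 0", call. = FALSE)
  if (nrow(pairs) < 2 || length(unique(pairs$u5mr)) < 2)
    stop("singular fit: need >= 2 distinct u5mr values", call. = FALSE)
  fit <- stats::lm(cost ~ u5mr, data = pairs)
  co <- stats::coef(fit)
  if (co[["u5mr"]] <= 1e-12)  # tolerate exact-zero slopes computed in floats
    warning("fitted slope is not positive; cost does not rise with U5MR",
            call. = FALSE)
  structure(list(intercept = unname(co[["(Intercept)"]]),
                 slope = unname(co[["u5mr"]]),
                 antibiotic_cost = antibiotic_cost,
                 residuals = unname(stats::resid(fit)),
                 sigma = suppressWarnings(summary(fit)$sigma),
                 n = nrow(pairs)),
            class = "ccm_cost_model")
}

#' Default cost model calibrated to the published table
#'
#' The straight line fitted by OLS to the 30 published (U5MR,
#' non-antibiotic cost) cells of [ccm_cost_table()], with the constant
#' antibiotic cost of US$ 0.27.  The published cells are collinear to
#' within rounding, so this recovers the cost law to the printed precision.
#'
#' @return a `ccm_cost_model`.
#' @export
default_cost_model <- function() fit_cost_model(ccm_cost_pairs())

#' @export
print.ccm_cost_model <- function(x, ...) {
  cat(sprintf(paste0("<ccm_cost_model> non-antibiotic cost = %.4f + %.6f",
                     " x U5MR; antibiotic cost = %.2f US$ (n = %d)\n"),
              x$intercept, x$slope, x$antibiotic_cost, x$n))
  invisible(x)
}

#' Total CCM cost per child treated
#'
#' Evaluates `antibiotic_cost + intercept + slope * u5mr`.  Vectorised in
#' `u5mr`.
#'
#' @param model a `ccm_cost_model`.
#' @param u5mr U5MR (deaths per 1000 live births), non-negative.
#' @return cost in US$ per child treated; never negative.
#' @export
cost_per_child <- function(model, u5mr) {
  stopifnot(inherits(model, "ccm_cost_model"))
  if (any(u5mr < 0)) stop("u5mr must be non-negative", call. = FALSE)
  pmax(0, model$antibiotic_cost + model$intercept + model$slope * u5mr)
}

#' Cost of a coverage scale-up in one quintile
#'
#' Cost per child treated times the number of pneumonia episodes in the
#' quintile times the coverage increment: the cost of newly treating a
#' `delta_coverage` share of the quintile's episodes.
#'
#' @param cost_per_child US$ per child treated in the quintile.
#' @param episodes annual under-five pneumonia episodes in the quintile.
#' @param delta_coverage coverage increment, in \[0, 1\].
#' @return cost in US$.
#' @export
scaleup_cost <- function(cost_per_child, episodes, delta_coverage) {
  if (any(episodes < 0)) stop("episodes must be >= 0", call. = FALSE)
  if (any(delta_coverage < 0 | delta_coverage > 1))
    stop("delta_coverage must lie in [0,1]", call. = FALSE)
  cost_per_child * episodes * delta_coverage
}
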