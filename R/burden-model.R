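#' Case-fatality-rate model in U5MR
#'
#' Pneumonia case fatality (deaths per episode) rises with the mortality
#' environment of a stratum.  Two parametric forms are available, both
#' clamped to `[cfr_min, cfr_max]` and non-decreasing in U5MR:
#'
#' * `"linear"`: `cfr = intercept + slope * u5mr`, `slope >= 0`;
#' * `"logistic"`: `cfr = cfr_max / (1 + exp((midpoint - u5mr) / scale))`,
#'   a saturating curve that is near-exponential at low U5MR and
#'   plateaus at `cfr_max`.
#'
#' The published quintile CFR curves are figure-only, so concrete
#' parameter values here are always configuration (see [demo_scenario()]
#' for the shipped synthetic calibration).
#'
#' @param form `"linear"` or `"logistic"`.
#' @param intercept,slope linear-form parameters.
#' @param cfr_max upper clamp (and logistic asymptote), in (0, 1\].
#' @param midpoint,scale logistic-form parameters (U5MR units;
#'   `scale > 0`).
#' @param cfr_min strictly positive lower clamp, default `1e-6`.
#' @return object of class `ccm_cfr_model`.
#' @examples
#' m <- cfr_model("linear", intercept = 0.01, slope = 1e-4)
#' cfr(m, 100)  # 0.02
#' @export
cfr_model <- function(form = c("linear", "logistic"), intercept = 0.005,
                      slope = 1e-4, cfr_max = 0.1, midpoint = 150,
                      scale = 40, cfr_min = 1e-6) {
  form <- match.arg(form)
  if (cfr_min <= 0 || cfr_max > 1 || cfr_min >= cfr_max)
    stop("need 0 < cfr_min < cfr_max <= 1", call. = FALSE)
  if (form == "linear" && slope < 0)
    stop("linear CFR slope must be >= 0 (CFR non-decreasing in U5MR)",
         call. = FALSE)
  if (form == "logistic" && scale <= 0)
    stop("logistic scale must be > 0", call. = FALSE)
  structure(list(form = form, intercept = intercept, slope = slope,
                 cfr_max = cfr_max, midpoint = midpoint, scale = scale,
                 cfr_min = cfr_min),
            class = "ccm_cfr_model")
}

#' Evaluate a CFR model
#'
#' @param model a [cfr_model()].
#' @param u5mr U5MR, non-negative; vectorised.
#' @return case fatality rate (deaths per episode), clamped to
#'   `[cfr_min, cfr_max]`, non-decreasing in `u5mr`.
#' @export
cfr <- function(model, u5mr) {
  stopifnot(inherits(model, "ccm_cfr_model"))
  if (any(u5mr < 0)) stop("u5mr must be non-negative", call. = FALSE)
  v <- switch(model$form,
    linear = model$intercept + model$slope * u5mr,
    logistic = model$cfr_max /
      (1 + exp((model$midpoint - u5mr) / model$scale)))
  pmin(model$cfr_max, pmax(model$cfr_min, v))
}

#' @export
print.ccm_cfr_model <- function(x, ...) {
  cat(sprintf("<ccm_cfr_model> %s form, clamp [%g, %g]\n",
              x$form, x$cfr_min, x$cfr_max))
  invisible(x)
}

#' Cause-of-death proportion trends in U5MR
#'
#' Cause-of-death structure shifts with the mortality environment:
#' infectious causes (pneumonia, diarrhoea, malaria) take a growing share
#' of under-five deaths as U5MR rises, while congenital abnormalities,
#' preterm complications and injury shrink in relative terms.  Each cause
#' carries a linear trend on the log-odds scale,
#' `logit_c(u5mr) = alpha_c + beta_c * u5mr`, and proportions are obtained
#' by softmax renormalisation, which guarantees a simplex at every U5MR.
#'
#' @param alpha named numeric vector of per-cause baselines (log scale).
#' @param beta named numeric vector of per-cause slopes (per U5MR unit);
#'   same names as `alpha`.
#' @return object of class `ccm_cause_model`.
#' @seealso [default_cause_model()] for the shipped synthetic calibration.
#' @export
cause_trend_model <- function(alpha, beta) {
  stopifnot(is.numeric(alpha), is.numeric(beta),
            !is.null(names(alpha)), identical(names(alpha), names(beta)))
  structure(list(causes = names(alpha), alpha = alpha, beta = beta),
            class = "ccm_cause_model")
}

#' Default synthetic cause-trend calibration
#'
#' A logit-linear calibration over the eight-cause list (pneumonia,
#' diarrhoea, malaria, preterm, asphyxia, congenital, injury, other) with
#' positive slopes for the infectious causes and negative slopes for
#' congenital, preterm and injury, anchored to plausible shares
#' (pneumonia ~15%, preterm ~18%, ...) at U5MR 50.  The published
#' quintile-level cause fits are supplement-only; this stands in for them
#' and is documented as synthetic.
#'
#' @return a `ccm_cause_model`.
#' @export
default_cause_model <- function() {
  alpha <- c(pneumonia = -2.097, diarrhoea = -2.32, malaria = -2.959,
             preterm = -1.565, asphyxia = -2.07, congenital = -2.359,
             injury = -2.8, other = -1.427)
  beta <- c(pneumonia = 0.004, diarrhoea = 0.004, malaria = 0.006,
            preterm = -0.003, asphyxia = -0.001, congenital = -0.006,
            injury = -0.004, other = 0)
  cause_trend_model(alpha, beta)
}

#' Cause-of-death proportions at a given U5MR
#'
#' @param model a [cause_trend_model()].
#' @param u5mr U5MR, non-negative; vectorised.
#' @return matrix with one row per `u5mr` value and one column per cause;
#'   each row is a simplex (sums to 1 within 1e-9).
#' @export
cause_proportions <- function(model, u5mr) {
  stopifnot(inherits(model, "ccm_cause_model"))
  if (any(u5mr < 0)) stop("u5mr must be non-negative", call. = FALSE)
  lg <- outer(u5mr, model$beta, `*`) +
    matrix(model$alpha, length(u5mr), length(model$alpha), byrow = TRUE)
  z <- exp(lg - apply(lg, 1, max))  # stabilised softmax
  p <- z / rowSums(z)
  colnames(p) <- model$causes
  rownames(p) <- NULL
  p
}

#' Under-five deaths in a stratum
#'
#' U5MR is deaths per 1000 live births, so a stratum with `births` annual
#' live births sustains `u5mr / 1000 * births` under-five deaths.
#'
#' @param u5mr U5MR, non-negative.
#' @param births annual live births in the stratum, non-negative.
#' @return deaths (real-valued expectation, not rounded).
#' @export
quintile_deaths <- function(u5mr, births) {
  if (any(u5mr < 0) || any(births < 0))
    stop("u5mr and births must be non-negative", call. = FALSE)
  u5mr / 1000 * births
}

#' Pneumonia episodes implied by deaths and case fatality
#'
#' Inverts the case fatality rate: `episodes = pneumonia_deaths / cfr`.
#'
#' @param pneumonia_deaths under-five pneumonia deaths, non-negative.
#' @param cfr case fatality rate (deaths per episode), strictly positive.
#' @return episode count (real-valued).
#' @export
pneumonia_episodes <- function(pneumonia_deaths, cfr) {
  if (any(cfr <= 0)) stop("cfr must be > 0", call. = FALSE)
  if (any(pneumonia_deaths < 0))
    stop("pneumonia_deaths must be >= 0", call. = FALSE)
  pneumonia_deaths / cfr
}

#' Per-quintile burden table for a populated dataset
#'
#' Converts the quintile U5MRs of a fully populated [country_dataset()]
#' (births, CFR and a `cause:pneumonia` proportion present) into total
#' under-five deaths, pneumonia deaths and pneumonia episodes.
#'
#' @param dataset a populated `country_dataset`.
#' @return data frame with columns `country`, `quintile`, `deaths`,
#'   `pneumonia_deaths`, `episodes`.
#' @export
burden_table <- function(dataset) {
  stopifnot(inherits(dataset, "country_dataset"))
  q <- dataset$quintiles
  need <- c("births", "cfr", "cause:pneumonia")
  miss <- setdiff(need, names(q))
  pres <- intersect(need, names(q))
  if (length(miss) || anyNA(q[pres]))
    stop(sprintf("dataset '%s' is not fully populated (need %s)",
                 dataset$country, paste(need, collapse = ", ")),
         call. = FALSE)
  deaths <- quintile_deaths(q$u5mr, q$births)
  pneu <- deaths * q[["cause:pneumonia"]]
  data.frame(country = dataset$country, quintile = q$quintile,
             deaths = deaths, pneumonia_deaths = pneu,
             episodes = pneumonia_episodes(pneu, q$cfr))
}
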