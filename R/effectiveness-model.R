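#' Fit the CCM effectiveness-versus-U5MR trendline
#'
#' Intervention effectiveness observed in historical CCM studies declines
#' with the U5MR of the setting: the harder the context, the less effect a
#' community programme achieves.  Two functional forms are supported:
#'
#' * `"anchored"` (default): a straight line constrained through the
#'   conventional anchor (U5MR 0, effectiveness 100%), with slope
#'   `sum(x * (y - 100)) / sum(x^2)`;
#' * `"ols"`: an unconstrained ordinary-least-squares line over the same
#'   points (the anchor participates as an ordinary data point).
#'
#' A positive fitted slope (effectiveness rising with U5MR) is
#' epidemiologically implausible and triggers a warning.
#'
#' @param studies data frame with columns `u5mr` and `effectiveness`
#'   (percent in \[0, 100\]), e.g. [ccm_effectiveness_studies()].
#' @param form `"anchored"` or `"ols"`.
#' @param adjustment fraction of the remaining gap to 100% recovered by
#'   programme-quality assumptions (see [adjust_effectiveness()]); stored
#'   on the model, default 0.5.
#' @return object of class `ccm_effectiveness_model` with elements `form`,
#'   `intercept`, `slope` and `adjustment`.
#' @examples
#' m <- fit_effectiveness(ccm_effectiveness_studies())
#' adjusted_effectiveness(m, 219)  # ~50 percent
#' @export
fit_effectiveness <- function(studies, form = c("anchored", "ols"),
                              adjustment = 0.5) {
  form <- match.arg(form)
  stopifnot(is.data.frame(studies),
            all(c("u5mr", "effectiveness") %in% names(studies)))
  if (nrow(studies) == 0) stop("empty study list", call. = FALSE)
  if (any(studies$u5mr < 0)) stop("u5mr must be >= 0", call. = FALSE)
  if (any(studies$effectiveness < 0 | studies$effectiveness > 100))
    stop("effectiveness must lie in [0,100]", call. = FALSE)
  if (adjustment < 0 || adjustment > 1)
    stop("adjustment must lie in [0,1]", call. = FALSE)
  x <- studies$u5mr
  y <- studies$effectiveness
  if (form == "anchored") {
    if (all(x == 0)) stop("need at least one study with u5mr > 0",
                          call. = FALSE)
    slope <- sum(x * (y - 100)) / sum(x^2)
    intercept <- 100
  } else {
    if (length(unique(x)) < 2)
      stop("OLS form needs >= 2 distinct u5mr values", call. = FALSE)
    co <- stats::coef(stats::lm(y ~ x))
    intercept <- unname(co[1])
    slope <- unname(co[2])
  }
  if (slope > 0)
    warning("fitted slope is positive; effectiveness rising with U5MR is ",
            "implausible", call. = FALSE)
  structure(list(form = form, intercept = intercept, slope = slope,
                 adjustment = adjustment, n = nrow(studies)),
            class = "ccm_effectiveness_model")
}

#' Default effectiveness model calibrated to the historical studies
#'
#' Anchored-line fit to [ccm_effectiveness_studies()] with the standard
#' 50% remaining-gap adjustment.
#'
#' @param form passed to [fit_effectiveness()].
#' @return a `ccm_effectiveness_model`.
#' @export
default_effectiveness_model <- function(form = "anchored") {
  fit_effectiveness(ccm_effectiveness_studies(), form = form)
}

#' @export
print.ccm_effectiveness_model <- function(x, ...) {
  cat(sprintf(paste0("<ccm_effectiveness_model> %s: E(u5mr) = %.3f %+.5f",
                     " x u5mr (%%); gap adjustment %.2f\n"),
              x$form, x$intercept, x$slope, x$adjustment))
  invisible(x)
}

#' Raw (unadjusted) effectiveness at a given U5MR
#'
#' Evaluates the trendline and clamps to \[0, 100\] (the anchored line goes
#' slightly negative at very high U5MR).  Vectorised in `u5mr`.
#'
#' @param model a `ccm_effectiveness_model`.
#' @param u5mr U5MR, non-negative.
#' @return effectiveness in percent, in \[0, 100\].
#' @export
raw_effectiveness <- function(model, u5mr) {
  stopifnot(inherits(model, "ccm_effectiveness_model"))
  if (any(u5mr < 0)) stop("u5mr must be non-negative", call. = FALSE)
  pmin(100, pmax(0, model$intercept + model$slope * u5mr))
}

#' Remaining-gap adjustment of effectiveness
#'
#' Published effectiveness estimates from the historical trials are
#' conventionally adjusted upwards by a fraction of the remaining gap to
#' 100%, reflecting improvements in programme quality since the studies
#' were run: `adjusted = raw + adjustment * (100 - raw)`.
#'
#' @param raw raw effectiveness in percent, in \[0, 100\].
#' @param adjustment fraction of the remaining gap recovered, in \[0, 1\];
#'   default 0.5.
#' @return adjusted effectiveness in percent, always in \[`raw`, 100\].
#' @export
adjust_effectiveness <- function(raw, adjustment = 0.5) {
  if (any(raw < 0 | raw > 100))
    stop("raw effectiveness must lie in [0,100]", call. = FALSE)
  if (any(adjustment < 0 | adjustment > 1))
    stop("adjustment must lie in [0,1]", call. = FALSE)
  raw + adjustment * (100 - raw)
}

#' Adjusted effectiveness at a given U5MR
#'
#' Convenience composition of [raw_effectiveness()] and
#' [adjust_effectiveness()] using the adjustment stored on the model.
#'
#' @inheritParams raw_effectiveness
#' @return adjusted effectiveness in percent.
#' @export
adjusted_effectiveness <- function(model, u5mr) {
  adjust_effectiveness(raw_effectiveness(model, u5mr), model$adjustment)
}

#' Potential impact fraction of a coverage change
#'
#' Fraction of the currently observed pneumonia deaths in a stratum that
#' would be averted by raising CCM coverage from `c0` to `c1`, given
#' adjusted intervention effectiveness `e = e_adj / 100`.  With observed
#' deaths proportional to `c0 * (1 - e) + (1 - c0)` (treated episodes die
#' at a fraction `1 - e` of the untreated rate),
#'
#'   `PIF = e * (c1 - c0) / (1 - c0 * e)`.
#'
#' The denominator accounts for current coverage already being reflected
#' in observed deaths; the expression degenerates correctly to
#' `e * c1` at `c0 = 0` and to `1` at `c0 = 0, c1 = 1, e = 1`.
#' Vectorised over all arguments.
#'
#' @param e_adj adjusted effectiveness in percent, in \[0, 100\].
#' @param c0 current coverage, in \[0, 1\].
#' @param c1 target coverage, in \[`c0`, 1\].
#' @return fraction of observed deaths averted, in \[0, 1\].
#' @examples
#' pif(100, 0, 1)        # 1
#' pif(50, 0.2, 0.3)     # 0.05 / 0.9
#' @export
pif <- function(e_adj, c0, c1) {
  if (any(e_adj < 0 | e_adj > 100))
    stop("e_adj must lie in [0,100]", call. = FALSE)
  if (any(c0 < 0 | c0 > 1 | c1 < 0 | c1 > 1))
    stop("coverages must lie in [0,1]", call. = FALSE)
  if (any(c1 < c0)) stop("c1 must be >= c0", call. = FALSE)
  e <- e_adj / 100
  denom <- 1 - c0 * e
  if (any(denom <= 0))
    stop("degenerate denominator: c0 * e must be < 1", call. = FALSE)
  e * (c1 - c0) / denom
}
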