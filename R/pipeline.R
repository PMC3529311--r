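#' Assemble and validate a run configuration
#'
#' A run configuration names the inputs and switches of a full pipeline
#' run.  `datasets = "demo"` uses the shipped synthetic demo scenario;
#' otherwise it is a path to a country-table CSV (see
#' [read_country_table()]).  `cost_pairs` / `effectiveness_studies` are
#' optional CSV paths overriding the packaged calibration tables.
#'
#' @param datasets `"demo"` or a CSV path.
#' @param cost_pairs optional CSV path with columns `u5mr`, `cost`.
#' @param effectiveness_studies optional CSV path with columns `u5mr`,
#'   `effectiveness`.
#' @param effectiveness_form `"anchored"` or `"ols"`.
#' @param adjustment remaining-gap adjustment fraction, in \[0, 1\].
#' @param step scale-up step, in (0, 1\].
#' @param budget fixed budget (US$) for the lives-per-budget comparison.
#' @param seed integer seed recorded in the manifest (the engine itself is
#'   deterministic; the seed matters only when synthetic generation is
#'   involved).
#' @return validated list of class `ccm_run_config`.
#' @export
run_config <- function(datasets = "demo", cost_pairs = NULL,
                       effectiveness_studies = NULL,
                       effectiveness_form = "anchored", adjustment = 0.5,
                       step = 0.10, budget = 1e6, seed = 1L) {
  if (!identical(datasets, "demo") && !file.exists(datasets))
    stop("config: dataset file not found: ", datasets, call. = FALSE)
  for (p in c(cost_pairs, effectiveness_studies))
    if (!is.null(p) && !file.exists(p))
      stop("config: file not found: ", p, call. = FALSE)
  effectiveness_form <- match.arg(effectiveness_form, c("anchored", "ols"))
  if (step <= 0 || step > 1)
    stop("config: step must lie in (0,1]", call. = FALSE)
  if (budget <= 0) stop("config: budget must be > 0", call. = FALSE)
  if (adjustment < 0 || adjustment > 1)
    stop("config: adjustment must lie in [0,1]", call. = FALSE)
  structure(list(datasets = datasets, cost_pairs = cost_pairs,
                 effectiveness_studies = effectiveness_studies,
                 effectiveness_form = effectiveness_form,
                 adjustment = adjustment, step = step, budget = budget,
                 seed = as.integer(seed)),
            class = "ccm_run_config")
}

#' Read a run configuration from JSON
#'
#' @param path JSON file whose keys match the [run_config()] arguments.
#' @return a `ccm_run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("config: unknown key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(run_config, raw)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes fit-costs, fit-effectiveness, burden and compare-strategies in
#' order and writes, under `out_dir`: `cost_model.json`,
#' `effectiveness_model.json`, `burden.csv`, `strategy_results.csv`,
#' `strategy_results.json` and `manifest.json` (a config echo plus package
#' version, sufficient to repeat the run exactly).  Any stage error aborts
#' with a stage-tagged message.  Identical config gives byte-identical
#' result files.
#'
#' @param config a [run_config()] (or [read_run_config()] result).
#' @param out_dir output directory, created if needed.
#' @param quiet suppress stage progress messages on stderr.
#' @return invisibly, a list with the fitted models, the burden table and
#'   the strategy results (all countries).
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "ccm_run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))

  say("[fit-costs] fitting non-antibiotic cost law")
  cost_m <- stage("fit-costs", {
    pairs <- if (is.null(config$cost_pairs)) ccm_cost_pairs() else
      utils::read.csv(config$cost_pairs)
    fit_cost_model(pairs)
  })
  jsonlite::write_json(unclass(cost_m)[c("intercept", "slope",
                                         "antibiotic_cost", "residuals")],
                       file.path(out_dir, "cost_model.json"),
                       auto_unbox = TRUE, digits = NA)

  say("[fit-effectiveness] fitting effectiveness trendline (%s)",
      config$effectiveness_form)
  eff_m <- stage("fit-effectiveness", {
    st <- if (is.null(config$effectiveness_studies))
      ccm_effectiveness_studies() else
      utils::read.csv(config$effectiveness_studies)
    fit_effectiveness(st, form = config$effectiveness_form,
                      adjustment = config$adjustment)
  })
  jsonlite::write_json(unclass(eff_m),
                       file.path(out_dir, "effectiveness_model.json"),
                       auto_unbox = TRUE, digits = NA)

  say("[load] loading datasets (%s)", config$datasets)
  datasets <- stage("load", {
    if (identical(config$datasets, "demo")) demo_scenario() else
      read_country_table(config$datasets)
  })

  say("[burden] computing burden tables for %d countries", length(datasets))
  burden <- stage("burden",
                  do.call(rbind, lapply(datasets, burden_table)))
  rownames(burden) <- NULL
  utils::write.csv(burden, file.path(out_dir, "burden.csv"),
                   row.names = FALSE, quote = FALSE)

  say("[compare] comparing strategies (step %.2f, budget %.0f)",
      config$step, config$budget)
  results <- stage("compare", do.call(rbind, lapply(datasets, function(d)
    compare_strategies(d, cost_m, eff_m, step = config$step,
                       budget = config$budget))))
  rownames(results) <- NULL
  utils::write.csv(results, file.path(out_dir, "strategy_results.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(results, file.path(out_dir, "strategy_results.json"),
                       dataframe = "rows", digits = NA)

  manifest <- list(config = unclass(config),
                   package = "ccmequity",
                   version = as.character(utils::packageVersion("ccmequity")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  say("[done] outputs in %s", out_dir)
  invisible(list(cost_model = cost_m, effectiveness_model = eff_m,
                 burden = burden, results = results))
}
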