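#' Uncovered pneumonia episodes per quintile
#'
#' @param coverage per-quintile current coverage fractions.
#' @param episodes per-quintile annual pneumonia episode counts.
#' @return numeric vector `(1 - coverage) * episodes`.
#' @export
uncovered_episodes <- function(coverage, episodes) {
  stopifnot(length(coverage) == length(episodes))
  if (any(coverage < 0 | coverage > 1))
    stop("coverage must lie in [0,1]", call. = FALSE)
  if (any(episodes < 0)) stop("episodes must be >= 0", call. = FALSE)
  (1 - coverage) * episodes
}

#' Scale-up strategy labels
#' @return character vector of the four strategies.
#' @export
ccm_strategies <- function() {
  c("mainstream", "inequity_promoting", "equity_neutral", "equity_promoting")
}

#' Allocate a coverage scale-up across wealth quintiles
#'
#' Distributes a target of `step * sum(uncovered)` newly covered pneumonia
#' episodes according to one of four strategies:
#'
#' * `"inequity_promoting"`: fill from the wealthiest uncovered pool (Q1)
#'   downward, spilling into Q2 when Q1 is exhausted, and so on;
#' * `"equity_promoting"`: fill from the poorest pool (Q5) upward;
#' * `"equity_neutral"`: take the band centred at the median of the
#'   wealth-ordered uncovered distribution (cumulative interval
#'   `[0.5 - step/2, 0.5 + step/2]`);
#' * `"mainstream"`: distribute proportionally to each quintile's share of
#'   currently covered episodes (scale-up continues to follow the existing
#'   delivery pattern); zero coverage everywhere falls back to uniform
#'   shares with a warning.  Pools are capped: overflow beyond a
#'   quintile's uncovered episodes is redistributed proportionally.
#'
#' @param strategy one of [ccm_strategies()].
#' @param step fraction of the national uncovered pool targeted, in
#'   (0, 1\]; default 0.10.
#' @param uncovered per-quintile uncovered episode counts, Q1..Q5.
#' @param covered per-quintile currently covered episode counts (required
#'   for `"mainstream"`).
#' @return object of class `ccm_allocation`: list with `strategy`, `step`,
#'   `target` and `newly_covered` (per-quintile vector summing to the
#'   target, never exceeding any quintile's uncovered pool).
#' @examples
#' unc <- c(200, 400, 500, 600, 800)
#' allocate_scaleup("equity_promoting", 0.10, unc)$newly_covered
#' @export
allocate_scaleup <- function(strategy, step = 0.10, uncovered,
                             covered = NULL) {
  strategy <- match.arg(strategy, ccm_strategies())
  if (step <= 0 || step > 1) stop("step must lie in (0,1]", call. = FALSE)
  if (any(uncovered < 0)) stop("uncovered must be >= 0", call. = FALSE)
  total <- sum(uncovered)
  if (total <= 0) stop("zero uncovered population", call. = FALSE)
  n <- length(uncovered)
  target <- step * total
  newly <- numeric(n)
  if (strategy %in% c("inequity_promoting", "equity_promoting")) {
    ord <- if (strategy == "inequity_promoting") seq_len(n) else rev(seq_len(n))
    left <- target
    for (q in ord) {
      take <- min(left, uncovered[q])
      newly[q] <- take
      left <- left - take
      if (left <= 0) break
    }
  } else if (strategy == "equity_neutral") {
    cum <- cumsum(uncovered) / total
    lo <- max(0, 0.5 - step / 2)
    hi <- min(1, 0.5 + step / 2)
    prev <- 0
    for (q in seq_len(n)) {
      a <- max(lo, prev); b <- min(hi, cum[q])
      if (b > a) newly[q] <- (b - a) * total
      prev <- cum[q]
    }
  } else { # mainstream
    if (is.null(covered))
      stop("mainstream allocation needs per-quintile covered episodes",
           call. = FALSE)
    if (sum(covered) <= 0) {
      warning("no current coverage anywhere: mainstream falls back to ",
              "uniform shares", call. = FALSE)
      covered <- rep(1, n)
    }
    w <- covered / sum(covered)
    newly <- target * w
    # redistribute overflow beyond uncovered pools proportionally
    repeat {
      over <- newly > uncovered
      if (!any(over)) break
      excess <- sum(newly[over] - uncovered[over])
      newly[over] <- uncovered[over]
      room <- !over & newly < uncovered
      if (!any(room) || excess <= 1e-12) break
      w2 <- covered[room] / sum(covered[room])
      newly[room] <- newly[room] + excess * w2
    }
  }
  structure(list(strategy = strategy, step = step, target = target,
                 newly_covered = newly),
            class = "ccm_allocation")
}

#' @export
print.ccm_allocation <- function(x, ...) {
  cat(sprintf("<ccm_allocation> %s, step %.2f, target %.1f episodes\n",
              x$strategy, x$step, x$target))
  print(round(x$newly_covered, 2))
  invisible(x)
}

#' Per-quintile model inputs for the scale-up engine
#'
#' Assembles, for a fully populated [country_dataset()], the per-quintile
#' quantities every strategy computation needs: unit cost, adjusted
#' effectiveness, burden (deaths, pneumonia deaths, episodes) and the
#' uncovered episode pool.
#'
#' @param dataset populated `country_dataset` (coverage, births, cfr and
#'   `cause:pneumonia` present).
#' @param cost_model a [fit_cost_model()] result; default
#'   [default_cost_model()].
#' @param eff_model a [fit_effectiveness()] result; default
#'   [default_effectiveness_model()].
#' @return data frame with columns `quintile`, `u5mr`, `coverage`,
#'   `unit_cost`, `e_adj`, `deaths`, `pneumonia_deaths`, `episodes`,
#'   `uncovered`, `covered`.
#' @export
quintile_inputs <- function(dataset, cost_model = default_cost_model(),
                            eff_model = default_effectiveness_model()) {
  b <- burden_table(dataset)
  q <- dataset$quintiles
  if (anyNA(q$coverage))
    stop(sprintf("dataset '%s' has missing coverage", dataset$country),
         call. = FALSE)
  data.frame(quintile = q$quintile, u5mr = q$u5mr, coverage = q$coverage,
             unit_cost = cost_per_child(cost_model, q$u5mr),
             e_adj = adjusted_effectiveness(eff_model, q$u5mr),
             deaths = b$deaths, pneumonia_deaths = b$pneumonia_deaths,
             episodes = b$episodes,
             uncovered = uncovered_episodes(q$coverage, b$episodes),
             covered = q$coverage * b$episodes)
}

newly_covered_of <- function(plan) {
  if (inherits(plan, "ccm_allocation")) plan$newly_covered else plan
}

#' Lives saved by an allocation
#'
#' Sums, over quintiles, observed pneumonia deaths times the potential
#' impact fraction of the coverage change the allocation implies:
#' `sum_q D_q * pif(e_q, c_q, c_q + n_q / E_q)`.
#'
#' @param plan a [allocate_scaleup()] result or a per-quintile vector of
#'   newly covered episode counts.
#' @param coverage,episodes,pneumonia_deaths,e_adj per-quintile inputs
#'   (see [quintile_inputs()]); `e_adj` in percent.
#' @return expected lives saved (real-valued).
#' @export
lives_saved <- function(plan, coverage, episodes, pneumonia_deaths, e_adj) {
  newly <- newly_covered_of(plan)
  stopifnot(length(newly) == length(coverage),
            length(newly) == length(episodes))
  dc <- ifelse(episodes > 0, newly / episodes, 0)
  if (any(dc > 1 - coverage + 1e-9))
    stop("allocation exceeds a quintile's uncovered pool", call. = FALSE)
  sum(pneumonia_deaths * pif(e_adj, coverage, pmin(1, coverage + dc)))
}

#' Cost per life saved of an allocation
#'
#' Total scale-up cost (unit cost times newly covered episodes, summed
#' over quintiles) divided by lives saved.
#'
#' @param plan allocation (as in [lives_saved()]).
#' @param unit_cost per-quintile US$ cost per child treated.
#' @param lives lives saved by the allocation; must be > 0.
#' @return US$ per life saved.
#' @export
cost_per_life_saved <- function(plan, unit_cost, lives) {
  newly <- newly_covered_of(plan)
  if (length(lives) != 1 || is.na(lives) || lives <= 0)
    stop("undefined result: zero lives saved", call. = FALSE)
  sum(unit_cost * newly) / lives
}

# marginal lives per newly covered episode, by quintile (constant in c1
# because PIF is linear in the target coverage)
lives_per_episode <- function(qi) {
  e <- qi$e_adj / 100
  ifelse(qi$episodes > 0,
         (qi$pneumonia_deaths / qi$episodes) * e / (1 - qi$coverage * e), 0)
}

#' Lives saved by spending a fixed budget under a strategy
#'
#' Expands the strategy's allocation greedily, at marginal cost, until the
#' budget is exhausted or the whole uncovered population is covered
#' (fractional coverage of an episode pool is allowed).  Quintile filling
#' order: poorest-first for `"equity_promoting"`, wealthiest-first for
#' `"inequity_promoting"`, middle-outward (by distance of the quintile's
#' cumulative midpoint from the median) for `"equity_neutral"`, and
#' proportional to current covered shares (with caps) for `"mainstream"`.
#' Because PIF is linear in the coverage increment, marginal lives per
#' newly covered episode are constant within a quintile and greedy filling
#' is exact.
#'
#' @param budget US$ available; must be > 0.
#' @param strategy one of [ccm_strategies()].
#' @param qi per-quintile inputs from [quintile_inputs()].
#' @return list with `lives` (expected lives saved), `spent` (US$ actually
#'   spent), `newly_covered` (per-quintile episode counts) and `capped`
#'   (`TRUE` when the budget exhausts the entire uncovered population, in
#'   which case `lives` is the attainable cap).
#' @export
lives_for_budget <- function(budget, strategy, qi) {
  strategy <- match.arg(strategy, ccm_strategies())
  if (budget <= 0) stop("budget must be > 0", call. = FALSE)
  lam <- lives_per_episode(qi)
  n <- nrow(qi)
  newly <- numeric(n)
  if (strategy == "mainstream") {
    covered <- qi$covered
    if (sum(covered) <= 0) {
      warning("no current coverage anywhere: mainstream falls back to ",
              "uniform shares", call. = FALSE)
      covered <- rep(1, n)
    }
    left <- budget
    open <- qi$uncovered > 0
    while (left > 1e-9 && any(open)) {
      w <- covered * open
      w <- w / sum(w)
      unit <- sum(w * qi$unit_cost)       # blended cost of one episode-mix
      afford <- left / unit               # episodes affordable at this mix
      # largest proportional expansion before some open pool saturates
      room <- (qi$uncovered - newly)[open] / w[open]
      scale <- min(afford, min(room))
      newly <- newly + scale * w
      left <- left - scale * unit
      open <- (qi$uncovered - newly) > 1e-9
    }
  } else {
    ord <- switch(strategy,
      equity_promoting = order(qi$quintile, decreasing = TRUE),
      inequity_promoting = order(qi$quintile),
      equity_neutral = {
        cum <- cumsum(qi$uncovered) / sum(qi$uncovered)
        mid <- cum - qi$uncovered / sum(qi$uncovered) / 2
        order(abs(mid - 0.5))
      })
    left <- budget
    for (q in ord) {
      if (left <= 1e-9) break
      if (qi$uncovered[q] <= 0 || qi$unit_cost[q] <= 0) next
      take <- min(left / qi$unit_cost[q], qi$uncovered[q])
      newly[q] <- take
      left <- left - take * qi$unit_cost[q]
    }
  }
  list(lives = sum(newly * lam), spent = sum(newly * qi$unit_cost),
       newly_covered = newly,
       capped = all(qi$uncovered - newly <= 1e-6))
}

#' Compare the four scale-up strategies on one country
#'
#' Runs mainstream, inequity-promoting, equity-neutral and
#' equity-promoting allocations of the same target (`step` times the
#' national uncovered episode pool), so that cost differences reflect unit
#' costs and lives differences reflect burden and effectiveness, and
#' additionally computes lives saved for a fixed budget under each
#' strategy.  Fully deterministic.
#'
#' @param dataset populated [country_dataset()].
#' @param cost_model,eff_model calibrated models; defaults fit the
#'   published tables.
#' @param step fraction of the uncovered pool targeted; default 0.10.
#' @param budget fixed budget for the lives-per-budget comparison, in
#'   US$; default 1e6.
#' @return data frame with one row per strategy: `country`, `strategy`,
#'   `target_episodes`, `cost`, `lives_saved`, `cost_per_life_saved`,
#'   `lives_for_budget`, `budget_capped`.
#' @examples
#' \donttest{
#' compare_strategies(demo_scenario()[["Nigeria"]])
#' }
#' @export
compare_strategies <- function(dataset, cost_model = default_cost_model(),
                               eff_model = default_effectiveness_model(),
                               step = 0.10, budget = 1e6) {
  qi <- quintile_inputs(dataset, cost_model, eff_model)
  rows <- lapply(ccm_strategies(), function(s) {
    plan <- allocate_scaleup(s, step, qi$uncovered, covered = qi$covered)
    lv <- lives_saved(plan, qi$coverage, qi$episodes, qi$pneumonia_deaths,
                      qi$e_adj)
    cost <- sum(qi$unit_cost * plan$newly_covered)
    lb <- lives_for_budget(budget, s, qi)
    data.frame(country = dataset$country, strategy = s,
               target_episodes = plan$target, cost = cost,
               lives_saved = lv,
               cost_per_life_saved = cost_per_life_saved(plan, qi$unit_cost,
                                                         lv),
               lives_for_budget = lb$lives, budget_capped = lb$capped)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
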