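# the worked toy from the allocation contract: coverage .8/.6/.5/.4/.2,
# 1000 episodes per quintile -> uncovered (200,400,500,600,800)
toy_unc <- function() uncovered_episodes(c(.8, .6, .5, .4, .2), rep(1000, 5))

test_that("uncovered episodes", {
  expect_equal(toy_unc(), c(200, 400, 500, 600, 800))
  expect_equal(uncovered_episodes(rep(1, 5), rep(1000, 5)), rep(0, 5))
  expect_equal(uncovered_episodes(0.5, 1000), 500)
  expect_error(uncovered_episodes(1.5, 10), "coverage")
})

test_that("the four strategies allocate the worked toy as specified", {
  unc <- toy_unc()
  eq <- allocate_scaleup("equity_promoting", 0.10, unc)
  expect_equal(eq$newly_covered, c(0, 0, 0, 0, 250))
  ineq <- allocate_scaleup("inequity_promoting", 0.10, unc)
  expect_equal(ineq$newly_covered, c(200, 50, 0, 0, 0))  # Q1 pool spills
  ms <- allocate_scaleup("mainstream", 0.10, unc,
                         covered = c(800, 600, 500, 400, 200))
  expect_equal(ms$newly_covered, c(80, 60, 50, 40, 20))
  # median band [0.45, 0.55] of the cumulative uncovered mass sits in Q4
  nt <- allocate_scaleup("equity_neutral", 0.10, unc)
  expect_equal(nt$newly_covered, c(0, 0, 0, 250, 0))

  expect_error(allocate_scaleup("equity_promoting", 1.2, unc), "step")
  expect_error(allocate_scaleup("equity_promoting", 0.1, rep(0, 5)),
               "zero uncovered")
  expect_warning(allocate_scaleup("mainstream", 0.1, unc,
                                  covered = rep(0, 5)), "uniform")
})

test_that("allocation conserves the target and respects pool caps", {
  for (s in 1:50) {
    set.seed(s)
    episodes <- runif(5, 100, 5000)
    coverage <- runif(5, 0, 0.95)
    unc <- uncovered_episodes(coverage, episodes)
    step <- runif(1, 0.02, 1)
    for (st in ccm_strategies()) {
      plan <- allocate_scaleup(st, step, unc, covered = coverage * episodes)
      expect_equal(sum(plan$newly_covered), step * sum(unc),
                   tolerance = 1 / max(1, step * sum(unc)))
      expect_true(all(plan$newly_covered <= unc + 1e-9))
      expect_true(all(plan$newly_covered >= 0))
    }
  }
})

test_that("lives saved matches the brute-force expectation oracle", {
  d <- toy_dataset()
  qi <- quintile_inputs(d)
  for (st in ccm_strategies()) {
    plan <- allocate_scaleup(st, 0.1, qi$uncovered, covered = qi$covered)
    expect_equal(
      lives_saved(plan, qi$coverage, qi$episodes, qi$pneumonia_deaths,
                  qi$e_adj),
      lives_saved_oracle(plan$newly_covered, qi$coverage, qi$episodes,
                         qi$pneumonia_deaths, qi$e_adj),
      tolerance = 1e-9)
  }
  # degenerate cases
  expect_equal(lives_saved(rep(0, 5), qi$coverage, qi$episodes,
                           qi$pneumonia_deaths, qi$e_adj), 0)
  expect_equal(lives_saved(1000, 0, 1000, 80, 100), 80)  # pif = 1
  expect_error(lives_saved(rep(1e9, 5), qi$coverage, qi$episodes,
                           qi$pneumonia_deaths, qi$e_adj), "exceeds")
})

test_that("cost per life saved arithmetic and guards", {
  expect_equal(cost_per_life_saved(1000, 2, 10), 200)
  # doubling allocation and budget within one quintile leaves CPLS unchanged
  expect_equal(cost_per_life_saved(2000, 2, 20), 200)
  expect_error(cost_per_life_saved(1000, 2, 0), "zero lives")
})

test_that("mainstream results are invariant to quintile relabelling", {
  d <- toy_dataset()
  qi <- quintile_inputs(d)
  run_ms <- function(qi) {
    plan <- allocate_scaleup("mainstream", 0.1, qi$uncovered,
                             covered = qi$covered)
    lv <- lives_saved(plan, qi$coverage, qi$episodes, qi$pneumonia_deaths,
                      qi$e_adj)
    c(lv, sum(plan$newly_covered * qi$unit_cost))
  }
  perm <- c(3, 5, 1, 4, 2)
  expect_equal(run_ms(qi), run_ms(qi[perm, ]), tolerance = 1e-12)
})

test_that("lives_for_budget is monotone, capped, and consistent with CPLS", {
  d <- toy_dataset()
  qi <- quintile_inputs(d)
  budgets <- c(1e3, 1e4, 1e5, 1e6, 1e9)
  for (st in ccm_strategies()) {
    lv <- vapply(budgets, function(b) lives_for_budget(b, st, qi)$lives,
                 numeric(1))
    expect_true(all(diff(lv) >= -1e-9))
    big <- lives_for_budget(1e12, st, qi)
    expect_true(big$capped)
    expect_equal(big$newly_covered, qi$uncovered, tolerance = 1e-6)
  }
  # within a single quintile, budget / unit-cost * lives-per-episode = lives
  one <- lives_for_budget(1e4, "equity_promoting", qi)
  expect_equal(one$newly_covered[1:4], rep(0, 4))
  expect_equal(one$spent, 1e4, tolerance = 1e-9)
  expect_error(lives_for_budget(0, "mainstream", qi), "budget")
})

test_that("identical quintiles make all four strategies equivalent", {
  d <- country_dataset("Flat", data.frame(
    quintile = 1:5, u5mr = 60, coverage = 0.4, births = 1e5, cfr = 0.02,
    `cause:pneumonia` = 0.2, `cause:other` = 0.8, check.names = FALSE))
  res <- compare_strategies(d)
  expect_equal(diff(range(res$cost_per_life_saved)), 0, tolerance = 1e-9)
  expect_equal(diff(range(res$lives_saved)), 0, tolerance = 1e-9)
})

test_that("strategy comparison is deterministic and internally consistent", {
  d <- demo_scenario()$Nigeria
  r1 <- compare_strategies(d)
  r2 <- compare_strategies(d)
  expect_identical(r1, r2)
  expect_equal(r1$cost_per_life_saved, r1$cost / r1$lives_saved)
  expect_setequal(r1$strategy, ccm_strategies())
  # all strategies compared at the same number of newly covered episodes
  expect_equal(diff(range(r1$target_episodes)), 0)
})
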