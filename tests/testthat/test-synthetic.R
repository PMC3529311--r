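test_that("generation is seed-deterministic and always valid", {
  cfg <- generator_config(seed = 42)
  expect_identical(generate_country(cfg), generate_country(cfg))
  expect_false(identical(generate_country(cfg),
                         generate_country(generator_config(seed = 43))))
  # every generated dataset passes full data-model validation
  for (s in 1:25) {
    d <- generate_country(generator_config(seed = s))
    expect_s3_class(validate_country_dataset(d), "country_dataset")
    cc <- grep("^cause:", names(d$quintiles))
    expect_equal(rowSums(d$quintiles[cc]), rep(1, 5), tolerance = 1e-9)
  }
  # generator does not disturb the caller's RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(generate_country(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("default config is Nigeria-like; degenerate config is flat", {
  d <- generate_country(generator_config(seed = 1))
  target <- c(87, 129, 165, 212, 219)
  expect_true(all(abs(d$quintiles$u5mr / target - 1) < 0.10))

  flat <- generate_country(generator_config(
    seed = 1, u5mr_shape = rep(1, 5), u5mr_noise_sd = 0,
    coverage_step = 0, coverage_noise_sd = 0))
  expect_equal(quintile_ratio(flat), 1)
  expect_equal(length(unique(flat$quintiles$coverage)), 1L)

  expect_error(generator_config(coverage_q1 = 0.2, coverage_step = 0.1),
               "infeasible")
  expect_error(generator_config(u5mr_shape = c(1, 0.9, 1, 1, 1)),
               "non-decreasing")
})

test_that("synthetic effectiveness studies expose a recoverable slope", {
  # noiseless: points lie exactly on the anchored line
  st0 <- generate_effectiveness_studies(n = 9, slope = -0.45, noise_sd = 0,
                                        seed = 3)
  expect_equal(st0$effectiveness, 100 - 0.45 * st0$u5mr, tolerance = 1e-12)
  m0 <- fit_effectiveness(st0)
  expect_equal(m0$slope, attr(st0, "true_slope"), tolerance = 1e-9)
  # zero slope, zero noise: everything at the anchor value
  stz <- generate_effectiveness_studies(n = 5, slope = 0, noise_sd = 0,
                                        seed = 3)
  expect_equal(stz$effectiveness, rep(100, 5))
  # noisy: recovered within 3 standard errors of the anchored estimator
  st <- generate_effectiveness_studies(n = 9, slope = -0.45, noise_sd = 8,
                                       seed = 11)
  m <- fit_effectiveness(st)
  resid <- st$effectiveness - (100 + m$slope * st$u5mr)
  se <- sqrt(sum(resid^2) / (nrow(st) - 1) / sum(st$u5mr^2))
  expect_lt(abs(m$slope - attr(st, "true_slope")), 3 * se)
})

test_that("the shipped demo CSV equals the in-code demo scenario", {
  path <- system.file("extdata", "demo_scenario_synthetic.csv",
                      package = "ccmequity")
  back <- read_country_table(path)
  demo <- demo_scenario()
  expect_identical(names(back), names(demo))
  for (cn in names(demo))
    expect_equal(back[[cn]]$quintiles, demo[[cn]]$quintiles,
                 tolerance = 1e-12)
})

test_that("demo scenario states the documented wealth gradients", {
  demo <- demo_scenario()
  tab <- ccm_cost_table()
  for (cn in names(demo)) {
    q <- demo[[cn]]$quintiles
    expect_equal(q$u5mr, tab$u5mr[tab$country == cn & tab$stratum != "Overall"])
    expect_true(all(diff(cfr(cfr_model("logistic"), q$u5mr)) >= 0))
    expect_true(all(q$coverage >= 0 & q$coverage <= 1))
  }
  # coverage declines with poverty except the documented Egypt bump
  for (cn in setdiff(names(demo), "Egypt"))
    expect_true(all(diff(demo[[cn]]$quintiles$coverage) < 0))
  eg <- demo$Egypt$quintiles$coverage
  expect_gt(eg[2], eg[1])                      # mid-wealth excess
  expect_equal(eg[1] - eg[5], 0.076)           # 7.6 percentage-point gap
})
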