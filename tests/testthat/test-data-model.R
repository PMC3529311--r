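test_that("dataset construction enforces the invariants with named errors", {
  q <- data.frame(quintile = 1:5, u5mr = c(20, 30, 40, 50, 60))
  expect_s3_class(country_dataset("A", q), "country_dataset")

  expect_error(country_dataset("A", q[1:4, ]), "exactly 5 quintiles")
  q2 <- q; q2$u5mr[3] <- -1
  expect_error(country_dataset("A", q2), "u5mr.*row 3")
  q3 <- q; q3$coverage <- c(0.5, 0.5, 0.5, 1.2, 0.5)
  expect_error(country_dataset("A", q3), "coverage.*row 4")
  q4 <- q; q4$cfr <- c(0.01, 0.01, 0, 0.01, 0.01)
  expect_error(country_dataset("A", q4), "cfr.*row 3")
  q5 <- q
  q5$`cause:pneumonia` <- 0.6
  q5$`cause:other` <- c(0.4, 0.4, 0.3, 0.4, 0.4)  # row 3 breaks the simplex
  expect_error(country_dataset("A", q5), "cause proportions.*row 3")
  # two causes summing to one, all others absent, is a valid simplex
  q6 <- q; q6$`cause:pneumonia` <- 0.5; q6$`cause:other` <- 0.5
  expect_s3_class(country_dataset("A", q6), "country_dataset")
})

test_that("CSV ingestion validates and errors name the problem", {
  path <- tempfile(fileext = ".csv")
  write_country_table(toy_dataset(), path)
  d <- read_country_table(path)
  expect_named(d, "Toyland")
  expect_equal(d$Toyland$quintiles$u5mr, c(20, 40, 60, 80, 100))

  writeLines("country,u5mr\nA,10", path)
  expect_error(read_country_table(path), "missing column.*quintile")
  writeLines(c("country,quintile,u5mr", "A,1,10", "A,2,x",
               "A,3,10", "A,4,10", "A,5,10"), path)
  expect_error(read_country_table(path), "non-numeric")
  writeLines(c("country,quintile,u5mr", paste0("A,", 1:4, ",10")), path)
  expect_error(read_country_table(path), "5 quintiles")
  expect_error(read_country_table(tempfile()), "no such file")
})

test_that("write/read round trip is the identity up to float formatting", {
  path <- tempfile(fileext = ".csv")
  orig <- demo_scenario()
  write_country_table(orig, path)
  back <- read_country_table(path)
  expect_identical(names(back), names(orig))
  for (cn in names(orig)) {
    expect_equal(back[[cn]]$quintiles, orig[[cn]]$quintiles,
                 tolerance = 1e-12)
    expect_equal(back[[cn]]$overall_u5mr, orig[[cn]]$overall_u5mr)
  }
})

test_that("quintile ratio divides poorest by wealthiest U5MR", {
  ex <- exemplar_datasets()
  expect_equal(quintile_ratio(ex$Nigeria), 219 / 87)
  expect_equal(quintile_ratio(ex$Bangladesh), 2.0)
  flat <- country_dataset("F", data.frame(quintile = 1:5, u5mr = 50))
  expect_equal(quintile_ratio(flat), 1.0)
  zero <- country_dataset("Z", data.frame(quintile = 1:5,
                                          u5mr = c(0, 1, 2, 3, 4)))
  expect_error(quintile_ratio(zero), "undefined")
  # any monotone non-decreasing profile has QR >= 1
  for (s in 1:20) {
    u <- sort(abs(rnorm(5, 50, 30))) + 1
    expect_gte(quintile_ratio(
      country_dataset("P", data.frame(quintile = 1:5, u5mr = u))), 1)
  }
})

test_that("packaged fixtures reproduce every published U5MR and cost cell", {
  tab <- ccm_cost_table()
  expect_equal(nrow(tab), 30)
  expect_true(all(tab$antibiotic_cost == 0.27))
  # spot-checked against the published table, full columns included
  expect_equal(tab$u5mr[tab$country == "Nigeria"],
               c(189, 87, 129, 165, 212, 219))
  expect_equal(tab$u5mr[tab$country == "Peru"], c(27, 9, 24, 24, 33, 59))
  expect_equal(tab$total_cost[tab$country == "Nigeria" & tab$stratum == "Q5"],
               3.11)
  expect_equal(tab$nonantibiotic_cost[tab$country == "Bangladesh" &
                                        tab$stratum == "Q1"], 0.95)
  expect_equal(tab$total_cost, tab$antibiotic_cost + tab$nonantibiotic_cost)

  st <- ccm_effectiveness_studies()
  expect_equal(nrow(st), 10)
  expect_equal(st[st$location == "Tanzania", c("u5mr", "effectiveness")],
               data.frame(u5mr = 161.4, effectiveness = 30.1),
               ignore_attr = TRUE)
  expect_equal(st[st$location == "Global", c("year", "u5mr", "effectiveness")],
               data.frame(year = 2012L, u5mr = 0, effectiveness = 100),
               ignore_attr = TRUE)

  ex <- exemplar_datasets()
  expect_equal(ex$Peru$quintiles$u5mr[1], 9)
  expect_equal(ex$Cambodia$overall_u5mr, 54)
  expect_true(all(is.na(ex$Nigeria$quintiles$coverage)))
})
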