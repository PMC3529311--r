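# shared fixtures and independent oracles, built in code

# a small fully populated country: five quintiles with simple round numbers
toy_dataset <- function(coverage = c(0.8, 0.6, 0.5, 0.4, 0.2),
                        u5mr = c(20, 40, 60, 80, 100),
                        cfr = c(0.01, 0.015, 0.02, 0.025, 0.03),
                        births = rep(1e5, 5),
                        pneu_share = rep(0.2, 5)) {
  country_dataset("Toyland", data.frame(
    quintile = 1:5, u5mr = u5mr, coverage = coverage, births = births,
    cfr = cfr, `cause:pneumonia` = pneu_share,
    `cause:other` = 1 - pneu_share, check.names = FALSE))
}

# PIF oracle: exact expectation by enumerating the (covered, dies) cells
# of a cohort of E episodes with untreated per-episode death risk d.
pif_oracle <- function(e_frac, c0, c1, E = 1e6, d = 0.02) {
  deaths_at <- function(c) {
    n_cov <- E * c
    n_unc <- E * (1 - c)
    n_cov * d * (1 - e_frac) + n_unc * d
  }
  (deaths_at(c0) - deaths_at(c1)) / deaths_at(c0)
}

# lives-saved oracle: back out the untreated risk consistent with the
# observed deaths, then difference expected deaths before/after scale-up
lives_saved_oracle <- function(newly, coverage, episodes, pneumonia_deaths,
                               e_adj) {
  e <- e_adj / 100
  d_raw <- pneumonia_deaths / (episodes * (1 - coverage * e))
  c1 <- coverage + newly / episodes
  before <- episodes * d_raw * (1 - coverage * e)
  after <- episodes * d_raw * (1 - c1 * e)
  sum(before - after)
}

# closed-form OLS via the normal equations, independent of stats::lm
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  unname(solve(t(X) %*% X, t(X) %*% y)[, 1])
}
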