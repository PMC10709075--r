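test_that("one-way sweeps span the range and include both endpoints", {
  s <- one_way_sweep("lvc_mortality_30d", n_points = 5)
  expect_equal(nrow(s), 5)
  expect_equal(s$value[1], 0.045)
  expect_equal(s$value[5], 0.061)
  expect_true(all(diff(s$value) > 0))
  # lvc mortality only moves the death delta
  expect_equal(length(unique(s$delta_complications)), 1)
  expect_true(all(diff(s$delta_deaths) > 0))

  # a degenerate range yields identical rows
  d <- one_way_sweep("p_hvc", n_points = 4)
  expect_equal(length(unique(d$delta_deaths)), 1)
  expect_equal(length(unique(d$delta_cost)), 1)

  # sweeping at the baseline value reproduces the baseline differential
  base <- one_way_sweep("lvc_mortality_30d", range = c(0.052, 0.052),
                        n_points = 2)
  d0 <- regionalization_differential(default_parameters(), rounding = "off")
  expect_equal(base$delta_deaths, rep(d0$delta_deaths, 2))
  expect_equal(base$delta_cost, rep(d0$delta_cost, 2))

  expect_error(one_way_sweep("nonsense"), "unknown parameter")
  expect_error(one_way_sweep("p_hvc", n_points = 1))
})

test_that("threshold fraction inverts the differential by bisection", {
  p <- default_parameters()
  full <- regionalization_differential(p, rounding = "off")

  # target equal to the complete-regionalization saving needs fraction 1
  expect_equal(threshold_fraction(p, "deaths", full$delta_deaths), 1,
               tolerance = 1e-5)
  # no improvement needed: stay at the current allocation
  expect_equal(threshold_fraction(p, "deaths", 0), p$p_hvc)
  # unattainable targets report NA
  expect_true(is.na(threshold_fraction(p, "deaths",
                                       full$delta_deaths + 1)))

  # midway target cross-checked against a 1e-4 grid search oracle
  target <- full$delta_deaths / 2
  got <- threshold_fraction(p, "deaths", target)
  grid <- seq(p$p_hvc, 1, by = 1e-4)
  n <- 5958 * 0.41 * 0.40
  delta_at <- function(f) {
    oracle_totals(n, p$p_hvc, 0.018, 0.343, 0.052, 0.398, 16815, 16815,
                  FALSE)$deaths -
      oracle_totals(n, f, 0.018, 0.343, 0.052, 0.398, 16815, 16815,
                    FALSE)$deaths
  }
  expected <- grid[which(sapply(grid, delta_at) >= target)[1]]
  expect_equal(got, expected, tolerance = 1e-4)

  # the cost metric works the same way
  gotc <- threshold_fraction(p, "cost", full$delta_cost / 2)
  expect_true(gotc > p$p_hvc && gotc < 1)
})

test_that("PSA is seed-deterministic and collapses under degenerate ranges", {
  a <- run_psa(n_draws = 150, seed = 42)
  b <- run_psa(n_draws = 150, seed = 42)
  expect_identical(a$summary, b$summary)
  expect_identical(a$draws, b$draws)
  expect_equal(a$seed, 42)
  expect_equal(a$n_draws, 150)
  c_ <- run_psa(n_draws = 150, seed = 43)
  expect_false(identical(a$summary, c_$summary))

  # degenerate ranges: every draw is the baseline, zero variance everywhere
  r <- parameter_ranges()
  r$low <- r$baseline
  r$high <- r$baseline
  deg <- run_psa(ranges = r, n_draws = 50, seed = 1)
  base <- regionalization_differential(default_parameters(),
                                       rounding = "off")
  expect_equal(unique(deg$draws$delta_deaths), base$delta_deaths)
  expect_equal(deg$summary$mean, deg$summary$q2.5)
  expect_equal(deg$summary$mean, deg$summary$q97.5)
  expect_equal(deg$summary$mean[deg$summary$metric == "delta_cost"],
               base$delta_cost)
  expect_equal(deg$prob_cost_saving, 1)
})

test_that("PSA draws respect their bounds and center on the range midpoints", {
  psa <- run_psa(n_draws = 3000, seed = 11)
  r <- parameter_ranges()
  for (i in seq_len(nrow(r))) {
    x <- psa$draws[[r$name[i]]]
    expect_true(all(x >= r$low[i] - 1e-12 & x <= r$high[i] + 1e-12),
                label = paste("draws within range for", r$name[i]))
  }
  # uniform independent sampling: E[delta_deaths] equals the differential at
  # the midpoint parameters (the delta is a product of independent factors)
  mid <- r
  midparams <- unflatten_parameters(
    stats::setNames((r$low + r$high) / 2, r$name))
  n_mid <- midparams$annual_incidence * midparams$p_resectable *
    midparams$p_resection
  o <- oracle_totals(n_mid, midparams$p_hvc,
                     midparams$hvc_rates$mortality_30d,
                     midparams$hvc_rates$complication_30d,
                     midparams$lvc_rates$mortality_30d,
                     midparams$lvc_rates$complication_30d,
                     midparams$cost_per_complication_hvc,
                     midparams$cost_per_complication_lvc, FALSE)
  o1 <- oracle_totals(n_mid, 1,
                      midparams$hvc_rates$mortality_30d,
                      midparams$hvc_rates$complication_30d,
                      midparams$lvc_rates$mortality_30d,
                      midparams$lvc_rates$complication_30d,
                      midparams$cost_per_complication_hvc,
                      midparams$cost_per_complication_lvc, FALSE)
  expected_mean <- o$deaths - o1$deaths
  mc_err <- 4 * stats::sd(psa$draws$delta_deaths) / sqrt(psa$n_draws)
  expect_lt(abs(mean(psa$draws$delta_deaths) - expected_mean), mc_err)

  # percentiles are ordered and the cost-saving probability is a proportion
  expect_true(all(psa$summary$q2.5 <= psa$summary$mean))
  expect_true(all(psa$summary$mean <= psa$summary$q97.5))
  expect_true(psa$prob_cost_saving >= 0 && psa$prob_cost_saving <= 1)
})
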