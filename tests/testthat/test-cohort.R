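test_that("half-up rounding rounds ties away from zero", {
  expect_equal(round_half_up(c(0.5, 1.5, 2.4, 2.5, 4.66)), c(1, 2, 2, 3, 5))
  expect_equal(round_half_up(-0.5), -1)
  expect_equal(round_half_up(0), 0)
})

test_that("cohort funnel reproduces the published counts and stays monotone", {
  co <- derive_cohort(5958, 0.41, 0.40)
  expect_equal(co$n_incident, 5958)
  expect_equal(co$n_resectable, 2443)
  expect_equal(co$n_resected, 977)

  expect_equal(unlist(derive_cohort(0, 0.41, 0.40)),
               c(n_incident = 0, n_resectable = 0, n_resected = 0))
  expect_equal(derive_cohort(1000, 0.5, 0.5)$n_resected, 250)

  set.seed(401)
  for (i in 1:50) {
    co <- derive_cohort(sample(0:10000, 1), runif(1), runif(1))
    expect_true(co$n_resected <= co$n_resectable)
    expect_true(co$n_resectable <= co$n_incident)
    expect_true(co$n_resected >= 0)
  }
})

test_that("allocation matches published split and conserves patients", {
  expect_equal(allocate_centers(977, 0.466), c(n_hvc = 455, n_lvc = 522))
  expect_equal(allocate_centers(977, 1.0), c(n_hvc = 977, n_lvc = 0))
  expect_equal(allocate_centers(10, 0.466), c(n_hvc = 5, n_lvc = 5))

  set.seed(402)
  for (i in 1:100) {
    n <- sample(0:5000, 1)
    a <- allocate_centers(n, runif(1))
    expect_equal(sum(a), n)
    expect_true(all(a >= 0))
  }
})

test_that("per-center outcomes match the published current state exactly", {
  lvc <- center_outcomes("LVC", 522, center_rates(0.052, 0.398), 16815)
  expect_equal(lvc$n_deaths, 27)
  expect_equal(lvc$n_complications, 208)
  expect_equal(lvc$complication_cost, 3497520)

  hvc <- center_outcomes("HVC", 455, center_rates(0.018, 0.343), 16815)
  expect_equal(hvc$n_deaths, 8)
  expect_equal(hvc$n_complications, 156)
  expect_equal(hvc$complication_cost, 2623140)

  none <- center_outcomes("HVC", 0, center_rates(0.5, 0.5), 99999)
  expect_equal(none$n_deaths, 0)
  expect_equal(none$n_complications, 0)
  expect_equal(none$complication_cost, 0)
})

test_that("run_state reproduces both published policy states", {
  p <- default_parameters()
  cur <- run_state(p, label = "current")
  expect_equal(cur$total_surgeries, 977)
  expect_equal(cur$total_deaths, 35)
  expect_equal(cur$total_complications, 364)
  expect_equal(cur$total_cost, 6120660)

  fut <- run_state(p, 1, label = "future")
  expect_equal(fut$total_surgeries, 977)
  expect_equal(fut$total_deaths, 18)
  expect_equal(fut$total_complications, 335)
  expect_equal(fut$total_cost, 5633025)

  # totals always equal the per-center sums
  for (s in list(cur, fut)) {
    expect_equal(s$total_deaths, sum(s$outcomes$n_deaths))
    expect_equal(s$total_complications, sum(s$outcomes$n_complications))
    expect_equal(s$total_cost, sum(s$outcomes$complication_cost))
  }
})

test_that("allocation is irrelevant when center classes have equal rates", {
  p <- set_parameters(default_parameters(),
                      list(hvc_mortality_30d = 0.03, lvc_mortality_30d = 0.03,
                           hvc_complication_30d = 0.37,
                           lvc_complication_30d = 0.37))
  for (rounding in c("half-up", "off")) {
    s0 <- run_state(p, 0, rounding = rounding)
    s1 <- run_state(p, 1, rounding = rounding)
    expect_equal(s0$total_deaths, s1$total_deaths)
    expect_equal(s0$total_complications, s1$total_complications)
    expect_equal(s0$total_cost, s1$total_cost)
    d <- compare_states(s0, s1)
    expect_equal(unlist(as.data.frame(d)), c(delta_deaths = 0,
                                             delta_complications = 0,
                                             delta_cost = 0))
  }
})

test_that("differentials subtract current minus future and check the cohort", {
  p <- default_parameters()
  cur <- run_state(p, label = "current")
  fut <- run_state(p, 1, label = "future")
  d <- compare_states(cur, fut)
  expect_equal(d$delta_deaths, 17)
  expect_equal(d$delta_complications, 29)
  expect_equal(d$delta_cost, 487635)

  self <- compare_states(cur, cur)
  expect_equal(c(self$delta_deaths, self$delta_complications,
                 self$delta_cost), c(0, 0, 0))

  other <- run_state(set_parameters(p, list(annual_incidence = 1000)))
  expect_error(compare_states(cur, other), "different cohorts")

  # equal complication counts, different unit costs: cost delta without a
  # complication delta
  pa <- params_for_cohort(100, c_hvc = 0.4, c_lvc = 0.4,
                          cost_hvc = 10000, cost_lvc = 20000)
  d2 <- compare_states(run_state(pa, 0, "cur"), run_state(pa, 1, "fut"))
  expect_equal(d2$delta_complications, 0)
  expect_equal(d2$delta_cost, 40 * 20000 - 40 * 10000)
})

test_that("run_state agrees with the brute-force oracle on a cohort/rate grid", {
  rate_grid <- list(
    c(m_h = 0.018, c_h = 0.343, m_l = 0.052, c_l = 0.398),
    c(m_h = 0, c_h = 0, m_l = 1, c_l = 1),
    c(m_h = 0.2, c_h = 0.75, m_l = 0.35, c_l = 0.85)
  )
  for (rates in rate_grid) {
    for (frac in c(0, 0.466, 1)) {
      for (rounding in c("half-up", "off")) {
        for (n in 0:200) {
          p <- params_for_cohort(n, rates[["m_h"]], rates[["c_h"]],
                                 rates[["m_l"]], rates[["c_l"]],
                                 cost_hvc = 16815, cost_lvc = 12345)
          s <- run_state(p, frac, rounding = rounding)
          o <- oracle_totals(n, frac, rates[["m_h"]], rates[["c_h"]],
                             rates[["m_l"]], rates[["c_l"]],
                             16815, 12345, rounding == "half-up")
          if (s$total_deaths != o$deaths ||
              s$total_complications != o$complications ||
              abs(s$total_cost - o$cost) > 1e-9 ||
              s$total_surgeries != o$surgeries) {
            fail(sprintf("oracle mismatch at n=%d frac=%g rounding=%s",
                         n, frac, rounding))
          }
        }
      }
    }
  }
  succeed()
})

test_that("complication costs are exact integer products of count and unit cost", {
  set.seed(403)
  for (i in 1:100) {
    n <- sample(0:3000, 1)
    unit <- sample(1:60000, 1)
    rate <- runif(1)
    out <- center_outcomes("LVC", n, center_rates(0.05, rate), unit)
    expect_true(out$n_complications == as.integer(out$n_complications))
    expect_identical(out$complication_cost, out$n_complications * unit)
    expect_true(out$n_complications <= n)
    expect_true(out$n_deaths <= n)
  }
})

test_that("deaths and complications fall monotonically with regionalization", {
  p <- default_parameters()  # HVC rates <= LVC rates
  fracs <- seq(0, 1, by = 0.05)

  # fractional counts: strictly non-increasing totals
  off <- t(sapply(fracs, function(f) {
    s <- run_state(p, f, rounding = "off")
    c(s$total_deaths, s$total_complications, s$total_cost)
  }))
  expect_true(all(diff(off[, 1]) <= 1e-12))
  expect_true(all(diff(off[, 2]) <= 1e-12))
  expect_true(all(diff(off[, 3]) <= 1e-9))

  # whole patients: non-increasing up to one rounding unit per center
  rounded <- sapply(fracs, function(f)
    run_state(p, f, rounding = "half-up")$total_deaths)
  expect_true(all(diff(rounded) <= 2))
  expect_equal(rounded[1] >= rounded[length(rounded)], TRUE)
})
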