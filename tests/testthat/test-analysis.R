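test_that("event waiting times are intervals between consecutive firings", {
  tr <- toy_trajectory(times = c(0, 1.0, 1.3, 1.7, 3.2),
                       states = c(0L, 1L, 1L, 2L, 3L),
                       fired = c(NA, 1L, 2L, 1L, 1L))
  expect_equal(event_waiting_times(tr, 1), c(0.7, 1.5))
  expect_equal(event_waiting_times(tr, "R2"), numeric(0))  # fired once
  expect_error(event_waiting_times(tr, "nope"), "unknown reaction")
  wset <- waiting_time_set(tr)
  expect_equal(sum(lengths(wset)),
               sum(pmax(table(tr$fired) - 1L, 0L)))
})

test_that("waiting-time analysis refuses tau-leap trajectories", {
  tr <- simulate_tau_leap(bd_model(), solver_settings(end = 50, seed = 1))
  expect_error(event_waiting_times(tr, 1), "tau-leap")
})

test_that("a constant-propensity channel is a Poisson process", {
  tr <- simulate_direct(bd_model(), solver_settings(end = 1e5, seed = 12))
  w <- event_waiting_times(tr, "Rsyn")
  expect_gt(stats::ks.test(w, "pexp", 10)$p.value, 0.001)
  expect_equal(mean(w), 0.1, tolerance = 0.02)
})

test_that("species distributions are holding-time weighted and normalized", {
  # X holds value 5 for 3 time units and 7 for 1 => P(5) = 0.75
  tr <- toy_trajectory(times = c(0, 3, 4), states = c(5L, 7L, 7L),
                       fired = c(NA, 1L, 1L))
  d <- species_distribution(tr, "X")
  expect_equal(d$support, c(5, 7))
  expect_equal(d$probability, c(0.75, 0.25))
  expect_equal(sum(d$probability), 1, tolerance = 1e-12)
  # constant trajectory: point mass
  tc <- toy_trajectory(times = c(0, 1, 2), states = c(4L, 4L, 4L),
                       fired = c(NA, 1L, 1L))
  dc <- species_distribution(tc, "X")
  expect_equal(dc$support, 4)
  expect_equal(dc$probability, 1)
})

test_that("distribution mean and moments agree through one weighting path", {
  tr <- simulate_direct(bd_model(), solver_settings(end = 2e4, seed = 33))
  d <- species_distribution(tr, "mRNA", burn_in = 0.1)
  mo <- moments(tr, "mRNA", burn_in = 0.1)
  expect_equal(distribution_mean(d), mo$mean, tolerance = 1e-12)
  expect_equal(sqrt(distribution_var(d)), mo$sd, tolerance = 1e-12)
})

test_that("moments handle constant and empty species correctly", {
  tr <- toy_trajectory(times = c(0, 1, 2), states = c(7L, 7L, 7L),
                       fired = c(NA, 1L, 1L))
  mo <- moments(tr, "X")
  expect_equal(mo$mean, 7); expect_equal(mo$sd, 0)
  tz <- toy_trajectory(times = c(0, 1, 2), states = c(0L, 0L, 0L),
                       fired = c(NA, 1L, 1L))
  expect_true(is.na(moments(tz, "X")$fano))
})

test_that("propensity distribution of a first-order channel is the scaled species law", {
  tr <- simulate_direct(bd_model(), solver_settings(end = 2e4, seed = 14))
  ds <- species_distribution(tr, "mRNA", burn_in = 0.1)
  dp <- propensity_distribution(tr, "Rdeg", burn_in = 0.1)
  expect_equal(dp$support, 0.2 * ds$support)
  expect_equal(dp$probability, ds$probability)
  # zero-order channel: point mass at its constant
  dz <- propensity_distribution(tr, "Rsyn")
  expect_equal(dz$support, 10)
  expect_equal(dz$probability, 1)
})

test_that("autocorrelation is 1 at lag zero and decays as exp(-kd*lag)", {
  tr <- simulate_direct(bd_model(), solver_settings(end = 2e5, seed = 41))
  lags <- c(0, 1, 2.5, 5, 10)
  a <- autocorrelation(tr, "mRNA", lags)
  expect_equal(a$acf[1], 1)
  expect_true(all(abs(a$acf - analytic_acf(0.2, a$lag_used)) < 0.05))
})

test_that("a shuffled surrogate decorrelates at long lags", {
  set.seed(6)
  n <- 5000
  tr <- toy_trajectory(times = seq(0, n) * 1.0,
                       states = as.integer(rpois(n + 1, 50)),
                       fired = c(NA, rep(1L, n)))
  a <- autocorrelation(tr, "X", lags = c(10, 25), grid_dt = 1)
  expect_true(all(abs(a$acf) < 3 / sqrt(n)))
})

test_that("fixed-interval regridding uses zero-order hold", {
  tr <- toy_trajectory(times = c(0, 5, 10), states = c(2L, 9L, 9L),
                       fired = c(NA, 1L, 1L))
  g <- regrid_fixed_interval(tr, 3)
  expect_equal(g$times, c(0, 5, 10))
  expect_equal(unname(g$states[, 1]), c(2L, 9L, 9L))
  g2 <- regrid_fixed_interval(tr, 2)
  expect_equal(g2$times, c(0, 10))
  expect_equal(unname(g2$states[, 1]), c(2L, 9L))
  expect_error(regrid_fixed_interval(tr, 1), "n_intervals")
})

test_that("gridded means converge to the time-weighted mean as the grid refines", {
  tr <- simulate_direct(bd_model(), solver_settings(end = 2e4, seed = 52))
  truth <- moments(tr, "mRNA")$mean
  errs <- vapply(c(1e2, 1e3, 1e4, 1e5), function(n) {
    g <- regrid_fixed_interval(tr, as.integer(n))
    abs(mean(g$states[, "mRNA"]) - truth)
  }, 0)
  expect_lt(errs[4], errs[1])
  expect_lt(mean(diff(errs)), 0)   # decreasing on average
  expect_lt(errs[4], 0.05)
})

test_that("ensemble averaging reduces to the obvious special cases", {
  tr <- simulate_direct(bd_model(), solver_settings(end = 100, mode = "time",
                                                    seed = 61))
  av <- average_trajectories(list(tr, tr, tr), "mRNA", grid = 11L)
  expect_true(all(av$sd == 0))
  tr2 <- simulate_direct(bd_model(), solver_settings(end = 100,
                                                     mode = "time", seed = 62))
  av2 <- average_trajectories(list(tr, tr2), "mRNA", grid = 11L)
  g1 <- regrid_fixed_interval(tr, 11L); g2 <- regrid_fixed_interval(tr2, 11L)
  expect_equal(av2$mean, (g1$states[, "mRNA"] + g2$states[, "mRNA"]) / 2)
})

test_that("single-enzyme ensemble mean product tracks the renewal rate line", {
  m <- build_fixture("single_enzyme", variant = "clamped")$model
  e <- run_ensemble(m, solver_settings(end = 400, mode = "time", seed = 71,
                                       n_trajectories = 60L))
  av <- average_trajectories(e, "P", grid = seq(0, 400, by = 50))
  # renewal rate: 1 / mean phase-type waiting time = k2 * P(ES) at stationarity
  o <- fixture_waiting_time_oracle("single_enzyme")
  mu <- sum(o$initial_distribution %*% solve(-o$sub_generator))
  pred <- av$time / mu
  se <- av$sd / sqrt(60)
  inside <- abs(av$mean - pred) <= 3 * se + 1
  expect_true(all(inside[av$time > 0]))
})

test_that("waiting-time densities integrate to one and fit the known slope", {
  set.seed(81)
  x <- rexp(2e4, 10)
  pdf <- waiting_time_pdf(x, bins = "linear", n_bins = 25)
  expect_equal(sum(pdf$density * (pdf$right - pdf$left)), 1, tolerance = 1e-9)
  keep <- pdf$count > 20
  fit <- lm(log(pdf$density[keep]) ~ pdf$mid[keep])
  expect_equal(unname(coef(fit)[2]), -10, tolerance = 0.08)
  one <- waiting_time_pdf(x, n_bins = 1)
  expect_equal(sum(one$density * (one$right - one$left)), 1)
  expect_error(waiting_time_pdf(numeric(0)), "empty")
  expect_warning(waiting_time_pdf(rexp(5, 1)), "fewer than 10")
  lg <- waiting_time_pdf(x, bins = "log", n_bins = 20)
  expect_equal(sum(lg$density * (lg$right - lg$left)), 1, tolerance = 1e-9)
})
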