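test_that("steps mode records exactly the requested number of events", {
  m <- bd_model()
  tr <- simulate_direct(m, solver_settings(end = 1000, seed = 1))
  expect_equal(n_events(tr), 1000L)
  expect_equal(length(tr$times), 1001L)   # initial row + 1000 events
  expect_true(all(diff(tr$times) > 0))
  expect_true(is.na(tr$fired[1]))
  expect_false(anyNA(tr$fired[-1]))
})

test_that("zero total propensity halts immediately with the absorbing flag", {
  m <- ssa_model(list(ssa_species("A", 0)),
                 list(ssa_reaction("R", c(A = 1), NULL, 1)))
  for (sim in list(simulate_direct, simulate_first_reaction,
                   simulate_next_reaction, simulate_tau_leap)) {
    tr <- sim(m, solver_settings(end = 100, seed = 1))
    expect_equal(n_events(tr), 0L)
    expect_true(tr$absorbing)
  }
})

test_that("an exhaustible reaction fires exactly its available count", {
  m <- ssa_model(list(ssa_species("A", 5), ssa_species("B", 0)),
                 list(ssa_reaction("R", c(A = 1), c(B = 1), 1)))
  tr <- simulate_direct(m, solver_settings(end = 1e6, mode = "time",
                                           seed = 2))
  expect_equal(n_events(tr), 5L)
  expect_true(tr$absorbing)
  expect_equal(unname(tr$states[nrow(tr$states), ]), c(0L, 5L))
  # terminal row closes the interval at exactly t_end
  expect_equal(tr$times[length(tr$times)], 1e6)
  expect_true(tr$terminal)
})

test_that("fixed seeds give bit-identical repeat runs for every solver", {
  m <- bd_model()
  for (sv in c("direct", "first_reaction", "next_reaction", "tau_leap")) {
    s <- solver_settings(end = 500, seed = 99, solver = sv)
    t1 <- simulate_ssa(m, s)
    t2 <- simulate_ssa(m, s)
    expect_identical(t1$times, t2$times)
    expect_identical(t1$states, t2$states)
    expect_identical(t1$propensities, t2$propensities)
  }
})

test_that("exact solvers respect stoichiometry and non-negativity", {
  set.seed(21)
  for (rep in 1:6) {
    m <- random_model()
    nu <- stoichiometry(m)
    for (sv in c("direct", "first_reaction", "next_reaction")) {
      tr <- simulate_ssa(m, solver_settings(end = 300, seed = 100 + rep,
                                            solver = sv))
      expect_true(all(tr$states >= 0L))
      ev <- which(!is.na(tr$fired))
      if (length(ev)) {
        dif <- tr$states[ev, , drop = FALSE] -
          tr$states[ev - 1L, , drop = FALSE]
        expect_equal(unname(dif), unname(t(nu[, tr$fired[ev], drop = FALSE])))
      }
      # recorded propensities always evaluate at the recorded state
      idx <- c(1L, length(tr$times))
      expect_equal(unname(tr$propensities[idx, , drop = FALSE]),
                   unname(propensities(m, tr$states[idx, , drop = FALSE])))
    }
  }
})

test_that("dependency graph follows the changed-species/read-species rule", {
  dep <- build_dependency_graph(bd_model())
  expect_equal(dep$Rsyn, c(1L, 2L))   # synthesis perturbs degradation
  expect_equal(dep$Rdeg, 2L)          # zero-order synthesis reads nothing
  m2 <- ssa_model(list(ssa_species("A", 1), ssa_species("B", 1),
                       ssa_species("C", 1), ssa_species("D", 1)),
                  list(ssa_reaction("r1", c(A = 1), c(B = 1), 1),
                       ssa_reaction("r2", c(B = 1), c(A = 1), 1),
                       ssa_reaction("r3", c(C = 1), c(D = 1), 1),
                       ssa_reaction("r4", c(D = 1), c(C = 1), 1)))
  dep2 <- build_dependency_graph(m2)
  expect_equal(dep2$r1, c(1L, 2L)); expect_equal(dep2$r3, c(3L, 4L))
  m3 <- parse_mdl(c("A = 1", "B = 1", "k : 2",
                    "ra: A > $pool, 1",
                    "rb: B > $pool, 1",
                    "rexp: $pool > A, k*(A + B)"))
  dep3 <- build_dependency_graph(m3)
  expect_true(all(c(1L, 3L) %in% dep3$ra))  # changing A perturbs the
  expect_true(all(c(2L, 3L) %in% dep3$rb))  # expression k*(A+B)
})

test_that("next reaction method orders a forced chain correctly", {
  tr <- simulate_next_reaction(chain_model(1),
                               solver_settings(end = 100, mode = "time",
                                               seed = 5))
  expect_equal(n_events(tr), 2L)
  expect_equal(tr$fired[2:3], c(1L, 2L))
  expect_equal(unname(tr$states[3, ]), c(0L, 0L, 1L))
})

test_that("a channel re-activated from zero propensity gets a fresh clock", {
  # degradation starts disabled (X = 0); it must never fire before a
  # synthesis has enabled it, under the clock-reuse scheme
  m <- ssa_model(list(ssa_species("X", 0)),
                 list(ssa_reaction("syn", NULL, c(X = 1), 0.5),
                      ssa_reaction("deg", c(X = 1), NULL, 5)))
  for (seed in 1:5) {
    tr <- simulate_next_reaction(m, solver_settings(end = 200, seed = seed))
    expect_equal(tr$fired[2], 1L)
    expect_true(all(tr$states >= 0L))
    # whenever deg fired, the pre-state had X > 0
    ev <- which(!is.na(tr$fired) & tr$fired == 2L)
    expect_true(all(tr$states[ev - 1L, "X"] > 0L))
  }
})

test_that("first reaction and next reaction agree with direct in the mean", {
  m <- bd_model()
  ms <- vapply(c("direct", "first_reaction", "next_reaction"), function(sv) {
    tr <- simulate_ssa(m, solver_settings(end = 5e4, seed = 31, solver = sv))
    moments(tr, "mRNA", burn_in = 0.1)$mean
  }, 0)
  # stationary se of the time-weighted mean is ~0.45 at 5e4 events
  expect_true(all(abs(ms - 50) < 2))
})

test_that("tau-leaping collapses to exact stepping as epsilon shrinks", {
  m <- bd_model()
  tr <- simulate_tau_leap(m, solver_settings(end = 100, seed = 3,
                                             tau_epsilon = 0.001))
  expect_false(tr$exact)
  expect_true(all(rowSums(tr$firings[-1, , drop = FALSE]) <= 1L))
})

test_that("tau-leaping aggregates events yet preserves the stationary mean", {
  m <- bd_model(ksyn = 1000, kd = 0.2, n0 = 5000)   # mean 5000 copies
  tr <- simulate_tau_leap(m, solver_settings(end = 500, mode = "time",
                                             seed = 8))
  expect_true(max(rowSums(tr$firings[-1, , drop = FALSE]), na.rm = TRUE) > 10)
  expect_true(all(tr$states >= 0L))
  mt <- moments(tr, "mRNA", burn_in = 0.2)$mean
  te <- simulate_direct(m, solver_settings(end = 500, mode = "time",
                                           seed = 9))
  me <- moments(te, "mRNA", burn_in = 0.2)$mean
  # both estimates carry se ~ sqrt(2 var tau_c / T) ~ 16
  expect_lt(abs(mt - 5000), 100)
  expect_lt(abs(mt - me), 150)
})

test_that("small-copy channels are handled exactly within tau leaps", {
  # conversion chain with a 3-copy reservoir: the consuming channel is
  # critical (3 < 10) and may never overdraw
  m <- ssa_model(list(ssa_species("A", 3), ssa_species("B", 0)),
                 list(ssa_reaction("use", c(A = 1), c(B = 1), 50),
                      ssa_reaction("back", c(B = 1), c(A = 1), 0.1)))
  tr <- simulate_tau_leap(m, solver_settings(end = 50, mode = "time",
                                             seed = 4))
  expect_true(all(tr$states >= 0L))
  expect_true(all(rowSums(tr$states) == 3L))
})

test_that("ensembles are reproducible with independent member streams", {
  m <- bd_model()
  s <- solver_settings(end = 200, seed = 17, n_trajectories = 4L)
  e1 <- run_ensemble(m, s)
  e2 <- run_ensemble(m, s)
  for (k in 1:4) expect_identical(e1[[k]]$times, e2[[k]]$times)
  expect_false(identical(e1[[1]]$times, e1[[2]]$times))
})

test_that("ensemble stationary means scatter around the analytic mean", {
  m <- bd_model()
  e <- run_ensemble(m, solver_settings(end = 5e3, seed = 23,
                                       n_trajectories = 24L))
  ms <- vapply(e, function(tr) moments(tr, "mRNA", burn_in = 0.2)$mean, 0)
  se <- sd(ms) / sqrt(length(ms))
  expect_lt(abs(mean(ms) - 50), 3 * se + 0.5)
})
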