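test_that("gamma interdivision draws have the configured mean and CV", {
  ds <- division_settings(shape = 1.0, scale = 60.0, end_generations = 1)
  set.seed(1)
  draws <- replicate(1e5, sample_division_interval(ds))
  expect_equal(mean(draws), 60, tolerance = 0.01)
  expect_equal(sd(draws) / mean(draws), 1, tolerance = 0.02)
  # shape 1 is memoryless: exponential intervals
  expect_gt(stats::ks.test(draws, "pexp", 1 / 60)$p.value, 0.001)
  set.seed(7); d1 <- sample_division_interval(ds)
  set.seed(7); d2 <- sample_division_interval(ds)
  expect_identical(d1, d2)
  # fixed-interval alternative returns the deterministic mean
  df <- division_settings(fixed_interval = TRUE, end_generations = 1)
  expect_equal(sample_division_interval(df), 60)
})

test_that("binomial partitioning conserves copy numbers exactly", {
  ds <- division_settings(end_generations = 1)
  set.seed(2)
  for (rep in 1:200) {
    n <- setNames(sample(0:50, 3, replace = TRUE), c("A", "B", "C"))
    sp <- binomial_partition(n, ds)
    expect_identical(sp$daughter + sp$discarded, n)
    expect_true(all(sp$daughter >= 0))
  }
  z <- binomial_partition(c(A = 0), ds)
  expect_equal(unname(z$daughter + z$discarded), 0L)
})

test_that("daughter counts follow binomial moments", {
  ds <- division_settings(end_generations = 1)
  set.seed(3)
  n <- 1e4
  reps <- vapply(1:1000, function(i)
    binomial_partition(c(A = n), ds)$daughter[["A"]], 0L)
  se <- sqrt(n * 0.25 / 1000)
  expect_lt(abs(mean(reps) - n * 0.5), 3 * se)
  expect_equal(var(reps), n * 0.25, tolerance = 0.1)
})

test_that("non-partitioned and fixed species pass through divisions whole", {
  ds <- division_settings(end_generations = 1)
  set.seed(4)
  sp <- binomial_partition(c(gene = 1, prot = 100, buf = 7), ds,
                           partition = c(FALSE, TRUE, TRUE),
                           fixed = c(FALSE, FALSE, TRUE))
  expect_equal(sp$daughter[["gene"]], 1L)       # tracked daughter keeps it
  expect_equal(sp$discarded[["gene"]], 0L)
  expect_equal(sp$daughter[["buf"]], 7L)        # buffered: copied to both
  expect_equal(sp$discarded[["buf"]], 7L)
  expect_equal(sp$daughter[["prot"]] + sp$discarded[["prot"]], 100L)
})

test_that("deterministic halving alternates the odd copy between daughters", {
  ds <- division_settings(deterministic_halving = TRUE, end_generations = 1)
  a <- binomial_partition(c(A = 7), ds, division_index = 0L)
  b <- binomial_partition(c(A = 7), ds, division_index = 1L)
  expect_equal(a$daughter[["A"]], 4L)
  expect_equal(b$daughter[["A"]], 3L)
  expect_equal(a$daughter + a$discarded, c(A = 7L))
})

test_that("explicit lineages book-keep divisions and conserve mass", {
  m <- build_fixture("tx_tl_division")$model
  lin <- simulate_with_divisions(m, solver_settings(seed = 5),
                                 division_settings(end_generations = 25))
  expect_length(lin$segments, 25L)
  expect_length(lin$division_times, 25L)
  for (r in lin$partition_records)
    expect_identical(r$daughter + r$discarded, r$pre)
  # global time axis is continuous across generations
  for (g in 2:25)
    expect_equal(lin$segments[[g]]$times[1],
                 lin$segments[[g - 1]]$times[
                   length(lin$segments[[g - 1]]$times)])
  # division times equal the cumulative segment ends
  ends <- vapply(lin$segments, function(s) s$times[length(s$times)], 0)
  expect_equal(lin$division_times, ends)
  # each segment starts from the recorded daughter state
  for (g in 2:25)
    expect_equal(unname(lin$segments[[g]]$states[1, ]),
                 unname(lin$partition_records[[g - 1]]$daughter))
})

test_that("a division interval beyond end_time leaves a single segment", {
  m <- bd_model()
  lin <- simulate_with_divisions(
    m, solver_settings(seed = 6),
    division_settings(scale = 1e6, end_time = 50))
  expect_length(lin$segments, 1L)
  expect_length(lin$division_times, 0L)
  expect_equal(lin$segments[[1]]$times[length(lin$segments[[1]]$times)], 50)
})

test_that("inter-division intervals are memoryless at shape 1", {
  m <- bd_model()
  lin <- simulate_with_divisions(
    m, solver_settings(seed = 7),
    division_settings(shape = 1, scale = 10, end_generations = 300))
  iv <- diff(c(0, lin$division_times))
  expect_gt(stats::ks.test(iv, "pexp", 1 / 10)$p.value, 0.001)
})

test_that("dilution reactions implement implicit division", {
  m <- bd_model()
  md <- add_dilution(m, growth_rate = 0.1)
  expect_length(md$species, 1L)
  expect_length(md$reactions, 3L)
  expect_error(add_dilution(m, 0), "positive")
  expect_error(add_dilution(md, 0.1), "collision")
  # stationary mean drops to ksyn / (kd + kg), the birth-death closed form
  tr <- simulate_direct(md, solver_settings(end = 3e5, seed = 8))
  expect_equal(moments(tr, "mRNA", burn_in = 0.1)$mean, 10 / 0.3,
               tolerance = 0.03)
})

test_that("explicit divisions at vanishing CV match implicit dilution", {
  # shape 50 makes the division clock nearly deterministic; with growth
  # rate ln(2)/mean-interval the two formulations agree in the long-run mean
  m <- bd_model()
  mean_int <- 60
  lin <- simulate_with_divisions(
    m, solver_settings(seed = 9),
    division_settings(shape = 50, scale = mean_int / 50,
                      end_generations = 120))
  gm <- lineage_generation_means(lin, "mRNA")
  explicit_mean <- mean(gm[-(1:20)])
  md <- add_dilution(m, log(2) / mean_int)
  tr <- simulate_direct(md, solver_settings(end = 3e5, seed = 10))
  implicit_mean <- moments(tr, "mRNA", burn_in = 0.1)$mean
  expect_lt(abs(explicit_mean - implicit_mean) / implicit_mean, 0.15)
})
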