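test_that("MDL parsing recovers the synthesis-degradation case study", {
  m <- parse_mdl(c("mRNA = 50",
                   "R1: $pool > mRNA, 10",
                   "R2: mRNA > $pool, 0.2*mRNA"))
  expect_length(m$species, 1L)
  expect_length(m$reactions, 2L)
  expect_equal(initial_state(m), c(mRNA = 50L))
  expect_equal(m$reactions[[1]]$law$type, "mass_action")
  expect_equal(m$reactions[[1]]$law$c, 10)
  # the expression law 0.2*mRNA equals first-order mass action at any state
  expect_equal(unname(propensities(m, c(mRNA = 50))), c(10, 10))
  expect_equal(unname(propensities(m, c(mRNA = 0))), c(10, 0))
})

test_that("MDL parse errors are specific and leave no partial model", {
  expect_error(parse_mdl(""), "no species and no reactions")
  expect_error(parse_mdl(c("A = 5", "R1: A > $pool, 0.1*X")), "X")
  expect_error(parse_mdl("A = -3"), "negative")
  expect_error(parse_mdl("A = 2.5"), "integer")
  expect_error(parse_mdl(c("A = 1", "what is this")), "line 2")
})

test_that("write_mdl/parse_mdl round-trips semantically identical models", {
  set.seed(11)
  for (rep in 1:20) {
    m <- random_model()
    m2 <- parse_mdl(write_mdl(m))
    expect_identical(species_names <- vapply(m$species, `[[`, "", "name"),
                     vapply(m2$species, `[[`, "", "name"))
    expect_identical(initial_state(m), initial_state(m2))
    expect_identical(stoichiometry(m), stoichiometry(m2))
    states <- matrix(sample(0:30, 5 * length(m$species), replace = TRUE),
                     nrow = 5, dimnames = list(NULL, names(initial_state(m))))
    expect_equal(propensities(m, states), propensities(m2, states))
  }
  # expression laws and fixed species survive verbatim modulo whitespace
  txt <- c("E = 1", "ES = 0", "$S = 20", "k1 : 0.5",
           "B: E + $S > ES, k1*E*S")
  m <- parse_mdl(txt)
  m2 <- parse_mdl(write_mdl(m))
  expect_equal(m2$reactions[[1]]$law$expr, "k1*E*S")
  expect_true(m2$species[[3]]$fixed)
  # species-only model round-trips
  m3 <- parse_mdl(write_mdl(parse_mdl("A = 7")))
  expect_length(m3$reactions, 0L)
  expect_equal(initial_state(m3), c(A = 7L))
})

test_that("mass-action propensities follow the combinatorial convention", {
  m <- bd_model()
  expect_equal(compute_propensity(m, "Rsyn", c(mRNA = 123)), 10)
  expect_equal(compute_propensity(m, "Rdeg", c(mRNA = 50)), 10)
  dimer <- ssa_model(list(ssa_species("A", 1)),
                     list(ssa_reaction("D", c(A = 2), NULL, 1)))
  expect_equal(compute_propensity(dimer, "D", c(A = 1)), 0)
  expect_equal(compute_propensity(dimer, "D", c(A = 5)), 10)  # 5*4/2
  bim <- ssa_model(list(ssa_species("A", 3), ssa_species("B", 4)),
                   list(ssa_reaction("R", c(A = 1, B = 1), NULL, 2)))
  expect_equal(compute_propensity(bim, "R", c(A = 3, B = 4)), 24)
})

test_that("expression laws match their mass-action encoding on random states", {
  m <- parse_mdl(c("A = 10", "B = 5",
                   "k : 0.3",
                   "Rma: A + B > A, 0.3",
                   "Rex: A + B > A, k*A*B"))
  set.seed(5)
  S <- matrix(sample(0:100, 2000, replace = TRUE), ncol = 2,
              dimnames = list(NULL, c("A", "B")))
  P <- propensities(m, S)
  expect_equal(P[, "Rma"], P[, "Rex"])
  expect_true(all(P >= 0))
})

test_that("negative expression propensities are clipped with a warning", {
  m <- parse_mdl(c("A = 1", "R: A > $pool, 1 - A"))
  expect_warning(p <- propensities(m, c(A = 5)), "clipped")
  expect_equal(unname(p), 0)
})

test_that("restricted expression interpreter supports its documented grammar", {
  m <- parse_mdl(c("A = 4", "k : 2",
                   "R1: $pool > A, min(k*A, 5)",
                   "R2: $pool > A, max(A - 6, 0) + exp(0) * 2^2",
                   "R3: $pool > A, k*A/(1 + A)"))
  p <- propensities(m, c(A = 4))
  expect_equal(unname(p), c(5, 4, 8 / 5))
  expect_error(parse_mdl(c("A = 1", "k : 2", "R: A > $pool, k*(A")),
               "unbalanced")
})

test_that("SBML subset import matches the MDL fixture and rejects events", {
  f <- system.file("extdata", "immigration_death_l2.xml", package = "ssakit")
  m <- import_sbml_subset(f)
  ref <- build_fixture("immigration_death")$model
  expect_length(m$reactions, 2L)
  expect_equal(initial_state(m), initial_state(ref))
  for (n in c(0, 1, 50, 200))
    expect_equal(unname(propensities(m, c(mRNA = n))),
                 unname(propensities(ref, c(mRNA = n))))
  doc_event <- sub("<listOfReactions>",
                   paste0("<listOfEvents><event id=\"e\"/></listOfEvents>",
                          "<listOfReactions>"),
                   paste(readLines(f), collapse = "\n"))
  tf <- tempfile(fileext = ".xml"); writeLines(doc_event, tf)
  expect_error(import_sbml_subset(tf), "unsupported-construct: event")
  doc_frac <- sub('initialAmount="50"', 'initialAmount="49.6"',
                  paste(readLines(f), collapse = "\n"))
  tf2 <- tempfile(fileext = ".xml"); writeLines(doc_frac, tf2)
  expect_error(import_sbml_subset(tf2), "integer")
  expect_warning(m3 <- import_sbml_subset(tf2, round_amounts = TRUE),
                 "rounding")
  expect_equal(initial_state(m3), c(mRNA = 50L))
})

test_that("SBML export round-trips propensities, including the Hill law", {
  m <- build_fixture("tx_tl_division")$model
  f <- tempfile(fileext = ".xml")
  export_sbml_subset(m, f)
  m2 <- import_sbml_subset(f)
  st <- initial_state(m)
  set.seed(2)
  for (r in 1:5) {
    s <- pmax(st + sample(-3:10, length(st), replace = TRUE), 0)
    expect_equal(unname(propensities(m2, s)), unname(propensities(m, s)))
  }
})
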