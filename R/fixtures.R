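# Built-in case-study models. Shipped as MDL files under inst/extdata so
# they double as format examples; parameters beyond the immigration-death
# model's printed ksyn = 10 / min and kd = 0.2 / min are package-chosen
# defaults, documented in each file.

#' Built-in case-study models
#'
#' Returns one of the package's fully parameterized case-study models:
#'
#' * `"immigration_death"`: zero-order mRNA synthesis (ksyn = 10 per min)
#'   and first-order degradation (kd = 0.2 per min); stationary law
#'   Poisson(50).
#' * `"two_state_gene"`: telegraph gene with transcription only in the ON
#'   state; `parameter_set = "bursty"` (long ON/OFF lifetimes) or
#'   `"non_bursty"` (short lifetimes). The rate values are package
#'   defaults, overridable by editing the returned model's parameters.
#' * `"single_enzyme"`: E + S <-> ES -> E + P with a single enzyme copy;
#'   `variant = "clamped"` fixes the substrate (for the exact waiting-time
#'   oracle), `"consumable"` depletes it (for the product time course).
#' * `"tx_tl_division"`: nine-reaction transcription-translation network
#'   with one saturating (Hill) non-mass-action rate law, for the explicit
#'   and implicit cell-division comparisons.
#'
#' @param name Fixture name (see above).
#' @param parameter_set For `"two_state_gene"`: `"bursty"` or
#'   `"non_bursty"`.
#' @param variant For `"single_enzyme"`: `"clamped"` or `"consumable"`.
#' @return A list of class `ssa_fixture` with elements `name`, `model`,
#'   `parameters`, and `notes` describing parameter provenance.
#' @export
build_fixture <- function(name = c("immigration_death", "two_state_gene",
                                   "single_enzyme", "tx_tl_division"),
                          parameter_set = c("bursty", "non_bursty"),
                          variant = c("clamped", "consumable")) {
  name <- match.arg(name)
  file <- switch(name,
    immigration_death = "immigration_death.mdl",
    two_state_gene = switch(match.arg(parameter_set),
                            bursty = "two_state_gene_bursty.mdl",
                            non_bursty = "two_state_gene_nonbursty.mdl"),
    single_enzyme = switch(match.arg(variant),
                           clamped = "single_enzyme.mdl",
                           consumable = "single_enzyme_consumable.mdl"),
    tx_tl_division = "tx_tl_division.mdl")
  path <- system.file("extdata", file, package = "ssakit", mustWork = TRUE)
  model <- parse_mdl(path = path)
  notes <- switch(name,
    immigration_death = paste("ksyn = 10 per min and kd = 0.2 per min are",
                              "the case study's printed values"),
    two_state_gene = paste("switching and synthesis rates are package",
                           "defaults chosen to realize the bursty /",
                           "non-bursty regimes"),
    single_enzyme = "rate constants are package defaults (k1*S = 1, km1 = 0.5, k2 = 1 per min)",
    tx_tl_division = paste("structure and parameters are a package",
                           "reconstruction; one Hill-type transcription",
                           "rate is the non-mass-action reaction"))
  structure(list(name = name, model = model,
                 parameters = model$parameters, notes = notes,
                 path = path),
            class = "ssa_fixture")
}

#' @export
print.ssa_fixture <- function(x, ...) {
  cat("<ssa_fixture> ", x$name, "\n  ", x$notes, "\n", sep = "")
  print(x$model)
  invisible(x)
}

#' Phase-type waiting-time oracle for a fixture's monitored channel
#'
#' Builds the sub-generator of the transient cycle between consecutive
#' firings of the monitored channel, from which the exact waiting-time
#' density follows as a phase-type law:
#'
#' * `"single_enzyme"` (clamped substrate): transient states (E, ES) with
#'   absorption at product formation; the density is hypoexponential-like
#'   with rates k1*S, km1, k2.
#' * `"two_state_gene"`: transient states (ON, OFF) with absorption at the
#'   next mRNA synthesis; after a synthesis the gene is ON, so the initial
#'   distribution is concentrated on ON. The bursty parameter set makes
#'   the density exhibit two log-slope regimes (fast within-burst scale,
#'   slow OFF-period scale).
#'
#' @param name `"single_enzyme"` or `"two_state_gene"`.
#' @param parameter_set Passed to [build_fixture()] for the gene model.
#' @return List with `sub_generator`, `initial_distribution`, `exit_rates`,
#'   and vectorized `pdf(t)` / `cdf(t)` functions.
#' @export
fixture_waiting_time_oracle <- function(name = c("single_enzyme",
                                                 "two_state_gene"),
                                        parameter_set = "bursty") {
  name <- match.arg(name)
  if (name == "single_enzyme") {
    fx <- build_fixture("single_enzyme", variant = "clamped")
    p <- fx$parameters
    S0 <- initial_state(fx$model)[["S"]]
    k1S <- p[["k1"]] * S0
    S <- matrix(c(-k1S, k1S,
                  p[["km1"]], -(p[["km1"]] + p[["k2"]])),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("E", "ES"), c("E", "ES")))
    alpha <- c(E = 1, ES = 0)
  } else {
    fx <- build_fixture("two_state_gene", parameter_set = parameter_set)
    p <- fx$parameters
    S <- matrix(c(-(p[["koff"]] + p[["ksyn"]]), p[["koff"]],
                  p[["kon"]], -p[["kon"]]),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("ON", "OFF"), c("ON", "OFF")))
    alpha <- c(ON = 1, OFF = 0)
  }
  list(sub_generator = S, initial_distribution = alpha,
       exit_rates = -rowSums(S),
       pdf = function(t) phase_type_waiting_pdf(S, alpha, t),
       cdf = function(t) phase_type_waiting_cdf(S, alpha, t))
}
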