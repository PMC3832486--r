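# Solver front end: settings, the four simulation methods, dependency
# graph, ensembles.

#' Simulation settings
#'
#' @param end End criterion value: number of reaction events in `"steps"`
#'   mode, end time in `"time"` mode.
#' @param mode `"steps"` or `"time"`.
#' @param n_trajectories Number of trajectories for [run_ensemble()].
#' @param seed Integer seed, or `NULL` to continue from the current RNG
#'   state.
#' @param solver One of `"direct"`, `"first_reaction"`, `"next_reaction"`,
#'   `"tau_leap"`.
#' @param tau_epsilon Tau-leap error-control parameter: each propensity's
#'   expected relative change per leap is bounded by this (default 0.03).
#' @param critical_threshold Channels within this many firings of exhausting
#'   a reactant are treated as critical and simulated exactly (default 10).
#' @param max_events Safety cap on recorded rows.
#' @return A list of class `ssa_settings`.
#' @export
solver_settings <- function(end = 1000, mode = c("steps", "time"),
                            n_trajectories = 1L, seed = NULL,
                            solver = c("direct", "first_reaction",
                                       "next_reaction", "tau_leap"),
                            tau_epsilon = 0.03, critical_threshold = 10L,
                            max_events = 2e7) {
  mode <- match.arg(mode)
  solver <- match.arg(solver)
  if (!is.numeric(end) || length(end) != 1L || end <= 0)
    stop("end must be a positive number")
  if (mode == "steps" && end != round(end))
    stop("in steps mode 'end' must be an integer number of events")
  if (tau_epsilon <= 0 || tau_epsilon >= 1)
    stop("tau_epsilon must be in (0, 1)")
  if (n_trajectories < 1L) stop("n_trajectories must be >= 1")
  structure(list(end = end, mode = mode,
                 n_trajectories = as.integer(n_trajectories), seed = seed,
                 solver = solver, tau_epsilon = tau_epsilon,
                 critical_threshold = as.integer(critical_threshold),
                 max_events = max_events),
            class = "ssa_settings")
}

new_trajectory <- function(raw, model, settings, exact) {
  sn <- species_names(model); rn <- reaction_names(model)
  states <- raw$states; colnames(states) <- sn
  props <- raw$propensities; colnames(props) <- rn
  n <- length(raw$times)
  # in time mode the last row is a non-event row at exactly t_end, unless a
  # tau leap landed on t_end itself
  terminal <- settings$mode == "time" && n >= 1L && is.na(raw$fired[n]) &&
    (is.null(raw$firings) || all(is.na(raw$firings[n, ])))
  if (settings$mode == "time" && n == 1L) terminal <- FALSE
  structure(list(times = raw$times, states = states, propensities = props,
                 fired = raw$fired,
                 firings = if (!is.null(raw$firings)) {
                   f <- raw$firings; colnames(f) <- rn; f
                 },
                 absorbing = raw$absorbing, clipped = raw$clipped,
                 exact = exact, terminal = terminal,
                 end_mode = settings$mode, end_value = settings$end,
                 species = sn, reactions = rn, model = model),
            class = "ssa_trajectory")
}

#' @export
print.ssa_trajectory <- function(x, ...) {
  cat("<ssa_trajectory> ", n_events(x), " events over ",
      format(duration(x)), " time units (",
      if (x$exact) "exact" else "tau-leap", " solver",
      if (x$absorbing) ", absorbing" else "", ")\n", sep = "")
  cat("  species:   ", paste(x$species, collapse = ", "), "\n", sep = "")
  cat("  reactions: ", paste(x$reactions, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Number of reaction events recorded in a trajectory
#' @param trajectory An `ssa_trajectory`.
#' @return Integer count of event rows (the initial row and, in time mode,
#'   the terminal row are excluded).
#' @export
n_events <- function(trajectory) {
  n <- length(trajectory$times) - 1L - as.integer(isTRUE(trajectory$terminal))
  max(n, 0L)
}

#' Simulated duration of a trajectory
#' @param trajectory An `ssa_trajectory`.
#' @return Time spanned from the initial row to the last recorded row.
#' @export
duration <- function(trajectory) {
  n <- length(trajectory$times)
  if (n == 0L) return(0)
  trajectory$times[n] - trajectory$times[1L]
}

run_solver <- function(model, settings, x0 = initial_state(model)) {
  validate_model(model)
  cm <- compile_model(model)
  x0 <- as.integer(x0)
  if (any(x0 < 0)) stop("initial state must be non-negative")
  if (!is.null(settings$seed)) set.seed(settings$seed)
  steps_mode <- settings$mode == "steps"
  raw <- switch(settings$solver,
    direct = .ssa_direct(x0, cm, settings$end, steps_mode,
                         settings$max_events),
    first_reaction = .ssa_first(x0, cm, settings$end, steps_mode,
                                settings$max_events),
    next_reaction = {
      dep <- build_dependency_graph(model)
      .ssa_next(x0, cm, unname(dep), settings$end, steps_mode,
                settings$max_events)
    },
    tau_leap = .ssa_tau(x0, cm, settings$end, steps_mode,
                        settings$tau_epsilon, settings$critical_threshold,
                        settings$max_events))
  if (isTRUE(raw$clipped))
    warning("negative expression propensities were clipped to 0 during ",
            "simulation")
  new_trajectory(raw, model, settings, exact = settings$solver != "tau_leap")
}

#' Simulate with the Gillespie direct method
#'
#' Each step draws an exponential waiting time with rate equal to the total
#' propensity and picks the firing channel proportionally to its propensity.
#' The returned trajectory records, for every reaction event, the time, the
#' full copy-number state, the full propensity vector evaluated at that
#' state, and the index of the fired channel (explicit output). Row 1 holds
#' the initial condition; in time mode a terminal non-event row at exactly
#' the end time closes the occupancy interval.
#'
#' @param model An `ssa_model`.
#' @param settings An [solver_settings()] object; its `solver` field is
#'   overridden by the method called.
#' @return An `ssa_trajectory`.
#' @export
simulate_direct <- function(model, settings = solver_settings()) {
  settings$solver <- "direct"
  run_solver(model, settings)
}

#' Simulate with the first reaction method
#'
#' Draws one candidate exponential firing time per reaction channel and
#' fires the minimum; statistically equivalent to the direct method. Ties
#' (measure zero) resolve to the lowest channel index.
#'
#' @inheritParams simulate_direct
#' @return An `ssa_trajectory`.
#' @export
simulate_first_reaction <- function(model, settings = solver_settings()) {
  settings$solver <- "first_reaction"
  run_solver(model, settings)
}

#' Simulate with the Gibson-Bruck next reaction method
#'
#' Keeps absolute putative firing times in an indexed priority queue; after
#' a firing only the channels in the dependency graph are updated, and
#' non-fired affected channels rescale their pending clocks by the old/new
#' propensity ratio. Statistically equivalent to the direct method, with
#' better scaling for sparse networks.
#'
#' @inheritParams simulate_direct
#' @return An `ssa_trajectory`.
#' @export
simulate_next_reaction <- function(model, settings = solver_settings()) {
  settings$solver <- "next_reaction"
  run_solver(model, settings)
}

#' Simulate with adaptive tau-leaping
#'
#' Approximate solver: chooses each leap so that every propensity's expected
#' relative change stays below `tau_epsilon`, fires Poisson-distributed
#' reaction counts per channel per leap, treats channels close to exhausting
#' a reactant as critical (simulated exactly), and falls back to exact
#' stepping when the candidate leap is shorter than ten expected inter-event
#' times. A leap that would drive a copy number negative is rejected and
#' halved, so negative populations are impossible. Rows are leap boundaries;
#' the `firings` matrix replaces the single fired index, and the trajectory
#' is marked non-exact (waiting-time analysis refuses it).
#'
#' @inheritParams simulate_direct
#' @return An `ssa_trajectory` with `exact = FALSE`.
#' @export
simulate_tau_leap <- function(model, settings = solver_settings()) {
  settings$solver <- "tau_leap"
  run_solver(model, settings)
}

#' Simulate a model with the solver named in the settings
#'
#' @inheritParams simulate_direct
#' @return An `ssa_trajectory`.
#' @export
simulate_ssa <- function(model, settings = solver_settings()) {
  switch(settings$solver,
         direct = simulate_direct(model, settings),
         first_reaction = simulate_first_reaction(model, settings),
         next_reaction = simulate_next_reaction(model, settings),
         tau_leap = simulate_tau_leap(model, settings))
}

#' Reaction dependency graph
#'
#' For each reaction, the set of reactions whose propensity may change when
#' it fires: reaction `j` depends on `i` iff a species changed by `i` is
#' read by `j`'s rate law (reactants for mass action, every species
#' identifier in the expression otherwise). Every reaction depends on
#' itself. Used by the next reaction method.
#'
#' @param model An `ssa_model`.
#' @return Named list: for each reaction, the integer indices of affected
#'   reactions.
#' @export
build_dependency_graph <- function(model) {
  sn <- species_names(model)
  nu <- stoichiometry(model)
  reads <- lapply(model$reactions, function(r) {
    if (r$law$type == "mass_action") names(r$reactants)
    else intersect(expr_identifiers(r$law$expr), sn)
  })
  nrx <- length(model$reactions)
  out <- vector("list", nrx)
  for (i in seq_len(nrx)) {
    changed <- sn[nu[, i] != 0L]
    aff <- which(vapply(reads, function(rs) length(intersect(rs, changed)) > 0L,
                        FALSE))
    out[[i]] <- sort(unique(c(i, aff)))
  }
  names(out) <- reaction_names(model)
  out
}

#' Run an ensemble of independent trajectories
#'
#' Trajectory `k` uses an independent stream derived from `(seed, k)`:
#' sub-seeds are drawn once from the master seed, so ensembles are
#' reproducible and trajectories exchangeable, and no two indices share a
#' stream.
#'
#' @param model An `ssa_model`.
#' @param settings An [solver_settings()]; `n_trajectories` and `seed` are
#'   taken from it.
#' @return A list of `ssa_trajectory` objects of class `ssa_ensemble`.
#' @export
run_ensemble <- function(model, settings = solver_settings()) {
  n <- settings$n_trajectories
  if (!is.null(settings$seed)) set.seed(settings$seed)
  sub <- sample.int(2147483646L, n)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    sk <- settings
    sk$seed <- sub[[k]]
    sk$n_trajectories <- 1L
    out[[k]] <- simulate_ssa(model, sk)
  }
  structure(out, class = "ssa_ensemble", sub_seeds = sub)
}
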