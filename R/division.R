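# Cell-division modeling: explicit sequential simulation with gamma
# interdivision times and binomial partitioning, and the implicit
# alternative of first-order dilution.

#' Cell-division settings
#'
#' @param shape,scale Gamma distribution of interdivision times, in
#'   minutes; defaults shape 1.0 (memoryless divisions) and scale 60.0
#'   (mean generation time 60 min).
#' @param partition_probability Probability that a molecule goes to the
#'   tracked daughter at division (default 0.5).
#' @param end_generations,end_time Exactly one end criterion: number of
#'   completed divisions, or total simulated time.
#' @param fixed_interval If `TRUE`, use a deterministic generation time of
#'   `shape * scale` (the gamma mean) instead of gamma draws.
#' @param deterministic_halving If `TRUE`, split copy numbers in half
#'   deterministically instead of binomially, alternating floor/ceil for
#'   odd counts across successive divisions.
#' @return A list of class `ssa_division_settings`.
#' @export
division_settings <- function(shape = 1.0, scale = 60.0,
                              partition_probability = 0.5,
                              end_generations = NULL, end_time = NULL,
                              fixed_interval = FALSE,
                              deterministic_halving = FALSE) {
  if (shape <= 0 || scale <= 0) stop("shape and scale must be positive")
  if (partition_probability <= 0 || partition_probability >= 1)
    stop("partition_probability must be in (0, 1)")
  if (is.null(end_generations) == is.null(end_time))
    stop("set exactly one of end_generations or end_time")
  structure(list(shape = shape, scale = scale,
                 partition_probability = partition_probability,
                 end_generations = end_generations, end_time = end_time,
                 fixed_interval = isTRUE(fixed_interval),
                 deterministic_halving = isTRUE(deterministic_halving)),
            class = "ssa_division_settings")
}

#' Sample one interdivision interval
#'
#' A gamma draw with the settings' shape and scale (shape 1 makes the
#' division process memoryless, i.e. exponential intervals), or the fixed
#' mean interval when `fixed_interval` is set. Uses the current RNG state,
#' so draws are reproducible under `set.seed()`.
#'
#' @param settings An [division_settings()] object.
#' @return A single positive time.
#' @export
sample_division_interval <- function(settings) {
  if (settings$fixed_interval) return(settings$shape * settings$scale)
  stats::rgamma(1L, shape = settings$shape, scale = settings$scale)
}

#' Binomially partition a state over two daughters
#'
#' Each partitioned species with `n` copies sends `Binomial(n, p)` copies
#' to the tracked daughter and the rest to the discarded daughter, so
#' `daughter + discarded = mother` exactly. Species flagged
#' `partition = FALSE` (gene-like) are kept whole by the tracked daughter,
#' and fixed species are copied unchanged to both records. With
#' `deterministic_halving`, counts are split in half, odd copies
#' alternating between daughters across divisions (`division_index` parity).
#'
#' @param state Named non-negative integer vector of copy numbers.
#' @param settings An [division_settings()] object.
#' @param partition Logical vector (recycled) marking which species are
#'   partitioned; default all.
#' @param fixed Logical vector marking buffered species copied to both
#'   daughters.
#' @param division_index Integer used only for the floor/ceil alternation
#'   of deterministic halving.
#' @return List with `daughter` and `discarded` integer vectors.
#' @export
binomial_partition <- function(state, settings,
                               partition = rep(TRUE, length(state)),
                               fixed = rep(FALSE, length(state)),
                               division_index = 0L) {
  if (any(state < 0) || any(state != round(state)))
    stop("state must be non-negative integers")
  n <- as.integer(round(state))
  partition <- rep_len(partition, length(n)) & !rep_len(fixed, length(n))
  daughter <- n
  discarded <- integer(length(n))
  if (any(partition)) {
    if (settings$deterministic_halving) {
      half <- n[partition] %/% 2L
      odd <- n[partition] %% 2L
      extra <- if (division_index %% 2L == 0L) odd else 0L * odd
      daughter[partition] <- half + extra
    } else {
      daughter[partition] <- stats::rbinom(sum(partition), n[partition],
                                           settings$partition_probability)
    }
    discarded[partition] <- n[partition] - daughter[partition]
  }
  discarded[rep_len(fixed, length(n))] <- n[rep_len(fixed, length(n))]
  names(daughter) <- names(discarded) <- names(state)
  list(daughter = daughter, discarded = discarded)
}

#' Simulate a single-cell lineage with explicit divisions
#'
#' Sequential simulation: the network is run with an exact solver until the
#' next sampled division time, the state is partitioned between two
#' daughters, and simulation continues with the tracked daughter. The time
#' axis is global (continuous across divisions). Interrupting the SSA
#' mid-waiting-time is exact for the direct method because exponential
#' clocks are memoryless; propensities are re-drawn from the post-partition
#' state.
#'
#' @param model An `ssa_model`.
#' @param solver_settings An [solver_settings()]; must name an exact solver.
#'   Its `seed` initializes the single RNG stream of the whole lineage; its
#'   end criterion is ignored (the division settings end the run).
#' @param division_settings An [division_settings()] object.
#' @return A list of class `ssa_lineage`: `segments` (one `ssa_trajectory`
#'   per generation, times global), `division_times`, and
#'   `partition_records` (per division: `time`, `pre`, `daughter`,
#'   `discarded`).
#' @export
simulate_with_divisions <- function(model, solver_settings,
                                    division_settings) {
  if (solver_settings$solver == "tau_leap")
    stop("explicit divisions require an exact solver")
  ds <- division_settings
  if (!is.null(solver_settings$seed)) set.seed(solver_settings$seed)
  x <- initial_state(model)
  fixed <- vapply(model$species, `[[`, FALSE, "fixed")
  part <- vapply(model$species, `[[`, TRUE, "partition")
  t_now <- 0
  segments <- list(); division_times <- numeric(0); records <- list()
  gen <- 0L
  repeat {
    interval <- sample_division_interval(ds)
    seg_end <- if (!is.null(ds$end_time)) min(interval, ds$end_time - t_now)
               else interval
    divide <- is.null(ds$end_time) || t_now + interval <= ds$end_time
    ss <- solver_settings
    ss$mode <- "time"; ss$end <- seg_end; ss$seed <- NULL
    seg <- run_solver(model, ss, x0 = x)
    seg$times <- seg$times + t_now
    segments[[length(segments) + 1L]] <- seg
    x_end <- seg$states[nrow(seg$states), ]
    t_now <- t_now + seg_end
    if (!divide) break
    split <- binomial_partition(x_end, ds, partition = part, fixed = fixed,
                                division_index = gen)
    division_times <- c(division_times, t_now)
    records[[length(records) + 1L]] <-
      list(time = t_now, pre = x_end, daughter = split$daughter,
           discarded = split$discarded)
    x <- split$daughter
    gen <- gen + 1L
    if (!is.null(ds$end_generations) && gen >= ds$end_generations) break
    if (!is.null(ds$end_time) && t_now >= ds$end_time) break
  }
  structure(list(segments = segments, division_times = division_times,
                 partition_records = records, model = model),
            class = "ssa_lineage")
}

#' @export
print.ssa_lineage <- function(x, ...) {
  cat("<ssa_lineage> ", length(x$segments), " generations, ",
      length(x$division_times), " divisions, total time ",
      format(x$segments[[length(x$segments)]]$times[
        length(x$segments[[length(x$segments)]]$times)]), "\n", sep = "")
  invisible(x)
}

#' Per-generation time-weighted species means of a lineage
#'
#' @param lineage An `ssa_lineage`.
#' @param species Species name or index.
#' @return Numeric vector, one holding-time-weighted mean per generation
#'   segment.
#' @export
lineage_generation_means <- function(lineage, species) {
  vapply(lineage$segments, function(seg) {
    d <- species_distribution(seg, species)
    distribution_mean(d)
  }, 0)
}

#' Add implicit dilution reactions to a model
#'
#' Implicit cell-division modeling: growth is incorporated as a first-order
#' rate constant that continuously dilutes cellular components. One
#' first-order degradation reaction with rate `growth_rate` is appended per
#' dilutable species (non-fixed species with the partition flag on, unless
#' `species` is given); the original model is untouched.
#'
#' @param model An `ssa_model`.
#' @param growth_rate Dilution rate constant, per minute (> 0); for a mean
#'   generation time `T` use `log(2) / T`.
#' @param species Optional character vector restricting which species are
#'   diluted.
#' @return A new `ssa_model` with the added `dilution_<species>` reactions.
#' @export
add_dilution <- function(model, growth_rate, species = NULL) {
  if (!is.numeric(growth_rate) || length(growth_rate) != 1L ||
      growth_rate <= 0)
    stop("growth_rate must be a positive number")
  sn <- species_names(model)
  if (is.null(species)) {
    keep <- vapply(model$species, function(s) !s$fixed && s$partition, FALSE)
    species <- sn[keep]
  } else {
    bad <- setdiff(species, sn)
    if (length(bad)) stop("unknown species: ", paste(bad, collapse = ", "))
  }
  rn <- reaction_names(model)
  for (sp in species) {
    nm <- paste0("dilution_", sp)
    if (nm %in% rn)
      stop("reaction name collision: '", nm, "' already exists")
    model$reactions[[length(model$reactions) + 1L]] <-
      ssa_reaction(nm, reactants = stats::setNames(1L, sp), products = NULL,
                   rate = growth_rate)
  }
  validate_model(model)
  model
}
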