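# Statistics on explicit-output trajectories: event waiting times,
# holding-time weighted distributions, moments, autocorrelation, and
# fixed-interval regridding.

resolve_species <- function(trajectory, species) {
  i <- if (is.character(species)) match(species, trajectory$species)
       else as.integer(species)
  if (is.na(i) || i < 1L || i > length(trajectory$species))
    stop("unknown species: ", species)
  i
}

resolve_channel <- function(trajectory, channel) {
  j <- if (is.character(channel)) match(channel, trajectory$reactions)
       else as.integer(channel)
  if (is.na(j) || j < 1L || j > length(trajectory$reactions))
    stop("unknown reaction channel: ", channel)
  j
}

# weight of each row's holding interval, clipped to the post-burn-in window;
# returns length(times) - 1 weights (the last recorded row has no interval)
holding_weights <- function(trajectory, burn_in = 0) {
  t <- trajectory$times
  n <- length(t)
  if (n < 2L) stop("trajectory has no elapsed time")
  if (burn_in < 0 || burn_in >= 1) stop("burn_in must be in [0, 1)")
  t0 <- t[1L]; tend <- t[n]
  if (tend <= t0) stop("zero-duration trajectory")
  tburn <- t0 + burn_in * (tend - t0)
  w <- pmax(0, pmin(t[-1L], tend) - pmax(t[-n], tburn))
  if (sum(w) <= 0) stop("no time retained after burn-in")
  w
}

new_distribution <- function(support, probability, label) {
  o <- order(support)
  structure(list(support = support[o],
                 probability = as.numeric(probability[o] / sum(probability)),
                 label = label),
            class = "ssa_distribution")
}

#' @export
print.ssa_distribution <- function(x, ...) {
  cat("<ssa_distribution> ", x$label, ": ", length(x$support),
      " support points, mean ", format(distribution_mean(x)), "\n", sep = "")
  invisible(x)
}

#' Mean of a discrete distribution object
#' @param dist An `ssa_distribution`.
#' @return `sum(support * probability)`.
#' @export
distribution_mean <- function(dist) sum(dist$support * dist$probability)

#' Variance of a discrete distribution object
#' @param dist An `ssa_distribution`.
#' @return Second central moment.
#' @export
distribution_var <- function(dist) {
  m <- distribution_mean(dist)
  sum(dist$probability * (dist$support - m)^2)
}

#' Total-variation distance between two discrete distributions
#'
#' @param a,b `ssa_distribution` objects (or lists with `support` and
#'   `probability`).
#' @return `0.5 * sum |p_a - p_b|` over the union support.
#' @export
tv_distance <- function(a, b) {
  supp <- sort(union(a$support, b$support))
  pa <- pb <- numeric(length(supp))
  pa[match(a$support, supp)] <- a$probability
  pb[match(b$support, supp)] <- b$probability
  0.5 * sum(abs(pa - pb))
}

#' Event waiting times of a reaction channel
#'
#' The intervals between consecutive firings of one channel. The span from
#' the trajectory start to the channel's first firing is excluded: no
#' preceding event of that channel exists.
#'
#' @param trajectory An exact-solver `ssa_trajectory` (tau-leap trajectories
#'   are rejected: waiting times are undefined for aggregated leaps).
#' @param channel Reaction name or index.
#' @return Numeric vector of positive intervals (empty if the channel fired
#'   fewer than twice).
#' @export
event_waiting_times <- function(trajectory, channel) {
  if (!isTRUE(trajectory$exact))
    stop("waiting times are undefined for tau-leap trajectories ",
         "(events are aggregated within leaps); use an exact solver")
  j <- resolve_channel(trajectory, channel)
  ft <- trajectory$times[!is.na(trajectory$fired) & trajectory$fired == j]
  diff(ft)
}

#' Waiting times for every channel
#'
#' @param trajectory An exact-solver `ssa_trajectory`.
#' @return Named list of interval vectors, one per reaction channel.
#' @export
waiting_time_set <- function(trajectory) {
  out <- lapply(seq_along(trajectory$reactions),
                function(j) event_waiting_times(trajectory, j))
  names(out) <- trajectory$reactions
  out
}

#' Holding-time weighted copy-number distribution
#'
#' Stationary estimate of a species' distribution over the observed
#' interval: each visited value is weighted by the total time the process
#' held it, which is the estimator consistent with the master equation's
#' stationary measure (not per-event weighting).
#'
#' @param trajectory An `ssa_trajectory` with at least one event.
#' @param species Species name or index.
#' @param burn_in Fraction of the simulated time span to drop from the
#'   start (default 0; set explicitly for stationary analyses).
#' @return An `ssa_distribution` (support, probability).
#' @export
species_distribution <- function(trajectory, species, burn_in = 0) {
  i <- resolve_species(trajectory, species)
  w <- holding_weights(trajectory, burn_in)
  v <- trajectory$states[-length(trajectory$times), i]
  agg <- rowsum(w, group = v)
  new_distribution(as.numeric(rownames(agg)), agg[, 1L],
                   paste0("species ", trajectory$species[i]))
}

#' Holding-time weighted propensity distribution
#'
#' The distribution of one channel's propensity value over time. For a
#' first-order channel this is the species distribution with its support
#' scaled by the rate constant.
#'
#' @inheritParams species_distribution
#' @param channel Reaction name or index.
#' @return An `ssa_distribution`.
#' @export
propensity_distribution <- function(trajectory, channel, burn_in = 0) {
  j <- resolve_channel(trajectory, channel)
  w <- holding_weights(trajectory, burn_in)
  v <- trajectory$propensities[-length(trajectory$times), j]
  agg <- rowsum(w, group = v)
  new_distribution(as.numeric(rownames(agg)), agg[, 1L],
                   paste0("propensity ", trajectory$reactions[j]))
}

#' Time-weighted moments of species copy numbers
#'
#' Holding-time weighted mean, standard deviation and Fano factor
#' (variance/mean; 1 for a Poisson law) per species. The Fano factor is
#' flagged `NA` when the mean is zero.
#'
#' @param trajectory An `ssa_trajectory`.
#' @param species Species names or indices (default: all).
#' @param burn_in Fraction of simulated time dropped from the start.
#' @return `data.frame` with columns `species`, `mean`, `sd`, `fano`.
#' @export
moments <- function(trajectory, species = NULL, burn_in = 0) {
  if (is.null(species)) species <- trajectory$species
  rows <- lapply(species, function(sp) {
    d <- species_distribution(trajectory, sp, burn_in)
    m <- distribution_mean(d)
    v <- distribution_var(d)
    data.frame(species = trajectory$species[resolve_species(trajectory, sp)],
               mean = m, sd = sqrt(v),
               fano = if (m > 0) v / m else NA_real_)
  })
  do.call(rbind, rows)
}

#' Autocorrelation of a species time series
#'
#' The piecewise-constant trajectory is resampled onto a uniform grid by
#' zero-order hold and the normalized autocorrelation is evaluated at the
#' requested physical-time lags (rounded to whole grid steps). `acf` at lag
#' 0 is exactly 1.
#'
#' @param trajectory An `ssa_trajectory`.
#' @param species Species name or index.
#' @param lags Numeric vector of lags, in simulation time units.
#' @param grid_dt Resampling interval; defaults to the mean inter-event
#'   time.
#' @return `data.frame` with columns `lag` (requested), `lag_used` (grid
#'   multiple) and `acf`.
#' @export
autocorrelation <- function(trajectory, species, lags, grid_dt = NULL) {
  i <- resolve_species(trajectory, species)
  dur <- duration(trajectory)
  if (any(lags < 0)) stop("lags must be non-negative")
  if (max(lags) > dur) stop("lag exceeds the trajectory duration")
  if (dur < 10 * max(lags))
    warning("trajectory shorter than 10x the largest lag; ",
            "autocorrelation estimates will be noisy")
  if (is.null(grid_dt)) {
    ne <- max(n_events(trajectory), 1L)
    grid_dt <- dur / ne
  }
  if (grid_dt <= 0) stop("grid_dt must be positive")
  t0 <- trajectory$times[1L]
  grid <- seq(t0, t0 + dur, by = grid_dt)
  x <- trajectory$states[findInterval(grid, trajectory$times), i]
  n <- length(x)
  xm <- mean(x)
  xc <- x - xm
  c0 <- mean(xc^2)
  if (c0 == 0) stop("constant series has no autocorrelation")
  ls <- as.integer(round(lags / grid_dt))
  r <- vapply(ls, function(l) {
    if (l == 0L) return(1)
    if (l >= n) return(NA_real_)
    sum(xc[1:(n - l)] * xc[(1 + l):n]) / (n * c0)
  }, 0)
  data.frame(lag = lags, lag_used = ls * grid_dt, acf = r)
}

#' Resample a trajectory onto a fixed-interval grid
#'
#' Samples the state at `n_intervals` equally spaced times spanning the
#' simulated interval, each sample being the state after the last event at
#' or before the sample time (zero-order hold). This reproduces what
#' fixed-interval simulators store, and is deliberately lossy compared to
#' the explicit output.
#'
#' @param trajectory An `ssa_trajectory`.
#' @param n_intervals Number of sample points (>= 2).
#' @return A list of class `ssa_grid` with `times` and a `states` matrix.
#' @export
regrid_fixed_interval <- function(trajectory, n_intervals) {
  if (length(trajectory$times) < 1L) stop("empty trajectory")
  if (n_intervals < 2L) stop("n_intervals must be >= 2")
  t0 <- trajectory$times[1L]
  tend <- trajectory$times[length(trajectory$times)]
  if (tend <= t0) stop("zero-duration trajectory")
  st <- seq(t0, tend, length.out = n_intervals)
  idx <- findInterval(st, trajectory$times)
  states <- trajectory$states[idx, , drop = FALSE]
  structure(list(times = st, states = states, species = trajectory$species),
            class = "ssa_grid")
}

#' Copy-number distribution of a gridded series
#'
#' Empirical distribution over equally weighted grid samples, comparable to
#' [species_distribution()] on the explicit output.
#'
#' @param grid An `ssa_grid` from [regrid_fixed_interval()].
#' @param species Species name or index.
#' @param burn_in Fraction of samples dropped from the start.
#' @return An `ssa_distribution`.
#' @export
grid_distribution <- function(grid, species, burn_in = 0) {
  i <- if (is.character(species)) match(species, grid$species)
       else as.integer(species)
  if (is.na(i)) stop("unknown species: ", species)
  v <- grid$states[, i]
  if (burn_in > 0) v <- v[-seq_len(floor(burn_in * length(v)))]
  tb <- table(v)
  new_distribution(as.numeric(names(tb)), as.numeric(tb),
                   paste0("gridded ", grid$species[i]))
}

#' Ensemble mean and spread on a common grid
#'
#' Each trajectory is regridded by zero-order hold onto a shared time grid,
#' then the pointwise mean and standard deviation across the ensemble are
#' returned.
#'
#' @param ensemble A list of `ssa_trajectory` objects over the same model
#'   (at least 2).
#' @param species Species name or index.
#' @param grid Either a numeric vector of sample times or a single integer
#'   number of equally spaced points spanning the shortest trajectory.
#' @return `data.frame` with columns `time`, `mean`, `sd`.
#' @export
average_trajectories <- function(ensemble, species, grid = 101L) {
  if (length(ensemble) < 2L) stop("need at least 2 trajectories")
  sp0 <- ensemble[[1L]]$species
  if (!all(vapply(ensemble, function(tr) identical(tr$species, sp0), FALSE)))
    stop("trajectories come from inconsistent models")
  i <- resolve_species(ensemble[[1L]], species)
  if (length(grid) == 1L) {
    tmax <- min(vapply(ensemble,
                       function(tr) tr$times[length(tr$times)], 0))
    t0 <- max(vapply(ensemble, function(tr) tr$times[1L], 0))
    grid <- seq(t0, tmax, length.out = as.integer(grid))
  }
  X <- vapply(ensemble, function(tr)
    tr$states[findInterval(grid, tr$times), i], numeric(length(grid)))
  data.frame(time = grid, mean = rowMeans(X),
             sd = apply(X, 1L, stats::sd))
}

#' Binned waiting-time density
#'
#' Normalized histogram density of inter-event intervals, with linear or
#' logarithmic bin edges (log bins resolve two-timescale distributions).
#'
#' @param intervals Numeric vector of positive intervals, e.g. from
#'   [event_waiting_times()].
#' @param bins `"linear"` or `"log"`.
#' @param n_bins Number of bins.
#' @return `data.frame` with columns `left`, `right`, `mid`, `count`,
#'   `density`; the densities integrate to 1 over the binned range.
#' @export
waiting_time_pdf <- function(intervals, bins = c("linear", "log"),
                             n_bins = 30L) {
  bins <- match.arg(bins)
  if (length(intervals) == 0L) stop("empty interval list")
  if (length(intervals) < 10L)
    warning("fewer than 10 intervals; density estimate will be crude")
  if (any(intervals <= 0)) stop("intervals must be positive")
  if (bins == "linear") {
    breaks <- seq(0, max(intervals), length.out = n_bins + 1L)
  } else {
    breaks <- exp(seq(log(min(intervals)), log(max(intervals)),
                      length.out = n_bins + 1L))
    breaks[1L] <- breaks[1L] * (1 - 1e-12)
  }
  cnt <- as.numeric(table(cut(intervals, breaks, include.lowest = TRUE)))
  width <- diff(breaks)
  data.frame(left = breaks[-length(breaks)], right = breaks[-1L],
             mid = (breaks[-length(breaks)] + breaks[-1L]) / 2,
             count = cnt,
             density = cnt / (sum(cnt) * width))
}
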