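# Independent numeric oracles: truncated chemical master equation
# stationary distributions, Poisson and exponential closed forms, and
# phase-type waiting-time densities.

#' Stationary distribution of the truncated master equation
#'
#' Enumerates the states reachable from the model's initial condition with
#' every (non-fixed) species capped, assembles the sparse generator `Q`
#' (`Q[s, s']` the propensity of the reaction taking `s` to `s'`, diagonal
#' the negative row sum, transitions leaving the truncated box dropped),
#' and solves for the stationary distribution as the normalized null vector
#' of `t(Q)` by sparse linear algebra.
#'
#' The probability mass sitting on states with at least one dropped
#' outgoing transition is reported as `boundary_mass`; a valid truncation
#' keeps it below `1e-6` (a warning is raised above that, an error above
#' `1e-4`).
#'
#' @param model An `ssa_model`.
#' @param caps Per-species cap on copy numbers: a single integer or a named
#'   vector over the non-fixed species.
#' @param max_states Guard on the enumerated state-space size (default
#'   `1e6`).
#' @return A list of class `ssa_cme`: `states` (matrix, one row per
#'   reachable state), `probability`, `boundary_mass`, and the species
#'   names.
#' @export
cme_stationary <- function(model, caps, max_states = 1e6) {
  validate_model(model)
  sn <- species_names(model)
  fixed <- vapply(model$species, `[[`, FALSE, "fixed")
  free <- which(!fixed)
  if (length(free) == 0L) stop("model has no non-fixed species")
  if (length(caps) == 1L && is.null(names(caps)))
    caps <- stats::setNames(rep(caps, length(free)), sn[free])
  if (!all(sn[free] %in% names(caps)))
    stop("caps must name every non-fixed species")
  caps <- as.integer(caps[sn[free]])
  radix <- cumprod(c(1, caps[-length(caps)] + 1))
  encode <- function(S) as.vector(S %*% radix)  # S: rows = free coords
  x0 <- initial_state(model)
  if (any(x0[free] > caps)) stop("initial state exceeds caps")
  nu <- stoichiometry(model)[free, , drop = FALSE]
  nrx <- length(model$reactions)

  # breadth-first enumeration of the reachable truncated space
  known <- new.env(hash = TRUE, size = 2^16)
  frontier <- matrix(x0[free], nrow = 1L)
  states <- frontier
  assign(as.character(encode(frontier)), 1L, envir = known)
  while (nrow(frontier) > 0L) {
    nxt <- NULL
    full <- matrix(rep(x0, each = nrow(frontier)), nrow = nrow(frontier))
    full[, free] <- frontier
    colnames(full) <- sn
    A <- propensities(model, full)
    if (is.null(dim(A))) A <- matrix(A, nrow = 1L)
    for (j in seq_len(nrx)) {
      act <- which(A[, j] > 0)
      if (!length(act)) next
      tgt <- frontier[act, , drop = FALSE] +
        matrix(nu[, j], nrow = length(act), ncol = length(free), byrow = TRUE)
      ok <- rowSums(tgt < 0L | tgt > matrix(caps, nrow(tgt), length(caps),
                                            byrow = TRUE)) == 0L
      tgt <- tgt[ok, , drop = FALSE]
      if (!nrow(tgt)) next
      keys <- as.character(encode(tgt))
      new <- !vapply(keys, exists, FALSE, envir = known, inherits = FALSE)
      if (any(new)) {
        tgt <- unique(tgt[new, , drop = FALSE])
        keys <- as.character(encode(tgt))
        for (k in seq_along(keys)) {
          assign(keys[k], nrow(states) + k, envir = known)
        }
        states <- rbind(states, tgt)
        nxt <- rbind(nxt, tgt)
        if (nrow(states) > max_states)
          stop("truncated state space exceeds max_states = ", max_states)
      }
    }
    frontier <- if (is.null(nxt)) matrix(0L, 0L, length(free)) else nxt
  }

  ns <- nrow(states)
  idx_of <- function(S) {
    vapply(as.character(encode(S)), function(k)
      get(k, envir = known, inherits = FALSE), 0L)
  }
  full <- matrix(rep(x0, each = ns), nrow = ns)
  full[, free] <- states
  colnames(full) <- sn
  A <- propensities(model, full)
  if (is.null(dim(A))) A <- matrix(A, nrow = 1L)
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  leaky <- logical(ns)
  for (j in seq_len(nrx)) {
    act <- which(A[, j] > 0)
    if (!length(act)) next
    tgt <- states[act, , drop = FALSE] +
      matrix(nu[, j], nrow = length(act), ncol = length(free), byrow = TRUE)
    ok <- rowSums(tgt < 0L | tgt > matrix(caps, nrow(tgt), length(caps),
                                          byrow = TRUE)) == 0L
    leaky[act[!ok]] <- TRUE
    if (!any(ok)) next
    to <- idx_of(tgt[ok, , drop = FALSE])
    ii <- c(ii, act[ok]); jj <- c(jj, to); vv <- c(vv, A[act[ok], j])
  }
  Q <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(ns, ns))
  Matrix::diag(Q) <- Matrix::diag(Q) - Matrix::rowSums(Q)

  # stationary: solve t(Q) p = 0 with the normalization replacing one row
  M <- Matrix::t(Q)
  M[ns, ] <- 1
  b <- c(rep(0, ns - 1L), 1)
  p <- as.numeric(Matrix::solve(M, b))
  p[p < 0 & p > -1e-12] <- 0
  if (any(p < 0)) stop("stationary solve produced negative probabilities")
  p <- p / sum(p)
  boundary <- sum(p[leaky])
  if (boundary > 1e-4)
    stop("probability mass at the truncation boundary is ",
         format(boundary), "; increase caps")
  if (boundary > 1e-6)
    warning("probability mass at the truncation boundary is ",
            format(boundary))
  structure(list(states = full, probability = p, boundary_mass = boundary,
                 species = sn, free_species = sn[free]),
            class = "ssa_cme")
}

#' @export
print.ssa_cme <- function(x, ...) {
  cat("<ssa_cme> ", nrow(x$states), " states over (",
      paste(x$free_species, collapse = ", "), "), boundary mass ",
      format(x$boundary_mass), "\n", sep = "")
  invisible(x)
}

#' Marginal species distribution of a CME solution
#'
#' @param cme An `ssa_cme` from [cme_stationary()].
#' @param species Species name.
#' @return An `ssa_distribution` over that species' copy numbers.
#' @export
cme_marginal <- function(cme, species) {
  i <- match(species, cme$species)
  if (is.na(i)) stop("unknown species: ", species)
  agg <- rowsum(cme$probability, group = cme$states[, i])
  new_distribution(as.numeric(rownames(agg)), agg[, 1L],
                   paste0("CME marginal ", species))
}

#' Mean copy number of a species under a CME solution
#' @inheritParams cme_marginal
#' @return The stationary mean.
#' @export
cme_mean <- function(cme, species) distribution_mean(cme_marginal(cme, species))

#' Poisson reference distribution
#'
#' @param mean Positive Poisson mean.
#' @param support Integer support (e.g. `0:200`).
#' @param normalized If `TRUE`, renormalize over the finite support;
#'   otherwise the probabilities sum to less than 1.
#' @return An `ssa_distribution`.
#' @export
analytic_poisson <- function(mean, support, normalized = FALSE) {
  if (mean <= 0) stop("mean must be positive")
  p <- stats::dpois(support, mean)
  if (!normalized) {
    d <- structure(list(support = support, probability = p,
                        label = sprintf("Poisson(%g)", mean)),
                   class = "ssa_distribution")
    return(d)
  }
  new_distribution(support, p, sprintf("Poisson(%g) renormalized", mean))
}

#' Analytic autocorrelation of the linear birth-death process
#'
#' For the immigration-death model the stationary autocorrelation decays
#' exponentially with the degradation rate constant: `exp(-kd * lag)`.
#'
#' @param kd Positive degradation rate constant.
#' @param lag Non-negative lag (vectorized).
#' @return Correlation value(s) in (0, 1].
#' @export
analytic_acf <- function(kd, lag) {
  if (kd <= 0) stop("kd must be positive")
  exp(-kd * lag)
}

phase_type_decompose <- function(sub_generator, initial_distribution) {
  S <- as.matrix(sub_generator)
  if (nrow(S) != ncol(S)) stop("sub_generator must be square")
  alpha <- as.numeric(initial_distribution)
  if (length(alpha) != nrow(S)) stop("initial_distribution length mismatch")
  if (abs(sum(alpha) - 1) > 1e-10 || any(alpha < 0))
    stop("initial_distribution must be a probability vector")
  exit <- -rowSums(S)
  offd <- S; diag(offd) <- 0
  if (any(exit < -1e-10) || any(offd < -1e-12))
    stop("non-conservative sub-generator: off-diagonals must be >= 0 and ",
         "row sums <= 0")
  exit <- pmax(exit, 0)
  E <- eigen(S)
  V <- E$vectors
  w <- as.vector(alpha %*% V)
  list(S = S, alpha = alpha, exit = exit, values = E$values, V = V, w = w,
       u_pdf = as.vector(solve(V, exit)),
       u_cdf = as.vector(solve(V, rep(1, nrow(S)))))
}

#' Phase-type waiting-time density
#'
#' Exact density of the absorption time of a transient Markov chain:
#' `f(t) = alpha %*% expm(t * S) %*% exit`, with `exit = -S %*% 1`,
#' evaluated on a grid via the eigendecomposition of the sub-generator.
#' This is the natural oracle for inter-event waiting times: `S` is the
#' generator restricted to the transient states of the cycle between
#' consecutive firings of the monitored channel.
#'
#' @param sub_generator Square matrix with non-negative off-diagonals and
#'   non-positive row sums.
#' @param initial_distribution Probability vector over transient states.
#' @param t_grid Non-negative times (vectorized).
#' @return Density values on `t_grid`; integrates to 1 over `[0, Inf)` for
#'   a conservative construction.
#' @export
phase_type_waiting_pdf <- function(sub_generator, initial_distribution,
                                   t_grid) {
  d <- phase_type_decompose(sub_generator, initial_distribution)
  f <- vapply(t_grid, function(t)
    Re(sum(d$w * exp(d$values * t) * d$u_pdf)), 0)
  pmax(f, 0)
}

#' Phase-type waiting-time distribution function
#'
#' `F(t) = 1 - alpha %*% expm(t * S) %*% 1`; the companion of
#' [phase_type_waiting_pdf()], usable directly in
#' `ks.test(x, phase_type_waiting_cdf, sub_generator, alpha)` style calls.
#'
#' @inheritParams phase_type_waiting_pdf
#' @return Cumulative probabilities on `t_grid`.
#' @export
phase_type_waiting_cdf <- function(sub_generator, initial_distribution,
                                   t_grid) {
  d <- phase_type_decompose(sub_generator, initial_distribution)
  F <- vapply(t_grid, function(t)
    1 - Re(sum(d$w * exp(d$values * t) * d$u_cdf)), 0)
  pmin(pmax(F, 0), 1)
}
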