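## Committor analysis on explicit 1-D model potentials with Langevin
## (BAOAB) shooting: the desk-scale analogue of validating a putative
## transition state by counting which basin unbiased trajectories reach.

#' Define a 1-D model potential with reactant/product basins
#'
#' `double_well` is `V(x) = h ((x/w)^2 - 1)^2` (kcal/mol): minima at
#' `x = -w` (reactant) and `x = +w` (product), barrier `h` at `x = 0`.
#' Basins default to the minima: reactant `x <= -w`, product `x >= w`.
#' `tabulated` interpolates a user table with splines.
#'
#' @param form `"double_well"` or `"tabulated"`.
#' @param barrier_height `h`, kcal/mol (double well).
#' @param half_separation `w`, Angstrom (double well).
#' @param table data.frame `x`, `energy` for `"tabulated"`.
#' @param basins length-2 numeric `c(a, b)`, reactant region `x <= a`,
#'   product region `x >= b`, `a < b`.
#' @return Object of class `model_potential` with closures `V(x)` and
#'   `dVdx(x)` and the basin bounds.
#' @export
model_potential <- function(form = c("double_well", "tabulated"),
                            barrier_height = 5, half_separation = 1,
                            table = NULL, basins = NULL) {
  form <- match.arg(form)
  if (form == "double_well") {
    h <- barrier_height; w <- half_separation
    stopifnot(h > 0, w > 0)
    V <- function(x) h * ((x / w)^2 - 1)^2
    dVdx <- function(x) 4 * h * x * ((x / w)^2 - 1) / w^2
    if (is.null(basins)) basins <- c(-w, w)
  } else {
    stopifnot(!is.null(table), all(c("x", "energy") %in% names(table)),
              !is.null(basins))
    sf <- stats::splinefun(table$x, table$energy, method = "natural")
    V <- function(x) sf(x)
    dVdx <- function(x) sf(x, deriv = 1)
  }
  if (basins[1] >= basins[2]) stop("basins must satisfy a < b")
  if (!all(is.finite(V(seq(basins[1], basins[2], length.out = 101)))))
    stop("potential not finite on [a, b]")
  structure(list(form = form, V = V, dVdx = dVdx,
                 basins = basins,
                 barrier_height = if (form == "double_well") barrier_height else NA,
                 half_separation = if (form == "double_well") half_separation else NA),
            class = "model_potential")
}

#' Default Langevin dynamics parameters for committor shooting
#'
#' @param temperature K.
#' @param friction ps^-1.
#' @param timestep ps.
#' @param max_steps step cap per shot; shots hitting it are timeouts.
#' @param mass amu of the fictitious 1-D particle.
#' @return Named list.
#' @export
langevin_dynamics <- function(temperature = 343.15, friction = 10,
                              timestep = 1e-3, max_steps = 1e5, mass = 12) {
  stopifnot(temperature > 0, friction > 0, timestep > 0, max_steps >= 1,
            mass > 0)
  list(temperature = temperature, friction = friction, timestep = timestep,
       max_steps = as.integer(max_steps), mass = mass)
}

## kcal/mol/A per amu -> A/ps^2 (4184 J/kcal, 1e-3 kg/g, A/ps unit algebra)
AKMA_ACC <- 418.4

#' Committor probability by Langevin shooting
#'
#' Launches `n_shots` trajectories from `start` with Maxwell-Boltzmann
#' initial velocities and BAOAB Langevin dynamics; each runs until its
#' position enters the reactant (`x <= a`) or product (`x >= b`) basin
#' (position-only criterion) or times out at `max_steps`. Timeouts are
#' excluded from the probability and counted separately. Bit-reproducible
#' for a given seed.
#'
#' @param potential a [model_potential()].
#' @param start starting coordinate, strictly inside `(a, b)`.
#' @param n_shots number of trajectories, >= 1.
#' @param dynamics a [langevin_dynamics()] list.
#' @param seed integer seed.
#' @return Object of class `committor_result`: `start_coordinate`,
#'   `n_shots`, `n_product`, `n_reactant`, `n_timeout`, `p_product`,
#'   `ci95` (Wilson), `seed`.
#' @export
committor_probability <- function(potential, start, n_shots = 100,
                                  dynamics = langevin_dynamics(),
                                  seed = 1L) {
  stopifnot(inherits(potential, "model_potential"), n_shots >= 1)
  a <- potential$basins[1]; b <- potential$basins[2]
  if (!(start > a && start < b))
    stop("start must lie strictly between the basin boundaries")
  RT <- fc_constants$R_kcal * dynamics$temperature
  dt <- dynamics$timestep
  m <- dynamics$mass
  c1 <- exp(-dynamics$friction * dt)
  sigma_v <- sqrt(AKMA_ACC * RT / m)
  c2 <- sigma_v * sqrt(1 - c1^2)
  acc <- function(x) -potential$dVdx(x) * AKMA_ACC / m

  set.seed(seed)
  x <- rep(start, n_shots)
  v <- stats::rnorm(n_shots, 0, sigma_v)
  fate <- integer(n_shots)           # 0 running, 1 reactant, 2 product
  active <- seq_len(n_shots)
  step <- 0L
  while (length(active) > 0 && step < dynamics$max_steps) {
    step <- step + 1L
    v[active] <- v[active] + 0.5 * dt * acc(x[active])
    x[active] <- x[active] + 0.5 * dt * v[active]
    v[active] <- c1 * v[active] + c2 * stats::rnorm(length(active))
    x[active] <- x[active] + 0.5 * dt * v[active]
    v[active] <- v[active] + 0.5 * dt * acc(x[active])
    hit_r <- x[active] <= a
    hit_p <- x[active] >= b
    fate[active[hit_r]] <- 1L
    fate[active[hit_p]] <- 2L
    active <- active[!(hit_r | hit_p)]
  }
  n_reac <- sum(fate == 1L); n_prod <- sum(fate == 2L)
  n_timeout <- n_shots - n_reac - n_prod
  n_done <- n_reac + n_prod
  if (n_done == 0)
    stop("inconclusive result: all shots timed out before committing")
  p <- n_prod / n_done
  structure(list(start_coordinate = start, n_shots = n_shots,
                 n_product = n_prod, n_reactant = n_reac,
                 n_timeout = n_timeout, p_product = p,
                 ci95 = wilson_interval(n_prod, n_done),
                 seed = as.integer(seed)),
            class = "committor_result")
}

#' Wilson 95% confidence interval for a binomial proportion
#'
#' @param k successes, `n` trials.
#' @param n trials.
#' @param z normal quantile (default 1.959964 for 95%).
#' @return Length-2 numeric `c(low, high)`.
#' @export
wilson_interval <- function(k, n, z = stats::qnorm(0.975)) {
  stopifnot(n >= 1, k >= 0, k <= n)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, center - half), min(1, center + half))
}

#' Validate a transition-state candidate ensemble by committor histogram
#'
#' Runs [committor_probability()] for each candidate coordinate (seeds
#' derived deterministically from `seed`), histograms the committor values
#' on 10 bins over [0, 1], and passes the ensemble when the median
#' committor lies in [0.4, 0.6] — the standard signature of configurations
#' drawn from a transition-state ensemble.
#'
#' @param potential a [model_potential()].
#' @param candidate_coordinates numeric vector, length >= 5.
#' @param n_shots shots per candidate.
#' @param dynamics a [langevin_dynamics()] list.
#' @param seed integer seed.
#' @return List of class `ts_validation`: `results` (per-candidate
#'   [committor_probability()] outputs), `p_values`, `histogram` (10 bin
#'   counts), `median_p`, `pass`.
#' @export
validate_ts_ensemble <- function(potential, candidate_coordinates,
                                 n_shots = 100,
                                 dynamics = langevin_dynamics(),
                                 seed = 1L) {
  if (length(candidate_coordinates) < 5)
    stop("need at least 5 candidate coordinates")
  results <- lapply(seq_along(candidate_coordinates), function(i) {
    committor_probability(potential, candidate_coordinates[i], n_shots,
                          dynamics, seed = seed + i)
  })
  p <- vapply(results, function(r) r$p_product, numeric(1))
  hist_counts <- tabulate(pmin(floor(p * 10) + 1L, 10L), nbins = 10L)
  med <- stats::median(p)
  structure(list(results = results, p_values = p, histogram = hist_counts,
                 median_p = med, pass = med >= 0.4 && med <= 0.6),
            class = "ts_validation")
}
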