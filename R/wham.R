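## Self-consistent WHAM over harmonically biased 1-D umbrella windows,
## with bootstrap uncertainties, overlap/convergence diagnostics and
## barrier extraction.

#' Harmonic bias specification for one umbrella window
#'
#' The restraint is `U(x) = k_f (x - center)^2` by default (no 1/2 factor,
#' the convention of the engine force constants this package consumes);
#' `half_k = TRUE` switches to `U(x) = k_f/2 (x - center)^2`.
#'
#' @param center bias center, Angstrom.
#' @param force_constant `k_f`, kcal/mol/A^2, >= 0.
#' @param half_k logical, use the 1/2-factor convention.
#' @return Object of class `bias_spec`.
#' @export
bias_spec <- function(center, force_constant, half_k = FALSE) {
  if (force_constant < 0) stop("force_constant must be >= 0")
  structure(list(center = as.numeric(center),
                 force_constant = as.numeric(force_constant),
                 half_k = isTRUE(half_k)),
            class = "bias_spec")
}

bias_energy <- function(bias, x) {
  pref <- if (bias$half_k) 0.5 else 1
  pref * bias$force_constant * (x - bias$center)^2
}

#' One umbrella window: bias plus sampled coordinate series
#'
#' @param bias a [bias_spec()].
#' @param series a [window_series()] or a bare numeric vector of coordinate
#'   samples (times then assumed uniform).
#' @return Object of class `umbrella_window`.
#' @export
umbrella_window <- function(bias, series) {
  stopifnot(inherits(bias, "bias_spec"))
  if (is.numeric(series))
    series <- window_series(seq_along(series) - 1, series)
  stopifnot(inherits(series, "window_series"), nrow(series) > 0)
  structure(list(bias = bias, series = series), class = "umbrella_window")
}

#' WHAM configuration
#'
#' Defaults mirror a thermophilic-cutinase analysis: 343.15 K, 0.02 A bins
#' for bond-distance coordinates (0.1 A is a reasonable choice for
#' center-of-mass distance profiles), offset tolerance 1e-5 kcal/mol, 100
#' bootstrap replicates, and the first half of every window discarded as
#' equilibration (the last 15 ps of 30-ps windows).
#'
#' @param temperature K.
#' @param bin_width Angstrom.
#' @param tolerance max offset change per iteration, kcal/mol.
#' @param max_iterations fixed-point iteration cap.
#' @param n_bootstrap bootstrap replicate count.
#' @param discard_fraction leading fraction of samples dropped, in [0, 1).
#' @param seed integer seed for the bootstrap stream.
#' @param damping log-space damping factor in (0, 1]; 1 is plain iteration.
#' @return Object of class `wham_config`.
#' @export
wham_config <- function(temperature = 343.15, bin_width = 0.02,
                        tolerance = 1e-5, max_iterations = 1e6,
                        n_bootstrap = 100, discard_fraction = 0.5,
                        seed = 1L, damping = 1.0) {
  stopifnot(temperature > 0, bin_width > 0, tolerance > 0,
            max_iterations >= 1, n_bootstrap >= 1,
            discard_fraction >= 0, discard_fraction < 1,
            damping > 0, damping <= 1)
  structure(list(temperature = temperature, bin_width = bin_width,
                 tolerance = tolerance, max_iterations = max_iterations,
                 n_bootstrap = n_bootstrap,
                 discard_fraction = discard_fraction,
                 seed = as.integer(seed), damping = damping),
            class = "wham_config")
}

retained_samples <- function(w, discard_fraction) {
  v <- w$series$value
  n <- length(v)
  v[(floor(n * discard_fraction) + 1L):n]
}

## Uniform grid spanning all retained samples, padded by one bin each side.
wham_grid <- function(samples_list, bin_width) {
  lo <- min(vapply(samples_list, min, numeric(1))) - bin_width
  hi <- max(vapply(samples_list, max, numeric(1))) + bin_width
  n_bins <- max(1L, as.integer(ceiling((hi - lo) / bin_width)))
  edges <- lo + bin_width * (0:n_bins)
  list(edges = edges, centers = (edges[-1] + edges[-length(edges)]) / 2)
}

logsumexp <- function(m) {
  ## row-wise log-sum-exp of a matrix
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

#' Solve the WHAM self-consistency equations
#'
#' Combines the biased histograms of all windows into one unbiased
#' free-energy profile. Unbiased bin probabilities and per-window free-
#' energy offsets are iterated (plain fixed point, optionally damped in log
#' space) until the largest absolute offset change falls below
#' `config$tolerance` in kcal/mol. The PMF is `-RT log p` on occupied bins,
#' shifted so its minimum is zero; empty bins are masked, never
#' interpolated. The solve is fully deterministic.
#'
#' @param windows list of [umbrella_window()] objects.
#' @param config a [wham_config()].
#' @param grid optional precomputed grid (list with `edges`, `centers`),
#'   used by the bootstrap so replicates share the full-data binning.
#' @return Object of class `free_energy_profile`: `bin_centers`, `pmf`
#'   (kcal/mol, `NA` on unoccupied bins), `pmf_std` (filled by
#'   [bootstrap_pmf()]), `window_offsets` (kcal/mol, first window 0),
#'   `occupied`, `n_iterations`, `residual`, plus the `config` used.
#' @export
wham_solve <- function(windows, config = wham_config(), grid = NULL) {
  stopifnot(length(windows) >= 1)
  RT <- fc_constants$R_kcal * config$temperature
  samples <- lapply(windows, retained_samples, config$discard_fraction)
  if (any(!vapply(samples, function(s) all(is.finite(s)), logical(1))))
    stop("non-finite samples in windows")
  if (is.null(grid)) grid <- wham_grid(samples, config$bin_width)
  nb <- length(grid$centers)
  nw <- length(windows)
  counts <- vapply(samples, function(s) {
    idx <- findInterval(s, grid$edges, rightmost.closed = TRUE)
    tabulate(idx, nbins = nb)
  }, integer(nb))
  counts <- matrix(counts, nrow = nb)          # bins x windows
  C_b <- rowSums(counts)
  N_w <- colSums(counts)
  occupied <- C_b > 0
  ## reduced bias energies at bin centers: bins x windows
  Ured <- vapply(windows, function(w) bias_energy(w$bias, grid$centers) / RT,
                 numeric(nb))
  Ured <- matrix(Ured, nrow = nb)
  ## adjacent-window overlap sanity check on raw histograms
  ord <- order(vapply(windows, function(w) w$bias$center, numeric(1)))
  if (nw > 1) {
    for (k in seq_len(nw - 1)) {
      if (!any(counts[, ord[k]] > 0 & counts[, ord[k + 1]] > 0))
        warning(sprintf(
          "no histogram overlap between adjacent windows %d and %d; profile may be piecewise",
          ord[k], ord[k + 1]))
    }
  }
  g <- rep(0, nw)                              # reduced offsets f_w / RT
  logN <- log(N_w)
  logC <- ifelse(occupied, log(C_b), -Inf)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    ## log p_b (unnormalized) = log C_b - log sum_w N_w exp(g_w - U_wb)
    denom <- logsumexp(sweep(-Ured, 2, logN + g, "+"))
    logp <- logC - denom
    logp <- logp - logsumexp(matrix(logp[occupied], nrow = 1))  # normalize
    ## g_w_new = -log sum_b p_b exp(-U_wb)
    g_new <- -apply(Ured[occupied, , drop = FALSE], 2, function(u) {
      m <- max(logp[occupied] - u)
      m + log(sum(exp(logp[occupied] - u - m)))
    })
    g_new <- g + config$damping * (g_new - g)
    resid <- max(abs(g_new - g)) * RT
    g <- g_new
    if (resid < config$tolerance) break
    if (iter >= config$max_iterations)
      stop(sprintf(
        "WHAM did not converge in %d iterations (residual %.3g kcal/mol)",
        iter, resid))
  }
  pmf <- rep(NA_real_, nb)
  pmf[occupied] <- -RT * logp[occupied]
  pmf <- pmf - min(pmf, na.rm = TRUE)
  offsets <- (g - g[1]) * RT
  structure(list(bin_centers = grid$centers, pmf = pmf,
                 pmf_std = rep(NA_real_, nb),
                 window_offsets = offsets, occupied = occupied,
                 bin_counts = C_b,
                 n_iterations = iter, residual = resid,
                 grid = grid, config = config),
            class = "free_energy_profile")
}

#' @export
print.free_energy_profile <- function(x, ...) {
  cat(sprintf(
    "<free_energy_profile> %d bins (%d occupied), range %.3f kcal/mol, %d iterations\n",
    length(x$bin_centers), sum(x$occupied),
    max(x$pmf, na.rm = TRUE), x$n_iterations))
  invisible(x)
}

#' Bootstrap uncertainties for a WHAM profile
#'
#' Draws `config$n_bootstrap` replicates by resampling the retained samples
#' of every window with replacement (window identities fixed), re-solves
#' each on the full-data grid, min-shifts each replicate, and reports the
#' per-bin standard deviation. If a reactant side is given, a barrier
#' standard deviation over replicates is attached too. Seeded and
#' reproducible: the same `config$seed` yields bit-identical results.
#'
#' @param windows list of [umbrella_window()] objects.
#' @param config a [wham_config()].
#' @param reactant_side optionally `"left"` or `"right"` to also bootstrap
#'   the barrier of [barrier_from_profile()].
#' @return The full-data `free_energy_profile` with `pmf_std` filled, and
#'   additional fields `barrier_std`, `barrier_values`, `n_failed`.
#' @export
bootstrap_pmf <- function(windows, config = wham_config(),
                          reactant_side = NULL) {
  full <- wham_solve(windows, config)
  samples <- lapply(windows, retained_samples, config$discard_fraction)
  nb <- length(full$bin_centers)
  set.seed(config$seed)
  reps <- matrix(NA_real_, nrow = nb, ncol = config$n_bootstrap)
  barriers <- rep(NA_real_, config$n_bootstrap)
  n_failed <- 0L
  for (r in seq_len(config$n_bootstrap)) {
    wr <- lapply(seq_along(windows), function(i) {
      v <- sample(samples[[i]], replace = TRUE)
      umbrella_window(windows[[i]]$bias, window_series(seq_along(v) - 1, v))
    })
    cfg_r <- config
    cfg_r$discard_fraction <- 0  # resampling already acts on retained data
    prof_r <- tryCatch(wham_solve(wr, cfg_r, grid = full$grid),
                       error = function(e) NULL)
    if (is.null(prof_r)) { n_failed <- n_failed + 1L; next }
    reps[, r] <- prof_r$pmf
    if (!is.null(reactant_side))
      barriers[r] <- tryCatch(
        barrier_from_profile(prof_r, reactant_side)$dg_barrier,
        error = function(e) NA_real_)
  }
  if (n_failed > 0.1 * config$n_bootstrap)
    stop(sprintf("bootstrap failure: %d of %d replicates failed",
                 n_failed, config$n_bootstrap))
  sd_or_na <- function(v) {
    v <- v[is.finite(v)]
    if (length(v) >= 2) stats::sd(v) else NA_real_
  }
  full$pmf_std <- apply(reps, 1, sd_or_na)
  full$pmf_std[!full$occupied] <- NA_real_
  full$barrier_values <- barriers
  full$barrier_std <- sd_or_na(barriers)
  full$n_failed <- n_failed
  full
}

#' Extract the activation and reaction free energies from a profile
#'
#' Moving from the reactant-side basin toward the other end, the barrier is
#' the dominant interior maximum relative to the reactant basin minimum;
#' the reaction free energy is the far-side basin minimum relative to the
#' reactant minimum. Among interior maxima the one with the largest
#' prominence (height above the lower of its two flanking basin minima) is
#' taken, which coincides with the highest maximum on clean profiles but
#' ignores shot-noise spikes in sparsely sampled tail bins. Ties break
#' toward the reactant side. A monotonic profile has no barrier and is an
#' error.
#'
#' @param profile a `free_energy_profile` (or any list with `pmf` and
#'   `occupied`).
#' @param reactant_side `"left"` or `"right"`.
#' @return List with `dg_barrier` and `dg_reaction`, kcal/mol.
#' @export
barrier_from_profile <- function(profile, reactant_side = c("left", "right")) {
  reactant_side <- match.arg(reactant_side)
  v <- profile$pmf[profile$occupied]
  v <- v[is.finite(v)]
  n <- length(v)
  if (n < 3) stop("need at least 3 occupied bins")
  if (reactant_side == "right") v <- rev(v)
  i <- 2:(n - 1)
  is_max <- v[i] >= v[i - 1] & v[i] >= v[i + 1] &
    (v[i] > v[i - 1] | v[i] > v[i + 1])
  loc <- i[is_max]
  ## plateau maxima flat on both sides: keep bins strictly above both ends
  if (length(loc) == 0) {
    flat <- i[v[i] >= v[i - 1] & v[i] >= v[i + 1]]
    loc <- flat[v[flat] > v[1] & v[flat] > v[n]]
  }
  if (length(loc) == 0) stop("no barrier: profile is monotonic")
  prominence <- vapply(loc, function(j)
    min(v[j] - min(v[1:j]), v[j] - min(v[j:n])), numeric(1))
  ib <- loc[which.max(prominence)]    # first index on ties = reactant side
  reactant_min <- min(v[1:ib])
  product_min <- min(v[ib:n])
  list(dg_barrier = v[ib] - reactant_min,
       dg_reaction = product_min - reactant_min)
}

#' Pairwise histogram-overlap diagnostic
#'
#' Overlap of two windows is `sum_b min(p_i, p_j)` of their normalized
#' retained-sample histograms on the common grid; 1 for identical sampling,
#' 0 for disjoint support. Zero overlap is a valid, reported outcome, not
#' an error.
#'
#' @param windows list of [umbrella_window()] objects.
#' @param config a [wham_config()].
#' @return List: `matrix` (windows ordered by bias center) and
#'   `min_adjacent`.
#' @export
overlap_diagnostic <- function(windows, config = wham_config()) {
  stopifnot(length(windows) >= 2)
  samples <- lapply(windows, retained_samples, config$discard_fraction)
  grid <- wham_grid(samples, config$bin_width)
  nb <- length(grid$centers)
  P <- vapply(samples, function(s) {
    h <- tabulate(findInterval(s, grid$edges, rightmost.closed = TRUE),
                  nbins = nb)
    h / sum(h)
  }, numeric(nb))
  ord <- order(vapply(windows, function(w) w$bias$center, numeric(1)))
  P <- P[, ord, drop = FALSE]
  nw <- ncol(P)
  M <- diag(1, nw)
  for (a in seq_len(nw - 1)) for (b in (a + 1):nw)
    M[a, b] <- M[b, a] <- sum(pmin(P[, a], P[, b]))
  adj <- vapply(seq_len(nw - 1), function(k) M[k, k + 1], numeric(1))
  list(matrix = M, min_adjacent = min(adj))
}

#' First-half / second-half convergence check
#'
#' Solves WHAM separately on the first and second halves of every window's
#' retained samples and reports the largest absolute bin difference of the
#' two min-shifted profiles. Only bins holding at least `min_count` samples
#' in both half-solves enter the comparison: tail bins with a handful of
#' counts carry shot noise of order RT/sqrt(count) and would otherwise
#' swamp the diagnostic (at the default 50 the per-bin noise is about
#' 0.1 kcal/mol at 343 K).
#'
#' @param windows list of [umbrella_window()] objects.
#' @param config a [wham_config()].
#' @param min_count minimum per-bin total sample count in each half.
#' @return List: `max_abs_diff` (kcal/mol), the two profiles.
#' @export
convergence_check <- function(windows, config = wham_config(),
                              min_count = 50) {
  samples <- lapply(windows, retained_samples, config$discard_fraction)
  if (any(vapply(samples, length, 1L) < 4))
    stop("insufficient data: need >= 4 retained samples per window")
  half <- function(take_first) {
    lapply(seq_along(windows), function(i) {
      v <- samples[[i]]
      h <- floor(length(v) / 2)
      v <- if (take_first) v[1:h] else v[(h + 1):length(v)]
      umbrella_window(windows[[i]]$bias, window_series(seq_along(v) - 1, v))
    })
  }
  cfg <- config
  cfg$discard_fraction <- 0
  grid <- wham_grid(samples, config$bin_width)
  p1 <- wham_solve(half(TRUE), cfg, grid = grid)
  p2 <- wham_solve(half(FALSE), cfg, grid = grid)
  both <- p1$bin_counts >= min_count & p2$bin_counts >= min_count
  if (!any(both))
    stop("insufficient data: no bin holds min_count samples in both halves")
  list(max_abs_diff = max(abs(p1$pmf[both] - p2$pmf[both])),
       first_half = p1, second_half = p2)
}
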