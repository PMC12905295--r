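## Independent oracles. Each is written from first principles (SI units,
## brute force, quadrature, or a different solver) and never calls the code
## path it is used to check.

## Coulomb field oracle: per-charge accumulation in SI units (meters,
## Coulombs, V/m), converted to MV/cm only at the end.
oracle_coulomb_field <- function(pos_A, q_e, r0_A) {
  eps0 <- 8.8541878128e-12
  e <- 1.602176634e-19
  F <- c(0, 0, 0)
  for (i in seq_len(nrow(pos_A))) {
    d <- unname(r0_A - pos_A[i, ]) * 1e-10    # m
    r <- sqrt(sum(d * d))
    F <- F + q_e[i] * e / (4 * pi * eps0) * d / r^3   # V/m
  }
  F / 1e8                                      # MV/cm
}

## Unit-field constant derived independently: field of one elementary
## charge at 1 Angstrom, in MV/cm.
oracle_unit_charge_field <- function() {
  eps0 <- 8.8541878128e-12
  e <- 1.602176634e-19
  (e / (4 * pi * eps0 * (1e-10)^2)) / 1e8
}

## Reference WHAM oracle: minimizes the convex WHAM negative log-likelihood
##   A(g) = -sum_w N_w g_w + sum_b C_b log sum_w N_w exp(g_w - u_wb)
## over reduced window offsets g (g_1 = 0 gauge) with BFGS and analytic
## gradients, then recovers the PMF from the stationary probabilities.
## A different algorithmic route from the package's fixed-point iteration.
oracle_wham <- function(windows, temperature, bin_width,
                        discard_fraction = 0) {
  RT <- 1.987204259e-3 * temperature
  samples <- lapply(windows, function(w) {
    v <- w$series$value
    v[(floor(length(v) * discard_fraction) + 1L):length(v)]
  })
  lo <- min(unlist(samples)) - bin_width
  hi <- max(unlist(samples)) + bin_width
  edges <- seq(lo, lo + bin_width * ceiling((hi - lo) / bin_width),
               by = bin_width)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  nb <- length(centers)
  counts <- vapply(samples, function(s)
    tabulate(findInterval(s, edges, rightmost.closed = TRUE), nbins = nb),
    integer(nb))
  C_b <- rowSums(counts)
  N_w <- colSums(counts)
  occ <- C_b > 0
  u <- vapply(windows, function(w) {
    pref <- if (isTRUE(w$bias$half_k)) 0.5 else 1
    pref * w$bias$force_constant * (centers - w$bias$center)^2 / RT
  }, numeric(nb))
  nw <- length(windows)
  logN <- log(N_w)
  obj <- function(g2) {
    g <- c(0, g2)
    M <- sweep(-u[occ, , drop = FALSE], 2, logN + g, "+")
    mx <- apply(M, 1, max)
    lse <- mx + log(rowSums(exp(M - mx)))
    -sum(N_w * g) + sum(C_b[occ] * lse)
  }
  grad <- function(g2) {
    g <- c(0, g2)
    M <- sweep(-u[occ, , drop = FALSE], 2, logN + g, "+")
    mx <- apply(M, 1, max)
    D <- rowSums(exp(M - mx))
    W <- exp(M - mx) / D                      # bins x windows responsibilities
    (-N_w + colSums(C_b[occ] * W))[-1]
  }
  fit <- stats::optim(rep(0, nw - 1), obj, grad, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  g <- c(0, fit$par)
  M <- sweep(-u[occ, , drop = FALSE], 2, logN + g, "+")
  mx <- apply(M, 1, max)
  logp <- log(C_b[occ]) - (mx + log(rowSums(exp(M - mx))))
  pmf <- rep(NA_real_, nb)
  pmf[occ] <- -RT * logp
  pmf <- pmf - min(pmf, na.rm = TRUE)
  list(bin_centers = centers, pmf = pmf, occupied = occ)
}

## Mean of a biased Boltzmann density by adaptive quadrature.
oracle_biased_mean <- function(V, bias_center, k_f, temperature, lower, upper) {
  RT <- 1.987204259e-3 * temperature
  dens <- function(x) exp(-(V(x) + k_f * (x - bias_center)^2) / RT)
  Z <- stats::integrate(dens, lower, upper, rel.tol = 1e-10)$value
  stats::integrate(function(x) x * dens(x), lower, upper,
                   rel.tol = 1e-10)$value / Z
}

## Debye-field-energy conversion derived independently in SI:
## (1 D) x (1 MV/cm) per molecule, scaled to kcal/mol.
oracle_debye_conversion <- function() {
  debye_Cm <- 1e-21 / 299792458
  debye_Cm * 1e8 * 6.02214076e23 / 4184
}

## Eyring prefactor oracle: direct CODATA kB*T/h.
oracle_kbT_over_h <- function(temperature) {
  1.380649e-23 * temperature / 6.62607015e-34
}

## Shared double-well umbrella fixture (memoised per session so several
## test files can reuse it without resampling).
double_well_fixture <- local({
  cache <- NULL
  function(n_samples = 10000, seed = 11) {
    key <- paste(n_samples, seed)
    if (!is.null(cache) && identical(cache$key, key)) return(cache$value)
    pot <- model_potential("double_well", barrier_height = 5,
                           half_separation = 1)
    biases <- lapply(seq(-1.25, 1.25, length.out = 21),
                     function(c0) bias_spec(c0, 50))
    wins <- sample_umbrella_windows(pot, biases, temperature = 343.15,
                                    n_samples = n_samples, seed = seed)
    value <- list(potential = pot, windows = wins)
    cache <<- list(key = key, value = value)
    value
  }
})
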