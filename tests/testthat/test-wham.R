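test_that("a single unbiased window reproduces the generating potential", {
  V <- function(x) 2 * x^2
  wins <- sample_umbrella_windows(V, list(bias_spec(0, 0)),
                                  temperature = 343.15, n_samples = 1e5,
                                  support = c(-1.6, 1.6), seed = 5)
  cfg <- wham_config(temperature = 343.15, bin_width = 0.05,
                     discard_fraction = 0)
  prof <- wham_solve(wins, cfg)
  inside <- abs(prof$bin_centers) <= 1 & prof$occupied
  ref <- V(prof$bin_centers[inside])
  expect_lt(max(abs(prof$pmf[inside] - (ref - min(ref)))), 0.1)

  ## zero-bias limit: the WHAM result IS the min-shifted log-histogram
  RT <- fc_constants$R_kcal * 343.15
  h <- tabulate(findInterval(wins[[1]]$series$value, prof$grid$edges,
                             rightmost.closed = TRUE),
                nbins = length(prof$bin_centers))
  direct <- -RT * log(h[prof$occupied])
  direct <- direct - min(direct)
  expect_equal(prof$pmf[prof$occupied], direct, tolerance = 1e-10)
  expect_equal(prof$n_iterations, 1L)
})

test_that("a flat potential under a ladder of biases stays flat", {
  V <- function(x) rep(0, length(x))
  biases <- lapply(seq(0, 1, length.out = 11), function(c0) bias_spec(c0, 10))
  wins <- sample_umbrella_windows(V, biases, temperature = 343.15,
                                  n_samples = 2e4, support = c(-1, 2),
                                  seed = 8)
  cfg <- wham_config(343.15, bin_width = 0.05, discard_fraction = 0)
  prof <- wham_solve(wins, cfg)
  core <- prof$occupied & prof$bin_centers >= 0 & prof$bin_centers <= 1 &
    prof$bin_counts >= 200
  expect_lt(max(prof$pmf[core]) - min(prof$pmf[core]), 0.1)
})

test_that("the double-well barrier is recovered within bootstrap error", {
  fx <- double_well_fixture()
  cfg <- wham_config(343.15, bin_width = 0.02, n_bootstrap = 25,
                     discard_fraction = 0, seed = 3)
  prof <- bootstrap_pmf(fx$windows, cfg, reactant_side = "left")
  bar <- barrier_from_profile(prof, "left")
  expect_lt(abs(bar$dg_barrier - 5.0), 2 * prof$barrier_std)
  expect_lt(abs(bar$dg_reaction), 0.2)   # symmetric well
  ## PMF tracks the generating potential pointwise in the resolved region
  fit_region <- prof$occupied & abs(prof$bin_centers) <= 1.1 &
    prof$bin_counts >= 100
  ref <- fx$potential$V(prof$bin_centers[fit_region])
  expect_lt(max(abs(prof$pmf[fit_region] - (ref - min(ref)))), 0.35)
})

test_that("the solver agrees with an independent likelihood-based oracle", {
  fx <- double_well_fixture(n_samples = 4000, seed = 19)
  cfg <- wham_config(343.15, bin_width = 0.05, discard_fraction = 0)
  prof <- wham_solve(fx$windows, cfg)
  ref <- oracle_wham(fx$windows, temperature = 343.15, bin_width = 0.05)
  both <- prof$occupied & ref$occupied
  expect_equal(prof$bin_centers, ref$bin_centers, tolerance = 1e-12)
  expect_lt(max(abs(prof$pmf[both] - ref$pmf[both])), 0.05)
})

test_that("translating the coordinate translates the profile, nothing else", {
  fx <- double_well_fixture(n_samples = 2000, seed = 29)
  cfg <- wham_config(343.15, bin_width = 0.05, discard_fraction = 0)
  prof1 <- wham_solve(fx$windows, cfg)
  shifted <- lapply(fx$windows, function(w)
    umbrella_window(bias_spec(w$bias$center + 10, w$bias$force_constant),
                    window_series(w$series$time, w$series$value + 10)))
  prof2 <- wham_solve(shifted, cfg)
  expect_equal(prof2$bin_centers, prof1$bin_centers + 10, tolerance = 1e-9)
  expect_equal(prof2$pmf, prof1$pmf, tolerance = 1e-9)
  expect_equal(prof2$window_offsets, prof1$window_offsets, tolerance = 1e-8)
})

test_that("temperature enters the solve the way the estimator predicts", {
  V <- function(x) 2 * x^2
  wins <- sample_umbrella_windows(V, list(bias_spec(0, 0)),
                                  temperature = 343.15, n_samples = 5e4,
                                  support = c(-1.6, 1.6), seed = 13)
  cfgT <- wham_config(343.15, bin_width = 0.04, discard_fraction = 0)
  cfg2T <- wham_config(2 * 343.15, bin_width = 0.04, discard_fraction = 0)
  pT <- wham_solve(wins, cfgT)
  p2T <- wham_solve(wins, cfg2T)
  ## single unbiased window: PMF = -RT log h, so doubling T doubles it
  expect_equal(p2T$pmf[p2T$occupied], 2 * pT$pmf[pT$occupied],
               tolerance = 1e-9)
})

test_that("the half-k restraint convention is the k/2 full convention", {
  fx <- double_well_fixture(n_samples = 2000, seed = 29)
  cfg <- wham_config(343.15, bin_width = 0.05, discard_fraction = 0)
  full_k <- wham_solve(fx$windows, cfg)
  halved <- lapply(fx$windows, function(w)
    umbrella_window(bias_spec(w$bias$center, 2 * w$bias$force_constant,
                              half_k = TRUE), w$series))
  expect_equal(wham_solve(halved, cfg)$pmf, full_k$pmf, tolerance = 1e-12)
})

test_that("bootstrap is seeded, stable under replicate doubling, and degenerate-safe", {
  fx <- double_well_fixture(n_samples = 2000, seed = 29)
  cfg10 <- wham_config(343.15, bin_width = 0.05, n_bootstrap = 10,
                       discard_fraction = 0, seed = 42)
  cfg20 <- wham_config(343.15, bin_width = 0.05, n_bootstrap = 20,
                       discard_fraction = 0, seed = 42)
  a <- bootstrap_pmf(fx$windows, cfg10)
  b <- bootstrap_pmf(fx$windows, cfg10)
  expect_identical(a$pmf_std, b$pmf_std)     # same seed, bit for bit
  d <- bootstrap_pmf(fx$windows, cfg20)
  ma <- mean(a$pmf_std[a$occupied], na.rm = TRUE)
  md <- mean(d$pmf_std[d$occupied], na.rm = TRUE)
  expect_lt(abs(ma - md) / md, 0.2)

  ## all samples exactly at their bias centers: zero bootstrap spread
  degenerate <- lapply(seq(0, 1, by = 0.25), function(c0)
    umbrella_window(bias_spec(c0, 100), rep(c0, 50)))
  cfgd <- wham_config(343.15, bin_width = 0.25, n_bootstrap = 10,
                      discard_fraction = 0, seed = 1)
  ## single-bin windows legitimately trigger the no-overlap warning
  suppressWarnings(pd <- bootstrap_pmf(degenerate, cfgd))
  expect_true(all(pd$pmf_std[pd$occupied] == 0))
})

test_that("barriers and reaction energies come off printed-style profiles", {
  mk <- function(v) list(pmf = v, occupied = rep(TRUE, length(v)))
  b1 <- barrier_from_profile(mk(c(0.0, 20.4, 15.3)), "left")
  expect_equal(b1$dg_barrier, 20.4)
  expect_equal(b1$dg_reaction, 15.3)
  b2 <- barrier_from_profile(mk(c(0.0, 10.7, 2.7)), "left")
  expect_equal(b2$dg_barrier, 10.7)
  expect_equal(b2$dg_reaction, 2.7)
  b3l <- barrier_from_profile(mk(c(0, 5, 0)), "left")
  b3r <- barrier_from_profile(mk(c(0, 5, 0)), "right")
  expect_equal(b3l$dg_barrier, 5)
  expect_equal(b3r$dg_barrier, 5)
  expect_error(barrier_from_profile(mk(c(0, 1, 2, 3)), "left"), "monotonic")
  ## right-side reading of an asymmetric profile
  b4 <- barrier_from_profile(mk(c(0.0, 20.4, 15.3)), "right")
  expect_equal(b4$dg_barrier, 20.4 - 15.3)
  expect_equal(b4$dg_reaction, -15.3)
})

test_that("overlap diagnostics report adjacent histogram overlap", {
  w <- umbrella_window(bias_spec(0, 1), c(0.1, 0.2, 0.3, 0.2, 0.15))
  same <- list(w, umbrella_window(bias_spec(0.01, 1), w$series))
  cfg <- wham_config(343.15, bin_width = 0.05, discard_fraction = 0)
  ov <- overlap_diagnostic(same, cfg)
  expect_equal(ov$min_adjacent, 1.0)

  apart <- list(umbrella_window(bias_spec(0, 1), c(0.0, 0.1, 0.05)),
                umbrella_window(bias_spec(5, 1), c(5.0, 5.1, 5.05)))
  expect_equal(overlap_diagnostic(apart, cfg)$min_adjacent, 0.0)

  ## two unit Gaussians 2 sigma apart overlap by 2*Phi(-1) ~ 0.3173
  set.seed(17)
  g1 <- umbrella_window(bias_spec(0, 0), rnorm(1e5, 0, 1))
  g2 <- umbrella_window(bias_spec(2, 0), rnorm(1e5, 2, 1))
  ovg <- overlap_diagnostic(list(g1, g2), cfg)
  expect_lt(abs(ovg$min_adjacent - 2 * pnorm(-1)), 0.02)
})

test_that("half-series convergence diagnostics behave", {
  fx <- double_well_fixture()
  cfg <- wham_config(343.15, bin_width = 0.02, discard_fraction = 0)
  cc <- convergence_check(fx$windows, cfg)
  expect_lt(cc$max_abs_diff, 0.3)

  dup <- lapply(fx$windows, function(w) {
    v <- w$series$value[1:100]
    umbrella_window(w$bias, c(v, v))
  })
  cc2 <- convergence_check(dup, cfg, min_count = 1)
  expect_equal(cc2$max_abs_diff, 0)

  tiny <- list(umbrella_window(bias_spec(0, 10), c(0.0, 0.1, 0.2)))
  expect_error(convergence_check(tiny, cfg), "nsufficient")
})

test_that("empty overlap between adjacent windows warns but returns a profile", {
  apart <- list(umbrella_window(bias_spec(0, 50), rnorm(200, 0, 0.08)),
                umbrella_window(bias_spec(5, 50), rnorm(200, 5, 0.08)))
  cfg <- wham_config(343.15, bin_width = 0.05, discard_fraction = 0)
  set.seed(2)
  expect_warning(prof <- wham_solve(apart, cfg), "overlap")
  expect_s3_class(prof, "free_energy_profile")
})
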