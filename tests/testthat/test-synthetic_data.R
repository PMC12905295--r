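test_that("point-charge generation is seed-reproducible and oracle-consistent", {
  g1 <- gen_point_charges(50, seed = 14)
  g2 <- gen_point_charges(50, seed = 14)
  expect_identical(g1$frame$atoms, g2$frame$atoms)
  expect_identical(g1$expected_field, g2$expected_field)
  g3 <- gen_point_charges(50, seed = 15)
  expect_false(identical(g1$frame$atoms$x, g3$frame$atoms$x))

  ## companion record equals the field module's evaluation
  env <- selection(mode = "exclude")
  for (seed in c(14, 99, 1234)) {
    g <- gen_point_charges(50, seed = seed)
    fs <- axial_field(g$frame, g$axis, env)
    expect_equal(fs$field_vector, g$expected_field, tolerance = 1e-10)
    expect_equal(fs$axial_component, g$expected_axial, tolerance = 1e-10)
  }

  g0 <- gen_point_charges(0, seed = 1)
  expect_equal(g0$expected_field, c(0, 0, 0))
  ## all charges clear the 2 Angstrom exclusion sphere around the probe
  chg <- g1$frame$atoms[g1$frame$atoms$residue_name == "CHG", ]
  expect_true(all(sqrt(chg$x^2 + chg$y^2 + chg$z^2) > 2))
})

test_that("prescribed-field trajectories hit the schedule to machine precision", {
  env <- selection(mode = "exclude")
  sched <- c(-37.1, -37.1, -52.5, 10, 0)
  frames <- gen_prescribed_field_traj(sched, seed = 3)
  ax <- reaction_axis(c(1, "O1"), c(1, "C1"))
  got <- trajectory_axial_field(frames, ax, env)
  expect_equal(got, sched, tolerance = 1e-12)

  ## a constant schedule yields a zero-spread window mean
  const <- gen_prescribed_field_traj(rep(-37.1, 6), seed = 3)
  stats <- window_field_statistics(trajectory_axial_field(const, ax, env),
                                   discard_fraction = 0.5)
  expect_equal(stats$mean, -37.1, tolerance = 1e-12)
  expect_equal(stats$std, 0, tolerance = 1e-12)

  ## decoy charges in the perpendicular plane change nothing axial
  dec <- gen_prescribed_field_traj(sched, n_decoys = 8, seed = 3)
  got_dec <- trajectory_axial_field(dec, ax, env)
  expect_equal(got_dec, sched, tolerance = 1e-9)

  expect_error(gen_prescribed_field_traj(5000, charge_distance = 5),
               "infeasible")
})

test_that("a Gaussian field schedule reproduces state statistics", {
  set.seed(61)
  sched <- rnorm(2000, mean = -52.5, sd = 10.2)
  frames <- gen_prescribed_field_traj(sched, seed = 8)
  ax <- reaction_axis(c(1, "O1"), c(1, "C1"))
  stats <- window_field_statistics(
    trajectory_axial_field(frames, ax, selection(mode = "exclude")),
    discard_fraction = 0)
  expect_lt(abs(stats$mean - (-52.5)), 3 * 10.2 / sqrt(2000))
  expect_lt(abs(stats$std - 10.2), 1.5)
})

test_that("umbrella sampling is exact: moments and goodness of fit", {
  ## harmonic V = 2 x^2 without bias: Var(x) = RT / (2 * 2)
  V <- function(x) 2 * x^2
  wins <- sample_umbrella_windows(V, list(bias_spec(0, 0)),
                                  temperature = 343.15, n_samples = 1e5,
                                  support = c(-1.8, 1.8), seed = 23)
  RT <- fc_constants$R_kcal * 343.15
  expect_lt(abs(var(wins[[1]]$series$value) - RT / 4) / (RT / 4), 0.05)

  ## strongly biased window mean against adaptive quadrature
  wins2 <- sample_umbrella_windows(V, list(bias_spec(0.3, 500)),
                                   temperature = 343.15, n_samples = 2e4,
                                   support = c(-1.8, 1.8), seed = 24)
  ref <- oracle_biased_mean(V, 0.3, 500, 343.15, -1.8, 1.8)
  expect_lt(abs(mean(wins2[[1]]$series$value) - ref), 0.01)

  ## chi-squared goodness of fit on the double-well fixture
  pot <- model_potential("double_well", 5, 1)
  w <- sample_umbrella_windows(pot, list(bias_spec(0.5, 20)),
                               temperature = 343.15, n_samples = 2e4,
                               seed = 25)[[1]]
  RTk <- fc_constants$R_kcal * 343.15
  edges <- quantile(w$series$value, probs = seq(0, 1, length.out = 21))
  edges[1] <- -Inf; edges[21] <- Inf
  obs <- table(cut(w$series$value, edges))
  dens <- function(x) exp(-(pot$V(x) + 20 * (x - 0.5)^2) / RTk)
  Z <- integrate(dens, -2.5, 2.5, rel.tol = 1e-10)$value
  probs <- vapply(seq_len(20), function(i)
    integrate(dens, max(edges[i], -2.5), min(edges[i + 1], 2.5),
              rel.tol = 1e-9)$value / Z, numeric(1))
  gof <- chisq.test(as.numeric(obs), p = probs / sum(probs))
  expect_gt(gof$p.value, 0.01)

  expect_error(
    sample_umbrella_windows(function(x) 0 * x, list(bias_spec(0, 0)),
                            n_samples = 10),
    "nnormalizable")
})

test_that("toy active-site generation is deterministic and self-consistent", {
  s1 <- gen_toy_active_site(seed = 2)
  s2 <- gen_toy_active_site(seed = 2)
  expect_identical(s1$pdb_lines, s2$pdb_lines)   # byte-identical
  expect_false(identical(s1$pdb_lines, gen_toy_active_site(seed = 3)$pdb_lines))

  pdb <- withr::local_tempfile(fileext = ".pdb")
  writeLines(s1$pdb_lines, pdb)
  expect_no_warning(frame <- read_structure(pdb, s1$charge_table))
  triad <- selection(residues = s1$triad_residues, mode = "exclude")
  kept <- resolve_selection(frame, triad)
  n_triad <- sum(frame$atoms$residue_id %in% s1$triad_residues)
  expect_equal(nrow(frame$atoms) - length(kept), n_triad)
  expect_equal(n_triad, 12)   # three backbone-only residues

  ## the embedded axis pair resolves and yields a finite field
  fs <- axial_field(frame, s1$axis, triad)
  expect_true(is.finite(fs$axial_component))
})

test_that("generator manifests record spec and seed", {
  dir <- withr::local_tempdir()
  p <- write_manifest(dir, list(generator = "gen_point_charges",
                                n_charges = 50, seed = 14L))
  m <- jsonlite::read_json(p)
  expect_equal(m$seed, 14)
  expect_error(write_manifest(dir, list(generator = "x")), "seed")
})
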