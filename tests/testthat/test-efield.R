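everything <- selection(mode = "exclude")   # empty exclusion = all atoms

## one explicit charge added to a bare two-atom axis frame
frame_with_charge <- function(x, y, z, q) {
  g <- gen_point_charges(n_charges = 0, seed = 1)
  ext <- data.frame(serial = 99L, atom_name = "QX", residue_name = "CHG",
                    residue_id = 99L, chain = "", element = "X",
                    x = x, y = y, z = z, charge = q)
  list(frame = charged_frame(rbind(g$frame$atoms, ext)), axis = g$axis)
}

test_that("a unit charge 1 Angstrom past the head atom gives -1439.96 MV/cm", {
  ## axis atoms sit at z = -0.5 and +0.5, so z = 1.0 is 1 Angstrom beyond
  ## the midpoint on the head side; the field at the midpoint points away
  ## from the +1e charge, i.e. against the tail->head unit vector
  fc <- frame_with_charge(0, 0, 1.0, +1)
  fs <- axial_field(fc$frame, fc$axis, everything)
  expect_equal(fs$axial_component, -oracle_unit_charge_field(),
               tolerance = 1e-12)
  expect_equal(fs$axial_component, -1439.964548, tolerance = 1e-7)
  ## and the package constant itself matches the SI derivation
  expect_equal(fc_constants$coulomb_MV_cm, oracle_unit_charge_field(),
               tolerance = 1e-12)
})

test_that("charges in the perpendicular plane contribute no axial field", {
  for (ang in c(0, 1, 2.5, 4)) {
    fc <- frame_with_charge(3 * cos(ang), 3 * sin(ang), 0, 0.7)
    fs <- axial_field(fc$frame, fc$axis, everything)
    expect_lt(abs(fs$axial_component), 1e-9)
  }
})

test_that("the Coulomb sum matches the brute-force SI oracle on random frames", {
  for (seed in 1:20) {
    g <- gen_point_charges(n_charges = 50, box_size = 20, seed = seed)
    fs <- axial_field(g$frame, g$axis, everything)
    env <- g$frame$atoms[g$frame$atoms$residue_name == "CHG", ]
    ref <- oracle_coulomb_field(as.matrix(env[, c("x", "y", "z")]),
                                env$charge, c(0, 0, 0))
    expect_equal(fs$field_vector, ref, tolerance = 1e-10)
    expect_equal(fs$axial_component, ref[3], tolerance = 1e-10)
  }
})

test_that("superposition, charge scaling, and axis reversal hold", {
  g <- gen_point_charges(n_charges = 40, seed = 33)
  a <- g$frame$atoms
  env_ids <- a$residue_id[a$residue_name == "CHG"]
  half1 <- selection(residues = env_ids[1:20])
  half2 <- selection(residues = env_ids[21:40])
  f_all <- axial_field(g$frame, g$axis, everything)
  f1 <- axial_field(g$frame, g$axis, half1)
  f2 <- axial_field(g$frame, g$axis, half2)
  expect_equal(f_all$field_vector, f1$field_vector + f2$field_vector,
               tolerance = 1e-12)
  expect_equal(f_all$axial_component, f1$axial_component + f2$axial_component,
               tolerance = 1e-12)

  scaled <- g$frame
  scaled$atoms$charge <- scaled$atoms$charge * 0.25
  f_sc <- axial_field(scaled, g$axis, everything)
  expect_equal(f_sc$field_vector, 0.25 * f_all$field_vector,
               tolerance = 1e-12)

  rev_axis <- reaction_axis(g$axis$head, g$axis$tail, label = "rev")
  f_rev <- axial_field(g$frame, rev_axis, everything)
  expect_equal(f_rev$axial_component, -f_all$axial_component,
               tolerance = 1e-12)
  expect_equal(sqrt(sum(f_rev$field_vector^2)),
               sqrt(sum(f_all$field_vector^2)), tolerance = 1e-12)
})

test_that("axis atoms are always excluded and degenerate inputs error", {
  fc <- frame_with_charge(0, 0, 1.0, +1)
  ## give the axis atoms big charges: the result must not change
  a <- fc$frame$atoms
  a$charge[a$residue_name == "AXS"] <- 5
  f <- axial_field(charged_frame(a), fc$axis, everything)
  expect_equal(f$axial_component, -fc_constants$coulomb_MV_cm,
               tolerance = 1e-12)

  ## an environment atom at the probe point is a singularity
  g <- frame_with_charge(0, 0, 1e-9, 0.1)
  expect_error(axial_field(g$frame, g$axis, everything), "ingularity")

  coincident <- data.frame(
    serial = 1:2, atom_name = c("O1", "C1"), residue_name = "AXS",
    residue_id = 1L, x = 0, y = 0, z = 0.3, charge = 0)
  coincident$z <- c(0.3, 0.3)
  expect_error(
    axial_field(charged_frame(coincident),
                reaction_axis(c(1, "O1"), c(1, "C1")), everything),
    "egenerate")
})

test_that("window statistics discard the leading fraction and recover means", {
  s <- window_field_statistics(c(-40, -40, -30, -30), discard_fraction = 0.5)
  expect_equal(s$mean, -30)
  expect_equal(s$std, 0)
  expect_equal(s$n_samples, 2)

  s2 <- window_field_statistics(rep(-12.5, 50), discard_fraction = 0.8)
  expect_equal(s2$mean, -12.5)
  expect_equal(s2$std, 0)

  set.seed(91)
  x <- rnorm(1e4, mean = -37.1, sd = 11.1)
  s3 <- window_field_statistics(x, discard_fraction = 0.5)
  expect_equal(s3$n_samples, 5000)
  expect_lt(abs(s3$mean - (-37.1)), 3 * 11.1 / sqrt(5000))
  expect_error(window_field_statistics(c(-1, -2), discard_fraction = 0.6),
               "nsufficient")
})

test_that("field correlations are symmetric, bounded, and null for noise", {
  x <- sin(seq(0, 10, length.out = 200))
  m <- field_correlation(list(a = x, b = x, c = -x))
  expect_equal(diag(m), c(a = 1, b = 1, c = 1))
  expect_equal(m["a", "b"], 1)
  expect_equal(m["a", "c"], -1)
  expect_true(all(m >= -1 & m <= 1))
  expect_equal(m, t(m))

  set.seed(7)
  g1 <- rnorm(1000); g2 <- rnorm(1000)
  m2 <- field_correlation(list(p = g1, q = g2))
  expect_lt(abs(m2["p", "q"]), 0.1)

  expect_error(field_correlation(list(a = rep(1, 10), b = rnorm(10))),
               "constant series.*a")
})
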