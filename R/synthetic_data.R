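## Seeded generators producing every input the pipeline consumes, each with
## analytically known ground truth: random point-charge environments with a
## brute-force companion field, trajectories whose axial field follows a
## prescribed schedule exactly, exactly-Boltzmann umbrella windows, and a
## toy active-site structure for selection tests.

default_axis_frame_atoms <- function(axis, axis_length = 1.0) {
  ## two axis atoms along z, midpoint at the origin
  data.frame(
    serial = 1:2,
    atom_name = c(axis$tail$atom_name, axis$head$atom_name),
    residue_name = "AXS",
    residue_id = c(axis$tail$residue_id, axis$head$residue_id),
    chain = "", element = "C",
    x = c(0, 0), y = c(0, 0),
    z = c(-axis_length / 2, axis_length / 2),
    charge = 0,
    stringsAsFactors = FALSE
  )
}

#' Generate a random point-charge environment with a known analytic field
#'
#' Places `n_charges` uniform charges in a cubic box centered on the probe
#' point (a 2 Angstrom exclusion sphere around the probe avoids
#' singularities) around a 1 Angstrom axis along z, and records the field
#' at the axis midpoint by an independent brute-force Coulomb accumulation
#' so the main field evaluation can be checked against it.
#'
#' @param n_charges number of environment charges.
#' @param box_size cube edge, Angstrom.
#' @param seed integer seed (bitwise reproducible).
#' @param axis a [reaction_axis()]; defaults to an O1-C1 style axis on
#'   residue 1.
#' @return List: `frame` ([charged_frame()]), `axis`, `expected_field`
#'   (3-vector, MV/cm), `expected_axial` (MV/cm), `seed`.
#' @export
gen_point_charges <- function(n_charges = 50, box_size = 20, seed = 1L,
                              axis = NULL) {
  if (is.null(axis))
    axis <- reaction_axis(c(1, "O1"), c(1, "C1"), label = "O1-C1")
  set.seed(seed)
  ax_atoms <- default_axis_frame_atoms(axis)
  r0 <- c(0, 0, 0)
  pos <- matrix(numeric(0), ncol = 3)
  while (nrow(pos) < n_charges) {
    cand <- matrix(stats::runif(3 * (n_charges - nrow(pos)),
                                -box_size / 2, box_size / 2), ncol = 3)
    ok <- sqrt(rowSums(sweep(cand, 2, r0)^2)) > 2
    pos <- rbind(pos, cand[ok, , drop = FALSE])
  }
  q <- if (n_charges > 0) stats::runif(n_charges, -1, 1) else numeric(0)
  env_atoms <- if (n_charges > 0) data.frame(
    serial = 2 + seq_len(n_charges),
    atom_name = "Q1", residue_name = "CHG",
    residue_id = 100 + seq_len(n_charges),
    chain = "", element = "X",
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    charge = q, stringsAsFactors = FALSE
  ) else NULL
  frame <- charged_frame(rbind(ax_atoms, env_atoms), frame_time = 0)
  ## brute-force companion: plain per-charge loop, kept independent of
  ## axial_field()'s vectorized path
  Fvec <- c(0, 0, 0)
  K <- fc_constants$coulomb_MV_cm
  for (i in seq_len(n_charges)) {
    d <- r0 - pos[i, ]
    r <- sqrt(sum(d * d))
    Fvec <- Fvec + K * q[i] * d / r^3
  }
  u <- c(0, 0, 1)
  list(frame = frame, axis = axis, expected_field = Fvec,
       expected_axial = sum(Fvec * u), seed = as.integer(seed))
}

#' Generate frames whose axial field follows a prescribed schedule exactly
#'
#' Each frame carries the two axis atoms plus a +/- charge pair on the axis
#' line at distance `charge_distance` from the midpoint, with magnitudes
#' solved in closed form so the axial field at the midpoint equals the
#' scheduled value exactly. Optional decoy charges sit in the plane through
#' the midpoint perpendicular to the axis and contribute exactly zero axial
#' field by symmetry. This makes the field pipeline self-validating: the
#' schedule is recovered to machine precision.
#'
#' @param schedule numeric vector of target axial fields, MV/cm (one per
#'   frame); e.g. draws around a reactant-state mean drifting to a
#'   transition-state mean.
#' @param axis a [reaction_axis()] (default O1-C1 style on residue 1).
#' @param charge_distance distance of the solver charges from the midpoint,
#'   Angstrom.
#' @param n_decoys decoy charges per frame in the perpendicular plane.
#' @param dt_ps frame spacing, ps.
#' @param seed integer seed (used only for decoys).
#' @return List of [charged_frame()] objects, one per schedule entry.
#' @export
gen_prescribed_field_traj <- function(schedule, axis = NULL,
                                      charge_distance = 5, n_decoys = 0,
                                      dt_ps = 0.006, seed = 1L) {
  if (is.null(axis))
    axis <- reaction_axis(c(1, "O1"), c(1, "C1"), label = "O1-C1")
  stopifnot(all(is.finite(schedule)), charge_distance > 2)
  K <- fc_constants$coulomb_MV_cm
  d <- charge_distance
  ## tail-side charge +q at z = -d, head-side -q at z = +d:
  ## axial field at origin = 2 K q / d^2  =>  q = F d^2 / (2 K)
  q_tail <- schedule * d^2 / (2 * K)
  if (any(abs(q_tail) > 10))
    stop(sprintf(
      "infeasible schedule: field %.1f MV/cm needs |q| = %.1f e > 10 e at %.1f Angstrom",
      schedule[which.max(abs(q_tail))], max(abs(q_tail)), d))
  set.seed(seed)
  lapply(seq_along(schedule), function(i) {
    ax_atoms <- default_axis_frame_atoms(axis)
    src <- data.frame(
      serial = 3:4, atom_name = c("QT", "QH"), residue_name = "SRC",
      residue_id = c(50L, 51L), chain = "", element = "X",
      x = 0, y = 0, z = c(-d, d),
      charge = c(q_tail[i], -q_tail[i]), stringsAsFactors = FALSE)
    dec <- NULL
    if (n_decoys > 0) {
      rho <- stats::runif(n_decoys, 3, 8)
      th <- stats::runif(n_decoys, 0, 2 * pi)
      dec <- data.frame(
        serial = 4 + seq_len(n_decoys), atom_name = "QD",
        residue_name = "DEC", residue_id = 60L + seq_len(n_decoys),
        chain = "", element = "X",
        x = rho * cos(th), y = rho * sin(th), z = 0,
        charge = stats::runif(n_decoys, -1, 1), stringsAsFactors = FALSE)
    }
    charged_frame(rbind(ax_atoms, src, dec), frame_time = (i - 1) * dt_ps)
  })
}

#' Exactly Boltzmann-distributed umbrella windows from a known potential
#'
#' Draws coordinate samples from the biased density
#' `exp(-(V(x) + U_bias(x)) / RT)` by inverse-CDF sampling on a 1e4-point
#' grid — no Markov chain, hence no burn-in or autocorrelation confounds
#' when the windows are fed to the WHAM solver.
#'
#' @param potential a [model_potential()] or a plain function `V(x)`
#'   (kcal/mol).
#' @param biases list of [bias_spec()] objects, one window each.
#' @param temperature K.
#' @param n_samples samples per window.
#' @param support length-2 numeric sampling support, Angstrom; defaults to
#'   2.5x the half-separation for a double-well [model_potential()].
#'   Required otherwise when any bias has zero force constant.
#' @param seed integer seed.
#' @param dt_ps nominal sample spacing, ps.
#' @return List of [umbrella_window()] objects.
#' @export
sample_umbrella_windows <- function(potential, biases, temperature = 343.15,
                                    n_samples = 1000, support = NULL,
                                    seed = 1L, dt_ps = 0.006) {
  V <- if (inherits(potential, "model_potential")) potential$V else potential
  stopifnot(is.function(V), length(biases) >= 1, n_samples >= 1)
  if (is.null(support)) {
    if (inherits(potential, "model_potential") &&
        potential$form == "double_well") {
      w <- potential$half_separation
      support <- c(-2.5 * w, 2.5 * w)
    } else if (any(vapply(biases, function(b) b$force_constant == 0,
                          logical(1)))) {
      stop("unnormalizable density: zero force constant with no sampling support")
    } else {
      ctr <- vapply(biases, function(b) b$center, numeric(1))
      kf <- vapply(biases, function(b) b$force_constant, numeric(1))
      RT <- fc_constants$R_kcal * temperature
      pad <- max(6 * sqrt(RT / (2 * kf)))
      support <- c(min(ctr) - pad, max(ctr) + pad)
    }
  }
  RT <- fc_constants$R_kcal * temperature
  xg <- seq(support[1], support[2], length.out = 1e4)
  set.seed(seed)
  lapply(biases, function(b) {
    logw <- -(V(xg) + bias_energy(b, xg)) / RT
    w <- exp(logw - max(logw))
    cdf <- cumsum((w[-1] + w[-length(w)]) / 2)
    cdf <- c(0, cdf / cdf[length(cdf)])
    u <- stats::runif(n_samples)
    x <- stats::approx(cdf, xg, xout = u, ties = "ordered")$y
    umbrella_window(b, window_series((seq_len(n_samples) - 1) * dt_ps, x))
  })
}

#' Generate a toy active-site structure as PDB text plus a charge table
#'
#' An eight-residue mini-protein whose residue ids include a catalytic
#' triad (Ser165, Asp210, His242) and a bound substrate fragment carrying
#' an O1-C1 axis pair — just enough structure to exercise the PDB reader,
#' charge assignment and the triad-exclusion selection. Deterministic:
#' the same seed yields byte-identical PDB text.
#'
#' @param seed integer seed for coordinate jitter.
#' @return List: `pdb_lines` (character vector of fixed-column PDB),
#'   `charge_table` (data.frame residue_name, atom_name, charge), `axis`
#'   (the substrate [reaction_axis()]), `triad_residues` (165, 210, 242),
#'   `seed`.
#' @export
gen_toy_active_site <- function(seed = 1L) {
  set.seed(seed)
  res <- data.frame(
    residue_id = c(95L, 130L, 165L, 180L, 210L, 230L, 242L, 260L),
    residue_name = c("TYR", "GLY", "SER", "ALA", "ASP", "LEU", "HIS", "MET"),
    stringsAsFactors = FALSE)
  bb_names <- c("N", "CA", "C", "O")
  bb_elems <- c("N", "C", "C", "O")
  bb_charges <- c(-0.4157, 0.0337, 0.5973, -0.5679)
  atoms <- do.call(rbind, lapply(seq_len(nrow(res)), function(i) {
    base <- c(4 * i, 2 * sin(i), 2 * cos(i))   # loose helical walk
    jit <- matrix(round(stats::rnorm(12, 0, 0.3), 3), ncol = 3)
    offs <- matrix(c(0, 0, 0, 1.46, 0, 0, 2.43, 1.1, 0, 3.2, 1.2, 1.0),
                   ncol = 3, byrow = TRUE)
    data.frame(residue_id = res$residue_id[i],
               residue_name = res$residue_name[i],
               atom_name = bb_names, element = bb_elems,
               x = round(base[1] + offs[, 1] + jit[, 1], 3),
               y = round(base[2] + offs[, 2] + jit[, 2], 3),
               z = round(base[3] + offs[, 3] + jit[, 3], 3),
               stringsAsFactors = FALSE)
  }))
  sub <- data.frame(residue_id = 301L, residue_name = "PET",
                    atom_name = c("C1", "O1", "O2"),
                    element = c("C", "O", "O"),
                    x = c(16.0, 14.9, 16.6), y = c(0.5, 0.9, -0.4),
                    z = c(2.0, 2.6, 1.2), stringsAsFactors = FALSE)
  atoms <- rbind(atoms, sub)
  atoms$serial <- seq_len(nrow(atoms))
  rec <- ifelse(atoms$residue_name == "PET", "HETATM", "ATOM  ")
  pdb_lines <- sprintf(
    "%s%5d  %-3s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    rec, atoms$serial, atoms$atom_name, atoms$residue_name,
    atoms$residue_id, atoms$x, atoms$y, atoms$z, 1.00, 0.00, atoms$element)
  pdb_lines <- c(pdb_lines, "END")
  charge_table <- unique(data.frame(
    residue_name = atoms$residue_name, atom_name = atoms$atom_name,
    stringsAsFactors = FALSE))
  bb_map <- stats::setNames(bb_charges, bb_names)
  sub_map <- c(C1 = 0.70, O1 = -0.60, O2 = -0.55)
  charge_table$charge <- ifelse(
    charge_table$residue_name == "PET",
    sub_map[charge_table$atom_name],
    bb_map[charge_table$atom_name])
  list(pdb_lines = pdb_lines, charge_table = charge_table,
       axis = reaction_axis(c(301, "O1"), c(301, "C1"), label = "O1-C1"),
       triad_residues = c(165L, 210L, 242L), seed = as.integer(seed))
}

#' Write a generator manifest recording spec and seed
#'
#' @param dir output directory (created if needed).
#' @param spec named list describing the generator call (must include
#'   `seed`).
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(dir, spec) {
  stopifnot(!is.null(spec$seed))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
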