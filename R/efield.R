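## Internal electric field at the midpoint of a reaction axis: bare Coulomb
## sum over a point-charge environment, projected onto the axis, in MV/cm.

#' Define a reaction axis
#'
#' An ordered atom pair defining a field-projection direction. The unit
#' vector points tail -> head in the order the axis is named ("O1-C1" means
#' O1 -> C1); the field probe point is the midpoint of the two
#' instantaneous atom positions.
#'
#' @param tail_atom,head_atom length-2 specs `c(residue_id, atom_name)` or
#'   lists `list(residue_id =, atom_name =)`.
#' @param label axis label, e.g. `"N1-H1"`.
#' @return An object of class `reaction_axis`.
#' @export
reaction_axis <- function(tail_atom, head_atom, label = NULL) {
  norm_spec <- function(s) {
    if (is.list(s)) list(residue_id = as.integer(s$residue_id),
                         atom_name = as.character(s$atom_name))
    else list(residue_id = as.integer(s[[1]]), atom_name = as.character(s[[2]]))
  }
  tail_atom <- norm_spec(tail_atom); head_atom <- norm_spec(head_atom)
  if (identical(tail_atom, head_atom))
    stop("axis tail and head atoms must differ")
  if (is.null(label))
    label <- paste0(tail_atom$atom_name, "-", head_atom$atom_name)
  structure(list(tail = tail_atom, head = head_atom, label = label),
            class = "reaction_axis")
}

axis_atom_index <- function(frame, spec) {
  i <- which(frame$atoms$residue_id == spec$residue_id &
               frame$atoms$atom_name == spec$atom_name)
  if (length(i) != 1)
    stop(sprintf("axis atom %s of residue %d not found uniquely in frame",
                 spec$atom_name, spec$residue_id))
  i
}

#' Axial internal electric field at a reaction-axis midpoint
#'
#' Evaluates the bare Coulomb field
#' `F = K * sum_i q_i (r0 - r_i) / |r0 - r_i|^3` at the midpoint `r0` of
#' the axis atoms, with charges in elementary units and distances in
#' Angstrom, and `K = fc_constants$coulomb_MV_cm` the single conversion to
#' MV/cm. No periodic images and no cutoff: every selected environment atom
#' contributes. The axial component is the projection onto the tail->head
#' unit vector, so a negative value points head -> tail.
#'
#' @param frame a [charged_frame()]; all atoms must carry charges.
#' @param axis a [reaction_axis()]; both atoms must be present.
#' @param environment an [selection()] naming the environment atoms.
#'   The two axis atoms are always removed from the environment regardless
#'   of the selection.
#' @return A list of class `field_sample` with `frame_time` (ps),
#'   `field_vector` (3-vector, MV/cm) and `axial_component` (MV/cm).
#' @export
axial_field <- function(frame, axis, environment) {
  stopifnot(inherits(frame, "charged_frame"), inherits(axis, "reaction_axis"))
  a <- frame$atoms
  it <- axis_atom_index(frame, axis$tail)
  ih <- axis_atom_index(frame, axis$head)
  pt <- c(a$x[it], a$y[it], a$z[it])
  ph <- c(a$x[ih], a$y[ih], a$z[ih])
  u <- ph - pt
  nu <- sqrt(sum(u^2))
  if (nu < 1e-9) stop("degenerate axis: tail and head atoms coincident")
  u <- u / nu
  r0 <- (pt + ph) / 2
  env_idx <- setdiff(resolve_selection(frame, environment), c(it, ih))
  fv <- c(0, 0, 0)
  if (length(env_idx) > 0) {
    dx <- r0[1] - a$x[env_idx]
    dy <- r0[2] - a$y[env_idx]
    dz <- r0[3] - a$z[env_idx]
    r2 <- dx * dx + dy * dy + dz * dz
    if (any(r2 < 1e-12))
      stop("singularity: environment atom within 1e-6 Angstrom of the probe point")
    w <- a$charge[env_idx] / (r2 * sqrt(r2))
    fv <- fc_constants$coulomb_MV_cm *
      c(sum(w * dx), sum(w * dy), sum(w * dz))
  }
  structure(list(frame_time = frame$frame_time,
                 field_vector = fv,
                 axial_component = sum(fv * u),
                 axis_label = axis$label),
            class = "field_sample")
}

#' Per-window field statistics after equilibration discard
#'
#' Mean and sample standard deviation of the axial field over the retained
#' tail of a time-ordered series of field samples. The default discard of
#' the first half mirrors analysing the last 15 ps of 30-ps windows.
#'
#' @param samples list of `field_sample` objects (time-ordered) or a
#'   numeric vector of axial components.
#' @param discard_fraction fraction of leading samples dropped, in [0, 1).
#' @return A list of class `field_statistics`: `mean`, `std` (n-1), both
#'   MV/cm, `n_samples`, `discarded_fraction`.
#' @export
window_field_statistics <- function(samples, discard_fraction = 0.5) {
  if (!(discard_fraction >= 0 && discard_fraction < 1))
    stop("discard_fraction must be in [0, 1)")
  ax <- if (is.numeric(samples)) samples
        else vapply(samples, function(s) s$axial_component, numeric(1))
  n_total <- length(ax)
  keep <- ax[(floor(n_total * discard_fraction) + 1L):n_total]
  if (length(keep) < 2)
    stop("insufficient data: fewer than 2 retained samples")
  structure(list(mean = mean(keep), std = stats::sd(keep),
                 n_samples = length(keep),
                 discarded_fraction = discard_fraction),
            class = "field_statistics")
}

#' Pearson correlation matrix of axial fields across reaction axes
#'
#' A plain linear-association summary of how the fields along different
#' reaction axes co-fluctuate on a common frame grid.
#'
#' @param per_axis_series named list, one numeric series of axial
#'   components per axis, all of equal length >= 3.
#' @return Symmetric correlation matrix with unit diagonal, dimnames the
#'   axis labels.
#' @export
field_correlation <- function(per_axis_series) {
  if (length(per_axis_series) < 2) stop("need at least 2 axes")
  lens <- vapply(per_axis_series, length, 1L)
  if (length(unique(lens)) != 1 || lens[1] < 3)
    stop("series must have equal lengths >= 3")
  sds <- vapply(per_axis_series, stats::sd, numeric(1))
  if (any(sds == 0))
    stop("undefined correlation: constant series for axis ",
         paste(names(per_axis_series)[sds == 0], collapse = ", "))
  stats::cor(do.call(cbind, per_axis_series))
}

#' Evaluate one axis over a trajectory of frames
#'
#' @param frames list of [charged_frame()] objects (one trajectory).
#' @param axis a [reaction_axis()].
#' @param environment an [selection()].
#' @return Numeric vector of axial components (MV/cm), one per frame.
#' @export
trajectory_axial_field <- function(frames, axis, environment) {
  vapply(frames, function(fr) axial_field(fr, axis, environment)$axial_component,
         numeric(1))
}
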