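## Stark response of reaction states to axial electric fields, and the
## static/dynamic decomposition of field-induced barrier shifts.

#' Construct a per-state Stark model
#'
#' Energy of a state in an axial field `F` (MV/cm):
#' `E(F) = e0 - mu c F - alpha c F^2 / 2`, with `c`
#' (`fc_constants$debye_MV_cm_kcal`, ~0.048 kcal/mol per D per MV/cm)
#' converting Debye x MV/cm to kcal/mol. A dipole parallel to a positive
#' field stabilizes the state (negative energy); `F` is measured along the
#' reaction axis's tail -> head direction.
#'
#' @param label state label ("RC", "TS1", ...).
#' @param e0 zero-field energy, kcal/mol (relative scale).
#' @param mu axial dipole-difference coefficient, D.
#' @param alpha axial polarizability coefficient, D cm/MV (0 for a linear
#'   model).
#' @param mu_se,alpha_se optional fitted standard errors.
#' @param residual_rms optional fit residual RMS, kcal/mol.
#' @return Object of class `stark_model` with an `energy(F)` closure.
#' @export
stark_model <- function(label, e0, mu, alpha = 0,
                        mu_se = NA_real_, alpha_se = NA_real_,
                        residual_rms = NA_real_) {
  stopifnot(is.finite(e0), is.finite(mu), is.finite(alpha))
  cc <- fc_constants$debye_MV_cm_kcal
  obj <- list(label = label, e0 = e0, mu = mu, alpha = alpha,
              mu_se = mu_se, alpha_se = alpha_se,
              residual_rms = residual_rms)
  obj$energy <- function(F) e0 - mu * cc * F - 0.5 * alpha * cc * F^2
  structure(obj, class = "stark_model")
}

#' Fit a Stark model to a field-energy scan table
#'
#' Least-squares fit of `E(F) = e0 - mu c F [- alpha c F^2 / 2]` to a
#' per-state scan of energies under applied axial fields (the kind of table
#' a gas-phase QM field scan produces). With exactly `order + 1` distinct
#' field points the fit interpolates exactly.
#'
#' @param field_energy_table data.frame (or 2-column matrix) with fields in
#'   MV/cm and energies in kcal/mol.
#' @param order 1 (linear Stark) or 2 (adds polarizability).
#' @param label state label carried into the model.
#' @return A [stark_model()] with fitted standard errors and residual RMS.
#' @export
fit_stark_model <- function(field_energy_table, order = 1, label = "state") {
  stopifnot(order %in% c(1, 2))
  tab <- as.data.frame(field_energy_table)
  names(tab)[1:2] <- c("field", "energy")
  if (anyDuplicated(tab$field))
    stop("fit error: duplicate field values make the design rank-deficient")
  if (nrow(tab) < order + 1)
    stop(sprintf("fit error: need >= %d distinct field points for order %d",
                 order + 1, order))
  cc <- fc_constants$debye_MV_cm_kcal
  X <- cbind(e0 = 1, mu = -cc * tab$field)
  if (order == 2) X <- cbind(X, alpha = -0.5 * cc * tab$field^2)
  fit <- stats::lm.fit(X, tab$energy)
  beta <- fit$coefficients
  dof <- nrow(tab) - length(beta)
  rms <- sqrt(mean(fit$residuals^2))
  se <- rep(NA_real_, length(beta))
  if (dof > 0) {
    sigma2 <- sum(fit$residuals^2) / dof
    XtXinv <- chol2inv(chol(crossprod(X)))
    se <- sqrt(sigma2 * diag(XtXinv))
  }
  stark_model(label = label, e0 = beta[["e0"]], mu = beta[["mu"]],
              alpha = if (order == 2) beta[["alpha"]] else 0,
              mu_se = se[2],
              alpha_se = if (order == 2) se[3] else NA_real_,
              residual_rms = rms)
}

#' Decompose a field-induced barrier shift into static and dynamic parts
#'
#' The barrier change caused by the environment's field splits into the
#' part both states would feel if they shared the reactant-state field
#' (static) and the extra stabilization the transition state gains because
#' its own mean field differs (dynamic):
#' \itemize{
#'   \item `static_part = [E_ts(F_rc) - E_rc(F_rc)] - [E_ts(0) - E_rc(0)]`
#'   \item `dynamic_extra = E_ts(F_ts) - E_ts(F_rc)`
#'   \item `total = [E_ts(F_ts) - E_rc(F_rc)] - [E_ts(0) - E_rc(0)]`
#' }
#' so `total = static_part + dynamic_extra` identically. Negative values
#' mean barrier lowering.
#'
#' @param rc,ts [stark_model()] objects for the reactant-side state and the
#'   transition state.
#' @param f_reactant,f_ts mean axial fields of the two states, MV/cm.
#' @return List of class `barrier_modulation`: `total`, `static_part`,
#'   `dynamic_extra` (kcal/mol), `f_reactant`, `f_ts`.
#' @export
decompose_dynamic_shift <- function(rc, ts, f_reactant, f_ts) {
  stopifnot(inherits(rc, "stark_model"), inherits(ts, "stark_model"))
  static_part <- (ts$energy(f_reactant) - rc$energy(f_reactant)) -
    (ts$energy(0) - rc$energy(0))
  dynamic_extra <- ts$energy(f_ts) - ts$energy(f_reactant)
  total <- (ts$energy(f_ts) - rc$energy(f_reactant)) -
    (ts$energy(0) - rc$energy(0))
  structure(list(total = total, static_part = static_part,
                 dynamic_extra = dynamic_extra,
                 f_reactant = f_reactant, f_ts = f_ts),
            class = "barrier_modulation")
}

#' Barrier shift as a function of an applied axial field
#'
#' Same-field-for-both-states convention (both states experience the
#' applied field `F`): returns `dG(F) - dG(0)` pointwise over a field
#' grid. In the linear case the curve is a line with slope
#' `-(ts$mu - rc$mu) c`.
#'
#' @param rc,ts [stark_model()] objects.
#' @param field_grid fields, MV/cm (nonempty).
#' @return data.frame with columns `field` and `barrier_shift` (kcal/mol).
#' @export
barrier_vs_field_curve <- function(rc, ts, field_grid) {
  stopifnot(length(field_grid) >= 1)
  shift <- (ts$energy(field_grid) - rc$energy(field_grid)) -
    (ts$energy(0) - rc$energy(0))
  data.frame(field = field_grid, barrier_shift = shift)
}
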