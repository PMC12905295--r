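## Eyring transition-state-theory conversion between free-energy barriers
## and first-order rate constants.

#' Rate constant from a free-energy barrier (Eyring equation)
#'
#' `k = kappa (k_B T / h) exp(-dG / (R T))` with `dG` in kcal/mol and
#' `R = 1.987204e-3` kcal/mol/K. Strictly decreasing in `dg` and linear in
#' the transmission coefficient.
#'
#' @param dg activation free energy, kcal/mol.
#' @param temperature K, > 0.
#' @param transmission_coefficient dimensionless `kappa` (default 1).
#' @return Rate constant, 1/s.
#' @export
#' @examples
#' eyring_rate(0, 298.15)          # k_B T / h ~ 6.21e12 s^-1
#' eyring_rate(10.7, 298.15)       # ~9e4 s^-1, i.e. of order 1e5
eyring_rate <- function(dg, temperature, transmission_coefficient = 1) {
  stopifnot(temperature > 0)
  pre <- fc_constants$kB_J_per_K * temperature / fc_constants$h_J_s
  transmission_coefficient * pre *
    exp(-dg / (fc_constants$R_kcal * temperature))
}

#' Free-energy barrier from a rate constant (inverse Eyring)
#'
#' Exact inverse of [eyring_rate()]:
#' `dG = -R T log(k h / (kappa k_B T))`.
#'
#' @param rate rate constant, 1/s, > 0.
#' @param temperature K, > 0.
#' @param transmission_coefficient dimensionless `kappa` (default 1).
#' @return Activation free energy, kcal/mol.
#' @export
#' @examples
#' eyring_barrier(1.6, 298.15)     # ~17.17 kcal/mol
#' eyring_barrier(0.3, 298.15)     # ~18.17 kcal/mol
eyring_barrier <- function(rate, temperature, transmission_coefficient = 1) {
  stopifnot(rate > 0, temperature > 0)
  pre <- fc_constants$kB_J_per_K * temperature / fc_constants$h_J_s
  -fc_constants$R_kcal * temperature *
    log(rate / (transmission_coefficient * pre))
}

#' Barrier/rate pair with consistency enforced
#'
#' Convenience record tying a barrier and a rate together at a stated
#' temperature; supply exactly one of `dg` or `rate` and the other is
#' computed.
#'
#' @param dg kcal/mol (or `NULL`).
#' @param rate 1/s (or `NULL`).
#' @param temperature K.
#' @param transmission_coefficient dimensionless (default 1).
#' @return List of class `rate_barrier` with both quantities, the
#'   temperature and `kappa`.
#' @export
rate_barrier <- function(dg = NULL, rate = NULL, temperature,
                         transmission_coefficient = 1) {
  if (is.null(dg) == is.null(rate))
    stop("supply exactly one of dg or rate")
  if (is.null(rate))
    rate <- eyring_rate(dg, temperature, transmission_coefficient)
  else
    dg <- eyring_barrier(rate, temperature, transmission_coefficient)
  structure(list(dg = dg, rate = rate, temperature = temperature,
                 transmission_coefficient = transmission_coefficient),
            class = "rate_barrier")
}
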