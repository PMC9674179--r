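#' Thermodynamic context
#'
#' Bundles the temperature, gas constant and standard concentration used for
#' dissociation-constant conversions and equilibrium-shift ratios. The
#' default temperature is 300 K with R = 0.0019872 kcal/mol/K, so that
#' RT = 0.596 kcal/mol.
#'
#' @param temperature Kelvin
#' @param gas_constant kcal/mol/K
#' @param standard_concentration molar
#' @return object of class `thermo_context`
#' @export
thermo_context <- function(temperature = 300,
                           gas_constant = 0.0019872,
                           standard_concentration = 1) {
  stopifnot(temperature > 0, gas_constant > 0, standard_concentration > 0)
  structure(list(temperature = temperature, gas_constant = gas_constant,
                 standard_concentration = standard_concentration),
            class = "thermo_context")
}

rt_of <- function(ctx) ctx$gas_constant * ctx$temperature

#' Convert a dissociation constant to a binding free energy
#'
#' \eqn{\Delta G = -RT \ln(K_d / c^0)}, reported as the (positive) magnitude
#' of the binding affinity for sub-molar Kd. A micromolar-range Kd at 300 K
#' gives affinities in the familiar 6-9 kcal/mol range.
#'
#' @param kd dissociation constant, molar
#' @param ctx a [thermo_context()]
#' @return binding free energy, kcal/mol
#' @export
kd_to_dg <- function(kd, ctx = thermo_context()) {
  if (any(!is.finite(kd)) || any(kd <= 0))
    stop("kd must be positive and finite")
  -rt_of(ctx) * log(kd / ctx$standard_concentration)
}

#' Convert a binding free energy to a dissociation constant
#'
#' Inverse of [kd_to_dg()]: \eqn{K_d = c^0 \exp(-\Delta G / RT)}.
#'
#' @param dg binding free energy, kcal/mol
#' @param ctx a [thermo_context()]
#' @return dissociation constant, molar
#' @export
dg_to_kd <- function(dg, ctx = thermo_context()) {
  stopifnot(all(is.finite(dg)))
  ctx$standard_concentration * exp(-dg / rt_of(ctx))
}

#' Equilibrium shift ratio implied by an affinity difference
#'
#' The Boltzmann partitioning ratio \eqn{\exp(\Delta\Delta G / RT)}: with an
#' affinity difference of 2 kcal/mol at 300 K the mRNA pool partitions about
#' 29:1 towards the higher-affinity binder. An optional abundance factor
#' multiplies the ratio when the two binding species are not equally
#' abundant (default 1, the equal-abundance assumption).
#'
#' @param ddg affinity difference, kcal/mol
#' @param ctx a [thermo_context()]
#' @param abundance_factor ratio of binder abundances (default 1)
#' @return dimensionless ratio
#' @export
shift_ratio <- function(ddg, ctx = thermo_context(), abundance_factor = 1) {
  stopifnot(all(is.finite(ddg)), abundance_factor > 0)
  abundance_factor * exp(ddg / rt_of(ctx))
}
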