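#' Assemble the standard demonstration system
#'
#' Builds the synthetic two-domain receptor with its 5-nt RNA ligand, the
#' planted reference complex, the residue-base potential calibrated from
#' its atomic contact counts at scale `lambda`, and the structure-based
#' topology of the bound complex. This is the system every simulation
#' stage of the pipeline runs on.
#'
#' @param lambda global residue-base scale
#' @param spec a [synthetic_spec()]
#' @param topology_params overrides for [build_topology()]
#' @return list with `receptor` (open/closed pair), `complex` (reference
#'   complex with ligand), `potential`, `topology`, and the contact
#'   `counts` table
#' @export
demo_system <- function(lambda = 1, spec = synthetic_spec(),
                        topology_params = list()) {
  receptor <- make_two_domain_receptor(spec)
  cx <- make_reference_complex(spec)
  counts <- count_atomic_contacts(cx)
  pot <- build_residue_base_potential(counts, lambda = lambda)
  topo <- build_topology(cx, pot, params = topology_params)
  list(receptor = receptor, complex = cx, potential = pot,
       topology = topo, counts = counts, spec = spec)
}

#' Estimate the RNA-binding affinity by umbrella sampling and WHAM
#'
#' Runs an umbrella series over the ligand-pocket distance R, reconstructs
#' the 1D free-energy profile with WHAM, and extracts the binding free
#' energy (unbound plateau minus bound minimum).
#'
#' @param topology a `cg_topology` containing the ligand
#' @param base_biases biases applied in every window (e.g. a tether)
#' @param window_centers umbrella centers, Angstrom
#' @param k_bias umbrella spring constant
#' @param n_steps_per_window integration steps per window
#' @param temperature Kelvin
#' @param seed integer
#' @param bins WHAM bins
#' @param n_boot bootstrap replicates for the error bar
#' @param ... passed to [run_umbrella_series()]
#' @return list with `affinity` (a `binding_affinity`), `surface`, and
#'   `dataset`
#' @export
estimate_affinity <- function(topology, base_biases = list(),
                              window_centers = seq(4, 30, length.out = 14),
                              k_bias = 2, n_steps_per_window = 2e5,
                              temperature = 300, seed = 1, bins = 50,
                              n_boot = 30, ...) {
  ds <- run_umbrella_series(topology, base_biases = base_biases,
                            window_centers = window_centers,
                            k_bias = k_bias,
                            n_steps_per_window = n_steps_per_window,
                            temperature = temperature, seed = seed, ...)
  surf <- wham(ds, bins = bins, n_boot = n_boot)
  aff <- binding_free_energy(surf)
  list(affinity = aff, surface = surf, dataset = ds)
}

#' Calibrate the residue-base potential scale to a target affinity
#'
#' Bracketed root search on the global scale lambda (regula falsi with a
#' midpoint fallback): the umbrella/WHAM affinity is re-estimated at each
#' trial scale until the achieved binding free energy lies within
#' `tolerance` of the target. The affinity is monotone non-decreasing in
#' lambda (deeper wells bind tighter); the sampled history is checked for
#' violations beyond the statistical errors.
#'
#' @param system_builder function(lambda) returning a `cg_topology`
#' @param target target affinity, kcal/mol (> 0)
#' @param tolerance kcal/mol, default 0.5
#' @param lambda_bracket initial search interval
#' @param max_expand bracket doublings allowed on each side
#' @param max_iter interpolation iterations, default 10
#' @param seed integer; trial evaluations derive their seeds from it
#' @param ... passed to [estimate_affinity()]
#' @return list with `lambda`, `affinity` (achieved, with `dg` and `se`),
#'   `surface`, and the evaluation `history`
#' @export
calibrate_scale <- function(system_builder, target = 8, tolerance = 0.5,
                            lambda_bracket = c(0.4, 3), max_expand = 3,
                            max_iter = 10, seed = 1, ...) {
  stopifnot(target > 0, tolerance > 0)
  history <- data.frame(lambda = numeric(0), dg = numeric(0),
                        se = numeric(0))
  eval_at <- function(lambda, k) {
    est <- estimate_affinity(system_builder(lambda),
                             seed = (seed + 104729L * k) %% 2147483647L,
                             ...)
    history <<- rbind(history, data.frame(lambda = lambda,
                                          dg = est$affinity$dg,
                                          se = est$affinity$se))
    est
  }
  lo <- lambda_bracket[1]; hi <- lambda_bracket[2]
  k <- 0L
  est_lo <- eval_at(lo, k <- k + 1L)
  if (abs(est_lo$affinity$dg - target) <= tolerance)
    return(list(lambda = lo, affinity = est_lo$affinity,
                surface = est_lo$surface, history = history))
  est_hi <- eval_at(hi, k <- k + 1L)
  if (abs(est_hi$affinity$dg - target) <= tolerance)
    return(list(lambda = hi, affinity = est_hi$affinity,
                surface = est_hi$surface, history = history))
  expand <- 0L
  while (est_lo$affinity$dg > target && expand < max_expand) {
    lo <- lo / 2; expand <- expand + 1L
    est_lo <- eval_at(lo, k <- k + 1L)
  }
  expand <- 0L
  while (est_hi$affinity$dg < target && expand < max_expand) {
    hi <- hi * 2; expand <- expand + 1L
    est_hi <- eval_at(hi, k <- k + 1L)
  }
  if (est_lo$affinity$dg > target || est_hi$affinity$dg < target)
    stop("calibration interval does not bracket the target affinity ",
         "after expansion (", round(est_lo$affinity$dg, 2), " .. ",
         round(est_hi$affinity$dg, 2), " kcal/mol)")
  best <- if (abs(est_lo$affinity$dg - target) <
              abs(est_hi$affinity$dg - target))
    list(lambda = lo, est = est_lo) else list(lambda = hi, est = est_hi)
  dg_lo <- est_lo$affinity$dg; dg_hi <- est_hi$affinity$dg
  for (it in seq_len(max_iter)) {
    ## regula falsi: linear interpolation inside the bracket, falling
    ## back to the midpoint when the secant step degenerates
    mid <- lo + (target - dg_lo) / (dg_hi - dg_lo) * (hi - lo)
    if (!is.finite(mid) || mid <= lo || mid >= hi) mid <- (lo + hi) / 2
    est_mid <- eval_at(mid, k <- k + 1L)
    if (abs(est_mid$affinity$dg - target) <
        abs(best$est$affinity$dg - target))
      best <- list(lambda = mid, est = est_mid)
    if (abs(est_mid$affinity$dg - target) <= tolerance) break
    if (est_mid$affinity$dg < target) {
      lo <- mid; dg_lo <- est_mid$affinity$dg
    } else {
      hi <- mid; dg_hi <- est_mid$affinity$dg
    }
  }
  ## monotonicity diagnostic over the sampled history
  h <- history[order(history$lambda), ]
  viol <- diff(h$dg) < -3 * sqrt(h$se[-1]^2 + h$se[-nrow(h)]^2)
  if (any(viol, na.rm = TRUE))
    warning("affinity not monotone in lambda beyond statistical error")
  list(lambda = best$lambda, affinity = best$est$affinity,
       surface = best$est$surface, history = history)
}

#' Tune the cross-link tether to a target affinity difference
#'
#' Bisection on the tether spring constant: the difference between the
#' tethered and untethered umbrella/WHAM binding free energies grows with
#' tether stiffness (the tether removes the conformational entropy the
#' receptor would gain by opening after ligand release). Stops when the
#' achieved difference is within `tolerance` of the target.
#'
#' @param topology the calibrated bound-complex topology
#' @param tether_builder function(k) returning the tether bias potential
#' @param target target affinity difference, kcal/mol
#' @param tolerance kcal/mol, default 0.4
#' @param k_bracket initial spring-constant interval
#' @param max_iter interpolation iterations, default 10
#' @param seed integer
#' @param ... passed to [estimate_affinity()]
#' @return list with `k_tether`, `ddg` (achieved, with error), and the
#'   evaluation `history`
#' @export
calibrate_tether <- function(topology, tether_builder, target = 2,
                             tolerance = 0.4, k_bracket = c(0.02, 2),
                             max_iter = 8, seed = 1, ...) {
  base <- estimate_affinity(topology, seed = seed, ...)
  history <- data.frame(k = numeric(0), ddg = numeric(0), se = numeric(0))
  i <- 0L
  eval_at <- function(k) {
    i <<- i + 1L
    est <- estimate_affinity(topology,
                             base_biases = list(tether_builder(k)),
                             seed = (seed + 15485863L * i) %% 2147483647L,
                             ...)
    dd <- delta_delta_g(est$affinity, base$affinity)
    history <<- rbind(history, data.frame(k = k, ddg = dd$ddg,
                                          se = dd$se))
    dd
  }
  lo <- k_bracket[1]; hi <- k_bracket[2]
  dd_lo <- eval_at(lo); dd_hi <- eval_at(hi)
  if (abs(dd_lo$ddg - target) <= tolerance)
    return(list(k_tether = lo, ddg = dd_lo, history = history))
  if (abs(dd_hi$ddg - target) <= tolerance)
    return(list(k_tether = hi, ddg = dd_hi, history = history))
  expand <- 0L
  while (dd_lo$ddg > target && expand < 3L) {
    lo <- lo / 4; expand <- expand + 1L
    dd_lo <- eval_at(lo)
    if (abs(dd_lo$ddg - target) <= tolerance)
      return(list(k_tether = lo, ddg = dd_lo, history = history))
  }
  expand <- 0L
  while (dd_hi$ddg < target && expand < 3L) {
    hi <- hi * 4; expand <- expand + 1L
    dd_hi <- eval_at(hi)
    if (abs(dd_hi$ddg - target) <= tolerance)
      return(list(k_tether = hi, ddg = dd_hi, history = history))
  }
  if (dd_lo$ddg > target || dd_hi$ddg < target)
    stop("tether bracket does not contain the target difference (",
         round(dd_lo$ddg, 2), " .. ", round(dd_hi$ddg, 2), " kcal/mol)")
  best <- if (abs(dd_lo$ddg - target) < abs(dd_hi$ddg - target))
    list(k = lo, dd = dd_lo) else list(k = hi, dd = dd_hi)
  for (it in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)   # geometric bisection: k spans decades
    dd <- eval_at(mid)
    if (abs(dd$ddg - target) < abs(best$dd$ddg - target))
      best <- list(k = mid, dd = dd)
    if (abs(dd$ddg - target) <= tolerance) break
    if (dd$ddg < target) lo <- mid else hi <- mid
  }
  list(k_tether = best$k, ddg = best$dd, history = history)
}

#' Packaged demonstration configuration
#'
#' Reads the packaged demonstration parameters: the synthetic-system
#' defaults, umbrella protocol (window range, spring constant, steps per
#' window, temperature), the calibrated residue-base scale and the tuned
#' tether spring constant.
#'
#' @return named list
#' @export
demo_config <- function() {
  path <- system.file("extdata", "demo_config.json", package = "rbdsumo")
  jsonlite::read_json(path, simplifyVector = TRUE)
}
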