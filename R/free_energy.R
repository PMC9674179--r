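#' Umbrella-sampling dataset
#'
#' A list of windows, each with a harmonic bias (center, spring constant,
#' bias energy \eqn{k(x - c)^2 / 2} on the biased coordinate) and a
#' data.frame of sampled order parameters containing at least the biased
#' coordinate.
#'
#' @param windows list of `list(center =, k =, samples = data.frame(...))`
#' @param temperature Kelvin
#' @param coord name of the biased coordinate column, default `"r"`
#' @param metadata optional list (e.g. analytic ground truth)
#' @return object of class `umbrella_dataset`
#' @export
umbrella_dataset <- function(windows, temperature, coord = "r",
                             metadata = list()) {
  if (length(windows) == 0) stop("zero-length window list")
  for (w in windows) {
    if (is.null(w$samples) || nrow(w$samples) < 1)
      stop("every window needs at least one sample")
    if (!coord %in% names(w$samples))
      stop("window samples lack the biased coordinate '", coord, "'")
    if (w$k < 0) stop("window spring constants must be non-negative")
  }
  structure(list(windows = windows, temperature = temperature,
                 coord = coord, metadata = metadata),
            class = "umbrella_dataset")
}

#' @export
print.umbrella_dataset <- function(x, ...) {
  ns <- vapply(x$windows, function(w) nrow(w$samples), integer(1))
  cat("umbrella_dataset:", length(x$windows), "windows on '", x$coord,
      "', ", sum(ns), "samples at", x$temperature, "K\n")
  invisible(x)
}

#' Histogram overlap diagnostics between neighbouring windows
#'
#' @param dataset an [umbrella_dataset()]
#' @param edges bin edges (default 50 bins over the sampled range)
#' @return data.frame of neighbour pairs (ordered by center) with the
#'   number of bins occupied by both
#' @export
window_overlap <- function(dataset, edges = NULL) {
  x <- lapply(dataset$windows, function(w) w$samples[[dataset$coord]])
  if (is.null(edges)) {
    rng <- range(unlist(x))
    edges <- seq(rng[1], rng[2], length.out = 51)
  }
  occ <- vapply(x, function(v)
    tabulate(findInterval(v, edges, all.inside = TRUE),
             nbins = length(edges) - 1) > 0,
    logical(length(edges) - 1))
  ord <- order(vapply(dataset$windows, function(w) w$center, numeric(1)))
  nb <- data.frame(a = ord[-length(ord)], b = ord[-1])
  nb$shared_bins <- vapply(seq_len(nrow(nb)), function(r)
    sum(occ[, nb$a[r]] & occ[, nb$b[r]]), integer(1))
  nb
}

## solve WHAM self-consistency for the window free energies f_i
## H: bins x windows count matrix; cb: bins x windows bias energy at centers
wham_solve <- function(H, cb, kT, tol, max_iter, f0 = NULL) {
  nwin <- ncol(H)
  N <- colSums(H)
  Htot <- rowSums(H)
  f <- if (is.null(f0)) numeric(nwin) else f0
  eb <- exp(-cb / kT)                     # bins x windows, fixed
  for (it in seq_len(max_iter)) {
    denom <- as.vector(eb %*% (N * exp(f / kT)))
    P <- ifelse(denom > 0, Htot / denom, 0)
    fnew <- -kT * log(as.vector(crossprod(eb, P)))
    fnew <- fnew - fnew[1]
    if (max(abs(fnew - f)) < tol) {
      f <- fnew
      break
    }
    f <- fnew
  }
  if (max(abs(fnew - f)) >= tol && it == max_iter)
    warning("WHAM did not converge in ", max_iter, " iterations")
  f
}

## per-sample unbiasing weights given converged window free energies
wham_weights <- function(xs, centers, ks, N, f, kT) {
  ## xs: vector of all samples' biased coordinate
  denom <- numeric(length(xs))
  for (i in seq_along(centers)) {
    u <- 0.5 * ks[i] * (xs - centers[i])^2
    denom <- denom + N[i] * exp((f[i] - u) / kT)
  }
  1 / denom
}

check_connectivity <- function(H, centers) {
  occ <- H > 0
  nwin <- ncol(H)
  shared <- crossprod(occ) > 0
  comp <- rep(0L, nwin)
  cur <- 0L
  for (s in seq_len(nwin)) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] > 0) next
      comp[v] <- cur
      queue <- c(queue, which(shared[v, ] & comp == 0L))
    }
  }
  if (max(comp) > 1) {
    groups <- split(seq_len(nwin), comp)
    txt <- vapply(groups, function(g)
      paste0("{", paste(g, collapse = ","), "}"), character(1))
    stop("umbrella windows do not overlap: disconnected groups ",
         paste(txt, collapse = " "))
  }
  invisible(TRUE)
}

#' WHAM reconstruction of a 1D free-energy profile
#'
#' Standard binned self-consistent weighted-histogram estimator: the window
#' free energies are iterated to convergence, then the unbiased profile is
#' built from per-sample weights. The surface is normalized to min = 0;
#' unsampled bins are NA (flagged, never interpolated). Uncertainties come
#' from a block bootstrap over each window's time series.
#'
#' @param dataset an [umbrella_dataset()]
#' @param bins number of bins (default 50) or a vector of bin edges
#' @param tol convergence tolerance on the window free energies, kcal/mol
#' @param max_iter maximum self-consistency iterations
#' @param n_boot block-bootstrap replicates (default 50; 0 disables)
#' @param n_blocks blocks per window for the bootstrap, default 10
#' @return object of class `free_energy_surface`: list with `coord`, `mids`,
#'   `edges`, `F` (kcal/mol, min 0), `se`, `F_boot`, window free energies
#'   `f`, and `kT`
#' @export
wham <- function(dataset, bins = 50, tol = 1e-7, max_iter = 1e5,
                 n_boot = 50, n_blocks = 10) {
  kT <- 0.0019872 * dataset$temperature
  xs_w <- lapply(dataset$windows, function(w) w$samples[[dataset$coord]])
  centers <- vapply(dataset$windows, function(w) w$center, numeric(1))
  ks <- vapply(dataset$windows, function(w) w$k, numeric(1))
  allx <- unlist(xs_w)
  edges <- if (length(bins) == 1)
    seq(min(allx), max(allx), length.out = bins + 1) else bins
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  nbin <- length(mids)

  H <- vapply(xs_w, function(v)
    tabulate(findInterval(v, edges, all.inside = TRUE), nbins = nbin),
    numeric(nbin))
  check_connectivity(H, centers)

  ## converge the window free energies on a fine internal grid so the
  ## bias-at-bin-center discretization does not bias the estimate
  nfine <- max(4 * nbin, 200)
  efine <- seq(min(allx), max(allx), length.out = nfine + 1)
  mfine <- (efine[-1] + efine[-length(efine)]) / 2
  Hf <- vapply(xs_w, function(v)
    tabulate(findInterval(v, efine, all.inside = TRUE), nbins = nfine),
    numeric(nfine))
  cbf <- vapply(seq_along(centers), function(i)
    0.5 * ks[i] * (mfine - centers[i])^2, numeric(nfine))

  f <- wham_solve(Hf, cbf, kT, tol, max_iter)
  N <- vapply(xs_w, length, integer(1))
  surf_from_weights <- function(xs_w, f) {
    allx <- unlist(xs_w)
    w <- wham_weights(allx, centers, ks, N, f, kT)
    bin <- findInterval(allx, edges, all.inside = TRUE)
    wsum <- vapply(seq_len(nbin), function(b) sum(w[bin == b]), numeric(1))
    F <- ifelse(wsum > 0, -kT * log(wsum), NA_real_)
    F - min(F, na.rm = TRUE)
  }
  F <- surf_from_weights(xs_w, f)

  F_boot <- NULL
  se <- rep(NA_real_, nbin)
  if (n_boot > 0) {
    F_boot <- matrix(NA_real_, n_boot, nbin)
    for (b in seq_len(n_boot)) {
      xs_b <- lapply(xs_w, function(v) {
        nb <- max(1, min(n_blocks, length(v)))
        blocks <- split(v, ceiling(seq_along(v) / (length(v) / nb)))
        unlist(blocks[sample.int(length(blocks), replace = TRUE)],
               use.names = FALSE)
      })
      Hb <- vapply(xs_b, function(v)
        tabulate(findInterval(v, efine, all.inside = TRUE),
                 nbins = nfine), numeric(nfine))
      fb <- wham_solve(Hb, cbf, kT, tol * 10, max_iter, f0 = f)
      F_boot[b, ] <- surf_from_weights(xs_b, fb)
    }
    se <- apply(F_boot, 2, stats::sd)
  }
  structure(list(coord = dataset$coord, mids = mids, edges = edges,
                 F = F, se = se, F_boot = F_boot, f = f, kT = kT),
            class = "free_energy_surface")
}

#' @export
print.free_energy_surface <- function(x, ...) {
  dims <- if (is.matrix(x$F)) paste(dim(x$F), collapse = " x ")
  else length(x$F)
  cat("free_energy_surface over", paste(x$coord, collapse = ", "),
      "(", dims, "bins ), range",
      round(max(x$F, na.rm = TRUE), 2), "kcal/mol\n")
  invisible(x)
}

#' WHAM reconstruction of a 2D free-energy surface
#'
#' The window free energies are converged on the biased coordinate exactly
#' as in [wham()]; every sample is then reweighted into a 2D histogram
#' over the requested axis pair (the bias acts on one coordinate only).
#' Unsampled bins are NA.
#'
#' @param dataset an [umbrella_dataset()] whose samples record both axes
#' @param axis_pair character length 2, e.g. `c("r", "pc0")`; one of the
#'   two must be the biased coordinate
#' @param bins integer length 2 (default `c(40, 40)`) or list of two edge
#'   vectors
#' @param tol,max_iter as in [wham()]
#' @return a `free_energy_surface` with matrix `F` and axis grids
#' @export
wham_2d <- function(dataset, axis_pair, bins = c(40, 40), tol = 1e-7,
                    max_iter = 1e5) {
  stopifnot(length(axis_pair) == 2)
  kT <- 0.0019872 * dataset$temperature
  for (w in dataset$windows)
    if (!all(axis_pair %in% names(w$samples)))
      stop("both order parameters must be recorded per sample")
  xs_w <- lapply(dataset$windows, function(w) w$samples[[dataset$coord]])
  centers <- vapply(dataset$windows, function(w) w$center, numeric(1))
  ks <- vapply(dataset$windows, function(w) w$k, numeric(1))
  N <- vapply(xs_w, length, integer(1))

  a1 <- unlist(lapply(dataset$windows, function(w) w$samples[[axis_pair[1]]]))
  a2 <- unlist(lapply(dataset$windows, function(w) w$samples[[axis_pair[2]]]))
  if (is.list(bins)) {
    e1 <- bins[[1]]; e2 <- bins[[2]]
  } else {
    e1 <- seq(min(a1), max(a1), length.out = bins[1] + 1)
    e2 <- seq(min(a2), max(a2), length.out = bins[2] + 1)
  }
  ## converge f on the biased coordinate (same solve as the 1D path)
  allx <- unlist(xs_w)
  rngx <- range(allx)
  edgesx <- seq(rngx[1], rngx[2], length.out = 201)
  midsx <- (edgesx[-1] + edgesx[-201]) / 2
  e50 <- seq(rngx[1], rngx[2], length.out = 51)
  H50 <- vapply(xs_w, function(v)
    tabulate(findInterval(v, e50, all.inside = TRUE), nbins = 50),
    numeric(50))
  check_connectivity(H50, centers)
  H <- vapply(xs_w, function(v)
    tabulate(findInterval(v, edgesx, all.inside = TRUE), nbins = 200),
    numeric(200))
  cb <- vapply(seq_along(centers), function(i)
    0.5 * ks[i] * (midsx - centers[i])^2, numeric(200))
  f <- wham_solve(H, cb, kT, tol, max_iter)

  w <- wham_weights(allx, centers, ks, N, f, kT)
  b1 <- findInterval(a1, e1, all.inside = TRUE)
  b2 <- findInterval(a2, e2, all.inside = TRUE)
  wsum <- matrix(0, length(e1) - 1, length(e2) - 1)
  for (t in seq_along(w))
    wsum[b1[t], b2[t]] <- wsum[b1[t], b2[t]] + w[t]
  F <- ifelse(wsum > 0, -kT * log(wsum), NA_real_)
  F <- F - min(F, na.rm = TRUE)
  structure(list(coord = axis_pair,
                 mids = list((e1[-1] + e1[-length(e1)]) / 2,
                             (e2[-1] + e2[-length(e2)]) / 2),
                 edges = list(e1, e2), F = F, se = NULL, F_boot = NULL,
                 f = f, kT = kT),
            class = "free_energy_surface")
}

#' Marginalize a 2D free-energy surface onto one axis
#'
#' \eqn{F(a) = -k_BT \log \sum_b \exp(-F(a,b)/k_BT)}, re-normalized to
#' min 0.
#'
#' @param surface a 2D `free_energy_surface`
#' @param keep which axis to keep (1 or 2)
#' @return a 1D `free_energy_surface`
#' @export
marginalize_surface <- function(surface, keep = 1) {
  stopifnot(is.matrix(surface$F), keep %in% c(1, 2))
  kT <- surface$kT
  M <- exp(-surface$F / kT)
  M[is.na(M)] <- 0
  tot <- if (keep == 1) rowSums(M) else colSums(M)
  F <- ifelse(tot > 0, -kT * log(tot), NA_real_)
  F <- F - min(F, na.rm = TRUE)
  structure(list(coord = surface$coord[keep], mids = surface$mids[[keep]],
                 edges = surface$edges[[keep]], F = F,
                 se = rep(NA_real_, length(F)), F_boot = NULL,
                 f = surface$f, kT = kT),
            class = "free_energy_surface")
}

#' Binding free energy from a 1D dissociation profile
#'
#' \eqn{\Delta G_{bind}} = mean F over the unbound plateau minus F at the
#' bound minimum. By default the plateau is the last 20 percent of the
#' sampled range of the order parameter. The statistical error is the
#' standard deviation of the same difference over the bootstrap replicate
#' surfaces. No standard-state volume correction is applied: the value is
#' a profile difference.
#'
#' @param surface a 1D `free_energy_surface` over the dissociation distance
#' @param bound_region optional `c(min, max)`; default: everything below
#'   the unbound region
#' @param unbound_region optional `c(min, max)`; default: last 20 percent
#'   of the sampled range
#' @return object of class `binding_affinity`: list with `dg` (kcal/mol),
#'   `se`, and the regions used
#' @export
binding_free_energy <- function(surface, bound_region = NULL,
                                unbound_region = NULL) {
  stopifnot(!is.matrix(surface$F))
  mids <- surface$mids
  sampled <- !is.na(surface$F)
  rng <- range(mids[sampled])
  if (is.null(unbound_region))
    unbound_region <- c(rng[1] + 0.8 * diff(rng), rng[2])
  if (is.null(bound_region))
    bound_region <- c(rng[1], unbound_region[1])
  ub <- sampled & mids >= unbound_region[1] & mids <= unbound_region[2]
  bd <- sampled & mids >= bound_region[1] & mids < unbound_region[1]
  if (!any(ub)) stop("unbound region unsampled")
  if (!any(bd)) stop("bound region unsampled")
  dg_of <- function(F) mean(F[ub], na.rm = TRUE) - min(F[bd], na.rm = TRUE)
  dg <- dg_of(surface$F)
  se <- NA_real_
  if (!is.null(surface$F_boot))
    se <- stats::sd(apply(surface$F_boot, 1, dg_of), na.rm = TRUE)
  structure(list(dg = dg, se = se, bound_region = bound_region,
                 unbound_region = unbound_region),
            class = "binding_affinity")
}

#' @export
print.binding_affinity <- function(x, ...) {
  cat(sprintf("binding free energy: %.2f +/- %.2f kcal/mol\n", x$dg, x$se))
  invisible(x)
}

#' Difference of two binding affinities with propagated error
#'
#' @param affinity_a,affinity_b `binding_affinity` objects (or lists with
#'   `dg` and `se`)
#' @return list with `ddg` = a - b and `se` combined in quadrature
#' @export
delta_delta_g <- function(affinity_a, affinity_b) {
  list(ddg = affinity_a$dg - affinity_b$dg,
       se = sqrt(affinity_a$se^2 + affinity_b$se^2))
}

#' Detect shoulders in a 1D free-energy profile
#'
#' Fits a smoothing spline and scans its first derivative: a shoulder is
#' an interior local minimum of dF/dx where the slope flattens towards
#' zero but does not change sign; sign changes are reported separately as
#' true extrema (barriers/minima).
#'
#' @param surface a 1D `free_energy_surface`
#' @param window half-width (in the order parameter's units) used to test
#'   for sign changes around a candidate, default 3
#' @param flatness a slope local minimum counts as a shoulder only if it is
#'   below this fraction of the profile's maximum slope, default 0.25
#' @return list with numeric vectors `shoulders` and `extrema` (locations)
#' @export
detect_shoulder <- function(surface, window = 3, flatness = 0.25) {
  sampled <- !is.na(surface$F)
  if (sum(sampled) < 6)
    stop("surface too coarse for derivative estimation")
  x <- surface$mids[sampled]
  y <- surface$F[sampled]
  sp <- stats::smooth.spline(x, y, spar = 0.5)
  grid <- seq(min(x), max(x), length.out = 400)
  d1 <- stats::predict(sp, grid, deriv = 1)$y
  loc_min <- which(diff(sign(diff(abs(d1)))) > 0) + 1
  shoulders <- extrema <- numeric(0)
  for (i in loc_min) {
    nb <- abs(grid - grid[i]) <= window
    if (any(d1[nb] > 0) && any(d1[nb] < 0)) {
      extrema <- c(extrema, grid[i])
    } else if (abs(d1[i]) < flatness * max(abs(d1))) {
      shoulders <- c(shoulders, grid[i])
    }
  }
  list(shoulders = shoulders, extrema = extrema)
}
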