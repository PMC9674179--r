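test_that("WHAM recovers the analytic harmonic free energy", {
  ds <- make_umbrella_oracle(k_true = 1, centers = seq(-5, 5, 1),
                             k_bias = 5, n_samples = 5000, seed = 4)
  surf <- wham(ds, bins = 50, n_boot = 20)
  ## closed-form truth for a binned estimator: the bin-integrated
  ## Boltzmann weight of U(x) = x^2/2
  kT <- 0.0019872 * 300
  lo <- surf$edges[-length(surf$edges)]; hi <- surf$edges[-1]
  truth <- -kT * log((pnorm(hi / sqrt(kT)) - pnorm(lo / sqrt(kT))) /
                       (hi - lo))
  truth <- truth - min(truth[!is.na(surf$F)])
  ## within 0.1 kcal/mol over the sampled range
  core <- !is.na(surf$F) & abs(surf$mids) <= 4
  expect_lt(max(abs(surf$F[core] - truth[core])), 0.1)
  expect_equal(min(surf$F, na.rm = TRUE), 0)
})

test_that("WHAM error vs truth shrinks roughly as 1/sqrt(n)", {
  err_of <- function(n, seed) {
    ds <- make_umbrella_oracle(k_true = 1, centers = seq(-4, 4, 1),
                               k_bias = 5, n_samples = n, seed = seed)
    surf <- wham(ds, bins = 40, n_boot = 0)
    truth <- 0.5 * surf$mids^2
    truth <- truth - min(truth[!is.na(surf$F)])
    core <- !is.na(surf$F) & abs(surf$mids) <= 3
    sqrt(mean((surf$F[core] - truth[core])^2))
  }
  e_small <- mean(vapply(1:3, function(s) err_of(200, s), numeric(1)))
  e_big <- mean(vapply(1:3, function(s) err_of(8000, s), numeric(1)))
  ## 40x samples: expect roughly 6x error reduction; accept > 2.5x
  expect_gt(e_small / e_big, 2.5)
})

test_that("single unbiased window reduces to a histogram estimate", {
  set.seed(9)
  kT <- 0.0019872 * 300
  x <- rnorm(20000, 0, 1)
  ds <- umbrella_dataset(list(list(center = 0, k = 0,
                                   samples = data.frame(x = x))),
                         temperature = 300, coord = "x")
  surf <- wham(ds, bins = 30, n_boot = 0)
  h <- hist(x, breaks = surf$edges, plot = FALSE)
  direct <- -kT * log(h$counts)
  direct <- direct - min(direct[is.finite(direct)])
  ok <- h$counts > 0
  expect_equal(surf$F[ok], direct[ok], tolerance = 1e-8)
})

test_that("bootstrap uncertainty decreases with more samples", {
  mk <- function(n) make_umbrella_oracle(k_true = 1,
                                         centers = seq(-4, 4, 1),
                                         k_bias = 5, n_samples = n,
                                         seed = 11)
  u_small <- mean(wham(mk(300), bins = 30, n_boot = 30)$se, na.rm = TRUE)
  u_big <- mean(wham(mk(4000), bins = 30, n_boot = 30)$se, na.rm = TRUE)
  expect_lt(u_big, u_small)
})

test_that("disconnected window groups are reported", {
  mkwin <- function(mu) list(center = mu, k = 5,
                             samples = data.frame(x = rnorm(500, mu, 0.2)))
  set.seed(3)
  ds <- umbrella_dataset(list(mkwin(-5), mkwin(-4.6), mkwin(4.6),
                              mkwin(5)), temperature = 300, coord = "x")
  expect_error(wham(ds, bins = 60), "disconnected groups")
  ## a single isolated sample per window also fails the overlap check
  ds1 <- umbrella_dataset(lapply(c(-5, 0, 5), function(m)
    list(center = m, k = 5, samples = data.frame(x = m))),
    temperature = 300, coord = "x")
  expect_error(wham(ds1, bins = 60), "disconnected")
})

test_that("2D reweighting marginalizes onto the 1D result", {
  ## biased coordinate x plus a decoupled Gaussian coordinate y
  set.seed(6)
  kT <- 0.0019872 * 300
  centers <- seq(-4, 4, 1)
  wins <- lapply(centers, function(cc) {
    x <- rnorm(3000, cc * 5 / 6, sqrt(kT / 6))
    list(center = cc, k = 5,
         samples = data.frame(x = x, y = rnorm(3000, 0, 1)))
  })
  ds <- umbrella_dataset(wins, temperature = 300, coord = "x")
  s2 <- wham_2d(ds, axis_pair = c("x", "y"), bins = c(30, 20))
  s1 <- wham(ds, bins = s2$edges[[1]], n_boot = 0)
  marg <- marginalize_surface(s2, keep = 1)
  ok <- !is.na(marg$F) & !is.na(s1$F)
  expect_lt(max(abs(marg$F[ok] - s1$F[ok])), 0.1)
  ## decoupled coordinates: F(x, y) = F(x) + F(y) + const
  margy <- marginalize_surface(s2, keep = 2)
  Fsum <- outer(marg$F, margy$F, "+")
  resid <- s2$F - Fsum
  ## compare only well-populated bins (small-count bins are noisy)
  good <- !is.na(resid) & (s2$F < 2.5)
  expect_lt(stats::sd(resid[good]), 0.15)
  ## unsampled bins stay NA
  expect_true(any(is.na(s2$F)))
})

test_that("binding free energy reads plateau minus minimum", {
  ## constructed profile: bound minimum at 0, flat plateau at 8
  mids <- seq(1, 30, length.out = 50)
  F <- ifelse(mids < 10, 8 * (1 - exp(-(mids - 3)^2 / 4)) *
                (mids > 3) + 8 * (mids <= 3) * (1 - exp(-(mids - 3)^2 / 4)),
              8)
  F[which.min(abs(mids - 3))] <- 0
  surf <- structure(list(coord = "r", mids = mids, F = F,
                         se = rep(0.1, 50), F_boot = NULL,
                         kT = 0.0019872 * 300),
                    class = "free_energy_surface")
  aff <- binding_free_energy(surf)
  expect_equal(aff$dg, 8, tolerance = 1e-6)
  ## gauge invariance: shifting the whole surface changes nothing
  surf2 <- surf; surf2$F <- surf$F + 3
  expect_equal(binding_free_energy(surf2)$dg, aff$dg)
  ## unsampled unbound region errors
  surf3 <- surf; surf3$F[mids > 20] <- NA
  expect_error(binding_free_energy(surf3,
                                   unbound_region = c(25, 30)),
               "unbound region unsampled")
})

test_that("analytic two-well depth difference is recovered end-to-end", {
  ## U(x) piecewise harmonic two-well via direct Boltzmann sampling:
  ## F difference between the wells is known analytically
  kT <- 0.0019872 * 300
  delta <- 1.2
  U <- function(x) pmin(2 * x^2, 2 * (x - 3)^2 + delta)
  set.seed(8)
  centers <- seq(-1, 4, 0.2)
  wins <- lapply(centers, function(cc) {
    ## Metropolis sampling of U + bias (exact at many sweeps)
    k <- 10
    xs <- numeric(800); x <- cc
    for (i in seq_len(8000)) {
      xp <- x + rnorm(1, 0, 0.25)
      dU <- (U(xp) + 0.5 * k * (xp - cc)^2) -
        (U(x) + 0.5 * k * (x - cc)^2)
      if (log(runif(1)) < -dU / kT) x <- xp
      if (i %% 10 == 0) xs[i / 10] <- x
    }
    list(center = cc, k = k, samples = data.frame(x = xs))
  })
  ds <- umbrella_dataset(wins, temperature = 300, coord = "x")
  surf <- wham(ds, bins = 60, n_boot = 20)
  iA <- !is.na(surf$F) & abs(surf$mids - 0) < 0.4
  iB <- !is.na(surf$F) & abs(surf$mids - 3) < 0.4
  dF <- min(surf$F[iB]) - min(surf$F[iA])
  expect_equal(dF, delta, tolerance = 0.25)
})

test_that("affinity differences propagate errors in quadrature", {
  a <- list(dg = 8, se = 0.3); b <- list(dg = 6, se = 0.4)
  dd <- delta_delta_g(a, b)
  expect_equal(dd$ddg, 2)
  expect_equal(dd$se, 0.5)
  expect_equal(delta_delta_g(a, a)$ddg, 0)
  ## antisymmetry
  expect_equal(delta_delta_g(b, a)$ddg, -dd$ddg)
})

test_that("shoulder detection separates plateaus from true extrema", {
  mids <- seq(1, 30, length.out = 80)
  ## rising profile with a plateau segment around 13
  F_sh <- vapply(mids, function(m) {
    if (m < 10) 0.8 * m
    else if (m < 16) 8 + 0.05 * (m - 10)
    else 8.3 + 0.6 * (m - 16)
  }, numeric(1))
  surf_sh <- structure(list(coord = "r", mids = mids, F = F_sh,
                            se = NULL, F_boot = NULL, kT = 0.6),
                       class = "free_energy_surface")
  det <- detect_shoulder(surf_sh)
  expect_gte(length(det$shoulders), 1)
  expect_lt(min(abs(det$shoulders - 13)), 2)
  ## strictly convex profile: no shoulders
  surf_cx <- surf_sh; surf_cx$F <- 0.02 * (mids - 1)^2
  det_cx <- detect_shoulder(surf_cx)
  expect_length(det_cx$shoulders, 0)
  ## a true barrier (sign change) is an extremum, not a shoulder
  surf_bar <- surf_sh
  surf_bar$F <- 3 * exp(-(mids - 8)^2 / 8) +
    5 * (1 - exp(-(mids - 25)^2 / 60))
  det_bar <- detect_shoulder(surf_bar)
  expect_gte(length(det_bar$extrema), 1)
  expect_lt(min(abs(det_bar$extrema - 8)), 3)
  ## too coarse a surface errors
  surf_c <- surf_sh; surf_c$F[6:80] <- NA
  expect_error(detect_shoulder(surf_c), "too coarse")
})

test_that("free energy in kT units is temperature-consistent", {
  ## rescaling T and energies jointly leaves F/kT invariant
  ds1 <- make_umbrella_oracle(k_true = 1, centers = seq(-4, 4, 1),
                              k_bias = 5, n_samples = 3000,
                              temperature = 300, seed = 21)
  ds2 <- make_umbrella_oracle(k_true = 2, centers = seq(-4, 4, 1),
                              k_bias = 10, n_samples = 3000,
                              temperature = 600, seed = 21)
  s1 <- wham(ds1, bins = 30, n_boot = 0)
  s2 <- wham(ds2, bins = s1$edges, n_boot = 0)
  ok <- !is.na(s1$F) & !is.na(s2$F) & abs(s1$mids) < 3
  expect_lt(max(abs(s1$F[ok] / (0.0019872 * 300) -
                      s2$F[ok] / (0.0019872 * 600))), 0.4)
})
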