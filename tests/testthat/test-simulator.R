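test_that("topology construction counts bonds and native contacts", {
  ## a single 40-residue domain: 39 bonds
  dom <- cg_structure(data.frame(
    chain_id = "A", residue_index = 1:40, residue_type = "GLY",
    molecule_class = "protein",
    x = rbdsumo:::lattice_snake(40)[, 1],
    y = rbdsumo:::lattice_snake(40)[, 2],
    z = rbdsumo:::lattice_snake(40)[, 3]))
  topo <- build_topology(dom)
  expect_equal(nrow(topo$bonds), 39)
  expect_gt(nrow(topo$natives), 0)
  ## closed reference has inter-domain native contacts, open fewer
  rec <- make_two_domain_receptor()
  tc <- build_topology(rec$closed)
  to <- build_topology(rec$open)
  d1 <- annotation_sites(rec$closed, "dom1")
  d2 <- annotation_sites(rec$closed, "dom2")
  n_inter <- function(tp) sum(tp$natives$i %in% d1 & tp$natives$j %in% d2 |
                                tp$natives$i %in% d2 & tp$natives$j %in% d1)
  expect_gt(n_inter(tc), n_inter(to))
  ## native-contact terms are minimized at the reference coordinates
  e_ref <- topology_energy(tc)
  set.seed(2)
  e_pert <- topology_energy(tc, coords(rec$closed) +
                              matrix(rnorm(3 * nrow(rec$closed$sites),
                                           0, 0.4), ncol = 3))
  expect_lt(e_ref, e_pert)
})

test_that("Langevin sampling reproduces closed-form statistics", {
  ## harmonic bond: var(r) = kT/k within 3 SE
  s <- toy_chain(2)
  topo <- build_topology(s, params = list(native_cutoff = 0))
  res <- run_langevin(topo, temperature = 300, n_steps = 2e5, stride = 20,
                      seed = 7)
  r <- vapply(res$frames, function(f) sqrt(sum((f[1, ] - f[2, ])^2)),
              numeric(1))
  kT <- 0.0019872 * 300
  v_exp <- kT / topo$bond_k
  n_eff <- 500  # conservative effective sample size (correlated series)
  expect_lt(abs(var(r) - v_exp), 3 * v_exp * sqrt(2 / n_eff))
})

test_that("trajectories are bit-identical under a fixed seed", {
  cx <- make_reference_complex()
  pot <- build_residue_base_potential(count_atomic_contacts(cx))
  topo <- build_topology(cx, pot)
  r1 <- run_langevin(topo, temperature = 300, n_steps = 3000, stride = 100,
                     seed = 12)
  r2 <- run_langevin(topo, temperature = 300, n_steps = 3000, stride = 100,
                     seed = 12)
  expect_identical(r1$frames, r2$frames)
  expect_identical(r1$energy, r2$energy)
  r3 <- run_langevin(topo, temperature = 300, n_steps = 3000, stride = 100,
                     seed = 13)
  expect_false(identical(r1$frames, r3$frames))
})

test_that("the frictionless integrator conserves total energy", {
  cx <- make_reference_complex()
  pot <- build_residue_base_potential(count_atomic_contacts(cx))
  topo <- build_topology(cx, pot)
  res <- run_langevin(topo, temperature = 50, n_steps = 1e4, stride = 100,
                      seed = 1, friction = 0, dt = 0.005)
  tot <- res$energy + res$kinetic
  expect_lt((max(tot) - min(tot)) / abs(mean(tot)), 0.01)
})

test_that("a double-well pair samples Boltzmann well occupancies", {
  ## two sites, soft bond plus two Gaussian wells of unequal depth:
  ## occupancy ratio of the wells must match the Boltzmann integral
  s <- toy_chain(2, b = 5.5)
  topo <- build_topology(s, params = list(native_cutoff = 0))
  topo$bond_k <- 0.25
  topo$bonds$r0 <- 5.5
  topo$natives <- data.frame(i = 1L, j = 2L, r0 = c(4, 7),
                             depth = c(1.2, 0.6))
  topo$native_sigma <- 0.5
  topo$ev_radius <- 0   # pure double-well test
  kT <- 0.0019872 * 300
  V <- function(r) 0.5 * 0.25 * (r - 5.5)^2 -
    1.2 * exp(-(r - 4)^2 / (2 * 0.25)) - 0.6 * exp(-(r - 7)^2 / (2 * 0.25))
  ## exact ratio by quadrature over the radial measure r^2 exp(-V/kT)
  p <- function(r) r^2 * exp(-V(r) / kT)
  zA <- integrate(p, 2, 5.5)$value
  zB <- integrate(p, 5.5, 10)$value
  res <- run_langevin(topo, temperature = 300, n_steps = 4e5, stride = 20,
                      seed = 3)
  r <- vapply(res$frames, function(f) sqrt(sum((f[1, ] - f[2, ])^2)),
              numeric(1))
  r <- r[-seq_len(2000)]  # equilibration
  ratio_sim <- mean(r < 5.5) / mean(r >= 5.5)
  ratio_exact <- zA / zB
  expect_equal(log(ratio_sim), log(ratio_exact), tolerance = 0.35)
})

test_that("energies are invariant under chain relabelling", {
  cx <- make_reference_complex()
  pot <- build_residue_base_potential(count_atomic_contacts(cx))
  e1 <- topology_energy(build_topology(cx, pot))
  ## permute chain order in the site table (B first)
  s2 <- cx$sites[order(cx$sites$chain_id, decreasing = TRUE), ]
  cx2 <- cg_structure(s2, annotations = cx$annotations,
                      atom_records = cx$atom_records)
  e2 <- topology_energy(build_topology(cx2, pot))
  expect_equal(e1, e2, tolerance = 1e-9)
})

test_that("umbrella series flags poor neighbour-window overlap", {
  sys <- demo_system(lambda = 1)
  ## sparse, short windows: gaps must be reported, and the report must
  ## agree with the overlap diagnostics
  expect_warning(
    ds <- run_umbrella_series(sys$topology,
                              window_centers = seq(4, 16, length.out = 5),
                              k_bias = 2, n_steps_per_window = 6000,
                              stride = 60, seed = 5),
    "low histogram overlap")
  expect_s3_class(ds, "umbrella_dataset")
  ov <- window_overlap(ds)
  expect_gt(nrow(ov[ov$shared_bins < 1, ]), 0)
  expect_error(run_umbrella_series(sys$topology, window_centers = c()),
               "zero-length")
  w <- capture_warnings(
    run_umbrella_series(sys$topology,
                        window_centers = seq(4, 10, length.out = 3),
                        k_bias = 0, n_steps_per_window = 2000,
                        stride = 100, seed = 5))
  expect_true(any(grepl("k_bias = 0", w)))
})

test_that("SUMO-mimic biases pair the SIM with the strand in register", {
  cx <- make_sim_partner_complex()
  bz <- make_sumo_biases(cx, "SIM", "beta2")
  expect_equal(nrow(bz$sheet$pairs), 6)
  ## restraints are in register: sorted site indices on both sides
  expect_true(all(diff(bz$sheet$pairs[, 1]) > 0))
  expect_true(all(diff(bz$sheet$pairs[, 2]) > 0))
  ## the relax phase carries no biases
  expect_length(bz$protocol$relax_phase, 0)
  expect_gte(nrow(bz$tether$pairs), 1)
  ## overlapping annotations are rejected
  cx_bad <- set_annotations(cx, list(SIM = list(chain = "P", from = 1,
                                                to = 6),
                                     beta2 = list(chain = "P", from = 3,
                                                  to = 6)))
  expect_error(make_sumo_biases(cx_bad, "SIM", "beta2"), "overlap")
})
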