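test_that("atomic contact counting recovers planted counts and is monotone", {
  cx <- make_reference_complex(synthetic_spec(seed = 2))
  planted <- attr(cx, "planted_contacts")
  got <- count_atomic_contacts(cx, cutoff = 4.5)
  expect_equal(got$count,
               planted$count[order(planted$residue_index,
                                   planted$base_index)])
  ## zero cutoff: empty mapping
  expect_equal(nrow(count_atomic_contacts(cx, cutoff = 0)), 0)
  ## doubling the cutoff never decreases any count
  wide <- count_atomic_contacts(cx, cutoff = 9)
  key <- paste(got$residue_index, got$base_index)
  keyw <- paste(wide$residue_index, wide$base_index)
  expect_true(all(key %in% keyw))
  expect_true(all(wide$count[match(key, keyw)] >= got$count))
  ## protein-only structure is rejected
  expect_error(count_atomic_contacts(toy_chain(5)), "no RNA")
})

test_that("residue-base potential normalizes pooled counts linearly", {
  one <- data.frame(residue_type = "ARG", base_type = "U", count = 4)
  p1 <- build_residue_base_potential(one, lambda = 1)
  expect_equal(unname(p1$residue_base["ARG", "U"]), 1)
  two <- data.frame(residue_type = c("ARG", "ARG", "LYS"),
                    base_type = c("U", "U", "A"), count = c(3, 1, 2))
  p2 <- build_residue_base_potential(two, lambda = 2)
  expect_equal(unname(p2$residue_base["ARG", "U"]), 2)
  expect_equal(unname(p2$residue_base["LYS", "A"]), 1)
  ## scaling lambda scales every well depth
  p4 <- build_residue_base_potential(two, lambda = 4)
  expect_equal(p4$residue_base, 2 * p2$residue_base)
  expect_error(build_residue_base_potential(
    data.frame(residue_type = "ARG", base_type = "U", count = 0)),
    "all-zero")
})

test_that("binding energy follows the switching-function geometry", {
  pot <- contact_potential(residue_base = matrix(1, 1, 1,
                                                 dimnames = list("GLY", "U")))
  ## single pair at contact range: full well depth
  expect_equal(binding_energy(toy_pair(6.5), "A", "B", pot), -1,
               tolerance = 1e-6)
  ## inside the range: also full depth; at rc + w: zero
  expect_equal(binding_energy(toy_pair(3), "A", "B", pot), -1)
  expect_equal(binding_energy(toy_pair(8.6), "A", "B", pot), 0)
  ## halfway through the taper: half depth
  expect_equal(binding_energy(toy_pair(7.5), "A", "B", pot), -0.5,
               tolerance = 1e-9)
  ## beyond rc + 3w: exactly zero
  expect_equal(binding_energy(toy_pair(13), "A", "B", pot), 0)
  expect_error(binding_energy(toy_pair(6), "A", "A", pot), "disjoint")
})

test_that("binding energy is rigid-invariant and chain-additive", {
  cx <- make_reference_complex(synthetic_spec(seed = 5))
  pot <- build_residue_base_potential(count_atomic_contacts(cx))
  e0 <- binding_energy(cx, "A", "B", pot)
  expect_lt(e0, 0)
  moved <- set_coords(cx, random_rigid(coords(cx), seed = 9))
  expect_equal(binding_energy(moved, "A", "B", pot), e0,
               tolerance = 1e-9)
  ## additivity over partner chain pairs: split the protein chain sites
  ## into two pseudo-chains and compare against the sum
  s2 <- cx$sites
  half <- s2$chain_id == "A" & s2$residue_index <= 40
  s2$chain_id[half] <- "C"
  cx2 <- cg_structure(s2)
  expect_equal(binding_energy(cx2, c("A", "C"), "B", pot),
               binding_energy(cx2, "A", "B", pot) +
                 binding_energy(cx2, "C", "B", pot),
               tolerance = 1e-9)
})

test_that("frustration z-scores match the closed-form 2-type decoy law", {
  ## two residue types in contact across chains; decoys redraw identities
  ## from the composition, so the decoy energy distribution is discrete
  ## with probabilities from the type frequencies
  n_a <- 6; n_b <- 2  # 6 GLY, 2 ILE in the protein pool
  sites <- data.frame(
    chain_id = rep(c("A", "B"), each = 4),
    residue_index = rep(1:4, 2),
    residue_type = c("ILE", "GLY", "GLY", "GLY",
                     "ILE", "GLY", "GLY", "GLY"),
    molecule_class = "protein",
    x = c(0, 40, 80, 120, 0, 40, 80, 120),
    y = rep(c(0, 5), each = 4), z = 0)
  cxs <- cg_structure(sites)
  pot <- contact_potential()  # hydropathy table: only ILE-ILE binds here
  fz <- frustration_zscores(cxs, pot, n_decoys = 10000, seed = 3,
                            z_threshold = 0.78)
  ## contact 1 is the native ILE-ILE pair (distance 5, inside the well)
  ii <- which(fz$site_i == 1 & fz$site_j == 5)
  depth <- hydropathy_pair_matrix()["ILE", "ILE"]
  p_ii <- (2 / 8)^2    # both decoy identities ILE
  p_ig <- 2 * (2 / 8) * (6 / 8)
  e_vals <- c(-depth, -depth * (0 + hydropathy_pair_matrix()["ILE", "GLY"]) / depth * depth, 0)
  ## closed-form mean/SD of the decoy energy at this geometry (switch = 1)
  d_ii <- -hydropathy_pair_matrix()["ILE", "ILE"]
  d_ig <- -hydropathy_pair_matrix()["ILE", "GLY"]
  d_gg <- -hydropathy_pair_matrix()["GLY", "GLY"]
  mu <- p_ii * d_ii + p_ig * d_ig + (1 - p_ii - p_ig) * d_gg
  sdv <- sqrt(p_ii * (d_ii - mu)^2 + p_ig * (d_ig - mu)^2 +
                (1 - p_ii - p_ig) * (d_gg - mu)^2)
  se <- sdv / sqrt(10000)
  expect_lt(abs(fz$decoy_mean[ii] - mu), 3 * se)
  expect_equal(fz$decoy_sd[ii], sdv, tolerance = 0.05)
  z_exact <- (mu - d_ii) / sdv
  expect_lt(abs(fz$z[ii] - z_exact), 0.1)
  ## the planted strong pair is minimally frustrated
  expect_gt(fz$z[ii], 0.78)
  expect_gte(attr(fz, "n_minimally_frustrated"), 1)
  ## count non-increasing in the threshold
  n_low <- sum(fz$z > 0.5); n_high <- sum(fz$z > 2)
  expect_gte(n_low, n_high)
  ## homogeneous composition: zero decoy variance is an error
  homo <- cg_structure(within(sites, residue_type <- "ILE"))
  expect_error(frustration_zscores(homo, pot, n_decoys = 200),
               "zero decoy variance")
})

test_that("model ranking maximizes frustration count then minimizes energy", {
  cx <- make_sim_partner_complex()
  pot <- contact_potential()
  ## frame 2: peptide pulled away (few contacts), frame 1: native pose
  xyz2 <- coords(cx)
  pidx <- annotation_sites(cx, "SIM")
  xyz2[pidx, 3] <- xyz2[pidx, 3] + 15
  ens <- cg_ensemble(cx, list(coords(cx), xyz2))
  rk <- rank_models(ens, pot, "P", "S", n_decoys = 300, seed = 2)
  expect_equal(rk$selected, 1)
  expect_lt(rk$table$energy[1], rk$table$energy[2])
  ## tie on counts: lower energy wins (scripted via the rule itself)
  tab <- data.frame(frame = 1:2, energy = c(-5, -7),
                    n_minimally_frustrated = c(3, 3))
  ord <- order(-tab$n_minimally_frustrated, tab$energy)
  expect_equal(ord[1], 2)
  ## single frame selects itself
  rk1 <- rank_models(cg_ensemble(cx, list(coords(cx))), pot, "P", "S",
                     n_decoys = 300, seed = 2)
  expect_equal(rk1$selected, 1)
})

test_that("sequence scan threads windows and reproduces the reference", {
  cx <- make_sim_partner_complex()
  pot <- contact_potential()
  prof <- scan_sequence_binding("VIDLTV", cx, potential = pot)
  ## the original peptide sequence reproduces the reference energy
  expect_equal(prof$energy[1], attr(prof, "reference_energy"),
               tolerance = 1e-12)
  expect_error(scan_sequence_binding("VID", cx, potential = pot),
               "shorter")
  expect_error(scan_sequence_binding("VIDLTZ", cx, potential = pot),
               "absent from the potential")
})
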