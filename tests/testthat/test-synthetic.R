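test_that("receptor generation is deterministic and conformers distinct", {
  r1 <- make_two_domain_receptor(synthetic_spec(seed = 3))
  r2 <- make_two_domain_receptor(synthetic_spec(seed = 3))
  expect_identical(coords(r1$open), coords(r2$open))
  expect_identical(coords(r1$closed), coords(r2$closed))
  check_same_topology(r1$open, r1$closed)
  qs <- q_spec(pair_scope = "inter_domain", domains = c("dom1", "dom2"))
  expect_lt(mutual_q(r1$open, r1$closed, qs), 0.5)
  expect_equal(mutual_q(r1$open, r1$open, qs), 1)
  ## the pocket lines the closed cleft: pocket residues from both domains
  pk <- annotation_sites(r1$closed, "pocket")
  expect_gt(length(intersect(pk, annotation_sites(r1$closed, "dom1"))), 0)
  expect_gt(length(intersect(pk, annotation_sites(r1$closed, "dom2"))), 0)
  ## identical hinge angles are rejected
  expect_error(synthetic_spec(open_angle_deg = 50, closed_angle_deg = 50))
})

test_that("bimodal ensemble honours mode fractions and noise limits", {
  spec <- synthetic_spec(seed = 9, noise_sigma = 0.5)
  n <- 400
  ens <- make_bimodal_ensemble(spec, n_frames = n,
                               mode_fractions = c(0.5, 0.5))
  expect_equal(n_frames(ens), n)
  n_open <- sum(ens$frame_labels == "open")
  ## binomial: within 3 SD of n/2
  expect_lt(abs(n_open - n / 2), 3 * sqrt(n * 0.25))
  ## all frames in one mode when the fraction is degenerate
  ens1 <- make_bimodal_ensemble(spec, n_frames = 50,
                                mode_fractions = c(1, 0))
  expect_true(all(ens1$frame_labels == "open"))
  ## zero noise: exactly two distinct frames repeated
  ens0 <- make_bimodal_ensemble(synthetic_spec(seed = 9, noise_sigma = 0),
                                n_frames = 50)
  uniq <- unique(lapply(ens0$frames, function(f) round(f, 10)))
  expect_equal(length(uniq), 2)
  expect_error(make_bimodal_ensemble(spec, n_frames = 1), "at least 2")
  expect_error(make_bimodal_ensemble(spec, 10, mode_fractions = c(2, 1)))
})

test_that("umbrella oracle draws exact Gaussian window distributions", {
  k_true <- 1; k_bias <- 5; T0 <- 300
  ds <- make_umbrella_oracle(k_true, centers = seq(-5, 5, 1),
                             k_bias = k_bias, n_samples = 4000,
                             temperature = T0, seed = 2)
  kT <- 0.0019872 * T0
  v_expect <- kT / (k_true + k_bias)
  vars <- vapply(ds$windows, function(w) var(w$samples$x), numeric(1))
  ## each window variance within 3 SE of kT/(k_true + k_bias)
  se <- v_expect * sqrt(2 / (4000 - 1))
  expect_true(all(abs(vars - v_expect) < 3 * se))
  ## doubling T doubles the per-window variance
  ds2 <- make_umbrella_oracle(k_true, centers = seq(-5, 5, 1),
                              k_bias = k_bias, n_samples = 4000,
                              temperature = 2 * T0, seed = 3)
  vars2 <- vapply(ds2$windows, function(w) var(w$samples$x), numeric(1))
  expect_equal(mean(vars2) / mean(vars), 2, tolerance = 0.1)
  ## window means sit at the analytic minimum of U + bias
  mus <- vapply(ds$windows, function(w) mean(w$samples$x), numeric(1))
  expect_equal(mus, seq(-5, 5, 1) * k_bias / (k_true + k_bias),
               tolerance = 0.05)
  expect_error(make_umbrella_oracle(k_true = -1), "positive")
  expect_error(make_umbrella_oracle(centers = c(0, 1)), "3 windows")
})

test_that("reference complex realizes planted contact counts exactly", {
  cx <- make_reference_complex(synthetic_spec(seed = 4))
  planted <- attr(cx, "planted_contacts")
  got <- count_atomic_contacts(cx, cutoff = 4.5)
  expect_equal(got[, c("residue_index", "base_index", "count")],
               planted[order(planted$residue_index, planted$base_index),
                       c("residue_index", "base_index", "count")],
               ignore_attr = TRUE)
  ## a 0.01 A jitter of all atoms cannot change any count
  cx_j <- cx
  set.seed(7)
  cx_j$atom_records[, c("x", "y", "z")] <-
    cx_j$atom_records[, c("x", "y", "z")] +
    matrix(runif(3 * nrow(cx_j$atom_records), -0.01, 0.01), ncol = 3)
  got_j <- count_atomic_contacts(cx_j, cutoff = 4.5)
  expect_equal(got_j$count, got$count)
  ## empty planted table: zero contacts counted
  cx0 <- make_reference_complex(synthetic_spec(
    planted_contacts = data.frame(residue_index = integer(0),
                                  base_index = integer(0),
                                  count = integer(0))))
  expect_equal(nrow(count_atomic_contacts(cx0, cutoff = 4.5)), 0)
})

test_that("scan sequences plant recoverable high-affinity windows", {
  sq <- make_scan_sequence(window_start = 273, length = 11, seed = 6)
  expect_equal(nchar(sq$sequence), 400)
  expect_equal(substr(sq$sequence, 273, 283), strrep("I", 11))
  cx <- make_sim_partner_complex()
  prof <- scan_sequence_binding(sq$sequence, cx)
  expect_equal(prof$start[which.min(prof$energy)], 273)
  ## two planted windows matching the peptide length: the two
  ## lowest-energy windows sit exactly at both starts
  sq2 <- make_scan_sequence(window_start = c(100, 273), length = 6,
                            seed = 6)
  prof2 <- scan_sequence_binding(sq2$sequence, cx)
  best2 <- prof2$start[order(prof2$energy)[1:2]]
  expect_setequal(best2, c(100, 273))
  ## uniform sequence: flat profile
  prof_u <- scan_sequence_binding(strrep("S", 60), cx)
  expect_lt(diff(range(prof_u$energy)), 1e-10)
  expect_error(make_scan_sequence(window_start = 395, length = 11),
               "does not fit")
})
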