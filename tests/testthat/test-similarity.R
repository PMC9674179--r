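test_that("mutual Q reproduces hand-evaluated single-pair values", {
  ## inter-molecular pair, r^A = 6, r^B = 7: exp(-1/(2*5))
  expect_equal(mutual_q(toy_pair(6), toy_pair(7)), exp(-0.1),
               tolerance = 1e-12)
  ## intra pair |i-j| = 2, distance difference 1: delta = 2^0.15
  mk <- function(d13) cg_structure(data.frame(
    chain_id = "A", residue_index = 1:3, residue_type = "GLY",
    molecule_class = "protein", x = c(0, 1, d13), y = 0, z = 0))
  q <- mutual_q(mk(5), mk(6), q_spec(min_seq_sep = 2))
  expect_equal(q, exp(-1 / (2 * 2^0.3)), tolerance = 1e-12)
})

test_that("mutual Q is 1 on identity, symmetric, in [0,1]", {
  rec <- make_two_domain_receptor()
  qs <- q_spec(pair_scope = "inter_domain", domains = c("dom1", "dom2"))
  expect_equal(mutual_q(rec$open, rec$open, qs), 1)
  expect_equal(mutual_q(rec$closed, rec$closed, qs), 1)
  q_oc <- mutual_q(rec$open, rec$closed, qs)
  q_co <- mutual_q(rec$closed, rec$open, qs)
  expect_equal(q_oc, q_co)
  expect_gte(q_oc, 0); expect_lte(q_oc, 1)
  ## generated open/closed conformers are structurally distinct
  expect_lt(q_oc, 0.5)
})

test_that("mutual Q is invariant under rigid motion of either structure", {
  rec <- make_two_domain_receptor()
  qs <- q_spec(pair_scope = "inter_domain", domains = c("dom1", "dom2"))
  q0 <- mutual_q(rec$open, rec$closed, qs)
  moved <- set_coords(rec$closed, random_rigid(coords(rec$closed), seed = 4))
  expect_equal(mutual_q(rec$open, moved, qs), q0, tolerance = 1e-10)
})

test_that("scoped Q equals brute-force enumeration over the same pairs", {
  rec <- make_two_domain_receptor()
  a <- rec$open; b <- rec$closed
  spec <- q_spec(pair_scope = "inter_domain", domains = c("dom1", "dom2"))
  ## brute force: enumerate every site pair, apply scope + union rule
  sa <- a$sites
  xa <- coords(a); xb <- coords(b)
  d1 <- annotation_sites(a, "dom1"); d2 <- annotation_sites(a, "dom2")
  acc <- c()
  for (i in seq_len(nrow(sa) - 1)) for (j in (i + 1):nrow(sa)) {
    in_dom <- (i %in% d1 && j %in% d2) || (i %in% d2 && j %in% d1)
    if (!in_dom) next
    same <- sa$chain_id[i] == sa$chain_id[j]
    if (same && abs(sa$residue_index[i] - sa$residue_index[j]) < 3) next
    ra <- sqrt(sum((xa[i, ] - xa[j, ])^2))
    rb <- sqrt(sum((xb[i, ] - xb[j, ])^2))
    if (ra > 12 && rb > 12) next
    dsq <- if (same)
      (abs(sa$residue_index[i] - sa$residue_index[j])^0.15)^2 else 5
    acc <- c(acc, exp(-(ra - rb)^2 / (2 * dsq)))
  }
  expect_equal(mutual_q(a, b, spec), mean(acc), tolerance = 1e-12)
})

test_that("template Q screens displaced poses with a strict threshold", {
  cx <- make_sim_partner_complex()
  expect_equal(q_to_template(cx, cx), 1)
  displaced <- set_coords(cx, {
    xy <- coords(cx)
    idx <- annotation_sites(cx, "SIM")
    xy[idx, 3] <- xy[idx, 3] + 20
    xy
  })
  qc <- q_to_template(displaced, cx)
  expect_lt(qc, 0.2)
  expect_false(screen_by_qc(qc))
  ## boundary is strict: exactly 0.2 is not selected
  expect_false(screen_by_qc(0.2))
  expect_true(screen_by_qc(0.2 + 1e-9))
})

test_that("pairwise Q matrix is symmetric with unit diagonal", {
  ens <- make_bimodal_ensemble(synthetic_spec(seed = 2, noise_sigma = 0.3),
                               n_frames = 12)
  qs <- q_spec(pair_scope = "inter_domain", domains = c("dom1", "dom2"))
  qm <- pairwise_q_matrix(ens, qs)
  expect_identical(qm, t(qm))
  expect_equal(diag(qm), rep(1, 12))
  expect_true(all(qm >= 0 & qm <= 1))
  ## block structure: within-mode Q exceeds between-mode Q
  lab <- ens$frame_labels
  same <- outer(lab, lab, "==") & upper.tri(qm)
  diff <- outer(lab, lab, "!=") & upper.tri(qm)
  expect_gt(min(qm[same]), max(qm[diff]))
  ## identical frames give an all-ones matrix
  ens0 <- cg_ensemble(ens$topology, rep(ens$frames[1], 3))
  expect_equal(pairwise_q_matrix(ens0, qs), matrix(1, 3, 3))
})

test_that("Q clustering recovers planted modes and honours k limits", {
  spec <- synthetic_spec(seed = 8, noise_sigma = 0.3)
  conf <- make_two_domain_receptor(spec)
  ## three planted modes: open, closed, and a half-way interpolation
  set.seed(42)
  mids <- lapply(1:6, function(k)
    0.5 * coords(conf$open) + 0.5 * coords(conf$closed) +
      matrix(rnorm(3 * nrow(conf$open$sites), 0, 0.3), ncol = 3))
  opens <- lapply(1:6, function(k)
    coords(conf$open) + matrix(rnorm(3 * nrow(conf$open$sites), 0, 0.3),
                               ncol = 3))
  closeds <- lapply(1:6, function(k)
    coords(conf$closed) + matrix(rnorm(3 * nrow(conf$open$sites), 0, 0.3),
                                 ncol = 3))
  ens <- cg_ensemble(conf$open, c(opens, mids, closeds))
  truth <- rep(1:3, each = 6)
  qs <- q_spec(pair_scope = "inter_domain", domains = c("dom1", "dom2"))
  qm <- pairwise_q_matrix(ens, qs)
  cl <- cluster_by_q(qm, k = 3)
  ## perfect agreement up to label permutation
  expect_equal(length(unique(paste(cl$labels, truth))), 3)
  ## representatives belong to their clusters
  expect_equal(cl$labels[cl$representatives], sort(unique(cl$labels)))
  expect_equal(unname(cluster_by_q(qm, k = 1)$labels), rep(1L, 18))
  expect_equal(sort(unname(cluster_by_q(qm, k = 18)$labels)), 1:18)
  expect_error(cluster_by_q(qm, k = 0), "between 1")
  expect_error(cluster_by_q(qm, k = 19), "between 1")
})

test_that("added coordinate noise does not increase expected Q", {
  rec <- make_two_domain_receptor()
  qs <- q_spec(pair_scope = "inter_domain", domains = c("dom1", "dom2"))
  set.seed(11)
  n <- nrow(rec$closed$sites)
  qbar <- vapply(c(0.2, 0.8, 2), function(sg)
    mean(vapply(1:8, function(k) {
      noisy <- set_coords(rec$closed,
                          coords(rec$closed) + matrix(rnorm(3 * n, 0, sg),
                                                      ncol = 3))
      mutual_q(rec$closed, noisy, qs)
    }, numeric(1))), numeric(1))
  expect_true(all(diff(qbar) < 0))
})

test_that("inter-domain contact frequency map applies the majority filter", {
  spec <- synthetic_spec(seed = 5, noise_sigma = 0.2)
  ens <- make_bimodal_ensemble(spec, n_frames = 20,
                               mode_fractions = c(0.5, 0.5))
  cmap <- contact_frequency_map(ens, "dom1", "dom2", cutoff = 8,
                                min_count = 10)
  ## closed frames (~half) carry the inter-domain contacts; only pairs
  ## present in more than half the frames survive the filter
  expect_true(all(cmap$count > 10))
  all_counts <- contact_frequency_map(ens, "dom1", "dom2", cutoff = 8,
                                      min_count = 0)
  expect_gte(nrow(all_counts), nrow(cmap))
})
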