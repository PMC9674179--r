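#' Build a structure-based topology from a reference structure
#'
#' Harmonic bonds connect consecutive sites in each chain with equilibrium
#' lengths from the reference. Protein-protein pairs within the native
#' cutoff in the reference become Gaussian native-contact wells; pairs
#' across the two annotated domains can be given a separate (typically
#' weaker) depth so the hinge interconverts at the simulation temperature.
#' Protein-RNA pairs in contact in the reference interact through Gaussian
#' wells of the same form, depth-weighted by the contact potential's
#' residue-base table. A soft quadratic wall provides excluded volume.
#'
#' @param reference a `cg_structure` (the native state; chains of at least
#'   2 sites)
#' @param potential optional [contact_potential()] supplying residue-base
#'   depths
#' @param params list overriding defaults: `bond_k` (20 kcal/mol/A^2),
#'   `native_cutoff` (8 A), `native_depth` (1.5 kcal/mol),
#'   `inter_domain_depth` (0.3), `native_sigma` (1 A), `rb_sigma` (1 A,
#'   the residue-base well width), `ev_radius` (3.5 A),
#'   `ev_k` (10), `min_seq_sep` (3), `domains` (annotation names, default
#'   `c("dom1", "dom2")` when present)
#' @return object of class `cg_topology`
#' @export
build_topology <- function(reference, potential = NULL, params = list()) {
  p <- utils::modifyList(list(bond_k = 20, native_cutoff = 8,
                              native_depth = 1.5, inter_domain_depth = 0.3,
                              native_sigma = 1, rb_sigma = 1,
                              ev_radius = 3.5, ev_k = 10,
                              min_seq_sep = 3, domains = NULL), params)
  s <- reference$sites
  n <- nrow(s)
  xyz <- coords(reference)

  bonds <- NULL
  for (ch in reference$chain_table$chain_id) {
    idx <- chain_sites(reference, ch)
    if (length(idx) < 2) {
      warning("chain ", ch, " has a single site")
      next
    }
    i <- idx[-length(idx)]; j <- idx[-1]
    r0 <- sqrt(rowSums((xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE])^2))
    bonds <- rbind(bonds, data.frame(i = i, j = j, r0 = r0))
  }

  dn <- p$domains
  if (is.null(dn))
    dn <- intersect(c("dom1", "dom2"), names(reference$annotations))
  dom <- rep(NA_character_, n)
  for (nm in dn) dom[annotation_sites(reference, nm)] <- nm

  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- ij[, 1]; j <- ij[, 2]
  prot <- s$molecule_class[i] == "protein" & s$molecule_class[j] == "protein"
  same_chain <- s$chain_id[i] == s$chain_id[j]
  sep <- abs(s$residue_index[i] - s$residue_index[j])
  cand <- prot & (!same_chain | sep >= p$min_seq_sep)
  d <- sqrt(rowSums((xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE])^2))
  nat <- cand & d <= p$native_cutoff
  inter_dom <- !is.na(dom[i]) & !is.na(dom[j]) & dom[i] != dom[j]
  natives <- data.frame(i = i[nat], j = j[nat], r0 = d[nat],
                        depth = ifelse(inter_dom[nat],
                                       p$inter_domain_depth,
                                       p$native_depth),
                        sigma = rep(p$native_sigma, sum(nat)))

  ## residue-base terms: Gaussian wells on the protein-RNA pairs in
  ## contact in the reference, depth-weighted by the contact potential
  ## (same functional form as the protein native contacts, so the bound
  ## ligand holds the cleft at its reference geometry)
  if (!is.null(potential) && !is.null(potential$residue_base)) {
    pr <- s$molecule_class[i] == "protein" & s$molecule_class[j] == "rna"
    rp <- s$molecule_class[i] == "rna" & s$molecule_class[j] == "protein"
    mix <- (pr | rp) & d <= potential$cg_cutoff
    if (any(mix)) {
      depth <- pair_depth(potential, s$residue_type[i[mix]],
                          s$molecule_class[i[mix]],
                          s$residue_type[j[mix]], s$molecule_class[j[mix]])
      keep <- depth > 0
      natives <- rbind(natives,
                       data.frame(i = i[mix][keep], j = j[mix][keep],
                                  r0 = d[mix][keep],
                                  depth = depth[keep],
                                  sigma = p$rb_sigma))
    }
  }
  rb <- data.frame(i = integer(0), j = integer(0), depth = numeric(0))
  rb_range <- if (!is.null(potential)) potential$contact_range else 6.5
  rb_width <- if (!is.null(potential)) potential$well_width else 2

  structure(list(sites = s, xyz_ref = xyz, annotations = reference$annotations,
                 chain_table = reference$chain_table,
                 bonds = bonds, bond_k = p$bond_k, natives = natives,
                 native_sigma = p$native_sigma, rb = rb,
                 rb_range = rb_range, rb_width = rb_width,
                 ev_radius = p$ev_radius, ev_k = p$ev_k, params = p),
            class = "cg_topology")
}

#' @export
print.cg_topology <- function(x, ...) {
  cat("cg_topology:", nrow(x$sites), "sites,", nrow(x$bonds), "bonds,",
      nrow(x$natives), "native contacts,", nrow(x$rb),
      "residue-base wells\n")
  invisible(x)
}

#' Total force-field energy of a configuration under a topology
#' @param topology a `cg_topology`
#' @param xyz coordinate matrix (default: the reference coordinates)
#' @return potential energy, kcal/mol
#' @export
topology_energy <- function(topology, xyz = topology$xyz_ref) {
  res <- run_langevin(topology, temperature = 1e-8, n_steps = 1,
                      stride = 1, dt = 0, seed = 1, coords0 = xyz,
                      friction = 0)
  res$energy[1]
}

## --- bias constructors ------------------------------------------------

#' Bias potentials for the simulator
#'
#' `bias_harmonic_r` restrains the distance between the centroids of two
#' site groups (the umbrella bias on the ligand-pocket distance R); with
#' `center_end` different from `center` the restraint center ramps
#' linearly over the run (steered dissociation). `bias_restraints`
#' harmonically restrains individual site pairs; it implements both the
#' cross-link tether (a SUMO-mimic bivalently pinning the two domains) and
#' the sheet-pairing guide. `bias_harmonic_pc0` restrains a fixed linear
#' collective coordinate (a principal component without realignment).
#'
#' @param group_a,group_b site row indices
#' @param k spring constant (kcal/mol/A^2, or per coordinate unit)
#' @param center restraint center
#' @param center_end optional ramp end value
#' @return a `bias_potential` list
#' @export
bias_harmonic_r <- function(group_a, group_b, k, center,
                            center_end = center) {
  stopifnot(k >= 0, length(group_a) > 0, length(group_b) > 0)
  structure(list(kind = "harmonic_R", group_a = group_a, group_b = group_b,
                 k = k, center = center, center_end = center_end),
            class = "bias_potential")
}

#' @rdname bias_harmonic_r
#' @param pairs two-column matrix of site row indices
#' @param r0 equilibrium distances (recycled)
#' @param kind `"crosslink_tether"` or `"sheet_pairs"`
#' @export
bias_restraints <- function(pairs, k, r0,
                            kind = c("crosslink_tether", "sheet_pairs")) {
  kind <- match.arg(kind)
  pairs <- matrix(as.integer(pairs), ncol = 2)
  stopifnot(all(k >= 0))
  structure(list(kind = kind, pairs = pairs,
                 k = rep_len(k, nrow(pairs)), r0 = rep_len(r0, nrow(pairs))),
            class = "bias_potential")
}

#' @rdname bias_harmonic_r
#' @param model a [fit_pca()] model supplying the coordinate direction
#' @export
bias_harmonic_pc0 <- function(model, k, center) {
  stopifnot(k >= 0)
  structure(list(kind = "harmonic_PC0", model = model, k = k,
                 center = center),
            class = "bias_potential")
}

#' Cross-link tether between two annotated regions
#'
#' Builds harmonic restraints pinning `n_pairs` site pairs across the
#' interface between two annotations at their distances in the given
#' (reference) conformation. Emulates the conformational clamp a
#' bivalently bound partner imposes: with a stiff tether the receptor
#' cannot open. Anchor pairs are chosen to be spatially spread over the
#' interface (greedy max-min selection among pairs within `cutoff`), so
#' the clamp suppresses hinge rotation rather than pinning one point.
#'
#' @param reference a `cg_structure` in the conformation to pin
#' @param ann_a,ann_b annotation names
#' @param k spring constant, kcal/mol/A^2
#' @param n_pairs number of restrained pairs, default 6
#' @param cutoff only pairs within this reference distance are candidate
#'   anchors, default 12 A
#' @return a `bias_potential` of kind `crosslink_tether`
#' @export
bias_tether_between <- function(reference, ann_a, ann_b, k, n_pairs = 6,
                                cutoff = 12) {
  ia <- annotation_sites(reference, ann_a)
  ib <- annotation_sites(reference, ann_b)
  xyz <- coords(reference)
  grid <- expand.grid(i = ia, j = ib)
  d <- sqrt(rowSums((xyz[grid$i, , drop = FALSE] -
                       xyz[grid$j, , drop = FALSE])^2))
  cand <- which(d <= cutoff)
  if (length(cand) == 0) cand <- order(d)[seq_len(min(10, length(d)))]
  ## greedy max-min spread over the pair midpoints
  mids <- (xyz[grid$i[cand], , drop = FALSE] +
             xyz[grid$j[cand], , drop = FALSE]) / 2
  chosen <- which.min(d[cand])
  while (length(chosen) < min(n_pairs, length(cand))) {
    dist_to_chosen <- apply(mids, 1, function(p)
      min(sqrt(colSums((t(mids[chosen, , drop = FALSE]) - p)^2))))
    dist_to_chosen[chosen] <- -1
    chosen <- c(chosen, which.max(dist_to_chosen))
  }
  sel <- cand[chosen]
  bias_restraints(cbind(grid$i[sel], grid$j[sel]), k = k, r0 = d[sel],
                  kind = "crosslink_tether")
}

#' Biases guiding SUMO-mimic complex formation
#'
#' Builds (a) a sheet-pairing bias: weak harmonic restraints between the
#' SIM residues and the partner beta-strand residues, paired in register;
#' and (b) a bivalent cross-link tether binding the strand-bearing chain
#' (the SUMO mimic) to both the SIM-bearing region and, when given, the
#' zinc-finger-like region. The returned protocol has a biased phase
#' (sheet guide on) followed by a relax phase with no biases, mirroring
#' the guide-then-relax construction of sheet-paired complexes.
#'
#' @param complex a `cg_structure`
#' @param sim_annotation,beta2_annotation,znf_annotation annotation names
#'   (znf optional)
#' @param params list: `k_sheet` (default 1), `k_tether` (default 5),
#'   `sheet_r0` (default 5 A)
#' @return list with `sheet`, `tether` bias potentials and `protocol`
#'   (list of phases, each a list of biases; the relax phase is empty)
#' @export
make_sumo_biases <- function(complex, sim_annotation = "SIM",
                             beta2_annotation = "beta2",
                             znf_annotation = NULL, params = list()) {
  p <- utils::modifyList(list(k_sheet = 1, k_tether = 5, sheet_r0 = 5),
                         params)
  is_ <- annotation_sites(complex, sim_annotation)
  ib <- annotation_sites(complex, beta2_annotation)
  if (length(intersect(is_, ib)) > 0)
    stop("annotations overlap: ", sim_annotation, " and ", beta2_annotation)
  npair <- min(length(is_), length(ib))
  sheet <- bias_restraints(cbind(is_[seq_len(npair)], ib[seq_len(npair)]),
                           k = p$k_sheet, r0 = p$sheet_r0,
                           kind = "sheet_pairs")
  mimic_chain <- unique(complex$sites$chain_id[ib])
  xyz <- coords(complex)
  anchor_of <- function(idx) {
    cen <- colMeans(xyz[idx, , drop = FALSE])
    idx[which.min(colSums((t(xyz[idx, , drop = FALSE]) - cen)^2))]
  }
  mimic_anchor <- anchor_of(chain_sites(complex, mimic_chain))
  tether_pairs <- rbind(c(mimic_anchor, anchor_of(is_)))
  if (!is.null(znf_annotation)) {
    iz <- annotation_sites(complex, znf_annotation)
    if (length(intersect(iz, union(is_, ib))) > 0)
      stop("annotations overlap: ", znf_annotation)
    tether_pairs <- rbind(tether_pairs, c(mimic_anchor, anchor_of(iz)))
  }
  r0 <- sqrt(rowSums((xyz[tether_pairs[, 1], , drop = FALSE] -
                        xyz[tether_pairs[, 2], , drop = FALSE])^2))
  tether <- bias_restraints(tether_pairs, k = p$k_tether, r0 = r0,
                            kind = "crosslink_tether")
  list(sheet = sheet, tether = tether,
       protocol = list(biased_phase = list(sheet), relax_phase = list()))
}

## --- dynamics ---------------------------------------------------------

collect_biases <- function(topology, biases) {
  n <- nrow(topology$sites)
  out <- list(ri = integer(0), rj = integer(0), rr0 = numeric(0),
              rk = numeric(0), ga = integer(0), gb = integer(0),
              rbias_k = 0, c0 = 0, c1 = 0,
              pc0_w = matrix(0, 0, 3), pc0_ref = numeric(0), pc0_k = 0,
              pc0_center = 0)
  for (b in biases) {
    if (b$kind %in% c("crosslink_tether", "sheet_pairs")) {
      out$ri <- c(out$ri, b$pairs[, 1] - 1L)
      out$rj <- c(out$rj, b$pairs[, 2] - 1L)
      out$rr0 <- c(out$rr0, b$r0)
      out$rk <- c(out$rk, b$k)
    } else if (b$kind == "harmonic_R") {
      if (out$rbias_k > 0) stop("only one harmonic_R bias is supported")
      out$ga <- as.integer(b$group_a - 1L)
      out$gb <- as.integer(b$group_b - 1L)
      out$rbias_k <- b$k; out$c0 <- b$center; out$c1 <- b$center_end
    } else if (b$kind == "harmonic_PC0") {
      if (out$pc0_k > 0) stop("only one harmonic_PC0 bias is supported")
      m <- b$model
      w <- matrix(0, n, 3)
      w[m$scope, ] <- matrix(m$components[, 1], ncol = 3, byrow = TRUE)
      ref <- matrix(0, n, 3)
      ref[m$scope, ] <- matrix(m$mean, ncol = 3, byrow = TRUE)
      out$pc0_w <- w
      out$pc0_ref <- as.vector(t(ref))
      out$pc0_k <- b$k; out$pc0_center <- b$center
    } else stop("unknown bias kind: ", b$kind)
  }
  out
}

#' Run Langevin dynamics on a topology
#'
#' BAOAB-discretized Langevin integration in reduced units (site mass 1,
#' energies kcal/mol, lengths Angstrom, kB = 0.0019872 kcal/mol/K). With
#' `friction = 0` the integrator is plain velocity Verlet (microcanonical),
#' which is used for energy-conservation checks. Fully reproducible under
#' a fixed seed.
#'
#' @param topology a [build_topology()] result
#' @param biases list of bias potentials
#' @param temperature Kelvin
#' @param n_steps integration steps (>= 1)
#' @param stride record every `stride` steps
#' @param seed integer
#' @param dt time step in reduced units, default 0.02
#' @param friction Langevin friction (1/time), default 0.2
#' @param coords0 starting coordinates (default: topology reference)
#' @return object of class `simulation_result`: recorded `frames` (list of
#'   matrices), per-frame potential/bias/kinetic energy, and the run
#'   parameters
#' @export
run_langevin <- function(topology, biases = list(), temperature = 300,
                         n_steps = 10000, stride = 100, seed = 1,
                         dt = 0.02, friction = 0.2, coords0 = NULL) {
  stopifnot(temperature > 0 || dt == 0, n_steps >= 1)
  if (is.null(coords0)) coords0 <- topology$xyz_ref
  coords0 <- as.matrix(coords0)
  bz <- collect_biases(topology, biases)
  kT <- 0.0019872 * temperature
  res <- cg_engine(coords0, 1.0,
                   as.integer(topology$bonds$i - 1L),
                   as.integer(topology$bonds$j - 1L),
                   topology$bonds$r0, topology$bond_k,
                   as.integer(topology$natives$i - 1L),
                   as.integer(topology$natives$j - 1L),
                   topology$natives$r0, topology$natives$depth,
                   if (is.null(topology$natives$sigma))
                     rep(topology$native_sigma, nrow(topology$natives))
                   else topology$natives$sigma,
                   as.integer(topology$rb$i - 1L),
                   as.integer(topology$rb$j - 1L),
                   topology$rb$depth, topology$rb_range, topology$rb_width,
                   topology$ev_radius, topology$ev_k,
                   bz$ri, bz$rj, bz$rr0, bz$rk,
                   bz$ga, bz$gb, bz$rbias_k, bz$c0, bz$c1,
                   bz$pc0_w, bz$pc0_ref, bz$pc0_k, bz$pc0_center,
                   dt, friction, kT, as.integer(n_steps),
                   as.integer(stride), as.integer(seed))
  ## engine stores coordinates site-major (x,y,z per site)
  frames <- lapply(seq_len(nrow(res$frames)), function(r)
    matrix(res$frames[r, ], ncol = 3, byrow = TRUE))
  structure(list(frames = frames, energy = res$energy,
                 bias_energy = res$bias_energy, kinetic = res$kinetic,
                 seed = seed,
                 params = list(temperature = temperature, dt = dt,
                               friction = friction, n_steps = n_steps,
                               stride = stride)),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("simulation_result:", length(x$frames), "frames,",
      x$params$n_steps, "steps at", x$params$temperature, "K\n")
  invisible(x)
}

#' Run an umbrella series over the ligand-pocket distance
#'
#' One window per center, each harmonically biased on R (the distance
#' between the pocket-site centroid and the ligand centroid). Windows run
#' sequentially from the bound configuration, each starting from the last
#' frame of the previous window; per-window seeds are derived from the
#' master seed. The first `equil_frac` of each window's frames is
#' discarded as equilibration.
#'
#' @param topology a `cg_topology` containing the ligand chain
#' @param base_biases biases applied in every window (e.g. the tether)
#' @param window_centers at least 3 centers, Angstrom
#' @param k_bias umbrella spring constant, kcal/mol/A^2 (0 triggers a
#'   warning: all windows sample the same distribution)
#' @param n_steps_per_window integration steps per window
#' @param temperature Kelvin
#' @param seed master seed
#' @param stride record every `stride` steps
#' @param pocket_annotation,ligand_chain define R
#' @param pca_model optional: record `pc0` per sample
#' @param qf_reference,qf_spec optional: record `q_f` per sample
#' @param equil_frac fraction of frames discarded per window, default 0.2
#' @param min_overlap warn when neighbouring windows share fewer occupied
#'   histogram bins than this, default 1
#' @return an [umbrella_dataset()] with coordinate `"r"`
#' @export
run_umbrella_series <- function(topology, base_biases = list(),
                                window_centers, k_bias = 2,
                                n_steps_per_window = 2e5,
                                temperature = 300, seed = 1, stride = 200,
                                pocket_annotation = "pocket",
                                ligand_chain = "B", pca_model = NULL,
                                qf_reference = NULL,
                                qf_spec = q_spec(pair_scope = "inter_domain"),
                                equil_frac = 0.2, min_overlap = 1) {
  if (length(window_centers) == 0) stop("zero-length window list")
  if (length(window_centers) < 3) stop("need at least 3 windows")
  if (k_bias == 0)
    warning("k_bias = 0: all windows sample the same distribution")
  topo_struct <- cg_structure(topology$sites, topology$annotations)
  pidx <- annotation_sites(topo_struct, pocket_annotation)
  lidx <- chain_sites(topo_struct, ligand_chain)

  centers <- sort(window_centers)
  coords0 <- topology$xyz_ref
  windows <- vector("list", length(centers))
  for (w in seq_along(centers)) {
    bias <- bias_harmonic_r(pidx, lidx, k_bias, centers[w])
    seed_w <- (seed + 7919L * w) %% 2147483647L
    res <- run_langevin(topology, biases = c(base_biases, list(bias)),
                        temperature = temperature,
                        n_steps = n_steps_per_window, stride = stride,
                        seed = seed_w, coords0 = coords0)
    coords0 <- res$frames[[length(res$frames)]]
    keep <- seq.int(floor(length(res$frames) * equil_frac) + 1,
                    length(res$frames))
    op <- frame_order_params(res$frames[keep], topo_struct,
                             pca_model = pca_model,
                             qf_reference = qf_reference,
                             qf_spec = qf_spec,
                             pocket_annotation = pocket_annotation,
                             ligand_chain = ligand_chain)
    windows[[w]] <- list(center = centers[w], k = k_bias,
                         samples = op[, setdiff(names(op), "frame"),
                                      drop = FALSE])
  }
  ds <- umbrella_dataset(windows, temperature = temperature, coord = "r")
  ov <- window_overlap(ds)
  gaps <- ov[ov$shared_bins < min_overlap, , drop = FALSE]
  if (nrow(gaps) > 0)
    warning("low histogram overlap between windows: ",
            paste(sprintf("%d-%d", gaps$a, gaps$b), collapse = ", "))
  ds
}
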