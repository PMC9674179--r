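#' Specification for the synthetic model system
#'
#' The synthetic system emulates the geometry of a tandem-RRM receptor: two
#' compact domains joined by a flexible linker, with an open and a closed
#' conformer related by a hinge rotation of domain 2 about the linker, and a
#' short single-stranded RNA ligand that docks into the inter-domain cleft
#' of the closed form. Domains are built as serpentine walks on a cubic
#' lattice with 3.8 A spacing (a compact fold with a well-defined native
#' contact network); the ligand is a 5-nucleotide chain with 6 A spacing.
#'
#' @param seed integer; every generator is a pure function of (spec, seed)
#' @param n_residues_per_domain default 40
#' @param linker_length residues between the domains, default 4
#' @param open_angle_deg hinge angle of the open conformer (degrees from the
#'   stacking axis), default 70
#' @param closed_angle_deg hinge angle of the closed conformer, default 100
#' @param ligand_length nucleotides, default 5
#' @param noise_sigma coordinate noise for ensemble generation, Angstrom
#' @param cleft_gap face-to-face gap of the closed cleft, Angstrom
#' @param planted_contacts optional data.frame with columns `residue_index`,
#'   `base_index`, `count` for the reference complex; default: each base
#'   contacts its two nearest pocket residues with counts 4 and 2
#' @return object of class `synthetic_spec`
#' @export
synthetic_spec <- function(seed = 1, n_residues_per_domain = 40,
                           linker_length = 4, open_angle_deg = 70,
                           closed_angle_deg = 100, ligand_length = 5,
                           noise_sigma = 0.5, cleft_gap = 8,
                           planted_contacts = NULL) {
  stopifnot(n_residues_per_domain >= 8, linker_length >= 1,
            ligand_length >= 1, noise_sigma >= 0,
            open_angle_deg != closed_angle_deg)
  structure(list(seed = as.integer(seed),
                 n_residues_per_domain = n_residues_per_domain,
                 linker_length = linker_length,
                 open_angle_deg = open_angle_deg,
                 closed_angle_deg = closed_angle_deg,
                 ligand_length = ligand_length,
                 noise_sigma = noise_sigma,
                 cleft_gap = cleft_gap,
                 planted_contacts = planted_contacts),
            class = "synthetic_spec")
}

## serpentine walk of n sites on a nx x ny x * lattice, spacing b:
## consecutive sites are lattice neighbours, so bonded distances are b
lattice_snake <- function(n, nx = 4, ny = 4, b = 3.8) {
  k <- seq_len(n) - 1
  l <- k %/% (nx * ny)
  r <- k %% (nx * ny)
  p <- ifelse(l %% 2 == 1, nx * ny - 1 - r, r)
  yy <- p %/% nx
  xx <- p %% nx
  xx <- ifelse(yy %% 2 == 1, nx - 1 - xx, xx)
  cbind(x = b * xx, y = b * yy, z = b * l)
}

rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}

## minimal rotation matrix mapping unit vector a onto unit vector b
rotation_align <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  cth <- sum(a * b)
  if (cth < -1 + 1e-10) {
    ## opposite vectors: 180 degrees about any perpendicular axis
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- p - sum(p * a) * a
    ax <- ax / sqrt(sum(ax^2))
    return(2 * outer(ax, ax) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + cth)
}

## receptor coordinates at hinge angle theta (degrees); returns list with
## coords, site bookkeeping and the ligand pose of the closed-form cleft
receptor_geometry <- function(spec, theta_deg) {
  n <- spec$n_residues_per_domain
  b <- 3.8
  d1 <- lattice_snake(n, b = b)
  L1 <- d1[n, ]
  d1_center <- colMeans(d1)

  d2_body <- lattice_snake(n, b = b)
  v1 <- d2_body[1, ] - colMeans(d2_body)
  d2_body <- sweep(d2_body, 2, colMeans(d2_body))

  ## arm radius fixed by the closed-cleft construction: at the closed angle
  ## domain 2 faces domain 1's +y face across a cleft_gap-wide cleft
  half_y <- (max(d1[, "y"]) - min(d1[, "y"])) / 2
  target <- c(d1_center["x"],
              max(d1[, "y"]) + spec$cleft_gap + half_y,
              d1_center["z"])
  arm <- sqrt(sum((target - L1)[2:3]^2))
  a <- theta_deg * pi / 180
  center <- c(d1_center["x"], L1["y"] + arm * sin(a), L1["z"] + arm * cos(a))
  ## orient domain 2 so its chain start faces the linker attachment
  d2_body <- d2_body %*% t(rotation_align(v1, L1 - center))
  d2 <- sweep(d2_body, 2, center, "+")

  ## linker: a bowed arc between the end of domain 1 and the start of
  ## domain 2 whose contour length matches 3.8 A bonds, so the free
  ## receptor has genuine slack (a taut straight linker would suppress
  ## the hinge entropy the closure thermodynamics depends on)
  nl <- spec$linker_length
  F2 <- d2[1, ]
  span <- F2 - L1
  mid_pt <- (L1 + F2) / 2
  away <- mid_pt - (d1_center + center) / 2
  away <- away - sum(away * span) * span / sum(span^2)
  if (sum(away^2) < 1e-8) away <- c(1, 0, 0)
  away <- away / sqrt(sum(away^2))
  target_len <- 3.8 * (nl + 1)
  bezier_pts <- function(h) {
    C <- mid_pt + h * away
    tt <- seq(0, 1, length.out = nl + 2)
    t(vapply(tt, function(t)
      (1 - t)^2 * L1 + 2 * t * (1 - t) * C + t^2 * F2, numeric(3)))
  }
  plen <- function(h) sum(sqrt(rowSums(diff(bezier_pts(h))^2)))
  h_hi <- target_len
  h <- if (plen(0) >= target_len) 0 else
    stats::uniroot(function(h) plen(h) - target_len, c(0, h_hi))$root
  linker <- bezier_pts(h)[2:(nl + 1), , drop = FALSE]
  xyz <- rbind(d1, linker, d2)
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))

  ## ligand pose in the closed cleft (defined by the closed construction)
  gap_mid_y <- max(d1[, "y"]) + spec$cleft_gap / 2
  lx <- (seq_len(spec$ligand_length) -
           (spec$ligand_length + 1) / 2) * 6 + d1_center["x"]
  ligand <- cbind(x = lx, y = rep(gap_mid_y, spec$ligand_length),
                  z = rep(d1_center["z"], spec$ligand_length))
  list(xyz = xyz, ligand = ligand, n = n, nl = nl)
}

## compress a sorted residue-index vector into annotation ranges
indices_to_ranges <- function(chain, idx) {
  idx <- sort(unique(idx))
  breaks <- c(0, which(diff(idx) > 1), length(idx))
  lapply(seq_len(length(breaks) - 1), function(k)
    list(chain = chain, from = idx[breaks[k] + 1], to = idx[breaks[k + 1]]))
}

#' Generate the open/closed two-domain receptor pair
#'
#' Two conformers sharing one topology (single protein chain A: domain 1,
#' linker, domain 2), differing by the hinge angle of domain 2. The closed
#' conformer presents an inter-domain cleft; residues lining it carry the
#' `pocket` annotation (defined on the closed geometry and attached to both
#' conformers). Pocket residues are assigned basic/polar residue types
#' (ARG/LYS/ASN/SER cycle) against a glycine background, so that a
#' residue-base potential built from the reference complex engages the
#' pocket specifically.
#'
#' @param spec a [synthetic_spec()]
#' @return list with elements `open` and `closed` (`cg_structure`)
#' @export
make_two_domain_receptor <- function(spec = synthetic_spec()) {
  go <- receptor_geometry(spec, spec$open_angle_deg)
  gc <- receptor_geometry(spec, spec$closed_angle_deg)
  n <- go$n; nl <- go$nl
  ntot <- 2 * n + nl

  ## degenerate-geometry guard
  for (g in list(go, gc)) {
    dmin <- min(stats::dist(g$xyz))
    if (dmin < 2.5)
      stop("degenerate geometry: overlapping sites (min distance ",
           round(dmin, 2), " A)")
  }

  ## pocket: receptor residues within 8 A of the closed-cleft ligand pose
  dl <- as.matrix(stats::dist(rbind(gc$xyz, gc$ligand)))
  dl <- dl[seq_len(ntot), ntot + seq_len(spec$ligand_length), drop = FALSE]
  pocket_idx <- which(apply(dl, 1, min) <= 8)

  types <- rep("GLY", ntot)
  types[pocket_idx] <- rep(c("ARG", "LYS", "ASN", "SER"),
                           length.out = length(pocket_idx))
  sites <- data.frame(chain_id = "A", residue_index = seq_len(ntot),
                      residue_type = types, molecule_class = "protein",
                      x = 0, y = 0, z = 0, site_role = "backbone_rep",
                      stringsAsFactors = FALSE)
  ann <- list(
    dom1 = list(chain = "A", from = 1, to = n),
    linker = list(chain = "A", from = n + 1, to = n + nl),
    dom2 = list(chain = "A", from = n + nl + 1, to = ntot),
    pocket = indices_to_ranges("A", pocket_idx)
  )
  open <- set_coords(cg_structure(sites, ann), go$xyz)
  closed <- set_coords(cg_structure(sites, ann), gc$xyz)
  list(open = open, closed = closed)
}

#' Generate an ensemble with a planted bimodal first principal component
#'
#' Frames are Gaussian-noise perturbations of the open and closed
#' conformers mixed in the stated proportions, so that a cartesian PCA of
#' the ensemble has a bimodal leading component separating the two modes.
#' The planted mode label of each frame is stored in `frame_labels`.
#'
#' @param spec a [synthetic_spec()]
#' @param n_frames at least 2
#' @param mode_fractions length-2 non-negative weights summing to 1
#'   (open, closed)
#' @return a `cg_ensemble` with `frame_labels` in `c("open", "closed")`
#' @export
make_bimodal_ensemble <- function(spec = synthetic_spec(), n_frames = 200,
                                  mode_fractions = c(0.5, 0.5)) {
  if (n_frames < 2) stop("n_frames must be at least 2")
  if (abs(sum(mode_fractions) - 1) > 1e-8 || any(mode_fractions < 0))
    stop("mode_fractions must be non-negative and sum to 1")
  conf <- make_two_domain_receptor(spec)
  refs <- list(open = coords(conf$open), closed = coords(conf$closed))
  set.seed(spec$seed)
  labels <- sample(c("open", "closed"), n_frames, replace = TRUE,
                   prob = mode_fractions)
  frames <- lapply(labels, function(lb) {
    x <- refs[[lb]]
    if (spec$noise_sigma > 0)
      x <- x + matrix(stats::rnorm(length(x), 0, spec$noise_sigma),
                      ncol = 3)
    x
  })
  cg_ensemble(conf$open, frames, frame_labels = labels)
}

#' Analytic umbrella-sampling oracle on a harmonic landscape
#'
#' Draws exact Boltzmann samples from the 1D potential
#' \eqn{U(x) = k_{true} x^2 / 2} plus a harmonic window bias
#' \eqn{k_{bias}(x - c)^2 / 2}: the biased distribution in window c is
#' Gaussian with mean \eqn{c\,k_{bias}/(k_{true}+k_{bias})} and variance
#' \eqn{k_B T/(k_{true}+k_{bias})}. The analytic free energy
#' \eqn{F(x) = k_{true} x^2/2} is attached as metadata, giving the WHAM
#' machinery a closed-form ground truth.
#'
#' @param k_true kcal/mol/A^2
#' @param centers at least 3 window centers
#' @param k_bias kcal/mol/A^2
#' @param n_samples samples per window
#' @param temperature Kelvin
#' @param seed integer
#' @return an [umbrella_dataset()] with coordinate name `"x"`
#' @export
make_umbrella_oracle <- function(k_true = 1, centers = seq(-5, 5, 1),
                                 k_bias = 5, n_samples = 5000,
                                 temperature = 300, seed = 1) {
  if (k_true <= 0 || k_bias <= 0) stop("spring constants must be positive")
  if (length(centers) < 3) stop("need at least 3 windows")
  kT <- 0.0019872 * temperature
  set.seed(seed)
  windows <- lapply(centers, function(cc) {
    mu <- cc * k_bias / (k_true + k_bias)
    sd <- sqrt(kT / (k_true + k_bias))
    list(center = cc, k = k_bias,
         samples = data.frame(x = stats::rnorm(n_samples, mu, sd)))
  })
  umbrella_dataset(windows, temperature = temperature, coord = "x",
                   metadata = list(k_true = k_true,
                                   truth = function(x) 0.5 * k_true * x^2))
}

default_planted_contacts <- function(receptor_closed, ligand, pocket_idx) {
  xyz <- coords(receptor_closed)
  out <- list()
  used <- integer(0)
  counts <- c(4, 2, 3, 2, 4)
  for (j in seq_len(nrow(ligand))) {
    d <- sqrt(colSums((t(xyz[pocket_idx, , drop = FALSE]) - ligand[j, ])^2))
    ord <- setdiff(pocket_idx[order(d)], used)[1]
    out[[length(out) + 1]] <- data.frame(
      residue_index = ord, base_index = j,
      count = counts[(j - 1) %% length(counts) + 1])
    used <- c(used, ord)
  }
  do.call(rbind, out)
}

#' Generate a reference complex with planted atomic contact counts
#'
#' Builds the closed receptor with the RNA ligand docked in the cleft, plus
#' a synthetic heavy-atom table constructed so that
#' [count_atomic_contacts()] (4.5 A atomic cutoff) recovers exactly the
#' planted per-pair counts: each planted (residue, base, count) pair is
#' realized as `count` atom pairs 3 A apart, arranged on a ring with enough
#' margin that cross pairs stay beyond the cutoff and a sub-0.1 A jitter of
#' the atoms cannot change any count.
#'
#' @param spec a [synthetic_spec()]
#' @return a `cg_structure` with chains A (protein) and B (RNA), a `pocket`
#'   annotation, and `atom_records`; the planted table is attached as
#'   attribute `planted_contacts`
#' @export
make_reference_complex <- function(spec = synthetic_spec()) {
  conf <- make_two_domain_receptor(spec)
  gc <- receptor_geometry(spec, spec$closed_angle_deg)
  rec <- conf$closed
  nrec <- nrow(rec$sites)

  bases <- rep(c("U", "A"), length.out = spec$ligand_length)
  lig_sites <- data.frame(chain_id = "B",
                          residue_index = seq_len(spec$ligand_length),
                          residue_type = bases, molecule_class = "rna",
                          x = gc$ligand[, "x"], y = gc$ligand[, "y"],
                          z = gc$ligand[, "z"], site_role = "backbone_rep",
                          stringsAsFactors = FALSE)
  sites <- rbind(rec$sites, lig_sites)

  planted <- spec$planted_contacts
  if (is.null(planted))
    planted <- default_planted_contacts(rec, gc$ligand,
                                        annotation_sites(rec, "pocket"))
  ## Each planted (residue, base, count) entry is realized as `count`
  ## atom pairs 4.0 A apart (cutoff 4.5: 0.5 A jitter margin), stacked
  ## 5 A apart along z; entries are spaced 25 A apart vertically so no
  ## cross-entry atom pair can approach the cutoff.
  atoms <- list()
  if (!is.null(planted) && nrow(planted) > 0) {
    ne <- nrow(planted)
    for (r in seq_len(ne)) {
      i <- planted$residue_index[r]
      j <- planted$base_index[r]
      cc <- planted$count[r]
      pj <- gc$ligand[j, ]
      z0 <- pj["z"] + (r - (ne + 1) / 2) * 25
      for (k in seq_len(cc)) {
        zk <- z0 + (k - 1) * 5
        atoms[[length(atoms) + 1]] <- data.frame(
          chain_id = c("A", "B"), residue_index = c(i, j),
          x = rep(pj["x"], 2), y = pj["y"] + c(-2, 2),
          z = rep(zk, 2), stringsAsFactors = FALSE)
      }
    }
  }
  atom_records <- if (length(atoms) > 0) do.call(rbind, atoms) else
    data.frame(chain_id = character(0), residue_index = integer(0),
               x = numeric(0), y = numeric(0), z = numeric(0))

  cx <- cg_structure(sites, annotations = rec$annotations,
                     atom_records = atom_records)
  ## verify the planting is realized exactly under the declared contact rule
  got <- count_atomic_contacts(cx, cutoff = 4.5)
  want <- planted[order(planted$residue_index, planted$base_index), ,
                  drop = FALSE]
  got <- got[order(got$residue_index, got$base_index), , drop = FALSE]
  ok <- nrow(got) == nrow(want) &&
    (nrow(got) == 0 ||
       (all(got$residue_index == want$residue_index) &&
          all(got$base_index == want$base_index) &&
          all(got$count == want$count)))
  if (!ok) stop("infeasible planting: realized contact counts differ ",
                "from the planted table")
  attr(cx, "planted_contacts") <- want
  cx
}

#' Generate a scan sequence with planted high-affinity windows
#'
#' Produces a random background sequence over hydrophilic residue types and
#' plants, at each requested start position, a window whose composition
#' (all isoleucine) maximizes the packaged hydropathy contact potential
#' against any partner, so an exhaustive binding scan attains its minimum
#' at the planted position(s).
#'
#' @param window_start 1-based start position(s) of the planted window(s)
#' @param length window length, default 11
#' @param seed integer
#' @param total_length sequence length, default 400
#' @return list with `id` and `sequence` (1-letter codes)
#' @export
make_scan_sequence <- function(window_start = 273, length = 11, seed = 1,
                               total_length = 400) {
  if (any(window_start < 1) || any(window_start + length - 1 > total_length))
    stop("planted window does not fit in the sequence")
  set.seed(seed)
  background <- c("D", "E", "K", "N", "Q", "R", "S", "T", "G", "P", "H")
  seq_chars <- sample(background, total_length, replace = TRUE)
  for (ws in window_start)
    seq_chars[ws:(ws + length - 1)] <- "I"
  list(id = sprintf("synthetic_scan_seed%d", seed),
       sequence = paste(seq_chars, collapse = ""))
}

#' Generate a synthetic SIM/SUMO-like peptide-partner complex
#'
#' A compact 24-residue partner protein (chain S) with a 6-residue peptide
#' (chain P) lying in register along its top face at beta-sheet pairing
#' distance. Annotations: `SIM` (the peptide), `beta2` (the partner strand
#' residues paired with it). Used as the template geometry for sequence
#' scans and for screening predicted peptide poses.
#'
#' @param gap peptide-to-strand distance, Angstrom (default 4.8)
#' @return a `cg_structure`
#' @export
make_sim_partner_complex <- function(gap = 4.8) {
  b <- 3.8
  partner <- lattice_snake(24, nx = 6, ny = 3, b = b)
  ztop <- max(partner[, "z"])
  ## the six top-layer sites of one row form the pairing strand; the
  ## peptide lies directly above them in register
  top <- which(partner[, "z"] == ztop)
  row_y <- sort(unique(partner[top, "y"]))[1]
  strand <- top[partner[top, "y"] == row_y]
  strand <- strand[order(partner[strand, "x"])][1:6]
  pep <- cbind(x = partner[strand, "x"], y = partner[strand, "y"],
               z = rep(ztop + gap, 6))
  beta2_idx <- strand
  types_s <- rep("SER", 24)
  types_s[beta2_idx] <- rep(c("ILE", "VAL"), length.out = length(beta2_idx))
  pep_types <- c("VAL", "ILE", "ASP", "LEU", "THR", "VAL")
  sites <- rbind(
    data.frame(chain_id = "S", residue_index = 1:24, residue_type = types_s,
               molecule_class = "protein", x = partner[, "x"],
               y = partner[, "y"], z = partner[, "z"],
               site_role = "backbone_rep", stringsAsFactors = FALSE),
    data.frame(chain_id = "P", residue_index = 1:6, residue_type = pep_types,
               molecule_class = "protein", x = pep[, "x"], y = pep[, "y"],
               z = pep[, "z"], site_role = "backbone_rep",
               stringsAsFactors = FALSE))
  ann <- list(SIM = list(chain = "P", from = 1, to = 6),
              beta2 = indices_to_ranges("S", beta2_idx))
  cg_structure(sites, annotations = ann)
}
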