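#' Pairwise contact potential
#'
#' Holds well depths (kcal/mol, positive = attractive well) for
#' protein-protein residue-type pairs and for residue-type x base-type
#' pairs, a global scale lambda, and the geometry of the interaction well:
#' full strength up to `contact_range`, then a smooth cosine taper to zero
#' over `well_width`. Interaction energies are negative (well depth times
#' the switching function).
#'
#' @param protein_pairs symmetric named matrix of residue-pair well depths,
#'   or NULL for the packaged hydropathy-based default
#' @param residue_base named matrix (rows: 3-letter residue types, columns:
#'   base letters) of residue-base well depths
#' @param lambda global scale applied to residue-base depths, > 0
#' @param contact_range Angstrom, default 6.5
#' @param well_width taper width, Angstrom, default 2
#' @param atomic_cutoff heavy-atom contact cutoff, default 4.5
#' @param cg_cutoff site-level contact cutoff, default 8
#' @return object of class `contact_potential`
#' @export
contact_potential <- function(protein_pairs = NULL, residue_base = NULL,
                              lambda = 1, contact_range = 6.5,
                              well_width = 2, atomic_cutoff = 4.5,
                              cg_cutoff = 8) {
  stopifnot(lambda > 0, contact_range > 0, well_width > 0)
  if (is.null(protein_pairs)) protein_pairs <- hydropathy_pair_matrix()
  if (!isSymmetric(unname(protein_pairs)))
    stop("protein pair strengths must be symmetric")
  if (!all(is.finite(protein_pairs)))
    stop("well depths must be finite")
  if (!is.null(residue_base) && !all(is.finite(residue_base)))
    stop("well depths must be finite")
  structure(list(protein_pairs = protein_pairs,
                 residue_base = residue_base, lambda = lambda,
                 contact_range = contact_range, well_width = well_width,
                 atomic_cutoff = atomic_cutoff, cg_cutoff = cg_cutoff),
            class = "contact_potential")
}

## Kyte-Doolittle hydropathy, 3-letter codes
kd_hydropathy <- c(
  ILE = 4.5, VAL = 4.2, LEU = 3.8, PHE = 2.8, CYS = 2.5, MET = 1.9,
  ALA = 1.8, GLY = -0.4, THR = -0.7, SER = -0.8, TRP = -0.9, TYR = -1.3,
  PRO = -1.6, HIS = -3.2, GLU = -3.5, GLN = -3.5, ASP = -3.5, ASN = -3.5,
  LYS = -3.9, ARG = -4.5)

#' Packaged hydropathy-based protein pair strengths
#'
#' A simple symmetric well-depth table
#' \eqn{\epsilon(a,b) = (h^+(a) + h^+(b)) / (2 h_{max})} from the positive
#' part of the Kyte-Doolittle hydropathy scale, normalized so the deepest
#' pair (Ile-Ile) has depth 1. A toy stand-in for a knowledge-based contact
#' scoring table: hydrophobic pairings score, polar ones do not.
#'
#' @return 20 x 20 named symmetric matrix
#' @export
hydropathy_pair_matrix <- function() {
  hp <- pmax(kd_hydropathy, 0)
  m <- outer(hp, hp, function(a, b) (a + b) / (2 * max(hp)))
  dimnames(m) <- list(names(kd_hydropathy), names(kd_hydropathy))
  m
}

## smooth switching function: 1 up to rc, cosine taper to 0 over w
switch_fun <- function(r, rc, w) {
  s <- numeric(length(r))
  s[r <= rc] <- 1
  mid <- r > rc & r < rc + w
  s[mid] <- 0.5 * (1 + cos(pi * (r[mid] - rc) / w))
  s
}

#' Count residue-base atomic contacts in a reference complex
#'
#' For every (protein residue, RNA base) pair, counts atom pairs within
#' `cutoff` when the structure carries heavy-atom records, or site pairs
#' (counts 0/1) at coarse-grained resolution. This is the reference
#' quantity a residue-base potential is calibrated from.
#'
#' @param reference a `cg_structure` containing at least one protein and
#'   one RNA chain
#' @param cutoff Angstrom; default 4.5 with atoms, 8 at CG resolution
#' @return data.frame with `residue_index`, `base_index`, `residue_type`,
#'   `base_type`, `count` (pairs with zero count omitted)
#' @export
count_atomic_contacts <- function(reference, cutoff = NULL) {
  s <- reference$sites
  if (!any(s$molecule_class == "rna")) stop("reference has no RNA chain")
  if (!any(s$molecule_class == "protein"))
    stop("reference has no protein chain")
  has_atoms <- !is.null(reference$atom_records)
  if (is.null(cutoff)) cutoff <- if (has_atoms) 4.5 else 8
  prot_chains <- unique(s$chain_id[s$molecule_class == "protein"])
  rna_chains <- unique(s$chain_id[s$molecule_class == "rna"])

  type_of <- function(chain, resno) {
    s$residue_type[match(paste(chain, resno), paste(s$chain_id,
                                                    s$residue_index))]
  }
  if (has_atoms) {
    at <- reference$atom_records
    pa <- at[at$chain_id %in% prot_chains, , drop = FALSE]
    na_ <- at[at$chain_id %in% rna_chains, , drop = FALSE]
    if (nrow(pa) == 0 || nrow(na_) == 0 || cutoff <= 0)
      return(data.frame(residue_index = integer(0), base_index = integer(0),
                        residue_type = character(0),
                        base_type = character(0), count = integer(0)))
    dx <- outer(pa$x, na_$x, "-")
    dy <- outer(pa$y, na_$y, "-")
    dz <- outer(pa$z, na_$z, "-")
    close <- sqrt(dx^2 + dy^2 + dz^2) <= cutoff
    hits <- which(close, arr.ind = TRUE)
    if (nrow(hits) == 0)
      return(data.frame(residue_index = integer(0), base_index = integer(0),
                        residue_type = character(0),
                        base_type = character(0), count = integer(0)))
    key <- data.frame(residue_index = pa$residue_index[hits[, 1]],
                      base_index = na_$residue_index[hits[, 2]])
    agg <- stats::aggregate(list(count = rep(1L, nrow(key))), key, sum)
  } else {
    pidx <- which(s$molecule_class == "protein")
    ridx <- which(s$molecule_class == "rna")
    xyz <- coords(reference)
    dx <- outer(xyz[pidx, 1], xyz[ridx, 1], "-")
    dy <- outer(xyz[pidx, 2], xyz[ridx, 2], "-")
    dz <- outer(xyz[pidx, 3], xyz[ridx, 3], "-")
    close <- sqrt(dx^2 + dy^2 + dz^2) <= cutoff
    hits <- which(close, arr.ind = TRUE)
    if (nrow(hits) == 0 || cutoff <= 0)
      return(data.frame(residue_index = integer(0), base_index = integer(0),
                        residue_type = character(0),
                        base_type = character(0), count = integer(0)))
    agg <- data.frame(residue_index = s$residue_index[pidx[hits[, 1]]],
                      base_index = s$residue_index[ridx[hits[, 2]]],
                      count = 1L)
  }
  agg$residue_type <- type_of(prot_chains[1], agg$residue_index)
  agg$base_type <- type_of(rna_chains[1], agg$base_index)
  agg <- agg[order(agg$residue_index, agg$base_index),
             c("residue_index", "base_index", "residue_type", "base_type",
               "count")]
  rownames(agg) <- NULL
  agg
}

#' Build a residue-base potential from reference contact counts
#'
#' Counts are pooled over instances by (residue type, base type); the well
#' depth of a type pair is `lambda` times its pooled count divided by the
#' maximum pooled count, so depths lie in (0, lambda] and scale linearly
#' with lambda. Type pairs absent from the reference get zero depth.
#'
#' @param contact_counts data.frame as returned by
#'   [count_atomic_contacts()] (needs `residue_type`, `base_type`, `count`)
#' @param lambda global scale, > 0
#' @param ... other arguments passed to [contact_potential()]
#' @return a `contact_potential`
#' @export
build_residue_base_potential <- function(contact_counts, lambda = 1, ...) {
  if (nrow(contact_counts) == 0 || all(contact_counts$count == 0))
    stop("cannot build a potential from all-zero contact counts")
  pooled <- stats::aggregate(count ~ residue_type + base_type,
                             contact_counts, sum)
  pooled <- pooled[pooled$count > 0, ]
  rtypes <- sort(unique(pooled$residue_type))
  btypes <- sort(unique(pooled$base_type))
  eps <- matrix(0, length(rtypes), length(btypes),
                dimnames = list(rtypes, btypes))
  for (r in seq_len(nrow(pooled)))
    eps[pooled$residue_type[r], pooled$base_type[r]] <-
      lambda * pooled$count[r] / max(pooled$count)
  contact_potential(residue_base = eps, lambda = lambda, ...)
}

## well depth for a pair of sites under a potential (0 when untabulated)
pair_depth <- function(potential, type_i, class_i, type_j, class_j) {
  n <- length(type_i)
  d <- numeric(n)
  pp <- class_i == "protein" & class_j == "protein"
  if (any(pp)) {
    m <- potential$protein_pairs
    ok <- pp & type_i %in% rownames(m) & type_j %in% colnames(m)
    d[ok] <- m[cbind(type_i[ok], type_j[ok])]
  }
  pr <- class_i == "protein" & class_j == "rna"
  rp <- class_i == "rna" & class_j == "protein"
  if ((any(pr) || any(rp)) && !is.null(potential$residue_base)) {
    m <- potential$residue_base
    ok <- pr & type_i %in% rownames(m) & type_j %in% colnames(m)
    d[ok] <- m[cbind(type_i[ok], type_j[ok])]
    ok <- rp & type_j %in% rownames(m) & type_i %in% colnames(m)
    d[ok] <- m[cbind(type_j[ok], type_i[ok])]
  }
  d
}

#' Binding energy between two groups of chains
#'
#' Sums, over all site pairs spanning the two partners, the (negative) well
#' depth times the smooth switching function of the pair distance. Zero
#' beyond `contact_range + well_width`; more negative means stronger
#' binding. Depends only on internal distances (rigid-motion invariant) and
#' decomposes additively over chain pairs.
#'
#' @param complex a `cg_structure`
#' @param partner_a,partner_b disjoint character vectors of chain ids
#' @param potential a [contact_potential()]
#' @return energy in kcal/mol
#' @export
binding_energy <- function(complex, partner_a, partner_b, potential) {
  if (length(intersect(partner_a, partner_b)) > 0)
    stop("partner chain sets must be disjoint")
  s <- complex$sites
  ia <- which(s$chain_id %in% partner_a)
  ib <- which(s$chain_id %in% partner_b)
  if (length(ia) == 0 || length(ib) == 0)
    stop("both partners must be non-empty")
  xyz <- coords(complex)
  grid <- expand.grid(i = ia, j = ib)
  d <- sqrt(rowSums((xyz[grid$i, , drop = FALSE] -
                       xyz[grid$j, , drop = FALSE])^2))
  keep <- d < potential$contact_range + potential$well_width
  if (!any(keep)) return(0)
  grid <- grid[keep, ]; d <- d[keep]
  depth <- pair_depth(potential, s$residue_type[grid$i],
                      s$molecule_class[grid$i], s$residue_type[grid$j],
                      s$molecule_class[grid$j])
  -sum(depth * switch_fun(d, potential$contact_range, potential$well_width))
}

#' Frustration z-scores against identity-shuffled decoys
#'
#' For every inter-molecular (or inter-domain) contact in the complex, the
#' native pair energy is compared with decoys obtained by redrawing the two
#' identities from the complex's own composition (mutational frustration
#' scheme). The z-score is (mean decoy energy - native energy) / SD(decoy
#' energies); a contact is minimally frustrated when z exceeds
#' `z_threshold` (0.78, the standard frustratometer convention).
#'
#' @param complex a `cg_structure`
#' @param potential a [contact_potential()]
#' @param n_decoys at least 100, default 1000
#' @param seed integer
#' @param z_threshold default 0.78
#' @param scope `"inter_molecular"` (default) or `"inter_domain"` (uses the
#'   structure's domain annotations)
#' @param domains annotation names for `"inter_domain"` scope
#' @return object of class `frustration_report`: data.frame of contacts
#'   with native energy, decoy mean/SD and z, plus attributes
#'   `n_minimally_frustrated` and `z_threshold`
#' @export
frustration_zscores <- function(complex, potential, n_decoys = 1000,
                                seed = 1, z_threshold = 0.78,
                                scope = c("inter_molecular", "inter_domain"),
                                domains = NULL) {
  scope <- match.arg(scope)
  if (n_decoys < 100) stop("n_decoys must be at least 100")
  s <- complex$sites
  xyz <- coords(complex)
  n <- nrow(s)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- ij[, 1]; j <- ij[, 2]
  if (scope == "inter_molecular") {
    keep <- s$chain_id[i] != s$chain_id[j]
  } else {
    dn <- domains
    if (is.null(dn)) dn <- names(complex$annotations)
    dom <- rep(NA_character_, n)
    for (nm in dn) dom[annotation_sites(complex, nm)] <- nm
    keep <- !is.na(dom[i]) & !is.na(dom[j]) & dom[i] != dom[j]
  }
  i <- i[keep]; j <- j[keep]
  d <- sqrt(rowSums((xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE])^2))
  inrange <- d < potential$contact_range + potential$well_width
  i <- i[inrange]; j <- j[inrange]; d <- d[inrange]
  if (length(i) == 0) stop("no contacts in scope")
  sw <- switch_fun(d, potential$contact_range, potential$well_width)
  native <- -pair_depth(potential, s$residue_type[i], s$molecule_class[i],
                        s$residue_type[j], s$molecule_class[j]) * sw

  set.seed(seed)
  dec_mean <- dec_sd <- numeric(length(i))
  for (k in seq_along(i)) {
    pool_i <- s$residue_type[s$molecule_class == s$molecule_class[i[k]]]
    pool_j <- s$residue_type[s$molecule_class == s$molecule_class[j[k]]]
    ti <- sample(pool_i, n_decoys, replace = TRUE)
    tj <- sample(pool_j, n_decoys, replace = TRUE)
    e <- -pair_depth(potential, ti,
                     rep(s$molecule_class[i[k]], n_decoys), tj,
                     rep(s$molecule_class[j[k]], n_decoys)) * sw[k]
    dec_mean[k] <- mean(e)
    dec_sd[k] <- stats::sd(e)
  }
  if (any(dec_sd == 0))
    stop("contact with zero decoy variance (homogeneous composition)")
  z <- (dec_mean - native) / dec_sd
  rep_df <- data.frame(site_i = i, site_j = j, distance = d,
                       native_energy = native, decoy_mean = dec_mean,
                       decoy_sd = dec_sd, z = z)
  structure(rep_df, class = c("frustration_report", "data.frame"),
            n_minimally_frustrated = sum(z > z_threshold),
            z_threshold = z_threshold)
}

#' Rank candidate complex structures by frustration and energy
#'
#' Evaluates each frame's inter-molecular binding energy and number of
#' minimally frustrated contacts, and selects the frame with the largest
#' count, breaking ties by lowest energy.
#'
#' @param ensemble a `cg_ensemble` whose topology has at least two chains
#' @param potential a [contact_potential()]
#' @param partner_a,partner_b chain sets for the binding energy
#' @param n_decoys,seed,z_threshold passed to [frustration_zscores()]
#' @return list with `table` (frame, energy, n_minimally_frustrated) and
#'   `selected` (frame index)
#' @export
rank_models <- function(ensemble, potential, partner_a, partner_b,
                        n_decoys = 1000, seed = 1, z_threshold = 0.78) {
  nf <- n_frames(ensemble)
  energy <- nmin <- numeric(nf)
  for (f in seq_len(nf)) {
    st <- ensemble_frame(ensemble, f)
    energy[f] <- binding_energy(st, partner_a, partner_b, potential)
    nmin[f] <- tryCatch(
      attr(frustration_zscores(st, potential, n_decoys = n_decoys,
                               seed = seed, z_threshold = z_threshold),
           "n_minimally_frustrated"),
      error = function(e) {
        if (grepl("no contacts", conditionMessage(e))) 0L else stop(e)
      })
  }
  ord <- order(-nmin, energy)
  list(table = data.frame(frame = seq_len(nf), energy = energy,
                          n_minimally_frustrated = nmin),
       selected = ord[1])
}

aa1_to_aa3 <- function(seq1) {
  map <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
           Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
           L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
           S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")
  ch <- strsplit(toupper(seq1), "")[[1]]
  out <- map[ch]
  if (any(is.na(out)))
    stop("sequence contains residues absent from the potential table: ",
         paste(unique(ch[is.na(out)]), collapse = ", "))
  unname(out)
}

#' Scan a sequence over a peptide in a complex
#'
#' Threads every window of the sequence onto the peptide sites of the
#' complex (same geometry, new residue identities) and evaluates the
#' binding energy of the peptide chain against the rest of the complex.
#' The energy of the original peptide sequence is attached as the
#' reference.
#'
#' @param sequence protein sequence, 1-letter codes
#' @param partner_complex a `cg_structure` with a peptide annotation
#' @param peptide_annotation annotation naming the peptide sites,
#'   default `"SIM"`
#' @param potential a [contact_potential()]
#' @return data.frame with `start` (1-based window start) and `energy`;
#'   attribute `reference_energy` holds the original peptide's energy
#' @export
scan_sequence_binding <- function(sequence, partner_complex,
                                  peptide_annotation = "SIM",
                                  potential = contact_potential()) {
  pep_idx <- annotation_sites(partner_complex, peptide_annotation)
  L <- length(pep_idx)
  if (nchar(sequence) < L)
    stop("sequence shorter than the peptide window")
  pep_chain <- unique(partner_complex$sites$chain_id[pep_idx])
  stopifnot(length(pep_chain) == 1)
  other <- setdiff(partner_complex$chain_table$chain_id, pep_chain)
  ref_energy <- binding_energy(partner_complex, pep_chain, other, potential)

  aa3 <- aa1_to_aa3(sequence)
  nwin <- length(aa3) - L + 1
  energy <- numeric(nwin)
  work <- partner_complex
  for (s0 in seq_len(nwin)) {
    work$sites$residue_type[pep_idx] <- aa3[s0:(s0 + L - 1)]
    energy[s0] <- binding_energy(work, pep_chain, other, potential)
  }
  structure(data.frame(start = seq_len(nwin), energy = energy),
            reference_energy = ref_energy)
}
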