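#' Specification for mutual-Q calculations
#'
#' The mutual Q between structures A and B averages
#' \eqn{\exp(-(r^A_{ij}-r^B_{ij})^2 / (2\delta_{ij}^2))} over a set of
#' residue pairs. For pairs within one chain the tolerance grows with
#' sequence separation, \eqn{\delta_{ij} = |i-j|^{0.15}} (Angstrom); for
#' pairs across chains \eqn{\delta_{ij}^2} is the constant
#' `delta_inter_sq` (default 5 A^2). A pair enters the average when the two
#' residues are within `contact_threshold` (default 12 A) in either
#' structure (union rule). Pairs closer than `min_seq_sep` in sequence along
#' one chain are excluded as trivially constrained by connectivity.
#'
#' @param pair_scope which pairs to include: `"all"` (all inter-molecular
#'   plus all intra-chain pairs beyond `min_seq_sep`), `"inter_domain"`
#'   (pairs whose residues belong to two different annotated domains),
#'   or `"inter_molecular"` (pairs across chains only)
#' @param contact_threshold Angstrom, default 12
#' @param delta_intra_exponent exponent of the intra-chain tolerance,
#'   default 0.15
#' @param delta_inter_sq squared inter-chain tolerance, A^2, default 5
#' @param min_seq_sep minimum |i-j| for intra-chain pairs, default 3
#' @param domains character vector of annotation names treated as domains
#'   for `"inter_domain"` scope; default: every annotation of the structure
#' @param qc_threshold screening threshold for template Q, default 0.2
#'   (selection is strict: Q_c must exceed it)
#' @return object of class `q_spec`
#' @export
q_spec <- function(pair_scope = c("all", "inter_domain", "inter_molecular"),
                   contact_threshold = 12, delta_intra_exponent = 0.15,
                   delta_inter_sq = 5, min_seq_sep = 3, domains = NULL,
                   qc_threshold = 0.2) {
  pair_scope <- match.arg(pair_scope)
  stopifnot(contact_threshold > 0, delta_intra_exponent >= 0,
            delta_inter_sq > 0, min_seq_sep >= 0)
  structure(list(pair_scope = pair_scope,
                 contact_threshold = contact_threshold,
                 delta_intra_exponent = delta_intra_exponent,
                 delta_inter_sq = delta_inter_sq,
                 min_seq_sep = min_seq_sep, domains = domains,
                 qc_threshold = qc_threshold),
            class = "q_spec")
}

## candidate pair table for a topology under a q_spec:
## columns i, j (site row indices), delta_sq
q_pair_table <- function(topology, spec) {
  s <- topology$sites
  n <- nrow(s)
  if (n < 2) stop("structure has fewer than 2 sites")
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- ij[, 1]; j <- ij[, 2]
  same_chain <- s$chain_id[i] == s$chain_id[j]
  sep <- abs(s$residue_index[i] - s$residue_index[j])
  keep <- !same_chain | sep >= spec$min_seq_sep

  if (spec$pair_scope == "inter_molecular") {
    keep <- keep & !same_chain
  } else if (spec$pair_scope == "inter_domain") {
    dn <- spec$domains
    if (is.null(dn)) dn <- names(topology$annotations)
    if (length(dn) == 0)
      stop("inter_domain scope requires domain annotations")
    dom <- rep(NA_character_, n)
    for (nm in dn) dom[annotation_sites(topology, nm)] <- nm
    keep <- keep & !is.na(dom[i]) & !is.na(dom[j]) & dom[i] != dom[j]
  }
  i <- i[keep]; j <- j[keep]; same_chain <- same_chain[keep]
  sep <- sep[keep]
  delta_sq <- ifelse(same_chain,
                     (sep^spec$delta_intra_exponent)^2,
                     spec$delta_inter_sq)
  data.frame(i = i, j = j, delta_sq = delta_sq)
}

pair_distances <- function(xyz, pairs) {
  d <- xyz[pairs$i, , drop = FALSE] - xyz[pairs$j, , drop = FALSE]
  sqrt(rowSums(d * d))
}

q_from_distances <- function(dA, dB, pairs, threshold) {
  sel <- dA <= threshold | dB <= threshold
  if (!any(sel)) stop("empty pair set: no pairs within the contact threshold")
  mean(exp(-(dA[sel] - dB[sel])^2 / (2 * pairs$delta_sq[sel])))
}

#' Mutual Q between two structures
#'
#' Symmetric structural similarity in [0, 1]; 1 for identical internal
#' distances. Depends only on internal distances, so it is invariant under
#' rigid-body motion of either structure.
#'
#' @param a,b `cg_structure` objects sharing one topology
#' @param spec a [q_spec()]
#' @return Q value in [0, 1]
#' @export
mutual_q <- function(a, b, spec = q_spec()) {
  check_same_topology(a, b)
  pairs <- q_pair_table(a, spec)
  if (nrow(pairs) == 0) stop("empty pair set under scope ", spec$pair_scope)
  dA <- pair_distances(coords(a), pairs)
  dB <- pair_distances(coords(b), pairs)
  q_from_distances(dA, dB, pairs, spec$contact_threshold)
}

#' Q of a model against a template over union-of-contacts pairs
#'
#' Restricted to inter-molecular residue pairs that form a contact (are
#' within the contact threshold) in the template structure or in the model.
#' Used to screen predicted complexes against a canonical binding geometry;
#' the companion [screen_by_qc()] applies the strict `Q_c > threshold` rule.
#'
#' @param model,template `cg_structure` objects
#' @param mapping optional two-column matrix/data.frame of site row indices
#'   `(model_site, template_site)`; default: identity (same topology)
#' @param spec a [q_spec()]; its `pair_scope` is ignored (inter-molecular
#'   union-of-contacts is used)
#' @return Q_c value in [0, 1]
#' @export
q_to_template <- function(model, template, mapping = NULL, spec = q_spec()) {
  if (is.null(mapping)) {
    check_same_topology(model, template)
    mapping <- cbind(seq_len(nrow(model$sites)),
                     seq_len(nrow(model$sites)))
  }
  mapping <- as.matrix(mapping)
  if (anyDuplicated(mapping[, 1]) || anyDuplicated(mapping[, 2]))
    stop("mapping must be injective")
  sub_spec <- spec
  sub_spec$pair_scope <- "inter_molecular"
  ## build pair table on the model subset touched by the mapping
  msub <- model$sites[mapping[, 1], , drop = FALSE]
  sub <- cg_structure(msub)
  pairs <- q_pair_table(sub, sub_spec)
  if (nrow(pairs) == 0) stop("no inter-molecular pairs under mapping")
  xm <- coords(model)[mapping[, 1], , drop = FALSE]
  xt <- coords(template)[mapping[, 2], , drop = FALSE]
  dM <- pair_distances(xm, pairs)
  dT <- pair_distances(xt, pairs)
  q_from_distances(dM, dT, pairs, spec$contact_threshold)
}

#' Screen Q_c values against a strict threshold
#' @param qc numeric vector of template Q values
#' @param threshold default 0.2
#' @return logical: TRUE where `qc > threshold` (strictly)
#' @export
screen_by_qc <- function(qc, threshold = 0.2) qc > threshold

#' Pairwise mutual-Q matrix over an ensemble
#'
#' @param ensemble a `cg_ensemble` (at least 2 frames)
#' @param spec a [q_spec()]
#' @return symmetric matrix with unit diagonal
#' @export
pairwise_q_matrix <- function(ensemble, spec = q_spec()) {
  nf <- n_frames(ensemble)
  if (nf < 2) stop("ensemble must have at least 2 frames")
  pairs <- q_pair_table(ensemble$topology, spec)
  dmat <- vapply(ensemble$frames, pair_distances, numeric(nrow(pairs)),
                 pairs = pairs)
  qm <- diag(1, nf)
  for (a in seq_len(nf - 1)) {
    for (b in seq((a + 1), nf)) {
      qm[a, b] <- qm[b, a] <-
        q_from_distances(dmat[, a], dmat[, b], pairs,
                         spec$contact_threshold)
    }
  }
  qm
}

#' Cluster frames by mutual-Q distance
#'
#' Average-linkage hierarchical clustering on the distance `1 - Q`, cut at
#' `k` clusters. The representative of a cluster is the frame maximizing the
#' mean within-cluster Q (ties broken by lowest frame index).
#'
#' @param qmat symmetric pairwise-Q matrix
#' @param k number of clusters (1..n)
#' @return list with `labels` (integer vector), `representatives` (one frame
#'   index per cluster) and the `hclust` object
#' @export
cluster_by_q <- function(qmat, k = 3) {
  n <- nrow(qmat)
  if (k < 1 || k > n) stop("k must be between 1 and the number of frames")
  hc <- stats::hclust(stats::as.dist(1 - qmat), method = "average")
  labels <- stats::cutree(hc, k = k)
  reps <- vapply(sort(unique(labels)), function(cl) {
    members <- which(labels == cl)
    if (length(members) == 1) return(members)
    mq <- vapply(members, function(m)
      mean(qmat[m, setdiff(members, m)]), numeric(1))
    members[which.max(mq)]  # which.max takes the first (lowest index) on ties
  }, integer(1))
  list(labels = labels, representatives = reps, hclust = hc)
}

#' Inter-domain contact frequency map over an ensemble
#'
#' Counts, for each residue pair across two annotated domains, in how many
#' frames the pair is within `cutoff`, and filters to pairs seen in more
#' than `min_count` frames (the convention used for consensus contact maps
#' of predicted ensembles, e.g. >30 of 60 predictions).
#'
#' @param ensemble a `cg_ensemble`
#' @param domain_a,domain_b annotation names
#' @param cutoff Angstrom, default 8
#' @param min_count keep pairs with count strictly greater, default half the
#'   number of frames
#' @return data.frame with residue indices of both partners and `count`
#' @export
contact_frequency_map <- function(ensemble, domain_a, domain_b, cutoff = 8,
                                  min_count = floor(n_frames(ensemble) / 2)) {
  topo <- ensemble$topology
  ia <- annotation_sites(topo, domain_a)
  ib <- annotation_sites(topo, domain_b)
  grid <- expand.grid(i = ia, j = ib)
  grid <- grid[grid$i != grid$j, ]
  pairs <- data.frame(i = grid$i, j = grid$j, delta_sq = 1)
  cnt <- rep(0L, nrow(pairs))
  for (f in ensemble$frames)
    cnt <- cnt + as.integer(pair_distances(f, pairs) <= cutoff)
  keep <- cnt > min_count
  data.frame(res_a = topo$sites$residue_index[pairs$i[keep]],
             res_b = topo$sites$residue_index[pairs$j[keep]],
             count = cnt[keep])
}
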