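#' Cartesian principal component analysis of an ensemble
#'
#' Frames are iteratively superposed (rigid-body least squares) onto the
#' evolving mean structure before the covariance eigendecomposition, so
#' that rigid-body motion does not contaminate the components. The sign of
#' the leading component (PC0) is fixed so that the open reference
#' structure projects into the positive range.
#'
#' @param ensemble a `cg_ensemble` with at least 2 frames
#' @param atom_scope optional site row indices to include (default: all)
#' @param open_reference optional `cg_structure` anchoring the PC0 sign
#' @param max_iter iterations of mean-structure realignment, default 10
#' @param tol convergence threshold on the mean (RMS Angstrom)
#' @return object of class `pca_model`: mean coordinates, orthonormal
#'   `components` (columns, decreasing variance), `explained_variance`
#'   (A^2), fitted `scores`, and the scope
#' @export
fit_pca <- function(ensemble, atom_scope = NULL, open_reference = NULL,
                    max_iter = 10, tol = 1e-4) {
  if (n_frames(ensemble) < 2) stop("need at least 2 frames")
  idx <- if (is.null(atom_scope)) seq_len(nrow(ensemble$topology$sites))
  else atom_scope
  if (length(idx) == 0) stop("empty atom scope")
  X <- t(vapply(ensemble$frames,
                function(f) as.vector(t(f[idx, , drop = FALSE])),
                numeric(3 * length(idx))))
  m <- length(idx)

  if (max(apply(X, 2, stats::sd)) < 1e-12) {
    warning("all frames identical: zero-variance model")
    comps <- diag(1, 3 * m)
    model <- list(mean = X[1, ], components = comps,
                  explained_variance = rep(0, 3 * m),
                  scores = matrix(0, nrow(X), 3 * m), scope = idx,
                  sign_convention = "none")
    class(model) <- "pca_model"
    return(model)
  }

  ref <- X[1, ]
  for (it in seq_len(max_iter)) {
    X <- bio3d::fit.xyz(fixed = ref, mobile = X,
                        fixed.inds = seq_along(ref),
                        mobile.inds = seq_along(ref))
    newmean <- colMeans(X)
    delta <- sqrt(mean((newmean - ref)^2))
    ref <- newmean
    if (delta < tol) break
  }
  Xc <- sweep(X, 2, ref)
  eg <- eigen(stats::cov(Xc), symmetric = TRUE)
  comps <- eg$vectors
  ev <- pmax(eg$values, 0)
  scores <- Xc %*% comps

  sign_convention <- "unanchored"
  if (!is.null(open_reference)) {
    op <- as.vector(t(coords(open_reference)[idx, , drop = FALSE]))
    op <- bio3d::fit.xyz(fixed = ref, mobile = matrix(op, nrow = 1),
                         fixed.inds = seq_along(ref),
                         mobile.inds = seq_along(ref))
    if (sum((op - ref) * comps[, 1]) < 0) {
      comps[, 1] <- -comps[, 1]
      scores[, 1] <- -scores[, 1]
    }
    sign_convention <- "open reference projects positive on PC0"
  }
  structure(list(mean = ref, components = comps, explained_variance = ev,
                 scores = scores, scope = idx,
                 sign_convention = sign_convention),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  tot <- sum(x$explained_variance)
  top <- if (tot > 0) x$explained_variance[1] / tot else 0
  cat("pca_model:", length(x$scope), "sites;",
      sprintf("PC0 explains %.1f%% of variance\n", 100 * top))
  invisible(x)
}

#' Project a structure onto the first principal component
#'
#' The structure (restricted to the model's scope) is superposed onto the
#' model's mean coordinates, centered, and projected onto the leading
#' component. Invariant under rigid motion of the input.
#'
#' @param model a [fit_pca()] model
#' @param structure a `cg_structure` congruent with the model's topology
#'   scope, or an n x 3 coordinate matrix of the scope sites
#' @return PC0 value (scalar)
#' @export
project_pc0 <- function(model, structure) {
  if (inherits(structure, "cg_structure")) {
    xyz <- coords(structure)[model$scope, , drop = FALSE]
  } else {
    xyz <- as.matrix(structure)
    if (nrow(xyz) == length(model$scope) * 3 && ncol(xyz) == 1)
      xyz <- matrix(xyz, ncol = 3, byrow = TRUE)
  }
  if (nrow(xyz) != length(model$scope))
    stop("structure does not match the model's topology scope")
  v <- as.vector(t(xyz))
  v <- bio3d::fit.xyz(fixed = model$mean, mobile = matrix(v, nrow = 1),
                      fixed.inds = seq_along(model$mean),
                      mobile.inds = seq_along(model$mean))
  sum((as.vector(v) - model$mean) * model$components[, 1])
}

#' Distance between the ligand and the binding pocket
#'
#' Geometric-center distance between the sites of a pocket annotation and
#' the sites of the ligand chain.
#'
#' @param structure a `cg_structure`
#' @param pocket_annotation annotation name, default `"pocket"`
#' @param ligand_chain chain id of the ligand
#' @return distance in Angstrom
#' @export
compute_r <- function(structure, pocket_annotation = "pocket",
                      ligand_chain = "B") {
  pidx <- annotation_sites(structure, pocket_annotation)
  if (length(pidx) == 0) stop("empty pocket annotation")
  lidx <- chain_sites(structure, ligand_chain)
  xyz <- coords(structure)
  sqrt(sum((colMeans(xyz[pidx, , drop = FALSE]) -
              colMeans(xyz[lidx, , drop = FALSE]))^2))
}

#' Assign an order-parameter frame to a labelled basin
#'
#' Basins are disjoint axis-aligned rectangles in order-parameter space
#' (e.g. over (q_f, pc0) or (r, pc0)). A frame outside every rectangle is
#' `"unassigned"`.
#'
#' @param frame named list / one-row data.frame of order-parameter values
#' @param basin_defs list of `list(label =, <var> = c(min, max), ...)`;
#'   all definitions must use the same variables
#' @return basin label (character)
#' @export
assign_basin <- function(frame, basin_defs) {
  vars <- setdiff(names(basin_defs[[1]]), "label")
  for (b in basin_defs)
    if (!setequal(setdiff(names(b), "label"), vars))
      stop("all basin definitions must use the same variables")
  ## disjointness: rectangles must not overlap in every shared variable
  nb <- length(basin_defs)
  if (nb > 1) {
    for (a in 1:(nb - 1)) for (b in (a + 1):nb) {
      olap <- vapply(vars, function(v) {
        ra <- basin_defs[[a]][[v]]; rb <- basin_defs[[b]][[v]]
        ra[1] < rb[2] && rb[1] < ra[2]
      }, logical(1))
      if (all(olap))
        stop("overlapping basin definitions: ", basin_defs[[a]]$label,
             " and ", basin_defs[[b]]$label)
    }
  }
  for (b in basin_defs) {
    inside <- vapply(vars, function(v) {
      val <- frame[[v]]
      !is.null(val) && val >= b[[v]][1] && val <= b[[v]][2]
    }, logical(1))
    if (all(inside)) return(b$label)
  }
  "unassigned"
}

#' Classify an RNA dissociation trajectory by pathway
#'
#' Path I: the receptor opens (PC0 enters the open range) before or at the
#' moment the ligand unbinds (R crosses the unbound threshold). Path II:
#' unbinding completes while PC0 stays in the closed range throughout.
#' Anything else is mixed.
#'
#' @param trajectory data.frame with per-frame columns `pc0` and `r`
#' @param thresholds list with `r_bound` (start must be below), `r_unbound`
#'   (dissociation), `pc0_open_min` (entering the open range) and
#'   `pc0_closed_max` (staying closed)
#' @return one of `"path_I"`, `"path_II"`, `"mixed"`
#' @export
classify_pathway <- function(trajectory, thresholds) {
  r <- trajectory$r
  pc0 <- trajectory$pc0
  th <- thresholds
  if (r[1] > th$r_bound)
    stop("trajectory does not start bound (r[1] = ", round(r[1], 2), ")")
  t_unbind <- which(r >= th$r_unbound)[1]
  if (is.na(t_unbind)) stop("no dissociation event")
  upto <- seq_len(t_unbind)
  if (any(pc0[upto] >= th$pc0_open_min)) return("path_I")
  if (all(pc0[upto] <= th$pc0_closed_max)) return("path_II")
  "mixed"
}

#' Order parameters of each frame of a simulation
#'
#' @param frames list of coordinate matrices (or a `cg_ensemble`)
#' @param topology the `cg_structure` topology
#' @param pca_model optional [fit_pca()] model for `pc0`
#' @param qf_reference optional free-state reference `cg_structure` for
#'   `q_f` (inter-domain mutual Q to the reference)
#' @param qf_spec [q_spec()] used for `q_f`
#' @param pocket_annotation,ligand_chain for `r` (skipped when the
#'   topology has no such chain)
#' @return data.frame with columns `frame` and those of `pc0`, `q_f`, `r`
#'   that are computable
#' @export
frame_order_params <- function(frames, topology, pca_model = NULL,
                               qf_reference = NULL,
                               qf_spec = q_spec(pair_scope = "inter_domain"),
                               pocket_annotation = "pocket",
                               ligand_chain = "B") {
  if (inherits(frames, "cg_ensemble")) frames <- frames$frames
  out <- data.frame(frame = seq_along(frames))
  has_lig <- ligand_chain %in% topology$chain_table$chain_id
  if (!is.null(pca_model))
    out$pc0 <- vapply(frames, function(f)
      project_pc0(pca_model, f[pca_model$scope, , drop = FALSE]),
      numeric(1))
  if (!is.null(qf_reference)) {
    pairs <- q_pair_table(topology, qf_spec)
    dref <- pair_distances(coords(qf_reference), pairs)
    out$q_f <- vapply(frames, function(f)
      q_from_distances(pair_distances(f, pairs), dref, pairs,
                       qf_spec$contact_threshold), numeric(1))
  }
  if (has_lig) {
    pidx <- annotation_sites(topology, pocket_annotation)
    lidx <- chain_sites(topology, ligand_chain)
    out$r <- vapply(frames, function(f)
      sqrt(sum((colMeans(f[pidx, , drop = FALSE]) -
                  colMeans(f[lidx, , drop = FALSE]))^2)), numeric(1))
  }
  out
}
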