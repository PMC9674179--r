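#' Coarse-grained structure objects
#'
#' A `cg_structure` holds one representative site per residue (protein) or
#' nucleotide (RNA): chain id, 1-based residue index inherited from the source
#' numbering, residue type (3-letter amino-acid or 1-letter base code),
#' molecule class and cartesian coordinates in Angstrom. Named domain
#' annotations (e.g. \code{RRM1}, \code{ZnF}, \code{SIM}, \code{pocket}) are
#' carried as residue-index ranges. An optional table of heavy-atom records
#' supports atomic contact counting against reference complexes.
#'
#' @param sites data.frame with columns `chain_id`, `residue_index`,
#'   `residue_type`, `molecule_class` ("protein" or "rna"), `x`, `y`, `z` and
#'   optionally `site_role` ("backbone_rep", the default, or "sidechain_rep").
#' @param annotations named list; each element a list with fields `chain`,
#'   `from`, `to` giving a residue-index range on one chain.
#' @param atom_records optional data.frame of heavy atoms with columns
#'   `chain_id`, `residue_index`, `x`, `y`, `z`.
#' @return object of class `cg_structure`
#' @export
cg_structure <- function(sites, annotations = list(), atom_records = NULL) {
  stopifnot(is.data.frame(sites))
  needed <- c("chain_id", "residue_index", "residue_type", "molecule_class",
              "x", "y", "z")
  miss <- setdiff(needed, names(sites))
  if (length(miss) > 0)
    stop("sites is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(sites) == 0) stop("structure must contain at least one site")
  if (!"site_role" %in% names(sites)) sites$site_role <- "backbone_rep"
  sites$chain_id <- as.character(sites$chain_id)
  sites$residue_index <- as.integer(sites$residue_index)
  if (!all(is.finite(as.matrix(sites[, c("x", "y", "z")]))))
    stop("site coordinates must be finite")
  if (!all(sites$molecule_class %in% c("protein", "rna")))
    stop("molecule_class must be 'protein' or 'rna'")

  ## per-chain invariants
  for (ch in unique(sites$chain_id)) {
    sel <- sites$chain_id == ch
    if (length(unique(sites$molecule_class[sel])) != 1)
      stop("molecule_class must be uniform within chain ", ch)
    for (role in unique(sites$site_role[sel])) {
      ri <- sites$residue_index[sel & sites$site_role == role]
      if (any(diff(ri) <= 0))
        stop("residue_index must be strictly increasing within chain ", ch)
    }
  }
  chains <- unique(sites$chain_id)
  chain_table <- data.frame(
    chain_id = chains,
    molecule_class = vapply(chains, function(ch)
      sites$molecule_class[sites$chain_id == ch][1], character(1)),
    first = vapply(chains, function(ch)
      min(sites$residue_index[sites$chain_id == ch]), integer(1)),
    last = vapply(chains, function(ch)
      max(sites$residue_index[sites$chain_id == ch]), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  s <- structure(list(sites = sites, chain_table = chain_table,
                      annotations = list(), atom_records = atom_records),
                 class = "cg_structure")
  if (length(annotations) > 0) s <- set_annotations(s, annotations)
  s
}

#' @export
print.cg_structure <- function(x, ...) {
  cat("cg_structure:", nrow(x$sites), "sites,",
      nrow(x$chain_table), "chain(s)\n")
  for (i in seq_len(nrow(x$chain_table))) {
    ct <- x$chain_table[i, ]
    cat(sprintf("  chain %s (%s): residues %d-%d\n",
                ct$chain_id, ct$molecule_class, ct$first, ct$last))
  }
  if (length(x$annotations) > 0)
    cat("  annotations:", paste(names(x$annotations), collapse = ", "), "\n")
  invisible(x)
}

#' Attach domain annotations to a structure
#'
#' An annotation is one residue-index range `list(chain =, from =, to =)`,
#' or an unnamed list of several such ranges for regions that are not
#' contiguous in sequence (e.g. a binding pocket lined by both domains).
#'
#' @param structure a `cg_structure`
#' @param annotations named list of ranges (or lists of ranges)
#' @return the structure with annotations validated and attached
#' @export
set_annotations <- function(structure, annotations) {
  stopifnot(inherits(structure, "cg_structure"))
  if (is.null(names(annotations)) || any(names(annotations) == ""))
    stop("annotations must be a named list")
  for (nm in names(annotations)) {
    for (a in annotation_ranges(annotations[[nm]])) {
      row <- structure$chain_table[structure$chain_table$chain_id == a$chain, ]
      if (nrow(row) == 0)
        stop("annotation '", nm, "' names unknown chain ", a$chain)
      if (a$from > a$to || a$from < row$first || a$to > row$last)
        stop("annotation '", nm, "' range [", a$from, ",", a$to,
             "] outside chain ", a$chain, " span [", row$first, ",",
             row$last, "]")
    }
  }
  structure$annotations <- annotations
  structure
}

## normalize an annotation to a list of ranges
annotation_ranges <- function(a) {
  if (!is.null(a$chain)) list(a) else a
}

#' Site coordinates of a structure
#' @param structure a `cg_structure`
#' @return numeric matrix, one row per site, columns x/y/z (Angstrom)
#' @export
coords <- function(structure) {
  as.matrix(structure$sites[, c("x", "y", "z")])
}

#' Replace site coordinates
#' @param structure a `cg_structure`
#' @param xyz matrix with one row per site
#' @return the updated structure
#' @export
set_coords <- function(structure, xyz) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != nrow(structure$sites) || ncol(xyz) != 3)
    stop("coordinate matrix must be n_sites x 3")
  structure$sites[, c("x", "y", "z")] <- xyz
  structure
}

#' Row indices of the sites in one chain
#' @param structure a `cg_structure`
#' @param chain chain id
#' @export
chain_sites <- function(structure, chain) {
  idx <- which(structure$sites$chain_id == chain)
  if (length(idx) == 0) stop("no chain '", chain, "' in structure")
  idx
}

#' Row indices of the sites covered by a named annotation
#' @param structure a `cg_structure`
#' @param name annotation name
#' @export
annotation_sites <- function(structure, name) {
  a <- structure$annotations[[name]]
  if (is.null(a)) stop("no annotation '", name, "' in structure")
  idx <- integer(0)
  for (r in annotation_ranges(a)) {
    idx <- c(idx, which(structure$sites$chain_id == r$chain &
                          structure$sites$residue_index >= r$from &
                          structure$sites$residue_index <= r$to))
  }
  sort(unique(idx))
}

#' Check that two structures share a topology
#'
#' Same number of sites, same chain ids, residue indices and molecule classes
#' in the same order; only coordinates may differ.
#' @param a,b `cg_structure` objects
#' @return TRUE invisibly, or an error
#' @export
check_same_topology <- function(a, b) {
  if (nrow(a$sites) != nrow(b$sites))
    stop("topology mismatch: different numbers of sites")
  same <- all(a$sites$chain_id == b$sites$chain_id) &&
    all(a$sites$residue_index == b$sites$residue_index) &&
    all(a$sites$molecule_class == b$sites$molecule_class)
  if (!same) stop("topology mismatch: site tables differ")
  invisible(TRUE)
}

#' Ensemble of conformations sharing one topology
#'
#' @param topology a `cg_structure` used as the reference topology
#' @param frames list of n_sites x 3 coordinate matrices
#' @param frame_labels optional character/integer labels, one per frame
#' @return object of class `cg_ensemble`
#' @export
cg_ensemble <- function(topology, frames, frame_labels = NULL) {
  stopifnot(inherits(topology, "cg_structure"), is.list(frames))
  if (length(frames) == 0) stop("ensemble must contain at least one frame")
  n <- nrow(topology$sites)
  for (k in seq_along(frames)) {
    frames[[k]] <- as.matrix(frames[[k]])
    if (nrow(frames[[k]]) != n || ncol(frames[[k]]) != 3)
      stop("frame ", k, " is not congruent with topology (", n, " sites)")
  }
  if (!is.null(frame_labels) && length(frame_labels) != length(frames))
    stop("frame_labels length must match number of frames")
  structure(list(topology = topology, frames = frames,
                 frame_labels = frame_labels),
            class = "cg_ensemble")
}

#' @export
print.cg_ensemble <- function(x, ...) {
  cat("cg_ensemble:", length(x$frames), "frames x",
      nrow(x$topology$sites), "sites\n")
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ensemble a `cg_ensemble`
#' @export
n_frames <- function(ensemble) length(ensemble$frames)

#' Extract one frame of an ensemble as a structure
#' @param ensemble a `cg_ensemble`
#' @param i frame index
#' @return `cg_structure` with the frame's coordinates
#' @export
ensemble_frame <- function(ensemble, i) {
  stopifnot(i >= 1, i <= length(ensemble$frames))
  set_coords(ensemble$topology, ensemble$frames[[i]])
}
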