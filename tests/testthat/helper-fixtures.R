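# Small structure builders shared across tests. Everything is generated in
# code; no fixture files.

## n-residue protein chain on a straight line (spacing b)
toy_chain <- function(n = 3, chain = "A", b = 3.8, types = "GLY",
                      mol = "protein") {
  cg_structure(data.frame(
    chain_id = chain, residue_index = seq_len(n),
    residue_type = rep_len(types, n), molecule_class = mol,
    x = b * (seq_len(n) - 1), y = 0, z = 0, site_role = "backbone_rep",
    stringsAsFactors = FALSE))
}

## two-site, two-chain structure at separation d (protein + RNA)
toy_pair <- function(d, type_a = "GLY", type_b = "U") {
  cg_structure(data.frame(
    chain_id = c("A", "B"), residue_index = c(1L, 1L),
    residue_type = c(type_a, type_b),
    molecule_class = c("protein", "rna"),
    x = c(0, d), y = 0, z = 0, site_role = "backbone_rep",
    stringsAsFactors = FALSE))
}

## random rigid-body motion applied to coordinates
random_rigid <- function(xyz, seed = 1) {
  set.seed(seed)
  th <- stats::runif(3, 0, 2 * pi)
  Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), sin(th[1]),
                 0, -sin(th[1]), cos(th[1])), 3, 3)
  Ry <- matrix(c(cos(th[2]), 0, -sin(th[2]), 0, 1, 0,
                 sin(th[2]), 0, cos(th[2])), 3, 3)
  Rz <- matrix(c(cos(th[3]), sin(th[3]), 0, -sin(th[3]), cos(th[3]), 0,
                 0, 0, 1), 3, 3)
  sweep(xyz %*% (Rx %*% Ry %*% Rz), 2, stats::runif(3, -20, 20), "+")
}

## write text lines to a temp file, return path
tmpfile_with <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
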