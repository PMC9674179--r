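#' Read a PDB file into a coarse-grained structure or ensemble
#'
#' One representative site is taken per residue: the CA atom for protein
#' chains and (by default) the C4' atom for RNA chains. Chains are classified
#' as RNA when their residue names are single-letter (or D/R-prefixed)
#' nucleotide codes. Multi-model files can be read as an ensemble.
#'
#' @param path PDB file
#' @param site_selection list naming the representative atom per molecule
#'   class, default `list(protein = "CA", rna = c("C4'", "C4*", "P"))`; for
#'   RNA the first name present in a residue is used.
#' @param multi if TRUE, a multi-MODEL file is returned as a [cg_ensemble()]
#'   (topology from the first model)
#' @return a `cg_structure`, or a `cg_ensemble` when `multi = TRUE`
#' @export
read_pdb_cg <- function(path,
                        site_selection = list(protein = "CA",
                                              rna = c("C4'", "C4*", "P")),
                        multi = FALSE) {
  pdb <- bio3d::read.pdb(path, multi = multi, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  at$chain[is.na(at$chain)] <- " "
  if (nrow(at) == 0 || length(unique(at$chain)) == 0)
    stop("no chains found in ", path)

  nuc_codes <- c("A", "C", "G", "U", "T",
                 "RA", "RC", "RG", "RU", "DA", "DC", "DG", "DT")
  rep_rows <- integer(0)
  rec <- list()
  for (ch in unique(at$chain)) {
    cat_rows <- which(at$chain == ch)
    is_rna <- all(at$resid[cat_rows] %in% nuc_codes)
    mol <- if (is_rna) "rna" else "protein"
    wanted <- if (is_rna) site_selection$rna else site_selection$protein
    for (rn in unique(at$resno[cat_rows])) {
      rr <- cat_rows[at$resno[cat_rows] == rn]
      hit <- rr[match(wanted, at$elety[rr])]
      hit <- hit[!is.na(hit)][1]
      if (is.na(hit))
        stop("missing representative atom (", paste(wanted, collapse = "/"),
             ") in chain ", ch, " residue ", rn)
      rtype <- at$resid[hit]
      if (is_rna) rtype <- sub("^[DR]", "", rtype)
      rep_rows <- c(rep_rows, hit)
      rec[[length(rec) + 1]] <- data.frame(
        chain_id = ch, residue_index = rn, residue_type = rtype,
        molecule_class = mol, x = at$x[hit], y = at$y[hit], z = at$z[hit],
        site_role = "backbone_rep", stringsAsFactors = FALSE)
    }
  }
  sites <- do.call(rbind, rec)
  topo <- cg_structure(sites)

  if (multi && is.matrix(pdb$xyz) && nrow(pdb$xyz) > 1) {
    ## map representative atoms back to xyz columns (atom order of model 1)
    atom_of_row <- match(paste(at$eleno[rep_rows]), paste(pdb$atom$eleno))
    cols <- as.vector(t(cbind(3 * atom_of_row - 2, 3 * atom_of_row - 1,
                              3 * atom_of_row)))
    frames <- lapply(seq_len(nrow(pdb$xyz)), function(m)
      matrix(pdb$xyz[m, cols], ncol = 3, byrow = TRUE))
    return(cg_ensemble(topo, frames))
  }
  topo
}

#' Write a coarse-grained structure or ensemble to PDB
#'
#' Protein sites are written as CA atoms (CB for sidechain representatives),
#' RNA sites as C4' atoms. An ensemble produces one MODEL/ENDMDL block per
#' frame. When the structure carries domain annotations, they are saved to a
#' JSON sidecar file `<path>.annotations.json` so they survive the
#' round-trip (PDB has no field for them).
#'
#' @param x a `cg_structure` or `cg_ensemble`
#' @param path output file
#' @param sidecar write the annotation sidecar when annotations are present
#'   (default TRUE)
#' @return invisibly, the path written
#' @export
write_pdb_cg <- function(x, path, sidecar = TRUE) {
  if (inherits(x, "cg_ensemble")) {
    topo <- x$topology
    xyz <- do.call(rbind, lapply(x$frames, function(f) as.vector(t(f))))
  } else if (inherits(x, "cg_structure")) {
    topo <- x
    xyz <- matrix(as.vector(t(coords(x))), nrow = 1)
  } else {
    stop("x must be a cg_structure or cg_ensemble")
  }
  s <- topo$sites
  elety <- ifelse(s$molecule_class == "rna", "C4'",
                  ifelse(s$site_role == "sidechain_rep", "CB", "CA"))
  bio3d::write.pdb(file = path, xyz = xyz, resno = s$residue_index,
                   resid = s$residue_type, chain = s$chain_id,
                   eleno = seq_len(nrow(s)), elety = elety)
  if (sidecar && length(topo$annotations) > 0)
    write_annotations_json(topo$annotations,
                           paste0(path, ".annotations.json"))
  invisible(path)
}

#' Save / load domain annotations as a JSON sidecar
#' @param annotations named list of `list(chain =, from =, to =)`
#' @param path JSON file
#' @export
write_annotations_json <- function(annotations, path) {
  jsonlite::write_json(annotations, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_annotations_json
#' @export
read_annotations_json <- function(path) {
  ann <- jsonlite::read_json(path, simplifyVector = FALSE)
  one <- function(a) list(chain = a$chain, from = as.integer(a$from),
                          to = as.integer(a$to))
  lapply(ann, function(a) {
    if (!is.null(a$chain)) one(a) else lapply(a, one)
  })
}

#' Read sequences from a FASTA file
#'
#' Sequences are uppercased and validated: only alphabetic residue codes are
#' accepted and empty records are rejected.
#'
#' @param path FASTA file
#' @return list of records, each a list with `id` and `sequence`
#' @export
read_fasta <- function(path) {
  first <- readLines(path, n = 1)
  if (length(first) == 0 || !startsWith(first, ">"))
    stop("malformed FASTA header in ", path,
         ": first line must start with '>'")
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             seqonly = FALSE)
  out <- lapply(seq_along(recs), function(i) {
    sq <- toupper(as.character(recs[[i]])[1])
    id <- attr(recs[[i]], "name")
    if (is.na(sq) || nchar(sq) == 0)
      stop("empty FASTA record '", id, "'")
    bad <- regexpr("[^A-Z]", sq)
    if (bad > 0)
      stop("illegal character '", substr(sq, bad, bad), "' at position ",
           bad, " of record '", id, "'")
    list(id = id, sequence = sq)
  })
  out
}
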