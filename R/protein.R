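# Protein structures: backbone extraction from PDB/mmCIF (via bio3d) and a
# minimal writer used by the synthetic fixture generator.

.FD_AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
                GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
                LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
                SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

#' Maximum accepted protein length
#'
#' Inputs longer than this many residues are rejected by [load_protein()].
#' @export
FD_MAX_RESIDUES <- 2000L

#' Protein structure (backbone representation)
#'
#' @param sequence character vector of one-letter residue codes.
#' @param n,ca,c n_res x 3 coordinate matrices for backbone N, C-alpha and C
#'   atoms (Angstrom).
#' @param chain character chain ids (recycled).
#' @param resno integer residue numbers.
#' @return Object of class `protein_structure`.
#' @export
protein_structure <- function(sequence, n, ca, c, chain = "A",
                              resno = seq_along(sequence)) {
  nres <- length(sequence)
  n <- matrix(as.numeric(n), ncol = 3)
  ca <- matrix(as.numeric(ca), ncol = 3)
  c <- matrix(as.numeric(c), ncol = 3)
  stopifnot(nrow(n) == nres, nrow(ca) == nres, nrow(c) == nres)
  if (nres > FD_MAX_RESIDUES) {
    rlang::abort(sprintf(
      "protein has %d residues; inputs longer than %d residues are rejected",
      nres, FD_MAX_RESIDUES), class = "fd_length_error")
  }
  structure(list(sequence = sequence, n = n, ca = ca, c = c,
                 chain = rep_len(as.character(chain), nres),
                 resno = as.integer(resno)),
            class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  cat(sprintf("<protein_structure> %d residues, chain(s) %s\n",
              length(x$sequence), paste(unique(x$chain), collapse = ",")))
  invisible(x)
}

#' Number of residues
#' @param protein A [protein_structure()].
#' @return Integer residue count.
#' @export
n_residues <- function(protein) length(protein$sequence)

#' Load a protein backbone from PDB or mmCIF
#'
#' Reads the file with bio3d, keeps the highest-occupancy alternate location
#' per atom (first on ties), drops residues with an incomplete N/CA/C
#' backbone (with a warning), and rejects chains longer than
#' `FD_MAX_RESIDUES` residues.
#'
#' @param path path to a `.pdb` or `.cif` file.
#' @return A [protein_structure()].
#' @export
load_protein <- function(path) {
  ext <- tolower(tools::file_ext(path))
  pdb <- tryCatch(
    if (ext %in% c("cif", "mmcif")) bio3d::read.cif(path) else bio3d::read.pdb(path),
    error = function(e) rlang::abort(
      sprintf("cannot parse '%s': %s", path, conditionMessage(e)),
      class = "fd_parse_error"))
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$elety %in% c("N", "CA", "C"), , drop = FALSE]
  if (nrow(at) == 0L) {
    rlang::abort("no usable residues in structure", class = "fd_empty_structure")
  }
  # alternate locations: highest occupancy wins, first on ties
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  occ <- at$o
  occ[is.na(occ)] <- 1
  ord <- order(key, -occ, seq_len(nrow(at)))
  at <- at[sort(ord[!duplicated(key[ord])]), , drop = FALSE]  # keep file order
  rkey <- paste(at$chain, at$resno, at$insert, sep = "|")
  rlev <- unique(rkey)   # file order
  seq1 <- character(0); N <- NULL; CA <- NULL; C <- NULL
  chain <- character(0); resno <- integer(0)
  dropped <- 0L
  for (rk in rlev) {
    rows <- at[rkey == rk, , drop = FALSE]
    getxyz <- function(ety) {
      r <- rows[rows$elety == ety, , drop = FALSE]
      if (nrow(r) != 1L) return(NULL)
      as.numeric(r[1, c("x", "y", "z")])
    }
    xn <- getxyz("N"); xca <- getxyz("CA"); xc <- getxyz("C")
    if (is.null(xn) || is.null(xca) || is.null(xc) ||
        !all(is.finite(c(xn, xca, xc)))) {
      dropped <- dropped + 1L
      next
    }
    aa <- .FD_AA3TO1[rows$resid[1]]
    seq1 <- c(seq1, if (is.na(aa)) "X" else unname(aa))
    N <- rbind(N, xn); CA <- rbind(CA, xca); C <- rbind(C, xc)
    chain <- c(chain, rows$chain[1])
    resno <- c(resno, rows$resno[1])
  }
  if (dropped > 0L) {
    warning(sprintf("dropped %d residue(s) with incomplete backbone", dropped),
            call. = FALSE)
  }
  if (length(seq1) == 0L) {
    rlang::abort("no residue has a complete N/CA/C backbone",
                 class = "fd_empty_structure")
  }
  protein_structure(seq1, N, CA, C, chain = chain, resno = resno)
}

#' Write a backbone-only PDB file
#'
#' Used by the synthetic fixture generator; writes N/CA/C ATOM records.
#'
#' @param protein A [protein_structure()].
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_protein_pdb <- function(protein, path) {
  nres <- length(protein$sequence)
  aa13 <- names(.FD_AA3TO1)[match(protein$sequence, .FD_AA3TO1)]
  aa13[is.na(aa13)] <- "UNK"
  xyz <- numeric(0)
  for (i in seq_len(nres)) {
    xyz <- c(xyz, protein$n[i, ], protein$ca[i, ], protein$c[i, ])
  }
  bio3d::write.pdb(
    file = path, xyz = xyz,
    resno = rep(protein$resno, each = 3L),
    resid = rep(aa13, each = 3L),
    chain = rep(protein$chain, each = 3L),
    elety = rep(c("N", "CA", "C"), nres),
    eleno = seq_len(3L * nres))
  invisible(path)
}

#' Rigidly transform a protein structure
#'
#' @param protein A [protein_structure()].
#' @param transform A [rigid_transform()].
#' @return The transformed [protein_structure()].
#' @export
transform_protein <- function(protein, transform) {
  protein$n <- frame_apply(transform, protein$n)
  protein$ca <- frame_apply(transform, protein$ca)
  protein$c <- frame_apply(transform, protein$c)
  protein
}
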