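# Input featurization: the unified single representation (protein residues
# followed by ligand atoms) and the blockwise pair representation (protein
# block, ligand block, mixed off-diagonal blocks).
#
# Geometry enters only through within-entity distances (residue-residue
# C-alpha distances, atom-atom conformer distances): there are no
# protein-ligand distances at input time because the pose is unknown, which
# is what makes the whole feature pipeline invariant to how the input
# conformer is placed relative to the protein.

.FD_ELEMENTS <- c("B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "Se", "Br", "I")
.FD_AA <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")

.one_hot <- function(idx, n) {
  M <- matrix(0, length(idx), n)
  M[cbind(seq_along(idx), idx)] <- 1
  M
}

# Gaussian radial basis expansion of a distance vector.
.rbf <- function(d, bins, dmin, dmax) {
  centers <- seq(dmin, dmax, length.out = bins)
  sigma <- (dmax - dmin) / (bins - 1)
  exp(-(outer(d, centers, "-"))^2 / (2 * sigma^2))
}

#' Per-atom ligand input features
#'
#' Element, degree, formal charge, aromaticity, ring membership, implicit
#' hydrogen count, and the canonical atom index (one-hot up to
#' `max_lig_idx` plus a scalar). The index features give the network and
#' the pooled molecule-level embeddings access to atom identity and
#' molecule size.
#'
#' @param ligand A [ligand_graph()].
#' @param config An [fd_config()].
#' @return n_atoms x d feature matrix.
#' @export
ligand_atom_features <- function(ligand, config = fd_config("tiny")) {
  n <- n_atoms(ligand)
  mx <- config$featurize$max_lig_idx
  el <- match(ligand$elements, .FD_ELEMENTS)
  if (anyNA(el)) {
    rlang::abort(sprintf("unknown element(s): %s; supported: %s",
                         paste(unique(ligand$elements[is.na(el)]), collapse = ","),
                         paste(.FD_ELEMENTS, collapse = ",")),
                 class = "fd_vocab_error")
  }
  deg <- pmin(rowSums(ligand$adjacency), 5L)
  cbind(
    .one_hot(el, length(.FD_ELEMENTS)),
    .one_hot(deg + 1L, 6L),
    .one_hot(pmin(pmax(ligand$charges, -2L), 2L) + 3L, 5L),
    as.numeric(ligand$aromatic),
    as.numeric(ligand$in_ring),
    pmin(ligand$implicit_h, 4L) / 4,
    .one_hot(pmin(seq_len(n), mx), mx),
    seq_len(n) / mx
  )
}

#' Per-residue protein input features
#'
#' Residue identity one-hot plus a normalized chain position scalar.
#' @param protein A [protein_structure()].
#' @return n_res x 22 feature matrix.
#' @export
protein_residue_features <- function(protein) {
  aa <- match(protein$sequence, .FD_AA)
  aa[is.na(aa)] <- length(.FD_AA)
  nres <- length(aa)
  cbind(.one_hot(aa, length(.FD_AA)), seq_len(nres) / max(nres, 1L))
}

#' Build the single representation
#'
#' Concatenates embedded protein residue features and ligand atom features
#' into one (n_res + n_atoms) x c_s matrix, protein rows first.
#'
#' @param protein A [protein_structure()].
#' @param ligand A [ligand_graph()].
#' @param params model parameters ([init_params()]); embedding weights may
#'   be autodiff nodes during training.
#' @param config An [fd_config()].
#' @return `list(single = <matrix or node>, mask_protein = <logical>)`.
#' @export
embed_single <- function(protein, ligand, params, config) {
  Fp <- protein_residue_features(protein)
  Fl <- ligand_atom_features(ligand, config)
  sp <- ad_linear(Fp, params$embed$w_protein, params$embed$b_protein)
  sl <- ad_linear(Fl, params$embed$w_ligand, params$embed$b_ligand)
  single <- ad_rbind2(sp, sl)
  list(single = single,
       mask_protein = c(rep(TRUE, nrow(Fp)), rep(FALSE, nrow(Fl))))
}

# Raw (pre-embedding) pair features for the within-entity blocks.
.pair_block_features <- function(protein, ligand, config) {
  fz <- config$featurize
  np <- n_residues(protein); nl <- n_atoms(ligand)
  # protein block: RBF of Ca-Ca distance + clipped relative position one-hot
  dp <- as.vector(as.matrix(stats::dist(protein$ca)))
  Dp <- matrix(0, np, np); Dp[] <- as.matrix(stats::dist(protein$ca))
  ii <- rep(seq_len(np), times = np); jj <- rep(seq_len(np), each = np)
  rel <- pmin(pmax(jj - ii, -fz$relpos_clip), fz$relpos_clip) + fz$relpos_clip + 1L
  prot_feat <- cbind(.rbf(as.vector(Dp), fz$rbf_bins, fz$rbf_min, fz$rbf_max),
                     .one_hot(rel, 2L * fz$relpos_clip + 1L))
  # ligand block: RBF of conformer distance + adjacency + bond order one-hot
  Dl <- as.matrix(stats::dist(ligand$coords))
  adj <- ligand$adjacency
  ordm <- matrix(0L, nl, nl)
  if (nrow(ligand$bonds) > 0L) {
    ordm[ligand$bonds[, 1:2, drop = FALSE]] <- ligand$bonds[, 3]
    ordm[ligand$bonds[, 2:1, drop = FALSE]] <- ligand$bonds[, 3]
  }
  lig_feat <- cbind(.rbf(as.vector(Dl), fz$rbf_bins, fz$rbf_min, fz$rbf_max),
                    as.numeric(as.vector(adj)),
                    .one_hot(pmin(as.vector(ordm), 4L) + 1L, 5L))
  list(protein = prot_feat, ligand = lig_feat)
}

#' Build the pair representation
#'
#' The (N x N) pair tensor (stored pair-flat, see [pair_flat_index()]) is
#' the sum of (i) linear embeddings of the single representation broadcast
#' over rows and columns (all blocks, including the mixed off-diagonal
#' blocks, which carry no geometry) and (ii) block-specific geometry
#' embeddings: residue-residue distance RBFs and clipped relative-position
#' encodings in the protein block; atom-atom conformer distance RBFs, the
#' adjacency matrix and bond orders in the ligand block.
#'
#' @inheritParams embed_single
#' @param single the single representation from [embed_single()].
#' @param return_raw also return the raw block feature matrices.
#' @return pair tensor as an (N*N) x c_z matrix (or node), optionally with
#'   raw features attached.
#' @export
embed_pair <- function(protein, ligand, single, params, config,
                       return_raw = FALSE) {
  np <- n_residues(protein); nl <- n_atoms(ligand)
  N <- np + nl
  U <- ad_linear(single, params$embed$w_pair_row)
  V <- ad_linear(single, params$embed$w_pair_col)
  pair <- ad_pair_broadcast(U, V)
  blocks <- .pair_block_features(protein, ligand, config)
  # flat row indices of the two within-entity blocks
  ip <- rep(seq_len(np), times = np); jp <- rep(seq_len(np), each = np)
  prot_rows <- pair_flat_index(ip, jp, N)
  il <- rep(seq_len(nl), times = nl); jl <- rep(seq_len(nl), each = nl)
  lig_rows <- pair_flat_index(np + il, np + jl, N)
  pair <- ad_add_rows_subset(pair, prot_rows,
                             ad_linear(blocks$protein, params$embed$w_pair_protein))
  pair <- ad_add_rows_subset(pair, lig_rows,
                             ad_linear(blocks$ligand, params$embed$w_pair_ligand))
  if (return_raw) {
    return(list(pair = pair, raw = blocks,
                prot_rows = prot_rows, lig_rows = lig_rows))
  }
  pair
}

#' Build the full complex features
#'
#' @inheritParams embed_single
#' @return A `complex_features` list: `single`, `pair` (pair-flat),
#'   `mask_protein`, `n_protein`, `n_ligand`, `N`.
#' @export
build_features <- function(protein, ligand, params, config) {
  es <- embed_single(protein, ligand, params, config)
  pair <- embed_pair(protein, ligand, es$single, params, config)
  structure(list(single = es$single, pair = pair,
                 mask_protein = es$mask_protein,
                 n_protein = n_residues(protein),
                 n_ligand = n_atoms(ligand),
                 N = n_residues(protein) + n_atoms(ligand)),
            class = "complex_features")
}
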