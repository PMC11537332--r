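# Deterministic synthetic protein-ligand complexes with known ground truth.
#
# The generator emulates the shape of a docking training example: a short
# rigid backbone whose residues lie on a hemispherical shell around a
# concave pocket, a small-molecule graph (5-30 heavy atoms, realistic bond
# lengths, optionally with a ring and therefore graph automorphisms), a
# "true" bound pose placed inside the pocket without steric clashes, and an
# affinity label that is a fixed deterministic function of ligand
# composition: 0.5 * heavy-atom count + ring-atom count / 6.

#' Affinity label of a fixture ligand
#'
#' `0.5 * n_heavy_atoms + n_ring_atoms / 6` - a composition function chosen
#' to be linearly recoverable from pooled embeddings.
#'
#' @param ligand A [ligand_graph()].
#' @return Numeric label (pKd-like scale).
#' @export
fixture_affinity <- function(ligand) {
  0.5 * n_atoms(ligand) + sum(ligand$in_ring) / 6
}

# Hemispherical backbone: residues follow a golden-angle spiral over the
# upper hemisphere so consecutive C-alphas sit ~3.8 A apart and every
# residue faces the pocket center at the origin.
.fixture_protein <- function(n_res) {
  r <- max(7.5, 3.8 * sqrt(n_res / (2 * pi)))
  golden <- pi * (3 - sqrt(5))
  ca <- matrix(0, n_res, 3)
  dirs <- matrix(0, n_res, 3)
  for (i in seq_len(n_res)) {
    zfrac <- 0.15 + 0.8 * (i - 1) / max(1, n_res - 1)
    phi <- golden * (i - 1)
    rho <- sqrt(1 - zfrac^2)
    d <- c(rho * cos(phi), rho * sin(phi), zfrac)
    dirs[i, ] <- d
    ca[i, ] <- r * d
  }
  N <- matrix(0, n_res, 3); C <- matrix(0, n_res, 3)
  for (i in seq_len(n_res)) {
    d <- dirs[i, ]
    ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    t1 <- c(d[2] * ref[3] - d[3] * ref[2],
            d[3] * ref[1] - d[1] * ref[3],
            d[1] * ref[2] - d[2] * ref[1])
    t1 <- t1 / sqrt(sum(t1^2))
    t2 <- c(d[2] * t1[3] - d[3] * t1[2],
            d[3] * t1[1] - d[1] * t1[3],
            d[1] * t1[2] - d[2] * t1[1])
    ang <- 110 * pi / 180
    N[i, ] <- ca[i, ] + 1.46 * t1
    C[i, ] <- ca[i, ] + 1.52 * (cos(ang) * t1 + sin(ang) * t2)
  }
  seqaa <- sample(names(.FD_AA3TO1), n_res, replace = TRUE)
  protein_structure(unname(.FD_AA3TO1[seqaa]), N, ca, C)
}

# Random small-molecule graph: optionally an aromatic 6-ring seed, remaining
# atoms attached as a random tree. Elements C/N/O.
.fixture_ligand <- function(n_atoms, conformer_seed, with_ring = NA) {
  if (is.na(with_ring)) with_ring <- n_atoms >= 6 && stats::runif(1) < 0.6
  elements <- character(n_atoms)
  bonds <- NULL
  if (with_ring && n_atoms >= 6) {
    elements[1:6] <- "C"
    ring <- cbind(1:6, c(2:6, 1L), 4L)
    bonds <- ring
    start <- 7L
  } else {
    elements[1] <- "C"
    start <- 2L
  }
  ring_seeded <- with_ring && n_atoms >= 6
  if (start <= n_atoms) {
    for (i in start:n_atoms) {
      elements[i] <- sample(c("C", "C", "C", "C", "C", "N", "O"), 1L)
      cand <- seq_len(i - 1L)
      deg <- if (is.null(bonds)) integer(n_atoms) else
        tabulate(c(bonds[, 1], bonds[, 2]), nbins = n_atoms)
      maxdeg <- ifelse(elements[cand] == "O", 2L,
                       ifelse(elements[cand] == "N", 3L, 4L))
      if (ring_seeded) maxdeg[cand <= 6L] <- 3L   # aromatic carbons
      open <- cand[deg[cand] < maxdeg]
      if (length(open) == 0L) open <- cand
      parent <- if (length(open) == 1L) open else sample(open, 1L)
      bonds <- rbind(bonds, c(parent, i, 1L))
    }
  }
  lig <- ligand_graph(elements, bonds, name = sprintf("FIX-%03d", n_atoms))
  generate_conformer(lig, seed = conformer_seed)
}

.random_rotation <- function() {
  quat_to_rotation(stats::rnorm(3))
}

#' Generate a synthetic protein-ligand complex
#'
#' Deterministic in `seed`. The true pose places the (rigid) conformer near
#' the pocket center with a random rotation and jitter, re-drawn with
#' shrinking jitter until no ligand-protein heavy-atom contact is below
#' 2 Angstrom.
#'
#' @param seed integer seed.
#' @param n_residues protein size (default drawn in 20-80).
#' @param n_lig_atoms ligand heavy-atom count (default drawn in 5-30).
#' @param with_ring force/suppress the aromatic ring (default random).
#' @param max_tries pose placement attempts before failing.
#' @return A `fixture_complex`: `protein`, `ligand`, `pose` (n x 3 true
#'   coordinates, canonical atom order), `affinity`, `pocket_center`,
#'   `seed`.
#' @export
make_complex <- function(seed, n_residues = NULL, n_lig_atoms = NULL,
                         with_ring = NA, max_tries = 50L) {
  withr::with_seed(seed, {
    if (is.null(n_residues)) n_residues <- sample(20:80, 1L)
    if (is.null(n_lig_atoms)) n_lig_atoms <- sample(5:30, 1L)
    stopifnot(n_residues >= 3L, n_lig_atoms >= 1L)
    protein <- .fixture_protein(n_residues)
    ligand <- .fixture_ligand(n_lig_atoms, conformer_seed = seed, with_ring)
    prot_atoms <- rbind(protein$n, protein$ca, protein$c)
    pose <- NULL
    for (try in seq_len(max_tries)) {
      jitter_scale <- 2.0 * (1 - (try - 1) / max_tries)
      R <- .random_rotation()
      jit <- stats::runif(3, -1, 1) * jitter_scale
      cand <- sweep(ligand$coords, 2, colMeans(ligand$coords)) %*% t(R)
      cand <- sweep(cand, 2, jit, "+")
      dmin <- min(sqrt(pmax(0, outer(rowSums(cand^2), rowSums(prot_atoms^2), "+") -
                              2 * cand %*% t(prot_atoms))))
      if (is.finite(dmin) && dmin >= 2.0) { pose <- cand; break }
    }
    if (is.null(pose)) {
      rlang::abort(sprintf(
        "could not place ligand without clashes (seed %d)", seed),
        class = "fd_generation_error")
    }
    structure(list(protein = protein, ligand = ligand, pose = pose,
                   affinity = fixture_affinity(ligand),
                   pocket_center = c(0, 0, 0), seed = seed),
              class = "fixture_complex")
  })
}

#' Write a fixture complex to disk (PDB + SDF)
#'
#' @param cx A `fixture_complex`.
#' @param dir output directory (created if needed).
#' @param stem file stem (default `complex_<seed>`).
#' @return Invisibly, the two paths.
#' @export
write_complex <- function(cx, dir, stem = NULL) {
  if (is.null(stem)) stem <- sprintf("complex_%d", cx$seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ppath <- file.path(dir, paste0(stem, ".pdb"))
  lpath <- file.path(dir, paste0(stem, ".sdf"))
  write_protein_pdb(cx$protein, ppath)
  write_pose(cx$ligand, cx$pose, lpath,
             provenance = list(affinity = cx$affinity, seed = cx$seed))
  invisible(c(protein = ppath, ligand = lpath))
}

# Topology signature used to enforce ligand disjointness across splits.
.ligand_signature <- function(lig) {
  paste(c(lig$elements, as.vector(t(lig$bonds))), collapse = ",")
}

#' Generate a train/validation/test fixture dataset
#'
#' Splits are disjoint in ligand chemical graphs: complexes whose ligands
#' share a topology always land in the same split.
#'
#' @param n number of complexes (>= 3).
#' @param seed integer seed.
#' @param frac length-3 split fractions (train, val, test).
#' @param ... forwarded to [make_complex()].
#' @return `list(train = , val = , test = )` of `fixture_complex` lists.
#' @export
make_dataset <- function(n, seed, frac = c(0.7, 0.15, 0.15), ...) {
  stopifnot(n >= 3L)
  complexes <- lapply(seq_len(n), function(i) {
    make_complex(seed = seed + 101L * i, ...)
  })
  sigs <- vapply(complexes, function(cx) .ligand_signature(cx$ligand),
                 character(1))
  usig <- unique(sigs)
  withr::with_seed(seed, {
    usig <- sample(usig)
  })
  k <- length(usig)
  n_train <- max(1L, round(frac[1] * k))
  n_val <- max(1L, round(frac[2] * k))
  if (n_train + n_val >= k) {
    n_train <- max(1L, k - 2L); n_val <- 1L
  }
  grp <- rep(3L, k)
  grp[seq_len(n_train)] <- 1L
  grp[n_train + seq_len(n_val)] <- 2L
  assign <- grp[match(sigs, usig)]
  list(train = complexes[assign == 1L],
       val = complexes[assign == 2L],
       test = complexes[assign == 3L])
}

#' Symmetric test ligands with a relabeled twin
#'
#' Produces a molecule with a nontrivial automorphism group and a coordinate
#' copy permuted by one of its automorphisms, for exercising
#' symmetry-corrected RMSD. Kinds: `"ring6"` (aromatic 6-ring, 12
#' automorphisms), `"triangle"` (3-ring, 6), `"linear-palindrome"`
#' (O-C-C-O, 2).
#'
#' @param kind one of `"ring6"`, `"triangle"`, `"linear-palindrome"`.
#' @return `list(ligand, twin_coords, permutation, kind)`.
#' @export
make_symmetric_ligand <- function(kind = c("ring6", "triangle",
                                           "linear-palindrome")) {
  kind <- match.arg(kind)
  if (kind == "ring6") {
    ang <- 2 * pi * (0:5) / 6
    coords <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
    lig <- ligand_graph(rep("C", 6), cbind(1:6, c(2:6, 1L), 4L),
                        coords = coords, name = "ring6",
                        canonicalize = FALSE)
    perm <- c(2:6, 1L)
  } else if (kind == "triangle") {
    ang <- 2 * pi * (0:2) / 3
    rr <- 1.51 / sqrt(3)
    coords <- cbind(rr * cos(ang), rr * sin(ang), 0)
    lig <- ligand_graph(rep("C", 3), cbind(1:3, c(2:3, 1L), 1L),
                        coords = coords, name = "triangle",
                        canonicalize = FALSE)
    perm <- c(2L, 3L, 1L)
  } else {
    coords <- rbind(c(0, 0, 0), c(1.2, 0.8, 0), c(2.7, 0.8, 0), c(3.9, 0, 0))
    lig <- ligand_graph(c("O", "C", "C", "O"),
                        rbind(c(1L, 2L, 1L), c(2L, 3L, 1L), c(3L, 4L, 1L)),
                        coords = coords, name = "palindrome",
                        canonicalize = FALSE)
    perm <- c(4L, 3L, 2L, 1L)
  }
  list(ligand = lig, twin_coords = lig$coords[perm, , drop = FALSE],
       permutation = perm, kind = kind)
}
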