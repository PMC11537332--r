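# Ligand I/O and preparation: parsing (SDF/MOL2/SMILES via ChemmineR and
# Open Babel), hydrogen stripping, canonical atom ordering, aromaticity and
# implicit-hydrogen perception, and seeded conformer generation.

.FD_COVALENT_RADII <- c(H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66,
                        F = 0.57, Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02,
                        Se = 1.20, Br = 1.20, I = 1.39)

.FD_ATOMIC_MASS <- c(H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999,
                     F = 18.998, Si = 28.086, P = 30.974, S = 32.065,
                     Cl = 35.453, Se = 78.971, Br = 79.904, I = 126.904)

.FD_DEFAULT_VALENCE <- c(B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3,
                         S = 2, Cl = 1, Se = 2, Br = 1, I = 1)

.lig_adjacency <- function(n, bonds) {
  A <- matrix(FALSE, n, n)
  if (nrow(bonds) > 0L) {
    A[cbind(bonds[, 1], bonds[, 2])] <- TRUE
    A[cbind(bonds[, 2], bonds[, 1])] <- TRUE
  }
  A
}

.lig_graph_obj <- function(lig) {
  g <- igraph::make_empty_graph(n = length(lig$elements), directed = FALSE)
  if (nrow(lig$bonds) > 0L) {
    g <- igraph::add_edges(g, as.vector(t(lig$bonds[, 1:2, drop = FALSE])))
  }
  g
}

# Ring bonds = edges not bridges; an atom is "in ring" if incident to one.
.perceive_rings <- function(n, bonds) {
  if (nrow(bonds) == 0L) {
    return(list(ring_bond = logical(0), in_ring = logical(n)))
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::add_edges(g, as.vector(t(bonds[, 1:2, drop = FALSE])))
  br <- igraph::bridges(g)
  ring_bond <- !(seq_len(nrow(bonds)) %in% as.integer(br))
  in_ring <- logical(n)
  if (any(ring_bond)) {
    in_ring[unique(as.vector(bonds[ring_bond, 1:2]))] <- TRUE
  }
  list(ring_bond = ring_bond, in_ring = in_ring)
}

# Aromatic perception: a ring-bond component that is a single 5-7 cycle is
# aromatic when every member atom either carries a double/aromatic ring bond
# or is a lone-pair heteroatom (N/O/S). Covers benzene-like and
# pyridine/furan-like rings; fused systems are handled ring-component-wise
# and are a documented approximation.
.perceive_aromatic <- function(n, bonds, ring_bond) {
  arom_atom <- logical(n)
  arom_bond <- logical(nrow(bonds))
  if (!any(ring_bond)) return(list(atom = arom_atom, bond = arom_bond))
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  rb <- which(ring_bond)
  g <- igraph::add_edges(g, as.vector(t(bonds[rb, 1:2, drop = FALSE])))
  comp <- igraph::components(g)
  for (cid in seq_len(comp$no)) {
    verts <- which(comp$membership == cid)
    if (length(verts) < 5L || length(verts) > 7L) next
    eidx <- rb[bonds[rb, 1] %in% verts & bonds[rb, 2] %in% verts]
    if (length(eidx) != length(verts)) next   # not a single simple cycle
    ok <- TRUE
    for (v in verts) {
      vb <- eidx[bonds[eidx, 1] == v | bonds[eidx, 2] == v]
      has_pi <- any(bonds[vb, 3] >= 2)
      elem <- attr(bonds, "elements")[v]
      if (!has_pi && !(elem %in% c("N", "O", "S"))) { ok <- FALSE; break }
    }
    if (ok) {
      arom_atom[verts] <- TRUE
      arom_bond[eidx] <- TRUE
    }
  }
  list(atom = arom_atom, bond = arom_bond)
}

.implicit_h <- function(elements, charges, bonds) {
  n <- length(elements)
  bsum <- numeric(n)
  if (nrow(bonds) > 0L) {
    ord <- ifelse(bonds[, 3] == 4, 1.5, bonds[, 3])
    for (b in seq_len(nrow(bonds))) {
      bsum[bonds[b, 1]] <- bsum[bonds[b, 1]] + ord[b]
      bsum[bonds[b, 2]] <- bsum[bonds[b, 2]] + ord[b]
    }
  }
  val <- .FD_DEFAULT_VALENCE[elements]
  val[is.na(val)] <- 0
  adj <- ifelse(elements %in% c("N", "P"), charges, -abs(charges))
  pmax(0L, as.integer(round(val + adj - bsum)))
}

#' Ligand chemical graph
#'
#' Heavy-atom molecular graph with conformer coordinates. Atoms are stored
#' in canonical order (see [canonicalize_ligand()]); hydrogens are implicit.
#'
#' @param elements character vector of element symbols.
#' @param bonds m x 3 integer matrix: atom i, atom j, bond order (4 =
#'   aromatic).
#' @param charges integer formal charges (default 0).
#' @param coords n x 3 conformer coordinates (Angstrom), or NULL.
#' @param name molecule name.
#' @param canonicalize reorder atoms canonically (default TRUE).
#' @return Object of class `ligand_graph` with fields `elements`, `charges`,
#'   `bonds`, `adjacency`, `coords`, `aromatic`, `in_ring`, `implicit_h`,
#'   `canonical_rank`.
#' @export
ligand_graph <- function(elements, bonds, charges = NULL, coords = NULL,
                         name = "ligand", canonicalize = TRUE) {
  n <- length(elements)
  bonds <- matrix(as.integer(bonds), ncol = 3)
  if (is.null(charges)) charges <- integer(n)
  if (!is.null(coords)) coords <- matrix(as.numeric(coords), ncol = 3)
  if (nrow(bonds) > 0L) {
    swap <- bonds[, 1] > bonds[, 2]
    bonds[swap, 1:2] <- bonds[swap, 2:1]
    if (any(bonds[, 1] == bonds[, 2]) || any(bonds[, 1:2] < 1L) ||
        any(bonds[, 1:2] > n)) {
      rlang::abort("invalid bond indices", class = "fd_parse_error")
    }
  }
  rings <- .perceive_rings(n, bonds)
  attr(bonds, "elements") <- elements
  arom <- .perceive_aromatic(n, bonds, rings$ring_bond)
  attr(bonds, "elements") <- NULL
  # normalize aromatic ring bonds to order 4 so the canonical graph does not
  # depend on an arbitrary Kekule assignment in the input
  if (any(arom$bond)) bonds[arom$bond, 3] <- 4L
  lig <- structure(list(
    elements = elements,
    charges = as.integer(charges),
    bonds = bonds,
    adjacency = .lig_adjacency(n, bonds),
    coords = coords,
    aromatic = arom$atom,
    in_ring = rings$in_ring,
    implicit_h = .implicit_h(elements, charges, bonds),
    canonical_rank = seq_len(n),
    name = name,
    provenance = list()
  ), class = "ligand_graph")
  if (canonicalize) canonicalize_ligand(lig) else lig
}

#' @export
print.ligand_graph <- function(x, ...) {
  cat(sprintf("<ligand_graph> %s: %d heavy atoms, %d bonds%s\n",
              x$name, length(x$elements), nrow(x$bonds),
              if (is.null(x$coords)) ", no conformer" else ""))
  invisible(x)
}

#' Number of heavy atoms in a ligand
#' @param ligand A [ligand_graph()].
#' @return Integer atom count.
#' @export
n_atoms <- function(ligand) length(ligand$elements)

#' Canonicalize ligand atom order
#'
#' Atoms are reordered by a canonical ranking of the colored molecular graph
#' (vertex colors from element and formal charge, edge colors from bond
#' order, computed with the BLISS canonical labeling in igraph). The ranking
#' is a pure graph property: it is invariant to the input atom order and
#' idempotent.
#'
#' @param lig A [ligand_graph()].
#' @return The ligand with atoms in canonical order; `canonical_rank` holds
#'   the applied permutation (new position of each input atom).
#' @export
canonicalize_ligand <- function(lig) {
  n <- length(lig$elements)
  if (n <= 1L) return(lig)
  akey <- paste0(lig$elements, ":", lig$charges)
  acol <- match(akey, sort(unique(akey)))
  m <- nrow(lig$bonds)
  # augment: one vertex per bond, colored by bond order, to give BLISS an
  # edge-colored graph
  edges <- integer(0)
  bcol <- integer(0)
  if (m > 0L) {
    for (b in seq_len(m)) {
      bv <- n + b
      edges <- c(edges, lig$bonds[b, 1], bv, bv, lig$bonds[b, 2])
      bcol <- c(bcol, max(acol) + lig$bonds[b, 3])
    }
  }
  g <- igraph::make_empty_graph(n = n + m, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  labeling <- igraph::canonical_permutation(
    g, colors = c(acol, bcol))$labeling
  ord <- order(labeling[seq_len(n)])
  perm <- integer(n)            # new position of input atom k
  perm[ord] <- seq_len(n)
  remap <- lig$bonds
  if (m > 0L) {
    remap[, 1] <- perm[lig$bonds[, 1]]
    remap[, 2] <- perm[lig$bonds[, 2]]
    swap <- remap[, 1] > remap[, 2]
    remap[swap, 1:2] <- remap[swap, 2:1]
    remap <- remap[order(remap[, 1], remap[, 2]), , drop = FALSE]
  }
  # If the relabeled graph is identical, the computed permutation is an
  # automorphism (the atoms are already in canonical order): keep the
  # current order so canonicalization is idempotent.
  if (identical(lig$elements[ord], lig$elements) &&
      identical(lig$charges[ord], lig$charges) &&
      identical(unname(remap), unname(lig$bonds))) {
    lig$canonical_rank <- seq_len(n)
    return(lig)
  }
  lig$elements <- lig$elements[ord]
  lig$charges <- lig$charges[ord]
  lig$aromatic <- lig$aromatic[ord]
  lig$in_ring <- lig$in_ring[ord]
  lig$implicit_h <- lig$implicit_h[ord]
  if (!is.null(lig$coords)) lig$coords <- lig$coords[ord, , drop = FALSE]
  lig$bonds <- remap
  lig$adjacency <- .lig_adjacency(n, remap)
  lig$canonical_rank <- perm
  lig
}

## ---- conformer generation --------------------------------------------------

.bond_length_target <- function(e1, e2, order) {
  r <- unname(.FD_COVALENT_RADII[e1] + .FD_COVALENT_RADII[e2])
  r[is.na(r)] <- 1.5
  f <- c(`1` = 1, `2` = 0.87, `3` = 0.78, `4` = 0.92)[as.character(order)]
  r * unname(f)
}

#' Generate a 3D conformer for a ligand graph
#'
#' Deterministic seeded embedding: coordinates are initialized from a seeded
#' normal draw and refined by L-BFGS on a harmonic objective with bond-length
#' terms (covalent-radius targets), 1-3 angle terms (109.5 degrees
#' tetrahedral, 120 degrees at sp2/aromatic centers) and a soft nonbonded
#' repulsion. Intended for realistic local geometry, not conformational
#' search.
#'
#' @param lig A [ligand_graph()].
#' @param seed integer seed (default 2024).
#' @return The ligand with `coords` set and provenance recorded.
#' @export
generate_conformer <- function(lig, seed = 2024L) {
  n <- length(lig$elements)
  if (n == 1L) {
    lig$coords <- matrix(0, 1, 3)
    return(lig)
  }
  b <- lig$bonds
  d0 <- .bond_length_target(lig$elements[b[, 1]], lig$elements[b[, 2]], b[, 3])
  # 1-3 pairs through each center atom
  a_i <- integer(0); a_k <- integer(0); a_d <- numeric(0)
  for (j in seq_len(n)) {
    nb <- which(lig$adjacency[j, ])
    if (length(nb) < 2L) next
    theta <- if (lig$aromatic[j] || any(b[b[, 1] == j | b[, 2] == j, 3] >= 2)) {
      120 * pi / 180
    } else 109.47 * pi / 180
    for (u in seq_along(nb)) {
      for (w in seq_along(nb)) {
        if (u >= w) next
        i <- nb[u]; k <- nb[w]
        if (lig$adjacency[i, k]) next   # 3-ring: closed by its own bond term
        di <- .bond_length_target(lig$elements[i], lig$elements[j],
                                  b[which((b[, 1] == min(i, j)) & (b[, 2] == max(i, j)))[1], 3])
        dk <- .bond_length_target(lig$elements[k], lig$elements[j],
                                  b[which((b[, 1] == min(k, j)) & (b[, 2] == max(k, j)))[1], 3])
        a_i <- c(a_i, i); a_k <- c(a_k, k)
        a_d <- c(a_d, sqrt(di^2 + dk^2 - 2 * di * dk * cos(theta)))
      }
    }
  }
  g <- .lig_graph_obj(lig)
  gd <- igraph::distances(g)
  rep_pairs <- which(upper.tri(gd) & gd >= 3, arr.ind = TRUE)
  rcut <- 2.5
  obj <- function(par) {
    X <- matrix(par, n, 3)
    db <- sqrt(rowSums((X[b[, 1], , drop = FALSE] - X[b[, 2], , drop = FALSE])^2))
    f <- sum((db - d0)^2)
    if (length(a_i)) {
      da <- sqrt(rowSums((X[a_i, , drop = FALSE] - X[a_k, , drop = FALSE])^2))
      f <- f + 0.3 * sum((da - a_d)^2)
    }
    if (nrow(rep_pairs)) {
      dr <- sqrt(rowSums((X[rep_pairs[, 1], , drop = FALSE] -
                            X[rep_pairs[, 2], , drop = FALSE])^2))
      f <- f + sum(pmax(0, rcut - dr)^2)
    }
    f
  }
  grad <- function(par) {
    X <- matrix(par, n, 3)
    G <- matrix(0, n, 3)
    acc <- function(i, j, w) {
      D <- X[i, , drop = FALSE] - X[j, , drop = FALSE]
      d <- sqrt(rowSums(D * D)) + 1e-12
      gg <- (w / d) * D
      # scatter-add per pair (loop is fine at this scale)
      for (p in seq_along(i)) {
        G[i[p], ] <<- G[i[p], ] + gg[p, ]
        G[j[p], ] <<- G[j[p], ] - gg[p, ]
      }
    }
    db <- sqrt(rowSums((X[b[, 1], , drop = FALSE] - X[b[, 2], , drop = FALSE])^2)) + 1e-12
    acc(b[, 1], b[, 2], 2 * (db - d0))
    if (length(a_i)) {
      da <- sqrt(rowSums((X[a_i, , drop = FALSE] - X[a_k, , drop = FALSE])^2)) + 1e-12
      acc(a_i, a_k, 0.3 * 2 * (da - a_d))
    }
    if (nrow(rep_pairs)) {
      dr <- sqrt(rowSums((X[rep_pairs[, 1], , drop = FALSE] -
                            X[rep_pairs[, 2], , drop = FALSE])^2)) + 1e-12
      w <- -2 * pmax(0, rcut - dr)
      keep <- w != 0
      if (any(keep)) acc(rep_pairs[keep, 1], rep_pairs[keep, 2], w[keep])
    }
    as.vector(G)
  }
  init <- withr::with_seed(seed, matrix(stats::rnorm(3 * n, sd = 1.5), n, 3))
  fit <- stats::optim(as.vector(init), obj, grad, method = "L-BFGS-B",
                      control = list(maxit = 500))
  lig$coords <- matrix(fit$par, n, 3)
  lig$provenance$conformer_seed <- seed
  lig$provenance$conformer_generated <- TRUE
  lig
}

## ---- file I/O ---------------------------------------------------------------

.sdf_charge_code <- c(`1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L, `6` = -2L,
                      `7` = -3L)

# Parse one V2000 molblock (character vector of lines) into raw fields.
.parse_molblock <- function(lines) {
  counts <- lines[4]
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(nb)) nb <- 0L
  if (is.na(na) || na < 1L) {
    rlang::abort("unparseable SDF counts line (line 4)",
                 class = "fd_parse_error")
  }
  atoms <- lines[5:(4 + na)]
  coords <- matrix(0, na, 3)
  elements <- character(na)
  charges <- integer(na)
  for (i in seq_len(na)) {
    ln <- atoms[i]
    coords[i, ] <- as.numeric(c(substr(ln, 1, 10), substr(ln, 11, 20),
                                substr(ln, 21, 30)))
    elements[i] <- trimws(substr(ln, 32, 34))
    code <- suppressWarnings(as.integer(substr(ln, 37, 39)))
    if (!is.na(code) && as.character(code) %in% names(.sdf_charge_code)) {
      charges[i] <- .sdf_charge_code[[as.character(code)]]
    }
  }
  bonds <- matrix(0L, nb, 3)
  if (nb > 0L) {
    blines <- lines[(5 + na):(4 + na + nb)]
    for (i in seq_len(nb)) {
      bonds[i, ] <- as.integer(c(substr(blines[i], 1, 3),
                                 substr(blines[i], 4, 6),
                                 substr(blines[i], 7, 9)))
    }
  }
  # M CHG lines override atom-block charge codes
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    toks <- as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))), "\\s+")[[1]])
    k <- toks[1]
    for (q in seq_len(k)) {
      charges[toks[2 * q]] <- toks[2 * q + 1]
    }
  }
  list(elements = elements, coords = coords, charges = charges, bonds = bonds,
       name = trimws(lines[1]))
}

.strip_hydrogens <- function(raw) {
  keep <- raw$elements != "H"
  if (all(keep)) return(raw)
  map <- cumsum(keep)
  b <- raw$bonds
  if (nrow(b) > 0L) {
    bk <- keep[b[, 1]] & keep[b[, 2]]
    b <- b[bk, , drop = FALSE]
    b[, 1] <- map[b[, 1]]
    b[, 2] <- map[b[, 2]]
  }
  list(elements = raw$elements[keep], coords = raw$coords[keep, , drop = FALSE],
       charges = raw$charges[keep], bonds = b, name = raw$name)
}

.keep_largest_fragment <- function(raw) {
  n <- length(raw$elements)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(raw$bonds) > 0L) {
    g <- igraph::add_edges(g, as.vector(t(raw$bonds[, 1:2, drop = FALSE])))
  }
  comp <- igraph::components(g)
  if (comp$no <= 1L) return(raw)
  warning("multi-fragment ligand record: keeping the largest fragment",
          call. = FALSE)
  big <- which.max(comp$csize)
  keep <- comp$membership == big
  map <- cumsum(keep)
  b <- raw$bonds
  bk <- keep[b[, 1]] & keep[b[, 2]]
  b <- b[bk, , drop = FALSE]
  b[, 1] <- map[b[, 1]]; b[, 2] <- map[b[, 2]]
  list(elements = raw$elements[keep], coords = raw$coords[keep, , drop = FALSE],
       charges = raw$charges[keep], bonds = b, name = raw$name)
}

#' Load a ligand from SDF, MOL2 or a SMILES string
#'
#' Hydrogens are stripped (the model works on heavy atoms), salts are reduced
#' to the largest fragment, atoms are reordered canonically, and a conformer
#' is generated with a fixed seed when the input has no 3D coordinates.
#'
#' @param x path to an `.sdf`/`.mol`/`.mol2` file, or a SMILES string.
#' @param conformer_seed seed for conformer generation (default 2024).
#' @param name optional molecule name override.
#' @return A [ligand_graph()].
#' @export
load_ligand <- function(x, conformer_seed = 2024L, name = NULL) {
  is_file <- length(x) == 1L && !grepl("\n", x) && file.exists(x)
  if (is_file) {
    ext <- tolower(tools::file_ext(x))
    if (ext == "mol2") {
      tmp <- tempfile(fileext = ".sdf")
      ChemmineOB::convertFormatFile("MOL2", "SDF", x, tmp)
      lines <- readLines(tmp, warn = FALSE)
    } else {
      lines <- readLines(x, warn = FALSE)
    }
    src <- x
  } else {
    sdf <- tryCatch(ChemmineR::smiles2sdf(x), error = function(e) {
      rlang::abort(sprintf("cannot parse SMILES '%s': %s", x, conditionMessage(e)),
                   class = "fd_parse_error")
    })
    lines <- ChemmineR::sdf2str(sdf[[1]])
    src <- paste0("SMILES:", x)
  }
  end <- which(grepl("^\\$\\$\\$\\$", lines))
  if (length(end) > 0L) lines <- lines[seq_len(end[1] - 1L)]
  raw <- .parse_molblock(lines)
  raw <- .strip_hydrogens(raw)
  raw <- .keep_largest_fragment(raw)
  if (length(raw$elements) == 0L) {
    rlang::abort("no heavy atoms in ligand record", class = "fd_parse_error")
  }
  bad <- !(raw$elements %in% names(.FD_COVALENT_RADII))
  if (any(bad)) {
    rlang::abort(sprintf(
      "unsupported element(s) %s; supported: %s",
      paste(unique(raw$elements[bad]), collapse = ", "),
      paste(names(.FD_COVALENT_RADII), collapse = ", ")),
      class = "fd_vocab_error")
  }
  lig <- ligand_graph(raw$elements, raw$bonds, raw$charges, raw$coords,
                      name = if (is.null(name)) {
                        if (nzchar(raw$name)) raw$name else "ligand"
                      } else name)
  lig$provenance$source <- src
  if (is.null(lig$coords) || max(abs(lig$coords[, 3])) < 1e-6) {
    lig <- generate_conformer(lig, seed = conformer_seed)
  }
  lig
}

#' Write a ligand pose to SDF
#'
#' Writes the ligand's chemical graph with the supplied coordinates as a
#' V2000 molblock, including formal charges and provenance data fields.
#'
#' @param ligand A [ligand_graph()].
#' @param coords n x 3 predicted coordinates; defaults to the stored
#'   conformer.
#' @param path output path.
#' @param provenance named list written as SDF data fields.
#' @param append append to an existing file (multi-model SDF).
#' @return Invisibly, the path.
#' @export
write_pose <- function(ligand, coords = NULL, path, provenance = list(),
                       append = FALSE) {
  if (is.null(coords)) coords <- ligand$coords
  coords <- matrix(as.numeric(coords), ncol = 3)
  n <- length(ligand$elements)
  if (nrow(coords) != n) {
    rlang::abort(sprintf("coords rows (%d) != atom count (%d)",
                         nrow(coords), n), class = "fd_parse_error")
  }
  b <- ligand$bonds
  lines <- c(
    ligand$name, "  framedock", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nrow(b)),
    vapply(seq_len(n), function(i) {
      sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
              coords[i, 1], coords[i, 2], coords[i, 3], ligand$elements[i])
    }, character(1)),
    if (nrow(b) > 0L) {
      vapply(seq_len(nrow(b)), function(i) {
        sprintf("%3d%3d%3d  0  0  0  0", b[i, 1], b[i, 2], b[i, 3])
      }, character(1))
    }
  )
  chg <- which(ligand$charges != 0L)
  if (length(chg)) {
    lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(chg)),
                             paste0(sprintf("%4d%4d", chg, ligand$charges[chg]),
                                    collapse = "")))
  }
  lines <- c(lines, "M  END")
  for (key in names(provenance)) {
    lines <- c(lines, sprintf(">  <%s>", key),
               as.character(provenance[[key]]), "")
  }
  lines <- c(lines, "$$$$")
  con <- file(path, open = if (append) "a" else "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
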