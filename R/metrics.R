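# Evaluation and interpretability: symmetry-corrected ligand RMSD, the
# strict 2 A success rate, physicochemical descriptors, and channel-wise
# Pearson correlation of pooled ligand embeddings with those descriptors.

# Enumerate element/charge/bond-order-preserving automorphisms of the heavy
# atom graph (VF2 with vertex and edge colors). Returns a list of
# permutations, or NULL if the count exceeds `cap`.
ligand_automorphisms <- function(ligand, cap = 10000L) {
  n <- n_atoms(ligand)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(ligand$bonds) > 0L) {
    g <- igraph::add_edges(g, as.vector(t(ligand$bonds[, 1:2, drop = FALSE])))
  }
  key <- paste0(ligand$elements, ":", ligand$charges)
  vc <- match(key, sort(unique(key)))
  ec <- as.integer(ligand$bonds[, 3])
  cnt <- igraph::count_isomorphisms(g, g, method = "vf2",
                                    vertex.color1 = vc, vertex.color2 = vc,
                                    edge.color1 = ec, edge.color2 = ec)
  if (cnt > cap) return(NULL)
  maps <- igraph::isomorphisms(g, g, method = "vf2",
                               vertex.color1 = vc, vertex.color2 = vc,
                               edge.color1 = ec, edge.color2 = ec)
  lapply(maps, as.integer)
}

#' Symmetry-corrected ligand RMSD
#'
#' Minimum in-place (no re-superposition) RMSD over all chemically valid
#' atom relabelings: graph automorphisms of the heavy-atom graph preserving
#' element, formal charge and bond order. If the automorphism group exceeds
#' `cap` permutations, the naive RMSD is returned with a warning.
#'
#' @param pred,target n x 3 coordinate matrices (canonical atom order).
#' @param ligand The [ligand_graph()] defining chemical equivalence.
#' @param cap automorphism enumeration cap (default 10000).
#' @return RMSD in Angstrom.
#' @export
symmetry_corrected_rmsd <- function(pred, target, ligand, cap = 10000L) {
  pred <- matrix(as.numeric(pred), ncol = 3)
  target <- matrix(as.numeric(target), ncol = 3)
  stopifnot(nrow(pred) == n_atoms(ligand), nrow(target) == n_atoms(ligand))
  autos <- ligand_automorphisms(ligand, cap = cap)
  if (is.null(autos)) {
    warning(sprintf(
      "automorphism count exceeds cap (%d): using naive RMSD", cap),
      call. = FALSE)
    return(naive_rmsd(pred, target))
  }
  min(vapply(autos, function(p) naive_rmsd(pred[p, , drop = FALSE], target),
             numeric(1)))
}

#' Docking success rate
#'
#' Percentage of predictions with symmetry-corrected RMSD strictly below
#' 2 Angstrom.
#'
#' @param rmsds numeric vector of per-complex RMSD values (Angstrom).
#' @return Percentage in `[0, 100]`.
#' @export
success_rate <- function(rmsds) {
  if (length(rmsds) == 0L) {
    rlang::abort("success rate of an empty RMSD list is undefined",
                 class = "fd_empty_error")
  }
  100 * mean(rmsds < 2)
}

## ---- physicochemical descriptors -------------------------------------------

#' Descriptor names (column order of [descriptor_table()])
#' @export
FD_DESCRIPTORS <- c("hydrophobic_sa", "mol_weight", "hba", "hbd", "psa",
                    "rotatable_bonds", "logp", "aromatic_rings")

# Approximate per-atom contribution descriptors. The surface-area, polar
# surface area and logP columns are additive per-atom schemes (documented
# approximations); weight/HBA/HBD/rotatable-bond/ring counts are exact.
.descriptors_one <- function(lig) {
  el <- lig$elements
  deg <- rowSums(lig$adjacency)
  imph <- lig$implicit_h
  nonpolar <- el %in% c("C", "S", "F", "Cl", "Br", "I")
  hsa <- sum(pmax(4, 25 - 6 * deg[nonpolar]))
  mw <- sum(.FD_ATOMIC_MASS[el], na.rm = TRUE) + 1.008 * sum(imph)
  hba <- sum(el %in% c("N", "O"))
  hbd <- sum(el %in% c("N", "O") & imph >= 1L)
  # Ertl-like polar contributions
  psa <- 0
  for (i in seq_along(el)) {
    if (el[i] == "O") {
      has_dbl <- any(lig$bonds[lig$bonds[, 1] == i | lig$bonds[, 2] == i, 3] == 2)
      psa <- psa + if (imph[i] >= 1L) 20.23 else if (has_dbl) 17.07 else 9.23
    } else if (el[i] == "N") {
      psa <- psa + if (imph[i] >= 2L) 26.02 else if (imph[i] == 1L) 12.03
      else if (lig$aromatic[i]) 12.89 else 3.24
    }
  }
  rot <- 0L
  if (nrow(lig$bonds) > 0L) {
    ring_bond <- .perceive_rings(length(el), lig$bonds)$ring_bond
    for (b in seq_len(nrow(lig$bonds))) {
      i <- lig$bonds[b, 1]; j <- lig$bonds[b, 2]
      if (lig$bonds[b, 3] == 1L && !ring_bond[b] && deg[i] >= 2 && deg[j] >= 2) {
        rot <- rot + 1L
      }
    }
  }
  atom_logp <- c(C = 0.20, N = -0.70, O = -0.65, S = 0.45, P = -0.30,
                 F = 0.50, Cl = 0.65, Br = 0.75, I = 0.85, B = 0.05,
                 Si = 0.20, Se = 0.45)
  lp <- sum(atom_logp[el], na.rm = TRUE) + 0.14 * sum(el == "C" & lig$aromatic) +
    0.12 * sum(imph[el == "C"])
  arom_idx <- which(lig$aromatic)
  n_arom_rings <- 0L
  if (length(arom_idx) >= 3L) {
    ab <- lig$bonds[lig$bonds[, 1] %in% arom_idx &
                      lig$bonds[, 2] %in% arom_idx &
                      lig$bonds[, 3] == 4L, , drop = FALSE]
    if (nrow(ab) > 0L) {
      sub <- igraph::make_empty_graph(n = length(el), directed = FALSE)
      sub <- igraph::add_edges(sub, as.vector(t(ab[, 1:2, drop = FALSE])))
      comp <- igraph::components(sub)
      used <- unique(as.vector(ab[, 1:2]))
      ncomp <- length(unique(comp$membership[used]))
      n_arom_rings <- nrow(ab) - length(used) + ncomp
    }
  }
  c(hydrophobic_sa = hsa, mol_weight = mw, hba = hba, hbd = hbd, psa = psa,
    rotatable_bonds = rot, logp = lp, aromatic_rings = n_arom_rings)
}

#' Physicochemical descriptor table
#'
#' Eight descriptors per ligand, in order: total hydrophobic surface area
#' (approximate per-atom contributions, A^2), molecular weight (Da, implicit
#' hydrogens included), H-bond acceptor count, H-bond donor count, polar
#' surface area (approximate Ertl-style contributions, A^2), rotatable bond
#' count, octanol-water partition coefficient (approximate additive scheme),
#' and aromatic ring count. Molecules whose descriptors fail are flagged via
#' the `ok` attribute and should be excluded from correlations.
#'
#' @param ligands list of [ligand_graph()].
#' @return n x 8 numeric matrix with `FD_DESCRIPTORS` columns and an `ok`
#'   logical attribute.
#' @export
descriptor_table <- function(ligands) {
  out <- matrix(NA_real_, length(ligands), length(FD_DESCRIPTORS),
                dimnames = list(NULL, FD_DESCRIPTORS))
  ok <- logical(length(ligands))
  for (i in seq_along(ligands)) {
    row <- tryCatch(.descriptors_one(ligands[[i]]), error = function(e) NULL)
    if (!is.null(row) && all(is.finite(row))) {
      out[i, ] <- row
      ok[i] <- TRUE
    }
  }
  attr(out, "ok") <- ok
  out
}

#' Channel-descriptor correlations
#'
#' For every embedding channel and descriptor, the Pearson R and two-sided
#' p-value (no multiple-testing correction). The best descriptor per
#' channel maximizes |R|; channels or descriptors with zero variance are
#' reported as missing and excluded from the selection.
#'
#' @param embeddings n_mol x n_channels matrix (pooled ligand embeddings).
#' @param descriptors n_mol x n_desc matrix from [descriptor_table()].
#' @return data.frame with columns `channel`, `descriptor`, `r`, `p`,
#'   `best` (logical: the selected descriptor for that channel).
#' @export
channel_correlations <- function(embeddings, descriptors) {
  embeddings <- as.matrix(embeddings)
  descriptors <- as.matrix(descriptors)
  ok <- attr(descriptors, "ok")
  if (!is.null(ok)) {
    embeddings <- embeddings[ok, , drop = FALSE]
    descriptors <- descriptors[ok, , drop = FALSE]
  }
  if (nrow(embeddings) < 3L) {
    rlang::abort("need at least 3 molecules for correlations",
                 class = "fd_empty_error")
  }
  nc <- ncol(embeddings); nd <- ncol(descriptors)
  dn <- colnames(descriptors) %||% paste0("D", seq_len(nd))
  res <- vector("list", nc * nd)
  k <- 0L
  for (ch in seq_len(nc)) {
    for (dd in seq_len(nd)) {
      k <- k + 1L
      x <- embeddings[, ch]; y <- descriptors[, dd]
      if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) {
        res[[k]] <- data.frame(channel = ch, descriptor = dn[dd],
                               r = NA_real_, p = NA_real_)
      } else {
        ct <- stats::cor.test(x, y, method = "pearson")
        res[[k]] <- data.frame(channel = ch, descriptor = dn[dd],
                               r = unname(ct$estimate),
                               p = max(ct$p.value, .Machine$double.xmin))
      }
    }
  }
  out <- do.call(rbind, res)
  out$best <- FALSE
  for (ch in seq_len(nc)) {
    rows <- which(out$channel == ch & !is.na(out$r))
    if (length(rows)) out$best[rows[which.max(abs(out$r[rows]))]] <- TRUE
  }
  out
}

#' Evaluate predicted poses against targets
#'
#' @param preds list of n x 3 predicted ligand coordinates.
#' @param targets list of matching target coordinates.
#' @param ligands list of [ligand_graph()].
#' @param ids complex identifiers.
#' @param validity_hook optional function(ligand, coords) returning TRUE /
#'   FALSE, a slot for an external structural-validity checker; results are
#'   recorded in a `valid` column (NA when absent).
#' @return data.frame (id, rmsd_naive, rmsd_corrected, success, valid) with
#'   the aggregate success rate as attribute `success_rate`.
#' @export
evaluate_poses <- function(preds, targets, ligands, ids = NULL,
                           validity_hook = NULL) {
  n <- length(preds)
  if (is.null(ids)) ids <- sprintf("complex_%d", seq_len(n))
  rows <- lapply(seq_len(n), function(i) {
    rn <- naive_rmsd(preds[[i]], targets[[i]])
    rc <- symmetry_corrected_rmsd(preds[[i]], targets[[i]], ligands[[i]])
    val <- if (is.null(validity_hook)) NA else
      isTRUE(validity_hook(ligands[[i]], preds[[i]]))
    data.frame(id = ids[i], rmsd_naive = rn, rmsd_corrected = rc,
               success = rc < 2, valid = val)
  })
  out <- do.call(rbind, rows)
  attr(out, "success_rate") <- success_rate(out$rmsd_corrected)
  out
}
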