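# Rigid-transform algebra and reference-frame construction.
#
# A reference frame attaches a local coordinate system (proper rotation +
# translation) to every protein residue and every ligand heavy atom. Residue
# frames follow the backbone convention: the translation is the Ca position
# and the rotation is built from the N, Ca, C atoms by Gram-Schmidt. Ligand
# atoms have no canonical backbone, so each heavy atom is framed by treating
# itself as the Ca slot and its two lowest-canonical-index neighbours as the
# N and C slots; terminal atoms (one bond) get a deterministic dummy anchor.

#' Rigid transform (rotation + translation)
#'
#' @param R 3x3 proper rotation matrix (orthonormal, det +1).
#' @param t length-3 translation vector (Angstrom).
#' @param check validate the rotation invariants (default TRUE).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(R, t, check = TRUE) {
  R <- matrix(as.numeric(R), 3, 3)
  t <- as.numeric(t)
  stopifnot(length(t) == 3L)
  if (check) {
    err <- max(abs(crossprod(R) - diag(3)))
    if (err > 1e-6 || abs(det(R) - 1) > 1e-6) {
      rlang::abort("rotation is not a proper orthonormal matrix",
                   class = "fd_degenerate_geometry")
    }
  }
  structure(list(R = R, t = t), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform> t =", sprintf("%.3f", x$t), "\n")
  print(round(x$R, 4))
  invisible(x)
}

#' Compose two rigid transforms
#'
#' `frame_compose(a, b)` returns the transform applying `b` first, then `a`.
#' @param a,b `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
frame_compose <- function(a, b) {
  rigid_transform(a$R %*% b$R, as.vector(a$R %*% b$t) + a$t, check = FALSE)
}

#' Invert a rigid transform
#' @param x A `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
frame_inverse <- function(x) {
  rigid_transform(t(x$R), as.vector(-t(x$R) %*% x$t), check = FALSE)
}

#' Apply a rigid transform to points
#' @param x A `rigid_transform`.
#' @param pts n x 3 matrix of coordinates (rows are points).
#' @return n x 3 matrix of transformed coordinates.
#' @export
frame_apply <- function(x, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  sweep(pts %*% t(x$R), 2, x$t, "+")
}

#' Frame anchors for one atom or residue
#'
#' The three anchor points used to construct a frame: `center` fills the
#' Ca slot, `left` the N slot and `right` the C slot.
#'
#' @param center,left,right length-3 coordinates (Angstrom).
#' @param is_dummy_left,is_dummy_right whether the slot holds a synthetic
#'   dummy point (terminal ligand atoms).
#' @param index optional atom/residue index used in error messages.
#' @return An object of class `frame_anchors`.
#' @export
frame_anchors <- function(center, left, right,
                          is_dummy_left = FALSE, is_dummy_right = FALSE,
                          index = NA_integer_) {
  structure(list(center = as.numeric(center), left = as.numeric(left),
                 right = as.numeric(right),
                 is_dummy_left = is_dummy_left,
                 is_dummy_right = is_dummy_right,
                 index = index),
            class = "frame_anchors")
}

.norm3 <- function(v) sqrt(sum(v * v))

#' Build a frame from three anchor points by Gram-Schmidt
#'
#' The translation is the center point. The rotation's first basis vector
#' points along `right - center`; the second lies in the plane spanned with
#' `left - center`, orthogonalized against the first; the third is their
#' cross product, giving a right-handed proper rotation.
#'
#' @param anchors A [frame_anchors()] object.
#' @param tol collinearity tolerance on the orthogonalized component.
#' @return A [rigid_transform()].
#' @export
frame_from_three_points <- function(anchors, tol = 1e-8) {
  ctr <- anchors$center
  v1 <- anchors$right - ctr
  v2 <- anchors$left - ctr
  n1 <- .norm3(v1)
  if (n1 < tol || .norm3(v2) < tol) {
    rlang::abort(sprintf(
      "degenerate frame at index %s: coincident anchor points", anchors$index),
      class = "fd_degenerate_geometry")
  }
  e1 <- v1 / n1
  u2 <- v2 - sum(v2 * e1) * e1
  n2 <- .norm3(u2)
  if (n2 < tol * max(1, .norm3(v2))) {
    rlang::abort(sprintf(
      "degenerate frame at index %s: collinear anchor points", anchors$index),
      class = "fd_degenerate_geometry")
  }
  e2 <- u2 / n2
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  rigid_transform(cbind(e1, e2, e3, deparse.level = 0), ctr, check = FALSE)
}

#' Residue backbone frames for a protein
#'
#' One frame per residue: translation at Ca, rotation from N/Ca/C.
#'
#' @param protein A [protein_structure()] object.
#' @return List of [rigid_transform()], one per residue.
#' @export
build_residue_frames <- function(protein) {
  n <- nrow(protein$ca)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    row_ok <- all(is.finite(protein$n[i, ])) && all(is.finite(protein$ca[i, ])) &&
      all(is.finite(protein$c[i, ]))
    if (!row_ok) {
      rlang::abort(sprintf("residue %d is missing a backbone atom", i),
                   class = "fd_missing_atom")
    }
    out[[i]] <- frame_from_three_points(frame_anchors(
      center = protein$ca[i, ], left = protein$n[i, ], right = protein$c[i, ],
      index = i))
  }
  out
}

# Deterministic dummy anchor for a terminal atom: 1 Angstrom from the atom,
# orthogonal to its single bond, along the cross product of the bond vector
# with the coordinate axis least aligned with it (ties -> lowest axis).
.dummy_anchor <- function(center, neighbor) {
  b <- neighbor - center
  nb <- .norm3(b)
  if (nb < 1e-8) {
    rlang::abort("coincident bonded atoms", class = "fd_degenerate_geometry")
  }
  b <- b / nb
  ax <- diag(3)[, which.min(abs(b))]
  d <- c(b[2] * ax[3] - b[3] * ax[2],
         b[3] * ax[1] - b[1] * ax[3],
         b[1] * ax[2] - b[2] * ax[1])
  center + d / .norm3(d)
}

#' Ligand atom frames
#'
#' Each heavy atom is framed by placing itself in the Ca slot and its two
#' adjacent atoms with the lowest canonical indices in the N and C slots
#' (lowest index -> N slot). Atoms with exactly one bond use their neighbour
#' in the N slot and a deterministic dummy point in the C slot. Atoms with
#' no bonds are rejected.
#'
#' @param ligand A [ligand_graph()] with conformer coordinates.
#' @param coords optional n x 3 coordinates overriding the stored conformer.
#' @return `list(frames = <list of rigid_transform>, anchors = <list of
#'   frame_anchors>)`.
#' @export
build_ligand_frames <- function(ligand, coords = NULL) {
  X <- if (is.null(coords)) ligand$coords else matrix(as.numeric(coords), ncol = 3)
  n <- nrow(X)
  frames <- vector("list", n)
  anchors <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- sort(which(ligand$adjacency[i, ]))
    if (length(nb) == 0L) {
      rlang::abort(sprintf(
        "atom %d has no bonds; isolated atoms cannot be framed", i),
        class = "fd_unsupported_topology")
    }
    if (length(nb) >= 2L) {
      anc <- frame_anchors(center = X[i, ], left = X[nb[1L], ],
                           right = X[nb[2L], ], index = i)
    } else {
      anc <- frame_anchors(center = X[i, ], left = X[nb[1L], ],
                           right = .dummy_anchor(X[i, ], X[nb[1L], ]),
                           is_dummy_right = TRUE, index = i)
    }
    frames[[i]] <- frame_from_three_points(anc)
    anchors[[i]] <- anc
  }
  list(frames = frames, anchors = anchors)
}

# Quaternion (implicit real part 1) to rotation matrix.
quat_to_rotation <- function(v) {
  q <- c(1, as.numeric(v))
  q <- q / sqrt(sum(q * q))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y * y + z * z), 2 * (x * y - w * z),     2 * (x * z + w * y),
    2 * (x * y + w * z),     1 - 2 * (x * x + z * z), 2 * (y * z - w * x),
    2 * (x * z - w * y),     2 * (y * z + w * x),     1 - 2 * (x * x + y * y)),
    3, 3, byrow = TRUE)
}

#' Update a frame with a quaternion rotation and a local translation
#'
#' The update is composed onto the existing frame: the rotation is the
#' quaternion `(1, quat)` normalized, and the translation is expressed in
#' the frame's local coordinates (the convention used by the structure
#' module's per-block updates).
#'
#' @param frame A [rigid_transform()].
#' @param quat length-3 quaternion vector part (real part fixed at 1).
#' @param trans length-3 local translation (Angstrom).
#' @return The updated [rigid_transform()].
#' @export
update_frame <- function(frame, quat, trans) {
  Rq <- quat_to_rotation(quat)
  rigid_transform(frame$R %*% Rq,
                  frame$t + as.vector(frame$R %*% as.numeric(trans)),
                  check = FALSE)
}

# Frame list -> arrays used by the network (R: 3x3xN, t: Nx3).
frames_to_arrays <- function(frames) {
  n <- length(frames)
  R <- array(0, c(3, 3, n))
  t <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    R[, , i] <- frames[[i]]$R
    t[i, ] <- frames[[i]]$t
  }
  list(R = R, t = t)
}

#' Serialize frames to a plain-text debug dump
#'
#' Writes one tab-separated line per frame: index, the 9 rotation entries
#' (row-major), and the 3 translation entries.
#'
#' @param frames list of [rigid_transform()].
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
write_frames <- function(frames, path) {
  lines <- vapply(seq_along(frames), function(i) {
    f <- frames[[i]]
    paste(c(i, sprintf("%.9g", c(t(f$R), f$t))), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
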