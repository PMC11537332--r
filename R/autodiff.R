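# Reverse-mode automatic differentiation on a dynamic tape.
#
# The docking network is trained on CPU with gradients computed by this
# engine. Values are plain numeric matrices/vectors; differentiable
# quantities are wrapped in environments ("nodes") carrying the value, an
# accumulated gradient, the parent inputs and a backward closure. Ops accept
# nodes or plain numerics; when no input is a node (or the tape is off) they
# return plain numerics, so evaluation-mode forward passes stay allocation
# light. Fused ops (attention, triangle updates, invariant point attention,
# FAPE, Kabsch) keep the tape short; each one's backward pass is verified
# against finite differences in the test suite.

.fd_ad <- new.env(parent = emptyenv())
.fd_ad$on <- FALSE
.fd_ad$nodes <- list()
.fd_ad$n <- 0L

ad_tape_active <- function() isTRUE(.fd_ad$on)

.row_max <- function(X) X[cbind(seq_len(nrow(X)), max.col(X, ties.method = "first"))]


ad_tape_start <- function(capacity = 4096L) {
  .fd_ad$on <- TRUE
  .fd_ad$nodes <- vector("list", capacity)
  .fd_ad$n <- 0L
  invisible(NULL)
}

ad_tape_stop <- function() {
  .fd_ad$on <- FALSE
  .fd_ad$nodes <- list()
  .fd_ad$n <- 0L
  invisible(NULL)
}

ad_is_node <- function(x) is.environment(x)

ad_val <- function(x) if (is.environment(x)) x$val else x

# Leaf node (trainable parameter). Not stored on the tape; gradients are
# accumulated into $grad during ad_backward.
ad_leaf <- function(val) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$parents <- NULL
  nd$back <- NULL
  nd
}

.ad_push <- function(nd) {
  n <- .fd_ad$n + 1L
  if (n > length(.fd_ad$nodes)) {
    .fd_ad$nodes <- c(.fd_ad$nodes, vector("list", max(length(.fd_ad$nodes), 1024L)))
  }
  .fd_ad$nodes[[n]] <- nd
  .fd_ad$n <- n
  invisible(NULL)
}

# Create an interior node. `back` maps the output gradient to a list of
# gradients parallel to `parents` (NULL entries allowed for constants).
ad_op <- function(val, parents, back) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$parents <- parents
  nd$back <- back
  .ad_push(nd)
  nd
}

.ad_any_node <- function(...) {
  for (x in list(...)) if (is.environment(x)) return(TRUE)
  FALSE
}

.ad_acc <- function(p, g) {
  if (is.environment(p) && !is.null(g)) {
    p$grad <- if (is.null(p$grad)) g else p$grad + g
  }
  invisible(NULL)
}

ad_backward <- function(loss) {
  stopifnot(is.environment(loss))
  loss$grad <- 1
  if (.fd_ad$n < 1L) return(invisible(NULL))
  for (k in seq(.fd_ad$n, 1L)) {
    nd <- .fd_ad$nodes[[k]]
    if (is.null(nd) || is.null(nd$grad) || is.null(nd$back)) next
    gs <- nd$back(nd$grad)
    ps <- nd$parents
    for (j in seq_along(ps)) .ad_acc(ps[[j]], gs[[j]])
  }
  invisible(NULL)
}

## ---- elementwise and linear-algebra primitives ----------------------------

ad_add <- function(a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  y <- av + bv
  if (!.fd_ad$on || !.ad_any_node(a, b)) return(y)
  ad_op(y, list(a, b), function(g) {
    ga <- if (length(av) == 1L) sum(g) else g
    gb <- if (length(bv) == 1L) sum(g) else g
    list(ga, gb)
  })
}

ad_sub <- function(a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  y <- av - bv
  if (!.fd_ad$on || !.ad_any_node(a, b)) return(y)
  ad_op(y, list(a, b), function(g) {
    ga <- if (length(av) == 1L) sum(g) else g
    gb <- if (length(bv) == 1L) -sum(g) else -g
    list(ga, gb)
  })
}

ad_mul <- function(a, b) {
  av <- ad_val(a); bv <- ad_val(b)
  y <- av * bv
  if (!.fd_ad$on || !.ad_any_node(a, b)) return(y)
  ad_op(y, list(a, b), function(g) {
    ga <- if (length(av) == 1L) sum(g * bv) else g * bv
    gb <- if (length(bv) == 1L) sum(g * av) else g * av
    list(ga, gb)
  })
}

ad_scale <- function(a, k) {
  av <- ad_val(a)
  y <- av * k
  if (!.fd_ad$on || !ad_is_node(a)) return(y)
  ad_op(y, list(a), function(g) list(g * k))
}

# Add a length-C bias vector to every row of an n x C matrix.
ad_addrow <- function(X, b) {
  Xv <- ad_val(X); bv <- ad_val(b)
  y <- Xv + matrix(bv, nrow(Xv), length(bv), byrow = TRUE)
  if (!.fd_ad$on || !.ad_any_node(X, b)) return(y)
  ad_op(y, list(X, b), function(g) list(g, colSums(g)))
}

ad_matmul <- function(A, B) {
  Av <- ad_val(A); Bv <- ad_val(B)
  y <- Av %*% Bv
  if (!.fd_ad$on || !.ad_any_node(A, B)) return(y)
  ad_op(y, list(A, B), function(g) {
    list(g %*% t(Bv), t(Av) %*% g)
  })
}

# y = X W (+ bias per row). One tape node for the most common layer.
ad_linear <- function(X, W, b = NULL) {
  Xv <- ad_val(X); Wv <- ad_val(W)
  y <- Xv %*% Wv
  if (!is.null(b)) {
    bv <- ad_val(b)
    y <- y + matrix(bv, nrow(y), length(bv), byrow = TRUE)
  }
  if (!.fd_ad$on || !.ad_any_node(X, W, b)) return(y)
  ad_op(y, list(X, W, b), function(g) {
    list(g %*% t(Wv), t(Xv) %*% g, if (is.null(b)) NULL else colSums(g))
  })
}

ad_sigmoid <- function(x) {
  xv <- ad_val(x)
  y <- 1 / (1 + exp(-xv))
  if (!.fd_ad$on || !ad_is_node(x)) return(y)
  ad_op(y, list(x), function(g) list(g * y * (1 - y)))
}

ad_relu <- function(x) {
  xv <- ad_val(x)
  y <- xv
  y[y < 0] <- 0
  if (!.fd_ad$on || !ad_is_node(x)) return(y)
  mask <- xv > 0
  ad_op(y, list(x), function(g) list(g * mask))
}

ad_softmax_rows <- function(X) {
  Xv <- ad_val(X)
  m <- .row_max(Xv)
  E <- exp(Xv - m)
  A <- E / rowSums(E)
  if (!.fd_ad$on || !ad_is_node(X)) return(A)
  ad_op(A, list(X), function(g) {
    list(A * (g - rowSums(g * A)))
  })
}

# Row-wise layer normalization with learned gain/offset (length C).
ad_layernorm <- function(X, gamma, beta, eps = 1e-5) {
  Xv <- ad_val(X); gv <- ad_val(gamma); bv <- ad_val(beta)
  C <- ncol(Xv)
  mu <- rowMeans(Xv)
  xc <- Xv - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- xhat * matrix(gv, nrow(Xv), C, byrow = TRUE) +
    matrix(bv, nrow(Xv), C, byrow = TRUE)
  if (!.fd_ad$on || !.ad_any_node(X, gamma, beta)) return(y)
  ad_op(y, list(X, gamma, beta), function(g) {
    dgamma <- colSums(g * xhat)
    dbeta <- colSums(g)
    dxhat <- g * matrix(gv, nrow(g), C, byrow = TRUE)
    dX <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
    list(dX, dgamma, dbeta)
  })
}

ad_sum <- function(x) {
  xv <- ad_val(x)
  y <- sum(xv)
  if (!.fd_ad$on || !ad_is_node(x)) return(y)
  ad_op(y, list(x), function(g) {
    gg <- xv; gg[] <- g
    list(gg)
  })
}

ad_mean <- function(x) {
  xv <- ad_val(x)
  y <- mean(xv)
  if (!.fd_ad$on || !ad_is_node(x)) return(y)
  n <- length(xv)
  ad_op(y, list(x), function(g) {
    gg <- xv; gg[] <- g / n
    list(gg)
  })
}

ad_slice_rows <- function(X, idx) {
  Xv <- ad_val(X)
  y <- Xv[idx, , drop = FALSE]
  if (!.fd_ad$on || !ad_is_node(X)) return(y)
  ad_op(y, list(X), function(g) {
    G <- matrix(0, nrow(Xv), ncol(Xv))
    # idx entries are unique in every use within the model
    G[idx, ] <- g
    list(G)
  })
}

ad_rbind2 <- function(A, B) {
  Av <- ad_val(A); Bv <- ad_val(B)
  y <- rbind(Av, Bv)
  if (!.fd_ad$on || !.ad_any_node(A, B)) return(y)
  na <- nrow(Av)
  ad_op(y, list(A, B), function(g) {
    list(g[seq_len(na), , drop = FALSE], g[-seq_len(na), , drop = FALSE])
  })
}

ad_cbind_list <- function(xs) {
  vals <- lapply(xs, ad_val)
  y <- do.call(cbind, vals)
  if (!.fd_ad$on || !any(vapply(xs, ad_is_node, logical(1)))) return(y)
  widths <- vapply(vals, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ad_op(y, xs, function(g) {
    lapply(seq_along(xs), function(j) g[, starts[j]:ends[j], drop = FALSE])
  })
}

ad_permute_rows <- function(X, perm) {
  Xv <- ad_val(X)
  y <- Xv[perm, , drop = FALSE]
  if (!.fd_ad$on || !ad_is_node(X)) return(y)
  inv <- integer(length(perm))
  inv[perm] <- seq_along(perm)
  ad_op(y, list(X), function(g) list(g[inv, , drop = FALSE]))
}

## ---- pair-tensor ops -------------------------------------------------------
# Pair tensors are stored flat as (N*N) x C matrices with column-major pair
# index f = i + (j-1)*N for the ordered pair (i, j): matrix(p[, c], N, N)
# recovers the N x N slice of channel c with [i, j] indexing.

pair_flat_index <- function(i, j, N) i + (j - 1L) * N

# Low-rank outer product: out[f(i,j), (a-1)*cb+b] = U[i,a] * V[j,b].
ad_outer_pair <- function(U, V) {
  Uv <- ad_val(U); Vv <- ad_val(V)
  N <- nrow(Uv); ca <- ncol(Uv); cb <- ncol(Vv)
  ri <- rep(seq_len(N), times = N)
  rj <- rep(seq_len(N), each = N)
  a_idx <- rep(seq_len(ca), each = cb)
  b_idx <- rep(seq_len(cb), times = ca)
  OU <- Uv[ri, a_idx, drop = FALSE]
  OV <- Vv[rj, b_idx, drop = FALSE]
  y <- OU * OV
  if (!.fd_ad$on || !.ad_any_node(U, V)) return(y)
  ad_op(y, list(U, V), function(g) {
    dOU <- g * OV
    dOV <- g * OU
    Mu <- rowsum(dOU, ri)
    Mv <- rowsum(dOV, rj)
    dU <- t(rowsum(t(Mu), a_idx))
    dV <- t(rowsum(t(Mv), b_idx))
    list(dU, dV)
  })
}

# Additive broadcast into the pair layout: y[f(i,j), ] = U[i, ] + V[j, ].
ad_pair_broadcast <- function(U, V) {
  Uv <- ad_val(U); Vv <- ad_val(V)
  N <- nrow(Uv)
  ri <- rep(seq_len(N), times = N)
  rj <- rep(seq_len(N), each = N)
  y <- Uv[ri, , drop = FALSE] + Vv[rj, , drop = FALSE]
  if (!.fd_ad$on || !.ad_any_node(U, V)) return(y)
  ad_op(y, list(U, V), function(g) {
    list(rowsum(g, ri), rowsum(g, rj))
  })
}

# y = Z with y[rows, ] <- Z[rows, ] + Y (rows unique).
ad_add_rows_subset <- function(Z, rows, Y) {
  Zv <- ad_val(Z); Yv <- ad_val(Y)
  y <- Zv
  y[rows, ] <- y[rows, , drop = FALSE] + Yv
  if (!.fd_ad$on || !.ad_any_node(Z, Y)) return(y)
  ad_op(y, list(Z, Y), function(g) {
    list(g, g[rows, , drop = FALSE])
  })
}

# Triangle multiplicative update core.
#   mode "out": o(i,j,c) = sum_k a(i,k,c) b(j,k,c)   ("outgoing" edges)
#   mode "in" : o(i,j,c) = sum_k a(k,i,c) b(k,j,c)   ("incoming" edges)
ad_tri_mul <- function(A, B, N, mode = c("out", "in")) {
  mode <- match.arg(mode)
  Av <- ad_val(A); Bv <- ad_val(B)
  C <- ncol(Av)
  y <- matrix(0, N * N, C)
  for (c in seq_len(C)) {
    Ac <- matrix(Av[, c], N, N)
    Bc <- matrix(Bv[, c], N, N)
    Oc <- if (mode == "out") Ac %*% t(Bc) else t(Ac) %*% Bc
    y[, c] <- as.vector(Oc)
  }
  if (!.fd_ad$on || !.ad_any_node(A, B)) return(y)
  ad_op(y, list(A, B), function(g) {
    dA <- matrix(0, N * N, C)
    dB <- matrix(0, N * N, C)
    for (c in seq_len(C)) {
      Ac <- matrix(Av[, c], N, N)
      Bc <- matrix(Bv[, c], N, N)
      Gc <- matrix(g[, c], N, N)
      if (mode == "out") {
        dA[, c] <- as.vector(Gc %*% Bc)
        dB[, c] <- as.vector(t(Gc) %*% Ac)
      } else {
        dA[, c] <- as.vector(Bc %*% t(Gc))
        dB[, c] <- as.vector(Ac %*% Gc)
      }
    }
    list(dA, dB)
  })
}

## ---- fused attention ops ---------------------------------------------------

# Multi-head attention. Q: Nq x (h*dq); K: Nk x (h*dq); V: Nk x (h*dv);
# bias: optional (Nq*Nk) x h (column-major pair flat, query index fast).
ad_mha <- function(Q, K, V, h, bias = NULL) {
  Qv <- ad_val(Q); Kv <- ad_val(K); Vv <- ad_val(V)
  Bv <- if (is.null(bias)) NULL else ad_val(bias)
  nq <- nrow(Qv); nk <- nrow(Kv)
  dq <- ncol(Qv) %/% h; dv <- ncol(Vv) %/% h
  scale <- 1 / sqrt(dq)
  out <- matrix(0, nq, h * dv)
  As <- vector("list", h)
  for (hh in seq_len(h)) {
    qc <- ((hh - 1L) * dq + 1L):(hh * dq)
    vc <- ((hh - 1L) * dv + 1L):(hh * dv)
    L <- (Qv[, qc, drop = FALSE] %*% t(Kv[, qc, drop = FALSE])) * scale
    if (!is.null(Bv)) L <- L + matrix(Bv[, hh], nq, nk)
    m <- .row_max(L)
    E <- exp(L - m)
    A <- E / rowSums(E)
    As[[hh]] <- A
    out[, vc] <- A %*% Vv[, vc, drop = FALSE]
  }
  if (!.fd_ad$on || !.ad_any_node(Q, K, V, bias)) return(out)
  ad_op(out, list(Q, K, V, bias), function(g) {
    dQ <- matrix(0, nq, h * dq); dK <- matrix(0, nk, h * dq)
    dV <- matrix(0, nk, h * dv)
    dB <- if (is.null(Bv)) NULL else matrix(0, nq * nk, h)
    for (hh in seq_len(h)) {
      qc <- ((hh - 1L) * dq + 1L):(hh * dq)
      vc <- ((hh - 1L) * dv + 1L):(hh * dv)
      A <- As[[hh]]
      Gh <- g[, vc, drop = FALSE]
      dA <- Gh %*% t(Vv[, vc, drop = FALSE])
      dV[, vc] <- t(A) %*% Gh
      dL <- A * (dA - rowSums(dA * A))
      dQ[, qc] <- (dL %*% Kv[, qc, drop = FALSE]) * scale
      dK[, qc] <- (t(dL) %*% Qv[, qc, drop = FALSE]) * scale
      if (!is.null(dB)) dB[, hh] <- as.vector(dL)
    }
    list(dQ, dK, dV, dB)
  })
}

# Triangle attention around the starting node on a pair tensor.
# Q, K, V: (N*N) x (h*d) pair-flat; bias: (N*N) x h giving b(j,k) slices.
# out(i,j) attends over k: logits = q(i,j).k(i,k)/sqrt(d) + b(j,k).
ad_tri_attn <- function(Q, K, V, bias, h, N) {
  Qv <- ad_val(Q); Kv <- ad_val(K); Vv <- ad_val(V); Bv <- ad_val(bias)
  d <- ncol(Qv) %/% h
  scale <- 1 / sqrt(d)
  out <- matrix(0, N * N, ncol(Vv))
  As <- vector("list", N * h)
  rows_i <- lapply(seq_len(N), function(i) seq(i, N * N, by = N))
  Bh <- lapply(seq_len(h), function(hh) matrix(Bv[, hh], N, N))
  for (i in seq_len(N)) {
    ri <- rows_i[[i]]
    for (hh in seq_len(h)) {
      cc <- ((hh - 1L) * d + 1L):(hh * d)
      L <- (Qv[ri, cc, drop = FALSE] %*% t(Kv[ri, cc, drop = FALSE])) * scale +
        Bh[[hh]]
      m <- .row_max(L)
      E <- exp(L - m)
      A <- E / rowSums(E)
      As[[(i - 1L) * h + hh]] <- A
      out[ri, cc] <- A %*% Vv[ri, cc, drop = FALSE]
    }
  }
  if (!.fd_ad$on || !.ad_any_node(Q, K, V, bias)) return(out)
  ad_op(out, list(Q, K, V, bias), function(g) {
    dQ <- matrix(0, N * N, ncol(Qv)); dK <- dQ
    dV <- matrix(0, N * N, ncol(Vv))
    dBh <- lapply(seq_len(h), function(hh) matrix(0, N, N))
    for (i in seq_len(N)) {
      ri <- rows_i[[i]]
      for (hh in seq_len(h)) {
        cc <- ((hh - 1L) * d + 1L):(hh * d)
        A <- As[[(i - 1L) * h + hh]]
        Gh <- g[ri, cc, drop = FALSE]
        dA <- Gh %*% t(Vv[ri, cc, drop = FALSE])
        dV[ri, cc] <- dV[ri, cc] + t(A) %*% Gh
        dL <- A * (dA - rowSums(dA * A))
        dQ[ri, cc] <- dQ[ri, cc] + (dL %*% Kv[ri, cc, drop = FALSE]) * scale
        dK[ri, cc] <- dK[ri, cc] + (t(dL) %*% Qv[ri, cc, drop = FALSE]) * scale
        dBh[[hh]] <- dBh[[hh]] + dL
      }
    }
    dB <- do.call(cbind, lapply(dBh, as.vector))
    list(dQ, dK, dV, dB)
  })
}

## ---- structure-module and loss ops ----------------------------------------

# Apply per-atom frame updates. raw: N x 6 (cols 1:3 quaternion vector part,
# cols 4:6 local-frame translation, scaled by `scale` Angstrom). Rotations
# are composed numerically and treated as constants downstream (rotation
# gradients are stopped); translations are differentiated.
# Returns list(t = node/numeric N x 3, R = 3x3xN numeric).
ad_frame_update <- function(t_old, R_old, raw, scale) {
  tv <- ad_val(t_old); rv <- ad_val(raw)
  N <- nrow(tv)
  delta <- rv[, 4:6, drop = FALSE] * scale
  gdelta <- .ipa_to_global(delta, R_old, NULL)   # R_i %*% delta_i per row
  t_new <- tv + gdelta
  R_new <- array(0, c(3, 3, N))
  for (i in seq_len(N)) {
    R_new[, , i] <- R_old[, , i] %*% quat_to_rotation(rv[i, 1:3])
  }
  if (!.fd_ad$on || !.ad_any_node(t_old, raw)) {
    return(list(t = t_new, R = R_new))
  }
  nd <- ad_op(t_new, list(t_old, raw), function(g) {
    draw <- matrix(0, N, 6)
    draw[, 4:6] <- .ipa_to_local(g, R_old, NULL) * scale
    list(g, draw)
  })
  list(t = nd, R = R_new)
}

# Frame-aligned point error over a set of alignment frames.
# X: n_pts x 3 predicted points. Rf: 3x3xNf predicted frame rotations
# (constant; rotation gradients stopped). Frame origins either rows of X
# (origin_idx, the ligand-frame case where each frame sits on an atom) or a
# constant matrix (origin_const, the residue-frame case).
# target_local: Nf x n_pts x 3 array of target points expressed in the
# target frames. Loss = mean over frames and points of the clamped
# point distance, divided by `scale`.
ad_fape <- function(X, Rf, target_local, clamp, scale,
                    origin_idx = NULL, origin_const = NULL) {
  Xv <- ad_val(X)
  Nf <- dim(Rf)[3]
  np <- nrow(Xv)
  tot <- 0
  for (f in seq_len(Nf)) {
    tf <- if (is.null(origin_idx)) origin_const[f, ] else Xv[origin_idx[f], ]
    L <- sweep(Xv, 2, tf) %*% Rf[, , f]
    E <- L - target_local[f, , ]
    d <- sqrt(rowSums(E * E))
    tot <- tot + sum(pmin(d, clamp))
  }
  y <- tot / (Nf * np * scale)
  if (!.fd_ad$on || !ad_is_node(X)) return(y)
  ad_op(y, list(X), function(g) {
    dX <- matrix(0, np, 3)
    for (f in seq_len(Nf)) {
      tf <- if (is.null(origin_idx)) origin_const[f, ] else Xv[origin_idx[f], ]
      L <- sweep(Xv, 2, tf) %*% Rf[, , f]
      E <- L - target_local[f, , ]
      d <- sqrt(rowSums(E * E))
      w <- as.numeric(d < clamp & d > 1e-12) / pmax(d, 1e-12)
      Gl <- (g / (Nf * np * scale)) * w * E
      Gg <- Gl %*% t(Rf[, , f])
      dX <- dX + Gg
      if (!is.null(origin_idx)) {
        dX[origin_idx[f], ] <- dX[origin_idx[f], ] - colSums(Gg)
      }
    }
    list(dX)
  })
}

# Kabsch RMSD with envelope-theorem gradient (the optimal rotation is
# treated as fixed at the optimum when differentiating).
ad_kabsch_rmsd <- function(X, target) {
  Xv <- ad_val(X)
  kb <- .kabsch_core(Xv, target)
  y <- kb$rmsd
  if (!.fd_ad$on || !ad_is_node(X)) return(y)
  n <- nrow(Xv)
  ad_op(y, list(X), function(g) {
    if (kb$rmsd < 1e-9) return(list(matrix(0, n, 3)))
    # u_i = R (x_i - cx) - (y_i - cy); dr/dx_i = R^T u_i / (n r)
    U <- kb$pc %*% t(kb$R) - kb$qc
    list(g * (U %*% kb$R) / (n * kb$rmsd))
  })
}

## ---- invariant point attention (fused) ------------------------------------

# Rotate local point columns (N x (m*3), xyz fastest) into the global frame:
# for atom i, block p: out = R[,,i] %*% pt + t[i,]. `t` may be NULL.
.ipa_to_global <- function(P, R, t) {
  m <- ncol(P) %/% 3L
  xs <- seq(1L, 3L * m, by = 3L)
  lx <- P[, xs, drop = FALSE]; ly <- P[, xs + 1L, drop = FALSE]
  lz <- P[, xs + 2L, drop = FALSE]
  gx <- R[1, 1, ] * lx + R[1, 2, ] * ly + R[1, 3, ] * lz
  gy <- R[2, 1, ] * lx + R[2, 2, ] * ly + R[2, 3, ] * lz
  gz <- R[3, 1, ] * lx + R[3, 2, ] * ly + R[3, 3, ] * lz
  if (!is.null(t)) { gx <- gx + t[, 1]; gy <- gy + t[, 2]; gz <- gz + t[, 3] }
  out <- matrix(0, nrow(P), ncol(P))
  out[, xs] <- gx; out[, xs + 1L] <- gy; out[, xs + 2L] <- gz
  out
}

# Inverse: local = R^T (global - t).
.ipa_to_local <- function(P, R, t) {
  m <- ncol(P) %/% 3L
  xs <- seq(1L, 3L * m, by = 3L)
  gx <- P[, xs, drop = FALSE]; gy <- P[, xs + 1L, drop = FALSE]
  gz <- P[, xs + 2L, drop = FALSE]
  if (!is.null(t)) { gx <- gx - t[, 1]; gy <- gy - t[, 2]; gz <- gz - t[, 3] }
  lx <- R[1, 1, ] * gx + R[2, 1, ] * gy + R[3, 1, ] * gz
  ly <- R[1, 2, ] * gx + R[2, 2, ] * gy + R[3, 2, ] * gz
  lz <- R[1, 3, ] * gx + R[2, 3, ] * gy + R[3, 3, ] * gz
  out <- matrix(0, nrow(P), ncol(P))
  out[, xs] <- lx; out[, xs + 1L] <- ly; out[, xs + 2L] <- lz
  out
}

# Gated invariant point attention core (everything between the input linears
# and the output projection). Frames' rotations R (3x3xN) are treated as
# constants (rotation gradients are stopped); translations t (N x 3) are
# differentiated. Inputs:
#   q, k : N x (h*dq)       scalar queries/keys
#   v    : N x (h*dv)       scalar values
#   qp,kp: N x (h*npq*3)    query/key points, local frames
#   vp   : N x (h*npv*3)    value points, local frames
#   bias : (N*N) x h        pair-derived logit bias, pair-flat
#   z    : (N*N) x cz       pair values attended into the output
#   gamma_raw: h            per-head point-weight (softplus applied here)
# Output columns: [scalar h*dv | pair h*cz | points-local h*npv*3 | norms h*npv]
ad_ipa_core <- function(q, k, v, qp, kp, vp, bias, z, gamma_raw, R, t, h) {
  qv <- ad_val(q); kv <- ad_val(k); vv <- ad_val(v)
  qpv <- ad_val(qp); kpv <- ad_val(kp); vpv <- ad_val(vp)
  Bv <- ad_val(bias); zv <- ad_val(z); grv <- ad_val(gamma_raw)
  tv <- ad_val(t)
  N <- nrow(qv)
  dq <- ncol(qv) %/% h; dv_ <- ncol(vv) %/% h
  npq <- ncol(qpv) %/% (3L * h); npv <- ncol(vpv) %/% (3L * h)
  cz <- ncol(zv)
  gam <- log1p(exp(grv))
  wL <- sqrt(1 / 3)
  wC <- sqrt(2 / (9 * npq))
  scale <- 1 / sqrt(dq)
  eps <- 1e-8

  QG <- .ipa_to_global(qpv, R, tv)
  KG <- .ipa_to_global(kpv, R, tv)
  VG <- .ipa_to_global(vpv, R, tv)

  rows_of_i <- lapply(seq_len(N), function(i) seq(i, N * N, by = N))

  out_sc <- matrix(0, N, h * dv_)
  out_pr <- matrix(0, N, h * cz)
  OGall <- matrix(0, N, h * npv * 3L)
  As <- vector("list", h)
  D2s <- vector("list", h)
  for (hh in seq_len(h)) {
    qc <- ((hh - 1L) * dq + 1L):(hh * dq)
    vc <- ((hh - 1L) * dv_ + 1L):(hh * dv_)
    pc <- (((hh - 1L) * npq) * 3L + 1L):((hh * npq) * 3L)
    pvc <- (((hh - 1L) * npv) * 3L + 1L):((hh * npv) * 3L)
    Ah <- QG[, pc, drop = FALSE]
    Bh <- KG[, pc, drop = FALSE]
    ra <- rowSums(Ah * Ah)
    rb <- rowSums(Bh * Bh)
    D2 <- matrix(ra, N, N) + matrix(rb, N, N, byrow = TRUE) - 2 * (Ah %*% t(Bh))
    D2s[[hh]] <- D2
    L <- wL * ((qv[, qc, drop = FALSE] %*% t(kv[, qc, drop = FALSE])) * scale +
                 matrix(Bv[, hh], N, N) - (gam[hh] * wC / 2) * D2)
    m <- .row_max(L)
    E <- exp(L - m)
    A <- E / rowSums(E)
    As[[hh]] <- A
    out_sc[, vc] <- A %*% vv[, vc, drop = FALSE]
    OGall[, pvc] <- A %*% VG[, pvc, drop = FALSE]
    zc <- ((hh - 1L) * cz + 1L):(hh * cz)
    for (i in seq_len(N)) {
      out_pr[i, zc] <- A[i, ] %*% zv[rows_of_i[[i]], , drop = FALSE]
    }
  }
  OL <- .ipa_to_local(OGall, R, tv)
  m3 <- ncol(OL) %/% 3L
  xs <- seq(1L, 3L * m3, by = 3L)
  nrm <- sqrt(OL[, xs, drop = FALSE]^2 + OL[, xs + 1L, drop = FALSE]^2 +
                OL[, xs + 2L, drop = FALSE]^2 + eps)
  out <- cbind(out_sc, out_pr, OL, nrm)
  if (!.fd_ad$on || !.ad_any_node(q, k, v, qp, kp, vp, bias, z, gamma_raw, t)) {
    return(out)
  }
  ad_op(out, list(q, k, v, qp, kp, vp, bias, z, gamma_raw, t), function(g) {
    c_sc <- h * dv_; c_pr <- h * cz; c_pt <- h * npv * 3L
    g_sc <- g[, seq_len(c_sc), drop = FALSE]
    g_pr <- g[, c_sc + seq_len(c_pr), drop = FALSE]
    g_pt <- g[, c_sc + c_pr + seq_len(c_pt), drop = FALSE]
    g_nr <- g[, c_sc + c_pr + c_pt + seq_len(h * npv), drop = FALSE]
    # norm -> local points
    dOL <- g_pt
    dOL[, xs] <- dOL[, xs] + g_nr * OL[, xs, drop = FALSE] / nrm
    dOL[, xs + 1L] <- dOL[, xs + 1L] + g_nr * OL[, xs + 1L, drop = FALSE] / nrm
    dOL[, xs + 2L] <- dOL[, xs + 2L] + g_nr * OL[, xs + 2L, drop = FALSE] / nrm
    # local = R^T (OG - t): dOG = R dOL ; dt -= sum over points of dOG
    dOG <- .ipa_to_global(dOL, R, NULL)
    dt <- matrix(0, N, 3L)
    for (p in seq_len(m3)) {
      dt <- dt - dOG[, (3L * (p - 1L) + 1L):(3L * p), drop = FALSE]
    }
    dq_ <- matrix(0, N, h * dq); dk_ <- dq_
    dv2 <- matrix(0, N, h * dv_)
    dQG <- matrix(0, N, h * npq * 3L); dKG <- dQG
    dVG <- matrix(0, N, h * npv * 3L)
    dB <- matrix(0, N * N, h)
    dz <- matrix(0, N * N, cz)
    dgr <- numeric(h)
    for (hh in seq_len(h)) {
      qc <- ((hh - 1L) * dq + 1L):(hh * dq)
      vc <- ((hh - 1L) * dv_ + 1L):(hh * dv_)
      pc <- (((hh - 1L) * npq) * 3L + 1L):((hh * npq) * 3L)
      pvc <- (((hh - 1L) * npv) * 3L + 1L):((hh * npv) * 3L)
      zc <- ((hh - 1L) * cz + 1L):(hh * cz)
      A <- As[[hh]]
      dA <- g_sc[, vc, drop = FALSE] %*% t(vv[, vc, drop = FALSE])
      dv2[, vc] <- t(A) %*% g_sc[, vc, drop = FALSE]
      dA <- dA + dOG[, pvc, drop = FALSE] %*% t(VG[, pvc, drop = FALSE])
      dVG[, pvc] <- t(A) %*% dOG[, pvc, drop = FALSE]
      for (i in seq_len(N)) {
        ri <- rows_of_i[[i]]
        Zi <- zv[ri, , drop = FALSE]
        gpi <- g_pr[i, zc]
        dA[i, ] <- dA[i, ] + as.vector(Zi %*% gpi)
        dz[ri, ] <- dz[ri, ] + outer(A[i, ], gpi)
      }
      dL <- A * (dA - rowSums(dA * A))
      dq_[, qc] <- (dL %*% kv[, qc, drop = FALSE]) * scale * wL
      dk_[, qc] <- (t(dL) %*% qv[, qc, drop = FALSE]) * scale * wL
      dB[, hh] <- as.vector(dL) * wL
      cD2 <- -wL * gam[hh] * wC / 2
      dD2 <- dL * cD2
      dgam <- (-wL * wC / 2) * sum(dL * D2s[[hh]])
      dgr[hh] <- dgam * (1 / (1 + exp(-grv[hh])))
      Ah <- QG[, pc, drop = FALSE]
      Bh <- KG[, pc, drop = FALSE]
      dQG[, pc] <- 2 * Ah * rowSums(dD2) - 2 * (dD2 %*% Bh)
      dKG[, pc] <- 2 * Bh * colSums(dD2) - 2 * (t(dD2) %*% Ah)
    }
    # global points back to local params and translations
    dqp <- .ipa_to_local(dQG, R, NULL)
    dkp <- .ipa_to_local(dKG, R, NULL)
    dvp <- .ipa_to_local(dVG, R, NULL)
    for (p in seq_len(ncol(dQG) %/% 3L)) {
      cols <- (3L * (p - 1L) + 1L):(3L * p)
      dt <- dt + dQG[, cols, drop = FALSE] + dKG[, cols, drop = FALSE]
    }
    for (p in seq_len(ncol(dVG) %/% 3L)) {
      cols <- (3L * (p - 1L) + 1L):(3L * p)
      dt <- dt + dVG[, cols, drop = FALSE]
    }
    list(dq_, dk_, dv2, dqp, dkp, dvp, dB, dz, dgr, dt)
  })
}
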