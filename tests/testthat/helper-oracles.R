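# Shared test utilities: independent oracles and a finite-difference
# gradient checker. Everything here is deliberately written without reusing
# the package's own implementation paths.

# Finite-difference gradient check for one input of a tape op. `fn` maps a
# plain array to a scalar-valued op output; returns max relative error.
fd_gradcheck <- function(fn, x, eps = 1e-5) {
  framedock:::ad_tape_start()
  xn <- framedock:::ad_leaf(x)
  loss <- fn(xn)
  framedock:::ad_backward(loss)
  g <- xn$grad
  framedock:::ad_tape_stop()
  if (is.null(g)) g <- x * 0
  gn <- x
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + eps
    xm[i] <- xm[i] - eps
    gn[i] <- (framedock:::ad_val(fn(xp)) - framedock:::ad_val(fn(xm))) / (2 * eps)
  }
  max(abs(g - gn)) / max(1e-4, max(abs(gn)))
}

# Independent Gram-Schmidt frame oracle with explicit normalize/project
# steps (vector-by-vector, no shared code with the package).
oracle_frame <- function(center, left, right) {
  normalize <- function(v) v / sqrt(sum(v^2))
  e1 <- normalize(right - center)
  proj <- function(v, u) sum(v * u) * u
  e2 <- normalize((left - center) - proj(left - center, e1))
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  list(R = cbind(e1, e2, e3, deparse.level = 0), t = center)
}

# Horn's quaternion method for optimal superposition RMSD: an algorithm
# independent of the SVD route used in the package.
oracle_superpose_rmsd <- function(pred, target) {
  P <- sweep(pred, 2, colMeans(pred))
  Q <- sweep(target, 2, colMeans(target))
  S <- t(P) %*% Q
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lam <- max(eigen(K, symmetric = TRUE)$values)
  ss <- sum(P^2) + sum(Q^2) - 2 * lam
  sqrt(max(0, ss) / nrow(P))
}

# Brute-force automorphism enumeration over all permutations (small n):
# element-, charge- and bond-order-preserving.
oracle_automorphisms <- function(lig) {
  n <- length(lig$elements)
  A <- matrix(0L, n, n)
  if (nrow(lig$bonds) > 0L) {
    A[lig$bonds[, 1:2, drop = FALSE]] <- lig$bonds[, 3]
    A[lig$bonds[, 2:1, drop = FALSE]] <- lig$bonds[, 3]
  }
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  keep <- list()
  for (p in perms(seq_len(n))) {
    if (any(lig$elements[p] != lig$elements) ||
        any(lig$charges[p] != lig$charges)) next
    if (all(A[p, p] == A)) keep[[length(keep) + 1L]] <- p
  }
  keep
}

random_rigid <- function() {
  rigid_transform(framedock:::quat_to_rotation(stats::rnorm(3)),
                  stats::rnorm(3, sd = 5))
}

# Small cached fixture complex shared across test files.
.test_cache <- new.env(parent = emptyenv())
tiny_complex <- function() {
  if (is.null(.test_cache$cx)) {
    .test_cache$cx <- make_complex(seed = 42, n_residues = 15L,
                                   n_lig_atoms = 6L)
  }
  .test_cache$cx
}

tiny_cfg <- function() fd_config("tiny")

tiny_params <- function() {
  if (is.null(.test_cache$params)) {
    .test_cache$params <- init_params(tiny_cfg(), seed = 5)
  }
  .test_cache$params
}
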