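# Gradient correctness of the differentiation engine: every fused op's
# hand-derived backward pass is checked against central finite differences.

test_that("elementwise and linear ops backpropagate correctly", {
  withr::with_seed(1, {
    X <- matrix(rnorm(12), 4, 3)
    W <- matrix(rnorm(9), 3, 3)
    C1 <- matrix(rnorm(12), 4, 3)
    g1 <- rnorm(3); b1 <- rnorm(3)
    ad <- asNamespace("framedock")
    expect_lt(fd_gradcheck(function(x)
      ad$ad_sum(ad$ad_linear(x, W, b1)), X), 1e-6)
    expect_lt(fd_gradcheck(function(x)
      ad$ad_sum(ad$ad_mul(ad$ad_softmax_rows(x), C1)), X), 1e-6)
    expect_lt(fd_gradcheck(function(x)
      ad$ad_sum(ad$ad_mul(ad$ad_layernorm(x, g1, b1), C1)), X), 1e-6)
    expect_lt(fd_gradcheck(function(x)
      ad$ad_sum(ad$ad_mul(ad$ad_relu(x), C1)), X + 0.1), 1e-6)
    expect_lt(fd_gradcheck(function(x)
      ad$ad_sum(ad$ad_mul(ad$ad_sigmoid(x), C1)), X), 1e-6)
  })
})

test_that("pair-layout ops backpropagate correctly", {
  withr::with_seed(2, {
    ad <- asNamespace("framedock")
    X <- matrix(rnorm(12), 4, 3)
    U <- matrix(rnorm(8), 4, 2)
    C2 <- matrix(rnorm(16 * 6), 16, 6)
    expect_lt(fd_gradcheck(function(x)
      ad$ad_sum(ad$ad_mul(ad$ad_outer_pair(x, U), C2)), X), 1e-6)
    V3 <- matrix(rnorm(12), 4, 3)
    C2b <- matrix(rnorm(16 * 3), 16, 3)
    expect_lt(fd_gradcheck(function(x)
      ad$ad_sum(ad$ad_mul(ad$ad_pair_broadcast(x, V3), C2b)), X), 1e-6)
    P <- matrix(rnorm(32), 16, 2)
    C3 <- matrix(rnorm(32), 16, 2)
    Y <- matrix(rnorm(32), 16, 2)
    for (mode in c("out", "in")) {
      expect_lt(fd_gradcheck(function(x)
        ad$ad_sum(ad$ad_mul(ad$ad_tri_mul(x, P, 4, mode), C3)), Y), 1e-6)
      expect_lt(fd_gradcheck(function(x)
        ad$ad_sum(ad$ad_mul(ad$ad_tri_mul(P, x, 4, mode), C3)), Y), 1e-6)
    }
  })
})

test_that("attention ops backpropagate correctly", {
  withr::with_seed(3, {
    ad <- asNamespace("framedock")
    Q <- matrix(rnorm(16), 4, 4); K <- matrix(rnorm(16), 4, 4)
    V <- matrix(rnorm(16), 4, 4); B <- matrix(rnorm(32), 16, 2)
    CM <- matrix(rnorm(16), 4, 4)
    expect_lt(fd_gradcheck(function(x)
      ad$ad_sum(ad$ad_mul(ad$ad_mha(x, K, V, 2, B), CM)), Q), 1e-6)
    expect_lt(fd_gradcheck(function(x)
      ad$ad_sum(ad$ad_mul(ad$ad_mha(Q, x, V, 2, B), CM)), K), 1e-6)
    expect_lt(fd_gradcheck(function(x)
      ad$ad_sum(ad$ad_mul(ad$ad_mha(Q, K, x, 2, B), CM)), V), 1e-6)
    expect_lt(fd_gradcheck(function(x)
      ad$ad_sum(ad$ad_mul(ad$ad_mha(Q, K, V, 2, x), CM)), B), 1e-6)
    Q2 <- matrix(rnorm(36), 9, 4); K2 <- matrix(rnorm(36), 9, 4)
    V2 <- matrix(rnorm(36), 9, 4); B2 <- matrix(rnorm(18), 9, 2)
    C4 <- matrix(rnorm(36), 9, 4)
    expect_lt(fd_gradcheck(function(x)
      ad$ad_sum(ad$ad_mul(ad$ad_tri_attn(x, K2, V2, B2, 2, 3), C4)), Q2), 1e-6)
    expect_lt(fd_gradcheck(function(x)
      ad$ad_sum(ad$ad_mul(ad$ad_tri_attn(Q2, K2, V2, x, 2, 3), C4)), B2), 1e-6)
  })
})

test_that("the fused IPA core backpropagates to every differentiable input", {
  withr::with_seed(4, {
    ad <- asNamespace("framedock")
    N <- 5; h <- 2; dq <- 3; dv <- 3; npq <- 2; npv <- 2; cz <- 4
    q <- matrix(rnorm(N * h * dq), N); k <- matrix(rnorm(N * h * dq), N)
    v <- matrix(rnorm(N * h * dv), N)
    qp <- matrix(rnorm(N * h * npq * 3), N); kp <- matrix(rnorm(N * h * npq * 3), N)
    vp <- matrix(rnorm(N * h * npv * 3), N)
    B <- matrix(rnorm(N * N * h), N * N, h)
    Z <- matrix(rnorm(N * N * cz), N * N, cz)
    gam <- rnorm(h)
    R <- array(0, c(3, 3, N))
    for (i in 1:N) R[, , i] <- ad$quat_to_rotation(rnorm(3))
    tt <- matrix(rnorm(N * 3, sd = 2), N, 3)
    ow <- h * dv + h * cz + h * npv * 3 + h * npv
    CM <- matrix(rnorm(N * ow), N, ow)
    f <- function(q1, k1, v1, qp1, kp1, vp1, B1, Z1, g1, t1) {
      ad$ad_sum(ad$ad_mul(
        ad$ad_ipa_core(q1, k1, v1, qp1, kp1, vp1, B1, Z1, g1, R, t1, h), CM))
    }
    expect_lt(fd_gradcheck(function(x) f(x, k, v, qp, kp, vp, B, Z, gam, tt), q), 1e-5)
    expect_lt(fd_gradcheck(function(x) f(q, x, v, qp, kp, vp, B, Z, gam, tt), k), 1e-5)
    expect_lt(fd_gradcheck(function(x) f(q, k, x, qp, kp, vp, B, Z, gam, tt), v), 1e-5)
    expect_lt(fd_gradcheck(function(x) f(q, k, v, x, kp, vp, B, Z, gam, tt), qp), 1e-5)
    expect_lt(fd_gradcheck(function(x) f(q, k, v, qp, x, vp, B, Z, gam, tt), kp), 1e-5)
    expect_lt(fd_gradcheck(function(x) f(q, k, v, qp, kp, x, B, Z, gam, tt), vp), 1e-5)
    expect_lt(fd_gradcheck(function(x) f(q, k, v, qp, kp, vp, x, Z, gam, tt), B), 1e-5)
    expect_lt(fd_gradcheck(function(x) f(q, k, v, qp, kp, vp, B, x, gam, tt), Z), 1e-5)
    expect_lt(fd_gradcheck(function(x) f(q, k, v, qp, kp, vp, B, Z, x, tt), gam), 1e-5)
    expect_lt(fd_gradcheck(function(x) f(q, k, v, qp, kp, vp, B, Z, gam, x), tt), 1e-5)
  })
})

test_that("frame update, FAPE and Kabsch ops backpropagate correctly", {
  withr::with_seed(5, {
    ad <- asNamespace("framedock")
    N <- 5
    R <- array(0, c(3, 3, N))
    for (i in 1:N) R[, , i] <- ad$quat_to_rotation(rnorm(3))
    tt <- matrix(rnorm(N * 3), N, 3)
    raw <- matrix(rnorm(N * 6), N, 6)
    CM2 <- matrix(rnorm(N * 3), N, 3)
    fu <- function(t1, raw1) {
      r <- ad$ad_frame_update(t1, R, raw1, 2.5)
      ad$ad_sum(ad$ad_mul(r$t, CM2))
    }
    expect_lt(fd_gradcheck(function(x) fu(x, raw), tt), 1e-6)
    # translation columns of the raw update get exact gradients
    framedock:::ad_tape_start()
    rn <- framedock:::ad_leaf(raw)
    L <- fu(tt, rn)
    framedock:::ad_backward(L)
    gr <- rn$grad
    framedock:::ad_tape_stop()
    eps <- 1e-5
    gn <- raw * 0
    for (i in seq_along(raw)) {
      rp <- raw; rm <- raw
      rp[i] <- rp[i] + eps; rm[i] <- rm[i] - eps
      gn[i] <- (framedock:::ad_val(fu(tt, rp)) -
                  framedock:::ad_val(fu(tt, rm))) / (2 * eps)
    }
    expect_lt(max(abs((gr - gn)[, 4:6])), 1e-6)

    Nf <- 3; np <- 6
    Rf <- array(0, c(3, 3, Nf))
    for (i in 1:Nf) Rf[, , i] <- ad$quat_to_rotation(rnorm(3))
    TL <- array(rnorm(Nf * np * 3), c(Nf, np, 3))
    oc <- matrix(rnorm(Nf * 3), Nf, 3)
    Xc <- matrix(rnorm(np * 3, sd = 2), np, 3)
    expect_lt(fd_gradcheck(function(x)
      ad$ad_fape(x, Rf, TL, 10, 10, origin_const = oc), Xc), 1e-5)
    expect_lt(fd_gradcheck(function(x)
      ad$ad_fape(x, Rf, TL, 10, 10, origin_idx = c(1L, 3L, 5L)), Xc), 1e-5)

    Yt <- matrix(rnorm(np * 3), np, 3)
    expect_lt(fd_gradcheck(function(x) ad$ad_kabsch_rmsd(x, Yt), Xc), 1e-5)
  })
})

test_that("ops return plain numerics when the tape is off", {
  ad <- asNamespace("framedock")
  expect_false(ad$ad_tape_active())
  x <- matrix(1:6, 2, 3)
  expect_true(is.matrix(ad$ad_add(x, x)))
  expect_false(is.environment(ad$ad_softmax_rows(x * 1.0)))
})
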