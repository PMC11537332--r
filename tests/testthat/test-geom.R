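# Rigid-transform algebra and frame construction.

test_that("frame construction from three points matches the Gram-Schmidt contract", {
  f <- frame_from_three_points(frame_anchors(
    center = c(0, 0, 0), left = c(0, 1, 0), right = c(1, 0, 0)))
  expect_equal(f$R, diag(3), tolerance = 1e-12)
  expect_equal(f$t, c(0, 0, 0))

  # scale invariance: magnitudes of the anchor offsets do not matter
  f2 <- frame_from_three_points(frame_anchors(
    center = c(0, 0, 0), left = c(0, 3, 0), right = c(2, 0, 0)))
  expect_equal(f2$R, f$R, tolerance = 1e-12)

  # independent Gram-Schmidt oracle on a slanted triple
  ctr <- c(1, 1, 1)
  rgt <- c(1 + cos(40 * pi / 180), 1 + sin(40 * pi / 180), 1)
  lft <- c(0, 1, 1)
  f3 <- frame_from_three_points(frame_anchors(ctr, left = lft, right = rgt))
  o <- oracle_frame(ctr, lft, rgt)
  expect_equal(f3$R, o$R, tolerance = 1e-12)
  expect_equal(f3$t, o$t)
})

test_that("degenerate anchor geometries are rejected with the atom index", {
  expect_error(frame_from_three_points(frame_anchors(
    c(0, 0, 0), left = c(2, 0, 0), right = c(1, 0, 0), index = 7L)),
    class = "fd_degenerate_geometry")
  expect_error(frame_from_three_points(frame_anchors(
    c(0, 0, 0), left = c(0, 0, 0), right = c(1, 0, 0), index = 3L)),
    class = "fd_degenerate_geometry")
  err <- tryCatch(frame_from_three_points(frame_anchors(
    c(0, 0, 0), left = c(2, 0, 0), right = c(1, 0, 0), index = 7L)),
    error = identity)
  expect_match(conditionMessage(err), "7")
})

test_that("random frames are proper rotations and transform algebra closes", {
  withr::with_seed(11, {
    for (k in 1:200) {
      pts <- matrix(rnorm(9, sd = 3), 3, 3)
      f <- tryCatch(frame_from_three_points(frame_anchors(
        pts[1, ], left = pts[2, ], right = pts[3, ])), error = function(e) NULL)
      if (is.null(f)) next
      expect_lt(max(abs(crossprod(f$R) - diag(3))), 1e-6)
      expect_lt(abs(det(f$R) - 1), 1e-6)
      idn <- frame_compose(f, frame_inverse(f))
      expect_lt(max(abs(idn$R - diag(3))), 1e-6)
      expect_lt(max(abs(idn$t)), 1e-6)
    }
  })
})

test_that("residue frames sit on the C-alphas and are rigidly equivariant", {
  cx <- tiny_complex()
  frames <- build_residue_frames(cx$protein)
  for (i in seq_along(frames)) {
    expect_identical(frames[[i]]$t, cx$protein$ca[i, ])
    o <- oracle_frame(cx$protein$ca[i, ], cx$protein$n[i, ], cx$protein$c[i, ])
    expect_equal(frames[[i]]$R, o$R, tolerance = 1e-10)
  }
  withr::with_seed(3, {
    Q <- random_rigid()
    framesT <- build_residue_frames(transform_protein(cx$protein, Q))
    for (i in seq_along(frames)) {
      ref <- frame_compose(Q, frames[[i]])
      expect_equal(framesT[[i]]$R, ref$R, tolerance = 1e-10)
      expect_equal(framesT[[i]]$t, ref$t, tolerance = 1e-10)
    }
  })
})

test_that("missing backbone coordinates raise a structured residue error", {
  cx <- tiny_complex()
  p <- cx$protein
  p$c[2, ] <- NA
  expect_error(build_residue_frames(p), class = "fd_missing_atom")
})

test_that("ligand frame anchors follow the lowest-index-neighbor rule", {
  # linear chain A-B-C: middle atom uses both neighbors, terminals get a dummy
  chain <- ligand_graph(c("C", "C", "O"),
                        rbind(c(1L, 2L, 1L), c(2L, 3L, 1L)),
                        coords = rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.2, 1.2, 0)),
                        canonicalize = FALSE)
  lf <- build_ligand_frames(chain)
  expect_identical(lf$anchors[[2]]$left, chain$coords[1, ])   # N slot: atom 1
  expect_identical(lf$anchors[[2]]$right, chain$coords[3, ])  # C slot: atom 3
  expect_false(lf$anchors[[2]]$is_dummy_right)
  expect_true(lf$anchors[[1]]$is_dummy_right)
  expect_true(lf$anchors[[3]]$is_dummy_right)
  expect_identical(lf$anchors[[1]]$left, chain$coords[2, ])
  # dummy sits 1 A from the center, orthogonal to the bond
  d <- lf$anchors[[1]]$right - lf$anchors[[1]]$center
  b <- chain$coords[2, ] - chain$coords[1, ]
  expect_equal(sqrt(sum(d^2)), 1, tolerance = 1e-10)
  expect_lt(abs(sum(d * b)), 1e-10)

  # benzene: every atom anchored by its two ring neighbors, lower index first
  bz <- make_symmetric_ligand("ring6")$ligand
  lfb <- build_ligand_frames(bz)
  for (i in 1:6) {
    nb <- sort(which(bz$adjacency[i, ]))
    expect_identical(lfb$anchors[[i]]$left, bz$coords[nb[1], ])
    expect_identical(lfb$anchors[[i]]$right, bz$coords[nb[2], ])
  }

  # 4-connected center with neighbors at indices {1,3,5,7}: picks 1 and 3
  el <- c("O", "C", "O", "C", "N", "C", "N")
  bonds <- rbind(c(2L, 1L, 1L), c(2L, 3L, 1L), c(2L, 5L, 1L), c(2L, 7L, 1L),
                 c(3L, 4L, 1L), c(5L, 6L, 1L))
  coords <- rbind(c(1.4, 0, 0), c(0, 0, 0), c(-0.7, 1.2, 0), c(-1.4, 2.4, 0.5),
                  c(-0.7, -1.2, 0), c(-1.4, -2.4, 0.5), c(0.7, 0.4, 1.3))
  star <- ligand_graph(el, bonds, coords = coords, canonicalize = FALSE)
  lfs <- build_ligand_frames(star)
  expect_identical(lfs$anchors[[2]]$left, coords[1, ])
  expect_identical(lfs$anchors[[2]]$right, coords[3, ])
})

test_that("isolated atoms cannot be framed", {
  iso <- ligand_graph(c("C", "C", "O"), rbind(c(1L, 2L, 1L)),
                      coords = rbind(c(0, 0, 0), c(1.5, 0, 0), c(5, 5, 5)),
                      canonicalize = FALSE)
  expect_error(build_ligand_frames(iso), class = "fd_unsupported_topology")
})

test_that("ligand frame anchors are deterministic across runs", {
  cx <- tiny_complex()
  a1 <- build_ligand_frames(cx$ligand)$anchors
  a2 <- build_ligand_frames(cx$ligand)$anchors
  expect_identical(a1, a2)
})

test_that("frame updates compose like rigid transforms", {
  withr::with_seed(8, {
    f <- frame_from_three_points(frame_anchors(
      rnorm(3), left = rnorm(3, sd = 2), right = rnorm(3, sd = 2)))
    # identity update
    f_id <- update_frame(f, c(0, 0, 0), c(0, 0, 0))
    expect_equal(f_id$R, f$R, tolerance = 1e-12)
    expect_equal(f_id$t, f$t, tolerance = 1e-12)

    # two successive updates equal their composition
    q1 <- rnorm(3, sd = 0.3); t1 <- rnorm(3)
    q2 <- rnorm(3, sd = 0.3); t2 <- rnorm(3)
    f12 <- update_frame(update_frame(f, q1, t1), q2, t2)
    u1 <- rigid_transform(framedock:::quat_to_rotation(q1), t1)
    u2 <- rigid_transform(framedock:::quat_to_rotation(q2), t2)
    fc <- frame_compose(f, frame_compose(u1, u2))
    expect_equal(f12$R, fc$R, tolerance = 1e-10)
    expect_equal(f12$t, fc$t, tolerance = 1e-10)

    # homogeneous 4x4 matrix oracle
    hom <- function(R, t) rbind(cbind(R, t), c(0, 0, 0, 1))
    q <- rnorm(3, sd = 0.5); tt <- rnorm(3)
    fu <- update_frame(f, q, tt)
    H <- hom(f$R, f$t) %*% hom(framedock:::quat_to_rotation(q), tt)
    expect_equal(hom(fu$R, fu$t), H, tolerance = 1e-10)
    # invariants preserved
    expect_lt(max(abs(crossprod(fu$R) - diag(3))), 1e-6)
    expect_lt(abs(det(fu$R) - 1), 1e-6)
  })
})

test_that("frame dumps serialize one tab-separated line per frame", {
  cx <- tiny_complex()
  frames <- build_residue_frames(cx$protein)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_frames(frames, path)
  lines <- readLines(path)
  expect_length(lines, length(frames))
  expect_length(strsplit(lines[1], "\t")[[1]], 13L)
})
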