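# Symmetry-corrected RMSD, success rate, descriptors, channel correlations.

test_that("automorphism relabelings are absorbed by the corrected RMSD", {
  tri <- make_symmetric_ligand("triangle")
  expect_gt(naive_rmsd(tri$twin_coords, tri$ligand$coords), 0.5)
  expect_lt(symmetry_corrected_rmsd(tri$twin_coords, tri$ligand$coords,
                                    tri$ligand), 1e-9)
})

test_that("asymmetric molecules reduce to the naive RMSD exactly", {
  lig <- load_ligand("CCO")
  withr::with_seed(41, {
    pred <- lig$coords + matrix(rnorm(9, sd = 0.3), ncol = 3)
  })
  expect_identical(symmetry_corrected_rmsd(pred, lig$coords, lig),
                   naive_rmsd(pred, lig$coords))
  expect_length(framedock:::ligand_automorphisms(lig), 1L)
})

test_that("corrected RMSD equals the brute-force permutation minimum", {
  for (kind in c("ring6", "triangle", "linear-palindrome")) {
    sym <- make_symmetric_ligand(kind)
    lig <- sym$ligand
    withr::with_seed(42, {
      pred <- frame_apply(random_rigid(), lig$coords)[sym$permutation, ]
      pred <- pred + matrix(rnorm(length(pred), sd = 0.2), ncol = 3)
    })
    autos <- oracle_automorphisms(lig)
    brute <- min(vapply(autos, function(p)
      naive_rmsd(pred[p, , drop = FALSE], lig$coords), numeric(1)))
    expect_equal(symmetry_corrected_rmsd(pred, lig$coords, lig), brute,
                 tolerance = 1e-12)
  }
})

test_that("symmetric fixture kinds have the expected automorphism counts", {
  counts <- vapply(c("ring6", "triangle", "linear-palindrome"), function(k) {
    length(oracle_automorphisms(make_symmetric_ligand(k)$ligand))
  }, numeric(1))
  expect_equal(unname(counts), c(12, 6, 2))
  # package enumeration agrees with the brute-force oracle
  pkg_counts <- vapply(c("ring6", "triangle", "linear-palindrome"), function(k) {
    length(framedock:::ligand_automorphisms(make_symmetric_ligand(k)$ligand))
  }, numeric(1))
  expect_equal(unname(pkg_counts), c(12, 6, 2))
})

test_that("an automorphism cap triggers the naive fallback with a warning", {
  bz <- make_symmetric_ligand("ring6")
  expect_warning(
    r <- symmetry_corrected_rmsd(bz$twin_coords, bz$ligand$coords,
                                 bz$ligand, cap = 4L), "cap")
  expect_equal(r, naive_rmsd(bz$twin_coords, bz$ligand$coords))
})

test_that("success rate uses a strict 2 Angstrom threshold", {
  expect_equal(success_rate(c(1.0, 3.0, 1.9, 2.0)), 50.0)
  expect_equal(success_rate(rep(0, 4)), 100.0)
  expect_equal(success_rate(rep(2.0, 3)), 0.0)
  expect_error(success_rate(numeric(0)), class = "fd_empty_error")
})

test_that("success rate responds monotonically to added predictions", {
  withr::with_seed(43, {
    rmsds <- runif(20, 0, 5)
    base <- success_rate(rmsds)
    expect_gte(success_rate(c(rmsds, 0.5)), base)
    expect_lte(success_rate(c(rmsds, 4.5)), base)
  })
})

test_that("textbook descriptor values come out right", {
  bz <- load_ligand("c1ccccc1")
  eth <- load_ligand("CCO")
  pyr <- load_ligand("c1ccncc1")
  D <- descriptor_table(list(bz, eth, pyr))
  expect_identical(colnames(D), FD_DESCRIPTORS)
  expect_true(all(attr(D, "ok")))
  expect_equal(D[1, "aromatic_rings"], c(aromatic_rings = 1))
  expect_equal(D[1, "rotatable_bonds"], c(rotatable_bonds = 0))
  expect_equal(D[1, "hbd"], c(hbd = 0))
  expect_equal(D[2, "hbd"], c(hbd = 1))
  expect_equal(D[2, "hba"], c(hba = 1))
  expect_equal(D[3, "mol_weight"], c(mol_weight = 79.1), tolerance = 0.1 / 79.1)
  expect_true(all(is.finite(D)))
})

test_that("channel correlations recover planted signals and report p-values", {
  withr::with_seed(44, {
    nmol <- 12
    ligs <- lapply(1:nmol, function(i) {
      make_complex(seed = 900 + i, n_lig_atoms = sample(5:20, 1))$ligand
    })
    D <- descriptor_table(ligs)
    emb <- matrix(rnorm(nmol * 8), nmol, 8)
    emb[, 3] <- D[, "mol_weight"]          # planted copy
    emb[, 5] <- -D[, "hba"]                # planted negation
    emb[, 7] <- 1.0                        # zero variance
    cc <- channel_correlations(emb, D)
    r3 <- cc[cc$channel == 3 & cc$descriptor == "mol_weight", ]
    expect_equal(r3$r, 1.0, tolerance = 1e-12)
    expect_true(r3$best)
    r5 <- cc[cc$channel == 5 & cc$descriptor == "hba", ]
    expect_equal(r5$r, -1.0, tolerance = 1e-12)
    expect_true(r5$best)                   # |R| selection keeps the sign out
    expect_true(all(is.na(cc$r[cc$channel == 7])))
    expect_false(any(cc$best[cc$channel == 7]))
    expect_true(all(cc$p > 0 & cc$p <= 1, na.rm = TRUE))
  })
})

test_that("the Pearson values match the closed-form formula to 1e-10", {
  withr::with_seed(45, {
    n <- 10
    emb <- matrix(rnorm(n * 6), n, 6)
    desc <- matrix(rnorm(n * 4), n, 4,
                   dimnames = list(NULL, paste0("d", 1:4)))
    cc <- channel_correlations(emb, desc)
    for (ch in 1:6) {
      for (dd in 1:4) {
        x <- emb[, ch]; y <- desc[, dd]
        r_formula <- (sum(x * y) - n * mean(x) * mean(y)) /
          sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
        got <- cc$r[cc$channel == ch & cc$descriptor == paste0("d", dd)]
        expect_equal(got, r_formula, tolerance = 1e-10)
      }
    }
  })
})

test_that("pose evaluation tables aggregate the success rate", {
  cx <- tiny_complex()
  preds <- list(cx$pose, sweep(cx$pose, 2, c(5, 0, 0), "+"))
  tab <- evaluate_poses(preds, list(cx$pose, cx$pose),
                        list(cx$ligand, cx$ligand))
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$success, c(TRUE, FALSE))
  expect_equal(attr(tab, "success_rate"), 50.0)
  expect_true(all(tab$rmsd_corrected <= tab$rmsd_naive + 1e-12))
  # validity hook is recorded when supplied
  tab2 <- evaluate_poses(preds[1], list(cx$pose), list(cx$ligand),
                         validity_hook = function(lig, coords) TRUE)
  expect_true(tab2$valid)
})
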