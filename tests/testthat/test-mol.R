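# Ligand parsing, canonical ordering, conformers, SDF round trips.

test_that("SMILES ethanol gives sane heavy-atom geometry", {
  lig <- load_ligand("CCO")
  expect_identical(sort(lig$elements), c("C", "C", "O"))
  expect_equal(nrow(lig$bonds), 2L)
  d <- sqrt(rowSums((lig$coords[lig$bonds[, 1], , drop = FALSE] -
                       lig$coords[lig$bonds[, 2], , drop = FALSE])^2))
  els <- cbind(lig$elements[lig$bonds[, 1]], lig$elements[lig$bonds[, 2]])
  cc <- d[rowSums(els == "C") == 2L]
  co <- d[rowSums(els == "O") == 1L]
  expect_equal(cc, 1.5, tolerance = 0.2 / 1.5)
  expect_equal(co, 1.4, tolerance = 0.2 / 1.4)
})

test_that("canonical ordering is input-order invariant and idempotent", {
  a <- load_ligand("CCO")
  b <- load_ligand("OCC")
  expect_identical(a$elements, b$elements)
  expect_identical(a$bonds, b$bonds)
  expect_identical(a$charges, b$charges)

  withr::with_seed(20, {
    for (k in 1:20) {
      cx <- make_complex(seed = 500 + k, n_lig_atoms = sample(5:14, 1))
      lig <- cx$ligand
      again <- canonicalize_ligand(lig)
      expect_identical(again$elements, lig$elements)
      expect_identical(again$bonds, lig$bonds)
      expect_identical(again$coords, lig$coords)
      expect_identical(again$canonical_rank, seq_along(lig$elements))
    }
  })
})

test_that("benzene has a symmetric aromatic adjacency", {
  bz <- load_ligand("c1ccccc1")
  expect_equal(sum(bz$adjacency), 12L)   # 6 bonds, symmetric
  expect_identical(bz$adjacency, t(bz$adjacency))
  expect_true(all(diag(bz$adjacency) == FALSE))
  expect_true(all(bz$aromatic))
  expect_true(all(bz$bonds[, 3] == 4L))
  # bond list and adjacency agree exactly
  A <- matrix(FALSE, 6, 6)
  A[bz$bonds[, 1:2]] <- TRUE
  A[bz$bonds[, 2:1]] <- TRUE
  expect_identical(A, bz$adjacency)
})

test_that("formal charges survive parsing and implicit hydrogens are sane", {
  ac <- load_ligand("CC(=O)[O-]")
  expect_equal(sum(ac$charges), -1L)
  o_minus <- which(ac$charges == -1L)
  expect_identical(ac$elements[o_minus], "O")
  expect_equal(ac$implicit_h[o_minus], 0L)
  eth <- load_ligand("CCO")
  expect_equal(sum(eth$implicit_h), 6L)    # C2H5-OH heavy-atom graph
  pyr <- load_ligand("c1ccncc1")
  expect_equal(eth$implicit_h[eth$elements == "O"], 1L)
  expect_equal(pyr$implicit_h[pyr$elements == "N"], 0L)
})

test_that("pose SDF round trips preserve graph, coordinates and provenance", {
  cx <- tiny_complex()
  path <- withr::local_tempfile(fileext = ".sdf")
  write_pose(cx$ligand, cx$pose, path,
             provenance = list(config_hash = "abc123", note = "unit"))
  txt <- readLines(path)
  expect_true(any(grepl("config_hash", txt)))
  expect_true(any(grepl("abc123", txt)))
  back <- load_ligand(path)
  expect_identical(back$elements, cx$ligand$elements)
  expect_identical(back$bonds, cx$ligand$bonds)
  expect_lt(max(abs(back$coords - cx$pose)), 1e-3)
})

test_that("coordinate count mismatches are rejected", {
  cx <- tiny_complex()
  expect_error(write_pose(cx$ligand, cx$pose[-1, ],
                          withr::local_tempfile(fileext = ".sdf")),
               class = "fd_parse_error")
})

test_that("multi-fragment records keep the largest fragment with a warning", {
  expect_warning(lig <- load_ligand("CCO.[Na+]"), "largest fragment")
  expect_identical(sort(lig$elements), c("C", "C", "O"))
})

test_that("unparseable SMILES raise a parse error", {
  expect_error(load_ligand("not_a_smiles(("), class = "fd_parse_error")
})

test_that("protein PDB round trips and incomplete backbones are dropped", {
  cx <- tiny_complex()
  path <- withr::local_tempfile(fileext = ".pdb")
  write_protein_pdb(cx$protein, path)
  back <- load_protein(path)
  expect_identical(back$sequence, cx$protein$sequence)
  expect_lt(max(abs(back$ca - cx$protein$ca)), 1e-2)
  expect_lt(max(abs(back$n - cx$protein$n)), 1e-2)

  # delete residue 2's C atom: that residue is dropped, count decremented
  lines <- readLines(path)
  drop <- grep("^ATOM", lines)
  drop <- drop[trimws(substr(lines[drop], 13, 16)) == "C" &
                 trimws(substr(lines[drop], 23, 26)) == "2"]
  expect_length(drop, 1L)
  path2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines[-drop], path2)
  expect_warning(back2 <- load_protein(path2), "incomplete backbone")
  expect_equal(n_residues(back2), n_residues(cx$protein) - 1L)
})

test_that("chains beyond the residue cap are rejected", {
  n <- 2001L
  expect_error(protein_structure(rep("A", n), matrix(0, n, 3),
                                 matrix(0, n, 3), matrix(0, n, 3)),
               class = "fd_length_error")
  # through the file path too
  path <- withr::local_tempfile(fileext = ".pdb")
  mk_res <- function(i) {
    z <- i * 3.8
    sprintf("ATOM  %5d  %-3s ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
            (i - 1L) * 3L + 1:3, c("N", "CA", "C"), i,
            c(0, 1.4, 2.4), c(0.5, 0, 0.7), rep(z, 3), c("N", "C", "C"))
  }
  writeLines(c(unlist(lapply(seq_len(n), mk_res)), "END"), path)
  expect_error(load_protein(path), class = "fd_length_error")
})

test_that("conformer generation is deterministic and seed-sensitive", {
  lig <- ligand_graph(c("C", "C", "C", "O"),
                      rbind(c(1L, 2L, 1L), c(2L, 3L, 1L), c(3L, 4L, 1L)))
  a <- generate_conformer(lig, seed = 7)
  b <- generate_conformer(lig, seed = 7)
  c2 <- generate_conformer(lig, seed = 8)
  expect_identical(a$coords, b$coords)
  expect_false(identical(a$coords, c2$coords))
  d <- sqrt(rowSums((a$coords[a$bonds[, 1], ] - a$coords[a$bonds[, 2], ])^2))
  expect_true(all(d > 1.2 & d < 1.8))
})
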