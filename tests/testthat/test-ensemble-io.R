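test_that("multi-model PDB files round-trip to PDB precision", {
  syn <- generate_ensemble(ensemble_spec(n_residues = 8, n_frames = 5,
                                         helical_segments = data.frame(),
                                         states = data.frame(label = "s", weight = 1,
                                                             compactness = 1.5),
                                         seed = 4))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(syn$ensemble, path)
  back <- read_multimodel_pdb(path)
  expect_equal(n_frames(back), 5)
  expect_identical(back$topology, syn$ensemble$topology)
  expect_lt(max(abs(back$frames - syn$ensemble$frames)), 1e-4)

  one <- conformational_ensemble(syn$ensemble$topology,
                                 syn$ensemble$frames[, , 1, drop = FALSE])
  write_multimodel_pdb(one, path)
  lines <- readLines(path)
  expect_equal(sum(grepl("^MODEL", lines)), 1)
  expect_equal(sum(grepl("^ENDMDL", lines)), 1)
})

test_that("PDB reading converts Angstrom to nm and validates models", {
  path <- withr::local_tempfile(fileext = ".pdb")
  atom <- function(serial, name, res, x)
    sprintf("ATOM  %5d  %-3s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           %1s",
            serial, name, "ALA", res, x, 0, 0, substr(name, 1, 1))
  writeLines(c("MODEL     1", atom(1, "N", 1, 1.5), atom(2, "CA", 1, 2.0),
               atom(3, "C", 1, 3.0), "ENDMDL",
               "MODEL     2", atom(1, "N", 1, 2.5), atom(2, "CA", 1, 3.0),
               atom(3, "C", 1, 4.0), "ENDMDL"), path)
  e <- read_multimodel_pdb(path)
  expect_equal(n_frames(e), 2)
  expect_equal(n_atoms(e), 3)
  expect_equal(e$frames[1, 1, 1], 0.15)  # 1.5 Angstrom -> 0.15 nm
  expect_identical(e$source_units, "angstrom")

  # bare single block, no MODEL records
  writeLines(c(atom(1, "N", 1, 1.0), atom(2, "CA", 1, 2.0),
               atom(3, "C", 1, 3.0)), path)
  expect_equal(n_frames(read_multimodel_pdb(path)), 1)

  # atom-count mismatch names the offending model
  writeLines(c("MODEL     1", atom(1, "N", 1, 1.5), atom(2, "CA", 1, 2.0),
               atom(3, "C", 1, 3.0), "ENDMDL",
               "MODEL     2", atom(1, "N", 1, 2.5), atom(2, "CA", 1, 3.0),
               "ENDMDL"), path)
  expect_error(read_multimodel_pdb(path), "MODEL 2")
})

test_that("ensemble concatenation discards head frames and labels replicates", {
  base <- random_ensemble(A = 6, F = 50, seed = 2)
  members <- lapply(1:9, function(k) base)
  cat9 <- concatenate_ensembles(members, discard_head = 5)
  expect_equal(n_frames(cat9), 9 * 45)
  expect_equal(unique(cat9$frame_labels), paste0("r", 1:9))
  expect_equal(sum(cat9$frame_labels == "r3"), 45)

  ident <- concatenate_ensembles(list(base), discard_head = 0)
  expect_equal(ident$frames, base$frames)

  other <- random_ensemble(A = 6, F = 50, seed = 2)
  other$topology$residue_names[1] <- "GLY"
  expect_error(concatenate_ensembles(list(base, other)), "topology")
  expect_error(concatenate_ensembles(list(base), discard_head = 50),
               "discard_head")
})

test_that("superposition removes rigid-body motion exactly and is idempotent", {
  set.seed(3)
  X <- matrix(rnorm(30, sd = 0.5), 10, 3)
  frames <- array(NA_real_, dim = c(10, 3, 10))
  for (f in 1:10)
    frames[, , f] <- rigid_transform(X, theta = f / 3, axis = rnorm(3),
                                     shift = rnorm(3))
  top <- list(atom_names = rep("CA", 10), residue_names = rep("ALA", 10),
              residue_ids = 1:10, elements = rep("C", 10))
  ens <- conformational_ensemble(top, frames)
  sup <- superpose_ensemble(ens, "ca", reference = 1)
  rmsds <- vapply(1:10, function(f)
    sqrt(mean(rowSums((sup$frames[, , f] - sup$frames[, , 1])^2))), 0)
  expect_lt(max(rmsds), 1e-6)

  # idempotence of the iterative-mean fit
  e2 <- superpose_ensemble(random_ensemble(A = 8, F = 6, seed = 9), "ca")
  e3 <- superpose_ensemble(e2, "ca")
  expect_lt(max(abs(e3$frames - e2$frames)), 1e-9)

  # rigid transforms preserve internal distances
  d_before <- dist(ens$frames[, , 4])
  d_after <- dist(sup$frames[, , 4])
  expect_lt(max(abs(d_before - d_after)), 1e-9)

  expect_error(superpose_ensemble(ens, selection = 1:2), "3")
})

test_that("per-frame fitting never increases the RMSD to the reference", {
  ens <- random_ensemble(A = 12, F = 20, seed = 5)
  sup <- superpose_ensemble(ens, "ca", reference = 1)
  for (f in 2:20) {
    before <- sqrt(mean(rowSums((ens$frames[, , f] - ens$frames[, , 1])^2)))
    after <- sqrt(mean(rowSums((sup$frames[, , f] - sup$frames[, , 1])^2)))
    expect_lte(after, before + 1e-12)
    # direct Kabsch solution per frame is the same optimum
    oracle <- idpens:::rmsd_pair(ens$frames[, , f], ens$frames[, , 1])
    expect_equal(after, oracle, tolerance = 1e-9)
  }
})

test_that("pairwise RMSD matrix matches an independent per-pair fit oracle", {
  ens <- random_ensemble(A = 8, F = 4, seed = 7)
  M <- pairwise_rmsd_matrix(ens, "ca")
  expect_equal(M, t(M))
  expect_equal(diag(M), rep(0, 4))
  skip_if_not_installed("bio3d")
  for (i in 1:3) for (j in (i + 1):4) {
    oracle <- bio3d::rmsd(as.vector(t(ens$frames[, , i])),
                          as.vector(t(ens$frames[, , j])), fit = TRUE)
    expect_equal(M[i, j], oracle, tolerance = 1e-3)  # bio3d rounds to 3 digits
  }

  # duplicates and pure translations give zero
  dup <- conformational_ensemble(ens$topology,
                                 ens$frames[, , c(1, 1), drop = FALSE])
  expect_equal(max(pairwise_rmsd_matrix(dup, "ca")), 0)
  tra <- dup
  tra$frames[, 1, 2] <- tra$frames[, 1, 2] + 1
  expect_lt(max(pairwise_rmsd_matrix(tra, "ca")), 1e-9)

  # rigid transform of one frame leaves the matrix unchanged
  rig <- ens
  rig$frames[, , 2] <- rigid_transform(rig$frames[, , 2])
  expect_equal(pairwise_rmsd_matrix(rig, "ca"), M, tolerance = 1e-9)
})
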