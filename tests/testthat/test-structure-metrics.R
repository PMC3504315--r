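test_that("ideal helices and extended chains are classified correctly", {
  helix <- torsion_ensemble(-57, -47, n = 30)
  ss <- assign_secondary_structure(helix)
  expect_gte(sum(ss$assignments[1, ] == "H"), 14)
  expect_false(any(ss$assignments[1, ] %in% c("G", "I")))

  g310 <- torsion_ensemble(-71, -18, n = 30)
  ss3 <- assign_secondary_structure(g310)
  expect_gte(sum(ss3$assignments[1, ] == "G"), 14)
  expect_false(any(ss3$assignments[1, ] == "H"))

  ext <- torsion_ensemble(-179.9, 179.9, n = 30)
  expect_false(any(assign_secondary_structure(ext)$assignments[1, ] %in%
                     c("H", "G", "I")))
})

test_that("helix assignment agrees >= 95% with an external DSSP implementation", {
  constructs <- list(alpha = c(-57, -47), g310 = c(-71, -18),
                     ext = c(-179.9, 179.9))
  dir <- withr::local_tempdir()
  for (nm in names(constructs)) {
    tor <- constructs[[nm]]
    write_multimodel_pdb(torsion_ensemble(tor[1], tor[2], n = 30),
                         file.path(dir, paste0(nm, ".pdb")))
  }
  script <- file.path(dir, "dssp_ref.py")
  writeLines(c(
    "import sys, mdtraj as md",
    "for name in sys.argv[1:]:",
    "    t = md.load(name + '.pdb')",
    "    print(name, ''.join(md.compute_dssp(t, simplified=False)[0]).replace(' ', 'C'))"),
    script)
  out <- withr::with_dir(dir,
    system2("python", c(shQuote(script), names(constructs)),
            stdout = TRUE, stderr = FALSE))
  expect_equal(length(out), 3)
  ref <- strsplit(out, " ")
  names(ref) <- vapply(ref, `[[`, "", 1)
  helixify <- function(s) {
    v <- strsplit(s, "")[[1]]
    ifelse(v %in% c("H", "G", "I"), v, "-")
  }
  for (nm in names(constructs)) {
    tor <- constructs[[nm]]
    ours <- assign_secondary_structure(
      torsion_ensemble(tor[1], tor[2], n = 30))$assignments[1, ]
    ours <- ifelse(ours %in% c("H", "G", "I"), ours, "-")
    theirs <- helixify(ref[[nm]][2])
    expect_gte(mean(ours == theirs), 0.95)
  }
})

test_that("partial helix occupancy is recovered as per-residue persistence", {
  spec <- ensemble_spec(n_residues = 40,
                        helical_segments = data.frame(start = 12, end = 25,
                                                      occupancy = 0.5),
                        states = data.frame(label = "one", weight = 1,
                                            compactness = 1.8),
                        n_frames = 200, seed = 8)
  syn <- generate_ensemble(spec)
  ss <- assign_secondary_structure(syn$ensemble)
  core <- 15:22
  measured <- mean(ss$persistence[core, "H"])
  realized <- mean(syn$helix_occupancy[, core])
  ci_half <- qnorm(0.995) * sqrt(0.25 / 200)
  expect_lt(abs(measured - 0.5), ci_half + 0.05)  # sampling + edge fraying
  expect_equal(measured, realized, tolerance = 0.1)
  # persistence rows are probability vectors
  expect_equal(unname(rowSums(ss$persistence)), rep(1, 40), tolerance = 1e-12)
})

test_that("secondary-structure assignment validates its topology", {
  ens <- random_ensemble(A = 4, F = 2)  # CA-only: no N/C/O backbone
  expect_error(assign_secondary_structure(ens), "missing backbone atom")
})

test_that("isolated and disjoint spheres match the closed-form surface", {
  top <- list(atom_names = "X", residue_names = "UNK", residue_ids = 1L,
              elements = "C")
  one <- conformational_ensemble(top, array(0, dim = c(1, 3, 1)))
  s <- shrake_rupley_sas(one, probe_radius = 0.14, n_points = 960)
  exact <- 4 * pi * (0.17 + 0.14)^2
  expect_lt(abs(s$total - exact) / exact, 0.005)

  top2 <- list(atom_names = c("X", "X"), residue_names = c("UNK", "UNK"),
               residue_ids = 1:2, elements = c("C", "C"))
  far <- conformational_ensemble(top2, array(c(0, 10, 0, 0, 0, 0),
                                             dim = c(2, 3, 1)))
  s2 <- shrake_rupley_sas(far, n_points = 960)
  expect_equal(s2$total, 2 * s$total, tolerance = 1e-9)

  bad <- conformational_ensemble(list(atom_names = "Q", residue_names = "UNK",
                                      residue_ids = 1L, elements = "Zz"),
                                 array(0, dim = c(1, 3, 1)))
  expect_error(shrake_rupley_sas(bad), "radius")
})

test_that("overlapping spheres match the exact two-sphere union area", {
  r1 <- 0.17 + 0.14
  r2 <- 0.155 + 0.14
  d <- 0.2
  top <- list(atom_names = c("X", "Y"), residue_names = c("UNK", "UNK"),
              residue_ids = 1:2, elements = c("C", "N"))
  ens <- conformational_ensemble(top, array(c(0, d, 0, 0, 0, 0),
                                            dim = c(2, 3, 1)))
  s <- shrake_rupley_sas(ens, n_points = 960)
  # exact buried spherical caps of the two-sphere union
  cap1 <- 2 * pi * r1 * (r1 - (d^2 + r1^2 - r2^2) / (2 * d))
  cap2 <- 2 * pi * r2 * (r2 - (d^2 + r2^2 - r1^2) / (2 * d))
  exact <- 4 * pi * r1^2 - cap1 + 4 * pi * r2^2 - cap2
  expect_lt(abs(s$total - exact) / exact, 0.01)
})

test_that("SAS quadrature converges and is rigid-motion invariant", {
  top <- list(atom_names = "X", residue_names = "UNK", residue_ids = 1L,
              elements = "O")
  one <- conformational_ensemble(top, array(0, dim = c(1, 3, 1)))
  exact <- 4 * pi * (0.152 + 0.14)^2
  errs <- vapply(c(240, 960, 3840), function(np)
    abs(shrake_rupley_sas(one, n_points = np)$total - exact), 0)
  expect_true(all(diff(errs) <= 1e-9))

  syn <- generate_ensemble(ensemble_spec(n_residues = 10, n_frames = 1,
                                         helical_segments = data.frame(),
                                         states = data.frame(label = "s",
                                                             weight = 1,
                                                             compactness = 1.5),
                                         seed = 5))
  s0 <- shrake_rupley_sas(syn$ensemble, n_points = 240)
  moved <- syn$ensemble
  moved$frames[, , 1] <- rigid_transform(moved$frames[, , 1])
  s1 <- shrake_rupley_sas(moved, n_points = 240)
  expect_lt(abs(s1$total - s0$total), 1e-9)
  expect_equal(s0$total, sum(s0$per_residue[1, ]), tolerance = 1e-9)
})

test_that("helical-content summaries follow the counting arithmetic", {
  ss <- structure(list(
    assignments = matrix(c(rep("H", 14), rep("C", 56)), nrow = 1,
                         ncol = 70, byrow = TRUE)[rep(1, 5), ],
    persistence = NULL, residue_ids = 1:70,
    classes = c("H", "G", "I", "T", "C")), class = "ss_profile")
  hs <- helical_content_summary(ss)
  expect_equal(hs$mean_alpha, 14)
  expect_equal(hs$max_alpha, 14)
  expect_equal(hs$total_helical_pct, 20.0)

  all_coil <- ss
  all_coil$assignments[] <- "C"
  hc <- helical_content_summary(all_coil)
  expect_equal(hc$mean_alpha + hc$mean_310 + hc$mean_pi, 0)
  expect_equal(hc$total_helical_pct, 0)
})

test_that("basin reports equal direct recomputation on the frame subsets", {
  syn <- generate_ensemble(ensemble_spec(
    n_residues = 20, n_frames = 12, seed = 9,
    helical_segments = data.frame(start = 5, end = 12, occupancy = 0.7)))
  ss <- assign_secondary_structure(syn$ensemble)
  sas <- shrake_rupley_sas(syn$ensemble, n_points = 240)

  # one basin holding all frames: the report row is the global summary
  rep1 <- basin_structure_report(rep("A", 12), ss, sas)
  expect_equal(nrow(rep1), 1)
  expect_equal(rep1$total_helical_pct, helical_content_summary(ss)$total_helical_pct)
  expect_equal(rep1$sas_mean, mean(sas$total))

  # compact/extended split: planted compactness orders the SAS means
  labs <- ifelse(syn$state == "compact", "A", "B")
  rep2 <- basin_structure_report(labs, ss, sas)
  expect_lt(rep2$sas_mean[rep2$basin == "A"],
            rep2$sas_mean[rep2$basin == "B"])
  for (lab in c("A", "B")) {
    fr <- which(labs == lab)
    expect_equal(rep2$sas_mean[rep2$basin == lab], mean(sas$total[fr]))
    expect_equal(rep2$helix_max_alpha[rep2$basin == lab],
                 helical_content_summary(ss, fr)$max_alpha)
  }
})
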