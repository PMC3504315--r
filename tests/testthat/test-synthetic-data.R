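test_that("helical-segment occupancy ground truth is forced by construction", {
  spec1 <- ensemble_spec(n_residues = 40,
                         helical_segments = data.frame(start = 12, end = 25,
                                                       occupancy = 1.0),
                         states = data.frame(label = "one", weight = 1,
                                             compactness = 1.8),
                         n_frames = 50, seed = 2)
  syn1 <- generate_ensemble(spec1)
  expect_true(all(syn1$helix_occupancy[, 12:25]))
  expect_true(all(!syn1$helix_occupancy[, c(1:11, 26:40)]))

  spec0 <- ensemble_spec(n_residues = 40,
                         helical_segments = data.frame(start = 12, end = 25,
                                                       occupancy = 0.0),
                         states = data.frame(label = "one", weight = 1,
                                             compactness = 1.8),
                         n_frames = 20, seed = 2)
  expect_false(any(generate_ensemble(spec0)$helix_occupancy))
})

test_that("occupied helical residues are assigned helix in >= 90% of frames", {
  spec <- ensemble_spec(n_residues = 40,
                        helical_segments = data.frame(start = 12, end = 25,
                                                      occupancy = 1.0),
                        states = data.frame(label = "one", weight = 1,
                                            compactness = 1.8),
                        n_frames = 30, seed = 6)
  syn <- generate_ensemble(spec)
  ss <- assign_secondary_structure(syn$ensemble)
  core <- 14:23  # interior of the planted segment
  expect_gte(mean(ss$assignments[, core] == "H"), 0.90)
})

test_that("two-state generation realizes weights and compactness ordering", {
  spec <- ensemble_spec(
    states = data.frame(label = c("compact", "extended"),
                        weight = c(0.7, 0.3), compactness = c(1.0, 2.5)),
    n_frames = 500, seed = 7)
  syn <- generate_ensemble(spec)
  n_compact <- sum(syn$state == "compact")
  ci <- qbinom(c(0.005, 0.995), 500, 0.7)
  expect_gte(n_compact, ci[1])
  expect_lte(n_compact, ci[2])
  expect_gt(mean(syn$rg[syn$state == "extended"]),
            mean(syn$rg[syn$state == "compact"]))
  # realized Rg tracks the per-state targets
  rg0 <- 0.22 * 70^0.38
  expect_equal(mean(syn$rg[syn$state == "compact"]), rg0, tolerance = 0.1)
  expect_equal(mean(syn$rg[syn$state == "extended"]), 2.5 * rg0,
               tolerance = 0.1)
})

test_that("generation is a pure function of the spec seed", {
  spec <- ensemble_spec(n_frames = 10, seed = 11)
  a <- generate_ensemble(spec)
  b <- generate_ensemble(spec)
  expect_identical(a$ensemble$frames, b$ensemble$frames)
  expect_identical(a$state, b$state)
  spec2 <- ensemble_spec(n_frames = 10, seed = 12)
  expect_false(identical(generate_ensemble(spec2)$ensemble$frames,
                         a$ensemble$frames))
})

test_that("invalid ensemble specs are rejected", {
  expect_error(ensemble_spec(helical_segments = data.frame(
    start = 60, end = 80, occupancy = 1)), "range")
  expect_error(ensemble_spec(helical_segments = data.frame(
    start = c(10, 15), end = c(20, 25), occupancy = c(1, 1))), "overlap")
  expect_error(ensemble_spec(states = data.frame(
    label = "a", weight = 0.5, compactness = 1)), "sum to 1")
  expect_error(ensemble_spec(helical_segments = data.frame(
    start = 10, end = 20, occupancy = 1.2)), "occupancy")
})

test_that("planted deterministic contact schedules are recovered exactly", {
  # charged residues only at the scheduled positions, extended single state
  seqv <- rep("S", 60)
  pos_basic <- c(5, 17, 29, 41, 53)
  pos_acidic <- c(11, 23, 35, 47, 59)
  seqv[pos_basic] <- "K"
  seqv[pos_acidic] <- "E"
  spec <- ensemble_spec(n_residues = 60, helical_segments = data.frame(),
                        states = data.frame(label = "ext", weight = 1,
                                            compactness = 2.5),
                        n_frames = 200, seed = 3,
                        sequence = paste(seqv, collapse = ""))
  syn <- generate_ensemble(spec)
  sched <- contact_schedule(data.frame(i = pos_basic, j = pos_acidic,
                                       persistence = c(0.1, 0.3, 0.5, 0.7, 0.9)))
  pl <- plant_contacts(syn$ensemble, sched)
  pm <- contact_persistence(pl$ensemble, "salt_bridge", 0.5)
  rids <- pm$residue_ids
  got <- pm$matrix[cbind(match(pos_basic, rids), match(pos_acidic, rids))]
  expect_identical(got, c(0.1, 0.3, 0.5, 0.7, 0.9))
  # all unplanted charged pairs stay at zero persistence
  M <- pm$matrix
  M[cbind(match(pos_basic, rids), match(pos_acidic, rids))] <- 0
  M[cbind(match(pos_acidic, rids), match(pos_basic, rids))] <- 0
  expect_equal(sum(M), 0)

  # the planted-mask fraction is the ground truth: 2 of 10 frames -> 0.2
  spec10 <- ensemble_spec(n_residues = 60, helical_segments = data.frame(),
                          states = data.frame(label = "ext", weight = 1,
                                              compactness = 2.5),
                          n_frames = 10, seed = 3,
                          sequence = paste(seqv, collapse = ""))
  syn10 <- generate_ensemble(spec10)
  pl10 <- plant_contacts(syn10$ensemble,
                         contact_schedule(data.frame(i = 5, j = 11,
                                                     persistence = 0.2)))
  pm10 <- contact_persistence(pl10$ensemble, "salt_bridge", 0.5)
  expect_identical(pm10$matrix[match(5, pm10$residue_ids),
                               match(11, pm10$residue_ids)], 0.2)
})

test_that("an empty contact schedule leaves the ensemble unchanged", {
  syn <- generate_ensemble(ensemble_spec(n_frames = 3, seed = 1))
  pl <- plant_contacts(syn$ensemble,
                       contact_schedule(data.frame(i = integer(0),
                                                   j = integer(0),
                                                   persistence = numeric(0))))
  expect_identical(pl$ensemble$frames, syn$ensemble$frames)
})

test_that("synthetic charge-state distributions honour their spec", {
  one <- generate_csd(csd_spec(data.frame(mean = 7, sigma = 0.8, area = 1),
                               z_range = c(1, 15), noise_sigma = 0, seed = 1))
  expect_equal(one$csd$charges[which.max(one$csd$intensities)], 7)

  two <- generate_csd(csd_spec(data.frame(mean = c(7, 14), sigma = c(0.8, 0.8),
                                          area = c(1, 1)),
                               z_range = c(1, 20), noise_sigma = 0, seed = 1))
  y <- two$csd$intensities
  z <- two$csd$charges
  locmax <- z[which(diff(sign(diff(y))) == -2) + 1]
  expect_setequal(locmax, c(7, 14))

  a <- generate_csd(csd_spec(data.frame(mean = 7, sigma = 1, area = 1),
                             noise_sigma = 0.05, seed = 5))
  b <- generate_csd(csd_spec(data.frame(mean = 7, sigma = 1, area = 1),
                             noise_sigma = 0.05, seed = 5))
  expect_identical(a$csd$intensities, b$csd$intensities)
})
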