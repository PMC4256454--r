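# Trajectory analytics: surface plane, distances, binding events,
# min-distance matrices, contact frequencies, domain occupancy

test_that("membrane surface is the mean head-group height of the leaflet", {
  m <- flat_membrane_frame(z_upper = 5, z_lower = 1)
  expect_equal(membrane_surface_z(m, "upper"), 5)
  expect_equal(membrane_surface_z(m, "lower"), 1)
  # alternating heights average
  tbl <- tibble::as_tibble(m)
  tbl$z[tbl$leaflet == "upper"] <- rep(c(4.9, 5.1), length.out = 36)
  m2 <- particle_frame(tbl, box = frame_box(m))
  expect_equal(membrane_surface_z(m2, "upper"), 5)
  # randomised heights equal the brute-force mean over selected beads
  set.seed(4)
  tbl$z[tbl$leaflet == "upper"] <- 5 + rnorm(36, sd = 0.1)
  m3 <- particle_frame(tbl, box = frame_box(m))
  expect_equal(membrane_surface_z(m3, "upper"),
               mean(tbl$z[tbl$leaflet == "upper"]))
  empty <- particle_frame(tbl[tbl$leaflet == "upper", ],
                          box = frame_box(m))
  expect_error(membrane_surface_z(empty, "lower"),
               class = "cyclomem_input_error")
})

test_that("surface distances are signed and zero at the plane", {
  base <- flat_membrane_frame(z_upper = 5)
  up <- add_peptide_bead(base, z = 7)       # 2 nm above
  at <- add_peptide_bead(base, z = 5)       # at the surface
  traj <- cg_trajectory(list(up))
  prof <- residue_surface_distances(traj, "PEP_A")
  expect_equal(prof$distance, 2.0)
  prof0 <- residue_surface_distances(cg_trajectory(list(at)), "PEP_A")
  expect_equal(prof0$distance, 0.0)
  expect_error(residue_surface_distances(traj, "NOPE"),
               class = "cyclomem_input_error")
})

test_that("binding events pick the first frame at or below the threshold", {
  prof <- structure(
    tibble::tibble(frame = 1:4, time = 0:3, molecule = "PEP_A", resid = 19L,
                   resname = "TRP", distance = c(2, 1, -0.1, -0.2)),
    class = c("distance_profile", class(tibble::tibble())))
  ev <- binding_events(prof)
  expect_equal(ev$first_binding_time, 2)
  expect_equal(ev$first_approach_time, 1)
  expect_equal(ev$intervals[[1]]$start_time, 2)
  # all-positive series never binds and yields no intervals
  prof$distance <- c(2, 1.5, 1.2, 1.1)
  ev2 <- binding_events(prof)
  expect_true(is.na(ev2$first_binding_time))
  expect_equal(nrow(ev2$intervals[[1]]), 0)
})

test_that("min-distance matrices match brute force and validate residue counts", {
  fr <- random_molecule_frame(31, n_mol = 3, n_res = 4, beads_per_res = 3)
  mols <- c("A", "B", "C")
  d <- residue_pair_min_distances(fr, mols)
  expect_equal(dim(d), c(12, 12))
  expect_true(isSymmetric(d))
  expect_equal(d, bf_min_dist_matrix(fr, mols))
  # explicit two-bead check
  tbl <- tibble::as_tibble(fr)
  tbl$x[1] <- 1; tbl$y[1] <- 1; tbl$z[1] <- 1
  # inconsistent residue counts error
  bad <- particle_frame(tbl[tbl$molecule != "A" | tbl$resid != 4, ],
                        box = frame_box(fr))
  expect_error(residue_pair_min_distances(bad, mols),
               class = "cyclomem_consistency_error")
})

test_that("contact frequencies are molecule-permutation invariant and frame-poolable", {
  frames <- lapply(1:3, function(s) random_molecule_frame(s, box = 4))
  mols <- c("A", "B", "C", "D")
  cf <- contact_frequency(frames, mols)
  cf_perm <- contact_frequency(frames, c("C", "A", "D", "B"))
  expect_equal(cf$percent, cf_perm$percent)
  # pooled tally equals the count-weighted average of per-frame matrices
  per_frame <- lapply(frames, function(f) contact_frequency(list(f), mols))
  avg <- Reduce(`+`, lapply(per_frame, function(x) x$percent)) / 3
  expect_equal(cf$percent, avg)
  expect_error(contact_frequency(frames, "A"),
               class = "cyclomem_input_error")
})

test_that("domain occupancy classifies ld, lo and interface correctly", {
  # peptide over a pure-DUPC membrane: ld fraction 1
  ld_m <- build_membrane(membrane_spec(ratio = c(1, 0, 0),
                                       n_lipids_per_leaflet = 40,
                                       box_xy = 6, box_z = 12, seed = 3))
  scen <- binding_scenario(binding_targets(29, rep(NA_real_, 29),
                                           t_total = 4, d_far = 1),
                           noise = 0, seed = 1)
  traj <- gen_binding_trajectory(scen, ld_m, n_frames = 5, dt = 1)
  occ <- domain_occupancy(traj, "PEP_A")
  expect_equal(glance(occ)$ld, 1.0)
  # over the DPPC core: lo fraction 1
  lo_m <- build_membrane(membrane_spec(ratio = c(0, 1, 0),
                                       n_lipids_per_leaflet = 40,
                                       box_xy = 6, box_z = 12, seed = 3))
  traj_lo <- gen_binding_trajectory(scen, lo_m, n_frames = 5, dt = 1)
  occ_lo <- domain_occupancy(traj_lo, "PEP_A")
  expect_equal(glance(occ_lo)$lo, 1.0)
  expect_equal(sum(tidy(occ_lo)$fraction), 1, tolerance = 1e-9)
})

test_that("a straddling peptide is classified interface, empty radii warn", {
  # hand-built frame: half DUPC, half DPPC within the radius
  mk_lipid <- function(sp, i, x) tibble::tibble(
    name = "PO4", species = sp, molecule = sprintf("%s_%02d", sp, i),
    resid = i, resname = sp, x = x, y = 3, z = 5,
    type = "Qa", charge = -1, leaflet = "upper", domain = NA_character_)
  tbl <- dplyr::bind_rows(mk_lipid("DUPC", 1, 2.6), mk_lipid("DUPC", 2, 2.8),
                          mk_lipid("DPPC", 3, 3.2), mk_lipid("DPPC", 4, 3.4))
  fr <- add_peptide_bead(particle_frame(tbl, box = c(6, 6, 8)), z = 5.5)
  occ <- domain_occupancy(cg_trajectory(list(fr)), "PEP_A",
                          config = analysis_config(lo_threshold = 0.75,
                                                   domain_radius = 1.5))
  expect_equal(glance(occ)$interface, 1.0)
  # peptide far from every lipid: warning, frame counted as interface
  far <- add_peptide_bead(particle_frame(tbl, box = c(20, 20, 8)),
                          z = 5.5, x = 15, y = 15)
  expect_warning(
    occ2 <- domain_occupancy(cg_trajectory(list(far)), "PEP_A"),
    "no lipid")
  expect_equal(glance(occ2)$interface, 1.0)
})
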