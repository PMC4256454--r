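# Synthetic generators: binding trajectories, tetramer configurations,
# Boltzmann umbrella samples

test_that("zero-noise binding trajectories realise their targets exactly", {
  m <- fixture_membrane()
  t_bind <- rep(NA_real_, 29); t_bind[19] <- 20
  scen <- binding_scenario(binding_targets(29, t_bind, t_total = 40),
                           noise = 0, seed = 1)
  traj <- gen_binding_trajectory(scen, m, n_frames = 41, dt = 1)
  prof <- residue_surface_distances(traj, "PEP_A")
  for (r in c(1, 19, 29)) {
    got <- dplyr::filter(prof, resid == r)
    expect_equal(got$distance, scenario_target(scen, r, got$time),
                 tolerance = 1e-10)
  }
})

test_that("noisy trajectories stay within the noise bound of their targets", {
  m <- fixture_membrane()
  t_bind <- c(rep(NA_real_, 18), 15, 25, rep(NA_real_, 9))
  scen <- binding_scenario(binding_targets(29, t_bind, t_total = 50),
                           noise = 0.05, seed = 8)
  traj <- gen_binding_trajectory(scen, m, n_frames = 51, dt = 1)
  prof <- residue_surface_distances(traj, "PEP_A")
  dev <- vapply(seq_len(nrow(prof)), function(i) {
    prof$distance[i] - scenario_target(scen, prof$resid[i], prof$time[i])
  }, numeric(1))
  expect_lt(mean(abs(dev)), 0.05)
  expect_lt(max(abs(dev)), 5 * 0.05)
})

test_that("a residue held at 2 nm is never classified bound, and inputs validate", {
  m <- fixture_membrane()
  scen <- binding_scenario(binding_targets(29, rep(NA_real_, 29),
                                           t_total = 10, d_far = 2.0),
                           noise = 0, seed = 1)
  traj <- gen_binding_trajectory(scen, m, n_frames = 11, dt = 1)
  ev <- binding_events(residue_surface_distances(traj, "PEP_A"))
  expect_true(all(is.na(ev$first_binding_time)))
  expect_error(gen_binding_trajectory(scen, m, n_frames = 1),
               class = "cyclomem_input_error")
  # same seed -> identical trajectories
  t2 <- gen_binding_trajectory(scen, m, n_frames = 11, dt = 1)
  expect_identical(tibble::as_tibble(traj), tibble::as_tibble(t2))
})

test_that("tetramer configurations realise exactly the requested contact pairs", {
  fr <- gen_tetramer_config(list(c("A", "B"), c("C", "D")))
  mols <- c("A", "B", "C", "D")
  pairs <- combn(mols, 2)
  hits <- vapply(seq_len(ncol(pairs)), function(k) {
    bf_residue_min_dist(fr, pairs[1, k], 1, pairs[2, k], 1) <= 1.2
  }, logical(1))
  expect_equal(sum(hits), 2)
  expect_true(hits[pairs[1, ] == "A" & pairs[2, ] == "B"])
  expect_true(hits[pairs[1, ] == "C" & pairs[2, ] == "D"])
  # empty pair set: nothing in contact
  fr0 <- gen_tetramer_config(list())
  hits0 <- vapply(seq_len(ncol(pairs)), function(k) {
    bf_residue_min_dist(fr0, pairs[1, k], 1, pairs[2, k], 1) <= 1.2
  }, logical(1))
  expect_equal(sum(hits0), 0)
  # all six pairs: downstream contact frequency is 100%
  fr6 <- gen_tetramer_config(as.list(as.data.frame(combn(mols, 2))))
  cf <- contact_frequency(list(fr6), mols)
  expect_equal(cf$percent["1", "1"], 100)
  # shared-molecule pair sets are feasible too (A touches B and C)
  frs <- gen_tetramer_config(list(c("A", "B"), c("A", "C")))
  hs <- vapply(seq_len(ncol(pairs)), function(k) {
    bf_residue_min_dist(frs, pairs[1, k], 1, pairs[2, k], 1) <= 1.2
  }, logical(1))
  expect_equal(sum(hs), 2)
  # infeasible geometry: five contacting pairs with a wide margin force
  # the remaining pair closer than the required separation
  five <- as.list(as.data.frame(combn(mols, 2)))[1:5]
  expect_error(gen_tetramer_config(five, margin = 0.7),
               class = "cyclomem_placement_error")
})

test_that("umbrella samples under a flat potential are Gaussian around each centre", {
  kT <- kBT(310)
  k <- 1500
  wins <- sample_umbrella_windows(function(z) 0 * z, centers = c(-1, 0, 1),
                                  force_constant = k, n_samples = 4000,
                                  seed = 5, grid_range = c(-1.5, 1.5))
  sigma2 <- kT / k
  for (i in 1:3) {
    s <- wins$samples[[i]]
    se_mean <- sqrt(sigma2 / length(s))
    expect_lt(abs(mean(s) - wins$center[i]), 3 * se_mean)
    expect_lt(abs(var(s) - sigma2) / sigma2, 0.1)
  }
})

test_that("harmonic potential plus bias gives the product-of-Gaussians law", {
  kT <- kBT(310)
  a <- 100; z0 <- 0.3; k <- 1500; cc <- 0
  wins <- sample_umbrella_windows(function(z) a * (z - z0)^2, centers = cc,
                                  force_constant = k, n_samples = 6000,
                                  seed = 12, grid_range = c(-1, 1.3))
  prec <- 2 * a + k
  mu <- (2 * a * z0 + k * cc) / prec
  sigma2 <- kT / prec
  s <- wins$samples[[1]]
  expect_lt(abs(mean(s) - mu), 3 * sqrt(sigma2 / length(s)))
  expect_lt(abs(var(s) - sigma2) / sigma2, 0.1)
})

test_that("umbrella sampler is deterministic and converges in distribution", {
  U <- function(z) 20 * z^2
  w1 <- sample_umbrella_windows(U, 0.2, n_samples = 300, seed = 77,
                                grid_range = c(-1, 1))
  w2 <- sample_umbrella_windows(U, 0.2, n_samples = 300, seed = 77,
                                grid_range = c(-1, 1))
  expect_identical(w1$samples, w2$samples)
  # KS distance to the target biased density shrinks with n
  zg <- seq(-1, 1, length.out = 2001)
  logd <- -(U(zg) + 0.5 * 1500 * (zg - 0.2)^2) / kBT(310)
  small <- sample_umbrella_windows(U, 0.2, n_samples = 300, seed = 3,
                                   grid_range = c(-1, 1))
  big <- sample_umbrella_windows(U, 0.2, n_samples = 30000, seed = 3,
                                 grid_range = c(-1, 1))
  ks_small <- bf_ks_distance(small$samples[[1]], zg, logd)
  ks_big <- bf_ks_distance(big$samples[[1]], zg, logd)
  expect_lt(ks_big, ks_small)
  expect_lt(ks_big, 0.02)
  # invalid thermal energy
  expect_error(sample_umbrella_windows(U, 0.2, temperature = -5,
                                       n_samples = 300),
               class = "cyclomem_input_error")
  expect_error(sample_umbrella_windows(U, 0.2, n_samples = 50),
               class = "cyclomem_input_error")
})
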