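# GRO/PDB structure reading, trajectory round trips, umbrella-sample files

test_that("GRO write/read round-trips positions, box and metadata", {
  fr <- particle_frame(
    tibble::tibble(name = c("BB", "SC1", "W"), species = c("PEP", "PEP", "W"),
                   molecule = c("M1", "M1", "M2"), resid = c(1L, 1L, 2L),
                   resname = c("TRP", "TRP", "W"),
                   x = c(1.234, 2.3456, 0.001), y = c(0.5, 1.5, 2.5),
                   z = c(3.333, 4.444, 5.555)),
    box = c(6, 7, 8), time = 2.5)
  path <- withr::local_tempfile(fileext = ".gro")
  write_structure(fr, path)
  back <- read_structure(path)
  expect_equal(nrow(back), 3)
  expect_equal(back$x, fr$x, tolerance = 1e-3)
  expect_equal(back$z, fr$z, tolerance = 1e-3)
  expect_equal(frame_box(back), c(6, 7, 8))
  expect_equal(frame_time(back), 2.5)
  expect_equal(back$resname, fr$resname)
  expect_equal(back$name, fr$name)
  # canonical formatting: a second write of the re-read frame is
  # byte-identical
  path2 <- withr::local_tempfile(fileext = ".gro")
  write_structure(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("malformed and empty GRO files raise parse errors with location", {
  p <- withr::local_tempfile(fileext = ".gro")
  writeLines(character(0), p)
  expect_error(read_structure(p), class = "cyclomem_parse_error")
  fr <- particle_frame(
    tibble::tibble(name = c("BB", "SC1"), species = "PEP", molecule = "M1",
                   resid = 1L, resname = "TRP", x = 1:2, y = 1:2, z = 1:2),
    box = c(5, 5, 5))
  write_structure(fr, p)
  lines <- readLines(p)
  substr(lines[4], 21, 28) <- "  x.000 "  # corrupt a coordinate field
  writeLines(lines, p)
  expect_error(read_structure(p), "4", class = "cyclomem_parse_error")
  expect_error(read_structure("no_such_file.gro"),
               class = "cyclomem_io_error")
  p2 <- withr::local_tempfile(fileext = ".xyz")
  file.create(p2)
  expect_error(read_structure(p2), class = "cyclomem_format_error")
})

test_that("PDB coordinates are converted from Angstrom to nm", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "CRYST1   50.000   50.000   50.000  90.00  90.00  90.00 P 1           1",
    "ATOM      1  CA  GLY A   1      10.000  20.000  30.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2      15.000  25.000  35.000  1.00  0.00           C",
    "END"), p)
  fr <- read_structure(p)
  expect_equal(fr$x[1], 1.0)
  expect_equal(fr$y[1], 2.0)
  expect_equal(fr$z[1], 3.0)
  expect_equal(frame_box(fr), c(5, 5, 5))
  expect_equal(fr$resname, c("GLY", "ALA"))
})

test_that("multi-frame GRO trajectories round-trip and validate topology", {
  frames <- lapply(0:4, function(i) {
    particle_frame(
      tibble::tibble(name = "W", species = "W", molecule = paste0("W", 1:3),
                     resid = 1:3, resname = "W",
                     x = c(1, 2, 3) + i * 0.01, y = 1:3, z = c(0.5, 1, 1.5)),
      box = c(5, 5, 5), time = i * 0.1)
  })
  traj <- cg_trajectory(frames)
  expect_equal(n_frames(traj), 5)
  path <- withr::local_tempfile(fileext = ".gro")
  write_trajectory(traj, path)
  back <- read_trajectory(path)
  expect_equal(n_frames(back), 5)
  expect_equal(back$x, traj$x, tolerance = 1e-3)
  expect_equal(traj_boxes(back)$time, traj_boxes(traj)$time)
  # topology metadata override and count validation
  top <- frames[[1]]
  back2 <- read_trajectory(path, topology_frame = top)
  expect_equal(unique(back2$molecule), c("W1", "W2", "W3"))
  small <- particle_frame(tibble::as_tibble(top)[1:2, ], box = c(5, 5, 5))
  expect_error(read_trajectory(path, topology_frame = small),
               class = "cyclomem_consistency_error")
  # empty file is an error, not an empty trajectory
  empty <- withr::local_tempfile(fileext = ".gro")
  file.create(empty)
  expect_error(read_trajectory(empty), class = "cyclomem_parse_error")
})

test_that("umbrella-sample files round-trip with sidecar metadata", {
  centers <- make_window_centers(-2, 2, 0.1) # 41
  centers <- c(centers, 0.05, 0.15)          # plus additional windows: 43
  wins <- sample_umbrella_windows(function(z) 0 * z, centers,
                                  force_constant = 1500, n_samples = 120,
                                  seed = 3, grid_range = c(-2.5, 2.5))
  dir <- withr::local_tempdir()
  write_umbrella_windows(wins, dir)
  meta <- readr::read_tsv(file.path(dir, "windows_meta.tsv"),
                          show_col_types = FALSE)
  back <- read_umbrella_windows(file.path(dir, meta$path), meta)
  expect_equal(nrow(back), 43)
  expect_equal(back$n_samples, rep(120L, 43))
  expect_equal(back$center, centers)
  expect_equal(back$samples[[1]], wins$samples[[1]], tolerance = 1e-5)
  # duplicate bias centres are allowed: both records kept
  dup <- read_umbrella_windows(file.path(dir, meta$path[c(1, 1)]),
                               meta[c(1, 1), ])
  expect_equal(nrow(dup), 2)
})

test_that("umbrella parser skips comment headers and flags bad rows", {
  p <- withr::local_tempfile(fileext = ".xvg")
  writeLines(c("# header", "@ xmgrace legend", "0.0 1.5", "0.1 1.6"), p)
  w <- read_umbrella_windows(p, tibble::tibble(center = 1.5,
                                               force_constant = 1500))
  expect_equal(w$samples[[1]], c(1.5, 1.6))
  writeLines(c("0.0 1.5", "0.1 oops"), p)
  expect_error(
    read_umbrella_windows(p, tibble::tibble(center = 1.5,
                                            force_constant = 1500)),
    "oops", class = "cyclomem_parse_error")
})
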