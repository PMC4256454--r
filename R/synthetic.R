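# Synthetic inputs with known ground truth: approach-and-binding
# trajectories with controllable per-residue binding times, tetramer
# configurations with a prescribed set of contacting molecule pairs, and
# umbrella-window samples drawn exactly from the biased Boltzmann density
# of a user-specified 1-D potential. Every generator is a pure function of
# (spec, seed).

#' Define a per-residue binding scenario
#'
#' Target distances to the membrane surface are piecewise-linear in time:
#' `targets` holds breakpoints (columns `resid`, `time` in ns, `distance`
#' in nm) interpolated linearly and extended as constants beyond the first
#' and last breakpoint. Gaussian noise of amplitude `noise` nm is added at
#' generation time.
#'
#' @param targets Breakpoint tibble (`resid`, `time`, `distance`).
#' @param noise Noise standard deviation (nm).
#' @param seed Integer seed.
#' @return A `binding_scenario` object.
#' @seealso [binding_targets()] for the common approach/plateau shape.
#' @export
binding_scenario <- function(targets, noise = 0.04, seed = 1L) {
  targets <- tibble::as_tibble(targets)
  stopifnot(all(c("resid", "time", "distance") %in% names(targets)))
  if (any(targets$distance < -2.0)) {
    abort("Target distances must stay >= -2.0 nm (membrane centre bound).",
          class = "cyclomem_input_error")
  }
  bad <- dplyr::summarise(dplyr::group_by(targets, .data$resid),
                          unsorted = is.unsorted(.data$time))
  if (any(bad$unsorted)) {
    abort("Breakpoint times must be nondecreasing within each residue.",
          class = "cyclomem_input_error")
  }
  structure(list(targets = targets, noise = noise, seed = as.integer(seed)),
            class = "binding_scenario")
}

#' Breakpoints for an approach-then-bind distance course
#'
#' Each residue starts at `d_far`, approaches linearly to `d_pre` just
#' before its binding time, then steps to the bound plateau `d_bound`
#' (below the surface) at `t_bind` and stays there. Residues with
#' `t_bind = NA` remain at `d_far`. Optional unbind/rebind events can be
#' appended as extra breakpoints afterwards.
#'
#' @param n_residues Number of residues.
#' @param t_bind Numeric vector (length `n_residues`) of binding times in
#'   ns; `NA` means the residue never binds.
#' @param t_total Total scenario duration (ns).
#' @param d_far,d_pre,d_bound Distances (nm) far from, just above, and
#'   below the surface.
#' @param approach_gap Time (ns) between reaching `d_pre` and dropping to
#'   `d_bound`; keep at or below the frame spacing so the zero crossing
#'   happens within one frame.
#' @return A breakpoint tibble for [binding_scenario()].
#' @export
binding_targets <- function(n_residues, t_bind, t_total,
                            d_far = 2.0, d_pre = 0.25, d_bound = -0.4,
                            approach_gap = 1) {
  stopifnot(length(t_bind) == n_residues)
  purrr::list_rbind(lapply(seq_len(n_residues), function(r) {
    tb <- t_bind[r]
    if (is.na(tb)) {
      tibble::tibble(resid = r, time = c(0, t_total),
                     distance = c(d_far, d_far))
    } else {
      tibble::tibble(resid = r,
                     time = c(0, max(tb - approach_gap, 0), tb, t_total),
                     distance = c(d_far, d_pre, d_bound, d_bound))
    }
  }))
}

#' Evaluate a scenario's target distance
#'
#' @param scenario A [binding_scenario()].
#' @param resid Residue index.
#' @param time Times (ns).
#' @return Target distances (nm).
#' @export
scenario_target <- function(scenario, resid, time) {
  tb <- dplyr::filter(scenario$targets, .data$resid == !!resid)
  if (nrow(tb) == 0) {
    abort(sprintf("Scenario has no targets for residue %d.", resid),
          class = "cyclomem_input_error")
  }
  if (nrow(tb) == 1) return(rep(tb$distance, length(time)))
  approx(tb$time, tb$distance, xout = time, rule = 2,
         ties = list("ordered", mean))$y
}

#' Generate a synthetic binding trajectory
#'
#' A rigid one-bead-per-residue peptide ring hovers over a static membrane
#' frame; each residue's height above the upper head-group plane follows
#' its scenario target plus Gaussian noise. Internal peptide dynamics are
#' not emulated. Deterministic given the scenario seed.
#'
#' @param scenario A [binding_scenario()] covering every residue.
#' @param membrane_model A membrane [particle_frame()] (from
#'   [build_membrane()]).
#' @param n_frames Number of frames (>= 2).
#' @param dt Frame spacing (ns).
#' @param sequence Peptide sequence used for residue names.
#' @param molecule Molecule id of the peptide.
#' @param xy Lateral position of the peptide ring centre (nm); defaults to
#'   the box centre (over the lo core of a raft membrane).
#' @return A [cg_trajectory()] of membrane plus peptide beads.
#' @export
gen_binding_trajectory <- function(scenario, membrane_model, n_frames, dt = 1,
                                   sequence = kb1_sequence(),
                                   molecule = "PEP_A", xy = NULL) {
  stopifnot(inherits(scenario, "binding_scenario"))
  if (n_frames < 2) {
    abort("`n_frames` must be at least 2.", class = "cyclomem_input_error")
  }
  res <- parse_sequence(sequence)
  n_res <- nrow(res)
  covered <- unique(scenario$targets$resid)
  if (!all(res$resid %in% covered)) {
    abort("Scenario must cover every residue of the peptide.",
          class = "cyclomem_input_error")
  }
  box <- frame_box(membrane_model)
  surface <- membrane_surface_z(membrane_model, leaflet = "upper")
  xy <- xy %||% (box[1:2] / 2)
  theta <- 2 * pi * (res$resid - 1) / n_res
  px <- xy[1] + 0.5 * cos(theta)
  py <- xy[2] + 0.5 * sin(theta)
  mem_tbl <- tibble::as_tibble(membrane_model)
  if (!"type" %in% names(mem_tbl)) mem_tbl$type <- NA_character_
  if (!"charge" %in% names(mem_tbl)) mem_tbl$charge <- 0
  times <- (seq_len(n_frames) - 1) * dt
  target_mat <- vapply(res$resid,
                       function(r) scenario_target(scenario, r, times),
                       numeric(n_frames))
  noise_mat <- withr::with_seed(scenario$seed, {
    matrix(rnorm(n_frames * n_res, sd = scenario$noise), n_frames, n_res)
  })
  z_mat <- surface + target_mat + noise_mat
  frames <- lapply(seq_len(n_frames), function(i) {
    pep <- tibble::tibble(
      name = "BB", species = "PEP", molecule = molecule,
      resid = res$resid, resname = res$resname,
      x = px, y = py, z = z_mat[i, ],
      type = "P5", charge = 0,
      leaflet = NA_character_, domain = NA_character_)
    particle_frame(dplyr::bind_rows(mem_tbl, pep), box = box,
                   time = times[i])
  })
  cg_trajectory(frames)
}

# normalise contacting-pair input to a 2-column character matrix
normalize_pairs <- function(contacting_pairs, molecules) {
  if (length(contacting_pairs) == 0) {
    return(matrix(character(0), ncol = 2))
  }
  if (is.character(contacting_pairs)) {
    contacting_pairs <- strsplit(contacting_pairs, "-", fixed = TRUE)
  }
  pm <- do.call(rbind, lapply(contacting_pairs, function(p) {
    if (length(p) != 2 || p[1] == p[2] || !all(p %in% molecules)) {
      abort("Contacting pairs must name two distinct molecules among A-D.",
            class = "cyclomem_input_error")
    }
    sort(p)
  }))
  unique(pm)
}

#' Generate a tetramer frame with prescribed contacting pairs
#'
#' Places four one-bead-per-residue molecules so that the designated
#' residue's minimum inter-molecular bead distance is at most
#' `cutoff - margin` for every listed molecule pair and at least
#' `cutoff + margin` for every unlisted pair (verified by a brute-force
#' scan; infeasible geometries raise a placement error). All other residue
#' pairs are kept beyond `cutoff + margin`.
#'
#' @param contacting_pairs Pairs of molecule labels among `"A".."D"`,
#'   as a list of length-2 vectors or strings like `"A-B"`.
#' @param residue Designated residue index (default 1, i.e. Cys1).
#' @param cutoff Contact cutoff (nm).
#' @param margin Separation margin (nm).
#' @param sequence Peptide sequence for residue names.
#' @param box_len Cubic box edge (nm).
#' @return A [particle_frame()] with molecules `A`, `B`, `C`, `D`.
#' @examples
#' fr <- gen_tetramer_config(list(c("A", "B"), c("C", "D")))
#' @export
gen_tetramer_config <- function(contacting_pairs, residue = 1, cutoff = 1.2,
                                margin = 0.2, sequence = kb1_sequence(),
                                box_len = 30) {
  mols <- c("A", "B", "C", "D")
  pairs <- normalize_pairs(contacting_pairs, mols)
  d_in <- cutoff - margin
  d_out <- cutoff + margin
  if (d_in <= 0) {
    abort("Placement error: margin leaves no room inside the cutoff.",
          class = "cyclomem_placement_error")
  }
  all_pairs <- t(utils::combn(mols, 2))
  is_edge <- apply(all_pairs, 1, function(p) {
    any(pairs[, 1] == p[1] & pairs[, 2] == p[2])
  })

  # lay out the four designated beads: edges at ~0.98*d_in, non-edges
  # pushed past 1.05*d_out, by least squares on 12 coordinates
  init <- as.vector(t(cbind(2.2 * cos(seq(0, 3) * pi / 2),
                            2.2 * sin(seq(0, 3) * pi / 2),
                            c(0, 0.1, 0, 0.1))))
  idx <- matrix(match(as.vector(all_pairs), mols), ncol = 2)
  loss <- function(par) {
    p <- matrix(par, ncol = 3, byrow = TRUE)
    d <- sqrt(rowSums((p[idx[, 1], ] - p[idx[, 2], ])^2))
    sum(ifelse(is_edge, (d - 0.98 * d_in)^2,
               pmax(0, 1.05 * d_out - d)^2))
  }
  fit <- optim(init, loss, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  p <- matrix(fit$par, ncol = 3, byrow = TRUE)
  d_fit <- sqrt(rowSums((p[idx[, 1], ] - p[idx[, 2], ])^2))
  if (any(d_fit[is_edge] > d_in) || any(d_fit[!is_edge] < d_out)) {
    abort("Placement error: contact-pair geometry infeasible at this margin.",
          class = "cyclomem_placement_error")
  }

  res <- parse_sequence(sequence)
  n_res <- nrow(res)
  if (residue < 1 || residue > n_res) {
    abort("`residue` is outside the peptide.", class = "cyclomem_input_error")
  }
  dirs <- matrix(c(1, 1, 1, 1, -1, -1, -1, 1, -1, -1, -1, 1),
                 ncol = 3, byrow = TRUE) / sqrt(3)
  ctr <- box_len / 2
  frame <- purrr::list_rbind(lapply(seq_along(mols), function(m) {
    others <- setdiff(res$resid, residue)
    pos <- matrix(0, n_res, 3)
    pos[residue, ] <- p[m, ]
    pos[others, ] <- matrix(p[m, ], length(others), 3, byrow = TRUE) +
      outer(3.0 + 0.35 * seq_along(others), dirs[m, ])
    tibble::tibble(
      name = "BB", species = "PEP", molecule = mols[m],
      resid = res$resid, resname = res$resname,
      x = pos[, 1] + ctr, y = pos[, 2] + ctr, z = pos[, 3] + ctr,
      type = "P5", charge = 0)
  }))
  out <- particle_frame(frame, box = rep(box_len, 3), time = 0)

  # brute-force verification of the designated residue's pair distances
  for (k in seq_len(nrow(all_pairs))) {
    a <- dplyr::filter(out, .data$molecule == all_pairs[k, 1],
                       .data$resid == residue)
    b <- dplyr::filter(out, .data$molecule == all_pairs[k, 2],
                       .data$resid == residue)
    d <- min(pair_dist_matrix(a[, c("x", "y", "z")], b[, c("x", "y", "z")],
                              frame_box(out)))
    ok <- if (is_edge[k]) d <= cutoff - margin else d >= cutoff + margin
    if (!ok) {
      abort("Placement error: verification of contact geometry failed.",
            class = "cyclomem_placement_error")
    }
  }
  out
}

#' Draw umbrella-window samples from a biased 1-D potential
#'
#' For each window centre `c_i`, samples are drawn i.i.d. from the density
#' proportional to `exp(-(U(z) + k/2 (z - c_i)^2) / kBT)` by inverse-CDF
#' sampling on a fine grid (exact up to grid resolution). Deterministic
#' given `seed`.
#'
#' @param potential A function `U(z)` (kJ/mol) or a two-column data frame
#'   (`z`, `U`) defining it on a grid.
#' @param centers Window centres (nm); must lie inside the grid.
#' @param force_constant Harmonic bias constant (kJ/(mol nm^2)).
#' @param n_samples Samples per window (>= 100).
#' @param temperature Temperature (K).
#' @param seed Integer seed.
#' @param grid_range Grid range (nm); defaults to the potential table's
#'   range, or the centre range widened by 1 nm for a function.
#' @param n_grid Grid size.
#' @return An [umbrella_windows()] tibble.
#' @examples
#' w <- sample_umbrella_windows(function(z) 50 * z^2, centers = c(-0.5, 0, 0.5),
#'                              n_samples = 200, seed = 7)
#' @export
sample_umbrella_windows <- function(potential, centers, force_constant = 1500,
                                    n_samples = 1000, temperature = 310,
                                    seed = 1L, grid_range = NULL,
                                    n_grid = 4001) {
  if (temperature <= 0) {
    abort("Temperature (hence kBT) must be > 0.",
          class = "cyclomem_input_error")
  }
  if (n_samples < 100) {
    abort("`n_samples` must be >= 100.", class = "cyclomem_input_error")
  }
  if (is.data.frame(potential)) {
    stopifnot(all(c("z", "U") %in% names(potential)))
    if (any(!is.finite(potential$U))) {
      abort("Potential must be finite on its grid.",
            class = "cyclomem_input_error")
    }
    grid_range <- grid_range %||% range(potential$z)
    U <- approxfun(potential$z, potential$U, rule = 2)
  } else {
    stopifnot(is.function(potential))
    grid_range <- grid_range %||% (range(centers) + c(-1, 1))
    U <- potential
  }
  if (any(centers < grid_range[1] | centers > grid_range[2])) {
    abort("All window centres must lie inside the potential grid.",
          class = "cyclomem_input_error")
  }
  zg <- seq(grid_range[1], grid_range[2], length.out = n_grid)
  Ug <- U(zg)
  if (any(!is.finite(Ug))) {
    abort("Potential must be finite on the sampling grid.",
          class = "cyclomem_input_error")
  }
  kT <- kBT(temperature)
  samples <- withr::with_seed(seed, {
    lapply(centers, function(cc) {
      logd <- -(Ug + 0.5 * force_constant * (zg - cc)^2) / kT
      dens <- exp(logd - max(logd))
      cdf <- cumsum((dens[-1] + dens[-n_grid]) / 2)
      cdf <- c(0, cdf / cdf[n_grid - 1])
      u <- runif(n_samples)
      approx(cdf, zg, xout = u, ties = list("ordered", min))$y
    })
  })
  umbrella_windows(centers, force_constant, samples,
                   temperature = temperature)
}
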