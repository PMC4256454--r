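# Nonbonded interaction energies between named bead groups: force-shifted
# Lennard-Jones 12-6 plus force-shifted Coulomb with a uniform relative
# permittivity, both exactly zero at the 1.2 nm cutoff (the standard CG
# nonbonded form). Group-pair means/sds over frames and loop-to-loop
# percentage decompositions.

.f_elec <- 138.935458  # Coulomb prefactor, kJ mol^-1 nm e^-2

#' Nonbonded parameter set
#'
#' Loads the packaged bead-type-pair Lennard-Jones table and wraps it with
#' the interaction-form constants: cutoff 1.2 nm, LJ shift onset 0.9 nm,
#' Coulomb shifted from 0, relative permittivity 15.
#'
#' @param cutoff Cutoff (nm).
#' @param shift_start LJ shift onset (nm); must be < cutoff.
#' @param epsilon_r Relative permittivity.
#' @param pairs Optional replacement pair table (columns `type_a`,
#'   `type_b`, `epsilon`, `sigma`).
#' @return An `nb_params` list.
#' @export
nonbonded_params <- function(cutoff = 1.2, shift_start = 0.9,
                             epsilon_r = 15, pairs = NULL) {
  if (shift_start < 0 || cutoff <= shift_start) {
    abort("Need cutoff > shift_start >= 0.", class = "cyclomem_input_error")
  }
  if (is.null(pairs)) {
    if (is.null(.cyclomem_cache$nb_pairs)) {
      path <- system.file("extdata", "cg_nonbonded_pairs.csv",
                          package = "cyclomem", mustWork = TRUE)
      .cyclomem_cache$nb_pairs <- readr::read_csv(path,
                                                  show_col_types = FALSE)
    }
    pairs <- .cyclomem_cache$nb_pairs
  }
  pairs <- tibble::as_tibble(pairs)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  lut_eps <- setNames(pairs$epsilon, key(pairs$type_a, pairs$type_b))
  lut_sig <- setNames(pairs$sigma, key(pairs$type_a, pairs$type_b))
  structure(list(pairs = pairs, lut_eps = lut_eps, lut_sig = lut_sig,
                 cutoff = cutoff, shift_start = shift_start,
                 epsilon_r = epsilon_r),
            class = "nb_params")
}

# force-shift coefficients for an r^-p term (GROMACS shift function):
# the force and its derivative vanish at the cutoff, the potential is
# shifted to exactly zero there.
shift_coefs <- function(p, r1, rc) {
  A <- -p * ((p + 4) * rc - (p + 1) * r1) / (rc^(p + 2) * (rc - r1)^2)
  B <- p * ((p + 3) * rc - (p + 1) * r1) / (rc^(p + 2) * (rc - r1)^3)
  C <- 1 / rc^p - A / 3 * (rc - r1)^3 - B / 4 * (rc - r1)^4
  list(A = A, B = B, C = C)
}

# shifted r^-p potential term, vectorised over r; zero at/beyond rc
shifted_power <- function(r, p, r1, rc) {
  cf <- shift_coefs(p, r1, rc)
  out <- r^(-p) - cf$C
  past <- r > r1
  out[past] <- out[past] - (cf$A / 3 * (r[past] - r1)^3 +
                            cf$B / 4 * (r[past] - r1)^4)
  out[r >= rc] <- 0
  out
}

lookup_pair <- function(params, type_i, type_j) {
  key <- paste(pmin(type_i, type_j), pmax(type_i, type_j), sep = "|")
  eps <- unname(params$lut_eps[key])
  sig <- unname(params$lut_sig[key])
  if (anyNA(eps)) {
    abort(sprintf("Unknown bead-type pair(s): %s",
                  paste(unique(key[is.na(eps)]), collapse = ", ")),
          class = "cyclomem_parameter_error")
  }
  list(eps = eps, sig = sig)
}

#' Nonbonded pair energy
#'
#' Force-shifted Lennard-Jones 12-6 plus force-shifted Coulomb
#' (`f q_i q_j / (eps_r r)`), both smoothly zero at the cutoff. Vectorised
#' over `r` (and over the type/charge vectors).
#'
#' @param r Distances (nm), > 0.
#' @param type_i,type_j Bead types.
#' @param params An [nonbonded_params()].
#' @param q_i,q_j Charges (e).
#' @return Energies (kJ/mol).
#' @examples
#' p <- nonbonded_params()
#' pair_energy(seq(0.4, 1.3, by = 0.1), "P4", "P4", p)
#' @export
pair_energy <- function(r, type_i, type_j, params = nonbonded_params(),
                        q_i = 0, q_j = 0) {
  if (any(r <= 0)) {
    abort("Pair distances must be > 0.", class = "cyclomem_input_error")
  }
  lj <- lookup_pair(params, type_i, type_j)
  rc <- params$cutoff
  r1 <- params$shift_start
  e_lj <- 4 * lj$eps * (lj$sig^12 * shifted_power(r, 12, r1, rc) -
                        lj$sig^6 * shifted_power(r, 6, r1, rc))
  e_el <- (.f_elec / params$epsilon_r) * q_i * q_j *
    shifted_power(r, 1, 0, rc)
  e_lj + e_el
}

# total nonbonded energy between two bead sets of one frame
frame_group_energy <- function(tbl, idx_a, idx_b, box, params) {
  if (length(idx_a) == 0 || length(idx_b) == 0) return(0)
  d <- pair_dist_matrix(tbl[idx_a, c("x", "y", "z")],
                        tbl[idx_b, c("x", "y", "z")], box)
  hit <- which(d < params$cutoff & d > 0, arr.ind = TRUE)
  if (nrow(hit) == 0) return(0)
  ia <- idx_a[hit[, 1]]
  ib <- idx_b[hit[, 2]]
  sum(pair_energy(d[hit], tbl$type[ia], tbl$type[ib], params,
                  q_i = tbl$charge[ia], q_j = tbl$charge[ib]))
}

require_energy_cols <- function(tbl) {
  if (!all(c("type", "charge") %in% names(tbl))) {
    abort("Frames need `type` and `charge` columns for energy evaluation.",
          class = "cyclomem_input_error")
  }
}

#' Interaction energy between two bead groups over a trajectory
#'
#' Per-frame energy is the sum of [pair_energy()] over all inter-group
#' bead pairs within the cutoff; the mean and standard deviation over
#' frames are reported. Groups must be disjoint.
#'
#' @param traj A [cg_trajectory()] (or single [particle_frame()]); frames
#'   need `type` and `charge` columns.
#' @param group_a,group_b Particle row indices (within a frame), e.g. from
#'   [select_particles()].
#' @param params An [nonbonded_params()].
#' @param frame_range Optional length-2 frame-index range.
#' @return A tibble: `mean`, `sd`, `n_frames`, plus the per-frame energies
#'   as a list column `energies`.
#' @export
group_interaction_energy <- function(traj, group_a, group_b,
                                     params = nonbonded_params(),
                                     frame_range = NULL) {
  if (length(intersect(group_a, group_b)) > 0) {
    abort("Groups overlap; energies would be double-counted.",
          class = "cyclomem_input_error")
  }
  frames <- if (inherits(traj, "particle_frame")) list(traj)
            else traj_frames(traj)
  if (!is.null(frame_range)) {
    if (frame_range[1] < 1 || frame_range[2] > length(frames)) {
      abort("`frame_range` lies outside the trajectory.",
            class = "cyclomem_input_error")
    }
    frames <- frames[seq(frame_range[1], frame_range[2])]
  }
  energies <- vapply(frames, function(f) {
    tbl <- tibble::as_tibble(f)
    require_energy_cols(tbl)
    frame_group_energy(tbl, group_a, group_b, frame_box(f), params)
  }, numeric(1))
  tibble::tibble(mean = mean(energies),
                 sd = if (length(energies) > 1) sd(energies) else 0,
                 n_frames = length(energies), energies = list(energies))
}

#' Inter-molecular loop-to-loop energy decomposition
#'
#' Computes the 21 unordered loop-pair interaction energies (6 loops)
#' between *different* molecules, plus the cysteine group's pairs when
#' requested, and reports each pair's percentage of the summed total over
#' the declared partition.
#'
#' @param traj A [cg_trajectory()] or [particle_frame()] with `type`,
#'   `charge` and `resid` columns.
#' @param loop_assignment Residue-to-loop table from [assign_loops()].
#' @param molecules Molecule ids of the peptides (>= 2).
#' @param params An [nonbonded_params()].
#' @param frame_range Optional frame-index range.
#' @param include_cys Include the cysteine group in the partition.
#' @return An `interaction_energy_report` tibble: `group_a`, `group_b`,
#'   `mean`, `sd`, `percent`, with the partition recorded as an attribute.
#' @export
loop_decomposition <- function(traj, loop_assignment, molecules,
                               params = nonbonded_params(),
                               frame_range = NULL, include_cys = FALSE) {
  frames <- if (inherits(traj, "particle_frame")) list(traj)
            else traj_frames(traj)
  if (!is.null(frame_range)) {
    frames <- frames[seq(frame_range[1], frame_range[2])]
  }
  groups <- paste0("loop", 1:6)
  if (include_cys) groups <- c(groups, "cys")
  pair_grid <- expand.grid(a = seq_along(groups), b = seq_along(groups))
  pair_grid <- pair_grid[pair_grid$a <= pair_grid$b, ]

  per_frame <- lapply(frames, function(f) {
    tbl <- tibble::as_tibble(f)
    require_energy_cols(tbl)
    tbl <- dplyr::filter(tbl, .data$molecule %in% molecules)
    tbl <- dplyr::left_join(tbl,
                            loop_assignment[, c("resid", "loop")],
                            by = "resid")
    if (anyNA(tbl$loop)) {
      abort("Loop assignment must cover every peptide residue.",
            class = "cyclomem_input_error")
    }
    box <- frame_box(f)
    # all inter-molecular bead pairs within cutoff, each counted once
    d <- pair_dist_matrix(tbl[, c("x", "y", "z")],
                          tbl[, c("x", "y", "z")], box)
    hit <- which(upper.tri(d) & d < params$cutoff & d > 0, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      inter <- tbl$molecule[hit[, 1]] != tbl$molecule[hit[, 2]]
      hit <- hit[inter, , drop = FALSE]
    }
    e_pair <- if (nrow(hit) > 0) {
      pair_energy(d[hit], tbl$type[hit[, 1]], tbl$type[hit[, 2]], params,
                  q_i = tbl$charge[hit[, 1]], q_j = tbl$charge[hit[, 2]])
    } else numeric(0)
    la <- tbl$loop[hit[, 1]]
    lb <- tbl$loop[hit[, 2]]
    vapply(seq_len(nrow(pair_grid)), function(k) {
      ga <- groups[pair_grid$a[k]]
      gb <- groups[pair_grid$b[k]]
      sum(e_pair[(la == ga & lb == gb) | (la == gb & lb == ga)])
    }, numeric(1))
  })
  emat <- do.call(rbind, per_frame)  # frames x group pairs
  means <- colMeans(emat)
  sds <- if (nrow(emat) > 1) apply(emat, 2, sd) else rep(0, ncol(emat))
  total <- sum(means)
  out <- tibble::tibble(
    group_a = groups[pair_grid$a], group_b = groups[pair_grid$b],
    mean = means, sd = sds,
    percent = if (abs(total) > 0) 100 * means / total else NA_real_)
  structure(out, partition = groups, total_mean = total,
            n_frames = nrow(emat),
            class = c("interaction_energy_report", class(tibble::tibble())))
}
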