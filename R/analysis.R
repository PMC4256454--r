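# Trajectory analytics: per-residue distance to the membrane surface
# (head-group plane), binding detection, the residue contact-frequency
# matrix (per-frame minimum-distance matrices reduced to residue-pair
# contact percentages), and lipid-domain occupancy classification.

#' Analysis configuration
#'
#' @param contact_cutoff Residue-residue contact cutoff (nm); beads at or
#'   below this distance are "in contact".
#' @param approach_threshold Distance (nm) below which a residue counts as
#'   approaching the membrane.
#' @param bound_threshold A residue is bound while its surface distance is
#'   at or below this value (0 = at/below the head-group plane).
#' @param domain_radius Lateral radius (nm) for lipid-domain occupancy.
#' @param lo_threshold Fraction of lo-species lipids (DPPC+CHOL) at or
#'   above which a frame is classified `lo`; at or below `1 - lo_threshold`
#'   it is `ld`, otherwise `interface`.
#' @param head_name Bead name defining the head-group plane.
#' @param time_range Optional length-2 time window (ns) for averaging.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(contact_cutoff = 1.2, approach_threshold = 1.5,
                            bound_threshold = 0, domain_radius = 1.5,
                            lo_threshold = 0.75, head_name = "PO4",
                            time_range = NULL) {
  if (contact_cutoff <= 0) {
    abort("`contact_cutoff` must be > 0.", class = "cyclomem_input_error")
  }
  if (lo_threshold <= 0 || lo_threshold >= 1) {
    abort("`lo_threshold` must lie in (0, 1).",
          class = "cyclomem_input_error")
  }
  structure(list(contact_cutoff = contact_cutoff,
                 approach_threshold = approach_threshold,
                 bound_threshold = bound_threshold,
                 domain_radius = domain_radius,
                 lo_threshold = lo_threshold,
                 head_name = head_name, time_range = time_range),
            class = "analysis_config")
}

#' Height of the membrane surface plane
#'
#' The membrane surface is defined as the mean z of the head-group beads
#' (default `PO4`) of the requested leaflet. Leaflet membership comes from
#' a `leaflet` metadata column when present, otherwise from each head
#' bead's position relative to the mean head-bead height.
#'
#' @param frame A [particle_frame()] containing membrane beads.
#' @param leaflet `"upper"` or `"lower"`.
#' @param head_name Head-group bead name.
#' @return Surface height z (nm).
#' @export
membrane_surface_z <- function(frame, leaflet = c("upper", "lower"),
                               head_name = "PO4") {
  leaflet <- match.arg(leaflet)
  tbl <- tibble::as_tibble(frame)
  heads <- dplyr::filter(tbl, .data$name == head_name)
  if (nrow(heads) == 0) {
    abort(sprintf("No '%s' head-group beads in the frame.", head_name),
          class = "cyclomem_input_error")
  }
  if ("leaflet" %in% names(heads) && !all(is.na(heads$leaflet))) {
    sel <- dplyr::filter(heads, .data$leaflet == !!leaflet)
  } else {
    mid <- mean(heads$z)
    sel <- if (leaflet == "upper") dplyr::filter(heads, .data$z >= mid)
           else dplyr::filter(heads, .data$z < mid)
  }
  if (nrow(sel) == 0) {
    abort(sprintf("No head-group beads in the %s leaflet.", leaflet),
          class = "cyclomem_input_error")
  }
  mean(sel$z)
}

#' Per-residue distances to the membrane surface
#'
#' For each frame, the signed distance of every peptide residue's centre
#' of geometry to the head-group plane of the chosen leaflet, with the
#' minimum-image convention applied along z. Negative values mean the
#' residue sits below the surface (inserted).
#'
#' @param traj A [cg_trajectory()] containing membrane and peptide beads.
#' @param peptide_molecules Molecule ids of the peptide(s).
#' @param config An [analysis_config()].
#' @param leaflet Which leaflet's surface to measure against.
#' @return A `distance_profile` tibble: `frame`, `time`, `molecule`,
#'   `resid`, `resname`, `distance`.
#' @export
residue_surface_distances <- function(traj, peptide_molecules,
                                      config = analysis_config(),
                                      leaflet = "upper") {
  frames <- traj_frames(traj)
  prof <- purrr::list_rbind(purrr::imap(frames, function(f, i) {
    pep <- dplyr::filter(tibble::as_tibble(f),
                         .data$molecule %in% peptide_molecules)
    if (nrow(pep) == 0) {
      abort("Peptide selection matches no particles.",
            class = "cyclomem_input_error")
    }
    surf <- membrane_surface_z(f, leaflet = leaflet,
                               head_name = config$head_name)
    lz <- frame_box(f)[3]
    res <- dplyr::summarise(
      dplyr::group_by(pep, .data$molecule, .data$resid, .data$resname),
      distance = min_image(mean(.data$z) - surf, lz), .groups = "drop")
    dplyr::mutate(res, frame = as.integer(i), time = frame_time(f),
                  .before = 1)
  }))
  structure(prof, class = c("distance_profile", class(tibble::tibble())))
}

#' First-binding times and bound intervals per residue
#'
#' A residue is *bound* while its surface distance is at or below the
#' bound threshold (default 0: inserted below the head-group plane) and
#' *approaching* while at or below the approach threshold. The
#' first-binding time is the time of the first frame of the earliest
#' bound interval (`NA` if the residue never binds).
#'
#' @param profile A `distance_profile` from [residue_surface_distances()].
#' @param config An [analysis_config()].
#' @return A tibble with one row per (molecule, residue): `molecule`,
#'   `resid`, `resname`, `first_approach_time`, `first_binding_time`,
#'   `n_bound_frames`, `intervals` (list of start/end-time tibbles).
#' @export
binding_events <- function(profile, config = analysis_config()) {
  if (nrow(profile) == 0) {
    abort("Distance profile is empty.", class = "cyclomem_input_error")
  }
  groups <- dplyr::group_split(dplyr::group_by(tibble::as_tibble(profile),
                                               .data$molecule, .data$resid))
  purrr::list_rbind(lapply(groups, function(g) {
    g <- dplyr::arrange(g, .data$time)
    bound <- g$distance <= config$bound_threshold
    approaching <- g$distance <= config$approach_threshold
    runs <- rle(bound)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    iv <- tibble::tibble(start_time = g$time[starts[runs$values]],
                         end_time = g$time[ends[runs$values]])
    tibble::tibble(
      molecule = g$molecule[1], resid = g$resid[1], resname = g$resname[1],
      first_approach_time = if (any(approaching)) g$time[which(approaching)[1]]
                            else NA_real_,
      first_binding_time = if (any(bound)) g$time[which(bound)[1]]
                           else NA_real_,
      n_bound_frames = sum(bound),
      intervals = list(iv))
  }))
}

#' Inter-residue minimum-distance matrix of a frame
#'
#' For `m` molecules of `n` residues each, returns the `(m n) x (m n)`
#' symmetric matrix whose entry (a, b) is the minimum bead-bead distance
#' between residue a and residue b under the periodic minimum image (for
#' the 4 x 29 tetramer this is the 116 x 116 matrix). Intra-molecular
#' blocks are included here but excluded from the contact-frequency
#' reduction.
#'
#' @param frame A [particle_frame()].
#' @param molecules Molecule ids, in the desired block order.
#' @return A numeric matrix with `molecule:resid` dimnames.
#' @export
residue_pair_min_distances <- function(frame, molecules) {
  tbl <- dplyr::filter(tibble::as_tibble(frame),
                       .data$molecule %in% molecules)
  tbl$molecule <- factor(tbl$molecule, levels = molecules)
  res_sets <- lapply(molecules, function(m) {
    sort(unique(tbl$resid[tbl$molecule == m]))
  })
  n_res <- lengths(res_sets)
  if (length(unique(n_res)) != 1) {
    abort("All molecules must share the same residue count.",
          class = "cyclomem_consistency_error")
  }
  keys <- paste(rep(molecules, each = n_res[1]),
                unlist(lapply(res_sets, identity)), sep = ":")
  tbl$key <- paste(tbl$molecule, tbl$resid, sep = ":")
  tbl$key_i <- match(tbl$key, keys)
  d_beads <- pair_dist_matrix(tbl[, c("x", "y", "z")],
                              tbl[, c("x", "y", "z")], frame_box(frame))
  n_keys <- length(keys)
  out <- matrix(Inf, n_keys, n_keys, dimnames = list(keys, keys))
  grp <- split(seq_len(nrow(tbl)), tbl$key_i)
  ids <- as.integer(names(grp))
  for (a in seq_along(grp)) {
    rows <- grp[[a]]
    for (b in a:length(grp)) {
      v <- min(d_beads[rows, grp[[b]], drop = FALSE])
      out[ids[a], ids[b]] <- v
      out[ids[b], ids[a]] <- v
    }
  }
  out
}

#' Residue contact-frequency matrix
#'
#' Two residues are in contact in a given frame and molecule pair when
#' their minimum bead distance is at or below the cutoff (default 1.2 nm).
#' Contacts are tallied over all frames and all unordered molecule pairs
#' (6 for a tetramer) and reported as the percentage
#' `100 * n_contact / (n_contact + n_noncontact)`, reducing the per-frame
#' `(m n) x (m n)` distance matrices to an `n x n` residue matrix.
#'
#' @param traj A [cg_trajectory()] or a list of [particle_frame()]s.
#' @param molecules Molecule ids (at least 2).
#' @param config An [analysis_config()].
#' @return A `contact_frequency` object: list with `percent` (n x n
#'   matrix), `contacts`, `totals`, `cutoff`, `n_frames`.
#' @export
contact_frequency <- function(traj, molecules, config = analysis_config()) {
  if (length(molecules) < 2) {
    abort("Contact frequencies need at least two molecules.",
          class = "cyclomem_input_error")
  }
  frames <- if (inherits(traj, "cg_trajectory")) traj_frames(traj)
            else if (inherits(traj, "particle_frame")) list(traj)
            else traj
  if (length(frames) == 0) {
    abort("Need at least one frame.", class = "cyclomem_input_error")
  }
  mol_pairs <- utils::combn(length(molecules), 2)
  first <- dplyr::filter(tibble::as_tibble(frames[[1]]),
                         .data$molecule == molecules[1])
  resids <- sort(unique(first$resid))
  n <- length(resids)
  contacts <- matrix(0L, n, n)
  for (f in frames) {
    dmat <- residue_pair_min_distances(f, molecules)
    for (k in seq_len(ncol(mol_pairs))) {
      ia <- (mol_pairs[1, k] - 1) * n + seq_len(n)
      ib <- (mol_pairs[2, k] - 1) * n + seq_len(n)
      block <- dmat[ia, ib, drop = FALSE] <= config$contact_cutoff
      contacts <- contacts + (block + t(block) - block * t(block))
    }
  }
  totals <- length(frames) * ncol(mol_pairs)
  percent <- 100 * contacts / totals
  dimnames(percent) <- list(resids, resids)
  structure(list(percent = percent, contacts = contacts, totals = totals,
                 cutoff = config$contact_cutoff, n_frames = length(frames),
                 resids = resids),
            class = "contact_frequency")
}

#' @export
print.contact_frequency <- function(x, ...) {
  cat(sprintf(
    "Contact-frequency matrix: %d x %d residues, %d frame(s) x %d molecule pair(s), cutoff %.2f nm\n",
    nrow(x$percent), ncol(x$percent), x$n_frames, x$totals / x$n_frames,
    x$cutoff))
  invisible(x)
}

#' @rdname contact_frequency
#' @param x A `contact_frequency` object.
#' @param ... Unused.
#' @return `tidy()`: a long tibble `resid_i`, `resid_j`, `contacts`,
#'   `total`, `percent`.
#' @export
tidy.contact_frequency <- function(x, ...) {
  grid <- expand.grid(i = seq_along(x$resids), j = seq_along(x$resids))
  tibble::tibble(resid_i = x$resids[grid$i], resid_j = x$resids[grid$j],
                 contacts = as.vector(x$contacts), total = x$totals,
                 percent = as.vector(x$percent))
}

#' Lipid-domain occupancy of a peptide
#'
#' Per frame, the lipids whose lateral (minimum-image x/y) distance from
#' the peptide centre of mass is within `domain_radius` are tallied; the
#' frame is classified `lo` when the lo-species (DPPC+CHOL) fraction is at
#' least `lo_threshold`, `ld` when it is at most `1 - lo_threshold`, and
#' `interface` otherwise. Frames with no lipid inside the radius are
#' classified `interface` and counted, with a warning.
#'
#' @param traj A [cg_trajectory()].
#' @param peptide_molecules Molecule ids of the peptide(s).
#' @param labels Optional per-molecule species table (columns `molecule`,
#'   `species`); defaults to the frame's own metadata.
#' @param config An [analysis_config()].
#' @param lo_species,lipid_species Species making up the lo phase and the
#'   lipid set.
#' @return A `domain_occupancy` object: list with `fractions` (tibble of
#'   `class`, `n_frames`, `fraction`) and `trace` (per-frame tibble).
#' @export
domain_occupancy <- function(traj, peptide_molecules, labels = NULL,
                             config = analysis_config(),
                             lo_species = c("DPPC", "CHOL"),
                             lipid_species = c("DUPC", "DPPC", "CHOL")) {
  frames <- traj_frames(traj)
  if (!is.null(config$time_range)) {
    times <- vapply(frames, frame_time, numeric(1))
    frames <- frames[times >= config$time_range[1] &
                     times <= config$time_range[2]]
  }
  if (length(frames) == 0) {
    abort("No frames in the requested time range.",
          class = "cyclomem_input_error")
  }
  n_empty <- 0
  trace <- purrr::list_rbind(purrr::imap(frames, function(f, i) {
    tbl <- tibble::as_tibble(f)
    if (!is.null(labels)) {
      tbl <- dplyr::select(tbl, -dplyr::any_of("species"))
      tbl <- dplyr::left_join(tbl, labels[, c("molecule", "species")],
                              by = "molecule")
    }
    box <- frame_box(f)
    pep <- dplyr::filter(tbl, .data$molecule %in% peptide_molecules)
    if (nrow(pep) == 0) {
      abort("Peptide selection matches no particles.",
            class = "cyclomem_input_error")
    }
    lip <- dplyr::filter(tbl, .data$species %in% lipid_species)
    if (nrow(lip) == 0) {
      abort("Membrane model carries no lipid species labels.",
            class = "cyclomem_input_error")
    }
    lip_xy <- dplyr::summarise(dplyr::group_by(lip, .data$molecule,
                                               .data$species),
                               x = mean(.data$x), y = mean(.data$y),
                               .groups = "drop")
    px <- mean(pep$x); py <- mean(pep$y)
    dlat <- sqrt(min_image(lip_xy$x - px, box[1])^2 +
                 min_image(lip_xy$y - py, box[2])^2)
    near <- lip_xy$species[dlat <= config$domain_radius]
    if (length(near) == 0) {
      n_empty <<- n_empty + 1
      cls <- "interface"
      frac_lo <- NA_real_
    } else {
      frac_lo <- mean(near %in% lo_species)
      cls <- if (frac_lo >= config$lo_threshold) "lo"
             else if (frac_lo <= 1 - config$lo_threshold) "ld"
             else "interface"
    }
    tibble::tibble(frame = as.integer(i), time = frame_time(f),
                   n_near = length(near), frac_lo_species = frac_lo,
                   class = cls)
  }))
  if (n_empty > 0) {
    warn(sprintf("%d frame(s) had no lipid within the classification radius; classified as 'interface'.",
                 n_empty))
  }
  fractions <- tibble::tibble(class = c("ld", "lo", "interface"))
  fractions$n_frames <- vapply(fractions$class,
                               function(cl) sum(trace$class == cl),
                               integer(1))
  fractions$fraction <- fractions$n_frames / nrow(trace)
  structure(list(fractions = fractions, trace = trace,
                 config = config),
            class = "domain_occupancy")
}

#' @export
print.domain_occupancy <- function(x, ...) {
  cat("Lipid-domain occupancy:\n")
  for (i in seq_len(nrow(x$fractions))) {
    cat(sprintf("  %-9s %6.1f%% (%d frames)\n", x$fractions$class[i],
                100 * x$fractions$fraction[i], x$fractions$n_frames[i]))
  }
  invisible(x)
}

#' @rdname domain_occupancy
#' @param x A `domain_occupancy` object.
#' @param ... Unused.
#' @export
tidy.domain_occupancy <- function(x, ...) x$fractions

#' @rdname domain_occupancy
#' @export
glance.domain_occupancy <- function(x, ...) {
  frac <- setNames(x$fractions$fraction, x$fractions$class)
  tibble::tibble(
    n_frames = nrow(x$trace),
    ld = unname(frac[["ld"]]), lo = unname(frac[["lo"]]),
    interface = unname(frac[["interface"]]))
}
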