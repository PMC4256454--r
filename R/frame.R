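# Particle frames and trajectories: the tabular containers every analysis
# consumes. A particle frame is a tibble (one row per bead) carrying the
# simulation box (nm) and time (ns) as attributes; a trajectory is a long
# tibble of frames with a per-frame box table.

.frame_required_cols <- c("name", "species", "molecule", "resid", "resname",
                          "x", "y", "z")

#' Construct a particle frame
#'
#' A particle frame is a tibble with one row per bead and the columns
#' `name`, `species`, `molecule`, `resid`, `resname`, `x`, `y`, `z`
#' (coordinates in nm), plus any extra metadata columns (e.g. `leaflet`,
#' `domain`, `type`, `charge`). The rectangular box (three edge lengths in
#' nm) and the frame time (ns) are stored as attributes.
#'
#' @param data A data frame with at least the required columns.
#' @param box Numeric length-3 vector of box edge lengths in nm.
#' @param time Frame time in ns.
#' @return A `particle_frame` tibble.
#' @examples
#' particle_frame(
#'   tibble::tibble(name = "W", species = "W", molecule = "W1",
#'                  resid = 1L, resname = "W", x = 1, y = 1, z = 1),
#'   box = c(5, 5, 5)
#' )
#' @export
particle_frame <- function(data, box, time = 0) {
  data <- tibble::as_tibble(data)
  missing_cols <- setdiff(.frame_required_cols, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Particle frame is missing columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "cyclomem_input_error")
  }
  xyz <- as.matrix(data[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) {
    abort("All particle coordinates must be finite.",
          class = "cyclomem_input_error")
  }
  box <- as.numeric(box)
  if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0)) {
    abort("`box` must be three positive lengths in nm.",
          class = "cyclomem_input_error")
  }
  assert_scalar_number(time, "time")
  structure(data, box = box, time = as.numeric(time),
            class = c("particle_frame", class(tibble::tibble())))
}

#' Box lengths of a particle frame
#' @param frame A `particle_frame`.
#' @return Numeric length-3 vector (nm).
#' @export
frame_box <- function(frame) attr(frame, "box")

#' Time stamp of a particle frame
#' @param frame A `particle_frame`.
#' @return Time in ns.
#' @export
frame_time <- function(frame) attr(frame, "time")

#' @export
print.particle_frame <- function(x, ...) {
  cat(sprintf("# Particle frame: %d beads, box %.3f x %.3f x %.3f nm, t = %g ns\n",
              nrow(x), frame_box(x)[1], frame_box(x)[2], frame_box(x)[3],
              frame_time(x)))
  NextMethod()
}

#' Assemble a trajectory from particle frames
#'
#' A trajectory is a long tibble (columns `frame`, `time`, then the particle
#' columns) with a per-frame box table stored as an attribute. Frames must be
#' in nondecreasing time order.
#'
#' @param frames A list of `particle_frame` objects.
#' @return A `cg_trajectory` tibble.
#' @export
cg_trajectory <- function(frames) {
  if (!is.list(frames) || length(frames) == 0) {
    abort("`frames` must be a non-empty list of particle frames.",
          class = "cyclomem_input_error")
  }
  times <- vapply(frames, frame_time, numeric(1))
  if (is.unsorted(times)) {
    abort("Trajectory frames must be in nondecreasing time order.",
          class = "cyclomem_input_error")
  }
  n_particles <- vapply(frames, nrow, integer(1))
  if (length(unique(n_particles)) != 1) {
    abort("All trajectory frames must contain the same number of particles.",
          class = "cyclomem_consistency_error")
  }
  boxes <- do.call(rbind, lapply(frames, frame_box))
  long <- purrr::list_rbind(purrr::imap(frames, function(f, i) {
    dplyr::mutate(tibble::as_tibble(f), frame = as.integer(i),
                  time = frame_time(f), .before = 1)
  }))
  structure(long,
            boxes = tibble::tibble(frame = seq_along(frames), time = times,
                                   lx = boxes[, 1], ly = boxes[, 2],
                                   lz = boxes[, 3]),
            class = c("cg_trajectory", class(tibble::tibble())))
}

#' Per-frame box table of a trajectory
#' @param traj A `cg_trajectory`.
#' @return A tibble with columns `frame`, `time`, `lx`, `ly`, `lz`.
#' @export
traj_boxes <- function(traj) attr(traj, "boxes")

#' Number of frames in a trajectory
#' @param traj A `cg_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) nrow(traj_boxes(traj))

#' Split a trajectory back into particle frames
#' @param traj A `cg_trajectory`.
#' @return A list of `particle_frame` objects.
#' @export
traj_frames <- function(traj) {
  boxes <- traj_boxes(traj)
  tbl <- tibble::as_tibble(traj)
  lapply(seq_len(nrow(boxes)), function(i) {
    sub <- dplyr::filter(tbl, .data$frame == boxes$frame[i])
    sub <- dplyr::select(sub, -"frame", -"time")
    particle_frame(sub, box = c(boxes$lx[i], boxes$ly[i], boxes$lz[i]),
                   time = boxes$time[i])
  })
}

#' @export
print.cg_trajectory <- function(x, ...) {
  b <- traj_boxes(x)
  cat(sprintf("# Trajectory: %d frames, %d particles, t = %g..%g ns\n",
              nrow(b), nrow(x) / nrow(b), min(b$time), max(b$time)))
  NextMethod()
}

#' Select particle row indices of a frame by metadata
#'
#' @param frame A `particle_frame`.
#' @param species,molecule,resid,name Optional vectors; a particle is kept
#'   if it matches every supplied filter.
#' @return Integer row indices into `frame`.
#' @export
select_particles <- function(frame, species = NULL, molecule = NULL,
                             resid = NULL, name = NULL) {
  keep <- rep(TRUE, nrow(frame))
  if (!is.null(species))  keep <- keep & frame$species %in% species
  if (!is.null(molecule)) keep <- keep & frame$molecule %in% molecule
  if (!is.null(resid))    keep <- keep & frame$resid %in% resid
  if (!is.null(name))     keep <- keep & frame$name %in% name
  which(keep)
}
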