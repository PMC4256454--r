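# File formats: GRO (read/write, the canonical interchange format, fixed
# column, nm), PDB (read-only, via bio3d, Angstrom -> nm), multi-frame GRO
# trajectories, and two-column umbrella-sample text files with a sidecar
# metadata table. All other modules work on the tibbles returned here.

# ---- GRO ------------------------------------------------------------------

parse_gro_block <- function(lines, offset, path) {
  # offset: 0-based index of the title line within the file
  title <- lines[1]
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n) || n < 0) {
    abort(sprintf("%s:%d: invalid atom count '%s'", path, offset + 2,
                  trimws(lines[2])), class = "cyclomem_parse_error")
  }
  if (length(lines) < n + 3) {
    abort(sprintf("%s:%d: truncated frame (expected %d atom lines)",
                  path, offset + 2, n), class = "cyclomem_parse_error")
  }
  atoms <- lines[3:(2 + n)]
  num <- function(s, line_no) {
    v <- suppressWarnings(as.numeric(s))
    bad <- which(is.na(v))
    if (length(bad) > 0) {
      abort(sprintf("%s:%d: malformed coordinate field '%s'", path,
                    offset + 2 + line_no[bad[1]], s[bad[1]]),
            class = "cyclomem_parse_error")
    }
    v
  }
  idx <- seq_len(n)
  resid <- suppressWarnings(as.integer(substr(atoms, 1, 5)))
  if (anyNA(resid)) {
    bad <- which(is.na(resid))[1]
    abort(sprintf("%s:%d: malformed residue number", path, offset + 2 + bad),
          class = "cyclomem_parse_error")
  }
  resname <- trimws(substr(atoms, 6, 10))
  name <- trimws(substr(atoms, 11, 15))
  x <- num(substr(atoms, 21, 28), idx)
  y <- num(substr(atoms, 29, 36), idx)
  z <- num(substr(atoms, 37, 44), idx)
  box_fields <- strsplit(trimws(lines[n + 3]), "\\s+")[[1]]
  box <- suppressWarnings(as.numeric(box_fields))
  if (length(box) < 3 || anyNA(box[1:3])) {
    abort(sprintf("%s:%d: malformed box line", path, offset + n + 3),
          class = "cyclomem_parse_error")
  }
  time <- 0
  tm <- regmatches(title, regexec("t=\\s*([-0-9.eE+]+)", title))[[1]]
  if (length(tm) == 2) time <- as.numeric(tm[2])
  # one molecule per residue block by default; trajectory readers may
  # override metadata from a topology frame
  new_res <- c(TRUE, resid[-1] != resid[-n] | resname[-1] != resname[-n])
  molecule <- paste0("M", cumsum(new_res))
  frame <- particle_frame(
    tibble::tibble(name = name, species = resname, molecule = molecule,
                   resid = resid, resname = resname, x = x, y = y, z = z),
    box = box[1:3], time = time
  )
  list(frame = frame, consumed = n + 3)
}

read_gro_frames <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) {
    abort(sprintf("%s: empty file", path), class = "cyclomem_parse_error")
  }
  frames <- list()
  pos <- 1
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos])) && pos == length(lines)) break
    block <- parse_gro_block(lines[pos:length(lines)], pos - 1, path)
    frames[[length(frames) + 1]] <- block$frame
    pos <- pos + block$consumed
  }
  frames
}

format_gro_frame <- function(frame, title = "written by cyclomem") {
  n <- nrow(frame)
  header <- c(sprintf("%s, t= %.5f", title, frame_time(frame)),
              sprintf("%5d", n))
  body <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                  frame$resid %% 100000L,
                  substr(frame$resname, 1, 5),
                  substr(frame$name, 1, 5),
                  seq_len(n) %% 100000L,
                  frame$x, frame$y, frame$z)
  box <- sprintf("%10.5f%10.5f%10.5f", frame_box(frame)[1],
                 frame_box(frame)[2], frame_box(frame)[3])
  c(header, body, box)
}

# ---- structures -----------------------------------------------------------

#' Read a structure file (GRO or PDB) into a particle frame
#'
#' GRO coordinates are interpreted as nm; PDB coordinates as Angstrom and
#' converted to nm. PDB reading covers ATOM/HETATM/CRYST1 records (via
#' bio3d); a missing CRYST1 yields a large dummy box.
#'
#' @param path Path to the file.
#' @param format `"auto"` (by extension), `"gro"` or `"pdb"`.
#' @return A [particle_frame()].
#' @export
read_structure <- function(path, format = c("auto", "gro", "pdb")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "cyclomem_io_error")
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("gro")) format <- "gro"
    else if (ext %in% c("pdb", "ent")) format <- "pdb"
    else abort(sprintf("Cannot infer format from extension '.%s'; pass `format`.",
                       ext), class = "cyclomem_format_error")
  }
  if (format == "gro") {
    return(read_gro_frames(path)[[1]])
  }
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  box <- c(100, 100, 100)
  cryst <- grep("^CRYST1", readLines(path), value = TRUE)
  if (length(cryst) > 0) {
    abc <- suppressWarnings(as.numeric(c(substr(cryst[1], 7, 15),
                                         substr(cryst[1], 16, 24),
                                         substr(cryst[1], 25, 33))))
    if (all(is.finite(abc)) && all(abc > 0)) box <- abc / 10
  }
  chain <- at$chain
  chain[is.na(chain) | chain == ""] <- "A"
  particle_frame(
    tibble::tibble(name = at$elety, species = at$resid,
                   molecule = paste0("chain_", chain),
                   resid = at$resno, resname = at$resid,
                   x = at$x / 10, y = at$y / 10, z = at$z / 10),
    box = box, time = 0
  )
}

#' Write a particle frame as a GRO file
#'
#' Canonical fixed-column GRO (nm, three decimals). Writing then reading a
#' frame reproduces coordinates to the format precision of 0.001 nm.
#'
#' @param frame A [particle_frame()].
#' @param path Output path.
#' @param title Title line prefix.
#' @return `path`, invisibly.
#' @export
write_structure <- function(frame, path, title = "written by cyclomem") {
  writeLines(format_gro_frame(frame, title), path)
  invisible(path)
}

# ---- trajectories ---------------------------------------------------------

#' Read a multi-frame GRO trajectory
#'
#' Frames must share a particle count and be in nondecreasing time order
#' (frame times are taken from a `t=` tag in each title line). When a
#' `topology_frame` is supplied its metadata columns (everything except the
#' coordinates) replace the per-frame metadata, which a bare GRO cannot
#' represent fully (e.g. multi-residue molecules).
#'
#' @param path Path to a (possibly multi-frame) GRO file.
#' @param topology_frame Optional [particle_frame()] supplying metadata.
#' @return A [cg_trajectory()].
#' @export
read_trajectory <- function(path, topology_frame = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "cyclomem_io_error")
  }
  frames <- read_gro_frames(path)
  if (length(frames) == 0) {
    abort(sprintf("%s: no frames found", path), class = "cyclomem_parse_error")
  }
  if (!is.null(topology_frame)) {
    n_top <- nrow(topology_frame)
    meta <- dplyr::select(tibble::as_tibble(topology_frame),
                          -"x", -"y", -"z")
    frames <- lapply(frames, function(f) {
      if (nrow(f) != n_top) {
        abort(sprintf(
          "Particle count mismatch: trajectory frame has %d, topology %d.",
          nrow(f), n_top), class = "cyclomem_consistency_error")
      }
      particle_frame(dplyr::bind_cols(meta, f[, c("x", "y", "z")]),
                     box = frame_box(f), time = frame_time(f))
    })
  }
  cg_trajectory(frames)
}

#' Write a trajectory as a multi-frame GRO file
#'
#' @param traj A [cg_trajectory()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  frames <- traj_frames(traj)
  lines <- unlist(lapply(frames, format_gro_frame))
  writeLines(lines, path)
  invisible(path)
}

# ---- umbrella windows -----------------------------------------------------

#' Construct an umbrella-window table
#'
#' One row per window: harmonic bias centre (nm), force constant
#' (kJ/(mol nm^2)), temperature (K) and the reaction-coordinate samples (nm)
#' as a list column.
#'
#' @param centers Numeric vector of bias centres.
#' @param force_constant Force constant(s), recycled across windows.
#' @param samples List of numeric sample vectors, one per window.
#' @param temperature Temperature in K.
#' @return An `umbrella_windows` tibble with columns `window`, `center`,
#'   `force_constant`, `temperature`, `n_samples`, `samples`.
#' @export
umbrella_windows <- function(centers, force_constant, samples,
                             temperature = 310) {
  if (length(samples) != length(centers)) {
    abort("`samples` must have one element per window centre.",
          class = "cyclomem_input_error")
  }
  force_constant <- rep_len(force_constant, length(centers))
  if (any(force_constant < 0)) {
    abort("Force constants must be >= 0.", class = "cyclomem_input_error")
  }
  if (temperature <= 0) {
    abort("`temperature` must be > 0 K.", class = "cyclomem_input_error")
  }
  n <- vapply(samples, length, integer(1))
  if (any(n < 1)) {
    abort("Every window needs at least one sample.",
          class = "cyclomem_input_error")
  }
  structure(
    tibble::tibble(window = seq_along(centers), center = as.numeric(centers),
                   force_constant = force_constant,
                   temperature = temperature, n_samples = n,
                   samples = lapply(samples, as.numeric)),
    class = c("umbrella_windows", class(tibble::tibble()))
  )
}

#' Read umbrella-sample files
#'
#' Each file is two-column text (time, reaction coordinate in nm); lines
#' starting with `#` or `@` are skipped. Bias centres and force constants
#' come from the `metadata` table (columns `center` and `force_constant`,
#' optionally `path` to match by file name; otherwise rows are matched to
#' `paths` by position).
#'
#' @param paths Character vector of sample-file paths.
#' @param metadata Data frame with one row per window.
#' @param temperature Temperature in K.
#' @return An [umbrella_windows()] tibble, one row per file.
#' @export
read_umbrella_windows <- function(paths, metadata, temperature = 310) {
  metadata <- tibble::as_tibble(metadata)
  if (!all(c("center", "force_constant") %in% names(metadata))) {
    abort("`metadata` needs columns `center` and `force_constant`.",
          class = "cyclomem_input_error")
  }
  if ("path" %in% names(metadata)) {
    ord <- match(basename(paths), basename(metadata$path))
    if (anyNA(ord)) {
      abort("Some sample files have no metadata row.",
            class = "cyclomem_input_error")
    }
    metadata <- metadata[ord, ]
  } else if (nrow(metadata) != length(paths)) {
    abort("`metadata` must have one row per sample file.",
          class = "cyclomem_input_error")
  }
  samples <- lapply(paths, function(p) {
    if (!file.exists(p)) {
      abort(sprintf("File not found: %s", p), class = "cyclomem_io_error")
    }
    lines <- readLines(p)
    keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*[#@]", lines))
    if (length(keep) == 0) {
      abort(sprintf("%s: no data rows", p), class = "cyclomem_parse_error")
    }
    vals <- vapply(keep, function(i) {
      fields <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (length(fields) < 2) {
        abort(sprintf("%s:%d: expected two columns", p, i),
              class = "cyclomem_parse_error")
      }
      v <- suppressWarnings(as.numeric(fields[2]))
      if (is.na(v)) {
        abort(sprintf("%s:%d: non-numeric value '%s'", p, i, fields[2]),
              class = "cyclomem_parse_error")
      }
      v
    }, numeric(1))
    vals
  })
  umbrella_windows(metadata$center, metadata$force_constant, samples,
                   temperature = temperature)
}

#' Write umbrella windows as sample files plus a metadata table
#'
#' Writes `window_###.xvg`-style two-column text files and a
#' `windows_meta.tsv` sidecar (columns `path`, `center`, `force_constant`).
#'
#' @param windows An [umbrella_windows()] tibble.
#' @param dir Output directory (created if needed).
#' @param dt Sample spacing used for the time column, in ns.
#' @return Paths of the written sample files, invisibly.
#' @export
write_umbrella_windows <- function(windows, dir, dt = 0.01) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, sprintf("window_%03d.xvg", windows$window))
  for (i in seq_len(nrow(windows))) {
    s <- windows$samples[[i]]
    writeLines(c("# cyclomem umbrella window: time(ns) coordinate(nm)",
                 sprintf("%.6f %.6f", (seq_along(s) - 1) * dt, s)),
               paths[i])
  }
  meta <- tibble::tibble(path = basename(paths), center = windows$center,
                         force_constant = windows$force_constant)
  readr::write_tsv(meta, file.path(dir, "windows_meta.tsv"))
  invisible(paths)
}
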