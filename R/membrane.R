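# Raft-mimicking bilayer builder: a DPPC+CHOL liquid-ordered (lo) core disc
# surrounded by a DUPC+CHOL liquid-disordered (ld) annulus, hydrated at a
# fixed water-per-lipid ratio. Placement is geometric (hexagonal lattice at
# a conventional area per lipid); the goal is labelled geometry for
# downstream analytics, not an equilibrated membrane.

# per-species bead templates: name, type, charge, dz below the head plane
.lipid_templates <- list(
  DPPC = tibble::tibble(
    name = c("NC3", "PO4", "GL1", "GL2", "C1A", "C2A", "C3A", "C4A",
             "C1B", "C2B", "C3B", "C4B"),
    type = c("Q0", "Qa", "Na", "Na", rep("C1", 8)),
    charge = c(1, -1, rep(0, 10)),
    dz = c(-0.30, 0, 0.30, 0.33, 0.60, 0.90, 1.20, 1.50,
           0.63, 0.93, 1.23, 1.53),
    dx = c(0, 0, 0, 0.15, 0, 0, 0, 0, 0.15, 0.15, 0.15, 0.15)),
  DUPC = tibble::tibble(
    name = c("NC3", "PO4", "GL1", "GL2", "C1A", "D2A", "C3A", "C4A",
             "C1B", "D2B", "C3B", "C4B"),
    type = c("Q0", "Qa", "Na", "Na", "C1", "C3", "C1", "C1",
             "C1", "C3", "C1", "C1"),
    charge = c(1, -1, rep(0, 10)),
    dz = c(-0.30, 0, 0.30, 0.33, 0.60, 0.90, 1.20, 1.50,
           0.63, 0.93, 1.23, 1.53),
    dx = c(0, 0, 0, 0.15, 0, 0, 0, 0, 0.15, 0.15, 0.15, 0.15)),
  CHOL = tibble::tibble(
    name = c("ROH", "R1", "R2", "R3", "R4", "R5", "C1", "C2"),
    type = c("SP1", rep("SC1", 5), "C1", "C1"),
    charge = rep(0, 8),
    dz = c(0.10, 0.30, 0.50, 0.70, 0.90, 1.05, 1.25, 1.45),
    dx = rep(0, 8))
)

#' Specify a raft-mimicking membrane
#'
#' Defaults follow the study conditions: DUPC:DPPC:CHOL mole ratio
#' 0.07:0.62:0.31, 6 water beads per lipid, a 16 nm lateral box and an area
#' per lipid of 0.64 nm^2.
#'
#' @param ratio Named or positional mole fractions `c(DUPC, DPPC, CHOL)`;
#'   must sum to 1.
#' @param n_lipids_per_leaflet Lipids (including cholesterol) per leaflet.
#' @param box_xy Lateral box edge (nm); box is `box_xy x box_xy x box_z`.
#' @param box_z Box height (nm).
#' @param waters_per_lipid Water beads per lipid (whole membrane).
#' @param area_per_lipid Lattice area per lipid (nm^2).
#' @param seed Integer seed controlling the (deterministic) species
#'   shuffling within core and annulus.
#' @return A `membrane_spec` list.
#' @export
membrane_spec <- function(ratio = c(DUPC = 0.07, DPPC = 0.62, CHOL = 0.31),
                          n_lipids_per_leaflet = 400, box_xy = 16,
                          box_z = 16, waters_per_lipid = 6,
                          area_per_lipid = 0.64, seed = 1L) {
  ratio <- as.numeric(ratio)
  if (length(ratio) != 3 || any(ratio < 0) || abs(sum(ratio) - 1) > 1e-9) {
    abort("`ratio` must be three nonnegative fractions (DUPC, DPPC, CHOL) summing to 1.",
          class = "cyclomem_input_error")
  }
  if (n_lipids_per_leaflet <= 0) {
    abort("`n_lipids_per_leaflet` must be positive.",
          class = "cyclomem_input_error")
  }
  if (waters_per_lipid < 0) {
    abort("`waters_per_lipid` must be >= 0.", class = "cyclomem_input_error")
  }
  assert_scalar_number(box_xy, "box_xy", positive = TRUE)
  assert_scalar_number(area_per_lipid, "area_per_lipid", positive = TRUE)
  structure(list(ratio = setNames(ratio, c("DUPC", "DPPC", "CHOL")),
                 n_lipids_per_leaflet = as.integer(n_lipids_per_leaflet),
                 box_xy = box_xy, box_z = box_z,
                 waters_per_lipid = waters_per_lipid,
                 area_per_lipid = area_per_lipid, seed = as.integer(seed)),
            class = "membrane_spec")
}

hex_lattice <- function(box_xy, area_per_site) {
  a <- sqrt(2 * area_per_site / sqrt(3))
  dy <- a * sqrt(3) / 2
  nx <- floor(box_xy / a)
  ny <- floor(box_xy / dy)
  sites <- purrr::list_rbind(lapply(seq_len(ny), function(iy) {
    xoff <- if (iy %% 2 == 0) a / 2 else 0
    tibble::tibble(x = (seq_len(nx) - 0.5) * a + xoff,
                   y = (iy - 0.5) * dy)
  }))
  dplyr::filter(sites, .data$x < box_xy, .data$y < box_xy)
}

#' Build a phase-separated membrane model
#'
#' Lipid counts per leaflet are apportioned from the mole ratio by
#' largest-remainder rounding. DPPC plus a proportional share of CHOL
#' occupy a central lateral disc (the lo core); DUPC and the remaining
#' CHOL occupy the surrounding annulus (the ld phase). Water beads
#' (`round(waters_per_lipid * total_lipids)`) are laid on a cubic lattice
#' above and below the bilayer. Deterministic given the spec's seed.
#'
#' @param spec A [membrane_spec()].
#' @return A `membrane_model`: a [particle_frame()] whose rows carry
#'   `leaflet` (`upper`/`lower`/`NA` for water) and `domain`
#'   (`lo-core`/`ld-annulus`/`water`) labels plus `type` and `charge`.
#' @examples
#' m <- build_membrane(membrane_spec(n_lipids_per_leaflet = 50, box_xy = 6))
#' composition_report(m)
#' @export
build_membrane <- function(spec) {
  stopifnot(inherits(spec, "membrane_spec"))
  counts <- largest_remainder(spec$n_lipids_per_leaflet, spec$ratio)
  names(counts) <- names(spec$ratio)
  n_dupc <- counts[["DUPC"]]; n_dppc <- counts[["DPPC"]]
  n_chol <- counts[["CHOL"]]

  sites <- hex_lattice(spec$box_xy, spec$area_per_lipid)
  n_need <- spec$n_lipids_per_leaflet
  if (nrow(sites) < n_need) {
    abort(sprintf(
      "Packing error: box %g nm holds %d lattice sites at %g nm^2/lipid, but %d lipids were requested.",
      spec$box_xy, nrow(sites), spec$area_per_lipid, n_need),
      class = "cyclomem_packing_error")
  }
  ctr <- spec$box_xy / 2
  sites <- dplyr::arrange(sites, (sites$x - ctr)^2 + (sites$y - ctr)^2)
  sites <- sites[seq_len(n_need), ]

  # CHOL split between core and annulus proportionally to DPPC:DUPC
  chol_core <- if (n_dppc + n_dupc > 0) {
    as.integer(round(n_chol * n_dppc / (n_dppc + n_dupc)))
  } else n_chol
  chol_ann <- n_chol - chol_core
  n_core <- n_dppc + chol_core

  leaflet_species <- function(leaflet_seed) {
    core <- c(rep("DPPC", n_dppc), rep("CHOL", chol_core))
    ann <- c(rep("DUPC", n_dupc), rep("CHOL", chol_ann))
    withr::with_seed(leaflet_seed, {
      core <- sample(core)
      ann <- sample(ann)
    })
    tibble::tibble(
      species = c(core, ann),
      domain = c(rep("lo-core", length(core)), rep("ld-annulus", length(ann))),
      x = sites$x, y = sites$y)
  }

  z_mid <- spec$box_z / 2
  z_head <- 1.9  # head-group (PO4) plane offset from the bilayer midplane
  place_leaflet <- function(assign, leaflet) {
    sgn <- if (leaflet == "upper") 1 else -1
    purrr::list_rbind(lapply(seq_len(nrow(assign)), function(i) {
      tpl <- .lipid_templates[[assign$species[i]]]
      tibble::tibble(
        name = tpl$name, species = assign$species[i],
        molecule = sprintf("%s_%s_%04d", assign$species[i],
                           substr(leaflet, 1, 1), i),
        resid = i, resname = assign$species[i],
        x = assign$x[i] + tpl$dx, y = assign$y[i],
        z = z_mid + sgn * (z_head - tpl$dz),
        type = tpl$type, charge = tpl$charge,
        leaflet = leaflet, domain = assign$domain[i])
    }))
  }
  upper <- place_leaflet(leaflet_species(child_seed(spec$seed, 1)), "upper")
  lower <- place_leaflet(leaflet_species(child_seed(spec$seed, 2)), "lower")

  n_lipids_total <- 2L * n_need
  n_water <- as.integer(round(spec$waters_per_lipid * n_lipids_total))
  water <- NULL
  if (n_water > 0) {
    spacing <- 0.47
    per_layer <- floor(spec$box_xy / spacing)^2
    n_layers <- ceiling(n_water / per_layer)
    slab_top <- z_mid + z_head + 0.5
    slab_bot <- z_mid - z_head - 0.5
    if (slab_top + ceiling(n_layers / 2) * spacing > spec$box_z ||
        slab_bot - ceiling(n_layers / 2) * spacing < 0) {
      abort("Packing error: box too short for the requested hydration.",
            class = "cyclomem_packing_error")
    }
    nl <- floor(spec$box_xy / spacing)
    grid <- expand.grid(ix = seq_len(nl), iy = seq_len(nl))
    layer_xy <- tibble::tibble(x = (grid$ix - 0.5) * spacing,
                               y = (grid$iy - 0.5) * spacing)
    pts <- purrr::list_rbind(lapply(seq_len(n_layers), function(l) {
      side <- if (l %% 2 == 1) 1 else -1
      lev <- ceiling(l / 2)
      zl <- if (side > 0) slab_top + (lev - 1) * spacing
            else slab_bot - (lev - 1) * spacing
      dplyr::mutate(layer_xy, z = zl)
    }))
    pts <- pts[seq_len(n_water), ]
    water <- tibble::tibble(
      name = "W", species = "W",
      molecule = sprintf("W_%05d", seq_len(n_water)),
      resid = seq_len(n_water), resname = "W",
      x = pts$x, y = pts$y, z = pts$z,
      type = "P4", charge = 0,
      leaflet = NA_character_, domain = "water")
  }

  all_beads <- dplyr::bind_rows(upper, lower, water)
  # unique residue numbering across the whole model for GRO round-trips
  mol_ids <- match(all_beads$molecule, unique(all_beads$molecule))
  all_beads$resid <- mol_ids
  frame <- particle_frame(all_beads,
                          box = c(spec$box_xy, spec$box_xy, spec$box_z),
                          time = 0)
  attr(frame, "membrane_spec") <- spec
  class(frame) <- c("membrane_model", class(frame))
  frame
}

#' Per-species composition of a membrane model
#'
#' Tallies molecules by species; mole fractions are reported among lipid
#' species (DUPC, DPPC, CHOL), with water listed but not included in the
#' fractions.
#'
#' @param model A `membrane_model` (or any [particle_frame()] with
#'   `species`/`molecule` columns).
#' @return A tibble with columns `species`, `n_molecules`, `mole_fraction`.
#' @export
composition_report <- function(model) {
  if (nrow(model) == 0) {
    abort("Cannot report composition of an empty model.",
          class = "cyclomem_input_error")
  }
  mols <- dplyr::distinct(tibble::as_tibble(model), .data$molecule,
                          .data$species)
  tally <- dplyr::count(mols, .data$species, name = "n_molecules")
  lipid <- tally$species != "W"
  total_lipids <- sum(tally$n_molecules[lipid])
  tally$mole_fraction <- ifelse(lipid, tally$n_molecules / total_lipids,
                                NA_real_)
  dplyr::arrange(tally, dplyr::desc(.data$n_molecules))
}

#' Per-molecule label table of a membrane model
#'
#' @param model A `membrane_model`.
#' @return A tibble with one row per molecule: `molecule`, `species`,
#'   `leaflet`, `domain`.
#' @export
membrane_labels <- function(model) {
  dplyr::distinct(tibble::as_tibble(model), .data$molecule, .data$species,
                  .data$leaflet, .data$domain)
}
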