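# Shared fixtures, built in code at test time.

fx <- new.env()

fixture_membrane <- function() {
  if (is.null(fx$membrane)) {
    fx$membrane <- build_membrane(membrane_spec(
      n_lipids_per_leaflet = 60, box_xy = 7, box_z = 14, seed = 42))
  }
  fx$membrane
}

fixture_params <- function() {
  if (is.null(fx$params)) fx$params <- nonbonded_params()
  fx$params
}

# a random frame of `n_mol` single-bead-per-residue molecules for oracle
# equivalence checks
random_molecule_frame <- function(seed, n_mol = 4, n_res = 8,
                                  beads_per_res = 4, box = 6) {
  withr::with_seed(seed, {
    n <- n_mol * n_res * beads_per_res
    types <- c("P5", "P4", "C1", "Qa", "Qd")
    particle_frame(
      tibble::tibble(
        name = "B", species = "PEP",
        molecule = rep(LETTERS[seq_len(n_mol)], each = n_res * beads_per_res),
        resid = rep(rep(seq_len(n_res), each = beads_per_res), n_mol),
        resname = "GLY",
        x = runif(n, 0, box), y = runif(n, 0, box), z = runif(n, 0, box),
        type = sample(types, n, replace = TRUE),
        charge = sample(c(-1, 0, 0, 1), n, replace = TRUE)),
      box = rep(box, 3))
  })
}

# minimal flat membrane patch: head beads on a grid at a given height
flat_membrane_frame <- function(z_upper = 5, z_lower = 1, box = c(6, 6, 8),
                                species = "DUPC") {
  grid <- expand.grid(x = seq(0.5, 5.5, by = 1), y = seq(0.5, 5.5, by = 1))
  n <- nrow(grid)
  mk <- function(zz, leaf, off) tibble::tibble(
    name = "PO4", species = species,
    molecule = sprintf("L_%s_%03d", leaf, seq_len(n)),
    resid = seq_len(n) + off, resname = species,
    x = grid$x, y = grid$y, z = zz,
    type = "Qa", charge = -1, leaflet = leaf, domain = "ld-annulus")
  particle_frame(dplyr::bind_rows(mk(z_upper, "upper", 0),
                                  mk(z_lower, "lower", n)),
                 box = box)
}

# append a one-bead peptide residue column to a frame
add_peptide_bead <- function(frame, z, resid = 1, molecule = "PEP_A",
                             x = 3, y = 3) {
  tbl <- dplyr::bind_rows(
    tibble::as_tibble(frame),
    tibble::tibble(name = "BB", species = "PEP", molecule = molecule,
                   resid = resid, resname = "TRP", x = x, y = y, z = z,
                   type = "P5", charge = 0,
                   leaflet = NA_character_, domain = NA_character_))
  particle_frame(tbl, box = frame_box(frame), time = frame_time(frame))
}
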