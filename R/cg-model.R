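# Coarse-grained model of a head-to-tail cyclic peptide: bead mapping,
# cyclization (closure-bond parameters copied from a designated donor bond),
# cystine-knot disulfide constraints, loop assignment, charge bookkeeping,
# and ITP-dialect topology emission.

.cyclomem_cache <- new.env(parent = emptyenv())

#' Standard CG protein bead table
#'
#' One row per amino acid: backbone bead type, side-chain bead types and
#' integer side-chain charges (Glu/Asp -1, Lys/Arg +1), and the generic
#' backbone-side-chain bond parameters. Shipped as plain-text package data.
#'
#' @return A tibble with columns `resname`, `code`, `bb_type`, `sc_types`
#'   (list column), `sc_charges` (list column), `sc_bond_length`,
#'   `sc_bond_k`, `n_beads`.
#' @export
cg_bead_table <- function() {
  if (is.null(.cyclomem_cache$bead_table)) {
    path <- system.file("extdata", "cg_protein_beads.csv",
                        package = "cyclomem", mustWork = TRUE)
    raw <- readr::read_csv(path, show_col_types = FALSE,
                           col_types = readr::cols(
                             sc_types = readr::col_character(),
                             sc_charges = readr::col_character()))
    split_field <- function(x, as_num = FALSE) {
      lapply(x, function(s) {
        if (is.na(s) || !nzchar(s)) {
          if (as_num) numeric(0) else character(0)
        } else {
          parts <- strsplit(s, ";", fixed = TRUE)[[1]]
          if (as_num) as.numeric(parts) else parts
        }
      })
    }
    tbl <- dplyr::mutate(raw,
                         sc_types = split_field(.data$sc_types),
                         sc_charges = split_field(.data$sc_charges, TRUE))
    tbl$n_beads <- 1L + lengths(tbl$sc_types)
    .cyclomem_cache$bead_table <- tbl
  }
  .cyclomem_cache$bead_table
}

#' The 29-residue kalata B1 sequence
#'
#' One-letter sequence starting at Cys1 with the backbone cyclised between
#' Val29 and Cys1. Cysteines sit at positions 1, 5, 10, 15, 17 and 22.
#'
#' @return A length-1 character string.
#' @examples
#' kb1_sequence()
#' @export
kb1_sequence <- function() "CGETCVGGTCNTPGCTCSWPVCTRNGLPV"

#' Parse a peptide sequence into a residue table
#'
#' @param sequence Either a one-letter string (e.g. `"CGET..."`) or a
#'   character vector of three-letter residue names.
#' @return A tibble with columns `resid`, `code`, `resname`.
#' @export
parse_sequence <- function(sequence) {
  tbl <- cg_bead_table()
  if (length(sequence) == 1 && !sequence %in% tbl$resname) {
    codes <- strsplit(toupper(sequence), "")[[1]]
    idx <- match(codes, tbl$code)
    if (anyNA(idx)) {
      abort(sprintf("Unknown residue code(s): %s",
                    paste(unique(codes[is.na(idx)]), collapse = ", ")),
            class = "cyclomem_input_error")
    }
  } else {
    idx <- match(toupper(sequence), tbl$resname)
    if (anyNA(idx)) {
      abort(sprintf("Unknown residue name(s): %s",
                    paste(unique(sequence[is.na(idx)]), collapse = ", ")),
            class = "cyclomem_input_error")
    }
  }
  tibble::tibble(resid = seq_along(idx), code = tbl$code[idx],
                 resname = tbl$resname[idx])
}

#' Assign cyclotide loop labels to residues
#'
#' Cyclotide sequences are divided into six loops by their six conserved
#' cysteines. Inter-cysteine segments are labelled `loop1`..`loop5` in
#' order; the segment wrapping across the cyclization junction (after the
#' sixth cysteine, through the junction, up to the first) is `loop6`.
#' Cysteines themselves carry the label `cys`.
#'
#' @param sequence Sequence as accepted by [parse_sequence()].
#' @return A tibble with columns `resid`, `resname`, `loop`.
#' @examples
#' dplyr::filter(assign_loops(kb1_sequence()), loop == "loop5")
#' @export
assign_loops <- function(sequence) {
  res <- parse_sequence(sequence)
  n <- nrow(res)
  cys <- which(res$code == "C")
  if (length(cys) != 6) {
    abort(sprintf(
      "Loop scheme requires exactly 6 cysteines; found %d.", length(cys)),
      class = "cyclomem_input_error")
  }
  loop <- character(n)
  loop[cys] <- "cys"
  for (k in 1:5) {
    seg <- setdiff(seq(cys[k], cys[k + 1]), cys)
    loop[seg] <- paste0("loop", k)
  }
  wrap <- c(if (cys[6] < n) seq(cys[6] + 1, n),
            if (cys[1] > 1) seq(1, cys[1] - 1))
  loop[wrap] <- "loop6"
  tibble::tibble(resid = res$resid, resname = res$resname, loop = loop)
}

default_disulfides <- function(cys_positions) {
  if (length(cys_positions) != 6) {
    abort("Default cystine-knot pairing needs exactly 6 cysteines; pass `disulfides`.",
          class = "cyclomem_input_error")
  }
  # cystine-knot pattern CysI-CysIV, CysII-CysV, CysIII-CysVI
  list(cys_positions[c(1, 4)], cys_positions[c(2, 5)], cys_positions[c(3, 6)])
}

#' Build the CG topology of a (cyclic) peptide
#'
#' Emits beads, bonds and disulfide constraints for a CG peptide. When
#' `cyclic = TRUE` a closure bond joins the last residue's backbone bead to
#' the first residue's, and its parameters are *copied* from a donor
#' backbone bond (`copy_from_pair` rule): by default the first interior
#' bond whose residue names match the junction pair (for kalata B1 this is
#' the Val21-Cys22 bond, donating to the Val29-Cys1 junction).
#'
#' @param sequence Sequence as accepted by [parse_sequence()].
#' @param disulfides List of residue-index pairs forming disulfides; the
#'   default is the cystine-knot pattern (for kB1: 1-15, 5-17, 10-22).
#'   Pairs must reference cysteines.
#' @param cyclic Head-to-tail cyclisation flag.
#' @param closure_from Length-2 residue-index vector naming the donor bond
#'   for the closure parameters, or `NULL` for the automatic rule above.
#' @return A `cg_topology` object: list with tibbles `beads` (columns
#'   `bead`, `name`, `type`, `resid`, `resname`, `loop`, `charge`), `bonds`
#'   (`i`, `j`, `length`, `k`, `kind`), `constraints` (`i`, `j`, `length`,
#'   `kind`) and fields `cyclic`, `closure_donor`, `sequence`.
#' @examples
#' top <- build_cyclic_topology(kb1_sequence())
#' glance(top)
#' @export
build_cyclic_topology <- function(sequence, disulfides = NULL, cyclic = TRUE,
                                  closure_from = NULL) {
  res <- parse_sequence(sequence)
  n <- nrow(res)
  tbl <- cg_bead_table()
  ridx <- match(res$resname, tbl$resname)
  loops <- if (sum(res$code == "C") == 6) assign_loops(sequence)$loop
           else rep(NA_character_, n)

  beads <- purrr::list_rbind(lapply(seq_len(n), function(i) {
    row <- tbl[ridx[i], ]
    sc_t <- row$sc_types[[1]]
    sc_q <- row$sc_charges[[1]]
    tibble::tibble(
      name = c("BB", if (length(sc_t)) paste0("SC", seq_along(sc_t))),
      type = c(row$bb_type, sc_t),
      resid = res$resid[i], resname = res$resname[i], loop = loops[i],
      charge = c(0, sc_q))
  }))
  beads <- dplyr::mutate(beads, bead = dplyr::row_number(), .before = 1)

  bb_bead <- vapply(seq_len(n), function(i) {
    beads$bead[beads$resid == i & beads$name == "BB"]
  }, integer(1))

  bb_len <- 0.35
  bb_k <- 1250
  bonds <- tibble::tibble(
    i = bb_bead[seq_len(n - 1)], j = bb_bead[seq(2, n)],
    resid_i = seq_len(n - 1), resid_j = seq(2, n),
    length = bb_len, k = bb_k, kind = "backbone")

  closure_donor <- NULL
  if (cyclic) {
    if (is.null(closure_from)) {
      # copy_from_pair rule: first interior backbone bond whose residue
      # names equal the junction pair (resname N, resname 1)
      cand <- which(res$resname[bonds$resid_i] == res$resname[n] &
                    res$resname[bonds$resid_j] == res$resname[1])
      closure_from <- if (length(cand) > 0) {
        c(bonds$resid_i[cand[1]], bonds$resid_j[cand[1]])
      } else {
        c(n - 1, n)
      }
    }
    donor <- dplyr::filter(bonds, .data$resid_i == closure_from[1],
                           .data$resid_j == closure_from[2])
    if (nrow(donor) != 1) {
      abort(sprintf("No backbone bond between residues %d and %d to copy from.",
                    closure_from[1], closure_from[2]),
            class = "cyclomem_topology_error")
    }
    closure_donor <- closure_from
    bonds <- dplyr::bind_rows(bonds, tibble::tibble(
      i = bb_bead[n], j = bb_bead[1], resid_i = n, resid_j = 1,
      length = donor$length, k = donor$k, kind = "closure"))
  }

  # backbone-side-chain and intra-side-chain bonds
  sc_bonds <- purrr::list_rbind(lapply(seq_len(n), function(i) {
    sc <- beads$bead[beads$resid == i & beads$name != "BB"]
    if (length(sc) == 0) return(NULL)
    row <- tbl[ridx[i], ]
    chain <- c(bb_bead[i], sc)
    tibble::tibble(i = chain[-length(chain)], j = chain[-1],
                   resid_i = i, resid_j = i,
                   length = row$sc_bond_length, k = row$sc_bond_k,
                   kind = "sidechain")
  }))
  bonds <- dplyr::bind_rows(bonds, sc_bonds)

  if (is.null(disulfides)) {
    cys <- res$resid[res$code == "C"]
    disulfides <- if (length(cys) == 6) default_disulfides(cys) else list()
  }
  constraints <- purrr::list_rbind(lapply(disulfides, function(pair) {
    if (length(pair) != 2) {
      abort("Each disulfide must be a pair of residue indices.",
            class = "cyclomem_topology_error")
    }
    for (p in pair) {
      if (p < 1 || p > n || res$code[p] != "C") {
        abort(sprintf("Disulfide pair (%d, %d) names a non-cysteine residue.",
                      pair[1], pair[2]), class = "cyclomem_topology_error")
      }
    }
    sc_a <- beads$bead[beads$resid == pair[1] & beads$name == "SC1"]
    sc_b <- beads$bead[beads$resid == pair[2] & beads$name == "SC1"]
    tibble::tibble(i = sc_a, j = sc_b, length = 0.24, kind = "disulfide")
  }))
  if (is.null(constraints)) {
    constraints <- tibble::tibble(i = integer(), j = integer(),
                                  length = numeric(), kind = character())
  }

  structure(list(beads = beads,
                 bonds = dplyr::select(bonds, -"resid_i", -"resid_j"),
                 bond_residues = dplyr::select(bonds, "resid_i", "resid_j",
                                               "kind"),
                 constraints = constraints, cyclic = cyclic,
                 closure_donor = closure_donor,
                 sequence = paste(res$code, collapse = "")),
            class = "cg_topology")
}

#' @export
print.cg_topology <- function(x, ...) {
  cat(sprintf("CG topology: %d residues, %d beads, %d bonds, %d constraints, %s\n",
              max(x$beads$resid), nrow(x$beads), nrow(x$bonds),
              nrow(x$constraints),
              if (x$cyclic) "cyclic" else "linear"))
  cat(sprintf("  net charge: %+d e\n", as.integer(sum(x$beads$charge))))
  invisible(x)
}

#' @rdname build_cyclic_topology
#' @param x A `cg_topology`.
#' @param ... Unused.
#' @export
tidy.cg_topology <- function(x, ...) x$beads

#' @rdname build_cyclic_topology
#' @export
glance.cg_topology <- function(x, ...) {
  tibble::tibble(
    n_residues = max(x$beads$resid), n_beads = nrow(x$beads),
    n_bonds = nrow(x$bonds),
    n_backbone_bonds = sum(x$bonds$kind %in% c("backbone", "closure")),
    n_constraints = nrow(x$constraints),
    net_charge = sum(x$beads$charge), cyclic = x$cyclic)
}

#' Map an atomistic structure onto CG beads
#'
#' Places one backbone bead per residue at the centre of geometry of the
#' backbone atoms (N, CA, C, O, OXT) and the residue's side-chain beads at
#' centres of geometry of contiguous chunks of its side-chain heavy atoms
#' (in file order), one chunk per bead in the mapping table.
#'
#' @param atomistic_frame A [particle_frame()] of an atomistic structure.
#' @param mapping_table Bead table, default [cg_bead_table()].
#' @return A [particle_frame()] of CG beads (species `"PEP"`), with `type`
#'   and `charge` columns.
#' @export
map_atomistic_to_cg <- function(atomistic_frame, mapping_table = cg_bead_table()) {
  backbone_names <- c("N", "CA", "C", "O", "OXT", "OT1", "OT2")
  at <- tibble::as_tibble(atomistic_frame)
  at <- dplyr::filter(at, !grepl("^[0-9]*H", .data$name))  # drop hydrogens
  groups <- dplyr::group_split(dplyr::group_by(at, .data$molecule, .data$resid))
  beads <- purrr::list_rbind(lapply(groups, function(g) {
    resname <- g$resname[1]
    row <- mapping_table[match(resname, mapping_table$resname), ]
    if (is.na(row$resname[1])) {
      abort(sprintf("Residue %s %d is not in the mapping table.",
                    resname, g$resid[1]), class = "cyclomem_mapping_error")
    }
    bb_atoms <- dplyr::filter(g, .data$name %in% backbone_names)
    if (nrow(bb_atoms) == 0) {
      abort(sprintf("Residue %s %d has no backbone atoms to map.",
                    resname, g$resid[1]), class = "cyclomem_mapping_error")
    }
    sc_types <- row$sc_types[[1]]
    sc_charges <- row$sc_charges[[1]]
    sc_atoms <- dplyr::filter(g, !.data$name %in% backbone_names)
    n_sc <- length(sc_types)
    if (n_sc > 0 && nrow(sc_atoms) == 0) {
      abort(sprintf("Residue %s %d has no side-chain atoms but needs %d side-chain bead(s).",
                    resname, g$resid[1], n_sc), class = "cyclomem_mapping_error")
    }
    cog <- function(d) colMeans(as.matrix(d[, c("x", "y", "z")]))
    pos <- list(cog(bb_atoms))
    if (n_sc > 0) {
      chunk <- sort(rep_len(seq_len(n_sc), nrow(sc_atoms)))
      for (kk in seq_len(n_sc)) {
        pos[[kk + 1]] <- cog(sc_atoms[chunk == kk, ])
      }
    }
    pos <- do.call(rbind, pos)
    tibble::tibble(
      name = c("BB", if (n_sc) paste0("SC", seq_len(n_sc))),
      species = "PEP", molecule = g$molecule[1],
      resid = g$resid[1], resname = resname,
      x = unname(pos[, 1]), y = unname(pos[, 2]), z = unname(pos[, 3]),
      type = c(row$bb_type, sc_types), charge = c(0, sc_charges))
  }))
  particle_frame(beads, box = frame_box(atomistic_frame),
                 time = frame_time(atomistic_frame))
}

#' Write a CG topology as ITP-dialect text
#'
#' Emits `[ moleculetype ]`, `[ atoms ]`, `[ bonds ]` and `[ constraints ]`
#' sections. Angle/dihedral terms across the cyclisation junction are not
#' emitted: only the closure bond is (documented behaviour).
#'
#' @param topology A `cg_topology`.
#' @param path Output path.
#' @param name Molecule name.
#' @return `path`, invisibly.
#' @export
write_topology <- function(topology, path, name = "PEP") {
  b <- topology$beads
  lines <- c(
    "; CG topology written by cyclomem",
    "[ moleculetype ]",
    "; name  nrexcl",
    sprintf("%s  1", name),
    "",
    "[ atoms ]",
    ";  nr  type  resnr  residue  atom  cgnr  charge",
    sprintf("%5d %5s %5d %6s %5s %5d %8.3f",
            b$bead, b$type, b$resid, b$resname, b$name, b$bead, b$charge),
    "",
    "[ bonds ]",
    ";   i    j  funct  length  force_k",
    sprintf("%5d %5d %5d %8.3f %10.1f ; %s",
            topology$bonds$i, topology$bonds$j, 1L,
            topology$bonds$length, topology$bonds$k, topology$bonds$kind))
  if (nrow(topology$constraints) > 0) {
    lines <- c(lines, "",
               "[ constraints ]",
               ";   i    j  funct  length",
               sprintf("%5d %5d %5d %8.3f ; %s",
                       topology$constraints$i, topology$constraints$j, 1L,
                       topology$constraints$length, topology$constraints$kind))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Build a bead-level particle frame from a topology
#'
#' Places the peptide's beads on a circle (backbone) with side-chain beads
#' displaced radially: a geometric starting structure for synthetic
#' trajectories, not an energy-minimised one.
#'
#' @param topology A `cg_topology`.
#' @param center Length-3 centre position (nm).
#' @param radius Backbone circle radius (nm).
#' @param box Box lengths (nm).
#' @param molecule Molecule id to stamp on the beads.
#' @return A [particle_frame()].
#' @export
topology_frame <- function(topology, center = c(2, 2, 2), radius = 0.8,
                           box = c(16, 16, 16), molecule = "PEP_A") {
  b <- topology$beads
  n_res <- max(b$resid)
  theta <- 2 * pi * (b$resid - 1) / n_res
  r <- radius + ifelse(b$name == "BB", 0,
                       0.3 * as.integer(sub("SC", "", sub("BB", "0", b$name))))
  particle_frame(
    tibble::tibble(name = b$name, species = "PEP", molecule = molecule,
                   resid = b$resid, resname = b$resname,
                   x = center[1] + r * cos(theta),
                   y = center[2] + r * sin(theta),
                   z = center[3], type = b$type, charge = b$charge),
    box = box, time = 0)
}
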