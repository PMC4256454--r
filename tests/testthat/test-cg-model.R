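# Cyclic peptide topology: loop assignment, cyclization, charges,
# disulfide constraints, atomistic-to-CG mapping

test_that("kB1 loop assignment matches the six-loop scheme", {
  la <- assign_loops(kb1_sequence())
  expect_equal(nrow(la), 29)
  expect_equal(la$resid[la$loop == "cys"], c(1, 5, 10, 15, 17, 22))
  expect_equal(la$resid[la$loop == "loop1"], 2:4)
  expect_equal(la$resid[la$loop == "loop2"], 6:9)
  expect_equal(la$resid[la$loop == "loop3"], 11:14)
  expect_equal(la$resid[la$loop == "loop4"], 16)
  # loop 5 holds Ser18, Trp19, Pro20, Val21
  l5 <- dplyr::filter(la, loop == "loop5")
  expect_equal(l5$resid, 18:21)
  expect_equal(l5$resname, c("SER", "TRP", "PRO", "VAL"))
  # loop 6 wraps across the junction: Thr23..Val29
  l6 <- dplyr::filter(la, loop == "loop6")
  expect_equal(l6$resid, 23:29)
  expect_equal(l6$resname,
               c("THR", "ARG", "ASN", "GLY", "LEU", "PRO", "VAL"))
  # every residue carries exactly one label
  expect_true(all(table(la$resid) == 1))
})

test_that("loop assignment requires exactly six cysteines", {
  expect_error(assign_loops("CGETCVGGTCNTPGCTASWPVATRNGLPV"),
               class = "cyclomem_input_error")
  expect_error(assign_loops("AAAA"), class = "cyclomem_input_error")
})

test_that("cyclic kB1 topology has zero charge and a donor-copied closure bond", {
  top <- build_cyclic_topology(kb1_sequence(), cyclic = TRUE)
  g <- glance(top)
  expect_equal(g$net_charge, 0)
  expect_equal(g$n_backbone_bonds, 29)
  expect_equal(g$n_constraints, 3)
  # the two charged residues cancel: Glu3 -1, Arg24 +1
  by_res <- dplyr::summarise(dplyr::group_by(tidy(top), resid),
                             q = sum(charge))
  expect_equal(by_res$q[3], -1)
  expect_equal(by_res$q[24], 1)
  # closure bond parameters equal the Val21-Cys22 donor bond's
  expect_equal(top$closure_donor, c(21, 22))
  donor <- top$bond_residues$kind == "backbone" &
    top$bond_residues$resid_i == 21 & top$bond_residues$resid_j == 22
  closure <- top$bonds[top$bonds$kind == "closure", ]
  expect_equal(closure$length, top$bonds$length[donor])
  expect_equal(closure$k, top$bonds$k[donor])
  # linear build has one fewer backbone bond
  lin <- build_cyclic_topology(kb1_sequence(), cyclic = FALSE)
  expect_equal(glance(lin)$n_backbone_bonds, 28)
})

test_that("topology construction is deterministic and disulfides are distinct from bonds", {
  t1 <- build_cyclic_topology(kb1_sequence())
  t2 <- build_cyclic_topology(kb1_sequence())
  expect_identical(t1$beads, t2$beads)
  expect_identical(t1$bonds, t2$bonds)
  expect_identical(t1$constraints, t2$constraints)
  # default cystine-knot pairing
  cys_res <- t1$beads$resid[match(t1$constraints$i, t1$beads$bead)]
  cys_res2 <- t1$beads$resid[match(t1$constraints$j, t1$beads$bead)]
  expect_equal(cbind(cys_res, cys_res2),
               cbind(c(1, 5, 10), c(15, 17, 22)), ignore_attr = TRUE)
  # no disulfide duplicates a bond
  bond_keys <- paste(pmin(t1$bonds$i, t1$bonds$j),
                     pmax(t1$bonds$i, t1$bonds$j))
  con_keys <- paste(pmin(t1$constraints$i, t1$constraints$j),
                    pmax(t1$constraints$i, t1$constraints$j))
  expect_length(intersect(bond_keys, con_keys), 0)
  expect_error(build_cyclic_topology(kb1_sequence(),
                                     disulfides = list(c(1, 2))),
               class = "cyclomem_topology_error")
})

test_that("ITP emission lists every bead, bond and constraint", {
  top <- build_cyclic_topology(kb1_sequence())
  p <- withr::local_tempfile(fileext = ".itp")
  write_topology(top, p)
  txt <- readLines(p)
  expect_true(any(grepl("\\[ moleculetype \\]", txt)))
  expect_equal(sum(grepl("; backbone|; closure|; sidechain", txt)),
               nrow(top$bonds))
  expect_equal(sum(grepl("; disulfide", txt)), 3)
})

make_atomistic_residue <- function(resname, resid, at_names, center,
                                   spread = 0.05) {
  n <- length(at_names)
  tibble::tibble(name = at_names, species = resname, molecule = "chain_A",
                 resid = resid, resname = resname,
                 x = center[1] + spread * seq_len(n),
                 y = center[2], z = center[3])
}

test_that("atomistic-to-CG mapping honours bead counts and centres of geometry", {
  # glycine maps to a single backbone bead
  gly <- particle_frame(make_atomistic_residue("GLY", 1,
                                               c("N", "CA", "C", "O"),
                                               c(1, 1, 1)),
                        box = c(5, 5, 5))
  cg <- map_atomistic_to_cg(gly)
  expect_equal(nrow(cg), 1)
  expect_equal(cg$name, "BB")
  # all atoms at one point -> bead at that point
  pt <- particle_frame(make_atomistic_residue("GLY", 1,
                                              c("N", "CA", "C", "O"),
                                              c(2, 3, 4), spread = 0),
                       box = c(5, 5, 5))
  cgp <- map_atomistic_to_cg(pt)
  expect_equal(c(cgp$x, cgp$y, cgp$z), c(2, 3, 4))
  # full kB1: bead count equals an independent per-residue tally
  res <- parse_sequence(kb1_sequence())
  atoms <- purrr::list_rbind(lapply(res$resid, function(i) {
    make_atomistic_residue(res$resname[i], i,
                           c("N", "CA", "C", "O", "CB", "CG", "CD", "CE"),
                           c(i %% 5, i %/% 5, 1))
  }))
  cg_all <- map_atomistic_to_cg(particle_frame(atoms, box = c(10, 10, 10)))
  # independent count: 1 bead + side-chain beads per standard CG mapping
  sc_counts <- c(GLY = 0, ALA = 0, CYS = 1, VAL = 1, LEU = 1, ILE = 1,
                 PRO = 1, MET = 1, SER = 1, THR = 1, ASN = 1, GLN = 1,
                 ASP = 1, GLU = 1, LYS = 2, ARG = 2, HIS = 3, PHE = 3,
                 TYR = 3, TRP = 4)
  expected <- sum(1 + sc_counts[res$resname])
  expect_equal(nrow(cg_all), expected)
  # missing backbone atoms are a mapping error naming the residue
  broken <- dplyr::filter(atoms, !(resid == 19 & name %in% c("N", "CA", "C", "O")))
  expect_error(map_atomistic_to_cg(particle_frame(broken, box = c(10, 10, 10))),
               "TRP 19", class = "cyclomem_mapping_error")
})
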