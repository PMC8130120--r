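test_that("read_pdb parses fixtures and classifies chains", {
  pep <- dnahotspot:::build_peptide(c("ALA", "GLY", "LYS"))
  m <- fake_model(pep, c(A = "protein"))
  parsed <- read_pdb(paste(write_pdb(m), collapse = "\n"))
  expect_s3_class(parsed, "hs_structure")
  expect_equal(unname(parsed$chain_kinds), "protein")
  expect_equal(nrow(dnahotspot:::residue_table(parsed)), 3)

  full <- toy_model(gap = 3.5, seed = 1)
  expect_equal(full$chain_kinds, c(A = "protein", B = "DNA", C = "DNA"))
})

test_that("read_pdb rejects degenerate input", {
  dna <- dnahotspot:::build_bdna(4)
  m <- fake_model(dna, c(B = "DNA", C = "DNA"))
  expect_error(read_pdb(paste(write_pdb(m), collapse = "\n")),
               "no protein chain")
  expect_error(read_pdb("REMARK nothing here"), "no ATOM records")
  bad <- "ATOM      1  CA  ALA A   1      xx.xxx   0.000   0.000  1.00  0.00           C"
  expect_error(read_pdb(bad), "line 1")
})

test_that("classify_chain follows majority vote with ties to other", {
  expect_equal(classify_chain(c("ALA", "GLY", "LYS")), "protein")
  expect_equal(classify_chain(c("DA", "DT", "DG")), "DNA")
  expect_equal(classify_chain("HOH"), "other")
  expect_equal(classify_chain(c("ALA", "DA")), "other")
})

test_that("altloc resolution keeps the highest-occupancy conformer", {
  lines <- c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       1.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CB AALA A   1       2.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CB BALA A   1       3.000   0.000   0.000  0.50  0.00           C")
  m <- read_pdb(paste(lines, collapse = "\n"))
  expect_equal(nrow(m$atoms), 2)
  expect_equal(m$atoms$x[m$atoms$name == "CA"], 1.0)  # occupancy 0.6 wins
  expect_equal(m$atoms$x[m$atoms$name == "CB"], 2.0)  # tie -> altloc A
})

test_that("multi-model files keep model 1 only", {
  one <- "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C"
  two <- "ATOM      1  CA  ALA A   1       9.000   9.000   9.000  1.00  0.00           C"
  txt <- paste(c("MODEL        1", one, "ENDMDL",
                 "MODEL        2", two, "ENDMDL"), collapse = "\n")
  m <- read_pdb(txt)
  expect_equal(nrow(m$atoms), 1)
  expect_equal(m$atoms$x, 0)
})

test_that("parse/serialize round-trip preserves atoms and coordinates", {
  m <- toy_model(gap = 5, seed = 2)
  again <- read_pdb(paste(write_pdb(m), collapse = "\n"))
  expect_equal(nrow(again$atoms), nrow(m$atoms))
  expect_equal(again$atoms$x, m$atoms$x, tolerance = 1e-3)
  expect_equal(again$atoms$y, m$atoms$y, tolerance = 1e-3)
  expect_equal(again$atoms$z, m$atoms$z, tolerance = 1e-3)
  expect_equal(again$atoms$name, m$atoms$name)
})

test_that("protein_view drops DNA atoms and freezes coordinates", {
  m <- toy_model(gap = 3.5, seed = 1)
  v <- protein_view(m)
  expect_true(all(v$atoms$chain == "A"))
  prot <- m$atoms[m$atoms$chain == "A", ]
  expect_identical(v$atoms[, c("x", "y", "z")], prot[, c("x", "y", "z")])
})

test_that("peptide far from DNA yields an empty interface", {
  m <- toy_model(gap = 30, seed = 1)
  ifc <- find_interface_residues(m, fast_sasa())
  expect_equal(nrow(ifc$residues), 0)
})

test_that("contacting residues are interfacial with positive ASA burial", {
  m <- toy_model(gap = 3.5, seed = 1)
  ifc <- find_interface_residues(m, fast_sasa())
  expect_gt(nrow(ifc$residues), 0)
  expect_true(all(ifc$residues$c_t_asa > 0))
  # brute-force differencing oracle: recompute both views directly
  p <- fast_sasa()
  mono <- residue_sasa(protein_view(m), p)
  comp <- residue_sasa(m, p)
  comp <- comp[comp$key %in% mono$key, ]
  casa <- mono$t_asa - comp$t_asa
  expect_setequal(ifc$residues$key, mono$key[casa > 0])
})

test_that("neighbor lists follow the 6.5 A C-alpha rule", {
  # three CA-only protein residues at 0, 5, 11 A along x, DNA P nearby
  atoms <- rbind(
    atom_row(1, "CA", "ALA", "A", 1, 0, 0, 0, "C"),
    atom_row(2, "CA", "ALA", "A", 2, 5, 0, 0, "C"),
    atom_row(3, "CA", "ALA", "A", 3, 11, 0, 0, "C"),
    atom_row(4, "P", "DA", "B", 1, 0, 0, 4, "P"),
    atom_row(5, "P", "DA", "B", 2, 5, 0, 4, "P"),
    atom_row(6, "P", "DA", "B", 3, 11, 0, 4, "P"))
  m <- fake_model(atoms, c(A = "protein", B = "DNA"))
  ifc <- find_interface_residues(m, fast_sasa(), criterion = "distance",
                                 contact_dist = 5)
  expect_equal(nrow(ifc$residues), 3)
  k <- ifc$residues$key
  expect_setequal(ifc$neighbors[[k[1]]], k[2])        # |0-5| <= 6.5 only
  expect_setequal(ifc$neighbors[[k[2]]], c(k[1], k[3]))
  expect_setequal(ifc$neighbors[[k[3]]], k[2])        # |5-11| = 6 <= 6.5
})

test_that("neighbor relation is symmetric and irreflexive", {
  for (seed in 1:3) {
    ifc <- find_interface_residues(toy_model(gap = 3.5, seed = seed),
                                   fast_sasa())
    for (k in names(ifc$neighbors)) {
      expect_false(k %in% ifc$neighbors[[k]])
      for (nb in ifc$neighbors[[k]]) {
        expect_true(k %in% ifc$neighbors[[nb]])
      }
    }
  }
})
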