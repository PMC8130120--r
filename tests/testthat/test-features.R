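test_that("asa_block derives bound / change / relative-change features", {
  mono <- c(s_asa = 50, s_rsa = 60, t_asa = 100, t_rsa = 80)
  comp <- c(s_asa = 20, s_rsa = 24, t_asa = 40, t_rsa = 32)
  b <- asa_block(mono, comp)
  expect_equal(b[["BtASA"]], 40)
  expect_equal(b[["CtASA"]], 60)
  expect_equal(b[["RtASA"]], 0.6)
  expect_equal(b[["RsASA"]], 0.6)
  # identity: mono == comp -> all changes zero
  same <- asa_block(mono, mono)
  expect_true(all(same[5:12] == 0))
  # degenerate denominator convention
  zero <- c(s_asa = 0, s_rsa = 0, t_asa = 0, t_rsa = 0)
  z <- asa_block(zero, zero)
  expect_true(all(z == 0))
})

test_that("INP values follow the defining ratios and conventions", {
  expect_equal(as.numeric(inp1(40, 10, c(40, 40), c(10, 10))), 0)
  expect_equal(as.numeric(inp1(80, 10, c(40, 40), c(10, 10))), 1.0)
  expect_equal(as.numeric(inp2(60, c(20, 30, 40))), 2.0)
  expect_equal(as.numeric(inp2(30, c(30))), 1.0)
  # n = 0 convention
  expect_equal(as.numeric(inp1(80, 10, numeric(0), numeric(0))), 0)
  expect_equal(as.numeric(inp2(60, numeric(0))), 0)
  # zero neighbor mean with nonzero numerator -> 0, masked
  v <- inp2(60, c(-10, 10))
  expect_equal(as.numeric(v), 0)
  expect_true(attr(v, "masked"))
})

test_that("INP implementations match brute-force oracles on random instances", {
  set.seed(7)
  for (i in 1:100) {
    n <- sample(1:5, 1)
    tm <- runif(1, 1, 100); tc <- runif(1, 0, tm)
    nm <- runif(n, 1, 100); nc <- runif(n, 0.1, 100)
    expect_equal(as.numeric(inp1(tm, tc, nm, nc)),
                 oracle_inp1(tm, tc, nm, nc), tolerance = 1e-12)
    casa <- rnorm(1); nbc <- rnorm(n)
    expect_equal(as.numeric(inp2(casa, nbc)), oracle_inp2(casa, nbc),
                 tolerance = 1e-12)
  }
})

test_that("INP features are invariant under uniform scaling of ASA values", {
  set.seed(8)
  for (i in 1:25) {
    n <- sample(1:6, 1)
    tm <- runif(1, 1, 100); tc <- runif(1, 0.1, tm)
    nm <- runif(n, 1, 100); nc <- runif(n, 0.1, 100)
    s <- runif(1, 0.1, 10)
    expect_equal(as.numeric(inp1(s * tm, s * tc, s * nm, s * nc)),
                 as.numeric(inp1(tm, tc, nm, nc)), tolerance = 1e-9)
    expect_equal(as.numeric(inp2(s * tm, s * nm)),
                 as.numeric(inp2(tm, nm)), tolerance = 1e-9)
  }
})

test_that("dihedral sign convention matches the external reference case", {
  # frozen case: verified against biotite structure.dihedral = +90 deg
  a <- c(1, 1, 0); b <- c(1, 0, 0); c0 <- c(0, 0, 0); d <- c(0, -0.5, 1.4)
  d <- dnahotspot:::place_atom(a, b, c0, 1.5, 109.5, 90)
  expect_equal(dihedral(a, b, c0, d), 90, tolerance = 1e-6)
  expect_equal(oracle_dihedral(a, b, c0, d), 90, tolerance = 1e-6)
})

test_that("psi angle: ideal strand, planar case, mirror antisymmetry", {
  pep <- dnahotspot:::build_peptide(c("ALA", "ALA", "ALA"), phi = -135,
                                    psi = 135)
  m <- fake_model(pep, c(A = "protein"))
  g <- function(key, name) dnahotspot:::residue_atom_xyz(m, key, name)
  psi <- psi_angle(g("A:1", "N"), g("A:1", "CA"), g("A:1", "C"), g("A:2", "N"))
  expect_equal(psi, 135, tolerance = 5)

  # coplanar cis arrangement -> 0
  expect_equal(dihedral(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0)), 0,
               tolerance = 1e-9)

  # mirror image flips the sign; random quadruples against the oracle
  set.seed(9)
  for (i in 1:100) {
    pts <- lapply(1:4, function(j) rnorm(3))
    ang <- dihedral(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
    mir <- lapply(pts, function(p) p * c(1, 1, -1))
    expect_equal(dihedral(mir[[1]], mir[[2]], mir[[3]], mir[[4]]), -ang,
                 tolerance = 1e-9)
    expect_equal(ang, oracle_dihedral(pts[[1]], pts[[2]], pts[[3]], pts[[4]]),
                 tolerance = 1e-9)
  }

  # chain-terminal residue -> missing, not an error
  expect_true(is.na(psi_angle(g("A:3", "N"), g("A:3", "CA"), g("A:3", "C"),
                              NULL)))
})

test_that("eigenvector centrality: path graph, complete graph, oracle", {
  # 3-node path: principal eigenvector proportional to (1, sqrt(2), 1)
  p3 <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3)
  expect_equal(dnahotspot:::eigencentrality_adj(p3),
               c(1 / sqrt(2), 1, 1 / sqrt(2)), tolerance = 1e-9)
  k4 <- 1 - diag(4)
  expect_equal(dnahotspot:::eigencentrality_adj(k4), rep(1, 4),
               tolerance = 1e-9)
  # isolated node -> 0; components normalized independently
  block <- rbind(cbind(p3, matrix(0, 3, 1)), rep(0, 4))
  expect_equal(dnahotspot:::eigencentrality_adj(block),
               c(1 / sqrt(2), 1, 1 / sqrt(2), 0), tolerance = 1e-9)

  # random connected graphs vs igraph
  set.seed(11)
  for (i in 1:10) {
    repeat {
      adj <- matrix(rbinom(64, 1, 0.4), 8, 8)
      adj <- 1 * ((adj + t(adj)) > 0)
      diag(adj) <- 0
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
      if (igraph::is_connected(g) && sum(adj) > 0) break
    }
    mine <- dnahotspot:::eigencentrality_adj(adj)
    ref <- igraph::eigen_centrality(g)$vector   # scaled to max 1 by default
    expect_equal(mine, unname(ref), tolerance = 1e-6)
  }
})

test_that("centrality of a real interface lies in [0,1] with a max of 1", {
  m <- toy_model(gap = 3.5, seed = 1)
  ifc <- find_interface_residues(m, fast_sasa())
  ev <- eigenvector_centrality(ifc, m)
  expect_true(all(ev >= 0 & ev <= 1))
  expect_equal(max(ev), 1)
})

test_that("half-sphere contact numbers split by the CA->CB hemisphere", {
  atoms <- rbind(
    atom_row(1, "N", "ALA", "A", 1, -1.45, 0, 0, "N"),
    atom_row(2, "CA", "ALA", "A", 1, 0, 0, 0, "C"),
    atom_row(3, "C", "ALA", "A", 1, 0.53, 1.43, 0, "C"),
    atom_row(4, "CB", "ALA", "A", 1, 0, 0, 1.53, "C"),
    atom_row(5, "CA", "GLY", "A", 2, 0, 0, 5, "C"))
  m <- fake_model(atoms, c(A = "protein"))
  # single contact exactly along CA->CB
  expect_equal(half_sphere_contact_numbers("A:1", m, radius = 13),
               c(up = 1, down = 0, total = 1))
  # isolated residue
  m2 <- fake_model(atoms[1:4, ], c(A = "protein"))
  expect_equal(half_sphere_contact_numbers("A:1", m2, radius = 13),
               c(up = 0, down = 0, total = 0))
  # beyond the radius
  expect_equal(half_sphere_contact_numbers("A:1", m, radius = 4),
               c(up = 0, down = 0, total = 0))
})

test_that("half-sphere counts match the brute-force oracle on random clusters", {
  set.seed(12)
  for (i in 1:20) {
    k <- sample(5:15, 1)
    cas <- matrix(rnorm(3 * k, sd = 6), k, 3)
    rows <- list(
      atom_row(1, "N", "ALA", "A", 1, -1.45, 0, 0, "N"),
      atom_row(2, "CA", "ALA", "A", 1, 0, 0, 0, "C"),
      atom_row(3, "C", "ALA", "A", 1, 0.53, 1.43, 0, "C"),
      atom_row(4, "CB", "ALA", "A", 1, 0, 0.8, 1.3, "C"))
    for (j in seq_len(k)) {
      rows[[length(rows) + 1]] <- atom_row(4 + j, "CA", "GLY", "A", 1 + j,
                                           cas[j, 1], cas[j, 2], cas[j, 3],
                                           "C")
    }
    m <- fake_model(do.call(rbind, rows), c(A = "protein"))
    mine <- half_sphere_contact_numbers("A:1", m, radius = 8)
    ref <- oracle_hse(c(0, 0, 0), c(0, 0.8, 1.3), as.data.frame(cas), 8)
    expect_equal(mine, ref)
  }
})

test_that("glycine uses a pseudo C-beta for the hemisphere axis", {
  atoms <- rbind(
    atom_row(1, "N", "GLY", "A", 1, -1.45, 0, 0, "N"),
    atom_row(2, "CA", "GLY", "A", 1, 0, 0, 0, "C"),
    atom_row(3, "C", "GLY", "A", 1, 0.53, 1.43, 0, "C"),
    atom_row(4, "CA", "ALA", "A", 2, 0, 0, 6, "C"))
  m <- fake_model(atoms, c(A = "protein"))
  out <- half_sphere_contact_numbers("A:1", m, radius = 13)
  expect_equal(out[["total"]], 1)
  expect_false(any(is.na(out)))
})

test_that("hydrogen-bond donor counting follows the geometric criteria", {
  ser_og <- function(dist) rbind(
    atom_row(1, "CA", "SER", "A", 1, -2, 0, 0, "C"),
    atom_row(2, "OG", "SER", "A", 1, 0, 0, 0, "O"),
    atom_row(3, "O1P", "DA", "B", 1, dist, 0, 0, "O"))
  m <- fake_model(ser_og(3.0), c(A = "protein", B = "DNA"))
  expect_equal(hbond_donor_count("A:1", m), 1)
  m2 <- fake_model(ser_og(4.5), c(A = "protein", B = "DNA"))
  expect_equal(hbond_donor_count("A:1", m2), 0)
})

test_that("hydrogen criteria gate the bond when explicit H present", {
  base <- rbind(
    atom_row(1, "CA", "SER", "A", 1, -2, 0, 0, "C"),
    atom_row(2, "OG", "SER", "A", 1, 0, 0, 0, "O"),
    atom_row(4, "O1P", "DA", "B", 1, 3.0, 0, 0, "O"))
  # H pointing toward the acceptor: D-H-A angle 180, H..A = 2.0 -> bonded
  good <- rbind(base, atom_row(3, "HG", "SER", "A", 1, 1.0, 0, 0, "H"))
  m <- fake_model(good, c(A = "protein", B = "DNA"))
  expect_equal(hbond_donor_count("A:1", m), 1)
  # H pointing away: angle ~0 -> rejected
  bad <- rbind(base, atom_row(3, "HG", "SER", "A", 1, -1.0, 0, 0, "H"))
  m2 <- fake_model(bad, c(A = "protein", B = "DNA"))
  expect_equal(hbond_donor_count("A:1", m2), 0)
})

test_that("donor counting equals exhaustive pair enumeration on fixtures", {
  set.seed(13)
  for (i in 1:10) {
    # lysine NZ donor amid scattered DNA phosphate oxygens
    k <- 6
    pos <- matrix(runif(3 * k, -5, 5), k, 3)
    rows <- list(atom_row(1, "NZ", "LYS", "A", 1, 0, 0, 0, "N"))
    for (j in seq_len(k)) {
      rows[[length(rows) + 1]] <- atom_row(1 + j, "OP1", "DA", "B", j,
                                           pos[j, 1], pos[j, 2], pos[j, 3],
                                           "O")
    }
    m <- fake_model(do.call(rbind, rows), c(A = "protein", B = "DNA"))
    expected <- sum(sqrt(rowSums(pos^2)) <= 3.9)
    expect_equal(hbond_donor_count("A:1", m), expected)
  }
})

test_that("featurize assembles the 24-column table", {
  m <- toy_model(gap = 3.5, seed = 1)
  ifc <- find_interface_residues(m, fast_sasa())
  ft <- featurize(m, ifc)
  expect_s3_class(ft, "hs_feature_table")
  expect_equal(names(ft)[6:29], feature_names())
  mask <- attr(ft, "mask")
  expect_equal(dim(mask), c(nrow(ft), 24))
  # every NA entry is flagged in the mask
  feat <- as.matrix(ft[, feature_names()])
  expect_true(all(mask[is.na(feat)]))
})

test_that("featurize composes the per-feature operations", {
  m <- toy_model(gap = 3.5, seed = 1)
  ifc <- find_interface_residues(m, fast_sasa())
  ft <- featurize(m, ifc)
  k <- ft[1, ]
  key <- dnahotspot:::residue_key(k$chain, k$resnum, k$icode)
  mono <- ifc$mono[ifc$mono$key == key, ]
  comp <- ifc$comp[ifc$comp$key == key, ]
  expect_equal(k$CtASA, mono$t_asa - comp$t_asa)
  expect_equal(k$BsASA, comp$s_asa)
  expect_equal(k$DN, hbond_donor_count(key, m))
  expect_equal(k$HbCN,
               half_sphere_contact_numbers(key, m)[["total"]])
  nb <- ifc$neighbors[[key]]
  if (length(nb)) {
    rownames(ifc$mono) <- ifc$mono$key
    rownames(ifc$comp) <- ifc$comp$key
    expect_equal(k[["INP1-tASA"]],
                 as.numeric(inp1(mono$t_asa, comp$t_asa,
                                 ifc$mono[nb, "t_asa"],
                                 ifc$comp[nb, "t_asa"])))
  }
})

test_that("geometric features are rigid-motion invariant", {
  m <- toy_model(gap = 3.5, seed = 1)
  set.seed(21)
  rot <- dnahotspot:::random_rotation()
  shift <- rnorm(3, sd = 15)
  m2 <- m
  m2$atoms[, c("x", "y", "z")] <-
    dnahotspot:::rigid_transform(as.matrix(m$atoms[, c("x", "y", "z")]),
                                 rot, shift)
  ifc <- find_interface_residues(m, fast_sasa())
  ifc2 <- find_interface_residues(m2, fast_sasa())
  expect_setequal(ifc$residues$key, ifc2$residues$key)
  common <- intersect(ifc$residues$key, ifc2$residues$key)
  ft <- featurize(m, ifc)
  ft2 <- featurize(m2, ifc2)
  for (col in c("Psi", "Eig", "HbCN", "DN")) {
    expect_equal(ft[[col]], ft2[[col]], tolerance = 1e-6, info = col)
  }
})
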