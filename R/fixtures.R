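# Synthetic fixtures: ideal-geometry toy protein-DNA complexes (PDB text) and
# labelled feature tables with controlled signal and correlation structure.

# atoms data frame in hs_structure layout
new_atoms <- function(serial, name, resname, chain, resseq, x, y, z,
                      element, het = FALSE) {
  data.frame(het = het, serial = serial, name = name, altloc = " ",
             resname = resname, chain = chain, resseq = resseq, icode = "",
             x = x, y = y, z = z, occupancy = 1, element = element,
             stringsAsFactors = FALSE)
}

# Extended polypeptide from ideal internal coordinates (N/CA/C/O/CB heavy
# atoms; glycine has no CB). phi/psi default to a beta-strand conformation.
build_peptide <- function(resnames, phi = -135, psi = 135, chain = "A",
                          start_serial = 1L) {
  n <- length(resnames)
  stopifnot(n >= 1)
  # bond lengths / angles: standard peptide values
  bN_CA <- 1.458; bCA_C <- 1.525; bC_N <- 1.329; bC_O <- 1.231
  aN_CA_C <- 111.2; aCA_C_N <- 116.2; aC_N_CA <- 121.7; aCA_C_O <- 120.8
  omega <- 180

  Ns <- CAs <- Cs <- vector("list", n)
  Ns[[1]] <- c(0, 0, 0)
  CAs[[1]] <- c(bN_CA, 0, 0)
  th <- (180 - aN_CA_C) * pi / 180
  Cs[[1]] <- CAs[[1]] + bCA_C * c(cos(th), sin(th), 0)
  for (i in seq_len(n - 1)) {
    Ns[[i + 1]] <- place_atom(Ns[[i]], CAs[[i]], Cs[[i]], bC_N, aCA_C_N, psi)
    CAs[[i + 1]] <- place_atom(CAs[[i]], Cs[[i]], Ns[[i + 1]], bN_CA, aC_N_CA,
                               omega)
    Cs[[i + 1]] <- place_atom(Cs[[i]], Ns[[i + 1]], CAs[[i + 1]], bCA_C,
                              aN_CA_C, phi)
  }

  rows <- list()
  serial <- start_serial
  for (i in seq_len(n)) {
    # carbonyl O: anti to the next amide N across the C(i) plane
    o <- place_atom(Ns[[i]], CAs[[i]], Cs[[i]], bC_O, aCA_C_O, psi - 180)
    atoms <- list(N = Ns[[i]], CA = CAs[[i]], C = Cs[[i]], O = o)
    if (resnames[i] != "GLY") {
      atoms$CB <- ideal_cb(Ns[[i]], CAs[[i]], Cs[[i]])
    }
    for (nm in names(atoms)) {
      rows[[length(rows) + 1]] <- new_atoms(
        serial, nm, resnames[i], chain, i,
        atoms[[nm]][1], atoms[[nm]][2], atoms[[nm]][3],
        substr(nm, 1, 1))
      serial <- serial + 1L
    }
  }
  do.call(rbind, rows)
}

# Idealized B-DNA duplex backbone: helical rise 3.4 A, twist 36 deg, sugar-
# phosphate atoms on an ~9 A radius shell plus a glycosidic-nitrogen anchor.
# Crude but parseable, clash-free geometry sufficient for surface/contact/
# hydrogen-bond computations.
build_bdna <- function(n_bp, chains = c("B", "C"), start_serial = 1000L) {
  stopifnot(n_bp >= 1)
  # atom template: name, radius, angular offset (deg), z offset, element
  tmpl <- data.frame(
    name = c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "C3'", "O3'", "N9"),
    r = c(8.9, 9.9, 9.4, 8.5, 8.0, 7.4, 7.8, 8.4, 4.6),
    dphi = c(0, 4, -6, 7, 14, 22, 30, 38, 26),
    dz = c(0, 0.7, -0.8, 0.35, 0.7, 1.0, 1.3, 1.65, 0.6),
    element = c("P", "O", "O", "O", "C", "C", "C", "O", "N"),
    stringsAsFactors = FALSE
  )
  bases <- rep(c("DA", "DT", "DG", "DC"), length.out = n_bp)
  comp <- c(DA = "DT", DT = "DA", DG = "DC", DC = "DG")
  rows <- list()
  serial <- start_serial
  for (strand in 1:2) {
    for (t in seq_len(n_bp)) {
      step <- if (strand == 1) t else n_bp - t + 1L
      base <- if (strand == 1) bases[t] else unname(comp[bases[step]])
      sgn <- if (strand == 1) 1 else -1
      phi0 <- step * 36 + if (strand == 1) 0 else 154   # minor-groove offset
      for (k in seq_len(nrow(tmpl))) {
        ang <- (phi0 + sgn * tmpl$dphi[k]) * pi / 180
        z <- step * 3.4 + sgn * tmpl$dz[k]
        nm <- tmpl$name[k]
        if (nm == "N9" && base %in% c("DT", "DC")) nm <- "N1"
        rows[[length(rows) + 1]] <- new_atoms(
          serial, nm, base, chains[strand], t,
          tmpl$r[k] * cos(ang), tmpl$r[k] * sin(ang), z, tmpl$element[k])
        serial <- serial + 1L
      }
    }
  }
  do.call(rbind, rows)
}

#' Generate a synthetic toy protein-DNA complex
#'
#' Builds an ideal extended peptide (heavy backbone atoms plus C-beta) and an
#' idealized B-DNA duplex backbone, and positions the peptide so that its
#' closest heavy atom lies `gap` Angstrom from the closest DNA atom. The
#' random seed controls the peptide sequence and a small (0.01 A) coordinate
#' jitter; output is deterministic given the parameters.
#'
#' @param peptide_len Number of peptide residues (>= 3).
#' @param dna_len Number of DNA base pairs (>= 3).
#' @param gap Inter-molecular gap in Angstrom (>= 0).
#' @param seed RNG seed.
#' @return Character vector of PDB-format lines (chain A = protein, chains
#'   B/C = DNA).
#' @export
make_toy_complex <- function(peptide_len = 8, dna_len = 6, gap = 3.5,
                             seed = 1) {
  stopifnot(peptide_len >= 3, dna_len >= 3, gap >= 0)
  with_seed(seed, {
    resnames <- sample(setdiff(AMINO_ACIDS_3, "GLY"), peptide_len,
                       replace = TRUE)
    pep <- build_peptide(resnames)
    dna <- build_bdna(dna_len)
    jitter <- matrix(rnorm(3 * (nrow(pep) + nrow(dna)), sd = 0.01), ncol = 3)
  })
  pep[, c("x", "y", "z")] <- pep[, c("x", "y", "z")] +
    jitter[seq_len(nrow(pep)), ]
  dna[, c("x", "y", "z")] <- dna[, c("x", "y", "z")] +
    jitter[nrow(pep) + seq_len(nrow(dna)), ]

  # orient the peptide long axis along z (parallel to the helix axis) and
  # walk it in along +x until the closest approach equals the gap
  pxyz <- as.matrix(pep[, c("x", "y", "z")])
  pxyz <- pxyz - matrix(colMeans(pxyz), nrow(pxyz), 3, byrow = TRUE)
  ax <- unitv(prcomp(pxyz, center = FALSE)$rotation[, 1])
  # rotation taking ax -> z
  z <- c(0, 0, 1)
  v <- cross3(ax, z)
  if (vnorm(v) < 1e-8) {
    rot <- diag(3)
  } else {
    s <- vnorm(v); cth <- sum(ax * z)
    vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
                 byrow = TRUE)
    rot <- diag(3) + vx + vx %*% vx * ((1 - cth) / s^2)
  }
  pxyz <- pxyz %*% t(rot)
  pxyz[, 3] <- pxyz[, 3] + mean(dna$z)
  pxyz[, 1] <- pxyz[, 1] + 40          # start well outside the duplex
  dxyz <- as.matrix(dna[, c("x", "y", "z")])
  for (it in 1:4) {
    dmin <- min_pair_dist(pxyz, dxyz)
    pxyz[, 1] <- pxyz[, 1] - (dmin - gap)
  }
  pep[, c("x", "y", "z")] <- pxyz

  model <- structure(list(atoms = rbind(pep, dna),
                          chain_kinds = c(A = "protein", B = "DNA", C = "DNA"),
                          source = "toy_complex"),
                     class = "hs_structure")
  write_pdb(model)
}

min_pair_dist <- function(a, b) {
  m <- Inf
  for (i in seq_len(nrow(a))) {
    d2 <- (b[, 1] - a[i, 1])^2 + (b[, 2] - a[i, 2])^2 + (b[, 3] - a[i, 3])^2
    m <- min(m, min(d2))
  }
  sqrt(m)
}

#' Generate a synthetic labelled feature table
#'
#' Emulates the residue-by-feature training table: informative features are
#' class-shifted Gaussians (standardized mean difference `effect_size`),
#' noise features are class-independent standard Gaussians, and each planted
#' correlated pair adds one extra feature built from a parent feature as
#' `r * parent + sqrt(1 - r^2) * noise`, hitting the target correlation in
#' expectation.
#'
#' @param n_pos,n_neg Samples per class (defaults 62 hot spots / 88 non-hot
#'   spots, the reference training composition).
#' @param n_informative Number of class-informative features.
#' @param effect_size Standardized mean shift of informative features
#'   (default 1).
#' @param n_noise Number of uninformative features.
#' @param n_pairs Number of planted correlated pairs (each adds one feature).
#' @param pair_r Target Pearson correlation of planted pairs.
#' @param seed RNG seed.
#' @return An `hs_feature_table`-like data frame with columns `F01..`,
#'   `label`, and attributes `informative` (column names carrying signal),
#'   `pairs` (data frame parent/partner/target r).
#' @export
make_feature_table <- function(n_pos = 62, n_neg = 88, n_informative = 4,
                               effect_size = 1.0, n_noise = 20 - 4,
                               n_pairs = 4, pair_r = 0.95, seed = 1) {
  stopifnot(n_pos >= 0, n_neg >= 0, n_informative >= 0, n_noise >= 0,
            n_pairs >= 0, abs(pair_r) < 1)
  n <- n_pos + n_neg
  p_base <- n_informative + n_noise
  stopifnot(n_pairs == 0 || p_base >= 1)
  with_seed(seed, {
    y <- c(rep(1, n_pos), rep(0, n_neg))
    x <- matrix(rnorm(n * p_base), n, p_base)
    if (n_informative > 0) {
      x[y == 1, seq_len(n_informative)] <-
        x[y == 1, seq_len(n_informative)] + effect_size
    }
    parents <- if (n_pairs > 0) {
      rep_len(seq_len(p_base), n_pairs)     # deterministic parent choice
    } else integer(0)
    extra <- matrix(0, n, n_pairs)
    for (k in seq_len(n_pairs)) {
      par <- x[, parents[k]]
      parc <- (par - mean(par)) / sd(par)
      extra[, k] <- pair_r * parc + sqrt(1 - pair_r^2) * rnorm(n)
    }
  })
  x <- cbind(x, extra)
  p <- ncol(x)
  colnames(x) <- sprintf("F%02d", seq_len(p))
  tab <- as.data.frame(x)
  tab$label <- y
  informative <- character(0)
  if (n_informative > 0) informative <- colnames(x)[seq_len(n_informative)]
  pairs <- data.frame(parent = colnames(x)[parents],
                      partner = colnames(x)[p_base + seq_len(n_pairs)],
                      target_r = rep(pair_r, n_pairs),
                      stringsAsFactors = FALSE)
  # partners of informative parents also carry class signal
  informative <- c(informative, pairs$partner[pairs$parent %in% informative])
  attr(tab, "informative") <- informative
  attr(tab, "pairs") <- pairs
  tab
}
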