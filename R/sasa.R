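# Solvent-accessible surface area: Shrake-Rupley numerical integration on a
# deterministic Fibonacci sphere lattice, with per-residue totals and relative
# accessibility against a self-consistent extended-tripeptide reference.

#' Surface-area computation parameters
#'
#' @param probe Probe (solvent) radius in Angstrom. Default 1.4 (water).
#' @param n_points Test points per atom sphere. Default 960.
#' @param vdw Named van der Waals radius table (Angstrom, by element symbol).
#' @param default_radius Radius for elements missing from `vdw`; `NA` (the
#'   default) makes an unknown element an error.
#' @return A list of class `sasa_params`.
#' @export
sasa_params <- function(probe = 1.4, n_points = 960, vdw = DEFAULT_VDW,
                        default_radius = NA_real_) {
  stopifnot(probe >= 0, n_points >= 24)
  structure(list(probe = probe, n_points = n_points, vdw = vdw,
                 default_radius = default_radius),
            class = "sasa_params")
}

# deterministic golden-angle spiral on the unit sphere
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

atom_radii <- function(elements, params) {
  r <- unname(params$vdw[elements])
  unknown <- is.na(r)
  if (any(unknown)) {
    if (is.na(params$default_radius)) {
      stop("no van der Waals radius for element(s): ",
           paste(unique(elements[unknown]), collapse = ", "))
    }
    r[unknown] <- params$default_radius
  }
  r
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' Each atom is surrounded by a sphere of radius `r_vdw + probe` carrying a
#' deterministic Fibonacci lattice of test points; the accessible area is the
#' exposed-point fraction times the sphere area. Hydrogens (radius 0) get
#' zero area and do not occlude.
#'
#' @param xyz Numeric matrix (n x 3) of atom coordinates in Angstrom.
#' @param elements Character vector of element symbols (length n).
#' @param params A [sasa_params()] object.
#' @param lattice Optional unit-sphere point matrix overriding the default
#'   Fibonacci lattice (e.g. a rotated copy, for exact rigid-motion
#'   invariance checks).
#' @return Numeric vector of per-atom ASA in square Angstrom.
#' @export
shrake_rupley <- function(xyz, elements, params = sasa_params(),
                          lattice = NULL) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3, nrow(xyz) == length(elements))
  r <- atom_radii(elements, params)
  n <- nrow(xyz)
  out <- numeric(n)
  heavy <- r > 0
  if (!any(heavy)) return(out)
  pts <- if (is.null(lattice)) fibonacci_sphere(params$n_points) else lattice
  probe <- params$probe
  ext <- r + probe
  hxyz <- xyz[heavy, , drop = FALSE]
  hext <- ext[heavy]
  for (i in which(heavy)) {
    ri <- ext[i]
    ci <- xyz[i, ]
    # candidate occluders: heavy atoms whose extended spheres intersect atom i's
    d2 <- (hxyz[, 1] - ci[1])^2 + (hxyz[, 2] - ci[2])^2 + (hxyz[, 3] - ci[3])^2
    nb <- which(d2 > 1e-12 & d2 < (ri + hext)^2)
    if (!length(nb)) {
      out[i] <- 4 * pi * ri^2
      next
    }
    p <- pts * ri
    p[, 1] <- p[, 1] + ci[1]; p[, 2] <- p[, 2] + ci[2]; p[, 3] <- p[, 3] + ci[3]
    exposed <- rep(TRUE, nrow(p))
    for (j in nb) {
      cj <- hxyz[j, ]
      rj2 <- hext[j]^2
      occ <- (p[, 1] - cj[1])^2 + (p[, 2] - cj[2])^2 + (p[, 3] - cj[3])^2 < rj2
      exposed <- exposed & !occ
      if (!any(exposed)) break
    }
    out[i] <- 4 * pi * ri^2 * mean(exposed)
  }
  out
}

#' Per-residue surface areas for a structure view
#'
#' @param model An `hs_structure` (the bound complex or the [protein_view()]
#'   monomer).
#' @param params A [sasa_params()] object.
#' @return Data frame, one row per residue: `key`, `chain`, `resseq`, `icode`,
#'   `resname`, `t_asa`, `s_asa` (total / side-chain absolute ASA, sq.
#'   Angstrom), `t_rsa`, `s_rsa` (relative ASA, percent; `NA` when the residue
#'   type has no reference value).
#' @details Total ASA is the sum over the residue's heavy atoms; side-chain
#'   ASA sums the non-backbone heavy atoms (backbone = N, CA, C, O, OXT), so
#'   glycine's side-chain ASA is 0 by convention. Relative ASA divides by the
#'   residue type's reference maximum from [rsa_reference()].
#' @export
residue_sasa <- function(model, params = sasa_params()) {
  a <- model$atoms
  asa <- shrake_rupley(a[, c("x", "y", "z")], a$element, params)
  key <- atom_keys(a)
  res <- residue_table(model)
  sidechain <- !(a$name %in% BACKBONE_ATOMS) & a$element != "H"
  t_asa <- vapply(res$key, function(k) sum(asa[key == k]), numeric(1))
  s_asa <- vapply(res$key, function(k) sum(asa[key == k & sidechain]), numeric(1))
  ref <- rsa_reference(params)
  rt <- ref$total[res$resname]
  rs <- ref$side[res$resname]
  res$t_asa <- unname(t_asa)
  res$s_asa <- unname(s_asa)
  res$t_rsa <- unname(100 * t_asa / rt)
  res$s_rsa <- unname(ifelse(rs > 0, 100 * s_asa / rs, ifelse(s_asa == 0, 0, NA)))
  res
}

#' Reference maximum accessibilities for relative ASA
#'
#' The reference for residue type X is the surface of X in an extended
#' Ala-X-Ala host tripeptide built from ideal internal coordinates and scored
#' with the same lattice, radii and probe as the query -- a self-consistent
#' construction in the spirit of the classical tripeptide normalization
#' tables. Computed once per parameter set and memoized.
#'
#' @param params A [sasa_params()] object.
#' @return List with named numeric vectors `total` and `side` (sq. Angstrom
#'   per residue type).
#' @export
rsa_reference <- function(params = sasa_params()) {
  tag <- paste0("rsaref:", params$probe, ":", params$n_points, ":",
                paste(names(params$vdw), params$vdw, collapse = ","))
  hit <- .hs_cache[[tag]]
  if (!is.null(hit)) return(hit)
  total <- side <- setNames(numeric(length(AMINO_ACIDS_3)), AMINO_ACIDS_3)
  for (aa in AMINO_ACIDS_3) {
    pep <- build_peptide(c("ALA", aa, "ALA"), phi = -135, psi = 135)
    asa <- shrake_rupley(pep[, c("x", "y", "z")], pep$element, params)
    mid <- pep$resseq == 2L
    total[aa] <- sum(asa[mid])
    side[aa] <- sum(asa[mid & !(pep$name %in% BACKBONE_ATOMS)])
  }
  out <- list(total = total, side = side)
  .hs_cache[[tag]] <- out
  out
}

#' Write a per-residue accessibility table
#'
#' TSV dump mirroring the usual `.rsa` column semantics: absolute and
#' relative ASA for all atoms and for side chains.
#'
#' @param model An `hs_structure`.
#' @param path Output TSV path.
#' @param params A [sasa_params()] object.
#' @return The table, invisibly.
#' @export
write_sasa_table <- function(model, path, params = sasa_params()) {
  tab <- residue_sasa(model, params)
  names(tab)[names(tab) %in% c("t_asa", "s_asa", "t_rsa", "s_rsa")] <-
    c("ABS_ALL", "ABS_SIDE", "REL_ALL", "REL_SIDE")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
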