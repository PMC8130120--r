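# The 24-feature structural encoding of an interface residue: bound/change/
# relative-change ASA block, network centrality, backbone psi, half-sphere
# contact numbers, hydrogen-bond donor count, and the interfacial
# neighborhood properties INP1/INP2.

FEATURE_NAMES <- c(
  "BsASA", "BsRSA", "BtASA", "BtRSA",
  "CsASA", "CsRSA", "CtASA", "CtRSA",
  "RsASA", "RsRSA", "RtASA", "RtRSA",
  "Eig", "Psi", "HbCN", "DN",
  "INP1-sASA", "INP1-sRSA", "INP1-tASA", "INP1-tRSA",
  "INP2-CsASA", "INP2-CsRSA", "INP2-CtASA", "INP2-CtRSA"
)

#' Feature names of the 24-column encoding
#' @return Character vector of the 24 feature names, in canonical order.
#' @export
feature_names <- function() FEATURE_NAMES

#' Surface-area feature block for one residue
#'
#' From the four accessibility components (side-chain/total x absolute/
#' relative) of a residue in the unbound monomer (`mono`) and the bound
#' complex (`comp`), derives the 12 ASA features: bound values `B*`, changes
#' on binding `C* = mono - comp`, and relative changes `R* = C*/mono` (0 by
#' convention when the monomer value is 0).
#'
#' @param mono,comp Numeric vectors with elements `s_asa`, `s_rsa`, `t_asa`,
#'   `t_rsa` (as produced by [residue_sasa()]).
#' @return Named numeric vector of 12 features.
#' @export
asa_block <- function(mono, comp) {
  rel <- function(chg, m) ifelse(m == 0, 0, chg / m)
  c(BsASA = unname(comp["s_asa"]), BsRSA = unname(comp["s_rsa"]),
    BtASA = unname(comp["t_asa"]), BtRSA = unname(comp["t_rsa"]),
    CsASA = unname(mono["s_asa"] - comp["s_asa"]),
    CsRSA = unname(mono["s_rsa"] - comp["s_rsa"]),
    CtASA = unname(mono["t_asa"] - comp["t_asa"]),
    CtRSA = unname(mono["t_rsa"] - comp["t_rsa"]),
    RsASA = unname(rel(mono["s_asa"] - comp["s_asa"], mono["s_asa"])),
    RsRSA = unname(rel(mono["s_rsa"] - comp["s_rsa"], mono["s_rsa"])),
    RtASA = unname(rel(mono["t_asa"] - comp["t_asa"], mono["t_asa"])),
    RtRSA = unname(rel(mono["t_rsa"] - comp["t_rsa"], mono["t_rsa"])))
}

#' Interfacial neighborhood property 1
#'
#' Ratio of the target residue's unbound accessibility to the mean unbound
#' accessibility of its interfacial neighbors, minus the same ratio in the
#' bound state:
#' `INP1(i) = ASA_mono(i) / mean_j ASA_mono(j) - ASA_comp(i) / mean_j ASA_comp(j)`.
#' With no neighbors (`n = 0`) the value is 0 by convention; a zero neighbor
#' mean with a nonzero numerator yields 0 with attribute `masked = TRUE`.
#'
#' @param target_mono,target_comp Target accessibility (one component) in the
#'   unbound / bound state.
#' @param nb_mono,nb_comp Neighbor accessibilities (equal-length vectors).
#' @return Numeric scalar; attribute `masked` flags the degenerate-denominator
#'   convention.
#' @export
inp1 <- function(target_mono, target_comp, nb_mono, nb_comp) {
  stopifnot(length(nb_mono) == length(nb_comp))
  if (length(nb_mono) == 0L) return(structure(0, masked = FALSE))
  ratio <- function(num, den_mean) {
    if (den_mean == 0) {
      if (num == 0) list(v = 0, m = FALSE) else list(v = 0, m = TRUE)
    } else list(v = num / den_mean, m = FALSE)
  }
  a <- ratio(target_mono, mean(nb_mono))
  b <- ratio(target_comp, mean(nb_comp))
  structure(a$v - b$v, masked = a$m || b$m)
}

#' Interfacial neighborhood property 2
#'
#' Ratio of the target residue's accessibility change on binding to the mean
#' change over its interfacial neighbors:
#' `INP2(i) = CASA(i) / mean_j CASA(j)`. Conventions as in [inp1()].
#'
#' @param target_casa Target change-on-binding value (one component).
#' @param nb_casa Neighbor change values.
#' @return Numeric scalar with attribute `masked`.
#' @export
inp2 <- function(target_casa, nb_casa) {
  if (length(nb_casa) == 0L) return(structure(0, masked = FALSE))
  m <- mean(nb_casa)
  if (m == 0) {
    return(structure(0, masked = target_casa != 0))
  }
  structure(target_casa / m, masked = FALSE)
}

#' Backbone psi torsion angle
#'
#' Signed dihedral N(i)-CA(i)-C(i)-N(i+1) in degrees, IUPAC convention.
#'
#' @param n,ca,c Backbone coordinates of residue i.
#' @param n_next Amide-nitrogen coordinates of residue i+1.
#' @return Angle in degrees in `(-180, 180]`, or `NA` if any atom is `NULL`.
#' @export
psi_angle <- function(n, ca, c, n_next) {
  if (is.null(n) || is.null(ca) || is.null(c) || is.null(n_next)) {
    return(NA_real_)
  }
  dihedral(n, ca, c, n_next)
}

#' Eigenvector centrality of the interface residue network
#'
#' Nodes are interface residues; an (unweighted) edge joins two residues whose
#' C-alpha atoms lie within `cutoff`. The centrality of a node is its
#' component of the principal eigenvector of the adjacency matrix, computed
#' per connected component and normalized so the maximum in each component is
#' 1; isolated nodes score 0.
#'
#' @param interface An `hs_interface`.
#' @param model The `hs_structure` the interface came from.
#' @param cutoff Edge distance cutoff in Angstrom (default 7).
#' @return Named numeric vector (by residue key) in `[0, 1]`.
#' @export
eigenvector_centrality <- function(interface, model, cutoff = 7.0) {
  keys <- interface$residues$key
  stopifnot(length(keys) >= 1)
  ca <- lapply(keys, function(k) residue_atom_xyz(model, k, "CA"))
  has <- !vapply(ca, is.null, logical(1))
  out <- setNames(numeric(length(keys)), keys)
  idx <- which(has)
  if (length(idx) < 2) return(out)
  m <- do.call(rbind, ca[idx])
  adj <- as.matrix(stats::dist(m)) <= cutoff
  diag(adj) <- FALSE
  out[keys[idx]] <- eigencentrality_adj(adj * 1)
  out
}

# principal-eigenvector centrality of an adjacency matrix, per connected
# component, max-normalized; isolated nodes -> 0
eigencentrality_adj <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] > 0 & comp == 0L)
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  out <- numeric(n)
  for (k in seq_len(cid)) {
    nodes <- which(comp == k)
    if (length(nodes) == 1L) next           # isolated node -> 0
    ev <- eigen(adj[nodes, nodes, drop = FALSE], symmetric = TRUE)
    v <- abs(ev$vectors[, 1])               # Perron vector, sign-fixed
    out[nodes] <- v / max(v)
  }
  out
}

#' Half-sphere C-alpha contact numbers
#'
#' Counts the other residues' C-alpha atoms within `radius` of the target's
#' C-alpha, split into the upper and lower hemisphere defined by the target's
#' C-alpha to C-beta unit vector (glycine uses an ideal tetrahedral pseudo
#' C-beta built from N, CA, C). A zero dot product counts as "up".
#'
#' @param key Target residue key.
#' @param model An `hs_structure`.
#' @param radius Contact radius in Angstrom (default 13).
#' @return Named numeric vector `c(up, down, total)`; all `NA` when the
#'   hemisphere axis cannot be constructed.
#' @export
half_sphere_contact_numbers <- function(key, model, radius = 13.0) {
  ca <- residue_atom_xyz(model, key, "CA")
  if (is.null(ca)) return(c(up = NA_real_, down = NA_real_, total = NA_real_))
  cb <- residue_atom_xyz(model, key, "CB")
  if (is.null(cb)) {
    n <- residue_atom_xyz(model, key, "N")
    cc <- residue_atom_xyz(model, key, "C")
    if (is.null(n) || is.null(cc)) {
      return(c(up = NA_real_, down = NA_real_, total = NA_real_))
    }
    cb <- ideal_cb(n, ca, cc)
  }
  axis <- unitv(cb - ca)
  a <- model$atoms
  prot <- names(model$chain_kinds)[model$chain_kinds == "protein"]
  cas <- a[a$name == "CA" & a$chain %in% prot, , drop = FALSE]
  cas <- cas[atom_keys(cas) != key, , drop = FALSE]
  if (!nrow(cas)) return(c(up = 0, down = 0, total = 0))
  d <- cbind(cas$x - ca[1], cas$y - ca[2], cas$z - ca[3])
  within <- sqrt(rowSums(d^2)) <= radius
  dots <- d %*% axis
  up <- sum(within & dots >= 0)
  down <- sum(within & dots < 0)
  c(up = up, down = down, total = up + down)
}

#' Hydrogen bonds donated by a residue
#'
#' Counts donor--acceptor pairs in the bound complex where the target residue
#' supplies the donor heavy atom. Geometric criteria: donor--acceptor
#' distance at most 3.9 Angstrom; when an explicit hydrogen is attached to
#' the donor (within 1.3 Angstrom), additionally H--acceptor at most 2.5
#' Angstrom and donor-H-acceptor angle at least 90 degrees for some attached
#' hydrogen. Acceptors are taken from all other residues, protein and DNA.
#'
#' @param key Target residue key.
#' @param model An `hs_structure` (bound view).
#' @param dist_da Donor-acceptor distance cutoff (default 3.9).
#' @param dist_ha Hydrogen-acceptor cutoff (default 2.5).
#' @param angle_dha Minimum donor-hydrogen-acceptor angle in degrees
#'   (default 90).
#' @return Integer count of hydrogen bonds donated.
#' @export
hbond_donor_count <- function(key, model, dist_da = 3.9, dist_ha = 2.5,
                              angle_dha = 90) {
  a <- model$atoms
  akey <- atom_keys(a)
  tgt <- a[akey == key, , drop = FALSE]
  if (!nrow(tgt)) return(0L)
  dnames <- hb_donor_atoms(tgt$resname[1])
  donors <- tgt[tgt$name %in% dnames, , drop = FALSE]
  if (!nrow(donors)) return(0L)

  others <- a[akey != key, , drop = FALSE]
  acc_ok <- vapply(seq_len(nrow(others)), function(i) {
    others$name[i] %in% hb_acceptor_atoms(others$resname[i])
  }, logical(1))
  acc <- others[acc_ok, , drop = FALSE]
  if (!nrow(acc)) return(0L)

  hyd <- tgt[tgt$element == "H", , drop = FALSE]
  count <- 0L
  for (i in seq_len(nrow(donors))) {
    dxyz <- as.numeric(donors[i, c("x", "y", "z")])
    # hydrogens covalently attached to this donor
    dh <- if (nrow(hyd)) {
      hd <- sqrt((hyd$x - dxyz[1])^2 + (hyd$y - dxyz[2])^2 + (hyd$z - dxyz[3])^2)
      hyd[hd <= 1.3, , drop = FALSE]
    } else hyd
    for (j in seq_len(nrow(acc))) {
      axyz <- as.numeric(acc[j, c("x", "y", "z")])
      if (vnorm(axyz - dxyz) > dist_da) next
      if (nrow(dh)) {
        ok <- FALSE
        for (h in seq_len(nrow(dh))) {
          hxyz <- as.numeric(dh[h, c("x", "y", "z")])
          if (vnorm(axyz - hxyz) > dist_ha) next
          v1 <- dxyz - hxyz
          v2 <- axyz - hxyz
          ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) / (vnorm(v1) * vnorm(v2))))) * 180 / pi
          if (ang >= angle_dha) { ok <- TRUE; break }
        }
        if (!ok) next
      }
      count <- count + 1L
    }
  }
  count
}

#' Compute the full 24-feature table for an interface
#'
#' Assembles one feature vector per interface residue: the 12-value ASA block,
#' eigenvector centrality of the interface network, backbone psi, half-sphere
#' contact number, hydrogen-bond donor count, and the 8 interfacial
#' neighborhood properties. Values that cannot be computed (chain-terminal
#' psi, degenerate INP denominators) are `NA` in the table and flagged in the
#' mask; imputation happens at model-training time, not here.
#'
#' @param model An `hs_structure`.
#' @param interface An `hs_interface` from [find_interface_residues()].
#' @param eig_cutoff Network edge cutoff (Angstrom, default 7).
#' @param hse_radius Half-sphere contact radius (Angstrom, default 13).
#' @param id Identifier stored in the table's `pdb_id` column.
#' @return An `hs_feature_table`: data frame with key columns (`pdb_id`,
#'   `chain`, `resnum`, `icode`, `resname`) and 24 feature columns in
#'   canonical order; attribute `mask` is a logical matrix marking
#'   unavailable/conventional entries.
#' @export
featurize <- function(model, interface, eig_cutoff = 7.0, hse_radius = 13.0,
                      id = model$source) {
  res <- interface$residues
  stopifnot(nrow(res) >= 1)
  mono <- interface$mono
  comp <- interface$comp
  rownames(mono) <- mono$key
  rownames(comp) <- comp$key

  eig <- eigenvector_centrality(interface, model, cutoff = eig_cutoff)

  feat <- matrix(NA_real_, nrow(res), length(FEATURE_NAMES),
                 dimnames = list(res$key, FEATURE_NAMES))
  mask <- matrix(FALSE, nrow(res), length(FEATURE_NAMES),
                 dimnames = list(res$key, FEATURE_NAMES))

  # next-residue amide N for psi: next author-numbered residue in the chain
  restab <- residue_table(model)

  for (r in seq_len(nrow(res))) {
    k <- res$key[r]
    m <- unlist(mono[k, c("s_asa", "s_rsa", "t_asa", "t_rsa")])
    cp <- unlist(comp[k, c("s_asa", "s_rsa", "t_asa", "t_rsa")])
    feat[r, 1:12] <- asa_block(m, cp)

    feat[r, "Eig"] <- eig[[k]]

    chain_res <- restab[restab$chain == res$chain[r] & restab$kind == "protein", ]
    pos <- which(chain_res$key == k)
    n_next <- if (length(pos) == 1L && pos < nrow(chain_res)) {
      residue_atom_xyz(model, chain_res$key[pos + 1L], "N")
    } else NULL
    psi <- psi_angle(residue_atom_xyz(model, k, "N"),
                     residue_atom_xyz(model, k, "CA"),
                     residue_atom_xyz(model, k, "C"), n_next)
    feat[r, "Psi"] <- psi
    mask[r, "Psi"] <- is.na(psi)

    hse <- half_sphere_contact_numbers(k, model, radius = hse_radius)
    feat[r, "HbCN"] <- hse[["total"]]
    mask[r, "HbCN"] <- is.na(hse[["total"]])

    feat[r, "DN"] <- hbond_donor_count(k, model)

    nb <- interface$neighbors[[k]]
    inp1_cols <- c(s_asa = "INP1-sASA", s_rsa = "INP1-sRSA",
                   t_asa = "INP1-tASA", t_rsa = "INP1-tRSA")
    for (comp_i in names(inp1_cols)) {
      col1 <- inp1_cols[[comp_i]]
      v1 <- inp1(mono[k, comp_i], comp[k, comp_i],
                 mono[nb, comp_i], comp[nb, comp_i])
      feat[r, col1] <- as.numeric(v1)
      mask[r, col1] <- attr(v1, "masked")
    }
    inp2_cols <- c(s_asa = "INP2-CsASA", s_rsa = "INP2-CsRSA",
                   t_asa = "INP2-CtASA", t_rsa = "INP2-CtRSA")
    for (comp_i in names(inp2_cols)) {
      v2 <- inp2(mono[k, comp_i] - comp[k, comp_i],
                 mono[nb, comp_i] - comp[nb, comp_i])
      feat[r, inp2_cols[[comp_i]]] <- as.numeric(v2)
      mask[r, inp2_cols[[comp_i]]] <- attr(v2, "masked")
    }
  }

  mask <- mask | is.na(feat)

  out <- data.frame(pdb_id = id, chain = res$chain, resnum = res$resseq,
                    icode = res$icode, resname = res$resname,
                    stringsAsFactors = FALSE, check.names = FALSE)
  out <- cbind(out, as.data.frame(feat, check.names = FALSE))
  rownames(out) <- NULL
  attr(out, "mask") <- mask
  class(out) <- c("hs_feature_table", "data.frame")
  out
}
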