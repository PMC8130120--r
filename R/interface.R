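# Interface residue identification and the 6.5 A interfacial neighbor graph.

#' Identify interface residues and their interfacial neighbors
#'
#' A protein residue is interfacial when its total absolute ASA drops by more
#' than `threshold` square Angstrom on complex formation (unbound monomer vs
#' bound complex, coordinates frozen). Alternatively (`criterion =
#' "distance"`) when any of its heavy atoms lies within `contact_dist` of a
#' DNA heavy atom. Neighbors of an interface residue are the *other interface
#' residues* whose C-alpha lies within `neighbor_cutoff` of its C-alpha.
#'
#' @param model An `hs_structure` with at least one protein and one DNA chain.
#' @param params A [sasa_params()] object.
#' @param threshold Burial threshold in square Angstrom (default 0: any strict
#'   ASA loss).
#' @param neighbor_cutoff C-alpha--C-alpha neighbor radius in Angstrom
#'   (default 6.5).
#' @param criterion `"casa"` (ASA burial, default) or `"distance"`.
#' @param contact_dist Heavy-atom contact distance for the `"distance"`
#'   criterion (default 5 Angstrom).
#' @return An object of class `hs_interface`: list with `residues` (data
#'   frame: key columns plus the four ASA-change components `c_t_asa`,
#'   `c_s_asa`, `c_t_rsa`, `c_s_rsa`, and mono/comp ASA tables) and
#'   `neighbors` (named list of neighbor key vectors).
#' @export
find_interface_residues <- function(model, params = sasa_params(),
                                    threshold = 0, neighbor_cutoff = 6.5,
                                    criterion = c("casa", "distance"),
                                    contact_dist = 5.0) {
  criterion <- match.arg(criterion)
  kinds <- model$chain_kinds
  if (!any(kinds == "protein") || !any(kinds == "DNA")) {
    stop("interface detection needs at least one protein and one DNA chain")
  }
  mono_model <- protein_view(model)
  comp <- residue_sasa(model, params)
  mono <- residue_sasa(mono_model, params)
  comp <- comp[comp$key %in% mono$key, , drop = FALSE]
  stopifnot(identical(comp$key, mono$key))

  if (criterion == "casa") {
    sel <- (mono$t_asa - comp$t_asa) > threshold
  } else {
    dna <- dna_view(model)$atoms
    dna <- dna[dna$element != "H", , drop = FALSE]
    prot <- mono_model$atoms
    prot <- prot[prot$element != "H", , drop = FALSE]
    pk <- atom_keys(prot)
    dxyz <- as.matrix(dna[, c("x", "y", "z")])
    near <- vapply(seq_len(nrow(prot)), function(i) {
      d2 <- (dxyz[, 1] - prot$x[i])^2 + (dxyz[, 2] - prot$y[i])^2 +
        (dxyz[, 3] - prot$z[i])^2
      any(d2 <= contact_dist^2)
    }, logical(1))
    sel <- mono$key %in% unique(pk[near])
  }

  res <- mono[sel, c("key", "chain", "resseq", "icode", "resname"), drop = FALSE]
  res$c_t_asa <- (mono$t_asa - comp$t_asa)[sel]
  res$c_s_asa <- (mono$s_asa - comp$s_asa)[sel]
  res$c_t_rsa <- (mono$t_rsa - comp$t_rsa)[sel]
  res$c_s_rsa <- (mono$s_rsa - comp$s_rsa)[sel]
  rownames(res) <- NULL

  # neighbor graph over interface residues, C-alpha distance <= cutoff
  ca <- lapply(res$key, function(k) residue_atom_xyz(model, k, "CA"))
  has_ca <- !vapply(ca, is.null, logical(1))
  if (any(!has_ca)) {
    warning("interface residue(s) without CA excluded from neighbor sets: ",
            paste(res$key[!has_ca], collapse = ", "))
  }
  neighbors <- setNames(vector("list", nrow(res)), res$key)
  idx <- which(has_ca)
  if (length(idx) >= 2) {
    m <- do.call(rbind, ca[idx])
    d <- as.matrix(stats::dist(m))
    for (a in seq_along(idx)) {
      nb <- idx[which(d[a, ] <= neighbor_cutoff & seq_along(idx) != a)]
      neighbors[[res$key[idx[a]]]] <- res$key[nb]
    }
  }
  for (k in res$key) if (is.null(neighbors[[k]])) neighbors[[k]] <- character(0)

  structure(list(residues = res, neighbors = neighbors,
                 mono = mono, comp = comp,
                 params = list(threshold = threshold,
                               neighbor_cutoff = neighbor_cutoff,
                               criterion = criterion)),
            class = "hs_interface")
}

#' @export
print.hs_interface <- function(x, ...) {
  cat("<hs_interface> ", nrow(x$residues), " interface residues (criterion: ",
      x$params$criterion, ")\n", sep = "")
  invisible(x)
}

#' Write the interface residue list as TSV
#'
#' Columns: chain, resnum, icode, resname and the total-ASA change on binding.
#'
#' @param interface An `hs_interface`.
#' @param path Output path.
#' @return The table, invisibly.
#' @export
write_interface_table <- function(interface, path) {
  tab <- interface$residues[, c("chain", "resseq", "icode", "resname", "c_t_asa")]
  names(tab) <- c("chain", "resnum", "icode", "resname", "CASA")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
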