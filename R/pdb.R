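# PDB parsing, chain classification and the bound/unbound structure views.

#' Read a protein-DNA complex from a PDB file or text
#'
#' Parses `ATOM`/`HETATM` records into a structure model. Only the first model
#' of a multi-model (NMR) file is kept; waters are dropped; alternate
#' locations are resolved by keeping the highest-occupancy conformer (ties
#' broken alphabetically by altloc code).
#'
#' @param x Path to a PDB file, or a character vector/string of PDB text.
#' @param protein_chains,dna_chains Optional chain identifiers overriding the
#'   automatic residue-name-based chain classification.
#' @return An object of class `hs_structure`: a list with `atoms` (data frame
#'   of atom records with coordinates in Angstrom), `chain_kinds` (named
#'   character vector, `"protein"`, `"DNA"` or `"other"`), and `source`.
#' @export
read_pdb <- function(x, protein_chains = NULL, dna_chains = NULL) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    src <- basename(x)
    lines <- readLines(x, warn = FALSE)
  } else {
    src <- "<text>"
    lines <- unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  }

  rec <- substr(lines, 1, 6)
  # first model only
  model_starts <- which(trimws(rec) == "MODEL")
  if (length(model_starts) >= 2L) {
    endm <- which(trimws(rec) == "ENDMDL")
    stop_at <- if (length(endm)) endm[1] else model_starts[2]
    lines <- lines[seq_len(stop_at - 1L)]
    rec <- rec[seq_len(stop_at - 1L)]
  }

  sel <- which(rec %in% c("ATOM  ", "HETATM"))
  if (!length(sel)) stop("no ATOM records found in ", src)

  f <- function(from, to) substr(lines[sel], from, to)
  xyz <- suppressWarnings(cbind(
    x = as.numeric(f(31, 38)), y = as.numeric(f(39, 46)), z = as.numeric(f(47, 54))
  ))
  bad <- which(!stats::complete.cases(xyz))
  if (length(bad)) {
    stop("unparseable ATOM record at line ", sel[bad[1]], " of ", src)
  }
  occ <- suppressWarnings(as.numeric(f(55, 60)))
  occ[is.na(occ)] <- 1

  atoms <- data.frame(
    het = rec[sel] == "HETATM",
    serial = suppressWarnings(as.integer(f(7, 11))),
    name = trimws(f(13, 16)),
    altloc = f(17, 17),
    resname = trimws(f(18, 20)),
    chain = f(22, 22),
    resseq = suppressWarnings(as.integer(f(23, 26))),
    icode = trimws(f(27, 27)),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = occ,
    element = vapply(seq_along(sel),
                     function(i) guess_element(trimws(f(13, 16))[i], f(77, 78)[i]),
                     character(1)),
    stringsAsFactors = FALSE
  )
  badseq <- which(is.na(atoms$resseq))
  if (length(badseq)) {
    stop("unparseable ATOM record at line ", sel[badseq[1]], " of ", src)
  }

  atoms <- atoms[!(atoms$resname %in% WATER_RESNAMES), , drop = FALSE]
  if (!nrow(atoms)) stop("no non-water atoms in ", src)

  # altloc resolution: within each residue/atom-name keep the conformer with
  # the highest occupancy; ties -> first altloc code alphabetically (blank
  # sorts first).
  if (any(atoms$altloc != " ")) {
    key <- paste(atoms$chain, atoms$resseq, atoms$icode, atoms$name)
    ord <- order(key, -atoms$occupancy, atoms$altloc)
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resseq, atoms$icode,
                                     atoms$name)), , drop = FALSE]
    atoms <- atoms[order(atoms$serial), , drop = FALSE]
  }
  rownames(atoms) <- NULL

  res_first <- !duplicated(paste(atoms$chain, atoms$resseq, atoms$icode))
  kinds <- vapply(split(atoms$resname[res_first], atoms$chain[res_first]),
                  classify_chain, character(1))
  if (!is.null(protein_chains)) kinds[protein_chains] <- "protein"
  if (!is.null(dna_chains)) kinds[dna_chains] <- "DNA"
  if (!any(kinds == "protein")) {
    stop("structure ", src, " contains no protein chain")
  }

  structure(list(atoms = atoms, chain_kinds = kinds, source = src),
            class = "hs_structure")
}

#' Classify a chain as protein, DNA or other
#'
#' Majority vote of the chain's residue names over the standard amino-acid and
#' deoxynucleotide name tables; ties (including no recognized names) give
#' `"other"`.
#'
#' @param residue_names Character vector of three-letter residue names (one
#'   entry per residue, or per atom -- the vote is taken over unique residues
#'   only when a `resseq` structure is not available, so pass per-residue
#'   names for exact counting).
#' @return `"protein"`, `"DNA"` or `"other"`.
#' @export
classify_chain <- function(residue_names) {
  stopifnot(length(residue_names) >= 1L)
  n_prot <- sum(residue_names %in% PROTEIN_RESNAMES)
  n_dna <- sum(residue_names %in% DNA_RESNAMES)
  n_other <- length(residue_names) - n_prot - n_dna
  top <- max(n_prot, n_dna, n_other)
  winners <- c("protein", "DNA", "other")[c(n_prot, n_dna, n_other) == top]
  if (length(winners) > 1L) "other" else winners
}

#' @export
print.hs_structure <- function(x, ...) {
  cat("<hs_structure> ", x$source, ": ", nrow(x$atoms), " atoms, chains [",
      paste0(names(x$chain_kinds), ":", x$chain_kinds, collapse = ", "),
      "]\n", sep = "")
  invisible(x)
}

#' Unbound (protein-only) view of a complex
#'
#' Returns the same structure restricted to its protein chains with
#' coordinates unchanged: the monomer state used for the change-on-binding
#' surface-area features.
#'
#' @param model An `hs_structure`.
#' @return An `hs_structure` containing only protein-chain atoms.
#' @export
protein_view <- function(model) {
  keep <- names(model$chain_kinds)[model$chain_kinds == "protein"]
  out <- model
  out$atoms <- model$atoms[model$atoms$chain %in% keep, , drop = FALSE]
  rownames(out$atoms) <- NULL
  out$chain_kinds <- model$chain_kinds[keep]
  out
}

dna_view <- function(model) {
  keep <- names(model$chain_kinds)[model$chain_kinds == "DNA"]
  out <- model
  out$atoms <- model$atoms[model$atoms$chain %in% keep, , drop = FALSE]
  rownames(out$atoms) <- NULL
  out$chain_kinds <- model$chain_kinds[keep]
  out
}

# residue key: "<chain>:<resseq><icode>", PDB author numbering
residue_key <- function(chain, resseq, icode = "") {
  paste0(chain, ":", resseq, ifelse(nzchar(icode), icode, ""))
}

atom_keys <- function(atoms) residue_key(atoms$chain, atoms$resseq, atoms$icode)

# one row per residue, in file order
residue_table <- function(model) {
  a <- model$atoms
  key <- atom_keys(a)
  first <- !duplicated(key)
  data.frame(
    key = key[first], chain = a$chain[first], resseq = a$resseq[first],
    icode = a$icode[first], resname = a$resname[first],
    kind = ifelse(a$resname[first] %in% PROTEIN_RESNAMES, "protein",
                  ifelse(a$resname[first] %in% DNA_RESNAMES, "DNA", "other")),
    stringsAsFactors = FALSE
  )
}

# named coordinate lookup for one atom of one residue; NULL when absent
residue_atom_xyz <- function(model, key, atom_name) {
  a <- model$atoms
  i <- which(atom_keys(a) == key & a$name == atom_name)
  if (!length(i)) return(NULL)
  as.numeric(a[i[1], c("x", "y", "z")])
}

#' Serialize a structure model to PDB text
#'
#' @param model An `hs_structure`.
#' @param path Optional file path; when `NULL` the text is returned.
#' @return Character vector of PDB lines (invisibly when written to `path`).
#' @export
write_pdb <- function(model, path = NULL) {
  a <- model$atoms
  lines <- sprintf(
    "%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    ifelse(a$het, "HETATM", "ATOM"), a$serial %% 100000L,
    ifelse(nchar(a$name) >= 4, a$name, paste0(" ", a$name)),
    a$altloc, a$resname, a$chain, a$resseq %% 10000L,
    ifelse(nzchar(a$icode), a$icode, " "),
    a$x, a$y, a$z, a$occupancy, 0, a$element
  )
  lines <- c(lines, "END")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
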