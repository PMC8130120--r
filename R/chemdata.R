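# Static chemistry tables: residue-name classification, van der Waals radii,
# backbone atom sets, hydrogen-bond donor/acceptor atoms.

#' @name chemdata
#' @title Chemistry lookup tables
#' @description Residue-name tables used for chain classification, the default
#'   van der Waals radius set (NACCESS-style heavy-atom radii), and the
#'   hydrogen-bond donor/acceptor atom tables for protein and DNA residues.
#' @keywords internal
NULL

AMINO_ACIDS_3 <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

# MSE (selenomethionine) is ubiquitous in crystal structures; counted as protein
PROTEIN_RESNAMES <- c(AMINO_ACIDS_3, "MSE")

DNA_RESNAMES <- c("DA", "DC", "DG", "DT", "DI")

WATER_RESNAMES <- c("HOH", "WAT", "DOD")

# Backbone heavy atoms of a protein residue; everything else is side chain.
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

# NACCESS-style heavy-atom van der Waals radii (Angstrom). Hydrogens carry
# radius 0 and are excluded from surface computation.
DEFAULT_VDW <- c(C = 1.87, N = 1.65, O = 1.40, S = 1.85, P = 1.90,
                 SE = 1.90, H = 0.00, D = 0.00)

# Hydrogen-bond donor heavy atoms by residue type (protein + DNA).
# Backbone amide N is a donor for every amino acid except proline.
HB_DONORS <- list(
  ARG = c("NE", "NH1", "NH2"), ASN = "ND2", GLN = "NE2",
  HIS = c("ND1", "NE2"), LYS = "NZ", SER = "OG", THR = "OG1",
  TRP = "NE1", TYR = "OH", CYS = "SG",
  DA = "N6", DC = "N4", DG = c("N1", "N2"), DT = "N3"
)

# Hydrogen-bond acceptor heavy atoms by residue type.
HB_ACCEPTORS <- list(
  ASN = "OD1", ASP = c("OD1", "OD2"), GLN = "OE1", GLU = c("OE1", "OE2"),
  HIS = c("ND1", "NE2"), MET = "SD", SER = "OG", THR = "OG1", TYR = "OH",
  DA = c("N1", "N3", "N7"), DC = c("O2", "N3"),
  DG = c("O6", "N3", "N7"), DT = c("O2", "O4"),
  # shared DNA backbone acceptors (applied to any DNA residue)
  .dna_backbone = c("OP1", "OP2", "O1P", "O2P", "O3'", "O4'", "O5'")
)

hb_donor_atoms <- function(resname) {
  out <- HB_DONORS[[resname]]
  if (resname %in% PROTEIN_RESNAMES && resname != "PRO") out <- c("N", out)
  out
}

hb_acceptor_atoms <- function(resname) {
  out <- HB_ACCEPTORS[[resname]]
  if (resname %in% PROTEIN_RESNAMES) out <- c("O", "OXT", out)
  if (resname %in% DNA_RESNAMES) out <- c(out, HB_ACCEPTORS[[".dna_backbone"]])
  out
}

# Element symbol from a PDB atom record: prefer columns 77-78, fall back to
# parsing the atom name (digits stripped; leading H/D variants are hydrogens).
guess_element <- function(name, element = "") {
  element <- toupper(trimws(element))
  if (nzchar(element)) return(element)
  nm <- toupper(gsub("[0-9'\\*]", "", trimws(name)))
  if (nm == "") return("")
  if (substr(nm, 1, 1) %in% c("H", "D")) return("H")
  if (nm %in% c("SE", "FE", "ZN", "MG", "MN", "NA", "CL", "BR")) return(nm)
  substr(nm, 1, 1)
}
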