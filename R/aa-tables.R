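# Residue chemistry lookup tables shared across modules.

# 20 standard amino acids, three-letter -> one-letter.
AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

# Common modified residues seen in PDB entries, mapped to their canonical
# parent; supplements (and is overridden by) MODRES records in the file.
MODIFIED_AA_MAP <- c(
  MSE = "MET", SEC = "CYS", PYL = "LYS", HYP = "PRO", SEP = "SER",
  TPO = "THR", PTR = "TYR", CSO = "CYS", CME = "CYS", KCX = "LYS",
  MLY = "LYS", M3L = "LYS", FME = "MET", PCA = "GLU", CGU = "GLU",
  LLP = "LYS", CSD = "CYS", OCS = "CYS"
)

DNA_COMPONENTS <- c("DA", "DT", "DG", "DC", "DI", "DU")
RNA_COMPONENTS <- c("A", "U", "G", "C", "I")
LEGACY_DNA_COMPONENTS <- c("A", "T", "G", "C", "U")
WATER_COMPONENTS <- c("HOH", "DOD", "WAT")

#' @keywords internal
aa_one_letter <- function(comp_id, modres_map = character()) {
  comp_id <- toupper(comp_id)
  out <- character(length(comp_id))
  for (i in seq_along(comp_id)) {
    cc <- comp_id[i]
    if (cc %in% names(modres_map)) cc <- toupper(modres_map[[cc]])
    if (cc %in% names(MODIFIED_AA_MAP)) cc <- MODIFIED_AA_MAP[[cc]]
    out[i] <- if (cc %in% names(AA_THREE_TO_ONE)) AA_THREE_TO_ONE[[cc]] else "X"
  }
  out
}

#' @keywords internal
is_amino_acid <- function(comp_id, modres_map = character()) {
  aa_one_letter(comp_id, modres_map) != "X" |
    toupper(comp_id) %in% c(names(MODIFIED_AA_MAP), toupper(names(modres_map)))
}

# Hydrogen-bond donor/acceptor typing for heavy atoms of the 20 standard
# amino acids.  Backbone: N donor (except PRO), O acceptor.  Sidechain O/N
# per residue chemistry.  Values: "donor", "acceptor", "both".
# Atoms not listed are typed "neither".
DONOR_ACCEPTOR_TABLE <- local({
  tab <- list(
    backbone = c(N = "donor", O = "acceptor", OXT = "acceptor"),
    ARG = c(NE = "donor", NH1 = "donor", NH2 = "donor"),
    ASN = c(OD1 = "acceptor", ND2 = "donor"),
    ASP = c(OD1 = "acceptor", OD2 = "acceptor"),
    CYS = c(SG = "both"),
    GLN = c(OE1 = "acceptor", NE2 = "donor"),
    GLU = c(OE1 = "acceptor", OE2 = "acceptor"),
    HIS = c(ND1 = "both", NE2 = "both"),
    LYS = c(NZ = "donor"),
    MET = c(SD = "acceptor"),
    SER = c(OG = "both"),
    THR = c(OG1 = "both"),
    TRP = c(NE1 = "donor"),
    TYR = c(OH = "both")
  )
  tab
})

#' Hydrogen-bond typing of a protein heavy atom
#'
#' @param comp_id three-letter residue code
#' @param atom_name PDB atom name (stripped)
#' @return one of `"donor"`, `"acceptor"`, `"both"`, `"neither"`
#' @keywords internal
protein_atom_da_type <- function(comp_id, atom_name) {
  comp_id <- toupper(comp_id)
  atom_name <- toupper(atom_name)
  if (comp_id == "PRO" && atom_name == "N") return("neither")
  bb <- DONOR_ACCEPTOR_TABLE$backbone
  if (atom_name %in% names(bb)) return(unname(bb[[atom_name]]))
  sc <- DONOR_ACCEPTOR_TABLE[[comp_id]]
  if (!is.null(sc) && atom_name %in% names(sc)) return(unname(sc[[atom_name]]))
  "neither"
}

#' Hydrogen-bond typing of a partner (ligand/DNA/peptide) heavy atom
#'
#' Arbitrary ligand chemistry is unknown, so typing is element-based:
#' nitrogen and oxygen are treated as both donor and acceptor (the safe
#' superset), sulfur as acceptor, everything else as neither.  Peptide
#' partners with standard residues get the protein table instead.
#' @keywords internal
partner_atom_da_type <- function(comp_id, atom_name, element) {
  comp_id <- toupper(comp_id)
  if (comp_id %in% names(AA_THREE_TO_ONE)) {
    return(protein_atom_da_type(comp_id, atom_name))
  }
  el <- toupper(element)
  if (el %in% c("N", "O")) "both" else if (el == "S") "acceptor" else "neither"
}

# ClustalX residue coloring classes (canonical palette).
CLUSTALX_CLASS <- c(
  A = "hydrophobic", I = "hydrophobic", L = "hydrophobic", M = "hydrophobic",
  F = "hydrophobic", W = "hydrophobic", V = "hydrophobic", C = "cysteine",
  K = "positive", R = "positive",
  E = "negative", D = "negative",
  N = "polar", Q = "polar", S = "polar", T = "polar",
  G = "glycine", P = "proline",
  H = "aromatic", Y = "aromatic",
  X = "unconserved"
)

CLUSTALX_COLORS <- c(
  hydrophobic = "#80a0f0", positive = "#f01505", negative = "#c048c0",
  polar = "#15c015", cysteine = "#f08080", glycine = "#f09048",
  proline = "#c0c000", aromatic = "#15a4a4", unconserved = "#ffffff"
)
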