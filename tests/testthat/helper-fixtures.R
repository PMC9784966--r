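# Hand-written PDB text fixtures with exact column control.

pdb_line <- function(serial, name, comp, chain, resno, xyz,
                     icode = " ", alt = " ", occ = 1.00, element = NULL,
                     het = FALSE) {
  if (is.null(element)) element <- substr(name, 1, 1)
  sprintf("%s%5d %s%s%3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          if (het) "HETATM" else "ATOM  ", serial,
          if (nchar(name) >= 4) substr(name, 1, 4) else sprintf(" %-3s", name),
          alt, comp, chain, resno, icode,
          xyz[1], xyz[2], xyz[3], occ, 0, element)
}

# Minimal 3-residue ALA peptide (N/CA/C/O only, arbitrary but sane coords).
minimal_ala_pdb <- function() {
  lines <- character(0)
  s <- 0L
  for (i in 1:3) {
    base <- c((i - 1) * 3.8, 0, 0)
    for (at in list(c("N", 0, 0, 0), c("CA", 1.46, 0, 0),
                    c("C", 2.0, 1.3, 0), c("O", 3.2, 1.4, 0))) {
      s <- s + 1L
      lines <- c(lines, pdb_line(s, at[1], "ALA", "A", i,
                                 base + as.numeric(at[2:4])))
    }
  }
  paste(c(lines, "END"), collapse = "\n")
}

# Two MODEL blocks with different coordinates for the same single atom.
two_model_pdb <- function() {
  paste(c(
    "MODEL        1",
    pdb_line(1, "CA", "ALA", "A", 1, c(1, 1, 1)),
    "ENDMDL",
    "MODEL        2",
    pdb_line(1, "CA", "ALA", "A", 1, c(9, 9, 9)),
    "ENDMDL",
    "END"), collapse = "\n")
}

# ALA(10), GLY(11), MSE(12) with a MODRES record mapping MSE -> MET.
modres_pdb <- function() {
  paste(c(
    "MODRES 1ABC MSE A   12  MET  SELENOMETHIONINE",
    pdb_line(1, "CA", "ALA", "A", 10, c(0, 0, 0)),
    pdb_line(2, "CA", "GLY", "A", 11, c(3.8, 0, 0)),
    pdb_line(3, "CA", "MSE", "A", 12, c(7.6, 0, 0), het = TRUE,
             element = "C"),
    "END"), collapse = "\n")
}

# Residues numbered 5, 6, 9, 10 (gap at 7-8).
gap_pdb <- function() {
  lines <- vapply(seq_along(c(5, 6, 9, 10)), function(k) {
    n <- c(5, 6, 9, 10)[k]
    pdb_line(k, "CA", "ALA", "A", n, c(k * 3.8, 0, 0))
  }, "")
  paste(c(lines, "END"), collapse = "\n")
}

# Insertion codes: 52, 52A, 53.
icode_pdb <- function() {
  paste(c(
    pdb_line(1, "CA", "SER", "A", 52, c(0, 0, 0)),
    pdb_line(2, "CA", "GLY", "A", 52, c(3.8, 0, 0), icode = "A"),
    pdb_line(3, "CA", "ALA", "A", 53, c(7.6, 0, 0)),
    "END"), collapse = "\n")
}

# Alternate locations: two A-alt/B-alt copies of one CA with different
# occupancies, B placed first in the file.
altloc_pdb <- function() {
  paste(c(
    pdb_line(1, "CA", "ALA", "A", 1, c(9, 9, 9), alt = "B", occ = 0.4),
    pdb_line(2, "CA", "ALA", "A", 1, c(1, 1, 1), alt = "A", occ = 0.6),
    pdb_line(3, "CA", "ALA", "A", 2, c(3.8, 0, 0)),
    "END"), collapse = "\n")
}

# SER whose OG sits exactly 3.0 A from a lone ligand carbonyl O; every
# other protein atom is > 3.9 A from the ligand.
ser_ligand_pdb <- function() {
  paste(c(
    pdb_line(1, "N", "SER", "A", 1, c(-8, 0, 0)),
    pdb_line(2, "CA", "SER", "A", 1, c(-6.5, 0, 0)),
    pdb_line(3, "C", "SER", "A", 1, c(-5.5, 1.2, 0)),
    pdb_line(4, "O", "SER", "A", 1, c(-5.8, 2.4, 0)),
    pdb_line(5, "OG", "SER", "A", 1, c(-3.0, 0, 0)),
    pdb_line(6, "O1", "LIG", "L", 900, c(0, 0, 0), het = TRUE,
             element = "O"),
    "END"), collapse = "\n")
}

# ALA CB exactly 3.5 A from a ligand carbon; nothing else in range.
ala_cb_ligand_pdb <- function() {
  paste(c(
    pdb_line(1, "N", "ALA", "A", 1, c(-9, 0, 0)),
    pdb_line(2, "CA", "ALA", "A", 1, c(-7.5, 0, 0)),
    pdb_line(3, "C", "ALA", "A", 1, c(-6.5, 1.2, 0)),
    pdb_line(4, "O", "ALA", "A", 1, c(-6.8, 2.4, 0)),
    pdb_line(5, "CB", "ALA", "A", 1, c(-3.5, 0, 0)),
    pdb_line(6, "C1", "LIG", "L", 900, c(0, 0, 0), het = TRUE,
             element = "C"),
    "END"), collapse = "\n")
}

# A toy protein-DNA complex: 3-residue peptide, 2-nucleotide duplex with
# one backbone N placed 3.2 A from the peptide's first N.
dna_complex_pdb <- function() {
  paste(c(
    pdb_line(1, "N", "ALA", "A", 1, c(0, 0, 0)),
    pdb_line(2, "CA", "ALA", "A", 1, c(1.46, 0, 0)),
    pdb_line(3, "C", "ALA", "A", 1, c(2.0, 1.3, 0)),
    pdb_line(4, "O", "ALA", "A", 1, c(3.2, 1.4, 0)),
    pdb_line(5, "CA", "ALA", "A", 2, c(5.2, 0, 0)),
    pdb_line(6, "CA", "ALA", "A", 3, c(9.0, 0, 0)),
    pdb_line(7, "P", "DA", "D", 1, c(0, 3.2, 0)),
    pdb_line(8, "C1'", "DA", "D", 1, c(1.5, 4.2, 0), element = "C"),
    pdb_line(9, "P", "DT", "E", 1, c(0, 13.2, 0)),
    pdb_line(10, "C1'", "DT", "E", 1, c(1.5, 14.2, 0), element = "C"),
    "END"), collapse = "\n")
}

make_records <- function(...) {
  seqs <- c(...)
  lapply(seq_along(seqs), function(i) {
    seq_record(names(seqs)[i], seqs[i])
  })
}
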