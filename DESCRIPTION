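Package: msaligmap
Title: Mapping Ligand-, Peptide-, and DNA-Binding Residues from PDB
    Structures onto Homologous Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies protein residues in contact with a ligand, a
    peptide chain, or DNA in PDB coordinate files, classifying each
    interaction as hydrogen-bonded or non-bonded by distance criteria;
    aligns the structure-derived sequences with user-supplied homologous
    sequences (external aligner or a built-in progressive aligner); and
    transfers the binding-site and secondary-structure annotations
    through the alignment columns onto every sequence, reporting which
    binding positions are identical and which are substituted.  Includes
    a DSSP file parser and a simplified Kabsch-Sander secondary-structure
    assignment, a PDBsum-style residue-list reader, plain-text and HTML
    alignment renderers, a command-line front end, and generators of
    synthetic test complexes with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
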