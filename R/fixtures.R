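# Synthetic test complexes with known ground truth: ideal-geometry
# peptides (helix, extended strand, two-strand hairpin) built from
# standard bond lengths/angles, ligand atoms placed at exact offsets from
# named protein atoms, minimal DNA duplexes, homolog sets with controlled
# substitutions, and a classic-layout DSSP writer.  Everything is
# deterministic given its seed, and the PDB output uses legal fixed-column
# records so fixtures exercise the real parser.

#' @keywords internal
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Internal-to-Cartesian placement: position d bonded to c with the given
# bond length, angle b-c-d (degrees) and dihedral a-b-c-d (degrees).
#' @keywords internal
place_atom <- function(a, b, c, length., angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- c - b
  bc <- bc / vnorm(bc)
  ab <- b - a
  n <- cross3(ab, bc)
  n <- n / vnorm(n)
  m <- cross3(n, bc)
  d2 <- c(-length. * cos(ang),
          length. * sin(ang) * cos(dih),
          length. * sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' @keywords internal
build_backbone <- function(phi_psi, first = list(N = c(0, 0, 0),
                                                 CA = c(1.458, 0, 0))) {
  n <- nrow(phi_psi)
  N <- matrix(NA_real_, n, 3); CA <- N; C <- N; O <- N
  N[1, ] <- first$N
  CA[1, ] <- first$CA
  # first C placed in the xy-plane at the N-CA-C angle
  C[1, ] <- place_atom(c(0, 0, 1) + first$N, N[1, ], CA[1, ],
                       1.525, 111.2, phi_psi$phi[1] + 60)
  for (i in seq_len(n - 1)) {
    N[i + 1, ] <- place_atom(N[i, ], CA[i, ], C[i, ], 1.329, 116.2,
                             phi_psi$psi[i])
    CA[i + 1, ] <- place_atom(CA[i, ], C[i, ], N[i + 1, ], 1.458, 121.7, 180)
    C[i + 1, ] <- place_atom(C[i, ], N[i + 1, ], CA[i + 1, ], 1.525, 111.2,
                             phi_psi$phi[i + 1])
    u <- C[i, ] - CA[i, ]; v <- C[i, ] - N[i + 1, ]
    w <- u / vnorm(u) + v / vnorm(v)
    O[i, ] <- C[i, ] + 1.231 * w / vnorm(w)
  }
  virt_n <- place_atom(N[n, ], CA[n, ], C[n, ], 1.329, 116.2,
                       phi_psi$psi[n])
  u <- C[n, ] - CA[n, ]; v <- C[n, ] - virt_n
  w <- u / vnorm(u) + v / vnorm(v)
  O[n, ] <- C[n, ] + 1.231 * w / vnorm(w)
  list(N = N, CA = CA, C = C, O = O)
}

#' @keywords internal
pdb_atom_line <- function(serial, name, comp, chain, resno, icode, xyz,
                          occ = 1.00, element, het = FALSE) {
  rec <- if (het) "HETATM" else "ATOM  "
  name_f <- if (nchar(name) >= 4) substr(name, 1, 4)
            else sprintf(" %-3s", name)
  sprintf("%s%5d %s %3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial, name_f, comp, chain, resno,
          if (nzchar(icode)) icode else " ",
          xyz[1], xyz[2], xyz[3], occ, 0, element)
}

#' Build a synthetic protein--partner complex with known ground truth
#'
#' Generates an ideal-geometry poly-alanine backbone (N, CA, C, O, CB) in
#' one of three presets -- `ideal_helix` (phi -57, psi -47), `extended`
#' (phi -139, psi 135), or `hairpin` (two antiparallel extended strands
#' related by a two-fold rotation) -- then places ligand atoms at exact
#' offsets from named protein atoms so the expected binding site follows
#' in closed form from the distance criteria.  Expected records are
#' evaluated over the anchor residue and its two sequence neighbours (a
#' point near a backbone atom is unavoidably within range of the adjacent
#' peptide units); the generator refuses placements whose ground truth
#' would be ambiguous -- a ligand atom within the non-bonded cutoff of any
#' residue outside that window is an error, as is any atom pair closer
#' than 0.5 Angstrom.
#'
#' @param n_residues number of residues (>= 3; the hairpin preset splits
#'   them into two strands)
#' @param geometry `"ideal_helix"`, `"extended"`, or `"hairpin"`
#' @param ligand_atoms list of placements: each a list with `element`,
#'   `name` (atom name), `anchor_residue` (1-based position in the chain),
#'   `anchor_atom` (e.g. `"N"`), and `offset` (3-vector, Angstrom)
#' @param ligand_comp chemical component code of the ligand (default LIG)
#' @param dna when `TRUE`, append a minimal 4-nucleotide duplex (chains D
#'   and E) displaced by `dna_offset` from the protein
#' @param dna_offset 3-vector, Angstrom
#' @param start_number author number of the first residue
#' @param insertion_at optional 1-based position rendered as an inserted
#'   residue: it repeats the previous author number with insertion code A
#' @param chain_id protein chain identifier
#' @param criteria [contact_criteria()] used for the closed-form expected
#'   site and the ambiguity check
#' @return list with `pdb_text`, `expected_site` (an `msl_binding_site`),
#'   `expected_track` (an `msl_sstrack`: helix interiors H, otherwise
#'   coil), and `sequence`
#' @export
make_toy_complex <- function(n_residues = 10,
                             geometry = c("ideal_helix", "extended",
                                          "hairpin"),
                             ligand_atoms = list(),
                             ligand_comp = "LIG",
                             dna = FALSE,
                             dna_offset = c(0, 20, 0),
                             start_number = 1L,
                             insertion_at = NULL,
                             chain_id = "A",
                             criteria = contact_criteria()) {
  geometry <- match.arg(geometry)
  stopifnot(n_residues >= 3)

  if (geometry == "hairpin") {
    n1 <- ceiling(n_residues / 2)
    n2 <- n_residues - n1
    pp <- data.frame(phi = rep(-139, n1), psi = rep(135, n1))
    bb1 <- build_backbone(pp)
    pp2 <- data.frame(phi = rep(-139, n2), psi = rep(135, n2))
    bb2 <- build_backbone(pp2)
    # Antiparallel placement: rotate strand 2 by 180 degrees about the x
    # axis, reverse its direction along x, and offset across the sheet.
    flip <- function(m, shift) {
      m2 <- m
      m2[, 2] <- -m2[, 2]; m2[, 3] <- -m2[, 3]
      m2[, 1] <- -m2[, 1] + shift[1]
      m2[, 2] <- m2[, 2] + shift[2]
      m2[, 3] <- m2[, 3] + shift[3]
      m2
    }
    shift <- HAIRPIN_SHIFT
    bb <- list(N = rbind(bb1$N, flip(bb2$N, shift)),
               CA = rbind(bb1$CA, flip(bb2$CA, shift)),
               C = rbind(bb1$C, flip(bb2$C, shift)),
               O = rbind(bb1$O, flip(bb2$O, shift)))
  } else {
    angles <- switch(geometry,
                     ideal_helix = c(-57, -47),
                     extended = c(-139, 135))
    pp <- data.frame(phi = rep(angles[1], n_residues),
                     psi = rep(angles[2], n_residues))
    bb <- build_backbone(pp)
  }

  # CB from the backbone frame (poly-alanine).
  CB <- t(vapply(seq_len(n_residues), function(i) {
    place_atom(bb$C[i, ], bb$N[i, ], bb$CA[i, ], 1.530, 110.5, 122.5)
  }, numeric(3)))

  numbering <- make_numbering(n_residues, start_number, insertion_at)

  lines <- character(0)
  serial <- 0L
  for (i in seq_len(n_residues)) {
    for (at in list(list("N", bb$N[i, ], "N"), list("CA", bb$CA[i, ], "C"),
                    list("C", bb$C[i, ], "C"), list("O", bb$O[i, ], "O"),
                    list("CB", CB[i, ], "C"))) {
      serial <- serial + 1L
      lines <- c(lines, pdb_atom_line(serial, at[[1]], "ALA", chain_id,
                                      numbering$number[i],
                                      numbering$icode[i], at[[2]],
                                      element = at[[3]]))
    }
  }
  lines <- c(lines, sprintf("TER   %5d      %3s %s%4d ", serial + 1L, "ALA",
                            chain_id, numbering$number[n_residues]))

  # Ligand atoms at exact offsets from their anchors.
  lig_xyz <- list()
  for (la in ligand_atoms) {
    anchor <- switch(toupper(la$anchor_atom),
                     N = bb$N[la$anchor_residue, ],
                     CA = bb$CA[la$anchor_residue, ],
                     C = bb$C[la$anchor_residue, ],
                     O = bb$O[la$anchor_residue, ],
                     CB = CB[la$anchor_residue, ],
                     msl_stop("msl_spec_error", "unknown anchor atom '%s'",
                              la$anchor_atom))
    lig_xyz[[length(lig_xyz) + 1L]] <- anchor + la$offset
  }
  if (length(lig_xyz) > 0) {
    for (k in seq_along(lig_xyz)) {
      serial <- serial + 1L
      la <- ligand_atoms[[k]]
      lines <- c(lines, pdb_atom_line(serial, la$name %||% la$element,
                                      ligand_comp, "L", 901L, "",
                                      lig_xyz[[k]], element = la$element,
                                      het = TRUE))
    }
  }

  if (dna) {
    lines <- c(lines, make_toy_duplex(serial, bb$CA[1, ] + dna_offset))
  }
  lines <- c(lines, "END")
  pdb_text <- paste(lines, collapse = "\n")

  expected_site <- toy_expected_site(bb, CB, numbering, ligand_atoms,
                                     lig_xyz, ligand_comp, chain_id,
                                     criteria)
  expected_track <- toy_expected_track(geometry, n_residues, chain_id)

  list(pdb_text = pdb_text, expected_site = expected_site,
       expected_track = expected_track,
       sequence = strrep("A", n_residues))
}

# Inter-strand displacement of the hairpin preset, chosen during
# development so the two extended strands H-bond in antiparallel register.
HAIRPIN_SHIFT <- c(13.25, 8.25, 3.5)

#' @keywords internal
make_numbering <- function(n, start, insertion_at) {
  number <- seq(start, length.out = n)
  icode <- rep("", n)
  if (!is.null(insertion_at)) {
    stopifnot(insertion_at >= 2, insertion_at <= n)
    number[insertion_at] <- number[insertion_at - 1L]
    icode[insertion_at] <- "A"
    if (insertion_at < n) {
      number[(insertion_at + 1L):n] <-
        seq(number[insertion_at] + 1L, length.out = n - insertion_at)
    }
  }
  list(number = as.integer(number), icode = icode)
}

#' @keywords internal
toy_expected_site <- function(bb, CB, numbering, ligand_atoms, lig_xyz,
                              ligand_comp, chain_id, criteria) {
  site <- empty_binding_site(list(pdb_code = "xxxx"), chain_id,
                             ligand_partner(ligand_comp))
  site <- structure(site, class = "msl_binding_site")
  if (length(lig_xyz) == 0) return(site)
  n <- nrow(bb$N)
  atom_names <- c("N", "CA", "C", "O", "CB")
  recs <- list()
  for (k in seq_along(lig_xyz)) {
    la <- ligand_atoms[[k]]
    q <- lig_xyz[[k]]
    qtype <- partner_atom_da_type(ligand_comp, la$name %||% la$element,
                                  la$element)
    for (i in seq_len(n)) {
      coords <- rbind(bb$N[i, ], bb$CA[i, ], bb$C[i, ], bb$O[i, ], CB[i, ])
      dd <- sqrt(rowSums((coords - matrix(q, 5, 3, byrow = TRUE))^2))
      near_anchor <- abs(i - la$anchor_residue) <= 1
      if (!near_anchor && any(dd <= criteria$nonbonded_max)) {
        msl_stop("msl_spec_error",
                 "ligand atom %d is within contact range of residue %d, outside the anchor window; ground truth would be ambiguous",
                 k, i)
      }
      if (any(dd < 0.5)) {
        msl_stop("msl_spec_error", "degenerate geometry: atoms < 0.5 A apart")
      }
      if (!near_anchor) next
      for (j in seq_along(atom_names)) {
        ptype <- protein_atom_da_type("ALA", atom_names[j])
        compat <- (ptype %in% c("donor", "both") &&
                     qtype %in% c("acceptor", "both")) ||
                  (ptype %in% c("acceptor", "both") &&
                     qtype %in% c("donor", "both"))
        cls <- if (compat && dd[j] >= criteria$hbond_min &&
                   dd[j] <= criteria$hbond_max) "hydrogen_bond"
               else if (dd[j] <= criteria$nonbonded_max) "non_bonded"
               else NA_character_
        if (is.na(cls)) next
        recs[[length(recs) + 1L]] <- data.frame(
          comp_id = "ALA", author_number = numbering$number[i],
          insertion_code = numbering$icode[i], chain_id = chain_id,
          partner_id = ligand_comp, interaction_class = cls,
          min_distance = dd[j], protein_atom = atom_names[j],
          partner_atom = la$name %||% la$element,
          flagged = cls == "non_bonded" && dd[j] < criteria$nonbonded_min,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(recs) == 0) return(site)
  records <- do.call(rbind, recs)
  # keep the minimum-distance pair per (residue, class)
  key <- paste(records$author_number, records$insertion_code,
               records$interaction_class, sep = "\r")
  records <- records[order(key, records$min_distance), , drop = FALSE]
  records <- records[!duplicated(paste(records$author_number,
                                       records$insertion_code,
                                       records$interaction_class,
                                       sep = "\r")), , drop = FALSE]
  records <- records[order(records$author_number, records$insertion_code,
                           records$interaction_class), , drop = FALSE]
  rownames(records) <- NULL
  site$records <- records
  site
}

#' @keywords internal
toy_expected_track <- function(geometry, n, chain_id) {
  codes <- rep(" ", n)
  if (geometry == "ideal_helix" && n >= 6) {
    codes[2:(n - 1)] <- "H"
  }
  new_sstrack(paste0("xxxx:", chain_id), codes)
}

#' @keywords internal
make_toy_duplex <- function(serial, origin) {
  comps1 <- c("DA", "DT", "DG", "DC")
  comps2 <- c("DG", "DC", "DA", "DT")
  lines <- character(0)
  for (strand in 1:2) {
    ch <- c("D", "E")[strand]
    comps <- list(comps1, comps2)[[strand]]
    for (i in 1:4) {
      base <- origin + c((i - 1) * 6, (strand - 1) * 10, 0)
      for (at in list(list("P", base, "P"),
                      list("C1'", base + c(1.5, 1.0, 0), "C"),
                      list("N1", base + c(2.5, 2.0, 0), "N"))) {
        serial <- serial + 1L
        lines <- c(lines, pdb_atom_line(serial, at[[1]], comps[i], ch,
                                        i, "", at[[2]], element = at[[3]]))
      }
    }
    lines <- c(lines, sprintf("TER   %5d      %3s %s%4d ", serial + 1L,
                              comps[4], ch, 4L))
    serial <- serial + 1L
  }
  lines
}

#' Random toy complex for oracle-equivalence testing
#'
#' A short extended poly-alanine chain plus `n_ligand_atoms` ligand atoms
#' scattered uniformly in a box around the chain (N/O/C elements drawn at
#' random), at most 50 atoms in total.  No ground truth attached; pairs of
#' independent contact-detection implementations are compared on it.
#'
#' @param n_residues residues in the protein chain (3--8)
#' @param n_ligand_atoms ligand atoms (1--10)
#' @param seed integer seed
#' @return list with `pdb_text`
#' @export
make_random_complex <- function(n_residues = 5, n_ligand_atoms = 6,
                                seed = 1) {
  stopifnot(n_residues >= 3, n_residues <= 8, n_ligand_atoms >= 1,
            n_ligand_atoms <= 10)
  pp <- data.frame(phi = rep(-139, n_residues),
                   psi = rep(135, n_residues))
  bb <- build_backbone(pp)
  rng <- local_rng(seed)
  center <- colMeans(bb$CA)
  span <- max(sqrt(rowSums((bb$CA - matrix(center, n_residues, 3,
                                           byrow = TRUE))^2))) + 5
  elements <- rng$sample(c("N", "O", "C"), n_ligand_atoms, replace = TRUE)
  xyz <- matrix(rng$runif(3 * n_ligand_atoms, -span, span),
                ncol = 3, byrow = TRUE) +
    matrix(center, n_ligand_atoms, 3, byrow = TRUE)
  lines <- character(0)
  serial <- 0L
  for (i in seq_len(n_residues)) {
    for (at in list(list("N", bb$N[i, ], "N"), list("CA", bb$CA[i, ], "C"),
                    list("C", bb$C[i, ], "C"), list("O", bb$O[i, ], "O"))) {
      serial <- serial + 1L
      lines <- c(lines, pdb_atom_line(serial, at[[1]], "ALA", "A", i, "",
                                      at[[2]], element = at[[3]]))
    }
  }
  for (k in seq_len(n_ligand_atoms)) {
    serial <- serial + 1L
    nm <- paste0(elements[k], k)
    lines <- c(lines, pdb_atom_line(serial, nm, "LIG", "L", 900L, "",
                                    xyz[k, ], element = elements[k],
                                    het = TRUE))
  }
  lines <- c(lines, "END")
  list(pdb_text = paste(lines, collapse = "\n"))
}

# Seeded draws that do not disturb the session RNG state.
#' @keywords internal
local_rng <- function(seed) {
  env <- new.env()
  run <- function(f, ...) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    if (!is.null(env$state)) {
      assign(".Random.seed", env$state, envir = globalenv())
    } else {
      set.seed(seed)
    }
    out <- f(...)
    env$state <- get(".Random.seed", globalenv())
    out
  }
  list(
    runif = function(...) run(stats::runif, ...),
    sample = function(...) run(sample, ...),
    rbinom = function(...) run(stats::rbinom, ...)
  )
}

#' Generate a homolog set with controlled edits
#'
#' Derives `n` target sequences from a base sequence by seeded point
#' substitutions (and optionally short 1--2 residue indels), recording
#' every edit so downstream conservation statuses are predictable.
#' `forced_substitutions` pins specific 1-based positions to be
#' substituted in every derived sequence (each letter replaced by the next
#' standard amino acid cyclically, never by itself).
#'
#' @param base_sequence one-letter string the homologs derive from
#' @param n number of derived sequences
#' @param mutation_rate per-position substitution probability
#' @param indel_rate per-sequence probability of one short indel
#' @param seed integer seed
#' @param forced_substitutions integer vector of 1-based positions
#' @param id_prefix identifier prefix for the derived records
#' @return list with `records` (list of [seq_record()]) and `edits`
#'   (data frame: `id`, `position`, `from`, `to`)
#' @export
make_homolog_set <- function(base_sequence, n, mutation_rate = 0.05,
                             indel_rate = 0, seed = 1,
                             forced_substitutions = integer(0),
                             id_prefix = "target") {
  aa <- setdiff(names(CLUSTALX_CLASS), "X")
  rng <- local_rng(seed)
  base <- strsplit(toupper(base_sequence), "")[[1]]
  records <- vector("list", n)
  edits <- list()
  for (k in seq_len(n)) {
    s <- base
    hit <- which(rng$runif(length(s)) < mutation_rate)
    hit <- sort(unique(c(hit, forced_substitutions)))
    for (p in hit) {
      from <- s[p]
      to <- aa[(match(from, aa) %% length(aa)) + 1L]
      s[p] <- to
      edits[[length(edits) + 1L]] <- data.frame(
        id = sprintf("%s%02d", id_prefix, k), position = p,
        from = from, to = to, stringsAsFactors = FALSE)
    }
    if (indel_rate > 0 && rng$runif(1) < indel_rate) {
      len <- rng$sample(1:2, 1)
      if (rng$runif(1) < 0.5 && length(s) > len + 2) {
        at <- rng$sample(seq_len(length(s) - len), 1)
        s <- s[-(at:(at + len - 1L))]
      } else {
        at <- rng$sample(seq_len(length(s)), 1)
        ins <- rng$sample(aa, len, replace = TRUE)
        s <- append(s, ins, after = at)
      }
    }
    records[[k]] <- seq_record(sprintf("%s%02d", id_prefix, k),
                               paste(s, collapse = ""))
  }
  list(records = records,
       edits = if (length(edits)) do.call(rbind, edits) else
         data.frame(id = character(), position = integer(),
                    from = character(), to = character(),
                    stringsAsFactors = FALSE))
}

#' Render a track as classic-layout DSSP text (synthetic)
#'
#' Writes the minimal fixed-column residue block that [parse_dssp()]
#' reads back: a synthetic stand-in for DSSP program output, used for
#' offline testing of the DSSP-file path.
#'
#' @param codes character vector of per-residue codes
#' @param chain_id chain identifier placed at column 12
#' @param aa_letters one-letter residues (defaults to all-A)
#' @param numbers author numbers (defaults to 1..n)
#' @param breaks_after 1-based positions after which a `!` chain-break
#'   line is inserted
#' @return DSSP-format text (single string)
#' @export
as_dssp_text <- function(codes, chain_id = "A",
                         aa_letters = rep("A", length(codes)),
                         numbers = seq_along(codes),
                         breaks_after = integer(0)) {
  hdr <- c("==== Secondary Structure Definition, synthetic fixture ====",
           "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O    O-->H-N    N-H-->O    O-->H-N    TCO  KAPPA ALPHA  PHI   PSI    X-CA   Y-CA   Z-CA")
  body <- character(0)
  k <- 0L
  for (i in seq_along(codes)) {
    k <- k + 1L
    body <- c(body, sprintf("%5d%5d %s %s  %s %s", k, numbers[i], chain_id,
                            aa_letters[i], codes[i],
                            strrep(" ", 100)))
    if (i %in% breaks_after) {
      k <- k + 1L
      body <- c(body, sprintf("%5d        !%s", k, strrep(" ", 100)))
    }
  }
  paste(c(hdr, body), collapse = "\n")
}

#' Write a complete fixture bundle to a directory
#'
#' Emits a toy complex PDB, a FASTA of the structure sequence plus derived
#' homologs, and an `expected.json` with the constructed ground truth --
#' the input set the pipeline's end-to-end closure tests run on.
#'
#' @param dir output directory (created if needed)
#' @param n_targets number of derived homolog sequences
#' @param forced_substitutions positions substituted in every target
#' @param seed integer seed
#' @return invisibly, the list of written paths
#' @export
write_fixture_bundle <- function(dir, n_targets = 3,
                                 forced_substitutions = integer(0),
                                 seed = 1) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  toy <- make_toy_complex(
    n_residues = 10, geometry = "extended",
    ligand_atoms = list(list(element = "O", name = "O1",
                             anchor_residue = 5, anchor_atom = "N",
                             offset = c(0, 0, 3.0))))
  pdb_path <- file.path(dir, "1tst.pdb")
  writeLines(toy$pdb_text, pdb_path)
  hom <- make_homolog_set(toy$sequence, n_targets,
                          mutation_rate = 0, indel_rate = 0, seed = seed,
                          forced_substitutions = forced_substitutions)
  fasta_path <- file.path(dir, "targets.fasta")
  write_fasta(hom$records, fasta_path)
  exp_path <- file.path(dir, "expected.json")
  jsonlite::write_json(
    list(binding_residues = toy$expected_site$records$author_number,
         classes = toy$expected_site$records$interaction_class,
         forced_substitutions = forced_substitutions,
         n_targets = n_targets),
    exp_path, auto_unbox = FALSE)
  invisible(list(pdb = pdb_path, fasta = fasta_path, expected = exp_path))
}
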