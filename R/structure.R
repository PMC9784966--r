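# PDB coordinate-file parsing and chain-sequence extraction.
#
# The parser reads the fixed-column PDB text format (ATOM/HETATM/MODEL/
# ENDMDL/MODRES/TER/HEADER records), keeps the first model of multi-model
# (NMR) entries, resolves alternate locations by highest occupancy, and
# preserves author residue numbering (numbers + insertion codes) so that
# binding-site residues can be located both in the 3D structure and in the
# extracted sequence.

#' Parse PDB-format text into a structure object
#'
#' Reads ATOM and HETATM records of the first model, groups them into
#' residues and chains in file order, resolves alternate locations by
#' keeping the highest-occupancy atom (ties broken by file order), collects
#' MODRES records into a modified-residue map, and classifies every chain
#' as protein, dna, rna, ligand, water, or other.
#'
#' @param pdb_text character: PDB file content, either a single string or a
#'   vector of lines.
#' @param pdb_code optional 4-character PDB identifier; normalized to
#'   lowercase.  Taken from the HEADER record when absent.
#' @return an object of class `msl_structure`: a list with elements
#'   `pdb_code`, `model_number`, `modres_map` (named character,
#'   component code -> canonical three-letter code), and `chains` (named
#'   list; each chain has `chain_id`, `entity_kind`, and `residues`, a list
#'   of residues each holding `comp_id`, `author_number`, `insertion_code`,
#'   `het_flag`, and an `atoms` data frame with columns `name`, `element`,
#'   `x`, `y`, `z`, `occupancy`, `alt_loc`).
#' @export
parse_structure <- function(pdb_text, pdb_code = NULL) {
  lines <- if (length(pdb_text) == 1L && grepl("\n", pdb_text, fixed = TRUE)) {
    strsplit(pdb_text, "\n", fixed = TRUE)[[1]]
  } else {
    pdb_text
  }
  rec <- substr(lines, 1, 6)

  if (is.null(pdb_code)) {
    hdr <- lines[rec == "HEADER"]
    if (length(hdr) > 0 && nchar(hdr[1]) >= 66) {
      cand <- trimws(substr(hdr[1], 63, 66))
      if (grepl("^[0-9][A-Za-z0-9]{3}$", cand)) pdb_code <- cand
    }
  }
  pdb_code <- tolower(pdb_code %||% "xxxx")

  # MODRES: cols 13-15 component, 25-27 standard residue.
  modres_map <- character()
  for (ln in lines[rec == "MODRES"]) {
    comp <- trimws(substr(ln, 13, 15))
    std <- trimws(substr(ln, 25, 27))
    if (nzchar(comp) && nzchar(std)) modres_map[comp] <- std
  }

  # Restrict coordinates to the first MODEL block when present.
  model_number <- 1L
  model_idx <- which(rec == "MODEL ")
  keep <- rep(TRUE, length(lines))
  if (length(model_idx) > 0) {
    model_number <- suppressWarnings(as.integer(trimws(substr(lines[model_idx[1]], 7, 80))))
    if (is.na(model_number)) model_number <- 1L
    endmdl_idx <- which(rec == "ENDMDL")
    end1 <- endmdl_idx[endmdl_idx > model_idx[1]][1]
    if (is.na(end1)) end1 <- length(lines)
    keep <- seq_along(lines) >= model_idx[1] & seq_along(lines) <= end1
  }

  is_coord <- (rec == "ATOM  " | rec == "HETATM") & keep
  if (!any(rec %in% c("ATOM  ", "HETATM"))) {
    msl_stop("msl_parse_error", "no ATOM or HETATM records found")
  }
  idx <- which(is_coord)
  cl <- lines[idx]

  x <- suppressWarnings(as.numeric(substr(cl, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(cl, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(cl, 47, 54)))
  bad <- which(!is.finite(x) | !is.finite(y) | !is.finite(z))
  if (length(bad) > 0) {
    msl_stop("msl_parse_error", "malformed coordinate columns at line %d",
             idx[bad[1]])
  }
  occ <- suppressWarnings(as.numeric(substr(cl, 55, 60)))
  occ[!is.finite(occ)] <- 1
  name <- trimws(substr(cl, 13, 16))
  alt <- trimws(substr(cl, 17, 17))
  comp <- trimws(substr(cl, 18, 20))
  chain <- substr(cl, 22, 22)
  resno <- suppressWarnings(as.integer(substr(cl, 23, 26)))
  if (anyNA(resno)) {
    msl_stop("msl_parse_error", "malformed residue number at line %d",
             idx[which(is.na(resno))[1]])
  }
  icode <- trimws(substr(cl, 27, 27))
  element <- trimws(substr(cl, 77, 78))
  # Infer element from the atom name when columns 77-78 are blank: first
  # alphabetic character, except a leading digit pattern like "1HB".
  blank <- !nzchar(element)
  if (any(blank)) {
    guess <- sub("^[0-9']*", "", name[blank])
    two <- toupper(substr(guess, 1, 2))
    one <- toupper(substr(guess, 1, 1))
    element[blank] <- ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "MN",
                                        "NA", "CA", "CU", "SE") &
                               !(comp[blank] %in% names(AA_THREE_TO_ONE) |
                                   comp[blank] %in% names(MODIFIED_AA_MAP)),
                             two, one)
    # In standard residues, names like "CA" are carbons; single-letter rule.
    std <- comp[blank] %in% c(names(AA_THREE_TO_ONE), names(MODIFIED_AA_MAP),
                              DNA_COMPONENTS, RNA_COMPONENTS, WATER_COMPONENTS)
    element[blank][std] <- one[std]
  }
  het <- rec[idx] == "HETATM"

  atoms <- data.frame(
    name = name, element = element, x = x, y = y, z = z,
    occupancy = occ, alt_loc = alt, comp_id = comp, chain_id = chain,
    author_number = resno, insertion_code = icode, het_flag = het,
    file_order = seq_along(cl), stringsAsFactors = FALSE
  )

  # Alternate-location resolution: within (chain, residue, atom name) keep
  # the highest occupancy; ties broken by file order.
  key <- paste(atoms$chain_id, atoms$author_number, atoms$insertion_code,
               atoms$name, sep = "\r")
  ord <- order(key, -atoms$occupancy, atoms$file_order)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  atoms <- atoms[order(atoms$file_order), , drop = FALSE]

  # Group into residues, then chains, in file order.
  res_key <- paste(atoms$chain_id, atoms$author_number,
                   atoms$insertion_code, atoms$comp_id, sep = "\r")
  res_first <- !duplicated(res_key)
  res_of_atom <- match(res_key, res_key[res_first])
  n_res <- sum(res_first)

  chains <- list()
  chain_ids_seen <- character()
  first_rows <- which(res_first)
  for (r in seq_len(n_res)) {
    rows <- atoms[res_of_atom == r, , drop = FALSE]
    cid <- rows$chain_id[1]
    residue <- list(
      comp_id = rows$comp_id[1],
      author_number = rows$author_number[1],
      insertion_code = rows$insertion_code[1],
      het_flag = all(rows$het_flag),
      atoms = rows[, c("name", "element", "x", "y", "z", "occupancy",
                       "alt_loc"), drop = FALSE]
    )
    if (!cid %in% chain_ids_seen) {
      chain_ids_seen <- c(chain_ids_seen, cid)
      chains[[cid]] <- list(chain_id = cid, entity_kind = "other",
                            residues = list())
    }
    chains[[cid]]$residues[[length(chains[[cid]]$residues) + 1L]] <- residue
  }

  for (cid in names(chains)) {
    chains[[cid]]$entity_kind <- classify_chain(chains[[cid]], modres_map)
  }

  structure(
    list(pdb_code = pdb_code, model_number = model_number,
         modres_map = modres_map, chains = chains),
    class = "msl_structure"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
classify_chain <- function(chain, modres_map) {
  comps <- toupper(vapply(chain$residues, `[[`, "", "comp_id"))
  het <- vapply(chain$residues, `[[`, FALSE, "het_flag")
  if (all(comps %in% WATER_COMPONENTS)) return("water")
  if (any(is_amino_acid(comps, modres_map) & !het) ||
      sum(is_amino_acid(comps, modres_map)) > 1) {
    return("protein")
  }
  non_water <- comps[!comps %in% WATER_COMPONENTS]
  if (length(non_water) > 0 && all(non_water %in% DNA_COMPONENTS)) return("dna")
  if (length(non_water) > 0 && all(non_water %in% LEGACY_DNA_COMPONENTS)) {
    return(if ("U" %in% non_water) "rna" else "dna")
  }
  if (length(non_water) == 1 && any(het)) return("ligand")
  if (length(non_water) >= 1 && all(het)) return("ligand")
  "other"
}

#' Extract the amino-acid sequence of a protein chain
#'
#' Builds the one-letter sequence from the observed ATOM-record residues
#' (not SEQRES): author-numbering gaps are left unfilled, MODRES-mapped and
#' built-in modified residues translate to their canonical letter, and
#' unmappable components become `X`.
#'
#' @param struct an `msl_structure`
#' @param chain_id single-character chain identifier
#' @return list with `sequence` (one-letter string) and `map`, a
#'   `msl_resmap` data frame with columns `seq_index` (0-based),
#'   `author_number`, `insertion_code`, `one_letter`.
#' @export
extract_chain_sequence <- function(struct, chain_id) {
  stopifnot(inherits(struct, "msl_structure"))
  chain <- struct$chains[[chain_id]]
  if (is.null(chain)) {
    msl_stop("msl_lookup_error", "chain '%s' not found in %s",
             chain_id, struct$pdb_code)
  }
  if (chain$entity_kind != "protein") {
    msl_stop("msl_type_error", "chain '%s' is %s, not protein",
             chain_id, chain$entity_kind)
  }
  res <- Filter(function(r) {
    is_amino_acid(r$comp_id, struct$modres_map) || !r$het_flag
  }, chain$residues)
  # Drop non-amino HETATM groups (ligands riding on the protein chain) and
  # waters that share the chain id.
  res <- Filter(function(r) !toupper(r$comp_id) %in% WATER_COMPONENTS, res)

  letters1 <- aa_one_letter(vapply(res, `[[`, "", "comp_id"),
                            struct$modres_map)
  map <- data.frame(
    seq_index = seq_along(res) - 1L,
    author_number = vapply(res, `[[`, 0L, "author_number"),
    insertion_code = vapply(res, `[[`, "", "insertion_code"),
    one_letter = letters1,
    stringsAsFactors = FALSE
  )
  class(map) <- c("msl_resmap", "data.frame")
  list(sequence = paste(letters1, collapse = ""), map = map)
}

#' Look up the 0-based sequence index of an author-numbered residue
#'
#' @param map a `msl_resmap`
#' @param author_number integer author residue number
#' @param insertion_code insertion code, `""` when none
#' @return 0-based sequence index, or `NA_integer_` when the residue is not
#'   observed in the coordinates
#' @export
resmap_index <- function(map, author_number, insertion_code = "") {
  hit <- which(map$author_number == author_number &
                 map$insertion_code == insertion_code)
  if (length(hit) == 0) NA_integer_ else map$seq_index[hit[1]]
}

#' @export
print.msl_structure <- function(x, ...) {
  cat(sprintf("<msl_structure %s> model %d, %d chain(s)\n",
              toupper(x$pdb_code), x$model_number, length(x$chains)))
  for (ch in x$chains) {
    cat(sprintf("  chain %s: %-7s %d residue(s)\n",
                ch$chain_id, ch$entity_kind, length(ch$residues)))
  }
  invisible(x)
}

#' Flatten the atoms of selected residues into one data frame
#'
#' @keywords internal
chain_atom_table <- function(chain, residue_filter = NULL) {
  res <- chain$residues
  if (!is.null(residue_filter)) res <- Filter(residue_filter, res)
  if (length(res) == 0) {
    return(data.frame(name = character(), element = character(),
                      x = numeric(), y = numeric(), z = numeric(),
                      comp_id = character(), author_number = integer(),
                      insertion_code = character(), chain_id = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(res, function(r) {
    a <- r$atoms
    a$comp_id <- r$comp_id
    a$author_number <- r$author_number
    a$insertion_code <- r$insertion_code
    a$chain_id <- chain$chain_id
    a[, c("name", "element", "x", "y", "z", "comp_id", "author_number",
          "insertion_code", "chain_id")]
  }))
}
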