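# Protein-partner contact detection.
#
# Interactions are classified by heavy-atom distance alone, following the
# two LigPlot-style classes: a hydrogen bond requires a donor/acceptor-
# compatible atom pair within [hbond_min, hbond_max]; any other heavy-atom
# pair within nonbonded_max is a non-bonded contact.  Angles and explicit
# hydrogens are deliberately not used (see the methods vignette).

#' Distance criteria for contact classification
#'
#' Defaults follow the LigPlot convention: hydrogen bonds at
#' 2.70--3.35 Angstrom between donor/acceptor atoms, non-bonded contacts at
#' 2.90--3.90 Angstrom.  `nonbonded_min` is a reporting floor only:
#' closer (clashing) pairs are still reported, flagged.
#'
#' @param hbond_min,hbond_max hydrogen-bond distance window, Angstrom
#' @param nonbonded_min,nonbonded_max non-bonded contact window, Angstrom
#' @return object of class `msl_criteria`
#' @export
contact_criteria <- function(hbond_min = 2.70, hbond_max = 3.35,
                             nonbonded_min = 2.90, nonbonded_max = 3.90) {
  stopifnot(hbond_min > 0, hbond_min < hbond_max,
            nonbonded_min > 0, nonbonded_min < nonbonded_max)
  structure(list(hbond_min = hbond_min, hbond_max = hbond_max,
                 nonbonded_min = nonbonded_min,
                 nonbonded_max = nonbonded_max),
            class = "msl_criteria")
}

#' Partner selectors for contact detection
#'
#' `ligand_partner(code)` selects every residue with the given chemical
#' component code in any chain; `chain_partner(id)` selects one chain
#' (peptide mode); `dna_partner()` selects the union of all DNA chains
#' (a duplex contributes both strands).
#'
#' @param code PDB chemical component code, e.g. `"NDP"`
#' @param chain_id single-character chain identifier
#' @return a partner selector understood by [detect_contacts()]
#' @export
ligand_partner <- function(code) {
  structure(list(type = "ligand", code = toupper(code)),
            class = "msl_partner")
}

#' @rdname ligand_partner
#' @export
chain_partner <- function(chain_id) {
  structure(list(type = "chain", chain_id = chain_id),
            class = "msl_partner")
}

#' @rdname ligand_partner
#' @export
dna_partner <- function() {
  structure(list(type = "dna"), class = "msl_partner")
}

#' @keywords internal
partner_label <- function(partner) {
  switch(partner$type,
         ligand = partner$code,
         chain = paste0("chain ", partner$chain_id),
         dna = "DNA")
}

#' @keywords internal
heavy <- function(at) at[!toupper(at$element) %in% c("H", "D"), , drop = FALSE]

#' @keywords internal
gather_partner_atoms <- function(struct, partner, protein_chain) {
  at <- switch(
    partner$type,
    ligand = {
      tabs <- lapply(struct$chains, function(ch) {
        chain_atom_table(ch, function(r) {
          toupper(r$comp_id) == partner$code
        })
      })
      do.call(rbind, tabs)
    },
    chain = {
      ch <- struct$chains[[partner$chain_id]]
      if (is.null(ch)) {
        msl_stop("msl_lookup_error", "partner chain '%s' not found",
                 partner$chain_id)
      }
      chain_atom_table(ch, function(r) {
        !toupper(r$comp_id) %in% WATER_COMPONENTS
      })
    },
    dna = {
      dna_chains <- Filter(function(ch) ch$entity_kind == "dna",
                           struct$chains)
      if (length(dna_chains) == 0) {
        msl_stop("msl_lookup_error", "no DNA chains in structure %s",
                 struct$pdb_code)
      }
      do.call(rbind, lapply(dna_chains, chain_atom_table))
    }
  )
  if (is.null(at) || nrow(at) == 0) {
    msl_stop("msl_lookup_error", "partner '%s' matched no residues",
             partner_label(partner))
  }
  heavy(at)
}

#' Detect binding-site residues of a protein chain against a partner
#'
#' Scans every heavy-atom pair between the protein chain and the partner
#' entity.  A pair is a hydrogen bond when one atom can donate and the
#' other accept (built-in typing table for standard residues; element-based
#' N/O typing for ligand atoms) and the distance lies within the
#' hydrogen-bond window; otherwise it is a non-bonded contact when within
#' `nonbonded_max`.  Per (residue, class) only the minimum-distance atom
#' pair is kept; a residue may appear once in each class.  Waters and
#' hydrogens never participate.
#'
#' @param struct an `msl_structure`
#' @param protein_chain chain identifier of the protein chain
#' @param partner a selector from [ligand_partner()], [chain_partner()], or
#'   [dna_partner()]
#' @param criteria a [contact_criteria()] object
#' @return object of class `msl_binding_site`: `structure_id`
#'   (`code:chain`), `partner_label`, and `records`, a data frame with one
#'   row per (residue, class) sorted by author numbering, holding the
#'   minimum distance and the atom pair that realizes it plus a `flagged`
#'   column marking sub-`nonbonded_min` clashes.
#' @export
detect_contacts <- function(struct, protein_chain, partner,
                            criteria = contact_criteria()) {
  stopifnot(inherits(struct, "msl_structure"))
  ch <- struct$chains[[protein_chain]]
  if (is.null(ch)) {
    msl_stop("msl_lookup_error", "chain '%s' not found", protein_chain)
  }
  if (ch$entity_kind != "protein") {
    msl_stop("msl_type_error", "chain '%s' is %s, not protein",
             protein_chain, ch$entity_kind)
  }
  prot <- heavy(chain_atom_table(ch, function(r) {
    (is_amino_acid(r$comp_id, struct$modres_map) || !r$het_flag) &&
      !toupper(r$comp_id) %in% WATER_COMPONENTS
  }))
  part <- gather_partner_atoms(struct, partner, protein_chain)
  # In ligand mode the ligand may ride on the protein chain itself; in
  # chain/dna mode exclude any partner atoms from the protein chain.
  if (partner$type != "ligand") {
    part <- part[part$chain_id != protein_chain, , drop = FALSE]
  } else {
    # never pair a residue with itself
    prot <- prot[toupper(prot$comp_id) != partner$code, , drop = FALSE]
  }

  empty <- empty_binding_site(struct, protein_chain, partner)
  if (nrow(prot) == 0 || nrow(part) == 0) return(empty)

  pm <- as.matrix(prot[, c("x", "y", "z")])
  qm <- as.matrix(part[, c("x", "y", "z")])
  d2 <- outer(rowSums(pm^2), rowSums(qm^2), "+") - 2 * pm %*% t(qm)
  d <- sqrt(pmax(d2, 0))

  ptype <- mapply(protein_atom_da_type, prot$comp_id, prot$name,
                  USE.NAMES = FALSE)
  qtype <- mapply(partner_atom_da_type, part$comp_id, part$name,
                  part$element, USE.NAMES = FALSE)
  can_donate_p <- ptype %in% c("donor", "both")
  can_accept_p <- ptype %in% c("acceptor", "both")
  can_donate_q <- qtype %in% c("donor", "both")
  can_accept_q <- qtype %in% c("acceptor", "both")
  compat <- outer(can_donate_p, can_accept_q, "&") |
    outer(can_accept_p, can_donate_q, "&")

  is_hb <- compat & d >= criteria$hbond_min & d <= criteria$hbond_max
  is_nb <- !is_hb & d <= criteria$nonbonded_max & d > 0

  res_key <- paste(prot$author_number, prot$insertion_code, sep = "\r")
  recs <- list()
  for (cls in c("hydrogen_bond", "non_bonded")) {
    hits <- if (cls == "hydrogen_bond") is_hb else is_nb
    pair_idx <- which(hits, arr.ind = TRUE)
    if (nrow(pair_idx) == 0) next
    for (rk in unique(res_key[pair_idx[, 1]])) {
      sel <- pair_idx[res_key[pair_idx[, 1]] == rk, , drop = FALSE]
      dist_sel <- d[sel]
      best <- sel[which.min(dist_sel), ]
      i <- best[1]; j <- best[2]
      recs[[length(recs) + 1L]] <- data.frame(
        comp_id = prot$comp_id[i],
        author_number = prot$author_number[i],
        insertion_code = prot$insertion_code[i],
        chain_id = protein_chain,
        partner_id = if (partner$type == "ligand") partner$code else
          sprintf("%s:%s%d%s", part$chain_id[j], part$comp_id[j],
                  part$author_number[j], part$insertion_code[j]),
        interaction_class = cls,
        min_distance = min(dist_sel),
        protein_atom = prot$name[i],
        partner_atom = part$name[j],
        flagged = min(dist_sel) < criteria$nonbonded_min &&
          cls == "non_bonded",
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(recs) == 0) return(empty)
  records <- do.call(rbind, recs)
  records <- records[order(records$author_number, records$insertion_code,
                           records$interaction_class), , drop = FALSE]
  rownames(records) <- NULL
  structure(list(structure_id = paste0(struct$pdb_code, ":", protein_chain),
                 partner_label = partner_label(partner),
                 records = records),
            class = "msl_binding_site")
}

#' @keywords internal
empty_binding_site <- function(struct, protein_chain, partner) {
  structure(list(
    structure_id = paste0(
      if (inherits(struct, "msl_structure")) struct$pdb_code else struct,
      ":", protein_chain),
    partner_label = if (inherits(partner, "msl_partner"))
      partner_label(partner) else as.character(partner),
    records = data.frame(
      comp_id = character(), author_number = integer(),
      insertion_code = character(), chain_id = character(),
      partner_id = character(), interaction_class = character(),
      min_distance = numeric(), protein_atom = character(),
      partner_atom = character(), flagged = logical(),
      stringsAsFactors = FALSE)),
    class = "msl_binding_site")
}

#' Parse a PDBsum-style residue interaction list
#'
#' One residue token per line in the form `COMP NUM[ICODE](CHAIN)`, e.g.
#' `SER 140(A)` or `SER 52A(B)`.  All records take the given interaction
#' class; distances are unset (`NA`), since these lists carry no geometry.
#'
#' @param text the list as a single string or vector of lines
#' @param class_hint `"hydrogen_bond"` or `"non_bonded"`
#' @param structure_id label for the originating structure (`code:chain`)
#' @param partner_label label for the partner entity
#' @return an `msl_binding_site`
#' @export
parse_pdbsum_residue_list <- function(text,
                                      class_hint = c("hydrogen_bond",
                                                     "non_bonded"),
                                      structure_id = "unknown:?",
                                      partner_label = "partner") {
  class_hint <- match.arg(class_hint)
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]]
           else text
  lines <- lines[nzchar(trimws(lines))]
  chain_guess <- sub("^.*:", "", structure_id)
  out <- empty_binding_site(sub(":.*$", "", structure_id), chain_guess,
                            partner_label)
  out$structure_id <- structure_id
  if (length(lines) == 0) return(out)
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    mi <- regexec("^\\s*([A-Za-z0-9]{1,3})\\s+([0-9]+)([A-Za-z]?)\\(([A-Za-z0-9])\\)\\s*$",
                  lines[i])
    g <- regmatches(lines[i], mi)[[1]]
    if (length(g) == 0) {
      msl_stop("msl_parse_error", "unparseable residue token at line %d: '%s'",
               i, lines[i])
    }
    recs[[i]] <- data.frame(
      comp_id = toupper(g[2]), author_number = as.integer(g[3]),
      insertion_code = toupper(g[4]), chain_id = g[5],
      partner_id = partner_label, interaction_class = class_hint,
      min_distance = NA_real_, protein_atom = NA_character_,
      partner_atom = NA_character_, flagged = FALSE,
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs)
  records <- records[order(records$author_number, records$insertion_code), ,
                     drop = FALSE]
  rownames(records) <- NULL
  out$records <- records
  out
}

#' Combine binding sites (e.g. hydrogen-bond and non-bonded lists)
#'
#' @param ... `msl_binding_site` objects sharing a structure id
#' @return a single `msl_binding_site` with the concatenated, re-sorted
#'   records (duplicate (residue, class) pairs removed, keeping the first)
#' @export
merge_binding_sites <- function(...) {
  sites <- list(...)
  stopifnot(length(sites) >= 1)
  records <- do.call(rbind, lapply(sites, `[[`, "records"))
  key <- paste(records$author_number, records$insertion_code,
               records$chain_id, records$interaction_class, sep = "\r")
  records <- records[!duplicated(key), , drop = FALSE]
  records <- records[order(records$author_number, records$insertion_code,
                           records$interaction_class), , drop = FALSE]
  rownames(records) <- NULL
  out <- sites[[1]]
  out$records <- records
  out
}

#' @export
print.msl_binding_site <- function(x, ...) {
  n_hb <- sum(x$records$interaction_class == "hydrogen_bond")
  n_nb <- sum(x$records$interaction_class == "non_bonded")
  cat(sprintf("<msl_binding_site %s ~ %s> %d hydrogen-bond, %d non-bonded record(s)\n",
              x$structure_id, x$partner_label, n_hb, n_nb))
  if (nrow(x$records) > 0) {
    print(utils::head(x$records[, c("comp_id", "author_number",
                                    "insertion_code", "interaction_class",
                                    "min_distance")], 10))
    if (nrow(x$records) > 10) cat(sprintf("  ... %d more\n",
                                          nrow(x$records) - 10))
  }
  invisible(x)
}
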