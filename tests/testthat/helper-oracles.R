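# Independent oracles used to cross-check the package implementations.
# These deliberately re-derive results with different code paths: literal
# nested loops, exhaustive enumeration, and standalone geometry.

# ---- contacts: literal O(n^2) all-pairs application of the criteria -------

# Walks the parsed structure lists with explicit loops and applies the
# contact rules pair by pair; returns the set of (author_number, icode,
# class) tuples.  Shares only the donor/acceptor typing tables with the
# implementation (the typing is part of the contract, not the algorithm).
brute_force_contact_set <- function(struct, protein_chain, partner,
                                    criteria = contact_criteria()) {
  ch <- struct$chains[[protein_chain]]
  prot_atoms <- list()
  for (r in ch$residues) {
    if (toupper(r$comp_id) %in% msaligmap:::WATER_COMPONENTS) next
    if (!(msaligmap:::is_amino_acid(r$comp_id, struct$modres_map) ||
          !r$het_flag)) next
    for (k in seq_len(nrow(r$atoms))) {
      if (toupper(r$atoms$element[k]) %in% c("H", "D")) next
      prot_atoms[[length(prot_atoms) + 1L]] <- list(
        res = c(r$author_number, r$insertion_code), comp = r$comp_id,
        name = r$atoms$name[k],
        xyz = c(r$atoms$x[k], r$atoms$y[k], r$atoms$z[k]))
    }
  }
  part_atoms <- list()
  for (cid in names(struct$chains)) {
    for (r in struct$chains[[cid]]$residues) {
      keep <- switch(partner$type,
                     ligand = toupper(r$comp_id) == partner$code,
                     chain = cid == partner$chain_id &&
                       !toupper(r$comp_id) %in% msaligmap:::WATER_COMPONENTS,
                     dna = struct$chains[[cid]]$entity_kind == "dna")
      if (partner$type != "ligand" && cid == protein_chain) keep <- FALSE
      if (!keep) next
      for (k in seq_len(nrow(r$atoms))) {
        if (toupper(r$atoms$element[k]) %in% c("H", "D")) next
        part_atoms[[length(part_atoms) + 1L]] <- list(
          comp = r$comp_id, name = r$atoms$name[k],
          element = r$atoms$element[k],
          xyz = c(r$atoms$x[k], r$atoms$y[k], r$atoms$z[k]))
      }
    }
  }
  out <- character(0)
  for (p in prot_atoms) {
    if (partner$type == "ligand" && toupper(p$comp) == partner$code) next
    for (q in part_atoms) {
      d <- sqrt(sum((p$xyz - q$xyz)^2))
      if (d <= 0) next
      pt <- msaligmap:::protein_atom_da_type(p$comp, p$name)
      qt <- msaligmap:::partner_atom_da_type(q$comp, q$name, q$element)
      compat <- (pt %in% c("donor", "both") && qt %in% c("acceptor", "both")) ||
        (pt %in% c("acceptor", "both") && qt %in% c("donor", "both"))
      cls <- if (compat && d >= criteria$hbond_min && d <= criteria$hbond_max) {
        "hydrogen_bond"
      } else if (d <= criteria$nonbonded_max) {
        "non_bonded"
      } else {
        NA_character_
      }
      if (!is.na(cls)) {
        out <- c(out, paste(p$res[1], p$res[2], cls, sep = "|"))
      }
    }
  }
  sort(unique(out))
}

binding_site_contact_set <- function(site) {
  r <- site$records
  sort(unique(paste(r$author_number, r$insertion_code,
                    r$interaction_class, sep = "|")))
}

# ---- alignment: exhaustive enumeration of global alignments ---------------

blosum62_oracle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# Visits every global alignment of a and b (three moves: match, gap-in-b,
# gap-in-a), accumulating the score incrementally with the affine
# convention gap_open + gap_extend * (L - 1); returns the maximum over all
# complete alignments.  No DP matrices, no per-state maximisation.
enumerate_alignment_optimum <- function(a, b, gap_open = -10,
                                        gap_extend = -0.5) {
  S <- blosum62_oracle()
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  la <- length(av); lb <- length(bv)
  best <- -Inf
  recurse <- function(i, j, last, acc) {
    if (i > la && j > lb) {
      if (acc > best) best <<- acc
      return(invisible(NULL))
    }
    if (i <= la && j <= lb) {
      recurse(i + 1, j + 1, "M", acc + S[av[i], bv[j]])
    }
    if (i <= la) {
      recurse(i + 1, j, "U",
              acc + if (identical(last, "U")) gap_extend else gap_open)
    }
    if (j <= lb) {
      recurse(i, j + 1, "L",
              acc + if (identical(last, "L")) gap_extend else gap_open)
    }
    invisible(NULL)
  }
  recurse(1, 1, "start", 0)
  best
}

# ---- secondary structure: standalone Kabsch-Sander energies ---------------

# Recomputes the backbone H-bond matrix from the parsed structure with its
# own vector arithmetic: amide H from the preceding peptide unit, energy
# 0.084 * 332 * (1/rON + 1/rCH - 1/rOH - 1/rCN), bond when < -0.5.
ks_oracle_hbonds <- function(struct, chain_id, cutoff = -0.5) {
  ch <- struct$chains[[chain_id]]
  res <- Filter(function(r) {
    (msaligmap:::is_amino_acid(r$comp_id, struct$modres_map) ||
       !r$het_flag) &&
      !toupper(r$comp_id) %in% msaligmap:::WATER_COMPONENTS
  }, ch$residues)
  n <- length(res)
  get_atom <- function(r, nm) {
    k <- which(toupper(r$atoms$name) == nm)[1]
    if (is.na(k)) return(NULL)
    c(r$atoms$x[k], r$atoms$y[k], r$atoms$z[k])
  }
  N <- lapply(res, get_atom, "N")
  C <- lapply(res, get_atom, "C")
  O <- lapply(res, get_atom, "O")
  H <- vector("list", n)
  for (j in 2:n) {
    if (is.null(N[[j]]) || is.null(C[[j - 1]]) || is.null(O[[j - 1]])) next
    if (toupper(res[[j]]$comp_id) == "PRO") next
    if (sqrt(sum((N[[j]] - C[[j - 1]])^2)) >= 2.5) next
    v <- C[[j - 1]] - O[[j - 1]]
    H[[j]] <- N[[j]] + v / sqrt(sum(v^2))
  }
  hb <- matrix(FALSE, n, n)
  for (i in 1:n) {
    for (j in 1:n) {
      if (abs(i - j) < 2) next
      if (is.null(C[[i]]) || is.null(O[[i]]) || is.null(N[[j]]) ||
          is.null(H[[j]])) next
      rON <- sqrt(sum((O[[i]] - N[[j]])^2))
      rCH <- sqrt(sum((C[[i]] - H[[j]])^2))
      rOH <- sqrt(sum((O[[i]] - H[[j]])^2))
      rCN <- sqrt(sum((C[[i]] - N[[j]])^2))
      e <- 0.084 * 332 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
      if (e < cutoff) hb[i, j] <- TRUE
    }
  }
  hb
}

# ---- rigid-body transforms ------------------------------------------------

random_rotation <- function(seed) {
  set.seed(seed)
  m <- matrix(stats::rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

transform_structure <- function(struct, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  for (cid in names(struct$chains)) {
    for (k in seq_along(struct$chains[[cid]]$residues)) {
      a <- struct$chains[[cid]]$residues[[k]]$atoms
      xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(rotation)
      a$x <- xyz[, 1] + translation[1]
      a$y <- xyz[, 2] + translation[2]
      a$z <- xyz[, 3] + translation[3]
      struct$chains[[cid]]$residues[[k]]$atoms <- a
    }
  }
  struct
}
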