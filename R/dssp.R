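# Per-residue secondary structure: either parsed from a classic DSSP file
# or assigned de novo by a simplified Kabsch-Sander procedure (backbone
# hydrogen bonds from an electrostatic energy model, then turns/helices/
# bridges/bends).  The code alphabet is {H, E, G, I, S, B, T, ' '} with
# ' ' = coil.

SS_ALPHABET <- c("H", "E", "G", "I", "S", "B", "T", " ")

#' @keywords internal
new_sstrack <- function(structure_id, codes) {
  stopifnot(all(codes %in% SS_ALPHABET))
  structure(list(structure_id = structure_id, codes = codes),
            class = "msl_sstrack")
}

#' @export
print.msl_sstrack <- function(x, ...) {
  cat(sprintf("<msl_sstrack %s> %d residue(s)\n", x$structure_id,
              length(x$codes)))
  cat(" ", gsub(" ", "-", paste(x$codes, collapse = "")), "\n")
  invisible(x)
}

#' Parse a classic DSSP file for one chain
#'
#' Reads the fixed-column residue block (after the `#  RESIDUE` header
#' line): chain identifier at column 12, structure summary code at column
#' 17.  Chain-break `!` lines contribute no code.  Codes outside the
#' `{H,E,G,I,S,B,T}` alphabet (e.g. the newer PPII `P`) map to coil `' '`.
#'
#' @param dssp_text DSSP file content (string or vector of lines)
#' @param chain_id chain to extract
#' @param structure_id label stored on the returned track
#' @return an `msl_sstrack`
#' @export
parse_dssp <- function(dssp_text, chain_id, structure_id = NULL) {
  lines <- if (length(dssp_text) == 1L &&
               grepl("\n", dssp_text, fixed = TRUE)) {
    strsplit(dssp_text, "\n", fixed = TRUE)[[1]]
  } else dssp_text
  hdr <- grep("^\\s*#\\s+RESIDUE", lines)
  if (length(hdr) == 0) {
    msl_stop("msl_parse_error", "no '#  RESIDUE' header line: not DSSP text")
  }
  body <- lines[seq(hdr[1] + 1L, length(lines))]
  body <- body[nzchar(trimws(body))]
  codes <- character(0)
  seen_chain <- FALSE
  for (k in seq_along(body)) {
    ln <- body[k]
    aa <- substr(ln, 14, 14)
    if (aa == "!") next                      # chain break marker
    if (nchar(ln) < 17) {
      msl_stop("msl_parse_error", "truncated DSSP residue line %d", k)
    }
    ch <- substr(ln, 12, 12)
    if (ch != chain_id) next
    seen_chain <- TRUE
    ss <- substr(ln, 17, 17)
    if (!ss %in% SS_ALPHABET) ss <- " "
    codes <- c(codes, ss)
  }
  if (!seen_chain) {
    msl_stop("msl_lookup_error", "chain '%s' absent from DSSP file", chain_id)
  }
  new_sstrack(structure_id %||% paste0("dssp:", chain_id), codes)
}

#' @keywords internal
vnorm <- function(v) sqrt(sum(v^2))

# Kabsch-Sander electrostatic H-bond energy (kcal/mol) between the C=O of
# an acceptor residue and the N-H of a donor residue.
#' @keywords internal
ks_energy <- function(C, O, N, H) {
  q <- 0.084 * 332
  q * (1 / vnorm(O - N) + 1 / vnorm(C - H) -
         1 / vnorm(O - H) - 1 / vnorm(C - N))
}

#' Assign secondary structure from backbone geometry
#'
#' A simplified Kabsch-Sander assignment: amide hydrogens are
#' reconstructed from the preceding peptide unit
#' (H = N + (C_prev - O_prev)/|C_prev - O_prev|, 1 Angstrom from N), a
#' backbone hydrogen bond exists when the electrostatic energy
#' 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN) falls below
#' -0.5 kcal/mol, and codes are derived with priority
#' H > E/B > G > I > T > S: two consecutive n-turns make a helix
#' (n = 4 -> H, 3 -> G, 5 -> I), bridge patterns make ladders (E) or
#' isolated bridges (B), remaining turn spans get T, CA-trace bends
#' (> 70 degrees over i-2, i, i+2) get S, and everything else is coil.
#' Residues lacking any of N, CA, C, O are coded coil.
#'
#' @param struct an `msl_structure`
#' @param chain_id protein chain to assign
#' @param hbond_energy_cutoff kcal/mol; bonds require energy below this
#' @return an `msl_sstrack` aligned 1:1 with the chain's extracted sequence
#' @export
assign_secondary_structure <- function(struct, chain_id,
                                       hbond_energy_cutoff = -0.5) {
  ext <- extract_chain_sequence(struct, chain_id)
  map <- ext$map
  n <- nrow(map)
  chain <- struct$chains[[chain_id]]
  res <- Filter(function(r) {
    (is_amino_acid(r$comp_id, struct$modres_map) || !r$het_flag) &&
      !toupper(r$comp_id) %in% WATER_COMPONENTS
  }, chain$residues)
  stopifnot(length(res) == n)

  bb <- lapply(res, function(r) {
    a <- r$atoms
    pick <- function(nm) {
      i <- which(toupper(a$name) == nm)[1]
      if (is.na(i)) NULL else c(a$x[i], a$y[i], a$z[i])
    }
    list(N = pick("N"), CA = pick("CA"), C = pick("C"), O = pick("O"),
         is_pro = toupper(r$comp_id) == "PRO")
  })
  complete <- vapply(bb, function(b) {
    !is.null(b$N) && !is.null(b$CA) && !is.null(b$C) && !is.null(b$O)
  }, FALSE)
  if (any(!complete)) {
    message(sprintf("assign_secondary_structure: %d residue(s) missing backbone atoms coded coil",
                    sum(!complete)))
  }

  # Chain breaks: peptide bond C(i)-N(i+1) longer than 2.5 A.
  linked <- rep(FALSE, n)       # linked[i]: residue i bonded to i-1
  for (i in seq_len(n)[-1]) {
    if (complete[i] && complete[i - 1]) {
      linked[i] <- vnorm(bb[[i]]$N - bb[[i - 1]]$C) < 2.5
    }
  }

  H <- vector("list", n)
  for (i in seq_len(n)) {
    if (!complete[i] || bb[[i]]$is_pro || !linked[i]) next
    d <- bb[[i - 1]]$C - bb[[i - 1]]$O
    H[[i]] <- bb[[i]]$N + d / vnorm(d)
  }

  # hb[i, j]: CO of i hydrogen-bonded to NH of j.
  hb <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    if (!complete[i]) next
    for (j in seq_len(n)) {
      if (abs(i - j) < 2 || !complete[j] || is.null(H[[j]])) next
      e <- ks_energy(bb[[i]]$C, bb[[i]]$O, bb[[j]]$N, H[[j]])
      if (e < hbond_energy_cutoff) hb[i, j] <- TRUE
    }
  }

  turn <- function(nt) {
    t <- rep(FALSE, n)
    for (i in seq_len(n)) if (i + nt <= n && hb[i, i + nt]) t[i] <- TRUE
    t
  }
  t3 <- turn(3); t4 <- turn(4); t5 <- turn(5)

  codes <- rep(" ", n)
  assign_helix <- function(codes, t, sym, span) {
    for (i in seq_len(n)) {
      if (i >= 2 && t[i - 1] && t[i]) {
        rng <- i:min(i + span - 1, n)
        free <- codes[rng] == " " | codes[rng] == sym
        codes[rng[free]] <- sym
      }
    }
    codes
  }
  codes <- assign_helix(codes, t4, "H", 4)

  # Bridges (parallel / antiparallel) for |i-j| > 2.
  bridge <- matrix(FALSE, n, n)
  if (n >= 6) for (i in 2:(n - 1)) {
    for (j in 2:(n - 1)) {
      if (abs(i - j) <= 2) next
      para <- (hb[i - 1, j] && hb[j, i + 1]) || (hb[j - 1, i] && hb[i, j + 1])
      anti <- (hb[i, j] && hb[j, i]) ||
        (i + 1 <= n && j + 1 <= n && hb[i - 1, j + 1] && hb[j - 1, i + 1])
      if (para || anti) bridge[i, j] <- TRUE
    }
  }
  has_bridge <- apply(bridge, 1, any)
  # Ladder: bridge (i,j) with an adjacent bridge (i+1, j+1) or (i+1, j-1).
  in_ladder <- rep(FALSE, n)
  for (i in seq_len(n - 1)) {
    for (j in seq_len(n)) {
      if (!bridge[i, j]) next
      nb <- c(if (j + 1 <= n) bridge[i + 1, j + 1] else FALSE,
              if (j - 1 >= 1) bridge[i + 1, j - 1] else FALSE)
      if (any(nb)) {
        in_ladder[c(i, i + 1, j)] <- TRUE
        if (j + 1 <= n && bridge[i + 1, j + 1]) in_ladder[j + 1] <- TRUE
        if (j - 1 >= 1 && bridge[i + 1, j - 1]) in_ladder[j - 1] <- TRUE
      }
    }
  }
  codes[in_ladder & codes == " "] <- "E"
  codes[has_bridge & !in_ladder & codes == " "] <- "B"

  codes <- assign_helix(codes, t3, "G", 3)
  codes <- assign_helix(codes, t5, "I", 5)

  # Isolated turns: interior residues of any n-turn span.
  for (nt in 3:5) {
    t <- list(`3` = t3, `4` = t4, `5` = t5)[[as.character(nt)]]
    for (i in which(t)) {
      rng <- (i + 1):min(i + nt - 1, n)
      codes[rng][codes[rng] == " "] <- "T"
    }
  }

  # Bends: CA-trace direction change > 70 degrees over (i-2, i, i+2).
  if (n >= 5) for (i in 3:(n - 2)) {
    if (!all(complete[(i - 2):(i + 2)])) next
    u <- bb[[i]]$CA - bb[[i - 2]]$CA
    v <- bb[[i + 2]]$CA - bb[[i]]$CA
    ang <- acos(pmin(1, pmax(-1, sum(u * v) / (vnorm(u) * vnorm(v))))) * 180 / pi
    if (ang > 70 && codes[i] == " ") codes[i] <- "S"
  }

  new_sstrack(paste0(struct$pdb_code, ":", chain_id), codes)
}
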