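# Rendering of the annotated alignment: a blocked plain-text view for the
# terminal and a self-contained HTML file following the alignment-viewer
# conventions (ClustalX residue palette; hydrogen-bond residues bold,
# non-bonded underlined; binding columns red when identical across all
# sequences, blue when substituted).

#' Assemble an annotated alignment
#'
#' @param msa an `msl_msa`
#' @param tracks named list: structure row id -> projected
#'   secondary-structure string (from [project_track()])
#' @param conservation an `msl_conservation` (possibly with zero sites)
#' @return object of class `msl_annotated`
#' @export
annotated_alignment <- function(msa, tracks = list(),
                                conservation = classify_conservation(list())) {
  stopifnot(inherits(msa, "msl_msa"), inherits(conservation,
                                               "msl_conservation"))
  for (id in names(tracks)) {
    stopifnot(id %in% msa$ids, nchar(tracks[[id]]) == msa$length)
  }
  structure(list(msa = msa, tracks = tracks, conservation = conservation),
            class = "msl_annotated")
}

#' @keywords internal
site_columns <- function(conservation) {
  sites <- conservation$sites
  if (length(sites) == 0) {
    return(data.frame(column = integer(), status = character(),
                      hydrogen_bond = logical(), non_bonded = logical(),
                      stringsAsFactors = FALSE))
  }
  col <- vapply(sites, `[[`, 0L, "column")
  cls <- vapply(sites, `[[`, "", "interaction_class")
  status <- vapply(sites, `[[`, "", "status")
  ucol <- sort(unique(col))
  frac <- vapply(ucol, function(cc) {
    s <- sites[[which(col == cc)[1]]]
    letters_s <- vapply(s$per_record, `[[`, "", "letter")
    mean(letters_s == s$source_letter)
  }, 0)
  data.frame(
    column = ucol,
    status = vapply(ucol, function(cc) status[col == cc][1], ""),
    hydrogen_bond = vapply(ucol, function(cc)
      any(cls[col == cc] == "hydrogen_bond"), FALSE),
    non_bonded = vapply(ucol, function(cc)
      any(cls[col == cc] == "non_bonded"), FALSE),
    frac_match = frac,
    stringsAsFactors = FALSE)
}

#' Render the annotated alignment as plain text
#'
#' Section 1 is the blocked alignment: above each structure row its
#' secondary-structure track (coil as `-`), beneath each row a class
#' marker line (`h` hydrogen bond, `n` non-bonded, `b` both) and beneath
#' the ruler a status marker line (`*` identical, `+` substituted).
#' Section 2 lists the binding-site sub-alignment column by column.
#'
#' @param annotated an [annotated_alignment()]
#' @param block_width columns per block (default 60)
#' @return a single string
#' @export
render_text <- function(annotated, block_width = 60) {
  msa <- annotated$msa
  sc <- site_columns(annotated$conservation)
  id_w <- max(nchar(msa$ids), 10L)
  pad <- function(s) formatC(s, width = id_w, flag = "-")

  class_marks <- rep(" ", msa$length)
  class_marks[sc$column[sc$hydrogen_bond & !sc$non_bonded] + 1L] <- "h"
  class_marks[sc$column[!sc$hydrogen_bond & sc$non_bonded] + 1L] <- "n"
  class_marks[sc$column[sc$hydrogen_bond & sc$non_bonded] + 1L] <- "b"
  status_marks <- rep(" ", msa$length)
  status_marks[sc$column[sc$status == "identical"] + 1L] <- "*"
  status_marks[sc$column[sc$status == "substituted"] + 1L] <- "+"

  out <- c("Section 1: annotated alignment", "")
  starts <- seq(1L, msa$length, by = block_width)
  has_sites <- nrow(sc) > 0
  for (s in starts) {
    e <- min(s + block_width - 1L, msa$length)
    out <- c(out, sprintf("%s columns %d-%d", pad("#"), s, e))
    if (has_sites) {
      out <- c(out, paste0(pad("#status"), " ",
                           substr(paste(status_marks, collapse = ""), s, e)))
    }
    for (i in seq_along(msa$ids)) {
      id <- msa$ids[i]
      if (id %in% names(annotated$tracks)) {
        tr <- gsub(" ", "-", substr(annotated$tracks[[id]], s, e))
        out <- c(out, paste0(pad("#ss"), " ", tr))
      }
      out <- c(out, paste0(pad(id), " ", substr(msa$aligned[i], s, e)))
      if (has_sites && id %in% names(annotated$tracks)) {
        out <- c(out, paste0(pad("#class"), " ",
                             substr(paste(class_marks, collapse = ""), s, e)))
      }
    }
    out <- c(out, "")
  }

  out <- c(out, "Section 2: binding-site sub-alignment", "")
  if (nrow(sc) == 0) {
    out <- c(out, "no binding sites mapped", "")
  } else {
    hdr <- site_headers(annotated)
    out <- c(out, paste0(pad("#residue"), " ", paste(hdr, collapse = " ")))
    for (i in seq_along(msa$ids)) {
      letters_i <- strsplit(msa$aligned[i], "")[[1]][sc$column + 1L]
      cells <- formatC(letters_i, width = max(nchar(hdr)))
      out <- c(out, paste0(pad(msa$ids[i]), " ", paste(cells, collapse = " ")))
    }
    stat <- formatC(ifelse(sc$status == "identical", "*", "+"),
                    width = max(nchar(hdr)))
    out <- c(out, paste0(pad("#status"), " ", paste(stat, collapse = " ")))
    out <- c(out, "")
  }
  paste(out, collapse = "\n")
}

#' @keywords internal
site_headers <- function(annotated) {
  sc <- site_columns(annotated$conservation)
  sites <- annotated$conservation$sites
  col <- vapply(sites, `[[`, 0L, "column")
  vapply(sc$column, function(cc) {
    s <- sites[[which(col == cc)[1]]]
    sprintf("%s%d%s", s$source_letter, s$author_number, s$insertion_code)
  }, "")
}

#' Render the annotated alignment as a self-contained HTML page
#'
#' Section 1: blocked alignment with the secondary-structure track above
#' each structure row, residues colored by ClustalX physicochemical class,
#' hydrogen-bond columns bold and non-bonded columns underlined.
#' Section 2: the binding-site sub-alignment with author-number headers,
#' identical columns on red, substituted on blue.  Byte-deterministic for
#' fixed input.
#'
#' @inheritParams render_text
#' @param graded when `TRUE`, substituted cells in Section 2 are shaded by
#'   the fraction of sequences matching the structure residue (darker =
#'   fewer matches) instead of the flat substituted blue
#' @return a single HTML string
#' @export
render_html <- function(annotated, block_width = 60, graded = FALSE) {
  msa <- annotated$msa
  sc <- site_columns(annotated$conservation)
  esc <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    gsub(">", "&gt;", s, fixed = TRUE)
  }
  css <- paste(
    "body{font-family:monospace;white-space:pre;}",
    ".hb{font-weight:bold;}",
    ".nb{text-decoration:underline;}",
    ".identical{background-color:#f01505;color:#ffffff;}",
    ".substituted{background-color:#80a0f0;color:#ffffff;}",
    ".ss{color:#555555;}",
    paste(sprintf(".%s{background-color:%s;}", names(CLUSTALX_COLORS),
                  unname(CLUSTALX_COLORS)), collapse = "\n"),
    sep = "\n")

  hb_cols <- sc$column[sc$hydrogen_bond]
  nb_cols <- sc$column[sc$non_bonded]
  id_w <- max(nchar(msa$ids), 10L)
  pad <- function(s) formatC(esc(s), width = id_w, flag = "-")

  residue_span <- function(ch, col0) {
    if (ch == "-") return(ch)
    cls <- unname(CLUSTALX_CLASS[ch])
    if (is.na(cls)) cls <- "unconserved"
    extra <- c(if (col0 %in% hb_cols) "hb",
               if (col0 %in% nb_cols) "nb")
    sprintf('<span class="%s">%s</span>',
            paste(c(cls, extra), collapse = " "), esc(ch))
  }

  body <- c("<h2>Section 1: annotated alignment</h2>")
  starts <- seq(1L, msa$length, by = block_width)
  for (s in starts) {
    e <- min(s + block_width - 1L, msa$length)
    block <- c(sprintf("%s columns %d-%d", pad("#"), s, e))
    for (i in seq_along(msa$ids)) {
      id <- msa$ids[i]
      if (id %in% names(annotated$tracks)) {
        tr <- gsub(" ", "-", substr(annotated$tracks[[id]], s, e))
        block <- c(block, sprintf('%s <span class="ss">%s</span>',
                                  pad("#ss"), esc(tr)))
      }
      chars <- strsplit(substr(msa$aligned[i], s, e), "")[[1]]
      cols0 <- seq(s - 1L, e - 1L)
      row <- paste(mapply(residue_span, chars, cols0), collapse = "")
      block <- c(block, paste0(pad(id), " ", row))
    }
    body <- c(body, "<div class=\"block\">",
              paste(block, collapse = "\n"), "</div>")
  }

  body <- c(body, "<h2>Section 2: binding-site sub-alignment</h2>")
  if (nrow(sc) == 0) {
    body <- c(body, "<p>no binding sites mapped</p>")
  } else {
    hdr <- site_headers(annotated)
    rows <- c(paste0("<tr><th></th>",
                     paste(sprintf("<th>%s</th>", esc(hdr)), collapse = ""),
                     "</tr>"))
    for (i in seq_along(msa$ids)) {
      letters_i <- strsplit(msa$aligned[i], "")[[1]][sc$column + 1L]
      style <- if (graded) {
        ifelse(sc$status == "substituted",
               sprintf(' style="background-color:rgba(40,80,200,%.2f)"',
                       0.25 + 0.75 * (1 - sc$frac_match)),
               "")
      } else rep("", nrow(sc))
      cells <- sprintf('<td class="%s"%s>%s</td>', sc$status, style,
                       esc(letters_i))
      rows <- c(rows, paste0(sprintf("<tr><th>%s</th>", esc(msa$ids[i])),
                             paste(cells, collapse = ""), "</tr>"))
    }
    body <- c(body, "<table>", rows, "</table>")
  }

  paste(c("<!DOCTYPE html>", "<html><head><meta charset=\"utf-8\"/>",
          "<title>binding-site annotation transfer</title>",
          "<style>", css, "</style></head><body>",
          body, "</body></html>"), collapse = "\n")
}

#' Summary table of conservation counts
#'
#' Per interaction class and per structure plus a pooled row
#' (deduplicated by alignment column): number of mapped sites, identical,
#' substituted, and unmappable interaction records.
#'
#' @param conservation an `msl_conservation`
#' @return a data frame (printed as the summary table)
#' @export
summarize_conservation <- function(conservation) {
  sites <- conservation$sites
  un <- conservation$unmappable
  classes <- c("hydrogen_bond", "non_bonded")
  if (length(sites) > 0) {
    classes <- sort(unique(c(classes,
                             vapply(sites, `[[`, "", "interaction_class"))))
  }
  structs <- if (length(sites) > 0) {
    sort(unique(vapply(sites, `[[`, "", "structure_id")))
  } else character(0)
  n_un <- function(ss, cc) {
    if (is.null(un) || nrow(un) == 0) return(0L)
    sel <- un$interaction_class == cc
    if (!is.null(ss) && "chain_id" %in% names(un)) {
      return(sum(sel))   # unmappable records carry no structure grouping
    }
    sum(sel)
  }
  mk_row <- function(scope, sel_sites, cc) {
    cls <- vapply(sel_sites, `[[`, "", "interaction_class")
    col <- vapply(sel_sites, `[[`, 0L, "column")
    status <- vapply(sel_sites, `[[`, "", "status")
    sel <- which(cls == cc)
    dedup <- sel[!duplicated(col[sel])]
    data.frame(scope = scope, interaction_class = cc,
               n_sites = length(dedup),
               n_identical = sum(status[dedup] == "identical"),
               n_substituted = sum(status[dedup] == "substituted"),
               n_unmappable = n_un(scope, cc),
               stringsAsFactors = FALSE)
  }
  rows <- list()
  for (ss in structs) {
    sel_sites <- Filter(function(x) x$structure_id == ss, sites)
    for (cc in classes) rows[[length(rows) + 1L]] <- mk_row(ss, sel_sites, cc)
  }
  for (cc in classes) rows[[length(rows) + 1L]] <- mk_row("pooled", sites, cc)
  do.call(rbind, rows)
}
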