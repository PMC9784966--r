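# Annotation transfer through alignment columns: residue-index <-> column
# maps, projection of binding-site residues and secondary-structure tracks
# onto every aligned sequence, and identical/substituted classification.

#' Build the residue-index <-> alignment-column map for one MSA row
#'
#' @param msa an `msl_msa`
#' @param record_id row identifier
#' @return object of class `msl_colmap`: list with `record_id`,
#'   `seq_to_col` (0-based sequence index -> 0-based column, strictly
#'   increasing) and `col_to_seq` (0-based column -> 0-based sequence
#'   index, `NA` at gap columns)
#' @export
build_column_map <- function(msa, record_id) {
  row <- msa_row(msa, record_id)
  chars <- strsplit(row, "")[[1]]
  non_gap <- which(chars != "-")
  seq_to_col <- non_gap - 1L
  col_to_seq <- rep(NA_integer_, length(chars))
  col_to_seq[non_gap] <- seq_along(non_gap) - 1L
  structure(list(record_id = record_id, seq_to_col = seq_to_col,
                 col_to_seq = col_to_seq),
            class = "msl_colmap")
}

#' Project binding-site residues onto alignment columns
#'
#' Each interaction record is resolved through the structure chain's
#' residue-number map to a 0-based sequence index, then through the
#' structure row's column map to an alignment column; the letter every
#' other row shows at that column is recorded.  Records whose residue is
#' absent from the coordinates (e.g. a PDBsum-listed residue not observed
#' in the ATOM records) land in `unmappable`, never silently dropped.
#'
#' @param site an `msl_binding_site`
#' @param num_map the structure chain's `msl_resmap`
#' @param col_map the structure row's [build_column_map()] result
#' @param msa the `msl_msa` containing the structure row
#' @return list with `sites` (list of mapped-site records: `column`
#'   0-based, `structure_id`, `author_number`, `insertion_code`,
#'   `interaction_class`, `source_letter`, and `per_record`, a named list
#'   id -> list(letter, seq_index)) and `unmappable` (data frame of
#'   unresolved interaction records)
#' @export
project_binding_site <- function(site, num_map, col_map, msa) {
  stopifnot(inherits(site, "msl_binding_site"))
  recs <- site$records
  sites <- list()
  unmappable <- recs[0, , drop = FALSE]
  row_chars <- lapply(msa$aligned, function(s) strsplit(s, "")[[1]])
  names(row_chars) <- msa$ids
  for (k in seq_len(nrow(recs))) {
    idx <- resmap_index(num_map, recs$author_number[k],
                        recs$insertion_code[k])
    if (is.na(idx)) {
      unmappable <- rbind(unmappable, recs[k, , drop = FALSE])
      next
    }
    column <- col_map$seq_to_col[idx + 1L]
    per_record <- lapply(msa$ids, function(id) {
      letter <- row_chars[[id]][column + 1L]
      cm <- build_column_map(msa, id)
      list(letter = letter,
           seq_index = if (letter == "-") NA_integer_
                       else cm$col_to_seq[column + 1L])
    })
    names(per_record) <- msa$ids
    src_letter <- row_chars[[col_map$record_id]][column + 1L]
    sites[[length(sites) + 1L]] <- list(
      column = column,
      structure_id = site$structure_id,
      author_number = recs$author_number[k],
      insertion_code = recs$insertion_code[k],
      comp_id = recs$comp_id[k],
      interaction_class = recs$interaction_class[k],
      source_letter = src_letter,
      per_record = per_record
    )
  }
  list(sites = sites, unmappable = unmappable)
}

#' Classify mapped binding columns as identical or substituted
#'
#' A column is identical when every aligned sequence shows the same
#' residue letter and none shows a gap; any mismatch or any gap makes it
#' substituted (a deletion at a binding position is functionally a
#' substitution).  Summary counts tally deduplicated columns per
#' interaction class.
#'
#' @param sites list of mapped sites from [project_binding_site()]
#'   (possibly concatenated across structures)
#' @param unmappable optional data frame of unresolved records
#' @return object of class `msl_conservation`: `sites` (each gaining a
#'   `status` field), `summary` (data frame per interaction class:
#'   `n_sites`, `n_identical`, `n_substituted` over deduplicated columns),
#'   `unmappable`
#' @export
classify_conservation <- function(sites, unmappable = NULL) {
  for (k in seq_along(sites)) {
    letters_k <- vapply(sites[[k]]$per_record, `[[`, "", "letter")
    sites[[k]]$status <-
      if (length(letters_k) > 0 && !any(letters_k == "-") &&
          length(unique(letters_k)) == 1L) "identical" else "substituted"
  }
  summary_df <- conservation_summary(sites)
  structure(list(sites = sites, summary = summary_df,
                 unmappable = unmappable %||%
                   data.frame(stringsAsFactors = FALSE)),
            class = "msl_conservation")
}

#' @keywords internal
conservation_summary <- function(sites) {
  if (length(sites) == 0) {
    return(data.frame(interaction_class = character(), n_sites = integer(),
                      n_identical = integer(), n_substituted = integer(),
                      stringsAsFactors = FALSE))
  }
  cls <- vapply(sites, `[[`, "", "interaction_class")
  col <- vapply(sites, `[[`, 0L, "column")
  status <- vapply(sites, `[[`, "", "status")
  out <- lapply(sort(unique(cls)), function(cc) {
    sel <- which(cls == cc)
    dedup <- sel[!duplicated(col[sel])]     # one count per alignment column
    data.frame(interaction_class = cc,
               n_sites = length(dedup),
               n_identical = sum(status[dedup] == "identical"),
               n_substituted = sum(status[dedup] == "substituted"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
print.msl_conservation <- function(x, ...) {
  cat(sprintf("<msl_conservation> %d mapped site(s), %d unmappable\n",
              length(x$sites), nrow(x$unmappable)))
  if (nrow(x$summary) > 0) print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Project a secondary-structure track into alignment coordinates
#'
#' @param track an `msl_sstrack` whose length equals the row's non-gap
#'   count
#' @param col_map the row's [build_column_map()] result
#' @param msa_length total number of alignment columns
#' @return a string of `msa_length` characters: the track codes at mapped
#'   columns, `-` at gap columns
#' @export
project_track <- function(track, col_map, msa_length) {
  codes <- track$codes
  if (length(codes) != length(col_map$seq_to_col)) {
    msl_stop("msl_contract_error",
             "track length %d != ungapped row length %d for '%s'",
             length(codes), length(col_map$seq_to_col), col_map$record_id)
  }
  out <- rep("-", msa_length)
  out[col_map$seq_to_col + 1L] <- codes
  paste(out, collapse = "")
}
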