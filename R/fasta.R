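# Sequence records and multi-FASTA I/O (Biostrings-backed).

#' Create a sequence record
#'
#' @param id unique identifier (first whitespace-delimited header token)
#' @param sequence one-letter amino-acid string; letters outside the 20
#'   standard residues are coerced to `X`, `*` stop symbols are stripped
#' @param description free-text remainder of the header
#' @param is_structure whether the record is a structure-derived sequence
#' @param source for structure records, `list(pdb_code, chain)`
#' @return object of class `msl_seqrecord`
#' @export
seq_record <- function(id, sequence, description = "",
                       is_structure = FALSE, source = NULL) {
  stopifnot(nzchar(id), nzchar(sequence))
  sequence <- unname(toupper(gsub("\\s", "", sequence)))
  id <- unname(id)
  if (grepl("\\*", sequence)) {
    msl_warn("record '%s': stripping '*' stop symbol(s)", id)
    sequence <- gsub("*", "", sequence, fixed = TRUE)
  }
  bad <- !strsplit(sequence, "")[[1]] %in% c(names(CLUSTALX_CLASS))
  if (any(bad)) {
    sequence <- paste(ifelse(bad, "X", strsplit(sequence, "")[[1]]),
                      collapse = "")
  }
  structure(list(id = id, description = description, sequence = sequence,
                 is_structure = is_structure, source = source),
            class = "msl_seqrecord")
}

#' Read a multi-FASTA file of protein sequences
#'
#' @param path file path
#' @return list of [seq_record()] objects, ids checked for uniqueness
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) {
    msl_stop("msl_parse_error", "no sequences in %s", path)
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    msl_stop("msl_validation_error", "duplicate sequence id(s): %s",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  mapply(function(i, d, s) seq_record(i, s, d),
         ids, desc, as.character(set), SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write sequence records as multi-FASTA (60-column wrap)
#'
#' @param records list of [seq_record()] objects
#' @param path output file path
#' @export
write_fasta <- function(records, path) {
  seqs <- Biostrings::AAStringSet(vapply(records, `[[`, "", "sequence"))
  names(seqs) <- vapply(records, function(r) {
    if (nzchar(r$description)) paste(r$id, r$description) else r$id
  }, "")
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}
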