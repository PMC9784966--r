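# Retrieval of PDB entries with a local cache; offline mode never touches
# the network, so pipelines are reproducible from a directory of files.

#' Fetch a PDB entry as text, using a local cache
#'
#' @param pdb_code 4-character PDB identifier (`[0-9][A-Za-z0-9]{3}`).
#' @param cache_dir directory holding `<code>.pdb` files; created when
#'   missing.
#' @param offline when `TRUE`, never download; a cache miss is an error.
#' @param url_template `sprintf` template with one `%s` slot for the
#'   uppercase PDB code.
#' @return the PDB file content as a single string
#' @export
fetch_structure <- function(pdb_code, cache_dir = tempdir(), offline = FALSE,
                            url_template = "https://files.rcsb.org/download/%s.pdb") {
  if (!grepl("^[0-9][A-Za-z0-9]{3}$", pdb_code)) {
    msl_stop("msl_validation_error",
             "'%s' is not a valid PDB code ([0-9][A-Za-z0-9]{3})", pdb_code)
  }
  code <- tolower(pdb_code)
  path <- file.path(cache_dir, paste0(code, ".pdb"))
  if (file.exists(path)) {
    return(paste(readLines(path, warn = FALSE), collapse = "\n"))
  }
  if (offline) {
    msl_stop("msl_availability_error",
             "offline mode and '%s' is not cached in %s", code, cache_dir)
  }
  if (!dir.exists(cache_dir)) dir.create(cache_dir, recursive = TRUE)
  url <- sprintf(url_template, toupper(code))
  status <- tryCatch(
    utils::download.file(url, path, quiet = TRUE, mode = "wb"),
    error = function(e) e, warning = function(w) w
  )
  if (inherits(status, "condition") || !file.exists(path) ||
      file.size(path) == 0) {
    if (file.exists(path)) unlink(path)
    msl_stop("msl_network_error", "download of %s from %s failed: %s",
             toupper(code), url,
             if (inherits(status, "condition")) conditionMessage(status)
             else "empty response")
  }
  paste(readLines(path, warn = FALSE), collapse = "\n")
}
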