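# Orchestration of the full workflow: resolve inputs, fetch/parse
# structures, detect contacts, align, assign secondary structure, project
# annotations, and write the HTML / text / TSV artifacts.  The exported
# command-line front end (inst/cli/msaligmap.R) is a thin wrapper over
# run_msaligmap().

STRUCTURE_TOKEN_RE <- "^[0-9][A-Za-z0-9]{3}:[A-Za-z0-9]$"

#' Build a run configuration
#'
#' @param mode `"ligand"`, `"dna"`, or `"peptide"`
#' @param fasta path to the multi-FASTA input
#' @param structures character vector (or one comma-separated string) of
#'   `PDBCODE:CHAIN` tokens; ignored in DNA mode, where structure tokens
#'   are read from the FASTA headers
#' @param ligand chemical component code (ligand mode)
#' @param peptide_chain partner chain id (peptide mode)
#' @param aligner `"mafft"`, `"clustalo"`, or `"builtin"`
#' @param pdb_dir directory of local `<code>.pdb` files; doubles as the
#'   download cache
#' @param dssp_dir optional directory of `<code>.dssp` files; when a file
#'   is absent the built-in assignment runs instead
#' @param offline never touch the network
#' @param criteria [contact_criteria()] overrides
#' @param out_html,out_text,out_tsv output paths (`NULL` = skip)
#' @param block_width alignment block width for the renderers
#' @param graded shade substituted cells by match fraction in HTML
#' @return object of class `msl_config`
#' @export
run_config <- function(mode = c("ligand", "dna", "peptide"), fasta,
                       structures = character(0), ligand = NULL,
                       peptide_chain = NULL, aligner = "mafft",
                       pdb_dir = tempdir(), dssp_dir = NULL,
                       offline = FALSE, criteria = contact_criteria(),
                       out_html = NULL, out_text = NULL, out_tsv = NULL,
                       block_width = 60, graded = FALSE) {
  mode <- match.arg(mode)
  if (length(structures) == 1 && grepl(",", structures)) {
    structures <- trimws(strsplit(structures, ",")[[1]])
  }
  if (mode == "ligand" && is.null(ligand)) {
    msl_stop("msl_config_error", "ligand mode requires a ligand code")
  }
  if (mode == "peptide" && is.null(peptide_chain)) {
    msl_stop("msl_config_error", "peptide mode requires --peptide-chain")
  }
  structure(list(mode = mode, fasta = fasta, structures = structures,
                 ligand = ligand, peptide_chain = peptide_chain,
                 aligner = aligner, pdb_dir = pdb_dir, dssp_dir = dssp_dir,
                 offline = offline, criteria = criteria,
                 out_html = out_html, out_text = out_text,
                 out_tsv = out_tsv, block_width = block_width,
                 graded = graded),
            class = "msl_config")
}

#' Resolve structure jobs and target sequences from a configuration
#'
#' Ligand/peptide modes take structure jobs from the token list and treat
#' every FASTA entry (except entries whose id repeats a token) as a
#' target.  DNA mode reads the tokens from the FASTA headers themselves:
#' headers matching `PDBCODE:CHAIN` become structure jobs, everything
#' else a target.  A malformed token is demoted to a target with a
#' warning, never a hard error.
#'
#' @param config an [run_config()] object
#' @return list with `jobs` (list of `list(pdb_code, chain)`) and
#'   `targets` (list of [seq_record()])
#' @export
resolve_inputs <- function(config) {
  records <- read_fasta(config$fasta)
  ids <- vapply(records, `[[`, "", "id")
  if (config$mode == "dna") {
    is_tok <- grepl(STRUCTURE_TOKEN_RE, ids)
    jobs <- lapply(ids[is_tok], function(t) {
      parts <- strsplit(t, ":")[[1]]
      list(pdb_code = tolower(parts[1]), chain = parts[2])
    })
    targets <- records[!is_tok]
  } else {
    ok <- grepl(STRUCTURE_TOKEN_RE, config$structures)
    if (any(!ok)) {
      msl_warn("token(s) not matching PDBCODE:CHAIN treated as non-structure input: %s",
               paste(config$structures[!ok], collapse = ", "))
    }
    jobs <- lapply(config$structures[ok], function(t) {
      parts <- strsplit(t, ":")[[1]]
      list(pdb_code = tolower(parts[1]), chain = parts[2])
    })
    tok_up <- toupper(config$structures[ok])
    targets <- records[!toupper(ids) %in% tok_up]
  }
  if (length(jobs) == 0) {
    msl_stop("msl_config_error", "nothing to map: no structure jobs resolved")
  }
  if (length(targets) == 0) {
    msl_warn("no target sequences: structure-vs-structure comparison only")
  }
  list(jobs = jobs, targets = targets)
}

#' Run the complete annotation-transfer workflow
#'
#' Fetch/parse the structures, extract their chain sequences, detect
#' binding-site contacts against the mode's partner, align structure and
#' target sequences, obtain per-structure secondary-structure tracks
#' (DSSP files when supplied, built-in assignment otherwise), project
#' binding sites and tracks through the alignment, classify conservation,
#' and write the requested artifacts.
#'
#' @param config an [run_config()] object
#' @return (invisibly) a list with `msa`, `tracks`, `conservation`,
#'   `summary`, `identity`, `annotated`, `sites_table` (the TSV content as
#'   a data frame), and `artifacts` (paths written)
#' @export
run_msaligmap <- function(config) {
  stopifnot(inherits(config, "msl_config"))
  inputs <- resolve_inputs(config)

  struct_records <- list()
  structure_data <- list()
  for (job in inputs$jobs) {
    pdb_text <- fetch_structure(job$pdb_code, cache_dir = config$pdb_dir,
                                offline = config$offline)
    struct <- parse_structure(pdb_text, pdb_code = job$pdb_code)
    ext <- extract_chain_sequence(struct, job$chain)
    sid <- toupper(paste0(job$pdb_code, ":", job$chain))
    partner <- switch(config$mode,
                      ligand = ligand_partner(config$ligand),
                      peptide = chain_partner(config$peptide_chain),
                      dna = dna_partner())
    site <- detect_contacts(struct, job$chain, partner, config$criteria)
    track <- structure_track(struct, job, config$dssp_dir)
    struct_records[[sid]] <- seq_record(sid, ext$sequence,
                                        is_structure = TRUE,
                                        source = list(pdb_code = job$pdb_code,
                                                      chain = job$chain))
    structure_data[[sid]] <- list(struct = struct, ext = ext, site = site,
                                  track = track)
  }

  records <- c(unname(struct_records), inputs$targets)
  msa <- align_records(records, config$aligner)
  identity <- pairwise_identity(msa)

  all_sites <- list()
  unmappable <- NULL
  tracks <- list()
  for (sid in names(structure_data)) {
    sd <- structure_data[[sid]]
    col_map <- build_column_map(msa, sid)
    sd$site$structure_id <- sid
    proj <- project_binding_site(sd$site, sd$ext$map, col_map, msa)
    all_sites <- c(all_sites, proj$sites)
    unmappable <- if (is.null(unmappable)) proj$unmappable
                  else rbind(unmappable, proj$unmappable)
    tracks[[sid]] <- project_track(sd$track, col_map, msa$length)
  }
  conservation <- classify_conservation(all_sites, unmappable)
  annotated <- annotated_alignment(msa, tracks, conservation)
  summary_df <- summarize_conservation(conservation)

  sites_table <- sites_as_table(conservation, msa)
  artifacts <- character(0)
  if (!is.null(config$out_html)) {
    writeLines(render_html(annotated, config$block_width,
                           graded = config$graded), config$out_html)
    artifacts <- c(artifacts, html = config$out_html)
  }
  if (!is.null(config$out_text)) {
    writeLines(render_text(annotated, config$block_width), config$out_text)
    artifacts <- c(artifacts, text = config$out_text)
  }
  if (!is.null(config$out_tsv)) {
    utils::write.table(sites_table, config$out_tsv, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    artifacts <- c(artifacts, tsv = config$out_tsv)
  }

  invisible(list(msa = msa, tracks = tracks, conservation = conservation,
                 summary = summary_df, identity = identity,
                 annotated = annotated, sites_table = sites_table,
                 artifacts = artifacts))
}

#' @keywords internal
structure_track <- function(struct, job, dssp_dir) {
  if (!is.null(dssp_dir)) {
    path <- file.path(dssp_dir, paste0(tolower(job$pdb_code), ".dssp"))
    if (file.exists(path)) {
      return(parse_dssp(paste(readLines(path, warn = FALSE),
                              collapse = "\n"),
                        job$chain,
                        structure_id = paste0(struct$pdb_code, ":",
                                              job$chain)))
    }
  }
  assign_secondary_structure(struct, job$chain)
}

#' Machine-readable table of mapped sites
#'
#' One row per mapped site: alignment column (0-based), structure id,
#' author number + insertion code, interaction class, conservation
#' status, then one letter column per MSA record.
#'
#' @param conservation an `msl_conservation`
#' @param msa the corresponding `msl_msa`
#' @return a data frame
#' @export
sites_as_table <- function(conservation, msa) {
  sites <- conservation$sites
  base_cols <- c("column", "structure", "author_number", "icode",
                 "class", "status")
  if (length(sites) == 0) {
    out <- as.data.frame(setNames(rep(list(character(0)),
                                      length(base_cols) + length(msa$ids)),
                                  c(base_cols, msa$ids)))
    return(out)
  }
  rows <- lapply(sites, function(s) {
    letters_s <- vapply(s$per_record, `[[`, "", "letter")
    cbind(data.frame(column = s$column, structure = s$structure_id,
                     author_number = s$author_number, icode = s$insertion_code,
                     class = s$interaction_class, status = s$status,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(setNames(letters_s[msa$ids], msa$ids)),
                        check.names = FALSE, stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  out[order(out$column, out$structure, out$class), , drop = FALSE]
}
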