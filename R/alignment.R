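# Multiple sequence alignment: an external-aligner wrapper (MAFFT or
# Clustal Omega on the PATH) and a self-contained progressive aligner
# (k-mer distances -> UPGMA guide tree -> profile-profile Needleman-
# Wunsch with BLOSUM62 and affine gaps), plus percent-identity scoring
# with the 30% twilight-zone usability warning.

#' Construct a validated MSA object
#'
#' @param ids record identifiers, unique
#' @param aligned aligned strings of equal length (gap `-`)
#' @return object of class `msl_msa` with `ids`, `aligned`, `length`
#' @export
new_msa <- function(ids, aligned) {
  stopifnot(length(ids) == length(aligned), !anyDuplicated(ids))
  widths <- nchar(aligned)
  if (length(unique(widths)) > 1) {
    msl_stop("msl_validation_error", "aligned rows differ in length")
  }
  structure(list(ids = as.character(ids), aligned = as.character(aligned),
                 length = widths[1]),
            class = "msl_msa")
}

#' @export
print.msl_msa <- function(x, ...) {
  cat(sprintf("<msl_msa> %d sequence(s), %d column(s)\n",
              length(x$ids), x$length))
  for (i in seq_along(x$ids)) {
    s <- x$aligned[i]
    cat(sprintf("  %-15s %s%s\n", substr(x$ids[i], 1, 15),
                substr(s, 1, 50), if (nchar(s) > 50) "..." else ""))
  }
  invisible(x)
}

#' @keywords internal
ungap <- function(s) gsub("-", "", s, fixed = TRUE)

#' @keywords internal
msa_row <- function(msa, id) {
  i <- match(id, msa$ids)
  if (is.na(i)) msl_stop("msl_lookup_error", "id '%s' not in MSA", id)
  msa$aligned[i]
}

#' Align records with an external aligner
#'
#' Invokes `mafft` or `clustalo` as a subprocess (FASTA in, FASTA out),
#' validates that ungapping each output row recovers its input sequence,
#' and restores input record order.
#'
#' @param records list of [seq_record()] objects, at least two
#' @param tool `"mafft"` or `"clustalo"`
#' @return an `msl_msa`
#' @export
align_external <- function(records, tool = c("mafft", "clustalo")) {
  tool <- match.arg(tool)
  stopifnot(length(records) >= 2)
  exe <- Sys.which(tool)
  if (!nzchar(exe)) {
    msl_stop("msl_environment_error",
             "aligner '%s' not found on PATH; use the builtin aligner (--aligner builtin)",
             tool)
  }
  fin <- tempfile(fileext = ".fasta")
  fout <- tempfile(fileext = ".fasta")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  write_fasta(records, fin)
  args <- switch(tool,
                 mafft = c("--auto", "--quiet", fin),
                 clustalo = c("-i", fin, "--outfmt=fasta", "--force",
                              "-o", fout))
  err <- tempfile()
  status <- if (tool == "mafft") {
    system2(exe, args, stdout = fout, stderr = err)
  } else {
    system2(exe, args, stdout = NULL, stderr = err)
  }
  if (!identical(status, 0L)) {
    msl_stop("msl_tool_error", "%s exited with status %s: %s", tool,
             status, paste(readLines(err, warn = FALSE), collapse = " "))
  }
  out <- read_aligned_fasta(fout)
  validate_alignment(records, out, tool)
}

#' @keywords internal
read_aligned_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0) msl_stop("msl_parse_error", "no FASTA records in aligner output")
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  ends <- c(hdr[-1] - 1L, length(lines))
  aligned <- vapply(seq_along(hdr), function(k) {
    paste(lines[seq(hdr[k] + 1L, ends[k])], collapse = "")
  }, "")
  list(ids = ids, aligned = toupper(gsub("\\s", "", aligned)))
}

#' @keywords internal
validate_alignment <- function(records, out, tool) {
  in_ids <- vapply(records, `[[`, "", "id")
  pos <- match(in_ids, out$ids)
  if (anyNA(pos)) {
    msl_stop("msl_validation_error",
             "%s output is missing input id(s): %s", tool,
             paste(in_ids[is.na(pos)], collapse = ", "))
  }
  aligned <- out$aligned[pos]
  for (k in seq_along(records)) {
    if (ungap(aligned[k]) != records[[k]]$sequence) {
      msl_stop("msl_validation_error",
               "%s output row '%s' does not ungap to its input sequence",
               tool, in_ids[k])
    }
  }
  new_msa(in_ids, aligned)
}

# ---- built-in progressive aligner ------------------------------------------

#' @keywords internal
blosum62 <- local({
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

#' @keywords internal
kmer_distance <- function(a, b, k = 3L) {
  k <- min(k, nchar(a), nchar(b))
  kmers <- function(s) {
    n <- nchar(s) - k + 1L
    vapply(seq_len(n), function(i) substr(s, i, i + k - 1L), "")
  }
  ka <- table(kmers(a)); kb <- table(kmers(b))
  common <- intersect(names(ka), names(kb))
  shared <- sum(pmin(ka[common], kb[common]))
  1 - shared / min(sum(ka), sum(kb))
}

#' Profile-profile Needleman-Wunsch with affine gaps
#'
#' Aligns two gapped profiles (each a character vector of equal-length
#' rows).  Column-pair score is the mean BLOSUM62 score over all row
#' pairs, gap characters contributing zero.  A gap run of length L costs
#' `gap_open + gap_extend * (L - 1)`; terminal gaps are charged.
#'
#' @param prof_a,prof_b character vectors of aligned rows
#' @param gap_open,gap_extend gap penalties (negative scores)
#' @return list with `score`, `rows_a`, `rows_b` (rows after merging)
#' @export
nw_profile_align <- function(prof_a, prof_b, gap_open = -10,
                             gap_extend = -0.5) {
  S <- blosum62()
  letters_s <- rownames(S)
  freq <- function(prof) {
    mat <- do.call(rbind, strsplit(prof, ""))
    f <- matrix(0, nrow = length(letters_s), ncol = ncol(mat),
                dimnames = list(letters_s, NULL))
    for (r in seq_len(nrow(mat))) {
      hit <- match(mat[r, ], letters_s)
      ok <- which(!is.na(hit))
      for (c in ok) f[hit[c], c] <- f[hit[c], c] + 1
    }
    f / nrow(mat)
  }
  fa <- freq(prof_a); fb <- freq(prof_b)
  CS <- t(fa) %*% S %*% fb                     # mean column-pair score
  la <- ncol(fa); lb <- ncol(fb)

  NEG <- -1e9
  M <- matrix(NEG, la + 1, lb + 1)
  X <- matrix(NEG, la + 1, lb + 1)   # gap in B (consumes A column)
  Y <- matrix(NEG, la + 1, lb + 1)   # gap in A (consumes B column)
  ptrM <- matrix(0L, la + 1, lb + 1)
  ptrX <- matrix(0L, la + 1, lb + 1)
  ptrY <- matrix(0L, la + 1, lb + 1)
  M[1, 1] <- 0
  for (i in seq_len(la)) {
    X[i + 1, 1] <- gap_open + (i - 1) * gap_extend
    ptrX[i + 1, 1] <- if (i == 1) 1L else 2L
  }
  for (j in seq_len(lb)) {
    Y[1, j + 1] <- gap_open + (j - 1) * gap_extend
    ptrY[1, j + 1] <- if (j == 1) 1L else 3L
  }
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      cand <- c(M[i, j], X[i, j], Y[i, j])
      w <- which.max(cand)
      M[i + 1, j + 1] <- cand[w] + CS[i, j]
      ptrM[i + 1, j + 1] <- w
      cand <- c(M[i, j + 1] + gap_open, X[i, j + 1] + gap_extend,
                Y[i, j + 1] + gap_open)
      w <- which.max(cand)
      X[i + 1, j + 1] <- cand[w]
      ptrX[i + 1, j + 1] <- w
      cand <- c(M[i + 1, j] + gap_open, X[i + 1, j] + gap_open,
                Y[i + 1, j] + gap_extend)
      w <- which.max(cand)
      Y[i + 1, j + 1] <- cand[w]
      ptrY[i + 1, j + 1] <- w
    }
  }
  finals <- c(M[la + 1, lb + 1], X[la + 1, lb + 1], Y[la + 1, lb + 1])
  state <- which.max(finals)
  score <- finals[state]

  # Traceback into merged column lists.
  cols_a <- integer(0); cols_b <- integer(0)   # 0 = gap column
  i <- la; j <- lb
  while (i > 0 || j > 0) {
    if (state == 1L) {
      prev <- ptrM[i + 1, j + 1]
      cols_a <- c(i, cols_a); cols_b <- c(j, cols_b)
      i <- i - 1; j <- j - 1
    } else if (state == 2L) {
      prev <- ptrX[i + 1, j + 1]
      cols_a <- c(i, cols_a); cols_b <- c(0L, cols_b)
      i <- i - 1
    } else {
      prev <- ptrY[i + 1, j + 1]
      cols_a <- c(0L, cols_a); cols_b <- c(j, cols_b)
      j <- j - 1
    }
    state <- prev
  }
  expand <- function(prof, cols) {
    chars <- strsplit(prof, "")
    vapply(chars, function(cc) {
      paste(ifelse(cols == 0L, "-", cc[pmax(cols, 1L)]), collapse = "")
    }, "")
  }
  list(score = score,
       rows_a = expand(prof_a, cols_a),
       rows_b = expand(prof_b, cols_b))
}

#' Global pairwise alignment score and alignment (BLOSUM62, affine gaps)
#'
#' @param seq_a,seq_b unaligned amino-acid strings
#' @inheritParams nw_profile_align
#' @return list with `score`, `aligned_a`, `aligned_b`
#' @export
nw_align <- function(seq_a, seq_b, gap_open = -10, gap_extend = -0.5) {
  r <- nw_profile_align(seq_a, seq_b, gap_open, gap_extend)
  list(score = r$score, aligned_a = r$rows_a[1], aligned_b = r$rows_b[1])
}

#' Built-in progressive multiple alignment
#'
#' Pairwise k-mer distances (k = 3) feed a UPGMA guide tree (average
#' linkage; ties broken by lexicographic id order), and profiles are
#' merged bottom-up with [nw_profile_align()].  Fully deterministic.
#'
#' @param records list of [seq_record()] objects, at least two
#' @param gap_open,gap_extend affine gap penalties
#' @return an `msl_msa` with rows in input record order
#' @export
align_builtin <- function(records, gap_open = -10, gap_extend = -0.5) {
  if (length(records) < 2) {
    msl_stop("msl_contract_error", "need at least 2 sequences to align")
  }
  ids <- vapply(records, `[[`, "", "id")
  seqs <- vapply(records, `[[`, "", "sequence")
  ord <- order(ids)                      # lexicographic for deterministic ties
  ids_s <- ids[ord]; seqs_s <- seqs[ord]
  n <- length(ids_s)

  if (n == 2) {
    r <- nw_profile_align(seqs_s[1], seqs_s[2], gap_open, gap_extend)
    aligned <- c(r$rows_a, r$rows_b)
    names(aligned) <- ids_s
    return(new_msa(ids, unname(aligned[ids])))
  }

  D <- matrix(0, n, n, dimnames = list(ids_s, ids_s))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      D[i, j] <- D[j, i] <- kmer_distance(seqs_s[i], seqs_s[j])
    }
  }
  tree <- stats::hclust(stats::as.dist(D), method = "average")

  profiles <- lapply(seq_len(n), function(i) {
    p <- seqs_s[i]; names(p) <- ids_s[i]; p
  })
  merged <- vector("list", n - 1)
  for (step in seq_len(n - 1)) {
    get_prof <- function(idx) {
      if (idx < 0) profiles[[-idx]] else merged[[idx]]
    }
    pa <- get_prof(tree$merge[step, 1])
    pb <- get_prof(tree$merge[step, 2])
    r <- nw_profile_align(unname(pa), unname(pb), gap_open, gap_extend)
    prof <- c(r$rows_a, r$rows_b)
    names(prof) <- c(names(pa), names(pb))
    merged[[step]] <- prof
  }
  final <- merged[[n - 1]]
  new_msa(ids, unname(final[ids]))
}

#' Align sequence records
#'
#' Dispatch over the aligner selector used throughout the pipeline.
#'
#' @param records list of [seq_record()] objects
#' @param aligner `"mafft"`, `"clustalo"`, or `"builtin"`
#' @return an `msl_msa`
#' @export
align_records <- function(records, aligner = c("mafft", "clustalo",
                                               "builtin")) {
  aligner <- match.arg(aligner)
  if (aligner == "builtin") align_builtin(records)
  else align_external(records, aligner)
}

#' Pairwise percent identity of MSA rows
#'
#' identity(a, b) = 100 x (columns where a and b hold the same residue,
#' case-insensitive, both non-gap) / (columns where at least one of a, b
#' is non-gap).  Pairs below the twilight threshold trigger a warning:
#' annotation transfer is unreliable below ~30% identity.
#'
#' @param msa an `msl_msa`
#' @param twilight_threshold percent; default 30
#' @return object of class `msl_identity`: a symmetric percent matrix with
#'   `twilight_threshold` and `below_twilight` (data frame of flagged
#'   pairs) attributes
#' @export
pairwise_identity <- function(msa, twilight_threshold = 30) {
  n <- length(msa$ids)
  chars <- lapply(msa$aligned, function(s) strsplit(toupper(s), "")[[1]])
  m <- matrix(100, n, n, dimnames = list(msa$ids, msa$ids))
  flagged <- list()
  if (n >= 2) for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      a <- chars[[i]]; b <- chars[[j]]
      either <- a != "-" | b != "-"
      both <- a != "-" & b != "-"
      denom <- sum(either)
      val <- if (denom == 0) 0 else 100 * sum(both & a == b) / denom
      m[i, j] <- m[j, i] <- val
      if (val < twilight_threshold) {
        flagged[[length(flagged) + 1L]] <- data.frame(
          id_a = msa$ids[i], id_b = msa$ids[j], identity = val,
          stringsAsFactors = FALSE)
      }
    }
  }
  below <- if (length(flagged)) do.call(rbind, flagged) else
    data.frame(id_a = character(), id_b = character(),
               identity = numeric(), stringsAsFactors = FALSE)
  if (nrow(below) > 0) {
    msl_warn("%d sequence pair(s) below the %g%% twilight zone; annotation transfer may be unreliable",
             nrow(below), twilight_threshold)
  }
  structure(m, class = c("msl_identity", class(m)),
            twilight_threshold = twilight_threshold, below_twilight = below)
}
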