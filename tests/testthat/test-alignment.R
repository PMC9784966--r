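test_that("FASTA round-trips through write and read", {
  recs <- make_records(a = "MKVLAT", b = strrep("ACDEFGHIKLMNPQRSTVWY", 5))
  f <- tempfile(fileext = ".fasta")
  write_fasta(recs, f)
  back <- read_fasta(f)
  expect_equal(vapply(back, `[[`, "", "id"), c("a", "b"))
  expect_equal(vapply(back, `[[`, "", "sequence"),
               vapply(recs, `[[`, "", "sequence"))
  # 60-column wrap
  expect_true(all(nchar(readLines(f)) <= 60))
})

test_that("stop symbols are stripped with a warning, odd letters become X", {
  expect_warning(r <- seq_record("s", "MKV*"), "stop")
  expect_equal(r$sequence, "MKV")
  r2 <- seq_record("s2", "MKVJZ")
  expect_equal(r2$sequence, "MKVXX")
})

test_that("two identical sequences align gap-free", {
  m <- align_builtin(make_records(a = "ACDEFG", b = "ACDEFG"))
  expect_equal(m$aligned, c("ACDEFG", "ACDEFG"))
  expect_equal(m$length, 6)
})

test_that("builtin pairwise score equals the enumeration optimum", {
  aa <- setdiff(names(msaligmap:::CLUSTALX_CLASS), "X")
  set.seed(42)
  for (k in 1:6) {
    a <- paste(sample(aa, sample(4:7, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aa, sample(4:7, 1), replace = TRUE), collapse = "")
    expect_equal(nw_align(a, b)$score,
                 enumerate_alignment_optimum(a, b),
                 info = sprintf("%s vs %s", a, b))
  }
})

test_that("the documented two-sequence example reaches the optimum", {
  r <- nw_align("HEAGAWGHEE", "PAWHEAE")
  expect_equal(gsub("-", "", r$aligned_a), "HEAGAWGHEE")
  expect_equal(gsub("-", "", r$aligned_b), "PAWHEAE")
  expect_equal(r$score, enumerate_alignment_optimum("HEAGAWGHEE", "PAWHEAE"))
})

test_that("identical pairs in a 3-sequence set align gap-free to each other", {
  set.seed(7)
  aa <- setdiff(names(msaligmap:::CLUSTALX_CLASS), "X")
  for (k in 1:5) {
    base <- paste(sample(aa, 12, replace = TRUE), collapse = "")
    other <- paste(sample(aa, 9, replace = TRUE), collapse = "")
    m <- align_builtin(make_records(s1 = base, s2 = base, s3 = other))
    r1 <- m$aligned[m$ids == "s1"]
    r2 <- m$aligned[m$ids == "s2"]
    expect_identical(r1, r2)
  }
})

test_that("builtin alignment is deterministic", {
  recs <- make_records(x = "MKVLATRES", y = "MKVATRQS", z = "KVLATRES")
  m1 <- align_builtin(recs)
  m2 <- align_builtin(recs)
  expect_identical(m1, m2)
})

test_that("ungapping every builtin MSA row recovers its input", {
  set.seed(11)
  aa <- setdiff(names(msaligmap:::CLUSTALX_CLASS), "X")
  seqs <- vapply(1:4, function(i) {
    paste(sample(aa, sample(8:15, 1), replace = TRUE), collapse = "")
  }, "")
  names(seqs) <- paste0("r", 1:4)
  recs <- make_records(seqs)
  m <- align_builtin(recs)
  for (i in seq_along(recs)) {
    expect_equal(gsub("-", "", m$aligned[m$ids == recs[[i]]$id]),
                 recs[[i]]$sequence)
  }
})

test_that("single-record input is a contract error", {
  expect_error(align_builtin(make_records(a = "ACDEF")),
               class = "msl_contract_error")
})

test_that("external aligner wrapper validates and reorders output", {
  skip_if(Sys.which("mafft") == "", "mafft not on PATH")
  recs <- make_records(zz = "MKVLATRESLIM", aa = "MKVATRQSLIM",
                       mm = "KVLATRESLI")
  m <- align_external(recs, "mafft")
  expect_equal(m$ids, c("zz", "aa", "mm"))
  for (i in seq_along(recs)) {
    expect_equal(gsub("-", "", m$aligned[i]), recs[[i]]$sequence)
  }
})

test_that("a missing aligner executable is an environment error", {
  withr::with_envvar(c(PATH = tempdir()), {
    expect_error(align_external(make_records(a = "ACDEF", b = "ACDEF"),
                                "clustalo"),
                 class = "msl_environment_error")
  })
})

test_that("percent identity follows the stated formula", {
  m <- new_msa(c("a", "b"), c("AAAA--", "AA--TT"))
  p <- suppressWarnings(pairwise_identity(m))
  expect_equal(p["a", "b"], 100 * 2 / 6)

  m2 <- new_msa(c("a", "b"), c("AA--", "--TT"))
  p2 <- suppressWarnings(pairwise_identity(m2))
  expect_equal(p2["a", "b"], 0)

  m3 <- new_msa(c("a", "b"), c("ACDE", "ACDE"))
  p3 <- pairwise_identity(m3)
  expect_equal(p3["a", "b"], 100)
  expect_equal(diag(p3), c(a = 100, b = 100))
})

test_that("identity matrix is symmetric and permutation-equivariant", {
  m <- new_msa(c("a", "b", "c"), c("ACDEFG", "AC--FG", "TCDEFA"))
  p <- suppressWarnings(pairwise_identity(m))
  expect_equal(p, t(p))
  m_perm <- new_msa(c("c", "a", "b"), c("TCDEFA", "ACDEFG", "AC--FG"))
  p_perm <- suppressWarnings(pairwise_identity(m_perm))
  expect_equal(p_perm[c("a", "b", "c"), c("a", "b", "c")],
               p[c("a", "b", "c"), c("a", "b", "c")])
})

test_that("sub-twilight pairs trigger a warning and are listed", {
  m <- new_msa(c("a", "b"), c("AAAAAAAAAA", "TTTTTTTTTT"))
  expect_warning(p <- pairwise_identity(m), "twilight")
  expect_equal(nrow(attr(p, "below_twilight")), 1)
})
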