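test_that("column maps follow the row's gap pattern", {
  m <- new_msa(c("s"), "AC-DE")
  cm <- build_column_map(m, "s")
  expect_equal(cm$seq_to_col, c(0L, 1L, 3L, 4L))
  expect_equal(cm$col_to_seq, c(0L, 1L, NA, 2L, 3L))

  m2 <- new_msa("t", "ACDEFG")
  cm2 <- build_column_map(m2, "t")
  expect_equal(cm2$seq_to_col, 0:5)
  expect_error(build_column_map(m2, "nope"), class = "msl_lookup_error")
})

test_that("column maps round-trip on random gapped rows", {
  set.seed(123)
  for (k in 1:200) {
    n <- sample(3:30, 1)
    chars <- sample(c("A", "C", "D", "-"), n, replace = TRUE,
                    prob = c(0.3, 0.3, 0.2, 0.2))
    if (all(chars == "-")) chars[1] <- "A"
    m <- new_msa("r", paste(chars, collapse = ""))
    cm <- build_column_map(m, "r")
    expect_true(all(diff(cm$seq_to_col) > 0))
    expect_equal(cm$col_to_seq[cm$seq_to_col + 1L],
                 seq_along(cm$seq_to_col) - 1L)
    expect_equal(length(cm$seq_to_col), sum(chars != "-"))
  }
})

make_site <- function(author_numbers, classes,
                      structure_id = "1tst:A") {
  rec <- data.frame(
    comp_id = "ALA", author_number = author_numbers,
    insertion_code = "", chain_id = "A", partner_id = "LIG",
    interaction_class = classes, min_distance = 3.0,
    protein_atom = "CA", partner_atom = "X", flagged = FALSE,
    stringsAsFactors = FALSE)
  site <- parse_pdbsum_residue_list("", "hydrogen_bond",
                                    structure_id = structure_id)
  site$records <- rec
  site
}

simple_resmap <- function(n, start = 1L) {
  m <- data.frame(seq_index = seq_len(n) - 1L,
                  author_number = seq(start, length.out = n),
                  insertion_code = "",
                  one_letter = rep("A", n), stringsAsFactors = FALSE)
  class(m) <- c("msl_resmap", "data.frame")
  m
}

test_that("binding residues project through gapped alignments", {
  msa <- new_msa(c("1tst:A", "t1"), c("ACDE", "AC-E"))
  cm <- build_column_map(msa, "1tst:A")
  site <- make_site(3L, "hydrogen_bond")     # residue index 2 = D
  proj <- project_binding_site(site, simple_resmap(4), cm, msa)
  expect_length(proj$sites, 1)
  s <- proj$sites[[1]]
  expect_equal(s$column, 2L)
  expect_equal(s$per_record[["t1"]]$letter, "-")
  expect_equal(s$per_record[["1tst:A"]]$letter, "D")
})

test_that("records absent from the coordinates land in unmappable", {
  msa <- new_msa(c("1tst:A", "t1"), c("ACDE", "ACDE"))
  cm <- build_column_map(msa, "1tst:A")
  site <- make_site(c(2L, 99L), c("hydrogen_bond", "hydrogen_bond"))
  proj <- project_binding_site(site, simple_resmap(4), cm, msa)
  expect_length(proj$sites, 1)
  expect_equal(nrow(proj$unmappable), 1)
  expect_equal(proj$unmappable$author_number, 99L)
  # conservation of records: mapped + unmappable = total
  expect_equal(length(proj$sites) + nrow(proj$unmappable),
               nrow(site$records))
})

test_that("conservation classifies identical vs substituted (gaps count)", {
  msa <- new_msa(c("1tst:A", "t1", "t2"), c("SSS", "SCS", "SS-"))
  cm <- build_column_map(msa, "1tst:A")
  site <- make_site(1:3, rep("hydrogen_bond", 3))
  proj <- project_binding_site(site, simple_resmap(3), cm, msa)
  rep_ <- classify_conservation(proj$sites, proj$unmappable)
  statuses <- vapply(rep_$sites, `[[`, "", "status")
  expect_equal(statuses, c("identical", "substituted", "substituted"))
  expect_equal(rep_$summary$n_sites, 3)
  expect_equal(rep_$summary$n_identical, 1)
  expect_equal(rep_$summary$n_substituted, 2)
})

test_that("summary counts are recomputable from the sites", {
  msa <- new_msa(c("1tst:A", "t1"), c("ACDEFG", "ACDQFG"))
  cm <- build_column_map(msa, "1tst:A")
  site <- make_site(c(1L, 4L, 4L, 6L),
                    c("hydrogen_bond", "hydrogen_bond", "non_bonded",
                      "non_bonded"))
  proj <- project_binding_site(site, simple_resmap(6), cm, msa)
  rep_ <- classify_conservation(proj$sites, proj$unmappable)
  for (cc in rep_$summary$interaction_class) {
    sel <- Filter(function(s) s$interaction_class == cc, rep_$sites)
    cols <- vapply(sel, `[[`, 0L, "column")
    st <- vapply(sel, `[[`, "", "status")
    dedup <- !duplicated(cols)
    row <- rep_$summary[rep_$summary$interaction_class == cc, ]
    expect_equal(row$n_sites, sum(dedup))
    expect_equal(row$n_identical, sum(st[dedup] == "identical"))
  }
})

test_that("projection is invariant to MSA row order", {
  msa1 <- new_msa(c("1tst:A", "t1", "t2"), c("ACDE", "ACDE", "AQDE"))
  msa2 <- new_msa(c("t2", "1tst:A", "t1"), c("AQDE", "ACDE", "ACDE"))
  site <- make_site(1:4, rep("hydrogen_bond", 4))
  get_status <- function(msa) {
    cm <- build_column_map(msa, "1tst:A")
    proj <- project_binding_site(site, simple_resmap(4), cm, msa)
    vapply(classify_conservation(proj$sites)$sites, `[[`, "", "status")
  }
  expect_equal(get_status(msa1), get_status(msa2))
})

test_that("self-copies of a structure sequence are all identical sites", {
  msa <- new_msa(c("1tst:A", "c1", "c2"),
                 c("MKVLAT", "MKVLAT", "MKVLAT"))
  cm <- build_column_map(msa, "1tst:A")
  site <- make_site(1:6, rep(c("hydrogen_bond", "non_bonded"), 3))
  proj <- project_binding_site(site, simple_resmap(6), cm, msa)
  rep_ <- classify_conservation(proj$sites)
  expect_true(all(vapply(rep_$sites, `[[`, "", "status") == "identical"))
  expect_equal(sum(rep_$summary$n_substituted), 0)
})

test_that("secondary-structure tracks project with '-' at gap columns", {
  msa <- new_msa(c("s"), "A-AA")
  cm <- build_column_map(msa, "s")
  tr <- msaligmap:::new_sstrack("x:A", c("H", "H", "T"))
  expect_equal(project_track(tr, cm, 4L), "H-HT")

  msa2 <- new_msa("s", "AAA")
  cm2 <- build_column_map(msa2, "s")
  tr2 <- msaligmap:::new_sstrack("x:A", c("H", "E", " "))
  expect_equal(project_track(tr2, cm2, 3L), "HE ")

  tr_short <- msaligmap:::new_sstrack("x:A", c("H", "H"))
  expect_error(project_track(tr_short, cm2, 3L),
               class = "msl_contract_error")
})
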