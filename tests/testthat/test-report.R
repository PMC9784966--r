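# Shared fixture: 1 structure row + 2 targets, 3 binding columns
# (identical / substituted / identical), one of them in both classes.
report_fixture <- function() {
  msa <- new_msa(c("1tst:A", "t1", "t2"),
                 c("MKVLATRES", "MKVQATRES", "MKVLATRES"))
  cm <- build_column_map(msa, "1tst:A")
  rec <- data.frame(
    comp_id = c("LYS", "LEU", "LEU", "ARG"),
    author_number = c(2L, 4L, 4L, 7L), insertion_code = "",
    chain_id = "A", partner_id = "LIG",
    interaction_class = c("hydrogen_bond", "hydrogen_bond", "non_bonded",
                          "non_bonded"),
    min_distance = 3, protein_atom = "CA", partner_atom = "X",
    flagged = FALSE, stringsAsFactors = FALSE)
  site <- parse_pdbsum_residue_list("", "hydrogen_bond",
                                    structure_id = "1tst:A")
  site$records <- rec
  m <- data.frame(seq_index = 0:8, author_number = 1:9,
                  insertion_code = "", one_letter = strsplit("MKVLATRES", "")[[1]],
                  stringsAsFactors = FALSE)
  class(m) <- c("msl_resmap", "data.frame")
  proj <- project_binding_site(site, m, cm, msa)
  cons <- classify_conservation(proj$sites, proj$unmappable)
  track <- paste(c("H", "H", "H", "H", "T", "T", " ", " ", " "),
                 collapse = "")
  annotated_alignment(msa, tracks = list(`1tst:A` = track), cons)
}

test_that("stripping markup from the text view recovers the MSA rows", {
  ann <- report_fixture()
  txt <- render_text(ann, block_width = 4)
  lines <- strsplit(txt, "\n")[[1]]
  lines <- lines[seq_len(grep("Section 2", lines) - 1L)]
  for (i in seq_along(ann$msa$ids)) {
    id <- ann$msa$ids[i]
    rows <- grep(sprintf("^%s\\s", gsub("([:])", "\\\\\\1", id)), lines,
                 value = TRUE)
    got <- paste(sub("^\\S+\\s+", "", rows), collapse = "")
    expect_equal(got, ann$msa$aligned[i])
  }
})

test_that("text blocks honour the block width", {
  ann <- report_fixture()   # 9 columns
  txt <- render_text(ann, block_width = 4)
  headers <- grep("columns", strsplit(txt, "\n")[[1]], value = TRUE)
  expect_length(headers, 3)   # widths 4, 4, 1
  expect_match(headers[3], "columns 9-9")
})

test_that("class and status markers sit at the binding columns", {
  ann <- report_fixture()
  txt <- render_text(ann, block_width = 60)
  lines <- strsplit(txt, "\n")[[1]]
  id_w <- max(nchar(ann$msa$ids), 10L)     # marker prefix width
  strip <- function(x) substring(x, id_w + 2L)
  class_line <- strip(grep("^#class", lines, value = TRUE)[1])
  # columns (0-based) 1 -> h, 3 -> b (both classes), 6 -> n
  expect_equal(substr(class_line, 2, 2), "h")
  expect_equal(substr(class_line, 4, 4), "b")
  expect_equal(substr(class_line, 7, 7), "n")
  status_line <- strip(grep("^#status", lines, value = TRUE)[1])
  expect_equal(substr(status_line, 2, 2), "*")
  expect_equal(substr(status_line, 4, 4), "+")
  expect_equal(substr(status_line, 7, 7), "*")
})

test_that("an empty report renders 'no binding sites mapped'", {
  msa <- new_msa(c("a", "b"), c("ACDE", "ACDE"))
  ann <- annotated_alignment(msa)
  expect_match(render_text(ann), "no binding sites mapped")
  expect_match(render_html(ann), "no binding sites mapped")
  # no marker lines when there are no sites
  expect_false(any(grepl("^#class|^#status",
                         strsplit(render_text(ann), "\n")[[1]])))
})

test_that("HTML is well-formed and uses only defined style classes", {
  skip_if_not_installed("xml2")
  ann <- report_fixture()
  html <- render_html(ann)
  doc <- xml2::read_html(html)
  css <- xml2::xml_text(xml2::xml_find_first(doc, "//style"))
  used <- unlist(strsplit(
    xml2::xml_attr(xml2::xml_find_all(doc, "//*[@class]"), "class"), " "))
  defined <- regmatches(css, gregexpr("\\.([a-zA-Z_]+)", css))[[1]]
  defined <- sub("^\\.", "", defined)
  expect_true(all(setdiff(unique(used), "block") %in% defined))
})

test_that("section 2 has one cell per row per binding column with status classes", {
  skip_if_not_installed("xml2")
  ann <- report_fixture()
  doc <- xml2::read_html(render_html(ann))
  cells <- xml2::xml_find_all(doc, "//table//td")
  expect_length(cells, 3 * 3)     # 3 rows x 3 deduplicated columns
  classes <- xml2::xml_attr(cells, "class")
  expect_equal(sum(classes == "identical"), 3 * 2)
  expect_equal(sum(classes == "substituted"), 3 * 1)
})

test_that("stripping tags from HTML section 1 recovers the MSA rows", {
  skip_if_not_installed("xml2")
  ann <- report_fixture()
  doc <- xml2::read_html(render_html(ann))
  blocks <- xml2::xml_text(xml2::xml_find_all(doc, "//div[@class='block']"))
  text <- paste(blocks, collapse = "\n")
  lines <- strsplit(text, "\n")[[1]]
  for (i in seq_along(ann$msa$ids)) {
    id <- ann$msa$ids[i]
    rows <- lines[startsWith(lines, paste0(id, " "))]
    got <- paste(sub("^\\S+\\s+", "", rows), collapse = "")
    expect_equal(got, ann$msa$aligned[i])
  }
})

test_that("graded HTML shades substituted cells by match fraction", {
  skip_if_not_installed("xml2")
  ann <- report_fixture()
  doc <- xml2::read_html(render_html(ann, graded = TRUE))
  cells <- xml2::xml_find_all(doc, "//table//td[@class='substituted']")
  expect_true(all(grepl("rgba", xml2::xml_attr(cells, "style"))))
})

test_that("summary table covers per-structure and pooled scopes", {
  ann <- report_fixture()
  df <- summarize_conservation(ann$conservation)
  expect_setequal(unique(df$scope), c("1tst:A", "pooled"))
  pooled_hb <- df[df$scope == "pooled" &
                    df$interaction_class == "hydrogen_bond", ]
  expect_equal(pooled_hb$n_sites, 2)
  expect_equal(pooled_hb$n_identical, 1)
  pooled_nb <- df[df$scope == "pooled" &
                    df$interaction_class == "non_bonded", ]
  expect_equal(pooled_nb$n_sites, 2)
  expect_equal(pooled_nb$n_identical, 1)

  empty <- summarize_conservation(classify_conservation(list()))
  expect_true(all(empty$n_sites == 0))
})
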