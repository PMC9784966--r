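test_that("a donor/acceptor pair at 3.0 A is one hydrogen bond", {
  s <- parse_structure(ser_ligand_pdb())
  bs <- detect_contacts(s, "A", ligand_partner("LIG"))
  expect_equal(nrow(bs$records), 1)
  expect_equal(bs$records$interaction_class, "hydrogen_bond")
  expect_equal(bs$records$min_distance, 3.0, tolerance = 1e-3)
  expect_equal(bs$records$protein_atom, "OG")
})

test_that("an untyped carbon pair at 3.5 A is one non-bonded contact", {
  s <- parse_structure(ala_cb_ligand_pdb())
  bs <- detect_contacts(s, "A", ligand_partner("LIG"))
  expect_equal(nrow(bs$records), 1)
  expect_equal(bs$records$interaction_class, "non_bonded")
  expect_equal(bs$records$min_distance, 3.5, tolerance = 1e-3)
})

test_that("a far ligand yields an empty binding site, not an error", {
  toy <- make_toy_complex(6, "extended",
                          ligand_atoms = list(list(
                            element = "O", name = "O1", anchor_residue = 3,
                            anchor_atom = "N", offset = c(0, 0, 20))))
  s <- parse_structure(toy$pdb_text)
  bs <- detect_contacts(s, "A", ligand_partner("LIG"))
  expect_equal(nrow(bs$records), 0)
  expect_equal(nrow(toy$expected_site$records), 0)
})

test_that("missing partners raise classed lookup errors", {
  s <- parse_structure(minimal_ala_pdb())
  expect_error(detect_contacts(s, "A", ligand_partner("NDP")),
               class = "msl_lookup_error")
  expect_error(detect_contacts(s, "A", dna_partner()),
               class = "msl_lookup_error")
})

test_that("DNA mode pools all DNA chains as the partner", {
  s <- parse_structure(dna_complex_pdb())
  bs <- detect_contacts(s, "A", dna_partner())
  expect_gt(nrow(bs$records), 0)
  expect_true(all(bs$records$author_number == 1))
  expect_equal(bs$partner_label, "DNA")
})

test_that("detected contacts equal the closed-form fixture ground truth", {
  toy <- make_toy_complex(
    10, "extended",
    ligand_atoms = list(
      list(element = "O", name = "O1", anchor_residue = 5,
           anchor_atom = "N", offset = c(0, 0, 3.0)),
      list(element = "C", name = "C2", anchor_residue = 8,
           anchor_atom = "CB", offset = c(0, 0, -3.6))))
  s <- parse_structure(toy$pdb_text)
  bs <- detect_contacts(s, "A", ligand_partner("LIG"))
  expect_equal(binding_site_contact_set(bs),
               binding_site_contact_set(toy$expected_site))
  expect_equal(bs$records$min_distance, toy$expected_site$records$min_distance,
               tolerance = 2e-3)
})

test_that("detect_contacts equals the brute-force oracle on random toys", {
  for (seed in 1:40) {
    set.seed(seed)
    toy <- make_random_complex(n_residues = sample(3:8, 1),
                               n_ligand_atoms = sample(1:10, 1),
                               seed = seed)
    s <- parse_structure(toy$pdb_text)
    expect_equal(
      binding_site_contact_set(detect_contacts(s, "A", ligand_partner("LIG"))),
      brute_force_contact_set(s, "A", ligand_partner("LIG")),
      info = paste("seed", seed))
  }
})

test_that("criteria are monotone: wider windows never drop records", {
  for (seed in c(3, 11, 27)) {
    toy <- make_random_complex(5, 8, seed = seed)
    s <- parse_structure(toy$pdb_text)
    base <- detect_contacts(s, "A", ligand_partner("LIG"),
                            contact_criteria())
    wider <- detect_contacts(s, "A", ligand_partner("LIG"),
                             contact_criteria(nonbonded_max = 4.5))
    expect_true(all(binding_site_contact_set(base) %in%
                      binding_site_contact_set(wider)))
    narrow <- detect_contacts(s, "A", ligand_partner("LIG"),
                              contact_criteria(hbond_max = 3.0))
    hb <- function(x) grep("hydrogen_bond", binding_site_contact_set(x),
                           value = TRUE)
    expect_true(all(hb(narrow) %in% hb(base)))
  }
})

test_that("contacts are invariant under rigid-body motion", {
  toy <- make_random_complex(6, 8, seed = 5)
  s <- parse_structure(toy$pdb_text)
  ref <- binding_site_contact_set(detect_contacts(s, "A",
                                                  ligand_partner("LIG")))
  rot <- random_rotation(99)
  s2 <- transform_structure(s, rot, c(11.2, -4.5, 7.9))
  moved <- binding_site_contact_set(detect_contacts(s2, "A",
                                                    ligand_partner("LIG")))
  expect_identical(ref, moved)
})

test_that("PDBsum-style residue lists parse verbatim", {
  bs <- parse_pdbsum_residue_list("GLY 15(A)\nSER 16(A)", "hydrogen_bond",
                                  structure_id = "1abc:A")
  expect_equal(nrow(bs$records), 2)
  expect_true(all(bs$records$interaction_class == "hydrogen_bond"))
  expect_true(all(is.na(bs$records$min_distance)))
  expect_equal(bs$records$author_number, c(15L, 16L))

  bs2 <- parse_pdbsum_residue_list("SER 52A(B)", "non_bonded")
  r <- bs2$records
  expect_equal(unname(unlist(r[1, c("comp_id", "author_number",
                                    "insertion_code", "chain_id")])),
               c("SER", "52", "A", "B"))

  expect_equal(nrow(parse_pdbsum_residue_list("", "non_bonded")$records), 0)
  expect_error(parse_pdbsum_residue_list("SER A(", "non_bonded"),
               class = "msl_parse_error")
})

test_that("merged binding sites deduplicate (residue, class) pairs", {
  a <- parse_pdbsum_residue_list("GLY 15(A)\nSER 16(A)", "hydrogen_bond")
  b <- parse_pdbsum_residue_list("SER 16(A)\nTHR 17(A)", "hydrogen_bond")
  m <- merge_binding_sites(a, b)
  expect_equal(nrow(m$records), 3)
  expect_equal(m$records$author_number, c(15L, 16L, 17L))
})
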