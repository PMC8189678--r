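# Hand-written miniature mmCIF files exercising the normalization rules.

write_cif_fixture <- function(lines) {
  path <- tempfile(fileext = ".cif")
  writeLines(lines, path)
  path
}

atom_line <- function(group, id, atom, comp, chain, seq, x, y, z,
                      entity = "1", label_seq = seq, ins = "?") {
  sprintf("%s %d %s \"%s\" . %s %s %s %s %s %.3f %.3f %.3f 1.00 %s %s 1",
          group, id, substr(atom, 1, 1), atom, comp, chain, entity,
          label_seq, ins, x, y, z, seq, chain)
}

cif_header <- c(
  "data_1TST",
  "_entry.id 1TST",
  "_refine.ls_d_res_high 2.50",
  "_pdbx_database_status.recvd_initial_deposition_date 2019-06-01",
  "loop_",
  "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
  "_atom_site.label_atom_id", "_atom_site.label_alt_id",
  "_atom_site.label_comp_id", "_atom_site.label_asym_id",
  "_atom_site.label_entity_id", "_atom_site.label_seq_id",
  "_atom_site.pdbx_PDB_ins_code",
  "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
  "_atom_site.occupancy", "_atom_site.auth_seq_id",
  "_atom_site.auth_asym_id", "_atom_site.pdbx_PDB_model_num")

# three C1'-only pseudo-nucleotides is enough for parsing-level tests
simple_res <- function(id0, comp, chain, seq, z, label_seq = seq) {
  c(atom_line("ATOM", id0, "C1'", comp, chain, seq, 0, 0, z, label_seq = label_seq),
    atom_line("ATOM", id0 + 1, "O4'", comp, chain, seq, 1.4, 0, z, label_seq = label_seq))
}

test_that("author numbering offset by a thousand is renumbered from one", {
  path <- write_cif_fixture(c(cif_header,
                              simple_res(1, "A", "A", "1001", 0, "1"),
                              simple_res(3, "C", "A", "1002", 4, "2"),
                              simple_res(5, "G", "A", "1003", 8, "3")))
  ch <- parse_mmcif(path)[[1]]
  expect_identical(vapply(ch$residues, `[[`, integer(1), "index"), 1:3)
  expect_identical(vapply(ch$residues, `[[`, character(1), "auth_label"),
                   c("1001", "1002", "1003"))
  expect_identical(chain_sequence(ch), "ACG")
  expect_equal(ch$resolution, 2.5)
  expect_identical(ch$release_date, "2019-06-01")
})

test_that("waters, ions and appended non-polymer ligands never become residues", {
  path <- write_cif_fixture(c(
    cif_header,
    simple_res(1, "A", "A", "1", 0),
    simple_res(3, "C", "A", "2", 4),
    simple_res(5, "G", "A", "3", 8),
    simple_res(7, "U", "A", "4", 12),
    # free GTP marked non-polymer, appended to the chain
    atom_line("HETATM", 9, "C1'", "GTP", "A", "101", 0, 0, 50, label_seq = "."),
    # water and a magnesium ion
    atom_line("HETATM", 10, "O", "HOH", "A", "201", 9, 9, 9, label_seq = "."),
    atom_line("HETATM", 11, "MG", "MG", "A", "202", 8, 8, 8, label_seq = ".")))
  expect_message(ch <- parse_mmcif(path)[[1]], "removed ligand GTP")
  expect_length(ch$residues, 4L)
  expect_identical(chain_sequence(ch), "ACGU")
})

test_that("unresolved polymer positions come from entity_poly_seq, in order", {
  path <- write_cif_fixture(c(
    cif_header,
    simple_res(1, "A", "A", "10", 0, "1"),
    simple_res(3, "C", "A", "11", 4, "2"),
    simple_res(5, "U", "A", "13", 12, "4"),
    "loop_",
    "_entity_poly_seq.entity_id", "_entity_poly_seq.num",
    "_entity_poly_seq.mon_id",
    "1 1 A", "1 2 C", "1 3 G", "1 4 U"))
  ch <- parse_mmcif(path)[[1]]
  expect_identical(chain_sequence(ch), "AC-U")
  expect_false(ch$residues[[3]]$resolved)
  expect_identical(ch$residues[[3]]$nt_code, "-")
  expect_identical(ch$residues[[3]]$parent_base, "G")
  expect_identical(vapply(ch$residues, `[[`, integer(1), "index"), 1:4)
})

test_that("insertion-coded and negative author labels normalize in file order", {
  path <- write_cif_fixture(c(
    cif_header,
    simple_res(1, "A", "A", "10", 0),
    c(atom_line("ATOM", 3, "C1'", "C", "A", "10", 0, 0, 4, ins = "A"),
      atom_line("ATOM", 4, "O4'", "C", "A", "10", 1.4, 0, 4, ins = "A")),
    c(atom_line("ATOM", 5, "C1'", "G", "A", "10", 0, 0, 8, ins = "B"),
      atom_line("ATOM", 6, "O4'", "G", "A", "10", 1.4, 0, 8, ins = "B")),
    simple_res(7, "U", "A", "11", 12)))
  ch <- parse_mmcif(path)[[1]]
  expect_identical(vapply(ch$residues, `[[`, character(1), "auth_label"),
                   c("10", "10A", "10B", "11"))
  expect_identical(vapply(ch$residues, `[[`, integer(1), "index"), 1:4)
})

test_that("normalize_numbering is idempotent and rejects duplicate labels", {
  ch <- make_test_helix(n = 4)
  expect_identical(normalize_numbering(ch), ch)
  ch$residues[[2]]$auth_label <- "7"
  ch$residues[[3]]$auth_label <- "7"
  expect_error(normalize_numbering(ch), "duplicate author labels.*7")
})

test_that("negative author numbering keeps polymer order", {
  ch <- make_test_helix(n = 4)
  labs <- c("-2", "-1", "0", "1")
  for (i in 1:4) ch$residues[[i]]$auth_label <- labs[[i]]
  ch2 <- normalize_numbering(ch)
  expect_identical(vapply(ch2$residues, `[[`, integer(1), "index"), 1:4)
  expect_identical(vapply(ch2$residues, `[[`, character(1), "auth_label"),
                   labs)
})

test_that("chains without nucleotides are skipped with a warning", {
  path <- write_cif_fixture(c(
    cif_header,
    simple_res(1, "A", "A", "1", 0),
    simple_res(3, "C", "A", "2", 4),
    # a protein-like chain B: no ribonucleotides at all
    atom_line("ATOM", 5, "CA", "ALA", "B", "1", 0, 0, 0, entity = "2",
              label_seq = "1"),
    atom_line("ATOM", 6, "CA", "GLY", "B", "2", 2, 0, 0, entity = "2",
              label_seq = "2")))
  expect_warning(chains <- parse_mmcif(path), "no nucleotides")
  expect_length(chains, 1L)
  expect_identical(chains[[1]]$chain_id, "A")
})

test_that("strip_ligands identity and all-ligand boundary cases", {
  ch <- make_test_helix(n = 3)
  expect_identical(strip_ligands(ch), ch)
  for (i in seq_along(ch$residues)) {
    ch$residues[[i]]$comp_id <- "SO4"
    ch$residues[[i]]$group <- "HETATM"
  }
  expect_message(stripped <- strip_ligands(ch), "removed ligand")
  expect_length(stripped$residues, 0L)
})

test_that("modified-base mapping folds parents and flags the unknown", {
  expect_identical(map_modified_base("G"),
                   list(parent_base = "G", is_modified = FALSE))
  expect_identical(map_modified_base("PSU"),
                   list(parent_base = "U", is_modified = TRUE))
  expect_identical(map_modified_base("5MC"),
                   list(parent_base = "C", is_modified = TRUE))
  expect_identical(map_modified_base("XYZ"),
                   list(parent_base = "N", is_modified = TRUE))
  expect_error(map_modified_base(""), "non-empty")
})

test_that("modified residues carry lowercase parent nt_codes through parsing", {
  path <- write_cif_fixture(c(cif_header,
                              simple_res(1, "A", "A", "1", 0),
                              simple_res(3, "PSU", "A", "2", 4),
                              simple_res(5, "G", "A", "3", 8)))
  ch <- parse_mmcif(path)[[1]]
  expect_identical(chain_sequence(ch), "AuG")
  expect_true(ch$residues[[2]]$is_modified)
  expect_identical(ch$residues[[2]]$parent_base, "U")
})

test_that("write_mmcif/parse_mmcif round-trip preserves chains field-wise", {
  ch <- make_test_helix(n = 5, noise = 0.05, seed = 21L)
  p1 <- tempfile(fileext = ".cif")
  write_mmcif(ch, p1)
  ch1 <- parse_mmcif(p1)[[1]]
  p2 <- tempfile(fileext = ".cif")
  write_mmcif(ch1, p2)
  ch2 <- parse_mmcif(p2)[[1]]
  expect_identical(chain_fields(ch1), chain_fields(ch2))
  # coordinates survive the second trip exactly (fixed-precision writer)
  expect_identical(ch1$residues[[3]]$atoms, ch2$residues[[3]]$atoms)
})
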