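# End-to-end store fixtures: two synthetic chains, one mapped to a family
# with a toy alignment, one unmapped.

build_fixture_store <- function(out_path = NULL, fill = TRUE) {
  ch1 <- make_test_helix(n = 6, sequence = "ACGUAC", seed = 1L)
  ch1$mapping <- list(family = "RF00001", start = 1L, end = 6L,
                      inferred = FALSE)
  # residue 3 unresolved in 3D
  ch1$residues[[3]]$atoms <- NULL
  ch1$residues[[3]]$resolved <- FALSE
  ch1$residues[[3]]$nt_code <- "-"
  ch2 <- make_helix_mmcif(helix_spec(n_residues = 4, sequence = "GGCC",
                                     seed = 2L),
                          structure_id = "2SYN", resolution = 3.1,
                          release_date = "2021-03-02")
  d1 <- annotate_chain(ch1)
  d2 <- annotate_chain(ch2)
  # pretend residue 3 of chain 1 is unresolved in 3D
  seq3d <- "AC-UAC"
  aln <- make_toy_alignment(
    toy_msa_spec(4, "ACGUAC", deletion_rate = 0, insertion_rate = 0,
                 substitution_rate = 0.2, seed = 5L),
    chain_sequence = seq3d, chain_name = "1SYN_A")
  pssm <- compute_pssm(aln)
  pos <- fill_missing(remap(seq3d, aln[["1SYN_A"]]), pssm, enabled = fill)
  build_store(list(ch1, ch2), list(d1, d2), list(pos, NULL),
              pssms = list(RF00001 = pssm), out_path = out_path)
}

test_that("store tables have the expected shapes and linkage", {
  store <- build_fixture_store()
  expect_identical(nrow(store$chains), 2L)
  expect_identical(nrow(store$nucleotides), 10L)  # L1 + L2
  expect_identical(nrow(store$families), 1L)
  expect_identical(store$families$n_columns,
                   nrow(store$align_columns))
  nt1 <- store$nucleotides[store$nucleotides$chain_key ==
                             "1SYN|A|RF00001", ]
  expect_identical(nt1$index, 1:6)
  # mapped nucleotides carry PSSM frequencies; unmapped chain has nulls
  expect_false(anyNA(nt1$freq_A))
  nt2 <- store$nucleotides[store$nucleotides$chain_key ==
                             "2SYN|A|unmapped", ]
  expect_true(all(is.na(nt2$freq_A)))
  expect_true(all(is.na(nt2$alignment_column)))
  # paired defaults to 0 (not null)
  expect_true(all(nt1$paired == 0L))
})

test_that("consensus fill labels the alignment field but keeps the gap", {
  store <- build_fixture_store()
  nt1 <- store$nucleotides[store$nucleotides$chain_key ==
                             "1SYN|A|RF00001", ]
  expect_identical(nt1$nt_code[3], "-")
  expect_true(nt1$nt_align_code[3] %in% c("A", "C", "G", "U"))
  unfilled <- build_fixture_store(fill = FALSE)
  nt1u <- unfilled$nucleotides[unfilled$nucleotides$chain_key ==
                                 "1SYN|A|RF00001", ]
  expect_identical(nt1u$nt_align_code[3], "-")
})

test_that("store dump is idempotent and read back loss-free", {
  p1 <- tempfile(fileext = ".sql")
  p2 <- tempfile(fileext = ".sql")
  build_fixture_store(out_path = p1)
  build_fixture_store(out_path = p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
  store <- build_fixture_store()
  rt <- read_store(p1)
  for (tab in c("chains", "families", "align_columns", "nucleotides")) {
    expect_equal(as.data.frame(rt[[tab]]), as.data.frame(store[[tab]]),
                 tolerance = 0, info = tab)
  }
})

test_that("CSV export round-trips field-wise including null vs zero", {
  store <- build_fixture_store()
  dir <- tempfile("csv")
  files <- export_csv(store, dir)
  expect_length(files, 2L)
  for (ck in store$chains$chain_key) {
    f <- file.path(dir, paste0(gsub("[|]", "_", ck), ".csv"))
    got <- read_chain_csv(f)
    want <- store$nucleotides[store$nucleotides$chain_key == ck,
                              setdiff(names(store$nucleotides), "chain_key")]
    rownames(want) <- NULL
    expect_equal(got, want, info = ck)
    # null (NA) and numeric zero are distinguishable after the round-trip
    expect_identical(is.na(got$freq_A), is.na(want$freq_A))
  }
})

test_that("store queries compose date, resolution and family filters", {
  store <- build_fixture_store()
  expect_identical(nrow(query_chains(store)), 2L)
  expect_identical(query_chains(store, resolution_max = 2.5)$structure_id,
                   "1SYN")
  expect_identical(query_chains(store,
                                released_before = "2021-01-01")$structure_id,
                   "1SYN")  # strict earlier-than
  expect_identical(nrow(query_chains(store,
                                     released_before = "2020-01-15")), 0L)
  expect_identical(query_chains(store, family = "RF00001")$structure_id,
                   "1SYN")
  expect_identical(nrow(query_chains(store, resolution_max = 2.5,
                                     family = "RF00001",
                                     released_before = "2020-02-01")), 1L)
  # empty selection exports nothing, with a notice
  expect_message(files <- export_csv(store, tempfile("none"),
                                     resolution_max = 0.5),
                 "no chains match")
  expect_length(files, 0L)
})

test_that("copies of one chain mapped to two families coexist in the store", {
  ch <- make_test_helix(n = 6, sequence = "ACGUAC")
  c1 <- truncate_chain(ch, "RF00001", 1, 3)
  c2 <- truncate_chain(ch, "RF00002", 4, 6)
  store <- build_store(list(c1, c2),
                       list(annotate_chain(c1), annotate_chain(c2)))
  expect_identical(store$chains$structure_id, c("1SYN", "1SYN"))
  expect_identical(sort(store$chains$family), c("RF00001", "RF00002"))
  expect_identical(store$chains$length, c(3L, 3L))
})

test_that("referential integrity violations abort the build", {
  store <- build_fixture_store()
  store$nucleotides$chain_key[1] <- "9ZZZ|A|unmapped"
  expect_error(rnaforge:::.check_store(store), "9ZZZ")
})

test_that("external annotations populate paired, pair_type and form labels", {
  ch <- make_test_helix(n = 4)
  d <- annotate_chain(ch)
  ann_file <- tempfile(fileext = ".json")
  jsonlite::write_json(list(
    pairs = data.frame(chain1 = c("A", "A", "A"), index1 = c(1L, 2L, 4L),
                       chain2 = c("A", "B", "A"), index2 = c(3L, 7L, 1L),
                       lw = c("cWW", "tHS", "n/a"),
                       stringsAsFactors = FALSE),
    forms = data.frame(chain = "A", index = 2L, form = "A",
                       stringsAsFactors = FALSE)),
    ann_file, dataframe = "rows", auto_unbox = TRUE)
  out <- ingest_external_annotation(d, ann_file, chain_id = "A")
  # intra-chain pair is symmetric
  expect_identical(out$paired[1], 3L)
  expect_identical(out$paired[3], 1L)
  expect_identical(out$pair_type[3], "cWW")
  # inter-chain: label recorded, paired stays 0
  expect_identical(out$paired[2], 0L)
  expect_identical(out$pair_type[2], "tHS")
  # non-Leontis-Westhof interaction goes to the catch-all group
  expect_identical(out$pair_type[4], "other")
  expect_identical(out$form_label, c("none", "A", "none", "none"))
  # residue 1 got a second interaction: labels accumulate, paired keeps
  # the first intra-chain partner
  expect_identical(out$pair_type[1], "cWW,other")
  expect_identical(out$paired[1], 3L)
  expect_identical(out$paired[4], 1L)
})

test_that("absent or malformed annotation files behave as documented", {
  d <- annotate_chain(make_test_helix(n = 3))
  out <- ingest_external_annotation(d, NULL)
  expect_true(all(out$paired == 0L))
  expect_true(all(is.na(out$pair_type)))
  expect_true(all(out$form_label == "none"))
  bad <- tempfile(fileext = ".json")
  writeLines("{not json", bad)
  expect_error(ingest_external_annotation(d, bad), "malformed")
  # out-of-range residue: warning, field untouched
  oob <- tempfile(fileext = ".json")
  jsonlite::write_json(list(pairs = data.frame(
    chain1 = "A", index1 = 9L, chain2 = "A", index2 = 1L, lw = "cWW")),
    oob, dataframe = "rows", auto_unbox = TRUE)
  expect_warning(out2 <- ingest_external_annotation(d, oob, "A"),
                 "outside chain")
  expect_identical(out2$paired[1], 0L)  # whole entry left at defaults
  expect_true(is.na(out2$pair_type[1]))
})
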