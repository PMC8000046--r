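test_that("annotation tables parse in file order with dialect options honoured", {
  tsv <- write_fixture_tsv(data.frame(
    genome_id = c("gA", "gA", "gB"),
    protein_id = c("p1", "p2", "p3"),
    family = c("GH5", "GH5_7", "PL1"),
    ec = c("3.2.1.4", "3.2.1.4;3.2.1.21", ""),
    note = c("x", "y", "z"),              # unknown extra column is ignored
    stringsAsFactors = FALSE
  ), name = "ann.tsv")
  rec <- read_annotations(tsv)
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$genome_id, c("gA", "gA", "gB"))
  expect_equal(rec$family, c("GH5", "GH5", "PL1"))
  expect_equal(rec$subfamily, c(NA, "GH5_7", NA))
  expect_equal(rec$ec_labels[[1]], "3.2.1.4")
  expect_length(rec$ec_labels[[2]], 2L)
  expect_length(rec$ec_labels[[3]], 0L)

  # custom delimiter
  tsv2 <- write_fixture_tsv(data.frame(genome_id = "g", protein_id = "p",
                                       family = "GH3", ec = "3.2.1.4|3.2.1.21"),
                            name = "ann2.tsv")
  rec2 <- read_annotations(tsv2, ec_delim = "|")
  expect_equal(rec2$ec_labels[[1]], c("3.2.1.4", "3.2.1.21"))
})

test_that("well-formed files of N rows yield exactly N records", {
  for (seed in 1:5) {
    rows <- random_fixture(seed)$rows
    rows <- rows[nzchar(rows$ec), , drop = FALSE]
    path <- write_fixture_tsv(rows, name = sprintf("ann_n_%d.tsv", seed))
    expect_equal(nrow(read_annotations(path)), nrow(rows))
  }
})

test_that("malformed annotation input is rejected with named diagnostics", {
  bad <- write_fixture_tsv(data.frame(genome_id = c("gA", "gA"),
                                      protein_id = c("p1", "p2"),
                                      family = c("GH5", "XX9"),
                                      ec = c("3.2.1.4", "1.1.1.1")),
                           name = "bad_fam.tsv")
  expect_error(read_annotations(bad), "row 2.*XX9")

  no_col <- write_fixture_tsv(data.frame(genome_id = "g", protein_id = "p",
                                         family = "GH5"),
                              name = "no_ec.tsv")
  expect_error(read_annotations(no_col), "required column")

  hdr_only <- file.path(tempdir(), "empty_ann.tsv")
  writeLines("genome_id\tprotein_id\tfamily\tec", hdr_only)
  expect_warning(rec <- read_annotations(hdr_only), "no data rows")
  expect_equal(nrow(rec), 0L)
})

test_that("comment lines are skipped on read", {
  path <- file.path(tempdir(), "commented.tsv")
  writeLines(c("# provenance note",
               "genome_id\tprotein_id\tfamily\tec",
               "gA\tp1\tGH5\t3.2.1.4"), path)
  expect_equal(nrow(read_annotations(path)), 1L)
})

test_that("substrate maps validate entries and reject unknown tokens and duplicates", {
  ok <- write_fixture_tsv(data.frame(ec_pattern = c("3.2.1.4", "3.2.1.8"),
                                     family_pattern = c("*", "*"),
                                     substrates = c("cellulose", "xylan")),
                          name = "map_ok.tsv")
  map <- read_substrate_map(ok)
  expect_s3_class(map, "substrate_map")
  expect_equal(map$substrates[[2]], "xylan")

  granite <- write_fixture_tsv(data.frame(ec_pattern = "3.2.1.4",
                                          family_pattern = "*",
                                          substrates = "cellulose,granite"),
                               name = "map_granite.tsv")
  expect_error(read_substrate_map(granite), "granite")

  dup <- write_fixture_tsv(data.frame(ec_pattern = c("3.2.1.4", "3.2.1.4"),
                                      family_pattern = c("*", "*"),
                                      substrates = c("cellulose", "xylan")),
                           name = "map_dup.tsv")
  expect_error(read_substrate_map(dup), "duplicate")
})

test_that("the shipped default map loads and covers all four substrates", {
  map <- default_substrate_map()
  expect_s3_class(map, "substrate_map")
  expect_setequal(unique(unlist(map$substrates)), SUBSTRATES)
  expect_gte(nrow(map), 40L)
})

test_that("assembly metadata resolves n50 from any of its three sources", {
  dir <- file.path(tempdir(), "asm")
  dir.create(dir, showWarnings = FALSE)
  writeLines(c(">c1", strrep("A", 50), ">c2", strrep("C", 40),
               ">c3", strrep("G", 30), ">c4", strrep("T", 20),
               ">c5", strrep("A", 10)),
             file.path(dir, "ACC3.fasta"))
  tsv <- write_fixture_tsv(data.frame(
    species_taxid = c("t1", "t2", "t3"),
    accession = c("ACC1", "ACC2", "ACC3"),
    coverage = c(10, 20, 30),
    n50 = c(50000, NA, NA),
    contig_lengths = c("", "100,80,20", ""),
    stringsAsFactors = FALSE
  ), name = "asm.tsv")
  asm <- read_assembly_metadata(tsv, fasta_dir = dir)
  expect_equal(asm$n50, c(50000, 100, 40))
  expect_equal(asm$contig_lengths[[3]], c(50, 40, 30, 20, 10))

  no_src <- write_fixture_tsv(data.frame(species_taxid = "t", accession = "NOPE",
                                         coverage = 5),
                              name = "asm_bad.tsv")
  expect_error(read_assembly_metadata(no_src, fasta_dir = dir), "NOPE")
  expect_error(read_assembly_metadata(no_src), "NOPE")
})

test_that("missing coverage downgrades to zero with a warning", {
  tsv <- write_fixture_tsv(data.frame(species_taxid = "t", accession = "A1",
                                      coverage = NA, n50 = 100),
                           name = "asm_cov.tsv")
  expect_warning(asm <- read_assembly_metadata(tsv), "coverage")
  expect_equal(asm$coverage, 0)
})

test_that("profile tables round-trip bit-exactly through TSV", {
  fx <- random_fixture(11)
  prof <- score_genomes(extract_observations(fixture_records(fx$rows)),
                        fixture_map(fx$map_df))
  path <- file.path(tempdir(), "profiles_rt.tsv")
  write_profiles(prof, path)
  back <- read_profiles(path)
  expect_identical(back$genome_id, prof$genome_id)
  for (col in setdiff(names(prof), "genome_id")) {
    expect_identical(back[[col]], prof[[col]], label = col)
  }
})
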