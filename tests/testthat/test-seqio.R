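test_that("header grammar extracts accession, ontology and organism", {
  h <- parse_fasta_header(
    "ACZ58378.1 glyphosate oxidoreductase [Ochrobactrum sp. G-1]")
  expect_equal(h$accession, "ACZ58378.1")
  expect_equal(h$ontology_raw, "glyphosate oxidoreductase")
  expect_equal(h$organism, "Ochrobactrum sp. G-1")

  # no bracketed organism -> empty organism
  h2 <- parse_fasta_header("WP_0001.1 FAD-binding oxidoreductase")
  expect_equal(h2$organism, "")
  expect_equal(h2$ontology_raw, "FAD-binding oxidoreductase")

  # organism is the LAST balanced bracket span
  h3 <- parse_fasta_header("X1 protein [fragment] name [Escherichia coli]")
  expect_equal(h3$organism, "Escherichia coli")
})

test_that("annotated FASTA reading populates records and taxonomy", {
  fam <- simulate_family(simulation_config(n_sequences = 30, n_clades = 3,
                                           seed = 5))
  f <- tempfile(fileext = ".fa")
  write_fasta(fam$records, f)
  tax <- fam$taxonomy
  rec <- read_annotated_fasta(f, taxonomy = tax)
  truth <- fam$truth$sequences

  expect_equal(nrow(rec), 30)
  expect_equal(rec$accession, truth$accession)
  expect_equal(rec$ontology_raw, truth$ontology_raw)
  expect_equal(rec$organism, truth$organism)
  expect_equal(rec$best_rank, truth$rank)
  expect_equal(rec$residues, fam$records$residues)
})

test_that("records without an organism get best_rank none", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">A1 some oxidoreductase", "ACDEFGHIKL"), f)
  rec <- read_annotated_fasta(f,
                              taxonomy = load_taxonomy_table(
                                system.file("extdata", "taxonomy_example.tsv",
                                            package = "goxprofiler")))
  expect_equal(rec$organism, "")
  expect_equal(rec$best_rank, "none")
})

test_that("malformed FASTA and duplicate accessions raise named errors", {
  f <- tempfile()
  writeLines(c("ACDE", ">A1", "ACDE"), f)
  expect_error(read_annotated_fasta(f), "line 1")

  f2 <- tempfile()
  writeLines(c(">A1 x", "ACDE", ">A1 y", "ACDF"), f2)
  expect_error(read_annotated_fasta(f2), "duplicate.*A1")

  f3 <- tempfile()
  writeLines(c(">A1 x", "AC DE"), f3)
  expect_error(read_annotated_fasta(f3), "line 2")
})

test_that("write/read round trip is byte-identical", {
  fam <- simulate_family(simulation_config(n_sequences = 12, n_clades = 2,
                                           seed = 3))
  f1 <- tempfile(fileext = ".fa")
  write_fasta(fam$records, f1)
  rec <- read_annotated_fasta(f1, taxonomy = fam$taxonomy)
  f2 <- tempfile(fileext = ".fa")
  write_fasta(rec, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("ontology normalization is idempotent, total, and groups synonyms", {
  expect_equal(normalize_ontology("oxidoreductase_ FAD-binding"),
               "FAD-binding oxidoreductase")
  expect_equal(normalize_ontology("D-amino acid dehydrogenase small subunit"),
               "(D-) amino acid dehydrogenase")
  expect_equal(normalize_ontology("completely novel label"),
               "completely novel label")

  # idempotent and total on every fixture label plus junk
  labels <- c(table2_fixture()$protein_type, "??", "x y-z_w")
  once <- normalize_ontology(labels)
  expect_equal(normalize_ontology(once), once)
})

test_that("ontology report partitions the dataset", {
  rec <- make_records(sprintf("A%02d", 1:9),
                      ontology = c(rep("FAD-binding oxidoreductase", 5),
                                   rep("D-amino acid dehydrogenase", 3),
                                   "dadA1"))
  rep <- ontology_report(rec)
  expect_equal(sum(rep$count), 9)
  expect_equal(sum(rep$fraction), 1, tolerance = 1e-9)
  expect_equal(attr(rep, "n_subtypes"), 3)

  one <- ontology_report(make_records("A1"))
  expect_equal(one$fraction, 1.0)
  expect_error(ontology_report(make_records(character(0))), "empty")
})

test_that("taxonomy report matches generator truth", {
  fam <- simulate_family(simulation_config(n_sequences = 80, n_clades = 4,
                                           seed = 9))
  tr <- taxonomy_report(fam$records)
  truth <- table(fam$truth$sequences$rank)
  for (r in names(truth))
    expect_equal(tr$rank_table$count[tr$rank_table$rank == r],
                 unname(as.integer(truth[r])))
  expect_equal(sum(tr$rank_table$fraction), 1, tolerance = 1e-9)
  expect_equal(sum(tr$class_table$count),
               sum(nzchar(fam$records$tax_class)))

  # all records at species rank -> species fraction 1
  rec <- make_records(c("A1", "A2"))
  rec$best_rank <- "species"
  tr2 <- taxonomy_report(rec)
  expect_equal(tr2$rank_table$fraction[tr2$rank_table$rank == "species"], 1)
})
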