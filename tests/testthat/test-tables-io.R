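test_that("interaction reader parses, normalizes and stays non-lossy", {
  path <- write_interactions_fixture(c(
    "hsa-miR-155-5p\tAGTR1\tLuciferase reporter assay//Western blot",
    "miR-21-5p\tagtr1\t",
    "miR-21-5p\tagtr1\t",
    "miR-21-5p\tagtr1\t"
  ))
  rec <- read_interactions(path, source = "fixture")
  expect_equal(nrow(rec), 4)                       # duplicates retained
  expect_equal(rec$mirna[1], "miR-155-5p")         # species prefix stripped
  expect_equal(rec$evidence[[1]],
               c("Luciferase reporter assay", "Western blot"))
  expect_equal(unique(rec$gene), "AGTR1")          # upper-cased
  expect_length(rec$evidence[[2]], 0)              # empty evidence allowed

  # missing mandatory column is a named format error
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("mirna\tevidence", "miR-1\tx"), bad)
  expect_error(read_interactions(bad), "gene")

  # empty file reads as an empty record sequence
  empty <- tempfile(fileext = ".tsv")
  file.create(empty)
  expect_equal(nrow(read_interactions(empty)), 0)
})

test_that("miRNA name normalization canonicalizes prefix, case and family", {
  expect_equal(normalize_mirna_name("hsa-miR-138-5p"), "miR-138-5p")
  expect_equal(normalize_mirna_name("miR-155-5p"), "miR-155-5p")
  expect_equal(normalize_mirna_name("HSA-LET-7A-5P"), "let-7a-5p")
  expect_equal(normalize_mirna_name("MIR-133B"), "miR-133b")
  expect_error(normalize_mirna_name(""), "non-empty")
})

test_that("loaded tables round-trip through their writers", {
  path <- write_interactions_fixture(c(
    "miR-155-5p\tAGTR1\tLuciferase reporter assay//Western blot",
    "miR-34a-5p\tAGTR1\tqRT-PCR"
  ))
  rec <- read_interactions(path, source = "fixture")
  out <- tempfile(fileext = ".tsv")
  write_interactions(rec, out)
  expect_equal(read_interactions(out, source = "fixture"), rec)

  snps <- read_snps(extdata("cvd_snp_panel.tsv"))
  out2 <- tempfile(fileext = ".tsv")
  write_table_tsv(snps, out2)
  expect_equal(read_snps(out2), snps)

  drugs <- read_drug_targets(extdata("agtr1_demo_drugs.tsv"))
  out3 <- tempfile(fileext = ".tsv")
  write_table_tsv(drugs, out3)
  expect_equal(read_drug_targets(out3), drugs)
})

test_that("SNP reader validates rs-numbers and 1-based coordinates", {
  snps <- read_snps(extdata("cvd_snp_panel.tsv"))
  expect_equal(nrow(snps), 4)
  expect_true(all(grepl("^rs[0-9]+$", snps$rsid)))
  expect_equal(snps$position[snps$rsid == "rs5186"], 148742201)
  expect_equal(snps$chromosome[snps$rsid == "rs5186"], "3")

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("rsid\tgene\tchromosome\tposition", "SNP_1\tA\t1\t5"), bad)
  expect_error(read_snps(bad), "rsID")
  writeLines(c("rsid\tgene\tchromosome\tposition", "rs1\tA\t1\t0"), bad)
  expect_error(read_snps(bad), "positive")
})

test_that("ontology edge-list reader finds roots and rejects cycles", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("child_id\tparent_id\trelation",
               "A\tC\tis_a", "B\tC\tis_a"), path)
  dag <- read_ontology(path, dialect = "edgelist")
  expect_equal(sort(dag$terms$term_id), c("A", "B", "C"))
  expect_equal(dag$roots, "C")
  expect_equal(dag$edges$weight, c(0.8, 0.8))

  writeLines(c("child_id\tparent_id\trelation",
               "A\tB\tis_a", "B\tA\tis_a"), path)
  expect_error(read_ontology(path, dialect = "edgelist"), "cycle")
})

test_that("unknown relation labels get the configurable default weight", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("child_id\tparent_id\trelation", "A\tC\tregulates"), path)
  expect_equal(read_ontology(path)$edges$weight, 0.7)
  expect_equal(read_ontology(path, default_weight = 0.55)$edges$weight, 0.55)
  expect_error(read_ontology(path, default_weight = 1), "between 0 and 1")
})

test_that("OBO parser reads stanzas, relationships and roots", {
  obo <- tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: DOID:1", "name: disease of anatomical entity", "",
    "[Term]", "id: DOID:2", "name: vascular disease",
    "is_a: DOID:1 ! disease of anatomical entity",
    "relationship: part_of DOID:1", "",
    "[Typedef]", "id: part_of"
  ), obo)
  dag <- read_ontology(obo, dialect = "obo")
  expect_equal(nrow(dag$terms), 2)
  expect_equal(dag$roots, "DOID:1")
  expect_equal(sort(dag$edges$relation), c("is_a", "part_of"))

  # single stanza without is_a is a root
  writeLines(c("[Term]", "id: DOID:9", "name: solo"), obo)
  solo <- read_ontology(obo, dialect = "obo")
  expect_equal(solo$terms$term_id, "DOID:9")
  expect_equal(solo$roots, "DOID:9")
})

test_that("generated DAGs load cleanly and a closing edge is caught", {
  set.seed(41)
  for (i in 1:5) {
    dag <- random_dag()
    path <- tempfile(fileext = ".tsv")
    write_ontology_edgelist(dag, path)
    reread <- read_ontology(path)
    expect_equal(sort(reread$terms$term_id), sort(dag$terms$term_id))
    # reverse one root-ward path edge to close a loop
    e <- dag$edges[1, ]
    back <- data.frame(child = e$parent, parent = e$child,
                       relation = "is_a")
    expect_error(
      ontology_dag(dag$terms,
                   rbind(dag$edges[, c("child", "parent", "relation")], back)),
      "cycle"
    )
  }
})
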