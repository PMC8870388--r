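agtr1_network <- function() {
  build_cluster_network(
    "AGTR1",
    interaction_set(c("miR-155-5p", "miR-34a-5p"), c("AGTR1", "AGTR1")),
    drugs = data.frame(drug = "candesartan", gene = "AGTR1"),
    snps = data.frame(rsid = "rs5186", gene = "AGTR1")
  )
}

test_that("the AGTR1 cluster builds a 5-node, 4-edge multilayer network", {
  net <- agtr1_network()
  expect_equal(nrow(net$nodes), 5)
  expect_equal(nrow(net$edges), 4)
  expect_equal(sort(unique(net$edges$edge_type)),
               c("drug_gene", "mirna_gene", "snp_gene"))
  expect_false(any(net$nodes$isolated))
})

test_that("network restriction and isolation flags behave", {
  pairs <- interaction_set(c("miR-1-3p", "miR-2-5p"), c("GENEA", "OUTSIDE"))
  net <- build_cluster_network(c("GENEA", "LONELY"), pairs)
  expect_equal(sort(net$nodes$id[net$nodes$node_type == "gene"]),
               c("GENEA", "LONELY"))
  # the interaction targeting a gene outside the cluster is excluded
  expect_false("OUTSIDE" %in% net$nodes$id)
  expect_false("miR-2-5p" %in% net$nodes$id)
  expect_true(net$nodes$isolated[net$nodes$id == "LONELY"])
  # no drug/SNP tables -> gene and miRNA nodes only
  expect_equal(sort(unique(net$nodes$node_type)), c("gene", "miRNA"))
})

test_that("the network constructor enforces typing invariants", {
  nodes <- data.frame(id = c("g", "m"), node_type = c("gene", "miRNA"))
  expect_error(multilayer_network(
    nodes, data.frame(from = "g", to = "g", edge_type = "mirna_gene")),
    "self-loops")
  expect_error(multilayer_network(
    nodes, data.frame(from = "g", to = "m", edge_type = "mirna_gene")),
    "edge type")
  # duplicate edges collapse
  net <- multilayer_network(
    nodes, data.frame(from = c("m", "m"), to = c("g", "g"),
                      edge_type = "mirna_gene"))
  expect_equal(nrow(net$edges), 1)
})

test_that("degree summary reproduces bucket counts and rounding", {
  # fixture degree sequence: 114 genes of degree 1, 29 of 5, 17 of 11
  deg <- c(rep(1, 114), rep(5, 29), rep(11, 17))
  net <- degree_profile_network(160, sum(deg), 114, 17, n_mirnas = 20)
  # the generator hits the same buckets from the marginals alone
  ds <- degree_summary(net)
  expect_equal(ds$n_genes, 160)
  expect_equal(ds$n_lt5, 114)
  expect_equal(ds$pct_lt5, 71.25)
  expect_equal(ds$n_gt10, 17)
  expect_equal(ds$pct_gt10, 10.63)  # 10.625 rounds half away from zero

  # no miRNA edges at all
  iso <- multilayer_network(
    data.frame(id = c("G1", "G2"), node_type = "gene"),
    data.frame(from = character(0), to = character(0),
               edge_type = character(0)))
  ds0 <- degree_summary(iso)
  expect_equal(ds0$mean_degree, 0)
  expect_equal(ds0$pct_lt5, 100)
  expect_error(degree_summary(multilayer_network(
    data.frame(id = "m", node_type = "miRNA"),
    data.frame(from = character(0), to = character(0),
               edge_type = character(0)))), "no gene nodes")
})

test_that("gene degrees, miRNA degrees and edge count close the handshake", {
  set.seed(19)
  for (i in 1:10) {
    cfg <- synthetic_config(seed = i, n_genes = 60, n_mirnas = 10)
    dag <- simulate_ontology(cfg)
    pairs <- filter_interactions(simulate_interactions(cfg, dag)$records)
    net <- build_cluster_network(unique(pairs$gene), pairs)
    mg <- net$edges[net$edges$edge_type == "mirna_gene", ]
    gene_deg <- table(factor(mg$to, levels = net$nodes$id[
      net$nodes$node_type == "gene"]))
    mirna_deg <- table(factor(mg$from, levels = net$nodes$id[
      net$nodes$node_type == "miRNA"]))
    ds <- degree_summary(net)
    expect_equal(sum(gene_deg), ds$n_edges)
    expect_equal(sum(mirna_deg), ds$n_edges)
    expect_equal(ds$n_edges, nrow(mg))
    # order invariance of the summary
    shuffled <- multilayer_network(
      net$nodes[sample(nrow(net$nodes)), ],
      net$edges[sample(nrow(net$edges)), ])
    expect_equal(degree_summary(shuffled), degree_summary(net))
  }
})

test_that("miRNA ranking counts distinct targets with deterministic ties", {
  pairs <- interaction_set(
    c(rep("miR-9-5p", 3), rep("miR-1-3p", 3), rep("miR-5-5p", 1)),
    c("A", "B", "C", "D", "E", "F", "G"))
  rk <- rank_mirnas(pairs, k = 10)
  expect_equal(rk$mirna, c("miR-1-3p", "miR-9-5p", "miR-5-5p"))
  expect_equal(rk$targeted_genes, c(3, 3, 1))
  expect_equal(rk$rank, 1:3)
  # brute-force recount agrees
  rc <- recount_targets(pairs)
  expect_equal(unname(rc[rk$mirna]), rk$targeted_genes)

  # SNP / drug / disease columns join on target genes
  rk2 <- rank_mirnas(
    pairs,
    snps = data.frame(rsid = c("rs1", "rs2"), gene = c("A", "D")),
    drugs = data.frame(drug = c("d1", "d2", "d2"), gene = c("A", "B", "G")),
    disease_map = data.frame(mirna = "miR-9-5p", term_name = "hypertension"),
    k = 2)
  expect_equal(rk2$n_snps, c(1, 1))
  expect_equal(rk2$n_drugs, c(0, 2))
  expect_equal(rk2$diseases, c("", "hypertension"))
})

test_that("printed per-disease target lists give the printed counts", {
  for (fix in list(list("mir146a_atherosclerosis_targets.tsv",
                        "miR-146a-5p", 18),
                   list("mir21_cardiomyopathy_targets.tsv",
                        "miR-21-5p", 10),
                   list("mir138_lipid_targets.tsv", "miR-138-5p", 8))) {
    pairs <- filter_interactions(read_interactions(extdata(fix[[1]])))
    rk <- rank_mirnas(pairs, k = 10)
    expect_equal(rk$mirna[1], fix[[2]])
    expect_equal(rk$targeted_genes[1], fix[[3]])
  }
})

test_that("drug-count gene ranking restricts to miRNA targets", {
  pairs <- interaction_set(c("miR-1-3p", "miR-2-5p"), c("CACNA1C", "OTHER"))
  drugs <- data.frame(
    drug = c(sprintf("ccb_%02d", 1:13), "x1", "x2"),
    gene = c(rep("CACNA1C", 13), "NOTTARGET", "OTHER"))
  rk <- rank_genes_by_drug_count(drugs, pairs, k = 10)
  expect_equal(rk$gene[1], "CACNA1C")
  expect_equal(rk$n_drugs[1], 13)
  expect_false("NOTTARGET" %in% rk$gene)
  empty <- rank_genes_by_drug_count(
    data.frame(drug = character(0), gene = character(0)), pairs)
  expect_equal(nrow(empty), 0)
})

test_that("GraphML and SIF exports round-trip exactly", {
  net <- agtr1_network()
  gml <- tempfile(fileext = ".graphml")
  export_network(net, "graphml", gml)
  expect_equal(import_network(gml, "graphml"), net)

  sif <- tempfile(fileext = ".sif")
  export_network(net, "sif", sif)
  expect_equal(length(readLines(sif)), 4)  # line per edge, no isolated nodes
  expect_equal(import_network(sif, "sif"), net)

  # empty network -> valid empty GraphML
  empty <- multilayer_network(
    data.frame(id = character(0), node_type = character(0)),
    data.frame(from = character(0), to = character(0),
               edge_type = character(0)))
  export_network(empty, "graphml", gml)
  expect_equal(nrow(import_network(gml, "graphml")$nodes), 0)

  # larger generated networks, both formats
  cfg <- synthetic_config(seed = 2, n_genes = 80, n_mirnas = 12)
  dag <- simulate_ontology(cfg)
  pairs <- filter_interactions(simulate_interactions(cfg, dag)$records)
  ds <- simulate_drugs_snps(cfg, unique(pairs$gene))
  big <- build_cluster_network(unique(pairs$gene), pairs,
                               drugs = ds$drugs, snps = ds$snps)
  export_network(big, "graphml", gml)
  expect_equal(import_network(gml, "graphml"), big)
  export_network(big, "sif", sif)
  expect_equal(import_network(sif, "sif"), big)
})

test_that("GraphML carries the Cytoscape styling attributes", {
  skip_if_not_installed("xml2")
  net <- agtr1_network()
  gml <- tempfile(fileext = ".graphml")
  export_network(net, "graphml", gml)
  doc <- xml2::read_xml(gml)
  ns <- xml2::xml_ns(doc)
  keys <- xml2::xml_attr(xml2::xml_find_all(doc, ".//d1:key", ns), "attr.name")
  expect_true(all(c("node_type", "shape", "edge_type") %in% keys))
  data_vals <- xml2::xml_text(xml2::xml_find_all(doc, ".//d1:data", ns))
  expect_true(all(c("circle", "diamond", "square", "triangle") %in%
                    data_vals))
})
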