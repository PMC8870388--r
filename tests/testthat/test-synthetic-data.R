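test_that("config validation catches infeasible shapes", {
  expect_error(synthetic_config(planted_effect = 1.2), "probabilities")
  expect_error(synthetic_config(depth = 1), "depth")
  expect_error(synthetic_config(depth = 2, branching = 2,
                                n_planted_terms = 5), "planted")
})

test_that("the generated ontology has the expected tree arithmetic", {
  cfg <- synthetic_config(seed = 3, n_genes = 100, depth = 3, branching = 3)
  dag <- simulate_ontology(cfg)
  expect_equal(nrow(dag$terms), 1 + 3 + 9 + 27)
  expect_equal(length(dag$roots), 1)
  # annotations sit on leaves and cover every gene exactly once
  expect_equal(sum(lengths(dag$annotations)), 100)
  expect_length(attr(dag, "planted_terms"), cfg$n_planted_terms)
  # the emitted edge list re-loads without a cycle complaint
  path <- tempfile(fileext = ".tsv")
  write_ontology_edgelist(dag, path)
  expect_s3_class(read_ontology(path), "ontology_dag")
})

test_that("identical configs give byte-identical bundles", {
  cfg <- synthetic_config(seed = 9, n_genes = 60, n_mirnas = 8,
                          n_drugs = 5, n_snps = 5)
  d1 <- tempfile("bundleA"); d2 <- tempfile("bundleB")
  b1 <- simulate_bundle(cfg, d1)
  b2 <- simulate_bundle(cfg, d2)
  for (f in names(b1$files)) {
    expect_equal(readLines(b1$files[[f]]), readLines(b2$files[[f]]),
                 info = f)
  }
})

test_that("generator truth matches a recount of the emitted tables", {
  cfg <- synthetic_config(seed = 21, n_genes = 80, n_mirnas = 10)
  dag <- simulate_ontology(cfg)
  sim <- simulate_interactions(cfg, dag)
  expect_equal(sim$truth$n_rows, nrow(sim$records))
  for (h in sim$truth$hub_mirnas) {
    expect_equal(unname(sim$truth$hub_target_counts[h]),
                 sum(sim$records$mirna == h))
  }
  # hubs carry the planted fraction of their term's genes
  for (i in seq_along(sim$truth$planted_terms)) {
    tg <- dag$annotations[[sim$truth$planted_terms[i]]]
    hub_targets <- sim$records$gene[sim$records$mirna ==
                                      sim$truth$hub_mirnas[i]]
    expect_gte(sum(tg %in% hub_targets),
               ceiling(cfg$planted_effect * length(tg)))
  }
})

test_that("full planted effect embeds the whole term in the hub targets", {
  cfg <- synthetic_config(seed = 4, n_genes = 60, n_mirnas = 6,
                          planted_effect = 1, n_planted_terms = 1)
  dag <- simulate_ontology(cfg)
  sim <- simulate_interactions(cfg, dag)
  tg <- dag$annotations[[sim$truth$planted_terms]]
  hub_targets <- sim$records$gene[sim$records$mirna == sim$truth$hub_mirnas]
  expect_true(all(tg %in% hub_targets))
})

test_that("zero evidence pass probability empties the filtered set", {
  cfg <- synthetic_config(seed = 5, n_genes = 60, n_mirnas = 6,
                          evidence_pass_prob = 0)
  dag <- simulate_ontology(cfg)
  sim <- simulate_interactions(cfg, dag)
  expect_equal(nrow(filter_interactions(sim$records)), 0)
})

test_that("drug and SNP tables have the declared shapes", {
  cfg <- synthetic_config(seed = 6, n_genes = 50, n_drugs = 8, n_snps = 12)
  genes <- paste0("G", sprintf("%04d", 1:50))
  ds <- simulate_drugs_snps(cfg, genes)
  expect_true(all(grepl("^rs[0-9]+$", ds$snps$rsid)))
  expect_true(all(ds$snps$position > 0))
  expect_equal(nrow(ds$snps), 12)
  expect_equal(length(unique(ds$drugs$drug)), 8)
  expect_true(all(ds$drugs$gene %in% genes))

  none <- simulate_drugs_snps(synthetic_config(seed = 6, n_drugs = 0,
                                               n_snps = 0), genes)
  expect_equal(nrow(none$drugs), 0)
  expect_equal(nrow(none$snps), 0)
})

test_that("a constructed 13-drug gene tops the drug ranking", {
  pairs <- interaction_set(rep("miR-1-3p", 2), c("HUB", "OTHER"))
  drugs <- data.frame(drug = sprintf("d%02d", 1:13), gene = "HUB")
  rk <- rank_genes_by_drug_count(drugs, pairs, k = 5)
  expect_equal(rk$gene[1], "HUB")
  expect_equal(rk$n_drugs[1], 13)
})

test_that("block fixture degenerate shapes behave", {
  one <- simulate_similarity_blocks(1, 3, synthetic_config(seed = 2))
  m1 <- similarity_matrix(one$terms, one$dag)
  expect_equal(max(cluster_terms(m1)$assignment), 1)
  tiny <- simulate_similarity_blocks(3, 1, synthetic_config(seed = 2))
  mt <- similarity_matrix(tiny$terms, tiny$dag)
  expect_equal(nrow(report_clusters(cluster_terms(mt), min_size = 2)), 0)
})

test_that("ORA recovers planted terms and rejects decoy leaves", {
  # 50-seed sweep at the default generator parameters; sensitivity >= 0.9
  # and decoy leaf false-positive rate <= 10%
  planted_found <- 0; planted_total <- 0
  decoy_hits <- 0; decoy_total <- 0
  for (seed in 1:50) {
    cfg <- synthetic_config(seed = seed)
    dag <- simulate_ontology(cfg)
    sim <- simulate_interactions(cfg, dag)
    pairs <- filter_interactions(sim$records)
    res <- run_ora(unique(pairs$gene), dag, term_filter = c(1, Inf))
    sig <- res$term_id[res$p_adj < 0.05]
    leaves <- setdiff(dag$terms$term_id, dag$edges$parent)
    decoys <- setdiff(intersect(leaves, res$term_id),
                      sim$truth$planted_terms)
    planted_total <- planted_total + length(sim$truth$planted_terms)
    planted_found <- planted_found +
      sum(sim$truth$planted_terms %in% sig)
    decoy_total <- decoy_total + length(decoys)
    decoy_hits <- decoy_hits + sum(decoys %in% sig)
  }
  expect_gte(planted_found / planted_total, 0.9)
  expect_lte(decoy_hits / decoy_total, 0.10)
})
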