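# Database-shaped synthetic inputs with known ground truth.
#
# The generator emits the five table shapes the pipeline consumes (miRNA
# targets with evidence strings, disease associations, drugs, SNPs,
# ontology edge list) from one seeded configuration: hub miRNAs
# preferentially target the genes of planted ontology terms, so
# over-representation of the validated target set at those terms is a known
# truth that recovery tests can score.

#' Configuration for the synthetic-data generator
#'
#' Defaults describe a desk-scale benchmark: 500 genes annotated over a
#' depth-3, branching-3 ontology (40 terms, 27 leaves), a panel of 30
#' miRNAs of which 3 are planted hubs that each target 80% of one planted
#' leaf term's genes, background miRNA-gene edges at probability 0.01, and
#' evidence strings that pass the strong-assay filter with probability
#' 0.9.
#'
#' @param seed integer seed driving every table.
#' @param n_genes number of genes in the universe.
#' @param n_mirnas number of miRNAs (the first `n_planted_terms` are hubs).
#' @param depth,branching shape of the ontology tree below the root.
#' @param n_planted_terms number of leaf terms with a planted hub signal.
#' @param planted_effect fraction of a planted term's genes included in
#'   its hub miRNA's target set.
#' @param background_edge_prob per-(miRNA, gene) probability of a
#'   background interaction.
#' @param evidence_pass_prob probability an emitted record carries a
#'   passing evidence string.
#' @param n_drugs,n_snps row counts for the drug and SNP tables.
#' @param drug_skew exponent of the truncated power law that concentrates
#'   drugs on a few hub genes.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1, n_genes = 500, n_mirnas = 30,
                             depth = 3, branching = 3,
                             n_planted_terms = 3, planted_effect = 0.8,
                             background_edge_prob = 0.01,
                             evidence_pass_prob = 0.9,
                             n_drugs = 30, n_snps = 20, drug_skew = 1.5) {
  cfg <- list(seed = as.integer(seed), n_genes = n_genes,
              n_mirnas = n_mirnas, depth = depth, branching = branching,
              n_planted_terms = n_planted_terms,
              planted_effect = planted_effect,
              background_edge_prob = background_edge_prob,
              evidence_pass_prob = evidence_pass_prob,
              n_drugs = n_drugs, n_snps = n_snps, drug_skew = drug_skew)
  probs <- c(cfg$planted_effect, cfg$background_edge_prob,
             cfg$evidence_pass_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$depth < 2) stop("ontology depth must be >= 2", call. = FALSE)
  if (cfg$n_planted_terms > cfg$branching^cfg$depth) {
    stop("config error: more planted terms than leaf terms", call. = FALSE)
  }
  structure(cfg, class = "synthetic_config")
}

syn_term_id <- function(i) sprintf("T%04d", i)
syn_gene_id <- function(i) sprintf("G%04d", i)

PASSING_EVIDENCE <- c("Luciferase reporter assay", "Western blot; qRT-PCR",
                      "Immunoblot", "Real-time PCR",
                      "Luciferase assay//Western blot")
FAILING_EVIDENCE <- c("Microarray", "pSILAC", "CLIP-seq", "Sequencing",
                      "Next Generation Sequencing (NGS)")

#' Generate a rooted annotated ontology
#'
#' A complete tree of the configured depth and branching (is_a edges) plus
#' a few part_of cross-links from deeper to strictly shallower levels, so
#' the result is a DAG but not a tree. Genes are assigned uniformly to
#' leaf terms; deeper layers inherit nothing at generation time —
#' propagation is the enrichment stage's job.
#'
#' @param config a [synthetic_config].
#' @return an [ontology_dag] with leaf-level annotations; attribute
#'   `"planted_terms"` records the leaf terms later used for hub targeting.
#' @export
simulate_ontology <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    b <- config$branching; d <- config$depth
    level_sizes <- b^(0:d)
    n_terms <- sum(level_sizes)
    offsets <- cumsum(c(0, level_sizes))
    ids <- syn_term_id(seq_len(n_terms))
    level_of <- rep(0:d, level_sizes)
    terms <- data.frame(term_id = ids,
                        term_name = paste0("synthetic term ", seq_len(n_terms),
                                           " (level ", level_of, ")"),
                        stringsAsFactors = FALSE)
    # tree is_a edges: node j at level l attaches to parent at level l-1
    child <- character(0); parent <- character(0)
    for (l in seq_len(d)) {
      idx <- seq_len(level_sizes[l + 1])
      child <- c(child, ids[offsets[l + 1] + idx])
      parent <- c(parent, ids[offsets[l] + ((idx - 1) %/% b) + 1])
    }
    edges <- data.frame(child = child, parent = parent, relation = "is_a",
                        stringsAsFactors = FALSE)
    # part_of cross-links: a handful of deeper terms gain a second parent
    # at a strictly shallower level (keeps the graph acyclic)
    deep <- which(level_of >= 2)
    n_cross <- min(length(deep), max(1L, n_terms %/% 10L))
    for (i in sample(deep, n_cross)) {
      shallow <- which(level_of < level_of[i])
      p <- ids[sample(shallow, 1)]
      if (!any(edges$child == ids[i] & edges$parent == p)) {
        edges <- rbind(edges, data.frame(child = ids[i], parent = p,
                                         relation = "part_of",
                                         stringsAsFactors = FALSE))
      }
    }
    leaves <- ids[level_of == d]
    leaf_of_gene <- sample(leaves, config$n_genes, replace = TRUE)
    genes <- syn_gene_id(seq_len(config$n_genes))
    annotations <- lapply(split(genes, leaf_of_gene), sort)
    planted <- sort(sample(leaves, config$n_planted_terms))
    dag <- ontology_dag(terms, edges, annotations = annotations)
    attr(dag, "planted_terms") <- planted
    dag
  })
}

#' Generate the miRNA-target interaction table
#'
#' Hub miRNAs (one per planted term) target a `planted_effect` fraction of
#' their term's genes plus background draws; every other miRNA draws each
#' gene independently at `background_edge_prob`. Evidence strings are
#' sampled from a fixed vocabulary of passing and failing assay
#' descriptions.
#'
#' @param config a [synthetic_config].
#' @param dag the ontology from [simulate_ontology()] (carries the planted
#'   terms).
#' @return list with `records` (an `interaction_records` data frame) and
#'   `truth` (a `synthetic_truth` list: planted terms, hub miRNA names and
#'   intended target counts, row count, seed).
#' @export
simulate_interactions <- function(config, dag) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(dag, "ontology_dag"))
  planted <- attr(dag, "planted_terms")
  with_seed(config$seed + 1L, {
    genes <- syn_gene_id(seq_len(config$n_genes))
    mirnas <- sprintf("miR-%d-5p", 100 + seq_len(config$n_mirnas))
    hubs <- mirnas[seq_along(planted)]
    mirna_col <- character(0); gene_col <- character(0)
    for (j in seq_along(mirnas)) {
      m <- mirnas[j]
      targets <- genes[stats::runif(length(genes)) < config$background_edge_prob]
      if (j <= length(planted)) {
        tg <- dag$annotations[[planted[j]]]
        n_take <- ceiling(config$planted_effect * length(tg))
        targets <- union(sample(tg, n_take), targets)
      }
      mirna_col <- c(mirna_col, rep(m, length(targets)))
      gene_col <- c(gene_col, targets)
    }
    pass <- stats::runif(length(mirna_col)) < config$evidence_pass_prob
    evidence <- ifelse(pass,
                       sample(PASSING_EVIDENCE, length(pass), replace = TRUE),
                       sample(FAILING_EVIDENCE, length(pass), replace = TRUE))
    records <- new_interaction_records(
      mirna = mirna_col, gene = gene_col,
      evidence = split_list_cell(evidence),
      source = rep("synthetic", length(mirna_col))
    )
    truth <- structure(
      list(planted_terms = planted, hub_mirnas = hubs,
           hub_target_counts = stats::setNames(
             vapply(hubs, function(h) sum(mirna_col == h), integer(1)), hubs),
           n_rows = nrow(records), seed = config$seed),
      class = "synthetic_truth"
    )
    list(records = records, truth = truth)
  })
}

#' Generate drug and SNP tables
#'
#' Drug-gene assignments follow a truncated power law over genes so a few
#' hub genes soak up most compounds; SNPs get synthetic rs-numbers and
#' 1-based coordinates.
#'
#' @param config a [synthetic_config].
#' @param genes character vector of gene symbols to draw from.
#' @return list with data frames `drugs` (`drug`, `gene`) and `snps`
#'   (`rsid`, `gene`, `chromosome`, `position`).
#' @export
simulate_drugs_snps <- function(config, genes) {
  stopifnot(inherits(config, "synthetic_config"), length(genes) > 0)
  with_seed(config$seed + 2L, {
    if (config$n_drugs > 0) {
      w <- seq_along(genes)^(-config$drug_skew)
      drug <- sprintf("drug_%03d", seq_len(config$n_drugs))
      n_targets <- sample(1:3, config$n_drugs, replace = TRUE)
      rows <- lapply(seq_len(config$n_drugs), function(i) {
        data.frame(drug = drug[i],
                   gene = sample(genes, n_targets[i], prob = w),
                   stringsAsFactors = FALSE)
      })
      drugs <- unique(do.call(rbind, rows))
    } else {
      drugs <- data.frame(drug = character(0), gene = character(0))
    }
    if (config$n_snps > 0) {
      snps <- data.frame(
        rsid = sprintf("rs%d", sample(10000:9999999, config$n_snps)),
        gene = sample(genes, config$n_snps, replace = TRUE),
        chromosome = as.character(sample(1:22, config$n_snps, replace = TRUE)),
        position = sample.int(2.5e8, config$n_snps),
        stringsAsFactors = FALSE
      )
    } else {
      snps <- data.frame(rsid = character(0), gene = character(0),
                         chromosome = character(0), position = integer(0))
    }
    list(drugs = drugs, snps = snps)
  })
}

#' Generate a miRNA-disease association table
#'
#' Associates each hub miRNA with its planted term and sprinkles random
#' associations for the rest.
#'
#' @param config a [synthetic_config].
#' @param dag the annotated ontology.
#' @param truth the `synthetic_truth` from [simulate_interactions()].
#' @return data frame with columns `mirna`, `term_id`, `term_name`.
#' @export
simulate_disease_associations <- function(config, dag, truth) {
  with_seed(config$seed + 3L, {
    nm <- stats::setNames(dag$terms$term_name, dag$terms$term_id)
    mirnas <- sprintf("miR-%d-5p", 100 + seq_len(config$n_mirnas))
    others <- setdiff(mirnas, truth$hub_mirnas)
    random_terms <- sample(dag$terms$term_id, length(others), replace = TRUE)
    out <- data.frame(
      mirna = c(truth$hub_mirnas, others),
      term_id = c(truth$planted_terms, random_terms),
      stringsAsFactors = FALSE
    )
    out$term_name <- unname(nm[out$term_id])
    out
  })
}

#' Ontology fixture with block-structured term similarity
#'
#' Builds a DAG in which `n_blocks` groups of leaf terms each share a deep
#' chain of common ancestors under one root, so within-block Wang
#' similarity (about 0.70 at the default is_a factor) clearly exceeds
#' between-block similarity (about 0.12). The leaf terms are the intended
#' input for [similarity_matrix()] and [cluster_terms()].
#'
#' @param n_blocks number of blocks (>= 1).
#' @param terms_per_block leaf terms per block.
#' @param config a [synthetic_config]; its seed shuffles term numbering.
#' @return list with `dag` (an [ontology_dag]), `terms` (leaf term ids)
#'   and `blocks` (named integer vector leaf -> block).
#' @export
simulate_similarity_blocks <- function(n_blocks, terms_per_block,
                                       config = synthetic_config()) {
  stopifnot(n_blocks >= 1, terms_per_block >= 1)
  with_seed(config$seed + 4L, {
    ids <- "ROOT"; child <- character(0); parent <- character(0)
    leaves <- character(0); block_of <- integer(0)
    perm <- sample(n_blocks)  # seed-dependent block numbering
    for (bi in seq_len(n_blocks)) {
      b <- perm[bi]
      chain <- sprintf("B%02d_L%d", b, 1:3)
      anchors <- c("ROOT", chain)
      for (i in seq_along(chain)) {
        ids <- c(ids, chain[i])
        child <- c(child, chain[i])
        parent <- c(parent, anchors[i])
      }
      for (t in seq_len(terms_per_block)) {
        leaf <- sprintf("B%02d_T%02d", b, t)
        ids <- c(ids, leaf)
        child <- c(child, leaf)
        parent <- c(parent, chain[3])
        leaves <- c(leaves, leaf)
        block_of <- c(block_of, b)
      }
    }
    terms <- data.frame(term_id = ids, term_name = ids,
                        stringsAsFactors = FALSE)
    edges <- data.frame(child = child, parent = parent, relation = "is_a",
                        stringsAsFactors = FALSE)
    dag <- ontology_dag(terms, edges)
    list(dag = dag, terms = leaves,
         blocks = stats::setNames(block_of, leaves))
  })
}

#' Write a full synthetic input bundle
#'
#' Emits the five input tables, the ontology edge list, the annotation
#' table and a JSON truth record into a directory.
#'
#' @param config a [synthetic_config].
#' @param dir output directory (created if needed).
#' @return list with the `truth` record and `files` (named paths).
#' @export
simulate_bundle <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dag <- simulate_ontology(config)
  sim <- simulate_interactions(config, dag)
  ds <- simulate_drugs_snps(config, syn_gene_id(seq_len(config$n_genes)))
  assoc <- simulate_disease_associations(config, dag, sim$truth)
  files <- c(
    interactions = file.path(dir, "interactions.tsv"),
    disease_associations = file.path(dir, "disease_associations.tsv"),
    drugs = file.path(dir, "drugs.tsv"),
    snps = file.path(dir, "snps.tsv"),
    ontology = file.path(dir, "ontology_edgelist.tsv"),
    annotations = file.path(dir, "annotations.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_interactions(sim$records, files["interactions"])
  write_table_tsv(assoc, files["disease_associations"])
  write_table_tsv(ds$drugs, files["drugs"])
  write_table_tsv(ds$snps, files["snps"])
  write_ontology_edgelist(dag, files["ontology"])
  ann_df <- data.frame(
    term_id = rep(names(dag$annotations), lengths(dag$annotations)),
    gene = unlist(dag$annotations, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  write_table_tsv(ann_df, files["annotations"])
  jsonlite::write_json(unclass(sim$truth), files["truth"], auto_unbox = TRUE)
  list(truth = sim$truth, files = files)
}

#' Bipartite fixture network matching published degree marginals
#'
#' Constructs a miRNA-gene network with an exact number of gene nodes and
#' miRNA-gene edges in which exactly `n_lt5` genes have fewer than 5 miRNA
#' partners and exactly `n_gt10` have more than 10 — the marginal shape in
#' which bipartite degree summaries are reported. Within-bucket degrees
#' are filled deterministically (low-degree genes start at 1, middle at 5,
#' high at 11; leftover edges are spread round-robin without crossing
#' bucket boundaries).
#'
#' @param n_genes,n_edges,n_lt5,n_gt10 the target marginals.
#' @param n_mirnas number of miRNA nodes to spread partners over (must be
#'   at least the largest degree).
#' @return a [multilayer_network].
#' @export
degree_profile_network <- function(n_genes, n_edges, n_lt5, n_gt10,
                                   n_mirnas) {
  n_mid <- n_genes - n_lt5 - n_gt10
  stopifnot(n_mid >= 0)
  deg <- c(rep(1L, n_lt5), rep(5L, n_mid), rep(11L, n_gt10))
  cap <- c(rep(4L, n_lt5), rep(10L, n_mid), rep(.Machine$integer.max, n_gt10))
  rem <- n_edges - sum(deg)
  if (rem < 0) stop("infeasible degree profile: too few edges", call. = FALSE)
  while (rem > 0) {
    open <- which(deg < cap)
    if (length(open) == 0) stop("infeasible degree profile", call. = FALSE)
    take <- utils::head(open, rem)
    deg[take] <- deg[take] + 1L
    rem <- rem - length(take)
  }
  if (max(deg) > n_mirnas) {
    stop("need at least ", max(deg), " miRNAs for this profile",
         call. = FALSE)
  }
  genes <- syn_gene_id(seq_len(n_genes))
  mirnas <- sprintf("miR-%d-5p", 100 + seq_len(n_mirnas))
  from <- character(0); to <- character(0)
  cursor <- 0L
  for (i in seq_len(n_genes)) {
    take <- ((cursor + seq_len(deg[i]) - 1L) %% n_mirnas) + 1L
    cursor <- cursor + deg[i]
    from <- c(from, mirnas[take])
    to <- c(to, rep(genes[i], deg[i]))
  }
  nodes <- rbind(
    data.frame(id = genes, node_type = "gene", stringsAsFactors = FALSE),
    data.frame(id = unique(from), node_type = "miRNA",
               stringsAsFactors = FALSE)
  )
  edges <- data.frame(from = from, to = to, edge_type = "mirna_gene",
                      stringsAsFactors = FALSE)
  multilayer_network(nodes, edges)
}
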