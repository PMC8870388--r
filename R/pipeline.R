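# End-to-end orchestration: filter -> enrich -> simcluster -> network.
# Each stage writes plain files before the next reads anything, so every
# stage is independently re-runnable; the manifest records per-stage counts.

#' Assemble a pipeline configuration
#'
#' @param interactions,disease_associations,drugs,snps,ontology,annotations
#'   input file paths (interactions and ontology mandatory; the ontology
#'   may be OBO or edge-list TSV; annotations TSV is required unless the
#'   OBO itself is unused and annotations ride with an edge list).
#' @param out_dir output directory.
#' @param keywords an [evidence_keywords] object.
#' @param alpha adjusted-p significance threshold in (0, 1).
#' @param term_filter `c(min, max)` bounds on tested term size.
#' @param universe `"annotated"` or `"custom"`.
#' @param linkage,cut_height,min_cluster_size clustering parameters.
#' @param top_k ranking depth.
#' @param seed seed recorded in the manifest (the analysis stages are
#'   deterministic; the seed matters only when the inputs are generated).
#' @return a `pipeline_config` list, validated.
#' @export
pipeline_config <- function(interactions, ontology, annotations = NULL,
                            disease_associations = NULL, drugs = NULL,
                            snps = NULL, out_dir = "pipeline_out",
                            keywords = evidence_keywords(), alpha = 0.05,
                            term_filter = c(5, 500),
                            universe = "annotated",
                            linkage = "average", cut_height = 0.7,
                            min_cluster_size = 2, top_k = 10, seed = 1) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  paths <- c(interactions = interactions, ontology = ontology,
             annotations = annotations,
             disease_associations = disease_associations,
             drugs = drugs, snps = snps)
  missing <- paths[!vapply(paths, file.exists, logical(1))]
  if (length(missing) > 0) {
    stop("input path(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure(list(interactions = interactions, ontology = ontology,
                 annotations = annotations,
                 disease_associations = disease_associations,
                 drugs = drugs, snps = snps, out_dir = out_dir,
                 keywords = keywords, alpha = alpha,
                 term_filter = term_filter, universe = universe,
                 linkage = linkage, cut_height = cut_height,
                 min_cluster_size = min_cluster_size, top_k = top_k,
                 seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields mirror the [pipeline_config()] arguments; `keywords` may
#' be a list of strings.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  kw <- if (is.null(y$keywords)) evidence_keywords() else {
    evidence_keywords(unlist(y$keywords),
                      mode = if (is.null(y$keyword_mode)) "any" else y$keyword_mode)
  }
  args <- y[intersect(names(y),
                      c("interactions", "ontology", "annotations",
                        "disease_associations", "drugs", "snps", "out_dir",
                        "alpha", "universe", "linkage", "cut_height",
                        "min_cluster_size", "top_k", "seed"))]
  if (!is.null(y$term_filter)) args$term_filter <- unlist(y$term_filter)
  args$keywords <- kw
  do.call(pipeline_config, args)
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' Stages, in order: evidence filtering of the interaction table;
#' over-representation analysis of the surviving target genes against the
#' ontology; Wang similarity and hierarchical clustering of the
#' significant terms; per-cluster multi-layer network assembly with degree
#' summaries and rankings. Every stage writes its outputs under
#' `config$out_dir` before the next stage runs.
#'
#' @param config a [pipeline_config].
#' @param verbose print one line per stage.
#' @return a `pipeline_manifest`: list with `files` (named paths) and
#'   `counts` (pairs kept, terms tested, terms significant, clusters
#'   reported, per-cluster degree summary rows).
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(...)
  files <- list()

  # stage: filter
  pairs <- pipeline_stage("filter", {
    records <- read_interactions(config$interactions, source = "input")
    filter_interactions(records, config$keywords)
  })
  files$pairs <- file.path(config$out_dir, "pairs.tsv")
  write_interaction_set(pairs, files$pairs)
  say("filter: ", nrow(pairs), " pairs kept")

  # stage: enrich
  enr <- pipeline_stage("enrich", {
    dag <- read_ontology(config$ontology)
    if (!is.null(config$annotations)) {
      dag <- set_annotations(dag, read_annotations(config$annotations))
    }
    run_ora(unique(pairs$gene), dag, term_filter = config$term_filter,
            universe = config$universe)
  })
  dag <- read_ontology(config$ontology)
  if (!is.null(config$annotations)) {
    dag <- set_annotations(dag, read_annotations(config$annotations))
  }
  files$enrichment <- file.path(config$out_dir, "enrichment.tsv")
  write_enrichment(enr, files$enrichment)
  sig <- enr[enr$p_adj < config$alpha, , drop = FALSE]
  files$dotplot <- file.path(config$out_dir, "dotplot.tsv")
  write_tsv_plain(dotplot_table(enr, config$alpha), files$dotplot)
  say("enrich: ", nrow(enr), " terms tested, ", nrow(sig), " significant")

  # stage: simcluster
  clusters <- pipeline_stage("simcluster", {
    if (nrow(sig) == 0) {
      stop("no significant terms to cluster", call. = FALSE)
    }
    simmat <- similarity_matrix(sig$term_id, dag)
    files$similarity <- file.path(config$out_dir, "similarity.tsv")
    write_similarity_matrix(simmat, files$similarity)
    cluster_terms(simmat, linkage = config$linkage,
                  cut_height = config$cut_height)
  })
  cl_table <- report_clusters(clusters, min_size = config$min_cluster_size)
  files$clusters <- file.path(config$out_dir, "clusters.tsv")
  write_tsv_plain(cl_table, files$clusters)
  say("simcluster: ", nrow(cl_table), " cluster(s) of size >= ",
      config$min_cluster_size)

  # stage: network
  drugs <- if (is.null(config$drugs)) NULL else read_drug_targets(config$drugs)
  snps <- if (is.null(config$snps)) NULL else read_snps(config$snps)
  assoc <- if (is.null(config$disease_associations)) NULL else {
    read_disease_associations(config$disease_associations, dag)
  }
  degree_rows <- list()
  pipeline_stage("network", {
    hit_genes_of <- stats::setNames(enr$hits, enr$term_id)
    for (i in seq_len(nrow(cl_table))) {
      label <- cl_table$cluster[i]
      members <- strsplit(cl_table$members[i], LIST_SEP, fixed = TRUE)[[1]]
      genes <- sort(unique(unlist(hit_genes_of[members])))
      net <- build_cluster_network(genes, pairs, drugs = drugs, snps = snps)
      gml <- file.path(config$out_dir,
                       sprintf("cluster%02d_network.graphml", label))
      sif <- file.path(config$out_dir,
                       sprintf("cluster%02d_network.sif", label))
      export_network(net, "graphml", gml)
      export_network(net, "sif", sif)
      files[[sprintf("network_cluster%02d", label)]] <- gml
      ds <- degree_summary(net)
      ds$cluster <- label
      degree_rows[[i]] <- ds
      cl_pairs <- pairs[pairs$gene %in% genes, , drop = FALSE]
      rk <- rank_mirnas(cl_pairs, snps = snps, drugs = drugs,
                        disease_map = assoc, k = config$top_k)
      rkf <- file.path(config$out_dir,
                       sprintf("cluster%02d_mirna_ranking.tsv", label))
      write_summary_tsv(rk, rkf)
      files[[sprintf("ranking_cluster%02d", label)]] <- rkf
    }
  })
  degrees <- do.call(rbind, degree_rows)
  files$degree_summary <- file.path(config$out_dir, "degree_summary.tsv")
  write_summary_tsv(degrees, files$degree_summary)
  files$global_ranking <- file.path(config$out_dir, "mirna_ranking.tsv")
  write_summary_tsv(rank_mirnas(pairs, snps = snps, drugs = drugs,
                                disease_map = assoc, k = config$top_k),
                    files$global_ranking)
  files$drug_gene_ranking <- file.path(config$out_dir, "gene_drug_ranking.tsv")
  if (!is.null(drugs)) {
    write_summary_tsv(rank_genes_by_drug_count(drugs, pairs,
                                               k = config$top_k),
                      files$drug_gene_ranking)
  } else {
    files$drug_gene_ranking <- NULL
  }
  say("network: ", nrow(cl_table), " cluster network(s) written")

  manifest <- structure(
    list(files = files,
         counts = list(pairs_kept = nrow(pairs), terms_tested = nrow(enr),
                       terms_significant = nrow(sig),
                       clusters_reported = nrow(cl_table),
                       degree_summaries = if (is.null(degrees)) 0L
                                          else nrow(degrees)),
         seed = config$seed),
    class = "pipeline_manifest"
  )
  # file names only, so manifests from different output roots compare equal
  jsonlite::write_json(
    list(files = lapply(files, basename), counts = manifest$counts),
    file.path(config$out_dir, "manifest.json"), auto_unbox = TRUE
  )
  manifest
}

#' @export
print.pipeline_manifest <- function(x, ...) {
  cat("pipeline_manifest:\n")
  for (nm in names(x$counts)) cat(" ", nm, "=", x$counts[[nm]], "\n")
  cat(" ", length(x$files), "output file(s)\n")
  invisible(x)
}
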