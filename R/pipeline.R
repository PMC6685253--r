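PIPELINE_STAGES <- c("enrich", "semsim", "cluster", "report")

default_config <- function() {
  list(annotation_format = "gaf", namespace = "biological_process",
       algorithm = "elim", alpha = 0.01, threshold = 0.01,
       measure = "wang", combine = "BMA",
       cut = list(mode = "dynamic", min_size = 2, deep_split = 2, k = NULL, h = NULL),
       images = TRUE, outdir = "goclust_results")
}

#' Read a pipeline configuration from YAML
#'
#' Missing fields fall back to the workflow defaults (elim Fisher tests at
#' alpha 0.01, merge threshold 0.01, Wang similarity, BMA set combination,
#' ward.D2 linkage, dynamic cut with min size 2 / deep split 2).
#'
#' @param path YAML file path.
#' @return Config list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  merge_config(cfg)
}

merge_config <- function(cfg) {
  out <- default_config()
  for (k in names(cfg)) {
    if (k == "cut" && is.list(cfg$cut)) {
      for (k2 in names(cfg$cut)) out$cut[[k2]] <- cfg$cut[[k2]]
    } else out[[k]] <- cfg[[k]]
  }
  out
}

read_gene_list <- function(path) {
  if (!file.exists(path)) stop("gene list file not found: ", path)
  x <- readLines(path, warn = FALSE)
  unique(x[nzchar(x)])
}

#' Run the full analysis pipeline
#'
#' Executes the workflow stage by stage — annotate, enrich, similarity,
#' cluster, report — writing every data product (TSV/JSON twins plus static
#' images) under `config$outdir`, and a structured run log. Stages after
#' `upto` are skipped. All computation is deterministic for fixed inputs:
#' two runs produce byte-identical TSV/JSON outputs (run-log timestamp
#' aside).
#'
#' @param config Config list (see [read_config()]); required fields: `obo`,
#'   `annotations`, `background`, `lists` (named list of gene-list files).
#' @param upto Last stage to run: `"enrich"`, `"semsim"`, `"cluster"` or
#'   `"report"`.
#' @return Invisible list with the main objects (`dag`, `annot`, `table`,
#'   `sim`, `tree`, `clusters`, ...) and the run-log list.
#' @export
run_pipeline <- function(config, upto = "report") {
  config <- merge_config(config)
  upto_i <- match(match.arg(upto, PIPELINE_STAGES), PIPELINE_STAGES)
  for (f in c("obo", "annotations", "background")) {
    if (is.null(config[[f]])) stop("config field '", f, "' is required")
    if (!file.exists(config[[f]])) stop("input file not found: ", config[[f]])
  }
  if (length(config$lists) == 0L) stop("config field 'lists' must name at least one gene list")
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()

  # --- annotate ---
  dag <- parse_obo(config$obo)
  annot <- switch(config$annotation_format,
    gaf = read_gaf(config$annotations, dag, config$namespace, config$evidence_filter),
    tsv = read_tsv_annotation(config$annotations, dag, config$namespace),
    stop("unknown annotation_format: ", config$annotation_format))
  annot <- propagate(annot, dag)
  background <- read_gene_list(config$background)
  interest <- lapply(config$lists, read_gene_list)
  n_annotated <- length(intersect(background, names(annot$propagated)))
  message(n_annotated, " background genes are annotated with at least one ",
          config$namespace, " term")
  counts$terms <- length(dag$ids)
  counts$annotated_background_genes <- n_annotated

  # --- enrich ---
  results <- lapply(interest, function(g) {
    switch(config$algorithm,
      classic = classic_enrichment(g, background, annot, dag),
      elim = elim_enrichment(g, background, annot, dag, alpha = config$alpha),
      stop("unknown algorithm: ", config$algorithm))
  })
  table <- merge_enrich_terms(results, dag, threshold = config$threshold)
  write_enrich_table(table, file.path(outdir, "enrichment.tsv"))
  cnt <- go_count(table)
  render_barchart(cnt, file.path(outdir, "go_count"), png = config$images)
  ups <- upset_memberships(table)
  render_upset(ups, file.path(outdir, "upset"), png = config$images)
  counts$enriched_terms_per_list <- as.list(cnt)
  counts$enriched_terms_union <- nrow(table)
  out <- list(dag = dag, annot = annot, results = results, table = table)

  ic <- compute_ic(annot, dag, universe = background)
  out$ic <- ic
  sim <- tree <- clusters <- NULL
  if (upto_i >= 2L) {
    # --- semsim ---
    if (nrow(table) >= 2L) {
      sim <- similarity_matrix(dag, ic, table$term_id, measure = config$measure)
      write_sim_matrix(sim, file.path(outdir, "term_similarity.tsv"),
                       file.path(outdir, "term_similarity_long.tsv"))
    } else message("fewer than two enriched terms: similarity stage skipped")
    out$sim <- sim
  }
  if (upto_i >= 3L && !is.null(sim)) {
    # --- cluster ---
    tree <- hclust_ward2(sim)
    write_dendrogram(tree, file.path(outdir, "terms_dendrogram.nwk"),
                     file.path(outdir, "terms_merges.tsv"))
    clusters <- if (identical(config$cut$mode, "static")) {
      cut_static(tree, k = config$cut$k, h = config$cut$h)
    } else {
      cut_dynamic(tree, min_cluster_size = config$cut$min_size,
                  deep_split = config$cut$deep_split)
    }
    write_clusters(clusters, dag, ic, file.path(outdir, "clusters.tsv"))
    counts$clusters <- length(unique(clusters$labels[clusters$labels > 0L]))
    counts$unassigned_terms <- sum(clusters$labels == 0L)
    out$tree <- tree; out$clusters <- clusters
  }
  if (upto_i >= 4L) {
    # --- report ---
    if (!is.null(clusters)) {
      hm <- build_terms_heatmap(table, tree, clusters, ic)
      export_heatmap(hm, file.path(outdir, "terms_heatmap"), png = config$images)
      out$heatmap <- hm
      coords <- mds_classical(sim, dims = min(2L, nrow(sim$sim) - 1L))
      render_mds(coords, file.path(outdir, "terms_mds"), png = config$images)
      n_cl <- counts$clusters
      if (n_cl >= 2L) {
        csim <- cluster_set_matrix(dag, ic, clusters, measure = config$measure,
                                   combine = config$combine)
        write_sim_matrix(csim, file.path(outdir, "cluster_similarity.tsv"))
        ctree <- hclust_ward2(csim)
        write_dendrogram(ctree, file.path(outdir, "clusters_dendrogram.nwk"),
                         file.path(outdir, "clusters_merges.tsv"))
        chm <- build_clusters_heatmap(clusters, ctree, dag, ic)
        export_heatmap(chm, file.path(outdir, "clusters_heatmap"), png = config$images)
        if (n_cl >= 3L) {
          ccoords <- mds_classical(csim, dims = min(2L, n_cl - 1L))
          sizes <- structure(chm$counts, names = chm$row_order)
          render_mds(ccoords, file.path(outdir, "clusters_mds"), sizes = sizes,
                     png = config$images)
        }
        out$cluster_sim <- csim; out$cluster_tree <- ctree; out$cluster_heatmap <- chm
      }
    }
  }
  log <- run_log(
    inputs = c(obo = config$obo, annotations = config$annotations,
               background = config$background,
               unlist(config$lists)),
    params = config[c("namespace", "algorithm", "alpha", "threshold",
                      "measure", "combine", "cut", "annotation_format")],
    counts = counts,
    path = file.path(outdir, "run_log.json"))
  out$log <- log
  invisible(out)
}
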