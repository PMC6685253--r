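#' Assemble the term-level heatmap bundle
#'
#' Joins the merged enrichment table, the dendrogram, the cluster assignment
#' and the IC table into one exportable structure: a -log10(p) matrix (terms
#' x lists) in dendrogram leaf order, an IC sidebar and per-row cluster
#' labels. Terms not tested in a list stay `NA` — "not tested" is rendered
#' distinctly from "not enriched" (p = 1 maps to 0).
#'
#' @param table A `go_enrich_table`.
#' @param tree The term dendrogram (`hclust` over the table's terms).
#' @param assignment A `go_clusters` over the same terms.
#' @param ic A `go_ic`.
#' @return A `go_heatmap` bundle: `row_order`, `row_labels`, `neglog10p`
#'   matrix, `ic`, `cluster` vector, `lists`.
#' @export
build_terms_heatmap <- function(table, tree, assignment, ic) {
  stopifnot(inherits(table, "go_enrich_table"), inherits(tree, "hclust"),
            inherits(assignment, "go_clusters"))
  row_order <- tree$labels[tree$order]
  if (!setequal(row_order, table$term_id))
    stop("dendrogram leaves and enrichment-table terms differ")
  lists <- attr(table, "lists")
  i <- match(row_order, table$term_id)
  m <- vapply(lists, function(lid) -log10(table[[paste0(lid, ".pvalue")]][i]),
              numeric(length(row_order)))
  m <- matrix(m, nrow = length(row_order), dimnames = list(row_order, lists))
  structure(list(row_order = row_order,
                 row_labels = paste0(row_order, " ", table$name[i]),
                 neglog10p = m,
                 ic = unname(ic$ic[row_order]),
                 cluster = unname(assignment$labels[row_order]),
                 lists = lists),
            class = "go_heatmap")
}

#' Assemble the cluster-level heatmap bundle
#'
#' Rows are clusters in cluster-dendrogram leaf order, labeled
#' `"cl<id> <most specific common ancestor name>"`; the value is the member
#' term count.
#'
#' @param assignment The term-level `go_clusters`.
#' @param cluster_tree `hclust` over cluster ids (`"cl<id>"` labels), or
#'   `NULL` to keep ascending cluster-id order.
#' @param dag A `go_dag`.
#' @param ic A `go_ic` or `NULL`.
#' @return A `go_cluster_heatmap` bundle: `row_order`, `row_labels`, `counts`.
#' @export
build_clusters_heatmap <- function(assignment, cluster_tree, dag, ic) {
  stopifnot(inherits(assignment, "go_clusters"))
  lab <- assignment$labels[assignment$labels > 0L]
  sets <- split(names(lab), lab)
  names(sets) <- paste0("cl", names(sets))
  row_order <- if (is.null(cluster_tree)) names(sets)
               else cluster_tree$labels[cluster_tree$order]
  if (!setequal(row_order, names(sets)))
    stop("cluster dendrogram leaves and assignment clusters differ")
  anc <- vapply(sets[row_order], function(m) name_cluster(dag, ic, m), "")
  structure(list(row_order = row_order,
                 row_labels = paste0(row_order, " ", unname(dag$name[anc])),
                 ancestor = unname(anc),
                 counts = lengths(sets[row_order])),
            class = "go_cluster_heatmap")
}

#' Export a heatmap bundle as TSV (+ optional PNG)
#'
#' The TSV twin carries everything the image shows; tests and downstream
#' consumers read the twin, never the pixels.
#'
#' @param bundle A `go_heatmap` or `go_cluster_heatmap`.
#' @param prefix Output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.png` (unless `png = FALSE`).
#' @param png Render the static image too.
#' @export
export_heatmap <- function(bundle, prefix, png = TRUE) {
  tsv <- paste0(prefix, ".tsv")
  if (inherits(bundle, "go_heatmap")) {
    df <- data.frame(term_id = bundle$row_order, label = bundle$row_labels,
                     cluster = bundle$cluster, ic = bundle$ic,
                     bundle$neglog10p, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(format_num_df(df), tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (png) {
      grDevices::png(paste0(prefix, ".png"), width = 900,
                     height = 200 + 14 * nrow(df))
      on.exit(grDevices::dev.off(), add = TRUE)
      m <- bundle$neglog10p
      m[is.na(m)] <- 0
      graphics::par(mar = c(4, 12, 2, 6))
      graphics::image(t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                      axes = FALSE, col = grDevices::hcl.colors(64, "Reds", rev = TRUE),
                      main = "-log10(p) by interest list")
      graphics::axis(2, at = seq(1, 0, length.out = nrow(m)),
                     labels = bundle$row_labels, las = 2, cex.axis = 0.55, tick = FALSE)
      graphics::axis(1, at = seq(0, 1, length.out = ncol(m)),
                     labels = colnames(m), tick = FALSE)
    }
  } else if (inherits(bundle, "go_cluster_heatmap")) {
    df <- data.frame(cluster = bundle$row_order, label = bundle$row_labels,
                     ancestor = bundle$ancestor, n_terms = bundle$counts,
                     stringsAsFactors = FALSE)
    utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    if (png) {
      grDevices::png(paste0(prefix, ".png"), width = 900,
                     height = 200 + 22 * nrow(df))
      on.exit(grDevices::dev.off(), add = TRUE)
      graphics::par(mar = c(4, 18, 2, 2))
      graphics::barplot(rev(bundle$counts), names.arg = rev(bundle$row_labels),
                        horiz = TRUE, las = 1, cex.names = 0.6,
                        xlab = "GO terms in cluster")
    }
  } else stop("not a heatmap bundle")
  invisible(tsv)
}

#' Render the enriched-term count barchart (data twin + PNG)
#'
#' @param counts Named vector from [go_count()].
#' @param prefix Output prefix (`.tsv`, `.json`, `.png`).
#' @param png Render the image.
#' @export
render_barchart <- function(counts, prefix, png = TRUE) {
  df <- data.frame(list_id = names(counts), enriched_terms = unname(counts),
                   stringsAsFactors = FALSE)
  utils::write.table(df, paste0(prefix, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_json_stable(as.list(counts), paste0(prefix, ".json"))
  if (png) {
    grDevices::png(paste0(prefix, ".png"), width = 600, height = 400)
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::barplot(counts, ylab = "enriched GO terms", las = 2)
  }
  invisible(paste0(prefix, ".tsv"))
}

#' Render the upset summary (data twin + PNG)
#'
#' @param memberships Output of [upset_memberships()].
#' @inheritParams render_barchart
#' @export
render_upset <- function(memberships, prefix, png = TRUE) {
  m <- memberships$membership
  df <- data.frame(term_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, paste0(prefix, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_json_stable(as.list(memberships$counts), paste0(prefix, ".json"))
  if (png && length(memberships$counts)) {
    grDevices::png(paste0(prefix, ".png"), width = 700, height = 400)
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::par(mar = c(10, 4, 2, 2))
    graphics::barplot(memberships$counts, las = 2, cex.names = 0.7,
                      ylab = "GO terms", main = "terms per intersection pattern")
  }
  invisible(paste0(prefix, ".tsv"))
}

#' Render the MDS scatter (data twin + PNG)
#'
#' Dot sizes are proportional to cluster sizes when `sizes` is given,
#' mirroring the cluster-level MDS view.
#'
#' @param coords Matrix from [mds_classical()] (rownames = item ids).
#' @param sizes Optional named numeric vector of point weights.
#' @inheritParams render_barchart
#' @export
render_mds <- function(coords, prefix, sizes = NULL, png = TRUE) {
  df <- data.frame(id = rownames(coords), coords, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(sizes)) df$size <- unname(sizes[rownames(coords)])
  utils::write.table(format_num_df(df), paste0(prefix, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (png) {
    grDevices::png(paste0(prefix, ".png"), width = 600, height = 600)
    on.exit(grDevices::dev.off(), add = TRUE)
    cex <- if (is.null(sizes)) 1 else 0.8 + 2 * sizes[rownames(coords)] / max(sizes)
    graphics::plot(coords[, 1L], coords[, 2L], cex = cex, pch = 19,
                   col = grDevices::adjustcolor("steelblue", 0.7),
                   xlab = colnames(coords)[1L], ylab = colnames(coords)[2L])
    graphics::text(coords[, 1L], coords[, 2L], rownames(coords), pos = 3, cex = 0.6)
  }
  invisible(paste0(prefix, ".tsv"))
}

#' Write the merged enrichment table as TSV
#'
#' @param table A `go_enrich_table`.
#' @param path Output path. A header comment line records the producing
#'   algorithm per list and the merge threshold.
#' @export
write_enrich_table <- function(table, path) {
  stopifnot(inherits(table, "go_enrich_table"))
  alg <- attr(table, "algorithm")
  hdr <- sprintf("# merge threshold=%g; algorithm: %s", attr(table, "threshold"),
                 paste(sprintf("%s=%s", names(alg), alg), collapse = ", "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format_num_df(as.data.frame(table)), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Structured run log
#'
#' Captures input digests, all thresholds/measures/seeds and per-stage counts
#' so a run is traceable end to end. Deterministic except for the `timestamp`
#' field.
#'
#' @param inputs Named character vector of input file paths (digested with
#'   md5 when they exist).
#' @param params Named list of effective parameters.
#' @param counts Named list of per-stage result counts.
#' @param path Optional JSON output path.
#' @param timestamp Include a wall-clock timestamp field.
#' @return The run-log list, invisibly if written.
#' @export
run_log <- function(inputs = character(0), params = list(), counts = list(),
                    path = NULL, timestamp = TRUE) {
  digests <- lapply(inputs, function(f) {
    if (length(f) == 1L && file.exists(f)) unname(tools::md5sum(f)) else NA_character_
  })
  log <- list(inputs = as.list(inputs), input_md5 = digests,
              parameters = params, counts = counts)
  if (timestamp) log$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  if (!is.null(path)) {
    write_json_stable(log, path)
    return(invisible(log))
  }
  log
}

# stable JSON writer (fixed precision-free representation, unboxed scalars)
write_json_stable <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  invisible(path)
}
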