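#' Ward (ward.D2) hierarchical clustering of a similarity/distance matrix
#'
#' Agglomerative clustering under Ward's minimum-variance criterion in its D2
#' form: the Lance-Williams update runs on squared dissimilarities and merge
#' heights are reported on the original scale (square roots). Deterministic
#' for fixed input.
#'
#' @param d A `go_sim` (its distance view 1 - s is used), a `dist`, or a
#'   square symmetric matrix with zero diagonal.
#' @return An `hclust` object (merge matrix, heights, leaf order, labels).
#' @export
hclust_ward2 <- function(d) {
  if (inherits(d, "go_sim")) d <- sim_dist(d)
  if (is.matrix(d)) {
    if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-12) || any(diag(d) != 0))
      stop("distance matrix must be square and symmetric with zero diagonal")
    d <- stats::as.dist(d)
  }
  if (!inherits(d, "dist")) stop("d must be a go_sim, dist or matrix")
  if (attr(d, "Size") < 2L) stop("need at least two leaves to cluster")
  stats::hclust(d, method = "ward.D2")
}

#' Static dendrogram cut
#'
#' Standard cut at a cluster count `k` or height `h`. Cluster labels are
#' renumbered by order of first appearance along the dendrogram leaf order,
#' so label 1 is always the leftmost displayed cluster.
#'
#' @param tree An `hclust` object.
#' @param k Number of clusters (exclusive with `h`).
#' @param h Cut height (exclusive with `k`).
#' @return A `go_clusters` object: `labels` (leaf id -> positive integer),
#'   `mode = "static"`, parameters.
#' @export
cut_static <- function(tree, k = NULL, h = NULL) {
  stopifnot(inherits(tree, "hclust"))
  if (is.null(k) == is.null(h)) stop("supply exactly one of k or h")
  raw <- stats::cutree(tree, k = k, h = h)
  leaf_order <- tree$labels[tree$order]
  labels <- renumber_by_leaf_order(raw, leaf_order)
  structure(list(labels = labels, mode = "static",
                 params = list(k = k, h = h)),
            class = "go_clusters")
}

# relabel cluster ids 1..K by first appearance in dendrogram display order
renumber_by_leaf_order <- function(raw, leaf_order) {
  first_seen <- unique(raw[leaf_order])
  out <- match(raw, first_seen)
  out[raw == 0L] <- 0L
  structure(as.integer(out), names = names(raw))
}

#' Dynamic dendrogram cut (adaptive branch detection)
#'
#' Adaptive alternative to a fixed-height cut, in the spirit of the dynamic
#' tree cut's "tree" mode: clusters are the maximal branches whose merge
#' profile separates them from their surroundings, operationalised as the
#' branches lying entirely below an adaptive cut height
#' `h0 = frac(deep_split) * max(height)` with
#' `frac = 0.95, 0.90, 0.85, 0.80, 0.75` for `deep_split = 0..4` — every
#' merge above `h0` only joins such branches to their surroundings.
#' `deep_split` therefore tunes how eagerly the tree is broken up
#' (0 = most conservative, 4 = most eager). Branches smaller than
#' `min_cluster_size` are left unassigned (label 0). Deterministic.
#'
#' @param tree An `hclust` object.
#' @param min_cluster_size Minimum leaves per cluster (>= 1).
#' @param deep_split Split sensitivity, integer 0-4.
#' @return A `go_clusters` object (`mode = "dynamic"`); label 0 marks
#'   unassigned leaves.
#' @export
cut_dynamic <- function(tree, min_cluster_size = 2, deep_split = 2) {
  stopifnot(inherits(tree, "hclust"))
  if (min_cluster_size < 1) stop("min_cluster_size must be >= 1")
  if (!deep_split %in% 0:4) stop("deep_split must be an integer in 0..4")
  frac <- c(0.95, 0.90, 0.85, 0.80, 0.75)[deep_split + 1L]
  h0 <- frac * max(tree$height)
  raw <- stats::cutree(tree, h = h0)
  sizes <- table(raw)
  raw[raw %in% as.integer(names(sizes)[sizes < min_cluster_size])] <- 0L
  labels <- renumber_by_leaf_order(raw, tree$labels[tree$order])
  structure(list(labels = labels, mode = "dynamic",
                 params = list(min_cluster_size = min_cluster_size,
                               deep_split = deep_split, cut_height = h0)),
            class = "go_clusters")
}

#' Name a cluster by its most specific common ancestor
#'
#' Among the (reflexive) common ancestors of all member terms, picks the one
#' with maximal longest-path level — the deepest, hence most specific — with
#' ties broken first by maximal IC, then by lexicographic id. A singleton
#' cluster is named by its own term.
#'
#' @param dag A `go_dag`.
#' @param ic A `go_ic` (may be `NULL`: IC tie-break then skipped).
#' @param members Character vector of member term ids.
#' @return A term id.
#' @export
name_cluster <- function(dag, ic, members) {
  cands <- common_ancestors(dag, members)
  if (length(cands) == 0L) stop("member terms share no common ancestor")
  ns <- dag$namespace[[resolve_id(dag, members[1L])]]
  lev <- term_levels(dag, ns)[cands]
  cands <- sort(cands[lev == max(lev)])
  if (length(cands) > 1L && !is.null(ic)) {
    icv <- ic$ic[cands]
    icv[is.na(icv)] <- -Inf
    cands <- cands[icv == max(icv)]
  }
  cands[1L]
}

#' Cluster-by-cluster similarity matrix
#'
#' Applies the term-set similarity (default best-match average) to every pair
#' of clusters from an assignment; unassigned leaves (label 0) are excluded.
#' Cluster ids become `"cl<label>"`.
#'
#' @param dag A `go_dag`.
#' @param ic A `go_ic` (unused for `measure = "wang"`).
#' @param assignment A `go_clusters`.
#' @param measure Pairwise term measure.
#' @param combine Set combination rule; the workflow default is `"BMA"`.
#' @param wang_weights Relation weights for Wang's method.
#' @return A `go_sim` over clusters.
#' @export
cluster_set_matrix <- function(dag, ic, assignment,
                               measure = c("wang", "resnik", "lin", "rel", "jiang"),
                               combine = "BMA",
                               wang_weights = c(is_a = 0.8, part_of = 0.6)) {
  stopifnot(inherits(assignment, "go_clusters"))
  lab <- assignment$labels
  lab <- lab[lab > 0L]
  if (length(lab) == 0L) stop("no assigned leaves in the cluster assignment")
  sets <- split(names(lab), lab)
  names(sets) <- paste0("cl", names(sets))
  similarity_matrix(dag, ic, sets, measure = measure, combine = combine,
                    wang_weights = wang_weights)
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared distance matrix, eigendecomposes, and returns
#' the top-`dims` coordinates scaled by the square roots of the eigenvalues.
#' Negative eigenvalues (non-Euclidean distortion) are truncated to zero and
#' their relative magnitude is reported in the `distortion` attribute.
#'
#' @param d A `go_sim`, `dist` or square symmetric matrix.
#' @param dims Embedding dimension.
#' @return Numeric matrix (items x dims) with a `distortion` attribute: the
#'   fraction of total absolute eigenvalue mass carried by truncated negative
#'   eigenvalues.
#' @export
mds_classical <- function(d, dims = 2) {
  if (inherits(d, "go_sim")) d <- sim_dist(d)
  if (is.matrix(d)) d <- stats::as.dist(d)
  n <- attr(d, "Size")
  if (dims >= n) stop("dims must be smaller than the number of items")
  fit <- stats::cmdscale(d, k = dims, eig = TRUE)
  coords <- fit$points
  if (ncol(coords) < dims)  # degenerate configurations can drop dimensions
    coords <- cbind(coords, matrix(0, nrow(coords), dims - ncol(coords)))
  neg <- fit$eig[fit$eig < 0]
  distortion <- if (length(neg)) sum(abs(neg)) / sum(abs(fit$eig)) else 0
  if (distortion > 1e-8)
    message(sprintf("MDS: truncated negative eigenvalues (distortion %.3g)", distortion))
  colnames(coords) <- paste0("dim", seq_len(dims))
  attr(coords, "distortion") <- distortion
  coords
}

#' Serialize a dendrogram as Newick and a merge-table TSV
#'
#' @param tree An `hclust`.
#' @param newick_path Output Newick file (heights become branch lengths).
#' @param merge_path Optional merge-table TSV (step, left, right, height,
#'   size). Negative left/right values index leaves, positive values earlier
#'   merge steps, following the `hclust` convention.
#' @export
write_dendrogram <- function(tree, newick_path, merge_path = NULL) {
  stopifnot(inherits(tree, "hclust"))
  phy <- ape::as.phylo(tree)
  ape::write.tree(phy, file = newick_path)
  if (!is.null(merge_path)) {
    sizes <- integer(nrow(tree$merge))
    for (i in seq_len(nrow(tree$merge))) {
      s <- function(v) if (v < 0L) 1L else sizes[v]
      sizes[i] <- s(tree$merge[i, 1L]) + s(tree$merge[i, 2L])
    }
    df <- data.frame(step = seq_len(nrow(tree$merge)),
                     left = tree$merge[, 1L], right = tree$merge[, 2L],
                     height = tree$height, size = sizes)
    utils::write.table(format_num_df(df), merge_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(newick_path)
}

#' Write a cluster assignment as TSV
#'
#' Columns: term_id, cluster, cluster_name (ancestor term id),
#' cluster_name_label (ancestor description).
#'
#' @param assignment A `go_clusters`.
#' @param dag A `go_dag`.
#' @param ic A `go_ic` or `NULL`.
#' @param path Output TSV path.
#' @export
write_clusters <- function(assignment, dag, ic, path) {
  stopifnot(inherits(assignment, "go_clusters"))
  lab <- assignment$labels
  cl_name <- rep(NA_character_, length(lab))
  for (cl in sort(unique(lab[lab > 0L]))) {
    nm <- name_cluster(dag, ic, names(lab)[lab == cl])
    cl_name[lab == cl] <- nm
  }
  df <- data.frame(term_id = names(lab), cluster = unname(lab),
                   cluster_name = cl_name,
                   cluster_name_label = ifelse(is.na(cl_name), NA_character_,
                                               unname(dag$name[cl_name])),
                   stringsAsFactors = FALSE)
  df <- df[order(df$term_id), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.go_clusters <- function(x, ...) {
  k <- length(unique(x$labels[x$labels > 0L]))
  cat("GO cluster assignment (", x$mode, "): ", k, " clusters over ",
      length(x$labels), " leaves",
      if (any(x$labels == 0L)) paste0(" (", sum(x$labels == 0L), " unassigned)") else "",
      "\n", sep = "")
  invisible(x)
}
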