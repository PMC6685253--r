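#' Information content of annotated terms
#'
#' IC(t) = -ln p(t), where p(t) is the fraction of the annotation corpus
#' carrying term t after true-path propagation: |genes(t)| / |genes(root)|.
#' The namespace root has IC 0; terms with zero annotation get no entry.
#' Natural log (nats) throughout.
#'
#' @param annot A `go_annotation`.
#' @param dag A `go_dag`.
#' @param universe Corpus gene set; defaults to every annotated gene in
#'   `annot` (the analysis universe).
#' @return A `go_ic` object: `ic` and `p` (named numeric vectors over
#'   annotated terms), `corpus_size` (gene count at the root), `max_ic`
#'   (largest finite IC), `root`, `namespace`.
#' @export
compute_ic <- function(annot, dag, universe = names(annot$direct)) {
  annot <- propagate(annot, dag)
  idx <- term_gene_index(annot, universe)
  if (length(idx) == 0L) stop("empty annotation corpus: no annotated gene in universe")
  root <- dag$roots[[annot$namespace]]
  counts <- lengths(idx)
  corpus <- counts[[root]]
  p <- counts / corpus
  structure(list(ic = -log(p), p = p, corpus_size = corpus,
                 max_ic = max(-log(p)), root = root, namespace = annot$namespace),
            class = "go_ic")
}

ic_lookup <- function(ic, t) {
  v <- ic$ic[t]
  if (is.na(v)) stop("term ", t, " has no information content (unannotated in corpus)")
  unname(v)
}

#' Most informative common ancestor of two terms
#'
#' The reflexive common ancestor with maximal IC; ties go to the
#' lexicographically smallest id so results are reproducible.
#'
#' @param dag A `go_dag`.
#' @param ic A `go_ic`.
#' @param a,b Term ids.
#' @return A term id.
#' @export
mica <- function(dag, ic, a, b) {
  a <- resolve_id(dag, a); b <- resolve_id(dag, b)
  cands <- intersect(c(a, ancestors(dag, a)), c(b, ancestors(dag, b)))
  cands <- cands[cands %in% names(ic$ic)]
  if (length(cands) == 0L)
    stop("no annotated common ancestor for ", a, " and ", b)
  cands <- sort(cands)
  cands[which.max(ic$ic[cands])]
}

#' Pairwise semantic similarity between two GO terms
#'
#' Five measures. IC-based (with `m` = the most informative common ancestor):
#' * `resnik`: IC(m) / max_ic — normalised by the corpus maximum so the value
#'   lies in \[0,1\] and 1 - s is a usable distance;
#' * `lin`: 2 IC(m) / (IC(a) + IC(b)), defined as 0 when both terms are the
#'   root (zero denominator);
#' * `rel`: Lin weighted by (1 - p(m)) (Schlicker's relevance);
#' * `jiang`: 1 - min(1, IC(a) + IC(b) - 2 IC(m)) — the bounded form of the
#'   Jiang–Conrath distance;
#'
#' and the purely graph-based `wang` (see [sim_wang()]), which needs no IC.
#'
#' @param dag A `go_dag`.
#' @param ic A `go_ic` (ignored by `wang`).
#' @param a,b Term ids.
#' @param measure One of `"resnik"`, `"lin"`, `"rel"`, `"jiang"`, `"wang"`.
#' @param wang_weights Relation weights for Wang's method.
#' @return Similarity in \[0, 1\].
#' @export
term_sim <- function(dag, ic, a, b,
                     measure = c("wang", "resnik", "lin", "rel", "jiang"),
                     wang_weights = c(is_a = 0.8, part_of = 0.6)) {
  measure <- match.arg(measure)
  make_pair_sim(dag, ic, measure, wang_weights)(a, b)
}

# pairwise-similarity closure with a per-term cache (Wang S-value profiles /
# reflexive ancestor closures), shared across all pairs of one matrix build
make_pair_sim <- function(dag, ic, measure, wang_weights) {
  cache <- new.env(parent = emptyenv())
  memo <- function(key, value_fn) {
    if (is.null(cache[[key]])) cache[[key]] <- value_fn()
    cache[[key]]
  }
  if (measure == "wang") {
    return(function(a, b) {
      a <- resolve_id(dag, a); b <- resolve_id(dag, b)
      if (a == b) return(1)
      wang_sim_from_profiles(memo(a, function() wang_svalues(dag, a, wang_weights)),
                             memo(b, function() wang_svalues(dag, b, wang_weights)))
    })
  }
  closure <- function(t) memo(t, function() c(t, ancestors(dag, t)))
  function(a, b) {
    a <- resolve_id(dag, a); b <- resolve_id(dag, b)
    ic_a <- ic_lookup(ic, a); ic_b <- ic_lookup(ic, b)
    cands <- intersect(closure(a), closure(b))
    cands <- cands[cands %in% names(ic$ic)]
    if (length(cands) == 0L)
      stop("no annotated common ancestor for ", a, " and ", b)
    cands <- sort(cands)
    m <- cands[which.max(ic$ic[cands])]
    ic_m <- ic_lookup(ic, m)
    s <- switch(measure,
      resnik = if (ic$max_ic > 0) ic_m / ic$max_ic else 0,
      lin = if (ic_a + ic_b > 0) 2 * ic_m / (ic_a + ic_b) else 0,
      rel = (if (ic_a + ic_b > 0) 2 * ic_m / (ic_a + ic_b) else 0) * (1 - unname(ic$p[m])),
      jiang = 1 - min(1, ic_a + ic_b - 2 * ic_m))
    min(max(s, 0), 1)
  }
}

# semantic contribution (S-value) profile of a term over its ancestor sub-DAG;
# children are processed before parents via a local topological (Kahn) order
wang_svalues <- function(dag, t, weights) {
  g <- induced_ancestor_graph(dag, t, relations = names(weights))
  nodes <- g$nodes
  s <- structure(rep(0, length(nodes)), names = nodes)
  s[t] <- 1
  if (length(nodes) > 1L) {
    indeg <- structure(integer(length(nodes)), names = nodes)
    tab <- table(g$edges$parent)
    indeg[names(tab)] <- as.integer(tab)   # unresolved sub-DAG children per node
    queue <- sort(nodes[indeg == 0L])      # leaves of the sub-DAG (t itself)
    while (length(queue)) {
      node <- queue[1L]; queue <- queue[-1L]
      if (node != t) {
        inc <- g$edges[g$edges$parent == node, , drop = FALSE]
        s[node] <- max(weights[inc$relation] * s[inc$child])
      }
      out <- g$edges$parent[g$edges$child == node]
      indeg[out] <- indeg[out] - 1L
      queue <- sort(c(queue, out[indeg[out] == 0L]))
    }
  }
  s
}

wang_sim_from_profiles <- function(sa, sb) {
  shared <- intersect(names(sa), names(sb))
  min(max(sum(sa[shared] + sb[shared]) / (sum(sa) + sum(sb)), 0), 1)
}

#' Wang's graph-based semantic similarity
#'
#' Each term's meaning is summarised by semantic contributions (S-values)
#' over its ancestor sub-DAG: S(t)=1 at the term itself and, moving rootward,
#' S(node) = max over sub-DAG children of weight(relation) * S(child), with
#' the canonical weights is_a = 0.8 and part_of = 0.6. The similarity of two
#' terms is the summed S-values over their shared ancestors relative to the
#' two total semantic values. Purely topological: annotations play no role.
#'
#' @param dag A `go_dag`.
#' @param a,b Term ids.
#' @param weights Named relation -> contribution factor in (0, 1).
#' @return Similarity in (0, 1]; exactly 1 for a term against itself.
#' @export
sim_wang <- function(dag, a, b, weights = c(is_a = 0.8, part_of = 0.6)) {
  a <- resolve_id(dag, a); b <- resolve_id(dag, b)
  wang_sim_from_profiles(wang_svalues(dag, a, weights),
                         wang_svalues(dag, b, weights))
}

#' Similarity between two sets of GO terms
#'
#' With M the pairwise similarity matrix between the sets:
#' `max` = max(M); `avg` = mean(M);
#' `rcmax` = the larger of the two directional means of row/column maxima;
#' `BMA` = (sum of row maxima + sum of column maxima) / (m + n), i.e. each
#' term's best match in the other set, averaged symmetrically.
#'
#' @param dag,ic,measure,wang_weights As in [term_sim()].
#' @param s1,s2 Character vectors of term ids (non-empty).
#' @param combine One of `"BMA"`, `"max"`, `"avg"`, `"rcmax"`.
#' @return Similarity in \[0, 1\].
#' @export
termset_sim <- function(dag, ic, s1, s2,
                        measure = c("wang", "resnik", "lin", "rel", "jiang"),
                        combine = c("BMA", "max", "avg", "rcmax"),
                        wang_weights = c(is_a = 0.8, part_of = 0.6)) {
  measure <- match.arg(measure)
  combine <- match.arg(combine)
  if (length(s1) == 0L || length(s2) == 0L) stop("empty term set")
  pair_sim <- make_pair_sim(dag, ic, measure, wang_weights)
  M <- outer(seq_along(s1), seq_along(s2),
             Vectorize(function(i, j) pair_sim(s1[i], s2[j])))
  combine_matrix(M, combine)
}

combine_matrix <- function(M, combine) {
  switch(combine,
    max = max(M),
    avg = mean(M),
    rcmax = max(mean(apply(M, 1L, max)), mean(apply(M, 2L, max))),
    BMA = (sum(apply(M, 1L, max)) + sum(apply(M, 2L, max))) / (nrow(M) + ncol(M)))
}

#' Similarity matrix over terms or term sets
#'
#' Evaluates all pairs (terms, or named term sets for cluster-level
#' similarity), clamps to \[0, 1\] against floating-point rounding, and
#' returns a symmetric matrix with unit diagonal plus its distance view
#' d = 1 - s (see [sim_dist()]).
#'
#' @param dag A `go_dag`.
#' @param ic A `go_ic` (may be `NULL` for `measure = "wang"`).
#' @param items Character vector of term ids, or a named list of term-id
#'   vectors (term sets).
#' @param measure Pairwise measure name.
#' @param combine Set-combination rule (used only for term sets).
#' @param wang_weights Relation weights for Wang's method.
#' @return A `go_sim` object.
#' @export
similarity_matrix <- function(dag, ic, items,
                              measure = c("wang", "resnik", "lin", "rel", "jiang"),
                              combine = c("BMA", "max", "avg", "rcmax"),
                              wang_weights = c(is_a = 0.8, part_of = 0.6)) {
  measure <- match.arg(measure)
  combine <- match.arg(combine)
  is_sets <- is.list(items)
  ids <- if (is_sets) names(items) else items
  if (length(ids) < 2L) stop("need at least two items for a similarity matrix")
  if (is_sets && (is.null(ids) || any(!nzchar(ids)))) stop("term sets must be named")
  k <- length(ids)
  S <- diag(1, k)
  dimnames(S) <- list(ids, ids)
  pair_sim <- make_pair_sim(dag, ic, measure, wang_weights)
  pairfun <- if (is_sets) {
    function(i, j) {
      s1 <- items[[i]]; s2 <- items[[j]]
      if (length(s1) == 0L || length(s2) == 0L) stop("empty term set")
      M <- outer(seq_along(s1), seq_along(s2),
                 Vectorize(function(a, b) pair_sim(s1[a], s2[b])))
      combine_matrix(M, combine)
    }
  } else {
    function(i, j) pair_sim(items[i], items[j])
  }
  for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
    s <- min(max(pairfun(i, j), 0), 1)
    S[i, j] <- s; S[j, i] <- s
  }
  structure(list(sim = S, measure = measure,
                 combine = if (is_sets) combine else NA_character_,
                 items = if (is_sets) items else NULL),
            class = "go_sim")
}

#' Distance view of a similarity matrix
#'
#' @param x A `go_sim`.
#' @return A `dist` object with d = 1 - s.
#' @export
sim_dist <- function(x) {
  stopifnot(inherits(x, "go_sim"))
  stats::as.dist(1 - x$sim)
}

#' Write a similarity matrix as TSV (square and long form)
#'
#' @param x A `go_sim`.
#' @param path Output TSV path (square matrix, ids as header row/column).
#' @param long_path Optional path for the long-format triplets
#'   (item_a, item_b, similarity).
#' @export
write_sim_matrix <- function(x, path, long_path = NULL) {
  stopifnot(inherits(x, "go_sim"))
  df <- data.frame(id = rownames(x$sim), x$sim, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(format_num_df(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(long_path)) {
    idx <- which(upper.tri(x$sim, diag = TRUE), arr.ind = TRUE)
    long <- data.frame(item_a = rownames(x$sim)[idx[, 1L]],
                       item_b = colnames(x$sim)[idx[, 2L]],
                       similarity = x$sim[idx], stringsAsFactors = FALSE)
    long <- long[order(long$item_a, long$item_b), ]
    utils::write.table(format_num_df(long), long_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

# stable numeric formatting for byte-reproducible TSV output
format_num_df <- function(df) {
  for (cn in names(df)) {
    if (is.numeric(df[[cn]])) df[[cn]] <- formatC(df[[cn]], digits = 15, format = "g")
  }
  df
}

#' @export
print.go_sim <- function(x, ...) {
  cat("GO similarity matrix: ", nrow(x$sim), " x ", ncol(x$sim),
      " (measure=", x$measure,
      if (!is.na(x$combine)) paste0(", combine=", x$combine) else "",
      ")\n", sep = "")
  invisible(x)
}
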