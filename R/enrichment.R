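#' Upper-tail Fisher (hypergeometric) p-value
#'
#' One-sided over-representation probability for a 2x2 table: drawing `n`
#' genes (the interest list) from an annotated universe of `N` genes of which
#' `K` carry the term, the p-value is the probability of observing `x` or
#' more term genes. Computed as a log-space sum of hypergeometric point
#' masses for numerical stability; exact and deterministic.
#'
#' @param x Significant genes annotated to the term.
#' @param n Interest-list size within the annotated universe.
#' @param K Annotated genes for the term in the universe.
#' @param N Annotated-universe size.
#' @return p-value in (0, 1].
#' @examples
#' fisher_upper_tail(4, 5, 4, 10)  # 6/252
#' @export
fisher_upper_tail <- function(x, n, K, N) {
  stopifnot(length(x) == 1L, length(n) == 1L, length(K) == 1L, length(N) == 1L)
  if (is.na(x) || is.na(n) || is.na(K) || is.na(N))
    stop("contingency counts must not be NA")
  if (x < 0 || x > min(n, K) || n > N || K > N || n < 0 || K < 0)
    stop("invalid contingency input: x=", x, " n=", n, " K=", K, " N=", N)
  if (x == 0) return(1)   # upper tail from zero covers all probability mass
  ks <- seq.int(x, min(n, K))
  logp <- lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n)
  m <- max(logp)
  p <- exp(m + log(sum(exp(logp - m))))
  min(p, 1)
}

# shared setup: propagate, restrict to annotated universe, build term index
enrich_setup <- function(interest, universe, annot, dag) {
  if (length(interest) == 0L) stop("empty interest gene list")
  if (length(universe) == 0L) stop("empty universe")
  annot <- propagate(annot, dag)
  annotated_universe <- intersect(universe, names(annot$propagated))
  if (length(annotated_universe) == 0L)
    stop("no universe gene carries any annotation in this namespace")
  idx <- term_gene_index(annot, annotated_universe)
  interest_ann <- intersect(interest, annotated_universe)
  list(annot = annot, universe = annotated_universe, idx = idx,
       interest = interest_ann, n = length(interest_ann),
       N = length(annotated_universe))
}

new_go_enrich <- function(setup, p, algorithm, alpha = NA_real_) {
  terms <- sort(names(setup$idx))
  x <- vapply(setup$idx[terms], function(g) length(intersect(g, setup$interest)), 0L)
  K <- lengths(setup$idx[terms])
  sig <- lapply(setup$idx[terms], function(g) sort(intersect(g, setup$interest)))
  structure(list(term = terms, p = p[terms], x = x, K = K, sig = sig,
                 n = setup$n, N = setup$N,
                 algorithm = algorithm, alpha = alpha),
            class = "go_enrich")
}

#' Classic per-term Fisher enrichment
#'
#' Every term with at least one annotated universe gene is tested
#' independently with [fisher_upper_tail()]. Terms with no annotated gene
#' (K = 0) are skipped, not reported.
#'
#' @param interest Character vector of interest gene ids.
#' @param universe Character vector of background gene ids. Only genes with
#'   at least one annotation count toward `N` (unannotated genes are
#'   uninformative for a test on GO terms).
#' @param annot A `go_annotation`.
#' @param dag A `go_dag`.
#' @return A `go_enrich` object: per-term p-values plus significant/annotated
#'   gene counts and significant gene ids.
#' @export
classic_enrichment <- function(interest, universe, annot, dag) {
  s <- enrich_setup(interest, universe, annot, dag)
  p <- vapply(s$idx, function(genes) {
    fisher_upper_tail(length(intersect(genes, s$interest)),
                      s$n, length(genes), s$N)
  }, 0)
  new_go_enrich(s, p, "classic")
}

#' Topology-aware elim Fisher enrichment
#'
#' Terms are processed bottom-up (decreasing longest-path level, ties by
#' ascending term id). Each term is tested on its annotated genes minus the
#' genes already eliminated at that term; when the resulting p-value falls
#' below `alpha`, all genes annotated to the term are marked eliminated at
#' every ancestor. This removes the inheritance signal a parent receives
#' purely from an already-significant child. Reported significant/annotated
#' counts (and gene ids) are the unreduced per-term values, as in the usual
#' enrichment-table convention; only the p-value reflects elimination.
#'
#' @inheritParams classic_enrichment
#' @param alpha Elimination significance cutoff in (0, 1].
#' @return A `go_enrich` object.
#' @export
elim_enrichment <- function(interest, universe, annot, dag, alpha = 0.01) {
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must be in (0, 1]")
  s <- enrich_setup(interest, universe, annot, dag)
  lev <- term_levels(dag, s$annot$namespace)
  terms <- names(s$idx)
  ord <- terms[order(-lev[terms], terms)]

  eliminated <- new.env(parent = emptyenv())
  anc_cache <- new.env(parent = emptyenv())
  p <- structure(rep(NA_real_, length(terms)), names = terms)
  for (t in ord) {
    genes_t <- s$idx[[t]]
    elim_t <- if (!is.null(eliminated[[t]])) eliminated[[t]] else character(0)
    keep <- setdiff(genes_t, elim_t)
    if (length(keep) == 0L) { p[t] <- 1; next }  # fully eliminated: no evidence left
    x <- length(intersect(keep, s$interest))
    p[t] <- fisher_upper_tail(x, s$n, length(keep), s$N)
    if (p[t] < alpha) {
      if (is.null(anc_cache[[t]])) anc_cache[[t]] <- ancestors(dag, t)
      for (a in anc_cache[[t]]) {
        eliminated[[a]] <- union(if (!is.null(eliminated[[a]])) eliminated[[a]] else character(0),
                                 genes_t)
      }
    }
  }
  new_go_enrich(s, p, "elim", alpha)
}

#' Merge per-list enrichment results into one table
#'
#' Retains the union, over interest lists, of terms with p below `threshold`
#' in at least one list, and reports every retained term's p-value in every
#' list (even where it is above the threshold), together with the gene
#' frequency (significant/annotated, rendered `"x/K"`) and the significant
#' gene ids. P-values are unadjusted for multiple testing: the table is an
#' exploratory mining product, not a confirmatory one.
#'
#' @param results Named list of `go_enrich` objects, one per interest list.
#' @param dag A `go_dag` (term names/namespace metadata).
#' @param threshold Retention p-value cutoff.
#' @return A `go_enrich_table`: a data.frame keyed by term with per-list
#'   column blocks `<list>.pvalue`, `<list>.gene_frequency`,
#'   `<list>.significant_genes`; attributes record the threshold and the
#'   algorithm that produced each run.
#' @export
merge_enrich_terms <- function(results, dag, threshold = 0.01) {
  if (length(results) == 0L) stop("no enrichment results supplied")
  if (is.null(names(results)) || any(!nzchar(names(results))))
    stop("results must be a named list (one name per interest list)")
  if (!(threshold > 0 && threshold <= 1)) stop("threshold must be in (0, 1]")
  retained <- sort(unique(unlist(lapply(results, function(r)
    r$term[r$p < threshold]), use.names = FALSE)))
  tab <- data.frame(term_id = retained,
                    name = unname(dag$name[retained]),
                    namespace = unname(dag$namespace[retained]),
                    stringsAsFactors = FALSE)
  for (lid in names(results)) {
    r <- results[[lid]]
    i <- match(retained, r$term)
    tab[[paste0(lid, ".pvalue")]] <- r$p[i]
    gf <- ifelse(is.na(i), NA_character_, paste0(r$x[i], "/", r$K[i]))
    tab[[paste0(lid, ".gene_frequency")]] <- gf
    tab[[paste0(lid, ".significant_genes")]] <- vapply(seq_along(i), function(k) {
      if (is.na(i[k])) NA_character_ else paste(r$sig[[i[k]]], collapse = ";")
    }, "")
  }
  structure(tab,
            class = c("go_enrich_table", "data.frame"),
            threshold = threshold,
            lists = names(results),
            algorithm = vapply(results, function(r) r$algorithm, ""))
}

#' Enriched-term count per interest list
#'
#' @param table A `go_enrich_table`.
#' @return Named integer vector: list id -> number of terms with p below the
#'   merge threshold in that list.
#' @export
go_count <- function(table) {
  threshold <- attr(table, "threshold")
  vapply(attr(table, "lists"), function(lid) {
    p <- table[[paste0(lid, ".pvalue")]]
    sum(!is.na(p) & p < threshold)
  }, 0L)
}

#' Upset memberships of enriched terms across lists
#'
#' @param table A `go_enrich_table`.
#' @return List with `membership` (binary term x list matrix of sub-threshold
#'   significance) and `counts` (terms per exclusive intersection pattern,
#'   pattern names are `&`-joined list ids).
#' @export
upset_memberships <- function(table) {
  threshold <- attr(table, "threshold")
  lists <- attr(table, "lists")
  m <- vapply(lists, function(lid) {
    p <- table[[paste0(lid, ".pvalue")]]
    as.integer(!is.na(p) & p < threshold)
  }, integer(nrow(table)))
  m <- matrix(m, nrow = nrow(table), dimnames = list(table$term_id, lists))
  pattern <- apply(m, 1L, function(row) paste(lists[row == 1L], collapse = "&"))
  pattern <- pattern[nzchar(pattern)]
  counts <- table(pattern)
  counts <- structure(as.integer(counts), names = names(counts))
  list(membership = m, counts = counts[order(names(counts))])
}

#' @export
print.go_enrich <- function(x, ...) {
  cat("GO enrichment (", x$algorithm,
      if (!is.na(x$alpha)) paste0(", alpha=", x$alpha) else "",
      "): ", length(x$term), " terms tested, n=", x$n, ", N=", x$N, "\n", sep = "")
  invisible(x)
}
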