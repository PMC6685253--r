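ASPECT_TO_NAMESPACE <- c(P = "biological_process",
                         F = "molecular_function",
                         C = "cellular_component")

new_annotation_set <- function(direct, namespace, provenance) {
  direct <- direct[order(names(direct))]
  direct <- lapply(direct, function(x) sort(unique(x)))
  structure(list(direct = direct, propagated = NULL,
                 namespace = namespace, provenance = provenance),
            class = "go_annotation")
}

#' Read gene-to-GO annotations from a GAF 2.x file
#'
#' Keeps rows whose aspect column matches the requested namespace and, if an
#' evidence filter is supplied, whose evidence code is in it. Rows whose
#' qualifier contains `NOT` are discarded (negative annotations). The gene key
#' is column 2 (the unique DB object id), taken verbatim. Obsolete terms are
#' dropped with a warning; alternative ids resolve to their primary term.
#'
#' @param path GAF file path or character vector of lines.
#' @param dag A `go_dag`.
#' @param namespace Namespace to keep (`"biological_process"` etc.).
#' @param evidence_filter Optional character vector of evidence codes to keep;
#'   default `NULL` keeps all codes, computational and experimental alike.
#' @return A `go_annotation` object (direct annotations only; see
#'   [propagate()]).
#' @export
read_gaf <- function(path, dag, namespace, evidence_filter = NULL) {
  lines <- if (length(path) == 1L && !grepl("\n", path) && file.exists(path)) {
    readLines(path, warn = FALSE)
  } else {
    unlist(strsplit(path, "\n", fixed = TRUE), use.names = FALSE)
  }
  src <- if (length(path) == 1L && file.exists(path)) basename(path) else "<in-memory GAF>"
  body_idx <- which(!startsWith(lines, "!") & nzchar(lines))
  body <- lines[body_idx]
  ntab <- nchar(body) - nchar(gsub("\t", "", body, fixed = TRUE))
  bad <- which(ntab != 16L)
  if (length(bad))
    stop("malformed GAF row at line ", body_idx[bad[1L]],
         ": expected 17 columns, found ", ntab[bad[1L]] + 1L)
  fields <- strsplit(body, "\t", fixed = TRUE)
  fields <- lapply(fields, function(f) c(f, rep("", 17L - length(f))))

  gene <- vapply(fields, `[`, "", 2L)
  qualifier <- vapply(fields, `[`, "", 4L)
  go_id <- vapply(fields, `[`, "", 5L)
  evidence <- vapply(fields, `[`, "", 7L)
  aspect <- vapply(fields, `[`, "", 9L)

  keep <- ASPECT_TO_NAMESPACE[aspect] == namespace & !is.na(ASPECT_TO_NAMESPACE[aspect])
  keep <- keep & !grepl("(^|\\|)NOT($|\\|)", qualifier)
  if (!is.null(evidence_filter)) keep <- keep & evidence %in% evidence_filter
  gene <- gene[keep]; go_id <- go_id[keep]

  filt <- filter_terms(go_id, dag, namespace)
  direct <- split(filt$term[filt$keep], gene[filt$keep])
  new_annotation_set(direct, namespace,
                     sprintf("%s (namespace=%s, evidence=%s)", src, namespace,
                             if (is.null(evidence_filter)) "all"
                             else paste(evidence_filter, collapse = "/")))
}

#' Read gene-to-GO annotations from a two-column TSV
#'
#' Columns are `gene_id<TAB>go_id`, no header. Duplicate pairs are stored
#' once; terms outside the requested namespace are dropped with a warning
#' reporting the count.
#'
#' @inheritParams read_gaf
#' @export
read_tsv_annotation <- function(path, dag, namespace) {
  lines <- if (length(path) == 1L && !grepl("\n", path) && file.exists(path)) {
    readLines(path, warn = FALSE)
  } else {
    unlist(strsplit(path, "\n", fixed = TRUE), use.names = FALSE)
  }
  src <- if (length(path) == 1L && file.exists(path)) basename(path) else "<in-memory TSV>"
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  if (length(bad))
    stop("malformed annotation row at line ", bad[1L],
         ": expected 2 tab-separated columns")
  gene <- vapply(fields, `[`, "", 1L)
  go_id <- vapply(fields, `[`, "", 2L)
  filt <- filter_terms(go_id, dag, namespace)
  direct <- split(filt$term[filt$keep], gene[filt$keep])
  new_annotation_set(direct, namespace, sprintf("%s (namespace=%s)", src, namespace))
}

# shared term-level filtering: resolve alt ids, drop obsolete and
# out-of-namespace terms (with counts in the warning)
filter_terms <- function(go_id, dag, namespace) {
  if (!namespace %in% names(dag$roots)) stop("unknown namespace: ", namespace)
  term <- go_id
  is_alt <- term %in% names(dag$alt)
  if (any(is_alt)) {
    message(sum(is_alt), " annotation(s) used alt ids; resolved to primary ids")
    term[is_alt] <- unname(dag$alt[term[is_alt]])
  }
  unknown <- !term %in% dag$ids
  if (any(unknown))
    stop("annotation references unknown GO term(s): ",
         paste(utils::head(unique(term[unknown]), 5), collapse = ", "))
  obsolete <- dag$obsolete[term]
  wrong_ns <- !obsolete & dag$namespace[term] != namespace
  if (any(obsolete))
    warning("dropped ", sum(obsolete), " annotation(s) to obsolete terms")
  if (any(wrong_ns))
    warning("dropped ", sum(wrong_ns), " annotation(s) outside namespace ", namespace)
  list(term = term, keep = !obsolete & !wrong_ns)
}

#' Propagate annotations to ancestors (true-path rule)
#'
#' Each gene annotated to a term is implicitly annotated to every ancestor of
#' that term. Idempotent; the result caches in the `propagated` slot.
#'
#' @param annot A `go_annotation`.
#' @param dag A `go_dag`.
#' @param relations Edge types followed during propagation.
#' @return The `go_annotation` with its `propagated` slot filled.
#' @export
propagate <- function(annot, dag, relations = c("is_a", "part_of")) {
  if (!is.null(annot$propagated)) return(annot)
  terms <- unique(unlist(annot$direct, use.names = FALSE))
  closure <- lapply(terms, function(t) c(t, ancestors(dag, t, relations)))
  names(closure) <- terms
  annot$propagated <- lapply(annot$direct, function(ts)
    sort(unique(unlist(closure[ts], use.names = FALSE))))
  annot
}

#' Genes annotated (after propagation) to a term, within a universe
#'
#' @param annot A `go_annotation` (propagated on the fly if needed —
#'   pass a propagated set to avoid recomputation).
#' @param dag A `go_dag` (used only if propagation is still pending).
#' @param t Term id.
#' @param universe Character vector of gene ids delimiting the search.
#' @return Character vector of gene ids.
#' @export
annotated_genes <- function(annot, dag, t, universe = names(annot$direct)) {
  annot <- propagate(annot, dag)
  t <- resolve_id(dag, t)
  genes <- intersect(universe, names(annot$propagated))
  genes[vapply(annot$propagated[genes], function(ts) t %in% ts, NA)]
}

# reverse index term -> genes over the propagated sets, restricted to a universe
term_gene_index <- function(annot, universe) {
  genes <- intersect(universe, names(annot$propagated))
  pairs_gene <- rep(genes, lengths(annot$propagated[genes]))
  pairs_term <- unlist(annot$propagated[genes], use.names = FALSE)
  split(pairs_gene, pairs_term)
}

#' @export
print.go_annotation <- function(x, ...) {
  n_annot <- length(x$direct)
  cat("GO annotation set (", x$namespace, "): ", n_annot,
      " genes with at least one direct term\n", sep = "")
  cat("  source: ", x$provenance, "\n", sep = "")
  cat("  propagated: ", if (is.null(x$propagated)) "no" else "yes", "\n", sep = "")
  invisible(x)
}
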