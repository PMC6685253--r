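GO_ID_PATTERN <- "^GO:[0-9]{7}$"

#' Parse an OBO 1.2 ontology into a validated DAG
#'
#' Reads `[Term]` stanzas and interprets the tags `id`, `name`, `namespace`,
#' `is_a`, `relationship` (only `part_of`), `is_obsolete` and `alt_id`.
#' Obsolete terms are kept in the term table but stripped of all edges;
#' relationship types other than `is_a`/`part_of` are dropped with a warning,
#' as are (rare) cross-namespace edges. Alternative ids are resolved to their
#' primary id transparently in all later lookups.
#'
#' @param path Path to an OBO 1.2 flat file, or a character vector of lines.
#' @return An object of class `go_dag` with components `ids`, `name`,
#'   `namespace`, `obsolete` (all keyed by term id), `alt` (alt id -> primary
#'   id), `edges` (data.frame child/parent/relation), `roots` (namespace ->
#'   root id) and parent/child adjacency lists.
#' @examples
#' obo <- c("[Term]", "id: GO:0000001", "name: root", "namespace: biological_process",
#'          "[Term]", "id: GO:0000002", "name: child", "namespace: biological_process",
#'          "is_a: GO:0000001 ! root")
#' dag <- parse_obo(obo)
#' ancestors(dag, "GO:0000002")
#' @export
parse_obo <- function(path) {
  lines <- if (length(path) == 1L && !grepl("\n", path) && file.exists(path)) {
    readLines(path, warn = FALSE)
  } else {
    unlist(strsplit(path, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- sub("\\s+$", "", lines)

  # locate [Term] stanzas; anything before the first stanza is header
  starts <- grep("^\\[", lines)
  term_starts <- grep("^\\[Term\\]$", lines)
  if (length(term_starts) == 0L) stop("no [Term] stanzas found in OBO input")
  bounds <- c(starts, length(lines) + 1L)

  ids <- character(0); nm <- character(0); ns <- character(0)
  obs <- logical(0); alt_from <- character(0); alt_to <- character(0)
  e_child <- character(0); e_parent <- character(0); e_rel <- character(0)
  dropped_rel <- character(0)

  for (s in term_starts) {
    e <- min(bounds[bounds > s]) - 1L
    stanza <- lines[seq.int(s + 1L, e)]
    stanza <- stanza[nzchar(stanza) & !startsWith(stanza, "!")]
    tagval <- regmatches(stanza, regexpr(":", stanza), invert = TRUE)
    tags <- vapply(tagval, `[`, "", 1L)
    vals <- sub("^\\s+", "", vapply(tagval, function(x) if (length(x) > 1L) x[2L] else "", ""))
    vals <- sub("\\s*!.*$", "", vals)  # strip trailing OBO comments

    id <- vals[tags == "id"][1L]
    if (is.na(id)) stop("OBO [Term] stanza without id (starting line ", s, ")")
    if (!grepl(GO_ID_PATTERN, id)) stop("malformed term id: '", id, "'")
    ids <- c(ids, id)
    nm[id] <- if (any(tags == "name")) vals[tags == "name"][1L] else ""
    ns[id] <- if (any(tags == "namespace")) vals[tags == "namespace"][1L] else NA_character_
    obsolete <- any(tags == "is_obsolete" & vals == "true")
    obs[id] <- obsolete

    for (a in vals[tags == "alt_id"]) {
      alt_from <- c(alt_from, a); alt_to <- c(alt_to, id)
    }
    if (!obsolete) {
      for (p in vals[tags == "is_a"]) {
        e_child <- c(e_child, id); e_parent <- c(e_parent, p); e_rel <- c(e_rel, "is_a")
      }
      for (r in vals[tags == "relationship"]) {
        parts <- strsplit(r, "\\s+")[[1L]]
        if (parts[1L] == "part_of") {
          e_child <- c(e_child, id); e_parent <- c(e_parent, parts[2L]); e_rel <- c(e_rel, "part_of")
        } else {
          dropped_rel <- c(dropped_rel, parts[1L])
        }
      }
    }
  }

  if (anyDuplicated(ids)) stop("duplicate term ids in OBO: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (length(dropped_rel)) {
    tab <- table(dropped_rel)
    warning("dropped unsupported relationship types: ",
            paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "))
  }

  # validate edge endpoints
  unknown <- setdiff(unique(c(e_child, e_parent)), ids)
  if (length(unknown)) stop("edge references undeclared term(s): ",
                            paste(unknown, collapse = ", "))
  # edges incident to obsolete parents are removed too (obsolete terms carry no edges)
  keep <- !obs[e_child] & !obs[e_parent]
  e_child <- e_child[keep]; e_parent <- e_parent[keep]; e_rel <- e_rel[keep]

  # drop cross-namespace edges
  cross <- ns[e_child] != ns[e_parent]
  cross[is.na(cross)] <- FALSE
  if (any(cross)) {
    warning("dropped ", sum(cross), " cross-namespace edge(s)")
    e_child <- e_child[!cross]; e_parent <- e_parent[!cross]; e_rel <- e_rel[!cross]
  }

  edges <- data.frame(child = e_child, parent = e_parent, relation = e_rel,
                      stringsAsFactors = FALSE)
  edges <- unique(edges)
  alt <- structure(alt_to, names = alt_from)
  if (length(alt) && anyDuplicated(names(alt)))
    stop("alt_id mapped to more than one primary id: ",
         paste(unique(names(alt)[duplicated(names(alt))]), collapse = ", "))

  dag <- build_dag(ids, nm, ns, obs, alt, edges)
  validate_dag(dag)
  dag
}

# assemble adjacency + roots; shared by parse_obo and the fixture generator.
# cycles are checked before root detection: a cycle typically leaves a
# namespace rootless and must be reported as what it is.
build_dag <- function(ids, nm, ns, obs, alt, edges) {
  parents <- split(seq_len(nrow(edges)), factor(edges$child, levels = ids))
  children <- split(seq_len(nrow(edges)), factor(edges$parent, levels = ids))
  dag <- structure(list(ids = ids, name = nm, namespace = ns, obsolete = obs,
                        alt = alt, edges = edges, roots = character(0),
                        parent_idx = parents, child_idx = children),
                   class = "go_dag")
  roots <- character(0)
  for (nsname in unique(stats::na.omit(ns))) {
    cyc <- find_cycle(dag, nsname)
    if (!is.null(cyc))
      stop("cycle detected in namespace '", nsname, "': ",
           paste(cyc, collapse = " -> "))
    members <- ids[!obs[ids] & !is.na(ns[ids]) & ns[ids] == nsname]
    r <- members[lengths(parents[members]) == 0L]
    if (length(r) != 1L)
      stop("namespace '", nsname, "' must have exactly one root, found ",
           length(r), if (length(r)) paste0(": ", paste(r, collapse = ", ")) else "")
    roots[nsname] <- r
  }
  dag$roots <- roots
  dag
}

validate_dag <- function(dag) invisible(dag)

# iterative DFS (white/grey/black); returns one cycle path or NULL
find_cycle <- function(dag, nsname) {
  members <- dag$ids[!dag$obsolete[dag$ids] & !is.na(dag$namespace[dag$ids]) &
                       dag$namespace[dag$ids] == nsname]
  color <- structure(integer(length(members)), names = members)  # 0 white 1 grey 2 black
  for (start in members) {
    if (color[start] != 0L) next
    stack <- list(list(node = start, i = 0L))
    path <- character(0)
    while (length(stack)) {
      fr <- stack[[length(stack)]]
      node <- fr$node
      if (fr$i == 0L) { color[node] <- 1L; path <- c(path, node) }
      pidx <- dag$parent_idx[[node]]
      ps <- dag$edges$parent[pidx]
      if (fr$i < length(ps)) {
        stack[[length(stack)]]$i <- fr$i + 1L
        nxt <- ps[fr$i + 1L]
        if (!nxt %in% members) next
        if (color[nxt] == 1L) {
          k <- match(nxt, path)
          return(c(path[k:length(path)], nxt))
        }
        if (color[nxt] == 0L) stack[[length(stack) + 1L]] <- list(node = nxt, i = 0L)
      } else {
        color[node] <- 2L
        path <- path[-length(path)]
        stack[[length(stack)]] <- NULL
      }
    }
  }
  NULL
}

# resolve an id through the alt_id map; error on unknown ids
resolve_id <- function(dag, t, allow_obsolete = FALSE) {
  if (!t %in% dag$ids) {
    if (t %in% names(dag$alt)) {
      primary <- unname(dag$alt[[t]])
      message("alt id ", t, " resolved to ", primary)
      t <- primary
    } else stop("unknown GO term: ", t)
  }
  if (!allow_obsolete && isTRUE(dag$obsolete[[t]]))
    stop("term ", t, " is obsolete")
  t
}

#' Ancestors of a term
#'
#' All terms reachable from `t` by repeatedly following child-to-parent edges
#' whose relation is in `relations`. The term itself is not included.
#'
#' @param dag A `go_dag`.
#' @param t A term id (alt ids are resolved).
#' @param relations Character vector of edge types to follow.
#' @return Character vector of ancestor term ids (unordered set).
#' @export
ancestors <- function(dag, t, relations = c("is_a", "part_of")) {
  t <- resolve_id(dag, t)
  out <- character(0)
  frontier <- t
  seen <- t
  while (length(frontier)) {
    idx <- unlist(dag$parent_idx[frontier], use.names = FALSE)
    if (length(idx)) idx <- idx[dag$edges$relation[idx] %in% relations]
    nxt <- setdiff(unique(dag$edges$parent[idx]), seen)
    out <- c(out, nxt)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  out
}

#' Descendants of a term
#'
#' Mirror of [ancestors()]: all terms from which `t` is reachable.
#' @inheritParams ancestors
#' @export
descendants <- function(dag, t, relations = c("is_a", "part_of")) {
  t <- resolve_id(dag, t)
  out <- character(0)
  frontier <- t
  seen <- t
  while (length(frontier)) {
    idx <- unlist(dag$child_idx[frontier], use.names = FALSE)
    if (length(idx)) idx <- idx[dag$edges$relation[idx] %in% relations]
    nxt <- setdiff(unique(dag$edges$child[idx]), seen)
    out <- c(out, nxt)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  out
}

#' Ancestor sub-DAG of a term
#'
#' The induced graph on `t` and all its ancestors: exactly the node set used
#' by Wang's semantic-contribution propagation. Edge relation labels are kept.
#'
#' @inheritParams ancestors
#' @return A list with `nodes` (term ids, `t` first) and `edges`
#'   (data.frame child/parent/relation restricted to `nodes`).
#' @export
induced_ancestor_graph <- function(dag, t, relations = c("is_a", "part_of")) {
  t <- resolve_id(dag, t)
  nodes <- c(t, ancestors(dag, t, relations))
  keep <- dag$edges$child %in% nodes & dag$edges$parent %in% nodes &
    dag$edges$relation %in% relations
  list(nodes = nodes, edges = dag$edges[keep, , drop = FALSE])
}

#' Longest-path levels of all terms in a namespace
#'
#' `level(root) = 0`; every other term sits one deeper than its deepest
#' parent. Longest-path (not shortest) grading guarantees children precede
#' parents in the elim bottom-up sweep. The processing order used throughout
#' the package is decreasing level, ties broken by ascending term id.
#'
#' @param dag A `go_dag`.
#' @param namespace Namespace name, e.g. `"biological_process"`.
#' @return Named integer vector, term id -> level.
#' @export
term_levels <- function(dag, namespace) {
  if (!namespace %in% names(dag$roots)) stop("unknown namespace: ", namespace)
  members <- dag$ids[!dag$obsolete[dag$ids] & !is.na(dag$namespace[dag$ids]) &
                       dag$namespace[dag$ids] == namespace]
  lev <- structure(rep(NA_integer_, length(members)), names = members)
  lev[dag$roots[[namespace]]] <- 0L
  # relax repeatedly in a queue; DAG guarantees termination
  pending <- setdiff(members, dag$roots[[namespace]])
  while (length(pending)) {
    progressed <- FALSE
    still <- character(0)
    for (t in pending) {
      pidx <- dag$parent_idx[[t]]
      ps <- dag$edges$parent[pidx]
      ps <- ps[ps %in% members]
      if (length(ps) == 0L) { # disconnected from root: level by definition 0? treat as error
        stop("term ", t, " has no path to the namespace root")
      }
      pl <- lev[ps]
      if (!anyNA(pl)) { lev[t] <- 1L + max(pl); progressed <- TRUE } else still <- c(still, t)
    }
    if (!progressed) stop("could not grade terms (unexpected cycle?): ",
                          paste(utils::head(still, 3), collapse = ", "))
    pending <- still
  }
  lev
}

#' Common ancestors of a set of terms
#'
#' Reflexive intersection: each term contributes itself plus its ancestors,
#' so the common-ancestor set of a singleton contains the term.
#'
#' @param dag A `go_dag`.
#' @param terms Character vector of term ids.
#' @inheritParams ancestors
#' @return Character vector of term ids present in every term's closure.
#' @export
common_ancestors <- function(dag, terms, relations = c("is_a", "part_of")) {
  if (length(terms) == 0L) stop("empty term set")
  closures <- lapply(terms, function(t) c(resolve_id(dag, t), ancestors(dag, t, relations)))
  Reduce(intersect, closures)
}

#' @export
print.go_dag <- function(x, ...) {
  cat("GO DAG:", length(x$ids), "terms (", sum(x$obsolete), "obsolete ),",
      nrow(x$edges), "edges\n")
  for (nsname in names(x$roots))
    cat("  ", nsname, ": root ", x$roots[[nsname]], "\n", sep = "")
  invisible(x)
}
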