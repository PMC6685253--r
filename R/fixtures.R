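#' Specification for a synthetic GO study fixture
#'
#' Bundles every knob of the fixture generator. A fixed `seed` fully
#' determines all three outputs (ontology, annotations, study lists); each
#' component draws from its own derived RNG stream, so regenerating the
#' annotations never perturbs the DAG.
#'
#' Defaults emulate a desk-scale differential-expression study: a 300-term
#' single-namespace DAG of depth 8 with 15% part_of edges, 2000 genes with
#' on average three direct annotations decaying geometrically with term
#' depth, and three interest lists of 200 genes in which the genes of one
#' planted term per list are sampled with 15-fold odds.
#'
#' @param n_terms Number of terms (>= 1; term 1 is the root).
#' @param max_depth Maximum term depth.
#' @param extra_parent_prob Probability a term gets a second parent.
#' @param part_of_fraction Fraction of edges typed `part_of` (rest `is_a`).
#' @param n_genes Number of genes.
#' @param terms_per_gene_lambda Direct annotations per gene are
#'   1 + Poisson(lambda).
#' @param depth_decay Per-depth geometric decay of a term's chance to be
#'   drawn as a direct annotation.
#' @param n_lists Number of interest lists.
#' @param list_size Genes per interest list.
#' @param planted_odds Sampling odds multiplier for genes of the planted term.
#' @param planted_min_genes Guaranteed minimum direct genes per planted term.
#' @param planted_depth Depth at which planted terms are picked.
#' @param namespace Namespace of the synthetic ontology.
#' @param seed Master seed (integer < 2^31).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_terms = 300, max_depth = 8,
                         extra_parent_prob = 0.3, part_of_fraction = 0.15,
                         n_genes = 2000, terms_per_gene_lambda = 2,
                         depth_decay = 0.65,
                         n_lists = 3, list_size = 200,
                         planted_odds = 15, planted_min_genes = 25,
                         planted_depth = 3,
                         namespace = "biological_process", seed = 1) {
  stopifnot(n_terms >= 1, max_depth >= 1, n_genes >= 0, n_lists >= 1)
  structure(list(n_terms = as.integer(n_terms), max_depth = as.integer(max_depth),
                 extra_parent_prob = extra_parent_prob,
                 part_of_fraction = part_of_fraction,
                 n_genes = as.integer(n_genes),
                 terms_per_gene_lambda = terms_per_gene_lambda,
                 depth_decay = depth_decay,
                 n_lists = as.integer(n_lists), list_size = as.integer(list_size),
                 planted_odds = planted_odds,
                 planted_min_genes = as.integer(planted_min_genes),
                 planted_depth = as.integer(planted_depth),
                 namespace = namespace, seed = as.integer(seed)),
            class = "fixture_spec")
}

# one RNG stream per fixture component, derived from the master seed
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + stream * 16807) %% 2147483647)
}

fixture_gene_ids <- function(n) sprintf("gene%05d", seq_len(n))
fixture_term_ids <- function(n) sprintf("GO:%07d", seq_len(n))

#' Generate a synthetic rooted DAG (and optionally its OBO file)
#'
#' Single-namespace DAG, acyclic by construction: every term's parents are
#' drawn only from strictly shallower depths, with the primary parent one
#' level up — so each term's longest-path level equals its assigned depth.
#' Depths 1..max_depth are each guaranteed at least one term.
#'
#' @param spec A `fixture_spec`.
#' @param obo_path Optional path; when given, the DAG is written as OBO 1.2
#'   (round-trips exactly through [parse_obo()]).
#' @return A `go_dag` with a `depth` attribute (named integer).
#' @export
make_dag <- function(spec, obo_path = NULL) {
  set.seed(derive_seed(spec$seed, 1L))
  n <- spec$n_terms
  ids <- fixture_term_ids(n)
  depth <- integer(n)
  if (n > 1L) {
    d_max <- min(spec$max_depth, n - 1L)
    depth[seq.int(2L, 1L + d_max)] <- seq_len(d_max)   # coverage of every depth
    if (n > 1L + d_max)
      depth[seq.int(2L + d_max, n)] <- sample(seq_len(d_max), n - 1L - d_max,
                                              replace = TRUE)
  }
  e_child <- character(0); e_parent <- character(0); e_rel <- character(0)
  pick_rel <- function(k) ifelse(stats::runif(k) < spec$part_of_fraction,
                                 "part_of", "is_a")
  for (i in seq_len(n)[-1L]) {
    d <- depth[i]
    primary_pool <- ids[depth == d - 1L & seq_len(n) < i]  # root covers d == 1
    p1 <- if (length(primary_pool) == 1L) primary_pool else sample(primary_pool, 1L)
    e_child <- c(e_child, ids[i]); e_parent <- c(e_parent, p1)
    e_rel <- c(e_rel, pick_rel(1L))
    if (d > 1L && stats::runif(1) < spec$extra_parent_prob) {
      pool2 <- setdiff(ids[depth < d & seq_len(n) < i], p1)
      pool2 <- setdiff(pool2, ids[1L])   # avoid redundant root edges
      if (length(pool2)) {
        p2 <- if (length(pool2) == 1L) pool2 else sample(pool2, 1L)
        e_child <- c(e_child, ids[i]); e_parent <- c(e_parent, p2)
        e_rel <- c(e_rel, pick_rel(1L))
      }
    }
  }
  nm <- structure(sprintf("synthetic term %d (depth %d)", seq_len(n), depth),
                  names = ids)
  nm[ids[1L]] <- "synthetic namespace root"
  ns <- structure(rep(spec$namespace, n), names = ids)
  obs <- structure(rep(FALSE, n), names = ids)
  edges <- data.frame(child = e_child, parent = e_parent, relation = e_rel,
                      stringsAsFactors = FALSE)
  dag <- build_dag(ids, nm, ns, obs, structure(character(0), names = character(0)),
                   edges)
  validate_dag(dag)
  attr(dag, "depth") <- structure(depth, names = ids)
  if (!is.null(obo_path)) write_obo(dag, obo_path)
  dag
}

#' Write a `go_dag` as an OBO 1.2 flat file
#'
#' @param dag A `go_dag`.
#' @param path Output path.
#' @export
write_obo <- function(dag, path) {
  out <- c("format-version: 1.2", "ontology: synthetic")
  for (id in sort(dag$ids)) {
    stanza <- c("", "[Term]",
                paste0("id: ", id),
                paste0("name: ", dag$name[[id]]),
                paste0("namespace: ", dag$namespace[[id]]))
    alts <- sort(names(dag$alt)[dag$alt == id])
    if (length(alts))
      stanza <- c(stanza, paste0("alt_id: ", alts, recycle0 = TRUE))
    if (isTRUE(dag$obsolete[[id]])) stanza <- c(stanza, "is_obsolete: true")
    e <- dag$edges[dag$edges$child == id, , drop = FALSE]
    e <- e[order(e$parent, e$relation), , drop = FALSE]
    for (j in seq_len(nrow(e))) {
      stanza <- c(stanza, if (e$relation[j] == "is_a")
        paste0("is_a: ", e$parent[j], " ! ", dag$name[[e$parent[j]]])
        else paste0("relationship: part_of ", e$parent[j], " ! ", dag$name[[e$parent[j]]]))
    }
    out <- c(out, stanza)
  }
  writeLines(out, path)
  invisible(path)
}

# planted terms: deterministically the first n_lists ids at the planted depth
# (falling back to the deepest available depth with enough terms)
planted_terms <- function(spec, dag) {
  depth <- attr(dag, "depth")
  d <- min(spec$planted_depth, max(depth))
  cands <- sort(names(depth)[depth == d])
  while (length(cands) < spec$n_lists && d > 1L) {
    d <- d - 1L
    cands <- sort(unique(c(cands, names(depth)[depth == d])))
  }
  if (length(cands) < spec$n_lists)
    stop("DAG too small to plant ", spec$n_lists, " terms")
  cands[seq_len(spec$n_lists)]
}

#' Generate synthetic annotations (and optionally a GAF 2.2 file)
#'
#' Every gene receives `1 + Poisson(lambda)` direct terms, sampled with
#' probability proportional to `depth_decay^depth` — shallow terms collect
#' more annotations, mirroring real corpora. Planted terms are topped up to
#' at least `planted_min_genes` direct genes so the planted signal has a
#' stable annotation base.
#'
#' @param spec A `fixture_spec`.
#' @param dag The DAG from [make_dag()].
#' @param gaf_path Optional GAF 2.2 output path (round-trips through
#'   [read_gaf()]).
#' @return A `go_annotation` with attribute `planted` (term ids, one per
#'   interest list).
#' @export
make_annotations <- function(spec, dag, gaf_path = NULL) {
  set.seed(derive_seed(spec$seed, 2L))
  genes <- fixture_gene_ids(spec$n_genes)
  depth <- attr(dag, "depth")
  pool <- setdiff(dag$ids, dag$roots[[spec$namespace]])
  direct <- list()
  if (spec$n_genes > 0L && length(pool)) {
    w <- spec$depth_decay ^ depth[pool]
    k <- 1L + stats::rpois(spec$n_genes, spec$terms_per_gene_lambda)
    k <- pmin(k, length(pool))
    direct <- lapply(seq_len(spec$n_genes), function(i)
      sample(pool, k[i], prob = w))
    names(direct) <- genes
    planted <- planted_terms(spec, dag)
    for (t in planted) {
      have <- genes[vapply(direct, function(ts) t %in% ts, NA)]
      need <- spec$planted_min_genes - length(have)
      if (need > 0L) {
        extra <- sample(setdiff(genes, have), min(need, spec$n_genes - length(have)))
        for (g in extra) direct[[g]] <- c(direct[[g]], t)
      }
    }
  } else planted <- character(0)
  annot <- new_annotation_set(direct, spec$namespace,
                              sprintf("synthetic fixture (seed=%d)", spec$seed))
  attr(annot, "planted") <- planted
  if (!is.null(gaf_path)) write_gaf(annot, gaf_path)
  annot
}

#' Write direct annotations as a GAF 2.2 file
#'
#' @param annot A `go_annotation` (direct annotations are written).
#' @param path Output path.
#' @export
write_gaf <- function(annot, path) {
  aspect <- names(ASPECT_TO_NAMESPACE)[match(annot$namespace, ASPECT_TO_NAMESPACE)]
  rows <- character(0)
  for (g in names(annot$direct)) {
    for (t in annot$direct[[g]]) {
      rows <- c(rows, paste(c("SYNDB", g, g, "", t, "GO_REF:0000000", "IEA", "",
                              aspect, "", "", "gene", "taxon:0000", "20260101",
                              "goclust", "", ""), collapse = "\t"))
    }
  }
  writeLines(c("!gaf-version: 2.2", "!generated-by: goclust fixture generator", rows),
             path)
  invisible(path)
}

#' Generate the study gene lists (background + interest lists)
#'
#' The background is every gene. Interest list j samples `list_size` genes
#' without replacement, with sampling weight `planted_odds` for genes
#' carrying (after propagation) the j-th planted term and 1 otherwise;
#' `planted_odds = 1` reduces to uniform sampling. A ground-truth manifest
#' is written alongside the lists when `dir` is given.
#'
#' @param spec A `fixture_spec`.
#' @param dag The fixture DAG.
#' @param annot The fixture annotation (from [make_annotations()]).
#' @param dir Optional directory: writes `background.txt`, `list_<j>.txt`
#'   and `manifest.json`.
#' @return List with `background`, `lists` (named list of gene vectors) and
#'   `planted` (named character: list id -> planted term).
#' @export
make_study <- function(spec, dag, annot, dir = NULL) {
  set.seed(derive_seed(spec$seed, 3L))
  genes <- fixture_gene_ids(spec$n_genes)
  annot <- propagate(annot, dag)
  planted <- attr(annot, "planted")
  if (is.null(planted)) planted <- planted_terms(spec, dag)
  lists <- list()
  for (j in seq_len(spec$n_lists)) {
    t <- planted[j]
    carriers <- annotated_genes(annot, dag, t, genes)
    w <- ifelse(genes %in% carriers, spec$planted_odds, 1)
    size <- min(spec$list_size, spec$n_genes)
    lists[[paste0("list_", j)]] <- sort(sample(genes, size, prob = w))
  }
  names(planted) <- names(lists)
  study <- list(background = genes, lists = lists, planted = planted)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeLines(genes, file.path(dir, "background.txt"))
    for (lid in names(lists)) writeLines(lists[[lid]], file.path(dir, paste0(lid, ".txt")))
    write_json_stable(list(planted = as.list(planted),
                           planted_odds = spec$planted_odds,
                           list_size = spec$list_size, seed = spec$seed),
                      file.path(dir, "manifest.json"))
  }
  study
}

#' Generate a complete fixture on disk
#'
#' Writes `ontology.obo`, `annotations.gaf`, the gene lists, the ground-truth
#' manifest, and a ready-to-run `config.yaml` for the pipeline.
#'
#' @param spec A `fixture_spec`.
#' @param dir Output directory (created if needed).
#' @return Invisible list with the in-memory `dag`, `annot`, `study` and the
#'   path of the written config.
#' @export
make_fixture <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dag <- make_dag(spec, obo_path = file.path(dir, "ontology.obo"))
  annot <- make_annotations(spec, dag, gaf_path = file.path(dir, "annotations.gaf"))
  study <- make_study(spec, dag, annot, dir = dir)
  cfg <- list(
    obo = file.path(dir, "ontology.obo"),
    annotations = file.path(dir, "annotations.gaf"),
    annotation_format = "gaf",
    namespace = spec$namespace,
    background = file.path(dir, "background.txt"),
    lists = as.list(structure(file.path(dir, paste0(names(study$lists), ".txt")),
                              names = names(study$lists))),
    algorithm = "elim", alpha = 0.01, threshold = 0.01,
    measure = "wang", combine = "BMA",
    cut = list(mode = "dynamic", min_size = 2, deep_split = 2),
    outdir = file.path(dir, "results"))
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  invisible(list(dag = dag, annot = annot, study = study, config = cfg_path))
}
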