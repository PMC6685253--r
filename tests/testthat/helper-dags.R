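# hand-built ontologies used across tests ------------------------------------

# chain: A is_a B is_a C (C = root)
obo_chain <- function() c(
  "format-version: 1.2",
  "[Term]", "id: GO:0000003", "name: C root", "namespace: biological_process",
  "[Term]", "id: GO:0000002", "name: B mid", "namespace: biological_process",
  "is_a: GO:0000003",
  "[Term]", "id: GO:0000001", "name: A leaf", "namespace: biological_process",
  "is_a: GO:0000002")

# diamond: A -> {B, C} -> D (D = root)
obo_diamond <- function() c(
  "format-version: 1.2",
  "[Term]", "id: GO:0000004", "name: D root", "namespace: biological_process",
  "[Term]", "id: GO:0000002", "name: B left", "namespace: biological_process",
  "is_a: GO:0000004",
  "[Term]", "id: GO:0000003", "name: C right", "namespace: biological_process",
  "is_a: GO:0000004",
  "[Term]", "id: GO:0000001", "name: A bottom", "namespace: biological_process",
  "is_a: GO:0000002", "is_a: GO:0000003")

chain_dag <- function() parse_obo(obo_chain())
diamond_dag <- function() parse_obo(obo_diamond())

# two-level enrichment fixture: root R with branches P (parent of C) and D
# C: g01..g05; P direct: g06,g07; D: g08..g20  -> N = 20 annotated genes
obo_two_level <- function() c(
  "format-version: 1.2",
  "[Term]", "id: GO:0000010", "name: R root", "namespace: biological_process",
  "[Term]", "id: GO:0000011", "name: P parent", "namespace: biological_process",
  "is_a: GO:0000010",
  "[Term]", "id: GO:0000012", "name: C child", "namespace: biological_process",
  "is_a: GO:0000011",
  "[Term]", "id: GO:0000013", "name: D other", "namespace: biological_process",
  "is_a: GO:0000010")

gene_ids <- function(i) sprintf("g%02d", i)

tsv_annotation <- function(pairs) {
  # pairs: data.frame(gene, term)
  paste(pairs$gene, pairs$term, sep = "\t")
}

two_level_annot <- function(dag) {
  pairs <- rbind(
    data.frame(gene = gene_ids(1:5), term = "GO:0000012"),
    data.frame(gene = gene_ids(6:7), term = "GO:0000011"),
    data.frame(gene = gene_ids(8:20), term = "GO:0000013"))
  read_tsv_annotation(tsv_annotation(pairs), dag, "biological_process")
}

# sibling elim fixture: P (direct g09,g10) with children C1 (g01..g04) and
# C2 (g05..g08); D: g11..g30 -> N = 30
obo_siblings <- function() c(
  "format-version: 1.2",
  "[Term]", "id: GO:0000020", "name: R root", "namespace: biological_process",
  "[Term]", "id: GO:0000021", "name: P parent", "namespace: biological_process",
  "is_a: GO:0000020",
  "[Term]", "id: GO:0000022", "name: C1", "namespace: biological_process",
  "is_a: GO:0000021",
  "[Term]", "id: GO:0000023", "name: C2", "namespace: biological_process",
  "is_a: GO:0000021",
  "[Term]", "id: GO:0000024", "name: D other", "namespace: biological_process",
  "is_a: GO:0000020")

siblings_annot <- function(dag) {
  pairs <- rbind(
    data.frame(gene = gene_ids(1:4), term = "GO:0000022"),
    data.frame(gene = gene_ids(5:8), term = "GO:0000023"),
    data.frame(gene = gene_ids(9:10), term = "GO:0000021"),
    data.frame(gene = gene_ids(11:30), term = "GO:0000024"))
  read_tsv_annotation(tsv_annotation(pairs), dag, "biological_process")
}

# diamond corpus for IC tests: 8 genes; propagated counts
# root D = 8, B = {g1..g4} = 4, C = {g1,g5,g6} = 3, A = {g1} = 1
diamond_ic_fixture <- function() {
  dia <- diamond_dag()
  pairs <- rbind(
    data.frame(gene = gene_ids(1),   term = "GO:0000001"),
    data.frame(gene = gene_ids(2:4), term = "GO:0000002"),
    data.frame(gene = gene_ids(5:6), term = "GO:0000003"),
    data.frame(gene = gene_ids(7:8), term = "GO:0000004"))
  a <- propagate(read_tsv_annotation(tsv_annotation(pairs), dia,
                                     "biological_process"), dia)
  list(dag = dia, annot = a, ic = compute_ic(a, dia))
}

# GAF row builder (17 columns)
gaf_row <- function(gene, go, aspect = "P", qualifier = "", evidence = "IEA") {
  paste(c("TESTDB", gene, gene, qualifier, go, "GO_REF:0000000", evidence, "",
          aspect, "", "", "gene", "taxon:0000", "20260101", "test", "", ""),
        collapse = "\t")
}

# small random DAG/annotation fixtures from the generator
small_fixture <- function(seed = 11, n_terms = 40, n_genes = 150, ...) {
  spec <- fixture_spec(n_terms = n_terms, n_genes = n_genes, seed = seed, ...)
  dag <- make_dag(spec)
  annot <- suppressMessages(make_annotations(spec, dag))
  list(spec = spec, dag = dag, annot = propagate(annot, dag))
}

# brute-force reachability oracle over the edge list (independent of
# the package's BFS): boolean transitive closure by iterated products
reach_closure <- function(dag, relations = c("is_a", "part_of")) {
  ids <- dag$ids[!dag$obsolete[dag$ids]]
  n <- length(ids)
  A <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  e <- dag$edges[dag$edges$relation %in% relations, , drop = FALSE]
  A[cbind(match(e$child, ids), match(e$parent, ids))] <- TRUE
  R <- A
  repeat {
    R2 <- R | (R %*% A > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  R
}

# brute-force ward.D2 oracle: Lance-Williams on squared dissimilarities,
# heights reported as square roots
ward_d2_oracle <- function(D) {
  D2 <- as.matrix(D)^2
  n <- nrow(D2)
  active <- seq_len(n)
  sizes <- rep(1, n)
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- c(Inf, NA, NA)
    for (ii in seq_along(active)[-length(active)]) {
      for (jj in seq.int(ii + 1, length(active))) {
        v <- D2[active[ii], active[jj]]
        if (v < best[1]) best <- c(v, ii, jj)
      }
    }
    i <- best[2]; j <- best[3]
    a <- active[i]; b <- active[j]
    heights[step] <- sqrt(best[1])
    ni <- sizes[a]; nj <- sizes[b]
    for (k in active[-c(i, j)]) {
      nk <- sizes[k]
      D2[a, k] <- D2[k, a] <-
        ((ni + nk) * D2[a, k] + (nj + nk) * D2[b, k] - nk * D2[a, b]) /
        (ni + nj + nk)
    }
    sizes[a] <- ni + nj
    active <- active[-j]
  }
  heights
}

# independent upper-tail oracle: sum of hypergeometric point masses
hyper_tail_oracle <- function(x, n, K, N) {
  if (x == 0) return(1)
  sum(stats::dhyper(x:min(n, K), K, N - K, n))
}
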