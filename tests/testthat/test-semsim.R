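test_that("information content is the negative log annotation frequency", {
  fx <- diamond_ic_fixture()
  ic <- fx$ic
  # propagated counts: D(root)=8, B = {g1,g2,g3,g4} = 4, C = {g1,g5,g6} = 3, A = 1
  expect_equal(unname(ic$ic["GO:0000004"]), 0)
  expect_equal(ic$corpus_size, 8)
  expect_equal(unname(ic$ic["GO:0000002"]), -log(4 / 8), tolerance = 1e-12)
  expect_equal(unname(ic$ic["GO:0000003"]), -log(3 / 8), tolerance = 1e-12)
  expect_equal(unname(ic$ic["GO:0000001"]), log(8), tolerance = 1e-12)
  expect_equal(ic$max_ic, log(8), tolerance = 1e-12)
  # a term annotated to exactly the root's gene set has IC 0
  dag <- chain_dag()
  a <- propagate(read_tsv_annotation(
    paste(gene_ids(1:4), "GO:0000002", sep = "\t"), dag, "biological_process"), dag)
  ic2 <- compute_ic(a, dag)
  expect_equal(unname(ic2$ic["GO:0000002"]), 0)
  expect_false("GO:0000001" %in% names(ic2$ic))  # unannotated: no entry
})

test_that("IC is monotone non-decreasing from parent to child", {
  fx <- small_fixture(seed = 17, n_terms = 40, n_genes = 200)
  ic <- compute_ic(fx$annot, fx$dag)
  e <- fx$dag$edges
  both <- e$child %in% names(ic$ic) & e$parent %in% names(ic$ic)
  expect_true(all(ic$ic[e$child[both]] >= ic$ic[e$parent[both]] - 1e-12))
  expect_equal(unname(ic$ic[fx$dag$roots[["biological_process"]]]), 0)
})

test_that("mica picks the most informative (deepest annotated) common ancestor", {
  fx <- diamond_ic_fixture()
  expect_equal(mica(fx$dag, fx$ic, "GO:0000001", "GO:0000001"), "GO:0000001")
  # siblings B and C share only the root
  expect_equal(mica(fx$dag, fx$ic, "GO:0000002", "GO:0000003"), "GO:0000004")
  # A vs B: common ancestors {B, D}; B carries more information than the root
  expect_equal(mica(fx$dag, fx$ic, "GO:0000001", "GO:0000002"), "GO:0000002")
})

test_that("IC-based measures match hand arithmetic on the diamond corpus", {
  fx <- diamond_ic_fixture()
  ic <- fx$ic
  icA <- log(8); icB <- -log(4 / 8); icC <- -log(3 / 8)
  # Lin(A, B): mica = B
  expect_equal(term_sim(fx$dag, ic, "GO:0000001", "GO:0000002", "lin"),
               2 * icB / (icA + icB), tolerance = 1e-12)
  expect_equal(term_sim(fx$dag, ic, "GO:0000001", "GO:0000001", "lin"), 1)
  # Resnik normalised by the corpus max; B,C only share the root -> 0
  expect_equal(term_sim(fx$dag, ic, "GO:0000002", "GO:0000003", "resnik"), 0)
  expect_equal(term_sim(fx$dag, ic, "GO:0000001", "GO:0000002", "resnik"),
               icB / log(8), tolerance = 1e-12)
  # Rel weights Lin by 1 - p(mica)
  expect_equal(term_sim(fx$dag, ic, "GO:0000001", "GO:0000002", "rel"),
               2 * icB / (icA + icB) * (1 - 4 / 8), tolerance = 1e-12)
  # Jiang: bounded distance form
  expect_equal(term_sim(fx$dag, ic, "GO:0000001", "GO:0000002", "jiang"),
               1 - min(1, icA + icB - 2 * icB), tolerance = 1e-12)
  # both-root pair: Lin defined as 0 by convention
  expect_equal(term_sim(fx$dag, ic, "GO:0000004", "GO:0000004", "lin"), 0)
  # unannotated term: no IC entry, explicit error naming the term
  dagc <- chain_dag()
  ac <- propagate(read_tsv_annotation(
    paste(gene_ids(1:4), "GO:0000002", sep = "\t"), dagc, "biological_process"), dagc)
  icc <- compute_ic(ac, dagc)
  expect_error(term_sim(dagc, icc, "GO:0000001", "GO:0000002", "lin"),
               "GO:0000001.*information content")
})

test_that("Wang similarity reproduces hand-computed S-value arithmetic", {
  dia <- diamond_dag()
  # self-similarity is exactly 1
  expect_identical(sim_wang(dia, "GO:0000001", "GO:0000001"), 1)
  # siblings under one root: SV = 1.8 each, shared root 0.8 + 0.8
  expect_equal(sim_wang(dia, "GO:0000002", "GO:0000003"), 1.6 / 3.6,
               tolerance = 1e-9)
  # chain A is_a B is_a C vs B: (0.8+1 + 0.64+0.8) / (2.44+1.8)
  expect_equal(sim_wang(chain_dag(), "GO:0000001", "GO:0000002"), 3.24 / 4.24,
               tolerance = 1e-9)
  # part_of weight 0.6: A part_of B is_a C vs B
  obo <- c("format-version: 1.2",
    "[Term]", "id: GO:0000003", "name: c", "namespace: biological_process",
    "[Term]", "id: GO:0000002", "name: b", "namespace: biological_process",
    "is_a: GO:0000003",
    "[Term]", "id: GO:0000001", "name: a", "namespace: biological_process",
    "relationship: part_of GO:0000002")
  dag <- parse_obo(obo)
  # S_A = {A:1, B:0.6, C:0.48}, SV(A)=2.08; S_B = {B:1, C:0.8}, SV(B)=1.8
  expect_equal(sim_wang(dag, "GO:0000001", "GO:0000002"),
               (0.6 + 1 + 0.48 + 0.8) / (2.08 + 1.8), tolerance = 1e-9)
  # diamond bottom vs root: S_A(D) = max(0.8*0.8, 0.8*0.8) = 0.64
  sv <- goclust:::wang_svalues(dia, "GO:0000001", c(is_a = 0.8, part_of = 0.6))
  expect_equal(unname(sv[c("GO:0000001", "GO:0000002", "GO:0000003", "GO:0000004")]),
               c(1, 0.8, 0.8, 0.64), tolerance = 1e-12)
})

test_that("Wang similarity is purely topological (annotation-invariant)", {
  fx <- small_fixture(seed = 29, n_terms = 30, n_genes = 100)
  terms <- sort(unique(unlist(fx$annot$direct)))[1:6]
  s1 <- similarity_matrix(fx$dag, NULL, terms, measure = "wang")
  # recompute under a shuffled annotation corpus: identical matrix
  fx2 <- small_fixture(seed = 99, n_terms = 30, n_genes = 100)
  ic2 <- compute_ic(fx2$annot, fx$dag)
  s2 <- similarity_matrix(fx$dag, ic2, terms, measure = "wang")
  expect_identical(s1$sim, s2$sim)
})

test_that("set combinations follow their formulas", {
  # 2x1 matrix M = [0.5; 0.9]
  M <- matrix(c(0.5, 0.9), nrow = 2)
  expect_equal(goclust:::combine_matrix(M, "BMA"), (0.5 + 0.9 + 0.9) / 3,
               tolerance = 1e-12)
  expect_equal(goclust:::combine_matrix(M, "max"), 0.9)
  expect_equal(goclust:::combine_matrix(M, "avg"), 0.7)
  expect_equal(goclust:::combine_matrix(M, "rcmax"), max(mean(c(0.5, 0.9)), 0.9))

  fx <- diamond_ic_fixture()
  S <- c("GO:0000001", "GO:0000002")
  # identical sets give BMA exactly 1 under a unit-self-similarity measure
  expect_equal(termset_sim(fx$dag, fx$ic, S, S, "wang", "BMA"), 1)
  # singleton sets: all four combinations equal the pairwise similarity
  pair <- sim_wang(fx$dag, "GO:0000001", "GO:0000002")
  for (cmb in c("BMA", "max", "avg", "rcmax")) {
    expect_equal(termset_sim(fx$dag, fx$ic, "GO:0000001", "GO:0000002",
                             "wang", cmb), pair, tolerance = 1e-12)
  }
  expect_error(termset_sim(fx$dag, fx$ic, character(0), S, "wang"), "empty")
})

test_that("similarity_matrix is symmetric, unit-diagonal and matches per-pair ops", {
  fx <- diamond_ic_fixture()
  terms <- c("GO:0000001", "GO:0000002", "GO:0000003", "GO:0000004")
  for (m in c("wang", "lin", "resnik", "rel", "jiang")) {
    sm <- similarity_matrix(fx$dag, fx$ic, terms, measure = m)
    expect_identical(sm$sim, t(sm$sim))
    expect_true(all(diag(sm$sim) == 1))
    expect_true(all(sm$sim >= 0 & sm$sim <= 1))
    for (i in 1:3) for (j in (i + 1):4) {
      expect_equal(sm$sim[i, j], term_sim(fx$dag, fx$ic, terms[i], terms[j], m),
                   tolerance = 1e-12)
    }
    d <- sim_dist(sm)
    expect_true(all(d >= 0 & d <= 1))
  }
  # duplicated term: off-diagonal 1
  sm2 <- similarity_matrix(fx$dag, fx$ic, c("GO:0000001", "GO:0000001"),
                           measure = "wang")
  expect_equal(sm2$sim[1, 2], 1)
})
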