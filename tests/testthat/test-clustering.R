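# two tight blobs {1,2,3} and {4,5,6}: within 0.1-0.12, across ~1
blob_dist <- function() {
  pts <- rbind(c(0, 0), c(0.1, 0), c(0, 0.1),
               c(2, 0), c(2.1, 0), c(2, 0.1))
  rownames(pts) <- paste0("t", 1:6)
  stats::dist(pts)
}

test_that("ward.D2 clustering reproduces Lance-Williams arithmetic", {
  d2 <- stats::dist(c(a = 0, b = 3))
  tr <- hclust_ward2(d2)
  expect_equal(tr$height, 3)            # 2 leaves merge at their distance

  d <- blob_dist()
  tr <- hclust_ward2(d)
  expect_equal(sort(tr$height), sort(ward_d2_oracle(d)), tolerance = 1e-12)
  # blobs merge internally before any cross-blob merge
  cl <- stats::cutree(tr, k = 2)
  expect_equal(unname(cl), c(1, 1, 1, 2, 2, 2))

  # deterministic under ties: equilateral triple, twice
  deq <- stats::as.dist(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3,
                               dimnames = list(letters[1:3], letters[1:3])))
  t1 <- hclust_ward2(deq); t2 <- hclust_ward2(deq)
  expect_identical(t1$merge, t2$merge)
  expect_identical(t1$height, t2$height)

  expect_error(hclust_ward2(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("ward.D2 accepts a go_sim and clusters on 1 - s", {
  fx <- small_fixture(seed = 13, n_terms = 25, n_genes = 90)
  terms <- sort(unique(unlist(fx$annot$direct)))[1:8]
  sm <- similarity_matrix(fx$dag, NULL, terms, measure = "wang")
  tr <- hclust_ward2(sm)
  expect_setequal(tr$labels, terms)
  expect_equal(sort(tr$height), sort(ward_d2_oracle(sim_dist(sm))),
               tolerance = 1e-9)
})

test_that("static cuts partition leaves with display-ordered labels", {
  tr <- hclust_ward2(blob_dist())
  singletons <- cut_static(tr, k = 6)
  expect_equal(sort(unique(singletons$labels)), 1:6)
  one <- cut_static(tr, k = 1)
  expect_true(all(one$labels == 1))
  two <- cut_static(tr, k = 2)
  expect_equal(length(unique(two$labels)), 2)
  expect_equal(unname(two$labels[c("t1", "t2", "t3")]),
               rep(two$labels[["t1"]], 3))
  # labels numbered by first appearance along the dendrogram
  leaf_order <- tr$labels[tr$order]
  expect_equal(unname(two$labels[leaf_order[1]]), 1L)
  expect_error(cut_static(tr), "exactly one")
  expect_error(cut_static(tr, k = 2, h = 0.5), "exactly one")
})

test_that("dynamic cut finds separated branches and respects min size", {
  tr <- hclust_ward2(blob_dist())
  cl <- cut_dynamic(tr, min_cluster_size = 2, deep_split = 2)
  expect_equal(length(unique(cl$labels[cl$labels > 0])), 2)
  expect_false(any(cl$labels == 0))
  expect_true(all(table(cl$labels) >= 2))
  # determinism
  expect_identical(cl$labels, cut_dynamic(tr, 2, 2)$labels)
  # min_cluster_size larger than n: everything unassigned
  all0 <- cut_dynamic(tr, min_cluster_size = 10)
  expect_true(all(all0$labels == 0))
  # mutually equidistant leaves: all singleton branches below the cut -> all 0
  deq <- stats::as.dist(matrix(1, 4, 4) - diag(4))
  attr(deq, "Labels") <- letters[1:4]
  eq <- cut_dynamic(hclust_ward2(deq), min_cluster_size = 2)
  expect_identical(eq$labels, cut_dynamic(hclust_ward2(deq), 2)$labels)
  expect_error(cut_dynamic(tr, min_cluster_size = 0), "min_cluster_size")
  expect_error(cut_dynamic(tr, deep_split = 7), "deep_split")
})

test_that("cluster sizes from a dynamic cut never fall below min size", {
  for (seed in c(3, 19)) {
    fx <- small_fixture(seed = seed, n_terms = 50, n_genes = 150)
    terms <- sort(unique(unlist(fx$annot$direct)))[1:15]
    tr <- hclust_ward2(similarity_matrix(fx$dag, NULL, terms, measure = "wang"))
    for (ds in 0:4) {
      cl <- cut_dynamic(tr, min_cluster_size = 3, deep_split = ds)
      sz <- table(cl$labels[cl$labels > 0])
      if (length(sz)) expect_true(all(sz >= 3))
    }
  }
})

test_that("clusters are named by their most specific common ancestor", {
  dia <- diamond_dag()
  fxic <- diamond_ic_fixture()
  expect_equal(name_cluster(dia, NULL, "GO:0000002"), "GO:0000002")  # singleton
  expect_equal(name_cluster(dia, NULL, c("GO:0000002", "GO:0000003")), "GO:0000004")
  # mixed depth: {A, B} share {B, D}; B is deeper
  expect_equal(name_cluster(dia, NULL, c("GO:0000001", "GO:0000002")), "GO:0000002")
  # level tie broken by IC: {B, C} in a DAG where both are ancestors of A... use
  # chain: {A} vs naming by ancestor-or-self invariant below
  members <- c("GO:0000001", "GO:0000003")
  nm <- name_cluster(fxic$dag, fxic$ic, members)
  expect_equal(nm, "GO:0000003")
  # the name is an ancestor-or-self of every member
  for (m in members) {
    expect_true(nm %in% c(m, ancestors(fxic$dag, m)))
  }
})

test_that("cluster-level similarity uses set similarity on assignments", {
  fxic <- diamond_ic_fixture()
  labels <- structure(c(1L, 1L, 2L, 0L),
                      names = c("GO:0000001", "GO:0000002", "GO:0000003", "GO:0000004"))
  asg <- structure(list(labels = labels, mode = "static", params = list()),
                   class = "go_clusters")
  cm <- cluster_set_matrix(fxic$dag, fxic$ic, asg, measure = "wang", combine = "BMA")
  expect_equal(rownames(cm$sim), c("cl1", "cl2"))
  # unassigned leaf (label 0) excluded; value equals the direct termset oracle
  expected <- termset_sim(fxic$dag, fxic$ic, c("GO:0000001", "GO:0000002"),
                          "GO:0000003", "wang", "BMA")
  expect_equal(cm$sim["cl1", "cl2"], expected, tolerance = 1e-12)
  # singleton clusters reduce to the pairwise term similarity
  labels2 <- structure(c(1L, 2L), names = c("GO:0000001", "GO:0000002"))
  asg2 <- structure(list(labels = labels2, mode = "static", params = list()),
                    class = "go_clusters")
  cm2 <- cluster_set_matrix(fxic$dag, fxic$ic, asg2, measure = "wang")
  expect_equal(cm2$sim["cl1", "cl2"],
               sim_wang(fxic$dag, "GO:0000001", "GO:0000002"), tolerance = 1e-12)
})

test_that("classical MDS recovers known geometry", {
  # two points at distance 3: 1-D embedding at +/- 1.5
  d <- stats::dist(c(a = 0, b = 3))
  xy <- mds_classical(d, dims = 1)
  expect_equal(sort(unname(xy[, 1])), c(-1.5, 1.5), tolerance = 1e-12)
  # three equidistant points: embedded pairwise distances all equal the input
  deq <- stats::as.dist(matrix(1, 3, 3) - diag(3))
  xy3 <- mds_classical(deq, dims = 2)
  expect_equal(as.numeric(stats::dist(xy3)), rep(1, 3), tolerance = 1e-9)
  # Euclidean-embeddable 4-point set: distances reproduced to 1e-9
  pts <- rbind(c(0, 0), c(1, 0), c(0.3, 2), c(-1, 0.5))
  d4 <- stats::dist(pts)
  xy4 <- mds_classical(d4, dims = 2)
  expect_equal(as.numeric(stats::dist(xy4)), as.numeric(d4), tolerance = 1e-9)
  expect_lt(attr(xy4, "distortion"), 1e-9)
  expect_error(mds_classical(d4, dims = 4), "dims")
})

test_that("dendrograms serialize to parseable Newick plus a merge table", {
  tr <- hclust_ward2(blob_dist())
  nwk <- tempfile(fileext = ".nwk"); mrg <- tempfile(fileext = ".tsv")
  write_dendrogram(tr, nwk, mrg)
  phy <- ape::read.tree(nwk)
  expect_setequal(phy$tip.label, tr$labels)
  m <- utils::read.delim(mrg)
  expect_equal(nrow(m), 5)
  expect_equal(m$size[5], 6)         # sizes telescope to n at the final merge
  expect_equal(m$height, tr$height, tolerance = 1e-12)
  expect_true(all(diff(tr$height) >= 0))  # Ward heights are monotone here
})
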