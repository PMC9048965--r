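test_that("network descriptors match hand graph-theory values", {
  empty <- igraph::make_empty_graph(directed = FALSE)
  expect_equal(unname(network_descriptors(empty)), rep(0, 16))

  tri <- igraph::make_ring(3)
  d <- network_descriptors(tri)
  expect_equal(length(d), 16)
  expect_equal(unname(d["n_nodes"]), 3)
  expect_equal(unname(d["n_edges"]), 3)
  expect_equal(unname(d["density"]), 1)
  expect_equal(unname(d["clustering"]), 1)
  expect_equal(unname(d["cycle_rank"]), 1)
  expect_equal(unname(d["leaves"]), 0)

  path <- igraph::make_graph(~ a - b - c - d)
  dp <- network_descriptors(path)
  expect_equal(unname(dp["diameter"]), 3)
  expect_equal(unname(dp["leaves"]), 2)
  expect_equal(unname(dp["articulation"]), 2)
  expect_equal(unname(dp["cycle_rank"]), 0)
})

test_that("feature table has 16 x genera columns, is scaled and deduplicated", {
  genera <- sprintf("G%02d", 1:21)
  set.seed(11)
  mk_set <- function(seed) {
    set.seed(seed)
    setNames(lapply(genera, function(g)
      { n <- sample(4:8, 1); igraph::sample_gnm(n, sample(2:min(6, n*(n-1)/2), 1)) }), genera)
  }
  sets <- lapply(1:6, mk_set)
  sets[[7]] <- sets[[3]]                     # exact duplicate
  tab <- build_feature_table(sets, genera)
  expect_equal(ncol(tab$features), 336)
  expect_equal(nrow(tab$features), 6)        # duplicate dropped
  nonflat <- !tab$flat
  expect_equal(unname(colMeans(tab$features[, nonflat])),
               rep(0, sum(nonflat)), tolerance = 1e-9)
  expect_equal(unname(apply(tab$features[, nonflat], 2, sd)),
               rep(1, sum(nonflat)), tolerance = 1e-9)
  expect_error(build_feature_table(list(list(a = igraph::make_ring(3))), c("a", "b")),
               "lacks genus")
})

test_that("selection keeps the cluster containing the natural row", {
  # two well-separated clusters of surrogate sets in descriptor space,
  # checked against a direct (no-UMAP) Mahalanobis gate in feature space
  genera <- c("Ga", "Gb", "Gc")
  small <- function(seed) {
    set.seed(seed)
    setNames(lapply(1:3, function(i) igraph::sample_gnm(4, 3)), genera)
  }
  big <- function(seed) {
    set.seed(seed)
    setNames(lapply(1:3, function(i) {
      g <- igraph::sample_gnm(30, 80)
      g
    }), genera)
  }
  sets <- c(lapply(1:8, small), lapply(101:108, big))
  tab <- build_feature_table(sets, genera)
  expect_gte(nrow(tab$features), 12)
  # natural data: another small-graph set
  nat_set <- small(999)
  nat_row <- unlist(lapply(genera, function(g) network_descriptors(nat_set[[g]])))
  sel <- embed_and_select(tab, nat_row, n_projections = 300,
                          chi2_quantile = 0.99, seed = 7, n_neighbors = 5)
  # map selected rows back: which original sets were kept after dedup
  kept_sets <- tab$kept[sel$selected]
  expect_true(all(kept_sets <= 8))           # only small-cluster sets
  expect_gt(length(kept_sets), 0)
  # direct feature-space oracle: small cluster is closer to the natural row
  nat_t <- iridograph:::.apply_table_transform(tab, nat_row)
  d <- sqrt(colSums((t(tab$features) - nat_t)^2))
  ds <- d[tab$kept <= 8]; db <- d[tab$kept > 8]
  expect_lt(max(ds), min(db))
})

test_that("selection is monotone in the chi-squared quantile", {
  genera <- c("Ga", "Gb")
  sets <- lapply(1:10, function(s) {
    set.seed(s)
    setNames(lapply(1:2, function(i)
      { n <- sample(6:12, 1); igraph::sample_gnm(n, sample(3:min(14, n*(n-1)/2), 1)) }), genera)
  })
  tab <- build_feature_table(sets, genera)
  nat_row <- tab$raw[3, ]
  picks <- lapply(c(0.2, 0.6, 0.999), function(q)
    embed_and_select(tab, nat_row, n_projections = 100, chi2_quantile = q,
                     seed = 3, n_neighbors = 4)$selected)
  expect_true(all(picks[[1]] %in% picks[[2]]))
  expect_true(all(picks[[2]] %in% picks[[3]]))
  # a surrogate identical to the natural row survives a generous gate
  expect_true(3 %in% tab$kept[picks[[3]]])
})
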