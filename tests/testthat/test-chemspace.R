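test_that("a 2-carbon toy space is the brute-force hypercube", {
  # two hydroxylatable carbons, everything else frozen: 4 nodes, 4 edges
  g <- iridoid_grammar(n_states = c(C1 = 2, C3 = 1, C4 = 1, C5 = 1, C6 = 2,
                                    C7 = 1, C8 = 1, C9 = 1, C10 = 1, C11 = 1),
                       bonds = NULL, epoxide_bonds = character(0),
                       edge_count = "undirected")
  sp <- enumerate_space(g)
  expect_equal(length(sp$keys), 4)
  expect_equal(count_reactions(sp), 4L)
  # brute force: every pair at calibrated distance 1 is an edge
  codes <- lapply(sp$keys, parse_code)
  brute <- 0
  for (i in 1:3) for (j in (i + 1):4)
    if (generalized_distance(codes[[i]], codes[[j]], g) == 1)
      brute <- brute + 1
  expect_equal(brute, 4)
})

test_that("enumeration is closed, valid, deterministic and self-consistent", {
  tg <- toy_grammar()
  sp <- toy_space()
  for (k in sample(sp$keys, 25))
    expect_true(validate_code(parse_code(k), tg)$valid)
  # reproducible: a second enumeration is identical
  sp2 <- enumerate_space(tg)
  expect_identical(sp$keys, sp2$keys)
  expect_identical(igraph::as_edgelist(sp$graph), igraph::as_edgelist(sp2$graph))
  # neighbor sets agree with list_moves images + preimages
  for (k in sample(sp$keys, 12)) {
    code <- parse_code(k)
    fwd <- vapply(list_moves(code, tg), function(m)
      format_code(apply_move(code, m, tg)), character(1))
    nb <- space_neighbors(sp, k)
    expect_true(all(fwd %in% nb))
    # symmetry: b in N(a) <=> a in N(b); and no self loops
    expect_false(k %in% nb)
    for (other in sample(nb, min(3, length(nb))))
      expect_true(k %in% space_neighbors(sp, other))
    # every neighbor is either a forward image or has k among its images
    for (other in nb) {
      oc <- parse_code(other)
      back <- vapply(list_moves(oc, tg), function(m)
        format_code(apply_move(oc, m, tg)), character(1))
      expect_true(other %in% fwd || k %in% back)
    }
  }
})

test_that("every edge endpoint pair is at calibrated distance 1", {
  tg <- toy_grammar()
  sp <- toy_space()
  el <- igraph::as_edgelist(sp$graph)
  idx <- sample(nrow(el), min(200, nrow(el)))
  for (i in idx) {
    expect_equal(generalized_distance(parse_code(el[i, 1]),
                                      parse_code(el[i, 2]), tg), 1)
  }
})

test_that("geodesics agree with an independent breadth-first search", {
  tg <- toy_grammar()
  sp <- toy_space()
  # hand BFS oracle over the adjacency implied by space_neighbors
  bfs_dist <- function(from, to) {
    seen <- stats::setNames(0L, from)
    frontier <- from
    d <- 0L
    while (length(frontier)) {
      if (to %in% frontier) return(d)
      d <- d + 1L
      nxt <- unique(unlist(lapply(frontier, function(k) space_neighbors(sp, k))))
      nxt <- setdiff(nxt, names(seen))
      seen <- c(seen, stats::setNames(rep(d, length(nxt)), nxt))
      frontier <- nxt
    }
    Inf
  }
  set.seed(5)
  pairs <- matrix(sample(sp$keys, 10), ncol = 2)
  for (i in seq_len(nrow(pairs))) {
    expect_equal(geodesic(sp, pairs[i, 1], pairs[i, 2]),
                 bfs_dist(pairs[i, 1], pairs[i, 2]))
  }
  expect_equal(geodesic(sp, sp$keys[1], sp$keys[1]), 0)
})

test_that("triangle inequality holds for the calibrated distance on triples", {
  tg <- toy_grammar()
  sp <- toy_space()
  set.seed(8)
  for (r in 1:40) {
    ks <- sample(sp$keys, 3)
    cs <- lapply(ks, parse_code)
    dab <- generalized_distance(cs[[1]], cs[[2]], tg)
    dbc <- generalized_distance(cs[[2]], cs[[3]], tg)
    dac <- generalized_distance(cs[[1]], cs[[3]], tg)
    expect_lte(dac, dab + dbc + 1e-12)
    # the graph geodesic dominates the calibrated distance
    expect_lte(dac, geodesic(sp, ks[1], ks[3]) + 1e-12)
  }
})

test_that("bartsioside and aucubin are reaction neighbors in the full space", {
  sp <- default_space()
  ba <- code_key(bartsioside_code())
  au <- code_key(aucubin_code())
  expect_true(au %in% space_neighbors(sp, ba))
  expect_equal(geodesic(sp, ba, au), 1)
  # aucubin -> catalpol is one epoxidation
  expect_equal(geodesic(sp, au, code_key(catalpol_code())), 1)
})

test_that("space serialization round-trips as edge-list TSV", {
  sp <- toy_space()
  tf <- tempfile(fileext = ".tsv")
  write_space(sp, tf)
  el <- utils::read.delim(tf, stringsAsFactors = FALSE)
  expect_equal(nrow(el), igraph::ecount(sp$graph))
  expect_true(all(c("from", "to", "kind") %in% names(el)))
  unlink(tf)
})
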