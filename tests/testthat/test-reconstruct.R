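# helper: tiny hand-built "space" stand-in graphs for pruning logic; the
# pruning operates on any naive graph, so a hand graph with explicit scores
# makes the connector-enumeration oracle transparent.
fake_scores <- function(values, scheme = "correlation", genus = "G1") {
  m <- matrix(values, 1, length(values),
              dimnames = list(genus, names(values)))
  structure(list(scores = m, aggregate = colSums(m), scheme = scheme,
                 basis = "reported", genera = genus),
            class = "item_scores")
}

fake_naive <- function(edges, reported) {
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::V(g)$reported <- igraph::V(g)$name %in% reported
  g
}

test_that("naive prediction matches the BFS-radius definition", {
  sp <- toy_space()
  # two scaffolds one reaction apart, n = 0: 2 nodes, 1 edge
  a <- sp$keys[1]
  b <- space_neighbors(sp, a)[1]
  rm0 <- report_matrix(c("G1", "G1"), c(a, b))
  nv <- naive_predict(rm0, sp, 0)
  expect_equal(igraph::vcount(nv$G1), 2)
  expect_equal(igraph::ecount(nv$G1), 1)
  # single reported scaffold: 1 node, no edges
  nv1 <- naive_predict(report_matrix("G1", a), sp, 0)
  expect_equal(igraph::vcount(nv1$G1), 1)
  expect_equal(igraph::ecount(nv1$G1), 0)
  # two scaffolds exactly two reactions apart bridge at n = 1
  two_away <- setdiff(unique(unlist(lapply(space_neighbors(sp, a),
                                           function(k) space_neighbors(sp, k)))),
                      c(a, space_neighbors(sp, a)))
  c2 <- two_away[1]
  rm2 <- report_matrix(c("G1", "G1"), c(a, c2))
  nv2a <- naive_predict(rm2, sp, 0)
  expect_equal(igraph::components(nv2a$G1)$no, 2)
  nv2b <- naive_predict(rm2, sp, 1)
  expect_equal(igraph::components(nv2b$G1)$no, 1)
  # BFS-radius oracle: node set equals union of closed 1-neighborhoods
  expect_setequal(igraph::V(nv2b$G1)$name,
                  unique(c(a, c2, space_neighbors(sp, a),
                           space_neighbors(sp, c2))))
  # unknown scaffold is named in the error
  expect_error(naive_predict(report_matrix("G1", "9,9,9,9,9,9,9,9,9,9"), sp, 0),
               "9,9")
})

test_that("diamond pruning keeps routes by tolerance, by exhaustive oracle", {
  # a -- b -- d and a -- c -- d; reported a, d; b scores 8, c scores 6
  g <- fake_naive(rbind(c("a", "b"), c("b", "d"), c("a", "c"), c("c", "d")),
                  reported = c("a", "d"))
  sc <- fake_scores(c(a = 1, b = 8, c = 6, d = 1))
  p10 <- prune_hypothesis(g, sc, reconstruction_params(tolerance = 10), "G1")
  expect_setequal(p10$nodes$key, c("a", "b", "d"))
  # top route scores 10, alternative 8: 20% tolerance admits both
  p20 <- prune_hypothesis(g, sc, reconstruction_params(tolerance = 20), "G1")
  expect_setequal(p20$nodes$key, c("a", "b", "c", "d"))
  # tolerance 100: the whole component survives
  p100 <- prune_hypothesis(g, sc, reconstruction_params(tolerance = 100), "G1")
  expect_setequal(p100$nodes$key, c("a", "b", "c", "d"))
  expect_equal(nrow(p100$edges), 4)
  # single reported node component passes through untouched
  g1 <- fake_naive(rbind(c("x", "y")), reported = "x") |>
    igraph::delete_vertices("y")
  ph <- prune_hypothesis(g1, fake_scores(c(x = 1)), reconstruction_params(), "G1")
  expect_equal(ph$nodes$key, "x")
})

test_that("pruning is monotone in tolerance", {
  set.seed(3)
  sp <- toy_space()
  fx <- generate_fixture(sp, n_tips = 6, fraction = 0.6,
                         config = evolution_config(ancestral_edges = 4,
                                                   max_enzymes = 8,
                                                   rounds_per_unit = 40),
                         seed = 5)
  scores <- score_items(fx$reports, fx$tree, "correlation", "reported")
  nv <- naive_predict(fx$reports, sp, 1)
  for (g in names(nv)[1:3]) {
    prev <- NULL
    for (tol in c(0, 20, 50, 100)) {
      h <- prune_hypothesis(nv[[g]], scores,
                            reconstruction_params(tolerance = tol), g)
      if (!is.null(prev)) {
        expect_true(all(prev$nodes$key %in% h$nodes$key))
        expect_true(all(prev$edges$id %in% h$edges$id))
      }
      prev <- h
    }
    # reported scaffolds are never dropped at tolerance 100
    rep_keys <- igraph::V(nv[[g]])$name[igraph::V(nv[[g]])$reported]
    expect_true(all(rep_keys %in% prev$nodes$key))
  }
})

test_that("edge-weighted pruning uses edge scores", {
  g <- fake_naive(rbind(c("a", "b"), c("b", "d"), c("a", "c"), c("c", "d")),
                  reported = c("a", "d"))
  vsc <- fake_scores(c(a = 0, b = 0, c = 0, d = 0))
  esc <- fake_scores(c("a|b" = 5, "b|d" = 5, "a|c" = 1, "c|d" = 1))
  p <- prune_hypothesis(g, vsc,
                        reconstruction_params(apply_on = "edges", tolerance = 10),
                        "G1", edge_scores = esc)
  expect_setequal(p$nodes$key, c("a", "b", "d"))
  expect_setequal(p$edges$id, c("a|b", "b|d"))
})

test_that("ancestral pathway keeps near-universal items and drops rare ones", {
  tr <- star_tree(6, len = 0.15)
  mk_hyp <- function(genus, nodes, edges = character(0)) {
    structure(list(genus = genus,
                   nodes = data.frame(key = nodes,
                                      reported = rep(TRUE, length(nodes)),
                                      stringsAsFactors = FALSE),
                   edges = if (length(edges)) {
                     ep <- strsplit(edges, "|", fixed = TRUE)
                     data.frame(id = edges,
                                from = vapply(ep, `[`, "", 1),
                                to = vapply(ep, `[`, "", 2),
                                stringsAsFactors = FALSE)
                   } else data.frame(id = character(0), from = character(0),
                                     to = character(0)),
                   params = reconstruction_params()),
              class = "pathway_hypothesis")
  }
  hyps <- setNames(lapply(letters[1:6], function(g)
    mk_hyp(g, nodes = c("m1", "m2", if (g == "a") "rare"),
           edges = "m1|m2")), letters[1:6])
  anc <- ancestral_pathway(hyps, tr, threshold = 0.9)
  expect_true(all(c("m1", "m2") %in% anc$nodes$item))
  expect_false("rare" %in% anc$nodes$item)
  expect_true("m1|m2" %in% anc$edges$item)
  # cross-check the rare item against the pruning recursion directly
  w <- felsenstein_root_weight(tr, "a")
  expect_lt(w, 0.9)
  expect_equal(anc$all_node_weights$weight[anc$all_node_weights$item == "rare"],
               w, tolerance = 1e-12)
  expect_error(ancestral_pathway(hyps, tr, threshold = 1.5), "threshold")
})

test_that("full reconstruction rescues unconnected reported scaffolds", {
  sp <- toy_space()
  set.seed(7)
  fx <- generate_fixture(sp, n_tips = 6, fraction = 0.5,
                         config = evolution_config(ancestral_edges = 5,
                                                   max_enzymes = 10,
                                                   rounds_per_unit = 60),
                         seed = 7)
  hyps <- reconstruct_pathways(fx$reports, sp, fx$tree)
  m <- presence_matrix(fx$reports, "reported")
  for (g in names(hyps$hypotheses)) {
    rep_keys <- colnames(m)[m[g, ] > 0]
    expect_true(all(rep_keys %in% hyps$hypotheses[[g]]$nodes$key))
  }
  s <- summary(hyps)
  expect_gte(s$n_reported, 1)
  expect_output(print(s), "unique scaffolds")
})
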