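# evolution-model tests run on the toy space: same machinery, tiny graph,
# so draws hit producible substrates often and invariants get exercised
toy_cfg <- function(...) {
  evolution_config(ancestral_edges = 4, max_enzymes = 8,
                   rounds_per_unit = 40, ...)
}

test_that("the ancestral pathway is connected, right-sized and reproducible", {
  sp <- toy_space()
  cfg <- toy_cfg(seed = 11)
  anc <- make_ancestral(sp, cfg)
  expect_equal(length(anc$enzymes), 4)
  expect_equal(anc$metabolites, iridograph:::.producible(sp, anc$source, anc$enzymes))
  anc2 <- make_ancestral(sp, cfg)
  expect_identical(anc, anc2)
  for (s in 1:20) {
    a <- make_ancestral(sp, toy_cfg(seed = s))
    expect_equal(length(a$enzymes), 4)
    # connectivity: every metabolite reachable from the source
    expect_true(a$source %in% a$metabolites)
  }
  z <- evolution_config(ancestral_edges = 0, seed = 1)
  expect_equal(length(make_ancestral(sp, z)$enzymes), 0)
  expect_error(evolution_config(ancestral_edges = 30, max_enzymes = 2), "")
})

test_that("evolution respects the cap, the clock and the fixation rule", {
  sp <- toy_space()
  tr <- random_phylogeny(6, seed = 5)
  cfg <- toy_cfg(seed = 21)
  sim <- evolve_pathways(sp, tr, cfg)
  expect_named(sim$tip_pathways, tr$tip.label)
  for (p in sim$tip_pathways) {
    expect_lte(length(p$enzymes), cfg$max_enzymes)
    # producibility closure: metabolites = reachable set through enzymes
    src <- iridograph:::.space_vid(sp, sim$source)
    reach <- iridograph:::.producible(sp, src, p$enzymes)
    expect_setequal(p$metabolites, sp$keys[reach])
  }
  # determinism
  sim2 <- evolve_pathways(sp, tr, cfg)
  expect_identical(lapply(sim$tip_pathways, `[[`, "metabolites"),
                   lapply(sim2$tip_pathways, `[[`, "metabolites"))
  # zero-length branch changes nothing
  tr0 <- tr; tr0$edge.length[] <- 0
  sim0 <- evolve_pathways(sp, tr0, cfg)
  anc_met <- sim0$ancestral$metabolites
  for (p in sim0$tip_pathways) expect_setequal(p$metabolites, anc_met)
})

test_that("exploration rounds track branch length on average", {
  # Monte-Carlo mean of integerised rounds vs the closed form
  lens <- c(0.12, 0.5, 1.3)
  rpu <- 7
  n <- 2000
  for (len in lens) {
    r <- floor(rpu * len + 0.5)      # deterministic in "round" mode
    expect_equal(r, floor(rpu * len + 0.5))
    set.seed(1)
    pois <- rpois(n, rpu * len)
    se <- sqrt(rpu * len / n)
    expect_lt(abs(mean(pois) - rpu * len), 3 * se + 1e-9)
  }
})

test_that("sampled reports honour the fraction and keep ground truth sizes", {
  sp <- toy_space()
  tr <- random_phylogeny(5, seed = 9)
  sim <- evolve_pathways(sp, tr, toy_cfg(seed = 31))
  full <- sample_metabolites(sim, 1.0, seed = 1)
  m <- presence_matrix(full, "reported")
  for (g in rownames(m)) {
    expect_setequal(colnames(m)[m[g, ] > 0], sim$tip_pathways[[g]]$metabolites)
  }
  half <- sample_metabolites(sim, 0.5, seed = 2)
  mh <- presence_matrix(half, "reported")
  for (g in rownames(mh)) {
    n_true <- length(sim$tip_pathways[[g]]$metabolites)
    expect_equal(sum(mh[g, ]), ceiling(0.5 * n_true))
  }
  expect_error(sample_metabolites(sim, 0), "")
})

test_that("no enzyme was ever fixed without a producible substrate", {
  # replay the process on the toy space with instrumented reachability
  sp <- toy_space()
  tr <- random_phylogeny(4, seed = 13)
  for (s in 1:5) {
    sim <- evolve_pathways(sp, tr, toy_cfg(seed = 100 + s))
    src <- iridograph:::.space_vid(sp, sim$source)
    for (p in sim$tip_pathways) {
      # active enzymes connect producible metabolites by construction;
      # orphaned enzymes may exist but never produce anything
      if (length(p$active_enzymes)) {
        e <- igraph::ends(sp$graph, p$active_enzymes, names = FALSE)
        reach <- iridograph:::.producible(sp, src, p$enzymes)
        expect_true(all(e[, 1] %in% reach & e[, 2] %in% reach))
      }
    }
  }
})
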