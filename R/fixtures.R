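# Synthetic fixture generation: random phylogenies, simulated pathway sets,
# sampled report matrices and spiked expression matrices, so the whole
# pipeline runs without any external file.

#' Random genus phylogeny
#'
#' @param n_tips number of genera (default 12).
#' @param ultrametric coalescent (ultrametric) or birth-death style
#'   branch lengths.
#' @param seed integer seed.
#' @return an \code{ape::phylo} with tips "G01", "G02", ...
#' @export
random_phylogeny <- function(n_tips = 12, ultrametric = TRUE, seed = 1) {
  set.seed(seed)
  tr <- if (ultrametric) ape::rcoal(n_tips) else ape::rtree(n_tips)
  # normalise depth to ~1 so rate/round parameters are comparable across draws
  depth <- max(ape::node.depth.edgelength(tr)[seq_len(n_tips)])
  tr$edge.length <- tr$edge.length / depth
  tr$tip.label <- sprintf("G%02d", seq_len(n_tips))
  tr
}

#' Synthetic expression matrix with one spiked coexpressed module
#'
#' Background transcripts draw independent profiles; module transcripts
#' share one profile plus transcript-level noise, emulating a coexpressed
#' biosynthetic module containing the baits.
#'
#' @param n_transcripts total transcripts.
#' @param n_tissues tissue columns.
#' @param module_size transcripts in the spiked module (baits included).
#' @param n_baits how many module members are designated baits.
#' @param noise_sd within-module noise, on the log2 scale.
#' @param seed integer seed.
#' @return a list with \code{expr} (FPKM-like matrix), \code{module}
#'   (module transcript ids) and \code{baits}.
#' @export
spiked_expression <- function(n_transcripts = 1000, n_tissues = 8,
                              module_size = 30, n_baits = 5,
                              noise_sd = 0.5, seed = 1) {
  stopifnot(module_size <= n_transcripts, n_baits <= module_size)
  set.seed(seed)
  ids <- sprintf("T%05d", seq_len(n_transcripts))
  tissues <- sprintf("tissue%02d", seq_len(n_tissues))
  base <- matrix(stats::rnorm(n_transcripts * n_tissues, 4, 2),
                 n_transcripts, n_tissues, dimnames = list(ids, tissues))
  profile <- stats::rnorm(n_tissues, 4, 3)
  mod <- seq_len(module_size)
  base[mod, ] <- matrix(profile, module_size, n_tissues, byrow = TRUE) +
    stats::rnorm(module_size * n_tissues, 0, noise_sd)
  expr <- 2^base - 1
  expr[expr < 0] <- 0
  list(expr = expr, module = ids[mod], baits = ids[seq_len(n_baits)])
}

#' Generate a complete synthetic fixture bundle
#'
#' Produces a random phylogeny, a pathway-evolution simulation on the given
#' chemical space, a sampled report matrix, and a spiked expression matrix,
#' all reproducible from the seed.
#'
#' @param space a \code{chem_space}.
#' @param n_tips genera in the tree.
#' @param fraction report sampling fraction.
#' @param config an \code{evolution_config}; its seed is overridden by
#'   \code{seed} for reproducibility of the bundle.
#' @param seed master seed.
#' @return a list of class \code{fixture_bundle} with \code{tree},
#'   \code{sim}, \code{reports}, \code{expression}, \code{seed}.
#' @export
generate_fixture <- function(space, n_tips = 12, fraction = 0.5,
                             config = evolution_config(), seed = 1) {
  config$seed <- seed + 1L
  tree <- random_phylogeny(n_tips, seed = seed)
  sim <- evolve_pathways(space, tree, config)
  reports <- sample_metabolites(sim, fraction, seed = seed + 2L)
  expr <- spiked_expression(seed = seed + 3L)
  structure(list(tree = tree, sim = sim, reports = reports,
                 expression = expr, fraction = fraction, seed = seed,
                 config = config),
            class = "fixture_bundle")
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat("<fixture_bundle> seed", x$seed, ":", length(x$tree$tip.label),
      "genera, sampling fraction", x$fraction, "\n")
  invisible(x)
}

#' Read / write grammar configuration as YAML
#'
#' @param grammar an \code{iridoid_grammar}.
#' @param path file path.
#' @export
write_grammar <- function(grammar, path) {
  yaml::write_yaml(list(
    n_states = as.list(stats::setNames(as.integer(grammar$n_states),
                                       grammar$carbons)),
    flag_states = grammar$flag_states,
    bonds = grammar$bond_labels,
    epoxide_bonds = grammar$bond_labels[grammar$epoxide_ok],
    moves = grammar$moves,
    edge_count = grammar$edge_count), path)
  invisible(path)
}

#' @rdname write_grammar
#' @export
read_grammar <- function(path) {
  y <- yaml::read_yaml(path)
  bonds <- do.call(rbind, strsplit(unlist(y$bonds), "-", fixed = TRUE))
  iridoid_grammar(n_states = unlist(y$n_states),
                  flag_states = y$flag_states,
                  bonds = bonds,
                  epoxide_bonds = unlist(y$epoxide_bonds),
                  moves = unlist(y$moves),
                  edge_count = y$edge_count)
}
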