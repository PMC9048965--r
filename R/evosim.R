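#' Configuration of the pathway-evolution simulation
#'
#' The neutral evolution model rests on three constraints: uniform random
#' exploration of the chemical space with fixation only when a substrate is
#' present, a cap on the number of enzymes a lineage can maintain, and a
#' molecular clock (exploration rounds proportional to branch length).
#'
#' @param ancestral_edges number of reactions in the root pathway.
#' @param max_enzymes enzyme cap per lineage.
#' @param rounds_per_unit exploration rounds per unit branch length.
#' @param source_scaffold key (or \code{scaffold_code}) of the pathway entry
#'   point; default is the all-zero (fully saturated) scaffold.
#' @param rounds_mode "round" integerises rounds by rounding half-up;
#'   "poisson" draws Poisson(rounds_per_unit x length).
#' @param seed integer seed for the simulation.
#' @return an object of class \code{evolution_config}.
#' @export
evolution_config <- function(ancestral_edges = 4, max_enzymes = 20,
                             rounds_per_unit = 30000, source_scaffold = NULL,
                             rounds_mode = c("round", "poisson"), seed = 1) {
  rounds_mode <- match.arg(rounds_mode)
  stopifnot(ancestral_edges >= 0, max_enzymes >= 1,
            ancestral_edges <= max_enzymes, rounds_per_unit >= 0)
  structure(list(ancestral_edges = as.integer(ancestral_edges),
                 max_enzymes = as.integer(max_enzymes),
                 rounds_per_unit = rounds_per_unit,
                 source_scaffold = source_scaffold,
                 rounds_mode = rounds_mode, seed = as.integer(seed)),
            class = "evolution_config")
}

.source_key <- function(space, config) {
  if (is.null(config$source_scaffold))
    return(code_key(scaffold_code(rep(0L, 10))))
  if (inherits(config$source_scaffold, "scaffold_code"))
    return(code_key(config$source_scaffold))
  config$source_scaffold
}

# enzymes: integer vector of edge ids of space$graph.
# producible set: vertices reachable from the source through enzyme edges.
.producible <- function(space, source_vid, enzymes) {
  if (!length(enzymes)) return(source_vid)
  ends <- igraph::ends(space$graph, enzymes, names = FALSE)
  reach <- source_vid
  repeat {
    hit <- ends[, 1] %in% reach | ends[, 2] %in% reach
    new <- setdiff(unique(as.vector(ends[hit, , drop = FALSE])), reach)
    if (!length(new)) break
    reach <- c(reach, new)
  }
  sort(reach)
}

#' Grow a random ancestral pathway
#'
#' Grows a connected subgraph of the space from the source scaffold by
#' repeatedly fixing a uniformly chosen reaction incident to the current
#' metabolite set, until the configured number of reactions is reached.
#'
#' @param space a \code{chem_space}.
#' @param config an \code{evolution_config}; its seed is used.
#' @return list with \code{enzymes} (edge ids), \code{metabolites} (vertex
#'   ids), \code{source} (vertex id).
#' @export
make_ancestral <- function(space, config) {
  set.seed(config$seed)
  src <- .space_vid(space, .source_key(space, config))
  enzymes <- integer(0)
  metab <- src
  for (i in seq_len(config$ancestral_edges)) {
    inc <- unique(unlist(igraph::incident_edges(space$graph, metab)))
    inc <- setdiff(inc, enzymes)
    if (!length(inc))
      stop("ancestral_edges exceeds the reachable neighborhood of the source")
    e <- if (length(inc) == 1) inc else sample(inc, 1)
    enzymes <- c(enzymes, e)
    metab <- .producible(space, src, enzymes)
  }
  list(enzymes = sort(enzymes), metabolites = metab, source = src)
}

#' Simulate pathway evolution along a phylogeny
#'
#' Pre-order traversal from the root: every branch runs a number of
#' exploration rounds proportional to its length.  A round draws one
#' reaction of the space uniformly at random and fixes it as a new enzyme
#' only if at least one of its substrates is currently producible from the
#' source; when the enzyme cap is exceeded, a uniformly chosen existing
#' enzyme is lost and producibility is recomputed.  Children evolve
#' independently from a copy of the parent state.
#'
#' @param space a \code{chem_space}.
#' @param tree an \code{ape::phylo} with branch lengths.
#' @param config an \code{evolution_config}.
#' @return an object of class \code{pathway_simulation}: \code{tip_pathways}
#'   (per-genus lists with \code{metabolites}, \code{enzymes}, and the
#'   igraph \code{graph} of active reactions), \code{node_snapshots},
#'   \code{ancestral}, \code{config}.
#' @export
evolve_pathways <- function(space, tree, config) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  set.seed(config$seed)
  src <- .space_vid(space, .source_key(space, config))
  anc <- make_ancestral(space, config)
  ne_total <- igraph::ecount(space$graph)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  states <- vector("list", ntip + tree$Nnode)
  states[[root]] <- list(enzymes = anc$enzymes, metab = anc$metabolites)
  # pre-order: parents before children
  eo <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(eo$edge))) {
    parent <- eo$edge[k, 1]; child <- eo$edge[k, 2]
    len <- eo$edge.length[k]
    st <- states[[parent]]
    rounds <- switch(config$rounds_mode,
                     round = as.integer(floor(config$rounds_per_unit * len + 0.5)),
                     poisson = stats::rpois(1, config$rounds_per_unit * len))
    if (rounds > 0) for (r in seq_len(rounds)) {
      draw <- sample.int(ne_total, 1)
      if (draw %in% st$enzymes) next
      ends <- igraph::ends(space$graph, draw, names = FALSE)
      if (!(ends[1] %in% st$metab || ends[2] %in% st$metab)) next
      st$enzymes <- c(st$enzymes, draw)
      if (length(st$enzymes) > config$max_enzymes) {
        st$enzymes <- st$enzymes[-sample.int(length(st$enzymes), 1)]
      }
      st$metab <- .producible(space, src, st$enzymes)
    }
    states[[child]] <- st
  }
  tips <- stats::setNames(vector("list", ntip), tree$tip.label)
  for (i in seq_len(ntip)) {
    st <- states[[i]]
    tips[[i]] <- .pathway_view(space, src, st)
  }
  snapshots <- lapply(states[(ntip + 1):(ntip + tree$Nnode)], function(st)
    if (is.null(st)) NULL else .pathway_view(space, src, st))
  structure(list(tip_pathways = tips, node_snapshots = snapshots,
                 ancestral = .pathway_view(space, src,
                                           list(enzymes = anc$enzymes,
                                                metab = anc$metabolites)),
                 source = space$keys[src], config = config, tree = tree),
            class = "pathway_simulation")
}

# pathway view of a lineage state: active enzymes (both endpoints
# producible), producible metabolites, as keys + an igraph
.pathway_view <- function(space, src, st) {
  keys <- space$keys[st$metab]
  active <- integer(0)
  if (length(st$enzymes)) {
    ends <- igraph::ends(space$graph, st$enzymes, names = FALSE)
    act <- ends[, 1] %in% st$metab & ends[, 2] %in% st$metab
    active <- st$enzymes[act]
  }
  g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(keys)
  if (length(active)) {
    ends <- igraph::ends(space$graph, active, names = TRUE)
    g <- igraph::add_edges(g, rbind(match(ends[, 1], keys),
                                    match(ends[, 2], keys)))
  }
  list(metabolites = keys, enzymes = st$enzymes, active_enzymes = active,
       edge_ids = if (length(active)) {
         e <- igraph::ends(space$graph, active, names = TRUE)
         .edge_id(e[, 1], e[, 2])
       } else character(0),
       graph = g)
}

#' @export
print.pathway_simulation <- function(x, ...) {
  sizes <- vapply(x$tip_pathways, function(p) length(p$metabolites), integer(1))
  cat("<pathway_simulation>", length(x$tip_pathways), "genera; metabolites per genus:",
      paste(range(sizes), collapse = "-"), "\n")
  invisible(x)
}

#' Randomly sample reported metabolites from a simulation
#'
#' Emulates incomplete literature coverage: per genus, a uniform random
#' subset of \code{ceiling(fraction x metabolites)} producible metabolites
#' is marked reported.
#'
#' @param sim a \code{pathway_simulation}.
#' @param fraction sampling fraction in (0, 1].
#' @param seed integer seed.
#' @return a \code{report_matrix} (items are scaffold keys).
#' @export
sample_metabolites <- function(sim, fraction, seed = 1) {
  stopifnot(fraction > 0, fraction <= 1)
  set.seed(seed)
  genus <- character(0); item <- character(0)
  for (g in names(sim$tip_pathways)) {
    mets <- sim$tip_pathways[[g]]$metabolites
    if (!length(mets)) { warning("genus ", g, " has an empty pathway"); next }
    k <- ceiling(fraction * length(mets))
    pick <- if (length(mets) == 1) mets else sample(mets, k)
    genus <- c(genus, rep(g, length(pick)))
    item <- c(item, pick)
  }
  report_matrix(genus, item)
}
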