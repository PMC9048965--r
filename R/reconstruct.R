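#' Reconstruction parameter bundle
#'
#' @param n_reactions extension radius (0, 1, 2, ...): how many reactions
#'   beyond the reported scaffolds the naive prediction reaches.
#' @param basis compute phylogenetic scores on "reported" or "predicted"
#'   presence.
#' @param scheme "correlation" or "felsenstein".
#' @param apply_on sum scores over "vertices", "edges" or "both".
#' @param tolerance percentage of the maximum pathway score within which
#'   alternative pathways are kept (0 = only optimal, 100 = no pruning).
#' @param tolerance_scope "global" measures the tolerance against the best
#'   pathway score anywhere in the naive graph, so whole low-affinity
#'   components drop out of a genus hypothesis; "component" measures it
#'   within each component, which never discards a component.
#' @return an object of class \code{reconstruction_params}.
#' @export
reconstruction_params <- function(n_reactions = 0,
                                  basis = c("reported", "predicted"),
                                  scheme = c("correlation", "felsenstein"),
                                  apply_on = c("vertices", "edges", "both"),
                                  tolerance = 10,
                                  tolerance_scope = c("global", "component")) {
  basis <- match.arg(basis); scheme <- match.arg(scheme)
  apply_on <- match.arg(apply_on)
  tolerance_scope <- match.arg(tolerance_scope)
  stopifnot(n_reactions >= 0, tolerance >= 0, tolerance <= 100)
  structure(list(n_reactions = as.integer(n_reactions), basis = basis,
                 scheme = scheme, apply_on = apply_on,
                 tolerance = tolerance, tolerance_scope = tolerance_scope),
            class = "reconstruction_params")
}

#' @export
print.reconstruction_params <- function(x, ...) {
  cat(sprintf("<reconstruction_params> %d reactions | %s | %s | %s | tolerance %g%%\n",
              x$n_reactions, x$basis, x$scheme, x$apply_on, x$tolerance))
  invisible(x)
}

#' Naive per-genus prediction networks
#'
#' Takes every scaffold reported anywhere in the family as a point in the
#' chemical space, expands the set by \code{n_reactions} (breadth-first
#' radius), and connects every included pair at unit reaction distance.
#' This shared family-wide graph is returned once per genus, with that
#' genus's own reported scaffolds flagged: scaffolds reported in other
#' genera sit in the graph as candidate intermediates, which is what lets a
#' pathway hypothesis predict a metabolite never reported in the focal
#' genus.  No phylogenetic information enters.
#'
#' @param reports a \code{report_matrix} whose items are scaffold keys.
#' @param space a \code{chem_space}.
#' @param n_reactions extension radius.
#' @return a named list of igraph graphs, one per genus (all sharing the
#'   family-wide node set), with a logical vertex attribute \code{reported}
#'   marking the focal genus's scaffolds.
#' @export
naive_predict <- function(reports, space, n_reactions = 0) {
  m <- presence_matrix(reports, "reported")
  all_keys <- colnames(m)[colSums(m) > 0]
  if (!length(all_keys))
    return(stats::setNames(rep(list(igraph::make_empty_graph(directed = FALSE)),
                               nrow(m)), rownames(m)))
  ids <- .space_vid(space, all_keys)
  if (n_reactions > 0) {
    hood <- igraph::ego(space$graph, order = n_reactions, nodes = ids)
    ids <- sort(unique(unlist(lapply(hood, as.integer))))
  }
  shared <- igraph::induced_subgraph(space$graph, ids)
  shared_names <- igraph::V(shared)$name
  igraph::V(shared)$family_reported <- shared_names %in% all_keys
  out <- list()
  for (g in rownames(m)) {
    keys <- colnames(m)[m[g, ] > 0]
    gg <- shared
    igraph::V(gg)$reported <- shared_names %in% keys
    out[[g]] <- gg
  }
  out
}

# ---- candidate pathway enumeration -----------------------------------------
# A candidate pathway of a component is a minimal connector: the reported
# (terminal) nodes plus a minimal set of intermediates whose induced subgraph
# joins every terminal.  Exhaustive below `exact_cutoff` nodes; otherwise a
# capped randomised shortest-path assembly.

# adjacency list of an igraph as a list of integer vectors
.adj_list <- function(g) {
  lapply(igraph::adjacent_vertices(g, igraph::V(g)), as.integer)
}

# BFS connectivity of the terminals within the kept vertex set
.connects_adj <- function(adj, keep, terminals) {
  seen <- logical(length(adj))
  seen[terminals[1]] <- TRUE
  frontier <- terminals[1]
  while (length(frontier)) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[keep[nxt] & !seen[nxt]]
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen[terminals])
}

.minimalize_adj <- function(adj, vids, terminals) {
  # single pass suffices: removing vertices never makes another vertex
  # removable that was not, so each candidate needs testing only once
  keep <- logical(length(adj)); keep[vids] <- TRUE
  extra <- setdiff(vids, terminals)
  if (length(extra) > 1) extra <- sample(extra)
  for (s in extra) {
    keep[s] <- FALSE
    if (!.connects_adj(adj, keep, terminals)) keep[s] <- TRUE
  }
  which(keep)
}

.enumerate_connectors <- function(g, terminals, exact_cutoff = 12,
                                  max_candidates = 10000, n_heuristic = 25,
                                  guide = NULL) {
  vnames <- igraph::V(g)$name
  tid <- match(terminals, vnames)
  if (length(tid) == 1) return(list(tid))
  adj <- .adj_list(g)
  nv <- length(adj)
  others <- setdiff(seq_len(nv), tid)
  keep <- logical(nv)
  if (nv <= exact_cutoff) {
    # exhaustive: every minimal connector of the terminals
    cands <- list()
    for (k in 0:length(others)) {
      sets <- if (k == 0) list(integer(0)) else
        utils::combn(others, k, simplify = FALSE)
      for (s in sets) {
        keep[] <- FALSE; keep[tid] <- TRUE; keep[s] <- TRUE
        if (!.connects_adj(adj, keep, tid)) next
        minimal <- TRUE
        for (x in s) {
          keep[x] <- FALSE
          ok <- .connects_adj(adj, keep, tid)
          keep[x] <- TRUE
          if (ok) { minimal <- FALSE; break }
        }
        if (minimal) cands[[length(cands) + 1]] <- sort(c(tid, s))
        if (length(cands) >= max_candidates) return(cands)
      }
    }
    return(cands)
  }
  # Large components: pairwise-route candidates.  A candidate pathway is a
  # route (path vertex set) between two reported scaffolds; several
  # near-shortest variants are drawn per pair with jittered weights, and,
  # when a score guide is given, additional variants discount edges between
  # high-scoring metabolites so routes deviate through phylogenetically
  # plausible intermediates.  Internally seeded from the component shape so
  # repeated pruning of the same naive graph sees identical candidates.
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed((nv * 7919L + length(tid) * 131L +
              igraph::ecount(g)) %% .Machine$integer.max)
  el <- igraph::as_edgelist(g, names = FALSE)
  smax <- if (!is.null(guide)) max(guide, 1e-9) else NULL
  seen <- new.env(hash = TRUE)
  cands <- list()
  n_variants <- if (is.null(guide)) 2L else 4L
  for (vset in seq_len(n_variants)) {
    if (!is.null(guide) && vset > 2L) {
      sc <- pmax(guide, 0) / smax
      w <- (0.05 + (1 - sc[el[, 1]]) + (1 - sc[el[, 2]])) *
        stats::runif(nrow(el), 1, 1.05)
    } else {
      w <- stats::runif(nrow(el), 1, 1.2)
    }
    for (src_t in tid) {
      sp <- suppressWarnings(
        igraph::shortest_paths(g, from = src_t, to = tid[tid > src_t],
                               weights = w, output = "vpath"))
      for (p in sp$vpath) {
        if (!length(p)) next
        vids <- sort(unique(as.integer(p)))
        key <- paste(vids, collapse = ",")
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          cands[[length(cands) + 1]] <- vids
          if (length(cands) >= max_candidates) return(cands)
        }
      }
    }
  }
  # terminals isolated from every other terminal still form a candidate
  covered <- unique(unlist(cands, use.names = FALSE))
  for (t in setdiff(tid, covered)) cands[[length(cands) + 1]] <- t
  cands
}

.lookup_scores <- function(keys, vec, scheme) {
  default <- if (scheme == "felsenstein") 0.5 else 0
  out <- vec[keys]
  out[is.na(out)] <- default
  unname(out)
}

#' Prune a naive prediction into a pathway hypothesis
#'
#' Per connected component of the naive graph, enumerates candidate pathways
#' (minimal connectors of the component's reported nodes), scores each by
#' the summed phylogenetic scores of its vertices, edges or both, and keeps
#' every candidate within \code{tolerance} percent of the maximum score.
#' The hypothesis is the union of the retained candidates; at tolerance 100
#' no pruning is applied and the reported components are returned whole.
#'
#' @param naive one genus graph from \code{\link{naive_predict}}.
#' @param scores an \code{item_scores} for the metabolites (vertices).
#' @param params a \code{reconstruction_params}.
#' @param genus focal genus name (selects the score row under the
#'   correlation scheme).
#' @param edge_scores optional \code{item_scores} over edge ids, required
#'   when \code{params$apply_on} involves edges.
#' @param exact_cutoff,max_candidates,n_heuristic connector enumeration
#'   controls: exhaustive enumeration up to \code{exact_cutoff} component
#'   nodes, then capped randomised assembly.
#' @return an object of class \code{pathway_hypothesis} with \code{nodes}
#'   (key, reported), \code{edges} (id, from, to) and provenance.
#' @export
prune_hypothesis <- function(naive, scores, params, genus = NULL,
                             edge_scores = NULL, exact_cutoff = 12,
                             max_candidates = 10000, n_heuristic = 25) {
  stopifnot(inherits(params, "reconstruction_params"))
  sc <- .scored_candidates(naive, scores, params$apply_on, genus,
                           edge_scores, exact_cutoff, max_candidates,
                           n_heuristic)
  .apply_tolerance(sc, params, genus, always_keep = .genus_reported(naive))
}

# the focal genus's reported scaffold keys of a naive graph
.genus_reported <- function(naive) {
  rep_attr <- igraph::V(naive)$reported
  if (is.null(rep_attr)) return(character(0))
  igraph::V(naive)$name[rep_attr]
}

# Enumerate candidate connectors per component, independent of both the
# tolerance and the scoring scheme, so several parameter combinations can
# share one (expensive) enumeration.
.component_connectors <- function(naive, guide = NULL, exact_cutoff = 12,
                                  max_candidates = 10000, n_heuristic = 25) {
  g <- naive
  vnames <- igraph::V(g)$name
  reported <- igraph::V(g)$family_reported
  if (is.null(reported)) reported <- igraph::V(g)$reported
  if (is.null(reported)) reported <- rep(TRUE, igraph::vcount(g))
  comp <- igraph::components(g)
  comps <- list()
  n_dropped <- 0L
  for (ci in seq_len(comp$no)) {
    vids <- which(comp$membership == ci)
    terms_mask <- reported[vids]
    if (!any(terms_mask)) { n_dropped <- n_dropped + 1L; next }
    sub <- igraph::induced_subgraph(g, vids)
    sub_names <- igraph::V(sub)$name
    el <- igraph::as_edgelist(sub, names = FALSE)
    all_eids <- if (nrow(el)) .edge_id(sub_names[el[, 1]], sub_names[el[, 2]])
                else character(0)
    edge_ends <- if (nrow(el)) cbind(sub_names[el[, 1]], sub_names[el[, 2]])
                 else matrix(character(0), 0, 2)
    terms <- sub_names[match(vnames[vids][terms_mask], sub_names)]
    gsub <- if (!is.null(guide)) .lookup_scores(sub_names, guide, "correlation")
            else NULL
    cands <- .enumerate_connectors(sub, terms, exact_cutoff, max_candidates,
                                   n_heuristic, guide = gsub)
    keys_list <- lapply(cands, function(cv) sub_names[cv])
    edges_list <- lapply(cands, function(cv) {
      keep <- logical(length(sub_names)); keep[cv] <- TRUE
      if (!nrow(el)) return(character(0))
      all_eids[keep[el[, 1]] & keep[el[, 2]]]
    })
    comps[[length(comps) + 1]] <-
      list(all_keys = sub_names,
           reported_keys = sub_names[match(vnames[vids][terms_mask], sub_names)],
           all_edges = all_eids, edge_ends = edge_ends,
           keys_list = keys_list, edges_list = edges_list)
  }
  if (n_dropped > 0)
    warning("dropped ", n_dropped,
            " component(s) with no reported scaffold for this genus")
  list(components = comps, vnames = vnames, reported = reported)
}

# Attach candidate scores for one weighting scheme / focal genus.
.score_connectors <- function(conns, scores, apply_on, genus = NULL,
                              edge_scores = NULL) {
  use_v <- apply_on %in% c("vertices", "both")
  use_e <- apply_on %in% c("edges", "both")
  if (use_e && is.null(edge_scores))
    stop("edge scores required when apply_on includes edges")
  vscore_vec <- if (!is.null(scores)) {
    if (scores$scheme == "correlation" && !is.null(genus))
      .genus_scores(scores, genus) else scores$aggregate
  } else NULL
  escore_vec <- if (!is.null(edge_scores)) {
    if (edge_scores$scheme == "correlation" && !is.null(genus))
      .genus_scores(edge_scores, genus) else edge_scores$aggregate
  } else NULL
  conns$components <- lapply(conns$components, function(cc) {
    cc$score <- vapply(seq_along(cc$keys_list), function(i) {
      s <- 0
      if (use_v) s <- s + sum(.lookup_scores(cc$keys_list[[i]], vscore_vec,
                                             scores$scheme))
      if (use_e) s <- s + sum(.lookup_scores(cc$edges_list[[i]], escore_vec,
                                             edge_scores$scheme))
      s
    }, numeric(1))
    cc
  })
  conns
}

.scored_candidates <- function(naive, scores, apply_on, genus = NULL,
                               edge_scores = NULL, exact_cutoff = 12,
                               max_candidates = 10000, n_heuristic = 25) {
  guide <- if (!is.null(scores)) {
    if (scores$scheme == "correlation" && !is.null(genus) &&
        genus %in% rownames(scores$scores)) scores$scores[genus, ]
    else scores$aggregate
  } else NULL
  conns <- .component_connectors(naive, guide = guide,
                                 exact_cutoff = exact_cutoff,
                                 max_candidates = max_candidates,
                                 n_heuristic = n_heuristic)
  .score_connectors(conns, scores, apply_on, genus, edge_scores)
}

# Apply the tolerance cutoff to pre-scored candidates and assemble the
# pathway hypothesis (union semantics over retained candidates).  The focal
# genus's own reported scaffolds are always retained, isolated if their
# pathway was discarded.
.apply_tolerance <- function(scored, params, genus = NULL,
                             always_keep = character(0)) {
  keep_keys <- character(0)
  keep_edges <- character(0)
  scope <- params$tolerance_scope %||% "global"
  global_max <- if (length(scored$components))
    max(vapply(scored$components, function(cc) max(cc$score), numeric(1)))
  else -Inf
  for (cc in scored$components) {
    if (params$tolerance >= 100) {
      keep_keys <- c(keep_keys, cc$all_keys)
      keep_edges <- c(keep_edges, cc$all_edges)
      next
    }
    ref <- if (scope == "global") global_max else max(cc$score)
    cutoff <- (1 - params$tolerance / 100) * ref
    kept <- which(cc$score >= cutoff - 1e-12)
    ck <- unlist(cc$keys_list[kept], use.names = FALSE)
    keep_keys <- c(keep_keys, ck)
    # a hypothesis keeps every unit-distance reaction among its retained
    # scaffolds, not only the reactions its routes traversed
    if (nrow(cc$edge_ends)) {
      ink <- cc$edge_ends[, 1] %in% ck & cc$edge_ends[, 2] %in% ck
      keep_edges <- c(keep_edges, cc$all_edges[ink])
    }
  }
  keep_keys <- sort(unique(c(keep_keys, always_keep)))
  keep_edges <- sort(unique(keep_edges))
  rep_mask <- keep_keys %in%
    (if (length(always_keep)) always_keep else scored$vnames[scored$reported])
  nodes <- data.frame(key = keep_keys, reported = rep_mask,
                      stringsAsFactors = FALSE)
  ep <- strsplit(keep_edges, "|", fixed = TRUE)
  edges <- data.frame(id = keep_edges,
                      from = vapply(ep, `[`, "", 1),
                      to = vapply(ep, `[`, "", 2),
                      stringsAsFactors = FALSE)
  structure(list(genus = genus, nodes = nodes, edges = edges,
                 params = params),
            class = "pathway_hypothesis")
}

#' @export
print.pathway_hypothesis <- function(x, ...) {
  cat("<pathway_hypothesis>", x$genus %||% "", ":", nrow(x$nodes),
      "metabolites (", sum(x$nodes$reported), "reported ),",
      nrow(x$edges), "reactions\n")
  invisible(x)
}

# igraph view of a hypothesis
.hyp_graph <- function(h) {
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(h$nodes$key)
  if (nrow(h$edges))
    g <- igraph::add_edges(g, rbind(match(h$edges$from, h$nodes$key),
                                    match(h$edges$to, h$nodes$key)))
  igraph::V(g)$reported <- h$nodes$reported
  g
}

#' Estimate the ancestral pathway from per-genus hypotheses
#'
#' Scores every metabolite and reaction occurring in any hypothesis with its
#' Felsenstein root weight over the across-genera presence pattern and keeps
#' the items whose weight exceeds the threshold.
#'
#' @param hypotheses named list of \code{pathway_hypothesis} (>= 2 genera).
#' @param tree phylogeny covering the genera.
#' @param threshold root-weight cutoff in (0, 1); default 0.9.
#' @param rate symmetric-model rate for the root weights.
#' @return a list of class \code{ancestral_pathway}: \code{nodes} and
#'   \code{edges} data.frames with root weights, and the induced
#'   \code{graph}.
#' @export
ancestral_pathway <- function(hypotheses, tree, threshold = 0.9, rate = 1) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  genera <- names(hypotheses)
  if (length(genera) < 2) stop("need hypotheses for at least two genera")
  node_pres <- list(); edge_pres <- list()
  for (g in genera) {
    node_pres[[g]] <- hypotheses[[g]]$nodes$key
    edge_pres[[g]] <- hypotheses[[g]]$edges$id
  }
  weight_items <- function(pres) {
    items <- sort(unique(unlist(pres)))
    w <- vapply(items, function(it) {
      present <- genera[vapply(genera, function(g) it %in% pres[[g]], logical(1))]
      felsenstein_root_weight(tree, present, rate = rate)
    }, numeric(1))
    data.frame(item = items, weight = w, stringsAsFactors = FALSE)
  }
  nw <- weight_items(node_pres)
  ew <- weight_items(edge_pres)
  keep_n <- nw[nw$weight > threshold, , drop = FALSE]
  keep_e <- ew[ew$weight > threshold, , drop = FALSE]
  # an edge needs both endpoints retained to enter the graph
  ep <- strsplit(keep_e$item, "|", fixed = TRUE)
  oke <- vapply(ep, function(p) all(p %in% keep_n$item), logical(1))
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(keep_n$item)
  if (any(oke)) {
    pe <- ep[oke]
    g <- igraph::add_edges(g, rbind(match(vapply(pe, `[`, "", 1), keep_n$item),
                                    match(vapply(pe, `[`, "", 2), keep_n$item)))
  }
  structure(list(nodes = keep_n, edges = keep_e, graph = g,
                 threshold = threshold, all_node_weights = nw,
                 all_edge_weights = ew),
            class = "ancestral_pathway")
}

#' @export
print.ancestral_pathway <- function(x, ...) {
  cat("<ancestral_pathway>", nrow(x$nodes), "metabolites,", nrow(x$edges),
      "reactions at root weight >", x$threshold, "\n")
  invisible(x)
}

#' Reconstruct pathway hypotheses for every genus
#'
#' The full reconstruction protocol: build naive predictions at the primary
#' extension radius, score items phylogenetically, prune to hypotheses, and
#' optionally rescue reported scaffolds left with no connection by re-running
#' the one-reaction extension model (Felsenstein weights, no tolerance) for
#' those scaffolds only, merging the result.
#'
#' @param reports \code{report_matrix} of scaffold keys.
#' @param space \code{chem_space}.
#' @param tree phylogeny over the report genera.
#' @param params primary \code{reconstruction_params} (default: the
#'   benchmark-selected 0-extension model: reported basis, correlation
#'   weights on vertices, tolerance 10).
#' @param rescue_params parameters for the unconnected-scaffold rescue pass
#'   (default: 1 extension, reported basis, Felsenstein weights, tolerance
#'   0); set NULL to skip the rescue.
#' @param ... passed to \code{\link{prune_hypothesis}}.
#' @return an object of class \code{pathway_hypotheses}: named list of
#'   per-genus \code{pathway_hypothesis} plus provenance.
#' @export
reconstruct_pathways <- function(reports, space, tree,
                                 params = reconstruction_params(),
                                 rescue_params = reconstruction_params(
                                   n_reactions = 1, scheme = "felsenstein",
                                   tolerance = 0),
                                 ...) {
  scores <- score_items(reports, tree, scheme = params$scheme,
                        basis = params$basis)
  naive <- naive_predict(reports, space, params$n_reactions)
  edge_scores <- if (params$apply_on != "vertices")
    .edge_item_scores(reports, naive, tree, params$scheme, params$basis) else NULL
  hyps <- list()
  for (g in names(naive)) {
    hyps[[g]] <- prune_hypothesis(naive[[g]], scores, params, genus = g,
                                  edge_scores = edge_scores, ...)
  }
  if (!is.null(rescue_params)) {
    m <- presence_matrix(reports, "reported")
    r_scores <- score_items(reports, tree, scheme = rescue_params$scheme,
                            basis = rescue_params$basis)
    nv_ext <- NULL
    for (g in names(hyps)) {
      rep_keys <- colnames(m)[m[g, ] > 0]
      deg <- table(c(hyps[[g]]$edges$from, hyps[[g]]$edges$to))
      lonely <- rep_keys[!(rep_keys %in% names(deg))]
      if (!length(lonely) || length(rep_keys) < 2) next
      if (is.null(nv_ext))
        nv_ext <- naive_predict(reports, space, rescue_params$n_reactions)
      h2 <- suppressWarnings(
        prune_hypothesis(nv_ext[[g]], r_scores, rescue_params, genus = g, ...))
      hyps[[g]] <- .merge_hypotheses(hyps[[g]], h2)
    }
  }
  structure(list(hypotheses = hyps, params = params,
                 rescue_params = rescue_params),
            class = "pathway_hypotheses")
}

.merge_hypotheses <- function(a, b) {
  nodes <- rbind(a$nodes, b$nodes)
  nodes <- nodes[order(nodes$key, -nodes$reported), ]
  nodes <- nodes[!duplicated(nodes$key), ]
  edges <- rbind(a$edges, b$edges)
  edges <- edges[!duplicated(edges$id), ]
  structure(list(genus = a$genus, nodes = nodes, edges = edges,
                 params = a$params),
            class = "pathway_hypothesis")
}

#' @export
print.pathway_hypotheses <- function(x, ...) {
  cat("<pathway_hypotheses>", length(x$hypotheses), "genera\n")
  for (g in names(x$hypotheses)) {
    h <- x$hypotheses[[g]]
    cat(sprintf("  %-14s %3d metabolites (%d reported) %3d reactions\n", g,
                nrow(h$nodes), sum(h$nodes$reported), nrow(h$edges)))
  }
  invisible(x)
}

#' @export
summary.pathway_hypotheses <- function(object, ...) {
  hyps <- object$hypotheses
  all_nodes <- unique(unlist(lapply(hyps, function(h) h$nodes$key)))
  rep_nodes <- unique(unlist(lapply(hyps, function(h)
    h$nodes$key[h$nodes$reported])))
  all_edges <- unique(unlist(lapply(hyps, function(h) h$edges$id)))
  out <- list(n_genera = length(hyps),
              n_scaffolds = length(all_nodes),
              n_reported = length(rep_nodes),
              n_predicted = length(setdiff(all_nodes, rep_nodes)),
              n_reactions = length(all_edges))
  class(out) <- "summary.pathway_hypotheses"
  out
}

#' @export
print.summary.pathway_hypotheses <- function(x, ...) {
  cat("pathway hypotheses over", x$n_genera, "genera\n")
  cat("  unique scaffolds:", x$n_scaffolds, "(", x$n_reported, "reported +",
      x$n_predicted, "predicted )\n")
  cat("  putative reactions:", x$n_reactions, "\n")
  invisible(x)
}

#' @export
plot.pathway_hypotheses <- function(x, genus = NULL, ...) {
  g <- genus %||% names(x$hypotheses)[1]
  h <- x$hypotheses[[g]]
  gr <- .hyp_graph(h)
  igraph::plot.igraph(gr, vertex.size = 6,
                      vertex.color = ifelse(igraph::V(gr)$reported,
                                            "tomato", "lightblue"),
                      vertex.label = NA, main = paste("pathway hypothesis:", g),
                      ...)
  invisible(x)
}

# edge-level item scores: edge present in a genus when both endpoints are
.edge_item_scores <- function(reports, naive, tree, scheme, basis) {
  m <- presence_matrix(reports, basis)
  edge_ids <- sort(unique(unlist(lapply(naive, .edge_ids_of))))
  if (!length(edge_ids)) return(NULL)
  ep <- strsplit(edge_ids, "|", fixed = TRUE)
  gmat <- matrix(0L, nrow(m), length(edge_ids),
                 dimnames = list(rownames(m), edge_ids))
  for (i in seq_along(ep)) {
    a <- ep[[i]][1]; b <- ep[[i]][2]
    if (a %in% colnames(m) && b %in% colnames(m))
      gmat[, i] <- as.integer(m[, a] > 0 & m[, b] > 0)
  }
  score_items(gmat, tree, scheme = scheme, basis = "reported")
}
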