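#' Sixteen network topology descriptors of a pathway graph
#'
#' Computes a fixed, documented vector of 16 classical topology descriptors
#' used to summarise a per-genus pathway graph: node count, edge count,
#' density, mean degree, degree variance, number of components, largest
#' component size, diameter and radius of the largest component, mean local
#' clustering coefficient, number of articulation points, number of leaves,
#' mean shortest path within the largest component, degree assortativity,
#' cycle rank and degree-distribution entropy.  Degenerate graphs get
#' defined sentinel values: the empty graph maps to the all-zero vector, and
#' any descriptor that is undefined on a given graph (e.g. assortativity of
#' a regular graph) is set to 0.
#'
#' @param g an \code{igraph} graph (undirected), possibly empty.
#' @return a named numeric vector of length 16.
#' @export
network_descriptors <- function(g) {
  nm <- c("n_nodes", "n_edges", "density", "mean_degree", "degree_var",
          "n_components", "largest_comp", "diameter", "radius",
          "clustering", "articulation", "leaves", "mean_path",
          "assortativity", "cycle_rank", "degree_entropy")
  out <- stats::setNames(numeric(16), nm)
  n <- igraph::vcount(g)
  if (n == 0) return(out)
  deg <- igraph::degree(g)
  comps <- igraph::components(g)
  big <- igraph::induced_subgraph(g, which(comps$membership ==
                                             which.max(comps$csize)))
  z <- function(x) if (is.na(x) || is.nan(x) || !is.finite(x)) 0 else x
  out["n_nodes"] <- n
  out["n_edges"] <- igraph::ecount(g)
  out["density"] <- if (n > 1) z(igraph::edge_density(g)) else 0
  out["mean_degree"] <- mean(deg)
  out["degree_var"] <- z(stats::var(deg))
  out["n_components"] <- comps$no
  out["largest_comp"] <- max(comps$csize)
  out["diameter"] <- if (igraph::vcount(big) > 1)
    igraph::diameter(big, unconnected = FALSE) else 0
  out["radius"] <- if (igraph::vcount(big) > 1) z(igraph::radius(big)) else 0
  out["clustering"] <- z(igraph::transitivity(g, type = "localaverage",
                                              isolates = "zero"))
  out["articulation"] <- length(igraph::articulation_points(g))
  out["leaves"] <- sum(deg == 1)
  out["mean_path"] <- if (igraph::vcount(big) > 1)
    z(igraph::mean_distance(big)) else 0
  out["assortativity"] <- z(igraph::assortativity_degree(g))
  out["cycle_rank"] <- igraph::ecount(g) - n + comps$no
  p <- tabulate(deg + 1L)
  p <- p[p > 0] / n
  out["degree_entropy"] <- z(-sum(p * log2(p)))
  out
}

#' Build the descriptor feature table for surrogate selection
#'
#' Concatenates the 16 per-genus descriptors of every pathway set in a fixed
#' genus order (16 x genera columns; 336 for 21 genera), drops duplicated
#' rows, applies \code{log10(x + 1)} elementwise (descriptors are counts or
#' bounded indices, and several are legitimately zero) and z-scales every
#' column; zero-variance columns are set to 0.
#'
#' @param sets a list of pathway sets; each set is a named list of
#'   \code{igraph} graphs, one per genus.
#' @param genera character vector fixing the genus order; every set must
#'   supply every genus.
#' @return a list of class \code{descriptor_table}: \code{features} (the
#'   scaled matrix, rows = kept sets), \code{kept} (indices of rows that
#'   survived deduplication), \code{center}, \code{scale} (per-column
#'   transform parameters on the log scale), and \code{raw} (pre-transform
#'   deduplicated matrix).
#' @export
build_feature_table <- function(sets, genera) {
  rows <- lapply(sets, function(s) {
    miss <- setdiff(genera, names(s))
    if (length(miss)) stop("set lacks genus graphs: ", paste(miss, collapse = ", "))
    unlist(lapply(genera, function(g) network_descriptors(s[[g]])))
  })
  m <- do.call(rbind, rows)
  colnames(m) <- as.vector(vapply(genera, function(g)
    paste(g, names(network_descriptors(igraph::make_empty_graph(directed = FALSE))),
          sep = "."), character(16)))
  # negative-capable columns (assortativity) are shifted by nothing: log10(x+1)
  # is applied to the magnitude-preserving signed transform
  keep <- !duplicated(m)
  m <- m[keep, , drop = FALSE]
  lg <- sign(m) * log10(abs(m) + 1)
  mu <- colMeans(lg)
  sd <- apply(lg, 2, stats::sd)
  flat <- sd == 0 | is.na(sd)
  sd[flat] <- 1
  sc <- sweep(sweep(lg, 2, mu), 2, sd, "/")
  sc[, flat] <- 0
  structure(list(features = sc, kept = which(keep), center = mu, scale = sd,
                 flat = flat, raw = m, genera = genera),
            class = "descriptor_table")
}

#' @export
print.descriptor_table <- function(x, ...) {
  cat("<descriptor_table>", nrow(x$features), "sets x", ncol(x$features),
      "columns (", length(x$genera), "genera x 16 descriptors )\n")
  invisible(x)
}

# apply a fitted table's transform to a new raw descriptor row
.apply_table_transform <- function(table, row) {
  lg <- sign(row) * log10(abs(row) + 1)
  out <- (lg - table$center) / table$scale
  out[table$flat] <- 0
  out
}

#' Embed surrogates with UMAP and select the sets nearest the natural data
#'
#' Fits a 2-D UMAP on the surrogate descriptor rows, projects the natural
#' (in natura) descriptor row \code{n_projections} times with the stochastic
#' transform, forms the mean and covariance of the projection cloud, and
#' keeps the surrogate rows whose squared Mahalanobis distance to the cloud
#' falls below the \code{chi2_quantile} quantile of the chi-squared
#' distribution with 2 degrees of freedom.
#'
#' @param table a \code{descriptor_table} built from the surrogate sets.
#' @param natural_row a raw (untransformed) 16 x genera descriptor vector
#'   for the natural naive model, e.g. from
#'   \code{unlist(lapply(genera, function(g) network_descriptors(gr[[g]])))}.
#' @param n_projections number of stochastic projections (default 10000).
#' @param chi2_quantile the chi-squared gate (default 0.99).
#' @param seed integer seed.
#' @param n_neighbors,min_dist UMAP hyperparameters.
#' @return a list of class \code{surrogate_selection}: \code{selected}
#'   (indices into the table rows), \code{embedding}, \code{cloud} (the
#'   natural projections), \code{d2} (squared Mahalanobis distances),
#'   \code{cutoff}.
#' @export
embed_and_select <- function(table, natural_row, n_projections = 10000,
                             chi2_quantile = 0.99, seed = 1,
                             n_neighbors = 15, min_dist = 0.1) {
  stopifnot(inherits(table, "descriptor_table"))
  X <- table$features
  if (length(natural_row) != ncol(X))
    stop("natural row has ", length(natural_row), " columns, table has ", ncol(X))
  nat <- .apply_table_transform(table, natural_row)
  nn <- min(n_neighbors, nrow(X) - 1)
  set.seed(seed)
  fit <- uwot::umap(X, n_neighbors = nn, min_dist = min_dist,
                    n_components = 2, ret_model = TRUE,
                    n_sgd_threads = 1, n_threads = 1)
  cloud <- matrix(NA_real_, n_projections, 2)
  # stochastic transform: each projection re-runs the SGD refinement from a
  # fresh seed, mirroring the stochastic placement of a single new point
  batch <- max(1L, min(n_projections, 500L))
  done <- 0L
  while (done < n_projections) {
    k <- min(batch, n_projections - done)
    pts <- uwot::umap_transform(
      matrix(nat, k, length(nat), byrow = TRUE), fit,
      n_epochs = 50, n_sgd_threads = 1, n_threads = 1)
    cloud[done + seq_len(k), ] <- pts
    done <- done + k
  }
  mu <- colMeans(cloud)
  S <- stats::cov(cloud)
  if (!all(is.finite(S)) || det(S) < 1e-12)
    S <- S + diag(1e-6, 2)                 # ridge for a degenerate cloud
  d2 <- stats::mahalanobis(fit$embedding, mu, S)
  cutoff <- stats::qchisq(chi2_quantile, df = 2)
  structure(list(selected = which(d2 < cutoff), embedding = fit$embedding,
                 cloud = cloud, d2 = d2, cutoff = cutoff,
                 chi2_quantile = chi2_quantile, seed = seed),
            class = "surrogate_selection")
}

#' @export
print.surrogate_selection <- function(x, ...) {
  cat("<surrogate_selection>", length(x$selected), "of", length(x$d2),
      "sets within the chi-squared", x$chi2_quantile, "gate\n")
  invisible(x)
}

#' Generate candidate surrogate pathway sets
#'
#' Runs the pathway-evolution simulator \code{n_evolutions} times (fresh
#' ancestral pathway per replicate), samples each simulation's metabolites
#' at every fraction, and applies the plain (0-extension) naive model to the
#' sampled reports, yielding one candidate surrogate per (evolution,
#' fraction) pair.
#'
#' @param space a \code{chem_space}.
#' @param tree the genus phylogeny shared by all simulations.
#' @param n_evolutions simulation replicates.
#' @param fractions sampling fractions (default the 10-60% ladder).
#' @param config base \code{evolution_config}; the seed is varied per
#'   replicate.
#' @param configs optional list of \code{evolution_config}s; replicates
#'   cycle through them, so the candidate pool spans evolution-parameter
#'   combinations.
#' @param seed master seed.
#' @return a list of candidates: each has \code{sim}, \code{fraction},
#'   \code{reports} and \code{graphs} (per-genus naive model graphs).
#' @export
build_surrogates <- function(space, tree, n_evolutions = 10,
                             fractions = seq(0.1, 0.6, by = 0.1),
                             config = evolution_config(), configs = NULL,
                             seed = 1) {
  out <- list()
  for (i in seq_len(n_evolutions)) {
    cfg <- if (is.null(configs)) config
           else configs[[(i - 1L) %% length(configs) + 1L]]
    cfg$seed <- seed * 1000L + i
    sim <- evolve_pathways(space, tree, cfg)
    for (f in fractions) {
      reports <- sample_metabolites(sim, f,
                                    seed = seed * 100000L + i * 100L +
                                      round(f * 10))
      graphs <- naive_predict(reports, space, 0)
      out[[length(out) + 1]] <- list(sim = sim, fraction = f,
                                     reports = reports, graphs = graphs)
    }
  }
  out
}

#' Select the surrogates nearest a natural naive model
#'
#' Builds the descriptor table over the candidates' naive-model graphs,
#' embeds with UMAP, projects the natural naive model repeatedly and gates
#' by Mahalanobis distance; convenience wrapper around
#' \code{\link{build_feature_table}} and \code{\link{embed_and_select}}.
#'
#' @param candidates output of \code{\link{build_surrogates}}.
#' @param natural_graphs named list of per-genus graphs for the natural
#'   naive model.
#' @param genera fixed genus order.
#' @param min_keep optional lower bound on the number of selected sets:
#'   when fewer candidates pass the chi-squared gate, the shortfall is
#'   filled with the next-nearest sets by Mahalanobis distance and the
#'   result is flagged \code{gate_relaxed}.
#' @param ... passed to \code{\link{embed_and_select}}.
#' @return list with \code{selected} (the retained candidates),
#'   \code{selection}, \code{table} and \code{gate_relaxed}.
#' @export
select_surrogates <- function(candidates, natural_graphs, genera,
                              min_keep = NULL, ...) {
  sets <- lapply(candidates, `[[`, "graphs")
  tab <- build_feature_table(sets, genera)
  nat_row <- unlist(lapply(genera, function(g)
    network_descriptors(natural_graphs[[g]])))
  sel <- embed_and_select(tab, nat_row, ...)
  idx <- sel$selected
  relaxed <- FALSE
  if (!is.null(min_keep) && length(idx) < min_keep) {
    idx <- order(sel$d2)[seq_len(min(min_keep, length(sel$d2)))]
    relaxed <- TRUE
  }
  picked <- tab$kept[idx]
  list(selected = candidates[picked], selection = sel, table = tab,
       picked = picked, gate_relaxed = relaxed)
}
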