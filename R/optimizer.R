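#' The reconstruction parameter grid
#'
#' Full factorial grid over the five reconstruction parameters: extension by
#' 0, 1 or 2 reactions; tolerance 0-100% in steps of 10; correlation or
#' Felsenstein weighting; weights applied on vertices, edges or both; scores
#' computed on reported or predicted items.  3 x 11 x 2 x 3 x 2 = 396 rows.
#'
#' @return a data.frame with columns \code{n_reactions}, \code{basis},
#'   \code{scheme}, \code{apply_on}, \code{tolerance}, in a fixed order.
#' @export
parameter_grid <- function() {
  g <- expand.grid(
    tolerance = seq(0, 100, by = 10),
    n_reactions = 0:2,
    scheme = c("correlation", "felsenstein"),
    apply_on = c("vertices", "edges", "both"),
    basis = c("reported", "predicted"),
    stringsAsFactors = FALSE)
  g <- g[, c("n_reactions", "basis", "scheme", "apply_on", "tolerance")]
  g[order(g$n_reactions, g$basis, g$scheme, g$apply_on, g$tolerance), ,
    drop = FALSE] -> g
  rownames(g) <- NULL
  g
}

#' Confusion metrics between a predicted and a true pathway graph
#'
#' Compares predictions and truth on two scopes: metabolites (nodes) and
#' enzymes (reactions, i.e. edges).  True negatives are counted over a
#' configurable universe; the default is the union of the naive prediction,
#' the truth and the prediction, because against the full enumerated space
#' the false-positive rate is vacuously near zero.
#'
#' @param predicted,truth lists with elements \code{nodes} (character keys)
#'   and \code{edges} (character edge ids); a \code{pathway_hypothesis} is
#'   accepted for either.
#' @param universe a list with \code{nodes} and \code{edges} defining the
#'   negative universe; it is unioned with predictions and truth.
#' @return a data.frame with one row per scope (metabolites, enzymes) and
#'   columns TP, FP, FN, TN, TPR, FPR, FOR, PPV, MCC and
#'   \code{mcc_undefined} (TRUE when an MCC denominator vanished and 0 was
#'   substituted).
#' @export
confusion_metrics <- function(predicted, truth, universe = NULL) {
  p <- .as_item_sets(predicted)
  t <- .as_item_sets(truth)
  if (!length(t$nodes)) stop("empty truth pathway")
  u <- .as_item_sets(universe)
  one <- function(pred, tru, univ) {
    univ <- unique(c(univ, pred, tru))
    TP <- length(intersect(pred, tru))
    FP <- length(setdiff(pred, tru))
    FN <- length(setdiff(tru, pred))
    TN <- length(univ) - TP - FP - FN
    .metric_row(TP, FP, FN, TN)
  }
  out <- rbind(one(p$nodes, t$nodes, u$nodes), one(p$edges, t$edges, u$edges))
  out$scope <- c("metabolites", "enzymes")
  out[, c("scope", setdiff(names(out), "scope"))]
}

.metric_row <- function(TP, FP, FN, TN) {
  TP <- as.numeric(TP); FP <- as.numeric(FP)
  FN <- as.numeric(FN); TN <- as.numeric(TN)
  safe <- function(num, den) if (den > 0) num / den else 0
  num <- TP * TN - FP * FN
  den2 <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  undef <- den2 <= 0
  data.frame(TP = TP, FP = FP, FN = FN, TN = TN,
             TPR = safe(TP, TP + FN), FPR = safe(FP, FP + TN),
             FOR = safe(FN, FN + TN), PPV = safe(TP, TP + FP),
             MCC = if (undef) 0 else num / sqrt(den2),
             mcc_undefined = undef)
}

.as_item_sets <- function(x) {
  if (is.null(x)) return(list(nodes = character(0), edges = character(0)))
  if (inherits(x, "pathway_hypothesis")) {
    return(list(nodes = x$nodes$key, edges = x$edges$id))
  }
  if (inherits(x, "igraph")) {
    return(list(nodes = igraph::V(x)$name, edges = .edge_ids_of(x)))
  }
  stopifnot(is.list(x))
  list(nodes = unique(as.character(x$nodes %||% character(0))),
       edges = unique(as.character(x$edges %||% character(0))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# canonical undirected edge id: sorted endpoint keys joined by "|"
.edge_id <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

.edge_ids_of <- function(g) {
  el <- igraph::as_edgelist(g, names = TRUE)
  if (!nrow(el)) return(character(0))
  .edge_id(el[, 1], el[, 2])
}

#' Benchmark the parameter grid on simulated surrogate pathway sets
#'
#' For every parameter combination and every surrogate set, regenerates
#' sampled reports at the surrogate's sampling fraction \code{resamples}
#' times, reconstructs pathway hypotheses, scores them against the
#' simulation's ground truth on both scopes, and aggregates medians and
#' quartiles per combination.  The best combination per extension level is
#' the one maximising median metabolite MCC.
#'
#' @param surrogates a list of surrogate sets, each a list with elements
#'   \code{sim} (a \code{pathway_simulation}) and \code{fraction} (the
#'   sampling fraction assigned to the set).
#' @param space the \code{chem_space} the simulations live in.
#' @param tree the phylogeny used for weighting.
#' @param grid a parameter grid (default \code{parameter_grid()}); subset it
#'   for scaled-down runs.
#' @param resamples report resamples per combination and surrogate.
#' @param seed integer seed; the run is fully reproducible.
#' @return a list of class \code{benchmark_result}: \code{metrics} (long
#'   data.frame of per-evaluation metrics), \code{summary} (per-combination
#'   medians and quartiles) and \code{best} (best row per extension level).
#' @export
run_benchmark <- function(surrogates, space, tree, grid = parameter_grid(),
                          resamples = 10, seed = 1) {
  stopifnot(length(surrogates) > 0)
  rows <- list()
  for (si in seq_along(surrogates)) {
    sur <- surrogates[[si]]
    sim <- sur$sim; fraction <- sur$fraction
    # the truth network is the adjacency structure of the true metabolite
    # set: the reconstruction predicts unit-distance reactions, and which
    # of two adjacent producible metabolites' reactions was the fixed
    # enzyme is not recoverable from presence data
    truths <- lapply(sim$tip_pathways, function(p) {
      ids <- .space_vid(space, p$metabolites)
      sub <- igraph::induced_subgraph(space$graph, ids)
      list(nodes = p$metabolites, edges = .edge_ids_of(sub))
    })
    for (ri in seq_len(resamples)) {
      set.seed((seed * 7919L + si * 101L + ri) %% .Machine$integer.max)
      reports <- sample_metabolites(sim, fraction,
                                    seed = sample.int(1e8, 1))
      # reconstruct once per (n_reactions, basis, scheme, apply_on) and prune
      # at every tolerance: pruning is monotone so share the naive graphs
      for (n_ext in unique(grid$n_reactions)) {
        naive <- naive_predict(reports, space, n_ext)
        # TN universe: the family-wide naive graph plus every genus's true
        # pathway (shared across genera)
        univ <- list(nodes = unique(c(igraph::V(naive[[1]])$name,
                                      unlist(lapply(truths, `[[`, "nodes"),
                                             use.names = FALSE))),
                     edges = unique(c(.edge_ids_of(naive[[1]]),
                                      unlist(lapply(truths, `[[`, "edges"),
                                             use.names = FALSE))))
        genus_rep <- lapply(naive, .genus_reported)
        # route candidates connect the family-wide reported set, so the
        # enumeration is shared by every genus and weighting scheme
        conns_shared <- suppressWarnings(.component_connectors(naive[[1]]))
        sub1 <- grid[grid$n_reactions == n_ext, , drop = FALSE]
        for (bs in unique(sub1$basis)) for (sc in unique(sub1$scheme)) {
          scores <- score_items(reports, tree, scheme = sc, basis = bs)
          sub2 <- sub1[sub1$basis == bs & sub1$scheme == sc, , drop = FALSE]
          esc <- if (any(sub2$apply_on != "vertices"))
            .edge_item_scores(reports, naive, tree, sc, bs) else NULL
          for (ap in unique(sub2$apply_on)) {
            tols <- sub2$tolerance[sub2$apply_on == ap]
            for (genus in names(naive)) {
              tru <- truths[[genus]]
              if (!length(tru$nodes)) next
              scored <- .score_connectors(
                conns_shared, scores, ap, genus,
                edge_scores = if (ap == "vertices") NULL else esc)
              for (tol in tols) {
                params <- reconstruction_params(n_ext, bs, sc, ap, tol)
                hyp <- .apply_tolerance(scored, params, genus,
                                        always_keep = genus_rep[[genus]])
                cm <- confusion_metrics(hyp, tru, universe = univ)
                cm$genus <- genus; cm$surrogate <- si; cm$resample <- ri
                cm$n_reactions <- n_ext; cm$basis <- bs; cm$scheme <- sc
                cm$apply_on <- ap; cm$tolerance <- tol
                rows[[length(rows) + 1L]] <- cm
              }
            }
          }
        }
      }
    }
  }
  metrics <- do.call(rbind, rows)
  key <- c("n_reactions", "basis", "scheme", "apply_on", "tolerance")
  agg <- function(v, f) stats::aggregate(
    metrics[metrics$scope == v, c("TPR", "FPR", "FOR", "PPV", "MCC")],
    metrics[metrics$scope == v, key], f)
  summ <- NULL
  for (scope in c("metabolites", "enzymes")) {
    med <- stats::aggregate(
      metrics[metrics$scope == scope, c("TPR", "FPR", "FOR", "PPV", "MCC")],
      metrics[metrics$scope == scope, key],
      function(x) c(median = stats::median(x),
                    q25 = unname(stats::quantile(x, 0.25)),
                    q75 = unname(stats::quantile(x, 0.75))))
    med$scope <- scope
    summ <- rbind(summ, med)
  }
  best <- do.call(rbind, lapply(unique(grid$n_reactions), function(n_ext) {
    s <- summ[summ$scope == "metabolites" & summ$n_reactions == n_ext, ]
    s[which.max(s$MCC[, "median"]), ]
  }))
  structure(list(metrics = metrics, summary = summ, best = best, seed = seed),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("<benchmark_result>", nrow(x$metrics), "evaluations\n")
  cat("best per extension level (median metabolite MCC):\n")
  b <- x$best
  for (i in seq_len(nrow(b)))
    cat(sprintf("  %d reactions | %s | %s | %s | tol %d%% : MCC %.3f\n",
                b$n_reactions[i], b$basis[i], b$scheme[i], b$apply_on[i],
                b$tolerance[i], b$MCC[i, "median"]))
  invisible(x)
}
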