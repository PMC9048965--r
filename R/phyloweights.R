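#' Phylogenetic tip correlation under Brownian motion
#'
#' Converts the Brownian-motion variance-covariance structure of a rooted,
#' branch-length-bearing tree into a tip-tip correlation matrix:
#' \code{corr(i, j)} is the shared root-to-MRCA path length divided by the
#' geometric mean of the two tip depths.  On an ultrametric tree this is the
#' usual phylogenetic correlation; on a non-ultrametric tree the diagonal is
#' still exactly 1.
#'
#' @param tree an \code{ape::phylo} object, rooted, with branch lengths.
#' @return a symmetric genus-by-genus correlation matrix with unit diagonal,
#'   rows and columns named by tip labels.
#' @export
phylo_correlation <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  V <- ape::vcv(tree)
  d <- diag(V)
  if (any(d <= 0)) stop("zero-depth tip: every tip needs positive root-to-tip path length")
  stats::cov2cor(V)
}

#' Felsenstein root weight for a presence/absence character
#'
#' Computes the posterior weight of the "present" state at the root of a tree
#' under a symmetric two-state continuous-time Markov model, by Felsenstein's
#' pruning recursion, with a flat prior at the root.  Tips that are not
#' scored as present are treated as missing data (conditional likelihood 1
#' for both states), so absence of a report never counts as evidence of
#' absence.
#'
#' @param tree an \code{ape::phylo} object with branch lengths.
#' @param presence either a character vector of tip labels scored "present",
#'   or a named logical/0-1 vector over (a subset of) the tips; tips missing
#'   from the vector (or FALSE/0 entries) are treated as unobserved.
#' @param rate transition rate of the symmetric two-state model per unit
#'   branch length (default 1).
#' @return the root weight of the "present" state, a number in [0, 1]; 0.5
#'   when no tip is scored present (the flat prior is returned).
#' @export
felsenstein_root_weight <- function(tree, presence, rate = 1) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  tips <- tree$tip.label
  pres <- .as_presence(presence, tips)
  lik <- .prune_partials(tree, pres, rate)
  unname(lik[2] / sum(lik))
}

.as_presence <- function(presence, tips) {
  if (length(presence) == 0) stop("empty presence map")
  if (is.character(presence)) {
    bad <- setdiff(presence, tips)
    if (length(bad)) stop("presence labels not in tree: ", paste(bad, collapse = ", "))
    stats::setNames(tips %in% presence, tips)
  } else {
    if (is.null(names(presence))) stop("presence vector must be named by tip label")
    bad <- setdiff(names(presence), tips)
    if (length(bad)) stop("presence labels not in tree: ", paste(bad, collapse = ", "))
    out <- stats::setNames(rep(FALSE, length(tips)), tips)
    out[names(presence)] <- as.logical(presence)
    out
  }
}

# Pruning recursion: returns the root partial likelihoods (absent, present)
# weighted by the flat prior numerator (unnormalised).  Missing tips carry
# partial likelihood (1, 1).
.prune_partials <- function(tree, pres, rate) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  partial <- matrix(1, ntip + nnode, 2)
  partial[seq_len(ntip), 2][!pres] <- 1   # missing: stay (1, 1)
  partial[seq_len(ntip), 1][pres] <- 0    # present tips: (0, 1)
  # postorder over edges
  eo <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(eo$edge))) {
    parent <- eo$edge[k, 1]; child <- eo$edge[k, 2]
    t <- eo$edge.length[k]
    pstay <- (1 + exp(-2 * rate * t)) / 2
    pswap <- 1 - pstay
    down <- c(pstay * partial[child, 1] + pswap * partial[child, 2],
              pswap * partial[child, 1] + pstay * partial[child, 2])
    partial[parent, ] <- partial[parent, ] * down
  }
  root <- ntip + 1L
  partial[root, ]
}

#' Score metabolites or reactions with phylogenetic weights
#'
#' Turns a binary genus-by-item report matrix into per-item scores, using
#' either the Brownian-motion tip correlation (each item gets one score per
#' focal genus, the presence row multiplied into the correlation matrix) or
#' the Felsenstein root weight of the item's presence pattern (one score per
#' item, shared by all genera).
#'
#' @param reports a \code{report_matrix} (see \code{\link{report_matrix}}) or
#'   a plain binary genus-by-item matrix with genus rownames.
#' @param tree an \code{ape::phylo} covering all report genera.
#' @param scheme "correlation" or "felsenstein".
#' @param basis which presence flags enter the scores: "reported" uses only
#'   literature-reported items, "predicted" uses reported plus predicted.
#' @param rate transition rate for the Felsenstein scheme.
#' @return an object of class \code{item_scores}: a list with \code{scores}
#'   (genus-by-item matrix for the correlation scheme; one-row matrix for the
#'   Felsenstein scheme), \code{aggregate} (per-item column sums or root
#'   weights) and the scheme/basis metadata.
#' @export
score_items <- function(reports, tree, scheme = c("correlation", "felsenstein"),
                        basis = c("reported", "predicted"), rate = 1) {
  scheme <- match.arg(scheme)
  basis <- match.arg(basis)
  m <- presence_matrix(reports, basis = basis)
  tips <- tree$tip.label
  if (!all(rownames(m) %in% tips))
    stop("report genera missing from tree: ",
         paste(setdiff(rownames(m), tips), collapse = ", "))
  if (scheme == "correlation") {
    corr <- phylo_correlation(tree)[rownames(m), rownames(m), drop = FALSE]
    scores <- corr %*% m           # genus x item: row g = sum_h corr(g,h) presence(h,)
    aggregate <- colSums(scores)
  } else {
    w <- vapply(colnames(m), function(j) {
      if (!any(m[, j] > 0)) return(0.5)
      felsenstein_root_weight(tree, rownames(m)[m[, j] > 0], rate = rate)
    }, numeric(1))
    scores <- matrix(w, 1, ncol(m), dimnames = list("root", colnames(m)))
    aggregate <- stats::setNames(as.numeric(w), colnames(m))
  }
  structure(list(scores = scores, aggregate = aggregate,
                 scheme = scheme, basis = basis, genera = rownames(m)),
            class = "item_scores")
}

#' @export
print.item_scores <- function(x, ...) {
  cat("<item_scores> scheme:", x$scheme, " basis:", x$basis,
      " items:", length(x$aggregate), "\n")
  invisible(x)
}

# Per-genus score lookup used by the pruning step: returns a named numeric
# vector of item scores for one focal genus.
.genus_scores <- function(scores, genus) {
  if (scores$scheme == "correlation") {
    if (!genus %in% rownames(scores$scores))
      stop("no scores for genus ", genus)
    scores$scores[genus, ]
  } else {
    scores$scores[1, ]
  }
}
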