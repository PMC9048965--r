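#' Log-transform and z-score an expression matrix
#'
#' Applies \code{log2(x + 1)} cell-wise, then centres and scales each
#' transcript (row) to mean 0 and standard deviation 1.  Constant rows
#' cannot be scaled and are set to all zero; their ids are recorded in the
#' \code{"flat_transcripts"} attribute.
#'
#' @param expr nonnegative numeric matrix, transcripts x tissues, with
#'   transcript rownames and at least two tissue columns.
#' @return the transformed matrix, same dimensions, with attribute
#'   \code{flat_transcripts}.
#' @export
zscore_expression <- function(expr) {
  stopifnot(is.matrix(expr), ncol(expr) >= 2)
  if (any(is.na(expr))) stop("expression matrix has missing cells")
  if (any(expr < 0)) stop("expression values must be nonnegative")
  lg <- log2(expr + 1)
  mu <- rowMeans(lg)
  sd <- apply(lg, 1, stats::sd)
  flat <- sd == 0
  sd[flat] <- 1
  out <- (lg - mu) / sd
  out[flat, ] <- 0
  attr(out, "flat_transcripts") <- rownames(expr)[flat]
  out
}

# -- toroidal hexagonal self-organizing map ----------------------------------
# Hex layout: odd rows offset by half a unit; the torus wraps both axes.
.som_grid_coords <- function(xdim, ydim) {
  gx <- rep(seq_len(xdim) - 1, ydim)
  gy <- rep(seq_len(ydim) - 1, each = xdim)
  cbind(x = gx + (gy %% 2) / 2, y = gy * sqrt(3) / 2, col = gx, row = gy)
}

# pairwise toroidal distance between neurons (minimum over the 9 wrapped
# copies of the plane)
.som_grid_dist <- function(coords, xdim, ydim) {
  wx <- xdim; wy <- ydim * sqrt(3) / 2
  n <- nrow(coords)
  best <- matrix(Inf, n, n)
  for (sx in -1:1) for (sy in -1:1) {
    dx <- outer(coords[, 1], coords[, 1] + sx * wx + (if (sy %% 2 != 0) 0.5 else 0), "-")
    dy <- outer(coords[, 2], coords[, 2] + sy * wy, "-")
    best <- pmin(best, sqrt(dx^2 + dy^2))
  }
  best
}

#' Train a self-organizing map on expression profiles
#'
#' Batch-trains a SOM on a toroidal hexagonal grid (default 20 x 20 = 400
#' neurons), assigns every transcript to its best-matching neuron, clusters
#' the codebook vectors by Ward's criterion on Manhattan distances, and
#' propagates the neuron clusters to the transcripts.
#'
#' @param z z-scored expression matrix (rows = transcripts).
#' @param xdim,ydim grid dimensions.
#' @param n_clusters number of codebook clusters (default 10).
#' @param rlen training iterations of the batch algorithm.
#' @param seed integer seed (codebook initialisation is random).
#' @return an object of class \code{som_clusters}: \code{cluster} (named
#'   integer vector per transcript), \code{neuron} (winning neuron per
#'   transcript), \code{codebook} (neurons x tissues), \code{neuron_cluster},
#'   and the grid metadata.
#' @export
som_cluster <- function(z, xdim = 20, ydim = 20, n_clusters = 10,
                        rlen = 30, seed = 1) {
  stopifnot(is.matrix(z), nrow(z) >= 1)
  n_neurons <- xdim * ydim
  if (nrow(z) < n_neurons)
    warning("fewer transcripts (", nrow(z), ") than neurons (", n_neurons, ")")
  set.seed(seed)
  init_idx <- sample.int(nrow(z), n_neurons, replace = nrow(z) < n_neurons)
  codebook <- z[init_idx, , drop = FALSE] +
    matrix(stats::rnorm(n_neurons * ncol(z), sd = 0.05), n_neurons)
  coords <- .som_grid_coords(xdim, ydim)
  gd <- .som_grid_dist(coords, xdim, ydim)
  r0 <- max(gd) / 2
  for (it in seq_len(rlen)) {
    bmu <- .som_bmu(z, codebook)
    radius <- r0 * (1 - (it - 1) / rlen) + 0.5
    h <- exp(-(gd / radius)^2)           # neighbourhood kernel
    w <- h[, bmu, drop = FALSE]          # neurons x samples
    denom <- rowSums(w)
    upd <- (w %*% z) / denom
    ok <- denom > 1e-12
    codebook[ok, ] <- upd[ok, ]
  }
  bmu <- .som_bmu(z, codebook)
  hc <- stats::hclust(stats::dist(codebook, method = "manhattan"),
                      method = "ward.D2")
  neuron_cluster <- stats::cutree(hc, k = n_clusters)
  cluster <- stats::setNames(neuron_cluster[bmu], rownames(z))
  structure(list(cluster = cluster, neuron = stats::setNames(bmu, rownames(z)),
                 codebook = codebook, neuron_cluster = neuron_cluster,
                 xdim = xdim, ydim = ydim, n_clusters = n_clusters,
                 seed = seed),
            class = "som_clusters")
}

.som_bmu <- function(z, codebook) {
  # squared Euclidean BMU lookup, vectorised: argmin_j |x_i - c_j|^2
  cross <- z %*% t(codebook)
  cb2 <- rowSums(codebook^2)
  max.col(cross - matrix(cb2 / 2, nrow(z), nrow(codebook), byrow = TRUE),
          ties.method = "first")
}

#' @export
print.som_clusters <- function(x, ...) {
  cat("<som_clusters>", length(x$cluster), "transcripts on a", x$xdim, "x",
      x$ydim, "toroidal hex grid,", x$n_clusters, "clusters\n")
  invisible(x)
}

#' Hypergeometric bait enrichment and candidate ranking
#'
#' Tests every cluster for enrichment of bait transcripts with the exact
#' hypergeometric upper tail (probability of at least the observed bait
#' count).  Candidates are all members of clusters with p below
#' \code{alpha}.
#'
#' @param clusters a \code{som_clusters} object or a named integer vector of
#'   cluster memberships.
#' @param baits character vector of bait transcript ids (must be a subset of
#'   the clustered transcripts).
#' @param alpha enrichment threshold (default 0.05).
#' @return an object of class \code{candidate_ranking}: \code{table}
#'   (per-cluster size, bait count, p-value, ordered by p), \code{candidates}
#'   (transcripts of enriched clusters, baits excluded),
#'   \code{enriched_clusters} and \code{alpha}.
#' @export
enrich_and_rank <- function(clusters, baits, alpha = 0.05) {
  cl <- if (inherits(clusters, "som_clusters")) clusters$cluster else clusters
  if (is.null(names(cl))) stop("cluster vector must be named by transcript")
  if (!length(baits)) stop("zero baits supplied")
  missing <- setdiff(baits, names(cl))
  if (length(missing))
    stop("baits not among clustered transcripts: ",
         paste(utils::head(missing, 5), collapse = ", "))
  N <- length(cl); K <- length(unique(baits))
  ids <- sort(unique(cl))
  tab <- do.call(rbind, lapply(ids, function(k) {
    members <- names(cl)[cl == k]
    n <- length(members)
    x <- length(intersect(unique(baits), members))
    p <- stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(cluster = k, size = n, baits = x, p_value = p)
  }))
  tab <- tab[order(tab$p_value, -tab$baits), ]
  enriched <- tab$cluster[tab$p_value < alpha]
  cand <- setdiff(names(cl)[cl %in% enriched], baits)
  structure(list(table = tab, candidates = cand,
                 enriched_clusters = enriched, alpha = alpha),
            class = "candidate_ranking")
}

#' @export
print.candidate_ranking <- function(x, ...) {
  cat("<candidate_ranking>", length(x$candidates), "candidates from",
      length(x$enriched_clusters), "enriched cluster(s) at alpha =",
      x$alpha, "\n")
  print(utils::head(x$table, 5), row.names = FALSE)
  invisible(x)
}

#' Read an expression TSV (transcript id column + one column per tissue)
#'
#' @param path file path; first column must be the transcript id.
#' @return numeric matrix with transcript rownames.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
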