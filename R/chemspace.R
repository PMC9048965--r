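# The chemical space: every valid scaffold code, connected by unit-distance
# reaction moves.  Enumeration is vectorised: states are generated per
# unsaturation pattern (a matching of the skeleton bonds with a bond type),
# and edges per move family, using exact integer packing for node lookup.

.pack_states <- function(R, B, nst) {
  # exact numeric packing: reals in mixed radix, bond states base 3 on top
  n <- nrow(R)
  key <- numeric(n)
  mult <- 1
  for (j in seq_len(ncol(R))) {
    key <- key + R[, j] * mult
    mult <- mult * nst[j]
  }
  for (b in seq_len(ncol(B))) {
    key <- key + B[, b] * mult
    mult <- mult * 3
  }
  key
}

.enum_matchings <- function(bonds, nb) {
  res <- list()
  rec <- function(i, used, cur) {
    if (i > nb) { res[[length(res) + 1]] <<- cur; return(invisible(NULL)) }
    rec(i + 1, used, cur)
    a <- bonds[i, 1]; b <- bonds[i, 2]
    if (!used[a] && !used[b]) {
      u <- used; u[a] <- u[b] <- TRUE
      rec(i + 1, u, c(cur, i))
    }
  }
  rec(1, rep(FALSE, 10), integer(0))
  res
}

#' Enumerate the full scaffold chemical space
#'
#' Generates every scaffold code the grammar admits (the product of
#' per-carbon oxidation states filtered by the unsaturation pairing and
#' valence rules) and connects every pair at unit reaction distance, giving
#' the undirected reaction-adjacency graph of the iridoid scaffold space.
#'
#' @param grammar an \code{iridoid_grammar}.
#' @return an object of class \code{chem_space}: a list with \code{graph}
#'   (igraph, vertices named by canonical code keys), \code{keys},
#'   \code{reals} and \code{bstate} matrices, and the grammar.
#' @export
enumerate_space <- function(grammar = iridoid_grammar()) {
  nst <- as.integer(grammar$n_states)
  fs <- grammar$flag_states
  fst <- pmin(nst, fs)
  bonds <- grammar$bonds
  nb <- nrow(bonds)
  matchings <- .enum_matchings(bonds, nb)
  Rl <- list(); Bl <- list()
  for (m in matchings) {
    vm <- if (length(m)) unique(as.vector(bonds[m, , drop = FALSE])) else integer(0)
    counts <- ifelse(seq_len(10) %in% vm, fst, nst)
    if (any(counts < 1)) next
    types <- if (length(m)) {
      expand.grid(lapply(m, function(b) if (grammar$epoxide_ok[b]) c(1L, 2L) else 1L))
    } else data.frame(row.names = 1)
    reals <- as.matrix(expand.grid(lapply(counts, function(k) 0:(k - 1))))
    storage.mode(reals) <- "integer"
    for (ti in seq_len(nrow(types))) {
      bs <- integer(nb)
      if (length(m)) bs[m] <- as.integer(types[ti, ])
      Rl[[length(Rl) + 1]] <- reals
      Bl[[length(Bl) + 1]] <- matrix(bs, nrow(reals), nb, byrow = TRUE)
    }
  }
  R <- do.call(rbind, Rl)
  B <- do.call(rbind, Bl)
  if (is.null(R) || nrow(R) == 0) stop("grammar admits an empty space")
  packed <- .pack_states(R, B, nst)
  ord <- order(packed)
  R <- R[ord, , drop = FALSE]; B <- B[ord, , drop = FALSE]
  packed <- packed[ord]
  keys <- .keys_of(R, B, grammar)
  el <- .edge_families(R, B, packed, grammar)
  g <- igraph::graph_from_edgelist(cbind(el$from, el$to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(R) - igraph::vcount(g)))
  igraph::V(g)$name <- keys
  igraph::E(g)$kind <- el$kind
  structure(list(graph = g, keys = keys, reals = R, bstate = B,
                 packed = packed, grammar = grammar),
            class = "chem_space")
}

# per-carbon imaginary flags from the bond-state matrix
.im_of <- function(B, grammar) {
  n <- nrow(B)
  im <- matrix(0L, n, 10)
  for (b in seq_len(ncol(B))) {
    sel <- B[, b] > 0L
    if (!any(sel)) next
    val <- ifelse(B[sel, b] == 1L, 1L, 3L)
    im[sel, grammar$bonds[b, 1]] <- val
    im[sel, grammar$bonds[b, 2]] <- val
  }
  im
}

.keys_of <- function(R, B, grammar) {
  im <- .im_of(B, grammar)
  toks <- matrix("", nrow(R), 10)
  for (j in seq_len(10)) {
    t <- as.character(R[, j])
    has <- im[, j] != 0L
    t[has] <- paste0(t[has], "+", im[has, j], "/4i")
    toks[, j] <- t
  }
  do.call(paste, c(lapply(seq_len(10), function(j) toks[, j]), sep = ","))
}

# generate all unit-distance edges as integer id pairs
.edge_families <- function(R, B, packed, grammar) {
  nst <- as.integer(grammar$n_states)
  fs <- grammar$flag_states
  bonds <- grammar$bonds
  nb <- nrow(bonds)
  n <- nrow(R)
  im <- .im_of(B, grammar)
  flagged <- im != 0L
  mult_re <- cumprod(c(1, nst))[seq_len(10)]
  mult_b <- prod(nst) * cumprod(c(1, rep(3, nb)))[seq_len(nb)]
  from <- list(); to <- list(); kind <- list()
  push <- function(src_idx, tgt_packed, k) {
    tid <- match(tgt_packed, packed)
    if (anyNA(tid)) stop("edge target missing from the enumerated space")
    from[[length(from) + 1]] <<- src_idx
    to[[length(to) + 1]] <<- tid
    kind[[length(kind) + 1]] <<- rep(k, length(src_idx))
  }
  if ("oxidation" %in% grammar$moves) {
    for (j in seq_len(10)) {
      lim <- ifelse(flagged[, j], min(nst[j], fs), nst[j])
      idx <- which(R[, j] < lim - 1L)
      if (length(idx)) push(idx, packed[idx] + mult_re[j], "oxidation")
    }
  }
  desaturable <- matrix(FALSE, n, nb)
  for (b in seq_len(nb)) {
    x <- bonds[b, 1]; y <- bonds[b, 2]
    desaturable[, b] <- !flagged[, x] & !flagged[, y] & R[, x] < fs & R[, y] < fs
  }
  if ("desaturation" %in% grammar$moves) {
    for (b in seq_len(nb)) {
      idx <- which(desaturable[, b])
      if (length(idx)) push(idx, packed[idx] + mult_b[b], "desaturation")
    }
  }
  if ("epoxidation" %in% grammar$moves) {
    for (b in which(grammar$epoxide_ok)) {
      idx <- which(B[, b] == 1L)
      if (length(idx)) push(idx, packed[idx] + mult_b[b], "epoxidation")
    }
  }
  if ("migration" %in% grammar$moves) {
    for (b in seq_len(nb)) for (b2 in seq_len(nb)) {
      if (b2 == b) next
      shared <- intersect(bonds[b, ], bonds[b2, ])
      if (length(shared) != 1) next
      far <- setdiff(bonds[b2, ], shared)
      idx <- which(B[, b] == 1L & !flagged[, far] & R[, far] < fs)
      if (length(idx))
        push(idx, packed[idx] - mult_b[b] + mult_b[b2], "migration")
    }
  }
  if ("relocation" %in% grammar$moves) {
    for (b in seq_len(nb)) for (b2 in seq_len(nb)) {
      if (b2 == b || any(bonds[b2, ] %in% bonds[b, ])) next
      idx <- which(B[, b] == 1L & desaturable[, b2])
      if (length(idx))
        push(idx, packed[idx] - mult_b[b] + mult_b[b2], "relocation")
    }
  }
  if ("double_desaturation" %in% grammar$moves && nb > 1) {
    for (b in seq_len(nb - 1)) for (b2 in (b + 1):nb) {
      if (any(bonds[b2, ] %in% bonds[b, ])) next
      idx <- which(desaturable[, b] & desaturable[, b2])
      if (length(idx))
        push(idx, packed[idx] + mult_b[b] + mult_b[b2], "double_desaturation")
    }
  }
  from <- unlist(from); to <- unlist(to); kind <- unlist(kind)
  a <- pmin(from, to); b <- pmax(from, to)
  dup <- duplicated(a * (n + 1) + b)
  list(from = a[!dup], to = b[!dup], kind = kind[!dup])
}

#' @export
print.chem_space <- function(x, ...) {
  cat("<chem_space>", length(x$keys), "scaffolds,",
      count_reactions(x), x$grammar$edge_count, "reactions\n")
  invisible(x)
}

#' Count the reactions of a chemical space
#'
#' @param space a \code{chem_space}.
#' @param convention "directed" counts each adjacency in both directions,
#'   "undirected" once; defaults to the grammar's convention.
#' @return integer reaction count.
#' @export
count_reactions <- function(space, convention = NULL) {
  convention <- convention %||% space$grammar$edge_count
  e <- igraph::ecount(space$graph)
  if (convention == "directed") 2L * e else e
}

#' Look up a code's vertex id in a space
#' @keywords internal
.space_vid <- function(space, code) {
  key <- if (inherits(code, "scaffold_code")) code_key(code) else code
  id <- match(key, space$keys)
  if (anyNA(id)) stop("code not in chemical space: ",
                      paste(key[is.na(id)], collapse = "; "))
  id
}

#' Reaction neighbors of a scaffold in the space
#'
#' @param space a \code{chem_space}.
#' @param code a \code{scaffold_code} or canonical key.
#' @return character vector of neighbor keys (never includes the query).
#' @export
space_neighbors <- function(space, code) {
  id <- .space_vid(space, code)
  nb <- igraph::neighbors(space$graph, id)
  igraph::V(space$graph)$name[nb]
}

#' Geodesic (minimum-reaction) distance between two scaffolds
#'
#' @param space a \code{chem_space}.
#' @param a,b codes or keys.
#' @return nonnegative integer number of reactions, or \code{Inf} when the
#'   scaffolds are not connected.
#' @export
geodesic <- function(space, a, b) {
  ia <- .space_vid(space, a); ib <- .space_vid(space, b)
  d <- igraph::distances(space$graph, v = ia, to = ib)
  as.numeric(d[1, 1])
}

#' Write / read a chemical space as GraphML or an edge-list TSV
#'
#' @param space a \code{chem_space}.
#' @param path output file; format chosen by extension (.graphml or .tsv).
#' @export
write_space <- function(space, path) {
  if (grepl("\\.graphml$", path)) {
    igraph::write_graph(space$graph, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(space$graph, names = TRUE)
    utils::write.table(
      data.frame(from = el[, 1], to = el[, 2], kind = igraph::E(space$graph)$kind),
      path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
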