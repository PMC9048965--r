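# Single-reaction moves on scaffold codes.  Every registered move has unit
# calibrated distance; the chemical-space graph is exactly the image of
# list_moves() over all valid codes.

.ox_kind <- function(carbon, from) {
  if (carbon == "C11")
    return(c("C11-direct-oxidation", "C11-direct-oxidation",
             "decarboxylation")[from + 1])
  c("hydroxylation", "alcohol-to-aldehyde", "aldehyde-to-acid",
    "decarboxylation")[from + 1]
}

.move <- function(kind, carbons, detail = NULL) {
  structure(list(kind = kind, carbons = carbons, detail = detail),
            class = "reaction_move")
}

#' @export
print.reaction_move <- function(x, ...) {
  cat("<reaction_move>", x$kind, "at", paste(x$carbons, collapse = ","), "\n")
  invisible(x)
}

#' List every applicable single-reaction move of a code
#'
#' Enumerates, in deterministic order, all forward moves the grammar allows
#' from a code: oxidation steps (hydroxylation, alcohol to aldehyde,
#' aldehyde to acid, decarboxylation, and the direct C11 steps),
#' desaturations, epoxidations of existing double bonds, and - when
#' registered - double-bond migrations along the skeleton and relocations
#' to a distant bond.
#'
#' @param code a valid \code{scaffold_code}.
#' @param grammar an \code{iridoid_grammar}.
#' @return a list of \code{reaction_move} objects.
#' @export
list_moves <- function(code, grammar = iridoid_grammar()) {
  vv <- validate_code(code, grammar)
  if (!vv$valid) stop("invalid code: ", paste(vv$violations, collapse = "; "))
  re <- code$re; im <- code$im
  carbons <- grammar$carbons
  flagged <- im != 0
  moves <- list()
  # oxidations
  if ("oxidation" %in% grammar$moves) {
    for (j in seq_along(carbons)) {
      lim <- if (flagged[j]) min(grammar$n_states[j], grammar$flag_states)
             else grammar$n_states[j]
      if (re[j] < lim - 1)
        moves[[length(moves) + 1]] <-
          .move(.ox_kind(carbons[j], re[j]), carbons[j])
    }
  }
  fs <- grammar$flag_states
  bonds <- grammar$bonds
  db <- .flag_bonds(im, grammar)
  double_on <- if (nrow(db)) db[db[, 2] == 1L, 1] else integer(0)
  desaturable <- vapply(seq_len(nrow(bonds)), function(b) {
    x <- bonds[b, 1]; y <- bonds[b, 2]
    !flagged[x] && !flagged[y] && re[x] < fs && re[y] < fs
  }, logical(1))
  if ("desaturation" %in% grammar$moves) {
    for (b in which(desaturable))
      moves[[length(moves) + 1]] <-
        .move("desaturation", carbons[bonds[b, ]], detail = b)
  }
  if ("epoxidation" %in% grammar$moves) {
    for (b in double_on[grammar$epoxide_ok[double_on]])
      moves[[length(moves) + 1]] <-
        .move("epoxidation", carbons[bonds[b, ]], detail = b)
  }
  if ("migration" %in% grammar$moves) {
    for (b in double_on) for (b2 in seq_len(nrow(bonds))) {
      if (b2 == b) next
      shared <- intersect(bonds[b, ], bonds[b2, ])
      if (length(shared) != 1) next
      far <- setdiff(bonds[b2, ], shared)
      if (!flagged[far] && re[far] < fs)
        moves[[length(moves) + 1]] <-
          .move("migration", carbons[bonds[b2, ]], detail = c(b, b2))
    }
  }
  if ("relocation" %in% grammar$moves) {
    for (b in double_on) for (b2 in which(desaturable)) {
      if (any(bonds[b2, ] %in% bonds[b, ])) next
      moves[[length(moves) + 1]] <-
        .move("relocation", carbons[bonds[b2, ]], detail = c(b, b2))
    }
  }
  if ("double_desaturation" %in% grammar$moves) {
    ds <- which(desaturable)
    if (length(ds) > 1) {
      for (i in seq_len(length(ds) - 1)) for (jj in (i + 1):length(ds)) {
        b1 <- ds[i]; b2 <- ds[jj]
        if (!any(bonds[b1, ] %in% bonds[b2, ]))
          moves[[length(moves) + 1]] <-
            .move("double_desaturation",
                  carbons[c(bonds[b1, ], bonds[b2, ])], detail = c(b1, b2))
      }
    }
  }
  moves
}

#' Apply a single-reaction move to a scaffold code
#'
#' @param code a valid \code{scaffold_code}.
#' @param move a \code{reaction_move} (from \code{\link{list_moves}}, or
#'   constructed with matching fields).
#' @param grammar an \code{iridoid_grammar}.
#' @return the resulting valid \code{scaffold_code}; inapplicable moves are
#'   rejected with the reason.
#' @export
apply_move <- function(code, move, grammar = iridoid_grammar()) {
  stopifnot(inherits(move, "reaction_move"))
  re <- code$re; im <- code$im
  carbons <- grammar$carbons
  bonds <- grammar$bonds
  kind <- move$kind
  if (kind %in% c("hydroxylation", "alcohol-to-aldehyde", "aldehyde-to-acid",
                  "decarboxylation", "C11-direct-oxidation")) {
    j <- match(move$carbons[1], carbons)
    if (is.na(j)) stop("unknown carbon ", move$carbons[1])
    lim <- if (im[j] != 0) min(grammar$n_states[j], grammar$flag_states)
           else grammar$n_states[j]
    if (re[j] >= lim - 1)
      stop("cannot oxidize ", carbons[j], " beyond state ", re[j],
           if (im[j] != 0) " (unsaturation flag caps the state)" else "")
    re[j] <- re[j] + 1L
  } else if (kind == "desaturation") {
    b <- .find_bond(move$carbons, grammar)
    x <- bonds[b, 1]; y <- bonds[b, 2]
    if (im[x] != 0 || im[y] != 0) stop("bond already unsaturated")
    if (re[x] >= grammar$flag_states || re[y] >= grammar$flag_states)
      stop("oxidation state too high for a double bond")
    im[x] <- im[y] <- 1L
  } else if (kind == "epoxidation") {
    b <- .find_bond(move$carbons, grammar)
    if (!grammar$epoxide_ok[b])
      stop("epoxide not allowed on bond ", grammar$bond_labels[b])
    x <- bonds[b, 1]; y <- bonds[b, 2]
    if (im[x] != 1L || im[y] != 1L)
      stop("epoxidation requires an existing double bond")
    im[x] <- im[y] <- 3L
  } else if (kind %in% c("migration", "relocation")) {
    b_old <- move$detail[1]; b_new <- move$detail[2]
    x <- bonds[b_old, 1]; y <- bonds[b_old, 2]
    if (im[x] != 1L || im[y] != 1L) stop("no double bond to move")
    im[x] <- 0L; im[y] <- 0L
    nx <- bonds[b_new, 1]; ny <- bonds[b_new, 2]
    if (im[nx] != 0 || im[ny] != 0) stop("target bond already unsaturated")
    if (re[nx] >= grammar$flag_states || re[ny] >= grammar$flag_states)
      stop("oxidation state too high for the migrated double bond")
    im[nx] <- 1L; im[ny] <- 1L
  } else if (kind == "double_desaturation") {
    for (b in move$detail) {
      x <- bonds[b, 1]; y <- bonds[b, 2]
      if (im[x] != 0 || im[y] != 0) stop("bond already unsaturated")
      if (re[x] >= grammar$flag_states || re[y] >= grammar$flag_states)
        stop("oxidation state too high for a double bond")
      im[x] <- im[y] <- 1L
    }
  } else stop("unknown move kind: ", kind)
  out <- scaffold_code(re, im)
  vv <- validate_code(out, grammar)
  if (!vv$valid)
    stop("move produced an invalid code: ",
         paste(vv$violations, collapse = "; "))
  out
}

.find_bond <- function(carbs, grammar) {
  idx <- match(carbs, grammar$carbons)
  b <- which((grammar$bonds[, 1] == idx[1] & grammar$bonds[, 2] == idx[2]) |
             (grammar$bonds[, 1] == idx[2] & grammar$bonds[, 2] == idx[1]))
  if (length(b) != 1) stop("not a skeleton bond: ", paste(carbs, collapse = "-"))
  b
}
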