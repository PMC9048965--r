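#' Construct a scaffold code
#'
#' A scaffold code assigns every scaffold carbon a complex value: the real
#' part is the ordinal oxidation state and the imaginary part, in fourths,
#' flags participation in a double bond (1/4) or epoxide (3/4).
#'
#' @param re integer vector of length 10 (ordinal oxidation states), in the
#'   fixed carbon order C1, C3, C4, C5, C6, C7, C8, C9, C10, C11 (or named).
#' @param im imaginary flags in fourths: 0, 1 (= 1/4, double bond) or
#'   3 (= 3/4, epoxide); default none.
#' @return an object of class \code{scaffold_code}.
#' @export
scaffold_code <- function(re, im = rep(0L, 10)) {
  carbons <- .IRIDOID_CARBONS
  if (!is.null(names(re))) {
    if (!setequal(names(re), carbons))
      stop("malformed position set: expected exactly ",
           paste(carbons, collapse = ", "))
    re <- re[carbons]
  }
  if (!is.null(names(im))) im <- im[carbons]
  if (length(re) != 10 || length(im) != 10)
    stop("malformed position set: a code needs all 10 carbon positions")
  structure(list(re = stats::setNames(as.integer(re), carbons),
                 im = stats::setNames(as.integer(im), carbons)),
            class = "scaffold_code")
}

#' @export
print.scaffold_code <- function(x, ...) {
  cat("<scaffold_code>", format_code(x), "\n")
  invisible(x)
}

#' @export
format.scaffold_code <- function(x, ...) format_code(x)

#' Serialize / parse scaffold codes
#'
#' The text form is a comma-separated list of per-carbon tokens in fixed
#' carbon order; each token is the oxidation state, optionally followed by
#' an imaginary flag written in fourths: \code{"1"}, \code{"0+1/4i"},
#' \code{"2+3/4i"}.
#'
#' @param code a \code{scaffold_code}.
#' @return \code{format_code}: a single string; \code{parse_code}: a
#'   \code{scaffold_code}.
#' @export
format_code <- function(code) {
  stopifnot(inherits(code, "scaffold_code"))
  tok <- as.character(code$re)
  has <- code$im != 0
  tok[has] <- paste0(tok[has], "+", code$im[has], "/4i")
  paste(tok, collapse = ",")
}

#' @rdname format_code
#' @param text a serialized code string.
#' @export
parse_code <- function(text) {
  tok <- strsplit(trimws(text), ",", fixed = TRUE)[[1]]
  tok <- trimws(tok)
  if (length(tok) != 10)
    stop("malformed position set: expected 10 tokens, got ", length(tok))
  re <- integer(10); im <- integer(10)
  for (j in seq_along(tok)) {
    m <- regmatches(tok[j],
                    regexec("^([0-9]+)(\\+([13])/4i)?$", tok[j]))[[1]]
    if (!length(m))
      stop("column ", j, " (", .IRIDOID_CARBONS[j], "): malformed token '",
           tok[j], "'")
    re[j] <- as.integer(m[2])
    im[j] <- if (m[4] == "") 0L else as.integer(m[4])
  }
  scaffold_code(re, im)
}

#' Canonical key of a scaffold code
#'
#' @param code a \code{scaffold_code} (or list of codes).
#' @return the serialized string, used as the node identifier everywhere.
#' @export
code_key <- function(code) {
  if (inherits(code, "scaffold_code")) return(format_code(code))
  vapply(code, format_code, character(1))
}

# Decompose an imaginary flag vector into bonds: returns a matrix with one
# row per flagged bond (bond index, flag value), or NULL when the flags do
# not pair up along the skeleton.  On the iridoid skeleton (a tree plus one
# odd cycle) a pairable flag vector decomposes uniquely.
.flag_bonds <- function(im, grammar) {
  flagged <- which(im != 0)
  if (!length(flagged)) return(matrix(integer(0), 0, 2))
  pairs <- NULL
  remaining <- flagged
  repeat {
    if (!length(remaining)) break
    progress <- FALSE
    for (c1 in remaining) {
      cand <- which((grammar$bonds[, 1] == c1 & grammar$bonds[, 2] %in% remaining) |
                    (grammar$bonds[, 2] == c1 & grammar$bonds[, 1] %in% remaining))
      cand <- cand[im[grammar$bonds[cand, 1]] == im[c1] &
                   im[grammar$bonds[cand, 2]] == im[c1]]
      if (length(cand) == 1) {
        b <- cand
        pairs <- rbind(pairs, c(b, im[c1]))
        remaining <- setdiff(remaining, grammar$bonds[b, ])
        progress <- TRUE
        break
      }
      if (length(cand) == 0) return(NULL)   # unpairable carbon
    }
    if (!progress) return(NULL)             # ambiguous / stuck
  }
  pairs
}

#' Validate a scaffold code against the grammar
#'
#' Checks oxidation-state bounds, pairing of unsaturation flags along the
#' ring skeleton, epoxide placement, and the valence rule that flags may
#' only sit on carbons below the flag oxidation limit.
#'
#' @param code a \code{scaffold_code}.
#' @param grammar an \code{iridoid_grammar}.
#' @return a list with \code{valid} (logical) and \code{violations}
#'   (character vector naming position and rule for each failure).
#' @export
validate_code <- function(code, grammar = iridoid_grammar()) {
  stopifnot(inherits(code, "scaffold_code"))
  v <- character(0)
  re <- code$re; im <- code$im
  for (j in seq_along(re)) {
    cn <- grammar$carbons[j]
    if (is.na(re[j]) || re[j] < 0 || re[j] >= grammar$n_states[j])
      v <- c(v, paste0(cn, ": oxidation state ", re[j],
                       " outside 0..", grammar$n_states[j] - 1))
    if (!im[j] %in% c(0L, 1L, 3L))
      v <- c(v, paste0(cn, ": imaginary part must be 0, 1/4 or 3/4"))
    if (im[j] != 0 && re[j] >= grammar$flag_states)
      v <- c(v, paste0(cn, ": unsaturation flag on oxidation state ", re[j],
                       " violates the valence rule (limit ",
                       grammar$flag_states, ")"))
  }
  fb <- .flag_bonds(im, grammar)
  if (is.null(fb)) {
    v <- c(v, "unsaturation flags do not pair along the ring skeleton")
  } else if (nrow(fb)) {
    epo <- fb[fb[, 2] == 3L, 1]
    bad <- epo[!grammar$epoxide_ok[epo]]
    if (length(bad))
      v <- c(v, paste0("epoxide not allowed on bond ",
                       grammar$bond_labels[bad]))
  }
  list(valid = length(v) == 0, violations = v)
}

#' Generalized reaction distance between two scaffold codes
#'
#' The literal distance is the summed modulus of the per-carbon complex
#' differences (imaginary parts in fourths).  The calibrated distance
#' rescales unsaturation changes so that every registered single-reaction
#' move scores exactly 1: real steps count 1 each, and the flag difference
#' is decomposed into the minimal number of registered bond events
#' (desaturation/saturation, epoxidation, double-bond migration or
#' relocation), each counting 1.
#'
#' @param a,b \code{scaffold_code}s, both valid under the grammar.
#' @param grammar an \code{iridoid_grammar}.
#' @param calibrate use the move-calibrated distance (default); if FALSE,
#'   return the literal complex Manhattan distance.
#' @return a nonnegative number; 0 iff the codes are equal.
#' @export
generalized_distance <- function(a, b, grammar = iridoid_grammar(),
                                 calibrate = TRUE) {
  for (x in list(a, b)) {
    vv <- validate_code(x, grammar)
    if (!vv$valid) stop("invalid code: ", paste(vv$violations, collapse = "; "))
  }
  dre <- sum(abs(a$re - b$re))
  if (!calibrate)
    return(dre + sum(abs(a$im - b$im)) / 4)
  fa <- .flag_bonds(a$im, grammar); fb <- .flag_bonds(b$im, grammar)
  sa <- integer(length(grammar$bond_labels)); sb <- sa
  if (nrow(fa)) sa[fa[, 1]] <- fa[, 2]
  if (nrow(fb)) sb[fb[, 1]] <- fb[, 2]
  changed <- sum(sa != 0 & sb != 0 & sa != sb)      # double <-> epoxide
  lost <- which(sa != 0 & sb == 0)
  gained <- which(sa == 0 & sb != 0)
  cost <- changed
  npair <- 0
  if (any(c("migration", "relocation") %in% grammar$moves))
    npair <- min(length(lost), length(gained))
  rem_lost <- length(lost) - npair
  rem_gained <- length(gained) - npair
  if ("double_desaturation" %in% grammar$moves) {
    # paired (de)saturations count as one concerted event
    cost <- cost + npair + ceiling(rem_lost / 2) + ceiling(rem_gained / 2)
  } else {
    cost <- cost + npair + rem_lost + rem_gained
  }
  dre + cost
}
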