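# Shared fixtures, built once per test run.

# a small toy grammar: few states, no unsaturation beyond one bond, so the
# space stays tiny and brute-force oracles are feasible
toy_grammar <- function(n = c(C1 = 2, C3 = 2, C4 = 2, C5 = 2, C6 = 2,
                              C7 = 2, C8 = 2, C9 = 2, C10 = 2, C11 = 2),
                        ...) {
  iridoid_grammar(n_states = n, ...)
}

# memoised full default space (enumeration is the expensive step)
.space_cache <- new.env(parent = emptyenv())
default_space <- function() {
  if (is.null(.space_cache$space)) .space_cache$space <- enumerate_space()
  .space_cache$space
}

toy_space_cache <- new.env(parent = emptyenv())
toy_space <- function() {
  if (is.null(toy_space_cache$space))
    toy_space_cache$space <- enumerate_space(toy_grammar())
  toy_space_cache$space
}

# the catalpol scaffold: C3=C4 double bond, C7-C8 epoxide, hydroxyls at
# C1, C6 and C10, C11 fully decarboxylated
catalpol_code <- function() {
  scaffold_code(re = c(C1 = 1, C3 = 0, C4 = 0, C5 = 0, C6 = 1, C7 = 0,
                       C8 = 0, C9 = 0, C10 = 1, C11 = 3),
                im = c(C1 = 0, C3 = 1, C4 = 1, C5 = 0, C6 = 0, C7 = 3,
                       C8 = 3, C9 = 0, C10 = 0, C11 = 0))
}

# aucubin: like catalpol but with the 7,8-double bond not yet epoxidised
aucubin_code <- function() {
  scaffold_code(re = c(C1 = 1, C3 = 0, C4 = 0, C5 = 0, C6 = 1, C7 = 0,
                       C8 = 0, C9 = 0, C10 = 1, C11 = 3),
                im = c(C1 = 0, C3 = 1, C4 = 1, C5 = 0, C6 = 0, C7 = 1,
                       C8 = 1, C9 = 0, C10 = 0, C11 = 0))
}

# bartsioside: aucubin without the 6-hydroxyl
bartsioside_code <- function() {
  scaffold_code(re = c(C1 = 1, C3 = 0, C4 = 0, C5 = 0, C6 = 0, C7 = 0,
                       C8 = 0, C9 = 0, C10 = 1, C11 = 3),
                im = c(C1 = 0, C3 = 1, C4 = 1, C5 = 0, C6 = 0, C7 = 1,
                       C8 = 1, C9 = 0, C10 = 0, C11 = 0))
}

# random valid codes drawn uniformly from an enumerated space
random_codes <- function(space, n, seed = 1) {
  set.seed(seed)
  idx <- sample.int(length(space$keys), n, replace = n > length(space$keys))
  lapply(space$keys[idx], parse_code)
}

# tiny 3-taxon tree: sisters a,b split at depth 0.2 from the tips; c basal
three_taxon_tree <- function() {
  ape::read.tree(text = "((a:0.2,b:0.2):0.8,c:1.0);")
}

# star tree: every tip attached directly to the root
star_tree <- function(n = 4, len = 1) {
  tr <- ape::read.tree(text = paste0("(", paste0(letters[1:n], ":", len,
                                                 collapse = ","), ");"))
  tr
}

# brute-force Felsenstein oracle: sum the likelihood over every assignment
# of states to internal nodes (exhaustive enumeration)
felsenstein_oracle <- function(tree, present, rate = 1) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  pstay <- function(t) (1 + exp(-2 * rate * t)) / 2
  tipstate <- ifelse(tree$tip.label %in% present, 1L, NA_integer_)
  total <- c(0, 0)  # likelihood with root = absent, present
  for (mask in 0:(2^nint - 1)) {
    states <- as.integer(intToBits(mask))[seq_len(nint)]
    full <- c(tipstate, states)
    lik <- 1
    for (k in seq_len(nrow(tree$edge))) {
      par <- full[tree$edge[k, 1]]; chi <- full[tree$edge[k, 2]]
      t <- tree$edge.length[k]
      if (is.na(chi)) next                       # missing tip: sums to 1
      p <- if (par == chi) pstay(t) else 1 - pstay(t)
      lik <- lik * p
    }
    root_state <- states[1]                       # node ntip+1 is the root
    total[root_state + 1] <- total[root_state + 1] + lik
  }
  # flat prior; but the masks above also enumerate internal non-root nodes:
  # lik already summed over them, with missing tips integrated out
  total[2] / sum(total)
}
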