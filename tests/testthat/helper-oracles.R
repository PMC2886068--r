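# Independent oracles used across the suite. These deliberately avoid the
# package's own computation paths: masses are summed from a local constant
# table, and parsimony minima come from exhaustive enumeration of internal
# labelings.

ORACLE_EL <- c(C = 12.000000, H = 1.007825, N = 14.003074, O = 15.994915,
               S = 31.972071)
ORACLE_PROTON <- 1.007276

oracle_mass <- function(counts) {
  sum(counts * ORACLE_EL[names(counts)])
}

# parse "C24H40O5" into element counts
oracle_parse_formula <- function(s) {
  m <- gregexpr("([A-Z])([0-9]*)", s)[[1]]
  toks <- regmatches(s, gregexpr("([A-Z])([0-9]*)", s))[[1]]
  el <- sub("[0-9]*$", "", toks)
  n <- as.integer(sub("^[A-Z]", "", toks))
  n[is.na(n)] <- 1L
  stats::setNames(n, el)
}

# minimal change count and optimal root states by brute force over all
# internal-node labelings (fixed tip states)
oracle_parsimony <- function(tree, states, alphabet) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  tips <- as.character(states[tree$tip.label])
  grids <- rep(list(alphabet), nnode)
  lab <- expand.grid(grids, stringsAsFactors = FALSE)
  costs <- apply(lab, 1L, function(assign) {
    full <- c(tips, as.character(assign))
    sum(full[tree$edge[, 1]] != full[tree$edge[, 2]])
  })
  best <- min(costs)
  root_states <- sort(unique(lab[costs == best, 1L]))
  list(changes = best, root_states = root_states)
}

# random rooted tree with polytomies: repeatedly merge 2..4 random subtrees
random_polytomy_tree <- function(ntip) {
  parts <- paste0("t", seq_len(ntip))
  while (length(parts) > 1L) {
    k <- sample(2:min(4, length(parts)), 1L)
    pick <- sample(seq_along(parts), k)
    merged <- paste0("(", paste(parts[pick], collapse = ","), ")")
    parts <- c(parts[-pick], merged)
  }
  ape::read.tree(text = paste0(parts, ";"))
}

# random valid descriptor spanning scaffolds, substituents and conjugation
random_descriptor <- function() {
  cc <- sample(c(23L, 24L, 27L), 1L)
  terminal <- if (cc == 27L && stats::runif(1) < 0.3) "alcohol" else "acid"
  positions <- sample(setdiff(1:17, 5L), sample(0:4, 1L))
  n_oh <- length(positions)
  oh <- if (n_oh) paste0(positions, sample(c("a", "b"), n_oh, TRUE)) else character()
  left <- setdiff(setdiff(1:17, 5L), positions)
  oxo <- sample(left, sample(0:2, 1L))
  db <- if (stats::runif(1) < 0.3) 22L else integer()
  bile_salt(cc, terminal, sample(c("5a", "5b"), 1L), oh, oxo, db, "none")
}

with_conjugation <- function(d, conj) {
  d$conjugation <- conj
  d
}
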