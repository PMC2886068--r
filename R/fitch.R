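#' Parsimony ancestral state sets (Fitch/Hartigan)
#'
#' Bottom-up most-parsimonious reconstruction of a discrete character on a
#' rooted tree. At each internal node the state set is the set of states
#' carried by the maximum number of child sets (Hartigan's generalization of
#' the Fitch intersection/union rule, exact on polytomies); the change count
#' accumulates (number of children - that maximum) and equals the global
#' parsimony minimum. The full most-parsimonious root set is reported — ties
#' are information, not errors.
#'
#' @param tree An `ape::phylo` tree, interpreted as rooted at its root node;
#'   polytomies (including basal ones) permitted; branch lengths ignored.
#' @param states Named character vector of tip states (names = tip labels).
#'   `NA` marks missing data.
#' @param missing `"prune"` (default) drops tips with missing states before
#'   reconstruction; `"error"` refuses them.
#' @return List with `changes` (minimal number of state changes),
#'   `root_states` (character vector), and `node_states` (list of state sets
#'   indexed by internal node number, named by node label where available).
#' @examples
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' fitch_ancestral(tr, c(A = "alcohol", B = "alcohol", C = "acid", D = "acid"))
#' @export
fitch_ancestral <- function(tree, states, missing = c("prune", "error")) {
  missing <- match.arg(missing)
  stopifnot(inherits(tree, "phylo"))
  # the tree is interpreted as rooted at its root node; a basal polytomy
  # (ape's "unrooted" flag) is accepted, as in published group-level trees
  if (is.null(names(states))) stop("states must be named by tip label")

  tip_states <- states[tree$tip.label]
  names(tip_states) <- tree$tip.label
  absent <- is.na(tip_states)
  if (any(absent)) {
    if (missing == "error") {
      stop("tip(s) without a state: ",
           paste(tree$tip.label[absent], collapse = ", "))
    }
    if (sum(!absent) < 2) stop("fewer than two tips carry a state")
    tree <- ape::drop.tip(tree, tree$tip.label[absent],
                          collapse.singles = TRUE)
    tip_states <- states[tree$tip.label]
  }

  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  sets <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) sets[[i]] <- as.character(tip_states[i])

  if (ntip == 1L) {
    internal <- list(sets[[1]])
    if (!is.null(tree$node.label)) names(internal) <- tree$node.label
    return(list(changes = 0L, root_states = sets[[1]],
                node_states = internal, tree = tree))
  }

  changes <- 0L
  edge <- tree$edge[ape::postorder(tree), , drop = FALSE]
  # visit each internal node at its *last* postorder edge, so that every
  # child subtree (even with interleaved edge storage) is already resolved
  node_order <- rev(unique(rev(edge[, 1])))
  for (node in node_order) {
    children <- edge[edge[, 1] == node, 2]
    tab <- table(unlist(lapply(children, function(ch) unique(sets[[ch]]))))
    k_max <- max(tab)
    sets[[node]] <- sort(names(tab)[tab == k_max])
    changes <- changes + length(children) - k_max
  }

  root <- ntip + 1L
  internal <- sets[(ntip + 1L):(ntip + nnode)]
  if (!is.null(tree$node.label)) names(internal) <- tree$node.label
  list(changes = as.integer(changes),
       root_states = sets[[root]],
       node_states = internal,
       tree = tree)
}

#' Ancestral state set at a named internal node
#'
#' Convenience accessor: the most-parsimonious state set at the internal node
#' carrying a given label (or at the most recent common ancestor of a set of
#' tips).
#'
#' @param fit Result of [fitch_ancestral()].
#' @param node Node label (matched against the tree's node labels), or a
#'   character vector of two or more tip labels whose MRCA is used.
#' @return Character vector of states.
#' @export
node_state_set <- function(fit, node) {
  tree <- fit$tree
  ntip <- length(tree$tip.label)
  if (length(node) == 1 && !is.null(tree$node.label) &&
      node %in% tree$node.label) {
    idx <- which(tree$node.label == node)
  } else {
    if (!all(node %in% tree$tip.label)) {
      stop("node must be an internal-node label or a vector of tip labels")
    }
    idx <- ape::getMRCA(tree, node) - ntip
  }
  fit$node_states[[idx]]
}
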