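## Binary-character parsimony on rooted trees (ape "phylo" objects).
## Branch lengths are ignored throughout: the scenario comparison is about
## event counts, not rates. Node ids follow ape numbering (tips 1..n, root
## n+1); node_label() gives stable printable names.

node_label <- function(tree, node) {
  n <- ape::Ntip(tree)
  vapply(node, function(v) {
    if (v <= n) tree$tip.label[v]
    else if (!is.null(tree$node.label) && nzchar(tree$node.label[v - n]))
      tree$node.label[v - n]
    else paste0("n", v)
  }, character(1))
}

check_states <- function(tree, states) {
  validate_tree(tree)
  if (is.null(names(states))) stop("states must be named by leaf label", call. = FALSE)
  missing <- setdiff(tree$tip.label, names(states))
  if (length(missing)) {
    stop(sprintf("leaf without state: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  unknown <- setdiff(names(states), tree$tip.label)
  if (length(unknown)) {
    stop(sprintf("state for unknown taxon: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  st <- as.integer(states[tree$tip.label])
  if (anyNA(st) || !all(st %in% c(0L, 1L))) {
    stop("states must be 0/1", call. = FALSE)
  }
  stats::setNames(st, tree$tip.label)
}

children_of <- function(tree) {
  split(tree$edge[, 2L], factor(tree$edge[, 1L],
                                levels = seq_len(ape::Ntip(tree) + tree$Nnode)))
}

#' Fitch parsimony cost of a binary character
#'
#' Minimum number of state changes over all ancestral labelings of a rooted
#' tree, with one optimal labeling returned. Polytomies are handled by the
#' generalized (multi-child count) rule: at each internal node the states
#' held by the largest number of child state-sets are kept and the cost grows
#' by the number of children not supporting them. The cost is invariant to
#' the root position; the labeling returned is one optimum.
#'
#' @param tree a rooted `phylo` tree.
#' @param states named 0/1 vector over all leaf labels.
#' @return list with `cost` (integer) and `labeling` (named 0/1 integer
#'   vector over all nodes, tips first).
#' @export
fitch_cost <- function(tree, states) {
  st <- check_states(tree, states)
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  kids <- children_of(tree)
  ## state sets as a 2-col logical matrix [node, c(state0, state1)]
  sets <- matrix(FALSE, nrow = nnode, ncol = 2L)
  sets[cbind(seq_len(ntip), st + 1L)] <- TRUE
  cost <- 0L
  po <- rev(postorder_nodes(tree))  # children before parents
  for (v in po) {
    ch <- kids[[v]]
    if (is.null(ch) || length(ch) == 0L) next
    k0 <- sum(sets[ch, 1L]); k1 <- sum(sets[ch, 2L])
    K <- max(k0, k1)
    sets[v, ] <- c(k0 == K, k1 == K)
    cost <- cost + (length(ch) - K)
  }
  ## top-down refinement: parent state when allowed, else any optimal state
  lab <- integer(nnode)
  lab[root] <- if (sets[root, 2L]) 1L else 0L
  pre <- preorder_edges(tree)
  for (i in seq_len(nrow(pre))) {
    u <- pre[i, 1L]; v <- pre[i, 2L]
    lab[v] <- if (sets[v, lab[u] + 1L]) lab[u]
    else if (sets[v, 2L]) 1L else 0L
  }
  names(lab) <- node_label(tree, seq_len(nnode))
  list(cost = as.integer(cost), labeling = lab)
}

## internal nodes in an order where every child precedes its parent is
## obtained by reversing this root-first ordering
postorder_nodes <- function(tree) {
  ntip <- ape::Ntip(tree)
  ord <- integer(0)
  stack <- ntip + 1L
  kids <- children_of(tree)
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    ord <- c(ord, v)
    ch <- kids[[v]]
    internal <- ch[ch > ntip]
    if (length(internal)) stack <- c(stack, internal)
  }
  ord
}

## edges ordered parent before child (preorder)
preorder_edges <- function(tree) {
  ntip <- ape::Ntip(tree)
  kids <- children_of(tree)
  out <- matrix(integer(0), ncol = 2L)
  stack <- ntip + 1L
  while (length(stack)) {
    u <- stack[length(stack)]
    stack <- stack[-length(stack)]
    ch <- kids[[u]]
    if (is.null(ch) || length(ch) == 0L) next
    out <- rbind(out, cbind(u, ch))
    stack <- c(stack, ch[ch > ntip])
  }
  out
}

subtree_state_flags <- function(tree, st) {
  ## for each node: does its leaf set consist entirely of 0s / of 1s
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  all0 <- logical(nnode); all1 <- logical(nnode)
  all0[seq_len(ntip)] <- st == 0L
  all1[seq_len(ntip)] <- st == 1L
  kids <- children_of(tree)
  for (v in rev(postorder_nodes(tree))) {
    ch <- kids[[v]]
    if (is.null(ch) || length(ch) == 0L) next
    all0[v] <- all(all0[ch])
    all1[v] <- all(all1[ch])
  }
  list(all0 = all0, all1 = all1)
}

#' Dollo scenario: single gain plus minimal secondary losses
#'
#' Under the constraint that the character is gained exactly once, the gain
#' is placed on the branch above the most recent common ancestor of all
#' state-1 leaves, and the losses are the minimal set of branches below it —
#' the roots of the maximal all-0 subtrees inside the gain clade. The event
#' count is `1 + losses` (0 for an all-absent character).
#'
#' @param tree a rooted `phylo` tree.
#' @param states named 0/1 vector over all leaf labels.
#' @return list with `gain_node`, `gain_label`, `loss_branches` (child-node
#'   ids identifying the branches), `loss_labels`, `n_losses`,
#'   `event_count`.
#' @export
dollo_scenario <- function(tree, states) {
  st <- check_states(tree, states)
  if (all(st == 0L)) {
    return(list(gain_node = NA_integer_, gain_label = NA_character_,
                loss_branches = integer(0), loss_labels = character(0),
                n_losses = 0L, event_count = 0L))
  }
  ntip <- ape::Ntip(tree)
  ones <- which(st == 1L)
  gain <- if (length(ones) == 1L) ones else ape::getMRCA(tree, ones)
  flags <- subtree_state_flags(tree, st)
  kids <- children_of(tree)
  losses <- integer(0)
  stack <- gain
  while (length(stack)) {
    u <- stack[length(stack)]
    stack <- stack[-length(stack)]
    ch <- kids[[u]]
    if (is.null(ch) || length(ch) == 0L) next
    for (v in ch) {
      if (flags$all0[v]) losses <- c(losses, v) else stack <- c(stack, v)
    }
  }
  losses <- sort(losses)
  list(gain_node = as.integer(gain),
       gain_label = node_label(tree, gain),
       loss_branches = losses,
       loss_labels = node_label(tree, losses),
       n_losses = length(losses),
       event_count = 1L + length(losses))
}

#' Minimum number of gains when losses are forbidden
#'
#' Equals the number of maximal subtrees whose leaves are all in state 1
#' (together covering every state-1 leaf); each such clade requires one
#' independent gain on the branch above it.
#'
#' @inheritParams dollo_scenario
#' @return integer gain count (0 for an all-absent character).
#' @export
gains_only_cost <- function(tree, states) {
  st <- check_states(tree, states)
  if (all(st == 0L)) return(0L)
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  flags <- subtree_state_flags(tree, st)
  parent <- integer(nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  maximal <- vapply(seq_len(nnode), function(v) {
    flags$all1[v] && (v == root || !flags$all1[parent[v]])
  }, logical(1))
  as.integer(sum(maximal))
}

#' Compare loss-based and convergence-based scenarios per character
#'
#' For every character of a binary presence/absence matrix, computes the
#' Fitch cost, the Dollo event count (one gain plus minimal losses) and the
#' gains-only cost, and renders a verdict: `convergence_scenario` when
#' independent gains need fewer events than the single-gain-plus-losses
#' history, `losses_scenario` when they need more, `tie` otherwise. This
#' operationalizes the qualitative argument that scattered presence across
#' distant clades demands an unparsimonious number of losses under a single
#' ancestral gain.
#'
#' @param tree a rooted `phylo` tree.
#' @param matrix a taxa-by-characters 0/1 matrix with rownames = taxa and
#'   colnames = character names (or a data.frame of the same shape).
#' @return data.frame with one row per character: `character`, `fitch_cost`,
#'   `gains_only_cost`, `dollo_gain`, `dollo_losses`, `dollo_event_count`,
#'   `verdict`.
#' @export
compare_scenarios <- function(tree, matrix) {
  validate_tree(tree)
  m <- as.matrix(matrix)
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("presence matrix needs taxon rownames and character colnames",
         call. = FALSE)
  }
  unknown <- setdiff(rownames(m), tree$tip.label)
  if (length(unknown)) {
    stop(sprintf("taxa not in tree: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  rows <- lapply(colnames(m), function(ch) {
    states <- stats::setNames(as.integer(m[, ch]), rownames(m))
    fc <- fitch_cost(tree, states)
    ds <- dollo_scenario(tree, states)
    gc <- gains_only_cost(tree, states)
    verdict <- if (gc < ds$event_count) "convergence_scenario"
    else if (gc > ds$event_count) "losses_scenario" else "tie"
    data.frame(character = ch,
               fitch_cost = fc$cost,
               gains_only_cost = gc,
               dollo_gain = if (is.na(ds$gain_node)) NA_character_ else ds$gain_label,
               dollo_losses = paste(ds$loss_labels, collapse = ";"),
               dollo_event_count = ds$event_count,
               verdict = verdict)
  })
  do.call(rbind, rows)
}
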