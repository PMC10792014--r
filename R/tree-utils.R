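# Shared low-level helpers over phylo objects: parent/children lookup,
# depths, LCA, postorder. All are O(n) or O(n log n) and index nodes by
# the ape convention (tips 1..Ntip, internals Ntip+1..Ntip+Nnode).

#' @keywords internal
n_nodes <- function(tree) length(tree$tip.label) + tree$Nnode

#' @keywords internal
root_node <- function(tree) {
  setdiff(unique(tree$edge[, 1]), tree$edge[, 2])[1]
}

#' @keywords internal
parent_vec <- function(tree) {
  p <- rep(NA_integer_, n_nodes(tree))
  p[tree$edge[, 2]] <- tree$edge[, 1]
  p
}

#' @keywords internal
children_list <- function(tree) {
  ch <- vector("list", n_nodes(tree))
  for (i in seq_len(nrow(tree$edge))) {
    a <- tree$edge[i, 1]; b <- tree$edge[i, 2]
    ch[[a]] <- c(ch[[a]], b)
  }
  for (i in seq_along(ch)) if (is.null(ch[[i]])) ch[[i]] <- integer(0)
  ch
}

# branch length indexed by child node, NA if absent
#' @keywords internal
edge_length_lookup <- function(tree) {
  lens <- rep(NA_real_, n_nodes(tree))
  if (!is.null(tree$edge.length)) lens[tree$edge[, 2]] <- tree$edge.length
  lens
}

# node ids in postorder (children before parents)
#' @keywords internal
postorder_ids <- function(tree) {
  ord <- integer(0)
  kids <- children_list(tree)
  stack <- root_node(tree)
  # iterative reverse-preorder then reverse
  out <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    out <- c(out, v)
    stack <- c(stack, kids[[v]])
  }
  rev(out)
}

# depth (edges from root) per node
#' @keywords internal
depth_vec <- function(tree) {
  d <- rep(NA_integer_, n_nodes(tree))
  d[root_node(tree)] <- 0L
  for (i in rev(postorder_ids(tree))) {
    if (is.na(d[i])) next
  }
  # preorder fill
  kids <- children_list(tree)
  stack <- root_node(tree)
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    for (c0 in kids[[v]]) {
      d[c0] <- d[v] + 1L
      stack <- c(stack, c0)
    }
  }
  d
}

# label per node id (tips then internal labels)
#' @keywords internal
node_labels <- function(tree) {
  nl <- tree$node.label
  if (is.null(nl)) nl <- paste0("node", seq_len(tree$Nnode))
  c(tree$tip.label, nl)
}

#' @keywords internal
label_to_id <- function(tree) {
  labs <- node_labels(tree)
  stats::setNames(seq_along(labs), labs)
}

# LCA of two nodes by climbing with depths; small trees only
#' @keywords internal
lca_pair <- function(a, b, parent, depth) {
  while (a != b) {
    if (depth[a] < depth[b]) b <- parent[b]
    else if (depth[b] < depth[a]) a <- parent[a]
    else { a <- parent[a]; b <- parent[b] }
  }
  a
}

# TRUE iff a is an ancestor of b or equal to it
#' @keywords internal
is_ancestor_or_equal <- function(a, b, parent, depth) {
  while (!is.na(b) && depth[b] > depth[a]) b <- parent[b]
  identical(a, b)
}

# path from ancestor `top` down to `bottom`, inclusive of both ends
#' @keywords internal
path_down <- function(top, bottom, parent) {
  p <- bottom
  out <- p
  while (p != top) {
    p <- parent[p]
    if (is.na(p)) stop("path_down: 'top' is not an ancestor of 'bottom'")
    out <- c(p, out)
  }
  out
}

# small bundle of precomputed species-tree lookups used by several modules
#' @keywords internal
species_index <- function(species_tree) {
  list(tree = species_tree,
       parent = parent_vec(species_tree),
       kids = children_list(species_tree),
       depth = depth_vec(species_tree),
       labels = node_labels(species_tree),
       id_of = label_to_id(species_tree),
       root = root_node(species_tree))
}
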