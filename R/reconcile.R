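# Gene-tree / species-tree reconciliation under weighted duplication-
# loss parsimony. The LCA mapping assigns each gene node to the last
# common species-tree ancestor of its descendant leaves' species; an
# internal node is a duplication (D) when it maps to the same species
# node as one of its children, a speciation (S) otherwise. Losses are
# counted from species-tree path lengths between mapped nodes:
#   S node at s, child mapped u:  pathlen(s, u) - 1
#   D node at s, child mapped u:  pathlen(s, u)
# (undated convention: duplications are "at" species nodes). LCA
# parsimony is simultaneously optimal for duplications and losses,
# which the test suite verifies against exhaustive history enumeration.

#' Resolve gene-tree polytomies at random
#'
#' Multifurcations are replaced by random binary resolutions with
#' zero-length branches (via [ape::multi2di()]), deterministically for a
#' fixed seed. Resolution is random, not DL-optimal -- mirroring the use
#' of an automatic resolver upstream of reconciliation.
#'
#' @param gene_tree A `phylo`, possibly multifurcating.
#' @param seed Optional integer seed.
#' @return A binary `phylo` with the same leaf set.
#' @export
resolve_polytomies <- function(gene_tree, seed = NULL) {
  stopifnot(inherits(gene_tree, "phylo"))
  if (ape::is.binary(gene_tree)) return(gene_tree)
  if (!is.null(seed)) set.seed(seed)
  ape::multi2di(gene_tree, random = TRUE)
}

#' Duplication/loss cost weights
#' @param c_d Cost per duplication (> 0).
#' @param c_l Cost per loss (>= 0).
#' @return An object of class `cost_weights`.
#' @export
cost_weights <- function(c_d = 1, c_l = 1) {
  stopifnot(c_d > 0, c_l >= 0)
  structure(list(c_d = c_d, c_l = c_l), class = "cost_weights")
}

#' LCA mapping of a gene tree into a species tree
#'
#' @param gene_tree Rooted binary `phylo` gene tree.
#' @param species_tree Validated species tree.
#' @param leaf_map Named character vector leaf label -> species label
#'   (see [leaf_species_map()]).
#' @return Integer vector: for every gene-tree node (ape numbering), the
#'   species-tree node id it maps to.
#' @export
lca_map <- function(gene_tree, species_tree, leaf_map) {
  stopifnot(inherits(gene_tree, "phylo"))
  if (length(gene_tree$tip.label) >= 2L &&
      (!ape::is.rooted(gene_tree) || !ape::is.binary(gene_tree))) {
    stop("gene tree must be rooted and binary; see resolve_polytomies()/root_by_dl()")
  }
  sx <- species_index(species_tree)
  unmapped <- setdiff(gene_tree$tip.label, names(leaf_map))
  if (length(unmapped)) stop("unmapped gene leaves: ",
                             paste(unmapped, collapse = ", "))
  ng <- n_nodes(gene_tree)
  M <- integer(ng)
  kids <- children_list(gene_tree)
  for (v in postorder_ids(gene_tree)) {
    if (v <= length(gene_tree$tip.label)) {
      M[v] <- sx$id_of[[leaf_map[[gene_tree$tip.label[v]]]]]
    } else {
      ch <- kids[[v]]
      m <- M[ch[1]]
      for (c0 in ch[-1]) m <- lca_pair(m, M[c0], sx$parent, sx$depth)
      M[v] <- m
    }
  }
  M
}

#' Label S/D events and count losses
#'
#' @param gene_tree Rooted binary gene tree.
#' @param M LCA mapping from [lca_map()] (recomputed if NULL).
#' @param species_tree Validated species tree.
#' @param leaf_map Leaf-to-species map (needed when `M` is NULL and kept
#'   for serialisation).
#' @param weights A [cost_weights()] object.
#' @return An object of class `dl_reconciliation`: gene/species trees,
#'   mapping `M`, `event` per gene node ("S"/"D"/"leaf"), per-gene-edge
#'   loss counts, per-species-edge loss counts (`losses_on_edge`,
#'   indexed by the species child node), totals and DL cost.
#' @export
label_events <- function(gene_tree, M = NULL, species_tree, leaf_map,
                         weights = cost_weights()) {
  if (is.null(M)) M <- lca_map(gene_tree, species_tree, leaf_map)
  sx <- species_index(species_tree)
  ntip_g <- length(gene_tree$tip.label)
  ng <- n_nodes(gene_tree)
  kids <- children_list(gene_tree)

  event <- rep("leaf", ng)
  losses_gene_edge <- numeric(ng)      # losses charged to the edge into node
  losses_on_edge <- stats::setNames(integer(n_nodes(species_tree)),
                                    sx$labels)  # by species child node
  for (v in seq_len(ng)) {
    if (v <= ntip_g) next
    ch <- kids[[v]]
    if (length(ch) == 1L) {            # unary root of a single-gene family
      event[v] <- "S"
      next
    }
    is_dup <- any(M[ch] == M[v])
    event[v] <- if (is_dup) "D" else "S"
    for (c0 in ch) {
      path <- path_down(M[v], M[c0], sx$parent)
      k <- length(path) - 1L           # pathlen(M[v], M[c0])
      losses_gene_edge[c0] <- if (is_dup) k else max(0L, k - 1L)
      # the lineage passes through the species nodes in `thru`; at each,
      # the child edge off the path receives one loss
      thru <- if (is_dup) path[-length(path)] else {
        if (length(path) > 2L) path[-c(1L, length(path))] else integer(0)
      }
      for (x in thru) {
        off <- setdiff(sx$kids[[x]], path)
        losses_on_edge[off] <- losses_on_edge[off] + 1L
      }
    }
  }
  n_dup <- sum(event == "D")
  n_loss <- sum(losses_gene_edge)
  structure(list(gene_tree = gene_tree, species_tree = species_tree,
                 leaf_map = leaf_map, M = M, event = event,
                 losses_gene_edge = losses_gene_edge,
                 losses_on_edge = losses_on_edge,
                 n_dup = n_dup, n_loss = n_loss, weights = weights,
                 cost = weights$c_d * n_dup + weights$c_l * n_loss),
            class = "dl_reconciliation")
}

#' @export
print.dl_reconciliation <- function(x, ...) {
  cat("<dl_reconciliation:", length(x$gene_tree$tip.label), "genes,",
      x$n_dup, "duplications,", x$n_loss, "losses, cost", x$cost, ">\n")
  invisible(x)
}

#' Reconcile a rooted gene tree against a species tree
#'
#' Convenience wrapper: LCA mapping plus event labelling.
#'
#' @inheritParams label_events
#' @return A `dl_reconciliation`.
#' @export
reconcile <- function(gene_tree, species_tree, leaf_map,
                      weights = cost_weights()) {
  M <- lca_map(gene_tree, species_tree, leaf_map)
  label_events(gene_tree, M, species_tree, leaf_map, weights)
}

#' Weighted DL cost of a reconciliation
#' @param reconciliation A `dl_reconciliation`.
#' @param weights A [cost_weights()] object.
#' @return c_d * duplications + c_l * losses.
#' @export
dl_cost <- function(reconciliation, weights = cost_weights()) {
  weights$c_d * reconciliation$n_dup + weights$c_l * reconciliation$n_loss
}

#' Root an unrooted gene tree by minimising the DL cost
#'
#' Every branch of the unrooted tree is evaluated as a root position;
#' the rooting of minimal weighted DL cost is returned. Ties among
#' co-optimal root branches are broken deterministically: the branch
#' whose smaller side's smallest leaf label is lexicographically least
#' wins (then by the other side's smallest label).
#'
#' @param gene_tree Unrooted (or rooted; re-evaluated anyway) `phylo`
#'   with >= 2 leaves, binary apart from the basal trifurcation.
#' @param species_tree Validated species tree.
#' @param leaf_map Leaf-to-species map.
#' @param weights A [cost_weights()] object.
#' @return List: `tree` (rooted `phylo`), `reconciliation`
#'   (`dl_reconciliation` at the optimum), `cost`, and `co_optimal`
#'   (data frame describing every cost-minimal root branch).
#' @export
root_by_dl <- function(gene_tree, species_tree, leaf_map,
                       weights = cost_weights()) {
  stopifnot(inherits(gene_tree, "phylo"))
  ntip <- length(gene_tree$tip.label)
  if (ntip < 2L) stop("need at least 2 leaves")
  if (ntip == 2L) {
    tr <- gene_tree
    return(list(tree = tr, reconciliation = reconcile(tr, species_tree,
                                                      leaf_map, weights),
                cost = reconcile(tr, species_tree, leaf_map, weights)$cost,
                co_optimal = data.frame(branch = 1L)))
  }
  utree <- if (ape::is.rooted(gene_tree)) ape::unroot(gene_tree) else gene_tree
  if (!ape::is.binary(utree)) {
    stop("resolve polytomies before rooting (resolve_polytomies())")
  }
  results <- vector("list", nrow(utree$edge))
  for (i in seq_len(nrow(utree$edge))) {
    rt <- root_at_edge(utree, i)
    rec <- reconcile(rt, species_tree, leaf_map, weights)
    # deterministic tie-break key from the two leaf sides of the branch
    kids <- children_list(rt)
    side1 <- tips_under(rt, kids[[root_node(rt)]][1])
    side2 <- tips_under(rt, kids[[root_node(rt)]][2])
    s1 <- rt$tip.label[side1]; s2 <- rt$tip.label[side2]
    small <- if (length(s1) < length(s2) ||
                 (length(s1) == length(s2) && min(s1) <= min(s2))) s1 else s2
    other <- if (identical(small, s1)) s2 else s1
    results[[i]] <- list(tree = rt, rec = rec, cost = rec$cost,
                         key = c(min(small), min(other)))
  }
  costs <- vapply(results, `[[`, 0, "cost")
  best <- which(costs == min(costs))
  keys <- t(vapply(results[best], `[[`, character(2), "key"))
  ord <- order(keys[, 1], keys[, 2])
  winner <- results[[best[ord[1]]]]
  list(tree = winner$tree, reconciliation = winner$rec, cost = winner$cost,
       co_optimal = data.frame(branch = best,
                               small_side_min = keys[, 1],
                               other_side_min = keys[, 2],
                               cost = costs[best]))
}

# root an unrooted binary phylo at edge i (placing a degree-2 root in
# the middle of the edge, halving its length)
#' @keywords internal
root_at_edge <- function(utree, i) {
  ntip <- length(utree$tip.label)
  nn <- n_nodes(utree)
  lens <- if (is.null(utree$edge.length)) rep(NA_real_, nrow(utree$edge)) else
    utree$edge.length
  # adjacency with edge lengths
  adj <- vector("list", nn)
  for (k in seq_len(nrow(utree$edge))) {
    a <- utree$edge[k, 1]; b <- utree$edge[k, 2]
    adj[[a]] <- rbind(adj[[a]], c(b, lens[k]))
    adj[[b]] <- rbind(adj[[b]], c(a, lens[k]))
  }
  u <- utree$edge[i, 1]; v <- utree$edge[i, 2]; lw <- lens[i]
  build <- function(node, from) {
    nbrs <- adj[[node]]
    ch <- list()
    if (!is.null(nbrs)) {
      for (r in seq_len(nrow(nbrs))) {
        nb <- nbrs[r, 1]
        if (nb == from) next
        sub <- build(nb, node)
        sub$length <- nbrs[r, 2]
        ch[[length(ch) + 1L]] <- sub
      }
    }
    if (length(ch) == 0L) {
      list(label = utree$tip.label[node], length = NA_real_,
           comment = NA_character_, children = list())
    } else {
      list(label = "", length = NA_real_, comment = NA_character_,
           children = ch)
    }
  }
  left <- build(u, v); left$length <- if (is.na(lw)) NA_real_ else lw / 2
  right <- build(v, u); right$length <- if (is.na(lw)) NA_real_ else lw / 2
  nested_to_phylo(list(label = "", length = NA_real_,
                       comment = NA_character_,
                       children = list(left, right)))
}

#' @keywords internal
tips_under <- function(tree, node) {
  ntip <- length(tree$tip.label)
  kids <- children_list(tree)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (v <= ntip) out <- c(out, v) else stack <- c(stack, kids[[v]])
  }
  sort(out)
}

#' Serialise a reconciliation as NHX-annotated Newick
#'
#' Internal nodes carry `[&&NHX:Ev=S|D:Sp=<species label>]` blocks;
#' leaves carry their mapped species. The output round-trips through
#' [parse_newick()] with annotations preserved.
#'
#' @param reconciliation A `dl_reconciliation`.
#' @return A Newick string.
#' @export
reconciliation_to_nhx <- function(reconciliation) {
  rec <- reconciliation
  tr <- rec$gene_tree
  sx_labels <- node_labels(rec$species_tree)
  com <- vapply(seq_len(n_nodes(tr)), function(v) {
    ev <- rec$event[v]
    if (ev == "leaf") {
      sprintf("[&&NHX:Sp=%s]", sx_labels[rec$M[v]])
    } else {
      sprintf("[&&NHX:Ev=%s:Sp=%s]", ev, sx_labels[rec$M[v]])
    }
  }, character(1))
  attr(tr, "node.comment") <- com
  write_newick(tr)
}

#' Summarise a reconciliation as a plain list (for JSON export)
#' @param reconciliation A `dl_reconciliation`.
#' @return A list with event counts, per-species-edge losses and cost.
#' @export
reconciliation_summary <- function(reconciliation) {
  rec <- reconciliation
  list(n_genes = length(rec$gene_tree$tip.label),
       n_dup = rec$n_dup, n_loss = rec$n_loss, cost = rec$cost,
       origin = node_labels(rec$species_tree)[rec$M[root_node(rec$gene_tree)]],
       losses_on_edge = as.list(rec$losses_on_edge[rec$losses_on_edge > 0]))
}
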