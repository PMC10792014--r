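# Fixtures and independent oracles shared across the suite. Oracles
# deliberately use different algorithms (and, where possible, different
# libraries) than the implementation they check.

fixture_species_tree <- function() {
  tr <- parse_newick(readLines(example_species_tree(), warn = FALSE)[1],
                     expect_rooted = TRUE)
  validate_species_tree(tr, require_lengths = TRUE)
  tr
}

# random labelled species tree with positive lengths and named internals
random_species_tree <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rtree(n, tip.label = paste0("S", seq_len(n)))
  tr$node.label <- paste0("N", seq_len(tr$Nnode))
  tr$edge.length <- tr$edge.length + 0.1
  tr
}

# random gene tree whose leaves are random draws from the species set
random_gene_tree <- function(n_leaves, species, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sp <- sample(species, n_leaves, replace = TRUE)
  labs <- paste0(sp, "_g", seq_len(n_leaves))
  tr <- ape::rtree(n_leaves, tip.label = labs)
  tr
}

# --- brute-force DL reconciliation oracle -------------------------------
# Enumerates every valid mapping M' (M'(v) ancestor-or-equal of the LCA
# of v's leaf species; M'(parent) ancestor-or-equal of M'(child)); for
# each, counts duplications (children not in distinct child subtrees of
# M'(v)) and losses (pathlen - 1 per child for speciations, pathlen for
# duplications). Returns the minima of D, L, and c_d*D + c_l*L.
oracle_dl_min <- function(gene_tree, species_tree, leaf_map,
                          c_d = 1, c_l = 1) {
  sx <- famrecon:::species_index(species_tree)
  kids <- famrecon:::children_list(gene_tree)
  ntip <- length(gene_tree$tip.label)
  po <- famrecon:::postorder_ids(gene_tree)
  lca_of <- integer(famrecon:::n_nodes(gene_tree))
  for (v in po) {
    lca_of[v] <- if (v <= ntip) {
      sx$id_of[[leaf_map[[gene_tree$tip.label[v]]]]]
    } else {
      Reduce(function(a, b) famrecon:::lca_pair(a, b, sx$parent, sx$depth),
             lca_of[kids[[v]]])
    }
  }
  ancestors_of <- function(s) {           # s and all its ancestors
    out <- s
    while (!is.na(sx$parent[out[length(out)]])) {
      out <- c(out, sx$parent[out[length(out)]])
    }
    out
  }
  pathlen <- function(top, bottom) {
    k <- 0L
    while (bottom != top) { bottom <- sx$parent[bottom]; k <- k + 1L }
    k
  }
  in_subtree <- function(a, b) famrecon:::is_ancestor_or_equal(
    a, b, sx$parent, sx$depth)

  best <- c(D = Inf, L = Inf, cost = Inf)
  rootg <- famrecon:::root_node(gene_tree)
  # recursive top-down assignment
  assign_node <- function(v, parent_m, M) {
    cands <- ancestors_of(lca_of[v])
    if (!is.na(parent_m)) {
      cands <- cands[vapply(cands, function(s)
        famrecon:::is_ancestor_or_equal(parent_m, s, sx$parent, sx$depth),
        logical(1))]
    }
    if (v <= ntip) cands <- lca_of[v]  # leaves are fixed
    out <- list()
    for (m in cands) {
      M2 <- M; M2[v] <- m
      subs <- list(M2)
      for (c0 in kids[[v]]) {
        subs <- do.call(c, lapply(subs, function(Mi) assign_node(c0, m, Mi)))
      }
      out <- c(out, subs)
    }
    out
  }
  all_M <- assign_node(rootg, NA_integer_,
                       integer(famrecon:::n_nodes(gene_tree)))
  for (M in all_M) {
    D <- 0L; L <- 0L
    for (v in seq_along(M)) {
      if (v <= ntip || length(kids[[v]]) == 0L) next
      ch <- kids[[v]]
      # speciation iff the children map into distinct child subtrees
      sides <- vapply(ch, function(c0) {
        if (M[c0] == M[v]) return(NA_integer_)
        x <- M[c0]
        while (sx$parent[x] != M[v]) x <- sx$parent[x]
        x
      }, integer(1))
      is_spec <- !anyNA(sides) && length(unique(sides)) == length(sides)
      if (!is_spec) D <- D + 1L
      for (c0 in ch) {
        k <- pathlen(M[v], M[c0])
        L <- L + if (is_spec) k - 1L else k
      }
    }
    cost <- c_d * D + c_l * L
    best["D"] <- min(best["D"], D)
    best["L"] <- min(best["L"], L)
    best["cost"] <- min(best["cost"], cost)
  }
  best
}

# --- transfer-distance oracle -------------------------------------------
# For a reference split (tip-label set A on one side), the minimum over
# all replicate branches (trivial ones included) of the smaller
# symmetric-difference size, computed with plain set operations on
# ape::prop.part output.
oracle_transfer <- function(side_labels, replicate) {
  tips <- replicate$tip.label
  n <- length(tips)
  pp <- ape::prop.part(replicate)
  clades <- lapply(pp, function(ix) attr(pp, "labels")[ix])
  clades <- c(clades, as.list(tips))          # trivial splits
  best <- Inf
  A <- side_labels
  for (X in clades) {
    inter <- length(intersect(A, X))
    h <- length(A) + length(X) - 2L * inter   # |A delta X|
    best <- min(best, h, n - h)
  }
  best
}

# --- connected-components oracle (hand-rolled union-find) ---------------
oracle_components <- function(graph, threshold) {
  ids <- graph$vertices$id
  idx <- stats::setNames(seq_along(ids), ids)
  par <- seq_along(ids)
  find <- function(i) { while (par[i] != i) i <- par[i]; i }
  e <- graph$edges[graph$edges$p <= threshold, , drop = FALSE]
  for (i in seq_len(nrow(e))) {
    a <- find(idx[[e$v1[i]]]); b <- find(idx[[e$v2[i]]])
    if (a != b) par[a] <- b
  }
  roots <- vapply(seq_along(ids), find, 0L)
  stats::setNames(match(roots, unique(roots)), ids)
}

# same partition up to label permutation?
same_partition <- function(a, b) {
  b <- b[names(a)]
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(paste(a, b))) == length(unique(b))
}

oracle_merge_threshold <- function(graph, setA, setB) {
  for (t in sort(unique(graph$edges$p))) {
    memb <- oracle_components(graph, t)
    if (length(intersect(memb[setA], memb[setB]))) return(t)
  }
  NA_real_
}

# random similarity graph on nv vertices
random_similarity_graph <- function(nv, n_edges, seed) {
  set.seed(seed)
  ids <- sprintf("v%02d", seq_len(nv))
  pairs <- t(utils::combn(nv, 2))
  take <- sample(nrow(pairs), min(n_edges, nrow(pairs)))
  edges <- data.frame(v1 = ids[pairs[take, 1]], v2 = ids[pairs[take, 2]],
                      p = 10^(-stats::runif(length(take), 0, 30)))
  similarity_graph(data.frame(id = ids), edges)
}
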