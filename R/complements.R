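# Ancestral gene-complement reconstruction from reconciliations:
# per-species-node copy numbers, family origin nodes, orthogroup
# delineation by duplication-node cutting, presence/absence matrices,
# and per-node duplication bursts.
#
# Lineage-propagation convention: N(s) counts gene lineages present at
# species node s *after* applying duplications mapped at s and losses
# on the edge into s; hence N(origin) = 1 + duplications mapped at the
# origin node and N(leaf) equals the observed gene count. Each gene-
# tree edge (u, v) contributes one lineage to every species node on the
# path M(u)..M(v), including M(u) only when u is a duplication and
# excluding M(v) only when v is a duplication (whose own children then
# cover M(v)).

#' Per-species-node gene copy numbers for one family
#'
#' @param reconciliation A `dl_reconciliation`.
#' @return Named integer vector over all species-tree nodes (labelled);
#'   0 outside the family's origin subtree.
#' @export
copy_numbers <- function(reconciliation) {
  rec <- reconciliation
  sx <- species_index(rec$species_tree)
  counts <- stats::setNames(integer(n_nodes(rec$species_tree)), sx$labels)
  tr <- rec$gene_tree
  rootg <- root_node(tr)
  if (rec$event[rootg] != "D") counts[rec$M[rootg]] <- 1L
  for (i in seq_len(nrow(tr$edge))) {
    u <- tr$edge[i, 1]; v <- tr$edge[i, 2]
    path <- path_down(rec$M[u], rec$M[v], sx$parent)
    if (rec$event[u] != "D") path <- path[-1L]
    if (length(path) && rec$event[v] == "D") path <- path[-length(path)]
    if (length(path)) counts[path] <- counts[path] + 1L
  }
  counts
}

#' Species-tree origin node of a family
#'
#' The species node to which the gene-tree root maps -- where the
#' family first appears under the parsimony reconstruction.
#'
#' @param reconciliation A `dl_reconciliation`.
#' @return The origin node's label.
#' @export
origin_node <- function(reconciliation) {
  rec <- reconciliation
  if (is.null(rec$gene_tree) || length(rec$gene_tree$tip.label) == 0L) {
    stop("empty/extinct family has no origin")
  }
  node_labels(rec$species_tree)[rec$M[root_node(rec$gene_tree)]]
}

#' Cut a reconciled gene tree into orthogroups
#'
#' Orthogroups are the maximal subtrees related by speciation only,
#' obtained by cutting the gene tree at every duplication node
#' (optionally only at duplications mapped at or above `cut_above`).
#' Each group is named by the gene token(s) of its reference-species
#' members (sorted, "/"-joined), else "unnamed-<k>" in preorder.
#'
#' @param reconciliation A `dl_reconciliation`.
#' @param reference_species Character vector of species labels whose
#'   gene names are used for naming (e.g. human and mouse).
#' @param cut_above Optional species node label: only duplications
#'   mapped at that node or its ancestors split groups.
#' @param separator,position Leaf-naming convention used to extract the
#'   gene token (see [leaf_species_map()]).
#' @return An object of class `orthogroup_assignment`: list with
#'   `assignment` (named character vector gene leaf -> orthogroup name)
#'   and `groups` (list of leaf-label vectors).
#' @export
orthogroups <- function(reconciliation, reference_species = character(0),
                        cut_above = NULL, separator = "_",
                        position = c("prefix", "suffix")) {
  position <- match.arg(position)
  rec <- reconciliation
  sx <- species_index(rec$species_tree)
  miss <- setdiff(reference_species, sx$labels)
  if (length(miss)) stop("unknown reference species: ",
                         paste(miss, collapse = ", "))
  tr <- rec$gene_tree
  ntip <- length(tr$tip.label)
  kids <- children_list(tr)

  cuts <- rec$event == "D"
  if (!is.null(cut_above)) {
    anchor <- sx$id_of[[cut_above]]
    if (is.null(anchor)) stop("unknown species node: ", cut_above)
    ok <- vapply(seq_along(cuts), function(v) {
      cuts[v] && is_ancestor_or_equal(rec$M[v], anchor, sx$parent, sx$depth)
    }, logical(1))
    cuts <- ok
  }

  # preorder walk: entering a cut node starts a new group per child
  groups <- list()
  collect <- function(v, gid) {
    if (cuts[v]) {
      for (c0 in kids[[v]]) {
        gid2 <- length(groups) + 1L
        groups[[gid2]] <<- character(0)
        collect(c0, gid2)
      }
    } else if (v <= ntip) {
      groups[[gid]] <<- c(groups[[gid]], tr$tip.label[v])
    } else {
      for (c0 in kids[[v]]) collect(c0, gid)
    }
  }
  rootg <- root_node(tr)
  if (!cuts[rootg]) groups[[1]] <- character(0)
  collect(rootg, 1L)
  groups <- Filter(length, groups)

  sp_of <- rec$leaf_map
  names_out <- character(length(groups))
  unnamed <- 0L
  for (k in seq_along(groups)) {
    leaves <- groups[[k]]
    ref <- leaves[sp_of[leaves] %in% reference_species]
    if (length(ref)) {
      names_out[k] <- paste(sort(unique(gene_token(ref, separator, position))),
                            collapse = "/")
    } else {
      unnamed <- unnamed + 1L
      names_out[k] <- paste0("unnamed-", unnamed)
    }
  }
  # disambiguate identically named groups deterministically
  dup <- duplicated(names_out) | duplicated(names_out, fromLast = TRUE)
  if (any(dup)) {
    for (nm in unique(names_out[dup])) {
      at <- which(names_out == nm)
      names_out[at] <- paste0(nm, ".", seq_along(at))
    }
  }
  assignment <- character(0)
  for (k in seq_along(groups)) {
    assignment[groups[[k]]] <- names_out[k]
  }
  structure(list(assignment = assignment,
                 groups = stats::setNames(groups, names_out)),
            class = "orthogroup_assignment")
}

#' Presence/absence matrix of orthogroups across species
#'
#' @param assignments List of `orthogroup_assignment` (or a single one).
#' @param species Character vector of extant species (rows).
#' @param leaf_maps List of leaf-to-species maps matching
#'   `assignments`; when NULL, species are parsed from leaf labels with
#'   the default convention.
#' @param separator,position Leaf-naming convention fallback.
#' @return Logical matrix species x orthogroup.
#' @export
presence_matrix <- function(assignments, species, leaf_maps = NULL,
                            separator = "_",
                            position = c("prefix", "suffix")) {
  position <- match.arg(position)
  if (inherits(assignments, "orthogroup_assignment")) {
    assignments <- list(assignments)
  }
  cols <- unique(unlist(lapply(assignments, function(a) names(a$groups))))
  mat <- matrix(FALSE, nrow = length(species), ncol = length(cols),
                dimnames = list(species, cols))
  for (k in seq_along(assignments)) {
    a <- assignments[[k]]
    lm <- if (!is.null(leaf_maps)) leaf_maps[[k]] else NULL
    for (g in names(a$groups)) {
      leaves <- a$groups[[g]]
      sp <- if (!is.null(lm)) unname(lm[leaves]) else {
        vapply(strsplit(leaves, separator, fixed = TRUE), function(p) {
          if (position == "prefix") p[[1]] else p[[length(p)]]
        }, character(1))
      }
      sp <- intersect(sp, species)
      mat[sp, g] <- TRUE
    }
  }
  mat
}

#' Per-node duplication counts across families
#'
#' For every species-tree node: total duplications mapped there across
#' the supplied reconciliations, paired with the complement delta
#' N(node) - N(parent). Localised peaks are the duplication bursts.
#'
#' @param reconciliations List of `dl_reconciliation` over the same
#'   species tree.
#' @return Data frame: node, n_dup, delta_N.
#' @export
duplication_bursts <- function(reconciliations) {
  if (inherits(reconciliations, "dl_reconciliation")) {
    reconciliations <- list(reconciliations)
  }
  stopifnot(length(reconciliations) >= 1)
  sp <- reconciliations[[1]]$species_tree
  sx <- species_index(sp)
  nd <- stats::setNames(integer(n_nodes(sp)), sx$labels)
  dN <- stats::setNames(numeric(n_nodes(sp)), sx$labels)
  for (rec in reconciliations) {
    stopifnot(inherits(rec, "dl_reconciliation"))
    dup_nodes <- rec$M[rec$event == "D"]
    if (length(dup_nodes)) {
      tab <- table(dup_nodes)
      nd[as.integer(names(tab))] <- nd[as.integer(names(tab))] + as.integer(tab)
    }
    N <- copy_numbers(rec)
    for (v in seq_along(N)) {
      p <- sx$parent[v]
      dN[v] <- dN[v] + if (is.na(p)) 0 else N[v] - N[p]
    }
  }
  data.frame(node = sx$labels, n_dup = as.integer(nd), delta_N = dN,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Complement table over families
#'
#' @param reconciliations Named list of `dl_reconciliation`.
#' @return Integer matrix: species-tree nodes x families.
#' @export
complement_table <- function(reconciliations) {
  stopifnot(length(reconciliations) >= 1)
  cols <- lapply(reconciliations, copy_numbers)
  mat <- do.call(cbind, cols)
  colnames(mat) <- if (!is.null(names(reconciliations)))
    names(reconciliations) else paste0("fam", seq_along(reconciliations))
  mat
}

#' Aggregate complement-table columns into named groups
#'
#' @param table Matrix from [complement_table()] (nodes x families).
#' @param group_map Named character vector family -> group; every
#'   column must be assigned.
#' @return Matrix nodes x groups with summed counts.
#' @export
aggregate_groups <- function(table, group_map) {
  miss <- setdiff(colnames(table), names(group_map))
  if (length(miss)) stop("families not assigned to a group: ",
                         paste(miss, collapse = ", "))
  groups <- unique(unname(group_map[colnames(table)]))
  out <- sapply(groups, function(g) {
    cols <- colnames(table)[group_map[colnames(table)] == g]
    rowSums(table[, cols, drop = FALSE])
  })
  out <- as.matrix(out)
  colnames(out) <- groups
  out
}
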