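# Branch support from replicate trees: Transfer Bootstrap Expectation
# (TBE) and the classical (Felsenstein) bootstrap proportion (FBP),
# plus the traffic-light classification used in figure annotation.
#
# A bipartition is the two-way leaf split induced by an internal
# branch, stored as a logical membership vector over the sorted leaf
# set, canonically oriented so the first leaf is FALSE. The transfer
# index of a reference bipartition b against a replicate tree T* is
# delta = min over branches b* of T* of the number of leaves that must
# be moved to turn b* into b (the orientation-minimal Hamming
# distance), capped at p - 1 where p is the lighter side of b; this cap
# is attained by trivial (leaf) branches. TBE averages 1 - delta/(p-1)
# over replicates; FBP is the fraction of replicates where delta = 0.

#' Non-trivial bipartitions of a tree
#'
#' One bipartition per internal branch; trivial (single-leaf) splits
#' are excluded. Rooted input gives the same set as its unrooted
#' version (the root branch is collapsed).
#'
#' @param tree A `phylo`.
#' @return List of class `bipartition_set`: each element a logical
#'   membership vector over `attr(, "leaves")` (sorted leaf labels),
#'   with the split's lighter-side size in attribute `p`.
#' @export
bipartitions <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  leaves <- sort(tree$tip.label)
  ntip <- length(leaves)
  out <- list()
  if (ntip >= 4L) {
    tip_idx <- match(tree$tip.label, leaves)
    kids <- children_list(tree)
    rootn <- root_node(tree)
    masks <- vector("list", n_nodes(tree))
    for (v in postorder_ids(tree)) {
      if (v <= length(tree$tip.label)) {
        m <- logical(ntip); m[tip_idx[v]] <- TRUE
      } else {
        m <- Reduce(`|`, masks[kids[[v]]])
      }
      masks[[v]] <- m
      if (v == rootn || v <= length(tree$tip.label)) next
      out[[length(out) + 1L]] <- m
    }
    # canonical orientation + drop trivial/degenerate splits, dedupe
    # (a rooted tree's two root-child branches induce the same split)
    canon <- lapply(out, function(m) if (m[1]) !m else m)
    sizes <- vapply(canon, sum, 0L)
    keep <- sizes >= 2L & sizes <= ntip - 2L
    canon <- canon[keep]
    key <- vapply(canon, function(m) paste(as.integer(m), collapse = ""),
                  character(1))
    canon <- canon[!duplicated(key)]
    out <- lapply(canon, function(m) {
      attr(m, "p") <- min(sum(m), ntip - sum(m))
      m
    })
  }
  structure(out, leaves = leaves, class = "bipartition_set")
}

#' Transfer index of a bipartition against a replicate tree
#'
#' @param bip One element of a [bipartitions()] set (logical vector
#'   with a `p` attribute), over leaf set `leaves`.
#' @param tree Replicate `phylo` with the identical leaf set.
#' @param leaves Sorted leaf labels the membership vector refers to.
#' @return Integer delta in [0, p - 1]; 0 iff the bipartition occurs in
#'   the replicate.
#' @export
transfer_index <- function(bip, tree, leaves) {
  if (!setequal(tree$tip.label, leaves) ||
      length(tree$tip.label) != length(leaves)) {
    stop("replicate leaf set differs from the reference leaf set")
  }
  p <- attr(bip, "p")
  reps <- bipartitions(tree)
  best <- p - 1L                      # attained by trivial branches
  for (b in reps) {
    h <- sum(bip != b)
    best <- min(best, h, length(leaves) - h)
  }
  as.integer(best)
}

#' Transfer Bootstrap Expectation supports
#'
#' @param ref_tree Reference `phylo` (>= 4 leaves).
#' @param replicates List of replicate `phylo` trees with the same leaf
#'   set (e.g. nonparametric bootstrap trees).
#' @return Data frame of class `branch_support`: one row per internal
#'   branch of the reference, with columns `branch` (index into
#'   `bipartitions(ref_tree)`), `p`, and `tbe` in [0, 1].
#' @export
tbe <- function(ref_tree, replicates) {
  sup <- support_raw(ref_tree, replicates)
  data.frame(branch = seq_along(sup$p), p = sup$p,
             tbe = rowMeans(1 - sup$delta / (sup$p - 1 + (sup$p == 1))),
             row.names = NULL)
}

#' Felsenstein bootstrap proportions
#'
#' Fraction of replicates containing each reference bipartition
#' exactly. Stand-in for inference-time resampling supports (e.g. UFB)
#' when only replicate trees are available.
#'
#' @inheritParams tbe
#' @return Data frame: branch, p, fbp in [0, 1].
#' @export
fbp <- function(ref_tree, replicates) {
  sup <- support_raw(ref_tree, replicates)
  data.frame(branch = seq_along(sup$p), p = sup$p,
             fbp = rowMeans(sup$delta == 0L), row.names = NULL)
}

#' TBE and FBP side by side
#' @inheritParams tbe
#' @return Data frame: branch, p, tbe, fbp.
#' @export
branch_supports <- function(ref_tree, replicates) {
  sup <- support_raw(ref_tree, replicates)
  data.frame(branch = seq_along(sup$p), p = sup$p,
             tbe = rowMeans(1 - sup$delta / (sup$p - 1 + (sup$p == 1))),
             fbp = rowMeans(sup$delta == 0L), row.names = NULL)
}

# delta matrix: reference branches x replicates
#' @keywords internal
support_raw <- function(ref_tree, replicates) {
  if (inherits(replicates, "phylo")) replicates <- list(replicates)
  if (!length(replicates)) stop("at least one replicate tree is required")
  bips <- bipartitions(ref_tree)
  if (!length(bips)) stop("reference tree has no non-trivial branch")
  leaves <- attr(bips, "leaves")
  delta <- matrix(0L, nrow = length(bips), ncol = length(replicates))
  for (j in seq_along(replicates)) {
    rep_bips <- bipartitions(replicates[[j]])
    if (!setequal(replicates[[j]]$tip.label, leaves) ||
        length(replicates[[j]]$tip.label) != length(leaves)) {
      stop("replicate ", j, " leaf set differs from the reference")
    }
    for (i in seq_along(bips)) {
      p <- attr(bips[[i]], "p")
      best <- p - 1L
      for (b in rep_bips) {
        h <- sum(bips[[i]] != b)
        best <- min(best, h, length(leaves) - h)
      }
      delta[i, j] <- best
    }
  }
  list(p = vapply(bips, attr, 0L, "p"), delta = delta, bips = bips)
}

#' Traffic-light classification of branch support
#'
#' @param value Support values, either proportions in [0, 1] or
#'   percentages in [0, 100] (set `percent = TRUE`).
#' @param scheme Named thresholds `c(high = , intermediate = )` on the
#'   [0, 1] scale; defaults 0.90 / 0.70 are module configuration, not a
#'   published convention.
#' @param percent Interpret `value` (and thresholds x 100) on the
#'   percentage scale.
#' @return Factor with levels low/intermediate/high.
#' @export
classify_support <- function(value, scheme = c(high = 0.90,
                                               intermediate = 0.70),
                             percent = FALSE) {
  stopifnot(all(c("high", "intermediate") %in% names(scheme)))
  hi <- if (percent) scheme[["high"]] * 100 else scheme[["high"]]
  mid <- if (percent) scheme[["intermediate"]] * 100 else
    scheme[["intermediate"]]
  top <- if (percent) 100 else 1
  if (any(is.na(value)) || any(value < 0) || any(value > top)) {
    stop("support values out of range [0, ", top, "]")
  }
  cls <- ifelse(value >= hi, "high",
                ifelse(value >= mid, "intermediate", "low"))
  factor(cls, levels = c("low", "intermediate", "high"))
}
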