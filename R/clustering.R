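# Homology-group delineation from pairwise similarity, CLANS-style:
# connected components of the similarity graph at graduated P-value
# stringency thresholds, plus bottleneck ("merge") threshold queries
# between clusters and a seeded 2D force-directed layout for inspection.

#' Construct a similarity graph
#'
#' @param vertices Data frame with at least an `id` column; optional
#'   annotation columns (`species`, `family`, ...) are kept.
#' @param edges Data frame with columns `v1`, `v2` and either `p`
#'   (P-value in (0,1]) or `score` (-log10 P).
#' @return An object of class `similarity_graph`.
#' @export
similarity_graph <- function(vertices, edges) {
  vertices <- as.data.frame(vertices)
  edges <- as.data.frame(edges)
  stopifnot("id" %in% names(vertices), all(c("v1", "v2") %in% names(edges)))
  if (anyDuplicated(vertices$id)) stop("duplicate vertex ids")
  if (is.null(edges$p)) edges$p <- 10^(-edges$score)
  edges$p <- pmin(edges$p, 1)
  if (nrow(edges) && any(edges$p <= 0)) stop("edge P-values must be in (0,1]")
  edges$score <- -log10(edges$p)
  if (nrow(edges) && any(edges$v1 == edges$v2)) stop("self-edges not allowed")
  unknown <- setdiff(unique(c(edges$v1, edges$v2)), vertices$id)
  if (length(unknown)) stop("edges reference unknown vertices: ",
                            paste(utils::head(unknown, 5), collapse = ", "))
  key <- paste(pmin(edges$v1, edges$v2), pmax(edges$v1, edges$v2))
  if (anyDuplicated(key)) stop("at most one edge per unordered pair")
  structure(list(vertices = vertices, edges = edges),
            class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat("<similarity_graph:", nrow(x$vertices), "vertices,",
      nrow(x$edges), "edges>\n")
  invisible(x)
}

#' Build a similarity graph from BLAST tabular pairs
#'
#' Reads a 12-column BLAST outfmt-6-like TSV (or an equivalent data
#' frame); columns 1 (query id), 2 (subject id) and 11 (E-value) are
#' consumed. E-values are treated as P-value surrogates after capping at
#' 1. Self-hits are dropped; asymmetric A->B / B->A pairs collapse per
#' `dedup_policy`.
#'
#' @param pairs Path to a TSV file, or a data frame.
#' @param dedup_policy How to collapse duplicate unordered pairs:
#'   "min" (most significant, default), "max", or "mean" of P-values.
#' @return A `similarity_graph`.
#' @export
build_graph <- function(pairs, dedup_policy = c("min", "max", "mean")) {
  dedup_policy <- match.arg(dedup_policy)
  if (is.character(pairs)) {
    pairs <- utils::read.delim(pairs, header = FALSE,
                               stringsAsFactors = FALSE)
  }
  if (ncol(pairs) < 11L) stop("expected >= 11 columns (BLAST outfmt 6)")
  q <- as.character(pairs[[1]]); s <- as.character(pairs[[2]])
  ev <- suppressWarnings(as.numeric(pairs[[11]]))
  if (anyNA(ev)) {
    stop("unparseable E-value on line(s): ",
         paste(utils::head(which(is.na(ev)), 5), collapse = ", "))
  }
  keep <- q != s
  q <- q[keep]; s <- s[keep]; ev <- pmin(pmax(ev, .Machine$double.xmin), 1)[keep]
  a <- pmin(q, s); b <- pmax(q, s)
  key <- paste(a, b, sep = "\r")
  agg <- switch(dedup_policy,
                min = tapply(ev, key, min),
                max = tapply(ev, key, max),
                mean = tapply(ev, key, mean))
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  edges <- data.frame(v1 = vapply(parts, `[[`, "", 1L),
                      v2 = vapply(parts, `[[`, "", 2L),
                      p = as.numeric(agg), stringsAsFactors = FALSE)
  ids <- sort(unique(c(pairs[[1]], pairs[[2]])))
  similarity_graph(data.frame(id = ids, stringsAsFactors = FALSE), edges)
}

#' Connected components at a P-value threshold
#'
#' Components of the subgraph keeping edges with P <= threshold
#' (equality included); isolated vertices form singleton components.
#' Component ids are deterministic: components are numbered by their
#' lexicographically smallest member.
#'
#' @param graph A `similarity_graph`.
#' @param threshold P-value threshold in (0,1].
#' @return An object of class `similarity_partition`: list with
#'   `threshold` and `membership` (named integer vector).
#' @export
components_at <- function(graph, threshold) {
  stopifnot(inherits(graph, "similarity_graph"),
            threshold > 0, threshold <= 1)
  e <- graph$edges[graph$edges$p <= threshold, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    e[, c("v1", "v2")], directed = FALSE,
    vertices = data.frame(name = graph$vertices$id))
  memb <- igraph::components(g)$membership
  memb <- memb[graph$vertices$id]
  # renumber deterministically by smallest member id
  reps <- tapply(names(memb), memb, min)
  newid <- stats::setNames(rank(reps, ties.method = "first"), names(reps))
  membership <- stats::setNames(as.integer(newid[as.character(memb)]),
                                names(memb))
  structure(list(threshold = threshold, membership = membership),
            class = "similarity_partition")
}

#' @export
print.similarity_partition <- function(x, ...) {
  cat("<similarity_partition: P <=", format(x$threshold),
      "->", max(x$membership), "components over",
      length(x$membership), "vertices>\n")
  invisible(x)
}

#' Strictest threshold at which two clusters merge
#'
#' Returns the smallest P-value threshold t such that some vertex of
#' `setA` and some vertex of `setB` share a connected component at t;
#' this equals the minimax (bottleneck) edge P-value over all A-B paths.
#' Computed by Kruskal-style incremental union-find over edges sorted by
#' increasing P.
#'
#' @param graph A `similarity_graph`.
#' @param setA,setB Disjoint, non-empty vertex id sets.
#' @return The merge P-value, or NA if no path connects the sets.
#' @export
merge_threshold <- function(graph, setA, setB) {
  stopifnot(inherits(graph, "similarity_graph"),
            length(setA) > 0, length(setB) > 0)
  if (length(intersect(setA, setB))) stop("setA and setB must be disjoint")
  ids <- graph$vertices$id
  miss <- setdiff(c(setA, setB), ids)
  if (length(miss)) stop("unknown vertices: ", paste(miss, collapse = ", "))
  idx <- stats::setNames(seq_along(ids), ids)
  parent <- seq_along(ids)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  inA <- ids %in% setA; inB <- ids %in% setB
  e <- graph$edges[order(graph$edges$p), , drop = FALSE]
  connected <- function() {
    rootsA <- unique(vapply(which(inA), find, 0L))
    rootsB <- unique(vapply(which(inB), find, 0L))
    length(intersect(rootsA, rootsB)) > 0L
  }
  if (connected()) return(NA_real_)  # cannot happen: sets disjoint, no edges yet
  for (i in seq_len(nrow(e))) {
    ra <- find(idx[[e$v1[i]]]); rb <- find(idx[[e$v2[i]]])
    if (ra != rb) parent[ra] <- rb
    # check only when the next edge has a strictly larger p, or at the end
    if (i == nrow(e) || e$p[i + 1L] > e$p[i]) {
      if (connected()) return(e$p[i])
    }
  }
  NA_real_
}

#' Partitions along a descending-stringency threshold ladder
#'
#' @param graph A `similarity_graph`.
#' @param thresholds Strictly increasing P-values (strictest, i.e.
#'   smallest, first) -- e.g. `c(1e-35, 1e-15, 1e-6)`.
#' @return A list of `similarity_partition`, one per threshold. Each
#'   stricter partition refines every looser one.
#' @export
threshold_profile <- function(graph, thresholds) {
  stopifnot(length(thresholds) >= 1)
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly increasing (strictest first)")
  }
  lapply(thresholds, function(t) components_at(graph, t))
}

#' Annotate components by majority vote of labelled members
#'
#' Mirrors cluster annotation by reference-species sequences: each
#' component is named by the most frequent non-missing annotation among
#' its members, ties broken lexicographically; components with no
#' annotated member get "unnamed-<k>".
#'
#' @param partition A `similarity_partition`.
#' @param annotations Named character vector vertex id -> annotation
#'   (NA/absent = unannotated).
#' @return Named character vector component id -> annotation.
#' @export
annotate_components <- function(partition, annotations) {
  memb <- partition$membership
  out <- character(max(memb))
  for (k in seq_len(max(memb))) {
    members <- names(memb)[memb == k]
    ann <- annotations[intersect(members, names(annotations))]
    ann <- ann[!is.na(ann)]
    if (length(ann)) {
      tab <- sort(table(ann), decreasing = TRUE)
      best <- names(tab)[tab == max(tab)]
      out[k] <- min(best)
    } else {
      out[k] <- paste0("unnamed-", k)
    }
  }
  stats::setNames(out, seq_len(max(memb)))
}

#' Seeded 2D force-directed layout
#'
#' A deliberately simple layout for eyeballing cluster structure:
#' attraction along edges proportional to the similarity score,
#' uniform pairwise repulsion otherwise. Deterministic for a fixed
#' seed; `iterations = 0` returns the seeded random initial
#' coordinates unchanged. Layout geometry is a visual aid only and is
#' never used by any inference step.
#'
#' @param graph A `similarity_graph`.
#' @param iterations Number of relaxation sweeps (>= 0).
#' @param seed Integer seed for the initial coordinates.
#' @param attraction,repulsion,step Layout constants (module defaults,
#'   not derived from any reference tool).
#' @return A data frame: id, x, y.
#' @export
layout2d <- function(graph, iterations = 500, seed = 1,
                     attraction = 0.01, repulsion = 0.05, step = 0.05) {
  stopifnot(iterations >= 0)
  ids <- graph$vertices$id
  nv <- length(ids)
  set.seed(seed)
  xy <- matrix(stats::runif(2L * nv), ncol = 2L)
  if (iterations > 0 && nv > 1) {
    idx <- stats::setNames(seq_along(ids), ids)
    ei <- cbind(idx[graph$edges$v1], idx[graph$edges$v2])
    w <- graph$edges$score
    for (it in seq_len(iterations)) {
      force <- matrix(0, nrow = nv, ncol = 2L)
      # uniform repulsion
      for (d in 1:2) {
        diff <- outer(xy[, d], xy[, d], "-")
        dist2 <- outer(xy[, 1], xy[, 1], "-")^2 +
          outer(xy[, 2], xy[, 2], "-")^2
        diag(dist2) <- Inf
        force[, d] <- force[, d] + repulsion * rowSums(diff / (dist2 + 1e-9))
      }
      # attraction on edges, proportional to score
      if (nrow(ei)) {
        d1 <- xy[ei[, 1], , drop = FALSE] - xy[ei[, 2], , drop = FALSE]
        pull <- attraction * w
        force[ei[, 1], ] <- force[ei[, 1], ] - pull * d1
        force[ei[, 2], ] <- force[ei[, 2], ] + pull * d1
      }
      disp <- sqrt(rowSums(force^2))
      scale <- pmin(1, step / pmax(disp, 1e-12))
      xy <- xy + force * scale
    }
  }
  data.frame(id = ids, x = xy[, 1], y = xy[, 2], stringsAsFactors = FALSE)
}

#' Adjusted Rand index between two labelings
#'
#' Used to score recovery of generative family labels by thresholded
#' components.
#'
#' @param a,b Two labelings of the same elements (named vectors are
#'   aligned by name).
#' @return The adjusted Rand index in [-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) b <- b[names(a)]
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
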