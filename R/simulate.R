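# Birth-death gene-family simulator on a fixed species tree.
#
# A family starts as a single gene lineage at the species-tree root.
# Along every species-tree edge each lineage duplicates at rate lambda
# and is lost at rate mu (independent exponential waiting times, i.e. a
# Gillespie process run per edge); at each species node every surviving
# lineage speciates into both child edges. Extinct sublineages are
# pruned from the emitted gene tree but the full history is retained in
# the event log, so observed trees look like real data while the oracle
# keeps complete truth.

#' Simulation parameters for the duplication-loss process
#'
#' @param dup_rate Duplication rate lambda (events per lineage per unit
#'   branch length), >= 0.
#' @param loss_rate Loss rate mu (same units), >= 0.
#' @param overrides Optional named list of per-branch rate overrides:
#'   names are species-tree node labels identifying the edge *into* that
#'   node, values are `c(dup = , loss = )`.
#' @param seed Optional integer seed; when given, [simulate_family()] is
#'   fully deterministic.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(dup_rate = 0.5, loss_rate = 0.2, overrides = list(),
                       seed = NULL) {
  stopifnot(dup_rate >= 0, loss_rate >= 0)
  if (length(overrides) && is.null(names(overrides))) {
    stop("overrides must be a named list (names = species edge labels)")
  }
  structure(list(dup_rate = dup_rate, loss_rate = loss_rate,
                 overrides = overrides, seed = seed),
            class = "sim_params")
}

#' Simulate one gene family by duplication and loss
#'
#' @param species_tree Rooted binary species tree with strictly positive
#'   branch lengths and unique labels (see [validate_species_tree()]).
#' @param params A [sim_params()] object.
#' @param family_id Identifier used in gene leaf names
#'   ("SPECIES_famID.gK").
#' @return An object of class `gene_family`: list with `gene_tree`
#'   (a `phylo`, or NULL when the family went extinct), `extinct` flag,
#'   `events` (data frame: event, species, lineage, time), `truth`
#'   (nested ground-truth lineage structure), `species_tree` and
#'   `family_id`.
#' @export
simulate_family <- function(species_tree, params = sim_params(),
                            family_id = "fam1") {
  validate_species_tree(species_tree, require_lengths = TRUE)
  stopifnot(inherits(params, "sim_params"))
  sx <- species_index(species_tree)
  ntip <- length(species_tree$tip.label)
  lens <- edge_length_lookup(species_tree)

  bad <- setdiff(names(params$overrides), sx$labels)
  if (length(bad)) stop("rate overrides reference unknown species edges: ",
                        paste(bad, collapse = ", "))
  if (!is.null(params$seed)) set.seed(params$seed)

  rates_for <- function(sp_child) {
    lab <- sx$labels[sp_child]
    ov <- params$overrides[[lab]]
    if (is.null(ov)) c(dup = params$dup_rate, loss = params$loss_rate)
    else c(dup = unname(ov["dup"]), loss = unname(ov["loss"]))
  }

  env <- new.env(parent = emptyenv())
  env$events <- list()
  env$lin_counter <- 0L
  env$leaf_counter <- stats::setNames(integer(ntip), species_tree$tip.label)

  new_lin <- function() { env$lin_counter <- env$lin_counter + 1L; env$lin_counter }
  log_event <- function(type, species_label, lineage, time) {
    env$events[[length(env$events) + 1L]] <-
      list(event = type, species = species_label, lineage = lineage,
           time = time)
  }

  # lineage entering the species edge that leads into node sp_child,
  # with `remaining` time left on that edge; returns a truth node:
  # list(type, sp, lineage, surv, children, blen) where blen is the time
  # elapsed on this gene branch up to the node (for gene-tree lengths)
  evolve_edge <- function(sp_child, remaining, lineage, elapsed0) {
    rt <- rates_for(sp_child)
    total <- rt["dup"] + rt["loss"]
    edge_len <- lens[sp_child]
    wait <- if (total > 0) stats::rexp(1L, rate = total) else Inf
    if (wait >= remaining) {
      nd <- at_node(sp_child, lineage)
      nd$blen <- elapsed0 + remaining
      return(nd)
    }
    t_frac <- (edge_len - (remaining - wait)) / edge_len
    if (stats::runif(1L) < rt["dup"] / total) {
      l1 <- new_lin(); l2 <- new_lin()
      log_event("duplication", sx$labels[sp_child], lineage, t_frac)
      c1 <- evolve_edge(sp_child, remaining - wait, l1, 0)
      c2 <- evolve_edge(sp_child, remaining - wait, l2, 0)
      list(type = "dup", sp = sp_child, lineage = lineage,
           surv = union(c1$surv, c2$surv), children = list(c1, c2),
           blen = elapsed0 + wait)
    } else {
      log_event("loss", sx$labels[sp_child], lineage, t_frac)
      list(type = "loss", sp = sp_child, lineage = lineage,
           surv = character(0), children = list(),
           blen = elapsed0 + wait)
    }
  }

  # lineage arriving at species node sp
  at_node <- function(sp, lineage) {
    if (sp <= ntip) {
      lab <- species_tree$tip.label[sp]
      env$leaf_counter[lab] <- env$leaf_counter[lab] + 1L
      log_event("leaf", lab, lineage, 1)
      list(type = "leaf", sp = sp, lineage = lineage, surv = lab,
           children = list(),
           leaf_label = sprintf("%s_%s.g%d", lab, family_id,
                                env$leaf_counter[lab]))
    } else {
      log_event("speciation", sx$labels[sp], lineage, 1)
      ch <- sx$kids[[sp]]
      c1 <- evolve_edge(ch[1], lens[ch[1]], new_lin(), 0)
      c2 <- evolve_edge(ch[2], lens[ch[2]], new_lin(), 0)
      list(type = "spec", sp = sp, lineage = lineage,
           surv = union(c1$surv, c2$surv), children = list(c1, c2))
    }
  }

  truth <- at_node(sx$root, new_lin())
  events <- do.call(rbind, lapply(env$events, function(e) {
    data.frame(event = e$event, species = e$species, lineage = e$lineage,
               time = e$time, stringsAsFactors = FALSE)
  }))
  extinct <- length(truth$surv) == 0L
  gene_tree <- if (extinct) NULL else truth_to_phylo(truth)
  structure(list(gene_tree = gene_tree, extinct = extinct, events = events,
                 truth = truth, species_tree = species_tree,
                 family_id = family_id),
            class = "gene_family")
}

#' @export
print.gene_family <- function(x, ...) {
  if (x$extinct) {
    cat("<gene_family", x$family_id, "- extinct>\n")
  } else {
    cat("<gene_family", x$family_id, "-", length(x$gene_tree$tip.label),
        "genes,", sum(x$events$event == "duplication"), "duplications,",
        sum(x$events$event == "loss"), "losses>\n")
  }
  invisible(x)
}

# Prune extinct sublineages from the truth structure and convert the
# observable part into a phylo object. Unary pass-through nodes (a
# duplication or speciation with a single surviving side) are
# suppressed, with branch lengths summed.
#' @keywords internal
truth_to_phylo <- function(truth) {
  prune <- function(nd, carried = 0) {
    blen <- if (is.null(nd$blen)) 0 else nd$blen
    alive <- Filter(function(ch) length(ch$surv) > 0L, nd$children)
    if (nd$type == "leaf") {
      return(list(label = nd$leaf_label, length = carried + blen,
                  comment = NA_character_, children = list()))
    }
    if (length(alive) == 1L) return(prune(alive[[1L]], carried + blen))
    list(label = "", length = carried + blen, comment = NA_character_,
         children = lapply(alive, prune, carried = 0))
  }
  obs <- prune(truth)
  if (length(obs$children) == 0L) {
    # single surviving gene: a one-leaf "tree"; represent as a 1-tip
    # phylo by hand since the Newick grammar needs >= 2 leaves
    tree <- list(edge = matrix(c(2L, 1L), nrow = 1),
                 tip.label = obs$label, Nnode = 1L,
                 edge.length = obs$length)
    class(tree) <- "phylo"
    return(tree)
  }
  nested_to_phylo(obs)
}

#' Replay the ground-truth event log into per-node lineage counts
#'
#' Computes, for every species-tree node, the number of *observable*
#' gene lineages present there (lineages with at least one surviving
#' descendant), under the undated placement convention: a surviving
#' duplication is attributed to the species LCA of its surviving
#' descendant species, and each loss to the species edge where the
#' lineage fails to continue. This is the simulator-side oracle against
#' which [copy_numbers()] is checked; it traverses the simulator's truth
#' structure and propagates counts top-down through the species tree,
#' sharing no code with the reconciliation-side interval computation.
#'
#' @param family A `gene_family` from [simulate_family()].
#' @return Named integer vector of lineage counts, one per species-tree
#'   node (tips and internal nodes, named by label).
#' @export
replay_complement <- function(family) {
  stopifnot(inherits(family, "gene_family"))
  sx <- species_index(family$species_tree)
  nsp <- n_nodes(family$species_tree)
  counts <- stats::setNames(integer(nsp), sx$labels)
  if (family$extinct) return(counts)

  # observable nested structure with species-LCA mapping per node
  build <- function(nd) {
    alive <- Filter(function(ch) length(ch$surv) > 0L, nd$children)
    if (nd$type == "leaf") return(list(m = nd$sp, children = list()))
    if (length(alive) == 1L) return(build(alive[[1L]]))
    ch <- lapply(alive, build)
    m <- ch[[1L]]$m
    for (k in seq_along(ch)[-1L]) {
      m <- lca_pair(m, ch[[k]]$m, sx$parent, sx$depth)
    }
    list(m = m, children = ch)
  }
  obs <- build(truth_root_wrap(family$truth))

  dup_at <- integer(nsp)          # duplications attributed to node
  loss_into <- integer(nsp)       # losses on the edge into node
  tally <- function(v) {
    if (!length(v$children)) return(invisible(NULL))
    is_dup <- any(vapply(v$children, function(c0) c0$m == v$m, logical(1)))
    if (is_dup) dup_at[v$m] <<- dup_at[v$m] + 1L
    for (c0 in v$children) {
      path <- path_down(v$m, c0$m, sx$parent)   # v$m ... c0$m inclusive
      thru <- if (is_dup) path[-length(path)] else path[-c(1L, length(path))]
      if (length(path) == 1L) thru <- integer(0)
      for (x in thru) {
        off <- setdiff(sx$kids[[x]], path)
        loss_into[off] <<- loss_into[off] + 1L
      }
      tally(c0)
    }
    invisible(NULL)
  }
  tally(obs)

  # top-down propagation within the origin subtree
  origin <- obs$m
  counts[origin] <- 1L + dup_at[origin]
  walk <- function(s) {
    for (c0 in sx$kids[[s]]) {
      counts[c0] <<- counts[s] + dup_at[c0] - loss_into[c0]
      walk(c0)
    }
  }
  walk(origin)
  counts
}

# the truth root is a speciation/leaf node with no incoming edge; wrap
# uniformly so build() can treat it like any node
#' @keywords internal
truth_root_wrap <- function(truth) truth

#' Simulate a pairwise similarity graph from gene families
#'
#' Emulates the structure of an all-vs-all BLAST similarity network.
#' Within a family, the similarity score (-log10 P) decays linearly
#' with patristic distance on the family's gene tree, plus Gaussian
#' alignment-quality jitter. Between families, P-values follow the
#' chance-alignment null (the count of chance hits at P <= x is
#' Poisson with mean x), rescaled so the typical between-family score
#' is `cross_family_mean`: P = 10^(-cross_family_mean) * Exp(1). The
#' null's exponentially light left tail in P means unrelated families
#' essentially never connect at strict thresholds by chance, matching
#' real local-alignment statistics. Scores are floored at 0 and
#' converted to P-values as P = 10^(-score), capped at 1.
#'
#' @param families List of `gene_family` objects (or `phylo` gene
#'   trees); names are used as family ids.
#' @param intercept Score at patristic distance 0 (default 40).
#' @param slope Score decay per unit patristic distance (default 2).
#' @param noise_sd Gaussian noise SD on within-family scores
#'   (default 2).
#' @param cross_family_mean Typical score of between-family pairs
#'   (default 4); must be < intercept.
#' @param seed Optional integer seed.
#' @return A `similarity_graph` (see [build_graph()]) whose vertices
#'   carry the generative family label in the `family` column.
#' @export
simulate_similarity <- function(families, intercept = 40, slope = 2,
                                noise_sd = 2, cross_family_mean = 4,
                                seed = NULL) {
  stopifnot(intercept > cross_family_mean)
  if (!is.null(seed)) set.seed(seed)
  trees <- lapply(families, function(f) {
    if (inherits(f, "gene_family")) f$gene_tree else f
  })
  if (is.null(names(trees))) names(trees) <- paste0("fam", seq_along(trees))
  trees <- Filter(Negate(is.null), trees)

  vs <- list(); es <- list()
  for (fam in names(trees)) {
    tr <- trees[[fam]]
    labs <- paste(fam, tr$tip.label, sep = "|")
    vs[[fam]] <- data.frame(id = labs, family = fam,
                            stringsAsFactors = FALSE)
    if (length(labs) < 2L) next
    dmat <- stats::cophenetic(tr)
    idx <- which(upper.tri(dmat), arr.ind = TRUE)
    score <- intercept - slope * dmat[idx] +
      stats::rnorm(nrow(idx), 0, noise_sd)
    es[[fam]] <- data.frame(
      v1 = labs[idx[, 1]], v2 = labs[idx[, 2]],
      score = pmax(0, score), stringsAsFactors = FALSE)
  }
  vertices <- do.call(rbind, vs)
  # between-family pairs
  fams <- names(trees)
  if (length(fams) > 1L) {
    for (i in seq_len(length(fams) - 1L)) for (j in (i + 1L):length(fams)) {
      a <- vs[[fams[i]]]$id; b <- vs[[fams[j]]]$id
      grid <- expand.grid(v1 = a, v2 = b, stringsAsFactors = FALSE)
      p_null <- 10^(-cross_family_mean) * stats::rexp(nrow(grid))
      grid$score <- pmax(0, -log10(p_null))
      es[[paste(fams[i], fams[j])]] <- grid
    }
  }
  edges <- do.call(rbind, es)
  rownames(edges) <- NULL
  edges$p <- pmin(1, 10^(-edges$score))
  edges$score <- -log10(edges$p)
  similarity_graph(vertices, edges)
}

#' Perturb a tree by random nearest-neighbour interchanges
#'
#' Bootstrap-replicate stand-in: applies `n_nni` NNI moves at uniformly
#' chosen internal edges of the unrooted tree (via [phangorn::rNNI()]).
#' The leaf set is unchanged.
#'
#' @param tree A `phylo` with >= 4 leaves (when `n_nni` > 0).
#' @param n_nni Number of NNI moves, >= 0.
#' @param seed Optional integer seed.
#' @return A perturbed, unrooted `phylo`.
#' @export
perturb_tree <- function(tree, n_nni, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), n_nni >= 0)
  if (n_nni == 0L) return(tree)
  if (length(tree$tip.label) < 4L) {
    stop("NNI perturbation requires at least 4 leaves")
  }
  if (!is.null(seed)) set.seed(seed)
  utree <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  phangorn::rNNI(utree, moves = n_nni, n = 1)
}

#' Export simulated similarity edges as BLAST outfmt-6-like TSV
#'
#' Writes the standard 12-column tabular layout; only columns 1 (query),
#' 2 (subject) and 11 (E-value) carry information, the rest are
#' placeholders. Each undirected edge is written once.
#'
#' @param graph A `similarity_graph`.
#' @param path Output TSV path.
#' @export
write_blast_pairs <- function(graph, path) {
  e <- graph$edges
  out <- data.frame(qseqid = e$v1, sseqid = e$v2, pident = 0, length = 0,
                    mismatch = 0, gapopen = 0, qstart = 0, qend = 0,
                    sstart = 0, send = 0,
                    evalue = format(e$p, digits = 8),
                    bitscore = round(e$score, 2))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
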