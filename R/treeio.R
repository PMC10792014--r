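# Newick parsing, validation and serialisation.
#
# Trees are stored as ape "phylo" objects. Two extensions to the plain
# Newick grammar are supported: internal node labels after ")" and NHX
# comment blocks ("[&&NHX:...]"), which are preserved verbatim in the
# attribute "node.comment" (a character vector indexed like the node
# numbering of the phylo object; NA where absent). All other "[...]"
# comments are discarded.

#' Parse a Newick string into a phylo object
#'
#' Parses a single Newick tree. Internal node labels, branch lengths and
#' NHX comment blocks are preserved. Unrooted trees (a basal
#' trifurcation) are returned as-is with `is.rooted()` FALSE; they are
#' only consumable by [root_by_dl()] downstream.
#'
#' @param text A Newick string ending in ";".
#' @param expect_rooted If TRUE, error when the tree has a basal
#'   polytomy (i.e. is unrooted).
#' @return An object of class `phylo`, with an additional
#'   `node.comment` attribute when NHX blocks are present.
#' @examples
#' tr <- parse_newick("((A:1,B:1)ab:1,C:2)r;")
#' tr$node.label
#' @export
parse_newick <- function(text, expect_rooted = FALSE) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) stop("empty Newick string")
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  pos <- 1L

  peek <- function() if (pos <= n) chars[pos] else ""
  bump <- function() pos <<- pos + 1L
  perr <- function(msg) {
    stop(sprintf("Newick parse error at character %d: %s", pos, msg),
         call. = FALSE)
  }

  # read an optional [..] comment; returns NHX blocks, drops the rest
  read_comment <- function() {
    com <- NA_character_
    while (peek() == "[") {
      start <- pos
      depth <- 0L
      repeat {
        if (pos > n) { pos <<- start; perr("unterminated comment") }
        if (chars[pos] == "[") depth <- depth + 1L
        if (chars[pos] == "]") depth <- depth - 1L
        bump()
        if (depth == 0L) break
      }
      block <- paste(chars[start:(pos - 1L)], collapse = "")
      if (startsWith(block, "[&&NHX")) com <- block
    }
    com
  }

  read_label <- function() {
    out <- character(0)
    while (pos <= n && !(chars[pos] %in% c("(", ")", ",", ":", ";", "["))) {
      out <- c(out, chars[pos]); bump()
    }
    paste(out, collapse = "")
  }

  # recursive descent; each node is list(label, length, comment, children)
  parse_clade <- function() {
    node <- list(label = "", length = NA_real_, comment = NA_character_,
                 children = list())
    if (peek() == "(") {
      bump()
      repeat {
        node$children[[length(node$children) + 1L]] <- parse_clade()
        if (peek() == ",") { bump(); next }
        if (peek() == ")") { bump(); break }
        perr("expected ',' or ')'")
      }
    }
    node$label <- read_label()
    node$comment <- read_comment()
    if (peek() == ":") {
      bump()
      num <- read_label()
      len <- suppressWarnings(as.numeric(num))
      if (is.na(len)) perr(sprintf("invalid branch length '%s'", num))
      node$length <- len
      cm2 <- read_comment()
      if (is.na(node$comment)) node$comment <- cm2
    }
    node
  }

  root <- parse_clade()
  if (peek() != ";") perr("expected ';'")
  bump()
  if (pos <= n) perr("trailing characters after ';'")
  if (length(root$children) == 0L) perr("tree must have at least 2 leaves")

  tree <- nested_to_phylo(root)
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup)) {
    stop("duplicate leaf labels: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (expect_rooted && !ape::is.rooted(tree)) {
    stop("tree is unrooted (basal polytomy) but a rooted tree was expected",
         call. = FALSE)
  }
  tree
}

# flatten a nested node list into a phylo object
nested_to_phylo <- function(root) {
  tips <- list(); ints <- list()
  # assign ids in two passes: tips first (phylo convention)
  collect <- function(nd) {
    if (length(nd$children) == 0L) tips[[length(tips) + 1L]] <<- nd
    else {
      ints[[length(ints) + 1L]] <<- nd
      for (ch in nd$children) collect(ch)
    }
    invisible(NULL)
  }
  collect(root)
  ntip <- length(tips); nint <- length(ints)
  if (ntip < 2L) stop("tree must have at least 2 leaves", call. = FALSE)

  edge <- matrix(0L, nrow = ntip + nint - 1L, ncol = 2L)
  edge_len <- rep(NA_real_, nrow(edge))
  tip.label <- character(ntip); node.label <- character(nint)
  comment <- rep(NA_character_, ntip + nint)
  tip_i <- 0L; int_i <- 0L; edge_i <- 0L

  assign_ids <- function(nd, parent_id) {
    if (length(nd$children) == 0L) {
      tip_i <<- tip_i + 1L
      id <- tip_i
      tip.label[tip_i] <<- nd$label
    } else {
      int_i <<- int_i + 1L
      id <- ntip + int_i
      node.label[int_i] <<- nd$label
    }
    comment[id] <<- nd$comment
    if (!is.na(parent_id)) {
      edge_i <<- edge_i + 1L
      edge[edge_i, ] <<- c(parent_id, id)
      edge_len[edge_i] <<- nd$length
    }
    for (ch in nd$children) assign_ids(ch, id)
    id
  }
  assign_ids(root, NA_integer_)

  tree <- list(edge = edge, tip.label = tip.label, Nnode = nint)
  if (any(nzchar(node.label))) tree$node.label <- node.label
  if (any(!is.na(edge_len))) {
    tree$edge.length <- ifelse(is.na(edge_len), 0, edge_len)
  }
  class(tree) <- "phylo"
  attr(tree, "order") <- "cladewise"
  if (any(!is.na(comment))) attr(tree, "node.comment") <- comment
  tree
}

#' Serialise a phylo object to Newick
#'
#' Canonical serialisation sorts the children of every node by their
#' smallest descendant leaf label, so that topologically identical trees
#' serialise identically regardless of input child order. NHX comments
#' stored in the `node.comment` attribute are emitted verbatim.
#'
#' @param tree A `phylo` object.
#' @param canonical Sort children by smallest leaf label (default TRUE).
#' @param digits Significant digits for branch lengths.
#' @return A single Newick string ending in ";".
#' @export
write_newick <- function(tree, canonical = TRUE, digits = 12) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  kids <- children_list(tree)
  root <- root_node(tree)
  comment <- attr(tree, "node.comment")
  lens <- edge_length_lookup(tree)

  lab_of <- function(id) {
    if (id <= ntip) tree$tip.label[id]
    else if (!is.null(tree$node.label)) tree$node.label[id - ntip]
    else ""
  }
  min_leaf <- character(ntip + tree$Nnode)
  fill_min <- function(id) {
    ch <- kids[[id]]
    if (length(ch) == 0L) min_leaf[id] <<- tree$tip.label[id]
    else {
      for (c0 in ch) fill_min(c0)
      min_leaf[id] <<- min(min_leaf[ch])
    }
  }
  fill_min(root)

  emit <- function(id, top = FALSE) {
    ch <- kids[[id]]
    if (canonical && length(ch) > 1L) ch <- ch[order(min_leaf[ch])]
    core <- if (length(ch)) {
      paste0("(", paste(vapply(ch, emit, ""), collapse = ","), ")", lab_of(id))
    } else {
      lab_of(id)
    }
    if (!top && !is.na(lens[id])) {
      core <- paste0(core, ":", format(lens[id], digits = digits))
    }
    if (!is.null(comment) && !is.na(comment[id])) {
      core <- paste0(core, comment[id])
    }
    core
  }
  paste0(emit(root, top = TRUE), ";")
}

#' Read one tree per line from a (multi-)Newick file
#' @param path File with one Newick string per line.
#' @param expect_rooted Passed to [parse_newick()].
#' @return A list of `phylo` objects.
#' @export
read_newick_file <- function(path, expect_rooted = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no trees in file: ", path)
  lapply(lines, parse_newick, expect_rooted = expect_rooted)
}

#' Write trees to a (multi-)Newick file, one per line
#' @param trees A `phylo` or list of `phylo` objects.
#' @param path Output file path.
#' @export
write_newick_file <- function(trees, path) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  writeLines(vapply(trees, write_newick, ""), path)
}

#' Validate a species tree
#'
#' The species tree is the fixed reference frame for reconciliation and
#' ancestral complement mapping: it must be rooted, strictly binary, and
#' all labels (tips and internal nodes, e.g. "Gnathostomata") must be
#' unique and non-empty so that every ancestral node is nameable.
#'
#' @param tree A `phylo` object.
#' @param require_lengths Require strictly positive branch lengths
#'   (needed by the simulator).
#' @return The tree, invisibly, on success; errors otherwise.
#' @export
validate_species_tree <- function(tree, require_lengths = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("species tree must be rooted")
  if (!ape::is.binary(tree)) stop("species tree must be strictly binary")
  if (is.null(tree$node.label) || any(!nzchar(tree$node.label))) {
    stop("every internal node of the species tree must carry a label")
  }
  labs <- c(tree$tip.label, tree$node.label)
  if (anyDuplicated(labs)) {
    stop("species tree labels are not unique: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))
  }
  if (require_lengths) {
    if (is.null(tree$edge.length) || any(tree$edge.length <= 0)) {
      stop("species tree must have strictly positive branch lengths")
    }
  }
  invisible(tree)
}

#' Map gene-tree leaves to species
#'
#' Gene-tree leaf labels encode their species as a token at a fixed
#' position, e.g. "HSAP_CCR5" with separator "_" and position "prefix".
#'
#' @param gene_tree A `phylo` gene tree.
#' @param species_tree The species tree the tokens must resolve against.
#' @param separator Separator string (fixed, not a regex).
#' @param position "prefix" (token before first separator) or "suffix"
#'   (token after last separator).
#' @return A named character vector: leaf label -> species label.
#' @export
leaf_species_map <- function(gene_tree, species_tree, separator = "_",
                             position = c("prefix", "suffix")) {
  position <- match.arg(position)
  leaves <- gene_tree$tip.label
  no_sep <- !vapply(leaves, function(x) grepl(separator, x, fixed = TRUE),
                    logical(1))
  if (any(no_sep)) {
    stop("leaf label(s) without separator '", separator, "': ",
         paste(leaves[no_sep], collapse = ", "))
  }
  parts <- strsplit(leaves, separator, fixed = TRUE)
  sp <- vapply(parts, function(p) {
    if (position == "prefix") p[[1]] else p[[length(p)]]
  }, character(1))
  unknown <- setdiff(unique(sp), species_tree$tip.label)
  if (length(unknown)) {
    stop("species not present in the species tree: ",
         paste(unknown, collapse = ", "))
  }
  stats::setNames(sp, leaves)
}

#' Strip the species token from a gene leaf label
#' @keywords internal
gene_token <- function(labels, separator = "_",
                       position = c("prefix", "suffix")) {
  position <- match.arg(position)
  parts <- strsplit(labels, separator, fixed = TRUE)
  vapply(parts, function(p) {
    if (position == "prefix") paste(p[-1], collapse = separator)
    else paste(p[-length(p)], collapse = separator)
  }, character(1))
}
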