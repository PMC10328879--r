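# A rooted_tree stores a rooted phylogenetic X-tree in canonical form:
#   root     : name of the root vertex
#   vertices : all vertex names in canonical preorder
#   parent   : named character, parent of every non-root vertex
#   children : named list of character vectors, children in canonical order
#   length   : named numeric, branch length of the edge above every non-root
#              vertex (edges are identified by their terminal vertex)
#   code     : named character, canonical shape code of the subtree at each
#              vertex (equal codes <=> isomorphic tree shapes)
#   cluster  : named list, leaves below each vertex in canonical order
#   auto     : names of internal vertices that were auto-generated rather than
#              read from input (omitted again when writing Newick)
# Canonical order sorts the children of every vertex by shape code (radix,
# C locale), breaking ties by smallest descendant leaf label, so vertex
# numbering, matrix column order and ratio positions are reproducible.

new_node <- function(label = NA_character_, length = NA_real_, children = list()) {
  list(label = label, length = length, children = children)
}

annotate_node <- function(node) {
  if (length(node$children) == 0L) {
    node$code <- "()"
    node$minlab <- node$label
    return(node)
  }
  node$children <- lapply(node$children, annotate_node)
  codes <- vapply(node$children, function(k) k$code, character(1))
  mins <- vapply(node$children, function(k) k$minlab, character(1))
  o <- order(codes, mins, method = "radix")
  node$children <- node$children[o]
  node$code <- paste0("(", paste0(codes[o], collapse = ""), ")")
  node$minlab <- min(mins[o])
  node
}

# Build the canonical flat representation from a nested node list.
build_rooted_tree <- function(nested, auto = character(0)) {
  n_missing <- 0L
  check <- function(node, is_root) {
    if (length(node$children) == 1L)
      stop("invalid tree: internal vertex with out-degree 1", call. = FALSE)
    if (length(node$children) == 0L && (is.na(node$label) || !nzchar(node$label)))
      stop("invalid tree: unlabelled leaf", call. = FALSE)
    if (is_root) {
      if (!is.na(node$length))
        stop("invalid tree: a branch length on the root is not allowed",
             call. = FALSE)
    } else {
      if (is.na(node$length)) n_missing <<- n_missing + 1L
      else if (node$length <= 0)
        stop(sprintf("invalid tree: non-positive branch length %g", node$length),
             call. = FALSE)
    }
    for (k in node$children) check(k, FALSE)
  }
  check(nested, TRUE)
  if (n_missing > 0L)
    warning(sprintf("%d missing branch length(s) set to 1", n_missing),
            call. = FALSE)

  nested <- annotate_node(nested)

  vertices <- character(0)
  parent <- character(0)
  len <- numeric(0)
  code <- character(0)
  children <- list()
  auto_out <- character(0)
  idx <- 0L

  walk <- function(node, parent_name) {
    idx <<- idx + 1L
    name <- if (!is.na(node$label) && nzchar(node$label)) node$label
            else paste0("v", idx)
    if (is.na(node$label) || !nzchar(node$label) || name %in% auto)
      auto_out <<- c(auto_out, name)
    vertices <<- c(vertices, name)
    code[name] <<- node$code
    if (!is.na(parent_name)) {
      parent[name] <<- parent_name
      len[name] <<- if (is.na(node$length)) 1 else node$length
    }
    kid_names <- vapply(node$children, function(k) walk(k, name), character(1))
    children[[name]] <<- kid_names
    name
  }
  root <- walk(nested, NA_character_)

  if (anyDuplicated(vertices))
    stop(sprintf("invalid tree: duplicate vertex label '%s'",
                 vertices[duplicated(vertices)][1]), call. = FALSE)

  cluster <- list()
  for (v in rev(vertices)) {
    kids <- children[[v]]
    cluster[[v]] <- if (length(kids) == 0L) v
                    else unlist(cluster[kids], use.names = FALSE)
  }
  cluster <- cluster[vertices]

  structure(list(root = root, vertices = vertices, parent = parent,
                 children = children, length = len, code = code,
                 cluster = cluster, auto = unique(auto_out)),
            class = "rooted_tree")
}

#' Parse a rooted tree from a Newick string
#'
#' Reads a single rooted tree in Newick format. Internal vertices may carry
#' labels; unlabelled internal vertices are auto-named `v<k>` by canonical
#' preorder index, and edges are referred to by the name of their terminal
#' (child) vertex throughout the package. Missing branch lengths default to 1
#' with a warning; non-positive lengths, duplicate labels, out-degree-1
#' vertices and a length on the root are rejected.
#'
#' @param text a single Newick string, e.g. `"((x1:1,x2:1):1,x3:1);"`.
#' @return an object of class `rooted_tree`.
#' @examples
#' tr <- parse_newick("((x1:1,x2:1):1,x3:1);")
#' total_pd(tr)
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  s <- trimws(text)
  nch <- nchar(s)
  if (nch == 0L)
    stop("newick parse error at character 1: empty string", call. = FALSE)
  i <- 1L
  peek <- function() if (i <= nch) substr(s, i, i) else ""
  fail <- function(msg, pos = i)
    stop(sprintf("newick parse error at character %d: %s", pos, msg),
         call. = FALSE)
  read_label <- function() {
    start <- i
    while (i <= nch && !(substr(s, i, i) %in% c("(", ")", ",", ":", ";")))
      i <<- i + 1L
    trimws(substr(s, start, i - 1L))
  }
  read_length <- function() {
    start <- i
    while (i <= nch && grepl("[-0-9eE+.]", substr(s, i, i))) i <<- i + 1L
    tok <- substr(s, start, i - 1L)
    val <- suppressWarnings(as.numeric(tok))
    if (!nzchar(tok) || is.na(val)) fail("invalid branch length", start)
    val
  }
  read_clade <- function() {
    if (peek() == "(") {
      open_pos <- i
      i <<- i + 1L
      kids <- list(read_clade())
      while (peek() == ",") {
        i <<- i + 1L
        kids[[length(kids) + 1L]] <- read_clade()
      }
      if (peek() != ")") fail("expected ',' or ')'")
      i <<- i + 1L
      if (length(kids) < 2L)
        fail("internal vertex with out-degree 1", open_pos)
      lab <- read_label()
      ln <- NA_real_
      if (peek() == ":") { i <<- i + 1L; ln <- read_length() }
      new_node(if (nzchar(lab)) lab else NA_character_, ln, kids)
    } else {
      lab <- read_label()
      if (!nzchar(lab)) fail("expected a leaf label or '('")
      ln <- NA_real_
      if (peek() == ":") { i <<- i + 1L; ln <- read_length() }
      new_node(lab, ln)
    }
  }
  root <- read_clade()
  if (peek() != ";") fail("expected ';'")
  i <- i + 1L
  if (i <= nch) fail("trailing characters after ';'")
  build_rooted_tree(root)
}

#' Read a rooted tree from a Newick file
#'
#' @param file path to a file containing a single Newick tree.
#' @return a `rooted_tree`.
#' @export
read_newick <- function(file) {
  parse_newick(paste(readLines(file, warn = FALSE), collapse = ""))
}

fmt_length <- function(x) {
  out <- sprintf("%.15g", x)
  sub("^([0-9.]+?)0*e", "\\1e", out)
}

#' Write a rooted tree as a Newick string
#'
#' Children are emitted in canonical shape-code order, so
#' `parse_newick(write_newick(tree))` reproduces `tree` exactly (labels,
#' lengths, vertex names). Auto-generated internal names are omitted.
#'
#' @param tree a `rooted_tree`.
#' @param file optional path; if given the string is also written to the file.
#' @return the Newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "rooted_tree"))
  emit <- function(v) {
    kids <- tree$children[[v]]
    lab <- if (length(kids) == 0L || !(v %in% tree$auto)) v else ""
    core <- if (length(kids) == 0L) lab
            else paste0("(", paste(vapply(kids, emit, character(1)),
                                   collapse = ","), ")", lab)
    if (v == tree$root) core
    else paste0(core, ":", fmt_length(tree$length[[v]]))
  }
  out <- paste0(emit(tree$root), ";")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' @export
print.rooted_tree <- function(x, ...) {
  cat(sprintf("rooted_tree: %d leaves, %d edges, PD = %g\n",
              length(tree_leaves(x)), length(tree_edges(x)), total_pd(x)))
  nwk <- write_newick(x)
  if (nchar(nwk) > 70) nwk <- paste0(substr(nwk, 1, 67), "...")
  cat(" ", nwk, "\n")
  invisible(x)
}

#' Leaves, edges and interior edges of a tree
#'
#' Edges are identified by their terminal (child) vertex name. `tree_leaves()`
#' returns leaf labels in canonical order, `tree_edges()` all edges in
#' canonical preorder, and `interior_edges()` the non-pendant edges.
#'
#' @param tree a `rooted_tree`.
#' @return a character vector of names.
#' @export
tree_leaves <- function(tree) {
  stopifnot(inherits(tree, "rooted_tree"))
  tree$cluster[[tree$root]]
}

#' @rdname tree_leaves
#' @export
tree_edges <- function(tree) {
  stopifnot(inherits(tree, "rooted_tree"))
  setdiff(tree$vertices, tree$root)
}

#' @rdname tree_leaves
#' @export
interior_edges <- function(tree) {
  e <- tree_edges(tree)
  e[vapply(tree$children[e], length, integer(1)) > 0L]
}

check_edge <- function(tree, e) {
  if (!(is.character(e) && length(e) == 1L && e %in% tree$vertices &&
        e != tree$root))
    stop(sprintf("unknown edge '%s'", as.character(e)[1]), call. = FALSE)
  invisible(e)
}

check_leaf <- function(tree, x) {
  if (!(is.character(x) && length(x) == 1L && x %in% tree$vertices &&
        length(tree$children[[x]]) == 0L))
    stop(sprintf("unknown leaf '%s'", as.character(x)[1]), call. = FALSE)
  invisible(x)
}

#' Total phylogenetic diversity of a tree
#'
#' PD is the sum of all branch lengths; the single-vertex tree has PD 0.
#'
#' @param tree a `rooted_tree`.
#' @return a non-negative number in branch-length units.
#' @export
total_pd <- function(tree) {
  stopifnot(inherits(tree, "rooted_tree"))
  sum(tree$length)
}

#' Cluster of leaves below an edge
#'
#' @param tree a `rooted_tree`.
#' @param e an edge, named by its terminal vertex.
#' @return character vector of leaf labels descended from `e`.
#' @export
tree_cluster <- function(tree, e) {
  stopifnot(inherits(tree, "rooted_tree"))
  check_edge(tree, e)
  tree$cluster[[e]]
}

#' Path of edges from the root to a leaf
#'
#' @param tree a `rooted_tree`.
#' @param x a leaf label.
#' @return character vector of edges in root-to-leaf order; the last element
#'   is the pendant edge of `x`.
#' @export
root_path <- function(tree, x) {
  stopifnot(inherits(tree, "rooted_tree"))
  check_leaf(tree, x)
  path <- character(0)
  v <- x
  while (v != tree$root) {
    path <- c(v, path)
    v <- tree$parent[[v]]
  }
  path
}

to_nested <- function(tree, v, as_root = FALSE) {
  kids <- tree$children[[v]]
  new_node(label = v,
           length = if (as_root) NA_real_ else unname(tree$length[v]),
           children = lapply(kids, function(k) to_nested(tree, k)))
}

#' Pendant subtree below an edge
#'
#' The subtree obtained by deleting edge `e`, rooted at `e`'s terminal vertex;
#' branch lengths are inherited.
#'
#' @inheritParams tree_cluster
#' @return a `rooted_tree`.
#' @export
pendant_subtree <- function(tree, e) {
  stopifnot(inherits(tree, "rooted_tree"))
  check_edge(tree, e)
  build_rooted_tree(to_nested(tree, e, as_root = TRUE), auto = tree$auto)
}

#' Contract an interior edge
#'
#' Merges the terminal vertex of `e` into its parent, re-attaching the
#' children; all other branch lengths and the leaf set are unchanged. Total PD
#' drops by the length of `e`.
#'
#' @inheritParams tree_cluster
#' @return a `rooted_tree` on the same leaf set with one fewer edge.
#' @export
contract_edge <- function(tree, e) {
  stopifnot(inherits(tree, "rooted_tree"))
  check_edge(tree, e)
  if (length(tree$children[[e]]) == 0L)
    stop("cannot contract a pendant edge", call. = FALSE)
  p <- tree$parent[[e]]
  kids_p <- tree$children[[p]]
  tree$children[[p]] <- c(setdiff(kids_p, e), tree$children[[e]])
  for (k in tree$children[[e]]) tree$parent[[k]] <- p
  tree$children[[e]] <- NULL
  build_rooted_tree(to_nested(tree, tree$root, as_root = TRUE),
                    auto = tree$auto)
}

#' Replace the branch lengths of a tree
#'
#' @param tree a `rooted_tree`.
#' @param lengths a positive numeric vector, either named by edge or given in
#'   canonical edge order (`tree_edges(tree)`).
#' @return a `rooted_tree` with the new lengths.
#' @export
set_edge_lengths <- function(tree, lengths) {
  stopifnot(inherits(tree, "rooted_tree"))
  edges <- tree_edges(tree)
  if (!is.null(names(lengths))) {
    if (!setequal(names(lengths), edges))
      stop("length names do not match the tree's edges", call. = FALSE)
    lengths <- lengths[edges]
  } else {
    if (length(lengths) != length(edges))
      stop("need one length per edge", call. = FALSE)
    names(lengths) <- edges
  }
  if (any(lengths <= 0))
    stop("invalid tree: non-positive branch length", call. = FALSE)
  tree$length[edges] <- lengths[edges]
  tree
}

#' Convert to and from 'ape' phylo objects
#'
#' Interconversion with the `phylo` class for plotting or cross-checking.
#' Requires the `ape` package; the single-vertex tree is not representable as
#' a `phylo` and is rejected.
#'
#' @param tree a `rooted_tree` (for `as_phylo`) or `phylo` (for
#'   `as_rooted_tree`).
#' @return a `phylo` or `rooted_tree` respectively.
#' @export
as_phylo <- function(tree) {
  stopifnot(inherits(tree, "rooted_tree"))
  if (!requireNamespace("ape", quietly = TRUE))
    stop("the 'ape' package is required for as_phylo()", call. = FALSE)
  leaves <- tree_leaves(tree)
  if (length(leaves) < 2L)
    stop("cannot convert a tree with fewer than 2 leaves to phylo",
         call. = FALSE)
  internals <- setdiff(tree$vertices, leaves)
  id <- c(seq_along(leaves), length(leaves) + seq_along(internals))
  names(id) <- c(leaves, internals)
  edges <- tree_edges(tree)
  mat <- cbind(id[tree$parent[edges]], id[edges])
  dimnames(mat) <- NULL
  phy <- list(edge = mat, tip.label = leaves,
              Nnode = length(internals),
              edge.length = unname(tree$length[edges]),
              node.label = internals)
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

#' @rdname as_phylo
#' @export
as_rooted_tree <- function(tree) {
  if (!requireNamespace("ape", quietly = TRUE))
    stop("the 'ape' package is required for as_rooted_tree()", call. = FALSE)
  stopifnot(inherits(tree, "phylo"))
  parse_newick(ape::write.tree(tree))
}
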