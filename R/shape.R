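# Tree-shape machinery: canonical shape codes (AHU-style), symmetry orbits of
# leaves, balancedness predicates and the ~-equivalence classes of interior
# non-root vertices that determine the dimension of the diversity index space.

#' Canonical shape code of a subtree
#'
#' The code is an AHU-style canonical form: a leaf is `"()"` and an internal
#' vertex wraps the sorted concatenation of its children's codes. Two vertices
#' have equal codes exactly when the subtrees below them have the same tree
#' shape (rooted isomorphism, ignoring labels and lengths).
#'
#' @param tree a `rooted_tree`.
#' @param v a vertex name; defaults to the root, giving the code of the whole
#'   tree shape.
#' @return a character scalar.
#' @export
shape_code <- function(tree, v = tree$root) {
  stopifnot(inherits(tree, "rooted_tree"))
  if (!(v %in% tree$vertices)) stop(sprintf("unknown vertex '%s'", v),
                                    call. = FALSE)
  tree$code[[v]]
}

# Orbit label of each leaf below v: the sequence of shape codes of the
# subtrees entered along the path from v down to the leaf. Two leaves below v
# carry the same label iff some symmetry (automorphism) of the subtree at v
# maps one to the other.
orbit_labels <- function(tree, v) {
  leaves <- tree$cluster[[v]]
  out <- vapply(leaves, function(x) {
    if (x == v) return(".")
    path <- character(0)
    u <- x
    while (u != v) {
      path <- c(u, path)
      u <- tree$parent[[u]]
    }
    paste(tree$code[path], collapse = "/")
  }, character(1))
  names(out) <- leaves
  out
}

#' Symmetry orbits of the leaves below a vertex
#'
#' Partitions the leaves below `v` into orbits of the automorphism group of
#' the subtree's shape: leaves in one orbit occupy corresponding positions and
#' must receive equal coefficients under the neutrality condition.
#'
#' @inheritParams shape_code
#' @return a list of character vectors (the orbits), ordered by their first
#'   leaf in canonical order.
#' @export
leaf_orbits <- function(tree, v = tree$root) {
  stopifnot(inherits(tree, "rooted_tree"))
  if (!(v %in% tree$vertices)) stop(sprintf("unknown vertex '%s'", v),
                                    call. = FALSE)
  labs <- orbit_labels(tree, v)
  orb <- split(names(labs), labs)
  orb <- unname(orb[order(vapply(orb, function(o)
    match(o[1], names(labs)), integer(1)))])
  orb
}

#' Number of leaves in a corresponding position to a leaf, below an edge
#'
#' `sigma_count(tree, x, e)` is the size of `x`'s symmetry orbit within the
#' pendant subtree below `e` (including `x` itself). Its reciprocal weights
#' the upper score bound: no diversity index can give `x` more than
#' `sum(l(e) / sigma_x(e))` along its root path.
#'
#' @param tree a `rooted_tree`.
#' @param x a leaf label descended from `e`.
#' @param e an edge (terminal-vertex name).
#' @return a positive integer.
#' @export
sigma_count <- function(tree, x, e) {
  stopifnot(inherits(tree, "rooted_tree"))
  check_edge(tree, e)
  check_leaf(tree, x)
  if (!(x %in% tree$cluster[[e]]))
    stop(sprintf("leaf '%s' is not descended from edge '%s'", x, e),
         call. = FALSE)
  labs <- orbit_labels(tree, e)
  sum(labs == labs[[x]])
}

#' Balanced and semi-balanced trees
#'
#' A tree is balanced when, at every vertex, all maximal pendant subtrees
#' share one tree shape; it is semi-balanced when every maximal pendant
#' subtree of the root is balanced. Semi-balanced trees are exactly those on
#' which all diversity indices coincide (the index space is a single point,
#' and FP equals ES).
#'
#' @param tree a `rooted_tree`.
#' @return a logical scalar.
#' @export
is_balanced <- function(tree) {
  stopifnot(inherits(tree, "rooted_tree"))
  internals <- tree$vertices[vapply(tree$children[tree$vertices], length,
                                    integer(1)) > 0L]
  all(vapply(internals, function(v)
    length(unique(tree$code[tree$children[[v]]])) == 1L, logical(1)))
}

#' @rdname is_balanced
#' @export
is_semi_balanced <- function(tree) {
  stopifnot(inherits(tree, "rooted_tree"))
  internals <- setdiff(
    tree$vertices[vapply(tree$children[tree$vertices], length,
                         integer(1)) > 0L],
    tree$root)
  all(vapply(internals, function(v)
    length(unique(tree$code[tree$children[[v]]])) == 1L, logical(1)))
}

#' Degrees of freedom of an interior non-root vertex
#'
#' One less than the number of distinct tree shapes among the maximal pendant
#' subtrees below `v`: the number of free parameters in the ratio of
#' allocations a diversity index may choose at `v`.
#'
#' @param tree a `rooted_tree`.
#' @param v an interior, non-root vertex name.
#' @return a non-negative integer.
#' @export
vertex_dof <- function(tree, v) {
  stopifnot(inherits(tree, "rooted_tree"))
  if (!(v %in% tree$vertices)) stop(sprintf("unknown vertex '%s'", v),
                                    call. = FALSE)
  if (v == tree$root)
    stop("the root carries no degrees of freedom", call. = FALSE)
  if (length(tree$children[[v]]) == 0L)
    stop("a leaf carries no degrees of freedom", call. = FALSE)
  length(unique(tree$code[tree$children[[v]]])) - 1L
}

#' Class signature of an internal vertex
#'
#' The multiset of child subtree shapes, rendered as the children's canonical
#' codes joined by `|`. Two interior non-root vertices are `~`-equivalent
#' exactly when their signatures are equal; ratio schemes key their entries by
#' this string.
#'
#' @param tree a `rooted_tree`.
#' @param v an internal vertex name.
#' @return a character scalar.
#' @export
class_signature <- function(tree, v) {
  stopifnot(inherits(tree, "rooted_tree"))
  kids <- tree$children[[v]]
  if (length(kids) == 0L)
    stop(sprintf("'%s' is a leaf and has no class signature", v),
         call. = FALSE)
  paste(tree$code[kids], collapse = "|")
}

interior_nonroot <- function(tree) {
  setdiff(tree$vertices[vapply(tree$children[tree$vertices], length,
                               integer(1)) > 0L],
          tree$root)
}

#' Equivalence classes of interior non-root vertices
#'
#' Partitions the interior non-root vertices by equality of their child
#' shape multiset (`~`-equivalence). Each class contributes its degrees of
#' freedom to the dimension of the diversity index space, and one extreme
#' ratio choice per distinct child shape to the corner count.
#'
#' @param tree a `rooted_tree`.
#' @return an `index_space_summary`: a list with `classes` (one entry per
#'   class, ordered by representative preorder position, holding
#'   `signature`, `representative`, `members`, `child_shapes` (distinct codes
#'   in canonical order), `multiplicity`, `out_degree` and `dof`),
#'   `dimension` and `corner_count`.
#' @export
equivalence_classes <- function(tree) {
  stopifnot(inherits(tree, "rooted_tree"))
  vs <- interior_nonroot(tree)
  sigs <- vapply(vs, function(v) class_signature(tree, v), character(1))
  keys <- unique(sigs)
  classes <- lapply(keys, function(k) {
    members <- vs[sigs == k]
    rep <- members[1]
    kid_codes <- tree$code[tree$children[[rep]]]
    shapes <- unique(kid_codes)
    list(signature = k,
         representative = rep,
         members = members,
         child_shapes = shapes,
         multiplicity = vapply(shapes, function(s) sum(kid_codes == s),
                               integer(1)),
         out_degree = length(kid_codes),
         dof = length(shapes) - 1L)
  })
  names(classes) <- keys
  dim <- sum(vapply(classes, function(cl) cl$dof, integer(1)), 0L)
  cc <- prod(vapply(classes, function(cl) length(cl$child_shapes),
                    integer(1)), 1L)
  structure(list(n_leaves = length(tree_leaves(tree)),
                 classes = classes,
                 dimension = as.integer(dim),
                 corner_count = cc),
            class = "index_space_summary")
}

#' Dimension of the diversity index space
#'
#' The sum of degrees of freedom over one representative per
#' `~`-equivalence class. It is 0 exactly for semi-balanced trees and never
#' exceeds `n - 2` for a tree on `n >= 2` leaves.
#'
#' @param tree a `rooted_tree`.
#' @return a non-negative integer.
#' @export
space_dimension <- function(tree) {
  equivalence_classes(tree)$dimension
}

#' Number of corner (extreme) indices of the index space
#'
#' The product over `~`-equivalence classes of the number of distinct child
#' shapes at a representative vertex.
#'
#' @param tree a `rooted_tree`.
#' @return a positive number.
#' @export
corner_count <- function(tree) {
  equivalence_classes(tree)$corner_count
}

#' @export
print.index_space_summary <- function(x, ...) {
  cat(sprintf(
    "diversity index space: %d leaves, dimension %d, %g corner(s), %d class(es)\n",
    x$n_leaves, x$dimension, x$corner_count, length(x$classes)))
  for (cl in x$classes) {
    cat(sprintf("  %s: %d member(s), out-degree %d, dof %d\n",
                cl$representative, length(cl$members), cl$out_degree, cl$dof))
  }
  invisible(x)
}
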