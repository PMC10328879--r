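# Consistent (flow) form of a diversity index. A consistent index splits the
# length of every ancestral edge among the maximal pendant subtrees below a
# vertex in one fixed ratio, so scores can be computed by pushing edge
# weights down the tree. Any diversity index coincides, for fixed branch
# lengths, with a consistent one whose per-vertex ratios are the
# length-weighted sums of its group allocations over the root path.

#' Group allocation of an edge at a vertex
#'
#' For vertex `v` descended from edge `e` (possibly `e`'s own terminal
#' vertex), sums the coefficients of `e` over the leaves of each maximal
#' pendant subtree below `v`, in canonical child order.
#'
#' @param matrix a coefficient matrix.
#' @param tree a `rooted_tree`.
#' @param v an internal vertex name.
#' @param e an edge (terminal-vertex name) from which `v` is descended.
#' @return a numeric vector with one entry per child of `v`.
#' @export
group_allocation <- function(matrix, tree, v, e) {
  stopifnot(inherits(tree, "rooted_tree"))
  m <- align_coef_matrix(matrix, tree)
  check_edge(tree, e)
  kids <- tree$children[[v]]
  if (is.null(kids) || length(kids) == 0L)
    stop(sprintf("'%s' is not an internal vertex", v), call. = FALSE)
  anc <- v
  ok <- FALSE
  while (!is.na(anc)) {
    if (anc == e) { ok <- TRUE; break }
    anc <- if (anc == tree$root) NA_character_ else tree$parent[[anc]]
  }
  if (!ok)
    stop(sprintf("vertex '%s' is not descended from edge '%s'", v, e),
         call. = FALSE)
  vapply(kids, function(k) sum(m[tree$cluster[[k]], e]), numeric(1))
}

ancestral_edges <- function(tree, v) {
  # edges on the path from the root down to v (inclusive of v's own edge)
  path <- character(0)
  u <- v
  while (u != tree$root) {
    path <- c(u, path)
    u <- tree$parent[[u]]
  }
  path
}

#' Is a diversity index consistent?
#'
#' TRUE when, at every vertex, the normalised ratio in which ancestral edges
#' are allocated among the vertex's maximal pendant subtrees is the same for
#' all ancestral edges (edges contributing nothing at the vertex are
#' unconstrained). FP and ES are consistent on every tree.
#'
#' @param matrix a coefficient matrix (should validate as a diversity index).
#' @param tree a `rooted_tree`.
#' @param tol absolute comparison tolerance.
#' @return a logical scalar.
#' @export
is_consistent <- function(matrix, tree, tol = 1e-9) {
  stopifnot(inherits(tree, "rooted_tree"))
  m <- align_coef_matrix(matrix, tree)
  for (v in interior_nonroot(tree)) {
    ref <- NULL
    for (e in ancestral_edges(tree, v)) {
      g <- group_allocation(m, tree, v, e)
      s <- sum(g)
      if (s <= tol) next
      g <- g / s
      if (is.null(ref)) ref <- g
      else if (max(abs(g - ref)) > tol) return(FALSE)
    }
  }
  TRUE
}

#' Construct a ratio scheme
#'
#' A ratio scheme holds, for internal vertices, the normalised ratio of
#' allocations: one non-negative value per child position (canonical order),
#' summing to 1, with equal values at positions whose child subtrees share a
#' tree shape. Entries are keyed either by a class signature (see
#' [class_signature()]; applies to every vertex of that `~`-class, and keeps
#' the neutrality condition automatic) or by a vertex name (vertex keys take
#' precedence, as produced by [matrix_to_consistent()]).
#'
#' @param ratios a named list of numeric vectors.
#' @return a `ratio_scheme`.
#' @export
ratio_scheme <- function(ratios) {
  stopifnot(is.list(ratios))
  if (length(ratios) > 0L)
    stopifnot(!is.null(names(ratios)), all(nzchar(names(ratios))))
  structure(list(ratios = lapply(ratios, as.numeric)), class = "ratio_scheme")
}

#' @export
print.ratio_scheme <- function(x, ...) {
  cat(sprintf("ratio_scheme with %d entr%s\n", length(x$ratios),
              if (length(x$ratios) == 1) "y" else "ies"))
  for (k in names(x$ratios))
    cat(sprintf("  %s: %s\n", k, paste(signif(x$ratios[[k]], 6),
                                       collapse = " : ")))
  invisible(x)
}

#' Resolve a ratio scheme against a tree
#'
#' Produces the per-vertex ratio vector for every interior non-root vertex.
#' Lookup order: the vertex's own name, then its class signature; vertices
#' with zero degrees of freedom may be omitted from the scheme (their ratio
#' is forced to an even split). Each resolved ratio is validated.
#'
#' @param tree a `rooted_tree`.
#' @param scheme a `ratio_scheme`.
#' @param fallback what to do for an uncovered vertex with free ratios:
#'   `"error"` (default) or `"fp"` (leaf-count-proportional ratio, with a
#'   notice), used when promoting a scheme to an index family on contracted
#'   trees.
#' @param tol validation tolerance.
#' @return a named list of numeric vectors, one per interior non-root vertex.
#' @export
resolve_ratios <- function(tree, scheme, fallback = c("error", "fp"),
                           tol = 1e-9) {
  stopifnot(inherits(tree, "rooted_tree"), inherits(scheme, "ratio_scheme"))
  fallback <- match.arg(fallback)
  out <- list()
  for (v in interior_nonroot(tree)) {
    kids <- tree$children[[v]]
    d <- length(kids)
    sig <- class_signature(tree, v)
    r <- scheme$ratios[[v]]
    if (is.null(r)) r <- scheme$ratios[[sig]]
    if (is.null(r)) {
      if (length(unique(tree$code[kids])) == 1L) {
        r <- rep(1 / d, d)
      } else if (fallback == "fp") {
        nl <- vapply(tree$cluster[kids], length, integer(1))
        r <- nl / sum(nl)
        message(sprintf(
          "ratio scheme has no entry for vertex '%s' (signature %s); using the leaf-count-proportional (FP) ratio",
          v, sig))
      } else {
        stop(sprintf("ratio scheme has no entry for vertex '%s' (signature %s)",
                     v, sig), call. = FALSE)
      }
    }
    if (length(r) != d)
      stop(sprintf("ratio for '%s' has length %d, expected out-degree %d",
                   v, length(r), d), call. = FALSE)
    if (any(r < -tol) || abs(sum(r) - 1) > tol)
      stop(sprintf("ratio for '%s' must be non-negative and sum to 1", v),
           call. = FALSE)
    codes <- tree$code[kids]
    for (s in unique(codes)) {
      grp <- r[codes == s]
      if (max(grp) - min(grp) > tol)
        stop(sprintf(
          "ratio for '%s' gives unequal shares to identically shaped subtrees",
          v), call. = FALSE)
    }
    out[[v]] <- pmax(r, 0)
  }
  out
}

#' Validate a ratio scheme against a tree
#'
#' @inheritParams resolve_ratios
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_ratio_scheme <- function(scheme, tree, tol = 1e-9) {
  invisible(!is.null(resolve_ratios(tree, scheme, tol = tol)))
}

#' Reconstruct a coefficient matrix from ratios of allocation
#'
#' The coefficient of leaf `x` for edge `e` is the product of the ratio
#' entries along the path from `e`'s terminal vertex down to `x`'s parent
#' (an empty product, i.e. 1, for pendant edges). The result is always a
#' consistent index; with class-keyed schemes it is a diversity index.
#'
#' @inheritParams resolve_ratios
#' @return a coefficient matrix.
#' @export
ratios_to_matrix <- function(tree, scheme, fallback = c("error", "fp")) {
  stopifnot(inherits(tree, "rooted_tree"))
  r <- resolve_ratios(tree, scheme, fallback = fallback)
  m <- empty_coef_matrix(tree)
  for (e in colnames(m)) {
    rec <- function(v, carry) {
      kids <- tree$children[[v]]
      if (length(kids) == 0L) {
        m[v, e] <<- carry
      } else {
        rv <- r[[v]]
        for (i in seq_along(kids)) rec(kids[i], carry * rv[i])
      }
    }
    rec(e, 1)
  }
  m
}

#' Flow-based evaluation of a consistent index
#'
#' Pushes each interior edge's weight onto its immediate descendant edges in
#' the vertex's ratio proportions until only pendant weights remain; the
#' score of a leaf is the final weight of its pendant edge. Total weight is
#' conserved at every step, so the scores sum to PD. Equals
#' `evaluate_index(ratios_to_matrix(tree, scheme), tree)`.
#'
#' @inheritParams resolve_ratios
#' @param lengths optional replacement branch lengths (see
#'   [evaluate_index()]).
#' @return a named numeric vector of per-leaf scores.
#' @export
flow_scores <- function(tree, scheme, fallback = c("error", "fp"),
                        lengths = NULL) {
  stopifnot(inherits(tree, "rooted_tree"))
  r <- resolve_ratios(tree, scheme, fallback = fallback)
  leaves <- tree_leaves(tree)
  edges <- tree_edges(tree)
  if (length(edges) == 0L) {
    out <- 0
    names(out) <- leaves
    return(out)
  }
  w <- if (is.null(lengths)) tree$length[edges] else {
    if (!is.null(names(lengths))) lengths[edges]
    else stats::setNames(lengths, edges)
  }
  for (v in edges) {
    kids <- tree$children[[v]]
    if (length(kids) == 0L) next
    w[kids] <- w[kids] + w[[v]] * r[[v]]
    w[[v]] <- 0
  }
  w[leaves]
}

#' Consistent form of a diversity index
#'
#' Builds, for fixed branch lengths, the per-vertex ratio scheme whose flow
#' scores coincide with the given index: at each interior non-root vertex the
#' ratio entries are the sums, over the edges of the root path, of the
#' edge's group allocation weighted by its length. A vertex receiving no
#' allocation from any ancestral edge has an undefined ratio; the
#' leaf-count-proportional (FP) ratio is substituted with a warning (scores
#' are unaffected, as no weight flows through such a vertex).
#'
#' @param matrix a coefficient matrix validating as a diversity index.
#' @param tree a `rooted_tree`.
#' @param tol tolerance below which a total incoming allocation counts as 0.
#' @return a vertex-keyed `ratio_scheme`.
#' @export
matrix_to_consistent <- function(matrix, tree, tol = 1e-12) {
  stopifnot(inherits(tree, "rooted_tree"))
  m <- align_coef_matrix(matrix, tree)
  ratios <- list()
  for (v in interior_nonroot(tree)) {
    kids <- tree$children[[v]]
    acc <- numeric(length(kids))
    for (e in ancestral_edges(tree, v))
      acc <- acc + group_allocation(m, tree, v, e) * tree$length[[e]]
    if (sum(acc) <= tol) {
      nl <- vapply(tree$cluster[kids], length, integer(1))
      acc <- nl / sum(nl)
      warning(sprintf(
        "vertex '%s' receives no allocation from any ancestral edge; substituting the leaf-count-proportional ratio",
        v), call. = FALSE)
    }
    ratios[[v]] <- acc / sum(acc)
  }
  ratio_scheme(ratios)
}

#' Read and write ratio schemes as JSON
#'
#' The JSON form is `{"classes": [{"signature": "...", "ratios": [...]}]}`;
#' ratio entries may be numbers or strings of the form `"p/q"`. Signatures
#' may equally be vertex names.
#'
#' @param file a path.
#' @param scheme a `ratio_scheme` (for writing).
#' @return a `ratio_scheme` (reading) or the path invisibly (writing).
#' @export
read_ratio_scheme <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = FALSE)
  if (is.null(obj$classes))
    stop("ratio scheme JSON must have a 'classes' field", call. = FALSE)
  ratios <- list()
  for (cl in obj$classes) {
    vals <- vapply(cl$ratios, function(z) {
      if (is.character(z) && grepl("/", z, fixed = TRUE)) {
        p <- strsplit(z, "/", fixed = TRUE)[[1]]
        as.numeric(p[1]) / as.numeric(p[2])
      } else as.numeric(z)
    }, numeric(1))
    ratios[[cl$signature]] <- vals
  }
  ratio_scheme(ratios)
}

#' @rdname read_ratio_scheme
#' @export
write_ratio_scheme <- function(scheme, file) {
  stopifnot(inherits(scheme, "ratio_scheme"))
  obj <- list(classes = lapply(names(scheme$ratios), function(k)
    list(signature = k, ratios = scheme$ratios[[k]])))
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
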