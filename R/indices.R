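# Coefficient-matrix representation of allocation functions and diversity
# indices. A coefficient matrix gamma has one row per leaf (canonical leaf
# order) and one column per edge (canonical preorder, named by terminal
# vertex); gamma[x, e] is the share of the length of e allocated to leaf x.
# Scores are the matrix-vector product with the branch lengths, so an index
# is linear in the lengths and conserves total PD whenever columns sum to 1.

empty_coef_matrix <- function(tree) {
  leaves <- tree_leaves(tree)
  edges <- tree_edges(tree)
  matrix(0, nrow = length(leaves), ncol = length(edges),
         dimnames = list(leaves, edges))
}

align_coef_matrix <- function(m, tree) {
  leaves <- tree_leaves(tree)
  edges <- tree_edges(tree)
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    if (nrow(m) != length(leaves) || ncol(m) != length(edges))
      stop("coefficient matrix dimensions do not match the tree",
           call. = FALSE)
    dimnames(m) <- list(leaves, edges)
    return(m)
  }
  if (!setequal(rownames(m), leaves) || !setequal(colnames(m), edges))
    stop("coefficient matrix rows/columns do not match the tree's leaves/edges",
         call. = FALSE)
  m[leaves, edges, drop = FALSE]
}

#' Fair Proportion coefficient matrix
#'
#' FP allocates each edge equally among the leaves of its cluster:
#' `gamma(x, e) = 1 / |c(e)|` for `x` descended from `e`, else 0. FP equals
#' the Shapley value of the PD coalition game and is the unique diversity
#' index that is continuous under contraction of interior edges.
#'
#' @param tree a `rooted_tree`.
#' @return a numeric matrix, leaves by edges.
#' @export
fp_matrix <- function(tree) {
  stopifnot(inherits(tree, "rooted_tree"))
  m <- empty_coef_matrix(tree)
  for (e in colnames(m)) {
    cl <- tree$cluster[[e]]
    m[cl, e] <- 1 / length(cl)
  }
  m
}

#' Equal-Splits coefficient matrix
#'
#' ES halves (more generally, splits `1/d`) the allocation at every interior
#' vertex on the way down: `gamma(x, e) = 1 / Pi(e, x)` where `Pi` is the
#' product of out-degrees of the interior vertices on the path from `e`'s
#' terminal vertex to `x` (1 when `e` is the pendant edge of `x`).
#'
#' @param tree a `rooted_tree`.
#' @return a numeric matrix, leaves by edges.
#' @export
es_matrix <- function(tree) {
  stopifnot(inherits(tree, "rooted_tree"))
  m <- empty_coef_matrix(tree)
  for (e in colnames(m)) {
    rec <- function(v, carry) {
      kids <- tree$children[[v]]
      if (length(kids) == 0L) {
        m[v, e] <<- carry
      } else {
        for (k in kids) rec(k, carry / length(kids))
      }
    }
    rec(e, 1)
  }
  m
}

#' Uniform allocation matrix
#'
#' Shares every edge equally among all `n` leaves: `gamma(x, e) = 1/n`. A
#' valid allocation function, but not a diversity index on any tree with an
#' edge that is not ancestral to all leaves (it ignores descent entirely).
#'
#' @param tree a `rooted_tree`.
#' @return a numeric matrix, leaves by edges.
#' @export
uniform_matrix <- function(tree) {
  stopifnot(inherits(tree, "rooted_tree"))
  m <- empty_coef_matrix(tree)
  m[] <- 1 / nrow(m)
  m
}

#' Evaluate an index: score vector from a coefficient matrix
#'
#' Computes `scores = gamma %*% lengths`. For a validated allocation function
#' the scores sum to the total PD of the tree.
#'
#' @param matrix a coefficient matrix (leaves by edges, dimnames matching the
#'   tree; unnamed matrices are accepted if the dimensions match canonical
#'   order).
#' @param tree a `rooted_tree`.
#' @param lengths optional replacement branch lengths (named by edge or in
#'   canonical edge order); non-negative values are allowed here so limits of
#'   the form `l(e) -> 0` can be evaluated exactly by linearity.
#' @return a named numeric vector of per-leaf scores in branch-length units.
#' @export
evaluate_index <- function(matrix, tree, lengths = NULL) {
  stopifnot(inherits(tree, "rooted_tree"))
  m <- align_coef_matrix(matrix, tree)
  edges <- colnames(m)
  if (is.null(lengths)) {
    l <- tree$length[edges]
  } else {
    if (!is.null(names(lengths))) l <- lengths[edges]
    else {
      stopifnot(length(lengths) == length(edges))
      l <- lengths
    }
    if (anyNA(l) || any(l < 0))
      stop("invalid replacement lengths", call. = FALSE)
  }
  if (length(edges) == 0L) {
    scores <- rep(0, nrow(m))
    names(scores) <- rownames(m)
    return(scores)
  }
  drop(m %*% l)
}

new_validation <- function(violations) {
  ok_alloc <- !any(violations$rule %in% c("nonneg", "column_sum"))
  structure(list(
    is_allocation = ok_alloc,
    is_diversity_index = ok_alloc && nrow(violations) == 0L,
    violations = violations), class = "index_validation")
}

violation_row <- function(rule, edge = NA_character_, leaf = NA_character_,
                          detail = "") {
  if (length(rule) == 0L)
    return(data.frame(rule = character(0), edge = character(0),
                      leaf = character(0), detail = character(0),
                      stringsAsFactors = FALSE))
  data.frame(rule = rule, edge = edge, leaf = leaf, detail = detail,
             stringsAsFactors = FALSE)
}

#' Validate a coefficient matrix as an allocation function
#'
#' An allocation function needs non-negative coefficients and unit column
#' sums (the latter is equivalent to conservation of total PD for every
#' choice of branch lengths).
#'
#' @param matrix a coefficient matrix.
#' @param tree a `rooted_tree`.
#' @param tol absolute comparison tolerance.
#' @return an `index_validation`: list with `is_allocation`,
#'   `is_diversity_index` and a `violations` data frame.
#' @export
check_allocation <- function(matrix, tree, tol = 1e-9) {
  stopifnot(inherits(tree, "rooted_tree"))
  m <- align_coef_matrix(matrix, tree)
  v <- list()
  neg <- which(m < -tol, arr.ind = TRUE)
  if (nrow(neg)) {
    for (i in seq_len(nrow(neg)))
      v[[length(v) + 1L]] <- violation_row(
        "nonneg", colnames(m)[neg[i, 2]], rownames(m)[neg[i, 1]],
        sprintf("gamma = %g", m[neg[i, 1], neg[i, 2]]))
  }
  if (ncol(m)) {
    cs <- colSums(m)
    bad <- which(abs(cs - 1) > tol)
    for (j in bad)
      v[[length(v) + 1L]] <- violation_row(
        "column_sum", colnames(m)[j],
        detail = sprintf("column sums to %g", cs[j]))
  }
  viol <- if (length(v) == 0L) violation_row(character(0))
          else do.call(rbind, v)
  new_validation(viol)
}

#' Validate a coefficient matrix as a diversity index
#'
#' Checks, in order: the allocation conditions (non-negativity, unit column
#' sums); the descent condition (zero coefficient whenever the leaf is not
#' descended from the edge); the pendant-edge consequence (a pendant edge is
#' allocated entirely to its leaf); and the neutrality condition — for every
#' pair of edges whose pendant subtrees share a tree shape, the coefficients
#' must agree under canonical position matching, and within one edge they
#' must be constant on symmetry orbits.
#'
#' @inheritParams check_allocation
#' @return an `index_validation`.
#' @export
check_diversity_index <- function(matrix, tree, tol = 1e-9) {
  stopifnot(inherits(tree, "rooted_tree"))
  m <- align_coef_matrix(matrix, tree)
  v <- list()
  add <- function(row) v[[length(v) + 1L]] <<- row

  base <- check_allocation(m, tree, tol)
  if (nrow(base$violations))
    for (i in seq_len(nrow(base$violations)))
      add(base$violations[i, , drop = FALSE])

  leaves <- rownames(m)
  for (e in colnames(m)) {
    cl <- tree$cluster[[e]]
    outside <- setdiff(leaves, cl)
    bad <- outside[abs(m[outside, e]) > tol]
    for (x in bad)
      add(violation_row("DI1", e, x,
                        sprintf("gamma = %g for leaf outside the cluster",
                                m[x, e])))
    if (length(cl) == 1L && abs(m[cl, e] - 1) > tol)
      add(violation_row("pendant", e, cl,
                        sprintf("pendant coefficient %g != 1", m[cl, e])))
  }

  # Neutrality: constant on orbits within each edge, and identical
  # label -> value maps across edges with the same pendant-subtree shape.
  edges <- colnames(m)
  shapes <- tree$code[edges]
  rep_maps <- list()
  for (e in edges) {
    labs <- orbit_labels(tree, e)
    vals <- m[names(labs), e]
    by_lab <- split(unname(vals), labs)
    spread <- vapply(by_lab, function(z) max(z) - min(z), numeric(1))
    bad <- names(spread)[spread > tol]
    for (b in bad)
      add(violation_row("DI2", e,
                        paste(names(labs)[labs == b], collapse = ","),
                        "unequal coefficients within a symmetry orbit"))
    key <- shapes[[e]]
    this_map <- vapply(by_lab, mean, numeric(1))
    this_map <- this_map[order(names(this_map), method = "radix")]
    if (is.null(rep_maps[[key]])) {
      rep_maps[[key]] <- list(edge = e, map = this_map)
    } else {
      ref <- rep_maps[[key]]
      if (max(abs(this_map - ref$map)) > tol)
        add(violation_row("DI2", e, NA_character_,
                          sprintf(
                            "coefficients differ from those of edge '%s' with the same pendant-subtree shape",
                            ref$edge)))
    }
  }

  if (length(v) == 0L)
    return(new_validation(violation_row(character(0))))
  new_validation(do.call(rbind, v))
}

#' Convex combination of coefficient matrices
#'
#' Entrywise weighted average; when all inputs are diversity indices on the
#' tree, so is the result (the index space is convex).
#'
#' @param matrices a list of coefficient matrices with identical dimnames.
#' @param weights non-negative weights summing to 1 (within `1e-12`).
#' @return a coefficient matrix.
#' @export
convex_combine <- function(matrices, weights) {
  stopifnot(is.list(matrices), length(matrices) >= 1L,
            length(weights) == length(matrices))
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-12)
    stop("weights must be non-negative and sum to 1", call. = FALSE)
  ref <- matrices[[1]]
  out <- ref * weights[1]
  for (i in seq_along(matrices)[-1]) {
    mi <- matrices[[i]]
    if (!identical(dim(mi), dim(ref)) ||
        !identical(dimnames(mi), dimnames(ref)))
      stop("matrices must share dimensions and dimnames", call. = FALSE)
    out <- out + mi * weights[i]
  }
  out
}

#' Read and write coefficient matrices as TSV
#'
#' The format has a header `leaf<TAB><edge>...` and one row per leaf; entries
#' may be decimals or fractions written `p/q`. On reading, rows and columns
#' are normalised to the tree's canonical order.
#'
#' @param file a path.
#' @param tree a `rooted_tree` used to validate and order the matrix.
#' @param matrix a coefficient matrix (for writing).
#' @return the coefficient matrix (reading), or the path invisibly (writing).
#' @export
read_coef_matrix <- function(file, tree) {
  stopifnot(inherits(tree, "rooted_tree"))
  df <- read.delim(file, check.names = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
  if (!identical(colnames(df)[1], "leaf"))
    stop("coefficient TSV must start with a 'leaf' column", call. = FALSE)
  parse_entry <- function(s) {
    s <- trimws(s)
    if (grepl("/", s, fixed = TRUE)) {
      parts <- strsplit(s, "/", fixed = TRUE)[[1]]
      as.numeric(parts[1]) / as.numeric(parts[2])
    } else as.numeric(s)
  }
  vals <- apply(as.matrix(df[, -1, drop = FALSE]), c(1, 2),
                parse_entry)
  if (!is.matrix(vals)) vals <- matrix(vals, nrow = nrow(df),
                                       dimnames = list(NULL, colnames(df)[-1]))
  rownames(vals) <- df$leaf
  align_coef_matrix(vals, tree)
}

#' @rdname read_coef_matrix
#' @export
write_coef_matrix <- function(matrix, file) {
  df <- data.frame(leaf = rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @export
print.index_validation <- function(x, ...) {
  cat(sprintf("allocation function: %s; diversity index: %s\n",
              x$is_allocation, x$is_diversity_index))
  if (nrow(x$violations)) {
    cat(sprintf("%d violation(s):\n", nrow(x$violations)))
    print(utils::head(x$violations, 20), row.names = FALSE)
  }
  invisible(x)
}
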