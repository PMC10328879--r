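# Geometry of the convex space S(T, l) of diversity index score vectors:
# corner (extreme) indices from extreme ratio choices per ~-equivalence
# class, Caratheodory bases of d + 1 corners, barycentric coordinates,
# per-leaf score bounds, seeded sampling, and checkers for two natural
# properties of shape-keyed index families.

corner_choice_scheme <- function(cls, choice) {
  ratios <- list()
  for (i in seq_along(cls$classes)) {
    cl <- cls$classes[[i]]
    chosen <- cl$child_shapes[choice[i]]
    k <- cl$multiplicity[[choice[i]]]
    kid_codes <- strsplit(cl$signature, "|", fixed = TRUE)[[1]]
    ratios[[cl$signature]] <- ifelse(kid_codes == chosen, 1 / k, 0)
  }
  ratio_scheme(ratios)
}

decode_choice <- function(id, radix) {
  # lexicographic order over classes: the first class varies slowest
  rem <- id - 1
  choice <- integer(length(radix))
  for (c in rev(seq_along(radix))) {
    choice[c] <- rem %% radix[c] + 1
    rem <- rem %/% radix[c]
  }
  choice
}

make_corner <- function(tree, cls, choice, id) {
  scheme <- corner_choice_scheme(cls, choice)
  names(choice) <- names(cls$classes)
  structure(list(id = id, choice = choice, scheme = scheme,
                 scores = flow_scores(tree, scheme)),
            class = "corner_index")
}

#' @export
print.corner_index <- function(x, ...) {
  cat(sprintf("corner index #%d; choices (%s); scores:\n", x$id,
              paste(unname(x$choice), collapse = ",")))
  print(round(x$scores, 6))
  invisible(x)
}

#' Corner (extreme) indices of the diversity index space
#'
#' Every extreme point of the index space gives, within each
#' `~`-equivalence class, the entire allocation to one of the distinct child
#' shapes (subtrees of the chosen shape, multiplicity `k`, get `1/k` each).
#' Corners are enumerated in deterministic lexicographic order over classes
#' (classes by representative preorder position, choices by canonical shape
#' code); the all-first-choice corner comes first.
#'
#' @param tree a `rooted_tree`.
#' @param limit refuse to materialise more than this many corners (use
#'   [corner_index()] to construct single corners of larger spaces).
#' @return a list of `corner_index` objects, each with `id`, `choice` (one
#'   chosen shape per class), `scheme` and `scores`.
#' @export
corner_indices <- function(tree, limit = 4096) {
  stopifnot(inherits(tree, "rooted_tree"))
  cls <- equivalence_classes(tree)
  if (cls$corner_count > limit)
    stop(sprintf(
      "the index space has %g corners, more than limit = %g; raise 'limit' or construct single corners with corner_index()",
      cls$corner_count, limit), call. = FALSE)
  radix <- vapply(cls$classes, function(cl) length(cl$child_shapes),
                  integer(1))
  lapply(seq_len(cls$corner_count), function(id)
    make_corner(tree, cls, decode_choice(id, radix), id))
}

#' A single corner index by choice vector or id
#'
#' @param tree a `rooted_tree`.
#' @param choice either an integer vector with one chosen child-shape per
#'   `~`-equivalence class (in class order), or a single corner id in the
#'   lexicographic enumeration.
#' @return a `corner_index`.
#' @export
corner_index <- function(tree, choice) {
  stopifnot(inherits(tree, "rooted_tree"))
  cls <- equivalence_classes(tree)
  radix <- vapply(cls$classes, function(cl) length(cl$child_shapes),
                  integer(1))
  if (length(choice) == 1L && length(radix) != 1L) {
    id <- as.integer(choice)
    stopifnot(id >= 1, id <= cls$corner_count)
    choice <- decode_choice(id, radix)
  } else {
    stopifnot(length(choice) == length(radix), all(choice >= 1),
              all(choice <= radix))
    id <- 0L
    for (c in seq_along(radix)) id <- id * radix[c] + (choice[c] - 1L)
    id <- as.integer(id + 1L)
  }
  make_corner(tree, cls, as.integer(choice), id)
}

#' Score vectors of a set of corners
#'
#' @param corners a list of `corner_index` objects.
#' @return a numeric matrix, corners by leaves.
#' @export
corner_scores <- function(corners) {
  t(vapply(corners, function(co) co$scores, corners[[1]]$scores))
}

#' Caratheodory basis of the index space
#'
#' For a space of dimension `d`, returns `d + 1` corners whose convex hull
#' contains every index score vector: the all-first-choice corner `B1`,
#' plus, for each class and each alternative extreme choice, the corner
#' differing from `B1` in that single class. On a semi-balanced tree the
#' space is one point and the single (FP) corner is returned.
#'
#' @param tree a `rooted_tree`.
#' @return a list of `d + 1` `corner_index` objects.
#' @export
caratheodory_basis <- function(tree) {
  stopifnot(inherits(tree, "rooted_tree"))
  cls <- equivalence_classes(tree)
  radix <- vapply(cls$classes, function(cl) length(cl$child_shapes),
                  integer(1))
  base_choice <- rep(1L, length(radix))
  basis <- list(corner_index(tree, if (length(radix)) base_choice else 1L))
  for (c in seq_along(radix)) {
    for (alt in seq_len(radix[c])[-1]) {
      ch <- base_choice
      ch[c] <- alt
      basis[[length(basis) + 1L]] <- corner_index(tree, ch)
    }
  }
  basis
}

#' Coordinates of a score vector in a corner basis
#'
#' Solves for the convex weights expressing `scores` as a combination of the
#' basis corners (augmented with the constraint that weights sum to 1).
#' Errors if the residual exceeds `tol` ("not in the affine span") or a
#' weight is below `-tol` ("outside the convex hull").
#'
#' @param scores a named numeric score vector on the same leaves.
#' @param basis a list of `corner_index` objects, e.g. from
#'   [caratheodory_basis()].
#' @param tol numeric tolerance.
#' @return a numeric vector of convex weights, one per basis corner. With a
#'   basis from [caratheodory_basis()], weights 2..(d+1) are the
#'   parametrisation relative to the first corner (e.g. `(p, q)` on the
#'   five-leaf caterpillar).
#' @export
corner_coordinates <- function(scores, basis, tol = 1e-9) {
  A <- t(corner_scores(basis))     # leaves x corners
  if (!is.null(names(scores))) scores <- scores[rownames(A)]
  M <- rbind(A, rep(1, ncol(A)))
  b <- c(scores, 1)
  qr_M <- qr(M)
  if (qr_M$rank < ncol(M))
    stop("basis corners are affinely dependent", call. = FALSE)
  w <- qr.coef(qr_M, b)
  resid <- max(abs(M %*% w - b))
  if (resid > tol)
    stop(sprintf("score vector is not in the affine span of the basis (residual %g)",
                 resid), call. = FALSE)
  if (any(w < -tol))
    stop("score vector lies outside the convex hull of the basis",
         call. = FALSE)
  w <- pmax(w, 0)
  names(w) <- vapply(basis, function(co) paste0("B", co$id), character(1))
  w
}

#' Per-leaf score bounds over all diversity indices
#'
#' Any diversity index gives leaf `x` at least its pendant length and at most
#' `sum(l(e) / sigma_x(e))` over the edges of its root path, where
#' `sigma_x(e)` is the size of `x`'s symmetry orbit below `e`.
#'
#' @param tree a `rooted_tree`.
#' @param x a leaf label, or `NULL` for all leaves.
#' @return a data frame with columns `leaf`, `lower`, `upper`.
#' @export
score_bounds <- function(tree, x = NULL) {
  stopifnot(inherits(tree, "rooted_tree"))
  leaves <- if (is.null(x)) tree_leaves(tree) else check_leaf(tree, x)
  rows <- lapply(leaves, function(lf) {
    path <- root_path(tree, lf)
    if (length(path) == 0L) return(data.frame(leaf = lf, lower = 0, upper = 0))
    upper <- sum(vapply(path, function(e)
      tree$length[[e]] / sigma_count(tree, lf, e), numeric(1)))
    data.frame(leaf = lf, lower = unname(tree$length[[lf]]), upper = upper)
  })
  do.call(rbind, rows)
}

local_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code()
}

#' Sample a random consistent diversity index
#'
#' Draws, independently for each `~`-equivalence class, the totals allocated
#' to the distinct child shapes from a flat Dirichlet distribution on the
#' simplex; subtrees sharing a shape split their group's total equally. The
#' result is a class-keyed ratio scheme, reproducible for a fixed seed; on a
#' semi-balanced tree it is the unique index.
#'
#' @param tree a `rooted_tree`.
#' @param seed an integer seed.
#' @return a `ratio_scheme`.
#' @export
sample_index <- function(tree, seed) {
  stopifnot(inherits(tree, "rooted_tree"))
  cls <- equivalence_classes(tree)
  local_seed(seed, function() {
    ratios <- list()
    for (cl in cls$classes) {
      g <- length(cl$child_shapes)
      tot <- if (g == 1L) 1 else {
        z <- rgamma(g, 1)
        z / sum(z)
      }
      kid_codes <- strsplit(cl$signature, "|", fixed = TRUE)[[1]]
      per_pos <- (tot / cl$multiplicity)[match(kid_codes, cl$child_shapes)]
      ratios[[cl$signature]] <- per_pos
    }
    ratio_scheme(ratios)
  })
}

#' Sample a random (not necessarily consistent) diversity index
#'
#' Diversity indices are exactly the matrices that, for each tree shape
#' occurring as a pendant subtree, distribute one unit over the leaf orbits
#' of that shape. This sampler draws a flat Dirichlet over the orbits of
#' every distinct pendant-subtree shape, giving a generic diversity index
#' that is typically not consistent.
#'
#' @param tree a `rooted_tree`.
#' @param seed an integer seed.
#' @return a coefficient matrix.
#' @export
random_index_matrix <- function(tree, seed) {
  stopifnot(inherits(tree, "rooted_tree"))
  edges <- tree_edges(tree)
  local_seed(seed, function() {
    m <- empty_coef_matrix(tree)
    shape_of <- tree$code[edges]
    maps <- list()
    for (e in edges) {
      key <- shape_of[[e]]
      labs <- orbit_labels(tree, e)
      if (is.null(maps[[key]])) {
        sizes <- table(labs)
        z <- rgamma(length(sizes), 1)
        w <- z / sum(z)
        per_leaf <- w / as.numeric(sizes)
        names(per_leaf) <- names(sizes)
        maps[[key]] <- per_leaf
      }
      m[names(labs), e] <- maps[[key]][labs]
    }
    m
  })
}

#' Check two natural properties of a shape-keyed index family
#'
#' For every tree supplied and every edge `e = (u, v)`, consider the group
#' allocation of `e` at its terminal vertex `v`. Property 1 holds when the
#' ratio of allocations depends only on the leaf counts of the maximal
#' pendant subtrees below `v` (not their shapes). Property 2 holds when a
#' subtree with at least as many leaves never receives a smaller allocation.
#' FP and ES satisfy both.
#'
#' @param family an `index_family` or a function mapping a `rooted_tree` to a
#'   coefficient matrix.
#' @param trees a list of `rooted_tree` objects.
#' @param tol numeric tolerance.
#' @return a list with logical flags `property1`, `property2` and a
#'   `violations` data frame.
#' @export
check_family_properties <- function(family, trees, tol = 1e-9) {
  fam <- as_index_family(family)
  if (inherits(trees, "rooted_tree")) trees <- list(trees)
  seen <- list()
  viol <- list()
  p1 <- TRUE
  p2 <- TRUE
  for (ti in seq_along(trees)) {
    tree <- trees[[ti]]
    m <- align_coef_matrix(fam$rule(tree), tree)
    for (v in interior_nonroot(tree)) {
      g <- group_allocation(m, tree, v, v)
      nl <- vapply(tree$cluster[tree$children[[v]]], length, integer(1))
      o <- order(nl, g, method = "radix")
      key <- paste(nl[o], collapse = ",")
      val <- g[o]
      # within a vertex, equal leaf counts must carry equal allocations
      for (cnt in unique(nl)) {
        grp <- g[nl == cnt]
        if (max(grp) - min(grp) > tol) {
          p1 <- FALSE
          viol[[length(viol) + 1L]] <- data.frame(
            property = "property1", tree = ti, vertex = v,
            detail = sprintf("unequal allocation among %d-leaf subtrees", cnt))
        }
      }
      if (is.null(seen[[key]])) seen[[key]] <- list(vertex = v, val = val)
      else if (max(abs(val - seen[[key]]$val)) > tol) {
        p1 <- FALSE
        viol[[length(viol) + 1L]] <- data.frame(
          property = "property1", tree = ti, vertex = v,
          detail = sprintf("ratio differs from vertex '%s' with the same leaf-count profile",
                           seen[[key]]$vertex))
      }
      cmp <- outer(nl, nl, `>=`) & outer(g, g, `<`) &
        outer(g, g, function(a, b) b - a > tol)
      if (any(cmp)) {
        p2 <- FALSE
        viol[[length(viol) + 1L]] <- data.frame(
          property = "property2", tree = ti, vertex = v,
          detail = "a larger subtree receives a smaller allocation")
      }
    }
  }
  violations <- if (length(viol)) do.call(rbind, viol)
  else data.frame(property = character(0), tree = integer(0),
                  vertex = character(0), detail = character(0))
  list(property1 = p1, property2 = p2, violations = violations)
}

#' Plot a two-leaf projection of the index space
#'
#' Projects the corner score vectors onto two leaves' scores (as in the
#' classic picture of the five-leaf caterpillar space), draws the convex
#' hull, and marks the FP and ES indices. Requires `ggplot2`.
#'
#' @param tree a `rooted_tree` with index-space dimension at least 1.
#' @param leaves two leaf labels; defaults to the two leaves whose corner
#'   scores vary most.
#' @param limit passed to [corner_indices()].
#' @return a `ggplot` object.
#' @export
plot_index_space <- function(tree, leaves = NULL, limit = 4096) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("the 'ggplot2' package is required for plot_index_space()",
         call. = FALSE)
  corners <- corner_indices(tree, limit = limit)
  sc <- corner_scores(corners)
  if (is.null(leaves)) {
    spread <- apply(sc, 2, function(z) max(z) - min(z))
    leaves <- colnames(sc)[order(-spread)][1:2]
  }
  stopifnot(length(leaves) == 2L, all(leaves %in% colnames(sc)))
  pts <- data.frame(x = sc[, leaves[1]], y = sc[, leaves[2]],
                    corner = paste0("B", seq_len(nrow(sc))))
  hull <- pts[grDevices::chull(pts$x, pts$y), ]
  fp <- evaluate_index(fp_matrix(tree), tree)
  es <- evaluate_index(es_matrix(tree), tree)
  marks <- data.frame(x = c(fp[leaves[1]], es[leaves[1]]),
                      y = c(fp[leaves[2]], es[leaves[2]]),
                      index = c("FP", "ES"))
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_polygon(data = hull, fill = "grey85", colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$corner),
                       nudge_y = 0.04, size = 3) +
    ggplot2::geom_point(data = marks, colour = "firebrick", size = 2) +
    ggplot2::geom_text(data = marks, ggplot2::aes(label = .data$index),
                       colour = "firebrick", nudge_y = 0.04, size = 3) +
    ggplot2::labs(x = sprintf("score of %s", leaves[1]),
                  y = sprintf("score of %s", leaves[2]),
                  title = "Diversity index space (two-leaf projection)") +
    ggplot2::theme_minimal()
}
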