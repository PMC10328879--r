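# Independent oracles and shared helpers for the suite.

# Brute-force Shapley value of the PD coalition game v(S) = PD of the
# root-spanning subtree of S, over all subsets. Exponential; use on trees
# with at most 7 leaves.
oracle_shapley <- function(tree) {
  X <- tree_leaves(tree)
  n <- length(X)
  edges <- tree_edges(tree)
  clusters <- lapply(edges, function(e) tree_cluster(tree, e))
  lens <- unname(tree$length[edges])
  vfun <- function(S) {
    if (length(S) == 0L) return(0)
    sum(lens[vapply(clusters, function(cl) any(cl %in% S), logical(1))])
  }
  out <- vapply(X, function(x) {
    others <- setdiff(X, x)
    k <- length(others)
    total <- 0
    for (mask in 0:(2^k - 1)) {
      S <- others[bitwAnd(mask, 2^(seq_len(k) - 1L)) > 0]
      w <- factorial(length(S)) * factorial(n - length(S) - 1) / factorial(n)
      total <- total + w * (vfun(c(S, x)) - vfun(S))
    }
    total
  }, numeric(1))
  names(out) <- X
  out
}

oracle_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in oracle_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

# Brute-force rooted shape isomorphism by trying all child matchings.
oracle_iso <- function(tA, a, tB, b) {
  kA <- tA$children[[a]]
  kB <- tB$children[[b]]
  if (length(kA) != length(kB)) return(FALSE)
  if (length(kA) == 0L) return(TRUE)
  for (p in oracle_perms(seq_along(kB))) {
    ok <- TRUE
    for (i in seq_along(kA)) {
      if (!oracle_iso(tA, kA[i], tB, kB[p[i]])) { ok <- FALSE; break }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

named_fixtures <- function() {
  nm <- c("cherry", "cat5", "fig2", "fig3", "fig4a", "fig4b", "balanced8",
          "hominoid")
  stats::setNames(lapply(nm, make_fixture), nm)
}

small_fixtures <- function() {
  fx <- named_fixtures()
  fx[vapply(fx, function(t) length(tree_leaves(t)) <= 7L, logical(1))]
}

# Per-corner mixture weight of a class-keyed scheme: the product over classes
# of the barycentric weight its group totals place on the chosen extreme.
# The score map is multilinear per class, so the flow scores of the scheme
# equal this convex combination of corner scores exactly.
corner_mixture_scores <- function(tree, scheme) {
  cls <- equivalence_classes(tree)
  corners <- corner_indices(tree, limit = 4096)
  wts <- lapply(cls$classes, function(cl) {
    r <- scheme$ratios[[cl$signature]]
    kid <- strsplit(cl$signature, "|", fixed = TRUE)[[1]]
    vapply(seq_along(cl$child_shapes), function(j)
      sum(r[kid == cl$child_shapes[j]]), numeric(1))
  })
  mix <- 0
  for (co in corners) {
    w <- if (length(wts) == 0L) 1
         else prod(mapply(function(wc, ch) wc[ch], wts, co$choice))
    mix <- mix + w * co$scores
  }
  mix
}

corner_affine_rank <- function(tree, limit = 4096) {
  sc <- corner_scores(corner_indices(tree, limit = limit))
  qr(sweep(sc, 2, sc[1, ]), tol = 1e-9)$rank
}
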