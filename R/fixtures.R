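# Worked example trees and a seeded random tree generator. The named
# fixtures all carry unit branch lengths; internal vertex labels name the
# edges discussed with them (e.g. edges g and h of the five-leaf
# caterpillar). The hominoid tree is a transcription of a published
# 25-species Hominoidea phylogeny chosen to realise its documented
# equivalence-class structure: nine one-degree-of-freedom classes (a 2,3
# pair, a 1,2 triple, and distinct classes for the two five-leaf subtree
# shapes) and two zero-degree-of-freedom classes.

fixture_newick <- list(
  cherry = "(x1:1,x2:1);",
  cat5 = "((((x1:1,x2:1)f:1,x3:1)g:1,x4:1)h:1,x5:1);",
  fig2 = "((((x1:1,x2:1)e:1,x3:1)c:1,x4:1)a:1,((x5:1,x6:1)d:1,x7:1)b:1);",
  fig3 = "(((x1:1,x2:1)e6:1,x3:1)e7:1,(x4:1,x5:1)e8:1);",
  fig4a = "(((x1:1,x2:1)f:1,x3:1,x4:1)g:1,x5:1);",
  fig4b = "(((x1:1,x2:1)f:1,(x3:1,x4:1)h:1)g:1,x5:1);",
  balanced8 = "(((x1:1,x2:1):1,(x3:1,x4:1):1):1,((x5:1,x6:1):1,(x7:1,x8:1):1):1);",
  hominoid = local({
    j <- function(a, b) paste0("(", a, ":1,", b, ":1)")
    pair <- j
    homo_pan <- j("Homo_sapiens", pair("Pan_troglodytes", "Pan_paniscus"))
    african <- j(homo_pan, pair("Gorilla_gorilla", "Gorilla_beringei"))
    hominidae <- j(african, pair("Pongo_abelii", "Pongo_pygmaeus"))
    hoolock <- j("Hoolock_hoolock",
                 pair("Hoolock_leuconedys", "Hoolock_tianxing"))
    nomascus <- j(j("Nomascus_concolor",
                    pair("Nomascus_nasutus", "Nomascus_hainanus")),
                  pair("Nomascus_leucogenys", "Nomascus_siki"))
    bal4 <- j(pair("Hylobates_lar", "Hylobates_pileatus"),
              pair("Hylobates_moloch", "Hylobates_agilis"))
    hyl5 <- j(bal4, "Hylobates_muelleri")
    hyl7 <- j(hyl5, pair("Hylobates_klossii", "Hylobates_albibarbis"))
    hyl9 <- j(hyl7, pair("Hylobates_abbotti", "Hylobates_funereus"))
    v1 <- j("Symphalangus_syndactylus", hoolock)
    v2 <- j(v1, nomascus)
    gibbons <- j(v2, hyl9)
    paste0("(", hominidae, ":1,", gibbons, ":1);")
  }))

#' Names of the built-in fixture trees
#'
#' @return a character vector.
#' @export
fixture_names <- function() {
  c(names(fixture_newick), "star", "caterpillar")
}

#' Built-in example trees
#'
#' All fixtures carry unit branch lengths. `"cat5"` is the five-leaf
#' caterpillar (index space of dimension 2 with corners kappa, lambda, mu,
#' nu); `"fig3"` a five-leaf tree with a one-dimensional space; `"fig4a"` a
#' non-binary five-leaf tree (one dimension); `"fig4b"` a semi-balanced
#' five-leaf tree (a single point, FP = ES); `"fig2"` a seven-leaf tree with
#' two isomorphic three-leaf pendant subtrees; `"hominoid"` a 25-species
#' great ape and gibbon phylogeny with a nine-dimensional space; `"cherry"`
#' and `"balanced8"` small balanced shapes; `"star"` and `"caterpillar"`
#' parametric shapes of `n` leaves.
#'
#' @param name a fixture name (see [fixture_names()]).
#' @param n number of leaves, required for `"star"` and `"caterpillar"`.
#' @return a `rooted_tree`.
#' @examples
#' space_dimension(make_fixture("cat5"))
#' @export
make_fixture <- function(name, n = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (name %in% names(fixture_newick))
    return(parse_newick(fixture_newick[[name]]))
  if (name == "star") {
    stopifnot(!is.null(n), n >= 2)
    return(parse_newick(paste0(
      "(", paste0("x", seq_len(n), ":1", collapse = ","), ");")))
  }
  if (name == "caterpillar") {
    stopifnot(!is.null(n), n >= 2)
    core <- paste0("(x1:1,x2:1)")
    for (k in seq_len(n - 2L) + 2L) core <- paste0("(", core, ":1,x", k, ":1)")
    return(parse_newick(paste0(core, ";")))
  }
  stop(sprintf("unknown fixture '%s'", name), call. = FALSE)
}

#' Random rooted phylogenetic tree
#'
#' Builds a binary tree by attaching leaves one at a time above an edge
#' chosen uniformly at random, then contracts each interior non-root edge
#' independently with probability `multifurcation_prob`. Branch lengths are
#' 1 unless a `lengths` sampler is supplied. Reproducible for a fixed seed.
#'
#' @param n number of leaves (`n = 1` gives the single-vertex tree).
#' @param seed integer seed.
#' @param multifurcation_prob probability in `[0, 1)` of contracting each
#'   interior non-root edge.
#' @param lengths `NULL` for unit lengths, or a function of one argument (the
#'   number of edges) returning positive lengths, applied in canonical edge
#'   order.
#' @return a `rooted_tree` with leaves `x1 ... xn`.
#' @export
random_tree <- function(n, seed, multifurcation_prob = 0, lengths = NULL) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1,
            multifurcation_prob >= 0, multifurcation_prob < 1)
  n <- as.integer(n)
  if (n == 1L) return(parse_newick("x1;"))
  local_seed(seed, function() {
    parent <- c(x1 = "r", x2 = "r")
    for (k in seq_len(n - 2L) + 2L) {
      target <- sample(names(parent), 1L)
      newint <- paste0("i", k)
      leaf <- paste0("x", k)
      parent[newint] <- parent[[target]]
      parent[target] <- newint
      parent[leaf] <- newint
    }
    kids_of <- split(names(parent), parent)
    build <- function(v) {
      kids <- kids_of[[v]]
      if (is.null(kids))
        new_node(label = v, length = 1)
      else
        new_node(label = if (grepl("^x", v)) v else NA_character_,
                 length = if (v == "r") NA_real_ else 1,
                 children = lapply(kids, build))
    }
    tree <- build_rooted_tree(build("r"))
    if (multifurcation_prob > 0) {
      for (e in interior_edges(tree)) {
        if (runif(1) < multifurcation_prob)
          tree <- contract_edge(tree, e)
      }
    }
    if (!is.null(lengths)) {
      m <- length(tree_edges(tree))
      tree <- set_edge_lengths(tree, lengths(m))
    }
    tree
  })
}
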