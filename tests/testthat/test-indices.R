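test_that("FP and ES coefficients match the worked values", {
  fig3 <- make_fixture("fig3")
  expect_equal(fp_matrix(fig3)["x3", "e7"], 1 / 3)
  expect_equal(es_matrix(fig3)["x3", "e7"], 1 / 2)
  cat5 <- make_fixture("cat5")
  expect_equal(fp_matrix(cat5)["x3", "h"], 1 / 4)
  expect_equal(es_matrix(cat5)["x1", "h"], 1 / 8)
  # pendant columns are unit indicators for both indices
  for (m in list(fp_matrix(cat5), es_matrix(cat5))) {
    for (x in tree_leaves(cat5)) {
      expect_equal(unname(m[x, x]), 1)
      expect_equal(sum(m[, x]), 1)
    }
  }
})

test_that("index evaluation reproduces hand-computed scores", {
  cat5 <- make_fixture("cat5")
  fp <- evaluate_index(fp_matrix(cat5), cat5)
  expect_equal(unname(fp["x3"]), 19 / 12)
  expect_equal(unname(fp["x1"]), 25 / 12)
  es <- evaluate_index(es_matrix(cat5), cat5)
  expect_equal(unname(es["x1"]), 1.875)
  expect_equal(evaluate_index(fp_matrix(parse_newick("x1;")),
                              parse_newick("x1;")),
               c(x1 = 0))
})

test_that("the one-dimensional family on the non-binary five-leaf tree matches its closed form", {
  f4a <- make_fixture("fig4a")
  sig <- class_signature(f4a, "g")
  kid <- f4a$children[["g"]]          # canonical order: cherry f, then leaves
  expect_equal(kid[1], "f")
  for (alpha in c(0, 0.2, 1 / 3, 0.5)) {
    sch <- ratio_scheme(stats::setNames(
      list(c(1 - 2 * alpha, alpha, alpha)), sig))
    l <- stats::setNames(seq(0.5, by = 0.25,
                             length.out = length(tree_edges(f4a))),
                         tree_edges(f4a))
    tr <- set_edge_lengths(f4a, l)
    sc <- flow_scores(tr, sch)
    expect_equal(unname(sc["x3"]), alpha * l[["g"]] + l[["x3"]])
    expect_equal(unname(sc["x1"]),
                 (1 - 2 * alpha) / 2 * l[["g"]] + l[["f"]] / 2 + l[["x1"]])
    expect_equal(unname(sc["x5"]), l[["x5"]])
  }
})

test_that("allocation validation accepts and rejects the textbook examples", {
  two <- parse_newick("(x:1,y:1);")
  sigma <- matrix(c(2, 2, -1, -1), nrow = 2, byrow = TRUE,
                  dimnames = list(c("x", "y"), c("x", "y")))
  rep <- check_allocation(sigma, two)
  expect_false(rep$is_allocation)
  expect_true("nonneg" %in% rep$violations$rule)

  cat5 <- make_fixture("cat5")
  expect_true(check_allocation(uniform_matrix(cat5), cat5)$is_allocation)
  expect_true(check_allocation(fp_matrix(cat5), cat5)$is_allocation)
  uni <- check_diversity_index(uniform_matrix(cat5), cat5)
  expect_false(uni$is_diversity_index)
  expect_true("DI1" %in% uni$violations$rule)
})

test_that("neutrality violations across same-shape subtrees are reported", {
  fig2 <- make_fixture("fig2")
  m <- fp_matrix(fig2)
  expect_true(check_diversity_index(m, fig2)$is_diversity_index)
  # break gamma(x7, b) = gamma(x3, c) while keeping column sums
  m2 <- m
  m2["x7", "b"] <- m2["x7", "b"] + 0.1
  m2["x5", "b"] <- m2["x5", "b"] - 0.05
  m2["x6", "b"] <- m2["x6", "b"] - 0.05
  rep2 <- check_diversity_index(m2, fig2)
  expect_false(rep2$is_diversity_index)
  expect_true(rep2$is_allocation)
  expect_true(any(rep2$violations$rule == "DI2"))
  # break the within-edge orbit equality gamma(x1, c) = gamma(x2, c)
  m3 <- m
  m3["x1", "c"] <- m3["x1", "c"] + 0.1
  m3["x2", "c"] <- m3["x2", "c"] - 0.1
  rep3 <- check_diversity_index(m3, fig2)
  expect_false(rep3$is_diversity_index)
  expect_true(any(rep3$violations$rule == "DI2"))
})

test_that("FP, ES and sampled matrices are diversity indices on random trees", {
  for (i in 1:30) {
    tr <- random_tree(2 + (i %% 9), seed = 1100 + i,
                      multifurcation_prob = 0.2)
    expect_true(check_diversity_index(fp_matrix(tr), tr)$is_diversity_index)
    expect_true(check_diversity_index(es_matrix(tr), tr)$is_diversity_index)
    expect_true(check_diversity_index(random_index_matrix(tr, 1100 + i),
                                      tr)$is_diversity_index)
  }
})

test_that("convex combinations blend scores linearly", {
  cat5 <- make_fixture("cat5")
  fp <- fp_matrix(cat5)
  es <- es_matrix(cat5)
  mid <- convex_combine(list(fp, es), c(0.5, 0.5))
  expect_true(check_diversity_index(mid, cat5)$is_diversity_index)
  expect_equal(evaluate_index(mid, cat5),
               (evaluate_index(fp, cat5) + evaluate_index(es, cat5)) / 2)
  expect_equal(convex_combine(list(fp, es), c(1, 0)), fp)
  expect_error(convex_combine(list(fp, es), c(0.7, 0.7)), "sum to 1")
  expect_error(convex_combine(list(fp, es), c(1.5, -0.5)), "non-negative")
})

test_that("scores conserve PD and are linear in the lengths", {
  for (i in 1:20) {
    tr <- random_tree(2 + (i %% 8), seed = 1200 + i,
                      multifurcation_prob = 0.25)
    edges <- tree_edges(tr)
    mats <- list(fp_matrix(tr), es_matrix(tr),
                 random_index_matrix(tr, 1200 + i))
    l1 <- stats::setNames(runif(length(edges), 0.5, 2), edges)
    l2 <- stats::setNames(runif(length(edges), 0.1, 1), edges)
    s <- 0.7; t <- 1.9
    for (m in mats) {
      expect_equal(sum(evaluate_index(m, tr)), total_pd(tr))
      expect_equal(
        evaluate_index(m, tr, lengths = s * l1 + t * l2),
        s * evaluate_index(m, tr, lengths = l1) +
          t * evaluate_index(m, tr, lengths = l2))
    }
  }
})

test_that("FP equals the brute-force Shapley value on small fixtures", {
  for (tr in small_fixtures()) {
    expect_equal(evaluate_index(fp_matrix(tr), tr), oracle_shapley(tr),
                 tolerance = 1e-12)
  }
})

test_that("FP and ES coincide exactly on semi-balanced binary trees", {
  hits <- 0L
  for (i in 1:60) {
    tr <- random_tree(2 + (i %% 8), seed = 1300 + i)
    same <- max(abs(evaluate_index(fp_matrix(tr), tr) -
                      evaluate_index(es_matrix(tr), tr))) <= 1e-12
    expect_equal(same, is_semi_balanced(tr))
    if (same) hits <- hits + 1L
  }
  expect_gt(hits, 0L)   # both sides of the equivalence were exercised
  expect_lt(hits, 60L)
})

test_that("coefficient matrices round-trip through TSV with fractions", {
  cat5 <- make_fixture("cat5")
  f <- tempfile(fileext = ".tsv")
  write_coef_matrix(fp_matrix(cat5), f)
  expect_equal(read_coef_matrix(f, cat5), fp_matrix(cat5))
  # hand-written fractions
  lines <- c(paste(c("leaf", tree_edges(cat5)), collapse = "\t"))
  m <- fp_matrix(cat5)
  for (x in rownames(m)) {
    ent <- ifelse(m[x, ] == 0, "0",
                  paste0("1/", as.integer(round(1 / pmax(m[x, ], 1e-9)))))
    lines <- c(lines, paste(c(x, ent), collapse = "\t"))
  }
  writeLines(lines, f)
  expect_equal(read_coef_matrix(f, cat5), m)
  unlink(f)
})
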