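test_that("the caterpillar's four corners carry the four worked corner score vectors", {
  cat5 <- make_fixture("cat5")
  corners <- corner_indices(cat5)
  expect_length(corners, 4L)
  sc <- corner_scores(corners)
  expected <- rbind(c(2.5, 2.5, 1, 1, 1),
                    c(1.5, 1.5, 3, 1, 1),
                    c(2, 2, 1, 2, 1),
                    c(1.5, 1.5, 2, 2, 1))
  dimnames(expected) <- dimnames(sc)
  expect_equal(sc, expected)
})

test_that("corner enumeration respects the space structure", {
  f4b <- make_fixture("fig4b")
  co <- corner_indices(f4b)
  expect_length(co, 1L)
  expect_equal(co[[1]]$scores, evaluate_index(fp_matrix(f4b), f4b))
  h <- make_fixture("hominoid")
  expect_equal(corner_count(h), 512)
  expect_error(corner_indices(h, limit = 100), "corner_index")
  expect_length(corner_indices(h, limit = 512), 512L)
  # single corners are addressable without materialising the set
  c17 <- corner_index(h, 17)
  expect_equal(c17$id, 17L)
  expect_equal(sum(c17$scores), total_pd(h))
})

test_that("corner coordinates recover the printed FP and ES positions", {
  cat5 <- make_fixture("cat5")
  co <- corner_indices(cat5)
  basis <- co[c(1, 2, 3)]          # kappa, lambda, mu
  w_fp <- corner_coordinates(evaluate_index(fp_matrix(cat5), cat5), basis)
  expect_equal(unname(w_fp), c(1 - 7 / 24 - 1 / 4, 7 / 24, 1 / 4))
  w_es <- corner_coordinates(evaluate_index(es_matrix(cat5), cat5), basis)
  expect_equal(unname(w_es), c(1 - 9 / 24 - 1 / 2, 9 / 24, 1 / 2))
  expect_equal(unname(corner_coordinates(co[[1]]$scores, basis)), c(1, 0, 0))
  # nu lies outside the kappa/lambda/mu triangle
  expect_error(corner_coordinates(co[[4]]$scores, basis), "outside")
  # a vector off the affine span is rejected
  off <- co[[1]]$scores + c(0.3, -0.3, 0, 0, 0)
  expect_error(corner_coordinates(off, basis), "affine span")
})

test_that("the Caratheodory basis construction yields d + 1 corners", {
  cat5 <- make_fixture("cat5")
  b <- caratheodory_basis(cat5)
  expect_length(b, space_dimension(cat5) + 1L)
  expect_equal(b[[1]]$choice, c(`((()())())|()` = 1L, `(()())|()` = 1L,
                                `()|()` = 1L))
  for (k in 2:3) expect_equal(sum(b[[k]]$choice != b[[1]]$choice), 1L)
  expect_length(caratheodory_basis(make_fixture("fig3")), 2L)
  f4b_b <- caratheodory_basis(make_fixture("fig4b"))
  expect_length(f4b_b, 1L)
  expect_equal(f4b_b[[1]]$scores,
               evaluate_index(fp_matrix(make_fixture("fig4b")),
                              make_fixture("fig4b")))
})

test_that("score bounds bracket every index and match hand values", {
  cat5 <- make_fixture("cat5")
  b <- score_bounds(cat5)
  expect_equal(b$lower[b$leaf == "x1"], 1)
  expect_equal(b$upper[b$leaf == "x1"], 2.5)
  expect_equal(b$upper[b$leaf == "x3"], 3)
  expect_equal(b$upper[b$leaf == "x5"], 1)
  expect_equal(b$lower, rep(1, 5))
  for (i in 1:12) {
    tr <- random_tree(2 + (i %% 8), seed = 1900 + i,
                      multifurcation_prob = 0.2)
    bb <- score_bounds(tr)
    mats <- list(fp_matrix(tr), es_matrix(tr),
                 random_index_matrix(tr, 1900 + i),
                 ratios_to_matrix(tr, sample_index(tr, 1900 + i)))
    for (m in mats) {
      sc <- evaluate_index(m, tr)[bb$leaf]
      expect_true(all(sc >= bb$lower - 1e-9))
      expect_true(all(sc <= bb$upper + 1e-9))
    }
    # corners saturate the upper bound for some leaf somewhere unless forced
    co <- corner_scores(corner_indices(tr, 4096))
    expect_true(all(t(co) >= bb$lower - 1e-9 & t(co) <= bb$upper + 1e-9))
  }
})

test_that("sampled indices are valid, reproducible and inside the corner hull", {
  cat5 <- make_fixture("cat5")
  expect_equal(sample_index(cat5, 7)$ratios, sample_index(cat5, 7)$ratios)
  # semi-balanced: the unique index equals FP for every seed
  f4b <- make_fixture("fig4b")
  for (s in 1:5) {
    expect_equal(flow_scores(f4b, sample_index(f4b, s)),
                 evaluate_index(fp_matrix(f4b), f4b))
  }
  # multilinear expansion: scheme scores equal the product-weighted corner mix
  for (i in 1:25) {
    tr <- random_tree(3 + (i %% 7), seed = 2000 + i,
                      multifurcation_prob = 0.2)
    sch <- sample_index(tr, 2000 + i)
    m <- ratios_to_matrix(tr, sch)
    expect_true(check_diversity_index(m, tr)$is_diversity_index)
    expect_true(is_consistent(m, tr))
    expect_equal(corner_mixture_scores(tr, sch), flow_scores(tr, sch),
                 tolerance = 1e-12)
  }
})

test_that("pairwise blends of indices stay in the space (convexity)", {
  for (i in 1:10) {
    tr <- random_tree(3 + (i %% 6), seed = 2100 + i,
                      multifurcation_prob = 0.2)
    m1 <- ratios_to_matrix(tr, sample_index(tr, 2100 + i))
    m2 <- random_index_matrix(tr, 4100 + i)
    t0 <- runif(1)
    blend <- convex_combine(list(m1, m2), c(t0, 1 - t0))
    expect_true(check_diversity_index(blend, tr)$is_diversity_index)
    expect_equal(evaluate_index(blend, tr),
                 t0 * evaluate_index(m1, tr) +
                   (1 - t0) * evaluate_index(m2, tr))
  }
})

test_that("corner affine rank matches the combinatorial dimension on the five-leaf examples", {
  for (nm in c("cat5", "fig3", "fig4a", "fig4b", "cherry", "balanced8")) {
    tr <- make_fixture(nm)
    expect_equal(corner_affine_rank(tr), space_dimension(tr))
  }
  # The combinatorial count is a lower bound in general: when one
  # equivalence class has members in different ancestral contexts the
  # corners span additional affine directions (the hominoid tree does).
  for (i in 1:40) {
    tr <- random_tree(3 + (i %% 8), seed = 2200 + i,
                      multifurcation_prob = 0.2)
    expect_gte(corner_affine_rank(tr), space_dimension(tr))
  }
  h <- make_fixture("hominoid")
  expect_equal(space_dimension(h), 9L)
  expect_equal(corner_affine_rank(h, limit = 512), 12L)
})

test_that("FP and ES satisfy the leaf-count monotonicity properties; corner families need not", {
  trees <- list(make_fixture("cat5"), make_fixture("fig3"),
                make_fixture("fig2"), random_tree(8, 11, 0.3))
  fp_rep <- check_family_properties(fp_family(), trees)
  expect_true(fp_rep$property1)
  expect_true(fp_rep$property2)
  es_rep <- check_family_properties(es_family(), trees)
  expect_true(es_rep$property1)
  expect_true(es_rep$property2)
  cat5 <- make_fixture("cat5")
  lam <- corner_index(cat5, c(1L, 2L, 1L))   # all of edge g onto leaf x3
  lam_rep <- check_family_properties(
    function(tree) ratios_to_matrix(tree, lam$scheme), cat5)
  expect_false(lam_rep$property2)
})

test_that("the two-leaf projection plot builds", {
  skip_if_not_installed("ggplot2")
  p <- plot_index_space(make_fixture("cat5"), leaves = c("x3", "x4"))
  expect_s3_class(p, "ggplot")
})
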