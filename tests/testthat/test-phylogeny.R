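test_that("load_tree parses and validates small trees", {
  tr <- load_tree("(A:1,B:1);")
  expect_equal(length(tr$tip.label), 2L)
  expect_equal(unname(tip_depths(tr)), c(1, 1))

  tr3 <- load_tree("((A:1,B:1):1,C:2);")
  expect_equal(unname(tip_depths(tr3)), c(2, 2, 2))

  expect_error(suppressWarnings(load_tree("((A:1,B:1")), "malformed")
  expect_error(load_tree("((A:1,A:1):1,C:2);"), "duplicate")
  expect_warning(load_tree("((A:1,B:1.5):1,C:2);"), "ultrametric")
})

test_that("graft_split attaches a calibrated sister pair and stays ultrametric", {
  tr <- load_tree("((A:1,B:1):1,C:2);")
  g <- graft_split(tr, "A", "A2", 0.4)
  expect_setequal(g$tip.label, c("A", "B", "C", "A2"))
  expect_equal(mrca_age(g, c("A", "A2")), 0.4)
  expect_equal(unname(tip_depths(g)), rep(2, 4))
  # boundary: split at the parent's age is invalid
  expect_error(graft_split(tr, "A", "A2", 1), "parent")
  expect_error(graft_split(tr, "Z", "A2", 0.4), "not in tree")
  expect_error(graft_split(tr, "A", "B", 0.4), "already present")
})

test_that("assembled 33-species tree carries the calibrated robin and dog/wolf splits", {
  tr <- example_timetree()
  expect_equal(length(tr$tip.label), 33L)
  dep <- tip_depths(tr)
  expect_lt(diff(range(dep)), 1e-8 * mean(dep))
  expect_equal(mrca_age(tr, c("North_Island_robin", "South_Island_robin")), 3)
  expect_equal(mrca_age(tr, c("dog", "wolf")), 0.015)
})

test_that("tree_to_correlation matches hand-computed and degenerate cases", {
  tr3 <- load_tree("((A:1,B:1):1,C:2);")
  V <- tree_to_correlation(tr3)$V
  expect_equal(unname(V),
               matrix(c(1, 0.5, 0, 0.5, 1, 0, 0, 0, 1), 3), tolerance = 1e-12)
  # star tree: no shared internal branches
  star <- load_tree("(A:1,B:1,C:1);")
  expect_equal(unname(tree_to_correlation(star)$V), diag(3))
  # single cherry shares only the root
  expect_equal(unname(tree_to_correlation(load_tree("(A:1,B:1);"))$V), diag(2))
  expect_error(tree_to_correlation(tr3, c("A", "Z")), "not in tree")
})

test_that("tree_to_correlation agrees with a brute-force MRCA path-sum oracle", {
  for (seed in 1:5) {
    tr <- simulate_tree(10, seed = seed)
    V <- tree_to_correlation(tr)$V
    expect_equal(V, brute_force_correlation(tr), tolerance = 1e-10)
    # positive semidefinite after tiny jitter
    expect_no_error(chol(V + 1e-9 * diag(10)))
  }
})

test_that("lambda_mix is the linear identity-V mix with endpoints exact", {
  tr3 <- load_tree("((A:1,B:1):1,C:2);")
  cv <- tree_to_correlation(tr3)
  expect_equal(lambda_mix(cv, 0)$M, diag(3), ignore_attr = TRUE)
  expect_equal(lambda_mix(cv, 1)$M, cv$V)
  half <- lambda_mix(cv, 0.5)$M
  expect_equal(half["A", "B"], 0.25)
  expect_equal(diag(half), c(A = 1, B = 1, C = 1))
  # linearity in lambda
  expect_equal(lambda_mix(cv, 0.3)$M,
               0.6 * lambda_mix(cv, 0.5)$M + 0.4 * diag(3), ignore_attr = TRUE)
  # PSD across lambda values
  for (lam in c(0.1, 0.5, 0.9)) {
    expect_true(all(eigen(lambda_mix(cv, lam)$M)$values > -1e-12))
  }
  expect_error(lambda_mix(cv, 1.2), "0, 1")
  expect_error(lambda_mix(cv, -0.1), "0, 1")
})

test_that("pgls_residuals reduces to OLS under identity and is exact on linear data", {
  set.seed(4)
  n <- 12
  idcov <- structure(list(labels = letters[1:n], V = diag(n), M = NULL, lambda = NULL),
                     class = "species_cov")
  x <- rnorm(n); y <- 1 + 2 * x + rnorm(n)
  expect_equal(unname(pgls_residuals(y, x, idcov)),
               unname(resid(lm(y ~ x))), tolerance = 1e-8)
  expect_equal(unname(pgls_residuals(3 - 0.5 * x, x, idcov)), rep(0, n),
               tolerance = 1e-10)
  expect_error(pgls_residuals(y, rep(1, n), idcov), "singular")
})

test_that("pgls_residuals matches a brute-force GLS oracle and nlme::gls", {
  tr3 <- load_tree("((A:1,B:1):1,C:2);")
  cv <- tree_to_correlation(tr3)
  y <- c(2.0, 1.1, -0.4); x <- c(0.5, -0.2, 1.3)
  expect_equal(unname(pgls_residuals(y, x, cv)),
               brute_force_gls_residuals(y, x, cv$V), tolerance = 1e-10)

  skip_if_not_installed("nlme")
  tr <- simulate_tree(12, seed = 9)
  cv12 <- tree_to_correlation(tr)
  set.seed(10)
  x12 <- rnorm(12); y12 <- 0.5 + 0.8 * x12 + rnorm(12)
  df <- data.frame(y = y12, x = x12, species = cv12$labels)
  gfit <- nlme::gls(y ~ x, data = df,
                    correlation = ape::corBrownian(1, tr, form = ~species))
  expect_equal(unname(pgls_residuals(y12, x12, cv12)),
               as.vector(resid(gfit, type = "response")), tolerance = 1e-6,
               ignore_attr = TRUE)
})
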