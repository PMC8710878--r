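test_that("ECV conversion uses brain tissue density 1.036 g/cm^3", {
  expect_equal(ecv_from_brain_mass(1.036), 1)
  expect_equal(ecv_from_brain_mass(2.072), 2)
  expect_equal(ecv_from_brain_mass(420), 420 / 1.036)
  expect_error(ecv_from_brain_mass(-1), "positive")
})

test_that("primate neuron scaling rules reproduce their coefficients", {
  expect_equal(primate_cortex_neurons(1), 37813551.018)
  expect_equal(primate_cortex_neurons(2), 37813551.018 * 2^0.891)
  expect_equal(primate_cerebellum_neurons(1), 69640042.656)
  expect_equal(primate_cerebellum_neurons(10), 69640042.656 * 10^0.936)
  expect_error(primate_cortex_neurons(0), "positive")
  expect_error(primate_cerebellum_neurons(-3), "positive")
  # measured data always win: imputation over a measured value refuses
  expect_error(primate_cortex_neurons(2, measured = 5e9), "refusing")
})

test_that("count imputation fills only missing primates and is idempotent", {
  tab <- data.frame(
    species = c("chimp", "lemur", "dog"),
    cortex_neurons = c(6e9, NA, NA),
    cortex_neuron_density = c(NA, NA, NA)
  )
  bm <- c(chimp = 400, lemur = 25, dog = 95)
  prim <- c(chimp = TRUE, lemur = TRUE, dog = FALSE)
  out <- impute_neuron_counts(tab, bm, prim, "cortex_neurons")
  expect_equal(out$cortex_neurons[1], 6e9)             # measured untouched
  expect_equal(out$cortex_neurons[2], primate_cortex_neurons(25))
  expect_true(is.na(out$cortex_neurons[3]))            # non-primate left alone
  expect_identical(impute_neuron_counts(out, bm, prim, "cortex_neurons")$cortex_neurons,
                   out$cortex_neurons)
  expect_equal(unname(attr(out, "provenance")$cortex_neurons["lemur"]),
               "scaled_from_brain_mass")
  expect_error(impute_neuron_counts(tab, bm, prim, "cortex_neuron_density"),
               "density")
})

test_that("cognition score reversal inverts the ranking exactly", {
  expect_equal(reverse_cognition_score(c(1, 2, 3)), c(-1, -2, -3))
  expect_equal(reverse_cognition_score(rep(2, 4)), rep(-2, 4))
  set.seed(1)
  raw <- rnorm(20)
  expect_equal(cor(raw, reverse_cognition_score(raw), method = "spearman"), -1)
  expect_error(reverse_cognition_score(numeric(0)), "empty")
})

test_that("apply_transforms logs exactly the size-like columns", {
  tab <- data.frame(
    species = c("a", "b"),
    ecv = c(1, exp(2)),
    group_size = c(exp(1), 10),
    pct_fruit = c(40, 60),
    self_control = c(0.5, 0.7),
    cerebellum_neurons = c(1e9, 2e9)
  )
  out <- apply_transforms(tab)
  expect_equal(out$ecv, c(0, 2))
  expect_equal(out$group_size[1], 1)
  expect_equal(out$pct_fruit, c(40, 60))          # not in the log list
  expect_equal(out$self_control, c(0.5, 0.7))
  expect_setequal(attr(out, "log_columns"),
                  c("ecv", "group_size", "cerebellum_neurons"))
  bad <- tab; bad$ecv[2] <- -1
  expect_error(apply_transforms(bad), "ecv.*b|b.*ecv")
})

test_that("residual brain volume is GLS-orthogonal to log body mass", {
  tr <- simulate_tree(12, seed = 21)
  cv <- tree_to_correlation(tr)
  set.seed(22)
  bm <- exp(rnorm(12, 8, 1))
  tab <- data.frame(species = cv$labels,
                    ecv = exp(0.7 * log(bm) + rnorm(12, 0, 0.3)),
                    body_mass = bm)
  out <- apply_transforms(tab, cov = cv)
  expect_true("rbv" %in% names(out))
  X <- cbind(1, log(bm))
  Vi <- solve(cv$V)
  # residual orthogonality under the fitting covariance
  expect_lt(max(abs(t(X) %*% Vi %*% out$rbv)), 1e-8)
})

test_that("predictor tables round-trip through CSV with metadata sidecar", {
  tab <- data.frame(species = c("chimp", "lemur", "dog"),
                    ecv = c(380, 23, NA),
                    cortex_neurons = c(6e9, NA, NA))
  bm <- c(chimp = 400, lemur = 25, dog = 95)
  prim <- c(chimp = TRUE, lemur = TRUE, dog = FALSE)
  tab <- impute_neuron_counts(tab, bm, prim, "cortex_neurons")
  tab <- apply_transforms(tab)
  path <- withr::local_tempfile(fileext = ".csv")
  write_predictor_table(tab, path, units = list(ecv = "log cm^3"))
  back <- read_predictor_table(path)
  expect_equal(back$ecv, tab$ecv)
  expect_equal(attr(back, "log_columns"), attr(tab, "log_columns"))
  prov <- attr(back, "provenance")
  expect_equal(unname(prov$cortex_neurons[c("chimp", "lemur", "dog")]),
               c("measured", "scaled_from_brain_mass", "missing"))
  expect_equal(unname(prov$ecv["dog"]), "missing")
  expect_equal(attr(back, "units")$ecv, "log cm^3")
})
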