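test_that("fit returns well-formed draws and validates its inputs", {
  d <- toy_dataset(4, seed = 51, trials_per_subject = c(10, 10))
  spec <- model_spec(predictor = "x", chains = 2, warmup = 80, draws = 50, seed = 2)
  ft <- suppressWarnings(fit(d$sim$trials, d$sim$predictors, d$cov, spec))
  expect_s3_class(ft, "weber_fit")
  expect_equal(dim(ft$draws)[1:2], c(50L, 2L))
  pn <- dimnames(ft$draws)[[3]]
  expect_true(all(c("beta0", "beta1", "lambda", "sigma_species", "sigma_study",
                    "sigma_subject", "sigma_task") %in% pn))
  lam <- as.vector(ft$draws[, , "lambda"])
  expect_true(all(lam >= 0 & lam <= 1))
  expect_true(all(is.finite(ft$draws)))

  # species in the data but not in the tree abort
  tr_bad <- d$sim$trials
  tr_bad$species[1] <- "martian"
  expect_error(fit(tr_bad, d$sim$predictors, d$cov, spec), "absent from the tree")
  # unknown paradigm aborts
  tr_bad2 <- d$sim$trials
  tr_bad2$task[1] <- "telepathy"
  expect_error(fit(tr_bad2, d$sim$predictors, d$cov, spec), "paradigm")
  # all-equal quantity pairs carry no information
  tr_flat <- d$sim$trials
  tr_flat$n1 <- tr_flat$n2
  expect_error(fit(tr_flat, d$sim$predictors, d$cov, spec), "informative")
})

test_that("species missing the predictor are dropped with a message", {
  d <- toy_dataset(5, seed = 52, trials_per_subject = c(6, 6))
  preds <- d$sim$predictors
  preds$x[1] <- NA
  spec <- model_spec(predictor = "x", chains = 2, warmup = 50, draws = 30, seed = 3)
  expect_message(
    ft <- suppressWarnings(fit(d$sim$trials, preds, d$cov, spec)),
    "dropping species"
  )
  expect_equal(length(ft$data$species), 4L)
  expect_false(preds$species[1] %in% ft$data$species)
})

test_that("with one species and lambda 0 the fit matches a grid-search ML estimate", {
  tree <- simulate_tree(2, seed = 53)
  cfg <- simulation_config(
    n_species = 2, n_studies = 1, subjects_per_species = c(1, 1),
    trials_per_subject = c(600, 600), beta0 = log(0.3),
    sigma_species = 0, sigma_study = 0, sigma_subject = 0, sigma_task = 0,
    seed = 54)
  sim <- simulate_dataset(tree, cfg)
  one <- sim$trials[sim$trials$species == sim$trials$species[1], ]
  cov <- tree_to_correlation(tree, unique(one$species))
  spec <- model_spec(predictor = NULL, chains = 2, warmup = 250, draws = 250,
                     seed = 4, lambda_fixed = 0)
  ft <- suppressWarnings(fit(one, NULL, cov, spec))

  # independent oracle: profile the single-w likelihood on a grid
  grid <- seq(0.05, 1.5, by = 0.002)
  ll <- vapply(grid, function(w) {
    p <- predict_accuracy(one$n1, one$n2, w)
    sum(ifelse(one$correct == 1, log(p), log(1 - p)))
  }, 0)
  w_ml <- grid[which.max(ll)]

  # the identified quantity is the trial-level w of the single subject:
  # the sum of the intercept and all effect components
  comps <- c("beta0", paste0("species[", one$species[1], "]"),
             paste0("study[", one$study[1], "]"),
             paste0("subject[", one$subject[1], "]"),
             paste0("task[", one$task[1], "]"))
  lw <- rowSums(sapply(comps, function(p) as.vector(ft$draws[, , p])))
  w_post <- exp(lw)
  expect_gt(w_ml, quantile(w_post, 0.025))
  expect_lt(w_ml, quantile(w_post, 0.975))
  expect_lt(abs(median(w_post) - w_ml) / w_ml, 0.15)

  # the species-level marginal w still brackets the ML value
  ws <- species_weber_summary(ft)
  expect_equal(nrow(ws), 1L)
  expect_gt(w_ml, ws$w2.5)
  expect_lt(w_ml, ws$w97.5)
})

test_that("species Weber summaries are exp-monotone and recover a common truth", {
  # all species share w = 0.3; medians should bracket it
  tree <- simulate_tree(5, seed = 55)
  cfg <- simulation_config(
    n_species = 5, n_studies = 3, subjects_per_species = c(5, 5),
    trials_per_subject = c(45, 45), beta0 = log(0.3),
    sigma_species = 0.05, sigma_study = 0.05, sigma_subject = 0.1,
    sigma_task = 0.05, seed = 56)
  sim <- simulate_dataset(tree, cfg)
  cov <- tree_to_correlation(tree)
  spec <- model_spec(predictor = NULL, chains = 2, warmup = 300, draws = 300, seed = 5)
  ft <- suppressWarnings(fit(sim$trials, NULL, cov, spec))
  ws <- species_weber_summary(ft)
  expect_equal(ws$species, ft$data$species)
  # quantiles monotone across probability levels
  expect_true(all(ws$w2.5 <= ws$w25 & ws$w25 <= ws$w50 &
                  ws$w50 <= ws$w75 & ws$w75 <= ws$w97.5))
  # exp monotonicity: w-scale quantiles = exp(log-scale quantiles)
  b0 <- as.vector(ft$draws[, , "beta0"])
  sp1 <- as.vector(ft$draws[, , paste0("species[", ws$species[1], "]")])
  # equal up to quantile interpolation (exp of an average of two middle
  # log values differs from the average of their exps at ~1e-6)
  expect_equal(ws$w50[1], exp(median(b0 + sp1)), tolerance = 1e-5)
  # true common w inside the central 50% interval for most species
  hits <- mean(ws$w25 <= 0.3 & 0.3 <= ws$w75)
  expect_gte(hits, 0.5)
})

test_that("model_spec round-trips through a JSON config file", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(predictor = "group_size", chains = 2, warmup = 50,
                            draws = 40, seed = 3, lambda_fixed = 0.5),
                       path, auto_unbox = TRUE)
  spec <- model_spec_from_json(path)
  expect_s3_class(spec, "model_spec")
  expect_equal(spec$predictor, "group_size")
  expect_equal(spec$chains, 2L)
  expect_equal(spec$lambda_fixed, 0.5)

  jsonlite::write_json(list(chains = 2, wrmup = 50), path, auto_unbox = TRUE)
  expect_error(model_spec_from_json(path), "unknown")
})
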