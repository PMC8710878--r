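# quick synthetic dataset at a chosen scale
toy_dataset <- function(n_species = 6, seed = 1, tree_seed = seed + 500, ...) {
  tree <- simulate_tree(n_species, seed = tree_seed)
  cfg <- simulation_config(n_species = n_species, seed = seed, ...)
  list(tree = tree, cov = tree_to_correlation(tree),
       sim = simulate_dataset(tree, cfg), cfg = cfg)
}

# random parameter point matching a dataset's labels, for likelihood tests
random_params <- function(sim, seed = 1, with_x = FALSE) {
  set.seed(seed)
  species <- unique(sim$trials$species)
  studies <- unique(sim$trials$study)
  subjects <- unique(sim$trials$subject)
  p <- list(
    beta0 = rnorm(1, log(0.4), 0.3),
    sigma_species = abs(rnorm(1, 0, 0.5)),
    sigma_study = abs(rnorm(1, 0, 0.5)),
    sigma_subject = abs(rnorm(1, 0, 0.5)),
    sigma_task = abs(rnorm(1, 0, 0.5)),
    u_species = setNames(rnorm(length(species)), species),
    u_study = setNames(rnorm(length(studies)), studies),
    u_subject = setNames(rnorm(length(subjects)), subjects),
    u_task = setNames(rnorm(3), c("controlled_array", "sequential", "simultaneous"))
  )
  if (with_x) {
    p$beta1 <- rnorm(1, 0, 0.3)
    p$x <- setNames(sim$predictors$x, sim$predictors$species)
  }
  p
}

# wrap hand-made posterior draws (named list of vectors, or of
# iterations x chains matrices) into the array layout reporting expects
fake_fit <- function(draws_list, n_chains = 2, has_beta1 = "beta1" %in% names(draws_list)) {
  n <- if (is.matrix(draws_list[[1]])) nrow(draws_list[[1]]) else
    length(draws_list[[1]]) / n_chains
  arr <- array(NA_real_, dim = c(n, n_chains, length(draws_list)),
               dimnames = list(NULL, NULL, names(draws_list)))
  for (p in names(draws_list)) arr[, , p] <- draws_list[[p]]
  species <- sub("^species\\[(.*)\\]$", "\\1",
                 grep("^species\\[", names(draws_list), value = TRUE))
  structure(list(draws = arr,
                 data = list(species = species, has_beta1 = as.integer(has_beta1),
                             lambda_fixed = -1),
                 spec = list(predictor = if (has_beta1) "x" else NULL)),
            class = "weber_fit")
}
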