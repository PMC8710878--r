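test_that("equal-quantity trials contribute exactly log(1/2)", {
  d <- toy_dataset(4, seed = 11)
  p <- random_params(d$sim, seed = 2)
  tr <- d$sim$trials[1, ]
  tr$n1 <- 5; tr$n2 <- 5
  expect_equal(log_likelihood(tr, p, d$cov), log(0.5))
  tr$correct <- 1 - tr$correct
  expect_equal(log_likelihood(tr, p, d$cov), log(0.5))
})

test_that("with all effects zero the likelihood composes with predict_accuracy", {
  d <- toy_dataset(4, seed = 12)
  p <- random_params(d$sim, seed = 3)
  p$beta0 <- log(0.2)
  for (nm in c("u_species", "u_study", "u_subject", "u_task")) p[[nm]][] <- 0
  tr <- d$sim$trials[1, ]
  tr$n1 <- 10; tr$n2 <- 12; tr$correct <- 1
  expect_equal(log_likelihood(tr, p, d$cov),
               log(predict_accuracy(10, 12, 0.2)), tolerance = 1e-12)
  tr$correct <- 0
  expect_equal(log_likelihood(tr, p, d$cov),
               log(1 - predict_accuracy(10, 12, 0.2)), tolerance = 1e-12)
})

test_that("vectorized likelihood matches a straight-loop reimplementation to 1e-10", {
  d <- toy_dataset(5, seed = 13, trials_per_subject = c(4, 4))
  trials <- d$sim$trials[1:20, ]
  for (ps in 1:3) {
    p <- random_params(d$sim, seed = ps, with_x = ps > 1)
    expect_equal(log_likelihood(trials, p, d$cov),
                 loop_log_likelihood(trials, p), tolerance = 1e-10)
  }
})

test_that("likelihood is invariant to species relabeling with permuted covariance", {
  d <- toy_dataset(5, seed = 14)
  p <- random_params(d$sim, seed = 5)
  base <- log_likelihood(d$sim$trials, p, d$cov)
  perm <- sample(d$cov$labels)
  cov2 <- structure(list(labels = perm, V = d$cov$V[perm, perm],
                         M = NULL, lambda = NULL), class = "species_cov")
  expect_equal(log_likelihood(d$sim$trials, p, cov2), base)
})

test_that("unindexed labels raise key errors", {
  d <- toy_dataset(4, seed = 15)
  p <- random_params(d$sim, seed = 6)
  p$u_study <- p$u_study[-1]
  expect_error(log_likelihood(d$sim$trials, p, d$cov), "unindexed study")
  tr <- d$sim$trials
  tr$species[1] <- "unknown_species"
  expect_error(log_likelihood(tr, random_params(d$sim, seed = 6), d$cov),
               "absent")
})

test_that("compiled log posterior equals R likelihood plus priors", {
  d <- toy_dataset(6, seed = 16)
  spec <- model_spec(predictor = "x", chains = 2, warmup = 10, draws = 10, seed = 1)
  md <- phyloweber:::build_model_data(d$sim$trials, d$sim$predictors, d$cov, spec)
  S <- length(md$species); J <- md$J; K <- md$K
  npar <- 1 + 1 + 4 + 1 + S + J + K + 3
  set.seed(7)
  theta <- rnorm(npar, 0, 0.3)
  got <- phyloweber:::weber_lp_grad(theta, md)$value

  # reassemble the same density in R from its pieces
  beta0 <- theta[1]; beta1 <- theta[2]
  sig <- exp(theta[3:6]); lam <- plogis(theta[7])
  z_sp <- theta[8:(7 + S)]
  z_st <- theta[(8 + S):(7 + S + J)]
  z_su <- theta[(8 + S + J):(7 + S + J + K)]
  z_ta <- theta[(8 + S + J + K):npar]
  m <- lam * md$d + (1 - lam)
  u_sp <- as.vector(md$Q %*% (sqrt(m) * z_sp))
  p <- list(beta0 = beta0, beta1 = beta1,
            x = setNames(md$x, md$species),
            sigma_species = 1, sigma_study = sig[2],
            sigma_subject = sig[3], sigma_task = sig[4],
            u_species = setNames(sig[1] * u_sp, md$species),
            u_study = setNames(z_st, md$studies),
            u_subject = setNames(z_su, md$subjects),
            u_task = setNames(z_ta, c("controlled_array", "sequential", "simultaneous")))
  loglik <- log_likelihood(d$sim$trials, p, d$cov)
  priors <- -0.5 * ((beta0 - log(0.5)) / 1)^2 - 0.5 * beta1^2 +
    sum(-0.5 * sig^2 + theta[3:6]) +
    log(lam) + log(1 - lam) +
    sum(-0.5 * c(z_sp, z_st, z_su, z_ta)^2)
  expect_equal(got, loglik + priors, tolerance = 1e-8)
})
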