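#' Hierarchical model configuration
#'
#' Collects everything needed for one model run: which species-level
#' predictor to regress log w on (or none, for the per-species Weber
#' fraction model), priors, sampler settings and an optional species
#' subset. Priors default to weakly informative choices centred on the
#' plausible animal Weber-fraction range: beta0 ~ Normal(log 0.5, 1),
#' beta1 ~ Normal(0, 1) on standardized predictors, half-Normal(1) on all
#' effect scales, and Uniform(0, 1) on lambda.
#'
#' @param predictor column name in the predictor table, or \code{NULL} for a
#'   no-predictor fit.
#' @param chains number of chains, at least 2 (Rhat needs several).
#' @param warmup,draws iterations per chain for adaptation and sampling.
#' @param seed single integer governing all chain seeds deterministically.
#' @param b0_loc,b0_sd,b1_sd,sigma_sd prior location/scales.
#' @param lambda_fixed \code{NULL} to sample lambda, or a fixed value in
#'   [0, 1].
#' @param species_subset optional character vector restricting the fit to
#'   those species (e.g. a primate-only refit).
#' @param target_accept,max_treedepth no-U-turn sampler controls.
#' @return a \code{model_spec} list.
#' @export
model_spec <- function(predictor = NULL, chains = 4, warmup = 1000,
                       draws = 1000, seed = 1L,
                       b0_loc = log(0.5), b0_sd = 1, b1_sd = 1, sigma_sd = 1,
                       lambda_fixed = NULL, species_subset = NULL,
                       target_accept = 0.85, max_treedepth = 10) {
  stopifnot(chains >= 2, warmup >= 1, draws >= 1,
            b0_sd > 0, b1_sd > 0, sigma_sd > 0)
  if (!is.null(lambda_fixed)) {
    stopifnot(lambda_fixed >= 0, lambda_fixed <= 1)
  }
  structure(list(predictor = predictor, chains = as.integer(chains),
                 warmup = as.integer(warmup), draws = as.integer(draws),
                 seed = as.integer(seed), b0_loc = b0_loc, b0_sd = b0_sd,
                 b1_sd = b1_sd, sigma_sd = sigma_sd,
                 lambda_fixed = lambda_fixed,
                 species_subset = species_subset,
                 target_accept = target_accept,
                 max_treedepth = as.integer(max_treedepth)),
            class = "model_spec")
}

# Assemble index vectors, the eigendecomposition of V and prior settings
# into the flat list the compiled log-posterior consumes.
build_model_data <- function(trials, predictors, cov, spec) {
  stopifnot(inherits(cov, "species_cov"), inherits(spec, "model_spec"))
  trials <- as.data.frame(trials)
  needed <- c("species", "subject", "study", "task", "n1", "n2", "correct")
  stopifnot(all(needed %in% names(trials)))
  if (!is.null(spec$species_subset)) {
    trials <- trials[trials$species %in% spec$species_subset, , drop = FALSE]
  }
  bad_task <- setdiff(unique(trials$task), TASK_LEVELS)
  if (length(bad_task)) {
    stop("unknown task paradigm: ", paste(bad_task, collapse = ", "), call. = FALSE)
  }
  absent <- setdiff(unique(trials$species), cov$labels)
  if (length(absent)) {
    stop("species present in data but absent from the tree: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  x_by_species <- NULL
  if (!is.null(spec$predictor)) {
    stopifnot(is.data.frame(predictors),
              all(c("species", spec$predictor) %in% names(predictors)))
    xv <- predictors[[spec$predictor]]
    names(xv) <- predictors$species
    have <- names(xv)[!is.na(xv)]
    dropped <- setdiff(unique(trials$species), have)
    if (length(dropped)) {
      message("dropping species with missing '", spec$predictor, "': ",
              paste(dropped, collapse = ", "))
      trials <- trials[trials$species %in% have, , drop = FALSE]
    }
    if (!nrow(trials)) stop("no trials left after predictor filtering", call. = FALSE)
    x_by_species <- xv
  }
  informative <- trials$n1 != trials$n2
  if (!any(informative)) stop("zero informative trials (all n1 == n2)", call. = FALSE)

  species <- intersect(cov$labels, unique(trials$species))
  Vs <- cov$V[species, species, drop = FALSE]
  eg <- eigen(Vs, symmetric = TRUE)
  x <- if (is.null(x_by_species)) numeric(length(species)) else {
    raw <- unname(x_by_species[species])
    if (stats::sd(raw) > 0) (raw - mean(raw)) / stats::sd(raw) else raw - mean(raw)
  }
  studies <- sort(unique(trials$study))
  subjects <- sort(unique(trials$subject))
  # trials sharing grouping cell, pair and outcome contribute identical
  # likelihood terms: collapse them to weighted rows
  key <- paste(trials$species, trials$study, trials$subject, trials$task,
               trials$n1, trials$n2, trials$correct, sep = "\r")
  first <- !duplicated(key)
  wt <- as.vector(table(key)[key[first]])
  grp <- trials[first, , drop = FALSE]
  list(
    Q = eg$vectors, d = pmax(eg$values, 0),
    sp = match(grp$species, species) - 1L,
    st = match(grp$study, studies) - 1L,
    su = match(grp$subject, subjects) - 1L,
    ta = match(grp$task, TASK_LEVELS) - 1L,
    cvec = abs(grp$n1 - grp$n2) / sqrt(grp$n1^2 + grp$n2^2),
    y = as.integer(grp$correct),
    wt = as.numeric(wt),
    x = x,
    has_beta1 = as.integer(!is.null(spec$predictor)),
    lambda_fixed = if (is.null(spec$lambda_fixed)) -1 else spec$lambda_fixed,
    b0_loc = spec$b0_loc, b0_sd = spec$b0_sd, b1_sd = spec$b1_sd,
    sig_sd = spec$sigma_sd,
    J = length(studies), K = length(subjects), T = 3L,
    species = species, studies = studies, subjects = subjects,
    n_trials = nrow(trials)
  )
}

param_names <- function(md, spec) {
  c("beta0",
    if (md$has_beta1) "beta1",
    "sigma_species", "sigma_study", "sigma_subject", "sigma_task",
    if (md$lambda_fixed < 0) "lambda",
    paste0("species[", md$species, "]"),
    paste0("study[", md$studies, "]"),
    paste0("subject[", md$subjects, "]"),
    paste0("task[", TASK_LEVELS, "]"))
}

# map one unconstrained draw to the constrained/reported scale:
# sigmas exponentiated, lambda inverse-logit, z blocks mapped to realized
# additive effects (scale included)
constrain_draw <- function(theta, md) {
  off <- 1L
  beta0 <- theta[off]; off <- off + 1L
  beta1 <- NULL
  if (md$has_beta1) { beta1 <- theta[off]; off <- off + 1L }
  sig <- exp(theta[off:(off + 3L)]); off <- off + 4L
  lam <- NULL
  if (md$lambda_fixed < 0) { lam <- stats::plogis(theta[off]); off <- off + 1L }
  S <- length(md$species); J <- md$J; K <- md$K
  z_sp <- theta[off:(off + S - 1L)]; off <- off + S
  z_st <- theta[off:(off + J - 1L)]; off <- off + J
  z_su <- theta[off:(off + K - 1L)]; off <- off + K
  z_ta <- theta[off:(off + 2L)]
  lam_eff <- if (is.null(lam)) md$lambda_fixed else lam
  m <- pmax(lam_eff * md$d + (1 - lam_eff), 1e-12)
  u_sp <- sig[1] * as.vector(md$Q %*% (sqrt(m) * z_sp))
  c(beta0, beta1, sig, lam, u_sp, sig[2] * z_st, sig[3] * z_su, sig[4] * z_ta)
}

#' Fit the joint phylogenetic-psychophysical model
#'
#' Samples the posterior of the hierarchical model by the no-U-turn sampler
#' (multinomial NUTS with dual-averaging step-size adaptation and a diagonal
#' metric estimated during warmup) over the analytic log-posterior
#' gradient. The model: each trial's log Weber fraction is
#' beta0 + beta1 x + species + study + subject + task effect; species
#' effects are multivariate normal with correlation
#' M = lambda V + (1 - lambda) I (lambda sampled jointly, V fixed from the
#' tree); the outcome likelihood is the probit scalar-variability model of
#' \code{\link{predict_accuracy}}. All random-effect blocks are
#' non-centered; reported draws are on the constrained scale with realized
#' (scale-multiplied) effects.
#'
#' @param trials trial data frame (species, subject, study, task, n1, n2,
#'   correct). Species missing the chosen predictor are dropped with a
#'   message; species absent from the tree are an error.
#' @param predictors per-species predictor data frame (column
#'   \code{species} plus value columns); may be \code{NULL} for a
#'   no-predictor fit. The chosen column is z-standardized over the modelled
#'   species.
#' @param cov \code{species_cov} from \code{\link{tree_to_correlation}}.
#' @param spec \code{model_spec}.
#' @return a \code{weber_fit}: list with \code{draws} (array iterations x
#'   chains x parameters, constrained scale), \code{sampler} diagnostics
#'   (divergences, step sizes, acceptance), \code{data} summary and the
#'   \code{spec}. Runs with identical seed and settings are bit-identical.
#' @export
fit <- function(trials, predictors, cov, spec) {
  md <- build_model_data(trials, predictors, cov, spec)
  lp_fun <- function(theta) weber_lp_grad(theta, md)
  npar_un <- 1L + md$has_beta1 + 4L + (md$lambda_fixed < 0) +
    length(md$species) + md$J + md$K + 3L
  pnames <- param_names(md, spec)
  draws <- array(NA_real_,
                 dim = c(spec$draws, spec$chains, length(pnames)),
                 dimnames = list(NULL, NULL, pnames))
  sampler <- list(divergences = integer(spec$chains),
                  step_size = numeric(spec$chains),
                  mean_accept = numeric(spec$chains),
                  seed = spec$seed)
  for (ch in seq_len(spec$chains)) {
    chain_seed <- spec$seed + 10000L * (ch - 1L)
    set.seed(chain_seed)
    init <- stats::rnorm(npar_un, 0, 0.2)
    init[1] <- init[1] + spec$b0_loc
    res <- nuts_sample(lp_fun, init, n_warmup = spec$warmup,
                       n_draws = spec$draws,
                       target_accept = spec$target_accept,
                       max_treedepth = spec$max_treedepth)
    for (i in seq_len(spec$draws)) {
      draws[i, ch, ] <- constrain_draw(res$draws[i, ], md)
    }
    sampler$divergences[ch] <- res$divergences
    sampler$step_size[ch] <- res$step_size
    sampler$mean_accept[ch] <- res$mean_accept
  }
  total_div <- sum(sampler$divergences)
  if (total_div > 0.10 * spec$draws * spec$chains) {
    warning(sprintf("%d divergent transitions (%.1f%% of draws)", total_div,
                    100 * total_div / (spec$draws * spec$chains)), call. = FALSE)
  }
  structure(list(draws = draws, sampler = sampler,
                 data = md[c("species", "studies", "subjects", "n_trials",
                             "has_beta1", "lambda_fixed")],
                 spec = spec),
            class = "weber_fit")
}

#' @export
print.weber_fit <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf("Phylogenetic Weber-fraction fit: %d species, %d studies, %d subjects, %d trials\n",
              length(x$data$species), length(x$data$studies),
              length(x$data$subjects), x$data$n_trials))
  cat(sprintf("  %d chains x %d draws; %d divergent transitions\n",
              d[2], d[1], sum(x$sampler$divergences)))
  core <- intersect(c("beta0", "beta1", "lambda", "sigma_species", "sigma_study",
                      "sigma_subject", "sigma_task"), dimnames(x$draws)[[3]])
  for (p in core) {
    v <- as.vector(x$draws[, , p])
    cat(sprintf("  %-14s mean %7.3f  sd %6.3f\n", p, mean(v), stats::sd(v)))
  }
  invisible(x)
}

#' Build a model_spec from a JSON configuration file
#'
#' Reads a JSON object whose fields mirror the arguments of
#' \code{\link{model_spec}} (unknown fields are an error), so a model run
#' can be described by a config file instead of code.
#'
#' @param path path to a JSON file.
#' @return a \code{model_spec}.
#' @export
model_spec_from_json <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(cfg), names(formals(model_spec)))
  if (length(unknown)) {
    stop("unknown model_spec fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(model_spec, cfg)
}
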