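merged_draws <- function(fit, par) {
  draws <- if (inherits(fit, "weber_fit")) fit$draws else fit
  if (!par %in% dimnames(draws)[[3]]) {
    stop("parameter not in draws: ", par, call. = FALSE)
  }
  as.vector(draws[, , par])
}

#' Per-species posterior quantiles of the Weber fraction
#'
#' For a no-predictor fit, summarizes each species' overall Weber fraction
#' exp(beta0 + species effect) by posterior quantiles (2.5, 25, 50, 75,
#' 97.5 percent). Because exp is monotone, these equal the exponentiated
#' quantiles of the log-scale draws.
#'
#' @param fit a \code{weber_fit} from a run with no predictor.
#' @return data frame: species, w2.5, w25, w50, w75, w97.5.
#' @export
species_weber_summary <- function(fit) {
  stopifnot(inherits(fit, "weber_fit"))
  if (fit$data$has_beta1) {
    stop("species Weber summaries are defined for no-predictor fits", call. = FALSE)
  }
  b0 <- merged_draws(fit, "beta0")
  probs <- c(0.025, 0.25, 0.5, 0.75, 0.975)
  rows <- lapply(fit$data$species, function(sp) {
    w <- exp(b0 + merged_draws(fit, paste0("species[", sp, "]")))
    q <- stats::quantile(w, probs, names = FALSE)
    data.frame(species = sp, w2.5 = q[1], w25 = q[2], w50 = q[3],
               w75 = q[4], w97.5 = q[5], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Posterior summary of the predictor coefficient
#'
#' Central posterior intervals for beta1 (the effect of the standardized
#' species-level predictor on log Weber fraction) with a sign-consistency
#' flag: TRUE when the whole central 95\% interval lies on one side of
#' zero.
#'
#' @param fits a single \code{weber_fit} or a named list of fits (one per
#'   predictor run).
#' @return data frame: predictor, mean, q2.5, q25, q75, q97.5,
#'   sign_consistent.
#' @export
coefficient_summary <- function(fits) {
  if (inherits(fits, "weber_fit")) fits <- list(fits)
  if (is.null(names(fits))) {
    names(fits) <- vapply(fits, function(f)
      if (is.null(f$spec$predictor)) "(none)" else f$spec$predictor, "")
  }
  rows <- lapply(names(fits), function(nm) {
    b <- merged_draws(fits[[nm]], "beta1")
    q <- stats::quantile(b, c(0.025, 0.25, 0.75, 0.975), names = FALSE)
    data.frame(predictor = nm, mean = mean(b), q2.5 = q[1], q25 = q[2],
               q75 = q[3], q97.5 = q[4],
               sign_consistent = q[1] > 0 || q[4] < 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Posterior summary of the phylogenetic-signal parameter
#'
#' Quantiles of the lambda draws plus the posterior probability that lambda
#' exceeds a small threshold — the quantity that answers whether species
#' effects carry phylogenetic correlation at all.
#'
#' @param fit a \code{weber_fit} (or draws array) with sampled lambda.
#' @param threshold exceedance threshold, default 0.05.
#' @return one-row data frame: mean, q2.5, q25, q50, q75, q97.5,
#'   p_exceed, threshold.
#' @export
lambda_summary <- function(fit, threshold = 0.05) {
  lam <- merged_draws(fit, "lambda")
  q <- stats::quantile(lam, c(0.025, 0.25, 0.5, 0.75, 0.975), names = FALSE)
  data.frame(mean = mean(lam), q2.5 = q[1], q25 = q[2], q50 = q[3],
             q75 = q[4], q97.5 = q[5],
             p_exceed = mean(lam > threshold), threshold = threshold)
}

#' Posterior summary of the effect scales
#'
#' Posterior means with central 50\% and 90\% intervals for the species,
#' study, subject and task effect scales (and beta1 when present). All are
#' on the log-Weber-fraction scale — each scale multiplies a unit-variance
#' effect, and beta1 multiplies the standardized predictor — so their
#' magnitudes are directly comparable.
#'
#' @param fit a \code{weber_fit} or draws array.
#' @return data frame: parameter, mean, q25, q75 (50\% interval), q5, q95
#'   (90\% interval).
#' @export
scale_summary <- function(fit) {
  draws <- if (inherits(fit, "weber_fit")) fit$draws else fit
  pars <- intersect(c("sigma_species", "sigma_study", "sigma_subject",
                      "sigma_task", "beta1"), dimnames(draws)[[3]])
  rows <- lapply(pars, function(p) {
    v <- merged_draws(draws, p)
    q <- stats::quantile(v, c(0.05, 0.25, 0.75, 0.95), names = FALSE)
    data.frame(parameter = p, mean = mean(v), q25 = q[2], q75 = q[3],
               q5 = q[1], q95 = q[4], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Kernel density of a merged-chain posterior
#'
#' Gaussian kernel with the standard reference bandwidth, over all chains
#' merged — the density behind coefficient-posterior panels.
#'
#' @param fit a \code{weber_fit} or draws array.
#' @param par parameter name.
#' @return a \code{stats::density} object.
#' @export
posterior_density <- function(fit, par) {
  stats::density(merged_draws(fit, par), bw = "nrd0", kernel = "gaussian")
}

#' Species Weber fraction vs predictor scatter table
#'
#' Joins the per-species posterior Weber-fraction summary from a
#' no-predictor fit with a predictor column — the data behind
#' w-vs-predictor scatterplots.
#'
#' @param fit a no-predictor \code{weber_fit}.
#' @param predictors per-species predictor data frame.
#' @param predictor column name.
#' @return data frame: species, predictor value, w50 and interval bounds.
#' @export
weber_scatter_table <- function(fit, predictors, predictor) {
  stopifnot(predictor %in% names(predictors))
  ws <- species_weber_summary(fit)
  out <- merge(ws, predictors[, c("species", predictor)], by = "species")
  out[order(out$species), ]
}
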