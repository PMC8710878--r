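#' Trial-level log likelihood at one parameter point
#'
#' Evaluates the sum over trials of the Bernoulli log probability of each
#' observed outcome, where the success probability is
#' \code{\link{predict_accuracy}}(n1, n2, w_trial) and the trial's log Weber
#' fraction is assembled additively:
#' \deqn{\log w = \beta_0 + \beta_1 x_{species} + \sigma_{sp} u_{sp}
#'   + \sigma_{study} u_{study} + \sigma_{subj} u_{subj}
#'   + \sigma_{task} u_{task}.}
#' The random-effect vectors u are on unit scale (their prior scales
#' multiply them here); under the model prior the species vector is
#' multivariate normal with correlation M = lambda V + (1 - lambda) I, but
#' that prior is not part of the likelihood and the covariance enters only
#' to fix the species ordering. Trials with n1 = n2 contribute exactly
#' log(0.5).
#'
#' @param trials data frame with columns species, subject, study, task, n1,
#'   n2, correct (0/1).
#' @param params named list: \code{beta0}; optional \code{beta1} and named
#'   per-species \code{x}; \code{sigma_species}, \code{sigma_study},
#'   \code{sigma_subject}, \code{sigma_task}; named unit-scale effect
#'   vectors \code{u_species}, \code{u_study}, \code{u_subject},
#'   \code{u_task}.
#' @param cov a \code{species_cov}; every trial species must be among its
#'   labels.
#' @return the scalar log likelihood.
#' @export
log_likelihood <- function(trials, params, cov) {
  stopifnot(inherits(cov, "species_cov"))
  lookup <- function(vec, keys, what) {
    if (anyNA(match(keys, names(vec)))) {
      missing <- setdiff(unique(keys), names(vec))
      stop("unindexed ", what, ": ", paste(missing, collapse = ", "), call. = FALSE)
    }
    unname(vec[keys])
  }
  if (!all(trials$species %in% cov$labels)) {
    stop("trial species absent from covariance labels: ",
         paste(setdiff(unique(trials$species), cov$labels), collapse = ", "),
         call. = FALSE)
  }
  beta1 <- if (is.null(params$beta1)) 0 else params$beta1
  xterm <- if (is.null(params$x) || beta1 == 0) 0 else
    beta1 * lookup(params$x, trials$species, "predictor species")
  lw <- params$beta0 + xterm +
    params$sigma_species * lookup(params$u_species, trials$species, "species") +
    params$sigma_study   * lookup(params$u_study,   trials$study,   "study") +
    params$sigma_subject * lookup(params$u_subject, trials$subject, "subject") +
    params$sigma_task    * lookup(params$u_task,    trials$task,    "task")
  cv <- abs(trials$n1 - trials$n2) / sqrt(trials$n1^2 + trials$n2^2)
  z <- cv / exp(lw)
  ll <- ifelse(trials$correct == 1,
               stats::pnorm(z, log.p = TRUE),
               stats::pnorm(z, lower.tail = FALSE, log.p = TRUE))
  out <- sum(ll)
  if (!is.finite(out)) stop("non-finite log likelihood", call. = FALSE)
  out
}
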