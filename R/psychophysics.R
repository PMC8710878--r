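#' Predicted accuracy of a two-quantity discrimination
#'
#' Under the linear-scale scalar-variability model, a quantity n is
#' represented as a Gaussian with mean n and standard deviation w * n, where
#' w is the Weber fraction. On a comparison of n1 vs n2 the probability of
#' correctly ordering two independent such representations is
#' \deqn{P = \Phi\!\left(\frac{|n_1 - n_2|}{w\sqrt{n_1^2 + n_2^2}}\right),}
#' the probit of the standardized difference. Accuracy is 0.5 for equal
#' quantities, approaches 1 as the ratio grows or w shrinks, never drops
#' below chance, and is symmetric in (n1, n2). It depends on the pair only
#' through its ratio (scale invariance): doubling both quantities leaves
#' predicted accuracy unchanged.
#'
#' @param n1,n2 positive quantities (vectorized).
#' @param w Weber fraction, positive (vectorized, recycled).
#' @return probability of a correct response, in [0.5, 1).
#' @export
predict_accuracy <- function(n1, n2, w) {
  if (any(!is.finite(n1)) || any(!is.finite(n2)) || any(n1 <= 0) || any(n2 <= 0)) {
    stop("quantities must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(w)) || any(w <= 0)) {
    stop("Weber fraction must be positive and finite", call. = FALSE)
  }
  stats::pnorm(abs(n1 - n2) / (w * sqrt(n1^2 + n2^2)))
}

#' Threshold reading of the Weber fraction
#'
#' The Weber fraction is the proportional difference between two quantities
#' needed for reliable discrimination. This returns the smallest integer
#' m > reference with (m - reference) / reference >= w: the finest
#' discriminable comparison against the reference. For example, w = 0.2 at
#' reference 10 gives 12 (10 vs 12), and w = 0.5 gives 15 (10 vs 15); very
#' small w bottoms out at reference + 1 because quantities are integers.
#'
#' @param reference positive integer reference quantity.
#' @param w Weber fraction, positive.
#' @return the smallest reliably discriminable integer above the reference.
#' @export
discrimination_bound <- function(reference, w) {
  stopifnot(length(reference) == 1L, length(w) == 1L)
  if (!is.finite(reference) || reference < 1 || reference != round(reference)) {
    stop("reference must be a positive integer", call. = FALSE)
  }
  if (!is.finite(w) || w <= 0) stop("Weber fraction must be positive", call. = FALSE)
  # tiny slack so e.g. 0.2 * 10 counts as the integer 2 despite binary rounding
  step <- ceiling(w * reference - 1e-9)
  as.integer(reference + max(1, step))
}
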