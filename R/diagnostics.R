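#' Split-chain rank-normalized Rhat
#'
#' Computes the potential scale reduction factor per scalar parameter after
#' splitting each chain in half (so within-chain drift registers as
#' disagreement) and rank-normalizing the pooled draws (so heavy tails do
#' not mask mixing failures). Values near 1 indicate that between-chain
#' variance matches within-chain variance; runs are conventionally
#' considered converged when every Rhat < 1.05. Parameters whose draws are
#' all identical (e.g. a fixed lambda) return exactly 1 by convention.
#'
#' @param x a \code{weber_fit}, or a draws array (iterations x chains x
#'   parameters), or a single iterations x chains matrix.
#' @return named vector of Rhat values (a single value for a matrix).
#' @export
rhat <- function(x) {
  if (inherits(x, "weber_fit")) x <- x$draws
  if (is.matrix(x)) return(rhat_matrix(x))
  stopifnot(is.array(x), length(dim(x)) == 3L)
  out <- apply(x, 3, rhat_matrix)
  names(out) <- dimnames(x)[[3]]
  out
}

rhat_matrix <- function(m) {
  n <- nrow(m)
  if (ncol(m) < 2L) stop("Rhat needs at least 2 chains", call. = FALSE)
  if (n < 10L) stop("Rhat needs at least 10 draws per chain", call. = FALSE)
  if (max(m) - min(m) == 0) return(1)
  half <- floor(n / 2)
  split <- cbind(m[seq_len(half), , drop = FALSE],
                 m[(n - half + 1):n, , drop = FALSE])
  r <- matrix(rank(split, ties.method = "average"), nrow(split), ncol(split))
  z <- stats::qnorm((r - 3 / 8) / (length(split) + 1 / 4))
  classic_rhat(z)
}

classic_rhat <- function(m) {
  n <- nrow(m)
  chain_means <- colMeans(m)
  chain_vars <- apply(m, 2, stats::var)
  w <- mean(chain_vars)
  b <- n * stats::var(chain_means)
  if (w == 0) return(1)
  var_plus <- (n - 1) / n * w + b / n
  sqrt(var_plus / w)
}
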