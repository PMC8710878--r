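# Independent oracles used across test files. These deliberately avoid the
# package's own code paths.

# brute-force phylogenetic correlation: for each tip pair, walk both
# root-paths through the edge matrix, sum the branch lengths they share,
# and divide by mean root-to-tip depth
brute_force_correlation <- function(tree, labels = tree$tip.label) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  parent_of <- integer(max(tree$edge))
  elen_of <- numeric(max(tree$edge))
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  elen_of[tree$edge[, 2]] <- tree$edge.length
  path_edges <- function(tip) {
    node <- tip
    out <- integer(0)
    while (node != root) {
      out <- c(out, node)   # edge identified by its child node
      node <- parent_of[node]
    }
    out
  }
  idx <- match(labels, tree$tip.label)
  paths <- lapply(idx, path_edges)
  depths <- vapply(paths, function(p) sum(elen_of[p]), 0)
  n <- length(idx)
  V <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      shared <- intersect(paths[[i]], paths[[j]])
      V[i, j] <- sum(elen_of[shared]) / mean(depths)
    }
  }
  diag(V) <- 1
  V
}

# closed-form GLS residuals by explicit matrix inversion
brute_force_gls_residuals <- function(y, x, V) {
  X <- cbind(1, x)
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  as.vector(y - X %*% beta)
}

# Monte-Carlo ordering probability for the scalar-variability model:
# draws two independent Gaussian magnitude representations and scores
# whether the larger quantity was judged larger (ties toward the smaller)
mc_accuracy <- function(n1, n2, w, n_draws = 1e6, seed = 99) {
  set.seed(seed)
  r1 <- rnorm(n_draws, n1, w * n1)
  r2 <- rnorm(n_draws, n2, w * n2)
  correct <- if (n1 > n2) r1 > r2 else r2 > r1
  p <- mean(correct)
  list(p = p, se = sqrt(p * (1 - p) / n_draws))
}

# straight-loop trial log likelihood, one trial at a time
loop_log_likelihood <- function(trials, params) {
  total <- 0
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    b1 <- if (is.null(params$beta1)) 0 else params$beta1
    xv <- if (is.null(params$x)) 0 else params$x[[tr$species]]
    lw <- params$beta0 + b1 * xv +
      params$sigma_species * params$u_species[[tr$species]] +
      params$sigma_study * params$u_study[[tr$study]] +
      params$sigma_subject * params$u_subject[[tr$subject]] +
      params$sigma_task * params$u_task[[tr$task]]
    p <- pnorm(abs(tr$n1 - tr$n2) / (exp(lw) * sqrt(tr$n1^2 + tr$n2^2)))
    total <- total + if (tr$correct == 1) log(p) else log(1 - p)
  }
  total
}
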