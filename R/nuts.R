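# No-U-turn sampler (multinomial variant) with dual-averaging step-size
# adaptation and a diagonal metric estimated in Stan-style warmup windows.
# Generic over any log-density: `lp_grad` takes the unconstrained parameter
# vector and returns list(value, grad). Used by fit(); kept free of model
# specifics so it can be unit-tested on known densities.

logsumexp2 <- function(a, b) {
  m <- max(a, b)
  if (!is.finite(m)) return(m)
  m + log(exp(a - m) + exp(b - m))
}

#' Sample from a log density with the no-U-turn sampler
#'
#' @param lp_grad function(theta) -> list(value, grad) for the joint log
#'   density on the unconstrained scale.
#' @param init initial unconstrained parameter vector.
#' @param n_warmup,n_draws adaptation and retained iterations.
#' @param target_accept dual-averaging acceptance target.
#' @param max_treedepth maximum tree doublings per iteration.
#' @return list with \code{draws} (n_draws x npar matrix), \code{lp},
#'   \code{divergences} (post-warmup count), \code{step_size},
#'   \code{mean_accept}, \code{treedepth}.
#' @keywords internal
#' @export
nuts_sample <- function(lp_grad, init, n_warmup = 1000, n_draws = 1000,
                        target_accept = 0.85, max_treedepth = 10) {
  npar <- length(init)
  inv_metric <- rep(1, npar)
  theta <- init
  f <- lp_grad(theta)
  if (!is.finite(f$value)) stop("non-finite log density at initial point", call. = FALSE)

  joint <- function(lp, r) lp - 0.5 * sum(r * r * inv_metric)

  leapfrog <- function(theta, r, grad, eps) {
    r <- r + (eps / 2) * grad
    theta <- theta + eps * inv_metric * r
    f <- lp_grad(theta)
    if (!is.finite(f$value)) f$value <- -Inf
    r <- r + (eps / 2) * f$grad
    list(theta = theta, r = r, f = f)
  }

  DIV_THRESHOLD <- 1000

  # recursive multinomial tree doubling; ends named by integration direction
  build_tree <- function(depth, theta, r, f, dir, eps, H0) {
    if (depth == 0L) {
      step <- leapfrog(theta, r, f$grad, dir * eps)
      lj <- joint(step$f$value, step$r)
      lw <- lj - H0
      if (!is.finite(lw)) lw <- -Inf   # NaN momenta/energy count as divergent
      div <- lw < -DIV_THRESHOLD
      list(ok = !div, div = as.integer(div),
           theta_m = step$theta, r_m = step$r, f_m = step$f,
           theta_p = step$theta, r_p = step$r, f_p = step$f,
           prop_theta = step$theta, prop_f = step$f,
           lw = lw, rho = step$r,
           alpha = exp(min(lw, 0)), n_alpha = 1L)
    } else {
      t1 <- build_tree(depth - 1L, theta, r, f, dir, eps, H0)
      if (!t1$ok) return(t1)
      t2 <- if (dir == 1L) {
        build_tree(depth - 1L, t1$theta_p, t1$r_p, t1$f_p, dir, eps, H0)
      } else {
        build_tree(depth - 1L, t1$theta_m, t1$r_m, t1$f_m, dir, eps, H0)
      }
      t1$alpha <- t1$alpha + t2$alpha
      t1$n_alpha <- t1$n_alpha + t2$n_alpha
      t1$div <- t1$div + t2$div
      if (!t2$ok) { t1$ok <- FALSE; return(t1) }
      lw_tot <- logsumexp2(t1$lw, t2$lw)
      if (log(stats::runif(1)) < t2$lw - lw_tot) {
        t1$prop_theta <- t2$prop_theta
        t1$prop_f <- t2$prop_f
      }
      t1$lw <- lw_tot
      t1$rho <- t1$rho + t2$rho
      if (dir == 1L) {
        t1$theta_p <- t2$theta_p; t1$r_p <- t2$r_p; t1$f_p <- t2$f_p
      } else {
        t1$theta_m <- t2$theta_m; t1$r_m <- t2$r_m; t1$f_m <- t2$f_m
      }
      rho_im <- t1$rho * inv_metric
      t1$ok <- sum(rho_im * t1$r_p) > 0 && sum(rho_im * t1$r_m) > 0
      t1
    }
  }

  # one NUTS transition; returns new state plus adaptation statistics
  transition <- function(theta, f, eps) {
    r0 <- stats::rnorm(npar, 0, sqrt(1 / inv_metric))
    H0 <- joint(f$value, r0)
    tree <- list(theta_m = theta, r_m = r0, f_m = f,
                 theta_p = theta, r_p = r0, f_p = f,
                 prop_theta = theta, prop_f = f,
                 lw = 0, rho = r0)
    alpha_sum <- 0; n_alpha <- 0L; div <- 0L; depth <- 0L
    while (depth < max_treedepth) {
      dir <- if (stats::runif(1) < 0.5) -1L else 1L
      sub <- if (dir == 1L) {
        build_tree(depth, tree$theta_p, tree$r_p, tree$f_p, dir, eps, H0)
      } else {
        build_tree(depth, tree$theta_m, tree$r_m, tree$f_m, dir, eps, H0)
      }
      alpha_sum <- alpha_sum + sub$alpha
      n_alpha <- n_alpha + sub$n_alpha
      div <- div + sub$div
      if (!sub$ok) break
      if (log(stats::runif(1)) < sub$lw - tree$lw) {
        tree$prop_theta <- sub$prop_theta
        tree$prop_f <- sub$prop_f
      }
      tree$lw <- logsumexp2(tree$lw, sub$lw)
      tree$rho <- tree$rho + sub$rho
      if (dir == 1L) {
        tree$theta_p <- sub$theta_p; tree$r_p <- sub$r_p; tree$f_p <- sub$f_p
      } else {
        tree$theta_m <- sub$theta_m; tree$r_m <- sub$r_m; tree$f_m <- sub$f_m
      }
      depth <- depth + 1L
      rho_im <- tree$rho * inv_metric
      if (sum(rho_im * tree$r_p) <= 0 || sum(rho_im * tree$r_m) <= 0) break
    }
    list(theta = tree$prop_theta, f = tree$prop_f,
         accept = if (n_alpha > 0) alpha_sum / n_alpha else 0,
         div = div, depth = depth)
  }

  # step-size heuristic: double/halve one leapfrog until the acceptance
  # ratio crosses 1/2
  find_epsilon <- function(theta, f) {
    eps <- 1
    r0 <- stats::rnorm(npar, 0, sqrt(1 / inv_metric))
    H0 <- joint(f$value, r0)
    step <- leapfrog(theta, r0, f$grad, eps)
    a <- joint(step$f$value, step$r) - H0
    dir <- if (is.finite(a) && a > log(0.5)) 1 else -1
    for (i in 1:50) {
      eps <- eps * 2^dir
      step <- leapfrog(theta, r0, f$grad, eps)
      a <- joint(step$f$value, step$r) - H0
      if (dir == 1 && !(is.finite(a) && a > log(0.5))) break
      if (dir == -1 && (is.finite(a) && a > log(0.5))) break
    }
    eps
  }

  eps <- find_epsilon(theta, f)
  gamma <- 0.05; t0 <- 10; kappa <- 0.75
  mu <- log(10 * eps)
  log_eps_bar <- 0; h_bar <- 0; adapt_count <- 0L

  da_update <- function(accept) {
    if (!is.finite(accept)) accept <- 0
    adapt_count <<- adapt_count + 1L
    m <- adapt_count
    h_bar <<- (1 - 1 / (m + t0)) * h_bar + (target_accept - accept) / (m + t0)
    log_eps <- mu - sqrt(m) / gamma * h_bar
    w <- m^(-kappa)
    log_eps_bar <<- w * log_eps + (1 - w) * log_eps_bar
    eps <<- exp(log_eps)
  }
  da_restart <- function() {
    mu <<- log(10 * eps)
    h_bar <<- 0; log_eps_bar <<- 0; adapt_count <<- 0L
  }

  # warmup schedule: stepsize-only head and tail around variance windows
  init_buffer <- min(75L, max(1L, as.integer(0.15 * n_warmup)))
  term_buffer <- min(50L, max(1L, as.integer(0.10 * n_warmup)))
  window_ends <- integer(0)
  if (n_warmup - init_buffer - term_buffer >= 20L) {
    wstart <- init_buffer + 1L
    wsize <- 25L
    pos <- init_buffer
    while (pos < n_warmup - term_buffer) {
      nxt <- pos + wsize
      if (nxt + 2L * wsize > n_warmup - term_buffer) nxt <- n_warmup - term_buffer
      window_ends <- c(window_ends, nxt)
      pos <- nxt
      wsize <- wsize * 2L
    }
  }

  welford_n <- 0L
  welford_mean <- rep(0, npar)
  welford_m2 <- rep(0, npar)
  welford_add <- function(v) {
    welford_n <<- welford_n + 1L
    delta <- v - welford_mean
    welford_mean <<- welford_mean + delta / welford_n
    welford_m2 <<- welford_m2 + delta * (v - welford_mean)
  }
  welford_reset <- function() {
    welford_n <<- 0L
    welford_mean <<- rep(0, npar)
    welford_m2 <<- rep(0, npar)
  }

  in_window <- function(i) length(window_ends) > 0 &&
    i > init_buffer && i <= max(window_ends)

  for (i in seq_len(n_warmup)) {
    tr <- transition(theta, f, eps)
    theta <- tr$theta; f <- tr$f
    da_update(tr$accept)
    if (in_window(i)) {
      welford_add(theta)
      if (i %in% window_ends && welford_n >= 10L) {
        v <- welford_m2 / (welford_n - 1L)
        n <- welford_n
        inv_metric <- (n / (n + 5)) * v + 1e-3 * (5 / (n + 5))
        inv_metric <- pmax(inv_metric, 1e-10)
        welford_reset()
        da_restart()
      }
    }
  }
  eps <- exp(if (adapt_count > 0) log_eps_bar else log(eps))

  draws <- matrix(NA_real_, n_draws, npar)
  lp <- numeric(n_draws)
  div_count <- 0L
  accept_sum <- 0
  depth_sum <- 0L
  for (i in seq_len(n_draws)) {
    tr <- transition(theta, f, eps)
    theta <- tr$theta; f <- tr$f
    draws[i, ] <- theta
    lp[i] <- f$value
    div_count <- div_count + tr$div
    accept_sum <- accept_sum + tr$accept
    depth_sum <- depth_sum + tr$depth
  }
  list(draws = draws, lp = lp, divergences = div_count, step_size = eps,
       mean_accept = accept_sum / n_draws,
       treedepth = depth_sum / n_draws)
}
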