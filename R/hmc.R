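# Adaptive Hamiltonian Monte Carlo. Gradient-based sampling with
# dual-averaging step-size adaptation, diagonal mass-matrix estimation
# during warm-up, and jittered leapfrog trajectory lengths. The sampler is
# generic: it takes a log-density and its gradient on an unconstrained
# parameter vector. Model-specific posteriors are built in fit.R.

# The (inverse) mass matrix is diagonal except for an optional dense block
# over a small set of coordinates (strongly correlated fixed effects);
# `v` holds the diagonal of M^-1, `S` the dense M^-1 block and `L` its
# Cholesky factor.
new_mass <- function(v, dense_idx = NULL, S = NULL) {
  L <- if (!is.null(S)) chol(S)  # upper triangular, S = t(L) %*% L
  list(v = v, di = dense_idx, S = S, L = L)
}

minv_mult <- function(mass, p) {
  out <- mass$v * p
  if (!is.null(mass$di)) out[mass$di] <- as.vector(mass$S %*% p[mass$di])
  out
}

kinetic_energy <- function(mass, p) {
  0.5 * sum(p * minv_mult(mass, p))
}

draw_momentum <- function(mass, d) {
  p <- rnorm(d) / sqrt(mass$v)
  if (!is.null(mass$di)) {
    # p_dense ~ N(0, S^-1): backsolve against the Cholesky of S
    p[mass$di] <- backsolve(mass$L, rnorm(length(mass$di)))
  }
  p
}

leapfrog <- function(q, p, eps, n_steps, grad, mass) {
  g <- grad(q)
  p <- p + 0.5 * eps * g
  for (s in seq_len(n_steps)) {
    q <- q + eps * minv_mult(mass, p)
    g <- grad(q)
    if (any(!is.finite(g))) return(list(q = q, p = p, ok = FALSE))
    p <- p + (if (s < n_steps) eps else 0.5 * eps) * g
  }
  list(q = q, p = p, ok = TRUE)
}

hamiltonian <- function(q, p, log_post, mass) {
  -log_post(q) + kinetic_energy(mass, p)
}

# reasonable starting step size: double/halve until the one-step acceptance
# probability crosses 1/2 (standard heuristic)
find_initial_eps <- function(q, log_post, grad, mass) {
  eps <- 0.1
  p <- draw_momentum(mass, length(q))
  h0 <- hamiltonian(q, p, log_post, mass)
  step_ratio <- function(eps) {
    lf <- leapfrog(q, p, eps, 1L, grad, mass)
    if (!lf$ok) return(-Inf)
    h1 <- hamiltonian(lf$q, lf$p, log_post, mass)
    h0 - h1
  }
  a <- if (step_ratio(eps) > log(0.5)) 1 else -1
  for (i in 1:50) {
    eps2 <- eps * 2^a
    if ((a == 1 && step_ratio(eps2) <= log(0.5)) ||
        (a == -1 && step_ratio(eps2) >= log(0.5))) break
    eps <- eps2
  }
  eps
}

hmc_chain <- function(log_post, grad, init, iter_warmup, iter_sampling,
                      control, chain_seed) {
  set.seed(chain_seed)
  d <- length(init)
  q <- init + rnorm(d, 0, control$init_jitter)
  dense_idx <- control$dense_idx
  mass <- new_mass(rep(1, d))
  eps <- find_initial_eps(q, log_post, grad, mass)

  # dual averaging state
  da_reset <- function(eps) {
    list(mu = log(10 * eps), log_eps_bar = 0, h_bar = 0, count = 0)
  }
  da <- da_reset(eps)
  gamma <- 0.05; t0 <- 10; kappa <- 0.75
  delta <- control$target_accept

  # Welford accumulator for the diagonal mass matrix, refreshed over
  # expanding (doubling) windows as in Stan's warm-up schedule; draws of
  # the dense-block coordinates are kept to estimate their covariance
  w_n <- 0; w_mean <- numeric(d); w_m2 <- numeric(d)
  dense_buf <- if (!is.null(dense_idx)) {
    matrix(NA_real_, iter_warmup, length(dense_idx))
  }
  t_init <- min(75L, max(1L, floor(0.15 * iter_warmup)))
  t_final <- max(1L, floor(0.2 * iter_warmup))
  window_ends <- integer(0)
  if (iter_warmup - t_init - t_final > 20) {
    wlen <- 25L
    pos <- t_init
    last <- iter_warmup - t_final
    while (pos + wlen < last) {
      pos <- pos + wlen
      window_ends <- c(window_ends, pos)
      wlen <- wlen * 2L
    }
    window_ends <- c(window_ends[window_ends < last], last)
    window_ends <- unique(window_ends)
  }

  draws <- matrix(NA_real_, iter_sampling, d)
  n_div <- 0L; acc_sum <- 0
  lp_q <- log_post(q)
  lp_draws <- numeric(iter_sampling)

  total <- iter_warmup + iter_sampling
  for (it in seq_len(total)) {
    p <- draw_momentum(mass, d)
    h0 <- -lp_q + kinetic_energy(mass, p)
    base_l <- max(1L, min(control$max_leapfrog,
                          as.integer(round(control$trajectory_length / eps))))
    n_steps <- max(1L, min(control$max_leapfrog,
                           as.integer(round(base_l * runif(1, 0.7, 1.3)))))
    lf <- leapfrog(q, p, eps, n_steps, grad, mass)
    if (lf$ok) {
      lp_new <- log_post(lf$q)
      h1 <- -lp_new + kinetic_energy(mass, lf$p)
      dh <- h0 - h1
    } else dh <- -Inf
    if (!is.finite(dh)) {
      accept_prob <- 0
      if (it > iter_warmup) n_div <- n_div + 1L
    } else {
      accept_prob <- min(1, exp(dh))
    }
    if (is.finite(dh) && log(runif(1)) < dh) {
      q <- lf$q
      lp_q <- lp_new
    }

    if (it <= iter_warmup) {
      # dual averaging step-size update
      da$count <- da$count + 1
      frac <- 1 / (da$count + t0)
      da$h_bar <- (1 - frac) * da$h_bar + frac * (delta - accept_prob)
      log_eps <- da$mu - sqrt(da$count) / gamma * da$h_bar
      w <- da$count^(-kappa)
      da$log_eps_bar <- w * log_eps + (1 - w) * da$log_eps_bar
      eps <- exp(log_eps)

      if (length(window_ends) > 0 && it > t_init &&
          it <= window_ends[length(window_ends)]) {
        w_n <- w_n + 1
        delta_q <- q - w_mean
        w_mean <- w_mean + delta_q / w_n
        w_m2 <- w_m2 + delta_q * (q - w_mean)
        if (!is.null(dense_idx)) dense_buf[w_n, ] <- q[dense_idx]
        if (it %in% window_ends && w_n > 10) {
          v <- w_m2 / (w_n - 1)
          # regularise towards unit as Stan does for small windows
          v <- (w_n / (w_n + 5)) * v + (5 / (w_n + 5)) * 1e-3
          v <- pmax(v, 1e-10)
          S <- NULL
          if (!is.null(dense_idx) && w_n > length(dense_idx) + 5) {
            Sw <- stats::cov(dense_buf[seq_len(w_n), , drop = FALSE])
            sh <- w_n / (w_n + 5)
            S <- sh * Sw + (1 - sh) * diag(diag(Sw) + 1e-3)
            ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
            if (!ok) S <- NULL
          }
          mass <- if (is.null(S)) new_mass(v) else new_mass(v, dense_idx, S)
          eps <- find_initial_eps(q, log_post, grad, mass)
          da <- da_reset(eps)
          w_n <- 0; w_mean <- numeric(d); w_m2 <- numeric(d)
          if (isTRUE(control$verbose)) {
            message(sprintf("  warmup %d: mass refresh (%s), eps -> %.4f",
                            it, if (is.null(S)) "diag" else "diag+dense",
                            eps))
          }
        }
      }
      if (it == iter_warmup) eps <- exp(da$log_eps_bar)
    } else {
      draws[it - iter_warmup, ] <- q
      lp_draws[it - iter_warmup] <- lp_q
      acc_sum <- acc_sum + accept_prob
    }
  }
  list(draws = draws, lp = lp_draws, eps = eps,
       accept_rate = acc_sum / iter_sampling, divergences = n_div)
}

#' Sample with adaptive Hamiltonian Monte Carlo
#'
#' Generic gradient-based MCMC on an unconstrained parameter vector:
#' dual-averaging step-size adaptation towards a target acceptance
#' statistic, diagonal mass-matrix estimation from the middle of warm-up,
#' and leapfrog trajectories of jittered length. Runs `n_chains`
#' independent chains (sequentially) from jittered starts and attaches
#' split-R-hat and effective-sample-size diagnostics per coordinate.
#'
#' @param log_post Function: unconstrained parameter vector -> log density.
#' @param grad Function: unconstrained parameter vector -> gradient vector.
#' @param init Initial parameter vector (names become draw column names).
#' @param n_chains Number of chains.
#' @param iter_warmup,iter_sampling Warm-up and retained iterations per
#'   chain.
#' @param seed Integer seed; chain `k` uses `seed + k`.
#' @param control List overriding `target_accept` (0.85), `max_leapfrog`
#'   (32), `trajectory_length` (1.2), `init_jitter` (0.5), and optionally
#'   `dense_idx`: indices of coordinates given a dense mass-matrix block
#'   (for small sets of strongly correlated parameters; all other
#'   coordinates keep a diagonal mass).
#' @return List with `draws` (matrix, `n_chains * iter_sampling` rows),
#'   `chain` (row chain ids), `lp` (log-density per draw), `diagnostics`
#'   (tibble: parameter, rhat, ess), `accept_rate`, `step_size`,
#'   `divergences`.
#' @export
hmc_sample <- function(log_post, grad, init, n_chains = 2,
                       iter_warmup = 500, iter_sampling = 500,
                       seed = 1, control = list()) {
  control <- utils::modifyList(
    list(target_accept = 0.85, max_leapfrog = 32,
         trajectory_length = 1.2, init_jitter = 0.5),
    control)
  chains <- lapply(seq_len(n_chains), function(k) {
    hmc_chain(log_post, grad, init, iter_warmup, iter_sampling,
              control, chain_seed = seed + k)
  })
  draws <- do.call(rbind, lapply(chains, `[[`, "draws"))
  colnames(draws) <- names(init)
  arr <- array(NA_real_, c(iter_sampling, n_chains, length(init)))
  for (k in seq_len(n_chains)) arr[, k, ] <- chains[[k]]$draws
  diagnostics <- tibble::tibble(
    parameter = names(init) %||% paste0("par", seq_along(init)),
    rhat = apply(arr, 3, split_rhat),
    ess = apply(arr, 3, ess_basic)
  )
  list(draws = draws,
       chain = rep(seq_len(n_chains), each = iter_sampling),
       lp = unlist(lapply(chains, `[[`, "lp")),
       diagnostics = diagnostics,
       accept_rate = vapply(chains, `[[`, numeric(1), "accept_rate"),
       step_size = vapply(chains, `[[`, numeric(1), "eps"),
       divergences = sum(vapply(chains, `[[`, integer(1), "divergences")))
}

#' Split-R-hat convergence diagnostic
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half, so within-chain drift is detected as well as between-chain
#' disagreement. Values near 1 indicate convergence.
#'
#' @param x Matrix of draws, one column per chain (or a vector for a single
#'   chain, which is split into two).
#' @return Scalar R-hat.
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  half <- floor(n / 2)
  sm <- cbind(x[seq_len(half), , drop = FALSE],
              x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sm); nn <- nrow(sm)
  means <- colMeans(sm)
  vars <- apply(sm, 2, var)
  w <- mean(vars)
  b <- nn * var(means)
  if (w == 0) return(1)
  sqrt((nn - 1) / nn + b / (w * nn))
}

#' Effective sample size
#'
#' Autocorrelation-based effective sample size using Geyer's initial
#' positive-sequence truncation, pooled across chains.
#'
#' @param x Matrix of draws, one column per chain (or a vector).
#' @return Scalar effective sample size.
#' @export
ess_basic <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  if (n < 4) return(n * m)
  w <- mean(apply(x, 2, var))
  if (w == 0) return(n * m)
  max_lag <- min(n - 2, 200)
  acov <- sapply(seq_len(m), function(k) {
    drop(stats::acf(x[, k], lag.max = max_lag, type = "covariance",
                    plot = FALSE, demean = TRUE)$acf)
  })
  rho <- rowMeans(acov) / w
  # Geyer initial positive sequence on paired sums
  tau <- 1
  lag <- 1
  while (lag + 1 <= max_lag) {
    pair <- rho[lag + 1] + rho[lag + 2]
    if (!is.finite(pair) || pair < 0) break
    tau <- tau + 2 * pair
    lag <- lag + 2
  }
  max(1, n * m / tau)
}
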