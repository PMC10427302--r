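# Posterior sampling for the three model blocks. The joint posterior
# factorises exactly: observed rating differences and standardised scores
# enter the choice submodel as data, so the choice block, the three rating
# blocks and the scales block share no parameters and are sampled
# independently (see the methods vignette). Each block is expressed on an
# unconstrained scale (log hyper-SDs, ordered-transform cut-points) with an
# analytic gradient, and sampled with the adaptive HMC backend in hmc.R.
# Varying intercepts use a mixed parameterisation chosen by how strongly
# the data inform each set: centred where every group has many
# observations (choice targets; rating targets and raters), non-centred
# where groups are data-poor (choice raters with 12 trials; target x rater
# pairs with 2 ratings).

log1pexp <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

# ---- choice block -----------------------------------------------------

build_choice_block <- function(data, priors, backend = c("cpp", "r")) {
  backend <- match.arg(backend)
  pred <- choice_predictors(data)
  if (nrow(pred) == 0) abort("No usable choice records")
  n <- nrow(pred)
  nt <- max(data$choices$target_id)
  nr <- nrow(data$raters)
  ci <- match(pred$condition, condition_levels)
  cond_ind <- function(k) as.numeric(ci == k)
  X <- cbind(
    cond_ind(1), cond_ind(2), cond_ind(3),
    cond_ind(1) * pred$d_attractiveness, cond_ind(2) * pred$d_attractiveness,
    cond_ind(3) * pred$d_attractiveness,
    cond_ind(1) * pred$d_formidability, cond_ind(2) * pred$d_formidability,
    cond_ind(3) * pred$d_formidability,
    cond_ind(1) * pred$d_healthiness, cond_ind(2) * pred$d_healthiness,
    cond_ind(3) * pred$d_healthiness,
    pred$z_pp, pred$z_rs, pred$side_contrast)
  nb <- ncol(X)
  prior_sd <- c(rep(priors$intercept[2], 3), rep(priors$slope[2], nb - 3))
  prior_mean <- c(rep(priors$intercept[1], 3), rep(priors$slope[1], nb - 3))
  y <- pred$chose_masculinised
  Zt <- Matrix::sparseMatrix(i = seq_len(n), j = pred$target_id, x = 1,
                             dims = c(n, nt))
  ri <- match(pred$rater_id, data$raters$rater_id)
  Zr <- Matrix::sparseMatrix(i = seq_len(n), j = ri, x = 1, dims = c(n, nr))
  rate <- priors$hyper_sd_rate

  idx_b <- 1:nb
  idx_ls <- nb + 1:2
  idx_u <- nb + 2 + seq_len(nt)
  idx_v <- nb + 2 + nt + seq_len(nr)
  d_total <- nb + 2 + nt + nr

  unpack <- function(q) {
    list(b = q[idx_b], st = exp(q[[idx_ls[1]]]), sr = exp(q[[idx_ls[2]]]),
         u = q[idx_u], v = q[idx_v])
  }
  # u_target centred (289 choices per target), v_rater non-centred
  eta_of <- function(p) {
    as.vector(X %*% p$b) + as.vector(Zt %*% p$u) +
      p$sr * as.vector(Zr %*% p$v)
  }
  log_post <- function(q) {
    p <- unpack(q)
    eta <- eta_of(p)
    sum(y * eta - log1pexp(eta)) -
      0.5 * sum(((p$b - prior_mean) / prior_sd)^2) -
      rate * (p$st + p$sr) + log(p$st) + log(p$sr) -
      0.5 * sum(p$u^2) / p$st^2 - nt * log(p$st) - 0.5 * sum(p$v^2)
  }
  grad <- function(q) {
    p <- unpack(q)
    eta <- eta_of(p)
    r <- y - plogis(eta)
    ztr_ <- as.vector(Matrix::crossprod(Zt, r))
    zrr_ <- as.vector(Matrix::crossprod(Zr, r))
    g <- numeric(d_total)
    g[idx_b] <- as.vector(crossprod(X, r)) - (p$b - prior_mean) / prior_sd^2
    g[idx_ls[1]] <- sum(p$u^2) / p$st^2 - nt - rate * p$st + 1
    g[idx_ls[2]] <- p$sr * sum(p$v * zrr_) - rate * p$sr + 1
    g[idx_u] <- ztr_ - p$u / p$st^2
    g[idx_v] <- p$sr * zrr_ - p$v
    g
  }
  if (backend == "cpp") {
    yi <- as.integer(y)
    cii <- as.integer(ci)
    tii <- as.integer(pred$target_id)
    rii <- as.integer(ri)
    dA <- pred$d_attractiveness; dF <- pred$d_formidability
    dH <- pred$d_healthiness
    zp <- pred$z_pp; zr <- pred$z_rs; sc <- pred$side_contrast
    log_post <- function(q) {
      choice_lp_cpp(q, yi, cii, dA, dF, dH, zp, zr, sc, tii, rii,
                    nt, nr, prior_mean, prior_sd, rate)
    }
    grad <- function(q) {
      choice_grad_cpp(q, yi, cii, dA, dF, dH, zp, zr, sc, tii, rii,
                      nt, nr, prior_mean, prior_sd, rate)
    }
  }
  init <- rep(0, d_total)
  init[idx_ls] <- log(0.5)
  names(init) <- c(
    sprintf("alpha[%s]", cond_short), sprintf("b_attr[%s]", cond_short),
    sprintf("b_form[%s]", cond_short), sprintf("b_heal[%s]", cond_short),
    "b_pp", "b_rs", "b_side", "log_sigma_target", "log_sigma_rater",
    sprintf("u_target[%d]", seq_len(nt)), sprintf("v_rater[%d]", seq_len(nr)))

  transform <- function(draws) {
    st <- exp(draws[, idx_ls[1]]); sr <- exp(draws[, idx_ls[2]])
    draws[, idx_ls[1]] <- st
    draws[, idx_ls[2]] <- sr
    draws[, idx_v] <- draws[, idx_v, drop = FALSE] * sr
    cn <- colnames(draws)
    cn[idx_ls] <- c("sigma_target", "sigma_rater")
    colnames(draws) <- cn
    draws
  }
  list(init = init, log_post = log_post, grad = grad, transform = transform,
       n_obs = n, n_dropped = attr(pred, "n_dropped"))
}

# ---- rating block -----------------------------------------------------

build_rating_block <- function(data, dimension, priors,
                               backend = c("cpp", "r")) {
  backend <- match.arg(backend)
  dimension <- match.arg(dimension, dimension_levels)
  rat <- data$ratings[data$ratings$dimension == dimension, ]
  if (nrow(rat) == 0) abort(sprintf("No '%s' ratings in the data", dimension))
  n <- nrow(rat)
  nt <- max(data$choices$target_id)
  nr <- nrow(data$raters)
  ri <- match(rat$rater_id, data$raters$rater_id)
  ci <- match(data$raters$condition[ri], condition_levels)
  z_pp <- data$raters$z_pp[ri]
  z_rs <- data$raters$z_rs[ri]
  mas <- as.numeric(rat$version == "masculinised")
  fem <- 1 - mas
  cond_ind <- function(k) as.numeric(ci == k)
  X <- cbind(mas * cond_ind(1), mas * cond_ind(2), mas * cond_ind(3),
             fem * cond_ind(1), fem * cond_ind(2), fem * cond_ind(3),
             mas * z_pp, mas * z_rs, fem * z_pp, fem * z_rs)
  nb <- ncol(X)
  prior_sd <- c(rep(priors$intercept[2], 6), rep(priors$slope[2], 4))
  prior_mean <- c(rep(priors$intercept[1], 6), rep(priors$slope[1], 4))
  y <- rat$score
  # observed target x rater pairs index the interaction intercepts
  pair_key <- paste(rat$target_id, ri)
  pair_levels <- unique(pair_key)
  pi_ <- match(pair_key, pair_levels)
  np <- length(pair_levels)
  pair_tr <- do.call(rbind, strsplit(pair_levels, " "))
  Zt <- Matrix::sparseMatrix(i = seq_len(n), j = rat$target_id, x = 1,
                             dims = c(n, nt))
  Zr <- Matrix::sparseMatrix(i = seq_len(n), j = ri, x = 1, dims = c(n, nr))
  Zp <- Matrix::sparseMatrix(i = seq_len(n), j = pi_, x = 1, dims = c(n, np))
  rate <- priors$hyper_sd_rate
  cut_prior_mean <- priors$cutpoint[1]
  cut_prior_sd <- priors$cutpoint[2]

  idx_b <- 1:nb
  idx_cut <- nb + 1:6
  idx_ls <- nb + 6 + 1:3
  idx_w <- nb + 9 + seq_len(nt)
  idx_x <- nb + 9 + nt + seq_len(nr)
  idx_z <- nb + 9 + nt + nr + seq_len(np)
  d_total <- nb + 9 + nt + nr + np

  unpack <- function(q) {
    raw <- q[idx_cut]
    list(b = q[idx_b], cut = cumsum(c(raw[1], exp(raw[-1]))), raw = raw,
         sT = exp(q[[idx_ls[1]]]), sR = exp(q[[idx_ls[2]]]),
         sP = exp(q[[idx_ls[3]]]),
         w = q[idx_w], x = q[idx_x], z = q[idx_z])
  }
  # w_target and x_rater centred (many ratings per group), z_tr
  # non-centred (two ratings per pair)
  phi_of <- function(p) {
    as.vector(X %*% p$b) + as.vector(Zt %*% p$w) +
      as.vector(Zr %*% p$x) + p$sP * as.vector(Zp %*% p$z)
  }
  log_post <- function(q) {
    p <- unpack(q)
    phi <- phi_of(p)
    cl <- c(-Inf, p$cut)[y]
    cu <- c(p$cut, Inf)[y]
    pk <- plogis(phi - cl) - plogis(phi - cu)
    if (any(pk <= 0)) return(-Inf)
    sum(log(pk)) -
      0.5 * sum(((p$b - prior_mean) / prior_sd)^2) -
      0.5 * sum(((p$raw - cut_prior_mean) / cut_prior_sd)^2) -
      rate * (p$sT + p$sR + p$sP) + log(p$sT) + log(p$sR) + log(p$sP) -
      0.5 * sum(p$w^2) / p$sT^2 - nt * log(p$sT) -
      0.5 * sum(p$x^2) / p$sR^2 - nr * log(p$sR) - 0.5 * sum(p$z^2)
  }
  grad <- function(q) {
    p <- unpack(q)
    phi <- phi_of(p)
    cl <- c(-Inf, p$cut)[y]
    cu <- c(p$cut, Inf)[y]
    s1 <- plogis(phi - cl)
    s2 <- plogis(phi - cu)
    pk <- pmax(s1 - s2, 1e-300)
    gphi <- 1 - s1 - s2
    # cut-point gradients: c[k-1] is the lower cut of score k, c[k] the upper
    g_lower <- -s1 * (1 - s1) / pk          # w.r.t. cut index y-1 (0 = none)
    g_upper <- s2 * (1 - s2) / pk           # w.r.t. cut index y (7 = none)
    g_cut <- numeric(6)
    low_idx <- y - 1L
    keep <- low_idx >= 1L
    if (any(keep)) {
      agg <- rowsum(g_lower[keep], low_idx[keep])
      g_cut[as.integer(rownames(agg))] <- g_cut[as.integer(rownames(agg))] + agg[, 1]
    }
    keep <- y <= 6L
    if (any(keep)) {
      agg <- rowsum(g_upper[keep], y[keep])
      g_cut[as.integer(rownames(agg))] <- g_cut[as.integer(rownames(agg))] + agg[, 1]
    }
    # chain rule through the ordered transform
    rev_cum <- rev(cumsum(rev(g_cut)))
    g_raw <- c(rev_cum[1], rev_cum[-1] * exp(p$raw[-1])) -
      (p$raw - cut_prior_mean) / cut_prior_sd^2
    ztw_ <- as.vector(Matrix::crossprod(Zt, gphi))
    zrx_ <- as.vector(Matrix::crossprod(Zr, gphi))
    zpz_ <- as.vector(Matrix::crossprod(Zp, gphi))
    g <- numeric(d_total)
    g[idx_b] <- as.vector(crossprod(X, gphi)) - (p$b - prior_mean) / prior_sd^2
    g[idx_cut] <- g_raw
    g[idx_ls[1]] <- sum(p$w^2) / p$sT^2 - nt - rate * p$sT + 1
    g[idx_ls[2]] <- sum(p$x^2) / p$sR^2 - nr - rate * p$sR + 1
    g[idx_ls[3]] <- p$sP * sum(p$z * zpz_) - rate * p$sP + 1
    g[idx_w] <- ztw_ - p$w / p$sT^2
    g[idx_x] <- zrx_ - p$x / p$sR^2
    g[idx_z] <- p$sP * zpz_ - p$z
    g
  }
  if (backend == "cpp") {
    yi <- as.integer(y)
    cii <- as.integer(ci)
    masi <- as.integer(mas)
    tii <- as.integer(rat$target_id)
    rii <- as.integer(ri)
    pii <- as.integer(pi_)
    log_post <- function(q) {
      rating_lp_cpp(q, yi, cii, masi, z_pp, z_rs, tii, rii, pii,
                    nt, nr, np, prior_mean, prior_sd,
                    cut_prior_mean, cut_prior_sd, rate)
    }
    grad <- function(q) {
      rating_grad_cpp(q, yi, cii, masi, z_pp, z_rs, tii, rii, pii,
                      nt, nr, np, prior_mean, prior_sd,
                      cut_prior_mean, cut_prior_sd, rate)
    }
  }
  # initialise cut-points at the empirical marginal logit quantiles
  ecum <- cumsum(tabulate(y, 7))[1:6] / n
  ecum <- pmin(pmax(ecum, 0.01), 0.99)
  ecut <- qlogis(ecum)
  ecut <- ecut + seq(0, 1e-3, length.out = 6)  # enforce strict ordering
  init <- rep(0, d_total)
  init[idx_cut] <- cutpoints_to_raw(ecut)
  init[idx_ls] <- log(0.5)
  pre <- dim_short[dimension]
  names(init) <- c(
    sprintf("%s.a_mas[%s]", pre, cond_short),
    sprintf("%s.a_fem[%s]", pre, cond_short),
    sprintf("%s.g_mas_pp", pre), sprintf("%s.g_mas_rs", pre),
    sprintf("%s.g_fem_pp", pre), sprintf("%s.g_fem_rs", pre),
    sprintf("%s.cut[%d]", pre, 1:6),
    sprintf("%s.log_sigma_target", pre), sprintf("%s.log_sigma_rater", pre),
    sprintf("%s.log_sigma_tr", pre),
    sprintf("%s.w_target[%d]", pre, seq_len(nt)),
    sprintf("%s.x_rater[%d]", pre, seq_len(nr)),
    sprintf("%s.z_tr[%s,%s]", pre, pair_tr[, 1], pair_tr[, 2]))

  transform <- function(draws) {
    # raw cut locations -> ordered cut-points
    cuts <- draws[, idx_cut, drop = FALSE]
    for (j in 2:6) cuts[, j] <- cuts[, j - 1] + exp(draws[, idx_cut[j]])
    draws[, idx_cut] <- cuts
    sT <- exp(draws[, idx_ls[1]]); sR <- exp(draws[, idx_ls[2]])
    sP <- exp(draws[, idx_ls[3]])
    draws[, idx_ls[1]] <- sT; draws[, idx_ls[2]] <- sR
    draws[, idx_ls[3]] <- sP
    draws[, idx_z] <- draws[, idx_z, drop = FALSE] * sP
    cn <- colnames(draws)
    cn[idx_ls] <- sprintf("%s.%s", pre,
                          c("sigma_target", "sigma_rater", "sigma_tr"))
    colnames(draws) <- cn
    draws
  }
  list(init = init, log_post = log_post, grad = grad, transform = transform,
       n_obs = n, pair_target = as.integer(pair_tr[, 1]),
       pair_rater = as.integer(pair_tr[, 2]))
}

# ---- scales block -----------------------------------------------------

build_scales_block <- function(data, priors, fix_resid_sd = NULL) {
  raters <- data$raters
  if (!all(c("z_pp", "z_rs") %in% names(raters))) {
    abort("Raters must carry `z_pp`, `z_rs`")
  }
  ci <- match(raters$condition, condition_levels)
  Zc <- Matrix::sparseMatrix(i = seq_len(nrow(raters)), j = ci, x = 1,
                             dims = c(nrow(raters), 3))
  z <- cbind(raters$z_pp, raters$z_rs)
  n_c <- as.vector(Matrix::colSums(Zc))
  pm <- priors$scale_mu
  rate <- priors$resid_sd_rate
  free_sd <- is.null(fix_resid_sd)
  d_total <- 6 + if (free_sd) 2 else 0

  unpack <- function(q) {
    mu <- matrix(q[1:6], 2, 3, byrow = TRUE)
    sd_ <- if (free_sd) exp(q[7:8]) else fix_resid_sd
    list(mu = mu, sd = sd_)
  }
  log_post <- function(q) {
    p <- unpack(q)
    ll <- 0
    for (s in 1:2) {
      res <- z[, s] - p$mu[s, ci]
      ll <- ll - 0.5 * sum(res^2) / p$sd[s]^2 -
        nrow(raters) * log(p$sd[s])
    }
    ll <- ll - 0.5 * sum((q[1:6] - pm[1]) / pm[2] * ((q[1:6] - pm[1]) / pm[2]))
    if (free_sd) ll <- ll - rate * sum(p$sd) + sum(q[7:8])
    ll
  }
  grad <- function(q) {
    p <- unpack(q)
    g <- numeric(d_total)
    for (s in 1:2) {
      res <- z[, s] - p$mu[s, ci]
      gmu <- as.vector(Matrix::crossprod(Zc, res)) / p$sd[s]^2
      g[(s - 1) * 3 + 1:3] <- gmu
      if (free_sd) {
        g[6 + s] <- sum(res^2) / p$sd[s]^2 - nrow(raters) -
          rate * p$sd[s] + 1
      }
    }
    g[1:6] <- g[1:6] - (q[1:6] - pm[1]) / pm[2]^2
    g
  }
  init <- rep(0, d_total)
  nm <- c(sprintf("mu_pp[%s]", cond_short), sprintf("mu_rs[%s]", cond_short))
  if (free_sd) nm <- c(nm, "log_resid_sd_pp", "log_resid_sd_rs")
  names(init) <- nm
  transform <- function(draws) {
    if (free_sd) {
      draws[, 7:8] <- exp(draws[, 7:8, drop = FALSE])
      colnames(draws)[7:8] <- c("resid_sd_pp", "resid_sd_rs")
    }
    draws
  }
  list(init = init, log_post = log_post, grad = grad, transform = transform,
       n_obs = 2 * nrow(raters))
}

# ---- fitting ----------------------------------------------------------

new_posterior_draws <- function(draws, chain, diagnostics, seed, settings,
                                meta = list()) {
  structure(list(draws = draws, chain = chain, diagnostics = diagnostics,
                 seed = seed, settings = settings, meta = meta),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat("<posterior_draws> ", nrow(x$draws), " draws x ", ncol(x$draws),
      " parameters (", max(x$chain), " chains)\n", sep = "")
  cat(sprintf("  max split-Rhat %.3f, min ESS %.0f, %d divergence(s)\n",
              max(x$diagnostics$rhat, na.rm = TRUE),
              min(x$diagnostics$ess, na.rm = TRUE),
              x$settings$divergences %||% 0L))
  invisible(x)
}

check_convergence <- function(fit_res, on_bad_rhat, label) {
  bad <- fit_res$diagnostics$rhat > 1.05
  bad[is.na(bad)] <- FALSE
  if (any(bad)) {
    worst <- fit_res$diagnostics[bad, ]
    worst <- worst[order(-worst$rhat), ]
    msg <- sprintf(
      "%s block: %d parameter(s) with split-Rhat > 1.05 (worst: %s = %.3f)",
      label, sum(bad), worst$parameter[1], worst$rhat[1])
    switch(on_bad_rhat,
           error = abort(msg, class = "harshpref_convergence_error"),
           warn = warn(msg),
           ignore = invisible(NULL))
  }
  invisible(NULL)
}

fit_block <- function(block, n_chains, iter_warmup, iter_sampling, seed,
                      control, on_bad_rhat, label) {
  res <- hmc_sample(block$log_post, block$grad, block$init,
                    n_chains = n_chains, iter_warmup = iter_warmup,
                    iter_sampling = iter_sampling, seed = seed,
                    control = control)
  draws <- block$transform(res$draws)
  # diagnostics on the constrained scale names
  res$diagnostics$parameter <- colnames(draws)
  check_convergence(res, on_bad_rhat, label)
  list(draws = draws, chain = res$chain, diagnostics = res$diagnostics,
       divergences = res$divergences, accept_rate = res$accept_rate,
       step_size = res$step_size)
}

#' Sample the posterior of one model block
#'
#' `fit_choice_model()` samples the forced-choice logistic block,
#' `fit_rating_model()` one cumulative-logit rating block, and
#' `fit_scales_model()` the scales (mediation) block; [fit_study()] runs
#' all five. Sampling is reproducible given `seed`; the fit fails loudly if
#' any split-R-hat exceeds 1.05 (override with `on_bad_rhat`).
#'
#' @param data A preprocessed [study_data] (exclusions applied, scales
#'   standardised, side contrast coded; see [preprocess_study()]).
#' @param priors A [default_priors()] object.
#' @param n_chains,iter_warmup,iter_sampling Chains and per-chain warm-up /
#'   retained iterations (total retained draws =
#'   `n_chains * iter_sampling`).
#' @param seed Integer seed.
#' @param control Passed to [hmc_sample()].
#' @param on_bad_rhat `"error"`, `"warn"` or `"ignore"`.
#' @return A `posterior_draws` object: draws on the constrained scale
#'   (hyper-SDs exponentiated, cut-points ordered, varying intercepts
#'   centred), chain ids, per-parameter diagnostics and sampler metadata.
#' @export
fit_choice_model <- function(data, priors = default_priors(), n_chains = 4,
                             iter_warmup = 500, iter_sampling = 2500,
                             seed = 1, control = list(),
                             on_bad_rhat = "error") {
  # dense mass block over the fixed effects and log hyper-SDs
  control <- utils::modifyList(
    list(max_leapfrog = 40, trajectory_length = 3, dense_idx = 1:17),
    control)
  block <- build_choice_block(data, priors)
  res <- fit_block(block, n_chains, iter_warmup, iter_sampling, seed,
                   control, on_bad_rhat, "choice")
  new_posterior_draws(res$draws, res$chain, res$diagnostics, seed,
                      list(n_chains = n_chains, iter_warmup = iter_warmup,
                           iter_sampling = iter_sampling,
                           divergences = res$divergences,
                           accept_rate = res$accept_rate),
                      meta = list(blocks = "choice",
                                  n_dropped_choice = block$n_dropped))
}

#' @rdname fit_choice_model
#' @param dimension Rating dimension to fit.
#' @export
fit_rating_model <- function(data, dimension, priors = default_priors(),
                             n_chains = 4, iter_warmup = 500,
                             iter_sampling = 2500, seed = 1,
                             control = list(), on_bad_rhat = "error") {
  dimension <- match.arg(dimension, dimension_levels)
  # the ordinal block's soft translation modes (cut-points vs. intercepts)
  # need longer trajectories than the other blocks
  # dense mass block over intercepts, slopes, cut-points and log
  # hyper-SDs: these carry the strong posterior correlations
  control <- utils::modifyList(
    list(max_leapfrog = 50, trajectory_length = 3.5, target_accept = 0.8,
         dense_idx = 1:19),
    control)
  block <- build_rating_block(data, dimension, priors)
  res <- fit_block(block, n_chains, iter_warmup, iter_sampling, seed,
                   control, on_bad_rhat, dimension)
  new_posterior_draws(res$draws, res$chain, res$diagnostics, seed,
                      list(n_chains = n_chains, iter_warmup = iter_warmup,
                           iter_sampling = iter_sampling,
                           divergences = res$divergences,
                           accept_rate = res$accept_rate),
                      meta = list(blocks = dimension,
                                  pair_target = block$pair_target,
                                  pair_rater = block$pair_rater))
}

#' @rdname fit_choice_model
#' @param fix_resid_sd Optional length-2 vector fixing the residual SDs
#'   (then only the six condition x scale means are sampled).
#' @export
fit_scales_model <- function(data, priors = default_priors(), n_chains = 4,
                             iter_warmup = 500, iter_sampling = 2500,
                             seed = 1, control = list(),
                             on_bad_rhat = "error", fix_resid_sd = NULL) {
  block <- build_scales_block(data, priors, fix_resid_sd)
  res <- fit_block(block, n_chains, iter_warmup, iter_sampling, seed,
                   control, on_bad_rhat, "scales")
  new_posterior_draws(res$draws, res$chain, res$diagnostics, seed,
                      list(n_chains = n_chains, iter_warmup = iter_warmup,
                           iter_sampling = iter_sampling,
                           divergences = res$divergences,
                           accept_rate = res$accept_rate),
                      meta = list(blocks = "scales"))
}

#' Sample the full joint posterior
#'
#' Fits all five blocks of the structural model (choice, three rating
#' dimensions, scales) and concatenates their draws column-wise into one
#' joint draw matrix; because the blocks share no parameters and condition
#' only on observed data, independent block sampling draws from the exact
#' joint posterior. Block `k` uses seed `seed + 1000 * k`.
#'
#' @inheritParams fit_choice_model
#' @return A `posterior_draws` object over the full parameter vector.
#' @export
fit_study <- function(data, priors = default_priors(), n_chains = 4,
                      iter_warmup = 500, iter_sampling = 2500, seed = 1,
                      control = list(), on_bad_rhat = "error") {
  fits <- list(
    choice = fit_choice_model(data, priors, n_chains, iter_warmup,
                              iter_sampling, seed + 1000, control,
                              on_bad_rhat))
  k <- 1
  for (d in dimension_levels) {
    k <- k + 1
    fits[[d]] <- fit_rating_model(data, d, priors, n_chains, iter_warmup,
                                  iter_sampling, seed + 1000 * k, control,
                                  on_bad_rhat)
  }
  fits$scales <- fit_scales_model(data, priors, n_chains, iter_warmup,
                                  iter_sampling, seed + 5000, control,
                                  on_bad_rhat)
  draws <- do.call(cbind, lapply(fits, function(f) f$draws))
  diagnostics <- dplyr::bind_rows(lapply(fits, function(f) f$diagnostics))
  meta <- list(blocks = c("choice", dimension_levels, "scales"),
               n_dropped_choice = fits$choice$meta$n_dropped_choice)
  for (d in dimension_levels) {
    meta[[paste0("pair_target_", d)]] <- fits[[d]]$meta$pair_target
    meta[[paste0("pair_rater_", d)]] <- fits[[d]]$meta$pair_rater
  }
  new_posterior_draws(
    draws, fits$choice$chain, diagnostics, seed,
    list(n_chains = n_chains, iter_warmup = iter_warmup,
         iter_sampling = iter_sampling,
         divergences = sum(vapply(fits, function(f)
           f$settings$divergences, numeric(1)))),
    meta = meta)
}

# ---- posterior summaries ----------------------------------------------

draws_matrix <- function(samples) {
  if (inherits(samples, "posterior_draws")) return(samples$draws)
  if (is.matrix(samples)) return(samples)
  if (is.numeric(samples)) {
    m <- matrix(samples, ncol = 1)
    colnames(m) <- attr(samples, "quantity") %||% "quantity"
    return(m)
  }
  abort("Expected posterior_draws, a draw matrix or a draw vector")
}

#' Summarise posterior draws
#'
#' Posterior mean and central compatibility interval (default 89%) for each
#' named quantity, plus convergence diagnostics where available.
#'
#' @param samples A `posterior_draws` object, a draws matrix with named
#'   columns, or a numeric draw vector.
#' @param prob Interval mass (default 0.89).
#' @param pars Optional regular expression selecting parameters.
#' @return A tibble with columns `name`, `mean`, `lower`, `upper` (and
#'   `rhat`, `ess` for fitted objects).
#' @export
summarise_posterior <- function(samples, prob = 0.89, pars = NULL) {
  m <- draws_matrix(samples)
  if (nrow(m) == 0) abort("Empty draw set")
  stopifnot(prob > 0, prob < 1)
  if (!is.null(pars)) {
    m <- m[, grepl(pars, colnames(m)), drop = FALSE]
  }
  a <- (1 - prob) / 2
  qs <- apply(m, 2, quantile, probs = c(a, 1 - a), names = FALSE)
  out <- tibble::tibble(
    name = colnames(m) %||% paste0("par", seq_len(ncol(m))),
    mean = unname(colMeans(m)),
    lower = unname(qs[1, ]),
    upper = unname(qs[2, ]))
  if (inherits(samples, "posterior_draws") && is.null(pars)) {
    out$rhat <- samples$diagnostics$rhat
    out$ess <- samples$diagnostics$ess
  } else if (inherits(samples, "posterior_draws")) {
    di <- samples$diagnostics[match(out$name, samples$diagnostics$parameter), ]
    out$rhat <- di$rhat
    out$ess <- di$ess
  }
  out
}

#' Posterior contrast between two named quantities
#'
#' Per-draw difference `a - b` between two columns of the draw matrix,
#' returned as a draw vector (summarise with [summarise_posterior()]).
#'
#' @param samples A `posterior_draws` object or draws matrix.
#' @param a,b Column names.
#' @return Numeric vector of per-draw differences with attribute
#'   `quantity = "a - b"`.
#' @export
posterior_contrast <- function(samples, a, b) {
  m <- draws_matrix(samples)
  for (nm in c(a, b)) {
    if (!nm %in% colnames(m)) {
      abort(sprintf("Unknown quantity `%s`", nm))
    }
  }
  out <- m[, a] - m[, b]
  attr(out, "quantity") <- paste(a, "-", b)
  out
}

#' Posterior of expected masculinised-minus-feminised rating differences
#'
#' For each posterior draw and each observed rater-target pair, computes
#' the expected Likert rating under the masculinised and the feminised
#' linear predictor (including that pair's target, rater and target-rater
#' varying intercepts), takes the difference, and averages the pairs within
#' each condition. Uses `E[Y] = 1 + sum_k P(Y > k)`.
#'
#' @param samples A `posterior_draws` from [fit_study()] or
#'   [fit_rating_model()].
#' @param data The preprocessed [study_data] the model was fitted to.
#' @param dimension Rating dimension.
#' @return Matrix of draws with one column per condition (named
#'   `diff_<dim>[<condition>]`).
#' @export
rating_difference_posterior <- function(samples, data, dimension) {
  dimension <- match.arg(dimension, dimension_levels)
  pre <- dim_short[dimension]
  m <- draws_matrix(samples)
  if (!sprintf("%s.cut[1]", pre) %in% colnames(m)) {
    abort(sprintf("Dimension '%s' not present in the fitted draws",
                  dimension))
  }
  pt <- samples$meta[[paste0("pair_target_", dimension)]] %||%
    samples$meta$pair_target
  pr <- samples$meta[[paste0("pair_rater_", dimension)]] %||%
    samples$meta$pair_rater
  if (is.null(pt)) abort("Fitted object lacks rater-target pair metadata")
  cond <- data$raters$condition[pr]
  ci <- match(cond, condition_levels)
  z_pp <- data$raters$z_pp[pr]
  z_rs <- data$raters$z_rs[pr]
  cuts <- m[, sprintf("%s.cut[%d]", pre, 1:6)]
  a_mas <- m[, sprintf("%s.a_mas[%s]", pre, cond_short)]
  a_fem <- m[, sprintf("%s.a_fem[%s]", pre, cond_short)]
  w <- m[, sprintf("%s.w_target[%d]", pre, pt), drop = FALSE]
  x <- m[, sprintf("%s.x_rater[%d]", pre, pr), drop = FALSE]
  z <- m[, sprintf("%s.z_tr[%d,%d]", pre, pt, pr), drop = FALSE]
  g_mas_pp <- m[, sprintf("%s.g_mas_pp", pre)]
  g_mas_rs <- m[, sprintf("%s.g_mas_rs", pre)]
  g_fem_pp <- m[, sprintf("%s.g_fem_pp", pre)]
  g_fem_rs <- m[, sprintf("%s.g_fem_rs", pre)]
  n_draws <- nrow(m)
  out <- matrix(NA_real_, n_draws, 3,
                dimnames = list(NULL, sprintf("diff_%s[%s]", pre, cond_short)))
  shared <- w + x + z   # draws x pairs
  ey <- function(phi, cutrow) {
    # 1 + sum_k plogis(phi - cut_k), vectorised over pairs
    acc <- numeric(length(phi)) + 1
    for (k in 1:6) acc <- acc + plogis(phi - cutrow[k])
    acc
  }
  for (s in seq_len(n_draws)) {
    base <- shared[s, ]
    phi_mas <- a_mas[s, ci] + g_mas_pp[s] * z_pp + g_mas_rs[s] * z_rs + base
    phi_fem <- a_fem[s, ci] + g_fem_pp[s] * z_pp + g_fem_rs[s] * z_rs + base
    d <- ey(phi_mas, cuts[s, ]) - ey(phi_fem, cuts[s, ])
    out[s, ] <- vapply(1:3, function(k) mean(d[ci == k]), numeric(1))
  }
  out
}
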