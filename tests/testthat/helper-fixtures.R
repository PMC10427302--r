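# Shared fixtures: all built in code, no files.

# small raw dataset, cheap enough for every test
tiny_study <- function(n_raters = c(4, 4, 4), n_targets = 4, seed = 101,
                       ...) {
  simulate_study(sim_config(n_raters = n_raters, n_targets = n_targets,
                            seed = seed, ...))
}

tiny_preprocessed <- function(...) {
  preprocess_study(tiny_study(...))$data
}

# the retained-sample fixture with the published recognition distribution:
# 289 raters x 12 targets; 21 raters recognise 1 face, 14 recognise 2,
# 7 recognise 3, 10 recognise 4
recognition_fixture <- function(seed = 202) {
  d <- simulate_study(sim_config(seed = seed))
  counts <- rep(c(1L, 2L, 3L, 4L), times = c(21L, 14L, 7L, 10L))
  ids <- d$raters$rater_id[seq_along(counts)]
  d$choices$recognised <- 0L
  for (i in seq_along(counts)) {
    rows <- which(d$choices$rater_id == ids[i])[seq_len(counts[i])]
    d$choices$recognised[rows] <- 1L
  }
  d
}

# draw valid parameter sets for fuzz tests
random_choice_params <- function(n_targets, n_raters) {
  choice_params(
    alpha = rnorm(3, 0, 0.5), beta_attr = rnorm(3, 0, 0.3),
    beta_form = rnorm(3, 0, 0.3), beta_heal = rnorm(3, 0, 0.3),
    beta_pp = rnorm(1, 0, 0.3), beta_rs = rnorm(1, 0, 0.3),
    beta_side = rnorm(1, 0, 0.3),
    sigma_target = rexp(1) + 0.1, sigma_rater = rexp(1) + 0.1,
    u_target = rnorm(n_targets, 0, 0.5), v_rater = rnorm(n_raters, 0, 0.3))
}

random_rating_params <- function(n_targets, n_raters) {
  rating_params(
    cutpoints = sort(rnorm(6, c(-2.5, -1.5, -0.5, 0.5, 1.5, 2.5), 0.2)),
    a_mas = rnorm(3, 0, 0.5), a_fem = rnorm(3, 0, 0.5),
    g_mas_pp = rnorm(1, 0, 0.3), g_mas_rs = rnorm(1, 0, 0.3),
    g_fem_pp = rnorm(1, 0, 0.3), g_fem_rs = rnorm(1, 0, 0.3),
    sigma_target = rexp(1) + 0.1, sigma_rater = rexp(1) + 0.1,
    sigma_tr = rexp(1) + 0.1,
    w_target = rnorm(n_targets, 0, 0.5), x_rater = rnorm(n_raters, 0, 0.5),
    z_tr = matrix(rnorm(n_targets * n_raters, 0, 0.3), n_targets, n_raters))
}

random_scale_params <- function() {
  scale_params(mu = matrix(rnorm(6, 0, 0.5), 2, 3),
               resid_sd = rexp(2) + 0.2)
}

random_joint_params <- function(data) {
  nt <- max(data$choices$target_id)
  nr <- nrow(data$raters)
  list(
    choice = random_choice_params(nt, nr),
    rating = setNames(
      lapply(1:3, function(i) random_rating_params(nt, nr)),
      c("attractiveness", "healthiness", "formidability")),
    scales = random_scale_params())
}

# fully naive single-loop reimplementation of the joint log-density,
# independent of the vectorised code paths in the package
naive_joint_logdensity <- function(params, data, priors) {
  raters <- as.data.frame(data$raters)
  choices <- as.data.frame(data$choices)
  ratings <- as.data.frame(data$ratings)
  rlookup <- function(id) which(raters$rater_id == id)
  cond_idx <- c(control = 1, pathogen_prevalence = 2, resource_scarcity = 3)

  ll <- 0
  # choice records, one by one
  for (i in seq_len(nrow(choices))) {
    rid <- choices$rater_id[i]; tid <- choices$target_id[i]
    r <- rlookup(rid)
    diffs <- numeric(3); ok <- TRUE
    dims <- c("attractiveness", "formidability", "healthiness")
    for (k in 1:3) {
      sub <- ratings[ratings$rater_id == rid & ratings$target_id == tid &
                       ratings$dimension == dims[k], ]
      m <- sub$score[sub$version == "masculinised"]
      f <- sub$score[sub$version == "feminised"]
      if (length(m) != 1 || length(f) != 1) { ok <- FALSE; break }
      diffs[k] <- m - f
    }
    if (!ok) next
    cp <- params$choice
    cc <- raters$condition[r]
    eta <- cp$alpha[[cc]] + cp$beta_attr[[cc]] * diffs[1] +
      cp$beta_form[[cc]] * diffs[2] + cp$beta_heal[[cc]] * diffs[3] +
      cp$beta_pp * raters$z_pp[r] + cp$beta_rs * raters$z_rs[r] +
      cp$beta_side * choices$side_contrast[i] +
      cp$u_target[tid] + cp$v_rater[r]
    p <- 1 / (1 + exp(-eta))
    y <- choices$chose_masculinised[i]
    ll <- ll + log(ifelse(y == 1, p, 1 - p))
  }
  # rating records
  for (i in seq_len(nrow(ratings))) {
    rp <- params$rating[[ratings$dimension[i]]]
    r <- rlookup(ratings$rater_id[i]); tid <- ratings$target_id[i]
    cc <- raters$condition[r]
    if (ratings$version[i] == "masculinised") {
      phi <- rp$a_mas[[cc]] + rp$g_mas_pp * raters$z_pp[r] +
        rp$g_mas_rs * raters$z_rs[r]
    } else {
      phi <- rp$a_fem[[cc]] + rp$g_fem_pp * raters$z_pp[r] +
        rp$g_fem_rs * raters$z_rs[r]
    }
    phi <- phi + rp$w_target[tid] + rp$x_rater[r] + rp$z_tr[tid, r]
    k <- ratings$score[i]
    upper <- if (k == 7) 0 else 1 / (1 + exp(-(phi - rp$cutpoints[k])))
    lower <- if (k == 1) 1 else 1 / (1 + exp(-(phi - rp$cutpoints[k - 1])))
    ll <- ll + log(lower - upper)
  }
  # scales
  sp <- params$scales
  for (r in seq_len(nrow(raters))) {
    ci <- cond_idx[[raters$condition[r]]]
    for (s in 1:2) {
      z <- if (s == 1) raters$z_pp[r] else raters$z_rs[r]
      ll <- ll + dnorm(z, sp$mu[s, ci], sp$resid_sd[s], log = TRUE)
    }
  }
  # varying-intercept densities
  cp <- params$choice
  ll <- ll + sum(dnorm(cp$u_target, 0, cp$sigma_target, log = TRUE)) +
    sum(dnorm(cp$v_rater, 0, cp$sigma_rater, log = TRUE))
  for (d in names(params$rating)) {
    rp <- params$rating[[d]]
    ll <- ll + sum(dnorm(rp$w_target, 0, rp$sigma_target, log = TRUE)) +
      sum(dnorm(rp$x_rater, 0, rp$sigma_rater, log = TRUE)) +
      sum(dnorm(as.numeric(rp$z_tr), 0, rp$sigma_tr, log = TRUE))
  }
  # priors
  pr <- priors
  ll <- ll + sum(dnorm(cp$alpha, pr$intercept[1], pr$intercept[2], log = TRUE)) +
    sum(dnorm(c(cp$beta_attr, cp$beta_form, cp$beta_heal, cp$beta_pp,
                cp$beta_rs, cp$beta_side), pr$slope[1], pr$slope[2],
              log = TRUE)) +
    dexp(cp$sigma_target, pr$hyper_sd_rate, log = TRUE) +
    dexp(cp$sigma_rater, pr$hyper_sd_rate, log = TRUE)
  for (d in names(params$rating)) {
    rp <- params$rating[[d]]
    raw <- c(rp$cutpoints[1], log(diff(rp$cutpoints)))
    ll <- ll + sum(dnorm(raw, pr$cutpoint[1], pr$cutpoint[2], log = TRUE)) +
      sum(dnorm(c(rp$a_mas, rp$a_fem), pr$intercept[1], pr$intercept[2],
                log = TRUE)) +
      sum(dnorm(c(rp$g_mas_pp, rp$g_mas_rs, rp$g_fem_pp, rp$g_fem_rs),
                pr$slope[1], pr$slope[2], log = TRUE)) +
      sum(dexp(c(rp$sigma_target, rp$sigma_rater, rp$sigma_tr),
               pr$hyper_sd_rate, log = TRUE))
  }
  ll + sum(dnorm(as.numeric(sp$mu), pr$scale_mu[1], pr$scale_mu[2],
                 log = TRUE)) +
    sum(dexp(sp$resid_sd, pr$resid_sd_rate, log = TRUE))
}
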