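test_that("ordinal category probabilities normalise, mirror and saturate", {
  cuts <- c(-2.5, -1.5, -0.5, 0.5, 1.5, 2.5)
  p <- ordinal_category_probs(cuts, 0)
  expect_equal(sum(p), 1)
  expect_true(all(p >= 0))
  # symmetric cut-points at phi = 0 give a symmetric category distribution
  expect_equal(p[1], p[7])
  expect_equal(p[2], p[6])
  expect_equal(p[3], p[5])
  # extreme predictor piles all mass on the top category
  expect_gt(ordinal_category_probs(cuts, 50)[7], 1 - 1e-15)
  # vectorised over phi: rows sum to one
  m <- ordinal_category_probs(cuts, c(-3, 0, 2))
  expect_equal(rowSums(m), rep(1, 3))
  expect_error(ordinal_category_probs(c(1, 0, 2, 3, 4, 5), 0),
               class = "harshpref_config_error")
})

test_that("choice linear predictor matches a term-by-term scalar oracle", {
  # null model: everything zero gives log-odds 0 (probability one half)
  p0 <- choice_params()
  expect_equal(choice_linear_predictor(p0, "control"), 0)
  # single term arithmetic
  ps <- choice_params(beta_side = 0.05)
  expect_equal(choice_linear_predictor(ps, "control", side_contrast = 0.5),
               0.025)
  # 100 fuzzed parameter/covariate draws against an independent scalar sum
  set.seed(42)
  for (i in 1:100) {
    pars <- random_choice_params(n_targets = 5, n_raters = 3)
    cond <- sample(c("control", "pathogen_prevalence",
                     "resource_scarcity"), 1)
    cov <- rnorm(6)
    t_i <- sample(5, 1); r_i <- sample(3, 1)
    got <- choice_linear_predictor(pars, cond, d_attr = cov[1],
                                   d_form = cov[2], d_heal = cov[3],
                                   z_pp = cov[4], z_rs = cov[5],
                                   side_contrast = cov[6],
                                   target_index = t_i, rater_index = r_i)
    want <- pars$alpha[[cond]] + pars$beta_attr[[cond]] * cov[1] +
      pars$beta_form[[cond]] * cov[2] + pars$beta_heal[[cond]] * cov[3] +
      pars$beta_pp * cov[4] + pars$beta_rs * cov[5] +
      pars$beta_side * cov[6] + pars$u_target[t_i] + pars$v_rater[r_i]
    expect_equal(got, unname(want))
  }
})

test_that("choice log-likelihood equals the brute-force Bernoulli product", {
  d <- tiny_preprocessed(n_raters = c(2, 1, 1), n_targets = 2, seed = 31)
  nt <- 2; nr <- 4
  set.seed(9)
  pars <- random_choice_params(nt, nr)
  # independent oracle: per-record probability product
  pred <- choice_predictors(d)
  ri <- match(pred$rater_id, d$raters$rater_id)
  probs <- numeric(nrow(pred))
  for (i in seq_len(nrow(pred))) {
    eta <- pars$alpha[[pred$condition[i]]] +
      pars$beta_attr[[pred$condition[i]]] * pred$d_attractiveness[i] +
      pars$beta_form[[pred$condition[i]]] * pred$d_formidability[i] +
      pars$beta_heal[[pred$condition[i]]] * pred$d_healthiness[i] +
      pars$beta_pp * pred$z_pp[i] + pars$beta_rs * pred$z_rs[i] +
      pars$beta_side * pred$side_contrast[i] +
      pars$u_target[pred$target_id[i]] + pars$v_rater[ri[i]]
    p <- 1 / (1 + exp(-eta))
    probs[i] <- if (pred$chose_masculinised[i] == 1) p else 1 - p
  }
  expect_equal(choice_loglik(pars, d), log(prod(probs)))
  # single record with predictor 0 gives log(1/2)
  p0 <- choice_params(u_target = rep(0, nt), v_rater = rep(0, nr))
  d1 <- d
  d1$choices <- d1$choices[1, ]
  d1$ratings <- d1$ratings[d1$ratings$rater_id == d1$choices$rater_id[1] &
                             d1$ratings$target_id == d1$choices$target_id[1], ]
  d1$raters$z_pp <- 0; d1$raters$z_rs <- 0
  d1$ratings$score <- 4L   # both versions equal -> zero differences
  d1$choices$side_contrast[1] <-
    ifelse(d1$raters$masc_side[match(d1$choices$rater_id[1],
                                     d1$raters$rater_id)] == "left",
           -0.5, 0.5)
  expect_equal(choice_loglik(p0, d1), log(0.5))
})

test_that("flipping choices and negating predictors leaves the likelihood unchanged", {
  d <- tiny_preprocessed(seed = 33)
  set.seed(12)
  pars <- random_choice_params(4, 12)
  neg <- pars
  for (f in c("alpha", "beta_attr", "beta_form", "beta_heal", "beta_pp",
              "beta_rs", "beta_side", "u_target", "v_rater")) {
    neg[[f]] <- -neg[[f]]
  }
  d2 <- d
  d2$choices$chose_masculinised <- 1L - d2$choices$chose_masculinised
  expect_equal(choice_loglik(neg, d2), choice_loglik(pars, d))
})

test_that("rating log-likelihood matches direct evaluation and a loop oracle", {
  # single record at phi = 0 with symmetric cut-points, score 4
  cuts <- c(-2.5, -1.5, -0.5, 0.5, 1.5, 2.5)
  expect_equal(ordinal_log_prob(cuts, 0, 4L),
               log(plogis(0.5) - plogis(-0.5)))
  # small dataset vs. a naive per-record loop
  d <- tiny_preprocessed(n_raters = c(2, 1, 1), n_targets = 2, seed = 35)
  set.seed(5)
  pars <- random_rating_params(2, nrow(d$raters))
  got <- rating_loglik(pars, d, "attractiveness")
  want <- 0
  rat <- d$ratings[d$ratings$dimension == "attractiveness", ]
  for (i in seq_len(nrow(rat))) {
    r <- match(rat$rater_id[i], d$raters$rater_id)
    cc <- d$raters$condition[r]
    phi <- if (rat$version[i] == "masculinised") {
      pars$a_mas[[cc]] + pars$g_mas_pp * d$raters$z_pp[r] +
        pars$g_mas_rs * d$raters$z_rs[r]
    } else {
      pars$a_fem[[cc]] + pars$g_fem_pp * d$raters$z_pp[r] +
        pars$g_fem_rs * d$raters$z_rs[r]
    }
    phi <- phi + pars$w_target[rat$target_id[i]] + pars$x_rater[r] +
      pars$z_tr[rat$target_id[i], r]
    want <- want + log(ordinal_category_probs(pars$cutpoints, phi)[rat$score[i]])
  }
  expect_equal(got, want)
})

test_that("the ordinal block is invariant to joint translation of cut-points and phi", {
  d <- tiny_preprocessed(seed = 36)
  set.seed(6)
  pars <- random_rating_params(4, 12)
  shifted <- pars
  delta <- 1.3
  shifted$cutpoints <- pars$cutpoints + delta
  shifted$a_mas <- pars$a_mas + delta
  shifted$a_fem <- pars$a_fem + delta
  expect_equal(rating_loglik(shifted, d, "healthiness"),
               rating_loglik(pars, d, "healthiness"))
})

test_that("scales log-likelihood matches hand-summed Gaussian densities", {
  r <- tibble::tibble(rater_id = c("a", "b", "c"),
                      condition = c("control", "pathogen_prevalence",
                                    "resource_scarcity"),
                      z_pp = c(0.2, -0.1, 0.5), z_rs = c(-1, 0, 1))
  sp <- scale_params(mu = rbind(pp = c(0.1, 0, -0.2), rs = c(0, 0.3, 0.4)),
                     resid_sd = c(pp = 0.8, rs = 1.2))
  want <- sum(dnorm(r$z_pp, c(0.1, 0, -0.2), 0.8, log = TRUE)) +
    sum(dnorm(r$z_rs, c(0, 0.3, 0.4), 1.2, log = TRUE))
  expect_equal(scales_loglik(sp, r), want)
  # mode density: one rater at z = mu with unit residual SD
  one <- tibble::tibble(rater_id = "a", condition = "control",
                        z_pp = 0.3, z_rs = 0)
  sp1 <- scale_params(mu = rbind(pp = c(0.3, 0, 0), rs = c(0, 0, 0)),
                      resid_sd = c(pp = 1, rs = 1))
  expect_equal(scales_loglik(sp1, one), 2 * log(1 / sqrt(2 * pi)))
  # doubling the residual SD at the mode costs log 2 per observation
  sp2 <- sp1; sp2$resid_sd[] <- c(2, 1)
  expect_equal(scales_loglik(sp1, one) - scales_loglik(sp2, one), log(2))
})

test_that("the joint log-density is additive and matches the naive reimplementation", {
  d <- tiny_preprocessed(n_raters = c(3, 3, 2), n_targets = 3, seed = 40)
  priors <- default_priors()
  set.seed(77)
  for (rep in 1:5) {
    pars <- random_joint_params(d)
    got <- joint_log_density(pars, d, priors)
    # additivity: the likelihood blocks are recovered exactly once the
    # prior and varying-intercept densities are subtracted
    extras <- harshpref:::varying_intercept_logdens(pars$choice) +
      sum(vapply(pars$rating, harshpref:::varying_intercept_logdens,
                 numeric(1))) +
      harshpref:::choice_prior_logdens(pars$choice, priors) +
      sum(vapply(pars$rating, harshpref:::rating_prior_logdens,
                 numeric(1), priors = priors)) +
      harshpref:::scales_prior_logdens(pars$scales, priors)
    blocks <- choice_loglik(pars$choice, d) +
      sum(vapply(c("attractiveness", "healthiness", "formidability"),
                 function(dd) rating_loglik(pars$rating[[dd]], d, dd),
                 numeric(1))) +
      scales_loglik(pars$scales, d$raters)
    expect_equal(got, blocks + extras)
    # full naive scalar-loop oracle
    want <- naive_joint_logdensity(pars, d, priors)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("the joint density stays finite under prior draws on simulated data", {
  d <- tiny_preprocessed(seed = 41)
  priors <- default_priors()
  set.seed(8)
  for (i in 1:200) {
    pars <- random_joint_params(d)
    expect_true(is.finite(joint_log_density(pars, d, priors)))
  }
})

test_that("sampler-backend gradients agree with finite differences", {
  d <- tiny_preprocessed(n_raters = c(3, 2, 2), n_targets = 3, seed = 44)
  priors <- default_priors()
  set.seed(3)
  blocks <- list(
    choice = build_choice_block(d, priors),
    rating = build_rating_block(d, "formidability", priors),
    scales = build_scales_block(d, priors))
  for (b in blocks) {
    q <- b$init + rnorm(length(b$init), 0, 0.3)
    g <- b$grad(q)
    idx <- sample(length(q), min(20, length(q)))
    fd <- vapply(idx, function(j) {
      e <- rep(0, length(q)); e[j] <- 1e-6
      (b$log_post(q + e) - b$log_post(q - e)) / 2e-6
    }, numeric(1))
    expect_equal(g[idx], fd, tolerance = 1e-5)
  }
})

test_that("the compiled kernels equal the reference R implementations", {
  d <- tiny_preprocessed(n_raters = c(3, 2, 2), n_targets = 3, seed = 45)
  priors <- default_priors()
  set.seed(4)
  for (builder in list(
    function(bk) build_choice_block(d, priors, backend = bk),
    function(bk) build_rating_block(d, "attractiveness", priors,
                                    backend = bk))) {
    cpp <- builder("cpp"); ref <- builder("r")
    for (i in 1:10) {
      q <- ref$init + rnorm(length(ref$init), 0, 0.5)
      expect_equal(cpp$log_post(q), ref$log_post(q), tolerance = 1e-12)
      expect_equal(cpp$grad(q), ref$grad(q), tolerance = 1e-10)
    }
  }
})
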