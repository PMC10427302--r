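# Sampler contract and posterior-summary operations. Heavy recovery and
# calibration runs live in test-acceptance.R.

test_that("summaries report means and central compatibility intervals", {
  # constant draws collapse to a point
  m <- matrix(2.5, nrow = 100, ncol = 1, dimnames = list(NULL, "c"))
  s <- summarise_posterior(m)
  expect_equal(s$mean, 2.5)
  expect_equal(s$lower, 2.5)
  expect_equal(s$upper, 2.5)
  # uniform draws: the 89% central interval is [0.055, 0.945]
  set.seed(10)
  u <- matrix(runif(10000), ncol = 1, dimnames = list(NULL, "u"))
  su <- summarise_posterior(u)
  expect_lt(abs(su$lower - 0.055), 0.01)
  expect_lt(abs(su$upper - 0.945), 0.01)
  expect_lt(abs(su$mean - 0.5), 0.02)
  # interval bounds always inside the draw range; level is honoured
  x <- matrix(rnorm(5000), ncol = 1, dimnames = list(NULL, "x"))
  for (prob in c(0.5, 0.89, 0.95)) {
    sx <- summarise_posterior(x, prob = prob)
    expect_gte(sx$lower, min(x)); expect_lte(sx$upper, max(x))
    expect_lt(sx$lower, sx$upper)
  }
  expect_error(summarise_posterior(x[0, , drop = FALSE]), "Empty")
})

test_that("summaries and contrasts are invariant to draw order", {
  set.seed(11)
  m <- cbind(a = rnorm(2000), b = rnorm(2000, 1))
  perm <- sample(nrow(m))
  s1 <- summarise_posterior(m)
  s2 <- summarise_posterior(m[perm, ])
  expect_equal(s1$mean, s2$mean)
  expect_equal(s1$lower, s2$lower)
  expect_equal(s1$upper, s2$upper)
})

test_that("posterior contrasts behave linearly", {
  set.seed(12)
  m <- cbind(a = rnorm(1000), b = rnorm(1000))
  m <- cbind(m, c = m[, "a"] + 3)
  # identity contrast is exactly zero
  expect_true(all(posterior_contrast(m, "a", "a") == 0))
  # constant shift is recovered exactly
  expect_true(all(abs(posterior_contrast(m, "c", "a") - 3) < 1e-12))
  # contrast mean equals difference of means
  expect_equal(mean(posterior_contrast(m, "a", "b")),
               mean(m[, "a"]) - mean(m[, "b"]))
  expect_error(posterior_contrast(m, "a", "zzz"), "Unknown quantity")
})

test_that("the sampler is reproducible and flags non-convergence loudly", {
  d <- tiny_preprocessed(n_raters = c(4, 3, 3), n_targets = 4, seed = 50)
  f1 <- fit_scales_model(d, n_chains = 2, iter_warmup = 200,
                         iter_sampling = 300, seed = 31)
  f2 <- fit_scales_model(d, n_chains = 2, iter_warmup = 200,
                         iter_sampling = 300, seed = 31)
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_scales_model(d, n_chains = 2, iter_warmup = 200,
                         iter_sampling = 300, seed = 32)
  expect_false(identical(f1$draws, f3$draws))
  # an unconverged fit (no warm-up to adapt) raises a classed error
  expect_error(
    fit_choice_model(d, n_chains = 2, iter_warmup = 2, iter_sampling = 40,
                     seed = 1, control = list(init_jitter = 3)),
    class = "harshpref_convergence_error")
})

test_that("a small joint fit passes its own convergence gate", {
  d <- tiny_preprocessed(n_raters = c(4, 3, 3), n_targets = 4, seed = 51)
  fit <- fit_study(d, n_chains = 2, iter_warmup = 500, iter_sampling = 250,
                   seed = 3)
  expect_lte(max(fit$diagnostics$rhat, na.rm = TRUE), 1.05)
  expect_equal(nrow(fit$draws), 500)
  # summaries order their interval correctly everywhere
  s <- summarise_posterior(fit)
  expect_true(all(s$lower <= s$mean + 1e-9))
  expect_true(all(s$mean <= s$upper + 1e-9))
})

test_that("split-Rhat and ESS detect healthy and unhealthy chains", {
  set.seed(13)
  good <- matrix(rnorm(4000), ncol = 2)
  expect_lt(split_rhat(good), 1.02)
  # two chains stuck in different places
  bad <- cbind(rnorm(2000), rnorm(2000, 5))
  expect_gt(split_rhat(bad), 1.5)
  # heavily autocorrelated draws have far fewer effective samples
  ar <- matrix(0, 2000, 2)
  for (k in 1:2) {
    for (i in 2:2000) ar[i, k] <- 0.95 * ar[i - 1, k] + rnorm(1, 0, 0.1)
  }
  expect_lt(ess_basic(ar), 600)
  expect_gt(ess_basic(good), 2000)
})

test_that("rating-difference posteriors respect symmetry and monotonicity", {
  d <- tiny_preprocessed(n_raters = c(4, 3, 3), n_targets = 3, seed = 52)
  fit <- fit_rating_model(d, "formidability", n_chains = 2,
                          iter_warmup = 300, iter_sampling = 300, seed = 5,
                          on_bad_rhat = "warn")
  dd <- rating_difference_posterior(fit, d, "formidability")
  expect_equal(ncol(dd), 3)
  expect_true(all(is.finite(dd)))
  # symmetry: forcing the masculinised coefficients equal to the feminised
  # ones collapses the difference to exactly zero
  sym <- fit
  for (cc in c("control", "pp", "rs")) {
    sym$draws[, sprintf("form.a_mas[%s]", cc)] <-
      sym$draws[, sprintf("form.a_fem[%s]", cc)]
  }
  sym$draws[, "form.g_mas_pp"] <- sym$draws[, "form.g_fem_pp"]
  sym$draws[, "form.g_mas_rs"] <- sym$draws[, "form.g_fem_rs"]
  dd0 <- rating_difference_posterior(sym, d, "formidability")
  expect_true(all(abs(dd0) < 1e-12))
  # monotonicity: raising a_mas in one condition raises that condition's
  # expected difference in every draw
  up <- fit
  up$draws[, "form.a_mas[pp]"] <- up$draws[, "form.a_mas[pp]"] + 0.5
  dd1 <- rating_difference_posterior(up, d, "formidability")
  expect_true(all(dd1[, "diff_form[pp]"] > dd[, "diff_form[pp]"]))
  expect_equal(dd1[, "diff_form[control]"], dd[, "diff_form[control]"])
  expect_error(rating_difference_posterior(fit, d, "attractiveness"),
               "not present")
})

test_that("a single-pair rating difference matches direct category arithmetic", {
  d <- tiny_preprocessed(n_raters = c(1, 1, 1), n_targets = 2, seed = 53)
  fit <- fit_rating_model(d, "healthiness", n_chains = 2, iter_warmup = 300,
                          iter_sampling = 200, seed = 6,
                          on_bad_rhat = "ignore")
  dd <- rating_difference_posterior(fit, d, "healthiness")
  # recompute draw 1 by hand from the stored draws
  s <- 1
  m <- fit$draws
  pt <- fit$meta$pair_target; pr <- fit$meta$pair_rater
  cond <- d$raters$condition[pr]
  ci <- match(cond, c("control", "pathogen_prevalence",
                      "resource_scarcity"))
  cuts <- m[s, sprintf("heal.cut[%d]", 1:6)]
  want <- numeric(3)
  for (k in 1:3) {
    sel <- which(ci == k)
    diffs <- vapply(sel, function(j) {
      base <- m[s, sprintf("heal.w_target[%d]", pt[j])] +
        m[s, sprintf("heal.x_rater[%d]", pr[j])] +
        m[s, sprintf("heal.z_tr[%d,%d]", pt[j], pr[j])]
      phim <- m[s, sprintf("heal.a_mas[%s]", c("control", "pp", "rs")[k])] +
        m[s, "heal.g_mas_pp"] * d$raters$z_pp[pr[j]] +
        m[s, "heal.g_mas_rs"] * d$raters$z_rs[pr[j]] + base
      phif <- m[s, sprintf("heal.a_fem[%s]", c("control", "pp", "rs")[k])] +
        m[s, "heal.g_fem_pp"] * d$raters$z_pp[pr[j]] +
        m[s, "heal.g_fem_rs"] * d$raters$z_rs[pr[j]] + base
      sum(ordinal_category_probs(unname(cuts), phim) * (1:7)) -
        sum(ordinal_category_probs(unname(cuts), phif) * (1:7))
    }, numeric(1))
    want[k] <- mean(diffs)
  }
  expect_equal(unname(dd[s, ]), want, tolerance = 1e-10)
})

test_that("posterior contraction: more raters shrink condition-intercept intervals", {
  # small target/rater heterogeneity so the intercept width is dominated
  # by the rater count rather than the 6 shared targets
  tight <- choice_params(sigma_target = 0.1, sigma_rater = 0.1)
  small <- preprocess_study(simulate_study(
    sim_config(n_raters = c(15, 15, 15), n_targets = 6, choice = tight,
               seed = 60)))$data
  big <- preprocess_study(simulate_study(
    sim_config(n_raters = c(60, 60, 60), n_targets = 6, choice = tight,
               seed = 60)))$data
  fs <- fit_choice_model(small, n_chains = 2, iter_warmup = 300,
                         iter_sampling = 400, seed = 9, on_bad_rhat = "warn")
  fb <- fit_choice_model(big, n_chains = 2, iter_warmup = 300,
                         iter_sampling = 400, seed = 9, on_bad_rhat = "warn")
  width <- function(f) {
    s <- summarise_posterior(f, pars = "^alpha\\[")
    mean(s$upper - s$lower)
  }
  expect_lt(width(fb), width(fs))
})
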