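test_that("the generator is deterministic given its seed and leaves the RNG alone", {
  cfg <- sim_config(n_raters = c(5, 5, 5), seed = 123)
  d1 <- simulate_study(cfg)
  d2 <- simulate_study(cfg)
  expect_identical(d1$choices, d2$choices)
  expect_identical(d1$ratings, d2$ratings)
  expect_identical(d1$raters, d2$raters)
  # a different seed gives different data
  d3 <- simulate_study(sim_config(n_raters = c(5, 5, 5), seed = 124))
  expect_false(identical(d1$choices$chose_masculinised,
                         d3$choices$chose_masculinised))
  # the caller's RNG stream is not consumed
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(simulate_study(cfg)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("defaults reproduce the retained design: 102/101/86 raters, 12 targets, no exclusions", {
  d <- simulate_study(sim_config(seed = 2))
  expect_equal(as.vector(table(factor(d$raters$condition,
                                      c("control", "pathogen_prevalence",
                                        "resource_scarcity")))),
               c(102, 101, 86))
  expect_equal(nrow(d$choices), 289 * 12)
  expect_equal(sum(d$choices$recognised), 0)
  expect_true(all(d$raters$attention_correct >= 1))
  res <- apply_exclusions(d)
  expect_equal(res$report$n_retained_datapoints, nrow(d$choices))
  # side assignment is counterbalanced
  expect_equal(sum(d$raters$masc_side == "left"), 145, tolerance = 0.01)
})

test_that("a null configuration produces masculinised choices at chance", {
  null_choice <- choice_params(sigma_target = 1e-6, sigma_rater = 1e-6)
  cfg <- sim_config(n_raters = c(300, 300, 300), n_targets = 12,
                    choice = null_choice, seed = 55)
  d <- simulate_study(cfg)
  n <- nrow(d$choices)
  phat <- mean(d$choices$chose_masculinised)
  se <- sqrt(0.25 / n)
  expect_lt(abs(phat - 0.5), 3 * se)
})

test_that("a pure side effect reproduces the closed-form Bernoulli mean", {
  # beta_side = 1: P(choose masc | side = right) = plogis(0.5) = 0.622
  side_only <- choice_params(beta_side = 1, sigma_target = 1e-6,
                             sigma_rater = 1e-6)
  cfg <- sim_config(n_raters = c(1400, 1400, 1400), n_targets = 12,
                    choice = side_only, seed = 66)
  d <- simulate_study(cfg)   # ~50,400 trials
  side <- d$raters$masc_side[match(d$choices$rater_id, d$raters$rater_id)]
  p_right <- mean(d$choices$chose_masculinised[side == "right"])
  p_left <- mean(d$choices$chose_masculinised[side == "left"])
  n_half <- sum(side == "right")
  se <- sqrt(plogis(0.5) * (1 - plogis(0.5)) / n_half)
  expect_lt(abs(p_right - plogis(0.5)), 4 * se)
  expect_lt(abs(p_left - plogis(-0.5)), 4 * se)
})

test_that("simulated rating frequencies follow the cumulative-logit probabilities", {
  # one rater, one target repeated many times via many raters with all
  # variance components switched off: category frequencies must match the
  # model probabilities (chi-square goodness of fit, alpha = 0.01)
  rp <- rating_params(cutpoints = c(-2, -1.2, -0.4, 0.4, 1.2, 2),
                      a_mas = c(0.3, 0.3, 0.3), a_fem = c(0.3, 0.3, 0.3),
                      sigma_target = 1e-9, sigma_rater = 1e-9,
                      sigma_tr = 1e-9)
  cfg <- sim_config(n_raters = c(700, 700, 700), n_targets = 12,
                    rating = list(attractiveness = rp, healthiness = rp,
                                  formidability = rp),
                    scales = scale_params(resid_sd = c(pp = 1e-9, rs = 1e-9)),
                    seed = 77)
  d <- simulate_study(cfg)
  obs <- table(factor(d$ratings$score, levels = 1:7))   # 50,400 x 3 draws
  want <- ordinal_category_probs(rp$cutpoints, 0.3)
  gof <- suppressWarnings(chisq.test(obs, p = want))
  expect_gt(gof$p.value, 0.01)
})

test_that("increasing a slope times its covariate increases choice frequency", {
  base <- choice_params(sigma_target = 1e-6, sigma_rater = 1e-6)
  up <- choice_params(beta_pp = 1.5, sigma_target = 1e-6, sigma_rater = 1e-6)
  n <- c(800, 800, 800)
  d0 <- simulate_study(sim_config(n_raters = n, choice = base, seed = 88))
  d1 <- simulate_study(sim_config(n_raters = n, choice = up, seed = 88))
  z <- attr(d1, "truth")$z_pp
  hi <- d1$choices$rater_id %in% d1$raters$rater_id[z > 0.5]
  # with a positive perceived-pathogen slope, high-z raters choose the
  # masculinised face more often than under the null configuration
  expect_gt(mean(d1$choices$chose_masculinised[hi]),
            mean(d0$choices$chose_masculinised[hi]) + 0.05)
})

test_that("batches derive per-replicate seeds reproducibly", {
  cfg <- sim_config(n_raters = c(4, 4, 4), seed = 9)
  b1 <- simulate_batch(cfg, 3)
  b2 <- simulate_batch(cfg, 3)
  expect_identical(lapply(b1, `[[`, "choices"), lapply(b2, `[[`, "choices"))
  # replicates differ from one another
  expect_false(identical(b1[[1]]$choices$chose_masculinised,
                         b1[[2]]$choices$chose_masculinised))
  # a single replicate equals simulate_study at the derived seed
  cfg1 <- cfg; cfg1$seed <- as.integer((9 + 1000003) %% .Machine$integer.max)
  expect_identical(simulate_batch(cfg, 1)[[1]]$choices,
                   simulate_study(cfg1)$choices)
})

test_that("the mean masculinised-choice rate over null replicates sits at one half", {
  null_cfg <- sim_config(n_raters = c(30, 30, 30), n_targets = 12,
                         choice = choice_params(sigma_target = 1e-6,
                                                sigma_rater = 1e-6),
                         seed = 14)
  reps <- simulate_batch(null_cfg, 20)
  rates <- vapply(reps, function(d) mean(d$choices$chose_masculinised),
                  numeric(1))
  n_total <- 20 * 90 * 12
  expect_lt(abs(mean(rates) - 0.5), 3 * sqrt(0.25 / n_total))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_raters = c(5, 5)),
               class = "harshpref_config_error")
  expect_error(sim_config(n_targets = 1), class = "harshpref_config_error")
  expect_error(sim_config(recognition_rate = 1.2),
               class = "harshpref_config_error")
  bad_rating <- reference_rating_params("healthiness")
  bad_rating$cutpoints <- rev(bad_rating$cutpoints)
  expect_error(
    sim_config(rating = list(attractiveness = bad_rating,
                             healthiness = bad_rating,
                             formidability = bad_rating)),
    class = "harshpref_config_error")
})

test_that("exclusion flags drawn at positive rates survive the pipeline arithmetic", {
  cfg <- sim_config(n_raters = c(40, 40, 40), recognition_rate = 0.05,
                    attention_fail_rate = 0.1, nonheterosexual_rate = 0.15,
                    seed = 21)
  d <- simulate_study(cfg)
  res <- apply_exclusions(d)
  rep <- res$report
  expect_gt(rep$n_removed_nonheterosexual, 0)
  expect_gt(rep$n_removed_attention, 0)
  expect_gt(rep$n_datapoints_removed_recognition, 0)
  expect_equal(rep$n_retained_datapoints,
               12 * rep$n_retained_raters - rep$n_datapoints_removed_recognition)
})
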