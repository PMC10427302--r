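# Joint model: 2AFC choice submodel (logit link), three cumulative-logit
# ordinal rating submodels with shared cut-points, scales-on-condition
# mediation submodel, cross-classified varying intercepts, and weakly
# regularising priors. Everything here is a pure function of parameters
# and data; sampling lives in fit.R / hmc.R.

cond_short <- c(control = "control",
                pathogen_prevalence = "pp",
                resource_scarcity = "rs")
dim_short <- c(attractiveness = "attr",
               healthiness = "heal",
               formidability = "form")

named_by_condition <- function(x, what) {
  if (length(x) == 1) x <- rep(x, 3)
  if (length(x) != 3) {
    abort(sprintf("`%s` must have one value per condition (3)", what))
  }
  names(x) <- condition_levels
  x
}

#' Parameters of the forced-choice logistic submodel
#'
#' The probability that a rater picks the masculinised version of a face is
#' modelled on the log-odds scale as
#' `alpha[c] + b_attr[c]*d_attr + b_form[c]*d_form + b_heal[c]*d_heal +
#'  b_pp*z_pp + b_rs*z_rs + b_side*side + u_target + v_rater`,
#' where `d_*` are the rater's masculinised-minus-feminised rating
#' differences for that face, `z_pp`/`z_rs` standardised perceived
#' pathogen-prevalence and resource-scarcity scores, `side` the +/-0.5
#' left-right placement contrast, and `u_target`/`v_rater` zero-mean normal
#' varying intercepts with hyper-SDs `sigma_target` and `sigma_rater`.
#' There is no global intercept: each condition has its own `alpha` and its
#' own rating-difference slopes.
#'
#' @param alpha Length-3 condition intercepts (log-odds), order
#'   control / pathogen_prevalence / resource_scarcity.
#' @param beta_attr,beta_form,beta_heal Length-3 condition-specific slopes
#'   on the rating differences (per rating unit).
#' @param beta_pp,beta_rs Slopes on the standardised perceived scores
#'   (per SD).
#' @param beta_side Slope on the +/-0.5 side contrast.
#' @param sigma_target,sigma_rater Hyper-SDs of the varying intercepts
#'   (must be positive).
#' @param u_target,v_rater Varying-intercept vectors (default all zero;
#'   lengths set the number of targets/raters).
#' @return A `choice_params` list.
#' @export
choice_params <- function(alpha = c(0, 0, 0),
                          beta_attr = c(0, 0, 0),
                          beta_form = c(0, 0, 0),
                          beta_heal = c(0, 0, 0),
                          beta_pp = 0, beta_rs = 0, beta_side = 0,
                          sigma_target = 1, sigma_rater = 1,
                          u_target = numeric(0), v_rater = numeric(0)) {
  if (sigma_target <= 0 || sigma_rater <= 0) {
    abort("Hyper-SDs `sigma_target` and `sigma_rater` must be positive")
  }
  structure(list(
    alpha = named_by_condition(alpha, "alpha"),
    beta_attr = named_by_condition(beta_attr, "beta_attr"),
    beta_form = named_by_condition(beta_form, "beta_form"),
    beta_heal = named_by_condition(beta_heal, "beta_heal"),
    beta_pp = beta_pp, beta_rs = beta_rs, beta_side = beta_side,
    sigma_target = sigma_target, sigma_rater = sigma_rater,
    u_target = u_target, v_rater = v_rater
  ), class = "choice_params")
}

#' Parameters of one cumulative-logit rating submodel
#'
#' Each 1-7 Likert rating of a face version is modelled with six ordered
#' cut-points shared by the masculinised and feminised versions of a
#' dimension: `P(Y > k) = plogis(phi - cut[k])`. The linear predictor is
#' `phi = a_mas[c] + g_mas_pp*z_pp + g_mas_rs*z_rs + w_target + x_rater +
#' z_tr` for masculinised versions (analogously `a_fem`, `g_fem_*` for
#' feminised), with three cross-classified varying-intercept sets (target,
#' rater, target x rater) shared between the two versions.
#'
#' @param cutpoints Six strictly increasing log-odds thresholds.
#' @param a_mas,a_fem Length-3 condition intercepts for the masculinised and
#'   feminised linear predictors.
#' @param g_mas_pp,g_mas_rs,g_fem_pp,g_fem_rs Slopes on the standardised
#'   perceived scores, separate per version.
#' @param sigma_target,sigma_rater,sigma_tr Positive hyper-SDs of the three
#'   varying-intercept sets.
#' @param w_target,x_rater Varying-intercept vectors.
#' @param z_tr Target x rater interaction intercepts, a matrix with one row
#'   per target and one column per rater.
#' @return A `rating_params` list.
#' @export
rating_params <- function(cutpoints = c(-2.5, -1.5, -0.5, 0.5, 1.5, 2.5),
                          a_mas = c(0, 0, 0), a_fem = c(0, 0, 0),
                          g_mas_pp = 0, g_mas_rs = 0,
                          g_fem_pp = 0, g_fem_rs = 0,
                          sigma_target = 1, sigma_rater = 1, sigma_tr = 1,
                          w_target = numeric(0), x_rater = numeric(0),
                          z_tr = NULL) {
  check_cutpoints(cutpoints)
  if (sigma_target <= 0 || sigma_rater <= 0 || sigma_tr <= 0) {
    abort("Rating-model hyper-SDs must be positive")
  }
  structure(list(
    cutpoints = cutpoints,
    a_mas = named_by_condition(a_mas, "a_mas"),
    a_fem = named_by_condition(a_fem, "a_fem"),
    g_mas_pp = g_mas_pp, g_mas_rs = g_mas_rs,
    g_fem_pp = g_fem_pp, g_fem_rs = g_fem_rs,
    sigma_target = sigma_target, sigma_rater = sigma_rater,
    sigma_tr = sigma_tr,
    w_target = w_target, x_rater = x_rater, z_tr = z_tr
  ), class = "rating_params")
}

#' Parameters of the scales (mediation) submodel
#'
#' Standardised perceived pathogen-prevalence and resource-scarcity scores
#' are themselves modelled as normal outcomes of the priming condition: one
#' intercept per scale x condition combination plus a residual SD per scale.
#' This block completes the indirect (mediation) paths of the structural
#' model.
#'
#' @param mu 2 x 3 matrix of means, rows `pp`/`rs`, columns the three
#'   conditions.
#' @param resid_sd Length-2 positive residual SDs, named `pp`/`rs`.
#' @return A `scale_params` list.
#' @export
scale_params <- function(mu = matrix(0, 2, 3,
                                     dimnames = list(c("pp", "rs"),
                                                     condition_levels)),
                         resid_sd = c(pp = 1, rs = 1)) {
  mu <- as.matrix(mu)
  if (!all(dim(mu) == c(2, 3))) abort("`mu` must be a 2 x 3 matrix")
  dimnames(mu) <- list(c("pp", "rs"), condition_levels)
  if (any(resid_sd <= 0)) abort("`resid_sd` must be positive")
  names(resid_sd) <- c("pp", "rs")
  structure(list(mu = mu, resid_sd = resid_sd), class = "scale_params")
}

check_cutpoints <- function(cutpoints) {
  if (length(cutpoints) != 6 || any(!is.finite(cutpoints)) ||
      any(diff(cutpoints) <= 0)) {
    abort("`cutpoints` must be six finite, strictly increasing thresholds",
          class = "harshpref_config_error")
  }
  invisible(cutpoints)
}

#' Weakly regularising priors for all model blocks
#'
#' Normal priors on intercept-like quantities (condition intercepts,
#' cut-point raw locations, scale means), tighter normal priors on slopes,
#' and exponential priors on every hyper-SD and residual SD. Cut-points are
#' given their prior on the unconstrained "raw" scale of the ordered
#' transform (first cut-point, then log-increments).
#'
#' @param intercept,slope,cutpoint,scale_mu Length-2 `(location, scale)`
#'   vectors of normal priors.
#' @param hyper_sd_rate,resid_sd_rate Exponential rates for hyper-SDs and
#'   scale residual SDs.
#' @return A `priors` list.
#' @export
default_priors <- function(intercept = c(0, 1.5), slope = c(0, 1),
                           cutpoint = c(0, 1.5), scale_mu = c(0, 1.5),
                           hyper_sd_rate = 1, resid_sd_rate = 1) {
  stopifnot(intercept[2] > 0, slope[2] > 0, cutpoint[2] > 0,
            scale_mu[2] > 0, hyper_sd_rate > 0, resid_sd_rate > 0)
  structure(list(intercept = intercept, slope = slope, cutpoint = cutpoint,
                 scale_mu = scale_mu, hyper_sd_rate = hyper_sd_rate,
                 resid_sd_rate = resid_sd_rate),
            class = "priors")
}

dnorm_l <- function(x, mean = 0, sd = 1) {
  stats::dnorm(x, mean, sd, log = TRUE)
}

# ordered transform: cutpoints <-> unconstrained raw (first + log-increments)
cutpoints_to_raw <- function(cutpoints) {
  c(cutpoints[1], log(diff(cutpoints)))
}
raw_to_cutpoints <- function(raw) {
  cumsum(c(raw[1], exp(raw[-1])))
}

#' Category probabilities of the cumulative-logit rating model
#'
#' Given six ordered cut-points on the log-odds scale and a linear predictor
#' `phi`, returns the seven Likert category probabilities
#' `P(Y = k) = plogis(phi - cut[k-1]) - plogis(phi - cut[k])` with the
#' conventions `P(Y > 0) = 1` and `P(Y > 7) = 0`. Probabilities are
#' non-negative and sum to one.
#'
#' @param cutpoints Six strictly increasing thresholds.
#' @param phi Linear predictor (scalar or vector).
#' @return If `phi` is scalar, a length-7 probability vector; otherwise a
#'   `length(phi) x 7` matrix with one row per predictor value.
#' @export
#' @examples
#' ordinal_category_probs(c(-2.5, -1.5, -0.5, 0.5, 1.5, 2.5), 0)
ordinal_category_probs <- function(cutpoints, phi) {
  check_cutpoints(cutpoints)
  s <- plogis(outer(phi, cutpoints, `-`))     # P(Y > k), k = 1..6
  upper <- cbind(1, s)                        # P(Y > k-1), k = 1..7
  lower <- cbind(s, 0)                        # P(Y > k),   k = 1..7
  p <- upper - lower
  if (length(phi) == 1) p <- drop(p)
  p
}

# log P(Y = score) for vectors of phi and score, numerically direct
ordinal_log_prob <- function(cutpoints, phi, score) {
  cl <- c(-Inf, cutpoints)[score]       # cut below the observed category
  cu <- c(cutpoints, Inf)[score]        # cut above
  log(plogis(phi - cl) - plogis(phi - cu))
}

#' Linear predictor of the forced-choice submodel
#'
#' Computes, on the log-odds scale, the probability that the masculinised
#' version is chosen: condition intercept plus condition-specific slopes on
#' the three rating differences, the perceived-score terms, the side
#' contrast, and the target and rater varying intercepts. Vectorised over
#' records.
#'
#' @param params A [choice_params] object.
#' @param condition Condition label(s).
#' @param d_attr,d_form,d_heal Masculinised-minus-feminised rating
#'   differences for attractiveness, formidability, healthiness.
#' @param z_pp,z_rs Standardised perceived scores.
#' @param side_contrast -0.5 (masculinised on the left) or +0.5 (right).
#' @param target_index,rater_index Optional integer indices into
#'   `params$u_target` / `params$v_rater`; omitted terms contribute 0
#'   (a population-typical target/rater).
#' @return Numeric vector of log-odds.
#' @export
choice_linear_predictor <- function(params, condition,
                                    d_attr = 0, d_form = 0, d_heal = 0,
                                    z_pp = 0, z_rs = 0, side_contrast = 0,
                                    target_index = NULL, rater_index = NULL) {
  stopifnot(inherits(params, "choice_params"))
  if (!all(condition %in% condition_levels)) {
    abort("Unknown condition label in `condition`")
  }
  eta <- params$alpha[condition] +
    params$beta_attr[condition] * d_attr +
    params$beta_form[condition] * d_form +
    params$beta_heal[condition] * d_heal +
    params$beta_pp * z_pp + params$beta_rs * z_rs +
    params$beta_side * side_contrast
  if (!is.null(target_index)) eta <- eta + params$u_target[target_index]
  if (!is.null(rater_index)) eta <- eta + params$v_rater[rater_index]
  unname(eta)
}

#' Assemble per-choice predictors from a study dataset
#'
#' Joins the rating table into the choice table: for every choice record the
#' rater's masculinised-minus-feminised rating difference on each dimension,
#' the rater's standardised perceived scores, condition and side contrast.
#' Choice records for which a complete set of rating differences is not
#' available (both versions rated on all three dimensions) are dropped; the
#' number dropped is recorded in the `n_dropped` attribute.
#'
#' @param data A preprocessed [study_data] object (side contrasts coded,
#'   scales standardised).
#' @return A tibble with one row per usable choice record and attribute
#'   `n_dropped`.
#' @export
choice_predictors <- function(data) {
  validate_study_data(data)
  if (!all(c("z_pp", "z_rs") %in% names(data$raters))) {
    abort("Raters must carry standardised scores `z_pp`, `z_rs`; run standardise_scales() first")
  }
  if (!"side_contrast" %in% names(data$choices)) {
    abort("Choices must carry `side_contrast`; run code_side_contrast() first")
  }
  diffs <- data$ratings |>
    tidyr::pivot_wider(names_from = "version", values_from = "score") |>
    dplyr::mutate(diff = .data$masculinised - .data$feminised) |>
    dplyr::select("rater_id", "target_id", "dimension", "diff") |>
    tidyr::pivot_wider(names_from = "dimension", values_from = "diff",
                      names_prefix = "d_")
  for (d in dimension_levels) {
    nm <- paste0("d_", d)
    if (!nm %in% names(diffs)) diffs[[nm]] <- NA_real_
  }
  out <- data$choices |>
    dplyr::inner_join(
      dplyr::select(data$raters, "rater_id", "condition", "z_pp", "z_rs"),
      by = "rater_id") |>
    dplyr::left_join(diffs, by = c("rater_id", "target_id"))
  complete <- stats::complete.cases(
    out[, c("d_attractiveness", "d_formidability", "d_healthiness",
            "z_pp", "z_rs", "side_contrast")])
  res <- out[complete, ]
  attr(res, "n_dropped") <- sum(!complete)
  res
}

#' Log-likelihood of the forced-choice submodel
#'
#' Sum over usable choice records of the Bernoulli log-probability of the
#' observed choice under the inverse-logit of [choice_linear_predictor()].
#' Records lacking complete rating differences are excluded (see
#' [choice_predictors()]).
#'
#' @param params A [choice_params] object with `u_target` indexed by
#'   `target_id` and `v_rater` aligned with the rater table's row order.
#' @param data A preprocessed [study_data] object.
#' @return Scalar log-likelihood.
#' @export
choice_loglik <- function(params, data) {
  pred <- choice_predictors(data)
  if (any(!is.finite(pred$z_pp)) || any(!is.finite(pred$z_rs))) {
    abort("Non-finite covariates in choice predictors")
  }
  rater_index <- match(pred$rater_id, data$raters$rater_id)
  eta <- choice_linear_predictor(
    params, pred$condition,
    d_attr = pred$d_attractiveness, d_form = pred$d_formidability,
    d_heal = pred$d_healthiness,
    z_pp = pred$z_pp, z_rs = pred$z_rs, side_contrast = pred$side_contrast,
    target_index = if (length(params$u_target)) pred$target_id else NULL,
    rater_index = if (length(params$v_rater)) rater_index else NULL)
  y <- pred$chose_masculinised
  # log(1 + e^eta) computed stably for large |eta|
  sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
}

# phi for every rating record of one dimension
rating_phi <- function(params, data, dimension) {
  rat <- data$ratings[data$ratings$dimension == dimension, ]
  ri <- match(rat$rater_id, data$raters$rater_id)
  cond <- data$raters$condition[ri]
  z_pp <- data$raters$z_pp[ri]
  z_rs <- data$raters$z_rs[ri]
  mas <- rat$version == "masculinised"
  a <- ifelse(mas, params$a_mas[cond], params$a_fem[cond])
  g_pp <- ifelse(mas, params$g_mas_pp, params$g_fem_pp)
  g_rs <- ifelse(mas, params$g_mas_rs, params$g_fem_rs)
  phi <- a + g_pp * z_pp + g_rs * z_rs
  if (length(params$w_target)) phi <- phi + params$w_target[rat$target_id]
  if (length(params$x_rater)) phi <- phi + params$x_rater[ri]
  if (!is.null(params$z_tr)) {
    phi <- phi + params$z_tr[cbind(rat$target_id, ri)]
  }
  list(phi = unname(phi), score = rat$score)
}

#' Log-likelihood of one ordinal rating submodel
#'
#' Sum over all rating records of a dimension of the cumulative-logit
#' category log-probability at
#' `phi = a_mas|a_fem[condition] + g_pp*z_pp + g_rs*z_rs + w_target +
#' x_rater + z_tr`.
#'
#' @param params A [rating_params] object (varying intercepts indexed by
#'   `target_id` and by the rater table's row order).
#' @param data A preprocessed [study_data] object.
#' @param dimension One of `"attractiveness"`, `"healthiness"`,
#'   `"formidability"`.
#' @return Scalar log-likelihood.
#' @export
rating_loglik <- function(params, data, dimension) {
  dimension <- match.arg(dimension, dimension_levels)
  if (!all(c("z_pp", "z_rs") %in% names(data$raters))) {
    abort("Raters must carry standardised scores `z_pp`, `z_rs`")
  }
  pr <- rating_phi(params, data, dimension)
  if (any(!(pr$score %in% 1:7))) abort("Rating score outside 1-7")
  sum(ordinal_log_prob(params$cutpoints, pr$phi, pr$score))
}

#' Log-likelihood of the scales (mediation) submodel
#'
#' Sum over raters and the two scales of the normal log-density of the
#' standardised perceived score given the condition-specific mean and the
#' scale's residual SD.
#'
#' @param params A [scale_params] object.
#' @param raters Rater table carrying `condition`, `z_pp`, `z_rs`.
#' @return Scalar log-likelihood.
#' @export
scales_loglik <- function(params, raters) {
  stopifnot(inherits(params, "scale_params"))
  if (any(params$resid_sd <= 0)) abort("Residual SDs must be positive")
  ci <- match(raters$condition, condition_levels)
  sum(dnorm_l(raters$z_pp, params$mu["pp", ci], params$resid_sd["pp"])) +
    sum(dnorm_l(raters$z_rs, params$mu["rs", ci], params$resid_sd["rs"]))
}

# log-density of varying intercepts given their hyper-SDs
varying_intercept_logdens <- function(params) {
  ld <- 0
  if (inherits(params, "choice_params")) {
    ld <- sum(dnorm_l(params$u_target, 0, params$sigma_target)) +
      sum(dnorm_l(params$v_rater, 0, params$sigma_rater))
  } else if (inherits(params, "rating_params")) {
    ld <- sum(dnorm_l(params$w_target, 0, params$sigma_target)) +
      sum(dnorm_l(params$x_rater, 0, params$sigma_rater)) +
      sum(dnorm_l(as.numeric(params$z_tr %||% numeric(0)), 0,
                  params$sigma_tr))
  }
  ld
}

# prior log-density of the top-level parameters of each block
choice_prior_logdens <- function(params, priors) {
  sum(dnorm_l(params$alpha, priors$intercept[1], priors$intercept[2])) +
    sum(dnorm_l(c(params$beta_attr, params$beta_form, params$beta_heal,
                  params$beta_pp, params$beta_rs, params$beta_side),
                priors$slope[1], priors$slope[2])) +
    stats::dexp(params$sigma_target, priors$hyper_sd_rate, log = TRUE) +
    stats::dexp(params$sigma_rater, priors$hyper_sd_rate, log = TRUE)
}

rating_prior_logdens <- function(params, priors) {
  raw <- cutpoints_to_raw(params$cutpoints)
  sum(dnorm_l(raw, priors$cutpoint[1], priors$cutpoint[2])) +
    sum(dnorm_l(c(params$a_mas, params$a_fem),
                priors$intercept[1], priors$intercept[2])) +
    sum(dnorm_l(c(params$g_mas_pp, params$g_mas_rs,
                  params$g_fem_pp, params$g_fem_rs),
                priors$slope[1], priors$slope[2])) +
    sum(stats::dexp(c(params$sigma_target, params$sigma_rater,
                      params$sigma_tr),
                    priors$hyper_sd_rate, log = TRUE))
}

scales_prior_logdens <- function(params, priors) {
  sum(dnorm_l(as.numeric(params$mu), priors$scale_mu[1],
              priors$scale_mu[2])) +
    sum(stats::dexp(params$resid_sd, priors$resid_sd_rate, log = TRUE))
}

#' Joint log-density of the full structural model
#'
#' The sum of the choice log-likelihood, the three ordinal rating
#' log-likelihoods, the scales log-likelihood, the normal log-densities of
#' every varying intercept given its hyper-SD, and the prior log-densities
#' of all top-level parameters. The prior on cut-points is evaluated on the
#' unconstrained ordered-transform scale (first cut-point plus
#' log-increments), matching the parameterisation the sampler uses.
#'
#' @param params List with elements `choice` ([choice_params]), `rating`
#'   (named list of [rating_params], one per dimension) and `scales`
#'   ([scale_params]).
#' @param data A preprocessed [study_data] object.
#' @param priors A [default_priors()] object.
#' @return Scalar joint log-density (unnormalised posterior at `params`).
#' @export
joint_log_density <- function(params, data, priors = default_priors()) {
  ll <- scales_loglik(params$scales, data$raters) +
    scales_prior_logdens(params$scales, priors)
  for (d in dimension_levels) {
    rp <- params$rating[[d]]
    ll <- ll + rating_loglik(rp, data, d) +
      varying_intercept_logdens(rp) + rating_prior_logdens(rp, priors)
  }
  ll + choice_loglik(params$choice, data) +
    varying_intercept_logdens(params$choice) +
    choice_prior_logdens(params$choice, priors)
}
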