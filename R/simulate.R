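# Synthetic-study generator: draws complete study-shaped datasets from the
# same generative model the analysis fits, so the whole pipeline is testable
# without the real data and parameter-recovery experiments are possible.

# Run code with a fixed seed without disturbing the caller's RNG stream
with_sim_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Reference generating values for the choice submodel
#'
#' Condition intercepts reproducing the estimated between-condition
#' log-odds contrasts (control-PP 0.17, control-RS 0.04, RS-PP 0.13) around
#' a near-chance baseline; attractiveness slopes 0.10/0.09/0.06 per rating
#' unit; a small positive healthiness slope only under resource scarcity;
#' a -0.06 per-SD perceived-pathogen slope; a side contrast worth a 0.51
#' right-side selection probability; and hyper-SDs 0.72 (targets) and 0.12
#' (raters).
#'
#' @return A [choice_params] object.
#' @export
reference_choice_params <- function() {
  choice_params(
    alpha = c(0.05, -0.12, 0.01),
    beta_attr = c(0.10, 0.09, 0.06),
    beta_form = c(0, 0, 0),
    beta_heal = c(0, 0, 0.07),
    beta_pp = -0.06, beta_rs = 0, beta_side = 0.08,
    sigma_target = 0.72, sigma_rater = 0.12
  )
}

# Calibrated cut-points and condition intercepts per dimension (see the
# methods vignette): cut-point spread follows the latent dispersion implied
# by the three varying-intercept SDs; the masculinised-minus-feminised
# intercept gaps are solved numerically so the population expected rating
# differences equal the estimated 0.06/0.02/0.04 (attractiveness),
# 0.44/0.47/0.42 (formidability) and 0.05/0.11/0.14 (healthiness).
rating_reference_table <- list(
  attractiveness = list(
    sigma = c(target = 5.97, rater = 3.00, tr = 2.48),
    cut_scale = 2.9, base = NA_real_, mean_fem = 2.7,
    gaps = c(0.06, 0.02, 0.04), g_pp = -0.2
  ),
  healthiness = list(
    sigma = c(target = 1.88, rater = 1.89, tr = 2.02),
    cut_scale = 1.35, base = NA_real_, mean_fem = 3.9,
    gaps = c(0.05, 0.11, 0.14), g_pp = 0
  ),
  formidability = list(
    sigma = c(target = 1.43, rater = 2.07, tr = 1.90),
    cut_scale = 1.3, base = NA_real_, mean_fem = 3.9,
    gaps = c(0.44, 0.47, 0.42), g_pp = 0
  )
)

# population E[Y] at intercept a, integrating the shared varying intercepts
# (total SD s) out of the cumulative-logit mean; Gauss-Hermite quadrature
ordinal_mean_at <- function(a, cutpoints, s, n_nodes = 61) {
  gh <- pracma_gauss_hermite(n_nodes)
  u <- sqrt(2) * s * gh$x
  w <- gh$w / sqrt(pi)
  ey <- vapply(u, function(ui) {
    sum(ordinal_category_probs(cutpoints, a + ui) * (1:7))
  }, numeric(1))
  sum(w * ey)
}

# Gauss-Hermite nodes/weights via the Golub-Welsch tridiagonal eigenproblem
pracma_gauss_hermite <- function(n) {
  b <- sqrt(seq_len(n - 1) / 2)
  J <- diag(0, n)
  J[cbind(1:(n - 1), 2:n)] <- b
  J[cbind(2:n, 1:(n - 1))] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = sqrt(pi) * e$vectors[1, ]^2)
}

# solve the per-condition masculinised gaps, anchoring the feminised
# intercept at zero (the identifiable decomposition: only intercepts minus
# cut-points enter the likelihood, so the location lives in the cut-points)
calibrate_rating_reference <- function(ref) {
  grid <- ref$cut_scale * c(-2.5, -1.5, -0.5, 0.5, 1.5, 2.5)
  s <- sqrt(sum(ref$sigma^2))
  base <- stats::uniroot(function(a) {
    ordinal_mean_at(a, grid, s) - ref$mean_fem
  }, c(-30, 30), tol = 1e-9)$root
  cutpoints <- grid - base    # feminised baseline mean_fem at intercept 0
  gaps <- vapply(ref$gaps, function(d) {
    stats::uniroot(function(g) {
      ordinal_mean_at(g, cutpoints, s) -
        ordinal_mean_at(0, cutpoints, s) - d
    }, c(0, 20), tol = 1e-9)$root
  }, numeric(1))
  list(cutpoints = cutpoints, base = 0, gaps = gaps)
}

#' Reference generating values for one rating submodel
#'
#' Hyper-SDs at the estimated per-dimension values (targets dominating
#' attractiveness; raters and target-rater interaction dominating
#' formidability; all three levelled for healthiness). Cut-points are spread
#' in proportion to the implied latent dispersion and carry the location:
#' the feminised condition intercepts are anchored at zero, which is the
#' identifiable decomposition of the translation-invariant ordinal block.
#' The per-condition
#' masculinised-minus-feminised intercept gaps are calibrated so the
#' population expected rating differences match the estimated values (the
#' formidability gap driving the ~0.45-unit difference). A small negative
#' perceived-pathogen slope on attractiveness ratings is included for both
#' versions.
#'
#' @param dimension One of `"attractiveness"`, `"healthiness"`,
#'   `"formidability"`.
#' @return A [rating_params] object.
#' @export
reference_rating_params <- function(dimension = dimension_levels) {
  dimension <- match.arg(dimension)
  ref <- rating_reference_table[[dimension]]
  cal <- calibrate_rating_reference(ref)
  rating_params(
    cutpoints = cal$cutpoints,
    a_mas = cal$base + cal$gaps,
    a_fem = rep(cal$base, 3),
    g_mas_pp = ref$g_pp, g_fem_pp = ref$g_pp,
    g_mas_rs = 0, g_fem_rs = 0,
    sigma_target = ref$sigma[["target"]],
    sigma_rater = ref$sigma[["rater"]],
    sigma_tr = ref$sigma[["tr"]]
  )
}

#' Reference generating values for the scales submodel
#'
#' A modest priming effect on the matching perceived scale (+0.25 raw-scale
#' units of pathogen-prevalence perception under PP priming, +0.25 of
#' resource-scarcity perception under RS priming) with unit residual SDs:
#' the manipulation-check regime of "some, although imperfect" evidence.
#'
#' @return A [scale_params] object.
#' @export
reference_scale_params <- function() {
  mu <- rbind(pp = c(0, 0.25, 0), rs = c(0, 0, 0.25))
  scale_params(mu = mu, resid_sd = c(pp = 1, rs = 1))
}

#' Configuration of the synthetic-study generator
#'
#' Defaults reproduce the retained analysis sample: 102/101/86 raters in
#' control / pathogen-prevalence / resource-scarcity conditions, 12 target
#' faces, generating parameters at the reference (estimated posterior-mean)
#' values, and no recognition, attention-check or orientation exclusions.
#'
#' @param n_raters Length-3 integer vector of raters per condition.
#' @param n_targets Number of target faces (>= 2).
#' @param choice [choice_params] generating values (varying intercepts are
#'   drawn, not taken from here).
#' @param rating Named list of [rating_params], one per dimension.
#' @param scales [scale_params] generating values for the perceived scores.
#' @param recognition_rate Probability a rater recognises any given target.
#' @param attention_fail_rate Probability a rater answers both attention
#'   checks wrong.
#' @param nonheterosexual_rate Probability a recruited rater is
#'   non-heterosexual.
#' @param simulate_items If `TRUE`, back-fill raw Likert-item columns for
#'   both scales from an equal-loading item model (so scale scoring and
#'   Cronbach's alpha can be exercised); scores are then item means and
#'   carry measurement noise. If `FALSE` (default) the latent scale scores
#'   are written directly.
#' @param n_items Items per scale when `simulate_items = TRUE`.
#' @param item_sd Item noise SDs tuned to give alphas near 0.84 (PP) and
#'   0.71 (RS) with 5 items.
#' @param seed Integer seed; the generator is fully reproducible given it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_raters = c(102, 101, 86), n_targets = 12,
                       choice = reference_choice_params(),
                       rating = list(
                         attractiveness = reference_rating_params("attractiveness"),
                         healthiness = reference_rating_params("healthiness"),
                         formidability = reference_rating_params("formidability")),
                       scales = reference_scale_params(),
                       recognition_rate = 0, attention_fail_rate = 0,
                       nonheterosexual_rate = 0,
                       simulate_items = FALSE, n_items = c(pp = 5, rs = 5),
                       item_sd = c(pp = 0.98, rs = 1.43),
                       seed = 1L) {
  if (length(n_raters) != 3 || any(n_raters < 1)) {
    abort("`n_raters` must give a positive count for each of the 3 conditions",
          class = "harshpref_config_error")
  }
  if (n_targets < 2) {
    abort("`n_targets` must be at least 2", class = "harshpref_config_error")
  }
  rates <- c(recognition_rate, attention_fail_rate, nonheterosexual_rate)
  if (any(rates < 0 | rates > 1)) {
    abort("Rates must be probabilities in [0, 1]",
          class = "harshpref_config_error")
  }
  stopifnot(inherits(choice, "choice_params"),
            inherits(scales, "scale_params"))
  for (d in dimension_levels) {
    if (!inherits(rating[[d]], "rating_params")) {
      abort(sprintf("`rating` must contain rating_params for '%s'", d),
            class = "harshpref_config_error")
    }
    check_cutpoints(rating[[d]]$cutpoints)
  }
  structure(list(n_raters = as.integer(n_raters), n_targets = as.integer(n_targets),
                 choice = choice, rating = rating, scales = scales,
                 recognition_rate = recognition_rate,
                 attention_fail_rate = attention_fail_rate,
                 nonheterosexual_rate = nonheterosexual_rate,
                 simulate_items = simulate_items, n_items = n_items,
                 item_sd = item_sd, seed = as.integer(seed)),
            class = "sim_config")
}

# inverse-CDF draw from the cumulative-logit model, vectorised over phi
draw_ordinal <- function(cutpoints, phi) {
  s <- plogis(outer(phi, cutpoints, `-`))  # P(Y > k)
  u <- runif(length(phi))
  1L + as.integer(rowSums(u < s))
}

#' Simulate a complete study dataset
#'
#' Draws a full study-shaped dataset from the generative model: raters are
#' assigned to conditions with a counterbalanced masculinised-side
#' assignment; perceived-score z values come from the scales submodel
#' (standardised within the realised sample, exactly as the analysis sees
#' them); ratings come from the cumulative-logit model with the configured
#' cut-points, version/condition intercepts and three freshly drawn
#' varying-intercept sets; choices are Bernoulli draws from the logistic
#' model using the *realised* rating differences as predictors; recognition
#' and attention-check flags are drawn independently.
#'
#' The generating truth (parameters plus the realised score-standardisation
#' affine map) is attached as attribute `"truth"` for parameter-recovery
#' work.
#'
#' @param config A [sim_config()].
#' @return A [study_data] object (raw: exclusions not applied, scores not
#'   yet standardised by the pipeline).
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_sim_seed(config$seed, simulate_study_impl(config))
}

simulate_study_impl <- function(config) {
  n <- sum(config$n_raters)
  nt <- config$n_targets
  condition <- rep(condition_levels, times = config$n_raters)
  rater_id <- sprintf("r%04d", seq_len(n))

  # counterbalanced side assignment: half left, half right, shuffled
  masc_side <- sample(rep(side_levels, length.out = n))

  heterosexual <- 1L - rbinom(n, 1, config$nonheterosexual_rate)
  att_fail <- rbinom(n, 1, config$attention_fail_rate)
  attention_correct <- ifelse(att_fail == 1, 0L, 1L + rbinom(n, 1, 0.5))

  # scales submodel: raw scores, then the standardised z the model consumes
  ci <- match(condition, condition_levels)
  sc <- config$scales
  pp_score <- rnorm(n, sc$mu["pp", ci], sc$resid_sd["pp"])
  rs_score <- rnorm(n, sc$mu["rs", ci], sc$resid_sd["rs"])
  z_pp <- as.numeric(scale(pp_score))
  z_rs <- as.numeric(scale(rs_score))

  raters <- tibble::tibble(
    rater_id = rater_id, condition = condition,
    heterosexual = heterosexual, attention_correct = attention_correct,
    masc_side = masc_side,
    age = pmax(18L, as.integer(round(rnorm(n, 21.03, 2.98)))),
    relationship_status = rbinom(n, 1, 109 / 289),
    mate_value_face = pmin(7L, pmax(1L, as.integer(round(rnorm(n, 4.58, 1.16))))),
    mate_value_body = pmin(7L, pmax(1L, as.integer(round(rnorm(n, 4.55, 1.32))))),
    pp_score = pp_score, rs_score = rs_score
  )
  if (config$simulate_items) {
    for (scl in c("pp", "rs")) {
      score <- if (scl == "pp") pp_score else rs_score
      for (j in seq_len(config$n_items[[scl]])) {
        raters[[sprintf("%s_%d", scl, j)]] <-
          score + rnorm(n, 0, config$item_sd[[scl]])
      }
    }
  }

  # ratings: one draw per rater x target x version x dimension
  grid <- expand.grid(target_id = seq_len(nt), rater = seq_len(n),
                      version = version_levels,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  truth_rating <- list()
  ratings <- vector("list", length(dimension_levels))
  names(ratings) <- dimension_levels
  for (d in dimension_levels) {
    rp <- config$rating[[d]]
    w <- rnorm(nt, 0, rp$sigma_target)
    x <- rnorm(n, 0, rp$sigma_rater)
    ztr <- matrix(rnorm(nt * n, 0, rp$sigma_tr), nt, n)
    mas <- grid$version == "masculinised"
    a <- ifelse(mas, rp$a_mas[condition[grid$rater]],
                rp$a_fem[condition[grid$rater]])
    g_pp <- ifelse(mas, rp$g_mas_pp, rp$g_fem_pp)
    g_rs <- ifelse(mas, rp$g_mas_rs, rp$g_fem_rs)
    phi <- a + g_pp * z_pp[grid$rater] + g_rs * z_rs[grid$rater] +
      w[grid$target_id] + x[grid$rater] + ztr[cbind(grid$target_id, grid$rater)]
    score <- draw_ordinal(rp$cutpoints, phi)
    ratings[[d]] <- tibble::tibble(
      rater_id = rater_id[grid$rater], target_id = grid$target_id,
      version = grid$version, dimension = d, score = score)
    rp$w_target <- w; rp$x_rater <- x; rp$z_tr <- ztr
    truth_rating[[d]] <- rp
  }
  ratings <- dplyr::bind_rows(ratings)

  # choices: logistic model on the realised rating differences
  cp <- config$choice
  u <- rnorm(nt, 0, cp$sigma_target)
  v <- rnorm(n, 0, cp$sigma_rater)
  diffs <- ratings |>
    tidyr::pivot_wider(names_from = "version", values_from = "score") |>
    dplyr::mutate(diff = .data$masculinised - .data$feminised) |>
    dplyr::select("rater_id", "target_id", "dimension", "diff") |>
    tidyr::pivot_wider(names_from = "dimension", values_from = "diff")
  ri <- match(diffs$rater_id, rater_id)
  side <- ifelse(masc_side[ri] == "left", -0.5, 0.5)
  eta <- choice_linear_predictor(
    cp, condition[ri],
    d_attr = diffs$attractiveness, d_form = diffs$formidability,
    d_heal = diffs$healthiness,
    z_pp = z_pp[ri], z_rs = z_rs[ri], side_contrast = side) +
    u[diffs$target_id] + v[ri]
  chose <- rbinom(length(eta), 1, plogis(eta))
  recognised <- rbinom(length(eta), 1, config$recognition_rate)
  choices <- tibble::tibble(
    rater_id = diffs$rater_id, target_id = diffs$target_id,
    chose_masculinised = chose, recognised = recognised)

  cp$u_target <- u; cp$v_rater <- v
  out <- study_data(raters, choices, ratings)
  attr(out, "truth") <- list(
    choice = cp, rating = truth_rating, scales = config$scales,
    score_center = c(pp = mean(pp_score), rs = mean(rs_score)),
    score_scale = c(pp = sd(pp_score), rs = sd(rs_score)),
    z_pp = z_pp, z_rs = z_rs
  )
  out
}

#' Simulate a batch of replicate datasets
#'
#' Replicate `r` uses the derived seed `config$seed + 1000003 * r`
#' (a documented splittable counter scheme), so the replicates are mutually
#' independent streams and the whole batch is reproducible from the master
#' seed.
#'
#' @param config A [sim_config()]; its `seed` acts as the master seed.
#' @param n_replicates Number of datasets (>= 1).
#' @return List of [study_data] objects.
#' @export
simulate_batch <- function(config, n_replicates) {
  stopifnot(n_replicates >= 1)
  lapply(seq_len(n_replicates), function(r) {
    cfg <- config
    cfg$seed <- as.integer((config$seed + 1000003 * r) %% .Machine$integer.max)
    simulate_study(cfg)
  })
}
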