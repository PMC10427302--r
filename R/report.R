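# Counterfactual predictions and the run report: translate posterior
# log-odds into choice probabilities over covariate grids, collect the
# headline posterior estimates, and tabulate raw descriptives.

#' Build a covariate grid for counterfactual choice predictions
#'
#' Expands the supplied covariate settings into a grid. Defaults isolate
#' the condition and perceived-score effects: rating differences 0, side
#' contrast 0 (the masculinised face equally often left and right),
#' population-typical rater and target (varying intercepts 0).
#'
#' @param condition Condition label(s).
#' @param z_pp,z_rs Standardised perceived-score value(s).
#' @param side_contrast Side contrast value(s) (-0.5 / 0 / +0.5).
#' @param d_attr,d_form,d_heal Rating-difference settings.
#' @return A tibble, one row per grid point.
#' @export
covariate_grid <- function(condition = condition_levels, z_pp = 0, z_rs = 0,
                           side_contrast = 0, d_attr = 0, d_form = 0,
                           d_heal = 0) {
  if (!all(condition %in% condition_levels)) {
    abort("Unknown condition label in `condition`")
  }
  vals <- list(condition = condition, z_pp = z_pp, z_rs = z_rs,
               side_contrast = side_contrast, d_attr = d_attr,
               d_form = d_form, d_heal = d_heal)
  if (any(!vapply(vals[-1], function(v) all(is.finite(v)), logical(1)))) {
    abort("Grid values must be finite")
  }
  tibble::as_tibble(expand.grid(vals, KEEP.OUT.ATTRS = FALSE,
                                stringsAsFactors = FALSE))
}

choice_eta_draws <- function(m, grid) {
  ci <- match(grid$condition, condition_levels)
  alpha <- m[, sprintf("alpha[%s]", cond_short)]
  b_attr <- m[, sprintf("b_attr[%s]", cond_short)]
  b_form <- m[, sprintf("b_form[%s]", cond_short)]
  b_heal <- m[, sprintf("b_heal[%s]", cond_short)]
  eta <- alpha[, ci, drop = FALSE] +
    b_attr[, ci, drop = FALSE] * rep(grid$d_attr, each = nrow(m)) +
    b_form[, ci, drop = FALSE] * rep(grid$d_form, each = nrow(m)) +
    b_heal[, ci, drop = FALSE] * rep(grid$d_heal, each = nrow(m)) +
    outer(m[, "b_pp"], grid$z_pp) + outer(m[, "b_rs"], grid$z_rs) +
    outer(m[, "b_side"], grid$side_contrast)
  eta
}

#' Posterior choice probabilities over a covariate grid
#'
#' For every posterior draw, takes the inverse logit of the choice linear
#' predictor at each grid point with varying intercepts set to 0
#' (a population-typical rater and target), and summarises with the
#' posterior mean and central 89% interval.
#'
#' @param samples A `posterior_draws` containing the choice block.
#' @param grid A [covariate_grid()] (or compatible tibble).
#' @param prob Interval mass.
#' @return The grid with `prob_mean`, `prob_lower`, `prob_upper` columns;
#'   the per-draw probability matrix (draws x grid points) is attached as
#'   attribute `"prob_draws"`.
#' @export
predict_choice_prob <- function(samples, grid = covariate_grid(),
                                prob = 0.89) {
  m <- draws_matrix(samples)
  if (!all(grid$condition %in% condition_levels)) {
    abort("Grid references an unknown condition")
  }
  p <- plogis(choice_eta_draws(m, grid))
  a <- (1 - prob) / 2
  qs <- apply(p, 2, quantile, probs = c(a, 1 - a), names = FALSE)
  out <- grid
  out$prob_mean <- unname(colMeans(p))
  out$prob_lower <- unname(qs[1, ])
  out$prob_upper <- unname(qs[2, ])
  attr(out, "prob_draws") <- p
  out
}

#' Headline posterior estimates of the full fit
#'
#' The report table of the analysis, each row a posterior mean with its
#' 89% compatibility interval: the three pairwise condition-intercept
#' contrasts of the choice model; the perceived-score slopes; the side
#' effect translated into left/right selection probabilities; the
#' per-condition rating-difference slopes for the three dimensions; the
#' per-condition expected masculinised-minus-feminised rating differences;
#' and every hyper-SD.
#'
#' @param samples A `posterior_draws` from [fit_study()].
#' @param data The preprocessed [study_data] the model was fitted to.
#' @param prob Interval mass.
#' @return A tibble with 36 rows: `quantity`, `mean`, `lower`, `upper`.
#' @export
headline_estimates <- function(samples, data, prob = 0.89) {
  m <- draws_matrix(samples)
  need <- c("alpha[control]", "b_pp", "form.cut[1]")
  if (!all(need %in% colnames(m))) {
    abort("headline_estimates() needs a full fit (choice + rating blocks)")
  }
  rows <- list()
  add <- function(name, draws) {
    rows[[length(rows) + 1]] <<- c(quantity = name, as.list(
      summarise_draws_vec(draws, prob)))
  }
  add("contrast_alpha[control-pp]",
      m[, "alpha[control]"] - m[, "alpha[pp]"])
  add("contrast_alpha[control-rs]",
      m[, "alpha[control]"] - m[, "alpha[rs]"])
  add("contrast_alpha[rs-pp]", m[, "alpha[rs]"] - m[, "alpha[pp]"])
  add("b_pp", m[, "b_pp"])
  add("b_rs", m[, "b_rs"])
  add("prob_masc_right", plogis(0.5 * m[, "b_side"]))
  add("prob_masc_left", plogis(-0.5 * m[, "b_side"]))
  for (slope in c("b_attr", "b_form", "b_heal")) {
    for (cc in cond_short) {
      add(sprintf("%s[%s]", slope, cc), m[, sprintf("%s[%s]", slope, cc)])
    }
  }
  for (d in dimension_levels) {
    dd <- rating_difference_posterior(samples, data, d)
    for (k in 1:3) add(colnames(dd)[k], dd[, k])
  }
  add("sigma_target", m[, "sigma_target"])
  add("sigma_rater", m[, "sigma_rater"])
  for (d in dimension_levels) {
    pre <- dim_short[d]
    for (s in c("sigma_target", "sigma_rater", "sigma_tr")) {
      add(sprintf("%s.%s", pre, s), m[, sprintf("%s.%s", pre, s)])
    }
  }
  dplyr::bind_rows(lapply(rows, tibble::as_tibble))
}

summarise_draws_vec <- function(x, prob = 0.89) {
  a <- (1 - prob) / 2
  q <- quantile(x, c(a, 1 - a), names = FALSE)
  list(mean = mean(x), lower = q[1], upper = q[2])
}

#' Raw descriptive statistics of a preprocessed dataset
#'
#' Overall and per-condition proportions of choices in which the
#' masculinised face was picked, mean ratings by version and dimension, and
#' retained-sample tallies.
#'
#' @param data A [study_data] object.
#' @return A list of tibbles: `choice_proportions`, `rating_means`,
#'   `sample_sizes`.
#' @export
raw_descriptives <- function(data) {
  validate_study_data(data)
  if (nrow(data$choices) == 0) abort("No choice records in the data")
  cond_of <- data$raters$condition[match(data$choices$rater_id,
                                         data$raters$rater_id)]
  by_cond <- tapply(data$choices$chose_masculinised, cond_of, mean)
  choice_prop <- tibble::tibble(
    condition = c("overall", condition_levels),
    n_choices = c(nrow(data$choices),
                  as.vector(table(factor(cond_of, condition_levels)))),
    prop_masculinised = c(mean(data$choices$chose_masculinised),
                          as.vector(by_cond[condition_levels])))
  rating_means <- data$ratings |>
    dplyr::group_by(.data$dimension, .data$version) |>
    dplyr::summarise(mean_rating = mean(.data$score),
                     sd_rating = sd(.data$score), .groups = "drop")
  sample_sizes <- tibble::tibble(
    condition = condition_levels,
    n_raters = as.vector(table(factor(data$raters$condition,
                                      condition_levels))))
  list(choice_proportions = choice_prop, rating_means = rating_means,
       sample_sizes = sample_sizes)
}
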