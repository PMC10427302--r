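# Parameter-recovery accounting for simulation studies: compare a fitted
# posterior against the generating values attached by simulate_study().

#' Tabulate recovery of the generating top-level parameters
#'
#' For every top-level parameter of the joint model (condition intercepts
#' and slopes, perceived-score slopes, side effect, cut-points, and all
#' hyper-SDs and scale parameters), looks up the generating value from a
#' [simulate_study()] `"truth"` attribute and checks whether it falls
#' inside the posterior compatibility interval. Generating scale means and
#' residual SDs are mapped onto the analysis (standardised) scale using the
#' realised score centring recorded by the generator.
#'
#' @param fit A `posterior_draws` from [fit_study()].
#' @param truth The `attr(simulated_data, "truth")` list.
#' @param prob Interval mass (default 0.89).
#' @return A tibble: `name`, `truth`, `mean`, `lower`, `upper`, `inside`.
#' @export
parameter_recovery <- function(fit, truth, prob = 0.89) {
  tv <- c()
  add <- function(names, values) {
    tv[names] <<- unname(values)
  }
  cp <- truth$choice
  add(sprintf("alpha[%s]", cond_short), cp$alpha)
  add(sprintf("b_attr[%s]", cond_short), cp$beta_attr)
  add(sprintf("b_form[%s]", cond_short), cp$beta_form)
  add(sprintf("b_heal[%s]", cond_short), cp$beta_heal)
  add(c("b_pp", "b_rs", "b_side"),
      c(cp$beta_pp, cp$beta_rs, cp$beta_side))
  add(c("sigma_target", "sigma_rater"),
      c(cp$sigma_target, cp$sigma_rater))
  for (d in dimension_levels) {
    rp <- truth$rating[[d]]
    pre <- dim_short[d]
    add(sprintf("%s.a_mas[%s]", pre, cond_short), rp$a_mas)
    add(sprintf("%s.a_fem[%s]", pre, cond_short), rp$a_fem)
    add(sprintf("%s.g_mas_pp", pre), rp$g_mas_pp)
    add(sprintf("%s.g_mas_rs", pre), rp$g_mas_rs)
    add(sprintf("%s.g_fem_pp", pre), rp$g_fem_pp)
    add(sprintf("%s.g_fem_rs", pre), rp$g_fem_rs)
    add(sprintf("%s.cut[%d]", pre, 1:6), rp$cutpoints)
    add(sprintf("%s.sigma_target", pre), rp$sigma_target)
    add(sprintf("%s.sigma_rater", pre), rp$sigma_rater)
    add(sprintf("%s.sigma_tr", pre), rp$sigma_tr)
  }
  # scales truth mapped to the standardised analysis scale
  for (s in c("pp", "rs")) {
    m <- truth$score_center[[s]]
    sc <- truth$score_scale[[s]]
    add(sprintf("mu_%s[%s]", s, cond_short),
        (truth$scales$mu[s, ] - m) / sc)
    add(sprintf("resid_sd_%s", s), truth$scales$resid_sd[[s]] / sc)
  }
  sm <- summarise_posterior(fit, prob = prob)
  sm <- sm[match(names(tv), sm$name), ]
  if (any(is.na(sm$name))) {
    abort("Fitted draws lack some top-level parameters; fit the full model")
  }
  tibble::tibble(
    name = names(tv), truth = unname(tv), mean = sm$mean,
    lower = sm$lower, upper = sm$upper,
    inside = tv >= sm$lower & tv <= sm$upper)
}
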