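# Participant- and data-point-level exclusion cascade, scale scoring,
# standardisation and side-contrast coding. The default variant is the
# main-text rule set; the alternative inclusion criteria are switchable
# flags.

#' Exclusion-rule variant
#'
#' The default (all flags `FALSE`) is the main rule set: drop
#' non-heterosexual raters, drop raters who answered both attention-check
#' questions wrong, remove raters who recognised more than four faces
#' entirely, and remove the individual data points where the face was
#' recognised. Each flag relaxes one rule, giving the alternative inclusion
#' criteria.
#'
#' @param keep_recognised_points Keep choice/rating records of recognised
#'   faces (raters recognising more than four faces are still removed).
#' @param keep_attention_failures Keep raters with `attention_correct == 0`.
#' @param keep_nonheterosexual Keep non-heterosexual raters.
#' @return An `exclusion_variant` list.
#' @export
exclusion_variant <- function(keep_recognised_points = FALSE,
                              keep_attention_failures = FALSE,
                              keep_nonheterosexual = FALSE) {
  structure(list(keep_recognised_points = keep_recognised_points,
                 keep_attention_failures = keep_attention_failures,
                 keep_nonheterosexual = keep_nonheterosexual),
            class = "exclusion_variant")
}

#' Apply the exclusion cascade
#'
#' Filters a raw study dataset in four ordered stages: (0) an optional
#' manual drop list for idiosyncratic removals, (1) non-heterosexual raters,
#' (2) raters with zero correct attention-check answers (one or two correct
#' retains), (3) raters recognising more than four faces (all their data),
#' (4) the remaining individual choice and rating records whose target was
#' recognised. Ratings of a recognised face are removed together with the
#' choice record, since both rest on the same contaminated knowledge of the
#' face-bearer.
#'
#' @param data A raw [study_data] object with orientation, attention and
#'   recognition fields populated.
#' @param variant An [exclusion_variant()].
#' @param drop_raters Character vector of rater ids removed up front for
#'   idiosyncratic reasons.
#' @return A list with elements `data` (the filtered [study_data]) and
#'   `report` (an `exclusion_report` with stage-by-stage tallies).
#' @export
apply_exclusions <- function(data, variant = exclusion_variant(),
                             drop_raters = character(0)) {
  validate_study_data(data)
  raters <- data$raters
  if (any(is.na(data$choices$recognised))) {
    abort("Missing recognition flags in the choices table")
  }
  if (any(is.na(raters$attention_correct)) ||
      any(!(raters$attention_correct %in% 0:2))) {
    abort("`attention_correct` must be 0, 1 or 2 for every rater")
  }

  n_recruited <- nrow(raters)

  keep <- !(raters$rater_id %in% drop_raters)
  n_idio <- sum(!keep)
  raters <- raters[keep, ]

  if (!variant$keep_nonheterosexual) {
    keep <- raters$heterosexual == 1
    n_hetero <- sum(!keep)
    raters <- raters[keep, ]
  } else n_hetero <- 0L

  if (!variant$keep_attention_failures) {
    keep <- raters$attention_correct >= 1
    n_attention <- sum(!keep)
    raters <- raters[keep, ]
  } else n_attention <- 0L

  rec_counts <- data$choices |>
    dplyr::filter(.data$rater_id %in% raters$rater_id) |>
    dplyr::group_by(.data$rater_id) |>
    dplyr::summarise(n_recognised = sum(.data$recognised), .groups = "drop")
  heavy <- rec_counts$rater_id[rec_counts$n_recognised > 4]
  n_heavy <- length(heavy)
  raters <- raters[!(raters$rater_id %in% heavy), ]

  choices <- data$choices[data$choices$rater_id %in% raters$rater_id, ]
  ratings <- data$ratings[data$ratings$rater_id %in% raters$rater_id, ]

  if (!variant$keep_recognised_points) {
    recognised_key <- with(choices[choices$recognised == 1, ],
                           paste(rater_id, target_id))
    n_points <- sum(choices$recognised == 1)
    choices <- choices[choices$recognised == 0, ]
    ratings <- ratings[!(paste(ratings$rater_id, ratings$target_id) %in%
                           recognised_key), ]
  } else n_points <- 0L

  by_cond <- tabulate(match(raters$condition, condition_levels), nbins = 3L)
  names(by_cond) <- condition_levels

  out <- study_data(raters, choices, ratings)
  report <- structure(list(
    n_recruited = n_recruited,
    n_removed_idiosyncratic = n_idio,
    n_removed_nonheterosexual = n_hetero,
    n_removed_attention = n_attention,
    n_raters_removed_recognition = n_heavy,
    n_datapoints_removed_recognition = n_points,
    n_retained_raters = nrow(raters),
    n_retained_datapoints = nrow(choices),
    retained_by_condition = by_cond
  ), class = "exclusion_report")
  list(data = out, report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("<exclusion_report>\n")
  cat(sprintf("  recruited raters:                %d\n", x$n_recruited))
  cat(sprintf("  removed (idiosyncratic):         %d\n",
              x$n_removed_idiosyncratic))
  cat(sprintf("  removed (non-heterosexual):      %d\n",
              x$n_removed_nonheterosexual))
  cat(sprintf("  removed (attention check):       %d\n",
              x$n_removed_attention))
  cat(sprintf("  removed (recognised > 4 faces):  %d raters\n",
              x$n_raters_removed_recognition))
  cat(sprintf("  removed (recognised data points):%d\n",
              x$n_datapoints_removed_recognition))
  cat(sprintf("  retained: %d raters (%s), %d data points\n",
              x$n_retained_raters,
              paste(x$retained_by_condition, collapse = "/"),
              x$n_retained_datapoints))
  invisible(x)
}

#' Cronbach's alpha of a multi-item scale
#'
#' Internal-consistency coefficient by the variance decomposition
#' `alpha = k/(k-1) * (1 - sum(var(item)) / var(total))` with sample
#' variances (denominator n-1) and `total` the per-respondent item sum.
#'
#' @param items Numeric matrix or data frame, one row per respondent, one
#'   column per item (at least 2 of each).
#' @return Scalar alpha.
#' @export
#' @examples
#' cronbach_alpha(cbind(c(1, 2, 3), c(2, 3, 4)))
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  if (ncol(items) < 2) abort("Cronbach's alpha needs at least 2 items")
  if (nrow(items) < 2) {
    abort("Cronbach's alpha is undefined for fewer than 2 respondents")
  }
  total_var <- var(rowSums(items))
  if (total_var == 0) {
    abort("Cronbach's alpha is undefined: total score has zero variance")
  }
  k <- ncol(items)
  (k / (k - 1)) * (1 - sum(apply(items, 2, var)) / total_var)
}

scale_item_columns <- function(raters, prefix) {
  nm <- grep(paste0("^", prefix, "_[0-9]+$"), names(raters), value = TRUE)
  nm[order(as.integer(sub(paste0(prefix, "_"), "", nm)))]
}

#' Score the perceived pathogen-prevalence and resource-scarcity scales
#'
#' Computes each rater's scale score as the mean of the scale's Likert item
#' responses (columns `pp_1`, `pp_2`, ... and `rs_1`, ...) and attaches
#' Cronbach's alpha for both scales.
#'
#' @param raters Rater table with the item columns.
#' @return The rater table with `pp_score` and `rs_score` columns; the
#'   attribute `alpha` carries `c(pp = ..., rs = ...)`.
#' @export
score_scales <- function(raters) {
  out <- raters
  alphas <- c(pp = NA_real_, rs = NA_real_)
  for (scale in c("pp", "rs")) {
    cols <- scale_item_columns(raters, scale)
    if (length(cols) < 2) {
      abort(sprintf("Need at least 2 `%s_*` item columns to score the %s scale",
                    scale, toupper(scale)))
    }
    items <- as.matrix(raters[, cols])
    out[[paste0(scale, "_score")]] <- rowMeans(items)
    alphas[scale] <- cronbach_alpha(items)
  }
  attr(out, "alpha") <- alphas
  out
}

#' Standardise the perceived scale scores
#'
#' Converts `pp_score` and `rs_score` into z-scores (`z_pp`, `z_rs`) with
#' mean 0 and SD 1 (denominator n-1) over the raters supplied. Run this on
#' the retained (post-exclusion) sample so the z-scores are centred in the
#' analysed population.
#'
#' @param raters Rater table carrying `pp_score` and `rs_score`.
#' @return The rater table with `z_pp` and `z_rs` added.
#' @export
standardise_scales <- function(raters) {
  for (scale in c("pp", "rs")) {
    score <- raters[[paste0(scale, "_score")]]
    if (is.null(score)) {
      abort(sprintf("Column `%s_score` missing; run score_scales() first",
                    scale))
    }
    s <- sd(score)
    if (!is.finite(s) || s == 0) {
      abort(sprintf("Cannot standardise `%s_score`: zero variance", scale))
    }
    raters[[paste0("z_", scale)]] <- (score - mean(score)) / s
  }
  raters
}

#' Code the left/right side contrast
#'
#' Adds the `side_contrast` column to the choices table: -0.5 when the
#' masculinised photo was displayed on the left of the screen for that
#' rater, +0.5 when on the right. The side assignment is constant within a
#' rater; if the choices table carries its own `masc_side` column it must
#' agree with the rater table.
#'
#' @param data A [study_data] object.
#' @return The [study_data] with `side_contrast` coded.
#' @export
code_side_contrast <- function(data) {
  side <- data$raters$masc_side[match(data$choices$rater_id,
                                      data$raters$rater_id)]
  if (any(!(side %in% side_levels))) {
    abort("Unknown `masc_side` label; must be 'left' or 'right'")
  }
  if ("masc_side" %in% names(data$choices)) {
    bad <- which(data$choices$masc_side != side)
    if (length(bad) > 0) {
      schema_error("choices", "masc_side", bad,
                   "side label differs from the rater's assignment")
    }
  }
  data$choices$side_contrast <- ifelse(side == "left", -0.5, 0.5)
  validate_study_data(data)
  data
}

#' Preprocess a raw study dataset for analysis
#'
#' Convenience wrapper running the full preparation chain: exclusion
#' cascade, scale scoring (when item columns are present; otherwise existing
#' `pp_score`/`rs_score` columns are used), standardisation on the retained
#' sample, and side-contrast coding.
#'
#' @inheritParams apply_exclusions
#' @return A list with `data` (analysis-ready [study_data]) and `report`
#'   (the [apply_exclusions()] report, with scale alphas attached as
#'   attribute `alpha` when items were scored).
#' @export
preprocess_study <- function(data, variant = exclusion_variant(),
                             drop_raters = character(0)) {
  res <- apply_exclusions(data, variant, drop_raters)
  raters <- res$data$raters
  if (length(scale_item_columns(raters, "pp")) >= 2 &&
      length(scale_item_columns(raters, "rs")) >= 2) {
    raters <- score_scales(raters)
    attr(res$report, "alpha") <- attr(raters, "alpha")
  }
  raters <- standardise_scales(raters)
  res$data$raters <- raters
  res$data <- code_side_contrast(res$data)
  res
}
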