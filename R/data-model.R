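#' @importFrom rlang %||% abort warn
#' @importFrom stats plogis qlogis rnorm rbinom runif rexp sd var quantile setNames
#' @importFrom utils head
#' @importFrom Rcpp sourceCpp
#' @useDynLib harshpref, .registration = TRUE
NULL

# Canonical factor levels used throughout the package
condition_levels <- c("control", "pathogen_prevalence", "resource_scarcity")
version_levels   <- c("masculinised", "feminised")
dimension_levels <- c("attractiveness", "healthiness", "formidability")
side_levels      <- c("left", "right")

#' Construct a validated study dataset
#'
#' Bundles the three long-format tables of a forced-choice masculinity
#' preference study into a single validated container: one row per rater
#' (condition assignment, orientation, attention check, perceived
#' pathogen-prevalence/resource-scarcity responses, side counterbalancing),
#' one row per rater x target forced choice, and one row per
#' rater x target x version x dimension Likert rating.
#'
#' @param raters Data frame with columns `rater_id`, `condition` (one of
#'   `"control"`, `"pathogen_prevalence"`, `"resource_scarcity"`),
#'   `heterosexual` (0/1), `attention_correct` (integer 0-2), `masc_side`
#'   (`"left"` or `"right"`). Optional columns: `age`, `relationship_status`,
#'   `mate_value_face`, `mate_value_body`, Likert item columns `pp_1`,
#'   `pp_2`, ... and `rs_1`, ..., and the derived columns `pp_score`,
#'   `rs_score`, `z_pp`, `z_rs` (absent until scoring/standardisation).
#' @param choices Data frame with columns `rater_id`, `target_id` (integer),
#'   `chose_masculinised` (0/1), `recognised` (0/1); optional `side_contrast`
#'   (-0.5 when the masculinised face was on the left, +0.5 on the right).
#' @param ratings Data frame with columns `rater_id`, `target_id`, `version`
#'   (`"masculinised"`/`"feminised"`), `dimension` (`"attractiveness"`,
#'   `"healthiness"`, `"formidability"`), `score` (integer 1-7).
#'
#' @return An object of class `study_data`: a list of the three validated
#'   tibbles.
#' @export
#' @examples
#' d <- simulate_study(sim_config(n_raters = c(4, 4, 4), seed = 1))
#' d
study_data <- function(raters, choices, ratings) {
  x <- structure(
    list(
      raters  = tibble::as_tibble(raters),
      choices = tibble::as_tibble(choices),
      ratings = tibble::as_tibble(ratings)
    ),
    class = "study_data"
  )
  validate_study_data(x)
  x
}

#' @export
print.study_data <- function(x, ...) {
  cat("<study_data>\n")
  cat("  raters:  ", nrow(x$raters), " (",
      paste(sprintf("%s=%d", abbreviate(condition_levels, 7),
                    tabulate(match(x$raters$condition, condition_levels),
                             nbins = 3L)),
            collapse = ", "), ")\n", sep = "")
  cat("  choices: ", nrow(x$choices), "\n", sep = "")
  cat("  ratings: ", nrow(x$ratings), "\n", sep = "")
  invisible(x)
}

schema_error <- function(table, field, rows, msg) {
  rows <- head(rows, 5L)
  abort(sprintf("Schema error in `%s`, field `%s` (row %s): %s",
                table, field, paste(rows, collapse = ", "), msg),
        class = "harshpref_schema_error")
}

require_columns <- function(df, cols, table) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("Table `%s` is missing required column(s): %s",
                  table, paste(missing, collapse = ", ")),
          class = "harshpref_schema_error")
  }
}

check_binary <- function(df, field, table) {
  v <- df[[field]]
  bad <- which(!(v %in% c(0, 1)) | is.na(v))
  if (length(bad) > 0) {
    schema_error(table, field, bad, "values must be 0 or 1")
  }
}

#' Validate a study dataset
#'
#' Checks the column schema, value ranges (Likert scores in 1-7, attention
#' check in 0-2, conditions and side labels among the known levels),
#' uniqueness of record keys, and referential integrity (every choice and
#' rating refers to an existing rater; side contrasts, when present, match
#' the rater's side assignment). Violations raise a classed error naming the
#' table, field and offending rows.
#'
#' @param x A `study_data` object (or plain list with the three tables).
#' @return `x`, invisibly, if valid.
#' @export
validate_study_data <- function(x) {
  raters  <- x$raters
  choices <- x$choices
  ratings <- x$ratings

  require_columns(raters, c("rater_id", "condition", "heterosexual",
                            "attention_correct", "masc_side"), "raters")
  require_columns(choices, c("rater_id", "target_id", "chose_masculinised",
                             "recognised"), "choices")
  require_columns(ratings, c("rater_id", "target_id", "version", "dimension",
                             "score"), "ratings")

  bad <- which(!(raters$condition %in% condition_levels))
  if (length(bad) > 0) {
    schema_error("raters", "condition", bad,
                 sprintf("unknown condition label %s",
                         paste(unique(raters$condition[bad]), collapse = ", ")))
  }
  bad <- which(!(raters$masc_side %in% side_levels))
  if (length(bad) > 0) schema_error("raters", "masc_side", bad,
                                    "must be 'left' or 'right'")
  bad <- which(!(raters$attention_correct %in% 0:2))
  if (length(bad) > 0) schema_error("raters", "attention_correct", bad,
                                    "must be an integer in 0-2")
  check_binary(raters, "heterosexual", "raters")
  if (anyDuplicated(raters$rater_id)) {
    schema_error("raters", "rater_id", which(duplicated(raters$rater_id)),
                 "duplicated rater identifier")
  }

  check_binary(choices, "chose_masculinised", "choices")
  check_binary(choices, "recognised", "choices")
  key <- paste(choices$rater_id, choices$target_id)
  if (anyDuplicated(key)) {
    schema_error("choices", "rater_id/target_id", which(duplicated(key)),
                 "more than one choice per rater x target")
  }
  bad <- which(!(choices$rater_id %in% raters$rater_id))
  if (length(bad) > 0) {
    schema_error("choices", "rater_id", bad,
                 "refers to a rater absent from the raters table")
  }
  if ("side_contrast" %in% names(choices) && nrow(choices) > 0) {
    expect <- ifelse(raters$masc_side[match(choices$rater_id,
                                            raters$rater_id)] == "left",
                     -0.5, 0.5)
    bad <- which(!is.na(choices$side_contrast) &
                   choices$side_contrast != expect)
    if (length(bad) > 0) {
      schema_error("choices", "side_contrast", bad,
                   "inconsistent with the rater's masc_side assignment")
    }
  }

  bad <- which(!(ratings$score %in% 1:7))
  if (length(bad) > 0) {
    schema_error("ratings", "score", bad, "Likert score must be in 1-7")
  }
  bad <- which(!(ratings$version %in% version_levels))
  if (length(bad) > 0) schema_error("ratings", "version", bad,
                                    "must be 'masculinised' or 'feminised'")
  bad <- which(!(ratings$dimension %in% dimension_levels))
  if (length(bad) > 0) {
    schema_error("ratings", "dimension", bad,
                 "must be one of attractiveness/healthiness/formidability")
  }
  key <- paste(ratings$rater_id, ratings$target_id, ratings$version,
               ratings$dimension)
  if (anyDuplicated(key)) {
    schema_error("ratings", "record key", which(duplicated(key)),
                 "duplicate rating for a rater x target x version x dimension")
  }
  bad <- which(!(ratings$rater_id %in% raters$rater_id))
  if (length(bad) > 0) {
    schema_error("ratings", "rater_id", bad,
                 "refers to a rater absent from the raters table")
  }
  invisible(x)
}

#' Read a study dataset from CSV tables
#'
#' Reads `raters.csv`, `choices.csv` and `ratings.csv` (comma-separated,
#' UTF-8, with headers) from a directory or from explicitly named paths and
#' returns a validated [study_data] object. Recognition flags live in the
#' choices table (`recognised` column).
#'
#' @param dir Directory containing the three CSV files; ignored if all three
#'   `*_file` paths are given.
#' @param raters_file,choices_file,ratings_file Optional explicit paths.
#' @return A validated [study_data] object.
#' @export
read_study <- function(dir = NULL, raters_file = NULL, choices_file = NULL,
                       ratings_file = NULL) {
  if (!is.null(dir)) {
    raters_file  <- raters_file  %||% file.path(dir, "raters.csv")
    choices_file <- choices_file %||% file.path(dir, "choices.csv")
    ratings_file <- ratings_file %||% file.path(dir, "ratings.csv")
  }
  for (f in c(raters_file, choices_file, ratings_file)) {
    if (is.null(f) || !file.exists(f)) {
      abort(sprintf("Study table not found: %s", f %||% "<missing path>"),
            class = "harshpref_io_error")
    }
  }
  read1 <- function(f) {
    tibble::as_tibble(utils::read.csv(f, stringsAsFactors = FALSE,
                                      fileEncoding = "UTF-8"))
  }
  study_data(read1(raters_file), read1(choices_file), read1(ratings_file))
}

#' Write a study dataset to CSV tables
#'
#' Writes the three tables as headed, comma-separated UTF-8 files
#' (`raters.csv`, `choices.csv`, `ratings.csv`). Round-trips with
#' [read_study()]: reading the written files reproduces the dataset up to
#' row order.
#'
#' @param data A [study_data] object.
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_study <- function(data, dir) {
  validate_study_data(data)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!dir.exists(dir)) {
    abort(sprintf("Cannot create output directory: %s", dir),
          class = "harshpref_io_error")
  }
  write1 <- function(df, f) {
    utils::write.csv(df, file.path(dir, f), row.names = FALSE,
                     fileEncoding = "UTF-8")
  }
  write1(data$raters, "raters.csv")
  write1(data$choices, "choices.csv")
  write1(data$ratings, "ratings.csv")
  invisible(dir)
}
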