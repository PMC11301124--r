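#' Questionnaire scale definitions
#'
#' A scale definition records the bounds of a questionnaire score and the
#' direction that counts as clinical improvement. The four built-in scales
#' cover the instruments used in the three-arm public speaking anxiety
#' design: the Implicit Association Test (IAT) for fear of negative
#' evaluation, the Personal Report of Communication Apprehension (PRCA-24),
#' the State Perceived Index of Competence (SPIC), and the short-form
#' State-Trait Anxiety Inventory (STAI, coded so that higher = more
#' comfort). PRCA-24 is the only scale where improvement is a decrease.
#'
#' @param name Scale label.
#' @param xmin,xmax Numeric score bounds, `xmax > xmin`.
#' @param improvement_direction `"increase"` or `"decrease"`.
#' @return An object of class `scale_definition`.
#' @examples
#' scale_definition("PRCA24", 24, 120, "decrease")
#' @export
scale_definition <- function(name, xmin, xmax,
                             improvement_direction = c("increase", "decrease")) {
  improvement_direction <- match.arg(improvement_direction)
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(xmin), is.numeric(xmax), length(xmin) == 1L,
            length(xmax) == 1L, is.finite(xmin), is.finite(xmax))
  if (xmax <= xmin) {
    stop("degenerate scale: xmax (", xmax, ") must exceed xmin (", xmin, ")")
  }
  structure(
    list(name = name, xmin = xmin, xmax = xmax,
         improvement_direction = improvement_direction),
    class = "scale_definition"
  )
}

#' @export
print.scale_definition <- function(x, ...) {
  cat(sprintf("<scale %s: [%g, %g], improvement = %s>\n",
              x$name, x$xmin, x$xmax, x$improvement_direction))
  invisible(x)
}

#' Built-in scales of the three-arm anxiety design
#'
#' @return Named list of [scale_definition()] objects: `IAT` (-2..2,
#'   improvement = increase), `PRCA24` (24..120, improvement = decrease),
#'   `SPIC` (15..105, increase), `STAI` (8..32, increase; this short form
#'   is coded so higher scores mean more comfort). `afterSPIC` shares the
#'   `SPIC` definition: "after" is a measurement role, not a new scale.
#' @examples
#' builtin_scales()$PRCA24
#' @export
builtin_scales <- function() {
  list(
    IAT    = scale_definition("IAT",    -2,   2, "increase"),
    PRCA24 = scale_definition("PRCA24", 24, 120, "decrease"),
    SPIC   = scale_definition("SPIC",   15, 105, "increase"),
    STAI   = scale_definition("STAI",    8,  32, "increase")
  )
}

#' Scale registry as a data frame
#'
#' Machine-readable export of [builtin_scales()] (one row per scale), for
#' writing alongside analysis artifacts.
#'
#' @param path Optional file path; when given, the registry is also written
#'   as CSV.
#' @return A data frame with columns `name`, `xmin`, `xmax`, `direction`.
#' @export
scale_registry <- function(path = NULL) {
  reg <- do.call(rbind, lapply(builtin_scales(), function(s) {
    data.frame(name = s$name, xmin = s$xmin, xmax = s$xmax,
               direction = s$improvement_direction,
               stringsAsFactors = FALSE)
  }))
  rownames(reg) <- NULL
  if (!is.null(path)) utils::write.csv(reg, path, row.names = FALSE)
  reg
}

#' Conditioning anchors of a scale
#'
#' The three covariate values at which conditional posterior distributions
#' and improvement probabilities are evaluated: 10% of the range above the
#' minimum, the midpoint, and 10% of the range below the maximum. With
#' `d = xmax - xmin` these are `xmin + 0.1 d`, `(xmin + xmax) / 2`, and
#' `xmax - 0.1 d`.
#'
#' @param scale A [scale_definition()].
#' @return Named numeric vector `c(lowest, middle, highest)`.
#' @examples
#' anchor_values(builtin_scales()$PRCA24)  # 33.6, 72, 110.4
#' @export
anchor_values <- function(scale) {
  stopifnot(inherits(scale, "scale_definition"))
  d <- scale$xmax - scale$xmin
  c(lowest  = scale$xmin + 0.1 * d,
    middle  = (scale$xmin + scale$xmax) / 2,
    highest = scale$xmax - 0.1 * d)
}

#' Map a bounded score to the open unit interval
#'
#' Affine map of `y` from `[xmin, xmax]` onto `[0, 1]`, optionally followed
#' by the Smithson-Verkuilen boundary compression
#' `u' = (u (n - 1) + 0.5) / n`, which pulls both endpoints strictly inside
#' `(0, 1)` so the value can serve as a Beta-distributed response. The
#' compression is applied whenever `n_obs` is given (not only at the
#' boundaries), keeping the map continuous and strictly increasing.
#'
#' @param y Numeric scores within the scale bounds.
#' @param scale A [scale_definition()].
#' @param n_obs Number of observations used for the boundary compression,
#'   or `NULL` for the plain affine map.
#' @return Values in `[0, 1]` (strictly inside `(0, 1)` when `n_obs` is
#'   given).
#' @seealso [denormalize_bounded()] for the inverse.
#' @examples
#' normalize_bounded(0, builtin_scales()$IAT)           # 0.5
#' normalize_bounded(2, builtin_scales()$IAT, n_obs = 45)
#' @export
normalize_bounded <- function(y, scale, n_obs = NULL) {
  stopifnot(inherits(scale, "scale_definition"))
  bad <- !is.na(y) & (y < scale$xmin | y > scale$xmax)
  if (any(bad)) {
    stop(sprintf("score(s) outside [%g, %g] for scale %s: %s",
                 scale$xmin, scale$xmax, scale$name,
                 paste(utils::head(y[bad], 5L), collapse = ", ")))
  }
  u <- (y - scale$xmin) / (scale$xmax - scale$xmin)
  if (!is.null(n_obs)) {
    stopifnot(n_obs >= 1)
    u <- (u * (n_obs - 1) + 0.5) / n_obs
  }
  u
}

#' Inverse of [normalize_bounded()]
#'
#' Undoes the boundary compression (when `n_obs` is given) and the affine
#' map. Values whose decompressed image falls outside `[0, 1]` (possible
#' for inputs very close to 0 or 1, since the compression is a strict
#' contraction) are clipped to the scale bounds.
#'
#' @param u Unit-interval values.
#' @param scale A [scale_definition()].
#' @param n_obs Same value used when normalizing, or `NULL`.
#' @return Scores on the original scale, inside `[xmin, xmax]`.
#' @export
denormalize_bounded <- function(u, scale, n_obs = NULL) {
  stopifnot(inherits(scale, "scale_definition"))
  if (!is.null(n_obs)) {
    stopifnot(n_obs >= 1)
    u <- (u * n_obs - 0.5) / (n_obs - 1)
  }
  y <- scale$xmin + u * (scale$xmax - scale$xmin)
  pmin(pmax(y, scale$xmin), scale$xmax)
}

# Column layout of a trial dataset (wide, one row per participant).
# postSTAI has no paired pre column: the short-form STAI was only
# administered before the test speech.
trial_columns <- function() {
  c("participant_id", "condition", "familiarity",
    "preIAT", "postIAT", "prePRCA24", "postPRCA24",
    "preSPIC", "postSPIC", "afterSPIC", "postSTAI")
}

condition_levels <- function() c("control", "multiple", "single")

# Map a score column name to its scale definition.
column_scale <- function(column) {
  scales <- builtin_scales()
  switch(column,
         preIAT = , postIAT = scales$IAT,
         prePRCA24 = , postPRCA24 = scales$PRCA24,
         preSPIC = , postSPIC = , afterSPIC = scales$SPIC,
         postSTAI = scales$STAI,
         stop("no scale registered for column ", column))
}

score_columns <- function() setdiff(trial_columns(),
                                    c("participant_id", "condition",
                                      "familiarity"))

#' Construct and validate a trial dataset
#'
#' Wraps a wide per-participant data frame (one row per participant,
#' columns `participant_id`, `condition`, `familiarity`, and the
#' pre/post/after score columns) after checking that every score lies
#' within its scale bounds, conditions come from
#' `control`/`multiple`/`single`, and familiarity is an integer in 1..5.
#' Violations are reported with their row index.
#'
#' @param df A data frame with the columns of `trial_columns()`.
#' @return The validated data frame with class `trial_dataset` prepended.
#' @export
trial_dataset <- function(df) {
  missing_cols <- setdiff(trial_columns(), names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- df[, trial_columns()]
  df$condition <- as.character(df$condition)
  bad_cond <- which(!df$condition %in% condition_levels())
  if (length(bad_cond)) {
    stop(sprintf("unknown condition label '%s' in row %d",
                 df$condition[bad_cond[1L]], bad_cond[1L]))
  }
  bad_fam <- which(!is.na(df$familiarity) &
                     (df$familiarity < 1 | df$familiarity > 5 |
                        df$familiarity != round(df$familiarity)))
  if (length(bad_fam)) {
    stop("familiarity must be an integer in 1..5; bad row(s): ",
         paste(utils::head(bad_fam, 5L), collapse = ", "))
  }
  for (col in score_columns()) {
    sc <- column_scale(col)
    v <- df[[col]]
    bad <- which(!is.na(v) & (v < sc$xmin | v > sc$xmax))
    if (length(bad)) {
      stop(sprintf("%s out of range [%g, %g] in row(s): %s",
                   col, sc$xmin, sc$xmax,
                   paste(utils::head(bad, 5L), collapse = ", ")))
    }
  }
  class(df) <- c("trial_dataset", "data.frame")
  df
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat(sprintf("<trial_dataset: %d participants (%s)>\n", nrow(x),
              paste(sprintf("%s n=%d", condition_levels(),
                            tabulate(factor(x$condition,
                                            condition_levels()), 3L)),
                    collapse = ", ")))
  print(as.data.frame(utils::head(x, 6L)))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Read a trial dataset from CSV
#'
#' Comma-delimited, UTF-8, header required; one row per participant (wide
#' format). The same validation as [trial_dataset()] is applied, so bad
#' condition labels or out-of-range scores fail with the offending row
#' index.
#'
#' @param path Path to a CSV file.
#' @return A `trial_dataset`.
#' @export
read_trial_dataset <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                        comment.char = "#")
  df$participant_id <- as.character(df$participant_id)
  if ("familiarity" %in% names(df)) df$familiarity <- as.integer(df$familiarity)
  for (col in intersect(score_columns(), names(df))) {
    df[[col]] <- as.double(df[[col]])
  }
  trial_dataset(df)
}

#' Write a trial dataset to CSV
#'
#' Inverse of [read_trial_dataset()]: `read_trial_dataset(write_trial_dataset(d, f))`
#' reproduces `d` exactly.
#'
#' @param dataset A `trial_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "trial_dataset"))
  out <- as.data.frame(dataset)
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      # 17 significant digits round-trip an IEEE double exactly
      v <- sprintf("%.17g", out[[col]])
      v[is.na(out[[col]])] <- NA
      out[[col]] <- v
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
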