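# Descriptive effect-size layer: change-score means/SEs per condition,
# paired Cohen d within condition, and between-condition Cohen d on the
# change scores.

#' Paired Cohen d on pre/post scores
#'
#' Default is the change-score standardization `d_z = mean(post - pre) /
#' SD(post - pre)` (sample SD, n - 1 denominator), the usual choice for
#' pre-post designs. `method = "dav"` standardizes by the average of the
#' pre and post SDs instead; the two can differ substantially when pre and
#' post are strongly correlated and should never be mixed within a table.
#'
#' @param pre,post Equal-length paired score vectors (length >= 2).
#' @param method `"dz"` (change-score SD) or `"dav"` (average SD).
#' @return Cohen d; `NA` with a warning when the standardizer is zero.
#' @examples
#' cohen_d_paired(c(0, 0, 0), c(1, 2, 3))  # 2
#' @export
cohen_d_paired <- function(pre, post, method = c("dz", "dav")) {
  method <- match.arg(method)
  stopifnot(length(pre) == length(post), length(pre) >= 2L)
  d <- post - pre
  if (all(d == 0)) return(0)  # no change at all: d is 0, not 0/0
  s <- if (method == "dz") stats::sd(d)
       else (stats::sd(pre) + stats::sd(post)) / 2
  if (!is.finite(s) || s == 0) {
    warning("zero change-score SD: paired Cohen d undefined")
    return(NA_real_)
  }
  mean(d) / s
}

#' Between-group Cohen d
#'
#' `(mean(a) - mean(b)) / s_p` with the pooled SD
#' `s_p = sqrt(((n_a - 1) s_a^2 + (n_b - 1) s_b^2) / (n_a + n_b - 2))`.
#' Antisymmetric in its arguments. No small-sample (Hedges) correction is
#' applied.
#'
#' @param a,b Numeric vectors (each length >= 2), e.g. per-arm change
#'   scores.
#' @return Cohen d; `NA` with a warning when the pooled SD is zero.
#' @export
cohen_d_between <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  na <- length(a); nb <- length(b)
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
               (na + nb - 2))
  if (!is.finite(sp) || sp == 0) {
    warning("zero pooled SD: between-group Cohen d undefined")
    return(NA_real_)
  }
  (mean(a) - mean(b)) / sp
}

#' Between-group Cohen d from summary statistics
#'
#' Reconstructs each group SD as `s = se * sqrt(n)` and proceeds as
#' [cohen_d_between()]. Applied to exact group summaries this equals the
#' raw-vector computation to machine precision; applied to published
#' rounded summaries it reproduces published d values only to the
#' precision the rounding allows.
#'
#' @param mean_a,mean_b Group means of the change scores.
#' @param se_a,se_b Standard errors of the group means (positive).
#' @param n_a,n_b Group sizes (>= 2).
#' @return Cohen d.
#' @examples
#' cohen_d_from_summary(0.35, 0.15, 16, -0.10, 0.20, 15)
#' @export
cohen_d_from_summary <- function(mean_a, se_a, n_a, mean_b, se_b, n_b) {
  stopifnot(se_a > 0, se_b > 0, n_a >= 2L, n_b >= 2L)
  sa <- se_a * sqrt(n_a); sb <- se_b * sqrt(n_b)
  sp <- sqrt(((n_a - 1) * sa^2 + (n_b - 1) * sb^2) / (n_a + n_b - 2))
  (mean_a - mean_b) / sp
}

# Change scores per outcome. postSTAI has no pre measure: its descriptive
# column is the post score itself (between-condition d is computed on the
# post scores).
change_scores <- function(dataset, outcome) {
  d <- as.data.frame(dataset)
  switch(outcome,
         postIAT    = d$postIAT - d$preIAT,
         postPRCA24 = d$postPRCA24 - d$prePRCA24,
         postSPIC   = d$postSPIC - d$preSPIC,
         afterSPIC  = d$afterSPIC - d$preSPIC,
         postSTAI   = d$postSTAI,
         stop("unknown outcome: ", outcome))
}

#' Descriptive effect-size table
#'
#' For each outcome and condition: the change-score mean, its standard
#' error, and the paired Cohen d; plus between-condition Cohen d on the
#' change scores for the three arm contrasts. The no-pre outcome
#' (`postSTAI`) contributes its post scores in place of change scores and
#' has no paired d.
#'
#' @param dataset A `trial_dataset`.
#' @param paired_method Passed to [cohen_d_paired()].
#' @return An `effect_size_table`: list of data frames `per_condition`
#'   and `between`.
#' @export
effect_size_table <- function(dataset, paired_method = "dz") {
  stopifnot(inherits(dataset, "trial_dataset"))
  outcomes <- c("postIAT", "postPRCA24", "postSPIC", "afterSPIC", "postSTAI")
  d <- as.data.frame(dataset)
  per <- list(); btw <- list()
  for (out in outcomes) {
    ch <- change_scores(dataset, out)
    for (j in condition_levels()) {
      v <- ch[d$condition == j]
      v <- v[!is.na(v)]
      paired <- if (out == "postSTAI") NA_real_ else {
        pre <- switch(out, postIAT = d$preIAT, postPRCA24 = d$prePRCA24,
                      d$preSPIC)[d$condition == j]
        post <- d[[out]][d$condition == j]
        ok <- !is.na(pre) & !is.na(post)
        cohen_d_paired(pre[ok], post[ok], method = paired_method)
      }
      per[[length(per) + 1L]] <- data.frame(
        outcome = out, condition = j, n = length(v), change_mean = mean(v),
        change_se = stats::sd(v) / sqrt(length(v)), cohen_d_paired = paired,
        stringsAsFactors = FALSE)
    }
    pairs <- rbind(c("single", "multiple"), c("single", "control"),
                   c("multiple", "control"))
    for (i in seq_len(nrow(pairs))) {
      a <- ch[d$condition == pairs[i, 1L]]; a <- a[!is.na(a)]
      b <- ch[d$condition == pairs[i, 2L]]; b <- b[!is.na(b)]
      btw[[length(btw) + 1L]] <- data.frame(
        outcome = out, comparison = paste(pairs[i, 1L], "vs", pairs[i, 2L]),
        cohen_d = cohen_d_between(a, b), stringsAsFactors = FALSE)
    }
  }
  structure(list(per_condition = do.call(rbind, per),
                 between = do.call(rbind, btw),
                 paired_method = paired_method),
            class = "effect_size_table")
}

#' @export
print.effect_size_table <- function(x, ...) {
  cat("Change scores by condition (paired d:", x$paired_method, ")\n")
  print(x$per_condition, row.names = FALSE, digits = 3)
  cat("\nBetween-condition Cohen d on change scores\n")
  print(x$between, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write an effect-size table to CSV
#'
#' @param table An `effect_size_table`.
#' @param path_per_condition,path_between Output paths.
#' @return Invisibly, the two paths.
#' @export
write_effect_size_table <- function(table, path_per_condition, path_between) {
  stopifnot(inherits(table, "effect_size_table"))
  utils::write.csv(table$per_condition, path_per_condition, row.names = FALSE)
  utils::write.csv(table$between, path_between, row.names = FALSE)
  invisible(c(path_per_condition, path_between))
}
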