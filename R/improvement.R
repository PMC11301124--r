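# Headline derived quantities: conditional posterior distributions of the
# outcome mean at scale anchors, probabilities of improvement, odds of
# improvement between arms, and slope-exceedance probabilities.

# Pooled draw matrix (all chains stacked) with fixed parameters appended
# as constant columns.
draw_matrix <- function(fit) {
  dm <- dim(fit$draws)
  m <- matrix(fit$draws, nrow = dm[1L] * dm[2L], ncol = dm[3L])
  colnames(m) <- fit$parameters
  if (length(fit$fixed)) {
    fx <- matrix(rep(fit$fixed, each = nrow(m)), nrow = nrow(m))
    colnames(fx) <- names(fit$fixed)
    m <- cbind(m, fx)
  }
  m
}

#' Posterior draws of the conditional outcome mean
#'
#' For every posterior draw, evaluates the linear predictor at one
#' condition, one pre-score value, and one familiarity value, then maps it
#' through the likelihood's link. For the Beta/logit outcome the pre value
#' is normalized (with the fitted dataset's boundary squeeze) before
#' entering the predictor and the mean is mapped back to the raw score
#' range, so anchors are used directly on the original scale. With
#' `type = "predictive"` a posterior-predictive observation is drawn
#' around each mean instead (off by default; the improvement probabilities
#' of the primary analysis are defined on the posterior of the mean).
#'
#' @param fit A `bancova_fit`.
#' @param condition One of `"control"`, `"multiple"`, `"single"`.
#' @param pre_value Pre-score conditioning value within the covariate's
#'   scale; must be omitted for the no-covariate outcome (`postSTAI`).
#' @param familiarity Familiarity covariate value in 1..5 (default 3, the
#'   reported median); ignored when the model does not use familiarity.
#' @param type `"mean"` (default) or `"predictive"`.
#' @return Numeric vector with one outcome-scale value per posterior draw.
#' @export
conditional_mu_draws <- function(fit, condition, pre_value = NULL,
                                 familiarity = 3, type = c("mean", "predictive")) {
  stopifnot(inherits(fit, "bancova_fit"), length(condition) == 1L)
  type <- match.arg(type)
  spec <- fit$spec
  if (!condition %in% condition_levels()) {
    stop("unknown condition label: ", condition)
  }
  if (has_covariate(spec) && is.null(pre_value)) {
    stop(spec$outcome, " conditions on a pre score; supply pre_value")
  }
  if (!has_covariate(spec) && !is.null(pre_value)) {
    stop(spec$outcome, " has no pre covariate; pre_value must be omitted")
  }
  if (!is.null(familiarity) && (familiarity < 1 || familiarity > 5)) {
    stop("familiarity must lie in 1..5")
  }
  sc <- builtin_scales()[[spec$scale_name]]
  cov_val <- NULL
  if (has_covariate(spec)) {
    if (pre_value < sc$xmin || pre_value > sc$xmax) {
      stop(sprintf("pre_value %g outside scale [%g, %g]", pre_value,
                   sc$xmin, sc$xmax))
    }
    cov_val <- if (spec$likelihood == "beta_logit") {
      normalize_bounded(pre_value, sc, n_obs = fit$n_obs)
    } else pre_value
  }
  m <- draw_matrix(fit)
  col <- function(nm) if (nm %in% colnames(m)) m[, nm] else 0
  eta <- col("intercept") +
    switch(condition, control = 0, multiple = col("arm_multiple"),
           single = col("arm_single"))
  if (!is.null(cov_val)) {
    gam <- switch(condition, control = 0,
                  multiple = col("slope_multiple"),
                  single = col("slope_single"))
    eta <- eta + (col("slope") + gam) * cov_val
  }
  if (spec$uses_familiarity) eta <- eta + col("familiarity") * familiarity
  if (spec$likelihood == "beta_logit") {
    mu <- stats::plogis(eta)
    if (type == "predictive") {
      mu <- stats::rbeta(length(mu), col("phi") * mu, col("phi") * (1 - mu))
    }
    denormalize_bounded(mu, sc, n_obs = fit$n_obs)
  } else {
    if (type == "predictive") {
      eta <- eta + col("sigma") *
        if (spec$likelihood == "normal") stats::rnorm(length(eta))
        else stats::rt(length(eta), df = col("nu"))
    }
    eta
  }
}

#' Posterior probability of improvement at an anchor
#'
#' Fraction of conditional-mean draws strictly beyond the anchor in the
#' beneficial direction: `P(post > x | pre = x)` for improvement-by-
#' increase scales and `P(post < x | pre = x)` for improvement-by-decrease
#' scales (PRCA-24).
#'
#' @param mu_draws Draws from [conditional_mu_draws()].
#' @param anchor Conditioning anchor value.
#' @param direction `"increase"` or `"decrease"`.
#' @return Probability in `[0, 1]`.
#' @export
prob_improvement <- function(mu_draws, anchor,
                             direction = c("increase", "decrease")) {
  direction <- match.arg(direction)
  if (!length(mu_draws)) stop("empty draw sample")
  if (direction == "increase") mean(mu_draws > anchor)
  else mean(mu_draws < anchor)
}

#' Odds of improvement between two arms
#'
#' Ratio of two improvement probabilities at the same anchor. A zero
#' denominator yields `Inf` labelled as infinite odds rather than an
#' error.
#'
#' @param p_a,p_b Improvement probabilities; `p_a` is the arm of interest.
#' @return The raw ratio `p_a / p_b` (attribute `"note"` flags infinite
#'   odds). See [format_odds()] for display rounding.
#' @examples
#' odds_of_improvement(0.257, 0.001)  # 257
#' @export
odds_of_improvement <- function(p_a, p_b) {
  stopifnot(p_a >= 0, p_a <= 1, p_b >= 0, p_b <= 1)
  if (p_b == 0) {
    return(structure(Inf, note = "infinite odds: denominator probability is 0"))
  }
  p_a / p_b
}

#' Display rounding for odds
#'
#' Odds at or above 10 are shown as integers; smaller odds with one
#' decimal. Rounding is round-half-to-even; raw ratios should always be
#' kept alongside the display value.
#'
#' @param x Numeric odds.
#' @return Character vector.
#' @examples
#' format_odds(c(257, 489, 27.48, 4.25))
#' @export
format_odds <- function(x) {
  ifelse(is.infinite(x), "Inf",
         ifelse(x >= 10, sprintf("%.0f", round(x)),
                sprintf("%.1f", round(x, 1L))))
}

#' Posterior probability that a condition's slope exceeds a threshold
#'
#' Fraction of posterior draws with `slope + interaction_j > t`; for the
#' control condition the interaction is a structural zero so this is
#' `P(slope > t)`. Only defined for outcomes with a pre covariate.
#'
#' @param fit A `bancova_fit`.
#' @param condition Condition label.
#' @param threshold Exceedance threshold `t` (e.g. 1 for "post grows
#'   faster than pre").
#' @return Probability in `[0, 1]`.
#' @export
slope_exceedance <- function(fit, condition, threshold) {
  stopifnot(inherits(fit, "bancova_fit"))
  if (!has_covariate(fit$spec)) {
    stop(fit$spec$outcome, " has no covariate; slope exceedance undefined")
  }
  if (!condition %in% condition_levels()) {
    stop("unknown condition label: ", condition)
  }
  m <- draw_matrix(fit)
  sl <- m[, "slope"]
  if (condition != "control") sl <- sl + m[, paste0("slope_", condition)]
  mean(sl > threshold)
}

# Anchor subsets actually reported: the improvement-by-decrease scale
# (PRCA-24) is conditioned at middle/highest; improvement-by-increase
# scales at lowest/middle.
reported_anchors <- function(direction) {
  if (direction == "decrease") c("middle", "highest") else c("lowest", "middle")
}

#' Improvement report across outcomes, conditions, and anchors
#'
#' Builds the full grid of improvement probabilities: each outcome at its
#' reported anchor subset (middle/highest with direction "<" for PRCA-24;
#' lowest/middle with ">" for the others; the no-covariate outcome
#' `postSTAI` is evaluated unconditionally against the same anchor
#' thresholds) for the three conditions, plus pairwise odds of improvement
#' (each treated arm vs control and single vs multiple) at every anchor.
#'
#' @param fits Named list of `bancova_fit` objects covering all five
#'   outcomes (`postIAT`, `postPRCA24`, `postSPIC`, `afterSPIC`,
#'   `postSTAI`).
#' @param familiarity Conditioning value for the familiarity covariate
#'   (default 3, the reported median).
#' @return An `improvement_report`: list with data frames `probabilities`
#'   (outcome, condition, anchor, anchor_value, direction, probability)
#'   and `odds` (outcome, anchor, comparison, raw odds, display value).
#' @export
improvement_report <- function(fits, familiarity = 3) {
  outcomes <- c("postIAT", "postPRCA24", "postSPIC", "afterSPIC", "postSTAI")
  missing_f <- setdiff(outcomes, names(fits))
  if (length(missing_f)) {
    stop("missing fit(s) for outcome(s): ", paste(missing_f, collapse = ", "))
  }
  prob_rows <- list(); odds_rows <- list()
  for (out in outcomes) {
    fit <- fits[[out]]
    spec <- fit$spec
    sc <- builtin_scales()[[spec$scale_name]]
    anchors <- anchor_values(sc)
    use <- reported_anchors(sc$improvement_direction)
    for (anc in use) {
      x <- anchors[[anc]]
      p <- vapply(condition_levels(), function(j) {
        mu <- conditional_mu_draws(
          fit, j, pre_value = if (has_covariate(spec)) x else NULL,
          familiarity = if (spec$uses_familiarity) familiarity else NULL)
        prob_improvement(mu, x, sc$improvement_direction)
      }, 0)
      prob_rows[[length(prob_rows) + 1L]] <- data.frame(
        outcome = out, condition = condition_levels(), anchor = anc,
        anchor_value = x, direction = sc$improvement_direction,
        probability = unname(p), stringsAsFactors = FALSE)
      cmp <- rbind(c("multiple", "control"), c("single", "control"),
                   c("single", "multiple"))
      for (i in seq_len(nrow(cmp))) {
        o <- odds_of_improvement(p[[cmp[i, 1L]]], p[[cmp[i, 2L]]])
        odds_rows[[length(odds_rows) + 1L]] <- data.frame(
          outcome = out, anchor = anc,
          comparison = paste(cmp[i, 1L], "vs", cmp[i, 2L]),
          odds = as.numeric(o), display = format_odds(as.numeric(o)),
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(probabilities = do.call(rbind, prob_rows),
                 odds = do.call(rbind, odds_rows),
                 familiarity = familiarity),
            class = "improvement_report")
}

#' @export
print.improvement_report <- function(x, ...) {
  cat("Improvement probabilities (familiarity =", x$familiarity, ")\n")
  tab <- stats::reshape(x$probabilities[, c("outcome", "condition", "anchor",
                                            "probability")],
                        idvar = c("outcome", "condition"),
                        timevar = "anchor", direction = "wide")
  names(tab) <- sub("^probability\\.", "", names(tab))
  print(tab, row.names = FALSE, digits = 3)
  cat("\nOdds of improvement\n")
  print(x$odds[, c("outcome", "anchor", "comparison", "display")],
        row.names = FALSE)
  invisible(x)
}

#' Write an improvement report to CSV
#'
#' @param report An `improvement_report`.
#' @param path_probabilities,path_odds Output paths for the two tables.
#' @return Invisibly, the two paths.
#' @export
write_improvement_report <- function(report, path_probabilities, path_odds) {
  stopifnot(inherits(report, "improvement_report"))
  utils::write.csv(report$probabilities, path_probabilities, row.names = FALSE)
  utils::write.csv(report$odds, path_odds, row.names = FALSE)
  invisible(c(path_probabilities, path_odds))
}

#' Overlay the conditional posterior densities of the three arms
#'
#' Base-graphics density plot of [conditional_mu_draws()] for each
#' condition at one anchor (one panel of the conditional-posterior
#' figure).
#'
#' @param fit A `bancova_fit`.
#' @param pre_value Conditioning pre score (omit for `postSTAI`).
#' @param familiarity Familiarity conditioning value.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the list of per-condition densities.
#' @export
plot_conditional_posteriors <- function(fit, pre_value = NULL,
                                        familiarity = 3, ...) {
  dens <- lapply(condition_levels(), function(j) {
    stats::density(conditional_mu_draws(
      fit, j, pre_value = pre_value,
      familiarity = if (fit$spec$uses_familiarity) familiarity else NULL))
  })
  names(dens) <- condition_levels()
  cols <- c(control = "blue", multiple = "darkgreen", single = "red")
  xr <- range(unlist(lapply(dens, `[[`, "x")))
  yr <- c(0, max(unlist(lapply(dens, `[[`, "y"))))
  graphics::plot(NA, xlim = xr, ylim = yr, xlab = fit$spec$outcome,
                 ylab = "posterior density", ...)
  for (j in condition_levels()) {
    graphics::lines(dens[[j]], col = cols[[j]], lwd = 2)
  }
  graphics::legend("topright", legend = condition_levels(),
                   col = cols, lwd = 2, bty = "n")
  invisible(dens)
}
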