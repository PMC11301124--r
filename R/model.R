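#' Prior specification
#'
#' Weakly informative priors used for every outcome model: all regression
#' coefficients (grand mean, condition effects, slopes, interactions,
#' familiarity effect) get independent normal(0, SD 100) priors, and every
#' positive parameter (Student-t scale `sigma`, degrees of freedom `nu`,
#' Beta precision `phi`) gets a Gamma(shape 2, rate 0.1) prior, whose
#' central 95% interval is (2.4, 55.7). `nu` is treated as continuous with
#' support (1, Inf); its Gamma prior is truncated below 1 and renormalized.
#'
#' @return A list with elements `coef_sd`, `pos_shape`, `pos_rate` and
#'   class `prior_spec`.
#' @export
prior_spec <- function() {
  structure(list(coef_sd = 100, pos_shape = 2, pos_rate = 0.1),
            class = "prior_spec")
}

#' Central credible intervals implied by the priors
#'
#' @param level Probability mass of the central interval.
#' @return For `prior_coef_interval()` the central interval of the
#'   normal(0, 100) coefficient prior; for `prior_positive_interval()` that
#'   of the Gamma(2, 0.1) prior on positive parameters.
#' @export
prior_coef_interval <- function(level = 0.95) {
  p <- prior_spec()
  a <- (1 - level) / 2
  stats::qnorm(c(a, 1 - a), mean = 0, sd = p$coef_sd)
}

#' @rdname prior_coef_interval
#' @export
prior_positive_interval <- function(level = 0.95) {
  p <- prior_spec()
  a <- (1 - level) / 2
  stats::qgamma(c(a, 1 - a), shape = p$pos_shape, rate = p$pos_rate)
}

#' Outcome model specification
#'
#' Each of the five outcomes gets one model: a linear predictor
#' `Condition + Covariate + Covariate:Condition (+ familiarity)` with the
#' control condition as reference (its main effect and interaction are
#' structural zeros), and a likelihood family chosen by the outcome's
#' measurement properties. The bounded IAT score uses a Beta likelihood
#' with a logit link on normalized scores; all other outcomes use a
#' location-scale Student-t (identity link). `postSTAI` has no paired pre
#' score, so its predictor reduces to condition main effects plus
#' familiarity. `likelihood = "normal"` is accepted for Student-t outcomes
#' as an explicit validation family (used to check the large-`nu` limit).
#'
#' @param outcome One of `"postIAT"`, `"postPRCA24"`, `"postSPIC"`,
#'   `"afterSPIC"`, `"postSTAI"`.
#' @param likelihood Optional override; only `"normal"` is accepted, and
#'   only for outcomes whose default is `"student_t"`.
#' @return A `model_spec` object.
#' @examples
#' model_spec("postPRCA24")
#' @export
model_spec <- function(outcome = c("postIAT", "postPRCA24", "postSPIC",
                                   "afterSPIC", "postSTAI"),
                       likelihood = NULL) {
  outcome <- match.arg(outcome)
  def <- switch(outcome,
    postIAT    = list(covariate = "preIAT",    fam = FALSE, lik = "beta_logit",
                      scale = "IAT"),
    postPRCA24 = list(covariate = "prePRCA24", fam = FALSE, lik = "student_t",
                      scale = "PRCA24"),
    postSPIC   = list(covariate = "preSPIC",   fam = TRUE,  lik = "student_t",
                      scale = "SPIC"),
    afterSPIC  = list(covariate = "preSPIC",   fam = TRUE,  lik = "student_t",
                      scale = "SPIC"),
    postSTAI   = list(covariate = NA_character_, fam = TRUE, lik = "student_t",
                      scale = "STAI")
  )
  if (!is.null(likelihood)) {
    if (!identical(likelihood, "normal") || def$lik != "student_t") {
      stop("likelihood can only be overridden to 'normal' for Student-t outcomes")
    }
    def$lik <- "normal"
  }
  structure(
    list(outcome = outcome, covariate = def$covariate,
         uses_familiarity = def$fam, likelihood = def$lik,
         scale_name = def$scale, priors = prior_spec()),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec %s: %s likelihood, covariate = %s%s>\n",
              x$outcome, x$likelihood,
              ifelse(is.na(x$covariate), "none", x$covariate),
              if (x$uses_familiarity) ", + familiarity" else ""))
  invisible(x)
}

#' All five outcome model specifications
#'
#' @return Named list of [model_spec()] objects, one per outcome.
#' @export
builtin_model_specs <- function() {
  outs <- c("postIAT", "postPRCA24", "postSPIC", "afterSPIC", "postSTAI")
  stats::setNames(lapply(outs, model_spec), outs)
}

has_covariate <- function(spec) !is.na(spec$covariate)

# Names of the free parameters of a spec, in sampling order.
free_param_names <- function(spec) {
  nm <- c("intercept", "arm_multiple", "arm_single")
  if (has_covariate(spec)) nm <- c(nm, "slope", "slope_multiple", "slope_single")
  if (spec$uses_familiarity) nm <- c(nm, "familiarity")
  nm <- c(nm, switch(spec$likelihood,
                     student_t = c("sigma", "nu"),
                     normal = "sigma",
                     beta_logit = "phi"))
  nm
}

coef_param_names <- function(spec) {
  setdiff(free_param_names(spec), c("sigma", "nu", "phi"))
}

#' Evaluate the linear predictor
#'
#' `eta = intercept + arm_j + slope * c + slope_j * c (+ familiarity * f)`,
#' with the control condition as reference: for `condition = "control"`
#' this reduces to `intercept + slope * c (+ familiarity * f)` because the
#' control main effect and interaction are structural zeros (they are not
#' parameters at all).
#'
#' @param params Named numeric vector; recognized names are `intercept`,
#'   `arm_multiple`, `arm_single`, `slope`, `slope_multiple`,
#'   `slope_single`, `familiarity`.
#' @param condition Character vector of condition labels.
#' @param covariate Numeric pre-score values, or `NULL` when the model has
#'   no covariate.
#' @param familiarity Numeric familiarity values, or `NULL` when unused.
#' @return Numeric vector of linear-predictor values.
#' @examples
#' linear_predictor(c(intercept = 0, slope = 1, slope_single = 0.5),
#'                  "single", covariate = 2)  # 3
#' @export
linear_predictor <- function(params, condition, covariate = NULL,
                             familiarity = NULL) {
  p <- function(nm) if (nm %in% names(params)) params[[nm]] else 0
  if (!all(condition %in% condition_levels())) {
    stop("unknown condition label: ",
         paste(setdiff(condition, condition_levels()), collapse = ", "))
  }
  arm <- c(control = 0, multiple = p("arm_multiple"),
           single = p("arm_single"))[condition]
  eta <- p("intercept") + arm
  if (!is.null(covariate)) {
    gam <- c(control = 0, multiple = p("slope_multiple"),
             single = p("slope_single"))[condition]
    eta <- eta + (p("slope") + gam) * covariate
  }
  if (!is.null(familiarity)) eta <- eta + p("familiarity") * familiarity
  unname(eta)
}

#' Map the linear predictor to the likelihood mean
#'
#' Identity for the Student-t (and normal) families; inverse logit
#' `1 / (1 + exp(-eta))` for the Beta family, so the Beta mean is always
#' strictly inside (0, 1).
#'
#' @param spec A [model_spec()].
#' @param eta Linear-predictor values.
#' @return Means on the likelihood's scale.
#' @export
likelihood_mean <- function(spec, eta) {
  if (spec$likelihood == "beta_logit") stats::plogis(eta) else eta
}

# Extract the modelling frame for one outcome: response, condition,
# covariate, familiarity, with Beta responses/covariates normalized to the
# open unit interval using the full dataset size for the boundary squeeze.
build_model_data <- function(spec, dataset) {
  stopifnot(inherits(spec, "model_spec"), inherits(dataset, "trial_dataset"))
  n_obs <- nrow(dataset)
  need <- c(spec$outcome,
            if (has_covariate(spec)) spec$covariate,
            if (spec$uses_familiarity) "familiarity")
  keep <- stats::complete.cases(as.data.frame(dataset)[, need, drop = FALSE])
  if (!all(keep)) {
    warning(sum(!keep), " incomplete record(s) dropped for ", spec$outcome)
  }
  d <- as.data.frame(dataset)[keep, , drop = FALSE]
  y <- d[[spec$outcome]]
  cov <- if (has_covariate(spec)) d[[spec$covariate]] else NULL
  if (spec$likelihood == "beta_logit") {
    sc <- builtin_scales()[[spec$scale_name]]
    y <- normalize_bounded(y, sc, n_obs = n_obs)
    cov <- normalize_bounded(cov, sc, n_obs = n_obs)
  }
  list(y = y, condition = d$condition, covariate = cov,
       familiarity = if (spec$uses_familiarity) d$familiarity else NULL,
       n_obs = n_obs, n_used = nrow(d))
}

# Per-record log density; returns -Inf entries rather than erroring so the
# sampler can reject invalid proposals.
loglik_vector <- function(spec, params, md) {
  eta <- linear_predictor(params, md$condition, md$covariate, md$familiarity)
  switch(spec$likelihood,
    student_t = {
      sigma <- params[["sigma"]]; nu <- params[["nu"]]
      if (!is.finite(sigma) || sigma <= 0 || !is.finite(nu) || nu <= 1) {
        return(rep(-Inf, length(md$y)))
      }
      stats::dt((md$y - eta) / sigma, df = nu, log = TRUE) - log(sigma)
    },
    normal = {
      sigma <- params[["sigma"]]
      if (!is.finite(sigma) || sigma <= 0) return(rep(-Inf, length(md$y)))
      stats::dnorm(md$y, eta, sigma, log = TRUE)
    },
    beta_logit = {
      phi <- params[["phi"]]
      if (!is.finite(phi) || phi <= 0) return(rep(-Inf, length(md$y)))
      mu <- stats::plogis(eta)
      stats::dbeta(md$y, phi * mu, phi * (1 - mu), log = TRUE)
    }
  )
}

#' Log likelihood of a dataset under one outcome model
#'
#' Sum of per-record log densities: Student-t
#' `y_i ~ t_nu(mu_i, sigma)` (location-scale), or Beta
#' `y_i ~ Beta(phi mu_i, phi (1 - mu_i))` on normalized responses with
#' `mu_i = logit^-1(eta_i)`.
#'
#' @param spec A [model_spec()].
#' @param params Named numeric vector with the coefficients of
#'   [free_params()] plus the family parameters (`sigma`, `nu` or `phi`).
#' @param dataset A `trial_dataset`.
#' @return The scalar log likelihood; an error names the first record whose
#'   density contribution is non-finite.
#' @export
log_likelihood <- function(spec, params, dataset) {
  md <- build_model_data(spec, dataset)
  ll <- loglik_vector(spec, params, md)
  if (any(!is.finite(ll))) {
    stop("non-finite log-density contribution at record ",
         which(!is.finite(ll))[1L], " for outcome ", spec$outcome)
  }
  sum(ll)
}

#' Free parameters of a model specification
#'
#' @param spec A [model_spec()].
#' @return Character vector of free parameter names in sampling order. The
#'   control condition's main effect and interaction never appear: they are
#'   fixed at zero by construction.
#' @export
free_params <- function(spec) free_param_names(spec)

# log of the Gamma(2, 0.1) prior truncated to nu > 1, renormalized.
log_prior_nu <- function(nu, pr) {
  stats::dgamma(nu, pr$pos_shape, rate = pr$pos_rate, log = TRUE) -
    stats::pgamma(1, pr$pos_shape, rate = pr$pos_rate, lower.tail = FALSE,
                  log.p = TRUE)
}

#' Log prior density
#'
#' Independent normal(0, 100) on every coefficient plus Gamma(2, 0.1) on
#' `sigma` / `phi` and a `nu > 1`-truncated Gamma(2, 0.1) on `nu`.
#'
#' @param spec A [model_spec()].
#' @param params Named numeric vector covering [free_params()].
#' @return Scalar log prior density.
#' @export
log_prior <- function(spec, params) {
  pr <- spec$priors
  nm <- free_param_names(spec)
  missing_p <- setdiff(nm, names(params))
  if (length(missing_p)) {
    stop("missing parameter(s): ", paste(missing_p, collapse = ", "))
  }
  lp <- sum(stats::dnorm(unlist(params[coef_param_names(spec)]),
                         0, pr$coef_sd, log = TRUE))
  for (pp in intersect(c("sigma", "phi"), nm)) {
    v <- params[[pp]]
    if (!is.finite(v) || v <= 0) stop(pp, " must be positive")
    lp <- lp + stats::dgamma(v, pr$pos_shape, rate = pr$pos_rate, log = TRUE)
  }
  if ("nu" %in% nm) {
    v <- params[["nu"]]
    if (!is.finite(v) || v <= 1) stop("nu must exceed 1")
    lp <- lp + log_prior_nu(v, pr)
  }
  lp
}
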