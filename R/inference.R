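# Posterior sampling via adaptive random-walk Metropolis over the
# package's own log posterior (log_likelihood + log_prior), with positive
# parameters sampled on an unconstrained scale:
#   sigma, phi -> log(.), nu -> log(nu - 1)
# (log-Jacobian terms included). Proposal covariance is adapted during
# warmup (Haario-style empirical covariance with a global step-size tuned
# toward 0.234 acceptance) and frozen afterwards.

transform_info <- function(par) {
  switch(par,
         sigma = , phi = list(to = log, from = exp, jac = function(z) z),
         nu = list(to = function(x) log(x - 1),
                   from = function(z) 1 + exp(z),
                   jac = function(z) z),
         list(to = identity, from = identity, jac = function(z) 0))
}

# Design matrix for the coefficient part of the linear predictor, columns
# in coef_param_names() order.
coef_design <- function(spec, md) {
  n <- length(md$y)
  im <- as.numeric(md$condition == "multiple")
  is_ <- as.numeric(md$condition == "single")
  X <- cbind(intercept = rep(1, n), arm_multiple = im, arm_single = is_)
  if (has_covariate(spec)) {
    X <- cbind(X, slope = md$covariate, slope_multiple = md$covariate * im,
               slope_single = md$covariate * is_)
  }
  if (spec$uses_familiarity) X <- cbind(X, familiarity = md$familiarity)
  X
}

# Fast unnormalized log posterior on the transformed (z) scale.
make_logpost <- function(spec, md, fixed = numeric()) {
  all_names <- free_param_names(spec)
  if (length(fixed) && !all(names(fixed) %in% all_names)) {
    stop("unknown fixed parameter(s): ",
         paste(setdiff(names(fixed), all_names), collapse = ", "))
  }
  free <- setdiff(all_names, names(fixed))
  if (!length(free)) stop("no free parameters left to sample")
  coef_names <- coef_param_names(spec)
  fam_names <- setdiff(all_names, coef_names)
  X <- coef_design(spec, md)
  y <- md$y
  pr <- spec$priors
  lg_nu_norm <- stats::pgamma(1, pr$pos_shape, rate = pr$pos_rate,
                              lower.tail = FALSE, log.p = TRUE)
  free_coef <- intersect(free, coef_names)
  free_fam <- intersect(free, fam_names)

  to_natural <- function(z) {
    p <- numeric(length(free))
    names(p) <- free
    for (i in seq_along(free)) p[i] <- transform_info(free[i])$from(z[i])
    p
  }
  from_natural <- function(p) {
    z <- numeric(length(free))
    names(z) <- free
    for (i in seq_along(free)) z[i] <- transform_info(free[i])$to(p[[free[i]]])
    z
  }

  logpost <- function(z) {
    params <- c(to_natural(z), fixed)
    coefs <- params[coef_names]
    eta <- drop(X %*% coefs)
    ll <- switch(spec$likelihood,
      student_t = {
        sigma <- params[["sigma"]]; nu <- params[["nu"]]
        if (sigma <= 0 || nu <= 1) return(-Inf)
        sum(stats::dt((y - eta) / sigma, df = nu, log = TRUE)) -
          length(y) * log(sigma)
      },
      normal = {
        sigma <- params[["sigma"]]
        if (sigma <= 0) return(-Inf)
        sum(stats::dnorm(y, eta, sigma, log = TRUE))
      },
      beta_logit = {
        phi <- params[["phi"]]
        if (phi <= 0) return(-Inf)
        mu <- stats::plogis(eta)
        sum(stats::dbeta(y, phi * mu, phi * (1 - mu), log = TRUE))
      })
    if (!is.finite(ll)) return(-Inf)
    lp <- sum(stats::dnorm(coefs[free_coef], 0, pr$coef_sd, log = TRUE))
    for (fp in free_fam) {
      v <- params[[fp]]
      lp <- lp + if (fp == "nu") {
        stats::dgamma(v, pr$pos_shape, rate = pr$pos_rate, log = TRUE) -
          lg_nu_norm
      } else {
        stats::dgamma(v, pr$pos_shape, rate = pr$pos_rate, log = TRUE)
      }
    }
    jac <- 0
    for (i in seq_along(free)) jac <- jac + transform_info(free[i])$jac(z[i])
    ll + lp + jac
  }

  # Data-driven starting values and rough proposal scales.
  yy <- if (spec$likelihood == "beta_logit") stats::qlogis(y) else y
  ls <- stats::lm.fit(X, yy)
  beta0 <- ls$coefficients
  beta0[is.na(beta0)] <- 0
  rdf <- max(length(y) - ncol(X), 1L)
  s2 <- sum(ls$residuals^2) / rdf
  XtX <- crossprod(X)
  se <- tryCatch(sqrt(pmax(diag(solve(XtX)) * s2, 1e-8)),
                 error = function(e) rep(0.5, ncol(X)))
  names(se) <- colnames(X)
  init_nat <- c(beta0,
                sigma = sqrt(s2), nu = 10,
                phi = max(2, 1 / max(s2 / 2, 1e-4)))[all_names]
  names(init_nat) <- all_names
  init_z <- from_natural(as.list(init_nat[free]))
  scale0 <- c(se * 2, sigma = 0.2, nu = 0.5, phi = 0.3)[free]
  scale0 <- pmax(scale0, 1e-3)

  # Initial proposal covariance: the least-squares coefficient covariance
  # (captures the strong intercept/slope correlation of uncentered
  # ANCOVA designs) plus fixed variances for the transformed family
  # parameters; refined by Haario adaptation during warmup.
  S0 <- diag(scale0^2, length(free))
  dimnames(S0) <- list(free, free)
  V <- tryCatch(solve(XtX) * s2, error = function(e) NULL)
  if (!is.null(V)) {
    dimnames(V) <- list(colnames(X), colnames(X))
    fc <- intersect(free, colnames(X))
    S0[fc, fc] <- V[fc, fc] + diag(1e-8, length(fc))
  }
  fam_var <- c(sigma = 0.04, nu = 0.25, phi = 0.09)
  for (fp in intersect(free, names(fam_var))) S0[fp, fp] <- fam_var[[fp]]
  prop_L0 <- tryCatch(t(chol(S0)), error = function(e) diag(scale0))

  list(free = free, logpost = logpost, to_natural = to_natural,
       init_z = init_z, scale0 = scale0, prop_L0 = prop_L0)
}

amh_chain <- function(lp, n_warm, n_keep, substeps, seed, jitter = 0.2) {
  set.seed(seed)
  d <- length(lp$init_z)
  z <- lp$init_z + stats::rnorm(d, 0, jitter * lp$scale0)
  f <- lp$logpost(z)
  tries <- 0L
  while (!is.finite(f) && tries < 50L) {
    z <- lp$init_z + stats::rnorm(d, 0, 0.01 * lp$scale0)
    f <- lp$logpost(z)
    tries <- tries + 1L
  }
  if (!is.finite(f)) stop("could not find a finite starting point")

  lam <- 2.38 / sqrt(d)
  mean_z <- numeric(d); M2 <- matrix(0, d, d); cnt <- 0L
  L <- lp$prop_L0
  refresh_L <- function() {
    if (cnt > 5L * d + 20L) {
      S <- M2 / (cnt - 1L)
      S <- S + diag(1e-8 + 1e-6 * mean(diag(S)), d)
      Lnew <- tryCatch(t(chol(S)), error = function(e) NULL)
      if (!is.null(Lnew)) L <<- Lnew
    }
  }
  step <- function(z, f, adapt_t = NULL) {
    prop <- z + lam * drop(L %*% stats::rnorm(d))
    fp <- lp$logpost(prop)
    acc <- is.finite(fp) && log(stats::runif(1)) < fp - f
    if (acc) { z <- prop; f <- fp }
    if (!is.null(adapt_t)) {
      lam <<- lam * exp(adapt_t^(-0.6) * ((if (acc) 1 else 0) - 0.234))
    }
    list(z = z, f = f, acc = acc)
  }

  for (t in seq_len(n_warm)) {
    st <- step(z, f, adapt_t = t)
    z <- st$z; f <- st$f
    cnt <- cnt + 1L
    delta <- z - mean_z
    mean_z <- mean_z + delta / cnt
    M2 <- M2 + outer(delta, z - mean_z)
    if (t %% 50L == 0L) refresh_L()
  }
  refresh_L()

  out <- matrix(NA_real_, n_keep, d)
  n_acc <- 0L
  for (k in seq_len(n_keep)) {
    for (s in seq_len(substeps)) {
      st <- step(z, f)
      z <- st$z; f <- st$f
      n_acc <- n_acc + st$acc
    }
    out[k, ] <- z
  }
  list(draws_z = out, accept = n_acc / (n_keep * substeps))
}

#' Sample the posterior of one outcome model
#'
#' Adaptive random-walk Metropolis on the unconstrained scale, with the
#' proposal covariance adapted during warmup and frozen for the kept
#' draws. Defaults mirror the analysis settings: 4 chains of 3000
#' iterations, half used as warmup. Convergence is certified with the
#' split-chain potential scale reduction statistic; any parameter with
#' Rhat above 1.01 flags the fit as non-converged (with a warning) rather
#' than failing silently.
#'
#' @param spec A [model_spec()].
#' @param dataset A `trial_dataset` containing the model's outcome,
#'   covariate, and (if used) familiarity columns.
#' @param chains Number of chains (at least 2 for diagnostics).
#' @param iter Iterations per chain, including warmup.
#' @param warmup Warmup (adaptation) iterations per chain.
#' @param seed Integer seed; the same seed reproduces the draws exactly.
#' @param fixed Optional named numeric vector of parameters to hold fixed
#'   (excluded from sampling); used for reduced models and for validation
#'   against the grid oracle or the normal-likelihood limit.
#' @param substeps Metropolis updates per kept iteration (post-warmup
#'   thinning at constant output size; raises effective sample size).
#' @return A `bancova_fit` with the draws array (`iteration x chain x
#'   parameter`, natural scale), per-parameter `rhat`, acceptance rates,
#'   and sampler metadata.
#' @export
fit_model <- function(spec, dataset, chains = 4L, iter = 3000L,
                      warmup = floor(iter / 2), seed = 1L,
                      fixed = NULL, substeps = 4L) {
  stopifnot(inherits(spec, "model_spec"), chains >= 1L,
            iter > warmup, warmup >= 10L)
  md <- build_model_data(spec, dataset)
  fixed <- if (is.null(fixed)) numeric() else fixed
  lp <- make_logpost(spec, md, fixed)
  set.seed(as.integer(seed))
  chain_seeds <- sample.int(.Machine$integer.max - 1L, chains)
  n_keep <- iter - warmup
  d <- length(lp$free)
  draws <- array(NA_real_, dim = c(n_keep, chains, d),
                 dimnames = list(NULL, NULL, lp$free))
  accept <- numeric(chains)
  for (ch in seq_len(chains)) {
    res <- amh_chain(lp, warmup, n_keep, substeps, chain_seeds[ch])
    for (j in seq_len(d)) {
      draws[, ch, j] <- transform_info(lp$free[j])$from(res$draws_z[, j])
    }
    accept[ch] <- res$accept
  }
  rh <- apply(draws, 3L, function(m) split_rhat(m))
  converged <- chains >= 2L && all(is.finite(rh)) && all(rh <= 1.01)
  if (chains >= 2L && !converged) {
    warning("possible non-convergence: max Rhat = ",
            sprintf("%.3f", max(rh)), " for ", spec$outcome)
  }
  structure(
    list(spec = spec, draws = draws, parameters = lp$free,
         fixed = fixed, rhat = rh, converged = converged,
         accept = accept, n_obs = md$n_obs, n_used = md$n_used,
         meta = list(chains = chains, iter = iter, warmup = warmup,
                     seed = as.integer(seed), substeps = substeps)),
    class = "bancova_fit")
}

#' @export
print.bancova_fit <- function(x, ...) {
  cat(sprintf("<bancova_fit %s: %d chains x %d kept draws, %d parameters>\n",
              x$spec$outcome, x$meta$chains, dim(x$draws)[1L],
              length(x$parameters)))
  cat(sprintf("  max Rhat %.3f (%s), mean acceptance %.2f\n",
              max(x$rhat), if (x$converged) "converged" else "FLAGGED",
              mean(x$accept)))
  invisible(x)
}

# Pooled draws for one parameter across chains.
param_draws <- function(fit, par) {
  if (!par %in% fit$parameters) {
    if (par %in% names(fit$fixed)) {
      return(rep(fit$fixed[[par]], dim(fit$draws)[1L] * dim(fit$draws)[2L]))
    }
    stop("unknown parameter: ", par)
  }
  as.vector(fit$draws[, , par])
}

#' Split-chain potential scale reduction (Rhat)
#'
#' Each chain is split in half and the classical between/within variance
#' ratio is computed over the split halves, so poor mixing within a chain
#' is detected as well as disagreement between chains. Values near 1
#' indicate converged, well-mixed chains.
#'
#' @param x A `bancova_fit` (returns the per-parameter vector) or a
#'   numeric matrix of draws with one column per chain.
#' @return Named numeric vector (fit) or scalar (matrix).
#' @export
rhat <- function(x) {
  if (inherits(x, "bancova_fit")) return(x$rhat)
  split_rhat(as.matrix(x))
}

split_rhat <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m)
  if (ncol(m) < 2L) stop("Rhat requires at least 2 chains")
  if (n < 20L) stop("Rhat requires at least 10 post-warmup draws per split")
  half <- floor(n / 2)
  sub <- cbind(m[seq_len(half), , drop = FALSE],
               m[(n - half + 1L):n, , drop = FALSE])
  nn <- nrow(sub); mm <- ncol(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2L, stats::var)
  W <- mean(vars)
  B <- nn * stats::var(means)
  if (W <= 0) return(if (B <= 0) 1 else Inf)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

# Batch-means Monte Carlo standard error of a posterior mean, pooled over
# chains (batch size ~ sqrt of chain length, at least 10).
mcse_mean <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m)
  b <- max(10L, floor(sqrt(n)))
  nb <- floor(n / b)
  if (nb < 2L) stop("too few draws for batch-means MCSE")
  bm <- c(apply(m[seq_len(nb * b), , drop = FALSE], 2L, function(v) {
    colMeans(matrix(v, nrow = b))
  }))
  stats::sd(bm) / sqrt(length(bm))
}

#' Posterior summary table
#'
#' Mean, SD, central 95% interval, and split-Rhat per free parameter,
#' pooling draws across chains.
#'
#' @param fit A `bancova_fit`.
#' @return A data frame with one row per parameter.
#' @export
posterior_summary <- function(fit) {
  stopifnot(inherits(fit, "bancova_fit"))
  rows <- lapply(fit$parameters, function(p) {
    v <- param_draws(fit, p)
    q <- stats::quantile(v, c(0.025, 0.975), names = FALSE)
    data.frame(parameter = p, mean = mean(v), sd = stats::sd(v),
               q2.5 = q[1L], q97.5 = q[2L], rhat = unname(fit$rhat[p]),
               mcse = mcse_mean(fit$draws[, , p]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
as.data.frame.bancova_fit <- function(x, ...) {
  dm <- dim(x$draws)
  long <- expand.grid(iteration = seq_len(dm[1L]), chain = seq_len(dm[2L]),
                      parameter = x$parameters, stringsAsFactors = FALSE)
  long$value <- as.vector(x$draws)
  long[, c("chain", "iteration", "parameter", "value")]
}

#' Export posterior draws to CSV (long format)
#'
#' @param fit A `bancova_fit`.
#' @param path Output path; columns `chain`, `iteration`, `parameter`,
#'   `value`.
#' @return `path`, invisibly.
#' @export
export_draws <- function(fit, path) {
  utils::write.csv(as.data.frame(fit), path, row.names = FALSE)
  invisible(path)
}

#' Brute-force grid posterior for reduced models
#'
#' Independent verification oracle for the sampler: every parameter except
#' at most three is held fixed, the joint posterior density is evaluated on
#' a dense tensor grid through the public [log_likelihood()] +
#' [log_prior()] functions (a code path separate from the sampler's), and
#' normalized by trapezoidal quadrature. If more than 0.1% of the
#' posterior mass sits in the outermost grid slices of any dimension the
#' grid is reported as too narrow.
#'
#' @param spec A [model_spec()].
#' @param dataset A `trial_dataset`.
#' @param free Named list of grid vectors (1 to 3 parameters, each an
#'   equally spaced increasing grid).
#' @param fixed Named numeric vector fixing every other free parameter of
#'   the model specification.
#' @return A `grid_posterior` object with the normalized density array and
#'   marginal summaries.
#' @export
grid_posterior <- function(spec, dataset, free, fixed) {
  stopifnot(inherits(spec, "model_spec"), length(free) >= 1L,
            length(free) <= 3L)
  all_names <- free_param_names(spec)
  if (!setequal(c(names(free), names(fixed)), all_names)) {
    stop("free + fixed must cover exactly the model's free parameters (",
         paste(all_names, collapse = ", "), ")")
  }
  md <- build_model_data(spec, dataset)
  grid_df <- expand.grid(free, KEEP.OUT.ATTRS = FALSE)
  lp <- apply(grid_df, 1L, function(row) {
    params <- c(as.numeric(row), fixed)
    names(params) <- c(names(free), names(fixed))
    sum(loglik_vector(spec, params, md)) + log_prior(spec, params)
  })
  dens <- exp(lp - max(lp))
  dims <- vapply(free, length, 1L)
  arr <- array(dens, dim = dims)
  # trapezoid weights per dimension
  wts <- lapply(free, function(g) {
    w <- rep(diff(g)[1L], length(g)); w[c(1L, length(g))] <- w[1L] / 2; w
  })
  warr <- Reduce(function(a, b) outer(a, b), wts)
  warr <- array(warr, dim = dims)
  Z <- sum(arr * warr)
  post <- arr * warr / Z
  # edge-mass check per dimension
  for (k in seq_along(free)) {
    idx_lo <- slice.index(post, k) == 1L
    idx_hi <- slice.index(post, k) == dims[k]
    edge <- sum(post[idx_lo]) + sum(post[idx_hi])
    if (edge > 1e-3) {
      warning(sprintf("grid for '%s' may be too narrow: %.2g%% of mass on the edges",
                      names(free)[k], 100 * edge))
    }
  }
  marg <- lapply(seq_along(free), function(k) {
    mk <- apply(post, k, sum)
    mk / sum(mk)
  })
  names(marg) <- names(free)
  means <- vapply(seq_along(free),
                  function(k) sum(free[[k]] * marg[[k]]), 0)
  sds <- vapply(seq_along(free), function(k) {
    sqrt(sum((free[[k]] - means[k])^2 * marg[[k]]))
  }, 0)
  structure(list(free = free, fixed = fixed, density = post,
                 marginals = marg,
                 marginal_mean = stats::setNames(means, names(free)),
                 marginal_sd = stats::setNames(sds, names(free))),
            class = "grid_posterior")
}

#' Marginal quantile from a grid posterior
#'
#' @param grid A `grid_posterior`.
#' @param par Parameter name.
#' @param probs Quantile probabilities.
#' @return Numeric quantiles interpolated from the weighted marginal CDF.
#' @export
grid_quantile <- function(grid, par, probs = c(0.025, 0.975)) {
  stopifnot(inherits(grid, "grid_posterior"), par %in% names(grid$free))
  g <- grid$free[[par]]
  cdf <- cumsum(grid$marginals[[par]])
  vapply(probs, function(p) {
    i <- which(cdf >= p)[1L]
    if (is.na(i)) g[length(g)] else g[i]
  }, 0)
}

#' @export
print.grid_posterior <- function(x, ...) {
  cat("<grid_posterior over", paste(names(x$free), collapse = ", "), ">\n")
  print(data.frame(parameter = names(x$free), mean = x$marginal_mean,
                   sd = x$marginal_sd, row.names = NULL))
  invisible(x)
}
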