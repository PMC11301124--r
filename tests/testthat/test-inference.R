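test_that("split-Rhat is calibrated on mixed and broken chains", {
  set.seed(401)
  iid <- matrix(rnorm(4000), ncol = 4)
  expect_gt(rhat(iid), 0.999)
  expect_lt(rhat(iid), 1.01)
  broken <- iid + rep(c(0, 0, 0, 10), each = 1000)
  expect_gt(rhat(broken), 1.1)
  # a within-chain trend is caught by the split (stationarity check)
  trending <- matrix(rnorm(4000), ncol = 4) + seq(0, 3, length.out = 1000)
  expect_gt(rhat(trending), 1.1)
  expect_error(rhat(matrix(rnorm(100), ncol = 1)), "2 chains")
  expect_error(rhat(matrix(rnorm(8), ncol = 2)), "10")
  # permuting exchangeable draws within a chain barely moves split-Rhat
  perm <- apply(iid, 2, sample)
  expect_lt(abs(rhat(perm) - rhat(iid)), 0.01)
})

test_that("sampling is deterministic given a seed", {
  d <- paperlike_data()
  spec <- model_spec("postSTAI")
  f1 <- suppressWarnings(fit_model(spec, d, chains = 2, iter = 300,
                                   warmup = 150, substeps = 1, seed = 7))
  f2 <- suppressWarnings(fit_model(spec, d, chains = 2, iter = 300,
                                   warmup = 150, substeps = 1, seed = 7))
  expect_identical(f1$draws, f2$draws)
  f3 <- suppressWarnings(fit_model(spec, d, chains = 2, iter = 300,
                                   warmup = 150, substeps = 1, seed = 8))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("posterior draws respect support constraints and carry diagnostics", {
  f <- quick_fit("postPRCA24")
  expect_true(all(f$draws[, , "sigma"] > 0))
  expect_true(all(f$draws[, , "nu"] > 1))
  expect_true(all(is.finite(rhat(f))))
  expect_named(rhat(f)[1:2], c("intercept", "arm_multiple"))
  fb <- quick_fit("postIAT")
  expect_true(all(fb$draws[, , "phi"] > 0))
  s <- posterior_summary(f)
  expect_equal(s$parameter, free_params(f$spec))
  expect_true(all(s$q2.5 < s$q97.5))
})

test_that("posterior intervals are far narrower than the priors at study size", {
  prior_coef_width <- diff(prior_coef_interval())
  prior_pos_width <- diff(prior_positive_interval())
  for (out in c("postPRCA24", "postSPIC")) {
    s <- posterior_summary(quick_fit(out))
    w <- s$q97.5 - s$q2.5
    coef_rows <- !s$parameter %in% c("sigma", "nu", "phi")
    expect_true(all(w[coef_rows] < prior_coef_width / 2))
    expect_true(all(w[s$parameter == "sigma"] < prior_pos_width / 2))
  }
})

test_that("long-format draw export round-trips", {
  f <- quick_fit("postSTAI")
  long <- as.data.frame(f)
  expect_equal(names(long), c("chain", "iteration", "parameter", "value"))
  expect_equal(nrow(long), prod(dim(f$draws)))
  path <- withr::local_tempfile(fileext = ".csv")
  export_draws(f, path)
  back <- utils::read.csv(path)
  expect_equal(back$value, long$value)
})

test_that("the grid posterior is symmetric for symmetric data", {
  # mirror-image responses around the scale midpoint, slope and condition
  # effects fixed at zero: the intercept posterior is symmetric about 72
  n <- 16L
  half <- 72 + c(2, 5, 9, 14, 3, 7, 11, 1)
  df <- data.frame(
    participant_id = sprintf("p%02d", 1:n),
    condition = rep("control", n), familiarity = 3L,
    preIAT = 0, postIAT = 0, prePRCA24 = 72,
    postPRCA24 = c(half, 144 - half), preSPIC = 60, postSPIC = 60,
    afterSPIC = 60, postSTAI = 20)
  g <- grid_posterior(model_spec("postPRCA24"), trial_dataset(df),
                      free = list(intercept = seq(52, 92, length.out = 201)),
                      fixed = c(arm_multiple = 0, arm_single = 0, slope = 0,
                                slope_multiple = 0, slope_single = 0,
                                sigma = 8, nu = 30))
  step <- diff(g$free$intercept)[1]
  expect_lt(abs(g$marginal_mean[["intercept"]] - 72), step)
})

test_that("grid refinement has converged on the test fixture", {
  d <- cached("grid_data30", generate_trial(
    null_config(c(control = 10L, multiple = 10L, single = 10L)), seed = 9))
  spec <- model_spec("postPRCA24")
  fixed <- c(arm_multiple = 0, arm_single = 0, slope_multiple = 0,
             slope_single = 0, intercept = 0, sigma = 8, nu = 30)
  free1 <- list(slope = seq(0.8, 1.2, length.out = 201))
  free2 <- list(slope = seq(0.8, 1.2, length.out = 401))
  g1 <- grid_posterior(spec, d, free = free1, fixed = fixed)
  g2 <- grid_posterior(spec, d, free = free2, fixed = fixed)
  expect_lt(abs(g1$marginal_mean[["slope"]] - g2$marginal_mean[["slope"]]),
            1e-3)
  expect_equal(sum(g1$density), 1, tolerance = 1e-9)
  q <- grid_quantile(g1, "slope", c(0.025, 0.5, 0.975))
  expect_true(all(diff(q) > 0))
})

test_that("a grid that misses posterior mass is reported", {
  d <- cached("grid_data30", generate_trial(
    null_config(c(control = 10L, multiple = 10L, single = 10L)), seed = 9))
  expect_warning(
    grid_posterior(model_spec("postPRCA24"), d,
                   free = list(slope = seq(1.05, 1.2, length.out = 41)),
                   fixed = c(arm_multiple = 0, arm_single = 0,
                             slope_multiple = 0, slope_single = 0,
                             intercept = 0, sigma = 8, nu = 30)),
    "too narrow")
})

test_that("an independent Gibbs sampler reproduces the posterior", {
  d <- paperlike_data()
  f <- quick_fit("postPRCA24")
  md <- as.data.frame(d)
  jm <- rjags::jags.model(textConnection("
    model {
      for (i in 1:N) {
        mu[i] <- b0 + a2 * m[i] + a3 * s[i] +
                 (b1 + g2 * m[i] + g3 * s[i]) * x[i]
        y[i] ~ dt(mu[i], tau, nu)
      }
      b0 ~ dnorm(0, 1e-4); a2 ~ dnorm(0, 1e-4); a3 ~ dnorm(0, 1e-4)
      b1 ~ dnorm(0, 1e-4); g2 ~ dnorm(0, 1e-4); g3 ~ dnorm(0, 1e-4)
      sigma ~ dgamma(2, 0.1); tau <- pow(sigma, -2)
      nu ~ dgamma(2, 0.1) T(1,)
    }"),
    data = list(N = nrow(md), y = md$postPRCA24, x = md$prePRCA24,
                m = as.numeric(md$condition == "multiple"),
                s = as.numeric(md$condition == "single")),
    inits = list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = 33),
    n.chains = 1, n.adapt = 1000, quiet = TRUE)
  sm <- rjags::coda.samples(jm, c("a3", "b1", "g3", "sigma"), n.iter = 6000)
  jags_mean <- colMeans(as.matrix(sm[[1]]))
  ours <- posterior_summary(f)
  for (pair in list(c("arm_single", "a3"), c("slope", "b1"),
                    c("slope_single", "g3"), c("sigma", "sigma"))) {
    row <- ours[ours$parameter == pair[1], ]
    expect_lt(abs(row$mean - jags_mean[[pair[2]]]),
              0.5 * row$sd + 4 * row$mcse)
  }
})
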