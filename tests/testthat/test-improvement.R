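test_that("improvement probability follows the beneficial direction", {
  set.seed(501)
  x <- 50
  draws <- rnorm(20000, mean = x, sd = 3)
  expect_equal(prob_improvement(draws, x, "increase"), 0.5, tolerance = 0.02)
  expect_equal(prob_improvement(draws, x, "decrease"), 0.5, tolerance = 0.02)
  expect_equal(prob_improvement(x + abs(rnorm(100)) + 0.1, x, "increase"), 1)
  # one-SD shift: closed-form normal tail as oracle
  shifted <- rnorm(50000, mean = x + 3, sd = 3)
  expect_equal(prob_improvement(shifted, x, "increase"), pnorm(1),
               tolerance = 0.01)
  expect_error(prob_improvement(numeric(0), x, "increase"), "empty")
  # monotone: shifting draws upward cannot decrease an increase-probability
  for (rep in 1:10) {
    dr <- rnorm(500, x, 5)
    expect_gte(prob_improvement(dr + abs(rnorm(1)), x, "increase"),
               prob_improvement(dr, x, "increase"))
  }
})

test_that("odds of improvement reproduce ratio arithmetic", {
  expect_equal(odds_of_improvement(0.257, 0.001), 257)
  expect_equal(odds_of_improvement(0.978, 0.002), 489)
  for (p in c(0.001, 0.3, 1)) expect_equal(odds_of_improvement(p, p), 1)
  # transitivity to machine precision
  pa <- 0.63; pb <- 0.21; pc <- 0.042
  expect_equal(odds_of_improvement(pa, pb) * odds_of_improvement(pb, pc),
               odds_of_improvement(pa, pc), tolerance = 1e-15)
  inf <- odds_of_improvement(0.5, 0)
  expect_true(is.infinite(inf))
  expect_match(attr(inf, "note"), "infinite odds")
  expect_equal(format_odds(c(257, 489, 27.478, 24.174, 9.14, 4.25)),
               c("257", "489", "27", "24", "9.1", "4.2"))
})

test_that("conditional mean draws follow the linear predictor algebra", {
  p <- list(intercept = 2, arm_multiple = 1, arm_single = 4, slope = 0.9,
            slope_multiple = -0.3, slope_single = 0.2, sigma = 5, nu = 30)
  f <- fake_fit("postPRCA24", p)
  x <- 30
  ctl <- conditional_mu_draws(f, "control", pre_value = x)
  sgl <- conditional_mu_draws(f, "single", pre_value = x)
  # degenerate draws give a point mass at the deterministic eta
  expect_equal(unique(ctl), 2 + 0.9 * x)
  expect_equal(unique(sgl) - unique(ctl), p$arm_single + p$slope_single * x)
  # the control mean never involves the arm effects
  p2 <- p; p2$arm_multiple <- 99; p2$slope_multiple <- -7
  expect_equal(conditional_mu_draws(fake_fit("postPRCA24", p2), "control",
                                    pre_value = x), ctl)
  expect_error(conditional_mu_draws(f, "treatmentB", pre_value = x),
               "unknown condition")
  expect_error(conditional_mu_draws(f, "control", pre_value = 10), "outside")
  expect_error(conditional_mu_draws(f, "control"), "pre score")
  # no-covariate outcome rejects conditioning
  fs <- fake_fit("postSTAI", list(intercept = 20, arm_multiple = 0,
                                  arm_single = 2, familiarity = 0.5,
                                  sigma = 3, nu = 30))
  expect_error(conditional_mu_draws(fs, "single", pre_value = 20), "no pre")
  expect_equal(unique(conditional_mu_draws(fs, "single", familiarity = 3)),
               20 + 2 + 0.5 * 3)
})

test_that("Beta-outcome means return to the raw score scale", {
  p <- list(intercept = 0, arm_multiple = 0, arm_single = 0, slope = 0,
            slope_multiple = 0, slope_single = 0, phi = 10)
  f <- fake_fit("postIAT", p, n_obs = 45L)
  mu <- conditional_mu_draws(f, "control", pre_value = 0)
  # eta = 0 -> normalized mean 0.5 -> raw IAT 0 (midpoint), exactly
  expect_equal(unique(mu), 0, tolerance = 1e-12)
  # monotone in the intercept, bounded by the scale
  p2 <- p; p2$intercept <- 3
  mu2 <- conditional_mu_draws(fake_fit("postIAT", p2, n_obs = 45L),
                              "control", pre_value = 0)
  expect_gt(unique(mu2), 0)
  expect_lt(unique(mu2), 2)
})

test_that("control improvement probability reduces to a sign condition", {
  # for fixed parameters, P(improve | pre = x) = 1{mu + (beta - 1) x +
  # beta_F f > 0} in the increase direction: checked across anchors
  set.seed(502)
  nm <- free_params(model_spec("postSPIC"))
  m <- cbind(matrix(rnorm(60 * 7, sd = c(10, 1, 1, 0.3, 0.1, 0.1, 1)),
                    ncol = 7, byrow = TRUE), sigma = 10, nu = 30)
  m[, 4] <- m[, 4] + 1  # slope near 1
  colnames(m) <- nm
  f <- fake_fit("postSPIC", m)
  for (x in anchor_values(builtin_scales()$SPIC)) {
    p_obs <- prob_improvement(conditional_mu_draws(f, "control", pre_value = x,
                                                   familiarity = 3),
                              x, "increase")
    p_alg <- mean(m[, "intercept"] + (m[, "slope"] - 1) * x +
                    m[, "familiarity"] * 3 > 0)
    expect_equal(p_obs, p_alg)
  }
})

test_that("slope exceedance counts draws beyond the threshold", {
  p <- list(intercept = 0, arm_multiple = 0, arm_single = 0, slope = 2,
            slope_multiple = 0, slope_single = -0.5, sigma = 5, nu = 30)
  f <- fake_fit("postPRCA24", p)
  expect_equal(slope_exceedance(f, "control", 1), 1)
  expect_equal(slope_exceedance(f, "single", 1.6), 0)
  set.seed(503)
  nm <- free_params(model_spec("postPRCA24"))
  m <- matrix(0, 2000, length(nm), dimnames = list(NULL, nm))
  m[, "slope"] <- rnorm(2000, 1, 0.2); m[, "sigma"] <- 5; m[, "nu"] <- 30
  expect_equal(slope_exceedance(fake_fit("postPRCA24", m), "control", 1), 0.5,
               tolerance = 0.05)
  # one SD below the mean: normal tail oracle
  expect_equal(slope_exceedance(fake_fit("postPRCA24", m), "control", 0.8),
               pnorm(1), tolerance = 0.05)
  fs <- fake_fit("postSTAI", list(intercept = 20, arm_multiple = 0,
                                  arm_single = 0, familiarity = 0,
                                  sigma = 3, nu = 30))
  expect_error(slope_exceedance(fs, "control", 1), "no covariate")
})

test_that("the improvement report populates the reported grid", {
  rep <- improvement_report(quick_fits_all())
  pr <- rep$probabilities
  expect_equal(sort(unique(pr$outcome)),
               sort(c("postIAT", "postPRCA24", "postSPIC", "afterSPIC",
                      "postSTAI")))
  # the decrease-direction scale is conditioned high, the others low
  expect_setequal(pr$anchor[pr$outcome == "postPRCA24"],
                  c("middle", "highest"))
  for (out in setdiff(unique(pr$outcome), "postPRCA24")) {
    expect_setequal(pr$anchor[pr$outcome == out], c("lowest", "middle"))
  }
  expect_equal(nrow(pr), 5L * 2L * 3L)
  expect_true(all(pr$probability >= 0 & pr$probability <= 1))
  expect_true(all(rep$odds$odds >= 0))
  expect_equal(nrow(rep$odds), 5L * 2L * 3L)
  expect_error(improvement_report(quick_fits_all()[-1]), "postIAT")
})

test_that("a strong configured single-arm effect raises its probability", {
  # afterSPIC has large positive single-session effects in the study-like
  # configuration: its middle-anchor improvement probability must beat
  # the control arm's on data generated under that configuration
  rep <- cached("improvement_report45", improvement_report(quick_fits_all()))
  pr <- rep$probabilities
  row <- function(cond, anc) {
    pr$probability[pr$outcome == "afterSPIC" & pr$condition == cond &
                     pr$anchor == anc]
  }
  expect_gt(row("single", "middle"), row("control", "middle"))
})
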