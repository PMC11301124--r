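test_that("model specifications pair each outcome with its likelihood", {
  specs <- builtin_model_specs()
  expect_equal(specs$postIAT$likelihood, "beta_logit")
  for (out in c("postPRCA24", "postSPIC", "afterSPIC", "postSTAI")) {
    expect_equal(specs[[out]]$likelihood, "student_t")
  }
  expect_true(is.na(specs$postSTAI$covariate))
  expect_equal(specs$postSPIC$covariate, "preSPIC")
  expect_equal(specs$afterSPIC$covariate, "preSPIC")
  fam <- vapply(specs, `[[`, TRUE, "uses_familiarity")
  expect_equal(unname(fam), c(FALSE, FALSE, TRUE, TRUE, TRUE))
  # the normal family is only a validation override for Student-t outcomes
  expect_equal(model_spec("postPRCA24", likelihood = "normal")$likelihood,
               "normal")
  expect_error(model_spec("postIAT", likelihood = "normal"))
})

test_that("the linear predictor honours the reference-condition constraint", {
  expect_equal(linear_predictor(c(intercept = 5), "multiple"), 5)
  expect_equal(linear_predictor(c(intercept = 0, slope = 1,
                                  slope_single = 0.5),
                                "single", covariate = 2), 3)
  p <- c(intercept = 1.5, arm_multiple = 2, arm_single = -1, slope = 0.7,
         slope_multiple = 0.1, slope_single = 0.4, familiarity = 0.3)
  ctl <- linear_predictor(p, "control", covariate = 10, familiarity = 3)
  sgl <- linear_predictor(p, "single", covariate = 10, familiarity = 3)
  expect_equal(sgl - ctl, p[["arm_single"]] + p[["slope_single"]] * 10)
  # control effects are structural zeros: not parameters at all
  for (spec in builtin_model_specs()) {
    expect_false(any(c("arm_control", "slope_control") %in% free_params(spec)))
  }
  expect_equal(linear_predictor(p, c("control", "single"), covariate = c(0, 0),
                                familiarity = c(0, 0)),
               c(1.5, 0.5))
  expect_error(linear_predictor(p, "placebo"), "unknown condition")
})

test_that("the link maps eta to the likelihood mean", {
  iat <- model_spec("postIAT"); prc <- model_spec("postPRCA24")
  expect_equal(likelihood_mean(iat, 0), 0.5)
  expect_equal(likelihood_mean(prc, -3.2), -3.2)
  eta <- seq(-30, 30, by = 0.5)
  mu <- likelihood_mean(iat, eta)
  expect_true(all(diff(mu) > 0))
  expect_true(all(mu > 0 & mu < 1))
  expect_equal(likelihood_mean(iat, 700), 1)  # saturates monotonically
})

test_that("log likelihood matches closed forms and is additive", {
  # single record at the Student-t mode with huge dof ~ standard normal mode
  row <- data.frame(participant_id = "a", condition = "control",
                    familiarity = 3L, preIAT = 0, postIAT = 0,
                    prePRCA24 = 70, postPRCA24 = 80, preSPIC = 60,
                    postSPIC = 60, afterSPIC = 60, postSTAI = 20)
  d1 <- trial_dataset(row)
  p <- c(intercept = 80, arm_multiple = 0, arm_single = 0, slope = 0,
         slope_multiple = 0, slope_single = 0, sigma = 1, nu = 1e6)
  expect_equal(log_likelihood(model_spec("postPRCA24"), p, d1),
               log(1 / sqrt(2 * pi)), tolerance = 1e-4)

  # Beta(phi mu, phi (1 - mu)) with mu = 1/2, phi = 2 is uniform on (0, 1)
  d3 <- trial_dataset(do.call(rbind, list(row, row, row)))
  d3$postIAT <- c(-1.3, 0.2, 1.7)
  p_iat <- c(intercept = 0, arm_multiple = 0, arm_single = 0, slope = 0,
             slope_multiple = 0, slope_single = 0, phi = 2)
  expect_equal(log_likelihood(model_spec("postIAT"), p_iat, d3), 0,
               tolerance = 1e-12)

  # additivity: duplicating the records doubles the log likelihood
  d <- generate_trial(paper_like_config(), seed = 3)
  dd <- as.data.frame(d)
  d2 <- trial_dataset(rbind(dd, dd))
  p2 <- c(intercept = 10, arm_multiple = 1, arm_single = 2, slope = 0.8,
          slope_multiple = -0.2, slope_single = -0.1, sigma = 9, nu = 20)
  spec <- model_spec("postPRCA24")
  expect_equal(log_likelihood(spec, p2, d2), 2 * log_likelihood(spec, p2, d),
               tolerance = 1e-10)
})

test_that("the priors reproduce their stated credible intervals", {
  expect_equal(round(prior_positive_interval(), 1), c(2.4, 55.7))
  expect_equal(prior_coef_interval(), c(-195.996, 195.996), tolerance = 1e-5)

  spec <- model_spec("postSPIC")
  base <- c(intercept = 0, arm_multiple = 0, arm_single = 0, slope = 0,
            slope_multiple = 0, slope_single = 0, familiarity = 0,
            sigma = 10, nu = 20)
  lp0 <- log_prior(spec, base)
  for (delta in c(-5, 5, 50)) {
    shifted <- base; shifted[["slope"]] <- delta
    expect_lt(log_prior(spec, shifted), lp0)  # symmetric unimodal at 0
  }
  bad <- base; bad[["sigma"]] <- -1
  expect_error(log_prior(spec, bad), "sigma")
  bad <- base; bad[["nu"]] <- 0.5
  expect_error(log_prior(spec, bad), "nu")
  # posterior building blocks are finite on any valid interior point
  d <- generate_trial(paper_like_config(), seed = 4)
  expect_true(is.finite(log_likelihood(spec, base, d) + log_prior(spec, base)))
})
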