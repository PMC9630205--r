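params <- bdat_default_params()

test_that("the modified-asymptote link behaves like a link-glm object", {
  lk <- logit_2asym(0.4, 0.98)
  expect_s3_class(lk, "link-glm")
  eta <- seq(-6, 6, by = 0.5)
  expect_equal(lk$linkinv(eta), 0.4 + 0.58 * plogis(eta))
  expect_equal(lk$linkfun(lk$linkinv(eta)), eta, tolerance = 1e-8)
  expect_equal(lk$mu.eta(eta), 0.58 * dlogis(eta))
})

test_that("quadrature marginal likelihood agrees with lme4 AGQ on person-only data", {
  skip_if_not_installed("lme4")
  d <- simulate_study1_dataset(120, params, include_track_effects = FALSE,
                               seed = 21)
  don <- d[d$condition == "ON", ]
  f <- lme4::glmer(response ~ I(as.numeric(target_beat == 3)) +
                     (1 | participant_id),
                   data = don,
                   family = binomial(link = logit_2asym(0.4, 0.98)),
                   nAGQ = 25, devFunOnly = TRUE)
  pts <- list(c(-0.76, 1.77, 1.19), c(-0.4, 1.3, 0.9))
  for (pt in pts) {
    ours <- marginal_log_likelihood(
      d, explanatory_params("ON", c(intercept = pt[1], strength = pt[2]),
                            pt[3], 1e-6, 0.4, 0.98))
    theirs <- -f(c(pt[3], pt[1], pt[2])) / 2
    expect_equal(ours, theirs, tolerance = 1e-5)
  }
})

test_that("marginal likelihood matches the importance-sampling oracle on a toy dataset", {
  d <- simulate_study1_dataset(10, params, n_tracks = 5, seed = 11)
  for (cond in c("ON", "OFF")) {
    ll <- marginal_log_likelihood(d, params[[cond]])
    ll_mc <- marginal_log_likelihood_mc(d, params[[cond]], n_draws = 1e5,
                                        seed = 5)
    expect_lt(abs(ll - ll_mc), 0.5)
  }
})

test_that("with g = 0, u = 1 the fit agrees with a plain mixed logit oracle", {
  skip_if_not_installed("lme4")
  ## logistic data without asymptotes
  p0 <- list(
    ON = explanatory_params("ON", params$ON$beta, 1.19, 0.3, 0, 1),
    OFF = explanatory_params("OFF", params$OFF$beta, 1.30, 0.05, 0, 1))
  d <- simulate_study1_dataset(150, p0, seed = 31)
  fit <- fit_explanatory(d, "ON", g = 0, u = 1, se = FALSE)
  don <- d[d$condition == "ON", ]
  don$strength <- as.numeric(don$target_beat == 3)
  or <- lme4::glmer(response ~ strength + (1 | participant_id) + (1 | track_id),
                    data = don, family = binomial())
  fe <- lme4::fixef(or)
  ## Laplace (oracle) and quadrature (ours) differ slightly by construction
  expect_equal(unname(fit$beta["intercept"]), unname(fe[1]), tolerance = 0.08)
  expect_equal(unname(fit$beta["strength"]), unname(fe[2]), tolerance = 0.08)
})

test_that("fit is invariant to row order and validates its inputs", {
  d <- simulate_study1_dataset(40, params, seed = 51)
  f1 <- fit_explanatory(d, "ON", se = FALSE)
  d2 <- d[sample.int(nrow(d)), ]
  f2 <- fit_explanatory(d2, "ON", se = FALSE)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-6)
  expect_equal(f1$sigma_person, f2$sigma_person, tolerance = 1e-6)
  expect_error(fit_explanatory(d[d$participant_id == 1, ], "ON"),
               "at least 2")
  dd <- d[d$condition == "ON", ]
  dd$response <- 1
  expect_error(fit_explanatory(dd, "ON"), "both response values")
})

test_that("fixed effects and variance components are recovered by simulation", {
  ## 20 replicates at the calibration-study scale of 500 participants
  rec <- recovery_experiment("calibrate", n_respondents = 500, reps = 20,
                             seed = 2026)
  ## mean bias small and 2-SE coverage near nominal for every coefficient
  expect_true(all(abs(rec$bias$mean_bias) < 0.1),
              label = paste("biases:",
                            paste(round(rec$bias$mean_bias, 3), collapse = " ")))
  expect_true(all(rec$coverage$coverage_2se >= 0.8),
              label = paste("coverages:",
                            paste(rec$coverage$coverage_2se, collapse = " ")))
  ## variance-component estimates track the truth on average
  est <- rec$estimates[rec$estimates$coef == "intercept", ]
  expect_equal(mean(est$sigma_person[est$condition == "ON"]), 1.19,
               tolerance = 0.1)
  expect_equal(mean(est$sigma_person[est$condition == "OFF"]), 1.30,
               tolerance = 0.1)
  expect_equal(mean(est$sigma_track[est$condition == "ON"]), 0.41,
               tolerance = 0.15)
  expect_true(all(est$converged))
})

test_that("a zero track variance is recovered at the boundary", {
  d <- simulate_study1_dataset(200, params, include_track_effects = FALSE,
                               seed = 61)
  fit <- fit_explanatory(d, "ON", se = FALSE)
  expect_lt(fit$sigma_track, 0.05)
})

test_that("prediction accuracy behaves at the edges and at study scale", {
  d <- simulate_study1_dataset(150, params, seed = 71)
  fit <- fit_explanatory(d, "ON", se = FALSE)
  acc <- prediction_accuracy(fit)
  ## band established by the repeated-simulation recovery runs: conditional
  ## classification under the bundled ON model sits around .7-.8
  expect_gt(acc, 0.6)
  expect_lt(acc, 0.9)

  ## perfectly separable strong effects give accuracy 1
  dsep <- d[d$condition == "ON", ]
  dsep$response <- as.integer(dsep$target_beat == 3)
  fsep <- suppressWarnings(fit_explanatory(dsep, "ON", g = 0.01, u = 0.99,
                                           se = FALSE))
  expect_equal(prediction_accuracy(fsep), 1)
})

test_that("track screening flags below-chance tracks only", {
  d <- data.frame(
    participant_id = rep(1:50, times = 3),
    track_id = rep(c(1, 2, 3), each = 50),
    condition = rep(c("OFF", "OFF", "ON"), each = 50),
    response = c(rep(0:1, c(26, 24)),   # mean 0.48, below chance
                 rep(1, 50),            # all correct
                 rep(c(0, 1), 25)))     # exactly at chance
  rep_ <- screen_tracks(d)
  expect_equal(rep_$flagged_tracks$track_id, 1)
  expect_equal(rep_$flagged_tracks$mean_accuracy, 0.48)
  ## exactly at chance is not flagged (strict inequality)
  expect_false(3 %in% rep_$flagged_tracks$track_id)
})

test_that("participant screening flags dominant responders", {
  conditions <- rep(c("ON", "OFF"), 15)
  ## participant 1 judges "on the beat" on 29/30 trials; participant 2
  ## alternates judgments 50/50
  judged_1 <- c(rep(TRUE, 29), FALSE)
  judged_2 <- rep(c(TRUE, FALSE), 15)
  d <- data.frame(
    participant_id = rep(1:2, each = 30),
    track_id = rep(1:30, 2),
    condition = rep(conditions, 2),
    response = as.integer((rep(conditions, 2) == "ON") == c(judged_1, judged_2)))
  rep_ <- screen_participants(d, dominance = 0.9)
  expect_equal(rep_$flagged_participants$participant_id, 1)
  expect_equal(rep_$flagged_participants$dominant_proportion, 29 / 30)
  ## at dominance 1 only constant responders are flagged
  expect_equal(nrow(screen_participants(d, dominance = 1)$flagged_participants), 0)
  d$response[1:30] <- as.integer(d$condition[1:30] == "ON")  # all "on"
  expect_equal(screen_participants(d, dominance = 1)$flagged_participants$participant_id, 1)
})
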