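params <- bdat_default_params()

test_that("feature coding follows the model's covariate definitions", {
  expect_equal(feature_vector(list(condition = "ON", target_beat = 3)),
               c(intercept = 1, strength = 1))
  expect_equal(
    feature_vector(list(condition = "OFF", target_beat = 4,
                        direction = "early", displacement_level = 1)),
    c(intercept = 1, displacement = 1, direction = 0, strength = 0,
      direction_x_strength = 0))
  expect_equal(
    feature_vector(list(condition = "OFF", target_beat = 3,
                        direction = "late", displacement_level = 7)),
    c(intercept = 1, displacement = 7, direction = 1, strength = 1,
      direction_x_strength = 1))
  expect_error(
    feature_vector(list(condition = "OFF", target_beat = 3,
                        direction = "none", displacement_level = 0)),
    "early")
})

test_that("linear predictor sums the bundled coefficients", {
  on3 <- feature_vector(list(condition = "ON", target_beat = 3))
  on4 <- feature_vector(list(condition = "ON", target_beat = 4))
  expect_equal(linear_predictor(on3, params$ON), -0.76 + 1.77)
  expect_equal(linear_predictor(on4, params$ON), -0.76)
  off <- feature_vector(list(condition = "OFF", target_beat = 3,
                             direction = "late", displacement_level = 1))
  expect_equal(linear_predictor(off, params$OFF),
               2.23 + 0.41 - 1.91 + 0.16 - 1.48)
  expect_equal(linear_predictor(on3, params$ON, person_effect = 0.5,
                                track_effect = -0.2), 1.01 + 0.3)
  expect_error(linear_predictor(on3, params$OFF), "OFF model")
})

test_that("response probability is bounded by and approaches the asymptotes", {
  expect_equal(response_probability(-50, 0.4, 0.98), 0.4, tolerance = 1e-12)
  expect_equal(response_probability(50, 0.4, 0.98), 0.98, tolerance = 1e-12)
  expect_equal(response_probability(0, 0.4, 0.98), (0.4 + 0.98) / 2)
  eta <- seq(-10, 10, by = 0.05)
  p <- response_probability(eta, 0.4, 0.96)
  expect_true(all(p >= 0.4 & p <= 0.96))
  expect_true(all(diff(p) > 0))
  ## at theta = b the 4PL sits midway between the asymptotes
  it <- item_params(a = 1.19, b = -0.849)
  expect_equal(irt_probability(it$b, it), 0.69)
})

test_that("the explanatory model maps onto constrained 4PL item parameters", {
  ip <- glmm_to_irt(list(condition = "ON", target_beat = 3), params)
  expect_equal(ip$a, 1.19)
  expect_equal(ip$b, -1.01 / 1.19, tolerance = 1e-9)
  ip0 <- glmm_to_irt(list(condition = "ON", target_beat = 3),
                     explanatory_params("ON", c(intercept = 0, strength = 0),
                                        1.19, 0.41, 0.4, 0.98))
  expect_equal(ip0$b, 0)
  ip2 <- glmm_to_irt(list(condition = "OFF", target_beat = 3,
                          direction = "late", displacement_level = 1), params)
  expect_equal(ip2$a, 1.30)
  expect_equal(ip2$b, 0.59 / 1.30, tolerance = 1e-9)
  expect_error(glmm_to_irt(list(condition = "ON", target_beat = 3),
                           explanatory_params("ON", c(intercept = 1, strength = 1),
                                              0, 0, 0.4, 0.98)),
               "sigma_person")

  ## algebraic identity: the IRT form at theta = person_effect / sigma
  ## reproduces the explanatory probability with zero track effect
  items <- tiny_irt_items(params)
  for (i in seq_len(nrow(items))) {
    it <- items[i, ]
    pr <- params[[it$condition]]
    theta <- 0.73
    eta <- linear_predictor(feature_vector(it), pr,
                            person_effect = theta * pr$sigma_person)
    expect_equal(irt_probability(theta, as.list(it[, c("a", "b", "g", "u")])),
                 response_probability(eta, pr$g, pr$u), tolerance = 1e-12)
  }
})

test_that("difficulty ordering matches the accuracy patterns", {
  items <- tiny_irt_items(params)
  ## strong-beat on-beat items are easier than weak-beat ones
  b_on <- tapply(items$b[items$condition == "ON"],
                 items$target_beat[items$condition == "ON"], unique)
  expect_lt(b_on[["3"]], b_on[["4"]])
  ## larger displacement -> easier off-beat item, within each cell
  off <- items[items$condition == "OFF" & items$track_id == 1, ]
  for (beat in c(3, 4)) for (dir in c("early", "late")) {
    cell <- off[off$target_beat == beat & off$direction == dir, ]
    cell <- cell[order(cell$displacement_level), ]
    expect_true(all(diff(cell$b) < 0))
  }
})

test_that("item information matches the finite-difference oracle", {
  items <- list(
    glmm_to_irt(list(condition = "ON", target_beat = 3), params),
    glmm_to_irt(list(condition = "OFF", target_beat = 4,
                     direction = "late", displacement_level = 4), params),
    item_params(a = 2, b = 1, g = 0, u = 1))
  for (it in items) for (theta in c(-2, it$b, 0.5)) {
    expect_equal(item_information(theta, it), info_fd_oracle(theta, it),
                 tolerance = 1e-4)
  }
  ## 2PL limit: reduces to a^2 p (1 - p)
  it <- item_params(a = 1.7, b = -0.3, g = 0, u = 1)
  th <- seq(-3, 3, by = 0.5)
  p <- plogis(it$a * (th - it$b))
  expect_equal(item_information(th, it), it$a^2 * p * (1 - p))
  ## non-negative, unimodal, vanishing in the tails
  it4 <- item_params(a = 1.19, b = 0, g = 0.4, u = 0.98)
  th <- seq(-10, 10, by = 0.01)
  info <- item_information(th, it4)
  expect_true(all(info >= 0))
  peak <- which.max(info)
  expect_true(all(diff(info[1:peak]) >= -1e-12))
  expect_true(all(diff(info[peak:length(info)]) <= 1e-12))
  expect_lt(item_information(10, it4), 1e-3)
})

test_that("log-likelihood is a sum of Bernoulli terms", {
  i1 <- glmm_to_irt(list(condition = "ON", target_beat = 3), params)
  i2 <- glmm_to_irt(list(condition = "OFF", target_beat = 3,
                         direction = "late", displacement_level = 1), params)
  items <- data.frame(a = c(i1$a, i2$a), b = c(i1$b, i2$b),
                      g = c(i1$g, i2$g), u = c(i1$u, i2$u))
  theta <- 0.4
  p1 <- irt_probability(theta, i1)
  p2 <- irt_probability(theta, i2)
  expect_equal(log_likelihood(items, c(1, 0), theta),
               log(p1) + log(1 - p2))
  ## invariant under reordering
  expect_equal(log_likelihood(items[2:1, ], c(0, 1), theta),
               log_likelihood(items, c(1, 0), theta))
  ## asymptote: a single correct response tends to log(u)
  expect_equal(log_likelihood(items[1, ], 1, 50), log(i1$u), tolerance = 1e-9)
  ## finite even for extreme abilities (g > 0, u < 1)
  expect_true(is.finite(log_likelihood(items, c(0, 1), -50)))
})

test_that("bundled parameter files load into valid objects", {
  expect_s3_class(params$ON, "bdat_explanatory_params")
  expect_equal(params$ON$sigma_person, 1.19)
  expect_equal(params$OFF$sigma_track, 0.05)
  expect_equal(params$OFF$u, 0.96)
  expect_equal(unname(params$OFF$beta["direction"]), -1.91)
  expect_error(explanatory_params("ON", c(intercept = 1), 1, 0.4, 0.4, 0.98),
               "missing coefficient")
  expect_error(explanatory_params("ON", c(intercept = 1, strength = 1),
                                  1, 0.4, 0.99, 0.98))
})
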