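## The probabilistic core: explanatory linear predictors for on-beat and
## off-beat items, the modified-asymptote (four-parameter logistic)
## response function, the mapping from the explanatory mixed model to IRT
## item parameters, and likelihood/information.

#' Explanatory model parameters
#'
#' Condition-level parameters of the explanatory response model: fixed
#' effects on the logit scale, standard deviations of the crossed
#' participant and track random intercepts, and the fixed lower (guessing)
#' and upper (1 - inattention) asymptotes.
#'
#' The response probability is
#' `P = g + (u - g) * plogis(beta . x + person_effect + track_effect)`.
#'
#' @param condition `"ON"` or `"OFF"`.
#' @param beta Named coefficient vector. ON items use `intercept` and
#'   `strength`; OFF items use `intercept`, `displacement` (level index
#'   1-7), `direction` (late = 1), `strength` (strong = 1) and
#'   `direction_x_strength`.
#' @param sigma_person,sigma_track Random-intercept standard deviations
#'   (logits), both non-negative.
#' @param g,u Lower and upper asymptotes, `0 <= g < u <= 1`.
#' @return An object of class `bdat_explanatory_params`.
#' @seealso [bdat_default_params()] for the bundled calibration defaults.
#' @export
explanatory_params <- function(condition, beta, sigma_person, sigma_track,
                               g, u) {
  condition <- match.arg(condition, c("ON", "OFF"))
  need <- feature_names(condition)
  if (!all(need %in% names(beta)))
    stop("missing coefficient(s): ", paste(setdiff(need, names(beta)), collapse = ", "))
  stopifnot(sigma_person >= 0, sigma_track >= 0, g >= 0, g < u, u <= 1)
  structure(list(condition = condition, beta = beta[need],
                 sigma_person = sigma_person, sigma_track = sigma_track,
                 g = g, u = u),
            class = "bdat_explanatory_params")
}

feature_names <- function(condition) {
  if (condition == "ON") c("intercept", "strength")
  else c("intercept", "displacement", "direction", "strength",
         "direction_x_strength")
}

#' Bundled default model parameters
#'
#' Default parameters of the two explanatory models (on-beat and off-beat
#' condition), as shipped in `inst/extdata/params_on.json` and
#' `params_off.json`. These are the calibration estimates the adaptive test
#' administers with: ON intercept -0.76, strength 1.77, person SD 1.19,
#' track SD 0.41, asymptotes .4/.98; OFF intercept 2.23, displacement 0.41
#' per level, direction -1.91 (late), strength 0.16, interaction -1.48,
#' person SD 1.30, track SD 0.05, asymptotes .4/.96.
#'
#' @return A list with elements `ON` and `OFF`, each a
#'   [explanatory_params()] object.
#' @export
bdat_default_params <- function() {
  read_one <- function(f) {
    p <- jsonlite::read_json(system.file("extdata", f, package = "bdat"),
                             simplifyVector = TRUE)
    explanatory_params(p$condition, unlist(p$beta), p$sigma_person,
                       p$sigma_track, p$g, p$u)
  }
  list(ON = read_one("params_on.json"), OFF = read_one("params_off.json"))
}

#' Feature coding of an item
#'
#' Codes one item into the covariates of its condition's explanatory model:
#' metrical strength 1 for the strong beat (beat 3) and 0 for the weak beat
#' (beat 4); probe direction 0 for early (before the target beat, the
#' reference category) and 1 for late; displacement as the level index 1-7;
#' interaction = direction x strength. On-beat items use only the intercept
#' and strength.
#'
#' @param item A single item (one row of an item bank, or equivalent list).
#' @return Named numeric vector of coded covariates.
#' @export
feature_vector <- function(item) {
  item <- as.list(item)
  strength <- as.numeric(item$target_beat == 3)
  if (item$condition == "ON") {
    c(intercept = 1, strength = strength)
  } else {
    if (!item$direction %in% c("early", "late"))
      stop("off-beat item must have direction 'early' or 'late'")
    late <- as.numeric(item$direction == "late")
    c(intercept = 1, displacement = as.numeric(item$displacement_level),
      direction = late, strength = strength,
      direction_x_strength = late * strength)
  }
}

#' Linear predictor of the explanatory model
#'
#' @param features Coded covariates from [feature_vector()].
#' @param params A [explanatory_params()] of the matching condition.
#' @param person_effect,track_effect Random-intercept values (logits).
#' @return Linear predictor (logits).
#' @export
linear_predictor <- function(features, params, person_effect = 0,
                             track_effect = 0) {
  stopifnot(inherits(params, "bdat_explanatory_params"))
  if (!setequal(names(features), names(params$beta)))
    stop("features do not match the ", params$condition, " model coefficients")
  sum(params$beta[names(features)] * features) + person_effect + track_effect
}

#' Modified-asymptote response probability
#'
#' `P = g + (u - g) * plogis(eta)`: a logistic response compressed between
#' a guessing floor `g` and an inattention ceiling `u`. In IRT form the
#' logit is `eta = a * (theta - b)`; see [irt_probability()].
#'
#' @param eta Linear predictor (logits).
#' @param g,u Asymptotes, `0 <= g < u <= 1`.
#' @return Probability in `[g, u]`, strictly increasing in `eta`.
#' @export
response_probability <- function(eta, g = 0.4, u = 0.98) {
  stopifnot(g >= 0, g < u, u <= 1)
  g + (u - g) * plogis(eta)
}

#' Four-parameter logistic item parameters
#'
#' @param a Discrimination (> 0), logits per ability SD.
#' @param b Difficulty on the ability (z-score) scale.
#' @param g,u Asymptotes.
#' @return An object of class `bdat_item_params`.
#' @export
item_params <- function(a, b, g = 0.4, u = 0.98) {
  stopifnot(a > 0, is.finite(b), g >= 0, g < u, u <= 1)
  structure(list(a = a, b = b, g = g, u = u), class = "bdat_item_params")
}

#' @rdname response_probability
#' @param theta Ability on the z-score scale.
#' @param item A [item_params()] object (or list with `a`, `b`, `g`, `u`).
#' @export
irt_probability <- function(theta, item) {
  response_probability(item$a * (theta - item$b), item$g, item$u)
}

#' Map the explanatory model to IRT item parameters
#'
#' The participant random-intercept SD becomes the constant discrimination
#' `a`; the fixed-effect predictor becomes the difficulty
#' `b = -(beta . x) / sigma_person`; the asymptotes carry over. With a
#' standard-normal ability `theta`, `a * (theta - b)` then reproduces the
#' explanatory linear predictor at `person_effect = theta * sigma_person`.
#' The track random effect is excluded at administration time (each track
#' is presented at most once per session).
#'
#' @param item A single item.
#' @param params The [explanatory_params()] for the item's condition (or a
#'   list with both conditions as returned by [bdat_default_params()]).
#' @return A [item_params()] object.
#' @export
glmm_to_irt <- function(item, params = bdat_default_params()) {
  item <- as.list(item)
  if (!inherits(params, "bdat_explanatory_params"))
    params <- params[[item$condition]]
  if (params$sigma_person <= 0)
    stop("degenerate model: sigma_person must be positive")
  x <- feature_vector(item)
  eta0 <- sum(params$beta[names(x)] * x)
  item_params(a = params$sigma_person, b = -eta0 / params$sigma_person,
              g = params$g, u = params$u)
}

#' Attach IRT parameters to an item bank
#'
#' Vectorized [glmm_to_irt()]: adds columns `a`, `b`, `g`, `u` to an item
#' bank.
#'
#' @param bank An item bank data frame.
#' @param params Parameter pair from [bdat_default_params()].
#' @return The bank with IRT parameter columns appended.
#' @export
irt_item_bank <- function(bank, params = bdat_default_params()) {
  ps <- lapply(seq_len(nrow(bank)), function(i) glmm_to_irt(bank[i, ], params))
  bank$a <- vapply(ps, `[[`, 0, "a")
  bank$b <- vapply(ps, `[[`, 0, "b")
  bank$g <- vapply(ps, `[[`, 0, "g")
  bank$u <- vapply(ps, `[[`, 0, "u")
  bank
}

#' Fisher information of a 4PL item
#'
#' Information about ability contributed by one Bernoulli response:
#' `I(theta) = a^2 (P - g)^2 (u - P)^2 / ((u - g)^2 P (1 - P))`, which
#' reduces to the familiar `a^2 P (1 - P)` when `g = 0, u = 1`.
#'
#' @param theta Ability value(s).
#' @param item A [item_params()] object.
#' @return Non-negative information value(s) (1 / ability units squared).
#' @export
item_information <- function(theta, item) {
  p <- irt_probability(theta, item)
  item$a^2 * (p - item$g)^2 * (item$u - p)^2 /
    ((item$u - item$g)^2 * p * (1 - p))
}

#' Bernoulli log-likelihood of a response pattern
#'
#' @param items Data frame with columns `a`, `b`, `g`, `u` (one row per
#'   administered item) or a list of [item_params()].
#' @param responses 0/1 vector, one per item.
#' @param theta Ability value(s) at which to evaluate.
#' @return Log-likelihood; finite for all `theta` whenever `g > 0` and
#'   `u < 1`.
#' @export
log_likelihood <- function(items, responses, theta) {
  if (!is.data.frame(items))
    items <- do.call(rbind, lapply(items, function(p) as.data.frame(unclass(p))))
  stopifnot(nrow(items) == length(responses), all(responses %in% 0:1))
  ## items x theta matrix; per-item asymptotes recycle down columns
  eta <- outer(items$a, theta) - items$a * items$b
  p <- items$g + (items$u - items$g) * plogis(eta)
  colSums(responses * log(p) + (1 - responses) * log1p(-p))
}
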