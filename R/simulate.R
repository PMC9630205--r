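## Synthetic-data backbone: simulated respondents, calibration-style
## datasets, and end-to-end recovery experiments.

#' Simulated calibration dataset
#'
#' Emulates the calibration-study design: every respondent hears each track
#' once; each trial is on-beat with probability 0.5; the off-beat
#' perturbation is drawn uniformly from the 28 variants (target beat 3/4 x
#' direction early/late x 7 displacement levels); on-beat trials use beat 3
#' or 4 with equal probability. Responses are Bernoulli with the
#' explanatory-model probability at the respondent's ability (person effect
#' `theta * sigma_person` of the trial's condition) plus, optionally, a
#' per-track random effect drawn once per condition with that condition's
#' `sigma_track`. Abilities are standard normal unless supplied.
#'
#' @param n_respondents Number of respondents (the calibration study used
#'   125).
#' @param params Parameter pair from [bdat_default_params()].
#' @param n_tracks Number of tracks (default 30).
#' @param scale A [displacement_scale()].
#' @param tempo_bpm Tempo of all items (default 125).
#' @param include_track_effects Simulate per-track random intercepts
#'   (default `TRUE`, the calibration design; adaptive-session simulations
#'   conventionally disable them).
#' @param seed Master seed; recorded in the output attributes, and
#'   re-running with the same seed reproduces the dataset exactly.
#' @param thetas Optional vector of abilities (length `n_respondents`).
#' @return A data frame of class `bdat_dataset` with columns
#'   `participant_id`, `track_id`, `condition`, `target_beat`, `direction`,
#'   `displacement_level`, `displacement`, `tempo_bpm`, `response`.
#'   Attributes record `seed`, `thetas`, `track_effects` and the parameter
#'   fingerprint.
#' @export
simulate_study1_dataset <- function(n_respondents = 125,
                                    params = bdat_default_params(),
                                    n_tracks = 30,
                                    scale = displacement_scale(),
                                    tempo_bpm = 125,
                                    include_track_effects = TRUE,
                                    seed = 1, thetas = NULL) {
  stopifnot(n_respondents >= 1)
  levels <- displacement_levels(scale)
  nl <- length(levels)

  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  if (is.null(thetas)) thetas <- rnorm(n_respondents)
  stopifnot(length(thetas) == n_respondents)
  bt <- list(
    ON = if (include_track_effects) rnorm(n_tracks, 0, params$ON$sigma_track) else numeric(n_tracks),
    OFF = if (include_track_effects) rnorm(n_tracks, 0, params$OFF$sigma_track) else numeric(n_tracks))

  n_rows <- n_respondents * n_tracks
  d <- data.frame(
    participant_id = rep(seq_len(n_respondents), each = n_tracks),
    track_id = rep(seq_len(n_tracks), n_respondents))
  on_trial <- runif(n_rows) < 0.5
  d$condition <- ifelse(on_trial, "ON", "OFF")
  ## ON: beat 3 or 4 with equal chance; OFF: one of the 28 variants
  variant <- integer(n_rows)
  variant[on_trial] <- sample.int(2, sum(on_trial), replace = TRUE)
  variant[!on_trial] <- sample.int(4 * nl, sum(!on_trial), replace = TRUE)
  d$target_beat <- ifelse(on_trial, c(3L, 4L)[variant],
                          c(3L, 4L)[((variant - 1L) %% 2L) + 1L])
  d$direction <- ifelse(on_trial, "none",
                        c("early", "late")[(((variant - 1L) %/% 2L) %% 2L) + 1L])
  d$displacement_level <- ifelse(on_trial, 0L, ((variant - 1L) %/% 4L) + 1L)
  d$displacement <- ifelse(on_trial, 0, levels[pmax(d$displacement_level, 1L)])
  d$tempo_bpm <- tempo_bpm

  strength <- as.numeric(d$target_beat == 3)
  late <- as.numeric(d$direction == "late")
  bon <- params$ON$beta; boff <- params$OFF$beta
  eta_on <- bon["intercept"] + bon["strength"] * strength +
    thetas[d$participant_id] * params$ON$sigma_person +
    bt$ON[d$track_id]
  eta_off <- boff["intercept"] + boff["displacement"] * d$displacement_level +
    boff["direction"] * late + boff["strength"] * strength +
    boff["direction_x_strength"] * late * strength +
    thetas[d$participant_id] * params$OFF$sigma_person +
    bt$OFF[d$track_id]
  p <- ifelse(on_trial,
              params$ON$g + (params$ON$u - params$ON$g) * plogis(eta_on),
              params$OFF$g + (params$OFF$u - params$OFF$g) * plogis(eta_off))
  d$response <- rbinom(n_rows, 1, p)

  structure(d, seed = seed, thetas = thetas, track_effects = bt,
            params_fingerprint = list(
              ON = unclass(params$ON), OFF = unclass(params$OFF),
              include_track_effects = include_track_effects),
            class = c("bdat_dataset", "data.frame"))
}

#' Simulated response oracle
#'
#' Returns a function usable as the `respond` argument of [run_session()]:
#' given an item, it answers correctly with the explanatory-model
#' probability at the fixed ability `theta` (no track effect, matching
#' administration-time scoring). With a `seed`, the oracle keeps a private
#' RNG stream, so the same oracle configuration always produces the same
#' response sequence regardless of surrounding RNG use.
#'
#' @param theta Respondent ability (z-score scale).
#' @param params Parameter pair from [bdat_default_params()].
#' @param seed Optional private seed for the oracle's stream.
#' @return A function `item -> 0/1`. The returned function has an attribute
#'   `prob` giving access to the underlying response probability.
#' @export
simulated_responder <- function(theta, params = bdat_default_params(),
                                seed = NULL) {
  state <- NULL
  if (!is.null(seed)) {
    old_seed <- get0(".Random.seed", globalenv())
    set.seed(seed)
    state <- new.env(parent = emptyenv())
    state$s <- get(".Random.seed", globalenv())
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }
  prob <- function(item) {
    pr <- if (inherits(params, "bdat_explanatory_params")) params
          else params[[as.list(item)$condition]]
    x <- feature_vector(item)
    eta <- sum(pr$beta[names(x)] * x) + theta * pr$sigma_person
    pr$g + (pr$u - pr$g) * plogis(eta)
  }
  f <- function(item) {
    p <- prob(item)
    if (is.null(state)) return(as.integer(runif(1) < p))
    old_seed <- get0(".Random.seed", globalenv())
    assign(".Random.seed", state$s, globalenv())
    draw <- runif(1)
    state$s <- get(".Random.seed", globalenv())
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
    else rm(".Random.seed", envir = globalenv())
    as.integer(draw < p)
  }
  attr(f, "prob") <- prob
  f
}

#' Recovery experiments
#'
#' End-to-end validation harness. `mode = "calibrate"` simulates
#' calibration datasets and refits both explanatory models, reporting
#' per-coefficient estimates, standard errors, bias and whether each truth
#' lies within 2 SEs. `mode = "adaptive"` simulates respondents with known
#' abilities and runs, for each, one adaptive and one random-selection
#' session of the same length, reporting RMSE and correlation of the final
#' estimates against truth.
#'
#' @param mode `"calibrate"` or `"adaptive"`.
#' @param n_respondents Respondents per replicate (calibrate) or number of
#'   simulated respondents (adaptive).
#' @param reps Number of replicates (calibrate mode).
#' @param length Session length (adaptive mode, default 25).
#' @param params Parameter pair (the simulation truth).
#' @param seed Master seed.
#' @param nodes Quadrature nodes for fitting.
#' @param se Whether to compute standard errors in calibrate mode.
#' @return A list report; see details of each mode in the returned
#'   structure. All seeds used are recorded.
#' @export
recovery_experiment <- function(mode = c("calibrate", "adaptive"),
                                n_respondents = 500, reps = 1, length = 25,
                                params = bdat_default_params(), seed = 1,
                                nodes = 20, se = TRUE) {
  mode <- match.arg(mode)
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  if (mode == "calibrate") {
    rep_seeds <- sample.int(2^30, reps)
    out <- vector("list", reps)
    for (r in seq_len(reps)) {
      d <- simulate_study1_dataset(n_respondents, params, seed = rep_seeds[r])
      res <- lapply(c("ON", "OFF"), function(cond) {
        fit <- fit_explanatory(d, cond, g = params[[cond]]$g,
                               u = params[[cond]]$u, nodes = nodes, se = se)
        truth <- params[[cond]]$beta
        data.frame(condition = cond, coef = names(truth),
                   truth = unname(truth),
                   estimate = unname(fit$beta[names(truth)]),
                   se = unname(fit$se[names(truth)]),
                   sigma_person = fit$sigma_person,
                   sigma_track = fit$sigma_track,
                   converged = fit$converged,
                   accuracy = prediction_accuracy(fit),
                   row.names = NULL)
      })
      out[[r]] <- cbind(rep = r, do.call(rbind, res))
    }
    tab <- do.call(rbind, out)
    tab$within_2se <- abs(tab$estimate - tab$truth) <= 2 * tab$se
    bias <- aggregate(estimate - truth ~ condition + coef, data = tab, FUN = mean)
    names(bias)[3] <- "mean_bias"
    cover <- if (se) {
      cv <- aggregate(within_2se ~ condition + coef, data = tab, FUN = mean)
      names(cv)[3] <- "coverage_2se"
      cv
    }
    list(mode = mode, seed = seed, rep_seeds = rep_seeds,
         n_respondents = n_respondents, estimates = tab,
         bias = bias, coverage = cover)
  } else {
    thetas <- rnorm(n_respondents)
    resp_seeds <- sample.int(2^30, n_respondents)
    sess_seeds <- sample.int(2^30, n_respondents)
    bank <- irt_item_bank(build_item_bank(), params)
    est <- matrix(NA_real_, n_respondents, 2,
                  dimnames = list(NULL, c("adaptive", "random")))
    for (i in seq_len(n_respondents)) {
      for (sel in c("adaptive", "random")) {
        respond <- simulated_responder(thetas[i], params, seed = resp_seeds[i])
        s <- run_session(respond, bank, params, length = length,
                         seed = sess_seeds[i],
                         select = if (sel == "adaptive") "difficulty" else "random")
        est[i, sel] <- s$final$theta
      }
    }
    rmse <- sqrt(colMeans((est - thetas)^2))
    list(mode = mode, seed = seed, n_respondents = n_respondents,
         length = length, thetas = thetas, estimates = est,
         rmse = rmse,
         correlation = c(adaptive = cor(thetas, est[, "adaptive"]),
                         random = cor(thetas, est[, "random"])))
  }
}

#' Write / read a calibration dataset
#'
#' CSV with the documented columns of [simulate_study1_dataset()].
#'
#' @param data A calibration dataset.
#' @param path File path.
#' @return `write_dataset` returns `path` invisibly; `read_dataset` returns
#'   the data frame.
#' @export
write_dataset <- function(data, path) {
  write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  structure(d, class = c("bdat_dataset", "data.frame"))
}
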