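## Adaptive administration: ability estimation after every response, item
## selection by difficulty match (or maximum information), fixed-length
## sessions, pseudo-IQ reporting.

#' Ability grid
#'
#' The fixed evaluation grid for expected-a-posteriori estimation: the
#' z-score ability scale from -4 to 4 in steps of 0.01.
#'
#' @param step Grid step (default 0.01).
#' @return Numeric vector of grid points.
#' @export
ability_grid <- function(step = 0.01) seq(-4, 4, by = step)

#' Estimate ability from a response pattern
#'
#' Expected a posteriori (EAP): the posterior mean of ability over a fixed
#' grid under the Bernoulli likelihood of the administered items and a
#' standard-normal prior; the posterior standard deviation is reported as
#' the standard error. EAP is defined for every response pattern, including
#' all-correct and all-incorrect, and returns the prior mean 0 with no
#' responses. Maximum likelihood (`method = "ML"`) is offered as an option
#' and maximizes the likelihood over the grid range.
#'
#' @param items Data frame with 4PL columns `a`, `b`, `g`, `u`, one row per
#'   administered item (e.g. rows of [irt_item_bank()]).
#' @param responses 0/1 vector of the same length.
#' @param method `"EAP"` (default) or `"ML"`.
#' @param grid Evaluation grid for EAP, from [ability_grid()].
#' @return An object of class `bdat_ability`: list with `theta`, `se`,
#'   `method`, `n_responses`.
#' @export
estimate_ability <- function(items, responses, method = c("EAP", "ML"),
                             grid = ability_grid()) {
  method <- match.arg(method)
  n <- length(responses)
  if (n == 0) {
    return(structure(list(theta = 0, se = 1, method = method,
                          n_responses = 0L), class = "bdat_ability"))
  }
  if (method == "EAP") {
    lp <- log_likelihood(items, responses, grid) + dnorm(grid, log = TRUE)
    w <- exp(lp - max(lp))
    ## trapezoidal end-point weights: the posterior can lean on the grid
    ## boundary (e.g. all-incorrect patterns), where plain rectangle sums
    ## leave an O(step) error
    w[c(1, length(w))] <- w[c(1, length(w))] / 2
    w <- w / sum(w)
    theta <- sum(w * grid)
    se <- sqrt(sum(w * (grid - theta)^2))
  } else {
    opt <- optimize(function(th) log_likelihood(items, responses, th),
                    range(grid), maximum = TRUE, tol = 1e-6)
    theta <- opt$maximum
    info <- sum(vapply(seq_len(n), function(i)
      item_information(theta, as.list(items[i, ])), 0))
    se <- 1 / sqrt(max(info, .Machine$double.eps))
  }
  structure(list(theta = theta, se = se, method = method,
                 n_responses = as.integer(n)), class = "bdat_ability")
}

#' Pseudo-IQ score
#'
#' Affine rescaling of the z-score ability to the familiar IQ metric:
#' mean 100, standard deviation 15.
#'
#' @param theta Ability value(s).
#' @return `100 + 15 * theta`.
#' @export
pseudo_iq <- function(theta) 100 + 15 * theta

#' Select the next item
#'
#' Default rule: among items whose track has not been used this session
#' (optionally restricted to one condition), pick the item whose difficulty
#' is closest to the target ability; ties are broken by a uniform draw from
#' the caller's RNG stream. `"information"` picks the item with maximum
#' Fisher information at the target instead; `"random"` picks uniformly
#' (the baseline selector for validation).
#'
#' @param bank_irt Item bank with IRT columns, from [irt_item_bank()].
#' @param theta Target ability (0 for the first trial).
#' @param used_tracks Track ids already administered this session.
#' @param condition Optional condition restriction (`"ON"`/`"OFF"`).
#' @param method `"difficulty"` (default), `"information"` or `"random"`.
#' @return The selected item (one-row data frame), or `NULL` when no track
#'   remains.
#' @export
select_next_item <- function(bank_irt, theta = 0, used_tracks = integer(),
                             condition = NULL,
                             method = c("difficulty", "information", "random")) {
  method <- match.arg(method)
  avail <- !(bank_irt$track_id %in% used_tracks)
  if (!is.null(condition)) avail <- avail & bank_irt$condition == condition
  idx <- which(avail)
  if (!length(idx)) return(NULL)
  crit <- switch(method,
    difficulty  = abs(bank_irt$b[idx] - theta),
    information = -vapply(idx, function(i)
      item_information(theta, as.list(bank_irt[i, c("a", "b", "g", "u")])), 0),
    random      = rep(0, length(idx)))
  best <- idx[crit <= min(crit) + 1e-12]
  if (length(best) > 1) best <- best[sample.int(length(best), 1)]
  bank_irt[best, , drop = FALSE]
}

#' Run one adaptive session
#'
#' Administers a fixed-length adaptive test: each trial draws the condition
#' (on-beat with probability `p_on`, mirroring the calibration design),
#' selects the item whose difficulty best matches the running ability
#' estimate (0 before any response), presents it to the response oracle,
#' and re-estimates ability. Each track is used at most once per session.
#' The session is deterministic given the oracle, bank and seed.
#'
#' @param respond Response oracle: a function taking a one-row item data
#'   frame and returning 0 or 1 (see [simulated_responder()]).
#' @param bank An item bank from [build_item_bank()].
#' @param params Parameter pair from [bdat_default_params()].
#' @param length Number of trials (default 25). The bank must contain at
#'   least this many distinct tracks.
#' @param seed Integer seed driving condition scheduling and tie-breaking.
#' @param select Item-selection method, see [select_next_item()].
#' @param p_on Per-trial probability of an on-beat item (default 0.5).
#' @param method Ability estimator, see [estimate_ability()].
#' @return An object of class `bdat_session`: `trials` (per-trial log with
#'   item features, difficulty, response, running `theta` and `se`) and
#'   `final` (ability estimate, standard error, `pseudo_iq`).
#' @export
run_session <- function(respond, bank, params = bdat_default_params(),
                        length = 25, seed = 1,
                        select = c("difficulty", "information", "random"),
                        p_on = 0.5, method = c("EAP", "ML")) {
  select <- match.arg(select)
  method <- match.arg(method)
  if (length(unique(bank$track_id)) < length)
    stop("bank supports only ", length(unique(bank$track_id)),
         " distinct tracks; session needs ", length)
  bank_irt <- if (is.null(bank$b)) irt_item_bank(bank, params) else bank

  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  theta <- 0; se <- 1
  used <- integer()
  administered <- NULL
  responses <- integer()
  trials <- vector("list", length)
  for (t in seq_len(length)) {
    cond <- if (runif(1) < p_on) "ON" else "OFF"
    item <- select_next_item(bank_irt, theta, used, cond, select)
    if (is.null(item))  # condition exhausted; fall back to the other
      item <- select_next_item(bank_irt, theta, used,
                               setdiff(c("ON", "OFF"), cond), select)
    if (is.null(item)) stop("item bank exhausted: session complete")
    y <- respond(item)
    if (!(is.numeric(y) || is.integer(y)) || !(y %in% 0:1))
      stop("protocol error: response oracle must return 0 or 1")
    used <- c(used, item$track_id)
    administered <- rbind(administered, item[, c("a", "b", "g", "u")])
    responses <- c(responses, as.integer(y))
    est <- estimate_ability(administered, responses, method = method)
    theta <- est$theta; se <- est$se
    trials[[t]] <- data.frame(trial = t, item_id = item$item_id,
                              track_id = item$track_id,
                              condition = item$condition,
                              target_beat = item$target_beat,
                              direction = item$direction,
                              displacement_level = item$displacement_level,
                              b = item$b, response = as.integer(y),
                              theta = theta, se = se)
  }
  trials <- do.call(rbind, trials)
  structure(list(trials = trials,
                 final = list(theta = theta, se = se,
                              pseudo_iq = pseudo_iq(theta),
                              n_responses = length(responses),
                              method = method),
                 seed = seed, select = select),
            class = "bdat_session")
}

#' @export
print.bdat_session <- function(x, ...) {
  cat(sprintf("Adaptive session: %d trials, final theta = %.3f (SE %.3f), pseudo-IQ = %.1f\n",
              x$final$n_responses, x$final$theta, x$final$se,
              x$final$pseudo_iq))
  invisible(x)
}

#' Write a session log
#'
#' Per-trial log as CSV and the summary (final ability, standard error,
#' pseudo-IQ, seed) as JSON.
#'
#' @param session A `bdat_session`.
#' @param path Output file (`.csv` for the trial log, `.json` for the
#'   summary).
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "bdat_session"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(final = session$final, seed = session$seed,
                              select = session$select,
                              trials = session$trials),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    write.csv(session$trials, path, row.names = FALSE)
  }
  invisible(path)
}
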