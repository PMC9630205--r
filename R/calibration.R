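## Fitting the explanatory mixed-effects logistic model with fixed
## asymptotes and crossed participant/track random intercepts.
##
## The marginal likelihood integrates the participant random effect by
## Gauss-Hermite quadrature and the track random effect by a Laplace
## approximation. The split reflects where the information lives: each
## participant contributes only ~15 binary responses whose information is
## further diluted by the 0.4 guessing floor, so a mode-based (Laplace)
## treatment of the person integral is visibly biased, whereas each track
## pools responses from every participant and its integral is benign.

## Gauss-Hermite rule against the N(0,1) weight (Golub-Welsch).
gh_rule <- function(K) {
  i <- seq_len(K - 1)
  J <- matrix(0, K, K)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(z = sqrt(2) * e$values[ord], lw = log(e$vectors[1, ord]^2))
}

#' Modified-asymptote logit link
#'
#' A `link-glm` object for a logistic response compressed between fixed
#' asymptotes `g` and `u`, usable with [stats::glm()] or `lme4::glmer()`
#' via `binomial(link = logit_2asym(g, u))`.
#'
#' @param g,u Lower and upper asymptotes, `0 <= g < u <= 1`.
#' @return An object of class `link-glm`.
#' @export
logit_2asym <- function(g, u) {
  stopifnot(g >= 0, g < u, u <= 1)
  eps <- .Machine$double.eps
  linkfun <- function(mu) {
    mu <- pmin(pmax(mu, g + eps), u - eps)
    qlogis((mu - g) / (u - g))
  }
  linkinv <- function(eta) g + (u - g) * plogis(eta)
  mu.eta <- function(eta) (u - g) * dlogis(eta)
  structure(list(linkfun = linkfun, linkinv = linkinv, mu.eta = mu.eta,
                 valideta = function(eta) TRUE,
                 name = sprintf("logit_2asym(%g, %g)", g, u)),
            class = "link-glm")
}

## Model frame for one condition: response, design matrix, 0-based person
## and track indices, rows grouped by person.
calibration_frame <- function(data, condition) {
  d <- data[data$condition == condition, , drop = FALSE]
  if (!nrow(d)) stop("no rows for condition ", condition)
  stopifnot(all(d$response %in% 0:1))
  if (condition == "ON") {
    X <- cbind(intercept = 1, strength = as.numeric(d$target_beat == 3))
  } else {
    late <- as.numeric(d$direction == "late")
    s <- as.numeric(d$target_beat == 3)
    X <- cbind(intercept = 1, displacement = as.numeric(d$displacement_level),
               direction = late, strength = s, direction_x_strength = late * s)
  }
  pid <- as.integer(factor(d$participant_id)) - 1L
  tid <- as.integer(factor(d$track_id)) - 1L
  ord <- order(pid)
  list(y = as.integer(d$response[ord]), X = X[ord, , drop = FALSE],
       pid = pid[ord], tid = tid[ord],
       n_person = max(pid) + 1L, n_track = max(tid) + 1L,
       person_levels = levels(factor(d$participant_id)),
       track_levels = levels(factor(d$track_id)),
       condition = condition)
}

## Laplace step over track effects at fixed (beta, sp, st): Newton with
## ridge safeguard, warm-started from `bt`. Returns the profiled pieces.
track_laplace <- function(fr, beta, sp, st, gh, g, u, bt,
                          tol = 1e-6, max_iter = 50) {
  eta0 <- drop(fr$X %*% beta)
  m <- fr$n_track
  kern <- function(bt, want) {
    asym_glmm_kernel(eta0, fr$y, fr$pid, fr$tid, fr$n_person, m,
                     sp, bt, gh$z, gh$lw, g, u, want)
  }
  h_of <- function(bt, ll) ll - sum(bt^2) / (2 * st^2)
  fw <- kern(bt, 2L)
  h <- h_of(bt, fw$ll)
  for (it in seq_len(max_iter)) {
    grad <- fw$grad - bt / st^2
    if (sqrt(sum(grad^2)) < tol) break
    Ht <- fw$H - diag(1 / st^2, m)
    step <- tryCatch(solve(-Ht, grad), error = function(e) grad * st^2)
    alpha <- 1
    repeat {
      bt_new <- bt + alpha * step
      fw_new <- kern(bt_new, 2L)
      h_new <- h_of(bt_new, fw_new$ll)
      if (h_new >= h - 1e-10 || alpha < 1e-4) break
      alpha <- alpha / 2
    }
    delta <- max(abs(alpha * step))
    bt <- bt_new; fw <- fw_new; h <- h_new
    if (delta < 1e-11) break
  }
  Ht <- fw$H - diag(1 / st^2, m)
  ## -Ht should be positive definite at the mode; ridge if needed
  ridge <- 0
  repeat {
    ch <- tryCatch(chol(-Ht + diag(ridge, m)), error = function(e) NULL)
    if (!is.null(ch)) break
    ridge <- if (ridge == 0) 1e-8 else ridge * 10
  }
  logdet <- 2 * sum(log(diag(ch)))
  ll <- fw$ll - m * log(st) - sum(bt^2) / (2 * st^2) - logdet / 2
  list(ll = ll, bt = bt, eb_person = fw$eb, eta0 = eta0)
}

#' Marginal log-likelihood of the explanatory model
#'
#' Evaluates the marginal likelihood of a calibration dataset under given
#' parameter values, integrating the participant random intercept by
#' Gauss-Hermite quadrature and the track random intercept by a Laplace
#' approximation.
#'
#' @param data Calibration dataset (see [fit_explanatory()]).
#' @param params A [explanatory_params()] object.
#' @param nodes Number of quadrature nodes (default 20).
#' @return Marginal log-likelihood (scalar).
#' @export
marginal_log_likelihood <- function(data, params, nodes = 20) {
  stopifnot(inherits(params, "bdat_explanatory_params"))
  fr <- calibration_frame(data, params$condition)
  gh <- gh_rule(nodes)
  st <- max(params$sigma_track, 1e-6)
  tl <- track_laplace(fr, params$beta[colnames(fr$X)], params$sigma_person,
                      st, gh, params$g, params$u, bt = rep(0, fr$n_track))
  tl$ll
}

#' Fit the explanatory model
#'
#' Maximizes the marginal likelihood of the modified-asymptote mixed logit
#' over the fixed effects and the two random-intercept standard deviations
#' (optimized on the log scale), with the asymptotes held fixed. See the
#' source-file notes for why the participant integral uses quadrature
#' rather than a pure Laplace approximation.
#'
#' @param data Calibration dataset: a data frame with columns
#'   `participant_id`, `track_id`, `condition`, `target_beat`, `direction`,
#'   `displacement_level` and `response` (0/1), e.g. from
#'   [simulate_study1_dataset()].
#' @param condition `"ON"` or `"OFF"`; only rows of this condition are used.
#' @param g,u Fixed asymptotes. `u` defaults to .98 for ON and .96 for OFF.
#' @param nodes Gauss-Hermite nodes for the person integral (default 20).
#' @param se Compute fixed-effect standard errors from a finite-difference
#'   Hessian of the marginal log-likelihood (default `TRUE`).
#' @param start Optional named start values; by default fixed effects start
#'   at a no-random-effect glm fit and both SDs at moderate values.
#' @return An object of class `bdat_fit`: coefficient estimates and
#'   standard errors, `sigma_person`, `sigma_track`, the asymptotes, the
#'   marginal log-likelihood, a convergence flag, empirical-Bayes person
#'   and track effects, and bookkeeping needed by [prediction_accuracy()].
#' @export
fit_explanatory <- function(data, condition = c("ON", "OFF"), g = 0.4,
                            u = NULL, nodes = 20, se = TRUE, start = NULL) {
  condition <- match.arg(condition)
  if (is.null(u)) u <- if (condition == "ON") 0.98 else 0.96
  fr <- calibration_frame(data, condition)
  if (fr$n_person < 2 || fr$n_track < 2)
    stop("need at least 2 participants and 2 tracks")
  if (length(unique(fr$y)) < 2)
    stop("both response values must be present")
  gh <- gh_rule(nodes)
  p <- ncol(fr$X)

  warm <- new.env(parent = emptyenv())
  warm$bt <- rep(0, fr$n_track)
  nll <- function(phi) {
    beta <- phi[seq_len(p)]
    sp <- exp(phi[p + 1]); st <- exp(phi[p + 2])
    tl <- track_laplace(fr, beta, sp, st, gh, g, u, warm$bt)
    warm$bt <- tl$bt
    -tl$ll
  }

  if (is.null(start)) {
    g0 <- suppressWarnings(
      glm.fit(fr$X, fr$y, family = binomial(link = logit_2asym(g, u))))
    start <- c(coef(g0), log_sp = log(1), log_st = log(0.3))
  }
  lower <- c(rep(-20, p), log(1e-3), log(1e-4))
  upper <- c(rep(20, p), log(20), log(20))
  opt <- nlminb(start, nll, lower = lower, upper = upper,
                control = list(iter.max = 500, rel.tol = 1e-8))

  beta <- setNames(opt$par[seq_len(p)], colnames(fr$X))
  sp <- exp(opt$par[p + 1]); st <- exp(opt$par[p + 2])
  tl <- track_laplace(fr, beta, sp, st, gh, g, u, warm$bt)

  se_beta <- rep(NA_real_, p)
  if (se) {
    hess <- fd_hessian(nll, opt$par)
    vc <- tryCatch(solve(hess), error = function(e) matrix(NA, p + 2, p + 2))
    se_all <- suppressWarnings(sqrt(diag(vc)))
    se_beta <- se_all[seq_len(p)]
  }

  structure(list(condition = condition,
                 beta = beta, se = setNames(se_beta, colnames(fr$X)),
                 sigma_person = sp, sigma_track = st, g = g, u = u,
                 logLik = tl$ll,
                 converged = opt$convergence == 0,
                 message = opt$message, iterations = opt$iterations,
                 ranef = list(
                   person = setNames(tl$eb_person, fr$person_levels),
                   track = setNames(tl$bt, fr$track_levels)),
                 frame = fr, nodes = nodes),
            class = "bdat_fit")
}

## central-difference Hessian of a scalar function
fd_hessian <- function(f, x, h = 1e-4) {
  p <- length(x)
  H <- matrix(0, p, p)
  f0 <- f(x)
  step <- function(i, s) { xi <- x; xi[i] <- xi[i] + s; xi }
  for (i in seq_len(p)) {
    H[i, i] <- (f(step(i, h)) - 2 * f0 + f(step(i, -h))) / h^2
    if (i < p) for (j in (i + 1):p) {
      xpp <- x; xpp[c(i, j)] <- xpp[c(i, j)] + h
      xpm <- x; xpm[i] <- xpm[i] + h; xpm[j] <- xpm[j] - h
      xmp <- x; xmp[i] <- xmp[i] - h; xmp[j] <- xmp[j] + h
      xmm <- x; xmm[c(i, j)] <- xmm[c(i, j)] - h
      H[i, j] <- H[j, i] <- (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h^2)
    }
  }
  (H + t(H)) / 2
}

#' @export
print.bdat_fit <- function(x, ...) {
  cat("Explanatory model fit, condition", x$condition, "\n")
  cat(sprintf("  asymptotes g = %.2f, u = %.2f; logLik = %.2f; %s\n",
              x$g, x$u, x$logLik,
              if (x$converged) "converged" else "NOT converged"))
  print(data.frame(estimate = round(x$beta, 3), se = round(x$se, 3)))
  cat(sprintf("  sigma_person = %.3f, sigma_track = %.3f\n",
              x$sigma_person, x$sigma_track))
  invisible(x)
}

#' Conditional prediction accuracy of a fit
#'
#' Proportion of rows whose observed response matches the classification
#' rule "conditional predicted probability > 0.5", with the random effects
#' at their empirical-Bayes estimates (posterior-mean person effects,
#' modal track effects).
#'
#' @param fit A [fit_explanatory()] result.
#' @return Proportion in `[0, 1]`.
#' @export
prediction_accuracy <- function(fit) {
  stopifnot(inherits(fit, "bdat_fit"))
  fr <- fit$frame
  eta <- drop(fr$X %*% fit$beta) +
    unname(fit$ranef$person)[fr$pid + 1L] +
    unname(fit$ranef$track)[fr$tid + 1L]
  p <- fit$g + (fit$u - fit$g) * plogis(eta)
  mean((p > 0.5) == (fr$y == 1))
}

#' Screen tracks for stimulus bias
#'
#' Flags, separately per condition, tracks whose mean response accuracy is
#' strictly below the chance level: a track that listeners systematically
#' get wrong suggests the stimulus itself is misleading rather than hard.
#' A mean exactly at chance is not flagged.
#'
#' @param data Calibration dataset (see [fit_explanatory()]).
#' @param chance Chance accuracy of the binary judgment (default 0.5).
#' @return An object of class `bdat_screen` with element `flagged_tracks`
#'   (data frame `track_id`, `condition`, `mean_accuracy`, `n`).
#' @export
screen_tracks <- function(data, chance = 0.5) {
  agg <- aggregate(response ~ track_id + condition, data = data,
                   FUN = mean)
  cnt <- aggregate(response ~ track_id + condition, data = data,
                   FUN = length)
  agg$n <- cnt$response
  names(agg)[names(agg) == "response"] <- "mean_accuracy"
  flagged <- agg[agg$mean_accuracy < chance, , drop = FALSE]
  rownames(flagged) <- NULL
  structure(list(flagged_tracks = flagged, chance = chance),
            class = "bdat_screen")
}

#' Screen participants for response-set bias
#'
#' Flags participants who gave (nearly) the same on/off judgment on every
#' trial. The judgment is reconstructed from condition and correctness: a
#' correct answer in the ON condition and an incorrect answer in the OFF
#' condition are both "on the beat" judgments.
#'
#' @param data Calibration dataset.
#' @param dominance Proportion at or above which the most frequent judgment
#'   flags a participant (default 0.9). The threshold is inclusive, so
#'   `dominance = 1` flags exactly the constant responders.
#' @return An object of class `bdat_screen` with element
#'   `flagged_participants` (data frame `participant_id`,
#'   `dominant_proportion`, `n`).
#' @export
screen_participants <- function(data, dominance = 0.9) {
  judged_on <- as.numeric((data$condition == "ON") == (data$response == 1))
  agg <- aggregate(judged_on, by = list(participant_id = data$participant_id),
                   FUN = function(v) max(mean(v), 1 - mean(v)))
  cnt <- aggregate(judged_on, by = list(participant_id = data$participant_id),
                   FUN = length)
  names(agg)[2] <- "dominant_proportion"
  agg$n <- cnt$x
  flagged <- agg[agg$dominant_proportion >= dominance, , drop = FALSE]
  rownames(flagged) <- NULL
  structure(list(flagged_participants = flagged, dominance = dominance),
            class = "bdat_screen")
}

#' Monte-Carlo oracle for the marginal log-likelihood
#'
#' Importance-sampling evaluation of the exact marginal likelihood,
#' integrating person and track random effects jointly. Intended as a slow,
#' quadrature-free cross-check of [marginal_log_likelihood()] on small
#' datasets: the proposal is a multivariate t centred at the joint
#' penalized mode with inflated Laplace covariance, so the estimate is
#' unbiased for any proposal and accurate for toy problem sizes.
#'
#' @param data Calibration dataset.
#' @param params A [explanatory_params()].
#' @param n_draws Number of importance draws (default 200000).
#' @param seed RNG seed.
#' @return Estimated marginal log-likelihood.
#' @export
marginal_log_likelihood_mc <- function(data, params, n_draws = 2e5,
                                       seed = 1) {
  stopifnot(inherits(params, "bdat_explanatory_params"))
  fr <- calibration_frame(data, params$condition)
  beta <- params$beta[colnames(fr$X)]
  sp <- max(params$sigma_person, 1e-6)
  st <- max(params$sigma_track, 1e-6)
  g <- params$g; u <- params$u
  eta0 <- drop(fr$X %*% beta)
  n <- fr$n_person; m <- fr$n_track
  dim_tot <- n + m
  sds <- c(rep(sp, n), rep(st, m))

  ## joint log density of (random effects, data)
  h <- function(b) {
    eta <- eta0 + b[fr$pid + 1L] + b[n + fr$tid + 1L]
    p <- g + (u - g) * plogis(eta)
    sum(fr$y * log(p) + (1 - fr$y) * log1p(-p)) + sum(dnorm(b, 0, sds, log = TRUE))
  }
  ## joint mode by BFGS with numerical gradient-free default
  opt <- optim(rep(0, dim_tot), function(b) -h(b), method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  mode <- opt$par
  Hj <- fd_hessian(function(b) -h(b), mode, h = 1e-4)
  ch <- chol(Hj + diag(1e-8, dim_tot))
  ## proposal: multivariate t(df = 8), covariance inflated by 1.5
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  df <- 8
  Z <- matrix(rnorm(n_draws * dim_tot), n_draws, dim_tot)
  scl <- sqrt(1.5)
  chi <- sqrt(rchisq(n_draws, df) / df)
  Draw <- t(mode + scl * backsolve(ch, t(Z / chi)))
  ## log proposal density: multivariate t with Sigma = 1.5 * Hj^{-1}
  delta <- rowSums((Z / chi)^2)
  lq <- lgamma((df + dim_tot) / 2) - lgamma(df / 2) -
    (dim_tot / 2) * log(df * pi) +
    sum(log(diag(ch))) - dim_tot * log(scl) -
    ((df + dim_tot) / 2) * log1p(delta / df)
  lh <- apply(Draw, 1, h)
  lw <- lh - lq
  mx <- max(lw)
  mx + log(mean(exp(lw - mx)))
}
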