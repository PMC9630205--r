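## Independent oracles used across the suite.

## Closed-form inverse of the perceptual-accuracy transform.
pa_inverse_closed_form <- function(pa, exponent = 4) {
  acos(pa^(1 / exponent)) / pi
}

## Expected (Fisher) information by Richardson-extrapolated central
## differences of the expected log-likelihood of a single 4PL item:
## I(theta) = -E_y[d^2/dt^2 log f(y | t)] at t = theta.
info_fd_oracle <- function(theta, item, h = 1e-3) {
  p0 <- item$g + (item$u - item$g) * plogis(item$a * (theta - item$b))
  eloglik <- function(t) {
    p <- item$g + (item$u - item$g) * plogis(item$a * (t - item$b))
    p0 * log(p) + (1 - p0) * log1p(-p)
  }
  d2 <- function(h) -(eloglik(theta + h) - 2 * eloglik(theta) +
                        eloglik(theta - h)) / h^2
  (16 * d2(h / 2) - d2(h)) / 15
}

## Fine-grid trapezoidal quadrature EAP oracle (step 1e-4).
eap_fine_grid_oracle <- function(items, responses, step = 1e-4) {
  grid <- seq(-4, 4, by = step)
  lp <- log_likelihood(items, responses, grid) + dnorm(grid, log = TRUE)
  w <- exp(lp - max(lp))
  w[c(1, length(w))] <- w[c(1, length(w))] / 2
  w <- w / sum(w)
  theta <- sum(w * grid)
  list(theta = theta, se = sqrt(sum(w * (grid - theta)^2)))
}

## A small all-conditions item set with IRT parameters attached.
tiny_irt_items <- function(params = bdat_default_params()) {
  bank <- build_item_bank(n_tracks = 2)
  irt_item_bank(bank, params)
}
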