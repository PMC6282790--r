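# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately avoid the code paths they check.

# OLS by explicit normal equations: beta = (X'X)^-1 X'y.
ols_normal_equations <- function(X, y) {
  X1 <- cbind(1, as.matrix(X))
  as.numeric(solve(t(X1) %*% X1, t(X1) %*% y))
}

# PRESS by explicitly refitting with each observation left out.
press_loo_explicit <- function(X, y) {
  X <- as.matrix(X)
  n <- length(y)
  sum(vapply(seq_len(n), function(i) {
    b <- ols_normal_equations(X[-i, , drop = FALSE], y[-i])
    pred <- as.numeric(c(1, X[i, ]) %*% b)
    (y[i] - pred)^2
  }, numeric(1)))
}

# Noise-free Gaussian trace builder (independent of simulate_chromatogram).
gaussian_trace <- function(centers, heights = 1, sd = 0.1, by = 0.01,
                           duration = 10) {
  tt <- seq(0, duration, by = by)
  heights <- rep_len(heights, length(centers))
  sig <- rowSums(vapply(seq_along(centers), function(i)
    heights[i] * exp(-(tt - centers[i])^2 / (2 * sd^2)),
    numeric(length(tt))))
  list(time = tt, signal = sig)
}

# Random well-conditioned regression dataset for property checks.
random_regression_data <- function(n, p, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  beta <- rnorm(p + 1)
  y <- as.numeric(cbind(1, X) %*% beta) + rnorm(n, 0, 0.5)
  list(X = X, y = y)
}

# Compound table whose %HIA encodes an exact linear logit (for exact-fit
# checks), built directly rather than via the package simulator.
exact_logit_table <- function(n = 12, beta = c(1, 2), seed = 42) {
  set.seed(seed)
  x <- runif(n, 0, 1)
  L <- beta[1] + beta[2] * x
  data.frame(name = paste0("c", seq_len(n)), x = x,
             hia_percent = 100 * 10^L / (1 + 10^L), role = "train")
}
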