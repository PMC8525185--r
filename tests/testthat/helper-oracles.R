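# Independent oracles, written as direct transcriptions of the defining
# formulas (loop/step-up form) so they share no code path with the package.

# Nei-Chesser (1983) two-population bias-corrected gene diversities,
# frequency-only mode (H_O taken at its HWE expectation).
nc83_oracle <- function(p1, p2, n1, n2) {
  nh <- 2 / (1 / n1 + 1 / n2)
  sum_s <- 0
  sum_t <- 0
  for (k in seq_along(p1)) {
    sum_s <- sum_s + (p1[k]^2 + p2[k]^2) / 2
    sum_t <- sum_t + ((p1[k] + p2[k]) / 2)^2
  }
  hs <- 1 - sum_s
  ht <- 1 - sum_t
  ho <- hs
  HS <- nh / (nh - 1) * (hs - ho / (2 * nh))
  HT <- ht + HS / (2 * nh) - ho / (4 * nh)
  list(HT = HT, HS = HS)
}

# Benjamini-Hochberg step-up by explicit backward minimum over the sorted
# p-values.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, m * p[o[i]] / i)
    q[o[i]] <- min(running, 1)
  }
  q
}

# OLS with two covariates solved through the normal equations.
ols_oracle <- function(y, x1, x2) {
  X <- cbind(1, x1, x2)
  XtX <- t(X) %*% X
  b <- solve(XtX, t(X) %*% y)
  r <- y - X %*% b
  df <- length(y) - 3
  s2 <- sum(r^2) / df
  se <- sqrt(diag(s2 * solve(XtX)))
  tt <- as.numeric(b) / as.numeric(se)
  list(b = as.numeric(b), se = as.numeric(se),
       p = as.numeric(2 * stats::pt(-abs(tt), df)), s2 = s2)
}

# Haversine on a 6371-km sphere.
haversine_oracle <- function(lat1, lon1, lat2, lon2) {
  d2r <- pi / 180
  dlat <- (lat2 - lat1) * d2r
  dlon <- (lon2 - lon1) * d2r
  a <- sin(dlat / 2)^2 + cos(lat1 * d2r) * cos(lat2 * d2r) * sin(dlon / 2)^2
  2 * 6371 * asin(pmin(1, sqrt(a)))
}
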