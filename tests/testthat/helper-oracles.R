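# brute-force least-squares oracle: residual sums of squares from the
# normal equations, independent of lm()'s fitting path
rss_of <- function(X, y) {
  beta <- solve(crossprod(X), crossprod(X, y))
  sum((y - X %*% beta)^2)
}

oracle_partial_f <- function(X_full, X_red, y) {
  rf <- rss_of(X_full, y)
  rr <- rss_of(X_red, y)
  q <- ncol(X_full) - ncol(X_red)
  dfe <- length(y) - ncol(X_full)
  ((rr - rf) / q) / (rf / dfe)
}
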