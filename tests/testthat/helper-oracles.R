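# Independent oracles kept deliberately naive: they re-derive results by the
# textbook route, not by the code path under test.

# OLS via the normal equations (X'X)^{-1} X'y, with the classical t test.
ols_oracle <- function(x_tf, x_m, y) {
  X <- cbind(1, x_tf, x_m, x_tf * x_m)
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  df <- length(y) - 4
  sigma2 <- sum(res^2) / df
  V <- solve(XtX)
  se3 <- sqrt(sigma2 * V[4, 4])
  t3 <- beta[4] / se3
  list(beta = as.numeric(beta), se3 = se3, t3 = t3,
       p3 = 2 * pt(abs(t3), df, lower.tail = FALSE))
}

# Benjamini-Hochberg step-up, written out longhand.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[ord[i]] * m / i)
    q[ord[i]] <- prev
  }
  q
}

write_tsv_lines <- function(lines, file = tempfile(fileext = ".tsv")) {
  writeLines(lines, file)
  file
}

# Small well-formed expression fixture built in code.
expr_fixture <- function() {
  write_tsv_lines(c(
    "gene_id\ts1\ts2\ts3\ts4",
    "TP53\t1\t2\t3\t4",
    "MDM2\t0\t0.5\tNA\t7",
    "NR3C1\t10\t20\t30\t40"))
}

psi_fixture <- function() {
  write_tsv_lines(c(
    "event_id\tevent_gene\ts1\ts2\ts3\ts4",
    "EV1\tMDM2\t0\t0.5\t1\tNA",
    "EV2\tTP53\t0.2\t0.4\t0.6\t0.8"))
}
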