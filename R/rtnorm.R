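# Truncated normal sampling by inverse CDF with log-space tail handling.
# Works element-wise over vectors of means/bounds; exact (no rejection),
# stable for truncation regions arbitrarily far into either tail.
rtnorm <- function(n, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  if (any(a >= b)) stop("empty truncation region")
  u <- stats::runif(n)
  z <- numeric(n)
  a <- rep_len(a, n); b <- rep_len(b, n)
  # work in whichever tail keeps the interval probabilities representable
  up <- (a + b) > 0  # interval mostly right of 0: use upper-tail log probs
  if (any(up)) {
    la <- stats::pnorm(a[up], lower.tail = FALSE, log.p = TRUE)
    lb <- stats::pnorm(b[up], lower.tail = FALSE, log.p = TRUE)
    # log of (1-u)*P(Z>a) + u*P(Z>b), interpolated stably from la >= lb
    lp <- la + log1p(u[up] * expm1(lb - la))
    z[up] <- stats::qnorm(lp, lower.tail = FALSE, log.p = TRUE)
  }
  if (any(!up)) {
    la <- stats::pnorm(a[!up], log.p = TRUE)
    lb <- stats::pnorm(b[!up], log.p = TRUE)
    lp <- lb + log1p((1 - u[!up]) * expm1(la - lb))
    z[!up] <- stats::qnorm(lp, log.p = TRUE)
  }
  # guard against -0/rounding pushing a draw onto a finite bound
  z <- pmin(pmax(z, a), b)
  mean + sd * z
}
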