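## Shared fixtures and independent brute-force oracles.

toy_chrom <- function() chromosome_spec("toy", 100000, 40000, 20000)

quick_params <- function(...) polymer_params(...)

## Build a trajectory data.frame by hand from a separation matrix
## (frames x 3) and a resolved flag vector.
make_traj <- function(sep, dt = 30, resolved = NULL, cell_id = "c1",
                      stage = "T0") {
  sep <- as.matrix(sep)
  if (is.null(resolved)) resolved <- rep(TRUE, nrow(sep))
  d <- data.frame(cell_id = cell_id, stage = stage,
                  frame = seq_len(nrow(sep)),
                  t_s = (seq_len(nrow(sep)) - 1) * dt,
                  dx_um = sep[, 1], dy_um = sep[, 2], dz_um = sep[, 3],
                  resolved = resolved, stringsAsFactors = FALSE)
  d$dx_um[!resolved] <- NA_real_
  d$dy_um[!resolved] <- NA_real_
  d$dz_um[!resolved] <- NA_real_
  d
}

## Brute-force pair-loop estimator of the time-averaged mean-square
## increment, the independent oracle for the fast implementation.  X is a
## frames x 3 matrix with NA rows for missing frames.
oracle_msq <- function(X, dt) {
  nf <- nrow(X)
  ok <- stats::complete.cases(X)
  lag <- seq_len(nf - 1)
  val <- rep(NA_real_, nf - 1)
  cnt <- integer(nf - 1)
  for (k in lag) {
    acc <- c()
    for (i in seq_len(nf - k)) {
      if (ok[i] && ok[i + k]) acc <- c(acc, sum((X[i + k, ] - X[i, ])^2))
    }
    cnt[k] <- length(acc)
    if (length(acc)) val[k] <- mean(acc)
  }
  list(lag = lag * dt, value = val, n = cnt)
}

## Monte-Carlo Gaussian-chain oracle for the linear-tether plateau:
## sample end-to-end vectors of an n-step ideal chain with Kuhn length b
## (um) and return 2 * mean squared end-to-end distance.
oracle_plateau_linear <- function(n, b, nsamp = 40000) {
  ee <- matrix(rnorm(3 * nsamp, 0, sqrt(n * b^2 / 3)), nsamp, 3)
  2 * mean(rowSums(ee^2))
}

## Ring oracle: the separation across a ring with arms n1, n2 equals a
## Brownian bridge of length n1 + n2 evaluated at n1.
oracle_plateau_ring <- function(n1, n2, b, nsamp = 40000) {
  n <- n1 + n2
  w1 <- matrix(rnorm(3 * nsamp, 0, sqrt(n1 * b^2 / 3)), nsamp, 3)
  wn <- w1 + matrix(rnorm(3 * nsamp, 0, sqrt(n2 * b^2 / 3)), nsamp, 3)
  br <- w1 - (n1 / n) * wn
  2 * mean(rowSums(br^2))
}
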