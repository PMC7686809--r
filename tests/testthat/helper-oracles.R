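# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# OLS coefficients by the normal equations.
ols_normal_equations <- function(y, X) {
  as.vector(solve(crossprod(X), crossprod(X, y)))
}

# Benjamini-Hochberg step-up from its definition: sort, raw_j = p_(j) * m / j,
# adjusted_(i) = min over j >= i of raw_j, capped at 1, back to input order.
bh_stepup_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  raw <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(raw)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Dense-grid Johnson-Neyman oracle: simple-slope p-values across n_grid points
# of the centered moderator range; returns the grid values where significance
# flips between adjacent points.
jn_grid_oracle <- function(fit, alpha = 0.05, n_grid = 10001) {
  rng <- range(fit$w_observed) - fit$w_center
  w <- seq(rng[1], rng[2], length.out = n_grid)
  b <- fit$coefficients; V <- fit$vcov
  slope <- b[["x"]] + b[["xw"]] * w
  se <- sqrt(V["x", "x"] + 2 * w * V["x", "xw"] + w^2 * V["xw", "xw"])
  p <- 2 * stats::pt(abs(slope / se), df = fit$df2, lower.tail = FALSE)
  sig <- p < alpha
  flips <- which(sig[-1] != sig[-n_grid])
  list(boundaries_centered = (w[flips] + w[flips + 1]) / 2,
       step = diff(w[1:2]), any_sig = any(sig))
}

# Random label matrix (epochs x samples) over k states.
random_label_matrix <- function(n_epochs, n_samples, k) {
  matrix(sample.int(k, n_epochs * n_samples, replace = TRUE),
         nrow = n_epochs)
}

# All permutations of 1..n (n small).
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(setdiff(seq_len(n), i)[sub], nrow = nrow(sub)))
  }))
}

# Small simulated subject shared by several tests (cheap: 20 s).
quick_sim <- function(seed = 11, duration = 20, snr = 3, ...) {
  simulate_subject_eeg(sim_config(record_duration = duration, snr = snr,
                                  seed = seed, ...))
}
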