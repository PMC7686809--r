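fake_behavior <- function(n, seed = 1, wcts = NULL, rses = NULL) {
  set.seed(seed)
  tibble::tibble(
    subject_id = sprintf("s%03d", seq_len(n)),
    wcts_total = if (is.null(wcts)) round(rnorm(n, 100, 10)) else wcts,
    risk_taking = round(rnorm(n, 24, 3)), curiosity = round(rnorm(n, 26, 3)),
    imagination = round(rnorm(n, 26, 3)), challenge = round(rnorm(n, 24, 3)),
    rses_total = if (is.null(rses)) round(rnorm(n, 28, 3)) else rses,
    sex = rbinom(n, 1, 0.7), age = rnorm(n, 18.3, 0.84)
  )
}

test_that("outlier exclusion drops subjects beyond 3 sd on either total", {
  b <- fake_behavior(100, seed = 1)
  b$wcts_total <- round(rnorm(100, 100, 5))
  m <- mean(b$wcts_total); s <- sd(b$wcts_total)
  b$wcts_total[7] <- round(m + 6 * s)  # well beyond 3 sd even after inflation
  res <- exclude_outliers(b)
  expect_equal(res$excluded, "s007")
  expect_equal(nrow(res$behavior), 99L)

  # no-op when nothing exceeds the threshold
  b2 <- fake_behavior(60, seed = 2)
  res2 <- exclude_outliers(b2)
  expect_equal(nrow(res2$behavior), 60L)
  expect_length(res2$excluded, 0L)

  # hand-built 12-row oracle: mean/sd computed explicitly in the test
  w <- c(100, 102, 98, 101, 99, 103, 97, 100, 101, 99, 100, 140)
  r <- rep(28, 12)
  b3 <- fake_behavior(12, seed = 3, wcts = w, rses = r + c(1:6, 1:6) * 0)
  b3$rses_total <- 28 + rep(c(-1, 1), 6)
  out_by_hand <- which(abs(w - mean(w)) / sd(w) > 3 |
                         abs(b3$rses_total - 28) / sd(b3$rses_total) > 3)
  res3 <- exclude_outliers(b3)
  expect_equal(res3$excluded, b3$subject_id[out_by_hand])
})

test_that("correlation table reports Pearson r with t-based p-values", {
  b <- fake_behavior(200, seed = 4)
  b$wcts_total <- 2 * b$rses_total
  ct <- correlation_table(b)
  expect_equal(ct$r[ct$scale == "wcts_total"], 1, tolerance = 1e-12)

  # symmetry of the underlying statistic
  expect_equal(cor(b$rses_total, b$curiosity), cor(b$curiosity, b$rses_total))

  # independent draws stay near zero at large n
  b2 <- fake_behavior(10000, seed = 5)
  ct2 <- correlation_table(b2)
  expect_true(all(abs(ct2$r) < 0.05))

  b3 <- fake_behavior(20, seed = 6)
  b3$curiosity <- 5
  expect_error(correlation_table(b3), "zero-variance")
})

test_that("moderated regression recovers planted coefficients and matches the normal equations", {
  set.seed(7)
  n <- 120
  x <- rnorm(n, 80, 10); w <- rnorm(n, 28, 3)
  sex <- rbinom(n, 1, 0.5); age <- rnorm(n, 18, 1)
  xc <- x - mean(x); wc <- w - mean(w)
  y0 <- 100 + 0.4 * xc - 0.8 * wc + 0.15 * xc * wc + 2 * sex + 0.5 * age
  fit0 <- suppressWarnings(moderated_regression(y0, x, w, sex, age))
  expect_equal(unname(fit0$coefficients[-1]), c(0.4, -0.8, 0.15, 2, 0.5),
               tolerance = 1e-8)

  # against an independent normal-equations oracle, on noisy data
  for (i in 1:20) {
    y <- y0 + rnorm(n, 0, 5)
    fit <- moderated_regression(y, x, w, sex, age)
    X <- cbind(1, xc, wc, xc * wc, sex, age)
    expect_equal(unname(fit$coefficients), ols_normal_equations(y, X),
                 tolerance = 1e-8)
    # F / delta-R2 identity
    expect_equal(fit$f_value, fit$delta_r2 * fit$df2 / (1 - fit$r2_full),
                 tolerance = 1e-10)
    expect_gte(fit$delta_r2, 0)
  }

  expect_error(moderated_regression(y0, x, x, sex, age), "rank-deficient")
})

test_that("simple slopes match the re-centering oracle", {
  set.seed(8)
  n <- 150
  x <- rnorm(n); w <- rnorm(n, 28, 3); sex <- rbinom(n, 1, 0.5); age <- rnorm(n, 18, 1)
  y <- 100 + 0.5 * x + 0.3 * w + 0.2 * x * (w - mean(w)) + rnorm(n, 0, 3)
  fit <- moderated_regression(y, x, w, sex, age)
  ss <- simple_slopes(fit)
  expect_equal(nrow(ss), 2L)
  for (i in 1:2) {
    # oracle: refit with the moderator centered at the probe; the slope and SE
    # of x there equal the conditional slope and its SE
    wshift <- w - ss$w_raw[i]
    xc <- x - mean(x)
    refit <- lm(y ~ xc + wshift + I(xc * wshift) + sex + age)
    expect_equal(ss$slope[i], unname(coef(refit)["xc"]), tolerance = 1e-8)
    expect_equal(ss$se[i], unname(sqrt(vcov(refit)["xc", "xc"])), tolerance = 1e-8)
    expect_equal(ss$t[i], ss$slope[i] / ss$se[i])
  }

  # no interaction: identical slope everywhere
  y2 <- 100 + 0.5 * x + 0.3 * w + rnorm(n, 0, 0.01)
  fit2 <- moderated_regression(y2, x, w, sex, age)
  ss2 <- simple_slopes(fit2, probe_points = c(20, 28, 36))
  expect_lt(diff(range(ss2$slope)), 1e-2)

  # arithmetic: slope(w) = b1 + b3 * wc
  b <- fit$coefficients
  expect_equal(ss$slope, unname(b["x"] + b["xw"] * ss$w_centered))
})

test_that("Johnson-Neyman boundaries agree with the dense-grid oracle", {
  set.seed(9)
  n_checked <- 0
  for (i in 1:25) {
    n <- 150
    x <- rnorm(n); w <- rnorm(n, 28, 3)
    sex <- rbinom(n, 1, 0.5); age <- rnorm(n, 18, 1)
    y <- 100 + rnorm(1, 0, 0.3) * x + 0.3 * w +
      rnorm(1, 0, 0.15) * x * (w - mean(w)) + rnorm(n, 0, 4)
    fit <- moderated_regression(y, x, w, sex, age)
    jn <- johnson_neyman(fit)
    gr <- jn_grid_oracle(fit)
    expect_equal(nrow(jn$boundaries), length(gr$boundaries_centered))
    if (nrow(jn$boundaries) > 0) {
      n_checked <- n_checked + 1
      expect_true(all(abs(sort(jn$boundaries$w_centered) -
                            sort(gr$boundaries_centered)) <= gr$step))
    }
  }
  expect_gt(n_checked, 5)  # the draw produced real boundary cases
})

test_that("Johnson-Neyman handles the no-interaction limits and centering invariance", {
  set.seed(10)
  n <- 200
  x <- rnorm(n); w <- rnorm(n, 28, 3); sex <- rbinom(n, 1, 0.5); age <- rnorm(n, 18, 1)

  # strong main effect, no interaction: significant across the whole range
  y_all <- 100 + 2 * x + rnorm(n, 0, 0.5)
  jn_all <- johnson_neyman(moderated_regression(y_all, x, w, sex, age))
  expect_equal(jn_all$status, "everywhere")

  # no effect at all: nowhere significant
  y_none <- 100 + rnorm(n, 0, 1)
  jn_none <- johnson_neyman(moderated_regression(y_none, x, w, sex, age))
  expect_equal(jn_none$status, "nowhere")

  # boundaries in raw units are invariant to pre-centering the moderator
  y <- 100 + 0.3 * x + 0.3 * w + 0.25 * x * (w - mean(w)) + rnorm(n, 0, 3)
  f1 <- moderated_regression(y, x, w, sex, age)
  f2 <- moderated_regression(y, x, w - mean(w), sex, age)
  j1 <- johnson_neyman(f1); j2 <- johnson_neyman(f2)
  if (nrow(j1$boundaries) > 0) {
    expect_equal(j2$boundaries$w_raw + mean(w), j1$boundaries$w_raw,
                 tolerance = 1e-8)
    expect_equal(j1$boundaries$pct_beyond, j2$boundaries$pct_beyond)
  }
})

test_that("BH adjustment matches the step-up definition and the published family", {
  set.seed(11)
  for (i in 1:50) {
    p <- runif(sample(5:40, 1))
    expect_equal(bh_adjust(p), bh_stepup_bruteforce(p), tolerance = 1e-12)
  }
  p_eq <- rep(0.03, 10)
  expect_equal(bh_adjust(p_eq), p_eq)

  ref <- reference_interaction_tests()
  adj <- bh_adjust(ref$p_uncorrected)
  expect_equal(round(adj[ref$parameter == "contribution_MS2"], 3), 0.024)
  expect_equal(round(adj[ref$parameter == "occurrence_MS3"], 3), 0.030)
  expect_equal(round(adj[ref$parameter == "transition_MS2_MS4"], 3), 0.030)
  expect_equal(round(adj[ref$parameter == "occurrence_MS1"], 3), 0.082)
  expect_error(bh_adjust(c(0.5, 1.2)), "p-values")
})

test_that("the moderation battery reports 24 rows and flags the planted interaction", {
  sim <- sim_config(seed = 1)
  eff <- list(list(parameter = "duration_MS2", b1 = 0, b2 = 0.5, b3 = -0.08))
  cc <- cohort_config(n_subjects = 335, effect_map = eff, noise_sd = 6, seed = 12)
  coh <- simulate_cohort(sim, cc)
  stats_table <- tibble::as_tibble(cbind(
    data.frame(subject_id = coh$behavior$subject_id),
    as.data.frame(coh$true_params)))
  res <- run_moderation_battery(stats_table, coh$behavior)
  expect_equal(nrow(res$report), 24L)
  expect_equal(res$report$parameter, microstate_parameter_names(4))
  expect_true(res$report$significant[res$report$parameter == "duration_MS2"])
  # disordinal pattern: positive slope at low self-esteem, negative at high
  ss <- res$followups$duration_MS2$simple_slopes
  expect_gt(ss$slope[1], 0)
  expect_lt(ss$slope[2], 0)
  # and the Johnson-Neyman regions agree: significant-positive below the
  # lower boundary, significant-negative above the upper one
  jb <- res$followups$duration_MS2$johnson_neyman$boundaries
  expect_equal(jb$direction, c("below", "above"))
  expect_equal(jb$slope_sign, c(1, -1))
  expect_lt(jb$w_raw[1], jb$w_raw[2])

  bad <- stats_table; bad$subject_id[1] <- "nope"
  expect_error(run_moderation_battery(bad, coh$behavior), "subject ids")
})
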