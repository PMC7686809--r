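test_that("GFP matches its definition and is reference-shift invariant", {
  expect_equal(compute_gfp(matrix(c(3, 3, 3), 3, 1)), 0)
  expect_equal(compute_gfp(matrix(c(1, -1), 2, 1)), 1)
  expect_equal(compute_gfp(matrix(c(2, 0, 0, -2), 4, 1)), sqrt(2))
  set.seed(1)
  X <- matrix(rnorm(40), 8, 5)
  expect_equal(compute_gfp(X + 7), compute_gfp(X), tolerance = 1e-12)
})

test_that("GFP peak detection follows the strict-maximum and plateau rules", {
  expect_equal(find_gfp_peaks(c(1, 3, 2)), 2L)
  expect_equal(find_gfp_peaks(c(1, 2, 3, 4, 5)), integer(0))
  expect_equal(find_gfp_peaks(c(1, 3, 3, 1)), 2L)   # first sample of a plateau
  expect_equal(find_gfp_peaks(c(5, 1, 5)), integer(0))  # endpoints never peaks
  expect_equal(find_gfp_peaks(c(1, 3, 1, 4, 1)), c(2L, 4L))
})

test_that("spatial similarity satisfies the GMD-correlation identity", {
  set.seed(2)
  u <- rnorm(16)
  s <- spatial_similarity(u, u)
  expect_equal(s$C, 1, tolerance = 1e-12)
  expect_equal(s$gmd, 0, tolerance = 1e-6)

  sp <- spatial_similarity(u, -u, polarity_invariant = TRUE)
  expect_equal(sp$C, 1, tolerance = 1e-12)
  ss <- spatial_similarity(u, -u, polarity_invariant = FALSE)
  expect_equal(ss$C, -1, tolerance = 1e-12)
  expect_equal(ss$gmd, 2, tolerance = 1e-6)

  # mean-removed orthogonal maps: C = 0, GMD = sqrt(2)
  a <- c(1, -1, 1, -1); b <- c(1, 1, -1, -1)
  so <- spatial_similarity(a, b, polarity_invariant = FALSE)
  expect_equal(so$C, 0, tolerance = 1e-12)
  expect_equal(so$gmd, sqrt(2), tolerance = 1e-12)

  # identity on random pairs
  for (i in 1:20) {
    v <- rnorm(16); w <- rnorm(16)
    sv <- spatial_similarity(v, w, polarity_invariant = FALSE)
    expect_equal(sv$gmd^2 + 2 * sv$C, 2, tolerance = 1e-10)
  }
  expect_error(spatial_similarity(rep(1, 4), rnorm(4)), "flat")
})

test_that("AAHC recovers planted templates from noiseless sign-flipped maps", {
  set.seed(3)
  tm <- generate_templates(64, 4, seed = 3)
  lab <- sample.int(4, 1000, replace = TRUE)
  amp <- runif(1000, 0.5, 2) * sample(c(-1, 1), 1000, replace = TRUE)
  maps <- tm[, lab] * matrix(amp, 64, 1000, byrow = TRUE)
  sets <- aahc_cluster(maps, k_range = 4)
  ts <- sets[["4"]]
  C <- abs(crossprod(tm, ts$maps))
  expect_equal(dim(ts$maps), c(64L, 4L))
  # permutation/sign resolved via best match per planted template
  expect_true(all(apply(C, 1, max) >= 0.999))
  expect_equal(ts$gev, 1, tolerance = 1e-6)

  # determinism
  sets2 <- aahc_cluster(maps, k_range = 4)
  expect_identical(sets[["4"]]$maps, sets2[["4"]]$maps)
})

test_that("AAHC centroids are polarity invariant and k = M returns the inputs", {
  u <- generate_templates(16, 1, seed = 7)[, 1]
  res <- aahc_cluster(cbind(u, -u), k_range = 1)[["1"]]
  expect_equal(abs(sum(res$maps[, 1] * u)), 1, tolerance = 1e-10)

  set.seed(8)
  V <- matrix(rnorm(16 * 5), 16, 5)
  res5 <- aahc_cluster(V, k_range = 5)[["5"]]
  Vn <- apply(V, 2, function(v) { v <- v - mean(v); v / sqrt(sum(v^2)) })
  C <- abs(crossprod(Vn, res5$maps))
  expect_true(all(apply(C, 1, max) > 1 - 1e-10))
})

test_that("segmentation is invariant to flipping the polarity of every input map", {
  set.seed(9)
  tm <- generate_templates(32, 4, seed = 9)
  lab <- sample.int(4, 300, replace = TRUE)
  maps <- tm[, lab] + matrix(rnorm(32 * 300, sd = 0.1), 32)
  a <- aahc_cluster(maps, k_range = 3:5)
  b <- aahc_cluster(-maps, k_range = 3:5)
  for (k in names(a)) {
    expect_equal(abs(diag(crossprod(a[[k]]$maps, b[[k]]$maps))),
                 rep(1, a[[k]]$k), tolerance = 1e-8)
    expect_equal(a[[k]]$cv_value, b[[k]]$cv_value, tolerance = 1e-10)
    expect_equal(a[[k]]$gev, b[[k]]$gev, tolerance = 1e-10)
  }
})

test_that("the CV criterion matches its closed form and penalizes extra templates", {
  # Construct maps = orthonormal template + residual of squared norm N - 1,
  # residual orthogonal to all templates: sigma^2 is exactly 1.
  set.seed(10)
  N <- 64
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(N * 10), N))))[, 2:11]  # zero-mean frame
  templates <- Q[, 1:4]
  M <- 40
  maps <- sapply(seq_len(M), function(i) {
    k <- ((i - 1) %% 4) + 1
    resid <- Q[, 5 + (i %% 5)] * sqrt(N - 1)
    3 * templates[, k] + resid
  })
  ts4 <- microstates:::new_template_set(templates)
  cv <- cv_criterion(maps, ts4)
  expect_equal(cv, ((N - 1) / (N - 1 - 4))^2, tolerance = 1e-10)

  # same maps, extra template orthogonal to every map: sigma^2 unchanged,
  # penalty strictly larger
  ts5 <- microstates:::new_template_set(cbind(templates, Q[, 10]))
  maps5 <- sapply(seq_len(M), function(i) {
    k <- ((i - 1) %% 4) + 1
    3 * templates[, k] + Q[, 5 + (i %% 4)] * sqrt(N - 1)
  })
  cv4 <- cv_criterion(maps5, ts4)
  cv5 <- cv_criterion(maps5, ts5)
  expect_equal(cv5 / cv4, ((N - 1 - 4) / (N - 1 - 5))^2, tolerance = 1e-8)
  expect_gt(cv5, cv4)

  expect_error(cv_criterion(maps[1:5, ], microstates:::new_template_set(matrix(rnorm(20), 5))),
               "CV undefined")
})

test_that("select_optimal_k picks the smallest k among CV ties", {
  mk <- function(k, cv) {
    ts <- microstates:::new_template_set(matrix(rnorm(8 * k), 8))
    ts$cv_value <- cv
    ts
  }
  sets <- list("2" = mk(2, 1.5), "3" = mk(3, 1.0), "4" = mk(4, 1.0))
  expect_equal(select_optimal_k(sets), 3L)
})

test_that("GEV is 1 for a perfect fit, 0 for orthogonal templates, and ranks labelings", {
  set.seed(11)
  tm <- generate_templates(32, 4, seed = 11)
  lab <- sample.int(4, 200, replace = TRUE)
  amp <- runif(200, 0.5, 2)
  maps <- tm[, lab] * matrix(amp, 32, 200, byrow = TRUE)
  ts <- microstates:::new_template_set(tm)
  expect_equal(compute_gev(maps, NULL, ts, lab), 1, tolerance = 1e-10)

  # templates orthogonal to every map
  maps10 <- maps[, 1:10]
  Q <- qr.Q(qr(cbind(1, maps10, matrix(rnorm(32 * 5), 32))))
  orth <- Q[, 13:16]
  tso <- microstates:::new_template_set(orth)
  expect_lt(compute_gev(maps10, NULL, tso, rep(1L, 10)), 1e-12)

  # correct labels beat random labels on noisy structured data
  noisy <- maps + matrix(rnorm(32 * 200, sd = 0.3), 32)
  backfit <- max.col(t(abs(crossprod(tm, noisy))), ties.method = "first")
  rand <- sample(backfit)
  expect_gt(compute_gev(noisy, NULL, ts, backfit),
            compute_gev(noisy, NULL, ts, rand))
})

test_that("backfit labels maximize GEV over exhaustive label permutations", {
  set.seed(12)
  tm <- generate_templates(16, 3, seed = 12)
  lab <- sample.int(3, 30, replace = TRUE)
  maps <- tm[, lab] + matrix(rnorm(16 * 30, sd = 0.2), 16)
  ts <- microstates:::new_template_set(tm)
  backfit <- max.col(t(abs(crossprod(tm, maps))), ties.method = "first")
  g_best <- compute_gev(maps, NULL, ts, backfit)
  for (p in seq_len(nrow(all_perms(3)))) {
    perm <- all_perms(3)[p, ]
    expect_lte(compute_gev(maps, NULL, ts, perm[backfit]), g_best + 1e-12)
  }
})

test_that("group clustering reduces pooled subject sets sensibly", {
  tm <- generate_templates(32, 4, seed = 13)
  ts <- microstates:::new_template_set(tm)

  # identical subject sets: group maps equal them up to sign/permutation
  g <- group_cluster(list(ts, ts, ts), 4)
  C <- abs(crossprod(tm, g$maps))
  expect_true(all(apply(C, 1, max) > 1 - 1e-8))
  expect_equal(g$source, "group")

  # single subject: identity up to sign/permutation
  g1 <- group_cluster(list(ts), 4)
  expect_true(all(apply(abs(crossprod(tm, g1$maps)), 1, max) > 1 - 1e-10))

  # noisy subject sets still recover the planted maps
  set.seed(14)
  noisy_sets <- lapply(1:6, function(i) {
    m <- tm + matrix(rnorm(32 * 4, sd = 0.05), 32)
    microstates:::new_template_set(microstates:::unit_norm_cols(
      microstates:::remove_map_means(m)))
  })
  gn <- group_cluster(noisy_sets, 4)
  expect_true(all(apply(abs(crossprod(tm, gn$maps)), 1, max) >= 0.99))

  expect_error(group_cluster(list(ts), 5), "fewer pooled maps")
})
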