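test_that("spike detection applies the mean + 2.5 sd rule strictly", {
  expect_length(detect_spikes(rep(0.2, 50)), 0L)

  fd <- rep(0.1, 100); fd[37] <- 5
  thresh <- mean(fd) + 2.5 * sd(fd)            # hand oracle
  expect_identical(which(fd > thresh), 37L)
  expect_equal(detect_spikes(fd), 37L)

  # points exactly at the threshold are not spikes (strict inequality)
  fd2 <- c(rep(0, 10), rep(1, 2))
  at <- mean(fd2) + 2.5 * sd(fd2)
  fd3 <- rep(at, 12)
  expect_length(detect_spikes(fd3), 0L)
})

test_that("spline despiking restores smooth signals exactly", {
  tgrid <- 1:40
  cubic <- cbind(0.01 * tgrid^3 - 0.2 * tgrid^2 + tgrid, 2 * tgrid + 5)
  spiked <- cubic
  spiked[c(12, 27), ] <- 99
  fixed <- despike(spiked, c(12, 27))
  expect_equal(fixed, cubic, tolerance = 1e-6)

  # untouched when there is nothing to fix
  expect_identical(despike(cubic, integer(0)), cubic)

  # a linear signal gets the linear interpolant back
  lin <- matrix(3 * tgrid - 1, ncol = 1)
  lin_sp <- lin; lin_sp[20, ] <- 1000
  expect_equal(despike(lin_sp, 20)[20, 1], 3 * 20 - 1, tolerance = 1e-8)

  expect_error(despike(cubic, 4:40), "too few")
})

test_that("time-course cleaning drops, regresses and despikes", {
  set.seed(101)
  T0 <- 162L
  mot <- matrix(rnorm(T0 * 24), T0, 24)
  vals <- matrix(rnorm(T0 * 3), T0, 3)
  tc <- timecourse(vals, fd = abs(rnorm(T0, 0.1, 0.02)), motion = mot)
  out <- clean_timecourse(tc)
  expect_equal(nrow(out$values), 160L)
  expect_equal(length(out$fd), 160L)

  # signal exactly spanned by the motion regressors vanishes
  beta <- rnorm(24)
  tc_m <- timecourse(cbind(mot %*% beta + 2), motion = mot)
  out_m <- clean_timecourse(tc_m)
  expect_lt(max(abs(out_m$values)), 1e-8)

  # all-zero motion regressors only remove the mean
  tc_z <- timecourse(vals, motion = matrix(0, T0, 24))
  out_z <- clean_timecourse(tc_z)
  trimmed <- vals[3:T0, , drop = FALSE]
  expect_equal(out_z$values, sweep(trimmed, 2, colMeans(trimmed)),
               tolerance = 1e-10, ignore_attr = TRUE)

  expect_error(timecourse(vals, motion = mot[1:10, ]), "mismatch")
})

test_that("sliding windows follow the T - w counting convention", {
  set.seed(103)
  tc <- matrix(rnorm(162 * 4), 162, 4)
  fnc <- sliding_windows(tc, 22)
  expect_length(fnc$windows, 140L)
  expect_equal(nrow(fnc$vectorized), 140L)
  expect_equal(ncol(fnc$vectorized), 4 * 3 / 2)

  expect_length(sliding_windows(matrix(rnorm(23 * 2), 23, 2), 22)$windows, 1L)
  expect_error(sliding_windows(matrix(rnorm(22 * 2), 22, 2), 22), "exceed")

  # each window is the sample covariance of its slice, row-wise upper triangle
  C5 <- cov(tc[5:26, ])
  expect_equal(fnc$windows[[5]], C5)
  expect_equal(fnc$vectorized[5, ], t(C5)[lower.tri(C5)])

  # i.i.d. unit-variance components: off-diagonals near 0 at w = 500
  big <- sliding_windows(matrix(rnorm(501 * 3), 501, 3), 500)
  expect_lt(max(abs(big$vectorized[1, ])), 4 / sqrt(500))
})

test_that("exemplars sit at strict interior local maxima of the variance series", {
  base <- c(-1, 1, -2, 2)                      # var(base) scales with b^2
  b <- rep(1, 120)
  b[c(10, 50, 90)] <- 3
  fake <- structure(list(vectorized = outer(b, base), w = 5L, r = 3L),
                    class = "windowed_fnc")
  expect_equal(select_exemplars(fake), c(10L, 50L, 90L))

  mono <- structure(list(vectorized = outer(seq_len(50), base)),
                    class = "windowed_fnc")
  expect_equal(select_exemplars(mono), 50L)      # fallback: global max

  flat <- structure(list(vectorized = outer(rep(1, 50), base)),
                    class = "windowed_fnc")
  expect_equal(select_exemplars(flat), 1L)       # constant: first index
})

test_that("correlation distance has its defining geometry", {
  a <- rnorm(10)
  expect_equal(correlation_distance(a, a), 0)
  expect_equal(correlation_distance(a, -a), 2)
  x <- c(1, -1, 1, -1); y <- c(1, 1, -1, -1)    # zero-mean orthogonal
  expect_equal(correlation_distance(x, y), 1)
  expect_error(correlation_distance(a, rep(1, 10)), "constant")
})

test_that("single-site decentralized K-Means is Lloyd's algorithm", {
  set.seed(107)
  X <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(70, 4), 35, 2))
  init <- X[c(1, 40), ]
  ours <- dkmeans(list(X), k = 2, init = init, distance = "euclidean")
  oracle <- suppressWarnings(
    kmeans(X, centers = init, algorithm = "Lloyd", iter.max = 100))
  expect_equal(ours$assignments[[1]], unname(oracle$cluster))
  expect_equal(ours$centroids, oracle$centers, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("multi-site K-Means merges by counts and matches a pooled run", {
  set.seed(109)
  blob1 <- matrix(rnorm(40, 0, 0.1), 20, 2)
  blob2 <- matrix(rnorm(50, 5, 0.1), 25, 2)
  init <- rbind(colMeans(blob1), colMeans(blob2))
  fit <- dkmeans(list(blob1, blob2), k = 2, init = init,
                 distance = "euclidean")
  expect_equal(fit$centroids, rbind(colMeans(blob1), colMeans(blob2)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(sum(fit$counts), 45L)

  # split vs pooled with identical init and synchronized updates
  X <- rbind(blob1, blob2)
  pooled <- dkmeans(list(X), k = 2, init = init, distance = "euclidean")
  split2 <- dkmeans(list(X[1:13, ], X[14:45, ]), k = 2, init = init,
                    distance = "euclidean")
  expect_equal(pooled$centroids, split2$centroids, tolerance = 1e-12)

  # converged centroids are a fixed point
  again <- dkmeans(list(blob1, blob2), k = 2, init = fit$centroids,
                   distance = "euclidean")
  expect_equal(again$centroids, fit$centroids, tolerance = 1e-12)

  # count-weighted merge identity: k = 1 centroid is the global mean
  one <- dkmeans(list(blob1, blob2), k = 1, init = rbind(rep(0, 2)),
                 distance = "euclidean")
  expect_equal(drop(one$centroids), colMeans(rbind(blob1, blob2)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("K-Means rounds log the centroid payloads both ways", {
  set.seed(113)
  X1 <- matrix(rnorm(40 * 6), 40, 6)
  X2 <- matrix(rnorm(30 * 6), 30, 6)
  log <- message_log()
  fit <- dkmeans(list(a = X1, b = X2), k = 3, init = X1[1:3, ],
                 distance = "euclidean", log = log)
  df <- as.data.frame(log)
  up <- df[df$sender == "a" & df$receiver == "AGG", ]
  expect_equal(nrow(up), fit$iterations)
  expect_true(all(up$scalar_count == 3 * 6))
  expect_equal(sum(df[df$sender == "AGG", "scalar_count"]),
               predicted_dkmeans_bandwidth(
                 bandwidth_model(r = 3, k = 3, J = fit$iterations, s = 2),
                 is_aggregator = TRUE) * 2 / 3)  # feature size 6 vs r^2 = 9
})

test_that("the full pipeline recovers planted connectivity states", {
  gen <- gen_fmri_subjects(fmri_truth(n_subjects = 8L, n_sites = 2L,
                                      T_len = 120L, seed = 31L))
  tr <- gen$truth
  cfg <- ddfnc_config(w = tr$w, k = tr$k, n_init = 30L, seed = 17L)
  res <- run_ddfnc(as_site_timecourses(gen), cfg)
  score <- ddfnc_state_accuracy(res, gen)
  expect_gte(mean(score$centroid_correlations), 0.9)
  expect_gte(score$accuracy, 0.9)
  expect_equal(sum(res$model$counts),
               sum(lengths(unlist(res$labels, recursive = FALSE))))

  # k = 1 degenerates to the global mean of all window features
  one <- run_ddfnc(as_site_timecourses(gen),
                   ddfnc_config(w = tr$w, k = 1L, n_init = 2L, seed = 5L))
  feats <- do.call(rbind, lapply(as_site_timecourses(gen), function(subjects)
    do.call(rbind, lapply(subjects, function(tc)
      sliding_windows(clean_timecourse(tc), tr$w)$vectorized))))
  expect_equal(drop(one$model$centroids), colMeans(feats), tolerance = 1e-10)
})
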