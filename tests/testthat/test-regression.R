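test_that("local objective matches a naive loop oracle", {
  # perfect fit on noiseless data
  X <- cbind(runif(10), 1)
  w <- c(2, -1)
  s <- site_dataset("a", X, X %*% w)
  expect_equal(local_objective(s, w), 0)

  # single point x=[1;1], y=2, w=0 -> 2^2
  s1 <- site_dataset("b", matrix(c(1, 1), 1), 2)
  expect_equal(local_objective(s1, c(0, 0)), 4)

  set.seed(11)
  X <- cbind(matrix(rnorm(40), 20, 2), 1)
  y <- rnorm(20)
  w <- rnorm(3)
  s <- site_dataset("c", X, y)
  acc <- 0
  for (i in 1:20) acc <- acc + (y[i] - sum(w * X[i, ]))^2
  expect_equal(local_objective(s, w), acc, tolerance = 1e-12)
})

test_that("local gradients sum to the pooled gradient and match finite differences", {
  sites <- random_sites(n = 60, d = 3, S = 3, seed = 4)
  pooled_X <- do.call(rbind, lapply(sites, `[[`, "design"))
  pooled_y <- do.call(rbind, lapply(sites, `[[`, "response"))
  w <- rnorm(4)

  pooled_grad <- drop(2 * crossprod(pooled_X, pooled_X %*% w - pooled_y))
  site_sum <- Reduce(`+`, lapply(sites, local_gradient, w = w))
  expect_equal(site_sum, pooled_grad, tolerance = 1e-12)

  # zero at the pooled least-squares optimum
  wstar <- qr.coef(qr(pooled_X), pooled_y)
  opt_sum <- Reduce(`+`, lapply(sites, local_gradient, w = wstar))
  expect_lt(max(abs(opt_sum)), 1e-9)

  # central finite differences of the local objective
  s <- sites[[1L]]
  g <- local_gradient(s, w)
  h <- 1e-4
  fd <- vapply(seq_along(w), function(m) {
    e <- rep(0, length(w)); e[m] <- h
    (local_objective(s, w + e) - local_objective(s, w - e)) / (2 * h)
  }, 0)
  expect_equal(g, fd, tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("single-shot averages local solutions by sample size", {
  set.seed(21)
  # weighted-average property against per-site lm solutions
  sites <- random_sites(n = 90, d = 2, S = 3, seed = 9)
  fit <- single_shot_fit(sites)
  wj <- lapply(sites, function(s) qr.coef(qr(s$design), s$response))
  nj <- vapply(sites, function(s) s$n_j, 0L)
  manual <- Reduce(`+`, Map(`*`, wj, nj)) / sum(nj)
  expect_equal(fit$weights, drop(manual), tolerance = 1e-12,
               ignore_attr = TRUE)

  # identical data replicated at every site -> global equals any local solution
  X <- cbind(rnorm(20), 1); y <- rnorm(20)
  rep_sites <- lapply(1:3, function(j) site_dataset(paste0("s", j), X, y))
  fit_rep <- single_shot_fit(rep_sites)
  expect_equal(fit_rep$weights, drop(qr.coef(qr(X), y)), tolerance = 1e-12,
               ignore_attr = TRUE)

  # locally collinear design is refused
  bad <- site_dataset("bad", cbind(c(1, 1, 1), 1), rnorm(3))
  expect_error(single_shot_fit(list(bad)), "collinearity")
})

test_that("DRNE equals the pooled solution for any partition", {
  # exact line through two one-sample sites
  s1 <- site_dataset("s1", matrix(c(1, 1), 1), 2)
  s2 <- site_dataset("s2", matrix(c(3, 1), 1), 4)
  fit <- drne_fit(list(s1, s2))
  expect_equal(fit$weights, c(1, 1), tolerance = 1e-12, ignore_attr = TRUE)

  # pooled least-squares oracle, and invariance to re-partitioning
  set.seed(2)
  X <- cbind(matrix(rnorm(240), 80, 3), 1)
  Y <- matrix(rnorm(160), 80, 2)
  pooled <- site_dataset("all", X, Y)
  w_oracle <- qr.coef(qr(X), Y)
  f3 <- drne_fit(partition_dataset(pooled, rep(1 / 3, 3), seed = 5))
  f2 <- drne_fit(partition_dataset(pooled, c(0.4, 0.6), seed = 6))
  f5 <- drne_fit(partition_dataset(pooled, rep(0.2, 5), seed = 7))
  expect_lt(max(abs(f3$weights - w_oracle)), 1e-10)
  expect_lt(max(abs(f2$weights - f5$weights)), 1e-10)

  # globally collinear design is refused
  Xc <- cbind(X[, 1], X[, 1], 1)
  sc <- site_dataset("c", Xc, Y[, 1])
  expect_error(drne_fit(list(sc)), "collinearity")
})

test_that("multi-shot converges to the normal-equation solution", {
  s1 <- site_dataset("s1", matrix(c(1, 1), 1), 2)
  s2 <- site_dataset("s2", matrix(c(3, 1), 1), 4)
  fit <- multi_shot_fit(list(s1, s2))
  expect_true(fit$converged)
  expect_equal(fit$weights, c(1, 1), tolerance = 1e-4, ignore_attr = TRUE)

  sites <- random_sites(n = 180, d = 5, S = 3, seed = 13)
  ref <- drne_fit(sites)
  ms <- multi_shot_fit(sites)
  expect_true(ms$converged)
  expect_lt(max(abs(ms$weights - ref$weights)), 1e-4)

  # started at the optimum, the gradient-norm stop fires immediately
  warm <- multi_shot_fit(sites, w0 = ref$weights)
  expect_true(warm$converged)
  expect_equal(warm$iterations, 1L)

  # an impossible iteration budget is reported, not hidden
  tight <- multi_shot_fit(sites, optimizer_config(max_iterations = 3L))
  expect_false(tight$converged)
  expect_equal(tight$iterations, 3L)
})

test_that("multi-shot rounds are logged symmetrically site<->aggregator", {
  sites <- random_sites(n = 30, d = 2, S = 2, seed = 3)
  log <- message_log()
  fit <- multi_shot_fit(sites, log = log)
  df <- as.data.frame(log)
  grad_msgs <- df[df$receiver == "AGG" & df$scalar_count == 3, ]
  expect_equal(nrow(grad_msgs), 2L * fit$iterations)
  bcast <- df[df$sender == "AGG", ]
  expect_equal(nrow(bcast), 2L * fit$iterations)
})

test_that("decentralized R^2 equals the pooled computation", {
  # noiseless data at the true weights
  X <- cbind(rnorm(30), 1)
  w <- c(1.5, -2)
  sites <- list(site_dataset("a", X[1:10, ], (X %*% w)[1:10]),
                site_dataset("b", X[11:30, ], (X %*% w)[11:30]))
  r2 <- decentralized_r2(sites, w)
  expect_equal(r2$r_squared, 1)

  # intercept-only model fit to its own data: SSE = SST
  y <- rnorm(25)
  io <- list(site_dataset("a", matrix(1, 10), y[1:10]),
             site_dataset("b", matrix(1, 15), y[11:25]))
  wbar <- drne_fit(io)$weights
  r2io <- decentralized_r2(io, wbar)
  expect_equal(r2io$r_squared, 0, tolerance = 1e-12)

  # pooled oracle at the DRNE weights
  sites <- random_sites(n = 90, d = 3, S = 3, seed = 17)
  w <- drne_fit(sites)$weights
  Xp <- do.call(rbind, lapply(sites, `[[`, "design"))
  yp <- do.call(rbind, lapply(sites, `[[`, "response"))
  sse_p <- sum((yp - Xp %*% w)^2)
  sst_p <- sum((yp - mean(yp))^2)
  dec <- decentralized_r2(sites, w)
  expect_lt(abs(dec$r_squared - (1 - sse_p / sst_p)), 1e-10)

  const <- list(site_dataset("a", matrix(1, 5), rep(2, 5)))
  expect_error(decentralized_r2(const, 2), "SST")
})

test_that("decentralized t/p values match the pooled OLS oracle", {
  sites <- random_sites(n = 120, d = 3, S = 4, seed = 23)
  w <- drne_fit(sites)$weights
  tv <- decentralized_tvalues(sites, w)

  Xp <- do.call(rbind, lapply(sites, `[[`, "design"))
  yp <- drop(do.call(rbind, lapply(sites, `[[`, "response")))
  fit <- lm(yp ~ Xp - 1)
  oracle <- summary(fit)$coefficients
  expect_equal(drop(tv$t_values), unname(oracle[, "t value"]),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(drop(tv$p_values), unname(oracle[, "Pr(>|t|)"]),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(tv$dof, fit$df.residual)

  # a coefficient of exactly zero scores t = 0, p = 1
  w0 <- drop(w); w0[2] <- 0
  tv0 <- decentralized_tvalues(sites, w0)
  expect_equal(drop(tv0$t_values)[[2]], 0)
  expect_equal(drop(tv0$p_values)[[2]], 1)

  # flipping a covariate's sign flips its t, p unchanged
  flipped <- lapply(sites, function(s) {
    X <- s$design; X[, 1] <- -X[, 1]
    site_dataset(s$site_id, X, s$response)
  })
  wf <- drne_fit(flipped)$weights
  tvf <- decentralized_tvalues(flipped, wf)
  expect_equal(drop(tvf$t_values)[[1]], -drop(tv$t_values)[[1]],
               tolerance = 1e-8)
  expect_equal(drop(tvf$p_values), drop(tv$p_values), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("partition invariance holds for fits and inference", {
  set.seed(31)
  X <- cbind(matrix(rnorm(300), 100, 3), 1)
  Y <- matrix(rnorm(200), 100, 2)
  pooled <- site_dataset("all", X, Y)
  a <- partition_dataset(pooled, c(0.3, 0.3, 0.4), seed = 1)
  b <- partition_dataset(pooled, rep(0.25, 4), seed = 2)
  fa <- drne_fit(a); fb <- drne_fit(b)
  expect_lt(max(abs(fa$weights - fb$weights)), 1e-10)
  expect_lt(max(abs(fa$r_squared - fb$r_squared)), 1e-10)
  expect_lt(max(abs(fa$t_values - fb$t_values)), 1e-8)
})

test_that("sum and sample-size-weighted-mean gradient aggregation share the optimum", {
  sites <- random_sites(n = 90, d = 3, S = 3, seed = 37)
  wstar <- drne_fit(sites)$weights
  grads <- lapply(sites, local_gradient, w = wstar)
  nj <- vapply(sites, function(s) s$n_j, 0L)
  sum_g <- Reduce(`+`, grads)
  mean_g <- Reduce(`+`, Map(`*`, grads, nj / sum(nj)))
  expect_lt(max(abs(sum_g)), 1e-8)
  expect_lt(max(abs(mean_g)), 1e-8)
})
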