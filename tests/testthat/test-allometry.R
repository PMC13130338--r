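test_that("noiseless allometric signal is recovered exactly", {
  set.seed(61)
  n <- 40L; d <- 6L
  s <- stats::runif(n, 10, 30)
  beta <- stats::rnorm(d)
  alpha <- stats::rnorm(d)
  V <- rep(1, n) %*% t(alpha) + s %*% t(beta)
  m <- allometric_regression(V, s)
  expect_lt(m$wilks_lambda, 1e-10)
  expect_equal(m$r_squared, 1, tolerance = 1e-10)
  expect_equal(m$slope, beta, tolerance = 1e-8)
  expect_equal(m$intercept, alpha, tolerance = 1e-6)
  expect_lt(m$p_value, 1e-12)
})

test_that("d = 1 reduces to simple linear regression", {
  set.seed(62)
  n <- 50L
  s <- stats::runif(n, 1, 5)
  v <- 0.3 * s + stats::rnorm(n, sd = 0.4)
  m <- allometric_regression(matrix(v), s)
  lmfit <- summary(stats::lm(v ~ s))
  t_sq <- lmfit$coefficients["s", "t value"]^2
  expect_equal(m$f_stat, t_sq, tolerance = 1e-10)
  expect_equal(m$r_squared, lmfit$r.squared, tolerance = 1e-10)
  expect_equal(m$p_value, lmfit$coefficients["s", "Pr(>|t|)"],
               tolerance = 1e-10)
})

test_that("fit statistics are invariant to rotation of the response basis", {
  set.seed(63)
  n <- 60L; d <- 5L
  s <- stats::runif(n, 1, 4)
  V <- s %*% t(stats::rnorm(d)) + matrix(stats::rnorm(n * d, sd = 0.5), n)
  Q <- qr.Q(qr(matrix(stats::rnorm(d * d), d)))
  m1 <- allometric_regression(V, s)
  m2 <- allometric_regression(V %*% Q, s)
  expect_equal(m2$wilks_lambda, m1$wilks_lambda, tolerance = 1e-9)
  expect_equal(m2$r_squared, m1$r_squared, tolerance = 1e-9)
  expect_equal(m2$mse, m1$mse, tolerance = 1e-9)
})

test_that("allometric_regression validates its inputs", {
  expect_error(allometric_regression(matrix(stats::rnorm(20), 10), rep(2, 10)),
               "zero variance")
  expect_error(allometric_regression(matrix(stats::rnorm(20), 10), rep(-1:8)),
               "positive")
  expect_error(allometric_regression(matrix(stats::rnorm(60), 6), 1:6),
               "n > d")
})

test_that("predict_shape_at_size passes through the Procrustes mean", {
  spec <- shape_population_spec(
    seed = 64L, allometry_beta = landmark_delta(c(2L, 6L), c(0.1, 0.08)))
  pr <- sim_pair(spec)
  fit <- gpa(landmark_sample(c(pr$a$configurations, pr$b$configurations)))
  tg <- tangent_coordinates(fit)
  red <- reduce_dimension(tg$coords[1:41, ], tg$coords[42:82, ])
  scores <- rbind(red$scores1, red$scores2)
  model <- allometric_regression(scores, fit$centroid_sizes)
  pred_mean <- predict_shape_at_size(model, mean(fit$centroid_sizes),
                                     fit$mean_shape, red$basis)
  expect_lt(riemann_rho(pred_mean, fit$mean_shape), 1e-6)
  # zero-slope model returns the reference everywhere
  model0 <- model
  model0$slope <- rep(0, length(model0$slope))
  model0$intercept <- rep(0, length(model0$intercept))
  p1 <- predict_shape_at_size(model0, 10, fit$mean_shape, red$basis)
  p2 <- predict_shape_at_size(model0, 90, fit$mean_shape, red$basis)
  expect_lt(riemann_rho(p1, fit$mean_shape), 1e-10)
  expect_lt(riemann_rho(p2, fit$mean_shape), 1e-10)
  expect_error(predict_shape_at_size(model, -2, fit$mean_shape, red$basis),
               "positive")
})

test_that("allometric slope recovery improves with sample size", {
  # median relative slope error over replicates must decrease n=20 -> 320;
  # the injected field is compared in the analysis frame, i.e. rotated by
  # the template -> sample-mean Procrustes rotation (the generator
  # randomizes orientations, so the GPA frame is arbitrary)
  beta_shape <- landmark_delta(c(2L, 6L, 11L), c(0.12, 0.1, 0.08))
  tpl <- preshape(template_cc_shape())
  zt <- complex(real = tpl[, 1L], imaginary = tpl[, 2L])
  bc <- complex(real = beta_shape[, 1L], imaginary = beta_shape[, 2L])
  med_err <- vapply(c(20L, 80L, 320L), function(n) {
    errs <- vapply(1:30, function(r) {
      spec <- shape_population_spec(seed = 7000L + 17L * r + n, n = n,
                                    allometry_beta = beta_shape,
                                    cs_sd = 0.15)
      fit <- gpa(simulate_sample(spec, 1L))
      tg <- tangent_coordinates(fit)
      half <- seq_len(n %/% 2L)
      red <- reduce_dimension(tg$coords[half, , drop = FALSE],
                              tg$coords[-half, , drop = FALSE],
                              target_dim = min(28L, n %/% 2L - 2L))
      scores <- rbind(red$scores1, red$scores2)
      model <- allometric_regression(scores, fit$centroid_sizes,
                                     use_log_cs = TRUE)
      est <- as.numeric(red$basis %*% model$slope)
      mu <- complex(real = fit$mean_shape[, 1L],
                    imaginary = fit$mean_shape[, 2L])
      ip <- sum(Conj(zt) * mu)
      tc <- bc * ip / Mod(ip)
      truth <- c(Re(tc), Im(tc))
      sqrt(sum((est - truth)^2) / sum(truth^2))
    }, numeric(1))
    stats::median(errs)
  }, numeric(1))
  expect_true(all(diff(med_err) < 0))
})

test_that("predicted shapes at CS +/- 2SD bracket the allometric range", {
  beta_shape <- landmark_delta(c(2L, 6L), c(0.15, 0.1))
  spec <- shape_population_spec(seed = 65L, n = 60L, sigma = 0.005,
                                allometry_beta = beta_shape, cs_sd = 0.12)
  fit <- gpa(simulate_sample(spec, 1L))
  tg <- tangent_coordinates(fit)
  red <- reduce_dimension(tg$coords[1:30, ], tg$coords[31:60, ], 20L)
  model <- allometric_regression(rbind(red$scores1, red$scores2),
                                 fit$centroid_sizes, use_log_cs = TRUE)
  cs <- fit$centroid_sizes
  lo <- predict_shape_at_size(model, exp(mean(log(cs)) - 2 * stats::sd(log(cs))),
                              fit$mean_shape, red$basis)
  hi <- predict_shape_at_size(model, exp(mean(log(cs)) + 2 * stats::sd(log(cs))),
                              fit$mean_shape, red$basis)
  spread <- riemann_rho(lo, hi)
  expect_gt(spread, 0)
  # the predicted extremes differ from the mean by about 2 SD of the fitted
  # size effect, hence must exceed the typical single-specimen allometric
  # displacement
  expect_gt(spread, riemann_rho(
    predict_shape_at_size(model, exp(mean(log(cs)) + stats::sd(log(cs))),
                          fit$mean_shape, red$basis),
    fit$mean_shape))
})
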