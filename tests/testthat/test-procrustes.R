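test_that("centroid_size matches definition, homogeneity and brute force", {
  sq <- cbind(c(-.5, .5, .5, -.5), c(-.5, -.5, .5, .5))
  expect_equal(centroid_size(sq), sqrt(2))
  set.seed(1)
  m <- rand_config(16L)
  for (c_ in c(0.5, 3.7)) expect_equal(centroid_size(c_ * m),
                                       c_ * centroid_size(m))
  # brute-force oracle: explicit loop over centered squared coordinates
  ctr <- c(mean(m[, 1L]), mean(m[, 2L]))
  acc <- 0
  for (i in seq_len(nrow(m))) acc <- acc + sum((m[i, ] - ctr)^2)
  expect_equal(centroid_size(m), sqrt(acc))
  # degenerate configuration flags and returns 0
  z <- centroid_size(matrix(1, 5L, 2L))
  expect_identical(as.numeric(z), 0)
  expect_true(attr(z, "degenerate"))
})

test_that("preshape centers, normalizes, is idempotent, translation-proof", {
  set.seed(2)
  m <- rand_config(10L)
  p <- preshape(m)
  expect_lt(max(abs(colMeans(p))), 1e-14)
  expect_equal(sum(p^2), 1)
  expect_equal(preshape(p), p, tolerance = 1e-12)
  expect_equal(preshape(sweep(m, 2L, c(13.5, -2.2), "+")), p,
               tolerance = 1e-12)
  expect_error(preshape(matrix(2, 4L, 2L)), "degenerate")
})

test_that("opa_align recovers rotations exactly and beats a grid search", {
  set.seed(3)
  target <- preshape(rand_config(12L))
  rotated <- apply_similarity(target, 30 * pi / 180)
  fit <- opa_align(rotated, target)
  expect_equal(fit$aligned, unclass(target), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(fit$rotation_angle, -30 * pi / 180, tolerance = 1e-10)
  idfit <- opa_align(target, target)
  expect_equal(idfit$rotation_angle, 0)
  expect_equal(idfit$scale, 1, tolerance = 1e-12)

  # grid-search oracle: the closed form must beat 360 brute-force rotations
  # (with per-angle least-squares scale) on random pairs
  for (rep in 1:5) {
    a <- preshape(rand_config(8L)); b <- preshape(rand_config(8L))
    rss_opa <- sum((opa_align(a, b)$aligned - b)^2)
    rss_grid <- min(vapply(seq(0, 359) * pi / 180, function(th) {
      ar <- apply_similarity(a, th)
      beta <- max(sum(ar * b), 0) / sum(ar^2)
      sum((beta * ar - b)^2)
    }, numeric(1)))
    expect_lte(rss_opa, rss_grid + 1e-12)
  }
})

test_that("riemann_rho is a similarity-invariant symmetric metric", {
  set.seed(4)
  a <- rand_config(16L)
  expect_lt(riemann_rho(a, apply_similarity(a, 1.1, 2.7, c(5, -3))), 1e-10)
  for (rep in 1:20) {
    x <- rand_config(6L); y <- rand_config(6L)
    expect_equal(riemann_rho(x, y), riemann_rho(y, x), tolerance = 1e-12)
    expect_gte(riemann_rho(x, y), 0)
    expect_lte(riemann_rho(x, y), pi / 2)
  }
  # triangle inequality on random triples
  for (rep in 1:50) {
    x <- rand_config(8L); y <- rand_config(8L); z <- rand_config(8L)
    expect_lte(riemann_rho(x, z),
               riemann_rho(x, y) + riemann_rho(y, z) + 1e-9)
  }
})

test_that("equilateral triangle vs mirror is maximally distant (SVD oracle)", {
  tri <- cbind(c(0, 1, 0.5), c(0, 0, sqrt(3) / 2))
  mir <- tri %*% diag(c(-1, 1))
  r <- riemann_rho(tri, mir)
  expect_equal(r, rho_svd_oracle(tri, mir), tolerance = 1e-9)
  set.seed(5)
  rand_rhos <- vapply(1:1000, function(i) riemann_rho(tri, rand_config(3L)),
                      numeric(1))
  expect_gte(r, max(rand_rhos))
})

test_that("gpa recovers a common shape under arbitrary similarity noise", {
  set.seed(6)
  shp <- rand_config(16L)
  cfs <- lapply(1:12, function(i)
    landmark_config(apply_similarity(shp, stats::runif(1, 0, 2 * pi),
                                     stats::runif(1, .2, 5),
                                     stats::rnorm(2L, 0, 40)),
                    as.character(i)))
  fit <- gpa(landmark_sample(cfs))
  expect_true(fit$converged)
  expect_lt(riemann_rho(fit$mean_shape, shp), 1e-8)
  # mean shape invariants
  expect_lt(max(abs(colMeans(fit$mean_shape))), 1e-10)
  expect_equal(centroid_size(fit$mean_shape), 1, tolerance = 1e-10)
  for (i in 1:12)
    expect_lt(max(abs(colMeans(fit$aligned[, , i]))), 1e-10)
})

test_that("gpa mean of two shapes is the geodesic midpoint", {
  set.seed(7)
  a <- rand_config(10L); b <- rand_config(10L)
  fit <- gpa(landmark_sample(list(landmark_config(a, "a"),
                                  landmark_config(b, "b"))))
  expect_equal(riemann_rho(fit$mean_shape, a), riemann_rho(fit$mean_shape, b),
               tolerance = 1e-8)
})

test_that("gpa convergence trace is non-increasing and order-insensitive", {
  spec <- shape_population_spec(seed = 31L, n = 15L)
  s <- simulate_sample(spec, 1L)
  fit <- gpa(s)
  tr <- fit$rho_trace
  if (length(tr) > 2L)
    expect_true(all(diff(tr[-1L]) <= 1e-12))
  # permuting specimen order leaves the mean unchanged
  perm <- rev(seq_along(s$configurations))
  fit2 <- gpa(landmark_sample(s$configurations[perm], "perm"))
  expect_lt(riemann_rho(fit$mean_shape, fit2$mean_shape), 1e-8)
})

test_that("rms_rho matches its definition in degenerate cases", {
  set.seed(8)
  ref <- preshape(rand_config(8L))
  arr <- array(rep(unclass(ref), 3L), dim = c(8L, 2L, 3L))
  expect_equal(rms_rho(arr, ref), 0)
  other <- rand_config(8L)
  one <- array(other, dim = c(8L, 2L, 1L))
  expect_equal(rms_rho(one, ref), riemann_rho(other, ref))
  expect_error(rms_rho(array(0, c(8L, 2L, 0L)), ref), "empty")
})

test_that("tangent coordinates: orthogonality, rank, norms, reconstruction", {
  spec <- shape_population_spec(seed = 32L)
  fit <- gpa(simulate_sample(spec, 1L))
  tg <- tangent_coordinates(fit)
  k <- 16L
  mu <- complex(real = fit$mean_shape[, 1L], imaginary = fit$mean_shape[, 2L])
  # projection orthogonality <mu, v_i> = 0 and zero column means
  for (i in c(1L, 20L, 41L)) {
    v <- complex(real = tg$coords[i, 1:k], imaginary = tg$coords[i, k + 1:k])
    expect_lt(Mod(sum(Conj(mu) * v)), 1e-10)
  }
  expect_lt(max(abs(colMeans(tg$coords))), 1e-8)
  expect_equal(tg$effective_rank, 2L * k - 4L)
  # reference specimen maps to the zero vector
  ref_sample <- landmark_sample(list(
    landmark_config(fit$mean_shape, "m1"),
    landmark_config(apply_similarity(fit$mean_shape, 0.3, 2), "m2")))
  tg0 <- tangent_coordinates(gpa(ref_sample)$aligned, fit$mean_shape)
  expect_lt(max(abs(tg0$coords)), 1e-8)
  # reconstruction mu + v recovers each preshape to rho < 1e-3 in the
  # small-dispersion regime; the linearization error grows like rho^3, so
  # the 1e-3 bound holds per specimen up to rho ~ 0.125 — specimens in the
  # dispersion tail are held to a 2x relaxed bound
  expect_lt(rms_rho(fit, fit$mean_shape), 0.1)
  rhos_i <- vapply(seq_len(nrow(tg$coords)), function(i)
    riemann_rho(fit$aligned[, , i], fit$mean_shape), numeric(1))
  recon_err <- vapply(seq_len(nrow(tg$coords)), function(i) {
    v <- cbind(tg$coords[i, 1:k], tg$coords[i, k + 1:k])
    riemann_rho(fit$mean_shape + v, fit$aligned[, , i])
  }, numeric(1))
  expect_lt(max(recon_err[rhos_i <= 0.1]), 1e-3)
  expect_lt(max(recon_err), 2e-3)
  expect_error(tangent_coordinates(fit, fit$mean_shape * 3), "unit centroid")
})

test_that("tangent norm equals sin(rho) in the small-dispersion limit", {
  spec <- shape_population_spec(seed = 33L, sigma = 5e-4, n = 20L)
  fit <- gpa(simulate_sample(spec, 1L))
  tg <- tangent_coordinates(fit)
  rhos <- vapply(1:20, function(i)
    riemann_rho(fit$aligned[, , i], fit$mean_shape), numeric(1))
  norms <- sqrt(rowSums(tg$coords^2))
  expect_lt(max(abs(norms - sin(rhos))), 1e-6)
})
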