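# Two-group tests on tangent coordinates: dimension reduction, Box-M
# covariance homogeneity, resampling James test, Hotelling T^2, and a
# summary-statistics t-test for demographic covariates.

.score_matrix <- function(x) {
  if (inherits(x, "tangent_sample")) x <- x$coords
  x <- as.matrix(x)
  stopifnot(is.numeric(x))
  x
}

#' Reduce two tangent-coordinate blocks to a common full-rank basis
#'
#' Tangent coordinates of planar shapes are rank-deficient (`2k - 4` out of
#' `2k` dimensions), so covariance inverses need a reduced basis. The basis
#' is the principal-component basis of the pooled data after centering each
#' group at its own mean (so a mean difference does not leak into the basis
#' rank); both groups are projected onto the same basis.
#'
#' @param x1,x2 `n_i x 2k` coordinate matrices (or [tangent_sample]s) with a
#'   common column count.
#' @param target_dim `"auto"` (the pooled effective rank) or an integer.
#'   The retained dimension is `min(target_dim, effective rank, n1+n2-2)`
#'   and must stay below `min(n1, n2) - 1` for the downstream covariance
#'   estimates to be nonsingular.
#' @return List with `scores1`, `scores2` (reduced blocks), `basis`
#'   (orthonormal `2k x d`), `center` (pooled-data column means removed
#'   before projection) and `reduced_dim`.
#' @export
reduce_dimension <- function(x1, x2, target_dim = "auto") {
  x1 <- .score_matrix(x1); x2 <- .score_matrix(x2)
  if (ncol(x1) != ncol(x2)) stop("blocks have differing column counts")
  n1 <- nrow(x1); n2 <- nrow(x2)
  centered <- rbind(scale(x1, scale = FALSE), scale(x2, scale = FALSE))
  sv <- svd(centered)
  eff_rank <- sum(sv$d > 1e-10)
  d <- if (identical(target_dim, "auto")) eff_rank
       else min(as.integer(target_dim), eff_rank, n1 + n2 - 2L)
  d <- min(d, eff_rank, n1 + n2 - 2L)
  if (d >= min(n1, n2) - 1L)
    stop("retained dimension ", d, " >= min group size - 1 (",
         min(n1, n2) - 1L, "); pass a smaller 'target_dim' or the group ",
         "covariance matrices would be singular")
  basis <- sv$v[, seq_len(d), drop = FALSE]
  center <- colMeans(rbind(x1, x2))
  list(scores1 = sweep(x1, 2L, center) %*% basis,
       scores2 = sweep(x2, 2L, center) %*% basis,
       basis = basis, center = center, reduced_dim = d)
}

#' Box-M test of covariance homogeneity for two groups
#'
#' `M = (N - g) log|S_pooled| - sum (n_i - 1) log|S_i|` with unbiased
#' covariance estimates, converted to an F statistic via Box's (1949)
#' F approximation. M is 0 when the group covariances are identical, and is
#' invariant to a common invertible linear transform of both groups.
#'
#' @param x1,x2 Reduced `n_i x d` score blocks; each `n_i` must exceed
#'   `d + 1`.
#' @return Object of class `homogeneity_result`: list with `box_m`, `f_stat`,
#'   `df1`, `df2`, `p_value`, `reduced_dim`.
#' @export
box_m_test <- function(x1, x2) {
  x1 <- .score_matrix(x1); x2 <- .score_matrix(x2)
  if (ncol(x1) != ncol(x2)) stop("blocks have differing column counts")
  p <- ncol(x1)
  ns <- c(nrow(x1), nrow(x2))
  if (any(ns <= p + 1L))
    stop("each group needs n > d + 1 (d = ", p, ", n = ",
         paste(ns, collapse = "/"), ")")
  g <- 2L
  N <- sum(ns)
  S <- list(stats::cov(x1), stats::cov(x2))
  ld <- numeric(2L)
  for (i in 1:2) {
    dt <- determinant(S[[i]], logarithm = TRUE)
    if (dt$sign <= 0) stop("singular within-group covariance in group ", i)
    ld[i] <- as.numeric(dt$modulus)
  }
  Sp <- ((ns[1L] - 1L) * S[[1L]] + (ns[2L] - 1L) * S[[2L]]) / (N - g)
  ldp <- determinant(Sp, logarithm = TRUE)
  if (ldp$sign <= 0) stop("singular pooled covariance")
  M <- (N - g) * as.numeric(ldp$modulus) - sum((ns - 1L) * ld)
  M <- max(M, 0)
  # Box (1949) F approximation
  c1 <- (sum(1 / (ns - 1)) - 1 / (N - g)) *
    (2 * p^2 + 3 * p - 1) / (6 * (p + 1) * (g - 1))
  c2 <- (sum(1 / (ns - 1)^2) - 1 / (N - g)^2) *
    (p - 1) * (p + 2) / (6 * (g - 1))
  df1 <- p * (p + 1) * (g - 1) / 2
  a2 <- c2 - c1^2
  if (abs(a2) < .Machine$double.eps) a2 <- .Machine$double.eps
  df2 <- (df1 + 2) / abs(a2)
  if (a2 > 0) {
    b <- df1 / (1 - c1 - df1 / df2)
    f_stat <- M / b
  } else {
    b <- df2 / (1 - c1 + 2 / df2)
    f_stat <- df2 * M / (df1 * (b - M))
  }
  f_stat <- max(f_stat, 0)
  structure(list(box_m = M, f_stat = f_stat, df1 = df1, df2 = df2,
                 p_value = stats::pf(f_stat, df1, df2, lower.tail = FALSE),
                 reduced_dim = p),
            class = "homogeneity_result")
}

#' @export
print.homogeneity_result <- function(x, ...) {
  cat(sprintf("Box-M test: M = %.4f, F = %.4f (df = %.1f, %.1f), p = %.4g\n",
              x$box_m, x$f_stat, x$df1, x$df2, x$p_value))
  invisible(x)
}

# James's unequal-covariance two-sample statistic
.james_t2 <- function(m1, m2, S1, S2, n1, n2) {
  d <- m1 - m2
  W <- S1 / n1 + S2 / n2
  as.numeric(crossprod(d, solve(W, d)))
}

# Deterministic, group-label-independent substream assignment: resampling
# index streams are attached to the groups in a canonical order (group size,
# then a data digest), so swapping the argument order reproduces the p-value.
# The digest is the sum of squares, which is also invariant to sign flips
# and rotations of a shared orthonormal basis.
.canonical_first <- function(x1, x2) {
  k1 <- c(nrow(x1), sum(x1^2)); k2 <- c(nrow(x2), sum(x2^2))
  if (k1[1L] != k2[1L]) return(k1[1L] < k2[1L])
  k1[2L] <= k2[2L]
}

#' Resampling James test of equal mean shapes under unequal covariances
#'
#' James's statistic `T2 = d' (S1/n1 + S2/n2)^{-1} d` (with `d` the group
#' mean difference and `S_i` unbiased covariances) does not assume equal
#' group covariances. The null distribution is obtained by a nonparametric
#' within-group centered bootstrap: each group is centered at its own mean,
#' specimens are resampled with replacement within group, and the statistic
#' recomputed; `p = (1 + #\{T2* >= T2_obs\}) / (1 + n_resamples)`.
#'
#' @param x1,x2 Reduced `n_i x d` score blocks, `n_i > d + 1`.
#' @param n_resamples Bootstrap resamples (default 999; fewer than 99 warns).
#' @param seed Integer seed; required, makes the p-value reproducible.
#' @return Object of class `mean_shape_test`: list with `statistic`,
#'   `p_value`, `method = "james_resampling"`, `n_resamples`, `seed`,
#'   `reduced_dim`.
#' @export
james_test <- function(x1, x2, n_resamples = 999L, seed) {
  x1 <- .score_matrix(x1); x2 <- .score_matrix(x2)
  if (ncol(x1) != ncol(x2)) stop("blocks have differing column counts")
  p <- ncol(x1)
  n1 <- nrow(x1); n2 <- nrow(x2)
  if (any(c(n1, n2) <= p + 1L))
    stop("each group needs n > d + 1 (d = ", p, ")")
  if (missing(seed)) stop("'seed' is required for the resampling null")
  n_resamples <- as.integer(n_resamples)
  if (n_resamples < 99L)
    warning("n_resamples < 99 gives a coarse p-value resolution")
  S1 <- stats::cov(x1); S2 <- stats::cov(x2)
  W <- S1 / n1 + S2 / n2
  if (rcond(W) < 1e-12) stop("singular combined covariance S1/n1 + S2/n2")
  t2_obs <- .james_t2(colMeans(x1), colMeans(x2), S1, S2, n1, n2)
  c1 <- sweep(x1, 2L, colMeans(x1))   # centered: both groups share null mean 0
  c2 <- sweep(x2, 2L, colMeans(x2))
  first_is_1 <- .canonical_first(x1, x2)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))
  nf <- if (first_is_1) n1 else n2
  ns <- if (first_is_1) n2 else n1
  t2_star <- vapply(seq_len(n_resamples), function(b) {
    i_f <- sample.int(nf, nf, replace = TRUE)
    i_s <- sample.int(ns, ns, replace = TRUE)
    if (first_is_1) { b1 <- c1[i_f, , drop = FALSE]; b2 <- c2[i_s, , drop = FALSE] }
    else            { b2 <- c2[i_f, , drop = FALSE]; b1 <- c1[i_s, , drop = FALSE] }
    .james_t2(colMeans(b1), colMeans(b2), stats::cov(b1), stats::cov(b2), n1, n2)
  }, numeric(1))
  structure(list(statistic = t2_obs,
                 p_value = (1 + sum(t2_star >= t2_obs)) / (1 + n_resamples),
                 method = "james_resampling",
                 n_resamples = n_resamples,
                 seed = as.integer(seed),
                 reduced_dim = p),
            class = "mean_shape_test")
}

#' Two-sample Hotelling T-squared test (equal covariances)
#'
#' The classical pooled-covariance test of equal multivariate means, with the
#' exact F transform `F = (n1+n2-d-1) / ((n1+n2-2) d) * T2` on
#' `(d, n1+n2-d-1)` degrees of freedom. Used when the Box-M gate does not
#' reject covariance homogeneity.
#'
#' @param x1,x2 Reduced `n_i x d` score blocks.
#' @return Object of class `mean_shape_test` with `method = "hotelling"`.
#' @export
hotelling_test <- function(x1, x2) {
  x1 <- .score_matrix(x1); x2 <- .score_matrix(x2)
  if (ncol(x1) != ncol(x2)) stop("blocks have differing column counts")
  p <- ncol(x1)
  n1 <- nrow(x1); n2 <- nrow(x2)
  if (n1 + n2 - p - 1L <= 0L) stop("too few specimens for d = ", p)
  Sp <- ((n1 - 1L) * stats::cov(x1) + (n2 - 1L) * stats::cov(x2)) / (n1 + n2 - 2L)
  if (rcond(Sp) < 1e-12) stop("singular pooled covariance")
  d <- colMeans(x1) - colMeans(x2)
  t2 <- (n1 * n2) / (n1 + n2) * as.numeric(crossprod(d, solve(Sp, d)))
  f_stat <- (n1 + n2 - p - 1) / ((n1 + n2 - 2) * p) * t2
  structure(list(statistic = t2,
                 p_value = stats::pf(f_stat, p, n1 + n2 - p - 1,
                                     lower.tail = FALSE),
                 method = "hotelling",
                 n_resamples = 0L,
                 seed = NA_integer_,
                 reduced_dim = p),
            class = "mean_shape_test")
}

#' @export
print.mean_shape_test <- function(x, ...) {
  cat(sprintf("Mean-shape test (%s): T2 = %.4f, p = %.4g\n",
              x$method, x$statistic, x$p_value))
  invisible(x)
}

#' Pooled two-sample t-test from summary statistics
#'
#' Recovers the classical equal-variance t-test from group sizes, means and
#' standard deviations — for demographic covariates reported only in summary
#' form.
#'
#' @param n1,n2 Group sizes (`>= 2`).
#' @param mean1,mean2 Group means.
#' @param sd1,sd2 Group standard deviations (`> 0`).
#' @return List with `t`, `df`, `p` (two-sided).
#' @examples
#' t_test_from_summary(41, 34.17, 10.14, 41, 35.10, 9.92)$p  # 0.676
#' @export
t_test_from_summary <- function(n1, mean1, sd1, n2, mean2, sd2) {
  if (n1 < 2 || n2 < 2) stop("group sizes must be >= 2")
  if (sd1 <= 0 || sd2 <= 0) stop("standard deviations must be positive")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}
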