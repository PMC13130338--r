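# Allometry: multivariate regression of reduced tangent coordinates on
# centroid size, with Wilks' lambda significance and R^2 / MSE fit summaries.

#' Multivariate allometric regression of shape on centroid size
#'
#' Fits `V = 1 a' + s b' + E` by least squares, where `V` (`n x d`) holds
#' reduced tangent scores and `s` is centroid size (or its natural log).
#' Significance of the single size predictor is tested with Wilks' lambda
#' `|E'E| / |E'E + H|` and its exact F transform
#' `F = ((1 - L)/L) ((n - d - 1)/d)` on `(d, n - d - 1)` degrees of freedom.
#' Fit quality is summarized by `R^2 = 1 - trace(E'E)/trace(T'T)` (with `T`
#' the intercept-only residuals) and `MSE = trace(E'E)/(n d)`.
#'
#' @param tangent A [tangent_sample], reduced score matrix, or bare `n x d`
#'   matrix; `n > d + 2` required.
#' @param cs Vector of `n` positive centroid sizes.
#' @param use_log_cs Regress on `log(cs)` instead of raw CS (morphometric
#'   practice varies; raw CS is the default).
#' @return Object of class `allometry_model`: list with `slope`, `intercept`
#'   (length-`d` vectors), `wilks_lambda`, `f_stat`, `df1`, `df2`, `p_value`,
#'   `r_squared`, `mse`, `use_log_cs`, `predictor_mean`, `n`, `d`.
#' @export
allometric_regression <- function(tangent, cs, use_log_cs = FALSE) {
  V <- .score_matrix(tangent)
  n <- nrow(V); d <- ncol(V)
  if (length(cs) != n) stop("'cs' length must match the number of specimens")
  if (any(cs <= 0)) stop("centroid sizes must be positive")
  if (n <= d + 2L) stop("need n > d + 2 (n = ", n, ", d = ", d, ")")
  s <- if (use_log_cs) log(cs) else as.numeric(cs)
  if (stats::var(s) == 0) stop("zero variance in centroid size")
  sc <- s - mean(s)
  Vc <- sweep(V, 2L, colMeans(V))
  beta <- as.numeric(crossprod(Vc, sc)) / sum(sc^2)   # slope, length d
  alpha <- colMeans(V) - beta * mean(s)
  E <- Vc - outer(sc, beta)                           # residuals
  EtE <- crossprod(E)
  H <- outer(beta, beta) * sum(sc^2)                  # hypothesis SSCP (rank 1)
  ldE <- determinant(EtE, logarithm = TRUE)
  ldT <- determinant(EtE + H, logarithm = TRUE)
  if (!is.finite(as.numeric(ldT$modulus)) || ldT$sign <= 0) {
    # total SSCP singular: the responses do not span d dimensions. A perfect
    # fit (negligible residual energy) is the limiting lambda = 0; anything
    # else is a degenerate design the caller must reduce.
    if (sum(E^2) <= 1e-10 * sum(Vc^2)) lambda <- 0
    else stop("singular total SSCP: responses are rank-deficient, reduce d")
  } else {
    lambda <- if (ldE$sign <= 0) 0 else
      exp(as.numeric(ldE$modulus) - as.numeric(ldT$modulus))
  }
  lambda <- min(max(lambda, 0), 1)
  df1 <- d; df2 <- n - d - 1
  if (df2 <= 0) stop("no residual degrees of freedom for the F transform")
  f_stat <- if (lambda == 0) Inf else (1 - lambda) / lambda * df2 / df1
  structure(list(slope = beta, intercept = alpha,
                 wilks_lambda = lambda, f_stat = f_stat,
                 df1 = df1, df2 = df2,
                 p_value = stats::pf(f_stat, df1, df2, lower.tail = FALSE),
                 r_squared = 1 - sum(E^2) / sum(Vc^2),
                 mse = sum(E^2) / (n * d),
                 use_log_cs = isTRUE(use_log_cs),
                 predictor_mean = mean(s),
                 n = n, d = d),
            class = "allometry_model")
}

#' @export
print.allometry_model <- function(x, ...) {
  cat(sprintf(paste0("Allometric regression (%s): Wilks' lambda = %.4g, ",
                     "F = %.4f (df = %d, %d), p = %.4g\n  R^2 = %.5f, ",
                     "MSE = %.4g\n"),
              if (x$use_log_cs) "log CS" else "CS",
              x$wilks_lambda, x$f_stat, x$df1, x$df2, x$p_value,
              x$r_squared, x$mse))
  invisible(x)
}

#' Predict the mean shape at a given centroid size
#'
#' Evaluates the fitted allometric trajectory at `cs_value`: the fitted
#' tangent vector is mapped back through the reduction basis to the full
#' `2k` tangent coordinates, added to the reference pole, and renormalized
#' to a unit-CS configuration. At the mean CS this returns the Procrustes
#' mean (the regression passes through the centroid of the data).
#'
#' @param model An [allometry_model].
#' @param cs_value Positive centroid size at which to predict.
#' @param reference `k x 2` unit-CS mean shape (the tangent pole).
#' @param basis `2k x d` orthonormal reduction basis from
#'   [reduce_dimension].
#' @param center Length-`2k` centering vector from [reduce_dimension]
#'   (defaults to zeros, appropriate when tangent coordinates are taken
#'   about the pooled mean).
#' @return `k x 2` unit-CS predicted shape.
#' @export
predict_shape_at_size <- function(model, cs_value, reference, basis,
                                  center = NULL) {
  stopifnot(inherits(model, "allometry_model"))
  if (cs_value <= 0) stop("'cs_value' must be positive")
  s <- if (model$use_log_cs) log(cs_value) else cs_value
  v_hat <- model$intercept + model$slope * s          # reduced coords
  full <- as.numeric(basis %*% v_hat)
  if (!is.null(center)) full <- full + center
  ref <- .as_coords(reference)
  k <- nrow(ref)
  shp <- ref + cbind(full[seq_len(k)], full[k + seq_len(k)])
  preshape(shp)
}
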