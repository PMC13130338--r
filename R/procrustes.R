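# Procrustes superimposition and Kendall shape-space geometry.
#
# Planar configurations are handled in the complex representation
# z_j = x_j + i*y_j: a rotation by theta plus rescaling by b is multiplication
# by the complex scalar b*exp(i*theta), which gives closed-form optimal
# superimposition. The Hermitian inner product used throughout is
# <z, w> = sum_j Conj(z_j) * w_j.

.as_coords <- function(x) {
  if (inherits(x, "landmark_config")) x <- unclass(x)
  x <- as.matrix(x)
  stopifnot(is.numeric(x), ncol(x) == 2L)
  x
}

.to_complex <- function(m) complex(real = m[, 1L], imaginary = m[, 2L])

.to_matrix <- function(z) cbind(x = Re(z), y = Im(z))

.cinner <- function(z, w) sum(Conj(z) * w)

#' Centroid size of a configuration
#'
#' CS is the square root of the summed squared Euclidean distances of the
#' landmarks to their centroid — the standard morphometric scale measure.
#' A fully degenerate configuration (all landmarks coincident) returns 0
#' with attribute `degenerate = TRUE`; downstream shape operations reject
#' CS = 0.
#'
#' @param config A [landmark_config] or bare `k x 2` matrix.
#' @return Non-negative scalar.
#' @examples
#' centroid_size(cbind(c(-.5, .5, .5, -.5), c(-.5, -.5, .5, .5)))  # sqrt(2)
#' @export
centroid_size <- function(config) {
  m <- .as_coords(config)
  cs <- sqrt(sum(scale(m, scale = FALSE)^2))
  if (cs == 0) attr(cs, "degenerate") <- TRUE
  cs
}

#' Preshape of a configuration
#'
#' Removes location (centering) and scale (division by centroid size),
#' leaving rotation: a point of the preshape sphere with centroid 0 and unit
#' centroid size.
#'
#' @param config A [landmark_config] or `k x 2` matrix with CS > 0.
#' @return A `k x 2` matrix.
#' @export
preshape <- function(config) {
  m <- .as_coords(config)
  m <- scale(m, scale = FALSE)
  attr(m, "scaled:center") <- NULL
  cs <- sqrt(sum(m^2))
  if (cs == 0) stop("degenerate configuration: centroid size is 0")
  m / cs
}

#' Ordinary Procrustes alignment of one configuration onto a target
#'
#' Finds the rotation (determinant +1 only; reflections are forbidden) and
#' positive rescaling of a centered configuration minimizing the summed
#' squared distance to a centered target. In the complex representation the
#' least-squares similarity is multiplication by `<z, w> / <z, z>`.
#'
#' @param config,target Centered `k x 2` matrices with CS > 0.
#' @return List with `aligned` (`k x 2`), `rotation_angle` (radians, the
#'   rotation applied to `config`) and `scale` (positive factor applied).
#' @export
opa_align <- function(config, target) {
  z <- .to_complex(.as_coords(config))
  w <- .to_complex(.as_coords(target))
  if (max(Mod(mean(z)), Mod(mean(w))) > 1e-8 * max(Mod(z - mean(z))))
    stop("opa_align expects centered configurations")
  ip <- .cinner(z, w)
  if (Mod(ip) < 1e-15 * sqrt(sum(Mod(z)^2) * sum(Mod(w)^2))) {
    warning("orthogonal shapes: rotation is ambiguous, using angle 0")
    b <- 0
    rot <- complex(real = 1)
  } else {
    rot <- ip / Mod(ip)
    b <- Mod(ip) / sum(Mod(z)^2)
  }
  list(aligned = .to_matrix(z * rot * b),
       rotation_angle = Arg(rot),
       scale = b)
}

#' Kendall's Riemann distance between two planar shapes
#'
#' The geodesic angle `rho = acos(|<z1, z2>|)` between the preshapes, in
#' `[0, pi/2]`; invariant to translation, rotation and positive scaling of
#' either argument, and symmetric.
#'
#' @param shape1,shape2 Configurations (matrices or [landmark_config]) with
#'   CS > 0 and equal landmark count.
#' @return Scalar in `[0, pi/2]`.
#' @export
riemann_rho <- function(shape1, shape2) {
  z1 <- .to_complex(preshape(shape1))
  z2 <- .to_complex(preshape(shape2))
  if (length(z1) != length(z2)) stop("shapes have differing landmark counts")
  .rho_preshape(z1, z2)
}

# rho = acos(|<z1,z2>|) computed through the rotation-aligned chordal
# distance 2*sin(rho/2): acos(|ip|) loses all precision below ~1.5e-8
# (acos near 1), while the coordinate-wise difference norm does not
.rho_preshape <- function(z1, z2) {
  ip <- .cinner(z2, z1)
  rot <- if (Mod(ip) > 0) ip / Mod(ip) else complex(real = 1)
  2 * asin(min(1, 0.5 * sqrt(sum(Mod(z1 - z2 * rot)^2))))
}

#' Generalized Procrustes analysis of a landmark sample
#'
#' Iterative full-Procrustes superimposition: starting from the first
#' specimen's preshape as the provisional mean, every preshape is aligned to
#' the mean by [opa_align] (rotation + least-squares scale), the mean is
#' recomputed as the average of the aligned configurations re-normalized to
#' unit centroid size, and iteration stops when the Riemann distance between
#' successive means falls below `tol`. Aligned configurations are stored as
#' full-Procrustes fits to the unit-CS mean (their CS is `cos(rho_i) <= 1`).
#'
#' @param sample A [landmark_sample] with `n >= 2` and all CS > 0.
#' @param tol Convergence threshold on the Riemann distance between
#'   successive means.
#' @param max_iter Iteration cap; non-convergence warns and sets
#'   `converged = FALSE`.
#' @return An object of class `procrustes_fit`: list with `mean_shape`
#'   (`k x 2`, centered, unit CS), `aligned` (`k x 2 x n`), `centroid_sizes`
#'   (raw CS of the inputs), `iterations`, `converged`, `rho_trace` (distance
#'   between successive means per iteration) and `specimen_ids`.
#' @export
gpa <- function(sample, tol = 1e-10, max_iter = 100L) {
  stopifnot(inherits(sample, "landmark_sample"))
  arr <- sample_array(sample)
  n <- dim(arr)[3L]
  if (n < 2L) stop("GPA needs at least 2 specimens")
  cs <- apply(arr, 3L, centroid_size)
  if (any(cs == 0)) stop("degenerate configuration(s): ",
                         paste(which(cs == 0), collapse = ", "))
  k <- dim(arr)[1L]
  # preshapes as columns of a complex k x n matrix
  Z <- vapply(seq_len(n), function(i) .to_complex(preshape(arr[, , i])),
              complex(k))
  mu <- Z[, 1L]
  rho_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    ip <- as.vector(crossprod(Conj(Z), mu))     # <z_i, mu>, preshapes unit
    A <- Z * rep(ip, each = k)                  # full-Procrustes fits
    mu_new <- rowMeans(A)
    mu_new <- (mu_new - mean(mu_new)) / sqrt(sum(Mod(mu_new - mean(mu_new))^2))
    d <- .rho_preshape(mu_new, mu)
    rho_trace <- c(rho_trace, d)
    mu <- mu_new
    if (d < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("GPA did not converge in ", max_iter, " iterations (last step ",
            signif(rho_trace[length(rho_trace)], 3), ")")
  ip <- as.vector(crossprod(Conj(Z), mu))
  A <- Z * rep(ip, each = k)
  aligned <- array(0, dim = c(k, 2L, n),
                   dimnames = list(NULL, c("x", "y"), dimnames(arr)[[3L]]))
  for (i in seq_len(n)) aligned[, , i] <- .to_matrix(A[, i])
  structure(list(mean_shape = .to_matrix(mu),
                 aligned = aligned,
                 centroid_sizes = cs,
                 iterations = iter,
                 converged = converged,
                 rho_trace = rho_trace,
                 specimen_ids = dimnames(arr)[[3L]]),
            class = "procrustes_fit")
}

#' @export
print.procrustes_fit <- function(x, ...) {
  cat("<procrustes_fit> n =", dim(x$aligned)[3L], "specimens, k =",
      nrow(x$mean_shape), "landmarks;",
      if (x$converged) "converged" else "NOT converged", "in",
      x$iterations, "iterations\n")
  invisible(x)
}

#' Root-mean-square Riemann distance to a reference shape
#'
#' `sqrt(mean(rho_i^2))` of every configuration's Riemann distance to the
#' reference — the summary used to describe overall within-group shape
#' dispersion about a mean shape.
#'
#' @param shapes A `k x 2 x n` array, a [procrustes_fit] (its aligned
#'   configurations), or a [landmark_sample].
#' @param reference Configuration with CS > 0.
#' @return Non-negative scalar.
#' @export
rms_rho <- function(shapes, reference) {
  if (inherits(shapes, "procrustes_fit")) shapes <- shapes$aligned
  if (inherits(shapes, "landmark_sample")) shapes <- sample_array(shapes)
  if (length(dim(shapes)) != 3L) stop("'shapes' must be a k x 2 x n array")
  n <- dim(shapes)[3L]
  if (n == 0L) stop("empty set of shapes")
  sqrt(mean(vapply(seq_len(n),
                   function(i) riemann_rho(shapes[, , i], reference)^2,
                   numeric(1))))
}

#' Project aligned configurations into the tangent space at a reference
#'
#' Each specimen's preshape is optimally superimposed on the reference pole
#' `mu` (full Procrustes: rotation and scale) and projected by the complex
#' projector `I - mu mu*`. When `reference` is the sample's own Procrustes
#' mean the tangent coordinates have (numerically) zero column means, which
#' is what makes two groups projected about one pooled pole commensurate.
#' Coordinates are returned as real `2k`-vectors: all real parts, then all
#' imaginary parts, landmark-major.
#'
#' @param fit A [procrustes_fit] (or `k x 2 x n` array of configurations).
#' @param reference Centered, unit-CS `k x 2` matrix (defaults to the fit's
#'   mean shape).
#' @return Object of class `tangent_sample`: list with `reference`, `coords`
#'   (`n x 2k`), and `effective_rank` (count of singular values > 1e-10 of
#'   the coordinate matrix; at most `2k - 4`).
#' @export
tangent_coordinates <- function(fit, reference = NULL) {
  if (inherits(fit, "procrustes_fit")) {
    if (is.null(reference)) reference <- fit$mean_shape
    arr <- fit$aligned
  } else {
    if (is.null(reference)) stop("'reference' required for a bare array")
    arr <- fit
  }
  ref <- .as_coords(reference)
  if (max(abs(colMeans(ref))) > 1e-8 || abs(sum(ref^2) - 1) > 1e-8)
    stop("reference must be centered with unit centroid size")
  mu <- .to_complex(ref)
  k <- length(mu)
  n <- dim(arr)[3L]
  V <- matrix(0, n, 2L * k)
  for (i in seq_len(n)) {
    z <- .to_complex(preshape(arr[, , i]))
    zal <- z * .cinner(z, mu)             # full-Procrustes fit to the pole
    v <- zal - mu * .cinner(mu, zal)      # (I - mu mu*) z
    V[i, ] <- c(Re(v), Im(v))
  }
  sv <- svd(V, nu = 0, nv = 0)$d
  structure(list(reference = ref, coords = V,
                 effective_rank = sum(sv > 1e-10)),
            class = "tangent_sample")
}

#' @export
print.tangent_sample <- function(x, ...) {
  cat("<tangent_sample> n =", nrow(x$coords), "specimens,",
      ncol(x$coords), "coordinates, effective rank", x$effective_rank, "\n")
  invisible(x)
}
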