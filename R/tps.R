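# Thin-plate spline warps, bending energy, Jacobian expansion grids, and the
# per-landmark dissimilarity ranking between two mean shapes.

# radial kernel U(r) = r^2 log r, U(0) = 0 (the r^2 log r^2 convention
# differs by a factor absorbed into the weights; this one is fixed here so
# bending energies are comparable across implementations)
.tps_u <- function(r) ifelse(r > 0, r^2 * log(r), 0)

#' Fit a thin-plate spline between two landmark configurations
#'
#' Solves the standard TPS interpolation system
#' `f(p) = A [p; 1] + sum_i w_i U(|p - s_i|)` with kernel `U(r) = r^2 log r`,
#' so that `f(source_i) = target_i` exactly. The non-affine weights satisfy
#' the side conditions (zero sum, orthogonal to the source coordinates), and
#' the bending energy is the quadratic form `trace(w' K w)` — zero exactly
#' when the target is an affine image of the source.
#'
#' @param source,target `k x 2` matrices, `k >= 3`; source landmarks must be
#'   pairwise distinct and not collinear.
#' @return Object of class `tps_warp`: list with `source`, `target`, `affine`
#'   (`2 x 3`, linear part then translation column), `weights` (`k x 2`) and
#'   `bending_energy`.
#' @export
fit_tps <- function(source, target) {
  source <- .as_coords(source); target <- .as_coords(target)
  k <- nrow(source)
  if (nrow(target) != k) stop("source and target have differing landmark counts")
  if (k < 3L) stop("TPS needs at least 3 landmarks")
  D <- as.matrix(stats::dist(source))
  close <- which(D < 1e-12 & upper.tri(D), arr.ind = TRUE)
  if (nrow(close) > 0L)
    stop("coincident source landmarks ", close[1L, 1L], " and ", close[1L, 2L])
  K <- .tps_u(D)
  P <- cbind(1, source)
  if (qr(P)$rank < 3L) stop("collinear source landmarks: TPS system is rank-deficient")
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3L, 3L)))
  rhs <- rbind(target, matrix(0, 3L, 2L))
  sol <- solve(L, rhs)
  w <- sol[seq_len(k), , drop = FALSE]
  a <- sol[k + 1:3, , drop = FALSE]          # rows: 1, x, y; cols: fx, fy
  affine <- rbind(c(a[2L, 1L], a[3L, 1L], a[1L, 1L]),
                  c(a[2L, 2L], a[3L, 2L], a[1L, 2L]))
  be <- sum(diag(t(w) %*% K %*% w))
  structure(list(source = source, target = target, affine = affine,
                 weights = w, bending_energy = max(be, 0)),
            class = "tps_warp")
}

#' @export
print.tps_warp <- function(x, ...) {
  cat(sprintf("<tps_warp> k = %d landmarks, bending energy = %.6g\n",
              nrow(x$source), x$bending_energy))
  invisible(x)
}

#' Evaluate a fitted thin-plate spline at arbitrary points
#'
#' @param warp A [tps_warp].
#' @param points `p x 2` matrix of source-plane coordinates.
#' @return `p x 2` matrix of warped coordinates.
#' @export
evaluate_warp <- function(warp, points) {
  stopifnot(inherits(warp, "tps_warp"))
  points <- .as_coords(points)
  aff <- points %*% t(warp$affine[, 1:2]) +
    rep(1, nrow(points)) %*% t(warp$affine[, 3L, drop = FALSE])
  dx <- outer(points[, 1L], warp$source[, 1L], "-")
  dy <- outer(points[, 2L], warp$source[, 2L], "-")
  U <- .tps_u(sqrt(dx^2 + dy^2))
  aff + U %*% warp$weights
}

# analytic Jacobian of the warp at each point: 2x2 per row, returned as
# p x 4 (j11, j12, j21, j22); dU/dx = (x - sx) (2 log r + 1)
.warp_jacobian <- function(warp, points) {
  points <- .as_coords(points)
  dx <- outer(points[, 1L], warp$source[, 1L], "-")
  dy <- outer(points[, 2L], warp$source[, 2L], "-")
  r2 <- dx^2 + dy^2
  g <- ifelse(r2 > 0, log(r2) + 1, 0)       # 2 log r + 1
  gx <- dx * g; gy <- dy * g
  out <- cbind(warp$affine[1L, 1L] + as.numeric(gx %*% warp$weights[, 1L]),
               warp$affine[1L, 2L] + as.numeric(gy %*% warp$weights[, 1L]),
               warp$affine[2L, 1L] + as.numeric(gx %*% warp$weights[, 2L]),
               warp$affine[2L, 2L] + as.numeric(gy %*% warp$weights[, 2L]))
  colnames(out) <- c("j11", "j12", "j21", "j22")
  out
}

#' Deformation grid with Jacobian expansion factors
#'
#' Lays a square lattice over the source bounding box (expanded by `margin`
#' per side), warps it, and computes at each node the determinant of the
#' analytic Jacobian of the warp — the local area expansion factor
#' (1 = area-preserving, >1 expansion, <1 contraction). `log2_expansion` is
#' provided for symmetric color scaling.
#'
#' @param warp A [tps_warp].
#' @param grid_size Nodes per side (default 24).
#' @param margin Fractional bounding-box expansion per side (default 0.1).
#' @return Object of class `deformation_grid`: list with `grid_points` and
#'   `warped_points` (`g*g x 2`, row-major over y then x), `expansion` and
#'   `log2_expansion` (`g x g` matrices), `grid_size`.
#' @export
expansion_grid <- function(warp, grid_size = 24L, margin = 0.1) {
  stopifnot(inherits(warp, "tps_warp"))
  grid_size <- as.integer(grid_size)
  if (grid_size < 2L) stop("'grid_size' must be at least 2")
  rngx <- range(warp$source[, 1L]); rngy <- range(warp$source[, 2L])
  padx <- margin * diff(rngx); pady <- margin * diff(rngy)
  xs <- seq(rngx[1L] - padx, rngx[2L] + padx, length.out = grid_size)
  ys <- seq(rngy[1L] - pady, rngy[2L] + pady, length.out = grid_size)
  pts <- as.matrix(expand.grid(x = xs, y = ys))
  J <- .warp_jacobian(warp, pts)
  det_j <- J[, "j11"] * J[, "j22"] - J[, "j12"] * J[, "j21"]
  l2 <- rep(NA_real_, length(det_j))       # NA where the warp folds
  l2[det_j > 0] <- log2(det_j[det_j > 0])
  structure(list(grid_points = pts,
                 warped_points = evaluate_warp(warp, pts),
                 expansion = matrix(det_j, grid_size, grid_size),
                 log2_expansion = matrix(l2, grid_size, grid_size),
                 grid_size = grid_size),
            class = "deformation_grid")
}

#' Per-landmark dissimilarity and contribution ranking
#'
#' Dissimilarity of landmark `j` is the Euclidean distance between the two
#' Procrustes-aligned mean shapes at that landmark; contribution is the
#' dissimilarity normalized to sum 1. Rows are sorted descending by
#' dissimilarity, ties broken by ascending landmark index. When the two
#' means coincide (all dissimilarities ~0) contributions fall back to the
#' uniform `1/k` and the result is flagged (`zero_difference`). Optionally, a
#' per-specimen averaged variant is reported alongside: the mean over one
#' group's aligned specimens of the distance of each landmark to the other
#' group's mean landmark, averaged over both directions.
#'
#' @param mean_a,mean_b `k x 2` group mean shapes superimposed in one common
#'   frame (Procrustes-aligned, unit CS).
#' @param aligned_a,aligned_b Optional `k x 2 x n_i` arrays of the groups'
#'   aligned specimens, enabling the `mean_specimen_dissimilarity` column.
#' @return A `data.frame` of class `landmark_dissimilarity` with columns
#'   `rank`, `landmark_index` (1-based), `dissimilarity`, `contribution`
#'   (and optionally `mean_specimen_dissimilarity`), plus attribute
#'   `zero_difference`.
#' @export
landmark_dissimilarity <- function(mean_a, mean_b,
                                   aligned_a = NULL, aligned_b = NULL) {
  mean_a <- .as_coords(mean_a); mean_b <- .as_coords(mean_b)
  k <- nrow(mean_a)
  if (nrow(mean_b) != k) stop("mean shapes have differing landmark counts")
  diss <- sqrt(rowSums((mean_a - mean_b)^2))
  zero <- sum(diss) < 1e-12
  contrib <- if (zero) rep(1 / k, k) else diss / sum(diss)
  ord <- order(-diss, seq_len(k))
  tab <- data.frame(rank = seq_len(k),
                    landmark_index = ord,
                    dissimilarity = diss[ord],
                    contribution = contrib[ord])
  if (!is.null(aligned_a) && !is.null(aligned_b)) {
    msd_a <- rowMeans(sqrt(apply(sweep(aligned_a, 1:2, mean_b), 3L,
                                 function(m) rowSums(m^2))))
    msd_b <- rowMeans(sqrt(apply(sweep(aligned_b, 1:2, mean_a), 3L,
                                 function(m) rowSums(m^2))))
    tab$mean_specimen_dissimilarity <- ((msd_a + msd_b) / 2)[ord]
  }
  structure(tab, zero_difference = zero,
            class = c("landmark_dissimilarity", "data.frame"))
}

#' @export
print.landmark_dissimilarity <- function(x, ...) {
  cat("Per-landmark dissimilarity ranking",
      if (isTRUE(attr(x, "zero_difference")))
        "(ZERO DIFFERENCE: uniform contributions)", "\n")
  print.data.frame(x, row.names = FALSE, digits = 5)
  invisible(x)
}

#' Serialize a dissimilarity table to CSV
#'
#' @param table A [landmark_dissimilarity] table.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_dissimilarity_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table)[, c("landmark_index", "dissimilarity",
                                            "contribution", "rank")],
                   path, row.names = FALSE)
  invisible(path)
}
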