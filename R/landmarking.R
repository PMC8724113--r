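#' Boundary surface sets
#'
#' A surface set is the geometric label of one OCT volume: K ordered
#' boundary surfaces giving axial depth z_k(x, b) in voxels for every image
#' column x and B-scan b. Depth increases downward (vitreous to choroid) and
#' surfaces must not cross: z_1 <= z_2 <= ... <= z_K everywhere.
#'
#' @param z numeric array of dimension `W x B x K` (column, B-scan, surface).
#' @param axial_depth H, the number of axial voxels; all z must lie in [0, H).
#' @param spacing optional voxel spacing `(dx, dy, dz)` in micrometres.
#' @param validate check the non-crossing and range invariants? Default TRUE.
#' @return An object of class `surface_set`.
#' @export
surface_set <- function(z, axial_depth, spacing = NULL, validate = TRUE) {
  z <- unclass(z)
  if (length(dim(z)) != 3L)
    stop("`z` must be a W x B x K array", call. = FALSE)
  axial_depth <- as.numeric(axial_depth)
  s <- structure(list(z = z, axial_depth = axial_depth, spacing = spacing),
                 class = "surface_set")
  if (validate) validate_surfaces(s)
  s
}

surf_dims <- function(s) {
  d <- dim(s$z)
  list(W = d[1L], B = d[2L], K = d[3L])
}

#' Validate a surface set
#'
#' Checks finiteness, the depth range 0 <= z < H and the non-crossing
#' ordering of successive surfaces, reporting the first offending surface,
#' B-scan and column on failure.
#'
#' @param s a [surface_set()].
#' @return `s` invisibly; errors on violation.
#' @export
validate_surfaces <- function(s) {
  z <- s$z
  if (!all(is.finite(z))) stop("surface depths must be finite", call. = FALSE)
  if (any(z < 0) || any(z >= s$axial_depth))
    stop("surface depths must lie in [0, axial_depth)", call. = FALSE)
  d <- surf_dims(s)
  if (d$K > 1L) {
    for (k in seq_len(d$K - 1L)) {
      diffz <- z[, , k + 1L] - z[, , k]
      if (any(diffz < 0)) {
        idx <- which(diffz < 0, arr.ind = TRUE)[1L, ]
        stop(sprintf(
          "crossing surfaces: z_%d > z_%d at column %d, B-scan %d",
          k, k + 1L, idx[1L] - 1L, idx[2L] - 1L), call. = FALSE)
      }
    }
  }
  invisible(s)
}

#' @export
print.surface_set <- function(x, ...) {
  d <- surf_dims(x)
  cat(sprintf("<surface_set> %d surfaces, %d B-scans x %d columns, H = %g\n",
              d$K, d$B, d$W, x$axial_depth))
  if (!is.null(x$spacing))
    cat(sprintf("  spacing (dx, dy, dz) = (%s) um/voxel\n",
                paste(signif(x$spacing, 4), collapse = ", ")))
  invisible(x)
}

#' Locate the foveal column
#'
#' The fovea is taken as the column minimizing total retinal thickness
#' (z_K - z_1) on the central B-scan.
#'
#' @param s a [surface_set()].
#' @return 0-based column index of the fovea.
#' @export
find_fovea <- function(s) {
  d <- surf_dims(s)
  b <- (d$B + 1L) %/% 2L
  thick <- s$z[, b, d$K] - s$z[, b, 1L]
  which.min(thick) - 1L
}

# Fovea-anchored landmark columns: first at 0, last at W-1, the middle
# landmark at the foveal column, the rest evenly spaced within each half.
landmark_columns <- function(width, points_per_curve, fovea_column) {
  p <- as.integer(points_per_curve)
  if (p < 3L) stop("points_per_curve must be >= 3", call. = FALSE)
  if (width < p)
    stop("image too narrow for the requested number of landmarks",
         call. = FALSE)
  if (fovea_column <= 0 || fovea_column >= width - 1)
    stop("fovea_column must lie strictly inside (0, W-1)", call. = FALSE)
  m <- (p + 1L) %/% 2L                 # 1-based index of the middle landmark
  left <- seq(0, fovea_column, length.out = m)
  right <- seq(fovea_column, width - 1, length.out = p - m + 1L)
  c(left, right[-1L])
}

#' Landmark grid layout
#'
#' Records how a dense surface set was subsampled into a shape vector so the
#' operation can be inverted: the sampled column positions, counts and
#' geometry.
#'
#' @param points_per_curve landmarks per boundary per B-scan (default 51).
#' @param column_indices 0-based (possibly fractional) sampled columns.
#' @param n_surfaces,n_bscans,width,axial_depth geometry of the source.
#' @param fovea_column 0-based foveal column anchoring the middle landmark.
#' @param spacing optional voxel spacing carried through.
#' @return An object of class `landmark_grid`.
#' @export
landmark_grid <- function(points_per_curve, column_indices, n_surfaces,
                          n_bscans, width, axial_depth, fovea_column,
                          spacing = NULL) {
  structure(list(points_per_curve = as.integer(points_per_curve),
                 column_indices = as.numeric(column_indices),
                 n_surfaces = as.integer(n_surfaces),
                 n_bscans = as.integer(n_bscans),
                 width = as.integer(width),
                 axial_depth = as.numeric(axial_depth),
                 fovea_column = as.numeric(fovea_column),
                 spacing = spacing),
            class = "landmark_grid")
}

#' Extract a corresponded landmark cloud from boundary surfaces
#'
#' Samples each boundary of each B-scan at `points_per_curve` columns — the
#' first at x = 0, the last at x = W-1 and the middle landmark anchored on
#' the foveal column, with the remaining points evenly spaced within each
#' half — interpolating depth linearly between columns. Landmarks are
#' concatenated surface-major, then by B-scan, then by column, each
#' contributing (x, y, z) coordinates (y being the B-scan index), so a
#' default 9-surface, 19-B-scan, 51-point volume yields 9 x 969 landmarks.
#'
#' @param surfaces a [surface_set()].
#' @param points_per_curve landmarks per boundary per B-scan (default 51).
#' @param fovea_column 0-based foveal column, or `"auto"` to locate it via
#'   [find_fovea()].
#' @return A [shape_vector()] with the [landmark_grid()] attached as `$grid`.
#' @export
extract_landmarks <- function(surfaces, points_per_curve = 51L,
                              fovea_column = "auto") {
  stopifnot(inherits(surfaces, "surface_set"))
  d <- surf_dims(surfaces)
  if (identical(fovea_column, "auto")) fovea_column <- find_fovea(surfaces)
  fovea_column <- as.numeric(fovea_column)
  if (fovea_column < 0 || fovea_column >= d$W)
    stop("fovea_column outside the image", call. = FALSE)
  cols <- landmark_columns(d$W, points_per_curve, fovea_column)
  xs <- 0:(d$W - 1L)
  p <- length(cols)
  coords <- numeric(d$K * d$B * p * 3L)
  i <- 0L
  for (k in seq_len(d$K)) {
    for (b in seq_len(d$B)) {
      zc <- stats::approx(xs, surfaces$z[, b, k], xout = cols)$y
      block <- rbind(cols, rep(b - 1L, p), zc)
      coords[i + seq_len(3L * p)] <- as.numeric(block)
      i <- i + 3L * p
    }
  }
  sv <- shape_vector(coords, dim = 3L)
  sv$grid <- landmark_grid(points_per_curve, cols, d$K, d$B, d$W,
                           surfaces$axial_depth, fovea_column,
                           surfaces$spacing)
  sv
}

#' Extract 2-D landmarks from a single B-scan's boundary curves
#'
#' The 2-D analogue of [extract_landmarks()] for the pathology pipeline:
#' each of the K boundary curves is sampled at the fovea-anchored column
#' scheme, contributing (x, z) pairs per landmark.
#'
#' @param boundaries `K x W` matrix of boundary depths z_k(x).
#' @param axial_depth H of the source B-scan.
#' @param points_per_curve landmarks per boundary (default 51).
#' @param fovea_column anchor column; `"auto"` uses the column of minimal
#'   total thickness between the first and last boundary.
#' @return A [shape_vector()] with `dim = 2` and the grid attached.
#' @export
extract_landmarks_2d <- function(boundaries, axial_depth,
                                 points_per_curve = 51L,
                                 fovea_column = "auto") {
  boundaries <- as.matrix(boundaries)
  K <- nrow(boundaries); W <- ncol(boundaries)
  if (identical(fovea_column, "auto"))
    fovea_column <- which.min(boundaries[K, ] - boundaries[1L, ]) - 1L
  cols <- landmark_columns(W, points_per_curve, fovea_column)
  xs <- 0:(W - 1L)
  p <- length(cols)
  coords <- numeric(K * p * 2L)
  i <- 0L
  for (k in seq_len(K)) {
    zc <- stats::approx(xs, boundaries[k, ], xout = cols)$y
    coords[i + seq_len(2L * p)] <- as.numeric(rbind(cols, zc))
    i <- i + 2L * p
  }
  sv <- shape_vector(coords, dim = 2L)
  sv$grid <- landmark_grid(points_per_curve, cols, K, 1L, W, axial_depth,
                           fovea_column)
  sv
}

# Interpolate one boundary curve from landmark (x, z) pairs onto all
# integer columns with a monotone cubic spline; falls back to the grid
# columns when sampled x positions are not strictly increasing.
curve_from_landmarks <- function(xk, zk, grid_cols, width) {
  ord <- order(xk)
  xk <- xk[ord]; zk <- zk[ord]
  if (any(diff(xk) <= 1e-9)) { xk <- grid_cols; zk <- zk }
  f <- stats::splinefun(xk, zk, method = "monoH.FC")
  f(0:(width - 1L))
}

#' Reconstruct dense surfaces from a landmark cloud
#'
#' Inverts [extract_landmarks()]: per surface per B-scan, a monotone cubic
#' spline through the landmarks is evaluated at every image column; the
#' non-crossing invariant is then enforced by a cumulative-max projection
#' from the top surface down and depths are clamped into [0, H).
#'
#' @param x a [shape_vector()] (3-D) carrying a grid, or pass `grid`.
#' @param grid the [landmark_grid()] layout (defaults to `x$grid`).
#' @param target_width output width W (defaults to the grid's width).
#' @return A [surface_set()].
#' @export
landmarks_to_surfaces <- function(x, grid = x$grid,
                                  target_width = grid$width) {
  stopifnot(inherits(x, "shape_vector"))
  if (is.null(grid)) stop("no landmark grid supplied", call. = FALSE)
  if (x$dim != 3L) stop("expected a 3-D shape vector", call. = FALSE)
  p <- grid$points_per_curve; K <- grid$n_surfaces; B <- grid$n_bscans
  if (x$n_landmarks != K * B * p)
    stop("shape vector inconsistent with the landmark grid", call. = FALSE)
  M <- lm_matrix(x)
  W <- as.integer(target_width)
  z <- array(0, c(W, B, K))
  row0 <- 0L
  for (k in seq_len(K)) {
    for (b in seq_len(B)) {
      idx <- row0 + seq_len(p)
      z[, b, k] <- curve_from_landmarks(M[idx, 1L], M[idx, 3L],
                                        grid$column_indices, W)
      row0 <- row0 + p
    }
  }
  z <- enforce_ordering(z, grid$axial_depth)
  surface_set(z, grid$axial_depth, spacing = grid$spacing)
}

#' Reconstruct 2-D boundary curves from a landmark cloud
#'
#' @param x a 2-D [shape_vector()] carrying a grid, or pass `grid`.
#' @param grid the [landmark_grid()] layout.
#' @param target_width output width (defaults to the grid's width).
#' @return `K x W` matrix of non-crossing boundary depths clamped to [0, H).
#' @export
landmarks_to_boundaries_2d <- function(x, grid = x$grid,
                                       target_width = grid$width) {
  stopifnot(inherits(x, "shape_vector"))
  if (is.null(grid)) stop("no landmark grid supplied", call. = FALSE)
  if (x$dim != 2L) stop("expected a 2-D shape vector", call. = FALSE)
  p <- grid$points_per_curve; K <- grid$n_surfaces
  if (x$n_landmarks != K * p)
    stop("shape vector inconsistent with the landmark grid", call. = FALSE)
  M <- lm_matrix(x)
  W <- as.integer(target_width)
  bnd <- matrix(0, K, W)
  for (k in seq_len(K)) {
    idx <- (k - 1L) * p + seq_len(p)
    bnd[k, ] <- curve_from_landmarks(M[idx, 1L], M[idx, 2L],
                                     grid$column_indices, W)
  }
  H <- grid$axial_depth
  bnd <- pmin(pmax(bnd, 0), H - 1e-6)
  for (k in seq_len(K)[-1L]) bnd[k, ] <- pmax(bnd[k, ], bnd[k - 1L, ])
  bnd
}

# cumulative-max ordering projection plus range clamp for W x B x K arrays
enforce_ordering <- function(z, axial_depth) {
  z <- pmin(pmax(z, 0), axial_depth - 1e-6)
  K <- dim(z)[3L]
  if (K > 1L) for (k in 2:K) z[, , k] <- pmax(z[, , k], z[, , k - 1L])
  z
}
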