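#' Shape vectors
#'
#' A shape vector is the flattened landmark cloud of one training example:
#' coordinates are interleaved per landmark, so a 3-D shape with n landmarks
#' is stored as (x1, y1, z1, ..., xn, yn, zn) and a 2-D one as
#' (x1, z1, ..., xn, zn). Vessel intensity profiles use `dim = 1`, in which
#' case the "coordinates" are the profile samples themselves.
#'
#' @param coords numeric vector of interleaved landmark coordinates.
#' @param dim coordinate dimensionality: 1, 2 or 3.
#' @return An object of class `shape_vector` with fields `coords`, `dim`
#'   and `n_landmarks`.
#' @export
shape_vector <- function(coords, dim = 3L) {
  coords <- as.numeric(coords)
  dim <- as.integer(dim)
  if (!dim %in% 1:3) stop("`dim` must be 1, 2 or 3", call. = FALSE)
  if (length(coords) == 0L || length(coords) %% dim != 0L)
    stop("length(coords) must be a positive multiple of `dim`", call. = FALSE)
  if (!all(is.finite(coords)))
    stop("all coordinates must be finite", call. = FALSE)
  structure(list(coords = coords, dim = dim,
                 n_landmarks = length(coords) %/% dim),
            class = "shape_vector")
}

#' @export
print.shape_vector <- function(x, ...) {
  cat(sprintf("<shape_vector> %d landmarks in %d-D (%d coordinates)\n",
              x$n_landmarks, x$dim, length(x$coords)))
  invisible(x)
}

# landmark matrix (n x dim) view of a shape vector
lm_matrix <- function(sv) {
  matrix(sv$coords, ncol = sv$dim, byrow = TRUE)
}

lm_to_shape <- function(M, template = NULL) {
  sv <- shape_vector(as.numeric(t(M)), dim = ncol(M))
  if (!is.null(template$grid)) sv$grid <- template$grid
  sv
}

check_same_layout <- function(shapes) {
  if (length(shapes) < 2L)
    stop("need at least 2 shapes", call. = FALSE)
  d <- vapply(shapes, function(s) s$dim, integer(1))
  n <- vapply(shapes, function(s) s$n_landmarks, integer(1))
  if (length(unique(d)) != 1L || length(unique(n)) != 1L)
    stop("shapes differ in landmark count or dimensionality", call. = FALSE)
  invisible(TRUE)
}

#' Similarity transforms
#'
#' @param rotation orthogonal `dim x dim` matrix with determinant +1.
#' @param scale positive scalar.
#' @param translation numeric vector of length `dim`.
#' @return An object of class `similarity_transform`.
#' @export
similarity_transform <- function(rotation, scale, translation) {
  rotation <- as.matrix(rotation)
  d <- nrow(rotation)
  if (ncol(rotation) != d) stop("rotation must be square", call. = FALSE)
  if (max(abs(crossprod(rotation) - diag(d))) > 1e-8)
    stop("rotation must be orthogonal", call. = FALSE)
  if (det(rotation) < 0) stop("rotation must be proper (det +1)", call. = FALSE)
  if (!is.finite(scale) || scale <= 0) stop("scale must be positive", call. = FALSE)
  structure(list(rotation = rotation, scale = scale,
                 translation = as.numeric(translation)),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf("<similarity_transform> dim %d, scale %.6g, |t| %.6g\n",
              nrow(x$rotation), x$scale, sqrt(sum(x$translation^2))))
  invisible(x)
}

apply_transform <- function(M, tf) {
  sweep(tf$scale * M %*% tf$rotation, 2, tf$translation, "+")
}

# Least-squares similarity fit of X onto Y (ordinary Procrustes with scaling).
fit_similarity <- function(X, Y) {
  d <- ncol(X)
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  ssx <- sum(Xc^2)
  if (ssx < .Machine$double.eps)
    stop("degenerate shape: all landmarks coincide", call. = FALSE)
  if (d == 1L) {
    R <- matrix(1, 1, 1)
    s <- abs(sum(Xc * Yc)) / ssx
    if (s <= 0) s <- 1
  } else {
    sv <- svd(crossprod(Xc, Yc))
    flip <- sign(det(sv$u %*% t(sv$v)))
    if (flip == 0) flip <- 1
    Dfix <- diag(c(rep(1, d - 1), flip), d)
    R <- sv$u %*% Dfix %*% t(sv$v)
    s <- sum(sv$d * diag(Dfix)) / ssx
    if (s <= 0) s <- .Machine$double.eps
  }
  tr <- cy - as.numeric(crossprod(cx, R)) * s
  similarity_transform(R, s, tr)
}

#' Generalized Procrustes alignment of a set of shapes
#'
#' Iteratively aligns every shape to the running mean shape by a similarity
#' transform (rotation, isotropic scale, translation), then recomputes the
#' mean, until the mean moves by less than `tol` or `max_iter` iterations are
#' reached. The first shape provides the initial reference frame, so a set of
#' identical shapes is returned unchanged with identity transforms.
#'
#' @param shapes list of [shape_vector()]s sharing landmark count and `dim`.
#' @param tol convergence tolerance on the mean shape (default 1e-8).
#' @param max_iter maximum number of Procrustes iterations (default 50).
#' @return list with `aligned` (list of shape vectors) and `transforms`
#'   (list of [similarity_transform()]s mapping each input onto its aligned
#'   version).
#' @export
align_shapes <- function(shapes, tol = 1e-8, max_iter = 50L) {
  check_same_layout(shapes)
  mats <- lapply(shapes, lm_matrix)
  for (M in mats) {
    if (sum(sweep(M, 2, colMeans(M))^2) < .Machine$double.eps)
      stop("degenerate shape: all landmarks coincide", call. = FALSE)
  }
  # anchoring the initial reference at the arithmetic mean makes alignment
  # of an already-aligned set a no-op (idempotence); renormalizing the mean
  # to its initial centroid size prevents the classic GPA scale shrinkage
  mean_ref <- Reduce(`+`, mats) / length(mats)
  csize <- function(M) sqrt(sum(sweep(M, 2, colMeans(M))^2))
  size0 <- csize(mean_ref)
  transforms <- NULL
  for (it in seq_len(max_iter)) {
    transforms <- lapply(mats, fit_similarity, Y = mean_ref)
    aligned <- Map(apply_transform, mats, transforms)
    new_mean <- Reduce(`+`, aligned) / length(aligned)
    ctr <- colMeans(new_mean)
    new_mean <- sweep(sweep(new_mean, 2, ctr) * (size0 / csize(new_mean)),
                      2, ctr, "+")
    delta <- max(abs(new_mean - mean_ref))
    mean_ref <- new_mean
    if (delta < tol) break
  }
  transforms <- lapply(mats, fit_similarity, Y = mean_ref)
  # pin the output frame to the first shape: composing every transform with
  # the inverse of the first leaves shape 1 exactly unchanged, makes
  # identical inputs map to identity transforms, and renders re-alignment
  # of an aligned set an exact no-op (the GPA solution is unique up to a
  # global similarity, which this rule fixes deterministically)
  inv1 <- invert_transform(transforms[[1L]])
  transforms <- lapply(transforms, function(tf) compose_transforms(inv1, tf))
  aligned <- Map(apply_transform, mats, transforms)
  list(aligned = Map(lm_to_shape, aligned, shapes),
       transforms = transforms)
}

invert_transform <- function(tf) {
  Rt <- t(tf$rotation)
  similarity_transform(Rt, 1 / tf$scale,
                       -as.numeric(tf$translation %*% Rt) / tf$scale)
}

# g(f(x)): apply f first, then g
compose_transforms <- function(g, f) {
  similarity_transform(f$rotation %*% g$rotation, g$scale * f$scale,
                       g$scale * as.numeric(f$translation %*% g$rotation) +
                         g$translation)
}

#' Fit a point distribution model
#'
#' Fits the linear generative shape model X = xbar + P b to a set of aligned
#' shape vectors: the mean shape is the arithmetic mean, the covariance uses
#' the 1/N normalization S = (1/N) sum (xbar - x_i)(xbar - x_i)^T, and the
#' modes P and variances sigma_i are its leading eigenpairs, computed through
#' the SVD of the centred data matrix so that wide problems (tens of
#' thousands of coordinates, few training shapes) stay cheap.
#'
#' The number of retained modes t is the smallest count whose cumulative
#' share of total variance reaches `variance_fraction`; with degenerate
#' (zero-variance) training sets a single zero-variance mode is kept by
#' convention. Mode signs are fixed so the first component of each mode that
#' is nonzero (beyond 1e-12) is positive.
#'
#' @param shapes list of aligned [shape_vector()]s (use [align_shapes()]
#'   first for 2-D/3-D landmark clouds).
#' @param variance_fraction cumulative explained-variance threshold in (0, 1]
#'   used to pick the mode count t (default 0.94).
#' @return An object of class `pdm`: list with `mean`, `modes` (L x t,
#'   orthonormal columns), `variances` (descending), `total_variance`,
#'   `all_variances`, `n_training`, `dim`, `n_landmarks`,
#'   `variance_fraction` and optionally the landmark `grid` carried by the
#'   training shapes.
#' @seealso [sample_shape()], [random_coefficients()], [project_shape()]
#' @export
pdm <- function(shapes, variance_fraction = 0.94) {
  if (length(shapes) < 2L)
    stop("insufficient data: need at least 2 shapes to fit a PDM", call. = FALSE)
  check_same_layout(shapes)
  if (!is.numeric(variance_fraction) || variance_fraction <= 0 ||
      variance_fraction > 1)
    stop("`variance_fraction` must be in (0, 1]", call. = FALSE)
  X <- do.call(rbind, lapply(shapes, function(s) s$coords))
  N <- nrow(X); L <- ncol(X)
  xbar <- colMeans(X)
  Xc <- sweep(X, 2, xbar)
  total_variance <- sum(Xc^2) / N
  sv <- svd(Xc, nu = 0)
  ev <- sv$d^2 / N                      # eigenvalues of (1/N) Xc' Xc
  keep <- which(ev > max(ev[1], 0) * 1e-12)
  if (total_variance < 1e-300 || length(keep) == 0L) {
    # all training shapes identical: one zero-variance mode by convention
    mode1 <- rep(0, L); mode1[1L] <- 1
    modes <- matrix(mode1, ncol = 1L)
    variances <- 0
    all_var <- 0
  } else {
    ev <- ev[keep]
    modes <- sv$v[, keep, drop = FALSE]
    share <- cumsum(ev) / total_variance
    t_sel <- which(share >= variance_fraction)[1L]
    if (is.na(t_sel)) t_sel <- length(ev)
    modes <- modes[, seq_len(t_sel), drop = FALSE]
    variances <- ev[seq_len(t_sel)]
    all_var <- ev
  }
  # deterministic sign convention: first non-negligible entry positive
  for (j in seq_len(ncol(modes))) {
    nz <- which(abs(modes[, j]) > 1e-12)
    if (length(nz) && modes[nz[1L], j] < 0) modes[, j] <- -modes[, j]
  }
  out <- structure(list(
    mean = xbar,
    modes = modes,
    variances = variances,
    total_variance = total_variance,
    all_variances = all_var,
    n_training = N,
    dim = shapes[[1L]]$dim,
    n_landmarks = shapes[[1L]]$n_landmarks,
    variance_fraction = variance_fraction
  ), class = "pdm")
  if (!is.null(shapes[[1L]]$grid)) out$grid <- shapes[[1L]]$grid
  out
}

n_modes <- function(model) ncol(model$modes)

#' @export
print.pdm <- function(x, ...) {
  cat(sprintf("<pdm> %d-D point distribution model\n", x$dim))
  cat(sprintf("  landmarks: %d (%d coordinates), training shapes: %d\n",
              x$n_landmarks, length(x$mean), x$n_training))
  expl <- if (x$total_variance > 0) sum(x$variances) / x$total_variance else 1
  cat(sprintf("  modes retained: %d (%.1f%% of variance, threshold %.0f%%)\n",
              n_modes(x), 100 * expl, 100 * x$variance_fraction))
  invisible(x)
}

#' @export
summary.pdm <- function(object, ...) {
  v <- object$all_variances
  tab <- data.frame(
    mode = seq_along(v),
    variance = v,
    share = if (object$total_variance > 0) v / object$total_variance else 1,
    cumulative = if (object$total_variance > 0)
      cumsum(v) / object$total_variance else 1,
    retained = seq_along(v) <= n_modes(object)
  )
  structure(list(table = tab, t = n_modes(object),
                 total_variance = object$total_variance,
                 n_training = object$n_training,
                 variance_fraction = object$variance_fraction),
            class = "summary.pdm")
}

#' @export
print.summary.pdm <- function(x, ...) {
  cat(sprintf("Point distribution model: %d training shapes, t = %d modes\n",
              x$n_training, x$t))
  cat(sprintf("Total variance %.6g; cumulative threshold %.2f\n",
              x$total_variance, x$variance_fraction))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.pdm <- function(object, ...) {
  stats::setNames(sqrt(object$variances),
                  paste0("sd_b", seq_along(object$variances)))
}

#' @export
plot.pdm <- function(x, ...) {
  v <- x$all_variances
  share <- if (x$total_variance > 0) v / x$total_variance else rep(1, length(v))
  graphics::barplot(100 * share, names.arg = seq_along(v),
                    xlab = "mode", ylab = "% of total variance",
                    main = "PDM scree", ...)
  graphics::abline(h = 0)
  invisible(x)
}

#' Generate a shape from mode coefficients
#'
#' Evaluates the linear generative model X = xbar + P b. In constrained mode
#' every coefficient is kept within plus/minus 3 sqrt(sigma_i) of zero
#' (coefficients outside the band are clipped with a warning); unconstrained
#' mode — used for pathology synthesis where boundary overshoots are
#' legitimate — passes b through unchanged.
#'
#' @param model a [pdm()] fit.
#' @param b numeric coefficient vector of length t (the retained mode count).
#' @param constrained clip coefficients to the 3-sigma band? Default TRUE.
#' @return A [shape_vector()].
#' @export
sample_shape <- function(model, b, constrained = TRUE) {
  stopifnot(inherits(model, "pdm"))
  b <- as.numeric(b)
  t_ <- n_modes(model)
  if (length(b) != t_)
    stop(sprintf("`b` must have length %d (got %d)", t_, length(b)),
         call. = FALSE)
  if (constrained) {
    lim <- 3 * sqrt(model$variances)
    out_of_band <- abs(b) > lim & lim >= 0
    if (any(out_of_band)) {
      warning(sprintf("%d coefficient(s) clipped to the +/-3*sqrt(sigma) band",
                      sum(out_of_band)), call. = FALSE)
      b <- pmin(pmax(b, -lim), lim)
    }
  }
  x <- model$mean + as.numeric(model$modes %*% b)
  sv <- shape_vector(x, dim = model$dim)
  if (!is.null(model$grid)) sv$grid <- model$grid
  sv
}

#' @export
predict.pdm <- function(object, b = NULL, constrained = TRUE, ...) {
  if (is.null(b)) b <- rep(0, n_modes(object))
  sample_shape(object, b, constrained = constrained)
}

#' Draw random mode coefficients
#'
#' Coefficients are drawn independently per mode from Normal(0, sigma_i),
#' the Gaussian assumed for the training population. In constrained mode,
#' out-of-band values are redrawn (per-component rejection) until every
#' |b_i| <= 3 sqrt(sigma_i), which preserves the truncated-Gaussian shape.
#'
#' @param model a [pdm()] fit.
#' @param n number of coefficient vectors to draw.
#' @param constrained enforce the 3-sigma band by rejection? Default TRUE.
#' @param seed optional integer seed for reproducibility.
#' @return An `n x t` numeric matrix of coefficients (one row per draw).
#' @export
random_coefficients <- function(model, n = 1L, constrained = TRUE,
                                seed = NULL) {
  stopifnot(inherits(model, "pdm"))
  if (!is.null(seed)) set.seed(seed)
  t_ <- n_modes(model)
  sdv <- sqrt(model$variances)
  B <- matrix(stats::rnorm(n * t_), n, t_) * rep(sdv, each = n)
  if (constrained) {
    lim <- matrix(3 * sdv, n, t_, byrow = TRUE)
    bad <- abs(B) > lim
    while (any(bad)) {
      idx <- which(bad)
      B[idx] <- stats::rnorm(length(idx)) *
        matrix(sdv, n, t_, byrow = TRUE)[idx]
      bad <- abs(B) > lim
    }
  }
  B
}

#' @export
simulate.pdm <- function(object, nsim = 1L, seed = NULL,
                         constrained = TRUE, ...) {
  B <- random_coefficients(object, n = nsim, constrained = constrained,
                           seed = seed)
  shapes <- lapply(seq_len(nsim), function(i)
    sample_shape(object, B[i, ], constrained = FALSE))
  attr(shapes, "coefficients") <- B
  shapes
}

#' Project a shape onto the model subspace
#'
#' Returns the least-squares mode coefficients b = P^T (x - xbar). Because
#' the modes are orthonormal, sampling a shape from coefficients b and
#' projecting it back recovers b exactly; for shapes outside the mode
#' subspace the reconstruction xbar + P b is the orthogonal projection.
#'
#' @param model a [pdm()] fit.
#' @param x a [shape_vector()] in the model frame.
#' @return Numeric coefficient vector of length t.
#' @export
project_shape <- function(model, x) {
  stopifnot(inherits(model, "pdm"))
  coords <- if (inherits(x, "shape_vector")) x$coords else as.numeric(x)
  if (length(coords) != length(model$mean))
    stop("shape length does not match the model", call. = FALSE)
  as.numeric(crossprod(model$modes, coords - model$mean))
}

#' @export
residuals.pdm <- function(object, x, ...) {
  coords <- if (inherits(x, "shape_vector")) x$coords else as.numeric(x)
  b <- project_shape(object, coords)
  coords - (object$mean + as.numeric(object$modes %*% b))
}
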