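#' OCT intensity volumes
#'
#' @param a numeric array `H x W x B` (axial row, column, B-scan) with
#'   values in [0, 1].
#' @param spacing optional voxel spacing `(dx, dy, dz)` in micrometres.
#' @param provenance list of free-form provenance fields (seeds, model ids,
#'   noise level, planted vessel placements, ...).
#' @return An object of class `oct_volume`.
#' @export
oct_volume <- function(a, spacing = NULL, provenance = list()) {
  a <- unclass(a)
  if (length(dim(a)) != 3L)
    stop("`a` must be an H x W x B array", call. = FALSE)
  if (any(!is.finite(a)) || any(a < 0) || any(a > 1))
    stop("intensities must be finite and within [0, 1]", call. = FALSE)
  structure(list(a = a, spacing = spacing, provenance = provenance),
            class = "oct_volume")
}

vol_dims <- function(v) {
  d <- dim(v$a)
  list(H = d[1L], W = d[2L], B = d[3L])
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- vol_dims(x)
  cat(sprintf("<oct_volume> %d B-scans x %d rows x %d columns, range [%.3f, %.3f]\n",
              d$B, d$H, d$W, min(x$a), max(x$a)))
  invisible(x)
}

#' @export
plot.oct_volume <- function(x, bscan = NULL, ...) {
  d <- vol_dims(x)
  if (is.null(bscan)) bscan <- (d$B + 1L) %/% 2L
  img <- x$a[, , bscan]
  graphics::image(t(img)[, d$H:1], col = grDevices::gray.colors(256, 0, 1),
                  axes = FALSE, asp = d$H / d$W,
                  main = sprintf("B-scan %d", bscan), ...)
  invisible(x)
}

# layer mask for one B-scan: H x W logical, rows r with z_lo <= r < z_hi
layer_mask_bscan <- function(z_lo, z_hi, H) {
  r <- 0:(H - 1L)
  outer(r, z_lo, ">=") & outer(r, z_hi, "<")
}

#' Layer appearance models
#'
#' Per-layer mean brightness learned from training B-scans; `mu[k]` fills
#' the layer between surfaces k and k+1 when rendering.
#'
#' @param mu numeric vector of K-1 layer brightnesses in [0, 1].
#' @param source list describing how the estimate was obtained (selected
#'   B-scans, seed, fraction).
#' @return An object of class `layer_appearance`.
#' @export
layer_appearance <- function(mu, source = list()) {
  mu <- as.numeric(mu)
  if (any(!is.finite(mu)) || any(mu < 0) || any(mu > 1))
    stop("layer brightness must be within [0, 1]", call. = FALSE)
  structure(list(mu = mu, source = source), class = "layer_appearance")
}

#' Estimate layer brightness from training volumes
#'
#' Selects `ceiling(fraction x total B-scans)` B-scans at random across the
#' training set (re-drawn per call so successive synthetic volumes vary in
#' appearance) and sets each layer's brightness to the mean intensity of the
#' voxels between its bounding surfaces over the selection. B-scans where a
#' layer has no voxels are excluded from that layer's average.
#'
#' @param volumes list of [oct_volume()]s.
#' @param surfaces list of matching [surface_set()]s.
#' @param fraction fraction of all B-scans to sample, in (0, 1]. Default 0.5.
#' @param seed optional integer seed.
#' @return A [layer_appearance()].
#' @export
estimate_appearance <- function(volumes, surfaces, fraction = 0.5,
                                seed = NULL) {
  if (length(volumes) != length(surfaces) || length(volumes) == 0L)
    stop("need matching, non-empty volume and surface lists", call. = FALSE)
  if (fraction <= 0 || fraction > 1)
    stop("`fraction` must be in (0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  scans <- do.call(rbind, lapply(seq_along(volumes), function(v) {
    d <- vol_dims(volumes[[v]])
    cbind(vol = v, b = seq_len(d$B))
  }))
  n_sel <- ceiling(fraction * nrow(scans))
  sel <- scans[sample.int(nrow(scans), n_sel), , drop = FALSE]
  K <- surf_dims(surfaces[[1L]])$K
  sums <- numeric(K - 1L); counts <- numeric(K - 1L)
  for (i in seq_len(nrow(sel))) {
    v <- sel[i, "vol"]; b <- sel[i, "b"]
    img <- volumes[[v]]$a[, , b]
    H <- nrow(img)
    z <- surfaces[[v]]$z
    for (k in seq_len(K - 1L)) {
      m <- layer_mask_bscan(z[, b, k], z[, b, k + 1L], H)
      n <- sum(m)
      if (n > 0) { sums[k] <- sums[k] + sum(img[m]); counts[k] <- counts[k] + n }
    }
  }
  if (any(counts == 0))
    stop("appearance estimation failed: a layer is empty in every selected B-scan",
         call. = FALSE)
  layer_appearance(sums / counts,
                   source = list(fraction = fraction, seed = seed,
                                 selected = sel))
}

#' Render boundary surfaces into a noise-free layer volume
#'
#' Fills the voxels between successive surfaces with the layer's mean
#' brightness. Voxel ownership is half-open: row r belongs to layer k when
#' z_k <= r < z_k+1, so a voxel exactly on a boundary belongs to the layer
#' below it. Regions above the first surface and below the last are left at
#' zero pending background compositing.
#'
#' @param surfaces a non-crossing [surface_set()].
#' @param appearance a [layer_appearance()] with K-1 brightness values.
#' @return An [oct_volume()].
#' @export
render_layers <- function(surfaces, appearance) {
  stopifnot(inherits(surfaces, "surface_set"),
            inherits(appearance, "layer_appearance"))
  validate_surfaces(surfaces)
  d <- surf_dims(surfaces)
  if (length(appearance$mu) != d$K - 1L)
    stop("appearance must supply K-1 layer brightnesses", call. = FALSE)
  H <- as.integer(surfaces$axial_depth)
  a <- array(0, c(H, d$W, d$B))
  for (b in seq_len(d$B)) {
    sl <- matrix(0, H, d$W)
    for (k in seq_len(d$K - 1L)) {
      m <- layer_mask_bscan(surfaces$z[, b, k], surfaces$z[, b, k + 1L], H)
      sl[m] <- appearance$mu[k]
    }
    a[, , b] <- sl
  }
  oct_volume(a, spacing = surfaces$spacing,
             provenance = list(stage = "layers"))
}

# resample a column segment to a new length by linear interpolation
resample_segment <- function(vals, n_out) {
  n_in <- length(vals)
  if (n_out <= 0L) return(numeric(0))
  if (n_in == 0L) return(rep(0, n_out))
  if (n_in == 1L) return(rep(vals, n_out))
  stats::approx(seq(0, 1, length.out = n_in), vals,
                xout = seq(0, 1, length.out = n_out))$y
}

#' Composite choroid and background from a reference volume
#'
#' Per A-scan, the voxels above the first surface are copied from the
#' reference's above-ILM region and those below the last surface from its
#' below-BM region, axially resampled (linear interpolation) so the copied
#' segment exactly fills the target extent. Retinal voxels are untouched.
#'
#' @param volume target [oct_volume()] (typically a layer render).
#' @param surfaces the target's [surface_set()].
#' @param reference reference [oct_volume()] providing background/choroid,
#'   or NULL (volume returned unchanged with a warning).
#' @param reference_surfaces the reference's [surface_set()].
#' @return An [oct_volume()].
#' @export
composite_background <- function(volume, surfaces, reference,
                                 reference_surfaces) {
  stopifnot(inherits(volume, "oct_volume"), inherits(surfaces, "surface_set"))
  if (is.null(reference)) {
    warning("no reference volume supplied; background left empty",
            call. = FALSE)
    return(volume)
  }
  d <- vol_dims(volume)
  dr <- vol_dims(reference)
  K <- surf_dims(surfaces)$K
  Kr <- surf_dims(reference_surfaces)$K
  a <- volume$a
  for (b in seq_len(d$B)) {
    br <- min(b, dr$B)
    # reference columns resampled laterally if widths differ
    xr_of <- if (d$W == dr$W) seq_len(d$W) else
      pmax(1L, pmin(dr$W, round(seq(1, dr$W, length.out = d$W))))
    for (x in seq_len(d$W)) {
      xr <- xr_of[x]
      # above first surface
      nt <- ceiling(surfaces$z[x, b, 1L])
      nr <- ceiling(reference_surfaces$z[xr, br, 1L])
      if (nt > 0L) {
        seg <- if (nr > 0L) reference$a[seq_len(nr), xr, br] else numeric(0)
        a[seq_len(nt), x, b] <- resample_segment(seg, nt)
      }
      # below last surface
      lo_t <- ceiling(surfaces$z[x, b, K])
      lo_r <- ceiling(reference_surfaces$z[xr, br, Kr])
      nt2 <- d$H - lo_t
      nr2 <- dr$H - lo_r
      if (nt2 > 0L) {
        seg <- if (nr2 > 0L) reference$a[lo_r + seq_len(nr2), xr, br]
               else numeric(0)
        a[lo_t + seq_len(nt2), x, b] <- resample_segment(seg, nt2)
      }
    }
  }
  oct_volume(pmin(pmax(a, 0), 1), spacing = volume$spacing,
             provenance = c(volume$provenance, list(background = "reference")))
}

#' Apply multiplicative speckle noise
#'
#' Uses the signal-proportional surrogate for OCT speckle:
#' I' = clip(I (1 + eta), 0, 1) with eta iid Normal(0, sigma^2) per voxel.
#' A gamma-multiplicative alternative (`family = "gamma"`, shape 1/sigma^2,
#' unit mean) is available.
#'
#' @param volume an [oct_volume()].
#' @param sigma noise standard deviation, >= 0. `sigma = 0` returns the
#'   input unchanged.
#' @param seed optional integer seed.
#' @param family `"gaussian"` (default) or `"gamma"`.
#' @return An [oct_volume()].
#' @export
add_speckle <- function(volume, sigma, seed = NULL,
                        family = c("gaussian", "gamma")) {
  stopifnot(inherits(volume, "oct_volume"))
  family <- match.arg(family)
  if (!is.numeric(sigma) || sigma < 0)
    stop("`sigma` must be a non-negative number", call. = FALSE)
  if (sigma == 0) return(volume)
  if (!is.null(seed)) set.seed(seed)
  n <- length(volume$a)
  mult <- if (family == "gaussian") 1 + stats::rnorm(n, 0, sigma)
          else stats::rgamma(n, shape = 1 / sigma^2, rate = 1 / sigma^2)
  a <- volume$a * array(mult, dim(volume$a))
  oct_volume(pmin(pmax(a, 0), 1), spacing = volume$spacing,
             provenance = c(volume$provenance,
                            list(speckle_sigma = sigma, speckle_seed = seed)))
}
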