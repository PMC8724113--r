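#' Phantom generator configuration
#'
#' Parametric-analytic phantom of a macular OCT cohort: each boundary
#' surface is a base depth plus a Gaussian foveal pit and a smooth seeded
#' perturbation, so closed-form ground truth is available for every test.
#' The default geometry is a 19-B-scan, 512-column, 496-row volume with
#' nine surfaces and a training cohort of five volumes, matching a typical
#' macular raster protocol.
#'
#' @param n_volumes number of training volumes (default 5).
#' @param n_surfaces K (default 9).
#' @param n_bscans B (default 19).
#' @param width W (default 512).
#' @param axial_depth H (default 496).
#' @param base_depths length-K baseline surface depths in voxels.
#' @param pit_depth foveal pit amplitude at the inner surface, voxels.
#' @param pit_profile length-K per-surface pit coefficients (1 at the inner
#'   limiting membrane decaying to 0 at the outer surfaces).
#' @param pit_width_x,pit_width_b Gaussian pit widths in columns / B-scans.
#' @param fovea_jitter max random lateral fovea shift per volume, columns.
#' @param shift_sd per-volume axial translation SD, voxels.
#' @param scale_sd per-volume retinal thickness scale SD (about 1).
#' @param pit_jitter_sd per-volume relative jitter of the pit depth
#'   (default 0.08; clamped to keep surfaces ordered).
#' @param perturb_amplitude per-surface smooth perturbation SD, voxels.
#' @param layer_brightness length K-1 mean layer brightness vector.
#' @param axial_gradient linear within-retina brightness gradient (default
#'   0 = off, so noise-free layer means equal `layer_brightness` exactly).
#' @param background_level,choroid_level background and choroid base
#'   brightness used when compositing synthetic content.
#' @param n_vessels vessels per volume for [generate_volume()] (default 6).
#' @param noise_sigma speckle level for generated volumes (default 0.05).
#' @param fluid_range number of fluid pockets per DME reference (inclusive
#'   range, default 1-3).
#' @param spacing voxel spacing `(dx, dy, dz)` in micrometres or NULL.
#' @param seed integer seed for all phantom randomness.
#' @return An object of class `phantom_config` (a validated list).
#' @export
phantom_config <- function(n_volumes = 5L, n_surfaces = 9L, n_bscans = 19L,
                           width = 512L, axial_depth = 496L,
                           base_depths = NULL, pit_depth = NULL,
                           pit_profile = NULL, pit_width_x = NULL,
                           pit_width_b = NULL, fovea_jitter = NULL,
                           shift_sd = NULL, scale_sd = 0.05,
                           pit_jitter_sd = 0.08,
                           perturb_amplitude = NULL,
                           layer_brightness = NULL, axial_gradient = 0,
                           background_level = 0.04, choroid_level = 0.45,
                           n_vessels = 6L, noise_sigma = 0.05,
                           fluid_range = c(1L, 3L), spacing = NULL,
                           seed = 1L) {
  K <- as.integer(n_surfaces)
  # depth-dependent defaults scale with the axial extent so reduced test
  # geometries keep the same relative anatomy as the full-size default
  zscale <- axial_depth / 496
  if (is.null(pit_depth)) pit_depth <- 40 * zscale
  if (is.null(shift_sd)) shift_sd <- 5 * zscale
  if (is.null(perturb_amplitude)) perturb_amplitude <- 1.0 * zscale
  if (is.null(fovea_jitter)) fovea_jitter <- max(width / 64, 2)
  if (is.null(base_depths)) {
    frac <- c(0, 8, 28, 36, 44, 51, 59, 66, 80) / 80
    base_depths <- axial_depth * (0.36 + 0.17 * frac[seq_len(K)])
  }
  if (is.null(pit_profile)) {
    pit_profile <- c(1, 0.93, 0.75, 0.62, 0.50, 0.38, 0.26, 0.13, 0)[seq_len(K)]
    pit_profile[is.na(pit_profile)] <- 0
  }
  if (is.null(pit_width_x)) pit_width_x <- width / 8
  if (is.null(pit_width_b)) pit_width_b <- max(n_bscans / 3.2, 1.5)
  if (is.null(layer_brightness))
    layer_brightness <- c(0.78, 0.40, 0.62, 0.33, 0.52, 0.30, 0.58,
                          0.85)[seq_len(K - 1L)]
  cfg <- list(n_volumes = as.integer(n_volumes), n_surfaces = K,
              n_bscans = as.integer(n_bscans), width = as.integer(width),
              axial_depth = as.numeric(axial_depth),
              base_depths = as.numeric(base_depths),
              pit_depth = pit_depth, pit_profile = pit_profile,
              pit_width_x = pit_width_x, pit_width_b = pit_width_b,
              fovea_jitter = fovea_jitter, shift_sd = shift_sd,
              scale_sd = scale_sd, pit_jitter_sd = pit_jitter_sd,
              perturb_amplitude = perturb_amplitude,
              layer_brightness = layer_brightness,
              axial_gradient = axial_gradient,
              background_level = background_level,
              choroid_level = choroid_level,
              n_vessels = as.integer(n_vessels),
              noise_sigma = noise_sigma,
              fluid_range = as.integer(fluid_range),
              spacing = spacing, seed = as.integer(seed))
  stopifnot(cfg$n_volumes > 0, cfg$n_surfaces > 1, cfg$n_bscans > 0,
            cfg$width > 2, cfg$axial_depth > 1,
            length(cfg$base_depths) == K, length(cfg$pit_profile) == K,
            length(cfg$layer_brightness) == K - 1L)
  structure(cfg, class = "phantom_config")
}

# smooth low-order 2D polynomial field with random coefficients
poly_field <- function(W, B, amplitude) {
  tx <- seq(-1, 1, length.out = W)
  tb <- if (B > 1L) seq(-1, 1, length.out = B) else 0
  cf <- stats::rnorm(6, 0, amplitude)
  outer(tx, tb, function(x, b)
    cf[1] + cf[2] * x + cf[3] * b + cf[4] * x * b + cf[5] * x^2 + cf[6] * b^2)
}

phantom_surface_array <- function(cfg) {
  W <- cfg$width; B <- cfg$n_bscans; K <- cfg$n_surfaces
  xf <- (W - 1) / 2 + stats::runif(1, -cfg$fovea_jitter, cfg$fovea_jitter)
  bf <- (B - 1) / 2
  shift <- stats::rnorm(1, 0, cfg$shift_sd)
  scl <- max(stats::rnorm(1, 1, cfg$scale_sd), 0.7)
  # the pit scales with retinal thickness so pit gradients cannot outrun
  # the (scaled) inter-surface gaps
  pit <- cfg$pit_depth *
    min(max(stats::rnorm(1, 1, cfg$pit_jitter_sd), 0.8), 1.15) * scl
  gx <- exp(-((0:(W - 1) - xf)^2) / (2 * cfg$pit_width_x^2))
  gb <- exp(-((0:(B - 1) - bf)^2) / (2 * cfg$pit_width_b^2))
  Gsurf <- outer(gx, gb)
  amp <- cfg$perturb_amplitude
  for (attempt in 1:4) {
    z <- array(0, c(W, B, K))
    shared <- poly_field(W, B, amp * 2)
    base1 <- cfg$base_depths[1L]
    for (k in seq_len(K)) {
      zk <- base1 + (cfg$base_depths[k] - base1) * scl + shift +
        pit * cfg$pit_profile[k] * Gsurf + shared +
        poly_field(W, B, amp * 0.3)
      z[, , k] <- zk
    }
    z <- pmin(pmax(z, 0), cfg$axial_depth - 1e-6)
    crossings <- 0
    if (K > 1L) for (k in 2:K)
      crossings <- crossings + sum(z[, , k] < z[, , k - 1L])
    if (crossings == 0) return(z)
    amp <- amp / 2
  }
  stop("generation error: surfaces keep crossing after amplitude reduction",
       call. = FALSE)
}

#' Generate phantom boundary surface sets
#'
#' Each surface is base depth + Gaussian foveal pit (deeper for inner
#' surfaces, vanishing at the outer ones) + a smooth low-order polynomial
#' perturbation, with per-volume axial shift, thickness scale, pit depth
#' and fovea position jitter supplying the population variation a shape
#' model can learn. Ordering is enforced by construction (amplitude is
#' halved and the volume re-drawn if surfaces cross) and verified.
#'
#' @param config a [phantom_config()].
#' @return list of `n_volumes` [surface_set()]s; reproducible per seed.
#' @export
generate_surfaces <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$seed)
  lapply(seq_len(config$n_volumes), function(v)
    surface_set(phantom_surface_array(config), config$axial_depth,
                spacing = config$spacing))
}

# analytic family of phantom vessel modulation profiles
phantom_vessel_profiles <- function(n = 12L, width = 15L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  u <- seq(-1, 1, length.out = width)
  lapply(seq_len(n), function(i) {
    a <- stats::runif(1, 0.3, 0.6)
    s <- stats::runif(1, 0.25, 0.4)
    p <- 1 - a * exp(-u^2 / (2 * s^2))
    p <- p / mean(p[c(1L, width)])
    vessel_profile(pmin(p, 1.049))
  })
}

# synthetic choroid/background reference content for one surface set
phantom_reference_volume <- function(surfaces, cfg) {
  d <- surf_dims(surfaces)
  H <- as.integer(surfaces$axial_depth)
  a <- array(cfg$background_level, c(H, d$W, d$B))
  r <- 0:(H - 1L)
  for (b in seq_len(d$B)) {
    zK <- surfaces$z[, b, d$K]
    below <- outer(r, zK, ">=")
    depth <- outer(r, zK, "-")
    chor <- cfg$choroid_level * exp(-pmax(depth, 0) / (H / 8)) + 0.05
    sl <- matrix(cfg$background_level, H, d$W)
    sl[below] <- chor[below]
    a[, , b] <- sl
  }
  oct_volume(pmin(pmax(a, 0), 1))
}

#' Render a phantom surface set into a full synthetic volume
#'
#' Renders the layers with the configured brightness vector (optionally
#' with a mild axial gradient), composites a synthetic choroid and
#' background, then optionally adds vessels (planted at known columns,
#' recorded in provenance) and speckle noise. Serves as the "real" data
#' stand-in throughout the test suite.
#'
#' @param surfaces a [surface_set()].
#' @param config a [phantom_config()].
#' @param vessels render vessels? Default `config$n_vessels > 0`.
#' @param noise_sigma speckle level; default from config. Use 0 for a
#'   noise-free volume.
#' @param seed optional integer seed (defaults to config seed).
#' @return An [oct_volume()]; planted vessel placements are in
#'   `$provenance$vessels`.
#' @export
generate_volume <- function(surfaces, config, vessels = NULL,
                            noise_sigma = NULL, seed = NULL) {
  stopifnot(inherits(surfaces, "surface_set"),
            inherits(config, "phantom_config"))
  if (is.null(vessels)) vessels <- config$n_vessels > 0L
  if (is.null(noise_sigma)) noise_sigma <- config$noise_sigma
  if (is.null(seed)) seed <- config$seed
  set.seed(seed)
  app <- layer_appearance(config$layer_brightness)
  vol <- render_layers(surfaces, app)
  if (config$axial_gradient != 0) {
    H <- vol_dims(vol)$H
    fac <- 1 - config$axial_gradient * (0:(H - 1)) / (H - 1)
    vol$a <- pmin(pmax(vol$a * fac, 0), 1)
  }
  ref <- phantom_reference_volume(surfaces, config)
  vol <- composite_background(vol, surfaces, ref, surfaces)
  if (vessels && config$n_vessels > 0L) {
    profs <- phantom_vessel_profiles(seed = seed + 1L)
    vm <- build_vessel_model(profs)
    # lateral parameters scale with width so reduced geometries stay feasible
    wscale <- config$width / 512
    pl <- sample_placements(
      surfaces, config$n_vessels, seed = seed + 2L,
      min_separation = max(3, round(12 * wscale)),
      fovea_radius = max(3, round(30 * wscale)),
      width_range = pmax(3, round(c(7, 13) * wscale)))
    vol <- render_vessels(vol, surfaces, pl, vm, seed = seed + 3L)
  }
  if (noise_sigma > 0) vol <- add_speckle(vol, noise_sigma, seed = seed + 4L)
  vol$spacing <- config$spacing
  vol$provenance$seed <- seed
  vol
}

#' Generate a phantom DME reference library
#'
#' Produces 2-D reference B-scans with bulged boundaries (the foveal pit
#' replaced by a central elevation, as edema lifts the inner retina),
#' rendered layer content with smooth texture variation and mild speckle,
#' and 1-3 ellipsoidal hyporeflective fluid pockets per scan placed inside
#' the mid-retinal layers; masks are consistent with the images and always
#' lie between boundaries 1 and 8.
#'
#' @param config a [phantom_config()]; `n_volumes` gives the number of
#'   reference B-scans.
#' @return A [dme_library()]; reproducible per seed.
#' @export
generate_dme_library <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$seed + 1000L)
  W <- config$width; H <- as.integer(config$axial_depth)
  K <- config$n_surfaces
  refs <- lapply(seq_len(config$n_volumes), function(i) {
    xf <- (W - 1) / 2 + stats::runif(1, -config$fovea_jitter,
                                     config$fovea_jitter)
    bulge <- stats::runif(1, 0.8, 1.6) * config$pit_depth
    gx <- exp(-((0:(W - 1) - xf)^2) / (2 * (config$pit_width_x * 1.3)^2))
    shift <- stats::rnorm(1, 0, config$shift_sd)
    bnd <- matrix(0, K, W)
    base1 <- config$base_depths[1L]
    for (k in seq_len(K)) {
      # inner boundaries lifted (smaller depth) by the central bulge
      bnd[k, ] <- config$base_depths[k] + shift -
        bulge * config$pit_profile[k] * gx +
        as.numeric(poly_field(W, 1L, config$perturb_amplitude * 0.3))
      # edema also thickens the retina: outer boundaries pushed mildly down
      bnd[k, ] <- bnd[k, ] + 0.25 * bulge * (1 - config$pit_profile[k]) * gx
    }
    bnd <- pmin(pmax(bnd, 1), H - 2)
    for (k in seq_len(K)[-1L]) bnd[k, ] <- pmax(bnd[k, ], bnd[k - 1L, ] + 0.5)
    # render the B-scan
    img <- matrix(config$background_level, H, W)
    r <- 0:(H - 1L)
    for (k in seq_len(K - 1L)) {
      m <- layer_mask_bscan(bnd[k, ], bnd[k + 1L, ], H)
      img[m] <- config$layer_brightness[k]
    }
    below <- outer(r, bnd[K, ], ">=")
    depth <- outer(r, bnd[K, ], "-")
    chor <- config$choroid_level * exp(-pmax(depth, 0) / (H / 8)) + 0.05
    img[below] <- chor[below]
    # smooth lateral texture variation so GLCM features are non-trivial
    tex <- 1 + 0.1 * sin(2 * pi * (0:(W - 1)) / W * stats::runif(1, 2, 5))
    img <- img * matrix(tex, H, W, byrow = TRUE)
    # fluid pockets between boundaries 4 and 7
    mask <- matrix(FALSE, H, W)
    fl_pool <- seq(config$fluid_range[1L], config$fluid_range[2L])
    n_fl <- fl_pool[sample.int(length(fl_pool), 1L)]
    for (f in seq_len(n_fl)) {
      cx <- stats::runif(1, 0.25 * W, 0.75 * W)
      k_lo <- 4L; k_hi <- min(7L, K - 1L)
      zc_lo <- bnd[k_lo, round(cx) + 0L]
      zc_hi <- bnd[k_hi, round(cx) + 0L]
      cz <- stats::runif(1, zc_lo + 2, max(zc_hi - 2, zc_lo + 3))
      rx <- stats::runif(1, W / 30, W / 12)
      rz <- stats::runif(1, 4, max((zc_hi - zc_lo) / 2, 5))
      ell <- outer(r, 0:(W - 1L), function(rr, xx)
        ((rr - cz) / rz)^2 + ((xx - cx) / rx)^2 <= 1)
      # clip to strictly inside boundaries 1..8
      k8 <- min(8L, K)
      inside <- outer(r, seq_len(W), function(rr, xx)
        rr > bnd[1L, xx] + 0.5 & rr < bnd[k8, xx] - 0.5)
      mask <- mask | (ell & inside)
    }
    img[mask] <- 0.08
    noisy <- add_speckle(oct_volume(array(pmin(pmax(img, 0), 1),
                                          c(H, W, 1L))), 0.04)$a[, , 1L]
    list(image = noisy, boundaries = bnd, fluid_mask = mask, id = i)
  })
  dme_library(refs)
}
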