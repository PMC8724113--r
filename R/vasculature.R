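#' Vessel intensity profiles
#'
#' A vessel profile is a 1-D multiplicative modulation curve across a
#' fixed-width column window: values near 1 at the window edges, dipping
#' below 1 at the centre where the vessel attenuates the signal beneath it.
#'
#' @param profile numeric vector of positive multiplicative factors.
#' @param center_column optional 0-based placement column.
#' @param edge_tol how close to 1 the window edges must be (default 0.05).
#' @return An object of class `vessel_profile`.
#' @export
vessel_profile <- function(profile, center_column = NA_real_,
                           edge_tol = 0.05) {
  profile <- as.numeric(profile)
  if (length(profile) < 3L) stop("profile too short", call. = FALSE)
  if (any(!is.finite(profile)) || any(profile <= 0))
    stop("profile factors must be positive", call. = FALSE)
  if (abs(profile[1L] - 1) > edge_tol ||
      abs(profile[length(profile)] - 1) > edge_tol)
    stop("profile must approach 1 at the window edges", call. = FALSE)
  structure(list(profile = profile, center_column = center_column,
                 width = length(profile)),
            class = "vessel_profile")
}

#' Fit a point distribution model to vessel profiles
#'
#' Reuses the PDM machinery with `dim = 1` over the profile samples, so the
#' same mean/modes/variance limits of the shape model apply to vessel
#' appearance. Profiles of differing widths are resampled to the widest one
#' with a warning.
#'
#' @param profiles list of [vessel_profile()]s (>= 2).
#' @param variance_fraction cumulative variance threshold (default 0.94).
#' @return A [pdm()] with `dim = 1`; the common width is stored as
#'   `$profile_width`.
#' @export
build_vessel_model <- function(profiles, variance_fraction = 0.94) {
  if (length(profiles) < 2L)
    stop("need at least 2 training profiles", call. = FALSE)
  widths <- vapply(profiles, function(p) p$width, integer(1))
  w <- max(widths)
  if (length(unique(widths)) > 1L) {
    warning("mixed profile widths; resampling to the widest", call. = FALSE)
    profiles <- lapply(profiles, function(p) {
      if (p$width == w) return(p)
      vessel_profile(resample_segment(p$profile, w), p$center_column)
    })
  }
  shapes <- lapply(profiles, function(p) shape_vector(p$profile, dim = 1L))
  model <- pdm(shapes, variance_fraction = variance_fraction)
  model$profile_width <- w
  model
}

#' Sample lateral vessel placements
#'
#' Draws `n_vessels` vessel tracks with seeded randomness: each track has a
#' base column kept outside the foveal avascular zone and separated from
#' other tracks by at least `min_separation`, then persists across B-scans
#' with bounded lateral jitter, emulating the cross-sectional continuity of
#' real vasculature. Real placements can be supplied instead via
#' [read_placements()].
#'
#' @param surfaces the target [surface_set()] (supplies geometry and fovea).
#' @param n_vessels number of vessel tracks (>= 0).
#' @param seed optional integer seed.
#' @param min_separation minimum distance between track centres in voxels.
#' @param fovea_radius half-width of the excluded foveal zone in columns.
#' @param jitter maximum per-B-scan lateral displacement in columns.
#' @param width_range inclusive range of window widths to draw from.
#' @param fovea_column 0-based foveal column, or `"auto"`.
#' @return An object of class `vessel_placement`: data frame with columns
#'   `bscan_idx`, `center_column`, `width`, `track_id` (0-based indices).
#' @export
sample_placements <- function(surfaces, n_vessels, seed = NULL,
                              min_separation = 12, fovea_radius = 30,
                              jitter = 2, width_range = c(7, 13),
                              fovea_column = "auto") {
  stopifnot(inherits(surfaces, "surface_set"), n_vessels >= 0)
  d <- surf_dims(surfaces)
  if (identical(fovea_column, "auto")) fovea_column <- find_fovea(surfaces)
  if (!is.null(seed)) set.seed(seed)
  empty <- data.frame(bscan_idx = integer(0), center_column = numeric(0),
                      width = integer(0), track_id = integer(0))
  if (n_vessels == 0L) return(structure(empty, class = c("vessel_placement", "data.frame")))
  wmax <- max(width_range)
  margin <- ceiling(wmax / 2) + jitter
  ok_col <- function(x) {
    x >= margin & x <= d$W - 1L - margin &
      abs(x - fovea_column) > fovea_radius + jitter
  }
  candidates <- which(ok_col(0:(d$W - 1L))) - 1L
  if (length(candidates) == 0L)
    stop("placement error: no admissible columns for this geometry",
         call. = FALSE)
  centers <- numeric(0)
  tries <- 0L
  while (length(centers) < n_vessels) {
    tries <- tries + 1L
    if (tries > 200L * n_vessels)
      stop("placement error: cannot fit the requested vessels with this separation",
           call. = FALSE)
    cand <- candidates[sample.int(length(candidates), 1L)]
    if (all(abs(cand - centers) >= min_separation + 2 * jitter))
      centers <- c(centers, cand)
  }
  widths_pool <- seq(min(width_range), max(width_range), by = 2)
  widths <- widths_pool[sample.int(length(widths_pool), n_vessels,
                                   replace = TRUE)]
  rows <- do.call(rbind, lapply(seq_len(n_vessels), function(tr) {
    jit_pool <- seq(-jitter, jitter)
    jit <- jit_pool[sample.int(length(jit_pool), d$B, replace = TRUE)]
    cc <- centers[tr] + jit
    # keep jittered centres outside the foveal zone and inside the image
    off <- abs(cc - fovea_column) <= fovea_radius
    cc[off] <- fovea_column +
      sign(cc[off] - fovea_column + 1e-9) * (fovea_radius + 1)
    cc <- pmin(pmax(cc, margin), d$W - 1L - margin)
    data.frame(bscan_idx = 0:(d$B - 1L), center_column = cc,
               width = widths[tr], track_id = tr - 1L)
  }))
  structure(rows, class = c("vessel_placement", "data.frame"))
}

#' @export
print.vessel_placement <- function(x, ...) {
  cat(sprintf("<vessel_placement> %d window(s), %d track(s)\n",
              nrow(x), length(unique(x$track_id))))
  if (nrow(x)) print.data.frame(utils::head(x, 10))
  invisible(x)
}

#' Render vessels into a volume
#'
#' For each vessel track a modulation profile is sampled from the vessel
#' model (constrained), resampled to the window width and normalized so its
#' edge baseline is exactly 1 — the multiplicative application then matches
#' the host region's local brightness by construction. Columns under the
#' vessel are multiplied by a bright factor (> 1, derived from the dip via
#' `1 + gain (1 - p)`) within the inner retinal layers above the vessel, and
#' by the dark profile (< 1) from the vessel's depth down through the outer
#' layers and choroid, producing the characteristic bright-inner/dark-outer
#' shadow pair. Only voxels inside placement windows are modified.
#'
#' @param volume target [oct_volume()].
#' @param surfaces the target's [surface_set()].
#' @param placements a [sample_placements()] result (or data read from CSV).
#' @param vessel_model a [build_vessel_model()] PDM.
#' @param seed optional integer seed for profile sampling.
#' @param gain bright-factor gain applied to the dip depth (default 0.6).
#' @param vessel_surface 1-based surface index at whose depth the vessel
#'   sits; inner layers are those above it (default 4).
#' @return An [oct_volume()] with placements recorded in provenance.
#' @export
render_vessels <- function(volume, surfaces, placements, vessel_model,
                           seed = NULL, gain = 0.6, vessel_surface = 4L) {
  stopifnot(inherits(volume, "oct_volume"), inherits(surfaces, "surface_set"))
  if (!is.null(seed)) set.seed(seed)
  d <- vol_dims(volume)
  a <- volume$a
  if (nrow(placements) == 0L) return(volume)
  tracks <- sort(unique(placements$track_id))
  prof_by_track <- lapply(tracks, function(tr) {
    b <- random_coefficients(vessel_model, n = 1L, constrained = TRUE)
    as.numeric(sample_shape(vessel_model, b[1L, ], constrained = TRUE)$coords)
  })
  names(prof_by_track) <- as.character(tracks)
  K <- surf_dims(surfaces)$K
  vs <- min(max(vessel_surface, 2L), K)
  for (i in seq_len(nrow(placements))) {
    b <- placements$bscan_idx[i] + 1L
    w <- placements$width[i]
    cc <- placements$center_column[i]
    half <- (w - 1) / 2
    cols <- round(cc - half) : round(cc + half)
    if (min(cols) < 0L || max(cols) > d$W - 1L) {
      warning(sprintf("placement window outside image at B-scan %d; skipped",
                      b - 1L), call. = FALSE)
      next
    }
    p <- resample_segment(prof_by_track[[as.character(placements$track_id[i])]],
                          length(cols))
    edge <- (p[1L] + p[length(p)]) / 2
    p <- pmin(p / edge, 1)               # baseline-normalized dark factors
    bright <- 1 + gain * (1 - p)
    for (j in seq_along(cols)) {
      x <- cols[j] + 1L
      z_top <- surfaces$z[x, b, 1L]
      z_v <- surfaces$z[x, b, vs]
      r_in <- which(0:(d$H - 1L) >= z_top & 0:(d$H - 1L) < z_v)
      r_out <- which(0:(d$H - 1L) >= z_v)
      a[r_in, x, b] <- a[r_in, x, b] * bright[j]
      a[r_out, x, b] <- a[r_out, x, b] * p[j]
    }
  }
  oct_volume(pmin(pmax(a, 0), 1), spacing = volume$spacing,
             provenance = c(volume$provenance,
                            list(vessels = placements, vessel_gain = gain,
                                 vessel_surface = vs)))
}
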