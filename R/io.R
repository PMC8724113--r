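#' Write boundary surfaces as long-format CSV
#'
#' One row per (surface, B-scan, column): `volume_id, surface_idx,
#' bscan_idx, column, z`. Indices are 0-based by default; `one_based = TRUE`
#' shifts surface, B-scan and column indices by exactly one on export.
#'
#' @param s a [surface_set()].
#' @param path output CSV path.
#' @param volume_id identifier written in the first column.
#' @param one_based export 1-based indices? Default FALSE.
#' @return `path` invisibly.
#' @export
write_surfaces <- function(s, path, volume_id = "vol1", one_based = FALSE) {
  stopifnot(inherits(s, "surface_set"))
  d <- surf_dims(s)
  off <- if (one_based) 1L else 0L
  grid <- expand.grid(column = 0:(d$W - 1L), bscan_idx = 0:(d$B - 1L),
                      surface_idx = 0:(d$K - 1L))
  df <- data.frame(volume_id = volume_id,
                   surface_idx = grid$surface_idx + off,
                   bscan_idx = grid$bscan_idx + off,
                   column = grid$column + off,
                   z = as.numeric(s$z))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read boundary surfaces from long-format CSV
#'
#' Inverts [write_surfaces()]. The non-crossing invariant is checked on
#' read and violations are rejected with a diagnostic naming the offending
#' surface pair, B-scan and column.
#'
#' @param path CSV path with columns `volume_id, surface_idx, bscan_idx,
#'   column, z`.
#' @param axial_depth H for the reconstructed set; default
#'   `ceiling(max(z)) + 1`.
#' @param one_based were indices exported 1-based? Default FALSE.
#' @param spacing optional spacing to attach.
#' @return A [surface_set()], or a named list of them when the file holds
#'   several volume ids.
#' @export
read_surfaces <- function(path, axial_depth = NULL, one_based = FALSE,
                          spacing = NULL) {
  df <- utils::read.csv(path)
  need <- c("volume_id", "surface_idx", "bscan_idx", "column", "z")
  if (!all(need %in% names(df)))
    stop("surface CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  off <- if (one_based) 1L else 0L
  one <- function(sub) {
    K <- length(unique(sub$surface_idx))
    B <- length(unique(sub$bscan_idx))
    W <- length(unique(sub$column))
    H <- axial_depth %||% (ceiling(max(sub$z)) + 1)
    z <- array(NA_real_, c(W, B, K))
    z[cbind(sub$column - off + 1L, sub$bscan_idx - off + 1L,
            sub$surface_idx - off + 1L)] <- sub$z
    if (any(is.na(z))) stop("incomplete surface grid in file", call. = FALSE)
    surface_set(z, H, spacing = spacing)   # validates, names the column
  }
  ids <- unique(df$volume_id)
  if (length(ids) == 1L) return(one(df))
  stats::setNames(lapply(ids, function(id) one(df[df$volume_id == id, ])),
                  as.character(ids))
}

#' Write an OCT volume to multi-page TIFF or NIfTI
#'
#' TIFF output stores one page per B-scan; NIfTI stores the raw `H x W x B`
#' array with the voxel spacing (micrometres) in the pixdim header. The
#' intensity domain is float [0, 1] internally; TIFF export quantizes to
#' the requested bit depth.
#'
#' @param v an [oct_volume()].
#' @param path output path; format chosen by extension (`.tif`/`.tiff` or
#'   `.nii`/`.nii.gz`).
#' @param bits TIFF bit depth, 8 or 16 (default 16).
#' @return `path` invisibly.
#' @export
write_volume <- function(v, path, bits = 16L) {
  stopifnot(inherits(v, "oct_volume"))
  d <- vol_dims(v)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- lapply(seq_len(d$B), function(b) v$a[, , b])
    tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits))
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::asNifti(v$a)
    if (!is.null(v$spacing)) {
      # header stores mm; convert from um
      RNifti::pixdim(img) <- c(v$spacing[3L], v$spacing[1L],
                               v$spacing[2L]) / 1000
    }
    RNifti::writeNifti(img, path)
  } else stop("unsupported volume format: ", path, call. = FALSE)
  invisible(path)
}

#' Read an OCT volume from multi-page TIFF or NIfTI
#'
#' @param path input path (`.tif`/`.tiff` or `.nii`/`.nii.gz`).
#' @return An [oct_volume()]; NIfTI spacing is restored to micrometres.
#' @export
read_volume <- function(path) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    a <- array(0, c(nrow(pages[[1L]]), ncol(pages[[1L]]), length(pages)))
    for (b in seq_along(pages)) {
      pg <- pages[[b]]
      if (length(dim(pg)) == 3L) pg <- pg[, , 1L]
      a[, , b] <- pg
    }
    oct_volume(pmin(pmax(a, 0), 1))
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::readNifti(path)
    pd <- attr(img, "pixdim") %||% RNifti::pixdim(img)
    a <- array(as.numeric(img), dim(img))
    spacing <- if (!is.null(pd) && all(pd > 0))
      c(pd[2L], pd[3L], pd[1L]) * 1000 else NULL
    oct_volume(pmin(pmax(a, 0), 1), spacing = spacing)
  } else stop("unsupported volume format: ", path, call. = FALSE)
}

#' Persist a point distribution model as JSON
#'
#' A single JSON document holding dim, landmark count, mean, variances,
#' total variance, the mode matrix (column-major) and provenance.
#'
#' @param model a [pdm()].
#' @param path output `.json` path.
#' @param provenance optional list recorded alongside the model.
#' @return `path` invisibly.
#' @export
write_pdm <- function(model, path, provenance = list()) {
  stopifnot(inherits(model, "pdm"))
  obj <- list(dim = model$dim, n_landmarks = model$n_landmarks,
              n_training = model$n_training,
              variance_fraction = model$variance_fraction,
              mean = model$mean, variances = model$variances,
              all_variances = model$all_variances,
              total_variance = model$total_variance,
              modes = as.numeric(model$modes),
              t = ncol(model$modes),
              grid = if (!is.null(model$grid)) unclass(model$grid),
              profile_width = model$profile_width,
              provenance = provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a point distribution model from JSON
#'
#' @param path a file written by [write_pdm()].
#' @return A [pdm()].
#' @export
read_pdm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- structure(list(
    mean = as.numeric(obj$mean),
    modes = matrix(as.numeric(obj$modes), ncol = obj$t),
    variances = as.numeric(obj$variances),
    total_variance = obj$total_variance,
    all_variances = as.numeric(obj$all_variances),
    n_training = obj$n_training,
    dim = obj$dim, n_landmarks = obj$n_landmarks,
    variance_fraction = obj$variance_fraction
  ), class = "pdm")
  if (!is.null(obj$grid))
    model$grid <- do.call(landmark_grid, obj$grid[c(
      "points_per_curve", "column_indices", "n_surfaces", "n_bscans",
      "width", "axial_depth", "fovea_column")])
  if (!is.null(obj$profile_width)) model$profile_width <- obj$profile_width
  model
}

#' Per-B-scan layer label image
#'
#' @param surfaces a [surface_set()].
#' @param bscan 1-based B-scan index.
#' @return Integer `H x W` matrix: 0 outside the retina, k inside layer k.
#' @export
layer_labels <- function(surfaces, bscan) {
  d <- surf_dims(surfaces)
  H <- as.integer(surfaces$axial_depth)
  lab <- matrix(0L, H, d$W)
  for (k in seq_len(d$K - 1L)) {
    m <- layer_mask_bscan(surfaces$z[, bscan, k], surfaces$z[, bscan, k + 1L], H)
    lab[m] <- k
  }
  lab
}

#' Write and read vessel placements as CSV
#'
#' @param placements a [sample_placements()] result.
#' @param path CSV path.
#' @return `path` (write) / a `vessel_placement` data frame (read).
#' @export
write_placements <- function(placements, path) {
  utils::write.csv(as.data.frame(placements), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_placements
#' @export
read_placements <- function(path) {
  df <- utils::read.csv(path)
  structure(df, class = c("vessel_placement", "data.frame"))
}

#' Export a DME scene to a directory
#'
#' Writes `image.png` (8-bit grayscale), `boundaries.csv` (long format:
#' surface_idx, column, z), `fluid_mask.png` and `provenance.json`.
#'
#' @param scene a [dme_scene()].
#' @param dir output directory (created if missing).
#' @return `dir` invisibly.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "dme_scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  png::writePNG(scene$image, file.path(dir, "image.png"))
  png::writePNG(scene$fluid_mask * 1, file.path(dir, "fluid_mask.png"))
  K <- nrow(scene$boundaries); W <- ncol(scene$boundaries)
  df <- data.frame(surface_idx = rep(0:(K - 1L), each = W),
                   column = rep(0:(W - 1L), K),
                   z = as.numeric(t(scene$boundaries)))
  utils::write.csv(df, file.path(dir, "boundaries.csv"), row.names = FALSE)
  prov <- scene$provenance
  prov$b <- as.numeric(prov$b)
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a DME scene from a directory written by [write_scene()]
#'
#' @param dir the scene directory.
#' @return A [dme_scene()] (validated).
#' @export
read_scene <- function(dir) {
  img <- png::readPNG(file.path(dir, "image.png"))
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  mask <- png::readPNG(file.path(dir, "fluid_mask.png"))
  if (length(dim(mask)) == 3L) mask <- mask[, , 1L]
  df <- utils::read.csv(file.path(dir, "boundaries.csv"))
  K <- max(df$surface_idx) + 1L; W <- max(df$column) + 1L
  bnd <- matrix(NA_real_, K, W)
  bnd[cbind(df$surface_idx + 1L, df$column + 1L)] <- df$z
  prov <- if (file.exists(file.path(dir, "provenance.json")))
    jsonlite::read_json(file.path(dir, "provenance.json"),
                        simplifyVector = TRUE) else list()
  dme_scene(img, bnd, mask > 0.5, provenance = prov)
}

#' Export and import a DME reference library
#'
#' Directory layout: one sub-directory per reference (`ref_001`, ...),
#' each holding the [write_scene()] files.
#'
#' @param library a [dme_library()].
#' @param dir target directory.
#' @return `dir` (write) / a [dme_library()] (read).
#' @export
write_dme_library <- function(library, dir) {
  stopifnot(inherits(library, "dme_library"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(library$refs)) {
    r <- library$refs[[i]]
    sc <- dme_scene(r$image, r$boundaries, r$fluid_mask,
                    provenance = list(id = r$id), validate = FALSE)
    write_scene(sc, file.path(dir, sprintf("ref_%03d", i)))
  }
  invisible(dir)
}

#' @rdname write_dme_library
#' @export
read_dme_library <- function(dir) {
  subs <- sort(list.dirs(dir, recursive = FALSE))
  subs <- subs[grepl("ref_\\d+$", subs)]
  if (length(subs) == 0L) stop("no references found in ", dir, call. = FALSE)
  refs <- lapply(subs, function(s) {
    sc <- read_scene(s)
    list(image = sc$image, boundaries = sc$boundaries,
         fluid_mask = sc$fluid_mask, id = basename(s))
  })
  dme_library(refs)
}
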