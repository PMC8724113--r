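#' DME scenes
#'
#' The labeled output triple of the pathology pipeline: one B-scan image,
#' its nine boundary curves, and a binary intraretinal-fluid mask. Fluid
#' voxels must lie between the first and the eighth boundary.
#'
#' @param image `H x W` numeric matrix in [0, 1].
#' @param boundaries `K x W` matrix of non-crossing boundary depths.
#' @param fluid_mask `H x W` logical matrix.
#' @param provenance list (reference id, coefficients, seed, ...).
#' @param validate check the invariants? Default TRUE.
#' @return An object of class `dme_scene`.
#' @export
dme_scene <- function(image, boundaries, fluid_mask, provenance = list(),
                      validate = TRUE) {
  image <- as.matrix(image)
  boundaries <- as.matrix(boundaries)
  fluid_mask <- matrix(as.logical(fluid_mask), nrow(image), ncol(image))
  s <- structure(list(image = image, boundaries = boundaries,
                      fluid_mask = fluid_mask, provenance = provenance),
                 class = "dme_scene")
  if (validate) validate_scene(s)
  s
}

validate_scene <- function(s) {
  H <- nrow(s$image); W <- ncol(s$image)
  K <- nrow(s$boundaries)
  if (ncol(s$boundaries) != W || any(dim(s$fluid_mask) != c(H, W)))
    stop("image, boundaries and mask disagree in size", call. = FALSE)
  if (any(s$image < 0) || any(s$image > 1))
    stop("image values must be within [0, 1]", call. = FALSE)
  if (K > 1L && any(apply(s$boundaries, 2, diff) < 0))
    stop("crossing boundaries in DME scene", call. = FALSE)
  k_hi <- min(8L, K)
  for (x in seq_len(W)) {
    r <- which(s$fluid_mask[, x]) - 1L
    if (length(r) &&
        (any(r < s$boundaries[1L, x]) || any(r >= s$boundaries[k_hi, x])))
      stop(sprintf("fluid outside boundaries 1..%d at column %d", k_hi, x - 1L),
           call. = FALSE)
  }
  invisible(s)
}

#' @export
print.dme_scene <- function(x, ...) {
  cat(sprintf("<dme_scene> %d x %d B-scan, %d boundaries, %d fluid voxels\n",
              nrow(x$image), ncol(x$image), nrow(x$boundaries),
              sum(x$fluid_mask)))
  invisible(x)
}

#' @export
plot.dme_scene <- function(x, ...) {
  H <- nrow(x$image); W <- ncol(x$image)
  graphics::image(t(x$image)[, H:1], col = grDevices::gray.colors(256, 0, 1),
                  axes = FALSE, asp = H / W, ...)
  xs <- (0:(W - 1)) / (W - 1)
  for (k in seq_len(nrow(x$boundaries)))
    graphics::lines(xs, 1 - x$boundaries[k, ] / (H - 1), col = "yellow")
  if (any(x$fluid_mask)) {
    idx <- which(x$fluid_mask, arr.ind = TRUE)
    graphics::points((idx[, 2] - 1) / (W - 1), 1 - (idx[, 1] - 1) / (H - 1),
                     pch = ".", col = "cyan")
  }
  invisible(x)
}

#' DME reference libraries
#'
#' @param refs list of references, each a list with `image` (`H x W`),
#'   `boundaries` (`K x W`) and `fluid_mask` (`H x W` logical); optionally
#'   an `id`.
#' @param validate check completeness and containment? Default TRUE.
#' @return An object of class `dme_library`.
#' @export
dme_library <- function(refs, validate = TRUE) {
  if (length(refs) == 0L) stop("empty reference library", call. = FALSE)
  W <- ncol(refs[[1L]]$image)
  refs <- lapply(seq_along(refs), function(i) {
    r <- refs[[i]]
    if (is.null(r$id)) r$id <- i
    r$fluid_mask <- matrix(as.logical(r$fluid_mask), nrow(r$image),
                           ncol(r$image))
    r
  })
  if (validate) {
    for (r in refs) {
      if (ncol(r$image) != W)
        stop("library members must share width", call. = FALSE)
      if (nrow(r$boundaries) > 1L && any(apply(r$boundaries, 2, diff) < 0))
        stop(sprintf("reference %s has crossing boundaries", r$id),
             call. = FALSE)
    }
  }
  structure(list(refs = refs, width = W, height = nrow(refs[[1L]]$image)),
            class = "dme_library")
}

#' @export
print.dme_library <- function(x, ...) {
  cat(sprintf("<dme_library> %d reference B-scans, %d x %d\n",
              length(x$refs), x$height, x$width))
  invisible(x)
}

#' @export
length.dme_library <- function(x) length(x$refs)

# exclude references lacking a complete boundary set
complete_refs <- function(library, n_boundaries) {
  keep <- vapply(library$refs, function(r) {
    nrow(r$boundaries) == n_boundaries && all(is.finite(r$boundaries))
  }, logical(1))
  if (!all(keep))
    warning(sprintf("%d reference(s) with incomplete boundaries excluded",
                    sum(!keep)), call. = FALSE)
  library$refs <- library$refs[keep]
  library
}

#' Fit the 2-D shape model for DME boundaries
#'
#' Builds a point distribution model over the 9 boundary curves of the
#' reference B-scans, landmarked with the fovea-anchored column scheme and
#' aligned by generalized Procrustes. Because edema pushes boundaries
#' beyond the healthy 3-sigma band, sampling from this model is meant to be
#' done unconstrained (the limit is eliminated). A single-reference library
#' yields a degenerate zero-variance model whose mean is that reference.
#'
#' @param library a [dme_library()].
#' @param points_per_curve landmarks per boundary (default 51).
#' @param variance_fraction cumulative variance threshold (default 0.94).
#' @param n_boundaries boundaries expected per reference (default 9).
#' @param fovea_column anchor column; default the central column.
#' @return A [pdm()] with `dim = 2` and the landmark grid attached.
#' @export
build_dme_model <- function(library, points_per_curve = 51L,
                            variance_fraction = 0.94, n_boundaries = 9L,
                            fovea_column = NULL) {
  stopifnot(inherits(library, "dme_library"))
  library <- complete_refs(library, n_boundaries)
  if (length(library$refs) == 0L)
    stop("no reference with a complete boundary set", call. = FALSE)
  if (is.null(fovea_column)) fovea_column <- floor((library$width - 1) / 2)
  shapes <- lapply(library$refs, function(r)
    extract_landmarks_2d(r$boundaries, nrow(r$image), points_per_curve,
                         fovea_column))
  if (length(shapes) == 1L) {
    # degenerate 1-member library: zero-variance model, mean = the reference
    x <- shapes[[1L]]
    L <- length(x$coords)
    mode1 <- rep(0, L); mode1[1L] <- 1
    model <- structure(list(mean = x$coords,
                            modes = matrix(mode1, ncol = 1L),
                            variances = 0, total_variance = 0,
                            all_variances = 0, n_training = 1L,
                            dim = 2L, n_landmarks = x$n_landmarks,
                            variance_fraction = variance_fraction,
                            grid = x$grid),
                       class = "pdm")
    return(model)
  }
  aligned <- align_shapes(shapes)$aligned
  pdm(aligned, variance_fraction = variance_fraction)
}

#' Select the most similar reference
#'
#' Returns the index of the library member whose first boundary (the inner
#' limiting membrane) is closest to the query's in mean squared difference
#' after removing each curve's mean depth, so axial placement differences
#' do not count. Ties go to the lowest index.
#'
#' @param new_boundaries `K x W` matrix of candidate boundaries.
#' @param library a [dme_library()].
#' @return 1-based reference index.
#' @export
match_reference <- function(new_boundaries, library) {
  stopifnot(inherits(library, "dme_library"))
  q <- new_boundaries[1L, ]
  q <- q - mean(q)
  costs <- vapply(library$refs, function(r) {
    ref1 <- r$boundaries[1L, ]
    if (length(ref1) != length(q))
      ref1 <- resample_segment(ref1, length(q))
    ref1 <- ref1 - mean(ref1)
    mean((q - ref1)^2)
  }, numeric(1))
  which.min(costs)           # which.min already breaks ties towards index 1
}

# per-column axial maps shared by texture and fluid transfer:
# list of segments (lo_t, hi_t, lo_r, hi_r) per column
segment_table <- function(new_b, ref_b, H, Hr) {
  K <- nrow(new_b)
  rbindl <- vector("list", K + 1L)
  rbindl[[1L]] <- list(lo_t = rep(0, ncol(new_b)), hi_t = new_b[1L, ],
                       lo_r = rep(0, ncol(ref_b)), hi_r = ref_b[1L, ])
  for (k in seq_len(K - 1L))
    rbindl[[k + 1L]] <- list(lo_t = new_b[k, ], hi_t = new_b[k + 1L, ],
                             lo_r = ref_b[k, ], hi_r = ref_b[k + 1L, ])
  rbindl[[K + 1L]] <- list(lo_t = new_b[K, ], hi_t = rep(H, ncol(new_b)),
                           lo_r = ref_b[K, ], hi_r = rep(Hr, ncol(ref_b)))
  rbindl
}

#' Column-wise texture transfer
#'
#' Builds the synthetic B-scan's content from the matched reference: per
#' column and per inter-boundary band (including the background above the
#' first boundary and below the last), the reference's intensity profile is
#' axially resampled by linear interpolation to the new band's thickness
#' and written between the new boundaries. When the new geometry equals the
#' reference's the transfer is the identity. Zero-thickness target bands
#' are skipped; zero-thickness reference bands contribute their boundary
#' value.
#'
#' @param new_boundaries `K x W` matrix of target boundaries.
#' @param reference list with `image` and `boundaries` (a library member).
#' @param axial_depth output image height (default: reference height).
#' @return `H x W` numeric matrix in [0, 1].
#' @export
transfer_texture <- function(new_boundaries, reference,
                             axial_depth = nrow(reference$image)) {
  ref_img <- reference$image
  Hr <- nrow(ref_img)
  H <- as.integer(axial_depth)
  W <- ncol(new_boundaries)
  segs <- segment_table(new_boundaries, reference$boundaries, H, Hr)
  out <- matrix(0, H, W)
  rr_ref <- 0:(Hr - 1L)
  for (x in seq_len(W)) {
    colv <- ref_img[, x]
    for (sg in segs) {
      lo_t <- sg$lo_t[x]; hi_t <- sg$hi_t[x]
      lo_r <- sg$lo_r[x]; hi_r <- sg$hi_r[x]
      rt <- seq.int(ceiling(lo_t), ceiling(hi_t) - 1L)
      if (length(rt) == 0L || hi_t <= lo_t) next
      if (hi_r - lo_r < 1e-9) {
        vals <- rep(colv[pmin(pmax(round(lo_r), 0), Hr - 1L) + 1L],
                    length(rt))
      } else {
        rr <- lo_r + (rt - lo_t) / (hi_t - lo_t) * (hi_r - lo_r)
        rr <- pmin(pmax(rr, 0), Hr - 1L)
        vals <- stats::approx(rr_ref, colv, xout = rr)$y
      }
      out[rt + 1L, x] <- vals
    }
  }
  pmin(pmax(out, 0), 1)
}

#' Column-wise fluid-mask transfer
#'
#' Applies the same per-column axial map as [transfer_texture()] to the
#' reference's binary fluid mask, using nearest-neighbour sampling so the
#' mask stays binary. Fluid therefore lands in the same layer of the new
#' geometry as it occupied in the reference.
#'
#' @param new_boundaries `K x W` matrix of target boundaries.
#' @param reference list with `boundaries` and `fluid_mask`.
#' @param axial_depth output mask height (default: reference height).
#' @return `H x W` logical matrix.
#' @export
transfer_fluid <- function(new_boundaries, reference,
                           axial_depth = nrow(reference$fluid_mask)) {
  ref_mask <- reference$fluid_mask
  Hr <- nrow(ref_mask)
  H <- as.integer(axial_depth)
  W <- ncol(new_boundaries)
  segs <- segment_table(new_boundaries, reference$boundaries, H, Hr)
  out <- matrix(FALSE, H, W)
  for (x in seq_len(W)) {
    for (sg in segs) {
      lo_t <- sg$lo_t[x]; hi_t <- sg$hi_t[x]
      lo_r <- sg$lo_r[x]; hi_r <- sg$hi_r[x]
      rt <- seq.int(ceiling(lo_t), ceiling(hi_t) - 1L)
      if (length(rt) == 0L || hi_t <= lo_t) next
      if (hi_r - lo_r < 1e-9) next
      rr <- lo_r + (rt - lo_t) / (hi_t - lo_t) * (hi_r - lo_r)
      rrn <- pmin(pmax(round(rr), 0), Hr - 1L)
      out[rt + 1L, x] <- ref_mask[rrn + 1L, x]
    }
  }
  out
}

#' Synthesize a labeled DME B-scan
#'
#' Composes the full pathology pipeline: draw unconstrained mode
#' coefficients, generate boundary landmarks, reconstruct dense boundary
#' curves, pick the most similar reference by first-boundary shape,
#' transfer its texture and fluid mask column-wise into the new geometry,
#' and add speckle noise to the image (the mask is untouched).
#'
#' @param model a [build_dme_model()] fit.
#' @param library the [dme_library()] used for content transfer.
#' @param seed optional integer seed driving coefficients and noise.
#' @param noise_sigma speckle standard deviation (default 0.05).
#' @param b optional explicit coefficient vector (skips the random draw).
#' @return A [dme_scene()].
#' @export
synthesize_dme <- function(model, library, seed = NULL, noise_sigma = 0.05,
                           b = NULL) {
  stopifnot(inherits(model, "pdm"), inherits(library, "dme_library"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(b))
    b <- random_coefficients(model, n = 1L, constrained = FALSE)[1L, ]
  shape <- sample_shape(model, b, constrained = FALSE)
  H <- library$height
  grid <- model$grid
  grid$axial_depth <- H
  boundaries <- landmarks_to_boundaries_2d(shape, grid = grid,
                                           target_width = library$width)
  ref_idx <- match_reference(boundaries, library)
  ref <- library$refs[[ref_idx]]
  img <- transfer_texture(boundaries, ref, axial_depth = H)
  mask <- transfer_fluid(boundaries, ref, axial_depth = H)
  if (noise_sigma > 0) {
    vol <- oct_volume(array(img, c(nrow(img), ncol(img), 1L)))
    img <- add_speckle(vol, noise_sigma)$a[, , 1L]
  }
  dme_scene(img, boundaries, mask,
            provenance = list(reference = ref$id, b = b, seed = seed,
                              noise_sigma = noise_sigma))
}
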