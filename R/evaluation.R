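#' Layer thickness maps
#'
#' Differences the depths of two surfaces to an en-face thickness map,
#' values(b, x) = z_k(x, b) - z_j(x, b), in voxels or micrometres when the
#' surface set carries an axial spacing.
#'
#' @param surfaces a [surface_set()].
#' @param pair integer pair `(j, k)` of 1-based surface indices, j < k.
#' @param layer_name label for the map (e.g. "RNFL", "total macula").
#' @param units `"voxel"` (default) or `"um"` (requires spacing).
#' @return An object of class `thickness_map`: list with `values`
#'   (`B x W` matrix), `surface_pair`, `layer_name`, `units`.
#' @export
thickness_map <- function(surfaces, pair, layer_name = NULL,
                          units = c("voxel", "um")) {
  stopifnot(inherits(surfaces, "surface_set"))
  units <- match.arg(units)
  j <- pair[1L]; k <- pair[2L]
  if (j >= k) stop("need surface pair with j < k", call. = FALSE)
  d <- surf_dims(surfaces)
  if (k > d$K) stop("surface index out of range", call. = FALSE)
  vals <- t(surfaces$z[, , k] - surfaces$z[, , j])   # B x W
  if (units == "um") {
    if (is.null(surfaces$spacing))
      stop("no spacing recorded; cannot convert to um", call. = FALSE)
    vals <- vals * surfaces$spacing[3L]
  }
  structure(list(values = vals, surface_pair = c(j, k),
                 layer_name = layer_name %||% sprintf("surfaces %d-%d", j, k),
                 units = units),
            class = "thickness_map")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.thickness_map <- function(x, ...) {
  cat(sprintf("<thickness_map> %s: %d x %d, mean %.2f %s\n",
              x$layer_name, nrow(x$values), ncol(x$values),
              mean(x$values), x$units))
  invisible(x)
}

#' @export
plot.thickness_map <- function(x, ...) {
  graphics::image(t(x$values), col = grDevices::hcl.colors(64, "viridis"),
                  axes = FALSE, main = x$layer_name, ...)
  invisible(x)
}

#' En-face projection images
#'
#' Mean intensity between two surfaces along depth, per (B-scan, column).
#' Vessels appear dark in outer-layer projections and bright in inner-layer
#' ones. Columns where the band contains no voxel are marked NA.
#'
#' @param volume an [oct_volume()].
#' @param surfaces the matching [surface_set()].
#' @param pair integer pair `(j, k)`, j < k.
#' @return `B x W` numeric matrix (possibly with NA).
#' @export
projection_image <- function(volume, surfaces, pair) {
  stopifnot(inherits(volume, "oct_volume"), inherits(surfaces, "surface_set"))
  j <- pair[1L]; k <- pair[2L]
  if (j >= k) stop("need surface pair with j < k", call. = FALSE)
  d <- vol_dims(volume)
  out <- matrix(NA_real_, d$B, d$W)
  for (b in seq_len(d$B)) {
    cs <- rbind(0, apply(volume$a[, , b], 2, cumsum))   # (H+1) x W
    lo <- ceiling(surfaces$z[, b, j])
    hi <- ceiling(surfaces$z[, b, k]) - 1L
    n <- hi - lo + 1L
    ok <- n >= 1L
    sums <- cs[cbind(hi + 2L, seq_len(d$W))] - cs[cbind(lo + 1L, seq_len(d$W))]
    out[b, ok] <- sums[ok] / n[ok]
  }
  if (all(is.na(out)))
    stop("empty projection: the band contains no voxels anywhere",
         call. = FALSE)
  out
}

#' Gray-level co-occurrence texture features
#'
#' Quantizes a region to `n_levels` equal-width bins over its intensity
#' range, counts ordered pixel pairs at the given offset, normalizes the
#' count matrix to probabilities p(i, j), and computes
#' energy = sum p^2, contrast = sum (i-j)^2 p, homogeneity =
#' sum p / (1 + (i-j)^2) and the normalized correlation. Pixels marked NA
#' (outside a region mask) are excluded from the pair count. Correlation is
#' NA when either marginal standard deviation vanishes (e.g. a constant
#' region), not an error.
#'
#' @param region numeric matrix (NA allowed for masked-out pixels).
#' @param n_levels number of gray levels (default 8, >= 2).
#' @param offset integer pair `(dr, dc)` giving the neighbour displacement
#'   (default `c(0, 1)`: the pixel to the right).
#' @return An object of class `glcm_features`: list with `energy`,
#'   `contrast`, `homogeneity`, `correlation`, `n_levels`, `offset`, and
#'   the probability matrix `p`.
#' @export
glcm_features <- function(region, n_levels = 8L, offset = c(0L, 1L)) {
  region <- as.matrix(region)
  n_levels <- as.integer(n_levels)
  if (n_levels < 2L) stop("n_levels must be >= 2", call. = FALSE)
  q <- quantize_levels(region, n_levels)
  dr <- offset[1L]; dc <- offset[2L]
  nr <- nrow(q); nc <- ncol(q)
  r1 <- seq_len(nr - abs(dr)); c1 <- seq_len(nc - abs(dc))
  if (dr < 0) r1 <- r1 + abs(dr)
  if (dc < 0) c1 <- c1 + abs(dc)
  i_vals <- q[r1, c1, drop = FALSE]
  j_vals <- q[r1 + dr, c1 + dc, drop = FALSE]
  keep <- !is.na(i_vals) & !is.na(j_vals)
  if (!any(keep))
    stop("no valid pixel pair at this offset", call. = FALSE)
  counts <- tabulate(i_vals[keep] + n_levels * (j_vals[keep] - 1L),
                     nbins = n_levels^2)
  P <- matrix(counts / sum(counts), n_levels, n_levels)
  iM <- matrix(seq_len(n_levels), n_levels, n_levels)
  jM <- t(iM)
  energy <- sum(P^2)
  contrast <- sum((iM - jM)^2 * P)
  homogeneity <- sum(P / (1 + (iM - jM)^2))
  px <- rowSums(P); py <- colSums(P)
  mx <- sum(seq_len(n_levels) * px); my <- sum(seq_len(n_levels) * py)
  sx <- sqrt(sum((seq_len(n_levels) - mx)^2 * px))
  sy <- sqrt(sum((seq_len(n_levels) - my)^2 * py))
  correlation <- if (sx < 1e-12 || sy < 1e-12) NA_real_
                 else sum((iM - mx) * (jM - my) * P) / (sx * sy)
  structure(list(energy = energy, contrast = contrast,
                 homogeneity = homogeneity, correlation = correlation,
                 n_levels = n_levels, offset = c(dr, dc), p = P),
            class = "glcm_features")
}

quantize_levels <- function(region, n_levels) {
  fin <- is.finite(region)
  if (!any(fin)) stop("region has no finite pixel", call. = FALSE)
  lo <- min(region[fin]); hi <- max(region[fin])
  q <- matrix(NA_integer_, nrow(region), ncol(region))
  if (hi - lo < 1e-300) {
    q[fin] <- 1L
  } else {
    q[fin] <- pmin(floor((region[fin] - lo) / (hi - lo) * n_levels) + 1L,
                   n_levels)
  }
  q
}

#' @export
print.glcm_features <- function(x, ...) {
  cat(sprintf(paste0("<glcm_features> %d levels, offset (%d, %d): ",
                     "energy %.4f, contrast %.4f, homogeneity %.4f, ",
                     "correlation %s\n"),
              x$n_levels, x$offset[1L], x$offset[2L], x$energy, x$contrast,
              x$homogeneity,
              if (is.na(x$correlation)) "NA" else sprintf("%.4f", x$correlation)))
  invisible(x)
}

#' Texture features per retinal layer region
#'
#' Extracts, for each listed layer, the image region between its bounding
#' boundaries (pixels outside the layer masked out) and computes the four
#' GLCM features, returning a tidy table. The default region set is layers
#' 1, 3 and 5 (between boundary pairs 1-2, 3-4 and 5-6).
#'
#' @param x a [dme_scene()], or a plain `H x W` image matrix (then supply
#'   `boundaries`).
#' @param layer_indices 1-based layer indices (layer k lies between
#'   boundaries k and k+1). Default `c(1, 3, 5)`.
#' @param boundaries `K x W` boundary matrix when `x` is a plain image.
#' @param n_levels,offset passed to [glcm_features()].
#' @return data frame with columns `region`, `feature`, `value` (value NA
#'   for empty layers or undefined correlation).
#' @export
region_features <- function(x, layer_indices = c(1L, 3L, 5L),
                            boundaries = NULL, n_levels = 8L,
                            offset = c(0L, 1L)) {
  if (inherits(x, "dme_scene")) {
    image <- x$image; boundaries <- x$boundaries
  } else {
    image <- as.matrix(x)
    if (is.null(boundaries)) stop("supply `boundaries`", call. = FALSE)
  }
  H <- nrow(image)
  feats <- c("energy", "contrast", "homogeneity", "correlation")
  rows <- lapply(layer_indices, function(k) {
    masked <- image
    r <- 0:(H - 1L)
    for (xcol in seq_len(ncol(image))) {
      inside <- r >= boundaries[k, xcol] & r < boundaries[k + 1L, xcol]
      masked[!inside, xcol] <- NA_real_
    }
    vals <- if (!any(!is.na(masked))) rep(NA_real_, 4L) else {
      g <- tryCatch(glcm_features(masked, n_levels, offset),
                    error = function(e) NULL)
      if (is.null(g)) rep(NA_real_, 4L)
      else c(g$energy, g$contrast, g$homogeneity, g$correlation)
    }
    data.frame(region = sprintf("layer %d", k), feature = feats,
               value = vals)
  })
  do.call(rbind, rows)
}

#' Two-sample Kolmogorov-Smirnov comparison with Q-Q points
#'
#' Computes D as the maximum gap between the two empirical CDFs evaluated
#' at all pooled sample points, the asymptotic two-sample Kolmogorov
#' p-value, and matched empirical quantiles for Q-Q plotting.
#'
#' @param a,b numeric samples, each with at least 2 finite values.
#' @return An object of class `ks_result`: list with `statistic`,
#'   `p_value`, `n` (the two sample sizes) and `qq_points` (data frame with
#'   columns `qa`, `qb`).
#' @export
ks_two_sample <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L || !all(is.finite(c(a, b))))
    stop("each sample needs at least 2 finite values", call. = FALSE)
  w <- sort(unique(c(a, b)))
  D <- max(abs(stats::ecdf(a)(w) - stats::ecdf(b)(w)))
  n <- length(a); m <- length(b)
  lambda <- sqrt(n * m / (n + m)) * D
  p <- 1 - pkolmogorov(lambda)
  qq <- stats::qqplot(a, b, plot.it = FALSE)
  structure(list(statistic = D, p_value = min(max(p, 0), 1), n = c(n, m),
                 qq_points = data.frame(qa = qq$x, qb = qq$y)),
            class = "ks_result")
}

# Kolmogorov distribution CDF. For large x the alternating series
# 1 - 2 sum (-1)^(k-1) exp(-2 k^2 x^2); for small x its theta-dual form,
# which converges where the alternating series does not.
pkolmogorov <- function(x, kmax = 100L) {
  if (x <= 0) return(0)
  k <- seq_len(kmax)
  v <- if (x >= 1) 1 - 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * x^2))
       else sqrt(2 * pi) / x * sum(exp(-(2 * k - 1)^2 * pi^2 / (8 * x^2)))
  max(0, min(1, v))
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("<ks_result> D = %.4f, p = %.4g (n = %d vs %d)\n",
              x$statistic, x$p_value, x$n[1L], x$n[2L]))
  invisible(x)
}

#' @export
plot.ks_result <- function(x, ...) {
  plot(x$qq_points$qa, x$qq_points$qb, xlab = "sample A quantiles",
       ylab = "sample B quantiles",
       main = sprintf("Q-Q (K-S p = %.3g)", x$p_value), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

default_layer_pairs <- function() {
  list("total macula" = c(1L, 9L), RNFL = c(1L, 2L), GCIPL = c(2L, 3L),
       RPE = c(8L, 9L))
}

# Welch two-sample p with graceful degenerate handling
welch_p <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) return(NA_real_)
  if (stats::sd(a) < 1e-12 && stats::sd(b) < 1e-12)
    return(if (abs(mean(a) - mean(b)) < 1e-12) 1 else 0)
  stats::t.test(a, b)$p.value
}

#' Compare a real and a synthetic group
#'
#' Reproduces the validation protocol for a generator: per configured layer
#' it computes each volume's mean thickness, the group mean and SD, and a
#' two-sample p-value (Welch t-test by default, Wilcoxon optionally); when
#' per-image feature tables are supplied it additionally runs the
#' Kolmogorov-Smirnov/Q-Q comparison per region and feature across images.
#'
#' @param real_group,synth_group lists of [surface_set()]s.
#' @param layer_pairs named list mapping layer names to surface index
#'   pairs; default total macula 1-9, RNFL 1-2, GCIPL 2-3, RPE 8-9.
#' @param units thickness units (`"voxel"` or `"um"`).
#' @param test `"welch"` (default) or `"wilcoxon"`.
#' @param real_scenes,synth_scenes optional lists of [dme_scene()]s (or
#'   plain images with boundaries) for the texture-feature comparison.
#' @param feature_args list of arguments passed to [region_features()].
#' @return An object of class `eval_report` with elements `thickness`
#'   (data frame), and optionally `features` (data frame of K-S results)
#'   and `qq` (named list of Q-Q point sets).
#' @export
compare_groups <- function(real_group, synth_group,
                           layer_pairs = default_layer_pairs(),
                           units = c("voxel", "um"),
                           test = c("welch", "wilcoxon"),
                           real_scenes = NULL, synth_scenes = NULL,
                           feature_args = list()) {
  units <- match.arg(units)
  test <- match.arg(test)
  if (length(real_group) == 0L || length(synth_group) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  mean_thick <- function(group, pair) vapply(group, function(s)
    mean(thickness_map(s, pair, units = units)$values), numeric(1))
  thick <- do.call(rbind, lapply(names(layer_pairs), function(nm) {
    pair <- layer_pairs[[nm]]
    a <- mean_thick(real_group, pair)
    b <- mean_thick(synth_group, pair)
    p <- if (length(a) < 2L || length(b) < 2L) NA_real_
         else if (test == "welch") welch_p(a, b)
         else stats::wilcox.test(a, b, exact = FALSE)$p.value
    data.frame(layer = nm,
               real_mean = mean(a), real_sd = stats::sd(a),
               synth_mean = mean(b), synth_sd = stats::sd(b),
               p_value = p)
  }))
  out <- list(thickness = thick, units = units, test = test,
              n = c(real = length(real_group), synth = length(synth_group)))
  if (!is.null(real_scenes) && !is.null(synth_scenes)) {
    tab_r <- do.call(rbind, lapply(real_scenes, function(s)
      do.call(region_features, c(list(s), feature_args))))
    tab_s <- do.call(rbind, lapply(synth_scenes, function(s)
      do.call(region_features, c(list(s), feature_args))))
    keys <- unique(tab_r[, c("region", "feature")])
    qq <- list()
    feat <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
      reg <- keys$region[i]; fe <- keys$feature[i]
      va <- tab_r$value[tab_r$region == reg & tab_r$feature == fe]
      vb <- tab_s$value[tab_s$region == reg & tab_s$feature == fe]
      va <- va[is.finite(va)]; vb <- vb[is.finite(vb)]
      if (length(va) < 2L || length(vb) < 2L)
        return(data.frame(region = reg, feature = fe, D = NA_real_,
                          p_value = NA_real_))
      ks <- ks_two_sample(va, vb)
      qq[[paste(reg, fe, sep = ":")]] <<- ks$qq_points
      data.frame(region = reg, feature = fe, D = ks$statistic,
                 p_value = ks$p_value)
    }))
    out$features <- feat
    out$qq <- qq
  }
  structure(out, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Group comparison (%d real vs %d synthetic volumes, %s test)\n",
              x$n["real"], x$n["synth"], x$test))
  tab <- x$thickness
  fmt <- function(m, s) sprintf("%.2f ± %.2f", m, s)
  disp <- data.frame(layer = tab$layer,
                     real = fmt(tab$real_mean, tab$real_sd),
                     synthetic = fmt(tab$synth_mean, tab$synth_sd),
                     p = signif(tab$p_value, 4))
  names(disp)[2:3] <- c(sprintf("real (mean ± SD, %s)", x$units),
                        "synthetic (mean ± SD)")
  print(disp, row.names = FALSE)
  if (!is.null(x$features)) {
    cat("\nTexture-feature K-S comparison:\n")
    print(x$features, row.names = FALSE, digits = 4)
  }
  invisible(x)
}
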