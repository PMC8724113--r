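# shared reduced-geometry phantom fixtures, built once per test run

small_cfg <- function(n_volumes = 6L, seed = 3L, n_bscans = 5L, ...) {
  phantom_config(n_volumes = n_volumes, width = 96L, n_bscans = n_bscans,
                 axial_depth = 160L, seed = seed, ...)
}

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

small_surfaces <- function() fixture("small_surfaces", function()
  generate_surfaces(small_cfg()))

small_shapes <- function() fixture("small_shapes", function()
  lapply(small_surfaces(), extract_landmarks, points_per_curve = 21L))

small_model <- function() fixture("small_model", function()
  pdm(align_shapes(small_shapes())$aligned, variance_fraction = 0.94))

small_full_model <- function() fixture("small_full_model", function()
  pdm(align_shapes(small_shapes())$aligned, variance_fraction = 1))

small_dme_library <- function() fixture("small_dme_library", function()
  generate_dme_library(small_cfg(n_volumes = 6L, n_bscans = 1L, seed = 4L)))

small_dme_model <- function() fixture("small_dme_model", function()
  build_dme_model(small_dme_library(), points_per_curve = 21L))

# 4-connected component count of a logical matrix (iterative flood fill)
count_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nextlab <- 0L
  for (start in which(mask & lab == 0L)) {
    nextlab <- nextlab + 1L
    stack <- start
    while (length(stack)) {
      i <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (!mask[i] || lab[i] != 0L) next
      lab[i] <- nextlab
      r <- (i - 1L) %% nrow(mask) + 1L
      cc <- (i - 1L) %/% nrow(mask) + 1L
      if (r > 1L) stack <- c(stack, i - 1L)
      if (r < nrow(mask)) stack <- c(stack, i + 1L)
      if (cc > 1L) stack <- c(stack, i - nrow(mask))
      if (cc < ncol(mask)) stack <- c(stack, i + nrow(mask))
    }
  }
  nextlab
}

# brute-force GLCM oracle: double loop over all pixel pairs at the offset
glcm_oracle <- function(region, n_levels, offset) {
  lo <- min(region, na.rm = TRUE); hi <- max(region, na.rm = TRUE)
  q <- matrix(NA_integer_, nrow(region), ncol(region))
  fin <- is.finite(region)
  q[fin] <- if (hi - lo < 1e-300) 1L else
    pmin(floor((region[fin] - lo) / (hi - lo) * n_levels) + 1L, n_levels)
  P <- matrix(0, n_levels, n_levels)
  for (r in seq_len(nrow(q))) for (cc in seq_len(ncol(q))) {
    r2 <- r + offset[1L]; c2 <- cc + offset[2L]
    if (r2 < 1L || r2 > nrow(q) || c2 < 1L || c2 > ncol(q)) next
    if (is.na(q[r, cc]) || is.na(q[r2, c2])) next
    P[q[r, cc], q[r2, c2]] <- P[q[r, cc], q[r2, c2]] + 1
  }
  P <- P / sum(P)
  en <- 0; co <- 0; ho <- 0
  for (i in seq_len(n_levels)) for (j in seq_len(n_levels)) {
    en <- en + P[i, j]^2
    co <- co + (i - j)^2 * P[i, j]
    ho <- ho + P[i, j] / (1 + (i - j)^2)
  }
  px <- rowSums(P); py <- colSums(P)
  mx <- sum(seq_len(n_levels) * px); my <- sum(seq_len(n_levels) * py)
  sx <- sqrt(sum((seq_len(n_levels) - mx)^2 * px))
  sy <- sqrt(sum((seq_len(n_levels) - my)^2 * py))
  corr <- if (sx < 1e-12 || sy < 1e-12) NA_real_ else {
    s <- 0
    for (i in seq_len(n_levels)) for (j in seq_len(n_levels))
      s <- s + (i - mx) * (j - my) * P[i, j]
    s / (sx * sy)
  }
  list(energy = en, contrast = co, homogeneity = ho, correlation = corr)
}

# exhaustive ECDF-gap oracle for the two-sample K-S statistic
ks_oracle_D <- function(a, b) {
  pts <- sort(c(a, b))
  max(vapply(pts, function(t) abs(mean(a <= t) - mean(b <= t)), numeric(1)))
}

make_shape <- function(M) shape_vector(as.numeric(t(M)), dim = ncol(M))

random_rotation <- function(d, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Q <- qr.Q(qr(matrix(rnorm(d * d), d, d)))
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}
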