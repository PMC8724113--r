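test_that("generalized Procrustes removes translation, rotation and scale", {
  set.seed(42)
  M <- matrix(rnorm(60), 20, 3)
  A <- make_shape(M)

  # identical shapes come back unchanged with identity transforms
  al <- align_shapes(list(A, A, A))
  for (i in 1:3) {
    expect_lt(max(abs(al$aligned[[i]]$coords - A$coords)), 1e-10)
    expect_lt(max(abs(al$transforms[[i]]$rotation - diag(3))), 1e-10)
    expect_lt(abs(al$transforms[[i]]$scale - 1), 1e-10)
    expect_lt(max(abs(al$transforms[[i]]$translation)), 1e-10)
  }

  # pure translation is removed
  B <- make_shape(sweep(M, 2, c(5, 3, -2), "+"))
  r <- align_shapes(list(A, B))
  expect_lt(sqrt(sum((r$aligned[[1]]$coords - r$aligned[[2]]$coords)^2)), 1e-6)

  # a known rotation + scale 1.7 + translation is recovered
  Q <- random_rotation(3, seed = 7)
  C <- make_shape(sweep(1.7 * M %*% Q, 2, c(2, -1, 3), "+"))
  r2 <- align_shapes(list(A, C))
  expect_lt(sqrt(sum((r2$aligned[[1]]$coords - r2$aligned[[2]]$coords)^2)),
            1e-6)
})

test_that("alignment rejects bad inputs and is idempotent", {
  set.seed(1)
  A <- make_shape(matrix(rnorm(30), 10, 3))
  B <- make_shape(matrix(rnorm(36), 12, 3))
  expect_error(align_shapes(list(A, B)), "landmark count")
  expect_error(align_shapes(list(A)), "at least 2")
  degenerate <- make_shape(matrix(1, 10, 3))
  expect_error(align_shapes(list(A, degenerate)), "degenerate")

  al <- align_shapes(small_shapes())
  al2 <- align_shapes(al$aligned)
  worst <- max(mapply(function(a, b) max(abs(a$coords - b$coords)),
                      al$aligned, al2$aligned))
  expect_lt(worst, 1e-8)
})

test_that("pdm matches a hand eigendecomposition of the 1/N covariance", {
  # two shapes differing by +/-1 in one coordinate: S is rank one with
  # eigenvalue (1^2 + 1^2)/2 = 1 under the 1/N normalization
  base <- c(0, 0, 5, 1, 2, 3)
  s1 <- shape_vector(base + c(1, 0, 0, 0, 0, 0), dim = 3)
  s2 <- shape_vector(base - c(1, 0, 0, 0, 0, 0), dim = 3)
  m <- pdm(list(s1, s2), variance_fraction = 0.94)
  expect_equal(m$variances, 1, tolerance = 1e-12)
  expect_equal(m$total_variance, 1, tolerance = 1e-12)
  expect_equal(abs(m$modes[, 1]), c(1, 0, 0, 0, 0, 0), tolerance = 1e-12)
  expect_equal(m$mean, base, tolerance = 1e-12)

  # identical training shapes: zero variance, one mode by convention
  m0 <- pdm(list(s1, s1, s1))
  expect_equal(m0$variances, 0)
  expect_equal(ncol(m0$modes), 1L)
  expect_equal(m0$mean, s1$coords)

  expect_error(pdm(list(s1)), "insufficient")
})

test_that("pdm eigenpairs agree with brute-force covariance eigendecomposition", {
  set.seed(11)
  for (rep in 1:3) {
    N <- 6; n_lm <- 8
    shapes <- lapply(seq_len(N), function(i)
      shape_vector(rnorm(2 * n_lm, sd = 2), dim = 2))
    m <- pdm(shapes, variance_fraction = 1)
    X <- do.call(rbind, lapply(shapes, function(s) s$coords))
    xbar <- colMeans(X)
    S <- matrix(0, ncol(X), ncol(X))
    for (i in seq_len(N)) S <- S + tcrossprod(xbar - X[i, ])
    S <- S / N
    eig <- eigen(S, symmetric = TRUE)
    nz <- seq_len(ncol(m$modes))
    expect_equal(m$variances, eig$values[nz], tolerance = 1e-10)
    expect_equal(m$total_variance, sum(diag(S)), tolerance = 1e-10)
    for (j in nz)
      expect_equal(abs(sum(m$modes[, j] * eig$vectors[, j])), 1,
                   tolerance = 1e-8)
    # modes are orthonormal, variances descending
    expect_lt(max(abs(crossprod(m$modes) - diag(ncol(m$modes)))), 1e-8)
    expect_true(all(diff(m$variances) <= 1e-12))
  }
})

test_that("mode count is the smallest cumulative-share threshold crossing", {
  for (seed in c(3L, 8L, 21L)) {
    shapes <- lapply(generate_surfaces(small_cfg(seed = seed)),
                     extract_landmarks, points_per_curve = 21L)
    m <- pdm(align_shapes(shapes)$aligned, variance_fraction = 0.94)
    shares <- cumsum(m$all_variances) / m$total_variance
    t_ <- length(m$variances)
    expect_gte(shares[t_], 0.94)
    if (t_ > 1L) expect_lt(shares[t_ - 1L], 0.94)
  }
})

test_that("sample_shape follows X = mean + P b with the 3-sigma clip", {
  m <- small_model()
  t_ <- length(m$variances)

  expect_equal(sample_shape(m, rep(0, t_))$coords, m$mean)
  expect_error(sample_shape(m, rep(0, t_ + 1L)), "length")

  # constrained: a 5*sqrt(sigma) request is clipped to 3*sqrt(sigma)
  b <- rep(0, t_); b[1] <- 5 * sqrt(m$variances[1])
  expect_warning(clipped <- sample_shape(m, b, constrained = TRUE), "clipped")
  expected <- m$mean + 3 * sqrt(m$variances[1]) * m$modes[, 1]
  expect_equal(clipped$coords, expected, tolerance = 1e-12)

  # unconstrained: passed through unchanged
  free <- sample_shape(m, b, constrained = FALSE)
  expect_equal(free$coords, m$mean + 5 * sqrt(m$variances[1]) * m$modes[, 1],
               tolerance = 1e-12)

  # clipping never increases |b_i|
  set.seed(5)
  for (i in 1:20) {
    braw <- rnorm(t_, 0, 3 * sqrt(m$variances))
    got <- suppressWarnings(sample_shape(m, braw, constrained = TRUE))
    bback <- project_shape(m, got)
    expect_true(all(abs(bback) <= abs(braw) + 1e-8))
  }
})

test_that("random coefficients are Gaussian per mode and respect the band", {
  m <- small_model()
  sdv <- sqrt(m$variances)

  b1 <- random_coefficients(m, n = 50, seed = 123)
  b2 <- random_coefficients(m, n = 50, seed = 123)
  expect_identical(b1, b2)

  Bc <- random_coefficients(m, n = 10000, constrained = TRUE, seed = 9)
  ratios <- sweep(abs(Bc), 2, sdv, "/")
  expect_lte(max(ratios), 3)

  Bu <- random_coefficients(m, n = 10000, constrained = FALSE, seed = 10)
  v <- apply(Bu, 2, var)
  expect_true(all(abs(v / m$variances - 1) < 0.10))
})

test_that("projection inverts sampling and yields orthogonal residuals", {
  m <- small_full_model()
  t_ <- length(m$variances)
  expect_equal(project_shape(m, shape_vector(m$mean, dim = m$dim)),
               rep(0, t_), tolerance = 1e-10)

  set.seed(77)
  bstar <- rnorm(t_, 0, sqrt(m$variances))
  x <- sample_shape(m, bstar, constrained = FALSE)
  expect_lt(max(abs(project_shape(m, x) - bstar)), 1e-8)

  # off-subspace perturbation: reconstruction is the orthogonal projection
  pert <- rnorm(length(m$mean))
  x2 <- shape_vector(m$mean + pert, dim = m$dim)
  res <- residuals(m, x2)
  expect_lt(max(abs(crossprod(m$modes, res))), 1e-8)
  expect_error(project_shape(m, shape_vector(1:6, dim = 3)), "length")
})
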