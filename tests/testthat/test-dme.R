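test_that("the DME shape model is unconstrained and linear in each mode", {
  lib <- small_dme_library()
  m <- small_dme_model()
  t_ <- length(m$variances)

  # b = 0 reproduces the mean boundary set
  expect_equal(sample_shape(m, rep(0, t_))$coords, m$mean)

  # |b1| = 4 sqrt(sigma1) accepted without clipping in unconstrained mode
  b <- rep(0, t_); b[1] <- 4 * sqrt(m$variances[1])
  expect_silent(x <- sample_shape(m, b, constrained = FALSE))
  expect_equal(x$coords, m$mean + b[1] * m$modes[, 1], tolerance = 1e-12)

  # varying one mode at a time moves the shape only along that mode
  for (i in seq_len(min(t_, 3L))) {
    bi <- rep(0, t_); bi[i] <- 2 * sqrt(m$variances[i])
    d <- sample_shape(m, bi, constrained = FALSE)$coords - m$mean
    expect_equal(d, bi[i] * m$modes[, i], tolerance = 1e-10)
  }

  # incomplete references are excluded with a warning
  bad <- lib$refs[[1]]
  bad$boundaries <- bad$boundaries[1:5, ]
  lib_bad <- dme_library(c(lib$refs, list(bad)))
  expect_warning(m2 <- build_dme_model(lib_bad, points_per_curve = 21L),
                 "incomplete")
  expect_equal(m2$n_training, length(lib$refs))
})

test_that("reference matching uses mean-centred first-boundary SSD", {
  lib <- small_dme_library()
  # a member's own boundaries select that member
  for (i in c(1L, 3L))
    expect_equal(match_reference(lib$refs[[i]]$boundaries, lib), i)

  # vertical shift is removed before comparing
  shifted <- lib$refs[[2]]$boundaries + 13.7
  expect_equal(match_reference(shifted, lib), 2L)

  # exact tie resolves to the lowest index
  tie_lib <- dme_library(list(lib$refs[[1]], lib$refs[[1]], lib$refs[[2]]))
  expect_equal(match_reference(lib$refs[[1]]$boundaries, tie_lib), 1L)
})

test_that("texture transfer is an identity at equal geometry and a linear
          stretch at doubled thickness", {
  lib <- small_dme_library()
  r <- lib$refs[[1]]
  expect_equal(transfer_texture(r$boundaries, r), r$image, tolerance = 1e-12)
  expect_equal(transfer_fluid(r$boundaries, r), r$fluid_mask)

  # synthetic reference with a linear ramp inside one band
  H <- 60L; W <- 8L
  img <- matrix(0, H, W)
  bnd <- matrix(0, 2L, W); bnd[1L, ] <- 20; bnd[2L, ] <- 30
  for (x in seq_len(W)) img[21:30, x] <- seq(0.1, 1.0, length.out = 10)
  ref <- list(image = img, boundaries = bnd)
  new_bnd <- matrix(0, 2L, W); new_bnd[1L, ] <- 10; new_bnd[2L, ] <- 30
  out <- transfer_texture(new_bnd, ref, axial_depth = H)
  # target rows 10..29 map linearly onto reference rows 20..29.95
  rt <- 10:29
  rr <- 20 + (rt - 10) / 20 * 10
  expected <- approx(0:(H - 1), img[, 1], xout = rr)$y
  expect_equal(out[rt + 1, 1], expected, tolerance = 1e-10)
  # band mean is approximately preserved under smooth resampling
  expect_lt(abs(mean(out[rt + 1, 1]) - mean(img[21:30, 1])) /
              mean(img[21:30, 1]), 0.06)

  # fluid transfer keeps the pocket inside the same layer
  r2 <- lib$refs[[which.max(vapply(lib$refs, function(q) sum(q$fluid_mask),
                                   numeric(1)))]]
  squeeze <- r2$boundaries
  mid <- (squeeze[4L, ] + squeeze[8L, ]) / 2
  for (k in 4:7) squeeze[k, ] <- mid + (squeeze[k, ] - mid) * 0.6
  for (k in 2:nrow(squeeze)) squeeze[k, ] <- pmax(squeeze[k, ],
                                                  squeeze[k - 1L, ])
  mask <- transfer_fluid(squeeze, r2)
  H2 <- nrow(r2$image)
  for (x in seq_len(ncol(mask))) {
    rows <- which(mask[, x]) - 1L
    if (length(rows)) {
      expect_true(all(rows >= squeeze[1L, x]))
      expect_true(all(rows < squeeze[8L, x]))
    }
  }
})

test_that("texture transfer is column-local", {
  lib <- small_dme_library()
  r <- lib$refs[[2]]
  pert <- r
  xcol <- 30L
  pert$image[, xcol] <- rev(pert$image[, xcol])
  bnd <- r$boundaries + 1.5
  a <- transfer_texture(bnd, r)
  b <- transfer_texture(bnd, pert)
  expect_true(all(a[, -xcol] == b[, -xcol]))
  expect_false(all(a[, xcol] == b[, xcol]))
})

test_that("synthesize_dme composes the pipeline reproducibly", {
  lib <- small_dme_library()
  m <- small_dme_model()
  s1 <- synthesize_dme(m, lib, seed = 5)
  s2 <- synthesize_dme(m, lib, seed = 5)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$fluid_mask, s2$fluid_mask)
  expect_identical(s1$boundaries, s2$boundaries)

  # every scene keeps fluid strictly inside boundaries 1..8
  for (seed in 1:5) {
    sc <- synthesize_dme(m, lib, seed = seed)
    expect_silent(octsynth:::validate_scene(sc))
  }

  # degenerate 1-member library: b = 0 reproduces the reference closely
  one <- dme_library(list(lib$refs[[1]]))
  m1 <- build_dme_model(one, points_per_curve = 21L)
  sc1 <- synthesize_dme(m1, one, seed = 1, noise_sigma = 0,
                        b = rep(0, length(m1$variances)))
  expect_lt(max(abs(sc1$boundaries - lib$refs[[1]]$boundaries)), 1)
  expect_lt(mean(abs(sc1$image - lib$refs[[1]]$image)), 0.05)

  # small b keeps the fluid topology of the matched reference
  msmall <- small_dme_model()
  b0 <- rep(0, length(msmall$variances))
  sc0 <- synthesize_dme(msmall, lib, seed = 2, noise_sigma = 0, b = b0)
  ref_mask <- lib$refs[[sc0$provenance$reference]]$fluid_mask
  expect_equal(count_components(sc0$fluid_mask), count_components(ref_mask))
})
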