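flat_surfaces <- function(depths, W = 24L, B = 2L, H = 200L) {
  z <- array(0, c(W, B, length(depths)))
  for (k in seq_along(depths)) z[, , k] <- depths[k]
  surface_set(z, H)
}

test_that("layer rendering fills half-open bands with the layer brightness", {
  s <- flat_surfaces(c(100, 110))
  app <- layer_appearance(0.7)
  v <- render_layers(s, app)
  expect_true(all(v$a[101:110, , ] == 0.7))   # rows 100..109 (0-based)
  expect_true(all(v$a[1:100, , ] == 0))
  expect_true(all(v$a[111:200, , ] == 0))

  # boundary voxel belongs to the layer below it
  s3 <- flat_surfaces(c(100, 110, 120))
  v3 <- render_layers(s3, layer_appearance(c(0.3, 0.9)))
  expect_equal(v3$a[111, 1, 1], 0.9)          # row 110 is in layer 2
  expect_equal(v3$a[110, 1, 1], 0.3)          # row 109 still in layer 1

  # per-layer mean of a phantom render equals mu exactly
  s4 <- small_surfaces()[[2]]
  mu <- small_cfg()$layer_brightness
  v4 <- render_layers(s4, layer_appearance(mu))
  d <- dim(s4$z)
  for (k in seq_len(d[3] - 1L)) {
    vals <- c()
    for (b in seq_len(d[2])) {
      r <- 0:(dim(v4$a)[1] - 1L)
      m <- outer(r, s4$z[, b, k], ">=") & outer(r, s4$z[, b, k + 1L], "<")
      vals <- c(vals, v4$a[, , b][m])
    }
    expect_equal(mean(vals), mu[k], tolerance = 1e-12)
  }

  crossing <- s
  crossing$z[5, 1, 1] <- 150
  expect_error(render_layers(crossing, app), "crossing")
})

test_that("appearance estimation averages voxels between the surfaces", {
  s <- flat_surfaces(c(100, 110))
  mk_vol <- function(val) {
    a <- array(0, c(200, 24, 2)); a[101:110, , ] <- val
    oct_volume(a)
  }
  # single volume, constant layer
  app1 <- estimate_appearance(list(mk_vol(0.6)), list(s), fraction = 1)
  expect_equal(app1$mu, 0.6, tolerance = 1e-12)
  # two volumes 0.4 / 0.8 with equal B-scan counts: pooled mean 0.6
  app2 <- estimate_appearance(list(mk_vol(0.4), mk_vol(0.8)), list(s, s),
                              fraction = 1)
  expect_equal(app2$mu, 0.6, tolerance = 1e-12)
  # fixed seed selects the same B-scans
  a <- estimate_appearance(list(mk_vol(0.4), mk_vol(0.8)), list(s, s),
                           fraction = 0.5, seed = 42)
  b <- estimate_appearance(list(mk_vol(0.4), mk_vol(0.8)), list(s, s),
                           fraction = 0.5, seed = 42)
  expect_identical(a$mu, b$mu)
  expect_identical(a$source$selected, b$source$selected)
})

test_that("background compositing fills above and below, retina untouched", {
  s <- flat_surfaces(c(100, 110))
  v <- render_layers(s, layer_appearance(0.7))
  ref_a <- array(0.05, c(200, 24, 2))
  ref <- oct_volume(ref_a)
  out <- composite_background(v, s, ref, s)
  expect_true(all(out$a[1:100, , ] == 0.05))
  expect_true(all(out$a[111:200, , ] == 0.05))
  expect_true(all(out$a[101:110, , ] == 0.7))   # retina unchanged

  # target ILM 10 voxels higher than the reference's: segment resampled,
  # and the band above stays exactly filled
  s_hi <- flat_surfaces(c(90, 110))
  v_hi <- render_layers(s_hi, layer_appearance(0.7))
  ref2_a <- array(0, c(200, 24, 2))
  ref2_a[1:100, , ] <- seq(0, 0.2, length.out = 100)  # graded background
  ref2 <- oct_volume(ref2_a)
  out2 <- composite_background(v_hi, s_hi, ref2, s)
  expect_equal(out2$a[1, 1, 1], 0, tolerance = 1e-9)
  expect_equal(out2$a[90, 1, 1], 0.2, tolerance = 1e-9)
  expect_true(all(out2$a[91:110, , ] == 0.7))

  expect_warning(same <- composite_background(v, s, NULL, NULL), "reference")
  expect_identical(same$a, v$a)
})

test_that("speckle is multiplicative with the requested moments", {
  v <- oct_volume(array(0.5, c(496, 512, 1)))
  expect_identical(add_speckle(v, 0)$a, v$a)
  expect_error(add_speckle(v, -0.1), "non-negative")

  n1 <- add_speckle(v, 0.1, seed = 4)
  expect_identical(add_speckle(v, 0.1, seed = 4)$a, n1$a)
  expect_lt(abs(mean(n1$a) - 0.5), 0.005)
  expect_lt(abs(sd(n1$a / v$a) - 0.1), 0.01)

  hard <- add_speckle(v, 1, seed = 5)
  expect_true(all(hard$a >= 0 & hard$a <= 1))

  # empirical noise level is monotone in sigma
  sds <- vapply(c(0, 0.05, 0.1, 0.2, 0.4), function(s)
    sd(add_speckle(v, s, seed = 6)$a), numeric(1))
  expect_true(all(diff(sds) >= 0))
})
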