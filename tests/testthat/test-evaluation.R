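test_that("thickness maps difference surfaces and telescope", {
  W <- 24L; B <- 2L
  z <- array(0, c(W, B, 3L))
  z[, , 1] <- 100; z[, , 2] <- 115; z[, , 3] <- 130
  s <- surface_set(z, 200)
  tm <- thickness_map(s, c(1, 2))
  expect_true(all(tm$values == 15))
  expect_equal(dim(tm$values), c(B, W))
  expect_error(thickness_map(s, c(2, 2)), "j < k")

  # telescoping: total equals the sum of consecutive layer maps
  sp <- small_surfaces()[[1]]
  total <- thickness_map(sp, c(1, 9))$values
  acc <- 0
  for (k in 1:8) acc <- acc + thickness_map(sp, c(k, k + 1))$values
  expect_equal(acc, total, tolerance = 1e-9)

  # micrometre conversion via the axial spacing
  s_um <- surface_set(z, 200, spacing = c(11.6, 244, 3.87))
  expect_true(all(thickness_map(s_um, c(1, 2), units = "um")$values ==
                    15 * 3.87))

  # analytic phantom: the map equals the generating formula
  cfg <- small_cfg(n_volumes = 1L, perturb_amplitude = 0, shift_sd = 0,
                   scale_sd = 0, fovea_jitter = 0, pit_jitter_sd = 0,
                   seed = 6L)
  sa <- generate_surfaces(cfg)[[1]]
  gx <- exp(-((0:(cfg$width - 1) - (cfg$width - 1) / 2)^2) /
              (2 * cfg$pit_width_x^2))
  gb <- exp(-((0:(cfg$n_bscans - 1) - (cfg$n_bscans - 1) / 2)^2) /
              (2 * cfg$pit_width_b^2))
  expected <- (cfg$base_depths[9] - cfg$base_depths[1]) -
    cfg$pit_depth * (cfg$pit_profile[1] - cfg$pit_profile[9]) * outer(gb, gx)
  got <- thickness_map(sa, c(1, 9))$values
  expect_equal(got, expected, tolerance = 1e-9)
})

test_that("projection images average the band and flag empty columns", {
  W <- 10L
  z <- array(0, c(W, 1L, 2L))
  z[, 1, 1] <- 50; z[, 1, 2] <- 52
  s <- surface_set(z, 100)
  a <- array(0.5, c(100, W, 1L))
  expect_true(all(projection_image(oct_volume(a), s, c(1, 2)) == 0.5))
  a2 <- a
  a2[51, , 1] <- 0.2; a2[52, , 1] <- 0.8
  expect_true(all(abs(projection_image(oct_volume(a2), s, c(1, 2)) - 0.5)
                  < 1e-12))
  # degenerate band in one column yields NA there
  z2 <- z; z2[3, 1, 2] <- z2[3, 1, 1]
  s2 <- surface_set(z2, 100)
  p <- projection_image(oct_volume(a), s2, c(1, 2))
  expect_true(is.na(p[1, 3]))
  expect_false(anyNA(p[1, -3]))

  # noise-free vessel-less phantom projection equals the analytic layer mix
  cfg <- small_cfg()
  sp <- small_surfaces()[[3]]
  v <- render_layers(sp, layer_appearance(cfg$layer_brightness))
  pr <- projection_image(v, sp, c(1, 9))
  for (b in c(1L, 3L)) for (x in c(10L, 48L, 90L)) {
    lo <- ceiling(sp$z[x, b, 1]); hi <- ceiling(sp$z[x, b, 9]) - 1
    expect_equal(pr[b, x], mean(v$a[(lo:hi) + 1L, x, b]), tolerance = 1e-12)
  }
})

test_that("GLCM features match the printed formulas on hand-checkable cases", {
  # constant region: single co-occurrence cell
  g0 <- glcm_features(matrix(0.4, 4, 4), n_levels = 8)
  expect_equal(g0$energy, 1)
  expect_equal(g0$contrast, 0)
  expect_equal(g0$homogeneity, 1)
  expect_true(is.na(g0$correlation))

  # 2x2 block with two identical-value pairs
  g1 <- glcm_features(matrix(c(0, 1, 0, 1), 2, 2), n_levels = 2,
                      offset = c(0, 1))
  expect_equal(g1$energy, 0.5)
  expect_equal(g1$contrast, 0)
  expect_equal(g1$homogeneity, 1)
  expect_equal(g1$correlation, 1)

  expect_error(glcm_features(matrix(1, 1, 1), n_levels = 2), "pair")
  expect_error(glcm_features(matrix(1:4, 2, 2), n_levels = 1), "n_levels")
})

test_that("GLCM equals the brute-force double-loop oracle", {
  set.seed(31)
  for (i in 1:25) {
    reg <- matrix(runif(64), 8, 8)
    off <- list(c(0, 1), c(1, 0), c(1, 1), c(0, 2))[[1 + (i %% 4)]]
    nl <- c(4L, 8L)[1 + (i %% 2)]
    got <- glcm_features(reg, n_levels = nl, offset = off)
    want <- glcm_oracle(reg, nl, off)
    expect_equal(got$energy, want$energy, tolerance = 1e-12)
    expect_equal(got$contrast, want$contrast, tolerance = 1e-12)
    expect_equal(got$homogeneity, want$homogeneity, tolerance = 1e-12)
    expect_equal(got$correlation, want$correlation, tolerance = 1e-12)
  }
})

test_that("region features return a tidy 4-feature table per layer", {
  sc <- synthesize_dme(small_dme_model(), small_dme_library(), seed = 3)
  tab <- region_features(sc)
  expect_equal(nrow(tab), 12L)
  expect_setequal(unique(tab$region), c("layer 1", "layer 3", "layer 5"))
  expect_setequal(unique(tab$feature),
                  c("energy", "contrast", "homogeneity", "correlation"))
  tab2 <- region_features(sc$image, boundaries = sc$boundaries)
  expect_equal(tab, tab2)
})

test_that("two-sample K-S matches ECDF enumeration and stats::ks.test", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(ks_two_sample(c(0, 0, 0), c(1, 1, 1))$statistic, 1)
  expect_equal(ks_two_sample(c(1, 2), c(1.5, 2.5))$statistic, 0.5)

  set.seed(17)
  for (i in 1:20) {
    a <- rnorm(sample(3:10, 1))
    b <- rnorm(sample(3:10, 1), mean = runif(1, -1, 1))
    got <- ks_two_sample(a, b)
    expect_equal(got$statistic, ks_oracle_D(a, b), tolerance = 1e-12)
    ref <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
    # R truncates its Kolmogorov series at 1e-6; agree to that scale
    expect_lt(abs(got$p_value - ref$p.value), 1e-5)
  }

  # D is invariant under a strictly monotone transform of both samples
  a <- rexp(15); b <- rexp(12) * 1.4
  d0 <- ks_two_sample(a, b)$statistic
  expect_equal(ks_two_sample(log(a), log(b))$statistic, d0)
  expect_equal(ks_two_sample(a^3, b^3)$statistic, d0)

  expect_error(ks_two_sample(1, c(1, 2)), "at least 2")
})

test_that("identical groups compare as indistinguishable", {
  g <- small_surfaces()[1:3]
  rep <- compare_groups(g, g)
  expect_true(all(rep$thickness$p_value == 1))
  expect_equal(rep$thickness$real_mean, rep$thickness$synth_mean)
  expect_setequal(rep$thickness$layer,
                  c("total macula", "RNFL", "GCIPL", "RPE"))

  scenes <- lapply(1:4, function(i)
    synthesize_dme(small_dme_model(), small_dme_library(), seed = i))
  rep2 <- compare_groups(g, g, real_scenes = scenes, synth_scenes = scenes)
  expect_true(all(rep2$features$D[is.finite(rep2$features$D)] == 0))

  # group of size one: descriptive stats only
  rep3 <- compare_groups(g[1], g[2])
  expect_true(all(is.na(rep3$thickness$p_value)))
})
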