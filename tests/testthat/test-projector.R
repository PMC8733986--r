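# forward projection and photon-counting simulation

test_that("line integrals through a uniform disk match the chord length", {
  gt <- make_phantom(phantom_spec("disk", 64, feature_radius = 16,
                                  wall_attenuation = 0.02))
  st <- forward_project(gt, c(0, 33.7, 90, 121.3))
  expect_s3_class(st, "projection_stack")
  expect_identical(st$domain, "attenuation")
  # ray through the centre: chord 2 r mu (within interpolation tolerance)
  centre <- st$images[32, 32, ]
  expect_true(all(abs(centre - 2 * 16 * 0.02) < 0.02 * 2 * 16 * 0.02))
})

test_that("projection is linear and zero on empty volumes", {
  gt <- make_phantom(phantom_spec("lattice", 32, seed = 2))
  zero <- volume(array(0, dim(gt$data)))
  expect_true(all(forward_project(zero, c(0, 45))$images == 0))
  a <- forward_project(gt, c(10, 70))$images
  gt3 <- volume(3 * gt$data)
  expect_equal(forward_project(gt3, c(10, 70))$images, 3 * a, tolerance = 1e-12)
  expect_error(forward_project(gt, numeric(0)), "nonempty")
})

test_that("a bright off-axis voxel traces a sinusoid across angles", {
  n <- 64
  vol <- array(0, c(n, n, 1))
  yv <- 20; xv <- 45                      # 1-based voxel position
  vol[yv, xv, 1] <- 1
  angles <- seq(0, 179, by = 3)
  st <- forward_project(volume(vol), angles)
  c0 <- (n - 1) / 2
  # expected detector coordinate (0-based): t = dx cos + dy sin + c0
  th <- angles * pi / 180
  expected <- (xv - 1 - c0) * cos(th) + (yv - 1 - c0) * sin(th) + c0
  observed <- apply(st$images[1, , ], 2, which.max) - 1
  expect_lt(max(abs(observed - expected)), 1.5)
  # least-squares sinusoid fit of the trace: amplitude equals the voxel's
  # radial distance from the rotation axis
  fit <- stats::lm(observed ~ cos(th) + sin(th))
  amp <- sqrt(sum(stats::coef(fit)[2:3]^2))
  r <- sqrt((xv - 1 - c0)^2 + (yv - 1 - c0)^2)
  expect_lt(abs(amp - r) / r, 0.03)
})

test_that("rotationally symmetric phantoms give angle-independent projections", {
  # smooth radial profile (a hard-edged voxelised disk is itself only
  # approximately symmetric)
  n <- 64; c0 <- (n - 1) / 2; xy <- seq_len(n) - 1
  sl <- 0.02 * exp(-outer((xy - c0)^2, (xy - c0)^2, "+") / (2 * 100))
  vol <- volume(array(rep(sl, 2), c(n, n, 2)))
  st <- forward_project(vol, seq(0, 174, by = 6))
  sino <- st$images[1, , ]                # detector x angle
  dev <- apply(sino, 1, function(v) diff(range(v)))
  expect_lt(max(dev), 0.01 * max(sino))
})

test_that("noise-free limit recovers Beer-Lambert transmission", {
  gt <- make_phantom(phantom_spec("disk", 32, feature_radius = 8,
                                  wall_attenuation = 0.01))
  st <- forward_project(gt, c(0, 90))
  acq <- acquisition_spec(n_angles = 2, mean_counts = 1e7, edge_level = 1,
                          seed = 4)
  tr <- simulate_counts(st, acq)
  expect_identical(tr$domain, "transmission")
  expect_lt(max(abs(tr$images - exp(-st$images))), 5e-3)
  # exact roundtrip through the log transform
  expect_lt(max(abs(to_sinograms(tr)$images + log(tr$images))), 1e-12)
})

test_that("Poisson noise scales as 1/sqrt(counts) and is seed-deterministic", {
  # same pixel observed over 1000 draws (one per projection)
  flat <- projection_stack(array(0, c(1, 1, 1000)), seq(0, 179.9, length.out = 1000))
  rel_sd <- vapply(c(200, 20000), function(mc) {
    tr <- simulate_counts(flat, acquisition_spec(n_angles = 1000,
                                                 mean_counts = mc, seed = 9))
    stats::sd(tr$images) / mean(tr$images)
  }, 0)
  expect_equal(rel_sd[1] / rel_sd[2], 10, tolerance = 0.1)
  a1 <- simulate_counts(flat, acquisition_spec(1000, mean_counts = 200, seed = 3))
  a2 <- simulate_counts(flat, acquisition_spec(1000, mean_counts = 200, seed = 3))
  expect_identical(a1$images, a2$images)
})

test_that("log-transmission variance quadruples where illumination is 25%", {
  # wide flat detector row: raised-cosine illumination falls to 25% at edges
  ncol <- 101
  flat <- projection_stack(array(0, c(1, ncol, 2000)),
                           seq(0, 179.9, length.out = 2000))
  acq <- acquisition_spec(n_angles = 2000, mean_counts = 2000,
                          edge_level = 0.25, seed = 11)
  lt <- -log(simulate_counts(flat, acq)$images)
  v_centre <- stats::var(lt[1, 51, ])
  v_edge <- stats::var(lt[1, 1, ])
  expect_equal(v_edge / v_centre, 4, tolerance = 0.25)
  # and the absolute level matches 1/counts
  expect_equal(v_centre, 1 / 2000, tolerance = 0.1)
})

test_that("to_sinograms rejects nonpositive transmission with the pixel index", {
  st <- projection_stack(array(c(0.5, 1), c(1, 2, 1)), 0, domain = "transmission")
  st$images[1, 2, 1] <- -1  # corrupt after construction
  expect_error(to_sinograms(st), "index 2")
})
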