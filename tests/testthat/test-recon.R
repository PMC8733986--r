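# sinogram filtering and filtered back-projection

test_that("filter responses: DC removal, identity, unknown names", {
  row <- matrix(2.5, 1, 64)
  expect_equal(max(abs(filter_sinogram(row))), 0)   # constant -> zero
  expect_identical(filter_sinogram(row, recon_config("none")), row)
  expect_error(recon_config("hamming"), "hamming")
  expect_error(filter_sinogram(matrix(1, 2, 3)), "width")
})

test_that("impulse response of the ramp filter matches a direct DFT oracle", {
  n <- 16
  cfg <- recon_config("ramlak", pad_factor = 2)
  row <- matrix(0, 1, n); row[1, 9] <- 1
  got <- filter_sinogram(row, cfg)[1, ]
  # independent oracle: explicit DFT sums on the same edge-padded buffer
  m <- 2 * 2^ceiling(log2(n))
  padded <- c(row[1, ], rep(row[1, n], (m - n + 1) %/% 2),
              rep(row[1, 1], (m - n) %/% 2))
  f <- c(seq(0, m / 2), -seq(m / 2 - 1, 1)) / m
  h <- 2 * abs(f)
  ft <- vapply(seq_len(m) - 1, function(k)
    sum(padded * exp(-2i * pi * k * (seq_len(m) - 1) / m)), 0i)
  expected <- Re(vapply(seq_len(m) - 1, function(j)
    sum(ft * h * exp(2i * pi * (seq_len(m) - 1) * j / m)), 0i) / m)[seq_len(n)]
  expect_equal(got, expected, tolerance = 1e-10)
  # symmetric about the impulse position
  expect_equal(got[9 + 1:6], got[9 - 1:6], tolerance = 1e-10)
  # maximum at the impulse
  expect_equal(which.max(got), 9)
})

test_that("FBP recovers a uniform disk quantitatively", {
  gt <- make_phantom(phantom_spec("disk", 128, feature_radius = 32,
                                  wall_attenuation = 0.02))
  angles <- seq(0, 180, length.out = 361)[1:360]
  sino <- t(forward_project(volume(gt$data[, , 64, drop = FALSE]),
                            angles)$images[1, , ])
  rec <- fbp_slice(sino, angles)
  n <- 128; c0 <- (n - 1) / 2; xy <- seq_len(n) - 1
  r2 <- outer((xy - c0)^2, (xy - c0)^2, "+")
  expect_lt(abs(mean(rec[r2 < 24^2]) - 0.02), 0.05 * 0.02)
  expect_lt(mean(abs(rec[r2 > 40^2 & r2 < 56^2])), 0.05 * 0.02)
})

test_that("FBP is linear and zero-preserving", {
  angles <- seq(0, 179, by = 1)
  sino <- matrix(rnorm(180 * 32), 180, 32)
  expect_true(all(fbp_slice(matrix(0, 180, 32), angles) == 0))
  r1 <- fbp_slice(sino, angles)
  r2 <- fbp_slice(2 * sino, angles)
  expect_equal(r2, 2 * r1, tolerance = 1e-12)
  expect_error(fbp_slice(sino, angles[-1]), "angles")
})

test_that("FBP is covariant under 90-degree rotation of the scan", {
  n <- 32; xy <- seq_len(n)
  img <- outer(exp(-(xy - 10)^2 / 18), exp(-(xy - 22)^2 / 30)) +
    0.5 * outer(exp(-(xy - 24)^2 / 8), exp(-(xy - 12)^2 / 14))
  c0 <- (n - 1) / 2
  img[outer((xy - 1 - c0)^2, (xy - 1 - c0)^2, "+") > (0.45 * n)^2] <- 0
  angles <- seq(0, 179, by = 2)
  th <- angles * pi / 180
  r0 <- fbp_slice(txmdenoise:::cpp_project_slice(img, th), angles)
  r90 <- fbp_slice(txmdenoise:::cpp_project_slice(img, th + pi / 2), angles)
  # shifting every scan angle by +90 deg rotates the reconstruction by
  # 90 deg counter-clockwise
  ccw <- t(r0)[rev(seq_len(n)), ]
  expect_lt(max(abs(r90 - ccw)) / diff(range(r0)), 0.01)
})

test_that("volume reconstruction: shape contract and lattice fidelity", {
  gt <- make_phantom(phantom_spec("lattice", 32, seed = 2))
  st <- forward_project(gt, seq(0, 179.9, length.out = 128))
  one <- projection_stack(st$images[16, , , drop = FALSE], st$angles)
  vol1 <- reconstruct_volume(one)
  expect_equal(dim(vol1$data), c(32L, 32L, 1L))
  expect_match(vol1$provenance, "shepp-logan")
})

test_that("noise-free splits reconstruct to nearly identical volumes", {
  gt <- make_phantom(phantom_spec("lattice", 32, seed = 4))
  st <- forward_project(gt, seq(0, 179.9, length.out = 256))
  pair <- split_projections(st)
  ra <- reconstruct_volume(pair$even)
  rb <- reconstruct_volume(pair$odd)
  expect_lt(max(abs(ra$data - rb$data)) / diff(range(ra$data)), 0.01)
})
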