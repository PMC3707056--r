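test_that("MRC round trip preserves values, voxel size and origin", {
  n <- 16
  vals <- array(sample(-500:500, n^3, replace = TRUE) * 1, c(n, n, n))
  m <- density_map(vals, voxel_size = 4.4, origin = c(1, -2, 3))
  f <- withr::local_tempfile(fileext = ".mrc")
  write_map(m, f)
  m2 <- read_map(f)
  expect_identical(m2$data, m$data)       # float32-exact integer payload
  expect_equal(m2$voxel_size, 4.4, tolerance = 1e-6)
  expect_equal(m2$origin, c(1, -2, 3), tolerance = 1e-5)
})

test_that("an independent MRC reader agrees on the written header and data", {
  n <- 8
  vals <- array(as.numeric(1:n^3), c(n, n, n))
  f <- withr::local_tempfile(fileext = ".mrc")
  write_map(density_map(vals, voxel_size = 4.4), f)
  out <- system2("python", c("-c", shQuote(paste0(
    "import gemmi; m = gemmi.read_ccp4_map('", f, "'); ",
    "import numpy as np; a = np.array(m.grid, copy=False); ",
    "print(a.shape[0], round(m.grid.spacing[0], 5), round(float(a.sum()), 3))"
  ))), stdout = TRUE)
  parts <- strsplit(out[length(out)], " ")[[1]]
  expect_equal(as.integer(parts[1]), n)
  expect_equal(as.numeric(parts[2]), 4.4, tolerance = 1e-3)
  expect_equal(as.numeric(parts[3]), sum(vals), tolerance = 1e-3)
})

test_that("malformed MRC inputs are rejected with clear errors", {
  f <- withr::local_tempfile(fileext = ".mrc")
  write_map(density_map(array(0, c(4, 4, 4))), f)
  # patch NZ to 2: non-cubic
  con <- file(f, "r+b"); seek(con, 8, rw = "write")
  writeBin(2L, con, size = 4, endian = "little"); close(con)
  expect_error(read_map(f), "cubic.*4 x 4 x 2")

  g <- withr::local_tempfile(fileext = ".mrc")
  writeBin(as.raw(rep(255, 2048)), g)
  expect_error(read_map(g), "header")

  expect_error(read_map(withr::local_tempfile()), "not found")
})

test_that("density_map enforces its invariants", {
  expect_error(density_map(array(0, c(8, 8, 4))), "cubic")
  expect_error(density_map(array(c(NA, rep(0, 7)), c(2, 2, 2))), "finite")
  expect_error(density_map(array(0, c(2, 2, 2)), voxel_size = -1), "positive")
})

test_that("mask realization matches brute-force voxel counts", {
  n <- 64
  ctr <- n %/% 2
  idx <- seq_len(n) - 1
  d2 <- outer(outer((idx - ctr)^2, (idx - ctr)^2, "+"), (idx - ctr)^2, "+")

  sph <- realize_mask(mask_sphere(radius = 10), n)
  expect_setequal(unique(as.vector(sph$data)), c(0, 1))
  expect_equal(sum(sph$data), sum(d2 <= 100))

  cyl <- realize_mask(mask_cylinder(radius = 4, height = 12), n)
  rho2 <- outer((idx - ctr)^2, (idx - ctr)^2, "+")
  brute_cyl <- sum(outer(rho2 <= 16, abs(idx - ctr) <= 6, "&"))
  expect_equal(sum(cyl$data), brute_cyl)

  # cylinder fully inside the sphere: difference counts subtract exactly
  dif <- realize_mask(mask_difference(mask_sphere(10), mask_cylinder(4, 12)),
                      n)
  expect_equal(sum(dif$data), sum(sph$data) - sum(cyl$data))
})

test_that("mask difference is A AND NOT B, and A = B union C", {
  n <- 32
  a <- mask_sphere(12); b <- mask_cylinder(5, 14)
  A <- realize_mask(a, n)$data
  B <- realize_mask(b, n)$data
  C <- realize_mask(mask_difference(a, b), n)$data
  expect_true(all(C == A * (1 - B)))
  expect_true(all(pmax(B * A, C) == A))  # B-within-A union C recovers A
  self <- realize_mask(mask_difference(a, a), n)$data
  expect_true(all(self == 0))
  expect_error(realize_mask(mask_sphere(radius = 20), 32), "exceeds half")
})

test_that("rigid transforms compose, invert and normalize angles", {
  t1 <- rigid_transform(c(400, -30, 10), c(1, 2, 3))
  expect_true(all(t1$euler >= 0 & t1$euler < 360))
  rt <- compose_transforms(invert_transform(t1), t1)
  expect_lt(max(abs(euler_matrix(rt$euler) - diag(3))), 1e-12)
  expect_lt(max(abs(rt$shift)), 1e-12)
  # matrix <-> euler round trip, including the gimbal poles
  for (e in list(c(40, 20, 10), c(123, 0, 0), c(10, 180, 0))) {
    R <- euler_matrix(e)
    expect_lt(max(abs(euler_matrix(matrix_euler(R)) - R)), 1e-12)
  }
})

test_that("apply_transform is identity-exact and interpolation-stable", {
  ph <- build_phantom(spec_small())
  expect_equal(apply_transform(ph, rigid_transform())$data, ph$data)

  t1 <- rigid_transform(c(40, 20, 10), c(1.5, -2, 0.5))
  fwd <- apply_transform(ph, t1)
  back <- apply_transform(fwd, invert_transform(t1))
  expect_gt(cor(as.vector(ph$data), as.vector(back$data)), 0.99)

  # rotating an ideal 8-fold phantom by 45 degrees about its axis
  r45 <- apply_transform(ph, rigid_transform(c(45, 0, 0)))
  expect_gt(cor(as.vector(ph$data), as.vector(r45$data)), 0.99)

  # integrated density of the compactly supported phantom survives transport
  expect_lt(abs(sum(fwd$data) / sum(ph$data) - 1), 0.01)
})

test_that("power-spectrum matching reproduces the target amplitude profile", {
  ph <- build_phantom(spec_small())
  self <- match_power_spectrum(ph, ph)
  expect_lt(max(abs(self$data - ph$data)), 1e-8)

  n <- 32
  set.seed(9)
  noise <- density_map(array(rnorm(n^3), c(n, n, n)), voxel_size = 6.6)
  # sharply low-passed target: zero beyond shell 8
  Ft <- fft(noise$data)
  si <- sptkit:::shell_index(n)
  Ft[si > 9] <- 0
  target <- density_map(Re(fft(Ft, inverse = TRUE)) / n^3, voxel_size = 6.6)
  set.seed(10)
  src <- density_map(array(rnorm(n^3), c(n, n, n)), voxel_size = 6.6)
  out <- match_power_spectrum(src, target)
  amp_out <- sptkit:::shell_amplitudes(out)
  amp_tgt <- sptkit:::shell_amplitudes(target)
  live <- amp_tgt$amplitude > 1e-9
  expect_lt(max(abs(amp_out$amplitude[live] / amp_tgt$amplitude[live] - 1)),
            0.01)
  # shells with no target power stay at zero rather than being amplified
  expect_lt(max(amp_out$amplitude[!live]), 1e-9)
  expect_error(match_power_spectrum(
    density_map(array(0, c(8, 8, 8))), density_map(array(1, c(8, 8, 8)))),
    "all zero")
})
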