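test_that("constrained correlation honors its normalization contract", {
  sp <- spec_small(occupancy_fraction = 60 / 950)
  ph <- build_phantom(sp)
  w <- wedge_spec(-60, 60)
  a <- simulate_subtomogram(ph, rigid_transform(c(30, 40, 50)), w,
                            snr = 2, seed = 1, id = "a")
  expect_lt(abs(constrained_cc(a, a) - 1), 1e-6)

  # with full wedges the score equals the real-space Pearson oracle
  af <- simulate_subtomogram(ph, rigid_transform(c(10, 20, 30)), full_wedge(),
                             snr = 2, seed = 2)
  bf <- simulate_subtomogram(ph, rigid_transform(c(10, 20, 30)), full_wedge(),
                             snr = 2, seed = 3)
  oracle <- cor(as.vector(af$map$data), as.vector(bf$map$data))
  expect_lt(abs(constrained_cc(af, bf) - oracle), 1e-4)

  # uniform scaling and offset of either input leave the score unchanged
  b <- simulate_subtomogram(ph, rigid_transform(c(30, 40, 50)), w,
                            snr = 2, seed = 4, id = "b")
  b_scaled <- subtomogram(density_map(3 * b$map$data + 5,
                                      voxel_size = b$map$voxel_size),
                          wedge = w, id = "bs")
  expect_lt(abs(constrained_cc(a, b) - constrained_cc(a, b_scaled)), 1e-9)
})

test_that("Fourier power outside the wedge overlap cannot move the score", {
  sp <- spec_small()
  ph <- build_phantom(sp)
  n <- map_side(ph)
  w <- wedge_spec(-60, 60)
  a <- simulate_subtomogram(ph, rigid_transform(c(15, 25, 35)), w,
                            snr = 5, seed = 11, id = "a")
  b <- simulate_subtomogram(ph, rigid_transform(c(15, 25, 35)), w,
                            snr = 5, seed = 12, id = "b")
  base <- constrained_cc(a, b)

  # inject strong junk into b strictly inside its own missing wedge
  # (outside any overlap), keeping the volume real via Friedel symmetry
  wm <- wedge_mask(n, w)
  Fb <- fft(b$map$data)
  set.seed(13)
  junk <- array(complex(real = rnorm(n^3), imaginary = rnorm(n^3)), dim(Fb))
  Fb2 <- Fb
  Fb2[!wm] <- Fb[!wm] + 50 * junk[!wm]
  vol <- fft(Fb2, inverse = TRUE) / n^3
  b2 <- subtomogram(density_map(Re(vol), voxel_size = b$map$voxel_size),
                    wedge = w, id = "b2")
  expect_lt(abs(constrained_cc(a, b2) - base), 1e-6)
})

test_that("constrained score is symmetric under transform inversion", {
  # exact regime: grid-exact rotation, compact support, full coverage -- no
  # interpolation error and no wedge ringing reaching the box edge
  ph <- asym_phantom()
  a <- subtomogram(ph, id = "a")
  b <- subtomogram(apply_transform(ph, rigid_transform(c(90, 0, 0))),
                   id = "b")
  t <- rigid_transform(c(270, 0, 0))
  expect_lt(abs(constrained_cc(a, b, t) -
                constrained_cc(b, a, invert_transform(t))), 1e-6)

  # wedged inputs spread ringing to the box edge, where quarter-turn
  # resampling about the integer-center voxel clips one boundary row; the
  # symmetry then holds to interpolation/clipping accuracy
  w <- wedge_spec(-60, 60)
  aw <- simulate_subtomogram(ph, rigid_transform(), w, snr = Inf, id = "aw")
  bw <- simulate_subtomogram(ph, rigid_transform(c(90, 0, 0)), w, snr = Inf,
                             id = "bw")
  for (tt in list(rigid_transform(c(270, 0, 0)),
                  rigid_transform(c(40, 20, 10)))) {
    expect_lt(abs(constrained_cc(aw, bw, tt) -
                  constrained_cc(bw, aw, invert_transform(tt))), 1e-2)
  }
})

test_that("alignment recovers known rotations and shifts", {
  ph <- asym_phantom()
  a <- subtomogram(ph, id = "a")
  b <- subtomogram(apply_transform(ph, rigid_transform(c(40, 20, 10))),
                   id = "b")
  al <- align_pair(a, b, coarse_step = 30, refine_steps = c(10, 5, 2),
                   max_shift = 3)
  truth <- invert_transform(rigid_transform(c(40, 20, 10)))
  expect_lt(sptkit:::rotation_distance(al$transform$euler, truth$euler), 2 + 1)
  expect_lt(max(abs(al$transform$shift - truth$shift)), 1)
  expect_gt(al$score, 0.95)

  # self-alignment: identity transform, perfect score
  al0 <- align_pair(a, a, coarse_step = 45, refine_steps = c(5), max_shift = 2)
  expect_lt(sptkit:::rotation_distance(al0$transform$euler, c(0, 0, 0)), 1e-6)
  expect_equal(al0$transform$shift, c(0, 0, 0))
  expect_lt(abs(al0$score - 1), 1e-6)

  # pure integer translation is recovered exactly at the correlation peak
  b2 <- subtomogram(apply_transform(ph, rigid_transform(shift = c(3, -2, 1))),
                    id = "b2")
  al2 <- align_pair(a, b2, coarse_step = 45, refine_steps = c(5), max_shift = 4)
  expect_equal(al2$transform$shift, c(-3, 2, -1))
  expect_gt(al2$score, 0.999)

  expect_error(align_pair(a, b, max_shift = 16), "half the box")
})

test_that("wedge-compensated averaging fills the missing wedge back in", {
  sp <- phantom_spec()          # native 4.4 A sampling
  ph <- build_phantom(sp)
  w <- wedge_spec(-60, 60)
  poses <- with(list(), {
    set.seed(31)
    lapply(1:10, function(i) rigid_transform(c(runif(1, 0, 360),
                                               runif(1, 0, 180),
                                               runif(1, 0, 360))))
  })
  parts <- lapply(seq_along(poses), function(i)
    simulate_subtomogram(ph, poses[[i]], w, snr = Inf, id = paste0("p", i)))
  # single wedged particle correlates imperfectly with the phantom...
  one <- cor(as.vector(parts[[1]]$map$data), as.vector(ph$data))
  # ...but averaging at the true poses reconstructs it
  avg <- wedge_average(parts, lapply(poses, invert_transform))
  cc <- cor(as.vector(avg$map$data), as.vector(ph$data))
  expect_gt(cc, 0.99)
  expect_gt(cc, one)
})

test_that("HAC merges identical particles first and produces n-1 events", {
  n <- 16
  set.seed(41)
  mk <- function(seed) {
    set.seed(seed)
    subtomogram(density_map(array(rnorm(n^3), c(n, n, n)), voxel_size = 6.6),
                id = paste0("r", seed))
  }
  parts <- lapply(1:6, mk)
  parts[[4]] <- subtomogram(parts[[2]]$map, id = "twin")  # duplicate of r2
  tree <- hac_average(parts, stop_k = 1, coarse_step = 60,
                      refine_steps = c(30), max_shift = 1)
  expect_equal(nrow(tree$merges), 5)
  first <- sort(c(tree$merges$left[1], tree$merges$right[1]))
  expect_equal(first, sort(c("r2", "twin")))
  expect_equal(sort(tree$leaves),
               sort(vapply(parts, `[[`, character(1), "id")))
})

test_that("HAC cut at two classes recovers a well-separated partition", {
  sp <- spec_small(occupancy_fraction = 0.3)  # strong cargo: well-separated
  coh <- generate_cohort(3, 3, 0, spec = sp, snr = 5, seed = 51,
                         max_shift_vox = 1)
  tree <- hac_average(coh$particles, stop_k = 2, coarse_step = 30,
                      refine_steps = c(10), max_shift = 2)
  groups <- lapply(tree$members, function(ids) sort(sub("_.*", "", ids)))
  expect_setequal(
    vapply(groups, paste, character(1), collapse = ","),
    c("empty,empty,empty", "occupied,occupied,occupied"))
})
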