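test_that("primitive rasterization matches analytic volumes", {
  # ball r = 10 mm on a 1 mm grid: center-inclusion count vs 4/3 pi r^3
  b <- ball_mask(10, spacing = 1)
  expect_rel(mask_volume_mm3(b), 4 / 3 * pi * 1000, 0.02)

  # box [0,10]^3 with voxel centers at 0.5 mm offsets: brute-force count
  g <- grid_spec(c(14, 14, 14), c(1, 1, 1), origin = c(-1.5, -1.5, -1.5))
  bx <- make_primitive("box", g, lo = c(0, 0, 0), hi = c(10, 10, 10))
  centers <- axis_coords(bx, 1)
  n_inside <- sum(centers >= 0 & centers <= 10)
  expect_identical(sum(bx$data), as.integer(n_inside^3))
  # with centers on integers 0..10 per axis: exactly 1000 when origin at 0.5
  g2 <- grid_spec(c(10, 10, 10), c(1, 1, 1), origin = c(0.5, 0.5, 0.5))
  bx2 <- make_primitive("box", g2, lo = c(0, 0, 0), hi = c(10, 10, 10))
  expect_identical(sum(bx2$data), 1000L)

  # tiny ball centered between voxel centers: no center inside
  g3 <- grid_spec(c(6, 6, 6), c(1, 1, 1))
  tiny <- make_primitive("ball", g3, center = c(2.5, 2.5, 2.5), radius = 0.1)
  expect_identical(sum(tiny$data), 0L)

  # shape outside the grid extent errors, naming the axis and extent
  expect_error(
    make_primitive("ball", g3, center = c(2, 2, 2), radius = 10),
    "outside the grid extent")
})

test_that("mandible phantom is deterministic and geometrically consistent", {
  ph1 <- small_phantom()
  ph2 <- make_mandible_phantom(
    grid = default_phantom_grid(spacing = c(0.5, 0.5, 1)), seed = 1)
  expect_identical(ph1$volume$data, ph2$volume$data)
  expect_identical(ph1$truth_masks, ph2$truth_masks)

  # landmark caliper ground truth: 3-4-5 triangle
  ph3 <- make_mandible_phantom(
    grid = default_phantom_grid(spacing = c(0.66, 0.66, 2)), seed = 1,
    extra_landmarks = list(P = c(0, 0, 0), Q = c(3, 4, 0)),
    extra_pairs = list(c("P", "Q")))
  expect_equal(ph3$caliper_pairs$truth_mm[ph3$caliper_pairs$a == "P"], 5)

  # tumor truth mask is the analytic ellipsoid (within rasterization error)
  va <- 4 / 3 * pi * prod(ph1$params$tumor_radii)
  expect_rel(mask_volume_mm3(ph1$truth_masks$tumor), va, 0.03)

  # masks disjoint; nerves single connected components
  expect_false(any(ph1$truth_masks$tumor$data & ph1$truth_masks$mandible$data))
  for (nm in c("nerve_left", "nerve_right")) {
    d <- dim(ph1$truth_masks[[nm]]$data)
    lab <- segqa:::.cc_label_cpp(as.vector(ph1$truth_masks[[nm]]$data), d, 26L)
    expect_identical(max(lab), 1L)
  }

  # sub-voxel residual wall warns but proceeds
  expect_warning(
    make_mandible_phantom(phantom_params(residual_wall = 0.2),
                          grid = default_phantom_grid(spacing = c(0.5, 0.5, 1)),
                          seed = 1),
    "residual wall")

  # a tumor that misses the arch is rejected
  expect_error(
    make_mandible_phantom(phantom_params(tumor_radii = c(2, 2, 2),
                                         residual_wall = 30),
                          grid = default_phantom_grid(spacing = c(0.5, 0.5, 1))),
    "bone-tumor interface")
})

test_that("mask volumes track their analytic solids at fine spacing", {
  ph <- make_mandible_phantom(
    grid = default_phantom_grid(spacing = c(0.5, 0.5, 0.5)), seed = 1)
  va <- 4 / 3 * pi * prod(ph$params$tumor_radii)
  expect_rel(mask_volume_mm3(ph$truth_masks$tumor), va, 0.05)
  # nerve canal: tube of radius r along the spline path; compare to the
  # analytic tube volume pi r^2 L with L from the densely sampled path
  p <- ph$params
  th <- seq(p$nerve_span_deg[1], p$nerve_span_deg[2], length.out = 400)
  fz <- splinefun(seq(p$nerve_span_deg[1], p$nerve_span_deg[2],
                      length.out = p$nerve_control_points),
                  rep(p$nerve_z_offset, p$nerve_control_points),
                  method = "natural")
  z <- fz(th) + p$nerve_undulation_amp *
    sinpi(2 * p$nerve_undulation_periods *
            (th - p$nerve_span_deg[1]) / diff(p$nerve_span_deg))
  xy <- cbind(p$arch_radius * sinpi(th / 180), p$arch_radius * cospi(th / 180))
  L <- sum(sqrt(rowSums(diff(cbind(xy, z))^2)))
  expect_rel(mask_volume_mm3(ph$truth_masks$nerve_right),
             pi * p$nerve_radius^2 * L, 0.15)
})

test_that("degradation models blur, resampling and noise faithfully", {
  ph <- small_phantom()
  v <- ph$volume

  # identity
  expect_identical(degrade(v, 0, 0)$data, v$data)

  # seeded Gaussian noise on a constant volume: sample sd within 5%
  cv <- image_volume(array(0, c(50, 50, 50)), c(1, 1, 1))
  dn <- degrade(cv, 0, 10, seed = 7)
  expect_rel(sd(dn$data), 10, 0.05)
  expect_identical(degrade(cv, 0, 10, seed = 7)$data, dn$data)

  # normalized blur kernel conserves total intensity: the phantom has a
  # constant-background margin, so the global mean is preserved
  db <- degrade(v, 1, 0)
  expect_lt(abs(mean(db$data) - mean(v$data)) / abs(mean(v$data)), 0.001)

  # resampling to coarser spacing; fabrication of resolution refused
  dr <- degrade(v, 0, 0, target_spacing = c(1, 1, 1))
  expect_equal(dr$spacing, c(1, 1, 1))
  expect_lt(abs(mean(dr$data) - mean(v$data)) / abs(mean(v$data)), 0.05)
  expect_error(degrade(v, 0, 0, target_spacing = c(0.1, 0.1, 0.1)), "finer")

  # partial-volume monotonicity: blur never increases pure-bone voxels
  hu_bone <- ph$params$hu[["cortical"]]
  counts <- vapply(c(0, 0.7, 1.4), function(fw)
    sum(abs(degrade(v, fw, 0)$data - hu_bone) < 1e-9), 0)
  expect_true(all(diff(counts) <= 0))
})
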