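test_that("virtual calipers measure Euclidean distances by name", {
  lm <- rbind(p = c(0, 0, 0), q = c(3, 4, 0), r = c(1, 1, 1))
  out <- landmark_distance(lm, list(c("p", "q"), c("q", "p"), c("p", "p")))
  expect_equal(out$distance_mm, c(5, 5, 0))
  expect_error(landmark_distance(lm, list(c("p", "zz"))), "available")

  # generator consistency: phantom caliper table reproduces its landmarks
  ph <- small_phantom()
  redo <- landmark_distance(ph$truth_landmarks,
                            ph$caliper_pairs[, c("a", "b")])
  expect_equal(redo$distance_mm, ph$caliper_pairs$truth_mm, tolerance = 1e-9)

  # rigid-motion invariance
  shift <- ph$truth_landmarks + matrix(c(3, -2, 7), nrow(ph$truth_landmarks),
                                       3, byrow = TRUE)
  redo2 <- landmark_distance(shift, ph$caliper_pairs[, c("a", "b")])
  expect_equal(redo2$distance_mm, redo$distance_mm, tolerance = 1e-9)
})

test_that("datum-plane slicing produces analytic sections", {
  cube <- cube_mesh()
  sl <- slice_mesh(cube, axis = c(0, 0, 1), n_planes = 3)
  expect_length(sl, 3)
  expect_equal(vapply(sl, function(s) s$plane$offset, 0), c(0.25, 0.5, 0.75))
  for (s in sl) {
    expect_length(s$loops, 1)
    expect_equal(s$total_area_mm2, 1, tolerance = 1e-9)
    expect_equal(s$centroid[1:2], c(0.5, 0.5), tolerance = 1e-9)
    expect_equal(s$centroid[3], s$plane$offset, tolerance = 1e-9)
  }

  # sphere equator: loop area within 1% of pi r^2
  sp <- icosphere(10, 4)
  eq <- slice_mesh(sp, axis = c(0, 0, 1), offsets = 0)[[1]]
  expect_rel(eq$total_area_mm2, 100 * pi, 0.01)

  # plane through a vertex only: degenerate contact flagged, not an error
  tet <- tetra_mesh()
  top <- slice_mesh(tet, axis = c(0, 0, 1), offsets = 1)[[1]]
  expect_true(top$empty || top$total_area_mm2 < 1e-9)

  expect_error(slice_mesh(cube, axis = c(0, 0, 0), n_planes = 1), "non-zero")
})

test_that("hole loops subtract from area and centroid", {
  # washer: torus sliced through its plane gives outer + inner loop
  tor <- torus_mesh(R0 = 10, r0 = 3, n = 96, m = 48)
  sl <- slice_mesh(tor, axis = c(0, 0, 1), offsets = 0)[[1]]
  expect_length(sl$loops, 2)
  expect_equal(sort(sign(sl$area_mm2)), c(-1, 1))
  expect_rel(sl$total_area_mm2, pi * (13^2 - 7^2), 0.01)
  expect_equal(sl$centroid[1:2], c(0, 0), tolerance = 1e-6)
})

test_that("contour extents measure centroid-to-edge distances", {
  cube <- cube_mesh()
  s <- slice_mesh(cube, axis = c(0, 0, 1), offsets = 0.5)[[1]]
  ce <- contour_centroid_extents(s, u = c(1, 0, 0), v = c(0, 1, 0))
  expect_equal(ce$centroid[1:2], c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(c(ce$ext_pu, ce$ext_mu, ce$ext_pv, ce$ext_mv),
               rep(0.5, 4), tolerance = 1e-9)
  expect_equal(ce$width_u, 1, tolerance = 1e-9)

  circ <- slice_mesh(icosphere(3, 4), axis = c(0, 0, 1), offsets = 0)[[1]]
  cec <- contour_centroid_extents(circ)
  expect_rel(cec$ext_pu, 3, 0.01)
  expect_rel(cec$ext_mv, 3, 0.01)

  # two disjoint equal squares, centers (0,0) and (4,0): centroid (2,0)
  twin <- mesh(rbind(cube_mesh(lo = c(-0.5, -0.5, 0), hi = c(0.5, 0.5, 1))$vertices,
                     cube_mesh(lo = c(3.5, -0.5, 0), hi = c(4.5, 0.5, 1))$vertices),
               rbind(cube_mesh()$faces, cube_mesh()$faces + 8))
  st <- slice_mesh(twin, axis = c(0, 0, 1), offsets = 0.5)[[1]]
  expect_length(st$loops, 2)
  ce2 <- contour_centroid_extents(st, u = c(1, 0, 0), v = c(0, 1, 0))
  expect_equal(ce2$centroid[1:2], c(2, 0), tolerance = 1e-9)

  empty_slice <- slice_mesh(cube, axis = c(0, 0, 1), offsets = 5)[[1]]
  expect_error(contour_centroid_extents(empty_slice), "zero area")
})

test_that("slicing is equivariant under translation", {
  sp <- icosphere(5, 3)
  sp2 <- mesh(sweep(sp$vertices, 2, c(2, -1, 3), "+"), sp$faces)
  s1 <- slice_mesh(sp, axis = c(0, 0, 1), offsets = 1)[[1]]
  s2 <- slice_mesh(sp2, axis = c(0, 0, 1), offsets = 4)[[1]]
  expect_equal(s2$centroid, s1$centroid + c(2, -1, 3), tolerance = 1e-9)
  expect_equal(s2$total_area_mm2, s1$total_area_mm2, tolerance = 1e-9)
})

test_that("nerve path comparison measures centroid spread per slice", {
  base <- cbind(seq(0, 10, by = 2), 0, 0)
  t0 <- path_trace("m1", 1:6, base)
  t_same <- path_trace("m2", 1:6, base)
  cmp0 <- nerve_path_compare(list(t0, t_same))
  expect_true(all(cmp0$per_slice$distance_mm == 0))

  # two models offset +-1 mm in x: every distance 1
  tp <- path_trace("m1", 1:6, sweep(base, 2, c(1, 0, 0), "+"))
  tm <- path_trace("m2", 1:6, sweep(base, 2, c(-1, 0, 0), "+"))
  cmp1 <- nerve_path_compare(list(tp, tm))
  expect_true(all(abs(cmp1$per_slice$distance_mm - 1) < 1e-12))

  # three models at x = 0, 1, 2 on one slice: mean 1, distances 1, 0, 1
  tr3 <- lapply(0:2, function(x)
    path_trace(paste0("m", x), 1:2, rbind(c(x, 0, 0), c(x, 5, 5))))
  cmp3 <- nerve_path_compare(tr3)
  d_slice1 <- cmp3$per_slice$distance_mm[cmp3$per_slice$slice == 1]
  expect_equal(sort(d_slice1), c(0, 1, 1))

  # invariance under a common offset
  tr3b <- lapply(tr3, function(t)
    path_trace(t$model_id, t$slice_index,
               sweep(t$centroids, 2, c(5, 5, 5), "+")))
  cmp3b <- nerve_path_compare(tr3b)
  expect_equal(cmp3b$per_slice$distance_mm, cmp3$per_slice$distance_mm)

  expect_error(nerve_path_compare(list(t0, path_trace("m3", 2:7, base))),
               "mismatched slice sets")
  expect_error(nerve_path_compare(list(t0)), "at least 2")
  expect_error(path_trace("m", c(1, 1, 2), base[1:3, ]), "strictly increasing")
})
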