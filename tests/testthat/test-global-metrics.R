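test_that("mesh volume and area match closed forms", {
  expect_equal(mesh_volume(cube_mesh()), 1)
  expect_equal(mesh_area(cube_mesh()), 6)
  expect_equal(mesh_volume(tetra_mesh()), 1 / 6)
  tri <- mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), matrix(1:3, 1))
  expect_equal(mesh_area(tri), 0.5)

  ico <- icosphere(1, 4)
  expect_rel(mesh_volume(ico), 4 * pi / 3, 0.005)
  expect_rel(mesh_area(ico), 4 * pi, 0.01)

  open_mesh <- mesh(cube_mesh()$vertices, cube_mesh()$faces[-1, ])
  expect_error(mesh_volume(open_mesh), "closed surfaces")
  expect_equal(mesh_area(open_mesh), 5.5)
})

test_that("voxelization reproduces analytic volumes from center-inclusion", {
  vox <- voxelize_mesh(cube_mesh(), 0.1)
  expect_rel(mask_volume_mm3(vox), 1, 0.02)

  ball <- icosphere(10, 4)
  expect_rel(mask_volume_mm3(voxelize_mesh(ball, 0.5)), 4 / 3 * pi * 1000,
             0.02)

  # pitch larger than the bbox: degenerate sampling, no crash
  tiny <- voxelize_mesh(icosphere(0.4, 2), 5)
  expect_gte(sum(tiny$data), 0)

  expect_error(voxelize_mesh(mesh(cube_mesh()$vertices,
                                  cube_mesh()$faces[-1, ]), 0.1),
               "watertight")
  expect_error(voxelize_mesh(cube_mesh(), -1), "pitch")
})

test_that("agreement/disagreement identities hold at any pitch", {
  cube <- cube_mesh()
  for (pitch in c(0.5, 0.23, 0.11)) {
    self <- agreement_disagreement(cube, cube, pitch = pitch)
    expect_equal(self$agreement_pct, 100)
    expect_equal(self$disagreement_pct, 0)
    rel <- agreement_disagreement(cube, cube, pitch = pitch,
                                  variant = "relative_to_a")
    expect_equal(rel$agreement_pct, 100)
  }
  far <- cube_mesh(lo = c(3, 3, 3), hi = c(4, 4, 4))
  dj <- agreement_disagreement(cube, far, pitch = 0.2)
  expect_equal(dj$agreement_pct, 0)
  expect_equal(dj$disagreement_pct, 100)
})

test_that("half-overlapping unit cubes tend to the analytic 33.3%", {
  a <- cube_mesh()
  b <- cube_mesh(lo = c(0.5, 0, 0), hi = c(1.5, 1, 1))
  ov <- agreement_disagreement(a, b, pitch = 0.05)
  expect_rel(ov$agreement_pct, 100 * 0.5 / 1.5, 0.01)
  expect_equal(ov$agreement_pct + ov$disagreement_pct, 100)
  # relative-to-a variant: V(A&B)/V(A) = 1/2
  rel <- agreement_disagreement(a, b, pitch = 0.05, variant = "relative_to_a")
  expect_rel(rel$agreement_pct, 50, 0.01)
  rel_ba <- agreement_disagreement(b, a, pitch = 0.05,
                                   variant = "relative_to_a")
  expect_rel(rel_ba$agreement_pct, 50, 0.01)
})

test_that("symmetric overlap invariants: swap invariance, volume bounds,
          pitch convergence", {
  a <- icosphere(6, 3)
  b <- icosphere(6, 3, center = c(2, 1, 0))
  ab <- agreement_disagreement(a, b, pitch = 0.3)
  ba <- agreement_disagreement(b, a, pitch = 0.3)
  expect_equal(ab$agreement_pct, ba$agreement_pct)
  expect_lte(ab$v_intersection, min(ab$v_a, ab$v_b) + 1e-9)
  expect_gte(ab$v_union, max(ab$v_a, ab$v_b) - 1e-9)
  expect_equal(ab$v_only_a, ab$v_a - ab$v_intersection)
  expect_equal(ab$agreement_pct + ab$disagreement_pct, 100)

  # halving the pitch moves symmetric agreement by < 1 percentage point
  ah <- agreement_disagreement(a, b, pitch = 0.15)
  expect_lt(abs(ah$agreement_pct - ab$agreement_pct), 1)

  # the relative_to_a matrix need not be symmetric
  c_small <- icosphere(3, 3, center = c(2, 1, 0))
  r1 <- agreement_disagreement(a, c_small, pitch = 0.2,
                               variant = "relative_to_a")
  r2 <- agreement_disagreement(c_small, a, pitch = 0.2,
                               variant = "relative_to_a")
  expect_gt(abs(r1$agreement_pct - r2$agreement_pct), 5)
})

test_that("deviation fields measure concentric offsets and vanish on identity", {
  a <- icosphere(10, 3)
  self <- deviation_field(a, a, samples_per_mm2 = 0.5, seed = 1)
  expect_true(all(abs(self$signed_d) < 1e-12))
  expect_equal(self$hausdorff, 0)

  b <- icosphere(12, 3)
  dv <- deviation_field(a, b, samples_per_mm2 = 1, seed = 1)
  edge_tol <- 12 * 2 * pi / (10 * 2^3)  # about one icosphere edge length
  expect_lt(abs(dv$mean_abs - 2), edge_tol)
  expect_lt(abs(dv$directed_ab - 2), edge_tol)
  expect_lt(abs(dv$hausdorff - 2), edge_tol)
  # A inside B: signed distances negative
  expect_true(all(dv$signed_d < 0))
  expect_equal(dv$hausdorff, max(dv$directed_ab, dv$directed_ba))
  expect_true(all(abs(dv$signed_d) <= dv$hausdorff + 1e-12))
})

test_that("triangle-exact distances never exceed vertex-only distances", {
  a <- cube_mesh()
  b <- cube_mesh(lo = c(2, 0.2, 0.2), hi = c(3, 1.2, 1.2))
  d_exact <- segqa:::.closest_tri_dist_cpp(a$vertices, b$vertices, b$faces)
  d_vertex <- apply(a$vertices, 1, function(p)
    sqrt(min(colSums((t(b$vertices) - p)^2))))
  expect_true(all(d_exact <= d_vertex + 1e-12))
  expect_true(any(d_exact < d_vertex - 1e-9))  # faces beat vertices somewhere
})

test_that("sampled Hausdorff obeys the triangle inequality surrogate", {
  a <- icosphere(8, 3)
  b <- icosphere(9, 3, center = c(1, 0, 0))
  c3 <- icosphere(10, 3, center = c(0, 1, 0))
  h <- function(x, y) deviation_field(x, y, samples_per_mm2 = 0.5,
                                      seed = 2)$hausdorff
  expect_lte(h(a, c3), h(a, b) + h(b, c3) + 0.5)  # sampling tolerance
})

test_that("unsigned fallback warns when the target is open", {
  a <- icosphere(5, 2)
  open_b <- mesh(a$vertices, a$faces[-1, ])
  expect_warning(dv <- deviation_field(a, open_b, samples_per_mm2 = 0,
                                       seed = 1), "watertight")
  expect_false(dv$signed)
  expect_true(all(dv$signed_d >= 0))
})
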