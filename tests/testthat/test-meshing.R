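test_that("surface extraction is watertight with convergent enclosed volume", {
  b <- ball_mask(20, spacing = 1)
  m <- extract_surface(b)
  dg <- mesh_diagnostics(m)
  expect_true(dg$watertight)
  expect_identical(dg$n_components, 1L)
  expect_rel(mesh_volume(m), 4 / 3 * pi * 20^3, 0.02)

  # single-voxel mask: closed surface with 0 < volume < 1 voxel volume
  one <- binary_mask(array(FALSE, c(5, 5, 5)), c(1, 1, 1))
  one$data[3, 3, 3] <- TRUE
  s1 <- extract_surface(one)
  expect_true(mesh_diagnostics(s1)$watertight)
  v1 <- mesh_volume(s1)
  expect_gt(v1, 0)
  expect_lt(v1, 1)

  # two disjoint blobs: exactly 2 connected components
  two <- binary_mask(array(FALSE, c(12, 6, 6)), c(1, 1, 1))
  two$data[2:4, 2:4, 2:4] <- TRUE
  two$data[8:10, 2:4, 2:4] <- TRUE
  expect_identical(mesh_diagnostics(extract_surface(two))$n_components, 2L)

  expect_error(extract_surface(binary_mask(array(FALSE, c(4, 4, 4)),
                                           c(1, 1, 1))), "nothing to mesh")
})

test_that("enclosed volume converges to the analytic volume as spacing shrinks", {
  va <- 4 / 3 * pi * 8^3
  err <- vapply(c(1, 0.5), function(h) {
    m <- extract_surface(ball_mask(8, spacing = h))
    abs(mesh_volume(m) - va) / va
  }, 0)
  expect_lt(err[2], err[1])
  expect_true(mesh_diagnostics(extract_surface(ball_mask(8, 0.5)))$watertight)
})

test_that("diagnostics report closedness, components and Euler characteristic", {
  cube <- cube_mesh()
  dg <- mesh_diagnostics(cube)
  expect_true(dg$watertight)
  expect_identical(dg$euler_characteristic, 2L)
  expect_identical(dg$n_components, 1L)
  expect_equal(dg$bbox, cbind(c(0, 1), c(0, 1), c(0, 1)),
               ignore_attr = TRUE)

  single <- mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                 matrix(c(1, 2, 3), 1))
  expect_false(mesh_diagnostics(single)$watertight)

  # torus: edge census gives V - E + F = 0 (genus 1); V, E, F known by
  # construction: V = n m, F = 2 n m, E = 3 n m
  tor <- torus_mesh(n = 24, m = 12)
  dgt <- mesh_diagnostics(tor)
  expect_true(dgt$watertight)
  expect_identical(dgt$euler_characteristic, 24L * 12L - 3L * 24L * 12L + 2L * 24L * 12L)
  expect_identical(dgt$euler_characteristic, 0L)
})

test_that("STL binary and ASCII round-trip the triangle soup", {
  cube <- cube_mesh()  # coordinates 0/1 are exact in float32
  fb <- tempfile(fileext = ".stl")
  write_stl(cube, fb)
  rb <- read_stl(fb)
  expect_identical(nrow(rb$faces), 12L)
  # identical triangle set: same sorted vertex rows, watertight again
  expect_equal(rb$vertices[order(rb$vertices[, 1], rb$vertices[, 2],
                                 rb$vertices[, 3]), ],
               cube$vertices[order(cube$vertices[, 1], cube$vertices[, 2],
                                   cube$vertices[, 3]), ],
               ignore_attr = TRUE)
  expect_true(mesh_diagnostics(rb)$watertight)
  expect_equal(mesh_volume(rb), 1)

  # ascii/binary volumes of the same mesh agree within 1e-6 mm^3
  ico <- icosphere(7, 2)
  fa <- tempfile(fileext = ".stl")
  write_stl(ico, fa, format = "ascii")
  write_stl(ico, fb, format = "binary")
  va <- mesh_volume(read_stl(fa))
  vb <- mesh_volume(read_stl(fb))
  expect_lt(abs(va - vb), 1e-3)  # float32 storage; identical soup either way
  expect_lt(abs(va - mesh_volume(ico)), 1e-3)
})

test_that("malformed STL files are rejected with a reason", {
  cube <- cube_mesh()
  f <- tempfile(fileext = ".stl")
  write_stl(cube, f)
  # corrupt the record count
  con <- file(f, "r+b")
  seek(con, 80, rw = "write")
  writeBin(99L, con, size = 4, endian = "little")
  close(con)
  expect_error(read_stl(f), "count")

  writeLines(c("solid t", "facet normal 0 0 1", " outer loop",
               "  vertex 0 0 0", "  vortex 1 0 0", "  vertex 0 1 0",
               " endloop", "endfacet", "endsolid t"), f)
  expect_error(read_stl(f), "line 5")
})

test_that("PLY export carries a per-vertex scalar channel", {
  cube <- cube_mesh()
  f <- tempfile(fileext = ".ply")
  write_ply(cube, f, scalar = seq_len(8) / 10)
  lines <- readLines(f)
  expect_identical(lines[1], "ply")
  expect_true(any(grepl("property float quality", lines)))
  expect_identical(sum(grepl("^3 ", lines)), 12L)
  expect_error(write_ply(cube, f, scalar = 1:3), "per vertex")
})
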