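make_two_ball_volume <- function() {
  g <- grid_spec(c(40, 20, 20), c(1, 1, 1))
  a <- make_primitive("ball", g, center = c(10, 10, 10), radius = 5)
  b <- make_primitive("ball", g, center = c(30, 10, 10), radius = 5)
  v <- array(-1000, c(40, 20, 20))
  v[a$data | b$data] <- 1200
  list(vol = image_volume(v, c(1, 1, 1)), a = a$data, b = b$data)
}

test_that("thresholding is inclusive on both ends and validates bounds", {
  v <- image_volume(array(c(-1000, 40, 1200), c(3, 2, 2)), c(1, 1, 1))
  expect_identical(threshold_mask(v, 200, 3000)$data, v$data == 1200)
  expect_true(all(threshold_mask(v, -2000, 4000)$data))
  expect_identical(threshold_mask(v, 40, 40)$data, v$data == 40)
  expect_error(threshold_mask(v, 10, -10), "hu_min")
})

test_that("region growing respects connectivity and seeds", {
  tb <- make_two_ball_volume()
  # seed in ball A keeps only A
  rg <- region_grow(tb$vol, matrix(c(10, 10, 10), ncol = 3), 1000, 2000)
  expect_identical(rg$data, tb$a)
  # background seed: empty mask with a warning
  expect_warning(expect_warning(
    empty <- region_grow(tb$vol, matrix(c(20, 10, 10), ncol = 3), 1000, 2000),
    "no valid seed"), "dropped")
  expect_identical(sum(empty$data), 0L)
  # seeds in both halves of one ball equal a single seed (flood-fill oracle)
  one <- region_grow(tb$vol, rbind(c(8, 10, 10), c(12, 10, 10)), 1000, 2000)
  expect_identical(one$data, rg$data)
  expect_error(region_grow(tb$vol, matrix(c(99, 1, 1), ncol = 3), 0, 1),
               "outside the volume grid")
})

test_that("region growing output is a subset of the threshold mask and every
          component touches a seed", {
  set.seed(11)
  for (rep in 1:3) {
    v <- image_volume(array(sample(c(-1000, 500), 14^3, TRUE,
                                   prob = c(0.7, 0.3)), c(14, 14, 14)),
                      c(1, 1, 1))
    thr <- threshold_mask(v, 400, 600)
    seeds <- which(thr$data, arr.ind = TRUE)[c(1, 5), , drop = FALSE]
    rg <- region_grow(v, seeds, 400, 600, connectivity = 6)
    expect_true(all(thr$data[rg$data]))
    lab <- array(segqa:::.cc_label_cpp(as.vector(rg$data), dim(rg$data), 6L),
                 dim(rg$data))
    for (comp in setdiff(unique(as.vector(lab)), 0))
      expect_true(any(lab[seeds] == comp))
  }
})

test_that("morphology steps edit masks as their structuring elements dictate", {
  g <- grid_spec(c(15, 15, 15), c(1, 1, 1))
  ball <- make_primitive("ball", g, center = c(7, 7, 7), radius = 4)

  # empty step list = identity
  expect_identical(apply_morphology(ball, list())$data, ball$data)

  # close (dilate then erode, r = 1) fills a single-voxel hole: brute-force
  # structuring-element application computed here as the oracle
  holed <- ball
  holed$data[8, 8, 8] <- FALSE
  off <- segqa:::ball_offsets(1)
  brute <- function(m, op) {
    d <- dim(m); out <- array(op == "erode", d)
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      nb <- cbind(x + off[, 1], y + off[, 2], z + off[, 3])
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      vals <- m[nb[ok, , drop = FALSE]]
      # erosion treats out-of-grid neighbors as foreground (adjoint pair
      # of grid-clipped dilation)
      out[x, y, z] <- if (op == "dilate") any(vals) else all(vals)
    }
    out
  }
  oracle <- brute(brute(holed$data, "dilate"), "erode")
  closed <- apply_morphology(holed, list(list(op = "close", radius = 1)))
  expect_identical(closed$data, oracle)
  expect_true(closed$data[8, 8, 8])

  # keep_largest retains the 100-voxel blob over the 10-voxel blob
  two <- binary_mask(array(FALSE, c(20, 10, 10)), c(1, 1, 1))
  two$data[2:6, 2:6, 2:5] <- TRUE   # 100 voxels
  two$data[12:16, 2:2, 2:3] <- TRUE # 10 voxels
  kept <- apply_morphology(two, list("keep_largest"))
  expect_identical(sum(kept$data), 100L)
  expect_true(all(kept$data[2:6, 2:6, 2:5]))

  expect_error(apply_morphology(ball, list("shrinkwrap")), "unknown")
  expect_error(apply_morphology(ball, list(list(op = "erode", radius = 0))),
               ">= 1")
})

test_that("close-open composite is idempotent on its own output", {
  set.seed(4)
  m <- binary_mask(array(runif(16^3) > 0.6, c(16, 16, 16)), c(1, 1, 1))
  steps <- list(list(op = "open", radius = 1), list(op = "close", radius = 1))
  once <- apply_morphology(m, steps)
  twice <- apply_morphology(once, steps)
  expect_identical(twice$data, once$data)
})

test_that("slice interpolation reconstructs shapes between annotations", {
  # identical disks on z = 1 and z = 5: constant interpolation
  disk <- function(r) {
    xy <- as.matrix(expand.grid(1:21, 1:21))
    sel <- (xy[, 1] - 11)^2 + (xy[, 2] - 11)^2 <= r^2
    m <- matrix(FALSE, 21, 21)
    m[xy[sel, , drop = FALSE]] <- TRUE
    m
  }
  m <- array(FALSE, c(21, 21, 5))
  m[, , 1] <- disk(3); m[, , 5] <- disk(3)
  out <- interpolate_slices(binary_mask(m, c(1, 1, 1)), c(1, 5))
  for (z in 2:4) expect_identical(out$data[, , z], disk(3))

  # concentric disks r = 2 and r = 4: mid-slice radius within 1 voxel of 3
  m2 <- array(FALSE, c(21, 21, 5))
  m2[, , 1] <- disk(2); m2[, , 5] <- disk(4)
  out2 <- interpolate_slices(binary_mask(m2, c(1, 1, 1)), c(1, 5))
  mid_r <- sqrt(sum(out2$data[, , 3]) / pi)
  expect_lt(abs(mid_r - 3), 1)
  # annotated slices unchanged, outside range empty
  expect_identical(out2$data[, , 1], disk(2))
  expect_identical(out2$data[, , 5], disk(4))

  # no gap: output equals input
  m3 <- array(FALSE, c(21, 21, 3))
  m3[, , 2] <- disk(2); m3[, , 3] <- disk(2)
  out3 <- interpolate_slices(binary_mask(m3, c(1, 1, 1)), c(2, 3))
  expect_identical(out3$data, m3)
  expect_false(any(out3$data[, , 1]))

  expect_error(interpolate_slices(binary_mask(m3, c(1, 1, 1)), 2),
               "at least 2")
  m4 <- m3; m4[, , 3] <- FALSE
  expect_error(interpolate_slices(binary_mask(m4, c(1, 1, 1)), c(2, 3)),
               "empty")
})

test_that("mask subtraction is a AND NOT b with a grid check", {
  g <- grid_spec(c(10, 10, 10), c(1, 1, 1))
  a <- make_primitive("box", g, lo = c(0, 0, 0), hi = c(5, 9, 9))
  b <- make_primitive("box", g, lo = c(3, 0, 0), hi = c(9, 9, 9))
  expect_identical(sum(mask_subtract(a, a)$data), 0L)
  empty <- binary_mask(array(FALSE, c(10, 10, 10)), c(1, 1, 1))
  expect_identical(mask_subtract(a, empty)$data, a$data)
  expect_identical(sum(mask_subtract(a, b)$data),
                   sum(a$data) - sum(a$data & b$data))
  other <- binary_mask(array(FALSE, c(10, 10, 10)), c(2, 1, 1))
  expect_error(mask_subtract(a, other), "different grids")
})
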