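# analytic mesh fixtures shared across tests

# axis-aligned box as 12 outward-oriented triangles
cube_mesh <- function(lo = c(0, 0, 0), hi = c(1, 1, 1)) {
  v <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                             z = c(lo[3], hi[3])))
  f <- rbind(c(1, 3, 4), c(1, 4, 2),   # z = lo
             c(5, 6, 8), c(5, 8, 7),   # z = hi
             c(1, 2, 6), c(1, 6, 5),   # y = lo
             c(3, 7, 8), c(3, 8, 4),   # y = hi
             c(1, 5, 7), c(1, 7, 3),   # x = lo
             c(2, 4, 8), c(2, 8, 6))   # x = hi
  mesh(v, f)
}

tetra_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  mesh(v, f)
}

# parametric torus (major R0, minor r0), watertight, genus 1
torus_mesh <- function(R0 = 10, r0 = 3, n = 24, m = 12) {
  th <- rep(2 * pi * (0:(n - 1)) / n, each = m)
  ph <- rep(2 * pi * (0:(m - 1)) / m, times = n)
  V <- cbind((R0 + r0 * cos(ph)) * cos(th),
             (R0 + r0 * cos(ph)) * sin(th),
             r0 * sin(ph))
  idx <- function(i, j) (i %% n) * m + (j %% m) + 1
  F <- matrix(0L, 2 * n * m, 3)
  k <- 1
  for (i in 0:(n - 1)) for (j in 0:(m - 1)) {
    F[k, ] <- c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1))
    F[k + 1, ] <- c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1))
    k <- k + 2
  }
  mesh(V, F)
}

ball_mask <- function(radius, spacing = 1, pad = 2) {
  half <- radius + pad
  n <- 2 * ceiling(half / spacing) + 1
  g <- grid_spec(rep(n, 3), rep(spacing, 3),
                 origin = rep(-(n - 1) / 2 * spacing, 3))
  make_primitive("ball", g, center = c(0, 0, 0), radius = radius)
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}

# small shared phantom on a coarse grid (kept cheap; built once per run)
small_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_mandible_phantom(
        grid = default_phantom_grid(spacing = c(0.5, 0.5, 1)), seed = 1)
    cache
  }
})
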