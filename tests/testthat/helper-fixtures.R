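# Fixture builders shared across the suite. Everything is generated in code;
# no binary data ships with the package.

# minimal hand-built track table: one dc candidate, optional references
toy_tracks <- function(positions, frame_interval = 20, cell_class = "dc_candidate",
                       id = "t1") {
  n <- nrow(positions)
  track_table(data.frame(
    track_id = id, frame = 0:(n - 1), time_min = (0:(n - 1)) * frame_interval,
    x_um = positions[, 1], y_um = positions[, 2], z_um = positions[, 3],
    cell_class = cell_class, stringsAsFactors = FALSE))
}

bind_tracks <- function(...) {
  track_table(do.call(rbind, lapply(list(...), as.data.frame)))
}

# scene with explicitly placed cells
toy_scene <- function(pos, markers = NULL, regions = list(), references = list()) {
  cells <- data.frame(id = sprintf("c%03d", seq_len(nrow(pos))),
                      x_um = pos[, 1], y_um = pos[, 2], z_um = pos[, 3],
                      stringsAsFactors = FALSE)
  if (!is.null(markers)) for (nm in names(markers)) cells[[nm]] <- markers[[nm]]
  scene_frame(cells, regions = regions, references = references)
}

row_norms <- function(m) sqrt(rowSums(m^2))

# n uniform points in a ball of radius r about the origin
runif_pts <- function(n, r) {
  d <- matrix(rnorm(3 * n), ncol = 3)
  d <- d / sqrt(rowSums(d^2))
  d * r * runif(n)^(1 / 3)
}

# digital ball mask (z,y,x array), radius in voxels
digital_ball <- function(r, pad = 4L) {
  n <- 2L * r + 2L * pad + 1L
  cc <- (n + 1) / 2
  idx <- expand.grid(z = 1:n, y = 1:n, x = 1:n)
  array((idx$x - cc)^2 + (idx$y - cc)^2 + (idx$z - cc)^2 <= r^2, dim = c(n, n, n))
}

# digital axis-aligned ellipsoid with semi-axes (in voxels) a (x), b (y), c (z)
digital_ellipsoid <- function(a, b, c3, pad = 4L) {
  nx <- 2L * ceiling(a) + 2L * pad + 1L
  ny <- 2L * ceiling(b) + 2L * pad + 1L
  nz <- 2L * ceiling(c3) + 2L * pad + 1L
  idx <- expand.grid(z = 1:nz, y = 1:ny, x = 1:nx)
  array(((idx$x - (nx + 1) / 2) / a)^2 + ((idx$y - (ny + 1) / 2) / b)^2 +
          ((idx$z - (nz + 1) / 2) / c3)^2 <= 1, dim = c(nz, ny, nx))
}

# analytic surface area of an axis-aligned ellipsoid with semi-axes a >= b = c
# (prolate spheroid closed form; a == b == c handled as sphere)
prolate_area <- function(a, c3) {
  # semi-axes (c3, c3, a), a > c3
  if (abs(a - c3) < 1e-12) return(4 * pi * a^2)
  e <- sqrt(1 - c3^2 / a^2)
  2 * pi * c3^2 * (1 + a / (c3 * e) * asin(e))
}

expect_equal_num <- function(object, expected, tol = 1e-9) {
  expect_equal(object, expected, tolerance = tol)
}
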