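# Drift correction, escape angles, and per-track motility metrics.

test_that("escape_angle matches hand-evaluated cases and the arccos formula", {
  expect_equal(escape_angle(c(0, 0, 0), c(5, 0, 0), c(20, 0, 0)), 0)
  expect_equal(escape_angle(c(0, 0, 0), c(0, 5, 0), c(20, 0, 0)), 90)
  expect_equal(escape_angle(c(0, 0, 0), c(-5, 0, 0), c(20, 0, 0)), 180)
  expect_equal(escape_angle(c(0, 0, 0), c(3, 3, 0), c(10, 0, 0)), 45)
  expect_error(escape_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)), "zero net")
  expect_error(escape_angle(c(0, 0, 0), c(1, 0, 0), c(0, 0, 0)), "centre")

  # brute-force arccos oracle on random triples
  set.seed(11)
  for (i in 1:500) {
    s <- rnorm(3); e <- rnorm(3); ctr <- rnorm(3)
    a <- e - s; b <- ctr - s
    expected <- acos(sum(a * b) / sqrt(sum(a^2) * sum(b^2))) * 180 / pi
    expect_equal(escape_angle(s, e, ctr), expected, tolerance = 1e-9)
  }
})

test_that("track metrics reproduce the hand-computed 3-point example", {
  tr <- toy_tracks(rbind(c(0, 0, 0), c(3, 0, 0), c(3, 4, 0)))
  m <- compute_track_metrics(tr, center = c(100, 0, 0))
  expect_equal(m$track_length_um, 7)
  expect_equal(m$displacement_um, 5)
  expect_equal(m$duration_min, 40)
  expect_equal(m$velocity_um_min, 0.175)
  expect_equal(m$net_velocity_um_min, 0.125)
  expect_equal(m$straightness, 5 / 7)
})

test_that("straightness is 1 for single segments and 0 for closed loops", {
  single <- compute_track_metrics(toy_tracks(rbind(c(0, 0, 0), c(2, 2, 1))),
                                  center = c(50, 0, 0))
  expect_identical(single$straightness, 1)
  loop <- compute_track_metrics(
    toy_tracks(rbind(c(0, 0, 0), c(5, 0, 0), c(5, 5, 0), c(0, 0, 0))),
    center = c(50, 0, 0))
  expect_identical(loop$straightness, 0)
  expect_true(is.na(loop$escape_angle_deg))
})

test_that("velocity >= net velocity on every simulated track", {
  sim <- simulate_condensation(simulation_config("migration", n_cells = 200,
                                                 n_frames = 15, seed = 3))
  m <- compute_track_metrics(sim$tracks, sim$config$dc_center)
  expect_true(all(m$velocity_um_min >= m$net_velocity_um_min - 1e-12))
  expect_true(all(m$straightness >= 0 & m$straightness <= 1 + 1e-12))
})

test_that("metrics are invariant to global rigid motions", {
  sim <- simulate_condensation(simulation_config("null", n_cells = 60,
                                                 n_frames = 10, seed = 5))
  ctr <- sim$config$dc_center
  m0 <- compute_track_metrics(sim$tracks, ctr)
  # rotation about z by 37 degrees plus a translation, applied to everything
  th <- 37 * pi / 180
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  shift <- c(12, -7, 3)
  tr <- sim$tracks
  pos <- as.matrix(tr[, c("x_um", "y_um", "z_um")]) %*% t(R)
  tr$x_um <- pos[, 1] + shift[1]; tr$y_um <- pos[, 2] + shift[2]
  tr$z_um <- pos[, 3] + shift[3]
  m1 <- compute_track_metrics(tr, as.numeric(R %*% ctr) + shift)
  for (col in c("track_length_um", "displacement_um", "velocity_um_min",
                "net_velocity_um_min", "straightness", "escape_angle_deg",
                "initial_distance_um")) {
    expect_equal(m1[[col]], m0[[col]], tolerance = 1e-9)
  }
})

test_that("drift correction recovers hand-computed reference means", {
  # two references with unequal drifts: correction is their mean displacement
  r1 <- toy_tracks(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                   cell_class = "reference", id = "r1")
  r2 <- toy_tracks(rbind(c(10, 0, 0), c(10, 2, 0), c(10, 4, 0)),
                   cell_class = "reference", id = "r2")
  cell <- toy_tracks(rbind(c(5, 5, 5), c(5, 5, 5), c(5, 5, 5)), id = "c1")
  tab <- bind_tracks(r1, r2, cell)
  corrected <- suppressWarnings(correct_drift(tab))
  cellrows <- corrected[corrected$track_id == "c1", ]
  # mean displacement at frame 1: ((1,0,0) + (0,2,0))/2 = (0.5, 1, 0)
  expect_equal(as.numeric(cellrows[2, c("x_um", "y_um", "z_um")]),
               c(5 - 0.5, 5 - 1, 5))
  expect_equal(as.numeric(cellrows[3, c("x_um", "y_um", "z_um")]),
               c(5 - 1, 5 - 2, 5))
})

test_that("stationary references leave tracks untouched and errors are informative", {
  r1 <- toy_tracks(rbind(c(0, 0, 0), c(0, 0, 0)), cell_class = "reference", id = "r1")
  cell <- toy_tracks(rbind(c(1, 2, 3), c(4, 5, 6)), id = "c1")
  tab <- bind_tracks(r1, cell)
  out <- suppressWarnings(correct_drift(tab))
  expect_equal(as.data.frame(out), as.data.frame(tab))
  expect_warning(correct_drift(tab), "7")
  expect_error(correct_drift(cell), "no reference")
  gap <- track_table(data.frame(track_id = "rg", frame = c(0L, 2L),
                                time_min = c(0, 40), x_um = 0, y_um = 0, z_um = 0,
                                cell_class = "reference"))
  expect_error(suppressWarnings(correct_drift(bind_tracks(gap, cell))), "rg")
})

test_that("inject_drift then correct_drift is the identity", {
  sim <- simulate_condensation(simulation_config("null", n_cells = 40,
                                                 n_frames = 12, seed = 8))
  drifted <- inject_drift(sim$tracks, c(1.5, -0.75, 0.25))
  restored <- correct_drift(drifted)
  for (col in c("x_um", "y_um", "z_um")) {
    expect_lt(max(abs(restored[[col]] - sim$tracks[[col]])), 1e-9)
  }
  # zero drift is the identity
  expect_equal(as.data.frame(inject_drift(sim$tracks, c(0, 0, 0))),
               as.data.frame(sim$tracks))
  # frame 5 shifted by exactly 5 um under unit x drift
  d <- inject_drift(sim$tracks, c(1, 0, 0))
  at5 <- d$frame == 5
  expect_equal(d$x_um[at5], sim$tracks$x_um[at5] + 5)
})

test_that("grouping splits at 30 um with the boundary assigned to near", {
  mk <- function(id, dist, cls = "dc_candidate") {
    data.frame(track_id = id, cell_class = cls, group = NA,
               track_length_um = 1, displacement_um = 1, duration_min = 20,
               velocity_um_min = 1, net_velocity_um_min = 1, straightness = 1,
               escape_angle_deg = 10, escape_angle_xy_deg = 10,
               initial_distance_um = dist, truncated_at_entry = FALSE)
  }
  m <- do.call(rbind, list(mk("a", 30), mk("b", 30.0001), mk("c", 12),
                           mk("d", 55), mk("e", 40, "interfollicular")))
  class(m) <- c("trajectory_metrics", class(m))
  g <- group_by_initial_distance(m, 30)
  expect_setequal(g$dc_near$track_id, c("a", "c"))
  expect_setequal(g$dc_far$track_id, c("b", "d"))
  expect_identical(g$interfollicular$track_id, "e")
  # exhaustive + disjoint, counts match a brute-force recount
  expect_equal(sum(vapply(g, nrow, integer(1))), nrow(m))
  set.seed(21)
  dists <- runif(200, 0, 80)
  m2 <- do.call(rbind, lapply(seq_along(dists), function(i) mk(paste0("t", i), dists[i])))
  class(m2) <- c("trajectory_metrics", class(m2))
  g2 <- group_by_initial_distance(m2, 30)
  expect_equal(nrow(g2$dc_far), sum(dists > 30))
  expect_equal(nrow(g2$dc_near), sum(dists <= 30))
})

test_that("entry truncation shortens tracks, never lengthens, and is a no-op at radius 0", {
  sim <- simulate_condensation(simulation_config("migration", n_cells = 300,
                                                 n_frames = 25, seed = 13))
  ctr <- sim$config$dc_center
  whole <- compute_track_metrics(sim$tracks, ctr, truncate = FALSE)
  cut <- compute_track_metrics(sim$tracks, ctr, truncate = TRUE, entry_radius = 15)
  shared <- intersect(whole$track_id, cut$track_id)
  expect_true(all(cut$duration_min[match(shared, cut$track_id)] <=
                  whole$duration_min[match(shared, whole$track_id)] + 1e-12))
  expect_true(any(cut$truncated_at_entry))
  nothing <- compute_track_metrics(sim$tracks, ctr, truncate = TRUE, entry_radius = 0)
  expect_equal(nothing$duration_min, whole$duration_min)
  # truncated far cells end near the entry sphere: displacement consistent
  tcut <- cut[cut$truncated_at_entry & cut$group == "dc_far", ]
  expect_true(all(tcut$initial_distance_um > 15))
})

test_that("dc centre estimate sits near the true simulated centre", {
  sim <- simulate_condensation(simulation_config("migration", seed = 2))
  est <- estimate_dc_center(sim$tracks)
  expect_lt(sqrt(sum((est - sim$config$dc_center)^2)), 10)
})
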