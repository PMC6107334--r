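# The agent-based condensation simulator and the scene/volume generators.

test_that("identical configs give bit-identical outputs", {
  cfg <- simulation_config("migration", n_cells = 80, n_frames = 10, seed = 99)
  a <- simulate_condensation(cfg)
  b <- simulate_condensation(cfg)
  expect_identical(as.data.frame(a$tracks), as.data.frame(b$tracks))
  expect_identical(a$scenes[[1]]$cells, b$scenes[[1]]$cells)
  cfg2 <- simulation_config("migration", n_cells = 80, n_frames = 10, seed = 100)
  expect_false(identical(as.data.frame(simulate_condensation(cfg2)$tracks),
                         as.data.frame(a$tracks)))
})

test_that("config invariants are enforced", {
  expect_error(simulation_config(n_frames = 1), "n_frames")
  expect_error(simulation_config(dc_radius = 40, domain_extent = c(60, 100, 100)),
               "dc_radius")
  expect_error(simulation_config(dc_center = c(-5, 10, 10)), "outside")
  expect_error(simulation_config(label_fraction = 1.5), "fractions")
  expect_error(simulation_config(bias_kappa = -1), ">= 0")
})

test_that("cell count is conserved outside proliferation mode", {
  for (mode in c("null", "migration", "nondispersal")) {
    cfg <- simulation_config(mode, n_cells = 70, n_frames = 8,
                             n_reference_cells = 5, seed = 4)
    tr <- simulate_condensation(cfg)$tracks
    last <- tr[tr$frame == max(tr$frame), ]
    expect_equal(nrow(last), 75)
    expect_equal(length(unique(tr$track_id)), 75)
  }
  # proliferation adds suffixed daughter tracks
  cfgp <- simulation_config("proliferation", n_cells = 400, n_frames = 20, seed = 4)
  trp <- simulate_condensation(cfgp)$tracks
  ids <- unique(trp$track_id)
  daughters <- grep("^cell_[0-9]+[a-z]", ids, value = TRUE)
  expect_gt(length(daughters), 0)
  expect_true(all(vapply(daughters, function(d)
    sub("[a-z]+$", "", d) %in% ids, logical(1))))
})

test_that("null-mode escape angles follow the uniform-on-sphere null", {
  cfg <- simulation_config("null", n_cells = 500, n_frames = 40, seed = 17)
  sim <- simulate_condensation(cfg)
  m <- compute_track_metrics(sim$tracks, cfg$dc_center)
  far <- m[m$initial_distance_um > 30 & m$cell_class == "dc_candidate", ]
  med <- median(far$escape_angle_deg, na.rm = TRUE)
  # isotropic directions against a fixed axis have median angle 90 deg;
  # allow Monte-Carlo error plus the small wall-reflection bias
  expect_gt(med, 75)
  expect_lt(med, 105)
})

test_that("single biased steps reproduce the von Mises-Fisher cosine mean", {
  # independent check of the step model: for one frame, the mean cosine of
  # the step direction against the inward axis is coth(k) - 1/k
  kappa <- 8
  cfg <- simulation_config("migration", n_cells = 400, n_frames = 2,
                           bias_kappa = kappa, recruitment_radius = 1000,
                           density_contrast = 1, seed = 23)
  sim <- simulate_condensation(cfg)
  tr <- sim$tracks[sim$tracks$cell_class == "dc_candidate", ]
  tr <- tr[order(tr$track_id, tr$frame), ]
  p0 <- as.matrix(tr[tr$frame == 0, c("x_um", "y_um", "z_um")])
  p1 <- as.matrix(tr[tr$frame == 1, c("x_um", "y_um", "z_um")])
  d0 <- row_norms(sweep(p0, 2, cfg$dc_center))
  outside <- d0 > cfg$dc_radius + 10   # exclude trap/reflection edge cases
  step <- p1[outside, ] - p0[outside, ]
  toctr <- sweep(p0[outside, , drop = FALSE], 2, cfg$dc_center) * -1
  cosang <- rowSums(step * toctr) / (row_norms(step) * row_norms(toctr))
  expected <- 1 / tanh(kappa) - 1 / kappa
  expect_equal(mean(cosang), expected, tolerance = 0.05)
})

test_that("migration mode biases far cells inward and beats the null by Watson U2", {
  cfg <- simulation_config("migration", n_cells = 400, n_frames = 30, seed = 31)
  sim <- simulate_condensation(cfg)
  m <- compute_track_metrics(sim$tracks, cfg$dc_center)
  far <- m[m$group == "dc_far", ]
  expect_lt(median(far$escape_angle_deg, na.rm = TRUE), 30)
  # against a null-mode cohort
  cfg0 <- simulation_config("null", n_cells = 400, n_frames = 30, seed = 32)
  m0 <- compute_track_metrics(simulate_condensation(cfg0)$tracks, cfg0$dc_center)
  far0 <- m0[m0$group == "dc_far", ]
  w <- watson_u2_test(angle_sample(far$escape_angle_xy_deg[!is.na(far$escape_angle_xy_deg)]),
                      angle_sample(far0$escape_angle_xy_deg[!is.na(far0$escape_angle_xy_deg)]),
                      n_permutations = 499, seed = 1)
  expect_lt(w$p_value, 0.05)
})

test_that("cycle labels follow configured fractions and divisions mark S/G2/M", {
  cfg <- simulation_config("migration", n_cells = 800, n_frames = 25, seed = 41)
  sim <- simulate_condensation(cfg)
  last <- sim$tracks[sim$tracks$frame == max(sim$tracks$frame) &
                       sim$tracks$cell_class != "reference", ]
  d <- sqrt((last$x_um - cfg$dc_center[1])^2 + (last$y_um - cfg$dc_center[2])^2 +
              (last$z_um - cfg$dc_center[3])^2)
  inside <- d <= cfg$dc_radius
  expect_gt(mean(last$fucci_g1[inside]), 0.85)     # ~0.95 configured
  expect_lt(mean(last$fucci_g1[!inside]), 0.6)     # ~0.50 configured
  # proliferation mode: S/G2/M fraction inside exceeds outside
  cfgp <- simulation_config("proliferation", n_cells = 1200, n_frames = 30, seed = 42)
  simp <- simulate_condensation(cfgp)
  lastp <- simp$tracks[simp$tracks$frame == max(simp$tracks$frame) &
                         simp$tracks$cell_class != "reference", ]
  dp <- sqrt((lastp$x_um - cfgp$dc_center[1])^2 + (lastp$y_um - cfgp$dc_center[2])^2 +
               (lastp$z_um - cfgp$dc_center[3])^2)
  expect_gt(mean(lastp$fucci_sgm[dp <= cfgp$dc_radius]),
            mean(lastp$fucci_sgm[dp > cfgp$dc_radius]))
  expect_true(all(lastp$fucci_sgm[lastp$edu]))
})

test_that("reference cells are exactly stationary before drift injection", {
  cfg <- simulation_config("null", n_cells = 30, n_frames = 12,
                           n_reference_cells = 9, seed = 6)
  tr <- simulate_condensation(cfg)$tracks
  refs <- tr[tr$cell_class == "reference", ]
  for (id in unique(refs$track_id)) {
    one <- refs[refs$track_id == id, ]
    expect_equal(var(one$x_um) + var(one$y_um) + var(one$z_um), 0)
  }
  # with drift, references move exactly with the drift
  cfgd <- simulation_config("null", n_cells = 30, n_frames = 12,
                            n_reference_cells = 9,
                            drift_per_frame = c(0.5, 0, -0.2), seed = 6)
  trd <- simulate_condensation(cfgd)$tracks
  refd <- trd[trd$cell_class == "reference" & trd$track_id == "ref_01", ]
  refd <- refd[order(refd$frame), ]
  expect_equal(diff(refd$x_um), rep(0.5, 11))
  expect_equal(diff(refd$z_um), rep(-0.2, 11))
})

test_that("generated scenes honour densities, markers and clustering", {
  d0 <- 10
  spec <- scene_spec(list(
    dc = list(shape = region_sphere(c(60, 60, 60), 30),
              density_per_1e4_um3 = 2 * d0,
              marker_fractions = list(lab = 0.5)),
    ifc = list(shape = region_box(c(150, 0, 0), c(350, 200, 200)),
               density_per_1e4_um3 = d0,
               marker_fractions = list(lab = 0.5))), seed = 77)
  sc <- generate_point_scene(spec)
  dens <- region_density(sc)
  ratio <- dens$density_per_1e4_um3[dens$region == "dc"] /
    dens$density_per_1e4_um3[dens$region == "ifc"]
  expect_equal(ratio, 2, tolerance = 0.25)
  # marker fraction 0 -> no positives
  spec0 <- scene_spec(list(dc = list(shape = region_sphere(c(0, 0, 0), 30),
                                     density_per_1e4_um3 = 10,
                                     marker_fractions = list(lab = 0))), seed = 1)
  expect_false(any(generate_point_scene(spec0)$cells$lab))
  # clustering raises the labelled-neighbour proportion above the fraction
  mk_prop <- function(clust, seed) {
    sp <- scene_spec(list(dc = list(shape = region_sphere(c(0, 0, 0), 40),
                                    density_per_1e4_um3 = 15,
                                    marker_fractions = list(lab = 0.3, pool = 1))),
                     label_clustering = clust, seed = seed)
    nb <- nearest_neighbor_labels(generate_point_scene(sp), "pool", "pool", "lab")
    nb$summary$prop_labeled_neighbor - nb$summary$expected_prop
  }
  excess_rand <- mean(vapply(1:15, function(s) mk_prop(0, s), numeric(1)))
  excess_clus <- mean(vapply(1:15, function(s) mk_prop(0.9, s), numeric(1)))
  expect_lt(abs(excess_rand), 0.06)
  expect_gt(excess_clus, 0.15)
})

test_that("low-density regions warn rather than error", {
  spec <- scene_spec(list(tiny = list(shape = region_sphere(c(0, 0, 0), 3),
                                      density_per_1e4_um3 = 0.1)), seed = 2)
  expect_warning(generate_point_scene(spec), "< 1")
})
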