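# Density, shells, surface distances, nearest neighbours, label fractions.

test_that("region density reproduces a constructed 2:1 contrast and edge cases", {
  dc <- region_sphere(c(0, 0, 0), 20)
  ifc <- region_sphere(c(100, 0, 0), 20)
  set.seed(2)
  in_dc <- sweep(runif_pts(60, 20), 2, c(0, 0, 0), `+`)
  in_if <- sweep(runif_pts(30, 20), 2, c(100, 0, 0), `+`)
  sc <- toy_scene(rbind(in_dc, in_if),
                  regions = list(dc = dc, interfollicular = ifc,
                                 empty = region_sphere(c(-100, 0, 0), 10)))
  d <- region_density(sc)
  expect_equal(d$count[d$region == "dc"], 60)
  expect_equal(d$count[d$region == "interfollicular"], 30)
  expect_equal(d$count[d$region == "empty"], 0)
  expect_equal(d$density_per_1e4_um3[d$region == "empty"], 0)
  r <- attr(d, "ratios")
  expect_equal(r$ratio[r$numerator == "dc" & r$denominator == "interfollicular"], 2)
  expect_error(region_density(sc, character(0)), "no regions")
  expect_error(region_density(sc, "nope"), "unknown region")
})

test_that("paired clone mode compares identical volumes", {
  sc <- toy_scene(matrix(runif(300, 0, 50), ncol = 3),
                  regions = list(dc = region_sphere(c(25, 25, 25), 10)))
  sc2 <- clone_region_at(sc, "dc", c(30, 0, 0), "if_control")
  d <- region_density(sc2, c("dc", "if_control"))
  expect_equal(d$volume_um3[1], d$volume_um3[2])
  expect_equal(sc2$regions$if_control$center, c(55, 25, 25))
})

test_that("region_density is invariant to rigid motion of cells and regions", {
  set.seed(9)
  pos <- matrix(runif(150, 0, 60), ncol = 3)
  reg <- region_sphere(c(30, 30, 30), 18)
  d0 <- region_density(toy_scene(pos, regions = list(r = reg)))
  th <- 0.6
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  shift <- c(5, -9, 2)
  pos2 <- sweep(pos %*% t(R), 2, shift, `+`)
  reg2 <- region_sphere(as.numeric(R %*% c(30, 30, 30)) + shift, 18)
  d1 <- region_density(toy_scene(pos2, regions = list(r = reg2)))
  expect_equal(d1$count, d0$count)
})

test_that("Poisson scenes recover the target density", {
  # estimated density within 3 SE of lambda over repeated seeds
  lambda <- 12  # cells per 1e4 um^3
  vol <- 100^3
  expected_n <- lambda * vol / 1e4
  counts <- vapply(1:100, function(s) {
    spec <- scene_spec(list(box = list(shape = region_box(c(0, 0, 0), rep(100, 3)),
                                       density_per_1e4_um3 = lambda)), seed = s)
    nrow(generate_point_scene(spec)$cells)
  }, numeric(1))
  est <- mean(counts) / vol * 1e4
  se <- sd(counts) / sqrt(length(counts)) / vol * 1e4
  expect_lt(abs(est - lambda), 3 * se + 1e-9)
})

test_that("shell densities assign boundary cells to the first shell and match a manual recount", {
  bead <- list(center = c(50, 50, 50), radius = 10)
  # hand-placed cells: on-surface, 5, 14.9, 15, 29 um from the surface (xy
  # plane through bead centre) and one far outside the outer shell
  pos <- rbind(c(60, 50, 50),     # distance 0 -> shell 1
               c(65, 50, 50),     # 5 -> shell 1
               c(50, 74.9, 50),   # 14.9 -> shell 1
               c(75, 50, 50),     # 15 -> shell 2 (right-open edges)
               c(50, 89, 50),     # 29 -> shell 2
               c(95, 50, 50))     # 35 -> outside
  sc <- toy_scene(pos, references = list(bead = bead))
  d <- shell_density(sc, mode = "midplane_slice", half_thickness = 0.5)
  expect_equal(d$count, c(3, 2))
  dv <- shell_density(sc, mode = "full_shell")
  expect_equal(dv$count, c(3, 2))
  # z-offset cell drops out of the midplane slice but stays in the full shell
  sc2 <- toy_scene(rbind(pos, c(60, 50, 58)), references = list(bead = bead))
  expect_equal(shell_density(sc2, mode = "midplane_slice")$count, c(3, 2))
  expect_equal(shell_density(sc2, mode = "full_shell")$count, c(4, 2))
  expect_error(shell_density(toy_scene(pos)), "bead")
  expect_error(shell_density(sc, shell_edges = c(5, 10)), "start at 0")
})

test_that("uniform scenes have equal shell densities within sampling error", {
  set.seed(14)
  pos <- matrix(runif(3 * 8000, 0, 120), ncol = 3)
  sc <- toy_scene(pos, references = list(bead = list(center = c(60, 60, 60),
                                                     radius = 8)))
  d <- shell_density(sc, mode = "full_shell", shell_edges = c(0, 12, 24))
  expect_lt(abs(d$density_per_1e4_um3[1] / d$density_per_1e4_um3[2] - 1), 0.35)
})

test_that("distances to meshes, masks and points are correct", {
  mesh <- sphere_mesh(center = c(10, 10, 10), radius = 5, subdivisions = 3L)
  # point on the surface
  expect_lt(distances_to_surface(c(15, 10, 10), mesh), 0.02)
  # outside point at distance d from the sphere: |p - c| = r + d
  expect_equal(distances_to_surface(c(18, 10, 10), mesh), 3, tolerance = 0.02)
  # brute-force per-triangle scalar oracle on random points
  set.seed(6)
  pts <- matrix(runif(30, 0, 20), ncol = 3)
  fast <- distances_to_surface(pts, mesh)
  slow <- vapply(seq_len(nrow(pts)), function(i) {
    p <- pts[i, ]
    min(vapply(seq_len(nrow(mesh$faces)), function(f) {
      tri <- mesh$vertices[mesh$faces[f, ], ]
      # project on plane, clamp to edges
      e0 <- tri[2, ] - tri[1, ]; e1 <- tri[3, ] - tri[1, ]
      nrm <- c(e0[2] * e1[3] - e0[3] * e1[2], e0[3] * e1[1] - e0[1] * e1[3],
               e0[1] * e1[2] - e0[2] * e1[1])
      seg <- function(A, B) {
        t <- max(0, min(1, sum((p - A) * (B - A)) / sum((B - A)^2)))
        sqrt(sum((A + t * (B - A) - p)^2))
      }
      dmin <- min(seg(tri[1, ], tri[2, ]), seg(tri[1, ], tri[3, ]),
                  seg(tri[2, ], tri[3, ]))
      # interior candidate via barycentric solve
      M <- cbind(e0, e1)
      st <- tryCatch(solve(crossprod(M), crossprod(M, p - tri[1, ])),
                     error = function(e) NULL)
      if (!is.null(st) && st[1] >= 0 && st[2] >= 0 && sum(st) <= 1) {
        q <- tri[1, ] + st[1] * e0 + st[2] * e1
        dmin <- min(dmin, sqrt(sum((q - p)^2)))
      }
      dmin
    }, numeric(1)))
  }, numeric(1))
  expect_equal(fast, slow, tolerance = 1e-9)
  # point-target variant
  expect_equal(distances_to_surface(rbind(c(0, 0, 0), c(3, 4, 0)), c(0, 0, 0)),
               c(0, 5))
  # mask variant: flat slab surface at known depth
  vox <- array(0L, dim = c(20, 20, 20))
  vox[1:5, , ] <- 1L
  lv <- label_volume(vox, c(1, 1, 1))
  d <- distances_to_surface(c(10.5, 10.5, 10.5), lv)
  expect_equal(d, 10.5 - 4.5, tolerance = 1e-9)
})

test_that("nearest-neighbour labelling follows ids, ties and the random expectation", {
  # three collinear cells at x = 0, 1, 10; first two labelled
  sc <- toy_scene(rbind(c(0, 0, 0), c(1, 0, 0), c(10, 0, 0)),
                  markers = list(pool = c(TRUE, TRUE, TRUE),
                                 lab = c(TRUE, TRUE, FALSE)))
  nb <- nearest_neighbor_labels(sc, "pool", "pool", "lab")
  expect_equal(nb$summary$n_focal, 2)
  first <- nb$per_focal[nb$per_focal$focal_id == "c001", ]
  expect_equal(first$neighbor_id, "c002")
  expect_true(first$neighbor_labeled)
  expect_equal(first$neighbor_distance_um, 1)
  # all cells labelled: proportion and expectation are both 1
  sc2 <- toy_scene(matrix(runif(60, 0, 30), ncol = 3),
                   markers = list(pool = rep(TRUE, 20), lab = rep(TRUE, 20)))
  nb2 <- nearest_neighbor_labels(sc2, "pool", "pool", "lab")
  expect_equal(nb2$summary$prop_labeled_neighbor, 1)
  expect_equal(nb2$summary$expected_prop, 1)
  # exact tie broken toward the lowest id and counted
  sc3 <- toy_scene(rbind(c(0, 0, 0), c(2, 0, 0), c(-2, 0, 0)),
                   markers = list(pool = rep(TRUE, 3), lab = c(TRUE, FALSE, TRUE)))
  nb3 <- nearest_neighbor_labels(sc3, "pool", "pool", "lab")
  row1 <- nb3$per_focal[nb3$per_focal$focal_id == "c001", ]
  expect_equal(row1$neighbor_id, "c002")
  expect_gte(nb3$summary$n_ties, 1)
  # removing cells outside the pool never changes results
  sc4 <- toy_scene(rbind(c(0, 0, 0), c(1, 0, 0), c(10, 0, 0), c(0.2, 0, 0)),
                   markers = list(pool = c(TRUE, TRUE, TRUE, FALSE),
                                  lab = c(TRUE, TRUE, FALSE, FALSE)))
  nb4 <- nearest_neighbor_labels(sc4, "pool", "pool", "lab")
  expect_equal(nb4$per_focal$neighbor_id, nb$per_focal$neighbor_id)
})

test_that("random assortment gives labelled-neighbour proportions near the label fraction", {
  p_lab <- 0.65
  props <- vapply(1:200, function(s) {
    spec <- scene_spec(list(dc = list(shape = region_sphere(c(0, 0, 0), 25),
                                      density_per_1e4_um3 = 30,
                                      marker_fractions = list(lab = p_lab, pool = 1))),
                       seed = 2000 + s)
    sc <- generate_point_scene(spec)
    nb <- tryCatch(nearest_neighbor_labels(sc, "pool", "pool", "lab"),
                   error = function(e) NULL)
    if (is.null(nb)) NA_real_ else nb$summary$prop_labeled_neighbor
  }, numeric(1))
  expect_lt(abs(mean(props, na.rm = TRUE) - p_lab), 0.03)
})

test_that("chi-square randomness test matches the hand-computed statistic", {
  r <- neighbor_randomness_test(list(observed_labeled = 90, n = 100,
                                     expected_prop = 0.5))
  expect_equal(r$statistic, 64)
  expect_lt(r$p_value, 1e-10)
  r0 <- neighbor_randomness_test(list(observed_labeled = 50, n = 100,
                                      expected_prop = 0.5))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  expect_error(neighbor_randomness_test(list(observed_labeled = 5, n = 10,
                                             expected_prop = 0)), "degenerate")
})

test_that("label fractions reproduce the lineage-labelling worked example", {
  lf <- label_fraction(53, 82)
  expect_equal(lf$percent, 100 * 53 / 82)
  expect_equal(round(lf$percent), 65)
  z <- label_fraction(0, 25)
  expect_equal(z$percent, 0)
  expect_equal(z$ci[1], 0)
  expect_error(label_fraction(5, 0), "positive")
})

test_that("four-way Fucci scoring partitions to 1 on a constructed scene", {
  sc <- toy_scene(matrix(runif(120, 0, 40), ncol = 3),
                  markers = list(fucci_g1 = rep(c(TRUE, TRUE, FALSE, FALSE), 10),
                                 fucci_sgm = rep(c(FALSE, TRUE, TRUE, FALSE), 10)))
  fr <- fucci_fractions(sc)
  expect_equal(sum(fr), 1)
  expect_equal(as.numeric(fr), rep(0.25, 4), ignore_attr = TRUE)
  expect_equal(attr(fr, "n"), 40)
})
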