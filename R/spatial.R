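#' Cell density per region
#'
#' Counts cells (optionally only those bearing `marker_filter`) whose
#' positions fall inside each named region (closed boundaries) and reports
#' densities in cells per 1e4 um^3 together with all pairwise ratios.
#' When a condensate region is compared with an interfollicular control, use
#' [clone_region_at()] first so both use identical volumes.
#'
#' @param scene a `scene_frame`.
#' @param region_names regions to measure (default: all).
#' @param marker_filter optional marker column name; only positive cells count.
#' @return a `density_report` data.frame with attribute `ratios`.
#' @export
region_density <- function(scene, region_names = names(scene$regions),
                           marker_filter = NULL) {
  stopifnot(inherits(scene, "scene_frame"))
  if (!length(region_names)) stopf("no regions to measure")
  missing_r <- setdiff(region_names, names(scene$regions))
  if (length(missing_r)) stopf("unknown region(s): %s", paste(missing_r, collapse = ", "))
  cells <- scene$cells
  if (!is.null(marker_filter)) {
    if (!marker_filter %in% names(cells)) stopf("marker '%s' not present", marker_filter)
    cells <- cells[cells[[marker_filter]], , drop = FALSE]
  }
  pts <- as.matrix(cells[, c("x_um", "y_um", "z_um"), drop = FALSE])
  rows <- lapply(region_names, function(nm) {
    reg <- scene$regions[[nm]]
    vol <- region_volume(reg)
    if (vol <= 0) stopf("region '%s' has zero volume", nm)
    cnt <- if (nrow(pts)) sum(points_in_region(pts, reg)) else 0L
    data.frame(region = nm, count = cnt, volume_um3 = vol,
               density_per_1e4_um3 = cnt / vol * 1e4, stringsAsFactors = FALSE)
  })
  rep_df <- do.call(rbind, rows)
  ratios <- NULL
  if (nrow(rep_df) > 1) {
    cmb <- utils::combn(nrow(rep_df), 2)
    ratios <- data.frame(
      numerator = rep_df$region[cmb[1, ]],
      denominator = rep_df$region[cmb[2, ]],
      ratio = rep_df$density_per_1e4_um3[cmb[1, ]] /
              rep_df$density_per_1e4_um3[cmb[2, ]],
      stringsAsFactors = FALSE)
  }
  attr(rep_df, "ratios") <- ratios
  class(rep_df) <- unique(c("density_report", class(rep_df)))
  rep_df
}

#' Clone a region shape at an offset for paired density comparisons
#'
#' Adds a translated copy of an existing region to the scene, so a condensate
#' volume can be compared with an interfollicular control of identical shape
#' and volume.
#'
#' @param scene a `scene_frame`.
#' @param region_name region to clone.
#' @param offset xyz translation, um.
#' @param new_name name of the clone.
#' @return the scene with the added region.
#' @export
clone_region_at <- function(scene, region_name, offset, new_name) {
  stopifnot(inherits(scene, "scene_frame"))
  if (!region_name %in% names(scene$regions)) stopf("unknown region '%s'", region_name)
  if (new_name %in% names(scene$regions)) stopf("region '%s' already exists", new_name)
  scene$regions[[new_name]] <- translate_region(scene$regions[[region_name]], offset)
  scene
}

#' Radial cell density in shells around a bead
#'
#' Distances are measured from the bead surface (not its centre). In
#' `midplane_slice` mode only cells within `half_thickness` of the bead's
#' equatorial plane are counted and areal densities (cells per 1e4 um^2) are
#' reported, emulating quantification on a single optical slice at mid-bead;
#' `full_shell` reports volumetric densities over entire spherical shells.
#' A cell exactly on the bead surface (distance 0) is assigned to the first
#' shell; shells are \[e_i, e_{i+1}) with the last edge inclusive.
#'
#' @param scene a `scene_frame`.
#' @param bead list with `center` (xyz um) and `radius` (um); defaults to
#'   `scene$references$bead`.
#' @param shell_edges increasing distances from the bead surface, starting
#'   at 0 (default `c(0, 15, 30)`).
#' @param mode `"midplane_slice"` (default) or `"full_shell"`.
#' @param half_thickness half slice thickness, um (default 0.5: one
#'   confocal z-step).
#' @param marker_filter optional marker restriction.
#' @return a `density_report` data.frame (one row per shell).
#' @export
shell_density <- function(scene, bead = NULL, shell_edges = c(0, 15, 30),
                          mode = c("midplane_slice", "full_shell"),
                          half_thickness = 0.5, marker_filter = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(scene, "scene_frame"))
  bead <- bead %||% scene$references$bead
  if (is.null(bead)) stopf("no bead in scene references and none supplied")
  if (length(shell_edges) < 2 || shell_edges[1] != 0 ||
      any(diff(shell_edges) <= 0)) {
    stopf("shell_edges must be strictly increasing and start at 0")
  }
  cells <- scene$cells
  if (!is.null(marker_filter)) cells <- cells[cells[[marker_filter]], , drop = FALSE]
  pts <- as.matrix(cells[, c("x_um", "y_um", "z_um"), drop = FALSE])
  ctr <- as.numeric(bead$center)
  r0 <- bead$radius
  if (mode == "midplane_slice") {
    keep <- abs(pts[, 3] - ctr[3]) <= half_thickness
    pts <- pts[keep, , drop = FALSE]
    d <- sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2) - r0
  } else {
    d <- vec_norm(sweep(pts, 2, ctr)) - r0
  }
  d <- pmax(d, 0)
  ne <- length(shell_edges) - 1L
  rows <- lapply(seq_len(ne), function(i) {
    lo <- shell_edges[i]; hi <- shell_edges[i + 1]
    inshell <- if (i == ne) d >= lo & d <= hi else d >= lo & d < hi
    if (mode == "midplane_slice") {
      size <- pi * ((r0 + hi)^2 - (r0 + lo)^2)
      data.frame(region = sprintf("shell_%g_%g", lo, hi), count = sum(inshell),
                 area_um2 = size, density_per_1e4_um2 = sum(inshell) / size * 1e4,
                 stringsAsFactors = FALSE)
    } else {
      size <- 4 / 3 * pi * ((r0 + hi)^3 - (r0 + lo)^3)
      data.frame(region = sprintf("shell_%g_%g", lo, hi), count = sum(inshell),
                 volume_um3 = size, density_per_1e4_um3 = sum(inshell) / size * 1e4,
                 stringsAsFactors = FALSE)
    }
  })
  rep_df <- do.call(rbind, rows)
  class(rep_df) <- unique(c("density_report", class(rep_df)))
  rep_df
}

# minimum distance from one point to a set of triangles (V1/V2/V3: m x 3)
point_triangles_min_dist <- function(p, V1, V2, V3) {
  e0 <- V2 - V1
  e1 <- V3 - V1
  a <- rowSums(e0 * e0); b <- rowSums(e0 * e1); c2 <- rowSums(e1 * e1)
  det <- a * c2 - b^2
  degen <- det < 1e-300
  dp <- sweep(V1, 2, p)                          # V1 - p
  d_ <- rowSums(e0 * dp); e_ <- rowSums(e1 * dp)
  s <- (b * e_ - c2 * d_) / pmax(det, 1e-300)
  t <- (b * d_ - a * e_) / pmax(det, 1e-300)
  inside <- !degen & s >= 0 & t >= 0 & (s + t) <= 1
  seg_dist <- function(A, B) {
    ab <- B - A
    denom <- pmax(rowSums(ab * ab), 1e-300)
    tt <- pmin(1, pmax(0, (-rowSums(ab * sweep(A, 2, p))) / denom))
    q <- A + ab * tt
    sqrt((q[, 1] - p[1])^2 + (q[, 2] - p[2])^2 + (q[, 3] - p[3])^2)
  }
  dmin <- pmin(seg_dist(V1, V2), seg_dist(V1, V3), seg_dist(V2, V3))
  if (any(inside)) {
    q <- V1[inside, , drop = FALSE] + e0[inside, , drop = FALSE] * s[inside] +
      e1[inside, , drop = FALSE] * t[inside]
    dmin[inside] <- sqrt((q[, 1] - p[1])^2 + (q[, 2] - p[2])^2 + (q[, 3] - p[3])^2)
  }
  list(d = dmin, degenerate = degen)
}

#' Shortest distances from points to a surface
#'
#' Euclidean shortest distance from each point to a `triangle_mesh`
#' (point-to-triangle minimum), to a binary mask `label_volume` (distance to
#' the nearest surface-voxel centre, i.e. foreground voxels with a background
#' 6-neighbour), or to a single reference point (length-3 numeric), the
#' point-target variant used for placode-surface-centre measurements.
#'
#' @param points n x 3 matrix (or length-3 vector) of xyz positions, um.
#' @param surface a `triangle_mesh`, a `label_volume` mask, or xyz point.
#' @return numeric distances, um.
#' @export
distances_to_surface <- function(points, surface) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  if (inherits(surface, "triangle_mesh")) {
    if (!nrow(surface$faces)) stopf("surface mesh is empty")
    V1 <- surface$vertices[surface$faces[, 1], , drop = FALSE]
    V2 <- surface$vertices[surface$faces[, 2], , drop = FALSE]
    V3 <- surface$vertices[surface$faces[, 3], , drop = FALSE]
    warned <- FALSE
    out <- numeric(nrow(points))
    for (i in seq_len(nrow(points))) {
      r <- point_triangles_min_dist(points[i, ], V1, V2, V3)
      if (!warned && any(r$degenerate)) {
        warnf("%d degenerate triangle(s) skipped", sum(r$degenerate))
        warned <- TRUE
      }
      d <- r$d
      d[r$degenerate] <- Inf
      out[i] <- min(d)
    }
    return(out)
  }
  if (inherits(surface, "label_volume")) {
    v <- surface$voxels > 0
    if (!any(v)) stopf("surface mask is empty")
    d <- dim(v)
    shift_or <- function(x, s, axis) {
      out <- array(FALSE, dim = d)
      n <- d[axis]
      src <- if (s >= 0) seq_len(n - s) else seq(1 - s, n)
      dst <- if (s >= 0) seq(1 + s, n) else seq_len(n + s)
      if (axis == 1) out[dst, , ] <- x[src, , ]
      else if (axis == 2) out[, dst, ] <- x[, src, ]
      else out[, , dst] <- x[, , src]
      out
    }
    # a surface voxel has at least one background 6-neighbour (or is on the
    # array border)
    interior <- array(TRUE, dim = d)
    for (axis in 1:3) for (s in c(-1L, 1L)) {
      nb <- shift_or(v, s, axis)
      edge <- array(FALSE, dim = d)
      if (axis == 1) { if (s > 0) edge[1, , ] <- TRUE else edge[d[1], , ] <- TRUE }
      else if (axis == 2) { if (s > 0) edge[, 1, ] <- TRUE else edge[, d[2], ] <- TRUE }
      else { if (s > 0) edge[, , 1] <- TRUE else edge[, , d[3]] <- TRUE }
      interior <- interior & (nb | edge)
    }
    surf_idx <- which(v & !interior)
    if (!length(surf_idx)) surf_idx <- which(v)
    ai <- arrayInd(surf_idx, d)
    vs <- surface$voxel_size
    sp <- cbind((ai[, 3] - 0.5) * vs[3], (ai[, 2] - 0.5) * vs[2],
                (ai[, 1] - 0.5) * vs[1])
    return(vapply(seq_len(nrow(points)), function(i) {
      sqrt(min((sp[, 1] - points[i, 1])^2 + (sp[, 2] - points[i, 2])^2 +
               (sp[, 3] - points[i, 3])^2))
    }, numeric(1)))
  }
  if (is.numeric(surface) && length(surface) == 3) {
    return(vec_norm(sweep(points, 2, as.numeric(surface))))
  }
  stopf("unsupported surface type")
}

#' Nearest-neighbour identity analysis for labelled cells
#'
#' For each focal cell (bearing `focal_marker` AND `labeled_marker`), finds
#' its nearest other cell in the pool (cells bearing `pool_marker`) and
#' records whether that neighbour carries the label. The summary reports the
#' labelled-neighbour proportion and its expectation under random assortment:
#' the labelled fraction of the pool excluding the focal cell itself. Exact
#' distance ties are broken toward the lowest cell id and counted.
#'
#' @param scene a `scene_frame`.
#' @param focal_marker marker defining focal cells (with `labeled_marker`).
#' @param pool_marker marker defining the neighbour pool.
#' @param labeled_marker the label whose assortment is tested.
#' @param expected `"global"` (default): one pooled expectation; or
#'   `"per_region"` with `region` naming a region column grouping.
#' @param region optional region name restricting the analysis.
#' @return a `neighbor_report`: list with `per_focal` and `summary`.
#' @export
nearest_neighbor_labels <- function(scene, focal_marker = "sox2",
                                    pool_marker = "sox2",
                                    labeled_marker = "tdtomato",
                                    region = NULL) {
  stopifnot(inherits(scene, "scene_frame"))
  cells <- scene$cells
  for (mk in unique(c(focal_marker, pool_marker, labeled_marker))) {
    if (!mk %in% names(cells)) stopf("marker '%s' not present in scene", mk)
  }
  if (!is.null(region)) {
    reg <- scene$regions[[region]]
    if (is.null(reg)) stopf("unknown region '%s'", region)
    cells <- cells[points_in_region(scene_positions(scene), reg), , drop = FALSE]
  }
  pool <- cells[cells[[pool_marker]], , drop = FALSE]
  if (nrow(pool) < 2) stopf("need at least 2 cells bearing '%s'", pool_marker)
  pool <- pool[order(pool$id), , drop = FALSE]
  ppos <- as.matrix(pool[, c("x_um", "y_um", "z_um")])
  focal <- which(pool[[focal_marker]] & pool[[labeled_marker]])
  if (!length(focal)) stopf("no focal cells bear both '%s' and '%s'",
                            focal_marker, labeled_marker)
  n_lab_pool <- sum(pool[[labeled_marker]])
  n_ties <- 0L
  per <- lapply(focal, function(i) {
    d2 <- (ppos[, 1] - ppos[i, 1])^2 + (ppos[, 2] - ppos[i, 2])^2 +
          (ppos[, 3] - ppos[i, 3])^2
    d2[i] <- Inf
    dmin <- min(d2)
    hits <- which(d2 <= dmin * (1 + 1e-12))
    if (length(hits) > 1L) n_ties <<- n_ties + 1L
    j <- hits[1L]   # pool sorted by id: lowest id wins
    data.frame(focal_id = pool$id[i], neighbor_id = pool$id[j],
               neighbor_distance_um = sqrt(d2[j]),
               neighbor_labeled = pool[[labeled_marker]][j],
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  expected_prop <- (n_lab_pool - 1) / (nrow(pool) - 1)
  structure(list(per_focal = per,
                 summary = list(n_focal = nrow(per),
                                prop_labeled_neighbor = mean(per$neighbor_labeled),
                                expected_prop = expected_prop,
                                n_ties = n_ties,
                                labeled_marker = labeled_marker)),
            class = "neighbor_report")
}

#' @export
print.neighbor_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<neighbor_report> %d focal cells: %.1f%% labelled neighbours (random expectation %.1f%%)\n",
              s$n_focal, 100 * s$prop_labeled_neighbor, 100 * s$expected_prop))
  if (s$n_ties) cat(sprintf("  %d exact distance tie(s) broken by lowest id\n", s$n_ties))
  invisible(x)
}

#' Chi-square test of neighbour-label randomness
#'
#' 1-df goodness-of-fit of the observed labelled/unlabelled neighbour counts
#' against the random-assortment expectation carried by the report.
#'
#' @param report a `neighbor_report`, or a list with `observed_labeled`,
#'   `n`, `expected_prop`.
#' @return a `dc_test_result`.
#' @export
neighbor_randomness_test <- function(report) {
  if (inherits(report, "neighbor_report")) {
    n <- report$summary$n_focal
    obs <- round(report$summary$prop_labeled_neighbor * n)
    p0 <- report$summary$expected_prop
  } else {
    n <- report$n; obs <- report$observed_labeled; p0 <- report$expected_prop
  }
  if (p0 <= 0 || p0 >= 1) stopf("degenerate expectation (%.3f): chi-square undefined", p0)
  expected <- n * c(p0, 1 - p0)
  if (any(expected < 5)) warnf("expected count below 5; chi-square approximation is poor")
  ct <- suppressWarnings(stats::chisq.test(c(obs, n - obs), p = c(p0, 1 - p0)))
  dc_test_result("chi-square (1 df)", unname(ct$statistic), ct$p.value, n,
                 method_note = sprintf("observed %d/%d labelled vs expectation %.3f",
                                       obs, n, p0))
}

#' Marker-positive fraction with binomial confidence interval
#'
#' Either supply raw counts (`k` positives of `n`) or a scene plus marker
#' (optionally restricted to a region or to a denominator marker).
#'
#' @param k positives count, or a `scene_frame`.
#' @param n denominator count (when `k` is a count).
#' @param marker,denominator_marker,region scene-based selection.
#' @param conf_level confidence level for the exact (Clopper-Pearson) CI.
#' @return list with `fraction`, `percent`, `ci`, `k`, `n`.
#' @export
label_fraction <- function(k, n = NULL, marker = NULL, denominator_marker = NULL,
                           region = NULL, conf_level = 0.95) {
  if (inherits(k, "scene_frame")) {
    scene <- k
    if (is.null(marker)) stopf("marker is required for scene input")
    cells <- scene$cells
    if (!is.null(region)) {
      cells <- cells[points_in_region(scene_positions(scene),
                                      scene$regions[[region]]), , drop = FALSE]
    }
    if (!is.null(denominator_marker)) {
      cells <- cells[cells[[denominator_marker]], , drop = FALSE]
    }
    n <- nrow(cells)
    k <- sum(cells[[marker]])
  }
  if (is.null(n) || n <= 0) stopf("denominator must be positive")
  if (k < 0 || k > n) stopf("k must lie in [0, n]")
  bt <- stats::binom.test(k, n, conf.level = conf_level)
  list(fraction = k / n, percent = 100 * k / n,
       ci = unname(bt$conf.int), k = k, n = n)
}

#' Four-way Fucci cell-cycle scoring
#'
#' Scores cells as G1-only, S/G2/M-only, both, or neither from the two Fucci
#' reporter channels; the four fractions sum to 1.
#'
#' @param scene a `scene_frame`.
#' @param g1_marker,sgm_marker marker column names.
#' @param denominator_marker,region optional restriction.
#' @return named numeric fractions `g1_only`, `sgm_only`, `both`, `neither`
#'   with attribute `n`.
#' @export
fucci_fractions <- function(scene, g1_marker = "fucci_g1",
                            sgm_marker = "fucci_sgm",
                            denominator_marker = NULL, region = NULL) {
  stopifnot(inherits(scene, "scene_frame"))
  cells <- scene$cells
  if (!is.null(region)) {
    cells <- cells[points_in_region(scene_positions(scene),
                                    scene$regions[[region]]), , drop = FALSE]
  }
  if (!is.null(denominator_marker)) {
    cells <- cells[cells[[denominator_marker]], , drop = FALSE]
  }
  if (!nrow(cells)) stopf("denominator is empty")
  g1 <- cells[[g1_marker]]; sg <- cells[[sgm_marker]]
  out <- c(g1_only = mean(g1 & !sg), sgm_only = mean(!g1 & sg),
           both = mean(g1 & sg), neither = mean(!g1 & !sg))
  attr(out, "n") <- nrow(cells)
  out
}
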