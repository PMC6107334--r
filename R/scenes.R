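#' Geometric regions for scene analysis
#'
#' Regions are closed sets: a point exactly on the boundary counts as inside.
#'
#' @param center numeric length-3, micrometres.
#' @param radius sphere radius, micrometres.
#' @return a `scene_region`.
#' @export
region_sphere <- function(center, radius) {
  stopifnot(length(center) == 3, radius > 0)
  structure(list(type = "sphere", center = as.numeric(center),
                 radius = as.numeric(radius)),
            class = "scene_region")
}

#' @rdname region_sphere
#' @param lo,hi opposite box corners, micrometres.
#' @export
region_box <- function(lo, hi) {
  stopifnot(length(lo) == 3, length(hi) == 3, all(hi > lo))
  structure(list(type = "box", lo = as.numeric(lo), hi = as.numeric(hi)),
            class = "scene_region")
}

#' @rdname region_sphere
#' @param mask a binary `label_volume` (nonzero = inside).
#' @param origin world coordinate (um) of the voxel grid corner.
#' @export
region_mask <- function(mask, origin = c(0, 0, 0)) {
  stopifnot(inherits(mask, "label_volume"))
  structure(list(type = "mask", mask = mask, origin = as.numeric(origin)),
            class = "scene_region")
}

#' @export
print.scene_region <- function(x, ...) {
  cat(sprintf("<scene_region> %s, volume %.1f um^3\n", x$type, region_volume(x)))
  invisible(x)
}

#' Volume of a region in cubic micrometres
#' @param region a `scene_region`.
#' @export
region_volume <- function(region) {
  switch(region$type,
         sphere = 4 / 3 * pi * region$radius^3,
         box = prod(region$hi - region$lo),
         mask = sum(region$mask$voxels > 0) * prod(region$mask$voxel_size),
         stopf("unknown region type '%s'", region$type))
}

#' Test points for region membership (closed boundary)
#' @param points n x 3 matrix of xyz positions, micrometres.
#' @param region a `scene_region`.
#' @return logical vector of length n.
#' @export
points_in_region <- function(points, region) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  switch(region$type,
    sphere = {
      d2 <- (points[, 1] - region$center[1])^2 +
            (points[, 2] - region$center[2])^2 +
            (points[, 3] - region$center[3])^2
      d2 <= region$radius^2 + 1e-12
    },
    box = {
      points[, 1] >= region$lo[1] & points[, 1] <= region$hi[1] &
      points[, 2] >= region$lo[2] & points[, 2] <= region$hi[2] &
      points[, 3] >= region$lo[3] & points[, 3] <= region$hi[3]
    },
    mask = {
      vs <- region$mask$voxel_size          # (z, y, x) um/voxel
      dims <- dim(region$mask$voxels)       # (z, y, x)
      rel <- sweep(points, 2, region$origin)
      iz <- floor(rel[, 3] / vs[1]) + 1L
      iy <- floor(rel[, 2] / vs[2]) + 1L
      ix <- floor(rel[, 1] / vs[3]) + 1L
      ok <- iz >= 1L & iz <= dims[1] & iy >= 1L & iy <= dims[2] &
            ix >= 1L & ix <= dims[3]
      out <- rep(FALSE, nrow(points))
      if (any(ok)) {
        out[ok] <- region$mask$voxels[cbind(iz[ok], iy[ok], ix[ok])] > 0
      }
      out
    },
    stopf("unknown region type '%s'", region$type))
}

#' Translate a region by an offset
#'
#' Used to clone a condensate region onto an interfollicular control location
#' so that density comparisons use identical volumes.
#'
#' @param region a `scene_region`.
#' @param offset numeric length-3, micrometres.
#' @export
translate_region <- function(region, offset) {
  offset <- as.numeric(offset)
  switch(region$type,
         sphere = region_sphere(region$center + offset, region$radius),
         box = region_box(region$lo + offset, region$hi + offset),
         mask = region_mask(region$mask, region$origin + offset))
}

#' Static 3D point-cloud scenes
#'
#' A scene frame is a snapshot of cell centres with logical markers, optional
#' intensity channels, named geometric regions, and optional reference
#' geometry (condensate centre, placode surface mesh, bead).
#'
#' @param cells data.frame with columns `id`, `x_um`, `y_um`, `z_um`, logical
#'   marker columns, and optional numeric `intensity_*` columns.
#' @param regions named list of `scene_region`s.
#' @param references optional list with any of `dc_center` (length-3),
#'   `placode_surface` (a `triangle_mesh`), `bead` (list of `center`, `radius`).
#' @return a `scene_frame`.
#' @export
scene_frame <- function(cells, regions = list(), references = list()) {
  req <- c("id", "x_um", "y_um", "z_um")
  missing_cols <- setdiff(req, names(cells))
  if (length(missing_cols)) {
    stopf("scene cells are missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  cells$id <- as.character(cells$id)
  if (anyDuplicated(cells$id)) stopf("scene cell ids must be unique")
  pos <- as.matrix(cells[, c("x_um", "y_um", "z_um")])
  if (nrow(cells) && !all(is.finite(pos))) stopf("scene positions must be finite")
  if (length(regions)) {
    if (is.null(names(regions)) || any(!nzchar(names(regions))))
      stopf("regions must be a named list")
    if (anyDuplicated(names(regions))) stopf("duplicate region names")
    ok <- vapply(regions, inherits, logical(1), what = "scene_region")
    if (!all(ok)) stopf("all regions must be scene_region objects")
  }
  structure(list(cells = cells, regions = regions, references = references),
            class = "scene_frame")
}

#' @export
print.scene_frame <- function(x, ...) {
  cat(sprintf("<scene_frame> %d cells, %d region(s)\n",
              nrow(x$cells), length(x$regions)))
  mk <- marker_columns(x$cells)
  if (length(mk)) cat("  markers:", paste(mk, collapse = ", "), "\n")
  if (length(x$references)) cat("  references:", paste(names(x$references), collapse = ", "), "\n")
  invisible(x)
}

scene_positions <- function(scene) {
  as.matrix(scene$cells[, c("x_um", "y_um", "z_um"), drop = FALSE])
}

#' Specification for synthetic point scenes
#'
#' Each named region gets a target density (cells per 1e4 um^3), marker
#' probabilities, and optionally ellipsoid semi-axes for nuclear shape (used
#' by [generate_label_volume()]).
#'
#' @param regions named list; each element a list with fields `shape`
#'   (a `scene_region`), `density_per_1e4_um3` (> 0), `marker_fractions`
#'   (named numeric in \[0,1\]), and optional `nuclear_axes` (length-3
#'   semi-axes, um).
#' @param label_clustering in \[0,1\]: probability that a labelled cell is
#'   placed within one mean nearest-neighbour distance of an existing labelled
#'   cell instead of uniformly. The clustered marker is the first marker named
#'   in `marker_fractions`.
#' @param seed integer RNG seed.
#' @return a `scene_spec`.
#' @export
scene_spec <- function(regions, label_clustering = 0, seed = 1L) {
  stopifnot(is.list(regions), length(regions) >= 1)
  if (is.null(names(regions)) || any(!nzchar(names(regions))))
    stopf("scene_spec regions must be named")
  for (nm in names(regions)) {
    r <- regions[[nm]]
    if (!inherits(r$shape, "scene_region")) stopf("region '%s' lacks a shape", nm)
    if (is.null(r$density_per_1e4_um3) || r$density_per_1e4_um3 <= 0)
      stopf("region '%s' needs density_per_1e4_um3 > 0", nm)
    if (!is.null(r$marker_fractions)) {
      p <- unlist(r$marker_fractions)
      if (any(p < 0 | p > 1)) stopf("marker fractions in region '%s' outside [0,1]", nm)
    }
    if (!is.null(r$nuclear_axes) && any(r$nuclear_axes <= 0))
      stopf("nuclear semi-axes in region '%s' must be positive", nm)
  }
  if (label_clustering < 0 || label_clustering > 1)
    stopf("label_clustering must be in [0,1]")
  structure(list(regions = regions, label_clustering = label_clustering,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

sample_in_region <- function(n, region) {
  if (n == 0L) return(matrix(numeric(0), ncol = 3))
  switch(region$type,
    box = cbind(stats::runif(n, region$lo[1], region$hi[1]),
                stats::runif(n, region$lo[2], region$hi[2]),
                stats::runif(n, region$lo[3], region$hi[3])),
    sphere = {
      dirs <- runif_sphere(n)
      r <- region$radius * stats::runif(n)^(1 / 3)
      sweep(dirs * r, 2, region$center, `+`)
    },
    stopf("cannot sample points in region type '%s'", region$type))
}

#' Generate a synthetic point scene
#'
#' Counts per region are Poisson with mean density x volume; positions are
#' uniform within each region; markers are independent Bernoulli draws unless
#' `label_clustering > 0`, in which case cells carrying the first marker are
#' preferentially seeded near already-labelled cells, emulating the non-random
#' neighbour assortment seen when lineage-labelled cells enter a condensate.
#'
#' @param spec a [scene_spec()].
#' @param references optional references list passed to the scene.
#' @return a `scene_frame` whose regions are those of the spec.
#' @export
generate_point_scene <- function(spec, references = list()) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  all_cells <- list()
  counter <- 0L
  for (nm in names(spec$regions)) {
    r <- spec$regions[[nm]]
    vol <- region_volume(r$shape)
    lambda <- r$density_per_1e4_um3 * vol / 1e4
    if (lambda < 1) warnf("region '%s': expected cell count %.2f < 1", nm, lambda)
    n <- stats::rpois(1, lambda)
    pos <- sample_in_region(n, r$shape)
    cells <- data.frame(id = sprintf("%s_%04d", nm, seq_len(n) + counter),
                        x_um = pos[, 1], y_um = pos[, 2], z_um = pos[, 3],
                        stringsAsFactors = FALSE)
    counter <- counter + n
    fr <- r$marker_fractions %||% list()
    for (mk in names(fr)) cells[[mk]] <- stats::runif(n) < fr[[mk]]
    if (spec$label_clustering > 0 && length(fr) && n > 1) {
      mk <- names(fr)[1]
      lab <- which(cells[[mk]])
      if (length(lab) > 1) {
        # mean NN spacing for a Poisson process at this density
        d_nn <- 0.55396 * (vol / max(n, 1))^(1 / 3)
        placed <- lab[1]
        for (i in lab[-1]) {
          if (stats::runif(1) < spec$label_clustering) {
            anchor <- placed[sample.int(length(placed), 1)]
            prop <- as.numeric(cells[anchor, c("x_um", "y_um", "z_um")]) +
              runif_sphere(1)[1, ] * stats::runif(1, 0, d_nn)
            # keep inside the region; fall back to original draw otherwise
            if (points_in_region(matrix(prop, ncol = 3), r$shape)) {
              cells[i, c("x_um", "y_um", "z_um")] <- prop
            }
          }
          placed <- c(placed, i)
        }
      }
    }
    all_cells[[nm]] <- cells
  }
  # harmonise marker columns across regions (absent marker -> FALSE)
  mks <- unique(unlist(lapply(all_cells, function(df)
    setdiff(names(df), c("id", "x_um", "y_um", "z_um")))))
  for (nm in names(all_cells)) {
    for (mk in setdiff(mks, names(all_cells[[nm]]))) all_cells[[nm]][[mk]] <- FALSE
    all_cells[[nm]] <- all_cells[[nm]][, c("id", "x_um", "y_um", "z_um", mks),
                                       drop = FALSE]
  }
  cells <- do.call(rbind, c(all_cells, list(make.row.names = FALSE)))
  scene_frame(cells,
              regions = lapply(spec$regions, `[[`, "shape"),
              references = references)
}

region_to_list <- function(r) {
  switch(r$type,
         sphere = list(type = "sphere", center = r$center, radius = r$radius),
         box = list(type = "box", lo = r$lo, hi = r$hi),
         stopf("region type '%s' has no JSON form (save masks as TIFF)", r$type))
}

region_from_list <- function(l) {
  switch(l$type,
         sphere = region_sphere(unlist(l$center), l$radius),
         box = region_box(unlist(l$lo), unlist(l$hi)),
         stopf("unknown region type '%s'", l$type))
}

#' Read / write scenes as JSON
#'
#' Cells are stored as a record list, regions and references as named objects.
#' Mask regions are not serialised (store them as TIFF volumes instead).
#'
#' @param scene a `scene_frame`.
#' @param path file path.
#' @export
write_scene <- function(scene, path) {
  stopifnot(inherits(scene, "scene_frame"))
  refs <- scene$references
  if (!is.null(refs$placode_surface)) {
    refs$placode_surface <- list(vertices = refs$placode_surface$vertices,
                                 faces = refs$placode_surface$faces)
  }
  obj <- list(cells = scene$cells,
              regions = lapply(scene$regions, region_to_list),
              references = refs)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cells <- as.data.frame(obj$cells, stringsAsFactors = FALSE)
  refs <- obj$references %||% list()
  if (!is.null(refs$dc_center)) refs$dc_center <- as.numeric(unlist(refs$dc_center))
  if (!is.null(refs$bead)) {
    refs$bead <- list(center = as.numeric(unlist(refs$bead$center)),
                      radius = as.numeric(refs$bead$radius))
  }
  if (!is.null(refs$placode_surface)) {
    refs$placode_surface <- triangle_mesh(
      as.matrix(refs$placode_surface$vertices),
      matrix(as.integer(as.matrix(refs$placode_surface$faces)), ncol = 3))
  }
  regions <- lapply(obj$regions %||% list(), region_from_list)
  scene_frame(cells, regions = regions, references = refs)
}
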