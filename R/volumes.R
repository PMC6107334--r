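#' 3D label volumes
#'
#' A label volume is a voxel grid of non-negative integer object labels
#' (0 = background) with a physical voxel size. Axis order is (z, y, x):
#' `voxels[i, j, k]` is slice i, row j (y), column k (x), and `voxel_size`
#' is `c(z, y, x)` in micrometres per voxel.
#'
#' @param voxels 3D integer array in (z, y, x) order.
#' @param voxel_size numeric length-3 `c(z, y, x)`, um/voxel.
#' @param meta optional metadata list (e.g. `border_labels`).
#' @return a `label_volume`.
#' @export
label_volume <- function(voxels, voxel_size, meta = list()) {
  stopifnot(length(dim(voxels)) == 3, length(voxel_size) == 3)
  if (any(voxel_size <= 0)) stopf("voxel_size must be positive on all axes")
  if (any(voxels < 0)) stopf("labels must be non-negative")
  structure(list(voxels = voxels, voxel_size = as.numeric(voxel_size),
                 meta = meta),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<label_volume> %d x %d x %d (z,y,x), voxel %.2f x %.2f x %.2f um, %d object(s)\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              length(setdiff(unique(as.vector(x$voxels)), 0L))))
  invisible(x)
}

# voxel centre world coordinates along one axis
axis_centers <- function(n, step) (seq_len(n) - 0.5) * step

#' Rasterize filled ellipsoids into a label volume
#'
#' Axis-aligned ellipsoids are filled at voxel centres; labels are consecutive
#' positive integers in input order. Overlapping ellipsoids are an error
#' (downstream morphometry assumes separated nuclei). Objects touching the
#' volume border are listed in `meta$border_labels`.
#'
#' @param centers n x 3 matrix of xyz centres, micrometres.
#' @param semi_axes n x 3 matrix (or length-3 vector recycled) of xyz
#'   semi-axes, micrometres.
#' @param dims volume dimensions `c(z, y, x)` in voxels.
#' @param voxel_size `c(z, y, x)` um/voxel.
#' @return a `label_volume`.
#' @export
rasterize_ellipsoids <- function(centers, semi_axes, dims, voxel_size) {
  if (is.null(dim(centers))) centers <- matrix(centers, ncol = 3)
  if (is.null(dim(semi_axes))) {
    semi_axes <- matrix(semi_axes, nrow = nrow(centers), ncol = 3, byrow = TRUE)
  }
  stopifnot(nrow(centers) == nrow(semi_axes), length(dims) == 3)
  vol <- array(0L, dim = dims)
  vs <- as.numeric(voxel_size)              # (z, y, x)
  if (nrow(centers) && any(semi_axes <= 0)) stopf("semi-axes must be positive")
  zc <- axis_centers(dims[1], vs[1])
  yc <- axis_centers(dims[2], vs[2])
  xc <- axis_centers(dims[3], vs[3])
  border <- integer(0)
  for (i in seq_len(nrow(centers))) {
    cx <- centers[i, 1]; cy <- centers[i, 2]; cz <- centers[i, 3]
    ax <- semi_axes[i, 1]; ay <- semi_axes[i, 2]; az <- semi_axes[i, 3]
    if (any(c(ax, ay, az) < 2 * rev(vs))) {
      warnf("object %d has a semi-axis under 2 voxels; its surface will be unreliable", i)
    }
    iz <- which(abs(zc - cz) <= az)
    iy <- which(abs(yc - cy) <= ay)
    ix <- which(abs(xc - cx) <= ax)
    if (!length(iz) || !length(iy) || !length(ix)) next
    dz2 <- ((zc[iz] - cz) / az)^2
    dy2 <- ((yc[iy] - cy) / ay)^2
    dx2 <- ((xc[ix] - cx) / ax)^2
    inside <- outer(outer(dz2, dy2, `+`), dx2, `+`) <= 1
    sub <- vol[iz, iy, ix, drop = FALSE]
    if (any(sub[inside] != 0L)) {
      stopf("ellipsoid %d overlaps object %d; morphometry assumes separated nuclei",
            i, sub[inside][sub[inside] != 0L][1])
    }
    sub[inside] <- i
    vol[iz, iy, ix] <- sub
    if (any(inside) &&
        (min(iz) == 1L || max(iz) == dims[1] ||
         min(iy) == 1L || max(iy) == dims[2] ||
         min(ix) == 1L || max(ix) == dims[3])) {
      border <- c(border, i)
    }
  }
  label_volume(vol, vs, meta = list(border_labels = border))
}

#' Generate a synthetic label volume of nuclei from a scene spec
#'
#' Samples nucleus centres per region as in [generate_point_scene()] (using
#' each region's `nuclear_axes` as ellipsoid semi-axes) and rasterizes them.
#' Candidate centres whose ellipsoids would overlap an earlier object are
#' rejected and resampled (up to 50 attempts each), keeping nuclei separated.
#'
#' @param spec a [scene_spec()]; every region needs `nuclear_axes`.
#' @param dims volume dimensions `c(z, y, x)` in voxels.
#' @param voxel_size `c(z, y, x)` um/voxel.
#' @return a `label_volume` with `meta$centers` and `meta$semi_axes`.
#' @export
generate_label_volume <- function(spec, dims, voxel_size) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  vs <- as.numeric(voxel_size)
  centers <- NULL; axes <- NULL
  for (nm in names(spec$regions)) {
    r <- spec$regions[[nm]]
    if (is.null(r$nuclear_axes))
      stopf("region '%s' needs nuclear_axes to build a label volume", nm)
    if (any(r$nuclear_axes < 2 * rev(vs)))
      stopf("region '%s': nuclear semi-axes must span at least 2 voxels per axis", nm)
    vol <- region_volume(r$shape)
    lambda <- r$density_per_1e4_um3 * vol / 1e4
    if (lambda < 1) warnf("region '%s': expected nucleus count %.2f < 1", nm, lambda)
    n <- stats::rpois(1, lambda)
    kept <- 0L
    while (kept < n) {
      ok <- FALSE
      for (attempt in seq_len(50L)) {
        p <- sample_in_region(1L, r$shape)
        # centre separation test against all accepted nuclei (bounding spheres)
        if (is.null(centers) ||
            all(vec_norm(sweep(centers, 2, p[1, ])) >
                max(r$nuclear_axes) + apply(axes, 1, max))) {
          centers <- rbind(centers, p)
          axes <- rbind(axes, r$nuclear_axes)
          ok <- TRUE
          break
        }
      }
      if (!ok) stopf("could not place %d non-overlapping nuclei in region '%s'", n, nm)
      kept <- kept + 1L
    }
  }
  if (is.null(centers)) {
    return(label_volume(array(0L, dims), vs,
                        meta = list(border_labels = integer(0),
                                    centers = matrix(numeric(0), ncol = 3),
                                    semi_axes = matrix(numeric(0), ncol = 3))))
  }
  lv <- rasterize_ellipsoids(centers, axes, dims, vs)
  lv$meta$centers <- centers
  lv$meta$semi_axes <- axes
  lv
}

#' Read / write label or intensity volumes as multi-page TIFF
#'
#' Pages are z slices. Values are stored as 16-bit; labels round-trip exactly
#' for up to 65535 objects. The voxel size travels in a JSON sidecar
#' (`<path>.json`) because baseline TIFF tags cannot carry anisotropic 3D
#' spacing portably.
#'
#' @param volume a `label_volume` (or numeric array for intensities).
#' @param path output TIFF path.
#' @export
write_label_volume <- function(volume, path) {
  stopifnot(inherits(volume, "label_volume"))
  v <- volume$voxels
  if (max(v) > 65535) stopf("more than 65535 labels cannot be stored as 16-bit TIFF")
  pages <- lapply(seq_len(dim(v)[1]), function(i) v[i, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(list(voxel_size_zyx_um = volume$voxel_size,
                            border_labels = volume$meta$border_labels %||% integer(0)),
                       paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_label_volume
#' @param voxel_size optional `c(z, y, x)` override when no sidecar exists.
#' @export
read_label_volume <- function(path, voxel_size = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  v <- array(0L, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (i in seq_along(pages)) v[i, , ] <- as.integer(round(pages[[i]] * 65535))
  side <- paste0(path, ".json")
  meta <- list()
  if (is.null(voxel_size)) {
    if (!file.exists(side)) stopf("no voxel size: sidecar '%s' missing and none supplied", side)
    sj <- jsonlite::read_json(side, simplifyVector = TRUE)
    voxel_size <- as.numeric(sj$voxel_size_zyx_um)
    meta$border_labels <- as.integer(sj$border_labels)
  }
  label_volume(v, voxel_size, meta = meta)
}
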