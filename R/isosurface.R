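# Triangulated isosurfaces of voxel data via marching tetrahedra.
#
# Each grid cell is split into six tetrahedra sharing the cube diagonal; the
# 0.5-level surface of a (smoothed) binary field is extracted by linear
# interpolation along tetrahedron edges. Voxel-face counting is deliberately
# avoided: it overestimates the area of smooth objects by ~50%, which would
# corrupt sphericity. Pre-smoothing the binary mask with a small Gaussian
# gives sub-voxel interpolation positions and near-analytic areas for
# well-resolved objects.

#' Triangle meshes
#'
#' @param vertices n x 3 numeric matrix of xyz coordinates (um).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @return a `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces) {
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  storage.mode(faces) <- "integer"
  if (nrow(faces) && (max(faces) > nrow(vertices) || min(faces) < 1L))
    stopf("face indices out of range")
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh> %d vertices, %d faces, area %.2f um^2\n",
              nrow(x$vertices), nrow(x$faces), mesh_area(x)))
  invisible(x)
}

#' Total surface area of a triangle mesh
#' @param mesh a `triangle_mesh`.
#' @export
mesh_area <- function(mesh) {
  if (!nrow(mesh$faces)) return(0)
  v1 <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  v2 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  v3 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  sum(0.5 * vec_norm(cross3(v2 - v1, v3 - v1)))
}

# separable Gaussian smoothing of a 3D array (sigma in voxels, zero padding)
gauss_smooth3 <- function(a, sigma) {
  if (sigma <= 0) return(a)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  d <- dim(a)
  shift_axis <- function(x, s, axis) {
    # shift array by s along axis, zero fill
    out <- array(0, dim = d)
    n <- d[axis]
    if (abs(s) >= n) return(out)
    src <- if (s >= 0) seq_len(n - s) else seq(1 - s, n)
    dst <- if (s >= 0) seq(1 + s, n) else seq_len(n + s)
    if (axis == 1L) out[dst, , ] <- x[src, , ]
    else if (axis == 2L) out[, dst, ] <- x[, src, ]
    else out[, , dst] <- x[, , src]
    out
  }
  for (axis in 1:3) {
    acc <- array(0, dim = d)
    for (j in seq_along(k)) {
      s <- j - r - 1L
      acc <- acc + k[j] * shift_axis(a, s, axis)
    }
    a <- acc
  }
  a
}

# six-tetrahedra decomposition of the unit cube (corners bit-ordered x,y,z)
.tet_corners <- rbind(
  c(0L, 5L, 1L, 6L),
  c(0L, 1L, 2L, 6L),
  c(0L, 2L, 3L, 6L),
  c(0L, 3L, 7L, 6L),
  c(0L, 7L, 4L, 6L),
  c(0L, 4L, 5L, 6L))

# corner offsets (x, y, z) for corners 0..7
.corner_offsets <- rbind(
  c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
  c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))

# tetrahedron edges as index pairs into its 4 local vertices
.tet_edges <- rbind(c(1L, 2L), c(1L, 3L), c(1L, 4L),
                    c(2L, 3L), c(2L, 4L), c(3L, 4L))

# case table: for each above-mask 1..14, list of triangles as edge-index triples
.tet_cases <- {
  tri <- vector("list", 15L)
  tri[[1L]]  <- list(c(1L, 2L, 3L))                       # v1 above
  tri[[2L]]  <- list(c(1L, 4L, 5L))                       # v2
  tri[[4L]]  <- list(c(2L, 4L, 6L))                       # v3
  tri[[8L]]  <- list(c(3L, 5L, 6L))                       # v4
  tri[[3L]]  <- list(c(2L, 4L, 5L), c(2L, 5L, 3L))        # v1,v2
  tri[[5L]]  <- list(c(1L, 4L, 6L), c(1L, 6L, 3L))        # v1,v3
  tri[[9L]]  <- list(c(1L, 5L, 6L), c(1L, 6L, 2L))        # v1,v4
  tri[[6L]]  <- tri[[9L]]                                 # v2,v3 (complementary cut)
  tri[[10L]] <- tri[[5L]]                                 # v2,v4
  tri[[12L]] <- tri[[3L]]                                 # v3,v4
  tri[[14L]] <- tri[[1L]]; tri[[13L]] <- tri[[2L]]
  tri[[11L]] <- tri[[4L]]; tri[[7L]]  <- tri[[8L]]
  tri
}

#' Extract a triangulated isosurface from a 3D scalar field
#'
#' Marching tetrahedra at the given level. Vertex coordinates are in
#' micrometres: the (z, y, x) voxel grid is scaled by `voxel_size` before
#' triangulation, so anisotropic stacks are handled.
#'
#' @param field 3D numeric array in (z, y, x) order.
#' @param level iso level (0.5 for binary masks).
#' @param voxel_size `c(z, y, x)` um/voxel.
#' @return a `triangle_mesh` (xyz coordinates, um).
#' @export
isosurface <- function(field, level = 0.5, voxel_size = c(1, 1, 1)) {
  d <- dim(field)
  stopifnot(length(d) == 3)
  vs <- as.numeric(voxel_size)
  nz <- d[1] - 1L; ny <- d[2] - 1L; nx <- d[3] - 1L
  if (nz < 1L || ny < 1L || nx < 1L) return(triangle_mesh(matrix(numeric(0), ncol = 3),
                                                          matrix(integer(0), ncol = 3)))
  # corner value arrays, one per cube corner, each of dim (nz, ny, nx)
  cv <- vector("list", 8L)
  for (c8 in 1:8) {
    off <- .corner_offsets[c8, ]            # (x, y, z)
    cv[[c8]] <- field[(1 + off[3]):(nz + off[3]),
                      (1 + off[2]):(ny + off[2]),
                      (1 + off[1]):(nx + off[1]), drop = FALSE]
  }
  lo <- pmin(cv[[1]], cv[[2]], cv[[3]], cv[[4]], cv[[5]], cv[[6]], cv[[7]], cv[[8]])
  hi <- pmax(cv[[1]], cv[[2]], cv[[3]], cv[[4]], cv[[5]], cv[[6]], cv[[7]], cv[[8]])
  active <- which(lo < level & hi >= level)
  if (!length(active)) {
    return(triangle_mesh(matrix(numeric(0), ncol = 3), matrix(integer(0), ncol = 3)))
  }
  # cell origin coordinates (voxel-centre convention: centre of voxel (i,j,k)
  # sits at ((i-0.5)vz, ...); cell corners are voxel centres)
  ai <- arrayInd(active, c(nz, ny, nx))
  orig <- cbind(x = (ai[, 3] - 0.5) * vs[3],
                y = (ai[, 2] - 0.5) * vs[2],
                z = (ai[, 1] - 0.5) * vs[1])
  vals <- do.call(cbind, lapply(cv, function(a) a[active]))  # m x 8
  m <- length(active)
  tris <- vector("list", 6L)
  for (t6 in 1:6) {
    corners <- .tet_corners[t6, ] + 1L
    v4 <- vals[, corners, drop = FALSE]                       # m x 4
    above <- v4 >= level
    mask <- as.integer(above %*% c(1L, 2L, 4L, 8L))
    use <- which(mask > 0L & mask < 15L)
    if (!length(use)) next
    # tetra vertex coordinates: origin + corner offset * voxel size
    pts <- lapply(1:4, function(j) {
      off <- .corner_offsets[corners[j], ]                    # (x, y, z)
      cbind(orig[use, 1] + off[1] * vs[3],
            orig[use, 2] + off[2] * vs[2],
            orig[use, 3] + off[3] * vs[1])
    })
    v4u <- v4[use, , drop = FALSE]
    # interpolated point on each of the 6 tetra edges
    epts <- vector("list", 6L)
    for (e in 1:6) {
      a <- .tet_edges[e, 1]; b <- .tet_edges[e, 2]
      denom <- v4u[, b] - v4u[, a]
      tt <- ifelse(abs(denom) < 1e-300, 0.5, (level - v4u[, a]) / denom)
      tt <- pmin(1, pmax(0, tt))
      epts[[e]] <- pts[[a]] + (pts[[b]] - pts[[a]]) * tt
    }
    out <- list()
    for (cs in sort(unique(mask[use]))) {
      rows <- which(mask[use] == cs)
      for (tr in .tet_cases[[cs]]) {
        out[[length(out) + 1L]] <- cbind(epts[[tr[1]]][rows, , drop = FALSE],
                                         epts[[tr[2]]][rows, , drop = FALSE],
                                         epts[[tr[3]]][rows, , drop = FALSE])
      }
    }
    tris[[t6]] <- do.call(rbind, out)
  }
  tri9 <- do.call(rbind, tris[!vapply(tris, is.null, logical(1))])
  nt <- nrow(tri9)
  verts <- rbind(tri9[, 1:3, drop = FALSE], tri9[, 4:6, drop = FALSE],
                 tri9[, 7:9, drop = FALSE])
  faces <- cbind(seq_len(nt), seq_len(nt) + nt, seq_len(nt) + 2L * nt)
  triangle_mesh(verts, faces)
}

#' Surface area of a binary object by smoothed triangulated isosurface
#'
#' @param mask 3D logical/0-1 array in (z, y, x) order (padded with background).
#' @param voxel_size `c(z, y, x)` um/voxel.
#' @param smooth_sigma Gaussian pre-smoothing sigma in voxels; 0 disables.
#' @return area in um^2.
#' @export
binary_surface_area <- function(mask, voxel_size, smooth_sigma = 0.7) {
  f <- gauss_smooth3(array(as.numeric(mask != 0), dim = dim(mask)), smooth_sigma)
  mesh_area(isosurface(f, level = 0.5, voxel_size = voxel_size))
}

#' Read / write triangle meshes as Wavefront OBJ
#' @param mesh a `triangle_mesh`.
#' @param path file path.
#' @export
write_obj <- function(mesh, path) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g",
                     mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d",
                     mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]), con)
  invisible(path)
}

#' @rdname write_obj
#' @export
read_obj <- function(path) {
  lines <- readLines(path)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  verts <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(p) as.numeric(p[2:4])))
  # faces may carry v/vt/vn specs; keep the vertex index
  faces <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(p)
    as.integer(vapply(strsplit(p[2:4], "/"), `[[`, character(1), 1L))))
  triangle_mesh(verts, faces)
}

#' Tessellate a sphere into a triangle mesh
#'
#' Subdivided icosahedron; handy as a reference surface for distance tests.
#'
#' @param center xyz centre (um).
#' @param radius radius (um).
#' @param subdivisions number of 4-way subdivision rounds (>= 0).
#' @export
sphere_mesh <- function(center = c(0, 0, 0), radius = 1, subdivisions = 2L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- unitize(v)
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nf <- nrow(f)
    newf <- matrix(0L, nrow = 4 * nf, ncol = 3)
    mid_cache <- new.env(hash = TRUE)
    midpoint <- function(i, j) {
      key <- paste(sort(c(i, j)), collapse = "_")
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      v <<- rbind(v, unitize(matrix(v[i, ] + v[j, ], nrow = 1)))
      mid_cache[[key]] <- nrow(v)
      nrow(v)
    }
    for (k in seq_len(nf)) {
      a <- f[k, 1]; b <- f[k, 2]; cc <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newf[4 * k - 3, ] <- c(a, ab, ca)
      newf[4 * k - 2, ] <- c(b, bc, ab)
      newf[4 * k - 1, ] <- c(cc, ca, bc)
      newf[4 * k, ] <- c(ab, bc, ca)
    }
    f <- newf
  }
  triangle_mesh(sweep(v * radius, 2, center, `+`), f)
}
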