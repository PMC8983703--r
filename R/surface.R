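# van der Waals radii (Bondi-style), Angstrom; elements not listed fall back
# to the carbon radius.
.vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
.vdw_default <- 1.70

vdw_radius <- function(element) {
  r <- .vdw_radii[toupper(element)]
  r[is.na(r)] <- .vdw_default
  unname(r)
}

#' Triangulate a molecular surface from an atom set
#'
#' Approximates the solvent-excluded surface as the iso-surface, at the
#' probe radius, of the Euclidean distance field of the union of atom van
#' der Waals spheres. The field is sampled on a regular grid and the
#' surface extracted by marching tetrahedra, which yields a closed
#' triangulated mesh in the atoms' own coordinate frame.
#'
#' @param atoms Data frame of atoms (as from [select_atoms()]) with columns
#'   `element`, `x`, `y`, `z`; or a `zd_structure` (all atoms used).
#' @param probe_radius Probe sphere radius in Angstrom (default 1.4, a
#'   water-sized probe).
#' @param resolution Grid spacing of the marching grid in Angstrom.
#'   Smaller values resolve finer surface detail at cubic cost.
#' @return A `zd_mesh`: list with `vertices` (n x 3 matrix), `faces`
#'   (m x 3 integer matrix, 1-based), `n_vertices`, `n_faces`.
#' @export
triangulate_surface <- function(atoms, probe_radius = 1.4, resolution = 0.7) {
  if (inherits(atoms, "zd_structure")) atoms <- atoms$atoms
  stopifnot(is.data.frame(atoms))
  if (nrow(atoms) == 0L) stop("cannot triangulate a surface for zero atoms")
  stopifnot(probe_radius >= 0, resolution > 0)
  centers <- as.matrix(atoms[, c("x", "y", "z")])
  radii <- vdw_radius(atoms$element)

  pad <- max(radii) + probe_radius + 3 * resolution
  lo <- apply(centers, 2, min) - pad
  hi <- apply(centers, 2, max) + pad
  dims <- as.integer(ceiling((hi - lo) / resolution)) + 2L
  field <- sphere_field_cpp(centers, radii, lo, resolution, dims,
                            reach = probe_radius + 3 * resolution)
  mc <- marching_tetrahedra_cpp(field, dims, lo, resolution, probe_radius)
  mesh <- clean_mesh(mc$vertices, mc$faces)
  if (mesh$n_faces == 0L)
    stop("empty surface mesh; increase resolution or check input atoms")
  # exact size reference in the atoms' frame: every surface point lies
  # within max(|c_i - center| + r_i) + probe of the atom centroid.  Unlike
  # the mesh's own max vertex radius this is exactly rotation invariant,
  # so downstream grid scaling does not wobble with orientation.
  center <- colMeans(centers)
  mesh$center <- center
  mesh$size_radius <- max(sqrt(rowSums(sweep(centers, 2, center)^2)) + radii) +
    probe_radius
  mesh
}

# Weld coincident vertices and drop degenerate (zero-area) faces.
clean_mesh <- function(vertices, faces) {
  key <- paste(round(vertices[, 1], 7), round(vertices[, 2], 7),
               round(vertices[, 3], 7))
  remap <- match(key, unique(key))
  keep <- !duplicated(key)
  vertices <- vertices[keep, , drop = FALSE]
  faces <- matrix(remap[faces], ncol = 3)
  distinct <- faces[, 1] != faces[, 2] & faces[, 2] != faces[, 3] &
    faces[, 1] != faces[, 3]
  faces <- faces[distinct, , drop = FALSE]
  if (nrow(faces)) {
    e1 <- vertices[faces[, 2], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE]
    e2 <- vertices[faces[, 3], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE]
    cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
    cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
    cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
    area2 <- cx^2 + cy^2 + cz^2
    faces <- faces[area2 > 1e-24, , drop = FALSE]
  }
  structure(list(vertices = vertices, faces = faces,
                 n_vertices = nrow(vertices), n_faces = nrow(faces)),
            class = "zd_mesh")
}

#' @export
print.zd_mesh <- function(x, ...) {
  cat("<zd_mesh> ", x$n_vertices, " vertices, ", x$n_faces, " faces\n", sep = "")
  invisible(x)
}

#' Vertex and face counts of a mesh
#'
#' These two numbers are carried alongside the shape descriptor and their
#' pairwise differences enter the pair-comparison features of the fold
#' network.
#'
#' @param mesh A `zd_mesh`.
#' @return Named integer vector `c(n_vertices =, n_faces =)`.
#' @export
mesh_summary <- function(mesh) {
  stopifnot(inherits(mesh, "zd_mesh"))
  c(n_vertices = mesh$n_vertices, n_faces = mesh$n_faces)
}

#' Voxelize a surface mesh onto a cubic binary grid
#'
#' The mesh (plus a margin of at least `cutoff + 1` voxels per side) is
#' fitted isotropically into an `N`^3 cube centered on its vertex centroid.
#' A voxel is set to 1 exactly when the distance from its center to the
#' nearest mesh triangle is smaller than `cutoff` grid intervals, and 0
#' otherwise; the resulting binary occupancy function is what the Zernike
#' expansion consumes. The grid spacing is derived from the largest
#' vertex-to-centroid distance — a rotation-invariant size measure that
#' bounds the bounding box — so the physical thickness of the voxel shell
#' does not depend on how the molecule happens to be oriented.
#'
#' @param mesh A `zd_mesh`.
#' @param N Grid size per axis (production default 200; tests and fixtures
#'   use coarser grids).
#' @param cutoff Surface-shell thickness in grid intervals (default 1.7).
#' @return A `zd_voxel_grid`: list with `N`, `data` (N x N x N 0/1 array),
#'   `origin` (coordinates of voxel \[1,1,1\] center) and `spacing`.
#' @export
voxelize_surface <- function(mesh, N = 200, cutoff = 1.7) {
  stopifnot(inherits(mesh, "zd_mesh"), N >= 8, cutoff > 0)
  if (mesh$n_faces == 0L) stop("cannot voxelize an empty mesh")
  center <- if (!is.null(mesh$center)) mesh$center else numeric(0)
  size_radius <- if (!is.null(mesh$size_radius)) mesh$size_radius else -1
  res <- voxelize_mesh_cpp(mesh$vertices, mesh$faces, as.integer(N), cutoff,
                           center, size_radius)
  if (res$spacing > min(.vdw_radii))
    stop("grid of size N = ", N, " is too coarse for this mesh (spacing ",
         signif(res$spacing, 3), " A exceeds the smallest atom radius)")
  structure(list(N = as.integer(N),
                 data = array(res$data, dim = c(N, N, N)),
                 origin = res$origin, spacing = res$spacing,
                 outer_radius = res$outer_radius),
            class = "zd_voxel_grid")
}

#' @export
print.zd_voxel_grid <- function(x, ...) {
  cat("<zd_voxel_grid> N = ", x$N, ", ", sum(x$data), " occupied voxels, ",
      "spacing = ", signif(x$spacing, 4), " A\n", sep = "")
  invisible(x)
}

#' Build a voxel grid directly from an occupancy array
#'
#' For synthetic voxel patterns (e.g. spherical shells) used in tests and
#' calibration.
#'
#' @param data 0/1 array with equal dimensions.
#' @param origin Coordinates of the first voxel center.
#' @param spacing Grid interval.
#' @return A `zd_voxel_grid`.
#' @export
as_voxel_grid <- function(data, origin = c(0, 0, 0), spacing = 1) {
  stopifnot(length(dim(data)) == 3, length(unique(dim(data))) == 1,
            all(data %in% c(0, 1)), spacing > 0)
  structure(list(N = dim(data)[1], data = data, origin = origin,
                 spacing = spacing), class = "zd_voxel_grid")
}

#' Export a mesh as ASCII OFF or PLY
#'
#' @param mesh A `zd_mesh`.
#' @param path Output file.
#' @param format `"off"` or `"ply"`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("off", "ply")) {
  stopifnot(inherits(mesh, "zd_mesh"))
  format <- match.arg(format)
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh$vertices
  f <- mesh$faces - 1L  # 0-based in both formats
  if (format == "off") {
    writeLines(c("OFF", paste(mesh$n_vertices, mesh$n_faces, 0)), con)
    writeLines(sprintf("%.6f %.6f %.6f", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  } else {
    writeLines(c("ply", "format ascii 1.0",
                 paste("element vertex", mesh$n_vertices),
                 "property float x", "property float y", "property float z",
                 paste("element face", mesh$n_faces),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(sprintf("%.6f %.6f %.6f", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  }
  invisible(path)
}

#' Export a voxel grid
#'
#' Writes a JSON header (`N`, `origin`, `spacing`) next to a flat text file
#' of 0/1 values in column-major order.
#'
#' @param grid A `zd_voxel_grid`.
#' @param path Output path for the data file; the header is written to
#'   `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_voxel_grid <- function(grid, path) {
  stopifnot(inherits(grid, "zd_voxel_grid"))
  jsonlite::write_json(list(N = grid$N, origin = grid$origin,
                            spacing = grid$spacing),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  writeLines(paste(as.integer(grid$data), collapse = " "), path)
  invisible(path)
}
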