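#' Number of rotation invariants up to a given order
#'
#' Counts the (n, l) index pairs with 0 <= l <= n <= order and n - l even;
#' each pair contributes one invariant F_nl. Order 20 gives the standard
#' 121-component descriptor.
#'
#' @param order Maximum expansion order n_max (non-negative integer).
#' @return Integer count.
#' @export
descriptor_length <- function(order) {
  if (length(order) != 1L || is.na(order) || order < 0)
    stop("order must be a single non-negative integer")
  order <- as.integer(order)
  sum(vapply(0:order, function(n) n %/% 2L + 1L, integer(1)))
}

# (n, l) index table in lexicographic (n asc, l asc) order
zernike_nl_table <- function(order) {
  idx <- do.call(rbind, lapply(0:order, function(n) {
    l <- seq(n %% 2L, n, by = 2L)
    cbind(n = rep.int(n, length(l)), l = l)
  }))
  as.data.frame(idx)
}

# Canterakis radial polynomial coefficients: R_nl(r) = sum_v q[v+1] r^(l+2v),
# v = 0..k, k = (n-l)/2, normalized so that 3 * int_0^1 R_nl R_n'l r^2 dr
# = delta_nn' (making Z_nl^m = R_nl Y_lm orthonormal under (3/4pi) int over
# the unit ball with unit-normalized spherical harmonics).
zernike_radial_coeffs <- function(n, l) {
  k <- (n - l) %/% 2L
  pref <- (-1)^k / 4^k * sqrt((2 * l + 4 * k + 3) / 3) * choose(2 * k, k)
  v <- 0:k
  pref * (-1)^v * choose(k, v) * choose(2 * (k + l + v) + 1, 2 * k) /
    choose(k + l + v, k)
}

# Evaluate R_nl at radii r (vector)
zernike_radial <- function(n, l, r) {
  q <- zernike_radial_coeffs(n, l)
  k <- (n - l) %/% 2L
  out <- numeric(length(r))
  rp <- r^l
  for (v in 0:k) {
    out <- out + q[v + 1L] * rp
    rp <- rp * r * r
  }
  out
}

# Normalized associated Legendre functions Pbar_l^m(x) for all
# 0 <= m <= l <= lmax, with the Condon-Shortley phase, scaled so that
# Y_l^m(theta, phi) = Pbar_l^m(cos theta) * exp(i m phi) satisfies
# int |Y|^2 dOmega = 4 pi; combined with the radial normalization this
# makes Z_nl^m = R_nl Y_l^m orthonormal under the (3 / 4 pi) * integral
# inner product of the moment definition.  Stable three-term recursion.
# Returns a list indexed [[l * (lmax + 1) + m + 1]] of vectors along x.
normalized_legendre <- function(lmax, x) {
  sint <- sqrt(pmax(0, 1 - x * x))
  P <- vector("list", (lmax + 1L)^2)
  key <- function(l, m) l * (lmax + 1L) + m + 1L
  P[[key(0L, 0L)]] <- rep.int(1, length(x))
  if (lmax >= 1L) {
    for (m in 1:lmax)
      P[[key(m, m)]] <- -sqrt((2 * m + 1) / (2 * m)) * sint * P[[key(m - 1L, m - 1L)]]
    for (m in 0:(lmax - 1L))
      P[[key(m + 1L, m)]] <- sqrt(2 * m + 3) * x * P[[key(m, m)]]
    if (lmax >= 2L) {
      for (m in 0:(lmax - 2L)) {
        for (l in (m + 2L):lmax) {
          a <- sqrt((4 * l^2 - 1) / (l^2 - m^2))
          b <- sqrt(((l - 1)^2 - m^2) / (4 * (l - 1)^2 - 1))
          P[[key(l, m)]] <- a * (x * P[[key(l - 1L, m)]] - b * P[[key(l - 2L, m)]])
        }
      }
    }
  }
  P
}

#' Map a voxel grid into the unit ball
#'
#' Occupied voxel centers are translated so their centroid sits at the
#' origin and scaled to radius `scale_margin` (default 0.6, keeping the
#' shape strictly inside the unit ball where the Zernike-Canterakis basis
#' is orthonormal). For plain grids the scale maps the farthest occupied
#' voxel center to `scale_margin` exactly. Grids produced by
#' [voxelize_surface()] carry a rotation-invariant `outer_radius` (maximal
#' possible shell radius, derived from the mesh size and the cutoff); when
#' present it is used as the reference radius instead, because the
#' farthest *occupied voxel center* wobbles by a fraction of a voxel as the
#' object is rotated against the grid, and that jitter would otherwise
#' leak into every descriptor component. The quadrature weight carried
#' along is the voxel volume in the rescaled coordinates.
#'
#' @param grid A `zd_voxel_grid`.
#' @param scale_margin Target radius of the mapped point set
#'   (0 < margin < 1).
#' @return A `zd_field`: list with `points` (k x 3 matrix, |x| <= margin),
#'   `weight` (scalar voxel volume) and `n` (number of occupied voxels).
#' @export
normalize_grid <- function(grid, scale_margin = 0.6) {
  stopifnot(inherits(grid, "zd_voxel_grid"),
            scale_margin > 0, scale_margin < 1)
  occ <- which(grid$data == 1)
  if (length(occ) == 0L) stop("voxel grid has no occupied voxels")
  idx <- arrayInd(occ, dim(grid$data)) - 1L
  pts <- sweep(idx * grid$spacing, 2, grid$origin, "+")
  center <- colMeans(pts)
  pts <- sweep(pts, 2, center, "-")
  rmax <- sqrt(max(rowSums(pts^2)))
  # stable reference: the grid-derived outer shell radius when available,
  # never smaller than the observed radius so all points stay in the ball
  rref <- if (!is.null(grid$outer_radius)) max(rmax, grid$outer_radius) else rmax
  scale <- if (rref > 0) scale_margin / rref else 1
  structure(list(points = pts * scale,
                 weight = (grid$spacing * scale)^3,
                 n = length(occ)),
            class = "zd_field")
}

#' Construct a unit-ball field from explicit points
#'
#' @param points k x 3 matrix of points with |x| < 1.
#' @param weight Quadrature weight per point.
#' @return A `zd_field`.
#' @export
as_zd_field <- function(points, weight = 1) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3)
  structure(list(points = points, weight = weight, n = nrow(points)),
            class = "zd_field")
}

#' 3D Zernike moments of a unit-ball field
#'
#' Projects the binary occupancy function onto the orthonormal
#' Zernike-Canterakis basis \eqn{Z_{nl}^m = R_{nl}(r) Y_l^m(\theta,\varphi)}:
#' \deqn{\Omega_{nl}^m = \frac{3}{4\pi} \int_{|x| \le 1} f(x)
#'   \bar{Z}_{nl}^m(x)\, \mathrm{d}x,}
#' evaluated as a sum of \eqn{\bar{Z}} over occupied voxel centers times the
#' voxel-volume weight. Moments are computed for m >= 0 and completed by
#' the conjugation symmetry \eqn{\Omega_{nl}^{-m} = (-1)^m
#' \overline{\Omega_{nl}^{m}}}, which holds for any real-valued field.
#'
#' @param field A `zd_field` from [normalize_grid()] or [as_zd_field()].
#' @param order Maximum order n (default 20).
#' @return A `zd_moments`: list with `order` and `omega`, a list keyed
#'   `"n,l"` of complex vectors indexed m = -l..l (names give m).
#' @export
compute_moments <- function(field, order = 20) {
  stopifnot(inherits(field, "zd_field"), order >= 0)
  order <- as.integer(order)
  pts <- field$points
  r2 <- rowSums(pts^2)
  if (any(r2 >= 1))
    stop("field is not normalized: points with |x| >= 1 present")
  r <- sqrt(r2)
  ct <- ifelse(r > 0, pts[, 3] / r, 1)
  ct <- pmin(1, pmax(-1, ct))
  phi <- atan2(pts[, 2], pts[, 1])
  Pbar <- normalized_legendre(order, ct)
  key <- function(l, m) l * (order + 1L) + m + 1L

  w <- (3 / (4 * pi)) * field$weight
  nl <- zernike_nl_table(order)
  # precompute radial values grouped by l for speed
  omega <- vector("list", nrow(nl))
  names(omega) <- paste(nl$n, nl$l, sep = ",")
  for (l in unique(nl$l)) {
    ns <- nl$n[nl$l == l]
    # angular part conj(Y_lm) = Pbar * exp(-i m phi), m = 0..l
    ang <- vapply(0:l, function(m) Pbar[[key(l, m)]] * exp(-1i * m * phi),
                  complex(length(r)))
    ang <- matrix(ang, nrow = length(r))
    for (n in ns) {
      rad <- zernike_radial(n, l, r)
      om_pos <- w * as.vector(t(ang) %*% rad)  # length l+1, m = 0..l
      m_all <- (-l):l
      om <- complex(length(m_all))
      om[m_all >= 0] <- om_pos
      if (l > 0) {
        mneg <- m_all[m_all < 0]
        om[m_all < 0] <- (-1)^(-mneg) * Conj(om_pos[-mneg + 1L])
      }
      names(om) <- m_all
      omega[[paste(n, l, sep = ",")]] <- om
    }
  }
  structure(list(order = order, omega = omega), class = "zd_moments")
}

#' Rotation-invariant descriptor from Zernike moments
#'
#' Collapses each (2l+1)-vector of moments into its norm:
#' \deqn{F_{nl} = \sqrt{\sum_{m=-l}^{l} |\Omega_{nl}^m|^2}.}
#' The squared modulus (not the literal complex square) is used because only
#' the modulus form is real and invariant under rotations. Components are
#' ordered by (n ascending, l ascending).
#'
#' @param moments A `zd_moments`.
#' @param source_mode Atom-subset tag carried on the descriptor
#'   (`"full_atom"`, `"main_chain"`, or `NA`).
#' @param mesh_vertices,mesh_faces Mesh summary counts carried from the
#'   surface stage (0 when not applicable).
#' @return A `zd_descriptor`: list with `order`, `values` (named numeric
#'   vector, names `"n,l"`), `source_mode`, `mesh_vertices`, `mesh_faces`.
#' @export
zernike_invariants <- function(moments, source_mode = NA_character_,
                               mesh_vertices = 0L, mesh_faces = 0L) {
  stopifnot(inherits(moments, "zd_moments"))
  vals <- vapply(moments$omega, function(om) sqrt(sum(Mod(om)^2)), numeric(1))
  new_zd_descriptor(moments$order, vals, source_mode, mesh_vertices, mesh_faces)
}

new_zd_descriptor <- function(order, values, source_mode = NA_character_,
                              mesh_vertices = 0L, mesh_faces = 0L) {
  nl <- zernike_nl_table(order)
  if (is.null(names(values))) names(values) <- paste(nl$n, nl$l, sep = ",")
  stopifnot(length(values) == nrow(nl))
  structure(list(order = as.integer(order), values = values,
                 source_mode = source_mode,
                 mesh_vertices = as.integer(mesh_vertices),
                 mesh_faces = as.integer(mesh_faces)),
            class = "zd_descriptor")
}

#' @export
print.zd_descriptor <- function(x, ...) {
  cat("<zd_descriptor> order ", x$order, " (", length(x$values),
      " invariants), mode = ", x$source_mode, "\n", sep = "")
  invisible(x)
}

#' Compute the 3D Zernike descriptor of a protein structure
#'
#' Full pipeline: atom selection, surface triangulation, voxelization on an
#' N^3 grid, unit-ball normalization, moment computation and reduction to
#' rotation invariants. The mesh vertex/face counts are carried on the
#' returned descriptor.
#'
#' @param structure A `zd_structure`.
#' @param mode Atom subset, `"full_atom"` or `"main_chain"`.
#' @param order Expansion order (default 20, i.e. 121 invariants).
#' @param N Voxel grid size per axis (default 200).
#' @param probe_radius,resolution,cutoff Surface-stage parameters, see
#'   [triangulate_surface()] and [voxelize_surface()].
#' @return A `zd_descriptor`.
#' @export
compute_descriptor <- function(structure, mode = c("full_atom", "main_chain"),
                               order = 20, N = 200, probe_radius = 1.4,
                               resolution = 0.7, cutoff = 1.7) {
  mode <- match.arg(mode)
  atoms <- select_atoms(structure, mode)
  mesh <- triangulate_surface(atoms, probe_radius = probe_radius,
                              resolution = resolution)
  grid <- voxelize_surface(mesh, N = N, cutoff = cutoff)
  field <- normalize_grid(grid)
  moments <- compute_moments(field, order = order)
  zernike_invariants(moments, source_mode = mode,
                     mesh_vertices = mesh$n_vertices,
                     mesh_faces = mesh$n_faces)
}

#' Write a descriptor to a text file
#'
#' Line 1 holds the order, then one `"n l value"` line per invariant,
#' followed by a single compact line of all whitespace-separated values.
#' Mode and mesh counts are stored in `#`-prefixed header comments.
#'
#' @param d A `zd_descriptor`.
#' @param path Output file (conventionally `.inv`).
#' @return `path`, invisibly.
#' @export
write_descriptor <- function(d, path) {
  stopifnot(inherits(d, "zd_descriptor"))
  nl <- zernike_nl_table(d$order)
  lines <- c(sprintf("# mode %s", d$source_mode),
             sprintf("# mesh %d %d", d$mesh_vertices, d$mesh_faces),
             as.character(d$order),
             sprintf("%d %d %.17g", nl$n, nl$l, unname(d$values)),
             paste(sprintf("%.17g", unname(d$values)), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Read a descriptor written by [write_descriptor()]
#'
#' @param path Input file.
#' @return A `zd_descriptor`.
#' @export
read_descriptor <- function(path) {
  lines <- readLines(path, warn = FALSE)
  mode <- NA_character_
  mesh <- c(0L, 0L)
  hdr <- grep("^#", lines, value = TRUE)
  m <- regmatches(hdr, regexec("^# mode (\\S+)", hdr))
  for (mm in m) if (length(mm)) mode <- mm[2]
  m <- regmatches(hdr, regexec("^# mesh (\\d+) (\\d+)", hdr))
  for (mm in m) if (length(mm)) mesh <- as.integer(mm[2:3])
  body <- lines[!grepl("^#", lines)]
  order <- as.integer(body[1])
  D <- descriptor_length(order)
  rows <- strsplit(body[1 + seq_len(D)], "\\s+")
  vals <- vapply(rows, function(r) as.numeric(r[3]), numeric(1))
  names(vals) <- vapply(rows, function(r) paste(r[1], r[2], sep = ","),
                        character(1))
  if (mode %in% "NA") mode <- NA_character_
  new_zd_descriptor(order, vals, mode, mesh[1], mesh[2])
}
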