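# Synthetic fixtures with known ground truth: idealized backbones, random
# compact "blob" proteins, descriptor clusters standing in for folds, and
# pLDDT profiles with prescribed run/gap layout.  Every generator is a pure
# function of its arguments (seed included), so regeneration is
# bit-identical.

helix_backbone_offsets <- list(
  # idealized cylindrical offsets (radius A, phase deg, rise offset A)
  # relative to the CA trace of an alpha-helix
  N = c(r = 1.64, dphi = -26.0, dz = -0.60),
  CA = c(r = 2.30, dphi = 0.0, dz = 0.00),
  C = c(r = 1.63, dphi = 26.5, dz = 0.55),
  O = c(r = 2.00, dphi = 40.0, dz = 0.95))

#' Ideal poly-alanine alpha-helix
#'
#' Backbone atoms (N, CA, C, O) placed on an idealized helix with a rise of
#' 1.5 Angstrom and 100 degrees of twist per residue (CA radius 2.3 A),
#' giving the canonical 3.8 A consecutive CA-CA distance. With `jitter = 0`
#' the output is bit-identical regardless of `seed`.
#'
#' @param n_residues Number of residues (>= 5).
#' @param seed Seed for the coordinate jitter.
#' @param jitter Standard deviation of isotropic Gaussian coordinate noise
#'   in Angstrom (default 0).
#' @param bfactor Per-residue confidence value stored in the B-factor
#'   column (scalar or vector of length `n_residues`).
#' @return A `zd_structure`.
#' @export
make_ideal_helix <- function(n_residues, seed = 1, jitter = 0, bfactor = 90) {
  if (n_residues < 5) stop("a helix fixture needs at least 5 residues")
  bfactor <- rep_len(bfactor, n_residues)
  rows <- lapply(seq_len(n_residues), function(i) {
    theta0 <- (i - 1) * 100 * pi / 180
    z0 <- (i - 1) * 1.5
    do.call(rbind, lapply(names(helix_backbone_offsets), function(nm) {
      o <- helix_backbone_offsets[[nm]]
      th <- theta0 + o[["dphi"]] * pi / 180
      data.frame(element = substr(nm, 1, 1), name = nm,
                 x = o[["r"]] * cos(th), y = o[["r"]] * sin(th),
                 z = z0 + o[["dz"]], chain = "A", resno = i,
                 bfactor = bfactor[i], stringsAsFactors = FALSE)
    }))
  })
  atoms <- do.call(rbind, rows)
  if (jitter > 0) {
    atoms[, c("x", "y", "z")] <- atoms[, c("x", "y", "z")] +
      with_seed(seed, matrix(rnorm(3 * nrow(atoms), sd = jitter), ncol = 3))
  }
  as_zd_structure(atoms, id = sprintf("helix%d", n_residues))
}

#' Ideal antiparallel beta-sheet
#'
#' Strands are extended zigzag CA traces (consecutive CA-CA 3.8 A,
#' i to i+2 distance 6.7 A) laid side by side 4.8 A apart in antiparallel
#' orientation; N and C atoms are interpolated along the trace.
#'
#' @param n_residues Residues per strand (>= 3).
#' @param n_strands Number of strands (default 2).
#' @param seed,jitter As in [make_ideal_helix()].
#' @param bfactor B-factor value(s) per residue.
#' @return A `zd_structure`.
#' @export
make_ideal_sheet <- function(n_residues, n_strands = 2, seed = 1, jitter = 0,
                             bfactor = 90) {
  if (n_residues < 3) stop("a sheet fixture needs at least 3 residues per strand")
  a <- 3.35   # half of the 6.7 A i,i+2 distance
  b <- sqrt((3.8^2 - a^2)) / 2  # pleat amplitude giving 3.8 A steps
  rows <- list()
  resno <- 0L
  for (s in seq_len(n_strands)) {
    direction <- if (s %% 2 == 1) 1 else -1
    y0 <- (s - 1) * 4.8
    xs <- (seq_len(n_residues) - 1) * a * direction
    if (direction < 0) xs <- xs + (n_residues - 1) * a
    zs <- b * (-1)^(seq_len(n_residues) - 1)
    for (i in seq_len(n_residues)) {
      resno <- resno + 1L
      ca <- c(xs[i], y0, zs[i])
      step <- c(a * direction, 0, 0)
      rows[[length(rows) + 1L]] <- data.frame(
        element = c("N", "C", "C"), name = c("N", "CA", "C"),
        x = c(ca[1] - 0.38 * step[1], ca[1], ca[1] + 0.40 * step[1]),
        y = c(y0 - 0.3, y0, y0 + 0.3),
        z = c(ca[3] * 0.6, ca[3], ca[3] * 0.6),
        chain = "A", resno = resno, bfactor = rep_len(bfactor, 1),
        stringsAsFactors = FALSE)
    }
  }
  atoms <- do.call(rbind, rows)
  if (jitter > 0) {
    atoms[, c("x", "y", "z")] <- atoms[, c("x", "y", "z")] +
      with_seed(seed, matrix(rnorm(3 * nrow(atoms), sd = jitter), ncol = 3))
  }
  as_zd_structure(atoms, id = sprintf("sheet%dx%d", n_strands, n_residues))
}

#' Random compact "blob" protein
#'
#' A self-avoiding random CA walk (3.8 A steps, minimum 3.2 A contact
#' distance) confined to a sphere whose radius scales with n^(1/3),
#' mimicking a globular chain without any real secondary structure. N and C
#' atoms are interpolated between consecutive CA positions.
#'
#' @param n_residues Chain length (>= 5).
#' @param seed Random seed (mandatory for reproducibility).
#' @param bfactor B-factor value(s).
#' @return A `zd_structure`.
#' @export
make_blob_protein <- function(n_residues, seed = 1, bfactor = 90) {
  if (n_residues < 5) stop("a blob fixture needs at least 5 residues")
  radius <- 3.2 * n_residues^(1 / 3)
  ca <- with_seed(seed, {
    pos <- matrix(0, n_residues, 3)
    for (i in 2:n_residues) {
      for (attempt in 1:200) {
        d <- rnorm(3)
        cand <- pos[i - 1, ] + 3.8 * d / sqrt(sum(d^2))
        ok <- sqrt(sum(cand^2)) <= radius
        if (ok && i > 2) {
          dmin <- min(sqrt(rowSums(sweep(pos[1:(i - 2), , drop = FALSE], 2,
                                         cand)^2)))
          ok <- dmin >= 3.2
        }
        if (ok) { pos[i, ] <- cand; break }
        if (attempt == 200) pos[i, ] <- cand  # accept rather than fail
      }
    }
    pos
  })
  rows <- lapply(seq_len(n_residues), function(i) {
    prev <- if (i > 1) ca[i - 1, ] else ca[i, ] - c(3.8, 0, 0)
    nxt <- if (i < n_residues) ca[i + 1, ] else ca[i, ] + c(3.8, 0, 0)
    npos <- ca[i, ] + 0.38 * (prev - ca[i, ])
    cpos <- ca[i, ] + 0.40 * (nxt - ca[i, ])
    data.frame(element = c("N", "C", "C"), name = c("N", "CA", "C"),
               x = c(npos[1], ca[i, 1], cpos[1]),
               y = c(npos[2], ca[i, 2], cpos[2]),
               z = c(npos[3], ca[i, 3], cpos[3]),
               chain = "A", resno = i, bfactor = rep_len(bfactor, 1),
               stringsAsFactors = FALSE)
  })
  as_zd_structure(do.call(rbind, rows),
                  id = sprintf("blob%d_s%d", n_residues, seed))
}

#' Synthetic descriptor clusters standing in for folds
#'
#' Draws `n_folds` cluster centers uniformly on the non-negative orthant of
#' a sphere of radius `separation` in descriptor space, then samples
#' `per_fold` members per cluster as the center plus Gaussian noise,
#' clipped at zero (descriptors are non-negative by construction). Each
#' fold has its own noise scale, drawn once from
#' `noise * U(noise_spread[1], noise_spread[2])`: real folds differ widely
#' in how much surface-shape variability their members show, and it is
#' precisely this heteroscedasticity that makes a single global distance
#' threshold underperform a learned pair comparator. Setting
#' `noise_spread = c(1, 1)` recovers homogeneous clusters.
#'
#' @param n_folds Number of clusters.
#' @param per_fold Members per cluster.
#' @param dim Descriptor length (default 121, matching order 20).
#' @param separation Radius Delta of the sphere the centers sit on.
#' @param noise Base within-cluster noise sigma (>= 0).
#' @param noise_spread Range of the per-fold noise multiplier.
#' @param seed Random seed (mandatory).
#' @return List with `descriptors` (list of `zd_descriptor`), `labels`
#'   (character fold ids `"f01"`, ...), `centers` (matrix), `fold_sigmas`.
#' @export
make_descriptor_clusters <- function(n_folds, per_fold, dim = 121,
                                     separation = 3, noise = 0.15,
                                     noise_spread = c(0.3, 2.5), seed = 1) {
  stopifnot(separation > 0, noise >= 0, n_folds >= 1, per_fold >= 1,
            length(noise_spread) == 2, noise_spread[1] <= noise_spread[2])
  order <- order_for_length(dim)
  with_seed(seed, {
    centers <- matrix(abs(rnorm(n_folds * dim)), n_folds, dim)
    centers <- centers / sqrt(rowSums(centers^2)) * separation
    sigmas <- noise * runif(n_folds, noise_spread[1], noise_spread[2])
    descriptors <- list()
    labels <- character(0)
    for (f in seq_len(n_folds)) {
      for (j in seq_len(per_fold)) {
        v <- pmax(0, centers[f, ] + rnorm(dim, sd = sigmas[f]))
        d <- new_zd_descriptor(order, v)
        descriptors[[length(descriptors) + 1L]] <- d
        labels <- c(labels, sprintf("f%02d", f))
      }
    }
    list(descriptors = descriptors, labels = labels, centers = centers,
         fold_sigmas = sigmas)
  })
}

# smallest order whose descriptor length is >= dim; exact for standard dims
order_for_length <- function(dim) {
  for (o in 0:200) if (descriptor_length(o) >= dim) {
    if (descriptor_length(o) != dim)
      stop("dim = ", dim, " is not a valid descriptor length")
    return(o)
  }
  stop("dim too large")
}

#' Synthetic pLDDT profile with a prescribed run layout
#'
#' Concatenates constant runs of given lengths and levels; optional jitter
#' perturbs values without ever crossing the 70.0 confidence boundary, so
#' the domain-extraction ground truth of the layout is preserved exactly.
#' A level of exactly 70 is refused: the extraction rule is strict
#' (`> 70`), and fixtures must not sit on the ambiguous boundary.
#'
#' @param layout List of `c(run_length, level)` pairs (or a 2-column
#'   matrix), levels on the 0-100 scale.
#' @param seed Seed for the jitter.
#' @param jitter Maximum absolute perturbation (uniform), truncated so no
#'   value crosses 70.
#' @return A `zd_confidence_profile` (numeric vector).
#' @export
make_plddt_profile <- function(layout, seed = 1, jitter = 0) {
  if (is.matrix(layout)) layout <- lapply(seq_len(nrow(layout)),
                                          function(i) layout[i, ])
  lens <- vapply(layout, function(p) p[1], numeric(1))
  levels <- vapply(layout, function(p) p[2], numeric(1))
  stopifnot(all(lens >= 1), all(levels >= 0 & levels <= 100))
  if (any(levels == 70))
    stop("a run level of exactly 70.0 is ambiguous under the strict ",
         "confidence rule; pick a value above or below it")
  vals <- rep(levels, times = lens)
  if (jitter > 0) {
    room <- pmin(jitter, abs(vals - 70) * 0.99, vals, 100 - vals)
    vals <- vals + with_seed(seed, runif(length(vals), -1, 1)) * room
  }
  structure(vals, class = "zd_confidence_profile")
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}
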