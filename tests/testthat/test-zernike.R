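test_that("descriptor length counts the (n, l) parity pairs", {
  expect_equal(descriptor_length(20), 121)
  expect_equal(descriptor_length(0), 1)
  # independent enumeration
  enum <- function(o) {
    g <- expand.grid(n = 0:o, l = 0:o)
    sum(g$l <= g$n & (g$n - g$l) %% 2 == 0)
  }
  expect_equal(descriptor_length(5), 12)
  expect_equal(descriptor_length(5), enum(5))
  for (o in c(0:8, 13, 20)) expect_equal(descriptor_length(o), enum(o))
  expect_error(descriptor_length(-1), "non-negative")
})

test_that("moment/descriptor index sets match the analytic count at all orders", {
  for (o in 0:20) {
    nl <- zdsurf:::zernike_nl_table(o)
    expect_equal(nrow(nl), descriptor_length(o))
    expect_true(all(nl$l <= nl$n & (nl$n - nl$l) %% 2 == 0))
    # lexicographic (n asc, l asc)
    expect_true(!is.unsorted(nl$n))
  }
  f <- as_zd_field(matrix(c(0.1, 0.2, 0.1), 1), 1)
  m <- compute_moments(f, order = 6)
  expect_equal(length(m$omega), descriptor_length(6))
  lens <- vapply(m$omega, length, integer(1))
  nl <- zdsurf:::zernike_nl_table(6)
  expect_equal(unname(lens), 2 * nl$l + 1)
})

test_that("grid normalization centers, scales and is translation invariant", {
  a <- array(0L, dim = c(8, 8, 8))
  a[2, 4, 4] <- 1L; a[7, 4, 4] <- 1L
  f <- normalize_grid(as_voxel_grid(a), scale_margin = 0.6)
  expect_equal(sort(f$points[, 1]), c(-0.6, 0.6), tolerance = 1e-12)
  expect_equal(f$points[, 2], c(0, 0), tolerance = 1e-12)

  b <- array(0L, dim = c(16, 16, 16))
  b[3:6, 4, 5] <- 1L
  b2 <- array(0L, dim = c(16, 16, 16))
  b2[8:11, 9, 10] <- 1L  # same pattern translated by 5 voxels
  f1 <- normalize_grid(as_voxel_grid(b))
  f2 <- normalize_grid(as_voxel_grid(b2))
  expect_equal(f1$points, f2$points, tolerance = 1e-12)

  set.seed(4)
  r <- array(as.integer(runif(12^3) < 0.1), dim = c(12, 12, 12))
  fr <- normalize_grid(as_voxel_grid(r))
  expect_equal(sqrt(max(rowSums(fr$points^2))), 0.6, tolerance = 1e-12)
  expect_error(normalize_grid(as_voxel_grid(array(0L, dim = c(4, 4, 4)))),
               "no occupied")
})

test_that("moments vanish for l > 0 at the origin and obey conjugation symmetry", {
  f0 <- as_zd_field(matrix(0, 1, 3), 1)
  m0 <- compute_moments(f0, order = 6)
  for (key in names(m0$omega)) {
    nl <- as.integer(strsplit(key, ",")[[1]])
    if (nl[2] > 0) expect_equal(max(Mod(m0$omega[[key]])), 0)
  }
  expect_gt(Mod(m0$omega[["0,0"]][["0"]]), 0)

  set.seed(8)
  pts <- matrix(runif(90, -0.5, 0.5), ncol = 3)
  m <- compute_moments(as_zd_field(pts, 0.01), order = 8)
  for (key in c("5,3", "8,4", "7,7")) {
    om <- m$omega[[key]]
    l <- as.integer(strsplit(key, ",")[[1]][2])
    for (mm in 1:l)
      expect_lt(Mod(om[[as.character(-mm)]] -
                      (-1)^mm * Conj(om[[as.character(mm)]])), 1e-10)
  }
  expect_error(compute_moments(as_zd_field(matrix(c(1.2, 0, 0), 1), 1), 4),
               "not normalized")
})

test_that("moments agree with independent dense-quadrature evaluation", {
  skip_if_not_installed("pracma")
  set.seed(12)
  pts <- matrix(runif(300, -0.45, 0.45), ncol = 3)  # 100-point field
  w <- 0.002
  m <- compute_moments(as_zd_field(pts, w), order = 8)
  nl <- zdsurf:::zernike_nl_table(8)
  for (r in seq_len(nrow(nl))) {
    n <- nl$n[r]; l <- nl$l[r]
    for (mm in 0:l) {
      expect_lt(Mod(m$omega[[paste(n, l, sep = ",")]][[as.character(mm)]] -
                      oracle_moment(n, l, mm, pts, w)),
                1e-6)
    }
  }
})

test_that("the discretized basis is orthonormal on the unit ball", {
  # dense cartesian quadrature over the ball, orders <= 6
  h <- 1 / 26
  ax <- seq(-1 + h / 2, 1 - h / 2, by = h)
  gr <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  gr <- gr[rowSums(gr^2) < (1 - 1e-9), ]
  w <- h^3 * 3 / (4 * pi)
  r <- sqrt(rowSums(gr^2))
  ct <- gr[, 3] / r
  phi <- atan2(gr[, 2], gr[, 1])
  P <- zdsurf:::normalized_legendre(6, ct)
  key <- function(l, m) l * 7 + m + 1
  zval <- function(n, l, m)
    zdsurf:::zernike_radial(n, l, r) * P[[key(l, m)]] * exp(1i * m * phi)
  cases <- list(c(0, 0, 0), c(2, 0, 0), c(4, 2, 1), c(5, 3, 2), c(6, 6, 4),
                c(6, 2, 0))
  for (a in cases) {
    za <- zval(a[1], a[2], a[3])
    self <- w * sum(za * Conj(za))
    expect_equal(Mod(self), 1, tolerance = 0.02)
    for (b in cases) {
      if (identical(a, b)) next
      cross <- w * sum(za * Conj(zval(b[1], b[2], b[3])))
      expect_lt(Mod(cross), 0.02)
    }
  }
})

test_that("invariants reduce moment blocks to rotation-invariant norms", {
  # all-zero moments -> all-zero descriptor
  f0 <- as_zd_field(matrix(0, 1, 3), 0)
  d0 <- zernike_invariants(compute_moments(f0, 4))
  expect_true(all(d0$values == 0))

  # a single nonzero moment Omega_20^0 = 3 + 4i gives F_20 = 5
  m <- compute_moments(f0, 4)
  m$omega[["2,0"]][["0"]] <- complex(real = 3, imaginary = 4)
  d <- zernike_invariants(m)
  expect_equal(unname(d$values[["2,0"]]), 5)

  # spherically symmetric shell: all l > 0 invariants are near zero
  set.seed(2)
  u <- matrix(rnorm(3 * 20000), ncol = 3)
  u <- u / sqrt(rowSums(u^2)) * 0.5
  ds <- zernike_invariants(compute_moments(as_zd_field(u, 1), 8))
  l0 <- grepl(",0$", names(ds$values))
  expect_lt(sum(ds$values[!l0]) / sum(ds$values), 0.05)
  expect_gt(sum(ds$values[l0]), 0)
})

test_that("the full descriptor pipeline is finite, mode-sensitive and rotation stable", {
  h <- make_ideal_helix(20)
  d <- compute_descriptor(h, "main_chain", order = 20, N = 48)
  expect_equal(length(d$values), 121)
  expect_true(all(is.finite(d$values)))
  expect_gt(sum(d$values), 0)
  expect_equal(d$source_mode, "main_chain")
  expect_gt(d$mesh_vertices, 0)

  dfa <- compute_descriptor(h, "full_atom", order = 20, N = 48)
  expect_gt(sqrt(sum((dfa$values - d$values)^2)), 0)

  set.seed(31)
  d2 <- compute_descriptor(rotate_structure(h, rand_rotation()),
                           "main_chain", order = 20, N = 48)
  expect_gt(cosine_sim(d$values, d2$values), 0.99)
})

test_that("descriptor files round-trip through the text format", {
  h <- make_ideal_helix(12)
  d <- compute_descriptor(h, "main_chain", order = 8, N = 32)
  f <- tempfile(fileext = ".inv")
  write_descriptor(d, f)
  d2 <- read_descriptor(f)
  expect_equal(d2$order, 8)
  expect_equal(d2$values, d$values)
  expect_equal(d2$source_mode, "main_chain")
  expect_equal(d2$mesh_vertices, d$mesh_vertices)
  # compact final line holds all values
  lines <- readLines(f)
  expect_equal(as.numeric(strsplit(lines[length(lines)], " ")[[1]]),
               unname(d$values))
})
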