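# Shared helpers: fixed-format fixture writers and independent oracles.
# Oracles are deliberately written along different routes than the package
# code they check.

# uniform random rotation matrix (quaternion method)
rand_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  matrix(c(1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
           2 * (q[2] * q[4] + q[1] * q[3]),
           2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
           2 * (q[3] * q[4] - q[1] * q[2]),
           2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]),
           1 - 2 * (q[2]^2 + q[3]^2)), 3, 3)
}

rotate_structure <- function(s, R) {
  s$atoms[, c("x", "y", "z")] <-
    as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(R)
  s
}

# hand-built fixed-column PDB ATOM line
pdb_atom_line <- function(serial, name, alt, resn, chain, resno, x, y, z,
                          occ, b, elem) {
  sprintf("ATOM  %5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, ifelse(nchar(name) < 4, paste0(" ", name), name),
          alt, resn, chain, resno, x, y, z, occ, b, elem)
}

# minimal mmCIF with an atom_site loop mirroring pdb_atom_line records
write_mmcif <- function(path, atoms) {
  lines <- c("data_fixture", "#", "loop_",
             "_atom_site.group_PDB", "_atom_site.id",
             "_atom_site.type_symbol", "_atom_site.label_atom_id",
             "_atom_site.label_alt_id", "_atom_site.label_comp_id",
             "_atom_site.label_asym_id", "_atom_site.label_entity_id",
             "_atom_site.label_seq_id", "_atom_site.pdbx_PDB_ins_code",
             "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
             "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
             "_atom_site.pdbx_formal_charge", "_atom_site.auth_seq_id",
             "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
             "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num")
  for (i in seq_len(nrow(atoms))) {
    a <- atoms[i, ]
    lines <- c(lines, sprintf(
      "ATOM %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f %.2f %.2f ? %d %s %s %s 1",
      i, a$element, a$name, a$resn, a$chain, a$resno, a$x, a$y, a$z,
      a$occ, a$b, a$resno, a$resn, a$chain, a$name))
  }
  writeLines(c(lines, "#"), path)
  path
}

# independent point-to-triangle distance: project on the plane, clamp to
# the three edges, take the minimum candidate (different formulation than
# the region-based routine in the package)
pt_tri_dist_oracle <- function(p, a, b, c) {
  seg_dist <- function(p, u, v) {
    w <- v - u
    t <- sum((p - u) * w) / sum(w * w)
    t <- min(1, max(0, t))
    sqrt(sum((p - (u + t * w))^2))
  }
  n <- pracma::cross(b - a, c - a)
  cands <- c(seg_dist(p, a, b), seg_dist(p, b, c), seg_dist(p, c, a))
  nn <- sum(n * n)
  if (nn > 0) {
    n <- n / sqrt(nn)
    q <- p - sum((p - a) * n) * n  # projection onto the triangle plane
    # inside test via barycentric coordinates
    v0 <- c - a; v1 <- b - a; v2 <- q - a
    d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
    d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
    den <- d00 * d11 - d01 * d01
    if (den > 0) {
      u <- (d11 * d20 - d01 * d21) / den
      v <- (d00 * d21 - d01 * d20) / den
      if (u >= 0 && v >= 0 && u + v <= 1) cands <- c(cands, sqrt(sum((p - q)^2)))
    }
  }
  min(cands)
}

# exhaustive voxelization oracle over every grid center
voxelize_oracle <- function(mesh, grid) {
  N <- grid$N
  occ <- array(0L, dim = c(N, N, N))
  cut <- 1.7 * grid$spacing
  for (k in 1:N) for (j in 1:N) for (i in 1:N) {
    p <- grid$origin + (c(i, j, k) - 1) * grid$spacing
    dmin <- Inf
    for (f in seq_len(mesh$n_faces)) {
      d <- pt_tri_dist_oracle(p, mesh$vertices[mesh$faces[f, 1], ],
                              mesh$vertices[mesh$faces[f, 2], ],
                              mesh$vertices[mesh$faces[f, 3], ])
      if (d < dmin) dmin <- d
    }
    if (dmin < cut) occ[i, j, k] <- 1L
  }
  occ
}

# naive quadratic-scan domain extraction oracle: enumerate runs by explicit
# loops, merge by repeated pairwise passes until nothing changes
naive_domains <- function(vals, plddt_min = 70, min_run = 50, merge_gap = 5) {
  n <- length(vals)
  runs <- list()
  i <- 1
  while (i <= n) {
    if (vals[i] > plddt_min) {
      j <- i
      while (j < n && vals[j + 1] > plddt_min) j <- j + 1
      if (j - i + 1 > min_run) runs[[length(runs) + 1]] <- c(i, j)
      i <- j + 1
    } else i <- i + 1
  }
  if (!length(runs)) return(matrix(numeric(0), ncol = 2))
  reg <- do.call(rbind, runs)
  repeat {
    changed <- FALSE
    if (nrow(reg) >= 2) {
      for (k in 1:(nrow(reg) - 1)) {
        if (reg[k + 1, 1] - reg[k, 2] - 1 <= merge_gap) {
          reg[k, 2] <- reg[k + 1, 2]
          reg <- reg[-(k + 1), , drop = FALSE]
          changed <- TRUE
          break
        }
      }
    }
    if (!changed) break
  }
  reg
}

# independent Zernike basis evaluation for the moment oracle:
# radial polynomials by Gram-Schmidt orthonormalization of monomials
# r^(l+2v) under the inner product 3 * int_0^1 f g r^2 dr (exact monomial
# moments), spherical harmonics from pracma's associated Legendre tables.
oracle_radial_coefs <- function(n, l) {
  k <- (n - l) %/% 2
  pow <- l + 2 * (0:k)
  # Gram matrix of monomials: 3 * int r^(a+b+2) dr = 3 / (a + b + 3)
  G <- outer(pow, pow, function(a, b) 3 / (a + b + 3))
  L <- chol(G)  # G = t(L) %*% L, L upper triangular
  # coefficients of the (k+1)-th orthonormal polynomial
  co <- backsolve(L, diag(k + 1)[, k + 1, drop = FALSE])[, 1]
  if (sum(co) < 0) co <- -co  # sign convention: positive value at r = 1
  co
}

oracle_zernike_eval <- function(n, l, m, pts) {
  # returns Z_nl^m at rows of pts (complex); m >= 0
  r <- sqrt(rowSums(pts^2))
  ct <- ifelse(r > 0, pts[, 3] / r, 1)
  phi <- atan2(pts[, 2], pts[, 1])
  co <- oracle_radial_coefs(n, l)
  pow <- l + 2 * (0:((n - l) %/% 2))
  R <- sapply(seq_along(r), function(i) sum(co * r[i]^pow))
  # pracma::legendre includes the Condon-Shortley phase (MATLAB convention);
  # harmonics normalized to int |Y|^2 dOmega = 4 pi, matching the basis
  norm <- sqrt((2 * l + 1) * factorial(l - m) / factorial(l + m))
  P <- pracma::legendre(l, ct)
  Plm <- if (l == 0) as.numeric(P) else P[m + 1, ]
  R * norm * Plm * exp(1i * m * phi)
}

oracle_moment <- function(n, l, m, pts, weight) {
  (3 / (4 * pi)) * weight * sum(Conj(oracle_zernike_eval(n, l, m, pts)))
}

# spherical shell occupancy pattern on an N^3 grid (centered)
shell_grid <- function(N = 64, r_frac = 0.35, thick_frac = 0.06) {
  ax <- seq_len(N) - (N + 1) / 2
  d <- sqrt(outer(outer(ax^2, ax^2, "+"), ax^2, "+"))
  r0 <- r_frac * N
  as_voxel_grid(array(as.integer(abs(d - r0) < thick_frac * N), dim = c(N, N, N)))
}

# connected components of a mesh from shared vertices
mesh_components <- function(mesh) {
  parent <- seq_len(mesh$n_vertices)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (f in seq_len(mesh$n_faces)) {
    a <- find(mesh$faces[f, 1]); b <- find(mesh$faces[f, 2]); c <- find(mesh$faces[f, 3])
    parent[b] <- a; parent[c] <- a
  }
  length(unique(vapply(seq_len(mesh$n_vertices), find, integer(1))))
}

mesh_euler <- function(mesh) {
  edges <- rbind(mesh$faces[, c(1, 2)], mesh$faces[, c(2, 3)],
                 mesh$faces[, c(1, 3)])
  edges <- t(apply(edges, 1, sort))
  n_edges <- nrow(unique(edges))
  mesh$n_vertices - n_edges + mesh$n_faces
}

cosine_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# balanced positive/negative pair table from cluster labels
make_pair_table <- function(idx, labels, n_neg_ratio = 1, seed = 1) {
  pos <- do.call(rbind, lapply(split(idx, labels[idx]), function(g)
    if (length(g) >= 2) t(combn(g, 2)) else NULL))
  set.seed(seed)
  neg <- matrix(0, 0, 2)
  while (nrow(neg) < nrow(pos) * n_neg_ratio) {
    cand <- matrix(sample(idx, 2 * nrow(pos), replace = TRUE), ncol = 2)
    cand <- cand[labels[cand[, 1]] != labels[cand[, 2]], , drop = FALSE]
    neg <- rbind(neg, cand)
  }
  neg <- neg[seq_len(nrow(pos) * n_neg_ratio), , drop = FALSE]
  data.frame(i = c(pos[, 1], neg[, 1]), j = c(pos[, 2], neg[, 2]),
             label = rep(c(1, 0), c(nrow(pos), nrow(neg))))
}
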