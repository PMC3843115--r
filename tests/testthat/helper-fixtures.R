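# Shared fixtures, memoized across test files to keep the suite fast.
.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# A small but fully structured segment (about 2.4k elements) for unit tests.
mini_spec <- function(seed = 7L) {
  phantom_spec(body_radius_lat = 8.4, body_radius_ap = 7.0,
               body_height = 8.4, disc_height = 4.2, housing_height = 2.8,
               seed = seed)
}

mini_phantom <- function() memo("mini_phantom", generate_phantom(mini_spec()))

mini_cemented_labels <- function() {
  memo("mini_cem", add_cement_region(mini_phantom()$labels, "L1", 0.2))
}

# The full-size default phantom used by the acceptance suite.
default_phantom <- function() memo("default_phantom", generate_phantom(phantom_spec()))

# Homogeneous bone column: nx x ny x nz voxels of constant greyscale (so the
# identity calibration gives E = grey), labelled as one trabecular block.
# With bone_nu = 0 its stiffness is exactly E * A / L.
column_model <- function(nx = 1, ny = 1, nz = 1, grey = 100, h = 1,
                         nu = 0, loading = "locked",
                         grey_profile = NULL) {
  img <- array(grey, c(nx, ny, nz))
  if (!is.null(grey_profile)) {
    for (k in seq_len(nz)) img[, , k] <- grey_profile[k]
  }
  labs <- label_map(array(1L, c(nx, ny, nz)), voxel_size = h,
                    labels = c(trabecular_T12 = 1L))
  mats <- default_materials()
  mats$bone_nu <- nu
  cfg <- model_config(materials = mats, loading = loading)
  build_model(voxel_image(img, h), labs, cfg)
}

# Independent dense reference solver: 3x3x3 Gauss quadrature element
# matrices built from scratch, dense assembly, base-R elimination of the
# prescribed dofs. Deliberately shares no code path with the package solver.
dense_reference_k <- function(Evec, dims, h, nu, delta = 0.01) {
  nel <- prod(dims)
  stopifnot(length(Evec) == nel)
  # trilinear shape gradients at an arbitrary local point
  grad <- function(xi, et, ze) {
    sx <- c(-1, 1, 1, -1, -1, 1, 1, -1)
    sy <- c(-1, -1, 1, 1, -1, -1, 1, 1)
    sz <- c(-1, -1, -1, -1, 1, 1, 1, 1)
    cbind(sx * (1 + et * sy) * (1 + ze * sz),
          sy * (1 + xi * sx) * (1 + ze * sz),
          sz * (1 + xi * sx) * (1 + et * sy)) / 8 * (2 / h)
  }
  gl <- c(-sqrt(3 / 5), 0, sqrt(3 / 5))
  gw <- c(5 / 9, 8 / 9, 5 / 9)
  lam <- nu / ((1 + nu) * (1 - 2 * nu))
  mu <- 1 / (2 * (1 + nu))
  C1 <- matrix(0, 6, 6); C1[1:3, 1:3] <- lam
  diag(C1)[1:3] <- lam + 2 * mu; diag(C1)[4:6] <- mu
  ke1 <- matrix(0, 24, 24)
  for (a in 1:3) for (b in 1:3) for (c in 1:3) {
    G <- grad(gl[a], gl[b], gl[c])
    B <- matrix(0, 6, 24)
    for (i in 1:8) {
      c0 <- 3 * (i - 1)
      B[1, c0 + 1] <- G[i, 1]; B[2, c0 + 2] <- G[i, 2]; B[3, c0 + 3] <- G[i, 3]
      B[4, c0 + 2] <- G[i, 3]; B[4, c0 + 3] <- G[i, 2]
      B[5, c0 + 1] <- G[i, 3]; B[5, c0 + 3] <- G[i, 1]
      B[6, c0 + 1] <- G[i, 2]; B[6, c0 + 2] <- G[i, 1]
    }
    ke1 <- ke1 + gw[a] * gw[b] * gw[c] * t(B) %*% C1 %*% B * (h / 2)^3
  }
  nn <- (dims[1] + 1) * (dims[2] + 1) * (dims[3] + 1)
  nid <- function(i, j, k) ((k - 1) * (dims[2] + 1) + (j - 1)) * (dims[1] + 1) + i
  K <- matrix(0, 3 * nn, 3 * nn)
  for (lin in 1:nel) {  # linear order matches which(): first index fastest
    ind <- arrayInd(lin, dims)
    i <- ind[1]; j <- ind[2]; k <- ind[3]
    nodes <- c(nid(i, j, k), nid(i + 1, j, k), nid(i + 1, j + 1, k), nid(i, j + 1, k),
               nid(i, j, k + 1), nid(i + 1, j, k + 1), nid(i + 1, j + 1, k + 1),
               nid(i, j + 1, k + 1))
    dofs <- as.vector(rbind(3 * nodes - 2, 3 * nodes - 1, 3 * nodes))
    K[dofs, dofs] <- K[dofs, dofs] + Evec[lin] * ke1
  }
  kz <- rep(0:dims[3], each = (dims[1] + 1) * (dims[2] + 1))
  bot <- which(kz == 0); top <- which(kz == dims[3])
  u <- rep(NA_real_, 3 * nn)
  u[c(3 * bot - 2, 3 * bot - 1, 3 * bot)] <- 0
  u[3 * top - 2] <- 0; u[3 * top - 1] <- 0; u[3 * top] <- -delta
  fixed <- which(!is.na(u))
  free <- which(is.na(u))
  uf <- solve(K[free, free], -K[free, fixed] %*% u[fixed])
  u[free] <- uf
  r <- K %*% u
  list(k = -sum(r[3 * top]) / delta, u = u)
}

# Rotate a Voigt stress tensor (11,22,33,23,13,12) by a 3x3 rotation matrix.
rotate_stress <- function(s, Q) {
  S <- matrix(c(s[1], s[6], s[5],
                s[6], s[2], s[4],
                s[5], s[4], s[3]), 3, 3)
  S2 <- Q %*% S %*% t(Q)
  c(S2[1, 1], S2[2, 2], S2[3, 3], S2[2, 3], S2[1, 3], S2[1, 2])
}

random_rotation <- function() {
  M <- matrix(rnorm(9), 3, 3)
  qr_d <- qr(M)
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
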