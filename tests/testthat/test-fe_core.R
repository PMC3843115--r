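test_that("hex8 element stiffness is symmetric with six rigid-body modes", {
  ke <- element_stiffness_hex8(material_isotropic(100, 0.3), 1.4)
  expect_equal(ke, t(ke), tolerance = 1e-14)
  ev <- eigen(ke, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-8 * max(ev)), 6L)
  expect_true(all(ev > -1e-8 * max(ev)))
  # rigid translation produces zero force
  for (dir in 1:3) {
    u <- rep(0, 24); u[seq(dir, 24, by = 3)] <- 1
    expect_lt(max(abs(ke %*% u)), 1e-10 * max(abs(ke)))
  }
})

test_that("hex8 axial compression reproduces the EA/L spring", {
  # unit cube, E = 100, nu = 0: compress top face by delta
  ke <- element_stiffness_hex8(material_isotropic(100, 0), 1)
  delta <- 0.01
  u <- rep(0, 24)
  u[seq(15, 24, by = 3)] <- -delta  # uz of local nodes 5:8 (top face)
  f <- ke %*% u
  top_z <- seq(15, 24, by = 3)
  expect_equal(-sum(f[top_z]), 100 * delta, tolerance = 1e-12)
})

test_that("single-element column gives k = EA/L exactly", {
  m <- column_model(1, 1, 1, grey = 100, h = 1, nu = 0)
  res <- assemble_and_solve(m, 0.01)
  expect_equal(res$reaction, 1, tolerance = 1e-10)
  expect_equal(segment_stiffness(res)$k, 100, tolerance = 1e-10)
})

test_that("stacked column of alternating moduli matches the series-spring law", {
  prof <- c(100, 50, 100, 50, 100, 50)
  m <- column_model(2, 2, 6, h = 1, nu = 0, grey_profile = prof)
  res <- assemble_and_solve(m, 0.05)
  A <- 4
  k_exact <- 1 / sum(1 / (prof * A))
  expect_equal(res$k, k_exact, tolerance = 1e-8)
})

test_that("solutions scale linearly with the applied displacement", {
  m <- column_model(2, 2, 3, grey = 200, h = 1.4, nu = 0.3)
  r1 <- assemble_and_solve(m, 0.01)
  r2 <- assemble_and_solve(m, 0.02)
  expect_equal(r2$reaction, 2 * r1$reaction, tolerance = 1e-10)
  expect_equal(r2$U, 2 * r1$U, tolerance = 1e-9)
  expect_equal(r2$k, r1$k, tolerance = 1e-10)
})

test_that("homogeneous uniaxial compression yields the uniform stress state", {
  E <- 80; L <- 4; delta <- 0.02
  m <- column_model(3, 3, 4, grey = E, h = 1, nu = 0)
  res <- assemble_and_solve(m, delta)
  expected <- c(0, 0, -E * delta / L, 0, 0, 0)
  for (cmp in 1:6) {
    expect_equal(res$stress[, cmp], rep(expected[cmp], nrow(res$stress)),
                 tolerance = 1e-10)
  }
})

test_that("a linear displacement field is reproduced exactly (patch test)", {
  # irregular-modulus 2x2x2 block; impose u = A x on the boundary nodes and
  # check the recovered stress is the exact constant field
  set.seed(4)
  m <- column_model(2, 2, 2, h = 1, nu = 0.25,
                    grey_profile = c(100, 100))
  K <- fe_assemble(m)
  Amat <- matrix(c(2e-3, 1e-4, -2e-4,
                   1e-4, -1e-3, 3e-4,
                   -2e-4, 3e-4, 5e-4), 3, 3, byrow = TRUE)  # symmetric grad
  u_exact <- as.vector(t(m$node_xyz %*% t(Amat)))
  boundary <- which(rowSums(
    m$node_xyz == 0 | m$node_xyz == 2) > 0)
  fixed <- as.vector(rbind(3 * boundary - 2, 3 * boundary - 1, 3 * boundary))
  free <- setdiff(seq_len(3 * m$n_nodes), fixed)
  u <- u_exact
  if (length(free)) {
    u[free] <- as.vector(Matrix::solve(K[free, free],
                                       -K[free, fixed] %*% u_exact[fixed]))
  }
  res <- structure(list(U = matrix(u, ncol = 3, byrow = TRUE)),
                   class = "solve_result")
  sig <- element_stresses(res, m)
  eps_v <- c(diag(Amat), 2 * Amat[2, 3], 2 * Amat[1, 3], 2 * Amat[1, 2])
  C <- constitutive_matrix(material_isotropic(100, 0.25))
  sig_exact <- as.vector(C %*% eps_v)
  for (cmp in 1:6) {
    expect_equal(sig[, cmp], rep(sig_exact[cmp], nrow(sig)), tolerance = 1e-10)
  }
  # interior solution equals the linear field itself
  expect_equal(u, u_exact, tolerance = 1e-10)
})

test_that("assembled solve matches an independent dense first-principles solve", {
  set.seed(9)
  dims <- c(3, 3, 3)
  grey <- matrix(runif(27, 50, 300), nrow = 27)
  img <- array(grey, dims)
  labs <- label_map(array(1L, dims), 1, labels = c(trabecular_T12 = 1L))
  mats <- default_materials(); mats$bone_nu <- 0.3
  m <- build_model(voxel_image(img, 1), labs,
                   model_config(materials = mats, loading = "locked"))
  res <- assemble_and_solve(m, 0.01)
  ref <- dense_reference_k(as.vector(img), dims, 1, 0.3, delta = 0.01)
  expect_equal(res$k, ref$k, tolerance = 1e-8)
  expect_equal(as.vector(t(res$U)), ref$u, tolerance = 1e-8)
})

test_that("equilibrium holds and stiffness is monotone in element moduli", {
  ph <- mini_phantom()
  model <- build_model(ph$image, ph$labels)
  res <- assemble_and_solve(model, 0.6,
                            compute_stress = FALSE)
  expect_lt(res$equilibrium, 1e-6)
  k0 <- res$k
  # raising single-element moduli never lowers the segmental stiffness
  set.seed(31)
  rows <- sample(which(!model$is_annulus), 3)
  for (r in rows) {
    m2 <- model
    m2$elem_E_iso[r] <- m2$elem_E_iso[r] * 10
    k2 <- assemble_and_solve(m2, 0.6,
                             compute_stress = FALSE)$k
    expect_gte(k2, k0 - 1e-9 * k0)
  }
})

test_that("conjugate-gradient path agrees with the direct solver", {
  m <- column_model(2, 2, 4, grey = 150, h = 1, nu = 0.3, loading = "ball")
  r1 <- assemble_and_solve(m, 0.01, method = "direct")
  r2 <- assemble_and_solve(m, 0.01, method = "cg")
  expect_equal(r2$k, r1$k, tolerance = 1e-6)
  expect_equal(r2$U, r1$U, tolerance = 1e-5)
})

test_that("floating components are reported as singular meshes", {
  # two disconnected blocks along z
  dat <- array(0L, c(2, 2, 5))
  dat[, , 1:2] <- 1L
  dat[, , 4:5] <- 1L
  labs <- label_map(dat, 1, labels = c(trabecular_T12 = 1L))
  img <- voxel_image(array(100, dim(dat)), 1)
  m <- build_model(img, labs)
  # CHOLMOD warns about the indefinite matrix before the solver raises
  expect_error(suppressWarnings(assemble_and_solve(m, 0.01)),
               "disconnected components")
})

test_that("ball loading leaves the top plate force-free in lateral directions", {
  ph <- mini_phantom()
  model <- build_model(ph$image, ph$labels)
  res <- assemble_and_solve(model, 0.6,
                            compute_stress = FALSE)
  # plate moves rigidly: uz over the top nodes is an affine function of
  # (x, y) -- the plate may tilt on the heterogeneous bone, but not warp --
  # and the reference point carries the prescribed axial displacement
  xy <- model$node_xyz[model$top_nodes, 1:2]
  top_uz <- res$U[model$top_nodes, 3]
  fit <- lm(top_uz ~ xy[, 1] + xy[, 2])
  expect_lt(max(abs(residuals(fit))), 1e-10)
  expect_equal(mean(top_uz), -0.6, tolerance = 1e-9)
  # the frictionless ball transmits no net lateral force or axial moment
  K <- fe_assemble(model)
  r <- as.vector(K %*% as.vector(t(res$U)))
  fx <- sum(r[3 * model$top_nodes - 2])
  fy <- sum(r[3 * model$top_nodes - 1])
  expect_lt(abs(fx) / res$reaction, 1e-8)
  expect_lt(abs(fy) / res$reaction, 1e-8)
})
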