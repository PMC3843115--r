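test_that("rescaling to a common load is exact, and identity at the target", {
  m <- column_model(2, 2, 3, grey = 150, h = 1, nu = 0.3)
  res <- assemble_and_solve(m, 0.01)
  same <- scale_to_common_load(scale_to_common_load(res, 1000), 1000)
  expect_equal(same$reaction, 1000)
  half <- res; half$reaction <- 500; half$stress <- res$stress
  doubled <- scale_to_common_load(half, 1000)
  expect_equal(doubled$stress, 2 * res$stress)
  expect_equal(doubled$k, half$k)  # stiffness invariant under rescaling
  expect_error(scale_to_common_load(res, -1), "target_reaction")
})

test_that("stress change is zero for identical states and exact on a fixture", {
  ph <- mini_phantom()
  model <- build_model(ph$image, ph$labels)
  res <- assemble_and_solve(model, 0.6)
  at_load <- scale_to_common_load(res, 1000)
  sc <- stress_change(at_load, at_load, model, "L1")
  expect_true(all(sc$changes == 0))
  expect_equal(sc$n_undefined + length(sc$changes), sc$n_total)

  # hand-built pre/post pair: vm 10 -> 12 MPa is +20 %
  pre <- at_load; post <- at_load
  rows <- vertebra_elements(model, "L1")
  pre$stress[rows, ] <- matrix(rep(c(10, 0, 0, 0, 0, 0), each = length(rows)),
                               ncol = 6)
  post$stress[rows, ] <- matrix(rep(c(12, 0, 0, 0, 0, 0), each = length(rows)),
                                ncol = 6)
  sc2 <- stress_change(pre, post, model, "L1")
  expect_true(all(abs(sc2$changes - 20) < 1e-12))
})

test_that("stress at a fixed load is invariant to a global modulus scale", {
  col1 <- column_model(2, 2, 4, grey = 120, h = 1, nu = 0.3)
  col2 <- scale_bone_quality(col1, 3.7)
  r1 <- scale_to_common_load(assemble_and_solve(col1, 0.01), 1000)
  r2 <- scale_to_common_load(assemble_and_solve(col2, 0.01), 1000)
  sc <- stress_change(r1, r2, col1, "T12")
  expect_true(all(abs(sc$changes) < 1e-8))
})

test_that("mismatched meshes and mismatched loads are rejected", {
  m1 <- column_model(2, 2, 3, grey = 100)
  m2 <- column_model(2, 2, 4, grey = 100)
  r1 <- assemble_and_solve(m1, 0.01)
  r2 <- assemble_and_solve(m2, 0.01)
  expect_error(stress_change(r1, r2, m1, "T12"), "identical mesh")
  r3 <- assemble_and_solve(m1, 0.02)
  expect_error(stress_change(r1, r3, m1, "T12"), "same reaction")
})

test_that("histograms count deterministically and conserve mass", {
  changes <- c(-150, -15, -5, 0, 3, 12, 250)
  hg <- stress_histogram(changes, edges = seq(-100, 100, 10))
  expect_equal(sum(hg$bins$fraction) + hg$undefined_fraction, 1,
               tolerance = 1e-12)
  # direct counting oracle
  expect_equal(hg$bins$count[hg$bins$lo == -Inf], 1)       # below -100
  expect_equal(hg$bins$count[hg$bins$lo == -20], 1)        # -15
  expect_equal(hg$bins$count[hg$bins$lo == -10], 1)        # -5
  expect_equal(hg$bins$count[hg$bins$lo == 0], 2)          # 0 and 3
  expect_equal(hg$bins$count[hg$bins$lo == 10], 1)         # 12
  expect_equal(hg$bins$count[hg$bins$hi == Inf], 1)        # above +100
  # all-zero changes put full mass in the bin containing zero
  hg0 <- stress_histogram(rep(0, 50))
  expect_equal(hg0$bins$fraction[hg0$bins$lo == 0], 1)
  # uniform draws match direct counts
  set.seed(3)
  u <- runif(500, -60, 60)
  hgu <- stress_histogram(u)
  expect_equal(hgu$bins$count[hgu$bins$lo == 20],
               sum(u >= 20 & u < 30))
  expect_error(stress_histogram(u, edges = c(1, 1, 2)), "strictly increasing")
})

test_that("undefined pre-stress elements land in the undefined bucket", {
  ph <- mini_phantom()
  model <- build_model(ph$image, ph$labels)
  res <- scale_to_common_load(
    assemble_and_solve(model, 0.6), 1000)
  pre <- res
  rows <- vertebra_elements(model, "L1")
  pre$stress[rows[1:5], ] <- 0
  sc <- stress_change(pre, res, model, "L1")
  expect_equal(sc$n_undefined, 5L)
  hg <- stress_histogram(sc)
  expect_equal(hg$undefined_fraction, 5 / sc$n_total)
  expect_equal(sum(hg$bins$fraction) + hg$undefined_fraction, 1,
               tolerance = 1e-12)
})

test_that("a sweep records one stiffness per cell and reuses the mesh", {
  ph <- mini_phantom()
  labs <- mini_cemented_labels()
  grid <- data.frame(augmented_levels = c("none", "L1", "L1"),
                     cement_modulus_fraction = c(1, 1, 0.25))
  sw <- run_sweep(ph$image, labs, grid,
                  base = treatment_config(disc_state = "degenerated"))
  expect_equal(nrow(sw$records), 3)
  expect_equal(nrow(sw$errors), 0)
  expect_true(all(sw$records$equilibrium < 1e-6))
  # untreated cell matches a direct solve of the same configuration
  m0 <- build_model(ph$image, labs, model_config(
    treatment = treatment_config("none", disc_state = "degenerated")))
  k0 <- assemble_and_solve(m0, 0.6,
                           compute_stress = FALSE)$k
  expect_equal(sw$records$k[1], k0, tolerance = 1e-10)
  # softer augmented region cannot stiffen the segment more than pure cement
  expect_lte(sw$records$k[3], sw$records$k[2])
  expect_gte(sw$records$k[2], sw$records$k[1])
})

test_that("failed sweep cells are recorded and the rest proceed", {
  ph <- mini_phantom()
  labs <- mini_cemented_labels()
  grid <- data.frame(augmented_levels = c("T12", "L1"))  # T12 has no cement
  sw <- run_sweep(ph$image, labs, grid,
                  base = treatment_config(disc_state = "degenerated"))
  expect_equal(nrow(sw$errors), 1)
  expect_match(sw$errors$message, "no cement region")
  expect_equal(nrow(sw$records), 1)
})

test_that("sweep histograms carry the common-load convention", {
  ph <- mini_phantom()
  labs <- mini_cemented_labels()
  grid <- data.frame(augmented_levels = "L1")
  sw <- run_sweep(ph$image, labs, grid,
                  base = treatment_config(disc_state = "degenerated"),
                  histogram_levels = c("T12", "L2"))
  expect_setequal(names(sw$histograms), c("cell1.T12", "cell1.L2"))
  for (hg in sw$histograms) {
    expect_equal(sum(hg$bins$fraction) + hg$undefined_fraction, 1,
                 tolerance = 1e-12)
  }
})
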