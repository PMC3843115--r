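test_that("treatment operators touch only their targeted label sets", {
  ph <- mini_phantom()
  labs <- mini_cemented_labels()
  model <- build_model(ph$image, labs,
                       model_config(treatment = treatment_config(
                         augmented_levels = "none", disc_state = "degenerated")))
  ids <- model$label_ids
  cement_rows <- which(model$elem_label == ids[["cement_L1"]])

  aug <- apply_augmentation(model, labs, treatment_config(
    augmented_levels = "L1", disc_state = "degenerated"))
  expect_true(all(aug$elem_E_iso[cement_rows] == 2040))
  other <- setdiff(seq_along(model$elem_label), cement_rows)
  expect_identical(aug$elem_E_iso[other], model$elem_E_iso[other])

  # un-augmented cement regions carry the underlying bone modulus
  expect_identical(model$elem_E_iso[cement_rows],
                   model$elem_E_bone[cement_rows])
})

test_that("composite cement fractions assign the expected moduli", {
  ph <- mini_phantom()
  labs <- mini_cemented_labels()
  model <- build_model(ph$image, labs)
  ids <- model$label_ids
  rows <- which(model$elem_label == ids[["cement_L1"]])
  aug <- apply_augmentation(model, labs, treatment_config(
    augmented_levels = "L1", cement_modulus_fraction = 0.125))
  expect_true(all(aug$elem_E_iso[rows] == 255))  # 0.125 x 2040
})

test_that("augmenting a level without a cement region errors", {
  ph <- mini_phantom()
  labs <- mini_cemented_labels()
  model <- build_model(ph$image, labs)
  expect_error(apply_augmentation(model, labs, treatment_config(
    augmented_levels = "T12")), "no cement region")
})

test_that("two-level augmentation commutes", {
  ph <- mini_phantom()
  labs <- add_cement_region(mini_cemented_labels(), "T12", 0.2)
  model <- build_model(ph$image, labs)
  ab <- apply_augmentation(
    apply_augmentation(model, labs, treatment_config("T12")),
    labs, treatment_config(c("T12", "L1")))
  ba <- apply_augmentation(
    apply_augmentation(model, labs, treatment_config("L1")),
    labs, treatment_config(c("T12", "L1")))
  expect_identical(ab$elem_E_iso, ba$elem_E_iso)
})

test_that("cement volume scaling hits the target count and restores bone exactly", {
  ph <- mini_phantom()
  labs <- mini_cemented_labels()
  model <- build_model(ph$image, labs,
                       model_config(treatment = treatment_config("L1")))
  ids <- model$label_ids
  n0 <- sum(labs$data == ids[["cement_L1"]])

  dbl <- vary_cement_volume(model, labs, "L1", 2)
  n2 <- sum(dbl$labels$data == ids[["cement_L1"]])
  expect_lte(abs(n2 - 2 * n0), 1)

  half <- vary_cement_volume(model, labs, "L1", 0.5)
  nh <- sum(half$labels$data == ids[["cement_L1"]])
  expect_lte(abs(nh - 0.5 * n0), 1)
  # shrunken region is a subset of the original (same deterministic ordering)
  expect_true(all(which(half$labels$data == ids[["cement_L1"]]) %in%
                    which(labs$data == ids[["cement_L1"]])))

  # halve then restore to the original count: bit-identical materials
  back <- vary_cement_volume(half$model, half$labels, "L1", n0 / nh)
  expect_identical(back$labels$data, labs$data)
  expect_identical(back$model$elem_E_iso, model$elem_E_iso)

  # elements that left the region recovered their greyscale-derived moduli
  released <- which(labs$data == ids[["cement_L1"]] &
                      half$labels$data != ids[["cement_L1"]])
  row_of <- match(released, model$elem_idx)
  expect_identical(half$model$elem_E_iso[row_of],
                   model$elem_E_bone[row_of])

  # growth beyond the trabecular reservoir errors with the maximum
  expect_error(vary_cement_volume(model, labs, "L1", 100), "maximum factor")
})

test_that("bone-quality scaling is exact, invertible, and spares other tissues", {
  ph <- mini_phantom()
  labs <- mini_cemented_labels()
  model <- build_model(ph$image, labs,
                       model_config(treatment = treatment_config("L1")))
  ids <- model$label_ids
  bone <- model$elem_label %in% ids[grepl("^(trabecular|cortical)_", names(ids))]
  cement <- model$elem_label == ids[["cement_L1"]]

  expect_identical(scale_bone_quality(model, 1)$elem_E_iso, model$elem_E_iso)
  up <- scale_bone_quality(model, 2)
  expect_identical(up$elem_E_iso[bone], 2 * model$elem_E_iso[bone])
  expect_identical(up$elem_E_iso[cement], model$elem_E_iso[cement])
  round_trip <- scale_bone_quality(up, 0.5)
  expect_identical(round_trip$elem_E_iso, model$elem_E_iso)

  # homogeneous bone column: k scales exactly with the bone factor
  col <- column_model(2, 2, 4, grey = 120, h = 1, nu = 0)
  k1 <- assemble_and_solve(col, 0.01, compute_stress = FALSE)$k
  k2 <- assemble_and_solve(scale_bone_quality(col, 2), 0.01,
                           compute_stress = FALSE)$k
  expect_equal(k2, 2 * k1, tolerance = 1e-12)
})

test_that("disc state switching applies the reference sets and is involutive", {
  ph <- mini_phantom()
  model <- build_model(ph$image, ph$labels)  # healthy start
  ids <- model$label_ids
  nuc <- model$elem_label %in% ids[grepl("^nucleus_", names(ids))]

  deg <- set_disc_state(model, "degenerated")
  expect_true(all(deg$elem_E_iso[nuc] == 4.9))
  expect_true(all(deg$elem_nu_iso[nuc] == 0.43))
  expect_equal(deg$annulus_material$E2 / deg$annulus_material$E1, 91.9 / 0.53)

  back <- set_disc_state(deg, "healthy")
  expect_true(all(back$elem_E_iso[nuc] == 1))
  expect_true(all(back$elem_nu_iso[nuc] == 0.499))
  expect_identical(back$elem_E_iso, model$elem_E_iso)
  expect_identical(back$annulus_material, model$annulus_material)
})
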