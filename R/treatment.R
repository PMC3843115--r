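#' Treatment configuration
#'
#' One cell of the parametric treatment space: which levels carry an active
#' cement augmentation, the modulus assigned to the augmented region (base
#' cement modulus times a composite fraction), the nominal fill fraction,
#' a cement volume factor, a bone-quality factor applied to every
#' element-specific bone modulus, and the disc state.
#'
#' The augmented-region modulus replaces the underlying bone modulus; the
#' composite fractions (1, 0.5, 0.25, 0.125 of the pure-cement value) span
#' reported bone-cement composite stiffnesses without layering a separate
#' mixture model.
#'
#' @param augmented_levels Character vector of vertebra labels carrying an
#'   active augmentation (e.g. `"L1"`, `c("T12", "L1")`), or `"none"`.
#' @param cement_E Pure cement elastic modulus, MPa (default 2040).
#' @param cement_modulus_fraction Fraction of `cement_E` assigned to the
#'   augmented region, in (0, 1].
#' @param fill_fraction Nominal cement fill as a fraction of vertebral body
#'   volume (default 0.2).
#' @param volume_factor Cement volume multiplier relative to the nominal
#'   fill (0.5, 1 or 2 in the study design; any positive value accepted).
#' @param bone_factor Multiplier on every bone element modulus (0.5 = poorer,
#'   2 = better bone quality).
#' @param disc_state `"healthy"` or `"degenerated"`.
#' @return A `treatment_config` object.
#' @export
treatment_config <- function(augmented_levels = "L1",
                             cement_E = 2040,
                             cement_modulus_fraction = 1,
                             fill_fraction = 0.2,
                             volume_factor = 1,
                             bone_factor = 1,
                             disc_state = c("degenerated", "healthy")) {
  disc_state <- match.arg(disc_state)
  if (identical(augmented_levels, "none") || !length(augmented_levels)) {
    augmented_levels <- character(0)
  }
  stopifnot(is.character(augmented_levels),
            cement_E > 0, cement_modulus_fraction > 0,
            cement_modulus_fraction <= 1,
            fill_fraction >= 0, fill_fraction <= 1,
            volume_factor > 0, bone_factor > 0)
  structure(list(augmented_levels = augmented_levels,
                 cement_E = cement_E,
                 cement_modulus_fraction = cement_modulus_fraction,
                 fill_fraction = fill_fraction,
                 volume_factor = volume_factor,
                 bone_factor = bone_factor,
                 disc_state = disc_state),
            class = "treatment_config")
}

#' Activate cement augmentation on a model
#'
#' Assigns the cement material (at `cement_E * cement_modulus_fraction`) to
#' the cement-labelled elements of each requested level; every other element
#' is untouched. Each requested level must carry a cement region in the
#' label map the model was built from (see [add_cement_region()]).
#'
#' @param model An `fe_model`.
#' @param labels The label map the model was built from (used to verify the
#'   requested regions exist).
#' @param config A [treatment_config()].
#' @return The updated `fe_model`.
#' @export
apply_augmentation <- function(model, labels, config) {
  stopifnot(inherits(model, "fe_model"), inherits(labels, "label_map"),
            inherits(config, "treatment_config"))
  for (lvl in config$augmented_levels) {
    nm <- paste0("cement_", lvl)
    if (!nm %in% names(labels$labels) ||
        !any(labels$data == labels$labels[[nm]])) {
      stop("level ", lvl, " has no cement region; run add_cement_region() first")
    }
  }
  model$config$treatment <- config
  refresh_materials(model)
}

#' Grow or shrink the cement region of one level
#'
#' Changes the number of cement-labelled elements by `volume_factor` using
#' the same deterministic centroid-distance ordering that grew the original
#' region: growing takes the next-closest trabecular elements, shrinking
#' keeps the closest ones. Elements that leave the region recover their
#' original greyscale-derived bone moduli exactly (materials are re-derived
#' from labels and stored greys, never mutated in place).
#'
#' @param model An `fe_model` built from `labels`.
#' @param labels The [label_map] carrying the current cement region.
#' @param level Vertebra label whose region is resized.
#' @param volume_factor Positive multiplier on the cement element count
#'   (0.5 and 2 in the study design).
#' @return List with the rebuilt `model` and the new `labels`.
#' @export
vary_cement_volume <- function(model, labels, level, volume_factor) {
  stopifnot(inherits(model, "fe_model"), inherits(labels, "label_map"),
            volume_factor > 0)
  cem_id <- label_id(labels, paste0("cement_", level))
  body_ids <- label_id(labels, c(paste0("trabecular_", level),
                                 paste0("cortical_", level)))
  n_cem <- sum(labels$data == cem_id)
  if (n_cem == 0L) stop("level ", level, " has no cement region to resize")
  n_body <- sum(labels$data %in% c(body_ids, cem_id))
  n_avail <- sum(labels$data %in% c(body_ids[1], cem_id))
  n_new <- round(volume_factor * n_cem)
  if (n_new > n_avail) {
    stop(sprintf(
      "volume_factor %g needs %d elements but only %d trabecular elements exist (maximum factor %.3f)",
      volume_factor, n_new, n_avail, n_avail / n_cem))
  }
  new_labels <- add_cement_region(labels, level, n_new / n_body)
  new_model <- model
  new_model$elem_label <- new_labels$data[new_model$elem_idx]
  new_model <- refresh_materials(new_model)
  list(model = new_model, labels = new_labels)
}

#' Scale bone quality
#'
#' Multiplies the element-specific modulus of every bone element (and of
#' cement-labelled elements reverting to bone in non-augmented levels) by
#' `bone_factor`; cement, disc, and housing materials are untouched.
#'
#' @param model An `fe_model`.
#' @param bone_factor Positive multiplier (0.5 = osteoporotic, 2 = dense).
#' @return The updated `fe_model`.
#' @export
scale_bone_quality <- function(model, bone_factor) {
  stopifnot(inherits(model, "fe_model"), bone_factor > 0)
  model$config$treatment$bone_factor <-
    model$config$treatment$bone_factor * bone_factor
  refresh_materials(model)
}

#' Switch the intervertebral disc state
#'
#' Assigns the healthy or degenerated reference property set to the annulus
#' and nucleus elements of both discs. Any disc scaling factors from a
#' previous inverse calibration are reset to one: the reference sets are
#' complete property states, not scalings.
#'
#' @param model An `fe_model`.
#' @param state `"healthy"` or `"degenerated"`.
#' @return The updated `fe_model`.
#' @export
set_disc_state <- function(model, state = c("healthy", "degenerated")) {
  state <- match.arg(state)
  stopifnot(inherits(model, "fe_model"))
  model$config$treatment$disc_state <- state
  model$config$disc_scale <- c(annulus = 1, nucleus = 1)
  refresh_materials(model)
}
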