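#' Scale disc properties preserving anisotropy ratios
#'
#' Multiplies all annulus Young's and shear moduli by `annulus_factor` and
#' the nucleus modulus by `nucleus_factor`, leaving every Poisson ratio at
#' its input value. The annulus modulus ratios E2/E1 and E3/E1 are preserved
#' exactly. The scaled constitutive matrices are re-validated; factors that
#' break positive definiteness raise an error.
#'
#' @param disc A [disc_properties()] set.
#' @param annulus_factor,nucleus_factor Positive scale factors.
#' @return A new `disc_properties` object.
#' @examples
#' healthy <- disc_properties("healthy")
#' scale_disc(healthy, 2.625, 4.9)$annulus$E2  # 91.875, i.e. the
#' # degenerated circumferential modulus to three significant figures
#' @export
scale_disc <- function(disc, annulus_factor, nucleus_factor) {
  stopifnot(inherits(disc, "disc_properties"),
            annulus_factor > 0, nucleus_factor > 0)
  a <- disc$annulus
  n <- disc$nucleus
  structure(list(
    state = disc$state,
    annulus = material_orthotropic(
      a$E1 * annulus_factor, a$E2 * annulus_factor, a$E3 * annulus_factor,
      a$nu12, a$nu13, a$nu23,
      G12 = a$G12 * annulus_factor, G13 = a$G13 * annulus_factor,
      G23 = a$G23 * annulus_factor),
    nucleus = material_isotropic(n$E * nucleus_factor, n$nu)
  ), class = "disc_properties")
}

#' Inverse calibration of disc properties against a target stiffness
#'
#' Reverse-engineers disc stiffness from a measured segmental stiffness:
#' starting from a reference (healthy) property set, annulus and nucleus
#' moduli are scaled -- anisotropy ratios preserved, Poisson ratios fixed --
#' until the model's simulated segmental stiffness matches `target_k`.
#'
#' One scalar (the annulus factor) is searched; the nucleus factor is slaved
#' through the power law `nucleus_factor = annulus_factor^coupling_exponent`.
#' The default exponent log(4.9)/log(2.625) is the one implied by the
#' healthy-to-degenerated transition of the reference property table (annulus
#' axial modulus 8 -> 21 MPa, nucleus 1 -> 4.9 MPa), and makes the coupling
#' exact at both ends: factor 1 reproduces the starting state, factor 2.625
#' the degenerated one. Segmental stiffness is strictly increasing in the
#' factor, so a bracketed search (secant step with bisection safeguard on the
#' log factor) converges unconditionally; each stiffness evaluation re-uses
#' the assembled non-disc stiffness blocks.
#'
#' @param image,labels Phantom image and label map (see [generate_phantom()]).
#' @param target_k Target segmental stiffness, N/mm.
#' @param start Starting [disc_properties()] (default healthy).
#' @param tolerance Relative stiffness tolerance (default 1e-3).
#' @param bracket Admissible annulus-factor range (default 1/16 to 16).
#' @param coupling_exponent Exponent of the nucleus-annulus coupling.
#' @param applied_displacement Axial compression used for the stiffness
#'   evaluations (mm); any positive value gives the same k in a linear model.
#' @param config Base [model_config()]; its treatment disc state is replaced
#'   by the state of `start`.
#' @param max_iterations Cap on stiffness evaluations (default 60).
#' @return A `calibration_result`: `annulus_factor`, `nucleus_factor`,
#'   `iterations` (stiffness evaluations), `achieved_k`, `target_k`,
#'   `converged`, the calibrated `disc` set, the calibrated `model`, and the
#'   evaluation `history`.
#' @export
calibrate_disc <- function(image, labels, target_k,
                           start = disc_properties("healthy"),
                           tolerance = 1e-3,
                           bracket = c(1 / 16, 16),
                           coupling_exponent = log(4.9) / log(2.625),
                           applied_displacement = 0.6,
                           config = model_config(),
                           max_iterations = 60L) {
  stopifnot(target_k > 0, tolerance > 0, length(bracket) == 2L,
            bracket[1] > 0, bracket[1] < bracket[2],
            inherits(start, "disc_properties"))
  config$materials[[paste0("annulus_", start$state)]] <- start$annulus
  config$materials[[paste0("nucleus_", start$state)]] <- start$nucleus
  config$treatment$disc_state <- start$state
  config$disc_scale <- c(annulus = 1, nucleus = 1)
  model <- build_model(image, labels, config)

  ids <- model$label_ids
  nuc <- model$elem_label %in% ids[grepl("^nucleus_", names(ids))]
  ann <- model$is_annulus
  other <- which(!nuc & !ann)
  K_other <- assemble_subset(model, other)
  K_ann <- assemble_subset(model, which(ann))
  K_nuc <- assemble_subset(model, which(nuc))

  history <- data.frame(annulus_factor = numeric(0), k = numeric(0))
  k_of <- function(af) {
    nf <- af^coupling_exponent
    K <- K_other + af * K_ann + nf * K_nuc
    res <- solve_displacement_system(model, K, applied_displacement,
                                     compute_stress = FALSE)
    rm(K); gc(verbose = FALSE)
    history[nrow(history) + 1L, ] <<- c(af, res$k)
    res$k
  }

  f_lo <- bracket[1]; f_hi <- bracket[2]
  k1 <- k_of(1)
  done <- abs(k1 - target_k) / target_k <= tolerance
  if (done) {
    lo <- hi <- 1; k_lo <- k_hi <- k1
  } else if (k1 < target_k) {
    lo <- 1; k_lo <- k1; hi <- NA
    f <- 1
    while (is.na(hi)) {
      f <- min(f * 4, f_hi)
      kf <- k_of(f)
      if (kf >= target_k) { hi <- f; k_hi <- kf }
      else if (f >= f_hi) {
        stop(sprintf(
          "target stiffness %.6g N/mm is above the achievable range [%.6g, %.6g] on the bracket [%g, %g]",
          target_k, history$k[which.min(history$annulus_factor)], kf,
          f_lo, f_hi))
      } else { lo <- f; k_lo <- kf }
    }
  } else {
    hi <- 1; k_hi <- k1; lo <- NA
    f <- 1
    while (is.na(lo)) {
      f <- max(f / 4, f_lo)
      kf <- k_of(f)
      if (kf <= target_k) { lo <- f; k_lo <- kf }
      else if (f <= f_lo) {
        stop(sprintf(
          "target stiffness %.6g N/mm is below the achievable range [%.6g, %.6g] on the bracket [%g, %g]",
          target_k, kf, history$k[which.max(history$annulus_factor)],
          f_lo, f_hi))
      } else { hi <- f; k_hi <- kf }
    }
  }

  best <- history[which.min(abs(history$k - target_k)), ]
  converged <- abs(best$k - target_k) / target_k <= tolerance
  while (!converged && nrow(history) < max_iterations) {
    # secant in log-factor, safeguarded by bisection within the bracket
    llo <- log(lo); lhi <- log(hi)
    lf <- llo + (lhi - llo) * (target_k - k_lo) / (k_hi - k_lo)
    mid <- (llo + lhi) / 2
    if (!is.finite(lf) || lf <= llo || lf >= lhi) lf <- mid
    f <- exp(lf)
    kf <- k_of(f)
    if (kf < target_k) { lo <- f; k_lo <- kf } else { hi <- f; k_hi <- kf }
    best <- history[which.min(abs(history$k - target_k)), ]
    converged <- abs(best$k - target_k) / target_k <= tolerance
  }

  af <- best$annulus_factor
  nf <- af^coupling_exponent
  model$config$disc_scale <- c(annulus = af, nucleus = nf)
  model <- refresh_materials(model)
  structure(list(
    annulus_factor = af,
    nucleus_factor = nf,
    iterations = nrow(history),
    achieved_k = best$k,
    target_k = target_k,
    converged = converged,
    tolerance = tolerance,
    disc = scale_disc(start, af, nf),
    model = model,
    history = history
  ), class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "<calibration_result> %s after %d stiffness evaluations\n  annulus factor %.5g, nucleus factor %.5g\n  achieved k %.6g N/mm (target %.6g, rel. error %.2e)\n",
    if (x$converged) "converged" else "NOT converged", x$iterations,
    x$annulus_factor, x$nucleus_factor, x$achieved_k, x$target_k,
    abs(x$achieved_k - x$target_k) / x$target_k))
  invisible(x)
}
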