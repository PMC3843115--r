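#' Isotropic linear-elastic material
#'
#' @param E Elastic modulus in MPa.
#' @param nu Poisson's ratio; must lie strictly inside (-1, 0.5).
#' @return An object of class `fe_material` with `kind = "isotropic"`.
#' @examples
#' material_isotropic(2040, 0.3)  # injected PMMA cement
#' @export
material_isotropic <- function(E, nu) {
  stopifnot(is.numeric(E), length(E) == 1L, is.finite(E),
            is.numeric(nu), length(nu) == 1L, is.finite(nu))
  if (E <= 0) stop("isotropic material requires E > 0, got ", E)
  if (nu <= -1 || nu >= 0.5) stop("isotropic Poisson's ratio must be in (-1, 0.5), got ", nu)
  structure(list(kind = "isotropic", E = E, nu = nu), class = "fe_material")
}

#' Orthotropic linear-elastic material
#'
#' Material axes follow the disc convention: 1 = radial, 2 = circumferential,
#' 3 = axial. The 6x6 constitutive matrix is checked for positive definiteness
#' at construction; shear moduli may be omitted, in which case Huber-type
#' estimates from the in-plane moduli and Poisson ratios are used
#' (see [huber_shear_moduli()]).
#'
#' @param E1,E2,E3 Elastic moduli (MPa) along the three material axes.
#' @param nu12,nu13,nu23 Poisson ratios (strain in axis j per strain in axis i).
#' @param G12,G13,G23 Shear moduli (MPa); `NULL` for the Huber default.
#' @return An object of class `fe_material` with `kind = "orthotropic"`.
#' @export
material_orthotropic <- function(E1, E2, E3, nu12, nu13, nu23,
                                 G12 = NULL, G13 = NULL, G23 = NULL) {
  E <- c(E1, E2, E3)
  if (any(!is.finite(E)) || any(E <= 0)) stop("orthotropic moduli must be positive and finite")
  G <- c(G12 %||% NA_real_, G13 %||% NA_real_, G23 %||% NA_real_)
  if (anyNA(G)) {
    Gh <- huber_shear_moduli(E1, E2, E3, nu12, nu13, nu23)
    G[is.na(G)] <- Gh[is.na(G)]
  }
  if (any(G <= 0)) stop("orthotropic shear moduli must be positive")
  m <- structure(list(kind = "orthotropic",
                      E1 = E1, E2 = E2, E3 = E3,
                      nu12 = nu12, nu13 = nu13, nu23 = nu23,
                      G12 = G[1], G13 = G[2], G23 = G[3]),
                 class = "fe_material")
  C <- constitutive_matrix(m)  # errors if not positive definite
  stopifnot(is.matrix(C))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Huber-type shear modulus estimates for an orthotropic solid
#'
#' Shear moduli are rarely reported together with orthotropic Young's moduli;
#' the Huber estimate \eqn{G_{ij} = \sqrt{E_i E_j} / (2 (1 + \sqrt{\nu_{ij}\nu_{ji}}))}
#' interpolates the isotropic relation and reduces to \eqn{E/(2(1+\nu))} when
#' the axes degenerate. The reciprocal ratios \eqn{\nu_{ji} = \nu_{ij} E_j / E_i}
#' follow from compliance symmetry.
#'
#' @inheritParams material_orthotropic
#' @return Named numeric vector `c(G12, G13, G23)` in MPa.
#' @export
huber_shear_moduli <- function(E1, E2, E3, nu12, nu13, nu23) {
  g <- function(Ei, Ej, nuij) {
    nuji <- nuij * Ej / Ei
    sqrt(Ei * Ej) / (2 * (1 + sqrt(nuij * nuji)))
  }
  c(G12 = g(E1, E2, nu12), G13 = g(E1, E3, nu13), G23 = g(E2, E3, nu23))
}

#' 6x6 constitutive (stiffness) matrix of a material
#'
#' Voigt ordering is (11, 22, 33, 23, 13, 12) with engineering shear strains.
#' For an isotropic material the standard Lame form is returned; for an
#' orthotropic material the compliance matrix is inverted. Non-positive
#' definite constants raise an error naming the offending eigenvalue.
#'
#' @param m An `fe_material`.
#' @return A symmetric positive-definite 6x6 matrix (MPa).
#' @examples
#' constitutive_matrix(material_isotropic(1, 0))  # diag(1,1,1,.5,.5,.5)
#' @export
constitutive_matrix <- function(m) {
  stopifnot(inherits(m, "fe_material"))
  if (m$kind == "isotropic") {
    lam <- m$E * m$nu / ((1 + m$nu) * (1 - 2 * m$nu))
    mu <- m$E / (2 * (1 + m$nu))
    C <- matrix(0, 6, 6)
    C[1:3, 1:3] <- lam
    diag(C)[1:3] <- lam + 2 * mu
    diag(C)[4:6] <- mu
  } else {
    S <- matrix(0, 6, 6)
    S[1, 1] <- 1 / m$E1; S[2, 2] <- 1 / m$E2; S[3, 3] <- 1 / m$E3
    S[1, 2] <- S[2, 1] <- -m$nu12 / m$E1
    S[1, 3] <- S[3, 1] <- -m$nu13 / m$E1
    S[2, 3] <- S[3, 2] <- -m$nu23 / m$E2
    S[4, 4] <- 1 / m$G23; S[5, 5] <- 1 / m$G13; S[6, 6] <- 1 / m$G12
    C <- solve(S)
    C <- (C + t(C)) / 2
  }
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop("constitutive matrix is not positive definite (smallest eigenvalue ",
         format(min(ev)), ")")
  }
  C
}

#' Rotate a constitutive matrix into a new frame
#'
#' Applies the Bond stress transformation for a rotation `Q` whose columns are
#' the material axes expressed in the global frame, i.e.
#' \eqn{C' = T_\sigma C T_\sigma^\top}. Used to orient the annulus fibrosus
#' material (radial / circumferential / axial) around the disc axis.
#'
#' @param C 6x6 constitutive matrix in material axes.
#' @param Q 3x3 rotation matrix, columns = material axes in global coordinates.
#' @return The rotated 6x6 constitutive matrix.
#' @export
rotate_constitutive <- function(C, Q) {
  stopifnot(is.matrix(C), all(dim(C) == 6L), is.matrix(Q), all(dim(Q) == 3L))
  Ts <- bond_stress_matrix(Q)
  Ts %*% C %*% t(Ts)
}

# Bond 6x6 stress transformation for Voigt order (11,22,33,23,13,12).
bond_stress_matrix <- function(Q) {
  p <- rbind(c(2L, 3L), c(1L, 3L), c(1L, 2L))  # shear index pairs 23, 13, 12
  Ts <- matrix(0, 6, 6)
  for (i in 1:3) {
    Ts[i, 1:3] <- Q[i, ]^2
    for (s in 1:3) Ts[i, 3 + s] <- 2 * Q[i, p[s, 1]] * Q[i, p[s, 2]]
  }
  for (r in 1:3) {
    a <- p[r, 1]; b <- p[r, 2]
    Ts[3 + r, 1:3] <- Q[a, ] * Q[b, ]
    for (s in 1:3) {
      Ts[3 + r, 3 + s] <- Q[a, p[s, 1]] * Q[b, p[s, 2]] + Q[a, p[s, 2]] * Q[b, p[s, 1]]
    }
  }
  Ts
}

#' Reference material constants for the segment model
#'
#' The set of literature-based constants used throughout the model: PMMA
#' cement and the cement end-housings (isotropic), healthy and degenerated
#' nucleus pulposus (isotropic), and healthy and degenerated annulus fibrosus
#' (orthotropic; axes 1 = radial, 2 = circumferential, 3 = axial, shear
#' moduli by the Huber estimate). Bone is not listed here because its modulus
#' is element-specific, mapped from the image greyscale.
#'
#' @return Named list of `fe_material` objects plus `bone_nu`, the Poisson
#'   ratio used for all bone elements.
#' @export
default_materials <- function() {
  list(
    bone_nu = 0.3,
    cement = material_isotropic(2040, 0.3),
    housing = material_isotropic(2450, 0.3),
    nucleus_healthy = material_isotropic(1, 0.499),
    nucleus_degenerated = material_isotropic(4.9, 0.43),
    annulus_healthy = material_orthotropic(0.2, 35, 8, 0.02, 0.065, 1.2),
    annulus_degenerated = material_orthotropic(0.53, 91.9, 21, 0.022, 0.072, 1.32)
  )
}

#' Disc property set for a given state
#'
#' @param state `"healthy"` or `"degenerated"`.
#' @param materials Material table, see [default_materials()].
#' @return A `disc_properties` object: list with `annulus` (orthotropic) and
#'   `nucleus` (isotropic) materials.
#' @export
disc_properties <- function(state = c("healthy", "degenerated"),
                            materials = default_materials()) {
  state <- match.arg(state)
  structure(list(
    state = state,
    annulus = materials[[paste0("annulus_", state)]],
    nucleus = materials[[paste0("nucleus_", state)]]
  ), class = "disc_properties")
}

#' von Mises equivalent stress
#'
#' @param stress Numeric vector of length 6 or an n x 6 matrix of stress
#'   tensors in Voigt order (s11, s22, s33, t23, t13, t12), MPa.
#' @return Non-negative scalar or vector of equivalent stresses (MPa).
#' @examples
#' von_mises(c(100, 0, 0, 0, 0, 0))   # 100
#' von_mises(c(50, 50, 50, 0, 0, 0))  # 0 (hydrostatic)
#' @export
von_mises <- function(stress) {
  if (is.null(dim(stress))) stress <- matrix(stress, ncol = 6)
  stopifnot(ncol(stress) == 6L)
  s1 <- stress[, 1]; s2 <- stress[, 2]; s3 <- stress[, 3]
  vm <- sqrt(0.5 * ((s1 - s2)^2 + (s2 - s3)^2 + (s3 - s1)^2) +
               3 * (stress[, 4]^2 + stress[, 5]^2 + stress[, 6]^2))
  if (length(vm) == 1L) vm <- as.numeric(vm)
  vm
}

#' @export
print.fe_material <- function(x, ...) {
  if (x$kind == "isotropic") {
    cat(sprintf("<fe_material> isotropic: E = %g MPa, nu = %g\n", x$E, x$nu))
  } else {
    cat(sprintf(
      "<fe_material> orthotropic: E = (%g, %g, %g) MPa, nu = (%g, %g, %g), G = (%g, %g, %g) MPa\n",
      x$E1, x$E2, x$E3, x$nu12, x$nu13, x$nu23, x$G12, x$G13, x$G23))
  }
  invisible(x)
}

#' @export
print.disc_properties <- function(x, ...) {
  cat("<disc_properties> state:", x$state, "\n")
  cat("  nucleus: "); print(x$nucleus)
  cat("  annulus: "); print(x$annulus)
  invisible(x)
}
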