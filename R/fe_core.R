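## Voxel hexahedral linear-elasticity engine.
## Units are fixed throughout: lengths mm, forces N, moduli MPa (MPa.mm^2 = N).

# Local node order of the trilinear hex8: sign pattern of (xi, eta, zeta).
hex8_signs <- function() {
  cbind(xi = c(-1, 1, 1, -1, -1, 1, 1, -1),
        eta = c(-1, -1, 1, 1, -1, -1, 1, 1),
        zeta = c(-1, -1, -1, -1, 1, 1, 1, 1))
}

# Strain-displacement matrices (6 x 24) at the 8 Gauss points of a cubic
# voxel of edge h, plus their mean (equal to the centroid value for a cube).
# Voigt order (11, 22, 33, 23, 13, 12), engineering shear.
hex8_B <- function(h) {
  s <- hex8_signs()
  gp <- 1 / sqrt(3)
  Bs <- vector("list", 8L)
  for (g in 1:8) {
    gx <- gp * s[g, 1]; gy <- gp * s[g, 2]; gz <- gp * s[g, 3]
    dNx <- s[, 1] * (1 + gy * s[, 2]) * (1 + gz * s[, 3]) / 8 * 2 / h
    dNy <- s[, 2] * (1 + gx * s[, 1]) * (1 + gz * s[, 3]) / 8 * 2 / h
    dNz <- s[, 3] * (1 + gx * s[, 1]) * (1 + gy * s[, 2]) / 8 * 2 / h
    B <- matrix(0, 6, 24)
    for (i in 1:8) {
      c0 <- 3L * (i - 1L)
      B[1, c0 + 1] <- dNx[i]
      B[2, c0 + 2] <- dNy[i]
      B[3, c0 + 3] <- dNz[i]
      B[4, c0 + 2] <- dNz[i]; B[4, c0 + 3] <- dNy[i]
      B[5, c0 + 1] <- dNz[i]; B[5, c0 + 3] <- dNx[i]
      B[6, c0 + 1] <- dNy[i]; B[6, c0 + 2] <- dNx[i]
    }
    Bs[[g]] <- B
  }
  Bbar <- Reduce(`+`, Bs) / 8
  list(gauss = Bs, mean = Bbar, detJ = (h / 2)^3)
}

ke_from_constitutive <- function(C, Bq) {
  ke <- matrix(0, 24, 24)
  for (B in Bq$gauss) ke <- ke + crossprod(B, C %*% B) * Bq$detJ
  (ke + t(ke)) / 2
}

#' Element stiffness matrix of a cubic trilinear hexahedron
#'
#' Full 2x2x2 Gauss quadrature on a voxel of edge `voxel_size`. For an
#' orthotropic material, `angle` orients the material 1-2 axes
#' (radial / circumferential) in the x-y plane by a rotation about the
#' axial (z) axis.
#'
#' @param m An `fe_material`.
#' @param voxel_size Element edge length (mm).
#' @param angle Rotation of the material frame about z (radians), or `NULL`.
#' @return Symmetric 24 x 24 stiffness matrix (N/mm); dofs are
#'   (ux, uy, uz) per node in the local hex8 node order.
#' @export
element_stiffness_hex8 <- function(m, voxel_size, angle = NULL) {
  stopifnot(inherits(m, "fe_material"), voxel_size > 0)
  C <- constitutive_matrix(m)
  if (!is.null(angle)) C <- rotate_constitutive(C, rotation_about_z(angle))
  ke_from_constitutive(C, hex8_B(voxel_size))
}

rotation_about_z <- function(theta) {
  a <- cos(theta); b <- sin(theta)
  # columns: radial, circumferential, axial directions in global coordinates
  cbind(c(a, b, 0), c(-b, a, 0), c(0, 0, 1))
}

## ---- model construction ----------------------------------------------------

#' Model-building configuration
#'
#' Collects everything that turns an image + label map into an FE problem:
#' the greyscale calibration, the material table, the treatment state, the
#' disc scaling factors used by the inverse calibration, and the top-plate
#' loading mode (`"ball"`: rigid plate with prescribed axial translation,
#' lateral translation and rotations free, emulating loading through a steel
#' ball; `"locked"`: all plate dofs prescribed).
#'
#' @param calibration A [modulus_calibration()].
#' @param materials Material table, see [default_materials()].
#' @param treatment A [treatment_config()]; the default is the pre-treatment
#'   state (no augmentation, healthy discs).
#' @param disc_scale Named factors `c(annulus = , nucleus = )` applied to the
#'   disc moduli on top of the disc state (anisotropy ratios preserved).
#' @param loading `"ball"` or `"locked"`.
#' @return A `model_config` object.
#' @export
model_config <- function(calibration = modulus_calibration(),
                         materials = default_materials(),
                         treatment = treatment_config(
                           augmented_levels = "none", disc_state = "healthy"),
                         disc_scale = c(annulus = 1, nucleus = 1),
                         loading = c("ball", "locked")) {
  loading <- match.arg(loading)
  stopifnot(inherits(calibration, "modulus_calibration"),
            inherits(treatment, "treatment_config"),
            all(c("annulus", "nucleus") %in% names(disc_scale)),
            all(disc_scale > 0))
  structure(list(calibration = calibration, materials = materials,
                 treatment = treatment, disc_scale = disc_scale,
                 loading = loading),
            class = "model_config")
}

#' Build a voxel FE model from an image and label map
#'
#' Every non-background voxel becomes one hex8 element. Node numbering is
#' gap-free over the nodes actually used; the bottom plate is the set of
#' nodes on the lowest node plane (tied to the bottom housing) and the top
#' plate the highest node plane. Element materials are resolved from the
#' labels: bone (trabecular + cortical) is element-specific via the greyscale
#' law, cement regions take the cement material when their level is
#' augmented and revert to the underlying bone modulus otherwise, discs take
#' the configured state (annulus orthotropic in cylindrical axes around the
#' disc centre), housings the housing material.
#'
#' @param image A [voxel_image].
#' @param labels The matching [label_map].
#' @param config A [model_config()].
#' @return An `fe_model` object.
#' @export
build_model <- function(image, labels, config = model_config()) {
  stopifnot(inherits(image, "voxel_image"), inherits(labels, "label_map"),
            inherits(config, "model_config"),
            all(dim(image$data) == dim(labels$data)))
  d <- dim(labels$data)
  elem_idx <- which(labels$data > 0L)
  if (!length(elem_idx)) stop("label map contains no foreground voxels")
  ijk <- arrayInd(elem_idx, d)
  nnx <- d[1] + 1L; nny <- d[2] + 1L
  s <- hex8_signs()
  conn_raw <- matrix(0L, length(elem_idx), 8L)
  for (q in 1:8) {
    oi <- (s[q, 1] + 1L) / 2L; oj <- (s[q, 2] + 1L) / 2L; ok <- (s[q, 3] + 1L) / 2L
    conn_raw[, q] <- (ijk[, 3] + ok - 1L) * nnx * nny +
      (ijk[, 2] + oj - 1L) * nnx + (ijk[, 1] + oi)
  }
  used <- sort(unique(as.vector(conn_raw)))
  nmap <- integer(max(used)); nmap[used] <- seq_along(used)
  conn <- matrix(nmap[conn_raw], ncol = 8L)
  node_k <- (used - 1L) %/% (nnx * nny)
  node_j <- (used - 1L) %/% nnx %% nny
  node_i <- (used - 1L) %% nnx
  h <- labels$voxel_size
  node_xyz <- cbind(labels$origin[1] + node_i * h,
                    labels$origin[2] + node_j * h,
                    labels$origin[3] + node_k * h)
  elem_label <- labels$data[elem_idx]
  ids <- labels$labels
  lvl_names <- sub("^(trabecular|cortical|cement)_", "",
                   names(ids)[grepl("^(trabecular|cortical|cement)_", names(ids))])
  level_of <- rep(NA_character_, max(ids))
  for (nm in names(ids)) {
    if (grepl("^(trabecular|cortical|cement)_", nm)) {
      level_of[ids[[nm]]] <- sub("^(trabecular|cortical|cement)_", "", nm)
    }
  }
  elem_level <- level_of[elem_label]
  # annulus element angle about its disc centre (cylindrical material axes)
  elem_angle <- rep(NA_real_, length(elem_idx))
  for (disc in c("upper", "lower")) {
    dn <- paste0(c("annulus_", "nucleus_"), disc)
    dn <- dn[dn %in% names(ids)]
    if (!length(dn)) next
    in_disc <- elem_label %in% ids[dn]
    if (!any(in_disc)) next
    cx <- mean(ijk[in_disc, 1]); cy <- mean(ijk[in_disc, 2])
    ann <- elem_label == ids[[paste0("annulus_", disc)]]
    elem_angle[ann] <- atan2(ijk[ann, 2] - cy, ijk[ann, 1] - cx)
  }
  model <- structure(list(
    dims = d, voxel_size = h, origin = labels$origin,
    elem_idx = elem_idx, elem_ijk = ijk,
    conn = conn, n_nodes = length(used),
    node_xyz = node_xyz,
    bottom_nodes = which(node_k == min(node_k)),
    top_nodes = which(node_k == max(node_k)),
    elem_label = elem_label, label_ids = ids,
    elem_level = elem_level,
    elem_E_bone = apply_calibration(config$calibration, image$data[elem_idx]),
    elem_angle = elem_angle,
    config = config
  ), class = "fe_model")
  refresh_materials(model)
}

#' @export
print.fe_model <- function(x, ...) {
  cat(sprintf("<fe_model> %d hex8 elements, %d nodes (%d dof), voxel %g mm\n",
              nrow(x$conn), x$n_nodes, 3L * x$n_nodes, x$voxel_size))
  tr <- x$config$treatment
  cat(sprintf("  treatment: levels=%s, cement E=%g MPa (x%g), bone x%g, disc %s\n",
              paste(tr$augmented_levels, collapse = "+"), tr$cement_E,
              tr$cement_modulus_fraction, tr$bone_factor, tr$disc_state))
  invisible(x)
}

# Re-derive per-element materials from labels + config. Isotropic elements
# carry (E, nu) vectors grouped by unique nu; annulus elements carry the
# oriented orthotropic material. Called by build_model and by every
# treatment operator; materials are a pure function of (labels, greys,
# config), which makes treatment round-trips bit-exact.
refresh_materials <- function(model) {
  cfg <- model$config
  tr <- cfg$treatment
  mats <- cfg$materials
  ids <- model$label_ids
  for (lvl in tr$augmented_levels) {
    nm <- paste0("cement_", lvl)
    if (!nm %in% names(ids) || !any(model$elem_label == ids[[nm]])) {
      stop("level ", lvl,
           " has no cement region; run add_cement_region() first")
    }
  }
  disc <- disc_properties(tr$disc_state, mats)
  disc <- scale_disc(disc, cfg$disc_scale[["annulus"]], cfg$disc_scale[["nucleus"]])
  m <- length(model$elem_label)
  E <- rep(NA_real_, m); nu <- rep(NA_real_, m)
  is_bone <- model$elem_label %in% ids[grepl("^(trabecular|cortical)_", names(ids))]
  E[is_bone] <- model$elem_E_bone[is_bone] * tr$bone_factor
  nu[is_bone] <- mats$bone_nu
  for (nm in names(ids)) {
    sel <- model$elem_label == ids[[nm]]
    if (!any(sel)) next
    if (grepl("^housing", nm)) {
      E[sel] <- mats$housing$E; nu[sel] <- mats$housing$nu
    } else if (grepl("^cement_", nm)) {
      lvl <- sub("^cement_", "", nm)
      if (lvl %in% tr$augmented_levels) {
        E[sel] <- tr$cement_E * tr$cement_modulus_fraction
        nu[sel] <- mats$cement$nu
      } else {  # region not augmented in this cell: underlying bone
        E[sel] <- model$elem_E_bone[sel] * tr$bone_factor
        nu[sel] <- mats$bone_nu
      }
    } else if (grepl("^nucleus_", nm)) {
      E[sel] <- disc$nucleus$E; nu[sel] <- disc$nucleus$nu
    }
  }
  is_annulus <- model$elem_label %in% ids[grepl("^annulus_", names(ids))]
  model$elem_E_iso <- E
  model$elem_nu_iso <- nu
  model$is_annulus <- is_annulus
  model$annulus_material <- disc$annulus
  model$nucleus_material <- disc$nucleus
  if (anyNA(E[!is_annulus])) stop("internal error: unresolved element material")
  model
}

## ---- assembly --------------------------------------------------------------

elem_dofs <- function(conn) {
  m <- nrow(conn)
  edof <- matrix(0L, m, 24L)
  for (q in 1:8) {
    edof[, 3L * q - 2L] <- 3L * conn[, q] - 2L
    edof[, 3L * q - 1L] <- 3L * conn[, q] - 1L
    edof[, 3L * q] <- 3L * conn[, q]
  }
  edof
}

#' Assemble the global stiffness matrix of a model
#'
#' Sparse symmetric assembly over material groups: isotropic elements share
#' one template element matrix per distinct Poisson ratio (scaled by the
#' element modulus); annulus elements get individually rotated orthotropic
#' matrices, cached over the distinct cylindrical angles.
#'
#' @param model An `fe_model`.
#' @return Sparse `dgCMatrix` of size 3 n_nodes, both triangles stored.
#' @export
fe_assemble <- function(model) {
  stopifnot(inherits(model, "fe_model"))
  assemble_subset(model, seq_len(nrow(model$conn)))
}

# Assemble the stiffness contribution of a subset of elements (row indices
# into the element table). Used whole by fe_assemble and piecewise by the
# disc calibration, which scales the disc blocks without re-assembly.
assemble_subset <- function(model, rows) {
  Bq <- hex8_B(model$voxel_size)
  edof <- elem_dofs(model$conn)
  ndof <- 3L * model$n_nodes
  ii <- list(); jj <- list(); xx <- list()
  push <- function(rows, kevec_matrix) {
    # kevec_matrix: 576 x n_elem matrix of element stiffness entries
    ed <- edof[rows, , drop = FALSE]
    ii[[length(ii) + 1L]] <<- as.vector(t(ed[, rep(1:24, times = 24), drop = FALSE]))
    jj[[length(jj) + 1L]] <<- as.vector(t(ed[, rep(1:24, each = 24), drop = FALSE]))
    xx[[length(xx) + 1L]] <<- as.vector(kevec_matrix)
  }
  sub_ann <- model$is_annulus[rows]
  iso <- rows[!sub_ann]
  for (nuv in unique(model$elem_nu_iso[iso])) {
    rws <- iso[model$elem_nu_iso[iso] == nuv]
    ke1 <- ke_from_constitutive(constitutive_matrix(material_isotropic(1, nuv)), Bq)
    push(rws, outer(as.vector(ke1), model$elem_E_iso[rws]))
  }
  ann <- rows[sub_ann]
  if (length(ann)) {
    Cann <- constitutive_matrix(model$annulus_material)
    angs <- model$elem_angle[ann]
    kemat <- matrix(0, 576L, length(ann))
    for (a in unique(angs)) {
      ke <- ke_from_constitutive(rotate_constitutive(Cann, rotation_about_z(a)), Bq)
      kemat[, angs == a] <- as.vector(ke)
    }
    push(ann, kemat)
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(ndof, ndof))
}

## ---- constrained solve -----------------------------------------------------

# Reduction u = A z + b for the plate boundary conditions.
# Bottom plate nodes fully fixed; top plate nodes move as a rigid body whose
# reference point carries the prescribed axial displacement. In "ball" mode
# the plate's lateral translations and rotations remain free unknowns
# (q = ux, uy, rx, ry, rz); in "locked" mode the plate dofs are all
# prescribed.
plate_reduction <- function(model, applied_displacement) {
  ndof <- 3L * model$n_nodes
  top <- model$top_nodes; bot <- model$bottom_nodes
  plate_dofs <- c(3L * c(top, bot) - 2L, 3L * c(top, bot) - 1L, 3L * c(top, bot))
  free_dofs <- setdiff(seq_len(ndof), plate_dofs)
  b <- numeric(ndof)
  b[3L * top] <- -applied_displacement
  nfree <- length(free_dofs)
  ti <- free_dofs; tj <- seq_len(nfree); tx <- rep(1, nfree)
  nq <- 0L
  if (model$config$loading == "ball") {
    ref <- colMeans(model$node_xyz[top, , drop = FALSE])
    rx <- model$node_xyz[top, 1] - ref[1]
    ry <- model$node_xyz[top, 2] - ref[2]
    q0 <- nfree
    ti <- c(ti, 3L * top - 2L, 3L * top - 1L,            # plate ux, uy
            3L * top - 2L, 3L * top - 1L,                # theta_z coupling
            3L * top, 3L * top)                          # theta_x, theta_y
    tj <- c(tj, rep(q0 + 1L, length(top)), rep(q0 + 2L, length(top)),
            rep(q0 + 5L, 2L * length(top)),
            rep(q0 + 3L, length(top)), rep(q0 + 4L, length(top)))
    tx <- c(tx, rep(1, 2L * length(top)), -ry, rx, ry, -rx)
    nq <- 5L
  }
  A <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(ndof, nfree + nq))
  list(A = A, b = b, free_dofs = free_dofs, nq = nq)
}

#' Assemble and solve the displacement-controlled problem
#'
#' Fixes the bottom plate, drives the top plate axially by
#' `applied_displacement` (compression positive), solves the reduced sparse
#' symmetric system, and recovers displacements, centroid stresses, and the
#' plate reaction. The direct path uses a supernodal Cholesky factorization,
#' recomputed per solve so that peak memory never exceeds one factor. A
#' diagonally preconditioned conjugate-gradient path is available as
#' `method = "cg"`.
#'
#' @param model An `fe_model`.
#' @param applied_displacement Axial compression of the top plate (mm, > 0).
#' @param method `"direct"` (default) or `"cg"`.
#' @param compute_stress Compute element centroid stresses (default TRUE).
#' @param K Optional pre-assembled stiffness matrix (as from [fe_assemble()]).
#' @return A `solve_result`: nodal displacements `U` (n x 3, mm), per-element
#'   stress `stress` (m x 6, MPa), `reaction` (N, compression positive),
#'   `applied_displacement` (mm), `k` (N/mm), and the relative equilibrium
#'   residual `equilibrium`.
#' @export
assemble_and_solve <- function(model, applied_displacement,
                               method = c("direct", "cg"),
                               compute_stress = TRUE, K = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(model, "fe_model"))
  if (!is.numeric(applied_displacement) || applied_displacement <= 0) {
    stop("applied_displacement must be > 0 (axial compression, mm)")
  }
  if (is.null(K)) K <- fe_assemble(model)
  solve_displacement_system(model, K, applied_displacement, method,
                            compute_stress)
}

solve_displacement_system <- function(model, K, delta, method = "direct",
                                      compute_stress = TRUE) {
  red <- plate_reduction(model, delta)
  Kred <- Matrix::forceSymmetric(Matrix::crossprod(red$A, K %*% red$A))
  rhs <- as.vector(-Matrix::crossprod(red$A, K %*% red$b))
  z <- if (method == "direct") {
    direct_solve(Kred, rhs, model)
  } else {
    cg_solve(Kred, rhs)
  }
  u <- as.vector(red$A %*% z) + red$b
  r <- as.vector(K %*% u)
  top_z <- 3L * model$top_nodes
  bot_z <- 3L * model$bottom_nodes
  f_top <- sum(r[top_z]); f_bot <- sum(r[bot_z])
  reaction <- -f_top  # compression positive
  if (reaction <= 0) warning("non-positive plate reaction; model may be degenerate")
  res <- structure(list(
    U = matrix(u, ncol = 3L, byrow = TRUE),
    stress = NULL,
    reaction = reaction,
    applied_displacement = delta,
    k = reaction / delta,
    equilibrium = abs(f_top + f_bot) / max(abs(f_top), .Machine$double.eps)
  ), class = "solve_result")
  if (compute_stress) res$stress <- element_stresses(res, model)
  res
}

# One fresh supernodal factorization per solve. The factor of a
# production-size segment runs to about a gigabyte, so it is deliberately
# not retained between solves: peak memory stays at one factor regardless
# of how many solves a calibration or sweep chains together.
direct_solve <- function(Kred, rhs, model = NULL) {
  ch <- tryCatch(
    Matrix::Cholesky(Kred, LDL = FALSE, super = TRUE),
    error = function(e) {
      if (!is.null(model)) {
        nc <- count_components(model)
        if (nc > 1L) {
          stop("stiffness matrix is singular: the mesh has ", nc,
               " disconnected components", call. = FALSE)
        }
      }
      stop("stiffness factorization failed: ", conditionMessage(e),
           call. = FALSE)
    })
  out <- as.vector(Matrix::solve(ch, rhs))
  rm(ch)
  out
}

count_components <- function(model) {
  edges <- rbind(rep(model$conn[, 1], 7L),
                 as.vector(model$conn[, 2:8]))
  g <- igraph::make_graph(as.vector(edges), n = model$n_nodes, directed = FALSE)
  igraph::components(g)$no
}

# Jacobi-preconditioned conjugate gradients, relative tolerance 1e-8.
cg_solve <- function(Kred, rhs, tol = 1e-8, maxit = 50000L) {
  dinv <- 1 / Matrix::diag(Kred)
  x <- numeric(length(rhs))
  r <- rhs
  z <- dinv * r
  p <- z
  rz <- sum(r * z)
  nb <- sqrt(sum(rhs^2))
  for (it in seq_len(maxit)) {
    Ap <- as.vector(Kred %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    if (sqrt(sum(r^2)) <= tol * nb) return(x)
    z <- dinv * r
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  warning("conjugate gradients reached maxit without converging to ", tol)
  x
}

## ---- stress recovery and stiffness ----------------------------------------

#' Element centroid stresses
#'
#' Stress at each element centroid from the trilinear shape-function strain,
#' averaged over the 2x2x2 Gauss points (for a cubic voxel this equals the
#' centroid evaluation), multiplied by the element constitutive matrix.
#'
#' @param result A `solve_result` (see [assemble_and_solve()]).
#' @param model The `fe_model` that produced it.
#' @return m x 6 matrix of stress tensors in Voigt order
#'   (s11, s22, s33, t23, t13, t12), MPa.
#' @export
element_stresses <- function(result, model) {
  stopifnot(inherits(result, "solve_result"), inherits(model, "fe_model"))
  Bq <- hex8_B(model$voxel_size)
  u <- as.vector(t(result$U))
  edof <- elem_dofs(model$conn)
  Ue <- matrix(u[edof], nrow = nrow(edof))
  eps <- Ue %*% t(Bq$mean)
  sig <- matrix(0, nrow(eps), 6L)
  iso <- which(!model$is_annulus)
  for (nuv in unique(model$elem_nu_iso[iso])) {
    rows <- iso[model$elem_nu_iso[iso] == nuv]
    C1 <- constitutive_matrix(material_isotropic(1, nuv))
    sig[rows, ] <- (eps[rows, , drop = FALSE] %*% t(C1)) * model$elem_E_iso[rows]
  }
  ann <- which(model$is_annulus)
  if (length(ann)) {
    Cann <- constitutive_matrix(model$annulus_material)
    angs <- model$elem_angle[ann]
    for (a in unique(angs)) {
      rows <- ann[angs == a]
      Ca <- rotate_constitutive(Cann, rotation_about_z(a))
      sig[rows, ] <- eps[rows, , drop = FALSE] %*% t(Ca)
    }
  }
  sig
}

#' Segmental stiffness of a solved model
#'
#' For a geometrically and materially linear model the load-displacement
#' curve is a line through the origin, so the experimental average gradient
#' reduces exactly to reaction / applied displacement.
#'
#' @param result A `solve_result`.
#' @return A `stiffness_result` with component `k` (N/mm).
#' @export
segment_stiffness <- function(result) {
  stopifnot(inherits(result, "solve_result"))
  if (result$applied_displacement <= 0) {
    stop("applied displacement must be positive to define a stiffness")
  }
  structure(list(k = result$reaction / result$applied_displacement),
            class = "stiffness_result")
}

#' @export
print.solve_result <- function(x, ...) {
  cat(sprintf(
    "<solve_result> reaction %.4g N at %.4g mm -> k = %.4g N/mm (equilibrium %.2e)\n",
    x$reaction, x$applied_displacement, x$k, x$equilibrium))
  invisible(x)
}

#' @export
print.stiffness_result <- function(x, ...) {
  cat(sprintf("<stiffness_result> k = %.6g N/mm\n", x$k))
  invisible(x)
}
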