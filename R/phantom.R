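#' Specification of the synthetic three-vertebra phantom
#'
#' Describes an idealized T12-L1-L2 segment on a regular voxel grid: three
#' elliptic-cylinder vertebral bodies with a cortical shell, two intervertebral
#' discs (annulus ring around a nucleus core), and cement end-housings that
#' carry the loading plates. Axial = third array axis, anterior = +second
#' axis; world coordinates are voxel-centred,
#' `x = origin + (index - 1 + 0.5) * voxel_size`.
#'
#' All heights must be whole multiples of `voxel_size` (no fractional voxels);
#' the in-plane radii may be arbitrary positive lengths. The default
#' trabecular greyscale moments are chosen so that the greyscale-to-modulus
#' map under the default [modulus_calibration()] reproduces the reference
#' element-specific bone modulus distribution (mean 128.41 MPa,
#' SD 66.20 MPa) in expectation after clipping at zero
#' (see [clipped_normal_params()]).
#'
#' @param voxel_size Edge length of the cubic voxels (mm). The default 1.4 mm
#'   matches the convergence-tested hexahedral element size of the segment
#'   models this phantom emulates.
#' @param body_radius_lat,body_radius_ap Lateral and anterior-posterior
#'   semi-axes of the vertebral body ellipse (mm).
#' @param body_height,disc_height,housing_height Heights of one vertebral
#'   body, one disc, and one end housing (mm); whole multiples of `voxel_size`.
#' @param cortical_thickness Cortical shell thickness in whole voxels (>= 1).
#' @param nucleus_radius_fraction Nucleus semi-axes as a fraction of the disc
#'   semi-axes, strictly inside (0, 1); the nucleus voxel-count fraction of the
#'   disc is approximately the square of this value.
#' @param housing_margin Extra in-plane margin of the housing footprint beyond
#'   the body ellipse (mm).
#' @param trabecular_grey_mean,trabecular_grey_sd Mean and SD of the i.i.d.
#'   Gaussian trabecular greyscale field (clipped at zero).
#' @param tissue_grey Named greyscale constants for the non-trabecular
#'   tissues: `cortical`, `annulus`, `nucleus`, `housing`, `cement`.
#' @param seed Integer seed for the trabecular field.
#' @param levels Ordered vertebra labels, top to bottom.
#' @return A validated `phantom_spec` object.
#' @export
phantom_spec <- function(voxel_size = 1.4,
                         body_radius_lat = 16.8,
                         body_radius_ap = 11.2,
                         body_height = 23.8,
                         disc_height = 8.4,
                         housing_height = 5.6,
                         cortical_thickness = 1L,
                         nucleus_radius_fraction = 0.6,
                         housing_margin = 1.4,
                         trabecular_grey_mean = NULL,
                         trabecular_grey_sd = NULL,
                         tissue_grey = c(cortical = 2600, annulus = 20,
                                         nucleus = 10, housing = 3000,
                                         cement = 4000),
                         seed = 42L,
                         levels = c("T12", "L1", "L2")) {
  lens <- c(voxel_size = voxel_size, body_radius_lat = body_radius_lat,
            body_radius_ap = body_radius_ap, body_height = body_height,
            disc_height = disc_height, housing_height = housing_height,
            housing_margin = housing_margin)
  if (any(!is.finite(lens)) || any(lens <= 0)) {
    stop("all phantom lengths must be positive and finite")
  }
  if (nucleus_radius_fraction <= 0 || nucleus_radius_fraction >= 1) {
    stop("nucleus_radius_fraction must lie strictly inside (0, 1)")
  }
  if (cortical_thickness < 1 || cortical_thickness != round(cortical_thickness)) {
    stop("cortical_thickness must be an integer number of voxels >= 1")
  }
  for (nm in c("body_height", "disc_height", "housing_height")) {
    v <- lens[[nm]] / voxel_size
    if (abs(v - round(v)) > 1e-8) {
      stop(nm, " = ", lens[[nm]], " mm is not a whole number of ",
           voxel_size, " mm voxels")
    }
  }
  if (is.null(trabecular_grey_mean) || is.null(trabecular_grey_sd)) {
    p <- clipped_normal_params(128.41, 66.20, floor = 0.01)
    if (is.null(trabecular_grey_mean)) trabecular_grey_mean <- p[["mean"]]
    if (is.null(trabecular_grey_sd)) trabecular_grey_sd <- p[["sd"]]
  }
  stopifnot(trabecular_grey_sd > 0)
  need <- c("cortical", "annulus", "nucleus", "housing", "cement")
  if (!all(need %in% names(tissue_grey))) {
    stop("tissue_grey must name: ", paste(need, collapse = ", "))
  }
  if (length(levels) != 3L || anyDuplicated(levels)) {
    stop("levels must be three distinct vertebra labels (top to bottom)")
  }
  structure(list(
    voxel_size = voxel_size,
    body_radius_lat = body_radius_lat, body_radius_ap = body_radius_ap,
    body_height = body_height, disc_height = disc_height,
    housing_height = housing_height,
    cortical_thickness = as.integer(cortical_thickness),
    nucleus_radius_fraction = nucleus_radius_fraction,
    housing_margin = housing_margin,
    trabecular_grey_mean = trabecular_grey_mean,
    trabecular_grey_sd = trabecular_grey_sd,
    tissue_grey = tissue_grey,
    seed = as.integer(seed),
    levels = levels
  ), class = "phantom_spec")
}

#' Parent-normal parameters that hit target moments after clipping
#'
#' The trabecular modulus field is modelled as max(N(mu, sigma), floor).
#' Clipping a normal at zero inflates the mean and deflates the SD relative
#' to the parent distribution; this helper inverts that bias, returning the
#' parent (mu, sigma) whose clipped distribution has exactly the requested
#' mean and SD. Closed-form truncated-normal moments are solved by
#' Nelder-Mead to high precision.
#'
#' @param target_mean,target_sd Desired moments of the clipped variable.
#' @param floor Clipping floor (same units), default 0.
#' @return Named vector `c(mean = mu, sd = sigma)` of the parent normal.
#' @export
clipped_normal_params <- function(target_mean, target_sd, floor = 0) {
  stopifnot(target_sd > 0, target_mean > floor)
  mom <- function(mu, sg) {
    a <- (floor - mu) / sg
    P <- stats::pnorm(a); ph <- stats::dnorm(a)
    m1 <- floor * P + mu * (1 - P) + sg * ph
    m2 <- floor^2 * P + (mu^2 + sg^2) * (1 - P) + (mu + floor) * sg * ph
    c(m1, sqrt(pmax(m2 - m1^2, 0)))
  }
  obj <- function(p) {
    if (p[2] <= 0) return(1e12)
    m <- mom(p[1], p[2])
    (m[1] - target_mean)^2 + (m[2] - target_sd)^2
  }
  fit <- stats::optim(c(target_mean, target_sd), obj,
                      control = list(reltol = 1e-14, maxit = 5000))
  fit <- stats::optim(fit$par, obj, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 500))
  c(mean = fit$par[1], sd = fit$par[2])
}

## ---- label bookkeeping -----------------------------------------------------

# Fixed integer coding of the tissue labels for a given level ordering.
phantom_labels <- function(levels = c("T12", "L1", "L2")) {
  ids <- integer(0)
  for (i in seq_along(levels)) {
    ids[paste0("trabecular_", levels[i])] <- 2L * i - 1L
    ids[paste0("cortical_", levels[i])] <- 2L * i
  }
  ids["annulus_upper"] <- 7L; ids["nucleus_upper"] <- 8L
  ids["annulus_lower"] <- 9L; ids["nucleus_lower"] <- 10L
  ids["housing_top"] <- 11L; ids["housing_bottom"] <- 12L
  for (i in seq_along(levels)) ids[paste0("cement_", levels[i])] <- 12L + i
  ids
}

#' Look up label ids in a label map
#'
#' @param labels A `label_map`.
#' @param name Character vector of label names (e.g. `"trabecular_L1"`).
#' @return Integer label ids.
#' @export
label_id <- function(labels, name) {
  stopifnot(inherits(labels, "label_map"))
  miss <- setdiff(name, names(labels$labels))
  if (length(miss)) stop("unknown label(s): ", paste(miss, collapse = ", "))
  unname(labels$labels[name])
}

#' @rdname label_id
#' @export
label_names <- function(labels) names(labels$labels)

## ---- containers ------------------------------------------------------------

#' Voxel image and label map containers
#'
#' Thin containers for a 3-D greyscale field and its tissue labels on a
#' regular grid. `voxel_size` is the cubic voxel edge (mm), `origin` the world
#' coordinate (mm) of the corner of voxel (1,1,1).
#'
#' @param data 3-D numeric (image) or integer (labels) array.
#' @param voxel_size Voxel edge length, mm.
#' @param origin Length-3 numeric, mm.
#' @param labels Named integer vector mapping label names to codes
#'   (label maps only); `0` is background and is implicit.
#' @return A `voxel_image` or `label_map` object.
#' @export
voxel_image <- function(data, voxel_size, origin = c(0, 0, 0)) {
  stopifnot(is.array(data), length(dim(data)) == 3L, voxel_size > 0,
            length(origin) == 3L)
  if (any(!is.finite(data))) stop("voxel image must be finite everywhere")
  if (any(data < 0)) stop("voxel image must be non-negative (clip before use)")
  structure(list(data = data, voxel_size = voxel_size, origin = origin),
            class = "voxel_image")
}

#' @rdname voxel_image
#' @export
label_map <- function(data, voxel_size, labels, origin = c(0, 0, 0)) {
  stopifnot(is.array(data), length(dim(data)) == 3L, voxel_size > 0,
            length(origin) == 3L, is.integer(labels), length(labels) > 0)
  storage.mode(data) <- "integer"
  present <- setdiff(unique(as.vector(data)), 0L)
  unknown <- setdiff(present, labels)
  if (length(unknown)) stop("label data contains unnamed codes: ",
                            paste(unknown, collapse = ", "))
  structure(list(data = data, voxel_size = voxel_size, origin = origin,
                 labels = labels),
            class = "label_map")
}

#' @export
print.voxel_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_image> %d x %d x %d voxels @ %g mm, grey range [%g, %g]\n",
              d[1], d[2], d[3], x$voxel_size, min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.label_map <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<label_map> %d x %d x %d voxels @ %g mm\n",
              d[1], d[2], d[3], x$voxel_size))
  tab <- table(factor(x$data, levels = c(0L, x$labels),
                      labels = c("background", names(x$labels))))
  print(tab[tab > 0])
  invisible(x)
}

## ---- generation ------------------------------------------------------------

# In-plane elliptic mask at voxel centres; a, b semi-axes in mm.
ellipse_mask <- function(nx, ny, cx, cy, a_vox, b_vox) {
  ix <- rep(seq_len(nx), times = ny)
  iy <- rep(seq_len(ny), each = nx)
  matrix(((ix - cx) / a_vox)^2 + ((iy - cy) / b_vox)^2 <= 1 + 1e-12, nx, ny)
}

phantom_grid <- function(spec) {
  h <- spec$voxel_size
  a_vox <- spec$body_radius_lat / h
  b_vox <- spec$body_radius_ap / h
  ah <- a_vox + spec$housing_margin / h
  bh <- b_vox + spec$housing_margin / h
  nx <- 2L * floor(ah) + 3L
  ny <- 2L * floor(bh) + 3L
  nb <- as.integer(round(spec$body_height / h))
  nd <- as.integer(round(spec$disc_height / h))
  nh <- as.integer(round(spec$housing_height / h))
  nz <- 2L * nh + 3L * nb + 2L * nd
  list(nx = nx, ny = ny, nz = nz, cx = (nx + 1) / 2, cy = (ny + 1) / 2,
       a_vox = a_vox, b_vox = b_vox, ah = ah, bh = bh,
       nb = nb, nd = nd, nh = nh)
}

#' Generate the synthetic three-vertebra phantom
#'
#' Builds the pre-treatment greyscale image and label map: three stacked
#' elliptic-cylinder vertebral bodies (trabecular core wrapped in a cortical
#' shell of the stated voxel thickness, including endplate slices), two disc
#' slabs split into annulus ring and nucleus core, and cement housings at both
#' ends. The trabecular greyscale is i.i.d. Gaussian clipped at zero and
#' seeded; every other tissue carries its constant greyscale from
#' `spec$tissue_grey`.
#'
#' @param spec A [phantom_spec()].
#' @return List with components `image` ([voxel_image]) and `labels`
#'   ([label_map]).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- phantom_grid(spec)
  t <- spec$cortical_thickness
  if (g$nb <= 2 * t) {
    stop("grid too small: body height of ", g$nb,
         " voxels cannot contain a trabecular core inside a ", t,
         "-voxel cortical shell")
  }
  if (g$a_vox - t < 1 || g$b_vox - t < 1) {
    stop("grid too small: body radii leave no trabecular interior after a ",
         t, "-voxel cortical shell")
  }
  if (g$nd < 1) stop("grid too small: disc height is below one voxel")
  body <- ellipse_mask(g$nx, g$ny, g$cx, g$cy, g$a_vox, g$b_vox)
  inner <- ellipse_mask(g$nx, g$ny, g$cx, g$cy, g$a_vox - t, g$b_vox - t)
  housing <- ellipse_mask(g$nx, g$ny, g$cx, g$cy, g$ah, g$bh)
  nucleus <- ellipse_mask(g$nx, g$ny, g$cx, g$cy,
                          g$a_vox * spec$nucleus_radius_fraction,
                          g$b_vox * spec$nucleus_radius_fraction)
  if (!any(nucleus)) stop("grid too small: nucleus region is empty")
  annulus <- body & !nucleus

  ids <- phantom_labels(spec$levels)
  lab <- array(0L, c(g$nx, g$ny, g$nz))
  z <- 0L
  put <- function(mask2d, n, code) {
    sl <- matrix(0L, g$nx, g$ny); sl[mask2d] <- code
    for (k in seq_len(n)) lab[, , z + k] <<- pmax(lab[, , z + k], sl)
    z <<- z + n
  }
  put_body <- function(level) {
    trab <- ids[[paste0("trabecular_", level)]]
    cort <- ids[[paste0("cortical_", level)]]
    for (k in seq_len(g$nb)) {
      sl <- matrix(0L, g$nx, g$ny)
      endplate <- k <= t || k > g$nb - t
      sl[body] <- cort
      if (!endplate) sl[inner] <- trab
      lab[, , z + k] <<- sl
    }
    z <<- z + g$nb
  }
  put_disc <- function(which) {
    ann <- ids[[paste0("annulus_", which)]]
    nuc <- ids[[paste0("nucleus_", which)]]
    sl <- matrix(0L, g$nx, g$ny); sl[annulus] <- ann; sl[nucleus] <- nuc
    for (k in seq_len(g$nd)) lab[, , z + k] <<- sl
    z <<- z + g$nd
  }
  # stacked bottom to top: housing, L2, lower disc, L1, upper disc, T12, housing
  put(housing, g$nh, ids[["housing_bottom"]])
  put_body(spec$levels[3])
  put_disc("lower")
  put_body(spec$levels[2])
  put_disc("upper")
  put_body(spec$levels[1])
  put(housing, g$nh, ids[["housing_top"]])

  img <- array(0, c(g$nx, g$ny, g$nz))
  tg <- spec$tissue_grey
  img[lab %in% ids[paste0("cortical_", spec$levels)]] <- tg[["cortical"]]
  img[lab %in% ids[c("annulus_upper", "annulus_lower")]] <- tg[["annulus"]]
  img[lab %in% ids[c("nucleus_upper", "nucleus_lower")]] <- tg[["nucleus"]]
  img[lab %in% ids[c("housing_top", "housing_bottom")]] <- tg[["housing"]]
  trab_idx <- which(lab %in% ids[paste0("trabecular_", spec$levels)])
  img[trab_idx] <- with_local_seed(spec$seed, {
    pmax(stats::rnorm(length(trab_idx), spec$trabecular_grey_mean,
                      spec$trabecular_grey_sd), 0)
  })

  list(image = voxel_image(img, spec$voxel_size),
       labels = label_map(lab, spec$voxel_size, ids))
}

# Run expr under a fixed seed without disturbing the caller's RNG stream.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Label an intravertebral cement region
#'
#' Re-labels trabecular voxels of one vertebral body as injected cement. The
#' region is grown from the body centroid in deterministic order (Euclidean
#' distance from the centroid, linear voxel index as tie-break), producing a
#' connected, centrally seeded blob whose voxel count is
#' `round(fill_fraction * body voxel count)`.
#'
#' `fill_fraction` is measured against the whole vertebral body
#' (trabecular + cortical); because the cortical shell cannot be augmented,
#' the largest admissible fraction is the body's trabecular fraction, and a
#' request beyond it raises an error naming that maximum.
#'
#' @param labels A [label_map] containing the phantom labels.
#' @param level Vertebra label, e.g. `"L1"`.
#' @param fill_fraction Cement volume as a fraction of vertebral body volume
#'   (0 to 1); the clinical reference point is 0.2.
#' @return A new `label_map` with the cement region labelled
#'   `cement_<level>`.
#' @export
add_cement_region <- function(labels, level, fill_fraction = 0.2) {
  stopifnot(inherits(labels, "label_map"))
  if (fill_fraction < 0 || fill_fraction > 1) {
    stop("fill_fraction must lie in [0, 1]")
  }
  trab_name <- paste0("trabecular_", level)
  cem_name <- paste0("cement_", level)
  body_ids <- label_id(labels, c(trab_name, paste0("cortical_", level),
                                 cem_name))
  trab_id <- body_ids[1]; cem_id <- body_ids[3]
  dat <- labels$data
  body_idx <- which(dat %in% body_ids)
  if (!length(body_idx)) stop("level ", level, " has no vertebral body voxels")
  avail_idx <- which(dat == trab_id | dat == cem_id)
  n_target <- round(fill_fraction * length(body_idx))
  if (n_target > length(avail_idx)) {
    stop(sprintf(
      "fill_fraction %.3f exceeds the trabecular fraction of the %s body; maximum achievable is %.3f",
      fill_fraction, level, length(avail_idx) / length(body_idx)))
  }
  # reset any existing cement of this level, then grow afresh
  dat[dat == cem_id] <- trab_id
  if (n_target > 0) {
    ijk <- arrayInd(body_idx, dim(dat))
    centroid <- colMeans(ijk)
    aijk <- arrayInd(avail_idx, dim(dat))
    d2 <- (aijk[, 1] - centroid[1])^2 + (aijk[, 2] - centroid[2])^2 +
      (aijk[, 3] - centroid[3])^2
    ord <- order(d2, avail_idx)
    dat[avail_idx[ord[seq_len(n_target)]]] <- cem_id
  }
  label_map(dat, labels$voxel_size, labels$labels, labels$origin)
}

#' Overlay cement greyscale to form a post-treatment image
#'
#' Produces the post-treatment greyscale image corresponding to a cemented
#' label map: voxels labelled as cement take the bright cement greyscale,
#' everything else keeps its pre-treatment value.
#'
#' @param image Pre-treatment [voxel_image].
#' @param labels [label_map] containing cement labels.
#' @param grey Cement greyscale value.
#' @return A new `voxel_image`.
#' @export
cement_image <- function(image, labels, grey = 4000) {
  stopifnot(inherits(image, "voxel_image"), inherits(labels, "label_map"),
            all(dim(image$data) == dim(labels$data)))
  cem <- labels$labels[grepl("^cement_", names(labels$labels))]
  dat <- image$data
  dat[labels$data %in% cem] <- grey
  voxel_image(dat, image$voxel_size, image$origin)
}
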