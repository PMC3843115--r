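#' Greyscale-to-modulus calibration
#'
#' Linear density-modulus law `E = max(slope * grey + intercept, floor)`
#' applied element-wise to bone voxels. QCT greyscale is assumed already
#' density-calibrated (hydroxyapatite phantom), so the default is the
#' identity map with a small positive floor that keeps every element modulus
#' strictly positive.
#'
#' @param slope MPa per greyscale unit, > 0.
#' @param intercept MPa.
#' @param floor Minimum assigned modulus, MPa, > 0.
#' @return A `modulus_calibration` object.
#' @export
modulus_calibration <- function(slope = 1, intercept = 0, floor = 0.01) {
  stopifnot(is.finite(slope), is.finite(intercept), is.finite(floor))
  if (slope <= 0) stop("calibration slope must be > 0")
  if (floor <= 0) stop("calibration floor must be > 0")
  structure(list(slope = slope, intercept = intercept, floor = floor),
            class = "modulus_calibration")
}

apply_calibration <- function(calib, grey) {
  pmax(calib$slope * grey + calib$intercept, calib$floor)
}

#' Map greyscale to element-specific elastic modulus
#'
#' Bone-labelled voxels (trabecular and cortical) receive the linear
#' greyscale law; non-bone tissues receive the nominal modulus of their
#' reference material (axial modulus for the orthotropic annulus). The result
#' is a per-voxel modulus field aligned with the image grid, `NA` outside the
#' labelled region.
#'
#' @param image A [voxel_image].
#' @param labels The matching [label_map].
#' @param calib A [modulus_calibration].
#' @param materials Material table, see [default_materials()].
#' @param disc_state Disc state used for the nominal disc moduli.
#' @return A `modulus_field`: list with `E` (3-D array, MPa), `labels`,
#'   `voxel_size`.
#' @export
greyscale_to_modulus <- function(image, labels, calib = modulus_calibration(),
                                 materials = default_materials(),
                                 disc_state = c("healthy", "degenerated")) {
  stopifnot(inherits(image, "voxel_image"), inherits(labels, "label_map"),
            inherits(calib, "modulus_calibration"),
            all(dim(image$data) == dim(labels$data)))
  disc_state <- match.arg(disc_state)
  ids <- labels$labels
  E <- array(NA_real_, dim(image$data))
  bone <- ids[grepl("^(trabecular|cortical)_", names(ids))]
  sel <- labels$data %in% bone
  E[sel] <- apply_calibration(calib, image$data[sel])
  disc <- disc_properties(disc_state, materials)
  const <- list(
    annulus = disc$annulus$E3,
    nucleus = disc$nucleus$E,
    housing = materials$housing$E,
    cement = materials$cement$E
  )
  for (nm in names(const)) {
    lab_ids <- ids[grepl(paste0("^", nm), names(ids))]
    if (length(lab_ids)) E[labels$data %in% lab_ids] <- const[[nm]]
  }
  structure(list(E = E, labels = labels, voxel_size = image$voxel_size),
            class = "modulus_field")
}

#' @export
print.modulus_field <- function(x, ...) {
  v <- x$E[!is.na(x$E)]
  cat(sprintf("<modulus_field> %d elements, E in [%g, %g] MPa\n",
              length(v), min(v), max(v)))
  invisible(x)
}

## ---- binary 3-D morphology (array-shift implementation) --------------------

# Offsets of a discrete ball of the given radius (voxels), 6-connected at r=1.
ball_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  g[g$dx^2 + g$dy^2 + g$dz^2 <= radius^2 + 1e-9, , drop = FALSE]
}

shift_mask <- function(mask, dx, dy, dz, fill = FALSE) {
  d <- dim(mask)
  out <- array(fill, d)
  sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
  sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
  sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
  if (!length(sx) || !length(sy) || !length(sz)) return(out)
  out[sx, sy, sz] <- mask[sx - dx, sy - dy, sz - dz]
  out
}

dilate3d <- function(mask, radius = 1) {
  if (radius <= 0) return(mask)
  off <- ball_offsets(radius)
  out <- array(FALSE, dim(mask))
  for (i in seq_len(nrow(off))) {
    out <- out | shift_mask(mask, off$dx[i], off$dy[i], off$dz[i], fill = FALSE)
  }
  out
}

# Erosion pads outside the volume with foreground, so closing does not eat
# structures that touch the array boundary.
erode3d <- function(mask, radius = 1) {
  if (radius <= 0) return(mask)
  off <- ball_offsets(radius)
  out <- array(TRUE, dim(mask))
  for (i in seq_len(nrow(off))) {
    out <- out & shift_mask(mask, off$dx[i], off$dy[i], off$dz[i], fill = TRUE)
  }
  out
}

close3d <- function(mask, radius = 1) erode3d(dilate3d(mask, radius), radius)

# Largest 6-connected component of a binary mask.
largest_component <- function(mask) {
  idx <- which(mask)
  if (!length(idx)) return(mask)
  d <- dim(mask)
  comp <- component_labels(idx, d)
  keep <- idx[comp == which.max(tabulate(comp))]
  out <- array(FALSE, d)
  out[keep] <- TRUE
  out
}

# Component id per foreground voxel (6-connectivity), via igraph.
component_labels <- function(idx, d) {
  pos <- integer(prod(d)); pos[idx] <- seq_along(idx)
  ijk <- arrayInd(idx, d)
  edges <- integer(0)
  for (ax in 1:3) {
    nb <- ijk; nb[, ax] <- nb[, ax] + 1L
    ok <- nb[, ax] <= d[ax]
    lin <- (nb[ok, 3] - 1L) * d[1] * d[2] + (nb[ok, 2] - 1L) * d[1] + nb[ok, 1]
    hit <- pos[lin] > 0L
    edges <- c(edges, rbind(pos[idx[ok]][hit], pos[lin][hit]))
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  igraph::components(g)$membership
}

#' Threshold segmentation with flood-fill and morphological closing
#'
#' Bins the image by an increasing sequence of greyscale cut-points: voxels in
#' `[t_i, t_{i+1})` fall into bin i, voxels at or above the last threshold
#' into the top bin (ties at a cut-point go to the higher bin), voxels below
#' the first threshold are background. Each bin is optionally reduced to its
#' largest 6-connected component (flood fill) and then regularized by a
#' morphological closing of the stated radius. When closings of different
#' bins claim the same voxel, the higher bin wins; the pipeline is fully
#' deterministic.
#'
#' @param image A [voxel_image].
#' @param thresholds Strictly increasing greyscale cut-points.
#' @param closing_radius Radius (voxels) of the closing ball; 0 disables.
#' @param keep_largest Keep only the largest connected component per bin.
#' @return A [label_map] with labels `bin_1 < bin_2 < ...`; empty bins are
#'   dropped with a warning.
#' @export
threshold_segment <- function(image, thresholds, closing_radius = 1,
                              keep_largest = TRUE) {
  stopifnot(inherits(image, "voxel_image"), length(thresholds) >= 1)
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly increasing")
  }
  nbin <- length(thresholds)
  dat <- image$data
  out <- array(0L, dim(dat))
  kept <- integer(0)
  for (b in seq_len(nbin)) {
    lo <- thresholds[b]
    hi <- if (b < nbin) thresholds[b + 1] else Inf
    mask <- dat >= lo & dat < hi
    if (!any(mask)) {
      warning("bin ", b, " [", lo, ", ", hi, ") is empty and was omitted")
      next
    }
    if (keep_largest) mask <- largest_component(mask)
    if (closing_radius > 0) mask <- close3d(mask, closing_radius)
    out[mask] <- b  # later (higher) bins overwrite
    kept <- c(kept, b)
  }
  ids <- stats::setNames(kept, paste0("bin_", kept))
  storage.mode(ids) <- "integer"
  label_map(out, image$voxel_size, ids, image$origin)
}
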