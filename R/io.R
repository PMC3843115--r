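## NIfTI, VTK and CSV interfaces.

#' Read and write voxel images and label maps as NIfTI
#'
#' Images are stored as floating-point NIfTI volumes with the voxel size in
#' the header; label maps as unsigned integer volumes with a JSON sidecar
#' (`<path minus .nii/.nii.gz>.labels.json`) naming each label code.
#'
#' @param x A [voxel_image] or [label_map].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `write_*` return `path` invisibly; `read_*` return the object.
#' @export
write_voxel_image <- function(x, path) {
  stopifnot(inherits(x, "voxel_image"))
  img <- RNifti::asNifti(x$data)
  RNifti::pixdim(img) <- rep(x$voxel_size, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_voxel_image
#' @export
read_voxel_image <- function(path) {
  img <- RNifti::readNifti(path)
  h <- RNifti::niftiHeader(img)
  voxel_image(array(as.numeric(img), dim(img)[1:3]),
              voxel_size = h$pixdim[2])
}

sidecar_path <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), ".labels.json")
}

#' @rdname write_voxel_image
#' @export
write_label_map <- function(x, path) {
  stopifnot(inherits(x, "label_map"))
  img <- RNifti::asNifti(x$data)
  RNifti::pixdim(img) <- rep(x$voxel_size, 3)
  RNifti::writeNifti(img, path, datatype = "int16")
  jsonlite::write_json(as.list(x$labels), sidecar_path(path),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_voxel_image
#' @export
read_label_map <- function(path) {
  img <- RNifti::readNifti(path)
  h <- RNifti::niftiHeader(img)
  ids <- unlist(jsonlite::read_json(sidecar_path(path)))
  storage.mode(ids) <- "integer"
  label_map(array(as.integer(img), dim(img)[1:3]),
            voxel_size = h$pixdim[2], labels = ids)
}

#' Export a modulus field
#'
#' `write_modulus_field` writes the per-voxel modulus as a float NIfTI volume
#' (background stored as 0); `write_modulus_csv` writes one row per labelled
#' voxel with its 1-based grid index, label name, and modulus.
#'
#' @param mf A `modulus_field` from [greyscale_to_modulus()].
#' @param path Output path (`.nii`/`.nii.gz` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_modulus_field <- function(mf, path) {
  stopifnot(inherits(mf, "modulus_field"))
  dat <- mf$E
  dat[is.na(dat)] <- 0
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- rep(mf$voxel_size, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_modulus_field
#' @export
write_modulus_csv <- function(mf, path) {
  stopifnot(inherits(mf, "modulus_field"))
  idx <- which(!is.na(mf$E))
  ijk <- arrayInd(idx, dim(mf$E))
  ids <- mf$labels$labels
  lab <- names(ids)[match(mf$labels$data[idx], ids)]
  utils::write.csv(
    data.frame(i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
               label = lab, E_MPa = mf$E[idx]),
    path, row.names = FALSE)
  invisible(path)
}

#' Export a solved model as legacy VTK
#'
#' Writes an ASCII legacy VTK structured-points file over the full voxel
#' grid: cell data carry the element label, modulus, von Mises stress and
#' the six stress components (zero outside the model); point data carry the
#' displacement vectors (zero on unused grid nodes). Readable by ParaView
#' and VTK-based tools.
#'
#' @param model An `fe_model`.
#' @param path Output `.vtk` path.
#' @param result Optional `solve_result` for displacement/stress fields.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(model, path, result = NULL) {
  stopifnot(inherits(model, "fe_model"))
  d <- model$dims
  h <- model$voxel_size
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "spinefe voxel model export", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d[1] + 1L, d[2] + 1L, d[3] + 1L),
               sprintf("ORIGIN %g %g %g", model$origin[1], model$origin[2],
                       model$origin[3]),
               sprintf("SPACING %g %g %g", h, h, h)), con)
  ncell <- prod(d)
  emit_cell <- function(name, values) {
    full <- numeric(ncell)
    full[model$elem_idx] <- values
    writeLines(sprintf("SCALARS %s float 1", name), con)
    writeLines("LOOKUP_TABLE default", con)
    writeLines(format(full, trim = TRUE, digits = 7), con)
  }
  writeLines(sprintf("CELL_DATA %d", ncell), con)
  emit_cell("label", model$elem_label)
  Eout <- model$elem_E_iso
  Eout[model$is_annulus] <- model$annulus_material$E3
  emit_cell("E_MPa", Eout)
  if (!is.null(result) && !is.null(result$stress)) {
    emit_cell("von_mises_MPa", von_mises(result$stress))
    comp <- c("s11", "s22", "s33", "t23", "t13", "t12")
    for (c6 in seq_len(6)) emit_cell(comp[c6], result$stress[, c6])
  }
  if (!is.null(result)) {
    npts <- prod(d + 1L)
    U <- matrix(0, npts, 3L)
    nnx <- d[1] + 1L; nny <- d[2] + 1L
    # recover each node's full-grid linear index from its coordinates
    ni <- round((model$node_xyz[, 1] - model$origin[1]) / h)
    nj <- round((model$node_xyz[, 2] - model$origin[2]) / h)
    nk <- round((model$node_xyz[, 3] - model$origin[3]) / h)
    lin <- nk * nnx * nny + nj * nnx + ni + 1L
    U[lin, ] <- result$U
    writeLines(sprintf("POINT_DATA %d", npts), con)
    writeLines("VECTORS displacement_mm float", con)
    writeLines(paste(format(U[, 1], trim = TRUE, digits = 7),
                     format(U[, 2], trim = TRUE, digits = 7),
                     format(U[, 3], trim = TRUE, digits = 7)), con)
  }
  invisible(path)
}

#' Write sweep outputs as CSV
#'
#' `write_stiffness_csv` writes the one-row-per-cell stiffness table;
#' `write_histograms_csv` writes one row per (cell, vertebra, bin) in
#' long, diff-friendly form.
#'
#' @param sweep A `study_sweep` from [run_sweep()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_stiffness_csv <- function(sweep, path) {
  stopifnot(inherits(sweep, "study_sweep"))
  utils::write.csv(sweep$records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stiffness_csv
#' @export
write_histograms_csv <- function(sweep, path) {
  stopifnot(inherits(sweep, "study_sweep"))
  rows <- NULL
  for (nm in names(sweep$histograms)) {
    hg <- sweep$histograms[[nm]]
    cell <- sub("^cell(\\d+)\\..*$", "\\1", nm)
    df <- hg$bins
    df$cell <- as.integer(cell)
    df$vertebra <- hg$level
    df$undefined_fraction <- hg$undefined_fraction
    rows <- rbind(rows, df[, c("cell", "vertebra", "lo", "hi", "count",
                               "fraction", "undefined_fraction")])
  }
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a calibration result to JSON
#'
#' @param x A `calibration_result`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_calibration_json <- function(x, path) {
  stopifnot(inherits(x, "calibration_result"))
  jsonlite::write_json(list(
    annulus_factor = x$annulus_factor,
    nucleus_factor = x$nucleus_factor,
    iterations = x$iterations,
    achieved_k = x$achieved_k,
    target_k = x$target_k,
    converged = x$converged,
    tolerance = x$tolerance,
    history = x$history
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
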