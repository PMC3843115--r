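#' Rescale a solved state to a common reaction force
#'
#' Displacement-controlled solves on different models reach different
#' reaction forces; comparisons of stress fields are made at a common
#' reaction (1000 N by convention). By linearity all displacements and
#' stresses scale with the ratio target / reaction; the stiffness is
#' invariant.
#'
#' @param result A `solve_result`.
#' @param target_reaction Target reaction force, N (> 0).
#' @return The rescaled `solve_result` with `reaction == target_reaction`.
#' @export
scale_to_common_load <- function(result, target_reaction = 1000) {
  stopifnot(inherits(result, "solve_result"))
  if (result$reaction <= 0) {
    stop("cannot rescale a result with non-positive reaction")
  }
  if (target_reaction <= 0) stop("target_reaction must be > 0")
  s <- target_reaction / result$reaction
  result$U <- result$U * s
  if (!is.null(result$stress)) result$stress <- result$stress * s
  result$applied_displacement <- result$applied_displacement * s
  result$reaction <- target_reaction
  result
}

#' Element rows of one vertebra
#'
#' The elements attributed to a vertebra: its trabecular, cortical, and (if
#' present) cement-labelled elements. Cement elements belong to the vertebra
#' they sit in, so pre/post comparisons cover the same element set.
#'
#' @param model An `fe_model`.
#' @param level Vertebra label.
#' @return Integer element row indices.
#' @export
vertebra_elements <- function(model, level) {
  stopifnot(inherits(model, "fe_model"))
  rows <- which(!is.na(model$elem_level) & model$elem_level == level)
  if (!length(rows)) stop("no elements belong to vertebra ", level)
  rows
}

#' Per-element von Mises stress change between two states
#'
#' Computes the percentage change of the von Mises stress of every element
#' of one vertebra between an untreated (`pre`) and a treated (`post`)
#' solve, element by element on the identical mesh. Both states must already
#' be at the same reaction force (see [scale_to_common_load()]). Elements
#' whose pre-treatment stress lies below `floor` have no well-defined
#' relative change and are reported in a separate undefined bucket rather
#' than clamped.
#'
#' @param pre,post `solve_result`s on the identical mesh at equal reactions.
#' @param model The `fe_model` the results belong to.
#' @param level Vertebra label.
#' @param floor Minimum pre-treatment von Mises stress (MPa) for a defined
#'   relative change.
#' @return A `stress_change` object: `changes` (percent, defined elements),
#'   `n_undefined`, `n_total`, `level`.
#' @export
stress_change <- function(pre, post, model, level, floor = 1e-9) {
  stopifnot(inherits(pre, "solve_result"), inherits(post, "solve_result"),
            inherits(model, "fe_model"))
  if (!identical(dim(pre$U), dim(post$U)) ||
      !identical(nrow(pre$stress), nrow(post$stress))) {
    stop("pre and post results are not on the identical mesh")
  }
  if (abs(pre$reaction - post$reaction) >
      1e-6 * max(pre$reaction, post$reaction)) {
    stop("pre and post results must be at the same reaction force; ",
         "use scale_to_common_load()")
  }
  rows <- vertebra_elements(model, level)
  vm_pre <- von_mises(pre$stress[rows, , drop = FALSE])
  vm_post <- von_mises(post$stress[rows, , drop = FALSE])
  defined <- vm_pre >= floor
  structure(list(
    changes = 100 * (vm_post[defined] - vm_pre[defined]) / vm_pre[defined],
    n_undefined = sum(!defined),
    n_total = length(rows),
    level = level
  ), class = "stress_change")
}

#' Default stress-change histogram bin edges
#'
#' Ten-percentage-point bins spanning -100 % to +100 %; the outermost bins
#' are extended to open tails when binning.
#'
#' @return Numeric vector of finite bin edges.
#' @export
histogram_bin_edges <- function() seq(-100, 100, by = 10)

#' Histogram of per-element stress changes
#'
#' Bins the percentage changes with half-open intervals `[lo, hi)` over the
#' given edges, extended by open tails below the first and above the last
#' edge. Fractions are normalized by the total number of elements of the
#' vertebra -- including the undefined bucket -- so all fractions plus the
#' undefined fraction sum to one.
#'
#' @param sc A [stress_change()] result (or a numeric vector of percentage
#'   changes, in which case `n_total` defaults to its length).
#' @param edges Strictly increasing finite bin edges.
#' @param n_total Total element count used for normalization.
#' @return A `stress_change_histogram`: data frame `bins` with `lo`, `hi`,
#'   `count`, `fraction`, plus `undefined_fraction`, `n_total`, `level`.
#' @export
stress_histogram <- function(sc, edges = histogram_bin_edges(),
                             n_total = NULL) {
  if (is.numeric(sc)) {
    sc <- list(changes = sc, n_undefined = 0L,
               n_total = n_total %||% length(sc), level = NA_character_)
  }
  stopifnot(is.numeric(edges), length(edges) >= 2)
  if (is.unsorted(edges, strictly = TRUE)) {
    stop("bin edges must be strictly increasing")
  }
  full <- c(-Inf, edges, Inf)
  idx <- findInterval(sc$changes, full, left.open = FALSE)
  counts <- tabulate(idx, nbins = length(full) - 1L)
  bins <- data.frame(lo = full[-length(full)], hi = full[-1],
                     count = counts,
                     fraction = counts / sc$n_total)
  structure(list(bins = bins,
                 undefined_fraction = sc$n_undefined / sc$n_total,
                 n_total = sc$n_total,
                 level = sc$level),
            class = "stress_change_histogram")
}

#' @export
print.stress_change_histogram <- function(x, ...) {
  cat(sprintf("<stress_change_histogram> vertebra %s, %d elements (%.2f%% undefined)\n",
              x$level, x$n_total, 100 * x$undefined_fraction))
  nz <- x$bins[x$bins$count > 0, ]
  for (i in seq_len(nrow(nz))) {
    cat(sprintf("  [%6s, %6s): %6.2f%%\n",
                format(nz$lo[i]), format(nz$hi[i]), 100 * nz$fraction[i]))
  }
  invisible(x)
}

## ---- parametric sweep ------------------------------------------------------

# Merge one grid row into a base treatment_config.
cell_config <- function(base, row) {
  cfg <- base
  for (nm in names(row)) {
    v <- row[[nm]]
    if (nm == "augmented_levels") {
      v <- if (identical(v, "none") || is.na(v)) character(0) else
        strsplit(v, "\\+")[[1]]
    }
    cfg[[nm]] <- v
  }
  do.call(treatment_config, c(
    list(augmented_levels = if (length(cfg$augmented_levels)) cfg$augmented_levels else "none"),
    cfg[c("cement_E", "cement_modulus_fraction", "fill_fraction",
          "volume_factor", "bone_factor", "disc_state")]))
}

#' Run a parametric treatment sweep
#'
#' Executes one displacement-controlled solve per grid cell: the base
#' treatment configuration is overridden by the cell's columns, cement
#' regions are resized for cells with a volume factor other than one, the
#' model is built, solved, and the segmental stiffness recorded. For cells
#' with `histogram_levels` set, the cell solve and its matched pre-treatment
#' reference (same configuration with no augmentation, solved once per
#' distinct reference state) are both rescaled to `common_reaction` and the
#' per-vertebra stress-change histograms computed.
#'
#' Cells that fail are recorded with their error message and skipped.
#'
#' @param image,labels Phantom image and cemented label map.
#' @param grid Data frame, one row per cell; columns may override
#'   `augmented_levels` (use `"T12+L1"` for both, `"none"` for neither),
#'   `cement_E`, `cement_modulus_fraction`, `fill_fraction`,
#'   `volume_factor`, `bone_factor`, `disc_state`.
#' @param base Base [treatment_config()] for unlisted columns.
#' @param config Base [model_config()]; its treatment slot is replaced per
#'   cell.
#' @param applied_displacement Axial compression per solve (mm).
#' @param common_reaction Reaction force at which stress fields are
#'   compared, N.
#' @param histogram_levels Vertebra labels for stress-change histograms, or
#'   `NULL` to skip stress comparisons.
#' @param bin_edges Histogram bin edges.
#' @param verbose Emit one log line per cell to stderr.
#' @return A `study_sweep`: `records` (one data-frame row per cell with the
#'   configuration and `k`), `histograms` (named list,
#'   `"cell<j>.<level>"`), `errors` (data frame).
#' @export
run_sweep <- function(image, labels, grid,
                      base = treatment_config(),
                      config = model_config(treatment = base),
                      applied_displacement = 0.6,
                      common_reaction = 1000,
                      histogram_levels = NULL,
                      bin_edges = histogram_bin_edges(),
                      verbose = FALSE) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1)
  records <- NULL
  histograms <- list()
  errors <- data.frame(cell = integer(0), message = character(0))
  refs <- list()  # pre-treatment references keyed by state

  ref_result <- function(tr) {
    key <- paste(tr$disc_state, tr$bone_factor, tr$cement_E, sep = "|")
    if (!is.null(refs[[key]])) return(refs[[key]])
    tr0 <- tr
    tr0$augmented_levels <- character(0)
    tr0$volume_factor <- 1
    cfg <- config; cfg$treatment <- tr0
    mod <- build_model(image, labels, cfg)
    res <- assemble_and_solve(mod, applied_displacement)
    refs[[key]] <<- list(model = mod,
                         result = scale_to_common_load(res, common_reaction))
    refs[[key]]
  }

  for (j in seq_len(nrow(grid))) {
    t0 <- proc.time()[3]
    out <- tryCatch({
      tr <- cell_config(base, grid[j, , drop = FALSE])
      labs <- labels
      if (tr$volume_factor != 1) {
        cfg0 <- config; cfg0$treatment <- tr
        tmp_model <- build_model(image, labels, cfg0)
        for (lvl in tr$augmented_levels) {
          vc <- vary_cement_volume(tmp_model, labs, lvl, tr$volume_factor)
          labs <- vc$labels
        }
      }
      cfg <- config; cfg$treatment <- tr
      model <- build_model(image, labs, cfg)
      res <- assemble_and_solve(model, applied_displacement)
      rec <- data.frame(
        cell = j,
        augmented_levels = paste(tr$augmented_levels, collapse = "+"),
        cement_E = tr$cement_E,
        cement_modulus_fraction = tr$cement_modulus_fraction,
        volume_factor = tr$volume_factor,
        bone_factor = tr$bone_factor,
        disc_state = tr$disc_state,
        k = res$k,
        equilibrium = res$equilibrium)
      if (!is.null(histogram_levels)) {
        ref <- ref_result(tr)
        post <- scale_to_common_load(res, common_reaction)
        for (lvl in histogram_levels) {
          sc <- stress_change(ref$result, post, model, lvl)
          histograms[[sprintf("cell%d.%s", j, lvl)]] <-
            stress_histogram(sc, bin_edges)
        }
      }
      rec
    }, error = function(e) e)
    gc(verbose = FALSE)  # each cell's factorization is ~1 GB; release eagerly
    if (inherits(out, "error")) {
      errors <- rbind(errors,
                      data.frame(cell = j, message = conditionMessage(out)))
      if (verbose) message(sprintf("cell %d FAILED: %s", j, conditionMessage(out)))
    } else {
      records <- rbind(records, out)
      if (verbose) {
        message(sprintf("cell %d: k = %.4g N/mm (%.1f s)", j, out$k,
                        proc.time()[3] - t0))
      }
    }
  }
  structure(list(records = records, histograms = histograms, errors = errors),
            class = "study_sweep")
}

#' @export
print.study_sweep <- function(x, ...) {
  cat(sprintf("<study_sweep> %d cells solved, %d failed, %d histograms\n",
              if (is.null(x$records)) 0L else nrow(x$records),
              nrow(x$errors), length(x$histograms)))
  if (!is.null(x$records)) print(x$records, row.names = FALSE)
  invisible(x)
}
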