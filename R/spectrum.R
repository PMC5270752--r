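#' Single-cell Raman spectrum
#'
#' One cell's Raman trace on a wavenumber grid, plus acquisition metadata:
#' the cell id and (optionally) its x/y stage coordinates on the chip, which
#' the sorter uses to locate the cell for ejection. Raw spectra must be
#' non-negative photon counts; baseline-subtracted spectra may go negative
#' and carry `processed = TRUE`.
#'
#' @param intensities Numeric vector, one value per grid point.
#' @param grid A [wn_grid()]; its `n_points` must equal
#'   `length(intensities)`.
#' @param cell_id Character scalar identifying the cell.
#' @param x,y Optional chip coordinates (micrometres, microscopy convention:
#'   origin top-left, y increasing downward).
#' @param label Optional ground-truth archetype tag (synthetic cohorts only).
#' @param processed Logical; `TRUE` marks a baseline-subtracted spectrum,
#'   which is allowed to be negative.
#' @param meta Named character vector of free-form metadata (e.g. parsed
#'   from `#` header lines of an instrument export).
#' @return An object of class `raman_spectrum`.
#' @examples
#' g <- wn_grid(700, 1, 32)
#' s <- raman_spectrum(rep(1, 32), g, cell_id = "demo")
#' s
#' @export
raman_spectrum <- function(intensities, grid, cell_id = "cell",
                           x = NA_real_, y = NA_real_, label = NA_character_,
                           processed = FALSE, meta = character()) {
  stopifnot(inherits(grid, "wn_grid"))
  intensities <- as.numeric(intensities)
  if (length(intensities) != grid$n_points)
    stop(sprintf("intensities length (%d) != grid n_points (%d)",
                 length(intensities), grid$n_points), call. = FALSE)
  if (any(!is.finite(intensities)))
    stop("intensities must be finite", call. = FALSE)
  if (!processed && any(intensities < 0))
    stop("raw intensities must be non-negative (set processed = TRUE for baseline-subtracted spectra)",
         call. = FALSE)
  structure(list(grid = grid, intensities = intensities,
                 cell_id = as.character(cell_id),
                 x = as.numeric(x), y = as.numeric(y),
                 label = as.character(label), processed = isTRUE(processed),
                 meta = meta),
            class = "raman_spectrum")
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum> cell '%s', %d points (%g-%g cm^-1)%s\n",
              x$cell_id, x$grid$n_points, x$grid$start,
              x$grid$start + x$grid$step * (x$grid$n_points - 1),
              if (isTRUE(x$processed)) ", baseline-subtracted" else ""))
  if (!is.na(x$label)) cat("  ground-truth label:", x$label, "\n")
  invisible(x)
}

#' @export
plot.raman_spectrum <- function(x, ...) {
  graphics::plot(grid_values(x$grid), x$intensities, type = "l",
                 xlab = expression(paste("wavenumber (", cm^-1, ")")),
                 ylab = "intensity", main = x$cell_id, ...)
  invisible(x)
}

#' Set of single-cell Raman spectra on a shared grid
#'
#' The cohort container used throughout the pipeline. Intensities are held
#' as a cells-by-wavenumbers matrix; per-cell metadata (id, chip position,
#' optional ground-truth label and carotenoid band triplet) live in a
#' data frame aligned with the matrix rows.
#'
#' @param intensities Numeric matrix, one row per cell, `grid$n_points`
#'   columns.
#' @param grid Shared [wn_grid()].
#' @param meta Data frame with at least a `cell_id` column (unique);
#'   recognised extra columns: `x`, `y`, `label`, `v1`, `v2`, `v3`.
#' @param provenance Optional list recording how the set was produced
#'   (e.g. generator preset and seed).
#' @return An object of class `scrs_set`.
#' @seealso [simulate_cohort()], [read_cohort_csv()]
#' @export
scrs_set <- function(intensities, grid, meta = NULL, provenance = list()) {
  stopifnot(inherits(grid, "wn_grid"))
  intensities <- as.matrix(intensities)
  if (ncol(intensities) != grid$n_points)
    stop("intensity matrix must have one column per grid point", call. = FALSE)
  n <- nrow(intensities)
  if (is.null(meta)) meta <- data.frame(cell_id = sprintf("cell_%05d", seq_len(n)))
  if (!is.data.frame(meta) || is.null(meta$cell_id))
    stop("`meta` must be a data frame with a cell_id column", call. = FALSE)
  if (nrow(meta) != n)
    stop("meta rows must match intensity rows", call. = FALSE)
  meta$cell_id <- as.character(meta$cell_id)
  dup <- meta$cell_id[duplicated(meta$cell_id)]
  if (length(dup))
    stop(sprintf("duplicate cell_id: %s", paste(unique(dup), collapse = ", ")),
         call. = FALSE)
  for (col in c("x", "y", "v1", "v2", "v3"))
    if (is.null(meta[[col]])) meta[[col]] <- NA_real_
  if (is.null(meta$label)) meta$label <- NA_character_
  rownames(intensities) <- meta$cell_id
  structure(list(grid = grid, intensities = intensities, meta = meta,
                 provenance = provenance),
            class = "scrs_set")
}

#' @export
print.scrs_set <- function(x, ...) {
  cat(sprintf("<scrs_set> %d spectra, %d points (%g-%g cm^-1)\n",
              nrow(x$intensities), x$grid$n_points, x$grid$start,
              x$grid$start + x$grid$step * (x$grid$n_points - 1)))
  if (any(!is.na(x$meta$label))) {
    tab <- table(x$meta$label, useNA = "no")
    cat("  ground-truth labels:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  if (!is.null(x$provenance$seed))
    cat("  provenance: preset", x$provenance$preset %||% "?",
        "seed", x$provenance$seed, "\n")
  invisible(x)
}

#' Number of spectra in a set
#' @param set An `scrs_set`.
#' @return Integer count.
#' @export
n_spectra <- function(set) {
  stopifnot(inherits(set, "scrs_set") || inherits(set, "scrs_processed"))
  nrow(set$intensities %||% set$corrected)
}

#' Extract one spectrum from a set
#' @param set An `scrs_set`.
#' @param i Row index or cell id.
#' @return A [raman_spectrum()].
#' @export
get_spectrum <- function(set, i) {
  stopifnot(inherits(set, "scrs_set"))
  if (is.character(i)) i <- match(i, set$meta$cell_id)
  if (is.na(i) || i < 1 || i > nrow(set$intensities))
    stop("no such spectrum", call. = FALSE)
  m <- set$meta[i, ]
  raman_spectrum(set$intensities[i, ], set$grid, cell_id = m$cell_id,
                 x = m$x, y = m$y, label = m$label)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Shared-grid guard used by every module that consumes a set built elsewhere.
check_same_grid <- function(grid_a, grid_b, what = "spectra") {
  if (!grids_equal(grid_a, grid_b))
    stop(sprintf("mixed wavenumber grids: all %s must share one grid", what),
         call. = FALSE)
  invisible(TRUE)
}
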