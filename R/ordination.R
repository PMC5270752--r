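#' Principal component analysis of a preprocessed cohort
#'
#' Mean-centred PCA of the normalised, baseline-corrected spectra, used to
#' verify that the spectral features separating the cohort are the
#' carotenoid resonance bands. Fluorescence-dominated cells are excluded by
#' default: their residual broadband amplitude would otherwise swamp the
#' leading component (a flag retains them). Loadings follow a deterministic
#' sign convention -- the largest-magnitude entry of each loading column is
#' positive -- so repeated runs are comparable.
#'
#' @param processed An `scrs_processed` object (see
#'   [preprocess_spectra()]).
#' @param n_components Number of components to retain.
#' @param exclude_fluorescent Drop screened-out cells before the
#'   decomposition (default TRUE). Screening uses `calls` when given,
#'   otherwise the preprocessed fluorescence index against `theta_f`.
#' @param calls Optional `scrs_calls` whose `is_fluorescent` column defines
#'   the exclusion.
#' @param theta_f Fluorescence-index threshold used when `calls` is absent.
#' @return An object of class `scrs_pca`: `scores` (cells x components),
#'   `loadings` (wavenumbers x components, orthonormal columns),
#'   `explained_variance_ratio`, `center`, `wavenumbers`, `cell_ids`,
#'   `n_excluded`.
#' @export
scrs_pca <- function(processed, n_components = 5, exclude_fluorescent = TRUE,
                     calls = NULL, theta_f = 0.85) {
  stopifnot(inherits(processed, "scrs_processed"))
  x <- processed$corrected
  keep <- rep(TRUE, nrow(x))
  if (exclude_fluorescent) {
    keep <- if (!is.null(calls)) {
      stopifnot(inherits(calls, "scrs_calls"))
      !calls$calls$is_fluorescent[match(processed$meta$cell_id,
                                        calls$calls$cell_id)]
    } else
      !(is.na(processed$fluor_index) | processed$fluor_index > theta_f |
          processed$flags$low_signal)
  }
  x <- x[keep, , drop = FALSE]
  if (nrow(x) < 2)
    stop("validation error: PCA needs at least 2 spectra", call. = FALSE)
  n_components <- min(n_components, nrow(x) - 1, ncol(x))
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_components)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  loadings <- pc$rotation
  scores <- pc$x
  for (j in seq_len(ncol(loadings))) {      # sign convention
    k <- which.max(abs(loadings[, j]))
    if (loadings[k, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(scores = scores, loadings = loadings,
                 explained_variance_ratio = evr[seq_len(n_components)],
                 center = pc$center, wavenumbers = wavenumbers(processed$grid),
                 cell_ids = processed$meta$cell_id[keep],
                 n_excluded = sum(!keep)),
            class = "scrs_pca")
}

#' @export
print.scrs_pca <- function(x, ...) {
  cat(sprintf("<scrs_pca> %d cells x %d components (%d excluded)\n",
              nrow(x$scores), ncol(x$scores), x$n_excluded))
  cat("  explained variance ratio:",
      paste(sprintf("%.3f", x$explained_variance_ratio), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
plot.scrs_pca <- function(x, components = c(1, 2), ...) {
  graphics::plot(x$scores[, components[1]], x$scores[, components[2]],
                 xlab = sprintf("PC%d (%.1f%%)", components[1],
                                100 * x$explained_variance_ratio[components[1]]),
                 ylab = sprintf("PC%d (%.1f%%)", components[2],
                                100 * x$explained_variance_ratio[components[2]]),
                 ...)
  invisible(x)
}

#' Top-loading wavenumber windows of a principal component
#'
#' Returns the maximal contiguous wavenumber runs where the loading
#' magnitude reaches at least `alpha` times the component's maximum
#' loading magnitude; runs separated by fewer than `merge_gap` grid points
#' are merged. On a cohort whose variation is driven by carotenoid
#' content, the axis-1 windows land on the v1/v2/v3 resonance bands.
#'
#' @param pca An `scrs_pca` object.
#' @param component Component index (default 1).
#' @param alpha Relative threshold in (0, 1), default 0.5.
#' @param merge_gap Runs closer than this many grid points are merged
#'   (default 3).
#' @return Data frame with `component`, `lo`, `hi` (cm^-1) and
#'   `peak_loading` (max |loading| inside the window).
#' @export
top_loading_windows <- function(pca, component = 1, alpha = 0.5,
                                merge_gap = 3) {
  stopifnot(inherits(pca, "scrs_pca"))
  if (!(alpha > 0 && alpha < 1)) stop("`alpha` must be in (0, 1)",
                                      call. = FALSE)
  l <- abs(pca$loadings[, component])
  thr <- alpha * max(l)
  above <- l >= thr
  if (!any(above))
    return(data.frame(component = integer(), lo = numeric(), hi = numeric(),
                      peak_loading = numeric()))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- cbind(starts[r$values], ends[r$values])
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1)
    for (i in 2:nrow(runs)) {
      gap <- runs[i, 1] - merged[nrow(merged), 2] - 1
      if (gap < merge_gap) merged[nrow(merged), 2] <- runs[i, 2]
      else merged <- rbind(merged, runs[i, ])
    }
  data.frame(component = component,
             lo = pca$wavenumbers[merged[, 1]],
             hi = pca$wavenumbers[merged[, 2]],
             peak_loading = apply(merged, 1, function(rr)
               max(l[rr[1]:rr[2]])))
}
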