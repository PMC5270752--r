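#' Biomarker band definitions
#'
#' A band definition names a wavenumber window and the role it plays in the
#' phenotype caller. `canonical_bands()` returns the package's default set:
#'
#' * carotenoid resonance windows v1 997--1007, v2 1145--1161 and v3
#'   1503--1526 cm\eqn{^{-1}} (the sorting criterion);
#' * PHB marker windows at 839, 1058, 1123 and 1403 cm\eqn{^{-1}}, each
#'   +/- 5 cm\eqn{^{-1}};
#' * base-cell windows at 785, 1245, 1450 and 1660 cm\eqn{^{-1}}, each
#'   +/- 5. The 1003 cm\eqn{^{-1}} phenylalanine band is deliberately not a
#'   base-cell match window: its window would overlap the carotenoid v1
#'   window, which band matching rejects.
#'
#' @param name Band name.
#' @param lo,hi Window bounds in cm^-1 (`lo < hi`).
#' @param role One of `"carotenoid_v1"`, `"carotenoid_v2"`,
#'   `"carotenoid_v3"`, `"phb_marker"`, `"base_cell"`.
#' @return A one-row data frame (`band_definition`) or their row-bound set
#'   (`canonical_bands`).
#' @export
band_definition <- function(name, lo, hi,
                            role = c("carotenoid_v1", "carotenoid_v2",
                                     "carotenoid_v3", "phb_marker",
                                     "base_cell")) {
  role <- match.arg(role)
  if (!(lo < hi)) stop("band window requires lo < hi", call. = FALSE)
  data.frame(name = name, lo = lo, hi = hi, role = role,
             stringsAsFactors = FALSE)
}

#' @rdname band_definition
#' @export
carotenoid_windows <- function() {
  m <- cbind(lo = c(997, 1145, 1503), hi = c(1007, 1161, 1526))
  rownames(m) <- c("v1", "v2", "v3")
  m
}

#' @rdname band_definition
#' @export
phb_marker_positions <- function() c(839, 1058, 1123, 1403)

#' @rdname band_definition
#' @export
canonical_bands <- function() {
  w <- carotenoid_windows()
  rbind(
    band_definition("carotenoid_v1", w["v1", 1], w["v1", 2], "carotenoid_v1"),
    band_definition("carotenoid_v2", w["v2", 1], w["v2", 2], "carotenoid_v2"),
    band_definition("carotenoid_v3", w["v3", 1], w["v3", 2], "carotenoid_v3"),
    do.call(rbind, lapply(phb_marker_positions(), function(pos)
      band_definition(sprintf("phb_%d", pos), pos - 5, pos + 5,
                      "phb_marker"))),
    do.call(rbind, lapply(c(785, 1245, 1450, 1660), function(pos)
      band_definition(sprintf("base_%d", pos), pos - 5, pos + 5,
                      "base_cell"))))
}

#' Fluorescence index of a raw spectrum
#'
#' The fraction of the total raw signal attributed to the smooth baseline,
#' `F = sum(baseline) / sum(raw)`, clipped to `[0, 1]`. Fluorescence-
#' dominated cells show a broad emission bump that dwarfs their Raman
#' bands, driving F towards 1. A non-positive raw sum means there is no
#' signal to screen: `NA` is returned (callers flag the cell `low_signal`).
#'
#' @param raw Raw intensity vector (or [raman_spectrum()]).
#' @param baseline Baseline estimate on the same grid (see
#'   [estimate_baseline()]).
#' @return F in `[0, 1]`, or `NA` for a non-positive raw sum.
#' @export
fluorescence_index <- function(raw, baseline) {
  if (inherits(raw, "raman_spectrum")) raw <- raw$intensities
  if (length(raw) != length(baseline))
    stop("raw and baseline must share one grid", call. = FALSE)
  s <- sum(raw)
  if (s <= 0) return(NA_real_)
  min(max(sum(baseline) / s, 0), 1)
}

#' Detect peaks by prominence
#'
#' Finds every strict local maximum of the spectrum and scores it by
#' topographic prominence: the height above the higher of the two basin
#' minima, where each basin extends to the nearest strictly higher sample
#' (or the signal edge). Peaks with prominence below
#' `min_prominence_sigma * noise_sigma` are discarded. Results are sorted
#' by position.
#'
#' @param y Corrected intensity vector (or [raman_spectrum()]).
#' @param wn Wavenumber axis; defaults to the spectrum's grid or the point
#'   index.
#' @param noise_sigma Noise scale; estimated with [estimate_noise()] when
#'   omitted.
#' @param min_prominence_sigma Detection threshold in noise-sd units
#'   (default 5); `0` keeps every local maximum.
#' @return Data frame with `position` (cm^-1), `height`, `prominence`.
#' @export
detect_peaks <- function(y, wn = NULL, noise_sigma = NULL,
                         min_prominence_sigma = 5) {
  if (inherits(y, "raman_spectrum")) {
    if (is.null(wn)) wn <- grid_values(y$grid)
    y <- y$intensities
  }
  y <- as.numeric(y)
  wn <- as.numeric(wn %||% seq_along(y))
  pk <- find_peaks_cpp(y)
  keep <- rep(TRUE, length(pk$index))
  if (min_prominence_sigma > 0) {
    if (is.null(noise_sigma)) noise_sigma <- estimate_noise(y)
    keep <- pk$prominence >= min_prominence_sigma * noise_sigma
  }
  data.frame(position = wn[pk$index[keep]], height = pk$height[keep],
             prominence = pk$prominence[keep])
}

#' Match detected peaks to biomarker bands
#'
#' For each band window the most prominent in-window peak is selected;
#' ties go to the peak closest to the window centre, remaining ties to the
#' lower wavenumber. Windows must be pairwise disjoint (so no peak can
#' serve two bands); overlapping windows are a configuration error.
#'
#' @param peaks Data frame from [detect_peaks()].
#' @param bands Band definition data frame (default [canonical_bands()]).
#' @return `bands` with columns `matched`, `position`, `height`,
#'   `prominence` appended (NA where no peak fell in the window).
#' @export
match_bands <- function(peaks, bands = canonical_bands()) {
  bands <- bands[order(bands$lo), , drop = FALSE]
  if (nrow(bands) > 1 && any(bands$lo[-1] <= bands$hi[-nrow(bands)]))
    stop("config error: band windows overlap", call. = FALSE)
  bands$matched <- FALSE
  bands$position <- NA_real_
  bands$height <- NA_real_
  bands$prominence <- NA_real_
  for (b in seq_len(nrow(bands))) {
    inw <- which(peaks$position >= bands$lo[b] & peaks$position <= bands$hi[b])
    if (!length(inw)) next
    cand <- peaks[inw, , drop = FALSE]
    ctr <- (bands$lo[b] + bands$hi[b]) / 2
    ord <- order(-cand$prominence, abs(cand$position - ctr), cand$position)
    best <- cand[ord[1], ]
    bands$matched[b] <- TRUE
    bands$position[b] <- best$position
    bands$height[b] <- best$height
    bands$prominence[b] <- best$prominence
  }
  rownames(bands) <- NULL
  bands
}

#' Classifier configuration
#'
#' @param theta_f Fluorescence-index threshold (default 0.85): cells with
#'   `F > theta_f` are screened out as fluorescence-dominated.
#' @param snr_min Minimum peak signal-to-noise (default 3): cells whose most
#'   prominent peak is below `snr_min * noise_sigma` have no distinguishable
#'   Raman bands and are screened out with the fluorescent group.
#' @param min_prominence_sigma Peak detection threshold (default 5), see
#'   [detect_peaks()].
#' @param carotenoid_min_matches Number of matched carotenoid windows
#'   required for a carotenoid call (default 3: all of v1, v2, v3; a 2-of-3
#'   relaxation for noisy data is available but off by default).
#' @param phb_min_matches Matched PHB marker windows required (default 4 =
#'   all; 3 relaxes the rule for noisy data).
#' @param base_min_matches Matched base-cell windows required for a
#'   "typical" call (default 2).
#' @param bands Band definitions (default [canonical_bands()]).
#' @return A list of class `scrs_classify_config`.
#' @export
classify_config <- function(theta_f = 0.85, snr_min = 3,
                            min_prominence_sigma = 5,
                            carotenoid_min_matches = 3, phb_min_matches = 4,
                            base_min_matches = 2, bands = canonical_bands()) {
  stopifnot(theta_f > 0, theta_f <= 1, snr_min >= 0,
            carotenoid_min_matches %in% 1:3, phb_min_matches %in% 1:4)
  structure(list(theta_f = theta_f, snr_min = snr_min,
                 min_prominence_sigma = min_prominence_sigma,
                 carotenoid_min_matches = carotenoid_min_matches,
                 phb_min_matches = phb_min_matches,
                 base_min_matches = base_min_matches, bands = bands),
            class = "scrs_classify_config")
}

# Phenotype decision for one preprocessed spectrum. Decision order:
# fluorescent screen first (a dominating emission bump preempts any band
# call), then carotenoid (all three resonance windows), then PHB, then
# typical, then other.
call_phenotype_one <- function(corrected, wn, noise_sigma, fluor_index,
                               low_signal, config) {
  out <- list(fluor_index = fluor_index, is_fluorescent = FALSE,
              label = "other", carotenoid_score = 0,
              v1 = NA_real_, v2 = NA_real_, v3 = NA_real_,
              n_carotenoid_matches = 0L, n_phb_matches = 0L,
              n_base_matches = 0L, max_snr = NA_real_,
              low_signal = isTRUE(low_signal))
  if (isTRUE(low_signal)) {
    out$is_fluorescent <- TRUE      # screened out: nothing distinguishable
    out$label <- "fluorescent"
    return(out)
  }
  peaks <- detect_peaks(corrected, wn, noise_sigma,
                        config$min_prominence_sigma)
  allpk <- find_peaks_cpp(corrected)
  maxprom <- if (length(allpk$prominence)) max(allpk$prominence) else 0
  out$max_snr <- if (noise_sigma > 0) maxprom / noise_sigma else Inf
  if (fluor_index > config$theta_f ||
      maxprom < config$snr_min * noise_sigma) {
    out$is_fluorescent <- TRUE
    out$label <- "fluorescent"
    return(out)                     # band_matches stay empty
  }
  m <- match_bands(peaks, config$bands)
  vroles <- c("carotenoid_v1", "carotenoid_v2", "carotenoid_v3")
  vrows <- m[match(vroles, m$role), ]
  out$n_carotenoid_matches <- sum(vrows$matched)
  out$n_phb_matches <- sum(m$matched[m$role == "phb_marker"])
  out$n_base_matches <- sum(m$matched[m$role == "base_cell"])
  if (out$n_carotenoid_matches >= config$carotenoid_min_matches) {
    out$label <- "carotenoid"
    out$carotenoid_score <- sum(vrows$prominence, na.rm = TRUE)
    out$v1 <- vrows$position[1]; out$v2 <- vrows$position[2]
    out$v3 <- vrows$position[3]
  } else if (out$n_phb_matches >= config$phb_min_matches) {
    out$label <- "phb"
  } else if (out$n_base_matches >= config$base_min_matches) {
    out$label <- "typical"
  }
  out
}

#' Call the phenotype of one preprocessed spectrum
#'
#' Applies the fluorescence screen and the biomarker-band decision rule to
#' a single cell of an [preprocess_spectra()] result. See
#' [classify_cohort()] for the cohort-level interface and the decision
#' order.
#'
#' @param processed An `scrs_processed` object.
#' @param i Row index or cell id.
#' @param config A [classify_config()].
#' @return One-row data frame with the phenotype call.
#' @export
call_phenotype <- function(processed, i = 1, config = classify_config()) {
  stopifnot(inherits(processed, "scrs_processed"))
  if (is.character(i)) i <- match(i, processed$meta$cell_id)
  wn <- wavenumbers(processed$grid)
  out <- call_phenotype_one(processed$corrected[i, ], wn,
                            processed$noise_sigma[i],
                            processed$fluor_index[i] %||% NA_real_,
                            processed$flags$low_signal[i], config)
  cbind(data.frame(cell_id = processed$meta$cell_id[i]),
        as.data.frame(out))
}

#' Classify a cohort of spectra
#'
#' Runs the per-cell phenotype caller over a preprocessed cohort and
#' assembles the cohort report: per-cell calls, counts and fractions per
#' label, and (when ground-truth labels are present) a confusion matrix and
#' accuracy. Raw [scrs_set()] input is preprocessed first with the given
#' parameters.
#'
#' The decision order is: (1) fluorescence screen (`F > theta_f`, or no
#' peak above `snr_min` noise sds -- no distinguishable bands); (2)
#' carotenoid if all three resonance windows are matched; (3) PHB if all
#' four marker windows are matched; (4) typical if at least two base-cell
#' windows are matched; (5) other.
#'
#' @param x An `scrs_processed` or raw [scrs_set()].
#' @param config A [classify_config()].
#' @param ... Passed to [preprocess_spectra()] when `x` is raw.
#' @return An object of class `scrs_calls`: data frame `calls`, named
#'   vectors `counts` and `fractions`, `confusion` matrix (or NULL),
#'   `accuracy` (or NA) and the configuration used.
#' @examples
#' set <- simulate_cohort(preset_red_sea_default(n_cells = 60), seed = 7)
#' rep <- classify_cohort(set)
#' rep$fractions
#' @export
classify_cohort <- function(x, config = classify_config(), ...) {
  if (inherits(x, "scrs_set")) x <- preprocess_spectra(x, ...)
  stopifnot(inherits(x, "scrs_processed"))
  n <- nrow(x$corrected)
  wn <- wavenumbers(x$grid)
  rows <- vector("list", n)
  for (i in seq_len(n))
    rows[[i]] <- as.data.frame(
      call_phenotype_one(x$corrected[i, ], wn, x$noise_sigma[i],
                         x$fluor_index[i], x$flags$low_signal[i], config))
  calls <- do.call(rbind, rows)
  calls <- cbind(data.frame(cell_id = x$meta$cell_id,
                            x = x$meta$x, y = x$meta$y,
                            stringsAsFactors = FALSE),
                 calls)
  labels <- c("fluorescent", "carotenoid", "phb", "typical", "other")
  counts <- vapply(labels, function(l) sum(calls$label == l), integer(1))
  fractions <- if (n > 0) counts / n else counts * NA_real_
  confusion <- NULL
  accuracy <- NA_real_
  truth <- x$meta$label
  if (n > 0 && any(!is.na(truth))) {
    truth_mapped <- ifelse(truth == "other_compound", "other", truth)
    confusion <- table(truth = factor(truth_mapped, levels = labels),
                       called = factor(calls$label, levels = labels))
    accuracy <- sum(diag(confusion)) / sum(confusion)
  }
  structure(list(calls = calls, counts = counts, fractions = fractions,
                 n = n, confusion = confusion, accuracy = accuracy,
                 config = config, provenance = x$provenance),
            class = "scrs_calls")
}

#' @export
print.scrs_calls <- function(x, ...) {
  cat(sprintf("<scrs_calls> %d cells\n", x$n))
  for (l in names(x$counts))
    cat(sprintf("  %-12s %6d  (%5.1f%%)\n", l, x$counts[l],
                100 * x$fractions[l]))
  cat(sprintf("  distinguishable: %.1f%% (= 100%% - fluorescent)\n",
              100 * (1 - x$fractions["fluorescent"])))
  if (!is.na(x$accuracy))
    cat(sprintf("  accuracy vs ground truth: %.2f%%\n", 100 * x$accuracy))
  invisible(x)
}

#' @export
summary.scrs_calls <- function(object, ...) {
  out <- list(n = object$n, counts = object$counts,
              fractions = object$fractions, accuracy = object$accuracy,
              confusion = object$confusion)
  class(out) <- "summary.scrs_calls"
  out
}

#' @export
print.summary.scrs_calls <- function(x, ...) {
  cat("Cohort phenotype summary --", x$n, "cells\n")
  print(data.frame(count = x$counts, fraction = round(x$fractions, 4)))
  if (!is.null(x$confusion)) {
    cat("\nConfusion matrix (truth x called):\n")
    print(x$confusion)
    cat(sprintf("accuracy: %.4f\n", x$accuracy))
  }
  invisible(x)
}
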