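#' Spectral archetypes for the synthetic cohort generator
#'
#' An archetype describes one ground-truth cell phenotype as a sum of
#' Lorentzian Raman bands over a smooth background. The five built-in
#' archetypes emulate the phenotypes seen in a marine surface-water
#' community under 532 nm excitation:
#'
#' * `typical` -- an ordinary bacterial cell: protein/nucleic-acid bands at
#'   785, 1003, 1245, 1450 and 1660 cm\eqn{^{-1}} (heights
#'   0.3/0.5/0.3/0.4/0.5, FWHM 20 cm\eqn{^{-1}}).
#' * `carotenoid` -- the typical bands plus the three resonance-enhanced
#'   carotenoid bands; their positions (v1, v2, v3) are drawn uniformly
#'   within the windows 997--1007, 1145--1161 and 1503--1526
#'   cm\eqn{^{-1}} at render time unless pinned. Resonance makes these
#'   bands dominate: heights 1.5 (v1), 3.0 (v2), 5.0 (v3), FWHM 12.
#' * `phb` -- the typical bands plus poly-beta-hydroxybutyrate markers at
#'   839, 1058, 1123 and 1403 cm\eqn{^{-1}} (height 2.0, FWHM 12).
#' * `fluorescent` -- a cell whose emission dwarfs the Raman signal: a broad
#'   Gaussian bump (height 20x the strongest typical band, sd 300
#'   cm\eqn{^{-1}}, centre drawn U(1100, 1500)) over weak typical bands.
#' * `other_compound` -- a cell dominated by an unidentified compound with
#'   bands at 890, 1332 and 1570 cm\eqn{^{-1}}, none of them canonical
#'   biomarker or base-cell bands.
#'
#' @param name Archetype name.
#' @param peaks Data frame with columns `center`, `height`, `fwhm`
#'   (cm^-1 / relative units / cm^-1).
#' @param background List: `list(kind = "none")`,
#'   `list(kind = "broad_gaussian", height=, sigma=, center_range=)` or
#'   `list(kind = "broad_gaussian", height=, sigma=, center=)`.
#' @param v_heights,v_fwhm Carotenoid resonance band heights (v1, v2, v3)
#'   and FWHM; only used when `carotenoid = TRUE`.
#' @param carotenoid Logical: draw/pin a (v1, v2, v3) triplet at render.
#' @param triplet Optional pinned `c(v1, v2, v3)` positions (cm^-1), each
#'   inside its canonical window.
#' @return An object of class `scrs_archetype`.
#' @examples
#' a <- archetype_default("carotenoid")
#' s <- render_archetype(a, triplet = c(1003, 1155, 1515))
#' @export
archetype <- function(name, peaks, background = list(kind = "none"),
                      carotenoid = FALSE, triplet = NULL,
                      v_heights = c(1.5, 3.0, 5.0), v_fwhm = 12) {
  peaks <- as.data.frame(peaks)
  if (nrow(peaks)) {
    stopifnot(all(c("center", "height", "fwhm") %in% names(peaks)))
    if (any(peaks$height <= 0) || any(peaks$fwhm <= 0))
      stop("peak heights and fwhm must be > 0", call. = FALSE)
  }
  if (!is.null(triplet)) {
    stopifnot(length(triplet) == 3)
    w <- carotenoid_windows()
    for (k in 1:3)
      if (triplet[k] < w[k, "lo"] || triplet[k] > w[k, "hi"])
        stop(sprintf("v%d position %g outside window [%g, %g]", k, triplet[k],
                     w[k, "lo"], w[k, "hi"]), call. = FALSE)
  }
  structure(list(name = name, peaks = peaks, background = background,
                 carotenoid = isTRUE(carotenoid), triplet = triplet,
                 v_heights = v_heights, v_fwhm = v_fwhm),
            class = "scrs_archetype")
}

base_cell_peaks <- function() {
  data.frame(center = c(785, 1003, 1245, 1450, 1660),
             height = c(0.3, 0.5, 0.3, 0.4, 0.5),
             fwhm = 20)
}

#' @rdname archetype
#' @export
archetype_names <- function() {
  c("typical", "carotenoid", "phb", "fluorescent", "other_compound")
}

#' @rdname archetype
#' @export
archetype_default <- function(name) {
  name <- match.arg(name, archetype_names())
  base <- base_cell_peaks()
  switch(name,
    typical = archetype("typical", base),
    carotenoid = archetype("carotenoid", base, carotenoid = TRUE),
    phb = archetype("phb", rbind(base,
            data.frame(center = c(839, 1058, 1123, 1403), height = 2.0,
                       fwhm = 12))),
    fluorescent = archetype("fluorescent", base,
            background = list(kind = "broad_gaussian",
                              height = 20 * max(base$height), sigma = 300,
                              center_range = c(1100, 1500))),
    other_compound = archetype("other_compound",
            data.frame(center = c(890, 1332, 1570),
                       height = c(1.2, 1.0, 1.5), fwhm = 12)))
}

#' Measurement noise model for synthetic spectra
#'
#' Additive Gaussian detector noise plus signal-dependent shot noise
#' (sd = `shot_scale * sqrt(signal)`), over a random smooth polynomial
#' substrate background scaled to `[0, baseline_amplitude]`. All units are
#' the generator's relative intensity units. `zero_noise()` is the noiseless
#' limit used by worked examples and accuracy tests.
#'
#' @param read_sigma Detector (read) noise sd, counts.
#' @param shot_scale Shot-noise scale (dimensionless).
#' @param baseline_poly_degree Degree of the random substrate polynomial.
#' @param baseline_amplitude Peak-to-peak amplitude of the substrate
#'   baseline, counts.
#' @param cosmic_ray_rate Expected cosmic-ray spikes per spectrum
#'   (default 0; hook, off).
#' @return An object of class `scrs_noise_model`.
#' @export
noise_model <- function(read_sigma = 0.02, shot_scale = 0.05,
                        baseline_poly_degree = 3, baseline_amplitude = 0.3,
                        cosmic_ray_rate = 0) {
  vals <- c(read_sigma, shot_scale, baseline_poly_degree, baseline_amplitude,
            cosmic_ray_rate)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("noise model parameters must be finite and >= 0", call. = FALSE)
  structure(list(read_sigma = read_sigma, shot_scale = shot_scale,
                 baseline_poly_degree = as.integer(baseline_poly_degree),
                 baseline_amplitude = baseline_amplitude,
                 cosmic_ray_rate = cosmic_ray_rate),
            class = "scrs_noise_model")
}

#' @rdname noise_model
#' @export
zero_noise <- function() noise_model(0, 0, 0, 0, 0)

lorentzian <- function(x, center, height, fwhm) {
  g2 <- (fwhm / 2)^2
  height * g2 / ((x - center)^2 + g2)
}

# Deterministic part of an archetype on a grid, with the carotenoid triplet
# and fluorescence-bump centre resolved to concrete values.
render_signal <- function(arch, wn, triplet = NULL, bump_center = NULL) {
  sig <- numeric(length(wn))
  pk <- arch$peaks
  if (nrow(pk))
    for (i in seq_len(nrow(pk)))
      sig <- sig + lorentzian(wn, pk$center[i], pk$height[i], pk$fwhm[i])
  if (arch$carotenoid && !is.null(triplet))
    for (k in 1:3)
      sig <- sig + lorentzian(wn, triplet[k], arch$v_heights[k], arch$v_fwhm)
  bg <- arch$background
  if (identical(bg$kind, "broad_gaussian")) {
    ctr <- bump_center %||% bg[["center"]]
    sig <- sig + bg$height * exp(-0.5 * ((wn - ctr) / bg$sigma)^2)
  } else if (!identical(bg$kind %||% "none", "none") &&
             !identical(bg$kind, "polynomial"))
    stop("unknown background kind: ", bg$kind, call. = FALSE)
  sig
}

# Random smooth substrate baseline in [0, amplitude].
random_substrate <- function(n, degree, amplitude) {
  if (amplitude <= 0 || degree < 1) return(numeric(n))
  x <- seq(-1, 1, length.out = n)
  coefs <- stats::runif(degree + 1, -1, 1)
  p <- drop(outer(x, 0:degree, `^`) %*% coefs)
  rng <- range(p)
  if (diff(rng) < 1e-12) return(numeric(n))
  (p - rng[1]) / diff(rng) * amplitude
}

#' Render one archetype as a spectrum
#'
#' Evaluates the archetype's Lorentzian bands (plus any broad background) on
#' the grid and, unless `noise` is `NULL` or [zero_noise()], adds a random
#' substrate baseline, detector read noise and shot noise drawn from the
#' current RNG stream. Negative noisy counts are clipped to zero so raw
#' spectra stay valid. The ground-truth archetype name is attached as the
#' spectrum label; for carotenoid archetypes the realised (v1, v2, v3)
#' triplet is attached as attribute `"triplet"`.
#'
#' @param arch An [archetype()] (or a name accepted by
#'   [archetype_default()]).
#' @param grid Target [wn_grid()].
#' @param noise An [noise_model()] or `NULL` for a noiseless render.
#' @param triplet Optional pinned carotenoid `c(v1, v2, v3)`; when omitted a
#'   carotenoid archetype draws one uniformly within the canonical windows.
#' @param cell_id Cell id for the returned spectrum.
#' @return A [raman_spectrum()].
#' @export
render_archetype <- function(arch, grid = default_grid(), noise = NULL,
                             triplet = NULL, cell_id = NULL) {
  if (is.character(arch)) arch <- archetype_default(arch)
  stopifnot(inherits(arch, "scrs_archetype"), inherits(grid, "wn_grid"))
  wn <- wavenumbers(grid)
  if (nrow(arch$peaks) && (min(arch$peaks$center) < wn[1] ||
                           max(arch$peaks$center) > wn[length(wn)]))
    stop("archetype peak centers must lie inside the grid", call. = FALSE)
  trip <- triplet %||% arch$triplet
  if (arch$carotenoid && is.null(trip)) {
    w <- carotenoid_windows()
    trip <- stats::runif(3, w[, "lo"], w[, "hi"])
  }
  bump_center <- NULL
  bg <- arch$background
  if (identical(bg$kind, "broad_gaussian") && is.null(bg[["center"]]))
    bump_center <- stats::runif(1, bg$center_range[1], bg$center_range[2])
  sig <- render_signal(arch, wn, triplet = trip, bump_center = bump_center)
  noiseless <- is.null(noise) ||
    (noise$read_sigma == 0 && noise$shot_scale == 0 &&
       noise$baseline_amplitude == 0 && noise$cosmic_ray_rate == 0)
  if (!noiseless) {
    substrate <- random_substrate(grid$n_points, noise$baseline_poly_degree,
                                  noise$baseline_amplitude)
    total <- sig + substrate
    sd <- sqrt(noise$read_sigma^2 + noise$shot_scale^2 * pmax(total, 0))
    y <- total + stats::rnorm(grid$n_points, 0, sd)
    if (noise$cosmic_ray_rate > 0 &&
        stats::runif(1) < noise$cosmic_ray_rate) {
      at <- sample.int(grid$n_points, 1)
      y[at] <- y[at] + 50 * max(sig, 1)
    }
    y <- pmax(y, 0)
  } else y <- sig
  s <- raman_spectrum(y, grid, cell_id = cell_id %||% arch$name,
                      label = arch$name)
  attr(s, "triplet") <- if (arch$carotenoid) trip else NULL
  s
}

#' Cohort composition presets
#'
#' A composition preset fixes the cohort size and the ground-truth archetype
#' proportions. `preset_red_sea_default()` emulates the published
#' surface-seawater cohort: 5321 cells of which 33% are
#' fluorescence-dominated and 23% contain carotenoids; the remaining 44% is
#' split 30% typical, 7% PHB, 7% other-compound (the residual split is a
#' package choice, configurable here).
#'
#' @param fractions Named numeric vector over [archetype_names()]; must be
#'   non-negative and sum to 1 (tolerance 1e-9).
#' @param n_cells Cohort size.
#' @param name Preset name recorded in provenance.
#' @return An object of class `scrs_preset`.
#' @export
composition_preset <- function(fractions, n_cells,
                               name = "custom") {
  miss <- setdiff(names(fractions), archetype_names())
  if (length(miss))
    stop("unknown archetype(s) in fractions: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9)
    stop("config error: fractions must be >= 0 and sum to 1", call. = FALSE)
  n_cells <- as.integer(n_cells)
  if (is.na(n_cells) || n_cells < 0) stop("n_cells must be >= 0", call. = FALSE)
  structure(list(name = name, fractions = fractions, n_cells = n_cells),
            class = "scrs_preset")
}

#' @param n_cells Cohort size (default 5321).
#' @rdname composition_preset
#' @export
preset_red_sea_default <- function(n_cells = 5321) {
  composition_preset(c(fluorescent = 0.33, carotenoid = 0.23, typical = 0.30,
                       phb = 0.07, other_compound = 0.07),
                     n_cells, name = "red_sea_default")
}

#' Simulate a seeded single-cell Raman cohort
#'
#' Draws ground-truth label counts from a multinomial over the preset
#' fractions, lays the cells out on a unique raster of chip positions
#' (10 um pitch), renders each cell from its archetype with the given noise
#' model, and records ground truth (label and, for carotenoid cells, the
#' realised band triplet) in the set metadata. The same seed reproduces the
#' output bit for bit; the caller's RNG state is left untouched.
#'
#' @param preset A [composition_preset()] (default
#'   [preset_red_sea_default()]).
#' @param noise An [noise_model()]; use [zero_noise()] for the noiseless
#'   limit.
#' @param seed Integer seed.
#' @param grid Wavenumber grid (default [default_grid()]).
#' @param archetypes Optional named list of [archetype()] overrides.
#' @return An [scrs_set()] with provenance `(preset, seed)`.
#' @examples
#' set <- simulate_cohort(preset_red_sea_default(n_cells = 50), seed = 1)
#' table(set$meta$label)
#' @export
simulate_cohort <- function(preset = preset_red_sea_default(),
                            noise = noise_model(), seed = 1,
                            grid = default_grid(), archetypes = NULL) {
  stopifnot(inherits(preset, "scrs_preset"))
  if (is.null(noise)) noise <- zero_noise()
  stopifnot(inherits(noise, "scrs_noise_model"))
  n <- preset$n_cells
  arch_list <- lapply(archetype_names(), archetype_default)
  names(arch_list) <- archetype_names()
  for (nm in names(archetypes)) arch_list[[nm]] <- archetypes[[nm]]
  mat <- matrix(0, n, grid$n_points)
  meta <- data.frame(cell_id = sprintf("cell_%05d", seq_len(n)),
                     x = rep(NA_real_, n), y = rep(NA_real_, n),
                     label = rep(NA_character_, n), v1 = rep(NA_real_, n),
                     v2 = rep(NA_real_, n), v3 = rep(NA_real_, n),
                     stringsAsFactors = FALSE)
  if (n > 0) {
    with_seed(seed, {
      fr <- preset$fractions[preset$fractions > 0]
      counts <- drop(stats::rmultinom(1, n, fr))
      labels <- sample(rep(names(fr), counts))
      ncols <- ceiling(sqrt(n))
      meta$x <- ((seq_len(n) - 1) %% ncols) * 10
      meta$y <- ((seq_len(n) - 1) %/% ncols) * 10
      meta$label <- labels
      for (i in seq_len(n)) {
        s <- render_archetype(arch_list[[labels[i]]], grid, noise)
        mat[i, ] <- s$intensities
        tr <- attr(s, "triplet")
        if (!is.null(tr)) {
          meta$v1[i] <- tr[1]; meta$v2[i] <- tr[2]; meta$v3[i] <- tr[3]
        }
      }
    })
  }
  scrs_set(mat, grid, meta,
           provenance = list(preset = preset$name, seed = seed,
                             fractions = preset$fractions,
                             noise = unclass(noise)))
}

#' Reference spectra of the seven sorted samples
#'
#' Seven noiseless carotenoid spectra named after the sorted samples
#' (P728-5, B728-3, H808-5, S709-6, P709-11, G610-8, P610-5), with pinned
#' (v1, v2, v3) triplets chosen inside the canonical carotenoid windows so
#' that the three Pelomonas-like samples (P728-5, P709-11, P610-5) share one
#' triplet and the other four are mutually distinct -- five unique
#' carotenoid types in total, resolvable at the ~1 cm^-1 instrument
#' resolution.
#'
#' @return An [scrs_set()] of 7 noiseless spectra with ground-truth triplets
#'   in the metadata.
#' @examples
#' ref <- sorted_samples_reference()
#' ref$meta[, c("cell_id", "v1", "v2", "v3")]
#' @export
sorted_samples_reference <- function() {
  samples <- data.frame(
    cell_id = c("P728-5", "B728-3", "H808-5", "S709-6", "P709-11", "G610-8",
                "P610-5"),
    v1 = c(1003, 1000, 1006,  998, 1003, 1001, 1003),
    v2 = c(1152, 1148, 1158, 1155, 1152, 1160, 1152),
    v3 = c(1509, 1516, 1522, 1505, 1509, 1525, 1509),
    stringsAsFactors = FALSE)
  grid <- default_grid()
  arch <- archetype_default("carotenoid")
  mat <- matrix(0, nrow(samples), grid$n_points)
  for (i in seq_len(nrow(samples)))
    mat[i, ] <- render_archetype(arch, grid,
                                 triplet = unlist(samples[i, c("v1", "v2", "v3")]),
                                 cell_id = samples$cell_id[i])$intensities
  meta <- data.frame(cell_id = samples$cell_id, x = NA_real_, y = NA_real_,
                     label = "carotenoid", v1 = samples$v1, v2 = samples$v2,
                     v3 = samples$v3, stringsAsFactors = FALSE)
  scrs_set(mat, grid, meta,
           provenance = list(preset = "sorted_samples_reference", seed = NA))
}

# Evaluate `code` under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  code
}
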