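test_that("noiseless carotenoid render peaks exactly at the pinned triplet", {
  s <- render_archetype("carotenoid", triplet = c(1003, 1155, 1515))
  wn <- wavenumbers(s$grid)
  y <- s$intensities
  for (pos in c(1003, 1155, 1515)) {
    i <- match(pos, wn)
    expect_true(y[i] > y[i - 1] && y[i] > y[i + 1],
                label = sprintf("local maximum at %d cm^-1", pos))
  }
  # the global maximum sits at the highest-height peak (v3)
  expect_identical(wn[which.max(y)], 1515)
})

test_that("noiseless PHB render has maxima at all four marker bands", {
  s <- render_archetype("phb")
  wn <- wavenumbers(s$grid)
  y <- s$intensities
  for (pos in c(839, 1058, 1123, 1403)) {
    i <- match(pos, wn)
    expect_true(y[i] > y[i - 1] && y[i] > y[i + 1],
                label = sprintf("local maximum at %d cm^-1", pos))
  }
})

test_that("an archetype with no peaks and no background renders to zero", {
  a <- archetype("empty", data.frame(center = numeric(), height = numeric(),
                                     fwhm = numeric()))
  s <- render_archetype(a, wn_grid(700, 1, 50))
  expect_identical(s$intensities, rep(0, 50))
})

test_that("noiseless renders peak at the highest-height band for every archetype", {
  for (nm in archetype_names()) {
    a <- archetype_default(nm)
    if (identical(a$background$kind, "broad_gaussian")) next # bump dominates
    s <- if (a$carotenoid)
      render_archetype(a, triplet = c(1002, 1150, 1510)) else
      render_archetype(a)
    wn <- wavenumbers(s$grid)
    # with tied heights any of the tied band centres may carry the maximum
    top_centers <- if (a$carotenoid) 1510 else
      a$peaks$center[a$peaks$height == max(a$peaks$height)]
    expect_true(wn[which.max(s$intensities)] %in% top_centers, label = nm)
  }
})

test_that("fluorescent archetype background mass dwarfs its Raman bands", {
  a <- archetype_default("fluorescent")
  with_bump <- render_archetype(a, wn_grid(700, 1, 1019),
                                cell_id = "f")$intensities
  peaks_only <- render_archetype(archetype_default("typical"),
                                 wn_grid(700, 1, 1019))$intensities
  # same base-band heights in both archetypes, so the difference is the bump
  bump <- sum(with_bump) - sum(peaks_only)
  expect_gt(bump, 10 * sum(peaks_only))
})

test_that("cohort composition follows the preset within binomial bounds", {
  set <- simulate_cohort(preset_red_sea_default(), noise_model(), seed = 1)
  expect_identical(n_spectra(set), 5321L)
  counts <- table(set$meta$label)
  for (nm in names(counts)) {
    p <- preset_red_sea_default()$fractions[nm]
    expect_lt(abs(counts[[nm]] - 5321 * p), 3 * sqrt(5321 * p * (1 - p)),
              label = sprintf("%s count within 3 sigma", nm))
  }
  # chip raster positions are unique
  expect_false(any(duplicated(paste(set$meta$x, set$meta$y))))
  # carotenoid cells (and only they) carry a ground-truth triplet
  has_trip <- !is.na(set$meta$v1)
  expect_identical(has_trip, set$meta$label == "carotenoid")
  w <- carotenoid_windows()
  expect_true(all(set$meta$v1[has_trip] >= w["v1", "lo"] &
                    set$meta$v1[has_trip] <= w["v1", "hi"]))
})

test_that("simulation is bit-reproducible under a seed and sensitive to it", {
  p <- preset_red_sea_default(n_cells = 40)
  a <- simulate_cohort(p, noise_model(), seed = 7)
  b <- simulate_cohort(p, noise_model(), seed = 7)
  c <- simulate_cohort(p, noise_model(), seed = 8)
  expect_identical(a$intensities, b$intensities)
  expect_identical(a$meta, b$meta)
  expect_false(identical(a$intensities, c$intensities))
  # the caller's RNG stream is not disturbed
  set.seed(123); x1 <- runif(3)
  set.seed(123); invisible(simulate_cohort(p, seed = 1)); x2 <- runif(3)
  expect_identical(x1, x2)
})

test_that("degenerate cohorts and invalid presets are handled", {
  empty <- simulate_cohort(preset_red_sea_default(n_cells = 0), seed = 1)
  expect_identical(n_spectra(empty), 0L)
  expect_error(composition_preset(c(typical = 0.5, phb = 0.4), 10),
               "sum to 1")
  expect_error(composition_preset(c(unknown = 1), 10), "unknown archetype")
})

test_that("sorted-sample references resolve as seven spectra with five triplets", {
  ref <- sorted_samples_reference()
  expect_identical(n_spectra(ref), 7L)
  expect_identical(ref$meta$cell_id,
                   c("P728-5", "B728-3", "H808-5", "S709-6", "P709-11",
                     "G610-8", "P610-5"))
  trip <- ref$meta[, c("v1", "v2", "v3")]
  expect_identical(nrow(unique(trip)), 5L)
  pel <- ref$meta$cell_id %in% c("P728-5", "P709-11", "P610-5")
  expect_identical(nrow(unique(trip[pel, ])), 1L)
  w <- carotenoid_windows()
  for (k in 1:3)
    expect_true(all(trip[[k]] >= w[k, "lo"] & trip[[k]] <= w[k, "hi"]))
})
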