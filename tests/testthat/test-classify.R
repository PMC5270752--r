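test_that("fluorescence index separates pure-peak from bump-dominated spectra", {
  # isolated narrow peaks on a zero background carry no baseline mass
  y <- rep(0, 500)
  y[c(100, 250, 400)] <- 10
  expect_lt(fluorescence_index(y, estimate_baseline(y)), 0.05)

  # broad Lorentzian bands lift the baseline a little, but a typical cell
  # stays far below the screening threshold
  s <- render_archetype("typical")
  expect_lt(fluorescence_index(s, estimate_baseline(s)), 0.5)

  set.seed(31)
  f <- render_archetype("fluorescent")
  expect_gt(fluorescence_index(f, estimate_baseline(f)), 0.85)

  expect_true(is.na(fluorescence_index(rep(0, 10), rep(0, 10))))
})

test_that("peak detection returns the pinned carotenoid bands and nothing on ramps", {
  s <- render_archetype("carotenoid", triplet = c(1003, 1155, 1515))
  pk <- detect_peaks(s, min_prominence_sigma = 5)
  expect_true(all(c(1003, 1155, 1515) %in% pk$position))
  expect_identical(nrow(detect_peaks(seq_len(50))), 0L)
})

test_that("peak detection agrees with the exhaustive brute-force oracle", {
  set.seed(77)
  for (case in 1:120) {
    n <- sample(8:64, 1)
    y <- switch(1 + case %% 3,
                rnorm(n),
                as.numeric(sample.int(5, n, replace = TRUE)),  # many ties
                cumsum(rnorm(n)))
    got <- detect_peaks(y, min_prominence_sigma = 0)
    want <- brute_force_peaks(y)
    expect_identical(got$position, as.numeric(want$index))
    expect_equal(got$height, want$height, tolerance = 1e-12)
    expect_equal(got$prominence, want$prominence, tolerance = 1e-12)
  }
})

test_that("band matching fills all and only the windows holding peaks", {
  peaks <- data.frame(position = c(1003, 1155, 1515),
                      height = c(2, 3, 5), prominence = c(2, 3, 5))
  m <- match_bands(peaks)
  vm <- m[grepl("carotenoid", m$role), ]
  expect_true(all(vm$matched))
  expect_identical(sort(vm$position), c(1003, 1155, 1515))

  m2 <- match_bands(peaks[1:2, ])
  expect_false(m2$matched[m2$role == "carotenoid_v3"])

  overlapping <- rbind(band_definition("a", 1000, 1010, "base_cell"),
                       band_definition("b", 1005, 1020, "phb_marker"))
  expect_error(match_bands(peaks, overlapping), "config error")
})

test_that("band-match ties resolve by prominence, centre distance, then lower wavenumber", {
  # v2 window [1145,1161] has centre 1153: 1150 and 1156 are equidistant at
  # equal prominence, so the lower wavenumber wins
  peaks <- data.frame(position = c(1150, 1156), height = c(1, 1),
                      prominence = c(1, 1))
  m <- match_bands(peaks)
  expect_identical(m$position[m$role == "carotenoid_v2"], 1150)

  peaks2 <- data.frame(position = c(1150, 1156), height = c(1, 2),
                       prominence = c(1, 2))
  m2 <- match_bands(peaks2)
  expect_identical(m2$position[m2$role == "carotenoid_v2"], 1156)
})

test_that("phenotype decision order is fluorescent > carotenoid > phb > typical > other", {
  g <- default_grid()
  mk_set <- function(y, label = NA_character_) {
    scrs_set(matrix(y, 1), g, data.frame(cell_id = "c1", label = label))
  }
  caro <- render_archetype("carotenoid", triplet = c(1003, 1155, 1515))
  expect_identical(classify_cohort(mk_set(caro$intensities))$calls$label,
                   "carotenoid")
  phb <- render_archetype("phb")
  pcall <- classify_cohort(mk_set(phb$intensities))$calls
  expect_identical(pcall$label, "phb")
  expect_identical(pcall$n_phb_matches, 4L)

  # carotenoid and PHB bands together: carotenoid has priority
  both_arch <- archetype("both", archetype_default("phb")$peaks,
                         carotenoid = TRUE)
  both <- render_archetype(both_arch, triplet = c(1003, 1155, 1515))
  expect_identical(classify_cohort(mk_set(both$intensities))$calls$label,
                   "carotenoid")

  # fluorescence preempts band calls and leaves the band slots empty
  set.seed(8)
  fl <- render_archetype("fluorescent")
  fcall <- classify_cohort(mk_set(fl$intensities))$calls
  expect_true(fcall$is_fluorescent)
  expect_identical(fcall$label, "fluorescent")
  expect_identical(fcall$n_carotenoid_matches, 0L)
  expect_true(is.na(fcall$v1))
})

test_that("an empty cohort classifies to zero counts without error", {
  empty <- simulate_cohort(preset_red_sea_default(n_cells = 0), seed = 1)
  rep <- classify_cohort(empty)
  expect_identical(unname(rep$counts), rep(0L, 5))
})

test_that("classification is invariant under positive rescaling of raw counts", {
  set <- simulate_cohort(preset_red_sea_default(n_cells = 60),
                         noise_model(), seed = 12)
  scaled <- set
  scaled$intensities <- set$intensities * 7.3
  a <- classify_cohort(set)
  b <- classify_cohort(scaled)
  expect_identical(a$calls$label, b$calls$label)
  expect_equal(a$calls$fluor_index, b$calls$fluor_index, tolerance = 1e-9)
  expect_equal(a$calls$v1, b$calls$v1)
})

test_that("the noiseless limit classifies every archetype correctly", {
  set <- simulate_cohort(preset_red_sea_default(n_cells = 150), zero_noise(),
                         seed = 21)
  rep <- classify_cohort(set)
  expect_identical(rep$accuracy, 1)
  expect_true(all(diag(rep$confusion) == rowSums(rep$confusion)))
})

test_that("fluorescent plus distinguishable fractions always sum to one", {
  for (seed in c(2, 9)) {
    set <- simulate_cohort(preset_red_sea_default(n_cells = 80),
                           noise_model(), seed = seed)
    rep <- classify_cohort(set)
    distinguishable <- sum(rep$counts[c("carotenoid", "phb", "typical",
                                        "other")])
    expect_identical(rep$counts[["fluorescent"]] + distinguishable, rep$n)
  }
})
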