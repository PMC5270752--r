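processed_from_matrix <- function(m) {
  # wrap an arbitrary matrix as a minimal processed set for PCA tests
  g <- wn_grid(700, 1, ncol(m))
  structure(list(grid = g, corrected = m,
                 baseline = matrix(0, nrow(m), ncol(m)),
                 noise_sigma = rep(1, nrow(m)), norm = rep(1, nrow(m)),
                 fluor_index = rep(0, nrow(m)), raw_sum = rowSums(m),
                 flags = data.frame(cell_id = sprintf("c%03d", seq_len(nrow(m))),
                                    low_signal = FALSE),
                 meta = data.frame(cell_id = sprintf("c%03d", seq_len(nrow(m)))),
                 params = list(), provenance = list()),
            class = "scrs_processed")
}

test_that("two distinct spectra put all variance on the first component", {
  m <- rbind(c(1, 2, 3, 4), c(2, 1, 5, 0))
  p <- scrs_pca(processed_from_matrix(m), n_components = 1,
                exclude_fluorescent = FALSE)
  expect_lt(abs(p$explained_variance_ratio[1] - 1), 1e-9)
  expect_error(scrs_pca(processed_from_matrix(m[1, , drop = FALSE])),
               "at least 2")
})

test_that("PCA matches a brute-force covariance eigendecomposition", {
  set.seed(14)
  m <- matrix(rnorm(20 * 32), 20, 32)
  p <- scrs_pca(processed_from_matrix(m), n_components = 5,
                exclude_fluorescent = FALSE)
  ev <- eigen(stats::cov(m), symmetric = TRUE)
  expect_equal(p$explained_variance_ratio,
               (ev$values / sum(ev$values))[1:5], tolerance = 1e-6)
  for (j in 1:5)
    expect_lt(max(abs(abs(p$loadings[, j]) - abs(ev$vectors[, j]))), 1e-6)
  # loading columns are orthonormal and signed so the largest entry is positive
  expect_lt(max(abs(crossprod(p$loadings) - diag(5))), 1e-8)
  for (j in 1:5)
    expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  # scores reconstruct the centred data up to the truncation error
  recon <- p$scores %*% t(p$loadings)
  centred <- sweep(m, 2, p$center)
  resid <- sum((centred - recon)^2) / sum(centred^2)
  expect_lt(resid, 1 - sum(p$explained_variance_ratio) + 1e-6)
})

test_that("PC1 separates noiseless carotenoid from typical cells perfectly", {
  p50 <- composition_preset(c(carotenoid = 0.5, typical = 0.5), 100)
  set <- simulate_cohort(p50, zero_noise(), seed = 17)
  proc <- preprocess_spectra(set)
  p <- scrs_pca(proc, n_components = 2, exclude_fluorescent = FALSE)
  s1 <- p$scores[, 1]
  caro <- set$meta$label == "carotenoid"
  # a single threshold separates the groups iff their score ranges disjoint
  separable <- max(s1[!caro]) < min(s1[caro]) ||
    max(s1[caro]) < min(s1[!caro])
  expect_true(separable)
})

test_that("PCA is invariant to spectrum order and maps duplicates together", {
  set.seed(23)
  m <- matrix(runif(12 * 30), 12, 30)
  m[12, ] <- m[1, ]                      # duplicate spectrum
  p <- scrs_pca(processed_from_matrix(m), n_components = 3,
                exclude_fluorescent = FALSE)
  perm <- sample(12)
  p2 <- scrs_pca(processed_from_matrix(m[perm, ]), n_components = 3,
                 exclude_fluorescent = FALSE)
  expect_equal(p2$scores[order(perm), ], p$scores, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(p$scores[12, ], p$scores[1, ], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("top-loading windows recover a rectangular bump exactly", {
  l <- rep(0.01, 64)
  l[20:25] <- 1
  fake <- structure(list(loadings = matrix(l / sqrt(sum(l^2)), ncol = 1),
                         wavenumbers = as.numeric(700:763)),
                    class = "scrs_pca")
  w <- top_loading_windows(fake, 1, alpha = 0.5)
  expect_identical(nrow(w), 1L)
  expect_identical(c(w$lo, w$hi), c(719, 724))

  # near-1 alpha keeps only the argmax of a strictly unimodal loading
  uni <- exp(-((1:64) - 30)^2 / 50)
  fake$loadings <- matrix(uni, ncol = 1)
  w2 <- top_loading_windows(fake, 1, alpha = 0.999)
  expect_lte(w2$hi - w2$lo, 2)
  expect_true(w2$lo <= 729 && w2$hi >= 729)
  expect_error(top_loading_windows(fake, 1, alpha = 1.2), "alpha")
})

test_that("runs separated by fewer than three points merge into one window", {
  l <- rep(0, 40)
  l[c(10, 11, 14, 15)] <- 1              # gap of 2 points -> merged
  l[30] <- 1                             # far run stays separate
  fake <- structure(list(loadings = matrix(l, ncol = 1),
                         wavenumbers = as.numeric(700:739)),
                    class = "scrs_pca")
  w <- top_loading_windows(fake, 1, alpha = 0.5)
  expect_identical(nrow(w), 2L)
  expect_identical(c(w$lo[1], w$hi[1]), c(709, 714))
})
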