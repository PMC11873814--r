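test_that("elliptical distortion correction inverts the forward distortion", {
  th <- seq(0, 2 * pi, length.out = 37)[-37]
  circle <- tibble::tibble(x = 0.2 * cos(th), y = 0.2 * sin(th))
  expect_equal(correct_elliptical_distortion(circle, 1, 85), circle)
  # apply the known forward distortion, then correct it
  ang <- 85 * pi / 180
  R <- matrix(c(cos(ang), -sin(ang), sin(ang), cos(ang)), 2, byrow = TRUE)
  P <- as.matrix(circle) %*% t(R %*% diag(c(1.023, 1)) %*% t(R))
  fixed <- correct_elliptical_distortion(
    tibble::tibble(x = P[, 1], y = P[, 2]), 1.023, 85)
  expect_equal(fixed$x, circle$x, tolerance = 1e-9)
  expect_equal(fixed$y, circle$y, tolerance = 1e-9)
  # a peak on the distortion axis halves its radius at ratio 2
  onaxis <- correct_elliptical_distortion(tibble::tibble(x = 1, y = 0), 2, 0)
  expect_equal(onaxis$x, 0.5)
  expect_equal(onaxis$y, 0)
})

test_that("autocorrelation extracts the basis of an exact oblique net", {
  peaks <- make_net_peaks(0.1, 0.15, 75)
  bas <- extract_basis(peaks)
  expect_equal(sqrt(sum(bas$v1^2)), 0.1, tolerance = 1e-6)
  expect_equal(sqrt(sum(bas$v2^2)), 0.15, tolerance = 1e-6)
  cosphi <- sum(bas$v1 * bas$v2) / (0.1 * 0.15)
  expect_equal(abs(cosphi), abs(cos(75 * pi / 180)), tolerance = 1e-5)
  expect_equal(bas$matched_fraction, 1)
})

test_that("basis extraction tolerates a minority of outlier peaks", {
  set.seed(31)
  peaks <- make_net_peaks(0.1, 0.15, 75)
  out <- tibble::tibble(x = runif(10, -0.4, 0.4), y = runif(10, -0.4, 0.4))
  bas <- extract_basis(dplyr::bind_rows(peaks, out))
  expect_equal(sqrt(sum(bas$v1^2)), 0.1, tolerance = 0.01)
  expect_equal(sqrt(sum(bas$v2^2)), 0.15, tolerance = 0.01)
})

test_that("basis extraction preconditions are enforced", {
  expect_error(extract_basis(make_net_peaks(n = 0)), "at least 5")
  collinear <- tibble::tibble(x = (1:6) * 0.1, y = 0)
  expect_error(extract_basis(collinear), "no 2D lattice")
})

test_that("least-squares refinement recovers a perturbed basis", {
  peaks <- make_net_peaks(0.1, 0.15, 75)
  v1 <- c(0.102, 0.001)
  v2 <- 0.152 * c(cos(76 * pi / 180), sin(76 * pi / 180))
  ref <- refine_basis(peaks, v1, v2)
  expect_equal(sqrt(sum(ref$v1^2)), 0.1, tolerance = 1e-8)
  expect_equal(sqrt(sum(ref$v2^2)), 0.15, tolerance = 1e-8)
  expect_lt(ref$residual, 1e-10)
  expect_equal(ref$matched_fraction, 1)
})

test_that("refinement under noise stays within the noise scale", {
  set.seed(32)
  peaks <- make_net_peaks(0.1, 0.15, 75)
  noisy <- dplyr::mutate(peaks,
                         x = x + rnorm(dplyr::n(), sd = 0.0005),
                         y = y + rnorm(dplyr::n(), sd = 0.0005))
  ref <- refine_basis(noisy, c(0.1, 0), 0.15 * c(cos(1.309), sin(1.309)))
  expect_equal(sqrt(sum(ref$v1^2)), 0.1, tolerance = 0.005)
  expect_equal(ref$matched_fraction, 1)
})

test_that("non-lattice peaks give a low matched fraction without crashing", {
  set.seed(33)
  rand <- tibble::tibble(x = runif(40, -0.5, 0.5), y = runif(40, -0.5, 0.5))
  ref <- refine_basis(rand, c(0.1, 0), c(0, 0.15))
  expect_lt(ref$matched_fraction, 0.5)
})

test_that("lattice score separates zonal from composite patterns", {
  peaks <- make_net_peaks(0.1, 0.15, 75)
  bas <- list(v1 = c(0.1, 0), v2 = 0.15 * c(cos(1.309), sin(1.309)))
  expect_equal(lattice_score(peaks, bas), 1.0)
  # half the peaks shifted off-lattice by half a basis vector
  n <- nrow(peaks)
  half <- peaks
  shift <- seq_len(n) <= n / 2
  half$x[shift] <- half$x[shift] + 0.05
  expect_equal(lattice_score(half, bas), 0.5, tolerance = 0.05)
  # a high-index section emulated by two interleaved nets scores below 1
  inter <- dplyr::bind_rows(peaks,
                            dplyr::mutate(peaks, x = x + 0.033, y = y + 0.041))
  expect_lt(lattice_score(inter, bas), 1)
})

test_that("peak lists reduce to pattern rows and read from text", {
  peaks <- make_net_peaks(0.1, 0.15, 75)
  row <- peaks_to_pattern(peaks, id = "p1")
  expect_equal(row$d1, 10, tolerance = 1e-5)
  expect_equal(row$d2, 1 / 0.15, tolerance = 1e-5)
  expect_equal(row$phi, 75, tolerance = 1e-4)
  expect_equal(row$lattice_score, 1)

  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("pattern_id,x,y", "a,0.1,0.0", "a,0.0,0.2"), tmp)
  pk <- read_peak_list(tmp, camera_constant = 2)
  expect_equal(pk$x, c(0.2, 0))
  expect_equal(pk$y, c(0, 0.4))
})
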