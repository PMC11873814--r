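test_that("volume layers follow the geometric progression", {
  l <- volume_layers(763, 1000, 0.025)
  expect_length(l, 12)
  expect_equal(round(l, 1),
               c(763.0, 782.1, 801.6, 821.7, 842.2, 863.3, 884.8, 907.0,
                 929.6, 952.9, 976.7, 1001.1))
  expect_equal(volume_layers(100, 100, 0.1), 100)
  expect_equal(volume_layers(500, 600, 0.05),
               c(500, 525, 551.25, 578.8125, 607.753125))
})

test_that("the scan frame fixes mesh area and the default V_min", {
  pats <- example_patterns("cupccl16")
  frame <- scan_frame(pats[pats$id == 7, ])
  expect_equal(frame$A, 14.15 * 14.45 / sin(68 * pi / 180), tolerance = 1e-9)
  expect_equal(vmin_default(frame, 3.46), 763, tolerance = 1e-3)
  sq <- scan_frame(as_zone_patterns(tibble::tibble(d1 = 10, d2 = 10,
                                                   phi = 90)))
  expect_equal(vmin_default(sq, 3.4), 340)
})

test_that("candidate grids respect the symmetry class", {
  pats <- as_zone_patterns(tibble::tibble(d1 = 10, d2 = 10, phi = 90))
  frame <- scan_frame(pats)
  layers <- volume_layers(763, 1000, 0.025)
  g4 <- candidate_grid(frame, layers, symmetry = "p4")
  expect_equal(nrow(g4), 24) # two points per layer
  g6 <- candidate_grid(frame, layers[1], symmetry = "p6")
  expect_equal(g6$xi, c(0, 1 / 3))
  expect_equal(g6$eta, c(0, 1 / 3))
  gp <- candidate_grid(frame, layers[1], symmetry = "pmm")
  expect_true(all(gp$xi %in% c(0, 0.5) | gp$eta %in% c(0, 0.5)))
  g1 <- candidate_grid(frame, layers[1], symmetry = "p1")
  # full grid: xi in [-1/2, 1/2), eta in [0, 1/2], at the layer's step
  expect_true(all(g1$eta >= 0 & g1$eta <= 0.5))
  expect_true(all(g1$xi >= -0.5 & g1$xi < 0.5))
  zeta <- 1 / (frame$A_star * layers[1])
  fs <- min(zeta, frame$g1, frame$g2) / 12 / frame$g1
  n_xi <- length(seq(-0.5, 0.5 - fs, by = fs))
  n_eta <- length(seq(0, 0.5, by = fs))
  expect_equal(nrow(g1), n_xi * n_eta)
})

test_that("candidate cells hit the requested volume exactly", {
  pats <- example_patterns("cupccl16")
  frame <- scan_frame(pats[pats$id == 7, ])
  cand <- build_candidate_cell(frame, 0, 0, 842)
  expect_equal(unname(cand[["alpha"]]), 90, tolerance = 1e-9)
  expect_equal(unname(cand[["beta"]]), 90, tolerance = 1e-9)
  # interlayer spacing = V / A is the known short axis
  expect_equal(842 / frame$A, 3.82, tolerance = 1e-3)
  set.seed(71)
  for (i in 1:20) {
    fr <- scan_frame(as_zone_patterns(tibble::tibble(
      d1 = runif(1, 5, 20), d2 = runif(1, 2, 20), phi = runif(1, 50, 130))))
    V <- runif(1, 200, 2000)
    cand <- build_candidate_cell(fr, runif(1, -0.5, 0.5), runif(1, 0, 0.5), V)
    expect_equal(cell_volume(reciprocal_of(cand)), V, tolerance = 1e-9)
  }
})

test_that("the initial zone is chosen by symmetry then by vector length", {
  pats <- example_patterns("cupccl16")
  expect_equal(select_initial_zone(pats), 7)
  expect_equal(select_initial_zone(pats[pats$id != 7, ]), 4)
  expect_equal(select_initial_zone(example_patterns("lysozyme")), 1)
})

test_that("a noise-free search recovers its generator and is deterministic", {
  cell <- unit_cell(9.5, 11.2, 13.1, 96, 84, 99)
  pats <- simulate_patterns(cell, n_zones = 5, max_index = 2, seed = 3)
  vtrue <- cell_volume(cell)
  fit <- cell_search(pats, v_min = 0.8 * vtrue, v_max = 1.25 * vtrue,
                     mode = "3d", max_index = 6)
  expect_true(cells_equivalent(cell, solution_cell(fit), 0.01, 1))
  expect_lt(fit$solutions$R[[1]], 0.05)
  expect_false(is.unsorted(fit$solutions$R))
  fit2 <- cell_search(pats, v_min = 0.8 * vtrue, v_max = 1.25 * vtrue,
                      mode = "3d", max_index = 6)
  expect_identical(tidy(fit), tidy(fit2))
  g <- glance(fit)
  expect_equal(g$n_patterns, 5)
  expect_gt(g$n_candidates, g$n_surviving)
})

test_that("an impossible search range reports no solution", {
  cell <- unit_cell(9.5, 11.2, 13.1, 96, 84, 99)
  pats <- simulate_patterns(cell, n_zones = 4, max_index = 2, seed = 4)
  expect_error(cell_search(pats, v_min = 80, v_max = 90, mode = "3d",
                           max_index = 4),
               "no solution in search range")
})

test_that("the traced inverse-FOM surface is consistent with the ranking", {
  cell <- unit_cell(9.5, 11.2, 13.1, 96, 84, 99)
  pats <- simulate_patterns(cell, n_zones = 4, max_index = 2, seed = 3)
  vtrue <- cell_volume(cell)
  fit <- cell_search(pats, v_min = 0.85 * vtrue, v_max = 1.2 * vtrue,
                     mode = "3d", max_index = 6, refine = FALSE,
                     trace = TRUE)
  expect_error(fom_surface(fit), "plane")
  tr <- fit$trace
  expect_true(all(tr$F_inv[!tr$accepted] == 0))
  best <- tr[which.max(tr$F_inv), ]
  surf <- fom_surface(fit, xi = best$xi)
  expect_equal(max(surf$F_inv), max(tr$F_inv))
  # argmax of the surface is the best unrefined candidate on that line
  top <- surf[which.max(surf$F_inv), ]
  expect_equal(top$V, best$V)
  fitq <- cell_search(pats, v_min = 0.85 * vtrue, v_max = 1.2 * vtrue,
                      mode = "3d", max_index = 6, refine = FALSE)
  expect_error(fom_surface(fitq, xi = 0), "trace")
})

test_that("refinement never increases R and stays within its grid cell", {
  cell <- unit_cell(9.5, 11.2, 13.1, 96, 84, 99)
  pats <- simulate_patterns(cell, n_zones = 4, max_index = 2, seed = 3)
  vtrue <- cell_volume(cell)
  raw <- cell_search(pats, v_min = 0.85 * vtrue, v_max = 1.2 * vtrue,
                     mode = "3d", max_index = 6, refine = FALSE)
  ref <- cell_search(pats, v_min = 0.85 * vtrue, v_max = 1.2 * vtrue,
                     mode = "3d", max_index = 6, refine = TRUE)
  expect_lte(ref$solutions$R[[1]], raw$solutions$R[[1]] + 1e-12)
  expect_true(all(ref$solutions$volume / ref$solutions$V_layer <= 1.026 &
                    ref$solutions$volume / ref$solutions$V_layer >= 1 / 1.026))
})
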