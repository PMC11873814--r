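test_that("zone enumeration is coprime, sign-folded and deterministic", {
  z1 <- enumerate_zones(1)
  expect_equal(nrow(z1), 13)
  z6 <- enumerate_zones(6)
  expect_true(any(z6$u == 3 & z6$v == 5 & z6$w == 6))
  g <- mapply(function(u, v, w) zonecell:::gcd3(u, v, w), z6$u, z6$v, z6$w)
  expect_true(all(g == 1))
  # one representative per +/- pair, first non-zero component positive
  key <- paste(z6$u, z6$v, z6$w)
  negkey <- paste(-z6$u, -z6$v, -z6$w)
  expect_length(intersect(key, negkey), 0)
  expect_identical(enumerate_zones(3), enumerate_zones(3))
})

test_that("zone kernel bases span the full in-zone sublattice", {
  set.seed(41)
  for (i in 1:100) {
    t3 <- sample(-9:9, 3, replace = TRUE)
    if (all(t3 == 0)) next
    g <- zonecell:::gcd3(t3[1], t3[2], t3[3])
    t3 <- t3 / g
    B <- zonecell:::zone_kernel_basis(t3[1], t3[2], t3[3])
    expect_equal(as.numeric(B %*% t3), c(0, 0))
    cr <- c(B[1, 2] * B[2, 3] - B[1, 3] * B[2, 2],
            B[1, 3] * B[2, 1] - B[1, 1] * B[2, 3],
            B[1, 1] * B[2, 2] - B[1, 2] * B[2, 1])
    # primitive basis: cross product equals the zone axis up to sign
    expect_true(all(cr == t3) || all(cr == -t3))
  }
})

test_that("zone nets match the printed and closed-form cases", {
  net <- zone_net(unit_cell(10, 10, 10), c(0, 0, 1))
  expect_equal(net$d1, 10)
  expect_equal(net$d2, 10)
  expect_equal(net$phi, 90)
  # the layer-stacking zone of the C-centred phthalocyanine cell: the two
  # {110} diagonals; closed-form d(110) = 1/sqrt(a*^2 + b*^2) = 14.569 A
  # (measured 14.15/14.45)
  d110 <- 1 / sqrt(1 / (17.685 * sin(95.05 * pi / 180))^2 + 1 / 25.918^2)
  netc <- zone_net(published_cupc(), c(0, 0, 1), centring = "C")
  expect_equal(netc$d1, d110, tolerance = 1e-9)
  expect_equal(netc$d2, d110, tolerance = 1e-9)
  expect_true(all(abs(c(netc$h1, netc$k1)) == 1))
})

test_that("zone nets agree with the brute-force shortest-pair oracle", {
  set.seed(42)
  zones <- as.matrix(enumerate_zones(2))
  for (i in 1:12) {
    cell <- random_cell()
    centring <- sample(c("P", "C", "I", "F"), 1)
    for (j in sample(nrow(zones), 6)) {
      uvw <- zones[j, ]
      bf <- bf_zone_net(cell, uvw, centring, hmax = 6)
      net <- zone_net(cell, uvw, centring = centring)
      expect_equal(net$g1, bf$g1, tolerance = 1e-9)
      expect_equal(net$g2, bf$g2, tolerance = 1e-9)
      expect_equal(net$phi, bf$phi, tolerance = 1e-6)
    }
  }
})

test_that("centring reflection conditions filter the zone nets", {
  # C centring: h + k = 2n, so (100) and (010) are absent from [001]
  netP <- zone_net(published_cupc(), c(0, 0, 1), centring = "P")
  netC <- zone_net(published_cupc(), c(0, 0, 1), centring = "C")
  expect_true((netP$h1 + netP$k1) %% 2 == 1) # (010)/(100) present for P
  expect_true((netC$h1 + netC$k1) %% 2 == 0)
  expect_true((netC$h2 + netC$k2) %% 2 == 0)
  # F centring in [001] (l = 0): h+k and h+l both even forces h and k even,
  # so the shortest allowed reflection is (200)
  netF <- zone_net(unit_cell(10, 10, 10), c(0, 0, 1), centring = "F")
  expect_equal(netF$g1, 0.2, tolerance = 1e-9)
  expect_true(all(c(netF$h1, netF$k1, netF$h2, netF$k2) %% 2 == 0))
})

test_that("pattern mismatch components follow the weighted scheme", {
  net <- zone_net(unit_cell(10, 12, 14, 90, 90, 90), c(0, 0, 1))
  p0 <- tibble::tibble(d1 = net$d1, d2 = net$d2, phi = net$phi)
  m0 <- pattern_mismatch(p0, net)
  expect_equal(m0$T_p, 0)
  expect_equal(c(m0$eps_ratio, m0$eps_angle, m0$eps_scale), c(0, 0, 0))
  # a pure 0.8% ratio mismatch with the default w1 contributes exactly 1/3
  p1 <- tibble::tibble(d1 = net$d1, d2 = net$d2 / 1.008, phi = net$phi)
  s_p <- pattern_mismatch(p1, net)$s_p
  m1 <- pattern_mismatch(p1, net, mean_scale = s_p)
  expect_equal(m1$eps_ratio, 0.008, tolerance = 1e-6)
  expect_equal(m1$eps_scale, 0)
  expect_equal(m1$T_p, 1 / 3, tolerance = 1e-3)
  # a 0.6 degree angle error at 90 degrees: eps = 0.00667, T = 0.370
  p2 <- tibble::tibble(d1 = net$d1, d2 = net$d2, phi = 89.4)
  m2 <- pattern_mismatch(p2, net, mean_scale = 1)
  expect_equal(m2$eps_angle, 0.6 / 90, tolerance = 1e-6)
  expect_equal(m2$T_p, (0.6 / 90) / 0.006 / 3, tolerance = 1e-3)
})

test_that("indexing against known cells recovers the published zones", {
  res <- index_patterns(example_patterns("cupccl16"), published_cupc(),
                        centring = "C")
  expect_true(all(res$accepted))
  r4 <- res[res$id == 4, ]
  expect_equal(sort(abs(c(r4$u, r4$v, r4$w))), c(0, 1, 4)) # [104]-type
  expect_setequal(abs(c(r4$h1, r4$k1, r4$l1)), c(0, 2, 0))

  grgds <- unit_cell(28.6756, 4.4446, 19.466, 90, 105.47, 90.02)
  res2 <- index_patterns(example_patterns("grgds"), grgds, centring = "C")
  r1 <- res2[res2$id == 1, ]
  expect_equal(abs(c(r1$u, r1$v, r1$w)), c(0, 0, 1))
  expect_equal(abs(c(r1$h1, r1$k1, r1$l1)), c(2, 0, 0))
  expect_equal(abs(c(r1$h2, r1$k2, r1$l2)), c(1, 1, 0))
})

test_that("noise-free synthetic patterns index back to their zone", {
  set.seed(43)
  for (i in 1:5) {
    cell <- random_cell()
    zones <- as.matrix(enumerate_zones(2))
    for (j in sample(nrow(zones), 4)) {
      pat <- simulate_zone_pattern(cell, zones[j, ])
      res <- index_patterns(pat, cell, max_index = 3)
      expect_true(res$accepted)
      expect_lt(res$T_p, 1e-6)
      got <- c(res$u, res$v, res$w)
      expect_true(all(got == zones[j, ]) || all(got == -zones[j, ]))
    }
  }
})

test_that("the reliability index aggregates and degenerates correctly", {
  perfect <- tibble::tibble(eps_ratio = c(0, 0), eps_angle = c(0, 0),
                            s_p = c(1, 1), accepted = TRUE)
  expect_equal(reliability_index(perfect), 0)
  two <- tibble::tibble(eps_ratio = c(0.2, 0.4) * 3 * 0.008,
                        eps_angle = 0, s_p = 1, accepted = TRUE)
  expect_equal(reliability_index(two), 0.3, tolerance = 1e-9)
  bad <- dplyr::mutate(two, accepted = c(TRUE, FALSE))
  expect_error(reliability_index(bad), "undefined")
})

test_that("R is invariant under a global camera-constant error", {
  cell <- unit_cell(11, 13, 9, 95, 88, 101)
  pats <- simulate_patterns(cell, n_zones = 4, max_index = 2,
                            sigma_d = 0.004, seed = 7)
  res1 <- index_patterns(pats, cell, max_index = 3)
  # a 3% camera-constant error, within the prior scale window
  scaled <- dplyr::mutate(pats[c("id", "d1", "d2", "phi")],
                          d1 = d1 * 1.03, d2 = d2 * 1.03)
  res2 <- index_patterns(scaled, cell, max_index = 3)
  expect_true(all(res1$accepted) && all(res2$accepted))
  expect_equal(reliability_index(res2), reliability_index(res1),
               tolerance = 1e-6)
})
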