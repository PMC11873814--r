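test_that("cell volume matches the triclinic formula and a determinant oracle", {
  expect_equal(cell_volume(published_cupc()), 1750.1, tolerance = 0.2 / 1750)
  expect_equal(cell_volume(unit_cell(10, 10, 10)), 1000)
  set.seed(11)
  for (i in 1:50) {
    cell <- random_cell()
    expect_equal(cell_volume(cell), abs(det(cell_basis(cell))),
                 tolerance = 1e-9)
  }
})

test_that("reciprocal cells obey the standard dualities", {
  rec <- reciprocal_of(unit_cell(10, 10, 10))
  expect_equal(unname(rec[["a"]]), 0.1)
  expect_equal(unname(rec[["alpha"]]), 90)
  # monoclinic: beta* = 180 - beta when the other angles are 90
  recm <- reciprocal_of(published_cupc())
  expect_equal(unname(recm[["beta"]]), 180 - 95.05, tolerance = 1e-9)
  expect_equal(unname(recm[["alpha"]]), 90, tolerance = 1e-9)
  set.seed(12)
  for (i in 1:200) {
    cell <- random_cell()
    back <- reciprocal_of(reciprocal_of(cell))
    expect_equal(as.numeric(back), as.numeric(cell), tolerance = 1e-9)
    expect_equal(cell_volume(cell) * cell_volume(reciprocal_of(cell)), 1,
                 tolerance = 1e-9)
  }
})

test_that("d-spacings follow the closed forms and are Friedel-symmetric", {
  tet <- unit_cell(79.06, 79.06, 38.22)
  expect_equal(d_spacing(tet, c(0, 1, 0)), 79.06, tolerance = 1e-9)
  expect_equal(d_spacing(tet, c(5, 0, 1)), 14.61, tolerance = 1e-3)
  expect_equal(d_spacing(unit_cell(10, 10, 10), c(1, 0, 0)), 10)
  set.seed(13)
  for (i in 1:20) {
    cell <- random_cell()
    hkl <- matrix(sample(-5:5, 30, replace = TRUE), ncol = 3)
    hkl <- hkl[rowSums(abs(hkl)) > 0, , drop = FALSE]
    expect_equal(d_spacing(cell, hkl), d_spacing(cell, -hkl))
  }
  expect_error(d_spacing(tet, c(0, 0, 0)), "no d-spacing")
})

test_that("transform_cell scales volume by |det| and supports rational entries", {
  cell <- unit_cell(3.817, 25.567, 17.329, 88.70, 95.35, 90.20)
  expect_equal(as.numeric(transform_cell(cell, diag(3))), as.numeric(cell))
  P <- matrix(c(0, 0, 1, 0, 1, 0, 1, 0, 0), 3, byrow = TRUE)
  perm <- transform_cell(cell, P)
  expect_equal(sort(as.numeric(perm[1:3])), sort(as.numeric(cell[1:3])))
  expect_equal(cell_volume(perm), cell_volume(cell), tolerance = 1e-9)
  # centred <-> primitive: |det| = 1/2 halves the volume, 2 doubles it
  Mhalf <- rbind(c(0, 1, 0), c(0.5, 0.5, 0), c(0, 0, 1))
  prim <- transform_cell(published_cupc(), Mhalf)
  expect_equal(cell_volume(prim), cell_volume(published_cupc()) / 2,
               tolerance = 1e-9)
  set.seed(14)
  for (i in 1:20) {
    cell <- random_cell()
    M <- matrix(sample(-1:1, 9, replace = TRUE), 3)
    if (abs(det(M)) != 1) next
    expect_equal(cell_volume(transform_cell(cell, M)), cell_volume(cell),
                 tolerance = 1e-9)
  }
  expect_error(transform_cell(cell, matrix(0, 3, 3)), "singular")
})

test_that("cell equivalence is reduction-based and scale-aware", {
  a <- unit_cell(10, 12, 14, 85, 95, 100)
  expect_true(cells_equivalent(a, a))
  expect_equal(attr(cells_equivalent(a, a), "mismatch_len"), 0)
  perm <- transform_cell(a, matrix(c(0, 1, 0, 0, 0, 1, 1, 0, 0), 3,
                                   byrow = TRUE))
  expect_true(cells_equivalent(a, perm))
  # the determined primitive cell vs the known reduced primitive cell
  found <- unit_cell(3.82, 15.28, 15.60, 111.7, 93.1, 92.9)
  known <- unit_cell(3.833, 15.688, 15.688, 111.39, 92.84, 92.84)
  expect_true(cells_equivalent(found, known, tol_len = 0.03, tol_ang = 1.5))
  # a global scale enters only via the reported factor
  scaled <- unit_cell(10.3, 12.36, 14.42, 85, 95, 100)
  eq <- cells_equivalent(a, scaled)
  expect_true(eq)
  expect_equal(attr(eq, "scale"), 1.03, tolerance = 1e-6)
  expect_false(cells_equivalent(a, unit_cell(10, 12, 17, 85, 95, 100)))
})

test_that("cells serialize to records and CIF fragments", {
  cell <- unit_cell(17.685, 25.918, 3.833, 90, 95.05, 90)
  rec <- cell_to_record(cell)
  expect_equal(as.numeric(cell_from_record(rec)), as.numeric(cell))
  cif <- cell_to_cif(cell)
  expect_true(any(grepl("_cell_length_a\\s+17.685", cif)))
  expect_true(any(grepl("_cell_volume", cif)))
})

test_that("invalid cells and inputs are rejected with messages", {
  expect_error(unit_cell(-1, 10, 10), "positive")
  expect_error(unit_cell(10, 10, 10, 0, 90, 90), "between 0 and 180")
  # angle triple that cannot close into a 3D cell
  expect_error(unit_cell(10, 10, 10, 170, 100, 60), "positive definite")
})
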