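#' Create a unit cell
#'
#' A unit cell is described by six parameters: three axis lengths and three
#' inter-axial angles. Lengths are in ångström for a direct-space cell and in
#' reciprocal ångström (Å⁻¹) for a reciprocal-space cell; angles are always in
#' degrees. The metric must be positive definite (the cell must enclose a
#' positive volume).
#'
#' @param a,b,c Axis lengths (> 0).
#' @param alpha,beta,gamma Inter-axial angles in degrees, each in (0, 180).
#'   `alpha` is the angle between **b** and **c**, `beta` between **a** and
#'   **c**, `gamma` between **a** and **b**.
#' @param space `"direct"` (Å) or `"reciprocal"` (Å⁻¹).
#'
#' @return An object of class `unit_cell`: a named numeric vector
#'   `(a, b, c, alpha, beta, gamma)` with a `space` attribute.
#' @examples
#' unit_cell(17.685, 25.918, 3.8330, 90, 95.05, 90)
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90,
                      space = c("direct", "reciprocal")) {
  space <- arg_match(space)
  p <- c(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(p))) {
    abort("all six cell parameters must be finite numbers")
  }
  if (any(p[1:3] <= 0)) {
    abort("cell lengths must be positive")
  }
  if (any(p[4:6] <= 0 | p[4:6] >= 180)) {
    abort("cell angles must lie strictly between 0 and 180 degrees")
  }
  cell <- structure(p, class = "unit_cell", space = space)
  if (det(cell_metric(cell)) <= 0) {
    abort("cell metric is not positive definite (volume^2 <= 0)")
  }
  cell
}

#' Reciprocal-space cell constructor
#'
#' Convenience wrapper around [unit_cell()] with `space = "reciprocal"`.
#'
#' @param a_star,b_star,c_star Reciprocal axis lengths in Å⁻¹.
#' @param alpha_star,beta_star,gamma_star Reciprocal angles in degrees.
#' @return A `unit_cell` in reciprocal space.
#' @export
reciprocal_cell <- function(a_star, b_star, c_star,
                            alpha_star = 90, beta_star = 90, gamma_star = 90) {
  unit_cell(a_star, b_star, c_star, alpha_star, beta_star, gamma_star,
            space = "reciprocal")
}

is_unit_cell <- function(x) inherits(x, "unit_cell")

cell_space <- function(cell) attr(cell, "space") %||% "direct"

#' @export
print.unit_cell <- function(x, digits = 4, ...) {
  sp <- cell_space(x)
  unit <- if (sp == "direct") "Å" else "Å⁻¹"
  cat(sprintf("<unit_cell (%s)>\n", sp))
  cat(sprintf("  a = %.*f  b = %.*f  c = %.*f %s\n",
              digits, x[["a"]], digits, x[["b"]], digits, x[["c"]], unit))
  cat(sprintf("  alpha = %.*f  beta = %.*f  gamma = %.*f deg\n",
              digits, x[["alpha"]], digits, x[["beta"]], digits, x[["gamma"]]))
  if (sp == "direct") {
    cat(sprintf("  V = %.*f Å³\n", digits, cell_volume(x)))
  }
  invisible(x)
}

#' @method as_tibble unit_cell
#' @export
as_tibble.unit_cell <- function(x, ...) {
  tibble(a = x[["a"]], b = x[["b"]], c = x[["c"]],
         alpha = x[["alpha"]], beta = x[["beta"]], gamma = x[["gamma"]],
         volume = cell_volume(x), space = cell_space(x))
}

#' @method tidy unit_cell
#' @export
tidy.unit_cell <- function(x, ...) as_tibble.unit_cell(x)

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Metric tensor of a cell
#'
#' The 3x3 matrix of pairwise scalar products of the basis vectors,
#' G\[i, j\] = **v**\_i · **v**\_j.
#'
#' @param cell A `unit_cell`.
#' @return A symmetric 3x3 matrix (units: length squared).
#' @export
cell_metric <- function(cell) {
  l <- unclass(cell)[1:3]
  ang <- deg2rad(unclass(cell)[4:6])
  ca <- cos(ang[[1]]); cb <- cos(ang[[2]]); cg <- cos(ang[[3]])
  matrix(c(l[[1]]^2,           l[[1]] * l[[2]] * cg, l[[1]] * l[[3]] * cb,
           l[[1]] * l[[2]] * cg, l[[2]]^2,           l[[2]] * l[[3]] * ca,
           l[[1]] * l[[3]] * cb, l[[2]] * l[[3]] * ca, l[[3]]^2),
         nrow = 3, byrow = TRUE)
}

#' Cartesian basis-vector matrix of a cell
#'
#' Realizes the cell as three Cartesian row vectors with the fixed convention:
#' **a** along x, **b** in the x-y plane, right-handed. Only invariants
#' (lengths, angles, volume) are meaningful to callers.
#'
#' @param cell A `unit_cell`.
#' @return A 3x3 matrix whose rows are the basis vectors.
#' @export
cell_basis <- function(cell) {
  l <- unclass(cell)[1:3]
  ang <- deg2rad(unclass(cell)[4:6])
  ca <- cos(ang[[1]]); cb <- cos(ang[[2]])
  cg <- cos(ang[[3]]); sg <- sin(ang[[3]])
  bx <- l[[2]] * cg
  by <- l[[2]] * sg
  cx <- l[[3]] * cb
  cy <- l[[3]] * (ca - cb * cg) / sg
  cz2 <- l[[3]]^2 - cx^2 - cy^2
  if (cz2 <= 0) {
    abort("cell metric is not positive definite (volume^2 <= 0)")
  }
  matrix(c(l[[1]], 0, 0, bx, by, 0, cx, cy, sqrt(cz2)),
         nrow = 3, byrow = TRUE)
}

params_from_metric <- function(G, space = "direct") {
  l <- sqrt(diag(G))
  alpha <- rad2deg(acos(pmin(1, pmax(-1, G[2, 3] / (l[[2]] * l[[3]])))))
  beta  <- rad2deg(acos(pmin(1, pmax(-1, G[1, 3] / (l[[1]] * l[[3]])))))
  gamma <- rad2deg(acos(pmin(1, pmax(-1, G[1, 2] / (l[[1]] * l[[2]])))))
  unit_cell(l[[1]], l[[2]], l[[3]], alpha, beta, gamma, space = space)
}

cell_from_basis <- function(B, space = "direct") {
  params_from_metric(B %*% t(B), space = space)
}

#' Cell volume
#'
#' Volume enclosed by the three basis vectors, via the standard triclinic
#' formula (square root of the metric-tensor determinant).
#'
#' @param cell A `unit_cell`.
#' @return Volume in Å³ (direct cell) or Å⁻³ (reciprocal cell).
#' @examples
#' cell_volume(unit_cell(17.685, 25.918, 3.8330, 90, 95.05, 90)) # 1750.1
#' @export
cell_volume <- function(cell) {
  stopifnot(is_unit_cell(cell))
  d <- det(cell_metric(cell))
  if (d <= 0) abort("cell metric is not positive definite (volume^2 <= 0)")
  sqrt(d)
}

#' Reciprocal (dual) cell
#'
#' Converts a direct cell to its reciprocal counterpart or vice versa, using
#' the crystallographic convention without 2*pi factors, so that the volumes
#' satisfy V * V_star = 1 and applying the operation twice returns the
#' original cell.
#'
#' @param cell A `unit_cell` (either space).
#' @return The dual `unit_cell` with the opposite `space`.
#' @examples
#' reciprocal_of(unit_cell(10, 10, 10)) # cubic, a* = 0.1
#' @export
reciprocal_of <- function(cell) {
  stopifnot(is_unit_cell(cell))
  Gr <- solve(cell_metric(cell))
  out_space <- if (cell_space(cell) == "direct") "reciprocal" else "direct"
  params_from_metric(Gr, space = out_space)
}

#' Interplanar spacing d(hkl)
#'
#' d = 1 / |h **a*** + k **b*** + l **c***| for one or more reflections.
#'
#' @param cell A direct-space `unit_cell`.
#' @param hkl Integer triple, or a matrix / data frame with three columns
#'   (one reflection per row).
#' @return Numeric vector of d-spacings in Å.
#' @examples
#' d_spacing(unit_cell(79.06, 79.06, 38.22), c(5, 0, 1)) # 14.61
#' @export
d_spacing <- function(cell, hkl) {
  stopifnot(is_unit_cell(cell))
  if (is.data.frame(hkl)) hkl <- as.matrix(hkl)
  if (is.null(dim(hkl))) hkl <- matrix(hkl, nrow = 1)
  storage.mode(hkl) <- "double"
  if (ncol(hkl) != 3) abort("`hkl` must have three columns (h, k, l)")
  if (any(rowSums(abs(hkl)) == 0)) abort("hkl = (0, 0, 0) has no d-spacing")
  Gstar <- if (cell_space(cell) == "direct") {
    solve(cell_metric(cell))
  } else {
    cell_metric(cell)
  }
  g2 <- rowSums((hkl %*% Gstar) * hkl)
  1 / sqrt(g2)
}

#' Re-basis a cell with a transformation matrix
#'
#' The rows of `M` give the new basis vectors as combinations of the old
#' ones: new_i = sum_j M\[i, j\] old_j. Rational entries (for example 1/2 for
#' centred-to-primitive conversions) are supported; the volume scales by
#' |det(M)|.
#'
#' @param cell A `unit_cell`.
#' @param M A 3x3 numeric matrix with non-zero determinant.
#' @return The transformed `unit_cell` (same space).
#' @export
transform_cell <- function(cell, M) {
  stopifnot(is_unit_cell(cell))
  M <- as.matrix(M)
  if (!all(dim(M) == c(3, 3))) abort("`M` must be a 3x3 matrix")
  if (abs(det(M)) < 1e-12) abort("transformation matrix is singular")
  params_from_metric(M %*% cell_metric(cell) %*% t(M),
                     space = cell_space(cell))
}

#' Serialize and deserialize a cell
#'
#' `cell_to_record()` flattens a cell into a named list suitable for writing
#' as a key-value record; `cell_from_record()` rebuilds it. `cell_to_cif()`
#' renders a minimal cell-only CIF fragment.
#'
#' @param cell A `unit_cell`.
#' @param record A named list or vector with entries a, b, c, alpha, beta,
#'   gamma (and optionally space).
#' @return A named list, a `unit_cell`, or a character vector of CIF lines.
#' @export
cell_to_record <- function(cell) {
  stopifnot(is_unit_cell(cell))
  c(as.list(setNames(as.numeric(cell), names(unclass(cell)))),
    list(space = cell_space(cell)))
}

#' @rdname cell_to_record
#' @export
cell_from_record <- function(record) {
  record <- as.list(record)
  needed <- c("a", "b", "c", "alpha", "beta", "gamma")
  if (!all(needed %in% names(record))) {
    abort(paste("record must contain fields:", paste(needed, collapse = ", ")))
  }
  unit_cell(as.numeric(record$a), as.numeric(record$b), as.numeric(record$c),
            as.numeric(record$alpha), as.numeric(record$beta),
            as.numeric(record$gamma),
            space = record$space %||% "direct")
}

#' @rdname cell_to_record
#' @export
cell_to_cif <- function(cell) {
  stopifnot(is_unit_cell(cell))
  c("data_cell",
    sprintf("_cell_length_a    %.6f", cell[["a"]]),
    sprintf("_cell_length_b    %.6f", cell[["b"]]),
    sprintf("_cell_length_c    %.6f", cell[["c"]]),
    sprintf("_cell_angle_alpha %.6f", cell[["alpha"]]),
    sprintf("_cell_angle_beta  %.6f", cell[["beta"]]),
    sprintf("_cell_angle_gamma %.6f", cell[["gamma"]]),
    sprintf("_cell_volume      %.6f", cell_volume(cell)))
}

# all 48 signed permutation matrices (|det| = 1), computed once
signed_permutations <- function() {
  if (!is.null(.zc_cache$signed_perms)) return(.zc_cache$signed_perms)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  signs <- expand.grid(s1 = c(1, -1), s2 = c(1, -1), s3 = c(1, -1))
  out <- list()
  for (p in perms) {
    P0 <- diag(3)[p, , drop = FALSE]
    for (i in seq_len(nrow(signs))) {
      out[[length(out) + 1]] <- diag(as.numeric(signs[i, ])) %*% P0
    }
  }
  .zc_cache$signed_perms <- out
  out
}

#' Test whether two cells describe equivalent lattices
#'
#' Both cells are Delaunay-reduced and the reduced settings compared over all
#' signed axis permutations. Lengths are compared as ratios after removing a
#' common scale factor, so a global scale error (camera-constant error) does
#' not by itself break equivalence; the fitted scale is reported.
#'
#' @param cell_a,cell_b Direct-space `unit_cell`s.
#' @param tol_len Relative length tolerance (default 0.02).
#' @param tol_ang Angle tolerance in degrees (default 2).
#' @return A logical scalar with attributes `mismatch_len` (max relative
#'   length deviation after scaling), `mismatch_ang` (max angle deviation,
#'   deg) and `scale` (b-to-a length ratio), for the best-matching setting.
#' @examples
#' cells_equivalent(unit_cell(10, 10, 10), unit_cell(10, 10, 10))
#' @export
cells_equivalent <- function(cell_a, cell_b, tol_len = 0.02, tol_ang = 2) {
  stopifnot(is_unit_cell(cell_a), is_unit_cell(cell_b))
  Ba <- delaunay_reduce(cell_a)$basis
  Bb <- delaunay_reduce(cell_b)$basis
  bases_equivalent(Ba, Bb, tol_len, tol_ang)
}

# equivalence of two Delaunay-reduced bases over signed axis permutations;
# a cheap sorted-length screen avoids the 48-permutation scan when the
# lattices are clearly different
bases_equivalent <- function(Ba, Bb, tol_len = 0.02, tol_ang = 2) {
  la <- sqrt(rowSums(Ba^2))
  lb <- sqrt(rowSums(Bb^2))
  sa <- sort(la)
  sb <- sort(lb)
  s0 <- exp(mean(log(sb / sa)))
  if (max(abs(sb / (s0 * sa) - 1)) > 2 * tol_len + 0.02) {
    return(structure(FALSE, mismatch_len = Inf, mismatch_ang = Inf,
                     scale = s0))
  }
  Ga <- Ba %*% t(Ba)
  anga <- c(angle_deg(Ga, 2, 3, la), angle_deg(Ga, 1, 3, la),
            angle_deg(Ga, 1, 2, la))
  best <- list(len = Inf, ang = Inf, scale = NA_real_)
  for (P in signed_permutations()) {
    Bp <- P %*% Bb
    lp <- sqrt(rowSums(Bp^2))
    Gp <- Bp %*% t(Bp)
    angp <- c(angle_deg(Gp, 2, 3, lp), angle_deg(Gp, 1, 3, lp),
              angle_deg(Gp, 1, 2, lp))
    s <- exp(mean(log(lp / la)))
    mlen <- max(abs(lp / (s * la) - 1))
    mang <- max(abs(angp - anga))
    if (mlen + mang / 90 < best$len + best$ang / 90) {
      best <- list(len = mlen, ang = mang, scale = s)
    }
  }
  structure(best$len <= tol_len && best$ang <= tol_ang,
            mismatch_len = best$len, mismatch_ang = best$ang,
            scale = best$scale)
}

angle_deg <- function(G, i, j, l) {
  rad2deg(acos(pmin(1, pmax(-1, G[i, j] / (l[[i]] * l[[j]])))))
}
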