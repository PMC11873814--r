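#' Delaunay reduction of a unit cell
#'
#' Iterates the classical Delaunay (Selling) transformation on the four
#' vectors \{**a**, **b**, **c**, **d** = -(**a**+**b**+**c**)\} until all six
#' pairwise scalar products are non-positive (within tolerance). The reduced
#' basis is assembled from the three shortest independent vectors among the
#' four Delaunay vectors and their pairwise sums, sign-normalized to the
#' all-obtuse setting and ordered by increasing length.
#'
#' @param cell A direct-space `unit_cell`.
#' @param tol Convergence tolerance on the scalar products, relative to the
#'   largest squared vector length (default 1e-10).
#' @param max_iter Iteration safeguard (default 10000).
#' @return An object of class `delaunay_reduced`: a list with elements
#'   `cell` (the reduced `unit_cell`), `basis` (3x3 Cartesian rows),
#'   `transform` (integer matrix from the input basis to the reduced basis,
#'   |det| = 1), and `products` (the six pairwise scalar products of the
#'   final Delaunay vectors, Å²).
#' @examples
#' delaunay_reduce(unit_cell(17.685, 25.918, 3.8330, 90, 95.05, 90))$cell
#' @export
delaunay_reduce <- function(cell, tol = 1e-10, max_iter = 10000) {
  stopifnot(is_unit_cell(cell))
  B <- cell_basis(cell)
  # integer coefficients of the four Delaunay vectors in the input basis
  Co <- rbind(diag(3), c(-1, -1, -1))
  V <- Co %*% B
  pairs <- list(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (it in seq_len(max_iter)) {
    S <- V %*% t(V)
    prods <- vapply(pairs, function(p) S[p[[1]], p[[2]]], numeric(1))
    eps <- tol * max(diag(S))
    if (all(prods <= eps)) {
      return(finish_delaunay(V, Co, B, prods))
    }
    p <- pairs[[which.max(prods)]]
    i <- p[[1]]; j <- p[[2]]
    others <- setdiff(1:4, c(i, j))
    # Selling step: negate v_i, add the old v_i to the two vectors outside
    # the offending pair; the quadruple keeps zero sum and the sum of squared
    # lengths drops by 2 v_i . v_j
    vi <- V[i, ]; ci <- Co[i, ]
    V[others[[1]], ] <- V[others[[1]], ] + vi
    V[others[[2]], ] <- V[others[[2]], ] + vi
    Co[others[[1]], ] <- Co[others[[1]], ] + ci
    Co[others[[2]], ] <- Co[others[[2]], ] + ci
    V[i, ] <- -vi
    Co[i, ] <- -ci
  }
  abort("Delaunay reduction did not converge")
}

finish_delaunay <- function(V, Co, B, prods) {
  # candidate short vectors: the four Delaunay vectors and pairwise sums
  sums <- rbind(V[1, ] + V[2, ], V[1, ] + V[3, ], V[1, ] + V[4, ])
  csums <- rbind(Co[1, ] + Co[2, ], Co[1, ] + Co[3, ], Co[1, ] + Co[4, ])
  W <- rbind(V, sums)
  Cw <- rbind(Co, csums)
  ord <- order(rowSums(W^2))
  W <- W[ord, , drop = FALSE]
  Cw <- Cw[ord, , drop = FALSE]
  # three shortest forming a basis (their integer transform has |det| = 1)
  pick <- c(1L, 2L)
  if (abs(det(rbind(Cw[1, ], Cw[2, ], Cw[3, ]))) < 0.5) {
    # first three coplanar; second vector slot may need replacing too
    if (max(abs(Cw[2, ] + Cw[1, ])) == 0 || max(abs(Cw[2, ] - Cw[1, ])) == 0) {
      pick <- c(1L, 3L)
    }
  }
  third <- NULL
  for (k in seq_len(nrow(Cw))) {
    if (k %in% pick) next
    if (abs(det(rbind(Cw[pick[[1]], ], Cw[pick[[2]], ], Cw[k, ]))) > 0.5) {
      third <- k
      break
    }
  }
  if (is.null(third)) abort("Delaunay reduction produced a degenerate basis")
  idx <- c(pick, third)
  Bred <- W[idx, , drop = FALSE]
  Cred <- Cw[idx, , drop = FALSE]
  # sign-normalize to the all-obtuse setting where possible
  G <- Bred %*% t(Bred)
  for (i in 2:3) {
    if (sum(G[i, seq_len(i - 1)] > 0) > sum(G[i, seq_len(i - 1)] < 0)) {
      Bred[i, ] <- -Bred[i, ]
      Cred[i, ] <- -Cred[i, ]
      G <- Bred %*% t(Bred)
    }
  }
  ordl <- order(rowSums(Bred^2))
  Bred <- Bred[ordl, , drop = FALSE]
  Cred <- Cred[ordl, , drop = FALSE]
  if (det(Bred) < 0) {
    Bred <- -Bred
    Cred <- -Cred
  }
  structure(
    list(cell = cell_from_basis(Bred),
         basis = Bred,
         transform = round(Cred),
         products = prods),
    class = "delaunay_reduced")
}

#' @export
print.delaunay_reduced <- function(x, ...) {
  cat("<delaunay_reduced>\n")
  print(x$cell)
  cat("  max pairwise scalar product:",
      format(max(x$products), digits = 3), "Å²\n")
  invisible(x)
}

#' @method tidy delaunay_reduced
#' @export
tidy.delaunay_reduced <- function(x, ...) as_tibble.unit_cell(x$cell)

# catalogue of integer transformation matrices with determinant 1..4, used
# to propose conventional (possibly centred) supercells of a reduced
# primitive cell. Row vectors have entries up to |2| with L1 norm <= 3,
# which covers every standard primitive-to-centred conversion (e.g. the
# C-centred monoclinic axis 2p2 - p1, the F/I cubic and R hexagonal
# combinations) relative to a reduced basis.
transform_catalogue <- function() {
  if (!is.null(.zc_cache$tcat)) return(.zc_cache$tcat)
  vecs <- as.matrix(expand.grid(h = -2:2, k = -2:2, l = -2:2))
  vecs <- vecs[rowSums(abs(vecs)) > 0 & rowSums(abs(vecs)) <= 4, ,
               drop = FALSE]
  n <- nrow(vecs)
  idx <- as.matrix(expand.grid(i = seq_len(n), j = seq_len(n), k = seq_len(n)))
  r1 <- vecs[idx[, 1], , drop = FALSE]
  r2 <- vecs[idx[, 2], , drop = FALSE]
  r3 <- vecs[idx[, 3], , drop = FALSE]
  dets <- r1[, 1] * (r2[, 2] * r3[, 3] - r2[, 3] * r3[, 2]) -
    r1[, 2] * (r2[, 1] * r3[, 3] - r2[, 3] * r3[, 1]) +
    r1[, 3] * (r2[, 1] * r3[, 2] - r2[, 2] * r3[, 1])
  keep <- dets >= 1 & dets <= 4
  .zc_cache$tcat <- list(r1 = r1[keep, , drop = FALSE],
                         r2 = r2[keep, , drop = FALSE],
                         r3 = r3[keep, , drop = FALSE],
                         det = dets[keep])
  .zc_cache$tcat
}

lattice_system_rank <- c(triclinic = 1, monoclinic = 2, orthorhombic = 3,
                         rhombohedral = 4, tetragonal = 5, hexagonal = 6,
                         cubic = 7)

centring_symbol <- function(M) {
  # cosets of the primitive lattice in the supercell spanned by rows of M
  n <- round(abs(det(M)))
  if (n == 1) return("P")
  # conventional rows C = M P, so a primitive vector x = c P has fractional
  # coordinates c %*% Minv in the conventional basis
  Minv <- solve(M)
  combos <- as.matrix(expand.grid(0:3, 0:3, 0:3))
  fr <- combos %*% Minv
  fr <- round(fr %% 1, 6) %% 1
  fr <- unique(fr[rowSums(fr) > 1e-6, , drop = FALSE])
  key <- apply(fr, 1, function(r) paste(sprintf("%.3f", r), collapse = ","))
  key <- sort(unique(key))
  sig <- paste(key, collapse = ";")
  known <- c("0.000,0.500,0.500" = "A",
             "0.500,0.000,0.500" = "B",
             "0.500,0.500,0.000" = "C",
             "0.500,0.500,0.500" = "I")
  if (length(key) == 1 && key %in% names(known)) return(unname(known[key]))
  if (length(key) == 3 &&
      setequal(key, c("0.000,0.500,0.500", "0.500,0.000,0.500",
                      "0.500,0.500,0.000"))) {
    return("F")
  }
  if (length(key) == 2 &&
      (setequal(key, c("0.333,0.667,0.667", "0.667,0.333,0.333")) ||
       setequal(key, c("0.333,0.333,0.667", "0.667,0.667,0.333")) ||
       setequal(key, c("0.333,0.667,0.333", "0.667,0.333,0.667")))) {
    return("R")
  }
  NA_character_
}

centring_valid <- function(system, symbol, det) {
  if (is.na(symbol)) return(FALSE)
  if (symbol == "P") return(det == 1)
  switch(system,
         triclinic = FALSE,
         monoclinic = symbol %in% c("A", "B", "C", "I") && det == 2,
         orthorhombic = (symbol %in% c("A", "B", "C", "I") && det == 2) ||
           (symbol == "F" && det == 4),
         tetragonal = symbol == "I" && det == 2,
         hexagonal = symbol == "R" && det == 3,
         rhombohedral = FALSE,
         cubic = (symbol == "I" && det == 2) || (symbol == "F" && det == 4),
         FALSE)
}

#' Conventional (possibly centred) setting of a reduced cell
#'
#' Tests candidate re-basing transformations with determinants 1-4 against
#' the lattice systems and returns the setting whose conventional cell best
#' matches a system within tolerance, preferring higher symmetry, then a
#' smaller conventional volume. Angles are reported as computed from the
#' input lattice, never snapped to special values. Monoclinic cells are
#' returned b-unique with obtuse beta, and an A-centred monoclinic setting is
#' permuted to the C-centred one.
#'
#' @param reduced A `delaunay_reduced` object (or a `unit_cell`, which is
#'   reduced first).
#' @param tol_ang Angle tolerance in degrees for recognizing special angles
#'   (default 2).
#' @param tol_len Relative length tolerance for recognizing equal axes
#'   (default 0.02).
#' @return An object of class `conventional_cell`: a list with `cell`,
#'   `centring` (P/A/B/C/I/F/R), `system`, `transform` (integer matrix from
#'   the reduced basis), and `volume_ratio` (conventional / primitive).
#' @export
conventional_setting <- function(reduced, tol_ang = 2, tol_len = 0.02) {
  if (is_unit_cell(reduced)) reduced <- delaunay_reduce(reduced)
  stopifnot(inherits(reduced, "delaunay_reduced"))
  B <- reduced$basis
  G <- B %*% t(B)
  cat_ <- transform_catalogue()
  r1 <- cat_$r1; r2 <- cat_$r2; r3 <- cat_$r3
  t1 <- r1 %*% G; t2 <- r2 %*% G; t3 <- r3 %*% G
  g11 <- rowSums(t1 * r1); g22 <- rowSums(t2 * r2); g33 <- rowSums(t3 * r3)
  g12 <- rowSums(t1 * r2); g13 <- rowSums(t1 * r3); g23 <- rowSums(t2 * r3)
  la <- sqrt(g11); lb <- sqrt(g22); lc <- sqrt(g33)
  al <- rad2deg(acos(pmin(1, pmax(-1, g23 / (lb * lc)))))
  be <- rad2deg(acos(pmin(1, pmax(-1, g13 / (la * lc)))))
  ga <- rad2deg(acos(pmin(1, pmax(-1, g12 / (la * lb)))))
  a90 <- abs(al - 90) <= tol_ang
  b90 <- abs(be - 90) <= tol_ang
  g90 <- abs(ga - 90) <= tol_ang
  ab_eq <- abs(la - lb) / pmax(la, lb) <= tol_len
  bc_eq <- abs(lb - lc) / pmax(lb, lc) <= tol_len
  all90 <- a90 & b90 & g90
  ang_eq <- abs(al - be) <= tol_ang & abs(be - ga) <= tol_ang
  system <- rep("triclinic", length(la))
  system[a90 & g90] <- "monoclinic"
  system[all90] <- "orthorhombic"
  system[ab_eq & bc_eq & ang_eq & !all90] <- "rhombohedral"
  system[all90 & ab_eq] <- "tetragonal"
  system[ab_eq & a90 & b90 & abs(ga - 120) <= tol_ang] <- "hexagonal"
  system[all90 & ab_eq & bc_eq] <- "cubic"
  # degenerate slivers (a nearly collinear re-basing can still show two
  # 90-degree angles) are not acceptable conventional settings
  shape_ok <- al >= 55 & al <= 125 & be >= 55 & be <= 125 &
    ga >= 55 & ga <= 125
  rank_ <- lattice_system_rank[system]
  angdev <- abs(al - 90) + abs(be - 90) + abs(ga - 90)
  ord <- order(-rank_, cat_$det, angdev)
  for (i in ord) {
    if (system[[i]] == "triclinic" && cat_$det[[i]] > 1) next
    if (!shape_ok[[i]] && system[[i]] != "triclinic") next
    M <- rbind(r1[i, ], r2[i, ], r3[i, ])
    symbol <- centring_symbol(M)
    if (!centring_valid(system[[i]], symbol, cat_$det[[i]]) &&
        !(system[[i]] == "triclinic" && identical(symbol, "P"))) {
      next
    }
    res <- list(M = M, symbol = symbol, system = system[[i]],
                det = cat_$det[[i]])
    return(standardize_conventional(res, B, reduced))
  }
  # unreachable: identity (P, triclinic) is always in the catalogue
  abort("no conventional setting found")
}

standardize_conventional <- function(res, B, reduced) {
  M <- res$M
  symbol <- res$symbol
  system <- res$system
  if (system == "monoclinic") {
    # bring to b-unique (the classification already guarantees alpha and
    # gamma near 90); convert A centring to C by swapping a and c
    if (symbol == "A") {
      M <- matrix(c(0, 0, 1, 0, 1, 0, 1, 0, 0), 3, byrow = TRUE) %*% M
      symbol <- "C"
    }
    if (symbol == "B") {
      # B-centred b-unique monoclinic reduces to a smaller primitive cell;
      # keep the symbol as computed (callers may re-reduce)
    }
    Bc <- M %*% B
    cellc <- cell_from_basis(Bc)
    if (cellc[["beta"]] < 90) {
      M <- diag(c(-1, 1, 1)) %*% M
    }
  }
  Bc <- M %*% B
  cellc <- cell_from_basis(Bc)
  structure(
    list(cell = cellc, centring = symbol, system = system,
         transform = M, volume_ratio = res$det,
         reduced = reduced),
    class = "conventional_cell")
}

#' @export
print.conventional_cell <- function(x, ...) {
  cat(sprintf("<conventional_cell> %s %s (volume ratio %d)\n",
              x$centring, x$system, x$volume_ratio))
  print(x$cell)
  invisible(x)
}

#' @method tidy conventional_cell
#' @export
tidy.conventional_cell <- function(x, ...) {
  dplyr::mutate(as_tibble.unit_cell(x$cell),
                centring = x$centring, system = x$system,
                volume_ratio = x$volume_ratio)
}
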