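with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate one zonal pattern from a known cell
#'
#' Computes the reduced 2D net of zone \[uvw\] of `cell` (respecting the
#' centring reflection condition) and emits the descriptor (d1, d2, phi)
#' with optional noise: multiplicative Gaussian on each d-spacing
#' (relative sigma `sigma_d`) and additive Gaussian on the angle
#' (`sigma_phi` degrees).
#'
#' @param cell A direct-space `unit_cell`.
#' @param uvw Coprime zone axis.
#' @param centring Bravais centring symbol (default P).
#' @param sigma_d Relative length noise (default 0).
#' @param sigma_phi Absolute angle noise in degrees (default 0).
#' @param seed Optional seed for reproducible noise (RNG state restored).
#' @return A one-row pattern tibble (`id`, `d1`, `d2`, `phi`, `u`, `v`, `w`).
#' @examples
#' simulate_zone_pattern(unit_cell(10, 10, 10), c(0, 0, 1))
#' @export
simulate_zone_pattern <- function(cell, uvw, centring = "P", sigma_d = 0,
                                  sigma_phi = 0, seed = NULL) {
  if (sigma_d < 0 || sigma_phi < 0) abort("noise sigmas must be >= 0")
  net <- zone_net(cell, uvw, centring = centring)
  with_seed(seed, {
    d1 <- net$d1 * (1 + sigma_d * rnorm(1))
    d2 <- net$d2 * (1 + sigma_d * rnorm(1))
    phi <- net$phi + sigma_phi * rnorm(1)
    phi <- min(max(phi, 1e-3), 180 - 1e-3)
    tibble(id = paste(uvw, collapse = ""), d1 = d1, d2 = d2, phi = phi,
           u = net$u, v = net$v, w = net$w)
  })
}

#' Are zone axes coplanar?
#'
#' TRUE when every triple of zone-index vectors has zero determinant, i.e.
#' all zones share a common reciprocal-lattice row (a Vainshtein tilt
#' series). Such a set cannot fix a 3D lattice on its own.
#'
#' @param zones An n x 3 matrix or data frame of integer zone axes.
#' @return Logical scalar.
#' @examples
#' zones_coplanar(rbind(c(5, 0, 6), c(1, 0, 5), c(2, 0, 7))) # TRUE
#' @export
zones_coplanar <- function(zones) {
  Z <- as.matrix(as.data.frame(zones))
  storage.mode(Z) <- "double"
  if (nrow(Z) < 2) abort("need at least 2 zones")
  if (nrow(Z) == 2) return(TRUE)
  combs <- combn(nrow(Z), 3)
  all(apply(combs, 2, function(ix) abs(det(Z[ix, ])) < 0.5))
}

#' Simulate a zonal-pattern dataset
#'
#' Draws zones from [enumerate_zones()] (preferring low |u|+|v|+|w|),
#' optionally resampling until the zone set is non-coplanar, and simulates
#' one pattern per zone. The generating cell and zone list (the ground
#' truth) are attached to the result.
#'
#' @param cell Generating direct-space `unit_cell`.
#' @param n_zones Number of zones to draw (ignored when `zones` is given).
#' @param zones Optional explicit list/matrix of zone axes.
#' @param max_index Zone enumeration bound for drawing (default 3).
#' @param centring Bravais centring symbol (default P).
#' @param sigma_d,sigma_phi Noise levels as in [simulate_zone_pattern()].
#' @param ensure_noncoplanar Resample until [zones_coplanar()] is FALSE
#'   (default TRUE; requires >= 3 zones).
#' @param seed Seed fixing all randomness of the draw and the noise.
#' @return A pattern tibble (canonicalized) with attributes `cell` (the
#'   generator) and `zones` (integer matrix of the generating zone axes).
#' @export
simulate_patterns <- function(cell, n_zones = 5, zones = NULL, max_index = 3,
                              centring = "P", sigma_d = 0, sigma_phi = 0,
                              ensure_noncoplanar = TRUE, seed = NULL) {
  stopifnot(is_unit_cell(cell))
  with_seed(seed, {
    if (is.null(zones)) {
      pool <- enumerate_zones(max_index)
      if (n_zones > nrow(pool)) abort("not enough zones below `max_index`")
      if (ensure_noncoplanar && n_zones < 3) {
        abort("non-coplanarity needs at least 3 zones")
      }
      wt <- 1 / rowSums(abs(as.matrix(pool)))^2
      for (try in 1:200) {
        pick <- sample(nrow(pool), n_zones, prob = wt)
        Z <- as.matrix(pool[pick, ])
        if (!ensure_noncoplanar || !zones_coplanar(Z)) break
        Z <- NULL
      }
      if (is.null(Z)) abort("could not draw a non-coplanar zone set")
    } else {
      Z <- as.matrix(as.data.frame(zones))
      if (ensure_noncoplanar && zones_coplanar(Z)) {
        abort("supplied zones are coplanar but `ensure_noncoplanar` is TRUE")
      }
    }
    pats <- bind_rows(lapply(seq_len(nrow(Z)), function(i) {
      simulate_zone_pattern(cell, Z[i, ], centring = centring,
                            sigma_d = sigma_d, sigma_phi = sigma_phi)
    }))
    pats$id <- seq_len(nrow(pats))
    out <- as_zone_patterns(pats[c("id", "d1", "d2", "phi")])
    attr(out, "cell") <- cell
    attr(out, "zones") <- Z
    out
  })
}
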