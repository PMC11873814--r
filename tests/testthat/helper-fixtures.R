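# fixtures and independent brute-force oracles used across the suite

# random triclinic cell with moderate obliquity (retry until the metric is
# positive definite)
random_cell <- function(len_range = c(6, 14), ang_range = c(78, 102)) {
  repeat {
    cell <- try(unit_cell(runif(1, len_range[1], len_range[2]),
                          runif(1, len_range[1], len_range[2]),
                          runif(1, len_range[1], len_range[2]),
                          runif(1, ang_range[1], ang_range[2]),
                          runif(1, ang_range[1], ang_range[2]),
                          runif(1, ang_range[1], ang_range[2])),
                silent = TRUE)
    if (!inherits(cell, "try-error")) return(cell)
  }
}

# brute-force oracle for zone_net: scan all hkl with |h|,|k|,|l| <= hmax in
# the zone (and passing the centring condition), return the canonical
# invariants of the shortest non-collinear pair
bf_zone_net <- function(cell, uvw, centring = "P", hmax = 6) {
  Gstar <- solve(cell_metric(cell))
  g <- expand.grid(h = -hmax:hmax, k = -hmax:hmax, l = -hmax:hmax)
  g <- as.matrix(g[rowSums(abs(g)) > 0, ])
  g <- g[g %*% matrix(as.numeric(uvw), ncol = 1) == 0, , drop = FALSE]
  allowed <- switch(centring,
                    P = rep(TRUE, nrow(g)),
                    A = (g[, 2] + g[, 3]) %% 2 == 0,
                    B = (g[, 1] + g[, 3]) %% 2 == 0,
                    C = (g[, 1] + g[, 2]) %% 2 == 0,
                    I = rowSums(g) %% 2 == 0,
                    F = (g[, 1] + g[, 2]) %% 2 == 0 &
                      (g[, 1] + g[, 3]) %% 2 == 0,
                    R = (-g[, 1] + g[, 2] + g[, 3]) %% 3 == 0)
  g <- g[allowed, , drop = FALSE]
  len2 <- rowSums((g %*% Gstar) * g)
  ord <- order(len2)
  g <- g[ord, , drop = FALSE]
  len2 <- len2[ord]
  v1 <- g[1, ]
  for (i in 2:nrow(g)) {
    cr <- c(v1[2] * g[i, 3] - v1[3] * g[i, 2],
            v1[3] * g[i, 1] - v1[1] * g[i, 3],
            v1[1] * g[i, 2] - v1[2] * g[i, 1])
    if (any(cr != 0)) {
      v2 <- g[i, ]
      break
    }
  }
  g1 <- unname(sqrt(len2[1]))
  g2 <- unname(sqrt(sum((v2 %*% Gstar) * v2)))
  cosphi <- abs(sum((v1 %*% Gstar) * v2)) / (g1 * g2)
  list(g1 = g1, g2 = g2, phi = acos(pmin(1, cosphi)) * 180 / pi)
}

# brute-force shortest lattice vectors (squared lengths) over small
# coefficient combinations
bf_shortest_lengths <- function(cell, n = 3, cmax = 4) {
  B <- cell_basis(cell)
  co <- as.matrix(expand.grid(-cmax:cmax, -cmax:cmax, -cmax:cmax))
  co <- co[rowSums(abs(co)) > 0, ]
  len2 <- unname(rowSums((co %*% B)^2))
  sort(len2)[seq_len(2 * n)] # each vector appears as +/- pair
}

# greedy successive minima: shortest vectors that are mutually independent
bf_successive_minima <- function(cell, cmax = 5) {
  B <- cell_basis(cell)
  co <- as.matrix(expand.grid(-cmax:cmax, -cmax:cmax, -cmax:cmax))
  co <- co[rowSums(abs(co)) > 0, ]
  len2 <- rowSums((co %*% B)^2)
  ord <- order(len2)
  picked <- matrix(numeric(0), 0, 3)
  lens <- numeric(0)
  for (i in ord) {
    v <- co[i, ]
    if (nrow(picked) == 0) {
      picked <- rbind(picked, v); lens <- c(lens, len2[[i]])
    } else if (nrow(picked) == 1) {
      if (any(abs(picked[1, 2] * v[3] - picked[1, 3] * v[2]) +
                abs(picked[1, 3] * v[1] - picked[1, 1] * v[3]) +
                abs(picked[1, 1] * v[2] - picked[1, 2] * v[1]) > 0)) {
        picked <- rbind(picked, v); lens <- c(lens, len2[[i]])
      }
    } else {
      if (abs(det(rbind(picked, v))) > 0.5) {
        picked <- rbind(picked, v); lens <- c(lens, len2[[i]])
        break
      }
    }
  }
  unname(lens)
}

# exact synthetic net of an oblique 2D lattice, for the peak-list tests
make_net_peaks <- function(g1 = 0.1, g2 = 0.15, phi = 75, n = 3) {
  v1 <- c(g1, 0)
  v2 <- g2 * c(cos(phi * pi / 180), sin(phi * pi / 180))
  idx <- expand.grid(i = -n:n, j = -n:n)
  tibble::tibble(x = idx$i * v1[1] + idx$j * v2[1],
                 y = idx$i * v1[2] + idx$j * v2[2])
}

published_cupc <- function() unit_cell(17.685, 25.918, 3.8330, 90, 95.05, 90)
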