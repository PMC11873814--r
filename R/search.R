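#' Volume layers with constant fractional increment
#'
#' Generates the non-equidistant volume grid V_1 = V_min,
#' V_(i+1) = V_i (1 + f), stopping at the first value reaching V_max
#' (included).
#'
#' @param v_min,v_max Direct-cell volume range in Å³ (0 < v_min <= v_max).
#' @param f Fractional increment (default 0.025).
#' @return Numeric vector of layer volumes.
#' @examples
#' volume_layers(763, 1000, 0.025) # 12 layers, last 1001.1
#' @export
volume_layers <- function(v_min, v_max, f = 0.025) {
  if (v_min <= 0 || v_max < v_min || f <= 0) {
    abort("need 0 < v_min <= v_max and f > 0")
  }
  out <- numeric()
  v <- v_min
  repeat {
    out <- c(out, v)
    if (v >= v_max) break
    v <- v * (1 + f)
  }
  out
}

#' Scan frame of the initial zone
#'
#' The initial pattern is taken to define zone \[001\] of one setting of the
#' unknown cell, fixing three reciprocal parameters: a* = g_short,
#' b* = g_long and gamma* = phi (canonical). The remaining axis **c*** is
#' scanned as c* = xi a* + eta b* + zeta c0*, with c0* the unit normal of
#' the pattern plane and zeta set by the layer volume.
#'
#' @param pattern One canonicalized pattern row (see [as_zone_patterns()]).
#' @return A list of class `scan_frame`: pattern id, `g1`, `g2` (Å⁻¹),
#'   `phi` (deg), in-plane basis row vectors `a_vec`, `b_vec`, reciprocal
#'   mesh area `A_star` (Å⁻²) and direct mesh area `A` = 1/A_star (Å²),
#'   and the effective symmetry label.
#' @export
scan_frame <- function(pattern) {
  if (!"g_short" %in% names(pattern)) {
    pattern <- as_zone_patterns(pattern)
  }
  g1 <- pattern$g_short[[1]]
  g2 <- pattern$g_long[[1]]
  phi <- pattern$phi_can[[1]]
  phir <- deg2rad(phi)
  A_star <- g1 * g2 * sin(phir)
  structure(
    list(id = pattern$id[[1]], g1 = g1, g2 = g2, phi = phi,
         a_vec = c(g1, 0), b_vec = c(g2 * cos(phir), g2 * sin(phir)),
         A_star = A_star, A = 1 / A_star,
         symmetry = pattern$symmetry_eff[[1]] %||% "p1"),
    class = "scan_frame")
}

#' Default minimal search volume
#'
#' The smallest cell compatible with the initial zone: its base area (the
#' direct mesh area of the pattern) times a minimal interlayer spacing.
#'
#' @param frame A [scan_frame()].
#' @param h_min Minimal interlayer spacing in Å (default 3.4).
#' @return V_min in Å³.
#' @export
vmin_default <- function(frame, h_min = 3.4) {
  if (h_min <= 0) abort("`h_min` must be positive")
  frame$A * h_min
}

#' Candidate c* grid for a symmetry class
#'
#' Enumerates scan positions (xi, eta) of the **c*** in-plane component, in
#' fractional coordinates of the pattern basis, for every volume layer.
#' The symmetry of the initial pattern restricts the scan: `p1` is a full 2D
#' grid per layer (eta >= 0; inversion halves the domain); `pmm` restricts
#' to the four mirror lines xi = 0, xi = 1/2, eta = 0, eta = 1/2; `cmm` to
#' three mirror planes expressed in the rectangular frame of the centred net
#' (both settings of cmm are handled); `p4` and `p6` reduce to two points
#' per layer, (0,0) with (1/2,1/2) or (1/3,1/3) respectively.
#'
#' The Cartesian step within a layer is `step` times the layer's resolution
#' scale, min(zeta(V), g1, g2) with zeta = 1/(A* V) the interlayer spacing
#' of that volume: scanning a short c* against long pattern vectors (or the
#' reverse) then still samples finely enough for the acceptance gate.
#'
#' @param frame A [scan_frame()].
#' @param layers Volume layers from [volume_layers()].
#' @param step Grid step as a fraction of the layer resolution scale
#'   (default 1/12).
#' @param symmetry Override the frame's symmetry label (optional).
#' @return A tibble with columns `xi`, `eta`, `V`, `plane` (scan-plane
#'   label), `coord` (free coordinate within the plane) and the plane
#'   parametrization (`org_*`, `dir_*`).
#' @export
candidate_grid <- function(frame, layers, step = 1 / 12, symmetry = NULL) {
  if (step <= 0 || step > 0.5) abort("`step` must be in (0, 0.5]")
  symmetry <- symmetry %||% frame$symmetry
  if (!symmetry %in% pattern_symmetry_levels) {
    abort(paste0("unknown symmetry label: ", symmetry))
  }
  line_pts <- function(org, dir, coords, plane) {
    tibble(xi = org[[1]] + coords * dir[[1]],
           eta = org[[2]] + coords * dir[[2]],
           plane = plane, coord = coords,
           org_xi = org[[1]], org_eta = org[[2]],
           dir_xi = dir[[1]], dir_eta = dir[[2]])
  }
  per_layer <- lapply(layers, function(V) {
    zeta <- 1 / (frame$A_star * V)
    s_c <- step * min(zeta, frame$g1, frame$g2)
    fs_a <- min(s_c / frame$g1, 0.25) # fractional steps along the two axes
    fs_b <- min(s_c / frame$g2, 0.25)
    half_a <- seq(0, 0.5, by = fs_a)
    half_b <- seq(0, 0.5, by = fs_b)
    pts <- switch(
      symmetry,
      p1 = {
        xi <- seq(-0.5, 0.5 - fs_a, by = fs_a)
        g <- expand.grid(xi = xi, eta = half_b)
        tibble(xi = g$xi, eta = g$eta, plane = "full", coord = NA_real_,
               org_xi = NA_real_, org_eta = NA_real_,
               dir_xi = NA_real_, dir_eta = NA_real_)
      },
      pmm = bind_rows(
        line_pts(c(0, 0), c(0, 1), half_b, "x0"),
        line_pts(c(0.5, 0), c(0, 1), half_b, "xh"),
        line_pts(c(0, 0), c(1, 0), half_a, "y0"),
        line_pts(c(0, 0.5), c(1, 0), half_a, "yh")),
      cmm = cmm_grid(frame, s_c),
      p4 = bind_rows(
        line_pts(c(0, 0), c(0, 0), 0, "origin"),
        line_pts(c(0.5, 0.5), c(0, 0), 0, "centre")),
      p6 = bind_rows(
        line_pts(c(0, 0), c(0, 0), 0, "origin"),
        line_pts(c(1 / 3, 1 / 3), c(0, 0), 0, "third")))
    pts <- distinct(pts, .data$xi, .data$eta, .keep_all = TRUE)
    pts$V <- V
    pts
  })
  out <- bind_rows(per_layer)
  out[c("xi", "eta", "V", "plane", "coord", "org_xi", "org_eta",
        "dir_xi", "dir_eta")]
}

# rectangular frame of a cmm net: returns the two rectangle axis vectors
# (Cartesian rows) for either setting of the centred net
cmm_rectangle <- function(frame) {
  g1 <- frame$g1; g2 <- frame$g2
  a_vec <- frame$a_vec; b_vec <- frame$b_vec
  if (abs(g1 - g2) / g2 <= 0.05) {
    # equal-length diagonal setting: rectangle axes are the diagonals
    list(u = a_vec + b_vec, v = a_vec - b_vec)
  } else {
    # centred-rectangular setting: g_short is one rectangle axis,
    # the other is 2 g_long - g_short
    list(u = a_vec, v = 2 * b_vec - a_vec)
  }
}

cmm_grid <- function(frame, s_c) {
  rect <- cmm_rectangle(frame)
  M <- cbind(frame$a_vec, frame$b_vec) # columns: pattern basis
  frac <- function(p) solve(M, p) # Cartesian in-plane point -> (xi, eta)
  u_f <- frac(rect$u)
  v_f <- frac(rect$v)
  fs_u <- min(s_c / sqrt(sum(rect$u^2)), 0.25)
  fs_v <- min(s_c / sqrt(sum(rect$v^2)), 0.25)
  line_pts <- function(org, dir, coords, plane) {
    tibble(xi = org[[1]] + coords * dir[[1]],
           eta = org[[2]] + coords * dir[[2]],
           plane = plane, coord = coords,
           org_xi = org[[1]], org_eta = org[[2]],
           dir_xi = dir[[1]], dir_eta = dir[[2]])
  }
  bind_rows(
    # along rectangle axis u (v-component 0), then along v, then the
    # centring-shifted copy of the v plane
    line_pts(c(0, 0), u_f, seq(0, 0.5, by = fs_u), "u0"),
    line_pts(c(0, 0), v_f, seq(0, 0.5, by = fs_v), "v0"),
    line_pts(0.5 * u_f, v_f, seq(0, 0.5, by = fs_v), "vh"))
}

#' Build a candidate reciprocal cell from scan coordinates
#'
#' c* = xi a* + eta b* + zeta c0*, where zeta is the unique positive value
#' making the direct cell volume equal to V (zeta = 1 / (A_star V), i.e. the
#' interlayer spacing along the zone axis is V / A).
#'
#' @param frame A [scan_frame()].
#' @param xi,eta Fractional in-plane components of **c***.
#' @param V Target direct-cell volume (Å³).
#' @return A reciprocal-space `unit_cell`.
#' @export
build_candidate_cell <- function(frame, xi, eta, V) {
  if (V <= 0) abort("`V` must be positive")
  Bstar <- candidate_basis(frame, xi, eta, V)
  cell_from_basis(Bstar, space = "reciprocal")
}

candidate_basis <- function(frame, xi, eta, V) {
  zeta <- 1 / (frame$A_star * V)
  cin <- xi * frame$a_vec + eta * frame$b_vec
  rbind(c(frame$a_vec, 0),
        c(frame$b_vec, 0),
        c(cin, zeta))
}

#' Select the initial-zone pattern
#'
#' Ranks patterns by symmetry class (p6 > p4 > cmm > pmm > p1), breaking
#' ties by the largest d1 + d2 (most prominent net). The winner defines the
#' \[001\] zone of the scan frame.
#'
#' @param patterns A pattern data frame.
#' @return The `id` of the selected pattern.
#' @examples
#' select_initial_zone(example_patterns("cupccl16")) # pattern 7
#' @export
select_initial_zone <- function(patterns) {
  patterns <- as_zone_patterns(patterns)
  if (nrow(patterns) == 0) abort("no patterns")
  rank_ <- match(patterns$symmetry_eff, pattern_symmetry_levels)
  d_sum <- patterns$d1 + patterns$d2
  patterns$id[[order(-rank_, -d_sum)[[1]]]]
}

scan_mode_for <- function(symmetry) {
  switch(symmetry, p1 = "3d", pmm = "2d", cmm = "2d", p4 = "1d", p6 = "1d")
}

# evaluate one candidate: index all non-initial patterns against the
# candidate reciprocal metric; early abort on first gate failure.
# obs: list of per-pattern canonical observations sorted most-constraining
# first. Returns NULL when rejected (unless keep_rejected).
eval_candidate <- function(frame, xi, eta, V, obs, zb, weights,
                           hkl_max = 12, keep_rejected = FALSE) {
  Bstar <- candidate_basis(frame, xi, eta, V)
  Gstar <- Bstar %*% t(Bstar)
  nets <- reduce_nets(zb, Gstar)
  max_ok <- net_max_index(zb, nets) <= hkl_max
  n <- length(obs)
  matches <- vector("list", n)
  for (i in seq_len(n)) {
    # pass 1 selects the zone: shape score, wide prior scale gate around 1
    m <- best_zone_match(obs[[i]], nets, weights, 1, max_ok)
    if (!m$accepted && !keep_rejected) return(NULL)
    matches[[i]] <- m
  }
  # pass 2: re-reference the kept zones to the dataset mean scale (the
  # initial pattern enters with scale exactly 1 by construction)
  ms <- mean(c(1, vapply(matches, `[[`, numeric(1), "s_p")))
  ok <- TRUE
  for (i in seq_len(n)) {
    m <- zone_match_at(obs[[i]], nets, matches[[i]]$idx, weights, ms)
    m$accepted <- m$accepted && matches[[i]]$accepted
    if (!m$accepted) {
      ok <- FALSE
      if (!keep_rejected) return(NULL)
    }
    matches[[i]] <- m
  }
  R <- mean(vapply(matches, `[[`, numeric(1), "T_p"))
  list(R = R, mean_scale = ms, matches = matches, accepted = ok,
       Gstar = Gstar)
}

#' Grid search for the unit cell
#'
#' The central operation: from N zonal patterns, pick (or accept) an initial
#' pattern defining zone \[001\], scan the missing reciprocal axis **c***
#' over a symmetry-adapted grid in (xi, eta, V) volume layers, keep every
#' candidate cell that indexes all remaining patterns within the acceptance
#' gate, rank candidates by the reliability index R, locally refine the
#' survivors, Delaunay-reduce them and propose conventional settings.
#' Near-duplicate solutions are merged (keeping the lowest R).
#'
#' @param patterns Pattern data frame (>= 2 rows after exclusions).
#' @param v_max Largest direct-cell volume to scan (Å³). Required.
#' @param v_min Smallest volume; default [vmin_default()] (base area times
#'   `h_min`).
#' @param f Fractional volume increment (default 0.025).
#' @param step Fractional in-plane grid step (default 1/12).
#' @param mode Scan dimensionality: `"auto"` (from the initial pattern's
#'   symmetry), `"1d"`, `"2d"` or `"3d"`. Forcing `"3d"` overrides a
#'   possibly overestimated pattern symmetry.
#' @param weights [match_weights()] for indexing and R.
#' @param max_index Zone enumeration bound (default 10).
#' @param hkl_max Largest admissible reduced |index| (default 12).
#' @param h_min Minimal interlayer spacing for the default V_min (Å).
#' @param initial Id of the initial pattern; default [select_initial_zone()].
#' @param exclude Ids of patterns to leave out of this run.
#' @param refine Locally refine surviving candidates over their scan
#'   coordinates (default TRUE). Refinement never leaves the scan plane of a
#'   symmetry-restricted run and never increases R.
#' @param refine_max Refine at most this many deduplicated solutions
#'   (default 50).
#' @param trace Keep the full candidate trace for [fom_surface()]
#'   (default FALSE).
#' @param dedup_tol_len,dedup_tol_ang Equivalence tolerances for merging
#'   near-duplicate solutions (default 2 percent, 2 deg).
#' @return An object of class `cell_search` with elements `solutions` (a
#'   ranked tibble: R, reduced primitive cell, volume, conventional setting,
#'   scan coordinates, per-pattern indexing in a list column), `initial`,
#'   `mode`, `frame`, `layers`, `config`, `counts` and optionally `trace`.
#' @examples
#' \donttest{
#' pats <- example_patterns("cupccl16")
#' fit <- cell_search(pats, v_min = 763, v_max = 1000, mode = "3d")
#' tidy(fit)
#' }
#' @export
cell_search <- function(patterns, v_max, v_min = NULL, f = 0.025,
                        step = 1 / 12, mode = c("auto", "1d", "2d", "3d"),
                        weights = match_weights(), max_index = 10,
                        hkl_max = 12, h_min = 3.4, initial = NULL,
                        exclude = NULL, refine = TRUE, refine_max = 50,
                        trace = FALSE, dedup_tol_len = 0.02,
                        dedup_tol_ang = 2) {
  mode <- arg_match(mode)
  weights <- as_match_weights(weights)
  patterns <- as_zone_patterns(patterns)
  if (!is.null(exclude)) {
    patterns <- dplyr::filter(patterns, !.data$id %in% exclude)
  }
  if (nrow(patterns) < 2) abort("need at least 2 patterns for a search")
  if (is.null(initial)) initial <- select_initial_zone(patterns)
  if (!initial %in% patterns$id) abort("`initial` is not a pattern id")
  init_row <- patterns[patterns$id == initial, ]
  frame <- scan_frame(init_row)
  others <- patterns[patterns$id != initial, ]
  # most constraining patterns (longest d1) first, for early abort
  others <- others[order(others$g_short), ]
  obs <- lapply(seq_len(nrow(others)), function(i) {
    list(rho = others$rho[[i]], phi = others$phi_can[[i]],
         g_short = others$g_short[[i]], g_long = others$g_long[[i]],
         id = others$id[[i]])
  })
  if (is.null(v_min)) v_min <- vmin_default(frame, h_min)
  layers <- volume_layers(v_min, v_max, f)
  grid_sym <- if (mode == "auto") {
    frame$symmetry
  } else {
    sym_for_mode(mode, frame$symmetry)
  }
  eff_mode <- scan_mode_for(grid_sym)
  grid <- candidate_grid(frame, layers, step = step, symmetry = grid_sym)
  zb <- zone_basis_table(max_index, "P")
  n_cand <- nrow(grid)
  surv <- vector("list", n_cand)
  trace_R <- if (trace) rep(NA_real_, n_cand) else NULL
  for (i in seq_len(n_cand)) {
    ev <- eval_candidate(frame, grid$xi[[i]], grid$eta[[i]], grid$V[[i]],
                         obs, zb, weights, hkl_max)
    if (!is.null(ev)) {
      surv[[i]] <- list(xi = grid$xi[[i]], eta = grid$eta[[i]],
                        V = grid$V[[i]], plane = grid$plane[[i]],
                        coord = grid$coord[[i]],
                        org_xi = grid$org_xi[[i]], org_eta = grid$org_eta[[i]],
                        dir_xi = grid$dir_xi[[i]], dir_eta = grid$dir_eta[[i]],
                        R = ev$R, mean_scale = ev$mean_scale)
      if (trace) trace_R[[i]] <- ev$R
    }
  }
  surv <- surv[!vapply(surv, is.null, logical(1))]
  counts <- list(patterns = nrow(patterns), layers = length(layers),
                 candidates = n_cand, surviving = length(surv))
  if (length(surv) == 0) {
    abort(paste0("no solution in search range [", round(v_min, 1), ", ",
                 round(v_max, 1),
                 "] Å³; consider raising `v_max`, loosening the gate ",
                 "(weights$k) or excluding suspicious patterns"))
  }
  surv <- surv[order(vapply(surv, `[[`, numeric(1), "R"))]
  # deduplicate on reduced cells, keeping the lowest R per lattice
  kept <- list()
  kept_bases <- list()
  for (s in surv) {
    cell <- reciprocal_of(build_candidate_cell(frame, s$xi, s$eta, s$V))
    red <- delaunay_reduce(cell)
    dup <- FALSE
    for (kb in kept_bases) {
      if (isTRUE(bases_equivalent(kb, red$basis,
                                  tol_len = dedup_tol_len,
                                  tol_ang = dedup_tol_ang))) {
        dup <- TRUE
        break
      }
    }
    if (!dup) {
      kept[[length(kept) + 1]] <- s
      kept_bases[[length(kept_bases) + 1]] <- red$basis
    }
  }
  # refine representatives
  sols <- vector("list", length(kept))
  sols_bases <- vector("list", length(kept))
  for (i in seq_along(kept)) {
    s <- kept[[i]]
    if (refine && i <= refine_max) {
      s <- refine_candidate_impl(s, frame, obs, zb, weights, hkl_max,
                                 eff_mode, f = f, step = step)
    }
    ev <- eval_candidate(frame, s$xi, s$eta, s$V, obs, zb, weights,
                         hkl_max, keep_rejected = TRUE)
    cell_star <- build_candidate_cell(frame, s$xi, s$eta, s$V)
    cell <- reciprocal_of(cell_star)
    red <- delaunay_reduce(cell)
    conv <- conventional_setting(red)
    nets <- reduce_nets(zb, ev$Gstar)
    idx <- vapply(ev$matches, `[[`, integer(1), "idx")
    hk <- net_hkl(zb, nets, idx)
    res <- tibble(
      id = vapply(obs, `[[`, numeric(1), "id"),
      u = zb$zones$u[idx], v = zb$zones$v[idx], w = zb$zones$w[idx],
      h1 = hk$h1[, 1], k1 = hk$h1[, 2], l1 = hk$h1[, 3],
      h2 = hk$h2[, 1], k2 = hk$h2[, 2], l2 = hk$h2[, 3],
      eps_ratio = vapply(ev$matches, `[[`, numeric(1), "eps_ratio"),
      eps_angle = vapply(ev$matches, `[[`, numeric(1), "eps_angle"),
      eps_scale = vapply(ev$matches, `[[`, numeric(1), "eps_scale"),
      s_p = vapply(ev$matches, `[[`, numeric(1), "s_p"),
      T_p = vapply(ev$matches, `[[`, numeric(1), "T_p"),
      accepted = TRUE)
    rc <- red$cell
    cc <- conv$cell
    sols_bases[[i]] <- red$basis
    sols[[i]] <- tibble(
      R = ev$R,
      a = rc[["a"]], b = rc[["b"]], c = rc[["c"]],
      alpha = rc[["alpha"]], beta = rc[["beta"]], gamma = rc[["gamma"]],
      volume = cell_volume(rc),
      centring = conv$centring, system = conv$system,
      conv_a = cc[["a"]], conv_b = cc[["b"]], conv_c = cc[["c"]],
      conv_alpha = cc[["alpha"]], conv_beta = cc[["beta"]],
      conv_gamma = cc[["gamma"]], conv_volume = cell_volume(cc),
      xi = s$xi, eta = s$eta, V_layer = s$V,
      plane = s$plane, coord = s$coord, mean_scale = ev$mean_scale,
      indexing = list(res))
  }
  solutions <- bind_rows(sols)
  # refinement can move distinct grid survivors onto the same lattice
  ord <- order(solutions$R)
  solutions <- solutions[ord, ]
  sols_bases <- sols_bases[ord]
  if (nrow(solutions) > 1) {
    keep_idx <- rep(TRUE, nrow(solutions))
    for (i in seq_len(nrow(solutions))[-1]) {
      for (j in seq_len(i - 1)) {
        if (keep_idx[[j]] &&
            isTRUE(bases_equivalent(sols_bases[[j]], sols_bases[[i]],
                                    tol_len = dedup_tol_len,
                                    tol_ang = dedup_tol_ang))) {
          keep_idx[[i]] <- FALSE
          break
        }
      }
    }
    solutions <- solutions[keep_idx, ]
  }
  solutions$rank <- seq_len(nrow(solutions))
  solutions <- solutions[c("rank", setdiff(names(solutions), "rank"))]
  out <- structure(
    list(solutions = solutions, initial = initial, mode = eff_mode,
         grid_symmetry = grid_sym, frame = frame, layers = layers,
         counts = counts, patterns = patterns,
         config = list(v_min = v_min, v_max = v_max, f = f, step = step,
                       weights = unclass(weights), max_index = max_index,
                       hkl_max = hkl_max, h_min = h_min,
                       exclude = exclude %||% character(0),
                       refine = refine)),
    class = "cell_search")
  if (trace) {
    out$trace <- mutate(grid, R = trace_R,
                        accepted = !is.na(trace_R),
                        F_inv = ifelse(is.na(trace_R), 0, 1 / trace_R))
  }
  out
}

sym_for_mode <- function(mode, symmetry) {
  if (mode == "3d") return("p1")
  if (mode == "2d") {
    if (symmetry %in% c("pmm", "cmm")) return(symmetry)
    if (symmetry %in% c("p4", "p6")) return("pmm")
    abort("2d scan requires a pattern with a mirror plane (pmm or cmm)")
  }
  if (symmetry %in% c("p4", "p6")) return(symmetry)
  abort("1d scan requires a fourfold or sixfold pattern")
}

# local derivative-free refinement of a surviving candidate, restricted to
# the scan manifold of the run (1d: V only; 2d: plane coordinate + V;
# 3d: xi, eta, V). The volume may move at most one layer increment and the
# in-plane coordinates at most one grid step from the starting candidate,
# so refinement polishes a grid optimum instead of tunnelling to another.
refine_candidate_impl <- function(s, frame, obs, zb, weights, hkl_max,
                                  eff_mode, f = 0.025, step = 1 / 12) {
  par0 <- encode_par(s, eff_mode)
  nv <- length(par0)
  lo <- par0
  hi <- par0
  lo[[nv]] <- par0[[nv]] - log(1 + f)
  hi[[nv]] <- par0[[nv]] + log(1 + f)
  if (nv > 1) {
    # one grid step in each in-plane direction, in the same units the grid
    # used (a fraction `step` of the layer resolution scale)
    zeta <- 1 / (frame$A_star * s$V)
    s_c <- step * min(zeta, frame$g1, frame$g2)
    if (eff_mode == "2d") {
      dir_cart <- s$dir_xi * frame$a_vec + s$dir_eta * frame$b_vec
      d1 <- s_c / sqrt(sum(dir_cart^2))
      lo[[1]] <- par0[[1]] - d1
      hi[[1]] <- par0[[1]] + d1
    } else {
      lo[[1]] <- par0[[1]] - s_c / frame$g1
      hi[[1]] <- par0[[1]] + s_c / frame$g1
      lo[[2]] <- par0[[2]] - s_c / frame$g2
      hi[[2]] <- par0[[2]] + s_c / frame$g2
    }
  }
  objective <- function(par) {
    if (any(par < lo) || any(par > hi)) return(1e9)
    p <- decode_par(par, s, eff_mode)
    if (p$V <= 0) return(1e9)
    ev <- eval_candidate(frame, p$xi, p$eta, p$V, obs, zb, weights,
                         hkl_max, keep_rejected = TRUE)
    if (!ev$accepted) return(1e6 + ev$R)
    ev$R
  }
  if (nv == 1) {
    opt <- stats::optimize(objective, lower = lo, upper = hi, tol = 1e-10)
    opt <- list(par = opt$minimum, value = opt$objective)
  } else {
    opt <- optim(par0, objective, method = "Nelder-Mead",
                 control = list(maxit = 400, reltol = 1e-9))
  }
  if (opt$value <= objective(par0) + 1e-12 && opt$value < 1e6) {
    p <- decode_par(opt$par, s, eff_mode)
    s$xi <- p$xi
    s$eta <- p$eta
    s$V <- p$V
    s$R <- opt$value
    if (eff_mode == "2d") s$coord <- opt$par[[1]]
  }
  s
}

encode_par <- function(s, mode) {
  switch(mode,
         "1d" = log(s$V),
         "2d" = c(s$coord, log(s$V)),
         "3d" = c(s$xi, s$eta, log(s$V)))
}

decode_par <- function(par, s, mode) {
  switch(mode,
         "1d" = list(xi = s$xi, eta = s$eta, V = exp(par[[1]])),
         "2d" = list(xi = s$org_xi + par[[1]] * s$dir_xi,
                     eta = s$org_eta + par[[1]] * s$dir_eta,
                     V = exp(par[[2]])),
         "3d" = list(xi = par[[1]], eta = par[[2]], V = exp(par[[3]])))
}

#' @export
print.cell_search <- function(x, n = 5, ...) {
  cat(sprintf("<cell_search> %s scan, initial pattern %s (%s)\n",
              x$mode, x$initial, x$grid_symmetry))
  cat(sprintf("  %d patterns, %d layers, %d candidates, %d surviving, %d solutions\n",
              x$counts$patterns, x$counts$layers, x$counts$candidates,
              x$counts$surviving, nrow(x$solutions)))
  cols <- c("rank", "R", "a", "b", "c", "alpha", "beta", "gamma", "volume",
            "centring")
  print(as.data.frame(head(x$solutions[cols], n)), digits = 4,
        row.names = FALSE)
  invisible(x)
}

#' @method tidy cell_search
#' @export
tidy.cell_search <- function(x, ...) {
  select(x$solutions, -"indexing")
}

#' @method glance cell_search
#' @export
glance.cell_search <- function(x, ...) {
  tibble(n_patterns = x$counts$patterns, initial = x$initial,
         mode = x$mode, n_layers = x$counts$layers,
         n_candidates = x$counts$candidates,
         n_surviving = x$counts$surviving,
         n_solutions = nrow(x$solutions),
         best_R = x$solutions$R[[1]],
         best_volume = x$solutions$volume[[1]])
}

#' Best solution of a search as a unit cell
#'
#' @param x A `cell_search` object.
#' @param rank Which solution to extract (default 1, the lowest R).
#' @param setting `"reduced"` (primitive Delaunay-reduced) or
#'   `"conventional"`.
#' @return A `unit_cell`.
#' @export
solution_cell <- function(x, rank = 1, setting = c("reduced", "conventional")) {
  stopifnot(inherits(x, "cell_search"))
  setting <- arg_match(setting)
  s <- x$solutions[x$solutions$rank == rank, ]
  if (nrow(s) != 1) abort("no solution with that rank")
  if (setting == "reduced") {
    unit_cell(s$a, s$b, s$c, s$alpha, s$beta, s$gamma)
  } else {
    unit_cell(s$conv_a, s$conv_b, s$conv_c,
              s$conv_alpha, s$conv_beta, s$conv_gamma)
  }
}

#' Inverse figure-of-merit surface
#'
#' Extracts the F_inv = 1/R values over (free coordinate, V) for one scan
#' plane of a traced search; rejected candidates contribute 0. The argmax of
#' the surface is the best unrefined candidate in that plane.
#'
#' @param x A `cell_search` run with `trace = TRUE`.
#' @param plane Scan-plane label (for 1d/2d runs, e.g. `"u0"`, `"x0"`); for
#'   3d runs use `xi =` or `eta =` instead to pick a grid line.
#' @param xi,eta For 3d runs: fix one in-plane coordinate (nearest grid
#'   value is used).
#' @return A tibble of class `zc_fom`: `coord`, `V`, `R`, `F_inv`.
#' @export
fom_surface <- function(x, plane = NULL, xi = NULL, eta = NULL) {
  stopifnot(inherits(x, "cell_search"))
  if (is.null(x$trace)) {
    abort("search was run without `trace = TRUE`")
  }
  tr <- x$trace
  if (!is.null(plane)) {
    tr <- dplyr::filter(tr, .data$plane == !!plane)
    if (nrow(tr) == 0) abort(paste0("no scan plane labelled ", plane))
    out <- tibble(coord = tr$coord, V = tr$V, R = tr$R, F_inv = tr$F_inv)
    if (all(is.na(out$coord))) out$coord <- tr$eta
  } else if (!is.null(xi)) {
    v <- unique(tr$xi)
    xi0 <- v[[which.min(abs(v - xi))]]
    tr <- dplyr::filter(tr, .data$xi == xi0)
    out <- tibble(coord = tr$eta, V = tr$V, R = tr$R, F_inv = tr$F_inv)
  } else if (!is.null(eta)) {
    v <- unique(tr$eta)
    eta0 <- v[[which.min(abs(v - eta))]]
    tr <- dplyr::filter(tr, .data$eta == eta0)
    out <- tibble(coord = tr$xi, V = tr$V, R = tr$R, F_inv = tr$F_inv)
  } else {
    abort("give `plane` (1d/2d scans) or one of `xi`/`eta` (3d scans)")
  }
  class(out) <- c("zc_fom", class(out))
  out
}

#' @method autoplot zc_fom
#' @export
autoplot.zc_fom <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$V, y = .data$coord,
                               fill = .data$F_inv)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = expression(F[inv] == 1 / R)) +
    ggplot2::labs(x = expression(V ~ (ring(A)^3)),
                  y = "scan coordinate (fractional)") +
    ggplot2::theme_minimal()
}

#' @method autoplot cell_search
#' @export
autoplot.cell_search <- function(object, ...) {
  sol <- tidy(object)
  ggplot2::ggplot(sol, ggplot2::aes(x = .data$volume, y = .data$R)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$rank), vjust = -0.8,
                       size = 3) +
    ggplot2::labs(x = expression(V ~ (ring(A)^3)),
                  y = "reliability index R") +
    ggplot2::theme_minimal()
}
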