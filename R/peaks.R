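#' Correct elliptical distortion of a peak list
#'
#' Detector or lens ellipticity stretches a pattern by a constant factor
#' along a fixed axis. The correction rescales coordinates by 1/ratio along
#' that axis: rotate by -axis_angle, divide x by ratio, rotate back.
#' `ratio = 1` is the identity.
#'
#' @param peaks Data frame with numeric columns `x`, `y` (reciprocal Å⁻¹ or
#'   pixels; any consistent unit).
#' @param ratio Long-axis / short-axis scale ratio (> 0), e.g. 1.023 for a
#'   2.3 percent distortion.
#' @param axis_angle Angle of the long axis in degrees from +x (default 0).
#' @return The peak tibble with corrected `x`, `y`.
#' @export
correct_elliptical_distortion <- function(peaks, ratio, axis_angle = 0) {
  if (ratio <= 0) abort("`ratio` must be positive")
  peaks <- as_tibble(peaks)
  th <- deg2rad(axis_angle)
  ct <- cos(th); st <- sin(th)
  xr <- ct * peaks$x + st * peaks$y
  yr <- -st * peaks$x + ct * peaks$y
  xr <- xr / ratio
  peaks$x <- ct * xr - st * yr
  peaks$y <- st * xr + ct * yr
  peaks
}

#' Extract a 2D lattice basis by autocorrelation of peak positions
#'
#' Forms all pairwise difference vectors, clusters them, and takes the two
#' shortest non-collinear cluster centroids as the basis, which is then
#' polished by [refine_basis()].
#'
#' @param peaks Data frame with columns `x`, `y` (>= 5 peaks).
#' @param cluster_tol Clustering radius; default 5 percent of the shortest
#'   difference-vector length.
#' @param min_count Minimum cluster population considered (default 3).
#' @return A list: `v1`, `v2` (basis row vectors, |v1| <= |v2|), `residual`
#'   (RMS positional residual from the refinement) and `matched_fraction`.
#' @export
extract_basis <- function(peaks, cluster_tol = NULL, min_count = 3) {
  peaks <- as_tibble(peaks)
  if (nrow(peaks) < 5) abort("need at least 5 peaks for basis extraction")
  P <- cbind(peaks$x, peaks$y)
  if (any(!is.finite(P))) abort("peak coordinates must be finite")
  n <- nrow(P)
  ii <- rep(seq_len(n), each = n)
  jj <- rep(seq_len(n), times = n)
  keep <- ii < jj
  D <- P[jj[keep], , drop = FALSE] - P[ii[keep], , drop = FALSE]
  # fold sign: represent each difference in the upper half plane
  flip <- D[, 2] < 0 | (D[, 2] == 0 & D[, 1] < 0)
  D[flip, ] <- -D[flip, , drop = FALSE]
  len <- sqrt(rowSums(D^2))
  D <- D[len > 1e-12, , drop = FALSE]
  len <- len[len > 1e-12]
  if (is.null(cluster_tol)) cluster_tol <- 0.05 * min(len)
  ord <- order(len)
  D <- D[ord, , drop = FALSE]
  centroids <- list()
  counts <- integer()
  sums <- list()
  for (i in seq_len(nrow(D))) {
    placed <- FALSE
    for (k in seq_along(centroids)) {
      if (sum((D[i, ] - centroids[[k]])^2) <= cluster_tol^2) {
        sums[[k]] <- sums[[k]] + D[i, ]
        counts[[k]] <- counts[[k]] + 1L
        centroids[[k]] <- sums[[k]] / counts[[k]]
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      centroids[[length(centroids) + 1]] <- D[i, ]
      sums[[length(sums) + 1]] <- D[i, ]
      counts[[length(counts) + 1]] <- 1L
    }
  }
  good <- which(counts >= min_count)
  if (length(good) < 2) good <- order(-counts)[seq_len(min(4, length(counts)))]
  C <- do.call(rbind, centroids[good])
  cl <- sqrt(rowSums(C^2))
  ord2 <- order(cl)
  C <- C[ord2, , drop = FALSE]
  v1 <- C[1, ]
  v2 <- NULL
  for (k in seq_len(nrow(C))[-1]) {
    cand <- C[k, ]
    sin_ang <- abs(v1[[1]] * cand[[2]] - v1[[2]] * cand[[1]]) /
      (sqrt(sum(v1^2)) * sqrt(sum(cand^2)))
    if (sin_ang > 0.05) {
      v2 <- cand
      break
    }
  }
  if (is.null(v2)) abort("no 2D lattice found (difference vectors collinear)")
  refine_basis(peaks, v1, v2)
}

#' Least-squares refinement of a 2D lattice basis
#'
#' Assigns each peak the nearest integer index pair under the current basis,
#' then solves the linear least-squares problem for the basis over the peaks
#' whose fractional residual is below 0.25, iterating to convergence.
#'
#' @param peaks Data frame with columns `x`, `y`.
#' @param v1,v2 Initial basis row vectors (non-collinear).
#' @param max_iter Iteration cap (default 20).
#' @param frac_tol Fractional residual for inlier selection (default 0.25).
#' @return A list: refined `v1`, `v2` (|v1| <= |v2|), `residual` (RMS
#'   Cartesian residual of the inliers) and `matched_fraction`.
#' @export
refine_basis <- function(peaks, v1, v2, max_iter = 20, frac_tol = 0.25) {
  peaks <- as_tibble(peaks)
  P <- cbind(peaks$x, peaks$y)
  B <- rbind(as.numeric(v1), as.numeric(v2))
  if (abs(det(B)) < 1e-14) abort("initial basis is collinear")
  matched <- NA_real_
  for (it in seq_len(max_iter)) {
    fr <- P %*% solve(B) # fractional indices of each peak
    idx <- round(fr)
    resid_fr <- fr - idx
    inlier <- rowSums(abs(resid_fr) > frac_tol) == 0
    matched <- mean(inlier)
    use <- which(inlier)
    if (length(use) < 3) break
    A <- idx[use, , drop = FALSE]
    if (abs(det(crossprod(A))) < 1e-12) {
      abort("refinement failed: degenerate normal equations")
    }
    Bnew <- solve(crossprod(A), crossprod(A, P[use, , drop = FALSE]))
    delta <- max(abs(Bnew - B))
    B <- Bnew
    if (delta < 1e-8) break
  }
  fr <- P %*% solve(B)
  idx <- round(fr)
  inlier <- rowSums(abs(fr - idx) > frac_tol) == 0
  resid <- if (any(inlier)) {
    sqrt(mean(rowSums(((fr - idx)[inlier, , drop = FALSE] %*% B)^2)))
  } else {
    NA_real_
  }
  if (sum(B[1, ]^2) > sum(B[2, ]^2)) B <- B[2:1, ]
  list(v1 = B[1, ], v2 = B[2, ], residual = resid,
       matched_fraction = mean(inlier))
}

#' Fraction of peaks explained by a 2D lattice
#'
#' Scores how "zonal" a pattern is: the fraction of peaks lying within
#' `tol` (default 0.15 of the shorter basis length) of a node of the net
#' spanned by the basis. Prominent zonal patterns score near 1; high-index
#' sections (interleaved nets) score visibly lower.
#'
#' @param peaks Data frame with columns `x`, `y`.
#' @param basis A list with `v1`, `v2` (e.g. from [extract_basis()]) or a
#'   2x2 matrix with basis rows.
#' @param tol Cartesian tolerance; default 0.15 * |v1|.
#' @return A fraction in \[0, 1\].
#' @export
lattice_score <- function(peaks, basis, tol = NULL) {
  peaks <- as_tibble(peaks)
  B <- if (is.list(basis) && !is.null(basis$v1)) {
    rbind(basis$v1, basis$v2)
  } else {
    as.matrix(basis)
  }
  if (abs(det(B)) < 1e-14) abort("basis is collinear")
  if (is.null(tol)) tol <- 0.15 * min(sqrt(rowSums(B^2)))
  P <- cbind(peaks$x, peaks$y)
  fr <- P %*% solve(B)
  dev <- (fr - round(fr)) %*% B
  mean(sqrt(rowSums(dev^2)) <= tol)
}

#' Reduce a peak list to a zone-pattern descriptor
#'
#' Convenience wrapper: extract and refine the basis of one peak list, then
#' emit the canonical (d1, d2, phi) pattern row used by [cell_search()].
#'
#' @param peaks Data frame with columns `x`, `y` in reciprocal Å⁻¹ (apply
#'   the camera constant and any distortion correction first).
#' @param id Pattern id for the emitted row.
#' @param ... Passed to [extract_basis()].
#' @return A one-row pattern tibble with `id`, `d1`, `d2`, `phi`,
#'   `lattice_score`.
#' @export
peaks_to_pattern <- function(peaks, id = 1, ...) {
  bas <- extract_basis(peaks, ...)
  g1 <- sqrt(sum(bas$v1^2))
  g2 <- sqrt(sum(bas$v2^2))
  cosphi <- sum(bas$v1 * bas$v2) / (g1 * g2)
  phi <- rad2deg(acos(pmin(1, pmax(-1, cosphi))))
  if (phi > 90) phi <- 180 - phi
  tibble(id = id, d1 = 1 / g1, d2 = 1 / g2, phi = phi,
         lattice_score = lattice_score(peaks, bas))
}

#' Read a peak list from delimited text
#'
#' Columns `pattern_id, x, y`; comma, tab or whitespace delimited; `#`
#' comments. Units are taken as-is (declare them upstream); an optional
#' `camera_constant` rescales pixel coordinates to Å⁻¹.
#'
#' @param path File path.
#' @param camera_constant Multiplier applied to `x`, `y` (default 1).
#' @return A tibble `pattern_id`, `x`, `y`.
#' @export
read_peak_list <- function(path, camera_constant = 1) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readLines(path, warn = FALSE)
  strip <- trimws(sub("#.*$", "", raw))
  strip <- strip[strip != ""]
  if (length(strip) == 0) abort("no peaks: file is empty")
  delim <- if (any(grepl(",", strip))) "," else "[\t ]+"
  rows <- lapply(strip, function(s) trimws(strsplit(s, delim)[[1]]))
  if (tolower(rows[[1]][[1]]) %in% c("pattern_id", "id")) rows <- rows[-1]
  tab <- bind_rows(lapply(rows, function(r) {
    if (length(r) < 3) abort("peak rows need pattern_id, x, y")
    tibble(pattern_id = r[[1]],
           x = as.numeric(r[[2]]) * camera_constant,
           y = as.numeric(r[[3]]) * camera_constant)
  }))
  if (anyNA(tab$x) || anyNA(tab$y)) abort("non-numeric peak coordinates")
  tab
}
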