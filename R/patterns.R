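#' Canonicalize a zone-pattern descriptor
#'
#' A zonal electron-diffraction pattern is summarized by two basis
#' reflections with d-spacings `d1`, `d2` (Å) and the inter-vector angle
#' `phi` (degrees). Because a diffraction pattern is centrosymmetric (g and
#' -g are indistinguishable), the descriptor is folded into a canonical form:
#' the 2D reciprocal basis is Lagrange(Gauss)-reduced, vectors are ordered so
#' that g_short <= g_long, and phi is mapped into (0, 90] via
#' phi -> 180 - phi. The operation is idempotent.
#'
#' @param d1,d2 d-spacings in Å (d = 1/|g|).
#' @param phi Inter-vector angle in degrees, in (0, 180).
#' @return A tibble with columns `g_short`, `g_long` (Å⁻¹), `phi` (deg,
#'   canonical), `rho` (= g_long / g_short >= 1), `d_long`, `d_short` (Å).
#' @examples
#' canonicalize_pattern(7.59, 3.75, 93.3)
#' @export
canonicalize_pattern <- function(d1, d2, phi) {
  n <- max(length(d1), length(d2), length(phi))
  d1 <- rep_len(d1, n); d2 <- rep_len(d2, n); phi <- rep_len(phi, n)
  if (any(!is.finite(d1) | !is.finite(d2) | d1 <= 0 | d2 <= 0)) {
    abort("d-spacings must be positive and finite")
  }
  if (any(!is.finite(phi) | phi <= 0 | phi >= 180)) {
    abort("phi must lie strictly between 0 and 180 degrees")
  }
  g1 <- 1 / d1
  g2 <- 1 / d2
  phir <- deg2rad(phi)
  # Lagrange reduction of the 2D basis, vectorized on squared lengths
  a2 <- g1^2
  b2 <- g2^2
  ab <- g1 * g2 * cos(phir)
  for (it in 1:64) {
    swap <- a2 > b2
    if (any(swap)) {
      tmp <- a2[swap]; a2[swap] <- b2[swap]; b2[swap] <- tmp
    }
    m <- round(ab / a2)
    if (all(m == 0)) break
    b2 <- b2 - 2 * m * ab + m^2 * a2
    ab <- ab - m * a2
  }
  swap <- a2 > b2
  if (any(swap)) {
    tmp <- a2[swap]; a2[swap] <- b2[swap]; b2[swap] <- tmp
  }
  gs <- sqrt(a2)
  gl <- sqrt(b2)
  cosphi <- abs(ab) / (gs * gl)
  phic <- rad2deg(acos(pmin(1, cosphi)))
  phic[phic < 1e-9] <- 0 # guarded below; degenerate bases cannot occur after reduction
  tibble(g_short = gs, g_long = gl, phi = phic, rho = gl / gs,
         d_long = 1 / gs, d_short = 1 / gl)
}

pattern_symmetry_levels <- c("p1", "pmm", "cmm", "p4", "p6")

normalize_symmetry_label <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x[x %in% c("", "na", "auto", "-")] <- NA_character_
  map_ <- c("p1" = "p1", "1" = "p1",
            "pmm" = "pmm", "2mm" = "pmm", "pmm2" = "pmm", "mm" = "pmm",
            "cmm" = "cmm", "c2mm" = "cmm",
            "p4" = "p4", "4" = "p4", "4mm" = "p4", "p4m" = "p4",
            "p6" = "p6", "6" = "p6", "6mm" = "p6", "p6m" = "p6")
  out <- unname(map_[x])
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    abort(paste0("unknown symmetry label(s): ",
                 paste(unique(x[bad]), collapse = ", ")))
  }
  out
}

#' Classify the metric plane symmetry of zone patterns
#'
#' Judged purely from the canonical basis metric (g_short, g_long, phi),
#' ignoring reflection intensities. Rules are checked from most to least
#' restrictive: `p4` (equal lengths, phi = 90), `p6` (equal lengths,
#' phi = 60; the canonical fold maps 120 to 60), `cmm` (equal lengths at any
#' angle, or the centred-rectangular identity 2 g_long cos(phi) = g_short),
#' `pmm` (phi = 90), else `p1`. A user-supplied label in the `symmetry`
#' column overrides the automatic classification.
#'
#' @param patterns A data frame with columns `d1`, `d2`, `phi` and optionally
#'   `symmetry` (labels such as "2mm", "4", "cmm"; `NA` or "auto" for
#'   automatic classification).
#' @param tol_len Relative length tolerance (default 0.01).
#' @param tol_ang Angle tolerance in degrees (default 0.5).
#' @return The input tibble with added canonical columns (`g_short`,
#'   `g_long`, `phi_can`, `rho`) and `symmetry_auto`, `symmetry_eff`.
#' @examples
#' classify_patterns(tibble::tibble(d1 = 79.06, d2 = 79.06, phi = 90))
#' @export
classify_patterns <- function(patterns, tol_len = 0.01, tol_ang = 0.5) {
  patterns <- as_tibble(patterns)
  if (!all(c("d1", "d2", "phi") %in% names(patterns))) {
    abort("`patterns` must have columns d1, d2, phi")
  }
  can <- canonicalize_pattern(patterns$d1, patterns$d2, patterns$phi)
  auto <- metric_symmetry(can$g_short, can$g_long, can$phi, tol_len, tol_ang)
  lab <- if ("symmetry" %in% names(patterns)) {
    normalize_symmetry_label(patterns$symmetry)
  } else {
    rep(NA_character_, nrow(patterns))
  }
  patterns$g_short <- can$g_short
  patterns$g_long <- can$g_long
  patterns$phi_can <- can$phi
  patterns$rho <- can$rho
  patterns$symmetry_auto <- auto
  patterns$symmetry_eff <- ifelse(is.na(lab), auto, lab)
  patterns
}

metric_symmetry <- function(g_short, g_long, phi, tol_len = 0.01,
                            tol_ang = 0.5) {
  eq_len <- abs(g_short - g_long) / g_long <= tol_len
  ang90 <- abs(phi - 90) <= tol_ang
  ang60 <- abs(phi - 60) <= tol_ang
  centred <- abs(2 * g_long * cos(deg2rad(phi)) - g_short) / g_short <=
    2 * tol_len
  out <- rep("p1", length(g_short))
  out[ang90] <- "pmm"
  out[eq_len | centred] <- "cmm"
  out[eq_len & ang60] <- "p6"
  out[eq_len & ang90] <- "p4"
  out
}

#' Assemble a validated zone-pattern table
#'
#' Validates ids, d-spacings and angles, then canonicalizes and classifies
#' (see [classify_patterns()]). This is the common entry point used by the
#' indexing and cell-search functions; they call it themselves, so passing a
#' plain `d1/d2/phi` data frame anywhere is fine.
#'
#' @param patterns Data frame with columns `id` (optional; defaults to row
#'   number), `d1`, `d2` (Å), `phi` (deg), `symmetry` (optional label),
#'   `exclude` (optional logical).
#' @inheritParams classify_patterns
#' @return A tibble of validated, canonicalized patterns.
#' @export
as_zone_patterns <- function(patterns, tol_len = 0.01, tol_ang = 0.5) {
  patterns <- as_tibble(patterns)
  if (!all(c("d1", "d2", "phi") %in% names(patterns))) {
    abort("`patterns` must have columns d1, d2, phi")
  }
  if (!"id" %in% names(patterns)) {
    patterns$id <- seq_len(nrow(patterns))
  }
  if (anyDuplicated(patterns$id)) {
    abort("pattern ids must be unique")
  }
  if ("exclude" %in% names(patterns)) {
    patterns <- dplyr::filter(patterns, !.data$exclude | is.na(.data$exclude))
  }
  classify_patterns(patterns, tol_len = tol_len, tol_ang = tol_ang)
}

#' Read a zone-pattern table from delimited text
#'
#' Expects one row per pattern with columns `id, d1, d2, phi[, symmetry]`.
#' The delimiter (comma, tab or whitespace) is auto-detected; lines starting
#' with `#` are comments. A header line naming the columns is optional.
#' Malformed rows are reported with their line numbers.
#'
#' @param path Path to the file.
#' @param tol_len,tol_ang Tolerances passed to [classify_patterns()].
#' @return A canonicalized pattern tibble (see [as_zone_patterns()]).
#' @export
read_pattern_table <- function(path, tol_len = 0.01, tol_ang = 0.5) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readLines(path, warn = FALSE)
  lineno <- seq_along(raw)
  strip <- sub("#.*$", "", raw)
  keep <- trimws(strip) != ""
  strip <- strip[keep]
  lineno <- lineno[keep]
  if (length(strip) == 0) abort("no patterns: file is empty")
  delim <- if (any(grepl(",", strip))) "," else "[\t ]+"
  rows <- lapply(strip, function(s) trimws(strsplit(trimws(s), delim)[[1]]))
  # optional header
  header <- c("id", "d1", "d2", "phi", "symmetry")
  first <- tolower(rows[[1]])
  if (any(first %in% header)) {
    header <- first
    rows <- rows[-1]
    lineno <- lineno[-1]
  }
  if (length(rows) == 0) abort("no patterns: file contains only a header")
  errs <- character()
  parsed <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (length(r) < 4) {
      errs <- c(errs, sprintf("line %d: expected at least 4 fields", lineno[[i]]))
      next
    }
    vals <- suppressWarnings(as.numeric(r[2:4]))
    if (any(is.na(vals))) {
      errs <- c(errs, sprintf("line %d: non-numeric d1/d2/phi", lineno[[i]]))
      next
    }
    if (any(vals[1:2] <= 0)) {
      errs <- c(errs, sprintf("line %d: d-spacings must be > 0", lineno[[i]]))
      next
    }
    if (vals[[3]] <= 0 || vals[[3]] >= 180) {
      errs <- c(errs, sprintf("line %d: phi outside (0, 180)", lineno[[i]]))
      next
    }
    parsed[[i]] <- tibble(id = r[[1]], d1 = vals[[1]], d2 = vals[[2]],
                          phi = vals[[3]],
                          symmetry = if (length(r) >= 5) r[[5]] else
                            NA_character_)
  }
  if (length(errs) > 0) {
    abort(paste0("invalid pattern table:\n",
                 paste("  ", errs, collapse = "\n")))
  }
  tab <- bind_rows(parsed)
  if (anyDuplicated(tab$id)) {
    dup <- unique(tab$id[duplicated(tab$id)])
    abort(paste0("duplicate pattern id(s): ", paste(dup, collapse = ", ")))
  }
  ids <- suppressWarnings(as.integer(tab$id))
  if (!anyNA(ids)) tab$id <- ids
  as_zone_patterns(tab, tol_len = tol_len, tol_ang = tol_ang)
}

#' Write a zone-pattern table
#'
#' @param patterns Pattern data frame (columns `id`, `d1`, `d2`, `phi` and
#'   optionally `symmetry`).
#' @param path Output path.
#' @param sep Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_pattern_table <- function(patterns, path, sep = "\t") {
  patterns <- as_tibble(patterns)
  cols <- intersect(c("id", "d1", "d2", "phi", "symmetry"), names(patterns))
  out <- patterns[cols]
  lines <- c(paste(cols, collapse = sep),
             vapply(seq_len(nrow(out)), function(i) {
               paste(vapply(out[i, ], function(v) {
                 if (is.numeric(v)) format(v, digits = 10) else
                   as.character(v %||% "")
               }, character(1)), collapse = sep)
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Bundled example pattern tables
#'
#' Measured zonal-pattern descriptor tables for three test materials:
#' copper perchlorophthalocyanine (`"cupccl16"`, 7 patterns), tetragonal hen
#' egg-white lysozyme (`"lysozyme"`, 6 patterns, angles fixed to 90 deg as
#' dictated by the mirror symmetry of the patterns) and the GRGDS
#' pentapeptide (`"grgds"`, 5 patterns).
#'
#' @param dataset One of `"cupccl16"`, `"lysozyme"`, `"grgds"`.
#' @return A canonicalized pattern tibble.
#' @examples
#' example_patterns("cupccl16")
#' @export
example_patterns <- function(dataset = c("cupccl16", "lysozyme", "grgds")) {
  dataset <- arg_match(dataset)
  path <- system.file("extdata", paste0(dataset, "_patterns.csv"),
                      package = "zonecell", mustWork = TRUE)
  read_pattern_table(path)
}
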