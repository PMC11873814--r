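#' Write ranked solutions of a search
#'
#' Writes the solution list as a delimited table (rank, R, reduced primitive
#' cell, volume, centring and conventional cell), and optionally a
#' machine-readable JSON run record holding the full per-pattern indexing
#' results and the run configuration for provenance.
#'
#' @param x A `cell_search` object.
#' @param path Output path for the delimited table.
#' @param record_path Optional path for the JSON run record.
#' @param sep Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_solutions <- function(x, path, record_path = NULL, sep = "\t") {
  stopifnot(inherits(x, "cell_search"))
  sol <- tidy(x)
  cols <- c("rank", "R", "a", "b", "c", "alpha", "beta", "gamma", "volume",
            "centring", "system", "conv_a", "conv_b", "conv_c",
            "conv_alpha", "conv_beta", "conv_gamma", "conv_volume")
  tab <- sol[cols]
  lines <- c(paste(cols, collapse = sep),
             vapply(seq_len(nrow(tab)), function(i) {
               paste(vapply(tab[i, ], function(v) {
                 if (is.numeric(v)) sprintf("%.6g", v) else as.character(v)
               }, character(1)), collapse = sep)
             }, character(1)))
  writeLines(lines, path)
  if (!is.null(record_path)) {
    rec <- list(
      config = x$config,
      initial = x$initial,
      mode = x$mode,
      counts = x$counts,
      solutions = lapply(seq_len(nrow(x$solutions)), function(i) {
        s <- x$solutions[i, ]
        c(as.list(s[setdiff(names(s), "indexing")]),
          list(indexing = as.data.frame(s$indexing[[1]])))
      }))
    jsonlite::write_json(rec, record_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Read back a solutions table
#'
#' Round-trip companion of [write_solutions()].
#'
#' @param path File written by [write_solutions()].
#' @param sep Field delimiter (default tab).
#' @return A tibble of solutions.
#' @export
read_solutions <- function(path, sep = "\t") {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  as_tibble(df)
}

#' Default run configuration
#'
#' The full set of tunable search parameters with their defaults:
#' f = 0.025, w1 = 0.008, w2 = 0.006, w3 = 0.003, step = 1/12,
#' max_index = 10, hkl_max = 12, h_min = 3.4 Å, gate multiplier k = 5.
#'
#' @param ... Overrides, by name.
#' @return A named list.
#' @export
run_config <- function(...) {
  cfg <- list(f = 0.025, w1 = 0.008, w2 = 0.006, w3 = 0.003, k = 5,
              step = 1 / 12, max_index = 10, hkl_max = 12, h_min = 3.4)
  modifyList(cfg, list(...))
}
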