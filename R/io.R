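# File formats: two-column spectra, 2D series containers, configuration.

#' Read a linear spectrum from two-column delimited text
#'
#' Lines starting with `#` are comments. The two numeric columns are
#' wavenumber (cm\eqn{^{-1}}) and absorbance; either axis order is accepted
#' and normalized to ascending on read.
#'
#' @param path file path.
#' @return A [linear_spectrum()].
#' @export
read_spectrum_1d <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "[,;[:space:]]+")
  bad <- which(vapply(fields, function(f)
    length(f) < 2 || anyNA(suppressWarnings(as.numeric(f[1:2]))), TRUE))
  if (length(bad))
    stop(sprintf("non-numeric row at line %d of %s", idx[bad[1]], path))
  m <- do.call(rbind, lapply(fields, function(f) as.numeric(f[1:2])))
  dup <- which(duplicated(m[, 1]))
  if (length(dup))
    stop(sprintf("duplicate frequency %.6g at line %d of %s",
                 m[dup[1], 1], idx[dup[1]], path))
  o <- order(m[, 1])
  linear_spectrum(m[o, 1], m[o, 2])
}

#' Write a linear spectrum as two-column delimited text
#'
#' @param spectrum a [linear_spectrum()].
#' @param path file path.
#' @param header optional comment lines (written with `#` prefixes).
#' @export
write_spectrum_1d <- function(spectrum, path, header = NULL) {
  stopifnot(inherits(spectrum, "linear_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# wavenumber_cm-1\tabsorbance", con)
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(sprintf("%.17g\t%.17g", spectrum$wavenumber,
                     spectrum$absorbance), con)
  invisible(path)
}

#' Write a 2D waiting-time series to a directory
#'
#' Writes `meta.json` (axes, waiting times, units, optional provenance) and
#' one tab-delimited matrix `frame_<i>.txt` per waiting time (rows =
#' omega1, columns = omega3).
#'
#' @param series a [tw_series()].
#' @param dir output directory (created if needed).
#' @param provenance optional list stored verbatim in the metadata (e.g.
#'   seed, model description).
#' @export
write_series_2d <- function(series, dir, provenance = NULL) {
  stopifnot(inherits(series, "tw_series2d"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(omega1 = series$omega1, omega3 = series$omega3,
               t_w = series$t_w,
               units = list(omega = "cm-1", t_w = "ps"),
               frames = sprintf("frame_%03d.txt", seq_along(series$t_w)))
  if (!is.null(provenance)) meta$provenance <- provenance
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  for (i in seq_along(series$spectra))
    utils::write.table(series$spectra[[i]]$amplitude,
                       file.path(dir, meta$frames[i]),
                       row.names = FALSE, col.names = FALSE, sep = "\t")
  invisible(dir)
}

#' Read a 2D waiting-time series from a directory
#'
#' Validates the metadata against the stored matrices: axis lengths vs
#' matrix dimensions, presence of every frame, strictly increasing waiting
#' times.
#'
#' @param dir directory written by [write_series_2d()].
#' @return A [tw_series()].
#' @export
read_series_2d <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) stop("missing meta.json in ", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  tws <- as.numeric(meta$t_w)
  if (length(tws) == 0 || any(diff(tws) <= 0))
    stop("metadata waiting times missing or not strictly increasing")
  frames <- lapply(seq_along(tws), function(i) {
    f <- file.path(dir, meta$frames[i])
    if (!file.exists(f)) stop("missing Tw frame: ", meta$frames[i])
    m <- as.matrix(utils::read.table(f, sep = "\t"))
    dimnames(m) <- NULL
    if (nrow(m) != length(meta$omega1) || ncol(m) != length(meta$omega3))
      stop(sprintf("shape mismatch in %s: %dx%d vs axes %dx%d",
                   meta$frames[i], nrow(m), ncol(m),
                   length(meta$omega1), length(meta$omega3)))
    spectrum2d(as.numeric(meta$omega1), as.numeric(meta$omega3), tws[i], m)
  })
  tw_series(frames)
}

#' Validated analysis configuration
#'
#' @param input either the name of a built-in fixture (see
#'   [p450_fixture()]) or a list with paths `series_dir` and `linear_path`.
#' @param seed integer seed for simulation-based inputs.
#' @param noise_sd relative noise level for simulation-based inputs.
#' @param alpha model-selection significance level.
#' @param window_frac CLS window half width as a fraction of the band FWHM.
#' @param out_dir optional output directory for reports.
#' @return An object of class `"analysis_config"`.
#' @export
analysis_config <- function(input, seed = 1, noise_sd = 0.01, alpha = 0.01,
                            window_frac = 0.6, out_dir = NULL) {
  if (is.character(input)) {
    if (!input %in% c("wt", "l358p", "pdx"))
      stop("unknown fixture name: ", input)
  } else if (is.list(input)) {
    if (is.null(input$series_dir) || is.null(input$linear_path))
      stop("list input must name 'series_dir' and 'linear_path'")
  } else stop("'input' must be a fixture name or a list of paths")
  stopifnot(is.numeric(seed), length(seed) == 1,
            is.numeric(noise_sd), noise_sd >= 0,
            is.numeric(alpha), alpha > 0, alpha < 1,
            is.numeric(window_frac), window_frac > 0)
  structure(list(input = input, seed = as.integer(seed), noise_sd = noise_sd,
                 alpha = alpha, window_frac = window_frac, out_dir = out_dir),
            class = "analysis_config")
}
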