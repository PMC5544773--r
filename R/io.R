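# Plain-text spectrum formats.
#
# Absorbance spectra: a one-line "#"-header of key=value pairs declaring
# unit, reference and N, then comma-separated rows <position>,<absorbance>.
# Water standards and index results use the same header style with three
# columns.  A minimal JCAMP-DX reader handles AFFN XYDATA blocks with a
# linear abscissa, the common export of benchtop FTIR software.

NUM_FMT <- "%.12g"

parse_header <- function(line, path) {
  if (!startsWith(line, "#"))
    stop_argument("missing '#' header line in ", path)
  toks <- strsplit(trimws(sub("^#+", "", line)), "[[:space:]]+")[[1]]
  toks <- toks[nzchar(toks)]
  kv <- strsplit(toks, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), "")
  stats::setNames(as.list(vals), keys)
}

header_unit <- function(hdr, path) {
  u <- hdr[["unit"]]
  if (is.null(u))
    stop_argument("header of ", path, " does not declare unit=")
  switch(u,
         "cm-1" = "wavenumber", "wavenumber" = "wavenumber",
         "um" = "wavelength", "wavelength" = "wavelength",
         stop_argument("unsupported unit '", u, "' in ", path))
}

read_numeric_rows <- function(all_lines, line_nos, ncol, path) {
  rows <- lapply(line_nos, function(i) {
    fields <- strsplit(trimws(all_lines[[i]]), "[,;[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) != ncol || any(!is.finite(vals)))
      stop_argument("parse error at line ", i, " of ", path,
                    ": expected ", ncol, " finite numeric fields, got '",
                    all_lines[[i]], "'")
    vals
  })
  do.call(rbind, rows)
}

#' Read and write absorbance spectra as delimited text
#'
#' The text dialect is one header line, e.g.
#' `# unit=cm-1 reference=atmosphere n_reflections=10`, followed by
#' comma-separated `<position>,<absorbance>` rows.  An optional non-numeric
#' column-title row after the header is skipped.  `dialect = "jcamp"` reads
#' a JCAMP-DX absorbance block instead (AFFN `(X++(Y..Y))` data, linear
#' abscissa only).  A write/read round trip preserves values to 1e-9
#' relative and metadata exactly.
#'
#' @param path file path.
#' @param dialect `"csv"` or `"jcamp"`.
#' @return [read_spectrum()] returns an [absorbance_spectrum()];
#'   [write_spectrum()] returns `path` invisibly.
#' @export
read_spectrum <- function(path, dialect = c("csv", "jcamp")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_argument("file not found: ", path)
  if (dialect == "jcamp") return(read_jcamp(path))
  lines <- readLines(path, warn = FALSE)
  lines_keep <- which(nzchar(trimws(lines)))
  if (!length(lines_keep)) stop_argument("empty spectrum file: ", path)
  first <- lines_keep[1]
  hdr <- parse_header(lines[first], path)
  unit <- header_unit(hdr, path)
  reference <- hdr[["reference"]] %||% "atmosphere"
  nref <- as.integer(hdr[["n_reflections"]] %||% "1")
  body_idx <- lines_keep[-1]
  if (length(body_idx) &&
      is.na(suppressWarnings(as.numeric(
        strsplit(trimws(lines[body_idx[1]]), "[,;[:space:]]+")[[1]][1]))))
    body_idx <- body_idx[-1]
  if (length(body_idx) < 2)
    stop_argument("spectrum file ", path, " has fewer than 2 data rows")
  m <- read_numeric_rows(lines, body_idx, 2L, path)
  absorbance_spectrum(spectral_axis(m[, 1], unit), m[, 2],
                      reference = reference, n_reflections = nref)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_spectrum
#' @param spectrum an [absorbance_spectrum()].
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "absorbance_spectrum"))
  unit <- if (spectrum$axis$unit == "wavenumber") "cm-1" else "um"
  hdr <- sprintf("# unit=%s reference=%s n_reflections=%d",
                 unit, spectrum$reference, spectrum$n_reflections)
  rows <- sprintf(paste0(NUM_FMT, ",", NUM_FMT),
                  spectrum$axis$values, spectrum$a)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read and write a water optical-constants table
#'
#' Three columns `<position>,<n>,<k>` after a `# unit=...` header.
#'
#' @param path file path.
#' @param standard a [water_standard()].
#' @param coverage_um required wavelength coverage, passed to
#'   [water_standard()].
#' @return A [water_standard()], or `path` invisibly for the writer.
#' @export
read_water_standard <- function(path, coverage_um = c(1.67, 200)) {
  if (!file.exists(path)) stop_argument("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines_keep <- which(nzchar(trimws(lines)))
  if (!length(lines_keep)) stop_argument("empty standard file: ", path)
  hdr <- parse_header(lines[lines_keep[1]], path)
  unit <- header_unit(hdr, path)
  m <- read_numeric_rows(lines, lines_keep[-1], 3L, path)
  water_standard(spectral_axis(m[, 1], unit), m[, 2], m[, 3],
                 coverage_um = coverage_um)
}

#' @rdname read_water_standard
#' @export
write_water_standard <- function(standard, path) {
  stopifnot(inherits(standard, "water_standard"))
  rows <- sprintf(paste0(NUM_FMT, ",", NUM_FMT, ",", NUM_FMT),
                  standard$nu, standard$n_ref, standard$k_ref)
  writeLines(c("# unit=cm-1 columns=wavenumber,n,k", rows), path)
  invisible(path)
}

#' Read and write a calibrated penetration-depth curve
#'
#' Three columns `<wavelength um>,<d_eff um>,<valid 0/1>`, so one water
#' calibration can be reused across all samples from a session.
#'
#' @param path file path.
#' @param curve a [penetration_depth_curve()].
#' @return A [penetration_depth_curve()], or `path` invisibly.
#' @export
read_deff <- function(path) {
  if (!file.exists(path)) stop_argument("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines_keep <- which(nzchar(trimws(lines)))
  if (!length(lines_keep)) stop_argument("empty d_eff file: ", path)
  hdr <- parse_header(lines[lines_keep[1]], path)
  nref <- as.integer(hdr[["n_reflections"]] %||% "1")
  m <- read_numeric_rows(lines, lines_keep[-1], 3L, path)
  penetration_depth_curve(spectral_axis(m[, 1], "wavelength"), m[, 2],
                          valid = m[, 3] != 0, n_reflections = nref)
}

#' @rdname read_deff
#' @export
write_deff <- function(curve, path) {
  stopifnot(inherits(curve, "penetration_depth_curve"))
  wl <- axis_wavelength(curve$axis)
  rows <- sprintf(paste0(NUM_FMT, ",", NUM_FMT, ",%d"),
                  wl, curve$d_eff, as.integer(curve$valid))
  writeLines(c(sprintf(
    "# unit=um columns=wavelength,d_eff,valid n_reflections=%d",
    curve$n_reflections), rows), path)
  invisible(path)
}

#' Write a complex index result as three-column text
#'
#' Columns are wavelength (um), n (or delta-n) and k (or delta-k), matching
#' the layout of deposited refractive-index datasets.  Masked points are
#' written with a 0 in the trailing `valid` column.
#'
#' @param index a [complex_index_spectrum()].
#' @param path file path.
#' @export
write_index <- function(index, path) {
  stopifnot(inherits(index, "complex_index_spectrum"))
  wl <- axis_wavelength(index$axis)
  lab <- if (index$differential) "dn,dk" else "n,k"
  rows <- sprintf(paste0(NUM_FMT, ",", NUM_FMT, ",", NUM_FMT, ",%d"),
                  wl, index$n, index$k, as.integer(index$valid))
  writeLines(c(sprintf("# unit=um columns=wavelength,%s,valid%s", lab,
                       if (index$differential) " differential=1" else ""),
               rows), path)
  invisible(path)
}

# Minimal JCAMP-DX absorbance reader: AFFN "(X++(Y..Y))" tables on a linear
# abscissa.  Compressed (SQZ/DIF/DUP) encodings are not supported.
read_jcamp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  labels <- list()
  data_start <- NA_integer_
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (startsWith(ln, "##")) {
      eq <- regexpr("=", ln, fixed = TRUE)
      if (eq < 0) next
      key <- toupper(trimws(substr(ln, 3, eq - 1)))
      val <- trimws(substr(ln, eq + 1, nchar(ln)))
      labels[[key]] <- val
      if (key == "XYDATA") {
        if (gsub("[[:space:]]", "", val) != "(X++(Y..Y))")
          stop_argument("unsupported XYDATA form '", val, "' in ", path)
        data_start <- i + 1L
        break
      }
    }
  }
  if (is.na(data_start))
    stop_argument("no ##XYDATA=(X++(Y..Y)) block found in ", path)
  need <- function(key) {
    v <- suppressWarnings(as.numeric(labels[[key]]))
    if (is.null(labels[[key]]) || is.na(v))
      stop_argument("JCAMP file ", path, " is missing numeric ##", key)
    v
  }
  firstx <- need("FIRSTX"); lastx <- need("LASTX")
  npoints <- as.integer(need("NPOINTS"))
  xfactor <- if (is.null(labels[["XFACTOR"]])) 1 else need("XFACTOR")
  yfactor <- if (is.null(labels[["YFACTOR"]])) 1 else need("YFACTOR")
  xunits <- toupper(labels[["XUNITS"]] %||% "1/CM")
  unit <- switch(xunits,
                 "1/CM" = "wavenumber", "MICROMETERS" = "wavelength",
                 stop_argument("unsupported ##XUNITS '", xunits,
                               "' in ", path))
  y <- numeric(0)
  for (i in seq(data_start, length(lines))) {
    ln <- trimws(lines[[i]])
    if (startsWith(ln, "##")) break
    if (!nzchar(ln)) next
    vals <- suppressWarnings(as.numeric(strsplit(ln, "[,;[:space:]]+")[[1]]))
    if (any(is.na(vals)))
      stop_argument("parse error at line ", i, " of ", path)
    y <- c(y, vals[-1] * yfactor)  # leading token is the line's X check value
  }
  if (length(y) != npoints)
    stop_argument("JCAMP file ", path, " declares ", npoints,
                  " points but contains ", length(y))
  x <- seq(firstx, lastx, length.out = npoints) * xfactor
  reference <- labels[["$REFERENCE"]] %||% "atmosphere"
  nref <- as.integer(labels[["$NREFLECTIONS"]] %||% "1")
  absorbance_spectrum(spectral_axis(x, unit), y,
                      reference = reference, n_reflections = nref)
}
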