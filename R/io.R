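#' Read and write two-column spectrum text files
#'
#' The on-disk format mirrors instrument-exported text: optional `#`-prefixed
#' header lines holding `key=value` metadata, followed by one row per grid
#' point with the wavenumber (cm^-1) and the intensity, delimited by
#' whitespace or commas. Wavenumbers may be ascending or descending
#' (descending input is reversed on read); non-uniform spacing is accepted
#' and flagged on the returned grid.
#'
#' @param path File path.
#' @return `read_spectrum_txt()` returns a [raman_spectrum()]; header
#'   metadata is kept in its `meta` field (recognised keys: `cell_id`, `x`,
#'   `y`, `label`).
#' @examples
#' f <- tempfile(fileext = ".txt")
#' s <- raman_spectrum(1:32 / 10, wn_grid(700, 1, 32), cell_id = "c1")
#' write_spectrum_txt(s, f)
#' identical(read_spectrum_txt(f)$cell_id, "c1")
#' @export
read_spectrum_txt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_meta <- grepl("^\\s*#", lines)
  meta <- character()
  for (ml in lines[is_meta]) {
    ml <- sub("^\\s*#\\s*", "", ml)
    if (grepl("=", ml, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", ml))
      val <- trimws(sub("^[^=]*=", "", ml))
      meta[key] <- val
    }
  }
  data_lines <- lines[!is_meta]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  if (length(data_lines) < 2L)
    stop(sprintf("format error in '%s': fewer than 2 data points", path),
         call. = FALSE)
  line_no <- which(!is_meta)[nzchar(trimws(lines[!is_meta]))]
  parts <- strsplit(trimws(data_lines), "[,[:space:]]+")
  ncols <- lengths(parts)
  if (any(ncols < 2L))
    stop(sprintf("parse error in '%s' at line %d: expected >= 2 columns",
                 path, line_no[which(ncols < 2L)[1]]), call. = FALSE)
  wn <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  y <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  bad <- which(!is.finite(wn) | !is.finite(y))
  if (length(bad))
    stop(sprintf("parse error in '%s' at line %d: non-numeric value",
                 path, line_no[bad[1]]), call. = FALSE)
  if (all(diff(wn) < 0)) {       # descending export
    wn <- rev(wn)
    y <- rev(y)
  }
  grid <- grid_from_wavenumbers(wn)
  mget0 <- function(key) if (key %in% names(meta)) meta[[key]] else NULL
  raman_spectrum(y, grid,
                 cell_id = mget0("cell_id") %||%
                   sub("\\.[^.]*$", "", basename(path)),
                 x = as.numeric(mget0("x") %||% NA),
                 y = as.numeric(mget0("y") %||% NA),
                 label = mget0("label") %||% NA_character_,
                 processed = identical(mget0("processed"), "TRUE"),
                 meta = meta)
}

#' @param spectrum A [raman_spectrum()].
#' @param digits Significant digits written (print precision of the round
#'   trip).
#' @rdname read_spectrum_txt
#' @return `write_spectrum_txt()` returns `path`, invisibly. Output is
#'   tab-delimited, UTF-8, `.` decimal separator.
#' @export
write_spectrum_txt <- function(spectrum, path, digits = 10) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  meta <- spectrum$meta
  meta["cell_id"] <- spectrum$cell_id
  if (!is.na(spectrum$x)) meta["x"] <- format(spectrum$x)
  if (!is.na(spectrum$y)) meta["y"] <- format(spectrum$y)
  if (!is.na(spectrum$label)) meta["label"] <- spectrum$label
  if (isTRUE(spectrum$processed)) meta["processed"] <- "TRUE"
  writeLines(sprintf("# %s=%s", names(meta), meta), con)
  wn <- grid_values(spectrum$grid)
  writeLines(paste(formatC(wn, digits = digits, format = "g"),
                   formatC(spectrum$intensities, digits = digits, format = "g"),
                   sep = "\t"), con)
  invisible(path)
}

#' Read and write cohort CSV matrices
#'
#' A cohort CSV holds one spectrum per row. The header is
#' `cell_id,x,y,label,<wn1>,<wn2>,...` with the remaining column names being
#' the wavenumbers in cm^-1; the grid is inferred from them. Writing then
#' reading preserves intensities to full double print precision.
#'
#' @param path File path.
#' @return `read_cohort_csv()` returns an [scrs_set()].
#' @export
read_cohort_csv <- function(path) {
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(unique(nf)) != 1L)
    stop(sprintf("format error in '%s': ragged rows (line %d)", path,
                 which(nf != nf[1])[1]), call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  fixed <- c("cell_id", "x", "y", "label")
  if (!all(fixed %in% names(df)[seq_along(fixed)]))
    stop(sprintf("format error in '%s': header must start with %s", path,
                 paste(fixed, collapse = ",")), call. = FALSE)
  wn_cols <- setdiff(names(df), fixed)
  wn <- suppressWarnings(as.numeric(wn_cols))
  if (any(!is.finite(wn)))
    stop(sprintf("format error in '%s': non-numeric wavenumber column '%s'",
                 path, wn_cols[which(!is.finite(wn))[1]]), call. = FALSE)
  grid <- grid_from_wavenumbers(wn)
  mat <- as.matrix(df[, wn_cols, drop = FALSE])
  storage.mode(mat) <- "double"
  meta <- df[, fixed]
  meta$label <- ifelse(meta$label == "" | is.na(meta$label),
                       NA_character_, as.character(meta$label))
  scrs_set(mat, grid, meta)
}

#' @param set An [scrs_set()].
#' @rdname read_cohort_csv
#' @return `write_cohort_csv()` returns `path`, invisibly.
#' @export
write_cohort_csv <- function(set, path) {
  stopifnot(inherits(set, "scrs_set"))
  wn <- grid_values(set$grid)
  df <- data.frame(cell_id = set$meta$cell_id, x = set$meta$x, y = set$meta$y,
                   label = ifelse(is.na(set$meta$label), "", set$meta$label),
                   check.names = FALSE)
  mat <- as.data.frame(set$intensities)
  names(mat) <- format(wn, trim = TRUE, digits = 10)
  utils::write.csv(cbind(df, mat), path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Resample a spectrum onto a target grid
#'
#' Linear interpolation of intensities at the target grid points, used to
#' co-register instrument exports onto the default analysis grid. Endpoints
#' are reproduced exactly when the grids share points. The target grid must
#' lie within the source wavenumber range.
#'
#' @param spectrum A [raman_spectrum()].
#' @param grid Target [wn_grid()].
#' @return A [raman_spectrum()] on `grid`.
#' @export
resample_to_grid <- function(spectrum, grid) {
  stopifnot(inherits(spectrum, "raman_spectrum"), inherits(grid, "wn_grid"))
  src <- grid_values(spectrum$grid)
  dst <- wavenumbers(grid)
  eps <- 1e-9 * max(abs(src))
  if (min(dst) < min(src) - eps || max(dst) > max(src) + eps)
    stop(sprintf("range error: target grid [%g, %g] extends beyond source [%g, %g]",
                 min(dst), max(dst), min(src), max(src)), call. = FALSE)
  y <- stats::approx(src, spectrum$intensities, xout = pmin(pmax(dst, min(src)),
                                                            max(src)))$y
  raman_spectrum(y, grid, cell_id = spectrum$cell_id, x = spectrum$x,
                 y = spectrum$y, label = spectrum$label,
                 processed = spectrum$processed, meta = spectrum$meta)
}
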