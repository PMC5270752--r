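#' Uniform wavenumber grid
#'
#' A wavenumber axis for Raman spectra, defined by its first point, its step
#' and its length. The package default emulates a confocal Raman acquisition
#' at ~1 cm\eqn{^{-1}} spectral resolution with 1019 data points, covering
#' 700--1718 cm\eqn{^{-1}} so that every biomarker band used by the
#' classifier (785, 839, 997--1007, 1058, 1123, 1145--1161, 1245, 1403, 1450,
#' 1503--1526, 1660 cm\eqn{^{-1}}) lies inside the axis.
#'
#' @param start First wavenumber (cm^-1).
#' @param step Grid spacing (cm^-1 per point); must be > 0.
#' @param n_points Number of grid points; must be >= 2.
#' @return An object of class `wn_grid`.
#' @examples
#' g <- default_grid()
#' g$n_points      # 1019
#' range(wavenumbers(g))
#' @export
wn_grid <- function(start = 700, step = 1, n_points = 1019L) {
  if (!is.numeric(step) || length(step) != 1L || !is.finite(step) || step <= 0)
    stop("`step` must be a positive number", call. = FALSE)
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 2L)
    stop("`n_points` must be an integer >= 2", call. = FALSE)
  if (!is.numeric(start) || length(start) != 1L || !is.finite(start))
    stop("`start` must be a finite number", call. = FALSE)
  structure(list(start = as.numeric(start), step = as.numeric(step),
                 n_points = n_points),
            class = "wn_grid")
}

#' @rdname wn_grid
#' @export
default_grid <- function() wn_grid(700, 1, 1019L)

#' @param grid A `wn_grid`.
#' @rdname wn_grid
#' @return `wavenumbers()` returns the numeric vector of grid values
#'   (strictly increasing).
#' @export
wavenumbers <- function(grid) {
  stopifnot(inherits(grid, "wn_grid"))
  grid$start + grid$step * (seq_len(grid$n_points) - 1)
}

#' @export
print.wn_grid <- function(x, ...) {
  cat(sprintf("<wn_grid> %g-%g cm^-1, step %g, %d points\n",
              x$start, x$start + x$step * (x$n_points - 1), x$step,
              x$n_points))
  invisible(x)
}

grids_equal <- function(a, b, tol = 1e-9) {
  abs(a$start - b$start) <= tol && abs(a$step - b$step) <= tol &&
    a$n_points == b$n_points
}

# Infer a wn_grid from an explicit vector of wavenumbers; flags non-uniform
# spacing rather than rejecting it (real instrument exports drift slightly).
grid_from_wavenumbers <- function(wn, tol = 1e-6) {
  n <- length(wn)
  if (n < 2L) stop("need at least 2 wavenumbers", call. = FALSE)
  if (any(diff(wn) <= 0)) stop("wavenumbers must be strictly increasing",
                               call. = FALSE)
  step <- (wn[n] - wn[1]) / (n - 1)
  g <- wn_grid(wn[1], step, n)
  attr(g, "uniform") <- max(abs(wavenumbers(g) - wn)) <= tol * max(abs(wn))
  if (!isTRUE(attr(g, "uniform"))) attr(g, "wavenumbers") <- wn
  g
}

# Actual axis values, honouring a stored non-uniform axis if present.
grid_values <- function(grid) {
  wn <- attr(grid, "wavenumbers")
  if (is.null(wn)) wavenumbers(grid) else wn
}
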