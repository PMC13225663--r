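#' Spatial geometry of a binned environment
#'
#' Describes the discretised environment on which place fields live: a 1D
#' linear track split into `n_bins` equal bins, or a 2D grid. Bin coordinates
#' are 0-based (the first bin has coordinate 0), bins are half-open intervals
#' `[edge_i, edge_{i+1})`, and a position exactly at the track end falls in
#' the last bin.
#'
#' @param n_bins integer vector: number of bins, length 1 for a linear track
#'   (default 50) or length 2 for a grid (e.g. `c(10, 10)`).
#' @param bin_width width of one bin in track units (purely informational for
#'   simulation; used when binning empirical positions).
#' @return An object of class `"geometry"`: a list with `dims`, `n_bins`
#'   (per-dimension counts), `bin_width` and `total_bins`.
#' @examples
#' geometry(50)
#' geometry(c(10, 10))
#' @export
geometry <- function(n_bins = 50L, bin_width = 1) {
  n_bins <- as.integer(n_bins)
  if (!length(n_bins) %in% c(1L, 2L))
    stop("n_bins must have length 1 (linear track) or 2 (grid)")
  if (any(is.na(n_bins)) || any(n_bins < 1L))
    stop("n_bins must be positive integers")
  if (prod(n_bins) < 2L)
    stop("total bin count must be at least 2")
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
    stop("bin_width must be a positive scalar")
  structure(
    list(dims = length(n_bins), n_bins = n_bins,
         bin_width = bin_width, total_bins = prod(n_bins)),
    class = "geometry"
  )
}

#' @export
print.geometry <- function(x, ...) {
  if (x$dims == 1L) {
    cat(sprintf("<geometry> 1D linear track, %d bins (bin width %g)\n",
                x$n_bins, x$bin_width))
  } else {
    cat(sprintf("<geometry> 2D grid, %d x %d bins (bin width %g)\n",
                x$n_bins[1], x$n_bins[2], x$bin_width))
  }
  invisible(x)
}

#' Bin-centre coordinates of a geometry
#'
#' Returns the 0-based coordinate of every bin. For 2D geometries bins are
#' flattened row-major (the second dimension varies fastest), and a two-column
#' matrix of (x, y) coordinates is returned.
#'
#' @param geom a [geometry()] object.
#' @return numeric vector (1D) or `total_bins` x 2 matrix (2D).
#' @export
bin_coords <- function(geom) {
  stopifnot(inherits(geom, "geometry"))
  if (geom$dims == 1L) {
    seq_len(geom$n_bins) - 1
  } else {
    xs <- seq_len(geom$n_bins[1]) - 1
    ys <- seq_len(geom$n_bins[2]) - 1
    cbind(x = rep(xs, each = geom$n_bins[2]),
          y = rep(ys, times = geom$n_bins[1]))
  }
}
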