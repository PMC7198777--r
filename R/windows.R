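#' Circular distance between genomic positions
#'
#' Distance on a circular chromosome of length `L`: the shorter of the two
#' arcs between `a` and `b`.
#'
#' @param a,b Positions in bp (0-based). Vectorised.
#' @param L Genome length in bp.
#' @return Numeric vector of distances in bp, each in `[0, L/2]`.
#' @export
circular_distance <- function(a, b, L) {
  d <- abs(a - b) %% L
  pmin(d, L - d)
}

#' Normalised origin distance
#'
#' `delta = 2 * d(position, ori) / L`, the position of a locus on the
#' ori-to-ter axis: 0 at the origin, 1 at the antipodal terminus.
#'
#' @param position Position in bp (vectorised).
#' @param ori Origin position in bp.
#' @param L Genome length in bp.
#' @return Numeric vector in `[0, 1]`.
#' @export
origin_delta <- function(position, ori, L) {
  2 * circular_distance(position, ori, L) / L
}

#' Window grid over a circular genome
#'
#' Tiles the circle with non-overlapping windows of `window` bp. Windows wrap:
#' if the genome length is not a multiple of the window size, the trailing
#' remainder merges into window 0 when it is shorter than half a window, and
#' otherwise stands as a final truncated window.
#'
#' @param L Genome length in bp.
#' @param window Window size in bp.
#' @return A list with `n` (number of windows), `starts` (0-based window
#'   starts), `widths` (window widths in bp; window 0 includes any merged
#'   wrap-around remainder), and `merged_tail` (logical).
#' @export
window_grid <- function(L, window) {
  stopifnot(L >= 1, window >= 1, window <= L)
  n0 <- L %/% window
  rem <- L %% window
  if (rem == 0L) {
    list(n = n0, starts = (seq_len(n0) - 1) * window,
         widths = rep(window, n0), merged_tail = FALSE)
  } else if (rem < window / 2) {
    widths <- rep(window, n0)
    widths[1] <- window + rem  # window 0 also covers [n0*window, L)
    list(n = n0, starts = (seq_len(n0) - 1) * window,
         widths = widths, merged_tail = TRUE)
  } else {
    list(n = n0 + 1L, starts = (seq_len(n0 + 1L) - 1) * window,
         widths = c(rep(window, n0), rem), merged_tail = FALSE)
  }
}

#' Window index of base positions
#'
#' Maps 0-based base positions to the index (1-based) of the window of a
#' [window_grid()] that contains them.
#'
#' @param position 0-based positions in `[0, L)`.
#' @param grid A grid from [window_grid()].
#' @param window Window size used to build the grid.
#' @return Integer window indices in `1..grid$n`.
#' @keywords internal
window_index <- function(position, grid, window) {
  idx <- (position %/% window) + 1L
  idx[idx > grid$n] <- 1L  # merged wrap-around tail belongs to window 0
  as.integer(idx)
}

#' Window midpoints of a grid
#' @param grid A grid from [window_grid()].
#' @param L Genome length (needed because window 0 may wrap).
#' @return Midpoint positions in bp (mod L).
#' @keywords internal
window_midpoints <- function(grid, L) {
  (grid$starts + grid$widths / 2) %% L
}

#' Round half away from zero
#'
#' Commercial rounding: 0.5 rounds to 1, -0.5 to -1 (unlike base R's
#' round-half-even). Used for copy-number bounds.
#'
#' @param x Numeric vector.
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Circular moving average
#'
#' Centred boxcar moving average with wrap-around; `NA`s are filled by
#' circular linear interpolation before smoothing.
#'
#' @param x Numeric vector (one value per window around the circle).
#' @param span Odd integer window count; even spans are raised by one.
#' @return Smoothed numeric vector of the same length.
#' @export
circular_moving_average <- function(x, span = 5L) {
  n <- length(x)
  if (span %% 2 == 0) span <- span + 1L
  if (span >= n) span <- if (n %% 2 == 1) n else n - 1L
  x <- fill_na_circular(x)
  h <- (span - 1L) %/% 2L
  idx <- outer(seq_len(n), -h:h, function(i, k) ((i - 1 + k) %% n) + 1)
  rowMeans(matrix(x[idx], nrow = n))
}

# Circular linear interpolation over NA runs.
fill_na_circular <- function(x) {
  if (!anyNA(x)) return(x)
  n <- length(x)
  ok <- which(!is.na(x))
  if (length(ok) == 0) stop("all values are NA; nothing to interpolate")
  for (i in which(is.na(x))) {
    lo <- ok[findInterval(i, ok)]
    if (length(lo) == 0 || is.na(lo)) lo <- ok[length(ok)]
    hi <- ok[which(ok > i)[1]]
    if (is.na(hi)) hi <- ok[1]
    gap <- (hi - lo) %% n
    if (gap == 0) { x[i] <- x[lo]; next }
    w <- ((i - lo) %% n) / gap
    x[i] <- (1 - w) * x[lo] + w * x[hi]
  }
  x
}
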