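#' Windowed profile container
#' @keywords internal
windowed_profile <- function(values, window, step, starts, genome_length,
                             kind, n_degenerate = 0L) {
  structure(
    list(values = as.numeric(values), window = window, step = step,
         starts = starts, genome_length = genome_length, kind = kind,
         n_degenerate = n_degenerate),
    class = "windowed_profile"
  )
}

#' @export
print.windowed_profile <- function(x, ...) {
  cat(sprintf("<windowed_profile> %s: %d windows of %d bp (step %d) over %s bp\n",
              x$kind, length(x$values), x$window, x$step,
              format(x$genome_length, big.mark = ",")))
  invisible(x)
}

#' Windowed GC skew of a circular genome
#'
#' Per window, `S = (nG - nC) / (nG + nC)` on the published strand, the
#' classic strand-composition statistic whose sign switches at the
#' replication origin and terminus. Windows wrap around the circle. `N`
#' bases are excluded from both counts; windows with no G or C at all get
#' `S = 0` (a logged degenerate-window convention that keeps cumulative sums
#' total).
#'
#' @param genome A [circular_genome()].
#' @param window Window size in bp (`0 < window <= L`).
#' @param step Step between window starts in bp; defaults to `window`
#'   (non-overlapping tiling with wrap-around merging, see [window_grid()]).
#'   A smaller step gives overlapping windows anchored every `step` bp.
#' @return A `windowed_profile` of kind `"gc_skew"`; `n_degenerate` counts
#'   the zero-convention windows.
#' @export
compute_gc_skew <- function(genome, window = 10000L, step = window) {
  stopifnot(inherits(genome, "circular_genome"))
  L <- genome$length
  stopifnot(window >= 1, window <= L, step >= 1, step <= window)
  chars <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]
  is_g <- chars == "G"
  is_c <- chars == "C"

  if (step == window) {
    grid <- window_grid(L, window)
    idx <- window_index(0:(L - 1), grid, window)
    nG <- as.numeric(tabulate(idx[is_g], nbins = grid$n))
    nC <- as.numeric(tabulate(idx[is_c], nbins = grid$n))
    starts <- grid$starts
  } else {
    starts <- seq(0, L - 1, by = step)
    csG <- c(0, cumsum(is_g))
    csC <- c(0, cumsum(is_c))
    count_circ <- function(cs, from, width) {
      to <- from + width
      wrap <- to > L
      out <- numeric(length(from))
      out[!wrap] <- cs[to[!wrap] + 1] - cs[from[!wrap] + 1]
      out[wrap] <- (cs[L + 1] - cs[from[wrap] + 1]) + cs[to[wrap] - L + 1]
      out
    }
    nG <- count_circ(csG, starts, window)
    nC <- count_circ(csC, starts, window)
  }
  tot <- nG + nC
  vals <- ifelse(tot == 0, 0, (nG - nC) / tot)
  windowed_profile(vals, window, step, starts, L, "gc_skew",
                   n_degenerate = sum(tot == 0))
}

#' Windowed CDS skew from a gene set
#'
#' Per window, `S = (F - R) / (F + R)` where F and R count genes whose
#' midpoint falls in the window on the forward and reverse strand. Genes are
#' assigned to a single window by midpoint, so border-spanning genes are not
#' double-counted. Empty windows get `S = 0`.
#'
#' @param genes A data.frame with 0-based half-open `start`, `end` and
#'   `strand` (`"+"`/`"-"`), e.g. from [generate_annotations()] or
#'   [read_genes_gff3()].
#' @param genome_length Genome length in bp.
#' @param window Window size in bp.
#' @return A `windowed_profile` of kind `"cds_skew"`.
#' @export
compute_cds_skew <- function(genes, genome_length, window = 10000L) {
  stopifnot(window >= 1, window <= genome_length)
  grid <- window_grid(genome_length, window)
  if (nrow(genes) == 0) {
    message("empty gene list: all-zero CDS skew profile")
    return(windowed_profile(rep(0, grid$n), window, window, grid$starts,
                            genome_length, "cds_skew",
                            n_degenerate = grid$n))
  }
  stopifnot(all(genes$start >= 0), all(genes$start < genes$end),
            all(genes$end <= genome_length),
            all(genes$strand %in% c("+", "-")))
  mid <- ((genes$start + genes$end) %/% 2) %% genome_length
  idx <- window_index(mid, grid, window)
  fwd <- as.numeric(tabulate(idx[genes$strand == "+"], nbins = grid$n))
  rev <- as.numeric(tabulate(idx[genes$strand == "-"], nbins = grid$n))
  tot <- fwd + rev
  vals <- ifelse(tot == 0, 0, (fwd - rev) / tot)
  windowed_profile(vals, window, window, grid$starts, genome_length,
                   "cds_skew", n_degenerate = sum(tot == 0))
}

#' Cumulative profile
#'
#' Running sum of a windowed profile; the replication origin and terminus of
#' a skewed genome appear as the global extrema of its cumulative skew.
#' Differencing the result recovers the parent values exactly.
#'
#' @param profile A `windowed_profile` (non-overlapping windows).
#' @return An object of class `cumulative_profile` with `positions` (the bp
#'   boundary at the end of each window, mod L), `cum_values` and `parent`.
#' @export
cumulative_profile <- function(profile) {
  stopifnot(inherits(profile, "windowed_profile"),
            length(profile$values) > 0)
  grid <- window_grid(profile$genome_length, profile$window)
  structure(
    list(positions = (grid$starts + grid$widths) %% profile$genome_length,
         cum_values = cumsum(profile$values),
         parent = profile),
    class = "cumulative_profile"
  )
}

#' Detect skew shift points on a circular cumulative profile
#'
#' Finds the candidate origin and terminus as the global minimum and maximum
#' of the rotation-adjusted cumulative profile: the running sum of the
#' mean-centred window values. Mean-centring makes the call independent of
#' where the deposited sequence was linearised (cumulative skew of a circle
#' otherwise depends on the starting point). Under the G-rich-leading-strand
#' convention, cumulative GC skew falls towards the origin and rises towards
#' the terminus, so ori is the argmin and ter the argmax; a genome with the
#' opposite polarity simply has the two labels swapped.
#'
#' V-shape regularity is scored as `R2_v`, the coefficient of determination
#' of the best two-segment piecewise-linear circular fit — the "tent"
#' interpolating linearly between the two extrema along both arcs. An ideal
#' two-segment profile scores 1; noise profiles score low.
#'
#' @param cum A [cumulative_profile()] with at least 8 windows.
#' @param r2_threshold Regularity threshold for `is_v_shaped`
#'   (default 0.90).
#' @return An object of class `shift_point_call` with `ori_candidate`,
#'   `ter_candidate` (bp; `NA` when no call), `r2_v` and `is_v_shaped`.
#' @export
detect_shift_points <- function(cum, r2_threshold = 0.90) {
  stopifnot(inherits(cum, "cumulative_profile"))
  vals <- cum$parent$values
  n <- length(vals)
  if (n < 8) stop("need at least 8 windows to call shift points")
  adj <- cumsum(vals - mean(vals))
  if (all(vals == 0) || sum((adj - mean(adj))^2) == 0) {
    warning("degenerate (flat) profile: no shift-point call")
    return(structure(
      list(ori_candidate = NA_real_, ter_candidate = NA_real_,
           r2_v = NA_real_, is_v_shaped = FALSE),
      class = "shift_point_call"
    ))
  }
  i_min <- which.min(adj)
  i_max <- which.max(adj)
  fit <- circular_tent_fit(adj, i_min, i_max)
  structure(
    list(ori_candidate = cum$positions[i_min],
         ter_candidate = cum$positions[i_max],
         r2_v = fit$r2, is_v_shaped = fit$r2 >= r2_threshold),
    class = "shift_point_call"
  )
}

#' @export
print.shift_point_call <- function(x, ...) {
  if (is.na(x$ori_candidate)) {
    cat("<shift_point_call> no call (degenerate profile)\n")
  } else {
    cat(sprintf(
      "<shift_point_call> ori ~ %s bp, ter ~ %s bp, R2_v = %.3f (%sV-shaped)\n",
      format(x$ori_candidate, big.mark = ","),
      format(x$ter_candidate, big.mark = ","),
      x$r2_v, if (x$is_v_shaped) "" else "not "))
  }
  invisible(x)
}

# Two-segment piecewise-linear circular fit ("tent") through the values at
# indices i_lo and i_hi; returns fitted values and R^2 against y.
circular_tent_fit <- function(y, i_lo, i_hi) {
  n <- length(y)
  if (i_lo == i_hi) return(list(fitted = rep(y[i_lo], n), r2 = 0))
  fitted <- numeric(n)
  arc1 <- (i_hi - i_lo) %% n          # i_lo -> i_hi forward
  arc2 <- n - arc1                    # i_hi -> i_lo forward
  for (i in seq_len(n)) {
    d1 <- (i - i_lo) %% n
    if (d1 <= arc1) {
      w <- if (arc1 == 0) 0 else d1 / arc1
      fitted[i] <- (1 - w) * y[i_lo] + w * y[i_hi]
    } else {
      d2 <- (i - i_hi) %% n
      w <- if (arc2 == 0) 0 else d2 / arc2
      fitted[i] <- (1 - w) * y[i_hi] + w * y[i_lo]
    }
  }
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(fitted = fitted, r2 = if (ss_tot == 0) 0 else 1 - ss_res / ss_tot)
}
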