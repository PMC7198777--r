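#' Read trimming parameters
#'
#' Quality-trimming settings for sequencing reads ahead of marker frequency
#' analysis: fixed clipping of `trim_5prime` nt from the 5' end and
#' `trim_3prime` nt from the 3' end, then end-trimming to the longest
#' contiguous segment whose bases all exceed `min_phred`, then removal of
#' reads shorter than `min_length`. The length filter is read as a minimum
#' post-trim length (quality control discards reads truncated below it).
#'
#' @param min_phred Phred threshold; bases must score strictly above it
#'   (default 30).
#' @param trim_5prime Fixed 5' clip in nt (default 15).
#' @param trim_3prime Fixed 3' clip in nt (default 2).
#' @param min_length Minimum retained read length in nt (default 100).
#' @return An object of class `trim_params`.
#' @export
trim_params <- function(min_phred = 30L, trim_5prime = 15L, trim_3prime = 2L,
                        min_length = 100L) {
  stopifnot(min_phred >= 0, trim_5prime >= 0, trim_3prime >= 0,
            min_length >= 0)
  structure(
    list(min_phred = min_phred, trim_5prime = trim_5prime,
         trim_3prime = trim_3prime, min_length = min_length),
    class = "trim_params"
  )
}

#' Read records
#'
#' Container pairing read sequences with per-base Phred qualities.
#'
#' @param bases Character vector of read sequences.
#' @param qualities List of integer vectors of per-base Phred scores, one per
#'   read, each the same length as its read.
#' @return An object of class `read_records`.
#' @export
read_records <- function(bases, qualities) {
  stopifnot(length(bases) == length(qualities),
            all(nchar(bases) == lengths(qualities)))
  structure(list(bases = bases, qualities = qualities),
            class = "read_records")
}

#' @export
length.read_records <- function(x) length(x$bases)

#' Quality-trim sequencing reads
#'
#' Applies the trimming scheme of [trim_params()] to each read and reports a
#' QC summary. An empty input yields an empty output with a warning.
#'
#' @param reads A [read_records()] object.
#' @param params A [trim_params()] object.
#' @return A list with `reads` (trimmed [read_records()]) and `qc` (a list
#'   with `n_input`, `n_retained`, `retained_fraction`, `mean_length`).
#' @export
trim_reads <- function(reads, params = trim_params()) {
  stopifnot(inherits(reads, "read_records"), inherits(params, "trim_params"))
  n_in <- length(reads)
  if (n_in == 0) {
    warning("no reads to trim")
    return(list(reads = reads,
                qc = list(n_input = 0L, n_retained = 0L,
                          retained_fraction = NaN, mean_length = NaN)))
  }
  out_bases <- character(0)
  out_quals <- list()
  for (i in seq_len(n_in)) {
    q <- reads$qualities[[i]]
    len <- length(q)
    from <- params$trim_5prime + 1L
    to <- len - params$trim_3prime
    if (to < from) next
    q <- q[from:to]
    run <- longest_true_run(q > params$min_phred)
    if (run$len < params$min_length) next
    a <- from + run$start - 1L
    out_bases <- c(out_bases, substring(reads$bases[i], a, a + run$len - 1L))
    out_quals <- c(out_quals, list(q[run$start:(run$start + run$len - 1L)]))
  }
  trimmed <- read_records(out_bases, out_quals)
  n_out <- length(trimmed)
  list(
    reads = trimmed,
    qc = list(n_input = n_in, n_retained = n_out,
              retained_fraction = n_out / n_in,
              mean_length = if (n_out) mean(nchar(out_bases)) else NaN)
  )
}

# Longest run of TRUE; returns start index and length (len 0 if none).
longest_true_run <- function(x) {
  if (!any(x)) return(list(start = 0L, len = 0L))
  r <- rle(x)
  ends <- cumsum(r$lengths)
  true_runs <- which(r$values)
  best <- true_runs[which.max(r$lengths[true_runs])]
  list(start = ends[best] - r$lengths[best] + 1L, len = r$lengths[best])
}

#' Load a depth profile from a bedGraph file
#'
#' Reads 0-based half-open coverage intervals and aggregates them onto the
#' window grid of [window_grid()]. Each interval's value is a read count
#' spread uniformly over the interval's bases (pro-rata), so an interval
#' exactly covering one window contributes its value to that window, and
#' boundary-spanning intervals split by base overlap; overlapping intervals
#' sum. Total reads default to the sum of all counts.
#'
#' @param path bedGraph file path.
#' @param window Window size in bp.
#' @param genome_length Genome length in bp; defaults to the largest interval
#'   end in the file. Intervals extending beyond it are a hard error naming
#'   the offending record.
#' @param label Sample label, `"exponential"` or `"stationary"`.
#' @return A [depth_profile()]; an empty file yields an all-zero profile with
#'   a QC failure flag (`qc$empty_input`).
#' @export
depth_from_bedgraph <- function(path, window = 1000L, genome_length = NULL,
                                label = c("exponential", "stationary")) {
  label <- match.arg(label)
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr) == 0) {
    if (is.null(genome_length))
      stop("empty bedGraph and no genome_length given")
    prof <- depth_profile(rep(0, window_grid(genome_length, window)$n),
                          window, genome_length, label, total_reads = 0)
    prof$qc$empty_input <- TRUE
    warning("empty bedGraph file: all-zero depth profile")
    return(prof)
  }
  start0 <- GenomicRanges::start(gr) - 1L  # back to 0-based half-open
  end0 <- GenomicRanges::end(gr)
  value <- gr$score
  if (is.null(genome_length)) genome_length <- max(end0)
  bad <- which(end0 > genome_length | start0 < 0)
  if (length(bad))
    stop(sprintf("bedGraph record %d (%s:%d-%d) outside [0, %d)",
                 bad[1], as.character(GenomicRanges::seqnames(gr))[bad[1]],
                 start0[bad[1]], end0[bad[1]], genome_length))
  grid <- window_grid(genome_length, window)
  counts <- numeric(grid$n)
  # window linear extents; the merged wrap tail maps to window 1
  win_start <- grid$starts
  win_end <- grid$starts + ifelse(seq_len(grid$n) == 1 & grid$merged_tail,
                                  window, grid$widths)
  for (i in seq_along(value)) {
    len <- end0[i] - start0[i]
    if (len <= 0) next
    per_base <- value[i] / len
    w_first <- window_index(start0[i], grid, window)
    w_last <- window_index(end0[i] - 1L, grid, window)
    if (w_first == w_last) {
      counts[w_first] <- counts[w_first] + value[i]
    } else {
      js <- unique(window_index(
        seq(start0[i], end0[i] - 1L, by = max(1L, window %/% 2L)) |>
          c(end0[i] - 1L), grid, window))
      # exact overlap per touched window
      for (j in js) {
        ov <- max(0, min(end0[i], win_end[j]) - max(start0[i], win_start[j]))
        if (grid$merged_tail && j == 1L) {
          tail_start <- grid$starts[grid$n] + window
          ov <- ov + max(0, min(end0[i], genome_length) -
                           max(start0[i], tail_start))
        }
        counts[j] <- counts[j] + per_base * ov
      }
    }
  }
  depth_profile(counts, window, genome_length, label)
}

#' Marker-frequency-analysis ratio profile
#'
#' Computes the per-window depth ratio
#' `R(x) = (exp counts / exp total) / (stat counts / stat total)` of the
#' replicating (exponential-phase) sample over the non-replicating
#' (stationary-phase) control at the fine window scale, then re-aggregates
#' counts (sum of counts, then ratio — more stable than averaging fine
#' ratios) at the coarse scale. Windows where the stationary count is zero
#' are masked (`NA`) and counted in QC; more than 1% masked raises a warning.
#'
#' @param exp,stat [depth_profile()]s on the same fine window grid and
#'   genome length.
#' @param coarse_window Coarse window size in bp (default 100000), a
#'   multiple of the fine window.
#' @return An object of class `mfa_profile` with fine and coarse ratio
#'   vectors, window starts, and a `qc` list.
#' @export
mfa_ratio <- function(exp, stat, coarse_window = 100000L) {
  stopifnot(inherits(exp, "depth_profile"), inherits(stat, "depth_profile"),
            exp$genome_length == stat$genome_length,
            exp$window == stat$window,
            length(exp$counts) == length(stat$counts),
            coarse_window %% exp$window == 0)
  L <- exp$genome_length
  fine_window <- exp$window
  norm_e <- exp$counts / exp$total_reads
  norm_s <- stat$counts / stat$total_reads
  fine_ratio <- ifelse(stat$counts == 0, NA_real_, norm_e / norm_s)

  fine_grid <- window_grid(L, fine_window)
  coarse_grid <- window_grid(L, coarse_window)
  mids <- window_midpoints(fine_grid, L)
  cidx <- window_index(floor(mids), coarse_grid, coarse_window)
  ce <- as.numeric(rowsum(exp$counts, cidx)[as.character(seq_len(coarse_grid$n)), ])
  cs <- as.numeric(rowsum(stat$counts, cidx)[as.character(seq_len(coarse_grid$n)), ])
  coarse_ratio <- ifelse(cs == 0, NA_real_,
                         (ce / exp$total_reads) / (cs / stat$total_reads))
  masked_frac <- mean(is.na(fine_ratio))
  if (masked_frac > 0.01)
    warning(sprintf("%.1f%% of fine windows masked (zero stationary depth)",
                    100 * masked_frac))
  structure(
    list(fine_window = fine_window, coarse_window = coarse_window,
         fine_ratio = fine_ratio, coarse_ratio = coarse_ratio,
         fine_starts = fine_grid$starts, coarse_starts = coarse_grid$starts,
         coarse_widths = coarse_grid$widths, genome_length = L,
         qc = list(masked_fine_fraction = masked_frac,
                   masked_coarse_fraction = mean(is.na(coarse_ratio)))),
    class = "mfa_profile"
  )
}

#' @export
print.mfa_profile <- function(x, ...) {
  cat(sprintf(
    "<mfa_profile> %d fine (%d bp) / %d coarse (%d bp) windows over %s bp\n",
    length(x$fine_ratio), x$fine_window, length(x$coarse_ratio),
    x$coarse_window, format(x$genome_length, big.mark = ",")))
  invisible(x)
}

#' Detect the replication origin and classify the replication mode
#'
#' Smooths the coarse ratio profile with a circular moving average, places
#' the origin at the argmax of the smoothed profile (window midpoint), and
#' computes the peak/trough ratio of the smoothed profile. The mode call
#' combines two pieces of evidence:
#' \itemize{
#'   \item a two-segment circular V fit (tent through the smoothed extrema's
#'     windows) to the coarse ratio profile, scored by R^2;
#'   \item a resampling-calibrated confidence interval for the peak/trough
#'     ratio: window permutations give the null spread of log(peak/trough)
#'     expected from noise alone under no spatial structure, and the CI is
#'     the observed log-ratio offset by the null quantiles. The raw
#'     peak/trough statistic is >= 1 by construction, so only a
#'     selection-corrected interval can ever include 1 on a genuinely flat
#'     profile.
#' }
#' Mode is `single_origin_V` when the V fit reaches `v_r2_threshold` and the
#' CI excludes 1; `flat_multi_origin` when the CI includes 1; `indeterminate`
#' otherwise, or when more than 20% of coarse windows are masked.
#'
#' The peak/trough ratio removes the known attenuation a boxcar moving
#' average imposes at a piecewise-linear extremum: a span-w average lowers a
#' V apex by `h(h+1)/(2w)` times the sum of the flanking slopes
#' (`h = (w-1)/2`), so the apex and trough are restored in closed form from
#' the smoothed amplitude and the two arc lengths. Without this the ratio
#' systematically under-reports the replicating fraction. The correction is
#' skipped when degenerate (very few windows, or a non-positive corrected
#' trough), and the ratio is floored at 1.
#'
#' @param mfa An [mfa_profile()] with at least 20 coarse windows.
#' @param span Smoothing span in coarse windows (default 5).
#' @param n_boot Resampling replicates (default 200).
#' @param v_r2_threshold V-fit R^2 threshold (default 0.5).
#' @param conf CI level (default 0.95).
#' @param seed Integer RNG seed for the resampling.
#' @return An object of class `origin_call` with `origin_position` (bp),
#'   `peak_trough_ratio`, `mode`, `bootstrap_ci` (ratio scale) and `v_r2`.
#' @export
detect_origin <- function(mfa, span = 5L, n_boot = 200L,
                          v_r2_threshold = 0.5, conf = 0.95, seed = 1L) {
  stopifnot(inherits(mfa, "mfa_profile"))
  x <- mfa$coarse_ratio
  n <- length(x)
  if (n < 20) stop("need at least 20 coarse windows")
  if (mean(is.na(x)) > 0.2) {
    return(structure(
      list(origin_position = NA_real_, peak_trough_ratio = NA_real_,
           mode = "indeterminate", bootstrap_ci = c(NA_real_, NA_real_),
           v_r2 = NA_real_,
           diagnostic = "more than 20% of coarse windows masked"),
      class = "origin_call"
    ))
  }
  xf <- fill_na_circular(x)
  sm <- circular_moving_average(xf, span)
  i_max <- which.max(sm)
  i_min <- which.min(sm)
  mids <- (mfa$coarse_starts + mfa$coarse_widths / 2) %% mfa$genome_length
  origin_position <- mids[i_max]
  ptr <- peak_trough_ratio_stat(sm, span)

  v_r2 <- circular_tent_fit(xf, i_max, i_min)$r2

  set.seed(seed)
  null_stat <- vapply(seq_len(n_boot), function(b) {
    log(peak_trough_ratio_stat(circular_moving_average(sample(xf), span),
                               span))
  }, numeric(1))
  alpha <- 1 - conf
  qs <- stats::quantile(null_stat, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  ci <- exp(log(ptr) - rev(qs))  # observed minus null spread, ratio scale
  excludes_1 <- ci[1] > 1
  mode <- if (!excludes_1) "flat_multi_origin"
          else if (v_r2 >= v_r2_threshold) "single_origin_V"
          else "indeterminate"
  structure(
    list(origin_position = origin_position, peak_trough_ratio = ptr,
         mode = mode, bootstrap_ci = ci, v_r2 = v_r2, diagnostic = NULL),
    class = "origin_call"
  )
}

# Attenuation-corrected peak/trough ratio of a smoothed circular profile.
# A span-w boxcar lowers a piecewise-linear apex (and raises the trough) by
# beta * (sum of flanking slope magnitudes), beta = h(h+1)/(2w), h=(w-1)/2.
# With tent geometry both slopes follow from the amplitude and the two arc
# lengths between the extrema, giving a closed-form de-attenuation.
peak_trough_ratio_stat <- function(sm, span) {
  n <- length(sm)
  i_max <- which.max(sm)
  i_min <- which.min(sm)
  raw <- max(sm) / min(sm)
  if (span %% 2 == 0) span <- span + 1L
  h <- (span - 1L) %/% 2L
  arc1 <- (i_min - i_max) %% n
  arc2 <- n - arc1
  if (h == 0L || arc1 == 0L || arc2 == 0L) return(max(raw, 1))
  beta <- h * (h + 1) / (2 * span)
  s_sum <- 1 / arc1 + 1 / arc2
  shrink <- 1 - 2 * beta * s_sum
  if (shrink <= 0) return(max(raw, 1))
  amp <- (sm[i_max] - sm[i_min]) / shrink
  corr <- beta * amp * s_sum
  peak <- sm[i_max] + corr
  trough <- sm[i_min] - corr
  if (trough <= 0) return(max(raw, 1))
  max(peak / trough, 1)
}

#' @export
print.origin_call <- function(x, ...) {
  if (is.na(x$origin_position)) {
    cat(sprintf("<origin_call> %s (%s)\n", x$mode, x$diagnostic))
  } else {
    cat(sprintf(
      "<origin_call> %s: origin ~ %s bp, peak/trough = %.3f (CI %.3f-%.3f), V R2 = %.2f\n",
      x$mode, format(round(x$origin_position), big.mark = ","),
      x$peak_trough_ratio, x$bootstrap_ci[1], x$bootstrap_ci[2], x$v_r2))
  }
  invisible(x)
}

#' Origin-to-terminus depth ratio
#'
#' Ratio of the coarse-window ratio value at the window containing the
#' origin to the value at the antipodal window (circular distance L/2). A
#' masked window falls back to its nearest unmasked neighbour, flagged in
#' the result's `fallback` attribute.
#'
#' @param mfa An [mfa_profile()].
#' @param origin Origin position in bp, in `[0, L)`.
#' @return The ori/ter ratio (numeric scalar).
#' @export
ori_ter_ratio <- function(mfa, origin) {
  stopifnot(inherits(mfa, "mfa_profile"),
            origin >= 0, origin < mfa$genome_length)
  L <- mfa$genome_length
  grid <- window_grid(L, mfa$coarse_window)
  i_ori <- window_index(floor(origin), grid, mfa$coarse_window)
  i_ter <- window_index(floor((origin + L / 2) %% L), grid, mfa$coarse_window)
  x <- mfa$coarse_ratio
  fallback <- FALSE
  nearest_unmasked <- function(i) {
    if (!is.na(x[i])) return(i)
    fallback <<- TRUE
    n <- length(x)
    for (d in seq_len(n %/% 2)) {
      for (j in c(((i - 1 + d) %% n) + 1, ((i - 1 - d) %% n) + 1)) {
        if (!is.na(x[j])) return(j)
      }
    }
    stop("all coarse windows masked")
  }
  i_ori <- nearest_unmasked(i_ori)
  i_ter <- nearest_unmasked(i_ter)
  out <- x[i_ori] / x[i_ter]
  attr(out, "fallback") <- fallback
  out
}
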