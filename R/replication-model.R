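#' Population replication model
#'
#' Parameters of the replication process of a cell population, used both to
#' derive expected marker-frequency profiles in closed form and to simulate
#' sequencing depth.
#'
#' Three modes are supported:
#' \describe{
#'   \item{`single_origin`}{A fraction `replicating_fraction` (r) of
#'     chromosome copies carry a single bidirectional fork pair started at
#'     `ori_position`, with fork progress uniformly staged on `[0, 1]`.
#'     Typical of polyploid cells in which only one or a few copies
#'     replicate at a time: the ori/ter depth ratio is `1 + r`, close to 1
#'     for small r, yet the profile is still V-shaped.}
#'   \item{`multifork`}{Overlapping replication rounds in an exponential
#'     steady-state population; `fork_intensity` (k) is the ratio of
#'     replication time to doubling time, giving an ori/ter ratio of `2^k`
#'     (> 2 when rounds overlap, k > 1).}
#'   \item{`multi_origin_async`}{Asynchronous initiation from many dispersed
#'     sites: expected relative copy number is flat; `ori_position` is
#'     ignored.}
#' }
#'
#' @param mode One of `"single_origin"`, `"multifork"`,
#'   `"multi_origin_async"`.
#' @param genome_length Genome length L in bp.
#' @param ori_position Origin position in bp (used by `single_origin` and
#'   `multifork`).
#' @param replicating_fraction r in `[0, 1]` (single_origin).
#' @param fork_intensity k >= 0 (multifork).
#' @param ploidy Chromosome copies per cell, >= 1 (bookkeeping only; ratios
#'   are ploidy-invariant).
#' @param seed Integer RNG seed used by simulators consuming the model.
#' @return An object of class `replication_model`.
#' @export
replication_model <- function(mode = c("single_origin", "multifork",
                                       "multi_origin_async"),
                              genome_length, ori_position = 0,
                              replicating_fraction = 0,
                              fork_intensity = 0, ploidy = 1, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(genome_length >= 1,
            replicating_fraction >= 0, replicating_fraction <= 1,
            fork_intensity >= 0, ploidy >= 1,
            ori_position >= 0, ori_position < genome_length)
  structure(
    list(mode = mode, genome_length = as.numeric(genome_length),
         ori_position = as.numeric(ori_position),
         replicating_fraction = replicating_fraction,
         fork_intensity = fork_intensity, ploidy = ploidy,
         seed = as.integer(seed)),
    class = "replication_model"
  )
}

#' Expected relative copy number at a genomic position
#'
#' Closed-form expected marker frequency m(delta) under a
#' [replication_model()], normalised so the terminus value is 1 for the
#' single-origin and multifork modes. `delta = 2 d(position, ori)/L` is the
#' normalised origin distance (0 at ori, 1 at ter).
#'
#' \itemize{
#'   \item single_origin: `m = 1 + r (1 - delta)` — with fork progress
#'     uniform on `[0,1]`, a locus is already duplicated on a replicating
#'     copy iff fork progress >= delta.
#'   \item multifork: `m = 2^(k (1 - delta))` — exponential steady-state age
#'     structure of overlapping rounds.
#'   \item multi_origin_async: `m = 1` everywhere.
#' }
#'
#' @param model A [replication_model()].
#' @param position Genomic position(s) in bp; vectorised.
#' @return Numeric vector of expected relative copy numbers.
#' @export
expected_relative_copy_number <- function(model, position) {
  stopifnot(inherits(model, "replication_model"))
  d <- origin_delta(position, model$ori_position, model$genome_length)
  switch(model$mode,
    single_origin = 1 + model$replicating_fraction * (1 - d),
    multifork = 2^(model$fork_intensity * (1 - d)),
    multi_origin_async = rep(1, length(d))
  )
}

#' Depth-profile container
#'
#' Per-window read counts for one sequencing sample over a circular genome.
#'
#' @param counts Non-negative read counts, one per window of the grid.
#' @param window Window size in bp.
#' @param genome_length Genome length in bp.
#' @param label `"exponential"` or `"stationary"`.
#' @param total_reads Total reads in the sample; defaults to `sum(counts)`.
#' @return An object of class `depth_profile` with fields `counts`, `window`,
#'   `starts`, `widths`, `genome_length`, `label`, `total_reads` and a `qc`
#'   list (`n_zero_windows`, `min_count`).
#' @export
depth_profile <- function(counts, window, genome_length,
                          label = c("exponential", "stationary"),
                          total_reads = sum(counts)) {
  label <- match.arg(label)
  grid <- window_grid(genome_length, window)
  stopifnot(length(counts) == grid$n, all(counts >= 0))
  structure(
    list(counts = as.numeric(counts), window = window,
         starts = grid$starts, widths = grid$widths,
         genome_length = genome_length, label = label,
         total_reads = total_reads,
         qc = list(n_zero_windows = sum(counts == 0),
                   min_count = min(counts))),
    class = "depth_profile"
  )
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("<depth_profile> %s: %d windows of %d bp, %s reads\n",
              x$label, length(x$counts), x$window,
              format(round(x$total_reads), big.mark = ",")))
  invisible(x)
}

#' Simulate exponential- and stationary-phase depth profiles
#'
#' Draws per-window read counts for a replicating (exponential-phase) sample,
#' whose expected depth follows the model's relative copy-number profile, and
#' a non-replicating (stationary-phase) control with flat expected depth.
#' Counts are Poisson; `poisson_noise = FALSE` returns the noiseless expected
#' counts for oracle checks. The copy-number profile is evaluated at window
#' midpoints (exact for the piecewise-linear single-origin profile) and
#' normalised by its mean so both samples share the same expected total.
#'
#' @param model A [replication_model()].
#' @param window Window size in bp (default 1000).
#' @param mean_depth Mean reads per window (>= 1).
#' @param seed Integer RNG seed; defaults to the model's seed.
#' @param poisson_noise Logical; draw Poisson counts (default) or return
#'   expectations.
#' @return A list with `exponential` and `stationary` [depth_profile()]s.
#' @export
simulate_depth_profiles <- function(model, window = 1000L, mean_depth = 500,
                                    seed = model$seed, poisson_noise = TRUE) {
  stopifnot(inherits(model, "replication_model"), mean_depth >= 1)
  L <- model$genome_length
  grid <- window_grid(L, window)
  mids <- window_midpoints(grid, L)
  m <- expected_relative_copy_number(model, mids)
  mu_exp <- mean_depth * m / mean(m)
  mu_stat <- rep(mean_depth, grid$n)
  if (poisson_noise) {
    set.seed(seed)
    c_exp <- stats::rpois(grid$n, mu_exp)
    c_stat <- stats::rpois(grid$n, mu_stat)
  } else {
    c_exp <- mu_exp
    c_stat <- mu_stat
  }
  list(
    exponential = depth_profile(c_exp, window, L, "exponential"),
    stationary = depth_profile(c_stat, window, L, "stationary")
  )
}

#' Specification of a flow-cytometry simulation
#'
#' Emulates per-cell DNA-stain fluorescence (e.g. SYBR Green) proportional to
#' total DNA per cell, i.e. chromosome copy number times genome size.
#'
#' @param n_cells Number of cells (>= 1).
#' @param copies_mean Mean chromosome copies per cell.
#' @param genome_size Genome size in bp.
#' @param cv Coefficient of variation of fluorescence (>= 0).
#' @param seed Integer RNG seed.
#' @return An object of class `flow_sim_spec`.
#' @export
flow_sim_spec <- function(n_cells, copies_mean, genome_size, cv = 0.3,
                          seed = 1L) {
  stopifnot(n_cells >= 1, copies_mean > 0, genome_size > 0, cv >= 0)
  structure(
    list(n_cells = as.integer(n_cells), copies_mean = copies_mean,
         genome_size = genome_size, cv = cv, seed = as.integer(seed)),
    class = "flow_sim_spec"
  )
}

#' Simulate per-cell fluorescence values
#'
#' Lognormal fluorescence with median proportional to
#' `copies_mean * genome_size` (arbitrary units; the proportionality constant
#' cancels in every downstream ratio) and the requested coefficient of
#' variation. `cv = 0` returns the median for every cell.
#'
#' @param spec A [flow_sim_spec()].
#' @return Numeric vector of fluorescence values, length `n_cells`.
#' @export
simulate_flow_cytometry <- function(spec) {
  stopifnot(inherits(spec, "flow_sim_spec"))
  med <- spec$copies_mean * spec$genome_size * 1e-9
  sigma <- sqrt(log(1 + spec$cv^2))
  if (sigma == 0) return(rep(med, spec$n_cells))
  set.seed(spec$seed)
  stats::rlnorm(spec$n_cells, meanlog = log(med), sdlog = sigma)
}
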