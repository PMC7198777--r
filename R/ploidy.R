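#' Fluorescence ratio between a sample and a reference population
#'
#' Ratio of median per-cell DNA-stain fluorescence. The median (rather than
#' the mean) is used because cytometry fluorescence distributions are
#' right-skewed.
#'
#' @param sample,reference Non-empty numeric vectors of per-event
#'   fluorescence values.
#' @return The ratio `rho = median(sample) / median(reference)`.
#' @export
fluorescence_ratio <- function(sample, reference) {
  stopifnot(length(sample) > 0, length(reference) > 0)
  m_ref <- stats::median(reference)
  if (!is.finite(m_ref) || m_ref <= 0)
    stop("reference median fluorescence must be positive")
  stats::median(sample) / m_ref
}

#' Estimate chromosome copy number from a fluorescence ratio
#'
#' Per-cell DNA-stain fluorescence is proportional to total DNA per cell
#' (copy number times genome size), so a target species' copy number follows
#' from its fluorescence ratio `rho` against a reference species of known
#' ploidy range:
#' `k_b = round(rho * c_b * ref_genome / target_genome)` for each reference
#' bound `c_b`, rounding half away from zero.
#'
#' @param rho Fluorescence ratio (> 0), e.g. from [fluorescence_ratio()].
#' @param ref_copies Integer vector `c(lo, hi)`: the reference species'
#'   chromosome copies per cell.
#' @param ref_genome Reference genome size in bp.
#' @param target_genome Target genome size in bp.
#' @return An object of class `ploidy_estimate`: a list with `estimate`
#'   (integer `c(lo, hi)`), plus the inputs.
#' @export
estimate_ploidy <- function(rho, ref_copies, ref_genome, target_genome) {
  stopifnot(rho > 0, length(ref_copies) == 2, ref_copies[1] <= ref_copies[2],
            ref_copies[1] > 0, ref_genome > 0, target_genome > 0)
  k <- round_half_away(rho * ref_copies * ref_genome / target_genome)
  structure(
    list(estimate = as.integer(k), fluorescence_ratio = rho,
         ref_copies = as.integer(ref_copies), ref_genome = ref_genome,
         target_genome = target_genome),
    class = "ploidy_estimate"
  )
}

#' @export
print.ploidy_estimate <- function(x, ...) {
  cat(sprintf(
    "<ploidy_estimate> %d-%d chromosome copies per cell (rho = %.3g, ref %d-%d copies, genomes %.3g / %.3g bp)\n",
    x$estimate[1], x$estimate[2], x$fluorescence_ratio,
    x$ref_copies[1], x$ref_copies[2], x$ref_genome, x$target_genome))
  invisible(x)
}
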