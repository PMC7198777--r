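#' Run a combined per-genome replication report
#'
#' Executes the requested stages — skew profiling, marker frequency
#' analysis, ploidy estimation — and aggregates their calls into a single
#' report, optionally written as JSON (plus TSV profile tables). Stage
#' failures are recorded per stage and a partial report is still produced.
#' Re-running with the same config and seed reproduces the JSON byte for
#' byte.
#'
#' @param config A list with entries:
#'   \describe{
#'     \item{`genome`}{A [circular_genome()] or FASTA path (enables the skew
#'       stage).}
#'     \item{`genes`}{Optional gene set data.frame or GFF3 path (adds CDS
#'       skew).}
#'     \item{`window`}{Skew window in bp (default 10000).}
#'     \item{`exp_depth`, `stat_depth`}{Optional [depth_profile()]s or
#'       bedGraph paths (enable the MFA stage).}
#'     \item{`fine_window`, `coarse_window`}{MFA windows (defaults 1000 /
#'       100000).}
#'     \item{`sample_fluor`, `ref_fluor`}{Optional numeric vectors or CSV
#'       paths (enable the ploidy stage).}
#'     \item{`ref_copies`, `ref_genome`, `target_genome`}{Ploidy-stage
#'       parameters.}
#'     \item{`seed`}{Integer seed for the stochastic MFA classification
#'       (default 1).}
#'     \item{`id`}{Report identifier (defaults to the genome id).}
#'   }
#' @param out_dir Optional output directory; when given, writes
#'   `report.json`, `gc_skew.tsv` (and `cds_skew.tsv`, `mfa.tsv` as
#'   applicable).
#' @return An object of class `genome_report`: a list with `id`, `skew`,
#'   `cds_skew`, `origin`, `ori_ter_ratio`, `ploidy`, `classification`,
#'   `qc`, `errors`, `config` (snapshot of scalar settings) and `seed`.
#' @export
run_report <- function(config, out_dir = NULL) {
  seed <- config$seed %||% 1L
  window <- config$window %||% 10000L
  fine_window <- config$fine_window %||% 1000L
  coarse_window <- config$coarse_window %||% 100000L
  errors <- list()
  qc <- list()
  skew_call <- cds_call <- origin_call <- ploidy_est <- NULL
  otr <- NULL
  gc_cum <- cds_cum <- mfa <- NULL

  genome <- config$genome
  if (is.character(genome)) genome <- read_genome_fasta(genome)

  if (!is.null(genome)) {
    res <- try({
      gc_cum <- cumulative_profile(compute_gc_skew(genome, window = window))
      skew_call <- detect_shift_points(gc_cum)
    }, silent = TRUE)
    if (inherits(res, "try-error"))
      errors$skew <- attr(res, "condition")$message
    if (!is.null(config$genes)) {
      genes <- config$genes
      res <- try({
        if (is.character(genes))
          genes <- read_genes_gff3(genes, genome_length = genome$length)
        cds_cum <- cumulative_profile(
          compute_cds_skew(genes, genome$length, window = window))
        cds_call <- detect_shift_points(cds_cum)
      }, silent = TRUE)
      if (inherits(res, "try-error"))
        errors$cds_skew <- attr(res, "condition")$message
    }
  }

  if (!is.null(config$exp_depth) && !is.null(config$stat_depth)) {
    res <- try({
      ed <- config$exp_depth
      sd <- config$stat_depth
      if (is.character(ed))
        ed <- depth_from_bedgraph(ed, window = fine_window,
                                  genome_length = genome$length,
                                  label = "exponential")
      if (is.character(sd))
        sd <- depth_from_bedgraph(sd, window = fine_window,
                                  genome_length = genome$length,
                                  label = "stationary")
      mfa <- mfa_ratio(ed, sd, coarse_window = coarse_window)
      qc$masked_fine_fraction <- mfa$qc$masked_fine_fraction
      origin_call <- detect_origin(mfa, seed = seed)
      if (!is.na(origin_call$origin_position))
        otr <- as.numeric(ori_ter_ratio(mfa, origin_call$origin_position))
    }, silent = TRUE)
    if (inherits(res, "try-error"))
      errors$mfa <- attr(res, "condition")$message
  }

  if (!is.null(config$sample_fluor) && !is.null(config$ref_fluor)) {
    res <- try({
      sf <- config$sample_fluor
      rf <- config$ref_fluor
      if (is.character(sf)) sf <- read_fluorescence_csv(sf)
      if (is.character(rf)) rf <- read_fluorescence_csv(rf)
      rho <- fluorescence_ratio(sf, rf)
      ploidy_est <- estimate_ploidy(rho, config$ref_copies,
                                    config$ref_genome, config$target_genome)
    }, silent = TRUE)
    if (inherits(res, "try-error"))
      errors$ploidy <- attr(res, "condition")$message
  }

  report <- structure(
    list(
      schema_version = "1.0",
      id = config$id %||% (if (!is.null(genome)) genome$id else "report"),
      skew = unclass(skew_call), cds_skew = unclass(cds_call),
      origin = unclass(origin_call), ori_ter_ratio = otr,
      ploidy = unclass(ploidy_est),
      classification = NULL, qc = qc, errors = errors,
      config = list(window = window, fine_window = fine_window,
                    coarse_window = coarse_window),
      seed = seed
    ),
    class = "genome_report"
  )
  report$classification <- classify_species_profile(report)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = 12, null = "null",
                         pretty = TRUE, force = TRUE)
    if (!is.null(gc_cum))
      write_profile_tsv(gc_cum, file.path(out_dir, "gc_skew.tsv"))
    if (!is.null(cds_cum))
      write_profile_tsv(cds_cum, file.path(out_dir, "cds_skew.tsv"))
    if (!is.null(mfa))
      write_mfa_tsv(mfa, file.path(out_dir, "mfa.tsv"))
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify a species' replication profile
#'
#' Deterministic mapping of the skew-regularity and MFA-mode calls onto the
#' qualitative replication-profile classes observed across cyanobacteria.
#' The labels describe profile shape only; no genotype is inferred:
#' \itemize{
#'   \item V-shaped skew + V-shaped MFA -> `"DnaA-oriC-like"` (regular
#'     skew, single origin — the classic bacterial pattern).
#'   \item irregular skew + V-shaped MFA ->
#'     `"unique-origin-DnaA-independent-like"` (a unique origin despite a
#'     collapsed skew footprint).
#'   \item irregular skew + flat MFA -> `"multi-origin-like"` (asynchronous
#'     replication from dispersed sites).
#'   \item missing or indeterminate MFA, or any other combination ->
#'     `"indeterminate"`.
#' }
#'
#' @param report A `genome_report` from [run_report()] (or any list with
#'   `skew$is_v_shaped` and `origin$mode`).
#' @return A single classification string.
#' @export
classify_species_profile <- function(report) {
  skew_v <- report$skew$is_v_shaped
  mode <- report$origin$mode
  if (is.null(mode) || is.null(skew_v)) return("indeterminate")
  if (mode == "single_origin_V") {
    if (isTRUE(skew_v)) "DnaA-oriC-like" else "unique-origin-DnaA-independent-like"
  } else if (mode == "flat_multi_origin" && !isTRUE(skew_v)) {
    "multi-origin-like"
  } else {
    "indeterminate"
  }
}

#' @export
print.genome_report <- function(x, ...) {
  cat(sprintf("<genome_report> %s: %s\n", x$id, x$classification))
  if (!is.null(x$skew))
    cat(sprintf("  skew: R2_v = %.3f, V-shaped = %s\n",
                x$skew$r2_v, x$skew$is_v_shaped))
  if (!is.null(x$origin))
    cat(sprintf("  MFA: mode = %s, ori/ter = %s\n", x$origin$mode,
                if (is.null(x$ori_ter_ratio)) "NA"
                else sprintf("%.3f", x$ori_ter_ratio)))
  if (!is.null(x$ploidy))
    cat(sprintf("  ploidy: %d-%d copies\n", x$ploidy$estimate[1],
                x$ploidy$estimate[2]))
  if (length(x$errors))
    cat("  stage errors:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}
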