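#' Write a genome to FASTA
#'
#' 60-column wrapped FASTA via Biostrings.
#'
#' @param genome A [circular_genome()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome$sequence)
  names(x) <- genome$id
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Read the first record of a FASTA file as a circular genome
#'
#' Multi-record files are accepted; each record is an independent genome and
#' `which` selects one.
#'
#' @param path FASTA file path.
#' @param which Record index (default 1).
#' @param circular Logical topology flag.
#' @return A [circular_genome()].
#' @export
read_genome_fasta <- function(path, which = 1L, circular = TRUE) {
  x <- Biostrings::readDNAStringSet(path)
  stopifnot(which >= 1, which <= length(x))
  id <- sub("\\s.*$", "", names(x)[which])
  circular_genome(as.character(x[[which]]), id = id, circular = circular)
}

#' Write a gene set to GFF3
#'
#' Converts the package's 0-based half-open coordinates to GFF3's 1-based
#' inclusive convention and writes through rtracklayer (with version
#' pragma).
#'
#' @param genes Gene data.frame (`start`, `end`, `strand`), e.g. from
#'   [generate_annotations()].
#' @param path Output path.
#' @param seqname Sequence name for column 1.
#' @param genome_length Genome length (defaults to the gene set's
#'   `genome_length` attribute).
#' @return `path`, invisibly.
#' @export
write_genes_gff3 <- function(genes, path, seqname = "genome",
                             genome_length = attr(genes, "genome_length")) {
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand
  )
  gr$type <- "CDS"
  gr$phase <- 0L
  gr$ID <- sprintf("gene%05d", seq_along(gr))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read genes from a GFF3 file
#'
#' Imports via rtracklayer and returns 0-based half-open `start`/`end` with
#' strand. Wrap-around genes (end beyond the genome length) are split at the
#' origin. Strandless features are dropped with a message.
#'
#' @param path GFF3 file path.
#' @param genome_length Genome length in bp (for wrap-around splitting);
#'   optional.
#' @return A `gene_set` data.frame (`start`, `end`, `strand`).
#' @export
read_genes_gff3 <- function(path, genome_length = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  strand <- as.character(GenomicRanges::strand(gr))
  keep <- strand %in% c("+", "-")
  if (any(!keep)) message(sum(!keep), " strandless features dropped")
  gr <- gr[keep]
  genes <- data.frame(
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  if (!is.null(genome_length) && nrow(genes) > 0) {
    over <- genes$end > genome_length
    if (any(over)) {
      wrapped <- genes[over, , drop = FALSE]
      genes <- genes[!over, , drop = FALSE]
      first <- transform(wrapped, end = genome_length)
      second <- transform(wrapped, start = 0L, end = wrapped$end - genome_length)
      genes <- rbind(genes, first, second)
    }
  }
  class(genes) <- c("gene_set", "data.frame")
  attr(genes, "genome_length") <- genome_length
  genes
}

#' Write a depth profile to bedGraph
#'
#' One 0-based half-open interval per window. When the grid merges the
#' wrap-around tail into window 0, window 0's count is split pro-rata over
#' its two linear segments.
#'
#' @param profile A [depth_profile()].
#' @param path Output path.
#' @param seqname Sequence name.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(profile, path, seqname = "genome") {
  grid <- window_grid(profile$genome_length, profile$window)
  starts <- grid$starts
  ends <- starts + pmin(grid$widths, profile$window)
  counts <- profile$counts
  lines <- sprintf("%s\t%d\t%d\t%.6g", seqname, starts, ends,
                   counts * pmin(grid$widths, profile$window) / grid$widths)
  if (grid$merged_tail) {
    tail_start <- starts[grid$n] + profile$window
    tail_len <- profile$genome_length - tail_start
    lines <- c(lines, sprintf("%s\t%d\t%d\t%.6g", seqname, tail_start,
                              profile$genome_length,
                              counts[1] * tail_len / grid$widths[1]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read per-event fluorescence values from CSV
#'
#' One column of numeric fluorescence values; a non-numeric first line is
#' treated as a header.
#'
#' @param path CSV file path.
#' @return Numeric vector of fluorescence values.
#' @export
read_fluorescence_csv <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- is.na(suppressWarnings(as.numeric(strsplit(first, ",")[[1]][1])))
  x <- utils::read.csv(path, header = has_header)[[1]]
  stopifnot(is.numeric(x))
  x
}

#' Read FASTQ reads (Phred+33) into read records
#'
#' @param path FASTQ file path.
#' @return A [read_records()] object.
#' @export
read_fastq_reads <- function(path) {
  qs <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = "phred"),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  quals <- as.list(methods::as(Biostrings::quality(qs), "IntegerList"))
  read_records(unname(as.character(qs)),
               unname(lapply(quals, as.integer)))
}

#' Write a windowed/cumulative profile as TSV
#'
#' Columns: `position` (window start), `value`, and `cumulative` when a
#' cumulative profile is supplied.
#'
#' @param profile A `windowed_profile` or [cumulative_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  if (inherits(profile, "cumulative_profile")) {
    df <- data.frame(position = profile$parent$starts,
                     value = profile$parent$values,
                     cumulative = profile$cum_values)
  } else {
    df <- data.frame(position = profile$starts, value = profile$values)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an MFA ratio profile as TSV
#'
#' Fine-scale table with the coarse ratio repeated over its fine windows,
#' mirroring the two-scale (1-kb / 100-kb) presentation of MFA plots.
#'
#' @param mfa An [mfa_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mfa_tsv <- function(mfa, path) {
  cgrid <- window_grid(mfa$genome_length, mfa$coarse_window)
  fgrid <- window_grid(mfa$genome_length, mfa$fine_window)
  cidx <- window_index(floor(window_midpoints(fgrid, mfa$genome_length)),
                       cgrid, mfa$coarse_window)
  df <- data.frame(window_start = mfa$fine_starts,
                   fine_R = mfa$fine_ratio,
                   coarse_R = mfa$coarse_ratio[cidx])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simulation truth record as JSON
#'
#' @param truth Truth list (e.g. from [generate_skewed_genome()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  invisible(path)
}
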