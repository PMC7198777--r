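#' Circular genome object
#'
#' Lightweight container for a circular nucleotide sequence.
#'
#' @param sequence Nucleotide string over `{A,C,G,T,N}` (a single character
#'   scalar, or a [Biostrings::DNAString]).
#' @param id Sequence identifier.
#' @param circular Logical; circular topology (default `TRUE`).
#' @return An object of class `circular_genome` with fields `id`, `sequence`
#'   (character), `length` and `circular`.
#' @export
circular_genome <- function(sequence, id = "genome", circular = TRUE) {
  sequence <- toupper(as.character(sequence))
  stopifnot(length(sequence) == 1, nchar(sequence) > 0)
  if (grepl("[^ACGTN]", sequence))
    stop("sequence contains letters outside {A,C,G,T,N}")
  structure(
    list(id = id, sequence = sequence, length = nchar(sequence),
         circular = circular),
    class = "circular_genome"
  )
}

#' @export
print.circular_genome <- function(x, ...) {
  cat(sprintf("<circular_genome> %s: %s bp (%s)\n", x$id,
              format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Reverse complement of a circular genome
#'
#' @param genome A [circular_genome()].
#' @return A `circular_genome` with the reverse-complemented sequence.
#' @export
reverse_complement_genome <- function(genome) {
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(genome$sequence)))
  circular_genome(rc, id = paste0(genome$id, "_rc"),
                  circular = genome$circular)
}

#' Rotate a circular genome
#'
#' Re-linearises the circle so that old position `shift` becomes position 0.
#'
#' @param genome A [circular_genome()].
#' @param shift 0-based position that becomes the new first base.
#' @return A rotated `circular_genome`.
#' @export
rotate_genome <- function(genome, shift) {
  L <- genome$length
  shift <- shift %% L
  if (shift == 0) return(genome)
  s <- genome$sequence
  circular_genome(paste0(substring(s, shift + 1, L), substring(s, 1, shift)),
                  id = genome$id, circular = genome$circular)
}
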