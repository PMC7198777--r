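#' Specification of a strand-biased synthetic genome
#'
#' Describes a circular genome whose strand-specific base composition
#' switches at the replication origin and terminus, the compositional
#' footprint of bidirectional replication: on the replichore running (in
#' ascending circular coordinates) from `ori` to `ter`, the published strand
#' is the leading strand and is enriched for G over C; on the other
#' replichore the bias is reversed.
#'
#' @param length Genome length L in bp.
#' @param ori_position Replication origin, 0-based, in `[0, L)`.
#' @param ter_position Terminus, 0-based, in `[0, L)`; must differ from ori.
#' @param skew_strength Excess probability `s` in `[0, 1]` of G over C on the
#'   leading strand: G is emitted with probability `(gc/2)(1+s)` and C with
#'   `(gc/2)(1-s)`.
#' @param gc_content Overall G+C fraction in (0, 1).
#' @param seed Integer RNG seed.
#' @return An object of class `skewed_genome_spec`.
#' @export
skewed_genome_spec <- function(length, ori_position = 0,
                               ter_position = floor(length / 2),
                               skew_strength = 0.3, gc_content = 0.5,
                               seed = 1L) {
  stopifnot(length >= 2, ori_position >= 0, ori_position < length,
            ter_position >= 0, ter_position < length,
            skew_strength >= 0, skew_strength <= 1,
            gc_content > 0, gc_content < 1)
  if (ori_position == ter_position)
    stop("ori_position and ter_position must differ")
  structure(
    list(length = as.integer(length), ori_position = as.integer(ori_position),
         ter_position = as.integer(ter_position),
         skew_strength = skew_strength, gc_content = gc_content,
         seed = as.integer(seed)),
    class = "skewed_genome_spec"
  )
}

#' Generate a circular genome with imposed GC skew
#'
#' Emits bases independently per position with replichore-specific
#' probabilities (see [skewed_genome_spec()]); A and T share the non-GC
#' probability evenly. Deterministic under the spec's seed.
#'
#' @param spec A [skewed_genome_spec()].
#' @param min_length Smallest genome length considered usable downstream
#'   (twice the intended analysis window); shorter genomes are generated but
#'   flagged with a warning.
#' @return A list with `genome` (a [circular_genome()]) and `truth` (a list
#'   recording `ori`, `ter` and the spec).
#' @export
generate_skewed_genome <- function(spec, min_length = 2L * 10000L) {
  stopifnot(inherits(spec, "skewed_genome_spec"))
  L <- spec$length
  if (L < min_length)
    warning(sprintf("genome length %d < %d; too short for the default windows",
                    L, min_length))
  gc <- spec$gc_content
  s <- spec$skew_strength
  # leading-strand (G-rich) emission; lagging mirrors G and C
  p_lead <- c(G = gc / 2 * (1 + s), C = gc / 2 * (1 - s),
              A = (1 - gc) / 2, T = (1 - gc) / 2)
  p_lag <- p_lead[c("C", "G", "A", "T")]
  names(p_lag) <- c("G", "C", "A", "T")

  pos <- 0:(L - 1)
  on_first <- in_circular_interval(pos, spec$ori_position, spec$ter_position, L)

  set.seed(spec$seed)
  bases <- character(L)
  n1 <- sum(on_first)
  bases[on_first] <- sample(names(p_lead), n1, replace = TRUE, prob = p_lead)
  bases[!on_first] <- sample(names(p_lag), L - n1, replace = TRUE, prob = p_lag)

  list(
    genome = circular_genome(paste(bases, collapse = ""), id = "synthetic"),
    truth = list(ori = spec$ori_position, ter = spec$ter_position, spec = spec)
  )
}

# TRUE where pos lies in the half-open circular arc [from, to) ascending.
in_circular_interval <- function(pos, from, to, L) {
  if (from < to) pos >= from & pos < to else pos >= from | pos < to
}

#' Generate a gene set with leading-strand orientation bias
#'
#' Places `n_genes` genes uniformly on the circle and orients each with the
#' leading strand of its replichore (determined by the gene midpoint) with
#' probability `leading_bias`. Gene overlap is not prevented; the gene set is
#' a statistical fixture, not a realistic annotation.
#'
#' @param truth Truth record from [generate_skewed_genome()], or any list
#'   with `ori`, `ter` and `spec$length` (alternatively pass `genome_length`,
#'   `ori`, `ter` directly).
#' @param n_genes Number of genes (0 gives a valid empty set).
#' @param leading_bias Probability `p` that a gene lies on the leading strand
#'   of its replichore; 0.5 is unbiased, 1 fully biased.
#' @param seed Integer RNG seed.
#' @param length_range Gene lengths are drawn uniformly from this range (bp).
#' @return A data.frame with columns `start`, `end` (0-based, half-open) and
#'   `strand` (`"+"`/`"-"`), class `gene_set`.
#' @export
generate_annotations <- function(truth, n_genes, leading_bias = 0.8,
                                 seed = 1L, length_range = c(300L, 1500L)) {
  stopifnot(leading_bias >= 0, leading_bias <= 1, n_genes >= 0)
  L <- truth$spec$length
  ori <- truth$ori
  ter <- truth$ter
  genes <- data.frame(start = integer(0), end = integer(0),
                      strand = character(0))
  if (n_genes > 0) {
    set.seed(seed)
    len <- sample(length_range[1]:length_range[2], n_genes, replace = TRUE)
    start <- vapply(len, function(l) sample.int(L - l, 1L) - 1L, integer(1))
    end <- start + len
    mid <- (start + end) %/% 2
    # leading strand is "+" on the ori->ter replichore, "-" on the other
    lead <- ifelse(in_circular_interval(mid, ori, ter, L), "+", "-")
    flip <- stats::runif(n_genes) > leading_bias
    strand <- ifelse(flip, chartr("+-", "-+", lead), lead)
    genes <- data.frame(start = start, end = end, strand = strand)
  }
  class(genes) <- c("gene_set", "data.frame")
  attr(genes, "genome_length") <- L
  genes
}
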