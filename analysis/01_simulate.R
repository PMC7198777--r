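#!/usr/bin/env Rscript
# Stage 1: build the synthetic study bundle.
#
# One skewed circular genome with a leading-strand-biased gene set, plus
# exponential/stationary coverage under the three population replication
# regimes (single-origin polyploid, multifork, asynchronous multi-origin)
# and flow-cytometry fluorescence samples for three species-like
# populations against a common reference. Everything lands under
# results/simulated/ in standard formats (FASTA, GFF3, bedGraph, CSV) with
# a JSON truth record, so later stages run off files alone.

suppressMessages(library(replimode))
out <- "results/simulated"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20260930L

L <- 1000000L
spec <- skewed_genome_spec(L, ori_position = 0, ter_position = L %/% 2L,
                           skew_strength = 0.3, gc_content = 0.5,
                           seed = seed)
gen <- generate_skewed_genome(spec)
write_genome_fasta(gen$genome, file.path(out, "genome.fasta"))
write_truth_json(gen$truth, file.path(out, "truth.json"))

genes <- generate_annotations(gen$truth, n_genes = 2000, leading_bias = 0.8,
                              seed = seed + 1L)
write_genes_gff3(genes, file.path(out, "genes.gff3"), seqname = "synthetic")
cat(sprintf("genome: %d bp, ori 0 / ter %d, skew strength 0.3; %d genes (80%% leading-strand)\n",
            L, L %/% 2L, nrow(genes)))

models <- list(
  single_origin = replication_model("single_origin", L, 0,
                                    replicating_fraction = 0.3,
                                    seed = seed + 2L),
  multifork = replication_model("multifork", L, 0, fork_intensity = 1.5,
                                seed = seed + 3L),
  multi_origin_async = replication_model("multi_origin_async", L,
                                         seed = seed + 4L)
)
for (mode in names(models)) {
  dp <- simulate_depth_profiles(models[[mode]], window = 1000L,
                                mean_depth = 500)
  write_bedgraph(dp$exponential,
                 file.path(out, sprintf("%s_exponential.bedgraph", mode)),
                 seqname = "synthetic")
  write_bedgraph(dp$stationary,
                 file.path(out, sprintf("%s_stationary.bedgraph", mode)),
                 seqname = "synthetic")
  cat(sprintf("coverage [%s]: %d windows x ~500 reads (exp + stat)\n",
              mode, length(dp$exponential$counts)))
}

# flow cytometry: reference (4.5 copies x 2.7 Mbp) and three populations
flows <- list(
  reference = flow_sim_spec(10000, 4.5, 2.7e6, cv = 0.3, seed = seed + 5L),
  highploidy_41 = flow_sim_spec(10000, 24, 4.1e6, cv = 0.3, seed = seed + 6L),
  highploidy_39 = flow_sim_spec(10000, 25, 3.9e6, cv = 0.3, seed = seed + 7L),
  midploidy_30 = flow_sim_spec(10000, 8, 3.0e6, cv = 0.3, seed = seed + 8L)
)
for (nm in names(flows)) {
  v <- simulate_flow_cytometry(flows[[nm]])
  writeLines(c("fluorescence", format(v, digits = 10)),
             file.path(out, sprintf("flow_%s.csv", nm)))
  cat(sprintf("flow [%s]: %d cells, median %.3g\n", nm, length(v), median(v)))
}
cat("bundle written to", out, "\n")
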