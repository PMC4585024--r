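#!/usr/bin/env Rscript
# Stage 2: build the ideal (best attainable) assembly at each depth from the
# known read coordinates and compute the assembly-statistics panel plus the
# per-species coverage / fragmentation / penalized-coverage spectra.
source("analysis/00_common.R")

st <- stage_genomes()

stats_rows <- list()
for (np in cfg$simulation$depths) {
  sim <- stage_sim(st, np)
  ideal <- stage_ideal(st, sim)
  s <- compute_assembly_stats(ideal, st$taxonomy, st$genomes$lengths,
                              chimera_threshold =
                                cfg$metrics$chimera_threshold,
                              fragments = cfg$metrics$fragments)
  stats_rows[[as.character(np)]] <- cbind(depth_pairs = np, s)
  sp <- species_spectra(ideal, st$genomes$lengths,
                        fragments = cfg$metrics$fragments)
  write_species_spectra(cbind(depth_pairs = np, sp),
                        sprintf("results/02_ideal_spectra_%d.tsv", np))
}
tab <- do.call(rbind, stats_rows)
print(tab[, c("depth_pairs", "n50", "num_contig", "pct_reads_assembled",
              "mean_contig_coverage", "mean_fragmentation")],
      row.names = FALSE)
write_tsv(tab, "results/02_ideal_stats.tsv")

message(sprintf(paste0("ideal assemblies assemble 100%% of reads by ",
                       "construction; mean fragmentation rises with depth ",
                       "(%s), the deepest run scoring highest"),
                paste(sprintf("%.3f", tab$mean_fragmentation),
                      collapse = " -> ")))
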