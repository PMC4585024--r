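#!/usr/bin/env Rscript
# Stage 5: compare assemblies with the ideal -- coverage/fragmentation
# profile distances, hierarchical clustering with bootstrap support, the
# Spearman panel correlation matrix, and the three-method association of
# assembly statistics with contig-mode Shannon diversity.
source("analysis/00_common.R")

st <- stage_genomes()
sim <- stage_sim(st, cfg$simulation$depths[2])
ideal <- stage_ideal(st, sim)
grid <- stage_grid()
glen <- st$genomes$lengths

spectra <- list(ideal = species_spectra(ideal, glen))
stats_rows <- list()
shannon_contig <- numeric(nrow(grid))
for (k in seq_len(nrow(grid))) {
  d <- degrade_assembly(ideal, grid$split[k], grid$loss[k],
                        grid$chimera[k], seed = grid$seed[k])
  spectra[[grid$id[k]]] <- species_spectra(d, glen)
  stats_rows[[k]] <- compute_assembly_stats(d, st$taxonomy, glen)
  shannon_contig[k] <- shannon(otu_spectrum(d, "contig"))
}
stats_tab <- do.call(rbind, stats_rows)

## distances to the ideal assembly: Bray-Curtis on coverage, Hellinger on
## fragmentation, grouped by split rate
cov_m <- profile_matrix(spectra, "coverage")
fr_m <- profile_matrix(spectra, "fragmentation")
d_cov <- distance_to_ideal(cov_m, "ideal", "bray",
                           groups = sprintf("s%.1f", grid$split))
d_fr <- distance_to_ideal(fr_m, "ideal", "hellinger",
                          groups = sprintf("s%.1f", grid$split))
dist_tab <- merge(d_cov$distances, d_fr$distances, by = "assembly",
                  suffixes = c("_bray_cov", "_hell_frag"))
write_tsv(dist_tab, "results/05_distance_to_ideal.tsv")
message(sprintf(paste0("coverage distance to ideal differs across split ",
                       "rates (Kruskal-Wallis p = %.2g)"),
                d_cov$kruskal$p.value))

## dendrogram over assemblies (ideal included) with bootstrap support
hb <- hcluster(cov_m, "bray", n_boot = 200, seed = cfg$seed)
writeLines(hb$newick, "results/05_dendrogram_coverage.nwk")
message("wrote results/05_dendrogram_coverage.nwk")

## pairwise Spearman correlations among the panel statistics
sm <- spearman_matrix(stats_tab)
write_tsv(data.frame(statistic = rownames(sm$rho), round(sm$rho, 3)),
          "results/05_spearman_rho.tsv")

## which statistics drive contig-mode Shannon? three-method consensus
assoc <- association_analysis(stats_tab, shannon_contig, seed = cfg$seed)
write_tsv(assoc, "results/05_association.tsv")
message(sprintf("consensus predictors of contig-mode Shannon: %s",
                paste(assoc$predictor[assoc$consensus], collapse = ", ")))
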