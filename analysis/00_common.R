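# Shared stage builders for the analysis drivers. Everything is derived
# deterministically from analysis/config.yaml; no intermediates on disk.
library(viromeval)

cfg <- read_run_config("analysis/config.yaml")
dir.create("results", showWarnings = FALSE)

stage_genomes <- function() {
  g <- generate_genomes(cfg$genomes$n_genomes,
                        c(cfg$genomes$min_len, cfg$genomes$max_len),
                        seed = cfg$seed)
  p <- sample_abundances(names(g$lengths),
                         cfg$simulation$abundance$model,
                         alpha = cfg$simulation$abundance$alpha,
                         seed = cfg$seed + 1)
  list(genomes = g, profile = p, taxonomy = inherit_taxonomy(g$taxonomy))
}

stage_sim <- function(st, n_pairs, sequences = FALSE) {
  simulate_paired_reads(st$genomes, st$profile, n_pairs,
                        read_len = cfg$simulation$read_len,
                        insert_mean = cfg$simulation$insert_mean,
                        insert_sd = cfg$simulation$insert_sd,
                        error_rate = cfg$simulation$error_rate,
                        qc_loss = cfg$simulation$qc_loss,
                        seed = cfg$seed + n_pairs,  # one stream per depth
                        sequences = sequences)
}

stage_ideal <- function(st, sim) {
  build_ideal_assembly(sim$provenance, st$genomes$lengths)
}

# the degradation grid: split x loss x replicate, fixed chimera rate
stage_grid <- function() {
  g <- expand.grid(split = cfg$degradation$split_rate,
                   loss = cfg$degradation$loss_rate,
                   rep = seq_len(cfg$degradation$replicates))
  g$chimera <- cfg$degradation$chimera_rate
  g$seed <- cfg$seed * 100 + seq_len(nrow(g))
  g$id <- sprintf("s%.1f_l%.2f_r%d", g$split, g$loss, g$rep)
  g
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
}
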