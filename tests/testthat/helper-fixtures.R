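# Shared fixtures and independent oracles, built in code at test time.

# small genome set + skewed profile + simulated reads, reused across files
make_fixture <- function(n_genomes = 12, n_pairs = 800, seed = 101,
                         error_rate = 0, qc_loss = 0) {
  g <- generate_genomes(n_genomes, c(2000, 12000), seed = seed)
  p <- sample_abundances(names(g$lengths), "power_law", alpha = 1,
                         seed = seed + 1)
  sim <- simulate_paired_reads(g, p, n_pairs = n_pairs,
                               insert_mean = 450, insert_sd = 40,
                               error_rate = error_rate, qc_loss = qc_loss,
                               seed = seed + 2)
  list(genomes = g, profile = p, sim = sim,
       ideal = build_ideal_assembly(sim$provenance, g$lengths),
       taxonomy = inherit_taxonomy(g$taxonomy))
}

# brute-force union by exhaustive pairwise merging: repeatedly fuse any two
# intervals that strictly overlap (half-open adjacency is not overlap)
oracle_union_spans <- function(start, end) {
  iv <- Map(c, start, end)
  repeat {
    merged <- FALSE
    for (i in seq_along(iv)) {
      for (j in seq_along(iv)) {
        if (i >= j) next
        a <- iv[[i]]; b <- iv[[j]]
        if (a[1] < b[2] && b[1] < a[2]) {
          iv[[i]] <- c(min(a[1], b[1]), max(a[2], b[2]))
          iv[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  out <- do.call(rbind, iv)
  out <- out[order(out[, 1]), , drop = FALSE]
  data.frame(start = out[, 1], end = out[, 2])
}

# merged spans per genome from an assembly's contig table
assembly_spans <- function(assembly) {
  ctg <- assembly$contigs[order(assembly$contigs$gi,
                                assembly$contigs$start), ]
  split(ctg[, c("start", "end")], ctg$gi)
}

# brute-force N50: scan cumulative sums explicitly
oracle_n50 <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  half <- sum(s) / 2
  acc <- 0
  for (x in s) {
    acc <- acc + x
    if (acc >= half) return(x)
  }
}

# random provenance table over a single small genome set
random_provenance <- function(n_reads, genome_lengths, seed,
                              read_len = 100) {
  set.seed(seed)
  gi <- sample(names(genome_lengths), n_reads, replace = TRUE)
  start <- floor(runif(n_reads) * (genome_lengths[gi] - read_len + 1))
  data.frame(read_id = sprintf("x%05d", seq_len(n_reads)), mate = 1L,
             gi = gi, start = as.integer(start),
             end = as.integer(start + read_len), strand = "+",
             stringsAsFactors = FALSE)
}
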