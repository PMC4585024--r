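test_that("genome generation respects count, lengths, determinism", {
  g <- generate_genomes(1, c(1000, 1000), seed = 7)
  expect_length(g$sequences, 1)
  expect_equal(unname(g$lengths), 1000)
  expect_equal(nchar(g$sequences[[1]]), 1000)

  g1 <- generate_genomes(15, c(2000, 9000), seed = 1)
  g2 <- generate_genomes(15, c(2000, 9000), seed = 1)
  expect_identical(g1, g2)
  expect_true(all(g1$lengths >= 2000 & g1$lengths <= 9000))
  expect_false(anyDuplicated(g1$taxonomy$gi) > 0)
  expect_equal(nchar(g1$sequences), unname(g1$lengths), ignore_attr = TRUE)

  expect_error(generate_genomes(3, c(100, 500), seed = 1), "read length")
})

test_that("taxonomy has the configured missingness, hierarchy-consistent", {
  g <- generate_genomes(60, c(2000, 4000), seed = 5,
                        missing_order_frac = 0.5, missing_genus_frac = 0.3)
  tax <- g$taxonomy
  expect_true(anyNA(tax$order))
  expect_true(anyNA(tax$genus))
  expect_false(anyNA(tax$species))
  expect_false(anyNA(tax$family))
  # order-missingness is a per-family property: no family half-classified
  by_fam <- tapply(is.na(tax$order), tax$family, function(x) length(unique(x)))
  expect_true(all(by_fam == 1))
})

test_that("abundance profiles are normalized and match closed forms", {
  expect_equal(sample_abundances(1, "uniform"), c(g1 = 1.0))
  expect_equal(unname(sample_abundances(4, "uniform")), rep(0.25, 4))
  # harmonic weights normalized by hand: (1, 1/2, 1/3) / H3
  h3 <- 1 + 1 / 2 + 1 / 3
  expect_equal(unname(sample_abundances(3, "power_law", alpha = 1)),
               c(1, 1 / 2, 1 / 3) / h3)
  expect_error(sample_abundances(3, "power_law", alpha = -1), "alpha")
  p <- sample_abundances(50, "power_law", alpha = 1.5, seed = 9)
  expect_equal(sum(p), 1)
  expect_true(all(p > 0))
})

test_that("abundance tables load with renormalization and row checks", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tab", "a\t5"), f)
  expect_equal(load_abundances(f), c(a = 1.0))

  writeLines(c("id\tab", "a\t3", "b\t0", "c\t1"), f)
  expect_warning(p <- load_abundances(f), "zero-abundance")
  expect_length(p, 2)
  expect_equal(sum(p), 1)

  writeLines(c("id\tab", "a\t3", "a\t1"), f)
  expect_error(load_abundances(f), "row 2")
  writeLines(c("id\tab", "a\tx"), f)
  expect_error(load_abundances(f), "non-numeric|missing")
})

test_that("shipped synthetic species-abundance table has 578 species", {
  p <- load_abundances(system.file("extdata",
                                   "abundance_table_s1_synthetic.tsv",
                                   package = "viromeval"))
  expect_length(p, 578)
  expect_equal(sum(p), 1)
})

test_that("read simulation honors pair counts, qc loss and coordinates", {
  g <- generate_genomes(5, c(2000, 5000), seed = 3)
  p <- sample_abundances(names(g$lengths), "uniform")
  sim <- simulate_paired_reads(g, p, n_pairs = 400, qc_loss = 0, seed = 11,
                               sequences = FALSE)
  expect_equal(nrow(sim$provenance), 800)
  expect_true(all(sim$provenance$end - sim$provenance$start == 300))
  expect_true(all(sim$provenance$start >= 0))
  expect_true(all(sim$provenance$end <= g$lengths[sim$provenance$gi]))

  # qc removes whole pairs: floor(1000 * 0.985) = 985 pairs -> 1970 reads
  sim2 <- simulate_paired_reads(g, p, n_pairs = 1000, qc_loss = 0.015,
                                seed = 11, sequences = FALSE)
  expect_equal(nrow(sim2$provenance), 1970)
  expect_equal(length(unique(sim2$provenance$read_id)), 985)
  # both mates always retained together
  expect_true(all(table(sim2$provenance$read_id) == 2))
})

test_that("zero-error reads are exact genome substrings on both strands", {
  g <- generate_genomes(1, c(4000, 4000), seed = 2)
  p <- sample_abundances(names(g$lengths), "uniform")
  sim <- simulate_paired_reads(g, p, n_pairs = 50, error_rate = 0,
                               qc_loss = 0, seed = 13)
  pv <- sim$provenance
  gseq <- g$sequences[[1]]
  m1 <- pv[pv$mate == 1, ]
  m2 <- pv[pv$mate == 2, ]
  expect_equal(as.character(sim$mate1),
               substring(gseq, m1$start + 1, m1$end), ignore_attr = TRUE)
  rc2 <- as.character(Biostrings::reverseComplement(sim$mate2))
  expect_equal(rc2, substring(gseq, m2$start + 1, m2$end),
               ignore_attr = TRUE)
})

test_that("identical seeds give byte-identical FASTQ and provenance", {
  g <- generate_genomes(4, c(2000, 3000), seed = 4)
  p <- sample_abundances(names(g$lengths), "power_law", seed = 4)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  s1 <- simulate_paired_reads(g, p, 100, seed = 21, fastq_prefix = f1)
  s2 <- simulate_paired_reads(g, p, 100, seed = 21, fastq_prefix = f2)
  expect_identical(s1$provenance, s2$provenance)
  expect_identical(readLines(s1$files[1]), readLines(s2$files[1]))
  expect_identical(readLines(s1$files[2]), readLines(s2$files[2]))
})

test_that("chi-squared abundance check matches hand arithmetic", {
  # counts (60, 40) against expected (50, 50): (10^2/50)*2 = 4.0
  prov <- data.frame(read_id = sprintf("r%03d", 1:100), mate = 1L,
                     gi = rep(c("a", "b"), c(60, 40)),
                     start = 0L, end = 100L, strand = "+")
  v <- verify_abundance(prov, c(a = 0.5, b = 0.5))
  expect_equal(v$statistic, 4.0)
  expect_equal(v$df, 1)

  # exactly proportional counts: statistic 0, p = 1
  prov2 <- data.frame(read_id = sprintf("r%03d", 1:100), mate = 1L,
                      gi = rep(c("a", "b"), c(25, 75)),
                      start = 0L, end = 100L, strand = "+")
  v2 <- verify_abundance(prov2, c(a = 0.25, b = 0.75))
  expect_equal(v2$statistic, 0)
  expect_equal(v2$p.value, 1)

  expect_error(verify_abundance(prov, c(a = 1)), "2")
  expect_error(verify_abundance(prov, c(a = 0.5, c = 0.5)), "absent")
})

test_that("degradation obeys its limit cases", {
  fx <- make_fixture(n_genomes = 6, n_pairs = 300)
  ideal <- fx$ideal

  # identity at zero rates: same read partition and same spans
  d0 <- degrade_assembly(ideal, 0, 0, 0, seed = 31)
  expect_equal(nrow(d0$contigs), nrow(ideal$contigs))
  expect_equal(assembly_spans(d0), assembly_spans(ideal))
  part <- function(a) unname(split(a$reads$read, a$reads$contig_id))
  expect_setequal(lapply(part(d0), sort), lapply(part(ideal), sort))

  # total loss empties the assembly
  d1 <- degrade_assembly(ideal, 0, 1, 0, seed = 31)
  expect_equal(nrow(d1$contigs), 0)
  expect_equal(pct_reads_assembled(d1), 0)

  # cutting all junctions isolates every read
  d2 <- degrade_assembly(ideal, 1, 0, 0, seed = 31)
  expect_equal(nrow(d2$contigs), nrow(ideal$reads))
  expect_true(all(d2$contigs$n_reads == 1))
})

test_that("degradation keeps the read partition valid and is seeded", {
  fx <- make_fixture(n_genomes = 8, n_pairs = 400)
  for (s in 1:5) {
    d <- degrade_assembly(fx$ideal, 0.4, 0.15, 0.1, seed = s)
    asm <- d$reads[!is.na(d$reads$contig_id), ]
    # every read exactly once: contig members + unassembled = all reads
    expect_equal(sort(d$reads$read), sort(fx$ideal$reads$read))
    expect_equal(sum(d$contigs$n_reads), nrow(asm))
  }
  da <- degrade_assembly(fx$ideal, 0.4, 0.15, 0.1, seed = 99)
  db <- degrade_assembly(fx$ideal, 0.4, 0.15, 0.1, seed = 99)
  expect_identical(da$reads, db$reads)
  expect_identical(da$contigs, db$contigs)
})

test_that("degradation responds monotonically to its rates over seeds", {
  fx <- make_fixture(n_genomes = 6, n_pairs = 250)
  seeds <- 1:20
  # mean fragmentation non-increasing in split_rate
  fr <- sapply(c(0.1, 0.5, 0.9), function(sr) {
    mean(sapply(seeds, function(s)
      mean_fragmentation(degrade_assembly(fx$ideal, sr, 0, 0, s),
                         fx$genomes$lengths)))
  })
  expect_true(all(diff(fr) <= 0))
  # chimera percentage non-decreasing in chimera_rate
  ch <- sapply(c(0, 0.1, 0.4), function(cr) {
    mean(sapply(seeds, function(s) {
      d <- degrade_assembly(fx$ideal, 0.3, 0, cr, s)
      chimera_rates(d, fx$taxonomy)[["pct_chim_gi"]]
    }))
  })
  expect_true(all(diff(ch) >= 0))
})
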