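---
title: "Evaluating viral metagenome assemblies with known read provenance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating viral metagenome assemblies with known read provenance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Viral metagenomes (viromes) have no universal marker gene, so community
composition and diversity are usually read off the assembly: contigs stand in
for taxa, contig abundances for taxon abundances. That makes every diversity
estimate hostage to assembler behavior. A fragmented assembly turns one
genome into many contigs; a chimeric contig fuses several genomes into one;
unassembled reads vanish from the accounting altogether. viromeval provides a
controlled laboratory for quantifying these effects: reads are simulated from
a known community, so the best attainable assembly is computable exactly, and
any real or emulated assembly can be scored against it.

```{r, eval = FALSE}
library(viromeval)
genomes <- generate_genomes(60, c(3000, 30000), seed = 1)
profile <- sample_abundances(names(genomes$lengths), "power_law",
                             alpha = 1, seed = 2)
sim   <- simulate_paired_reads(genomes, profile, n_pairs = 5000, seed = 3)
ideal <- build_ideal_assembly(sim$provenance, genomes$lengths)
```

# Simulation model

Each read pair is generated in four steps. A genome is drawn from the
relative-abundance profile; a fragment length is drawn
Normal(`insert_mean`, `insert_sd`) and clamped to [`read_len`, genome
length]; a fragment start is drawn uniformly over valid positions (genomes
are treated as linear, so no fragment spans the end); mate 1 is the forward
prefix of the fragment and mate 2 the reverse complement of its end.
Substitution errors are i.i.d. per base at `error_rate`, with flat Phred+33
quality strings. Finally a fraction `qc_loss` of whole pairs (default 1.5%)
is removed uniformly at random, emulating quality filtering in which
singletons are discarded; `floor(n_pairs * (1 - qc_loss))` pairs survive.

Every retained read carries a provenance record — genome, start, end, strand,
all 0-based half-open on the forward strand — which is the ground truth for
everything downstream.

Defaults mirror a MiSeq 2 x 300 bp run. The three depth scenarios of
interest are 0.05M, 0.5M and 5M reads (25,000 / 250,000 / 2,500,000 pairs),
i.e. 15 Mbp to 1.5 Gbp; the analysis drivers in `analysis/` run a
1:10:100-scaled series (500 / 5,000 / 50,000 pairs over 60 genomes) so every
stage re-runs in seconds, and the acceptance script runs the 0.05M scenario
in full over a 578-species community.

The abundance check (`verify_abundance`) is a chi-squared goodness of fit of
realized per-species counts against the profile. It is computed at the
*pair* level deliberately: both mates of a pair share one genome draw, so a
read-level statistic would be exactly twice the pair-level one and the test
would reject far too often under its own null.

What the generator does **not** emulate: indel and homopolymer errors,
quality decay along the read, GC or amplification (MDA/SISPA) bias,
circular genomes, strain-level variation within a species. Tests passing on
these simulations show the metrics behave correctly under the stated model,
not that any particular real assembler will reproduce them.

# The ideal assembly

The hypothetical best attainable assembly is built from provenance alone:
reads are grouped by genome, sorted by start (ties: end descending, then
read id, for determinism), and a running contig extends while the next read
starts strictly before the current maximum end. Exact adjacency does not
merge — half-open intervals that touch share no base. This is the interval
union of the read placements, verified in the tests against an exhaustive
pairwise-merging oracle. Every read is assembled by construction, which is
what makes the ideal assembly the upper bound: degradations can only lose
reads, split contigs, or mix genomes.

Real assemblies enter through `read_alignments()` (SAM/BAM of reads mapped
to contigs, primary alignments only); emulated ones through
`degrade_assembly()`, which applies three independent error processes —
per-read loss, per-junction splitting, and per-contig grafting of a read
block from another species. The grafted block is sized to at least 1/7 of
the contig so a grafted contig reliably crosses the 10% alternative-taxon
threshold; grafting *moves* reads (it never duplicates them), so the
partition invariant — every read in exactly one contig or unassembled —
survives degradation.

# The metrics panel

Per assembly: N50 (first length, descending, at which the cumulative sum
reaches half the total), largest contig, number of contigs, % reads
assembled, mean contig coverage (member-read bases over contig length,
averaged unweighted over contigs), chimera percentages at five taxonomic
levels, and mean fragmentation.

**Fragmentation.** For a genome of length L reconstructed in n fragments of
lengths l_i, F = (Σ l_i / L) / n, clamped to [0, 1]. One complete fragment
scores 1; splitting any fragment leaves Σ l_i/L unchanged but increments n,
so F strictly decreases. The assembly's mean fragmentation averages F over
all genomes with at least one read in the dataset; a genome whose reads left
no fragment contributes 0 but stays in the denominator. By default a
genome's fragments are its assigned contigs *plus* each of its unassembled
reads as a fragment of its own length (`fragments =
"contigs_and_unassembled"`); the `"contigs_only"` policy is available since
either reading of "fragment" is defensible, and the choice matters exactly
when read loss is heavy.

**Coverage and penalized coverage.** Species coverage C = (bases of reads in
contigs assigned to the genome + bases of its unassembled reads) / L, with
contigs assigned by the modal origin of their member reads. The
penalized-coverage index P = C x F deflates coverage for scattered
reconstructions; P = C exactly when F = 1 and P = 0 when the genome is
maximally fragmented, and P ≤ C always.

**Chimeras.** A contig is chimera-free at a rank when its modal taxon holds
at least 90% of member reads (the threshold is a parameter; the boundary
9/10 case is chimera-free). Viral taxonomy is full of missing genus and
order labels, so before counting, missing ranks inherit the nearest defined
rank with one "n_" prefix per step (more-specific neighbor searched first:
an order gap under family *Poxviridae* becomes n_Poxviridae), keeping
unclassified lineages distinguishable. The synthetic taxonomy generator
assigns order-missingness per family and genus-missingness per genome; this
keeps the filled taxonomy nested, which in turn guarantees the panel
invariant that chimera rates never increase from gi to order. With missing
labels assigned adversarially (half a family lacking its order, say),
inherited labels could split a coarser rank and break that monotonicity —
a constraint worth knowing when supplying external taxonomies.

# Diversity accounting

`otu_spectrum()` builds the abundance vector under two accountings: each
contig an OTU, or each species (GI) an OTU, with unassembled reads counted
as singleton OTUs (contig mode) or toward their species (gi mode) by
default. With read-count weights this makes the contig partition an exact
refinement of the species partition, which is why contig-as-OTU Shannon and
richness dominate the species-as-OTU values on every fragmented assembly —
the central caution of the framework: treating contigs as taxa inflates
diversity, and the inflation grows with fragmentation.

Estimators: Shannon H = −Σ p_i log p_i (conventional sign, natural log
default); Chao1 = S_obs + n1²/(2 n2), falling back to the standard
bias-corrected S_obs + n1(n1−1)/2 when there are no doubletons (the classic
formula divides by zero); ACE with the rare group defined as counts ≤ 10 —
consistent with its N_rare = Σ_{k=1..10} k f_k summation; a strict < 10
variant is a flag — returning NA with a warning when every rare OTU is a
singleton (C_ACE = 0); and observed species number. Chao1 and ACE need
integer counts, so coverage weighting is accepted for Shannon only. The
contig spectrum (number of contigs per read count q) is exported in PHACCS
text form together with the mean contig length for its genlengths
parameter; the PHACCS model fit itself is an external tool and is not
reproduced.

# Comparison machinery

Profiles (coverage, fragmentation or penalized coverage per genome) are
compared with Bray–Curtis or Hellinger distances. One empirical subtlety the
tests document: Hellinger is scale-invariant, so when splitting shrinks all
fragmentation scores roughly proportionally, the Hellinger distance to the
ideal need not grow with the split rate — Bray–Curtis, being
scale-sensitive, does grow monotonically and is the right metric for
"how far from ideal" questions on fragmentation profiles; Hellinger remains
useful for shape comparisons between assemblies.

Hierarchical clustering uses average linkage (UPGMA) with plain bootstrap
probabilities — the fraction of column-resampled replicates reproducing each
node's leaf set; multiscale (AU) corrections are out of scope. Group
contrasts are Kruskal–Wallis with Benjamini–Hochberg q-values, q < 0.05
throughout.

`association_analysis()` links each panel statistic to a diversity estimator
with three methods and flags predictors supported by at least two:
Spearman (BH q < 0.05), LASSO-penalized Gaussian GLM (nonzero coefficient at
the cross-validated lambda.1se — the sparser choice, preferred to keep false
flags rare under a null response), and random-forest permutation importance.
The forest flag requires the scaled %IncMSE — importance divided by its
standard error over trees, a z-like score — to exceed 2, roughly a
one-sided 95% criterion; a plain "importance > 0" rule would flag about half
of all pure-noise predictors. On the degradation grids the consensus set
recovered for contig-mode Shannon centers on the number of contigs, the
mean contig coverage and the mean fragmentation, the three statistics that
mechanically drive how many OTUs a fixed read set is carved into.

# Numerical and design choices

* Coordinates are 0-based half-open everywhere, including files; reverse
  reads are recorded by their forward-strand interval.
* Merge tie-breaks (end descending, then read id) make assemblies
  deterministic; identical seeds give byte-identical FASTQ, provenance and
  degradations.
* F is clamped to [0, 1] to absorb rounding at the upper boundary.
* Degenerate inputs refuse loudly: empty fragment lists, all-zero spectra,
  provenance coordinates beyond the genome, taxa missing every rank.
* Problem sizes: unit tests run communities of 4–20 genomes (2–12 kb) at
  100–800 pairs; the acceptance harnesses use 10–60 genomes, 25,000-pair
  simulations for the depth arithmetic and abundance calibration, a
  30-assembly degradation grid for association recovery, and the shipped
  578-species profile (a synthetic stand-in with power-law abundances — the
  published per-species table it emulates is not redistributed here) over
  genomes of 3–300 kb.

# Limitations

The degradation model is a caricature of real assemblers — three independent
error channels with no sequence dependence; it is designed to span the
metric space (fragmentation, loss, chimerism), not to imitate any specific
tool. Coverage uses read bases, so it measures depth semantics; a
consensus-length variant sits behind a flag. The ideal assembly assumes
provenance is exact, which holds for simulation but approximates real-data
mode, where alignment error leaks in. ACE is undefined on all-singleton rare
groups, which genuinely occurs on fully split assemblies; the report then
carries NA rather than a made-up number.
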