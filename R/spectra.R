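#' Genome fragmentation (completeness) score
#'
#' The mean fragment-to-genome length ratio: F = (sum_i l_i / L) / n for n
#' fragments of lengths l_i on a genome of length L, clamped to [0, 1]. A
#' single fragment covering the whole genome scores 1 (the optimum); many
#' small fragments drive the score toward 0 — splitting any fragment in two
#' leaves the ratio sum unchanged but increments n, so F strictly decreases.
#'
#' @param fragment_lengths non-empty vector of fragment lengths (bases).
#' @param genome_length genome length L > 0.
#' @return fragmentation score in [0, 1].
#' @export
genome_fragmentation <- function(fragment_lengths, genome_length) {
  stopifnot(genome_length > 0)
  if (length(fragment_lengths) == 0)
    stop("fragmentation undefined for a genome with no fragments")
  f <- sum(fragment_lengths / genome_length) / length(fragment_lengths)
  min(max(f, 0), 1)
}

#' Per-species coverage, fragmentation and penalized coverage
#'
#' For every genome with at least one read in the dataset:
#' \itemize{
#'   \item coverage C = (bases of reads in contigs assigned to the genome +
#'     bases of its unassembled reads) / genome length. Contigs are assigned
#'     to the genome of their modal member read.
#'   \item fragmentation F from \code{\link{genome_fragmentation}} over the
#'     genome's fragments: its assigned contigs plus (by default) each of its
#'     unassembled reads as a fragment of its own length; genomes with reads
#'     but no fragments score F = 0.
#'   \item penalized coverage P = C x F.
#' }
#'
#' @param assembly a \code{contig_assembly}.
#' @param genome_lengths named vector of genome lengths.
#' @param fragments \code{"contigs_and_unassembled"} (default) or
#'   \code{"contigs_only"}: whether unassembled reads count as fragments.
#' @param coverage_bases \code{"reads"} (default: member-read bases, i.e.
#'   sequencing depth) or \code{"consensus"} (contig consensus lengths).
#' @return data.frame with columns gi, coverage, fragmentation,
#'   penalized_coverage, n_fragments, genome_length; one row per genome with
#'   reads, ordered by gi.
#' @export
species_spectra <- function(assembly, genome_lengths,
                            fragments = c("contigs_and_unassembled",
                                          "contigs_only"),
                            coverage_bases = c("reads", "consensus")) {
  fragments <- match.arg(fragments)
  coverage_bases <- match.arg(coverage_bases)
  reads <- assembly$reads
  if (!all(reads$gi %in% names(genome_lengths)))
    stop("reads with unknown gi")
  gis <- sort(unique(reads$gi))
  ctg <- assembly$contigs
  asm <- reads[!is.na(reads$contig_id), , drop = FALSE]
  una <- reads[is.na(reads$contig_id), , drop = FALSE]
  ## bases of each contig attributed to its modal genome
  ctg_gi <- ctg$gi
  ctg_read_bases <- if (nrow(ctg) > 0) {
    tapply(asm$length, asm$contig_id, sum)[ctg$contig_id]
  } else numeric(0)

  out <- lapply(gis, function(g) {
    L <- genome_lengths[[g]]
    mine <- which(ctg_gi == g)
    una_g <- una[una$gi == g, , drop = FALSE]
    cov_contigs <- if (coverage_bases == "reads")
      sum(ctg_read_bases[mine]) else sum(ctg$length[mine])
    C <- (cov_contigs + sum(una_g$length)) / L
    frag_len <- ctg$length[mine]
    if (fragments == "contigs_and_unassembled")
      frag_len <- c(frag_len, una_g$length)
    Fg <- if (length(frag_len) == 0) 0 else
      genome_fragmentation(frag_len, L)
    data.frame(gi = g, coverage = C, fragmentation = Fg,
               penalized_coverage = C * Fg,
               n_fragments = length(frag_len), genome_length = L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Mean fragmentation of an assembly
#'
#' The sum of per-genome fragmentation scores divided by the number of
#' distinct genomes (GIs) with at least one read in the dataset. Genomes
#' whose reads left no fragment contribute 0 but stay in the denominator.
#'
#' @inheritParams species_spectra
#' @return mean fragmentation in [0, 1].
#' @export
mean_fragmentation <- function(assembly, genome_lengths,
                               fragments = "contigs_and_unassembled") {
  mean(species_spectra(assembly, genome_lengths,
                       fragments = fragments)$fragmentation)
}

#' Per-gi species coverage
#'
#' Convenience accessor returning the coverage column of
#' \code{\link{species_spectra}} as a named vector.
#'
#' @inheritParams species_spectra
#' @return named numeric vector of per-genome coverages.
#' @export
species_coverage <- function(assembly, genome_lengths,
                             coverage_bases = "reads") {
  sp <- species_spectra(assembly, genome_lengths,
                        coverage_bases = coverage_bases)
  stats::setNames(sp$coverage, sp$gi)
}

#' Penalized-coverage index
#'
#' The product of a genome's coverage and its fragmentation score: scattered,
#' incomplete reconstructions are penalized even when deeply covered, since
#' F < 1 deflates C and F = 0 annihilates it.
#'
#' @param C coverage (>= 0).
#' @param F_ fragmentation score in [0, 1].
#' @return P = C x F.
#' @export
penalized_coverage <- function(C, F_) {
  stopifnot(all(C >= 0), all(F_ >= 0), all(F_ <= 1))
  C * F_
}

#' Contig-coverage spectrum
#'
#' Per-contig coverage (member-read bases over contig length), in contig-id
#' order; its mean equals \code{\link{mean_contig_coverage}}.
#'
#' @param assembly a non-empty \code{contig_assembly}.
#' @return named numeric vector of per-contig coverages.
#' @export
contig_coverage_spectrum <- function(assembly) {
  ctg <- assembly$contigs
  if (nrow(ctg) == 0) stop("empty assembly")
  if (any(ctg$length <= 0)) stop("zero-length contig")
  asm <- assembly$reads[!is.na(assembly$reads$contig_id), , drop = FALSE]
  bases <- tapply(asm$length, asm$contig_id, sum)[ctg$contig_id]
  stats::setNames(as.numeric(bases) / ctg$length, ctg$contig_id)
}

#' Write per-species spectra to TSV
#'
#' @param spectra data.frame from \code{\link{species_spectra}}.
#' @param path output path.
#' @export
write_species_spectra <- function(spectra, path) {
  utils::write.table(spectra, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
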