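#' N50 of a set of contig lengths
#'
#' The contig length at which, with lengths sorted descending, the cumulative
#' sum first reaches at least half the assembly total.
#'
#' @param contig_lengths non-empty vector of positive lengths (bases).
#' @return the N50 in bases.
#' @export
n50 <- function(contig_lengths) {
  if (length(contig_lengths) == 0) stop("N50 undefined for an empty assembly")
  stopifnot(all(contig_lengths > 0))
  s <- sort(contig_lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Mean per-contig coverage of an assembly
#'
#' Coverage of a contig is the total bases of its member reads divided by the
#' contig length; the assembly value is the unweighted mean over contigs.
#'
#' @param assembly a \code{contig_assembly}.
#' @return mean contig coverage (dimensionless).
#' @export
mean_contig_coverage <- function(assembly) {
  mean(contig_coverage_spectrum(assembly))
}

#' Percentage of reads assembled into contigs
#'
#' @param assembly a \code{contig_assembly}.
#' @return percentage in [0, 100].
#' @export
pct_reads_assembled <- function(assembly) {
  n <- nrow(assembly$reads)
  stopifnot(n > 0)
  100 * sum(!is.na(assembly$reads$contig_id)) / n
}

#' Fill missing taxonomy ranks by neighbor inheritance
#'
#' Viral taxonomies frequently lack genus and order labels. To keep
#' unclassified lineages distinguishable when counting chimeras, each missing
#' rank inherits the label of the nearest defined rank, prefixed with one
#' "n_" per step: the nearest more-specific rank is searched first, then the
#' nearest less-specific one. For example a genome with no order but family
#' Poxviridae acquires order n_Poxviridae; if family is also missing and
#' genus is G, family becomes n_G and order n_n_G. The operation is
#' idempotent.
#'
#' @param taxonomy data.frame with columns gi, species, genus, family, order
#'   (NA = missing). Every row must have at least one defined rank.
#' @return the taxonomy with no missing labels.
#' @export
inherit_taxonomy <- function(taxonomy) {
  ranks <- c("species", "genus", "family", "order")
  stopifnot(all(c("gi", ranks) %in% names(taxonomy)))
  m <- as.matrix(taxonomy[, ranks])
  filled <- m
  for (r in seq_len(nrow(m))) {
    def <- which(!is.na(m[r, ]))
    if (length(def) == 0)
      stop("all ranks missing for gi ", taxonomy$gi[r])
    for (i in which(is.na(m[r, ]))) {
      for (d in seq_len(3)) {
        src <- c(i - d, i + d)
        src <- src[src >= 1 & src <= 4]
        src <- src[src %in% def]
        if (length(src) > 0) {
          filled[r, i] <- paste0(strrep("n_", d), m[r, src[1]])
          break
        }
      }
    }
  }
  taxonomy[, ranks] <- as.data.frame(filled, stringsAsFactors = FALSE)
  taxonomy
}

#' Chimera rates per taxonomic rank
#'
#' A contig is chimera-free at a rank when the reads of its most frequent
#' taxon make up at least \code{threshold} of its member reads (default 90\%);
#' otherwise it counts toward the chimeric percentage. Rates are computed per
#' GI and per rank (species, genus, family, order); unassembled reads are
#' excluded. Since the (inherited) taxonomy is nested, coarsening the rank
#' can only merge taxa, so the chimeric percentage is non-increasing from gi
#' to order.
#'
#' @param assembly a \code{contig_assembly}.
#' @param taxonomy inherited taxonomy table (no missing labels; see
#'   \code{\link{inherit_taxonomy}}).
#' @param threshold modal-read fraction required to call a contig
#'   chimera-free.
#' @return named numeric vector of chimeric-contig percentages:
#'   pct_chim_gi, pct_chim_species, pct_chim_genus, pct_chim_family,
#'   pct_chim_order.
#' @export
chimera_rates <- function(assembly, taxonomy, threshold = 0.9) {
  asm <- assembly$reads[!is.na(assembly$reads$contig_id), , drop = FALSE]
  if (nrow(asm) == 0) stop("chimera rates undefined for an empty assembly")
  ranks <- c("species", "genus", "family", "order")
  if (anyNA(taxonomy[, ranks]))
    stop("taxonomy has missing labels; run inherit_taxonomy() first")
  if (!all(asm$gi %in% taxonomy$gi))
    stop("assembly contains gis absent from the taxonomy")
  idx <- match(asm$gi, taxonomy$gi)
  labels <- cbind(gi = asm$gi,
                  as.matrix(taxonomy[idx, ranks, drop = FALSE]))
  cid <- asm$contig_id
  out <- vapply(colnames(labels), function(rk) {
    dt <- data.table::data.table(cid = cid, tx = labels[, rk])
    cnt <- dt[, list(n = .N), by = c("cid", "tx")]
    per <- cnt[, list(modal = max(n), size = sum(n)), by = "cid"]
    100 * mean(per$modal / per$size < threshold)
  }, numeric(1))
  names(out) <- paste0("pct_chim_", colnames(labels))
  out
}

#' Assembly-statistics panel
#'
#' Computes the full per-assembly statistics panel: N50, largest contig,
#' number of contigs, percentage of reads assembled, mean contig coverage,
#' chimeric-contig percentages at five taxonomic levels, and the mean genome
#' fragmentation score.
#'
#' @param assembly a \code{contig_assembly}.
#' @param taxonomy taxonomy table; inherited automatically if it still has
#'   missing labels.
#' @param genome_lengths named vector of genome lengths.
#' @param chimera_threshold modal-read fraction for the chimera rule.
#' @param fragments fragment policy for the fragmentation score (see
#'   \code{\link{species_spectra}}).
#' @return one-row data.frame of class \code{assembly_stats}.
#' @export
compute_assembly_stats <- function(assembly, taxonomy, genome_lengths,
                                   chimera_threshold = 0.9,
                                   fragments = "contigs_and_unassembled") {
  ranks <- c("species", "genus", "family", "order")
  if (anyNA(taxonomy[, ranks])) taxonomy <- inherit_taxonomy(taxonomy)
  ctg <- assembly$contigs
  if (nrow(ctg) == 0) stop("cannot compute statistics of an empty assembly")
  chim <- chimera_rates(assembly, taxonomy, chimera_threshold)
  out <- data.frame(
    n50                 = as.numeric(n50(ctg$length)),
    largest_contig      = as.numeric(max(ctg$length)),
    num_contig          = nrow(ctg),
    pct_reads_assembled = pct_reads_assembled(assembly),
    mean_contig_coverage = mean_contig_coverage(assembly),
    t(chim),
    mean_fragmentation  = mean_fragmentation(assembly, genome_lengths,
                                             fragments = fragments),
    stringsAsFactors = FALSE
  )
  class(out) <- c("assembly_stats", "data.frame")
  out
}

#' Aggregate assembly statistics over several assemblies
#'
#' Mean and standard deviation of each panel field over a set of assemblies,
#' the per-assembler / per-depth summary used to compare methods.
#'
#' @param stats_list list of \code{assembly_stats} rows (or a data.frame of
#'   stacked rows).
#' @return data.frame with one row per statistic: mean and sd.
#' @export
aggregate_assembly_stats <- function(stats_list) {
  df <- if (is.data.frame(stats_list)) stats_list else
    do.call(rbind, lapply(stats_list, as.data.frame))
  data.frame(statistic = names(df),
             mean = vapply(df, mean, numeric(1)),
             sd = vapply(df, stats::sd, numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
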