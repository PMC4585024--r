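#' Emulate real-assembler degradation of an ideal assembly
#'
#' Applies three independent error processes to an assembly, standing in for
#' the fragmentation, read loss and mis-assembly that distinguish real
#' assemblers from the ideal reconstruction:
#' \enumerate{
#'   \item each read is dropped (moved to the unassembled set) with
#'     probability \code{loss_rate};
#'   \item surviving reads of each contig are re-merged by the ideal overlap
#'     rule, and each internal read junction of each re-merged contig is cut
#'     with probability \code{split_rate}, producing sub-contigs;
#'   \item each resulting contig, with probability \code{chimera_rate},
#'     receives a block of reads moved from a contig of a different species,
#'     creating a chimeric contig (the block is sized to exceed the 10\%
#'     alternative-taxon threshold).
#' }
#' Deterministic for a fixed seed. With all rates 0 the read partition is
#' unchanged; with \code{split_rate = 1} every read becomes its own contig;
#' with \code{loss_rate = 1} the assembly is empty.
#'
#' @param ideal a \code{contig_assembly} (typically from
#'   \code{\link{build_ideal_assembly}}).
#' @param split_rate per-junction cut probability in [0,1].
#' @param loss_rate per-read drop probability in [0,1].
#' @param chimera_rate per-contig grafting probability in [0,1].
#' @param seed integer seed.
#' @return a degraded \code{contig_assembly} sharing the input's provenance.
#' @export
degrade_assembly <- function(ideal, split_rate, loss_rate, chimera_rate, seed) {
  stopifnot(inherits(ideal, "contig_assembly"),
            split_rate >= 0, split_rate <= 1,
            loss_rate >= 0, loss_rate <= 1,
            chimera_rate >= 0, chimera_rate <= 1)
  set.seed(as.integer(seed))
  reads <- ideal$reads

  ## 1. read loss
  drop <- stats::runif(nrow(reads)) < loss_rate
  lost <- reads$contig_id
  lost[drop] <- NA_character_

  ## 2. re-merge survivors per original contig, then cut junctions
  surv <- which(!is.na(lost))
  member <- vector("list", 0)
  if (length(surv) > 0) {
    o <- surv[order(reads$gi[surv], lost[surv], reads$start[surv],
                    -reads$end[surv], reads$read[surv])]
    grp <- split(o, lost[o])
    for (g in grp) {
      s <- reads$start[g]; e <- reads$end[g]
      cm <- cummax(e)
      newrun <- c(TRUE, s[-1] >= cm[-length(cm)])
      ## a junction joins consecutive reads inside a merged run; cut some
      if (split_rate > 0 && length(g) > 1) {
        cut <- stats::runif(length(g) - 1) < split_rate
        newrun[-1] <- newrun[-1] | cut
      }
      member <- c(member, unname(split(g, cumsum(newrun))))
    }
  }

  ## 3. chimera grafting: move a block of reads from a donor of another species
  if (chimera_rate > 0 && length(member) > 1) {
    ## contigs before grafting are single-species runs, so the modal genome
    ## is the genome of the first member read
    modal_gi <- reads$gi[vapply(member, `[`, integer(1), 1L)]
    sizes <- lengths(member)
    is_target <- stats::runif(length(member)) < chimera_rate
    if (length(unique(modal_gi)) > 1) {
      for (k in which(is_target)) {
        ## rejection-sample a non-empty donor contig of a different species
        d <- 0L
        for (try in 1:50) {
          cand <- sample.int(length(member), 1L)
          if (cand != k && sizes[cand] > 0L &&
              modal_gi[cand] != modal_gi[k]) { d <- cand; break }
        }
        if (d == 0L) next
        m <- min(max(1L, ceiling(sizes[k] / 6)), sizes[d])
        take <- utils::tail(member[[d]], m)
        member[[d]] <- utils::head(member[[d]], sizes[d] - m)
        member[[k]] <- c(member[[k]], take)
        sizes[d] <- sizes[d] - m
        sizes[k] <- sizes[k] + m
      }
    }
    member <- member[lengths(member) > 0]
  }

  new_cid <- rep(NA_character_, nrow(reads))
  for (k in seq_along(member))
    new_cid[member[[k]]] <- sprintf("d_c%05d", k)
  reads$contig_id <- new_cid
  .new_assembly(reads, .contig_table(reads), ideal$provenance)
}
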