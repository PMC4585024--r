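#' @title Contig assemblies
#' @description A \code{contig_assembly} holds a partition of reads into
#'   contigs plus an unassembled set, with a back-pointer to the provenance
#'   table. It is the unit every assembly metric consumes. Reads live in one
#'   table (\code{reads}: read, gi, start, end, length, contig_id; NA
#'   contig_id marks an unassembled read); contigs in another
#'   (\code{contigs}: contig_id, gi = modal origin, start/end span of the
#'   modal-origin reads, length = consensus length, n_reads).
#' @name contig_assembly
NULL

.new_assembly <- function(reads, contigs, provenance) {
  rownames(reads) <- NULL
  rownames(contigs) <- NULL
  structure(list(reads = reads, contigs = contigs, provenance = provenance),
            class = "contig_assembly")
}

#' @export
print.contig_assembly <- function(x, ...) {
  cat("contig_assembly:", nrow(x$contigs), "contigs,",
      sum(!is.na(x$reads$contig_id)), "assembled /",
      nrow(x$reads), "reads\n")
  invisible(x)
}

## total length of the union of half-open intervals [start, end)
.interval_union_length <- function(start, end) {
  o <- order(start, -end)
  start <- start[o]; end <- end[o]
  cm <- cummax(end)
  newrun <- c(TRUE, start[-1] >= cm[-length(cm)])
  run <- cumsum(newrun)
  sum(vapply(split(seq_along(run), run), function(i)
    max(end[i]) - start[i[1]], numeric(1)))
}

## modal value, ties broken lexicographically
.modal <- function(x) {
  tb <- sort(table(x), decreasing = TRUE)
  nm <- names(tb)[tb == tb[1]]
  sort(nm)[1]
}

## rebuild the contig table from an assigned read table; vectorized with
## data.table so it scales to assemblies with tens of thousands of contigs
.contig_table <- function(reads) {
  asm <- reads[!is.na(reads$contig_id), , drop = FALSE]
  if (nrow(asm) == 0) {
    return(data.frame(contig_id = character(), gi = character(),
                      start = integer(), end = integer(), length = integer(),
                      n_reads = integer(), stringsAsFactors = FALSE))
  }
  dt <- data.table::as.data.table(asm[, c("contig_id", "gi", "start", "end")])
  data.table::setorder(dt, contig_id, gi, start, -end)
  ## union length of the reads each (contig, genome) pair contributes
  per_gi <- dt[, {
    cm <- cummax(end)
    newrun <- c(TRUE, start[-1] >= cm[-.N])
    last <- c(which(newrun[-1]) , .N)
    list(n = .N, ulen = sum(cm[last] - start[newrun]),
         smin = start[1L], emax = cm[.N])
  }, by = c("contig_id", "gi")]
  ## modal genome per contig: most reads, ties to the lexicographic smallest
  data.table::setorderv(per_gi, c("contig_id", "n", "gi"),
                        order = c(1L, -1L, 1L))
  modal <- per_gi[, .SD[1L], by = "contig_id"]
  totals <- per_gi[, list(length = as.integer(sum(ulen)),
                          n_reads = as.integer(sum(n))), by = "contig_id"]
  out <- data.frame(contig_id = modal$contig_id, gi = modal$gi,
                    start = modal$smin, end = modal$emax,
                    length = totals$length[match(modal$contig_id,
                                                 totals$contig_id)],
                    n_reads = totals$n_reads[match(modal$contig_id,
                                                   totals$contig_id)],
                    stringsAsFactors = FALSE)
  out <- out[order(out$contig_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the ideal assembly from read provenance
#'
#' Constructs the hypothetical best attainable assembly: reads are grouped by
#' genome of origin, sorted by start position, and a running contig extends
#' while the next read starts before the current maximum end. Exact adjacency
#' (next start == current end) does not merge: half-open intervals that touch
#' share no base. Ties on start are broken by end descending, then read id.
#' Every read is assembled; the resulting contig set is the yardstick real
#' assemblies are compared against.
#'
#' @param provenance provenance data.frame (read_id, mate, gi, start, end,
#'   strand), coordinates 0-based half-open on the forward strand.
#' @param genome_lengths named integer vector of genome lengths.
#' @return a \code{contig_assembly}.
#' @export
build_ideal_assembly <- function(provenance, genome_lengths) {
  stopifnot(nrow(provenance) > 0)
  if (!all(provenance$gi %in% names(genome_lengths)))
    stop("provenance gis missing from genome_lengths")
  bad <- provenance$end > genome_lengths[provenance$gi] | provenance$start < 0
  if (any(bad))
    stop("read coordinates exceed genome length: ",
         provenance$read_id[which(bad)[1]])

  reads <- data.frame(
    read   = paste0(provenance$read_id, "/", provenance$mate),
    gi     = provenance$gi,
    start  = provenance$start,
    end    = provenance$end,
    length = provenance$end - provenance$start,
    stringsAsFactors = FALSE
  )
  o <- order(reads$gi, reads$start, -reads$end, reads$read)
  reads <- reads[o, , drop = FALSE]

  cid <- character(nrow(reads))
  for (g in split(seq_len(nrow(reads)), reads$gi)) {
    s <- reads$start[g]; e <- reads$end[g]
    cm <- cummax(e)
    newc <- c(TRUE, s[-1] >= cm[-length(cm)])
    cid[g] <- sprintf("%s_c%04d", reads$gi[g][1], cumsum(newc))
  }
  reads$contig_id <- cid
  .new_assembly(reads, .contig_table(reads), provenance)
}

#' Export ideal contigs to FASTA
#'
#' Writes one FASTA record per contig, the genome substring of the contig
#' span; headers carry contig id, origin gi and the 0-based half-open span.
#' Only defined for assemblies whose contigs have genomic spans (ideal
#' contigs).
#'
#' @param assembly a \code{contig_assembly} with per-contig spans.
#' @param genomes the \code{genome_set} the reads were simulated from.
#' @param path output FASTA path.
#' @return invisibly, the \code{DNAStringSet} written.
#' @export
export_contigs <- function(assembly, genomes, path) {
  ctg <- assembly$contigs
  if (nrow(ctg) == 0) {
    writeLines(character(0), path)
    return(invisible(Biostrings::DNAStringSet()))
  }
  glen <- genomes$lengths[ctg$gi]
  if (anyNA(glen) || any(ctg$end > glen) || any(ctg$start < 0))
    stop("contig span outside its genome")
  seqs <- Biostrings::DNAStringSet(
    substring(genomes$sequences[ctg$gi], ctg$start + 1L, ctg$end))
  names(seqs) <- sprintf("%s gi=%s span=%d-%d", ctg$contig_id, ctg$gi,
                         ctg$start, ctg$end)
  Biostrings::writeXStringSet(seqs, path)
  invisible(seqs)
}
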