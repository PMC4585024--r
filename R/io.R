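#' Write / read a read-provenance table
#'
#' TSV with header read_id, mate, gi, start, end, strand. Coordinates are
#' 0-based half-open on the forward genome strand, stated in a leading
#' comment line.
#'
#' @param provenance provenance data.frame.
#' @param path file path.
#' @return the path (write) or the provenance data.frame (read).
#' @export
write_provenance <- function(provenance, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates: 0-based half-open, forward strand", con)
  utils::write.table(provenance, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_provenance
#' @export
read_provenance <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    colClasses = c("character", "integer", "character",
                                   "integer", "integer", "character"),
                    stringsAsFactors = FALSE)
}

#' Build a contig assembly from read-to-contig alignments
#'
#' Real-data mode: ingests a SAM/BAM file of reads mapped against a contig
#' FASTA. Reads are assigned to contigs by their primary alignment
#' (secondary and supplementary records are ignored); unmapped reads go to
#' the unassembled set. If a provenance table is supplied, origin gis attach
#' to reads so chimera and per-species metrics become available; otherwise
#' gi is NA and only taxonomy-free statistics apply.
#'
#' Contig lengths are taken from the SAM header (@SQ LN); read coordinates
#' in the resulting assembly are contig coordinates (0-based half-open).
#'
#' @param sam_or_bam path to a SAM or BAM file.
#' @param provenance optional provenance data.frame keyed by read id
#'   ("read_id/mate" must match the alignment query names).
#' @return a \code{contig_assembly}.
#' @export
read_alignments <- function(sam_or_bam, provenance = NULL) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("read_alignments requires the Rsamtools package")
  path <- sam_or_bam
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "qwidth"))
  aln <- Rsamtools::scanBam(path, param = p)[[1]]
  flag <- aln$flag
  primary <- bitwAnd(flag, 0x100) == 0 & bitwAnd(flag, 0x800) == 0
  unmapped <- bitwAnd(flag, 0x4) != 0
  keep <- primary
  qname <- aln$qname[keep]
  if (anyDuplicated(qname[!unmapped[keep]]))
    stop("duplicate primary alignments for read ",
         qname[duplicated(qname) & !unmapped[keep]][1])
  rname <- as.character(aln$rname)[keep]
  pos <- aln$pos[keep]
  w <- aln$qwidth[keep]
  un <- unmapped[keep]

  start <- ifelse(un, 0L, pos - 1L)            # SAM pos is 1-based
  end <- ifelse(un, w, pos - 1L + w)
  gi <- rep(NA_character_, length(qname))
  if (!is.null(provenance)) {
    key <- paste0(provenance$read_id, "/", provenance$mate)
    gi <- provenance$gi[match(qname, key)]
  }
  reads <- data.frame(read = qname, gi = gi,
                      start = as.integer(start), end = as.integer(end),
                      length = as.integer(w),
                      contig_id = ifelse(un, NA_character_, rname),
                      stringsAsFactors = FALSE)
  contigs <- .contig_table_alignments(reads)
  .new_assembly(reads, contigs, provenance)
}

## contig table for alignment-derived assemblies: contig length = span of
## aligned reads on the contig; gi = modal origin when provenance is known
.contig_table_alignments <- function(reads) {
  asm <- reads[!is.na(reads$contig_id), , drop = FALSE]
  if (nrow(asm) == 0) {
    return(data.frame(contig_id = character(), gi = character(),
                      start = integer(), end = integer(), length = integer(),
                      n_reads = integer(), stringsAsFactors = FALSE))
  }
  sp <- split(asm, asm$contig_id)
  out <- do.call(rbind, lapply(sp, function(d) {
    gi <- if (all(is.na(d$gi))) NA_character_ else .modal(d$gi[!is.na(d$gi)])
    data.frame(contig_id = d$contig_id[1], gi = gi,
               start = min(d$start), end = max(d$end),
               length = max(d$end) - min(d$start),
               n_reads = nrow(d), stringsAsFactors = FALSE)
  }))
  out[order(out$contig_id), , drop = FALSE]
}

#' Read a pipeline run configuration
#'
#' YAML file with a \code{seed}, a \code{simulation} block (n_pairs,
#' read_len, insert_mean, insert_sd, error_rate, qc_loss, abundance model
#' and alpha), a \code{degradation} block (vectors split_rate, loss_rate,
#' chimera_rate forming the grid) and a \code{metrics} block
#' (chimera_threshold, fragments policy, weighting). Missing fields take the
#' package defaults, so a persisted config re-runs to identical outputs.
#'
#' @param path YAML config path.
#' @return list of class \code{run_config}.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  def <- list(
    seed = 1L,
    simulation = list(n_pairs = 25000L, read_len = 300L, insert_mean = 500,
                      insert_sd = 50, error_rate = 0.001, qc_loss = 0.015,
                      abundance = list(model = "power_law", alpha = 1)),
    degradation = list(split_rate = c(0.2, 0.5, 0.8), loss_rate = 0.1,
                       chimera_rate = 0.05),
    metrics = list(chimera_threshold = 0.9,
                   fragments = "contigs_and_unassembled",
                   weighting = "reads")
  )
  merged <- utils::modifyList(def, cfg)
  structure(merged, class = c("run_config", "list"))
}
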