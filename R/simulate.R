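#' Simulate provenance-tagged paired-end reads
#'
#' Emulates an Illumina-style 2 x \code{read_len} bp paired-end run over a
#' genome set: for each pair a genome is drawn from the abundance profile, a
#' fragment start is placed uniformly over valid positions, mate 1 is the
#' forward prefix of the fragment and mate 2 the reverse complement of the
#' fragment end. Substitution errors are i.i.d. per base at
#' \code{error_rate}; a fraction \code{qc_loss} of whole pairs is removed at
#' the end, emulating quality filtering with singleton removal. Every
#' retained read carries a provenance record (genome, start, end, strand; all
#' coordinates 0-based half-open on the forward strand), the ground truth for
#' ideal assembly and chimera calls.
#'
#' Genomes are treated as linear: no fragment spans the genome end. Fragment
#' lengths are drawn Normal(\code{insert_mean}, \code{insert_sd}) and clamped
#' to [\code{read_len}, genome length]; overlapping mates are allowed.
#'
#' @param genomes a \code{genome_set} (see \code{\link{generate_genomes}}).
#' @param profile named abundance vector over (a subset of) the genome gis;
#'   must be positive and sum to 1.
#' @param n_pairs number of read pairs to simulate before quality loss.
#' @param read_len read length in bases (default 300).
#' @param insert_mean,insert_sd fragment-length distribution in bases.
#' @param error_rate per-base substitution probability.
#' @param qc_loss fraction of pairs removed by the quality-filtering step
#'   (default 0.015); \code{floor(n_pairs * (1 - qc_loss))} pairs survive.
#' @param seed integer seed; identical seeds give byte-identical output.
#' @param sequences if FALSE, only the provenance table is generated (fast
#'   path for abundance-calibration studies that never look at base calls).
#' @param fastq_prefix if non-NULL, write mates to
#'   \code{<prefix>_R1.fastq} / \code{<prefix>_R2.fastq} (Phred+33, flat
#'   quality).
#' @return list of class \code{sim_reads} with elements \code{provenance}
#'   (data.frame: read_id, mate, gi, start, end, strand), \code{mate1},
#'   \code{mate2} (named \code{DNAStringSet}s, NULL when
#'   \code{sequences = FALSE}) and \code{files}.
#' @export
simulate_paired_reads <- function(genomes, profile, n_pairs,
                                  read_len = 300L,
                                  insert_mean = 500, insert_sd = 50,
                                  error_rate = 0.001, qc_loss = 0.015,
                                  seed = 1L, sequences = TRUE,
                                  fastq_prefix = NULL) {
  stopifnot(inherits(genomes, "genome_set"), n_pairs >= 1,
            qc_loss >= 0, qc_loss < 1, error_rate >= 0, error_rate <= 1)
  if (length(profile) == 0) stop("empty abundance profile")
  if (is.null(names(profile)) || !all(names(profile) %in% names(genomes$lengths)))
    stop("profile contains gis absent from the genome set")
  if (any(profile <= 0)) stop("abundances must be positive")
  if (abs(sum(profile) - 1) > 1e-9) stop("abundances must sum to 1")
  glen <- genomes$lengths[names(profile)]
  if (any(glen < read_len))
    stop("every genome with nonzero abundance must be at least read_len long")

  set.seed(as.integer(seed))
  gi_idx <- sample.int(length(profile), n_pairs, replace = TRUE, prob = profile)
  gi <- names(profile)[gi_idx]
  L <- glen[gi_idx]
  frag <- round(stats::rnorm(n_pairs, insert_mean, insert_sd))
  frag <- pmin(pmax(frag, read_len), L)
  start <- floor(stats::runif(n_pairs) * (L - frag + 1))  # 0-based

  ## quality filtering removes whole pairs, uniformly at random
  n_keep <- floor(n_pairs * (1 - qc_loss))
  keep <- sort(sample.int(n_pairs, n_keep))

  pid <- sprintf("r%07d", keep)
  s1 <- start[keep]; e1 <- s1 + read_len
  e2 <- start[keep] + frag[keep]; s2 <- e2 - read_len
  prov <- data.frame(
    read_id = rep(pid, each = 2L),
    mate    = rep(c(1L, 2L), times = n_keep),
    gi      = rep(gi[keep], each = 2L),
    start   = as.integer(rbind(s1, s2)),
    end     = as.integer(rbind(e1, e2)),
    strand  = rep(c("+", "-"), times = n_keep),
    stringsAsFactors = FALSE
  )

  mate1 <- mate2 <- NULL
  files <- NULL
  if (sequences) {
    gseq <- genomes$sequences
    raw1 <- substring(gseq[gi[keep]], s1 + 1L, e1)
    raw2_fwd <- substring(gseq[gi[keep]], s2 + 1L, e2)
    seq1 <- .add_substitutions(raw1, error_rate)
    seq2_fwd <- .add_substitutions(raw2_fwd, error_rate)
    mate1 <- Biostrings::DNAStringSet(seq1)
    mate2 <- Biostrings::reverseComplement(Biostrings::DNAStringSet(seq2_fwd))
    names(mate1) <- paste0(pid, "/1")
    names(mate2) <- paste0(pid, "/2")
    if (!is.null(fastq_prefix)) {
      files <- paste0(fastq_prefix, c("_R1.fastq", "_R2.fastq"))
      qual <- Biostrings::BStringSet(rep(strrep("I", read_len), n_keep))
      Biostrings::writeXStringSet(mate1, files[1], format = "fastq",
                                  qualities = qual)
      Biostrings::writeXStringSet(mate2, files[2], format = "fastq",
                                  qualities = qual)
    }
  }

  structure(list(provenance = prov, mate1 = mate1, mate2 = mate2,
                 files = files, read_len = as.integer(read_len)),
            class = "sim_reads")
}

## i.i.d. substitutions; each mutated base is replaced by one of the 3 others
.add_substitutions <- function(seqs, error_rate) {
  if (error_rate <= 0 || length(seqs) == 0) return(seqs)
  n_mut <- stats::rbinom(length(seqs), nchar(seqs), error_rate)
  hit <- which(n_mut > 0)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    pos <- sample.int(length(ch), n_mut[i])
    for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1)
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Chi-squared check of simulated abundances against the target profile
#'
#' Goodness-of-fit of the realized per-species read-pair counts against the
#' abundance profile the reads were drawn from. The test is carried out at
#' the fragment (pair) level, the level at which species are actually drawn:
#' both mates of a pair share one origin, so counting mates separately would
#' double the statistic and break the test's calibration.
#'
#' @param provenance provenance data.frame from
#'   \code{\link{simulate_paired_reads}} (or any table with read_id and gi).
#' @param profile the named abundance profile used for simulation.
#' @return list with \code{statistic}, \code{p.value}, \code{df},
#'   \code{observed} and \code{expected}.
#' @export
verify_abundance <- function(provenance, profile) {
  stopifnot(length(profile) >= 2)
  pairs <- provenance[!duplicated(provenance$read_id), , drop = FALSE]
  if (!all(pairs$gi %in% names(profile)))
    stop("provenance contains species absent from the profile")
  obs <- table(factor(pairs$gi, levels = names(profile)))
  obs <- as.numeric(obs)
  expd <- profile / sum(profile) * sum(obs)
  stat <- sum((obs - expd)^2 / expd)
  df <- length(profile) - 1L
  list(statistic = stat,
       p.value = stats::pchisq(stat, df, lower.tail = FALSE),
       df = df, observed = obs, expected = expd)
}
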