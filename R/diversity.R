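#' OTU spectrum of an assembly
#'
#' Builds the abundance spectrum that alpha-diversity estimators consume,
#' under one of two accountings:
#' \itemize{
#'   \item \code{mode = "contig"}: each contig is an OTU, weighted by its
#'     member-read count (or by its coverage); each unassembled read is a
#'     singleton OTU (weight 1) when \code{include_unassembled} is TRUE.
#'   \item \code{mode = "gi"}: each species (GI) is an OTU; its weight is the
#'     sum of the weights of the contigs assigned to it plus its unassembled
#'     reads.
#' }
#' With read-count weights and \code{include_unassembled = TRUE} the contig
#' partition is an exact refinement of the gi partition, which is what makes
#' contig-as-OTU diversity dominate species-as-OTU diversity on fragmented
#' assemblies.
#'
#' @param assembly a \code{contig_assembly}.
#' @param mode \code{"contig"} or \code{"gi"}.
#' @param weighting \code{"reads"} (integer counts; required by Chao1/ACE) or
#'   \code{"coverage"}.
#' @param include_unassembled count unassembled reads as singleton OTUs
#'   (contig mode) / toward their species (gi mode). Default TRUE.
#' @return list of class \code{otu_spectrum}: mode, weighting, and
#'   \code{weights} (named numeric vector).
#' @export
otu_spectrum <- function(assembly, mode = c("contig", "gi"),
                         weighting = c("reads", "coverage"),
                         include_unassembled = TRUE) {
  mode <- match.arg(mode)
  weighting <- match.arg(weighting)
  ctg <- assembly$contigs
  reads <- assembly$reads
  una <- reads[is.na(reads$contig_id), , drop = FALSE]
  w_ctg <- if (weighting == "reads") {
    stats::setNames(as.numeric(ctg$n_reads), ctg$contig_id)
  } else {
    contig_coverage_spectrum(assembly)
  }
  if (mode == "contig") {
    w <- w_ctg
    if (include_unassembled && nrow(una) > 0)
      w <- c(w, stats::setNames(rep(1, nrow(una)), paste0("u_", una$read)))
  } else {
    gis <- sort(unique(c(ctg$gi, if (include_unassembled) una$gi)))
    w <- stats::setNames(numeric(length(gis)), gis)
    if (nrow(ctg) > 0) {
      per_gi <- tapply(w_ctg, ctg$gi, sum)
      w[names(per_gi)] <- per_gi
    }
    if (include_unassembled && nrow(una) > 0) {
      per_gi_u <- table(una$gi)
      w[names(per_gi_u)] <- w[names(per_gi_u)] + as.numeric(per_gi_u)
    }
  }
  if (sum(w) <= 0) stop("all-zero OTU spectrum")
  structure(list(mode = mode, weighting = weighting, weights = w),
            class = "otu_spectrum")
}

.spectrum_weights <- function(x) {
  if (inherits(x, "otu_spectrum")) x$weights else as.numeric(x)
}

#' Shannon entropy index
#'
#' H = -sum_i p_i log_b p_i over OTU proportions p_i. Zero-weight OTUs are
#' skipped; the conventional minus sign is used so H >= 0, with H = 0 for a
#' single OTU and H = ln S for S equally abundant OTUs (natural log default).
#'
#' @param x an \code{otu_spectrum} or a vector of non-negative weights.
#' @param base logarithm base (default e).
#' @return Shannon index H.
#' @export
shannon <- function(x, base = exp(1)) {
  w <- .spectrum_weights(x)
  w <- w[w > 0]
  if (length(w) == 0) stop("all-zero spectrum")
  p <- w / sum(w)
  -sum(p * log(p, base = base))
}

#' Chao1 richness estimator
#'
#' S_Chao1 = S_obs + n1^2 / (2 n2), with n1 the number of singletons and n2
#' the number of doubletons. When n2 = 0 the classic formula divides by zero;
#' the standard bias-corrected fallback S_obs + n1 (n1 - 1) / 2 is used.
#'
#' @param counts integer OTU counts (or an \code{otu_spectrum} with read
#'   weights).
#' @return the Chao1 richness estimate.
#' @export
chao1 <- function(counts) {
  n <- .integer_counts(counts)
  s_obs <- sum(n > 0)
  n1 <- sum(n == 1)
  n2 <- sum(n == 2)
  if (n2 > 0) s_obs + n1^2 / (2 * n2) else s_obs + n1 * (n1 - 1) / 2
}

#' ACE richness estimator
#'
#' Abundance-based Coverage Estimator: S_ACE = S_rest + S_rare / C_ACE +
#' (F1 / C_ACE) gamma^2, where the rare group holds OTUs with at most
#' \code{rare_cutoff} observations (default 10, consistent with the
#' N_rare = sum_{k=1..10} k f_k summation; set \code{strict} for < 10),
#' C_ACE = 1 - F1 / N_rare is the sample coverage of the rare group, and
#' gamma^2 = max[(S_rare / C_ACE) sum k(k-1) f_k / (N_rare (N_rare - 1)) - 1,
#' 0] its coefficient of variation. When no OTU is rare, S_ACE = S_rest =
#' S_obs. When every rare OTU is a singleton C_ACE = 0 and the estimator is
#' undefined: NA is returned with a warning.
#'
#' @param counts integer OTU counts (or an \code{otu_spectrum} with read
#'   weights).
#' @param rare_cutoff largest count still considered rare (default 10).
#' @param strict if TRUE, the rare group is counts < 10 rather than <= 10.
#' @return the ACE richness estimate (NA if undefined).
#' @export
ace <- function(counts, rare_cutoff = 10, strict = FALSE) {
  n <- .integer_counts(counts)
  n <- n[n > 0]
  cutoff <- if (strict) rare_cutoff - 1 else rare_cutoff
  rare <- n[n <= cutoff]
  s_rest <- sum(n > cutoff)
  if (length(rare) == 0) return(as.numeric(s_rest))
  s_rare <- length(rare)
  n_rare <- sum(rare)
  f1 <- sum(rare == 1)
  c_ace <- 1 - f1 / n_rare
  if (c_ace == 0) {
    warning("ACE undefined: every rare OTU is a singleton (C_ACE = 0)")
    return(NA_real_)
  }
  fk <- tabulate(rare, nbins = rare_cutoff)
  k <- seq_len(rare_cutoff)
  sum_kk1 <- sum(k * (k - 1) * fk)
  gamma2 <- if (n_rare > 1) {
    max(s_rare / c_ace * sum_kk1 / (n_rare * (n_rare - 1)) - 1, 0)
  } else 0
  s_rest + s_rare / c_ace + f1 / c_ace * gamma2
}

#' Observed number of species
#'
#' The number of OTUs with at least one observation.
#'
#' @param counts OTU counts (or an \code{otu_spectrum}).
#' @return integer species count.
#' @export
spec_number <- function(counts) {
  w <- .spectrum_weights(counts)
  sum(w > 0)
}

.integer_counts <- function(x) {
  w <- .spectrum_weights(x)
  if (inherits(x, "otu_spectrum") && x$weighting != "reads")
    stop("count-based estimators require read-count weighting, not ",
         x$weighting)
  if (any(w < 0)) stop("counts must be non-negative")
  if (any(abs(w - round(w)) > 1e-8))
    stop("count-based estimators require integer counts")
  round(w)
}

#' Contig spectrum for PHACCS
#'
#' The distribution counting, for each q, the number of contigs composed of
#' q reads, plus the mean contig length (the PHACCS "genlengths" parameter).
#' Unassembled reads can be counted as one-read contigs at position 1.
#'
#' @param assembly a non-empty \code{contig_assembly}.
#' @param include_unassembled count unassembled reads as 1-read contigs
#'   (default TRUE).
#' @return list of class \code{contig_spectrum}: \code{spectrum} (integer
#'   vector indexed by q = 1..max reads per contig) and \code{genlengths}
#'   (mean contig length in bases).
#' @export
contig_spectrum_phaccs <- function(assembly, include_unassembled = TRUE) {
  ctg <- assembly$contigs
  if (nrow(ctg) == 0) stop("empty assembly")
  q <- ctg$n_reads
  spec <- tabulate(q, nbins = max(q))
  if (include_unassembled) {
    n_una <- sum(is.na(assembly$reads$contig_id))
    spec[1] <- spec[1] + n_una
  }
  names(spec) <- seq_along(spec)
  structure(list(spectrum = spec, genlengths = mean(ctg$length)),
            class = "contig_spectrum")
}

#' Write a contig spectrum in PHACCS text format
#'
#' One line of whitespace-separated counts, position q holding the number of
#' q-read contigs, preceded by a comment line with the genlengths value.
#'
#' @param cs a \code{contig_spectrum}.
#' @param path output path.
#' @export
write_phaccs_spectrum <- function(cs, path) {
  writeLines(c(sprintf("# genlengths=%g", cs$genlengths),
               paste(cs$spectrum, collapse = " ")), path)
  invisible(path)
}

#' Alpha-diversity report for an assembly
#'
#' Computes the four estimators (Shannon, Chao1, ACE, species number) under
#' the requested OTU accounting. Chao1 and ACE need integer counts, so
#' coverage weighting is only accepted for the Shannon index.
#'
#' @param assembly a \code{contig_assembly}.
#' @param mode OTU accounting: \code{"contig"}, \code{"gi"}, or both.
#' @param weighting \code{"reads"} (default) or \code{"coverage"}.
#' @param include_unassembled see \code{\link{otu_spectrum}}.
#' @param assembly_id label recorded in the output.
#' @return data.frame with one row per mode: assembly, mode, weighting,
#'   shannon, chao1, ace, spec_number.
#' @export
diversity_report <- function(assembly, mode = c("contig", "gi"),
                             weighting = "reads",
                             include_unassembled = TRUE,
                             assembly_id = "assembly") {
  mode <- match.arg(mode, c("contig", "gi"), several.ok = TRUE)
  if (weighting == "coverage")
    stop("coverage weighting is only defined for shannon(); ",
         "count-based estimators (Chao1, ACE) require read counts")
  rows <- lapply(mode, function(m) {
    sp <- otu_spectrum(assembly, mode = m, weighting = weighting,
                       include_unassembled = include_unassembled)
    data.frame(assembly = assembly_id, mode = m, weighting = weighting,
               shannon = shannon(sp), chao1 = chao1(sp), ace = ace(sp),
               spec_number = spec_number(sp), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
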