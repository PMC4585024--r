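#' Generate a synthetic set of viral reference genomes
#'
#' Creates \code{n_genomes} random genomes with i.i.d. uniform base
#' composition and lengths drawn uniformly from \code{length_range}, together
#' with a nested five-rank taxonomy (gi, species, genus, family, order).
#' Genomes stand in for RefSeq records: each carries a unique GI-style
#' identifier used as the species-level accounting unit throughout the
#' package.
#'
#' Taxonomy is generated as a nested hierarchy (species within genera within
#' families within orders). Missing labels -- common in viral taxonomy at the
#' genus and order ranks -- are introduced in a hierarchy-consistent way:
#' order labels go missing for whole families at a time and genus labels per
#' genome, so that filling them by rank inheritance (see
#' \code{\link{inherit_taxonomy}}) never splits a coarser rank.
#'
#' @param n_genomes number of genomes (>= 1).
#' @param length_range numeric length-2 vector, min and max genome length in
#'   bases. The minimum must be at least \code{read_len}, otherwise no read
#'   could be placed.
#' @param seed integer seed; identical seeds give byte-identical genome sets.
#' @param read_len read length the genomes must accommodate (default 300).
#' @param missing_order_frac fraction of families whose order label is missing.
#' @param missing_genus_frac fraction of genomes whose genus label is missing.
#' @param species_per_genus,genera_per_family,families_per_order branching of
#'   the synthetic taxonomy.
#' @return an object of class \code{genome_set}: a list with elements
#'   \code{sequences} (named character vector of genome sequences),
#'   \code{lengths} (named integer vector) and \code{taxonomy} (data.frame
#'   with columns gi, species, genus, family, order; NA marks missing labels).
#' @export
generate_genomes <- function(n_genomes, length_range, seed,
                             read_len = 300L,
                             missing_order_frac = 0.3,
                             missing_genus_frac = 0.2,
                             species_per_genus = 3L,
                             genera_per_family = 3L,
                             families_per_order = 3L) {
  stopifnot(n_genomes >= 1, length(length_range) == 2)
  length_range <- as.integer(round(length_range))
  if (length_range[1] > length_range[2])
    stop("length_range must be (min, max) with min <= max")
  if (length_range[1] < read_len)
    stop("minimum genome length (", length_range[1],
         ") is below the read length (", read_len, "): cannot place a read")

  set.seed(as.integer(seed))
  lens <- if (length_range[1] == length_range[2]) {
    rep(length_range[1], n_genomes)
  } else {
    sample(seq(length_range[1], length_range[2]), n_genomes, replace = TRUE)
  }
  seqs <- vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
  gi <- sprintf("gi_%06d", seq_len(n_genomes))
  names(seqs) <- gi
  names(lens) <- gi

  ## nested hierarchy by contiguous blocks: species -> genus -> family -> order
  genus_id  <- ceiling(seq_len(n_genomes) / species_per_genus)
  family_id <- ceiling(genus_id / genera_per_family)
  order_id  <- ceiling(family_id / families_per_order)
  tax <- data.frame(
    gi      = gi,
    species = sprintf("sp_%06d", seq_len(n_genomes)),
    genus   = sprintf("g_%05d", genus_id),
    family  = sprintf("f_%04d", family_id),
    order   = sprintf("o_%03d", order_id),
    stringsAsFactors = FALSE
  )

  ## order-missingness per family (whole families lose their order label)
  fams <- unique(family_id)
  n_missing_fam <- round(missing_order_frac * length(fams))
  if (n_missing_fam > 0) {
    miss_fams <- sample(fams, n_missing_fam)
    tax$order[family_id %in% miss_fams] <- NA_character_
  }
  ## genus-missingness per genome (filled later from the genome-unique species)
  n_missing_gen <- round(missing_genus_frac * n_genomes)
  if (n_missing_gen > 0) {
    miss_rows <- sample(n_genomes, n_missing_gen)
    tax$genus[miss_rows] <- NA_character_
  }

  structure(list(sequences = seqs,
                 lengths = stats::setNames(as.integer(lens), gi),
                 taxonomy = tax),
            class = "genome_set")
}

#' @export
print.genome_set <- function(x, ...) {
  cat("genome_set:", length(x$sequences), "genomes,",
      "lengths", min(x$lengths), "-", max(x$lengths), "bp\n")
  invisible(x)
}

#' Sample a relative-abundance profile
#'
#' Draws a species-abundance profile over a set of genomes, either uniform or
#' power-law-like (rank-abundance weight i^(-alpha)), emulating the strongly
#' skewed abundance distributions typical of gut viromes.
#'
#' @param gis either an integer count of species or a character vector of
#'   genome identifiers. With a count, identifiers \code{g1..gn} are used.
#'   Rank 1 (most abundant) is the first identifier.
#' @param model \code{"power_law"} or \code{"uniform"}.
#' @param alpha power-law exponent (>= 0); ignored for the uniform model.
#' @param seed optional seed; when given, species ranks are shuffled so the
#'   most abundant species is not always the first genome.
#' @return named numeric vector of relative abundances summing to 1.
#' @export
sample_abundances <- function(gis, model = c("power_law", "uniform"),
                              alpha = 1, seed = NULL) {
  model <- match.arg(model)
  if (is.numeric(gis) && length(gis) == 1) gis <- paste0("g", seq_len(gis))
  n <- length(gis)
  stopifnot(n >= 1)
  if (alpha < 0) stop("alpha must be >= 0")
  w <- switch(model,
    uniform   = rep(1, n),
    power_law = seq_len(n)^(-alpha)
  )
  if (!is.null(seed)) {
    set.seed(as.integer(seed))
    w <- w[sample.int(n)]
  }
  p <- w / sum(w)
  names(p) <- gis
  p
}

#' Load a relative-abundance profile from a two-column table
#'
#' Reads a tab-separated table of species identifiers and abundances (such as
#' a published per-species virome abundance table), drops zero-abundance rows
#' with a warning (they can emit no reads) and renormalizes to sum 1.
#'
#' @param path path to a TSV with two columns: identifier and numeric
#'   abundance. A header line is expected; lines starting with '#' are
#'   ignored.
#' @return named numeric vector of relative abundances summing to 1.
#' @export
load_abundances <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("abundance table must have two columns")
  ids <- as.character(tab[[1]])
  ab <- tab[[2]]
  if (!is.numeric(ab)) {
    bad <- which(is.na(suppressWarnings(as.numeric(ab))))[1]
    stop("non-numeric abundance at row ", bad)
  }
  if (anyNA(ab)) stop("missing abundance at row ", which(is.na(ab))[1])
  if (any(ab < 0)) stop("negative abundance at row ", which(ab < 0)[1])
  if (anyDuplicated(ids)) {
    stop("duplicate identifier at row ", which(duplicated(ids))[1])
  }
  zero <- ab == 0
  if (any(zero)) {
    warning(sum(zero), " zero-abundance row(s) dropped")
    ids <- ids[!zero]
    ab <- ab[!zero]
  }
  if (length(ab) == 0) stop("no rows with positive abundance")
  p <- ab / sum(ab)
  names(p) <- ids
  p
}
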