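#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' sum |x_i - y_i| / sum (x_i + y_i): 0 for identical vectors, 1 for
#' disjoint supports.
#'
#' @param x,y non-negative vectors of equal length.
#' @return distance in [0, 1].
#' @export
bray_curtis <- function(x, y) {
  stopifnot(length(x) == length(y), all(x >= 0), all(y >= 0))
  tot <- sum(x + y)
  if (tot == 0) stop("Bray-Curtis undefined for two all-zero vectors")
  sum(abs(x - y)) / tot
}

#' Hellinger distance between two abundance vectors
#'
#' Euclidean distance between the square roots of the total-normalized
#' vectors; bounded by sqrt(2), attained for disjoint supports.
#'
#' @param x,y non-negative vectors of equal length, each with at least one
#'   positive entry.
#' @return Hellinger distance.
#' @export
hellinger_distance <- function(x, y) {
  stopifnot(length(x) == length(y), all(x >= 0), all(y >= 0))
  if (sum(x) == 0 || sum(y) == 0) stop("all-zero vector")
  sqrt(sum((sqrt(x / sum(x)) - sqrt(y / sum(y)))^2))
}

#' Assemble per-genome spectra into a profile matrix
#'
#' Stacks per-assembly species spectra into an assemblies x genomes matrix of
#' one chosen quantity (coverage, fragmentation or penalized coverage),
#' filling genomes absent from an assembly with 0, so rows are comparable.
#'
#' @param spectra_list named list of \code{\link{species_spectra}}
#'   data.frames, one per assembly.
#' @param value column to extract: \code{"coverage"},
#'   \code{"fragmentation"} or \code{"penalized_coverage"}.
#' @return numeric matrix, rows = assemblies, columns = gis.
#' @export
profile_matrix <- function(spectra_list,
                           value = c("coverage", "fragmentation",
                                     "penalized_coverage")) {
  value <- match.arg(value)
  gis <- sort(unique(unlist(lapply(spectra_list, `[[`, "gi"))))
  m <- t(vapply(spectra_list, function(sp) {
    v <- stats::setNames(numeric(length(gis)), gis)
    v[sp$gi] <- sp[[value]]
    v
  }, numeric(length(gis))))
  rownames(m) <- names(spectra_list)
  m
}

.profile_dist <- function(m, distance) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    d[i, j] <- d[j, i] <- switch(distance,
      bray        = bray_curtis(m[i, ], m[j, ]),
      hellinger   = hellinger_distance(m[i, ], m[j, ]),
      correlation = 1 - stats::cor(m[i, ], m[j, ]))
  }
  stats::as.dist(d)
}

#' Hierarchical clustering with bootstrap support
#'
#' Agglomerative clustering of assembly profiles (average linkage by
#' default) with plain bootstrap probabilities: columns of the profile
#' matrix are resampled with replacement \code{n_boot} times, the clustering
#' recomputed, and each internal node's support is the fraction of
#' replicates reproducing its leaf set. For the correlation distance,
#' columns are standardized before 1 - Pearson correlation between rows.
#'
#' @param profiles assemblies x variables numeric matrix (rows named).
#' @param distance \code{"bray"}, \code{"hellinger"} or
#'   \code{"correlation"}.
#' @param linkage agglomeration method passed to \code{hclust} (default
#'   \code{"average"}, i.e. UPGMA).
#' @param n_boot number of bootstrap replicates.
#' @param seed integer seed.
#' @return list of class \code{hcluster_bp}: \code{hclust} (the dendrogram),
#'   \code{bp} (bootstrap probability per internal node, in merge order) and
#'   \code{newick} (Newick string with BP node labels).
#' @export
hcluster <- function(profiles, distance = c("bray", "hellinger",
                                            "correlation"),
                     linkage = "average", n_boot = 100, seed = 1) {
  distance <- match.arg(distance)
  stopifnot(is.matrix(profiles), nrow(profiles) >= 2)
  m <- if (distance == "correlation") scale(profiles) else profiles
  if (distance == "correlation") m[is.nan(m)] <- 0
  hc <- stats::hclust(.profile_dist(m, distance), method = linkage)

  leafsets <- function(h) {
    n <- nrow(h$merge)
    sets <- vector("list", n)
    for (k in seq_len(n)) {
      kids <- h$merge[k, ]
      sets[[k]] <- sort(unlist(lapply(kids, function(x)
        if (x < 0) h$labels[-x] else sets[[x]])))
    }
    vapply(sets, paste, character(1), collapse = "|")
  }
  ref <- leafsets(hc)
  hits <- numeric(length(ref))
  set.seed(as.integer(seed))
  for (b in seq_len(n_boot)) {
    cols <- sample.int(ncol(m), replace = TRUE)
    hb <- stats::hclust(.profile_dist(m[, cols, drop = FALSE], distance),
                        method = linkage)
    hits <- hits + (ref %in% leafsets(hb))
  }
  bp <- hits / n_boot
  phy <- ape::as.phylo(hc)
  ## node labels in ape order: match each internal node's leaf set
  phy_sets <- vapply(seq_len(phy$Nnode) + length(phy$tip.label),
                     function(nd) {
    tips <- ape::extract.clade(phy, nd)$tip.label
    paste(sort(tips), collapse = "|")
  }, character(1))
  phy$node.label <- sprintf("%.2f", bp[match(phy_sets, ref)])
  structure(list(hclust = hc, bp = stats::setNames(bp, ref),
                 newick = ape::write.tree(phy)),
            class = "hcluster_bp")
}

#' Kruskal-Wallis tests with Benjamini-Hochberg correction
#'
#' One rank-based one-way analysis of variance per comparison, with the
#' p-value family adjusted by the Benjamini-Hochberg step-up procedure and
#' reported as q-values.
#'
#' @param comparisons named list; each element is a named list of numeric
#'   vectors (the groups of one comparison, each with >= 2 values).
#' @return data.frame: comparison, statistic, df, p, q.
#' @export
kruskal_wallis_bh <- function(comparisons) {
  stopifnot(length(comparisons) >= 1)
  rows <- lapply(names(comparisons), function(nm) {
    groups <- comparisons[[nm]]
    if (length(groups) < 2 || any(vapply(groups, length, integer(1)) < 2))
      stop("comparison '", nm, "' needs >= 2 groups with >= 2 values each")
    kt <- stats::kruskal.test(groups)
    data.frame(comparison = nm, statistic = unname(kt$statistic),
               df = unname(kt$parameter), p = kt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Pairwise Spearman correlations among assembly statistics
#'
#' Spearman's rank correlation for every pair of statistics across
#' assemblies, with two-sided p-values adjusted (BH) over the family of
#' pairs. Constant columns leave their pairs undefined (NA) and are flagged.
#'
#' @param stats_table assemblies x statistics data.frame or matrix (>= 3
#'   rows).
#' @param q_threshold significance cutoff on the q-value (default 0.05).
#' @return list: \code{rho}, \code{p}, \code{q} (matrices),
#'   \code{significant} (logical matrix, q < threshold),
#'   \code{constant} (names of constant columns).
#' @export
spearman_matrix <- function(stats_table, q_threshold = 0.05) {
  m <- as.matrix(stats_table)
  stopifnot(nrow(m) >= 3)
  k <- ncol(m)
  const <- colnames(m)[apply(m, 2, function(v) stats::sd(v) == 0)]
  rho <- p <- matrix(NA_real_, k, k, dimnames = list(colnames(m), colnames(m)))
  diag(rho) <- 1; diag(p) <- 0
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    if (colnames(m)[i] %in% const || colnames(m)[j] %in% const) next
    ct <- suppressWarnings(
      stats::cor.test(m[, i], m[, j], method = "spearman", exact = FALSE))
    rho[i, j] <- rho[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  q <- p
  ut <- upper.tri(p)
  q[ut] <- stats::p.adjust(p[ut], method = "BH")
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  list(rho = rho, p = p, q = q, significant = q < q_threshold & ut | t(q < q_threshold & ut),
       constant = const)
}

#' Three-method association of assembly statistics with a diversity estimator
#'
#' Links each assembly statistic (predictor) to one diversity estimator
#' (response) with three methods and flags the consensus:
#' \itemize{
#'   \item Spearman correlation, BH-adjusted over predictors; flagged at
#'     q < \code{q_threshold}.
#'   \item L1-regularized (LASSO) Gaussian GLM with the penalty chosen by
#'     cross-validation; flagged when the coefficient at lambda.1se is
#'     nonzero.
#'   \item Random-forest permutation importance (%IncMSE, scaled by its
#'     standard error over trees); flagged when the scaled importance
#'     exceeds \code{rf_z}.
#' }
#' A predictor is a consensus association when at least 2 of the 3 methods
#' flag it. Predictors are standardized; constant columns are dropped with a
#' warning.
#'
#' @param X assemblies x statistics data.frame or matrix (>= 10 rows).
#' @param y numeric response (one diversity estimator per assembly).
#' @param seed integer seed (controls CV folds and forest growth).
#' @param q_threshold Spearman significance cutoff.
#' @param rf_z scaled-importance cutoff for the random-forest flag.
#' @param ntree number of trees.
#' @return data.frame: predictor, rho, p, q, spearman_flag, glm_coef,
#'   glm_flag, rf_importance, rf_flag, consensus.
#' @export
association_analysis <- function(X, y, seed = 1, q_threshold = 0.05,
                                 rf_z = 2, ntree = 1000) {
  m <- as.matrix(X)
  stopifnot(nrow(m) >= 10, nrow(m) == length(y))
  keep <- apply(m, 2, function(v) stats::sd(v) > 0)
  if (!all(keep)) {
    warning("dropping constant predictor(s): ",
            paste(colnames(m)[!keep], collapse = ", "))
    m <- m[, keep, drop = FALSE]
  }
  ms <- scale(m)

  sp <- apply(ms, 2, function(v) {
    ct <- suppressWarnings(
      stats::cor.test(v, y, method = "spearman", exact = FALSE))
    c(rho = unname(ct$estimate), p = ct$p.value)
  })
  q <- stats::p.adjust(sp["p", ], method = "BH")

  set.seed(as.integer(seed))
  foldid <- sample(rep_len(seq_len(min(10, nrow(ms))), nrow(ms)))
  cvfit <- glmnet::cv.glmnet(ms, y, alpha = 1, foldid = foldid)
  beta <- as.numeric(stats::coef(cvfit, s = "lambda.1se"))[-1]

  rf <- randomForest::randomForest(ms, y, importance = TRUE, ntree = ntree)
  imp <- randomForest::importance(rf, type = 1, scale = TRUE)[, 1]

  out <- data.frame(
    predictor = colnames(ms),
    rho = sp["rho", ], p = sp["p", ], q = q,
    spearman_flag = q < q_threshold,
    glm_coef = beta, glm_flag = beta != 0,
    rf_importance = imp, rf_flag = imp > rf_z,
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$consensus <- rowSums(out[, c("spearman_flag", "glm_flag", "rf_flag")]) >= 2
  out
}

#' Distance of each assembly profile to its ideal
#'
#' Bray-Curtis (coverage / penalized-coverage profiles) or Hellinger
#' (fragmentation profiles) distance from every assembly row to the ideal
#' row, optionally followed by a Kruskal-Wallis comparison of the distances
#' across assembler groups.
#'
#' @param profiles profile matrix from \code{\link{profile_matrix}}, with
#'   the ideal assembly as one row.
#' @param ideal_id row name of the ideal assembly.
#' @param metric \code{"bray"} or \code{"hellinger"}.
#' @param groups optional factor (one level per assembler) over the
#'   non-ideal rows; when given and >= 2 values per group, a Kruskal-Wallis
#'   test across groups is reported.
#' @return list: \code{distances} (data.frame assembly, distance),
#'   \code{kruskal} (htest or NULL).
#' @export
distance_to_ideal <- function(profiles, ideal_id,
                              metric = c("bray", "hellinger"),
                              groups = NULL) {
  metric <- match.arg(metric)
  if (!ideal_id %in% rownames(profiles)) stop("missing ideal row: ", ideal_id)
  ideal <- profiles[ideal_id, ]
  others <- setdiff(rownames(profiles), ideal_id)
  d <- vapply(others, function(r) switch(metric,
    bray = bray_curtis(profiles[r, ], ideal),
    hellinger = hellinger_distance(profiles[r, ], ideal)), numeric(1))
  res <- data.frame(assembly = others, distance = unname(d),
                    stringsAsFactors = FALSE)
  kw <- NULL
  if (!is.null(groups)) {
    groups <- factor(groups)
    stopifnot(length(groups) == length(others))
    if (nlevels(groups) >= 2 && all(table(groups) >= 2))
      kw <- stats::kruskal.test(res$distance, groups)
  }
  list(distances = res, kruskal = kw)
}
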