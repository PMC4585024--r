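test_that("bray-curtis and hellinger match hand values and vegan", {
  expect_equal(bray_curtis(c(2, 2), c(2, 2)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 2)), 1)
  expect_equal(bray_curtis(c(2, 2), c(1, 3)), 0.25)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")

  expect_equal(hellinger_distance(c(3, 1), c(3, 1)), 0)
  expect_equal(hellinger_distance(c(1, 0), c(0, 1)), sqrt(2))
  expect_error(hellinger_distance(c(0, 0), c(1, 1)), "all-zero")

  skip_if_not_installed("vegan")
  for (case in 1:20) {
    set.seed(800 + case)
    x <- runif(10); y <- runif(10)
    expect_equal(bray_curtis(x, y),
                 as.numeric(vegan::vegdist(rbind(x, y), "bray")),
                 tolerance = 1e-12)
    hx <- vegan::decostand(rbind(x, y), "hellinger")
    expect_equal(hellinger_distance(x, y),
                 as.numeric(dist(hx)), tolerance = 1e-12)
    # metric axioms: symmetry, non-negativity, identity
    expect_equal(bray_curtis(x, y), bray_curtis(y, x))
    expect_equal(hellinger_distance(x, y), hellinger_distance(y, x))
    expect_gte(bray_curtis(x, y), 0)
    expect_equal(bray_curtis(x, x), 0)
    expect_equal(hellinger_distance(x, x), 0)
  }
})

test_that("profile matrices align genomes across assemblies with 0 fill", {
  sp1 <- data.frame(gi = c("a", "b"), coverage = c(1, 2),
                    fragmentation = c(1, 0.5), penalized_coverage = c(1, 1),
                    n_fragments = 1L, genome_length = 1000L)
  sp2 <- data.frame(gi = c("b", "c"), coverage = c(3, 4),
                    fragmentation = c(0.2, 0.8),
                    penalized_coverage = c(0.6, 3.2),
                    n_fragments = 2L, genome_length = 1000L)
  m <- profile_matrix(list(x = sp1, y = sp2), "coverage")
  expect_equal(dim(m), c(2, 3))
  expect_equal(m["x", ], c(a = 1, b = 2, c = 0))
  expect_equal(m["y", ], c(a = 0, b = 3, c = 4))
  # an all-zero genome column leaves Bray-Curtis unchanged
  expect_equal(bray_curtis(c(m["x", ], z = 0), c(m["y", ], z = 0)),
               bray_curtis(m["x", ], m["y", ]))
})

test_that("hierarchical clustering reproduces forced topologies with high BP", {
  # two leaves: the single node always has BP 1
  m2 <- matrix(runif(20), 2, dimnames = list(c("p", "q"), NULL))
  h2 <- hcluster(m2, "bray", n_boot = 25, seed = 1)
  expect_length(h2$bp, 1)
  expect_equal(unname(h2$bp), 1)

  # well-separated pair joins first with BP ~ 1
  set.seed(42)
  base <- runif(30, 1, 2)
  m <- rbind(a = base + rnorm(30, 0, 0.01),
             b = base + rnorm(30, 0, 0.01),
             c = runif(30, 5, 9))
  h <- hcluster(m, "bray", n_boot = 50, seed = 2)
  expect_equal(unname(h$bp["a|b"]), 1)
  # same matrix and seed give the identical result
  h_again <- hcluster(m, "bray", n_boot = 50, seed = 2)
  expect_identical(h$bp, h_again$bp)
  expect_identical(h$newick, h_again$newick)
  # newick output parses back to the same topology
  phy <- ape::read.tree(text = h$newick)
  expect_setequal(phy$tip.label, c("a", "b", "c"))
})

test_that("kruskal-wallis + BH behave on identical groups and known p sets", {
  set.seed(3)
  same <- list(g1 = rnorm(20), g2 = rnorm(20))
  res <- kruskal_wallis_bh(list(cmp = list(g1 = 1:10, g2 = 1:10)))
  expect_gt(res$p, 0.9)
  # BH step-up by hand on p = (0.01, 0.02, 0.03): all q = 0.03
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
  expect_error(kruskal_wallis_bh(list(x = list(a = 1, b = 2:5))), "x")

  # null calibration: exchangeable groups give roughly uniform p
  ps <- sapply(1:60, function(s) {
    set.seed(900 + s)
    v <- rnorm(30)
    kruskal_wallis_bh(list(k = list(a = v[1:10], b = v[11:20],
                                    c = v[21:30])))$p
  })
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps < 0.05), 0.15)
  expect_true(all(kruskal_wallis_bh(
    list(a = list(x = 1:5, y = 2:6), b = list(x = 1:5, y = 2:6)))$q >=
      kruskal_wallis_bh(
        list(a = list(x = 1:5, y = 2:6), b = list(x = 1:5, y = 2:6)))$p))
})

test_that("spearman matrix recovers exact rank correlations", {
  x <- c(1, 2, 3); y <- c(2, 1, 3)
  m <- cbind(a = c(x, 4:10), b = c(y, 4:10), c = -c(x, 4:10))
  sm <- spearman_matrix(m)
  expect_equal(sm$rho["a", "a"], 1)
  expect_equal(sm$rho["a", "c"], -1)
  # hand value on 3 points: 1 - 6*2/24 = 0.5
  sm3 <- spearman_matrix(cbind(a = x, b = y, d = c(5, 6, 7)))
  expect_equal(sm3$rho["a", "b"], 0.5)
  # constant column flagged, its pairs NA
  smc <- spearman_matrix(cbind(a = 1:5, b = rep(2, 5), c = 5:1))
  expect_equal(smc$constant, "b")
  expect_true(is.na(smc$rho["a", "b"]))
  expect_equal(smc$rho["a", "c"], -1)
})

test_that("association analysis recovers a planted predictor and stays quiet on noise", {
  set.seed(12)
  n <- 40
  X <- matrix(rnorm(n * 5), n, dimnames = list(NULL, paste0("v", 1:5)))
  # noiseless monotone function of one predictor: all three methods flag it
  y <- exp(X[, "v3"])
  res <- association_analysis(X, y, seed = 1)
  row3 <- res[res$predictor == "v3", ]
  expect_true(row3$spearman_flag)
  expect_true(row3$glm_flag)
  expect_true(row3$rf_flag)
  expect_true(row3$consensus)

  # duplicated predictors get identical spearman statistics
  X2 <- cbind(X, v3b = X[, "v3"])
  res2 <- association_analysis(X2, y, seed = 1)
  expect_equal(res2$rho[res2$predictor == "v3"],
               res2$rho[res2$predictor == "v3b"])

  # pure-noise response: consensus flags are rare across seeds
  hits <- sapply(1:10, function(s) {
    set.seed(1000 + s)
    yn <- rnorm(n)
    sum(association_analysis(X, yn, seed = s)$consensus)
  })
  expect_lt(mean(hits), 0.5)
  expect_error(association_analysis(X[1:5, ], y[1:5]), ">= 10")
})

test_that("planted predictor attains the top forest importance across seeds", {
  top <- sapply(1:20, function(s) {
    set.seed(1100 + s)
    X <- matrix(rnorm(35 * 4), 35, dimnames = list(NULL, paste0("v", 1:4)))
    y <- X[, "v2"]^3 + rnorm(35, 0, 0.1)
    res <- association_analysis(X, y, seed = s)
    res$predictor[which.max(res$rf_importance)] == "v2"
  })
  expect_gte(mean(top), 0.9)
})

test_that("distance to ideal is zero for itself and grows with degradation", {
  fx <- make_fixture(n_genomes = 6, n_pairs = 250)
  glen <- fx$genomes$lengths
  mk_prof <- function(srs, seeds) {
    sp <- c(list(ideal = species_spectra(fx$ideal, glen)),
            unlist(lapply(seeds, function(s) {
              setNames(lapply(srs, function(sr)
                species_spectra(degrade_assembly(fx$ideal, sr, 0, 0, s),
                                glen)),
                paste0("s", srs, "_", s))
            }), recursive = FALSE))
    profile_matrix(sp, "fragmentation")
  }
  prof <- mk_prof(c(0.0, 0.2, 0.8), 1:8)
  dh <- distance_to_ideal(prof, "ideal", "hellinger")
  db <- distance_to_ideal(prof, "ideal", "bray")
  expect_true(all(dh$distances$distance >= 0))
  # split 0 reproduces the ideal exactly: distance 0 under both metrics
  expect_true(all(dh$distances$distance[grepl("^s0_",
                                              dh$distances$assembly)] == 0))
  expect_true(all(db$distances$distance[grepl("^s0_",
                                              db$distances$assembly)] == 0))
  # mean distance grows with split rate (Bray-Curtis sees the shrinking
  # fragmentation scores; Hellinger is scale-invariant so it need not)
  m02 <- mean(db$distances$distance[grepl("^s0.2_", db$distances$assembly)])
  m08 <- mean(db$distances$distance[grepl("^s0.8_", db$distances$assembly)])
  expect_lt(m02, m08)
  expect_error(distance_to_ideal(prof, "nope"), "missing ideal")
  # group comparison runs when groups are supplied
  grp <- sub("_.*", "", dh$distances$assembly)
  dk <- distance_to_ideal(prof, "ideal", "hellinger", groups = grp)
  expect_s3_class(dk$kruskal, "htest")
})
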