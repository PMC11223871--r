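# Synthetic two-population panel used across several blocks.
two_pop_space <- function(seed = 101, n_per_pop = 30, n_snps = 400,
                          fst = 0.15, n_pcs = 4) {
  cfg <- sim_config(n_populations = 2, n_ref_per_pop = n_per_pop,
                    n_study = 4, n_snps = n_snps, fst = fst, seed = seed)
  panel <- simulate_panel(cfg)
  list(panel = panel,
       space = fit_reference_pca(panel$ref_genotypes, panel$ref_labels,
                                 n_pcs = n_pcs))
}

test_that("PC1 separates two strongly diverged populations", {
  tp <- two_pop_space()
  pc1 <- tp$space$ref_coords[, 1]
  a <- pc1[tp$panel$ref_labels == "AFR"]
  b <- pc1[tp$panel$ref_labels == "EUR"]
  expect_true(max(a) < min(b) || max(b) < min(a))  # zero range overlap
})

test_that("a rank-2 genotype matrix is captured by two PCs", {
  set.seed(31)
  u <- matrix(rnorm(40), 20, 2)
  v <- matrix(runif(2 * 50), 2, 50)
  G <- u %*% v
  G <- 2 * (G - min(G)) / (max(G) - min(G))  # map into [0, 2]
  colnames(G) <- paste0("s", 1:50)
  sp <- fit_reference_pca(G, rep(c("AFR", "EUR"), each = 10), n_pcs = 2,
                          maf_min = 0)
  p <- colMeans(G) / 2
  Z <- sweep(sweep(G, 2, 2 * p, "-"), 2, sqrt(2 * p * (1 - p)), "/")
  recon <- sp$ref_coords %*% t(sp$loadings)
  expect_lt(sum((Z - recon)^2) / sum(Z^2), 1e-3)  # >= 99.9% of variance
})

test_that("sample permutation only permutes coordinates (up to PC sign)", {
  tp <- two_pop_space(seed = 103, n_per_pop = 15, n_snps = 200)
  set.seed(12)
  perm <- sample(nrow(tp$panel$ref_genotypes))
  sp2 <- fit_reference_pca(tp$panel$ref_genotypes[perm, ],
                           tp$panel$ref_labels[perm], n_pcs = 4)
  for (j in 1:4) {
    a <- tp$space$ref_coords[perm, j]
    b <- sp2$ref_coords[, j]
    expect_true(isTRUE(all.equal(a, b, check.attributes = FALSE, tolerance = 1e-6)) ||
                  isTRUE(all.equal(a, -b, check.attributes = FALSE, tolerance = 1e-6)))
  }
})

test_that("projection is self-consistent and mean-imputes missing data", {
  tp <- two_pop_space(seed = 104, n_per_pop = 20, n_snps = 300)
  # uncorrected projection of the reference's own genotypes is an identity
  co <- project_samples(tp$space, tp$panel$ref_genotypes, correct = FALSE)
  expect_equal(co, tp$space$ref_coords, tolerance = 1e-6)
  # the out-of-sample correction only rescales PCs, by a factor in [1, 10]
  coc <- project_samples(tp$space, tp$panel$ref_genotypes)
  expect_equal(coc, sweep(co, 2, tp$space$shrinkage, "/"), tolerance = 1e-12)
  expect_true(all(tp$space$shrinkage > 0.09 & tp$space$shrinkage <= 1))
  # an all-missing sample lands at the origin
  gm <- matrix(NA_real_, 1, nrow(tp$space$snps),
               dimnames = list("x", tp$space$snps$key))
  expect_equal(unname(project_samples(tp$space, gm)), matrix(0, 1, 4))
  # insufficient overlap is an error reporting the fraction
  few <- tp$panel$ref_genotypes[1:2, 1:50, drop = FALSE]
  expect_error(project_samples(tp$space, few), "%")
})

test_that("study samples from one population project into its reference hull", {
  # The hull is estimated from the reference points themselves, so the
  # panel must be dense enough that its convex hull covers the cluster
  # (a hull over few dozen points misses >10% of its own distribution).
  cfg <- sim_config(n_populations = 3, n_ref_per_pop = 100, n_study = 60,
                    n_snps = 2000, fst = 0.12, seed = 105)
  panel <- simulate_panel(cfg)
  space <- fit_reference_pca(panel$ref_genotypes, panel$ref_labels, n_pcs = 5)
  afr <- panel$study_labels == "AFR"
  co <- project_samples(space, panel$study_dosages[afr, , drop = FALSE])
  ref12 <- space$ref_coords[panel$ref_labels == "AFR", 1:2]
  hull <- ref12[grDevices::chull(ref12), ]
  inside <- mgcv::in.out(rbind(hull, hull[1, ]), co[, 1:2])
  expect_gte(mean(inside), 0.95)
})

test_that("weighted K-NN votes behave at the degenerate extremes", {
  refc <- rbind(matrix(0, 1, 2), matrix(10 + rnorm(38), 19, 2))
  space <- structure(list(ref_coords = refc,
                          ref_labels = c("EUR", rep("AFR", 19)), n_pcs = 2),
                     class = "pca_space")
  # coincident with the lone EUR reference: epsilon weight dominates
  call <- classify_knn(c(0, 0), space, k = 5)
  expect_equal(call$calls$label, "EUR")
  expect_gt(call$votes[1, "EUR"], 0.999)
  # equidistant 10 AFR / 10 EUR: 0.5/0.5 votes, unclassified
  theta <- seq(0, 2 * pi, length.out = 21)[-21]
  ring <- cbind(cos(theta), sin(theta))
  space2 <- structure(list(ref_coords = ring,
                           ref_labels = rep(c("AFR", "EUR"), 10), n_pcs = 2),
                      class = "pca_space")
  call2 <- classify_knn(c(0, 0), space2, k = 20)
  expect_equal(call2$calls$label, "UNCLASSIFIED")
  expect_equal(unname(call2$votes[1, c("AFR", "EUR")]), c(0.5, 0.5))
  expect_equal(sum(call2$votes), 1)
  # parameter validation
  expect_error(classify_knn(c(0, 0), space2, k = 0), "positive")
  expect_error(classify_knn(c(0, 0), space2, k = 21), "exceeds")
  expect_error(classify_knn(c(0, 0), space2, vote_threshold = 1.2), "vote_threshold")
})

test_that("classifier equals the brute-force K-NN oracle on random instances", {
  set.seed(107)
  for (i in 1:100) {
    n_ref <- sample(10:30, 1)
    k <- sample(1:5, 1)
    npc <- sample(2:4, 1)
    refc <- matrix(rnorm(n_ref * npc), n_ref, npc)
    labels <- sample(c("AFR", "EUR", "EAS"), n_ref, replace = TRUE)
    space <- structure(list(ref_coords = refc, ref_labels = labels,
                            n_pcs = npc), class = "pca_space")
    x <- rnorm(npc)
    thr <- runif(1, 0.3, 0.9)
    got <- classify_knn(x, space, k = k, vote_threshold = thr)
    expect_equal(got$calls$label, oracle_knn(x, refc, labels, k, thr))
    expect_equal(sum(got$votes), 1)
  }
})

test_that("raising the vote threshold never converts UNCLASSIFIED to a label", {
  set.seed(108)
  refc <- matrix(rnorm(60), 30, 2)
  labels <- sample(c("AFR", "EUR"), 30, replace = TRUE)
  space <- structure(list(ref_coords = refc, ref_labels = labels, n_pcs = 2),
                     class = "pca_space")
  for (i in 1:20) {
    x <- rnorm(2)
    prev_labeled <- TRUE
    for (thr in c(0.5, 0.65, 0.75, 0.9)) {
      lab <- classify_knn(x, space, k = 5, vote_threshold = thr)$calls$label
      labeled <- lab != "UNCLASSIFIED"
      expect_false(!prev_labeled && labeled)
      prev_labeled <- labeled
    }
  }
})

test_that("population matching excludes mismatches and unclassified samples", {
  expect_equal(match_population("EUR", c("EUR")), "INCLUDED")
  expect_equal(match_population("EAS", c("EUR")), "EXCLUDED_POP_MISMATCH")
  expect_equal(match_population("UNCLASSIFIED",
                                c("EUR", "EAS", "AFR", "GME", "SAS", "AMR", "OTH")),
               "EXCLUDED_UNCLASSIFIED")
  ann <- score_annotation("X", populations = c("EUR", "AFR"), n_variants = 1L)
  expect_equal(match_population(c("EUR", "SAS", "UNCLASSIFIED"), ann),
               c("INCLUDED", "EXCLUDED_POP_MISMATCH", "EXCLUDED_UNCLASSIFIED"))
  # empty population annotation restricts nothing beyond unclassified
  expect_equal(match_population(c("EUR", "UNCLASSIFIED"), character()),
               c("INCLUDED", "EXCLUDED_UNCLASSIFIED"))
})
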