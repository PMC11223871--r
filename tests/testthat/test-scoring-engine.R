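test_that("allele matching follows the frozen orientation table", {
  cases <- list(
    # effect, other, ref, alt, mode, expected
    list("A", "G", "G", "A", "resolve", "DIRECT"),
    list("A", "G", "A", "G", "resolve", "SWAPPED"),
    list("A", "T", "A", "T", "resolve", "EXCLUDED_PALINDROMIC"),
    list("G", "C", "C", "G", "resolve", "EXCLUDED_PALINDROMIC"),
    list("A", "T", "A", "T", "strict", "SWAPPED"),
    list("C", "T", "A", "G", "resolve", "FLIPPED"),
    list("C", "T", "G", "A", "resolve", "FLIPPED_SWAPPED"),
    list("C", "T", "A", "G", "strict", "EXCLUDED_MISMATCH"),
    list("C", "T", "C", "G", "resolve", "EXCLUDED_MISMATCH"),
    # other allele absent: no flips attempted
    list("A", NA, "G", "A", "resolve", "DIRECT"),
    list("A", NA, "A", "G", "resolve", "SWAPPED"),
    list("C", NA, "G", "A", "resolve", "EXCLUDED_MISMATCH"),
    # indels: exact orientation only, never flipped, never palindromic
    list("AT", "A", "A", "AT", "resolve", "DIRECT"),
    list("A", "AT", "A", "AT", "resolve", "SWAPPED"),
    list("TA", "T", "A", "AT", "resolve", "EXCLUDED_MISMATCH")
  )
  for (cs in cases) {
    expect_equal(match_alleles(cs[[1]], cs[[2]], cs[[3]], cs[[4]], cs[[5]]),
                 cs[[6]], info = paste(unlist(cs), collapse = " "))
  }
})

test_that("allele matching symmetries hold over all SNV configurations", {
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  grid <- expand.grid(e = bases, o = bases, ref = bases, alt = bases,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$e != grid$o & grid$ref != grid$alt, ]
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    st <- match_alleles(g$e, g$o, g$ref, g$alt)
    # swapping effect/other mirrors the orientation
    sw <- match_alleles(g$o, g$e, g$ref, g$alt)
    mirror <- c(DIRECT = "SWAPPED", SWAPPED = "DIRECT",
                FLIPPED = "FLIPPED_SWAPPED", FLIPPED_SWAPPED = "FLIPPED",
                EXCLUDED_PALINDROMIC = "EXCLUDED_PALINDROMIC",
                EXCLUDED_MISMATCH = "EXCLUDED_MISMATCH")
    expect_equal(sw, unname(mirror[st]))
    # complementing the score alleles toggles FLIPPED-ness
    fl <- match_alleles(unname(comp[g$e]), unname(comp[g$o]), g$ref, g$alt)
    toggle <- c(DIRECT = "FLIPPED", FLIPPED = "DIRECT",
                SWAPPED = "FLIPPED_SWAPPED", FLIPPED_SWAPPED = "SWAPPED",
                EXCLUDED_PALINDROMIC = "EXCLUDED_PALINDROMIC",
                EXCLUDED_MISMATCH = "EXCLUDED_MISMATCH")
    expect_equal(fl, unname(toggle[st]))
    # palindromic score pairs are always excluded in resolve mode
    if (comp[g$o] == g$e) expect_equal(st, "EXCLUDED_PALINDROMIC")
  }
})

test_that("effect dosage inverts for swapped orientations", {
  expect_equal(effect_dosage("DIRECT", 1.3), 1.3)
  expect_equal(effect_dosage("FLIPPED", 0.4), 0.4)
  expect_equal(effect_dosage("SWAPPED", 0.0), 2.0)
  expect_equal(effect_dosage("SWAPPED", 0.73), 1.27)
  expect_equal(effect_dosage("FLIPPED_SWAPPED", 2.0), 0.0)
  expect_error(effect_dosage("EXCLUDED_PALINDROMIC", 1), "excluded")
})

test_that("chunk scoring applies weights, quality filter and audit reasons", {
  rows <- data.frame(chrom = "1", pos = 100L, other_allele = "G",
                     effect_allele = "A", S1 = 1.0, stringsAsFactors = FALSE)
  d <- make_dset("1", 100, "G", "A", 0.9, matrix(2.0, 1, 1))
  p <- score_chunk(d, rows)
  expect_equal(unname(p$sums[1, 1]), 2.0)
  expect_equal(unname(p$used), 1L)
  expect_equal(p$audits$reason, "USED_DIRECT")

  d_low <- make_dset("1", 100, "G", "A", 0.2, matrix(2.0, 1, 1))
  p_low <- score_chunk(d_low, rows, min_r2 = 0.3)
  expect_equal(unname(p_low$sums[1, 1]), 0)
  expect_equal(unname(p_low$used), 0L)
  expect_equal(p_low$audits$reason, "EXCLUDED_LOW_R2")

  # absent quality passes the filter
  d_nq <- make_dset("1", 100, "G", "A", NA_real_, matrix(1.0, 1, 1))
  expect_equal(score_chunk(d_nq, rows)$audits$reason, "USED_DIRECT")

  # repository row with no VCF record
  d_off <- make_dset("1", 999, "G", "A", 0.9, matrix(1.0, 1, 1))
  expect_equal(score_chunk(d_off, rows)$audits$reason, "NOT_FOUND")
})

test_that("engine equals the naive triple-loop oracle on a dense chunk", {
  cfg <- sim_config(n_populations = 3, n_ref_per_pop = 5, n_study = 20,
                    n_snps = 200, n_scores = 5, variants_per_score = 60,
                    low_r2_rate = 0.1, missing_rate = 0.005, n_chroms = 1,
                    seed = 77)
  panel <- simulate_panel(cfg)
  sims <- simulate_scores(panel, frac_flipped = 0.3)
  repo <- merge_scores(sims$scores)
  d <- make_dset(panel$sites$chrom, panel$sites$pos, panel$sites$ref,
                 panel$sites$alt, panel$sites$quality,
                 t(panel$study_dosages), samples = panel$study_samples)
  p <- score_chunk(d, repo$rows)
  orc <- oracle_scores(sims$scores, d$sites, d$dosages)
  expect_lt(max(abs(t(p$sums) - orc$scores)) / max(abs(orc$scores)), 1e-9)
  expect_equal(unname(p$used), orc$used)
})

test_that("one missing dosage excludes the variant for every sample", {
  set.seed(5)
  d_full <- make_dset(c("1", "1"), c(10, 20), c("G", "C"), c("A", "T"),
                      c(0.9, 0.9), matrix(runif(6, 0, 2), 2, 3))
  rows <- data.frame(chrom = c("1", "1"), pos = c(10L, 20L),
                     other_allele = c("G", "C"), effect_allele = c("A", "T"),
                     S1 = c(0.5, -2), stringsAsFactors = FALSE)
  d_miss <- d_full
  d_miss$dosages[2, 1] <- NA
  p_miss <- score_chunk(d_miss, rows)
  # equivalent to deleting the variant from the score
  p_del <- score_chunk(d_full, rows[1, , drop = FALSE])
  expect_equal(p_miss$sums, p_del$sums)
  expect_true("EXCLUDED_MISSING_DOSAGE" %in% p_miss$audits$reason)
  # opt-out: per-sample missing handling keeps the other samples
  p_ps <- score_chunk(d_miss, rows, missing_global = FALSE)
  expect_equal(unname(p_ps$sums[1, 2:3]),
               unname(p_miss$sums[1, 2:3] - 2 * d_full$dosages[2, 2:3]))
})

test_that("coverage classes use strict boundaries", {
  expect_equal(classify_coverage(c(0.80, 0.75, 0.7501, 0.25, 0.2499, 0.10, 0, 1)),
               c("HIGH", "MEDIUM", "HIGH", "MEDIUM", "LOW", "LOW", "LOW", "HIGH"))
  expect_error(classify_coverage(1.2), "\\[0, 1\\]")
})

test_that("aggregation sums chunks in genomic order and checks overlap", {
  ids <- "S1"
  mk <- function(val, used, chrom, start, end) {
    structure(list(chunk = list(chrom = chrom, start = start, end = end),
                   sums = matrix(val, 1, 2, dimnames = list(ids, c("a", "b"))),
                   used = setNames(used, ids),
                   audits = data.frame()), class = "pgs_partial")
  }
  ann <- list(S1 = score_annotation("S1", n_variants = 4L))
  agg <- aggregate_partials(list(mk(0.4, 1L, "1", 1, 10), mk(-0.1, 2L, "1", 11, 20)), ann)
  expect_equal(unname(agg$scores[, "S1"]), c(0.3, 0.3))
  expect_equal(agg$summary$n_used, 3L)
  expect_equal(agg$summary$coverage, 0.75)
  expect_equal(agg$summary$coverage_class, "MEDIUM")

  one <- aggregate_partials(list(mk(1.5, 4L, "1", 1, 10)), ann)
  expect_equal(unname(one$scores[1, 1]), 1.5)
  expect_equal(one$summary$coverage_class, "HIGH")

  expect_error(aggregate_partials(list(mk(1, 1L, "1", 1, 10), mk(1, 1L, "1", 5, 15)), ann),
               "overlapping")
})

test_that("coverage is non-increasing in the quality threshold", {
  cfg <- sim_config(n_populations = 2, n_ref_per_pop = 5, n_study = 10,
                    n_snps = 150, n_scores = 3, variants_per_score = 50,
                    low_r2_rate = 0.3, n_chroms = 1, seed = 88)
  panel <- simulate_panel(cfg)
  sims <- simulate_scores(panel)
  repo <- merge_scores(sims$scores)
  d <- make_dset(panel$sites$chrom, panel$sites$pos, panel$sites$ref,
                 panel$sites$alt, panel$sites$quality,
                 t(panel$study_dosages), samples = panel$study_samples)
  prev <- rep(Inf, 3)
  for (thr in c(0, 0.3, 0.6, 0.9, 1)) {
    used <- unname(score_chunk(d, repo$rows, min_r2 = thr)$used)
    expect_true(all(used <= prev))
    prev <- used
  }
})
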