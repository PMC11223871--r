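# Synthetic data with known ground truth: Balding-Nichols structured
# reference panels, imputed-dosage study VCFs and scoring files, plus a
# naive oracle score matrix honouring every exclusion rule. Everything is
# driven by one integer seed for byte-identical reproducibility.

#' Simulation configuration
#'
#' Defaults describe a desk-scale HGDP-like panel: 7 labelled populations at
#' moderate divergence (Fst 0.08, the level at which continental groups
#' separate cleanly on the first PCs), 50 reference samples per population
#' and 2000 SNPs spread over 3 chromosomes. Study dosages are genotypes
#' perturbed by truncated Gaussian noise (sd 0.05) to mimic imputation
#' uncertainty, with per-variant imputation quality mostly high and a small
#' fraction (`low_r2_rate`) below the default 0.3 filter.
#'
#' @param n_populations Number of populations (labels are taken from the 7
#'   super-population codes).
#' @param n_ref_per_pop Reference samples per population.
#' @param n_study Study samples (assigned to populations round-robin).
#' @param n_snps Number of SNPs.
#' @param fst Balding-Nichols divergence parameter in `[0, 1)`.
#' @param n_scores,variants_per_score Score-set shape for
#'   [simulate_scores()].
#' @param missing_rate Probability that a study dosage cell is missing.
#' @param low_r2_rate Fraction of variants drawn with imputation quality
#'   below 0.3.
#' @param dosage_noise_sd Standard deviation of the imputation noise added
#'   to study genotypes (default 0.05).
#' @param n_chroms,chrom_span_bp Genome shape: chromosomes `"1"..` with
#'   positions uniform in `[1, chrom_span_bp]`.
#' @param seed Integer seed controlling all draws.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_populations = 7, n_ref_per_pop = 50, n_study = 100,
                       n_snps = 2000, fst = 0.08, n_scores = 5,
                       variants_per_score = 100, missing_rate = 0,
                       low_r2_rate = 0.05, dosage_noise_sd = 0.05,
                       n_chroms = 3, chrom_span_bp = 30e6, seed = 1) {
  cfg <- list(n_populations = n_populations, n_ref_per_pop = n_ref_per_pop,
              n_study = n_study, n_snps = n_snps, fst = fst,
              n_scores = n_scores, variants_per_score = variants_per_score,
              missing_rate = missing_rate, low_r2_rate = low_r2_rate,
              dosage_noise_sd = dosage_noise_sd, n_chroms = n_chroms,
              chrom_span_bp = chrom_span_bp, seed = as.integer(seed))
  counts <- c("n_populations", "n_ref_per_pop", "n_study", "n_snps",
              "n_scores", "variants_per_score", "n_chroms")
  if (any(unlist(cfg[counts]) < 1)) stop_usage("all counts must be positive")
  rates <- c("missing_rate", "low_r2_rate")
  if (any(unlist(cfg[rates]) < 0 | unlist(cfg[rates]) > 1)) {
    stop_usage("rates must lie in [0, 1]")
  }
  if (fst < 0 || fst >= 1) stop_usage("fst must lie in [0, 1)")
  if (n_populations > length(SUPER_POPULATIONS)) {
    stop_usage("at most ", length(SUPER_POPULATIONS), " populations supported")
  }
  structure(cfg, class = "sim_config")
}

# Balding-Nichols population allele frequencies around ancestral p.
bn_pop_freq <- function(p, fst) {
  if (fst < 1e-8) return(p)
  a <- p * (1 - fst) / fst
  b <- (1 - p) * (1 - fst) / fst
  f <- rbeta(length(p), a, b)
  bad <- !is.finite(f)
  while (any(bad)) {
    f[bad] <- rbeta(sum(bad), a[bad], b[bad])
    bad <- !is.finite(f)
  }
  f
}

#' Simulate a structured panel with imputed study dosages
#'
#' Draws ancestral allele frequencies `p ~ Uniform(0.05, 0.95)`,
#' per-population frequencies from the Balding-Nichols
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` model, reference genotypes
#' `Binomial(2, p_pop)`, and study dosages as genotype plus truncated
#' Gaussian noise in `[0, 2]`. Dosages and qualities are rounded to the
#' precision written in the VCF so that the in-memory truth equals the
#' parsed file exactly.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `"sim_panel"`: `sites` (chrom/pos/ref/alt/
#'   quality), `ref_genotypes` and `ref_labels`, `study_dosages`,
#'   `study_labels`, `study_genotypes`, sample ids and `cfg`.
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  m <- cfg$n_snps
  pops <- SUPER_POPULATIONS[seq_len(cfg$n_populations)]

  chrom <- sort(sample(as.character(seq_len(cfg$n_chroms)), m, replace = TRUE))
  pos <- unlist(lapply(unique(chrom), function(ch) {
    sort(sample.int(cfg$chrom_span_bp, sum(chrom == ch)))
  }))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))

  p_anc <- runif(m, 0.05, 0.95)
  p_pop <- vapply(pops, function(pop) bn_pop_freq(p_anc, cfg$fst), numeric(m))
  if (m == 1L) p_pop <- matrix(p_pop, nrow = 1, dimnames = list(NULL, pops))

  ref_labels <- rep(pops, each = cfg$n_ref_per_pop)
  n_ref <- length(ref_labels)
  ref_geno <- matrix(0L, n_ref, m)
  for (i in seq_len(n_ref)) {
    ref_geno[i, ] <- rbinom(m, 2, p_pop[, ref_labels[i]])
  }

  study_labels <- pops[((seq_len(cfg$n_study) - 1) %% length(pops)) + 1]
  study_geno <- matrix(0L, cfg$n_study, m)
  for (i in seq_len(cfg$n_study)) {
    study_geno[i, ] <- rbinom(m, 2, p_pop[, study_labels[i]])
  }
  noise <- matrix(rnorm(cfg$n_study * m, 0, cfg$dosage_noise_sd), cfg$n_study, m)
  dos <- pmin(pmax(study_geno + noise, 0), 2)
  dos <- round(dos, 3)  # VCF write precision: truth == file
  if (cfg$missing_rate > 0) {
    dos[matrix(runif(length(dos)) < cfg$missing_rate, nrow(dos))] <- NA_real_
  }

  n_low <- round(cfg$low_r2_rate * m)
  quality <- round(runif(m, 0.7, 1), 4)
  if (n_low > 0) {
    low_idx <- sample.int(m, n_low)
    quality[low_idx] <- round(runif(n_low, 0.01, 0.29), 4)
  }

  key <- variant_key(chrom, pos, ref, alt)
  ref_samples <- sprintf("REF%04d", seq_len(n_ref))
  study_samples <- sprintf("STU%04d", seq_len(cfg$n_study))
  dimnames(ref_geno) <- list(ref_samples, key)
  dimnames(study_geno) <- list(study_samples, key)
  dimnames(dos) <- list(study_samples, key)

  structure(list(
    sites = data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                       quality = quality, stringsAsFactors = FALSE),
    ref_genotypes = ref_geno, ref_labels = ref_labels,
    ref_samples = ref_samples,
    study_genotypes = study_geno, study_dosages = dos,
    study_labels = study_labels, study_samples = study_samples,
    p_pop = p_pop, cfg = cfg
  ), class = "sim_panel")
}

#' @export
print.sim_panel <- function(x, ...) {
  cat(sprintf("<sim_panel> %d SNPs; %d reference samples (%d populations); %d study samples\n",
              nrow(x$sites), nrow(x$ref_genotypes),
              length(unique(x$ref_labels)), nrow(x$study_dosages)))
  invisible(x)
}

#' Simulate scoring files with a known oracle score matrix
#'
#' Draws each score's variants from the panel (optionally restricted to
#' palindromic or non-palindromic sites), with weights `Normal(0, 1)` and
#' the effect allele chosen as REF or ALT at random so that dosage
#' inversion is exercised. Optionally a fraction of entries point at
#' positions absent from the VCF (`frac_absent`) or carry strand-flipped
#' alleles (`frac_flipped`, complemented non-palindromic SNVs). The oracle
#' matrix is computed by direct naive summation honouring every exclusion
#' rule (palindromic, low quality, missing dosage, absent variant).
#'
#' @param panel A [simulate_panel()] result.
#' @param n_scores,variants_per_score Overrides of the panel's config.
#' @param frac_absent Fraction of score variants absent from the VCF.
#' @param frac_flipped Fraction written with complemented alleles.
#' @param palindromic One of `"mixed"` (sites as drawn), `"only"`
#'   (palindromic sites only) or `"none"`.
#' @param min_r2 Quality threshold the oracle assumes (default 0.3).
#' @param seed Seed for the score draws (defaults to `cfg$seed + 1`).
#' @return A list of class `"sim_scores"`: `scores` (list of `"pgs_score"`
#'   objects), `oracle` (samples x scores matrix), `expected_used` (per
#'   score), `expected_total`.
#' @export
simulate_scores <- function(panel, n_scores = NULL, variants_per_score = NULL,
                            frac_absent = 0, frac_flipped = 0,
                            palindromic = c("mixed", "only", "none"),
                            min_r2 = 0.3, seed = NULL) {
  stopifnot(inherits(panel, "sim_panel"))
  palindromic <- match.arg(palindromic)
  cfg <- panel$cfg
  n_scores <- n_scores %||% cfg$n_scores
  vps <- variants_per_score %||% cfg$variants_per_score
  set.seed(seed %||% (cfg$seed + 1L))

  sites <- panel$sites
  pal <- is_palindromic_pair(sites$alt, sites$ref)
  pool <- switch(palindromic,
                 mixed = seq_len(nrow(sites)),
                 only = which(pal),
                 none = which(!pal))
  n_absent <- round(frac_absent * vps)
  n_present <- vps - n_absent
  if (n_present > length(pool)) {
    stop_usage("requesting more variants per score than available in the panel")
  }

  scores <- vector("list", n_scores)
  oracle <- matrix(0, nrow(panel$study_dosages), n_scores,
                   dimnames = list(panel$study_samples,
                                   sprintf("SIM%06d", seq_len(n_scores))))
  used <- integer(n_scores)
  for (s in seq_len(n_scores)) {
    id <- sprintf("SIM%06d", s)
    take <- sample(pool, n_present)
    v <- sites[take, c("chrom", "pos", "ref", "alt"), drop = FALSE]
    eff_is_alt <- runif(n_present) < 0.5
    effect <- ifelse(eff_is_alt, v$alt, v$ref)
    other <- ifelse(eff_is_alt, v$ref, v$alt)
    beta <- rnorm(n_present)

    # oracle: per-variant contribution unless excluded
    for (j in seq_len(n_present)) {
      i <- take[j]
      if (pal[i]) next                                   # EXCLUDED_PALINDROMIC
      q <- sites$quality[i]
      if (!is.na(q) && q < min_r2) next                  # EXCLUDED_LOW_R2
      d_alt <- panel$study_dosages[, i]
      if (anyNA(d_alt)) next                             # EXCLUDED_MISSING_DOSAGE
      d_eff <- if (eff_is_alt[j]) d_alt else 2 - d_alt
      oracle[, s] <- oracle[, s] + beta[j] * d_eff
      used[s] <- used[s] + 1L
    }

    # written alleles: optionally strand-flipped (non-palindromic SNVs only)
    w_eff <- effect; w_oth <- other
    if (frac_flipped > 0) {
      flippable <- which(!pal[take])
      n_flip <- round(frac_flipped * length(flippable))
      if (n_flip > 0) {
        fl <- sample(flippable, n_flip)
        w_eff[fl] <- complement_allele(effect[fl])
        w_oth[fl] <- complement_allele(other[fl])
      }
    }

    variants <- data.frame(chrom = v$chrom, pos = v$pos,
                           effect_allele = w_eff, other_allele = w_oth,
                           weight = beta, stringsAsFactors = FALSE)
    if (n_absent > 0) {
      # positions guaranteed off-panel: beyond the simulated span
      ab_pos <- as.integer(cfg$chrom_span_bp) + sample.int(1e6, n_absent)
      variants <- rbind(variants, data.frame(
        chrom = sample(as.character(seq_len(cfg$n_chroms)), n_absent, replace = TRUE),
        pos = ab_pos, effect_allele = "A", other_allele = "G",
        weight = rnorm(n_absent), stringsAsFactors = FALSE))
    }
    ord <- variant_order(variants$chrom, variants$pos,
                         variants$other_allele, variants$effect_allele)
    variants <- variants[ord, , drop = FALSE]
    rownames(variants) <- NULL

    scores[[s]] <- structure(list(
      annotation = score_annotation(id, trait = sprintf("simulated trait %d", s),
                                    populations = character(),
                                    n_variants = nrow(variants)),
      variants = variants, n_dropped = 0L, n_duplicates = 0L
    ), class = "pgs_score")
  }

  structure(list(scores = scores, oracle = oracle,
                 expected_used = used, expected_total = rep(vps, n_scores)),
            class = "sim_scores")
}

#' Write a panel's study dosages (and optionally the reference) as VCF
#'
#' Writes a VCF 4.2 file with `GT:DS` sample fields and `R2` INFO values,
#' bgzip-compresses and tabix-indexes it. With the same panel the output is
#' byte-identical across calls.
#'
#' @param panel A [simulate_panel()] result.
#' @param path Output path ending in `.vcf.gz` (intermediate text removed).
#' @param what `"study"` (dosages; default) or `"reference"` (hard
#'   genotypes, no DS).
#' @return Invisibly, the bgzipped path.
#' @export
write_panel_vcf <- function(panel, path, what = c("study", "reference")) {
  what <- match.arg(what)
  stopifnot(grepl("\\.vcf\\.gz$", path))
  sites <- panel$sites
  if (what == "study") {
    samples <- panel$study_samples
    dos <- panel$study_dosages
    geno <- panel$study_genotypes
  } else {
    samples <- panel$ref_samples
    dos <- NULL
    geno <- panel$ref_genotypes
  }
  gt_t <- t(matrix(c("0/0", "0/1", "1/1")[geno + 1L], nrow(geno), ncol(geno)))
  if (!is.null(dos)) {
    ds_t <- t(dos)  # site-major
    cells <- matrix(paste0(gt_t, ":", sprintf("%.3f", ds_t)),
                    nrow(ds_t), ncol(ds_t))
    cells[is.na(ds_t)] <- "./.:."
  } else {
    cells <- gt_t
  }

  contigs <- sort(unique(sites$chrom))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=pgsdesk-simulate",
    sprintf("##contig=<ID=%s,length=%d>", contigs,
            as.integer(panel$cfg$chrom_span_bp + 2e6)),
    '##INFO=<ID=R2,Number=1,Type=Float,Description="Estimated imputation accuracy">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Estimated alternate allele dosage">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  fmt <- if (!is.null(dos)) "GT:DS" else "GT"
  body <- paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt, ".", "PASS",
                sprintf("R2=%.4f", sites$quality), fmt,
                apply(cells, 1, paste, collapse = "\t"), sep = "\t")

  txt <- sub("\\.gz$", "", path)
  writeLines(c(header, body), txt)
  Rsamtools::bgzip(txt, dest = path, overwrite = TRUE)
  unlink(txt)
  Rsamtools::indexTabix(path, format = "vcf")
  invisible(path)
}

#' Write simulated scores as PGS Catalog style files
#'
#' @param sim A [simulate_scores()] result.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths.
#' @export
write_score_files <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vapply(sim$scores, function(sc) {
    p <- file.path(dir, paste0(sc$annotation$score_id, ".txt"))
    v <- sc$variants
    other <- v$other_allele
    other[is.na(other)] <- ""
    writeLines(c(
      "###PGS CATALOG SCORING FILE - simulated",
      paste0("#pgs_id=", sc$annotation$score_id),
      paste0("#trait_reported=", sc$annotation$trait),
      paste0("#variants_number=", nrow(v)),
      paste(c("chr_name", "chr_position", "effect_allele", "other_allele",
              "effect_weight"), collapse = "\t"),
      paste(v$chrom, v$pos, v$effect_allele, other,
            sprintf("%.17g", v$weight), sep = "\t")
    ), p)
    p
  }, character(1))
}

#' Write the reference sample labels as a two-column TSV
#'
#' @param panel A [simulate_panel()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_labels_tsv <- function(panel, path) {
  write.table(data.frame(sample = panel$ref_samples, population = panel$ref_labels),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
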