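# Small programmatic fixtures shared across test files.

# Build a dosage_set directly (engine-level tests that need no VCF file).
make_dset <- function(chrom, pos, ref, alt, quality, dosages,
                      samples = NULL, typed = FALSE) {
  if (is.null(dim(dosages))) dosages <- matrix(dosages, nrow = length(chrom))
  samples <- samples %||% paste0("S", seq_len(ncol(dosages)))
  colnames(dosages) <- samples
  structure(list(
    sites = data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                       ref = ref, alt = alt, quality = quality,
                       typed = rep_len(typed, length(chrom)),
                       stringsAsFactors = FALSE),
    dosages = dosages, samples = samples), class = "dosage_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write a minimal VCF (optionally bgzipped + indexed) from record strings.
write_test_vcf <- function(records, samples = c("S1", "S2"),
                           path = tempfile(fileext = ".vcf"),
                           bgzip = FALSE) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1,length=100000000>",
    "##contig=<ID=2,length=100000000>",
    '##INFO=<ID=R2,Number=1,Type=Float,Description="r2">',
    '##INFO=<ID=ER2,Number=1,Type=Float,Description="er2">',
    '##INFO=<ID=TYPED,Number=0,Type=Flag,Description="typed">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="gt">',
    '##FORMAT=<ID=DS,Number=1,Type=Float,Description="ds">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
  if (bgzip) {
    gz <- Rsamtools::bgzip(path, paste0(path, ".gz"), overwrite = TRUE)
    Rsamtools::indexTabix(gz, format = "vcf")
    return(gz)
  }
  path
}

vcf_rec <- function(chrom, pos, ref, alt, info, fmt, ...) {
  paste(c(chrom, pos, ".", ref, alt, ".", "PASS", info, fmt, ...),
        collapse = "\t")
}

# Write a PGS Catalog style scoring file from a variant data frame.
write_test_score <- function(variants, pgs_id = "PGS_TEST",
                             meta = character(),
                             path = tempfile(fileext = ".txt")) {
  other <- variants$other_allele
  other[is.na(other)] <- ""
  writeLines(c(
    "###PGS CATALOG SCORING FILE",
    paste0("#pgs_id=", pgs_id),
    meta,
    paste(c("chr_name", "chr_position", "effect_allele", "other_allele",
            "effect_weight"), collapse = "\t"),
    paste(variants$chrom, variants$pos, variants$effect_allele, other,
          variants$weight, sep = "\t")), path)
  path
}

# Random score definitions over a shared variant pool (for merge tests).
random_scores <- function(n_scores, pool, per_score, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_scores), function(s) {
    take <- sample(nrow(pool), per_score)
    v <- pool[take, , drop = FALSE]
    v$weight <- rnorm(per_score)
    v <- v[order(v$chrom, v$pos), , drop = FALSE]
    rownames(v) <- NULL
    structure(list(
      annotation = score_annotation(sprintf("RS%03d", s), n_variants = nrow(v)),
      variants = v, n_dropped = 0L, n_duplicates = 0L), class = "pgs_score")
  })
}

random_pool <- function(n, seed = 1, chroms = c("1", "2", "3")) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             pos = sample.int(5e7, n), effect_allele = alt,
             other_allele = ref, stringsAsFactors = FALSE)
}
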