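# The scoring core: match score variants to VCF dosage records, resolve
# strand flips, apply the palindromic / imputation-quality / missing-dosage
# filters, and accumulate PGS_j = sum_i beta_i * D_ij per sample.

USED_STATUSES <- c("DIRECT", "SWAPPED", "FLIPPED", "FLIPPED_SWAPPED")

#' Match a score variant's alleles against a VCF record
#'
#' Determines how (or whether) a score variant applies to a biallelic VCF
#' record at the same position. `DIRECT` means the effect allele is the ALT
#' allele; `SWAPPED` means it is the REF allele, so the effect dosage is
#' `2 - D`. In `"resolve"` mode, single-base pairs that fail to match are
#' retried after complementing the score alleles (`FLIPPED` /
#' `FLIPPED_SWAPPED`), and palindromic pairs (A/T, G/C) are excluded
#' outright because their strand cannot be determined. With no other allele
#' recorded, only un-flipped matching against ALT or REF is attempted.
#' Indels (any allele longer than one base) match exactly or not at all.
#'
#' @param effect_allele,other_allele Score alleles; `other_allele` may be
#'   `NA`.
#' @param ref,alt VCF record alleles.
#' @param strand_mode `"resolve"` (flip resolution + palindromic exclusion,
#'   the default) or `"strict"` (exact orientation only, palindromic pairs
#'   retained).
#' @return One of `"DIRECT"`, `"SWAPPED"`, `"FLIPPED"`, `"FLIPPED_SWAPPED"`,
#'   `"EXCLUDED_PALINDROMIC"`, `"EXCLUDED_MISMATCH"`.
#' @export
match_alleles <- function(effect_allele, other_allele, ref, alt,
                          strand_mode = c("resolve", "strict")) {
  strand_mode <- match.arg(strand_mode)
  e <- effect_allele; o <- other_allele
  if (is.na(o)) {
    if (e == alt) return("DIRECT")
    if (e == ref) return("SWAPPED")
    return("EXCLUDED_MISMATCH")
  }
  snv <- all(nchar(c(e, o, ref, alt)) == 1L)
  if (!snv) {
    if (e == alt && o == ref) return("DIRECT")
    if (e == ref && o == alt) return("SWAPPED")
    return("EXCLUDED_MISMATCH")
  }
  if (strand_mode == "resolve" && is_palindromic_pair(e, o)) {
    return("EXCLUDED_PALINDROMIC")
  }
  if (e == alt && o == ref) return("DIRECT")
  if (e == ref && o == alt) return("SWAPPED")
  if (strand_mode == "resolve") {
    ce <- complement_allele(e); co <- complement_allele(o)
    if (ce == alt && co == ref) return("FLIPPED")
    if (ce == ref && co == alt) return("FLIPPED_SWAPPED")
  }
  "EXCLUDED_MISMATCH"
}

#' Effect-allele dosage from the ALT dosage
#'
#' The published weight applies to the effect allele. When the matched
#' orientation has the effect allele on the REF side (`SWAPPED`,
#' `FLIPPED_SWAPPED`), the effect dosage is `2 - D_alt`; otherwise it is the
#' ALT dosage unchanged.
#'
#' @param match A match status from [match_alleles()]; must be a used
#'   status.
#' @param alt_dosage ALT-allele dosage in `[0, 2]`.
#' @return Effect-allele dosage in `[0, 2]`.
#' @export
effect_dosage <- function(match, alt_dosage) {
  if (!match %in% USED_STATUSES) {
    stop("effect_dosage() called with excluded match status: ", match)
  }
  if (match %in% c("SWAPPED", "FLIPPED_SWAPPED")) 2 - alt_dosage else alt_dosage
}

new_partial <- function(chunk, ids, samples) {
  structure(list(
    chunk = chunk,
    sums = matrix(0, length(ids), length(samples), dimnames = list(ids, samples)),
    used = setNames(integer(length(ids)), ids),
    audits = data.frame(chrom = character(), pos = integer(),
                        other_allele = character(), effect_allele = character(),
                        score_id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  ), class = "pgs_partial")
}

#' Score one genomic chunk
#'
#' For each repository row in the chunk, finds the matching VCF record at
#' the same position, applies [match_alleles()], the imputation-quality
#' filter and the missing-dosage rule, and accumulates `beta * D_effect`
#' into every score holding a weight at that row. A variant with any missing
#' sample dosage is excluded for all samples, so that samples with missing
#' genotypes do not get systematically lower scores. Accumulation runs in
#' sorted `(chrom, pos, other, effect)` order for floating-point
#' reproducibility.
#'
#' @param dosages A `"dosage_set"` restricted to the chunk's interval.
#' @param repo_rows Repository rows (from [query_interval()]) for the same
#'   interval.
#' @param min_r2 Imputation-quality threshold (default 0.3); applies only to
#'   records that carry a quality value.
#' @param strand_mode Passed to [match_alleles()].
#' @param missing_global If `TRUE` (default), one missing sample dosage
#'   excludes the variant for all samples; if `FALSE`, only the missing
#'   samples skip it.
#' @param chunk Optional chunk descriptor (list with `chrom`, `start`,
#'   `end`, `ordinal`) recorded in the result.
#' @return A `"pgs_partial"`: `sums` (scores x samples matrix of partial
#'   sums), `used` (per-score used-variant counts) and `audits` (one row per
#'   (variant, score) with a reason code).
#' @export
score_chunk <- function(dosages, repo_rows, min_r2 = 0.3,
                        strand_mode = c("resolve", "strict"),
                        missing_global = TRUE, chunk = NULL) {
  strand_mode <- match.arg(strand_mode)
  stopifnot(inherits(dosages, "dosage_set"))
  ids <- setdiff(names(repo_rows),
                 c("chrom", "pos", "other_allele", "effect_allele"))
  samples <- dosages$samples
  part <- new_partial(chunk, ids, samples)
  if (!nrow(repo_rows)) return(part)

  ord <- variant_order(repo_rows$chrom, repo_rows$pos,
                       repo_rows$other_allele, repo_rows$effect_allele)
  repo_rows <- repo_rows[ord, , drop = FALSE]

  site_key <- paste(dosages$sites$chrom, dosages$sites$pos)
  site_index <- split(seq_along(site_key), site_key)
  wmat <- as.matrix(repo_rows[, ids, drop = FALSE])

  audits <- vector("list", nrow(repo_rows))
  multi_match_warned <- FALSE
  for (r in seq_len(nrow(repo_rows))) {
    scores_here <- which(!is.na(wmat[r, ]))
    cand <- site_index[[paste(repo_rows$chrom[r], repo_rows$pos[r])]]
    reason <- "NOT_FOUND"
    rec <- NA_integer_
    status <- NULL
    if (!is.null(cand)) {
      statuses <- vapply(cand, function(i) {
        match_alleles(repo_rows$effect_allele[r], repo_rows$other_allele[r],
                      dosages$sites$ref[i], dosages$sites$alt[i], strand_mode)
      }, character(1))
      used_i <- which(statuses %in% USED_STATUSES)
      if (length(used_i)) {
        if (length(used_i) > 1L && !multi_match_warned) {
          warning("multiple VCF records match the same score variant; using the first in file order")
          multi_match_warned <- TRUE
        }
        rec <- cand[used_i[1]]
        status <- statuses[used_i[1]]
      } else if (any(statuses == "EXCLUDED_PALINDROMIC")) {
        reason <- "EXCLUDED_PALINDROMIC"
      } else {
        reason <- "EXCLUDED_MISMATCH"
      }
    }

    if (!is.na(rec)) {
      q <- dosages$sites$quality[rec]
      d <- dosages$dosages[rec, ]
      if (!is.na(q) && q < min_r2) {
        reason <- "EXCLUDED_LOW_R2"
      } else if (missing_global && anyNA(d)) {
        reason <- "EXCLUDED_MISSING_DOSAGE"
      } else {
        de <- effect_dosage(status, d)
        if (!missing_global) de[is.na(de)] <- 0
        for (s in scores_here) {
          part$sums[s, ] <- part$sums[s, ] + wmat[r, s] * de
        }
        part$used[scores_here] <- part$used[scores_here] + 1L
        reason <- paste0("USED_", status)
      }
    }
    audits[[r]] <- data.frame(
      chrom = repo_rows$chrom[r], pos = repo_rows$pos[r],
      other_allele = repo_rows$other_allele[r],
      effect_allele = repo_rows$effect_allele[r],
      score_id = ids[scores_here], reason = reason,
      stringsAsFactors = FALSE)
  }
  part$audits <- do.call(rbind, audits)
  rownames(part$audits) <- NULL
  part
}

#' Classify score coverage
#'
#' Coverage is the fraction of a score's variants usable after matching and
#' filtering. Classes follow the strict boundaries: above 0.75 is `HIGH`,
#' below 0.25 is `LOW`, and the closed band `[0.25, 0.75]` (including both
#' boundary values) is `MEDIUM`.
#'
#' @param coverage Numeric vector in `[0, 1]`.
#' @return Character vector of `"HIGH"`, `"MEDIUM"`, `"LOW"`.
#' @export
classify_coverage <- function(coverage) {
  if (any(is.na(coverage) | coverage < 0 | coverage > 1)) {
    stop("coverage must lie in [0, 1]")
  }
  ifelse(coverage > 0.75, "HIGH", ifelse(coverage < 0.25, "LOW", "MEDIUM"))
}

#' Aggregate per-chunk partial scores into final scores
#'
#' Sums the per-chunk partial sums in genomic chunk order into final
#' per-sample scores, totals the used-variant counts, computes per-score
#' coverage against the annotated variant counts and classifies it.
#'
#' @param partials List of `"pgs_partial"` objects over disjoint chunks.
#' @param annotations Named list of [score_annotation()]s, one per score
#'   column.
#' @return A list of class `"pgs_result"`: `scores` (samples x scores
#'   matrix), `summary` (per-score data frame with `n_total`, `n_used`,
#'   `coverage`, `coverage_class`), `audits`, `samples`.
#' @export
aggregate_partials <- function(partials, annotations) {
  stopifnot(length(partials) >= 1)
  chunks <- lapply(partials, `[[`, "chunk")
  if (!any(vapply(chunks, is.null, logical(1)))) {
    key <- vapply(chunks, function(c) paste(c$chrom, c$start, c$end), character(1))
    if (anyDuplicated(key)) stop("overlapping chunks passed to aggregate_partials()")
    iv <- data.frame(chrom = vapply(chunks, `[[`, character(1), "chrom"),
                     start = vapply(chunks, function(c) as.numeric(c$start), numeric(1)),
                     end = vapply(chunks, function(c) as.numeric(c$end), numeric(1)))
    for (ch in unique(iv$chrom)) {
      sub <- iv[iv$chrom == ch, , drop = FALSE]
      sub <- sub[order(sub$start), , drop = FALSE]
      if (nrow(sub) > 1 && any(sub$start[-1] <= sub$end[-nrow(sub)])) {
        stop("overlapping chunks passed to aggregate_partials()")
      }
    }
    ord <- order(chrom_rank(iv$chrom), iv$start, method = "radix")
    partials <- partials[ord]
  }
  ids <- rownames(partials[[1]]$sums)
  samples <- colnames(partials[[1]]$sums)
  sums <- matrix(0, length(ids), length(samples), dimnames = list(ids, samples))
  used <- setNames(integer(length(ids)), ids)
  for (p in partials) {
    stopifnot(identical(rownames(p$sums), ids), identical(colnames(p$sums), samples))
    sums <- sums + p$sums
    used <- used + p$used
  }
  n_total <- vapply(ids, function(id) annotations[[id]]$n_variants, integer(1))
  coverage <- ifelse(n_total > 0, used / n_total, 0)
  summ <- data.frame(score_id = ids, n_total = n_total, n_used = as.integer(used),
                     coverage = coverage,
                     coverage_class = classify_coverage(coverage),
                     stringsAsFactors = FALSE, row.names = NULL)
  audits <- do.call(rbind, lapply(partials, `[[`, "audits"))
  rownames(audits) <- NULL
  structure(list(scores = t(sums), summary = summ, audits = audits,
                 samples = samples),
            class = "pgs_result")
}

#' @export
print.pgs_result <- function(x, ...) {
  cat(sprintf("<pgs_result> %d samples x %d scores\n",
              length(x$samples), ncol(x$scores)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
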