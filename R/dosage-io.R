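# Reading imputed VCFs into per-site effect-dosage records with imputation
# quality. Dosages are the expected ALT-allele counts in [0,2] written by
# imputation servers in the DS FORMAT field; imputation quality comes from
# the R2 (imputed) or ER2 (genotyped) INFO field.

#' Read per-site dosages from an imputed VCF
#'
#' Produces one record per biallelic ALT allele. The dosage is taken from the
#' `DS` FORMAT field when present; otherwise the hard-call ALT count from
#' `GT`. A sample with neither is `NA` (missing). Multi-allelic records are
#' emitted once per ALT only when the file carries a per-allele `DS`
#' (`Number=A`); otherwise they are skipped with a warning. Dosages outside
#' `[0, 2]` raise an error rather than being clamped, since they indicate
#' wrong field semantics.
#'
#' @param vcf Path to a VCF (plain, or bgzipped and tabix-indexed for region
#'   queries).
#' @param region `NULL` to read the whole file, or a list/vector with
#'   `chrom`, `start`, `end` (1-based inclusive) to stream one interval;
#'   region queries require a tabix index.
#' @param quality_field INFO key carrying the imputation quality; the default
#'   reads `R2` and falls back to `ER2` per site.
#' @return A list of class `"dosage_set"`: `sites` (data frame with `chrom`,
#'   `pos`, `ref`, `alt`, `quality`, `typed`), `dosages` (numeric matrix,
#'   sites x samples, `NA` = missing) and `samples`.
#' @export
read_dosages <- function(vcf, region = NULL, quality_field = "R2") {
  if (!file.exists(vcf)) stop_data("VCF not found: ", vcf)
  if (!is.null(region)) {
    region <- as.list(region)
    names(region) <- c("chrom", "start", "end")[seq_along(region)]
    if (!file.exists(paste0(vcf, ".tbi")) && !file.exists(paste0(vcf, ".csi"))) {
      stop_data("region query requires a tabix index; run indexTabix()/tabix on ", vcf)
    }
    param <- VariantAnnotation::ScanVcfParam(
      which = GenomicRanges::GRanges(region$chrom,
                                     IRanges::IRanges(as.numeric(region$start),
                                                      as.numeric(region$end))))
    v <- VariantAnnotation::readVcf(Rsamtools::TabixFile(vcf), param = param)
  } else {
    v <- VariantAnnotation::readVcf(vcf)
  }
  vcf_to_dosage_set(v, quality_field)
}

vcf_samples <- function(vcf) {
  VariantAnnotation::samples(VariantAnnotation::scanVcfHeader(vcf))
}

# Count occurrences of allele index `k` in GT strings ("0/1", "1|1", ...);
# NA when the call contains a missing allele.
gt_allele_count <- function(gt, k = 1L) {
  cnt <- nchar(gt) - nchar(gsub(as.character(k), "", gt, fixed = TRUE))
  cnt[is.na(gt) | grepl(".", gt, fixed = TRUE)] <- NA_integer_
  cnt
}

vcf_to_dosage_set <- function(v, quality_field = "R2") {
  samples <- colnames(v)
  rr <- SummarizedExperiment::rowRanges(v)
  n <- length(rr)
  g <- VariantAnnotation::geno(v)
  ds <- if ("DS" %in% names(g)) g$DS else NULL
  gt <- if ("GT" %in% names(g)) g$GT else NULL
  inf <- VariantAnnotation::info(v)

  qual_of <- function(idx) {
    q <- rep(NA_real_, length(idx))
    for (key in unique(c(quality_field, "R2", "ER2"))) {
      if (key %in% names(inf)) {
        qi <- suppressWarnings(as.numeric(inf[[key]][idx]))
        q[is.na(q)] <- qi[is.na(q)]
      }
    }
    q
  }
  typed_of <- function(idx) {
    t <- rep(FALSE, length(idx))
    for (key in c("TYPED", "GENOTYPED")) {
      if (key %in% names(inf)) {
        ti <- inf[[key]][idx]
        if (is.logical(ti)) t <- t | (!is.na(ti) & ti)
      }
    }
    t
  }

  alt_list <- VariantAnnotation::alt(v)
  n_alt <- lengths(alt_list)
  bi <- which(n_alt == 1L)
  multi <- which(n_alt > 1L)

  chrom <- normalize_chrom(as.character(GenomicRanges::seqnames(rr)))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(VariantAnnotation::ref(v))

  ds_is_per_allele <- !is.null(ds) && is.list(ds)

  # biallelic fast path
  out_sites <- list()
  out_dos <- list()
  if (length(bi)) {
    alt1 <- vapply(bi, function(i) as.character(alt_list[[i]][1]), character(1))
    dmat <- matrix(NA_real_, length(bi), length(samples))
    if (!is.null(ds)) {
      dsm <- if (ds_is_per_allele) {
        matrix(vapply(ds[bi, , drop = FALSE], function(x) as.numeric(x)[1], numeric(1)),
               nrow = length(bi))
      } else {
        matrix(as.numeric(ds[bi, , drop = FALSE]), nrow = length(bi))
      }
      dmat <- dsm
    }
    if (!is.null(gt)) {
      hc <- matrix(as.numeric(gt_allele_count(gt[bi, , drop = FALSE], 1L)),
                   nrow = length(bi))
      na <- is.na(dmat)
      dmat[na] <- hc[na]
    }
    out_sites[[1]] <- data.frame(chrom = chrom[bi], pos = pos[bi],
                                 ref = ref[bi], alt = alt1,
                                 quality = qual_of(bi), typed = typed_of(bi),
                                 stringsAsFactors = FALSE)
    out_dos[[1]] <- dmat
  }
  if (length(multi)) {
    if (!ds_is_per_allele && is.null(gt)) {
      warning(sprintf("skipping %d multi-allelic record(s) without per-allele DS", length(multi)))
    } else {
      for (i in multi) {
        alts <- as.character(alt_list[[i]])
        per_allele_ds <- if (ds_is_per_allele) as.numeric(unlist(ds[i, ])) else NULL
        if (!ds_is_per_allele && !is.null(ds) && any(!is.na(as.numeric(ds[i, ])))) {
          warning(sprintf("skipping multi-allelic record %s:%d: DS is not per-allele", chrom[i], pos[i]))
          next
        }
        for (k in seq_along(alts)) {
          dk <- if (ds_is_per_allele) {
            vapply(seq_along(samples), function(j) as.numeric(ds[i, j][[1]])[k], numeric(1))
          } else {
            rep(NA_real_, length(samples))
          }
          if (!is.null(gt)) {
            hc <- as.numeric(gt_allele_count(gt[i, ], k))
            dk[is.na(dk)] <- hc[is.na(dk)]
          }
          out_sites[[length(out_sites) + 1L]] <-
            data.frame(chrom = chrom[i], pos = pos[i], ref = ref[i], alt = alts[k],
                       quality = qual_of(i), typed = typed_of(i),
                       stringsAsFactors = FALSE)
          out_dos[[length(out_dos) + 1L]] <- matrix(dk, nrow = 1L)
        }
      }
    }
  }

  sites <- if (length(out_sites)) do.call(rbind, out_sites) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), quality = numeric(), typed = logical(),
               stringsAsFactors = FALSE)
  dosages <- if (length(out_dos)) do.call(rbind, out_dos) else
    matrix(numeric(), 0L, length(samples))
  colnames(dosages) <- samples

  # preserve file order within the set (rbind keeps biallelic block first;
  # restore genomic file order)
  if (nrow(sites) > 1L) {
    ord <- order(chrom_rank(sites$chrom), sites$pos, method = "radix")
    sites <- sites[ord, , drop = FALSE]
    dosages <- dosages[ord, , drop = FALSE]
  }
  rownames(sites) <- NULL

  bad <- which(!is.na(dosages) & (dosages < -1e-9 | dosages > 2 + 1e-9), arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1, 1]
    stop_data(sprintf("dosage out of [0,2] at %s:%d sample %s: %g",
                      sites$chrom[i], sites$pos[i], samples[bad[1, 2]],
                      dosages[bad[1, 1], bad[1, 2]]))
  }

  structure(list(sites = sites, dosages = dosages, samples = samples),
            class = "dosage_set")
}

#' @export
print.dosage_set <- function(x, ...) {
  cat(sprintf("<dosage_set> %d sites x %d samples\n", nrow(x$sites), length(x$samples)))
  invisible(x)
}

# Subset a dosage_set to an interval (used when the VCF has no index).
subset_dosage_set <- function(dset, chrom, start, end) {
  hit <- dset$sites$chrom == normalize_chrom(chrom) &
    dset$sites$pos >= start & dset$sites$pos <= end
  out <- list(sites = dset$sites[hit, , drop = FALSE],
              dosages = dset$dosages[hit, , drop = FALSE],
              samples = dset$samples)
  rownames(out$sites) <- NULL
  structure(out, class = "dosage_set")
}
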