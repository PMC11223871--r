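# Fixed-size genomic chunking and the scoring driver: per chunk, extract
# the relevant repository rows via the tabix index, read the dosages for
# the region, score, then merge the partial sums in genomic order.

#' Tile contigs into fixed-size chunks
#'
#' Chunk `k` of a contig spans positions `[(k-1)*S + 1, k*S]` for chunk size
#' `S`; the last chunk is truncated at the contig length. Chunks are
#' returned in genomic order with a global ordinal.
#'
#' @param contigs Named numeric vector: contig name to length (or observed
#'   maximum position).
#' @param chunk_size_mb Chunk size in megabases (default 20).
#' @return Data frame with columns `chrom`, `start`, `end`, `ordinal`.
#' @export
make_chunks <- function(contigs, chunk_size_mb = 20) {
  if (!length(contigs)) stop_data("make_chunks: empty contig set")
  stopifnot(chunk_size_mb >= 1)
  s <- chunk_size_mb * 1e6
  nm <- normalize_chrom(names(contigs))
  ord <- order(chrom_rank(nm), method = "radix")
  out <- do.call(rbind, lapply(ord, function(i) {
    L <- as.numeric(contigs[[i]])
    n <- ceiling(L / s)
    data.frame(chrom = nm[i], start = (seq_len(n) - 1) * s + 1,
               end = pmin(seq_len(n) * s, L), stringsAsFactors = FALSE)
  }))
  out$ordinal <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Run chunked scoring over a VCF
#'
#' Drives the whole scoring pipeline: tiles the repository's contigs into
#' chunks, and for each chunk extracts the repository rows
#' ([query_interval()]), reads the region's dosages ([read_dosages()]) and
#' scores it ([score_chunk()]); the partials are merged in chunk-ordinal
#' order ([aggregate_partials()]), so results are bit-stable across worker
#' counts and chunk sizes.
#'
#' @param vcf Path to the imputed VCF. If the file is not tabix-indexed it
#'   is read once and subset per chunk in memory.
#' @param repo A `"pgs_repository"`.
#' @param min_r2,strand_mode,missing_global Passed to [score_chunk()].
#' @param chunk_size_mb Chunk size in megabases (default 20); `Inf` scores
#'   whole chromosomes in one chunk.
#' @param threads Number of parallel workers (forked; default 1). The
#'   merged result does not depend on this value.
#' @param contigs Optional named lengths; defaults to the maximum position
#'   per chromosome observed in the repository.
#' @return A `"pgs_result"` (see [aggregate_partials()]).
#' @export
run_scoring <- function(vcf, repo, min_r2 = 0.3, chunk_size_mb = 20,
                        strand_mode = c("resolve", "strict"),
                        missing_global = TRUE, threads = 1, contigs = NULL) {
  strand_mode <- match.arg(strand_mode)
  stopifnot(inherits(repo, "pgs_repository"))
  if (is.null(contigs)) {
    rows <- repo$rows
    if (!nrow(rows)) stop_data("repository has no variants")
    contigs <- tapply(rows$pos, rows$chrom, max)
  }
  if (is.infinite(chunk_size_mb)) {
    chunks <- data.frame(chrom = names(contigs), start = 1,
                         end = as.numeric(contigs), stringsAsFactors = FALSE)
    chunks <- chunks[order(chrom_rank(chunks$chrom)), , drop = FALSE]
    chunks$ordinal <- seq_len(nrow(chunks))
  } else {
    chunks <- make_chunks(contigs, chunk_size_mb)
  }

  indexed <- file.exists(paste0(vcf, ".tbi")) || file.exists(paste0(vcf, ".csi"))
  full <- if (!indexed) read_dosages(vcf) else NULL
  samples <- vcf_samples(vcf)

  score_one <- function(i) {
    ck <- as.list(chunks[i, ])
    rows <- tryCatch(query_interval(repo, ck$chrom, ck$start, ck$end),
                     error = function(e) stop_data("chunk ", ck$ordinal, " (",
                                                   ck$chrom, ":", ck$start, "-",
                                                   ck$end, "): ", conditionMessage(e)))
    if (!nrow(rows)) {
      return(new_partial(ck, repo_score_ids(repo), samples))
    }
    dset <- if (indexed) {
      read_dosages(vcf, region = list(chrom = ck$chrom, start = ck$start, end = ck$end))
    } else {
      subset_dosage_set(full, ck$chrom, ck$start, ck$end)
    }
    if (!identical(dset$samples, samples)) {
      stop_data("inconsistent sample set in chunk ", ck$ordinal)
    }
    score_chunk(dset, rows, min_r2 = min_r2, strand_mode = strand_mode,
                missing_global = missing_global, chunk = ck)
  }

  idx <- seq_len(nrow(chunks))
  partials <- if (threads > 1) {
    parallel::mclapply(idx, score_one, mc.cores = threads, mc.preschedule = TRUE)
  } else {
    lapply(idx, score_one)
  }
  err <- vapply(partials, function(p) inherits(p, "try-error") || inherits(p, "condition"), logical(1))
  if (any(err)) stop_data("chunk scoring failed: ", conditionMessage(partials[[which(err)[1]]]))
  partials <- partials[order(chunks$ordinal)]
  aggregate_partials(partials, repo$annotations)
}
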