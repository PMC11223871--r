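# Scoring-file parsing and the unified, coordinate-sorted, tabix-indexed
# multi-score weight repository.

#' Construct a score annotation
#'
#' Per-score metadata carried alongside the weights: the trait, the super
#' populations of the source GWAS (used later for population matching), the
#' GWAS sample count, publication info and the number of variants.
#'
#' @param score_id Score identifier (e.g. `"PGS000027"`).
#' @param trait Free-text trait description, or `NA`.
#' @param populations Character vector of super-population codes, a subset of
#'   `c("AFR","EUR","GME","EAS","SAS","AMR","OTH")`. Empty means the source
#'   populations are unknown; population matching then only excludes
#'   unclassified samples.
#' @param gwas_sample_count Non-negative integer or `NA`.
#' @param publication Free text / DOI or `NA`.
#' @param n_variants Positive integer, the number of variants in the score.
#' @param genome_build Declared genome build or `NA`.
#' @return A list of class `"pgs_annotation"`.
#' @export
score_annotation <- function(score_id, trait = NA_character_,
                             populations = character(),
                             gwas_sample_count = NA_integer_,
                             publication = NA_character_,
                             n_variants = NA_integer_,
                             genome_build = NA_character_) {
  populations <- toupper(as.character(populations))
  bad <- setdiff(populations, SUPER_POPULATIONS)
  if (length(bad)) {
    warning("dropping unknown population code(s): ", paste(bad, collapse = ", "))
    populations <- intersect(populations, SUPER_POPULATIONS)
  }
  structure(list(
    score_id = as.character(score_id),
    trait = trait,
    populations = populations,
    gwas_sample_count = gwas_sample_count,
    publication = publication,
    n_variants = as.integer(n_variants),
    genome_build = genome_build
  ), class = "pgs_annotation")
}

#' Parse a PGS Catalog style scoring file
#'
#' Reads a tab-delimited scoring file whose `#`-prefixed header lines carry
#' `key=value` metadata. Variant positions are taken from the harmonized
#' columns (`hm_chr`/`hm_pos`) when present, falling back to the
#' author-reported columns (`chr_name`/`chr_position`); `dialect` forces one
#' or the other. Rows lacking a position or effect allele are dropped and
#' counted; duplicate variant keys keep the first occurrence with a warning.
#'
#' @param path Path to the scoring file (plain or gzip).
#' @param dialect One of `"auto"`, `"author_reported"`, `"harmonized"`.
#' @return A list of class `"pgs_score"` with elements `annotation`
#'   (a [score_annotation()]), `variants` (data frame with columns `chrom`,
#'   `pos`, `effect_allele`, `other_allele`, `weight`), `n_dropped` and
#'   `n_duplicates`.
#' @export
parse_score_file <- function(path, dialect = c("auto", "author_reported", "harmonized")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_data("scoring file not found: ", path)
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]

  meta <- list()
  kv <- grep("^#[^#]", meta_lines, value = TRUE)
  for (l in kv) {
    l <- sub("^#", "", l)
    eq <- regexpr("=", l, fixed = TRUE)
    if (eq > 0) meta[[substr(l, 1, eq - 1)]] <- sub("^\\s+|\\s+$", "", substring(l, eq + 1))
  }

  if (!length(body)) stop_data("empty score: no data rows in ", path)
  header <- strsplit(body[[1]], "\t", fixed = TRUE)[[1]]
  need <- c("effect_allele", "effect_weight")
  for (col in need) {
    if (!col %in% header) stop_data("scoring file format error: missing column '", col, "' in ", path)
  }
  use_hm <- switch(dialect,
    auto = all(c("hm_chr", "hm_pos") %in% header),
    harmonized = TRUE,
    author_reported = FALSE
  )
  chr_col <- if (use_hm) "hm_chr" else "chr_name"
  pos_col <- if (use_hm) "hm_pos" else "chr_position"
  for (col in c(chr_col, pos_col)) {
    if (!col %in% header) stop_data("scoring file format error: missing column '", col, "' in ", path)
  }

  if (length(body) < 2) stop_data("empty score: no variants parsed from ", path)
  tab <- read.table(text = body[-1], sep = "\t", header = FALSE,
                    col.names = make.unique(header), comment.char = "",
                    quote = "", colClasses = "character",
                    stringsAsFactors = FALSE, fill = TRUE)
  names(tab) <- make.unique(header)

  chrom <- normalize_chrom(tab[[chr_col]])
  pos <- suppressWarnings(as.integer(tab[[pos_col]]))
  effect <- toupper(tab[["effect_allele"]])
  other <- if ("other_allele" %in% names(tab)) toupper(tab[["other_allele"]]) else rep(NA_character_, nrow(tab))
  other[!is.na(other) & (other == "" | other == ".")] <- NA_character_
  weight <- suppressWarnings(as.numeric(tab[["effect_weight"]]))

  ok <- !is.na(pos) & pos >= 1 & !is.na(effect) & nzchar(effect) &
    !is.na(chrom) & nzchar(chrom) & is.finite(weight)
  n_dropped <- sum(!ok)
  v <- data.frame(chrom = chrom[ok], pos = pos[ok],
                  effect_allele = effect[ok], other_allele = other[ok],
                  weight = weight[ok], stringsAsFactors = FALSE)
  if (!nrow(v)) stop_data("empty score: no variants parsed from ", path)

  key <- variant_key(v$chrom, v$pos, v$other_allele, v$effect_allele)
  dup <- duplicated(key)
  n_duplicates <- sum(dup)
  if (n_duplicates > 0) {
    warning(sprintf("%d duplicate variant key(s) in %s; keeping first occurrence", n_duplicates, path))
    v <- v[!dup, , drop = FALSE]
  }
  rownames(v) <- NULL

  ann <- score_annotation(
    score_id = meta$pgs_id %||% sub("\\.(txt|tsv)(\\.gz)?$", "", basename(path)),
    trait = meta$trait_reported %||% NA_character_,
    populations = if (!is.null(meta$populations)) strsplit(meta$populations, ",\\s*")[[1]] else character(),
    gwas_sample_count = as.integer(meta$n_samples %||% meta$gwas_sample_count %||% NA),
    publication = meta$citation %||% meta$pgp_id %||% NA_character_,
    n_variants = nrow(v),
    genome_build = meta$HmPOS_build %||% meta$genome_build %||% NA_character_
  )
  structure(list(annotation = ann, variants = v,
                 n_dropped = n_dropped, n_duplicates = n_duplicates),
            class = "pgs_score")
}

#' @export
print.pgs_score <- function(x, ...) {
  cat(sprintf("<pgs_score> %s: %d variants (%d dropped, %d duplicates collapsed)\n",
              x$annotation$score_id, nrow(x$variants), x$n_dropped, x$n_duplicates))
  invisible(x)
}

#' Merge scores into a unified weight repository
#'
#' Groups the variants of many scores by their full variant key
#' `(chrom, pos, other_allele, effect_allele)` into one coordinate-sorted
#' table with one weight column per score (`NA` where a score lacks the
#' variant). The same position may host several rows, which is required for
#' multi-allelic sites split into biallelic records.
#'
#' @param scores List of [parse_score_file()] results (or objects with the
#'   same structure).
#' @return A list of class `"pgs_repository"` with elements `rows` (the
#'   merged table), `annotations` (named list of annotations) and `source`
#'   (path of the backing file, `NULL` for in-memory repositories).
#' @export
merge_scores <- function(scores) {
  if (inherits(scores, "pgs_score")) scores <- list(scores)
  if (!length(scores)) stop_data("merge_scores: need at least one score")
  ids <- vapply(scores, function(s) s$annotation$score_id, character(1))
  if (anyDuplicated(ids)) {
    stop_data("duplicate score_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }

  all_v <- do.call(rbind, lapply(seq_along(scores), function(i) {
    v <- scores[[i]]$variants
    v$score <- i
    v
  }))
  key <- variant_key(all_v$chrom, all_v$pos, all_v$other_allele, all_v$effect_allele)
  ukey <- !duplicated(key)
  rows <- all_v[ukey, c("chrom", "pos", "other_allele", "effect_allele")]
  rows$pos <- as.integer(rows$pos)
  ord <- variant_order(rows$chrom, rows$pos, rows$other_allele, rows$effect_allele)
  rows <- rows[ord, , drop = FALSE]
  rownames(rows) <- NULL
  row_of <- match(key, variant_key(rows$chrom, rows$pos, rows$other_allele, rows$effect_allele))

  w <- matrix(NA_real_, nrow = nrow(rows), ncol = length(scores),
              dimnames = list(NULL, ids))
  w[cbind(row_of, all_v$score)] <- all_v$weight
  rows <- cbind(rows, as.data.frame(w, optional = TRUE))

  anns <- setNames(lapply(scores, function(s) s$annotation), ids)
  structure(list(rows = rows, annotations = anns, source = NULL),
            class = "pgs_repository")
}

#' @export
print.pgs_repository <- function(x, ...) {
  cat(sprintf("<pgs_repository> %d variant rows x %d scores%s\n",
              nrow(x$rows), length(x$annotations),
              if (is.null(x$source)) " (in memory)" else paste0(" [", x$source, "]")))
  invisible(x)
}

repo_score_ids <- function(repo) names(repo$annotations)

#' Write a repository to a bgzipped, tabix-indexed file set
#'
#' Emits the coordinate-sorted weight table as a bgzip-compressed TSV with
#' columns `CHROM`, `POS`, `OTHER`, `EFFECT` and one column per score
#' (`"."` for absent weights), a tabix index on the position column, and one
#' `key=value` annotation sidecar per score.
#'
#' @param repo A `"pgs_repository"`.
#' @param out_prefix Output path prefix; files are written as
#'   `<prefix>.txt.gz`, `<prefix>.txt.gz.tbi` and
#'   `<prefix>.<score_id>.annotation.txt`.
#' @return Invisibly, a list with the written `data`, `index` and
#'   `annotations` paths.
#' @export
write_repository <- function(repo, out_prefix) {
  stopifnot(inherits(repo, "pgs_repository"))
  rows <- repo$rows
  ord <- variant_order(rows$chrom, rows$pos, rows$other_allele, rows$effect_allele)
  if (!identical(ord, seq_len(nrow(rows)))) {
    stop("internal error: repository rows are not coordinate-sorted")
  }
  ids <- repo_score_ids(repo)

  txt <- file.path(tempdir(), paste0(basename(out_prefix), ".repo.tmp"))
  on.exit(unlink(txt), add = TRUE)
  header <- paste(c("#CHROM", "POS", "OTHER", "EFFECT", ids), collapse = "\t")
  other <- rows$other_allele
  other[is.na(other)] <- "."
  cells <- vapply(ids, function(id) format_weight(rows[[id]]),
                  character(nrow(rows)))
  if (nrow(rows) == 1L) cells <- matrix(cells, nrow = 1L)
  body <- do.call(paste, c(list(rows$chrom, rows$pos, other, rows$effect_allele),
                           lapply(seq_along(ids), function(j) cells[, j]),
                           sep = "\t"))
  writeLines(c("##pgsdesk-repository=1", header, body), txt)

  gz <- paste0(out_prefix, ".txt.gz")
  Rsamtools::bgzip(txt, dest = gz, overwrite = TRUE)
  idx <- Rsamtools::indexTabix(gz, seq = 1, start = 2, end = 2, comment = "#")

  ann_paths <- vapply(ids, function(id) {
    a <- repo$annotations[[id]]
    p <- paste0(out_prefix, ".", id, ".annotation.txt")
    writeLines(c(
      paste0("score_id=", a$score_id),
      paste0("trait=", if (is.na(a$trait)) "" else a$trait),
      paste0("populations=", paste(a$populations, collapse = ",")),
      paste0("gwas_sample_count=", if (is.na(a$gwas_sample_count)) "" else a$gwas_sample_count),
      paste0("publication=", if (is.na(a$publication)) "" else a$publication),
      paste0("n_variants=", a$n_variants),
      paste0("genome_build=", if (is.na(a$genome_build)) "" else a$genome_build)
    ), p)
    p
  }, character(1))

  invisible(list(data = gz, index = idx, annotations = ann_paths))
}

parse_repo_lines <- function(lines, ids) {
  empty <- data.frame(chrom = character(), pos = integer(),
                      other_allele = character(), effect_allele = character(),
                      stringsAsFactors = FALSE)
  for (id in ids) empty[[id]] <- numeric()
  if (!length(lines)) return(empty)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  m <- matrix(unlist(parts), ncol = 4L + length(ids), byrow = TRUE)
  rows <- data.frame(chrom = m[, 1], pos = as.integer(m[, 2]),
                     other_allele = ifelse(m[, 3] == ".", NA_character_, m[, 3]),
                     effect_allele = m[, 4], stringsAsFactors = FALSE)
  for (j in seq_along(ids)) {
    cell <- m[, 4L + j]
    rows[[ids[j]]] <- suppressWarnings(as.numeric(ifelse(cell == ".", NA, cell)))
  }
  rows
}

read_annotation_file <- function(path) {
  kv <- strsplit(readLines(path), "=", fixed = TRUE)
  vals <- setNames(vapply(kv, function(x) paste(x[-1], collapse = "="), character(1)),
                   vapply(kv, `[[`, character(1), 1))
  val <- function(k) {
    x <- if (k %in% names(vals)) vals[[k]] else ""
    if (!nzchar(x)) NA_character_ else x
  }
  pops <- val("populations")
  score_annotation(
    score_id = val("score_id"),
    trait = val("trait"),
    populations = if (is.na(pops)) character() else strsplit(pops, ",")[[1]],
    gwas_sample_count = suppressWarnings(as.integer(val("gwas_sample_count"))),
    publication = val("publication"),
    n_variants = as.integer(val("n_variants")),
    genome_build = val("genome_build")
  )
}

#' Read a repository written by [write_repository()]
#'
#' Loads the annotation sidecars and the full weight table into memory and
#' remembers the backing bgzip file so that [query_interval()] can use the
#' tabix index.
#'
#' @param out_prefix The prefix passed to [write_repository()].
#' @return A `"pgs_repository"`.
#' @export
read_repository <- function(out_prefix) {
  gz <- paste0(out_prefix, ".txt.gz")
  if (!file.exists(gz)) stop_data("repository not found: ", gz)
  lines <- readLines(gzfile(gz))
  hdr <- grep("^#CHROM", lines, value = TRUE)[1]
  ids <- strsplit(hdr, "\t", fixed = TRUE)[[1]][-(1:4)]
  rows <- parse_repo_lines(lines[!grepl("^#", lines)], ids)
  ann_paths <- paste0(out_prefix, ".", ids, ".annotation.txt")
  anns <- setNames(lapply(ann_paths, read_annotation_file), ids)
  structure(list(rows = rows, annotations = anns, source = gz),
            class = "pgs_repository")
}

#' Extract repository rows overlapping a genomic interval
#'
#' Returns the rows with matching chromosome and `start <= pos <= end`
#' (1-based, inclusive, as in tabix), in coordinate order. File-backed
#' repositories are queried through the tabix index; in-memory repositories
#' by a sorted scan. An unknown chromosome yields an empty result.
#'
#' @param repo A `"pgs_repository"`.
#' @param chrom Chromosome name (normalized with [normalize_chrom()]).
#' @param start,end 1-based inclusive interval bounds, `start <= end`.
#' @return Data frame with the same columns as `repo$rows`.
#' @export
query_interval <- function(repo, chrom, start, end) {
  stopifnot(inherits(repo, "pgs_repository"), start <= end, start >= 1)
  chrom <- normalize_chrom(chrom)
  ids <- repo_score_ids(repo)
  if (!is.null(repo$source) && file.exists(paste0(repo$source, ".tbi"))) {
    tf <- Rsamtools::TabixFile(repo$source)
    rng <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
    lines <- tryCatch(unlist(Rsamtools::scanTabix(tf, param = rng), use.names = FALSE),
                      error = function(e) character())
    return(parse_repo_lines(lines, ids))
  }
  rows <- repo$rows
  hit <- rows$chrom == chrom & rows$pos >= start & rows$pos <= end
  out <- rows[hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}
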