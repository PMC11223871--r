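# Output artifacts: the per-sample score matrix as TSV, per-score summary
# statistics restricted to ancestry-matched samples, and a self-contained
# HTML report with coverage colour classes and score distributions.

#' Write the score matrix as a tab-delimited file
#'
#' First column `sample`, one column per score, full-precision decimal
#' values; row order follows the VCF sample order, column order the
#' repository score order. Scores are written for every sample, including
#' samples later excluded from summary statistics.
#'
#' @param result A `"pgs_result"` from [run_scoring()] /
#'   [aggregate_partials()].
#' @param out Output path.
#' @return Invisibly, `out`.
#' @export
write_scores_tsv <- function(result, out) {
  stopifnot(inherits(result, "pgs_result"), length(result$samples) >= 1,
            ncol(result$scores) >= 1)
  ids <- colnames(result$scores)
  lines <- c(paste(c("sample", ids), collapse = "\t"),
             vapply(seq_along(result$samples), function(i) {
               paste(c(result$samples[i], sprintf("%.17g", result$scores[i, ])),
                     collapse = "\t")
             }, character(1)))
  writeLines(lines, out)
  invisible(out)
}

#' Read a score matrix written by [write_scores_tsv()]
#'
#' @param path Path to the TSV.
#' @return Numeric matrix, samples x scores, with sample row names.
#' @export
read_scores_tsv <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$sample
  m
}

#' Per-score summaries with population matching
#'
#' For each score, matches every sample's ancestry call against the score's
#' annotated GWAS populations ([match_population()]), excludes mismatching
#' and unclassified samples, and summarizes the remaining samples' scores
#' (mean, sd, min, max). Scores with zero coverage are flagged with a
#' warning so a structural 0 cannot be mistaken for a real score.
#'
#' @param result A `"pgs_result"`.
#' @param calls An `"ancestry_calls"` covering the same samples, or `NULL`
#'   to include everyone.
#' @param annotations Named list of [score_annotation()]s; defaults to the
#'   attribute carried by the result when present.
#' @return A list of class `"pgs_summaries"`: `table` (per-score data
#'   frame), `included` (named list of included-sample vectors), `warnings`.
#' @export
summarize_scores <- function(result, calls = NULL, annotations = NULL) {
  stopifnot(inherits(result, "pgs_result"))
  ids <- colnames(result$scores)
  samples <- result$samples
  if (!is.null(calls)) {
    if (!setequal(calls$calls$sample, samples)) {
      stop_data("sample sets of scores and ancestry calls disagree")
    }
    labels <- calls$calls$label[match(samples, calls$calls$sample)]
  } else {
    labels <- NULL
  }

  included <- list()
  warns <- character()
  rows <- lapply(ids, function(id) {
    ann <- annotations[[id]]
    pops <- if (!is.null(ann)) ann$populations else character()
    status <- if (is.null(labels)) rep("INCLUDED", length(samples)) else
      match_population(labels, pops)
    inc <- samples[status == "INCLUDED"]
    included[[id]] <<- inc
    x <- result$scores[match(inc, samples), id]
    cov_row <- result$summary[result$summary$score_id == id, ]
    if (cov_row$coverage == 0) {
      warns <<- c(warns, sprintf("score %s has zero coverage; reported values are structural zeros", id))
    }
    n_mm <- sum(status == "EXCLUDED_POP_MISMATCH")
    if (n_mm > 0) {
      warns <<- c(warns, sprintf("score %s: %d sample(s) excluded from summary statistics (population mismatch)", id, n_mm))
    }
    data.frame(
      score_id = id,
      trait = if (!is.null(ann)) ann$trait else NA_character_,
      populations = paste(pops, collapse = ","),
      n_variants = cov_row$n_total,
      n_used = cov_row$n_used,
      coverage = cov_row$coverage,
      coverage_class = cov_row$coverage_class,
      n_included = length(inc),
      n_excluded_mismatch = n_mm,
      n_excluded_unclassified = sum(status == "EXCLUDED_UNCLASSIFIED"),
      mean = if (length(x)) mean(x) else NA_real_,
      sd = if (length(x) > 1) sd(x) else NA_real_,
      min = if (length(x)) min(x) else NA_real_,
      max = if (length(x)) max(x) else NA_real_,
      stringsAsFactors = FALSE)
  })
  structure(list(table = do.call(rbind, rows), included = included,
                 warnings = warns),
            class = "pgs_summaries")
}

#' @export
print.pgs_summaries <- function(x, ...) {
  print(x$table[, c("score_id", "n_included", "coverage", "coverage_class",
                    "mean", "sd")], row.names = FALSE)
  if (length(x$warnings)) cat(paste0("warning: ", x$warnings, collapse = "\n"), "\n")
  invisible(x)
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

hist_data <- function(x) {
  if (!length(x) || !is.finite(diff(range(x))) ) {
    return(list(breaks = numeric(), counts = integer()))
  }
  h <- graphics::hist(x, breaks = "Sturges", plot = FALSE)
  list(breaks = h$breaks, counts = h$counts)
}

#' Render a self-contained HTML report
#'
#' One table row per score, coloured by coverage class (green HIGH, orange
#' MEDIUM, red LOW), an ancestry overview, the warning list, and per-score
#' histograms of the included samples' score distributions. Every number is
#' taken from [summarize_scores()] and the score matrix; nothing is
#' recomputed. Histogram data are embedded as JSON
#' (`<script type="application/json" class="histogram">`) next to an inline
#' SVG rendering, so the counts are machine-readable.
#'
#' @param summaries A `"pgs_summaries"`.
#' @param calls An `"ancestry_calls"` or `NULL`.
#' @param result The `"pgs_result"` the summaries were computed from (used
#'   only for the histogram values of included samples).
#' @param out Output path.
#' @return Invisibly, `out`.
#' @export
render_html <- function(summaries, calls, result, out) {
  stopifnot(inherits(summaries, "pgs_summaries"), nrow(summaries$table) >= 1)
  tab <- summaries$table
  cls_color <- c(HIGH = "#2e7d32", MEDIUM = "#ef6c00", LOW = "#c62828")

  score_rows <- vapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    sprintf(paste0(
      '<tr class="score %s"><td>%s</td><td>%s</td><td>%s</td><td>%d</td>',
      '<td>%d</td><td>%.1f%%</td><td class="class-cell" style="color:%s">%s</td>',
      '<td>%d</td><td>%s</td><td>%s</td></tr>'),
      r$coverage_class, html_escape(r$score_id),
      html_escape(ifelse(is.na(r$trait), "", r$trait)),
      html_escape(r$populations), r$n_variants, r$n_used, 100 * r$coverage,
      cls_color[[r$coverage_class]], r$coverage_class, r$n_included,
      ifelse(is.na(r$mean), "", sprintf("%.4f", r$mean)),
      ifelse(is.na(r$sd), "", sprintf("%.4f", r$sd)))
  }, character(1))

  hists <- vapply(seq_len(nrow(tab)), function(i) {
    id <- tab$score_id[i]
    inc <- summaries$included[[id]]
    x <- result$scores[match(inc, result$samples), id]
    h <- hist_data(x)
    json <- jsonlite::toJSON(list(score = id, breaks = h$breaks,
                                  counts = h$counts), auto_unbox = TRUE,
                             digits = NA)
    svg <- if (length(h$counts)) {
      mx <- max(h$counts, 1)
      bars <- paste(vapply(seq_along(h$counts), function(b) {
        sprintf('<rect x="%d" y="%.1f" width="18" height="%.1f" fill="#1565c0"/>',
                (b - 1) * 20, 100 - 95 * h$counts[b] / mx, 95 * h$counts[b] / mx)
      }, character(1)), collapse = "")
      sprintf('<svg width="%d" height="100">%s</svg>', 20 * length(h$counts), bars)
    } else "<em>no included samples</em>"
    sprintf('<section><h3>%s</h3><script type="application/json" class="histogram" data-score="%s">%s</script>%s</section>',
            html_escape(id), html_escape(id), json, svg)
  }, character(1))

  anc <- if (!is.null(calls)) {
    counts <- table(calls$calls$label)
    paste0("<table><tr><th>Population</th><th>Samples</th></tr>",
           paste(sprintf("<tr><td>%s</td><td>%d</td></tr>",
                         html_escape(names(counts)), as.integer(counts)),
                 collapse = ""),
           "</table>")
  } else "<p>No ancestry calls supplied.</p>"

  warns <- if (length(summaries$warnings)) {
    paste0("<ul>", paste(sprintf('<li class="warning">%s</li>',
                                 html_escape(summaries$warnings)), collapse = ""),
           "</ul>")
  } else "<p>No warnings.</p>"

  html <- c(
    "<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\"><title>Polygenic score report</title>",
    "<style>body{font-family:sans-serif;margin:2em}table{border-collapse:collapse}",
    "td,th{border:1px solid #ccc;padding:4px 8px}</style></head><body>",
    "<h1>Polygenic score report</h1>",
    "<h2>Scores</h2>",
    "<table id=\"scores\"><tr><th>Score</th><th>Trait</th><th>Populations</th>",
    "<th>Variants</th><th>Used</th><th>Coverage</th><th>Class</th>",
    "<th>Included samples</th><th>Mean</th><th>SD</th></tr>",
    score_rows,
    "</table>",
    "<h2>Ancestry overview</h2>", anc,
    "<h2>Warnings</h2>", warns,
    "<h2>Score distributions (included samples)</h2>", hists,
    "</body></html>")
  writeLines(html, out)
  invisible(out)
}
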