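# Ancestry estimation: a labelled reference PC space, direct projection of
# study samples onto the reference loadings, and an inverse-distance
# weighted K-NN vote over the seven super populations with an unclassified
# fallback for samples between clusters.

#' Build a labelled reference PCA space
#'
#' Filters reference SNPs by minor allele frequency, standardizes genotypes
#' under Hardy-Weinberg scaling (centre `2p`, scale `sqrt(2p(1-p))` for
#' reference allele frequency `p`), and computes the top principal
#' components. Study samples are later placed into this space by projecting
#' onto the SNP loadings with the reference means and scales.
#'
#' @param genotypes Numeric matrix, samples x SNPs, dosages in `[0, 2]`;
#'   column names are variant keys used to align study genotypes.
#' @param labels Character vector of super-population codes, one per sample.
#' @param n_pcs Number of principal components to keep (default 10).
#' @param maf_min Minimum minor allele frequency (default 0.01); SNPs below
#'   it (or monomorphic) are dropped.
#' @return A list of class `"pca_space"`: `snps` (data frame with `key`,
#'   `p`, `scale`), `loadings` (SNPs x `n_pcs`), `ref_coords` (samples x
#'   `n_pcs`), `ref_labels`, `n_pcs`, `sdev`.
#' @export
fit_reference_pca <- function(genotypes, labels, n_pcs = 10, maf_min = 0.01) {
  stopifnot(is.matrix(genotypes), nrow(genotypes) == length(labels))
  if (nrow(genotypes) <= n_pcs) {
    stop("need more reference samples than principal components")
  }
  bad_lab <- setdiff(unique(labels), SUPER_POPULATIONS)
  if (length(bad_lab)) {
    stop("unknown population label(s): ", paste(bad_lab, collapse = ", "))
  }
  if (is.null(colnames(genotypes))) {
    colnames(genotypes) <- paste0("snp", seq_len(ncol(genotypes)))
  }
  p <- colMeans(genotypes, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- which(is.finite(maf) & maf >= maf_min & p > 0 & p < 1)
  if (length(keep) < n_pcs) {
    stop(sprintf("only %d usable SNPs after MAF filter; need at least %d",
                 length(keep), n_pcs))
  }
  G <- genotypes[, keep, drop = FALSE]
  p <- p[keep]
  sc <- sqrt(2 * p * (1 - p))
  Z <- sweep(sweep(G, 2, 2 * p, "-"), 2, sc, "/")
  Z[is.na(Z)] <- 0

  sv <- svd(Z, nu = n_pcs, nv = n_pcs)
  loadings <- sv$v
  # deterministic sign: largest-magnitude loading positive in each PC
  for (j in seq_len(n_pcs)) {
    peak <- which.max(abs(loadings[, j]))
    if (loadings[peak, j] < 0) {
      loadings[, j] <- -loadings[, j]
    }
  }
  coords <- Z %*% loadings
  colnames(coords) <- colnames(loadings) <- paste0("PC", seq_len(n_pcs))
  rownames(coords) <- rownames(genotypes)

  # Per-PC shrinkage of out-of-sample projections under the spiked
  # covariance model (noise variance 1 after standardization): a new
  # sample's expected score along sample PC k is rho_k times the in-sample
  # scale. PCs whose eigenvalue sits below the Marchenko-Pastur edge carry
  # no signal and are left uncorrected.
  n <- nrow(Z)
  gam <- ncol(Z) / n
  ell <- sv$d[seq_len(n_pcs)]^2 / max(1, n - 1)
  shrink <- rep(1, n_pcs)
  above <- ell > (1 + sqrt(gam))^2
  if (any(above)) {
    l <- ell[above]
    lam <- ((l + 1 - gam) + sqrt(pmax((l + 1 - gam)^2 - 4 * l, 0))) / 2
    cos2 <- pmax(0, 1 - gam / (lam - 1)^2) / (1 + gam / (lam - 1))
    shrink[above] <- pmin(1, pmax(sqrt(cos2 * lam / l), 0.1))
  }

  structure(list(
    snps = data.frame(key = colnames(G), p = unname(p), scale = unname(sc),
                      stringsAsFactors = FALSE),
    loadings = loadings,
    ref_coords = coords,
    ref_labels = as.character(labels),
    n_pcs = n_pcs,
    sdev = sv$d[seq_len(n_pcs)] / sqrt(max(1, nrow(Z) - 1)),
    shrinkage = shrink
  ), class = "pca_space")
}

#' @export
print.pca_space <- function(x, ...) {
  cat(sprintf("<pca_space> %d reference samples, %d SNPs, %d PCs; populations: %s\n",
              nrow(x$ref_coords), nrow(x$snps), x$n_pcs,
              paste(sort(unique(x$ref_labels)), collapse = " ")))
  invisible(x)
}

#' Project study samples into a reference PC space
#'
#' Standardizes study dosages with the reference allele frequencies and
#' scales, mean-imputes missing or absent SNPs (zero after centring) and
#' multiplies into the reference loadings. By default the projection is
#' rescaled by the per-PC out-of-sample shrinkage factors estimated from
#' the reference spectrum, so that new samples land on the reference
#' clusters rather than systematically closer to the origin (the role the
#' Procrustes step plays in projection tools built for sequence data).
#' With `correct = FALSE`, projecting a reference sample's own genotypes
#' reproduces its stored coordinates exactly.
#'
#' @param space A `"pca_space"`.
#' @param genotypes Study dosage matrix, samples x SNPs, with variant-key
#'   column names matching `space$snps$key`.
#' @param min_overlap Minimum fraction of the space's SNPs that must be
#'   present in `genotypes` (default 0.5).
#' @param correct Apply the out-of-sample shrinkage correction (default
#'   `TRUE`; use `FALSE` when projecting the reference samples themselves).
#' @return Numeric matrix, samples x `n_pcs`.
#' @export
project_samples <- function(space, genotypes, min_overlap = 0.5,
                            correct = TRUE) {
  stopifnot(inherits(space, "pca_space"), is.matrix(genotypes))
  idx <- match(space$snps$key, colnames(genotypes))
  overlap <- mean(!is.na(idx))
  if (overlap < min_overlap) {
    stop(sprintf("study genotypes cover only %.1f%% of the reference SNPs (minimum %.1f%%)",
                 100 * overlap, 100 * min_overlap))
  }
  n <- nrow(genotypes)
  Z <- matrix(0, n, nrow(space$snps))
  present <- which(!is.na(idx))
  G <- genotypes[, idx[present], drop = FALSE]
  Zp <- sweep(sweep(G, 2, 2 * space$snps$p[present], "-"), 2,
              space$snps$scale[present], "/")
  Zp[is.na(Zp)] <- 0
  Z[, present] <- Zp
  coords <- Z %*% space$loadings
  if (correct && !is.null(space$shrinkage)) {
    coords <- sweep(coords, 2, space$shrinkage, "/")
  }
  rownames(coords) <- rownames(genotypes)
  colnames(coords) <- colnames(space$loadings)
  coords
}

knn_vote <- function(x, space, k, vote_threshold) {
  d <- sqrt(colSums((t(space$ref_coords) - x)^2))
  nn <- order(d, method = "radix")[seq_len(k)]  # stable: ties keep input order
  w <- 1 / (d[nn] + 1e-12)
  votes <- vapply(SUPER_POPULATIONS, function(pop) {
    sum(w[space$ref_labels[nn] == pop])
  }, numeric(1))
  frac <- votes / sum(w)
  top <- which.max(frac)
  label <- if (frac[top] > vote_threshold) SUPER_POPULATIONS[top] else UNCLASSIFIED
  list(label = label, fractions = frac)
}

#' Classify samples by weighted K-nearest neighbours in PC space
#'
#' For each sample, computes Euclidean distances to the reference samples
#' over the space's PCs, takes the `k` nearest (ties at the k-th distance
#' broken by reference input order), weights each neighbour's population
#' label by the inverse distance `1/(d + 1e-12)`, and assigns the top
#' population only when its weighted vote fraction strictly exceeds
#' `vote_threshold`; otherwise the sample is `UNCLASSIFIED` (typical for
#' admixed samples lying between clusters).
#'
#' @param coords Numeric matrix (samples x `n_pcs`) from
#'   [project_samples()], or a single coordinate vector.
#' @param space A `"pca_space"`.
#' @param k Number of neighbours (default 20).
#' @param vote_threshold Required vote fraction, in `(0, 1]` (default 0.75).
#' @return A list of class `"ancestry_calls"`: `calls` (data frame with
#'   `sample`, `label`), `votes` (samples x 7 fraction matrix), `coords`.
#' @export
classify_knn <- function(coords, space, k = 20, vote_threshold = 0.75) {
  stopifnot(inherits(space, "pca_space"))
  if (is.null(dim(coords))) coords <- matrix(coords, nrow = 1)
  if (k < 1) stop_usage("k must be a positive integer")
  if (k > nrow(space$ref_coords)) {
    stop_usage("k exceeds the number of reference samples")
  }
  if (vote_threshold <= 0 || vote_threshold > 1) {
    stop_usage("vote_threshold must lie in (0, 1]")
  }
  n <- nrow(coords)
  labels <- character(n)
  votes <- matrix(0, n, length(SUPER_POPULATIONS),
                  dimnames = list(rownames(coords), SUPER_POPULATIONS))
  for (i in seq_len(n)) {
    v <- knn_vote(coords[i, seq_len(space$n_pcs)], space, k, vote_threshold)
    labels[i] <- v$label
    votes[i, ] <- v$fractions
  }
  ids <- rownames(coords) %||% paste0("sample", seq_len(n))
  if (is.null(rownames(coords))) rownames(votes) <- ids
  structure(list(
    calls = data.frame(sample = ids, label = labels, stringsAsFactors = FALSE),
    votes = votes, coords = coords
  ), class = "ancestry_calls")
}

#' @export
print.ancestry_calls <- function(x, ...) {
  cat(sprintf("<ancestry_calls> %d samples\n", nrow(x$calls)))
  print(table(x$calls$label))
  invisible(x)
}

#' Match a sample's ancestry call against a score's source populations
#'
#' Unclassified samples are always excluded; classified samples are excluded
#' when their population is not among the score's annotated GWAS
#' populations. Scores with no annotated populations restrict nothing
#' beyond the unclassified rule.
#'
#' @param label Character vector of population labels (or `"UNCLASSIFIED"`).
#' @param annotation A [score_annotation()] (or a character vector of
#'   population codes).
#' @return Character vector of `"INCLUDED"`, `"EXCLUDED_POP_MISMATCH"`,
#'   `"EXCLUDED_UNCLASSIFIED"`.
#' @export
match_population <- function(label, annotation) {
  pops <- if (inherits(annotation, "pgs_annotation")) annotation$populations else as.character(annotation)
  ifelse(label == UNCLASSIFIED, "EXCLUDED_UNCLASSIFIED",
         ifelse(length(pops) == 0 | label %in% pops, "INCLUDED",
                "EXCLUDED_POP_MISMATCH"))
}

#' Fit, project and classify in one call
#'
#' Convenience wrapper used by the command-line interface: builds the
#' reference space from a labelled panel, projects the study samples and
#' runs the K-NN classifier.
#'
#' @param ref_genotypes,ref_labels Reference panel (samples x SNPs) and
#'   labels.
#' @param study_genotypes Study dosage matrix (samples x SNPs).
#' @param n_pcs,maf_min Passed to [fit_reference_pca()].
#' @param k,vote_threshold Passed to [classify_knn()].
#' @param min_overlap Passed to [project_samples()].
#' @return An `"ancestry_calls"` object with the fitted `space` attached.
#' @export
estimate_ancestry <- function(ref_genotypes, ref_labels, study_genotypes,
                              n_pcs = 10, maf_min = 0.01, k = 20,
                              vote_threshold = 0.75, min_overlap = 0.5) {
  space <- fit_reference_pca(ref_genotypes, ref_labels, n_pcs = n_pcs,
                             maf_min = maf_min)
  coords <- project_samples(space, study_genotypes, min_overlap = min_overlap)
  calls <- classify_knn(coords, space, k = k, vote_threshold = vote_threshold)
  calls$space <- space
  calls
}
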