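# Independent brute-force oracles. These reimplement the scoring and
# classification rules from first principles, deliberately sharing no code
# with the package internals.

COMP <- c(A = "T", C = "G", G = "C", T = "A")

# Naive per-sample score: loop over every score variant, find the VCF site,
# decide orientation by explicit case analysis, apply the filters, sum.
oracle_scores <- function(scores, sites, dosages, min_r2 = 0.3,
                          strand_mode = "resolve") {
  n_samples <- ncol(dosages)
  out <- matrix(0, n_samples, length(scores))
  used <- integer(length(scores))
  for (s in seq_along(scores)) {
    v <- scores[[s]]$variants
    for (r in seq_len(nrow(v))) {
      e <- v$effect_allele[r]; o <- v$other_allele[r]
      hit <- which(sites$chrom == v$chrom[r] & sites$pos == v$pos[r])
      d_eff <- NULL
      for (i in hit) {
        ref <- sites$ref[i]; alt <- sites$alt[i]
        snv <- nchar(e) == 1 && nchar(ref) == 1 && nchar(alt) == 1 &&
          (is.na(o) || nchar(o) == 1)
        if (!is.na(o) && snv && strand_mode == "resolve" &&
            unname(COMP[o]) == e) next  # palindromic: strand unresolvable
        d <- NULL
        if (is.na(o)) {
          if (e == alt) d <- dosages[i, ]
          else if (e == ref) d <- 2 - dosages[i, ]
        } else if (e == alt && o == ref) {
          d <- dosages[i, ]
        } else if (e == ref && o == alt) {
          d <- 2 - dosages[i, ]
        } else if (snv && !is.na(o) && strand_mode == "resolve") {
          if (unname(COMP[e]) == alt && unname(COMP[o]) == ref) {
            d <- dosages[i, ]
          } else if (unname(COMP[e]) == ref && unname(COMP[o]) == alt) {
            d <- 2 - dosages[i, ]
          }
        }
        if (!is.null(d)) { d_eff <- d; break }
      }
      if (is.null(d_eff)) next
      q <- sites$quality[hit[1]]
      if (!is.na(q) && q < min_r2) next
      if (anyNA(d_eff)) next
      out[, s] <- out[, s] + v$weight[r] * d_eff
      used[s] <- used[s] + 1L
    }
  }
  list(scores = out, used = used)
}

# Brute-force inverse-distance-weighted K-NN vote.
oracle_knn <- function(x, ref_coords, labels, k, threshold = 0.75) {
  d <- apply(ref_coords, 1, function(r) sqrt(sum((r - x)^2)))
  nn <- head(seq_along(d)[order(d)], k)
  w <- 1 / (d[nn] + 1e-12)
  tot <- tapply(w, labels[nn], sum)
  frac <- tot / sum(w)
  best <- names(frac)[which.max(frac)]
  if (frac[[best]] > threshold) best else "UNCLASSIFIED"
}

# Hudson Fst estimator for two populations from genotype matrices
# (samples x SNPs, 0/1/2), averaged over SNPs as ratio-of-averages.
hudson_fst <- function(g1, g2) {
  p1 <- colMeans(g1) / 2
  p2 <- colMeans(g2) / 2
  n1 <- 2 * nrow(g1)
  n2 <- 2 * nrow(g2)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}
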