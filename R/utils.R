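#' @keywords internal
"_PACKAGE"

#' @importFrom stats rbeta rbinom rnorm runif sd setNames
#' @importFrom utils read.table write.table
NULL

# The seven GWAS Catalog super-population codes used for score annotation
# and ancestry calls.
SUPER_POPULATIONS <- c("AFR", "EUR", "GME", "EAS", "SAS", "AMR", "OTH")

UNCLASSIFIED <- "UNCLASSIFIED"

#' Normalize chromosome names
#'
#' Strips a leading `"chr"` prefix (any case) and upper-cases the sex and
#' mitochondrial chromosomes, so that scoring files and VCFs written in
#' different dialects key to the same contig.
#'
#' @param x Character vector of chromosome names.
#' @return Character vector of normalized names (`"1"`, `"X"`, `"MT"`, ...).
#' @examples
#' normalize_chrom(c("chr1", "ChrX", "mt", "22"))
#' @export
normalize_chrom <- function(x) {
  x <- sub("^[Cc][Hh][Rr]", "", as.character(x))
  sex <- x %in% c("x", "y", "mt", "m", "M")
  x[sex] <- toupper(x[sex])
  x[x == "M"] <- "MT"
  x
}

# Sort rank for chromosomes: numeric first in numeric order, then X, Y, MT,
# then anything else alphabetically.
chrom_rank <- function(x) {
  n <- suppressWarnings(as.numeric(x))
  r <- n
  r[x == "X"] <- 100
  r[x == "Y"] <- 101
  r[x == "MT"] <- 102
  other <- is.na(r)
  if (any(other)) {
    lv <- sort(unique(x[other]))
    r[other] <- 200 + match(x[other], lv)
  }
  r
}

# Order index for variant tables: (chrom, pos, other, effect).
variant_order <- function(chrom, pos, other = NULL, effect = NULL) {
  if (is.null(other)) other <- rep("", length(chrom))
  if (is.null(effect)) effect <- rep("", length(chrom))
  other[is.na(other)] <- ""
  order(chrom_rank(chrom), pos, other, effect, method = "radix")
}

#' Complement alleles (strand flip)
#'
#' @param a Character vector of allele strings.
#' @return The base-complemented alleles (`A<->T`, `C<->G`, per character).
#' @export
complement_allele <- function(a) {
  chartr("ACGTacgt", "TGCAtgca", a)
}

is_snv_allele <- function(a) {
  !is.na(a) & nchar(a) == 1L & a %in% c("A", "C", "G", "T")
}

#' Is an allele pair palindromic?
#'
#' A/T and G/C pairs map onto themselves under complementation, so the
#' strand of such a variant cannot be determined and it is excluded in
#' strand-resolve mode.
#'
#' @param effect,other Single-base allele vectors.
#' @return Logical vector; `FALSE` for indels or missing other alleles.
#' @export
is_palindromic_pair <- function(effect, other) {
  is_snv_allele(effect) & is_snv_allele(other) &
    effect == complement_allele(other)
}

#' Canonical variant key string
#'
#' @param chrom,pos,other,effect Variant fields; `NA` other alleles print
#'   as `"."`.
#' @return `"chrom:pos:other:effect"` strings.
#' @export

# Full-precision decimal formatting that survives an as.numeric() round trip
# bit-exactly; "." for NA.
format_weight <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "."
  out
}

variant_key <- function(chrom, pos, other, effect) {
  other[is.na(other)] <- "."
  paste(chrom, pos, other, effect, sep = ":")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("pgsdesk_data_error", "error")))
}

stop_usage <- function(...) {
  stop(errorCondition(paste0(...), class = c("pgsdesk_usage_error", "error")))
}
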