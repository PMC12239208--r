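#' @keywords internal
"_PACKAGE"

#' @importFrom stats median rbinom rpois runif setNames
#' @importFrom utils head read.table write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample roles recognised by the pipeline
#' @keywords internal
POOL_ROLES <- c("mutant_pool", "wildtype_pool", "sterile_sector", "fertile_sector")

IMPACT_LEVELS <- c("HIGH", "MODERATE", "LOW", "MODIFIER")

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Empty variant-call table
#'
#' Canonical zero-row data frame with the columns every variant set in the
#' package carries: `chrom`, `pos`, `ref`, `alt`, `depth`, `alt_depth`, `af`.
#' @return a zero-row data.frame
#' @keywords internal
empty_calls <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), depth = integer(), alt_depth = integer(),
             af = numeric(), stringsAsFactors = FALSE)
}

#' Validate a variant-call data frame
#'
#' Checks the invariants of a single-nucleotide variant call table: single-base
#' ref/alt with ref != alt, `1 <= depth`, `0 <= alt_depth <= depth`, and
#' `af == alt_depth / depth`.
#'
#' @param calls data.frame with columns chrom, pos, ref, alt, depth, alt_depth, af
#' @param genome optional reference genome; when given, calls on chromosomes
#'   absent from the genome are rejected
#' @return `calls`, row-ordered by (chrom, pos), invisibly unchanged otherwise
#' @export
validate_calls <- function(calls, genome = NULL) {
  need <- c("chrom", "pos", "ref", "alt", "depth", "alt_depth", "af")
  miss <- setdiff(need, names(calls))
  if (length(miss)) stopf("variant table is missing column(s): %s", paste(miss, collapse = ", "))
  if (nrow(calls) == 0) return(calls[, need])
  if (any(nchar(calls$ref) != 1L) || any(nchar(calls$alt) != 1L))
    stopf("only single-nucleotide alleles are allowed")
  if (any(calls$ref == calls$alt)) stopf("ref and alt alleles must differ")
  if (any(calls$depth < 1L)) stopf("depth must be >= 1")
  if (any(calls$alt_depth < 0L | calls$alt_depth > calls$depth))
    stopf("alt_depth must lie in [0, depth]")
  if (any(abs(calls$af - calls$alt_depth / calls$depth) > 1e-9))
    stopf("allele frequency must equal alt_depth / depth")
  if (anyDuplicated(paste(calls$chrom, calls$pos)))
    stopf("at most one call per (chrom, pos) is allowed")
  if (!is.null(genome)) {
    bad <- setdiff(unique(calls$chrom), names(genome))
    if (length(bad)) stopf("calls on chromosome(s) absent from the genome: %s",
                           paste(bad, collapse = ", "))
  }
  out <- calls[order(calls$chrom, calls$pos), need, drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Construct a pooled/sector variant sample
#'
#' Bundles a variant-call table with a sample identifier and its role in the
#' screen (mutant pool, wild-type sibling pool, or sterile/fertile sector).
#'
#' @param sample_id sample name
#' @param role one of `"mutant_pool"`, `"wildtype_pool"`, `"sterile_sector"`,
#'   `"fertile_sector"`
#' @param calls variant-call data.frame (see [validate_calls()])
#' @param genome optional reference genome used to check chromosome names
#' @return an object of class `pool_variant_set`
#' @export
pool_variant_set <- function(sample_id, role, calls, genome = NULL) {
  role <- match.arg(role, POOL_ROLES)
  calls <- validate_calls(calls, genome)
  structure(list(sample_id = sample_id, role = role, calls = calls),
            class = "pool_variant_set")
}

#' @export
print.pool_variant_set <- function(x, ...) {
  cat(sprintf("<pool_variant_set> %s (%s): %d SNV call(s)\n",
              x$sample_id, x$role, nrow(x$calls)))
  invisible(x)
}

site_key <- function(chrom, pos) paste(chrom, pos, sep = ":")
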