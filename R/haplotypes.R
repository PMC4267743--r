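#' Phased binary haplotype matrix
#'
#' Container for a sample of phased, biallelic SNP haplotypes from one
#' genomic region: an \code{n x S} 0/1 matrix together with the physical
#' positions (kb) of the \code{S} SNPs and the region length \code{L} (kb).
#' Positions must be strictly increasing and lie inside \code{[0, L]}
#' (two SNPs at the same coordinate are rejected: infinite-sites data).
#'
#' @param alleles integer or numeric matrix with entries in \{0, 1\};
#'   rows are haplotypes, columns are SNPs.
#' @param positions numeric vector of SNP positions in kb, strictly
#'   increasing, one per column of \code{alleles}.
#' @param region_length total region length L in kb (> 0).
#' @param labels optional character vector of per-haplotype identifiers.
#' @return an object of class \code{"haplotypes"} with components
#'   \code{alleles}, \code{positions}, \code{region_length}, \code{labels}.
#' @examples
#' h <- haplotypes(rbind(c(0, 1), c(1, 0)), positions = c(5, 15),
#'                 region_length = 20)
#' h
#' @export
haplotypes <- function(alleles, positions, region_length, labels = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  positions <- as.numeric(positions)
  region_length <- as.numeric(region_length)[1]
  if (!is.finite(region_length) || region_length <= 0)
    stop("region_length must be a positive number of kb")
  if (ncol(alleles) != length(positions))
    stop("number of SNP columns (", ncol(alleles), ") does not match ",
         "number of positions (", length(positions), ")")
  if (length(positions)) {
    if (anyNA(alleles) || !all(alleles == 0L | alleles == 1L))
      stop("allele entries must all be 0 or 1 (phased biallelic data)")
    if (any(!is.finite(positions)))
      stop("positions must be finite")
    if (any(diff(positions) <= 0))
      stop("positions must be strictly increasing (infinite-sites data; ",
           "duplicated coordinates are not allowed)")
    if (positions[1] < 0 || positions[length(positions)] > region_length)
      stop("positions must lie within [0, region_length]")
  }
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != nrow(alleles))
      stop("labels must have one entry per haplotype")
  }
  structure(list(alleles = alleles, positions = positions,
                 region_length = region_length, labels = labels),
            class = "haplotypes")
}

#' @export
print.haplotypes <- function(x, ...) {
  cat(sprintf("haplotypes: %d sequences, %d segregating sites, %.4g kb region\n",
              nrow(x$alleles), ncol(x$alleles), x$region_length))
  if (ncol(x$alleles))
    cat(sprintf("  positions %.4g .. %.4g kb\n",
                x$positions[1], x$positions[length(x$positions)]))
  invisible(x)
}

#' @export
dim.haplotypes <- function(x) dim(x$alleles)

n_hap <- function(x) nrow(x$alleles)
n_snp <- function(x) ncol(x$alleles)

# guard used by every likelihood entry point
check_likelihood_input <- function(x) {
  stopifnot(inherits(x, "haplotypes"))
  if (n_hap(x) < 2) stop("at least 2 haplotypes are required")
  if (n_snp(x) < 1) stop("at least 1 segregating site is required")
  invisible(x)
}

#' Watterson's estimate of the per-kb mutation rate
#'
#' \eqn{\hat\theta_W = S / (L \sum_{i=1}^{n-1} 1/i)} from the segregating-site
#' count; used to parameterise mutation when simulating bootstrap replicates.
#'
#' @param x a \code{\link{haplotypes}} object.
#' @return estimated mutation rate per kb.
#' @export
watterson_theta <- function(x) {
  stopifnot(inherits(x, "haplotypes"))
  n <- n_hap(x)
  if (n < 2) stop("need n >= 2")
  n_snp(x) / (x$region_length * sum(1 / seq_len(n - 1)))
}
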