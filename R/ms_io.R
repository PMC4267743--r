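#' Read haplotype replicates from an ms-format stream
#'
#' Parses Hudson's \code{ms}-style output: replicate blocks introduced by
#' \code{//}, each with a \code{segsites:} line, a \code{positions:} line of
#' fractional coordinates in [0, 1], and one 0/1 row per haplotype. Anything
#' before the first \code{//} (command echo, seeds) is ignored; trailing
#' blank lines are tolerated. Fractional positions are rescaled to kb by the
#' caller-supplied region length.
#'
#' @param file path to an ms-format text file, or a character vector of
#'   lines (treated as the file contents).
#' @param region_length region length L in kb used to rescale positions.
#' @return a list of \code{\link{haplotypes}} objects, one per replicate.
#' @seealso \code{\link{write_ms}}
#' @export
read_ms <- function(file, region_length) {
  lines <- if (length(file) == 1L && !grepl("\n", file) && file.exists(file))
    readLines(file) else unlist(strsplit(file, "\n", fixed = TRUE))
  starts <- grep("^//", lines)
  if (!length(starts))
    stop("no replicate blocks ('//' lines) found in ms input")
  ends <- c(starts[-1] - 1L, length(lines))
  out <- vector("list", length(starts))
  for (r in seq_along(starts)) {
    block <- lines[(starts[r] + 1L):ends[r]]
    block <- block[nzchar(trimws(block))]
    segline <- grep("^segsites:", block)
    if (length(segline) != 1L)
      stop("replicate ", r, ": expected exactly one 'segsites:' line")
    S <- as.integer(sub("^segsites:\\s*", "", block[segline]))
    if (is.na(S) || S < 0)
      stop("replicate ", r, ": malformed segsites count")
    if (S == 0L) {
      rows <- block[-seq_len(segline)]
      rows <- rows[!grepl("^positions:", rows)]
      out[[r]] <- haplotypes(matrix(0L, length(rows), 0L), numeric(0),
                             region_length)
      next
    }
    posline <- grep("^positions:", block)
    if (length(posline) != 1L)
      stop("replicate ", r, ": expected exactly one 'positions:' line")
    frac <- as.numeric(strsplit(trimws(sub("^positions:\\s*", "",
                                           block[posline])), "\\s+")[[1]])
    if (length(frac) != S)
      stop("replicate ", r, ": line ", posline,
           ": position count does not match segsites")
    if (any(!is.finite(frac)) || any(diff(frac) <= 0))
      stop("replicate ", r, ": line ", posline,
           ": positions must be increasing numbers")
    rows <- block[(posline + 1L):length(block)]
    bad <- grep("^[01]+$", rows, invert = TRUE)
    if (length(bad))
      stop("replicate ", r, ": line ", bad[1],
           " of block: haplotype rows must contain only 0/1 characters")
    if (any(nchar(rows) != S))
      stop("replicate ", r, ": haplotype row length does not match segsites")
    alle <- matrix(as.integer(unlist(strsplit(rows, "", fixed = TRUE))),
                   nrow = length(rows), byrow = TRUE)
    out[[r]] <- haplotypes(alle, frac * region_length, region_length)
  }
  out
}

#' Write haplotype replicates in ms format
#'
#' Inverse of \code{\link{read_ms}}: positions are written as fractions of
#' the region length with 6 decimals, so a round trip reproduces alleles
#' exactly and positions to within \code{1e-6 * L}.
#'
#' @param x a \code{\link{haplotypes}} object or a list of them.
#' @param file optional path; if omitted the lines are returned invisibly.
#' @param header logical; write an ms-like header line first.
#' @return invisibly, the character vector of lines written.
#' @export
write_ms <- function(x, file = NULL, header = TRUE) {
  if (inherits(x, "haplotypes")) x <- list(x)
  stopifnot(all(vapply(x, inherits, TRUE, "haplotypes")))
  lines <- if (header)
    c(sprintf("ms %d %d", if (length(x)) nrow(x[[1]]$alleles) else 0L,
              length(x)), "") else character(0)
  for (h in x) {
    if (h$region_length <= 0) stop("region_length must be positive")
    lines <- c(lines, "//", sprintf("segsites: %d", n_snp(h)))
    if (n_snp(h) > 0) {
      lines <- c(lines,
                 paste("positions:",
                       paste(sprintf("%.6f", h$positions / h$region_length),
                             collapse = " ")),
                 apply(h$alleles, 1, paste, collapse = ""))
    }
    lines <- c(lines, "")
  }
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Read a plain-format haplotype file
#'
#' Plain interchange format: a header line \code{n S L}, one line of S
#' positions in kb, then n rows of S characters in \{0,1\}.
#'
#' @param file path or character vector of lines.
#' @return a \code{\link{haplotypes}} object.
#' @export
read_hap <- function(file) {
  lines <- if (length(file) == 1L && !grepl("\n", file) && file.exists(file))
    readLines(file) else unlist(strsplit(file, "\n", fixed = TRUE))
  lines <- lines[nzchar(trimws(lines))]
  hdr <- as.numeric(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(hdr) != 3 || anyNA(hdr)) stop("malformed header: expected 'n S L'")
  n <- as.integer(hdr[1]); S <- as.integer(hdr[2]); L <- hdr[3]
  pos <- if (S > 0) as.numeric(strsplit(trimws(lines[2]), "\\s+")[[1]])
         else numeric(0)
  rows <- if (S > 0) lines[3:(2 + n)] else character(0)
  alle <- if (S > 0)
    matrix(as.integer(unlist(strsplit(rows, "", fixed = TRUE))),
           nrow = n, byrow = TRUE) else matrix(0L, n, 0L)
  haplotypes(alle, pos, L)
}

#' Write a plain-format haplotype file
#'
#' @param x a \code{\link{haplotypes}} object.
#' @param file optional path.
#' @return invisibly, the lines written.
#' @export
write_hap <- function(x, file = NULL) {
  stopifnot(inherits(x, "haplotypes"))
  lines <- c(sprintf("%d %d %.10g", n_hap(x), n_snp(x), x$region_length))
  if (n_snp(x) > 0)
    lines <- c(lines, paste(sprintf("%.10g", x$positions), collapse = " "),
               apply(x$alleles, 1, paste, collapse = ""))
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Split a locus into overlapping SNP windows
#'
#' Divides a haplotype matrix into windows of \code{window} SNPs with
#' \code{overlap} shared SNPs between adjacent windows, the segmentation
#' used when testing long loci piece by piece. Window starts are at SNP
#' offsets 0, window-overlap, 2(window-overlap), ...; the final window
#' absorbs a remainder shorter than the step, so it may carry up to
#' \code{window + step - 1} SNPs (e.g. 41 SNPs at window 20 / overlap 15
#' give windows of 20, 20, 20, 20 and 21 SNPs). Each segment keeps the
#' physical coordinates of its SNPs; its own region spans first to last SNP.
#'
#' @param x a \code{\link{haplotypes}} object with at least \code{window} SNPs.
#' @param window SNPs per segment (default 20).
#' @param overlap SNPs shared by adjacent segments (default 15);
#'   \code{0 <= overlap < window}.
#' @return a list of \code{\link{haplotypes}} segments; each has attribute
#'   \code{"snp_index"} giving the source column range.
#' @export
segment_haplotypes <- function(x, window = 20L, overlap = 15L) {
  stopifnot(inherits(x, "haplotypes"))
  window <- as.integer(window); overlap <- as.integer(overlap)
  if (overlap < 0L || overlap >= window)
    stop("need 0 <= overlap < window")
  S <- n_snp(x)
  if (S < window)
    stop("locus has ", S, " SNPs, fewer than one window of ", window,
         "; analyse the whole locus instead of segmenting")
  step <- window - overlap
  starts <- seq.int(1L, by = step, length.out = max(1L, (S - overlap) %/% step))
  # drop any start whose full window would not fit; the previous window absorbs it
  starts <- starts[starts + window - 1L <= S]
  ends <- starts + window - 1L
  ends[length(ends)] <- S  # final segment extended to cover trailing SNPs
  lapply(seq_along(starts), function(i) {
    idx <- starts[i]:ends[i]
    pos <- x$positions[idx]
    seg <- haplotypes(x$alleles[, idx, drop = FALSE], pos - pos[1],
                      region_length = max(pos[length(pos)] - pos[1],
                                          .Machine$double.eps),
                      labels = x$labels)
    attr(seg, "snp_index") <- c(starts[i], ends[i])
    seg
  })
}
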