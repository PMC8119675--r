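#' Genome specification
#'
#' A minimal description of the genome a track or matrix lives on: an ordered
#' set of chromosome names, their lengths in bp, and which chromosomes are sex
#' chromosomes (excluded from compartment scoring and z-scaling).
#'
#' @param lengths Named numeric vector of chromosome lengths in bp.  Names are
#'   the chromosome identifiers; order is preserved.
#' @param sex_chroms Character vector of chromosome names to treat as sex
#'   chromosomes.  Must be a subset of `names(lengths)`.
#' @return An object of class `GenomeSpec`.
#' @examples
#' gs <- genome_spec(c(chr1 = 20e6, chr2 = 20e6, chrX = 10e6),
#'                   sex_chroms = "chrX")
#' autosomes(gs)
#' @export
genome_spec <- function(lengths, sex_chroms = character()) {
  if (is.null(names(lengths)) || anyDuplicated(names(lengths)))
    stop("chromosome lengths must be uniquely named")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("chromosome lengths must be positive")
  if (!all(sex_chroms %in% names(lengths)))
    stop("sex_chroms must name chromosomes present in `lengths`")
  structure(
    list(chroms = names(lengths),
         lengths = setNames(as.numeric(lengths), names(lengths)),
         sex_chroms = as.character(sex_chroms)),
    class = "GenomeSpec")
}

#' @export
print.GenomeSpec <- function(x, ...) {
  cat("GenomeSpec:", length(x$chroms), "chromosomes,",
      format(sum(x$lengths), big.mark = ","), "bp total\n")
  if (length(x$sex_chroms))
    cat("  sex chromosomes:", paste(x$sex_chroms, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname genome_spec
#' @param genome A `GenomeSpec`.
#' @export
autosomes <- function(genome) {
  setdiff(genome$chroms, genome$sex_chroms)
}

#' Number of fixed-width bins on a chromosome
#'
#' The last bin may be shorter than `bin_size` (a partial terminal bin); it is
#' counted here but excluded from HMM fitting and compartment scoring.
#'
#' @param genome A `GenomeSpec`.
#' @param chrom Chromosome name.
#' @param bin_size Bin width in bp.
#' @return Integer bin count, `ceiling(length / bin_size)`.
#' @export
n_bins <- function(genome, chrom, bin_size) {
  stopifnot(chrom %in% genome$chroms, bin_size > 0)
  as.integer(ceiling(genome$lengths[[chrom]] / bin_size))
}

# complete (full-width) bins on a chromosome
n_complete_bins <- function(genome, chrom, bin_size) {
  as.integer(floor(genome$lengths[[chrom]] / bin_size))
}

# width in bp of bin i (1-based) on a chromosome
bin_widths <- function(genome, chrom, bin_size) {
  nb <- n_bins(genome, chrom, bin_size)
  w <- rep(bin_size, nb)
  rem <- genome$lengths[[chrom]] - (nb - 1) * bin_size
  w[nb] <- rem
  w
}
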