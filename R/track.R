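#' Per-chromosome binned signal track
#'
#' Fixed-width bin values for every chromosome of a genome.  Units are one of
#' `raw` (read counts), `normalized` (depth-normalized counts), `rpkm`, or
#' `zscore`.  Count-like tracks carry the total number of mapped reads in the
#' library they came from, which drives depth normalization and RPKM.
#'
#' @param values Named list (one element per chromosome) of numeric vectors,
#'   one value per bin.
#' @param genome A [genome_spec()].
#' @param bin_size Bin width in bp.
#' @param units One of `"raw"`, `"normalized"`, `"rpkm"`, `"zscore"`.
#' @param total_reads Total mapped reads in the library backing this track.
#'   Required (and positive) for count-like units; ignored for z-scores.
#'   Note this is the library total, which for a track covering a subset of a
#'   genome can exceed the sum of bin counts.
#' @return An object of class `BinnedTrack`.
#' @export
binned_track <- function(values, genome, bin_size, units = "raw",
                         total_reads = NA_real_) {
  units <- match.arg(units, c("raw", "normalized", "rpkm", "zscore"))
  if (!identical(sort(names(values)), sort(genome$chroms)))
    stop("`values` must have one element per chromosome of the genome")
  values <- values[genome$chroms]
  for (chrom in genome$chroms) {
    nb <- n_bins(genome, chrom, bin_size)
    if (length(values[[chrom]]) != nb)
      stop(sprintf("chromosome %s: expected %d bins, got %d",
                   chrom, nb, length(values[[chrom]])))
  }
  if (units %in% c("raw", "normalized", "rpkm")) {
    if (any(unlist(values, use.names = FALSE) < 0, na.rm = TRUE))
      stop("count-like track values must be non-negative")
    if (!is.na(total_reads) && total_reads < 0)
      stop("total_reads must be non-negative")
  }
  structure(
    list(values = values, genome = genome, bin_size = as.numeric(bin_size),
         units = units, total_reads = as.numeric(total_reads)),
    class = "BinnedTrack")
}

#' @export
print.BinnedTrack <- function(x, ...) {
  cat(sprintf("BinnedTrack [%s], bin %s bp, %d chromosomes, %d bins\n",
              x$units, format(x$bin_size, big.mark = ","),
              length(x$values), sum(lengths(x$values))))
  if (!is.na(x$total_reads))
    cat("  library total:", format(x$total_reads, big.mark = ","), "reads\n")
  invisible(x)
}

#' Depth-normalize a raw count track
#'
#' Rescales every bin count by `scale_to / total_reads` so that libraries of
#' different depth become comparable.  The default scale of 30,000,000 reads
#' is the convention used for broad H3K9me2 domain calling.
#'
#' @param track A raw `BinnedTrack` with `total_reads > 0`.
#' @param scale_to Reference library size (reads).
#' @return A `BinnedTrack` with `units = "normalized"`.
#' @export
normalize_counts <- function(track, scale_to = 30e6) {
  stopifnot(inherits(track, "BinnedTrack"))
  if (track$units != "raw")
    stop("normalize_counts expects a raw count track")
  if (is.na(track$total_reads) || track$total_reads <= 0)
    stop("cannot normalize a track with zero or unknown total_reads")
  f <- scale_to / track$total_reads
  track$values <- lapply(track$values, function(v) v * f)
  track$units <- "normalized"
  track
}

#' Cap normalized bin counts at a maximum
#'
#' Replaces values above `max_count` with `max_count`.  Suppresses the
#' repeat-pileup artifact bins (satellite arrays, blacklist regions) that would
#' otherwise dominate the enriched-state emission estimate.
#'
#' @param track A normalized `BinnedTrack`.
#' @param max_count Cap; defaults to 150 normalized reads per bin.
#' @return The capped track, still `normalized`.
#' @export
cap_counts <- function(track, max_count = 150) {
  stopifnot(inherits(track, "BinnedTrack"))
  if (track$units != "normalized")
    stop("cap_counts expects a normalized track")
  if (!is.finite(max_count) || max_count <= 0)
    stop("max_count must be positive")
  track$values <- lapply(track$values, function(v) pmin(v, max_count))
  track
}

#' Convert raw counts to RPKM
#'
#' Reads per kilobase per million mapped reads, using the track's library
#' total.  The partial terminal bin uses its true width.
#'
#' @param track A raw `BinnedTrack` with `total_reads > 0`.
#' @return A `BinnedTrack` with `units = "rpkm"`.
#' @export
rpkm_track <- function(track) {
  stopifnot(inherits(track, "BinnedTrack"))
  if (track$units != "raw")
    stop("rpkm_track expects a raw count track")
  if (is.na(track$total_reads) || track$total_reads <= 0)
    stop("cannot compute RPKM with zero or unknown total_reads")
  mil <- track$total_reads / 1e6
  for (chrom in track$genome$chroms) {
    kb <- bin_widths(track$genome, chrom, track$bin_size) / 1000
    track$values[[chrom]] <- track$values[[chrom]] / kb / mil
  }
  track$units <- "rpkm"
  track
}

#' Z-scale an RPKM track over autosomal bins
#'
#' Standardizes a per-sample RPKM track to mean 0 and (population) standard
#' deviation 1, computed across all autosomal bins.  Sex chromosomes are
#' dropped from the result.
#'
#' @param track An `rpkm` `BinnedTrack`.
#' @return A `BinnedTrack` with `units = "zscore"` restricted to autosomes.
#' @export
zscale_track <- function(track) {
  stopifnot(inherits(track, "BinnedTrack"))
  if (track$units != "rpkm")
    stop("zscale_track expects an RPKM track")
  auto <- autosomes(track$genome)
  vals <- unlist(track$values[auto], use.names = FALSE)
  vals <- vals[is.finite(vals)]
  if (length(vals) < 2)
    stop("need at least two finite autosomal bins to z-scale")
  mu <- mean(vals)
  sigma <- sqrt(mean((vals - mu)^2))  # population sd
  if (sigma == 0)
    stop("zero variance across autosomal bins; cannot z-scale")
  sub <- genome_spec(track$genome$lengths[auto])
  binned_track(lapply(track$values[auto], function(v) (v - mu) / sigma),
               sub, track$bin_size, units = "zscore")
}

#' Aggregate a count track to coarser bins
#'
#' Sums raw counts from fine bins into coarser bins whose width is an exact
#' multiple of the fine width (e.g. 2 kb to 10 kb or 100 kb).
#'
#' @param track A raw `BinnedTrack`.
#' @param new_bin_size Target bin width, a multiple of `track$bin_size`.
#' @return A raw `BinnedTrack` at `new_bin_size`.
#' @export
rebin_track <- function(track, new_bin_size) {
  stopifnot(inherits(track, "BinnedTrack"), track$units == "raw")
  k <- new_bin_size / track$bin_size
  if (k != round(k) || k < 1)
    stop("new_bin_size must be a positive multiple of the current bin size")
  out <- list()
  for (chrom in track$genome$chroms) {
    nb_new <- n_bins(track$genome, chrom, new_bin_size)
    grp <- rep(seq_len(nb_new), each = k)[seq_along(track$values[[chrom]])]
    out[[chrom]] <- as.numeric(
      rowsum(track$values[[chrom]], grp, reorder = TRUE))
  }
  binned_track(out, track$genome, new_bin_size, units = "raw",
               total_reads = track$total_reads)
}

#' Project per-bin values onto a different bin grid
#'
#' Coverage-weighted averaging of one fixed-width grid onto another (used to
#' carry 100-kb compartment scores onto e.g. 80-kb ChIP bins).  `NA` source
#' bins contribute nothing; a target bin with no finite source coverage is
#' `NA`.
#'
#' @param values Numeric vector of source-bin values for one chromosome.
#' @param from_bin Source bin width (bp).
#' @param to_bin Target bin width (bp).
#' @param chrom_len Chromosome length (bp).
#' @return Numeric vector of target-bin values.
#' @export
project_bins <- function(values, from_bin, to_bin, chrom_len) {
  nb_to <- as.integer(ceiling(chrom_len / to_bin))
  out <- rep(NA_real_, nb_to)
  for (j in seq_len(nb_to)) {
    lo <- (j - 1) * to_bin
    hi <- min(j * to_bin, chrom_len)
    i0 <- floor(lo / from_bin) + 1
    i1 <- min(ceiling(hi / from_bin), length(values))
    if (i0 > length(values)) next
    idx <- i0:i1
    ov <- pmin(idx * from_bin, hi) - pmax((idx - 1) * from_bin, lo)
    keep <- is.finite(values[idx]) & ov > 0
    if (any(keep))
      out[j] <- sum(values[idx][keep] * ov[keep]) / sum(ov[keep])
  }
  out
}

#' Standard error of the mean
#'
#' `sd(x) / sqrt(n)` with the population (divide-by-n) standard deviation.
#'
#' @param x Numeric vector.
#' @return The SEM.
#' @export
sem <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n == 0) return(NA_real_)
  sqrt(mean((x - mean(x))^2)) / sqrt(n)
}
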