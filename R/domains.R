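#' Connect runs of enriched bins into domains
#'
#' Maximal runs of consecutively enriched bins on each chromosome are merged
#' into a single bin-aligned interval; the mean enriched posterior over the
#' run is recorded.
#'
#' @param states A `StatePosteriorTrack` from [decode_states()].
#' @return A domain data.frame with columns `chrom`, `start`, `end`, `name`,
#'   `mean_posterior`, `status` (initially `"unassigned"`).
#' @export
connect_domains <- function(states) {
  out <- list()
  for (chrom in states$genome$chroms) {
    e <- states$enriched[[chrom]]
    if (!any(e)) next
    r <- rle(e)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values
    if (!any(keep)) next
    s <- starts[keep]; en <- ends[keep]
    post <- vapply(seq_along(s), function(k)
      mean(states$posterior[[chrom]][s[k]:en[k]]), 0)
    out[[chrom]] <- data.frame(
      chrom = chrom,
      start = (s - 1) * states$bin_size,
      end = pmin(en * states$bin_size, states$genome$lengths[[chrom]]),
      mean_posterior = post, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), name = character(),
                      mean_posterior = numeric(), status = character()))
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df$name <- sprintf("domain_%05d", seq_len(nrow(df)))
  df$status <- "unassigned"
  df[c("chrom", "start", "end", "name", "mean_posterior", "status")]
}

#' Call broad enriched domains from a raw count track
#'
#' The full domain-calling pipeline for one condition: depth-normalize to
#' 30 M reads, round, cap at `max_count`, fit the two-state Poisson HMM per
#' chromosome, pool the parameters across chromosomes by arithmetic
#' averaging, decode posteriors genome-wide with the pooled parameters, and
#' connect enriched runs into domains.
#'
#' @param track A raw `BinnedTrack` (typically 2-kb bins).
#' @param max_count Post-normalization cap, default 150.
#' @param posterior_threshold Enriched-label threshold, default 0.9.
#' @param scale_to Normalization target depth, default 30,000,000.
#' @param chroms Chromosomes to fit (default: all); decoding always covers
#'   every chromosome.
#' @return A list of class `domain_call`: `domains` (data.frame), `params`
#'   (pooled `HmmParams`), `per_chrom_params`, and `states`
#'   (`StatePosteriorTrack`).
#' @export
call_domains <- function(track, max_count = 150, posterior_threshold = 0.9,
                         scale_to = 30e6, chroms = NULL) {
  stopifnot(inherits(track, "BinnedTrack"), track$units == "raw")
  capped <- cap_counts(normalize_counts(track, scale_to = scale_to),
                       max_count = max_count)
  if (is.null(chroms)) chroms <- capped$genome$chroms
  per_chrom <- lapply(chroms, function(ch)
    fit_hmm_per_chromosome(capped, ch))
  names(per_chrom) <- chroms
  pooled <- average_hmm_params(per_chrom)
  states <- decode_states(capped, pooled,
                          posterior_threshold = posterior_threshold)
  structure(list(domains = connect_domains(states), params = pooled,
                 per_chrom_params = per_chrom, states = states),
            class = "domain_call")
}

#' @export
print.domain_call <- function(x, ...) {
  cat(sprintf("domain_call: %d domains, pooled lambda_d=%.2f lambda_e=%.2f\n",
              nrow(x$domains), x$params$lambda[1], x$params$lambda[2]))
  invisible(x)
}

# GRanges view of an interval data.frame (0-based half-open -> 1-based)
as_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1, end = df$end))
}

#' Count reads of a raw track inside intervals
#'
#' Sums bin counts overlapping each interval, weighting border bins by their
#' overlap fraction.  For bin-aligned intervals (domains) this is an exact
#' read count.
#'
#' @param track A raw `BinnedTrack`.
#' @param intervals Interval data.frame (`chrom`, `start`, `end`).
#' @return Numeric vector of counts, one per interval.
#' @export
count_reads_in_intervals <- function(track, intervals) {
  vapply(seq_len(nrow(intervals)), function(k) {
    chrom <- intervals$chrom[k]
    lo <- intervals$start[k]; hi <- intervals$end[k]
    v <- track$values[[chrom]]
    bs <- track$bin_size
    i0 <- floor(lo / bs) + 1
    i1 <- min(ceiling(hi / bs), length(v))
    if (i0 > length(v)) return(0)
    idx <- i0:i1
    w <- bin_widths(track$genome, chrom, bs)[idx]
    ov <- pmin(idx * bs, hi) - pmax((idx - 1) * bs, lo)
    ov <- pmin(ov, w)
    sum(v[idx] * ov / w)
  }, 0)
}

#' Identify lost domains between two conditions
#'
#' For each reference-condition domain, reads are counted in both conditions
#' and depth-normalized to a common total (default 10,000,000).  A domain is
#' `lost` when the normalized fold change reference/target is at least
#' `fold_min` *and* the lower-tail Poisson probability
#' `P(X <= target | lambda = reference)` is at most `p_max`; otherwise it is
#' `retained`.  Domains with zero reference reads cannot be tested and are
#' `unassigned` (with a warning).
#'
#' @param domains Reference-condition domain data.frame.
#' @param reference Raw `BinnedTrack` of the reference condition, with
#'   `total_reads`.
#' @param target Raw `BinnedTrack` of the target condition.
#' @param fold_min Fold-change threshold, default 4.
#' @param p_max Poisson p-value threshold, default 1e-4.
#' @param depth Common depth both conditions are normalized to.
#' @return The domain data.frame with `status` set to `lost`, `retained` or
#'   `unassigned`, plus columns `ref_norm`, `target_norm`, `fold`, `p_value`.
#' @export
call_lost_domains <- function(domains, reference, target, fold_min = 4,
                              p_max = 1e-4, depth = 1e7) {
  if (!nrow(domains)) return(domains)
  stopifnot(reference$units == "raw", target$units == "raw")
  if (is.na(reference$total_reads) || reference$total_reads <= 0 ||
      is.na(target$total_reads) || target$total_reads <= 0)
    stop("both tracks need positive total_reads for depth normalization")
  ref_n <- count_reads_in_intervals(reference, domains) *
    depth / reference$total_reads
  tgt_n <- count_reads_in_intervals(target, domains) *
    depth / target$total_reads
  fold <- ifelse(tgt_n > 0, ref_n / tgt_n, Inf)
  pval <- stats::ppois(floor(tgt_n), lambda = ref_n)
  status <- ifelse(ref_n <= 0, "unassigned",
                   ifelse(fold >= fold_min & pval <= p_max,
                          "lost", "retained"))
  if (any(status == "unassigned"))
    warning(sum(status == "unassigned"),
            " domain(s) with zero reference reads left unassigned")
  domains$ref_norm <- ref_n
  domains$target_norm <- tgt_n
  domains$fold <- fold
  domains$p_value <- pval
  domains$status <- status
  domains
}

#' Mark conserved domains
#'
#' A reference domain is `conserved` when it overlaps (>= 1 bp) a domain
#' called independently in the target condition and was not identified as
#' lost.  Lost domains keep their status; the remainder stay `unassigned`.
#'
#' @param domains_ref Reference domains after [call_lost_domains()] (their
#'   `status` column holds `lost`/`retained`/`unassigned`).
#' @param domains_target Domains called in the target condition.
#' @return `domains_ref` with `status` in `lost`/`conserved`/`unassigned`.
#' @export
conserved_domains <- function(domains_ref, domains_target) {
  if (!nrow(domains_ref)) return(domains_ref)
  hit <- rep(FALSE, nrow(domains_ref))
  if (nrow(domains_target)) {
    ov <- GenomicRanges::countOverlaps(as_granges(domains_ref),
                                       as_granges(domains_target))
    hit <- ov > 0
  }
  st <- domains_ref$status
  st[st != "lost"] <- ifelse(hit[st != "lost"], "conserved", "unassigned")
  domains_ref$status <- st
  domains_ref
}

#' Base-pair Jaccard index between two interval sets
#'
#' Intersection over union of genomic base pairs covered; used to compare a
#' called domain set to planted truth.
#'
#' @param a,b Interval data.frames (`chrom`, `start`, `end`).
#' @return Jaccard index in `[0, 1]` (1 when both sets are empty).
#' @export
jaccard_bp <- function(a, b) {
  if (!nrow(a) && !nrow(b)) return(1)
  if (!nrow(a) || !nrow(b)) return(0)
  ga <- GenomicRanges::reduce(as_granges(a))
  gb <- GenomicRanges::reduce(as_granges(b))
  inter <- sum(GenomicRanges::width(GenomicRanges::intersect(ga, gb)))
  uni <- sum(GenomicRanges::width(GenomicRanges::union(ga, gb)))
  inter / uni
}

#' Base pairs of `a` covered by `b`
#'
#' @param a,b Interval data.frames.
#' @return Total bp of `a` intersecting `b`.
#' @export
covered_bp <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(0)
  ga <- GenomicRanges::reduce(as_granges(a))
  gb <- GenomicRanges::reduce(as_granges(b))
  sum(GenomicRanges::width(GenomicRanges::intersect(ga, gb)))
}
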