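#' RPKM in an arbitrary genomic window
#'
#' Reads per kilobase per million mapped reads inside one window.  `x` is
#' either a raw `BinnedTrack` (border bins contribute proportionally to their
#' overlap) or a read-interval data.frame (reads counted by midpoint); the
#' library size comes from `total_reads` (track) or must be supplied.
#'
#' @param x Raw `BinnedTrack`, or interval data.frame of reads.
#' @param window One-row interval data.frame (`chrom`, `start`, `end`).
#' @param total_reads Library size; defaults to the track's `total_reads`.
#' @return RPKM value.
#' @export
rpkm_window <- function(x, window, total_reads = NULL) {
  width <- window$end - window$start
  if (width <= 0) stop("zero-length window")
  if (inherits(x, "BinnedTrack")) {
    stopifnot(x$units == "raw")
    if (is.null(total_reads)) total_reads <- x$total_reads
    count <- count_reads_in_intervals(x, window)
  } else {
    if (is.null(total_reads))
      stop("total_reads must be supplied when counting raw read intervals")
    mid <- floor((x$start + x$end) / 2)
    count <- sum(x$chrom == window$chrom & mid >= window$start &
                   mid < window$end)
  }
  if (is.na(total_reads) || total_reads <= 0)
    stop("positive total_reads required for RPKM")
  count / (width / 1000) / (total_reads / 1e6)
}

#' TSS-proximal RPKM for every gene
#'
#' Convenience wrapper applying [rpkm_window()] to the symmetric window
#' `[TSS - flank, TSS + flank)` of every gene.
#'
#' @param track Raw `BinnedTrack`.
#' @param genes Gene table (`gene_id`, `chrom`, `tss`).
#' @param flank Half-window in bp, default 500.
#' @return Named numeric vector of RPKM, one per gene.
#' @export
tss_rpkm <- function(track, genes, flank = 500) {
  out <- vapply(seq_len(nrow(genes)), function(k) {
    len <- track$genome$lengths[[genes$chrom[k]]]
    w <- data.frame(chrom = genes$chrom[k],
                    start = max(0, genes$tss[k] - flank),
                    end = min(len, genes$tss[k] + flank))
    rpkm_window(track, w)
  }, 0)
  names(out) <- genes$gene_id
  out
}

#' Does a domain lie within `flank` bp of each gene's TSS?
#'
#' @param genes Gene table (`gene_id`, `chrom`, `tss`).
#' @param domains Domain data.frame.
#' @param flank Distance in bp; the tested window is
#'   `[TSS - flank, TSS + flank]`.
#' @return Logical vector, one per gene.
#' @export
tss_domain_overlap <- function(genes, domains, flank) {
  stopifnot(flank >= 0)
  if (!nrow(domains) || !nrow(genes))
    return(rep(FALSE, nrow(genes)))
  gw <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(start = genes$tss - flank + 1,
                     end = genes$tss + flank + 1))
  GenomicRanges::countOverlaps(gw, as_granges(domains)) > 0
}

#' Select genes with SETDB1-dependent H3K9me2 and no H3K9me3
#'
#' Applies four promoter-proximal criteria, all at the TSS +/- `flank`
#' window:
#' 1. an H3K9me2 domain is present in inhibitor-treated wild type but absent
#'    in inhibitor-treated Setdb1 knockout;
#' 2. no H3K9me3 domain in any supplied condition;
#' 3. H3K9me2 RPKM above `rpkm_bound` in treated wild type and below it in
#'    the treated knockout (strict inequalities);
#' 4. H3K9me3 RPKM below `rpkm_bound` in every condition.
#'
#' @param genes Gene table.
#' @param me2_domains_wt,me2_domains_ko H3K9me2 domain sets for
#'   inhibitor-treated wild type / knockout.
#' @param me3_domains Named list of H3K9me3 domain sets, one per condition.
#' @param me2_track_wt,me2_track_ko Raw H3K9me2 tracks matching the two
#'   domain sets.
#' @param me3_tracks Named list of raw H3K9me3 tracks, one per condition.
#' @param flank TSS half-window, default 500 bp.
#' @param rpkm_bound RPKM threshold, default 1.
#' @return Data.frame of per-gene criteria plus a `selected` flag.
#' @export
select_setdb1_dependent_genes <- function(genes, me2_domains_wt,
                                          me2_domains_ko, me3_domains,
                                          me2_track_wt, me2_track_ko,
                                          me3_tracks, flank = 500,
                                          rpkm_bound = 1) {
  for (nm in c("me2_domains_wt", "me2_domains_ko", "me2_track_wt",
               "me2_track_ko"))
    if (is.null(get(nm))) stop("missing input: ", nm)
  if (!length(me3_domains) || !length(me3_tracks))
    stop("missing input: H3K9me3 domains/tracks per condition")
  if (!identical(sort(names(me3_domains)), sort(names(me3_tracks))))
    stop("H3K9me3 domain and track condition names differ")
  c1 <- tss_domain_overlap(genes, me2_domains_wt, flank) &
    !tss_domain_overlap(genes, me2_domains_ko, flank)
  me3_dom_any <- Reduce(`|`, lapply(me3_domains, function(d)
    tss_domain_overlap(genes, d, flank)))
  c2 <- !me3_dom_any
  c3 <- tss_rpkm(me2_track_wt, genes, flank) > rpkm_bound &
    tss_rpkm(me2_track_ko, genes, flank) < rpkm_bound
  me3_rpkm_max <- Reduce(pmax, lapply(me3_tracks, function(tr)
    tss_rpkm(tr, genes, flank)))
  c4 <- me3_rpkm_max < rpkm_bound
  data.frame(gene_id = genes$gene_id,
             me2_wt_not_ko = c1, no_me3_domain = c2,
             me2_rpkm_switch = c3, me3_rpkm_low = c4,
             selected = c1 & c2 & c3 & c4,
             stringsAsFactors = FALSE)
}

#' Fraction of upregulated genes with a nearby domain
#'
#' Share of upregulated genes having a domain within `flank` of the TSS,
#' with a two-proportion chi-square against the background of all genes.
#'
#' @param genes Gene table.
#' @param upregulated Logical vector (or gene-id character vector) marking
#'   upregulated genes.
#' @param domains Domain data.frame.
#' @param flank Distance in bp, default 5000.
#' @return List: `fraction`, `n_upregulated`, `background_fraction`, `test`
#'   (from [two_proportion_test()]).
#' @export
upregulated_overlap_fraction <- function(genes, upregulated, domains,
                                         flank = 5000) {
  if (is.character(upregulated))
    upregulated <- genes$gene_id %in% upregulated
  if (!any(upregulated)) stop("no upregulated genes")
  hit <- tss_domain_overlap(genes, domains, flank)
  k1 <- sum(hit[upregulated]); n1 <- sum(upregulated)
  k2 <- sum(hit); n2 <- length(hit)
  list(fraction = k1 / n1, n_upregulated = n1,
       background_fraction = k2 / n2,
       test = two_proportion_test(k1, n1, k2, n2))
}
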