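#' Fraction of each bin covered by domains
#'
#' Per fixed-width bin, the number of base pairs covered by (merged) domains
#' divided by the true bin width.
#'
#' @param domains Domain data.frame.
#' @param genome A [genome_spec()].
#' @param bin_size Bin width in bp, default 100 kb.
#' @return A `BinnedTrack` (units `zscore` slot unused; values in `[0, 1]`)
#'   — returned as a plain named list of per-chromosome numeric vectors.
#' @export
domain_fraction_per_bin <- function(domains, genome, bin_size = 1e5) {
  out <- list()
  for (chrom in genome$chroms) {
    nb <- n_bins(genome, chrom, bin_size)
    frac <- numeric(nb)
    sel <- domains$chrom == chrom
    if (any(sel)) {
      red <- GenomicRanges::reduce(as_granges(domains[sel, , drop = FALSE]))
      st <- GenomicRanges::start(red) - 1
      en <- GenomicRanges::end(red)
      for (k in seq_along(st)) {
        i0 <- floor(st[k] / bin_size) + 1
        i1 <- min(ceiling(en[k] / bin_size), nb)
        idx <- i0:i1
        ov <- pmin(idx * bin_size, en[k]) - pmax((idx - 1) * bin_size, st[k])
        frac[idx] <- frac[idx] + pmax(ov, 0)
      }
    }
    frac <- frac / bin_widths(genome, chrom, bin_size)
    out[[chrom]] <- pmin(frac, 1)
  }
  out
}

#' Join compartment scores, mark RPKM and domain fractions per bin
#'
#' One row per bin scored in both conditions: compartment score and delta,
#' RPKM and delta, domain fraction and delta, and the compartment-change
#' class.  Deltas are condition B (treated) minus condition A (untreated).
#'
#' @param scores_a,scores_b Named lists of `CompartmentTrack`s per
#'   chromosome.
#' @param rpkm_a,rpkm_b RPKM `BinnedTrack`s on the same bin grid.
#' @param frac_a,frac_b Domain-fraction lists from
#'   [domain_fraction_per_bin()].
#' @return Data.frame (`chrom`, `bin`, `score_a`, `score_b`, `dscore`,
#'   `rpkm_a`, `rpkm_b`, `drpkm`, `frac_a`, `frac_b`, `dfrac`, `change`).
#' @export
build_join_table <- function(scores_a, scores_b, rpkm_a, rpkm_b,
                             frac_a, frac_b) {
  chroms <- intersect(names(scores_a), names(scores_b))
  if (!length(chroms)) stop("no chromosomes shared between score sets")
  rows <- list()
  for (chrom in chroms) {
    sa <- scores_a[[chrom]]; sb <- scores_b[[chrom]]
    if (sa$bin_size != sb$bin_size ||
        sa$bin_size != rpkm_a$bin_size || sa$bin_size != rpkm_b$bin_size)
      stop("bin-size mismatch between compartment scores and RPKM tracks")
    chg <- classify_compartment_change(sa, sb)
    ok <- which(!sa$mask & !sb$mask)
    if (!length(ok)) next
    rows[[chrom]] <- data.frame(
      chrom = chrom, bin = ok,
      score_a = sa$score[ok], score_b = sb$score[ok],
      dscore = sb$score[ok] - sa$score[ok],
      rpkm_a = rpkm_a$values[[chrom]][ok],
      rpkm_b = rpkm_b$values[[chrom]][ok],
      drpkm = rpkm_b$values[[chrom]][ok] - rpkm_a$values[[chrom]][ok],
      frac_a = frac_a[[chrom]][ok], frac_b = frac_b[[chrom]][ok],
      dfrac = frac_b[[chrom]][ok] - frac_a[[chrom]][ok],
      change = chg$class[ok], stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}

# cut a delta into groups defined by interior edges; the top group is
# "[last_edge, Inf)" to match the published ">= 0.01" focal class
delta_groups <- function(x, edges) {
  if (is.unsorted(edges, strictly = TRUE))
    stop("edges must be strictly increasing")
  br <- c(-Inf, edges, Inf)
  labs <- c(sprintf("< %g", edges[1]),
            if (length(edges) > 1)
              sprintf("[%g, %g)", edges[-length(edges)], edges[-1]),
            sprintf(">= %g", edges[length(edges)]))
  cut(x, breaks = br, labels = labs, right = FALSE)
}

#' Summarize a response delta within groups of another delta
#'
#' Bins are grouped by one delta (e.g. compartment-score change) at the given
#' edges; the response delta (e.g. RPKM change) is summarized per group, with
#' pairwise Tukey honest-significant-difference comparisons and the focal
#' (top) group versus the rest.
#'
#' @param table Join table from [build_join_table()].
#' @param grouping Column to group on (`"dscore"` or `"dfrac"`).
#' @param response Column to summarize.
#' @param edges Strictly increasing interior edges; the top group is
#'   `>= last edge`.
#' @return List: `summary` (group, n, mean, median), `tukey` (Tukey HSD table
#'   or `NULL` when fewer than two populated groups), `focal_vs_rest`
#'   (Welch t of the top group against all others, or `NULL`).
#' @export
delta_group_summary <- function(table, grouping = "dscore",
                                response = "drpkm",
                                edges = c(-0.01, 0, 0.01)) {
  g <- delta_groups(table[[grouping]], edges)
  y <- table[[response]]
  summ <- do.call(rbind, lapply(levels(g), function(lv) {
    sel <- which(g == lv)
    data.frame(group = lv, n = length(sel),
               mean = if (length(sel)) mean(y[sel]) else NA_real_,
               median = if (length(sel)) stats::median(y[sel]) else NA_real_)
  }))
  populated <- levels(g)[table(g) > 0]
  tukey <- NULL; focal <- NULL
  if (length(populated) >= 2 && stats::var(y) > 0) {
    sub <- droplevels(data.frame(y = y, g = g)[g %in% populated, ])
    fit <- stats::aov(y ~ g, data = sub)
    tk <- stats::TukeyHSD(fit)$g
    tukey <- data.frame(comparison = rownames(tk), tk, row.names = NULL)
    top <- levels(g)[length(levels(g))]
    if (top %in% populated && sum(g == top) >= 2 &&
        sum(g != top, na.rm = TRUE) >= 2) {
      tt <- stats::t.test(y[g == top], y[g != top])
      focal <- list(group = top, t = unname(tt$statistic),
                    p.value = tt$p.value,
                    mean_focal = mean(y[g == top]),
                    mean_rest = mean(y[g != top]))
    }
  }
  list(summary = summ, tukey = tukey, focal_vs_rest = focal)
}

#' Fraction of B-to-A compartment conversions per domain-change group
#'
#' Groups bins by the change in domain fraction and reports, per group, the
#' share of bins whose compartment flipped from B to A.
#'
#' @param table Join table from [build_join_table()].
#' @param edges Interior edges on `dfrac`, default `c(-0.5, -0.25, 0)` (the
#'   focal published class is `< -0.5`).
#' @return Data.frame `group`, `n`, `b_to_a_fraction`.
#' @export
b_to_a_enrichment <- function(table, edges = c(-0.5, -0.25, 0)) {
  g <- delta_groups(table$dfrac, edges)
  out <- do.call(rbind, lapply(levels(g), function(lv) {
    sel <- which(g == lv)
    data.frame(group = lv, n = length(sel),
               b_to_a_fraction = if (length(sel))
                 mean(table$change[sel] == "B->A", na.rm = TRUE)
               else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

#' Compartment-score shift at upregulated genes
#'
#' Maps every gene to the compartment bin containing its TSS, takes the
#' per-gene score delta (condition B minus A), and tests whether upregulated
#' genes shifted more than a same-size random background sample by a
#' one-tailed two-sample Student's t test (upregulated > background).
#'
#' @param genes Gene table (`gene_id`, `chrom`, `tss`).
#' @param upregulated Logical vector or character vector of gene ids.
#' @param scores_a,scores_b Named lists of `CompartmentTrack`s.
#' @param seed Seed for the background sample (recorded in the output).
#' @param n_background Background sample size; defaults to the upregulated
#'   count.
#' @return List: `mean_upregulated`, `mean_background`, `t`, `p.value`,
#'   `n_up`, `n_bg`, `seed`.  Genes in unscored bins are dropped with a
#'   warning.
#' @export
gene_compartment_shift <- function(genes, upregulated, scores_a, scores_b,
                                   seed = 17, n_background = NULL) {
  if (is.character(upregulated))
    upregulated <- genes$gene_id %in% upregulated
  dsc <- rep(NA_real_, nrow(genes))
  for (chrom in intersect(unique(genes$chrom), names(scores_a))) {
    sel <- which(genes$chrom == chrom)
    bin <- floor(genes$tss[sel] / scores_a[[chrom]]$bin_size) + 1
    ok <- bin >= 1 & bin <= length(scores_a[[chrom]]$score)
    dsc[sel[ok]] <- scores_b[[chrom]]$score[bin[ok]] -
      scores_a[[chrom]]$score[bin[ok]]
  }
  dropped <- sum(upregulated & !is.finite(dsc))
  if (dropped > 0)
    warning(dropped, " upregulated gene(s) in unscored bins dropped")
  up_d <- dsc[upregulated & is.finite(dsc)]
  pool <- which(!upregulated & is.finite(dsc))
  if (length(up_d) < 2 || length(pool) < 2)
    stop("need at least two scored genes in each group")
  if (is.null(n_background)) n_background <- length(up_d)
  n_background <- min(n_background, length(pool))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  bg_d <- dsc[sample(pool, n_background)]
  tt <- stats::t.test(up_d, bg_d, alternative = "greater",
                      var.equal = TRUE)
  list(mean_upregulated = mean(up_d), mean_background = mean(bg_d),
       t = unname(tt$statistic), p.value = tt$p.value,
       n_up = length(up_d), n_bg = length(bg_d), seed = seed)
}

# save/restore the RNG state so seeded sampling inside a function does not
# perturb the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv())
}
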