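#' Configuration of the synthetic genome generator
#'
#' The generator emulates ChIP-seq, Hi-C, recovery time-course and
#' expression data for a contiguous multi-chromosome slice of a large
#' (2.7-Gb-scale) genome sequenced at a realistic library size.  Bin counts
#' are desk-scale; `library_size` carries the full-library depth so RPKM and
#' depth normalization operate on the published scale.
#'
#' @param seed Master seed; every stream is derived from it.
#' @param chrom_lengths Named chromosome lengths (bp).
#' @param chip_bin,hic_bin,recovery_bin Bin widths for ChIP counts, Hi-C and
#'   the recovery time course.
#' @param block_mean Mean A/B compartment block length (bp); must be at
#'   least `hic_bin`.
#' @param lambda_d,lambda_e Poisson mean per `chip_bin` in depleted /
#'   enriched (broad-domain) states at the reference library size.
#' @param lambda_promoter Poisson mean per `chip_bin` for promoter-planted
#'   marks (strong, RPKM ~2 at 30 M reads).
#' @param satellite_len Length (bp) of the pericentromeric satellite block
#'   planted on each chromosome (0 disables); its read pileup saturates the
#'   downstream count cap.
#' @param satellite_rate Poisson mean per `chip_bin` inside satellite.
#' @param library_size Reference library size (mapped reads).
#' @param p_dom_A,p_dom_B Target broad-domain coverage per compartment.
#' @param domain_mean_bins,domain_min_bins Planted domain length
#'   distribution (chip bins).
#' @param strength_jitter Half-width of the per-domain enrichment multiplier
#'   (uniform in `1 +/- strength_jitter`); 0 disables.
#' @param retention Matrix (conditions x compartments A,B) of per-domain
#'   retention probabilities, emulating compartment-dependent removal by the
#'   G9a/GLP inhibitor and Setdb1 knockout.
#' @param alpha Contact distance-decay exponent.
#' @param delta Same-compartment contact boost.
#' @param contact_depth Expected contacts at distance one bin.
#' @param flip_drop Domain-fraction drop (per hic bin) beyond which a B bin
#'   may convert to A in that condition.
#' @param p_flip Conversion probability given a qualifying drop.
#' @param n_genes Number of genes.
#' @param p_gene_setdb1 Share of genes planted with SETDB1-dependent
#'   promoter H3K9me2 (and no H3K9me3).
#' @param p_gene_me3 Share of genes planted with promoter H3K9me3 (on top of
#'   the same H3K9me2 switch, so only criterion 2/4 rejects them).
#' @param p_up_null Baseline upregulation probability of any gene.
#' @param coupling_up Additional upregulation probability when the gene's
#'   promoter or covering domain is lost in the contrast condition; 0 gives
#'   the null world for calibration.
#' @param lfc_up_mean,lfc_up_sd,lfc_null_sd log2 fold-change distribution
#'   for upregulated / unchanged genes.
#' @param onset_probs Probabilities of middle/late/none onset for
#'   recovering bins not adjacent to residual domains.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       chrom_lengths = c(chr1 = 20e6, chr2 = 20e6,
                                         chr3 = 20e6),
                       chip_bin = 2000, hic_bin = 1e5, recovery_bin = 1e4,
                       block_mean = 2e6,
                       lambda_d = 2, lambda_e = 30, lambda_promoter = 120,
                       satellite_len = 100e3, satellite_rate = 200,
                       library_size = 30e6,
                       p_dom_A = 0.45, p_dom_B = 0.85,
                       domain_mean_bins = 20, domain_min_bins = 10,
                       strength_jitter = 0.3,
                       retention = NULL,
                       alpha = 1, delta = 0.5, contact_depth = 100,
                       flip_drop = 0.5, p_flip = 0.8,
                       n_genes = 400, p_gene_setdb1 = 0.12,
                       p_gene_me3 = 0.08,
                       p_up_null = 0.02, coupling_up = 0.78,
                       lfc_up_mean = 4, lfc_up_sd = 1, lfc_null_sd = 0.3,
                       onset_probs = c(middle = 0.45, late = 0.45,
                                       none = 0.10)) {
  if (is.null(retention))
    retention <- matrix(c(1, 1,        # WT keeps everything
                          0.40, 0.70,  # inhibitor: B more resistant
                          0.85, 1.00,  # Setdb1 KO alone: slight A loss
                          0.02, 0.45), # inhibitor + Setdb1 KO
                        nrow = 4, byrow = TRUE,
                        dimnames = list(c("WT", "UNC", "KO", "UNC_KO"),
                                        c("A", "B")))
  if (block_mean < hic_bin)
    stop("compartment block length must be at least the Hi-C bin size")
  stopifnot(lambda_e > lambda_d, alpha > 0,
            all(retention >= 0 & retention <= 1),
            p_dom_A >= 0, p_dom_A <= 1, p_dom_B >= 0, p_dom_B <= 1)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# deterministic sub-seed for a named stream; keeps everything below 2^31
sub_seed <- function(seed, tag) {
  (seed * 1009 + sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))) %% 2147483647
}

#' Simulate a genome with planted compartments and domains
#'
#' Draws alternating A/B compartment blocks (exponential lengths rounded to
#' the Hi-C grid), plants broad enriched domains at compartment-dependent
#' coverage, plants one satellite block per chromosome, draws per-condition
#' domain retention, and derives per-condition compartment labels including
#' the coupled B-to-A conversions where domain coverage collapses.
#' Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return A `sim_truth` list: `genome`, `labels` (per-chromosome A/B per
#'   hic bin, baseline), `labels_cond` (per condition, after coupled flips),
#'   `domains` (planted domains with per-condition retention), `satellite`,
#'   `flipped` (per condition, logical per hic bin), `config`.
#' @export
simulate_genome <- function(config) {
  set.seed(sub_seed(config$seed, "genome"))
  genome <- genome_spec(config$chrom_lengths)
  conds <- rownames(config$retention)
  labels <- list(); satellite <- list(); doms <- list()
  for (chrom in genome$chroms) {
    len <- genome$lengths[[chrom]]
    nb_hic <- ceiling(len / config$hic_bin)
    # compartment blocks
    lab <- character(0)
    cur <- sample(c("A", "B"), 1)
    while (length(lab) < nb_hic) {
      bl <- max(1, round(stats::rexp(1, 1 / config$block_mean) /
                           config$hic_bin))
      # real chromosomes always carry both compartments: cap the first
      # block so at least one boundary falls on the chromosome
      if (!length(lab)) bl <- min(bl, max(1, floor(0.6 * nb_hic)))
      lab <- c(lab, rep(cur, bl))
      cur <- if (cur == "A") "B" else "A"
    }
    labels[[chrom]] <- lab[seq_len(nb_hic)]
    # satellite block at 40% of the chromosome
    if (config$satellite_len > 0) {
      s0 <- floor(0.4 * len / config$chip_bin) * config$chip_bin
      satellite[[chrom]] <- data.frame(
        chrom = chrom, start = s0,
        end = min(s0 + config$satellite_len, len))
    }
    # domain tiling at base coverage, thinned per compartment
    p_base <- max(config$p_dom_A, config$p_dom_B, 1e-6)
    dom_mean <- config$domain_mean_bins
    gap_mean <- max(1, dom_mean * (1 - p_base) / p_base)
    nb_chip <- floor(len / config$chip_bin)
    pos <- 1 + stats::rgeom(1, 1 / gap_mean)
    st <- integer(0); en <- integer(0)
    while (pos <= nb_chip) {
      dl <- config$domain_min_bins +
        stats::rgeom(1, 1 / max(1, dom_mean - config$domain_min_bins + 1))
      d_end <- min(pos + dl - 1, nb_chip)
      st <- c(st, pos); en <- c(en, d_end)
      pos <- d_end + 1 + 1 + stats::rgeom(1, 1 / gap_mean)
    }
    if (length(st)) {
      mid_bp <- (st + en - 1) / 2 * config$chip_bin
      comp <- labels[[chrom]][pmin(floor(mid_bp / config$hic_bin) + 1,
                                   nb_hic)]
      p_keep <- ifelse(comp == "A", config$p_dom_A, config$p_dom_B) / p_base
      keep <- stats::runif(length(st)) < p_keep
      st <- st[keep]; en <- en[keep]; comp <- comp[keep]
    }
    d <- data.frame(chrom = chrom,
                    start = (st - 1) * config$chip_bin,
                    end = en * config$chip_bin,
                    compartment = comp, stringsAsFactors = FALSE)
    # drop domains inside the satellite block
    if (!is.null(satellite[[chrom]]) && nrow(d)) {
      s <- satellite[[chrom]]
      d <- d[d$end <= s$start | d$start >= s$end, , drop = FALSE]
    }
    doms[[chrom]] <- d
  }
  domains <- do.call(rbind, doms)
  rownames(domains) <- NULL
  if (is.null(domains)) domains <- data.frame(
    chrom = character(), start = numeric(), end = numeric(),
    compartment = character())
  n <- nrow(domains)
  domains$strength <- if (config$strength_jitter > 0 && n)
    stats::runif(n, 1 - config$strength_jitter, 1 + config$strength_jitter)
  else rep(1, n)
  for (cond in conds)
    domains[[paste0("retained_", cond)]] <-
      stats::runif(n) < config$retention[cond,
                                         ifelse(domains$compartment == "A",
                                                "A", "B")]
  satellite <- if (length(satellite)) do.call(rbind, satellite) else
    data.frame(chrom = character(), start = numeric(), end = numeric())
  rownames(satellite) <- NULL
  truth <- structure(
    list(genome = genome, labels = labels, domains = domains,
         satellite = satellite, config = config),
    class = "sim_truth")
  # coupled per-condition labels: B bins losing most domain coverage flip
  truth$labels_cond <- list(); truth$flipped <- list()
  for (cond in conds) {
    lc <- labels; fl <- list()
    for (chrom in genome$chroms) {
      cov_wt <- planted_coverage(truth, "WT", chrom, config$hic_bin)
      cov_c <- planted_coverage(truth, cond, chrom, config$hic_bin)
      drop <- cov_wt - cov_c
      isB <- labels[[chrom]] == "B"
      flip <- isB & drop > config$flip_drop &
        stats::runif(length(isB)) < config$p_flip
      lc[[chrom]][flip] <- "A"
      fl[[chrom]] <- flip
    }
    truth$labels_cond[[cond]] <- lc
    truth$flipped[[cond]] <- fl
  }
  truth
}

#' Planted domains of one condition
#'
#' @param truth A `sim_truth`.
#' @param condition Condition name (a row of the retention matrix).
#' @return Interval data.frame of domains retained in that condition.
#' @export
planted_domains <- function(truth, condition) {
  col <- paste0("retained_", condition)
  if (!col %in% names(truth$domains))
    stop("unknown condition: ", condition)
  truth$domains[truth$domains[[col]], c("chrom", "start", "end",
                                        "compartment", "strength")]
}

# fraction of each hic bin covered by the condition's planted domains
planted_coverage <- function(truth, condition, chrom, bin_size) {
  d <- planted_domains(truth, condition)
  d <- d[d$chrom == chrom, , drop = FALSE]
  nb <- ceiling(truth$genome$lengths[[chrom]] / bin_size)
  cov <- numeric(nb)
  for (k in seq_len(nrow(d))) {
    i0 <- floor(d$start[k] / bin_size) + 1
    i1 <- min(ceiling(d$end[k] / bin_size), nb)
    idx <- i0:i1
    ov <- pmin(idx * bin_size, d$end[k]) -
      pmax((idx - 1) * bin_size, d$start[k])
    cov[idx] <- cov[idx] + pmax(ov, 0)
  }
  pmin(cov / bin_size, 1)
}

# per chip-bin Poisson rate for one condition and mark, at the reference
# library size
chip_rates <- function(truth, condition, mark = "me2") {
  cfg <- truth$config
  rates <- list()
  for (chrom in truth$genome$chroms) {
    nb <- n_bins(truth$genome, chrom, cfg$chip_bin)
    r <- rep(cfg$lambda_d, nb)
    if (mark == "me2") {
      d <- planted_domains(truth, condition)
      d <- d[d$chrom == chrom, , drop = FALSE]
      for (k in seq_len(nrow(d))) {
        i0 <- d$start[k] / cfg$chip_bin + 1
        i1 <- min(d$end[k] / cfg$chip_bin, nb)
        r[i0:i1] <- cfg$lambda_e * d$strength[k]
      }
    }
    # promoter-planted marks (if genes simulated)
    pd <- truth[[paste0(mark, "_promoter_domains")]]
    if (!is.null(pd) && nrow(pd)) {
      p <- pd[pd$chrom == chrom & pd[[paste0("present_", condition)]], ,
              drop = FALSE]
      for (k in seq_len(nrow(p))) {
        i0 <- floor(p$start[k] / cfg$chip_bin) + 1
        i1 <- min(ceiling(p$end[k] / cfg$chip_bin), nb)
        r[i0:i1] <- cfg$lambda_promoter
      }
    }
    # satellite pileup (both marks accumulate repeat reads)
    s <- truth$satellite[truth$satellite$chrom == chrom, , drop = FALSE]
    if (nrow(s)) {
      i0 <- floor(s$start / cfg$chip_bin) + 1
      i1 <- min(ceiling(s$end / cfg$chip_bin), nb)
      r[i0:i1] <- cfg$satellite_rate
    }
    rates[[chrom]] <- r
  }
  rates
}

#' Simulate a binned ChIP-seq count track
#'
#' Per-bin Poisson counts: `lambda_e` (times the per-domain strength) inside
#' the condition's retained domains, `lambda_d` outside, promoter rates at
#' planted promoter marks, and the satellite pileup.  Rates scale linearly
#' with `library_size` relative to the reference library.
#'
#' @param truth A `sim_truth` (after [simulate_genes()] if promoter-planted
#'   marks are wanted).
#' @param condition Condition name.
#' @param mark `"me2"` (broad domains) or `"me3"` (promoter-only).
#' @param library_size Library depth; default the reference depth.
#' @return A raw `BinnedTrack` at `chip_bin` with `total_reads =
#'   library_size`.
#' @export
simulate_chip <- function(truth, condition, mark = "me2",
                          library_size = NULL) {
  cfg <- truth$config
  if (is.null(library_size)) library_size <- cfg$library_size
  set.seed(sub_seed(cfg$seed, paste("chip", condition, mark,
                                    round(library_size / 1e5))))
  scale <- library_size / cfg$library_size
  rates <- chip_rates(truth, condition, mark)
  values <- lapply(rates, function(r) stats::rpois(length(r), r * scale))
  binned_track(lapply(values, as.numeric), truth$genome, cfg$chip_bin,
               units = "raw", total_reads = library_size)
}

#' Simulate an intrachromosomal Hi-C contact matrix
#'
#' Expected contacts `contact_depth * max(|i-j|,1)^(-alpha) * (1 + delta)`
#' for same-compartment pairs (under the condition's labels, including
#' coupled B-to-A flips) and without the boost otherwise; counts are Poisson
#' and symmetric.
#'
#' @param truth A `sim_truth`.
#' @param condition Condition name.
#' @param chrom Chromosome.
#' @return A raw `ContactMatrix` at `hic_bin`.
#' @export
simulate_contacts <- function(truth, condition, chrom) {
  cfg <- truth$config
  set.seed(sub_seed(cfg$seed, paste("hic", condition, chrom)))
  lab <- truth$labels_cond[[condition]][[chrom]]
  n <- length(lab)
  d <- abs(outer(seq_len(n), seq_len(n), `-`))
  E <- cfg$contact_depth * pmax(d, 1)^(-cfg$alpha) *
    (1 + cfg$delta * outer(lab, lab, `==`))
  up <- upper.tri(E, diag = TRUE)
  counts <- matrix(0, n, n)
  counts[up] <- stats::rpois(sum(up), E[up])
  counts <- counts + t(counts) - diag(diag(counts))
  contact_matrix(counts, chrom, cfg$hic_bin,
                 partial_bin = truth$genome$lengths[[chrom]] %%
                   cfg$hic_bin != 0)
}

#' Simulate the recovery time course
#'
#' Tracks at 0-72 h after inhibitor withdrawal, on the recovery bin grid.
#' Bins overlapping residual (inhibitor-retained) domains recover first
#' (onset 24 h); other bins with recoverable domain material draw a
#' middle/late/none onset; recovery follows a logistic ramp over ~8 h.
#' Domain strength jitter is ignored here (full-strength domains) so the
#' planted classes separate cleanly.
#'
#' @param truth A `sim_truth`.
#' @param times Sampling times in hours.
#' @return List: `tracks` (named by hour, raw `BinnedTrack`s), `wt_track`
#'   (untreated reference), `classes` (planted class per autosomal bin, in
#'   track order), `onset` (hours, `Inf` for none).
#' @export
simulate_recovery <- function(truth,
                              times = c(0, 24, 32, 40, 48, 56, 64, 72)) {
  cfg <- truth$config
  set.seed(sub_seed(cfg$seed, "recovery"))
  bs <- cfg$recovery_bin
  lam_scale <- bs / cfg$chip_bin            # chip-bin rates per recovery bin
  excess <- cfg$lambda_e - cfg$lambda_d
  classes <- list(); onset <- list(); base <- list(); full <- list()
  rec <- list()
  for (chrom in truth$genome$chroms) {
    cov_wt <- planted_coverage(truth, "WT", chrom, bs)
    cov_res <- planted_coverage(truth, "UNC", chrom, bs)
    cov_rec <- pmax(cov_wt - cov_res, 0)
    nb <- length(cov_wt)
    on <- rep(Inf, nb)
    cl <- rep("none", nb)
    recovering <- cov_rec >= 0.2 - 1e-9
    near_res <- cov_res > 0
    cl[recovering & near_res] <- "early"
    on[recovering & near_res] <- 24
    rest <- which(recovering & !near_res)
    if (length(rest)) {
      pick <- sample(names(cfg$onset_probs), length(rest), replace = TRUE,
                     prob = cfg$onset_probs)
      cl[rest] <- pick
      on[rest] <- c(middle = 40, late = 64, none = Inf)[pick]
    }
    # bins with only one-fifth of recoverable material sit on domain edges;
    # their z excursion is intrinsically borderline, so the planted class is
    # marked ambiguous (they still ramp with their drawn onset)
    cl[recovering & cov_rec < 0.4 - 1e-9 & is.finite(on)] <- "ambiguous"
    base_rate <- lam_scale * (cfg$lambda_d + cov_res * excess)
    full_excess <- lam_scale * cov_rec * excess
    # satellite pileup persists at every time point
    s <- truth$satellite[truth$satellite$chrom == chrom, , drop = FALSE]
    if (nrow(s)) {
      i0 <- floor(s$start / bs) + 1
      i1 <- min(ceiling(s$end / bs), nb)
      base_rate[i0:i1] <- lam_scale * cfg$satellite_rate
      full_excess[i0:i1] <- 0
      cl[i0:i1] <- "none"; on[i0:i1] <- Inf
    }
    classes[[chrom]] <- cl; onset[[chrom]] <- on
    base[[chrom]] <- base_rate; rec[[chrom]] <- full_excess
    full[[chrom]] <- lam_scale * (cfg$lambda_d + cov_wt * excess)
  }
  make_track <- function(rates) {
    binned_track(lapply(rates, function(r)
      as.numeric(stats::rpois(length(r), r))),
      truth$genome, bs, units = "raw", total_reads = cfg$library_size)
  }
  tracks <- list()
  for (t in times) {
    rates <- lapply(truth$genome$chroms, function(chrom) {
      ramp <- stats::plogis((t - onset[[chrom]] - 4) / 2)
      ramp[!is.finite(onset[[chrom]])] <- 0
      base[[chrom]] + rec[[chrom]] * ramp
    })
    names(rates) <- truth$genome$chroms
    tracks[[as.character(t)]] <- make_track(rates)
  }
  list(tracks = tracks, wt_track = make_track(full),
       classes = unlist(classes[autosomes(truth$genome)],
                        use.names = FALSE),
       onset = unlist(onset[autosomes(truth$genome)], use.names = FALSE))
}

#' Simulate genes, promoter-planted marks and differential expression
#'
#' Places TSSs uniformly (outside satellite blocks), assigns gene classes
#' (SETDB1-dependent promoter H3K9me2, promoter-H3K9me3-marked, neutral),
#' plants the corresponding promoter mark intervals per condition, and draws
#' upregulation: every gene whose promoter mark or covering broad domain is
#' lost in a contrast condition is upregulated with probability `p_up_null +
#' coupling_up`; all other genes with probability `p_up_null`.
#'
#' @param truth A `sim_truth` from [simulate_genome()].
#' @param contrasts Conditions contrasted against WT.
#' @return The `sim_truth` augmented with `genes`, `me2_promoter_domains`,
#'   `me3_promoter_domains` and `de_table` (long TSV-ready data.frame).
#' @export
simulate_genes <- function(truth, contrasts = c("UNC", "KO", "UNC_KO")) {
  cfg <- truth$config
  set.seed(sub_seed(cfg$seed, "genes"))
  genome <- truth$genome
  tot <- sum(genome$lengths)
  n <- cfg$n_genes
  chrom <- sample(genome$chroms, n, replace = TRUE,
                  prob = genome$lengths / tot)
  tss <- floor(stats::runif(n, 2000, genome$lengths[chrom] - 2000))
  # keep TSSs out of satellite blocks
  for (k in seq_len(nrow(truth$satellite))) {
    s <- truth$satellite[k, ]
    bad <- which(chrom == s$chrom & tss >= s$start - 2000 &
                   tss < s$end + 2000)
    tss[bad] <- (tss[bad] + cfg$satellite_len + 4000) %%
      (genome$lengths[chrom[bad]] - 4000) + 2000
  }
  cls <- sample(c("setdb1_dep", "me3_marked", "neutral"), n, replace = TRUE,
                prob = c(cfg$p_gene_setdb1, cfg$p_gene_me3,
                         1 - cfg$p_gene_setdb1 - cfg$p_gene_me3))
  # promoter-marked genes live outside broad planted domains: their promoter
  # methylation is specifically SETDB1-dependent, not broad-domain context
  wt_dom <- truth$domains[truth$domains$retained_WT, , drop = FALSE]
  clear_of <- function(ch, pos) {
    sel <- wt_dom$chrom == ch
    ssel <- truth$satellite$chrom == ch
    !any(pos > wt_dom$start[sel] - 3000 & pos < wt_dom$end[sel] + 3000) &&
      !any(pos > truth$satellite$start[ssel] - 3000 &
             pos < truth$satellite$end[ssel] + 3000)
  }
  for (i in which(cls != "neutral")) {
    tries <- 0
    while (!clear_of(chrom[i], tss[i]) && tries < 200) {
      tss[i] <- floor(stats::runif(1, 2000,
                                   genome$lengths[chrom[i]] - 2000))
      tries <- tries + 1
    }
  }
  genes <- data.frame(gene_id = sprintf("gene_%04d", seq_len(n)),
                      chrom = chrom,
                      strand = sample(c("+", "-"), n, replace = TRUE),
                      tss = tss, class = cls, stringsAsFactors = FALSE)
  # promoter H3K9me2: present in WT/UNC/KO, lost in UNC_KO (SETDB1-dependent)
  marked <- genes$class %in% c("setdb1_dep", "me3_marked")
  me2p <- data.frame(chrom = genes$chrom[marked],
                     start = pmax(genes$tss[marked] - 1000, 0),
                     end = genes$tss[marked] + 1000,
                     gene_id = genes$gene_id[marked],
                     stringsAsFactors = FALSE)
  for (cond in rownames(cfg$retention))
    me2p[[paste0("present_", cond)]] <- cond != "UNC_KO"
  # promoter H3K9me3: me3-class genes, present in every condition
  m3 <- genes$class == "me3_marked"
  me3p <- data.frame(chrom = genes$chrom[m3],
                     start = pmax(genes$tss[m3] - 1000, 0),
                     end = genes$tss[m3] + 1000,
                     gene_id = genes$gene_id[m3], stringsAsFactors = FALSE)
  for (cond in rownames(cfg$retention))
    me3p[[paste0("present_", cond)]] <- TRUE
  truth$me2_promoter_domains <- me2p
  truth$me3_promoter_domains <- me3p
  # differential expression per contrast
  de <- list()
  for (cond in contrasts) {
    prom_lost <- genes$gene_id %in%
      me2p$gene_id[!me2p[[paste0("present_", cond)]]]
    dom_lost_iv <- truth$domains[
      truth$domains$retained_WT & !truth$domains[[paste0("retained_",
                                                         cond)]], ,
      drop = FALSE]
    in_lost <- tss_domain_overlap(genes, dom_lost_iv, flank = 0)
    loss <- prom_lost | in_lost
    p_up <- ifelse(loss, cfg$p_up_null + cfg$coupling_up, cfg$p_up_null)
    up <- stats::runif(n) < p_up
    lfc <- ifelse(up, stats::rnorm(n, cfg$lfc_up_mean, cfg$lfc_up_sd),
                  stats::rnorm(n, 0, cfg$lfc_null_sd))
    de[[cond]] <- data.frame(gene_id = genes$gene_id, contrast = cond,
                             log2fc = lfc,
                             de_flag = ifelse(up, "upregulated", "ns"),
                             planted_loss = loss, stringsAsFactors = FALSE)
  }
  truth$genes <- genes
  truth$de_table <- do.call(rbind, de)
  rownames(truth$de_table) <- NULL
  truth
}
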