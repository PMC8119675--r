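test_that("domain fraction per bin is an exact coverage ratio", {
  gs <- tiny_genome(3e5)
  d <- data.frame(chrom = "chr1", start = 20000, end = 66000)  # 46 kb in bin 1
  fr <- domain_fraction_per_bin(d, gs, 1e5)
  expect_equal(fr$chr1, c(0.46, 0, 0))
  # bounds and additivity
  d2 <- data.frame(chrom = "chr1",
                   start = c(0, 100000, 250000, 2e5),
                   end = c(10000, 200000, 260000, 2.1e5))
  fr2 <- domain_fraction_per_bin(d2, gs, 1e5)
  expect_equal(fr2$chr1, c(0.1, 1, 0.2))
  expect_true(all(unlist(fr2) >= 0 & unlist(fr2) <= 1))
  # sum over bins equals total merged bp / bin size
  merged_bp <- 10000 + 100000 + 20000
  expect_equal(sum(fr2$chr1) * 1e5, merged_bp)
  expect_equal(domain_fraction_per_bin(d[0, ], gs, 1e5)$chr1, c(0, 0, 0))
})

test_that("join table propagates masks and computes deltas", {
  gs <- tiny_genome(3e5)
  mk_score <- function(score) structure(
    list(chrom = "chr1", bin_size = 1e5, score = score,
         mask = is.na(score), orientation_reference = "x"),
    class = "CompartmentTrack")
  sa <- list(chr1 = mk_score(c(-0.4, 0.2, NA)))
  sb <- list(chr1 = mk_score(c(-0.4, -0.1, 0.3)))
  rp <- function(v) binned_track(list(chr1 = v), gs, 1e5, "rpkm",
                                 total_reads = 1e6)
  fr <- list(chr1 = c(0.5, 0.4, 0.2))
  tab <- build_join_table(sa, sb, rp(c(2, 1, 3)), rp(c(2, 0.5, 3)),
                          fr, list(chr1 = c(0.5, 0.1, 0.2)))
  expect_equal(nrow(tab), 2)            # masked bin 3 excluded
  expect_equal(tab$dscore, c(0, -0.3))
  expect_equal(tab$drpkm, c(0, -0.5))
  expect_equal(tab$dfrac, c(0, -0.3))
  expect_equal(tab$change, c("B->B", "A->B"))
})

test_that("delta grouping uses the published focal edges", {
  x <- c(-0.5, -0.005, 0.004, 0.02, 0.01)
  g <- domainscape:::delta_groups(x, c(-0.01, 0, 0.01))
  expect_equal(levels(g),
               c("< -0.01", "[-0.01, 0)", "[0, 0.01)", ">= 0.01"))
  expect_equal(as.character(g),
               c("< -0.01", "[-0.01, 0)", "[0, 0.01)", ">= 0.01",
                 ">= 0.01"))
  expect_error(domainscape:::delta_groups(x, c(0, 0)), "increasing")
})

test_that("group summaries handle degenerate and planted-coupling cases", {
  tab <- data.frame(dscore = rep(0.02, 5), drpkm = rep(1, 5))
  out <- delta_group_summary(tab, "dscore", "drpkm")
  expect_equal(sum(out$summary$n > 0), 1)  # single populated group
  expect_null(out$tukey)                   # tests skipped
  # planted negative coupling: the top group has the lowest response mean
  set.seed(31)
  n <- 400
  dscore <- c(rnorm(n / 2, 0, 0.004), rnorm(n / 2, 0.05, 0.01))
  drpkm <- ifelse(dscore >= 0.01, rnorm(n, -2, 0.3), rnorm(n, 0, 0.3))
  tab2 <- data.frame(dscore = dscore, drpkm = drpkm)
  out2 <- delta_group_summary(tab2, "dscore", "drpkm")
  s <- out2$summary[out2$summary$n > 0, ]
  expect_equal(s$group[which.min(s$mean)], ">= 0.01")
  expect_false(is.null(out2$tukey))
  expect_lt(out2$focal_vs_rest$p.value, 1e-6)
})

test_that("B-to-A enrichment is reported per domain-change group", {
  tab <- data.frame(
    dfrac = c(rep(-0.6, 10), rep(0.1, 5)),
    change = c(rep("B->A", 2), rep("B->B", 8), rep("A->A", 5)))
  out <- b_to_a_enrichment(tab)
  expect_equal(out$b_to_a_fraction[out$group == "< -0.5"], 0.2)
  expect_equal(out$b_to_a_fraction[out$group == ">= 0"], 0)
  expect_equal(out$n, c(10, 0, 0, 5))
})

test_that("gene compartment shift is one-tailed with a seeded background", {
  gs_len <- 2e6
  mk_score <- function(score) structure(
    list(chrom = "chr1", bin_size = 1e5, score = score,
         mask = rep(FALSE, length(score)), orientation_reference = "x"),
    class = "CompartmentTrack")
  set.seed(4)
  base <- rnorm(20, 0, 0.05)
  up_bins <- 1:8
  shift <- rep(0, 20); shift[up_bins] <- 0.05
  sa <- list(chr1 = mk_score(base))
  sb <- list(chr1 = mk_score(base + shift + rnorm(20, 0, 0.005)))
  genes <- data.frame(gene_id = paste0("g", 1:40), chrom = "chr1",
                      strand = "+",
                      tss = (rep(0:19, 2)) * 1e5 + 50000)
  up <- genes$tss < 8e5      # genes in the shifted bins
  res <- gene_compartment_shift(genes, up, sa, sb, seed = 7)
  expect_gt(res$mean_upregulated, res$mean_background)
  expect_lt(res$p.value, 0.05)
  # the reported t and p match the closed form on the same seeded sample
  dsc <- sb$chr1$score[floor(genes$tss / 1e5) + 1] -
    sa$chr1$score[floor(genes$tss / 1e5) + 1]
  set.seed(7)
  bg <- dsc[sample(which(!up), sum(up))]
  x <- dsc[up]
  sp <- sqrt(((length(x) - 1) * var(x) + (length(bg) - 1) * var(bg)) /
               (length(x) + length(bg) - 2))
  t_closed <- (mean(x) - mean(bg)) / (sp * sqrt(1 / length(x) +
                                                  1 / length(bg)))
  p_closed <- pt(t_closed, df = length(x) + length(bg) - 2,
                 lower.tail = FALSE)
  expect_equal(res$t, t_closed, tolerance = 1e-10)
  expect_equal(res$p.value, p_closed, tolerance = 1e-10)
  # flipping the direction flips the tail
  res_flip <- gene_compartment_shift(genes, !up, sa, sb, seed = 7)
  expect_gt(res_flip$p.value, 0.5)
})
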