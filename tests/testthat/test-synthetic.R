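test_that("simulation is fully deterministic given the seed", {
  cfg <- sim_config(seed = 9, chrom_lengths = c(chr1 = 8e6, chr2 = 8e6))
  t1 <- simulate_genes(simulate_genome(cfg))
  t2 <- simulate_genes(simulate_genome(cfg))
  expect_identical(t1$domains, t2$domains)
  expect_identical(t1$labels, t2$labels)
  expect_identical(t1$de_table, t2$de_table)
  expect_identical(simulate_chip(t1, "WT")$values,
                   simulate_chip(t2, "WT")$values)
  expect_identical(simulate_contacts(t1, "WT", "chr1")$mat,
                   simulate_contacts(t2, "WT", "chr1")$mat)
  # written datasets are byte-identical
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_dataset(t1, d1, conditions = "WT")
  simulate_dataset(t2, d2, conditions = "WT")
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
})

test_that("planted domain coverage matches the compartment targets", {
  cfg <- sim_config(seed = 10, satellite_len = 0)
  truth <- simulate_genome(cfg)
  d <- truth$domains
  for (comp in c("A", "B")) {
    comp_bp <- sum(vapply(truth$genome$chroms, function(ch)
      sum(truth$labels[[ch]] == comp) * cfg$hic_bin, 0))
    cov <- sum((d$end - d$start)[d$compartment == comp]) / comp_bp
    target <- if (comp == "A") cfg$p_dom_A else cfg$p_dom_B
    expect_lt(abs(cov - target), 0.05)   # within 5 points at 60 Mb
  }
  # no A-compartment domains when p_dom_A is zero
  cfg0 <- sim_config(seed = 10, p_dom_A = 0, satellite_len = 0)
  t0 <- simulate_genome(cfg0)
  expect_equal(sum(t0$domains$compartment == "A"), 0)
  # compartment blocks shorter than the Hi-C bin are rejected
  expect_error(sim_config(block_mean = 5e4), "block length")
})

test_that("chip counts follow the planted Poisson field", {
  cfg <- sim_config(seed = 12, chrom_lengths = c(chr1 = 10e6),
                    satellite_len = 0, strength_jitter = 0)
  truth <- simulate_genome(cfg)
  # a condition retaining nothing is indistinguishable from background
  truth$domains$retained_UNC_KO <- FALSE
  tr <- simulate_chip(truth, "UNC_KO")
  x <- tr$values$chr1
  expect_lt(abs(mean(x) - cfg$lambda_d), 0.1)
  gof <- suppressWarnings(chisq.test(table(factor(pmin(x, 8), 0:8)),
                    p = c(dpois(0:7, cfg$lambda_d),
                          ppois(7, cfg$lambda_d, lower.tail = FALSE))))
  expect_gt(gof$p.value, 0.001)
  # doubling depth doubles the expected totals
  lo <- simulate_chip(truth, "WT", library_size = 15e6)
  hi <- simulate_chip(truth, "WT", library_size = 30e6)
  expect_lt(abs(sum(unlist(hi$values)) / sum(unlist(lo$values)) - 2),
            0.05)
  expect_equal(lo$total_reads, 15e6)
  # contact matrices are symmetric by construction
  m <- simulate_contacts(truth, "WT", "chr1")
  expect_identical(m$mat, t(m$mat))
})

test_that("recovery time course starts at the inhibitor state", {
  cfg <- sim_config(seed = 13, chrom_lengths = c(chr1 = 10e6))
  truth <- simulate_genome(cfg)
  rec <- simulate_recovery(truth)
  expect_named(rec$tracks, c("0", "24", "32", "40", "48", "56", "64",
                             "72"))
  # time 0 matches the inhibitor-condition rate field in distribution
  unc <- simulate_chip(truth, "UNC")
  t0_mean <- mean(unlist(rec$tracks[["0"]]$values))
  unc_mean <- mean(unlist(unc$values)) * cfg$recovery_bin / cfg$chip_bin
  expect_lt(abs(t0_mean / unc_mean - 1), 0.12)
  # never-recovering bins keep their class; planted classes partition bins
  expect_true(all(rec$classes %in% c("early", "middle", "late", "none",
                                     "ambiguous")))
  expect_true(all(is.infinite(rec$onset[rec$classes == "none"])))
  # by 72 h, early bins have regained the untreated rate (ramp ~ 1)
  c72 <- unlist(rec$tracks[["72"]]$values)
  cwt <- unlist(rec$wt_track$values)
  early <- rec$classes == "early"
  expect_lt(abs(mean(c72[early]) / mean(cwt[early]) - 1), 0.1)
})

test_that("planted recovery classes drive the downstream classifier", {
  cfg <- sim_config(seed = 3)
  truth <- simulate_genome(cfg)
  rec <- simulate_recovery(truth)
  cl <- classify_recovery(recovery_z_matrix(rec$tracks))
  keep <- rec$classes != "ambiguous"
  expect_gt(mean((cl == rec$classes)[keep]), 0.95)
  # residual-domain overlap is enriched in the early class (two-proportion)
  res_dom <- planted_domains(truth, "UNC")
  bs <- cfg$recovery_bin
  overlap <- unlist(lapply(truth$genome$chroms, function(ch) {
    cov <- domainscape:::planted_coverage(truth, "UNC", ch, bs)
    cov > 0
  }))
  early <- cl == "early"; late <- cl == "late"
  tt <- two_proportion_test(sum(overlap & early), sum(early),
                            sum(overlap & late), sum(late))
  expect_gt(sum(early), 0)
  expect_gt(mean(overlap[early]), mean(overlap[late]))
  expect_lt(tt$p.value, 0.01)
  # matched-level curves separate in onset order: early leads at 32 h,
  # middle leads late at 48 h (at 32 h neither middle nor late has begun,
  # so their curves coincide up to noise)
  zwt <- unlist(zscale_track(rpkm_track(rec$wt_track))$values,
                use.names = FALSE)
  mc <- matched_class_curves(recovery_z_matrix(rec$tracks), cl, zwt)
  at <- function(class, time) mc$mean_z[mc$class == class &
                                          mc$time == time]
  expect_gt(at("early", 32), at("middle", 32))
  expect_gt(at("early", 32), at("late", 32))
  expect_gt(at("middle", 48), at("late", 48))
})

test_that("gene coupling controls upregulation", {
  cfg <- sim_config(seed = 15, chrom_lengths = c(chr1 = 10e6),
                    p_up_null = 0, coupling_up = 1)
  truth <- simulate_genes(simulate_genome(cfg))
  de <- truth$de_table[truth$de_table$contrast == "UNC_KO", ]
  # coupling 1, null 0: upregulated exactly the planted-loss genes
  expect_identical(de$de_flag == "upregulated", de$planted_loss)
  # coupling 0: flags independent of loss status
  cfg0 <- sim_config(seed = 15, chrom_lengths = c(chr1 = 10e6),
                     p_up_null = 0.3, coupling_up = 0)
  t0 <- simulate_genes(simulate_genome(cfg0))
  de0 <- t0$de_table[t0$de_table$contrast == "UNC_KO", ]
  tt <- two_proportion_test(
    sum(de0$de_flag == "upregulated" & de0$planted_loss),
    sum(de0$planted_loss),
    sum(de0$de_flag == "upregulated" & !de0$planted_loss),
    sum(!de0$planted_loss))
  expect_gt(tt$p.value, 0.001)
})
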