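test_that("window RPKM follows the definition and is depth invariant", {
  gs <- tiny_genome(1e5)
  w <- data.frame(chrom = "chr1", start = 10000, end = 11000)
  set.seed(3)
  reads <- data.frame(chrom = "chr1",
                      start = floor(runif(30, 10000, 10900)))
  reads$end <- reads$start + 100
  expect_equal(rpkm_window(reads, w, total_reads = 30e6), 1.0)
  none <- reads[0, ]
  expect_equal(rpkm_window(none, w, total_reads = 30e6), 0)
  expect_error(rpkm_window(reads, data.frame(chrom = "chr1", start = 5,
                                             end = 5), 30e6),
               "zero-length")
  # track route: border bins contribute by overlap fraction
  tr <- track_from(list(chr1 = c(rep(0, 5), 40, rep(0, 44))), gs,
                   total_reads = 30e6)
  w2 <- data.frame(chrom = "chr1", start = 10000, end = 12000)
  expect_equal(rpkm_window(tr, w2), 40 / 2 / 30)
  w3 <- data.frame(chrom = "chr1", start = 10000, end = 11000)
  expect_equal(rpkm_window(tr, w3), 20 / 1 / 30)   # half the bin
  # doubling counts and depth together leaves RPKM fixed
  tr2 <- track_from(list(chr1 = 2 * tr$values$chr1), gs,
                    total_reads = 60e6)
  expect_equal(rpkm_window(tr2, w2), rpkm_window(tr, w2))
})

test_that("TSS-domain overlap respects the flank window", {
  gs <- tiny_genome(1e5)
  dom <- data.frame(chrom = "chr1", start = 10000, end = 20000)
  genes <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                      tss = 22000)
  expect_true(tss_domain_overlap(genes, dom, 5000))
  expect_false(tss_domain_overlap(genes, dom, 1000))
  inside <- data.frame(gene_id = "g2", chrom = "chr1", strand = "+",
                       tss = 15000)
  expect_true(tss_domain_overlap(inside, dom, 0))
  expect_false(tss_domain_overlap(genes, dom[0, ], 5000))
})

test_that("gene selection applies the four criteria as a conjunction", {
  gs <- tiny_genome(1e5)
  bins <- 50
  flat <- function(v = 0) track_from(list(chr1 = rep(v, bins)), gs,
                                     total_reads = 30e6)
  # promoter bin 11 covers [20000, 22000); TSS at 21000
  marked <- function() {
    v <- rep(1, bins); v[11] <- 120
    track_from(list(chr1 = v), gs, total_reads = 30e6)
  }
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                      strand = "+", tss = c(21000, 61000))
  dom_at_tss <- data.frame(chrom = "chr1", start = 20000, end = 22000)
  no_dom <- dom_at_tss[0, ]
  conds <- c("wt_i", "ko_i")
  me3_doms <- list(wt_i = no_dom, ko_i = no_dom)
  me3_trks <- list(wt_i = flat(1), ko_i = flat(1))
  sel <- select_setdb1_dependent_genes(
    genes, dom_at_tss, no_dom, me3_doms, marked(), flat(1), me3_trks)
  expect_equal(sel$selected, c(TRUE, FALSE))  # gB has no domain/RPKM
  # H3K9me3 domain at the TSS rejects via criterion 2
  me3_doms2 <- list(wt_i = dom_at_tss, ko_i = no_dom)
  sel2 <- select_setdb1_dependent_genes(
    genes, dom_at_tss, no_dom, me3_doms2, marked(), flat(1), me3_trks)
  expect_false(sel2$selected[1])
  # H3K9me3 RPKM 1.2 in one condition rejects via criterion 4
  hot <- function() {
    v <- rep(1, bins); v[11] <- 1.2 * 2 * 30   # RPKM 1.2 in the window
    track_from(list(chr1 = v), gs, total_reads = 30e6)
  }
  sel3 <- select_setdb1_dependent_genes(
    genes, dom_at_tss, no_dom, me3_doms, marked(), flat(1),
    list(wt_i = flat(1), ko_i = hot()))
  expect_false(sel3$selected[1])
  # retained H3K9me2 domain in the treated KO rejects via criterion 1
  sel4 <- select_setdb1_dependent_genes(
    genes, dom_at_tss, dom_at_tss, me3_doms, marked(), flat(1), me3_trks)
  expect_false(sel4$selected[1])
  # missing inputs are named
  expect_error(select_setdb1_dependent_genes(
    genes, dom_at_tss, no_dom, list(), marked(), flat(1), me3_trks),
    "H3K9me3")
})

test_that("selection is monotone when the H3K9me3 ceiling is relaxed", {
  cfg <- sim_config(seed = 14, chrom_lengths = c(chr1 = 10e6),
                    n_genes = 120)
  truth <- simulate_genes(simulate_genome(cfg))
  me2_wt <- simulate_chip(truth, "UNC", "me2")
  me2_ko <- simulate_chip(truth, "UNC_KO", "me2")
  me3 <- list(UNC = simulate_chip(truth, "UNC", "me3"),
              UNC_KO = simulate_chip(truth, "UNC_KO", "me3"))
  doms_wt <- call_domains(me2_wt)$domains
  doms_ko <- call_domains(me2_ko)$domains
  me3_doms <- lapply(me3, function(tr) call_domains(tr)$domains)
  run_at <- function(bound) {
    # criterion 4 ceiling only: keep criterion 3 fixed at 1 by scaling
    sel <- select_setdb1_dependent_genes(
      truth$genes, doms_wt, doms_ko, me3_doms, me2_wt, me2_ko, me3,
      rpkm_bound = 1)
    relax <- select_setdb1_dependent_genes(
      truth$genes, doms_wt, doms_ko,
      lapply(me3_doms, function(d) d[0, , drop = FALSE]),
      me2_wt, me2_ko,
      lapply(me3, function(tr) {
        tr$values <- lapply(tr$values, function(v) v * 0); tr
      }), rpkm_bound = 1)
    list(strict = sel$selected, relaxed = relax$selected)
  }
  r <- run_at(1)
  # dropping the H3K9me3 constraints can only grow the selected set
  expect_true(all(r$relaxed[r$strict]))
})

test_that("upregulated overlap fraction and enrichment test", {
  gs <- tiny_genome(1e5)
  genes <- data.frame(gene_id = paste0("g", 1:8), chrom = "chr1",
                      strand = "+", tss = seq(5000, 75000, by = 10000))
  dom <- data.frame(chrom = "chr1", start = 0, end = 29000)
  up <- c(rep(TRUE, 4), rep(FALSE, 4))    # 3 of 4 upregulated overlap
  out <- upregulated_overlap_fraction(genes, up, dom, flank = 5000)
  expect_equal(out$fraction, 0.75)
  expect_equal(out$background_fraction, 3 / 8)
  expect_error(upregulated_overlap_fraction(genes, rep(FALSE, 8), dom),
               "no upregulated")
  out0 <- upregulated_overlap_fraction(
    genes, c(rep(FALSE, 4), TRUE, TRUE, FALSE, FALSE), dom, flank = 0)
  expect_equal(out0$fraction, 0)
})
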