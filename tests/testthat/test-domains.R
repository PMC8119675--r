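test_that("depth normalization applies the 30M scaling exactly", {
  gs <- tiny_genome(10000)
  tr <- track_from(list(chr1 = c(10, 0, 3, 7, 2)), gs,
                   total_reads = 15e6)
  nm <- normalize_counts(tr)
  expect_equal(nm$values$chr1, c(20, 0, 6, 14, 4))
  expect_equal(nm$units, "normalized")
  # a library already at the reference depth is unchanged
  tr30 <- track_from(list(chr1 = c(5, 1, 2, 0, 9)), gs,
                     total_reads = 30e6)
  expect_equal(normalize_counts(tr30)$values$chr1, tr30$values$chr1)
  tr0 <- track_from(list(chr1 = rep(0, 5)), gs, total_reads = 0)
  expect_error(normalize_counts(tr0), "total_reads")
})

test_that("count capping truncates at the maximum only", {
  gs <- tiny_genome(10000)
  nm <- normalize_counts(track_from(list(chr1 = c(400, 150, 149, 0, 7)),
                                    gs))
  capped <- cap_counts(nm, 150)
  expect_equal(capped$values$chr1, c(150, 150, 149, 0, 7))
  expect_error(cap_counts(nm, 0), "positive")
})

test_that("Baum-Welch recovers chain parameters and is monotone", {
  chain <- sim_hmm_chain(50000, lambda = c(2, 30), a_stay = 0.95,
                         seed = 11)
  gs <- tiny_genome(50000 * 2000)
  capped <- cap_counts(normalize_counts(
    track_from(list(chr1 = chain$x), gs)))
  fit <- fit_hmm_per_chromosome(capped, "chr1")
  expect_false(fit$degenerate)
  expect_lt(abs(fit$lambda[1] - 2) / 2, 0.10)
  expect_lt(abs(fit$lambda[2] - 30) / 30, 0.10)
  expect_lt(abs(fit$trans[1, 1] - 0.95), 0.02)
  expect_lt(abs(fit$trans[2, 2] - 0.95), 0.02)
  expect_false(is.unsorted(fit$loglik_trace))
  # relabeling symmetry: swapped initial guesses give identical ordered fits
  x <- as.integer(round(capped$values$chr1))
  f1 <- domainscape:::hmm_baum_welch_cpp(
    x, c(1, 25), matrix(c(.9, .1, .1, .9), 2), c(.5, .5), 1e-6, 500L)
  f2 <- domainscape:::hmm_baum_welch_cpp(
    x, c(25, 1), matrix(c(.9, .1, .1, .9), 2), c(.5, .5), 1e-6, 500L)
  expect_equal(sort(f1$lambda), sort(f2$lambda), tolerance = 1e-4)
})

test_that("degenerate chromosomes are flagged and excluded from pooling", {
  gs <- tiny_genome(2000 * 200)
  capped <- cap_counts(normalize_counts(
    track_from(list(chr1 = rep(0, 200)), gs, total_reads = 30e6)))
  fit <- fit_hmm_per_chromosome(capped, "chr1")
  expect_true(fit$degenerate)
  good <- hmm_params(matrix(c(.9, .1, .1, .9), 2), c(2, 20))
  good2 <- hmm_params(matrix(c(.9, .1, .1, .9), 2), c(2, 30))
  pooled <- average_hmm_params(list(fit, good, good2))
  expect_equal(pooled$lambda[2], 25)   # mean over non-degenerate only
  expect_error(average_hmm_params(list(fit)), "degenerate")
  # too few bins is an error
  small <- cap_counts(normalize_counts(
    track_from(list(chr1 = rpois(5, 3)), tiny_genome(10000))))
  expect_error(fit_hmm_per_chromosome(small, "chr1"), "complete bins")
})

test_that("posterior decoding matches exhaustive enumeration on toy chains", {
  # brute-force posteriors: sum over all 2^T state paths
  brute_posterior <- function(x, params) {
    T <- length(x)
    paths <- as.matrix(expand.grid(rep(list(1:2), T)))
    pp <- apply(paths, 1, function(s) {
      p <- params$init[s[1]] * dpois(x[1], params$lambda[s[1]])
      for (t in 2:T)
        p <- p * params$trans[s[t - 1], s[t]] *
          dpois(x[t], params$lambda[s[t]])
      p
    })
    sapply(seq_len(T), function(t)
      sum(pp[paths[, t] == 2]) / sum(pp))
  }
  params <- hmm_params(matrix(c(.99, .01, .05, .95), 2, byrow = TRUE),
                       c(2, 30), c(.8, .2))
  x <- c(1, 3, 28, 33, 2, 0, 31, 2, 1, 4)
  gs <- tiny_genome(20000)
  tr <- track_from(list(chr1 = x), gs, units = "normalized")
  st <- decode_states(tr, params)
  expect_equal(st$posterior$chr1, brute_posterior(x, params),
               tolerance = 1e-9)
  # posteriors normalize: enriched + depleted = 1 at every bin
  fb <- domainscape:::hmm_posteriors_cpp(
    as.integer(x), params$lambda, params$trans, params$init)
  expect_equal(rowSums(fb$gamma), rep(1, 10), tolerance = 1e-9)
  # a lone high bin inside a sticky depleted run stays depleted
  sticky <- hmm_params(matrix(c(.99, .01, .10, .90), 2, byrow = TRUE),
                       c(2, 8), c(.99, .01))
  x2 <- c(2, 1, 9, 2, 1)
  tr2 <- track_from(list(chr1 = x2), tiny_genome(10000),
                    units = "normalized")
  st2 <- decode_states(tr2, sticky)
  expect_equal(st2$posterior$chr1, brute_posterior(x2, sticky),
               tolerance = 1e-9)
  expect_false(any(st2$enriched$chr1))
})

test_that("connect_domains merges maximal enriched runs", {
  gs <- tiny_genome(20000)
  mk_states <- function(enriched_bins) {
    post <- rep(0.01, 10); post[enriched_bins] <- 0.99
    structure(list(genome = gs, bin_size = 2000,
                   posterior = list(chr1 = post),
                   enriched = list(chr1 = post >= 0.9), threshold = 0.9),
              class = "StatePosteriorTrack")
  }
  d <- connect_domains(mk_states(4:6))   # bins 4-6 are 0-based 3,4,5
  expect_equal(nrow(d), 1)
  expect_equal(c(d$start, d$end), c(6000, 12000))
  expect_equal(d$mean_posterior, 0.99)
  expect_equal(nrow(connect_domains(mk_states(integer(0)))), 0)
  d2 <- connect_domains(mk_states(c(4, 6)))
  expect_equal(nrow(d2), 2)              # a gap breaks the run
})

test_that("lost-domain calls agree with a brute-force Poisson oracle", {
  gs <- tiny_genome(40000)
  dom <- function(i) data.frame(chrom = "chr1", start = (i - 1) * 2000,
                                end = i * 2000, name = paste0("d", i),
                                mean_posterior = 1, status = "unassigned")
  # both libraries at 1e7 so normalized counts equal raw bin counts
  mk <- function(v) track_from(list(chr1 = v), gs, total_reads = 1e7)
  ref <- mk(c(120, 40, 8, 100, rep(0, 16)))
  tgt <- mk(c(10, 20, 1, 0, rep(0, 16)))
  d <- do.call(rbind, lapply(1:4, dom))
  res <- call_lost_domains(d, ref, tgt)
  # fold 12, P(X<=10 | 120) astronomically small -> lost
  expect_equal(res$status[1], "lost")
  expect_lt(res$p_value[1], 1e-4)
  # fold 2 < 4 -> retained regardless of P
  expect_equal(res$status[2], "retained")
  # fold 8 but P(X<=1 | 8) = 9 e^-8 = 3.02e-3 > 1e-4 -> retained
  expect_equal(res$status[3], "retained")
  expect_equal(res$p_value[3], 9 * exp(-8), tolerance = 1e-12)
  # target 0: infinite fold, P = e^-100 -> lost
  expect_equal(res$status[4], "lost")

  # exact agreement with an independent CDF + fold rule on random pairs,
  # including boundary cases planted at fold = 4 and P close to 1e-4
  set.seed(99)
  n <- 1000
  refc <- c(rpois(n - 4, 40), 40, 80, 400, 4)
  tgtc <- c(rpois(n - 4, 15), 10, 20, 100, 1)
  gs2 <- tiny_genome(2000 * n)
  d2 <- data.frame(chrom = "chr1", start = (seq_len(n) - 1) * 2000,
                   end = seq_len(n) * 2000,
                   name = paste0("d", seq_len(n)),
                   mean_posterior = 1, status = "unassigned")
  res2 <- suppressWarnings(call_lost_domains(
    d2, track_from(list(chr1 = refc), gs2, total_reads = 1e7),
    track_from(list(chr1 = tgtc), gs2, total_reads = 1e7)))
  oracle <- vapply(seq_len(n), function(i) {
    if (refc[i] == 0) return("unassigned")
    fold_ok <- tgtc[i] == 0 || refc[i] / tgtc[i] >= 4
    p_ok <- poisson_cdf_brute(tgtc[i], refc[i]) <= 1e-4
    if (fold_ok && p_ok) "lost" else "retained"
  }, "")
  expect_identical(res2$status, oracle)
})

test_that("lost calls are monotone in the target count", {
  gs <- tiny_genome(2000)
  d <- data.frame(chrom = "chr1", start = 0, end = 2000, name = "d1",
                  mean_posterior = 1, status = "unassigned")
  ref <- track_from(list(chr1 = 100), gs, total_reads = 1e7)
  status <- vapply(0:100, function(tc) {
    tgt <- track_from(list(chr1 = tc), gs, total_reads = 1e7)
    call_lost_domains(d, ref, tgt)$status
  }, "")
  # once not-lost, larger target counts never flip back to lost
  first_retained <- match("retained", status)
  expect_true(all(status[first_retained:length(status)] == "retained"))
})

test_that("conserved domains overlap the target call and exclude lost", {
  gs <- tiny_genome(40000)
  ref <- data.frame(chrom = "chr1", start = c(0, 10000, 20000),
                    end = c(6000, 14000, 26000),
                    name = c("a", "b", "c"), mean_posterior = 1,
                    status = c("retained", "lost", "retained"))
  tgt <- data.frame(chrom = "chr1", start = c(4000, 10000),
                    end = c(8000, 12000), name = c("x", "y"),
                    mean_posterior = 1, status = "unassigned")
  out <- conserved_domains(ref, tgt)
  expect_equal(out$status, c("conserved", "lost", "unassigned"))
  expect_equal(sum(out$status == "lost" & out$status == "conserved"), 0)
})
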