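# shared fixtures: tiny genomes and hand-built tracks

tiny_genome <- function(len = 20000, chroms = "chr1", sex = character()) {
  lens <- rep(len, length(chroms))
  names(lens) <- chroms
  genome_spec(lens, sex_chroms = sex)
}

# track from explicit per-chromosome vectors
track_from <- function(values, genome, bin_size = 2000, units = "raw",
                       total_reads = 30e6) {
  binned_track(lapply(values, as.numeric), genome, bin_size,
               units = units, total_reads = total_reads)
}

# simulate a two-state Poisson HMM chain; returns observations and states
sim_hmm_chain <- function(T, lambda = c(2, 30), a_stay = 0.95, seed = 1) {
  set.seed(seed)
  s <- integer(T)
  s[1] <- sample(1:2, 1)
  for (t in 2:T)
    s[t] <- if (runif(1) < a_stay) s[t - 1] else 3L - s[t - 1]
  list(x = rpois(T, lambda[s]), states = s)
}

# independent lower-tail Poisson CDF by direct summation of the pmf
poisson_cdf_brute <- function(q, lambda) {
  if (q < 0) return(0)
  k <- 0:floor(q)
  sum(exp(-lambda + k * log(lambda) - lfactorial(k)))
}

# textbook pooled-variance two-proportion chi-square
prop_chisq_textbook <- function(k1, n1, k2, n2) {
  p <- (k1 + k2) / (n1 + n2)
  ((k1 / n1 - k2 / n2)^2) / (p * (1 - p) * (1 / n1 + 1 / n2))
}

# leading eigenvector of a symmetric matrix by power iteration (independent
# of eigen())
power_iter_pc1 <- function(C, iters = 10000, tol = 1e-14) {
  v <- rep(1 / sqrt(nrow(C)), nrow(C))
  v <- v + seq_len(nrow(C)) * 1e-4  # break symmetry
  v <- v / sqrt(sum(v^2))
  lam <- 0
  for (i in seq_len(iters)) {
    w <- C %*% v
    lam_new <- sqrt(sum(w^2))
    w <- as.vector(w) / lam_new
    if (max(abs(w - v)) < tol || max(abs(w + v)) < tol) {
      v <- w; lam <- lam_new; break
    }
    v <- w; lam <- lam_new
  }
  list(vector = v, value = lam)
}
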