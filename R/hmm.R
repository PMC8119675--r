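#' @useDynLib domainscape, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Two-state Poisson HMM parameters
#'
#' State 1 is the depleted state, state 2 the enriched state; emissions are
#' Poisson with means `lambda[1] < lambda[2]` (rounded, capped, normalized
#' counts per bin).
#'
#' @param trans 2x2 transition matrix, rows (from-state) summing to 1;
#'   order (depleted, enriched).
#' @param lambda Emission means `c(depleted, enriched)`.
#' @param init Initial state probabilities summing to 1.
#' @param degenerate Logical: `TRUE` when the fit collapsed (the two emission
#'   means are indistinguishable) and the parameters should not enter
#'   cross-chromosome averaging.
#' @param loglik_trace Optional Baum-Welch log-likelihood trace.
#' @param converged Optional convergence flag.
#' @return An object of class `HmmParams`.
#' @export
hmm_params <- function(trans, lambda, init = c(0.5, 0.5),
                       degenerate = FALSE, loglik_trace = numeric(),
                       converged = NA) {
  trans <- matrix(as.numeric(trans), 2, 2)
  if (any(trans < 0) || any(abs(rowSums(trans) - 1) > 1e-8))
    stop("transition rows must be non-negative and sum to 1")
  if (abs(sum(init) - 1) > 1e-8 || any(init < 0))
    stop("initial probabilities must sum to 1")
  if (length(lambda) != 2 || any(lambda < 0))
    stop("lambda must be two non-negative emission means")
  if (!degenerate && lambda[2] <= lambda[1])
    stop("enriched mean must exceed depleted mean (or mark degenerate)")
  structure(list(trans = trans, lambda = as.numeric(lambda),
                 init = as.numeric(init), degenerate = degenerate,
                 loglik_trace = loglik_trace, converged = converged),
            class = "HmmParams")
}

#' @export
print.HmmParams <- function(x, ...) {
  cat(sprintf(
    "HmmParams: lambda_d=%.3f lambda_e=%.3f a_dd=%.4f a_ee=%.4f%s\n",
    x$lambda[1], x$lambda[2], x$trans[1, 1], x$trans[2, 2],
    if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

# order the two states so state 2 carries the larger emission mean
order_states <- function(lambda, trans, init) {
  if (lambda[2] >= lambda[1])
    return(list(lambda = lambda, trans = trans, init = init))
  list(lambda = rev(lambda), trans = trans[2:1, 2:1], init = rev(init))
}

# integer observation vector for HMM fitting/decoding: complete bins only,
# rounded to the nearest count
hmm_observations <- function(track, chrom) {
  ncb <- n_complete_bins(track$genome, chrom, track$bin_size)
  as.integer(round(track$values[[chrom]][seq_len(ncb)]))
}

#' Fit the two-state Poisson HMM on one chromosome
#'
#' Baum-Welch maximum-likelihood fit on rounded, capped, depth-normalized
#' counts of the complete bins of one chromosome.  Initialization is fixed
#' (no randomness): the depleted mean starts at the 25th and the enriched
#' mean at the 90th percentile of the non-zero bins, self-transitions at 0.9.
#'
#' @param track A capped, normalized `BinnedTrack`.
#' @param chrom Chromosome to fit.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum Baum-Welch iterations.
#' @param min_bins Minimum number of complete bins required.
#' @return An `HmmParams`; `degenerate = TRUE` when the chromosome carries no
#'   usable contrast (all values identical, or the fitted means collapse).
#' @export
fit_hmm_per_chromosome <- function(track, chrom, tol = 1e-6,
                                   max_iter = 500, min_bins = 100) {
  stopifnot(inherits(track, "BinnedTrack"))
  x <- hmm_observations(track, chrom)
  if (length(x) < min_bins)
    stop(sprintf("chromosome %s has %d complete bins; need >= %d",
                 chrom, length(x), min_bins))
  if (length(unique(x)) == 1)
    return(hmm_params(matrix(c(.9, .1, .1, .9), 2, 2),
                      c(x[1], x[1]), c(.5, .5), degenerate = TRUE))
  nz <- x[x > 0]
  if (!length(nz)) nz <- x
  l0 <- as.numeric(stats::quantile(nz, 0.25))
  l1 <- as.numeric(stats::quantile(nz, 0.90))
  if (l1 <= l0) l1 <- l0 * 2 + 1
  fit <- hmm_baum_welch_cpp(x, c(l0, l1),
                            matrix(c(.9, .1, .1, .9), 2, 2),
                            c(.5, .5), tol, as.integer(max_iter))
  o <- order_states(fit$lambda, fit$trans, fit$init)
  degenerate <- (o$lambda[2] - o$lambda[1]) <= 1e-6 * max(1, o$lambda[2])
  hmm_params(o$trans, if (degenerate) rep(mean(o$lambda), 2) else o$lambda,
             o$init, degenerate = degenerate,
             loglik_trace = fit$loglik_trace, converged = fit$converged)
}

#' Average HMM parameters across chromosomes
#'
#' Arithmetic mean of every parameter over the non-degenerate per-chromosome
#' fits, with transition rows renormalized.  Pooling protects chromosomes on
#' which too few enriched domains exist for a stable local fit.
#'
#' @param per_chrom List of `HmmParams`.
#' @return A pooled `HmmParams`.
#' @export
average_hmm_params <- function(per_chrom) {
  keep <- Filter(function(p) !p$degenerate, per_chrom)
  if (!length(keep))
    stop("all per-chromosome fits are degenerate; cannot pool parameters")
  lam <- Reduce(`+`, lapply(keep, `[[`, "lambda")) / length(keep)
  trans <- Reduce(`+`, lapply(keep, `[[`, "trans")) / length(keep)
  trans <- trans / rowSums(trans)
  init <- Reduce(`+`, lapply(keep, `[[`, "init")) / length(keep)
  init <- init / sum(init)
  hmm_params(trans, lam, init)
}

#' Posterior state decoding of a binned track
#'
#' Forward-backward posteriors for every complete bin under fixed parameters;
#' a bin is labeled enriched when its enriched-state posterior reaches
#' `posterior_threshold`.  Partial terminal bins get `NA` posteriors and are
#' never enriched.
#'
#' @param track A capped, normalized `BinnedTrack`.
#' @param params An `HmmParams` (typically genome-pooled).
#' @param posterior_threshold Enriched-label threshold, default 0.9.
#' @return A `StatePosteriorTrack`: list with `posterior` and `enriched`
#'   per-chromosome vectors, plus the genome/bin size.
#' @export
decode_states <- function(track, params, posterior_threshold = 0.9) {
  stopifnot(inherits(track, "BinnedTrack"), inherits(params, "HmmParams"))
  posterior <- list(); enriched <- list()
  for (chrom in track$genome$chroms) {
    nb <- n_bins(track$genome, chrom, track$bin_size)
    post <- rep(NA_real_, nb)
    x <- hmm_observations(track, chrom)
    if (length(x) > 0 && !params$degenerate) {
      fb <- hmm_posteriors_cpp(x, params$lambda, params$trans, params$init)
      post[seq_along(x)] <- fb$gamma[, 2]
    } else if (length(x) > 0) {
      post[seq_along(x)] <- params$init[2]
    }
    posterior[[chrom]] <- post
    enriched[[chrom]] <- !is.na(post) & post >= posterior_threshold
  }
  structure(list(genome = track$genome, bin_size = track$bin_size,
                 posterior = posterior, enriched = enriched,
                 threshold = posterior_threshold),
            class = "StatePosteriorTrack")
}
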