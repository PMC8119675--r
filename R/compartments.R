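#' Intrachromosomal contact matrix
#'
#' A square symmetric matrix of contact values for one chromosome at a fixed
#' bin size, with a processing state (`raw`, `balanced`, `oe`) and a mask of
#' bins excluded from scoring (sparse rows, partial terminal bin).
#'
#' @param mat Square numeric matrix; must be symmetric (1e-8 relative).
#' @param chrom Chromosome name.
#' @param bin_size Bin width in bp.
#' @param state One of `"raw"`, `"balanced"`, `"oe"`.
#' @param mask Logical vector, `TRUE` for bins excluded from scoring.
#' @param partial_bin Logical: mask the last bin (it is shorter than
#'   `bin_size`).
#' @return An object of class `ContactMatrix`.
#' @export
contact_matrix <- function(mat, chrom, bin_size, state = "raw",
                           mask = NULL, partial_bin = FALSE) {
  state <- match.arg(state, c("raw", "balanced", "oe"))
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) stop("contact matrix must be square")
  fin <- is.finite(mat)
  if (max(abs(mat[fin & t(fin)] - t(mat)[fin & t(fin)])) >
      1e-8 * max(1, max(abs(mat[fin]))))
    stop("contact matrix must be symmetric")
  if (state != "oe" && any(mat[fin] < 0))
    stop("raw/balanced contact values must be non-negative")
  if (is.null(mask)) mask <- rep(FALSE, nrow(mat))
  if (partial_bin) mask[nrow(mat)] <- TRUE
  structure(list(mat = mat, chrom = chrom, bin_size = as.numeric(bin_size),
                 state = state, mask = as.logical(mask)),
            class = "ContactMatrix")
}

#' @export
print.ContactMatrix <- function(x, ...) {
  cat(sprintf("ContactMatrix %s [%s]: %d x %d bins @ %s bp (%d masked)\n",
              x$chrom, x$state, nrow(x$mat), ncol(x$mat),
              format(x$bin_size, big.mark = ","), sum(x$mask)))
  invisible(x)
}

#' Balance a raw contact matrix
#'
#' Symmetric diagonal scaling (Knight-Ruiz/Sinkhorn style fixed point): finds
#' d such that `diag(d) M diag(d)` has equal row sums on unmasked bins.  Bins
#' with fewer than `min_nonzero` non-zero contacts are masked before
#' balancing, as are all-zero rows.
#'
#' @param m A `ContactMatrix` in `raw` state.
#' @param tol Convergence tolerance on the maximum relative row-sum
#'   deviation.
#' @param max_iter Maximum iterations.
#' @param min_nonzero Minimum non-zero contacts for a bin to be scorable.
#' @return A `ContactMatrix` in `balanced` state (masked rows/cols are `NA`).
#' @export
balance_matrix <- function(m, tol = 1e-8, max_iter = 3000,
                           min_nonzero = 10) {
  stopifnot(inherits(m, "ContactMatrix"))
  if (m$state != "raw") stop("balance_matrix expects a raw matrix")
  nz <- rowSums(m$mat > 0)
  mask <- m$mask | nz < min_nonzero | rowSums(m$mat) == 0
  keep <- which(!mask)
  if (length(keep) < 2)
    stop("fewer than two scorable bins after masking; matrix unusable")
  A <- m$mat[keep, keep, drop = FALSE]
  d <- rep(1, length(keep))
  ok <- FALSE
  for (it in seq_len(max_iter)) {
    s <- d * as.vector(A %*% d)        # row sums of diag(d) A diag(d)
    if (any(s <= 0))
      stop("balancing hit a zero row sum; matrix not irreducible on kept bins")
    dev <- max(abs(s / mean(s) - 1))
    if (dev < tol) { ok <- TRUE; break }
    d <- d / sqrt(s)
  }
  if (!ok)
    stop(sprintf("balancing did not converge in %d iterations (residual %.3g)",
                 max_iter, dev))
  # scale so row sums are exactly 1 on average
  s <- d * as.vector(A %*% d)
  d <- d / sqrt(mean(s))
  B <- matrix(NA_real_, nrow(m$mat), ncol(m$mat))
  B[keep, keep] <- A * outer(d, d)
  contact_matrix(B, m$chrom, m$bin_size, state = "balanced", mask = mask)
}

#' Distance-normalize a balanced matrix (observed over expected)
#'
#' Divides every entry by the mean balanced value at its genomic distance
#' `|i - j|`, the mean being taken over unmasked pairs at that distance.
#' Distances with no unmasked pairs (or zero mean) stay `NA`.
#'
#' @param m A `ContactMatrix` in `balanced` state.
#' @return A `ContactMatrix` in `oe` state.
#' @export
observed_over_expected <- function(m) {
  stopifnot(inherits(m, "ContactMatrix"))
  if (m$state != "balanced")
    stop("observed_over_expected expects a balanced matrix")
  n <- nrow(m$mat)
  keep <- which(!m$mask)
  d_idx <- abs(outer(keep, keep, `-`))
  vals <- m$mat[keep, keep]
  exp_by_d <- tapply(as.vector(vals), as.vector(d_idx),
                     function(x) mean(x, na.rm = TRUE))
  E <- matrix(NA_real_, n, n)
  expected <- exp_by_d[as.character(as.vector(d_idx))]
  expected[!is.finite(expected) | expected == 0] <- NA
  E[keep, keep] <- as.vector(vals) / expected
  contact_matrix(E, m$chrom, m$bin_size, state = "oe", mask = m$mask)
}

#' Signed A/B compartment score of one chromosome
#'
#' Pearson correlation matrix of the O/E columns over unmasked bins, then the
#' first principal component: the leading eigenvector scaled by the square
#' root of its eigenvalue.  The sign is flipped, per chromosome, so the score
#' correlates positively with an orientation reference (gene density or an
#' active-mark track); positive score = A compartment.
#'
#' @param m A `ContactMatrix` in `oe` state.
#' @param orientation Numeric vector, one value per bin, whose correlation
#'   with the score fixes the sign (e.g. gene density).
#' @param orientation_name Label recorded on the output.
#' @param min_bins Minimum unmasked bins required.
#' @return A `CompartmentTrack`: list with per-bin `score` (`NA` when
#'   masked), `mask`, `chrom`, `bin_size`, `orientation_reference`.
#' @export
compartment_score <- function(m, orientation,
                              orientation_name = "orientation",
                              min_bins = 10) {
  stopifnot(inherits(m, "ContactMatrix"))
  if (m$state != "oe") stop("compartment_score expects an O/E matrix")
  n <- nrow(m$mat)
  if (length(orientation) != n)
    stop("orientation must have one value per bin")
  keep <- which(!m$mask)
  sub <- m$mat[keep, keep, drop = FALSE]
  # drop bins whose O/E column is constant or unobserved
  v <- apply(sub, 2, function(col) stats::var(col, na.rm = TRUE))
  good <- is.finite(v) & v > 0
  if (sum(good) < min_bins)
    stop("fewer than ", min_bins, " scorable bins; cannot compute PC1")
  keep <- keep[good]
  sub <- sub[good, good, drop = FALSE]
  C <- suppressWarnings(stats::cor(sub, use = "pairwise.complete.obs"))
  C[!is.finite(C)] <- 0
  eig <- eigen(C, symmetric = TRUE)
  pc1 <- eig$vectors[, 1] * sqrt(max(eig$values[1], 0))
  r <- suppressWarnings(stats::cor(pc1, orientation[keep]))
  if (!is.finite(r) || r == 0)
    stop("orientation reference is uncorrelated with PC1; supply another")
  if (r < 0) pc1 <- -pc1
  score <- rep(NA_real_, n)
  score[keep] <- pc1
  mask <- rep(TRUE, n); mask[keep] <- FALSE
  structure(list(chrom = m$chrom, bin_size = m$bin_size, score = score,
                 mask = mask, orientation_reference = orientation_name),
            class = "CompartmentTrack")
}

#' @export
print.CompartmentTrack <- function(x, ...) {
  cat(sprintf(
    "CompartmentTrack %s: %d bins @ %s bp, %d scored (A: %d, B: %d)\n",
    x$chrom, length(x$score), format(x$bin_size, big.mark = ","),
    sum(!x$mask), sum(x$score > 0, na.rm = TRUE),
    sum(x$score <= 0, na.rm = TRUE)))
  invisible(x)
}

#' Compartment scores for a genome of contact matrices
#'
#' Runs balancing, O/E and PC1 scoring per autosome; sex chromosomes are
#' skipped.
#'
#' @param mats Named list of raw `ContactMatrix` objects (one per
#'   chromosome).
#' @param orientations Named list of orientation vectors matching `mats`.
#' @param genome A [genome_spec()]; its `sex_chroms` are excluded.
#' @param ... Passed to [balance_matrix()].
#' @return Named list of `CompartmentTrack`s for the autosomes.
#' @export
compartment_scores_genome <- function(mats, orientations, genome, ...) {
  chroms <- intersect(names(mats), autosomes(genome))
  out <- lapply(chroms, function(ch) {
    oe <- observed_over_expected(balance_matrix(mats[[ch]], ...))
    compartment_score(oe, orientations[[ch]])
  })
  names(out) <- chroms
  out
}

#' Classify per-bin compartment changes between two conditions
#'
#' Bins are classed by the sign of the score in each condition (`A->A`,
#' `B->B`, `A->B`, `B->A`); the conserved fraction is the share of scored
#' bins keeping their sign.
#'
#' @param a,b `CompartmentTrack`s on identical binning.
#' @return List with `class` (character per bin, `NA` where either track is
#'   masked) and `conserved_fraction`.
#' @export
classify_compartment_change <- function(a, b) {
  if (a$bin_size != b$bin_size || length(a$score) != length(b$score))
    stop("compartment tracks must share bin size and bin count")
  cls <- rep(NA_character_, length(a$score))
  ok <- !a$mask & !b$mask & is.finite(a$score) & is.finite(b$score)
  la <- ifelse(a$score > 0, "A", "B")
  lb <- ifelse(b$score > 0, "A", "B")
  cls[ok] <- paste0(la[ok], "->", lb[ok])
  structure(list(
    class = cls,
    conserved_fraction = if (any(ok))
      mean(cls[ok] %in% c("A->A", "B->B")) else NA_real_),
    class = "compartment_change")
}
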