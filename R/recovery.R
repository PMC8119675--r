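#' Classify bins by the timing of mark recovery
#'
#' A bin is `early` when its z-score has increased by at least `delta` at
#' 32 h relative to 0 h; otherwise `middle` if so at 48 h; otherwise `late`
#' if so at 72 h; otherwise `none`.  The earliest qualifying time wins.
#'
#' @param z Numeric matrix (bins x time points) of per-sample z-scores; the
#'   columns are named by time in hours and must include 0, 32, 48 and 72.
#' @param delta Required z increase, default 0.3.
#' @return Character vector of classes (`early`, `middle`, `late`, `none`).
#' @examples
#' z <- rbind(c(0, 0.35, 0.6, 0.7), c(0, 0.1, 0.4, 0.6), c(0, 0, 0.1, 0.2))
#' colnames(z) <- c(0, 32, 48, 72)
#' classify_recovery(z)  # early, middle, none
#' @export
classify_recovery <- function(z, delta = 0.3) {
  z <- as.matrix(z)
  need <- c("0", "32", "48", "72")
  if (is.null(colnames(z)) || !all(need %in% colnames(z)))
    stop("z matrix must have columns named for hours 0, 32, 48 and 72")
  d32 <- z[, "32"] - z[, "0"]
  d48 <- z[, "48"] - z[, "0"]
  d72 <- z[, "72"] - z[, "0"]
  if (any(!is.finite(cbind(d32, d48, d72))))
    stop("missing z value at a required time point")
  ifelse(d32 >= delta, "early",
         ifelse(d48 >= delta, "middle",
                ifelse(d72 >= delta, "late", "none")))
}

#' Mean recovery curves per class, matched on final mark level
#'
#' Restricts to bins whose reference (untreated) z-score lies in
#' `[wt_low, wt_high]` so the classes being compared end at similar mark
#' levels, then reports the mean z per class at every time point.
#'
#' @param z Bins x time matrix of z-scores (columns named by hour).
#' @param classes Class per bin from [classify_recovery()].
#' @param z_wt Reference (untreated) z per bin.
#' @param wt_low,wt_high Inclusive matching window, default 0.5-0.7.
#' @return Data.frame `class`, `time`, `mean_z`, `n`.  Classes emptied by the
#'   filter are omitted with a warning.
#' @export
matched_class_curves <- function(z, classes, z_wt, wt_low = 0.5,
                                 wt_high = 0.7) {
  z <- as.matrix(z)
  keep <- is.finite(z_wt) & z_wt >= wt_low & z_wt <= wt_high
  lost <- setdiff(unique(classes), unique(classes[keep]))
  if (length(lost))
    warning("class(es) empty after WT matching: ",
            paste(lost, collapse = ", "))
  if (!any(keep))
    return(data.frame(class = character(), time = numeric(),
                      mean_z = numeric(), n = integer()))
  zs <- z[keep, , drop = FALSE]
  cl <- classes[keep]
  out <- do.call(rbind, lapply(split(seq_along(cl), cl), function(idx)
    data.frame(class = cl[idx[1]],
               time = as.numeric(colnames(zs)),
               mean_z = colMeans(zs[idx, , drop = FALSE]),
               n = length(idx))))
  rownames(out) <- NULL
  out
}

#' Two-sample proportion test (pooled-variance chi-square)
#'
#' The standard two-proportion chi-square with pooled variance, equivalent to
#' `prop.test`; the Yates continuity correction is off by default.
#'
#' @param k1,n1 Successes and trials in group 1.
#' @param k2,n2 Successes and trials in group 2.
#' @param correct Apply the Yates continuity correction (default `FALSE`).
#' @return List with `statistic` (chi-square, 1 df), `p.value` (two-sided),
#'   and `estimate` (the two proportions).
#' @export
two_proportion_test <- function(k1, n1, k2, n2, correct = FALSE) {
  if (n1 < 1 || n2 < 1) stop("both group sizes must be at least 1")
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2)
    stop("successes must lie in [0, n]")
  obs <- matrix(c(k1, n1 - k1, k2, n2 - k2), 2, 2, byrow = TRUE)
  expd <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  if (any(expd == 0)) {
    stat <- 0
  } else {
    dev <- abs(obs - expd)
    if (correct) dev <- pmax(dev - 0.5, 0)
    stat <- sum(dev^2 / expd)
  }
  list(statistic = stat,
       p.value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       estimate = c(p1 = k1 / n1, p2 = k2 / n2))
}
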