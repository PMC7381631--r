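## Agreement statistics between quantification methods.

#' Pearson correlation coefficient
#'
#' Thin wrapper over [stats::cor()] with the preconditions made explicit:
#' equal lengths of at least 3 and nonzero variance in both vectors.
#'
#' @param x,y numeric vectors.
#' @return numeric(1) in [-1, 1].
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("at least 3 paired values required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(x, y)
}

#' Stratified mean absolute percent deviation of MPI from MPS masses
#'
#' Per-sample deviation |mpi - mps| / mps x 100, averaged overall and within
#' the strata at-or-above and below the mass cut (default 1 ug, the
#' operating regime boundary of the scanner; the boundary itself counts as
#' "above"). An empty stratum is reported as `NA` (absent), not 0.
#'
#' @param mpi,mps numeric vectors of per-sample iron masses (ug); `mps` is
#'   the denominator and must be positive.
#' @param cut numeric(1), stratum boundary in ug.
#' @return named numeric(3): overall, above, below (percent).
#' @export
stratifiedDeviation <- function(mpi, mps, cut = 1) {
  if (length(mpi) != length(mps)) stop("mpi and mps must have equal length")
  if (any(mps <= 0)) stop("all mps masses must be positive")
  dev <- abs(mpi - mps) / mps * 100
  above <- mps >= cut
  c(overall = mean(dev),
    above = if (any(above)) mean(dev[above]) else NA_real_,
    below = if (any(!above)) mean(dev[!above]) else NA_real_)
}

#' Unpaired two-tailed Student's t test
#'
#' Equal-variance two-sample t test (the classical Student form); p < 0.05
#' is the study's significance level.
#'
#' @param groupA,groupB numeric vectors of at least 2 values each.
#' @param varEqual logical(1), pooled-variance form (default TRUE).
#' @return numeric(1), two-tailed p value.
#' @export
unpairedTTest <- function(groupA, groupB, varEqual = TRUE) {
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("each group needs at least 2 values")
  if (stats::sd(groupA) == 0 && stats::sd(groupB) == 0)
    stop("both groups have zero variance: t statistic undefined")
  stats::t.test(groupA, groupB, var.equal = varEqual,
                alternative = "two.sided")$p.value
}
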