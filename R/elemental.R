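## Elemental bioimaging: synthetic line-by-line scans with matrix-matched
## gelatin standards, linear calibration, LOD/LOQ, map quantification.

#' Generate a synthetic elemental line scan
#'
#' Emulates a line-by-line laser-ablation scan of a tissue section: per-pixel
#' intensity is a linear response to the local iron concentration plus
#' Gaussian blank noise. A matrix-matched standards table (gelatin standards
#' including a blank, several scanned lines each) is emitted alongside, with
#' the same response and noise.
#'
#' @param concMap numeric matrix, true iron concentration in ug/g per pixel
#'   (rows are ablation lines).
#' @param standards numeric, standard concentrations in ug/g; must include a
#'   blank (0) and cover the map's range. Default: nine gelatin standards,
#'   blank to 5000 ug/g.
#' @param slope numeric(1), detector response per (ug/g).
#' @param intercept numeric(1), blank intensity.
#' @param blankSigma numeric(1) >= 0, per-pixel noise.
#' @param nStandardLines integer(1), scanned lines per standard.
#' @param seed integer(1) or `NULL`.
#' @return list: `scans` data.frame (line, pixel, intensity), `standards`
#'   data.frame (concentration, line, intensity = line-mean intensity),
#'   `meta` list (slope, intercept, shape of the map).
#' @export
makeElementalScan <- function(concMap,
                              standards = c(0, 1, 5, 25, 100, 250,
                                            1000, 2500, 5000),
                              slope = 50, intercept = 400,
                              blankSigma = 10,
                              nStandardLines = 8L, seed = NULL) {
  if (blankSigma < 0) stop("blankSigma must be nonnegative")
  if (!any(standards == 0))
    stop("standards must include a blank (0 ug/g)")
  if (max(standards) < max(concMap))
    stop("standards do not cover the map's concentration range")
  withSeed(seed, {
    nl <- nrow(concMap); np <- ncol(concMap)
    intensity <- slope * as.vector(t(concMap)) + intercept
    if (blankSigma > 0)
      intensity <- intensity + stats::rnorm(length(intensity),
                                            sd = blankSigma)
    scans <- data.frame(line = rep(seq_len(nl), each = np),
                        pixel = rep(seq_len(np), times = nl),
                        intensity = intensity)
    ## standards: each scanned line's mean intensity; line-mean noise shrinks
    ## with the pixels averaged per line (use the map's line length)
    stdLines <- expand.grid(line = seq_len(nStandardLines),
                            concentration = standards)
    mu <- slope * stdLines$concentration + intercept
    if (blankSigma > 0)
      mu <- mu + stats::rnorm(length(mu), sd = blankSigma)
    standardsTab <- data.frame(concentration = stdLines$concentration,
                               line = stdLines$line,
                               intensity = mu)
    list(scans = scans,
         standards = standardsTab,
         meta = list(slope = slope, intercept = intercept,
                     shape = c(nl, np)))
  })
}

#' Fit a linear calibration curve to elemental standards
#'
#' Ordinary least squares of per-standard mean intensity against
#' concentration; blank noise is the standard deviation of the blank line
#' intensities; LOD and LOQ follow the 3-sigma and 10-sigma criteria.
#'
#' @param standards data.frame with columns `concentration` (ug/g) and
#'   `intensity` (one row per scanned line).
#' @return A [CalibrationCurve-class].
#' @export
fitCalibration <- function(standards) {
  concs <- unique(standards$concentration)
  if (length(concs) < 3L)
    stop("at least 3 distinct standard concentrations required")
  if (!any(standards$concentration == 0))
    stop("standards must include a blank")
  means <- stats::aggregate(intensity ~ concentration, data = standards,
                            FUN = mean)
  fit <- stats::lm(intensity ~ concentration, data = means)
  blanks <- standards$intensity[standards$concentration == 0]
  blankSigma <- if (length(blanks) > 1L) stats::sd(blanks) else 0
  slope <- unname(stats::coef(fit)[2L])
  ## R^2 computed directly; summary.lm warns on numerically perfect fits
  r2 <- 1 - sum(stats::residuals(fit)^2) /
    sum((means$intensity - mean(means$intensity))^2)
  r2 <- min(max(r2, 0), 1)
  ll <- if (slope > 0) unname(lodLoq(blankSigma, slope)) else c(0, 0)
  new("CalibrationCurve",
      slope = slope,
      intercept = unname(stats::coef(fit)[1L]),
      rSquared = r2,
      blankSigma = blankSigma,
      lod = ll[1L], loq = ll[2L],
      standards = means)
}

#' Limits of detection and quantification
#'
#' 3-sigma and 10-sigma criteria on the blank noise over the calibration
#' slope: LOD = 3 sigma / slope, LOQ = 10 sigma / slope, so LOQ/LOD = 10/3
#' exactly.
#'
#' @param blankSigma numeric(1) >= 0, intensity units.
#' @param slope numeric(1) > 0, intensity per (ug/g).
#' @return numeric(2): c(lod, loq) in ug/g.
#' @export
lodLoq <- function(blankSigma, slope) {
  if (slope <= 0) stop("slope must be positive")
  c(lod = 3 * blankSigma / slope, loq = 10 * blankSigma / slope)
}

#' Quantify an elemental map from line scans
#'
#' Inverts the calibration (concentration = (intensity - intercept) / slope,
#' floored at 0) and flags pixels below the limit of detection.
#'
#' @param scans data.frame with columns `line`, `pixel`, `intensity`.
#' @param curve a [CalibrationCurve-class].
#' @return list: `map` numeric matrix (ug/g, lines x pixels), `belowLod`
#'   logical matrix.
#' @export
quantifyMap <- function(scans, curve) {
  nl <- max(scans$line); np <- max(scans$pixel)
  conc <- pmax((scans$intensity - curve@intercept) / curve@slope, 0)
  map <- matrix(0, nl, np)
  map[cbind(scans$line, scans$pixel)] <- conc
  list(map = map, belowLod = map < curve@lod)
}
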