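## Perls' Prussian Blue morphometry: synthetic stained sections, colour
## profile segmentation, iron-area ratio, and mask colocalization.

#' Colour profile for stain segmentation
#'
#' Reference colour of iron oxide under Perls' Prussian Blue plus a
#' perceptual tolerance. Matching happens in CIE Lab space, so the tolerance
#' is a Delta-E-like distance.
#'
#' @param referenceRGB numeric(3) in [0, 255].
#' @param tolerance numeric(1) > 0, Lab-space distance threshold.
#' @return list with elements `referenceRGB` and `tolerance`.
#' @export
colorProfile <- function(referenceRGB = c(45, 65, 150), tolerance = 30) {
  stopifnot(length(referenceRGB) == 3L, all(referenceRGB >= 0),
            all(referenceRGB <= 255), tolerance > 0)
  list(referenceRGB = as.numeric(referenceRGB), tolerance = tolerance)
}

#' Generate a synthetic Perls'-stained section
#'
#' Draws a vessel cross-section (elliptical ring of eosin-pink tissue around
#' a lumen on a white background) and paints exactly
#' \code{round(ironAreaFraction * tissue pixels)} tissue pixels in Perls'
#' blue, clustered into patches via a smooth seeded random field. Per-pixel
#' colour jitter emulates staining variability. Ground-truth masks are
#' returned so segmentation accuracy is checkable.
#'
#' @param ironAreaFraction numeric(1) in [0, 1].
#' @param size integer(2), image width and height in pixels.
#' @param seed integer(1).
#' @param jitterSD numeric(1), per-channel colour noise (0-255 scale).
#' @return list: `image` (size[1] x size[2] x 3 array, 0-255),
#'   `tissueMask`, `ironMask` (logical matrices).
#' @export
makeStainImage <- function(ironAreaFraction, size = c(192L, 192L),
                           seed = 1L, jitterSD = 7) {
  if (ironAreaFraction < 0 || ironAreaFraction > 1)
    stop("ironAreaFraction must lie in [0, 1]")
  withSeed(seed, {
    w <- size[1L]; h <- size[2L]
    x <- (seq_len(w) - (w + 1) / 2) / (w / 2)
    y <- (seq_len(h) - (h + 1) / 2) / (h / 2)
    X <- matrix(x, w, h)
    Y <- matrix(y, w, h, byrow = TRUE)
    outer <- (X / 0.8)^2 + (Y / 0.7)^2 <= 1
    lumen <- (X / 0.35)^2 + (Y / 0.28)^2 <= 1
    tissue <- outer & !lumen
    nIron <- round(ironAreaFraction * sum(tissue))
    iron <- matrix(FALSE, w, h)
    if (nIron > 0) {
      ## smooth field: superposition of random Gaussian bumps; the nIron
      ## highest-valued tissue pixels become iron -> clustered patches,
      ## exact pixel count
      field <- matrix(0, w, h)
      for (b in seq_len(12L)) {
        cx <- stats::runif(1, -1, 1) * 0.7
        cy <- stats::runif(1, -1, 1) * 0.6
        s <- stats::runif(1, 0.08, 0.2)
        field <- field + exp(-((X - cx)^2 + (Y - cy)^2) / (2 * s^2))
      }
      field[!tissue] <- -Inf
      thr <- sort(field[tissue], decreasing = TRUE)[nIron]
      iron <- field >= thr & tissue
      ## break exact ties beyond the requested count deterministically
      if (sum(iron) > nIron) {
        extra <- which(iron)[seq.int(nIron + 1L, sum(iron))]
        iron[extra] <- FALSE
      }
    }
    img <- array(0, c(w, h, 3L))
    cols <- list(background = c(246, 246, 244),
                 tissue = c(214, 152, 170),
                 iron = c(45, 65, 150))
    for (ch in 1:3) {
      plane <- matrix(cols$background[ch], w, h)
      plane[tissue] <- cols$tissue[ch]
      plane[iron] <- cols$iron[ch]
      plane <- plane + matrix(stats::rnorm(w * h, sd = jitterSD), w, h)
      img[, , ch] <- pmin(pmax(plane, 0), 255)
    }
    list(image = img, tissueMask = tissue, ironMask = iron)
  })
}

#' Tissue mask by luminance thresholding
#'
#' Otsu threshold on the luminance channel: tissue (and any stain on it) is
#' darker than the background and the open lumen, so thresholding keeps the
#' tissue annulus while the lumen -- which carries no tissue area -- stays
#' excluded, as it should for an area-ratio denominator.
#'
#' @param image array w x h x 3, 0-255.
#' @return logical matrix.
#' @export
tissueMaskOtsu <- function(image) {
  lum <- (0.299 * image[, , 1L] + 0.587 * image[, , 2L] +
            0.114 * image[, , 3L]) / 255
  th <- EBImage::otsu(EBImage::Image(lum))
  matrix(lum < th, nrow(lum), ncol(lum))
}

#' Segment iron by colour profile and compute the iron-area ratio
#'
#' Records all pixels within the perceptual tolerance of the reference
#' Perls'-blue colour (Euclidean distance in CIE Lab), intersects them with
#' the tissue mask, and divides by the overall tissue area.
#'
#' @param image array w x h x 3, 0-255.
#' @param profile a [colorProfile()].
#' @param tissueMask logical matrix; `NULL` derives one via
#'   [tissueMaskOtsu()].
#' @return list: `ironMask` (logical matrix), `ratio` (numeric in [0, 1]).
#' @export
segmentByProfile <- function(image, profile = colorProfile(),
                             tissueMask = NULL) {
  if (is.null(tissueMask)) tissueMask <- tissueMaskOtsu(image)
  if (!any(tissueMask)) stop("tissue mask is empty")
  px <- cbind(as.vector(image[, , 1L]), as.vector(image[, , 2L]),
              as.vector(image[, , 3L])) / 255
  lab <- grDevices::convertColor(px, from = "sRGB", to = "Lab")
  refLab <- grDevices::convertColor(matrix(profile$referenceRGB / 255, 1L),
                                    from = "sRGB", to = "Lab")
  d <- sqrt(rowSums(sweep(lab, 2L, as.numeric(refLab), "-")^2))
  ironMask <- matrix(d <= profile$tolerance, nrow(tissueMask),
                     ncol(tissueMask)) & tissueMask
  list(ironMask = ironMask, ratio = sum(ironMask) / sum(tissueMask))
}

#' Dice overlap of two masks
#'
#' 2 |A n B| / (|A| + |B|); 0 when both masks are empty (by convention).
#' Used to score colocalization of e.g. macrophage and iron masks.
#'
#' @param maskA,maskB logical arrays of equal shape.
#' @return numeric(1) in [0, 1].
#' @export
colocalize <- function(maskA, maskB) {
  if (!identical(dim(maskA), dim(maskB)))
    stop("mask shapes do not match")
  denom <- sum(maskA) + sum(maskB)
  if (denom == 0) return(0)
  2 * sum(maskA & maskB) / denom
}
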